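#' Build and validate a probe panel
#'
#' A probe panel is a data frame with one row per oligonucleotide probe:
#' columns `name` (unique identifier), `sequence` (uppercase IUPAC string)
#' and `tm` (reported melting temperature in degrees Celsius, may be NA).
#'
#' @param name Character vector of probe names.
#' @param sequence Character vector of IUPAC sequences.
#' @param tm Numeric vector of reported melting temperatures (NA allowed).
#' @return A validated `data.frame` of class `probe_panel`.
#' @export
probe_panel <- function(name, sequence, tm = NA_real_) {
  df <- data.frame(name = as.character(name),
                   sequence = as.character(sequence),
                   tm = as.numeric(tm),
                   stringsAsFactors = FALSE)
  validate_probe_panel(df)
}

#' @rdname probe_panel
#' @param panel A candidate probe panel data frame.
#' @export
validate_probe_panel <- function(panel) {
  stopifnot(is.data.frame(panel),
            all(c("name", "sequence") %in% names(panel)))
  if (is.null(panel$tm)) panel$tm <- NA_real_
  if (anyDuplicated(panel$name)) {
    stop("duplicate probe names: ",
         paste(unique(panel$name[duplicated(panel$name)]), collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(panel))) {
    assert_iupac(panel$sequence[i], sprintf("probe '%s'", panel$name[i]))
  }
  bad_tm <- !is.na(panel$tm) & (!is.finite(panel$tm) |
                                panel$tm < 40 | panel$tm > 80)
  if (any(bad_tm)) {
    stop("reported Tm outside 40-80 degC for probe(s): ",
         paste(panel$name[bad_tm], collapse = ", "), call. = FALSE)
  }
  class(panel) <- c("probe_panel", "data.frame")
  panel
}

#' Read / write a probe panel as TSV
#'
#' Canonical on-disk format: tab-separated, header `name`, `sequence`, `tm`.
#'
#' @param path File path.
#' @return `read_probe_tsv()` returns a validated probe panel.
#' @export
read_probe_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  if (!all(c("name", "sequence") %in% names(df))) {
    stop("probe TSV must have columns 'name' and 'sequence'", call. = FALSE)
  }
  df$tm <- if ("tm" %in% names(df)) suppressWarnings(as.numeric(df$tm)) else NA_real_
  validate_probe_panel(df[, c("name", "sequence", "tm")])
}

#' @rdname read_probe_tsv
#' @param panel Probe panel to write.
#' @export
write_probe_tsv <- function(panel, path) {
  panel <- validate_probe_panel(as.data.frame(panel))
  utils::write.table(panel, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' The packaged Limnohabitans RLBH probe panel
#'
#' Loads the 18 group-specific probes targeting diagnostic sites on the
#' 16S-23S rRNA ITS of *Limnohabitans* genotype groups, together with their
#' reported melting temperatures. Probes whose names carry a `+` target
#' genotypes of the R-BT subcluster; `Lim4AusCurv+Lim3+` is a combined probe
#' covering both of its constituent groups.
#'
#' @return A `probe_panel` data frame with 18 rows.
#' @export
load_probe_panel <- function() {
  read_probe_tsv(system.file("extdata", "probes_limnohabitans.tsv",
                             package = "limnodiv", mustWork = TRUE))
}

#' The packaged ITS primer pairs
#'
#' Two PCR primer pairs: the *Limnohabitans*-specific ITS pair (forward
#' Lim379F, reverse LimCurvITS-R; product around 1,900 bp) and the universal
#' bacterial ITS pair (1406f / 23Sr) used as the outer pair of a nested PCR
#' when template is scarce.
#'
#' @return Data frame with columns `label`, `forward`, `reverse`.
#' @export
load_primer_pairs <- function() {
  df <- utils::read.delim(system.file("extdata", "primers_its.tsv",
                                      package = "limnodiv", mustWork = TRUE),
                          stringsAsFactors = FALSE)
  for (i in seq_len(nrow(df))) {
    assert_iupac(df$forward[i], sprintf("forward primer '%s'", df$label[i]))
    assert_iupac(df$reverse[i], sprintf("reverse primer '%s'", df$label[i]))
  }
  df
}

#' Primer pair constructor
#'
#' @param forward,reverse IUPAC primer sequences, written 5' to 3'.
#' @param label Identifier for the pair.
#' @return A list of class `primer_pair`.
#' @export
primer_pair <- function(forward, reverse, label = "pair") {
  assert_iupac(forward, "forward primer")
  assert_iupac(reverse, "reverse primer")
  structure(list(forward = forward, reverse = reverse, label = label),
            class = "primer_pair")
}

#' Oligonucleotide melting temperature
#'
#' Two estimators: the Wallace rule (2 degC per A/T, 4 degC per G/C; only
#' sensible for short oligos) and a nearest-neighbor model using the
#' SantaLucia (1998) unified parameter set with monovalent-salt entropy
#' correction. Degenerate IUPAC letters are handled by averaging the
#' estimate over all concrete expansions of the sequence.
#'
#' The nearest-neighbor defaults (0.25 uM oligo, 50 mM Na+) are typical
#' hybridization-buffer conditions; reported panel Tm values were produced
#' by an unspecified method, so computed values are for comparison only and
#' are never asserted equal to reported ones.
#'
#' @param sequence IUPAC nucleotide string.
#' @param method `"wallace"` or `"nearest-neighbor"`.
#' @param conc_m Oligo concentration in mol/L (nearest-neighbor only).
#' @param na_m Monovalent cation concentration in mol/L.
#' @return Numeric Tm in degrees Celsius, with attribute `method`.
#' @examples
#' melting_temperature("ACGT", "wallace") # 12
#' @export
melting_temperature <- function(sequence,
                                method = c("nearest-neighbor", "wallace"),
                                conc_m = 0.25e-6, na_m = 0.05) {
  method <- match.arg(method)
  assert_iupac(sequence, "sequence")
  seqs <- iupac_expansions(sequence)
  tm <- mean(vapply(seqs, function(s) {
    if (method == "wallace") tm_wallace(s) else tm_nn(s, conc_m, na_m)
  }, numeric(1L)))
  structure(tm, method = method)
}

tm_wallace <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  2 * sum(chars %in% c("A", "T")) + 4 * sum(chars %in% c("G", "C"))
}

# SantaLucia (1998) unified NN parameters: dH kcal/mol, dS cal/(mol K).
.NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
            CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
            TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2,
            CC = -8.0)
.NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
            CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
            TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
            CC = -19.9)

tm_nn <- function(s, conc_m, na_m) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n < 2L) stop("nearest-neighbor Tm needs >= 2 bases", call. = FALSE)
  steps <- paste0(chars[-n], chars[-1L])
  dh <- sum(.NN_DH[steps])
  ds <- sum(.NN_DS[steps])
  # initiation terms per terminal base pair
  for (end in chars[c(1L, n)]) {
    if (end %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else                      { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  ds <- ds + 0.368 * (n - 1L) * log(na_m)   # monovalent-salt correction
  r_gas <- 1.987                            # cal/(mol K)
  tm_k <- dh * 1000 / (ds + r_gas * log(conc_m / 4))
  tm_k - 273.15
}
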