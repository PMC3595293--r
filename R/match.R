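#' In-silico hybridization of degenerate probes to ITS sequences
#'
#' Slides a probe across a target sequence and reports every window whose
#' mismatch count does not exceed `max_mismatches`. Degeneracy semantics
#' mirror how RLBH probes are designed: a degenerate letter in the PROBE
#' matches any base of its IUPAC set, while an `N` in the TARGET is treated
#' as sequencing uncertainty and matches nothing unless
#' `target_n = "any"`.
#'
#' Both strands are searched by default — the hybridized amplicon is
#' denatured double-stranded DNA, so either strand can bind the membrane
#' probe. Antisense hits are reported in sense-strand coordinates of the
#' window start. Coordinates are 0-based, half-open throughout.
#'
#' @param probe IUPAC probe sequence (character scalar) or a single row of a
#'   [probe_panel()].
#' @param target Target sequence (A/C/G/T/N character scalar).
#' @param max_mismatches Maximum tolerated mismatches per window (>= 0).
#' @param strands `"both"`, `"sense"` or `"antisense"`.
#' @param target_n `"none"` (default: target N never matches) or `"any"`.
#' @return Data frame with columns `position` (0-based window start on the
#'   sense strand), `strand` (`"sense"`/`"antisense"`) and `mismatches`,
#'   sorted by (position, strand).
#' @export
match_probe <- function(probe, target, max_mismatches = 0L,
                        strands = c("both", "sense", "antisense"),
                        target_n = c("none", "any")) {
  strands <- match.arg(strands)
  target_n <- match.arg(target_n)
  if (is.data.frame(probe)) probe <- probe$sequence[1L]
  assert_iupac(probe, "probe")
  assert_iupac(target, "target", strict = TRUE)
  stopifnot(max_mismatches >= 0L)

  out <- list()
  if (strands %in% c("both", "sense")) {
    pos <- scan_windows(probe, target, max_mismatches, target_n)
    if (nrow(pos) > 0L) pos$strand <- "sense"
    out$sense <- pos
  }
  if (strands %in% c("both", "antisense")) {
    pos <- scan_windows(reverse_complement(probe), target,
                        max_mismatches, target_n)
    if (nrow(pos) > 0L) pos$strand <- "antisense"
    out$antisense <- pos
  }
  hits <- do.call(rbind, out)
  if (is.null(hits) || nrow(hits) == 0L) {
    return(data.frame(position = integer(0), strand = character(0),
                      mismatches = integer(0)))
  }
  hits <- hits[order(hits$position, hits$strand), c("position", "strand",
                                                    "mismatches")]
  rownames(hits) <- NULL
  hits
}

# Core window scan: probe letters index a lookup table of allowed target
# bases; a window matches when its mismatch count is within budget.
scan_windows <- function(probe, target, max_mismatches, target_n) {
  plen <- nchar(probe)
  tlen <- nchar(target)
  empty <- data.frame(position = integer(0), mismatches = integer(0))
  if (plen > tlen) return(empty)

  t_chars <- strsplit(target, "", fixed = TRUE)[[1L]]
  t_code <- match(t_chars, c("A", "C", "G", "T", "N"))
  p_sets <- lapply(strsplit(probe, "", fixed = TRUE)[[1L]], expand_iupac)

  # allowed[b, j]: may target base b sit under probe position j?
  allowed <- matrix(FALSE, nrow = 5L, ncol = plen)
  bases <- c("A", "C", "G", "T")
  for (j in seq_len(plen)) {
    allowed[match(p_sets[[j]], bases), j] <- TRUE
    allowed[5L, j] <- target_n == "any"
  }

  nwin <- tlen - plen + 1L
  starts <- seq_len(nwin)
  idx <- outer(seq_len(plen) - 1L, starts, `+`)          # plen x nwin
  hit_codes <- matrix(t_code[idx], nrow = plen)
  ok <- matrix(allowed[cbind(as.vector(hit_codes),
                             rep(seq_len(plen), times = nwin))],
               nrow = plen)
  mm <- colSums(!ok)
  keep <- which(mm <= max_mismatches)
  data.frame(position = keep - 1L, mismatches = as.integer(mm[keep]))
}

#' In-silico PCR on a single template
#'
#' Pairs every sense-strand binding site of the forward primer with every
#' antisense binding site of the reverse primer and emits the implied
#' product whenever its length — forward-site start to the end of the
#' reverse-primer site — falls within `length_bounds`. Nested PCR is plain
#' function composition: run the outer pair, then run the inner pair on
#' each outer amplicon.
#'
#' @param pair A [primer_pair()] (or list with `forward`/`reverse`).
#' @param target Template sequence (sense strand).
#' @param max_mismatches Mismatch budget per primer site.
#' @param length_bounds Numeric `c(min, max)` product length in bp.
#' @return Data frame with columns `start`, `end` (0-based half-open on the
#'   sense strand), `length`, `sequence`; zero rows when nothing amplifies.
#' @export
in_silico_pcr <- function(pair, target, max_mismatches = 0L,
                          length_bounds = c(100, 5000)) {
  fwd <- pair$forward
  rev_ <- pair$reverse
  stopifnot(length(length_bounds) == 2L, length_bounds[1L] <= length_bounds[2L])
  if (length_bounds[1L] < nchar(fwd) + nchar(rev_)) {
    stop("minimum product length must be >= combined primer length",
         call. = FALSE)
  }
  f_hits <- match_probe(fwd, target, max_mismatches, strands = "sense")
  r_hits <- match_probe(rev_, target, max_mismatches, strands = "antisense")
  out <- data.frame(start = integer(0), end = integer(0),
                    length = integer(0), sequence = character(0))
  if (nrow(f_hits) == 0L || nrow(r_hits) == 0L) return(out)
  rlen <- nchar(rev_)
  for (fs in f_hits$position) {
    for (rs in r_hits$position) {
      end <- rs + rlen               # product runs through the reverse site
      len <- end - fs
      if (len >= length_bounds[1L] && len <= length_bounds[2L]) {
        out <- rbind(out, data.frame(
          start = fs, end = end, length = len,
          sequence = substr(target, fs + 1L, end)))
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Probe-panel coverage over a sequence collection
#'
#' For every probe, the set of records it hits (either strand counts); the
#' panel-level summary is the fraction of records hit by at least one probe
#' and the mean number of target records per probe. This is the in-silico
#' analogue of asking how much of a culture collection an RLBH panel can
#' detect.
#'
#' @param panel A [probe_panel()].
#' @param records An ITS record collection (see [its_records()]).
#' @param max_mismatches Mismatch budget (0 = exact, the design default).
#' @return List of class `coverage_report`: `per_probe_targets` (named list
#'   of record-id character vectors), `n_records`, `fraction_covered`,
#'   `mean_targets_per_probe`, plus a tidy `summary` data frame.
#' @export
compute_coverage <- function(panel, records, max_mismatches = 0L) {
  panel <- validate_probe_panel(as.data.frame(panel))
  records <- validate_its_records(records)
  if (nrow(panel) == 0L) stop("probe panel is empty", call. = FALSE)
  if (nrow(records) == 0L) stop("record collection is empty", call. = FALSE)

  targets <- lapply(seq_len(nrow(panel)), function(i) {
    hit <- vapply(seq_len(nrow(records)), function(r) {
      nrow(match_probe(panel$sequence[i], records$sequence[r],
                       max_mismatches, strands = "both")) > 0L
    }, logical(1L))
    records$id[hit]
  })
  names(targets) <- panel$name
  covered <- unique(unlist(targets, use.names = FALSE))
  res <- list(
    per_probe_targets = targets,
    n_records = nrow(records),
    fraction_covered = length(covered) / nrow(records),
    mean_targets_per_probe = mean(lengths(targets)),
    summary = data.frame(probe = panel$name,
                         n_targets = unname(lengths(targets)))
  )
  class(res) <- "coverage_report"
  res
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("Probe-panel coverage: %d probes vs %d records\n",
              nrow(x$summary), x$n_records))
  cat(sprintf("  fraction covered       : %.3f\n", x$fraction_covered))
  cat(sprintf("  mean targets per probe : %.2f\n", x$mean_targets_per_probe))
  invisible(x)
}
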