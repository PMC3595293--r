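#' IUPAC nucleotide degeneracy codes
#'
#' Named list mapping each of the 15 IUPAC nucleotide letters to the set of
#' canonical bases it stands for. Probes in RLBH panels are routinely written
#' with degeneracy codes (R, Y, M, K, ...) so that one oligo covers several
#' closely related genotypes.
#'
#' @format Named list of character vectors.
#' @export
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), M = c("A", "C"), K = c("G", "T"),
  S = c("C", "G"), W = c("A", "T"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

#' Expand one IUPAC letter to its canonical base set
#'
#' @param code Single uppercase IUPAC nucleotide letter.
#' @return Character vector of canonical bases (subset of A, C, G, T).
#' @examples
#' expand_iupac("R") # A, G
#' @export
expand_iupac <- function(code) {
  if (!is.character(code) || length(code) != 1L || nchar(code) != 1L) {
    stop("`code` must be a single IUPAC letter", call. = FALSE)
  }
  set <- IUPAC_CODES[[code]]
  if (is.null(set)) {
    stop(sprintf("invalid IUPAC letter: '%s'", code), call. = FALSE)
  }
  set
}

#' Check that a sequence uses only IUPAC letters
#'
#' @param x Character scalar, an uppercase nucleotide sequence.
#' @param what Label used in error messages.
#' @param strict If TRUE only canonical A/C/G/T/N are allowed (target
#'   sequences); otherwise all 15 IUPAC letters (probes, primers).
#' @return `x`, invisibly, after validation.
#' @export
assert_iupac <- function(x, what = "sequence", strict = FALSE) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L) {
    stop(sprintf("%s must be a non-empty string", what), call. = FALSE)
  }
  if (x != toupper(x)) {
    stop(sprintf("%s must be uppercase: '%s'", what, x), call. = FALSE)
  }
  letters_ok <- if (strict) c("A", "C", "G", "T", "N") else names(IUPAC_CODES)
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), letters_ok)
  if (length(bad) > 0L) {
    stop(sprintf("%s contains invalid letter(s): %s", what,
                 paste(sQuote(bad), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Reverse complement of an IUPAC sequence
#'
#' Complements degeneracy codes correctly (R <-> Y, B <-> V, ...).
#'
#' @param x Character scalar nucleotide sequence (IUPAC letters).
#' @return Reverse-complemented sequence as a character scalar.
#' @export
reverse_complement <- function(x) {
  assert_iupac(x, "sequence")
  comp <- chartr("ACGTRYMKSWBDHVN", "TGCAYRKMSWVHDBN", x)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Enumerate every concrete expansion of a degenerate sequence
#'
#' @param x IUPAC sequence.
#' @param max_expansions Guard against combinatorial blow-up.
#' @return Character vector of all A/C/G/T sequences matching `x`.
#' @export
iupac_expansions <- function(x, max_expansions = 4096L) {
  assert_iupac(x, "sequence")
  sets <- lapply(strsplit(x, "", fixed = TRUE)[[1L]], expand_iupac)
  n <- prod(vapply(sets, length, integer(1L)))
  if (n > max_expansions) {
    stop(sprintf("sequence has %d expansions (limit %d)", n, max_expansions),
         call. = FALSE)
  }
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  apply(grid[, rev(seq_along(sets)), drop = FALSE], 1L, paste, collapse = "")
}

# Evaluate `code` with a temporary, seeded RNG state; the caller's RNG
# stream is untouched. seed = NULL leaves the global stream in charge.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Half-up decimal rounding (base round() is half-even); used wherever
# printed percentages are reproduced.
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
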