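# Independent brute-force oracles. These deliberately re-derive everything
# from first principles (own IUPAC table, all-expansion enumeration, full
# permutation scans) so they share no code path with the implementation.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), M = c("A", "C"), K = c("G", "T"),
  S = c("C", "G"), W = c("A", "T"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_expansions <- function(seq) {
  sets <- ORACLE_IUPAC[strsplit(seq, "")[[1]]]
  out <- ""
  for (s in sets) out <- as.vector(outer(out, s, paste0))
  out
}

oracle_revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# window mismatch count = min Hamming distance over all probe expansions;
# a target N never equals an expansion letter, matching the default
# "target N matches nothing" semantics
oracle_match <- function(probe, target, max_mm, strands = "both") {
  hits <- data.frame(position = integer(0), strand = character(0),
                     mismatches = integer(0))
  scan <- function(p, strand) {
    exps <- strsplit(oracle_expansions(p), "")
    tc <- strsplit(target, "")[[1]]
    plen <- nchar(p)
    for (s in seq_len(nchar(target) - plen + 1)) {
      win <- tc[s:(s + plen - 1)]
      mm <- min(vapply(exps, function(e) sum(e != win), numeric(1)))
      if (mm <= max_mm) {
        hits[nrow(hits) + 1, ] <<- list(s - 1L, strand, as.integer(mm))
      }
    }
  }
  if (nchar(probe) <= nchar(target)) {
    if (strands %in% c("both", "sense")) scan(probe, "sense")
    if (strands %in% c("both", "antisense")) {
      scan(oracle_revcomp(probe), "antisense")
    }
  }
  hits <- hits[order(hits$position, hits$strand), ]
  rownames(hits) <- NULL
  hits
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_probe <- function(n) {
  # mostly concrete letters, a sprinkle of degeneracy
  letters_pool <- c(rep(c("A", "C", "G", "T"), 10), "R", "Y", "M", "K",
                    "S", "W", "B", "D", "H", "V", "N")
  paste(sample(letters_pool, n, replace = TRUE), collapse = "")
}

# straightforward moving mean by explicit summation
oracle_gliding <- function(x, window) {
  h <- (window - 1) / 2
  n <- length(x)
  sapply(seq_len(n), function(i) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    sum(x[lo:hi]) / (hi - lo + 1)
  })
}

# all permutations of 1..n by recursive prefix growth (independent of the
# package's enumerator)
oracle_perms <- function(n) {
  grow <- function(prefix, remaining) {
    if (length(remaining) == 0) return(list(prefix))
    out <- list()
    for (r in remaining) {
      out <- c(out, grow(c(prefix, r), setdiff(remaining, r)))
    }
    out
  }
  grow(integer(0), seq_len(n))
}

# exhaustive Mantel p by rebuilding the permuted matrix wholesale
oracle_mantel_exhaustive <- function(d1, d2, tail = "two-sided") {
  n <- nrow(d1)
  lt <- lower.tri(d1)
  r_obs <- cor(d1[lt], d2[lt])
  rs <- sapply(oracle_perms(n), function(p) {
    dp <- d2[p, p]
    cor(d1[lt], dp[lt])
  })
  hit <- switch(tail,
    "two-sided" = abs(rs) >= abs(r_obs) - 1e-12,
    "one-sided-positive" = rs >= r_obs - 1e-12,
    "one-sided-negative" = rs <= r_obs + 1e-12)
  mean(hit)
}

random_score_matrix <- function(n_hab, n_probe) {
  m <- matrix(sample(0:3, n_hab * n_probe, replace = TRUE,
                     prob = c(0.5, 0.2, 0.2, 0.1)),
              nrow = n_hab,
              dimnames = list(sprintf("H%03d", seq_len(n_hab)),
                              sprintf("P%02d", seq_len(n_probe))))
  score_matrix(m)
}
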