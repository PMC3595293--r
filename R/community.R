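#' Per-habitat detection counts
#'
#' Number of probe-defined groups detected in each habitat (row sums of the
#' detection/no-detection matrix).
#'
#' @param b A `binary_matrix` (see [binarize()]).
#' @return Named integer vector, one count per habitat.
#' @export
detection_counts <- function(b) {
  stopifnot(is.matrix(b), all(b %in% 0:1))
  rowSums(unclass(b))
}

#' Co-occurrence histogram
#'
#' How many habitats host exactly k probe-defined groups, for k = 0 up to
#' the panel size.
#'
#' @param b A `binary_matrix`.
#' @return Data frame with columns `k` and `n_habitats`; counts sum to the
#'   number of habitats.
#' @export
cooccurrence_histogram <- function(b) {
  k <- detection_counts(b)
  ks <- 0:ncol(b)
  data.frame(k = ks,
             n_habitats = vapply(ks, function(x) sum(k == x), integer(1L)))
}

#' Percentage with half-up rounding
#'
#' `100 * count / total`, rounded half-up to `decimals` places — the
#' convention used for printed survey percentages (e.g. 15 of 161 habitats
#' = 9.3%).
#'
#' @param count Non-negative integer, `count <= total`.
#' @param total Positive integer.
#' @param decimals Decimal places to keep.
#' @return Numeric percentage.
#' @export
percentage <- function(count, total, decimals = 1L) {
  stopifnot(length(count) == 1L, length(total) == 1L)
  if (total <= 0) stop("total must be positive", call. = FALSE)
  if (count < 0 || count > total) {
    stop("count must be in [0, total]", call. = FALSE)
  }
  round_half_up(100 * count / total, decimals)
}

#' Richness summary by pH class
#'
#' Mean and SD of the per-habitat detection count within user-supplied pH
#' classes. Classes are half-open `[lo, hi)` except the last, which closes
#' at the top so the gradient maximum is included. Habitats outside all
#' classes are excluded (their number is messaged).
#'
#' @param b A `binary_matrix` aligned with `habitats`.
#' @param habitats A `habitat_table`.
#' @param class_edges Strictly increasing pH breakpoints; the survey default
#'   `c(3.8, 4.8, 5.8, 6.8, 7.8, 9.1)` gives classes of roughly one pH unit.
#' @return Data frame: `class_low`, `class_high`, `n`, `mean_k`, `sd_k`
#'   (NA when n = 1).
#' @export
richness_by_ph_class <- function(b, habitats,
                                 class_edges = c(3.8, 4.8, 5.8, 6.8, 7.8, 9.1)) {
  stopifnot(length(class_edges) >= 2L, all(diff(class_edges) > 0))
  al <- align_scores(b, habitats)
  k <- detection_counts(al$scores)
  ph <- al$habitats$ph
  n_classes <- length(class_edges) - 1L
  idx <- rep(NA_integer_, length(ph))
  for (ci in seq_len(n_classes)) {
    hi_ok <- if (ci == n_classes) ph <= class_edges[ci + 1L]
             else ph < class_edges[ci + 1L]
    idx[ph >= class_edges[ci] & hi_ok] <- ci
  }
  if (any(is.na(idx))) {
    message(sprintf("richness_by_ph_class: %d habitat(s) outside all classes",
                    sum(is.na(idx))))
  }
  out <- do.call(rbind, lapply(seq_len(n_classes), function(ci) {
    kk <- k[which(idx == ci)]
    data.frame(class_low = class_edges[ci], class_high = class_edges[ci + 1L],
               n = length(kk),
               mean_k = if (length(kk) > 0L) mean(kk) else NA_real_,
               sd_k = if (length(kk) > 1L) stats::sd(kk) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Mean richness below and above a pH boundary
#'
#' The headline acid/alkaline contrast: mean detection count over habitats
#' with pH < `boundary` versus pH >= `boundary` (the boundary habitat goes
#' to the upper class, half-open convention).
#'
#' @param b A `binary_matrix` aligned with `habitats`.
#' @param habitats A `habitat_table`.
#' @param boundary pH split point.
#' @return List with `mean_below`, `mean_above`, `ratio` (above/below),
#'   `n_below`, `n_above`.
#' @export
richness_split <- function(b, habitats, boundary = 7.0) {
  al <- align_scores(b, habitats)
  k <- detection_counts(al$scores)
  lo <- al$habitats$ph < boundary
  list(mean_below = mean(k[lo]), mean_above = mean(k[!lo]),
       ratio = mean(k[!lo]) / mean(k[lo]),
       n_below = sum(lo), n_above = sum(!lo))
}

#' Pairwise niche overlap between probe-defined groups
#'
#' For every pair of probes: the number of habitats where both are
#' detected, a normalized overlap index, and a complete-separation flag
#' (both groups detected somewhere, yet never together) — the pattern that
#' signals non-overlapping niches.
#'
#' @param b A `binary_matrix`.
#' @param index `"jaccard"` (shared / union, 0 when both sets empty) or
#'   `"shared-count"` (index = shared habitats / min set size).
#' @return List of class `overlap_matrix`: `shared` (count matrix), `index`
#'   (normalized matrix), `separated` (logical matrix), `index_type`.
#' @export
pairwise_overlap <- function(b, index = c("jaccard", "shared-count")) {
  index <- match.arg(index)
  stopifnot(is.matrix(b), all(b %in% 0:1))
  x <- unclass(b)
  p <- ncol(x)
  shared <- t(x) %*% x                       # |A intersect B|
  sizes <- diag(shared)
  uni <- outer(sizes, sizes, `+`) - shared   # |A union B|
  idx <- matrix(0, p, p, dimnames = dimnames(shared))
  if (index == "jaccard") {
    nz <- uni > 0
    idx[nz] <- shared[nz] / uni[nz]
  } else {
    mins <- pmin(outer(sizes, rep(1, p)), outer(rep(1, p), sizes))
    nz <- mins > 0
    idx[nz] <- shared[nz] / mins[nz]
  }
  separated <- shared == 0 & outer(sizes > 0, sizes > 0, `&`)
  diag(separated) <- FALSE
  structure(list(shared = shared, index = idx, separated = separated,
                 index_type = index),
            class = "overlap_matrix")
}
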