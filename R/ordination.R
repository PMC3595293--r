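#' Community similarity between habitats
#'
#' Pairwise similarity of habitats from their 0/1 detection profiles.
#' `simple-matching` is the fraction of probes on which two habitats agree
#' (both detected or both not); `jaccard` compares the detection sets and
#' is 0 when both are empty. `1 - similarity` is returned alongside as a
#' community-dissimilarity matrix.
#'
#' @param b A `binary_matrix` with >= 2 habitats.
#' @param method `"simple-matching"` (default) or `"jaccard"`.
#' @return List with `similarity` and `distance` (both square, habitat ids
#'   as dimnames) and `method`.
#' @export
community_similarity <- function(b, method = c("simple-matching", "jaccard")) {
  method <- match.arg(method)
  stopifnot(is.matrix(b), all(b %in% 0:1))
  if (nrow(b) < 2L) stop("need at least 2 habitats", call. = FALSE)
  x <- unclass(b)
  n <- nrow(x); p <- ncol(x)
  both <- x %*% t(x)                        # probes detected in both
  sizes <- diag(both)
  if (method == "simple-matching") {
    neither <- (1 - x) %*% t(1 - x)
    s <- (both + neither) / p
  } else {
    uni <- outer(sizes, sizes, `+`) - both
    s <- matrix(0, n, n, dimnames = dimnames(both))
    nz <- uni > 0
    s[nz] <- both[nz] / uni[nz]
    diag(s) <- 1                            # a habitat matches itself
  }
  dimnames(s) <- list(rownames(x), rownames(x))
  list(similarity = s, distance = 1 - s, method = method)
}

#' Geographic distance matrix between habitats
#'
#' `equator-1d` reproduces the legacy survey transform: each habitat is
#' collapsed to its distance from the equator (latitude times 111,319.49
#' m/degree, longitude discarded) and distances are absolute differences of
#' that single coordinate. `great-circle` is the recommended general mode:
#' haversine distance on a sphere of radius 6,371,000 m.
#'
#' @param habitats A `habitat_table` with coordinates.
#' @param method `"great-circle"` (default) or `"equator-1d"`.
#' @return Square matrix of distances in meters, habitat ids as dimnames.
#' @export
geo_distance <- function(habitats, method = c("great-circle", "equator-1d")) {
  method <- match.arg(method)
  h <- validate_habitat_table(as.data.frame(habitats))
  missing <- is.na(h$latitude) | (method == "great-circle" & is.na(h$longitude))
  if (any(missing)) {
    stop("missing coordinates for habitat(s): ",
         paste(h$habitat_id[missing], collapse = ", "), call. = FALSE)
  }
  n <- nrow(h)
  if (method == "equator-1d") {
    pos <- h$latitude * 111319.49
    d <- abs(outer(pos, pos, `-`))
  } else {
    d <- matrix(0, n, n)
    pair <- which(upper.tri(d), arr.ind = TRUE)
    dd <- geosphere::distHaversine(
      cbind(h$longitude[pair[, 1L]], h$latitude[pair[, 1L]]),
      cbind(h$longitude[pair[, 2L]], h$latitude[pair[, 2L]]),
      r = 6371000)
    d[pair] <- dd
    d <- d + t(d)
  }
  dimnames(d) <- list(h$habitat_id, h$habitat_id)
  d
}

#' Environmental-delta distance matrix
#'
#' Absolute pairwise differences of one covariate (pH by default); used to
#' ask whether habitat *types* — not just communities — are spatially
#' structured.
#'
#' @param habitats A `habitat_table`.
#' @param variable Covariate column name.
#' @return Square matrix of absolute differences.
#' @export
env_delta_matrix <- function(habitats, variable = "ph") {
  h <- validate_habitat_table(as.data.frame(habitats))
  v <- h[[variable]]
  if (is.null(v)) stop("unknown covariate: ", variable, call. = FALSE)
  if (any(is.na(v))) {
    stop("missing ", variable, " for habitat(s): ",
         paste(h$habitat_id[is.na(v)], collapse = ", "), call. = FALSE)
  }
  d <- abs(outer(v, v, `-`))
  dimnames(d) <- list(h$habitat_id, h$habitat_id)
  d
}

#' Permutation Mantel test
#'
#' Pearson correlation between the lower triangles of two distance
#' matrices; the null distribution is built by jointly permuting rows and
#' columns of `d2`. The p-value uses the add-one estimator
#' `(count + 1) / (n_permutations + 1)` so it can never be exactly zero.
#' With `method = "exhaustive"` (feasible for small n) every one of the n!
#' relabelings is evaluated and p is the exact proportion meeting the tail
#' criterion (the identity included).
#'
#' @param d1,d2 Square symmetric matrices with matching dimnames/order.
#' @param n_permutations Number of random relabelings (sampled mode).
#' @param tail `"two-sided"`, `"one-sided-positive"` or
#'   `"one-sided-negative"` (distance decay of similarity shows up as a
#'   negative correlation between community similarity and distance).
#' @param seed Integer seed for reproducibility (optional).
#' @param method `"sampled"` or `"exhaustive"`.
#' @return List of class `mantel_result`: `r`, `p`, `n_permutations`,
#'   `tail`, `seed`, `method`.
#' @export
mantel <- function(d1, d2, n_permutations = 10000L,
                   tail = c("two-sided", "one-sided-positive",
                            "one-sided-negative"),
                   seed = NULL, method = c("sampled", "exhaustive")) {
  tail <- match.arg(tail)
  method <- match.arg(method)
  stopifnot(is.matrix(d1), is.matrix(d2), nrow(d1) == ncol(d1),
            all(dim(d1) == dim(d2)))
  n <- nrow(d1)
  if (n < 4L) stop("need at least 4 objects", call. = FALSE)
  if (!is.null(dimnames(d1)) && !is.null(dimnames(d2)) &&
      !identical(rownames(d1), rownames(d2))) {
    stop("d1 and d2 must be ordered over the same ids", call. = FALSE)
  }
  lt <- which(lower.tri(d1))
  v1 <- d1[lt]
  if (stats::sd(v1) == 0 || stats::sd(d2[lt]) == 0) {
    stop("zero variance in a distance matrix; correlation undefined",
         call. = FALSE)
  }
  # index arithmetic: lower-triangle entry -> (row, col) of d2 under a
  # permutation, evaluated with one vectorized lookup per relabeling
  rc <- which(lower.tri(d1), arr.ind = TRUE)
  r_obs <- stats::cor(v1, d2[lt])
  perm_r <- function(perm) {
    stats::cor(v1, d2[cbind(perm[rc[, 1L]], perm[rc[, 2L]])])
  }
  crit <- switch(tail,
    "two-sided" = function(r) abs(r) >= abs(r_obs) - 1e-12,
    "one-sided-positive" = function(r) r >= r_obs - 1e-12,
    "one-sided-negative" = function(r) r <= r_obs + 1e-12)
  if (method == "exhaustive") {
    if (n > 8L) stop("exhaustive mode limited to n <= 8", call. = FALSE)
    perms <- all_permutations(n)
    rs <- vapply(perms, perm_r, numeric(1L))
    p <- mean(crit(rs))
    n_used <- length(perms)
  } else {
    rs <- with_seed(seed, vapply(seq_len(n_permutations), function(i) {
      perm_r(sample.int(n))
    }, numeric(1L)))
    p <- (sum(crit(rs)) + 1) / (n_permutations + 1)
    n_used <- n_permutations
  }
  structure(list(r = r_obs, p = p, n_permutations = n_used, tail = tail,
                 seed = seed, method = method),
            class = "mantel_result")
}

# all permutations of 1..n as a list (n! entries; small n only)
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    for (s in sub) {
      k <- k + 1L
      out[[k]] <- append(s + (s >= i), i, after = 0L)
    }
  }
  out
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test (%s, %s): r = %.4f, p = %.4g (%d permutations)\n",
              x$method, x$tail, x$r, x$p, x$n_permutations))
  invisible(x)
}

#' PCA on detection/no-detection data
#'
#' Column-centered (optionally unit-scaled) principal component analysis of
#' a binary detection matrix, via the singular value decomposition. Axis
#' signs are fixed deterministically: the largest-magnitude loading of each
#' axis is made positive.
#'
#' @param b A `binary_matrix` (>= 2 habitats, >= 2 probes, at least one
#'   probe with varying detections).
#' @param scale Unit-scale columns before decomposition (zero-variance
#'   columns make this an error).
#' @return List of class `pca_result`: `scores` (habitats x axes),
#'   `loadings` (probes x axes), `explained_fraction`.
#' @export
pca_binary <- function(b, scale = FALSE) {
  stopifnot(is.matrix(b))
  x <- unclass(b)
  storage.mode(x) <- "double"
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop("need >= 2 habitats and >= 2 probes", call. = FALSE)
  }
  vars <- apply(x, 2L, stats::var)
  if (all(vars == 0)) stop("all probe columns are constant", call. = FALSE)
  if (scale && any(vars == 0)) {
    stop("zero-variance column(s) cannot be unit-scaled: ",
         paste(colnames(x)[vars == 0], collapse = ", "), call. = FALSE)
  }
  fit <- stats::prcomp(x, center = TRUE, scale. = scale)
  flip <- apply(fit$rotation, 2L, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  scores <- sweep(fit$x, 2L, flip, `*`)
  loadings <- sweep(fit$rotation, 2L, flip, `*`)
  structure(list(scores = scores, loadings = loadings,
                 explained_fraction = fit$sdev^2 / sum(fit$sdev^2)),
            class = "pca_result")
}

#' Cluster probes by occurrence similarity
#'
#' Hierarchical clustering (average linkage) of probe detection columns on
#' correlation distance (1 - Pearson r), cut at `k` clusters — the
#' "environmentally similar" grouping of probe-defined groups. Probes are
#' ordered lexicographically before clustering so ties break
#' deterministically; probes never detected (or detected everywhere, i.e.
#' zero column variance) cannot be placed and are returned separately.
#'
#' @param b A `binary_matrix`.
#' @param k Number of clusters.
#' @return List with `assignment` (named integer vector), `unplaced`
#'   (character vector of zero-variance probes), `tree` (the hclust object).
#' @export
cluster_probes <- function(b, k = 4L) {
  stopifnot(is.matrix(b), all(b %in% 0:1))
  x <- unclass(b)
  storage.mode(x) <- "double"
  vars <- apply(x, 2L, stats::var)
  usable <- sort(colnames(x)[vars > 0])
  if (k < 1L || k > length(usable)) {
    stop(sprintf("k must be in 1..%d (probes with varying detections)",
                 length(usable)), call. = FALSE)
  }
  xs <- x[, usable, drop = FALSE]
  d <- stats::as.dist(1 - stats::cor(xs))
  tree <- stats::hclust(d, method = "average")
  assignment <- stats::cutree(tree, k = k)
  list(assignment = assignment,
       unplaced = setdiff(colnames(x), usable),
       tree = tree)
}
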