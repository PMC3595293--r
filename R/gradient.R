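#' Configuration for pH-gradient profiling
#'
#' The gradient algorithm bins habitats into narrow pH classes (default
#' width 0.2, bin edges anchored at pH 0 with half-open `[lo, hi)`
#' intervals), sums the ordinal scores per class, expresses each class sum
#' as a fraction of the probe's total score over all habitats, rescales by
#' the maximum so the best class reads 1, and finally smooths with a
#' centered gliding average of 7 values (middle +/- 3).
#'
#' @param class_width pH units per class (> 0).
#' @param class_origin pH anchor for the bin edges.
#' @param window Odd smoothing-window width (>= 1).
#' @param edge_policy `"shrink"` (average only in-range positions at the
#'   edges) or `"reflect"` (mirror-pad the series).
#' @return List of class `gradient_config`.
#' @export
gradient_config <- function(class_width = 0.2, class_origin = 0,
                            window = 7L, edge_policy = c("shrink", "reflect")) {
  edge_policy <- match.arg(edge_policy)
  stopifnot(is.finite(class_width), class_width > 0, is.finite(class_origin))
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("smoothing window must be an odd integer >= 1", call. = FALSE)
  }
  structure(list(class_width = class_width, class_origin = class_origin,
                 window = window, edge_policy = edge_policy),
            class = "gradient_config")
}

#' Map a pH value to its class index
#'
#' Class `k` covers `[origin + k*w, origin + (k+1)*w)`; the boundary value
#' belongs to the upper class (half-open rule), so pH 7.0 with width 0.2
#' falls in `[7.0, 7.2)`.
#'
#' @param ph Numeric vector of pH values.
#' @param cfg A [gradient_config()].
#' @return Integer class indices (k as above).
#' @export
assign_ph_class <- function(ph, cfg = gradient_config()) {
  if (any(!is.finite(ph))) stop("pH values must be finite", call. = FALSE)
  # guard against 7.0 landing below its own edge through float division
  as.integer(floor((ph - cfg$class_origin) / cfg$class_width + 1e-9))
}

#' Centered gliding average
#'
#' @param x Numeric series.
#' @param window Odd window width.
#' @param edge_policy `"shrink"` averages only the positions that exist near
#'   the series ends; `"reflect"` mirror-pads before averaging.
#' @return Smoothed series, same length as `x`.
#' @export
gliding_average <- function(x, window = 7L,
                            edge_policy = c("shrink", "reflect")) {
  edge_policy <- match.arg(edge_policy)
  window <- as.integer(window)
  n <- length(x)
  if (window %% 2L == 0L || window < 1L) {
    stop("window must be odd and >= 1", call. = FALSE)
  }
  if (window > 2L * n - 1L) stop("window too wide for series", call. = FALSE)
  h <- (window - 1L) %/% 2L
  if (h == 0L) return(x)
  if (edge_policy == "reflect") {
    pad <- c(x[(h + 1L):2L], x, x[(n - 1L):(n - h)])
    return(vapply(seq_len(n), function(i) mean(pad[i:(i + 2L * h)]),
                  numeric(1L)))
  }
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - h):min(n, i + h)])
  }, numeric(1L))
}

#' Per-probe normalized relative-intensity profile along the pH gradient
#'
#' Implements the class-sum / fraction / max-normalize / smooth sequence
#' described in [gradient_config()]. Classes span from the class containing
#' the lowest observed pH to the class containing the highest, and empty
#' classes stay in the series with value 0 so the gliding average is defined
#' across gaps. A probe with total score 0 yields an `undetected` profile
#' whose fraction/normalized/smoothed series are all-zero placeholders.
#'
#' @param scores Integer vector of ordinal scores (one per habitat), or a
#'   single-column piece of a `score_matrix`.
#' @param ph Numeric vector of habitat pH values, same length/order.
#' @param cfg A [gradient_config()].
#' @param probe_name Identifier stored on the profile.
#' @return List of class `gradient_profile` with `class_low`, `class_high`,
#'   `class_mid`, `raw_sums`, `fractions`, `normalized`, `smoothed`,
#'   `undetected`, `config`.
#' @export
compute_profile <- function(scores, ph, cfg = gradient_config(),
                            probe_name = "probe") {
  scores <- as.integer(scores)
  stopifnot(length(scores) == length(ph), length(scores) > 0L)
  if (any(is.na(scores)) || any(scores < 0L)) {
    stop("scores must be non-negative integers", call. = FALSE)
  }
  cls <- assign_ph_class(ph, cfg)
  k_range <- seq(min(cls), max(cls))
  raw <- vapply(k_range, function(k) sum(scores[cls == k]), numeric(1L))
  total <- sum(raw)
  undetected <- total == 0
  if (undetected) {
    fractions <- normalized <- smoothed <- rep(0, length(raw))
  } else {
    fractions <- raw / total
    normalized <- fractions / max(fractions)
    # short series (few occupied pH classes): shrink the window to the
    # widest legal odd width so degenerate profiles still smooth
    w_eff <- min(cfg$window, 2L * length(raw) - 1L)
    smoothed <- gliding_average(normalized, w_eff, cfg$edge_policy)
  }
  structure(list(
    probe_name = probe_name,
    class_low = cfg$class_origin + k_range * cfg$class_width,
    class_high = cfg$class_origin + (k_range + 1L) * cfg$class_width,
    class_mid = cfg$class_origin + (k_range + 0.5) * cfg$class_width,
    raw_sums = raw, fractions = fractions, normalized = normalized,
    smoothed = smoothed, undetected = undetected, config = cfg
  ), class = "gradient_profile")
}

#' Profiles for every probe of a score matrix
#'
#' @param m A `score_matrix` aligned with `habitats`.
#' @param habitats A `habitat_table` whose rows match the matrix rows.
#' @param cfg A [gradient_config()].
#' @return Named list of `gradient_profile` objects, one per probe column.
#' @export
compute_profiles <- function(m, habitats, cfg = gradient_config()) {
  al <- align_scores(m, habitats)
  stats::setNames(lapply(colnames(al$scores), function(p) {
    compute_profile(al$scores[, p], al$habitats$ph, cfg, probe_name = p)
  }), colnames(al$scores))
}

#' Classify the shape of a gradient profile
#'
#' Peaks are local maxima of the smoothed series at or above
#' `peak_threshold` times its maximum; peaks closer than `min_separation`
#' pH units are merged (the higher one survives). Two or more surviving
#' peaks make the profile `bimodal` (the two highest are reported) provided
#' a real valley separates them (smoothed minimum between the two maxima
#' below `peak_threshold` of the series maximum); without such a valley a
#' widely occupied profile is `broad`, not bimodal. A single peak is
#' `broad` when at least 60% of the pH classes carry appreciable signal
#' (smoothed >= 0.25 of max), otherwise `acidic`, `alkaline` or
#' `circumneutral-narrow` by peak position relative to `acid_cut` +/- 0.5.
#' All-zero profiles are `undetected`.
#'
#' @param profile A [compute_profile()] result.
#' @param peak_threshold Fraction of the smoothed maximum a local maximum
#'   must reach to count as a peak.
#' @param min_separation Minimum pH distance between distinct peaks.
#' @param acid_cut pH boundary between acidic and alkaline preference.
#' @return List of class `distribution_label`: `label`, `peaks` (pH of the
#'   class midpoints of the reported maxima).
#' @export
classify_distribution <- function(profile, peak_threshold = 0.5,
                                  min_separation = 1.0, acid_cut = 7.0) {
  stopifnot(inherits(profile, "gradient_profile"))
  if (profile$undetected) {
    return(structure(list(label = "undetected", peaks = numeric(0)),
                     class = "distribution_label"))
  }
  s <- profile$smoothed
  mid <- profile$class_mid
  n <- length(s)
  # local maxima by exhaustive scan (plateaus: left-most class wins)
  is_peak <- vapply(seq_len(n), function(i) {
    left <- if (i == 1L) -Inf else s[i - 1L]
    right <- if (i == n) -Inf else s[i + 1L]
    s[i] > left && s[i] >= right && s[i] >= peak_threshold * max(s)
  }, logical(1L))
  peaks <- data.frame(ph = mid[is_peak], height = s[is_peak])
  peaks <- peaks[order(-peaks$height, peaks$ph), , drop = FALSE]
  kept <- peaks[0, ]
  for (i in seq_len(nrow(peaks))) {
    if (nrow(kept) == 0L || all(abs(peaks$ph[i] - kept$ph) >= min_separation)) {
      kept <- rbind(kept, peaks[i, ])
    }
  }
  kept <- kept[order(kept$ph), , drop = FALSE]
  occupied <- mean(s >= 0.25 * max(s))
  if (nrow(kept) >= 2L) {
    top2 <- kept[order(-kept$height), ][1:2, ]
    span <- which(mid >= min(top2$ph) & mid <= max(top2$ph))
    trough <- min(s[span])
    if (trough < peak_threshold * max(s)) {
      return(structure(list(label = "bimodal", peaks = sort(top2$ph)),
                       class = "distribution_label"))
    }
    if (occupied > 0.6) {
      return(structure(list(label = "broad", peaks = sort(top2$ph)),
                       class = "distribution_label"))
    }
    # peaks with no separating valley and narrow occupancy: treat as one mode
    kept <- top2[which.max(top2$height), , drop = FALSE]
  }
  peak_ph <- kept$ph[1L]
  label <- if (occupied > 0.6) "broad"
  else if (peak_ph < acid_cut - 0.5) "acidic"
  else if (peak_ph > acid_cut + 0.5) "alkaline"
  else "circumneutral-narrow"
  structure(list(label = label, peaks = peak_ph),
            class = "distribution_label")
}

#' Long-format view of one or many profiles
#'
#' @param profiles A `gradient_profile` or a list of them.
#' @return Data frame with columns probe, class_low, class_high, raw_sum,
#'   fraction, normalized, smoothed.
#' @export
profile_table <- function(profiles) {
  if (inherits(profiles, "gradient_profile")) profiles <- list(profiles)
  do.call(rbind, lapply(profiles, function(p) {
    data.frame(probe = p$probe_name, class_low = p$class_low,
               class_high = p$class_high, raw_sum = p$raw_sums,
               fraction = p$fractions, normalized = p$normalized,
               smoothed = p$smoothed)
  }))
}
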