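#' Niche specification for a synthetic probe-defined group
#'
#' Each group's detectability along the pH gradient is a Gaussian response
#' curve (or, for bimodal groups, the pointwise maximum of two Gaussians so
#' the peak suitability stays in (0,1]): suitability
#' `f(pH) = amplitude * max_j exp(-(pH - mu_j)^2 / (2 sigma^2))`.
#'
#' @param name Group name (matches a probe name for probe-bearing groups).
#' @param optima One or two pH optima in `[3, 10]`; two optima must differ
#'   by at least `2 * tolerance`.
#' @param tolerance Niche breadth sigma in pH units (> 0).
#' @param amplitude Peak suitability in `[0, 1]` (0 = never detected).
#' @param baseline Spurious weak-detection rate in `[0, 0.05]`.
#' @return List of class `niche_spec`.
#' @export
niche_spec <- function(name, optima, tolerance, amplitude, baseline = 0.01) {
  stopifnot(length(optima) %in% 1:2, all(optima >= 3), all(optima <= 10),
            tolerance > 0, amplitude >= 0, amplitude <= 1,
            baseline >= 0, baseline <= 0.05)
  if (length(optima) == 2L && abs(diff(optima)) < 2 * tolerance) {
    stop("bimodal optima must differ by >= 2 * tolerance", call. = FALSE)
  }
  structure(list(name = name, optima = sort(optima), tolerance = tolerance,
                 amplitude = amplitude, baseline = baseline),
            class = "niche_spec")
}

#' Latent suitability of a niche spec at given pH values
#'
#' @param spec A [niche_spec()].
#' @param ph Numeric pH vector.
#' @return Suitability values in `[0, amplitude]`.
#' @export
niche_suitability <- function(spec, ph) {
  g <- vapply(spec$optima, function(mu) {
    exp(-(ph - mu)^2 / (2 * spec$tolerance^2))
  }, numeric(length(ph)))
  spec$amplitude * apply(matrix(g, nrow = length(ph)), 1L, max)
}

#' Ordinal score model
#'
#' Maps latent suitability plus Gaussian noise to the 0/1/2/3 RLBH score
#' scale through three increasing thresholds.
#'
#' @param thresholds Strictly increasing cut points in (0,1) for scores
#'   1, 2, 3.
#' @param noise_sd SD of the additive Gaussian noise (>= 0).
#' @return List of class `score_model`.
#' @export
score_model <- function(thresholds = c(0.25, 0.5, 0.75), noise_sd = 0.1) {
  stopifnot(length(thresholds) == 3L, all(diff(thresholds) > 0),
            all(thresholds > 0), all(thresholds < 1), noise_sd >= 0)
  structure(list(thresholds = thresholds, noise_sd = noise_sd),
            class = "score_model")
}

#' Default niche panel emulating the survey's observed archetypes
#'
#' One spec per packaged probe. The mix mirrors the qualitative patterns a
#' broad pan-European pond/lake survey shows: mostly alkaline-preferring
#' groups, a single acid specialist (Lim12+A), several bimodal groups
#' (Lim3+, Lim4AusCurv and its combined probe, Lim11+), a strong narrow
#' circumneutral group (Lim1+), one broad generalist (Lim10+), a weak-signal
#' alkaline group (Lim6+B), and four probes that never fire in environmental
#' samples (Lim5+, Lim6+A, Lim7+A, Lim9Plankt+; amplitude 0).
#'
#' @return Named list of [niche_spec()] objects (18 entries).
#' @export
default_niche_panel <- function() {
  specs <- list(
    niche_spec("Lim1+",             7.0,          0.35, 1.00),
    niche_spec("Lim2+",             8.2,          0.50, 0.90),
    niche_spec("Lim3+",             c(5.6, 8.3),  0.50, 0.80),
    niche_spec("Lim4AusCurv+Lim3+", c(5.5, 8.5),  0.50, 0.90),
    niche_spec("Lim4AusCurv",       c(5.5, 8.5),  0.55, 1.00),
    niche_spec("Lim5+",             7.0,          0.50, 0.00, baseline = 0),
    niche_spec("Lim6+A",            7.0,          0.50, 0.00, baseline = 0),
    niche_spec("Lim6+B",            8.0,          0.40, 0.35),
    niche_spec("Lim7+A",            7.0,          0.50, 0.00, baseline = 0),
    niche_spec("Lim7+B",            8.2,          0.40, 0.80),
    niche_spec("Lim7+C",            8.4,          0.40, 0.80),
    niche_spec("Lim7+D",            8.0,          0.45, 0.70),
    niche_spec("Lim8Parv+",         5.7,          0.90, 0.80),
    niche_spec("Lim9Plankt+",       7.0,          0.50, 0.00, baseline = 0),
    niche_spec("Lim10+",            6.8,          2.00, 0.70),
    niche_spec("Lim11+",            c(5.8, 8.4),  0.50, 0.80),
    niche_spec("Lim12+A",           4.6,          0.60, 0.90),
    niche_spec("Lim13+",            8.3,          0.60, 0.85)
  )
  stats::setNames(specs, vapply(specs, `[[`, character(1L), "name"))
}

#' Generate a synthetic habitat table
#'
#' Habitats emulate a Central-European standing-freshwater survey: pH is a
#' mixture of a uniform background over the range and two bumps (humic/acid
#' ponds near pH 4.8, hardwater/alkaline ponds near pH 8.0); conductivity
#' is log-normal and rises with pH; absorbance (DOC proxy) falls with pH
#' and depresses oxygen; altitude and temperature are independent;
#' coordinates sit in a Central-European box, mildly clustered by habitat
#' type when `spatial_clustering` is on (so community similarity can decay
#' with distance).
#'
#' @param n Number of habitats (>= 1).
#' @param seed Integer seed (full determinism under a fixed seed).
#' @param ph_range Length-2 pH range of the survey.
#' @param spatial_clustering Cluster coordinates by pH type.
#' @return A `habitat_table` with n rows (ids `H001`, `H002`, ...).
#' @export
generate_habitats <- function(n, seed = NULL, ph_range = c(3.8, 9.1),
                              spatial_clustering = TRUE) {
  if (length(n) != 1L || n < 1L) stop("n must be >= 1", call. = FALSE)
  if (length(ph_range) != 2L || ph_range[1L] >= ph_range[2L] ||
      ph_range[1L] < 0 || ph_range[2L] > 14) {
    stop("invalid pH range", call. = FALSE)
  }
  with_seed(seed, {
    comp <- sample.int(3L, n, replace = TRUE, prob = c(0.5, 0.25, 0.25))
    rtrunc <- function(m, mu, sd) {
      pmin(ph_range[2L], pmax(ph_range[1L], stats::rnorm(m, mu, sd)))
    }
    ph <- numeric(n)
    ph[comp == 1L] <- stats::runif(sum(comp == 1L), ph_range[1L], ph_range[2L])
    ph[comp == 2L] <- rtrunc(sum(comp == 2L), 4.8, 0.6)
    ph[comp == 3L] <- rtrunc(sum(comp == 3L), 8.0, 0.6)

    conductivity <- exp(3.0 + 0.35 * ph + stats::rnorm(n, 0, 0.35))
    absorbance <- stats::rlnorm(n, meanlog = 0.3 - 0.35 * (ph - 6.5),
                                sdlog = 0.3)
    oxygen <- pmax(0, 11 - 2.2 * absorbance + stats::rnorm(n, 0, 0.8))
    altitude <- stats::runif(n, 100, 1100)
    temperature <- stats::rnorm(n, 18, 3.5)

    if (spatial_clustering) {
      centers <- cbind(lat = stats::runif(6L, 46.8, 50.2),
                       lon = stats::runif(6L, 9.5, 16.5))
      # acidic habitats favour the first two centers, alkaline the last two
      pick <- vapply(ph, function(p) {
        w <- rep(1, 6L)
        if (p < 6) w[1:2] <- 4 else if (p > 7.5) w[5:6] <- 4
        sample.int(6L, 1L, prob = w)
      }, integer(1L))
      latitude <- centers[pick, "lat"] + stats::rnorm(n, 0, 0.25)
      longitude <- centers[pick, "lon"] + stats::rnorm(n, 0, 0.25)
    } else {
      latitude <- stats::runif(n, 46.5, 50.5)
      longitude <- stats::runif(n, 9.0, 17.0)
    }
    validate_habitat_table(data.frame(
      habitat_id = sprintf("H%03d", seq_len(n)),
      ph = ph, conductivity = conductivity, oxygen = oxygen,
      absorbance = absorbance, altitude = altitude,
      temperature = temperature, latitude = latitude, longitude = longitude))
  })
}

#' Generate an ordinal score matrix from niche truth
#'
#' Per (habitat, group): latent suitability from the group's niche curve,
#' plus Gaussian noise, thresholded to the 0..3 scale; a Bernoulli baseline
#' additionally injects spurious weak (score 1) detections.
#'
#' @param habitats A `habitat_table`.
#' @param specs Named list of [niche_spec()] objects.
#' @param model A [score_model()].
#' @param seed Integer seed.
#' @return A `score_matrix` (habitats x groups).
#' @export
generate_scores <- function(habitats, specs, model = score_model(),
                            seed = NULL) {
  h <- validate_habitat_table(as.data.frame(habitats))
  stopifnot(length(specs) >= 1L)
  with_seed(seed, {
    n <- nrow(h)
    m <- matrix(0L, nrow = n, ncol = length(specs),
                dimnames = list(h$habitat_id,
                                unname(vapply(specs, `[[`,
                                              character(1L), "name"))))
    th <- model$thresholds
    for (j in seq_along(specs)) {
      f <- niche_suitability(specs[[j]], h$ph)
      y <- f + stats::rnorm(n, 0, model$noise_sd)
      sc <- findInterval(y, th)
      spurious <- stats::runif(n) < specs[[j]]$baseline
      m[, j] <- pmax(sc, spurious * 1L)
    }
    score_matrix(m)
  })
}

#' Generate ITS-like sequences with planted primer and probe sites
#'
#' One record per group: a random background sequence of roughly
#' `length_mean` bases carrying one concrete expansion of the forward
#' primer at its start and the reverse complement of one expansion of the
#' reverse primer at its end (so in-silico PCR recovers the whole record as
#' a single product). Groups whose name matches a probe additionally carry
#' exactly one concrete expansion of that probe at a random internal
#' position; other groups carry no planted probe site.
#'
#' @param groups Character vector of group names.
#' @param panel A [probe_panel()] (probe lookup by group name).
#' @param pair A [primer_pair()].
#' @param seed Integer seed.
#' @param length_mean,length_sd Record length distribution (bp).
#' @return An `its_records` collection.
#' @export
generate_sequences <- function(groups, panel, pair, seed = NULL,
                               length_mean = 1900, length_sd = 25) {
  panel <- validate_probe_panel(as.data.frame(panel))
  with_seed(seed, {
    recs <- lapply(groups, function(g) {
      len <- max(200L, round(stats::rnorm(1L, length_mean, length_sd)))
      fwd <- sample(iupac_expansions(pair$forward), 1L)
      rev_site <- reverse_complement(sample(iupac_expansions(pair$reverse), 1L))
      core_len <- len - nchar(fwd) - nchar(rev_site)
      if (core_len < 50L) stop("record too short for primer sites",
                               call. = FALSE)
      core <- paste(sample(c("A", "C", "G", "T"), core_len, replace = TRUE),
                    collapse = "")
      probe_seq <- panel$sequence[match(g, panel$name)]
      if (!is.na(probe_seq)) {
        site <- sample(iupac_expansions(probe_seq), 1L)
        if (nchar(site) > core_len) {
          stop(sprintf("probe '%s' longer than record core", g),
               call. = FALSE)
        }
        at <- sample.int(core_len - nchar(site) + 1L, 1L)
        substr(core, at, at + nchar(site) - 1L) <- site
      }
      paste0(fwd, core, rev_site)
    })
    its_records(id = paste0("SYN_", gsub("[^A-Za-z0-9]+", "_", groups)),
                sequence = unlist(recs), group_label = groups)
  })
}

#' Generate a complete synthetic survey dataset
#'
#' One seeded call yields a self-consistent bundle: habitat table, ordinal
#' score matrix, ITS-like sequences with planted sites, and the generating
#' truth. With `out_dir` set, everything is also written to disk
#' (`habitats.tsv`, `scores.tsv`, `sequences.fasta`, `truth.json`).
#'
#' @param n_habitats Number of habitats (survey default 161).
#' @param specs Named list of [niche_spec()]s (default: the 18-group panel).
#' @param model A [score_model()].
#' @param panel A [probe_panel()] for sequence planting.
#' @param pair A [primer_pair()] (default: the packaged specific ITS pair).
#' @param seed Integer master seed; component seeds are derived from it.
#' @param out_dir Optional output directory.
#' @return List of class `synthetic_dataset`: `habitats`, `scores`,
#'   `records`, `truth`.
#' @export
generate_dataset <- function(n_habitats = 161L,
                             specs = default_niche_panel(),
                             model = score_model(),
                             panel = load_probe_panel(),
                             pair = NULL, seed = 1L, out_dir = NULL) {
  if (is.null(pair)) {
    pp <- load_primer_pairs()
    i <- match("limnohabitans_its", pp$label)
    pair <- primer_pair(pp$forward[i], pp$reverse[i], pp$label[i])
  }
  seed <- as.integer(seed)
  habitats <- generate_habitats(n_habitats, seed = seed)
  scores <- generate_scores(habitats, specs, model, seed = seed + 1L)
  records <- generate_sequences(names(specs), panel, pair, seed = seed + 2L)
  truth <- list(
    seed = seed, n_habitats = n_habitats,
    model = unclass(model),
    specs = lapply(specs, unclass)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_habitat_table(habitats, file.path(out_dir, "habitats.tsv"))
    write_score_table(scores, file.path(out_dir, "scores.tsv"))
    write_its_fasta(records, file.path(out_dir, "sequences.fasta"))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(habitats = habitats, scores = scores, records = records,
                 truth = truth),
            class = "synthetic_dataset")
}
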