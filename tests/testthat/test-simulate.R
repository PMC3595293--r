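test_that("generators are fully deterministic under a fixed seed", {
  h1 <- generate_habitats(40, seed = 101)
  h2 <- generate_habitats(40, seed = 101)
  expect_identical(h1, h2)
  specs <- default_niche_panel()
  s1 <- generate_scores(h1, specs, seed = 5)
  s2 <- generate_scores(h1, specs, seed = 5)
  expect_identical(s1, s2)
  expect_false(identical(s1, generate_scores(h1, specs, seed = 6)))
  expect_error(generate_habitats(0), "n must be")
  expect_error(generate_habitats(5, ph_range = c(9, 4)), "invalid pH range")
})

test_that("habitat covariates carry the documented correlation structure", {
  h <- generate_habitats(10000, seed = 3)
  expect_true(all(h$ph >= 3.8 & h$ph <= 9.1))
  expect_gt(cor(h$ph, log(h$conductivity)), 0)
  expect_lt(cor(h$oxygen, h$absorbance), 0)
  expect_true(all(h$latitude > 45 & h$latitude < 52))
})

test_that("the score model maps suitability to the ordinal scale", {
  h1 <- validate_habitat_table(data.frame(habitat_id = "H1", ph = 6.0))
  spec <- niche_spec("g", 6.0, 0.5, 1.0, baseline = 0)
  m0 <- score_model(noise_sd = 0)
  s <- generate_scores(h1, list(g = spec), m0, seed = 1)
  expect_equal(s[1, 1], 3L)      # suitability 1 clears the 0.75 threshold
  # amplitude 0 and baseline 0: nothing is ever detected
  dead <- niche_spec("d", 6.0, 0.5, 0, baseline = 0)
  h <- generate_habitats(60, seed = 4)
  expect_true(all(generate_scores(h, list(d = dead), seed = 2) == 0L))
  # with no noise, score is non-decreasing in latent suitability
  f <- niche_suitability(spec, h$ph)
  sc <- generate_scores(h, list(g = spec), m0, seed = 3)[, 1]
  ord <- order(f)
  expect_true(all(diff(sc[ord]) >= 0))
})

test_that("niche specs validate their geometry", {
  expect_error(niche_spec("x", c(6, 6.5), 0.5, 1), "2 \\* tolerance")
  expect_error(niche_spec("x", 12, 0.5, 1))
  expect_error(niche_spec("x", 6, 0.5, 1, baseline = 0.2))
  b <- niche_spec("x", c(8.5, 5.5), 0.5, 0.8)
  expect_equal(b$optima, c(5.5, 8.5))   # stored sorted
  # bimodal suitability is a max of Gaussians, so it never exceeds amplitude
  f <- niche_suitability(b, seq(3.8, 9.1, 0.01))
  expect_lte(max(f), 0.8)
  expect_equal(max(f), 0.8, tolerance = 1e-6)
})

test_that("planted sequences close the loop with matching and PCR", {
  panel <- load_probe_panel()
  pp <- load_primer_pairs()
  pair <- primer_pair(pp$forward[1], pp$reverse[1])
  recs <- generate_sequences(panel$name, panel, pair, seed = 12)
  expect_equal(nrow(recs), 18)
  for (i in seq_len(nrow(panel))) {
    rec <- recs$sequence[recs$group_label == panel$name[i]]
    expect_gte(nrow(match_probe(panel$sequence[i], rec, 0)), 1)
  }
  cov <- compute_coverage(panel, recs)
  expect_equal(cov$fraction_covered, 1.0)
  # every record amplifies as one roughly 1.9 kb product
  amp <- in_silico_pcr(pair, recs$sequence[1], length_bounds = c(1500, 2300))
  expect_equal(nrow(amp), 1)
  expect_lt(abs(amp$length - 1900), 150)
  # a probe-free group gets no planted site
  extra <- generate_sequences(c("Lim1+", "nogroup"), panel, pair, seed = 9)
  bg <- extra$sequence[extra$group_label == "nogroup"]
  expect_equal(nrow(match_probe(panel$sequence[panel$name == "Lim1+"],
                                bg, 0)), 0)
  # new seed: new background, same planted detectability
  recs2 <- generate_sequences(panel$name, panel, pair, seed = 13)
  expect_false(any(recs2$sequence == recs$sequence))
  expect_equal(compute_coverage(panel, recs2)$fraction_covered, 1.0)
})

test_that("no probe hits another group's record at exact matching", {
  panel <- load_probe_panel()
  pp <- load_primer_pairs()
  pair <- primer_pair(pp$forward[1], pp$reverse[1])
  recs <- generate_sequences(panel$name, panel, pair, seed = 21)
  cov <- compute_coverage(panel, recs)
  for (p in panel$name) {
    expect_equal(cov$per_probe_targets[[p]],
                 recs$id[recs$group_label == p],
                 info = p)
  }
  expect_equal(cov$mean_targets_per_probe, 1.0)
})

test_that("generate_dataset writes a self-consistent fixture bundle", {
  out <- withr::local_tempdir()
  ds <- generate_dataset(n_habitats = 30, seed = 99, out_dir = out)
  expect_true(all(file.exists(file.path(out, c("habitats.tsv", "scores.tsv",
                                               "sequences.fasta",
                                               "truth.json")))))
  h <- read_habitat_table(file.path(out, "habitats.tsv"))
  m <- read_score_table(file.path(out, "scores.tsv"))
  expect_equal(as.data.frame(h), as.data.frame(ds$habitats),
               tolerance = 1e-9)
  expect_equal(unclass(m), unclass(ds$scores))
  al <- align_scores(m, h)
  expect_equal(al$dropped_from_matrix, 0)
  expect_equal(al$dropped_from_habitats, 0)
  fa <- read_its_fasta(file.path(out, "sequences.fasta"))
  expect_equal(fa$sequence, ds$records$sequence)
  expect_equal(fa$group_label, ds$records$group_label)
  truth <- jsonlite::read_json(file.path(out, "truth.json"))
  expect_equal(truth$seed, 99)
  expect_length(truth$specs, 18)
})

test_that("fasta round-trip preserves records and wraps at 60 columns", {
  recs <- its_records(id = c("r1", "r2"),
                      sequence = c(random_seq(150), random_seq(61)),
                      group_label = c("GrpA", NA))
  tf <- withr::local_tempfile(fileext = ".fasta")
  write_its_fasta(recs, tf)
  lines <- readLines(tf)
  expect_true(all(nchar(lines[!startsWith(lines, ">")]) <= 60))
  back <- read_its_fasta(tf)
  expect_equal(back$sequence, recs$sequence)
  expect_equal(back$group_label, recs$group_label)
})
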