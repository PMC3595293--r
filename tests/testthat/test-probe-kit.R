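test_that("IUPAC letters expand to their canonical base sets", {
  expect_identical(expand_iupac("A"), "A")
  expect_setequal(expand_iupac("R"), c("A", "G"))
  expect_setequal(expand_iupac("N"), c("A", "C", "G", "T"))
  expect_error(expand_iupac("X"), "invalid IUPAC letter: 'X'")
  expect_error(expand_iupac("AR"), "single IUPAC letter")
})

test_that("reverse complement handles degeneracy codes", {
  expect_identical(reverse_complement("ACGT"), "ACGT")
  expect_identical(reverse_complement("GMAAGYCTGATCCAGCCATT"),
                   oracle_revcomp("GMAAGYCTGATCCAGCCATT"))
  set.seed(11)
  for (i in 1:20) {
    s <- random_probe(sample(5:15, 1))
    expect_identical(reverse_complement(s), oracle_revcomp(s))
  }
})

test_that("match_probe finds planted and degenerate sites", {
  # ACGT is its own reverse complement: one hit on each strand
  h <- match_probe("ACGT", "ACGT", 0, strands = "both")
  expect_equal(h$position, c(0, 0))
  expect_setequal(h$strand, c("sense", "antisense"))
  # degenerate probe AR = {AA, AG}
  h <- match_probe("AR", "AAAG", 0, strands = "sense")
  expect_equal(h$position, c(0, 1, 2))
  expect_equal(nrow(match_probe("CCCC", "AAAA", 0)), 0)
  expect_error(match_probe("", "ACGT"), "non-empty")
})

test_that("match_probe equals the all-expansion brute-force oracle", {
  set.seed(42)
  for (i in 1:60) {
    probe <- random_probe(sample(4:12, 1))
    target <- random_seq(sample(30:200, 1))
    for (mm in 0:1) {
      got <- match_probe(probe, target, mm, strands = "both")
      want <- oracle_match(probe, target, mm, strands = "both")
      expect_equal(got, want, info = sprintf("probe=%s mm=%d", probe, mm))
    }
  }
})

test_that("strand symmetry and mismatch monotonicity hold", {
  set.seed(7)
  for (i in 1:25) {
    probe <- random_probe(sample(4:10, 1))
    target <- random_seq(120)
    anti <- match_probe(probe, target, 1, strands = "antisense")
    sense_rc <- match_probe(reverse_complement(probe), target, 1,
                            strands = "sense")
    expect_equal(nrow(anti), nrow(sense_rc))
    expect_equal(anti$position, sense_rc$position)
    h0 <- match_probe(probe, target, 0)
    h1 <- match_probe(probe, target, 1)
    key <- function(h) paste(h$position, h$strand)
    expect_true(all(key(h0) %in% key(h1)))
  }
})

test_that("target N is sequencing uncertainty, not a wildcard", {
  expect_equal(nrow(match_probe("ANT", "ANT", 0, strands = "sense")), 0)
  expect_equal(nrow(match_probe("ANT", "ANT", 0, strands = "sense",
                                target_n = "any")), 1)
  # probe-side N still matches any concrete base
  expect_equal(nrow(match_probe("ANT", "ACT", 0, strands = "sense")), 1)
})

test_that("in-silico PCR emits length-bounded products from primer sites", {
  pp <- load_primer_pairs()
  pair <- primer_pair(pp$forward[pp$label == "limnohabitans_its"],
                      pp$reverse[pp$label == "limnohabitans_its"])
  expect_equal(nrow(in_silico_pcr(pair, random_seq(500),
                                  length_bounds = c(100, 5000))), 0)
  # planted fixture: forward at 0, reverse site ending at 1900
  set.seed(3)
  fwd <- iupac_expansions(pair$forward)[1]
  rev_rc <- reverse_complement(iupac_expansions(pair$reverse)[1])
  mid <- random_seq(1900 - nchar(fwd) - nchar(rev_rc))
  rec <- paste0(fwd, mid, rev_rc, random_seq(100))
  amp <- in_silico_pcr(pair, rec, length_bounds = c(1000, 2500))
  expect_equal(nrow(amp), 1)
  expect_equal(amp$length, 1900)
  expect_equal(amp$start, 0)
  expect_identical(amp$sequence, substr(rec, 1, 1900))
  expect_error(in_silico_pcr(pair, rec, length_bounds = c(10, 20)),
               "combined primer length")
})

test_that("nested PCR by composition yields a contained inner product", {
  pp <- load_primer_pairs()
  inner <- primer_pair(pp$forward[1], pp$reverse[1])
  outer_ <- primer_pair(pp$forward[2], pp$reverse[2])
  set.seed(5)
  of <- iupac_expansions(outer_$forward)[1]
  or_ <- reverse_complement(iupac_expansions(outer_$reverse)[1])
  if_ <- iupac_expansions(inner$forward)[1]
  ir <- reverse_complement(iupac_expansions(inner$reverse)[1])
  rec <- paste0(random_seq(50), of, random_seq(80), if_, random_seq(1800),
                ir, random_seq(60), or_, random_seq(40))
  outer_amp <- in_silico_pcr(outer_, rec, length_bounds = c(500, 5000))
  expect_equal(nrow(outer_amp), 1)
  inner_amp <- in_silico_pcr(inner, outer_amp$sequence[1],
                             length_bounds = c(500, 5000))
  expect_equal(nrow(inner_amp), 1)
  expect_lt(inner_amp$length, outer_amp$length)
  expect_true(grepl(inner_amp$sequence, outer_amp$sequence, fixed = TRUE))
})

test_that("coverage reports match set arithmetic on planted fixtures", {
  panel <- probe_panel(c("P1", "P2"), c("ACGTACGT", "TTTTTGGGGG"))
  recs <- its_records(
    id = c("S1", "S2", "S3"),
    sequence = c(paste0(random_seq(40), "ACGTACGT", random_seq(40)),
                 paste0("ACGTACGT", random_seq(60)),
                 random_seq(80)))
  set.seed(13)
  cov <- compute_coverage(panel, recs)
  expect_equal(cov$fraction_covered, 2 / 3)
  expect_equal(cov$mean_targets_per_probe, 1.0)
  expect_setequal(cov$per_probe_targets$P1, c("S1", "S2"))
  expect_length(cov$per_probe_targets$P2, 0)
  expect_error(compute_coverage(panel[0, ], recs), "empty")
  # adding a probe never decreases the covered fraction
  panel2 <- probe_panel(c("P1", "P2", "P3"),
                        c("ACGTACGT", "TTTTTGGGGG",
                          substr(recs$sequence[3], 10, 25)))
  cov2 <- compute_coverage(panel2, recs)
  expect_gte(cov2$fraction_covered, cov$fraction_covered)
  expect_equal(cov2$fraction_covered, 1.0)
})

test_that("melting temperature estimators behave as documented", {
  expect_equal(as.numeric(melting_temperature("ACGT", "wallace")), 12)
  expect_equal(as.numeric(melting_temperature("AAAA", "wallace")), 8)
  # degenerate letters: mean over expansions (Wallace is linear, so R in
  # place of A adds exactly 1 degC on average)
  expect_equal(as.numeric(melting_temperature("RAAA", "wallace")), 9)
  tm <- melting_temperature("CTGTGTCAAAGAGTTATTCACATT", "nearest-neighbor")
  expect_gt(as.numeric(tm), 40)
  expect_lt(as.numeric(tm), 80)
  expect_identical(attr(tm, "method"), "nearest-neighbor")
  expect_error(melting_temperature(""), "non-empty")
})

test_that("packaged probe panel and primers load and validate", {
  panel <- load_probe_panel()
  expect_equal(nrow(panel), 18)
  expect_true(all(panel$tm > 40 & panel$tm < 80))
  expect_true("Lim4AusCurv+Lim3+" %in% panel$name)
  pp <- load_primer_pairs()
  expect_setequal(pp$label, c("limnohabitans_its", "universal_its"))
  expect_error(probe_panel("bad", "ACGZ"), "invalid letter")
  expect_error(probe_panel(c("a", "a"), c("ACGT", "ACGT")), "duplicate")
  expect_error(probe_panel("a", "ACGT", tm = 120), "Tm outside")
})
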