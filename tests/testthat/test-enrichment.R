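toy_genome <- function(L = 1000, n_chr = 1) {
  genome_model(paste0("chr", seq_len(n_chr)), rep(L, n_chr))
}

test_that("base_coverage_fraction merges before dividing", {
  g <- toy_genome(1000)
  regions <- cnv_regions(c("chr1", "chr1"), c(1, 51), c(100, 150))
  expect_equal(base_coverage_fraction(regions, g), 0.150)
  expect_equal(base_coverage_fraction(regions[0, ], g), 0)
  expect_error(base_coverage_fraction(cnv_regions("chr9", 1, 10), g), "absent")
  # mitochondrial regions drop out of numerator and denominator
  g2 <- genome_model(c("chr1", "chrM"), c(1000, 100))
  rM <- cnv_regions(c("chr1", "chrM"), c(1, 1), c(100, 100))
  expect_equal(base_coverage_fraction(rM, g2), 0.1)
})

test_that("base_coverage_fraction equals the bitmap fraction on random sets", {
  set.seed(19)
  g <- toy_genome(100000)
  for (rep in 1:10) {
    x <- random_intervals(500, 100000, max_len = 400)
    regions <- cnv_regions(x$chrom, x$start + 1, x$end)
    expect_equal(base_coverage_fraction(regions, g),
                 mean(bitmap_cover(x, 100000)))
  }
})

test_that("feature_coverage_count counts distinct identities once", {
  fs <- fixture_sets()
  expect_equal(feature_coverage_count(fs$loci_smc, fs$cnv_smc), 4)
  expect_equal(feature_coverage_count(fs$loci_dc, fs$cnv_dc), 8)
  far <- mirna_loci("m1", "chr7", 1, 100)
  expect_equal(feature_coverage_count(far, fs$cnv_smc), 0)
  # a feature hit by two overlapping records still counts once
  loci <- mirna_loci("m1", "chr1", 50, 80)
  regions <- cnv_regions(c("chr1", "chr1"), c(1, 40), c(60, 100))
  expect_equal(feature_coverage_count(loci, regions), 1)
  expect_error(feature_coverage_count(loci, regions, min_overlap_bp = 0), ">= 1")
  # min_overlap_bp threshold is respected
  edge <- mirna_loci("m2", "chr1", 95, 110)   # 6 bp inside the union
  expect_equal(feature_coverage_count(edge, regions, min_overlap_bp = 7), 0)
  expect_equal(feature_coverage_count(edge, regions, min_overlap_bp = 6), 1)
})

test_that("narrow_by_support depth semantics match the per-base oracle", {
  records <- cnv_regions(rep("chr1", 3), c(1, 51, 61), c(100, 150, 90))
  got <- narrow_by_support(records, 2)
  expect_identical(format_region(got), "chr1:51-100")
  expect_equal(narrow_by_support(records, 1), gi_merge(records))
  expect_equal(nrow(narrow_by_support(records, 4)), 0)
  expect_error(narrow_by_support(records, 0), ">= 1")

  set.seed(23)
  for (rep in 1:20) {
    x <- random_intervals(200, 10000, max_len = 100)
    records <- cnv_regions(x$chrom, x$start + 1, x$end)
    depth <- bitmap_depth(x, 10000)
    for (k in c(1, 2, 3, 5)) {
      got <- narrow_by_support(records, k)
      expect_equal(got, bitmap_runs(depth >= k), ignore_attr = TRUE)
    }
    # base-wise monotone shrinkage in k
    expect_true(all(bitmap_cover(narrow_by_support(records, 3), 10000) <=
                    bitmap_cover(narrow_by_support(records, 2), 10000)))
  }
})

test_that("narrow_by_support reference criterion stacks one layer per study", {
  records <- cnv_regions(rep("chr1", 4), c(1, 21, 41, 61), c(100, 120, 140, 160),
                         reference = c("A", "A", "B", "C"))
  # bases 61-120 are in studies A (via either record), B and C
  got <- narrow_by_support(records, 3, criterion = "references")
  expect_identical(format_region(got), "chr1:61-120")
  # two records of the same study never produce depth 2 on their own
  solo <- cnv_regions(rep("chr1", 2), c(1, 21), c(100, 120), reference = "A")
  expect_equal(nrow(narrow_by_support(solo, 2, criterion = "references")), 0)
  noref <- cnv_regions("chr1", 1, 10)
  expect_error(narrow_by_support(noref, 1, criterion = "references"),
               "reference")
})

test_that("narrow_by_support record-filter variant keeps whole records", {
  records <- cnv_regions(rep("chr1", 2), c(1, 201), c(100, 300),
                         n_records = c(5L, 1L))
  got <- narrow_by_support(records, 2, method = "filter")
  expect_identical(format_region(got), "chr1:1-100")
})

test_that("depletion_test matches direct log-space summation", {
  for (case in list(c(4, 715, 0.012), c(8, 715, 0.023), c(0, 10, 0.3),
                    c(50, 100, 0.5), c(3, 2000, 0.001))) {
    got <- depletion_test(case[1], case[2], case[3])
    expect_equal(got$p_lower_tail,
                 binom_lower_tail_oracle(case[1], case[2], case[3]),
                 tolerance = 1e-12)
    expect_equal(got$expected, case[2] * case[3])
  }
  # the headline polymorphic-set case sits in the marginal band
  p <- depletion_test(4, 715, 0.012)$p_lower_tail
  expect_equal(p, 0.0697, tolerance = 1e-3)
  expect_gt(p, 0.01); expect_lt(p, 0.10)
})

test_that("depletion_test boundary and monotonicity behavior", {
  expect_equal(depletion_test(10, 10, 0.3)$p_lower_tail, 1)
  r <- depletion_test(0, 5, 0)
  expect_equal(r$p_lower_tail, 1)
  expect_equal(r$expected, 0)
  expect_equal(depletion_test(0, 1, 0.25)$p_lower_tail, 0.75)  # closed form n=1
  ps <- vapply(0:20, function(k) depletion_test(k, 20, 0.4)$p_lower_tail, 1)
  expect_true(all(diff(ps) >= 0))   # non-decreasing in n_covered
  expect_error(depletion_test(5, 715, 1.2), "0, 1")
  expect_error(depletion_test(-1, 10, 0.5), "n_covered")
})

test_that("observed_vs_expected_ratio reproduces the two-fold deficit", {
  expect_equal(observed_vs_expected_ratio(depletion_test(4, 715, 0.012)),
               4 / 8.58, tolerance = 1e-12)
  expect_equal(observed_vs_expected_ratio(depletion_test(8, 715, 0.023)),
               8 / 16.445, tolerance = 1e-12)
  expect_equal(observed_vs_expected_ratio(depletion_test(6, 10, 0.6)), 1)
  expect_error(observed_vs_expected_ratio(depletion_test(0, 10, 0)), "undefined")
})

test_that("snp_density_test agrees with fisher.test and brute enumeration", {
  set.seed(31)
  for (rep in 1:25) {
    bp_in <- sample(20:60, 1); bp_out <- sample(20:60, 1)
    a <- sample.int(bp_in, 1) - 1; c <- sample.int(bp_out, 1) - 1
    got <- snp_density_test(a, bp_in, c, bp_out)
    tab <- matrix(c(a, bp_in - a, c, bp_out - c), 2, byrow = TRUE)
    expect_equal(got$p_fisher, stats::fisher.test(tab)$p.value,
                 tolerance = 1e-9)
    expect_equal(got$p_fisher, fisher_oracle(a, bp_in, c, bp_out),
                 tolerance = 1e-9)
  }
})

test_that("snp_density_test reproduces the pre-miRNA purification contrast", {
  # bp_in back-computed from 229 SNPs at 3.7/kb; bp_out from ~13.6M at 4.8/kb
  got <- snp_density_test(229, 61892, 13599864, 2833290000)
  expect_equal(round(got$rate_in, 1), 3.7)
  expect_equal(round(got$rate_out, 1), 4.8)
  expect_lt(got$p_fisher, 1e-4)

  null <- snp_density_test(100, 10000, 100, 10000)
  expect_gt(null$p_fisher, 0.99)
  zero <- snp_density_test(0, 1000, 50, 1000)
  expect_equal(zero$p_fisher, fisher_oracle(0, 1000, 50, 1000), tolerance = 1e-9)
  expect_error(snp_density_test(10, 5, 0, 10), "exceed")
  expect_error(snp_density_test(-1, 5, 0, 10), "non-negative")
})

test_that("capture_recapture_union reproduces the printed extrapolation", {
  cr <- capture_recapture_union(0.012, 0.023, 0.39, 0.20)
  expect_equal(cr$estimate, 0.0595, tolerance = 1e-3)
  expect_lte(cr$estimate, 0.10)
  expect_equal(cr$range, c(0.023 / 0.39, 0.012 / 0.20), tolerance = 1e-12)
  # self-consistency: identical sets recover their own coverage
  expect_equal(capture_recapture_union(0.3, 0.3, 1, 1)$estimate, 0.3)
  expect_error(capture_recapture_union(0.1, 0.1, 0, 0), "do not overlap")
  expect_error(capture_recapture_union(1.2, 0.1, 0.5, 0.5), "fractions")
})

test_that("extrapolate_cnv_mirna_count arithmetic and warnings", {
  expect_equal(extrapolate_cnv_mirna_count(715, 0.10, 0.47), 33.605)
  expect_equal(extrapolate_cnv_mirna_count(1000, 0.5, 0.5), 250)
  expect_equal(extrapolate_cnv_mirna_count(715, 0, 1), 0)
  expect_warning(extrapolate_cnv_mirna_count(10, 1.5, 1), "exceeds 1")
  expect_error(extrapolate_cnv_mirna_count(-1, 0.5, 0.5), "non-negative")
})
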