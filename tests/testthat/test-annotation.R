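test_that("call_cnv_mirnas reproduces the polymorphic fixture calls", {
  fs <- fixture_sets()
  smc <- call_cnv_mirnas(fs$loci_smc, fs$cnv_smc)
  dc <- call_cnv_mirnas(fs$loci_dc, fs$cnv_dc)
  expect_equal(nrow(smc), 4)
  expect_equal(nrow(dc), 8)
  expect_true(all(smc$overlap_bp >= 1) && all(dc$overlap_bp >= 1))
  # every printed locus is fully contained in its printed region
  expect_true(all(smc$fully_contained) && all(dc$fully_contained))
  expect_true(all(smc$overlap_bp == smc$end - smc$start))
  m650 <- dc[dc$id == "mir-650", ]
  expect_equal(m650$flank_left, 784251)
  expect_equal(m650$flank_right, 83585)
  # flank arithmetic conserves region length for all contained calls
  both <- rbind(smc, dc)
  expect_equal(both$flank_left + both$flank_right + (both$end - both$start),
               both$region_end - both$region_start)
  # loci on chromosomes absent from the region set give no calls
  off <- mirna_loci("m1", "chr21", 100, 200)
  expect_equal(nrow(call_cnv_mirnas(off, fs$cnv_smc)), 0)
})

test_that("dedupe_loci counts shared and duplicated loci correctly", {
  fs <- fixture_sets()
  smc <- call_cnv_mirnas(fs$loci_smc, fs$cnv_smc)
  dc <- call_cnv_mirnas(fs$loci_dc, fs$cnv_dc)
  dd <- dedupe_loci(rbind(smc, dc))
  expect_equal(nrow(dd), 11)                     # 4 + 8 with one shared locus
  expect_equal(sum(dd$id == "mir-1233"), 2)      # two distinct chr15 loci
  expect_equal(nrow(dedupe_loci(smc)), 4)        # single set: identity
  expect_equal(nrow(dedupe_loci(rbind(smc, smc, smc))), 4)  # 3 sets, same loci
  expect_lte(nrow(dd), nrow(smc) + nrow(dc))
})

test_that("minimal_region is the record intersection around the locus", {
  locus <- mirna_loci("m", "chr1", 500, 600)
  records <- cnv_regions(rep("chr1", 3), c(100, 400, 450), c(900, 1200, 800))
  mr <- minimal_region(locus, records)
  expect_identical(format_region(mr$interval), "chr1:450-800")
  expect_equal(mr$n_records, 3)
  expect_true(mr$contains_locus)

  one <- minimal_region(locus, records[2, ])
  expect_identical(format_region(one$interval), "chr1:400-1200")
  expect_equal(one$n_records, 1)

  # records not all containing the locus: intersection flagged
  partial <- cnv_regions(rep("chr1", 2), c(100, 550), c(560, 900))
  mp <- minimal_region(locus, partial)
  expect_false(mp$contains_locus)
  expect_identical(format_region(mp$interval), "chr1:550-560")
  expect_error(minimal_region(locus, records[0, ]), "at least one")
  expect_error(minimal_region(locus, cnv_regions("chr1", 5000, 6000)),
               "must overlap")
})

test_that("copy_number_summary spans 0-6 on the fixtures and flags multiallelics", {
  fs <- fixture_sets()
  calls <- rbind(call_cnv_mirnas(fs$loci_smc, fs$cnv_smc),
                 call_cnv_mirnas(fs$loci_dc, fs$cnv_dc))
  s <- copy_number_summary(calls)
  expect_equal(s$copy_min, 0)
  expect_equal(s$copy_max, 6)
  expect_true(s$multiallelic[grep("mir-1268", names(s$multiallelic))])  # 2..6
  expect_false(s$multiallelic[grep("mir-384", names(s$multiallelic))])  # 0,1,2
  m1233 <- s$multiallelic[grep("mir-1233", names(s$multiallelic))]
  expect_true(all(m1233))

  flat <- calls[1, ]; flat$genotypes <- "2"
  sf <- copy_number_summary(flat)
  expect_equal(c(sf$copy_min, sf$copy_max), c(2, 2))
  expect_false(sf$multiallelic[[1]])
  none <- calls[1:2, ]; none$genotypes <- NA
  expect_error(copy_number_summary(none), "no call carries")
  some <- calls[1:2, ]; some$genotypes[2] <- NA
  expect_warning(copy_number_summary(some), "skipped")
})

test_that("classify_flanks thresholds and fixture counts", {
  fs <- fixture_sets()
  calls <- rbind(call_cnv_mirnas(fs$loci_smc, fs$cnv_smc),
                 call_cnv_mirnas(fs$loci_dc, fs$cnv_dc))
  key <- paste(calls$id, calls$chrom, calls$start, calls$end)
  per_locus <- tapply(calls$flank_class, key,
                      function(x) if (all(x == "short_both")) "short_both" else "other")
  expect_equal(sum(per_locus == "short_both"), 3)
  short_ids <- unique(calls$id[calls$flank_class == "short_both"])
  expect_setequal(short_ids, c("mir-384", "mir-1977", "mir-1275"))
  expect_equal(calls$flank_class[calls$id == "mir-1268"], "large_both")

  mk <- function(l, r) data.frame(fully_contained = TRUE, flank_left = l,
                                  flank_right = r)
  expect_equal(classify_flanks(mk(0, 0)), "short_both")       # boundary
  expect_equal(classify_flanks(mk(4999, 4999)), "short_both")
  expect_equal(classify_flanks(mk(5000, 100)), "mixed")
  expect_equal(classify_flanks(mk(20000, 20000)), "large_both")
  expect_equal(classify_flanks(mk(19999, 25000)), "mixed")
  expect_equal(classify_flanks(data.frame(fully_contained = FALSE,
                                          flank_left = NA, flank_right = NA)),
               "partial_overlap")
})

make_gene <- function(strand = "+") {
  # transcript chr1:1001-4000 (internal 1000..4000), hairpin 2500..2600
  gene_model_sketch(gi("chr1", 1000, 4000), gi("chr1", 2500, 2600), strand)
}

test_that("classify_dosage follows the rule table", {
  g <- make_gene()
  whole <- gi("chr1", 900, 4100)
  expect_equal(classify_dosage(g, whole, "deletion"), "decrease")
  expect_equal(classify_dosage(g, whole, "duplication"), "increase")
  # 5' deletion removes the promoter but not the hairpin
  expect_equal(classify_dosage(g, gi("chr1", 500, 1500), "deletion"), "decrease")
  # 3' deletion crossing the transcript end, hairpin intact
  expect_equal(classify_dosage(g, gi("chr1", 3000, 5000), "deletion"),
               "indeterminate")
  # intragenic deletion sparing hairpin and promoter
  expect_equal(classify_dosage(g, gi("chr1", 1200, 2000), "deletion"), "none")
  expect_equal(classify_dosage(g, gi("chr1", 2700, 3500), "deletion"), "none")
  # intragenic tandem duplication containing the hairpin
  expect_equal(classify_dosage(g, gi("chr1", 2000, 3000), "duplication"),
               "increase")
  # duplication without the hairpin
  expect_equal(classify_dosage(g, gi("chr1", 1200, 2000), "duplication"), "none")
  # 3' duplicated segment with hairpin but neither promoter nor containment
  expect_equal(classify_dosage(g, gi("chr1", 2000, 5000), "duplication"), "none")
  expect_error(classify_dosage(g, gi("chr1", 9000, 9500), "deletion"),
               "does not overlap")
})

test_that("classify_dosage is strand-aware and monotone to whole gene", {
  gm <- make_gene("-")   # 5' end at internal 3999, 3' end at 1000
  expect_equal(classify_dosage(gm, gi("chr1", 3500, 4500), "deletion"),
               "decrease")       # removes minus-strand promoter
  expect_equal(classify_dosage(gm, gi("chr1", 500, 1500), "deletion"),
               "indeterminate")  # minus-strand 3' truncation
  g <- make_gene()
  whole <- gi("chr1", 900, 4100)
  parts <- list(gi("chr1", 500, 1500), gi("chr1", 3000, 5000),
                gi("chr1", 1200, 2000), gi("chr1", 2000, 3000))
  for (kind in c("deletion", "duplication")) {
    w <- classify_dosage(g, whole, kind)
    for (p in parts) {
      got <- classify_dosage(g, p, kind)
      # enlarging to the whole gene never flips increase <-> decrease
      expect_false(paste(got, w) %in% c("increase decrease", "decrease increase"))
    }
  }
})

test_that("disease_region_overlap groups calls by syndrome region", {
  # six loci inside one syndrome region, mirroring a microdeletion locus cluster
  loci <- mirna_loci(sprintf("mir-d%d", 1:7), rep("chr22", 7),
                     seq(17e6, by = 2e5, length.out = 7),
                     seq(17e6, by = 2e5, length.out = 7) + 80)
  region <- data.frame(chrom = "chr22", start = 16.9e6, end = 18.1e6,
                       name = "DiGeorge")
  calls <- disease_region_overlap(loci, region)
  expect_equal(nrow(calls), 6)
  expect_equal(unique(calls$region_name), "DiGeorge")
  expect_equal(unique(calls$set_label), "disease")

  empty <- disease_region_overlap(loci, region[0, ])
  expect_equal(nrow(empty), 0)
  # a locus straddling the boundary is still called (>= 1 bp rule)
  straddle <- mirna_loci("mir-x", "chr22", 18.1e6 - 10, 18.1e6 + 70)
  expect_equal(nrow(disease_region_overlap(straddle, region)), 1)
})
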