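#' Fraction of the genome covered by a region set
#'
#' Merges the regions and divides the covered bases by the genome size.
#' Chromosomes in the model's exclusion set (default mitochondrial) are
#' removed from both numerator and denominator.
#'
#' @param regions CNV region (or any interval) data.frame.
#' @param genome a [genome_model()].
#' @return coverage fraction in \[0, 1\].
#' @export
base_coverage_fraction <- function(regions, genome) {
  excl <- attr(genome, "exclude")
  keep <- !regions$chrom %in% excl
  regions <- regions[keep, , drop = FALSE]
  if (nrow(regions) == 0) return(0)
  check_in_genome(regions, genome)
  gi_total_bp(regions) / genome_total_bp(genome)
}

#' Count features covered by a region set
#'
#' Counts distinct feature identities whose total overlap with the *merged*
#' region set reaches `min_overlap_bp`; a feature hit by several regions is
#' counted once. Identity is `(id, chrom, start, end)` when an `id` column is
#' present, the coordinates alone otherwise.
#'
#' @param features locus/interval data.frame.
#' @param regions interval data.frame.
#' @param min_overlap_bp minimum shared bases to call a feature covered
#'   (default 1).
#' @return integer count of covered distinct features.
#' @export
feature_coverage_count <- function(features, regions, min_overlap_bp = 1L) {
  if (min_overlap_bp < 1) stop("min_overlap_bp must be >= 1")
  if (nrow(features) == 0) return(0L)
  key <- feature_key(features)
  u <- !duplicated(key)
  ov <- overlap_with_set(features[u, , drop = FALSE], gi_merge(regions))
  sum(ov >= min_overlap_bp)
}

feature_key <- function(x) {
  if ("id" %in% names(x))
    paste(x$id, x$chrom, x$start, x$end, sep = "|")
  else
    paste(x$chrom, x$start, x$end, sep = "|")
}

# total overlap (bp) of each row of x with a merged (disjoint) interval set
overlap_with_set <- function(x, merged) {
  out <- numeric(nrow(x))
  if (nrow(merged) == 0 || nrow(x) == 0) return(out)
  for (ch in unique(x$chrom)) {
    xi <- which(x$chrom == ch)
    m <- merged[merged$chrom == ch, , drop = FALSE]
    if (nrow(m) == 0) next
    out[xi] <- vapply(xi, function(i) {
      sum(pmax(0, pmin(m$end, x$end[i]) - pmax(m$start, x$start[i])))
    }, numeric(1))
  }
  out
}

#' Narrow a region set by record/reference support
#'
#' Returns, as merged intervals, the genomic bases supported by at least `k`
#' deposited records (`criterion = "records"`) or by records from at least
#' `k` distinct reporting publications (`criterion = "references"`; requires a
#' non-NA `reference` column carrying per-record publication identity).
#' The default base-depth semantics shrink the output base-wise as `k` grows;
#' `method = "filter"` instead keeps whole records whose own `n_records` /
#' `n_references` annotation reaches `k` and merges them.
#'
#' @param records CNV region data.frame (one row per deposited record).
#' @param k support threshold, >= 1.
#' @param criterion `"records"` or `"references"`.
#' @param method `"depth"` (base-wise, default) or `"filter"` (record-wise).
#' @return merged interval data.frame of supported bases.
#' @export
narrow_by_support <- function(records, k, criterion = c("records", "references"),
                              method = c("depth", "filter")) {
  criterion <- match.arg(criterion)
  method <- match.arg(method)
  if (k < 1) stop("k must be >= 1")
  if (nrow(records) == 0) return(gi_empty())
  if (method == "filter") {
    col <- if (criterion == "records") records$n_records else records$n_references
    if (all(is.na(col)))
      stop("method='filter' needs the ", criterion, " annotation column")
    return(gi_merge(records[!is.na(col) & col >= k, , drop = FALSE]))
  }
  if (criterion == "references") {
    if (all(is.na(records$reference)))
      stop("criterion='references' needs a per-record 'reference' column")
    # one layer per publication: within a publication depth never exceeds 1
    layers <- lapply(split(records, records$reference), gi_merge)
    records <- do.call(rbind, layers)
  }
  parts <- lapply(split(records, records$chrom), function(r) {
    ir <- IRanges::IRanges(start = as.integer(r$start + 1),
                           end = as.integer(r$end))
    sl <- IRanges::slice(IRanges::coverage(ir), lower = k, rangesOnly = TRUE)
    if (length(sl) == 0) return(NULL)
    gi(r$chrom[1], IRanges::start(sl) - 1, IRanges::end(sl))
  })
  parts <- parts[!vapply(parts, is.null, FALSE)]
  if (length(parts) == 0) return(gi_empty())
  out <- do.call(rbind, parts[order(names(parts))])
  rownames(out) <- NULL
  out
}

#' Exact binomial depletion test
#'
#' Tests whether the number of features covered by a region set is lower than
#' expected when each feature independently falls in the covered fraction of
#' the genome: under the null, `n_covered ~ Binomial(n_total, genome_fraction)`
#' and the reported probability is the exact lower tail
#' `P(X <= n_covered)`. Feature length is ignored in the null (features are
#' treated as points; pre-miRNA loci of ~50-150 bp are negligible against CNV
#' scale).
#'
#' @param n_covered observed number of covered features.
#' @param n_total number of features tested.
#' @param genome_fraction covered genome fraction in \[0, 1\].
#' @return object of class `depletion_result`: list with `n_total`,
#'   `n_covered`, `genome_fraction`, `expected`, `p_lower_tail`.
#' @examples
#' depletion_test(4, 715, 0.012)
#' @export
depletion_test <- function(n_covered, n_total, genome_fraction) {
  if (genome_fraction < 0 || genome_fraction > 1)
    stop("genome_fraction must be in [0, 1]")
  if (n_covered < 0 || n_covered > n_total)
    stop("n_covered must be in [0, n_total]")
  res <- list(n_total = n_total, n_covered = n_covered,
              genome_fraction = genome_fraction,
              expected = n_total * genome_fraction,
              p_lower_tail = stats::pbinom(n_covered, n_total, genome_fraction))
  class(res) <- "depletion_result"
  res
}

#' @export
print.depletion_result <- function(x, ...) {
  cat(sprintf(
    "Binomial depletion test: %.0f/%.0f features covered (expected %.2f, genome fraction %.4g)\n  P(X <= %.0f) = %.4g\n",
    x$n_covered, x$n_total, x$expected, x$genome_fraction, x$n_covered,
    x$p_lower_tail))
  invisible(x)
}

#' Observed / expected coverage ratio
#' @param result a `depletion_result`.
#' @return `n_covered / expected`.
#' @export
observed_vs_expected_ratio <- function(result) {
  if (result$expected <= 0)
    stop("observed/expected ratio undefined: expected count is 0")
  result$n_covered / result$expected
}

#' SNP density comparison inside vs outside feature loci
#'
#' Two-sided Fisher's exact test on the base-level 2x2 table
#' `[[snps_in, bp_in - snps_in], [snps_out, bp_out - snps_out]]`, with SNP
#' rates reported per 1,000 bp. The p-value is the exact sum of hypergeometric
#' probabilities not exceeding that of the observed table (the classic
#' two-sided definition), computed with `dhyper` over the table support —
#' this matches `stats::fisher.test` on small tables and, unlike it, handles
#' genome-scale margins.
#'
#' @param snps_in,bp_in SNP count and total bases inside features.
#' @param snps_out,bp_out SNP count and total bases outside features.
#' @return object of class `snp_density_result`: list with the four counts,
#'   `rate_in`, `rate_out` (per 1,000 bp) and `p_fisher`.
#' @export
snp_density_test <- function(snps_in, bp_in, snps_out, bp_out) {
  counts <- c(snps_in, bp_in, snps_out, bp_out)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (snps_in > bp_in || snps_out > bp_out)
    stop("SNP counts cannot exceed the corresponding base counts")
  res <- list(snps_in = snps_in, bp_in = bp_in,
              snps_out = snps_out, bp_out = bp_out,
              rate_in = 1000 * snps_in / bp_in,
              rate_out = 1000 * snps_out / bp_out,
              p_fisher = fisher_2x2_two_sided(snps_in, bp_in, snps_out, bp_out))
  class(res) <- "snp_density_result"
  res
}

fisher_2x2_two_sided <- function(a, row1, c, row2) {
  m <- a + c                      # column-1 margin (all SNPs)
  n <- (row1 - a) + (row2 - c)    # column-2 margin (all non-SNP bases)
  k <- row1                       # row-1 margin (feature bases)
  if (m == 0 || n == 0 || k == 0 || row2 == 0) return(1)
  lo <- max(0, k - n); hi <- min(k, m)
  x <- lo:hi
  ld <- stats::dhyper(x, m, n, k, log = TRUE)
  lobs <- stats::dhyper(a, m, n, k, log = TRUE)
  # relative tolerance mirrors fisher.test's handling of ties
  sum(exp(ld[ld <= lobs + log(1 + 1e-7)]))
}

#' @export
print.snp_density_result <- function(x, ...) {
  cat(sprintf(
    "SNP density: %.1f/1,000 bp inside (%.0f SNPs in %.0f bp) vs %.1f/1,000 bp outside\n  Fisher's exact (two-sided) p = %.3g\n",
    x$rate_in, x$snps_in, x$bp_in, x$rate_out, x$p_fisher))
  invisible(x)
}

#' Capture-recapture estimate of total coverage
#'
#' Lincoln-Petersen estimate of the genome fraction covered by the union of an
#' (unobserved) full CNV complement, from two incompletely overlapping
#' surveyed sets: with coverages `cov_a`, `cov_b` and mutual overlap fractions
#' (`frac_a_in_b` = fraction of set A bases also covered by B, and vice
#' versa), the overlap coverage is estimated as the mean of
#' `frac_a_in_b * cov_a` and `frac_b_in_a * cov_b`, and the total as
#' `cov_a * cov_b / overlap`. The two single-sided variants bracket the point
#' estimate.
#'
#' @param cov_a,cov_b genome coverage fractions of the two sets, in \[0, 1\].
#' @param frac_a_in_b,frac_b_in_a mutual overlap fractions, in \[0, 1\].
#' @return list with `estimate`, `range` (the two single-sided estimates,
#'   sorted), and the estimated `overlap` coverage.
#' @examples
#' capture_recapture_union(0.012, 0.023, 0.39, 0.20)
#' @export
capture_recapture_union <- function(cov_a, cov_b, frac_a_in_b, frac_b_in_a) {
  v <- c(cov_a, cov_b, frac_a_in_b, frac_b_in_a)
  if (any(v < 0 | v > 1)) stop("all inputs must be fractions in [0, 1]")
  o1 <- frac_a_in_b * cov_a
  o2 <- frac_b_in_a * cov_b
  if (o1 <= 0 && o2 <= 0)
    stop("sets do not overlap: capture-recapture estimate is infinite")
  overlap <- mean(c(o1, o2))
  sides <- cov_a * cov_b / c(o1, o2)
  list(estimate = cov_a * cov_b / overlap,
       range = sort(sides[is.finite(sides)]),
       overlap = overlap)
}

#' Extrapolate the genome-wide CNV-miRNA count
#'
#' Expected number of miRNA loci covered by the full (extrapolated) CNV
#' complement: `n_loci * est_coverage * depletion_ratio`, where the depletion
#' ratio discounts coverage by the observed purifying-selection deficit at
#' miRNA loci.
#'
#' @param n_loci number of (nuclear) miRNA loci.
#' @param est_coverage estimated total genome coverage fraction.
#' @param depletion_ratio observed/expected coverage ratio at miRNA loci.
#' @return expected CNV-miRNA count (not rounded).
#' @export
extrapolate_cnv_mirna_count <- function(n_loci, est_coverage, depletion_ratio) {
  if (any(c(n_loci, est_coverage, depletion_ratio) < 0))
    stop("inputs must be non-negative")
  if (est_coverage > 1 || depletion_ratio > 1)
    warning("coverage or depletion ratio exceeds 1; extrapolating anyway")
  n_loci * est_coverage * depletion_ratio
}
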