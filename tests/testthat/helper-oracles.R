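# Independent per-base oracles for interval arithmetic, on toy genomes
# small enough for a logical-vector bitmap. These never call the package's
# merge/coverage path.

# bitmap of covered bases of one chromosome of length L (0-based half-open df)
bitmap_cover <- function(intervals, L) {
  v <- logical(L)
  for (i in seq_len(nrow(intervals))) {
    s <- intervals$start[i]; e <- min(intervals$end[i], L)
    if (e > s) v[(s + 1):e] <- TRUE
  }
  v
}

# per-base depth vector
bitmap_depth <- function(intervals, L) {
  v <- integer(L)
  for (i in seq_len(nrow(intervals))) {
    s <- intervals$start[i]; e <- min(intervals$end[i], L)
    if (e > s) v[(s + 1):e] <- v[(s + 1):e] + 1L
  }
  v
}

# contiguous TRUE runs of a bitmap as a 0-based half-open data.frame
bitmap_runs <- function(v, chrom = "chr1") {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  if (!any(keep)) return(data.frame(chrom = character(), start = numeric(),
                                    end = numeric()))
  data.frame(chrom = chrom, start = starts[keep], end = ends[keep],
             stringsAsFactors = FALSE)
}

random_intervals <- function(n, L, max_len = max(2, L %/% 10), chrom = "chr1") {
  len <- sample.int(max_len, n, replace = TRUE)
  start <- vapply(len, function(l) sample.int(L - l + 1, 1) - 1, numeric(1))
  gi(rep(chrom, n), start, start + len)
}

# exact binomial lower tail by direct log-space summation (oracle for pbinom)
binom_lower_tail_oracle <- function(q, n, p) {
  if (p == 0) return(1)
  if (p == 1) return(if (q >= n) 1 else 0)
  i <- 0:q
  sum(exp(lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)))
}

# two-sided Fisher p by brute-force enumeration of all tables with the
# observed margins (oracle for the dhyper-based implementation)
fisher_oracle <- function(a, row1, c, row2) {
  m <- a + c; n <- (row1 - a) + (row2 - c); k <- row1
  support <- max(0, k - n):min(k, m)
  probs <- vapply(support, function(x) {
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k))
  }, numeric(1))
  pobs <- probs[support == a]
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

fixture_sets <- function() {
  fx <- reference_tables()
  list(
    loci_smc = fx$mirna[fx$mirna$set_label == "polymorphic-SMC", ],
    loci_dc = fx$mirna[fx$mirna$set_label == "polymorphic-DC", ],
    cnv_smc = fx$cnvs[fx$cnvs$set_label == "polymorphic-SMC", ],
    cnv_dc = fx$cnvs[fx$cnvs$set_label == "polymorphic-DC", ],
    fx = fx)
}
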