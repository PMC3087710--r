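#' Configuration for synthetic dataset generation
#'
#' The generator emulates the structure the analysis assumes: pre-miRNA-sized
#' loci scattered without overlap on a genome, CNVs (1 kb - 1 Mb, log-uniform
#' lengths) placed with a relative propensity `rho` to overlap miRNA loci
#' (`rho = 1` neutral, `rho < 1` purifying depletion), and SNPs placed as
#' independent per-bp Bernoulli events with separate densities inside and
#' outside the loci.
#'
#' @param seed integer seed; identical seed + config gives a bit-identical
#'   dataset. Component sub-streams (loci, CNVs, SNPs) are derived
#'   deterministically so adding SNPs does not perturb CNV placement.
#' @param chromosomes data.frame `chrom`, `length` (default 5 x 2 Mb toy
#'   genome for fast tests).
#' @param n_mirnas number of non-overlapping miRNA loci.
#' @param mirna_length locus length range in bp, sampled uniformly (default
#'   60-150, the pre-miRNA hairpin scale).
#' @param n_cnvs number of CNV regions.
#' @param cnv_length CNV length range in bp, sampled log-uniformly (default
#'   1 kb - 1 Mb, the field's working definition of CNV scale).
#' @param rho relative propensity of a CNV to overlap a miRNA locus, >= 0.
#' @param snp_rate_in,snp_rate_out SNP densities per 1,000 bp inside/outside
#'   miRNA loci (defaults 3.7 and 4.8, the observed human pre-miRNA vs
#'   genome-background rates).
#' @param records_lambda Poisson mean for the number of extra deposited
#'   records stacked on each CNV region (each region has 1 + Pois records).
#' @param genotype_model named numeric vector of copy-number state
#'   probabilities (names = integer copy numbers).
#' @param genotype_draws individuals drawn per region to form the observed
#'   genotype list.
#' @return validated config list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             chromosomes = data.frame(
                               chrom = paste0("chr", 1:5),
                               length = rep(2e6, 5)),
                             n_mirnas = 200L,
                             mirna_length = c(60, 150),
                             n_cnvs = 100L,
                             cnv_length = c(1e3, 1e6),
                             rho = 1,
                             snp_rate_in = 3.7,
                             snp_rate_out = 4.8,
                             records_lambda = 3,
                             genotype_model = c("0" = 0.05, "1" = 0.15,
                                                "2" = 0.55, "3" = 0.15,
                                                "4" = 0.10),
                             genotype_draws = 20L) {
  stopifnot(rho >= 0, snp_rate_in >= 0, snp_rate_out >= 0,
            length(mirna_length) == 2, mirna_length[1] <= mirna_length[2],
            length(cnv_length) == 2, cnv_length[1] <= cnv_length[2],
            cnv_length[1] >= 1, all(genotype_model >= 0))
  cfg <- list(seed = as.integer(seed), chromosomes = chromosomes,
              n_mirnas = as.integer(n_mirnas), mirna_length = mirna_length,
              n_cnvs = as.integer(n_cnvs), cnv_length = cnv_length, rho = rho,
              snp_rate_in = snp_rate_in, snp_rate_out = snp_rate_out,
              records_lambda = records_lambda,
              genotype_model = genotype_model / sum(genotype_model),
              genotype_draws = as.integer(genotype_draws))
  class(cfg) <- "synthetic_config"
  cfg
}

# deterministic per-component sub-stream seeds, kept under 2^31
component_seed <- function(seed, component) {
  offs <- c(loci = 1L, cnvs = 2L, snps = 3L, records = 4L)
  as.integer((as.numeric(seed) * 48271 + offs[[component]] * 1000003) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic dataset
#'
#' Places miRNA loci uniformly without overlap, CNVs by rejection thinning
#' (a candidate CNV that overlaps >= 1 miRNA locus is kept with probability
#' `rho` when `rho <= 1`; for `rho > 1` non-overlapping candidates are thinned
#' by `1/rho`), and SNPs as per-bp Bernoulli draws at the configured inside/
#' outside rates. Each CNV region also receives a simulated deposited-record
#' stack and an observed genotype list.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_dataset` with elements `genome`
#'   ([genome_model()]), `loci`, `cnvs`, `records` (per-region stacks),
#'   `snps`, and `truth` (the generating parameters).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  genome <- genome_model(config$chromosomes$chrom, config$chromosomes$length)
  loci <- with_seed(component_seed(config$seed, "loci"),
                    place_loci(config, genome))
  cnvs <- with_seed(component_seed(config$seed, "cnvs"),
                    place_cnvs(config, genome, loci))
  records <- with_seed(component_seed(config$seed, "records"),
                       stack_records(config, cnvs))
  snps <- with_seed(component_seed(config$seed, "snps"),
                    place_snps(config, genome, loci))
  out <- list(genome = genome, loci = loci, cnvs = cnvs, records = records,
              snps = snps, truth = config)
  class(out) <- "synthetic_dataset"
  out
}

place_loci <- function(config, genome) {
  n <- config$n_mirnas
  if (n == 0)
    return(mirna_loci(character(), character(), numeric(), numeric()))
  lens <- round(stats::runif(n, config$mirna_length[1], config$mirna_length[2]))
  if (sum(lens) > 0.5 * genome_total_bp(genome))
    stop("infeasible packing: miRNA loci would occupy more than half the genome")
  # chromosome assignment proportional to length, then per-chromosome
  # batch rejection until all loci are disjoint
  probs <- genome$length / sum(genome$length)
  chrom <- sample(genome$chrom, n, replace = TRUE, prob = probs)
  starts <- numeric(n)
  for (ch in unique(chrom)) {
    L <- genome$length[genome$chrom == ch]
    if (any(lens[chrom == ch] > L))
      stop("infeasible packing: locus longer than chromosome ", ch)
    s <- numeric(0); e <- numeric(0)
    pending <- which(chrom == ch)
    for (iter in 1:500) {
      cand <- floor(stats::runif(length(pending), 0, L - lens[pending] + 1))
      ord <- order(cand)
      cand <- cand[ord]; who <- pending[ord]
      acc <- logical(length(cand)); last <- -1
      for (j in seq_along(cand)) {
        cs <- cand[j]; ce <- cs + lens[who[j]]
        if (cs >= last && !overlaps_any(cs, ce, s, e)) {
          acc[j] <- TRUE; last <- ce
        }
      }
      starts[who[acc]] <- cand[acc]
      s <- c(s, cand[acc]); e <- c(e, cand[acc] + lens[who[acc]])
      pending <- who[!acc]
      if (!length(pending)) break
    }
    if (length(pending))
      stop("infeasible packing: could not place all miRNA loci on ", ch)
  }
  loci <- mirna_loci(sprintf("syn-mir-%04d", seq_len(n)), chrom,
                     starts + 1, starts + lens)
  loci[order(loci$chrom, loci$start), , drop = FALSE]
}

overlaps_any <- function(s2, e2, s, e) {
  if (!length(s)) return(rep(FALSE, length(s2)))
  o <- order(s); s <- s[o]; e <- e[o]
  vapply(seq_along(s2), function(j) {
    i <- findInterval(s2[j], s)
    (i >= 1 && e[i] > s2[j]) || (i < length(s) && s[i + 1] < e2[j])
  }, logical(1))
}

place_cnvs <- function(config, genome, loci) {
  n <- config$n_cnvs
  if (n == 0) return(cnv_regions(character(), numeric(), numeric()))
  by_chr <- split(loci, loci$chrom)
  probs <- genome$length / sum(genome$length)
  acc_chrom <- character(0); acc_start <- numeric(0); acc_end <- numeric(0)
  guard <- 0
  while (length(acc_chrom) < n && guard < 10000) {
    guard <- guard + 1
    m <- 2L * (n - length(acc_chrom)) + 10L
    chrom <- sample(genome$chrom, m, replace = TRUE, prob = probs)
    len <- round(exp(stats::runif(m, log(config$cnv_length[1]),
                                  log(config$cnv_length[2]))))
    L <- genome$length[match(chrom, genome$chrom)]
    len <- pmin(len, L)
    start <- floor(stats::runif(m, 0, L - len))
    end <- start + len
    hits <- logical(m)
    for (ch in unique(chrom)) {
      lo <- by_chr[[ch]]
      if (is.null(lo) || !nrow(lo)) next
      j <- which(chrom == ch)
      o <- order(lo$start); ls <- lo$start[o]; le <- lo$end[o]
      i <- findInterval(start[j], ls)
      hits[j] <- (i >= 1 & le[pmax(i, 1)] > start[j]) |
        (i < length(ls) & ls[pmin(i + 1, length(ls))] < end[j])
    }
    u <- stats::runif(m)
    keep <- if (config$rho <= 1) !hits | u < config$rho else hits | u < 1 / config$rho
    k <- which(keep)
    if (length(k)) {
      take <- utils::head(k, n - length(acc_chrom))
      acc_chrom <- c(acc_chrom, chrom[take])
      acc_start <- c(acc_start, start[take])
      acc_end <- c(acc_end, end[take])
    }
  }
  if (length(acc_chrom) < n)
    stop("CNV placement did not converge (rho too extreme for this genome?)")
  gts <- replicate(n, {
    cn <- sort(unique(sample(as.integer(names(config$genotype_model)),
                             config$genotype_draws, replace = TRUE,
                             prob = config$genotype_model)))
    paste(cn, collapse = ",")
  })
  out <- cnv_regions(acc_chrom, acc_start + 1, acc_end, set_label = "synthetic",
                     genotypes = gts, cnv_id = sprintf("syn-cnv-%05d", seq_len(n)))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$cnv_id <- sprintf("syn-cnv-%05d", seq_len(n))
  rownames(out) <- NULL
  out
}

stack_records <- function(config, cnvs) {
  if (!nrow(cnvs)) return(cnv_regions(character(), numeric(), numeric()))
  reps <- lapply(seq_len(nrow(cnvs)), function(i) {
    k <- 1L + stats::rpois(1, config$records_lambda)
    len <- cnvs$end[i] - cnvs$start[i]
    jit_s <- c(0, round(stats::runif(k - 1, -0.2, 0.2) * len))
    jit_e <- c(0, round(stats::runif(k - 1, -0.2, 0.2) * len))
    s <- pmax(0, cnvs$start[i] + jit_s)
    e <- pmax(s + 1, cnvs$end[i] + jit_e)
    cnv_regions(rep(cnvs$chrom[i], k), s + 1, e, set_label = "synthetic-records",
                cnv_id = cnvs$cnv_id[i],
                reference = sprintf("study-%02d", sample.int(5, k, replace = TRUE)))
  })
  out <- do.call(rbind, reps)
  rownames(out) <- NULL
  out
}

place_snps <- function(config, genome, loci) {
  if (config$snp_rate_in == 0 && config$snp_rate_out == 0)
    return(snp_set(character(), numeric(), "synthetic"))
  res_chrom <- character(0); res_pos <- numeric(0)
  for (ci in seq_len(nrow(genome))) {
    ch <- genome$chrom[ci]; L <- genome$length[ci]
    lo <- loci[loci$chrom == ch, , drop = FALSE]
    lo <- lo[order(lo$start), , drop = FALSE]
    seg_in <- cbind(lo$start, lo$end)
    bnd <- c(0, as.vector(t(seg_in)), L)
    gap_s <- bnd[seq(1, length(bnd) - 1, by = 2)]
    gap_e <- bnd[seq(2, length(bnd), by = 2)]
    keep <- gap_e > gap_s
    pos_in <- sample_segment_positions(lo$start, lo$end, config$snp_rate_in / 1000)
    pos_out <- sample_segment_positions(gap_s[keep], gap_e[keep],
                                        config$snp_rate_out / 1000)
    pos <- c(pos_in, pos_out)
    res_chrom <- c(res_chrom, rep(ch, length(pos)))
    res_pos <- c(res_pos, pos + 1)
  }
  snp_set(res_chrom, res_pos, "synthetic")
}

# per-bp Bernoulli over a union of disjoint segments = binomial count +
# uniform distinct offsets, mapped back through the segment structure
sample_segment_positions <- function(seg_s, seg_e, p) {
  total <- sum(seg_e - seg_s)
  if (total <= 0 || p <= 0) return(numeric(0))
  count <- stats::rbinom(1, total, p)
  if (count == 0) return(numeric(0))
  off <- sort(sample.int(total, count)) - 1
  cl <- cumsum(seg_e - seg_s)
  idx <- findInterval(off, c(0, cl), rightmost.closed = FALSE)
  seg_s[idx] + (off - c(0, cl)[idx])
}

#' Summarize the realized depletion of a synthetic dataset
#'
#' Convenience wrapper: computes the CNV genome coverage fraction, counts the
#' covered miRNA loci, and runs [depletion_test()].
#'
#' @param dataset a [simulate_dataset()] result.
#' @return a `depletion_result`.
#' @export
dataset_depletion <- function(dataset) {
  frac <- base_coverage_fraction(dataset$cnvs, dataset$genome)
  ncov <- feature_coverage_count(dataset$loci, dataset$cnvs)
  depletion_test(ncov, nrow(dataset$loci), frac)
}
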