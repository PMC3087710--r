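#' Validate a pipeline run configuration
#'
#' A run config is an R list (or a path to a JSON file with the same shape)
#' with fields:
#' \describe{
#'   \item{genome}{path to a chrom/length TSV, or a data.frame, or a
#'     [genome_model()]. Required unless every set has an explicit
#'     `genome_fraction`.}
#'   \item{mirna}{path to a miRNA TSV or a locus data.frame. Required.}
#'   \item{cnv_sets}{named list; each element a CNV region data.frame or a
#'     list `list(path=, dialect=)` for [read_cnv_table()]. Required.}
#'   \item{snp}{optional SNP table path or data.frame.}
#'   \item{disease_regions}{optional interval data.frame or BED path.}
#'   \item{genome_fraction}{optional named numeric: per-set coverage fraction
#'     overriding the computed one (the printed-value route; a notice is
#'     logged when it wins).}
#'   \item{n_loci_total}{optional explicit total miRNA locus count for the
#'     depletion null (same printed-value route: needed when the locus table
#'     only lists the called loci; defaults to the distinct nuclear loci
#'     read).}
#'   \item{min_overlap_bp, short_kb, large_kb}{thresholds (defaults 1, 5, 20).}
#'   \item{k_grid}{strictly increasing integer vector of narrowing thresholds
#'     (default `c(1, 2, 5, 10)`), applied per set with `criterion="records"`.}
#'   \item{extrapolation}{optional list `cov_a`, `cov_b`, `frac_a_in_b`,
#'     `frac_b_in_a`, and optionally `depletion_ratio` (default: mean observed/
#'     expected ratio over the sets) and `n_loci` (default: nuclear locus
#'     count).}
#'   \item{out_dir}{output directory. Required.}
#'   \item{seed}{integer seed recorded in the log (no pipeline stage is
#'     stochastic; present for config completeness).}
#' }
#'
#' @param config list or JSON path.
#' @return validated config list (paths resolved, defaults filled).
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config))
      stop(validation_error(paste0("config file not found: ", config)))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop(validation_error("config must be a list"))
  need <- c("mirna", "cnv_sets", "out_dir")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop(validation_error(paste0("config lacks field(s): ",
                                 paste(miss, collapse = ", "))))
  for (f in c("mirna", "genome", "snp")) {
    v <- config[[f]]
    if (!is.null(v) && is.character(v) && !file.exists(v))
      stop(validation_error(paste0(f, " path not found: ", v)))
  }
  if (is.null(names(config$cnv_sets)) || any(!nzchar(names(config$cnv_sets))))
    stop(validation_error("cnv_sets must be a named list"))
  for (nm in names(config$cnv_sets)) {
    v <- config$cnv_sets[[nm]]
    if (is.list(v) && !is.data.frame(v) && !is.null(v$path) && !file.exists(v$path))
      stop(validation_error(paste0("cnv set '", nm, "' path not found: ", v$path)))
  }
  defaults <- list(min_overlap_bp = 1L, short_kb = 5, large_kb = 20,
                   k_grid = c(1L, 2L, 5L, 10L), seed = 1L)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  k <- config$k_grid
  if (any(diff(k) <= 0) || any(k < 1))
    stop(validation_error("k_grid must be strictly increasing and >= 1"))
  gf <- config$genome_fraction
  if (!is.null(gf) && is.null(names(gf)))
    stop(validation_error("genome_fraction must be a named vector/list"))
  if (is.null(config$genome) && !all(names(config$cnv_sets) %in% names(gf)))
    stop(validation_error(
      "without a genome model every cnv set needs an explicit genome_fraction"))
  config
}

validation_error <- function(msg) {
  structure(class = c("mircnv_validation_error", "error", "condition"),
            list(message = msg, call = NULL))
}

stage_error <- function(stage, e) {
  structure(class = c("mircnv_stage_error", "error", "condition"),
            list(message = paste0("stage '", stage, "' failed: ",
                                  conditionMessage(e)), call = NULL))
}

load_input <- function(x, reader, ...) {
  if (is.data.frame(x) || is.null(x)) x else reader(x, ...)
}

#' Run the full CNV-miRNA analysis pipeline
#'
#' Reads inputs, filters mitochondrial loci, calls CNV-miRNAs per set,
#' computes the depletion test per set and per narrowing stratum, compares
#' SNP density inside vs outside loci, classifies calls, extrapolates total
#' polymorphic coverage, and writes a deterministic TSV report bundle plus a
#' machine-readable JSON run log.
#'
#' @param config see [validate_run_config()].
#' @return invisibly, a list with the in-memory results (`calls`, `depletion`,
#'   `snp_density`, `extrapolation`, `log`).
#' @export
run_pipeline <- function(config) {
  cfg <- validate_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      if (inherits(e, "mircnv_stage_error")) stop(e)
      stop(stage_error(stage, e))
    })
  }
  genome <- run_stage("read-genome", {
    g <- cfg$genome
    if (is.character(g)) g <- read_genome_model(g)
    else if (is.data.frame(g) && !inherits(g, "genome_model"))
      g <- genome_model(g$chrom, g$length)
    g
  })
  loci <- run_stage("read-mirna", {
    filter_nuclear(load_input(cfg$mirna, read_mirna_table))
  })
  sets <- run_stage("read-cnv", {
    lapply(cfg$cnv_sets, function(v) {
      if (is.data.frame(v)) v
      else read_cnv_table(v$path,
                          dialect = if (is.null(v$dialect)) "dgv-tsv" else v$dialect)
    })
  })

  calls <- run_stage("call", {
    out <- lapply(names(sets), function(nm) {
      call_cnv_mirnas(loci, sets[[nm]], set_label = nm,
                      min_overlap_bp = cfg$min_overlap_bp,
                      short_kb = cfg$short_kb, large_kb = cfg$large_kb)
    })
    names(out) <- names(sets)
    out
  })

  depletion <- run_stage("deplete", {
    rows <- list()
    n_distinct <- sum(!duplicated(feature_key(loci)))
    n_tot <- if (!is.null(cfg$n_loci_total)) as.numeric(cfg$n_loci_total)
             else n_distinct
    for (nm in names(sets)) {
      explicit <- cfg$genome_fraction[[nm]]
      for (k in cfg$k_grid) {
        regions <- if (k == 1) gi_merge(sets[[nm]])
                   else narrow_by_support(sets[[nm]], k)
        frac <- if (!is.null(explicit) && k == 1) {
          log_msg("set '", nm, "': explicit genome_fraction ", explicit,
                  " overrides computed value")
          as.numeric(explicit)
        } else if (is.null(genome)) NA_real_
          else base_coverage_fraction(regions, genome)
        if (is.na(frac)) next
        ncov <- feature_coverage_count(loci, regions,
                                       min_overlap_bp = cfg$min_overlap_bp)
        dt <- depletion_test(ncov, n_tot, frac)
        rows[[paste(nm, k)]] <- data.frame(
          set_label = nm, k = k, n_total = dt$n_total, n_covered = dt$n_covered,
          genome_fraction = dt$genome_fraction, expected = dt$expected,
          ratio = if (dt$expected > 0) observed_vs_expected_ratio(dt) else NA_real_,
          p_lower_tail = dt$p_lower_tail, stringsAsFactors = FALSE)
      }
    }
    if (!length(rows)) NULL
    else do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })

  snp_res <- NULL
  if (!is.null(cfg$snp)) {
    snp_res <- run_stage("snp-density", {
      snps <- load_input(cfg$snp, read_snp_table)
      snp_density_vs_loci(snps, loci, genome)
    })
  }

  extrap <- NULL
  if (!is.null(cfg$extrapolation)) {
    extrap <- run_stage("extrapolate", {
      ex <- cfg$extrapolation
      cr <- capture_recapture_union(ex$cov_a, ex$cov_b,
                                    ex$frac_a_in_b, ex$frac_b_in_a)
      ratio <- if (!is.null(ex$depletion_ratio)) ex$depletion_ratio
               else mean(depletion$ratio[depletion$k == 1], na.rm = TRUE)
      n_loci <- if (!is.null(ex$n_loci)) ex$n_loci else nrow(loci)
      n_est <- extrapolate_cnv_mirna_count(n_loci, cr$estimate, ratio)
      data.frame(est_coverage = cr$estimate, coverage_lo = cr$range[1],
                 coverage_hi = cr$range[length(cr$range)],
                 depletion_ratio = ratio, n_loci = n_loci,
                 expected_cnv_mirnas = n_est)
    })
  }

  disease <- NULL
  if (!is.null(cfg$disease_regions)) {
    disease <- run_stage("disease-overlap", {
      dr <- cfg$disease_regions
      if (is.character(dr)) dr <- read_cnv_table(dr, dialect = "bed",
                                                 set_label = "disease")
      disease_region_overlap(loci, dr, min_overlap_bp = cfg$min_overlap_bp)
    })
  }

  run_stage("report", {
    all_calls <- do.call(rbind, c(calls, list(make.row.names = FALSE)))
    for (nm in names(calls))
      write_calls_tsv(calls[[nm]], file.path(cfg$out_dir,
                                             paste0("calls_", nm, ".tsv")))
    write_calls_tsv(all_calls, file.path(cfg$out_dir, "classification.tsv"))
    utils::write.table(depletion, file.path(cfg$out_dir, "depletion.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(snp_res)) {
      d <- data.frame(snps_in = snp_res$snps_in, bp_in = snp_res$bp_in,
                      snps_out = snp_res$snps_out, bp_out = snp_res$bp_out,
                      rate_in = round(snp_res$rate_in, 1),
                      rate_out = round(snp_res$rate_out, 1),
                      p_fisher = snp_res$p_fisher)
      utils::write.table(d, file.path(cfg$out_dir, "snp_density.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(extrap))
      utils::write.table(extrap, file.path(cfg$out_dir, "extrapolation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(disease))
      write_calls_tsv(disease, file.path(cfg$out_dir, "disease_calls.tsv"))
  })

  log <- run_stage("log", {
    inputs <- Filter(is.character, cfg[c("genome", "mirna", "snp")])
    checks <- if (length(inputs))
      as.list(tools::md5sum(unlist(inputs))) else list()
    cfg_for_hash <- cfg[setdiff(names(cfg), "out_dir")]
    cfg_json <- jsonlite::toJSON(cfg_for_hash, auto_unbox = TRUE, digits = NA,
                                 force = TRUE)
    hash_file <- tempfile(); writeLines(cfg_json, hash_file)
    entry <- list(package = "mircnv",
                  version = as.character(utils::packageVersion("mircnv")),
                  seed = cfg$seed,
                  config_md5 = unname(tools::md5sum(hash_file)),
                  input_md5 = checks,
                  timestamp = format(Sys.time(), tz = "UTC"))
    unlink(hash_file)
    jsonlite::write_json(entry, file.path(cfg$out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    entry
  })

  invisible(list(calls = calls, depletion = depletion, snp_density = snp_res,
                 extrapolation = extrap, disease = disease, log = log))
}

#' SNP density inside vs outside a locus set
#'
#' Counts SNPs falling in the merged loci, takes locus bp as the "inside"
#' denominator and the remaining (non-excluded) genome as the "outside"
#' denominator, and runs [snp_density_test()].
#'
#' @param snps SNP data.frame (`chrom`, 1-based `pos`).
#' @param loci locus data.frame.
#' @param genome a [genome_model()].
#' @return a `snp_density_result`.
#' @export
snp_density_vs_loci <- function(snps, loci, genome) {
  if (is.null(genome)) stop("snp density needs a genome model")
  excl <- attr(genome, "exclude")
  snps <- snps[!snps$chrom %in% excl, , drop = FALSE]
  loci <- loci[!loci$chrom %in% excl, , drop = FALSE]
  merged <- gi_merge(loci)
  pt <- gi(snps$chrom, snps$pos - 1, snps$pos)
  inside <- overlap_with_set(pt, merged) > 0
  bp_in <- sum(gi_length(merged))
  bp_out <- genome_total_bp(genome) - bp_in
  snp_density_test(sum(inside), bp_in, sum(!inside) , bp_out)
}
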