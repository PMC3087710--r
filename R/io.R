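#' Read a miRNA locus table
#'
#' Reads miRBase-style locus tables. The `tsv` format expects header columns
#' `id`, `chrom`, `start`, `end` (1-based inclusive) plus optional `dupl`
#' (comma-separated list of other chromosomes carrying near-identical copies).
#' The `gff-like` format is a 9-column tab file whose column 1 is the
#' chromosome, columns 4/5 the 1-based inclusive span, and whose attribute
#' field (column 9) carries `ID=<name>` or `Name=<name>`.
#'
#' The same miRNA id may legitimately occur at several distinct loci
#' (e.g. mir-1233 on chr15); locus identity for all counting downstream is
#' `(id, chrom, start, end)`, never the id alone.
#'
#' @param path file path.
#' @param format `"tsv"` or `"gff-like"`.
#' @return data.frame with columns `id`, `chrom`, `start`, `end` (internal
#'   0-based half-open), `dupl`, `mitochondrial`.
#' @export
read_mirna_table <- function(path, format = c("tsv", "gff-like")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("miRNA table not found: ", path)
  if (format == "tsv") {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("id", "chrom", "start", "end")
    miss <- setdiff(need, names(d))
    if (length(miss))
      stop("miRNA table ", path, " lacks column(s): ", paste(miss, collapse = ", "))
    if (nrow(d) == 0) {
      warning("miRNA table ", path, " has a header but no rows")
      return(mirna_loci(character(), character(), numeric(), numeric()))
    }
    loci <- mirna_loci(d$id, d$chrom, d$start, d$end,
                       dupl = if ("dupl" %in% names(d)) d$dupl else NA)
  } else {
    d <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
    if (nrow(d) == 0) {
      warning("miRNA table ", path, " is empty")
      return(mirna_loci(character(), character(), numeric(), numeric()))
    }
    if (ncol(d) < 9) stop("gff-like file ", path, " needs 9 columns")
    id <- sub(".*(?:ID|Name)=([^;]+).*", "\\1", d[[9]])
    loci <- mirna_loci(id, d[[1]], d[[4]], d[[5]])
  }
  log_msg("read ", nrow(loci), " miRNA loci from ", path)
  loci
}

#' Build a miRNA locus table from vectors
#'
#' @param id miRNA names (miRBase style, e.g. "hsa-mir-384").
#' @param chrom,start,end coordinates, 1-based inclusive as printed.
#' @param dupl optional comma-separated duplicate-chromosome annotations.
#' @return locus data.frame (see [read_mirna_table()]).
#' @export
mirna_loci <- function(id, chrom, start, end, dupl = NA) {
  if (length(id) == 0)
    return(cbind(data.frame(id = character()), gi_empty(),
                 data.frame(dupl = character(), mitochondrial = logical())))
  id <- as.character(id)
  if (anyNA(id) || any(!nzchar(id))) stop("miRNA ids must be non-empty")
  bad <- which(is.na(suppressWarnings(as.numeric(start))) |
               is.na(suppressWarnings(as.numeric(end))))
  if (length(bad))
    stop("unparseable coordinates in miRNA table at row ", bad[1])
  iv <- gi(chrom, as.numeric(start) - 1, as.numeric(end))
  out <- cbind(data.frame(id = id, stringsAsFactors = FALSE), iv)
  out$dupl <- rep_len(as.character(dupl), nrow(out))
  out$mitochondrial <- is_mitochondrial(out$chrom)
  out
}

#' Drop mitochondrial loci
#'
#' Pre-miRNA loci on the mitochondrial genome are excluded from all nuclear
#' analyses (the depletion null is defined on the nuclear genome).
#'
#' @param loci locus data.frame.
#' @return the non-mitochondrial subset.
#' @export
filter_nuclear <- function(loci) {
  keep <- !is_mitochondrial(loci$chrom)
  out <- loci[keep, , drop = FALSE]
  rownames(out) <- NULL
  log_msg("nuclear filter: ", nrow(loci), " -> ", nrow(out), " loci")
  out
}

#' Registry of known CNV set labels
#' @return character vector of declared labels; user-defined labels are
#'   accepted anywhere a `set_label` is taken.
#' @export
cnv_set_labels <- function() c("DGV", "polymorphic-SMC", "polymorphic-DC")

#' Build a CNV region table from vectors
#'
#' @param chrom,start,end coordinates, 1-based inclusive as printed.
#' @param set_label CNV set label (see [cnv_set_labels()]; free labels allowed).
#' @param n_records count of overlapping deposited records.
#' @param n_references count of reporting publications.
#' @param frequency observation count in discovery studies.
#' @param genotypes comma-separated observed integer copy numbers ("0,1,2").
#' @param cnv_id source identifier.
#' @param reference optional per-record publication identifier (needed for
#'   reference-wise narrowing).
#' @return CNV region data.frame with internal 0-based half-open coordinates.
#' @export
cnv_regions <- function(chrom, start, end, set_label = "user-defined",
                        n_records = 1L, n_references = NA_integer_,
                        frequency = NA_integer_, genotypes = NA_character_,
                        cnv_id = NA_character_, reference = NA_character_) {
  if (length(chrom) == 0)
    return(cbind(gi_empty(),
                 data.frame(set_label = character(), n_records = integer(),
                            n_references = integer(), frequency = integer(),
                            genotypes = character(), cnv_id = character(),
                            reference = character())))
  iv <- gi(chrom, as.numeric(start) - 1, as.numeric(end))
  n <- nrow(iv)
  out <- iv
  out$set_label <- rep_len(as.character(set_label), n)
  out$n_records <- rep_len(as.integer(n_records), n)
  out$n_references <- rep_len(as.integer(n_references), n)
  out$frequency <- rep_len(as.integer(frequency), n)
  out$genotypes <- rep_len(as.character(genotypes), n)
  out$cnv_id <- rep_len(as.character(cnv_id), n)
  out$reference <- rep_len(as.character(reference), n)
  bad <- with(out, c(n_records, n_references, frequency))
  if (any(bad < 0, na.rm = TRUE))
    stop("n_records / n_references / frequency must be >= 0")
  gt <- parse_genotypes(out$genotypes)
  if (any(vapply(gt, function(g) any(g < 0), FALSE)))
    stop("genotype copy numbers must be >= 0")
  out
}

#' Parse genotype strings
#' @param x character vector like "2,3,4,5,6" (NA allowed).
#' @return list of integer vectors (empty for NA/blank).
#' @export
parse_genotypes <- function(x) {
  lapply(as.character(x), function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(integer())
    v <- suppressWarnings(as.integer(strsplit(trimws(s), "\\s*,\\s*")[[1]]))
    if (anyNA(v)) stop("malformed genotype list: ", s)
    v
  })
}

#' Read a CNV region table
#'
#' Dialects:
#' \describe{
#'   \item{dgv-tsv}{generic DGV-style TSV with named columns `chrom`, `start`,
#'     `end` (1-based inclusive) and optional `variation_type`, `n_records`,
#'     `n_references`, `frequency`, `genotypes`, `cnv_id`, `reference`. Rows
#'     are retained only when `variation_type` equals `include_type`
#'     (default "Copy Number"); a file without that column keeps all rows.}
#'   \item{bed}{3+ column BED, 0-based half-open, no header.}
#'   \item{region-tsv}{TSV with columns `set_label`, `id`, `region`
#'     (printed "chrN:a-b" form), `genotypes`, `cnv_id` — the layout of the
#'     bundled polymorphic CNV-miRNA table transcription.}
#' }
#'
#' @param path file path.
#' @param dialect one of `"dgv-tsv"`, `"bed"`, `"region-tsv"`.
#' @param set_label label attached to the returned regions (defaults by
#'   dialect; `region-tsv` keeps its own column).
#' @param include_type variation-type inclusion value for `dgv-tsv`.
#' @return CNV region data.frame (see [cnv_regions()]).
#' @export
read_cnv_table <- function(path, dialect = c("dgv-tsv", "bed", "region-tsv"),
                           set_label = NULL, include_type = "Copy Number") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("CNV table not found: ", path)
  if (dialect == "dgv-tsv") {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end")
    miss <- setdiff(need, names(d))
    if (length(miss))
      stop("CNV table ", path, " lacks column(s): ", paste(miss, collapse = ", "))
    if ("variation_type" %in% names(d)) d <- d[d$variation_type == include_type, ]
    col <- function(nm, default) if (nm %in% names(d)) d[[nm]] else default
    out <- cnv_regions(d$chrom, d$start, d$end,
                       set_label = if (is.null(set_label)) "DGV" else set_label,
                       n_records = col("n_records", 1L),
                       n_references = col("n_references", NA_integer_),
                       frequency = col("frequency", NA_integer_),
                       genotypes = col("genotypes", NA_character_),
                       cnv_id = col("cnv_id", NA_character_),
                       reference = col("reference", NA_character_))
  } else if (dialect == "bed") {
    d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(d) < 3) stop("BED file ", path, " needs >= 3 columns")
    # BED is already 0-based half-open; cnv_regions() expects printed 1-based
    out <- cnv_regions(d[[1]], d[[2]] + 1, d[[3]],
                       set_label = if (is.null(set_label)) "user-defined" else set_label,
                       cnv_id = if (ncol(d) >= 4) as.character(d[[4]]) else NA_character_)
  } else {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    iv <- parse_region(d$region)
    out <- cnv_regions(iv$chrom, iv$start + 1, iv$end,
                       set_label = d$set_label,
                       genotypes = if ("genotypes" %in% names(d)) d$genotypes else NA,
                       cnv_id = if ("cnv_id" %in% names(d)) as.character(d$cnv_id) else NA)
    if (!is.null(set_label)) out$set_label <- set_label
  }
  log_msg("read ", nrow(out), " CNV regions (", dialect, ") from ", path)
  out
}

#' Write intervals as BED
#'
#' @param x interval data.frame (internal 0-based half-open — identical to
#'   BED, so this is a direct column dump).
#' @param path output path.
#' @param name optional name column.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, name = NULL) {
  d <- data.frame(chrom = x$chrom, start = x$start, end = x$end)
  if (!is.null(name)) d$name <- name
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a SNP position list
#'
#' @param path TSV with header columns `chrom`, `pos` (1-based), or a 2+
#'   column headerless BED-like file (`chrom`, 0-based `pos`... use
#'   `format = "bed"` for that).
#' @param format `"tsv"` or `"bed"`.
#' @param build_label free-text provenance label.
#' @return data.frame `chrom`, `pos` (1-based), unique per (chrom, pos), with
#'   attribute `build_label`.
#' @export
read_snp_table <- function(path, format = c("tsv", "bed"), build_label = "") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("SNP table not found: ", path)
  if (format == "tsv") {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("chrom", "pos") %in% names(d)))
      stop("SNP table ", path, " needs columns chrom, pos")
    out <- snp_set(d$chrom, d$pos, build_label)
  } else {
    d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    out <- snp_set(d[[1]], d[[2]] + 1, build_label)
  }
  out
}

#' Build a SNP set from vectors
#' @param chrom chromosome names.
#' @param pos 1-based positions.
#' @param build_label free-text provenance label.
#' @return data.frame `chrom`, `pos`, deduplicated.
#' @export
snp_set <- function(chrom, pos, build_label = "") {
  d <- unique(data.frame(chrom = normalize_chrom(chrom), pos = as.numeric(pos),
                         stringsAsFactors = FALSE))
  d <- d[order(d$chrom, d$pos), , drop = FALSE]
  rownames(d) <- NULL
  attr(d, "build_label") <- build_label
  d
}

#' Read a genome model from a two-column TSV
#' @param path TSV with header columns `chrom`, `length`.
#' @param exclude excluded chromosomes (default mitochondrial).
#' @return a [genome_model()].
#' @export
read_genome_model <- function(path, exclude = "chrM") {
  if (!file.exists(path)) stop("genome model not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("chrom", "length") %in% names(d)))
    stop("genome model ", path, " needs columns chrom, length")
  genome_model(d$chrom, d$length, exclude = exclude)
}

#' Write / read CNV-miRNA call tables
#'
#' Serializes calls (see [call_cnv_mirnas()]) with deterministic column order
#' and (chrom, start, set_label) row sort; locus and region coordinates are
#' written in printed 1-based inclusive form so a write-read round trip
#' reproduces the calls.
#'
#' @param calls call data.frame.
#' @param path output TSV path.
#' @return `path` invisibly (`write_calls_tsv`); the call data.frame
#'   (`read_calls_tsv`).
#' @export
write_calls_tsv <- function(calls, path) {
  cols <- c("id", "locus", "set_label", "region", "overlap_bp",
            "fully_contained", "flank_left", "flank_right", "minimal_region",
            "n_supporting_records", "genotypes", "copy_min", "copy_max",
            "multiallelic", "flank_class", "dosage_effect", "region_name")
  d <- calls
  d$locus <- format_region(gi(d$chrom, d$start, d$end))
  d$region <- format_region(gi(d$region_chrom, d$region_start, d$region_end))
  for (nm in setdiff(cols, names(d))) d[[nm]] <- rep(NA, nrow(d))
  d <- d[order(d$chrom, d$start, d$set_label), cols, drop = FALSE]
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls_tsv
#' @export
read_calls_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  loc <- parse_region(d$locus)
  reg <- parse_region(d$region)
  d$chrom <- loc$chrom; d$start <- loc$start; d$end <- loc$end
  d$region_chrom <- reg$chrom; d$region_start <- reg$start; d$region_end <- reg$end
  d$locus <- NULL; d$region <- NULL
  d
}

log_msg <- function(...) {
  if (isTRUE(getOption("mircnv.quiet", TRUE))) return(invisible())
  message("[mircnv] ", ...)
}
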