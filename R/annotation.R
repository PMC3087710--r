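#' Call CNV-miRNAs for one region set
#'
#' Emits one call per distinct locus identity with >= `min_overlap_bp` shared
#' bases against the merged region set. The reported `region_*` columns come
#' from the single deposited record with the largest overlap (ties broken by
#' coordinate order); flank distances and flank class are computed within that
#' record when it fully contains the locus, the minimal region is the common
#' intersection of *all* records overlapping the locus, and
#' `n_supporting_records` counts those records.
#'
#' @param loci nuclear-filtered locus data.frame ([read_mirna_table()]).
#' @param regions CNV region data.frame ([read_cnv_table()] / [cnv_regions()]).
#' @param set_label label stamped on the calls (default: the regions' own).
#' @param min_overlap_bp minimum shared bases (default 1).
#' @param short_kb,large_kb flank-class thresholds, see [classify_flanks()].
#' @return call data.frame, one row per called locus, ordered by
#'   (chrom, start, end, id).
#' @export
call_cnv_mirnas <- function(loci, regions, set_label = NULL,
                            min_overlap_bp = 1L, short_kb = 5, large_kb = 20) {
  if (is.null(set_label))
    set_label <- if (nrow(regions)) regions$set_label[1] else "user-defined"
  key <- feature_key(loci)
  loci <- loci[!duplicated(key), , drop = FALSE]
  merged <- gi_merge(regions)
  ov <- overlap_with_set(loci, merged)
  hit <- which(ov >= min_overlap_bp)
  calls <- lapply(hit, function(i) {
    locus <- loci[i, , drop = FALSE]
    rec <- regions[overlap_bp(regions, locus) >= 1, , drop = FALSE]
    rec_ov <- overlap_bp(rec, locus)
    best <- rec[order(-rec_ov, rec$chrom, rec$start, rec$end)[1], , drop = FALSE]
    contained <- best$start <= locus$start && best$end >= locus$end
    fl <- if (contained) flank_distances(locus, best) else c(left = NA_real_, right = NA_real_)
    mr <- minimal_region(locus, rec)
    gt <- parse_genotypes(best$genotypes)[[1]]
    data.frame(
      id = if ("id" %in% names(locus)) locus$id else NA_character_,
      chrom = locus$chrom, start = locus$start, end = locus$end,
      set_label = set_label,
      region_chrom = best$chrom, region_start = best$start,
      region_end = best$end,
      overlap_bp = ov[i], fully_contained = contained,
      flank_left = fl[["left"]], flank_right = fl[["right"]],
      minimal_region = format_region(mr$interval),
      minimal_region_contains_locus = mr$contains_locus,
      n_supporting_records = mr$n_records,
      genotypes = best$genotypes,
      copy_min = if (length(gt)) min(gt) else NA_integer_,
      copy_max = if (length(gt)) max(gt) else NA_integer_,
      multiallelic = if (length(gt)) is_multiallelic(gt) else NA,
      cnv_id = best$cnv_id,
      stringsAsFactors = FALSE)
  })
  out <- if (length(calls)) do.call(rbind, calls) else
    utils::head(data.frame(id = character(), chrom = character(),
                           start = numeric(), end = numeric(),
                           set_label = character(), region_chrom = character(),
                           region_start = numeric(), region_end = numeric(),
                           overlap_bp = numeric(), fully_contained = logical(),
                           flank_left = numeric(), flank_right = numeric(),
                           minimal_region = character(),
                           minimal_region_contains_locus = logical(),
                           n_supporting_records = integer(),
                           genotypes = character(), copy_min = integer(),
                           copy_max = integer(), multiallelic = logical(),
                           cnv_id = character(), stringsAsFactors = FALSE), 0)
  out <- out[order(out$chrom, out$start, out$end, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out$flank_class <- classify_flanks(out, short_kb = short_kb, large_kb = large_kb)
  out
}

#' Distinct locus identities across call sets
#'
#' Deduplicates calls (possibly concatenated from several CNV sets) down to
#' distinct `(id, chrom, start, end)` locus identities. A locus shared by two
#' sets counts once; two distinct loci of the same miRNA id count separately.
#'
#' @param calls call data.frame (rows from one or more sets).
#' @return data.frame of distinct loci (`id`, `chrom`, `start`, `end`).
#' @export
dedupe_loci <- function(calls) {
  key <- feature_key(calls)
  out <- calls[!duplicated(key), c("id", "chrom", "start", "end"), drop = FALSE]
  out <- out[order(out$chrom, out$start, out$end, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Minimal CNV region for a locus
#'
#' The narrowest segment supported by every deposited record overlapping the
#' locus: the common intersection of the records. When not all records contain
#' the locus the intersection may exclude part of (or all of) it; the result
#' flags this, and an empty common intersection falls back to the
#' highest-depth segment of the record stack restricted to the locus
#' neighborhood (the deepest common evidence), still flagged.
#'
#' @param locus one-row locus/interval data.frame.
#' @param overlapping_records CNV region data.frame; every row must overlap
#'   the locus.
#' @return list with `interval` (one-row data.frame), `n_records`, and
#'   `contains_locus` (logical).
#' @export
minimal_region <- function(locus, overlapping_records) {
  if (nrow(overlapping_records) == 0)
    stop("minimal_region() needs at least one overlapping record")
  if (any(overlap_bp(overlapping_records, locus) < 1))
    stop("all records must overlap the locus")
  common <- intersect_all(overlapping_records)
  if (nrow(common) == 0) {
    depth <- narrow_by_support(overlapping_records, nrow(overlapping_records))
    common <- if (nrow(depth)) depth[1, , drop = FALSE] else
      gi(locus$chrom, locus$start, locus$end)
  }
  list(interval = common[, c("chrom", "start", "end")],
       n_records = nrow(overlapping_records),
       contains_locus = common$start <= locus$start && common$end >= locus$end)
}

is_multiallelic <- function(genotypes) {
  sum(genotypes > 2) >= 2 || length(unique(genotypes)) > 3
}

#' Copy-number summary over calls
#'
#' Global minimum and maximum copy number over all genotype lists, plus the
#' per-call multiallelic flag (a call is multiallelic when its genotype list
#' has at least two states above 2 copies or spans more than 3 states).
#'
#' @param calls call data.frame with a `genotypes` column.
#' @return list with `copy_min`, `copy_max`, and `multiallelic`
#'   (named logical vector, one per call with genotypes).
#' @export
copy_number_summary <- function(calls) {
  gt <- parse_genotypes(calls$genotypes)
  has <- vapply(gt, length, 1L) > 0
  if (!any(has)) stop("no call carries genotype data")
  if (!all(has))
    warning(sum(!has), " call(s) without genotypes skipped")
  all_gt <- unlist(gt[has])
  flags <- vapply(gt[has], is_multiallelic, FALSE)
  names(flags) <- paste(calls$id[has], format_region(calls[has, , drop = FALSE]))
  list(copy_min = min(all_gt), copy_max = max(all_gt), multiallelic = flags)
}

#' Classify flank geometry of contained calls
#'
#' For a locus fully contained in its CNV region: `short_both` when both flank
#' distances are below `short_kb` kilobases, `large_both` when both reach
#' `large_kb`, `mixed` otherwise; calls not fully contained are
#' `partial_overlap`.
#'
#' @param calls call data.frame (needs `fully_contained`, `flank_left`,
#'   `flank_right`).
#' @param short_kb,large_kb thresholds in kb (defaults 5 and 20).
#' @return character vector of classes, one per call.
#' @export
classify_flanks <- function(calls, short_kb = 5, large_kb = 20) {
  s <- short_kb * 1000; l <- large_kb * 1000
  out <- rep("partial_overlap", nrow(calls))
  fc <- which(calls$fully_contained)
  left <- calls$flank_left[fc]; right <- calls$flank_right[fc]
  out[fc] <- ifelse(left < s & right < s, "short_both",
                    ifelse(left >= l & right >= l, "large_both", "mixed"))
  out
}

#' Sketch of a miRNA gene model
#'
#' Minimal gene architecture needed for dosage prediction: the primary
#' transcript span, the pre-miRNA hairpin inside it, and the promoter/TSS
#' anchor at the transcript's 5' end (strand-dependent).
#'
#' @param transcript one-row interval data.frame (primary transcript span).
#' @param hairpin one-row interval data.frame (pre-miRNA), contained in the
#'   transcript span.
#' @param strand `"+"` or `"-"`.
#' @return object of class `gene_model_sketch`.
#' @export
gene_model_sketch <- function(transcript, hairpin, strand = "+") {
  strand <- match.arg(strand, c("+", "-"))
  if (hairpin$chrom != transcript$chrom ||
      hairpin$start < transcript$start || hairpin$end > transcript$end)
    stop("hairpin must be contained in the transcript span")
  g <- list(transcript = transcript, hairpin = hairpin, strand = strand,
            promoter = if (strand == "+") transcript$start else transcript$end - 1)
  class(g) <- "gene_model_sketch"
  g
}

#' Predict the dosage effect of a CNV on a miRNA gene
#'
#' Rule table for the change in functional miRNA copy output when a deletion
#' or (tandem) duplication overlaps a miRNA gene:
#' \describe{
#'   \item{deletion}{removes the hairpin -> `decrease`; removes the
#'     promoter/5' end but not the hairpin -> `decrease` (the truncated
#'     transcript lacks a promoter); crosses only the 3' transcript boundary,
#'     sparing hairpin and promoter -> `indeterminate` (depends on the
#'     stability of the 3'-truncated transcript); wholly intragenic, sparing
#'     hairpin and promoter -> `none`.}
#'   \item{duplication}{covers the whole gene -> `increase`; a tandem segment
#'     containing the hairpin and either the promoter or lying wholly inside
#'     the transcript -> `increase` (extra hairpin copies in one primary
#'     transcript); a segment without the hairpin -> `none`.}
#' }
#'
#' @param gene a [gene_model_sketch()].
#' @param cnv_interval one-row interval data.frame; must overlap the
#'   transcript span.
#' @param cnv_kind `"deletion"` or `"duplication"`.
#' @return one of `"increase"`, `"decrease"`, `"none"`, `"indeterminate"`.
#' @export
classify_dosage <- function(gene, cnv_interval, cnv_kind = c("deletion", "duplication")) {
  cnv_kind <- match.arg(cnv_kind)
  tx <- gene$transcript; hp <- gene$hairpin
  if (overlap_bp(cnv_interval, tx) < 1)
    stop("CNV does not overlap the gene's transcript span")
  covers_hairpin <- cnv_interval$start <= hp$start && cnv_interval$end >= hp$end
  covers_promoter <- cnv_interval$start <= gene$promoter &&
    cnv_interval$end > gene$promoter
  whole_gene <- cnv_interval$start <= tx$start && cnv_interval$end >= tx$end
  inside_tx <- cnv_interval$start >= tx$start && cnv_interval$end <= tx$end
  # which transcript boundary does a partial CNV cross? (strand-aware 3' end)
  crosses_3p <- if (gene$strand == "+") cnv_interval$end > tx$end &&
    cnv_interval$start > tx$start else cnv_interval$start < tx$start &&
    cnv_interval$end < tx$end
  if (cnv_kind == "deletion") {
    if (covers_hairpin) return("decrease")
    if (covers_promoter) return("decrease")
    if (crosses_3p) return("indeterminate")
    return("none")
  }
  if (whole_gene) return("increase")
  if (covers_hairpin && (covers_promoter || inside_tx)) return("increase")
  "none"
}

#' Overlap miRNA loci with disease-implicated regions
#'
#' Same >= 1 bp co-localization contract as [call_cnv_mirnas()] with set label
#' `"disease"`; when the region table carries a `name` column (syndrome
#' label), each call is annotated with the name(s) of the region(s) hit.
#'
#' @param loci nuclear-filtered locus data.frame.
#' @param disease_regions interval data.frame, optionally with a `name`
#'   column (e.g. read from BED column 4 into `cnv_id`).
#' @param min_overlap_bp minimum shared bases (default 1).
#' @return call data.frame with a `region_name` column.
#' @export
disease_region_overlap <- function(loci, disease_regions, min_overlap_bp = 1L) {
  if (nrow(disease_regions) == 0) {
    out <- call_cnv_mirnas(loci, cnv_regions(character(), numeric(), numeric()),
                           set_label = "disease")
    out$region_name <- character(0)
    return(out)
  }
  nm <- if ("name" %in% names(disease_regions)) disease_regions$name
        else if ("cnv_id" %in% names(disease_regions)) disease_regions$cnv_id
        else format_region(disease_regions)
  regions <- cnv_regions(disease_regions$chrom, disease_regions$start + 1,
                         disease_regions$end, set_label = "disease",
                         cnv_id = nm)
  calls <- call_cnv_mirnas(loci, regions, set_label = "disease",
                           min_overlap_bp = min_overlap_bp)
  calls$region_name <- vapply(seq_len(nrow(calls)), function(i) {
    locus <- calls[i, c("chrom", "start", "end"), drop = FALSE]
    paste(sort(unique(nm[overlap_bp(regions, locus) >= 1])), collapse = ";")
  }, character(1))
  calls[order(calls$region_name, calls$chrom, calls$start), , drop = FALSE]
}
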