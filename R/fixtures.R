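#' Bundled CNV-miRNA reference tables
#'
#' Machine-readable transcription of the published polymorphic CNV-miRNA
#' tables bundled with the package: the 12 locus/region rows of the two
#' highly polymorphic CNV sets ('polymorphic-SMC', 4 rows; 'polymorphic-DC',
#' 8 rows, with mir-1233 occupying two distinct chr15 loci inside one region)
#' and the 23 top-validated rows with their minimal CNV regions and
#' deposited-record counts.
#'
#' @return list with elements
#'   \describe{
#'     \item{mirna}{locus data.frame with a `set_label` column (12 rows).}
#'     \item{cnvs}{deduplicated CNV region data.frame (one row per distinct
#'       region per set) carrying genotypes and source ids.}
#'     \item{validated}{data.frame of top-validated loci: locus coordinates,
#'       `minimal_region` (printed form), `n_records`.}
#'   }
#' @examples
#' fx <- reference_tables()
#' table(fx$mirna$set_label)
#' @export
reference_tables <- function() {
  p1 <- system.file("extdata", "polymorphic_cnv_mirnas.tsv", package = "mircnv",
                    mustWork = TRUE)
  p2 <- system.file("extdata", "validated_cnv_mirnas.tsv", package = "mircnv",
                    mustWork = TRUE)
  t1 <- utils::read.delim(p1, stringsAsFactors = FALSE)
  loc <- parse_region(t1$locus)
  mirna <- cbind(data.frame(set_label = t1$set_label, stringsAsFactors = FALSE),
                 mirna_loci(t1$id, loc$chrom, loc$start + 1, loc$end,
                            dupl = t1$dupl))
  reg <- parse_region(t1$region)
  cnvs <- cnv_regions(reg$chrom, reg$start + 1, reg$end,
                      set_label = t1$set_label, genotypes = t1$genotypes,
                      cnv_id = as.character(t1$cnv_id))
  cnvs <- cnvs[!duplicated(cnvs[c("set_label", "chrom", "start", "end", "cnv_id")]), ]
  rownames(cnvs) <- NULL
  t2 <- utils::read.delim(p2, stringsAsFactors = FALSE)
  vloc <- parse_region(t2$locus)
  validated <- cbind(mirna_loci(t2$id, vloc$chrom, vloc$start + 1, vloc$end,
                                dupl = t2$dupl),
                     data.frame(minimal_region = t2$minimal_region,
                                n_records = t2$n_records,
                                stringsAsFactors = FALSE))
  list(mirna = mirna, cnvs = cnvs, validated = validated)
}
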