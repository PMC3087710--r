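#' Genomic interval tables
#'
#' All coordinate-carrying objects in mircnv are plain `data.frame`s with at
#' least the columns `chrom` (character), `start` and `end` (numeric).
#' Internally coordinates are 0-based half-open, so an interval's length is
#' `end - start`. Printed/serialized coordinates ("chrN:a-b", and the `start`/
#' `end` columns of TSV inputs) are 1-based inclusive, the dialect of
#' 2009-era genome browsers, miRBase and DGV; [parse_region()] and
#' [format_region()] convert between the two.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end numeric vectors, 0-based half-open.
#' @return A `data.frame` with columns `chrom`, `start`, `end`.
#' @examples
#' gi("chr1", 0, 100)
#' @export
gi <- function(chrom, start, end) {
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(as.character(chrom), n)
  start <- rep_len(as.numeric(start), n)
  end <- rep_len(as.numeric(end), n)
  if (anyNA(chrom) || any(!nzchar(chrom)))
    stop("interval chromosome names must be non-empty")
  if (anyNA(start) || anyNA(end))
    stop("interval coordinates must not be NA")
  if (any(start < 0))
    stop("interval start must be >= 0 (0-based internal convention)")
  if (any(end <= start))
    stop("intervals must have positive length (start < end)")
  data.frame(chrom = normalize_chrom(chrom), start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Interval lengths in base pairs
#' @param x interval data.frame (see [gi()]).
#' @return numeric vector of span lengths.
#' @export
gi_length <- function(x) x$end - x$start

#' Normalize chromosome names
#'
#' Mitochondrial aliases ("chrM", "chrMT", "M", "MT", case-insensitively) are
#' collapsed onto the single label `"chrM"` so the mitochondrial exclusion
#' filter is robust to input dialect. All other names pass through unchanged
#' (case-sensitively).
#'
#' @param chrom character vector.
#' @return character vector of normalized names.
#' @export
normalize_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  mito <- tolower(chrom) %in% c("chrm", "chrmt", "m", "mt")
  chrom[mito] <- "chrM"
  chrom
}

#' Is a chromosome name mitochondrial?
#' @param chrom character vector.
#' @return logical vector.
#' @export
is_mitochondrial <- function(chrom) normalize_chrom(chrom) == "chrM"

#' Parse printed region strings
#'
#' Parses `"chrom:start-end"` strings (1-based inclusive, e.g.
#' `"chrX:76056092-76056179"`) into internal 0-based half-open intervals.
#' Round-trips with [format_region()].
#'
#' @param text character vector of region strings.
#' @return interval data.frame; `gi_length()` of the result equals
#'   printed end - printed start + 1.
#' @examples
#' gi_length(parse_region("chrX:76056092-76056179")) # 88
#' @export
parse_region <- function(text) {
  text <- as.character(text)
  m <- regmatches(text, regexec("^([^:[:space:]]+):([0-9]+)-([0-9]+)$", text))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stop("malformed region string (expected 'chrom:start-end'): ",
         paste(text[bad], collapse = ", "))
  chrom <- vapply(m, `[`, "", 2L)
  s1 <- as.numeric(vapply(m, `[`, "", 3L))
  e1 <- as.numeric(vapply(m, `[`, "", 4L))
  if (any(s1 < 1))
    stop("region start must be positive (1-based): ", text[s1 < 1][1])
  if (any(s1 > e1))
    stop("region start exceeds end: ", text[s1 > e1][1])
  gi(chrom, s1 - 1, e1)
}

#' Serialize intervals to printed 1-based inclusive form
#' @param x interval data.frame.
#' @return character vector like `"chr1:100-200"`.
#' @export
format_region <- function(x) {
  sprintf("%s:%.0f-%.0f", x$chrom, x$start + 1, x$end)
}

#' Shared bases between two intervals
#'
#' Symmetric; 0 when the chromosomes differ or the spans are disjoint.
#' Vectorized over rows (shorter argument recycled).
#'
#' @param a,b interval data.frames.
#' @return numeric vector of overlap lengths in bp.
#' @export
overlap_bp <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  ov <- pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi])
  ov[a$chrom[ai] != b$chrom[bi]] <- 0
  pmax(ov, 0)
}

#' Merge intervals into a disjoint sorted set
#'
#' Union of the input bases as pairwise-disjoint intervals sorted by
#' (chrom, start). Backed by `IRanges::reduce()`; book-ended (touching)
#' intervals are joined, so total bp never exceeds the sum of input lengths.
#'
#' @param x interval data.frame (any number of chromosomes; may be empty).
#' @return disjoint sorted interval data.frame.
#' @export
gi_merge <- function(x) {
  if (is.null(x) || nrow(x) == 0)
    return(gi_empty())
  parts <- lapply(split(seq_len(nrow(x)), x$chrom), function(i) {
    r <- IRanges::reduce(IRanges::IRanges(start = as.integer(x$start[i] + 1),
                                          end = as.integer(x$end[i])))
    gi(x$chrom[i][1], IRanges::start(r) - 1, IRanges::end(r))
  })
  out <- do.call(rbind, parts[order(names(parts))])
  rownames(out) <- NULL
  out
}

gi_empty <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             stringsAsFactors = FALSE)
}

#' Total bases covered by an interval set
#' @param x interval data.frame (need not be disjoint).
#' @return total bp in the union of `x`.
#' @export
gi_total_bp <- function(x) sum(gi_length(gi_merge(x)))

#' Common intersection of intervals on one chromosome
#'
#' Returns `max(starts)..min(ends)` when that span is positive, otherwise an
#' empty interval table.
#'
#' @param x non-empty interval data.frame, all rows on one chromosome.
#' @return one-row interval data.frame, or a zero-row one when the common
#'   intersection is empty.
#' @export
intersect_all <- function(x) {
  if (nrow(x) == 0) stop("intersect_all() needs at least one interval")
  if (length(unique(x$chrom)) != 1L)
    stop("intersect_all() requires all intervals on one chromosome")
  s <- max(x$start); e <- min(x$end)
  if (s >= e) return(gi_empty())
  gi(x$chrom[1], s, e)
}

#' Flank distances of a contained feature
#'
#' For a feature fully contained in a region (same chromosome), the distances
#' from the region boundaries to the feature: `left + right + length(feature)
#' = length(region)`.
#'
#' @param feature,region one-row interval data.frames.
#' @return named numeric vector `c(left = ..., right = ...)`.
#' @export
flank_distances <- function(feature, region) {
  if (feature$chrom != region$chrom ||
      feature$start < region$start || feature$end > region$end)
    stop("feature is not fully contained in region ",
         "(partial overlaps must be handled by the caller)")
  c(left = feature$start - region$start, right = region$end - feature$end)
}

#' Genome model
#'
#' An ordered chromosome-name/length table with an excluded-chromosome set
#' (default: the mitochondrial genome). Excluded chromosomes are dropped from
#' both numerator and denominator of every coverage fraction.
#'
#' @param chrom character vector of unique chromosome names.
#' @param length positive chromosome lengths in bp.
#' @param exclude chromosome names excluded from analysis (normalized).
#' @return object of class `genome_model`: a data.frame with attribute
#'   `exclude`.
#' @export
genome_model <- function(chrom, length, exclude = "chrM") {
  chrom <- normalize_chrom(as.character(chrom))
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(length <= 0) || anyNA(length))
    stop("chromosome lengths must be strictly positive")
  g <- data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE)
  attr(g, "exclude") <- unique(normalize_chrom(exclude))
  class(g) <- c("genome_model", "data.frame")
  g
}

#' @rdname genome_model
#' @param g a `genome_model`.
#' @return `genome_total_bp()`: total bp of the non-excluded chromosomes.
#' @export
genome_total_bp <- function(g) {
  sum(g$length[!g$chrom %in% attr(g, "exclude")])
}

#' Check intervals against genome bounds
#'
#' Errors when an interval lies on a chromosome absent from the model or
#' extends past its chromosome's length.
#'
#' @param x interval data.frame.
#' @param g a `genome_model`.
#' @return `x`, invisibly.
#' @export
check_in_genome <- function(x, g) {
  i <- match(x$chrom, g$chrom)
  if (anyNA(i))
    stop("interval(s) on chromosome(s) absent from genome model: ",
         paste(unique(x$chrom[is.na(i)]), collapse = ", "))
  over <- x$end > g$length[i]
  if (any(over))
    stop("interval(s) exceed chromosome bounds: ",
         paste(format_region(x[over, , drop = FALSE])[1], collapse = ", "))
  invisible(x)
}
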