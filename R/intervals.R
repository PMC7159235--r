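#' Genomic interval tables
#'
#' All coordinates inside the package are 0-based half-open (BED convention):
#' an interval covers positions `start, start+1, ..., end-1`. One-based formats
#' (VCF) are converted at the boundary by the readers and writers, so every
#' piece of overlap arithmetic speaks a single dialect.
#'
#' An interval table is a tibble with columns `chrom` (character), `start`
#' and `end` (non-negative integers, `start < end`) and optionally `name`.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open.
#' @param name optional character vector of feature names.
#' @return A validated tibble with class `tbl_df`.
#' @examples
#' interval_table("chr1", 100, 200)
#' @export
interval_table <- function(chrom, start, end, name = NULL) {
  df <- tibble::tibble(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end)
  )
  if (!is.null(name)) df$name <- as.character(name)
  validate_intervals(df)
}

#' Validate an interval table
#'
#' Enforces the interval invariants (`start >= 0`, `start < end`, no missing
#' coordinates). Every interval emitted anywhere in the package passes through
#' this check.
#'
#' @param df a data frame with `chrom`, `start`, `end` columns.
#' @param context string used in error messages (e.g. a file name).
#' @return `df`, invisibly unchanged, as a tibble.
#' @export
validate_intervals <- function(df, context = "interval table") {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (anyNA(df$chrom) || anyNA(df$start) || anyNA(df$end)) {
    stop(context, ": missing chrom/start/end values", call. = FALSE)
  }
  bad <- which(df$start < 0 | df$start >= df$end)
  if (length(bad) > 0) {
    stop(context, ": invalid interval at row ", bad[1], " (start=",
         df$start[bad[1]], ", end=", df$end[bad[1]],
         "); need 0 <= start < end", call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Canonical enhancer identifier
#'
#' Enhancer ids are canonicalized as `"chrom:start-end"` in internal (0-based
#' half-open) coordinates, matching the compound keys used by enhancer-target
#' network files (`chr:start-end$GENE`).
#'
#' @param chrom,start,end coordinate vectors.
#' @return character vector of ids.
#' @export
enhancer_id <- function(chrom, start, end) {
  sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))
}

#' Parse region ids, including compound network keys
#'
#' Accepts `"chr1:100-200"` and the compound form `"chr1:100-200$GENE"`; the
#' gene part, when present, is returned in a `gene` column.
#'
#' @param ids character vector of region ids.
#' @return tibble with `id`, `chrom`, `start`, `end` and `gene` (NA when the
#'   id is not compound).
#' @export
parse_region_id <- function(ids) {
  ids <- as.character(ids)
  m <- regmatches(ids, regexec("^([^:]+):([0-9]+)-([0-9]+)(\\$(.+))?$", ids))
  bad <- which(vapply(m, length, integer(1)) == 0)
  if (length(bad) > 0) {
    stop("cannot parse region id '", ids[bad[1]], "'", call. = FALSE)
  }
  tibble::tibble(
    id = vapply(m, function(x) paste0(x[2], ":", x[3], "-", x[4]), character(1)),
    chrom = vapply(m, `[`, character(1), 2),
    start = as.integer(vapply(m, `[`, character(1), 3)),
    end = as.integer(vapply(m, `[`, character(1), 4)),
    gene = ifelse(vapply(m, `[`, character(1), 6) == "", NA_character_,
                  vapply(m, `[`, character(1), 6))
  )
}

# Internal: convert an interval table to GRanges (1-based closed) for overlap
# machinery. The +1 happens here and only here.
as_granges0 <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# Internal: for each row of `a`, does it overlap (>= 1 bp) any row of `b`?
overlaps_any <- function(a, b) {
  if (nrow(b) == 0 || nrow(a) == 0) return(rep(FALSE, nrow(a)))
  ga <- as_granges0(a)
  gb <- as_granges0(b)
  IRanges::overlapsAny(ga, gb)
}

# Internal: for each row of `a`, is it fully contained in some row of `b`?
contained_in_any <- function(a, b) {
  if (nrow(b) == 0 || nrow(a) == 0) return(rep(FALSE, nrow(a)))
  ga <- as_granges0(a)
  gb <- as_granges0(b)
  IRanges::overlapsAny(ga, gb, type = "within")
}

# Internal: for each row of `a`, does some row of `b` satisfy strict reciprocal
# overlap: overlap/len(a) > frac AND overlap/len(b) > frac?
reciprocal_overlap_any <- function(a, b, frac = 0.5) {
  if (nrow(b) == 0 || nrow(a) == 0) return(rep(FALSE, nrow(a)))
  ga <- as_granges0(a)
  gb <- as_granges0(b)
  hits <- GenomicRanges::findOverlaps(ga, gb)
  if (length(hits) == 0) return(rep(FALSE, nrow(a)))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(ga[qi], gb[si]))
  ok <- ov / GenomicRanges::width(ga[qi]) > frac &
    ov / GenomicRanges::width(gb[si]) > frac
  out <- rep(FALSE, nrow(a))
  out[unique(qi[ok])] <- TRUE
  out
}

# Internal: pairwise overlap width in bp between single intervals (vectors ok).
overlap_width <- function(a_start, a_end, b_start, b_end) {
  pmax(0L, pmin(a_end, b_end) - pmax(a_start, b_start))
}
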