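#' @importFrom data.table data.table as.data.table setDT setorder fread fwrite :=
#' @importFrom GenomicRanges GRanges findOverlaps reduce
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

# All user-facing tables carry 0-based half-open coordinates (BED convention).
# GRanges is 1-based closed, so conversion happens only inside these helpers.

#' Validate a table of genomic intervals
#'
#' Checks the 0-based half-open coordinate invariants shared by every table
#' in the package: non-empty chromosome names, `start >= 0`, `end > start`.
#'
#' @param x data.frame with columns `chrom`, `start`, `end` (plus any others).
#' @param what label used in error messages.
#' @return `x`, invisibly, with chromosome names normalized (see
#'   [normalize_chrom()]).
#' @export
validate_intervals <- function(x, what = "interval table") {
  req <- c("chrom", "start", "end")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols))
    stop(what, " lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(x)) {
    if (any(is.na(x$chrom)) || any(!nzchar(as.character(x$chrom))))
      stop(what, ": empty chromosome name")
    if (any(x$start < 0)) stop(what, ": negative start coordinate")
    if (any(x$end <= x$start)) stop(what, ": end must exceed start (half-open)")
  }
  x$chrom <- normalize_chrom(x$chrom)
  invisible(x)
}

#' Normalize chromosome names
#'
#' Strips a leading `"chr"` prefix so mixed dialects (`chr1` vs `1`) compare
#' equal within a run. CNVs are unstranded; strand is never considered.
#'
#' @param chrom character vector of chromosome names.
#' @return character vector without the `chr` prefix.
#' @export
normalize_chrom <- function(chrom) {
  sub("^chr", "", as.character(chrom))
}

# Internal: interval table -> GRanges (shift to 1-based closed).
to_granges <- function(x) {
  GRanges(seqnames = normalize_chrom(x$chrom),
          ranges = IRanges(start = x$start + 1L, end = x$end))
}

# Internal: GRanges -> 0-based half-open data.frame.
from_granges <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Do two intervals overlap?
#'
#' Half-open semantics: intervals sharing only a boundary coordinate
#' (`end == start`) do not overlap.
#'
#' @param a,b single-row data.frames (or lists) with `chrom`, `start`, `end`.
#' @return logical scalar, `TRUE` iff the intervals share at least 1 bp.
#' @export
interval_overlaps <- function(a, b) {
  a <- validate_intervals(as.data.frame(a, stringsAsFactors = FALSE))
  b <- validate_intervals(as.data.frame(b, stringsAsFactors = FALSE))
  a$chrom == b$chrom & a$start < b$end & b$start < a$end
}

#' Length of the overlap between two intervals
#'
#' @inheritParams interval_overlaps
#' @return integer number of shared bases (0 when disjoint or on different
#'   chromosomes).
#' @export
overlap_width <- function(a, b) {
  if (a$chrom != b$chrom) return(0L)
  w <- min(a$end, b$end) - max(a$start, b$start)
  max(0L, as.integer(w))
}

#' Baits hit by an interval
#'
#' Returns the `bait_id`s of every target bait overlapping a query interval
#' by at least 1 bp, in genomic order. The bait table must already be sorted
#' by (chrom, start); an unsorted table is an error so callers cannot silently
#' get order-dependent results.
#'
#' @param query data.frame of intervals (`chrom`, `start`, `end`), one or
#'   more rows.
#' @param baits bait table with `chrom`, `start`, `end`, `bait_id`, sorted by
#'   (chrom, start).
#' @return for a single-row query, a character vector of bait ids; for a
#'   multi-row query, a list of such vectors (one per row).
#' @export
baits_hit <- function(query, baits) {
  baits <- check_sorted_baits(baits)
  query <- validate_intervals(as.data.frame(query), "query")
  hits <- findOverlaps(to_granges(query), to_granges(baits))
  out <- split(baits$bait_id[subjectHits(hits)],
               factor(queryHits(hits), levels = seq_len(nrow(query))))
  out <- lapply(out, as.character)
  if (nrow(query) == 1L) out[[1L]] else unname(out)
}

check_sorted_baits <- function(baits) {
  baits <- validate_intervals(baits, "bait table")
  if (!"bait_id" %in% names(baits)) stop("bait table lacks a bait_id column")
  if (anyDuplicated(baits$bait_id)) stop("bait_ids are not unique")
  o <- order(baits$chrom, baits$start)
  if (!identical(as.integer(o), seq_len(nrow(baits))))
    stop("bait table must be sorted by (chrom, start); sort it first")
  baits
}

#' Merge intervals into disjoint regions
#'
#' Merges overlapping intervals, and intervals on the same chromosome whose
#' gap is at most `gap` bases. With `gap = 0`, book-ended half-open intervals
#' (`end == start`) merge, so the union of covered bases is preserved.
#'
#' @param x interval data.frame.
#' @param gap non-negative integer; intervals separated by at most this many
#'   bases are joined.
#' @return data.frame of disjoint, sorted intervals.
#' @export
merge_intervals <- function(x, gap = 0L) {
  stopifnot(gap >= 0)
  if (nrow(x) == 0L)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  x <- validate_intervals(x)
  from_granges(reduce(to_granges(x), min.gapwidth = gap + 1L))
}

# ---- readers / writers ------------------------------------------------------

#' Read a BED file (3+ columns)
#'
#' @param path path to a tab-separated BED file without header.
#' @param extra_names optional names for columns beyond the first three.
#' @return data.frame with `chrom`, `start`, `end` and any extra columns,
#'   coordinates 0-based half-open as in the file.
#' @export
read_bed <- function(path, extra_names = NULL) {
  x <- fread(path, header = FALSE, sep = "\t", data.table = FALSE)
  n <- ncol(x)
  nm <- c("chrom", "start", "end")
  if (n > 3L) {
    more <- if (!is.null(extra_names)) extra_names else paste0("V", seq_len(n - 3L))
    nm <- c(nm, more[seq_len(n - 3L)])
  }
  names(x) <- nm
  validate_intervals(x, basename(path))
  x$chrom <- normalize_chrom(x$chrom)
  x[order(x$chrom, x$start), , drop = FALSE]
}

#' Write intervals as BED
#'
#' Output is sorted, tab-separated and newline-terminated.
#'
#' @param x interval data.frame; columns beyond chrom/start/end are kept.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- x[order(x$chrom, x$start), , drop = FALSE]
  fwrite(x, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a CNV call table
#'
#' Expects a header `chrom start end type sample caller` with BED-style
#' 0-based half-open coordinates and `type` in `{DEL, DUP}`.
#'
#' @param path path to the tab-separated call table.
#' @return data.frame of calls with normalized chromosome names.
#' @export
read_calls <- function(path) {
  x <- fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  req <- c("chrom", "start", "end", "type", "sample", "caller")
  if (!all(req %in% names(x)))
    stop("call table needs columns: ", paste(req, collapse = " "))
  x <- validate_intervals(x, basename(path))
  check_cnv_type(x$type)
  x[order(x$chrom, x$start), req, drop = FALSE]
}

check_cnv_type <- function(type) {
  bad <- setdiff(unique(type), c("DEL", "DUP"))
  if (length(bad))
    stop("cnv type must be DEL or DUP; found: ", paste(bad, collapse = ", "))
  invisible(type)
}

#' Write a CNV call table
#'
#' @param x call data.frame (`chrom start end type sample caller`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(x, path) {
  x <- x[order(x$chrom, x$start), , drop = FALSE]
  fwrite(x, path, sep = "\t")
  invisible(path)
}

#' Read a target-bait table
#'
#' Accepts BED3 plus a `bait_id` fourth column and optional `gc` /
#' `mappability` columns. When no id column is present one is fabricated
#' from the coordinates.
#'
#' @param path path to the bait BED/TSV.
#' @return sorted bait data.frame with unique `bait_id`s.
#' @export
read_baits <- function(path) {
  x <- read_bed(path, extra_names = c("bait_id", "gc", "mappability"))
  if (!"bait_id" %in% names(x))
    x$bait_id <- paste0(x$chrom, ":", x$start, "-", x$end)
  check_sorted_baits(x[order(x$chrom, x$start), , drop = FALSE])
}
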