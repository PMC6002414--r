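#' Genomic intervals
#'
#' Intervals are plain data frames with columns `contig`, `start`, `end` in
#' 0-based half-open coordinates (BED convention); extra columns are carried
#' along untouched.
#'
#' @param contig character vector.
#' @param start,end numeric vectors, `0 <= start < end`.
#' @param ... further columns of the same length.
#' @return a data frame of validated intervals.
#' @export
genomic_intervals <- function(contig, start, end, ...) {
  x <- data.frame(contig = as.character(contig), start = as.numeric(start),
                  end = as.numeric(end), ..., stringsAsFactors = FALSE)
  validate_intervals(x)
  x
}

#' @rdname genomic_intervals
#' @param x a data frame of intervals.
#' @export
validate_intervals <- function(x) {
  stopifnot(all(c("contig", "start", "end") %in% names(x)))
  if (nrow(x) && any(x$start < 0 | x$start >= x$end))
    .stopf("invalid interval(s): need 0 <= start < end")
  invisible(x)
}

.sort_intervals <- function(x) x[order(x$contig, x$start, x$end), , drop = FALSE]

# IRanges view of one contig's intervals (1-based closed internally; only
# used where coordinates are bounded by real contig sizes, i.e. < 2^31)
.ir <- function(x) IRanges::IRanges(start = x$start + 1L, end = x$end)

.from_ir <- function(ir, contig) {
  data.frame(contig = rep(contig, length(ir)),
             start = IRanges::start(ir) - 1L, end = IRanges::end(ir),
             stringsAsFactors = FALSE)
}

.per_contig <- function(x, f) {
  out <- lapply(split(x, x$contig), f)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res %||% data.frame(contig = character(), start = numeric(), end = numeric())
}

# merge overlapping/bookended intervals of one contig (double-safe sweep)
.merge_one <- function(d) {
  d <- d[order(d$start, d$end), , drop = FALSE]
  keep_s <- d$start[1L]; keep_e <- d$end[1L]
  s <- e <- numeric()
  for (i in seq_len(nrow(d))[-1L]) {
    if (d$start[i] <= keep_e) keep_e <- max(keep_e, d$end[i])
    else { s <- c(s, keep_s); e <- c(e, keep_e)
           keep_s <- d$start[i]; keep_e <- d$end[i] }
  }
  data.frame(contig = d$contig[1L], start = c(s, keep_s),
             end = c(e, keep_e), stringsAsFactors = FALSE)
}

#' Write intervals to BED
#'
#' Tab-separated, 0-based half-open, sorted by contig then start.  Unsorted
#' input is sorted; duplicate identical rows are removed with a message.
#' Overlapping intervals are written as-is (the writer never merges).
#'
#' @param intervals data frame of intervals (see [genomic_intervals()]).
#' @param path output path.
#' @param extra_columns optional character vector naming columns of
#'   `intervals` to append after the first three.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path, extra_columns = NULL) {
  validate_intervals(intervals)
  cols <- c("contig", "start", "end", extra_columns)
  x <- .sort_intervals(intervals[, cols, drop = FALSE])
  dup <- duplicated(x)
  if (any(dup)) {
    .msg(sum(dup), " duplicate interval row(s) removed")
    x <- x[!dup, , drop = FALSE]
  }
  x$start <- format(x$start, scientific = FALSE, trim = TRUE)
  x$end <- format(x$end, scientific = FALSE, trim = TRUE)
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file
#'
#' @param path BED path (>= 3 columns, no header).
#' @param extra_names optional names for columns beyond the third.
#' @return data frame of intervals.
#' @export
read_bed <- function(path, extra_names = NULL) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  nms <- c("contig", "start", "end")
  if (ncol(d) > 3L) {
    ex <- extra_names %||% paste0("V", seq_len(ncol(d) - 3L))
    nms <- c(nms, ex[seq_len(ncol(d) - 3L)])
  }
  names(d) <- nms
  d$contig <- as.character(d$contig)
  validate_intervals(d)
  d
}

#' Callable-region mask
#'
#' Normalises a set of intervals into a mask: sorted, with overlapping or
#' bookended intervals merged.  If `intervals` is omitted, the whole of each
#' contig in `contig_lengths` is callable.
#'
#' @param intervals optional data frame of callable intervals.
#' @param contig_lengths named vector of contig lengths (required when
#'   `intervals` is NULL).
#' @return data frame of sorted, non-overlapping intervals with class
#'   `callable_mask` prepended.
#' @export
callable_mask <- function(intervals = NULL, contig_lengths = NULL) {
  if (is.null(intervals)) {
    if (is.null(contig_lengths)) .stopf("need intervals or contig_lengths")
    intervals <- data.frame(contig = names(contig_lengths), start = 0,
                            end = as.numeric(contig_lengths),
                            stringsAsFactors = FALSE)
  }
  validate_intervals(intervals)
  if (nrow(intervals) == 0L) .stopf("callable mask is empty")
  out <- .per_contig(intervals, .merge_one)
  out <- .sort_intervals(out)
  if (sum(out$end - out$start) <= 0) .stopf("callable mask is empty")
  class(out) <- c("callable_mask", class(out))
  out
}

#' Total length of a set of intervals
#' @param x data frame of intervals.
#' @param merge merge overlaps before summing (default TRUE).
#' @return total bp.
#' @export
interval_bp <- function(x, merge = TRUE) {
  if (nrow(x) == 0L) return(0)
  if (!merge) return(sum(x$end - x$start))
  m <- .per_contig(x, .merge_one)
  sum(m$end - m$start)
}

#' Clip intervals to a mask
#'
#' Intersects each interval with the mask; extra columns are propagated to
#' every clipped piece.
#'
#' @param x data frame of intervals (extra columns allowed).
#' @param mask a [callable_mask()] (or any interval data frame).
#' @return clipped intervals.
#' @export
clip_intervals <- function(x, mask) {
  validate_intervals(x); validate_intervals(mask)
  if (nrow(x) == 0L) return(x)
  pieces <- lapply(seq_len(nrow(x)), function(i) {
    m <- mask[mask$contig == x$contig[i], , drop = FALSE]
    if (nrow(m) == 0L) return(NULL)
    s <- pmax(m$start, x$start[i]); e <- pmin(m$end, x$end[i])
    keep <- e > s
    if (!any(keep)) return(NULL)
    out <- data.frame(contig = x$contig[i], start = s[keep], end = e[keep],
                      stringsAsFactors = FALSE)
    extra <- x[i, setdiff(names(x), c("contig", "start", "end")), drop = FALSE]
    if (ncol(extra)) out <- cbind(out, extra[rep(1L, nrow(out)), , drop = FALSE])
    out
  })
  res <- do.call(rbind, pieces)
  rownames(res) <- NULL
  res %||% x[0L, , drop = FALSE]
}
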