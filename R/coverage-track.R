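#' Construct a coverage track
#'
#' A coverage track is a sparse per-base signal over a genome: a sorted set of
#' non-overlapping half-open intervals, each carrying a constant signal value.
#' Bases not covered by any interval implicitly carry value 0, following the
#' bedGraph convention of omitting zero runs. The total signal
#' `wigsum = sum(value * (end - start))` is carried along and used as the
#' normalization denominator.
#'
#' @param intervals data.frame with columns `chrom` (character), `start`
#'   (0-based, inclusive), `end` (exclusive), `value` (finite numeric).
#'   Intervals must be non-overlapping within each chromosome.
#' @param chrom_sizes named numeric vector of chromosome lengths in bp.
#' @return An object of class `coverage_track` with elements `chrom_sizes`,
#'   `intervals` (sorted), and `wigsum`.
#' @seealso [read_bedgraph()], [normalize_track()], [extract_profiles()]
#' @export
coverage_track <- function(intervals, chrom_sizes) {
  stopifnot(is.data.frame(intervals),
            all(c("chrom", "start", "end", "value") %in% names(intervals)))
  if (is.null(names(chrom_sizes)) && length(chrom_sizes) > 0)
    stop("chrom_sizes must be a named vector")
  intervals <- intervals[, c("chrom", "start", "end", "value")]
  intervals$chrom <- as.character(intervals$chrom)
  for (col in c("start", "end", "value"))
    intervals[[col]] <- as.numeric(intervals[[col]])
  if (nrow(intervals) > 0) {
    if (any(!is.finite(intervals$value)))
      stop("non-finite signal value in coverage track")
    bad_chrom <- setdiff(unique(intervals$chrom), names(chrom_sizes))
    if (length(bad_chrom) > 0)
      stop("unknown chromosome(s): ", paste(bad_chrom, collapse = ", "))
    if (any(intervals$start >= intervals$end))
      stop("interval with start >= end")
    if (any(intervals$start < 0))
      stop("negative start coordinate")
    if (any(intervals$end > chrom_sizes[intervals$chrom]))
      stop("interval extends beyond chromosome end")
    ord <- order(intervals$chrom, intervals$start)
    intervals <- intervals[ord, , drop = FALSE]
    rownames(intervals) <- NULL
    same <- intervals$chrom[-1] == intervals$chrom[-nrow(intervals)]
    if (nrow(intervals) > 1 &&
        any(same & intervals$start[-1] < intervals$end[-nrow(intervals)]))
      stop("overlapping intervals in coverage track")
  }
  structure(list(chrom_sizes = chrom_sizes,
                 intervals = intervals,
                 wigsum = track_wigsum(intervals)),
            class = "coverage_track")
}

track_wigsum <- function(intervals) {
  if (nrow(intervals) == 0) return(0)
  sum(intervals$value * (intervals$end - intervals$start))
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: %d intervals on %d chromosome(s), wigsum = %.6g\n",
              nrow(x$intervals), length(x$chrom_sizes), x$wigsum))
  invisible(x)
}

#' Read a bedGraph coverage file
#'
#' Reads a 4-column bedGraph (`chrom start end value`, 0-based half-open).
#' `track`, `browser` and `#` comment lines are tolerated and skipped.
#' Book-ended intervals with equal value are merged. Overlapping intervals,
#' chromosomes absent from `chrom_sizes`, and non-numeric values are errors;
#' the overlap error names the offending input line.
#'
#' @param path path to a bedGraph file.
#' @param chrom_sizes named numeric vector of chromosome lengths; must cover
#'   every chromosome referenced in the file.
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, chrom_sizes) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0)
    return(coverage_track(
      data.frame(chrom = character(), start = numeric(),
                 end = numeric(), value = numeric()),
      chrom_sizes))
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 4))
    stop("line ", line_no[which(nf < 4)[1]], ": expected 4 bedGraph columns")
  m <- matrix(unlist(lapply(fields, `[`, 1:4)), ncol = 4, byrow = TRUE)
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  value <- suppressWarnings(as.numeric(m[, 4]))
  for (v in list(start = start, end = end, value = value)) NULL
  bad <- which(!is.finite(start) | !is.finite(end) | !is.finite(value))
  if (length(bad) > 0)
    stop("line ", line_no[bad[1]], ": non-numeric coordinate or value")
  chrom <- m[, 1]
  unknown <- which(!(chrom %in% names(chrom_sizes)))
  if (length(unknown) > 0)
    stop("line ", line_no[unknown[1]], ": unknown chromosome '",
         chrom[unknown[1]], "'")
  if (any(start >= end))
    stop("line ", line_no[which(start >= end)[1]], ": start >= end")
  if (any(end > chrom_sizes[chrom])) {
    i <- which(end > chrom_sizes[chrom])[1]
    stop("line ", line_no[i], ": interval beyond end of ", chrom[i])
  }
  ord <- order(chrom, start)
  chrom <- chrom[ord]; start <- start[ord]; end <- end[ord]
  value <- value[ord]; line_no <- line_no[ord]
  n <- length(start)
  if (n > 1) {
    same <- chrom[-1] == chrom[-n]
    ovl <- which(same & start[-1] < end[-n])
    if (length(ovl) > 0)
      stop("line ", line_no[ovl[1] + 1], ": overlapping interval on ",
           chrom[ovl[1] + 1])
    # merge book-ended runs of equal value
    new_run <- c(TRUE, !(same & start[-1] == end[-n] & value[-1] == value[-n]))
    run <- cumsum(new_run)
    first <- which(new_run)
    chrom <- chrom[first]
    start <- start[first]
    end <- as.numeric(tapply(end, run, max))
    value <- value[first]
  }
  coverage_track(
    data.frame(chrom = chrom, start = start, end = end, value = value),
    chrom_sizes)
}

#' Write a coverage track as bedGraph
#'
#' Emits the covered intervals of a track as 4-column bedGraph. Zero-valued
#' intervals are written as-is; uncovered bases are simply absent.
#'
#' @param track a [coverage_track()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  iv <- track$intervals
  lines <- sprintf("%s\t%s\t%s\t%s", iv$chrom,
                   format(iv$start, scientific = FALSE, trim = TRUE),
                   format(iv$end, scientific = FALSE, trim = TRUE),
                   format(iv$value, digits = 17, scientific = FALSE,
                          trim = TRUE))
  writeLines(lines, path)
  invisible(path)
}

#' Rescale a track to a target total signal (wigsum normalization)
#'
#' Multiplies every signal value by `target_wigsum / wigsum(track)` so that
#' the genome-wide total signal equals `target_wigsum` (default 1e8, i.e.
#' a factor of 100 million). This makes tracks from libraries of different
#' sequencing depth directly comparable.
#'
#' @param track a [coverage_track()] with positive wigsum.
#' @param target_wigsum target total signal; default `1e8`.
#' @return A normalized [coverage_track()].
#' @export
normalize_track <- function(track, target_wigsum = 1e8) {
  if (track$wigsum == 0)
    stop("cannot normalize empty track")
  scale <- target_wigsum / track$wigsum
  track$intervals$value <- track$intervals$value * scale
  track$wigsum <- track_wigsum(track$intervals)
  track
}

#' Read a two-column chromosome sizes file
#'
#' @param path TSV with columns chromosome name and length (no header).
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "size"),
                           colClasses = c("character", "numeric"))
  stats::setNames(tab$size, tab$chrom)
}

#' Write a chromosome sizes file
#' @param chrom_sizes named numeric vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  writeLines(sprintf("%s\t%s", names(chrom_sizes),
                     format(chrom_sizes, scientific = FALSE, trim = TRUE)),
             path)
  invisible(path)
}
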