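#' Construct a profile matrix
#'
#' An L x G matrix of binned coverage, one row per region, on a common grid
#' of relative coordinates in `[-flank, +flank)`. The grid stores the left
#' edge of each bin; bins have constant width.
#'
#' @param values numeric L x G matrix of mean per-base signal per bin.
#' @param region_ids character vector of length L.
#' @param grid numeric vector of length G, strictly increasing, equidistant.
#' @return An object of class `profile_matrix`.
#' @export
profile_matrix <- function(values, region_ids, grid) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(region_ids),
            ncol(values) == length(grid))
  if (length(grid) > 1) {
    d <- diff(grid)
    if (any(d <= 0) || max(abs(d - d[1])) > 1e-9 * abs(d[1]))
      stop("grid must be strictly increasing and equidistant")
  }
  if (any(!is.finite(values)))
    stop("non-finite profile values")
  dimnames(values) <- NULL
  structure(list(values = values,
                 region_ids = as.character(region_ids),
                 grid = as.numeric(grid)),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("profile_matrix: %d regions x %d bins, grid [%g, %g] step %g\n",
              nrow(x$values), ncol(x$values), min(x$grid), max(x$grid),
              if (length(x$grid) > 1) x$grid[2] - x$grid[1] else NA))
  invisible(x)
}

#' Extract strand-oriented per-region coverage profiles
#'
#' Bins each region window `[anchor - flank, anchor + flank)` into
#' `G = 2 * flank / bin_size` bins and fills each cell with the mean per-base
#' signal over the bin (uncovered bases contribute 0). For `-` strand
#' regions the bin sequence is reversed, so the relative coordinate axis is
#' transcription-oriented: `-flank` is always upstream of the anchor.
#' Regions on a chromosome absent from the track yield an all-zero row and a
#' warning.
#'
#' @param track a [coverage_track()].
#' @param regions a [region_set()].
#' @param bin_size bin width in bp; `2 * flank` must be divisible by it.
#' @param oriented if `FALSE`, profiles are kept in genome orientation
#'   (no reversal of `-` strand rows); used by the ordinary
#'   coverage-correlation baseline.
#' @return A [profile_matrix()] with grid of bin left edges
#'   `-flank, -flank + bin_size, ...`.
#' @export
extract_profiles <- function(track, regions, bin_size = 10, oriented = TRUE) {
  flank <- regions$flank
  if ((2 * flank) %% bin_size != 0)
    stop("2 * flank must be divisible by bin_size")
  G <- as.integer(2 * flank / bin_size)
  e <- regions$entries
  L <- nrow(e)
  vals <- matrix(0, nrow = L, ncol = G)
  iv <- track$intervals
  missing_chroms <- character(0)
  for (ch in unique(e$chrom)) {
    ri <- which(e$chrom == ch)
    if (!(ch %in% names(track$chrom_sizes))) {
      missing_chroms <- c(missing_chroms, ch)
      next
    }
    ci <- which(iv$chrom == ch)
    if (length(ci) == 0) next
    win_start <- e$anchor[ri] - flank
    bin_start <- rep(win_start, each = G) +
      rep(seq_len(G) - 1, times = length(ri)) * bin_size
    q <- IRanges::IRanges(start = bin_start + 1, width = bin_size)
    s <- IRanges::IRanges(start = iv$start[ci] + 1, end = iv$end[ci])
    hits <- IRanges::findOverlaps(q, s)
    if (length(hits) > 0) {
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      ow <- pmin(IRanges::end(q)[qh], IRanges::end(s)[sh]) -
        pmax(IRanges::start(q)[qh], IRanges::start(s)[sh]) + 1
      contrib <- ow * iv$value[ci][sh]
      acc <- numeric(length(q))
      agg <- rowsum(contrib, group = qh)
      acc[as.integer(rownames(agg))] <- agg[, 1]
      block <- matrix(acc, nrow = length(ri), ncol = G, byrow = TRUE)
      vals[ri, ] <- block / bin_size
    }
  }
  if (length(missing_chroms) > 0)
    warning("chromosome(s) absent from track, rows set to 0: ",
            paste(missing_chroms, collapse = ", "))
  if (oriented) {
    neg <- which(e$strand == "-")
    if (length(neg) > 0)
      vals[neg, ] <- vals[neg, G:1, drop = FALSE]
  }
  profile_matrix(vals, e$region_id, -flank + (seq_len(G) - 1) * bin_size)
}

#' Write a profile matrix as TSV
#'
#' First column `region_id`, remaining columns one per grid coordinate, with
#' the grid values as the header.
#'
#' @param profiles a [profile_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_matrix <- function(profiles, path) {
  df <- data.frame(region_id = profiles$region_ids,
                   profiles$values, check.names = FALSE)
  names(df)[-1] <- format(profiles$grid, trim = TRUE, scientific = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a profile matrix written by [write_profile_matrix()]
#' @param path TSV path.
#' @return A [profile_matrix()].
#' @export
read_profile_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character")
  grid <- as.numeric(names(df)[-1])
  vals <- matrix(as.numeric(as.matrix(df[, -1, drop = FALSE])),
                 nrow = nrow(df))
  profile_matrix(vals, df[[1]], grid)
}
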