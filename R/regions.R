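#' Construct an anchored region set
#'
#' A region set is a collection of stranded, fixed-width genomic windows, each
#' centred on a single anchor base (typically a transcription start site).
#' The window of a region is `[anchor - flank, anchor + flank)` in 0-based
#' half-open coordinates, so every window has width `2 * flank`.
#'
#' @param entries data.frame with columns `region_id` (unique character),
#'   `chrom`, `anchor` (0-based bp), `strand` (`"+"` or `"-"`), and
#'   `class_label` (free-form, e.g. `"pc"` / `"nc"`).
#' @param flank half-width of the window in bp.
#' @return An object of class `region_set`.
#' @export
region_set <- function(entries, flank) {
  stopifnot(is.data.frame(entries),
            all(c("region_id", "chrom", "anchor", "strand", "class_label")
                %in% names(entries)),
            length(flank) == 1, flank > 0)
  entries <- entries[, c("region_id", "chrom", "anchor", "strand",
                         "class_label")]
  entries$region_id <- as.character(entries$region_id)
  entries$chrom <- as.character(entries$chrom)
  entries$anchor <- as.numeric(entries$anchor)
  entries$strand <- as.character(entries$strand)
  entries$class_label <- as.character(entries$class_label)
  if (anyDuplicated(entries$region_id))
    stop("duplicate region_id: ",
         entries$region_id[which(duplicated(entries$region_id))[1]])
  if (!all(entries$strand %in% c("+", "-")))
    stop("malformed strand; expected '+' or '-'")
  rownames(entries) <- NULL
  structure(list(entries = entries, flank = as.numeric(flank)),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region_set: %d regions, flank %g bp (window width %g bp)\n",
              nrow(x$entries), x$flank, 2 * x$flank))
  if (nrow(x$entries) > 0) {
    tab <- table(x$entries$class_label)
    cat("  classes:", paste(sprintf("%s=%d", names(tab), tab),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read anchored regions from a BED6 file
#'
#' The anchor of each feature is its transcription start site: the `start`
#' coordinate for `+` strand features and `end - 1` for `-` strand features.
#' Column 4 is the region id (must be unique), column 5 is read as a
#' free-form class label (e.g. `pc`/`nc`; a plain BED score is simply kept as
#' a string), column 6 the strand. Entries whose window
#' `[anchor - flank, anchor + flank)` would leave the chromosome are dropped
#' (the count is reported via `message()`); duplicate `(chrom, anchor,
#' strand)` entries are dropped keeping the first occurrence.
#'
#' @param path BED6 file path.
#' @param flank window half-width in bp.
#' @param chrom_sizes named numeric vector of chromosome lengths; every
#'   chromosome referenced must be present.
#' @return A [region_set()].
#' @export
read_regions <- function(path, flank, chrom_sizes) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  fields <- strsplit(lines, "[ \t]+")
  if (any(lengths(fields) < 6))
    stop("expected BED6 (6 columns)")
  m <- matrix(unlist(lapply(fields, `[`, 1:6)), ncol = 6, byrow = TRUE)
  chrom <- m[, 1]
  start <- as.numeric(m[, 2])
  end <- as.numeric(m[, 3])
  name <- m[, 4]
  class_label <- m[, 5]
  strand <- m[, 6]
  if (!all(strand %in% c("+", "-")))
    stop("malformed strand; expected '+' or '-'")
  unknown <- setdiff(unique(chrom), names(chrom_sizes))
  if (length(unknown) > 0)
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(name))
    stop("duplicate region_id: ", name[which(duplicated(name))[1]])
  anchor <- ifelse(strand == "+", start, end - 1)
  in_bounds <- anchor - flank >= 0 & anchor + flank <= chrom_sizes[chrom]
  n_dropped <- sum(!in_bounds)
  if (n_dropped > 0)
    message(n_dropped, " region(s) dropped: window exceeds chromosome bounds")
  keep <- in_bounds & !duplicated(paste(chrom, anchor, strand))
  n_dup <- sum(in_bounds) - sum(keep)
  if (n_dup > 0)
    message(n_dup, " duplicate (chrom, anchor, strand) region(s) dropped")
  region_set(data.frame(region_id = name[keep], chrom = chrom[keep],
                        anchor = anchor[keep], strand = strand[keep],
                        class_label = class_label[keep]),
             flank)
}

#' Write a region set as BED6
#'
#' Inverse of [read_regions()]: each region is written as a 1-bp feature at
#' its anchor, with the class label in column 5.
#'
#' @param regions a [region_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  e <- regions$entries
  start <- ifelse(e$strand == "+", e$anchor, e$anchor)
  lines <- sprintf("%s\t%s\t%s\t%s\t%s\t%s", e$chrom,
                   format(start, scientific = FALSE, trim = TRUE),
                   format(start + 1, scientific = FALSE, trim = TRUE),
                   e$region_id, e$class_label, e$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED3 blacklist file
#'
#' @param path BED3 file of artifact intervals to exclude.
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
read_blacklist <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  fields <- strsplit(lines, "[ \t]+")
  if (any(lengths(fields) < 3))
    stop("expected BED3 (3 columns)")
  m <- matrix(unlist(lapply(fields, `[`, 1:3)), ncol = 3, byrow = TRUE)
  data.frame(chrom = m[, 1], start = as.numeric(m[, 2]),
             end = as.numeric(m[, 3]))
}

#' Remove blacklisted and explicitly excluded regions
#'
#' Drops every region whose window overlaps a blacklist interval by at least
#' one base (half-open coordinates on both sides), and every region whose id
#' appears in `exclude_ids`. Input order is preserved; an empty result is
#' allowed.
#'
#' @param regions a [region_set()].
#' @param blacklist data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. from [read_blacklist()]; may be empty or `NULL`.
#' @param exclude_ids optional character vector of region ids to drop
#'   regardless of position (e.g. ribosomal genes).
#' @return A filtered [region_set()].
#' @export
filter_blacklist <- function(regions, blacklist = NULL, exclude_ids = NULL) {
  e <- regions$entries
  drop <- rep(FALSE, nrow(e))
  if (!is.null(blacklist) && nrow(blacklist) > 0 && nrow(e) > 0) {
    win_start <- e$anchor - regions$flank
    win_end <- e$anchor + regions$flank
    for (ch in unique(e$chrom)) {
      ri <- which(e$chrom == ch)
      bi <- which(blacklist$chrom == ch)
      if (length(bi) == 0) next
      q <- IRanges::IRanges(start = win_start[ri] + 1, end = win_end[ri])
      s <- IRanges::IRanges(start = blacklist$start[bi] + 1,
                            end = blacklist$end[bi])
      hit <- IRanges::overlapsAny(q, s)
      drop[ri[hit]] <- TRUE
    }
  }
  if (!is.null(exclude_ids))
    drop <- drop | e$region_id %in% exclude_ids
  region_set(e[!drop, , drop = FALSE], regions$flank)
}
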