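# Interval algebra on 0-based half-open genomic spans.
#
# Intervals travel as tibbles with at least `chrom`, `start`, `end`;
# optional `genome_id` and arbitrary metadata columns are preserved.

#' Build a genome coordinate table
#'
#' The backbone coordinate system every feature set refers to: one row per
#' chromosome with its length in bp.
#'
#' @param chrom Character vector of chromosome names (unique).
#' @param length Numeric vector of chromosome lengths in bp (> 0).
#' @return A tibble with columns `chrom`, `length`.
#' @examples
#' genome_coords(c("chr1", "chr2"), c(1e7, 5e6))
#' @export
genome_coords <- function(chrom, length) {
  if (anyDuplicated(chrom)) abort("chromosome names must be unique")
  if (any(length <= 0)) abort("chromosome lengths must be > 0")
  tibble(chrom = as.character(chrom), length = as.numeric(length))
}

#' Construct an interval tibble
#'
#' Coordinates are 0-based half-open: `start` inclusive, `end` exclusive.
#'
#' @param chrom,start,end Vectors of equal length (or length 1, recycled).
#' @param ... Further columns (e.g. `genome_id`, `strand`, scores).
#' @return A validated interval tibble.
#' @examples
#' intervals("chr1", c(0, 500), c(100, 900), genome_id = "G1")
#' @export
intervals <- function(chrom, start, end, ...) {
  iv <- tibble(chrom = as.character(chrom), start = as.numeric(start),
               end = as.numeric(end), ...)
  validate_intervals(iv)
  iv
}

validate_intervals <- function(iv, allow_empty = FALSE) {
  req <- c("chrom", "start", "end")
  missing_cols <- setdiff(req, names(iv))
  if (length(missing_cols)) {
    abort(paste("interval table lacks column(s):",
                paste(missing_cols, collapse = ", ")))
  }
  bad <- if (allow_empty) iv$start > iv$end else iv$start >= iv$end
  if (any(bad)) abort("intervals must satisfy start < end (0-based half-open)")
  if (any(iv$start < 0)) abort("interval starts must be >= 0")
  invisible(iv)
}

#' Overlap length of two intervals
#'
#' Vectorised; intervals on different chromosomes overlap by 0 bp.
#'
#' @param a,b Interval tibbles of compatible length.
#' @return Numeric vector of overlap lengths in bp.
#' @examples
#' overlap_length(intervals("chr1", 0, 100), intervals("chr1", 50, 150))
#' @export
overlap_length <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  same <- a$chrom == b$chrom
  ov <- pmax(0, pmin(a$end, b$end) - pmax(a$start, b$start))
  ifelse(same, ov, 0)
}

#' Reciprocal overlap fraction
#'
#' Overlap length divided by the length of the shorter of the two intervals,
#' so a feature nested inside a larger one scores 1. Symmetric in its
#' arguments. Used with a strict `> 0.5` cutoff for loop-anchor conservation.
#'
#' @inheritParams overlap_length
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
reciprocal_overlap_fraction <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  shorter <- pmin(a$end - a$start, b$end - b$start)
  if (any(shorter <= 0)) abort("zero-length interval in reciprocal overlap")
  overlap_length(a, b) / shorter
}

#' Merge intervals allowing a maximum gap
#'
#' Sorts per chromosome and merges any run of intervals whose pairwise gaps
#' (`next start - previous end`) are `<= max_gap`; the merged interval is the
#' envelope of its members. Gap semantics are inclusive, matching common
#' merge-tool `-d` behaviour, so abutting or overlapping intervals always
#' merge. Per-genome membership is retained in the list columns
#' `members` (row indices into the input) and `genome_ids` when the input
#' carries a `genome_id` column.
#'
#' @param iv Interval tibble.
#' @param max_gap Maximum tolerated gap in bp (`>= 0`).
#' @return Tibble of merged intervals with `n_members`, `members` and (when
#'   available) `genome_ids` list columns.
#' @examples
#' merge_with_gap(intervals("chr1", c(0, 60000), c(40000, 100000)), 40000)
#' @export
merge_with_gap <- function(iv, max_gap) {
  validate_intervals(iv)
  if (length(max_gap) != 1 || is.na(max_gap) || max_gap < 0) {
    abort("max_gap must be a single non-negative number")
  }
  if (nrow(iv) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  n_members = integer(), members = list()))
  }
  iv2 <- iv |>
    mutate(.row = dplyr::row_number()) |>
    arrange(.data$chrom, .data$start, .data$end)
  # cluster id increments whenever the gap to the running envelope end
  # exceeds max_gap or the chromosome changes
  res <- iv2 |>
    group_by(.data$chrom) |>
    mutate(.cummax_end = cummax(.data$end),
           .new = .data$start - dplyr::lag(.data$.cummax_end,
                                           default = -Inf) > max_gap,
           .cluster = cumsum(.data$.new)) |>
    group_by(.data$chrom, .data$.cluster) |>
    summarise(start = min(.data$start), end = max(.data$end),
              n_members = dplyr::n(), members = list(.data$.row),
              .groups = "drop") |>
    select(-".cluster") |>
    arrange(.data$chrom, .data$start)
  if ("genome_id" %in% names(iv)) {
    res$genome_ids <- map(res$members, \(i) iv$genome_id[i])
  }
  res
}

#' Fraction of a target interval covered by a feature set
#'
#' Base pairs of `target` covered by the union of `features`, divided by the
#' target length. Features may overlap each other; the union is taken.
#'
#' @param target A single-row interval tibble (or a tibble; rows are handled
#'   independently and a vector is returned).
#' @param features Interval tibble.
#' @return Numeric vector of fractions in `[0, 1]`, one per target row.
#' @examples
#' coverage_fraction(intervals("chr1", 0, 100),
#'                   intervals("chr1", c(0, 25), c(50, 75)))
#' @export
coverage_fraction <- function(target, features) {
  validate_intervals(target)
  if (any(target$end - target$start <= 0)) abort("empty target interval")
  idx <- coverage_index(features)
  covered_bp(idx, target$chrom, target$start, target$end) /
    (target$end - target$start)
}

# Prefix-sum index over the disjoint union of a feature set: O(log n) covered
# bp queries, fully vectorised. Used by coverage_fraction and the bootstrap
# null, where the feature set is fixed and queried tens of thousands of times.
coverage_index <- function(features) {
  validate_intervals(features)
  if (nrow(features) == 0) return(list())
  u <- merge_with_gap(features, 0)
  # strictly disjoint pieces per chromosome (gap 0 merges abutting intervals)
  split(u, u$chrom) |>
    lapply(\(d) {
      d <- d[order(d$start), ]
      list(start = d$start, end = d$end,
           cum = c(0, cumsum(d$end - d$start)))
    })
}

covered_bp <- function(idx, chrom, start, end) {
  out <- numeric(length(chrom))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    g <- idx[[ch]]
    if (is.null(g)) next
    out[sel] <- cum_cov_at(g, end[sel]) - cum_cov_at(g, start[sel])
  }
  out
}

# covered bp in [0, x) against one chromosome's disjoint pieces
cum_cov_at <- function(g, x) {
  i <- findInterval(x, g$start)           # pieces starting at or before x
  full <- g$cum[i + 1]                    # covered bp through end of piece i
  ii <- pmax(i, 1)
  # subtract the part of piece i beyond x, if x falls inside it
  partial <- ifelse(i > 0 & x < g$end[ii], g$end[ii] - x, 0)
  full - partial
}
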