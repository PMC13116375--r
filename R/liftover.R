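# Block liftover between a genome and the backbone coordinate system.
#
# A liftover map is a tibble of equal-length aligned blocks:
#   src_chrom, src_start, src_end, tgt_chrom, tgt_start, tgt_end
# Blocks are non-overlapping and sorted in source coordinates; positions
# falling between blocks are unaligned.

#' Read / write a liftover block map
#'
#' Plain TSV with columns `src_chrom`, `src_start`, `src_end`, `tgt_chrom`,
#' `tgt_start`, `tgt_end`; 0-based half-open on both sides, block lengths
#' equal on both sides.
#'
#' @param path File path.
#' @return A validated liftover map tibble.
#' @export
read_liftover_map <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_liftover_map(m)
}

#' @rdname read_liftover_map
#' @param map A liftover map tibble.
#' @export
write_liftover_map <- function(map, path) {
  validate_liftover_map(map)
  readr::write_tsv(map, path, progress = FALSE)
  invisible(path)
}

validate_liftover_map <- function(map) {
  req <- c("src_chrom", "src_start", "src_end",
           "tgt_chrom", "tgt_start", "tgt_end")
  if (!all(req %in% names(map))) {
    abort(paste("liftover map needs columns:", paste(req, collapse = ", ")))
  }
  if (any(map$src_end - map$src_start != map$tgt_end - map$tgt_start)) {
    abort("liftover blocks must have equal length on both sides")
  }
  m <- map |> arrange(.data$src_chrom, .data$src_start)
  ovl <- m |>
    group_by(.data$src_chrom) |>
    mutate(bad = .data$src_start < dplyr::lag(.data$src_end, default = -Inf)) |>
    pull(.data$bad)
  if (any(ovl)) abort("liftover blocks overlap in source coordinates")
  m
}

#' Invert a liftover map
#'
#' Swaps source and target sides, so coordinates can be mapped backbone-to-
#' genome as well as genome-to-backbone.
#'
#' @param map A liftover map tibble.
#' @return The inverted map.
#' @export
invert_liftover_map <- function(map) {
  map |>
    rename(src_chrom = "tgt_chrom", src_start = "tgt_start",
           src_end = "tgt_end", tgt_chrom = "src_chrom",
           tgt_start = "src_start", tgt_end = "src_end") |>
    validate_liftover_map()
}

# map single positions through blocks; returns tibble(chrom, pos) with NA
# where the position is unaligned
lift_positions <- function(map, chrom, pos) {
  out_chrom <- rep(NA_character_, length(pos))
  out_pos <- rep(NA_real_, length(pos))
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    blk <- map[map$src_chrom == ch, ]
    if (nrow(blk) == 0) next
    i <- findInterval(pos[sel], blk$src_start)
    ok <- i > 0 & pos[sel] < blk$src_end[pmax(i, 1)]
    ii <- i[ok]
    out_chrom[sel[ok]] <- blk$tgt_chrom[ii]
    out_pos[sel[ok]] <- blk$tgt_start[ii] + (pos[sel][ok] - blk$src_start[ii])
  }
  tibble(chrom = out_chrom, pos = out_pos)
}

#' Lift intervals through a block map
#'
#' Maps the start and the last base of each interval independently through
#' their containing aligned blocks. When both endpoints land on the same
#' target chromosome in consistent order the result is the envelope of the
#' two mapped positions; an interval whose endpoints fall in unaligned gaps
#' (or on an absent chromosome) is returned unmapped with a reason code.
#' Intervals fully inside a single block map with their length preserved.
#'
#' @param iv Interval tibble in the map's source coordinate system.
#' @param map Liftover map tibble.
#' @return `iv` with columns `chrom`, `start`, `end` replaced by target
#'   coordinates, plus `mapped` (logical) and `unmapped_reason` (NA, or one
#'   of "chrom_absent", "start_unaligned", "end_unaligned",
#'   "both_unaligned", "inconsistent"). Unmapped rows keep their source
#'   coordinates in `src_*` columns only.
#' @examples
#' m <- tibble::tibble(src_chrom = "chr1", src_start = 0, src_end = 1e5,
#'                     tgt_chrom = "chr1", tgt_start = 1e4, tgt_end = 1.1e5)
#' liftover_intervals(intervals("chr1", 500, 700), m)
#' @export
liftover_intervals <- function(iv, map) {
  validate_intervals(iv)
  map <- validate_liftover_map(map)
  n <- nrow(iv)
  s <- lift_positions(map, iv$chrom, iv$start)
  e <- lift_positions(map, iv$chrom, iv$end - 1)   # last covered base
  reason <- rep(NA_character_, n)
  absent <- !(iv$chrom %in% map$src_chrom)
  reason[absent] <- "chrom_absent"
  s_un <- is.na(s$pos) & !absent
  e_un <- is.na(e$pos) & !absent
  reason[s_un & e_un] <- "both_unaligned"
  reason[s_un & !e_un] <- "start_unaligned"
  reason[!s_un & e_un] <- "end_unaligned"
  ok <- is.na(reason)
  incons <- ok & (s$chrom != e$chrom | e$pos < s$pos)
  reason[incons] <- "inconsistent"
  ok <- is.na(reason)
  out <- iv
  out$src_chrom <- iv$chrom
  out$src_start <- iv$start
  out$src_end <- iv$end
  out$chrom <- ifelse(ok, s$chrom, NA_character_)
  out$start <- ifelse(ok, s$pos, NA_real_)
  out$end <- ifelse(ok, e$pos + 1, NA_real_)
  out$mapped <- ok
  out$unmapped_reason <- reason
  out
}
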