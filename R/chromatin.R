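# Chromatin-architecture calling from binned Hi-C contact matrices:
# insulation score -> Li-thresholded TAD boundaries -> TADs; A/B compartments
# from the first eigenvector of the contact correlation matrix; map
# resolution; LT-CRE identification and loop anchor typing; TAD
# reorganization; boundary activity classes.

#' Contact matrix container
#'
#' A symmetric, non-negative matrix of binned interaction counts for one
#' chromosome. Conventional resolutions: 40-kb bins for insulation/TAD
#' calling, 100-kb bins for compartments.
#'
#' @param M Square symmetric numeric matrix.
#' @param chrom Chromosome name.
#' @param bin_size Bin size in bp.
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(M, chrom = "chr1", bin_size = 40000) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) abort("contact matrix must be square")
  if (!isTRUE(all.equal(M, t(M), tolerance = 1e-8))) {
    abort("contact matrix must be symmetric")
  }
  if (any(!is.finite(M)) || any(M < 0)) {
    abort("contact matrix entries must be finite and non-negative")
  }
  structure(list(M = M, chrom = as.character(chrom),
                 bin_size = as.numeric(bin_size)),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s: %d bins of %g bp, total %g contacts\n",
              x$chrom, nrow(x$M), x$bin_size, sum(x$M)))
  invisible(x)
}

#' Insulation score track
#'
#' Diamond insulation: for each bin b the raw score is the mean contact count
#' in the off-diagonal window spanning `w` bins upstream by `w` bins
#' downstream of b (the center bin itself excluded). The normalised score is
#' `log2(IS / mean IS)` over valid bins, so boundaries appear as local
#' minima below zero. Edge bins where the full window does not fit are
#' flagged invalid.
#'
#' @param cm A [contact_matrix()].
#' @param w Window half-width in bins (default 2 at 40-kb resolution).
#' @return Tibble with one row per bin: `bin` (1-based), `chrom`, `start`,
#'   `end`, `insulation`, `log2_insulation`, `valid`.
#' @export
insulation_score <- function(cm, w = 2) {
  stopifnot(inherits(cm, "contact_matrix"))
  M <- cm$M
  n <- nrow(M)
  if (w < 1) abort("window must be >= 1 bin")
  if (n <= 2 * w) abort("matrix too small for the requested window")
  if (all(M == 0)) abort("all-zero contact matrix: insulation undefined")
  raw <- rep(NA_real_, n)
  for (b in (w + 1):(n - w)) {
    raw[b] <- mean(M[(b - w):(b - 1), (b + 1):(b + w)])
  }
  valid <- !is.na(raw)
  m <- mean(raw[valid])
  if (m == 0) abort("insulation mean is zero: cannot normalise")
  # zero-count windows are floored so the log stays finite (depth ~ -30)
  ratio <- pmax(raw / m, 1e-9)
  tibble(bin = seq_len(n), chrom = cm$chrom,
         start = (seq_len(n) - 1) * cm$bin_size,
         end = seq_len(n) * cm$bin_size,
         insulation = raw,
         log2_insulation = ifelse(valid, log2(ratio), NA_real_),
         valid = valid)
}

#' Li's minimum cross-entropy threshold
#'
#' The iterative version of Li & Lee's threshold: starting from the sample
#' mean, alternate between splitting the values at t and updating
#' `t <- (mu_bg - mu_fg) / (log(mu_bg) - log(mu_fg))` with `mu_bg`/`mu_fg`
#' the means at or below / above t, until the update moves less than `tol`.
#' Zero values are shifted by machine epsilon so the logarithms exist.
#'
#' @param values Non-negative numeric vector with at least 2 distinct values.
#' @param tol Absolute convergence tolerance.
#' @return The threshold (scalar).
#' @export
li_threshold <- function(values, tol = 1e-8) {
  x <- values[is.finite(values)]
  if (length(unique(x)) < 2) abort("li_threshold needs >= 2 distinct values")
  if (any(x < 0)) abort("li_threshold expects non-negative values")
  # iterate on min-shifted values (the reference convention): the cross-
  # entropy functional is not shift-invariant and needs strictly positive
  # means on both sides of the split
  mn <- min(x)
  x <- x - mn
  eps <- .Machine$double.eps
  x <- x + ifelse(x == 0, eps, 0)
  t_cur <- mean(x)
  for (i in 1:500) {
    lo <- x[x <= t_cur]; hi <- x[x > t_cur]
    if (!length(lo) || !length(hi)) break
    m_lo <- mean(lo); m_hi <- mean(hi)
    t_new <- (m_lo - m_hi) / (log(m_lo) - log(m_hi))
    if (abs(t_new - t_cur) < tol) break
    t_cur <- t_new
  }
  t_cur + mn
}

# topographic prominence of local minima of y (NA allowed at edges):
# depth of the minimum relative to the lower of the two highest values
# reachable before a deeper point is met on each side.
minima_prominence <- function(y) {
  v <- which(!is.na(y))
  yy <- y[v]
  n <- length(yy)
  is_min <- rep(FALSE, n)
  for (i in seq_len(n)) {
    l <- if (i > 1) yy[i - 1] else Inf
    r <- if (i < n) yy[i + 1] else Inf
    is_min[i] <- yy[i] <= l && yy[i] <= r && (yy[i] < l || yy[i] < r)
  }
  # plateau handling: a run of equal values flanked by higher values is one
  # minimum; mark the whole run
  prom <- rep(NA_real_, n)
  for (i in which(is_min)) {
    left_max <- -Inf
    j <- i - 1
    while (j >= 1 && yy[j] >= yy[i]) { left_max <- max(left_max, yy[j]); j <- j - 1 }
    if (left_max == -Inf) left_max <- Inf    # sat at the track edge
    right_max <- -Inf
    j <- i + 1
    while (j <= n && yy[j] >= yy[i]) { right_max <- max(right_max, yy[j]); j <- j + 1 }
    if (right_max == -Inf) right_max <- Inf
    prom[i] <- min(left_max, right_max) - yy[i]
  }
  tibble(index = v[is_min], prominence = prom[is_min])
}

#' Call TAD boundaries from an insulation track
#'
#' Candidate boundaries are the local minima of the normalised insulation
#' score; each minimum's strength is its topographic prominence (depth below
#' the lower of the flanking maxima). The strength threshold is set
#' adaptively by [li_threshold()] over all candidate strengths; contiguous
#' minimum bins are merged into one boundary interval.
#'
#' @param track Tibble from [insulation_score()].
#' @param bin_size Bin size in bp (taken from the track's coordinates).
#' @return Tibble `chrom,start,end,strength,passes_threshold`, one row per
#'   merged boundary; only rows with `passes_threshold` are boundaries.
#' @export
call_boundaries <- function(track, bin_size = NULL) {
  bin_size <- bin_size %||% (track$end[1] - track$start[1])
  y <- track$log2_insulation
  if (sum(!is.na(y)) < 3) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  strength = numeric(), passes_threshold = logical()))
  }
  mins <- minima_prominence(y)
  if (nrow(mins) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  strength = numeric(), passes_threshold = logical()))
  }
  fin <- mins$prominence[is.finite(mins$prominence)]
  thr <- if (length(unique(fin)) >= 2) {
    li_threshold(fin)
  } else {
    0  # single candidate or flat strengths: keep everything
  }
  calls <- tibble(chrom = track$chrom[mins$index],
                  start = track$start[mins$index],
                  end = track$end[mins$index],
                  strength = mins$prominence,
                  passes = mins$prominence >= thr)
  # merge contiguous minimum bins (plateaus) into one boundary interval
  kept <- calls |>
    mutate(.gap = .data$start - dplyr::lag(.data$end, default = -Inf),
           .grp = cumsum(.data$.gap > 0)) |>
    group_by(.data$chrom, .data$.grp) |>
    summarise(start = min(.data$start), end = max(.data$end),
              strength = max(.data$strength),
              passes_threshold = any(.data$passes), .groups = "drop") |>
    select(-".grp") |>
    arrange(.data$start)
  kept
}

#' TADs as the regions between adjacent boundaries
#'
#' Spans from each boundary to the next; the chromosome ends up to the first
#' and after the last boundary are emitted too, flagged `partial`.
#'
#' @param boundaries Boundary tibble (rows failing the threshold are
#'   dropped here if a `passes_threshold` column is present).
#' @param chrom_length Chromosome length in bp.
#' @param chrom Chromosome name (defaults to the boundaries').
#' @return Tibble `chrom,start,end,partial`; always `k + 1` rows for `k`
#'   boundaries.
#' @export
call_tads <- function(boundaries, chrom_length, chrom = NULL) {
  b <- boundaries
  if ("passes_threshold" %in% names(b)) b <- b[b$passes_threshold, ]
  chrom <- chrom %||% (if (nrow(b)) b$chrom[1] else "chr1")
  b <- b[order(b$start), ]
  starts <- c(0, b$end)
  ends <- c(b$start, chrom_length)
  out <- tibble(chrom = chrom, start = starts, end = ends)
  out$partial <- seq_len(nrow(out)) %in% c(1L, nrow(out))
  out[out$end > out$start, ]
}

#' A/B compartment calls from a contact matrix
#'
#' Observed/expected normalisation (each entry divided by the mean of its
#' diagonal), Pearson correlation matrix, first eigenvector. The sign is
#' oriented so the eigenvector correlates positively with the supplied
#' orientation track (typically per-bin gene density); positive bins are A,
#' negative B, and contiguous same-label bins are merged. Bins with zero
#' marginal are masked; zero eigenvector entries are labelled B
#' (deterministic tie-break, flagged in the per-bin output).
#'
#' @param cm A [contact_matrix()] at compartment resolution (100-kb bins).
#' @param orientation_track Numeric per-bin track used only to fix the
#'   eigenvector sign.
#' @return List with `bins` (per-bin tibble: `bin`, `eigenvector`,
#'   `compartment`, `masked`) and `compartments` (merged interval tibble
#'   `chrom,start,end,compartment`).
#' @export
call_compartments <- function(cm, orientation_track) {
  stopifnot(inherits(cm, "contact_matrix"))
  M <- cm$M
  n <- nrow(M)
  if (length(orientation_track) != n) {
    abort("orientation track length must equal the number of bins")
  }
  keep <- rowSums(M) > 0
  Mk <- M[keep, keep, drop = FALSE]
  nk <- nrow(Mk)
  if (nk < 3) abort("too few unmasked bins for compartment calling")
  # observed / expected by diagonal mean
  d <- abs(row(Mk) - col(Mk))
  dm <- tapply(Mk, d, mean)
  E <- matrix(dm[as.character(d)], nk, nk)
  OE <- ifelse(E > 0, Mk / E, 0)
  C <- suppressWarnings(stats::cor(OE))
  C[!is.finite(C)] <- 0
  ev <- eigen(C, symmetric = TRUE)$vectors[, 1]
  ori <- orientation_track[keep]
  s <- suppressWarnings(stats::cor(ev, ori))
  if (is.finite(s) && s < 0) ev <- -ev
  full_ev <- rep(NA_real_, n)
  full_ev[keep] <- ev
  comp <- ifelse(is.na(full_ev), NA_character_,
                 ifelse(full_ev > 0, "A", "B"))
  bins <- tibble(bin = seq_len(n), eigenvector = full_ev,
                 compartment = comp, masked = !keep)
  runs <- bins |>
    filter(!is.na(.data$compartment)) |>
    mutate(.grp = cumsum(.data$compartment !=
                           dplyr::lag(.data$compartment, default = "")) +
             cumsum(c(0, diff(.data$bin) != 1))) |>
    group_by(.data$.grp, .data$compartment) |>
    summarise(start = (min(.data$bin) - 1) * cm$bin_size,
              end = max(.data$bin) * cm$bin_size, .groups = "drop") |>
    transmute(chrom = cm$chrom, start = .data$start, end = .data$end,
              compartment = .data$compartment) |>
    arrange(.data$start)
  list(bins = bins, compartments = runs)
}

#' Hi-C map resolution
#'
#' The smallest bin size at which at least 80% of bins accumulate at least
#' 1,000 contacts. If no candidate qualifies the largest bin size is
#' returned with a warning.
#'
#' @param matrices Named list of [contact_matrix()] objects (one per
#'   candidate bin size) or a tibble with columns `bin_size` and
#'   `bin_totals` (list column of per-bin total contacts).
#' @param min_contacts,min_fraction Rule parameters (defaults 1000, 0.80;
#'   the fraction test is inclusive).
#' @return Resolution in bp.
#' @export
estimate_map_resolution <- function(matrices, min_contacts = 1000,
                                    min_fraction = 0.8) {
  if (inherits(matrices, "data.frame")) {
    tab <- matrices
  } else {
    tab <- tibble(bin_size = map_dbl(matrices, "bin_size"),
                  bin_totals = map(matrices, \(cm) rowSums(cm$M)))
  }
  tab <- tab |>
    mutate(frac = map_dbl(.data$bin_totals,
                          \(v) mean(v >= min_contacts))) |>
    arrange(.data$bin_size)
  ok <- tab$frac >= min_fraction
  if (any(ok)) return(tab$bin_size[which(ok)[1]])
  warn("no bin size reaches the contact threshold; returning the largest")
  max(tab$bin_size)
}

#' Identify long-range cis-regulatory elements (LT-CREs)
#'
#' An ATAC peak qualifies as an LT-CRE when it lies at least `min_tss_dist`
#' bp from the nearest TSS (peak edge to TSS point) and overlaps at least
#' one chromatin-loop anchor.
#'
#' @param peaks ATAC peak interval tibble.
#' @param anchors Loop-anchor interval tibble.
#' @param genes Gene tibble with a `tss` column (see [gene_table()]).
#' @param min_tss_dist Minimum peak-to-TSS distance in bp (default 2000).
#' @return The qualifying peaks with `dist_tss` and `n_anchors` columns.
#' @export
identify_ltcres <- function(peaks, anchors, genes, min_tss_dist = 2000) {
  validate_intervals(peaks)
  if (nrow(peaks) == 0) return(mutate(peaks, dist_tss = numeric(0),
                                      n_anchors = integer(0)))
  peaks$dist_tss <- map_dbl(seq_len(nrow(peaks)), function(i) {
    g <- genes[genes$chrom == peaks$chrom[i], ]
    if (nrow(g) == 0) return(Inf)
    # 0 if TSS inside the peak, else edge-to-point gap
    min(pmax(0, pmax(peaks$start[i] - g$tss, g$tss - (peaks$end[i] - 1))))
  })
  peaks$n_anchors <- count_overlaps(peaks, anchors)
  peaks[peaks$dist_tss >= min_tss_dist & peaks$n_anchors >= 1, ]
}

# number of features (any overlap >= 1 bp) per query row
count_overlaps <- function(query, features) {
  validate_intervals(query)
  if (nrow(features) == 0) return(rep(0L, nrow(query)))
  validate_intervals(features)
  out <- integer(nrow(query))
  for (ch in unique(query$chrom)) {
    qs <- which(query$chrom == ch)
    f <- features[features$chrom == ch, ]
    if (nrow(f) == 0) next
    out[qs] <- vapply(qs, function(i) {
      sum(f$start < query$end[i] & f$end > query$start[i])
    }, integer(1))
  }
  out
}

#' Annotate loops by anchor content
#'
#' Each anchor is labelled E when it overlaps an LT-CRE; otherwise G when it
#' overlaps the 2-kb window upstream of a TSS (strand-aware by default);
#' otherwise unlabelled. Loop types are the unordered label pairs E-E, E-G,
#' G-G; loops with an unlabelled anchor are `unannotated`.
#'
#' @param loops Loop tibble (BEDPE columns).
#' @param ltcres LT-CRE interval tibble.
#' @param genes Gene tibble with `tss` and `strand`.
#' @param upstream Window size upstream of the TSS (default 2000 bp).
#' @param strand_aware Use gene strand to orient "upstream" (default TRUE;
#'   FALSE takes the window left of the TSS).
#' @return `loops` with `anchor1_label`, `anchor2_label`, `loop_type`.
#' @export
annotate_loops <- function(loops, ltcres, genes, upstream = 2000,
                           strand_aware = TRUE) {
  validate_loops(loops)
  up <- if (strand_aware && "strand" %in% names(genes)) {
    tibble(chrom = genes$chrom,
           start = ifelse(genes$strand == "-", genes$tss + 1,
                          genes$tss - upstream),
           end = ifelse(genes$strand == "-", genes$tss + 1 + upstream,
                        genes$tss))
  } else {
    tibble(chrom = genes$chrom, start = genes$tss - upstream,
           end = genes$tss)
  }
  up <- up[up$end > up$start, ]
  up$start <- pmax(up$start, 0)
  label_anchor <- function(anc) {
    e <- count_overlaps(anc, ltcres) > 0
    g <- count_overlaps(anc, up) > 0
    ifelse(e, "E", ifelse(g, "G", NA_character_))   # E takes precedence
  }
  l1 <- label_anchor(anchor1(loops))
  l2 <- label_anchor(anchor2(loops))
  pair <- ifelse(is.na(l1) | is.na(l2), "unannotated",
                 paste(pmin(l1, l2), pmax(l1, l2), sep = "-"))
  loops$anchor1_label <- l1
  loops$anchor2_label <- l2
  loops$loop_type <- pair
  loops
}

#' Classify TAD reorganization between two genomes
#'
#' Each query TAD is compared to the reference TAD set: `stable` when
#' exactly one reference TAD matches with reciprocal overlap of at least
#' `stable_frac` of both lengths; `fusion` when two or more reference TADs
#' each cover at least `fusion_each` of the query and jointly at least
#' `fusion_joint`; `neo` when reference TADs cover at most `neo_max` of the
#' query; otherwise `unclassified`. Thresholds are tunable; the defaults
#' (0.8, 0.2, 0.8, 0.5) are this package's convention.
#'
#' @param ref_tads,query_tads Sorted non-overlapping interval tibbles.
#' @param stable_frac,fusion_each,fusion_joint,neo_max Rule thresholds.
#' @return `query_tads` with a `reorg` label column.
#' @export
classify_tad_reorganization <- function(ref_tads, query_tads,
                                        stable_frac = 0.8,
                                        fusion_each = 0.2,
                                        fusion_joint = 0.8, neo_max = 0.5) {
  validate_intervals(ref_tads); validate_intervals(query_tads)
  lab <- map_chr(seq_len(nrow(query_tads)), function(i) {
    q <- query_tads[i, ]
    qlen <- q$end - q$start
    r <- ref_tads[ref_tads$chrom == q$chrom &
                    ref_tads$start < q$end & ref_tads$end > q$start, ]
    if (nrow(r) == 0) return("neo")
    ov <- pmax(0, pmin(r$end, q$end) - pmax(r$start, q$start))
    frac_q <- ov / qlen
    frac_r <- ov / (r$end - r$start)
    if (sum(frac_q >= stable_frac & frac_r >= stable_frac) == 1) {
      return("stable")
    }
    big <- frac_q >= fusion_each
    if (sum(big) >= 2 && sum(frac_q[big]) >= fusion_joint) return("fusion")
    if (sum(frac_q) <= neo_max) return("neo")
    "unclassified"
  })
  query_tads$reorg <- lab
  query_tads
}

#' Classify boundary activity from ATAC, expression and gene count
#'
#' For each boundary the mean ATAC signal, mean expression of overlapping
#' genes and gene count are computed in the boundary extended by `flank` bp
#' on each side, z-scored, and clustered with seeded k-means (k = 3, 50
#' restarts). Clusters are relabelled by descending mean ATAC z-score as
#' `active`, `neutral`, `inactive`.
#'
#' @param boundaries Boundary interval tibble.
#' @param atac ATAC signal intervals with a `score` column (signal density).
#' @param genes Gene tibble with an `expression` column.
#' @param flank Flank in bp added on each side (default 20000).
#' @param seed Seed for the k-means restarts.
#' @return `boundaries` with `atac_z`, `expr_z`, `n_genes_z` and `activity`.
#' @export
classify_boundary_activity <- function(boundaries, atac, genes,
                                       flank = 20000, seed = 1) {
  validate_intervals(boundaries)
  if (nrow(boundaries) < 3) abort("need >= 3 boundaries to cluster")
  ext <- boundaries |>
    mutate(start = pmax(0, .data$start - flank), end = .data$end + flank)
  feat <- map(seq_len(nrow(ext)), function(i) {
    b <- ext[i, ]
    a <- atac[atac$chrom == b$chrom & atac$start < b$end &
                atac$end > b$start, ]
    g <- genes[genes$chrom == b$chrom & genes$start < b$end &
                 genes$end > b$start, ]
    atac_sig <- if (nrow(a)) {
      ov <- pmin(a$end, b$end) - pmax(a$start, b$start)
      sum(a$score * ov) / (b$end - b$start)
    } else 0
    c(atac = atac_sig,
      expr = if (nrow(g)) mean(g$expression) else 0,
      n_genes = nrow(g))
  })
  X <- do.call(rbind, feat)
  Z <- scale(X)
  Z[!is.finite(Z)] <- 0
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  km <- kmeans(Z, centers = 3, nstart = 50)
  ord <- order(tapply(Z[, "atac"], km$cluster, mean), decreasing = TRUE)
  lab <- c("active", "neutral", "inactive")[match(km$cluster, ord)]
  boundaries$atac_z <- Z[, "atac"]
  boundaries$expr_z <- Z[, "expr"]
  boundaries$n_genes_z <- Z[, "n_genes"]
  boundaries$activity <- lab
  boundaries
}

# save/restore the RNG state so seeded helpers don't disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
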