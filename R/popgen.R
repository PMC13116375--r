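# Bootstrap enrichment/depletion of SV coverage in chromatin features,
# Weir-Cockerham Fst, nucleotide diversity, Pi-ratio candidate screening,
# and SV-loop gene linkage.

#' Bootstrap test of feature coverage in a region set
#'
#' The observed statistic is the fraction of the region set covered by the
#' feature set. The null relocates every region to a uniformly random,
#' length-preserving position (chromosome drawn proportional to length;
#' relocated regions may overlap each other) `n_draws` times and recomputes
#' the coverage. Empirical p-values use the add-one convention
#' `(k + 1) / (N + 1)` so they are never zero.
#'
#' @param features Interval tibble (e.g. merged SVs); held fixed.
#' @param regions Interval tibble (e.g. pan-TAD boundaries); relocated.
#' @param genome [genome_coords()] tibble.
#' @param n_draws Number of null draws (default 1000).
#' @param seed RNG seed.
#' @return Object of class `bootstrap_result`: list with `observed`,
#'   `null_draws`, `p_depletion`, `p_enrichment`, `z`, `n_draws`, `seed`.
#' @export
bootstrap_coverage_test <- function(features, regions, genome,
                                    n_draws = 1000, seed = 1) {
  validate_intervals(features); validate_intervals(regions)
  if (nrow(regions) == 0) abort("region set is empty")
  widths <- regions$end - regions$start
  if (max(widths) > max(genome$length)) {
    abort("a region is longer than every chromosome")
  }
  idx <- coverage_index(features)
  total_w <- sum(widths)
  observed <- sum(covered_bp(idx, regions$chrom, regions$start,
                             regions$end)) / total_w
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  nr <- nrow(regions)
  # chromosomes able to host each region, sampled proportional to length
  null_draws <- vapply(seq_len(n_draws), function(d) {
    ci <- sample.int(nrow(genome), nr, replace = TRUE,
                     prob = genome$length)
    # redraw chromosomes too short for their region
    bad <- genome$length[ci] < widths
    while (any(bad)) {
      ci[bad] <- sample.int(nrow(genome), sum(bad), replace = TRUE,
                            prob = genome$length)
      bad <- genome$length[ci] < widths
    }
    st <- floor(runif(nr, 0, genome$length[ci] - widths + 1))
    sum(covered_bp(idx, genome$chrom[ci], st, st + widths)) / total_w
  }, numeric(1))
  z <- if (sd(null_draws) > 0) {
    (observed - mean(null_draws)) / sd(null_draws)
  } else NA_real_
  structure(list(observed = observed, null_draws = null_draws,
                 p_depletion = (sum(null_draws <= observed) + 1) /
                   (n_draws + 1),
                 p_enrichment = (sum(null_draws >= observed) + 1) /
                   (n_draws + 1),
                 z = z, n_draws = n_draws, seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(paste0("<bootstrap_result> observed coverage %.4g, null ",
                     "%.4g +/- %.4g (N=%d)\n  p_depletion=%.4g ",
                     "p_enrichment=%.4g z=%.3g\n"),
              x$observed, mean(x$null_draws), sd(x$null_draws), x$n_draws,
              x$p_depletion, x$p_enrichment, x$z))
  invisible(x)
}

#' @export
tidy.bootstrap_result <- function(x, ...) {
  tibble(statistic = c("observed", "null_mean", "null_sd", "z"),
         value = c(x$observed, mean(x$null_draws), sd(x$null_draws), x$z))
}

#' @export
glance.bootstrap_result <- function(x, ...) {
  tibble(observed = x$observed, null_mean = mean(x$null_draws),
         null_sd = sd(x$null_draws), z = x$z,
         p_depletion = x$p_depletion, p_enrichment = x$p_enrichment,
         n_draws = x$n_draws, seed = x$seed)
}

#' Weir-Cockerham Fst (two populations, biallelic sites)
#'
#' The 1984 variance-component estimator: per site, components `a` (among
#' populations), `b` (among individuals within populations) and `c` (within
#' individuals) are formed from sample sizes, allele frequencies and
#' observed heterozygosity, and theta-hat = a / (a + b + c). The multi-site
#' weighted estimate is `sum(a) / sum(a + b + c)`. Sites monomorphic across
#' both populations are undefined and returned as NA (excluded from the
#' weighted estimate).
#'
#' @param g1,g2 Integer matrices of alt-allele dosage (0/1/2, NA missing),
#'   sites in rows, individuals in columns.
#' @return List: `per_site` tibble (`site`, `a`, `b`, `c`, `theta`),
#'   `weighted` (scalar), `n_excluded`.
#' @export
wc_fst <- function(g1, g2) {
  g1 <- as.matrix(g1); g2 <- as.matrix(g2)
  if (nrow(g1) != nrow(g2)) abort("g1 and g2 need the same sites")
  r <- 2
  per_site <- map(seq_len(nrow(g1)), function(s) {
    x1 <- g1[s, ]; x2 <- g2[s, ]
    x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
    n_i <- c(length(x1), length(x2))
    if (any(n_i < 2)) return(tibble(a = NA, b = NA, c = NA))
    p_i <- c(mean(x1) / 2, mean(x2) / 2)
    h_i <- c(mean(x1 == 1), mean(x2 == 1))
    nbar <- mean(n_i)
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    if (pbar == 0 || pbar == 1) return(tibble(a = NA, b = NA, c = NA))
    a <- nbar / nc *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    tibble(a = a, b = b, c = cc)
  }) |> list_rbind()
  per_site$site <- seq_len(nrow(g1))
  per_site$theta <- with(per_site, ifelse(a + b + c == 0, NA,
                                          a / (a + b + c)))
  ok <- !is.na(per_site$a) & !is.na(per_site$theta)
  weighted <- if (any(ok)) {
    sum(per_site$a[ok]) /
      sum(per_site$a[ok] + per_site$b[ok] + per_site$c[ok])
  } else NA_real_
  list(per_site = per_site[c("site", "a", "b", "c", "theta")],
       weighted = weighted, n_excluded = sum(!ok))
}

#' Per-site and windowed nucleotide diversity
#'
#' Per site, pi is the fraction of haplotype pairs that differ:
#' `2 p (1 - p) n / (n - 1)` with `p` the allele frequency over the `n`
#' non-missing haplotypes (each diploid contributes two). Window pi sums
#' site pi over sliding windows and divides by window length.
#'
#' @param geno Integer matrix of alt dosage (sites x individuals).
#' @param pos Optional site positions in bp (needed for windows).
#' @param window,step Sliding window and step in bp (defaults 50 kb / 25
#'   kb); windows are only computed when `pos` is given.
#' @return List: `per_site` tibble (`site`, `pos`, `pi`), `windows` tibble
#'   (`start`, `end`, `n_sites`, `pi`) or NULL.
#' @export
nucleotide_diversity <- function(geno, pos = NULL, window = 50000,
                                 step = 25000) {
  geno <- as.matrix(geno)
  pi_site <- apply(geno, 1, function(x) {
    x <- x[!is.na(x)]
    n <- 2 * length(x)
    if (n < 2) return(NA_real_)
    p <- sum(x) / n
    2 * p * (1 - p) * n / (n - 1)
  })
  per_site <- tibble(site = seq_along(pi_site),
                     pos = pos %||% NA_real_, pi = pi_site)
  windows <- NULL
  if (!is.null(pos)) {
    starts <- seq(0, max(pos), by = step)
    windows <- tibble(start = starts, end = starts + window) |>
      mutate(n_sites = map_int(.data$start, \(s) {
        sum(pos >= s & pos < s + window)
      }),
      pi = map_dbl(.data$start, \(s) {
        sum(pi_site[pos >= s & pos < s + window], na.rm = TRUE) / window
      }))
  }
  list(per_site = per_site, windows = windows)
}

#' Screen candidate SVs by joint Fst / Pi-ratio outliers
#'
#' A marker is a candidate when its Fst and its Pi-ratio (diversity in
#' population 1 over population 2, high values flagging sweeps in
#' population 2) both reach their 95th percentile (ties at the cutoff
#' included; linear-interpolation quantiles). Candidates are ranked by the
#' Euclidean distance `sqrt(x^2 + y^2)` where x and y are the min-max
#' scaled Fst and log2 Pi-ratio over all markers, making the two axes
#' commensurate.
#'
#' @param table Tibble with columns `fst` and `pi_ratio` (finite).
#' @param top_frac Tail fraction for both cutoffs (default 0.05).
#' @return `table` with `fst_quantile`, `ratio_quantile`, `euclid`,
#'   `candidate`, sorted candidates first by descending distance.
#' @export
screen_candidate_svs <- function(table, top_frac = 0.05) {
  if (nrow(table) < 20) abort("too few markers for a 95th percentile")
  if (any(!is.finite(table$fst)) || any(!is.finite(table$pi_ratio))) {
    abort("fst and pi_ratio must be finite")
  }
  q_fst <- quantile(table$fst, 1 - top_frac, names = FALSE)
  q_rat <- quantile(table$pi_ratio, 1 - top_frac, names = FALSE)
  mm <- function(v) {
    rng <- range(v)
    if (diff(rng) == 0) rep(0, length(v)) else (v - rng[1]) / diff(rng)
  }
  x <- mm(table$fst)
  y <- mm(log2(pmax(table$pi_ratio, .Machine$double.xmin)))
  table$fst_quantile <- stats::ecdf(table$fst)(table$fst)
  table$ratio_quantile <- stats::ecdf(table$pi_ratio)(table$pi_ratio)
  table$euclid <- sqrt(x^2 + y^2)
  table$candidate <- table$fst >= q_fst & table$pi_ratio >= q_rat
  table[order(-table$candidate, -table$euclid), ]
}

#' Genes linked to SVs through chromatin loops
#'
#' A loop with at least one anchor overlapped (>= 1 bp) by an SV is an
#' SV-loop; the genes assigned to the opposite anchor are its SV-loop
#' genes. A gene belongs to an anchor when its body overlaps the anchor or
#' the anchor overlaps the 2-kb window upstream of its TSS (the same rule
#' that defines G anchors). SVs hitting both anchors emit both directions,
#' flagged.
#'
#' @param svs SV interval tibble (an `id` column is kept if present).
#' @param loops Loop tibble (BEDPE columns).
#' @param genes Gene tibble with `tss` and `strand`.
#' @param upstream Upstream window for gene-anchor assignment (bp).
#' @return Tibble `sv_id, loop, sv_anchor, genes (list), both_anchors`.
#' @export
sv_loop_genes <- function(svs, loops, genes, upstream = 2000) {
  validate_loops(loops); validate_intervals(svs)
  sv_id <- if ("id" %in% names(svs)) svs$id else {
    sprintf("sv_%05d", seq_len(nrow(svs)))
  }
  up <- tibble(chrom = genes$chrom,
               start = pmax(0, ifelse(genes$strand == "-", genes$tss + 1,
                                      genes$tss - upstream)),
               end = ifelse(genes$strand == "-",
                            genes$tss + 1 + upstream, genes$tss),
               gene_id = genes$gene_id)
  up <- up[up$end > up$start, ]
  genes_at <- function(anc) {
    body <- genes$gene_id[genes$chrom == anc$chrom &
                            genes$start < anc$end & genes$end > anc$start]
    upg <- up$gene_id[up$chrom == anc$chrom & up$start < anc$end &
                        up$end > anc$start]
    unique(c(body, upg))
  }
  rows <- list()
  for (li in seq_len(nrow(loops))) {
    a1 <- anchor1(loops)[li, ]; a2 <- anchor2(loops)[li, ]
    hit1 <- which(svs$chrom == a1$chrom & svs$start < a1$end &
                    svs$end > a1$start)
    hit2 <- which(svs$chrom == a2$chrom & svs$start < a2$end &
                    svs$end > a2$start)
    both <- intersect(hit1, hit2)
    for (s in hit1) {
      rows[[length(rows) + 1]] <- tibble(sv_id = sv_id[s], loop = li,
                                         sv_anchor = 1L,
                                         genes = list(genes_at(a2)),
                                         both_anchors = s %in% both)
    }
    for (s in hit2) {
      rows[[length(rows) + 1]] <- tibble(sv_id = sv_id[s], loop = li,
                                         sv_anchor = 2L,
                                         genes = list(genes_at(a1)),
                                         both_anchors = s %in% both)
    }
  }
  if (!length(rows)) {
    return(tibble(sv_id = character(), loop = integer(),
                  sv_anchor = integer(), genes = list(),
                  both_anchors = logical()))
  }
  list_rbind(rows)
}

#' Pan-category enrichment of candidate loop clusters
#'
#' Compares category proportions among a candidate subset of loop clusters
#' to all clusters, with a one-sided hypergeometric enrichment p-value per
#' category.
#'
#' @param candidate_clusters,all_clusters Cluster tibbles with a
#'   `category` column (candidates are a subset of all).
#' @return Tibble per category: counts, proportions, `p_enrichment`.
#' @export
pan_type_enrichment <- function(candidate_clusters, all_clusters) {
  if (nrow(candidate_clusters) == 0) abort("empty candidate set")
  lev <- levels(classify_pan_category(1, 2))
  N <- nrow(all_clusters); n <- nrow(candidate_clusters)
  map(lev, function(cat) {
    K <- sum(all_clusters$category == cat)
    k <- sum(candidate_clusters$category == cat)
    tibble(category = cat, n_all = K, n_candidate = k,
           prop_all = K / N, prop_candidate = k / n,
           p_enrichment = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  }) |> list_rbind()
}
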