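# Structural-variant toolkit: multi-genome merging into a non-redundant
# set, junction-feature mechanism classification, breakpoint hotspots,
# SV-gene annotation, and genotype-level quality filtering.

#' Merge SVs across genomes into a non-redundant set
#'
#' SURVIVOR-style merging: records shorter than `min_size` are dropped; two
#' SVs are linked when they have the same type (if `require_type`), lie on
#' the same chromosome and both breakpoints are within `max_dist` of each
#' other; merged sets are the connected components of the link graph. The
#' representative record of a component is its medoid (the member with the
#' smallest summed breakpoint distance to the others; ties broken by lowest
#' genome id, then coordinate).
#'
#' @param svs SV tibble: `chrom,start,end,sv_type,size,genome_id` plus any
#'   extra columns (kept from the medoid).
#' @param max_dist Maximum breakpoint distance in bp (default 1000).
#' @param min_size Minimum SV size in bp (default 50).
#' @param require_type Require type agreement for linking (default TRUE).
#' @return Tibble of merged records with `n_members`, `support` (number of
#'   distinct genomes), `genome_ids` and `member_rows` list columns.
#' @export
merge_svs <- function(svs, max_dist = 1000, min_size = 50,
                      require_type = TRUE) {
  validate_intervals(svs)
  if (!all(c("sv_type", "size", "genome_id") %in% names(svs))) {
    abort("svs need sv_type, size and genome_id columns")
  }
  svs <- svs[svs$size >= min_size, ]
  n <- nrow(svs)
  if (n == 0) return(mutate(svs, n_members = integer(), support = integer()))
  key <- if (require_type) paste(svs$chrom, svs$sv_type) else svs$chrom
  ord <- order(key, svs$start)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (u in seq_len(n - 1)) {
    i <- ord[u]
    for (v in (u + 1):n) {
      j <- ord[v]
      if (key[j] != key[i]) break
      if (svs$start[j] - svs$start[i] > max_dist) break
      if (abs(svs$end[j] - svs$end[i]) <= max_dist) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  comp <- match(root, unique(root[ord]))   # stable component ids
  pick_medoid <- function(idx) {
    if (length(idx) == 1) return(idx)
    s <- svs$start[idx]; e <- svs$end[idx]
    d <- vapply(seq_along(idx),
                \(k) sum(abs(s - s[k]) + abs(e - e[k])), numeric(1))
    idx[order(d, svs$genome_id[idx], s)[1]]
  }
  groups <- split(seq_len(n), comp)
  med <- vapply(groups, pick_medoid, integer(1))
  out <- svs[med, ]
  out$n_members <- unname(lengths(groups))
  out$genome_ids <- unname(map(groups, \(i) sort(unique(svs$genome_id[i]))))
  out$support <- lengths(out$genome_ids)
  out$member_rows <- unname(groups)
  out[order(out$chrom, out$start), ]
}

#' Classify SV formation mechanism from junction features
#'
#' First matching rule in fixed order: tandem-repeat coverage at least
#' `tr_min` is VNTR; transposable-element coverage at least `te_min` with a
#' single dominant family is TEI; flanking homology of at least `nahr_min`
#' bp is NAHR; a templated-switch junction is FoSTeS/MMBIR; microhomology
#' of `altej_range` bp is alt-EJ; microhomology up to `nhej_max` bp is
#' NHEJ; anything else (or a missing junction block) is unassigned. The
#' thresholds approximate the conventions of Meerkat-style pipelines and
#' are all tunable.
#'
#' @param svs SV tibble with junction columns `tr_cov`, `te_cov`,
#'   `te_family`, `flank_hom`, `microhom`, `templated_switch`.
#' @param tr_min,te_min,nahr_min,altej_range,nhej_max Rule thresholds.
#' @return `svs` with `mechanism` and `rule_fired` columns.
#' @export
classify_sv_mechanism <- function(svs, tr_min = 0.8, te_min = 0.8,
                                  nahr_min = 100, altej_range = c(3, 20),
                                  nhej_max = 2) {
  jcols <- c("tr_cov", "te_cov", "flank_hom", "microhom",
             "templated_switch")
  has_junction <- if (all(jcols %in% names(svs))) {
    stats::complete.cases(svs[jcols])
  } else rep(FALSE, nrow(svs))
  mech <- rep("unassigned", nrow(svs))
  rule <- rep("missing_junction", nrow(svs))
  h <- which(has_junction)
  tef <- if ("te_family" %in% names(svs)) svs$te_family else {
    rep(NA_character_, nrow(svs))
  }
  fam_ok <- !is.na(tef[h]) & nzchar(as.character(tef[h]))
  pick <- function(cond, label, rname) {
    sel <- h[cond & mech[h] == "unassigned" &
               rule[h] %in% c("missing_junction", "no_rule")]
    mech[sel] <<- label
    rule[sel] <<- rname
  }
  if (length(h)) {
    rule[h] <- "no_rule"
    pick(svs$tr_cov[h] >= tr_min, "VNTR", "tr_coverage")
    pick(svs$te_cov[h] >= te_min & fam_ok, "TEI", "te_coverage")
    pick(svs$flank_hom[h] >= nahr_min, "NAHR", "flank_homology")
    pick(svs$templated_switch[h], "FoSTeS_MMBIR", "templated_switch")
    pick(svs$microhom[h] >= altej_range[1] &
           svs$microhom[h] <= altej_range[2], "alt_EJ", "microhomology")
    pick(svs$microhom[h] <= nhej_max, "NHEJ", "blunt_junction")
  }
  svs$mechanism <- mech
  svs$rule_fired <- rule
  svs
}

#' SV breakpoint hotspots in tiling windows
#'
#' Counts SV breakpoints (both ends of every record) in non-overlapping
#' windows tiling each chromosome; a window is a hotspot when its count
#' exceeds the genome-wide mean by more than `n_sd` standard deviations
#' (population sd over all windows). `method = "percentile"` instead flags
#' windows above the `1 - top_frac` count quantile. Uniform counts (zero
#' variance) yield no hotspots.
#'
#' @param svs SV interval tibble.
#' @param genome [genome_coords()] tibble.
#' @param window,step Window and step size in bp (default 100 kb tiling).
#' @param method "sd" (default) or "percentile".
#' @param n_sd Threshold in sd units (default 2).
#' @param top_frac Fraction for the percentile method (default 0.01).
#' @return Window tibble `chrom,start,end,n_breakpoints,hotspot` with the
#'   threshold as attribute `threshold`.
#' @export
sv_hotspots <- function(svs, genome, window = 1e5, step = 1e5,
                        method = c("sd", "percentile"), n_sd = 2,
                        top_frac = 0.01) {
  method <- match.arg(method)
  wins <- map(seq_len(nrow(genome)), function(ci) {
    starts <- seq(0, genome$length[ci] - 1, by = step)
    tibble(chrom = genome$chrom[ci], start = starts,
           end = pmin(starts + window, genome$length[ci]))
  }) |> list_rbind()
  bp <- tibble(chrom = rep(svs$chrom, 2),
               pos = c(svs$start, pmax(svs$end - 1, svs$start)))
  wins$n_breakpoints <- 0L
  for (ch in unique(wins$chrom)) {
    w <- which(wins$chrom == ch)
    p <- bp$pos[bp$chrom == ch]
    if (!length(p)) next
    idx <- findInterval(p, wins$start[w])
    idx <- idx[idx > 0 & p < wins$end[w][pmax(idx, 1)]]
    cnt <- table(idx)
    wins$n_breakpoints[w[as.integer(names(cnt))]] <- as.integer(cnt)
  }
  x <- wins$n_breakpoints
  thr <- if (method == "sd") {
    s <- sqrt(mean((x - mean(x))^2))
    if (s == 0) Inf else mean(x) + n_sd * s
  } else {
    quantile(x, 1 - top_frac, names = FALSE)
  }
  wins$hotspot <- x > thr
  attr(wins, "threshold") <- thr
  wins
}

#' Pair SVs with genes near their breakpoints
#'
#' A gene is an SV-gene when its span overlaps the window extending
#' `flank` bp on both sides of either SV breakpoint.
#'
#' @param svs SV interval tibble (an `id` column is kept if present).
#' @param genes Gene tibble from [gene_table()].
#' @param flank Breakpoint flank in bp (default 5000).
#' @return Tibble of (sv row, breakpoint, gene_id) pairs.
#' @export
annotate_sv_genes <- function(svs, genes, flank = 5000) {
  validate_intervals(svs)
  sv_id <- if ("id" %in% names(svs)) svs$id else {
    sprintf("sv_%05d", seq_len(nrow(svs)))
  }
  bp <- tibble(sv = rep(seq_len(nrow(svs)), 2),
               breakpoint = rep(c("start", "end"), each = nrow(svs)),
               chrom = rep(svs$chrom, 2),
               pos = c(svs$start, pmax(svs$end - 1, svs$start)))
  rows <- map(seq_len(nrow(bp)), function(i) {
    g <- genes[genes$chrom == bp$chrom[i] &
                 genes$start < bp$pos[i] + flank + 1 &
                 genes$end > bp$pos[i] - flank, ]
    if (!nrow(g)) return(NULL)
    tibble(sv_id = sv_id[bp$sv[i]], breakpoint = bp$breakpoint[i],
           gene_id = g$gene_id)
  })
  out <- list_rbind(rows)
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(sv_id = character(), breakpoint = character(),
                  gene_id = character()))
  }
  distinct(out, .data$sv_id, .data$gene_id, .keep_all = TRUE)
}

#' Genotype-level SV site filtering
#'
#' Per call, the genotype is set missing unless read depth exceeds
#' `dp_min` and genotype quality exceeds `gq_min` (both strict). Per site,
#' the site is dropped when the missing fraction exceeds `max_missing` or
#' the minor-allele frequency over non-missing alleles falls below
#' `min_maf`.
#'
#' @param genotypes Long tibble `site_id, sample_id, gt, dp, gq` (gt =
#'   alt-dosage 0/1/2, NA = missing).
#' @param dp_min,gq_min Strict lower bounds (call kept when DP > 2 and
#'   GQ > 10 at the defaults).
#' @param max_missing Maximum tolerated missing fraction per site.
#' @param min_maf Minimum minor-allele frequency per site.
#' @return List: `sites` (per-site tibble with `missing_frac`, `maf`,
#'   `kept`), `genotypes` (the masked long table of kept sites).
#' @export
filter_genotyped_svs <- function(genotypes, dp_min = 2, gq_min = 10,
                                 max_missing = 0.5, min_maf = 0.05) {
  g <- genotypes
  g$gt_masked <- ifelse(g$dp > dp_min & g$gq > gq_min, g$gt, NA_integer_)
  sites <- g |>
    group_by(.data$site_id) |>
    summarise(n = dplyr::n(),
              missing_frac = mean(is.na(.data$gt_masked)),
              maf = {
                ok <- !is.na(.data$gt_masked)
                if (!any(ok)) NA_real_ else {
                  p <- sum(.data$gt_masked[ok]) / (2 * sum(ok))
                  min(p, 1 - p)
                }
              }, .groups = "drop") |>
    mutate(kept = .data$missing_frac <= max_missing &
             !is.na(.data$maf) & .data$maf >= min_maf)
  kept_ids <- sites$site_id[sites$kept]
  list(sites = sites,
       genotypes = g[g$site_id %in% kept_ids, ] |>
         mutate(gt = .data$gt_masked) |> select(-"gt_masked"))
}
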