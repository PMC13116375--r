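# Synthetic multi-genome pan datasets with planted ground truth.
#
# Generation is class-first: each feature cluster draws its conservation
# category, then genome membership consistent with it, then per-genome
# coordinates through that genome's indel-shifted liftover map plus bounded
# jitter. Downstream classification therefore has an exact right answer.

sim_kinds <- c("family", "boundary", "ltcre", "loop", "sv")

#' Simulation configuration
#'
#' Defaults describe a 15-assembly pan-genome study on a 10-Mb backbone
#' chromosome with class probabilities close to the genome-wide proportions
#' reported for pan-gene families (core 0.30, softcore 0.13, dispensable
#' 0.29, private 0.28). Counts are per feature kind.
#'
#' @param n_genomes Number of genomes.
#' @param chrom_sizes [genome_coords()] tibble for the backbone.
#' @param class_probs Named probabilities over core/softcore/dispensable/
#'   private; must sum to 1.
#' @param n_gene_families,n_boundaries,n_ltcres,n_loops,n_svs Cluster counts.
#' @param boundary_depletion_factor SV density multiplier inside boundary
#'   regions (1 = no depletion).
#' @param tad_sizes Mean/min TAD size in bins, used by the contact-matrix
#'   fixture.
#' @param pop_sizes Two diploid sample sizes for the genotype generator.
#' @param fst_target Planted allele-frequency divergence level in [0, 1].
#' @param seed Integer seed; every stochastic path draws from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genomes = 15,
                       chrom_sizes = genome_coords("chr1", 1e7),
                       class_probs = c(core = 0.30, softcore = 0.13,
                                       dispensable = 0.29, private = 0.28),
                       n_gene_families = 200, n_boundaries = 50,
                       n_ltcres = 200, n_loops = 100, n_svs = 200,
                       boundary_depletion_factor = 1,
                       tad_sizes = c(mean_bins = 10, min_bins = 3),
                       pop_sizes = c(25, 25), fst_target = 0.3, seed = 1) {
  if (abs(sum(class_probs) - 1) > 1e-8) abort("class_probs must sum to 1")
  if (n_genomes < 10) {
    abort("softcore band is empty for n_genomes < 10; choose n >= 10")
  }
  structure(list(n_genomes = n_genomes, chrom_sizes = chrom_sizes,
                 class_probs = class_probs,
                 n_gene_families = n_gene_families,
                 n_boundaries = n_boundaries, n_ltcres = n_ltcres,
                 n_loops = n_loops, n_svs = n_svs,
                 boundary_depletion_factor = boundary_depletion_factor,
                 tad_sizes = tad_sizes, pop_sizes = pop_sizes,
                 fst_target = fst_target, seed = seed),
            class = "sim_config")
}

# membership count for one cluster given its class
draw_presence_count <- function(class, n) {
  lo_soft <- ceiling(0.9 * n)
  pick1 <- function(v) if (length(v) == 1) v else sample(v, 1)
  as.integer(switch(class,
                    core = n,
                    softcore = if (lo_soft > n - 1) {
                      abort("softcore band empty for this n_genomes")
                    } else pick1(lo_soft:(n - 1)),
                    private = 1L,
                    dispensable = pick1(2:(lo_soft - 1))))
}

# indel-shifted liftover maps, one per genome: src = genome, tgt = backbone.
# 1-10 indels of 1-50 kb per chromosome keeps > 95% of the backbone
# alignable at the default sizes.
simulate_liftover_maps <- function(genome, n_genomes,
                                   n_indel_range = c(1, 10),
                                   indel_size_range = c(1000, 50000)) {
  maps <- map(seq_len(n_genomes), function(g) {
    blocks <- map(seq_len(nrow(genome)), function(ci) {
      L <- genome$length[ci]
      ch <- genome$chrom[ci]
      k <- sample(n_indel_range[1]:n_indel_range[2], 1)
      sizes <- round(runif(k, indel_size_range[1], indel_size_range[2]))
      pos <- sort(round(runif(k, 0.02 * L, 0.98 * L)))
      # drop events closer together than their sizes allow
      keep <- c(TRUE, diff(pos) > utils::head(sizes, -1) + 1000)
      pos <- pos[keep]; sizes <- sizes[keep]
      type <- sample(c("del", "ins"), length(pos), replace = TRUE)
      b <- 0; gpos <- 0
      out <- list()
      for (i in seq_along(pos)) {
        len <- pos[i] - b
        out[[length(out) + 1]] <- c(gpos, gpos + len, b, pos[i])
        gpos <- gpos + len; b <- pos[i]
        if (type[i] == "del") b <- b + sizes[i]       # genome lacks it
        else gpos <- gpos + sizes[i]                  # genome gained it
      }
      out[[length(out) + 1]] <- c(gpos, gpos + (L - b), b, L)
      m <- do.call(rbind, out)
      tibble(src_chrom = ch, src_start = m[, 1], src_end = m[, 2],
             tgt_chrom = ch, tgt_start = m[, 3], tgt_end = m[, 4],
             event = NA_character_)
    }) |> list_rbind()
    blocks[c("src_chrom", "src_start", "src_end",
             "tgt_chrom", "tgt_start", "tgt_end")]
  })
  names(maps) <- sprintf("G%02d", seq_len(n_genomes))
  maps
}

# backbone intervals that are NOT cleanly alignable in every genome:
# deleted backbone segments plus block junctions (insertion points)
backbone_footprints <- function(maps) {
  fp <- map(maps, function(m) {
    m <- m |> arrange(.data$tgt_chrom, .data$tgt_start)
    gaps <- m |>
      group_by(.data$tgt_chrom) |>
      reframe(start = utils::head(.data$tgt_end, -1) - 1,
              end = utils::tail(.data$tgt_start, -1) + 1) |>
      rename(chrom = "tgt_chrom")
    gaps[gaps$end > gaps$start, ]
  }) |> list_rbind()
  fp
}

# grid slots on the backbone avoiding footprints; errors when too few fit.
# extent = footprint of one cluster around its slot (width + jitter range)
place_slots <- function(genome, footprints, n_needed, spacing, extent) {
  slots <- map(seq_len(nrow(genome)), function(ci) {
    L <- genome$length[ci]
    pos <- seq(extent, L - spacing - extent, by = spacing)
    tibble(chrom = genome$chrom[ci], pos = pos)
  }) |> list_rbind()
  if (nrow(footprints)) {
    bad <- slot_hits_footprint(slots, footprints, extent)
    slots <- slots[!bad, ]
  }
  if (nrow(slots) < n_needed) {
    abort(sprintf(paste("only %d clean placement slots for %d clusters;",
                        "enlarge the backbone or reduce counts"),
                  nrow(slots), n_needed))
  }
  slots[sample(nrow(slots), n_needed), ]
}

slot_hits_footprint <- function(slots, fp, extent) {
  out <- rep(FALSE, nrow(slots))
  for (ch in unique(slots$chrom)) {
    s <- which(slots$chrom == ch)
    f <- fp[fp$chrom == ch, ]
    if (!nrow(f)) next
    out[s] <- vapply(slots$pos[s], function(p) {
      any(f$start < p + extent & f$end > p - extent)
    }, logical(1))
  }
  out
}

#' Simulate a multi-genome pan dataset with planted conservation classes
#'
#' Emits per-genome feature tables (TAD boundaries and LT-CREs in genome
#' coordinates, chromatin loops and SVs on the backbone), per-genome
#' liftover maps, a gene-family presence matrix, and a truth table holding
#' each cluster's planted category (plus each SV cluster's planted
#' formation mechanism). Cluster spacing and jitter bounds are chosen so
#' that downstream clustering recovers the planted classes exactly: jitter
#' stays below half the merge gap of each feature kind.
#'
#' @param config A [sim_config()].
#' @return List with elements `maps`, `features` (named list of per-genome
#'   tibbles by kind), `presence` (gene-family logical matrix), `truth`
#'   (tibble: kind, cluster_id, chrom, pos, class, presence_count,
#'   genomes, mechanism), `genomes` (ids), `config`.
#' @export
simulate_pan_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  n <- config$n_genomes
  gids <- sprintf("G%02d", seq_len(n))
  genome <- config$chrom_sizes
  maps <- simulate_liftover_maps(genome, n)
  fp <- backbone_footprints(maps)
  classes <- names(config$class_probs)

  draw_clusters <- function(kind, n_clusters, width, spacing, jitter,
                            with_pos = TRUE) {
    cls <- sample(classes, n_clusters, replace = TRUE,
                  prob = config$class_probs)
    cnt <- vapply(cls, draw_presence_count, integer(1), n = n)
    members <- map(cnt, \(k) sort(sample(n, k)))
    slots <- if (with_pos) {
      place_slots(genome, fp, n_clusters, spacing,
                  extent = jitter + width + 2)
    } else tibble(chrom = NA_character_, pos = NA_real_)[rep(1, n_clusters), ]
    tibble(kind = kind,
           cluster_id = sprintf("%s_T%04d", kind, seq_len(n_clusters)),
           chrom = slots$chrom, pos = slots$pos, class = cls,
           presence_count = cnt,
           genomes = map(members, \(i) gids[i]))
  }

  # gene families: presence only
  fam <- draw_clusters("family", config$n_gene_families, 0, 1, 0,
                       with_pos = FALSE)
  pres <- vapply(gids, \(g) map_lgl_(fam$genomes, g),
                 logical(nrow(fam)))
  pres <- matrix(pres, nrow = nrow(fam),
                 dimnames = list(fam$cluster_id, gids))

  # interval kinds: width, merge gap -> spacing and jitter
  geom <- list(
    boundary = list(width = 40000, gap = 40000),
    ltcre = list(width = 400, gap = 500),
    sv = list(width = 2000, gap = 1000)   # gap = SV merge breakpoint dist
  )
  feats <- list()
  truths <- list(fam)
  for (kind in names(geom)) {
    gpar <- geom[[kind]]
    n_clusters <- switch(kind, boundary = config$n_boundaries,
                         ltcre = config$n_ltcres, sv = config$n_svs)
    jitter <- floor(gpar$gap * 0.45)
    spacing <- gpar$width + 3 * gpar$gap + 2 * jitter
    tr <- draw_clusters(kind, n_clusters, gpar$width, spacing, jitter)
    if (kind == "sv") {
      mech <- sample(c("TEI", "NHEJ", "VNTR", "FoSTeS_MMBIR", "NAHR",
                       "alt_EJ"), n_clusters, replace = TRUE,
                     prob = c(0.45, 0.20, 0.18, 0.06, 0.06, 0.05))
      tr$mechanism <- mech
      tr$sv_type <- sample(c("DEL", "INS", "INV", "DUP"), n_clusters,
                           replace = TRUE, prob = c(0.45, 0.35, 0.1, 0.1))
    }
    rows <- map(seq_len(nrow(tr)), function(i) {
      g <- tr$genomes[[i]]
      jit <- round(runif(length(g), -jitter, jitter))
      bb <- tibble(chrom = tr$chrom[i], start = tr$pos[i] + jit,
                   end = tr$pos[i] + jit + gpar$width,
                   genome_id = g, cluster_id = tr$cluster_id[i])
      if (kind == "sv") {
        bb$sv_type <- tr$sv_type[i]
        bb$size <- gpar$width
        bb <- bind_cols(bb, junction_signature(tr$mechanism[i], length(g)))
        bb$mechanism_truth <- tr$mechanism[i]
      }
      bb
    }) |> list_rbind()
    if (kind %in% c("boundary", "ltcre")) {
      # express in each genome's own coordinates through its map
      rows <- split(rows, rows$genome_id) |>
        map(function(d) {
          inv <- invert_liftover_map(maps[[d$genome_id[1]]])
          lifted <- liftover_intervals(d, inv)
          if (any(!lifted$mapped)) abort("internal: planted feature unmapped")
          lifted |> select(-"mapped", -"unmapped_reason",
                           -"src_chrom", -"src_start", -"src_end")
        }) |>
        list_rbind()
    }
    feats[[kind]] <- rows
    truths[[length(truths) + 1]] <- tr
  }

  # loops: anchor pairs on the backbone
  lw <- 10000; ljit <- 2000
  ltr <- draw_clusters("loop", config$n_loops, lw, 6 * lw, ljit)
  loop_rows <- map(seq_len(nrow(ltr)), function(i) {
    g <- ltr$genomes[[i]]
    L <- genome$length[match(ltr$chrom[i], genome$chrom)]
    max_span <- L - ltr$pos[i] - lw - ljit - 1
    span <- min(round(runif(1, 20 * lw, 60 * lw)), max_span)
    a1 <- ltr$pos[i] + round(runif(length(g), -ljit, ljit))
    a2 <- ltr$pos[i] + span + round(runif(length(g), -ljit, ljit))
    tibble(chrom1 = ltr$chrom[i], start1 = a1, end1 = a1 + lw,
           chrom2 = ltr$chrom[i], start2 = a2, end2 = a2 + lw,
           genome_id = g, cluster_id = ltr$cluster_id[i])
  }) |> list_rbind()
  feats$loop <- loop_rows
  truths[[length(truths) + 1]] <- ltr

  truth <- list_rbind(map(truths, \(d) {
    if (!"mechanism" %in% names(d)) d$mechanism <- NA_character_
    if (!"sv_type" %in% names(d)) d$sv_type <- NA_character_
    d
  }))
  list(maps = maps, features = feats, presence = pres, truth = truth,
       genomes = gids, config = config)
}

# junction-feature signature satisfying a mechanism's rule and violating
# every earlier rule in the classifier's fixed order
junction_signature <- function(mechanism, k) {
  low_te <- runif(k, 0, 0.3); low_tr <- runif(k, 0, 0.3)
  base <- tibble(te_cov = low_te, te_family = NA_character_,
                 tr_cov = low_tr, flank_hom = 0,
                 microhom = sample(0:2, k, replace = TRUE),
                 templated_switch = FALSE)
  switch(mechanism,
         VNTR = mutate(base, tr_cov = runif(k, 0.85, 1)),
         TEI = mutate(base, te_cov = runif(k, 0.85, 1),
                      te_family = "LTR/ERV"),
         NAHR = mutate(base, flank_hom = sample(120:400, k, replace = TRUE)),
         FoSTeS_MMBIR = mutate(base, templated_switch = TRUE,
                               microhom = sample(0:30, k, replace = TRUE)),
         alt_EJ = mutate(base, microhom = sample(3:20, k, replace = TRUE)),
         NHEJ = mutate(base, microhom = sample(0:2, k, replace = TRUE)))
}

#' Simulate a block-model contact matrix with planted TADs
#'
#' Expected counts are `within` inside planted TAD blocks and `between`
#' elsewhere; Poisson noise by default (counts), truncated-Gaussian
#' optional, and `noise = "none"` returns the exact block model.
#'
#' @param tads Interval tibble tiling one chromosome, bin-aligned.
#' @param bin_size Bin size in bp.
#' @param within,between Mean contact counts inside / outside TADs.
#' @param noise One of "poisson", "gaussian", "none".
#' @param noise_sd Gaussian sd (ignored otherwise).
#' @param seed RNG seed.
#' @return A [contact_matrix()].
#' @export
simulate_contact_matrix <- function(tads, bin_size = 40000, within = 5,
                                    between = 1,
                                    noise = c("poisson", "gaussian", "none"),
                                    noise_sd = 0.5, seed = 1) {
  noise <- match.arg(noise)
  validate_intervals(tads)
  if (within <= between || between < 0) abort("need within > between >= 0")
  nb <- (tads$end - tads$start) / bin_size
  if (any(nb < 2)) abort("every TAD must span at least 2 bins")
  n <- sum(nb)
  tad_of <- rep(seq_len(nrow(tads)), nb)
  B <- matrix(between, n, n)
  B[outer(tad_of, tad_of, "==")] <- within
  if (noise != "none") {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    up <- upper.tri(B, diag = TRUE)
    vals <- if (noise == "poisson") {
      rpois(sum(up), B[up])
    } else {
      pmax(0, B[up] + rnorm(sum(up), 0, noise_sd))
    }
    M <- matrix(0, n, n)
    M[up] <- vals
    M <- M + t(M) - diag(diag(M))
  } else {
    M <- B
  }
  contact_matrix(M, chrom = tads$chrom[1], bin_size = bin_size)
}

#' Random bin-aligned TAD partition of a chromosome
#'
#' @param chrom_length Chromosome length (multiple of `bin_size`).
#' @param n_tads Number of TADs.
#' @param bin_size Bin size in bp.
#' @param min_bins Minimum TAD width in bins. The default of 5 bins
#'   (200 kb at 40-kb resolution) is the smallest domain a `w = 2` diamond
#'   window can resolve: junctions closer than about `2w + 1` bins share
#'   insulation windows and their minima merge.
#' @param chrom Chromosome name.
#' @param seed RNG seed.
#' @return Interval tibble tiling the chromosome.
#' @export
simulate_tads <- function(chrom_length, n_tads, bin_size = 40000,
                          min_bins = 5, chrom = "chr1", seed = 1) {
  nb <- chrom_length / bin_size
  if (n_tads * min_bins > nb) abort("chromosome too short for these TADs")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  extra <- stats::rmultinom(1, nb - n_tads * min_bins, rep(1, n_tads))[, 1]
  widths <- (min_bins + extra) * bin_size
  ends <- cumsum(widths)
  intervals(chrom, c(0, utils::head(ends, -1)), ends)
}

#' Simulate two-population diploid genotypes with divergence
#'
#' Hardy-Weinberg draws within each population at the supplied per-site
#' allele frequencies; read depth is Poisson, genotype quality truncated
#' Gaussian, so downstream DP/GQ filters have something to act on.
#'
#' @param pop_sizes Two diploid sample counts.
#' @param p1,p2 Per-site alternate allele frequencies (equal length).
#' @param dp_mean Mean read depth.
#' @param gq_mean,gq_sd Genotype quality distribution.
#' @param seed RNG seed.
#' @return Tibble `site_id, sample_id, pop, gt, dp, gq` (gt = alt-allele
#'   dosage 0/1/2).
#' @export
simulate_genotypes <- function(pop_sizes, p1, p2, dp_mean = 20,
                               gq_mean = 40, gq_sd = 15, seed = 1) {
  stopifnot(length(p1) == length(p2),
            all(p1 >= 0 & p1 <= 1), all(p2 >= 0 & p2 <= 1))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_sites <- length(p1)
  samples <- c(sprintf("P1_%03d", seq_len(pop_sizes[1])),
               sprintf("P2_%03d", seq_len(pop_sizes[2])))
  pop <- rep(c("pop1", "pop2"), pop_sizes)
  tab <- crossing(site_id = sprintf("site_%04d", seq_len(n_sites)),
                  sample_id = samples) |>
    arrange(.data$site_id, .data$sample_id)
  tab$pop <- pop[match(tab$sample_id, samples)]
  site_idx <- match(tab$site_id, sprintf("site_%04d", seq_len(n_sites)))
  p <- ifelse(tab$pop == "pop1", p1[site_idx], p2[site_idx])
  tab$gt <- rbinom(nrow(tab), 2, p)
  tab$dp <- rpois(nrow(tab), dp_mean)
  tab$gq <- pmax(0, round(rnorm(nrow(tab), gq_mean, gq_sd)))
  tab
}

#' Simulate a paired WT/MT Capture Hi-C score table
#'
#' A planted fraction of rows is MT-specific by construction (MT score >= 3,
#' WT score < 3, difference > 3); the rest violate at least one of the
#' three conditions, in either direction never qualifying as differential.
#'
#' @param n_interactions Number of rows.
#' @param frac_mt_specific Planted fraction (exactly
#'   `round(frac * n)` truth-positive rows).
#' @param seed RNG seed.
#' @return Tibble with bait/other-end coordinates, `score_wt`, `score_mt`
#'   and the truth flag `mt_specific_truth`.
#' @export
simulate_capture_table <- function(n_interactions, frac_mt_specific = 0.2,
                                   seed = 1) {
  stopifnot(frac_mt_specific >= 0, frac_mt_specific <= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- n_interactions
  n_mt <- round(frac_mt_specific * n)
  truth <- c(rep(TRUE, n_mt), rep(FALSE, n - n_mt))
  wt <- numeric(n); mt <- numeric(n)
  wt[truth] <- runif(n_mt, 0, 2.9)
  mt[truth] <- pmax(3.01, wt[truth] + 3.01) + runif(n_mt, 0, 8)
  bg_kind <- sample(c("both_low", "both_sig", "small_diff"), n - n_mt,
                    replace = TRUE)
  for (i in which(!truth)) {
    k <- bg_kind[sum(!truth[seq_len(i)])]
    if (k == "both_low") {
      wt[i] <- runif(1, 0, 2.9); mt[i] <- runif(1, 0, 2.9)
    } else if (k == "both_sig") {
      wt[i] <- runif(1, 3, 10); mt[i] <- wt[i] + runif(1, -2.5, 2.5)
      mt[i] <- max(mt[i], 3)
    } else {
      wt[i] <- runif(1, 0, 2.9); mt[i] <- wt[i] + runif(1, 0, 2.9)
    }
  }
  pos <- sort(sample(seq(0, 1e7 - 5000, by = 5000), n))
  tibble(bait_chrom = "chr1", bait_start = 1e5, bait_end = 1.05e5,
         oe_chrom = "chr1", oe_start = pos, oe_end = pos + 5000,
         score_wt = wt, score_mt = mt, mt_specific_truth = truth)
}

#' Place SVs with controlled density inside given regions
#'
#' Uniform placement over the genome, with candidates whose midpoint falls
#' inside `regions` retained with probability `factor` (a factor below 1
#' plants depletion; 1 is the uniform null). Used to exercise the bootstrap
#' coverage test with a known effect.
#'
#' @param genome [genome_coords()] tibble.
#' @param regions Interval tibble (e.g. pan-TAD boundaries).
#' @param n_svs Number of SVs to place.
#' @param factor Acceptance probability inside regions.
#' @param sv_size SV length in bp (single value or range c(lo, hi)).
#' @param seed RNG seed.
#' @return Interval tibble of placed SVs.
#' @export
simulate_sv_placement <- function(genome, regions, n_svs, factor = 1,
                                  sv_size = c(200, 2000), seed = 1) {
  stopifnot(factor >= 0, factor <= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  idx <- coverage_index(regions)
  out <- list()
  got <- 0
  probs <- genome$length / sum(genome$length)
  while (got < n_svs) {
    m <- max(1000, 2 * (n_svs - got))
    ci <- sample(nrow(genome), m, replace = TRUE, prob = probs)
    size <- if (length(sv_size) == 2) {
      round(runif(m, sv_size[1], sv_size[2]))
    } else rep(sv_size, m)
    start <- floor(runif(m, 0, genome$length[ci] - size))
    mid <- start + size / 2
    inside <- covered_bp(idx, genome$chrom[ci], mid, mid + 1) > 0
    keep <- !inside | (runif(m) < factor)
    k <- utils::head(which(keep), n_svs - got)
    if (length(k)) {
      s_k <- start[k]
      out[[length(out) + 1]] <- tibble(chrom = genome$chrom[ci[k]],
                                       start = s_k, end = s_k + size[k])
      got <- got + length(k)
    }
  }
  list_rbind(out)
}
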