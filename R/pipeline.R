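# End-to-end orchestration on a synthetic dataset: simulate, lift and
# classify pan features, call chromatin architecture, merge and type SVs,
# run the enrichment and selection screens, call differential capture
# interactions. Deterministic for a fixed config.

#' Run the full pipeline on a simulated pan dataset
#'
#' Stages run in dependency order (simulate, chromatin, pan-classify, sv,
#' select/enrich, capture-diff); identical config and seed give identical
#' outputs. The manifest records the package version, the seed and the
#' per-stage parameters used.
#'
#' @param config A [sim_config()].
#' @param stages Character subset of
#'   `c("chromatin", "pan", "sv", "select", "capture")`; the simulation
#'   always runs first.
#' @return Named list of result tibbles plus `truth`, `manifest`.
#' @export
run_pipeline <- function(config = sim_config(),
                         stages = c("chromatin", "pan", "sv", "select",
                                    "capture")) {
  stages <- match.arg(stages, several.ok = TRUE)
  sim <- simulate_pan_dataset(config)
  out <- list(truth = sim$truth)
  n <- config$n_genomes

  if ("chromatin" %in% stages) {
    tads <- simulate_tads(4e6, 10, bin_size = 40000,
                          seed = config$seed)
    cm <- simulate_contact_matrix(tads, within = 5, between = 1,
                                  seed = config$seed)
    track <- insulation_score(cm, w = 2)
    bounds <- call_boundaries(track)
    out$insulation <- track
    out$boundaries <- bounds
    out$tads <- call_tads(bounds, 4e6)
  }

  if ("pan" %in% stages) {
    lift_kind <- function(kind, gap) {
      lifted <- split(sim$features[[kind]],
                      sim$features[[kind]]$genome_id) |>
        map(\(d) liftover_intervals(d, sim$maps[[d$genome_id[1]]])) |>
        list_rbind()
      cluster_lifted_intervals(lifted, n_genomes = n, max_gap = gap,
                               kind = kind)
    }
    out$pan_boundaries <- lift_kind("boundary", 40000)
    out$pan_ltcres <- lift_kind("ltcre", 500)
    out$pan_loops <- cluster_loops(sim$features$loop, n_genomes = n)
    out$accumulation <- accumulation_curves(sim$presence, n_orders = 20,
                                            seed = config$seed)
  }

  if ("sv" %in% stages) {
    merged <- merge_svs(sim$features$sv)
    merged$category <- classify_pan_category(merged$support, n)
    out$pan_svs <- classify_sv_mechanism(merged)
    out$hotspots <- sv_hotspots(merged, config$chrom_sizes)
  }

  if ("select" %in% stages) {
    p1 <- runif_seeded(200, config$seed + 11)
    shift <- config$fst_target
    p2 <- pmin(1, pmax(0, p1 + sample_seeded(c(-shift, shift), 200,
                                             config$seed + 12)))
    gt <- simulate_genotypes(config$pop_sizes, p1, p2,
                             seed = config$seed + 13)
    gm <- genotype_matrix(gt)
    fst <- wc_fst(gm$pop1, gm$pop2)
    pi1 <- nucleotide_diversity(gm$pop1)$per_site$pi
    pi2 <- nucleotide_diversity(gm$pop2)$per_site$pi
    tab <- tibble(site = seq_along(p1), fst = fst$per_site$theta,
                  pi_pop1 = pi1, pi_pop2 = pi2,
                  pi_ratio = pi1 / pmax(pi2, 1e-6))
    tab <- tab[is.finite(tab$fst) & is.finite(tab$pi_ratio), ]
    out$selection <- screen_candidate_svs(tab)
    if ("sv" %in% stages) {
      regs <- out$pan_svs[out$pan_svs$support == n,
                          c("chrom", "start", "end")]
      if (nrow(regs)) {
        out$bootstrap <- glance(bootstrap_coverage_test(
          sim$features$sv, regs, config$chrom_sizes, n_draws = 200,
          seed = config$seed))
      }
    }
  }

  if ("capture" %in% stages) {
    cap <- simulate_capture_table(200, 0.2, seed = config$seed)
    out$capture <- differential_interactions(call_significant(cap))
  }

  out$manifest <- tibble(
    package = "panchrom3d",
    version = as.character(utils::packageVersion("panchrom3d")),
    seed = config$seed,
    n_genomes = n,
    stages = paste(stages, collapse = ","),
    timestamp = NA_character_)   # kept NA so reruns are byte-identical
  out
}

# seeded draws that restore the caller's RNG state
runif_seeded <- function(n, seed, min = 0.05, max = 0.95) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  runif(n, min, max)
}
sample_seeded <- function(x, n, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sample(x, n, replace = TRUE)
}

#' Split a long genotype table into per-population dosage matrices
#'
#' @param gt Long tibble from [simulate_genotypes()].
#' @return List of matrices `pop1`, `pop2` (sites x individuals).
#' @export
genotype_matrix <- function(gt) {
  wide <- gt |>
    select("site_id", "sample_id", "gt") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "gt") |>
    arrange(.data$site_id)
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$site_id
  pops <- gt |> distinct(.data$sample_id, .data$pop)
  list(pop1 = m[, pops$sample_id[pops$pop == "pop1"], drop = FALSE],
       pop2 = m[, pops$sample_id[pops$pop == "pop2"], drop = FALSE])
}
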