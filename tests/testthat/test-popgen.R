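test_that("bootstrap p-values use the add-one empirical convention", {
  gen <- genome_coords("chr1", 1e6)
  regions <- intervals("chr1", c(100000, 300000), c(120000, 320000))
  # features cover everything except the two observed regions: observed
  # coverage 0, and a null draw of 0 needs both relocated regions to land
  # exactly inside the uncovered 20-kb slots
  feats <- intervals("chr1", c(0, 120000, 320000),
                     c(100000, 300000, 1e6))
  bt <- bootstrap_coverage_test(feats, regions, gen, n_draws = 1000,
                                seed = 1)
  expect_equal(bt$observed, 0)
  expect_equal(bt$p_depletion, (sum(bt$null_draws <= 0) + 1) / 1001)
  expect_lte(bt$p_depletion, 0.01)

  whole <- intervals("chr1", 0, 1e6)
  sat <- bootstrap_coverage_test(whole, regions, gen, n_draws = 100,
                                 seed = 1)
  expect_equal(sat$observed, 1)
  expect_equal(sat$p_enrichment, 1)   # every null draw is also 1

  expect_error(bootstrap_coverage_test(feats,
                                       intervals("chr1", 0, 1)[0, ], gen))
  expect_error(bootstrap_coverage_test(feats, intervals("chr1", 0, 2e6),
                                       gen))
})

test_that("bootstrap is deterministic under a fixed seed", {
  gen <- genome_coords(c("chr1", "chr2"), c(1e6, 5e5))
  regions <- intervals("chr1", seq(0, 9e5, 1e5), seq(0, 9e5, 1e5) + 2e4)
  feats <- simulate_sv_placement(gen, regions, 500, seed = 4)
  b1 <- bootstrap_coverage_test(feats, regions, gen, n_draws = 50,
                                seed = 7)
  b2 <- bootstrap_coverage_test(feats, regions, gen, n_draws = 50,
                                seed = 7)
  expect_identical(b1$null_draws, b2$null_draws)
})

test_that("planted depletion is detected", {
  gen <- genome_coords("chr1", 1e7)
  regions <- intervals("chr1", seq(0, 9e6, 1e6), seq(0, 9e6, 1e6) + 5e4)
  svs <- simulate_sv_placement(gen, regions, 10000, factor = 0.3,
                               seed = 1)
  bt <- bootstrap_coverage_test(svs, regions, gen, n_draws = 500,
                                seed = 1)
  expect_lte(bt$p_depletion, 0.01)
  expect_lt(bt$observed, mean(bt$null_draws))
})

test_that("Weir-Cockerham Fst matches the brute-force 1984 oracle", {
  g1 <- matrix(0L, 1, 10); g2 <- matrix(2L, 1, 10)
  expect_equal(wc_fst(g1, g2)$per_site$theta, 1)

  same <- matrix(c(2L, 1L, 1L, 0L), 1, 4)
  expect_lte(wc_fst(same, same)$per_site$theta, 0)

  set.seed(31)
  n1 <- 12; n2 <- 9
  G1 <- matrix(rbinom(100 * n1, 2, runif(100, 0.05, 0.95)), 100, n1)
  G2 <- matrix(rbinom(100 * n2, 2, runif(100, 0.05, 0.95)), 100, n2)
  G1[sample(length(G1), 30)] <- NA
  G2[sample(length(G2), 20)] <- NA
  got <- wc_fst(G1, G2)$per_site$theta
  want <- brute_wc_fst(G1, G2)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("per-site pi equals exhaustive pairwise difference counting", {
  # 4 haplotypes with 2 alt: 4 differing of 6 pairs
  expect_equal(nucleotide_diversity(matrix(c(1L, 1L), 1, 2))$per_site$pi,
               2 / 3)
  expect_equal(nucleotide_diversity(matrix(0L, 1, 5))$per_site$pi, 0)
  set.seed(17)
  G <- matrix(sample(c(0:2, NA), 40 * 6, replace = TRUE,
                     prob = c(0.4, 0.3, 0.2, 0.1)), 40, 6)
  got <- nucleotide_diversity(G)$per_site$pi
  want <- apply(G, 1, brute_pi)
  expect_equal(got, want)
})

test_that("windowed pi follows the 50-kb/25-kb convention", {
  G <- matrix(rep(1L, 4), 2, 2)         # two maximally het sites
  pos <- c(10000, 60000)
  nd <- nucleotide_diversity(G, pos = pos)
  w <- nd$windows
  expect_equal(w$end - w$start, rep(50000, nrow(w)))
  expect_equal(diff(w$start)[1], 25000)
  expect_equal(w$n_sites[1], 1)         # only the site at 10 kb
  expect_equal(w$pi[1], nd$per_site$pi[1] / 50000)
})

test_that("candidate screen takes the joint top tail, ranked by distance", {
  set.seed(1)
  n <- 1000
  tab <- tibble::tibble(fst = rnorm(n, 0.1, 0.05),
                        pi_ratio = exp(rnorm(n, 0, 0.5)))
  # plant 10 outliers shifted +5 sd on both axes
  tab$fst[1:10] <- max(tab$fst) + 5 * sd(tab$fst) * runif(10, 1, 1.2)
  tab$pi_ratio[1:10] <- max(tab$pi_ratio) *
    exp(5 * sd(log(tab$pi_ratio))) * runif(10, 1, 1.2)
  tab$id <- seq_len(n)
  sc <- screen_candidate_svs(tab)
  expect_true(all(1:10 %in% sc$id[sc$candidate]))
  expect_lte(sum(sc$candidate), ceiling(0.05 * n) + 1)
  # the joint maximum ranks first
  top <- sc$id[1]
  expect_equal(tab$fst[top], max(tab$fst))
  # high fst alone is not enough: the 0.9-fst marker sits at the median
  # of the pi_ratio distribution
  solo <- tibble::tibble(fst = c(rep(0.1, 99), 0.9),
                         pi_ratio = c(seq(0.5, 1.5, length.out = 99), 1))
  sc2 <- screen_candidate_svs(solo)
  expect_false(any(sc2$candidate[sc2$fst == 0.9]))
  expect_error(screen_candidate_svs(tab[1:10, ]))
})

test_that("SV-loop genes come from the opposite anchor", {
  genes <- toy_genes()
  loops <- tibble::tibble(chrom1 = "chr1", start1 = 4000, end1 = 6000,
                          chrom2 = "chr1", start2 = 50000, end2 = 52000)
  sv_hit1 <- intervals("chr1", 4500, 4600, id = "svA")
  res <- sv_loop_genes(sv_hit1, loops, genes)
  expect_equal(nrow(res), 1)
  expect_equal(res$genes[[1]], "gB")     # gB body overlaps anchor2
  expect_false(res$both_anchors)

  sv_miss <- intervals("chr1", 20000, 20100)   # inside span, not anchors
  expect_equal(nrow(sv_loop_genes(sv_miss, loops, genes)), 0)

  empty_side <- tibble::tibble(chrom1 = "chr1", start1 = 4000, end1 = 6000,
                               chrom2 = "chr1", start2 = 150000,
                               end2 = 152000)
  res2 <- sv_loop_genes(sv_hit1, empty_side, genes)
  expect_equal(nrow(res2), 1)
  expect_equal(length(res2$genes[[1]]), 0)

  spanning <- intervals("chr1", 4500, 51000, id = "svB")
  res3 <- sv_loop_genes(spanning, loops, genes)
  expect_true(all(res3$both_anchors))
  expect_equal(sort(res3$sv_anchor), c(1L, 2L))
})

test_that("pan-type enrichment compares proportions with hypergeometric p", {
  all_cl <- tibble::tibble(category = factor(
    rep(c("core", "softcore", "dispensable", "private"),
        c(40, 10, 30, 20)),
    levels = c("core", "softcore", "dispensable", "private")))
  cand_core <- all_cl[all_cl$category == "core", ][1:10, ]
  res <- pan_type_enrichment(cand_core, all_cl)
  expect_equal(res$prop_candidate[res$category == "core"], 1)
  expect_lt(res$p_enrichment[res$category == "core"], 0.01)
  expect_error(pan_type_enrichment(all_cl[0, ], all_cl))
})
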