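two_block_cm <- function() {
  M <- matrix(0, 6, 6)
  M[1:3, 1:3] <- 1
  M[4:6, 4:6] <- 1
  contact_matrix(M, bin_size = 10)
}

test_that("insulation score reads off single-cell windows on a two-block matrix", {
  tr <- insulation_score(two_block_cm(), w = 1)
  expect_equal(tr$insulation[2:5], c(1, 0, 0, 1))
  expect_true(all(is.na(tr$insulation[c(1, 6)])))
  flat <- insulation_score(contact_matrix(matrix(1, 8, 8), bin_size = 10),
                           w = 2)
  expect_equal(unique(flat$insulation[flat$valid]), 1)
  expect_error(insulation_score(contact_matrix(matrix(0, 8, 8),
                                               bin_size = 10), 2))
})

test_that("insulation equals the brute-force double loop on random matrices", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    A <- matrix(rpois(n * n, 4), n, n)
    M <- A + t(A)
    w <- sample(1:3, 1)
    tr <- insulation_score(contact_matrix(M, bin_size = 1000), w = w)
    expect_equal(tr$insulation, brute_insulation(M, w))
  }
})

test_that("li threshold separates modes, matches the reference value and scales", {
  t1 <- li_threshold(c(1, 1, 1, 9, 9, 9))
  expect_gt(t1, 1)
  expect_lt(t1, 9)
  # frozen from scikit-image 0.26 threshold_li on the identical sample:
  #   set.seed(42); x <- c(rnorm(100, 1, 0.1), rnorm(100, 10, 0.1))
  set.seed(42)
  x <- c(rnorm(100, 1, 0.1), rnorm(100, 10, 0.1))
  expect_equal(li_threshold(x), 3.325328495675896, tolerance = 1e-9)
  expect_gt(li_threshold(x), 2)
  expect_lt(li_threshold(x), 9)
  expect_equal(li_threshold(2 * x), 2 * li_threshold(x), tolerance = 1e-6)
  expect_error(li_threshold(rep(3, 10)))
})

test_that("boundary calling finds block junctions and merges plateau bins", {
  b <- call_boundaries(insulation_score(two_block_cm(), w = 1))
  expect_equal(nrow(b), 1)
  expect_equal(c(b$start, b$end), c(20, 40))
  expect_true(b$passes_threshold)

  # monotone track: no local minima
  n <- 12
  A <- outer(1:n, 1:n, function(i, j) 100 - abs(i - j))
  mono <- insulation_score(contact_matrix(A, bin_size = 10), w = 2)
  expect_true(all(diff(mono$insulation[mono$valid]) > -1e-9) ||
                nrow(call_boundaries(mono)) == 0)

  tads <- simulate_tads(4e6, 10, 40000, seed = 3)
  cm <- simulate_contact_matrix(tads, within = 5, between = 1,
                                noise = "none")
  bb <- call_boundaries(insulation_score(cm, w = 2))
  bb <- bb[bb$passes_threshold, ]
  expect_equal(nrow(bb), 9)
  junctions <- utils::head(tads$end, -1)
  expect_true(all(vapply(junctions, function(j) {
    any(bb$start <= j & bb$end >= j)
  }, logical(1))))
})

test_that("TADs are the spans between boundaries, ends flagged partial", {
  b <- tibble::tibble(chrom = "chr1", start = c(80000, 400000),
                      end = c(160000, 440000),
                      passes_threshold = TRUE)
  tads <- call_tads(b, 1e6)
  expect_equal(nrow(tads), 3)
  expect_equal(tads$start, c(0, 160000, 440000))
  expect_equal(tads$end, c(80000, 400000, 1e6))
  expect_equal(tads$partial, c(TRUE, FALSE, TRUE))

  none <- call_tads(b[0, ], 1e6, chrom = "chr1")
  expect_equal(nrow(none), 1)
  expect_true(none$partial)

  for (k in 1:5) {
    bk <- tibble::tibble(chrom = "chr1", start = (1:k) * 1e5,
                         end = (1:k) * 1e5 + 4e4)
    expect_equal(nrow(call_tads(bk, 1e6)), k + 1)
  }
})

test_that("compartment eigenvector splits a two-block pattern and obeys sign conventions", {
  lab <- rep(c(1, -1), times = c(10, 10))
  B <- outer(lab, lab, function(a, b) ifelse(a == b, 5, 1)) + diag(2, 20)
  cm <- contact_matrix(B, bin_size = 1e5)
  cc <- call_compartments(cm, orientation_track = lab)
  expect_equal(cc$bins$compartment, ifelse(lab > 0, "A", "B"))
  expect_equal(nrow(cc$compartments), 2)

  flipped <- call_compartments(cm, orientation_track = -lab)
  expect_equal(flipped$bins$compartment, ifelse(lab > 0, "B", "A"))

  scaled <- call_compartments(contact_matrix(7 * B, bin_size = 1e5), lab)
  expect_equal(scaled$bins$compartment, cc$bins$compartment)
})

test_that("map resolution picks the smallest qualifying bin size", {
  tab <- tibble::tibble(
    bin_size = c(10000, 20000),
    bin_totals = list(c(rep(2000, 70), rep(10, 30)),    # 70% pass
                      c(rep(2000, 85), rep(10, 15))))   # 85% pass
  expect_equal(estimate_map_resolution(tab), 20000)
  all_pass <- tibble::tibble(bin_size = c(10000, 20000),
                             bin_totals = list(rep(2000, 10),
                                               rep(2000, 5)))
  expect_equal(estimate_map_resolution(all_pass), 10000)
  exactly80 <- tibble::tibble(bin_size = 5000,
                              bin_totals = list(c(rep(1500, 8),
                                                  rep(10, 2))))
  expect_equal(estimate_map_resolution(exactly80), 5000)
  none <- tibble::tibble(bin_size = c(10000, 20000),
                         bin_totals = list(rep(1, 10), rep(1, 5)))
  expect_warning(res <- estimate_map_resolution(none))
  expect_equal(res, 20000)
})

test_that("LT-CREs need TSS distance and anchor support", {
  genes <- toy_genes()
  peaks <- intervals("chr1", c(5000, 10500, 30000, 70000),
                     c(5400, 10900, 30500, 70400))
  anchors <- intervals("chr1", c(4800, 10000, 29900), c(5600, 11000, 30600))
  lt <- identify_ltcres(peaks, anchors, genes)
  # peak2 is 1.5 kb from gA's TSS; peak4 has no anchor
  expect_equal(lt$start, c(5000, 30000))
  expect_true(all(lt$dist_tss >= 2000))
  expect_true(all(lt$n_anchors >= 1))
})

test_that("loop typing labels anchors E/G with E precedence", {
  genes <- toy_genes()
  ltcres <- intervals("chr1", 5000, 5400)
  mk <- function(s2, e2) {
    tibble::tibble(chrom1 = "chr1", start1 = 4800, end1 = 5600,
                   chrom2 = "chr1", start2 = s2, end2 = e2)
  }
  # anchor2 overlapping [48000,50000), the 2-kb window upstream of gB (+)
  eg <- annotate_loops(mk(47000, 48100), ltcres, genes)
  expect_equal(eg$loop_type, "E-G")
  # anchor2 overlapping another LT-CRE
  ee <- annotate_loops(tibble::tibble(chrom1 = "chr1", start1 = 4800,
                                      end1 = 5600, chrom2 = "chr1",
                                      start2 = 30000, end2 = 30500),
                       intervals("chr1", c(5000, 30000), c(5400, 30400)),
                       genes)
  expect_equal(ee$loop_type, "E-E")
  # anchor overlapping both an LT-CRE and an upstream window stays E
  both <- annotate_loops(mk(47000, 48100),
                         intervals("chr1", c(5000, 47500), c(5400, 47900)),
                         genes)
  expect_equal(both$anchor2_label, "E")
  expect_equal(both$loop_type, "E-E")
  # minus-strand gene: upstream window right of the TSS
  minus <- annotate_loops(tibble::tibble(chrom1 = "chr1", start1 = 4800,
                                         end1 = 5600, chrom2 = "chr1",
                                         start2 = 90500, end2 = 91000),
                          ltcres, genes)
  expect_equal(minus$anchor2_label, "G")   # gC TSS at 89999, "-" strand
  # no annotation at all
  none <- annotate_loops(mk(200000, 201000), ltcres, genes)
  expect_equal(none$loop_type, "unannotated")
})

test_that("TAD reorganization labels stable, fusion, neo", {
  ref <- intervals("chr1", c(0, 100000), c(100000, 200000))
  fusion <- classify_tad_reorganization(ref, intervals("chr1", 0, 200000))
  expect_equal(fusion$reorg, "fusion")
  stable <- classify_tad_reorganization(intervals("chr1", 0, 100000),
                                        intervals("chr1", 0, 98000))
  expect_equal(stable$reorg, "stable")
  neo <- classify_tad_reorganization(ref, intervals("chr1", 3e5, 4e5))
  expect_equal(neo$reorg, "neo")
})

test_that("boundary activity recovers separated groups, ordered by ATAC", {
  set.seed(5)
  b <- intervals("chr1", (1:30) * 1e6, (1:30) * 1e6 + 40000)
  grp <- rep(1:3, each = 10)
  atac <- intervals("chr1", b$start, b$end,
                    score = c(100, 10, 1)[grp] + rnorm(30, 0, 0.5))
  genes <- gene_table("chr1", b$start + 1000, b$start + 5000, "+",
                      sprintf("g%d", 1:30))
  genes$expression <- c(50, 5, 0.5)[grp] + rnorm(30, 0, 0.2)
  act <- classify_boundary_activity(b, atac, genes, seed = 1)
  expect_equal(act$activity, c("active", "neutral",
                               "inactive")[grp])
  # permuting the input order leaves per-boundary labels unchanged
  perm <- sample(30)
  act2 <- classify_boundary_activity(b[perm, ], atac, genes, seed = 1)
  expect_equal(act2$activity[order(perm)], act$activity)
  expect_error(classify_boundary_activity(b[1:2, ], atac, genes))
})
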