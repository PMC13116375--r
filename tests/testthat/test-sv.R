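sv_row <- function(chrom, start, end, type, size, genome) {
  tibble::tibble(chrom = chrom, start = start, end = end, sv_type = type,
                 size = size, genome_id = genome)
}

test_that("SV merging follows the distance/type/size rules", {
  pair <- dplyr::bind_rows(sv_row("chr1", 1000, 2000, "DEL", 1000, "G1"),
                           sv_row("chr1", 1300, 2300, "DEL", 1000, "G2"))
  m <- merge_svs(pair)
  expect_equal(nrow(m), 1)
  expect_equal(m$support, 2L)

  mixed <- dplyr::bind_rows(sv_row("chr1", 1000, 2000, "DEL", 1000, "G1"),
                            sv_row("chr1", 1000, 2000, "INS", 1000, "G2"))
  expect_equal(nrow(merge_svs(mixed)), 2)

  small <- sv_row("chr1", 1000, 1040, "DEL", 40, "G1")
  expect_equal(nrow(merge_svs(small)), 0)

  far <- dplyr::bind_rows(sv_row("chr1", 1000, 2000, "DEL", 1000, "G1"),
                          sv_row("chr1", 2100, 3100, "DEL", 1000, "G2"))
  expect_equal(nrow(merge_svs(far)), 2)   # start distance 1100 > 1000
})

test_that("SV merging is order-invariant and partitions the input", {
  set.seed(13)
  for (rep in 1:10) {
    n <- 40
    starts <- sample(seq(0, 1e6, by = 100), n)
    svs <- sv_row("chr1", starts, starts + 500,
                  sample(c("DEL", "INS", "DUP"), n, replace = TRUE), 500,
                  sample(sprintf("G%d", 1:5), n, replace = TRUE))
    m1 <- merge_svs(svs)
    m2 <- merge_svs(svs[sample(n), ])
    expect_equal(m1[c("chrom", "start", "end", "sv_type")],
                 m2[c("chrom", "start", "end", "sv_type")])
    expect_equal(sum(m1$n_members), n)
  }
})

test_that("mechanism rules fire in fixed order on worked examples", {
  base <- tibble::tibble(chrom = "chr1", start = 0, end = 1000,
                         sv_type = "DEL", size = 1000, genome_id = "G1",
                         te_cov = 0.1, te_family = NA_character_,
                         tr_cov = 0.1, flank_hom = 0, microhom = 0,
                         templated_switch = FALSE)
  cases <- list(
    list(mut = list(tr_cov = 0.9), want = "VNTR"),
    list(mut = list(te_cov = 0.95, te_family = "LTR/ERV"), want = "TEI"),
    list(mut = list(), want = "NHEJ"),
    list(mut = list(flank_hom = 150), want = "NAHR"),
    list(mut = list(templated_switch = TRUE), want = "FoSTeS_MMBIR"),
    list(mut = list(microhom = 10), want = "alt_EJ"),
    list(mut = list(microhom = 25), want = "unassigned"),
    # priority: VNTR beats TEI beats NAHR
    list(mut = list(tr_cov = 0.9, te_cov = 0.9, te_family = "SINE",
                    flank_hom = 500), want = "VNTR"))
  for (cs in cases) {
    row <- base
    for (nm in names(cs$mut)) row[[nm]] <- cs$mut[[nm]]
    expect_equal(classify_sv_mechanism(row)$mechanism, cs$want)
  }
  no_junction <- base[setdiff(names(base), "microhom")]
  res <- classify_sv_mechanism(no_junction)
  expect_equal(res$mechanism, "unassigned")
  expect_equal(res$rule_fired, "missing_junction")
})

test_that("planted mechanisms are recovered exactly, no spurious NAHR", {
  sim <- simulate_pan_dataset(sim_config(n_genomes = 10,
                                         n_gene_families = 20,
                                         n_boundaries = 5, n_ltcres = 10,
                                         n_loops = 5, n_svs = 60,
                                         seed = 9))
  svs <- sim$features$sv
  called <- classify_sv_mechanism(svs)
  expect_equal(called$mechanism, svs$mechanism_truth)
  low_hom <- called[called$flank_hom < 100, ]
  expect_false(any(low_hom$mechanism == "NAHR"))
})

test_that("hotspot threshold is mean + 2 sd of window counts", {
  gen <- genome_coords("chr1", 1e6)
  # nine windows with one breakpoint pair and one with twenty: plant SV
  # midpoints so both ends of each record fall in one window
  svs <- dplyr::bind_rows(
    intervals("chr1", seq(0, 8) * 1e5 + 100, seq(0, 8) * 1e5 + 300),
    intervals("chr1", rep(9e5 + 100, 10), rep(9e5 + 300, 10)))
  h <- sv_hotspots(svs, gen, window = 1e5, step = 1e5)
  counts <- h$n_breakpoints
  expect_equal(sort(unique(counts)), c(2, 20))
  s <- sqrt(mean((counts - mean(counts))^2))
  expect_equal(attr(h, "threshold"), mean(counts) + 2 * s)
  expect_equal(sum(h$hotspot), 1)
  expect_equal(h$start[h$hotspot], 9e5)

  uniform <- intervals("chr1", seq(0, 9) * 1e5 + 100,
                       seq(0, 9) * 1e5 + 300)
  expect_equal(sum(sv_hotspots(uniform, gen)$hotspot), 0)
  empty <- intervals("chr1", 1, 2)[0, ]
  expect_equal(sum(sv_hotspots(empty, gen)$hotspot), 0)
})

test_that("SV-gene pairing uses a 5-kb breakpoint flank", {
  genes <- gene_table("chr1", c(15000, 20000, 11000),
                      c(20000, 30000, 11500), "+",
                      c("near", "far", "inside"))
  sv <- intervals("chr1", 10000, 12000)
  pairs <- annotate_sv_genes(sv, genes)
  expect_setequal(pairs$gene_id, c("near", "inside"))
  # gap from end breakpoint 11999 to gene "near" start 15000 is 3001 bp;
  # "far" starts 8001 bp away
  expect_false("far" %in% pairs$gene_id)
})

test_that("genotype filter matches the worked example and a brute force", {
  tab <- tibble::tibble(site_id = "s1",
                        sample_id = sprintf("i%d", 1:4),
                        gt = c(1, 0, 1, 0),
                        dp = c(3, 3, 1, 3), gq = rep(20, 4))
  res <- filter_genotyped_svs(tab)
  expect_equal(res$sites$missing_frac, 0.25)
  expect_equal(res$sites$maf, 1 / 6, tolerance = 1e-12)
  expect_true(res$sites$kept)

  mostly_missing <- tab
  mostly_missing$dp <- c(3, 1, 1, 1)
  expect_false(filter_genotyped_svs(mostly_missing)$sites$kept)

  monomorphic <- tab
  monomorphic$gt <- 0
  expect_false(filter_genotyped_svs(monomorphic)$sites$kept)

  set.seed(99)
  for (rep in 1:100) {
    n <- sample(4:20, 1)
    g <- tibble::tibble(site_id = "x", sample_id = sprintf("i%d", 1:n),
                        gt = sample(0:2, n, replace = TRUE),
                        dp = sample(0:10, n, replace = TRUE),
                        gq = sample(0:30, n, replace = TRUE))
    got <- filter_genotyped_svs(g)$sites$kept
    keep_call <- g$dp > 2 & g$gq > 10
    miss <- mean(!keep_call)
    want <- FALSE
    if (miss <= 0.5 && any(keep_call)) {
      p <- sum(g$gt[keep_call]) / (2 * sum(keep_call))
      want <- min(p, 1 - p) >= 0.05
    }
    expect_equal(got, want)
  }
})

test_that("SV VCF IO round-trips records and genotypes", {
  path <- withr::local_tempfile(fileext = ".vcf")
  gt <- tibble::tibble(sample = c("s1", "s2"), gt = c("0/1", "1/1"),
                       dp = c(10, 20), gq = c(30, 40))
  svs <- tibble::tibble(chrom = "chr1", start = 100, end = 600,
                        sv_type = "DEL", size = 500, id = "sv1",
                        genotypes = list(gt))
  write_sv_vcf(svs, path)
  back <- read_sv_vcf(path)
  expect_equal(back$start, 100)
  expect_equal(back$end, 600)
  expect_equal(back$size, 500)
  expect_equal(back$genotypes[[1]]$gq, c(30, 40))
})
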