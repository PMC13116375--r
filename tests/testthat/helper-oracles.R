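# Independent brute-force oracles used to cross-check the package's
# implementations. Written deliberately in the most literal style possible
# and kept free of package internals.

# per-base boolean union coverage (targets up to ~10 kb)
brute_coverage_fraction <- function(target, features) {
  covered <- rep(FALSE, target$end - target$start)
  for (i in seq_len(nrow(features))) {
    if (features$chrom[i] != target$chrom) next
    lo <- max(features$start[i], target$start)
    hi <- min(features$end[i], target$end)
    if (hi > lo) covered[(lo - target$start + 1):(hi - target$start)] <- TRUE
  }
  mean(covered)
}

# double-loop diamond window mean
brute_insulation <- function(M, w) {
  n <- nrow(M)
  out <- rep(NA_real_, n)
  for (b in seq_len(n)) {
    if (b - w < 1 || b + w > n) next
    vals <- c()
    for (i in (b - w):(b - 1)) for (j in (b + 1):(b + w)) {
      vals <- c(vals, M[i, j])
    }
    out[b] <- mean(vals)
  }
  out
}

# literal transcription of the Weir & Cockerham (1984) two-population
# variance components from allele counts, looped site by site
brute_wc_fst <- function(g1, g2) {
  r <- 2
  theta <- numeric(nrow(g1))
  for (s in seq_len(nrow(g1))) {
    x <- list(g1[s, ][!is.na(g1[s, ])], g2[s, ][!is.na(g2[s, ])])
    n_i <- vapply(x, length, numeric(1))
    p_i <- vapply(x, function(v) sum(v) / (2 * length(v)), numeric(1))
    h_i <- vapply(x, function(v) sum(v == 1) / length(v), numeric(1))
    n_bar <- sum(n_i) / r
    n_c <- (r * n_bar - sum(n_i^2) / (r * n_bar)) / (r - 1)
    p_bar <- sum(n_i * p_i) / (r * n_bar)
    s_sq <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
    h_bar <- sum(n_i * h_i) / (r * n_bar)
    if (p_bar <= 0 || p_bar >= 1) { theta[s] <- NA; next }
    a <- (n_bar / n_c) *
      (s_sq - (1 / (n_bar - 1)) *
         (p_bar * (1 - p_bar) - ((r - 1) / r) * s_sq - (1 / 4) * h_bar))
    b <- (n_bar / (n_bar - 1)) *
      (p_bar * (1 - p_bar) - ((r - 1) / r) * s_sq -
         ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
    cc <- h_bar / 2
    theta[s] <- a / (a + b + cc)
  }
  theta
}

# exhaustive pairwise haplotype difference counting
brute_pi <- function(dosages) {
  haps <- unlist(lapply(dosages[!is.na(dosages)], function(d) {
    if (d == 0) c(0, 0) else if (d == 1) c(0, 1) else c(1, 1)
  }))
  n <- length(haps)
  if (n < 2) return(NA_real_)
  diffs <- 0; pairs <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    pairs <- pairs + 1
    if (haps[i] != haps[j]) diffs <- diffs + 1
  }
  diffs / pairs
}

# shared small fixture: genes with TSSs on both strands
toy_genes <- function() {
  gene_table(chrom = "chr1",
             start = c(9000, 50000, 80000),
             end = c(12000, 60000, 90000),
             strand = c("+", "+", "-"),
             gene_id = c("gA", "gB", "gC"))
}
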