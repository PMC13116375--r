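# Conservation classification across genomes: core / softcore / dispensable
# / private categories for any feature kind, interval and loop clustering on
# the backbone, pan/core accumulation curves, compartment status comparison.

#' Pan-category from presence count
#'
#' Mutually exclusive categories over `n` genomes: `core` when present in
#' all; `softcore` when present in at least 90% but not all; `private` when
#' present in exactly one; `dispensable` otherwise. Vectorised over `c`.
#'
#' @param c Presence counts (number of genomes carrying the feature).
#' @param n Total number of genomes.
#' @return Factor with levels core, softcore, dispensable, private.
#' @examples
#' classify_pan_category(c(15, 14, 7, 1), 15)
#' @export
classify_pan_category <- function(c, n) {
  if (any(c < 1 | c > n)) abort("presence count must be in [1, n]")
  out <- ifelse(c == n, "core",
                ifelse(c / n >= 0.9, "softcore",
                       ifelse(c == 1, "private", "dispensable")))
  factor(out, levels = c("core", "softcore", "dispensable", "private"))
}

#' Cluster backbone-lifted intervals into pan-feature clusters
#'
#' Pools intervals from all genomes (already lifted to the backbone), merges
#' them with [merge_with_gap()] at the feature kind's gap (40 kb for TAD
#' boundaries, 500 bp for LT-CREs), and classifies each merged cluster by
#' the number of distinct genomes contributing at least one member.
#' Unmapped rows (a `mapped` column that is FALSE) are excluded and counted.
#'
#' @param features Interval tibble with a `genome_id` column.
#' @param n_genomes Total genome count `n` (defaults to the number of
#'   distinct `genome_id` values observed).
#' @param max_gap Merge gap in bp.
#' @param kind Feature kind label carried into the output.
#' @return Tibble of clusters: `cluster_id`, `kind`, `chrom`, `start`,
#'   `end`, `presence_count`, `n_genomes`, `category`, `genome_ids` (list),
#'   plus attribute `n_unmapped`.
#' @export
cluster_lifted_intervals <- function(features, n_genomes = NULL,
                                     max_gap = 40000, kind = "feature") {
  n_unmapped <- 0L
  if ("mapped" %in% names(features)) {
    n_unmapped <- sum(!features$mapped)
    features <- features[features$mapped, ]
  }
  if (!"genome_id" %in% names(features)) {
    abort("features need a genome_id column")
  }
  n_genomes <- n_genomes %||% dplyr::n_distinct(features$genome_id)
  merged <- merge_with_gap(features, max_gap)
  merged$presence_count <- map_int(merged$genome_ids,
                                   \(g) length(unique(g)))
  out <- merged |>
    mutate(cluster_id = sprintf("%s_%05d", kind, dplyr::row_number()),
           kind = kind, n_genomes = n_genomes,
           category = classify_pan_category(.data$presence_count,
                                            n_genomes)) |>
    select("cluster_id", "kind", "chrom", "start", "end", "presence_count",
           "n_genomes", "category", "genome_ids", "members")
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Cluster chromatin loops across genomes
#'
#' Two loops are linked when both anchor pairs correspond: anchor1 with
#' anchor1 and anchor2 with anchor2, each with
#' [reciprocal_overlap_fraction()] strictly greater than `min_frac`.
#' Clusters are the connected components of the link graph (single
#' linkage); each cluster's category comes from the number of distinct
#' genomes represented. Loops with an unmapped anchor (a `mapped` column
#' that is FALSE) are excluded and counted.
#'
#' @param loops Loop tibble (BEDPE columns) with `genome_id`.
#' @param n_genomes Total genome count.
#' @param min_frac Overlap fraction threshold (strict `>`, default 0.5).
#' @return Tibble of loop clusters with envelope anchors, `presence_count`,
#'   `category` and member indices; attribute `n_unmapped`.
#' @export
cluster_loops <- function(loops, n_genomes = NULL, min_frac = 0.5) {
  n_unmapped <- 0L
  if ("mapped" %in% names(loops)) {
    n_unmapped <- sum(!loops$mapped)
    loops <- loops[loops$mapped, ]
  }
  validate_loops(loops)
  if (!"genome_id" %in% names(loops)) abort("loops need a genome_id column")
  n_genomes <- n_genomes %||% dplyr::n_distinct(loops$genome_id)
  n <- nrow(loops)
  comp <- seq_len(n)           # union-find over loop indices
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  c1 <- loops$chrom1; s1 <- loops$start1; e1 <- loops$end1
  c2 <- loops$chrom2; s2 <- loops$start2; e2 <- loops$end2
  w1 <- e1 - s1; w2 <- e2 - s2
  # candidate pairs: anchor1 overlap by sort-and-sweep per chromosome,
  # fractions computed on plain vectors (same arithmetic as
  # reciprocal_overlap_fraction, cross-checked in the tests)
  ord <- order(c1, s1)
  for (u in seq_len(max(n - 1, 0))) {
    i <- ord[u]
    for (v in (u + 1):n) {
      j <- ord[v]
      if (c1[j] != c1[i]) break
      if (s1[j] >= e1[i]) break  # sorted: no anchor1 overlap further on
      f1 <- (min(e1[i], e1[j]) - max(s1[i], s1[j])) / min(w1[i], w1[j])
      if (f1 <= min_frac) next
      if (c2[i] != c2[j]) next
      ov2 <- min(e2[i], e2[j]) - max(s2[i], s2[j])
      if (ov2 / min(w2[i], w2[j]) > min_frac) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) comp[ri] <- rj
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  loops$cluster <- match(root, unique(root))
  out <- loops |>
    group_by(.data$cluster) |>
    summarise(chrom1 = dplyr::first(.data$chrom1),
              start1 = min(.data$start1), end1 = max(.data$end1),
              chrom2 = dplyr::first(.data$chrom2),
              start2 = min(.data$start2), end2 = max(.data$end2),
              presence_count = dplyr::n_distinct(.data$genome_id),
              n_members = dplyr::n(),
              genome_ids = list(unique(.data$genome_id)),
              .groups = "drop") |>
    mutate(cluster_id = sprintf("loop_%05d", .data$cluster),
           kind = "loop", n_genomes = n_genomes,
           category = classify_pan_category(.data$presence_count,
                                            n_genomes)) |>
    select(-"cluster")
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Presence matrix from cluster membership
#'
#' @param clusters Cluster tibble with a `genome_ids` list column.
#' @param genomes Character vector of all genome ids (columns).
#' @return Logical matrix, rows = clusters, columns = genomes.
#' @export
presence_matrix <- function(clusters, genomes) {
  pm <- vapply(genomes, \(g) map_lgl_(clusters$genome_ids, g),
               logical(nrow(clusters)))
  pm <- matrix(pm, nrow = nrow(clusters),
               dimnames = list(clusters$cluster_id, genomes))
  if (nrow(pm) && any(rowSums(pm) == 0)) {
    abort("presence matrix rows must have at least one present genome")
  }
  pm
}

map_lgl_ <- function(lst, g) vapply(lst, \(x) g %in% x, logical(1))

#' Pan/core accumulation curves
#'
#' For each of `n_orders` random genome orderings, the pan size at step k is
#' the number of clusters present in at least one of the first k genomes,
#' and the core size the number present in all first k. Pan curves are
#' non-decreasing and core curves non-increasing in k by construction.
#'
#' @param pm Logical presence matrix (clusters x genomes).
#' @param n_orders Number of random orders.
#' @param seed RNG seed.
#' @return Tibble `order_id, k, pan, core`.
#' @export
accumulation_curves <- function(pm, n_orders = 100, seed = 1) {
  n <- ncol(pm)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  map(seq_len(n_orders), function(o) {
    ord <- sample(n)
    pan_seen <- rep(FALSE, nrow(pm))
    core_seen <- rep(TRUE, nrow(pm))
    res <- map(seq_len(n), function(k) {
      pan_seen <<- pan_seen | pm[, ord[k]]
      core_seen <<- core_seen & pm[, ord[k]]
      tibble(order_id = o, k = k, pan = sum(pan_seen),
             core = sum(core_seen))
    })
    list_rbind(res)
  }) |>
    list_rbind()
}

#' Compare compartment status across genomes
#'
#' Regions with the same A/B status in every genome where they are mappable
#' are conservative (A or B); any disagreement makes them variable. Regions
#' missing (NA) in more than half the genomes are flagged and excluded.
#'
#' @param status_matrix Character matrix of "A"/"B"/NA, rows = orthologous
#'   regions, columns = genomes.
#' @return Tibble `region, n_called, pan_status` where `pan_status` is
#'   conservative_A, conservative_B, variable or excluded.
#' @export
compare_compartment_status <- function(status_matrix) {
  n <- ncol(status_matrix)
  res <- map_chr(seq_len(nrow(status_matrix)), function(i) {
    s <- status_matrix[i, ]
    called <- s[!is.na(s)]
    if (length(called) < n / 2) return("excluded")
    if (all(called == "A")) return("conservative_A")
    if (all(called == "B")) return("conservative_B")
    "variable"
  })
  tibble(region = rownames(status_matrix) %||%
           as.character(seq_len(nrow(status_matrix))),
         n_called = rowSums(!is.na(status_matrix)),
         pan_status = res)
}
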