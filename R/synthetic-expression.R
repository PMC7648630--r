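#' Generate a clustered UMI matrix with planted detection fractions
#'
#' Synthetic stand-in for a droplet scRNA-seq count matrix: for every
#' (cluster, gene), each cell is detected (UMI > 0) with a Bernoulli
#' probability — the background rate by default, or a planted rate where one
#' is given — and detected cells receive a shifted-Poisson count
#' `1 + Poisson(lambda)`. Deterministic given `rng_seed`.
#'
#' @param n_clusters number of clusters (labelled C1, C2, ...).
#' @param cells_per_cluster cells per cluster.
#' @param genes character vector of gene symbols, or a gene count (labelled
#'   G1, G2, ...).
#' @param planted data frame with columns `cluster`, `gene`,
#'   `detection_rate` overriding the background for those cells; rates must
#'   lie in \[0, 1\].
#' @param rng_seed integer seed.
#' @param background_rate detection rate where nothing is planted
#'   (default 0.05).
#' @param lambda Poisson mean of the count excess over 1 (default 1).
#' @return An [expression_matrix()].
#' @export
generate_synthetic_expression <- function(n_clusters, cells_per_cluster,
                                          genes,
                                          planted = NULL, rng_seed = 0L,
                                          background_rate = 0.05,
                                          lambda = 1) {
  n_clusters <- assert_count(n_clusters, "n_clusters", min = 1L)
  cells_per_cluster <- assert_count(cells_per_cluster, "cells_per_cluster",
                                    min = 1L)
  if (is.numeric(genes) && length(genes) == 1L) {
    genes <- paste0("G", seq_len(genes))
  }
  genes <- toupper(as.character(genes))
  if (!is.null(planted)) {
    if (!all(c("cluster", "gene", "detection_rate") %in% names(planted))) {
      stop_validation("planted needs columns cluster, gene, detection_rate")
    }
    if (any(planted$detection_rate < 0 | planted$detection_rate > 1)) {
      stop_validation("planted detection rates must be in [0, 1]")
    }
  }
  cluster_labels <- paste0("C", seq_len(n_clusters))
  rates <- matrix(background_rate, n_clusters, length(genes),
                  dimnames = list(cluster_labels, genes))
  if (!is.null(planted)) {
    for (i in seq_len(nrow(planted))) {
      rates[as.character(planted$cluster[i]),
            toupper(as.character(planted$gene[i]))] <-
        planted$detection_rate[i]
    }
  }
  counts <- with_rng_seed(rng_seed, {
    m <- matrix(0L, n_clusters * cells_per_cluster, length(genes))
    for (ci in seq_len(n_clusters)) {
      rows <- ((ci - 1L) * cells_per_cluster + 1L):(ci * cells_per_cluster)
      n <- cells_per_cluster * length(genes)
      det <- rbinom(n, 1L, rep(rates[ci, ], each = cells_per_cluster))
      m[rows, ] <- det * (1L + rpois(n, lambda))
    }
    m
  })
  rownames(counts) <- paste0("cell", seq_len(nrow(counts)))
  colnames(counts) <- genes
  expression_matrix(counts,
                    rep(cluster_labels, each = cells_per_cluster))
}
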