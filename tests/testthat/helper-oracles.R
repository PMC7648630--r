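# Independent oracles and fixture builders. Each oracle is a deliberately
# naive re-derivation (brute force / direct formula) of the quantity the
# implementation computes by a different route.

# Otsu: exhaustive search over all 256 candidate thresholds, between-class
# variance computed from class weights and means by the textbook definition.
otsu_bruteforce <- function(counts) {
  stopifnot(length(counts) == 256)
  levels <- 0:255
  n <- sum(counts)
  best_t <- NA_integer_
  best_v <- -Inf
  for (t in 0:254) {
    c0 <- counts[levels <= t]
    c1 <- counts[levels > t]
    n0 <- sum(c0); n1 <- sum(c1)
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(levels[levels <= t] * c0) / n0
    mu1 <- sum(levels[levels > t] * c1) / n1
    v <- (n0 / n) * (n1 / n) * (mu0 - mu1)^2
    if (v > best_v + 1e-12) {  # strict improvement: lowest tie wins
      best_v <- v
      best_t <- t
    }
  }
  best_t
}

# Binary morphology by direct neighborhood loops on small matrices.
morph_bruteforce <- function(mat, radius, op, pad_value) {
  h <- nrow(mat); w <- ncol(mat)
  out <- matrix(0L, h, w)
  agg <- if (op == "dilate") max else min
  for (i in seq_len(h)) for (j in seq_len(w)) {
    vals <- integer(0)
    for (dy in -radius:radius) for (dx in -radius:radius) {
      if (dy * dy + dx * dx > radius * radius) next
      ii <- i + dy; jj <- j + dx
      v <- if (ii < 1 || ii > h || jj < 1 || jj > w) pad_value
           else mat[ii, jj]
      vals <- c(vals, v)
    }
    out[i, j] <- agg(vals)
  }
  out
}

closing_bruteforce <- function(mat, radius) {
  morph_bruteforce(morph_bruteforce(mat, radius, "dilate", 0L),
                   radius, "erode", 1L)
}

# Crosstalk: exhaustive triple loop over clusters x clusters x pairs.
graph_bruteforce <- function(sets, pairs, self_loops = TRUE) {
  out <- list()
  for (a in names(sets)) for (b in names(sets)) {
    if (!self_loops && a == b) next
    w <- 0L
    for (k in seq_len(nrow(pairs))) {
      if (pairs$ligand[k] %in% sets[[a]] &&
          pairs$receptor[k] %in% sets[[b]]) {
        w <- w + 1L
      }
    }
    if (w > 0L) out[[paste(a, b, sep = "->")]] <- w
  }
  out
}

graph_as_weights <- function(graph) {
  w <- as.list(graph$edges$weight)
  names(w) <- paste(graph$edges$source, graph$edges$target, sep = "->")
  w[order(names(w))]
}

# Random expressed-set instance for the graph oracle.
random_graph_instance <- function(seed, n_clusters = 10, n_genes = 50,
                                  n_pairs = 20) {
  set.seed(seed)
  genes <- paste0("G", seq_len(n_genes))
  sets <- lapply(seq_len(n_clusters), function(i) {
    sample(genes, rbinom(1, n_genes, 0.3))
  })
  names(sets) <- paste0("C", seq_len(n_clusters))
  pairs <- unique(data.frame(ligand = sample(genes, n_pairs, replace = TRUE),
                             receptor = sample(genes, n_pairs,
                                               replace = TRUE),
                             stringsAsFactors = FALSE))
  class(pairs) <- c("lr_pair_table", "data.frame")
  list(sets = sets, pairs = pairs)
}

# Welch p value by quadrature of the t density written from first
# principles (no pt()); t and df also from the direct formulas.
welch_bruteforce <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  dens <- function(x) {
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df * pi) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  p <- 2 * integrate(dens, abs(tstat), Inf, rel.tol = 1e-12)$value
  list(t = tstat, df = df, p = p)
}

# Holm-Sidak decisions by a literal reading of the step-down inequalities.
holm_sidak_bruteforce <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  rejected <- logical(m)
  for (i in seq_len(m)) {
    idx <- ord[i]
    crit <- 1 - (1 - alpha)^(1 / (m - i + 1))
    if (p[idx] <= crit) {
      rejected[idx] <- TRUE
    } else {
      break
    }
  }
  rejected
}

# Small deterministic expression matrix: one cluster with an exact number
# of detected cells for one gene.
exact_detection_matrix <- function(n_cells, n_detected, gene = "LIG1") {
  counts <- matrix(0L, n_cells, 2,
                   dimnames = list(paste0("cell", seq_len(n_cells)),
                                   c(gene, "OTHER")))
  if (n_detected > 0) counts[seq_len(n_detected), 1] <- 1L
  counts[, 2] <- 1L
  expression_matrix(counts, rep("C1", n_cells))
}

noise_free_lattice_image <- function(airspace_side, wall = 5, px = 1,
                                     cells = 10) {
  g <- generate_lattice(lattice_spec(airspace_side, wall, px, cells, cells))
  list(gen = g,
       image = render_grayscale(g$mask, render_spec(220, 60, 0, 1)))
}
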