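#' Construct a cluster-labeled expression matrix
#'
#' @param counts cells x genes matrix of non-negative integer UMI counts
#'   (dense or `Matrix` sparse); rownames = cell ids, colnames = gene
#'   symbols.
#' @param clusters character/factor vector of cluster labels, one per cell.
#' @return An `expression_matrix` list with `counts` (cells x genes,
#'   symbols uppercased), `cluster_of` (named character vector) and
#'   `clusters` (sorted unique labels).
#' @export
expression_matrix <- function(counts, clusters) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_validation("counts needs cell rownames and gene colnames")
  }
  if (length(clusters) != nrow(counts)) {
    stop_validation("one cluster label per cell required: ", nrow(counts),
                    " cells vs ", length(clusters), " labels")
  }
  if (anyNA(clusters)) stop_validation("NA cluster labels not allowed")
  if (min(counts) < 0) stop_validation("UMI counts must be >= 0")
  colnames(counts) <- toupper(colnames(counts))
  if (anyDuplicated(colnames(counts))) {
    stop_validation("gene symbols must be unique after uppercasing: ",
                    paste(unique(colnames(counts)[
                      duplicated(colnames(counts))]), collapse = ", "))
  }
  structure(list(counts = counts,
                 cluster_of = setNames(as.character(clusters),
                                       rownames(counts)),
                 clusters = sort(unique(as.character(clusters)))),
            class = "expression_matrix")
}

#' Load a cluster-labeled UMI matrix from disk
#'
#' Accepts either 10x-style MatrixMarket input (`matrix_path` = .mtx of
#' genes x cells, `genes_path` and `cells_path` = one-column TSVs) or a
#' dense CSV (genes x cells with gene ids in the first column and cell ids
#' as header). `clusters_path` is a CSV with columns `cell_id, cluster`;
#' cells without an assignment are dropped with a message.
#'
#' @param matrix_path MTX or dense CSV path.
#' @param genes_path,cells_path row/column id TSVs (MTX input only).
#' @param clusters_path cluster assignment CSV.
#' @return An [expression_matrix()].
#' @export
load_expression <- function(matrix_path, genes_path = NULL,
                            cells_path = NULL, clusters_path) {
  if (!file.exists(matrix_path)) stop_io("matrix not found: ", matrix_path)
  if (grepl("\\.mtx$", matrix_path, ignore.case = TRUE)) {
    m <- Matrix::readMM(matrix_path)  # genes x cells
    genes <- read.delim(genes_path, header = FALSE,
                        stringsAsFactors = FALSE)[[1L]]
    cells <- read.delim(cells_path, header = FALSE,
                        stringsAsFactors = FALSE)[[1L]]
    if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
      stop_io("dimension mismatch: matrix ", nrow(m), " x ", ncol(m),
              " vs ", length(genes), " genes, ", length(cells), " cells")
    }
    counts <- Matrix::t(m)
    rownames(counts) <- cells
    colnames(counts) <- genes
  } else {
    d <- read.csv(matrix_path, check.names = FALSE,
                  stringsAsFactors = FALSE)
    genes <- d[[1L]]
    counts <- t(as.matrix(d[, -1L, drop = FALSE]))
    colnames(counts) <- genes
  }
  cl <- read.csv(clusters_path, stringsAsFactors = FALSE)
  names(cl)[1:2] <- c("cell_id", "cluster")
  keep <- rownames(counts) %in% cl$cell_id
  if (any(!keep)) {
    message(sum(!keep), " cell(s) without cluster assignment dropped")
  }
  counts <- counts[keep, , drop = FALSE]
  clusters <- cl$cluster[match(rownames(counts), cl$cell_id)]
  expression_matrix(counts, clusters)
}

#' Load a ligand-receptor pair table
#'
#' Two-column TSV (FANTOM5-style) with columns `ligand` and `receptor`
#' (header optional); symbols are uppercased and duplicate pairs dropped.
#'
#' @param path TSV path, or a data frame with two columns.
#' @return An `lr_pair_table` data frame with columns `ligand`, `receptor`.
#' @export
load_lr_pairs <- function(path) {
  d <- if (is.data.frame(path)) path else {
    if (!file.exists(path)) stop_io("pair table not found: ", path)
    first <- read.delim(path, nrows = 1L, header = FALSE,
                        stringsAsFactors = FALSE)
    has_header <- any(tolower(unlist(first)) %in% c("ligand", "receptor"))
    read.delim(path, header = has_header, stringsAsFactors = FALSE)
  }
  if (ncol(d) < 2L) stop_validation("pair table needs two columns")
  out <- data.frame(ligand = toupper(as.character(d[[1L]])),
                    receptor = toupper(as.character(d[[2L]])),
                    stringsAsFactors = FALSE)
  out <- unique(out)
  class(out) <- c("lr_pair_table", "data.frame")
  out
}

#' Per-cluster gene detection fractions
#'
#' `fraction[c, g]` = proportion of cluster c's cells with UMI > 0 for
#' gene g — the quantity the 30 percent expression rule thresholds.
#'
#' @param expr an [expression_matrix()].
#' @return A `detection_profile`: numeric matrix clusters x genes plus the
#'   per-cluster cell counts as attribute `n_cells`.
#' @export
detection_fraction <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  cl <- expr$cluster_of[rownames(expr$counts)]
  sizes <- table(cl)
  if (any(sizes == 0L)) stop_validation("empty cluster")
  detected <- (expr$counts > 0) * 1
  frac <- rowsum(as.matrix(detected), group = cl) /
    as.vector(sizes[sort(unique(cl))])
  frac <- frac[expr$clusters, , drop = FALSE]
  attr(frac, "n_cells") <- as.vector(sizes[expr$clusters])
  class(frac) <- c("detection_profile", class(frac))
  frac
}

#' Per-cluster expressed gene sets under the detection-fraction rule
#'
#' A gene is expressed in a cluster iff its detection fraction is `>=`
#' `threshold` (inclusive: a gene detected in exactly 30 percent of cells
#' qualifies at the default threshold).
#'
#' @param profile a [detection_fraction()] matrix.
#' @param threshold detection-fraction cutoff in (0, 1], default 0.30.
#' @return Named list: cluster -> character vector of expressed genes.
#' @export
expressed_sets <- function(profile, threshold = 0.30) {
  stopifnot(inherits(profile, "detection_profile"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0 ||
      threshold > 1) {
    stop_validation("threshold must be in (0, 1]")
  }
  genes <- colnames(profile)
  out <- lapply(rownames(profile),
                function(cl) genes[profile[cl, ] >= threshold])
  names(out) <- rownames(profile)
  out
}

#' Build the directed cluster-to-cluster crosstalk graph
#'
#' Nodes are clusters; the edge from source A to target B is weighted by the
#' number of ligand-receptor pairs whose ligand is expressed in A and whose
#' receptor is expressed in B. Self-loops (autocrine signalling, A = B) are
#' retained by default; zero-weight edges are omitted.
#'
#' @param sets cluster -> expressed gene sets, from [expressed_sets()].
#' @param pairs an [load_lr_pairs()] table.
#' @param self_loops keep A -> A edges (default TRUE).
#' @return A `crosstalk_graph` list: `nodes`, `edges` (data frame `source`,
#'   `target`, `weight`), `edge_pairs` (list of `"LIGAND:RECEPTOR"` vectors
#'   parallel to the edge rows).
#' @export
build_graph <- function(sets, pairs, self_loops = TRUE) {
  if (length(sets) == 0L) stop_validation("no clusters in expressed sets")
  stopifnot(inherits(pairs, "lr_pair_table") || is.data.frame(pairs))
  nodes <- names(sets)
  all_genes <- unique(unlist(sets))
  usable <- pairs$ligand %in% all_genes | pairs$receptor %in% all_genes
  if (!any(usable)) {
    warning("no ligand or receptor of the pair table is expressed anywhere; ",
            "graph is empty")
  }
  # cluster x pair indicator matrices: ligand (receptor) expressed there
  lig_in <- vapply(sets, function(g) pairs$ligand %in% g,
                   logical(nrow(pairs)))
  rec_in <- vapply(sets, function(g) pairs$receptor %in% g,
                   logical(nrow(pairs)))
  if (nrow(pairs) == 1L) {  # vapply drops to vector
    lig_in <- matrix(lig_in, nrow = 1L, dimnames = list(NULL, nodes))
    rec_in <- matrix(rec_in, nrow = 1L, dimnames = list(NULL, nodes))
  }
  src <- character(); tgt <- character(); wt <- integer()
  edge_pairs <- list()
  for (a in nodes) for (b in nodes) {
    if (!self_loops && a == b) next
    hit <- lig_in[, a] & rec_in[, b]
    w <- sum(hit)
    if (w > 0L) {
      src <- c(src, a); tgt <- c(tgt, b); wt <- c(wt, w)
      edge_pairs[[length(edge_pairs) + 1L]] <-
        paste(pairs$ligand[hit], pairs$receptor[hit], sep = ":")
    }
  }
  structure(list(nodes = nodes,
                 edges = data.frame(source = src, target = tgt, weight = wt,
                                    stringsAsFactors = FALSE),
                 edge_pairs = edge_pairs),
            class = "crosstalk_graph")
}

#' @export
print.crosstalk_graph <- function(x, ...) {
  cat(sprintf("<crosstalk_graph> %d clusters, %d edges, total weight %d\n",
              length(x$nodes), nrow(x$edges), sum(x$edges$weight)))
  invisible(x)
}

#' Hub scores of a crosstalk graph
#'
#' Weighted out-degree (ligands sent), weighted in-degree (receptors
#' listened with) and their total per cluster; self-loops count in both.
#' Betweenness centrality (weight-as-strength, via inverse-weight distances)
#' is reported for reference. Rows are ordered by descending total.
#'
#' @param graph a [build_graph()] result with at least one node.
#' @return Data frame: `cluster`, `out_weight`, `in_weight`, `total`,
#'   `betweenness`.
#' @export
hub_scores <- function(graph) {
  stopifnot(inherits(graph, "crosstalk_graph"))
  if (length(graph$nodes) == 0L) stop_validation("empty graph")
  e <- graph$edges
  outw <- setNames(numeric(length(graph$nodes)), graph$nodes)
  inw <- outw
  for (i in seq_len(nrow(e))) {
    outw[e$source[i]] <- outw[e$source[i]] + e$weight[i]
    inw[e$target[i]] <- inw[e$target[i]] + e$weight[i]
  }
  btw <- setNames(numeric(length(graph$nodes)), graph$nodes)
  if (nrow(e) > 0L) {
    ig <- igraph::graph_from_data_frame(e, directed = TRUE,
                                        vertices = graph$nodes)
    b <- igraph::betweenness(ig, directed = TRUE,
                             weights = 1 / igraph::E(ig)$weight)
    btw[names(b)] <- b
  }
  out <- data.frame(cluster = graph$nodes, out_weight = as.vector(outw),
                    in_weight = as.vector(inw),
                    total = as.vector(outw + inw),
                    betweenness = as.vector(btw),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$total, out$cluster), ]
  rownames(out) <- NULL
  out
}

#' Edge-wise difference of two crosstalk graphs
#'
#' Union of the two edge sets; an edge absent from one graph contributes
#' weight 0. Supports disjoint node label spaces.
#'
#' @param g1,g2 [build_graph()] results.
#' @return Data frame: `source`, `target`, `w1`, `w2`, `diff` (= w1 - w2),
#'   one row per edge present in either graph.
#' @export
diff_graph <- function(g1, g2) {
  stopifnot(inherits(g1, "crosstalk_graph"), inherits(g2, "crosstalk_graph"))
  key <- function(e) paste(e$source, e$target, sep = "\r")
  e1 <- g1$edges; e2 <- g2$edges
  keys <- union(key(e1), key(e2))
  w1 <- setNames(rep(0L, length(keys)), keys)
  w2 <- w1
  w1[key(e1)] <- e1$weight
  w2[key(e2)] <- e2$weight
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(source = vapply(parts, `[[`, "", 1L),
                    target = vapply(parts, `[[`, "", 2L),
                    w1 = as.integer(w1), w2 = as.integer(w2),
                    stringsAsFactors = FALSE)
  out$diff <- out$w1 - out$w2
  out[order(out$source, out$target), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Export a crosstalk graph to GraphML or edge-list TSV
#'
#' GraphML carries `weight` and a semicolon-joined `pairs` edge attribute
#' (written via igraph); the TSV has columns `source`, `target`, `weight`,
#' `pairs`. Both round-trip losslessly through [import_graph()].
#'
#' @param graph a [build_graph()] result.
#' @param path output file path.
#' @param format `"graphml"` or `"edgelist_tsv"`.
#' @return Invisibly, `path`.
#' @export
export_graph <- function(graph, path, format = c("graphml",
                                                 "edgelist_tsv")) {
  stopifnot(inherits(graph, "crosstalk_graph"))
  format <- match.arg(format)
  pairs_str <- vapply(graph$edge_pairs, paste, "", collapse = ";")
  if (format == "edgelist_tsv") {
    e <- graph$edges
    e$pairs <- if (nrow(e) > 0L) pairs_str else character()
    ok <- tryCatch({
      write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
      TRUE
    }, error = function(err) FALSE, warning = function(err) FALSE)
    if (!ok) stop_io("cannot write: ", path)
  } else {
    e <- graph$edges
    ig <- igraph::graph_from_data_frame(
      if (nrow(e) > 0L) cbind(e, pairs = pairs_str) else e,
      directed = TRUE, vertices = graph$nodes)
    ok <- tryCatch({
      igraph::write_graph(ig, path, format = "graphml")
      TRUE
    }, error = function(err) FALSE, warning = function(err) FALSE)
    if (!ok) stop_io("cannot write: ", path)
  }
  invisible(path)
}

#' Import a crosstalk graph written by [export_graph()]
#'
#' @param path file path.
#' @param format `"graphml"` or `"edgelist_tsv"`.
#' @return A `crosstalk_graph`.
#' @export
import_graph <- function(path, format = c("graphml", "edgelist_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_io("graph file not found: ", path)
  if (format == "edgelist_tsv") {
    e <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "integer",
                                   "character"))
    nodes <- sort(unique(c(e$source, e$target)))
    pairs <- strsplit(e$pairs, ";", fixed = TRUE)
  } else {
    ig <- igraph::read_graph(path, format = "graphml")
    nodes <- igraph::V(ig)$name
    el <- igraph::as_edgelist(ig)
    e <- data.frame(source = el[, 1L], target = el[, 2L],
                    weight = as.integer(igraph::E(ig)$weight),
                    stringsAsFactors = FALSE)
    pairs <- strsplit(as.character(igraph::E(ig)$pairs), ";", fixed = TRUE)
  }
  structure(list(nodes = nodes, edges = e[, c("source", "target", "weight")],
                 edge_pairs = pairs),
            class = "crosstalk_graph")
}

#' Full crosstalk inference from an expression matrix
#'
#' Convenience wrapper: detection fractions, thresholded expressed sets and
#' the directed graph in one call.
#'
#' @param expr an [expression_matrix()].
#' @param pairs an [load_lr_pairs()] table.
#' @param threshold detection-fraction cutoff (default 0.30, inclusive).
#' @param self_loops keep autocrine edges (default TRUE).
#' @return A `crosstalk_graph`.
#' @export
infer_crosstalk <- function(expr, pairs, threshold = 0.30,
                            self_loops = TRUE) {
  sets <- expressed_sets(detection_fraction(expr), threshold = threshold)
  build_graph(sets, pairs, self_loops = self_loops)
}
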