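#' Permutation test for elevated ERC between two diseases
#'
#' Tests whether the mean ERC across gene pairs spanning two disease groups
#' is elevated. Genes shared by both groups are dropped from both before
#' forming cross pairs, so an edge's mean never uses an ERC value involving a
#' shared gene. The null distribution is built from `n_perm` pseudo-disease
#' pairs: two disjoint random gene sets, size-matched to the post-drop groups,
#' drawn from the matrix universe; the p-value is the fraction of pseudo-pair
#' means greater than or equal to the observed mean.
#'
#' @param matrix An `erc_matrix`.
#' @param group_a,group_b `gene_group` objects (or character vectors).
#' @param n_perm Number of pseudo-disease pairs (default 10000).
#' @param seed Integer seed. The test is symmetric: swapping the groups gives
#'   the same mean, and with the same seed the same p-value.
#' @return A `disease_edge`: list with `disease_a`, `disease_b`, `n_genes_a`,
#'   `n_genes_b` (present, post-drop), `n_cross_pairs`, `mean_erc`, `p`,
#'   `p_censored`, `p_display`, `p_fdr`, `n_perm`.
#' @export
disease_pair_test <- function(matrix, group_a, group_b, n_perm = 10000L,
                              seed = NULL) {
  stopifnot(inherits(matrix, "erc_matrix"))
  if (is.character(group_a)) group_a <- gene_group("A", group_a)
  if (is.character(group_b)) group_b <- gene_group("B", group_b)
  shared <- intersect(group_a$genes, group_b$genes)
  a <- setdiff(present_members(matrix, group_a), shared)
  b <- setdiff(present_members(matrix, group_b), shared)
  if (length(a) == 0L || length(b) == 0L) {
    stop_ercnet("groups '", group_a$name, "' and '", group_b$name,
                "' share all their usable genes (degenerate pair)",
                class = "ercnet_degenerate_error")
  }
  cross <- matrix$values[a, b, drop = FALSE]
  vals <- cross[!is.na(cross)]
  if (length(vals) == 0L) {
    stop_ercnet("no defined cross pairs between '", group_a$name, "' and '",
                group_b$name, "'", class = "ercnet_insufficient_error")
  }
  obs <- mean(vals)
  universe <- gene_ids(matrix)
  k1 <- min(length(a), length(b))
  k2 <- max(length(a), length(b))
  if (length(universe) < k1 + k2) {
    stop_ercnet("gene universe too small for pseudo-disease sets",
                class = "ercnet_degenerate_error")
  }
  g <- length(universe)
  values <- matrix$values
  null_means <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(g, k1 + k2)
      sub <- values[idx[seq_len(k1)], idx[seq.int(k1 + 1L, k1 + k2)],
                    drop = FALSE]
      m <- mean(sub, na.rm = TRUE)
      if (is.nan(m)) NA_real_ else m
    }, numeric(1))
  })
  tally <- sum(null_means >= obs, na.rm = TRUE)
  p <- tally / n_perm
  censored <- tally == 0L
  structure(
    list(
      disease_a = group_a$name,
      disease_b = group_b$name,
      n_genes_a = length(a),
      n_genes_b = length(b),
      n_cross_pairs = length(vals),
      mean_erc = obs,
      p = p,
      p_censored = censored,
      p_display = if (censored) paste0("< ", format(1 / n_perm, scientific = FALSE))
                  else format(p, scientific = FALSE),
      p_fdr = if (censored) 1 / (2 * n_perm) else p,
      n_perm = as.integer(n_perm)
    ),
    class = "disease_edge"
  )
}

#' @export
print.disease_edge <- function(x, ...) {
  cat("disease edge ", x$disease_a, " -- ", x$disease_b, ": mean ERC = ",
      signif(x$mean_erc, 3), " over ", x$n_cross_pairs, " cross pairs; p ",
      if (x$p_censored) x$p_display else paste0("= ", x$p_display), "\n",
      sep = "")
  invisible(x)
}

# Scan-size accounting for n groups: unordered pairs including
# self-pairings, n (n + 1) / 2. Self-pairs are never tested and never
# become edges; they only enter this count.
enumerate_pair_count <- function(n_groups) {
  n_groups * (n_groups + 1) / 2
}

#' Build the disease-disease ERC network ("disease map")
#'
#' Tests all unordered pairs of distinct admissible disease groups with
#' [disease_pair_test()], estimates q-values over the full pair table, keeps
#' pairs with q below the FDR threshold as edges, and assigns each connected
#' disease to a cluster (connected component).
#'
#' @param matrix An `erc_matrix`.
#' @param groups List of `gene_group` objects (>= 2 admissible).
#' @param n_perm Permutations per pair (default 10000).
#' @param fdr_threshold Edge significance threshold on q (default 0.05).
#' @param seed Master seed; per-pair seeds are derived deterministically.
#' @param min_group_size Minimum present genes for a group to enter the scan.
#' @param fdr_method Passed to [estimate_qvalues()].
#' @return A `disease_map`: list with `nodes` (data frame: disease, cluster),
#'   `edges` (data frame of significant pairs), `pair_table` (all tested
#'   pairs with mean, p, q), and `summary` (group count, enumerated
#'   comparison count including self-pairings, tested pair count, counts
#'   below nominal p cutoffs, edge and cluster counts, eta0).
#' @export
build_disease_map <- function(matrix, groups, n_perm = 10000L,
                              fdr_threshold = 0.05, seed = NULL,
                              min_group_size = 3L,
                              fdr_method = c("storey", "bh")) {
  stopifnot(inherits(matrix, "erc_matrix"))
  fdr_method <- match.arg(fdr_method)
  names(groups) <- vapply(groups, function(g) g$name, character(1))
  admissible <- Filter(function(g) {
    length(present_members(matrix, g)) >= min_group_size
  }, groups)
  if (length(admissible) < 2L) {
    stop_ercnet("need at least 2 admissible groups",
                class = "ercnet_empty_error")
  }
  nm <- names(admissible)
  pairs <- utils::combn(nm, 2L)
  seeds <- derive_seeds(seed, ncol(pairs))
  rows <- vector("list", ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    res <- tryCatch(
      disease_pair_test(matrix, admissible[[pairs[1, j]]],
                        admissible[[pairs[2, j]]],
                        n_perm = n_perm, seed = seeds[[j]]),
      ercnet_error = function(e) NULL
    )
    if (is.null(res)) next
    rows[[j]] <- data.frame(
      disease_a = res$disease_a, disease_b = res$disease_b,
      n_genes_a = res$n_genes_a, n_genes_b = res$n_genes_b,
      n_cross_pairs = res$n_cross_pairs, mean_erc = res$mean_erc,
      p = res$p, p_fdr = res$p_fdr, p_display = res$p_display,
      stringsAsFactors = FALSE
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    stop_ercnet("no testable disease pairs", class = "ercnet_empty_error")
  }
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  fdr <- estimate_qvalues(tab$p_fdr, method = fdr_method)
  tab$q <- fdr$qvalues
  # among tied (censored) p-values, larger observed means rank first
  tab <- tab[order(tab$p_fdr, -tab$mean_erc, tab$disease_a, tab$disease_b),
             , drop = FALSE]
  rownames(tab) <- NULL

  edges <- tab[tab$q <= fdr_threshold, , drop = FALSE]
  rownames(edges) <- NULL
  if (nrow(edges) > 0L) {
    gr <- igraph::graph_from_data_frame(
      edges[, c("disease_a", "disease_b")], directed = FALSE
    )
    comp <- igraph::components(gr)
    nodes <- data.frame(
      disease = names(comp$membership),
      cluster = as.integer(comp$membership),
      stringsAsFactors = FALSE
    )
    n_clusters <- comp$no
  } else {
    nodes <- data.frame(disease = character(0), cluster = integer(0),
                        stringsAsFactors = FALSE)
    n_clusters <- 0L
  }
  structure(
    list(
      nodes = nodes,
      edges = edges,
      pair_table = tab,
      summary = list(
        n_groups = length(admissible),
        n_enumerated_comparisons = enumerate_pair_count(length(admissible)),
        n_pairs_tested = nrow(tab),
        n_below_5e4 = sum(tab$p_fdr <= 5e-4),
        n_below_0.05 = sum(tab$p_fdr < 0.05),
        n_edges = nrow(edges),
        n_clusters = n_clusters,
        fdr_threshold = fdr_threshold,
        eta0 = fdr$eta0
      )
    ),
    class = "disease_map"
  )
}

#' @export
print.disease_map <- function(x, ...) {
  s <- x$summary
  cat("disease_map:", s$n_groups, "diseases;", s$n_pairs_tested,
      "pairs tested;", s$n_edges, "edges at FDR", s$fdr_threshold,
      "forming", s$n_clusters, "clusters\n")
  invisible(x)
}

#' Export / import a disease map
#'
#' `export_disease_map` writes the network as GraphML (mean ERC, p, q as edge
#' attributes; cluster id as node attribute) or as an edge-list TSV.
#' `import_disease_map_graphml` reads a GraphML file back into node and edge
#' tables for round-trip checks.
#'
#' @param map A `disease_map`.
#' @param path Output file.
#' @param format `"graphml"` or `"edgelist"`.
#' @export
export_disease_map <- function(map, path, format = c("graphml", "edgelist")) {
  stopifnot(inherits(map, "disease_map"))
  format <- tryCatch(match.arg(format),
                     error = function(e) {
                       stop_ercnet("unknown export format",
                                   class = "ercnet_format_error")
                     })
  if (format == "edgelist") {
    utils::write.table(map$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  gr <- disease_map_graph(map)
  igraph::write_graph(gr, path, format = "graphml")
  invisible(path)
}

# igraph object with attributes, including isolated... nodes are only those
# in >= 1 significant edge, per the map definition.
disease_map_graph <- function(map) {
  if (nrow(map$edges) == 0L) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  gr <- igraph::graph_from_data_frame(
    map$edges[, c("disease_a", "disease_b", "mean_erc", "p", "q")],
    directed = FALSE,
    vertices = map$nodes
  )
  gr
}

#' @rdname export_disease_map
#' @export
import_disease_map_graphml <- function(path) {
  gr <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(
    disease = igraph::vertex_attr(gr, "name") %||% character(0),
    cluster = as.integer(igraph::vertex_attr(gr, "cluster") %||% integer(0)),
    stringsAsFactors = FALSE
  )
  if (igraph::ecount(gr) > 0L) {
    el <- igraph::as_edgelist(gr)
    edges <- data.frame(
      disease_a = el[, 1], disease_b = el[, 2],
      mean_erc = igraph::edge_attr(gr, "mean_erc"),
      p = igraph::edge_attr(gr, "p"),
      q = igraph::edge_attr(gr, "q"),
      stringsAsFactors = FALSE
    )
  } else {
    edges <- data.frame(disease_a = character(0), disease_b = character(0),
                        mean_erc = numeric(0), p = numeric(0), q = numeric(0),
                        stringsAsFactors = FALSE)
  }
  list(nodes = nodes, edges = edges)
}
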