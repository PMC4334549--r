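# Shared fixture builders. Everything is generated in code; no data files.

# 5-species reference topology used by the hand-worked placement tests.
toy_topology <- function() {
  species_topology("((a:1,b:1):1,(c:1,d:1):1,e:1);")
}

write_tree_file <- function(dir, id, text) {
  path <- file.path(dir, paste0(id, ".nwk"))
  writeLines(text, path)
  path
}

# Build a branch_rate_matrix directly from a values matrix whose columns are
# a topology's canonical branch ids (bypasses tree parsing for arithmetic
# tests). Species sets default to the full species set.
make_rate_matrix <- function(values, topology, gene_species = NULL) {
  if (is.null(gene_species)) {
    gene_species <- rep(list(topology$species), nrow(values))
    names(gene_species) <- rownames(values)
  }
  ercnet:::new_branch_rate_matrix(values, topology, gene_species)
}

# Build an erc_matrix object from an explicit symmetric values matrix.
make_erc <- function(values, counts = NULL) {
  if (is.null(counts)) {
    counts <- matrix(60L, nrow(values), ncol(values),
                     dimnames = dimnames(values))
  }
  ercnet:::new_erc_matrix(values, counts, min_shared = 10L,
                          method = "pearson")
}

# One simulated dataset through rates -> relative rates -> ERC matrix.
quick_erc <- function(seed, rho = 0.5, n_genes = 120L, path_size = 10L,
                      n_species = 20L, missing_prob = 0.2, min_shared = 10L,
                      ...) {
  pathways <- if (path_size > 0) list(seq_len(path_size)) else list()
  cfg <- simulation_config(
    n_species = n_species, n_genes = n_genes, pathways = pathways,
    rho = if (path_size > 0) rho else numeric(0),
    missing_prob = missing_prob, seed = seed, ...
  )
  phy <- simulate_phylogeny(cfg$n_species, seed = seed + 1000L,
                            time_meanlog = cfg$time_meanlog,
                            time_sdlog = cfg$time_sdlog)
  sim <- simulate_rate_matrix(phy, cfg)
  rates <- normalize_relative_rates(sim$matrix)
  list(erc = erc_matrix(rates, min_shared = min_shared),
       rates = rates, sim = sim, phy = phy, cfg = cfg)
}

# Independent Pearson oracle: explicit sums over the shared branches.
pearson_oracle <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- sum(x * y) - sx * sy / n
  den <- sqrt((sum(x^2) - sx^2 / n) * (sum(y^2) - sy^2 / n))
  num / den
}

# Independent connected-components oracle on an edge list (BFS over
# adjacency lists; no graph library).
components_oracle <- function(nodes, edges_a, edges_b) {
  adj <- lapply(stats::setNames(vector("list", length(nodes)), nodes),
                function(x) character(0))
  for (i in seq_along(edges_a)) {
    adj[[edges_a[i]]] <- c(adj[[edges_a[i]]], edges_b[i])
    adj[[edges_b[i]]] <- c(adj[[edges_b[i]]], edges_a[i])
  }
  comp <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  cid <- 0L
  for (n in nodes) {
    if (!is.na(comp[[n]])) next
    cid <- cid + 1L
    queue <- n
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[[v]])) next
      comp[[v]] <- cid
      queue <- c(queue, adj[[v]])
    }
  }
  comp
}
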