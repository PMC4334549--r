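#' Configuration for the synthetic ERC testbed
#'
#' Defines the generative model under which every pipeline stage is testable
#' without external data: a random species phylogeny with log-normal branch
#' times, per-gene branch lengths
#' \deqn{b_{g,i} = t_i \, \mu_g \, e^{\sigma d_{g,i}},}
#' where the log-deviation \eqn{d_{g,i} = \sqrt{\rho}\, s_{P(g),i} +
#' \sqrt{1-\rho}\, e_{g,i}} mixes a per-(pathway, branch) factor s with
#' per-(gene, branch) noise e (both standard normal). Genes in the same
#' pathway therefore share branch-specific rate deviations with correlation
#' exactly `rho` on the log scale; genes outside any pathway use d = e.
#' Species are dropped per gene with probability `missing_prob` to exercise
#' the presence-mask machinery.
#'
#' @param n_species Number of species (>= 4; default 32, giving 61 unrooted
#'   branches — the "about 60 branches" regime of a mammal-scale phylogeny).
#' @param n_genes Number of genes (default 500, so that a planted pathway is
#'   a small fraction of the gene universe; a pathway that dominates the
#'   universe contaminates the genome-average vector and projection then
#'   strips part of the pathway signal itself).
#' @param pathways List of integer vectors of gene indices; a gene may belong
#'   to at most one pathway. Default: one 20-gene pathway (genes 1-20).
#' @param rho Covariation strength per pathway, each in [0, 1) (default 0.5).
#' @param mu_meanlog,mu_sdlog Log-normal parameters of per-gene base rates
#'   (defaults 0 and 0.3: ~35% spread in gene-wide rate).
#' @param sigma Scale of branch-specific log rate deviations (default 0.3).
#' @param time_meanlog,time_sdlog Log-normal parameters of branch times
#'   (defaults log(0.05) and 0.1: mean branch length about 0.05
#'   substitutions/site with modest dispersion. Unweighted Pearson
#'   correlation over branches follows the Fisher sampling law only when
#'   branch-time dispersion is modest; heavier dispersion — as on real
#'   phylogenies — reweights branches and inflates the sampling variance of
#'   ERC values.)
#' @param missing_prob Per-gene probability that a given species is missing
#'   (default 0.2).
#' @param seed Mandatory integer seed; all generator output is a pure
#'   function of the seed and config.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_species = 32L, n_genes = 500L,
                              pathways = list(1:20), rho = 0.5,
                              mu_meanlog = 0, mu_sdlog = 0.3,
                              sigma = 0.3,
                              time_meanlog = log(0.05), time_sdlog = 0.1,
                              missing_prob = 0.2, seed) {
  if (missing(seed) || is.null(seed)) {
    stop_ercnet("a seed is mandatory for the synthetic generator",
                class = "ercnet_format_error")
  }
  stopifnot(n_species >= 4L, n_genes >= 2L,
            missing_prob >= 0, missing_prob < 1,
            sigma > 0, mu_sdlog >= 0, time_sdlog >= 0)
  pathways <- lapply(pathways, as.integer)
  if (length(rho) == 1L) rho <- rep(rho, length(pathways))
  stopifnot(length(rho) == length(pathways), all(rho >= 0), all(rho < 1))
  all_idx <- unlist(pathways)
  if (length(all_idx)) {
    stopifnot(all(all_idx >= 1L), all(all_idx <= n_genes))
    if (anyDuplicated(all_idx)) {
      stop_ercnet("a gene may belong to at most one pathway",
                  class = "ercnet_format_error")
    }
  }
  structure(
    list(n_species = as.integer(n_species), n_genes = as.integer(n_genes),
         pathways = pathways, rho = rho,
         mu_meanlog = mu_meanlog, mu_sdlog = mu_sdlog, sigma = sigma,
         time_meanlog = time_meanlog, time_sdlog = time_sdlog,
         missing_prob = missing_prob, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Simulate a species phylogeny with branch times
#'
#' Draws a random unrooted binary topology over `n_species` labeled species
#' and log-normal branch times on its canonical branches.
#'
#' @param n_species Number of species (>= 4).
#' @param seed Integer seed (mandatory; output is deterministic given it).
#' @param time_meanlog,time_sdlog Log-normal branch-time parameters.
#' @return A `sim_phylogeny`: list with `topology` (a [species_topology()]),
#'   `times` (named by canonical branch id) and `tree` (phylo with the times
#'   as edge lengths, for writing to newick).
#' @export
simulate_phylogeny <- function(n_species, seed,
                               time_meanlog = log(0.05), time_sdlog = 0.1) {
  if (n_species < 4L) {
    stop_ercnet("need at least 4 species", class = "ercnet_format_error")
  }
  labels <- sprintf("s%03d", seq_len(n_species))
  with_seed(seed, {
    tree <- ape::rtopology(n_species, rooted = FALSE, tip.label = labels)
    topology <- species_topology(tree)
    n_branch <- length(topology$branch_ids)
    times <- stats::rlnorm(n_branch, meanlog = time_meanlog,
                           sdlog = time_sdlog)
    names(times) <- topology$branch_ids
    # Put the times back on the tree's edges for newick output.
    keys <- vapply(edge_far_sides(topology$tree), split_key, character(1),
                   species = topology$species)
    tree_out <- topology$tree
    tree_out$edge.length <- unname(times[keys])
    structure(list(topology = topology, times = times, tree = tree_out),
              class = "sim_phylogeny")
  })
}

#' Simulate a branch-rate matrix with planted pathway covariation
#'
#' @param phylogeny A `sim_phylogeny` from [simulate_phylogeny()].
#' @param config A [simulation_config()]. Rate draws use a sub-seed derived
#'   from `config$seed`, so phylogeny and rates can be generated from the
#'   same config reproducibly.
#' @return List with `matrix` (the masked `branch_rate_matrix`) and `truth`
#'   (list: `pathway` — integer pathway id per gene, `NA` outside pathways;
#'   `rho`; `mu`; `full_values` — the unmasked gene x branch lengths, used to
#'   write complete gene trees; `times`; `gene_species`; `config`).
#' @export
simulate_rate_matrix <- function(phylogeny, config) {
  stopifnot(inherits(phylogeny, "sim_phylogeny"),
            inherits(config, "simulation_config"),
            config$n_species == length(phylogeny$topology$species))
  topo <- phylogeny$topology
  t_i <- phylogeny$times[topo$branch_ids]
  nb <- length(t_i)
  ng <- config$n_genes
  genes <- sprintf("g%04d", seq_len(ng))
  pathway <- rep(NA_integer_, ng)
  for (p in seq_along(config$pathways)) pathway[config$pathways[[p]]] <- p

  sub <- derive_seeds(config$seed, 3L)
  mu <- with_seed(sub[[1]], stats::rlnorm(ng, config$mu_meanlog,
                                          config$mu_sdlog))
  d <- with_seed(sub[[2]], {
    e <- matrix(stats::rnorm(ng * nb), ng, nb)
    if (length(config$pathways)) {
      s <- matrix(stats::rnorm(length(config$pathways) * nb),
                  length(config$pathways), nb)
      for (g in seq_len(ng)) {
        p <- pathway[g]
        if (!is.na(p)) {
          e[g, ] <- sqrt(config$rho[p]) * s[p, ] +
            sqrt(1 - config$rho[p]) * e[g, ]
        }
      }
    }
    e
  })
  full <- sweep(exp(config$sigma * d) * mu, 2L, t_i, `*`)
  dimnames(full) <- list(genes, topo$branch_ids)

  gene_species <- with_seed(sub[[3]], {
    lapply(seq_len(ng), function(g) {
      keep <- topo$species[stats::runif(config$n_species) >= config$missing_prob]
      # A usable gene tree needs at least 4 species; keep everything if the
      # draw was too aggressive (rare at the default missing_prob).
      if (length(keep) < 4L) topo$species else keep
    })
  })
  names(gene_species) <- genes

  values <- matrix(NA_real_, ng, nb, dimnames = dimnames(full))
  map_cache <- new.env(parent = emptyenv())
  for (g in seq_len(ng)) {
    key <- paste(gene_species[[g]], collapse = ",")
    ids <- map_cache[[key]]
    if (is.null(ids)) {
      ids <- unname(unique_restricted_map(topo, gene_species[[g]]))
      map_cache[[key]] <- ids
    }
    values[g, ids] <- full[g, ids]
  }
  matrix <- new_branch_rate_matrix(values, topo, gene_species)
  truth <- list(pathway = stats::setNames(pathway, genes),
                rho = config$rho, mu = stats::setNames(mu, genes),
                full_values = full, times = t_i,
                gene_species = gene_species, config = config)
  list(matrix = matrix, truth = truth)
}

#' Simulate disease-group assignments over synthetic genes
#'
#' Builds labeled gene groups for power/FDR evaluation: "signal" groups are
#' drawn within a single planted pathway (so their genes share covarying
#' rates), "null" groups uniformly from all genes. When the signal groups
#' assigned to a pathway collectively fit inside it, they are drawn as
#' disjoint subsets (a random partition), so that between-group statistics
#' reflect rate covariation rather than shared membership — shared genes are
#' excluded by the disease-pair test anyway. If they do not fit, each group
#' is drawn independently and overlaps may occur.
#'
#' @param truth The `truth` record of [simulate_rate_matrix()].
#' @param n_groups Total number of groups.
#' @param sizes Group sizes: a single size or a vector recycled over groups.
#' @param signal_fraction Fraction of groups that are signal groups.
#' @param seed Integer seed.
#' @return List with `groups` (list of `gene_group`) and `labels` (character
#'   vector, "signal" or "null", named by group).
#' @export
simulate_disease_groups <- function(truth, n_groups, sizes = 10L,
                                    signal_fraction = 0.2, seed = NULL) {
  stopifnot(n_groups >= 1L, all(sizes >= 2L),
            signal_fraction >= 0, signal_fraction <= 1)
  sizes <- rep_len(as.integer(sizes), n_groups)
  n_signal <- round(n_groups * signal_fraction)
  genes <- names(truth$pathway)
  pathway_sets <- lapply(seq_along(truth$rho), function(p) {
    genes[!is.na(truth$pathway) & truth$pathway == p]
  })
  if (n_signal > 0L && length(pathway_sets) == 0L) {
    stop_ercnet("signal groups requested but the config plants no pathway",
                class = "ercnet_format_error")
  }
  with_seed(seed, {
    groups <- vector("list", n_groups)
    labels <- character(n_groups)
    if (n_signal > 0L) {
      pathway_of <- (seq_len(n_signal) - 1L) %% length(pathway_sets) + 1L
      for (p in seq_along(pathway_sets)) {
        pool <- pathway_sets[[p]]
        mine <- which(pathway_of == p)
        if (any(sizes[mine] > length(pool))) {
          stop_ercnet("requested signal group size ", max(sizes[mine]),
                      " exceeds pathway size ", length(pool),
                      class = "ercnet_format_error")
        }
        disjoint <- sum(sizes[mine]) <= length(pool)
        shuffled <- sample(pool)
        off <- 0L
        for (i in mine) {
          members <- if (disjoint) {
            off <- off + sizes[i]
            shuffled[(off - sizes[i] + 1L):off]
          } else {
            sample(pool, sizes[i])
          }
          groups[[i]] <- gene_group(sprintf("signal_%03d", i), members)
          labels[i] <- "signal"
        }
      }
    }
    for (i in seq_len(n_groups)) {
      if (i > n_signal) {
        groups[[i]] <- gene_group(sprintf("null_%03d", i - n_signal),
                                  sample(genes, sizes[i]))
        labels[i] <- "null"
      }
    }
    names(labels) <- vapply(groups, function(g) g$name, character(1))
    list(groups = groups, labels = labels)
  })
}

#' Write a complete on-disk benchmark fixture
#'
#' Generates a phylogeny and rate matrix from `config` and writes everything
#' the command-line pipeline consumes: a reference topology (newick, no
#' lengths), one newick tree per gene (complete branch lengths on the gene's
#' species subset; branches merged by pruning carry the summed length, which
#' the loader correctly records as absent), a GMT file of disease groups, a
#' BED file placing genes on synthetic chromosomes (each signal gene centered
#' among decoys within one window), and a JSON truth record.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @param n_groups,sizes,signal_fraction Passed to
#'   [simulate_disease_groups()].
#' @param window_bp Window width the BED layout is designed for (default
#'   1e6); genes are spaced so a window holds `decoys_per_window` decoys
#'   around each planted gene.
#' @param decoys_per_window Number of decoy genes co-located with each
#'   planted pathway gene (default 10).
#' @return Invisibly, a list of paths (`topology`, `trees` (dir), `groups`,
#'   `bed`, `truth`) plus the in-memory `matrix`, `truth`, `groups`,
#'   `labels`.
#' @export
make_benchmark_fixture <- function(config, out_dir, n_groups = 10L,
                                   sizes = 5L, signal_fraction = 0.2,
                                   window_bp = 1e6, decoys_per_window = 10L) {
  stopifnot(inherits(config, "simulation_config"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop_ercnet("cannot create output directory ", out_dir,
                class = "ercnet_io_error")
  }
  sub <- derive_seeds(config$seed, 2L)
  phy <- simulate_phylogeny(config$n_species, seed = sub[[1]],
                            time_meanlog = config$time_meanlog,
                            time_sdlog = config$time_sdlog)
  sim <- simulate_rate_matrix(phy, config)
  grp <- simulate_disease_groups(sim$truth, n_groups = n_groups,
                                 sizes = sizes,
                                 signal_fraction = signal_fraction,
                                 seed = sub[[2]])

  topo_path <- file.path(out_dir, "topology.nwk")
  ape::write.tree(phy$topology$tree, topo_path)

  tree_dir <- file.path(out_dir, "trees")
  dir.create(tree_dir, showWarnings = FALSE)
  genes <- rownames(sim$matrix$values)
  for (g in genes) {
    tr <- phy$tree
    # Full branch lengths for this gene, then prune to its species; drop.tip
    # sums the lengths of merged edges, as a real inferred gene tree would.
    keys <- vapply(edge_far_sides(tr), split_key, character(1),
                   species = phy$topology$species)
    tr$edge.length <- unname(sim$truth$full_values[g, keys])
    tr <- ape::keep.tip(tr, sim$truth$gene_species[[g]])
    ape::write.tree(tr, file.path(tree_dir, paste0(g, ".nwk")))
  }

  gmt_path <- file.path(out_dir, "groups.gmt")
  write_gmt(grp$groups, gmt_path,
            descriptions = paste0("label=", grp$labels))

  bed_path <- file.path(out_dir, "genes.bed")
  ann <- fixture_annotation(genes, sim$truth$pathway, window_bp,
                            decoys_per_window)
  write_gene_annotation(ann, bed_path)

  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(
    list(
      seed = config$seed,
      n_species = config$n_species,
      n_genes = config$n_genes,
      rho = config$rho,
      pathway = as.list(sim$truth$pathway),
      group_labels = as.list(grp$labels)
    ),
    truth_path, auto_unbox = TRUE, digits = NA, na = "null"
  )

  invisible(list(
    topology = topo_path, trees = tree_dir, groups = gmt_path,
    bed = bed_path, truth_file = truth_path,
    matrix = sim$matrix, truth = sim$truth,
    groups_list = grp$groups, labels = grp$labels
  ))
}

# Deterministic BED layout: each pathway (planted) gene gets its own
# chromosome slot centered among `decoys_per_window` non-pathway genes, all
# within one window; leftover genes fill additional chromosomes.
fixture_annotation <- function(genes, pathway, window_bp, decoys_per_window) {
  spacing <- floor(window_bp / (decoys_per_window + 2L))
  gene_len <- min(10000L, spacing - 1L)
  planted <- names(pathway)[!is.na(pathway)]
  decoys <- setdiff(genes, planted)
  rows <- list()
  di <- 1L
  chrom_i <- 1L
  for (g in planted) {
    slots <- decoys_per_window + 1L
    center <- (slots + 1L) %/% 2L
    ids <- character(slots)
    for (s in seq_len(slots)) {
      if (s == center) {
        ids[s] <- g
      } else {
        ids[s] <- if (di <= length(decoys)) decoys[di] else NA_character_
        di <- di + 1L
      }
    }
    ids <- ids[!is.na(ids)]
    start <- spacing * (seq_along(ids) - 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      gene = ids, chrom = paste0("chr", chrom_i),
      start = start, end = start + gene_len, stringsAsFactors = FALSE
    )
    chrom_i <- chrom_i + 1L
  }
  if (di <= length(decoys)) {
    rest <- decoys[di:length(decoys)]
    start <- spacing * (seq_along(rest) - 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      gene = rest, chrom = paste0("chr", chrom_i),
      start = start, end = start + gene_len, stringsAsFactors = FALSE
    )
  }
  validate_annotation(do.call(rbind, rows))
}

#' Write a gene annotation as BED4
#' @param annotation Data frame with `gene`, `chrom`, `start`, `end`
#'   (0-based, half-open).
#' @param path Output BED path.
#' @export
write_gene_annotation <- function(annotation, path) {
  annotation <- validate_annotation(annotation)
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = annotation$start + 1L,
                              end = annotation$end),
    name = annotation$gene
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
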