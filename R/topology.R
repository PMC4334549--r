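#' Reference species topology with canonical branch coordinates
#'
#' Builds the shared coordinate system on which every gene's branch lengths
#' are placed. The topology is treated as unrooted; each branch is identified
#' by the bipartition (split) of the species set it induces, written as the
#' sorted, comma-separated list of species on the side *not* containing the
#' alphabetically first species. Branch identifiers are therefore unique and
#' their canonical order (lexicographic) is independent of how the input file
#' orders clades.
#'
#' @param tree An [ape::phylo] object, a newick string, or a path to a newick
#'   file. Branch lengths, if any, are discarded.
#' @return An object of class `species_topology`: a list with elements
#'   `tree` (unrooted `phylo`, lengths stripped), `species` (sorted leaf
#'   labels), `branch_ids` (canonical ordered branch identifiers) and
#'   `branch_sides` (named list giving, for each branch id, the species on
#'   its far side).
#' @examples
#' topo <- species_topology("((a,b),(c,d));")
#' topo$branch_ids
#' @export
species_topology <- function(tree) {
  phy <- as_phylo(tree)
  if (length(phy$tip.label) < 3L) {
    stop_ercnet("a species topology needs at least 3 species",
                class = "ercnet_topology_error")
  }
  if (anyDuplicated(phy$tip.label)) {
    stop_ercnet("duplicate leaf labels in reference topology: ",
                paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
                      collapse = ", "),
                class = "ercnet_topology_error")
  }
  phy$edge.length <- NULL
  phy$node.label <- NULL
  if (ape::is.rooted(phy)) phy <- ape::unroot(phy)
  species <- sort(phy$tip.label)
  sides <- edge_far_sides(phy)
  keys <- vapply(sides, split_key, character(1), species = species)
  if (anyDuplicated(keys)) {
    stop_ercnet("reference topology contains duplicated splits",
                class = "ercnet_topology_error")
  }
  ord <- order(keys)
  branch_sides <- lapply(sides[ord], function(s) {
    k <- split_key(s, species)
    strsplit(k, ",", fixed = TRUE)[[1]]
  })
  names(branch_sides) <- keys[ord]
  # Branch x species membership matrix of the far sides; used for fast
  # bitmask restriction of splits to species subsets.
  side_matrix <- t(vapply(branch_sides, function(s) species %in% s,
                          logical(length(species))))
  colnames(side_matrix) <- species
  structure(
    list(tree = phy, species = species,
         branch_ids = keys[ord], branch_sides = branch_sides,
         side_matrix = side_matrix),
    class = "species_topology"
  )
}

#' @export
print.species_topology <- function(x, ...) {
  cat("species_topology:", length(x$species), "species,",
      length(x$branch_ids), "branches\n")
  invisible(x)
}

# Coerce newick string / file path / phylo to phylo.
as_phylo <- function(tree, file_hint = NULL) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1L) {
    phy <- tryCatch({
      if (file.exists(tree) && !grepl("\\(", tree)) ape::read.tree(tree)
      else ape::read.tree(text = tree)
    }, error = function(e) NULL)
    if (inherits(phy, "multiPhylo")) {
      phy <- if (length(phy) == 1L) phy[[1L]] else NULL
    }
    if (is.null(phy) || !inherits(phy, "phylo")) {
      stop_ercnet("unparseable newick input",
                  if (!is.null(file_hint)) paste0(" in file ", file_hint) else "",
                  class = "ercnet_format_error")
    }
    return(phy)
  }
  stop_ercnet("cannot interpret input as a phylogenetic tree",
              class = "ercnet_format_error")
}

# For each edge of `phy` (in tree$edge row order), the sorted tip labels on
# the child side of that edge.
edge_far_sides <- function(phy) {
  n_tip <- length(phy$tip.label)
  n_node <- max(phy$edge)
  tips <- vector("list", n_node)
  for (i in seq_len(n_tip)) tips[[i]] <- phy$tip.label[i]
  post <- ape::reorder.phylo(phy, "postorder")
  for (k in seq_len(nrow(post$edge))) {
    p <- post$edge[k, 1L]
    ch <- post$edge[k, 2L]
    tips[[p]] <- c(tips[[p]], tips[[ch]])
  }
  lapply(phy$edge[, 2L], function(ch) sort(tips[[ch]]))
}

# Canonical key of a split: the side not containing the anchor (first sorted
# species), sorted and comma-separated. `side` is one side of the split;
# `species` the full (sorted) leaf set the split partitions.
split_key <- function(side, species) {
  anchor <- species[1L]
  if (anchor %in% side) side <- setdiff(species, side)
  paste(sort(side), collapse = ",")
}

# Compact string key of a split restricted to a sorted species subset.
# `side_logical` marks, in subset order, the species on one side; the key is
# canonicalized so the side not containing the subset's first species is
# encoded. Bits are packed into 26-bit words joined by ":", so any number of
# species is supported exactly.
split_key_bits <- function(side_logical) {
  if (side_logical[1L]) side_logical <- !side_logical
  if (!any(side_logical) || all(side_logical)) return(NA_character_)
  k <- length(side_logical)
  chunks <- split(seq_len(k), (seq_len(k) - 1L) %/% 26L)
  paste(vapply(chunks, function(ix) {
    sum(2^(seq_along(ix) - 1L) * side_logical[ix])
  }, numeric(1)), collapse = ":")
}

# Logical membership vector encoded by a split key (inverse of
# split_key_bits).
bit_decode <- function(key, n) {
  words <- as.numeric(strsplit(key, ":", fixed = TRUE)[[1]])
  idx <- logical(n)
  off <- 0L
  for (w in words) {
    len <- min(26L, n - off)
    for (i in seq_len(len)) {
      b <- 2^(i - 1L)
      if (w %% (2 * b) >= b) idx[off + i] <- TRUE
    }
    off <- off + len
  }
  idx
}

# Restriction of the reference branches to a species subset. Returns a
# numeric vector (named by branch id) of restricted split keys; NA where
# the branch vanishes (one side empty after restriction). Branches whose
# restricted key is shared with another branch correspond to branch chains
# merged by pruning; they are not attributable to a single reference branch.
restricted_keys <- function(topology, species_subset) {
  sp <- sort(species_subset)
  cols <- match(sp, topology$species)
  m <- topology$side_matrix[, cols, drop = FALSE]
  # Canonicalize every row at once: complement rows containing the anchor
  # (first subset species), then encode as packed bitmasks with one matrix
  # product per 26-bit word.
  m <- xor(m, m[, 1L])
  k <- ncol(m)
  chunks <- split(seq_len(k), (seq_len(k) - 1L) %/% 26L)
  words <- lapply(chunks, function(ix) {
    as.numeric(m[, ix, drop = FALSE] %*% 2^(seq_along(ix) - 1L))
  })
  keys <- do.call(paste, c(words, list(sep = ":")))
  n_side <- rowSums(m)
  keys[n_side == 0L | n_side == k] <- NA_character_
  names(keys) <- topology$branch_ids
  keys
}

# Reference branches that survive restriction to `species_subset` uniquely
# (i.e. are identifiable on the pruned tree). Returns a character vector of
# branch ids named by restricted key (multiplicity-1 keys only).
unique_restricted_map <- function(topology, species_subset) {
  keys <- restricted_keys(topology, species_subset)
  keys <- keys[!is.na(keys)]
  dup <- keys %in% keys[duplicated(keys)]
  map <- names(keys)[!dup]
  names(map) <- keys[!dup]
  map
}
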