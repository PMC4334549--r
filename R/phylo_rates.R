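#' Branch-rate and relative-rate matrices
#'
#' A `branch_rate_matrix` holds, for G genes, the branch lengths
#' (substitutions/site) of each gene placed on the canonical branch
#' coordinates of a [species_topology()]. Absent branches (species missing
#' for that gene, or branches merged by pruning) are `NA`; the presence mask
#' is `!is.na(values)`. A `relative_rate_matrix` has the same shape and mask
#' but holds signed relative-rate deviations after projection normalization.
#'
#' @name rate-matrices
NULL

new_branch_rate_matrix <- function(values, topology, gene_species,
                                   class = "branch_rate_matrix") {
  stopifnot(identical(colnames(values), topology$branch_ids))
  structure(
    list(values = values, topology = topology, gene_species = gene_species),
    class = class
  )
}

#' @export
print.branch_rate_matrix <- function(x, ...) {
  cat(class(x)[1], ":", nrow(x$values), "genes x", ncol(x$values),
      "branches;", sum(!is.na(x$values)), "present cells\n")
  invisible(x)
}

#' @export
print.relative_rate_matrix <- print.branch_rate_matrix

#' Gene ids of a rate or ERC matrix
#' @param x a `branch_rate_matrix`, `relative_rate_matrix` or `erc_matrix`.
#' @return Character vector of gene identifiers.
#' @export
gene_ids <- function(x) {
  if (inherits(x, "erc_matrix")) return(rownames(x$values))
  rownames(x$values)
}

#' Load per-gene trees onto the canonical branch coordinates
#'
#' Reads one newick tree per gene (one file per gene, or multi-tree files
#' with tree labels) and places each tree's branch lengths on the reference
#' branch coordinate system by far-side leaf-set identity. Genes may cover a
#' subset of the reference species; branches of the reference that are merged
#' into a single edge by pruning are not attributable to one reference branch
#' and are recorded as absent for that gene.
#'
#' @param paths Character vector of newick file paths. A file holding a
#'   single tree contributes one gene whose id is the tree label if present,
#'   otherwise the file base name; multi-tree files must label every tree.
#' @param topology A [species_topology()].
#' @param strict If `TRUE`, a gene tree whose topology conflicts with the
#'   reference aborts the load; if `FALSE` (default) conflicting genes are
#'   dropped with a warning naming the offending split.
#' @return A `branch_rate_matrix`. Rows are ordered by gene id so the result
#'   is identical for any file order. Attribute `"rejected"` lists genes
#'   dropped for topology conflicts (when `strict = FALSE`).
#' @export
load_gene_trees <- function(paths, topology, strict = FALSE) {
  stopifnot(inherits(topology, "species_topology"))
  trees <- list()
  for (f in paths) {
    phy <- tryCatch(suppressWarnings(ape::read.tree(f)),
                    error = function(e) NULL)
    if (is.null(phy)) {
      stop_ercnet("unparseable newick in file ", f,
                  class = "ercnet_format_error")
    }
    if (inherits(phy, "phylo")) {
      id <- attr(phy, "name", exact = TRUE)
      if (is.null(id) || !nzchar(id)) {
        id <- sub("\\.(nwk|newick|tre|tree|txt)$", "", basename(f))
      }
      trees[[id]] <- phy
    } else {
      ids <- names(phy)
      if (is.null(ids) || any(!nzchar(ids))) {
        stop_ercnet("multi-tree file ", f, " has unlabeled trees",
                    class = "ercnet_format_error")
      }
      for (i in seq_along(phy)) trees[[ids[i]]] <- phy[[i]]
    }
  }
  if (anyDuplicated(names(trees))) {
    stop_ercnet("duplicate gene ids across tree files: ",
                paste(unique(names(trees)[duplicated(names(trees))]),
                      collapse = ", "),
                class = "ercnet_format_error")
  }
  genes <- sort(names(trees))
  b <- length(topology$branch_ids)
  values <- matrix(NA_real_, nrow = length(genes), ncol = b,
                   dimnames = list(genes, topology$branch_ids))
  gene_species <- vector("list", length(genes))
  names(gene_species) <- genes
  rejected <- character(0)

  for (g in genes) {
    phy <- trees[[g]]
    row <- tryCatch(place_gene_tree(phy, topology, gene = g),
                    ercnet_conflict_error = function(e) e)
    if (inherits(row, "condition")) {
      if (strict) stop(row)
      warning("gene ", g, " rejected: ", conditionMessage(row), call. = FALSE)
      rejected <- c(rejected, g)
      next
    }
    values[g, names(row$lengths)] <- row$lengths
    gene_species[[g]] <- row$species
  }
  if (length(rejected)) {
    keep <- setdiff(genes, rejected)
    values <- values[keep, , drop = FALSE]
    gene_species <- gene_species[keep]
  }
  out <- new_branch_rate_matrix(values, topology, gene_species)
  attr(out, "rejected") <- rejected
  out
}

# Place one gene tree on the reference coordinates. Returns list(lengths =
# named numeric (branch id -> length) over identifiable branches, species).
place_gene_tree <- function(phy, topology, gene = "?") {
  sp <- sort(phy$tip.label)
  extra <- setdiff(sp, topology$species)
  if (length(extra)) {
    stop_ercnet("gene ", gene, ": leaves not in the reference species set: ",
                paste(extra, collapse = ", "),
                class = "ercnet_label_error")
  }
  if (anyDuplicated(sp)) {
    stop_ercnet("gene ", gene, ": duplicate leaf labels",
                class = "ercnet_label_error")
  }
  if (is.null(phy$edge.length) || anyNA(phy$edge.length)) {
    stop_ercnet("gene ", gene, ": branch lengths missing",
                class = "ercnet_format_error")
  }
  if (any(phy$edge.length < 0)) {
    stop_ercnet("gene ", gene, ": negative branch length",
                class = "ercnet_format_error")
  }
  if (length(sp) > 3L && ape::is.rooted(phy)) phy <- ape::unroot(phy)
  sides <- edge_far_sides(phy)
  keys <- vapply(sides, function(s) split_key_bits(sp %in% s), character(1))
  lens <- tapply(phy$edge.length, keys, sum)
  ref <- restricted_keys(topology, sp)
  ref_defined <- ref[!is.na(ref)]
  bad <- setdiff(names(lens), ref_defined)
  if (length(bad)) {
    side <- sp[bit_decode(bad[1], length(sp))]
    stop_ercnet("gene ", gene,
                ": split {", paste(side, collapse = ","),
                "} conflicts with the reference topology",
                class = "ercnet_conflict_error")
  }
  map <- unique_restricted_map(topology, sp)
  usable <- intersect(names(lens), names(map))
  out <- as.numeric(lens[usable])
  names(out) <- unname(map[usable])
  list(lengths = out, species = sp)
}

#' Drop genes represented in too few species
#'
#' @param matrix A `branch_rate_matrix`.
#' @param min_species Minimum number of species a gene must be present in
#'   (default 17, matching a 17-of-33 ortholog-presence requirement on
#'   mammalian data).
#' @return The filtered `branch_rate_matrix`, with attribute `"dropped"`:
#'   a data frame of dropped gene ids and their species counts.
#' @export
filter_min_species <- function(matrix, min_species = 17L) {
  stopifnot(inherits(matrix, "branch_rate_matrix"), min_species >= 2)
  n_sp <- vapply(matrix$gene_species, length, integer(1))
  keep <- n_sp >= min_species
  if (!any(keep)) {
    stop_ercnet("all genes dropped at min_species = ", min_species,
                class = "ercnet_empty_error")
  }
  out <- new_branch_rate_matrix(
    matrix$values[keep, , drop = FALSE],
    matrix$topology,
    matrix$gene_species[keep]
  )
  attr(out, "dropped") <- data.frame(
    gene = names(n_sp)[!keep],
    n_species = unname(n_sp[!keep]),
    stringsAsFactors = FALSE
  )
  out
}

#' Genome-average branch-length vector
#'
#' For each canonical branch, the mean branch length over genes having that
#' branch. This is the estimate of the shared (time/phylogeny) component that
#' projection normalization removes.
#'
#' @param matrix A `branch_rate_matrix` with at least 2 genes.
#' @return An `average_rate_vector`: list with `mean` (named numeric, `NA`
#'   where no gene contributes), `count` (contributing genes per branch) and
#'   `branch_ids`.
#' @export
compute_average_vector <- function(matrix) {
  stopifnot(inherits(matrix, "branch_rate_matrix"))
  if (nrow(matrix$values) < 2L) {
    stop_ercnet("need at least 2 genes to average",
                class = "ercnet_empty_error")
  }
  count <- colSums(!is.na(matrix$values))
  mean <- colMeans(matrix$values, na.rm = TRUE)
  mean[count == 0L] <- NA_real_
  structure(
    list(mean = mean, count = count, branch_ids = matrix$topology$branch_ids),
    class = "average_rate_vector"
  )
}

#' @export
print.average_rate_vector <- function(x, ...) {
  cat("average_rate_vector over", length(x$mean), "branches;",
      sum(x$count > 0), "usable\n")
  invisible(x)
}

#' Normalize branch lengths into relative evolutionary rates
#'
#' For each gene g with branch-length vector b over its present branches P,
#' the relative-rate vector is the residual of the orthogonal projection of b
#' onto the genome-average vector a, with inner products restricted to P:
#' \deqn{r_g = b_g - \frac{\langle b_g, a\rangle_P}{\langle a, a\rangle_P} a.}
#' This removes the component shared with the genome-wide average (divergence
#' time plus average rate), leaving gene-specific rate deviations. Raw branch
#' lengths are used by default; `transform` applies an optional variance-
#' stabilizing transform to both the matrix and the average beforehand.
#'
#' @param matrix A `branch_rate_matrix`.
#' @param avg An `average_rate_vector` computed on the same branch coordinate
#'   system (and same transform scale); computed from `matrix` if `NULL`.
#' @param transform One of `"none"` (default), `"sqrt"`, `"log1p"`.
#' @return A `relative_rate_matrix` with the same presence mask. Genes whose
#'   present branches have an all-zero (or absent) average vector cannot be
#'   projected; they are flagged in attribute `"non_normalizable"` and their
#'   rows set to `NA`.
#' @export
normalize_relative_rates <- function(matrix, avg = NULL,
                                     transform = c("none", "sqrt", "log1p")) {
  stopifnot(inherits(matrix, "branch_rate_matrix"))
  transform <- match.arg(transform)
  vals <- apply_transform(matrix$values, transform)
  if (is.null(avg)) {
    tm <- matrix
    tm$values <- vals
    avg <- compute_average_vector(tm)
  }
  stopifnot(inherits(avg, "average_rate_vector"),
            identical(avg$branch_ids, matrix$topology$branch_ids))
  a <- avg$mean
  # Vectorized per-gene projection: inner products restricted to each gene's
  # present branches (and branches with a usable average).
  a0 <- ifelse(is.na(a), 0, a)
  mask <- !is.na(vals)
  v0 <- ifelse(mask, vals, 0)
  usable <- !is.na(a)
  num <- v0[, usable, drop = FALSE] %*% a0[usable]
  den <- (mask[, usable, drop = FALSE] * 1) %*% (a0[usable]^2)
  beta <- as.numeric(num) / as.numeric(den)
  r <- vals - outer(beta, a0)
  r[!mask] <- NA_real_
  bad <- !is.finite(beta)
  flagged <- rownames(vals)[bad]
  if (any(bad)) r[bad, ] <- NA_real_
  dimnames(r) <- dimnames(vals)
  out <- new_branch_rate_matrix(r, matrix$topology, matrix$gene_species,
                                class = c("relative_rate_matrix",
                                          "branch_rate_matrix"))
  attr(out, "non_normalizable") <- flagged
  attr(out, "transform") <- transform
  out
}

apply_transform <- function(values, transform) {
  switch(transform,
         none = values,
         sqrt = sqrt(values),
         log1p = log1p(values))
}

#' Write / read a rate matrix as TSV
#'
#' Genes are rows, canonical branch ids are columns; absent cells are empty.
#' A `species` column (comma-separated species set per gene) is carried along
#' so that species counts survive a round trip: a species set cannot always
#' be recovered from the presence mask alone, because pruning can merge even
#' a terminal branch into its neighbor.
#'
#' @param matrix A `branch_rate_matrix` or `relative_rate_matrix`.
#' @param path Output file path.
#' @export
write_rate_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "branch_rate_matrix"))
  species <- vapply(matrix$gene_species, paste, character(1), collapse = ",")
  utils::write.table(
    cbind(gene = rownames(matrix$values),
          species = unname(species[rownames(matrix$values)]),
          as.data.frame(matrix$values, check.names = FALSE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, na = ""
  )
  invisible(path)
}

#' @rdname write_rate_matrix
#' @param topology The [species_topology()] the matrix was written against.
#'   Column ids must match its canonical branch ids.
#' @export
read_rate_matrix <- function(path, topology) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE)
  genes <- df[["gene"]]
  gene_species <- lapply(strsplit(df[["species"]], ",", fixed = TRUE), sort)
  names(gene_species) <- genes
  vals <- as.matrix(df[, !(names(df) %in% c("gene", "species")), drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- genes
  if (!identical(colnames(vals), topology$branch_ids)) {
    stop_ercnet("matrix columns do not match the topology's branch ids",
                class = "ercnet_format_error")
  }
  new_branch_rate_matrix(vals, topology, gene_species)
}
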