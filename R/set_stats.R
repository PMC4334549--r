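#' Disease gene groupings
#'
#' A `gene_group` names a set of genes annotated to one disease (or pathway).
#'
#' @param name Disease (group) name; nonempty.
#' @param genes Character vector of member gene ids; deduplicated.
#' @param mim Optional character vector of MIM identifiers.
#' @return A `gene_group` object.
#' @export
gene_group <- function(name, genes, mim = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  genes <- unique(as.character(genes))
  if (length(genes) == 0L) {
    stop_ercnet("gene group ", name, " has no genes",
                class = "ercnet_empty_error")
  }
  structure(list(name = name, genes = genes, mim = mim),
            class = "gene_group")
}

#' @export
print.gene_group <- function(x, ...) {
  cat("gene_group '", x$name, "': ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

# Member genes present in the ERC matrix.
present_members <- function(matrix, group) {
  intersect(group$genes, gene_ids(matrix))
}

#' Mean ERC within a gene group
#'
#' Mean over all defined unordered pairs of member genes; undefined pairs are
#' excluded from both numerator and denominator.
#'
#' @param matrix An `erc_matrix`.
#' @param group A `gene_group` (or character vector of gene ids).
#' @return List with `mean` and `n_pairs` (defined pairs used).
#' @export
group_mean_erc <- function(matrix, group) {
  vals <- group_pair_values(matrix, group)
  list(mean = mean(vals), n_pairs = length(vals))
}

#' Fraction of positive ERC values within a gene group
#'
#' @inheritParams group_mean_erc
#' @return Fraction of defined member pairs with ERC > 0.
#' @export
positive_fraction <- function(matrix, group) {
  vals <- group_pair_values(matrix, group)
  mean(vals > 0)
}

# Defined pairwise ERC values among present members, with validation.
group_pair_values <- function(matrix, group) {
  stopifnot(inherits(matrix, "erc_matrix"))
  if (is.character(group)) group <- gene_group("<ad hoc>", group)
  members <- present_members(matrix, group)
  if (length(members) < 2L) {
    stop_ercnet("group '", group$name,
                "' has fewer than 2 genes present in the ERC matrix",
                class = "ercnet_insufficient_error")
  }
  sub <- matrix$values[members, members, drop = FALSE]
  vals <- sub[upper.tri(sub)]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) {
    stop_ercnet("group '", group$name, "' has no defined ERC pairs",
                class = "ercnet_insufficient_error")
  }
  vals
}

# Mean of defined upper-triangle entries of values[idx, idx]; NA if none.
null_group_mean <- function(values, idx) {
  sub <- values[idx, idx]
  m <- mean(sub[upper.tri(sub)], na.rm = TRUE)
  if (is.nan(m)) NA_real_ else m
}

#' Permutation test for elevated mean ERC in a gene group
#'
#' Compares the observed within-group mean ERC against a null distribution of
#' `n_perm` random gene sets of the same size (same count of matrix-present
#' genes), drawn without replacement from all genes in the ERC matrix. The
#' p-value is the fraction of null means greater than or equal to the
#' observed mean; a zero tally is reported censored as "< 1/n_perm" and, for
#' downstream FDR input, imputed at 1/(2 n_perm).
#'
#' @param matrix An `erc_matrix`.
#' @param group A `gene_group`.
#' @param n_perm Number of permutations (default 100000, as used for the
#'   disease-group scans).
#' @param seed Integer seed; fully determines the draw sequence.
#' @return A `group_test_result`: list with `name`, `n_genes` (present),
#'   `n_pairs`, `mean_erc`, `positive_fraction`, `p` (tally fraction),
#'   `p_censored` (logical), `p_display`, `p_fdr` (FDR input), `n_perm`.
#' @export
permutation_test_group <- function(matrix, group, n_perm = 100000L,
                                   seed = NULL) {
  stopifnot(inherits(matrix, "erc_matrix"), n_perm >= 100L)
  if (is.character(group)) group <- gene_group("<ad hoc>", group)
  members <- present_members(matrix, group)
  obs <- group_mean_erc(matrix, group)
  universe <- gene_ids(matrix)
  k <- length(members)
  if (length(universe) < 2L * k) {
    stop_ercnet("gene universe (", length(universe),
                ") is too small for a size-", k, " null",
                class = "ercnet_degenerate_error")
  }
  g <- length(universe)
  values <- matrix$values
  null_means <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      null_group_mean(values, sample.int(g, k))
    }, numeric(1))
  })
  tally <- sum(null_means >= obs$mean, na.rm = TRUE)
  p <- tally / n_perm
  censored <- tally == 0L
  structure(
    list(
      name = group$name,
      n_genes = k,
      n_pairs = obs$n_pairs,
      mean_erc = obs$mean,
      positive_fraction = positive_fraction(matrix, group),
      p = p,
      p_censored = censored,
      p_display = if (censored) paste0("< ", format(1 / n_perm, scientific = FALSE))
                  else format(p, scientific = FALSE),
      p_fdr = if (censored) 1 / (2 * n_perm) else p,
      n_perm = as.integer(n_perm)
    ),
    class = "group_test_result"
  )
}

#' @export
print.group_test_result <- function(x, ...) {
  cat("group '", x$name, "': mean ERC = ", signif(x$mean_erc, 3),
      " over ", x$n_pairs, " pairs; p ", if (x$p_censored) x$p_display
      else paste0("= ", x$p_display), " (", x$n_perm, " permutations)\n",
      sep = "")
  invisible(x)
}

#' Storey q-values and null-proportion estimate
#'
#' Estimates the proportion of true nulls eta0 from the flat right tail of
#' the p-value distribution (Storey's smoother: eta0(lambda) =
#' mean(p > lambda) / (1 - lambda) on a lambda grid, smoothed by a cubic
#' spline and evaluated at the largest lambda), then computes Storey-style
#' q-values q_i = eta0 * m * p_(i) / i with enforced monotonicity.
#' Benjamini-Hochberg adjustment (eta0 fixed at 1) is available as a
#' fallback mode.
#'
#' @param pvals Numeric p-values in [0, 1]. Censored "< 1/N" permutation
#'   p-values should be entered at their imputed value 1/(2N) (`p_fdr` of
#'   [permutation_test_group()]).
#' @param method `"storey"` (default) or `"bh"`.
#' @param lambda Grid for the eta0 smoother (default 0, 0.05, ..., 0.9).
#' @return List with `qvalues` (same order as input) and `eta0`.
#' @export
estimate_qvalues <- function(pvals, method = c("storey", "bh"),
                             lambda = seq(0, 0.9, by = 0.05)) {
  method <- match.arg(method)
  if (length(pvals) == 0L) {
    stop_ercnet("no p-values supplied", class = "ercnet_empty_error")
  }
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop_ercnet("p-values must lie in [0, 1]", class = "ercnet_format_error")
  }
  m <- length(pvals)
  if (method == "bh") {
    return(list(qvalues = stats::p.adjust(pvals, method = "BH"), eta0 = 1))
  }
  eta0 <- estimate_eta0(pvals, lambda)
  o <- order(pvals, decreasing = TRUE)
  ro <- order(o)
  q <- eta0 * m * pvals[o] / (m:1L)
  q <- cummin(pmin(q, 1))
  list(qvalues = q[ro], eta0 = eta0)
}

# Storey's smoother estimate of the null proportion.
estimate_eta0 <- function(pvals, lambda = seq(0, 0.9, by = 0.05)) {
  m <- length(pvals)
  lambda <- sort(unique(lambda))
  raw <- vapply(lambda, function(l) mean(pvals > l) / (1 - l), numeric(1))
  if (length(lambda) < 4L || m < 20L) {
    # Too little information to smooth; fall back to the most conservative
    # grid point.
    return(min(1, max(raw[length(raw)], 0)))
  }
  fit <- tryCatch(stats::smooth.spline(lambda, raw, df = 3),
                  error = function(e) NULL)
  eta0 <- if (is.null(fit)) raw[length(raw)]
          else stats::predict(fit, x = max(lambda))$y
  min(1, max(eta0, 1 / m))
}

#' Scan many gene groups for elevated mean ERC
#'
#' Runs [permutation_test_group()] for every admissible group, computes
#' q-values across the scan, and returns a table sorted by p-value then name.
#' Groups with fewer present genes than `min_group_size` are skipped with a
#' reason (recorded in the `"skipped"` attribute), never silently dropped.
#'
#' @param matrix An `erc_matrix`.
#' @param groups List of `gene_group` objects.
#' @param n_perm Permutations per group.
#' @param seed Master seed; per-group seeds are derived deterministically.
#' @param min_group_size Minimum number of matrix-present genes (default 3;
#'   2 reproduces the looser "more than one gene" admission rule).
#' @param fdr_method Passed to [estimate_qvalues()].
#' @return A data frame with one row per tested group (columns `disease`,
#'   `n_genes`, `n_pairs`, `mean_erc`, `positive_fraction`, `p`, `p_display`,
#'   `q`), sorted by p then name. Attributes: `"eta0"`, `"skipped"`
#'   (data frame of group, reason), `"summary"` (list with counts of groups
#'   with positive mean ERC and below nominal p cutoffs).
#' @export
scan_groups <- function(matrix, groups, n_perm = 100000L, seed = NULL,
                        min_group_size = 3L,
                        fdr_method = c("storey", "bh")) {
  stopifnot(inherits(matrix, "erc_matrix"), length(groups) >= 1L)
  fdr_method <- match.arg(fdr_method)
  if (inherits(groups, "gene_group")) groups <- list(groups)
  names(groups) <- vapply(groups, function(g) g$name, character(1))
  seeds <- derive_seeds(seed, length(groups))
  results <- list()
  skipped <- list()
  for (i in seq_along(groups)) {
    grp <- groups[[i]]
    n_present <- length(present_members(matrix, grp))
    if (n_present < min_group_size) {
      skipped[[grp$name]] <- "below minimum group size"
      next
    }
    res <- tryCatch(
      permutation_test_group(matrix, grp, n_perm = n_perm, seed = seeds[[i]]),
      ercnet_error = function(e) e
    )
    if (inherits(res, "condition")) {
      skipped[[grp$name]] <- conditionMessage(res)
      next
    }
    results[[grp$name]] <- res
  }
  if (length(results) == 0L) {
    stop_ercnet("no admissible groups", class = "ercnet_empty_error")
  }
  tab <- data.frame(
    disease = vapply(results, `[[`, character(1), "name"),
    n_genes = vapply(results, `[[`, integer(1), "n_genes"),
    n_pairs = vapply(results, `[[`, integer(1), "n_pairs"),
    mean_erc = vapply(results, `[[`, numeric(1), "mean_erc"),
    positive_fraction = vapply(results, `[[`, numeric(1), "positive_fraction"),
    p = vapply(results, `[[`, numeric(1), "p"),
    p_fdr = vapply(results, `[[`, numeric(1), "p_fdr"),
    p_display = vapply(results, `[[`, character(1), "p_display"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  fdr <- estimate_qvalues(tab$p_fdr, method = fdr_method)
  tab$q <- fdr$qvalues
  # p first; among tied (typically censored) p-values the observed effect
  # size is the natural secondary key, then name for full determinism
  tab <- tab[order(tab$p_fdr, -tab$mean_erc, tab$disease), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "eta0") <- fdr$eta0
  attr(tab, "skipped") <- if (length(skipped)) {
    data.frame(group = names(skipped),
               reason = unlist(skipped, use.names = FALSE),
               stringsAsFactors = FALSE)
  } else {
    data.frame(group = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  }
  attr(tab, "summary") <- list(
    n_tested = nrow(tab),
    n_positive_mean = sum(tab$mean_erc > 0),
    fraction_positive_mean = mean(tab$mean_erc > 0),
    n_below_0.05 = sum(tab$p_fdr < 0.05),
    n_below_0.01 = sum(tab$p_fdr < 0.01),
    eta0 = fdr$eta0
  )
  tab
}
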