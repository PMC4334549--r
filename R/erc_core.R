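#' Pairwise evolutionary rate covariation (ERC)
#'
#' The ERC value of a gene pair is the correlation coefficient of their
#' relative evolutionary rates over the branches present in both genes. An
#' entry is defined only when the pair shares at least `min_shared` branches
#' and both restricted rate vectors have nonzero variance.
#'
#' @param r1,r2 Relative-rate rows on the same branch coordinate system
#'   (named numeric vectors; `NA` = absent branch).
#' @param min_shared Minimum number of shared branches (default 10).
#' @param method Correlation coefficient: `"pearson"` (default) or
#'   `"spearman"`.
#' @return The ERC value, or `NA` if undefined. The shared-branch count is
#'   attached as attribute `"n_shared"`.
#' @examples
#' r1 <- c(0, 1, 1, 2); r2 <- c(1, 1, 2, 2)
#' erc_pair(r1, r2, min_shared = 2)  # 0.7071
#' @export
erc_pair <- function(r1, r2, min_shared = 10L,
                     method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(r1) != length(r2)) {
    stop_ercnet("rate vectors live on different branch coordinate systems",
                class = "ercnet_structure_error")
  }
  if (!is.null(names(r1)) && !is.null(names(r2)) &&
      !identical(names(r1), names(r2))) {
    stop_ercnet("rate vectors live on different branch coordinate systems",
                class = "ercnet_structure_error")
  }
  shared <- which(!is.na(r1) & !is.na(r2))
  n <- length(shared)
  if (n < max(min_shared, 2L)) {
    return(structure(NA_real_, n_shared = n))
  }
  x <- r1[shared]
  y <- r2[shared]
  if (method == "spearman") {
    x <- rank(x)
    y <- rank(y)
  }
  dx <- x - mean(x)
  dy <- y - mean(y)
  sxx <- sum(dx^2)
  syy <- sum(dy^2)
  if (sxx == 0 || syy == 0) {
    return(structure(NA_real_, n_shared = n))
  }
  structure(sum(dx * dy) / sqrt(sxx * syy), n_shared = n)
}

#' ERC matrix over all gene pairs
#'
#' Computes the symmetric gene-by-gene matrix of ERC values from a
#' relative-rate matrix, together with shared-branch counts. Entries with
#' fewer than `min_shared` shared branches, or with zero variance on the
#' shared branches, are undefined (`NA`) and stay undefined in all downstream
#' statistics (they are never treated as 0). The diagonal is `NA`.
#'
#' @param rates A `relative_rate_matrix` (or any `branch_rate_matrix`).
#' @param min_shared Minimum shared-branch count for a defined entry.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return An `erc_matrix`: list with `values` (G x G, `NA` where undefined),
#'   `counts` (shared-branch counts), and metadata fields `min_shared`,
#'   `method`.
#' @export
erc_matrix <- function(rates, min_shared = 10L,
                       method = c("pearson", "spearman")) {
  stopifnot(inherits(rates, "branch_rate_matrix"))
  method <- match.arg(method)
  vals <- rates$values
  if (nrow(vals) < 2L) {
    stop_ercnet("need at least 2 genes", class = "ercnet_empty_error")
  }
  mask <- !is.na(vals)
  counts <- tcrossprod(mask * 1L)
  storage.mode(counts) <- "integer"
  cors <- suppressWarnings(
    stats::cor(t(vals), use = "pairwise.complete.obs", method = method)
  )
  cors[counts < max(min_shared, 2L)] <- NA_real_
  diag(cors) <- NA_real_
  new_erc_matrix(cors, counts, min_shared = as.integer(min_shared),
                 method = method)
}

new_erc_matrix <- function(values, counts, min_shared, method,
                           source_hash = NA_character_) {
  stopifnot(identical(dim(values), dim(counts)))
  structure(
    list(values = values, counts = counts,
         min_shared = min_shared, method = method,
         source_hash = source_hash),
    class = "erc_matrix"
  )
}

#' @export
print.erc_matrix <- function(x, ...) {
  n <- nrow(x$values)
  off <- x$values[upper.tri(x$values)]
  cat("erc_matrix:", n, "genes;", sum(!is.na(off)), "of", length(off),
      "pairs defined (min_shared =", x$min_shared, ", method =", x$method,
      ")\n")
  invisible(x)
}

#' Look up the ERC value of one gene pair
#' @param matrix An `erc_matrix`.
#' @param g1,g2 Gene ids.
#' @return ERC value or `NA`.
#' @export
erc_value <- function(matrix, g1, g2) {
  stopifnot(inherits(matrix, "erc_matrix"))
  matrix$values[g1, g2]
}

#' Save / load an ERC matrix
#'
#' `save_erc_matrix` writes three plain-text files under a common prefix:
#' `<prefix>.erc.tsv` (square value matrix, empty cell = undefined),
#' `<prefix>.counts.tsv` (shared-branch counts) and `<prefix>.meta.json`
#' (min_shared, method, gene count and an md5 of the value file).
#' `load_erc_matrix` reads them back; with `strict = TRUE` an md5 mismatch of
#' the value file against the recorded hash is an integrity error.
#'
#' @param matrix An `erc_matrix`.
#' @param prefix Path prefix for the three files.
#' @return `save_erc_matrix` returns the prefix invisibly;
#'   `load_erc_matrix` returns the `erc_matrix`.
#' @export
save_erc_matrix <- function(matrix, prefix) {
  stopifnot(inherits(matrix, "erc_matrix"))
  vfile <- paste0(prefix, ".erc.tsv")
  write_square_tsv(matrix$values, vfile)
  write_square_tsv(matrix$counts, paste0(prefix, ".counts.tsv"))
  meta <- list(
    n_genes = nrow(matrix$values),
    min_shared = matrix$min_shared,
    method = matrix$method,
    values_md5 = unname(tools::md5sum(vfile))
  )
  jsonlite::write_json(meta, paste0(prefix, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname save_erc_matrix
#' @param strict Verify the stored md5 of the value file on load.
#' @export
load_erc_matrix <- function(prefix, strict = FALSE) {
  vfile <- paste0(prefix, ".erc.tsv")
  meta <- jsonlite::read_json(paste0(prefix, ".meta.json"),
                              simplifyVector = TRUE)
  if (strict) {
    md5 <- unname(tools::md5sum(vfile))
    if (!identical(md5, meta$values_md5)) {
      stop_ercnet("integrity error: value file hash does not match metadata",
                  class = "ercnet_integrity_error")
    }
  }
  values <- read_square_tsv(vfile)
  counts <- read_square_tsv(paste0(prefix, ".counts.tsv"))
  storage.mode(counts) <- "integer"
  new_erc_matrix(values, counts,
                 min_shared = as.integer(meta$min_shared),
                 method = meta$method,
                 source_hash = meta$values_md5)
}

write_square_tsv <- function(m, path) {
  utils::write.table(
    cbind(gene = rownames(m), as.data.frame(m, check.names = FALSE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, na = ""
  )
  invisible(path)
}

read_square_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  if (!identical(rownames(m), colnames(m))) {
    stop_ercnet("matrix file is not square with matching gene ids",
                class = "ercnet_format_error")
  }
  m
}
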