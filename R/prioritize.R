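#' Candidate gene scores against a training set
#'
#' `group_erc_scores` scores each candidate by its mean ERC over the defined
#' (candidate, training-gene) entries (the GROUP strategy; the default used
#' throughout the package). `best_erc_scores` uses the maximum defined entry
#' instead (the BEST strategy). Candidates with no defined entry get an
#' undefined (`NA`) score and are ranked last.
#'
#' @param matrix An `erc_matrix`.
#' @param training Character vector of training gene ids (disjoint from
#'   candidates; at least one present in the matrix).
#' @param candidates Character vector of candidate gene ids.
#' @return Named numeric vector of scores (NA = undefined).
#' @export
group_erc_scores <- function(matrix, training, candidates) {
  cand_rows(matrix, training, candidates, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else mean(v)
  })
}

#' @rdname group_erc_scores
#' @export
best_erc_scores <- function(matrix, training, candidates) {
  cand_rows(matrix, training, candidates, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else max(v)
  })
}

cand_rows <- function(matrix, training, candidates, f) {
  stopifnot(inherits(matrix, "erc_matrix"))
  if (length(intersect(training, candidates))) {
    stop_ercnet("training and candidate sets must be disjoint",
                class = "ercnet_structure_error")
  }
  tr <- intersect(training, gene_ids(matrix))
  if (length(tr) == 0L) {
    stop_ercnet("no training gene present in the ERC matrix",
                class = "ercnet_insufficient_error")
  }
  scores <- vapply(candidates, function(cand) {
    if (!cand %in% gene_ids(matrix)) return(NA_real_)
    f(matrix$values[cand, tr])
  }, numeric(1))
  names(scores) <- candidates
  scores
}

#' Rank candidates and compute prioritization percentiles
#'
#' Candidates are ranked by descending score (rank 1 = best); ties receive
#' the mean of their occupied ranks. The percentile of a candidate is the
#' fraction of all candidates scoring *strictly lower* (so the top candidate
#' of n sits at (n-1)/n and the bottom at 0). Candidates with undefined
#' scores rank below every defined score and never count as "scoring lower"
#' for other candidates' percentiles.
#'
#' @param scores Named numeric vector of candidate scores (NA = undefined).
#' @return Data frame with columns `candidate`, `score`, `rank`,
#'   `percentile`, sorted by rank.
#' @export
rank_and_percentile <- function(scores) {
  if (length(scores) < 2L) {
    stop_ercnet("need at least 2 candidates", class = "ercnet_empty_error")
  }
  if (all(is.na(scores))) {
    stop_ercnet("all candidate scores are undefined",
                class = "ercnet_insufficient_error")
  }
  n <- length(scores)
  defined <- !is.na(scores)
  rank <- numeric(n)
  # Descending-score average ranks among defined scores.
  rank[defined] <- rank(-scores[defined], ties.method = "average")
  if (any(!defined)) {
    d <- sum(defined)
    rank[!defined] <- mean(seq.int(d + 1L, n))
  }
  percentile <- vapply(seq_len(n), function(i) {
    if (!defined[i]) return(0)
    sum(scores[defined] < scores[i]) / n
  }, numeric(1))
  out <- data.frame(
    candidate = names(scores) %||% as.character(seq_len(n)),
    score = unname(scores),
    rank = rank,
    percentile = percentile,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$rank, out$candidate), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Empirical p-value for a candidate's GROUP score
#'
#' Compares the candidate's GROUP ERC score with the scores of random matrix
#' genes (excluding the training set and the candidate itself): p is the
#' fraction of sampled genes scoring greater than or equal to the candidate.
#' When fewer than `n_rand` genes are available the comparison is exhaustive.
#'
#' @param matrix An `erc_matrix`.
#' @param training Training gene ids.
#' @param candidate A single candidate gene id with a defined GROUP score.
#' @param n_rand Number of random genes to sample (default 1000).
#' @param seed Integer seed.
#' @return List with `p`, `p_censored` (zero tally, reported as < 1/n used),
#'   `p_display`, `n_used`, `score`.
#' @export
empirical_candidate_p <- function(matrix, training, candidate,
                                  n_rand = 1000L, seed = NULL) {
  score <- group_erc_scores(matrix, training, candidate)
  if (is.na(score)) {
    stop_ercnet("candidate ", candidate, " has no defined GROUP score",
                class = "ercnet_insufficient_error")
  }
  pool <- setdiff(gene_ids(matrix), c(training, candidate))
  if (length(pool) == 0L) {
    stop_ercnet("no genes left to sample for the empirical null",
                class = "ercnet_degenerate_error")
  }
  sampled <- if (length(pool) <= n_rand) pool
             else with_seed(seed, sample(pool, n_rand))
  null_scores <- group_erc_scores(matrix, training, sampled)
  tally <- sum(null_scores >= score, na.rm = TRUE)
  n_used <- length(sampled)
  p <- tally / n_used
  censored <- tally == 0L
  list(
    p = p,
    p_censored = censored,
    p_display = if (censored) paste0("< ", format(1 / n_used, scientific = FALSE))
                else format(p, scientific = FALSE),
    n_used = n_used,
    score = unname(score)
  )
}

#' Read a BED4 gene annotation
#'
#' Reads gene coordinates from a BED file (0-based, half-open; 4th column =
#' gene id) into the plain annotation table the prioritization functions use.
#'
#' @param path BED file path.
#' @return Data frame with columns `gene`, `chrom`, `start`, `end` (0-based,
#'   half-open), one row per gene id.
#' @export
read_gene_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- gr$name
  if (is.null(nm) || any(is.na(nm)) || any(!nzchar(nm))) {
    stop_ercnet("BED file lacks gene ids in column 4",
                class = "ercnet_format_error")
  }
  ann <- data.frame(
    gene = nm,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # back to 0-based
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  validate_annotation(ann)
}

validate_annotation <- function(ann) {
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(ann)))
  if (anyDuplicated(ann$gene)) {
    stop_ercnet("annotation has duplicated gene ids",
                class = "ercnet_format_error")
  }
  if (any(ann$start >= ann$end)) {
    stop_ercnet("annotation has intervals with start >= end",
                class = "ercnet_format_error")
  }
  ann
}

#' Candidate genes within a chromosomal window around a target
#'
#' Returns the genes whose interval overlaps the window of total width
#' `window_bp` centered on the target gene's midpoint (same chromosome,
#' half-open window, truncated at coordinate 0). The target itself is always
#' a member of the returned candidate list.
#'
#' @param annotation Annotation data frame (see [read_gene_annotation()]).
#' @param target Target gene id (must be annotated).
#' @param window_bp Total window width in bp (default 1e6, i.e. a 1 Mb
#'   window).
#' @return Character vector of candidate gene ids ordered by start
#'   coordinate.
#' @export
window_candidates <- function(annotation, target, window_bp = 1e6) {
  annotation <- validate_annotation(annotation)
  i <- match(target, annotation$gene)
  if (is.na(i)) {
    stop_ercnet("target gene ", target, " absent from the annotation",
                class = "ercnet_label_error")
  }
  mid <- (annotation$start[i] + annotation$end[i]) / 2
  lo <- max(0, mid - window_bp / 2)
  hi <- mid + window_bp / 2
  same <- annotation$chrom == annotation$chrom[i]
  hit <- same & annotation$start < hi & annotation$end > lo
  cand <- annotation[hit, , drop = FALSE]
  cand$gene[order(cand$start, cand$gene)]
}

#' Leave-one-out prioritization benchmark
#'
#' For every member of every (large enough) group in turn, treats that member
#' as the unknown "target", the remaining members as the training set, and
#' asks where the target's GROUP ERC score ranks among candidates. Candidates
#' are either the target's chromosomal-window neighbors (`mode = "window"`)
#' or random matrix genes scattered across the genome (`mode = "scattered"`,
#' size-matched via `n_scattered`). Each group's training-set permutation
#' p-value is recorded so prioritization success can be stratified by
#' training-set ERC strength.
#'
#' @param matrix An `erc_matrix`.
#' @param groups List of `gene_group` objects.
#' @param annotation Annotation data frame (required for window mode).
#' @param mode `"window"` or `"scattered"`.
#' @param window_bp Window width for window mode (default 1 Mb).
#' @param n_scattered Number of decoy genes in scattered mode (default 90,
#'   comparable to a typical 1 Mb window's candidate count).
#' @param n_perm Permutations for the training-set test.
#' @param seed Master seed.
#' @param min_group_size Groups with fewer present genes are skipped (>= 3 so
#'   every training set keeps >= 2 genes).
#' @return Data frame with one row per (group, target): columns `group`,
#'   `target`, `training_p`, `n_candidates`, `rank`, `percentile`. Attribute
#'   `"skipped"` lists skipped groups; attribute `"by_training_p"` bins the
#'   median percentile by training p-value band.
#' @export
loo_benchmark <- function(matrix, groups, annotation = NULL,
                          mode = c("window", "scattered"),
                          window_bp = 1e6, n_scattered = 90L,
                          n_perm = 1000L, seed = NULL,
                          min_group_size = 3L) {
  mode <- match.arg(mode)
  stopifnot(inherits(matrix, "erc_matrix"))
  if (mode == "window" && is.null(annotation)) {
    stop_ercnet("window mode needs a gene annotation",
                class = "ercnet_format_error")
  }
  if (inherits(groups, "gene_group")) groups <- list(groups)
  min_group_size <- max(min_group_size, 3L)
  seeds <- derive_seeds(seed, 2L * length(groups))
  rows <- list()
  skipped <- list()
  for (gi in seq_along(groups)) {
    grp <- groups[[gi]]
    members <- present_members(matrix, grp)
    if (length(members) < min_group_size) {
      skipped[[grp$name]] <- "below minimum group size"
      next
    }
    scat_seeds <- derive_seeds(seeds[[2L * gi]], length(members))
    for (mi in seq_along(members)) {
      target <- members[mi]
      training <- setdiff(members, target)
      training_p <- tryCatch(
        permutation_test_group(matrix, gene_group(grp$name, training),
                               n_perm = n_perm,
                               seed = seeds[[2L * gi - 1L]])$p_fdr,
        ercnet_error = function(e) NA_real_
      )
      cands <- if (mode == "window") {
        if (!target %in% annotation$gene) next
        window_candidates(annotation, target, window_bp)
      } else {
        pool <- setdiff(gene_ids(matrix), c(training, target))
        n_dec <- min(n_scattered, length(pool))
        c(target, with_seed(scat_seeds[[mi]], sample(pool, n_dec)))
      }
      cands <- setdiff(cands, training)
      if (length(cands) < 2L) next
      scores <- group_erc_scores(matrix, training, cands)
      if (all(is.na(scores))) next
      ranked <- rank_and_percentile(scores)
      ti <- match(target, ranked$candidate)
      rows[[paste(grp$name, target)]] <- data.frame(
        group = grp$name,
        target = target,
        training_p = training_p,
        n_candidates = length(cands),
        rank = ranked$rank[ti],
        percentile = ranked$percentile[ti],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    stop_ercnet("no benchmarkable targets", class = "ercnet_empty_error")
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "skipped") <- names(skipped) %||% character(0)
  attr(out, "by_training_p") <- bin_by_training_p(out)
  out
}

# Median target percentile within training-p bands (Fig.-3-style summary).
bin_by_training_p <- function(bench) {
  breaks <- c(0, 1e-4, 1e-3, 1e-2, 0.05, 1)
  band <- cut(bench$training_p, breaks = breaks, include.lowest = TRUE,
              labels = c("<1e-4", "1e-4..1e-3", "1e-3..0.01",
                         "0.01..0.05", ">0.05"))
  med <- tapply(bench$percentile, band, stats::median)
  n <- tapply(rep(1L, nrow(bench)), band, sum)
  data.frame(
    training_p_band = names(med),
    median_percentile = as.numeric(med),
    n_targets = as.integer(ifelse(is.na(n), 0L, n)),
    stringsAsFactors = FALSE
  )
}
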