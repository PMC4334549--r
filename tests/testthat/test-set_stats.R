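toy_group_matrix <- function() {
  g <- paste0("g", 1:6)
  v <- matrix(NA_real_, 6, 6, dimnames = list(g, g))
  pairs <- rbind(
    c(1, 2, 0.2), c(1, 3, 0.4), c(2, 3, 0.6),
    c(1, 4, -0.5), c(2, 4, 0.5), c(3, 4, 0.1),
    c(1, 5, 0.0), c(2, 5, -0.1), c(3, 5, 0.3), c(4, 5, -0.2),
    c(1, 6, 0.05), c(2, 6, 0.15), c(3, 6, -0.25), c(4, 6, 0.35),
    c(5, 6, -0.45)
  )
  for (k in seq_len(nrow(pairs))) {
    v[pairs[k, 1], pairs[k, 2]] <- v[pairs[k, 2], pairs[k, 1]] <- pairs[k, 3]
  }
  make_erc(v)
}

test_that("group mean ERC averages the defined member pairs only", {
  e <- toy_group_matrix()
  res <- group_mean_erc(e, gene_group("trio", c("g1", "g2", "g3")))
  expect_equal(res$mean, 0.4)
  expect_equal(res$n_pairs, 3L)
  # 2-gene group: the mean is the single pairwise value
  res2 <- group_mean_erc(e, c("g1", "g2"))
  expect_equal(res2$mean, 0.2)
  expect_equal(res2$n_pairs, 1L)
  # undefined pairs drop out of numerator and denominator
  v <- e$values
  v["g1", "g2"] <- v["g2", "g1"] <- NA
  e2 <- make_erc(v)
  res3 <- group_mean_erc(e2, c("g1", "g2", "g3"))
  expect_equal(res3$mean, 0.5)
  expect_equal(res3$n_pairs, 2L)
  # genes absent from the matrix don't count
  expect_error(group_mean_erc(e, c("g1", "zz")),
               class = "ercnet_insufficient_error")
  expect_error(group_mean_erc(e2, gene_group("und", c("g1", "g2"))),
               class = "ercnet_insufficient_error")
})

test_that("positive fraction counts defined pairs above zero", {
  e <- toy_group_matrix()
  expect_equal(positive_fraction(e, c("g1", "g2", "g3")), 1)
  expect_equal(positive_fraction(e, c("g1", "g2", "g4")), 2 / 3)
  # with the {g1,g2} pair undefined only {0.5, -0.5} remain -> 0.5
  v <- e$values
  v["g1", "g2"] <- v["g2", "g1"] <- NA
  expect_equal(positive_fraction(make_erc(v), c("g1", "g2", "g4")), 0.5)
})

test_that("sampled permutation p matches exhaustive enumeration on a small universe", {
  e <- toy_group_matrix()
  grp <- gene_group("trio", c("g1", "g2", "g3"))
  obs <- group_mean_erc(e, grp)$mean
  combos <- utils::combn(paste0("g", 1:6), 3)
  null_means <- apply(combos, 2, function(gs) group_mean_erc(e, gs)$mean)
  p_exact <- mean(null_means >= obs)
  n_perm <- 4000L
  res <- permutation_test_group(e, grp, n_perm = n_perm, seed = 99)
  se <- sqrt(p_exact * (1 - p_exact) / n_perm)
  expect_lt(abs(res$p - p_exact), 3 * se + 1e-12)
  expect_equal(res$mean_erc, obs)
  expect_equal(res$n_genes, 3L)
})

test_that("permutation p is reproducible and monotone in the observed mean", {
  e <- toy_group_matrix()
  grp <- gene_group("trio", c("g1", "g2", "g3"))
  r1 <- permutation_test_group(e, grp, n_perm = 500, seed = 4)
  r2 <- permutation_test_group(e, grp, n_perm = 500, seed = 4)
  expect_identical(r1$p, r2$p)
  # same size, higher observed mean, same seed (same null draws): p can't rise
  lower <- permutation_test_group(e, gene_group("lo", c("g1", "g4", "g5")),
                                  n_perm = 500, seed = 4)
  expect_gte(lower$p, r1$p)
  # a group below every null mean has p = 1
  v <- e$values
  v["g1", "g4"] <- v["g4", "g1"] <- -1
  v["g1", "g5"] <- v["g5", "g1"] <- -1
  v["g4", "g5"] <- v["g5", "g4"] <- -1
  worst <- permutation_test_group(make_erc(v), gene_group("w", c("g1", "g4", "g5")),
                                  n_perm = 300, seed = 1)
  expect_equal(worst$p, 1)
})

test_that("a zero tally is reported censored with the <1/N convention", {
  # make one group's mean unbeatable; with a 40-gene universe the chance of
  # redrawing the group itself in 200 permutations is negligible (and the
  # fixed seed makes the outcome deterministic)
  g <- paste0("g", 1:40)
  set.seed(8)
  v <- matrix(stats::runif(1600, -0.2, 0.2), 40, 40, dimnames = list(g, g))
  v[lower.tri(v)] <- t(v)[lower.tri(v)]
  diag(v) <- NA
  v["g1", "g2"] <- v["g2", "g1"] <- 0.99
  v["g1", "g3"] <- v["g3", "g1"] <- 0.99
  v["g2", "g3"] <- v["g3", "g2"] <- 0.99
  res <- permutation_test_group(make_erc(v), gene_group("top", c("g1", "g2", "g3")),
                                n_perm = 200, seed = 2)
  expect_true(res$p_censored)
  expect_equal(res$p, 0)
  expect_match(res$p_display, "^< 0.005$")
  expect_equal(res$p_fdr, 1 / 400)
})

test_that("a degenerate null universe is refused", {
  e <- toy_group_matrix()
  expect_error(permutation_test_group(e, gene_group("big", paste0("g", 1:4)),
                                      n_perm = 100, seed = 1),
               class = "ercnet_degenerate_error")
})

test_that("q-value estimation recovers the BH table and degenerate cases", {
  # all p = 1: everything is null
  res <- estimate_qvalues(rep(1, 40))
  expect_equal(res$eta0, 1)
  expect_true(all(res$qvalues == 1))
  # hand-computed Benjamini-Hochberg on 4 p-values
  bh <- estimate_qvalues(c(0.001, 0.02, 0.03, 0.5), method = "bh")
  expect_equal(bh$qvalues, c(0.004, 0.04, 0.04, 0.5))
  expect_equal(bh$eta0, 1)
  expect_error(estimate_qvalues(numeric(0)), class = "ercnet_empty_error")
  expect_error(estimate_qvalues(c(0.5, 1.2)), class = "ercnet_format_error")
})

test_that("storey q-values are monotone along sorted p-values", {
  set.seed(31)
  p <- c(stats::rbeta(60, 0.2, 1), stats::runif(140))
  res <- estimate_qvalues(p)
  o <- order(p)
  expect_true(all(diff(res$qvalues[o]) >= -1e-12))
  expect_true(all(res$qvalues >= 0 & res$qvalues <= 1))
  expect_gt(res$eta0, 0)
})

test_that("eta0 recovers the null proportion of a uniform/beta mixture", {
  set.seed(77)
  reps <- 40
  eta0s <- vapply(seq_len(reps), function(i) {
    p <- c(stats::runif(100), stats::rbeta(100, 0.1, 1))
    estimate_qvalues(p)$eta0
  }, numeric(1))
  expect_lt(abs(mean(eta0s) - 0.5), 0.1)
})

test_that("scan_groups skips small groups, sorts by p and is reproducible", {
  e <- toy_group_matrix()
  groups <- list(
    gene_group("solo", "g1"),
    gene_group("duo", c("g1", "g2")),
    gene_group("trio", c("g1", "g2", "g3")),
    gene_group("other", c("g2", "g4", "g5"))
  )
  tab <- scan_groups(e, groups, n_perm = 400, seed = 10, min_group_size = 3)
  expect_setequal(tab$disease, c("trio", "other"))
  skipped <- attr(tab, "skipped")
  expect_setequal(skipped$group, c("solo", "duo"))
  expect_true(all(skipped$reason == "below minimum group size"))
  expect_true(!is.unsorted(tab$p_fdr))
  expect_true(all(c("q", "mean_erc", "positive_fraction") %in% names(tab)))
  tab2 <- scan_groups(e, groups, n_perm = 400, seed = 10, min_group_size = 3)
  expect_identical(tab, tab2)
  # the looser admission rule admits 2-gene groups
  tab3 <- scan_groups(e, groups, n_perm = 400, seed = 10, min_group_size = 2)
  expect_true("duo" %in% tab3$disease)
  s <- attr(tab, "summary")
  expect_equal(s$n_tested, 2L)
  expect_equal(s$fraction_positive_mean, mean(tab$mean_erc > 0))
})
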