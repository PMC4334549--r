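test_that("a gene tree identical to the reference maps onto every branch", {
  topo <- toy_topology()
  d <- withr::local_tempdir()
  write_tree_file(d, "g1", "((a:0.1,b:0.1):0.1,(c:0.1,d:0.1):0.1,e:0.1);")
  m <- load_gene_trees(file.path(d, "g1.nwk"), topo)
  expect_identical(rownames(m$values), "g1")
  expect_true(all(!is.na(m$values)))
  expect_equal(unname(m$values["g1", ]), rep(0.1, 7))
  expect_identical(m$gene_species$g1, letters[1:5])
})

test_that("pruning a species leaves merged branches absent, others mapped", {
  topo <- toy_topology()
  d <- withr::local_tempdir()
  # e missing: the reference branches {c,d} and {c,d,e} both restrict to the
  # same split on {a,b,c,d} and are merged -> absent; e's terminal branch
  # vanishes.
  write_tree_file(d, "g1", "((a:0.2,b:0.1):0.2,(c:0.1,d:0.3):0.1);")
  m <- load_gene_trees(file.path(d, "g1.nwk"), topo)
  v <- m$values["g1", ]
  expect_true(all(is.na(v[c("c,d", "c,d,e", "e")])))
  expect_equal(unname(v[c("b", "b,c,d,e", "c", "d")]), c(0.1, 0.2, 0.1, 0.3))
  expect_identical(m$gene_species$g1, c("a", "b", "c", "d"))
})

test_that("loading is deterministic in file order", {
  topo <- toy_topology()
  d <- withr::local_tempdir()
  f1 <- write_tree_file(d, "g1", "((a:0.1,b:0.2):0.3,(c:0.4,d:0.5):0.6,e:0.7);")
  f2 <- write_tree_file(d, "g2", "((a:0.7,b:0.6):0.5,(c:0.4,d:0.3):0.2,e:0.1);")
  f3 <- write_tree_file(d, "g3", "((a:0.2,b:0.1):0.2,(c:0.1,d:0.3):0.1);")
  m1 <- load_gene_trees(c(f1, f2, f3), topo)
  m2 <- load_gene_trees(c(f3, f1, f2), topo)
  expect_identical(m1$values, m2$values)
  expect_identical(m1$gene_species, m2$gene_species)
})

test_that("load errors name the offending file, leaf, or split", {
  topo <- toy_topology()
  d <- withr::local_tempdir()
  bad <- file.path(d, "broken.nwk")
  writeLines("((a:0.1,b:0.1", bad)
  expect_error(load_gene_trees(bad, topo), "broken.nwk",
               class = "ercnet_format_error")
  alien <- write_tree_file(d, "alien", "((a:1,zz:1):1,(c:1,d:1):1,e:1);")
  expect_error(load_gene_trees(alien, topo), "zz",
               class = "ercnet_label_error")
  confl <- write_tree_file(d, "confl",
                           "((a:1,c:1):1,(b:1,d:1):1,e:1);")
  expect_error(load_gene_trees(confl, topo, strict = TRUE),
               "conflicts with the reference",
               class = "ercnet_conflict_error")
  # non-strict: rejected with a warning, other genes survive
  ok <- write_tree_file(d, "g1", "((a:0.1,b:0.1):0.1,(c:0.1,d:0.1):0.1,e:0.1);")
  expect_warning(m <- load_gene_trees(c(confl, ok), topo), "rejected")
  expect_identical(rownames(m$values), "g1")
  expect_identical(attr(m, "rejected"), "confl")
})

test_that("min-species filtering drops exactly the under-covered genes", {
  set.seed(42)
  phy <- simulate_phylogeny(20, seed = 1)
  d <- withr::local_tempdir()
  # genes covering 10..19 of 20 species
  for (k in 10:19) {
    tr <- ape::keep.tip(phy$tree, phy$topology$species[1:k])
    ape::write.tree(tr, file.path(d, sprintf("gene%02d.nwk", k)))
  }
  m <- load_gene_trees(list.files(d, full.names = TRUE), phy$topology)
  f17 <- filter_min_species(m, 17)
  expect_equal(nrow(f17$values), 3)
  expect_equal(nrow(attr(f17, "dropped")), 7)
  expect_true(all(attr(f17, "dropped")$n_species < 17))
  # a gene present in 16 of the species is dropped at the default threshold
  expect_false("gene16" %in% rownames(f17$values))
  f2 <- filter_min_species(m, 2)
  expect_equal(nrow(f2$values), 10)
  expect_error(filter_min_species(m, 20), class = "ercnet_empty_error")
})

test_that("average vector is the per-branch mean over contributing genes", {
  topo <- species_topology("(a:1,b:1,c:1);")
  v <- matrix(c(1, 2, 3,
                3, 4, 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), topo$branch_ids))
  m <- make_rate_matrix(v, topo)
  avg <- compute_average_vector(m)
  expect_equal(unname(avg$mean), c(2, 3, 4))
  expect_equal(unname(avg$count), c(2L, 2L, 2L))
  # single contributor: the average equals that gene's value with count 1
  v2 <- v
  v2[2, 1] <- NA
  m2 <- make_rate_matrix(v2, topo)
  avg2 <- compute_average_vector(m2)
  expect_equal(unname(avg2$mean[1]), 1)
  expect_equal(unname(avg2$count[1]), 1L)
  expect_error(compute_average_vector(make_rate_matrix(v[1, , drop = FALSE], topo)),
               class = "ercnet_empty_error")
})

test_that("projection normalization matches the closed-form residual", {
  topo <- species_topology("(a:1,b:1,c:1);")
  # choose the second row so the column means are exactly a = (1, 2, 2)
  v <- matrix(c(2, 2, 5,
                0, 2, -1), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), topo$branch_ids))
  m <- make_rate_matrix(v, topo)
  avg <- compute_average_vector(m)
  expect_equal(unname(avg$mean), c(1, 2, 2))
  r <- normalize_relative_rates(m, avg)
  # <b,a> = 16, <a,a> = 9: r = b - (16/9) a
  expect_equal(unname(r$values["g1", ]),
               c(2, 2, 5) - (16 / 9) * c(1, 2, 2), tolerance = 1e-12)
  # a gene exactly proportional to the average projects to zero
  v3 <- rbind(v, g3 = 3 * c(1, 2, 2))
  m3 <- make_rate_matrix(v3, topo)
  r3 <- normalize_relative_rates(m3, avg)
  expect_equal(unname(r3$values["g3", ]), c(0, 0, 0), tolerance = 1e-12)
})

test_that("projection restricted to present branches is orthogonal to the average", {
  topo <- species_topology("(a:1,b:1,c:1);")
  v <- matrix(c(2, 2, 5,
                0, 2, -1,
                2, 2, NA), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), topo$branch_ids))
  avg <- structure(list(mean = stats::setNames(c(1, 2, 2), topo$branch_ids),
                        count = stats::setNames(c(3L, 3L, 2L), topo$branch_ids),
                        branch_ids = topo$branch_ids),
                   class = "average_rate_vector")
  r <- normalize_relative_rates(make_rate_matrix(v, topo), avg)
  # gene missing branch 3: inner product over branches {1, 2} only
  expect_equal(sum(r$values["g3", 1:2] * avg$mean[1:2]), 0, tolerance = 1e-9)
  expect_true(is.na(r$values["g3", 3]))
})

test_that("orthogonality, scale equivariance and mask conservation hold on simulated data", {
  q <- quick_erc(seed = 7, n_genes = 60, path_size = 5)
  m <- q$sim$matrix
  avg <- compute_average_vector(m)
  r <- normalize_relative_rates(m, avg)
  # mask conservation
  expect_identical(is.na(r$values), is.na(m$values))
  # orthogonality over each gene's present branches
  dots <- vapply(seq_len(nrow(r$values)), function(g) {
    idx <- which(!is.na(r$values[g, ]))
    sum(r$values[g, idx] * avg$mean[idx])
  }, numeric(1))
  expect_true(all(abs(dots) < 1e-9))
  # scale equivariance: scaling a gene's lengths by c scales its residual by c
  m2 <- m
  m2$values[3, ] <- 2.5 * m2$values[3, ]
  r2 <- normalize_relative_rates(m2, avg)
  expect_equal(r2$values[3, ], 2.5 * r$values[3, ], tolerance = 1e-12)
})

test_that("genes that cannot be projected are flagged non-normalizable", {
  topo <- species_topology("(a:1,b:1,c:1);")
  v <- matrix(c(0, 0, NA,
                0, 0, 2,
                1, 2, 3), nrow = 3, byrow = TRUE,
              dimnames = list(c("gz", "g2", "g3"), topo$branch_ids))
  avg <- structure(list(mean = stats::setNames(c(0, 0, 2.5), topo$branch_ids),
                        count = stats::setNames(c(3L, 3L, 2L), topo$branch_ids),
                        branch_ids = topo$branch_ids),
                   class = "average_rate_vector")
  r <- normalize_relative_rates(make_rate_matrix(v, topo), avg)
  expect_identical(attr(r, "non_normalizable"), "gz")
  expect_true(all(is.na(r$values["gz", ])))
  expect_false(anyNA(r$values["g3", ]))
})

test_that("optional transforms are applied before averaging and projection", {
  q <- quick_erc(seed = 11, n_genes = 30, path_size = 0)
  m <- q$sim$matrix
  r_sqrt <- normalize_relative_rates(m, transform = "sqrt")
  tm <- m
  tm$values <- sqrt(m$values)
  expect_equal(r_sqrt$values, normalize_relative_rates(tm)$values,
               tolerance = 1e-12)
  expect_identical(attr(r_sqrt, "transform"), "sqrt")
})

test_that("rate matrices round-trip through TSV", {
  q <- quick_erc(seed = 3, n_genes = 25, path_size = 0)
  m <- q$sim$matrix
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rate_matrix(m, path)
  back <- read_rate_matrix(path, m$topology)
  expect_equal(back$values, m$values, tolerance = 1e-12)
  expect_identical(back$gene_species, m$gene_species)
})
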