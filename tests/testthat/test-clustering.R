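test_that("normalization is log2 fold-change with an exact inverse", {
  base <- base_params()
  pop <- matrix(rep(as.numeric(base), each = 5), nrow = 5,
                dimnames = list(NULL, param_names()))
  nm <- normalize_population(pop)
  expect_equal(dim(nm), c(5, 27))
  expect_true(all(nm == 0))

  pop2 <- pop
  pop2[, "tau_si"] <- pop2[, "tau_si"] * 2
  nm2 <- normalize_population(pop2)
  expect_equal(unname(nm2[, "tau_si"]), rep(1, 5))

  back <- denormalize_population(nm2)
  expect_equal(back, pop2, tolerance = 1e-12)

  pop3 <- pop; pop3[2, "tau_fi"] <- -1
  expect_error(normalize_population(pop3), "non-positive")
})

test_that("two separated blobs are clustered perfectly with high cophenetic cc", {
  bl <- blob_population()
  nm <- normalize_population(bl$raw)
  tree <- ahc_linkage(nm)
  expect_gt(tree$cophenetic_cc, 0.95)
  expect_true(all(diff(tree$hclust$height) >= -1e-12))

  cut <- cut_top(tree, nm, 2)
  expect_equal(sum(cut$sizes), nrow(nm))
  # adjusted-Rand-style perfect agreement: memberships coincide with truth
  # up to label swap
  agree <- max(mean(cut$membership == bl$labels),
               mean(cut$membership == 3 - bl$labels))
  expect_equal(agree, 1)

  # centroids near the true blob centers in normalized space
  cz <- cut$centroids_normalized[, 1]
  expect_lt(min(abs(cz - 0)), 3 * 0.1 / sqrt(30))
  expect_lt(min(abs(cz - 6)), 3 * 0.1 / sqrt(30))

  # membership is invariant (up to relabeling) under row permutation
  perm <- withr::with_seed(8, sample(nrow(nm)))
  tree_p <- ahc_linkage(nm[perm, ])
  cut_p <- cut_top(tree_p, nm[perm, ], 2)
  agree_p <- max(mean(cut_p$membership == bl$labels[perm]),
                 mean(cut_p$membership == 3 - bl$labels[perm]))
  expect_equal(agree_p, 1)
})

test_that("top-k cuts nest and handle degenerate k", {
  bl <- blob_population(n_per = 15)
  nm <- normalize_population(bl$raw)
  tree <- ahc_linkage(nm)
  c2 <- cut_top(tree, nm, 2)
  c4 <- cut_top(tree, nm, 4)
  expect_equal(sum(c4$sizes), nrow(nm))
  # k = 2 is a coarsening of k = 4: every k = 4 cluster maps into one
  # k = 2 cluster
  tab <- table(c4$membership, c2$membership)
  expect_true(all(rowSums(tab > 0) == 1))
  # k = n: every point its own cluster
  cn <- cut_top(tree, nm, nrow(nm))
  expect_equal(cn$sizes, rep(1L, nrow(nm)))
})

test_that("an outlier forms its own cluster at k = 2", {
  base <- base_params()
  pop <- matrix(rep(as.numeric(base), each = 12), nrow = 12,
                dimnames = list(NULL, param_names()))
  pop[12, "tau_w1_minus"] <- pop[12, "tau_w1_minus"] * 2^8
  nm <- normalize_population(pop)
  tree <- ahc_linkage(nm)
  cut <- cut_top(tree, nm, 2)
  expect_equal(cut$sizes, c(11L, 1L))
})

test_that("identical populations give a valid tree with undefined cophenetic cc", {
  base <- base_params()
  pop <- matrix(rep(as.numeric(base), each = 4), nrow = 4,
                dimnames = list(NULL, param_names()))
  tree <- ahc_linkage(normalize_population(pop))
  expect_true(is.na(tree$cophenetic_cc))
  expect_true(tree$degenerate)
})

test_that("cophenetic distances correlate perfectly with themselves", {
  bl <- blob_population(n_per = 10)
  tree <- ahc_linkage(normalize_population(bl$raw))
  cd <- cophenetic(tree$hclust)
  expect_equal(cor(cd, cophenetic(tree$hclust)), 1)
})

test_that("percentile constraint removes planted extreme rows only", {
  bl <- blob_population(n_per = 40, sep = 0)  # one homogeneous cloud
  nm <- normalize_population(bl$raw)
  out_rows <- c(3, 17, 29, 51, 66)
  nm[out_rows, 5] <- 40  # far outside every marginal band
  kept <- percentile_constrain(nm, 95)
  expect_true(!any(out_rows %in% attr(kept, "kept_rows")))

  # p = 100 keeps everything
  expect_equal(nrow(percentile_constrain(nm, 100)), nrow(nm))
  # single row survives any p
  one <- nm[1, , drop = FALSE]
  expect_equal(nrow(percentile_constrain(one, 95)), 1)
  expect_error(percentile_constrain(nm, 40), "p > 50")
})

test_that("dendrograms export as parseable Newick trees", {
  bl <- blob_population(n_per = 8)
  tree <- ahc_linkage(normalize_population(bl$raw))
  f <- tempfile(fileext = ".nwk")
  write_newick_tree(tree, f)
  phy <- ape::read.tree(f)
  expect_equal(ape::Ntip(phy), 16)
})
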