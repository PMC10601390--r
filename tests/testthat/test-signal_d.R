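test_that("the d kernel matches hand-derived values on the 4-tip tree", {
  tr <- four_tip_tree()
  expect_equal(sum_sister_differences(tr, c(A = 0, B = 0, C = 0, D = 0)), 0)
  # clade-perfect split: cherries agree, root contributes |1 - 0|
  expect_equal(sum_sister_differences(tr, c(A = 1, B = 1, C = 0, D = 0)), 1)
  # alternating: each cherry contributes 1, root |0.5 - 0.5| = 0
  expect_equal(sum_sister_differences(tr, c(A = 1, B = 0, C = 1, D = 0)), 2)
  expect_error(sum_sister_differences(tr, c(A = 1, B = 0, C = 1)), "missing")
})

test_that("d is symmetric in trait inversion and relabeling of equal-valued tips", {
  tr <- random_tree(40, seed = 9)
  set.seed(9)
  v <- setNames(sample(rep(c(1, 0), c(12, 28))), tr$tip.label)
  expect_equal(sum_sister_differences(tr, v),
               sum_sister_differences(tr, 1 - v))
  # swapping labels between two tips with the same value changes nothing
  ones <- names(v)[v == 1][1:2]
  v2 <- v; v2[ones] <- v[rev(ones)]
  expect_equal(sum_sister_differences(tr, v2), sum_sister_differences(tr, v))
})

test_that("D is invariant under rescaling all branch lengths", {
  tr <- random_tree(60, seed = 4)
  set.seed(4)
  v <- setNames(sample(rep(c(1, 0), c(20, 40))), tr$tip.label)
  f1 <- phylo_d(tr, v, n_perm = 200, seed = 123)
  tr2 <- tr; tr2$edge.length <- tr2$edge.length * 37.5
  f2 <- phylo_d(tr2, v, n_perm = 200, seed = 123)
  expect_equal(f1$D, f2$D, tolerance = 1e-10)
  expect_equal(f1$p_rand, f2$p_rand)
})

test_that("Brownian threshold traits have exact prevalence and seeded determinism", {
  tr <- random_tree(50, seed = 2)
  x <- simulate_brownian_threshold(tr, 17, seed = 5)
  expect_equal(sum(x), 17)
  expect_named(x, tr$tip.label)
  expect_identical(x, simulate_brownian_threshold(tr, 17, seed = 5))
  expect_false(identical(x, simulate_brownian_threshold(tr, 17, seed = 6)))
  expect_error(simulate_brownian_threshold(tr, 0), "prevalence")
  expect_error(simulate_brownian_threshold(tr, 50), "prevalence")
  M <- simulate_brownian_threshold(tr, 10, n = 25, seed = 1)
  expect_equal(unname(colSums(M)), rep(10, 25))
})

test_that("on a star tree every k-subset is equally likely (exchangeability)", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  n_rep <- 1200
  M <- simulate_brownian_threshold(star, 2, n = n_rep, seed = 77)
  key <- apply(M, 2, function(col) paste(which(col == 1), collapse = "-"))
  counts <- table(factor(key, levels = c("1-2", "1-3", "1-4",
                                         "2-3", "2-4", "3-4")))
  p <- stats::chisq.test(counts, p = rep(1 / 6, 6))$p.value
  expect_gt(p, 0.001)
})

test_that("phylo_d rejects degenerate traits and obeys its own identity", {
  tr <- random_tree(30, seed = 8)
  expect_error(phylo_d(tr, setNames(rep(1, 30), tr$tip.label)), "constant")
  set.seed(8)
  v <- setNames(sample(rep(c(1, 0), c(10, 20))), tr$tip.label)
  fit <- phylo_d(tr, v, n_perm = 100, seed = 3)
  expect_equal(fit$D, (fit$d_obs - fit$d_brownian_mean) /
                 (fit$d_random_mean - fit$d_brownian_mean))
  expect_true(fit$p_rand > 0 && fit$p_rand <= 1)
  expect_true(fit$p_brownian > 0 && fit$p_brownian <= 1)
  expect_equal(fit$prevalence, 10)
  # determinism under a fixed seed
  fit2 <- phylo_d(tr, v, n_perm = 100, seed = 3)
  expect_equal(fit$D, fit2$D)
})

test_that("D anchors land near 0 for Brownian traits and 1 for shuffles", {
  tr <- simulate_tree(120, seed = 21)
  Db <- Dr <- numeric(25)
  base <- rep(c(1, 0), c(36, 84))
  for (i in seq_len(25)) {
    tb <- simulate_brownian_threshold(tr, 36, seed = 400 + i)
    Db[i] <- phylo_d(tr, tb, n_perm = 150, seed = 500 + i)$D
    set.seed(600 + i)
    ts <- setNames(sample(base), tr$tip.label)
    Dr[i] <- phylo_d(tr, ts, n_perm = 150, seed = 700 + i)$D
  }
  expect_lt(abs(mean(Db)), 0.2)
  expect_lt(abs(mean(Dr) - 1), 0.2)
})

test_that("p_rand is uniform under its own shuffle null", {
  tr <- simulate_tree(60, seed = 31)
  base <- rep(c(1, 0), c(18, 42))
  p <- numeric(120)
  for (i in seq_len(120)) {
    set.seed(900 + i)
    v <- setNames(sample(base), tr$tip.label)
    p[i] <- phylo_d(tr, v, n_perm = 99, seed = 2000 + i)$p_rand
  }
  # p is discrete at (n_perm + 1) levels; the KS tie warning is expected
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.001)
})
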