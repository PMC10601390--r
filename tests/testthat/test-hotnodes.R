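test_that("clade counts conserve totals and match descendant enumeration", {
  tr <- ape::read.tree(text = "(((A:1,B:1):1,(C:1,D:1):1):1,(E:2,F:2):1);")
  trait <- c(A = 1, B = 1, C = 0, D = 0, E = 1, F = 0)
  cc <- clade_counts(tr, trait)
  expect_equal(cc$focal_count[cc$node == ape::Ntip(tr) + 1L], 3)  # root
  for (i in seq_len(nrow(cc))) {
    tips <- bf_descendant_tips(tr, cc$node[i])
    expect_equal(cc$clade_size[i], length(tips))
    expect_equal(cc$focal_count[i], sum(trait[tips]))
  }
  # parents dominate children
  for (i in seq_len(nrow(cc))) {
    kids <- tr$edge[tr$edge[, 1] == cc$node[i], 2]
    for (k in kids[kids > ape::Ntip(tr)]) {
      expect_gte(cc$focal_count[i], cc$focal_count[cc$node == k])
    }
  }
})

test_that("random traits match clade count conservation on random trees", {
  for (seed in 1:10) {
    tr <- random_tree(sample(8:20, 1), seed = seed)
    set.seed(seed)
    v <- setNames(rbinom(ape::Ntip(tr), 1, 0.4), tr$tip.label)
    cc <- clade_counts(tr, v)
    expect_equal(cc$focal_count[cc$node == ape::Ntip(tr) + 1L], sum(v))
    i <- sample(nrow(cc), 1)
    expect_equal(cc$focal_count[i],
                 sum(v[bf_descendant_tips(tr, cc$node[i])]))
  }
})

test_that("permutation moments agree with the hypergeometric closed form", {
  tr <- simulate_tree(120, seed = 51)
  set.seed(51)
  v <- setNames(sample(rep(c(1, 0), c(30, 90))), tr$tip.label)
  scan <- hot_node_scan(tr, v, min_clade = 10, n_perm = 999, seed = 3)
  n <- 120; k <- 30
  m <- scan$clade_size
  mean_hg <- m * k / n
  sd_hg <- sqrt(m * (k / n) * (1 - k / n) * (n - m) / (n - 1))
  # Monte-Carlo error at 999 permutations: means within a few SE
  se_mean <- sd_hg / sqrt(999)
  expect_true(all(abs(scan$null_mean - mean_hg) < 5 * se_mean + 1e-9))
  proper <- m < n  # the root clade always holds all positives: sd exactly 0
  expect_true(all(abs(scan$null_sd[proper] - sd_hg[proper]) /
                    sd_hg[proper] < 0.2))
  expect_equal(scan$null_sd[!proper], rep(0, sum(!proper)))
})

test_that("a planted clade is flagged hot; a constant trait warns", {
  tr <- simulate_tree(300, seed = 61)
  members <- plant_in_clades_for_test(tr, 30, seed = 4)
  v <- setNames(as.integer(tr$tip.label %in% members), tr$tip.label)
  scan <- hot_node_scan(tr, v, min_clade = 10, n_perm = 299, seed = 9)
  expect_true(any(scan$is_hot))
  # the top hot clade should consist mostly of planted members
  top <- scan[which.max(scan$ses), ]
  expect_gt(top$focal_count / top$clade_size, 0.8)
  # maximal filter returns a subset of hot rows
  mx <- maximal_hot_nodes(tr, scan)
  expect_true(all(mx$node %in% scan$node[scan$is_hot]))
  expect_gte(nrow(scan[scan$is_hot, ]), nrow(mx))

  expect_warning(hot_node_scan(tr, setNames(rep(1, 300), tr$tip.label),
                               n_perm = 19), "constant")
})

test_that("false-flag rate under shuffled traits stays near the threshold tail", {
  tr <- simulate_tree(150, seed = 71)
  base <- rep(c(1, 0), c(45, 105))
  rates <- numeric(40)
  for (i in seq_len(40)) {
    set.seed(7000 + i)
    v <- setNames(sample(base), tr$tip.label)
    scan <- hot_node_scan(tr, v, min_clade = 10, n_perm = 199,
                          seed = 8000 + i)
    rates[i] <- mean(scan$is_hot)
  }
  # one-sided 1.96 threshold: upper-tail mass ~0.025, discreteness-inflated
  expect_lt(mean(rates), 0.08)
})

test_that("annotation round-trips ses labels and rejects stale results", {
  tr <- simulate_tree(120, seed = 81)
  members <- plant_in_clades_for_test(tr, 20, seed = 5)
  v <- setNames(as.integer(tr$tip.label %in% members), tr$tip.label)
  scan <- hot_node_scan(tr, v, min_clade = 10, n_perm = 199, seed = 6)
  ann <- annotate_tree(tr, scan)
  expect_equal(sum(nzchar(ann$node.label)), sum(scan$is_hot))

  tmp <- withr::local_tempfile(fileext = ".nwk")
  write_newick(ann, tmp)
  back <- read_newick(tmp)
  got <- sort(as.numeric(sub("HOT\\|ses=", "",
                             back$node.label[nzchar(back$node.label)])))
  expect_equal(got, sort(round(scan$ses[scan$is_hot], 4)), tolerance = 1e-8)

  other <- simulate_tree(120, seed = 82)
  expect_error(annotate_tree(other, scan), "stale|match")
})
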