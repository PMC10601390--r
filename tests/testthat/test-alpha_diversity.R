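test_that("PD, MPD and MNTD match the worked 4-tip values", {
  tr <- four_tip_tree()
  expect_equal(faith_pd(tr, c("A", "B", "C", "D")), 6)  # whole tree
  expect_equal(faith_pd(tr, c("A", "B")), 3)
  expect_equal(faith_pd(tr, c("A", "B"), include_root = FALSE), 2)
  expect_equal(faith_pd(tr, "A"), 2)
  expect_equal(mpd_guild(tr, c("A", "B", "C", "D")), 20 / 6)
  expect_equal(mntd_guild(tr, c("A", "B", "C", "D")), 2)
  expect_equal(mpd_guild(tr, c("A", "C")), 4)
  expect_equal(mntd_guild(tr, c("A", "C")), 4)
  expect_error(mpd_guild(tr, "A"), "two species")
  expect_error(faith_pd(tr, c("A", "Z")), "Z")
})

test_that("metrics equal brute-force path enumeration on small random trees", {
  for (seed in 1:10) {
    n <- sample(4:6, 1)
    tr <- random_tree(n, seed = seed)
    set.seed(seed)
    tr$edge.length <- stats::runif(length(tr$edge.length), 0.1, 2)
    taxa <- sample(tr$tip.label, sample(2:n, 1))
    expect_equal(faith_pd(tr, taxa), bf_pd(tr, taxa), tolerance = 1e-9)
    expect_equal(faith_pd(tr, taxa, include_root = FALSE),
                 bf_pd(tr, taxa, include_root = FALSE), tolerance = 1e-9)
    expect_equal(mpd_guild(tr, taxa), bf_mpd(tr, taxa), tolerance = 1e-9)
    expect_equal(mntd_guild(tr, taxa), bf_mntd(tr, taxa), tolerance = 1e-9)
  }
})

test_that("PD is monotone under adding species and exact on the full set", {
  tr <- random_tree(40, seed = 12)
  set.seed(12)
  taxa <- sample(tr$tip.label, 10)
  pd0 <- faith_pd(tr, taxa)
  for (extra in sample(setdiff(tr$tip.label, taxa), 5)) {
    pd1 <- faith_pd(tr, c(taxa, extra))
    expect_gte(pd1, pd0 - 1e-12)
    taxa <- c(taxa, extra); pd0 <- pd1
  }
  expect_equal(faith_pd(tr, tr$tip.label), sum(tr$edge.length))
})

test_that("ses_alpha flags planted clades and degrades gracefully on the full pool", {
  tr <- simulate_tree(200, seed = 33)
  # find a mid-sized clade: clustered by construction
  ntip <- ape::Ntip(tr)
  sizes <- vapply((ntip + 2):(ntip + tr$Nnode), function(nd)
    length(bf_descendant_tips(tr, nd)), integer(1))
  node <- ((ntip + 2):(ntip + tr$Nnode))[which(sizes >= 15 & sizes <= 60)[1]]
  clade <- bf_descendant_tips(tr, node)
  res <- ses_alpha(tr, clade, "PD", n_null = 199, seed = 17)
  expect_lt(res$p, 0.05)
  expect_lt(res$ses, 0)
  # degenerate pool: every draw is the observed set
  res_full <- ses_alpha(tr, tr$tip.label, "PD", n_null = 49, seed = 1)
  expect_true(is.na(res_full$ses))
  expect_equal(res_full$p, 1)
})

test_that("guild_summary mirrors ses_alpha, is deterministic, and matches picante's observed metrics", {
  ds <- make_study_like_dataset(seed = 3)
  tr <- ds$tree
  s1 <- guild_summary(tr, ds$traits, guilds = c("condiment", "wrapping"),
                      n_null = 99, seed = 5)
  s2 <- guild_summary(tr, ds$traits, guilds = c("condiment", "wrapping"),
                      n_null = 99, seed = 5)
  expect_equal(s1, s2)
  expect_equal(s1$SR, c(51, 26))
  # clade-planted guilds should read as clustered
  expect_lt(s1$p.PD[s1$guild == "condiment"], 0.05)

  skip_if_not_installed("picante")
  comm <- matrix(0, 2, ape::Ntip(tr),
                 dimnames = list(c("condiment", "wrapping"), tr$tip.label))
  comm["condiment", guild_members(ds$traits, "condiment")] <- 1
  comm["wrapping", guild_members(ds$traits, "wrapping")] <- 1
  pd_ref <- picante::pd(comm, tr, include.root = TRUE)
  expect_equal(s1$PD, pd_ref$PD, tolerance = 1e-8)
  dis <- ape::cophenetic.phylo(tr)
  expect_equal(s1$MPD, unname(picante::mpd(comm, dis)), tolerance = 1e-8)
  expect_equal(s1$MNTD, unname(picante::mntd(comm, dis)), tolerance = 1e-8)
})

test_that("identical-membership guilds give identical rows under one seed", {
  ds <- make_study_like_dataset(seed = 9)
  traits <- ds$traits
  traits$condiment2 <- traits$condiment
  # condiment2 is not a standard column; bypass via direct ses calls
  a <- guild_summary(ds$tree, traits, guilds = c("condiment"),
                     n_null = 49, seed = 11)
  traits2 <- traits; traits2$condiment <- traits$condiment2
  b <- guild_summary(ds$tree, traits2, guilds = c("condiment"),
                     n_null = 49, seed = 11)
  expect_equal(a[-1], b[-1])
})

test_that("p under the tip-pool null is calibrated for random guilds", {
  tr <- simulate_tree(100, seed = 41)
  p <- numeric(200)
  for (i in seq_len(200)) {
    set.seed(3000 + i)
    taxa <- sample(tr$tip.label, 15)
    p[i] <- ses_alpha(tr, taxa, "PD", n_null = 99, seed = 4000 + i)$p
  }
  # empirical P(p < 0.05) should sit near its discrete null mass (5/100)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.04)
})
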