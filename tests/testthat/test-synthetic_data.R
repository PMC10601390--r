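test_that("simulated trees are ultrametric, unit-depth, deterministic", {
  tr <- simulate_tree(4, seed = 1)
  expect_true(is_ultrametric_tree(tr, tol = 1e-9))
  expect_equal(max(ape::node.depth.edgelength(tr)[1:4]), 1)
  expect_identical(ape::write.tree(simulate_tree(50, seed = 9)),
                   ape::write.tree(simulate_tree(50, seed = 9)))
  big <- simulate_tree(500, seed = 2)
  expect_equal(big$Nnode, 499)  # fully bifurcating
  expect_error(simulate_tree(1), "at least 2")
})

test_that("assigned taxonomies are clade-respecting partitions", {
  tr <- random_tree(60, seed = 14)
  tax <- assign_taxonomy(tr, n_genera = 25, n_families = 8, seed = 14)
  tn <- tax$tree
  expect_equal(length(unique(tax$taxonomy$genus)), 25)
  expect_equal(length(unique(tax$taxonomy$family)), 8)
  expect_equal(tax$taxonomy$species, tn$tip.label)

  # each genus's tips form a clade: MRCA purity via brute-force descendants
  for (g in unique(tax$taxonomy$genus)) {
    tips <- tax$taxonomy$species[tax$taxonomy$genus == g]
    if (length(tips) == 1) next
    mrca <- bf_mrca(tn, tips)
    expect_setequal(bf_descendant_tips(tn, mrca), tips)
  }
  # families partition genera
  g2f <- unique(tax$taxonomy[c("genus", "family")])
  expect_equal(nrow(g2f), 25)
  # every genus monotypic at the boundary
  tax1 <- assign_taxonomy(random_tree(10, seed = 3), 10, 3, seed = 3)
  expect_equal(anyDuplicated(tax1$taxonomy$genus), 0)
})

test_that("guild simulation realizes sizes exactly for every clustering mode", {
  tr <- simulate_tree(100, seed = 25)
  tab <- simulate_use_traits(tr, list(
    big = list(size = 60, clustering = "brownian"),
    inner = list(size = 20, clustering = "random", parent = "big"),
    packed = list(size = 15, clustering = "clade"),
    far = list(size = 10, clustering = "clade", exclude = "packed")
  ), seed = 31)
  expect_equal(colSums(tab[-1]), c(big = 60, inner = 20, packed = 15, far = 10))
  # nesting honoured
  expect_true(all(tab$big[tab$inner == 1] == 1))
  # exclusion honoured
  expect_false(any(tab$packed == 1 & tab$far == 1))
  expect_error(simulate_use_traits(tr, list(
    a = list(size = 5, clustering = "random"),
    b = list(size = 10, clustering = "random", parent = "a"))), "pool")
})

test_that("generator modes are recovered by the signal statistic", {
  tr <- simulate_tree(150, seed = 35)
  D_clade <- D_rand <- numeric(5)
  for (i in 1:5) {
    tab <- simulate_use_traits(tr, list(
      planted = list(size = 40, clustering = "clade"),
      scattered = list(size = 40, clustering = "random")
    ), seed = 100 + i)
    vp <- setNames(tab$planted, tab$species)
    vs <- setNames(tab$scattered, tab$species)
    D_clade[i] <- phylo_d(tr, vp, n_perm = 150, seed = 200 + i)$D
    D_rand[i] <- phylo_d(tr, vs, n_perm = 150, seed = 300 + i)$D
  }
  expect_lt(mean(D_clade), mean(D_rand))
  expect_lt(mean(D_clade), 0.5)
  expect_gt(mean(D_rand), 0.7)
})

test_that("the study-like dataset reproduces its guild sizes and invariants", {
  ds <- make_study_like_dataset(seed = 17)
  expect_true(is_ultrametric_tree(ds$tree, 1e-9))
  expect_equal(ape::Ntip(ds$tree), 473)
  sr <- colSums(ds$traits[c("edible", "condiment", "wrapping",
                            "cultivated", "wild")])
  expect_equal(unname(sr), c(437, 51, 26, 55, 416))
  # full determinism from one master seed
  ds2 <- make_study_like_dataset(seed = 17)
  expect_identical(ape::write.tree(ds$tree), ape::write.tree(ds2$tree))
  expect_identical(ds$traits, ds2$traits)
  expect_identical(ds$taxonomy, ds2$taxonomy)
  # every species carries at least one use flag
  expect_true(all(rowSums(ds$traits[use_flag_columns()]) >= 1))
  # trait species set equals the tip set
  expect_setequal(ds$traits$species, ds$tree$tip.label)
  # condiment and wrapping planted apart: no shared members
  expect_false(any(ds$traits$condiment == 1 & ds$traits$wrapping == 1))
})

test_that("hot-node scans detect the planted condiment clades in the study-like data", {
  ds <- make_study_like_dataset(seed = 29)
  v <- setNames(ds$traits$condiment, ds$traits$species)
  scan <- hot_node_scan(ds$tree, v, min_clade = 10, n_perm = 199, seed = 2)
  expect_true(any(scan$is_hot))
})
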