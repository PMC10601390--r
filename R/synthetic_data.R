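# Synthetic datasets with known ground truth.
#
# Yule trees (ultrametric by construction, scaled to unit depth), clade-
# respecting genus/family taxonomies so crown-node grafting is exercised,
# and guild tables whose clustering structure is chosen per guild: uniform
# draws ("random"), Brownian-threshold draws ("brownian"), or species
# packed into the smallest set of disjoint clades reaching the requested
# size ("clade"). Guild sizes are realized exactly, so recovery tests have
# sharp expectations.

#' Simulate a pure-birth (Yule) ultrametric tree
#'
#' Tips are labeled `G<i>_s1` (binomial-shaped, one genus per tip until a
#' taxonomy is assigned) and the tree is rescaled to unit root-to-tip
#' depth.
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Optional RNG seed.
#' @return An ultrametric `phylo` object.
#' @export
simulate_tree <- function(n_tips, seed = NULL) {
  if (n_tips < 2L) stop("need at least 2 tips", call. = FALSE)
  maybe_seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  depth <- max(tip_depths(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- paste0("G", seq_len(n_tips), "_s1")
  tree
}

# Split a tree's tip set into k monophyletic blocks by repeatedly breaking
# the largest current block (random tie-break) at its root node. Returns a
# list of integer tip-index vectors in left-to-right tip order.
clade_partition <- function(tree, k) {
  info <- tree_info(tree)
  ntip <- info$ntip
  if (k > ntip) stop("cannot cut ", ntip, " tips into ", k, " blocks",
                     call. = FALSE)
  sizes <- accumulate_counts(info, matrix(1, ntip, 1))[, 1]
  blocks <- info$root  # node numbers; tips count as unsplittable blocks
  while (length(blocks) < k) {
    splittable <- blocks[blocks > ntip]
    big <- splittable[sizes[splittable] == max(sizes[splittable])]
    pick <- if (length(big) == 1L) big else sample(big, 1L)
    ch <- info$edge[info$child_rows[[as.character(pick)]], 2]
    blocks <- c(setdiff(blocks, pick), ch)
  }
  sets <- clade_tip_sets(tree)
  tip_idx <- lapply(blocks, function(b) which(tree$tip.label %in% sets[[b]]))
  tip_idx[order(vapply(tip_idx, min, integer(1)))]
}

#' Assign a clade-respecting genus/family taxonomy to a tree
#'
#' Families are monophyletic tip blocks; genera subdivide families (every
#' genus's tips form a clade, and no genus spans two families), so genus
#' and family crown nodes are well-defined for grafting tests. Tip labels
#' are rewritten to `Genus<g>_sp<i>` binomials.
#'
#' @param tree A `phylo` object.
#' @param n_genera Number of genera (`n_families <= n_genera <= Ntip`).
#' @param n_families Number of families.
#' @param seed Optional RNG seed (tie-breaks among equal-size blocks).
#' @return A list with `tree` (relabeled) and `taxonomy` (data frame
#'   `species`, `genus`, `family` in tip order).
#' @export
assign_taxonomy <- function(tree, n_genera, n_families, seed = NULL) {
  ntip <- ape::Ntip(tree)
  stopifnot(n_families >= 1L, n_families <= n_genera, n_genera <= ntip)
  maybe_seed(seed)
  fam_blocks <- clade_partition(tree, n_families)

  # subdivide each family block independently; distribute the extra splits
  # proportionally to family size (largest remainders first)
  fam_sizes <- lengths(fam_blocks)
  quota <- pmax(1, floor(n_genera * fam_sizes / ntip))
  quota <- pmin(quota, fam_sizes)
  while (sum(quota) < n_genera) {
    room <- which(quota < fam_sizes)
    i <- room[which.max(fam_sizes[room] / quota[room])]
    quota[i] <- quota[i] + 1L
  }
  while (sum(quota) > n_genera) {
    i <- which(quota > 1L)[which.max(quota[quota > 1L])]
    quota[i] <- quota[i] - 1L
  }

  genus <- character(ntip)
  family <- character(ntip)
  g <- 0L
  for (f in seq_along(fam_blocks)) {
    idx <- fam_blocks[[f]]
    sub <- ape::keep.tip(tree, tree$tip.label[idx])
    sub_blocks <- clade_partition(sub, quota[f])
    for (blk in sub_blocks) {
      g <- g + 1L
      orig <- match(sub$tip.label[blk], tree$tip.label)
      genus[orig] <- paste0("Genus", g)
      family[orig] <- paste0("Family", f)
    }
  }
  species <- character(ntip)
  for (gn in unique(genus)) {
    at <- which(genus == gn)
    species[at] <- paste0(gn, "_sp", seq_along(at))
  }
  tree$tip.label <- species
  list(tree = tree,
       taxonomy = data.frame(species = species, genus = genus,
                             family = family, stringsAsFactors = FALSE))
}

# Fill a guild by packing whole clades: greedily take the largest clade
# (within `pool`, avoiding `exclude` and already-chosen tips) that still
# fits; when nothing fits, take the smallest sufficient clade and trim the
# overflow at random. Returns species names; size realized exactly.
plant_in_clades <- function(tree, size, pool = NULL, exclude = character(0)) {
  if (is.null(pool)) pool <- tree$tip.label
  pool <- setdiff(pool, exclude)
  if (size > length(pool)) {
    stop("guild size ", size, " exceeds available pool (", length(pool), ")",
         call. = FALSE)
  }
  sets <- clade_tip_sets(tree)
  eff <- lapply(sets, function(s) setdiff(intersect(s, pool), exclude))
  chosen <- character(0)
  remaining <- size
  while (remaining > 0L) {
    ok <- vapply(eff, function(s)
      length(s) > 0L && !any(s %in% chosen), logical(1))
    ns <- lengths(eff)
    fits <- which(ok & ns <= remaining)
    if (length(fits)) {
      best <- fits[ns[fits] == max(ns[fits])]
      pick <- if (length(best) == 1L) best else sample(best, 1L)
      chosen <- c(chosen, eff[[pick]])
      remaining <- remaining - length(eff[[pick]])
    } else {
      over <- which(ok & ns > remaining)
      best <- over[ns[over] == min(ns[over])]
      pick <- if (length(best) == 1L) best else sample(best, 1L)
      chosen <- c(chosen, sample(eff[[pick]], remaining))
      remaining <- 0L
    }
  }
  chosen
}

#' Simulate binary use guilds with chosen clustering structure
#'
#' Each guild is a named entry of `guild_spec`: a list with `size`
#' (realized exactly), `clustering` (`"random"`, `"brownian"` or
#' `"clade"`), optional `parent` (an earlier guild whose members form the
#' sampling pool — nested guilds), and optional `exclude` (an earlier
#' guild whose members' clades are avoided — distant guilds).
#'
#' @param tree A `phylo` object.
#' @param guild_spec Named list of guild specifications; parents must
#'   precede their children.
#' @param seed Optional RNG seed.
#' @return Data frame with `species` plus one 0/1 integer column per guild.
#' @export
simulate_use_traits <- function(tree, guild_spec, seed = NULL) {
  maybe_seed(seed)
  tips <- tree$tip.label
  out <- data.frame(species = tips, stringsAsFactors = FALSE)
  members_of <- list()
  for (g in names(guild_spec)) {
    spec <- guild_spec[[g]]
    pool <- tips
    if (!is.null(spec$parent)) {
      if (is.null(members_of[[spec$parent]])) {
        stop("guild '", g, "': parent '", spec$parent,
             "' must be generated first", call. = FALSE)
      }
      pool <- members_of[[spec$parent]]
    }
    if (spec$size > length(pool)) {
      stop("guild '", g, "' (", spec$size,
           ") larger than its pool (", length(pool), ")", call. = FALSE)
    }
    exclude <- if (is.null(spec$exclude)) character(0) else
      members_of[[spec$exclude]]
    members <- switch(spec$clustering,
      random = sample(setdiff(pool, exclude), spec$size),
      brownian = {
        avail <- setdiff(pool, exclude)
        vals <- bm_tip_values(tree)[avail, 1]
        avail[order(vals, decreasing = TRUE)[seq_len(spec$size)]]
      },
      clade = plant_in_clades(tree, spec$size, pool, exclude),
      stop("unknown clustering '", spec$clustering, "' for guild '", g, "'",
           call. = FALSE)
    )
    members_of[[g]] <- members
    out[[g]] <- as.integer(tips %in% members)
  }
  out
}

#' Generate a study-like synthetic dataset
#'
#' A 473-tip Yule tree with a clade-respecting taxonomy and a full 17-flag
#' use-trait table whose guild sizes match the study conditions exactly:
#' edible 437, condiment 51, wrapping 26, cultivated 55, wild 416.
#' Condiment is clade-planted (strong signal), wrapping is clade-planted in
#' lineages away from condiment (high turnover between the two), edible is
#' Brownian-flavored: it contains every species with no other use flag,
#' topped up to 437 with the highest Brownian scores among
#' condiment/wrapping members — so all 473 species carry at least one use
#' flag. Cultivated is clade-planted and wild uniform; the two management
#' flags may overlap. Organ flags are independent Bernoulli draws at
#' field-plausible prevalences.
#'
#' @param seed Master seed; every component draws from a derived child
#'   stream ([derive_seed()]), so the whole dataset is reproducible
#'   bit-for-bit.
#' @return An object of class `synthetic_dataset`: a list with `tree`,
#'   `taxonomy`, `traits` and `params`.
#' @export
make_study_like_dataset <- function(seed = 1) {
  n_tips <- 473L
  sizes <- c(edible = 437L, condiment = 51L, wrapping = 26L,
             cultivated = 55L, wild = 416L)
  tree <- simulate_tree(n_tips, derive_seed(seed, "tree"))
  tax <- assign_taxonomy(tree, n_genera = 320, n_families = 96,
                         seed = derive_seed(seed, "taxonomy"))
  tree <- tax$tree

  guilds <- simulate_use_traits(tree, list(
    condiment = list(size = sizes[["condiment"]], clustering = "clade"),
    wrapping = list(size = sizes[["wrapping"]], clustering = "clade",
                    exclude = "condiment"),
    cultivated = list(size = sizes[["cultivated"]], clustering = "clade"),
    wild = list(size = sizes[["wild"]], clustering = "random")
  ), seed = derive_seed(seed, "guilds"))

  # edible: every species with no other use flag, plus the top Brownian
  # scores among condiment/wrapping members up to 437
  tips <- tree$tip.label
  in_other <- guilds$condiment == 1L | guilds$wrapping == 1L
  base <- tips[!in_other]
  need <- sizes[["edible"]] - length(base)
  stopifnot(need >= 0, need <= sum(in_other))
  maybe_seed(derive_seed(seed, "edible"))
  vals <- bm_tip_values(tree)[tips[in_other], 1]
  extra <- tips[in_other][order(vals, decreasing = TRUE)[seq_len(need)]]
  edible <- as.integer(tips %in% c(base, extra))

  maybe_seed(derive_seed(seed, "organs"))
  organ_prev <- c(root_rhizome_bulb = 0.08, stem = 0.10, bark = 0.02,
                  wood = 0.02, leaf = 0.28, flowers = 0.15, fruits = 0.35,
                  seeds = 0.12, resin_latex = 0.03)
  traits <- data.frame(species = tips, stringsAsFactors = FALSE)
  traits$wild <- guilds$wild
  traits$cultivated <- guilds$cultivated
  traits$edible <- edible
  traits$condiment <- guilds$condiment
  traits$wrapping <- guilds$wrapping
  for (org in names(organ_prev)) {
    traits[[org]] <- stats::rbinom(n_tips, 1L, organ_prev[[org]])
  }
  validate_trait_table(traits, tax$taxonomy)

  structure(list(
    tree = tree,
    taxonomy = tax$taxonomy,
    traits = traits,
    params = list(n_tips = n_tips, birth_rate = 1, n_genera = 320,
                  n_families = 96, guild_sizes = as.list(sizes),
                  clustering = list(edible = "brownian-cover",
                                    condiment = "clade",
                                    wrapping = "clade-distant",
                                    cultivated = "clade", wild = "random"),
                  organ_prevalence = as.list(organ_prev),
                  seed = seed)
  ), class = "synthetic_dataset")
}

#' Write a synthetic dataset to a directory
#'
#' Writes `tree.nwk`, `taxa.csv`, `traits.csv` and `params.yaml` in the
#' formats the pipeline reads back.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_newick(dataset$tree, file.path(dir, "tree.nwk"))
  utils::write.csv(dataset$taxonomy, file.path(dir, "taxa.csv"),
                   row.names = FALSE, quote = FALSE)
  write_trait_table(dataset$traits, dataset$taxonomy,
                    file.path(dir, "traits.csv"))
  yaml::write_yaml(dataset$params, file.path(dir, "params.yaml"))
  invisible(dir)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic ethnobotanical dataset\n")
  cat(sprintf("  tree: %d tips, unit depth; taxonomy: %d genera, %d families\n",
              ape::Ntip(x$tree), length(unique(x$taxonomy$genus)),
              length(unique(x$taxonomy$family))))
  sr <- colSums(x$traits[, c(use_flag_columns(), management_flag_columns())])
  cat("  guild sizes:", paste(names(sr), sr, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
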