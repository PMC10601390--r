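# Brute-force oracles, deliberately independent of the package internals:
# everything here works by explicit root-path edge enumeration on the raw
# ape edge matrix.

# edge-row indices on the path from a tip to the root
bf_root_path <- function(tree, tip) {
  rows <- integer(0)
  node <- if (is.character(tip)) match(tip, tree$tip.label) else tip
  repeat {
    r <- which(tree$edge[, 2] == node)
    if (length(r) == 0L) break
    rows <- c(rows, r)
    node <- tree$edge[r, 1]
  }
  rows
}

bf_pd <- function(tree, taxa, include_root = TRUE) {
  paths <- lapply(taxa, bf_root_path, tree = tree)
  rows <- unique(unlist(paths))
  if (!include_root) {
    shared <- Reduce(intersect, paths)
    rows <- setdiff(rows, shared)
  }
  sum(tree$edge.length[rows])
}

bf_dist <- function(tree, a, b) {
  pa <- bf_root_path(tree, a)
  pb <- bf_root_path(tree, b)
  sum(tree$edge.length[c(setdiff(pa, pb), setdiff(pb, pa))])
}

bf_mpd <- function(tree, taxa) {
  prs <- utils::combn(taxa, 2)
  mean(apply(prs, 2, function(p) bf_dist(tree, p[1], p[2])))
}

bf_mntd <- function(tree, taxa) {
  mean(vapply(taxa, function(a) {
    min(vapply(setdiff(taxa, a), function(b) bf_dist(tree, a, b), numeric(1)))
  }, numeric(1)))
}

bf_abc <- function(tree, A, B) {
  uA <- unique(unlist(lapply(A, bf_root_path, tree = tree)))
  uB <- unique(unlist(lapply(B, bf_root_path, tree = tree)))
  len <- tree$edge.length
  c(a = sum(len[intersect(uA, uB)]),
    b = sum(len[setdiff(uA, uB)]),
    c = sum(len[setdiff(uB, uA)]))
}

# descendant tip labels of a node by walking the edge matrix
bf_descendant_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, bf_descendant_tips, tree = tree))
}

# MRCA by intersecting root paths (node form)
bf_mrca <- function(tree, tips) {
  idx <- match(tips, tree$tip.label)
  paths <- lapply(idx, function(i) c(i, tree$edge[bf_root_path(tree, i), 1]))
  common <- Reduce(intersect, paths)
  common[1]  # paths list ancestors tip-to-root; first shared is the MRCA
}

# fixtures -------------------------------------------------------------

four_tip_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
}

genus_tree <- function() {
  ape::read.tree(text = "((Piper_a:2,Piper_b:2):3,Ocotea_c:5);")
}

random_tree <- function(n, seed) {
  tr <- simulate_tree(n, seed = seed)
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

# clade-packed guild via the generator's internal planter
plant_in_clades_for_test <- function(tree, size, seed, exclude = character(0)) {
  set.seed(seed)
  ethnophylo:::plant_in_clades(tree, size, exclude = exclude)
}

# a small valid trait table + taxonomy for I/O tests
tiny_table <- function() {
  traits <- data.frame(
    species = c("Piper_auritum", "Ocotea_helicterifolia", "Annona_muricata"),
    wild = c(1L, 1L, 0L), cultivated = c(0L, 0L, 1L),
    edible = c(1L, 1L, 1L), condiment = c(1L, 0L, 0L),
    wrapping = c(0L, 0L, 0L),
    root_rhizome_bulb = c(0L, 0L, 0L), stem = c(0L, 0L, 0L),
    bark = c(0L, 0L, 0L), wood = c(0L, 0L, 0L), leaf = c(1L, 1L, 0L),
    flowers = c(0L, 0L, 0L), fruits = c(0L, 0L, 1L),
    seeds = c(0L, 0L, 0L), resin_latex = c(0L, 0L, 0L),
    stringsAsFactors = FALSE)
  taxa <- data.frame(
    species = traits$species,
    genus = c("Piper", "Ocotea", "Annona"),
    family = c("Piperaceae", "Lauraceae", "Annonaceae"),
    stringsAsFactors = FALSE)
  list(traits = traits, taxa = taxa)
}
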