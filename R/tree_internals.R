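# Shared traversal machinery.
#
# Every permutation-heavy statistic in the package is vectorized over
# *columns of a trait/membership matrix*: one bottom-up pass over the tree
# updates all permutations at once, which is what keeps 1000-replicate
# nulls fast without compiled code.

# Precomputed traversal info for a tree. `order_bottom_up` lists internal
# node numbers so that every child is processed before its parent (sorted
# by decreasing topological depth); `child_rows` maps each internal node to
# its edge-matrix rows.
tree_info <- function(tree) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  edge <- tree$edge
  nedge <- nrow(edge)
  depth <- integer(ntip + nnode)
  root <- ntip + 1L
  # cladewise order: parents appear before children along edge rows
  tre <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(tre$edge))) {
    depth[tre$edge[i, 2]] <- depth[tre$edge[i, 1]] + 1L
  }
  internal <- root:(ntip + nnode)
  order_bottom_up <- internal[order(depth[internal], decreasing = TRUE)]
  child_rows <- split(seq_len(nedge), edge[, 1])
  list(tree = tree, ntip = ntip, nnode = nnode, edge = edge,
       edge_length = tree$edge.length, nedge = nedge, root = root,
       order_bottom_up = order_bottom_up, child_rows = child_rows,
       edge_cladewise = tre$edge, edge_length_cladewise = tre$edge.length)
}

# Per-node descendant-sum accumulation, vectorized over columns of M
# (n_tips x k). Returns an (n_tips + n_nodes) x k matrix whose row for an
# internal node holds the column sums over its descendant tips.
accumulate_counts <- function(info, M) {
  M <- as.matrix(M)
  k <- ncol(M)
  C <- matrix(0, info$ntip + info$nnode, k)
  C[seq_len(info$ntip), ] <- M
  for (node in info$order_bottom_up) {
    rows <- info$child_rows[[as.character(node)]]
    ch <- info$edge[rows, 2]
    C[node, ] <- if (length(ch) == 1L) C[ch, ] else colSums(C[ch, , drop = FALSE])
  }
  C
}

# Align a trait vector with tree tips. Accepts a named vector (values for
# every tip label) or an unnamed vector in tip order.
align_trait <- function(tree, trait) {
  ntip <- ape::Ntip(tree)
  if (!is.null(names(trait))) {
    missing <- setdiff(tree$tip.label, names(trait))
    if (length(missing)) {
      stop("trait value missing for tip(s): ",
           paste(utils::head(missing, 5), collapse = ", "),
           if (length(missing) > 5) ", ...", call. = FALSE)
    }
    trait <- trait[tree$tip.label]
  } else if (length(trait) != ntip) {
    stop("unnamed trait vector must have one value per tip", call. = FALSE)
  }
  v <- as.numeric(trait)
  if (anyNA(v)) stop("trait contains missing values", call. = FALSE)
  unname(v)
}

# Membership indicator (0/1 integer vector over tips) for a species set.
membership_vector <- function(tree, taxa) {
  taxa <- unique(taxa)
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown)) {
    stop("species not in tree: ",
         paste(utils::head(unknown, 5), collapse = ", "),
         if (length(unknown) > 5) ", ...", call. = FALSE)
  }
  as.integer(tree$tip.label %in% taxa)
}

# Local seeding: set the RNG only when a seed is supplied.
maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

#' Derive a per-stage child seed from a master seed
#'
#' Fixed splitting rule used throughout the package so that adding or
#' reordering one pipeline stage never silently shifts the random draws of
#' another. Seeds stay below 2^31 - 1.
#'
#' @param master Master seed (integer).
#' @param stage Stage label (string); distinct labels give distinct streams.
#' @return An integer seed.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% 1048573
  as.integer((as.numeric(master) %% 65521) * 32749 + h + 1)
}
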