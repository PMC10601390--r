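# Hot-node scan: clade enrichment in a focal binary use trait.
#
# For every internal node, the count of trait-positive descendants is
# compared with a null distribution obtained by shuffling trait values
# across tips; one shuffle yields counts for all nodes at once. A node is
# "hot" when ses = (count - null_mean)/null_sd exceeds the threshold
# (one-sided: enrichment only). Only clades of at least `min_clade` tips
# are evaluated — smaller lineages give unstable permutation moments. The
# marginal null at a clade of m tips is hypergeometric (m draws from k
# positives among n tips), which tests use as an analytic cross-check.

#' Per-node descendant and trait-positive counts
#'
#' Single bottom-up pass: a node's counts are the sums over its children.
#'
#' @param tree A `phylo` object.
#' @param trait Binary 0/1 vector named by tip label (or in tip order).
#' @return Data frame with one row per internal node: `node` (ape node
#'   number), `clade_size`, `focal_count`.
#' @export
clade_counts <- function(tree, trait) {
  v <- align_trait(tree, trait)
  info <- tree_info(tree)
  C <- accumulate_counts(info, cbind(rep(1, info$ntip), v))
  internal <- info$root:(info$ntip + info$nnode)
  data.frame(node = internal,
             clade_size = as.integer(C[internal, 1]),
             focal_count = as.integer(C[internal, 2]))
}

# Stable signature of a clade: a small rolling hash over the sorted tip
# labels, so results can be checked against a (possibly renumbered) tree.
clade_signature <- function(labels) {
  s <- paste(sort(labels), collapse = "|")
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 131 + code) %% 2147483647
  sprintf("%010d", h)
}

# Tip labels under each internal node.
clade_tip_sets <- function(tree) {
  info <- tree_info(tree)
  sets <- vector("list", info$ntip + info$nnode)
  for (i in seq_len(info$ntip)) sets[[i]] <- tree$tip.label[i]
  for (node in info$order_bottom_up) {
    ch <- info$edge[info$child_rows[[as.character(node)]], 2]
    sets[[node]] <- unlist(sets[ch], use.names = FALSE)
  }
  sets
}

#' Permutation scan for clades enriched in a focal trait
#'
#' Shuffles the trait across tips `n_perm` times; each shuffle produces
#' counts for every node simultaneously. Nodes whose clade has at least
#' `min_clade` tips are evaluated; others are absent from the output. A
#' node with `null_sd = 0` gets `ses = NA` and `is_hot = FALSE`. With a
#' constant trait the scan warns and returns all-`NA` ses values.
#'
#' @param tree A `phylo` object.
#' @param trait Binary 0/1 vector named by tip label (or in tip order).
#' @param min_clade Minimum clade size evaluated (default 10).
#' @param n_perm Number of tip shuffles (default 999).
#' @param ses_threshold One-sided enrichment threshold (default 1.96).
#' @param seed Optional RNG seed.
#' @return An object of class `hotnode_scan`: a data frame sorted by `ses`
#'   descending with columns `node`, `signature`, `clade_size`,
#'   `focal_count`, `null_mean`, `null_sd`, `ses`, `is_hot`,
#'   `example_tips`; attributes keep `min_clade`, `n_perm`,
#'   `ses_threshold`, `seed`.
#' @export
hot_node_scan <- function(tree, trait, min_clade = 10, n_perm = 999,
                          ses_threshold = 1.96, seed = NULL) {
  maybe_seed(seed)
  v <- align_trait(tree, trait)
  if (!all(v %in% c(0, 1))) stop("trait must be binary 0/1", call. = FALSE)
  constant <- length(unique(v)) == 1L
  if (constant) {
    warning("trait is constant; every node's null has zero spread")
  }
  info <- tree_info(tree)
  obs <- clade_counts(tree, v)
  keep <- obs$clade_size >= min_clade
  obs <- obs[keep, , drop = FALSE]
  if (nrow(obs) == 0L) {
    stop("no clade reaches min_clade = ", min_clade, call. = FALSE)
  }

  # shuffles are drawn over the trait value multiset, not tip positions
  ntip <- info$ntip
  shuffles <- vapply(seq_len(n_perm), function(i) v[sample.int(ntip)],
                     numeric(ntip))
  C <- accumulate_counts(info, shuffles)[obs$node, , drop = FALSE]
  null_mean <- rowMeans(C)
  null_sd <- sqrt(pmax(0, (rowSums(C^2) - n_perm * null_mean^2) / (n_perm - 1)))
  ses <- ifelse(null_sd > 0, (obs$focal_count - null_mean) / null_sd, NA_real_)

  sets <- clade_tip_sets(tree)
  res <- data.frame(
    node = obs$node,
    signature = vapply(sets[obs$node], clade_signature, character(1)),
    clade_size = obs$clade_size,
    focal_count = obs$focal_count,
    null_mean = null_mean,
    null_sd = null_sd,
    ses = ses,
    is_hot = !is.na(ses) & ses > ses_threshold,
    example_tips = vapply(sets[obs$node], function(s)
      paste(utils::head(sort(s), 3), collapse = ";"), character(1)),
    stringsAsFactors = FALSE
  )
  res <- res[order(-ifelse(is.na(res$ses), -Inf, res$ses)), ]
  rownames(res) <- NULL
  structure(res, class = c("hotnode_scan", "data.frame"),
            min_clade = min_clade, n_perm = n_perm,
            ses_threshold = ses_threshold, seed = seed,
            tree_ntip = ntip)
}

#' Keep only maximal (outermost) hot clades
#'
#' Collapses nested hot lineages to the hot clades not contained in any
#' other hot clade.
#'
#' @param tree The tree the scan was run on.
#' @param results A `hotnode_scan` object.
#' @return The filtered `hotnode_scan`.
#' @export
maximal_hot_nodes <- function(tree, results) {
  hot <- results[results$is_hot, , drop = FALSE]
  if (nrow(hot) <= 1L) return(hot)
  sets <- clade_tip_sets(tree)
  keep <- vapply(seq_len(nrow(hot)), function(i) {
    si <- sets[[hot$node[i]]]
    !any(vapply(seq_len(nrow(hot)), function(j) {
      j != i && length(sets[[hot$node[j]]]) > length(si) &&
        all(si %in% sets[[hot$node[j]]])
    }, logical(1)))
  }, logical(1))
  hot[keep, , drop = FALSE]
}

#' Label hot nodes on a tree
#'
#' Writes `"HOT|ses=<value>"` into the node labels of evaluated hot nodes
#' (other internal nodes get empty labels), as a Newick-serializable
#' stand-in for a shaded-clade figure. Errors if the results do not match
#' the tree's clades (stale results).
#'
#' @param tree The tree the scan was run on.
#' @param results A `hotnode_scan` object.
#' @return The tree with `node.label` set.
#' @export
annotate_tree <- function(tree, results) {
  ntip <- ape::Ntip(tree)
  sets <- clade_tip_sets(tree)
  sig_now <- vapply(sets[results$node], clade_signature, character(1))
  if (!identical(unname(sig_now), unname(results$signature))) {
    stop("results do not match this tree (stale node numbering?)",
         call. = FALSE)
  }
  labels <- rep("", tree$Nnode)
  hot <- results[results$is_hot, , drop = FALSE]
  labels[hot$node - ntip] <- sprintf("HOT|ses=%.4f", hot$ses)
  tree$node.label <- labels
  tree
}

#' Write a hot-node table to CSV
#'
#' @param results A `hotnode_scan` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hotnode_table <- function(results, path) {
  utils::write.csv(as.data.frame(results), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
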