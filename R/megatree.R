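# Megatree grafting and pruning.
#
# Missing species are attached at the crown (basal) node of their genus, or
# of their family when the genus is absent from the tree, with a pendant
# edge equal to that node's age — the only placement that keeps a dated
# tree ultrametric without inventing stem ages. Grafts therefore create
# polytomies; all downstream statistics accept polytomies.

# Ages of every node of an ultrametric tree: max tip depth minus node depth.
node_ages <- function(tree) {
  nd <- ape::node.depth.edgelength(tree)
  max(nd[seq_len(ape::Ntip(tree))]) - nd
}

#' Crown node of a genus in a tree
#'
#' The most recent common ancestor of all tips whose label's first
#' underscore-separated token equals `genus`; for a genus with a single tip
#' in the tree, that tip's parent node. Returns `NA_integer_` when the
#' genus has no tips in the tree (callers fall back to the family).
#'
#' @param tree A `phylo` object.
#' @param genus Genus name (string).
#' @return Internal node number, or `NA_integer_` if the genus is absent.
#' @export
genus_basal_node <- function(tree, genus) {
  tips <- which(genus_of(tree$tip.label) == genus)
  mrca_or_parent(tree, tips)
}

# MRCA of a tip set; for a single tip its parent; NA for an empty set.
mrca_or_parent <- function(tree, tips) {
  if (length(tips) == 0L) return(NA_integer_)
  if (length(tips) == 1L) {
    return(tree$edge[tree$edge[, 2] == tips, 1])
  }
  ape::getMRCA(tree, tips)
}

#' Graft missing species onto a dated megatree
#'
#' Every requested species already present in the tree is left untouched.
#' A species whose genus has tips in the tree is attached as a new child of
#' the genus crown node; when the genus is absent but the family is known
#' (via `family_map` for megatree tips, plus the families of the requested
#' taxa themselves), the species is attached at the family crown node. The
#' pendant edge length equals the attachment node's age, so the output tree
#' is ultrametric within the input tolerance. Species with neither genus
#' nor family represented are reported as unplaced and left out.
#'
#' @param tree Ultrametric `phylo` megatree (tips labeled with canonical
#'   underscore binomials).
#' @param taxa Data frame with columns `species`, `genus`, `family`
#'   (canonicalized, as from [read_trait_table()]).
#' @param family_map Optional data frame mapping megatree tips to families
#'   (columns `species`, `family`); genus membership is always derived
#'   lexically from tip labels.
#' @param tol Relative ultrametricity tolerance for input validation.
#' @return A list with `tree` (the grafted `phylo`) and `report`, a list
#'   with counts `n_already_present`, `n_grafted_to_genus`,
#'   `n_grafted_to_family`, the character vector `unplaced`, and a
#'   `placements` data frame (species, method, attachment_age).
#' @export
graft_species <- function(tree, taxa, family_map = NULL, tol = 1e-6) {
  validate_phylogeny(tree, "megatree")
  if (!is_ultrametric_tree(tree, tol)) {
    stop("megatree is not ultrametric within tolerance ", tol,
         "; node ages are undefined", call. = FALSE)
  }
  stopifnot(all(c("species", "genus", "family") %in% names(taxa)))

  # family lookup for tips: user map first, then the requested taxa
  fam_lookup <- new.env(parent = emptyenv())
  assign_fam <- function(sp, fam) {
    if (nzchar(fam)) assign(sp, fam, envir = fam_lookup)
  }
  if (!is.null(family_map)) {
    stopifnot(all(c("species", "family") %in% names(family_map)))
    mapply(assign_fam, family_map$species, family_map$family)
  }
  mapply(assign_fam, taxa$species, taxa$family)
  genus_family <- new.env(parent = emptyenv())
  mapply(function(g, f) if (nzchar(f)) assign(g, f, envir = genus_family),
         taxa$genus, taxa$family)
  tip_family <- function(tr) {
    vapply(tr$tip.label, function(sp) {
      if (exists(sp, envir = fam_lookup)) return(get(sp, envir = fam_lookup))
      g <- genus_of(sp)
      if (exists(g, envir = genus_family)) return(get(g, envir = genus_family))
      NA_character_
    }, character(1), USE.NAMES = FALSE)
  }

  placements <- data.frame(species = taxa$species,
                           method = NA_character_,
                           attachment_age = NA_real_,
                           stringsAsFactors = FALSE)
  present <- taxa$species %in% tree$tip.label
  placements$method[present] <- "present"

  for (i in which(!present)) {
    sp <- taxa$species[i]
    node <- genus_basal_node(tree, taxa$genus[i])
    method <- "genus"
    if (is.na(node)) {
      fams <- tip_family(tree)
      fam_tips <- which(!is.na(fams) & fams == taxa$family[i])
      node <- mrca_or_parent(tree, fam_tips)
      method <- "family"
    }
    if (is.na(node)) {
      placements$method[i] <- "unplaced"
      next
    }
    age <- node_ages(tree)[node]
    tree <- phytools::bind.tip(tree, sp, edge.length = age,
                               where = node, position = 0)
    placements$method[i] <- method
    placements$attachment_age[i] <- age
  }

  report <- list(
    n_already_present = sum(placements$method == "present"),
    n_grafted_to_genus = sum(placements$method == "genus"),
    n_grafted_to_family = sum(placements$method == "family"),
    unplaced = placements$species[placements$method == "unplaced"],
    placements = placements
  )
  stopifnot(report$n_already_present + report$n_grafted_to_genus +
              report$n_grafted_to_family + length(report$unplaced) ==
              nrow(taxa))
  list(tree = tree, report = report)
}

#' Prune a tree to a species set
#'
#' Keeps exactly `keep`, suppressing unbranched internal nodes (their edge
#' lengths are summed), so surviving root-to-tip depths are unchanged.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of tip labels to retain (must all be tips).
#' @return The pruned `phylo`.
#' @export
prune_to <- function(tree, keep) {
  keep <- unique(keep)
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing)) {
    stop("species not in tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(keep) < 2L) stop("need at least two species to keep", call. = FALSE)
  ape::keep.tip(tree, keep)
}

#' Write a graft report to CSV
#'
#' @param report The `report` element of [graft_species()]'s result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graft_report <- function(report, path) {
  utils::write.csv(report$placements, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
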