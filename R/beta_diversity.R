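# Phylogenetic beta diversity between guild pairs.
#
# PBD = 1 - PhyloSor, where PhyloSor = a / (a + (b + c)/2) with a the
# branch length shared by the two guilds' path unions and b, c the lengths
# unique to each. PBD decomposes additively into a Simpson-derived "true
# turnover" component, pbd_sim = min(b,c) / (a + min(b,c)), and a
# nestedness-resultant remainder pbd_sne = pbd_sor - pbd_sim. SES scores
# come from a tip-shuffle null that holds both guild sizes and their
# overlap fixed, so the null isolates *where* on the tree the guilds sit.

#' Shared / unique branch-length partition of two guilds
#'
#' Classifies every edge by whether its descendant tips intersect guild A
#' and/or guild B (root paths included, consistent with the
#' [faith_pd()] default): `a` is the length shared by both path unions,
#' `b` unique to A, `c` unique to B, and `a + b + c = PD(A union B)`
#' exactly.
#'
#' @param tree A `phylo` object.
#' @param setA,setB Non-empty character vectors of tip labels.
#' @param include_root Root-path convention (default `TRUE`).
#' @return Named numeric vector `c(a =, b =, c =)`.
#' @export
branch_partition <- function(tree, setA, setB, include_root = TRUE) {
  if (length(setA) < 1L || length(setB) < 1L) {
    stop("both species sets must be non-empty", call. = FALSE)
  }
  info <- tree_info(tree)
  abc_pairs(info, matrix(membership_vector(tree, setA), ncol = 1),
            matrix(membership_vector(tree, setB), ncol = 1),
            include_root)[1, ]
}

# a/b/c for paired membership count matrices; CA/CB are accumulate_counts
# outputs laid side by side: columns 1..k guild A, k+1..2k guild B.
abc_pairs <- function(info, MA, MB, include_root = TRUE) {
  k <- ncol(MA)
  C <- accumulate_counts(info, cbind(MA, MB))
  child <- info$edge[, 2]
  len <- info$edge_length
  inA <- C[child, seq_len(k), drop = FALSE] > 0
  inB <- C[child, k + seq_len(k), drop = FALSE] > 0
  if (!include_root) {
    totA <- colSums(as.matrix(MA))
    totB <- colSums(as.matrix(MB))
    inA <- inA & C[child, seq_len(k), drop = FALSE] <
      rep(totA, each = length(child))
    inB <- inB & C[child, k + seq_len(k), drop = FALSE] <
      rep(totB, each = length(child))
  }
  cbind(a = drop(crossprod(inA & inB, len)),
        b = drop(crossprod(inA & !inB, len)),
        c = drop(crossprod(!inA & inB, len)))
}

# Sorensen / Simpson / nestedness components from an (a, b, c) row matrix.
components_from_abc <- function(abc) {
  a <- abc[, "a"]; b <- abc[, "b"]; cc <- abc[, "c"]
  minbc <- pmin(b, cc)
  sor <- (b + cc) / (2 * a + b + cc)
  sim <- minbc / (a + minbc)
  cbind(pbd_sim = sim, pbd_sne = sor - sim, pbd_sor = sor)
}

#' PhyloSor dissimilarity components for one guild pair
#'
#' @param tree A `phylo` object.
#' @param setA,setB Non-empty character vectors of tip labels.
#' @param include_root Root-path convention.
#' @return A list with `a`, `b`, `c`, `pbd_sim` (true turnover), `pbd_sne`
#'   (nestedness-resultant), `pbd_sor` (overall PBD = 1 - PhyloSor).
#' @export
phylosor_pair <- function(tree, setA, setB, include_root = TRUE) {
  abc <- branch_partition(tree, setA, setB, include_root)
  comp <- components_from_abc(rbind(abc))
  list(a = unname(abc["a"]), b = unname(abc["b"]), c = unname(abc["c"]),
       pbd_sim = unname(comp[1, "pbd_sim"]),
       pbd_sne = unname(comp[1, "pbd_sne"]),
       pbd_sor = unname(comp[1, "pbd_sor"]))
}

#' PhyloSor components with tip-shuffle SES scores
#'
#' Null replicates permute the tree's tip labels uniformly — equivalently,
#' both guild memberships are redrawn with their sizes and overlap
#' `|A intersect B|` held fixed — and each component's SES is
#' `(obs - mean(null)) / sd(null)`. Components with `|ses| > 1.96` are
#' flagged (two-sided). A null with zero spread yields `ses = NA`, flagged
#' `FALSE`.
#'
#' @param tree A `phylo` object.
#' @param setA,setB Non-empty character vectors of tip labels.
#' @param n_null Number of tip shuffles (default 999).
#' @param seed Optional RNG seed.
#' @param include_root Root-path convention.
#' @param ses_threshold Two-sided flag threshold (default 1.96).
#' @return An object of class `betadiv_result`: observed components plus
#'   `ses_sim`, `ses_sne`, `ses_sor`, logical flags, `n_null`, `seed`.
#' @export
ses_phylo_beta <- function(tree, setA, setB, n_null = 999, seed = NULL,
                           include_root = TRUE, ses_threshold = 1.96) {
  maybe_seed(seed)
  info <- tree_info(tree)
  mA <- membership_vector(tree, setA)
  mB <- membership_vector(tree, setB)
  ntip <- info$ntip
  abc_obs <- abc_pairs(info, matrix(mA, ncol = 1), matrix(mB, ncol = 1),
                       include_root)
  obs <- components_from_abc(abc_obs)

  MA <- matrix(0L, ntip, n_null)
  MB <- matrix(0L, ntip, n_null)
  for (j in seq_len(n_null)) {
    p <- sample.int(ntip)  # one label shuffle moves both guilds together
    MA[, j] <- mA[p]
    MB[, j] <- mB[p]
  }
  null <- components_from_abc(abc_pairs(info, MA, MB, include_root))

  ses <- vapply(colnames(obs), function(cn) {
    s <- stats::sd(null[, cn])
    if (s > 0) (obs[1, cn] - mean(null[, cn])) / s else NA_real_
  }, numeric(1))
  structure(list(
    a = unname(abc_obs[1, "a"]),
    b = unname(abc_obs[1, "b"]),
    c = unname(abc_obs[1, "c"]),
    pbd_sim = unname(obs[1, "pbd_sim"]),
    pbd_sne = unname(obs[1, "pbd_sne"]),
    pbd_sor = unname(obs[1, "pbd_sor"]),
    ses_sim = unname(ses["pbd_sim"]),
    ses_sne = unname(ses["pbd_sne"]),
    ses_sor = unname(ses["pbd_sor"]),
    flag_sim = isTRUE(abs(ses["pbd_sim"]) > ses_threshold),
    flag_sne = isTRUE(abs(ses["pbd_sne"]) > ses_threshold),
    flag_sor = isTRUE(abs(ses["pbd_sor"]) > ses_threshold),
    null_mean = colMeans(null),
    null_sd = apply(null, 2, stats::sd),
    n_null = n_null, seed = seed
  ), class = "betadiv_result")
}

#' Pairwise beta-diversity table across guild pairs
#'
#' Applies [ses_phylo_beta()] to each named guild pair. The default pair
#' list is the nine use-versus-management comparisons conventionally
#' reported for this analysis.
#'
#' @param tree A `phylo` object.
#' @param traits Trait data frame ([read_trait_table()]).
#' @param pairs List of 2-element character vectors of flag column names;
#'   `NULL` for the default nine comparisons.
#' @param n_null,seed,include_root,ses_threshold Passed to
#'   [ses_phylo_beta()]; with a master `seed`, each pair's child seed is
#'   keyed by its (unordered) memberships, so (X, Y) and (Y, X) give
#'   identical results.
#' @return Data frame with one row per pair: guild1, guild2, pbd_sne,
#'   pbd_sim, pbd_sor, ses_sne, ses_sim, ses_sor, flag_sne, flag_sim,
#'   flag_sor.
#' @export
guild_beta_matrix <- function(tree, traits, pairs = NULL, n_null = 999,
                              seed = NULL, include_root = TRUE,
                              ses_threshold = 1.96) {
  if (is.null(pairs)) {
    pairs <- list(c("edible", "condiment"), c("edible", "wrapping"),
                  c("condiment", "wrapping"), c("edible", "cultivated"),
                  c("edible", "wild"), c("condiment", "cultivated"),
                  c("condiment", "wild"), c("wrapping", "cultivated"),
                  c("wrapping", "wild"))
  }
  rows <- lapply(pairs, function(pr) {
    a <- intersect(guild_members(traits, pr[1]), tree$tip.label)
    b <- intersect(guild_members(traits, pr[2]), tree$tip.label)
    if (length(a) < 1L || length(b) < 1L) {
      warning("pair ", pr[1], " vs ", pr[2], " has an empty guild; skipped")
      return(NULL)
    }
    key <- paste(sort(c(paste(sort(a), collapse = ","),
                        paste(sort(b), collapse = ","))), collapse = "|")
    res <- ses_phylo_beta(tree, a, b, n_null = n_null,
                          seed = if (is.null(seed)) NULL else
                            derive_seed(seed, paste0("beta:", key)),
                          include_root = include_root,
                          ses_threshold = ses_threshold)
    data.frame(guild1 = pr[1], guild2 = pr[2],
               pbd_sne = res$pbd_sne, pbd_sim = res$pbd_sim,
               pbd_sor = res$pbd_sor, ses_sne = res$ses_sne,
               ses_sim = res$ses_sim, ses_sor = res$ses_sor,
               flag_sne = res$flag_sne, flag_sim = res$flag_sim,
               flag_sor = res$flag_sor, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' @export
print.betadiv_result <- function(x, ...) {
  cat("PhyloSor beta-diversity decomposition\n")
  cat(sprintf("  pbd_sor = %.4f = turnover %.4f + nestedness %.4f\n",
              x$pbd_sor, x$pbd_sim, x$pbd_sne))
  cat(sprintf("  ses: sor %.3f%s  sim %.3f%s  sne %.3f%s   (null n = %d)\n",
              x$ses_sor, if (x$flag_sor) "*" else "",
              x$ses_sim, if (x$flag_sim) "*" else "",
              x$ses_sne, if (x$flag_sne) "*" else "", x$n_null))
  invisible(x)
}
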