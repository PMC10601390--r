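# Alpha phylodiversity: Faith's PD, MPD, MNTD and their standardized
# effect sizes against a tip-pool randomization null.
#
# PD is a whole-tree metric, MPD probes basal structure and MNTD terminal
# structure. Null replicates draw guilds of the observed size uniformly
# without replacement from the full tip pool; low rank-based P (< 0.05)
# flags clustering and high P (> 0.95) overdispersion.

# PD for every column of a tips x k membership matrix, include_root style:
# an edge counts when at least one selected tip descends from it.
pd_many <- function(info, M, include_root = TRUE) {
  C <- accumulate_counts(info, M)
  child <- info$edge[, 2]
  len <- info$edge_length
  sel <- C[child, , drop = FALSE] > 0
  pd <- drop(crossprod(sel, len))
  if (!include_root) {
    # drop the root-to-MRCA path: edges subtending *all* selected tips
    totals <- colSums(as.matrix(M))
    on_spine <- C[child, , drop = FALSE] >= rep(totals, each = length(child))
    pd <- pd - drop(crossprod(sel & on_spine, len))
  }
  pd
}

#' Faith's phylogenetic diversity of a species set
#'
#' Sum of branch lengths of the union of root-to-tip paths of the set
#' (`include_root = TRUE`, the conventional definition on a rooted, dated
#' tree), or of the minimal subtree spanning the set only
#' (`include_root = FALSE`).
#'
#' @param tree A `phylo` object.
#' @param taxa Character vector of tip labels, at least one.
#' @param include_root Include the path up to the root (default `TRUE`).
#' @return PD in the tree's branch-length units (Myr for a dated tree).
#' @export
faith_pd <- function(tree, taxa, include_root = TRUE) {
  if (length(taxa) < 1L) stop("need at least one species", call. = FALSE)
  m <- membership_vector(tree, taxa)
  pd_many(tree_info(tree), matrix(m, ncol = 1), include_root = include_root)
}

#' Mean pairwise and mean nearest-taxon patristic distance
#'
#' `mpd_guild` is the mean patristic distance over all unordered pairs of
#' the set; `mntd_guild` is the mean, over members, of the distance to the
#' nearest other member. Both need at least two species.
#'
#' @param tree A `phylo` object.
#' @param taxa Character vector of tip labels (>= 2).
#' @param dmat Optional precomputed patristic distance matrix
#'   ([patristic_matrix()]); computed from the tree when `NULL`.
#' @return Distance in branch-length units.
#' @export
mpd_guild <- function(tree, taxa, dmat = NULL) {
  idx <- guild_indices(tree, taxa)
  if (is.null(dmat)) dmat <- patristic_matrix(tree)
  sub <- dmat[idx, idx]
  sum(sub) / (length(idx) * (length(idx) - 1L))
}

#' @rdname mpd_guild
#' @export
mntd_guild <- function(tree, taxa, dmat = NULL) {
  idx <- guild_indices(tree, taxa)
  if (is.null(dmat)) dmat <- patristic_matrix(tree)
  sub <- dmat[idx, idx]
  diag(sub) <- Inf
  mean(apply(sub, 1L, min))
}

guild_indices <- function(tree, taxa) {
  m <- membership_vector(tree, taxa)
  idx <- which(m == 1L)
  if (length(idx) < 2L) {
    stop("metric undefined for fewer than two species", call. = FALSE)
  }
  idx
}

#' Patristic (tip-to-tip path) distance matrix
#'
#' @param tree A `phylo` object.
#' @return A symmetric `Ntip x Ntip` matrix in tip order.
#' @export
patristic_matrix <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}

#' Standardized effect size of an alpha-diversity metric
#'
#' Draws `n_null` random guilds of the observed size uniformly without
#' replacement from the full tip pool, and reports
#' `ses = (obs - mean(null)) / sd(null)` together with the rank-based
#' `p = (1 + #\{null <= obs\}) / (n_null + 1)`; low p means the guild packs
#' less diversity than random draws of its size (phylogenetic clustering).
#' When the null has zero spread (e.g. the guild is the whole pool) `ses`
#' is `NA` and `p` is still computed by ranks.
#'
#' @param tree A `phylo` object.
#' @param taxa Guild species (tip labels).
#' @param metric One of `"PD"`, `"MPD"`, `"MNTD"`.
#' @param n_null Number of null draws (default 999).
#' @param seed Optional RNG seed.
#' @param include_root Root-path convention for PD.
#' @param dmat Optional precomputed [patristic_matrix()] (MPD/MNTD).
#' @param info Optional precomputed traversal info (internal reuse).
#' @return A list with `obs`, `ses`, `p`, `null_mean`, `null_sd`, `n_null`.
#' @export
ses_alpha <- function(tree, taxa, metric = c("PD", "MPD", "MNTD"),
                      n_null = 999, seed = NULL, include_root = TRUE,
                      dmat = NULL, info = NULL) {
  metric <- match.arg(metric)
  maybe_seed(seed)
  taxa <- unique(taxa)
  m <- membership_vector(tree, taxa)
  sr <- sum(m)
  ntip <- ape::Ntip(tree)
  if (metric != "PD" && sr < 2L) {
    stop(metric, " undefined for fewer than two species", call. = FALSE)
  }
  if (is.null(info)) info <- tree_info(tree)

  draws <- vapply(seq_len(n_null),
                  function(i) sample.int(ntip, sr), integer(sr))
  if (metric == "PD") {
    obs <- pd_many(info, matrix(m, ncol = 1), include_root)
    Mnull <- matrix(0L, ntip, n_null)
    Mnull[cbind(as.vector(draws), rep(seq_len(n_null), each = sr))] <- 1L
    null <- pd_many(info, Mnull, include_root)
  } else {
    if (is.null(dmat)) dmat <- patristic_matrix(tree)
    idx <- which(m == 1L)
    if (metric == "MPD") {
      stat <- function(ix) {
        sub <- dmat[ix, ix]
        sum(sub) / (length(ix) * (length(ix) - 1L))
      }
    } else {
      stat <- function(ix) {
        sub <- dmat[ix, ix]
        diag(sub) <- Inf
        mean(apply(sub, 1L, min))
      }
    }
    obs <- stat(idx)
    null <- apply(draws, 2L, stat)
  }
  null_sd <- stats::sd(null)
  list(obs = unname(obs),
       ses = if (null_sd > 0) unname((obs - mean(null)) / null_sd) else NA_real_,
       p = (1 + sum(null <= obs)) / (n_null + 1),
       null_mean = mean(null), null_sd = null_sd, n_null = n_null)
}

#' Alpha-diversity summary table across guilds
#'
#' One row per guild: species richness after intersecting with the tree's
#' tips, observed PD / MPD / MNTD, and standardized effect sizes with
#' rank-based P values against the tip-pool null ([ses_alpha()]). Species
#' in a guild but absent from the tree are dropped with a message; guilds
#' left empty (or below two species for MPD/MNTD) are skipped with a
#' warning.
#'
#' @param tree A `phylo` object.
#' @param traits Trait data frame ([read_trait_table()]).
#' @param guilds Character vector of flag column names (default: the five
#'   management and use guilds).
#' @param n_null Null draws per metric (default 999).
#' @param seed Optional master seed; each guild x metric gets a derived
#'   child seed, so adding a guild never shifts another guild's draws.
#' @param include_root Root-path convention for PD.
#' @return Data frame with columns guild, SR, PD, MPD, MNTD, ses.PD, p.PD,
#'   ses.MPD, p.MPD, ses.MNTD, p.MNTD.
#' @export
guild_summary <- function(tree, traits,
                          guilds = c(use_flag_columns(),
                                     management_flag_columns()),
                          n_null = 999, seed = NULL, include_root = TRUE) {
  info <- tree_info(tree)
  dmat <- patristic_matrix(tree)
  rows <- vector("list", length(guilds))
  for (gi in seq_along(guilds)) {
    g <- guilds[gi]
    members <- guild_members(traits, g)
    dropped <- setdiff(members, tree$tip.label)
    if (length(dropped)) {
      message("guild '", g, "': ", length(dropped),
              " species not in tree, excluded")
      members <- setdiff(members, dropped)
    }
    if (length(members) < 2L) {
      warning("guild '", g, "' has fewer than two species in the tree; skipped")
      next
    }
    res <- lapply(c("PD", "MPD", "MNTD"), function(metric) {
      # seed keyed by membership, not guild name: two guilds with the same
      # species give identical rows under one master seed
      ses_alpha(tree, members, metric, n_null = n_null,
                seed = if (is.null(seed)) NULL else
                  derive_seed(seed, paste0("alpha:", metric, ":",
                                           paste(sort(members), collapse = ","))),
                include_root = include_root, dmat = dmat, info = info)
    })
    names(res) <- c("PD", "MPD", "MNTD")
    rows[[gi]] <- data.frame(
      guild = g, SR = length(members),
      PD = res$PD$obs, MPD = res$MPD$obs, MNTD = res$MNTD$obs,
      ses.PD = res$PD$ses, p.PD = res$PD$p,
      ses.MPD = res$MPD$ses, p.MPD = res$MPD$p,
      ses.MNTD = res$MNTD$ses, p.MNTD = res$MNTD$p,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
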