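# Pipeline driver: graft -> signal -> alpha -> beta -> hot nodes.
#
# One configuration (paths, guild and pair lists, permutation counts,
# thresholds, master seed) drives every stage in dependency order and
# writes the full set of result tables plus a manifest with seeds and
# checksums. Stage seeds derive from the master seed, so reruns are
# bit-for-bit reproducible.

#' Build a pipeline run configuration
#'
#' Collects every analysis constant in one validated list: 1000
#' permutations for the D statistic, 999 randomizations for SES nulls and
#' the hot-node scan, clade-size floor 10, clustering/overdispersion P
#' cutoffs 0.05/0.95 via ranks and the SES flag threshold 1.96.
#'
#' @param megatree,taxa,traits Input paths (Newick; taxa CSV with
#'   species,genus,family; trait table per [read_trait_table()]).
#' @param family_map Optional CSV mapping megatree tips to families.
#' @param out_dir Output directory.
#' @param guilds Flag columns analysed as guilds.
#' @param signal_columns Flag columns tested for phylogenetic signal.
#' @param signal_subsets Management subsets for the signal stage
#'   (`"all"` analyses every species; `"wild"`/`"cultivated"` restrict the
#'   tree to that management class first).
#' @param pairs Guild pairs for beta diversity (`NULL` = the standard nine).
#' @param n_perm Permutations per D statistic and hot-node scan.
#' @param n_null Null draws per SES statistic.
#' @param min_clade Hot-node clade-size floor.
#' @param ses_threshold SES flag threshold.
#' @param include_root Root-path convention for PD-based metrics.
#' @param tol Ultrametricity tolerance.
#' @param seed Master seed.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(megatree, taxa, traits, family_map = NULL,
                       out_dir = "results",
                       guilds = c(use_flag_columns(),
                                  management_flag_columns()),
                       signal_columns = c(use_flag_columns(),
                                          organ_flag_columns()),
                       signal_subsets = c("all", "cultivated", "wild"),
                       pairs = NULL, n_perm = 1000, n_null = 999,
                       min_clade = 10, ses_threshold = 1.96,
                       include_root = TRUE, tol = 1e-6, seed = 1) {
  cfg <- list(megatree = megatree, taxa = taxa, traits = traits,
              family_map = family_map, out_dir = out_dir, guilds = guilds,
              signal_columns = signal_columns,
              signal_subsets = signal_subsets, pairs = pairs,
              n_perm = as.integer(n_perm), n_null = as.integer(n_null),
              min_clade = as.integer(min_clade),
              ses_threshold = ses_threshold, include_root = include_root,
              tol = tol, seed = as.integer(seed))
  counts <- c(cfg$n_perm, cfg$n_null, cfg$min_clade)
  if (any(counts <= 0)) stop("permutation/clade counts must be positive",
                             call. = FALSE)
  known <- all_flag_columns()
  bad <- setdiff(c(cfg$guilds, cfg$signal_columns), known)
  if (length(bad)) {
    stop("unknown guild column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bad_sub <- setdiff(cfg$signal_subsets, c("all", management_flag_columns()))
  if (length(bad_sub)) {
    stop("unknown signal subset(s): ", paste(bad_sub, collapse = ", "),
         call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; relative paths are
#' resolved against the YAML file's directory.
#'
#' @param path Path to the YAML configuration.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p) || file.exists(p)) p else file.path(base, p)
  }
  for (key in c("megatree", "taxa", "traits", "family_map")) {
    raw[[key]] <- resolve(raw[[key]])
  }
  if (!is.null(raw$pairs)) {
    raw$pairs <- lapply(raw$pairs, function(p)
      strsplit(p, ":", fixed = TRUE)[[1]])
  }
  do.call(run_config, raw)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: read and validate inputs; graft the study
#' species onto the megatree and prune to the study list; Fritz-Purvis D
#' per management subset and flag column; alpha-diversity SES table; beta-
#' diversity pair table; hot-node scan per guild. Writes `grafted_tree.nwk`,
#' `graft_report.csv`, `signal.csv`, `alpha.csv`, `beta.csv`,
#' `hotnodes_<guild>.csv`, `annotated_<guild>.nwk` and `manifest.json`
#' under `config$out_dir`.
#'
#' @param config A `run_config` object (or path to a YAML file).
#' @return The manifest list, invisibly.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  inputs <- stage("read_inputs", {
    megatree <- read_newick(config$megatree)
    tt <- read_trait_table(config$traits)
    taxa <- utils::read.csv(config$taxa, stringsAsFactors = FALSE)
    taxa$species <- canonicalize_name(taxa$species)
    fam_map <- if (is.null(config$family_map)) NULL else
      utils::read.csv(config$family_map, stringsAsFactors = FALSE)
    missing_guilds <- setdiff(config$guilds, names(tt$traits))
    if (length(missing_guilds)) {
      stop("guild column(s) absent from trait table: ",
           paste(missing_guilds, collapse = ", "))
    }
    list(megatree = megatree, traits = tt$traits, taxa = taxa,
         fam_map = fam_map)
  })

  grafted <- stage("graft", {
    res <- graft_species(inputs$megatree, inputs$taxa,
                         family_map = inputs$fam_map, tol = config$tol)
    placeable <- intersect(inputs$traits$species, res$tree$tip.label)
    tree <- prune_to(res$tree, placeable)
    write_newick(tree, file.path(config$out_dir, "grafted_tree.nwk"))
    write_graft_report(res$report,
                       file.path(config$out_dir, "graft_report.csv"))
    list(tree = tree, report = res$report)
  })
  tree <- grafted$tree
  traits <- inputs$traits[inputs$traits$species %in% tree$tip.label, ]

  signal <- stage("signal", {
    rows <- list()
    for (subset in config$signal_subsets) {
      members <- if (subset == "all") traits$species else
        guild_members(traits, subset)
      members <- intersect(members, tree$tip.label)
      if (length(members) < 3L) next
      tr_s <- prune_to(tree, members)
      tt_s <- traits[match(members, traits$species), ]
      for (col in config$signal_columns) {
        v <- stats::setNames(tt_s[[col]], tt_s$species)
        if (length(unique(v)) < 2L) {
          rows[[length(rows) + 1L]] <- data.frame(
            subset = subset, column = col, D = NA_real_, p_rand = NA_real_,
            p_brownian = NA_real_, d_obs = NA_real_,
            prevalence = sum(v), n_perm = config$n_perm,
            stringsAsFactors = FALSE)
          next
        }
        fit <- phylo_d(tr_s, v, n_perm = config$n_perm,
                       seed = derive_seed(seed,
                                          paste0("signal:", subset, ":", col)))
        rows[[length(rows) + 1L]] <- data.frame(
          subset = subset, column = col, D = fit$D, p_rand = fit$p_rand,
          p_brownian = fit$p_brownian, d_obs = fit$d_obs,
          prevalence = fit$prevalence, n_perm = fit$n_perm,
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    utils::write.csv(out, file.path(config$out_dir, "signal.csv"),
                     row.names = FALSE, quote = FALSE)
    out
  })

  alpha <- stage("alpha", {
    out <- guild_summary(tree, traits, guilds = config$guilds,
                         n_null = config$n_null,
                         seed = derive_seed(seed, "alpha"),
                         include_root = config$include_root)
    utils::write.csv(out, file.path(config$out_dir, "alpha.csv"),
                     row.names = FALSE, quote = FALSE)
    out
  })

  beta <- stage("beta", {
    out <- guild_beta_matrix(tree, traits, pairs = config$pairs,
                             n_null = config$n_null,
                             seed = derive_seed(seed, "beta"),
                             include_root = config$include_root,
                             ses_threshold = config$ses_threshold)
    utils::write.csv(out, file.path(config$out_dir, "beta.csv"),
                     row.names = FALSE, quote = FALSE)
    out
  })

  hot_files <- stage("hotnodes", {
    files <- character(0)
    for (g in config$guilds) {
      v <- stats::setNames(traits[[g]], traits$species)
      if (length(unique(v)) < 2L) {
        warning("guild '", g, "' constant on the tree; hot-node scan skipped")
        next
      }
      scan <- hot_node_scan(tree, v, min_clade = config$min_clade,
                            n_perm = config$n_perm,
                            ses_threshold = config$ses_threshold,
                            seed = derive_seed(seed, paste0("hotnodes:", g)))
      f <- file.path(config$out_dir, paste0("hotnodes_", g, ".csv"))
      write_hotnode_table(scan, f)
      write_newick(annotate_tree(tree, scan),
                   file.path(config$out_dir, paste0("annotated_", g, ".nwk")))
      files <- c(files, f)
    }
    files
  })

  manifest <- stage("manifest", {
    outputs <- list.files(config$out_dir, full.names = TRUE)
    outputs <- outputs[!grepl("manifest\\.json$", outputs)]
    m <- list(
      package = "ethnophylo",
      version = as.character(utils::packageVersion("ethnophylo")),
      seed = seed,
      config = unclass(config),
      n_species_analysed = ape::Ntip(tree),
      input_checksums = as.list(tools::md5sum(
        unlist(config[c("megatree", "taxa", "traits")]))),
      output_checksums = as.list(tools::md5sum(outputs))
    )
    jsonlite::write_json(m, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    m
  })
  invisible(manifest)
}
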