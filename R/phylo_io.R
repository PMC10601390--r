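# Tree and trait-table input/output with validation.
#
# All downstream statistics assume a rooted tree with non-negative branch
# lengths and unique tip labels; trait tables are strictly binary and keyed
# by canonical underscore binomials matching megatree tip-label convention.

#' Flag columns of a use-trait table
#'
#' Column-name constants shared by the readers, the generator and the
#' pipeline: management flags, use-type flags, and the nine organ flags.
#'
#' @return Character vector of column names.
#' @export
use_flag_columns <- function() c("edible", "condiment", "wrapping")

#' @rdname use_flag_columns
#' @export
management_flag_columns <- function() c("wild", "cultivated")

#' @rdname use_flag_columns
#' @export
organ_flag_columns <- function() {
  c("root_rhizome_bulb", "stem", "bark", "wood", "leaf", "flowers",
    "fruits", "seeds", "resin_latex")
}

#' @rdname use_flag_columns
#' @export
all_flag_columns <- function() {
  c(management_flag_columns(), use_flag_columns(), organ_flag_columns())
}

#' Canonicalize a species name to an underscore binomial
#'
#' Trims and collapses whitespace, joins name parts with underscores,
#' capitalizes the genus and lowercases the remaining epithets. Idempotent:
#' applying it to its own output is a no-op. Dated megatrees label tips
#' with underscore binomials, so all name matching in this package happens
#' on this canonical form, case-sensitively.
#'
#' @param raw Character vector of raw names ("Piper auritum", "piper_auritum").
#' @return Character vector of canonical binomials ("Piper_auritum").
#' @examples
#' canonicalize_name(" piper  auritum ")
#' @export
canonicalize_name <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  if (!is.character(raw)) raw <- as.character(raw)
  out <- vapply(raw, function(x) {
    x <- gsub("_", " ", x)
    x <- trimws(gsub("[[:space:]]+", " ", x))
    parts <- strsplit(x, " ", fixed = TRUE)[[1]]
    if (length(parts) < 2L) {
      stop("not a binomial (need at least genus and epithet): '", x, "'",
           call. = FALSE)
    }
    parts <- tolower(parts)
    substr(parts[1], 1, 1) <- toupper(substr(parts[1], 1, 1))
    paste(parts, collapse = "_")
  }, character(1), USE.NAMES = FALSE)
  out
}

#' Genus of a canonical binomial
#'
#' First underscore-separated token of a tip label; how genus membership of
#' megatree tips is derived (megatree labels carry genus but not family).
#'
#' @param species Character vector of canonical binomials.
#' @return Character vector of genus names.
#' @export
genus_of <- function(species) {
  sub("_.*$", "", species)
}

#' Test whether a tree is ultrametric within a relative tolerance
#'
#' @param tree A `phylo` object.
#' @param tol Relative tolerance: the spread of root-to-tip depths must not
#'   exceed `tol` times the maximum depth.
#' @return Logical scalar.
#' @export
is_ultrametric_tree <- function(tree, tol = 1e-6) {
  depths <- tip_depths(tree)
  dmax <- max(depths)
  if (dmax == 0) return(TRUE)
  (dmax - min(depths)) <= tol * dmax
}

# Root-to-tip path lengths, in tree edge-length units.
tip_depths <- function(tree) {
  ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
}

# Shared validation used by read_newick and the generator.
validate_phylogeny <- function(tree, context = "tree") {
  if (!inherits(tree, "phylo")) stop(context, ": not a phylo object", call. = FALSE)
  labs <- tree$tip.label
  if (any(!nzchar(labs))) stop(context, ": empty tip label(s)", call. = FALSE)
  dup <- unique(labs[duplicated(labs)])
  if (length(dup)) {
    stop(context, ": duplicate tip label(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop(context, ": tree has no branch lengths", call. = FALSE)
  }
  if (anyNA(tree$edge.length)) {
    stop(context, ": missing branch length on one or more edges", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    bad <- which(tree$edge.length < 0)[1]
    stop(context, ": negative branch length (edge to node ",
         tree$edge[bad, 2], ": ", tree$edge.length[bad], ")", call. = FALSE)
  }
  invisible(tree)
}

#' Read a single tree from a Newick file
#'
#' Thin wrapper over [ape::read.tree()] adding the validation every
#' downstream statistic relies on: a single rooted tree, unique non-empty
#' tip labels, a branch length on every edge, no negative lengths.
#' Quoted labels and bracketed comments are handled by the ape parser;
#' polytomies are preserved as-is; internal node labels are kept but unused.
#'
#' @param path Path to a file holding one Newick string ending in ";".
#' @return A validated `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  # strip [...] comments; ape's parser chokes on them mid-token
  txt <- gsub("\\[[^]]*\\]", "", txt)
  if (!grepl(";", txt, fixed = TRUE)) {
    stop("not a Newick file (no ';' terminator): ", path, call. = FALSE)
  }
  open_n <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  close_n <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (open_n != close_n) {
    stop("unbalanced parentheses in Newick (", open_n, " '(' vs ",
         close_n, "  ')'): ", path, call. = FALSE)
  }
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stop("Newick parse error in ", path,
                                            ": ", conditionMessage(e),
                                            call. = FALSE))
  if (is.null(tree)) stop("Newick parse error in ", path, call. = FALSE)
  if (inherits(tree, "multiPhylo")) {
    if (length(tree) != 1L) stop("expected one tree, found ", length(tree),
                                 " in ", path, call. = FALSE)
    tree <- tree[[1]]
  }
  validate_phylogeny(tree, context = path)
}

#' Write a tree to a Newick file
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# Coerce a flag column to strict 0/1 integers, with row-level error reporting.
coerce_flag <- function(x, column, species) {
  if (is.logical(x)) return(as.integer(x))
  x_chr <- tolower(trimws(as.character(x)))
  map <- c("0" = 0L, "1" = 1L, "true" = 1L, "false" = 0L,
           "t" = 1L, "f" = 0L, "yes" = 1L, "no" = 0L)
  out <- unname(map[x_chr])
  if (anyNA(out)) {
    bad <- which(is.na(out))
    stop("non-binary value in column '", column, "' for row(s) ",
         paste(sprintf("%d (%s='%s')", bad, species[bad], x[bad]),
               collapse = ", "), call. = FALSE)
  }
  out
}

#' Read a species use-trait table
#'
#' Reads a delimited table with columns `species, genus, family` plus the
#' binary flag columns listed by [all_flag_columns()], canonicalizes names,
#' and validates: flags strictly 0/1 (or true/false spellings), species
#' unique, and every species carrying at least one use flag (edible,
#' condiment or wrapping). The delimiter is auto-detected among comma and
#' tab, overridable via `delim`.
#'
#' @param path Path to the delimited text file (header row required).
#' @param delim `NULL` for auto-detection, or an explicit "," / "\t".
#' @return A list with elements `traits` (data.frame keyed by `species`,
#'   one integer 0/1 column per flag) and `taxa` (data.frame with
#'   `species`, `genus`, `family`).
#' @export
read_trait_table <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
                 lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"", comment.char = "")
  required <- c("species", "genus", "family", all_flag_columns())
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("trait table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  species <- canonicalize_name(df$species)
  taxa <- data.frame(species = species,
                     genus = trimws(df$genus),
                     family = trimws(df$family),
                     stringsAsFactors = FALSE)
  traits <- data.frame(species = species, stringsAsFactors = FALSE)
  for (col in all_flag_columns()) {
    traits[[col]] <- coerce_flag(df[[col]], col, species)
  }
  validate_trait_table(traits, taxa)
  list(traits = traits, taxa = taxa)
}

#' Validate a use-trait table and its taxonomy
#'
#' Checks the structural invariants: unique species keys, strictly binary
#' flags, at least one use flag per species, genus equal to the first
#' epithet of the species binomial, non-empty family.
#'
#' @param traits Data frame as returned in `read_trait_table()$traits`.
#' @param taxa Optional matching taxonomy data frame.
#' @return `traits`, invisibly; errors describe offending rows.
#' @export
validate_trait_table <- function(traits, taxa = NULL) {
  dup <- unique(traits$species[duplicated(traits$species)])
  if (length(dup)) {
    stop("duplicate species in trait table: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  for (col in intersect(all_flag_columns(), names(traits))) {
    v <- traits[[col]]
    if (!all(v %in% c(0L, 1L))) {
      stop("column '", col, "' is not strictly 0/1", call. = FALSE)
    }
  }
  use <- traits[, use_flag_columns(), drop = FALSE]
  none <- rowSums(use) == 0
  if (any(none)) {
    stop("species with no use flag set (need edible, condiment or wrapping): ",
         paste(traits$species[none], collapse = ", "), call. = FALSE)
  }
  if (!is.null(taxa)) {
    if (!all(taxa$species == traits$species)) {
      stop("taxonomy rows do not match trait rows", call. = FALSE)
    }
    bad_genus <- taxa$genus != genus_of(taxa$species)
    if (any(bad_genus)) {
      stop("genus does not match species binomial for: ",
           paste(taxa$species[bad_genus], collapse = ", "), call. = FALSE)
    }
    if (any(!nzchar(taxa$family))) {
      stop("empty family for: ",
           paste(taxa$species[!nzchar(taxa$family)], collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(traits)
}

#' Write a use-trait table
#'
#' Inverse of [read_trait_table()]: writes the standard 17-flag layout with
#' taxonomy columns, so that read(write(T)) reproduces T.
#'
#' @param traits Trait data frame (`species` plus flag columns).
#' @param taxa Taxonomy data frame (`species`, `genus`, `family`).
#' @param path Output path.
#' @param delim Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(traits, taxa, path, delim = ",") {
  stopifnot(all(taxa$species == traits$species))
  out <- data.frame(species = traits$species,
                    genus = taxa$genus,
                    family = taxa$family,
                    stringsAsFactors = FALSE)
  for (col in all_flag_columns()) out[[col]] <- traits[[col]]
  utils::write.table(out, path, sep = delim, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Extract a guild (species set) from a trait table
#'
#' @param traits Trait data frame.
#' @param guild Name of a flag column.
#' @return Character vector of species with that flag set.
#' @export
guild_members <- function(traits, guild) {
  if (!guild %in% names(traits)) {
    stop("unknown guild column: ", guild, call. = FALSE)
  }
  traits$species[traits[[guild]] == 1L]
}
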