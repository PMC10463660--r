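#' Read an ASV count table from TSV
#'
#' Reads a tab-delimited count table into the canonical community tibble
#' (one row per sample, one column per ASV). Amplicon tables are most often
#' written with ASVs as rows and samples as columns, which is the default
#' orientation; set `orientation = "samples_as_rows"` for the transposed
#' dialect. The table is validated on the way in: counts must be non-negative
#' integers and identifiers unique.
#'
#' @param path Path to a TSV file with a header row; the first column holds
#'   ASV (default) or sample identifiers.
#' @param orientation `"asvs_as_rows"` (default) or `"samples_as_rows"`.
#' @return A community tibble: `sample_id` column plus one integer column per
#'   ASV.
#' @seealso [write_community_table()], [read_biom_table()]
#' @export
read_community_table <- function(path, orientation = c("asvs_as_rows", "samples_as_rows")) {
  orientation <- match.arg(orientation)
  raw <- readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  if (ncol(raw) < 2) abort("count table needs an identifier column plus at least one data column")
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate identifiers in %s: %s", path,
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (anyDuplicated(names(raw)[-1])) {
    abort(sprintf("duplicate identifiers in %s header", path))
  }
  m <- as.matrix(raw[-1])
  rownames(m) <- ids
  if (orientation == "asvs_as_rows") m <- t(m)
  # report first offending cell in file coordinates
  bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    s <- rownames(m)[bad[1, 1]]; a <- colnames(m)[bad[1, 2]]
    abort(sprintf("non-integer or negative count at sample '%s', ASV '%s' in %s", s, a, path))
  }
  tbl <- community_tibble(m)
  validate_community(tbl)
  tbl
}

#' Write an ASV count table to TSV
#'
#' @inheritParams community_matrix
#' @param path Output file path.
#' @param orientation Orientation to write; default matches
#'   [read_community_table()]'s default (ASVs as rows).
#' @return `path`, invisibly.
#' @export
write_community_table <- function(table, path,
                                  orientation = c("asvs_as_rows", "samples_as_rows")) {
  orientation <- match.arg(orientation)
  m <- community_matrix(table)
  if (orientation == "asvs_as_rows") {
    out <- dplyr::bind_cols(tibble::tibble(asv_id = colnames(m)),
                            tibble::as_tibble(t(m)))
  } else {
    out <- community_tibble(m)
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a community table from a BIOM (JSON) file
#'
#' Optional reader for the BIOM interchange format, mapped onto the same
#' community tibble as [read_community_table()]. Requires the `biomformat`
#' package.
#'
#' @param path Path to a BIOM-JSON file.
#' @return A community tibble.
#' @export
read_biom_table <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    abort("read_biom_table() requires the 'biomformat' package")
  }
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix") # taxa x samples
  tbl <- community_tibble(t(m))
  validate_community(tbl)
  tbl
}

#' Read a rooted phylogeny from a Newick file
#'
#' Reads a Newick tree whose tips are ASV identifiers. Branch lengths are
#' required (all phylogenetic turnover metrics are in branch-length units).
#' Unrooted trees are midpoint-rooted: cophenetic distances are
#' rooting-invariant, so any deterministic rooting suffices and midpoint is
#' the convention.
#'
#' @param path Path to a Newick file.
#' @return An [ape::phylo] object, rooted, with branch lengths.
#' @export
read_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) abort(paste0("could not parse Newick file: ", path))
  validate_tree(tr)
}

#' Validate (and if needed midpoint-root) a phylogeny
#'
#' @param tree An [ape::phylo] object.
#' @return The validated, rooted tree.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) abort("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  if (anyNA(tree$edge.length)) abort("tree has missing branch lengths")
  if (any(tree$edge.length < 0)) abort("tree has negative branch lengths")
  if (anyDuplicated(tree$tip.label)) {
    abort(paste0("duplicate tip labels: ",
                 paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", ")))
  }
  if (length(tree$tip.label) < 2) abort("tree must have at least 2 tips")
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  tree
}

#' Write a phylogeny to Newick
#' @param tree An [ape::phylo] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Expects one row per sample keyed by `sample_id`, with the design columns
#' used downstream (`site`, `substrate`, `time`, `replicate`; optional planar
#' `x`, `y` coordinates for distance-decay analyses).
#'
#' @param path Path to a TSV file.
#' @return A tibble with a character `sample_id` column.
#' @export
read_sample_metadata <- function(path) {
  meta <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (!"sample_id" %in% names(meta)) abort("metadata must have a `sample_id` column")
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id)) abort("duplicate sample_id in metadata")
  meta
}

#' Read a per-site environmental table from TSV
#'
#' One row per site (`site` column), one numeric column per environmental
#' variable.
#'
#' @param path Path to a TSV file.
#' @return A tibble keyed by `site`.
#' @export
read_env_table <- function(path) {
  env <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (!"site" %in% names(env)) abort("environmental table must have a `site` column")
  env$site <- as.character(env$site)
  if (anyDuplicated(env$site)) abort("duplicate site in environmental table")
  env
}

#' Align a community table, phylogeny and metadata
#'
#' Intersects the ASV namespace of the count table with the tree's tips and
#' the sample namespace with the metadata, prunes all three objects to the
#' common sets, and reports what was dropped. Erroring on an empty
#' intersection protects against mismatched inputs (e.g. a tree from a
#' different run).
#'
#' @inheritParams community_matrix
#' @param tree An [ape::phylo] whose tips are ASV identifiers (optional).
#' @param metadata A sample metadata tibble (optional).
#' @param quiet Suppress the dropped-identifier messages.
#' @return A list with elements `table`, `tree`, `metadata`, mutually aligned.
#' @export
align_inputs <- function(table, tree = NULL, metadata = NULL, quiet = FALSE) {
  m <- community_matrix(table)
  if (!is.null(tree)) {
    keep_asv <- intersect(colnames(m), tree$tip.label)
    if (length(keep_asv) == 0) abort("no ASVs shared between the count table and the tree")
    dropped_tbl <- ncol(m) - length(keep_asv)
    dropped_tip <- length(tree$tip.label) - length(keep_asv)
    if (!quiet && (dropped_tbl > 0 || dropped_tip > 0)) {
      inform(sprintf("align_inputs: dropped %d table ASVs and %d tree tips outside the intersection",
                     dropped_tbl, dropped_tip))
    }
    m <- m[, keep_asv, drop = FALSE]
    if (dropped_tip > 0) {
      tree <- ape::keep.tip(tree, keep_asv)
    }
  }
  if (!is.null(metadata)) {
    keep_s <- intersect(rownames(m), metadata$sample_id)
    if (length(keep_s) == 0) abort("no samples shared between the count table and the metadata")
    dropped_s <- nrow(m) - length(keep_s)
    dropped_m <- nrow(metadata) - length(keep_s)
    if (!quiet && (dropped_s > 0 || dropped_m > 0)) {
      inform(sprintf("align_inputs: dropped %d table samples and %d metadata rows outside the intersection",
                     dropped_s, dropped_m))
    }
    m <- m[keep_s, , drop = FALSE]
    metadata <- metadata[match(keep_s, metadata$sample_id), , drop = FALSE]
  }
  list(table = community_tibble(m), tree = tree, metadata = metadata)
}
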