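#' Run the full assembly-inference pipeline
#'
#' Wires the stages together per analysis group (by default substrate x
#' time): betaNTI (tip-shuffle null) -> RCbray (for pairs not dominated by
#' selection) -> process classification -> percentage summary. Samples below
#' `min_reads` are removed first (low library sizes obscure biological
#' pattern); the framework runs on the raw counts of the retained samples,
#' since the RCbray null explicitly reconstructs each sample's read depth.
#'
#' Each stochastic stage derives its seed deterministically from the master
#' seed and the group index, so adding a stage or group never perturbs
#' another's random stream, and the run manifest suffices to reproduce every
#' output bitwise.
#'
#' @inheritParams community_matrix
#' @param tree An [ape::phylo] over the table's ASVs.
#' @param metadata Sample metadata tibble (`sample_id` plus grouping
#'   columns).
#' @param group_by Grouping columns defining within-group pairs; use
#'   `character(0)` to analyse all samples as one group.
#' @param reps Null randomisations for both betaNTI and RCbray.
#' @param seed Master seed.
#' @param bnti_threshold,rc_threshold Classification thresholds.
#' @param min_reads Minimum sample total; smaller samples are dropped.
#' @param weighted Abundance-weighted betaMNTD (default) or presence/absence.
#' @param out_dir Optional directory: writes `pairs.tsv`, `profile.tsv` and
#'   `manifest.json`.
#' @return An `assembly_analysis` object: list with `pairs` (classified
#'   pairwise turnover tibble), `profile` ([summarize_assembly()] output),
#'   `manifest`, and the inputs' dimensions.
#' @export
run_pipeline <- function(table, tree, metadata, group_by = c("substrate", "time"),
                         reps = 999, seed = 1L, bnti_threshold = 2,
                         rc_threshold = 0.95, min_reads = 1000,
                         weighted = TRUE, out_dir = NULL) {
  if (is.null(tree)) abort("stage bnti requires a phylogeny")
  if (length(group_by) > 0 && !all(group_by %in% names(metadata))) {
    abort(paste0("stage grouping: metadata lacks column(s) ",
                 paste(setdiff(group_by, names(metadata)), collapse = ", ")))
  }
  al <- align_inputs(table, tree, metadata, quiet = TRUE)
  m <- community_matrix(al$table)
  keep <- rowSums(m) >= min_reads
  if (!any(keep)) abort(sprintf("no samples with >= %d reads", min_reads))
  if (any(!keep)) {
    inform(sprintf("run_pipeline: dropped %d sample(s) with < %d reads", sum(!keep), min_reads))
    m <- m[keep, , drop = FALSE]
    al$metadata <- al$metadata[al$metadata$sample_id %in% rownames(m), , drop = FALSE]
  }
  D <- phylo_distances(al$tree)

  groups <- if (length(group_by) > 0) {
    split(al$metadata$sample_id,
          interaction(al$metadata[group_by], drop = TRUE, lex.order = TRUE))
  } else {
    list(all = rownames(m))
  }
  seeds <- list()
  pair_list <- list()
  for (g in seq_along(groups)) {
    ids <- intersect(rownames(m), groups[[g]])
    if (length(ids) < 2) {
      abort(sprintf("stage bnti: group '%s' has fewer than 2 samples", names(groups)[g]))
    }
    sub <- community_tibble(m[ids, , drop = FALSE])
    s_bnti <- stage_seed(seed, "bnti") + g
    s_rc <- stage_seed(seed, "rcbray") + g
    seeds[[names(groups)[g]]] <- list(bnti = s_bnti, rcbray = s_rc)
    pb <- bnti(sub, D, reps = reps, seed = s_bnti, weighted = weighted)
    pr <- rcbray(sub, reps = reps, seed = s_rc)
    pairs <- dplyr::left_join(pb, pr, by = c("sample_a", "sample_b"))
    pair_list[[g]] <- pairs
  }
  pairs <- dplyr::bind_rows(pair_list)
  pairs <- classify_processes(pairs, bnti_threshold, rc_threshold)
  profile <- summarize_assembly(pairs, al$metadata, group_by = group_by)
  if (length(group_by) > 0) {
    ga <- al$metadata[match(pairs$sample_a, al$metadata$sample_id), group_by, drop = FALSE]
    pairs <- dplyr::bind_cols(pairs, ga)
  }

  manifest <- list(
    subcommand = "run_pipeline",
    package_version = as.character(utils::packageVersion("assemblr")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    parameters = list(
      group_by = group_by, reps = reps, bnti_threshold = bnti_threshold,
      rc_threshold = rc_threshold, min_reads = min_reads, weighted = weighted
    ),
    master_seed = as.integer(seed),
    stage_seeds = seeds,
    inputs = list(
      n_samples = nrow(m), n_asvs = ncol(m), n_groups = length(groups),
      checksums = input_checksums(al$table, al$tree, al$metadata)
    )
  )
  out <- structure(
    list(pairs = pairs, profile = profile, manifest = manifest,
         group_by = group_by),
    class = "assembly_analysis"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(pairs, file.path(out_dir, "pairs.tsv"), progress = FALSE)
    readr::write_tsv(profile, file.path(out_dir, "profile.tsv"), progress = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

# md5 checksums of the aligned inputs, via their canonical on-disk form
input_checksums <- function(table, tree, metadata) {
  td <- tempfile("assemblr-checksum-")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  write_community_table(table, file.path(td, "table.tsv"))
  paths <- file.path(td, "table.tsv")
  names(paths) <- "table"
  if (!is.null(tree)) {
    write_tree(tree, file.path(td, "tree.nwk"))
    paths <- c(paths, tree = file.path(td, "tree.nwk"))
  }
  if (!is.null(metadata)) {
    readr::write_tsv(metadata, file.path(td, "metadata.tsv"), progress = FALSE)
    paths <- c(paths, metadata = file.path(td, "metadata.tsv"))
  }
  as.list(setNames(unname(tools::md5sum(paths)), names(paths)))
}

#' @export
print.assembly_analysis <- function(x, ...) {
  cat(sprintf("assembly analysis: %d pairs, %d group(s)\n",
              nrow(x$pairs), x$manifest$inputs$n_groups))
  print(x$profile)
  invisible(x)
}

#' @method tidy assembly_analysis
#' @export
tidy.assembly_analysis <- function(x, ...) tibble::as_tibble(x$pairs)

#' @method glance assembly_analysis
#' @export
glance.assembly_analysis <- function(x, ...) {
  prof <- x$profile
  grouped <- dplyr::group_by(prof, dplyr::across(dplyr::all_of(x$group_by)))
  dplyr::summarise(
    grouped,
    n_classified = .data$n_classified[1],
    n_undefined = .data$n_undefined[1],
    modal_process = as.character(.data$process[which.max(.data$percent)]),
    modal_percent = max(.data$percent),
    .groups = "drop"
  )
}
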