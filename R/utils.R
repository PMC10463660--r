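#' Convert a community tibble to a count matrix
#'
#' The canonical in-memory form of a community table in assemblr is a tibble
#' with a `sample_id` column and one numeric column per ASV. Internally most
#' computations run on the equivalent samples-by-ASVs matrix.
#'
#' @param table A community tibble (`sample_id` column plus one column per
#'   ASV) as returned by [read_community_table()].
#' @return A numeric matrix, samples as rows (named), ASVs as columns (named).
#' @export
#' @examples
#' tbl <- tibble::tibble(sample_id = c("s1", "s2"), a = c(1, 0), b = c(2, 3))
#' community_matrix(tbl)
community_matrix <- function(table) {
  stopifnot(is.data.frame(table))
  if (!"sample_id" %in% names(table)) {
    abort("community table must have a `sample_id` column")
  }
  ids <- as.character(table$sample_id)
  m <- as.matrix(table[setdiff(names(table), "sample_id")])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Convert a count matrix to a community tibble
#'
#' @param mat Numeric matrix, samples as rows, ASVs as columns, both named.
#' @return A community tibble.
#' @export
community_tibble <- function(mat) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(mat)),
    tibble::as_tibble(mat)
  )
}

#' Validate a community table
#'
#' Checks the invariants every downstream analysis relies on: unique sample and
#' ASV identifiers, non-negative integer counts, no missing values.
#'
#' @inheritParams community_matrix
#' @param min_samples,min_asvs Minimum dimensions to accept.
#' @return The table, invisibly, if valid; otherwise an error.
#' @export
validate_community <- function(table, min_samples = 1L, min_asvs = 1L) {
  m <- community_matrix(table)
  if (anyDuplicated(rownames(m))) {
    abort(paste0("duplicate sample identifiers: ",
                 paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", ")))
  }
  if (anyDuplicated(colnames(m))) {
    abort(paste0("duplicate ASV identifiers: ",
                 paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", ")))
  }
  if (anyNA(m)) abort("community table contains missing values")
  bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("invalid count %s at sample '%s', ASV '%s' (must be a non-negative integer)",
                  format(m[bad[1, , drop = FALSE]]),
                  rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  if (nrow(m) < min_samples || ncol(m) < min_asvs) {
    abort(sprintf("community table must have at least %d samples and %d ASVs (has %d x %d)",
                  min_samples, min_asvs, nrow(m), ncol(m)))
  }
  invisible(table)
}

#' Row-normalise a count matrix to relative abundances
#' @param mat samples-by-ASVs matrix with positive row sums.
#' @return Matrix of the same shape whose rows sum to 1.
#' @keywords internal
rel_abund <- function(mat) {
  tot <- rowSums(mat)
  if (any(tot <= 0)) {
    abort(paste0("samples with zero total counts: ",
                 paste(rownames(mat)[tot <= 0], collapse = ", ")))
  }
  sweep(mat, 1, tot, "/")
}

#' Tidy a distance matrix into a long tibble
#'
#' @param d A `dist` object or symmetric matrix with identifiers.
#' @return Tibble with columns `id_a`, `id_b`, `distance`, one row per
#'   unordered pair (lower triangle).
#' @export
tidy_dist <- function(d) {
  m <- as.matrix(d)
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  idx <- which(lower.tri(m), arr.ind = TRUE)
  tibble::tibble(
    id_a = ids[idx[, 2]],
    id_b = ids[idx[, 1]],
    distance = m[idx]
  )
}

# column minima of a matrix (rows kept); base-R workhorse used in hot loops
col_mins <- function(m) {
  if (nrow(m) == 1L) return(m[1L, ])
  do.call(pmin, lapply(seq_len(nrow(m)), function(i) m[i, ]))
}

# Deterministic per-stage seed derivation from a master seed. Offsets are
# fixed per stage name so adding a stage never perturbs another stage's stream.
stage_seed <- function(master_seed, stage) {
  offsets <- c(
    tree = 11L, traits = 23L, communities = 37L, bnti = 101L,
    rcbray = 211L, correlogram = 307L, mantel = 401L, rarefy = 503L,
    benchmark = 601L
  )
  if (!stage %in% names(offsets)) abort(paste0("unknown stage: ", stage))
  (as.integer(master_seed) %% 2000000000L) + offsets[[stage]]
}

# permutation p-value with add-one smoothing
perm_pvalue <- function(n_as_extreme, n_perm) {
  (n_as_extreme + 1) / (n_perm + 1)
}

# all permutations of 1:n (n small), as a list
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- all_permutations(n - 1L)
    out <- c(out, lapply(rest, function(p) c(i, (seq_len(n)[-i])[p])))
  }
  out
}
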