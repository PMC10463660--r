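#' Rarefy a count table to even depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric, the semantics of `vegan::rrarefy`) down to `depth`.
#' Samples whose total is below `depth` are dropped with a message, matching
#' the usual practice of rarefying alpha-diversity data to a fixed depth.
#'
#' @inheritParams community_matrix
#' @param depth Target reads per sample (positive integer).
#' @param seed Integer seed; the subsampling is reproducible given the seed.
#' @return A community tibble in which every retained sample sums to `depth`.
#' @export
rarefy_counts <- function(table, depth, seed = 1L) {
  stopifnot(depth >= 1)
  m <- community_matrix(table)
  validate_community(table)
  tot <- rowSums(m)
  keep <- tot >= depth
  if (!any(keep)) abort(sprintf("all samples have fewer than %d reads", depth))
  if (any(!keep)) {
    inform(sprintf("rarefy_counts: dropped %d sample(s) with < %d reads: %s",
                   sum(!keep), depth, paste(rownames(m)[!keep], collapse = ", ")))
  }
  m <- m[keep, , drop = FALSE]
  withr_seed(seed)
  out <- suppressWarnings(vegan::rrarefy(m, depth))
  community_tibble(out)
}

# set.seed scoped like withr::with_seed but without the dependency: callers
# inside the package always reseed explicitly, so a plain set.seed is fine.
withr_seed <- function(seed) set.seed(as.integer(seed))

#' Cumulative sum scaling (CSS) normalisation
#'
#' Divides each sample's counts by the cumulative sum of its counts up to a
#' fixed quantile of its own nonzero-count distribution, then rescales by the
#' median of those per-sample sums so values stay on a count-like scale.
#' CSS reduces the influence of a few very abundant taxa on depth scaling.
#' The quantile is fixed (default 0.5) rather than chosen adaptively, which
#' keeps the transformation deterministic.
#'
#' @inheritParams community_matrix
#' @param quantile Quantile of each sample's nonzero counts defining the
#'   cumulative sum; in (0, 1]. `quantile = 1` reduces to total-sum scaling.
#' @return A numeric matrix (samples x ASVs) of normalised abundances.
#' @export
css_normalize <- function(table, quantile = 0.5) {
  stopifnot(quantile > 0, quantile <= 1)
  m <- community_matrix(table)
  tot <- rowSums(m)
  if (any(tot <= 0)) {
    abort(paste0("samples with zero total counts: ",
                 paste(rownames(m)[tot <= 0], collapse = ", ")))
  }
  scal <- vapply(seq_len(nrow(m)), function(i) {
    x <- m[i, ]
    nz <- x[x > 0]
    q <- stats::quantile(nz, probs = quantile, names = FALSE)
    sum(x[x <= q])
  }, numeric(1))
  const <- stats::median(scal)
  out <- sweep(m, 1, scal, "/") * const
  rownames(out) <- rownames(m)
  out
}

#' Shannon diversity per sample
#'
#' H = -sum(p * log(p)) over each sample's nonzero relative abundances,
#' natural logarithm.
#'
#' @inheritParams community_matrix
#' @return Tibble with columns `sample_id`, `shannon`.
#' @export
shannon_diversity <- function(table) {
  m <- community_matrix(table)
  if (any(rowSums(m) <= 0)) {
    abort(paste0("samples with zero total counts: ",
                 paste(rownames(m)[rowSums(m) <= 0], collapse = ", ")))
  }
  tibble::tibble(
    sample_id = rownames(m),
    shannon = as.numeric(vegan::diversity(m, index = "shannon"))
  )
}

#' Bray-Curtis dissimilarity between samples
#'
#' BC(x, y) = sum(|x - y|) / sum(x + y) over ASVs, computed on whatever
#' abundance scale the table carries (raw counts, relative abundances or
#' CSS-normalised values).
#'
#' @param table A community tibble or a samples-by-ASVs numeric matrix.
#' @return A `dist` object labelled by sample identifiers.
#' @export
bray_curtis <- function(table) {
  m <- if (is.matrix(table)) table else community_matrix(table)
  if (nrow(m) < 2) abort("need at least 2 samples")
  if (any(rowSums(m) <= 0)) {
    abort(paste0("all-zero samples have undefined Bray-Curtis dissimilarity: ",
                 paste(rownames(m)[rowSums(m) <= 0], collapse = ", ")))
  }
  vegan::vegdist(m, method = "bray")
}

#' Shared and unique ASV fractions across substrates
#'
#' For each substrate and sampling time, partitions the substrate's presence
#' set (ASVs with nonzero counts in any sample of that substrate/time) into
#' ASVs unique to it, ASVs shared with exactly one other substrate, and ASVs
#' shared with all substrates, and reports each part as a fraction of the
#' focal presence set.
#'
#' @inheritParams community_matrix
#' @param metadata Sample metadata tibble with `sample_id`, `substrate`,
#'   `time`.
#' @return Tibble with columns `substrate`, `time`, `category`, `n_asvs`,
#'   `fraction`; fractions sum to 1 within each substrate-time.
#' @export
shared_unique_fractions <- function(table, metadata) {
  m <- community_matrix(table)
  meta <- metadata[match(rownames(m), metadata$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) abort("every sample needs a metadata row")
  out <- list()
  for (tm in unique(meta$time)) {
    sel_t <- meta$time == tm
    subs <- unique(meta$substrate[sel_t])
    presence <- lapply(subs, function(s) {
      rows <- sel_t & meta$substrate == s
      colnames(m)[colSums(m[rows, , drop = FALSE]) > 0]
    })
    names(presence) <- subs
    for (s in subs) {
      focal <- presence[[s]]
      if (length(focal) == 0) abort(sprintf("empty presence set for substrate '%s' at time '%s'", s, tm))
      others <- setdiff(subs, s)
      in_other <- vapply(others, function(o) focal %in% presence[[o]],
                         logical(length(focal)))
      in_other <- matrix(in_other, nrow = length(focal))
      n_shared <- rowSums(in_other)
      cats <- c("unique",
                paste0("shared_with_", others),
                if (length(others) > 1) "shared_with_all")
      counts <- c(sum(n_shared == 0),
                  vapply(seq_along(others), function(k) {
                    sum(in_other[, k] & n_shared == 1)
                  }, numeric(1)),
                  if (length(others) > 1) sum(n_shared == length(others)))
      # with 3+ substrates, pairs shared with exactly two (but not all) of
      # >2 others would need finer categories; the three-substrate design
      # (leaf / fruit / soil) is the supported case
      if (length(others) > 2) abort("shared_unique_fractions supports at most 3 substrates")
      out[[length(out) + 1]] <- tibble::tibble(
        substrate = s, time = tm, category = cats,
        n_asvs = as.numeric(counts),
        fraction = counts / length(focal)
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the lower-triangle entries, with significance from
#' simultaneous row/column permutations of one matrix. P-values use add-one
#' smoothing ((count + 1) / (permutations + 1)) so they are never exactly 0.
#' With `exhaustive = TRUE` (or automatically when the number of objects is
#' at most `exhaustive_max`), all n! permutations are enumerated and the
#' p-value is the exact tail probability (the identity permutation included).
#'
#' @param d1,d2 `dist` objects or symmetric matrices over the same
#'   identifiers, in the same order.
#' @param permutations Number of random permutations (>= 99).
#' @param seed Integer seed for the permutations.
#' @param alternative `"greater"` (default, the distance-decay hypothesis),
#'   `"less"`, or `"two.sided"`.
#' @param exhaustive Force exact enumeration of all permutations.
#' @param exhaustive_max Enumerate exactly when n objects <= this (default 0,
#'   i.e. never unless `exhaustive = TRUE`).
#' @return An object of class `mantel_test`: list with `statistic` (r),
#'   `p_value`, `permutations`, `alternative`, `exact`.
#' @export
mantel_test <- function(d1, d2, permutations = 999, seed = 1L,
                        alternative = c("greater", "less", "two.sided"),
                        exhaustive = FALSE, exhaustive_max = 0L) {
  alternative <- match.arg(alternative)
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  if (!identical(dim(m1), dim(m2))) abort("distance matrices must have matching dimensions")
  n <- nrow(m1)
  if (n < 3) abort("Mantel test needs at least 3 objects")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2))) {
    abort("distance matrices must be over the same identifiers in the same order")
  }
  ltri <- lower.tri(m1)
  x <- m1[ltri]
  r_for <- function(perm) cor(x, m2[perm, perm][ltri])
  r_obs <- r_for(seq_len(n))

  exact <- exhaustive || n <= exhaustive_max
  if (exact) {
    perms <- all_permutations(n)
    r_null <- vapply(perms, r_for, numeric(1))
    p <- switch(alternative,
      greater   = mean(r_null >= r_obs - 1e-12),
      less      = mean(r_null <= r_obs + 1e-12),
      two.sided = mean(abs(r_null) >= abs(r_obs) - 1e-12)
    )
    n_perm <- length(perms)
  } else {
    if (permutations < 99) abort("use at least 99 permutations")
    withr_seed(seed)
    r_null <- vapply(seq_len(permutations), function(i) {
      r_for(sample.int(n))
    }, numeric(1))
    p <- switch(alternative,
      greater   = perm_pvalue(sum(r_null >= r_obs - 1e-12), permutations),
      less      = perm_pvalue(sum(r_null <= r_obs + 1e-12), permutations),
      two.sided = perm_pvalue(sum(abs(r_null) >= abs(r_obs) - 1e-12), permutations)
    )
    n_perm <- permutations
  }
  structure(
    list(statistic = r_obs, p_value = p, permutations = n_perm,
         alternative = alternative, exact = exact, n = n),
    class = "mantel_test"
  )
}

#' @export
print.mantel_test <- function(x, ...) {
  cat("Mantel test (", if (x$exact) "exact enumeration" else paste0(x$permutations, " permutations"),
      ")\n", sep = "")
  cat(sprintf("  r = %.4f, p = %.4g (%s)\n", x$statistic, x$p_value, x$alternative))
  invisible(x)
}

#' @method tidy mantel_test
#' @export
tidy.mantel_test <- function(x, ...) {
  tibble::tibble(
    estimate = x$statistic, p.value = x$p_value,
    permutations = x$permutations, alternative = x$alternative,
    exact = x$exact
  )
}
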