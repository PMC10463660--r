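#' Abundance-weighted environmental niche optima per ASV
#'
#' Each ASV's niche optimum for an environmental variable is the mean of that
#' variable over the samples the ASV occurs in, weighted by the ASV's
#' within-sample relative abundance f_ij: optimum(i, k) =
#' sum_j f_ij e_jk / sum_j f_ij, where e_jk is the environmental value of
#' sample j's site. Relative abundances make the optima invariant to
#' sequencing depth. Variables are standardised to zero
#' mean and unit variance across sites by default, so the Euclidean niche
#' distances built from the optima are not dominated by any one variable's
#' units.
#'
#' @inheritParams community_matrix
#' @param env Per-site environmental tibble (`site` column plus numeric
#'   variables).
#' @param metadata Sample metadata tibble mapping `sample_id` to `site`.
#' @param variables Which environmental columns to use; default all numeric
#'   columns.
#' @param standardize Standardise variables across sites first (default
#'   TRUE).
#' @return Tibble with `asv_id` plus one optimum column per variable; ASVs
#'   absent from every sample are dropped with a warning.
#' @export
niche_optima <- function(table, env, metadata, variables = NULL,
                         standardize = TRUE) {
  m <- community_matrix(table)
  meta <- metadata[match(rownames(m), metadata$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) abort("every sample needs a metadata row")
  if (is.null(variables)) {
    variables <- names(env)[vapply(env, is.numeric, logical(1))]
  }
  if (length(variables) == 0) abort("no environmental variables selected")
  ev <- as.matrix(env[, variables, drop = FALSE])
  rownames(ev) <- env$site
  if (anyNA(ev)) abort("missing values in the selected environmental variables")
  if (standardize) ev <- scale(ev)
  if (!all(meta$site %in% rownames(ev))) {
    abort(paste0("sites missing from the environmental table: ",
                 paste(setdiff(meta$site, rownames(ev)), collapse = ", ")))
  }
  E <- ev[meta$site, , drop = FALSE] # samples x variables
  f <- rel_abund(m)
  absent <- colSums(m) == 0
  if (any(absent)) {
    warn(sprintf("niche_optima: dropped %d ASV(s) absent from every sample", sum(absent)))
    f <- f[, !absent, drop = FALSE]
  }
  opt <- sweep(t(f) %*% E, 1, colSums(f), "/")
  dplyr::bind_cols(tibble::tibble(asv_id = colnames(f)),
                   tibble::as_tibble(opt))
}

#' Euclidean distance between ASV niche optima
#'
#' @param optima Tibble from [niche_optima()] (`asv_id` plus optimum
#'   columns).
#' @return A `dist` object labelled by ASV identifiers.
#' @export
niche_distance <- function(optima) {
  m <- as.matrix(optima[setdiff(names(optima), "asv_id")])
  rownames(m) <- optima$asv_id
  if (anyNA(m)) abort("missing niche optima")
  dist(m, method = "euclidean")
}

#' Mantel correlogram between niche and phylogenetic distances
#'
#' Tests the framework's precondition that ecological niches are
#' phylogenetically conserved at short distances. Phylogenetic distances are
#' binned into equal-width classes; for each class, the Mantel correlation
#' between the niche distance matrix and the class-membership model matrix is
#' computed, with the sign oriented so that positive r means pairs in the
#' class are *more similar* in niche than average (clustering). Significance
#' comes from row/column permutations of the niche matrix, one-tailed for
#' clustering by default, with progressive Holm correction (class k corrected
#' among the first k tested classes). Classes whose lower bound exceeds the
#' cutoff (default half the maximum phylogenetic distance, the usual
#' correlogram validity domain) are computed but flagged untested.
#'
#' @param niche_d,phylo_d `dist` objects or symmetric matrices over the same
#'   ASVs in the same order ([niche_distance()] and [phylo_distances()]).
#' @param n_classes Number of distance classes, or `"auto"` for Sturges'
#'   rule on the number of pairs.
#' @param permutations Number of permutations (>= 99).
#' @param seed Integer seed.
#' @param cutoff_frac Classes with lower bound beyond `cutoff_frac` x max
#'   distance are flagged untested.
#' @param alternative `"greater"` (clustering, default), `"less"`, or
#'   `"two.sided"`.
#' @return A `mantel_correlogram` object: list with a `classes` tibble
#'   (`class`, `lower`, `upper`, `center`, `n_pairs`, `mantel_r`, `p_value`,
#'   `p_holm`, `tested`) and the call parameters.
#' @export
mantel_correlogram <- function(niche_d, phylo_d, n_classes = "auto",
                               permutations = 999, seed = 1L,
                               cutoff_frac = 0.5,
                               alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (permutations < 99) abort("use at least 99 permutations")
  mn <- as.matrix(niche_d); mp <- as.matrix(phylo_d)
  if (!identical(dim(mn), dim(mp))) abort("matrices must have matching dimensions")
  if (!is.null(rownames(mn)) && !is.null(rownames(mp)) &&
      !identical(rownames(mn), rownames(mp))) {
    abort("matrices must be over the same ASVs in the same order")
  }
  n <- nrow(mn)
  ltri <- lower.tri(mn)
  x <- mn[ltri]
  dphy <- mp[ltri]
  n_p <- length(x)
  if (identical(n_classes, "auto")) n_classes <- ceiling(1 + log2(n_p))
  dmax <- max(dphy)
  breaks <- seq(0, dmax, length.out = n_classes + 1)
  cls <- findInterval(dphy, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  n_d <- tabulate(cls, nbins = n_classes)

  mean_x <- mean(x)
  sd_x <- sd(x)
  if (sd_x == 0) abort("niche distances have zero variance")
  sd_m <- vapply(n_d, function(k) {
    if (k == 0 || k == n_p) return(NA_real_)
    sd(c(rep(1, k), rep(0, n_p - k)))
  }, numeric(1))
  # Mantel r of niche distances against the class model matrix, negated so
  # that positive r = within-class similarity (clustering)
  r_from_sums <- function(S) {
    -(S - n_d * mean_x) / ((n_p - 1) * sd_x * sd_m)
  }
  S_obs <- vapply(seq_len(n_classes), function(k) sum(x[cls == k]), numeric(1))
  r_obs <- r_from_sums(S_obs)

  idx <- which(ltri, arr.ind = TRUE)
  i1 <- idx[, 1]; i2 <- idx[, 2]
  withr_seed(seed)
  count <- matrix(0, permutations, n_classes)
  for (p in seq_len(permutations)) {
    prm <- sample.int(n)
    xp <- mn[cbind(prm[i1], prm[i2])]
    Sp <- vapply(split(xp, cls), sum, numeric(1))
    S_full <- numeric(n_classes)
    S_full[as.integer(names(Sp))] <- Sp
    count[p, ] <- r_from_sums(S_full)
  }
  p_raw <- vapply(seq_len(n_classes), function(k) {
    if (is.na(r_obs[k])) return(NA_real_)
    rp <- count[, k]
    switch(alternative,
      greater   = perm_pvalue(sum(rp >= r_obs[k] - 1e-12), permutations),
      less      = perm_pvalue(sum(rp <= r_obs[k] + 1e-12), permutations),
      two.sided = perm_pvalue(sum(abs(rp) >= abs(r_obs[k]) - 1e-12), permutations)
    )
  }, numeric(1))

  lower <- breaks[-(n_classes + 1)]
  upper <- breaks[-1]
  tested <- lower <= cutoff_frac * dmax & n_d > 0 & !is.na(r_obs)
  p_holm <- rep(NA_real_, n_classes)
  t_idx <- which(tested)
  for (k in seq_along(t_idx)) {
    p_holm[t_idx[k]] <- stats::p.adjust(p_raw[t_idx[seq_len(k)]], method = "holm")[k]
  }
  classes <- tibble::tibble(
    class = seq_len(n_classes), lower = lower, upper = upper,
    center = (lower + upper) / 2, n_pairs = n_d,
    mantel_r = r_obs, p_value = p_raw, p_holm = p_holm, tested = tested
  )
  structure(
    list(classes = classes, n_objects = n, permutations = permutations,
         cutoff = cutoff_frac * dmax, alternative = alternative, seed = seed),
    class = "mantel_correlogram"
  )
}

#' @export
print.mantel_correlogram <- function(x, ...) {
  cat(sprintf("Mantel correlogram: %d objects, %d classes (%d tested), %d permutations\n",
              x$n_objects, nrow(x$classes), sum(x$classes$tested), x$permutations))
  print(x$classes, n = nrow(x$classes))
  invisible(x)
}

#' @method tidy mantel_correlogram
#' @export
tidy.mantel_correlogram <- function(x, ...) x$classes

#' @method glance mantel_correlogram
#' @export
glance.mantel_correlogram <- function(x, ...) {
  tibble::tibble(
    n_objects = x$n_objects,
    n_classes = nrow(x$classes),
    n_tested = sum(x$classes$tested),
    n_significant = sum(x$classes$tested & x$classes$p_holm < 0.05, na.rm = TRUE),
    shortest_class_r = x$classes$mantel_r[which(x$classes$tested)[1]],
    permutations = x$permutations
  )
}
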