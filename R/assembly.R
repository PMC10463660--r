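#' Cophenetic (patristic) distances between tree tips
#'
#' D(i, j) is the sum of branch lengths along the path between tips i and j.
#' This matrix is the phylogenetic substrate of all nearest-taxon metrics.
#'
#' @param tree An [ape::phylo] object with branch lengths.
#' @return A symmetric numeric matrix with tips as dimnames, zero diagonal.
#' @export
phylo_distances <- function(tree) {
  tree <- validate_tree(tree)
  D <- ape::cophenetic.phylo(tree)
  D[tree$tip.label, tree$tip.label]
}

# beta mean nearest taxon distance for all sample pairs.
# W: samples x taxa relative abundances (rows sum to 1; equal weights if
# unweighted), presence: list of integer column indices present per sample,
# D: taxa x taxa distances. Returns samples x samples symmetric matrix.
# For pair (a, b): 0.5 * [ sum_i w_ai min_{j in b} D(i,j)
#                        + sum_j w_bj min_{i in a} D(i,j) ];
# a taxon present in both contributes 0 (its own distance is 0).
bmntd_matrix <- function(W, presence, D) {
  n_s <- nrow(W)
  n_t <- ncol(W)
  MD <- matrix(0, n_s, n_t)
  for (s in seq_len(n_s)) {
    MD[s, ] <- col_mins(D[presence[[s]], , drop = FALSE])
  }
  A <- W %*% t(MD) # A[a, b] = abundance-weighted mean NTD of a's taxa into b
  out <- 0.5 * (A + t(A))
  dimnames(out) <- list(rownames(W), rownames(W))
  out
}

# build weights + presence lists from a count matrix
community_weights <- function(m, weighted = TRUE) {
  presence <- lapply(seq_len(nrow(m)), function(i) which(m[i, ] > 0))
  empty <- lengths(presence) == 0
  if (any(empty)) {
    abort(paste0("samples with no ASVs present: ",
                 paste(rownames(m)[empty], collapse = ", ")))
  }
  W <- if (weighted) rel_abund(m) else rel_abund((m > 0) * 1)
  list(W = W, presence = presence)
}

#' Beta mean nearest taxon distance (betaMNTD)
#'
#' Abundance-weighted phylogenetic turnover between every pair of samples:
#' for each taxon in one sample, the patristic distance to its closest
#' relative in the other sample, averaged with the taxon's within-sample
#' relative abundance as weight, and symmetrised. A taxon present in both
#' samples contributes zero to both directions.
#'
#' @inheritParams community_matrix
#' @param tree An [ape::phylo] over the table's ASVs (or a precomputed
#'   cophenetic matrix from [phylo_distances()]).
#' @param weighted Weight by relative abundance (default) or use equal
#'   weights over present taxa.
#' @return A `dist` object of betaMNTD values labelled by sample identifiers.
#' @export
bmntd <- function(table, tree, weighted = TRUE) {
  m <- community_matrix(table)
  D <- if (is.matrix(tree)) tree else phylo_distances(tree)
  if (!all(colnames(m) %in% colnames(D))) {
    abort("every table ASV must appear in the tree; run align_inputs() first")
  }
  D <- D[colnames(m), colnames(m)]
  cw <- community_weights(m, weighted)
  as.dist(bmntd_matrix(cw$W, cw$presence, D))
}

#' Beta nearest taxon index (betaNTI) for all sample pairs
#'
#' Standardised effect size of betaMNTD against a tip-shuffle null: taxon
#' identities (names and abundances) are shuffled across the tips of the
#' phylogeny and betaMNTD recomputed for every pair, `reps` times. Each
#' randomisation draws one permutation shared by all pairs (`shared_null =
#' TRUE`, the framework convention) or an independent permutation per pair.
#' betaNTI = (observed - null mean) / null sd, with the sd computed over the
#' `reps` null values (denominator reps - 1).
#'
#' Pairs whose null distribution is degenerate (null sd below `sd_tol`; e.g.
#' a star phylogeny with equal branch lengths, or two samples with identical
#' ASV sets, where every shuffled betaMNTD equals the observed value) are
#' flagged undefined rather than silently classified.
#'
#' @inheritParams bmntd
#' @param reps Number of tip-shuffle randomisations (>= 99; 999 is the
#'   conventional choice).
#' @param seed Integer seed.
#' @param shared_null One tip shuffle per randomisation shared across pairs
#'   (default), or an independent shuffle per pair per randomisation.
#' @param sd_tol Null standard deviations below this are treated as zero.
#' @return Tibble with one row per unordered sample pair: `sample_a`,
#'   `sample_b`, `bmntd_obs`, `null_mean`, `null_sd`, `bnti`, `bnti_defined`.
#' @export
bnti <- function(table, tree, reps = 999, seed = 1L, weighted = TRUE,
                 shared_null = TRUE, sd_tol = 1e-12) {
  if (reps < 99) abort("use at least 99 randomisations")
  m <- community_matrix(table)
  if (nrow(m) < 2) abort("need at least 2 samples")
  D <- if (is.matrix(tree)) tree else phylo_distances(tree)
  if (!all(colnames(m) %in% colnames(D))) {
    abort("every table ASV must appear in the tree; run align_inputs() first")
  }
  D <- D[colnames(m), colnames(m)]
  cw <- community_weights(m, weighted)
  n_t <- ncol(m)
  obs <- bmntd_matrix(cw$W, cw$presence, D)
  ltri <- lower.tri(obs)
  obs_v <- obs[ltri]

  withr_seed(seed)
  sum_v <- numeric(length(obs_v))
  sumsq_v <- numeric(length(obs_v))
  if (shared_null) {
    for (r in seq_len(reps)) {
      perm <- sample.int(n_t)
      nv <- bmntd_matrix(cw$W, cw$presence, D[perm, perm])[ltri]
      sum_v <- sum_v + nv
      sumsq_v <- sumsq_v + nv * nv
    }
  } else {
    # independent shuffle per pair per randomisation; only sensible for
    # small problems
    idx <- which(ltri, arr.ind = TRUE)
    for (r in seq_len(reps)) {
      nv <- vapply(seq_len(nrow(idx)), function(k) {
        perm <- sample.int(n_t)
        a <- idx[k, 2]; b <- idx[k, 1]
        Dp <- D[perm, perm]
        pa <- cw$presence[[a]]; pb <- cw$presence[[b]]
        0.5 * (sum(cw$W[a, pa] * col_mins(Dp[pb, pa, drop = FALSE])) +
               sum(cw$W[b, pb] * col_mins(Dp[pa, pb, drop = FALSE])))
      }, numeric(1))
      sum_v <- sum_v + nv
      sumsq_v <- sumsq_v + nv * nv
    }
  }
  null_mean <- sum_v / reps
  null_var <- pmax(sumsq_v - reps * null_mean^2, 0) / (reps - 1)
  null_sd <- sqrt(null_var)
  defined <- null_sd > sd_tol
  if (any(!defined)) {
    warn(sprintf("bnti: %d pair(s) have a degenerate null (sd ~ 0); betaNTI flagged undefined",
                 sum(!defined)))
  }
  ids <- rownames(obs)
  idx <- which(ltri, arr.ind = TRUE)
  tibble::tibble(
    sample_a = ids[idx[, 2]],
    sample_b = ids[idx[, 1]],
    bmntd_obs = obs_v,
    null_mean = null_mean,
    null_sd = null_sd,
    bnti = ifelse(defined, (obs_v - null_mean) / null_sd, NA_real_),
    bnti_defined = defined
  )
}

# draw one null community: recruit `richness` ASVs without replacement with
# probability proportional to occupancy, seed each with one read, then draw
# the remaining reads with replacement proportional to metacommunity-wide
# relative abundance restricted to the recruited ASVs.
rc_null_community <- function(richness, depth, occupancy, meta_relabund) {
  candidates <- which(occupancy > 0)
  if (richness > length(candidates)) {
    abort(sprintf("sample richness (%d) exceeds metacommunity richness (%d)",
                  richness, length(candidates)))
  }
  ids <- if (richness == length(candidates)) candidates else {
    candidates[sample.int(length(candidates), richness,
                          prob = occupancy[candidates])]
  }
  counts <- numeric(length(occupancy))
  counts[ids] <- 1
  extra <- depth - richness
  if (extra > 0) {
    p <- meta_relabund[ids]
    if (sum(p) <= 0) p <- rep(1, length(ids))
    counts[ids] <- counts[ids] + rmultinom(1, extra, p)[, 1]
  }
  counts
}

# Bray-Curtis between two vectors on relative-abundance scale
bc_rel <- function(x, y) {
  px <- x / sum(x); py <- y / sum(y)
  sum(abs(px - py)) / 2
}

rc_score <- function(bc_null, bc_obs, tol = 1e-12) {
  less <- sum(bc_null < bc_obs - tol)
  equal <- sum(abs(bc_null - bc_obs) <= tol)
  2 * ((less + 0.5 * equal) / length(bc_null)) - 1
}

#' Raup-Crick (Bray-Curtis) metric for one sample pair
#'
#' Compares the observed Bray-Curtis dissimilarity of two communities with a
#' null distribution built by probabilistic reassembly from the
#' metacommunity: each null community recruits ASVs without replacement with
#' probability proportional to occupancy (the number of metacommunity samples
#' occupied) until the observed richness is reached, seeds each recruited ASV
#' with one read, then draws the remaining reads with replacement with
#' probability proportional to each ASV's metacommunity-wide relative
#' abundance, until the observed read depth is reached. Observed and null
#' dissimilarities are computed on relative abundances so pairs with unequal
#' depths remain comparable.
#'
#' RCbray = 2 x (fraction of null values below the observed, ties counted
#' half) - 1, so it lies in \[-1, 1\]: near -1 the pair is far more similar
#' than drift alone predicts, near +1 far less similar.
#'
#' @param x,y Named count vectors over the metacommunity's ASV namespace
#'   (names may be omitted if already in table column order).
#' @param metacommunity Community tibble defining occupancies and pool
#'   relative abundances (typically all samples of the same group).
#' @param reps Number of null assemblies (>= 99; 999 conventional).
#' @param seed Integer seed.
#' @return RCbray value in \[-1, 1\], with attributes `bc_obs` and `reps`.
#' @export
rcbray_pair <- function(x, y, metacommunity, reps = 999, seed = 1L) {
  if (reps < 99) abort("use at least 99 randomisations")
  mm <- community_matrix(metacommunity)
  asvs <- colnames(mm)
  arrange_vec <- function(v) {
    if (!is.null(names(v))) {
      if (!all(names(v) %in% asvs)) abort("pair ASVs missing from the metacommunity")
      out <- setNames(numeric(length(asvs)), asvs)
      out[names(v)] <- v
      out
    } else {
      if (length(v) != length(asvs)) abort("unnamed pair vectors must match the metacommunity ASV count")
      v
    }
  }
  x <- arrange_vec(x); y <- arrange_vec(y)
  if (sum(x) <= 0 || sum(y) <= 0) abort("both samples need positive totals")
  occupancy <- colSums(mm > 0)
  meta_relabund <- colSums(mm) / sum(mm)
  rx <- sum(x > 0); nx <- sum(x)
  ry <- sum(y > 0); ny <- sum(y)
  bc_obs <- bc_rel(x, y)
  withr_seed(seed)
  bc_null <- vapply(seq_len(reps), function(r) {
    bc_rel(rc_null_community(rx, nx, occupancy, meta_relabund),
           rc_null_community(ry, ny, occupancy, meta_relabund))
  }, numeric(1))
  structure(rc_score(bc_null, bc_obs), bc_obs = bc_obs, reps = reps)
}

#' Raup-Crick (Bray-Curtis) metric for all sample pairs
#'
#' All-pairs driver for [rcbray_pair()]'s null model. For speed, each
#' randomisation assembles one null community per sample (with that sample's
#' observed richness and depth) and scores every pair against it, the same
#' sharing convention the tip-shuffle betaNTI null uses; each pair's marginal
#' null distribution is identical to the per-pair construction.
#'
#' @inheritParams community_matrix
#' @param reps Number of null assemblies (>= 99).
#' @param seed Integer seed.
#' @param metacommunity Optional community tibble defining the species pool;
#'   defaults to `table` itself (the usual choice: all samples of the group
#'   being analysed).
#' @return Tibble with `sample_a`, `sample_b`, `bc_obs`, `rcbray`.
#' @export
rcbray <- function(table, reps = 999, seed = 1L, metacommunity = NULL) {
  if (reps < 99) abort("use at least 99 randomisations")
  m <- community_matrix(table)
  if (nrow(m) < 2) abort("need at least 2 samples")
  mm <- if (is.null(metacommunity)) m else community_matrix(metacommunity)
  if (!identical(colnames(m), colnames(mm))) {
    abort("table and metacommunity must share the same ASV columns")
  }
  occupancy <- colSums(mm > 0)
  meta_relabund <- colSums(mm) / sum(mm)
  richness <- rowSums(m > 0)
  depth <- rowSums(m)
  n_s <- nrow(m)
  obs <- as.matrix(bray_curtis(rel_abund(m)))
  ltri <- lower.tri(obs)
  bc_obs <- obs[ltri]
  less <- numeric(length(bc_obs))
  equal <- numeric(length(bc_obs))
  withr_seed(seed)
  for (r in seq_len(reps)) {
    nullm <- matrix(0, n_s, length(occupancy))
    for (s in seq_len(n_s)) {
      nullm[s, ] <- rc_null_community(richness[s], depth[s], occupancy, meta_relabund)
    }
    bc_null <- as.matrix(vegan::vegdist(rel_abund(nullm), method = "bray"))[ltri]
    less <- less + (bc_null < bc_obs - 1e-12)
    equal <- equal + (abs(bc_null - bc_obs) <= 1e-12)
  }
  ids <- rownames(m)
  idx <- which(ltri, arr.ind = TRUE)
  tibble::tibble(
    sample_a = ids[idx[, 2]],
    sample_b = ids[idx[, 1]],
    bc_obs = bc_obs,
    rcbray = 2 * ((less + 0.5 * equal) / reps) - 1
  )
}

#' Classify sample pairs into assembly processes
#'
#' Applies the two-step decision rule: betaNTI below -`bnti_threshold` is
#' homogeneous selection, above +`bnti_threshold` heterogeneous selection;
#' otherwise RCbray below -`rc_threshold` is homogenising dispersal, above
#' +`rc_threshold` dispersal limitation, and anything in between is drift.
#' All comparisons are strict, so exact boundary values fall through to the
#' next step. Pairs with an undefined betaNTI are left unclassified
#' (`process = NA`) and should be reported separately.
#'
#' @param pairs Tibble with columns `bnti` and (for pairs with
#'   |betaNTI| <= `bnti_threshold`) `rcbray`, as produced by joining [bnti()]
#'   and [rcbray()] output.
#' @param bnti_threshold Selection significance threshold (default 2).
#' @param rc_threshold Raup-Crick significance threshold (default 0.95).
#' @return `pairs` with a `process` factor column added (levels:
#'   homogeneous_selection, heterogeneous_selection, homogenising_dispersal,
#'   dispersal_limitation, drift).
#' @export
classify_processes <- function(pairs, bnti_threshold = 2, rc_threshold = 0.95) {
  if (!"bnti" %in% names(pairs)) abort("pairs must have a `bnti` column")
  defined <- if ("bnti_defined" %in% names(pairs)) pairs$bnti_defined else !is.na(pairs$bnti)
  needs_rc <- defined & abs(pairs$bnti) <= bnti_threshold
  if (!"rcbray" %in% names(pairs)) {
    if (any(needs_rc)) abort("pairs with |betaNTI| <= threshold need an `rcbray` column")
    pairs$rcbray <- NA_real_
  }
  if (any(needs_rc & is.na(pairs$rcbray))) {
    abort(sprintf("%d pair(s) with |betaNTI| <= %g lack an RCbray value",
                  sum(needs_rc & is.na(pairs$rcbray)), bnti_threshold))
  }
  pairs$process <- factor(
    dplyr::case_when(
      !defined ~ NA_character_,
      pairs$bnti < -bnti_threshold ~ "homogeneous_selection",
      pairs$bnti > bnti_threshold ~ "heterogeneous_selection",
      pairs$rcbray < -rc_threshold ~ "homogenising_dispersal",
      pairs$rcbray > rc_threshold ~ "dispersal_limitation",
      TRUE ~ "drift"
    ),
    levels = assembly_processes()
  )
  pairs
}

#' The five assembly processes, in display order
#' @return Character vector of process names.
#' @export
assembly_processes <- function() {
  c("homogeneous_selection", "heterogeneous_selection",
    "homogenising_dispersal", "dispersal_limitation", "drift")
}

#' Summarise assembly processes as per-group percentages
#'
#' Computes, for each group (by default substrate and time), the percentage
#' of classified pairwise comparisons attributed to each process. Pairs with
#' an undefined betaNTI are reported in `n_undefined` and excluded from the
#' percentage denominator. Errors if a pair's two samples disagree on any
#' grouping value: pairs must be formed within groups.
#'
#' @param pairs Classified pair tibble from [classify_processes()].
#' @param metadata Sample metadata tibble with `sample_id` and the grouping
#'   columns; omit if `pairs` already carries the grouping columns.
#' @param group_by Character vector of grouping column names; use
#'   `character(0)` for a single overall profile.
#' @return An `assembly_profile` tibble: grouping columns, `process`,
#'   `n_pairs`, `percent`, plus per-group `n_classified` and `n_undefined`.
#' @export
summarize_assembly <- function(pairs, metadata = NULL,
                               group_by = c("substrate", "time")) {
  if (!"process" %in% names(pairs)) abort("run classify_processes() first")
  if (!is.null(metadata) && length(group_by) > 0) {
    ga <- metadata[match(pairs$sample_a, metadata$sample_id), group_by, drop = FALSE]
    gb <- metadata[match(pairs$sample_b, metadata$sample_id), group_by, drop = FALSE]
    mismatch <- rowSums(as.matrix(ga) != as.matrix(gb)) > 0
    if (any(is.na(mismatch)) || any(mismatch)) {
      abort("every pair must lie within one group (both samples sharing the grouping values)")
    }
    pairs <- dplyr::bind_cols(pairs, ga)
  }
  missing_cols <- setdiff(group_by, names(pairs))
  if (length(missing_cols) > 0) {
    abort(paste0("grouping columns not found: ", paste(missing_cols, collapse = ", ")))
  }
  totals <- dplyr::summarise(
    dplyr::group_by(pairs, dplyr::across(dplyr::all_of(group_by))),
    n_classified = sum(!is.na(.data$process)),
    n_undefined = sum(is.na(.data$process)),
    .groups = "drop"
  )
  if (any(totals$n_classified == 0)) abort("group with no classified pairs")
  counts <- dplyr::count(
    dplyr::filter(pairs, !is.na(.data$process)),
    dplyr::across(dplyr::all_of(group_by)), .data$process,
    .drop = FALSE, name = "n_pairs"
  )
  prof <- if (length(group_by) > 0) {
    # inner join drops phantom level crossings .drop = FALSE can introduce
    dplyr::inner_join(counts, totals, by = group_by)
  } else {
    dplyr::bind_cols(counts, totals)
  }
  prof$percent <- 100 * prof$n_pairs / prof$n_classified
  prof <- prof[, c(group_by, "process", "n_pairs", "percent", "n_classified", "n_undefined")]
  class(prof) <- c("assembly_profile", class(prof))
  prof
}

#' Median betaNTI per site and substrate
#'
#' For each sample, collects the betaNTI values of every pairwise comparison
#' it participates in, then pools these over a site's samples and over all
#' sampling times to report one median per site and substrate. This is the
#' site-level turnover summary used to correlate assembly with per-site
#' environmental variables.
#'
#' @param pairs Pair tibble with `sample_a`, `sample_b`, `bnti` (undefined
#'   values NA).
#' @param metadata Sample metadata tibble with `sample_id`, `site`,
#'   `substrate`.
#' @return Tibble with `site`, `substrate`, `median_bnti`, `n_values`.
#' @export
median_bnti <- function(pairs, metadata) {
  long <- dplyr::bind_rows(
    tibble::tibble(sample_id = pairs$sample_a, bnti = pairs$bnti),
    tibble::tibble(sample_id = pairs$sample_b, bnti = pairs$bnti)
  )
  long <- dplyr::left_join(long,
                           metadata[, intersect(c("sample_id", "site", "substrate"), names(metadata))],
                           by = "sample_id")
  if (anyNA(long$site)) abort("every pair sample needs a metadata row with `site`")
  grp <- intersect(c("site", "substrate"), names(long))
  out <- dplyr::summarise(
    dplyr::group_by(long, dplyr::across(dplyr::all_of(grp))),
    median_bnti = stats::median(.data$bnti, na.rm = TRUE),
    n_values = sum(!is.na(.data$bnti)),
    .groups = "drop"
  )
  if (any(out$n_values == 0)) {
    warn("sites with no defined betaNTI omitted")
    out <- out[out$n_values > 0, , drop = FALSE]
  }
  out
}

#' Correlate median betaNTI with an environmental variable
#'
#' Ordinary least-squares regression of median betaNTI on one per-site
#' environmental variable, with Pearson's correlation and its two-tailed
#' t-test. Used to ask which site-level conditions shift the balance between
#' deterministic and stochastic assembly.
#'
#' @param data Tibble with `site` and `median_bnti` (from [median_bnti()]).
#' @param env Per-site environmental tibble with `site` and `variable`.
#' @param variable Name of the environmental column to use.
#' @return An `env_correlation` object: list with `slope`, `r`, `p_value`,
#'   `n`, `variable`, the fitted `model` and the joined `data`.
#' @export
env_correlation <- function(data, env, variable) {
  if (!variable %in% names(env)) abort(paste0("no column '", variable, "' in env"))
  joined <- dplyr::inner_join(data, env[, c("site", variable)], by = "site")
  joined <- joined[complete.cases(joined[, c("median_bnti", variable)]), , drop = FALSE]
  if (nrow(joined) < 3) abort("need at least 3 sites with both values")
  x <- joined[[variable]]
  y <- joined$median_bnti
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance in betaNTI or the environmental variable")
  fit <- lm(y ~ x)
  ct <- cor.test(x, y, method = "pearson")
  structure(
    list(slope = unname(coef(fit)[2]), r = unname(ct$estimate),
         p_value = ct$p.value, n = nrow(joined), variable = variable,
         model = fit, data = joined),
    class = "env_correlation"
  )
}

#' @export
print.env_correlation <- function(x, ...) {
  cat(sprintf("median betaNTI ~ %s: slope = %.3f, r = %.3f, p = %.4g (n = %d sites)\n",
              x$variable, x$slope, x$r, x$p_value, x$n))
  invisible(x)
}

#' @method tidy env_correlation
#' @export
tidy.env_correlation <- function(x, ...) {
  tibble::tibble(variable = x$variable, slope = x$slope, estimate = x$r,
                 p.value = x$p_value, n_sites = x$n)
}

#' @method glance env_correlation
#' @export
glance.env_correlation <- function(x, ...) {
  s <- summary(x$model)
  tibble::tibble(r.squared = s$r.squared, sigma = s$sigma, n_sites = x$n)
}
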