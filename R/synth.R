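#' Simulate an ultrametric pure-birth phylogeny
#'
#' Yule (pure-birth) tree with exponentially distributed waiting times,
#' ultrametric by construction, tips labelled `asv_001` .. `asv_n`.
#'
#' @param n_taxa Number of tips (>= 3).
#' @param seed Integer seed.
#' @return An [ape::phylo] object.
#' @export
simulate_tree <- function(n_taxa, seed = 1L) {
  if (n_taxa < 3) abort("need at least 3 taxa")
  withr_seed(seed)
  tr <- ape::rphylo(n_taxa, birth = 1, death = 0)
  tr$tip.label <- sprintf("asv_%03d", seq_len(n_taxa))
  tr
}

#' Evolve a continuous trait by Brownian motion along a tree
#'
#' Starting from 0 at the root, each branch adds an independent Gaussian
#' increment with variance `bm_rate` x branch length, so the covariance of
#' any two tips equals `bm_rate` x their shared root-to-tip path length. This
#' is the standard model of gradual niche evolution, and it is what makes
#' closely related taxa share habitat preferences in the synthetic
#' communities.
#'
#' @param tree An [ape::phylo] with branch lengths.
#' @param bm_rate Brownian rate (variance per unit branch length, > 0).
#' @param seed Integer seed.
#' @return Named numeric vector of tip trait values.
#' @export
evolve_traits <- function(tree, bm_rate = 1, seed = 1L) {
  if (bm_rate <= 0) abort("bm_rate must be positive")
  tree <- validate_tree(tree)
  tr <- stats::reorder(tree, "cladewise") # parents before children
  n_tip <- length(tr$tip.label)
  vals <- numeric(n_tip + tr$Nnode)
  withr_seed(seed)
  incr <- rnorm(nrow(tr$edge), 0, sqrt(bm_rate * tr$edge.length))
  for (e in seq_len(nrow(tr$edge))) {
    vals[tr$edge[e, 2]] <- vals[tr$edge[e, 1]] + incr[e]
  }
  setNames(vals[seq_len(n_tip)], tr$tip.label)
}

#' Configuration for a synthetic community simulation
#'
#' Bundles and validates the parameters of one simulated dataset. The
#' defaults emulate a 12-site, 5-replicate field design (60 samples), 200
#' taxa and 1,000 reads per sample. The environmental spread across sites
#' defaults to a regime-appropriate value: zero under homogeneous selection
#' (all sites filter toward the same optimum), wide under heterogeneous
#' selection and homogenising dispersal (distinct site conditions), and
#' intermediate otherwise.
#'
#' @param regime One of [assembly_processes()].
#' @param n_sites,n_replicates,n_taxa,read_depth Design sizes.
#' @param selection_strength Gaussian niche breadth sigma (in trait standard
#'   deviations) of the environmental filter; smaller = stronger filtering.
#' @param migration_rate Fraction of each sample's reads drawn from the
#'   shared regional community under homogenising dispersal (0-1).
#' @param founder_pool_size Taxa per site pool under dispersal limitation.
#'   The default (40 percent of the default regional richness) keeps
#'   per-sample richness high enough that segregation is statistically
#'   separable from the reassembly null at the default read depth.
#' @param trait_bm_rate Brownian rate for niche trait evolution.
#' @param env_spread Total range of site environmental optima, in trait
#'   standard deviations; `NULL` picks the regime default.
#' @param lognormal_sdlog sdlog of the lognormal metacommunity abundance
#'   distribution.
#' @param lottery_sdlog Within-guild lottery strength under the selection
#'   regimes: each sample multiplies its filtered expected abundances by
#'   independent lognormal factors with this sdlog, modelling priority
#'   effects and competitive lotteries among the ecologically equivalent
#'   members of the favoured guild. Zero disables the lottery.
#' @param env_jitter Sample-level standard deviation of the realised
#'   environmental optimum around the site value (micro-environmental
#'   variation), in trait standard deviations.
#' @param local_community_size Number of individuals in each realised local
#'   community. Every sample is a finite community assembled from its
#'   expected composition before reads are drawn, so counts are
#'   overdispersed relative to a single multinomial — the demographic
#'   stochasticity that constitutes ecological drift, not just sequencing
#'   noise.
#' @param seed Master seed for the dataset.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(regime,
                              n_sites = 12L, n_replicates = 5L,
                              n_taxa = 200L, read_depth = 1000L,
                              selection_strength = 0.2,
                              migration_rate = 0.9,
                              founder_pool_size = 80L,
                              trait_bm_rate = 1,
                              env_spread = NULL,
                              lognormal_sdlog = 1.5,
                              local_community_size = 1000L,
                              lottery_sdlog = 3,
                              env_jitter = 0.2,
                              seed = 1L) {
  regime <- match.arg(regime, assembly_processes())
  if (is.null(env_spread)) {
    env_spread <- switch(regime,
      homogeneous_selection = 0,
      heterogeneous_selection = 3,
      homogenising_dispersal = 3,
      dispersal_limitation = 1.5,
      drift = 1.5
    )
  }
  cfg <- list(
    regime = regime, n_sites = as.integer(n_sites),
    n_replicates = as.integer(n_replicates), n_taxa = as.integer(n_taxa),
    read_depth = as.integer(read_depth),
    selection_strength = selection_strength,
    migration_rate = migration_rate,
    founder_pool_size = as.integer(founder_pool_size),
    trait_bm_rate = trait_bm_rate, env_spread = env_spread,
    lognormal_sdlog = lognormal_sdlog,
    local_community_size = as.integer(local_community_size),
    lottery_sdlog = lottery_sdlog, env_jitter = env_jitter,
    seed = as.integer(seed)
  )
  if (any(c(cfg$n_sites, cfg$n_replicates, cfg$n_taxa, cfg$read_depth) < 1)) {
    abort("design sizes must be positive")
  }
  if (cfg$selection_strength < 0) abort("selection_strength must be >= 0")
  if (cfg$migration_rate < 0 || cfg$migration_rate > 1) abort("migration_rate must be in [0, 1]")
  if (regime == "homogenising_dispersal" && cfg$migration_rate == 0) {
    abort("homogenising_dispersal requires migration_rate > 0")
  }
  if (regime == "dispersal_limitation" && cfg$founder_pool_size > cfg$n_taxa) {
    abort("founder_pool_size cannot exceed n_taxa")
  }
  if (cfg$env_spread < 0) abort("env_spread must be >= 0")
  if (cfg$local_community_size < 1) abort("local_community_size must be positive")
  if (cfg$lottery_sdlog < 0 || cfg$env_jitter < 0) {
    abort("lottery_sdlog and env_jitter must be >= 0")
  }
  structure(cfg, class = "simulation_config")
}

#' Assemble synthetic communities under a known regime
#'
#' Generates a complete dataset (count table, environmental table, sample
#' metadata, ground truth) under one of the five assembly regimes:
#'
#' * **Selection regimes**: each sample's expected composition is the
#'   lognormal metacommunity abundance multiplied by a Gaussian environmental
#'   filter `exp(-(trait - env)^2 / (2 sigma^2))` and a within-guild lottery
#'   (see `lottery_sdlog`). The niche trait is Brownian motion plus a derived
#'   jump carried by one recent, phylogenetically compact clade — habitat
#'   specialisation as a conserved, clade-level innovation. Under homogeneous
#'   selection every site's environment matches the specialist clade's
#'   optimum (micro-jittered per sample), so the same coherent guild is
#'   filtered in everywhere; under heterogeneous selection site environments
#'   are spread across the background trait range, so different sites favour
#'   different lineages.
#' * **Drift**: expected composition is the metacommunity abundance itself;
#'   all structure is multinomial sampling noise.
#' * **Dispersal limitation**: each site's pool is an independent uniform
#'   draw of `founder_pool_size` taxa, and the abundances founders reach are
#'   an independent lognormal draw per site (arrival order and local drift
#'   decouple local abundance from the regional pool); samples are
#'   multinomial within the pool.
#' * **Homogenising dispersal**: mass effects — one regional community is
#'   realised by multinomial sampling, and every sample copies a fraction
#'   `migration_rate` of its reads from that shared realisation (a
#'   hypergeometric subsample), recruiting the remainder locally under
#'   site-specific selection. The read-level coupling is what makes pairs
#'   more similar than independent sampling from the pool could ever be.
#'
#' Counts are multinomial at fixed `read_depth`. One environmental variable
#' (`env1`) drives selection; two decoy variables carry no signal. The
#' sample metadata uses a single substrate/time so that all pairs fall in one
#' analysis group, matching the per-group design of the inference framework.
#'
#' @param config A [simulation_config()].
#' @param tree Optional pre-built phylogeny (simulated from the config seed
#'   if omitted).
#' @param traits Optional named trait vector (evolved on `tree` if omitted).
#' @return A list of class `synthetic_community`: `table` (community
#'   tibble), `env`, `metadata`, `tree`, and `truth` (regime, standardised
#'   traits, site environments, realised parameters, seed).
#' @export
assemble_communities <- function(config, tree = NULL, traits = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(tree)) tree <- simulate_tree(config$n_taxa, stage_seed(config$seed, "tree"))
  if (length(tree$tip.label) != config$n_taxa) abort("tree size does not match config n_taxa")
  if (is.null(traits)) {
    traits <- evolve_traits(tree, config$trait_bm_rate, stage_seed(config$seed, "traits"))
  }
  selection_acts <- config$regime %in% c("homogeneous_selection",
                                         "heterogeneous_selection",
                                         "homogenising_dispersal")
  raw <- traits[tree$tip.label]
  specialists <- NULL
  if (selection_acts) {
    # habitat specialisation as derived, clade-level niches: several recent,
    # phylogenetically compact radiations each carry a distinct trait jump,
    # so an environment matching one of them favours a coherent guild
    specialists <- find_specialist_clades(tree, n_clades = 4L)
    offs <- 4 * sd(raw) * seq(-1.5, 1.5, length.out = length(specialists))
    for (k in seq_along(specialists)) {
      raw[specialists[[k]]] <- raw[specialists[[k]]] + offs[k]
    }
  }
  z <- as.numeric(scale(raw))
  names(z) <- tree$tip.label
  n_s <- config$n_sites * config$n_replicates

  withr_seed(stage_seed(config$seed, "communities"))
  pool <- rlnorm(config$n_taxa, meanlog = 0, sdlog = config$lognormal_sdlog)
  pool <- pool / sum(pool)
  names(pool) <- tree$tip.label

  site_ids <- sprintf("site%02d", seq_len(config$n_sites))
  if (selection_acts) {
    optima <- vapply(specialists, function(tips) mean(z[tips]), numeric(1))
    site_env <- if (config$regime == "homogeneous_selection") {
      # every site filters toward the same clade-level niche; the most
      # extreme optimum keeps the guild clear of background (unjumped) taxa
      rep(optima[which.max(abs(optima))], config$n_sites)
    } else {
      # sites cycle through the clade-level niches: consistently different
      # conditions across sites
      optima[(seq_len(config$n_sites) - 1L) %% length(optima) + 1L]
    }
  } else {
    site_env <- if (config$env_spread == 0) {
      rep(0, config$n_sites)
    } else {
      seq(-config$env_spread / 2, config$env_spread / 2,
          length.out = config$n_sites)
    }
  }
  names(site_env) <- site_ids

  # one realised finite community per sample: demographic (birth-death)
  # stochasticity on top of which reads are drawn
  realize_local <- function(w, J) rmultinom(1, J, w)[, 1] / J

  gaussian_filter <- function(env_value) {
    if (config$selection_strength == 0) {
      w <- as.numeric(abs(z - env_value) == min(abs(z - env_value)))
    } else {
      w <- pool * exp(-(z - env_value)^2 / (2 * config$selection_strength^2))
    }
    w / sum(w)
  }

  meta <- tidyr::expand_grid(site = site_ids, replicate = seq_len(config$n_replicates))
  meta$sample_id <- sprintf("s%03d", seq_len(n_s))
  meta$substrate <- "synthetic"
  meta$time <- "t1"
  meta <- meta[, c("sample_id", "site", "substrate", "time", "replicate")]

  counts <- matrix(0, n_s, config$n_taxa,
                   dimnames = list(meta$sample_id, tree$tip.label))

  if (config$regime == "dispersal_limitation") {
    # founder effects: which taxa arrive is a uniform draw per site, and the
    # abundances they reach are decoupled from the regional pool (arrival
    # order and local drift), so each site gets its own lognormal weights
    pools <- lapply(site_ids, function(s) sort(sample.int(config$n_taxa, config$founder_pool_size)))
    names(pools) <- site_ids
    pool_weights <- lapply(site_ids, function(s) {
      w <- numeric(config$n_taxa)
      w[pools[[s]]] <- rlnorm(config$founder_pool_size, 0, config$lognormal_sdlog)
      w / sum(w)
    })
    names(pool_weights) <- site_ids
  }
  if (config$regime == "homogenising_dispersal") {
    regional <- rmultinom(1, config$read_depth, pool)[, 1]
    n_migrant <- round(config$migration_rate * config$read_depth)
  }

  for (i in seq_len(n_s)) {
    s <- meta$site[i]
    sample_env <- function(e) e + rnorm(1, 0, config$env_jitter)
    lottery <- function(w) {
      w <- w * rlnorm(config$n_taxa, 0, config$lottery_sdlog)
      w / sum(w)
    }
    w <- switch(config$regime,
      homogeneous_selection = ,
      heterogeneous_selection = lottery(gaussian_filter(sample_env(site_env[[s]]))),
      drift = pool,
      dispersal_limitation = pool_weights[[s]],
      homogenising_dispersal = lottery(gaussian_filter(sample_env(site_env[[s]])))
    )
    if (config$regime == "homogenising_dispersal") {
      migrants <- vegan::rrarefy(matrix(regional, nrow = 1), n_migrant)[1, ]
      local <- rmultinom(1, config$read_depth - n_migrant,
                         realize_local(w, config$local_community_size))[, 1]
      counts[i, ] <- migrants + local
    } else {
      counts[i, ] <- rmultinom(1, config$read_depth,
                               realize_local(w, config$local_community_size))[, 1]
    }
  }

  env <- tibble::tibble(
    site = site_ids,
    env1 = site_env,
    decoy1 = rnorm(config$n_sites),
    decoy2 = rnorm(config$n_sites)
  )

  truth <- structure(
    list(regime = config$regime, traits = z, site_env = site_env,
         pool = pool, specialist_clades = specialists,
         config = config, seed = config$seed),
    class = "synthetic_truth"
  )
  structure(
    list(table = community_tibble(counts), env = env, metadata = meta,
         tree = tree, truth = truth),
    class = "synthetic_community"
  )
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat(sprintf("synthetic community: regime '%s', %d samples x %d taxa, depth %d\n",
              x$truth$regime, nrow(x$table), ncol(x$table) - 1,
              x$truth$config$read_depth))
  invisible(x)
}

#' Generate one benchmark dataset per assembly regime
#'
#' @param regimes Regimes to generate (default all five).
#' @param seed Master seed; each regime gets a deterministic sub-seed.
#' @param out_dir Optional directory; if given, each bundle is written as
#'   TSV/Newick files under `out_dir/<regime>/`.
#' @param ... Overrides passed to [simulation_config()].
#' @return Named list of `synthetic_community` bundles.
#' @export
generate_benchmark <- function(regimes = assembly_processes(), seed = 1L,
                               out_dir = NULL, ...) {
  regimes <- match.arg(regimes, assembly_processes(), several.ok = TRUE)
  out <- lapply(seq_along(regimes), function(k) {
    cfg <- simulation_config(regimes[k], seed = stage_seed(seed, "benchmark") + k, ...)
    assemble_communities(cfg)
  })
  names(out) <- regimes
  if (!is.null(out_dir)) {
    for (r in regimes) {
      d <- file.path(out_dir, r)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      write_community_table(out[[r]]$table, file.path(d, "counts.tsv"))
      readr::write_tsv(out[[r]]$metadata, file.path(d, "metadata.tsv"), progress = FALSE)
      readr::write_tsv(out[[r]]$env, file.path(d, "env.tsv"), progress = FALSE)
      write_tree(out[[r]]$tree, file.path(d, "tree.nwk"))
      jsonlite::write_json(
        list(regime = r, seed = out[[r]]$truth$seed,
             config = unclass(out[[r]]$truth$config)),
        file.path(d, "truth.json"), auto_unbox = TRUE, digits = NA
      )
    }
  }
  out
}

# greedy disjoint set of phylogenetically compact clades (25-45 tips each
# where the tree allows, else the tightest clades of >= 3 tips): within-clade
# mean patristic distance relative to the tree-wide mean, minimised
find_specialist_clades <- function(tree, n_clades = 4L,
                                   min_tips = 25L, max_tips = 45L) {
  n <- length(tree$tip.label)
  D <- ape::cophenetic.phylo(tree)
  overall <- mean(D[upper.tri(D)])
  all_clades <- lapply((n + 1):(n + tree$Nnode), function(nd) {
    ape::extract.clade(tree, nd)$tip.label
  })
  pick <- function(clades) {
    scores <- vapply(clades, function(tips) mean(D[tips, tips]) / overall,
                     numeric(1))
    found <- list(); used <- character(0)
    while (length(found) < n_clades) {
      free <- vapply(clades, function(tips) !any(tips %in% used), logical(1))
      if (!any(free)) break
      k <- which(free)[which.min(scores[free])]
      found[[length(found) + 1]] <- clades[[k]]
      used <- c(used, clades[[k]])
    }
    found
  }
  sized <- Filter(function(tips) {
    length(tips) >= min_tips && length(tips) <= max_tips
  }, all_clades)
  out <- pick(sized)
  if (length(out) == 0) {
    small <- Filter(function(tips) length(tips) >= 3 && length(tips) < n,
                    all_clades)
    out <- pick(small)
  }
  if (length(out) == 0) abort("tree has no usable specialist clade")
  out
}
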