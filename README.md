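# assemblr

Microbial communities assemble through a mixture of deterministic selection
and stochastic dispersal and drift, and the balance among these processes is
invisible to ordinary diversity statistics. assemblr quantifies that balance
from the two things an amplicon study produces — an ASV count table and a
rooted phylogeny — using the two-step null-model framework that partitions
every pairwise comparison of communities among five assembly processes. It
is written for microbial ecologists analysing 16S/ITS ASV tables across
sites, substrates and time points.

## The method

**Step 1 — phylogenetic turnover.** For each pair of communities the
abundance-weighted beta mean nearest taxon distance

βMNTD = ½ [ Σ_{i∈a} f_ia · min_{j∈b} D(i,j) + Σ_{j∈b} f_jb · min_{i∈a} D(i,j) ]

is compared with a null distribution obtained by shuffling taxon identities
across the tips of the phylogeny (999 randomisations by default). The
standardised effect size, the beta nearest taxon index
βNTI = (βMNTD_obs − mean null)/(sd null), classifies a pair as shaped by
**homogeneous selection** (βNTI < −2) or **heterogeneous selection**
(βNTI > +2).

**Step 2 — compositional turnover.** Pairs with |βNTI| ≤ 2 are passed to an
abundance-based Raup–Crick metric: null communities are reassembled from the
metacommunity (taxa recruited in proportion to occupancy up to the observed
richness, reads added in proportion to pool-wide relative abundance up to
the observed depth), and the observed Bray–Curtis dissimilarity is ranked
against the null values, rescaled to RCbray ∈ [−1, 1]. RCbray < −0.95 is
**homogenising dispersal**, RCbray > +0.95 is **dispersal limitation**, and
anything in between is **drift**.

The framework's precondition — that close relatives share habitat
preferences — is checked with abundance-weighted niche optima and a Mantel
correlogram against phylogenetic distance, with progressive Holm correction.

A synthetic-data module generates complete datasets (counts, tree,
environment, metadata, ground truth) under each of the five regimes in a
12-site × 5-replicate design, so the entire inference chain is testable by
parameter recovery without any sequence data.

## Worked example

Simulate a community dataset assembled under heterogeneous selection, then
ask the pipeline which process it infers:

```r
library(assemblr)

cfg <- simulation_config("heterogeneous_selection", seed = 11)
sim <- assemble_communities(cfg)
sim
#> synthetic community: regime 'heterogeneous_selection', 60 samples x 200 taxa, depth 1000

res <- run_pipeline(sim$table, sim$tree, sim$metadata,
                    reps = 199, seed = 7, min_reads = 0)
glance(res)
#> # A tibble: 1 × 6
#>   substrate time  n_classified n_undefined modal_process           modal_percent
#>   <chr>     <chr>        <int>       <int> <chr>                           <dbl>
#> 1 synthetic t1            1770           0 heterogeneous_selection          61.6

res$profile[, c("process", "n_pairs", "percent")]
#> # A tibble: 5 × 3
#>   process                 n_pairs percent
#>   <fct>                     <int>   <dbl>
#> 1 homogeneous_selection       146   8.25
#> 2 heterogeneous_selection    1091  61.6
#> 3 homogenising_dispersal       10   0.565
#> 4 dispersal_limitation         39   2.20
#> 5 drift                       484  27.3
```

All 1,770 within-group pairs were classified (none had a degenerate null),
and 61.6% are attributed to heterogeneous selection — the generating
process. The 8.25% called homogeneous selection are mostly within-site
pairs: sites impose consistent conditions internally, so the classification
is recovering real structure, not noise. `autoplot(res)` draws the stacked
process-percentage bars.

Site-level turnover can then be related to the environment:

```r
pairs <- tidy(res)                       # per-pair βNTI, RCbray, process
mb <- median_bnti(pairs, sim$metadata)   # median βNTI per site
env_correlation(mb, sim$env, "env1")
#> median betaNTI ~ env1: slope = 0.028, r = 0.221, p = 0.4908 (n = 12 sites)
```

Here the correlation is weak, as it should be: under this regime *every*
site is strongly selective (median βNTI > 2.5 everywhere), so site-to-site
variation in βNTI carries little environmental signal.

Everything is reproducible: `run_pipeline()` derives all stage seeds from
the master seed and writes them, with input checksums, to a JSON run
manifest (`out_dir = ...`).

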