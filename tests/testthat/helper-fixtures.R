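# Shared fixtures and independent oracles, built in code at test time.

# small deterministic community tibble
toy_table <- function() {
  community_tibble(matrix(
    c(5L, 0L, 2L, 1L,
      0L, 3L, 3L, 0L,
      1L, 1L, 0L, 4L),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("s1", "s2", "s3"), c("a", "b", "c", "d"))
  ))
}

toy_metadata <- function() {
  tibble::tibble(
    sample_id = c("s1", "s2", "s3"),
    site = c("site1", "site1", "site2"),
    substrate = c("leaf", "leaf", "leaf"),
    time = "t1",
    replicate = c(1, 2, 1)
  )
}

random_table <- function(n_samples, n_taxa, labels = NULL, lambda = 3) {
  m <- matrix(rpois(n_samples * n_taxa, lambda), n_samples, n_taxa)
  empty <- rowSums(m) == 0
  m[empty, 1] <- 1L
  rownames(m) <- sprintf("s%02d", seq_len(n_samples))
  colnames(m) <- labels %||% sprintf("t%03d", seq_len(n_taxa))
  community_tibble(m)
}

random_tree <- function(n_taxa) {
  tr <- ape::rtree(n_taxa)
  tr$tip.label <- sprintf("t%03d", seq_len(n_taxa))
  tr
}

# independent nested-loop betaMNTD oracle: no shared code with bmntd()
bmntd_oracle <- function(m, D, weighted = TRUE) {
  n_s <- nrow(m)
  out <- matrix(0, n_s, n_s, dimnames = list(rownames(m), rownames(m)))
  for (a in seq_len(n_s)) {
    for (b in seq_len(n_s)) {
      if (a == b) next
      pa <- which(m[a, ] > 0)
      pb <- which(m[b, ] > 0)
      wa <- if (weighted) m[a, pa] / sum(m[a, pa]) else rep(1 / length(pa), length(pa))
      acc <- 0
      for (k in seq_along(pa)) {
        dmin <- Inf
        for (l in seq_along(pb)) {
          dmin <- min(dmin, D[colnames(m)[pa[k]], colnames(m)[pb[l]]])
        }
        acc <- acc + wa[k] * dmin
      }
      out[a, b] <- acc
    }
  }
  (out + t(out)) / 2
}

# tip-to-tip path-sum oracle via node paths (independent of cophenetic.phylo)
patristic_oracle <- function(tree, tip_a, tip_b) {
  ia <- match(tip_a, tree$tip.label)
  ib <- match(tip_b, tree$tip.label)
  path <- ape::nodepath(tree, ia, ib)
  total <- 0
  for (k in seq_len(length(path) - 1)) {
    e <- which((tree$edge[, 1] == path[k] & tree$edge[, 2] == path[k + 1]) |
                 (tree$edge[, 2] == path[k] & tree$edge[, 1] == path[k + 1]))
    total <- total + tree$edge.length[e]
  }
  total
}

# two-loop CSS reference (independent of css_normalize)
css_oracle <- function(m, q) {
  scal <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    nz <- sort(m[i, m[i, ] > 0])
    qv <- quantile(nz, q, names = FALSE)
    s <- 0
    for (j in seq_len(ncol(m))) if (m[i, j] <= qv) s <- s + m[i, j]
    scal[i] <- s
  }
  out <- m
  for (i in seq_len(nrow(m))) out[i, ] <- m[i, ] / scal[i] * median(scal)
  out
}

# fixture for betaNTI clustering: a 20-tip simulated tree whose most compact
# 6-12 tip clade is shrunk into a recent radiation, and two communities that
# interleave across sister taxa within it (each taxon's nearest relative sits
# in the other sample)
clustered_pair_fixture <- function(seed, shrink = 0.1) {
  tr <- simulate_tree(20, seed)
  D <- phylo_distances(tr)
  best <- NULL; best_score <- Inf
  for (nd in 21:(20 + tr$Nnode)) {
    tips <- ape::extract.clade(tr, nd)$tip.label
    if (length(tips) >= 6 && length(tips) <= 12) {
      score <- mean(D[tips, tips]) / mean(D[upper.tri(D)])
      if (score < best_score) { best_score <- score; best <- nd }
    }
  }
  tips <- ape::extract.clade(tr, best)$tip.label
  desc <- phangorn::Descendants(tr, best, "all")
  in_clade <- tr$edge[, 2] %in% c(desc, best) & tr$edge[, 1] %in% c(desc, best)
  tr$edge.length[in_clade] <- tr$edge.length[in_clade] * shrink
  D <- phylo_distances(tr)
  # greedy sister pairing: split each closest remaining pair across samples
  Dm <- D[tips, tips]; diag(Dm) <- Inf
  a <- character(0); b <- character(0); left <- tips
  while (length(left) >= 2) {
    sub <- Dm[left, left, drop = FALSE]
    k <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    a <- c(a, left[k[1]]); b <- c(b, left[k[2]])
    left <- left[-k]
  }
  m <- matrix(0, 2, 20, dimnames = list(c("a", "b"), tr$tip.label))
  m["a", a] <- 10
  m["b", b] <- 10
  list(tree = tr, table = community_tibble(m))
}

# heterogeneous metacommunity with a small cosmopolitan core (15 uneven,
# ubiquitous taxa) plus many patchy rare taxa; the shape needed for the
# Raup-Crick null to assemble overlapping communities
rc_metacommunity <- function(seed) {
  set.seed(seed)
  m <- matrix(0, 20, 100,
              dimnames = list(sprintf("m%02d", 1:20), sprintf("a%03d", 1:100)))
  core <- 1:15
  for (i in 1:20) {
    m[i, core] <- rpois(15, exp(rnorm(15, 3, 1))) + 1
    rare <- sample(16:100, 8)
    m[i, rare] <- rpois(8, 2) + 1
  }
  m
}
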