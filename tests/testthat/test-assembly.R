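test_that("cophenetic distances match hand values and a node-path oracle", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  D <- phylo_distances(tr)
  expect_equal(D["A", "B"], 2)
  expect_equal(D["A", "C"], 4)
  expect_equal(unname(diag(D)), rep(0, 3))

  set.seed(10)
  tr2 <- random_tree(50)
  D2 <- phylo_distances(tr2)
  picks <- matrix(sample(50, 20, replace = TRUE), 10, 2)
  for (k in seq_len(nrow(picks))) {
    if (picks[k, 1] == picks[k, 2]) next
    a <- tr2$tip.label[picks[k, 1]]; b <- tr2$tip.label[picks[k, 2]]
    expect_equal(D2[a, b], patristic_oracle(tr2, a, b), tolerance = 1e-9)
  }
})

test_that("betaMNTD handles the degenerate pairs and the hand-unrolled fixture", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:1,D:3):2);")
  D <- phylo_distances(tr)

  # identical composition -> 0
  m_id <- rbind(s1 = c(3, 1, 0, 2), s2 = c(3, 1, 0, 2))
  colnames(m_id) <- c("A", "B", "C", "D")
  expect_equal(as.numeric(bmntd(community_tibble(m_id), tr)), 0)

  # single-taxon samples -> D(A, C)
  m_ac <- rbind(s1 = c(5, 0, 0, 0), s2 = c(0, 0, 7, 0))
  colnames(m_ac) <- c("A", "B", "C", "D")
  expect_equal(as.numeric(bmntd(community_tibble(m_ac), tr)), D["A", "C"])

  # 4-taxon 2-sample fixture with unequal abundances, hand-unrolled:
  # a = {A:2, B:6}, b = {B:1, C:3}; D(A,B)=3, D(A,C)=5, D(B,C)=6
  m <- rbind(a = c(2, 6, 0, 0), b = c(0, 1, 3, 0))
  colnames(m) <- c("A", "B", "C", "D")
  # term a->b: 0.25*min(D(A,B),D(A,C)) + 0.75*0 = 0.25*3
  # term b->a: 0.25*0 + 0.75*min(D(C,A),D(C,B)) = 0.75*5
  hand <- 0.5 * (0.25 * 3 + 0.75 * 5)
  expect_equal(as.numeric(bmntd(community_tibble(m), tr)), hand)
  expect_equal(as.matrix(bmntd(community_tibble(m), tr)),
               bmntd_oracle(m, D), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("vectorised betaMNTD equals the nested-loop oracle and picante", {
  skip_if_not_installed("picante")
  set.seed(11)
  for (k in 1:10) {
    n_t <- sample(4:12, 1); n_s <- sample(2:6, 1)
    tr <- random_tree(n_t)
    tbl <- random_table(n_s, n_t, labels = tr$tip.label)
    m <- community_matrix(tbl)
    D <- phylo_distances(tr)
    mine <- as.matrix(bmntd(tbl, tr))
    expect_equal(mine, bmntd_oracle(m, D), tolerance = 1e-10, ignore_attr = TRUE)
    ref <- as.matrix(picante::comdistnt(m, D, abundance.weighted = TRUE))
    expect_equal(mine[rownames(ref), colnames(ref)], ref,
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("betaNTI flags degenerate nulls instead of classifying them", {
  # star phylogeny with equal branch lengths: distances are shuffle-invariant
  star <- ape::stree(6, "star")
  star$edge.length <- rep(1, nrow(star$edge))
  star$tip.label <- paste0("t", 1:6)
  m <- rbind(a = c(4L, 2L, 1L, 0L, 0L, 0L), b = c(0L, 0L, 1L, 3L, 2L, 1L))
  colnames(m) <- star$tip.label
  res <- suppressWarnings(bnti(community_tibble(m), star, reps = 99, seed = 1))
  expect_false(res$bnti_defined)
  expect_true(is.na(res$bnti))

  # identical samples: every shuffled betaMNTD is also 0
  tr <- simulate_tree(20, 1)
  m2 <- matrix(0L, 2, 20, dimnames = list(c("a", "b"), tr$tip.label))
  m2[1, 1:6] <- c(5L, 4L, 3L, 2L, 1L, 1L); m2[2, ] <- m2[1, ]
  res2 <- suppressWarnings(bnti(community_tibble(m2), tr, reps = 99, seed = 1))
  expect_false(res2$bnti_defined)
})

test_that("betaNTI detects phylogenetic clustering and flips sign for segregation", {
  fx <- clustered_pair_fixture(1)
  res <- suppressWarnings(bnti(fx$table, fx$tree, reps = 199, seed = 1))
  expect_lt(res$bnti, -2)

  # anti-clustered fixture: each sample confined to a different deep clade
  tr <- simulate_tree(20, 3)
  D <- phylo_distances(tr)
  far <- which(D == max(D), arr.ind = TRUE)[1, ]
  ord_a <- order(D[far[1], ])[1:5]
  ord_b <- order(D[far[2], ])[1:5]
  m <- matrix(0, 2, 20, dimnames = list(c("a", "b"), tr$tip.label))
  m["a", ord_a] <- 10; m["b", ord_b] <- 10
  res2 <- suppressWarnings(bnti(community_tibble(m), tr, reps = 199, seed = 1))
  expect_gt(res2$bnti, 0)
})

test_that("betaNTI is stable in the number of randomisations", {
  fx <- clustered_pair_fixture(2)
  b1 <- suppressWarnings(bnti(fx$table, fx$tree, reps = 999, seed = 5))$bnti
  b2 <- suppressWarnings(bnti(fx$table, fx$tree, reps = 4999, seed = 6))$bnti
  expect_lt(abs(b1 - b2), 0.2)
})

test_that("rcbray_pair respects bounds, depth bookkeeping and richness limits", {
  m <- rc_metacommunity(1)
  tbl <- community_tibble(m)
  rc <- rcbray_pair(m[1, ], m[2, ], tbl, reps = 199, seed = 1)
  expect_gte(as.numeric(rc), -1)
  expect_lte(as.numeric(rc), 1)
  rel <- sweep(m[1:2, ], 1, rowSums(m[1:2, ]), "/")
  expect_equal(attr(rc, "bc_obs"), sum(abs(rel[1, ] - rel[2, ])) / 2,
               tolerance = 1e-12)

  too_rich <- setNames(rep(1, 100), colnames(m))
  meta_small <- community_tibble(m[, 1:40][, colSums(m[, 1:40]) > 0, drop = FALSE])
  expect_error(
    rcbray_pair(setNames(rep(1, ncol(community_matrix(meta_small))),
                         setdiff(names(meta_small), "sample_id")),
                setNames(1, setdiff(names(meta_small), "sample_id")[1]),
                meta_small, reps = 99, seed = 1),
    NA
  )
  expect_error(rcbray_pair(too_rich, m[1, ], community_tibble(m[, 1:50]), reps = 99),
               "missing from the metacommunity|exceeds")
})

test_that("the all-pairs RCbray driver matches the per-pair null distributionally", {
  m <- rc_metacommunity(2)[1:8, ]
  m <- m[, colSums(m) > 0]
  tbl <- community_tibble(m)
  all_rc <- rcbray(tbl, reps = 499, seed = 3)
  one <- as.numeric(rcbray_pair(m[1, ], m[2, ], tbl, reps = 499, seed = 4))
  row <- all_rc[all_rc$sample_a == "m01" & all_rc$sample_b == "m02", ]
  expect_lt(abs(row$rcbray - one), 0.25) # same null, independent Monte Carlo
  expect_true(all(all_rc$rcbray >= -1 & all_rc$rcbray <= 1))
})

test_that("RCbray is monotone in the observed dissimilarity for a fixed null", {
  set.seed(12)
  bc_null <- runif(500)
  rcs <- vapply(seq(0, 1, by = 0.1), function(b) {
    assemblr:::rc_score(bc_null, b)
  }, numeric(1))
  expect_true(all(diff(rcs) >= 0))
})

test_that("classification applies the strict two-step threshold rules", {
  pairs <- tibble::tibble(
    bnti = c(-3.1, 3.5, 1.0, -1.0, 0.5, -2.0, 2.0, NA),
    bnti_defined = c(rep(TRUE, 7), FALSE),
    rcbray = c(NA, NA, 0.3, -0.99, 0.99, 0.5, -0.5, NA)
  )
  out <- classify_processes(pairs)
  expect_equal(as.character(out$process),
               c("homogeneous_selection", "heterogeneous_selection", "drift",
                 "homogenising_dispersal", "dispersal_limitation",
                 "drift",   # bnti = -2 exactly falls through to RCbray
                 "drift",   # bnti = +2 exactly falls through
                 NA))
  # missing RCbray where needed is an error
  expect_error(classify_processes(tibble::tibble(bnti = 0.5, bnti_defined = TRUE,
                                                 rcbray = NA_real_)),
               "lack an RCbray")
})

test_that("assembly profiles partition pairs and sum to 100 percent", {
  set.seed(13)
  n <- 40
  pairs <- tibble::tibble(
    sample_a = sprintf("s%02d", sample(20, n, TRUE)),
    sample_b = sprintf("s%02d", sample(20, n, TRUE)),
    bnti = rnorm(n, sd = 3),
    bnti_defined = rep(c(TRUE, TRUE, TRUE, FALSE), n / 4),
    rcbray = runif(n, -1, 1),
    group = sample(c("g1", "g2"), n, TRUE)
  )
  pairs$bnti[!pairs$bnti_defined] <- NA
  out <- classify_processes(pairs)
  prof <- summarize_assembly(out, group_by = "group")
  sums <- tapply(prof$percent, prof$group, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  expect_equal(sum(prof$n_pairs) + sum(unique(prof[, c("group", "n_undefined")])$n_undefined),
               n)
  # every classified pair got exactly one process
  expect_equal(sum(!is.na(out$process)), sum(out$bnti_defined))
})

test_that("all-drift and mixed profiles report the right percentages", {
  pairs <- tibble::tibble(
    bnti = c(rep(-3, 6), rep(0, 4)),
    bnti_defined = TRUE,
    rcbray = c(rep(NA, 6), rep(0, 4))
  )
  prof <- summarize_assembly(classify_processes(pairs), group_by = character(0))
  expect_equal(prof$percent[prof$process == "homogeneous_selection"], 60)
  expect_equal(prof$percent[prof$process == "drift"], 40)
})

test_that("median betaNTI pools each sample's comparisons by site", {
  meta <- tibble::tibble(
    sample_id = c("s1", "s2", "s3", "s4"),
    site = c("A", "A", "B", "C"),
    substrate = "soil"
  )
  pairs <- tibble::tibble(
    sample_a = c("s1", "s1", "s2", "s3"),
    sample_b = c("s2", "s3", "s4", "s4"),
    bnti = c(1.5, 2.5, -1.0, 0.5)
  )
  out <- median_bnti(pairs, meta)
  # site A values: s1 in (1.5, 2.5), s2 in (1.5, -1.0) -> pooled {1.5,2.5,1.5,-1}
  expect_equal(out$median_bnti[out$site == "A"], median(c(1.5, 2.5, 1.5, -1)))
  expect_equal(out$median_bnti[out$site == "B"], median(c(2.5, 0.5)))

  # single pair -> that value for both sites involved
  one <- median_bnti(tibble::tibble(sample_a = "s1", sample_b = "s3", bnti = 1.5), meta)
  expect_true(all(one$median_bnti == 1.5))
})

test_that("betaNTI-environment correlation recovers exact and null relationships", {
  # exact affine relation: env = a * bnti + b
  bnti_vals <- c(-2, -1, 0, 1, 2, 3)
  a <- 0.5
  env <- tibble::tibble(site = paste0("o", 1:6), tn = a * bnti_vals + 1)
  dat <- tibble::tibble(site = paste0("o", 1:6), median_bnti = bnti_vals)
  ec <- env_correlation(dat, env, "tn")
  expect_equal(ec$r, 1, tolerance = 1e-12)
  expect_equal(ec$slope, 1 / a, tolerance = 1e-12)

  # 5-point hand dataset against closed forms
  x <- c(1, 2, 4, 5, 7); y <- c(2, 1, 5, 4, 8)
  ec2 <- env_correlation(
    tibble::tibble(site = paste0("o", 1:5), median_bnti = y),
    tibble::tibble(site = paste0("o", 1:5), v = x), "v"
  )
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  expect_equal(ec2$slope, sxy / sum((x - mean(x))^2), tolerance = 1e-12)
  expect_equal(ec2$r, sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)),
               tolerance = 1e-12)

  expect_error(env_correlation(
    tibble::tibble(site = paste0("o", 1:3), median_bnti = c(1, 1, 1)),
    tibble::tibble(site = paste0("o", 1:3), v = 1:3), "v"
  ), "zero variance")

  # null calibration: independent vectors, n = 12
  set.seed(14)
  rej <- 0
  for (i in 1:200) {
    dat <- tibble::tibble(site = paste0("o", 1:12), median_bnti = rnorm(12))
    env <- tibble::tibble(site = paste0("o", 1:12), v = rnorm(12))
    rej <- rej + (env_correlation(dat, env, "v")$p_value < 0.05)
  }
  expect_lt(rej / 200, 0.05 + 3 * sqrt(0.05 * 0.95 / 200) + 0.01)
})
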