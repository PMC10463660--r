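test_that("rarefaction keeps totals exact, drops shallow samples, matches the hypergeometric mean", {
  m <- matrix(c(60L, 40L, 0L,
                5L, 3L, 1L),
              2, 3, byrow = TRUE,
              dimnames = list(c("deep", "shallow"), c("a", "b", "c")))
  tbl <- community_tibble(m)

  # boundary: a sample whose total equals the depth is returned unchanged
  exact <- rarefy_counts(community_tibble(m["deep", , drop = FALSE]), 100, seed = 1)
  expect_equal(community_matrix(exact)["deep", ], m["deep", ])

  out <- suppressMessages(rarefy_counts(tbl, 50, seed = 1))
  om <- community_matrix(out)
  expect_equal(rownames(om), "deep")
  expect_equal(sum(om), 50)
  expect_equal(unname(om["deep", "c"]), 0) # zero support is preserved

  expect_error(rarefy_counts(tbl, 1000), "fewer than")

  # hypergeometric oracle: 2 ASVs (900, 100) rarefied to 100
  m2 <- matrix(c(900L, 100L), 1, 2, dimnames = list("s", c("x", "y")))
  draws <- vapply(1:2000, function(s) {
    community_matrix(rarefy_counts(community_tibble(m2), 100, seed = s))[1, "x"]
  }, numeric(1))
  mu <- 100 * 900 / 1000
  v <- 100 * 0.9 * 0.1 * (1000 - 100) / (1000 - 1)
  expect_lt(abs(mean(draws) - mu), 3 * sqrt(v / 2000))
})

test_that("CSS normalisation has its limiting cases and matches a two-loop reference", {
  set.seed(3)
  tbl <- random_table(5, 8)
  m <- community_matrix(tbl)

  # quantile 1 reduces to total-sum scaling
  n1 <- css_normalize(tbl, quantile = 1)
  rel <- sweep(m, 1, rowSums(m), "/")
  expect_equal(n1 / median(rowSums(m)), rel, tolerance = 1e-12)

  # scalar-multiple samples normalise identically
  m2 <- rbind(s1 = c(2, 4, 0, 6), s2 = c(1, 2, 0, 3))
  colnames(m2) <- letters[1:4]
  n2 <- css_normalize(community_tibble(m2), quantile = 0.5)
  expect_equal(n2["s1", ], n2["s2", ], tolerance = 1e-12)

  expect_equal(css_normalize(tbl, quantile = 0.5), css_oracle(m, 0.5),
               tolerance = 1e-9)

  zero <- community_tibble(matrix(c(0, 0, 1, 2), 2, 2, byrow = TRUE,
                                  dimnames = list(c("z", "ok"), c("a", "b"))))
  expect_error(css_normalize(zero), "zero total")
})

test_that("Shannon diversity matches closed forms and the hand-computed case", {
  m <- matrix(c(5L, 5L, 5L, 5L,
                8L, 0L, 0L, 0L,
                1L, 2L, 3L, 0L),
              3, 4, byrow = TRUE,
              dimnames = list(c("uniform", "single", "mixed"), letters[1:4]))
  h <- shannon_diversity(community_tibble(m))
  expect_equal(h$shannon[h$sample_id == "uniform"], log(4), tolerance = 1e-12)
  expect_equal(h$shannon[h$sample_id == "single"], 0, tolerance = 1e-12)
  p <- c(1, 2, 3) / 6
  expect_equal(h$shannon[h$sample_id == "mixed"], -sum(p * log(p)), tolerance = 1e-12)

  # maximal iff uniform over observed taxa
  set.seed(4)
  rnd <- shannon_diversity(random_table(10, 6))
  expect_true(all(rnd$shannon <= log(6) + 1e-12))
})

test_that("Bray-Curtis matches hand values and satisfies distance invariants", {
  m <- matrix(c(1, 1, 0,
                0, 1, 1,
                1, 1, 0,
                2, 0, 0),
              4, 3, byrow = TRUE,
              dimnames = list(c("x", "y", "x2", "w"), c("a", "b", "c")))
  d <- as.matrix(bray_curtis(community_tibble(m)))
  expect_equal(d["x", "y"], 0.5)       # (|1-0|+|1-1|+|0-1|) / 4
  expect_equal(d["x", "x2"], 0)        # identical samples
  expect_equal(d["y", "w"], 1)         # disjoint support

  set.seed(5)
  rd <- as.matrix(bray_curtis(random_table(8, 12)))
  expect_equal(rd, t(rd), tolerance = 1e-12)
  expect_equal(unname(diag(rd)), rep(0, 8))
  expect_true(all(rd >= 0 & rd <= 1))
})

test_that("shared/unique fractions partition each substrate's presence set", {
  # hand-built 6-ASV presence sets across 3 substrates
  m <- matrix(0L, 6, 6, dimnames = list(
    paste0("s", 1:6), paste0("a", 1:6)
  ))
  # leaf: a1 a2 a3 a4; fruit: a3 a4 a5; soil: a4 a6
  m[1, 1:4] <- 1L; m[2, 1:2] <- 1L
  m[3, 3:5] <- 2L; m[4, 5] <- 1L
  m[5, c(4, 6)] <- 3L; m[6, 6] <- 1L
  meta <- tibble::tibble(
    sample_id = paste0("s", 1:6),
    substrate = rep(c("leaf", "fruit", "soil"), each = 2),
    time = "t1"
  )
  sf <- shared_unique_fractions(community_tibble(m), meta)
  leaf <- sf[sf$substrate == "leaf", ]
  expect_equal(leaf$fraction[leaf$category == "unique"], 2 / 4)          # a1 a2
  expect_equal(leaf$fraction[leaf$category == "shared_with_fruit"], 1 / 4) # a3
  expect_equal(leaf$fraction[leaf$category == "shared_with_all"], 1 / 4)   # a4
  expect_equal(sum(leaf$fraction), 1, tolerance = 1e-9)
  for (s in unique(sf$substrate)) {
    expect_equal(sum(sf$fraction[sf$substrate == s]), 1, tolerance = 1e-9)
  }

  # identical presence sets -> everything shared with all
  m_id <- rbind(s1 = c(1L, 1L), s2 = c(2L, 1L), s3 = c(1L, 3L))
  colnames(m_id) <- c("a", "b")
  meta_id <- tibble::tibble(sample_id = paste0("s", 1:3),
                            substrate = c("leaf", "fruit", "soil"), time = "t1")
  sf_id <- shared_unique_fractions(community_tibble(m_id), meta_id)
  expect_true(all(sf_id$fraction[sf_id$category == "shared_with_all"] == 1))
  expect_true(all(sf_id$fraction[sf_id$category == "unique"] == 0))

  # fully disjoint -> unique fraction 1
  m_dj <- rbind(s1 = c(1L, 0L), s2 = c(0L, 2L))
  colnames(m_dj) <- c("a", "b")
  meta_dj <- tibble::tibble(sample_id = c("s1", "s2"),
                            substrate = c("leaf", "soil"), time = "t1")
  sf_dj <- shared_unique_fractions(community_tibble(m_dj), meta_dj)
  expect_true(all(sf_dj$fraction[sf_dj$category == "unique"] == 1))
})

test_that("the Mantel test is exact under proportionality and agrees with vegan", {
  set.seed(6)
  pts <- matrix(rnorm(20), 10, 2)
  d1 <- dist(pts)
  d2 <- 2 * d1
  mt <- mantel_test(d1, d2, permutations = 99, seed = 1)
  expect_equal(mt$statistic, 1, tolerance = 1e-12)

  d3 <- dist(matrix(rnorm(20), 10, 2))
  mine <- mantel_test(d1, d3, permutations = 999, seed = 1)
  ref <- vegan::mantel(d1, d3, permutations = 999)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(mine$p_value - ref$signif), 0.08) # same test, different streams

  expect_error(mantel_test(dist(pts[1:2, ]), dist(pts[1:2, ])), "at least 3")
})

test_that("exhaustive Mantel p equals the enumerated permutation tail", {
  set.seed(7)
  p4 <- matrix(rnorm(8), 4, 2)
  d1 <- as.matrix(dist(p4))
  d2 <- as.matrix(dist(p4 + rnorm(8, sd = 0.5)))
  mt <- mantel_test(d1, d2, exhaustive = TRUE)
  # independent enumeration of all 4! = 24 relabelings
  ltri <- lower.tri(d1)
  r_obs <- cor(d1[ltri], d2[ltri])
  perms <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  r_all <- apply(perms, 1, function(p) {
    p <- as.integer(p)
    cor(d1[ltri], d2[p, p][ltri])
  })
  expect_equal(length(r_all), 24)
  expect_equal(mt$p_value, mean(r_all >= r_obs - 1e-12), tolerance = 1e-12)
  expect_true(mt$exact)
})

test_that("Mantel p-values are valid under an exchangeable null", {
  set.seed(8)
  rej <- 0
  n_sim <- 200
  for (i in seq_len(n_sim)) {
    d1 <- dist(matrix(rnorm(16), 8, 2))
    d2 <- dist(matrix(rnorm(16), 8, 2))
    p <- mantel_test(d1, d2, permutations = 99, seed = i)$p_value
    rej <- rej + (p <= 0.05)
  }
  # binomial band around the nominal level
  expect_lt(rej / n_sim, 0.05 + 3 * sqrt(0.05 * 0.95 / n_sim) + 0.01)
})
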