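test_that("cosine similarity matches its defining cases", {
  set.seed(30)
  u <- rnorm(52)
  expect_equal(cosine_similarity(u, u), 1)
  expect_equal(cosine_similarity(u, -u), -1)
  expect_equal(cosine_similarity(u, 2 * u), 1)
  expect_error(cosine_similarity(u, rep(0, 52)), "zero")
})

test_that("cosine similarity is scale invariant for positive factors", {
  set.seed(31)
  for (rep in 1:50) {
    u <- rnorm(52); v <- rnorm(52); c <- runif(1, 1e-3, 1e3)
    expect_equal(cosine_similarity(u, c * v), cosine_similarity(u, v),
                 tolerance = 1e-12)
    expect_true(abs(cosine_similarity(u, v)) <= 1 + 1e-12)
  }
})

test_that("greedy pairing hand-traces the 3x3 example", {
  S <- rbind(c(0.9, 0.2, 0.1),
             c(0.8, 0.95, 0.3),
             c(0.1, 0.2, 0.7))
  p <- vfarchetypes:::greedy_pair_matrix(S)
  expect_equal(p$at1, c(2, 1, 3))
  expect_equal(p$at2, c(2, 1, 3))
  expect_equal(p$similarity, c(0.95, 0.9, 0.7))
})

test_that("pairing a permuted map recovers the permutation at similarity 1", {
  Z <- make_default_archetypes(6)
  perm <- c(4, 1, 6, 2, 5, 3)
  pr <- greedy_pair(Z, Z[perm, ])
  expect_equal(max(abs(pr$pairs$similarity - 1)), 0, tolerance = 1e-12)
  got <- pr$pairs$at2[order(pr$pairs$at1)]
  expect_equal(Z[perm, ][got[1], ], Z[1, ])
  expect_equal(order(perm), got)
  expect_equal(pr$n_above, 6)
})

test_that("greedy pairing follows the sequential-max oracle, not the optimum", {
  S <- rbind(c(0.9, 0.85),
             c(0.8, 0.1))
  g <- vfarchetypes:::greedy_pair_matrix(S)
  expect_equal(g$at2[g$at1 == 1], 1)            # greedy grabs 0.9 first
  expect_equal(sum(g$similarity), 1.0)
  opt <- assignment_oracle(S)                   # optimum crosses over
  expect_equal(opt, c(2L, 1L))
  expect_gt(sum(S[cbind(1:2, opt)]), sum(g$similarity))
})

test_that("greedy pairing equals the brute-force oracle on random matrices", {
  set.seed(32)
  for (rep in 1:60) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    S <- matrix(sample(seq(-1, 1, by = 0.25), n1 * n2, replace = TRUE), n1, n2)
    expect_equal(vfarchetypes:::greedy_pair_matrix(S), greedy_oracle(S))
  }
})

test_that("unequal maps pair to min(k) and report leftovers", {
  Z <- make_default_archetypes(5)
  pr <- greedy_pair(Z, Z[1:3, ])
  expect_equal(nrow(pr$pairs), 3)
  expect_equal(length(pr$unmatched1), 2)
  expect_equal(length(pr$unmatched2), 0)
})

test_that("Wilcoxon comparisons flag untestable and significant archetypes", {
  W <- matrix(runif(40), 10, 4)
  res <- wilcoxon_rw(W, W)
  expect_true(all(res$untestable))
  expect_true(all(is.na(res$p_value)))
  expect_false(any(res$significant))

  set.seed(33)
  W1 <- matrix(runif(20, 0.4, 0.6), 10, 2)
  W2 <- W1
  W2[, 1] <- W1[, 1] - runif(10, 0.05, 0.1)   # all positive differences
  res2 <- wilcoxon_rw(W1, W2)
  expect_lt(res2$p_value[1], 0.05)             # exact two-sided p = 2/2^10
  expect_equal(res2$p_value[1], 2 / 2^10, tolerance = 1e-12)
  expect_true(res2$untestable[2])
})

test_that("combined analysis of identical stimuli yields zero RW differences", {
  Zt <- make_default_archetypes(3)
  cfg <- synthetic_config(k_true = 3, true_archetypes = Zt, noise_sd = 1,
                          n_patients = 60, fp_contamination = 0, seed = 41)
  X <- td_matrix(preprocess_vf(simulate_vf_dataset(cfg)$vf_III,
                               cfg = censoring_config())$td)
  res <- combined_analysis(X, X, k = 3, seed = 42)
  expect_equal(max(res$rw_comparison$abs_diff), 0, tolerance = 1e-8)
  expect_true(all(res$rw_comparison$untestable))
  expect_equal(res$mean_abs_diff, 0, tolerance = 1e-8)
  # decomposed weights sum to 100% per field
  expect_equal(max(abs(rowSums(res$weights_III) - 1)), 0, tolerance = 1e-8)
  expect_equal(max(abs(rowSums(res$weights_V) - 1)), 0, tolerance = 1e-8)
  expect_equal(sum(res$map$rw_percent), 100, tolerance = 1e-6)
  expect_false(is.unsorted(rev(res$map$rw_percent)))
})

test_that("combined analysis refuses unpairable inputs when paired tests requested", {
  X <- matrix(rnorm(10 * 52), 10, 52)
  expect_error(combined_analysis(X, X[1:5, ], k = 2, paired = TRUE),
               "different row counts")
})

test_that("the published pairing table is well-formed", {
  tab <- reference_pair_table()
  expect_equal(nrow(tab), 28)
  for (d in unique(tab$disease)) {
    sub <- tab[tab$disease == d, ]
    expect_equal(sort(sub$at_III), 1:14)
    expect_equal(sort(sub$at_V), 1:14)      # a bijection
    expect_true(all(sub$similarity >= -1 & sub$similarity <= 1))
  }
})
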