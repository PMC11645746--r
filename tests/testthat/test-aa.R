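test_that("a single archetype is the data mean", {
  set.seed(10)
  for (n in c(7, 60)) {
    X <- matrix(rnorm(n * 5), n, 5)
    m <- fit_aa(X, 1, seed = 2)
    expect_equal(max(abs(m$archetypes - colMeans(X))), 0, tolerance = 1e-6)
    expect_equal(unname(m$A[, 1]), rep(1, n))
  }
})

test_that("k = n distinct points interpolates exactly", {
  set.seed(11)
  X <- matrix(rnorm(6 * 4), 6, 4)
  m <- fit_aa(X, 6, seed = 3)
  expect_lt(m$rss, 1e-6)
})

test_that("training RSS is non-increasing across iterations", {
  set.seed(12)
  X <- matrix(rnorm(80 * 10), 80, 10)
  for (k in c(2, 5)) {
    m <- fit_aa(X, k, seed = 4)
    h <- m$rss_history
    expect_true(all(diff(h) <= 1e-8 * pmax(h[-length(h)], 1)))
  }
})

test_that("model capacity is monotone: best RSS does not rise with k", {
  Zt <- make_default_archetypes(5)
  cfg <- synthetic_config(k_true = 5, true_archetypes = Zt, noise_sd = 1,
                          n_patients = 120, fp_contamination = 0, seed = 13)
  sim <- simulate_vf_dataset(cfg)
  X <- td_matrix(preprocess_vf(sim$vf_III,
                               cfg = censoring_config(threshold_III = 0,
                                                      threshold_V = 0))$td)
  rss <- vapply(2:7, function(k) fit_aa(X, k, seed = 5)$rss, numeric(1))
  expect_true(all(diff(rss) <= 1e-6 * pmax(rss[-length(rss)], 1)))
})

test_that("weight rows live on the probability simplex", {
  set.seed(14)
  X <- matrix(rnorm(40 * 8), 40, 8)
  m <- fit_aa(X, 4, seed = 6)
  expect_true(all(m$A >= 0))
  expect_equal(max(abs(rowSums(m$A) - 1)), 0, tolerance = 1e-8)
  expect_true(all(m$B >= 0))
  expect_equal(max(abs(rowSums(m$B) - 1)), 0, tolerance = 1e-8)
  expect_equal(m$rss, sum((X - m$A %*% m$archetypes)^2), tolerance = 1e-6)
})

test_that("decompose returns exact weights when an exact representation exists", {
  set.seed(15)
  Z <- rbind(c(4, 0, 0, 1), c(0, 4, 0, -1), c(0, 0, 4, 0))  # affinely independent
  expect_equal(unname(decompose(Z[2, , drop = FALSE], Z)[1, ]), c(0, 1, 0),
               tolerance = 1e-4)
  mid <- (Z[1, ] + Z[2, ]) / 2
  expect_equal(unname(decompose(matrix(mid, 1), Z)[1, ]), c(0.5, 0.5, 0),
               tolerance = 1e-3)
  expect_equal(unname(decompose(matrix(mid, 1), Z)[1, ]),
               qp_simplex(Z, mid), tolerance = 1e-5)
  expect_equal(unname(decompose(Z, Z)), diag(3), tolerance = 1e-4)
})

test_that("a zero field loads on the near-zero archetype (grid-search oracle)", {
  Z <- make_default_archetypes(3)  # normal, severe, superior altitudinal
  x <- rep(0, 52)
  w <- decompose(matrix(x, 1), Z)[1, ]
  # brute force over the simplex at resolution 0.01
  grid01 <- seq(0, 1, by = 0.01)
  best <- c(-1, -1); bv <- Inf
  for (a in grid01) for (b in grid01[grid01 <= 1 - a + 1e-12]) {
    cc <- 1 - a - b
    r <- sum((x - (a * Z[1, ] + b * Z[2, ] + cc * Z[3, ]))^2)
    if (r < bv) { bv <- r; best <- c(a, b, cc) }
  }
  expect_equal(unname(which.max(w)), which.max(best))
  expect_equal(unname(which.max(w)), 1L)  # the near-zero archetype
})

test_that("decompose agrees with a quadratic-programming oracle", {
  set.seed(16)
  for (rep in 1:20) {
    n <- sample(5:20, 1); k <- sample(2:4, 1); d <- sample(3:8, 1)
    Z <- matrix(rnorm(k * d), k, d)
    X <- matrix(rnorm(n * d), n, d)
    A <- decompose(X, Z)
    expect_equal(max(abs(rowSums(A) - 1)), 0, tolerance = 1e-8)
    for (i in seq_len(n)) {
      expect_equal(unname(A[i, ]), qp_simplex(Z, X[i, ]), tolerance = 1e-5)
    }
  }
})

test_that("relative weights are mean column mass in percent", {
  expect_equal(unname(relative_weights(matrix(1 / 3, 9, 3))), rep(100 / 3, 3))
  A <- matrix(0, 5, 4); A[, 1] <- 1
  expect_equal(unname(relative_weights(A)), c(100, 0, 0, 0))
  A2 <- rbind(c(1, 0), c(0.5, 0.5))
  expect_equal(unname(relative_weights(A2)), c(75, 25))
  expect_error(relative_weights(matrix(numeric(0), 0, 3)), "empty")
})

test_that("archetype maps order by descending RW with stable ties", {
  model <- list(archetypes = diag(3) * c(1, 2, 3),
                A = rbind(c(0.1, 0.6, 0.3)))  # RWs (10, 60, 30)
  map <- build_map(model)
  expect_equal(map$order, c(2, 3, 1))
  expect_equal(map$rw_percent, c(60, 30, 10))
  expect_equal(map$archetypes[1, 2], 2)  # archetype 2 promoted to rank 1

  tied <- list(archetypes = diag(2), A = rbind(c(0.5, 0.5)))
  expect_equal(build_map(tied)$order, c(1, 2))  # ties keep original index

  sorted <- list(archetypes = diag(2), A = rbind(c(0.9, 0.1)))
  expect_equal(build_map(sorted)$order, c(1, 2))
})

test_that("archetype maps survive a JSON round-trip", {
  set.seed(17)
  X <- td_matrix(preprocess_vf(
    simulate_vf_dataset(synthetic_config(k_true = 3, n_patients = 40,
                                         seed = 18))$vf_III,
    cfg = censoring_config())$td)
  map <- build_map(fit_aa(X, 3, seed = 19), stimulus = "III", label = "demo")
  path <- withr::local_tempfile(fileext = ".json")
  write_at_map(map, path)
  back <- read_at_map(path)
  expect_equal(back$archetypes, unname(map$archetypes), tolerance = 1e-12)
  expect_equal(back$rw_percent, map$rw_percent, tolerance = 1e-12)
  expect_equal(back$stimulus, "III")
})

test_that("degenerate and invalid inputs are rejected", {
  X <- matrix(rnorm(20), 5, 4)
  expect_error(fit_aa(X, 6), "k")
  bad <- X; bad[1, 1] <- NA
  expect_error(fit_aa(bad, 2), "finite")
  expect_error(decompose(X, matrix(rnorm(6), 2, 3)), "mismatch")
})
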