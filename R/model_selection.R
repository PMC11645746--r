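#' Cross-validated RSS curves over the number of archetypes
#'
#' For each candidate `k`, the data are split into `n_folds` folds (a true
#' partition: each row appears in the test set exactly once). Per fold, an
#' archetypal-analysis model is fitted on the training rows; the held-out
#' rows are then decomposed onto the *frozen* fold archetypes (weights
#' refit, archetypes fixed -- the only meaningful out-of-sample residual
#' for AA) and their squared residuals summed. Both the training and test
#' RSS are recorded per fold and averaged.
#'
#' When `groups` is supplied (e.g. patient ids for paired size-III/size-V
#' fields), all rows of a group are assigned to the same fold, preventing
#' leakage between paired fields.
#'
#' @param X Numeric matrix (`n x d`) or `td_table`.
#' @param k_values Candidate archetype counts (default 2..20).
#' @param n_folds Number of folds (default 10).
#' @param seed Seed for the fold shuffle and the fits.
#' @param groups Optional grouping vector of length `n`.
#' @param n_restarts Restarts per fit (kept small inside CV).
#' @param ... Further arguments to [fit_aa()].
#' @return An `aa_cv`: list with `folds` (fold id per row), `results`
#'   (data frame: k, fold, train_rss, test_rss), `curve` (data frame: k,
#'   mean_train_rss, mean_test_rss), `k_values`, `n_folds`, `seed`.
#' @export
cv_rss_curve <- function(X, k_values = 2:20, n_folds = 10, seed = 1,
                         groups = NULL, n_restarts = 2, ...) {
  if (inherits(X, "td_table")) X <- td_matrix(X)
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n_folds >= 2, n >= n_folds)

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  if (is.null(groups)) {
    folds <- sample(rep_len(seq_len(n_folds), n))
  } else {
    stopifnot(length(groups) == n)
    gu <- unique(groups)
    gf <- sample(rep_len(seq_len(n_folds), length(gu)))
    folds <- gf[match(groups, gu)]
  }

  res <- list()
  for (f in seq_len(n_folds)) {
    tr <- X[folds != f, , drop = FALSE]
    te <- X[folds == f, , drop = FALSE]
    for (k in k_values) {
      if (k >= nrow(tr)) stop(sprintf("k = %d too large for training fold of size %d",
                                      k, nrow(tr)), call. = FALSE)
      m <- fit_aa(tr, k, n_restarts = n_restarts,
                  seed = seed + 1000L * f + k, ...)
      Ate <- decompose(te, m)
      test_rss <- sum((te - Ate %*% m$archetypes)^2)
      res[[length(res) + 1L]] <- data.frame(k = k, fold = f,
                                            train_rss = m$rss,
                                            test_rss = test_rss)
    }
  }
  results <- do.call(rbind, res)
  curve <- do.call(rbind, lapply(sort(unique(results$k)), function(k) {
    rk <- results[results$k == k, ]
    data.frame(k = k, mean_train_rss = mean(rk$train_rss),
               mean_test_rss = mean(rk$test_rss))
  }))
  structure(list(folds = folds, results = results, curve = curve,
                 k_values = k_values, n_folds = n_folds, seed = seed),
            class = "aa_cv")
}

#' @export
print.aa_cv <- function(x, ...) {
  cat(sprintf("AA cross-validation: %d folds, k in [%d, %d]\n",
              x$n_folds, min(x$k_values), max(x$k_values)))
  print(x$curve, row.names = FALSE)
  invisible(x)
}

#' Choose the number of archetypes from a CV curve
#'
#' Automatic mode applies the elbow rule to the mean test-RSS curve: the
#' chosen `k` maximizes the perpendicular distance to the chord joining
#' the curve's endpoints, with ties broken toward the smaller `k` (a flat
#' curve therefore yields the smallest `k`). Manual mode returns
#' `manual_k` -- the number of archetypes is ultimately a judgment call
#' balancing parsimony against residual error -- and warns if its mean
#' test RSS exceeds the curve's global minimum by more than `slack`
#' (fraction, default 10%).
#'
#' @param cv An `aa_cv`.
#' @param mode `"auto_elbow"` or `"manual"`.
#' @param manual_k Archetype count for manual mode.
#' @param slack Tolerated fractional excess over the minimum mean test RSS
#'   before a manual choice triggers a warning.
#' @return The chosen `k` (integer).
#' @export
select_k <- function(cv, mode = c("auto_elbow", "manual"), manual_k = NULL,
                     slack = 0.10) {
  mode <- match.arg(mode)
  curve <- cv$curve
  if (mode == "manual") {
    if (is.null(manual_k) || !manual_k %in% curve$k) {
      stop("manual_k must be one of the evaluated k values", call. = FALSE)
    }
    rss_min <- min(curve$mean_test_rss)
    rss_k <- curve$mean_test_rss[curve$k == manual_k]
    if (rss_k > (1 + slack) * rss_min) {
      warning(sprintf(paste0("manual k = %d has mean test RSS %.4g, more than ",
                             "%.0f%% above the minimum %.4g"),
                      manual_k, rss_k, 100 * slack, rss_min), call. = FALSE)
    }
    return(as.integer(manual_k))
  }
  k <- curve$k
  r <- curve$mean_test_rss
  p1 <- c(k[1], r[1])
  p2 <- c(k[length(k)], r[length(r)])
  chord <- p2 - p1
  nc <- sqrt(sum(chord^2))
  # perpendicular distance of each curve point to the endpoint chord
  d <- abs(chord[2] * (k - p1[1]) - chord[1] * (r - p1[2])) / max(nc, .Machine$double.eps)
  as.integer(k[which.max(d)])  # which.max: first maximum = smallest k on ties
}
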