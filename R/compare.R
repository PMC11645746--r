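#' Cosine similarity between two fields or archetypes
#'
#' The normalized dot product `(u . v) / (|u| |v|)`, treating each visual
#' field as a 52-point vector. The score lies in \[-1, 1\], is independent
#' of intensity (doubling every TD value leaves it unchanged -- relevant
#' because archetypes are weighted sums of patterns), and compares the
#' *shape* of a defect without confounding by severity.
#'
#' @param u,v Numeric vectors of equal length; both must be nonzero.
#' @return Cosine similarity in \[-1, 1\].
#' @examples
#' cosine_similarity(c(1, 0), c(2, 0))  # 1
#' @export
cosine_similarity <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("cosine similarity undefined for a zero vector", call. = FALSE)
  }
  sum(u * v) / (nu * nv)
}

cosine_matrix <- function(Z1, Z2) {
  n1 <- sqrt(rowSums(Z1^2)); n2 <- sqrt(rowSums(Z2^2))
  if (any(n1 == 0) || any(n2 == 0)) {
    stop("cosine similarity undefined for a zero archetype", call. = FALSE)
  }
  (Z1 %*% t(Z2)) / outer(n1, n2)
}

#' Greedy cosine-similarity pairing of two archetype maps
#'
#' Computes the cosine similarity between every possible archetype pair,
#' then pairs sequentially: the globally most similar remaining pair is
#' recorded and both of its archetypes are excluded from further pairing,
#' until one map is exhausted. Exact ties are broken toward the lowest
#' (row, column) index. With equal `k` the result is a bijection; with
#' unequal `k`, `min(k1, k2)` pairs are formed and the leftovers listed.
#'
#' @param map1,map2 `at_map`s or plain `k x d` archetype matrices.
#' @param threshold Similarity counted as "matching" (default 0.8).
#' @return A `pairing_result`: list with `pairs` (data frame `at1`, `at2`,
#'   `similarity`, in assignment order, descending similarity), `n_above`
#'   (pairs with similarity >= `threshold`), `threshold`, `unmatched1`,
#'   `unmatched2`, `similarity_matrix`.
#' @export
greedy_pair <- function(map1, map2, threshold = 0.8) {
  Z1 <- archetype_matrix(map1)
  Z2 <- archetype_matrix(map2)
  if (nrow(Z1) == 0 || nrow(Z2) == 0) stop("empty archetype map", call. = FALSE)
  S <- cosine_matrix(Z1, Z2)
  pairs <- greedy_pair_matrix(S)
  structure(list(pairs = pairs,
                 n_above = sum(pairs$similarity >= threshold),
                 threshold = threshold,
                 unmatched1 = setdiff(seq_len(nrow(S)), pairs$at1),
                 unmatched2 = setdiff(seq_len(ncol(S)), pairs$at2),
                 similarity_matrix = S),
            class = "pairing_result")
}

# Sequential global-maximum selection with row/column deletion.
greedy_pair_matrix <- function(S) {
  S <- as.matrix(S)
  live_r <- seq_len(nrow(S)); live_c <- seq_len(ncol(S))
  out <- vector("list", min(nrow(S), ncol(S)))
  for (t in seq_along(out)) {
    sub <- S[live_r, live_c, drop = FALSE]
    best <- which(sub == max(sub), arr.ind = TRUE)
    # ties: lowest row index, then lowest column index
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- live_r[best[1]]; j <- live_c[best[2]]
    out[[t]] <- data.frame(at1 = i, at2 = j, similarity = S[i, j])
    live_r <- setdiff(live_r, i); live_c <- setdiff(live_c, j)
  }
  do.call(rbind, out)
}

#' @export
print.pairing_result <- function(x, ...) {
  cat(sprintf("Greedy archetype pairing: %d pairs, %d with similarity >= %.2f\n",
              nrow(x$pairs), x$n_above, x$threshold))
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Optimal-assignment pairing (diagnostic)
#'
#' Exhaustive search for the permutation maximizing total similarity.
#' The analysis pipeline pairs greedily; the optimal assignment is
#' provided only as a diagnostic and is limited to small maps.
#'
#' @param map1,map2 `at_map`s or archetype matrices (equal `k <= 8`).
#' @return Data frame `at1`, `at2`, `similarity`.
#' @export
optimal_pair <- function(map1, map2) {
  S <- cosine_matrix(archetype_matrix(map1), archetype_matrix(map2))
  k <- nrow(S)
  stopifnot(k == ncol(S), k <= 8)
  perms <- perm_all(k)
  tot <- vapply(perms, function(p) sum(S[cbind(seq_len(k), p)]), numeric(1))
  p <- perms[[which.max(tot)]]
  data.frame(at1 = seq_len(k), at2 = p, similarity = S[cbind(seq_len(k), p)])
}

perm_all <- function(k) {
  if (k == 1) return(list(1L))
  do.call(c, lapply(seq_len(k), function(i) {
    lapply(perm_all(k - 1L), function(p) c(i, ifelse(p >= i, p + 1L, p)))
  }))
}

#' Per-archetype Wilcoxon signed-rank comparison of paired weights
#'
#' For each archetype column, a two-sided Wilcoxon signed-rank test on the
#' paired per-field weight differences. Zero differences are dropped
#' before ranking (the classical convention); a column whose differences
#' are all zero is reported as untestable (`NA` p-value) rather than
#' forced to a p-value.
#'
#' @param W1,W2 `n x k` paired weight matrices (same fields, same order).
#' @param alpha Significance level for the `significant` flag.
#' @param adjust Multiple-testing correction passed to [stats::p.adjust()]
#'   (`"none"`, the default, matches per-test alpha; `"holm"` available).
#' @return Data frame: `at`, `n_nonzero`, `p_value`, `significant`,
#'   `untestable`.
#' @export
wilcoxon_rw <- function(W1, W2, alpha = 0.05, adjust = "none") {
  W1 <- as.matrix(W1); W2 <- as.matrix(W2)
  stopifnot(all(dim(W1) == dim(W2)))
  k <- ncol(W1)
  res <- lapply(seq_len(k), function(j) {
    d <- W1[, j] - W2[, j]
    d <- d[d != 0]
    if (length(d) == 0) {
      data.frame(at = j, n_nonzero = 0L, p_value = NA_real_, untestable = TRUE)
    } else {
      p <- suppressWarnings(wilcox.test(d, mu = 0,
                                        alternative = "two.sided")$p.value)
      data.frame(at = j, n_nonzero = length(d), p_value = p, untestable = FALSE)
    }
  })
  out <- do.call(rbind, res)
  out$p_value <- p.adjust(out$p_value, method = adjust)
  out$significant <- !out$untestable & out$p_value < alpha
  out[, c("at", "n_nonzero", "p_value", "significant", "untestable")]
}

#' Combined-stimulus archetypal analysis
#'
#' Pools the size-III and size-V total-deviation matrices (each
#' preprocessed under its own stimulus threshold), fits a single
#' archetypal model on the pooled rows, and builds the combined map. Each
#' stimulus subset is then decomposed separately onto the combined
#' archetypes; per-archetype relative weights per stimulus, their absolute
#' differences, the mean absolute difference, and per-archetype Wilcoxon
#' signed-rank p-values on the paired per-field weights are reported.
#'
#' @param td_III,td_V `n x 52` TD matrices or `td_table`s, paired row by
#'   row (same patients, same order) when `paired = TRUE`.
#' @param k Number of archetypes.
#' @param seed Seed for the fit.
#' @param paired Run the paired Wilcoxon tests (requires equal row counts).
#' @param label Map label.
#' @param ... Further arguments to [fit_aa()].
#' @return List with `map` (combined `at_map`), `weights_III`,
#'   `weights_V` (per-field simplex weights on the combined map),
#'   `rw_comparison` (data frame: `at`, `rw_III`, `rw_V`, `abs_diff`,
#'   plus Wilcoxon columns when paired), `mean_abs_diff`, `model`.
#' @export
combined_analysis <- function(td_III, td_V, k, seed = 1, paired = TRUE,
                              label = "", ...) {
  X1 <- if (inherits(td_III, "td_table")) td_matrix(td_III) else as.matrix(td_III)
  X2 <- if (inherits(td_V, "td_table")) td_matrix(td_V) else as.matrix(td_V)
  if (paired && nrow(X1) != nrow(X2)) {
    stop("paired comparison requested but the stimuli have different row counts",
         call. = FALSE)
  }
  model <- fit_aa(rbind(X1, X2), k, seed = seed, ...)
  map <- build_map(model, stimulus = "combined", label = label)
  W1 <- decompose(X1, map)
  W2 <- decompose(X2, map)
  rw1 <- relative_weights(W1)
  rw2 <- relative_weights(W2)
  cmp <- data.frame(at = seq_len(k), rw_III = rw1, rw_V = rw2,
                    abs_diff = abs(rw1 - rw2))
  if (paired) {
    wt <- wilcoxon_rw(W1, W2)
    cmp$p_value <- wt$p_value
    cmp$significant <- wt$significant
    cmp$untestable <- wt$untestable
  }
  list(map = map, weights_III = W1, weights_V = W2, rw_comparison = cmp,
       mean_abs_diff = mean(cmp$abs_diff), model = model)
}

#' Published archetype-pair similarities (reference table)
#'
#' The published comparison of size-III and size-V archetype maps reports,
#' for each disease cohort (moderate-to-severe glaucoma and NAION), 14
#' greedy-paired archetypes with their cosine similarities. These values
#' are inputs for threshold-count checks (how many pairs reach a given
#' similarity), frozen here from the published pairing table.
#'
#' @return Data frame: `disease`, `at_III`, `at_V`, `similarity`.
#' @export
reference_pair_table <- function() {
  rbind(
    data.frame(disease = "glaucoma",
               at_III = 1:14,
               at_V = c(1, 7, 4, 10, 6, 3, 2, 8, 9, 14, 11, 5, 12, 13),
               similarity = c(1.00, 0.99, 0.96, 0.67, 0.96, 0.95, 0.96,
                              0.98, 0.92, 0.97, 0.95, -0.75, 0.93, 0.92)),
    data.frame(disease = "naion",
               at_III = 1:14,
               at_V = c(1, 2, 3, 7, 6, 8, 10, 11, 5, 12, 13, 14, 4, 9),
               similarity = c(1.00, 0.99, 0.99, 0.97, 0.92, 0.97, 0.98,
                              0.83, 0.98, 0.93, 0.97, 0.37, 0.81, 0.34))
  )
}

#' Count archetype pairs at or above a similarity threshold
#'
#' @param pairs A `pairing_result` or a data frame with a `similarity`
#'   column (e.g. [reference_pair_table()] subset).
#' @param threshold Similarity threshold (default 0.8).
#' @return Integer count.
#' @export
count_pairs_above <- function(pairs, threshold = 0.8) {
  if (inherits(pairs, "pairing_result")) pairs <- pairs$pairs
  sum(pairs$similarity >= threshold)
}
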