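#' Fit an archetypal-analysis model
#'
#' Archetypal analysis factorizes an `n x d` data matrix `X` as
#' `X ~ A %*% Z` with `Z = B %*% X`: each observation is approximated by a
#' convex combination (rows of `A` on the probability simplex) of `k`
#' archetypes, and each archetype is itself a convex combination (rows of
#' `B`) of observations, so archetypes are extremal patterns lying on the
#' convex hull of the data. The fit alternates exact simplex-constrained
#' least-squares updates of `A` (per observation) and Gauss-Seidel updates
#' of `B` (per archetype), which makes the residual sum of squares
#' non-increasing at every step. The best of `n_restarts` fits by RSS is
#' returned.
#'
#' @param X Numeric matrix (`n x d`), e.g. a [td_matrix()].
#' @param k Number of archetypes, `1 <= k <= n`.
#' @param init `"furthest_sum"` (deterministic given seed; spreads the
#'   initial archetypes across the data cloud) or `"random"` (k distinct
#'   rows).
#' @param n_restarts Number of random restarts.
#' @param tol Relative RSS improvement below which iteration stops.
#' @param max_iter Maximum alternating iterations per restart.
#' @param seed Integer seed controlling initialization.
#' @return An `aa_model`: list with `k`, `archetypes` (`k x d`), `A`
#'   (`n x k`), `B` (`k x n`), `rss`, `rss_history`, `converged`,
#'   `n_iter`, `init`, `seed`.
#' @examples
#' X <- matrix(rnorm(200), 50, 4)
#' m <- fit_aa(X, k = 3, seed = 1)
#' m$rss
#' @export
fit_aa <- function(X, k, init = c("furthest_sum", "random"), n_restarts = 5,
                   tol = 1e-6, max_iter = 500, seed = 1) {
  init <- match.arg(init)
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("X must be finite", call. = FALSE)
  n <- nrow(X)
  if (k < 1 || k > n) stop("need 1 <= k <= nrow(X)", call. = FALSE)

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  best <- NULL
  for (r in seq_len(n_restarts)) {
    idx <- if (init == "furthest_sum") {
      furthest_sum_init(X, k, start = sample.int(n, 1))
    } else {
      sample.int(n, k)
    }
    fit <- cpp_fit_aa(X, as.integer(k), as.integer(idx - 1L), tol,
                      as.integer(max_iter))
    if (is.null(best) || fit$rss < best$rss) best <- fit
  }

  structure(list(k = k, archetypes = best$archetypes, A = best$A, B = best$B,
                 rss = best$rss, rss_history = as.numeric(best$rss_history),
                 converged = isTRUE(best$converged), n_iter = best$n_iter,
                 init = init, seed = seed),
            class = "aa_model")
}

# Furthest-sum seeding: greedily add the point with the largest summed
# distance to those already chosen, starting from a (seeded) random point.
furthest_sum_init <- function(X, k, start) {
  n <- nrow(X)
  chosen <- start
  if (k == 1) return(chosen)
  sumd <- sqrt(rowSums(sweep(X, 2, X[start, ])^2))
  for (t in 2:k) {
    cand <- sumd
    cand[chosen] <- -Inf
    nxt <- which.max(cand)
    chosen <- c(chosen, nxt)
    if (t < k) sumd <- sumd + sqrt(rowSums(sweep(X, 2, X[nxt, ])^2))
  }
  chosen
}

#' @export
print.aa_model <- function(x, ...) {
  cat(sprintf("Archetypal analysis model: k = %d, n = %d, d = %d\n",
              x$k, nrow(x$A), ncol(x$archetypes)))
  cat(sprintf("  RSS %.6g after %d iterations (%s)\n", x$rss, x$n_iter,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Decompose fields onto a fixed archetype set
#'
#' Per-row simplex-constrained least squares against frozen archetypes:
#' each field receives nonnegative weights summing to 1 (reported
#' externally in percent) that best reconstruct it as a convex combination
#' of the archetypes.
#'
#' @param X Numeric matrix (`m x d`) of fields, or a `td_table`.
#' @param Z `k x d` archetype matrix, an `aa_model`, or an `at_map`.
#' @return `m x k` weight matrix, rows on the simplex.
#' @export
decompose <- function(X, Z) {
  if (inherits(X, "td_table")) X <- td_matrix(X)
  X <- as.matrix(X)
  Z <- archetype_matrix(Z)
  if (ncol(X) != ncol(Z)) stop("dimension mismatch between fields and archetypes",
                               call. = FALSE)
  A <- cpp_simplex_decompose(X, Z)
  colnames(A) <- rownames(Z)
  A
}

archetype_matrix <- function(Z) {
  if (inherits(Z, "aa_model")) return(as.matrix(Z$archetypes))
  if (inherits(Z, "at_map")) return(as.matrix(Z$archetypes))
  as.matrix(Z)
}

#' Relative weights of archetypes
#'
#' An archetype's relative weight (RW) is its share of the dataset's total
#' decomposition mass: `RW_j = 100 * sum(A[, j]) / sum(A)`, i.e. 100 times
#' the mean weight on archetype `j`. RWs sum to 100%.
#'
#' @param A `n x k` simplex-weight matrix.
#' @return Numeric vector of `k` RWs in percent.
#' @export
relative_weights <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) == 0) stop("empty weight matrix", call. = FALSE)
  100 * colSums(A) / sum(A)
}

#' Build an ordered archetype map
#'
#' Orders archetypes by descending relative weight (frequency within the
#' dataset), renumbering from 1; ties keep the original index order. The
#' permutation from model order to map order is recorded.
#'
#' @param model An `aa_model` (or list with `archetypes` and `A`).
#' @param stimulus Label: `"III"`, `"V"` or `"combined"`.
#' @param label Free-text dataset/disease label.
#' @return An `at_map`: list with `archetypes` (sorted `k x d`),
#'   `rw_percent`, `order` (original indices in map order), `stimulus`,
#'   `label`, `k`.
#' @export
build_map <- function(model, stimulus = "III", label = "") {
  rw <- relative_weights(model$A)
  ord <- order(-rw, seq_along(rw))  # stable: ties by original index
  structure(list(archetypes = as.matrix(model$archetypes)[ord, , drop = FALSE],
                 rw_percent = rw[ord], order = ord,
                 stimulus = stimulus, label = label, k = length(ord)),
            class = "at_map")
}

#' @export
print.at_map <- function(x, ...) {
  cat(sprintf("Archetype map (%s%s): %d archetypes\n",
              x$stimulus, if (nzchar(x$label)) paste0(", ", x$label) else "", x$k))
  cat("  RW%:", paste(sprintf("%.1f", x$rw_percent), collapse = " "), "\n")
  invisible(x)
}

#' Serialize an archetype map to JSON
#'
#' Layout: `{"grid": [{"x":..,"y":..} x 52], "archetypes": [{"index": i,
#' "rw_percent": w, "td": [52 floats]}], "meta": {...}}`.
#'
#' @param map An `at_map`.
#' @param path Output JSON path.
#' @param grid Grid convention.
#' @return `path` invisibly; `read_at_map()` returns the map.
#' @export
write_at_map <- function(map, path, grid = vf_grid()) {
  obj <- list(
    grid = grid[, c("x", "y")],
    archetypes = lapply(seq_len(map$k), function(i) {
      list(index = i, rw_percent = map$rw_percent[i],
           td = as.numeric(map$archetypes[i, ]))
    }),
    meta = list(stimulus = map$stimulus, label = map$label, k = map$k)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_at_map
#' @export
read_at_map <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  Z <- do.call(rbind, lapply(obj$archetypes$td, as.numeric))
  structure(list(archetypes = Z, rw_percent = obj$archetypes$rw_percent,
                 order = seq_len(nrow(Z)), stimulus = obj$meta$stimulus,
                 label = obj$meta$label, k = nrow(Z)),
            class = "at_map")
}
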