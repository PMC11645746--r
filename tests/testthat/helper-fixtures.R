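# Small in-code fixtures shared across test files.

# A minimal well-formed visual-field table.
tiny_vf <- function(n = 3, stimulus = "III", eye = "right", age = 60,
                    fp_rate = 0.05, fill = 28) {
  df <- data.frame(patient_id = sprintf("T%03d", seq_len(n)),
                   eye = eye, age = age, stimulus = stimulus,
                   fp_rate = fp_rate, stringsAsFactors = FALSE)
  m <- matrix(fill, n, 52)
  df[, sprintf("loc_%02d", 1:52)] <- m
  as_vf_table(df)
}

# Sequential-max greedy pairing oracle: literal double loop, independent of
# the package's implementation.
greedy_oracle <- function(S) {
  S <- as.matrix(S)
  rows <- seq_len(nrow(S)); cols <- seq_len(ncol(S))
  out <- NULL
  while (length(rows) > 0 && length(cols) > 0) {
    best <- c(NA, NA); bv <- -Inf
    for (i in rows) for (j in cols) {
      if (S[i, j] > bv) { bv <- S[i, j]; best <- c(i, j) }
      # ties: first (lowest row, then column) encountered wins
    }
    out <- rbind(out, data.frame(at1 = best[1], at2 = best[2], similarity = bv))
    rows <- setdiff(rows, best[1]); cols <- setdiff(cols, best[2])
  }
  out
}

# Exhaustive optimal assignment (total-similarity maximizer) on a square S.
assignment_oracle <- function(S) {
  k <- nrow(S)
  perms <- vfarchetypes:::perm_all(k)
  tot <- vapply(perms, function(p) sum(S[cbind(seq_len(k), p)]), numeric(1))
  perms[[which.max(tot)]]
}

# Simplex-constrained least squares via pracma's quadratic programming,
# used as the independent oracle for decompose().
qp_simplex <- function(Z, x) {
  k <- nrow(Z)
  res <- pracma::quadprog(Z %*% t(Z), -as.numeric(Z %*% x),
                          Aeq = matrix(1, 1, k), beq = 1, lb = rep(0, k))
  res$xmin
}
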