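#' Ground-truth archetype library for simulation
#'
#' Builds `k` distinct 52-point total-deviation patterns that qualitatively
#' mimic the archetypes seen in anterior optic neuropathy: a near-normal
#' pattern, uniform severe loss, superior/inferior altitudinal defects,
#' arcuate defects, nasal steps, central and ring scotomas, wedge and
#' quadrant defects. The first two patterns are always the near-zero
#' "normal" pattern and the uniform severe-loss pattern. All values lie in
#' \[-20, 5\] dB and every pair of patterns has cosine similarity at most
#' 0.9 (verified at construction).
#'
#' @param k Number of archetypes, between 1 and 16.
#' @param grid Grid convention.
#' @param seed Seed for the optional jitter.
#' @param jitter_sd Standard deviation (dB) of smooth Gaussian jitter added
#'   to each pattern; 0 (default) gives the fixed library.
#' @return A `k` x 52 matrix of TD patterns (rows are archetypes).
#' @export
make_default_archetypes <- function(k, grid = vf_grid(), seed = 1,
                                    jitter_sd = 0) {
  if (k < 1 || k > 16) stop("k must be between 1 and 16", call. = FALSE)
  x <- grid$x; y <- grid$y; ecc <- sqrt(x^2 + y^2)
  lib <- rbind(
    normal        = 1 - 0.03 * ecc,
    severe        = rep(-15, 52),
    sup_altitud   = ifelse(y > 0, -13, -1),
    inf_altitud   = ifelse(y < 0, -13, -1),
    sup_arcuate   = ifelse(y > 0 & ecc >= 10, -11, -0.5),
    inf_arcuate   = ifelse(y < 0 & ecc >= 10, -11, -0.5),
    sup_nasal     = ifelse(x <= -9 & y > 0, -10, -0.5),
    inf_nasal     = ifelse(x <= -9 & y < 0, -10, -0.5),
    central       = ifelse(ecc <= 11, -12, -1),
    ring          = ifelse(ecc >= 18, -12, -1),
    temp_wedge    = ifelse(x >= 9 & abs(y) <= 9, -10, -0.5),
    sup_paracen   = ifelse(x >= -9 & x <= 9 & y >= 3 & y <= 9, -12, -0.5),
    suptemp_quad  = ifelse(x > 0 & y > 0, -12, -0.5),
    arcuate_nasal = ifelse((y > 0 & ecc >= 10) | (x <= -9 & y < 0), -10, -0.5),
    inf_temporal  = ifelse(x >= 3 & y < 0, -11, -0.5),
    nasal_hemi    = ifelse(x < 0, -10, -0.5)
  )
  Z <- lib[seq_len(k), , drop = FALSE]
  if (jitter_sd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    Z <- Z + matrix(rnorm(length(Z), sd = jitter_sd), nrow = k)
  }
  Z <- pmin(pmax(Z, -20), 5)
  if (k > 1) {
    Zn <- Z / sqrt(rowSums(Z^2))
    cmax <- max((Zn %*% t(Zn))[upper.tri(diag(k))])
    if (cmax > 0.9 + 1e-9) {
      stop("archetype library degenerate: a pattern pair exceeds cosine 0.9",
           call. = FALSE)
    }
  }
  Z
}

#' Configuration of the synthetic visual-field generator
#'
#' @param k_true Number of ground-truth archetypes.
#' @param true_archetypes `k_true` x 52 TD matrix; defaults to
#'   [make_default_archetypes()].
#' @param weight_concentration Symmetric Dirichlet concentration for the
#'   per-patient mixture weights. Small values (< 1) concentrate mass near
#'   the simplex corners, matching fields dominated by one or two patterns.
#' @param noise_sd Measurement noise SD (dB).
#' @param noise_model `"homoscedastic"` (i.i.d. Gaussian on the dB scale)
#'   or `"sensitivity_dependent"` (SD doubled where the noiseless
#'   sensitivity falls below 25 dB, mimicking the loss of signal-to-noise
#'   at low sensitivities).
#' @param n_patients Number of patients; each contributes one size-III and
#'   one size-V field with the same underlying TD pattern.
#' @param age_range Uniform age range (years).
#' @param fp_contamination Fraction of fields per stimulus given a
#'   false-positive rate above 0.2 (so they trip the quality filter).
#' @param left_eye_fraction Fraction of patients simulated as left eyes
#'   (stored in the eye's native orientation).
#' @param seed Integer seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(k_true = 14,
                             true_archetypes = make_default_archetypes(k_true),
                             weight_concentration = 0.3,
                             noise_sd = 1.0,
                             noise_model = c("homoscedastic", "sensitivity_dependent"),
                             n_patients = 500,
                             age_range = c(45, 85),
                             fp_contamination = 0.013,
                             left_eye_fraction = 0.5,
                             seed = 1) {
  noise_model <- match.arg(noise_model)
  stopifnot(k_true >= 1, nrow(true_archetypes) == k_true,
            ncol(true_archetypes) == 52, weight_concentration > 0,
            noise_sd >= 0, n_patients >= 1,
            fp_contamination >= 0, fp_contamination <= 1,
            left_eye_fraction >= 0, left_eye_fraction <= 1)
  structure(list(k_true = k_true, true_archetypes = true_archetypes,
                 weight_concentration = weight_concentration,
                 noise_sd = noise_sd, noise_model = noise_model,
                 n_patients = n_patients, age_range = age_range,
                 fp_contamination = fp_contamination,
                 left_eye_fraction = left_eye_fraction, seed = seed),
            class = "synthetic_config")
}

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

#' Simulate a paired size-III / size-V visual-field dataset
#'
#' Per patient: age is uniform on `age_range`, mixture weights are drawn
#' from a symmetric Dirichlet, and the underlying TD pattern is the convex
#' mixture `weights %*% archetypes`. The same TD pattern generates both
#' stimuli of the pair (the premise under test downstream: one defect,
#' seen through two stimulus sizes). Per stimulus, sensitivity is the
#' normative value at the patient's age plus the true TD plus Gaussian
#' noise, floored at 0 dB (stimulus not seen).
#' A fraction `fp_contamination` of fields per stimulus receives a
#' false-positive rate above 0.2; the rest stay below 0.15. Left-eye
#' patients are stored in the eye's native (mirrored) orientation so the
#' canonicalization step is exercised.
#'
#' @param cfg A [synthetic_config()].
#' @param normative A `normative_model`.
#' @param grid Grid convention.
#' @param weights Optional `n_patients` x `k_true` matrix forcing the
#'   mixture weights (rows must lie on the simplex); overrides the
#'   Dirichlet draw.
#' @return List with `vf_III`, `vf_V` (both `vf_table`s, matching
#'   `patient_id` order), and `truth` (list: `weights`, `archetypes`,
#'   `td_true`, `ages`, `eyes`).
#' @export
simulate_vf_dataset <- function(cfg = synthetic_config(),
                                normative = default_normative(),
                                grid = vf_grid(), weights = NULL) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(cfg$seed)

  n <- cfg$n_patients
  k <- cfg$k_true
  Z <- cfg$true_archetypes
  ages <- round(runif(n, cfg$age_range[1], cfg$age_range[2]), 1)
  W <- if (is.null(weights)) {
    rdirichlet(n, rep(cfg$weight_concentration, k))
  } else {
    stopifnot(nrow(weights) == n, ncol(weights) == k,
              all(weights >= 0), max(abs(rowSums(weights) - 1)) < 1e-8)
    weights
  }
  td_true <- W %*% Z
  eyes <- ifelse(runif(n) < cfg$left_eye_fraction, "left", "right")
  ids <- sprintf("P%04d", seq_len(n))
  p <- mirror_permutation(grid)

  one_stim <- function(stim) {
    norm_m <- t(vapply(ages, function(a) normative_values(normative, stim, a),
                       numeric(52)))
    sens0 <- norm_m + td_true
    sd_m <- matrix(cfg$noise_sd, n, 52)
    if (cfg$noise_model == "sensitivity_dependent") sd_m[sens0 < 25] <- 2 * cfg$noise_sd
    sens <- sens0 + matrix(rnorm(n * 52), n, 52) * sd_m
    sens <- pmax(sens, 0)
    left <- eyes == "left"
    sens[left, ] <- sens[left, p, drop = FALSE]  # store in native orientation
    n_bad <- round(cfg$fp_contamination * n)
    bad <- sample.int(n, n_bad)
    fp <- round(runif(n, 0, 0.15), 3)
    fp[bad] <- round(runif(n_bad, 0.25, 0.45), 3)
    df <- data.frame(patient_id = ids, eye = eyes, age = ages,
                     stimulus = stim, fp_rate = fp, stringsAsFactors = FALSE)
    df[, loc_cols()] <- sens
    as_vf_table(df, grid)
  }

  list(vf_III = one_stim("III"), vf_V = one_stim("V"),
       truth = list(weights = W, archetypes = Z, td_true = td_true,
                    ages = ages, eyes = eyes))
}

#' Mixture weights with guaranteed simplex-corner coverage
#'
#' Draws per-patient weights from the symmetric Dirichlet and replaces a
#' small fraction of rows by exact unit vectors, spread equally over the
#' archetypes, before shuffling. Archetypal analysis can only recover an
#' archetype whose corner of the weight simplex is actually visited by
#' the data; clinical cohorts do contain such pure presentations (fully
#' normal eyes, textbook altitudinal or arcuate defects), while a plain
#' low-concentration Dirichlet at moderate `n` essentially never produces
#' them. This constructor is the weight design used by the package's
#' parameter-recovery experiments.
#'
#' @param n Number of patients.
#' @param k Number of archetypes.
#' @param concentration Symmetric Dirichlet concentration for the
#'   non-pure rows.
#' @param pure_fraction Fraction of rows made exactly pure (unit weight
#'   on one archetype), spread equally across archetypes.
#' @param seed Integer seed.
#' @return `n x k` matrix, rows on the probability simplex.
#' @export
recovery_weights <- function(n, k, concentration = 0.3, pure_fraction = 0.05,
                             seed = 1) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  W <- rdirichlet(n, rep(concentration, k))
  per <- ceiling(pure_fraction * n / k)
  stopifnot(per * k <= n)
  idx <- 1L
  for (j in seq_len(k)) {
    for (r in seq_len(per)) {
      w <- rep(0, k); w[j] <- 1
      W[idx, ] <- w
      idx <- idx + 1L
    }
  }
  W[sample.int(n), , drop = FALSE]
}
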