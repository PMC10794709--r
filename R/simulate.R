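#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities (response peak near 5 s, undershoot
#' near 15 s), scaled to unit peak. Used only by the simulator; the FIR
#' analysis itself assumes no response shape.
#'
#' @param t time in seconds (vector).
#' @param peak_shape,peak_scale shape/scale of the response gamma.
#' @param under_shape,under_scale shape/scale of the undershoot gamma.
#' @param under_ratio undershoot amplitude relative to the response.
#' @return HRF values at `t`, max 1.
#' @export
hrf_double_gamma <- function(t, peak_shape = 6, peak_scale = 1,
                             under_shape = 16, under_scale = 1,
                             under_ratio = 1 / 6) {
  h <- stats::dgamma(t, shape = peak_shape, scale = peak_scale) -
    under_ratio * stats::dgamma(t, shape = under_shape, scale = under_scale)
  h[t < 0] <- 0
  h / max(h)
}

# fine time grid used for envelope construction / convolution (seconds)
.env_dt <- 0.1

#' Default neural-response envelopes of the coded attributes
#'
#' Each envelope is a nonnegative activity profile over post-sample seconds,
#' sampled at 0.1 s, which the simulator convolves with the HRF. Defaults:
#' the sample code is a stimulus-evoked transient over 0-1.6 s, so its
#' BOLD response (envelope convolved with the canonical HRF) peaks in the
#' middle of the delay (4-8 s); the result code ramps up from 3 s (once the
#' 2 s operation cue has been processed) and is sustained until the probe,
#' so its BOLD response dominates the late delay (8-12 s). Operation and
#' operand codes are cue-locked transients (2-3.6 s). No envelope is active
#' before its attribute's earliest causal event.
#'
#' The condition-stable nuisance code (see [make_voxel_population()]) is
#' active throughout the pre-probe delay.
#'
#' @param spec a [design_spec()] (sets trial length and cue onset).
#' @return Named list of numeric envelope vectors (sample, operation,
#'   operand, result, nuisance) on the 0.1 s grid spanning one trial.
#' @export
default_envelopes <- function(spec = design_spec()) {
  t <- seq(0, spec$trial_length, by = .env_dt)
  ramp01 <- function(x) pmin(pmax(x, 0), 1)
  sample_env <- as.numeric(t >= 0 & t < 1.6)
  cue_env <- as.numeric(t >= spec$cue_onset & t < spec$cue_onset + 1.6)
  result_env <- ramp01((t - 3) / 3) *
    as.numeric(t < spec$probe_soa_standard)
  trial_env <- as.numeric(t < spec$probe_soa_standard)
  list(sample = sample_env, operation = cue_env, operand = cue_env,
       result = result_env, nuisance = trial_env)
}

#' Noise model for simulated BOLD runs
#'
#' Additive noise is a stationary AR(1) process of marginal standard
#' deviation `sigma`, plus a per-voxel slow drift built from the first
#' `drift_order` non-constant discrete-cosine components with random
#' coefficients of standard deviation `drift_sd`, plus a constant baseline.
#'
#' @param ar1_rho lag-1 autocorrelation, |rho| < 1.
#' @param sigma marginal noise standard deviation (signal units).
#' @param drift_order number of slow cosine drift components per voxel.
#' @param drift_sd standard deviation of the drift coefficients.
#' @param baseline constant signal offset.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(ar1_rho = 0.3, sigma = 1, drift_order = 3,
                        drift_sd = 0.5, baseline = 100) {
  stopifnot(abs(ar1_rho) < 1, sigma >= 0, drift_order >= 0, drift_sd >= 0)
  structure(list(ar1_rho = ar1_rho, sigma = sigma,
                 drift_order = drift_order, drift_sd = drift_sd,
                 baseline = baseline),
            class = "noise_model")
}

#' Build a voxel population with known attribute codes
#'
#' Numerosity attributes (sample, result) are coded by embedding the four
#' log-spaced numerosity levels as points in pattern space with a fixed,
#' compressively saturating representational geometry (see
#' [level_geometry()]): adjacent levels sit at graded distances and
#' far-apart levels saturate, a monotone log-scale magnitude code. Each
#' condition additionally carries an identity component whose energy
#' equalizes the centered pattern norms across conditions, so the
#' population's correlation-distance structure is homogeneous and, in the
#' group expectation, spanned by the design's log-distance predictors at
#' any measurement noise level. Categorical attributes (operation,
#' operand) are coded as value times a unit-norm gain vector.
#'
#' The geometry between the sample and result codes is controlled by
#' `subspace_share`: the result code reuses the same level embedding on a
#' basis mixed as `share * B_sample + sqrt(1 - share^2) * B_independent`,
#' so the leading sample and result code directions (reported in
#' `weights`) correlate exactly `subspace_share` (1 = a fully shared
#' representational space in which, e.g., 12 evokes the same pattern as
#' sample or as result; 0 = orthogonal subspaces). Operation and operand
#' gains are orthogonalized against the numerosity bases. Weights may be
#' restricted to an `active_voxels` subset (zero elsewhere) to embed the
#' code in a spatial region of a larger grid.
#'
#' The population also carries a condition-stable nuisance code: random
#' per-condition values (drawn with the population seed, hence
#' idiosyncratic per subject) on their own weight directions, active
#' throughout the pre-probe delay. This emulates reliable
#' condition-specific pattern structure unrelated to the design predictors
#' (display idiosyncrasies, strategy differences), the component that
#' makes representational effects scatter across subjects in real data; it
#' averages out at the group level.
#'
#' @param n_voxels total number of voxels.
#' @param subspace_share in [0, 1]; cosine between sample and result codes.
#' @param amplitudes named vector of effect sizes (signal units at the
#'   BOLD response peak) for sample, result, operation, operand and the
#'   condition-stable nuisance code. The defaults embed sample and result
#'   codes (plus the nuisance code) only.
#' @param seed integer seed; identical seeds give identical populations.
#' @param active_voxels optional integer indices of the voxels carrying the
#'   code.
#' @param envelopes named list of envelopes, see [default_envelopes()].
#' @param spec a [design_spec()].
#' @return An object of class `coding_model`.
#' @export
make_voxel_population <- function(n_voxels, subspace_share = 0,
                                  amplitudes = c(sample = 1.2, result = 2,
                                                 operation = 0, operand = 0,
                                                 nuisance = 1.5),
                                  seed = 1,
                                  active_voxels = NULL,
                                  envelopes = default_envelopes(spec),
                                  spec = design_spec()) {
  if (subspace_share < 0 || subspace_share > 1) {
    stop("subspace_share must lie in [0, 1]")
  }
  attrs <- c("sample", "result", "operation", "operand", "nuisance")
  amp <- c(sample = 0, result = 0, operation = 0, operand = 0, nuisance = 0)
  amp[names(amplitudes)] <- amplitudes
  if (is.null(active_voxels)) active_voxels <- seq_len(n_voxels)
  n_act <- length(active_voxels)
  if (n_act < 2) stop("need at least 2 active voxels per coded attribute")
  # check envelope causality: nothing result/cue-related before the cue
  t <- seq(0, spec$trial_length, by = .env_dt)
  for (a in c("result", "operation", "operand")) {
    if (any(envelopes[[a]][t < spec$cue_onset] != 0)) {
      stop("envelope for '", a, "' must be zero before cue_onset")
    }
  }
  conditions <- build_conditions(spec)
  geom <- level_geometry()
  n_cond <- nrow(conditions)
  with_seed(seed, {
    unit <- function(v) v / sqrt(sum(v^2))
    full <- function(w) {
      out <- numeric(n_voxels)
      out[active_voxels] <- w
      out
    }
    # orthonormal basis supply for all code components
    basis <- matrix(0, n_act, 0)
    draw <- function() {
      v <- stats::rnorm(n_act)
      if (n_act > ncol(basis) + 1) {
        v <- unit(v - basis %*% crossprod(basis, v))
        basis <<- cbind(basis, v)
      } else v <- unit(v)
      as.numeric(v)
    }
    r_geo <- ncol(geom$factor)
    B_s <- t(vapply(seq_len(r_geo), function(i) draw(), numeric(n_act)))
    B_i <- t(vapply(seq_len(r_geo), function(i) draw(), numeric(n_act)))
    B_r <- subspace_share * B_s + sqrt(1 - subspace_share^2) * B_i
    w_op <- draw()
    w_opnd <- draw()
    n_nuis <- 5L # dimensionality of the condition-identity nuisance code
    nuisance_weights <- vapply(seq_len(n_nuis), function(i) full(draw()),
                               numeric(n_voxels))
    nuisance_values <- matrix(stats::rnorm(n_cond * n_nuis),
                              n_cond, n_nuis) / sqrt(n_nuis)
    # level embeddings: condition c of value level l gets pattern
    # factor_l %*% B_attr, plus an identity component whose energy
    # equalizes the centered pattern norms across conditions
    value_patterns <- list(
      sample = matrix(0, n_cond, n_voxels),
      result = matrix(0, n_cond, n_voxels))
    identity <- list()
    for (a in c("sample", "result")) {
      lv <- match(conditions[[a]], geom$levels)
      B <- if (a == "sample") B_s else B_r
      value_patterns[[a]][, active_voxels] <- geom$factor[lv, , drop = FALSE] %*% B
      dirs <- matrix(0, n_cond, n_voxels)
      for (cc in seq_len(n_cond)) dirs[cc, active_voxels] <- draw()
      identity[[a]] <- list(energies = geom$energies[lv], directions = dirs)
    }
    weights <- list(sample = full(B_s[1, ]), result = full(B_r[1, ]),
                    operation = full(w_op), operand = full(w_opnd))
  })
  structure(list(n_voxels = n_voxels, weights = weights,
                 value_patterns = value_patterns,
                 nuisance_weights = nuisance_weights, identity = identity,
                 nuisance_values = nuisance_values,
                 envelopes = envelopes, subspace_share = subspace_share,
                 amplitudes = amp[attrs], active_voxels = active_voxels,
                 seed = seed),
            class = "coding_model")
}

# z-scored attribute values across the analyzed conditions: log numerosity
# for sample/result (so the coded magnitude is monotone in log numerosity),
# centered/scaled indicators for the categorical attributes
condition_values <- function(conditions) {
  cbind(sample = zscore(log(conditions$sample)),
        result = zscore(log(conditions$result)),
        operation = zscore(as.numeric(conditions$operation == "multiply")),
        operand = zscore(as.numeric(conditions$operand ==
                                      max(conditions$operand))))
}

# HRF-convolved attribute response over one trial, sampled at volume times
# relative to trial onset; normalized to unit peak so model amplitudes are
# peak BOLD effects
trial_responses <- function(model, spec, n_beyond = 2) {
  t_fine <- seq(0, spec$trial_length * (1 + n_beyond), by = .env_dt)
  hrf <- hrf_double_gamma(t_fine)
  lapply(model$envelopes, function(env) {
    full <- c(env, rep(0, length(t_fine) - length(env)))
    conv <- stats::convolve(full, rev(hrf), type = "open")[seq_along(t_fine)] *
      .env_dt
    conv / max(abs(conv))
  })
}

#' Simulate one BOLD run of the calculation task
#'
#' Lays out trials back to back (one per `trial_length`), draws or accepts a
#' condition sequence with the specified number of standard trials per
#' condition plus catch trials, and writes, for every trial and coded
#' attribute, `amplitude x population response to the trial's condition x
#' (envelope convolved with the HRF)` into the voxel time series — the
#' level-embedding (plus identity) response for sample/result, value times
#' gain for operation/operand, and the condition-stable nuisance code. AR(1)
#' noise, slow cosine drift and a baseline are added per voxel.
#'
#' @param spec a [design_spec()].
#' @param model a [make_voxel_population()] coding model.
#' @param noise a [noise_model()].
#' @param condition_sequence optional data frame with columns `condition`
#'   and `is_catch`; by default a seeded random order of 2 standard trials
#'   per condition plus `n_catch_per_run` catch trials (random conditions).
#' @param seed integer seed for trial order, catch SOAs, ratios and noise.
#' @param grid_shape 3-D grid dimensions; product must equal the model's
#'   voxel count.
#' @return An object of class `bold_run`: list with `data` (volumes x
#'   voxels), `tr`, `grid_shape`, `events` (one row per trial: onset,
#'   condition, is_catch, probe_onset, probe_ratio, correct_side) and `seed`.
#' @export
simulate_bold_run <- function(spec, model, noise = noise_model(),
                              condition_sequence = NULL, seed = 1,
                              grid_shape = c(model$n_voxels, 1, 1)) {
  stopifnot(inherits(spec, "design_spec"), inherits(model, "coding_model"))
  if (prod(grid_shape) != model$n_voxels) {
    stop("grid_shape product must equal the model's voxel count")
  }
  conditions <- build_conditions(spec)
  n_cond <- nrow(conditions)
  with_seed(derive_seed(seed, 1), {
    if (is.null(condition_sequence)) {
      std <- rep(conditions$condition, spec$trials_per_condition_per_run)
      cat_cond <- sample(conditions$condition, spec$n_catch_per_run,
                         replace = TRUE)
      condition_sequence <- data.frame(
        condition = c(std, cat_cond),
        is_catch = rep(c(FALSE, TRUE), c(length(std), length(cat_cond))))
      condition_sequence <-
        condition_sequence[sample(nrow(condition_sequence)), , drop = FALSE]
    }
    if (!all(condition_sequence$condition %in% conditions$condition)) {
      stop("unknown condition id in condition_sequence")
    }
    n_trials <- nrow(condition_sequence)
    onsets <- (seq_len(n_trials) - 1) * spec$trial_length
    soa <- ifelse(condition_sequence$is_catch,
                  stats::runif(n_trials, spec$catch_soa_range[1],
                               spec$catch_soa_range[2]),
                  spec$probe_soa_standard)
    ratio <- sample(spec$probe_ratios, n_trials, replace = TRUE)
    events <- data.frame(onset = onsets,
                         condition = condition_sequence$condition,
                         is_catch = condition_sequence$is_catch,
                         probe_onset = onsets + soa,
                         probe_ratio = ratio,
                         correct_side = ifelse(ratio > 1, "larger",
                                               "smaller"))
  })
  n_vol <- ceiling(n_trials * spec$trial_length / spec$tr)
  vals <- condition_values(conditions)
  resp <- trial_responses(model, spec)
  t_vol <- (seq_len(n_vol) - 1) * spec$tr

  # per attribute: per-condition trial time basis (volumes x conditions),
  # mixed into voxels through the population response matrix
  # (conditions x voxels): threshold tuning for numerosities, value x gain
  # for the categorical attributes
  data <- matrix(0, n_vol, model$n_voxels)
  for (a in c(names(model$weights), "nuisance")) {
    if (model$amplitudes[[a]] == 0) next
    rfun <- stats::approxfun(seq(0, by = .env_dt,
                                 length.out = length(resp[[a]])),
                             resp[[a]], yleft = 0, yright = 0)
    Tb <- matrix(0, n_vol, n_cond)
    for (i in seq_len(nrow(events))) {
      ci <- match(events$condition[i], conditions$condition)
      Tb[, ci] <- Tb[, ci] + rfun(t_vol - events$onset[i])
    }
    Fw <- if (a %in% c("sample", "result")) {
      model$value_patterns[[a]] +
        sqrt(model$identity[[a]]$energies) * model$identity[[a]]$directions
    } else if (a == "nuisance") {
      model$nuisance_values %*% t(model$nuisance_weights)
    } else {
      outer(vals[, a], model$weights[[a]])
    }
    data <- data + model$amplitudes[[a]] * (Tb %*% Fw)
  }

  with_seed(derive_seed(seed, 2), {
    if (noise$drift_order > 0) {
      D <- dct_basis(n_vol, noise$drift_order)
      coefs <- matrix(stats::rnorm(noise$drift_order * model$n_voxels,
                                   sd = noise$drift_sd),
                      noise$drift_order, model$n_voxels)
      data <- data + D %*% coefs
    }
    if (noise$sigma > 0) {
      burn <- 50L
      innov <- matrix(stats::rnorm((n_vol + burn) * model$n_voxels,
                                   sd = noise$sigma *
                                     sqrt(1 - noise$ar1_rho^2)),
                      n_vol + burn, model$n_voxels)
      ar <- apply(innov, 2, function(e)
        stats::filter(e, noise$ar1_rho, method = "recursive"))
      data <- data + ar[(burn + 1):(burn + n_vol), , drop = FALSE]
    }
  })
  data <- data + noise$baseline
  structure(list(data = data, tr = spec$tr, grid_shape = grid_shape,
                 events = events, seed = seed),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("BOLD run: %d volumes x %d voxels (TR %gs, grid %s), %d trials (%d catch)\n",
              nrow(x$data), ncol(x$data), x$tr,
              paste(x$grid_shape, collapse = "x"),
              nrow(x$events), sum(x$events$is_catch)))
  invisible(x)
}

#' Simulate all runs of one subject
#'
#' @inheritParams simulate_bold_run
#' @param n_runs number of runs (defaults to the spec's).
#' @return List of [simulate_bold_run()] objects.
#' @export
simulate_subject <- function(spec, model, noise = noise_model(),
                             n_runs = spec$n_runs, seed = 1,
                             grid_shape = c(model$n_voxels, 1, 1)) {
  lapply(seq_len(n_runs), function(r)
    simulate_bold_run(spec, model, noise, seed = derive_seed(seed, r),
                      grid_shape = grid_shape))
}

#' Simulate a Weber-fraction observer in the probe comparison task
#'
#' The observer compares the probe with the internally computed result; the
#' probability of responding "larger" follows a cumulative Gaussian in log
#' probe:result ratio, `P = pnorm((log(ratio) - pse) / sigma)` with
#' `sigma = weber / qnorm(0.75)`, so `weber` is the just-noticeable
#' difference on the natural-log scale. A per-operation PSE shift
#' implements operational-momentum scenarios.
#'
#' @param weber Weber fraction (log-scale JND), > 0.
#' @param pse_shift_by_operation named numeric `c(multiply = ., divide = .)`
#'   PSE of each operation in log-ratio units.
#' @param ratios probe:result ratio set.
#' @param n_trials number of trials.
#' @param seed integer seed.
#' @return Data frame of class `behavioral_data`: per trial `operation`,
#'   `operand`, `ratio`, `response` ("smaller"/"larger"), `correct`.
#' @export
simulate_observer <- function(weber,
                              pse_shift_by_operation = c(multiply = 0,
                                                         divide = 0),
                              ratios = design_spec()$probe_ratios,
                              n_trials = 240, seed = 1) {
  if (weber <= 0) stop("weber must be positive")
  stopifnot(all(ratios > 0), n_trials >= 1)
  sigma <- weber / stats::qnorm(0.75)
  with_seed(seed, {
    operation <- sample(c("multiply", "divide"), n_trials, replace = TRUE)
    operand <- sample(c(2, 4), n_trials, replace = TRUE)
    ratio <- ratios[sample.int(length(ratios), n_trials, replace = TRUE)]
    pse <- pse_shift_by_operation[operation]
    p_larger <- stats::pnorm((log(ratio) - pse) / sigma)
    response <- ifelse(stats::runif(n_trials) < p_larger, "larger",
                       "smaller")
  })
  out <- data.frame(operation = operation, operand = operand, ratio = ratio,
                    response = response,
                    correct = (response == "larger") == (ratio > 1))
  class(out) <- c("behavioral_data", "data.frame")
  out
}

#' Representational geometry of the numerosity levels
#'
#' The four log-spaced numerosity levels (6, 12, 24, 48) are embedded as
#' points in pattern space with squared inter-level distances
#' `(d12, d13, d14, d23, d24, d34)` forming a monotone, compressively
#' saturating magnitude code: adjacent levels at graded distances,
#' far-apart levels saturating (the classic compressive number-line
#' similarity gradient). The distances and the per-condition identity
#' energies are jointly calibrated, once, so that after condition
#' centering, norm equalization and correlation-distance normalization the
#' population dissimilarity structure projects (in expectation) onto the
#' sample/result log-distance predictors and not onto the categorical
#' operation/operand predictors — the geometry is representational-
#' similarity neutral with respect to the non-numeric design factors.
#'
#' @return List with `levels`, `sq_distances`, `factor` (4 x r embedding
#'   factor, unit mean energy), `energies` (identity energies per
#'   condition of the default design, in the same units).
#' @export
level_geometry <- function() {
  levels <- c(6, 12, 24, 48)
  q <- c(d12 = 1, d13 = 3.03418, d14 = 3.03418,
         d23 = 1.36358, d24 = 3.03418, d34 = 1)
  D4 <- matrix(0, 4, 4)
  D4[lower.tri(D4)] <- c(q[1], q[2], q[3], q[4], q[5], q[6])
  D4 <- D4 + t(D4)
  H4 <- diag(4) - 1 / 4
  G4 <- -0.5 * H4 %*% D4 %*% H4
  eg <- eigen(G4, symmetric = TRUE)
  r <- sum(eg$values > 1e-9)
  A <- eg$vectors[, seq_len(r), drop = FALSE] %*%
    diag(sqrt(eg$values[seq_len(r)]), r)
  # identity energies equalizing centered condition norms for the default
  # 10-condition design (same level multiplicities for sample and result)
  conds <- build_conditions(design_spec())
  lv <- match(conds$sample, levels)
  G0 <- G4[lv, lv]
  n <- length(lv)
  H <- diag(n) - 1 / n
  N <- diag(H %*% G0 %*% H)
  e <- (max(N) - N) / (1 - 2 / n)
  # energies depend only on the condition's level (multiplicities are
  # level-symmetric); report per level so sample and result codes can map
  # them through their own condition -> level assignment
  e_lev <- e[match(seq_len(4), lv)]
  sc <- mean(diag(G0) + e) # unit mean pattern energy incl. identity
  list(levels = levels, sq_distances = q, factor = A / sqrt(sc),
       energies = e_lev / sc)
}
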