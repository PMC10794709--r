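test_that("voxel populations realize the requested code geometry", {
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  m1 <- make_voxel_population(200, subspace_share = 1, seed = 4)
  expect_equal(cosine(m1$weights$sample, m1$weights$result), 1,
               tolerance = 1e-12)
  m0 <- make_voxel_population(500, subspace_share = 0, seed = 4)
  expect_lt(abs(cosine(m0$weights$sample, m0$weights$result)), 0.1)
  mh <- make_voxel_population(300, subspace_share = 0.6, seed = 4)
  expect_equal(cosine(mh$weights$sample, mh$weights$result), 0.6,
               tolerance = 1e-12)
  for (w in m0$weights) expect_equal(sum(w^2), 1, tolerance = 1e-12)
  # determinism contract
  expect_identical(make_voxel_population(100, 0.3, seed = 9),
                   make_voxel_population(100, 0.3, seed = 9))
  expect_false(identical(make_voxel_population(100, 0.3, seed = 9)$weights,
                         make_voxel_population(100, 0.3, seed = 10)$weights))
  expect_error(make_voxel_population(100, subspace_share = 1.2),
               "subspace_share")
  # weights confined to the active region
  ma <- make_voxel_population(50, 0, seed = 1, active_voxels = 11:20)
  expect_true(all(ma$weights$sample[-(11:20)] == 0))
})

test_that("envelopes respect event causality", {
  spec <- design_spec()
  env <- default_envelopes(spec)
  t <- seq(0, spec$trial_length, by = 0.1)
  for (a in c("result", "operation", "operand")) {
    expect_true(all(env[[a]][t < spec$cue_onset] == 0))
    expect_true(all(env[[a]] >= 0))
  }
  bad <- env
  bad$result[1] <- 1 # active before the cue
  expect_error(make_voxel_population(50, 0, seed = 1, envelopes = bad),
               "cue_onset")
})

test_that("a default run has the paradigm's trial structure and length", {
  spec <- design_spec()
  model <- make_voxel_population(30, 0, seed = 2)
  run <- simulate_bold_run(spec, model, seed = 5)
  expect_equal(nrow(run$data), 240) # 24 trials x 20 s at TR 2 s (~8 min)
  ev <- run$events
  expect_equal(nrow(ev), 24)
  expect_equal(sum(!ev$is_catch), 20)
  expect_equal(sum(ev$is_catch), 4)
  expect_true(all(diff(ev$onset) > 0))
  std <- ev[!ev$is_catch, ]
  expect_equal(std$probe_onset - std$onset, rep(12, 20))
  soa <- ev$probe_onset[ev$is_catch] - ev$onset[ev$is_catch]
  expect_true(all(soa >= 5.4 & soa <= 9.6))
  expect_equal(as.vector(table(std$condition)), rep(2, 10))
  expect_true(all(ev$probe_ratio %in% spec$probe_ratios))
  # seed determinism, bit-reproducible
  expect_identical(run, simulate_bold_run(spec, model, seed = 5))
  expect_error(
    simulate_bold_run(spec, model, seed = 1,
                      condition_sequence = data.frame(condition = 99,
                                                      is_catch = FALSE)),
    "unknown condition")
})

test_that("zero signal and zero noise leave only the drift baseline", {
  spec <- design_spec()
  model <- make_voxel_population(20, 0, seed = 2,
                                 amplitudes = c(sample = 0, result = 0))
  run <- simulate_bold_run(spec, model,
                           noise_model(sigma = 0, drift_order = 0,
                                       baseline = 100), seed = 3)
  expect_equal(max(abs(run$data - 100)), 0)
})

test_that("a noiseless sample-only run is the HRF-convolved sample regressor", {
  spec <- design_spec()
  model <- make_voxel_population(12, 0, seed = 6,
                                 amplitudes = c(sample = 1.5))
  run <- simulate_bold_run(spec, model,
                           noise_model(sigma = 0, drift_order = 0,
                                       baseline = 0), seed = 7)
  # independent regressor for one voxel: sum over trials of the voxel's
  # per-condition sample-code response (level embedding plus identity
  # component) times the envelope-convolved HRF, built by direct
  # summation on a fine grid
  voxel <- which.max(abs(model$weights$sample))
  vals <- model$value_patterns$sample[, voxel] +
    sqrt(model$identity$sample$energies) *
      model$identity$sample$directions[, voxel]
  dt <- 0.01
  tf <- seq(0, 60, by = dt)
  env <- as.numeric(tf >= 0 & tf < 1.6)
  hrf <- hrf_double_gamma(tf)
  conv <- sapply(seq_along(tf), function(i)
    sum(env[1:i] * hrf[i:1]) * dt)
  conv <- conv / max(conv)
  t_vol <- (0:239) * 2
  reg <- numeric(240)
  for (i in seq_len(nrow(run$events))) {
    v <- vals[run$events$condition[i]]
    idx <- round((t_vol - run$events$onset[i]) / dt) + 1
    ok <- idx >= 1 & idx <= length(tf)
    reg[ok] <- reg[ok] + v * conv[idx[ok]]
  }
  expect_gt(abs(cor(run$data[, voxel], reg)), 0.999)
})

test_that("AR(1) noise has the requested lag-1 autocorrelation", {
  spec <- design_spec()
  model <- make_voxel_population(150, 0, seed = 1,
                                 amplitudes = c(sample = 0))
  for (rho in c(0.2, 0.5)) {
    run <- simulate_bold_run(spec, model,
                             noise_model(ar1_rho = rho, drift_order = 0),
                             seed = 11)
    x <- sweep(run$data, 2, colMeans(run$data))
    ac <- mean(sapply(seq_len(ncol(x)), function(v)
      cor(x[-1, v], x[-nrow(x), v])))
    expect_equal(ac, rho, tolerance = 0.05)
  }
})

test_that("the simulated observer follows the log-Gaussian response rule", {
  # symmetric case: ratio 1 at pse 0 responds larger half the time
  obs <- simulate_observer(0.3, ratios = 1, n_trials = 20000, seed = 2)
  expect_equal(mean(obs$response == "larger"), 0.5, tolerance = 0.02)
  # vanishing weber: responses deterministic by the sign of the log ratio
  det <- simulate_observer(1e-8, ratios = c(0.5, 2), n_trials = 500,
                           seed = 3)
  expect_true(all(det$correct))
  # closed form at the design's extreme ratio and the reported precision:
  # P(correct | ratio 2) = Phi(log 2 / sigma), sigma = weber / Phi^-1(0.75)
  obs2 <- simulate_observer(0.289, ratios = 2, n_trials = 40000, seed = 4)
  p_expect <- pnorm(log(2) * qnorm(0.75) / 0.289)
  expect_equal(mean(obs2$correct), p_expect, tolerance = 0.01)
  expect_error(simulate_observer(0), "positive")
  expect_error(simulate_observer(-1), "positive")
})
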