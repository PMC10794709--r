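test_that("FIR design has the expected regressor complement", {
  spec <- design_spec()
  model <- make_voxel_population(10, 0, seed = 1)
  run <- simulate_bold_run(spec, model, seed = 1)
  des <- build_fir_design(run$events, spec)
  # 11 conditions (10 + pooled catch) x 10 bins + run constant + 3 drift
  expect_equal(ncol(des$matrix), 110 + 1 + 3)
  expect_equal(sum(des$labels$type == "condition"), 100)
  expect_equal(sum(des$labels$type == "catch"), 10)
  expect_equal(sum(des$labels$type == "drift"), 3)
  # sticks are 0/1 and abut without overlap: every volume covered once,
  # which aliases the run constant (flagged) but leaves the stick + drift
  # design well conditioned
  sticks <- des$matrix[, des$labels$type %in% c("condition", "catch")]
  expect_true(all(sticks %in% c(0, 1)))
  expect_equal(rowSums(sticks), rep(1, 240))
  expect_true(des$labels$aliased[des$labels$type == "intercept"])
  Xk <- des$matrix[, !des$labels$aliased]
  expect_true(is.finite(kappa(Xk, exact = TRUE)))
  # empty event table: only nuisance columns remain
  e0 <- data.frame(onset = numeric(0), condition = integer(0),
                   is_catch = logical(0))
  d0 <- build_fir_design(e0, spec, n_volumes = 240)
  expect_true(all(d0$labels$type %in% c("drift", "intercept")))
})

test_that("collinear confounds are rejected with their names", {
  spec <- design_spec()
  run <- simulate_bold_run(spec, make_voxel_population(5, 0, seed = 1),
                           seed = 1)
  cf <- cbind(a = sin(1:240), b = sin(1:240)) # duplicated column
  expect_error(build_fir_design(run$events, spec, confounds = cf),
               "collinear.*confound")
})

test_that("OLS recovers injected bin amplitudes exactly without noise", {
  spec <- design_spec()
  run <- simulate_bold_run(spec, make_voxel_population(8, 0, seed = 3),
                           seed = 3)
  des <- build_fir_design(run$events, spec)
  keep <- !des$labels$aliased
  set.seed(42)
  true_beta <- matrix(rnorm(sum(keep) * 8), sum(keep), 8)
  Y <- des$matrix[, keep] %*% true_beta
  fit <- fit_fir(Y, des)
  lab <- des$labels[keep, ]
  for (j in which(lab$type == "condition")) {
    expect_equal(fit$estimates[lab$condition[j], lab$bin[j], ],
                 true_beta[j, ], tolerance = 1e-8)
  }
  # and equals an explicit normal-equations solve
  X <- des$matrix[, keep]
  oracle <- solve(t(X) %*% X, t(X) %*% Y)
  got <- rbind(matrix(aperm(fit$estimates, c(2, 1, 3)), 100, 8),
               fit$catch, fit$nuisance)
  reorder <- order(c(which(lab$type == "condition"),
                     which(lab$type == "catch"),
                     which(!lab$type %in% c("condition", "catch"))))
  expect_equal(max(abs(got[reorder, ] - oracle)), 0, tolerance = 1e-10)
})

test_that("pure-noise betas shrink as one over sqrt volumes", {
  spec <- design_spec()
  conds <- default_conditions
  mean_abs_beta <- function(n_rep, seed) {
    # n_rep standard passes per condition in one long run
    seq_cond <- data.frame(condition = rep(conds$condition, n_rep),
                           is_catch = FALSE)
    mb <- numeric(30)
    for (s in 1:30) {
      set.seed(seed + s)
      seq_cond <- seq_cond[sample(nrow(seq_cond)), , drop = FALSE]
      ev <- data.frame(onset = (seq_len(nrow(seq_cond)) - 1) * 20,
                       condition = seq_cond$condition,
                       is_catch = FALSE)
      des <- build_fir_design(ev, spec)
      Y <- matrix(rnorm(nrow(des$matrix) * 4), ncol = 4)
      fit <- fit_fir(Y, des)
      mb[s] <- mean(abs(fit$estimates))
    }
    mean(mb)
  }
  m2 <- mean_abs_beta(2, 100)
  m8 <- mean_abs_beta(8, 200)
  # 4x the volumes -> half the noise on each estimate
  expect_equal(m8 / m2, 0.5, tolerance = 0.1)
})

test_that("per-run estimates average to the concatenated estimates", {
  spec <- design_spec(n_runs = 6)
  model <- make_voxel_population(40, 0, seed = 5)
  runs <- simulate_subject(spec, model, noise_model(sigma = 0.5), seed = 6)
  events <- lapply(runs, `[[`, "events")
  concat <- fit_fir(runs, build_fir_design(events, spec))
  per_run <- fit_fir(runs, build_fir_design(events, spec, mode = "per_run"))
  expect_length(per_run, 6)
  expect_equal(vapply(per_run, `[[`, numeric(1), "run"), 1:6)
  avg <- Reduce(`+`, lapply(per_run, `[[`, "estimates")) / 6
  expect_gt(cor(as.vector(avg), as.vector(concat$estimates)), 0.98)
  expect_lt(mean(abs(avg - concat$estimates)), 0.15)
})

test_that("slow signals are removed by the drift model", {
  # a sinusoid slower than the 244 s cutoff is >= 90% attenuated once the
  # design's drift columns are projected out
  spec <- design_spec()
  run <- simulate_bold_run(spec, make_voxel_population(5, 0, seed = 1),
                           seed = 1)
  des <- build_fir_design(run$events, spec)
  drift <- cbind(1, des$matrix[, des$labels$type == "drift"])
  t <- (0:239) * 2
  y <- sin(2 * pi * t / 480)
  res <- y - drift %*% qr.coef(qr(drift), y)
  expect_gte(1 - var(res) / var(y), 0.9)
})

test_that("non-finite data and size mismatches are explicit errors", {
  spec <- design_spec()
  run <- simulate_bold_run(spec, make_voxel_population(5, 0, seed = 1),
                           seed = 1)
  des <- build_fir_design(run$events, spec)
  bad <- run$data
  bad[17, 3] <- NaN
  expect_error(fit_fir(bad, des), "volume 17, voxel 3")
  expect_error(fit_fir(run$data[1:100, ], des), "rows")
})

test_that("AR(1) prewhitening leaves estimates essentially unchanged", {
  spec <- design_spec()
  model <- make_voxel_population(20, 0, seed = 8)
  run <- simulate_bold_run(spec, model, noise_model(ar1_rho = 0.4),
                           seed = 9)
  des <- build_fir_design(run$events, spec)
  f0 <- fit_fir(run, des)
  f1 <- fit_fir(run, des, ar1 = TRUE)
  expect_gt(cor(as.vector(f0$estimates), as.vector(f1$estimates)), 0.95)
})
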