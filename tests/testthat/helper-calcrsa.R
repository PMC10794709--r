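# shared fixtures for the calcrsa suite; everything is generated in code

default_conditions <- build_conditions(design_spec())
default_predictors <- build_predictor_rdms(default_conditions)

# simulate one subject and return concatenated and per-run FIR fits
quick_subject <- function(seed, n_voxels = 60, n_runs = 4,
                          subspace_share = 0,
                          amplitudes = c(sample = 2, result = 2),
                          sigma = 1, per_run = FALSE,
                          spec = design_spec(n_runs = n_runs)) {
  model <- make_voxel_population(n_voxels, subspace_share, amplitudes,
                                 seed = derive_seed(seed, 1), spec = spec)
  runs <- simulate_subject(spec, model, noise_model(sigma = sigma),
                           seed = derive_seed(seed, 2))
  events <- lapply(runs, `[[`, "events")
  if (per_run) {
    fit_fir(runs, build_fir_design(events, spec, mode = "per_run"))
  } else {
    fit_fir(runs, build_fir_design(events, spec))
  }
}

# synthetic per-run FIR fits with a known linear numerosity code:
# pattern(cond, bin, voxel) = gain[bin] * label[cond] * w[voxel] + noise
fake_run_fits <- function(n_runs = 4, n_voxels = 40, seed = 1,
                          gain_sample = rep(1, 10), gain_result = rep(0, 10),
                          noise_sd = 0, share = 1) {
  conditions <- default_conditions
  ls <- zscore_test(log(conditions$sample))
  lr <- zscore_test(log(conditions$result))
  set.seed(seed)
  ws <- rnorm(n_voxels); ws <- ws / sqrt(sum(ws^2))
  u <- rnorm(n_voxels); u <- u - sum(u * ws) * ws; u <- u / sqrt(sum(u^2))
  wr <- share * ws + sqrt(1 - share^2) * u
  structure(lapply(seq_len(n_runs), function(r) {
    est <- array(0, c(10, 10, n_voxels))
    for (b in 1:10) {
      est[, b, ] <- gain_sample[b] * outer(ls, ws) +
        gain_result[b] * outer(lr, wr) +
        matrix(rnorm(10 * n_voxels, sd = noise_sd), 10, n_voxels)
    }
    structure(list(estimates = est, conditions = conditions,
                   mode = "per_run", run = r),
              class = "fir_fit")
  }), class = "fir_fit_list")
}

# independent z-score used by test oracles
zscore_test <- function(x) (x - mean(x)) / sd(x)
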