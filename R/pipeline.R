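#' Voxel indices of a cubic region of interest
#'
#' Linear indices (in `which(mask)` order of a full-grid mask) of an
#' axis-aligned cube, used to embed coding populations and define analysis
#' ROIs on the synthetic grid.
#'
#' @param grid_shape 3-D grid dimensions.
#' @param side cube side length in voxels.
#' @param center cube center (defaults to the grid center).
#' @return Integer vector of linear voxel indices.
#' @export
cube_roi <- function(grid_shape, side = 5,
                     center = ceiling(grid_shape / 2)) {
  h <- c(floor((side - 1) / 2), ceiling((side - 1) / 2))
  rng <- function(d) max(1, center[d] - h[1]):min(grid_shape[d],
                                                  center[d] + h[2])
  g <- expand.grid(x = rng(1), y = rng(2), z = rng(3))
  as.integer(g$x + (g$y - 1) * grid_shape[1] +
               (g$z - 1) * grid_shape[1] * grid_shape[2])
}

#' Configuration of the end-to-end synthetic pipeline
#'
#' Collects every parameter of a simulate-analyze cycle; all randomness
#' derives from the single `seed`. The constructor rejects unknown keys, so
#' configurations round-trip unchanged through [write_config()] /
#' [read_config()].
#'
#' @param n_subjects cohort size.
#' @param n_runs runs per subject.
#' @param grid_shape 3-D voxel grid.
#' @param roi_side side of the central cubic coding region / analysis ROI.
#' @param subspace_share sample/result code sharing, see
#'   [make_voxel_population()].
#' @param amplitudes named attribute effect sizes (signal units).
#' @param ar1_rho,sigma,drift_order,drift_sd,baseline noise parameters, see
#'   [noise_model()].
#' @param weber,weber_sd mean and between-subject SD of the behavioral
#'   Weber fraction.
#' @param pse_shift_multiply,pse_shift_divide operation-wise PSE shifts
#'   (log-ratio units).
#' @param behavior_trials behavioral trials per subject.
#' @param n_perm cluster-permutation count.
#' @param fdr_q FDR level.
#' @param radius searchlight radius (voxels).
#' @param searchlight run the searchlight + cluster permutation stage (the
#'   slowest stage; ROI statistics are always computed).
#' @param seed master seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 17, n_runs = 6,
                            grid_shape = c(20, 20, 20), roi_side = 5,
                            subspace_share = 0,
                            amplitudes = c(sample = 1.2, result = 2,
                                           operation = 0, operand = 0,
                                           nuisance = 1.5),
                            ar1_rho = 0.3, sigma = 1, drift_order = 3,
                            drift_sd = 0.5, baseline = 100,
                            weber = 0.29, weber_sd = 0.05,
                            pse_shift_multiply = 0, pse_shift_divide = 0,
                            behavior_trials = 240,
                            n_perm = 200, fdr_q = 0.05, radius = 3,
                            searchlight = FALSE, seed = 1) {
  cfg <- as.list(environment())
  cfg$grid_shape <- as.integer(grid_shape)
  cfg$amplitudes <- unlist(amplitudes)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("Pipeline config: %d subjects x %d runs, grid %s, ROI side %d, share %.2f, seed %d\n",
              x$n_subjects, x$n_runs, paste(x$grid_shape, collapse = "x"),
              x$roi_side, x$subspace_share, x$seed))
  invisible(x)
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes simulate -> FIR GLM -> ROI RSA (windowed, with group t tests
#' and FDR) -> sample/result cross-decoding -> psychometrics (JND/Weber,
#' PSE, operational momentum) -> brain-behavior correlation, and optionally
#' a searchlight RSA with sign-flip cluster permutation on the
#' middle-window sample map. Deterministic given the configuration: the
#' same config yields a byte-identical summary.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional directory; when given, writes `summary.json`,
#'   long-format TSV tables of ROI effects, decoding scores and
#'   psychometric fits, and a log with seeds and package version.
#' @return Object of class `calc_pipeline` with elements `config`,
#'   `rsa` (per-subject window betas + group table), `decoding`,
#'   `behavior`, `brain_behavior`, `clusters` (if searchlight), `summary`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  spec <- design_spec(n_runs = config$n_runs)
  conditions <- build_conditions(spec)
  predictors <- build_predictor_rdms(conditions)
  n_vox <- prod(config$grid_shape)
  roi <- cube_roi(config$grid_shape, config$roi_side)
  noise <- noise_model(config$ar1_rho, config$sigma, config$drift_order,
                       config$drift_sd, config$baseline)
  nS <- config$n_subjects
  preds <- names(predictors$matrices)
  windows <- c("early", "middle", "late")

  window_betas <- array(NA_real_, c(nS, length(preds), length(windows)),
                        dimnames = list(NULL, preds, windows))
  scores <- numeric(nS)
  webers_true <- numeric(nS)
  weber_hat <- numeric(nS)
  pse_div <- numeric(nS)
  pse_mul <- numeric(nS)
  maps_mid <- if (config$searchlight) vector("list", nS) else NULL

  for (s in seq_len(nS)) {
    sseed <- derive_seed(config$seed, s)
    model <- make_voxel_population(n_vox, config$subspace_share,
                                   config$amplitudes,
                                   seed = derive_seed(sseed, 11),
                                   active_voxels = roi, spec = spec)
    runs <- simulate_subject(spec, model, noise, seed = derive_seed(sseed, 12),
                             grid_shape = config$grid_shape)
    design <- build_fir_design(lapply(runs, `[[`, "events"), spec)
    fit <- fit_fir(runs, design)
    eff <- rsa_effects(fit, predictors, voxels = roi, bins = 1:6)
    window_betas[s, , ] <- window_average(eff)

    run_designs <- build_fir_design(lapply(runs, `[[`, "events"), spec,
                                    mode = "per_run")
    run_fits <- fit_fir(runs, run_designs)
    scores[s] <- cross_decoding(run_fits, voxels = roi)

    if (config$searchlight) {
      mask <- array(TRUE, config$grid_shape)
      sl <- searchlight_rsa(fit, mask, predictors,
                            radius = config$radius, bins = 3:4)
      maps_mid[[s]] <- apply(sl$beta[, , , which(preds == "sample"), ,
                                     drop = FALSE],
                             1:3, mean)
    }

    webers_true[s] <- max(0.05, with_seed(derive_seed(sseed, 13),
                                          stats::rnorm(1, config$weber,
                                                       config$weber_sd)))
    obs <- simulate_observer(webers_true[s],
                             c(multiply = config$pse_shift_multiply,
                               divide = config$pse_shift_divide),
                             ratios = spec$probe_ratios,
                             n_trials = config$behavior_trials,
                             seed = derive_seed(sseed, 14))
    weber_hat[s] <- fit_psychometric(obs)$jnd
    pse_div[s] <- fit_psychometric(obs, "divide")$pse
    pse_mul[s] <- fit_psychometric(obs, "multiply")$pse
  }

  # group RSA table with FDR over the predictor x window family
  grid <- expand.grid(predictor = preds, window = windows,
                      stringsAsFactors = FALSE)
  gt <- lapply(seq_len(nrow(grid)), function(i)
    group_onesample_t(window_betas[, grid$predictor[i], grid$window[i]]))
  rsa_group <- data.frame(grid,
                          mean_beta = vapply(gt, `[[`, numeric(1), "mean"),
                          t = vapply(gt, `[[`, numeric(1), "t"),
                          df = nS - 1,
                          p = vapply(gt, `[[`, numeric(1), "p"))
  fdr <- bh_fdr(rsa_group$p, config$fdr_q)
  rsa_group$p_fdr <- fdr$p_adjusted
  rsa_group$significant <- fdr$reject

  dec_t <- group_onesample_t(scores)
  om <- operational_momentum(pse_div, pse_mul)
  bb <- brain_behavior_correlation(scores, weber_hat, config$fdr_q)

  clusters <- NULL
  if (config$searchlight) {
    clusters <- cluster_permutation(maps_mid, n_perm = config$n_perm,
                                    seed = derive_seed(config$seed, 31))
  }

  summary <- list(
    n_subjects = nS, df = nS - 1,
    rsa_group = rsa_group,
    cross_decoding = list(mean_score = mean(scores), t = dec_t$t,
                          df = dec_t$df, p = dec_t$p),
    behavior = list(mean_weber = mean(weber_hat),
                    operational_momentum = unclass(om)),
    brain_behavior = bb,
    clusters = if (!is.null(clusters)) clusters$clusters,
    seed = config$seed)

  out <- structure(list(config = config,
                        rsa = list(window_betas = window_betas,
                                   group = rsa_group),
                        decoding = list(scores = scores, group = dec_t),
                        behavior = list(weber = weber_hat,
                                        weber_true = webers_true,
                                        pse_division = pse_div,
                                        pse_multiplication = pse_mul,
                                        momentum = om),
                        brain_behavior = bb,
                        clusters = clusters,
                        summary = summary),
                   class = "calc_pipeline")
  if (!is.null(outdir)) write_pipeline(out, outdir)
  out
}

write_pipeline <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(result$summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, dataframe = "rows")
  utils::write.table(result$rsa$group, file.path(outdir, "rsa_group.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  nS <- result$config$n_subjects
  long <- data.frame(subject = seq_len(nS),
                     score = result$decoding$scores,
                     weber = result$behavior$weber,
                     pse_division = result$behavior$pse_division,
                     pse_multiplication = result$behavior$pse_multiplication)
  utils::write.table(long, file.path(outdir, "subjects.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(c(sprintf("calcrsa %s",
                       as.character(utils::packageVersion("calcrsa"))),
               sprintf("seed %d", result$config$seed),
               sprintf("R %s", as.character(getRversion()))),
             file.path(outdir, "log.txt"))
  invisible(outdir)
}

#' @export
print.calc_pipeline <- function(x, ...) {
  cat(sprintf("calcrsa pipeline: %d subjects (group df = %d)\n",
              x$summary$n_subjects, x$summary$df))
  cat("\nROI RSA group effects (window means):\n")
  print(x$rsa$group, row.names = FALSE, digits = 3)
  cat(sprintf("\nCross-decoding: mean z = %.3f, t(%d) = %.2f, p = %.3g\n",
              x$summary$cross_decoding$mean_score,
              x$summary$cross_decoding$df, x$summary$cross_decoding$t,
              x$summary$cross_decoding$p))
  cat(sprintf("Behavior: mean Weber %.3f; ", x$summary$behavior$mean_weber))
  print(x$behavior$momentum)
  bb <- x$brain_behavior
  cat(sprintf("Brain-behavior: r = %.2f, p = %.3g%s\n", bb$r[1], bb$p[1],
              if (bb$significant[1]) " *" else ""))
  if (!is.null(x$clusters)) {
    cat("\n")
    print(x$clusters)
  }
  invisible(x)
}
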