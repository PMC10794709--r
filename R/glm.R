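#' Discrete cosine drift basis
#'
#' Non-constant discrete cosine transform components, the standard basis for
#' modeling slow scanner drift. Component `k` has `k` half-cycles over the
#' run; amplitudes are 1.
#'
#' @param n number of time points.
#' @param K number of components.
#' @return `n x K` matrix (0 columns when `K = 0`).
#' @export
dct_basis <- function(n, K) {
  if (K <= 0) return(matrix(0, n, 0))
  t <- 0:(n - 1)
  sapply(seq_len(K), function(k) cos(pi * (2 * t + 1) * k / (2 * n)))
}

# number of non-constant DCT components for a high-pass cutoff (s)
n_drift_terms <- function(duration, cutoff) {
  max(0L, as.integer(floor(2 * duration / cutoff + 1)) - 1L)
}

#' Build a finite-impulse-response design matrix
#'
#' One 0/1 stick regressor per analyzed condition and FIR bin, aligned to
#' `trial onset + (bin - 1) * bin width` and sampled at the TR; catch trials
#' are pooled into their own condition with the same bin structure. Slow
#' drift is modeled per run by a discrete cosine basis with a 244 s cutoff,
#' and each run gets its own constant. Arbitrary confound columns (e.g.
#' motion parameters) can be appended.
#'
#' When the FIR window equals the trial spacing the condition sticks of a
#' run sum to that run's constant; this structural aliasing is detected and
#' recorded (the constant is dropped at fit time, baseline being absorbed
#' into the FIR estimates, which is immaterial after the pattern centering
#' applied downstream). Any other collinearity is an error naming the
#' collinear columns.
#'
#' @param events a single event table or list of per-run event tables (data
#'   frames with `onset`, `condition`, `is_catch`), as produced by
#'   [simulate_bold_run()].
#' @param spec a [design_spec()].
#' @param n_volumes volumes per run (recycled); default: trials x trial
#'   length / TR.
#' @param confounds optional matrix (or per-run list) of confound columns.
#' @param mode `"concatenated"` (one design spanning all runs, one constant
#'   per run) or `"per_run"` (a list of independent single-run designs).
#' @param drift_cutoff high-pass cutoff in seconds.
#' @return Object of class `fir_design`: `matrix`, `labels` (one row per
#'   column: `type` in condition/catch/confound/drift/intercept, `condition`,
#'   `bin`, `run`, `aliased`), `mode`, `n_volumes`; in `per_run` mode a list
#'   of such objects (class `fir_design_list`).
#' @export
build_fir_design <- function(events, spec = design_spec(), n_volumes = NULL,
                             confounds = NULL,
                             mode = c("concatenated", "per_run"),
                             drift_cutoff = 244) {
  mode <- match.arg(mode)
  if (is.data.frame(events)) events <- list(events)
  events <- lapply(events, function(e) {
    if (inherits(e, "bold_run")) e$events else e
  })
  n_runs <- length(events)
  if (is.null(n_volumes)) {
    n_volumes <- vapply(events, function(e) {
      if (nrow(e) == 0) return(as.integer(spec$trial_length / spec$tr))
      as.integer(ceiling((max(e$onset) + spec$trial_length) / spec$tr))
    }, integer(1))
  } else {
    n_volumes <- rep_len(as.integer(n_volumes), n_runs)
  }
  if (!is.null(confounds) && !is.list(confounds)) {
    confounds <- rep(list(confounds), n_runs)
  }

  if (mode == "per_run") {
    out <- lapply(seq_len(n_runs), function(r)
      build_fir_design(events[r], spec, n_volumes[r],
                       if (!is.null(confounds)) confounds[r],
                       mode = "concatenated", drift_cutoff = drift_cutoff))
    for (r in seq_len(n_runs)) {
      out[[r]]$mode <- "per_run"
      out[[r]]$run <- r
    }
    class(out) <- "fir_design_list"
    return(out)
  }

  conditions <- build_conditions(spec)
  n_cond <- nrow(conditions)
  nb <- spec$n_fir_bins
  cond_ids <- c(conditions$condition, 0L) # 0 = pooled catch condition

  blocks <- list()
  labels <- list()
  run_offsets <- c(0L, cumsum(n_volumes))
  total_vol <- sum(n_volumes)

  # condition x bin sticks spanning all runs
  sticks <- matrix(0, total_vol, (n_cond + 1L) * nb)
  for (r in seq_len(n_runs)) {
    ev <- events[[r]]
    if (nrow(ev) == 0) next
    for (i in seq_len(nrow(ev))) {
      ci <- if (ev$is_catch[i]) n_cond + 1L else match(ev$condition[i],
                                                       conditions$condition)
      if (is.na(ci)) stop("unknown condition id: ", ev$condition[i])
      for (k in seq_len(nb)) {
        t <- ev$onset[i] + (k - 1) * spec$tr
        v <- as.integer(round(t / spec$tr)) + 1L
        if (v >= 1 && v <= n_volumes[r]) {
          row <- run_offsets[r] + v
          col <- (ci - 1L) * nb + k
          sticks[row, col] <- sticks[row, col] + 1
        }
      }
    }
  }
  stick_labels <- data.frame(
    type = rep(c(rep("condition", n_cond), "catch"), each = nb),
    condition = rep(cond_ids, each = nb),
    bin = rep(seq_len(nb), n_cond + 1L),
    run = NA_integer_)
  # drop all-zero sticks (conditions absent from the events, e.g. empty runs)
  nz <- colSums(abs(sticks)) > 0
  blocks$sticks <- sticks[, nz, drop = FALSE]
  labels$sticks <- stick_labels[nz, , drop = FALSE]

  if (!is.null(confounds)) {
    cf <- do.call(rbind, lapply(confounds, as.matrix))
    stopifnot(nrow(cf) == total_vol)
    blocks$confounds <- cf
    labels$confounds <- data.frame(type = "confound", condition = NA,
                                   bin = NA, run = NA_integer_)[
                                     rep(1, ncol(cf)), , drop = FALSE]
  }

  for (r in seq_len(n_runs)) {
    K <- n_drift_terms(n_volumes[r] * spec$tr, drift_cutoff)
    if (K > 0) {
      D <- matrix(0, total_vol, K)
      D[(run_offsets[r] + 1):run_offsets[r + 1], ] <- dct_basis(n_volumes[r], K)
      blocks[[paste0("drift", r)]] <- D
      labels[[paste0("drift", r)]] <-
        data.frame(type = "drift", condition = NA, bin = seq_len(K), run = r)
    }
  }
  for (r in seq_len(n_runs)) {
    ic <- matrix(0, total_vol, 1)
    ic[(run_offsets[r] + 1):run_offsets[r + 1], 1] <- 1
    blocks[[paste0("const", r)]] <- ic
    labels[[paste0("const", r)]] <-
      data.frame(type = "intercept", condition = NA, bin = NA, run = r)
  }

  X <- do.call(cbind, blocks)
  lab <- do.call(rbind, labels)
  rownames(lab) <- NULL
  lab$aliased <- FALSE

  # structural aliasing: run constant equals the sum of that run's sticks
  # whenever the FIR windows tile the run exactly
  stick_cols <- which(lab$type %in% c("condition", "catch"))
  for (r in seq_len(n_runs)) {
    rows <- (run_offsets[r] + 1):run_offsets[r + 1]
    covered <- rowSums(X[rows, stick_cols, drop = FALSE])
    if (all(covered == 1)) {
      lab$aliased[lab$type == "intercept" & lab$run == r] <- TRUE
    }
  }
  keep <- !lab$aliased
  rk <- qr(X[, keep, drop = FALSE])$rank
  if (rk < sum(keep)) {
    # identify offenders (error path; cost immaterial)
    bad <- character(0)
    idx <- integer(0)
    for (j in which(keep)) {
      trial <- c(idx, j)
      if (qr(X[, trial, drop = FALSE])$rank < length(trial)) {
        bad <- c(bad, column_name(lab[j, ]))
      } else idx <- trial
    }
    stop("rank-deficient FIR design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  structure(list(matrix = X, labels = lab, mode = "concatenated",
                 n_volumes = n_volumes, spec = spec,
                 bin_width = spec$tr, n_bins = nb),
            class = "fir_design")
}

column_name <- function(lab_row) {
  switch(lab_row$type,
         condition = sprintf("cond%d_bin%d", lab_row$condition, lab_row$bin),
         catch = sprintf("catch_bin%d", lab_row$bin),
         drift = sprintf("drift%d_run%d", lab_row$bin, lab_row$run),
         intercept = sprintf("const_run%d", lab_row$run),
         "confound")
}

#' @export
print.fir_design <- function(x, ...) {
  tab <- table(x$labels$type)
  cat(sprintf("FIR design: %d volumes x %d regressors (%s)\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  if (any(x$labels$aliased))
    cat("  ", sum(x$labels$aliased),
        "run constant(s) aliased with the FIR sticks (dropped at fit)\n")
  invisible(x)
}

#' Fit the FIR general linear model
#'
#' Ordinary least squares per voxel. Columns flagged as structurally aliased
#' in the design (run constants when the FIR sticks tile the run) are
#' excluded from the solve. Optional AR(1) prewhitening with a single rho
#' pooled over voxels, estimated from the OLS residuals, is available but
#' off by default (OLS estimates are unbiased and the downstream contracts
#' do not depend on whitening).
#'
#' @param runs a `bold_run`, a list of them, or a volumes x voxels matrix.
#' @param design a [build_fir_design()] result (or, for per-run fitting, a
#'   `fir_design_list`; then `runs` must be the matching list of runs and a
#'   list of fits is returned).
#' @param ar1 logical; prewhiten with a pooled AR(1) coefficient.
#' @return Object of class `fir_fit`: `estimates` (condition x bin x voxel
#'   array over the analyzed conditions), `catch` (bin x voxel), `nuisance`
#'   (remaining coefficients), `mode`, `run` (per-run fits), `sigma2`
#'   (residual variance per voxel), `df_residual`.
#' @export
fit_fir <- function(runs, design, ar1 = FALSE) {
  if (inherits(design, "fir_design_list")) {
    stopifnot(is.list(runs), length(runs) == length(design))
    return(structure(lapply(seq_along(runs), function(r) {
      f <- fit_fir(runs[[r]], design[[r]], ar1 = ar1)
      f$mode <- "per_run"
      f$run <- design[[r]]$run
      f
    }), class = "fir_fit_list"))
  }
  Y <- if (is.list(runs) && !inherits(runs, "bold_run")) {
    do.call(rbind, lapply(runs, function(x)
      if (inherits(x, "bold_run")) x$data else x))
  } else if (inherits(runs, "bold_run")) runs$data else runs
  X <- design$matrix
  if (nrow(Y) != nrow(X)) stop("design rows must equal total volumes")
  bad <- which(!is.finite(Y))
  if (length(bad)) {
    ij <- arrayInd(bad[1], dim(Y))
    stop(sprintf("non-finite data at volume %d, voxel %d", ij[1], ij[2]))
  }
  keep <- !design$labels$aliased
  Xk <- X[, keep, drop = FALSE]
  if (ar1) {
    cf0 <- qr.coef(qr(Xk), Y)
    res <- Y - Xk %*% cf0
    num <- sum(res[-1, ] * res[-nrow(res), ])
    rho <- num / sum(res[-nrow(res), ]^2)
    Wf <- function(M) rbind(M[1, ] * sqrt(1 - rho^2),
                            M[-1, ] - rho * M[-nrow(M), ])
    Xk <- Wf(Xk)
    Y <- Wf(Y)
  }
  qrx <- qr(Xk)
  coefs <- qr.coef(qrx, Y)
  res <- qr.resid(qrx, Y)
  dfres <- nrow(Y) - qrx$rank
  lab <- design$labels[keep, , drop = FALSE]

  conditions <- build_conditions(design$spec)
  n_cond <- nrow(conditions)
  nb <- design$n_bins
  nvox <- ncol(Y)
  est <- array(0, c(n_cond, nb, nvox),
               dimnames = list(condition = conditions$condition,
                               bin = seq_len(nb), voxel = NULL))
  for (j in which(lab$type == "condition")) {
    est[match(lab$condition[j], conditions$condition), lab$bin[j], ] <-
      coefs[j, ]
  }
  catch <- matrix(0, nb, nvox)
  for (j in which(lab$type == "catch")) catch[lab$bin[j], ] <- coefs[j, ]
  structure(list(estimates = est, catch = catch,
                 nuisance = coefs[!(lab$type %in% c("condition", "catch")), ,
                                  drop = FALSE],
                 conditions = conditions, mode = design$mode, run = NA,
                 sigma2 = colSums(res^2) / max(dfres, 1),
                 df_residual = dfres, ar1 = ar1),
            class = "fir_fit")
}

#' @export
print.fir_fit <- function(x, ...) {
  d <- dim(x$estimates)
  cat(sprintf("FIR fit (%s%s): %d conditions x %d bins x %d voxels, residual df %d\n",
              x$mode, if (!is.na(x$run)) paste0(", run ", x$run) else "",
              d[1], d[2], d[3], x$df_residual))
  invisible(x)
}
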