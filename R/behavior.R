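#' Fit a psychometric function to probe-comparison responses
#'
#' Maximum-likelihood fit of a cumulative Gaussian in log probe:result
#' ratio, `P(larger) = lapse + (1 - 2 lapse) * pnorm((log ratio - pse) /
#' sigma)`, under a binomial likelihood per ratio. The fit is deterministic:
#' a fixed grid of starting values feeds a bounded quasi-Newton optimizer.
#' `lapse` is fixed at 0 by default. The just-noticeable difference is
#' `jnd = sigma * qnorm(0.75)`, the Weber fraction on the log scale.
#'
#' Perfect separation drives `sigma` to its floor and non-informative data
#' (all ratios at chance) to its ceiling; both cases are flagged as
#' boundary fits with a warning.
#'
#' @param data a `behavioral_data` frame (see [simulate_observer()]) with
#'   columns `ratio` and `response`, optionally `operation`.
#' @param operation `"pooled"` or a single operation to filter on.
#' @param lapse_free free the lapse rate (in [0, 0.5)) instead of fixing 0.
#' @param sigma_floor,sigma_ceiling bounds on sigma (log-ratio units).
#' @return Object of class `psychfit` with elements `pse`, `sigma`, `jnd`,
#'   `lapse`, `n_trials`, `log_likelihood`, `operation`, `boundary`.
#' @examples
#' obs <- simulate_observer(weber = 0.29, n_trials = 2000, seed = 7)
#' fit <- fit_psychometric(obs)
#' jnd_weber(fit)
#' @export
fit_psychometric <- function(data, operation = "pooled",
                             lapse_free = FALSE,
                             sigma_floor = 1e-3, sigma_ceiling = 25) {
  if (operation != "pooled") {
    data <- data[data$operation == operation, , drop = FALSE]
  }
  if (nrow(data) == 0) stop("no trials after filtering")
  k <- tapply(data$response == "larger", data$ratio, sum)
  n <- tapply(rep(1L, nrow(data)), data$ratio, sum)
  agg <- data.frame(ratio = as.numeric(names(k)), k = as.numeric(k),
                    n = as.numeric(n))
  if (nrow(agg) < 2) stop("need responses at >= 2 distinct ratios")
  lr <- log(agg$ratio)
  nll <- function(par) {
    pse <- par[1]
    sigma <- exp(par[2])
    lapse <- if (lapse_free) stats::plogis(par[3]) * 0.5 else 0
    p <- lapse + (1 - 2 * lapse) * stats::pnorm((lr - pse) / sigma)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(agg$k * log(p) + (agg$n - agg$k) * log(1 - p))
  }
  starts <- expand.grid(pse = c(-0.2, 0, 0.2),
                        lsig = log(c(0.1, 0.3, 0.8)),
                        lap = if (lapse_free) c(-4, -2) else 0)
  lb <- c(-2, log(sigma_floor), if (lapse_free) -10)
  ub <- c(2, log(sigma_ceiling), if (lapse_free) 3)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- as.numeric(starts[i, seq_along(lb)])
    fit <- tryCatch(
      stats::optim(p0, nll, method = "L-BFGS-B", lower = lb, upper = ub),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
      best <- fit
    }
  }
  if (is.null(best)) stop("psychometric optimization failed")
  sigma <- exp(best$par[2])
  separated <- all(agg$k == 0 | agg$k == agg$n)
  if (separated) sigma <- sigma_floor # likelihood flat below the floor
  boundary <- separated || sigma <= sigma_floor * (1 + 1e-6) ||
    sigma >= sigma_ceiling * (1 - 1e-6)
  if (boundary) {
    warning("sigma estimate at its ", if (sigma <= sigma_floor * 2)
      "floor (perfect separation)" else "ceiling (non-informative data)",
      "; fit flagged as boundary")
  }
  structure(list(pse = best$par[1], sigma = sigma,
                 jnd = sigma * stats::qnorm(0.75),
                 lapse = if (lapse_free) stats::plogis(best$par[3]) * 0.5
                         else 0,
                 n_trials = sum(agg$n),
                 log_likelihood = -best$value,
                 operation = operation, boundary = boundary,
                 ratios = agg$ratio, k = agg$k, n = agg$n),
            class = "psychfit")
}

#' @export
print.psychfit <- function(x, ...) {
  cat(sprintf("Psychometric fit (%s, %d trials): PSE %.3f, sigma %.3f, JND/Weber %.3f%s\n",
              x$operation, x$n_trials, x$pse, x$sigma, x$jnd,
              if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

#' @export
coef.psychfit <- function(object, ...) {
  c(pse = object$pse, sigma = object$sigma, lapse = object$lapse)
}

#' @export
logLik.psychfit <- function(object, ...) {
  structure(object$log_likelihood,
            df = if (object$lapse > 0) 3 else 2, class = "logLik")
}

#' @export
predict.psychfit <- function(object, ratio, ...) {
  object$lapse + (1 - 2 * object$lapse) *
    stats::pnorm((log(ratio) - object$pse) / object$sigma)
}

#' @export
summary.psychfit <- function(object, ...) {
  cat(sprintf("Psychometric function, cumulative Gaussian in log ratio (%s)\n",
              object$operation))
  print(coef(object))
  cat(sprintf("JND (log-scale Weber fraction): %.4f\n", object$jnd))
  tab <- data.frame(ratio = object$ratios,
                    p_larger_obs = object$k / object$n,
                    p_larger_fit = predict(object, object$ratios),
                    n = object$n)
  print(tab, row.names = FALSE, digits = 3)
  invisible(object)
}

#' Weber fraction of a psychometric fit
#'
#' The just-noticeable difference on the log-ratio scale,
#' `sigma * qnorm(0.75)`; log-scale JND and Weber fraction are used
#' interchangeably.
#'
#' @param fit a [fit_psychometric()] result.
#' @return Scalar Weber fraction; boundary fits warn.
#' @export
jnd_weber <- function(fit) {
  stopifnot(inherits(fit, "psychfit"))
  if (fit$boundary) warning("Weber fraction from a boundary-flagged fit")
  fit$jnd
}

#' Operational-momentum test on per-subject PSE estimates
#'
#' Paired two-tailed t test of the division against the multiplication PSE
#' across subjects. A positive shift of the multiplication PSE relative to
#' division indicates operational momentum (over-estimation of
#' multiplication outcomes, under-estimation of division outcomes).
#'
#' @param pse_division,pse_multiplication per-subject PSE estimates
#'   (log-ratio units), paired.
#' @return List of class `om_test`: `t`, `df`, `p`, `cohens_d`,
#'   `mean_difference`.
#' @export
operational_momentum <- function(pse_division, pse_multiplication) {
  stopifnot(length(pse_division) == length(pse_multiplication),
            length(pse_division) >= 2)
  d <- pse_division - pse_multiplication
  if (stats::sd(d) <= 1e-10 * (abs(mean(d)) + 1)) {
    if (all(d == 0)) {
      return(structure(list(t = 0, df = length(d) - 1, p = 1, cohens_d = 0,
                            mean_difference = 0), class = "om_test"))
    }
    stop("zero-variance PSE differences: degenerate paired test")
  }
  tt <- stats::t.test(pse_division, pse_multiplication, paired = TRUE)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, cohens_d = mean(d) / stats::sd(d),
                 mean_difference = mean(d)),
            class = "om_test")
}

#' @export
print.om_test <- function(x, ...) {
  cat(sprintf("Operational momentum: t(%d) = %.2f, p = %.3g, Cohen's d = %.2f (division - multiplication PSE = %.3f)\n",
              x$df, x$t, x$p, x$cohens_d, x$mean_difference))
  invisible(x)
}
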