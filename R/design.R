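#' Specification of the approximate-calculation experiment
#'
#' Bundles the timing and composition parameters of the event-related
#' calculation paradigm: a dot-cloud sample appears at 0 s, a symbolic
#' operation cue (multiply/divide by 2 or 4) at 2 s, and a probe dot cloud
#' at 12 s on standard trials. On 20% catch trials the probe arrives
#' unpredictably early (SOA uniform in [5.4, 9.6] s) to force immediate
#' computation; catch trials are modeled but never analyzed. Trials last
#' 20 s, acquired at TR = 2 s, so 10 FIR bins of one TR tile the trial.
#'
#' @param numerosities ordered set of item counts used as samples (and, via
#'   the closure rule, results).
#' @param operands multiplicative/divisive factors.
#' @param trial_length seconds between consecutive sample onsets.
#' @param cue_onset seconds from sample to operation cue.
#' @param probe_soa_standard sample-to-probe SOA on standard trials (s).
#' @param catch_fraction proportion of catch trials.
#' @param catch_soa_range range of the uniform catch-trial probe SOA (s).
#' @param probe_ratios the probe:result ratios used for the comparison task.
#' @param trials_per_condition_per_run standard trials per condition per run.
#' @param n_catch_per_run catch trials per run.
#' @param n_runs runs per subject.
#' @param tr repetition time (s).
#' @param n_fir_bins number of FIR bins (of width `tr`) per trial.
#' @return An object of class `design_spec`.
#' @examples
#' spec <- design_spec()
#' nrow(build_conditions(spec)) # 10
#' @export
design_spec <- function(numerosities = c(6, 12, 24, 48),
                        operands = c(2, 4),
                        trial_length = 20,
                        cue_onset = 2,
                        probe_soa_standard = 12,
                        catch_fraction = 0.2,
                        catch_soa_range = c(5.4, 9.6),
                        probe_ratios = c(0.5, 0.667, 0.8, 0.909,
                                         1.1, 1.25, 1.5, 2),
                        trials_per_condition_per_run = 2,
                        n_catch_per_run = 4,
                        n_runs = 6,
                        tr = 2,
                        n_fir_bins = 10) {
  stopifnot(length(numerosities) >= 1, all(numerosities > 0),
            all(operands > 0), all(operands == round(operands)),
            trial_length > 0, tr > 0, n_fir_bins >= 1,
            length(catch_soa_range) == 2,
            all(probe_ratios > 0))
  if (probe_soa_standard > trial_length) {
    stop("probe_soa_standard must not exceed trial_length")
  }
  if (catch_soa_range[1] <= 0 || catch_soa_range[2] >= probe_soa_standard ||
      catch_soa_range[1] > catch_soa_range[2]) {
    stop("catch_soa_range must lie within (0, probe_soa_standard)")
  }
  spec <- list(numerosities = sort(unique(numerosities)),
               operands = sort(unique(operands)),
               trial_length = trial_length,
               cue_onset = cue_onset,
               probe_soa_standard = probe_soa_standard,
               catch_fraction = catch_fraction,
               catch_soa_range = catch_soa_range,
               probe_ratios = probe_ratios,
               trials_per_condition_per_run = trials_per_condition_per_run,
               n_catch_per_run = n_catch_per_run,
               n_runs = n_runs,
               tr = tr,
               n_fir_bins = n_fir_bins)
  class(spec) <- "design_spec"
  spec
}

#' @export
print.design_spec <- function(x, ...) {
  cat("Approximate-calculation design\n")
  cat("  numerosities:", paste(x$numerosities, collapse = ", "), "\n")
  cat("  operands: x/", paste(x$operands, collapse = ", x/"), "\n", sep = "")
  cat(sprintf("  trial %gs | cue %gs | probe %gs | TR %gs | %d FIR bins\n",
              x$trial_length, x$cue_onset, x$probe_soa_standard,
              x$tr, x$n_fir_bins))
  cat(sprintf("  %d std trials/cond/run + %d catch, %d runs\n",
              x$trials_per_condition_per_run, x$n_catch_per_run, x$n_runs))
  invisible(x)
}

#' Enumerate the conditions closed under the design numerosity set
#'
#' A sample x operation x operand combination is a condition only if its
#' exact result is itself a member of the design numerosity set (the closure
#' rule). For the default set {6, 12, 24, 48} with multiplication/division
#' by 2 or 4 this yields exactly 10 conditions, balanced 5/5 across the two
#' operations and with the operation equally correlated with sample and
#' result numerosity. Non-integer divisions are silently excluded.
#'
#' @param spec a [design_spec()].
#' @return A data frame with columns `condition` (1-based id in canonical
#'   order: sample, then operation with `multiply` first, then operand),
#'   `sample`, `operation`, `operand`, `result`.
#' @export
build_conditions <- function(spec = design_spec()) {
  rows <- list()
  for (s in spec$numerosities) {
    for (op in c("multiply", "divide")) {
      for (k in spec$operands) {
        r <- if (op == "multiply") s * k else s / k
        if (r == round(r) && r %in% spec$numerosities) {
          rows[[length(rows) + 1L]] <-
            data.frame(sample = s, operation = op, operand = k, result = r,
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(condition = integer(), sample = numeric(),
                      operation = character(), operand = numeric(),
                      result = numeric()))
  }
  d <- do.call(rbind, rows)
  ord <- order(d$sample, match(d$operation, c("multiply", "divide")),
               d$operand)
  d <- d[ord, , drop = FALSE]
  d <- cbind(condition = seq_len(nrow(d)), d)
  rownames(d) <- NULL
  d
}

#' Build the four predictor dissimilarity matrices
#'
#' The sample and result predictors hold Euclidean distances between
#' log-scaled numerosities, `|log(a) - log(b)|`; the operation and operand
#' predictors are 0/1 categorical dissimilarities. Downstream every matrix
#' is z-scored before regression, so the log base and the categorical
#' constant are immaterial (asserted by tests).
#'
#' @param conditions condition table from [build_conditions()].
#' @param log_base base of the logarithm for the numeric predictors.
#' @return An object of class `predictor_set`: list with `matrices` (named
#'   list sample/operation/operand/result of symmetric zero-diagonal
#'   matrices), `log_base` and the `conditions` table.
#' @export
build_predictor_rdms <- function(conditions, log_base = 2) {
  if (nrow(conditions) < 2) stop("need at least 2 conditions")
  if (any(conditions$sample <= 0) || any(conditions$result <= 0)) {
    stop("invalid design: non-positive numerosity")
  }
  stopifnot(log_base > 0, log_base != 1)
  lg <- function(x) log(x, base = log_base)
  num_rdm <- function(v) abs(outer(lg(v), lg(v), "-"))
  cat_rdm <- function(v) {
    m <- outer(v, v, FUN = function(a, b) as.numeric(a != b))
    diag(m) <- 0
    m
  }
  mats <- list(sample = num_rdm(conditions$sample),
               operation = cat_rdm(conditions$operation),
               operand = cat_rdm(conditions$operand),
               result = num_rdm(conditions$result))
  mats <- lapply(mats, function(m) {
    dimnames(m) <- list(conditions$condition, conditions$condition)
    m
  })
  structure(list(matrices = mats, log_base = log_base,
                 conditions = conditions),
            class = "predictor_set")
}

#' @export
print.predictor_set <- function(x, ...) {
  cat(sprintf("Predictor set: 4 %dx%d dissimilarity matrices (log base %g)\n",
              nrow(x$matrices$sample), ncol(x$matrices$sample), x$log_base))
  print(round(predictor_correlations(x), 2))
  invisible(x)
}

#' Correlations between the predictor dissimilarity structures
#'
#' Pearson correlations between the vectorized strict upper triangles of the
#' four predictor matrices. For the default design the sample and result
#' predictors are slightly negatively correlated (r = -0.34) and equally
#' correlated with the operation predictor, the property the condition set
#' was chosen for.
#'
#' @param predictors a [build_predictor_rdms()] result.
#' @return Symmetric 4x4 correlation matrix with unit diagonal.
#' @export
predictor_correlations <- function(predictors) {
  vecs <- lapply(predictors$matrices, ut_vec)
  sds <- vapply(vecs, stats::sd, numeric(1))
  if (any(!is.finite(sds)) || any(sds == 0)) {
    stop("zero-variance predictor matrix: correlation undefined for ",
         paste(names(vecs)[sds == 0], collapse = ", "))
  }
  stats::cor(do.call(cbind, vecs))
}
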