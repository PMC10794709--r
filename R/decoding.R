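#' Decoder specification for numerosity decoding
#'
#' Linear support vector regression with regularization parameter `C = 1`,
#' trained on voxel-wise z-scored patterns with continuous labels equal to
#' the z-scored logarithm of numerosity (sample or result), evaluated by
#' leave-one-run-out cross-validation with a Fisher-z correlation score.
#'
#' @param C regularization parameter.
#' @param epsilon SVR insensitivity width.
#' @param scale_test `"per_set"` (default) recomputes the voxel-wise
#'   z-scoring within the test set; `"train"` applies the training-set
#'   statistics to the test patterns.
#' @return Object of class `decoder_spec`.
#' @export
decoder_spec <- function(C = 1, epsilon = 0.1,
                         scale_test = c("per_set", "train")) {
  stopifnot(C > 0, epsilon >= 0)
  structure(list(C = C, epsilon = epsilon,
                 scale_test = match.arg(scale_test)),
            class = "decoder_spec")
}

# z-scored log numerosity labels for an attribute over the condition table
numerosity_labels <- function(conditions, attr = c("sample", "result")) {
  attr <- match.arg(attr)
  zscore(log(conditions[[attr]]))
}

# voxel-wise z-scoring across rows (conditions); zero-variance voxels -> 0
scale_patterns <- function(X, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) scale <- apply(X, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  sweep(sweep(X, 2, center), 2, scale, "/")
}

# gather the condition x voxel pattern of one bin from a per-run fit
run_patterns <- function(fit, bin, voxels = NULL) {
  p <- fit$estimates[, bin, , drop = TRUE]
  if (!is.null(voxels)) p <- p[, voxels, drop = FALSE]
  p
}

#' Cross-validated numerosity decoding between time bins and attributes
#'
#' Trains a linear SVR on the run-wise FIR patterns of `train_bin`, labeled
#' by the z-scored log numerosity of `train_attr`, and predicts the labels
#' of `test_attr` from held-out-run patterns at `test_bin`, cycling through
#' leave-one-run-out folds. Patterns are voxel-wise z-scored across
#' conditions within each set. The per-fold score is the Fisher-z
#' transformed Pearson correlation between true and predicted labels; folds
#' with constant predictions score 0 (counted in `n_constant`). The
#' returned score is the fold average.
#'
#' @param run_fits `fir_fit_list` of per-run FIR fits (see [fit_fir()]).
#' @param train_bin,test_bin FIR bin used for training / testing.
#' @param train_attr,test_attr `"sample"` or `"result"`.
#' @param voxels optional voxel subset (ROI).
#' @param spec a [decoder_spec()].
#' @return Scalar Fisher-z score with attribute `n_constant`.
#' @export
fit_predict_numerosity <- function(run_fits, train_bin, test_bin,
                                   train_attr = "sample",
                                   test_attr = train_attr,
                                   voxels = NULL, spec = decoder_spec()) {
  n_runs <- length(run_fits)
  if (n_runs < 2) stop("leave-one-run-out needs at least 2 runs")
  conditions <- run_fits[[1]]$conditions
  lab_train <- numerosity_labels(conditions, train_attr)
  lab_test <- numerosity_labels(conditions, test_attr)
  zs <- numeric(n_runs)
  n_const <- 0L
  for (r in seq_len(n_runs)) {
    Xtr <- do.call(rbind, lapply(run_fits[-r], run_patterns, bin = train_bin,
                                 voxels = voxels))
    ytr <- rep(lab_train, n_runs - 1)
    ctr <- colMeans(Xtr)
    str_ <- apply(Xtr, 2, stats::sd)
    Xtr <- scale_patterns(Xtr, ctr, str_)
    Xte <- run_patterns(run_fits[[r]], test_bin, voxels)
    Xte <- if (spec$scale_test == "train") {
      scale_patterns(Xte, ctr, str_)
    } else scale_patterns(Xte)
    if (stats::sd(ytr) == 0) stop("labels do not vary within training set")
    fit <- e1071::svm(Xtr, ytr, type = "eps-regression",
                      kernel = "linear", cost = spec$C,
                      epsilon = spec$epsilon, scale = FALSE)
    pred <- as.numeric(stats::predict(fit, Xte))
    if (stats::sd(pred) == 0 || anyNA(pred)) {
      zs[r] <- 0
      n_const <- n_const + 1L
    } else {
      zs[r] <- fisher_z(stats::cor(lab_test, pred))
    }
  }
  structure(mean(zs), n_constant = n_const)
}

#' Temporal generalization matrix of decoding scores
#'
#' Scores [fit_predict_numerosity()] for train/test bin combinations,
#' by default all 10 x 10. A `cells` restriction (two-column matrix of
#' train/test bins) computes only those entries, leaving the rest NA.
#'
#' @inheritParams fit_predict_numerosity
#' @param bins bins spanning the matrix.
#' @param cells optional matrix of (train bin, test bin) rows to compute.
#' @return Object of class `generalization_matrix`: `scores` (train bin x
#'   test bin), `train_attr`, `test_attr`.
#' @export
generalization_matrix <- function(run_fits, train_attr = "sample",
                                  test_attr = "result", voxels = NULL,
                                  spec = decoder_spec(), bins = 1:10,
                                  cells = NULL) {
  if (is.null(cells)) {
    cells <- as.matrix(expand.grid(train = bins, test = bins))
  }
  scores <- matrix(NA_real_, length(bins), length(bins),
                   dimnames = list(train = bins, test = bins))
  for (i in seq_len(nrow(cells))) {
    scores[match(cells[i, 1], bins), match(cells[i, 2], bins)] <-
      fit_predict_numerosity(run_fits, cells[i, 1], cells[i, 2],
                             train_attr, test_attr, voxels, spec)
  }
  structure(list(scores = scores, train_attr = train_attr,
                 test_attr = test_attr, bins = bins),
            class = "generalization_matrix")
}

#' Valid cell set of the sample/result cross-decoding window
#'
#' The window of interest pairs sample-period bins (2-4, i.e. 2-8 s
#' post-sample) with result-period bins (4-6, 6-12 s), keeping only
#' non-overlapping combinations separated by at least one intervening bin
#' (|sample bin - result bin| >= 2): exactly 6 cells per train direction at
#' the defaults.
#'
#' @param sample_bins bins attributed to the stimulus-evoked sample code.
#' @param result_bins bins attributed to the internally generated result.
#' @param min_sep minimum bin separation.
#' @return Data frame with columns `sample_bin`, `result_bin`.
#' @export
cross_decoding_cells <- function(sample_bins = 2:4, result_bins = 4:6,
                                 min_sep = 2) {
  g <- expand.grid(sample_bin = sample_bins, result_bin = result_bins)
  g <- g[abs(g$sample_bin - g$result_bin) >= min_sep, , drop = FALSE]
  if (nrow(g) == 0) stop("empty valid-cell set for the given windows")
  rownames(g) <- NULL
  g
}

#' Sample/result cross-decoding score
#'
#' Averages the generalization scores over the window-of-interest cells
#' ([cross_decoding_cells()]), combining both train directions: training on
#' the sample at sample-period bins and testing on the result at
#' result-period bins, and vice versa.
#'
#' @param m_sr generalization matrix trained on sample, tested on result.
#' @param m_rs generalization matrix trained on result, tested on sample.
#' @param cells valid cells, see [cross_decoding_cells()].
#' @return Mean Fisher-z score over the 2 x 6 default cells.
#' @export
cross_decoding_score <- function(m_sr, m_rs,
                                 cells = cross_decoding_cells()) {
  pick <- function(m, train_bins, test_bins) {
    s <- if (inherits(m, "generalization_matrix")) m$scores else m
    bins <- as.integer(rownames(s))
    s[cbind(match(train_bins, bins), match(test_bins, bins))]
  }
  v <- c(pick(m_sr, cells$sample_bin, cells$result_bin),
         pick(m_rs, cells$result_bin, cells$sample_bin))
  if (anyNA(v)) stop("requested cells not computed in generalization matrix")
  mean(v)
}

#' One-call subject-level cross-decoding score
#'
#' Convenience wrapper: computes only the window-of-interest cells of the
#' two directed generalization matrices and averages them.
#'
#' @inheritParams fit_predict_numerosity
#' @param cells valid cells, see [cross_decoding_cells()].
#' @return Scalar Fisher-z cross-decoding score.
#' @export
cross_decoding <- function(run_fits, voxels = NULL, spec = decoder_spec(),
                           cells = cross_decoding_cells()) {
  m_sr <- generalization_matrix(run_fits, "sample", "result", voxels, spec,
                                cells = cbind(cells$sample_bin,
                                              cells$result_bin))
  m_rs <- generalization_matrix(run_fits, "result", "sample", voxels, spec,
                                cells = cbind(cells$result_bin,
                                              cells$sample_bin))
  cross_decoding_score(m_sr, m_rs, cells)
}
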