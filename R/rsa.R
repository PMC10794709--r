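#' Neural representational dissimilarity matrix at one FIR bin
#'
#' Extracts the condition x voxel pattern of one time bin, applies
#' voxel-wise scaling by subtracting each voxel's mean across the analyzed
#' conditions, and returns pairwise correlation distances, 1 minus the
#' Pearson correlation across voxels. Patterns with zero variance after
#' centering produce undefined (NA) entries, which are flagged and
#' propagated.
#'
#' @param betas a [fit_fir()] result, or directly a condition x voxel
#'   pattern matrix.
#' @param bin FIR bin (ignored when a matrix is given).
#' @param voxels optional voxel index subset (searchlight sphere or ROI).
#' @return Object of class `neural_rdm`: `matrix` (n_cond x n_cond,
#'   symmetric, zero diagonal, entries in [0, 2] where defined), `bin`,
#'   `n_voxels`, `undefined` flag.
#' @export
neural_rdm <- function(betas, bin = NULL, voxels = NULL) {
  pat <- if (inherits(betas, "fir_fit")) {
    stopifnot(!is.null(bin))
    betas$estimates[, bin, , drop = TRUE]
  } else as.matrix(betas)
  if (!is.null(voxels)) pat <- pat[, voxels, drop = FALSE]
  if (ncol(pat) < 2) stop("need at least 2 voxels")
  centered <- sweep(pat, 2, colMeans(pat))
  sds <- apply(centered, 1, stats::sd)
  D <- 1 - suppressWarnings(stats::cor(t(centered)))
  D[sds == 0, ] <- NA_real_
  D[, sds == 0] <- NA_real_
  diag(D) <- 0
  structure(list(matrix = D, bin = bin, n_voxels = ncol(pat),
                 undefined = anyNA(D)),
            class = "neural_rdm")
}

# z-scored predictor design for the RDM regression: intercept + the four
# z-scored vectorized predictors, plus its pseudo-inverse (precomputed once
# per searchlight/ROI analysis)
predictor_design <- function(predictors) {
  P <- vapply(predictors$matrices,
              function(m) zscore(ut_vec(m), "predictor matrix"),
              numeric(length(ut_vec(predictors$matrices[[1]]))))
  X <- cbind(intercept = 1, P)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) stop("singular predictor set")
  list(X = X, pinv = solve(crossprod(X), t(X)))
}

#' Regress a neural RDM on the four predictor RDMs
#'
#' Vectorizes the strict upper triangles (45 values for the 10-condition
#' design), z-scores the neural vector and each predictor vector, and fits
#' an ordinary multiple regression of the neural vector on the four
#' predictors plus an intercept. Returns the four predictor coefficients,
#' the unique (partialled) effect of each design attribute on pattern
#' dissimilarity.
#'
#' @param neural a [neural_rdm()] (or square matrix).
#' @param predictors a [build_predictor_rdms()] result.
#' @return Named numeric vector of betas (sample, operation, operand,
#'   result).
#' @export
rdm_regression <- function(neural, predictors) {
  nm <- if (inherits(neural, "neural_rdm")) neural$matrix else neural
  y <- ut_vec(nm)
  if (anyNA(y)) stop("neural RDM has undefined entries")
  pd <- predictor_design(predictors)
  if (length(y) != nrow(pd$X)) stop("predictor/neural shape mismatch")
  b <- drop(pd$pinv %*% zscore(y, "neural RDM"))
  b[-1]
}

#' Time-resolved RSA effects for one voxel set
#'
#' Runs [neural_rdm()] + [rdm_regression()] at each FIR bin of a fitted
#' model for a fixed ROI/voxel set.
#'
#' @param betas a [fit_fir()] result.
#' @param predictors a [build_predictor_rdms()] result.
#' @param voxels optional voxel subset.
#' @param bins bins to analyze.
#' @return Object of class `rsa_effects`: `beta` matrix (predictor x bin).
#' @export
rsa_effects <- function(betas, predictors, voxels = NULL,
                        bins = seq_len(dim(betas$estimates)[2])) {
  b <- vapply(bins, function(k)
    rdm_regression(neural_rdm(betas, k, voxels), predictors),
    numeric(length(predictors$matrices)))
  colnames(b) <- bins
  structure(list(beta = b, bins = bins), class = "rsa_effects")
}

#' Average time-binned effects into delay windows
#'
#' The early window averages FIR bins 1-2 (0-4 s post-sample), the middle
#' window bins 3-4 (4-8 s), the late window bins 5-6 (8-12 s, up to the
#' standard probe onset). Bins are 1-based with bin k covering
#' (k-1)*2 s to k*2 s.
#'
#' @param effects an [rsa_effects()] object, or a predictor x bin matrix
#'   with columns named by bin.
#' @param windows named list of bin vectors.
#' @return Predictor x window matrix of mean betas.
#' @export
window_average <- function(effects,
                           windows = list(early = 1:2, middle = 3:4,
                                          late = 5:6)) {
  b <- if (inherits(effects, "rsa_effects")) effects$beta else effects
  bins_present <- as.integer(colnames(b))
  out <- vapply(windows, function(w) {
    if (!all(w %in% bins_present)) {
      stop("missing bin(s) ", paste(setdiff(w, bins_present), collapse = ","),
           " for window averaging")
    }
    rowMeans(b[, match(w, bins_present), drop = FALSE])
  }, numeric(nrow(b)))
  out
}

#' Integer offsets of a lattice sphere
#'
#' All integer (dx, dy, dz) with squared norm at most `radius^2`, center
#' included: 123 offsets at the default radius of 3 voxels.
#'
#' @param radius sphere radius in voxels.
#' @return Matrix of offsets, one row each.
#' @export
sphere_offsets <- function(radius = 3) {
  r <- as.integer(floor(radius))
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  as.matrix(g[g$dx^2 + g$dy^2 + g$dz^2 <= radius^2, , drop = FALSE])
}

#' Searchlight RSA over a voxel grid
#'
#' For every in-mask voxel, gathers the in-mask voxels within Euclidean
#' distance `radius` (boundary and center included), computes the neural
#' RDM at each requested bin and regresses it on the predictors, writing
#' the betas at the center. Centers whose neighborhood holds fewer than 2
#' voxels, or whose RDM has undefined entries, are skipped (NA) and counted.
#'
#' @param betas a [fit_fir()] result whose voxels are the in-mask voxels of
#'   `mask`, in `which(mask)` order.
#' @param mask 3-D logical array.
#' @param predictors a [build_predictor_rdms()] result.
#' @param radius sphere radius in voxels.
#' @param bins bins to analyze.
#' @return Object of class `searchlight_map`: `beta` array of dim
#'   `c(dim(mask), n_predictor, n_bins)` (NA off-mask / skipped),
#'   `n_skipped`, `radius`, `bins`.
#' @export
searchlight_rsa <- function(betas, mask, predictors, radius = 3,
                            bins = seq_len(dim(betas$estimates)[2])) {
  stopifnot(length(dim(mask)) == 3)
  if (!any(mask)) stop("empty mask")
  dims <- dim(mask)
  in_mask <- which(mask)
  stopifnot(dim(betas$estimates)[3] == length(in_mask))
  # map from linear grid index to row in the pattern matrix
  vox_row <- array(NA_integer_, dims)
  vox_row[in_mask] <- seq_along(in_mask)
  offs <- sphere_offsets(radius)
  pd <- predictor_design(predictors)
  pnames <- names(predictors$matrices)
  out <- array(NA_real_, c(dims, length(pnames), length(bins)))
  centers <- arrayInd(in_mask, dims)
  n_skipped <- 0L
  pat_bins <- lapply(bins, function(k) betas$estimates[, k, , drop = TRUE])
  for (ci in seq_len(nrow(centers))) {
    nb <- sweep(offs, 2, centers[ci, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
      nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    nb <- nb[ok, , drop = FALSE]
    rows <- vox_row[nb]
    rows <- rows[!is.na(rows)]
    if (length(rows) < 2) {
      n_skipped <- n_skipped + 1L
      next
    }
    cx <- centers[ci, ]
    for (bi in seq_along(bins)) {
      pat <- pat_bins[[bi]][, rows, drop = FALSE]
      centered <- sweep(pat, 2, colMeans(pat))
      D <- 1 - suppressWarnings(stats::cor(t(centered)))
      y <- D[upper.tri(D)]
      if (anyNA(y) || stats::sd(y) == 0) {
        n_skipped <- n_skipped + 1L
        next
      }
      b <- drop(pd$pinv %*% ((y - mean(y)) / stats::sd(y)))[-1]
      out[cx[1], cx[2], cx[3], , bi] <- b
    }
  }
  structure(list(beta = out, predictors = pnames, bins = bins,
                 radius = radius, n_skipped = n_skipped, mask = mask),
            class = "searchlight_map")
}

#' @export
print.searchlight_map <- function(x, ...) {
  cat(sprintf("Searchlight RSA map: %s grid, radius %g, %d bins, %d centers skipped\n",
              paste(dim(x$mask), collapse = "x"), x$radius,
              length(x$bins), x$n_skipped))
  invisible(x)
}
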