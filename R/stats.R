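#' One-sample t test(s) against zero
#'
#' Standard one-sample t statistic with two-tailed p, applied to a vector
#' of per-subject scalars or column-wise to a subjects x units matrix.
#'
#' @param values numeric vector, or matrix with one row per subject.
#' @return List with `t`, `p` (two-tailed), `df`, `mean`.
#' @export
group_onesample_t <- function(values) {
  X <- if (is.matrix(values)) values else matrix(values, ncol = 1)
  if (nrow(X) < 2) stop("need at least 2 subjects")
  if (any(!is.finite(X))) stop("non-finite values")
  n <- nrow(X)
  m <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  if (any(s == 0)) stop("zero-variance input: t undefined")
  t <- m / (s / sqrt(n))
  out <- list(t = t, p = 2 * stats::pt(-abs(t), n - 1), df = n - 1,
              mean = m)
  if (!is.matrix(values)) out[c("t", "p", "mean")] <-
      lapply(out[c("t", "p", "mean")], unname)
  out
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up procedure over the whole input family (e.g. 32 ROIs x 2 delay
#' windows for the ROI RSA family).
#'
#' @param pvals p values in [0, 1].
#' @param q FDR level.
#' @return List with `reject` (logical), `p_adjusted`, `q`.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  if (length(pvals) == 0) {
    return(list(reject = logical(0), p_adjusted = numeric(0), q = q))
  }
  adj <- stats::p.adjust(pvals, method = "BH")
  list(reject = adj <= q, p_adjusted = adj, q = q)
}

#' Label 6-connected components of a 3-D mask
#'
#' Face-connectivity flood fill; the volumetric analog of the vertex
#' clusters used in surface-based group statistics.
#'
#' @param mask 3-D logical array.
#' @return Integer array of component labels (0 = background).
#' @export
label_clusters <- function(mask) {
  dims <- dim(mask)
  stopifnot(length(dims) == 3)
  labels <- array(0L, dims)
  idx <- which(mask)
  if (length(idx) == 0) return(labels)
  nxy <- dims[1] * dims[2]
  cur <- 0L
  for (start in idx) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ijk <- arrayInd(v, dims)
      nb <- integer(0)
      if (ijk[1] > 1) nb <- c(nb, v - 1L)
      if (ijk[1] < dims[1]) nb <- c(nb, v + 1L)
      if (ijk[2] > 1) nb <- c(nb, v - dims[1])
      if (ijk[2] < dims[2]) nb <- c(nb, v + dims[1])
      if (ijk[3] > 1) nb <- c(nb, v - nxy)
      if (ijk[3] < dims[3]) nb <- c(nb, v + nxy)
      nb <- nb[mask[nb] & labels[nb] == 0L]
      labels[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  labels
}

# column-wise one-sample t for a signs-flipped subject matrix, using the
# sign-flip invariance of the sum of squares
signed_t <- function(X, signs, ssq, n) {
  m <- colMeans(X * signs)
  v <- (ssq - n * m^2) / (n - 1)
  v[v <= 0] <- .Machine$double.eps
  m / sqrt(v / n)
}

#' Sign-flip cluster-extent permutation test on subject beta maps
#'
#' Group one-sample inference with family-wise-error control at the cluster
#' level, the volumetric-grid adaptation of surface-based cluster
#' permutation: a two-tailed t map against zero is thresholded at the
#' cluster-forming p, suprathreshold voxels are grouped into 6-connected
#' components separately for positive and negative effects, and each
#' observed cluster's extent is compared against the permutation null of
#' the maximum cluster extent under random sign flips of whole subject
#' maps. Permutation p values are lower-bounded by `1/(n_perm + 1)`.
#'
#' @param subject_maps 4-D array, subjects in the first dimension, or a
#'   list of per-subject 3-D arrays on a common grid.
#' @param n_perm number of sign-flip permutations.
#' @param cluster_forming_p two-tailed voxel-wise threshold p.
#' @param alpha cluster-level FWE threshold reported in the summary.
#' @param seed integer seed for the sign flips.
#' @return Object of class `group_stat_map`: `t` and `p` arrays,
#'   `clusters` data frame (label, sign, extent, peak_t, p_fwe),
#'   `cluster_labels` array (signed labels), `n_subjects`, `n_perm`,
#'   `alpha`.
#' @export
cluster_permutation <- function(subject_maps, n_perm = 5000,
                                cluster_forming_p = 0.01, alpha = 0.05,
                                seed = 1) {
  if (is.list(subject_maps)) {
    dims <- dim(subject_maps[[1]])
    X <- t(vapply(subject_maps, as.numeric, numeric(prod(dims))))
  } else {
    dims <- dim(subject_maps)[-1]
    X <- matrix(subject_maps, nrow = dim(subject_maps)[1])
  }
  n <- nrow(X)
  if (n < 2) stop("need at least 2 subjects")
  if (any(!is.finite(X))) stop("non-finite map entries")
  if (n_perm < 100) warning("fewer than 100 permutations: p values coarse")
  df <- n - 1
  thr <- stats::qt(1 - cluster_forming_p / 2, df)
  ssq <- colSums(X^2)
  t_obs <- signed_t(X, rep(1, n), ssq, n)
  t_arr <- array(t_obs, dims)

  observed_clusters <- function(tv) {
    out <- list()
    for (sgn in c(1, -1)) {
      lab <- label_clusters(array(sgn * tv > thr, dims))
      k <- max(lab)
      if (k > 0) {
        for (cl in seq_len(k)) {
          vox <- which(lab == cl)
          out[[length(out) + 1]] <-
            data.frame(sign = sgn, extent = length(vox),
                       peak_t = sgn * max(sgn * tv[vox]))
        }
      }
    }
    if (length(out) == 0) {
      return(data.frame(sign = numeric(0), extent = integer(0),
                        peak_t = numeric(0)))
    }
    do.call(rbind, out)
  }
  obs <- observed_clusters(t_obs)

  max_extent <- function(tv) {
    m <- 0L
    for (sgn in c(1, -1)) {
      mask <- array(sgn * tv > thr, dims)
      if (any(mask)) m <- max(m, max(tabulate(label_clusters(mask))))
    }
    m
  }
  null_max <- with_seed(derive_seed(seed, 97), {
    vapply(seq_len(n_perm), function(i) {
      signs <- sample(c(-1, 1), n, replace = TRUE)
      max_extent(signed_t(X, signs, ssq, n))
    }, integer(1))
  })
  if (nrow(obs) > 0) {
    obs$p_fwe <- vapply(obs$extent, function(e)
      (1 + sum(null_max >= e)) / (n_perm + 1), numeric(1))
    obs <- obs[order(obs$p_fwe, -obs$extent), , drop = FALSE]
    obs$label <- seq_len(nrow(obs))
    obs <- obs[, c("label", "sign", "extent", "peak_t", "p_fwe")]
  } else {
    obs$p_fwe <- numeric(0)
    obs$label <- integer(0)
  }
  # signed cluster label map for the observed clusters
  lab_arr <- array(0L, dims)
  for (sgn in c(1, -1)) {
    lab <- label_clusters(array(sgn * t_obs > thr, dims))
    lab_arr[lab > 0] <- sgn * lab[lab > 0]
  }
  structure(list(t = t_arr, p = array(2 * stats::pt(-abs(t_obs), df), dims),
                 clusters = obs, cluster_labels = lab_arr,
                 threshold_t = thr, n_subjects = n, n_perm = n_perm,
                 alpha = alpha, null_max_extent = null_max),
            class = "group_stat_map")
}

#' @export
print.group_stat_map <- function(x, ...) {
  cat(sprintf("Group stat map: n = %d (df %d), %d permutations, cluster-forming |t| > %.2f\n",
              x$n_subjects, x$n_subjects - 1, x$n_perm, x$threshold_t))
  if (nrow(x$clusters) == 0) {
    cat("  no suprathreshold clusters\n")
  } else {
    sig <- x$clusters$p_fwe <= x$alpha
    cat(sprintf("  %d cluster(s), %d significant at p_FWE <= %.2f\n",
                nrow(x$clusters), sum(sig), x$alpha))
    print(x$clusters, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Brain-behavior correlation across subjects
#'
#' Pearson correlation, per ROI, between subject-wise cross-decoding scores
#' and behavioral Weber fractions, with two-tailed p from the t transform
#' `t = r sqrt(n-2) / sqrt(1-r^2)` and Benjamini-Hochberg correction across
#' ROIs. A negative correlation means better sample/result cross-decoding
#' in subjects with more precise numerical comparison behavior.
#'
#' @param scores per-subject scores: vector or subjects x ROI matrix.
#' @param webers per-subject Weber fractions.
#' @param q FDR level.
#' @return Data frame with one row per ROI: `roi`, `r`, `t`, `df`, `p`,
#'   `p_fdr`, `significant`.
#' @export
brain_behavior_correlation <- function(scores, webers, q = 0.05) {
  S <- if (is.matrix(scores)) scores else matrix(scores, ncol = 1)
  n <- nrow(S)
  stopifnot(length(webers) == n)
  if (n < 3) stop("need at least 3 subjects")
  if (any(!is.finite(S)) || any(!is.finite(webers))) {
    stop("non-finite input")
  }
  if (stats::sd(webers) == 0) stop("constant Weber fractions: r undefined")
  if (any(apply(S, 2, stats::sd) == 0)) {
    stop("constant score vector: r undefined")
  }
  r <- drop(stats::cor(S, webers))
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * stats::pt(-abs(t), n - 2)
  fdr <- bh_fdr(p, q)
  data.frame(roi = colnames(S) %||% seq_along(r), r = r, t = t, df = n - 2,
             p = p, p_fdr = fdr$p_adjusted, significant = fdr$reject,
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
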