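test_that("correlation distance behaves at its anchor points", {
  base <- matrix(rnorm(50), 5, 10)
  base <- sweep(base, 2, colMeans(base)) # mean-centered patterns
  pat <- rbind(base[1, ], base[1, ], -base[1, ])
  d <- neural_rdm(pat)
  expect_equal(d$matrix[1, 2], 0)            # identical patterns
  expect_equal(d$matrix[1, 3], 2)            # pattern and its negation
  # orthogonal mean-centered patterns -> distance 1 (the pattern set is
  # balanced so the voxel-wise centering leaves the patterns unchanged)
  a <- c(1, -1, 0, 0); b <- c(0, 0, 1, -1)
  d2 <- neural_rdm(rbind(a, -a, b, -b))
  expect_equal(d2$matrix[1, 3], 1)
  expect_equal(d2$matrix[1, 2], 2)
  expect_true(all(abs(d$matrix - t(d$matrix)) < 1e-12))
  expect_equal(diag(d$matrix), rep(0, 3))
})

test_that("degenerate patterns give flagged undefined entries", {
  # build a 4th pattern that is constant after voxel-wise mean centering:
  # solving row4 - colMeans(all four rows) = c gives
  # row4 = (4c + row1 + row2 + row3) / 3
  set.seed(3)
  pat <- matrix(rnorm(30), 3, 10)
  pat <- rbind(pat, (4 * 0.7 + colSums(pat)) / 3)
  d <- neural_rdm(pat)
  expect_true(d$undefined)
  expect_true(anyNA(d$matrix))
  expect_error(rdm_regression(d, default_predictors), "undefined")
  expect_error(neural_rdm(matrix(1, 10, 1)), "2 voxels")
})

test_that("rdm regression matches the explicit normal-equations oracle", {
  ps <- default_predictors
  zs <- lapply(ps$matrices, function(m) zscore_test(m[upper.tri(m)]))
  X <- cbind(1, zs$sample, zs$operation, zs$operand, zs$result)
  oracle_beta <- function(y) {
    solve(t(X) %*% X, t(X) %*% zscore_test(y))[-1]
  }
  # neural RDM equal to the z-scored sample predictor: R^2 = 1, betas from
  # the oracle (correlated predictors receive their partial weights)
  m_s <- matrix(0, 10, 10)
  m_s[upper.tri(m_s)] <- zs$sample
  m_s <- m_s + t(m_s)
  got <- rdm_regression(m_s, ps)
  want <- oracle_beta(zs$sample)
  expect_equal(unname(got), as.vector(want), tolerance = 1e-10)
  fitted <- X %*% solve(t(X) %*% X, t(X) %*% zs$sample)
  expect_equal(as.vector(fitted), zs$sample, tolerance = 1e-10) # R^2 = 1
  # random RDMs: identical to the oracle to 1e-10
  set.seed(1)
  for (i in 1:20) {
    y <- rnorm(45)
    m <- matrix(0, 10, 10)
    m[upper.tri(m)] <- y
    m <- m + t(m)
    expect_equal(unname(rdm_regression(m, ps)),
                 as.vector(oracle_beta(y)), tolerance = 1e-10)
  }
})

test_that("null neural RDMs give centered betas", {
  ps <- default_predictors
  set.seed(7)
  betas <- matrix(NA_real_, 1000, 4)
  for (i in 1:1000) {
    m <- matrix(0, 10, 10)
    m[upper.tri(m)] <- rnorm(45)
    m <- m + t(m)
    betas[i, ] <- rdm_regression(m, ps)
  }
  expect_true(all(abs(colMeans(betas)) < 0.02))
})

test_that("beta ratios are invariant to neural-vector scaling", {
  ps <- default_predictors
  zs <- lapply(ps$matrices, function(m) zscore_test(m[upper.tri(m)]))
  y <- 0.7 * zs$sample + 0.3 * zs$result
  m <- matrix(0, 10, 10); m[upper.tri(m)] <- y; m <- m + t(m)
  m5 <- matrix(0, 10, 10); m5[upper.tri(m5)] <- 5 * y; m5 <- m5 + t(m5)
  b1 <- rdm_regression(m, ps)
  b5 <- rdm_regression(m5, ps)
  expect_equal(b1[["sample"]] / b1[["result"]],
               b5[["sample"]] / b5[["result"]], tolerance = 1e-10)
})

test_that("window averages are plain bin means over the stated windows", {
  b <- matrix(rep(1:10, each = 4), 4, 10,
              dimnames = list(c("sample", "operation", "operand", "result"),
                              1:10))
  w <- window_average(b)
  expect_equal(unname(w[1, ]), c(1.5, 3.5, 5.5))
  const <- matrix(2, 4, 10, dimnames = dimnames(b))
  expect_true(all(window_average(const) == 2))
  expect_error(window_average(b[, 1:4, drop = FALSE]), "missing bin")
})

test_that("the lattice sphere and searchlight neighborhoods are exact", {
  offs <- sphere_offsets(3)
  expect_equal(nrow(offs), 123)
  # independent enumeration
  cnt <- 0
  for (x in -3:3) for (y in -3:3) for (z in -3:3) {
    if (x^2 + y^2 + z^2 <= 9) cnt <- cnt + 1
  }
  expect_equal(nrow(offs), cnt)
})

test_that("searchlight equals a brute-force per-center loop", {
  spec <- design_spec(n_runs = 2)
  dims <- c(6, 6, 6)
  mask <- array(TRUE, dims)
  model <- make_voxel_population(prod(dims), 0, seed = 3,
                                 active_voxels = cube_roi(dims, 3))
  runs <- simulate_subject(spec, model, noise_model(), seed = 4,
                           grid_shape = dims)
  fit <- fit_fir(runs, build_fir_design(lapply(runs, `[[`, "events"), spec))
  ps <- default_predictors
  sl <- searchlight_rsa(fit, mask, ps, radius = 3, bins = 3)
  # brute force: explicit loops, stats computed with plain base calls
  zs <- lapply(ps$matrices, function(m) zscore_test(m[upper.tri(m)]))
  X <- cbind(1, zs$sample, zs$operation, zs$operand, zs$result)
  pat_all <- fit$estimates[, 3, ]
  for (cx in c(1, 3, 6)) for (cy in c(1, 4)) for (cz in c(2, 6)) {
    vox <- integer(0)
    for (x in 1:6) for (y in 1:6) for (z in 1:6) {
      if ((x - cx)^2 + (y - cy)^2 + (z - cz)^2 <= 9) {
        vox <- c(vox, x + (y - 1) * 6 + (z - 1) * 36)
      }
    }
    pat <- pat_all[, vox]
    pat <- sweep(pat, 2, colMeans(pat))
    D <- 1 - cor(t(pat))
    y <- zscore_test(D[upper.tri(D)])
    beta <- solve(t(X) %*% X, t(X) %*% y)[-1]
    expect_equal(sl$beta[cx, cy, cz, , 1], as.vector(beta),
                 tolerance = 1e-10)
  }
  # corner neighborhoods are truncated below 123 voxels
  corner <- sum(sapply(1:6, function(x) sapply(1:6, function(y)
    sum((x - 1)^2 + (y - 1)^2 + (0:5)^2 <= 9))))
  expect_lt(corner, 123)
})

test_that("searchlight betas localize the embedded coding region", {
  # moderate SNR: the local beta tracks the fraction of coding voxels in
  # the sphere, so the map peaks at the region centroid (at very high SNR
  # the correlation-distance structure saturates and the map plateaus)
  spec <- design_spec(n_runs = 4)
  dims <- c(10, 10, 10)
  region <- cube_roi(dims, 5, center = c(4, 5, 6))
  model <- make_voxel_population(prod(dims), 0, seed = 11,
                                 amplitudes = c(sample = 3),
                                 active_voxels = region)
  runs <- simulate_subject(spec, model, noise_model(), seed = 12,
                           grid_shape = dims)
  fit <- fit_fir(runs, build_fir_design(lapply(runs, `[[`, "events"), spec))
  sl <- searchlight_rsa(fit, array(TRUE, dims), default_predictors,
                        bins = 3:4)
  smap <- apply(sl$beta[, , , 1, ], 1:3, mean) # sample predictor
  peak <- arrayInd(which.max(smap), dims)
  expect_lte(max(abs(peak - c(4, 5, 6))), 1)
})
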