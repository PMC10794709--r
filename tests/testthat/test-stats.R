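test_that("one-sample t statistics match their closed form", {
  r <- group_onesample_t(c(1, 2, 3)) # mean 2, sd 1, n 3
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(r$t, 3.464, tolerance = 1e-3)
  expect_equal(r$p, 2 * pt(-2 * sqrt(3), 2), tolerance = 1e-12)
  expect_equal(r$p, 0.0742, tolerance = 1e-3)
  sym <- group_onesample_t(c(-2, -1, 1, 2))
  expect_equal(sym$t, 0)
  expect_equal(sym$p, 1)
  # the cohort-size convention: 17 subjects report df = 16
  expect_equal(group_onesample_t(rnorm(17))$df, 16)
  expect_error(group_onesample_t(rep(1, 5)), "zero-variance")
  expect_error(group_onesample_t(1), "2 subjects")
  expect_error(group_onesample_t(c(1, NA, 2)), "non-finite")
})

test_that("BH step-up matches hand-computed thresholds", {
  # thresholds i/m * q for sorted p; largest i with p_(i) <= i/m*q rejects
  # all smaller p: 0.04 <= 4/4 * 0.05 -> all four rejected
  r <- bh_fdr(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(r$reject))
  expect_equal(r$p_adjusted, c(0.04, 0.04, 0.04, 0.04))
  r2 <- bh_fdr(c(0.5, 0.6), q = 0.05)
  expect_false(any(r2$reject))
  r3 <- bh_fdr(1e-6, q = 0.05)
  expect_true(r3$reject)
  expect_equal(r3$p_adjusted, 1e-6)
  expect_length(bh_fdr(numeric(0))$reject, 0)
  # independent step-up oracle on a random family
  set.seed(4)
  p <- runif(20)^2
  got <- bh_fdr(p, 0.05)
  o <- order(p)
  ps <- p[o]
  kmax <- suppressWarnings(max(which(ps <= seq_along(ps) / 20 * 0.05)))
  reject_oracle <- logical(20)
  if (is.finite(kmax)) reject_oracle[o[seq_len(kmax)]] <- TRUE
  expect_equal(got$reject, reject_oracle)
  # FDR monotonicity: stricter q rejects a subset
  expect_true(all(bh_fdr(p, 0.01)$reject <= bh_fdr(p, 0.05)$reject))
})

test_that("6-connected labeling separates face-disconnected components", {
  m <- array(FALSE, c(4, 4, 4))
  m[1:2, 1, 1] <- TRUE          # component of 2
  m[4, 4, 4] <- TRUE            # singleton
  m[3, 3, 3] <- TRUE            # diagonal neighbor of (4,4,4): not joined
  lab <- label_clusters(m)
  expect_equal(max(lab), 3)
  expect_equal(lab[1, 1, 1], lab[2, 1, 1])
  expect_true(lab[3, 3, 3] != lab[4, 4, 4])
  expect_equal(sort(tabulate(lab)), c(1, 1, 2))
})

test_that("cluster permutation finds a consistent embedded effect", {
  dims <- c(8, 8, 8)
  set.seed(5)
  maps <- lapply(1:17, function(s) {
    m <- array(rnorm(prod(dims), 0, 1), dims)
    m[3:5, 3:5, 3:5] <- m[3:5, 3:5, 3:5] + 1.5
    m
  })
  g <- cluster_permutation(maps, n_perm = 200, seed = 3)
  expect_gt(nrow(g$clusters), 0)
  top <- g$clusters[1, ]
  expect_lte(top$p_fwe, 0.05)
  expect_gte(top$extent, 20)
  expect_equal(top$sign, 1)
  # p values are valid permutation p values
  expect_true(all(g$clusters$p_fwe >= 1 / 201))
  expect_true(all(g$clusters$p_fwe <= 1))
  # flipping every subject map flips t but not the cluster inference
  gneg <- cluster_permutation(lapply(maps, function(m) -m), n_perm = 200,
                              seed = 3)
  expect_equal(gneg$t, -g$t)
  canon <- function(cl, flip = 1) {
    cl$sign <- flip * cl$sign
    cl <- cl[order(cl$extent, cl$sign, cl$p_fwe), c("sign", "extent",
                                                    "p_fwe")]
    rownames(cl) <- NULL
    cl
  }
  expect_equal(canon(gneg$clusters, flip = -1), canon(g$clusters))
  expect_warning(cluster_permutation(maps, n_perm = 50, seed = 1),
                 "100 permutations")
  maps[[1]][1] <- NA
  expect_error(cluster_permutation(maps, n_perm = 200), "non-finite")
})

test_that("brain-behavior correlations match the t transform of r", {
  # perfectly anticorrelated toy vectors
  x <- c(1, 2, 3, 4)
  bb <- brain_behavior_correlation(-x, x)
  expect_equal(bb$r, -1)
  expect_equal(bb$p, 0)
  # r = -0.8 at n = 17: p from t = r sqrt(n-2)/sqrt(1-r^2), df = 15,
  # checked against an independent evaluation via the t distribution
  set.seed(9)
  w <- rnorm(17)
  resid <- rnorm(17)
  resid <- residuals(lm(resid ~ w))
  s <- -0.8 * zscore_test(w) + sqrt(1 - 0.64) * zscore_test(resid)
  bb2 <- brain_behavior_correlation(s, w)
  expect_equal(bb2$r, -0.8, tolerance = 1e-10)
  t_oracle <- -0.8 * sqrt(15) / sqrt(1 - 0.64)
  expect_equal(bb2$t, t_oracle, tolerance = 1e-10)
  expect_equal(bb2$p, 2 * pt(t_oracle, 15), tolerance = 1e-10)
  expect_equal(bb2$df, 15)
  # FDR is applied across the ROI family
  S <- cbind(roiA = s, roiB = rnorm(17))
  bb3 <- brain_behavior_correlation(S, w)
  expect_equal(bb3$roi, c("roiA", "roiB"))
  expect_equal(bb3$p_fdr, p.adjust(bb3$p, "BH"))
  expect_error(brain_behavior_correlation(rep(1, 17), w), "constant")
  expect_error(brain_behavior_correlation(rnorm(2), rnorm(2)), "3 subjects")
})
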