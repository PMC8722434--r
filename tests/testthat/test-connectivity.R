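test_that("BVAR and AR fits recover known generative models", {
  set.seed(10)
  N <- 20000
  # independent white noise: no cross-coupling, unit residual variances
  x <- rnorm(N); y <- rnorm(N)
  f <- fit_bvar(x, y, 15)
  expect_lt(max(abs(c(f$a_xy, f$a_yx))), 0.05)
  expect_lt(abs(f$resid_var_x_full - 1), 0.05)
  expect_lt(abs(f$resid_var_y_full - 1), 0.05)

  # planted lag-1 transfer: x(n) = 0.5 y(n-1) + e
  x2 <- c(0, 0.5 * y[-N]) + rnorm(N)
  f2 <- fit_bvar(x2, y, 15)
  expect_lt(abs(f2$a_xy[1] - 0.5), 0.03)

  # planted AR(1): coefficient and residual variance
  ar <- as.numeric(stats::filter(rnorm(N), 0.9, method = "recursive"))
  fa <- fit_univariate_ar(ar, 15)
  expect_lt(abs(fa$coefficients[1] - 0.9), 0.03)
  expect_lt(abs(fa$resid_var - 1), 0.05)

  # degenerate inputs
  expect_error(fit_bvar(rep(1, 200), rnorm(200), 5), "singular|constant")
  expect_error(fit_bvar(rnorm(40), rnorm(40), 15), "too short")
  expect_error(fit_univariate_ar(rnorm(20), 15), "too short")
})

test_that("OLS fits agree with brute-force normal equations at p = 1, N <= 50", {
  set.seed(3)
  for (N in c(20, 50)) {
    x <- rnorm(N); y <- rnorm(N)
    f <- fit_bvar(x, y, 1)
    # independent oracle: explicit normal equations on the same window
    X <- cbind(x[1:(N - 1)], y[1:(N - 1)])
    bx <- solve(t(X) %*% X, t(X) %*% x[2:N])
    by <- solve(t(X) %*% X, t(X) %*% y[2:N])
    expect_lt(abs(f$a_xx - bx[1]), 1e-10)
    expect_lt(abs(f$a_xy - bx[2]), 1e-10)
    expect_lt(abs(f$a_yx - by[1]), 1e-10)
    expect_lt(abs(f$a_yy - by[2]), 1e-10)
    expect_lt(abs(f$resid_var_x_full -
                    mean((x[2:N] - X %*% bx)^2)), 1e-10)
    fu <- fit_univariate_ar(x, 1)
    bu <- sum(x[1:(N - 1)] * x[2:N]) / sum(x[1:(N - 1)]^2)
    expect_lt(abs(fu$coefficients - bu), 1e-10)
  }
})

test_that("Granger causality matches the analytic oracle on the planted process", {
  # x(n) = 0.5 y(n-1) + e_x with unit variances: V_restricted = 1.25,
  # V_full = 1, so GC_{y->x} = ln 1.25; reverse direction is null
  gc_at <- function(N, seed) {
    set.seed(seed)
    y <- rnorm(N)
    x <- c(0, 0.5 * y[-N]) + rnorm(N)
    c(as.numeric(granger_causality(x, y, 15)),
      as.numeric(granger_causality(y, x, 15)))
  }
  g20k <- gc_at(20000, 1)
  expect_lt(abs(g20k[1] - log(1.25)), 0.02)
  expect_lt(g20k[2], 0.01)
  # estimate converges: mean absolute error over seeds shrinks with N
  err_at <- function(N) {
    mean(vapply(1:5, function(s) abs(gc_at(N, s)[1] - log(1.25)),
                numeric(1)))
  }
  expect_lt(err_at(20000), err_at(2000))

  # independence gives (finite-sample) zero
  set.seed(2)
  expect_lt(as.numeric(granger_causality(rnorm(20000), rnorm(20000), 15)),
            0.01)

  # identical series: collinear design
  z <- rnorm(500)
  expect_error(granger_causality(z, z, 5), "singular")

  # invariance under common rescaling of both series
  set.seed(5)
  a <- rnorm(1000); b <- rnorm(1000)
  expect_lt(abs(as.numeric(granger_causality(a, b, 5)) -
                  as.numeric(granger_causality(10 * a, 10 * b, 5))), 1e-10)
})

test_that("the all-pairs GC matrix has the contracted structure and matches pairwise fits", {
  ep <- noise_epoch(6, 400, seed = 6)
  M <- gc_matrix(ep, p = 5)
  expect_equal(dim(M), c(6L, 6L))
  expect_equal(diag(M), rep(0, 6))
  expect_true(all(M >= 0))
  for (i in 1:3) {
    for (j in 1:3) {
      if (i == j) next
      expect_equal(M[i, j],
                   as.numeric(granger_causality(ep$data[i, ], ep$data[j, ], 5)),
                   tolerance = 1e-8)
    }
  }
  # structural counts at the full 32-electrode epoch geometry
  ep32 <- noise_epoch(32, 500, seed = 7)
  M32 <- gc_matrix(ep32, p = 15)
  expect_equal(sum(diag(M32) == 0), 32L)
  expect_equal(sum(M32 > 0), 992L)  # all off-diagonal entries computed
  expect_length(as.vector(t(M32)), 1024L)
  expect_error(gc_matrix(noise_epoch(2, 30, 1), p = 15), "too short")
})

test_that("a single planted edge is recovered as the argmax of the mean GC matrix", {
  pool <- matrix(c(2L, 5L), 1)  # channel 2 -> channel 5
  m <- make_subject_model(n_channels = 6, order = 1, base_coupling = 0,
                          n_planted = 1, seed = 2, planted_strength = 0.5,
                          planted_pool = pool)
  rec <- simulate_session(m, session_specs("A", 1L)[1, ], duration_s = 100,
                          fs = 125, noise_scale = 0.2, seed = 9)
  eps <- segment_epochs(rec, 2)[1:50]
  mean_gc <- Reduce(`+`, lapply(eps, gc_matrix, p = 5)) / 50
  off <- mean_gc; diag(off) <- -Inf
  expect_equal(as.integer(which(off == max(off), arr.ind = TRUE)),
               c(5L, 2L))  # (target row, source column)
})

test_that("GC estimates are nonnegative up to solver round-off on random epochs", {
  set.seed(12)
  worst <- Inf
  for (r in 1:1000) {
    ep <- matrix(rnorm(4 * 100), 4, 100)
    worst <- min(worst, min(gc_matrix(ep, p = 5, clip = FALSE)))
  }
  expect_gte(worst, -1e-9)
})

test_that("histogram MI matches closed-form cases and is symmetric bit for bit", {
  # MI(x, x) = H(x) = log2 16 for 16 equiprobable values
  v <- rep(1:16, each = 100)
  est <- suppressWarnings(mutual_information(v, v, 16))
  expect_equal(est$mi, 4)
  expect_equal(sum(est$joint_hist), 1600L)
  expect_equal(est$marginals$x, rowSums(est$joint_hist))

  # independent uniforms: plug-in bias approx (B-1)^2 / (2 N ln 2) is
  # well under 0.05 bits at N = 10000
  set.seed(8)
  x <- runif(10000); y <- runif(10000)
  expect_lt(mutual_information(x, y, 16)$mi, 0.05)

  # symmetry: identical value, transposed joint histogram
  a <- rnorm(3000); b <- a + rnorm(3000)
  mab <- mutual_information(a, b, 16)
  mba <- mutual_information(b, a, 16)
  expect_identical(mab$mi, mba$mi)
  expect_identical(mab$joint_hist, t(mba$joint_hist))

  # invariance under per-series monotone affine maps
  expect_identical(mutual_information(2 * a, b, 16)$mi, mab$mi)
  expect_identical(mutual_information(-a, b, 16)$mi, mab$mi)

  # degenerate marginal: MI defined as 0 with a warning
  expect_warning(z <- mutual_information(rep(1, 500), rnorm(500), 16),
                 "constant")
  expect_equal(z$mi, 0)
})

test_that("the MI vector is the strict upper triangle with the expected extremes", {
  ep <- noise_epoch(32, 500, seed = 13)
  v <- mi_vector(ep)
  expect_length(v, 496L)  # 32 * 31 / 2
  expect_true(all(v >= 0))

  # independent channels stay under the small-sample bias bound at N = 10000
  ep_ind <- noise_epoch(5, 10000, seed = 14)
  expect_lt(max(mi_vector(ep_ind)), 0.05)

  # duplicated channel pair dominates
  ep2 <- noise_epoch(8, 500, seed = 15)
  ep2$data[2, ] <- ep2$data[1, ]
  v2 <- mi_vector(ep2)
  expect_equal(which.max(v2), 1L)  # pair (1,2) is the first upper-tri entry

  # agreement with the scalar estimator: vector entry 3 is pair (1, 4)
  expect_equal(unname(v2[3]), suppressWarnings(
    mutual_information(ep2$data[1, ], ep2$data[4, ])$mi))
})

test_that("connectivity_dataset builds labelled feature tables deterministically", {
  co <- small_cohort()
  eps <- preprocess_recording(co$recordings[[1]], seg_len_s = 2)[1:8]
  gc <- connectivity_dataset(eps, "GC", p = 8)
  expect_equal(dim(gc$values), c(8L, 1024L))
  expect_equal(gc$subject_id, rep("S01", 8))
  expect_equal(gc$epoch_index, 1:8)
  expect_true(all(gc$values >= 0))
  mi <- connectivity_dataset(eps, "MI", n_bins = 16)
  expect_equal(dim(mi$values), c(8L, 496L))
  gc2 <- connectivity_dataset(eps, "GC", p = 8)
  expect_identical(gc$values, gc2$values)
  expect_error(connectivity_dataset(list(), "GC"), "empty")

  # epochs that fail are skipped with a message (here: a constant channel)
  eps12 <- preprocess_recording(co$recordings[[1]], seg_len_s = 2)[1:12]
  bad <- eps12[[1]]
  bad$data[3, ] <- 0
  expect_message(
    mixed <- connectivity_dataset(c(eps12, list(bad)), "GC", p = 8),
    "skipping")
  expect_equal(nrow(mixed$values), 12L)
  # more than 10% failing epochs aborts
  expect_error(
    suppressMessages(connectivity_dataset(c(eps[1:4], list(bad)), "GC", p = 8)),
    "> 10%")
})

test_that("feature positions map back to electrode pairs in both layouts", {
  ch <- standard_montage()$names
  gp <- feature_pairs("GC", ch)
  expect_equal(nrow(gp), 1024L)
  expect_equal(sum(gp$self), 32L)
  # row-major flattening: feature 2 is matrix entry (1, 2) = influence of
  # channel 2 on channel 1
  expect_equal(gp$from[2], "Fp2")
  expect_equal(gp$to[2], "Fp1")
  mp <- feature_pairs("MI", ch)
  expect_equal(nrow(mp), 496L)
  expect_equal(mp$from[1], "Fp1")
  expect_equal(mp$to[1], "Fp2")
  expect_false(any(mp$self))
})
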