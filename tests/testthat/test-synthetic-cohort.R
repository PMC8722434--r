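test_that("subject models are stable and respect the no-coupling / planted-count contracts", {
  m0 <- make_subject_model(n_channels = 2, order = 1, base_coupling = 0,
                           n_planted = 0, seed = 7)
  expect_lte(spectral_radius(m0$coefficients), 0.95)
  off <- m0$coefficients[1, , ][!diag(2)]
  expect_true(all(off == 0))  # diagonal-only AR(1)

  m <- make_subject_model(n_channels = 32, order = 2, base_coupling = 0.1,
                          n_planted = 12, seed = 1)
  expect_equal(nrow(m$planted_edges), 12L)
  expect_lte(spectral_radius(m$coefficients), 0.95)
  expect_true(all(m$planted_edges$from != m$planted_edges$to))
  # planted edges sit on nonzero coefficients
  expect_true(all(m$coefficients[cbind(1L, m$planted_edges$to,
                                       m$planted_edges$from)] != 0))
  # default planted pool is intra-frontal (first 11 electrodes)
  expect_true(all(m$planted_edges$from <= 11 & m$planted_edges$to <= 11))
})

test_that("same backbone, different subject seeds differ only at planted positions", {
  m1 <- make_subject_model(seed = 1, backbone_seed = 99)
  m2 <- make_subject_model(seed = 2, backbone_seed = 99)
  diff_pos <- which(m1$coefficients != m2$coefficients, arr.ind = TRUE)
  planted <- rbind(cbind(1L, m1$planted_edges$to, m1$planted_edges$from),
                   cbind(1L, m2$planted_edges$to, m2$planted_edges$from))
  # every differing tensor element is a planted position of one of the two
  key <- function(x) paste(x[, 1], x[, 2], x[, 3])
  expect_true(all(key(diff_pos) %in% key(planted)))
  expect_gt(nrow(diff_pos), 0)
})

test_that("stability rescaling rejects after bounded attempts on an explosive tensor", {
  m <- make_subject_model(n_channels = 2, order = 1, base_coupling = 0,
                          n_planted = 0, seed = 1)
  expect_error(stabilize_coefs(m$coefficients * 1e60, max_attempts = 5),
               "stability failure")
})

test_that("session simulation has the contracted shape, determinism and burn-in behavior", {
  m <- make_subject_model(n_channels = 2, order = 1, base_coupling = 0.1,
                          n_planted = 1, seed = 3)
  sp <- session_specs(c("A"), c(1L))
  r1 <- simulate_session(m, sp[1, ], duration_s = 240, fs = 250, seed = 5)
  expect_equal(ncol(r1$data), 60000L)  # 240 s x 250 Hz
  expect_equal(nrow(r1$data), 2L)
  r2 <- simulate_session(m, sp[1, ], duration_s = 240, fs = 250, seed = 5)
  expect_identical(r1$data, r2$data)   # pure function of the seed
  expect_error(simulate_session(m, sp[1, ], duration_s = 0.01, fs = 250),
               ">= 10")
})

test_that("zero-drift sessions reproduce the model's stationary second moments", {
  # closed-form oracle: for a VAR(1), Gamma0 solves Gamma0 = A Gamma0 A' + S
  # and the lag-1 autocovariance is Gamma1 = A Gamma0
  m <- make_subject_model(n_channels = 2, order = 1, base_coupling = 0.2,
                          n_planted = 1, seed = 3)
  A <- m$coefficients[1, , ]
  S <- m$noise_cov
  g0 <- matrix(solve(diag(4) - kronecker(A, A), as.vector(S)), 2, 2)
  g1 <- A %*% g0
  sp <- session_specs("A", 1L)  # day 1 -> drift 0 under the log law
  expect_equal(sp$drift_scale, 0)
  rec <- simulate_session(m, sp[1, ], duration_s = 400, fs = 250,
                          noise_scale = 0, seed = 8)
  x <- rec$data
  n <- ncol(x)
  emp_g1 <- tcrossprod(x[, 2:n], x[, 1:(n - 1)]) / (n - 1)
  expect_lt(max(abs(emp_g1 - g1)), 0.05)
})

test_that("cohort generation is reproducible and produces the full subject x session grid", {
  sessions <- session_specs(c("A", "B"), c(1L, 2L))
  co <- make_cohort(n_subjects = 3, sessions = sessions, duration_s = 4,
                    fs = 125, seed = 21, n_channels = 8, order = 1,
                    base_coupling = 0.05, n_planted = 2)
  expect_length(co$recordings, 6L)  # subjects x sessions
  expect_length(co$models, 3L)
  expect_equal(vapply(co$recordings, function(r) r$subject_id, character(1)),
               rep(sprintf("S%02d", 1:3), each = 2))
  co2 <- make_cohort(n_subjects = 3, sessions = sessions, duration_s = 4,
                     fs = 125, seed = 21, n_channels = 8, order = 1,
                     base_coupling = 0.05, n_planted = 2)
  expect_identical(co$recordings[[5]]$data, co2$recordings[[5]]$data)
  # default schedule: 15 x 6 = 90 recordings of 240 s (shape checked on the
  # small grid above; the default durations are part of the profile)
  cfg <- full_profile()
  expect_equal(cfg$n_subjects * nrow(cfg$sessions), 90)
  expect_equal(cfg$duration_s, 240)
})

test_that("stronger planted edges push subjects' long-run GC matrices further apart", {
  dist_at <- function(strength) {
    ms <- lapply(1:3, function(s) {
      make_subject_model(n_channels = 8, order = 1, base_coupling = 0.05,
                         n_planted = 4, seed = s, backbone_seed = 5,
                         planted_strength = strength)
    })
    sp <- session_specs("A", 1L)
    gcs <- lapply(ms, function(m) {
      r <- simulate_session(m, sp[1, ], duration_s = 60, fs = 125,
                            noise_scale = 0.2, seed = 100 + m$seed)
      gc_matrix(r$data, p = 5)
    })
    mean(c(norm(gcs[[1]] - gcs[[2]], "F"), norm(gcs[[1]] - gcs[[3]], "F"),
           norm(gcs[[2]] - gcs[[3]], "F")))
  }
  d <- vapply(c(0.1, 0.3, 0.6), dist_at, numeric(1))
  expect_lt(d[1], d[2])
  expect_lt(d[2], d[3])
})

test_that("recordings round-trip through the plain-text container", {
  m <- make_subject_model(n_channels = 2, order = 1, base_coupling = 0,
                          n_planted = 0, seed = 1)
  m$subject_id <- "S01"
  rec <- simulate_session(m, session_specs("A", 1L)[1, ], duration_s = 2,
                          fs = 125, seed = 4)
  path <- tempfile(fileext = ".tsv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$subject_id, "S01")
  expect_equal(back$session_id, "A")
  expect_equal(back$fs, 125)
  expect_equal(dim(back$data), dim(rec$data))
  expect_lt(max(abs(back$data - rec$data)), 1e-8)
})

test_that("session schedules enforce monotone drift", {
  sp <- session_specs()
  expect_equal(sp$session_id, LETTERS[1:6])
  expect_equal(sp$nominal_day, c(1L, 2L, 7L, 30L, 90L, 180L))
  expect_true(!is.unsorted(sp$drift_scale))
  expect_error(session_specs(c("A", "B"), c(1L, 2L),
                             drift_scale = c(0.5, 0.1)),
               "non-decreasing")
})
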