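#' Longitudinal session schedule
#'
#' The default schedule mirrors a six-visit longitudinal design: sessions
#' A-F recorded on days 1, 2, 7, 30, 90 and 180. Session-to-session change is
#' modelled as a coefficient perturbation whose scale grows with the log of
#' the nominal day gap, `drift_scale = drift_c * log(nominal_day)`, so the
#' first-day session is drift-free and later sessions drift monotonically.
#'
#' @param session_id Character vector of session labels.
#' @param nominal_day Integer vector of nominal recording days (same length).
#' @param drift_c Drift-law constant c in `drift = c * log(day)`
#'   (fractional coefficient perturbation per log-day; default 0.2).
#' @param drift_scale Optional explicit drift scales overriding the log law.
#' @return A data.frame with columns `session_id`, `nominal_day`,
#'   `drift_scale`, ordered by nominal day.
#' @export
session_specs <- function(session_id = LETTERS[1:6],
                          nominal_day = c(1L, 2L, 7L, 30L, 90L, 180L),
                          drift_c = 0.2,
                          drift_scale = NULL) {
  stopifnot(length(session_id) == length(nominal_day), !anyDuplicated(session_id))
  if (is.null(drift_scale)) drift_scale <- drift_c * log(nominal_day)
  stopifnot(length(drift_scale) == length(session_id), all(drift_scale >= 0))
  o <- order(nominal_day)
  spec <- data.frame(session_id = as.character(session_id)[o],
                     nominal_day = as.integer(nominal_day)[o],
                     drift_scale = drift_scale[o],
                     stringsAsFactors = FALSE)
  if (is.unsorted(spec$drift_scale)) {
    stop("drift_scale must be non-decreasing in nominal_day")
  }
  spec
}

# companion-matrix spectral radius of a (p, n, n) coefficient array
spectral_radius <- function(coefs) {
  p <- dim(coefs)[1]
  n <- dim(coefs)[2]
  comp <- matrix(0, n * p, n * p)
  for (k in seq_len(p)) comp[1:n, ((k - 1) * n + 1):(k * n)] <- coefs[k, , ]
  if (p > 1) {
    comp[(n + 1):(n * p), 1:(n * (p - 1))] <- diag(n * (p - 1))
  }
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

# shrink coefficients geometrically until the companion radius drops to the
# target; bounded attempts so a pathological tensor fails loudly
stabilize_coefs <- function(coefs, target = 0.95, shrink = 0.9,
                            max_attempts = 60L) {
  for (i in seq_len(max_attempts)) {
    if (spectral_radius(coefs) <= target) return(coefs)
    coefs <- coefs * shrink
  }
  if (spectral_radius(coefs) <= target) return(coefs)
  stop("stability failure: could not rescale coefficients to spectral radius <= ",
       target, " in ", max_attempts, " attempts")
}

run_seeded <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# deterministic sub-seeds below 2^31
derive_seeds <- function(seed, n) {
  run_seeded(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Build a subject-specific stable VAR generator
#'
#' Each synthetic subject is a stationary vector-autoregressive process over
#' the montage channels. All subjects share a common "backbone": per-channel
#' autoregressive dynamics plus weak dense cross-coupling drawn from
#' `backbone_seed`. On top of the backbone, each subject gets `n_planted`
#' distinctive directed couplings ("planted edges") at subject-specific
#' positions and strengths drawn from `seed`; these edges are what makes the
#' subject identifiable downstream. By default (32 channels) planted edges
#' are confined to intra-frontal channel pairs, so region-level localization
#' of subject-specific connectivity has a known ground truth; pass
#' `planted_pool` to change that.
#'
#' Stability is enforced by shrinking the coefficient tensor until the
#' companion-matrix spectral radius is at most 0.95; with the default knobs
#' no shrinking is needed, so the backbone stays bit-identical across
#' subjects and coefficient tensors differ only at planted positions.
#'
#' @param n_channels Number of channels (>= 2; default 32).
#' @param order Autoregressive order of the generator (>= 1; default 2).
#' @param base_coupling Scale of the dense backbone cross-coupling
#'   (unitless AR weight; default 0.1; 0 disables cross-coupling).
#' @param n_planted Number of subject-specific directed edges (default 12).
#' @param seed Subject seed (drives planted positions and strengths).
#' @param backbone_seed Seed of the shared backbone (default 76543).
#' @param planted_strength Mean magnitude of a planted lag-1 coefficient
#'   (default 0.35; individual edges vary by +-20% with random sign).
#' @param planted_pool Optional 2-column matrix of candidate directed edges,
#'   columns `from`, `to` (channel indices, from != to). Default: all
#'   intra-frontal ordered pairs when `n_channels == 32`, otherwise all
#'   off-diagonal ordered pairs.
#' @return An object of class `subject_model`: list with `subject_id`
#'   (filled by [make_cohort()]), `order`, `coefficients` (order x channel x
#'   channel array; `[k, i, j]` is the lag-k weight of channel j on channel
#'   i), `noise_cov`, `planted_edges` (data.frame from/to) and `seed`.
#' @export
make_subject_model <- function(n_channels = 32L, order = 2L,
                               base_coupling = 0.1, n_planted = 12L,
                               seed = 1L, backbone_seed = 76543L,
                               planted_strength = 0.35,
                               planted_pool = NULL) {
  stopifnot(n_channels >= 2, order >= 1, n_planted >= 0,
            n_planted <= n_channels * (n_channels - 1))
  if (is.null(planted_pool)) {
    if (n_channels == 32L) {
      frontal <- 1:11  # Fp1..FC6 in the standard montage order
      planted_pool <- as.matrix(expand.grid(from = frontal, to = frontal))
    } else {
      planted_pool <- as.matrix(expand.grid(from = seq_len(n_channels),
                                            to = seq_len(n_channels)))
    }
    planted_pool <- planted_pool[planted_pool[, 1] != planted_pool[, 2], ,
                                 drop = FALSE]
  }
  stopifnot(ncol(planted_pool) == 2, n_planted <= nrow(planted_pool))

  coefs <- run_seeded(backbone_seed, {
    a <- array(0, dim = c(order, n_channels, n_channels))
    # per-channel dynamics: damped AR with mild channel-to-channel variation
    a[1, , ][cbind(1:n_channels, 1:n_channels)] <- stats::runif(n_channels, 0.30, 0.50)
    if (order >= 2) {
      a[2, , ][cbind(1:n_channels, 1:n_channels)] <- stats::runif(n_channels, -0.25, -0.10)
    }
    if (base_coupling > 0) {
      for (k in 1:min(order, 2L)) {
        off <- matrix(stats::rnorm(n_channels^2,
                                   sd = base_coupling / sqrt(n_channels)),
                      n_channels, n_channels)
        diag(off) <- 0
        a[k, , ] <- a[k, , ] + off
      }
    }
    a
  })

  planted <- run_seeded(seed, {
    if (n_planted == 0) {
      list(edges = data.frame(from = integer(0), to = integer(0)),
           strength = numeric(0))
    } else {
      pick <- sample.int(nrow(planted_pool), n_planted)
      list(edges = data.frame(from = planted_pool[pick, 1],
                              to = planted_pool[pick, 2]),
           strength = planted_strength * stats::runif(n_planted, 0.8, 1.2) *
             sample(c(-1, 1), n_planted, replace = TRUE))
    }
  })
  if (n_planted > 0) {
    idx <- cbind(1L, planted$edges$to, planted$edges$from)
    coefs[idx] <- coefs[idx] + planted$strength
  }
  coefs <- stabilize_coefs(coefs)

  structure(
    list(subject_id = NA_character_, order = as.integer(order),
         coefficients = coefs, noise_cov = diag(n_channels),
         planted_edges = planted$edges, seed = as.integer(seed)),
    class = "subject_model"
  )
}

#' @export
print.subject_model <- function(x, ...) {
  cat("<subject_model> ", dim(x$coefficients)[2], " channels, order ",
      x$order, ", ", nrow(x$planted_edges), " planted edges, radius ",
      round(spectral_radius(x$coefficients), 3), "\n", sep = "")
  invisible(x)
}

#' Simulate one recording session from a subject model
#'
#' Applies the session's drift to the subject's coefficients elementwise,
#' `A' = A + drift_scale * |A| * Z` with `Z` standard normal drawn
#' once per subject-session (then stability-rescaled if needed), runs the VAR
#' recursion with innovations from the model's noise covariance, discards a
#' burn-in of `max(500, 10 * order)` samples, and adds white channel-
#' independent sensor noise of standard deviation `noise_scale`.
#'
#' @param model A [make_subject_model()] object.
#' @param spec One row of [session_specs()] (list or single-row data.frame
#'   with `session_id`, `nominal_day`, `drift_scale`).
#' @param duration_s Recording duration in seconds (default 240, i.e. a
#'   4-minute resting block).
#' @param fs Sampling rate in Hz (default 250).
#' @param noise_scale Sensor-noise standard deviation in signal units
#'   (default 0.5; innovation variance is 1).
#' @param seed Integer seed; the same (model, spec, seed) gives a
#'   bit-identical recording.
#' @param montage Montage attached to the recording (default
#'   [standard_montage()] for 32 channels, else NULL).
#' @return An object of class `eeg_recording`: list with `data` (channel x
#'   sample matrix), `fs`, `montage`, `subject_id`, `session_id`.
#' @export
simulate_session <- function(model, spec, duration_s = 240, fs = 250,
                             noise_scale = 0.5, seed = 1L,
                             montage = NULL) {
  n <- dim(model$coefficients)[2]
  p <- model$order
  n_samples <- floor(duration_s * fs)
  if (n_samples < 10 * p) stop("duration_s * fs must be >= 10 * order samples")
  drift <- as.numeric(spec$drift_scale)
  if (is.null(montage) && n == 32L) montage <- standard_montage()

  run_seeded(seed, {
    a <- model$coefficients
    if (drift > 0) {
      # fractional perturbation: each coefficient moves by a Gaussian share
      # of its own magnitude, so structure (zeros) is preserved
      delta <- abs(a) * array(stats::rnorm(length(a)), dim = dim(a))
      a <- stabilize_coefs(a + drift * delta)
    }
    burn <- max(500L, 10L * p)
    n_tot <- n_samples + burn
    ch <- chol(model$noise_cov)
    innov <- t(matrix(stats::rnorm(n_tot * n), n_tot, n) %*% ch)  # n x n_tot
    x <- matrix(0, n, n_tot)
    x[, 1:p] <- innov[, 1:p]
    for (t in (p + 1):n_tot) {
      acc <- innov[, t]
      for (k in 1:p) acc <- acc + a[k, , ] %*% x[, t - k]
      x[, t] <- acc
    }
    out <- x[, (burn + 1):n_tot, drop = FALSE]
    if (noise_scale > 0) {
      out <- out + matrix(stats::rnorm(length(out), sd = noise_scale),
                          n, n_samples)
    }
    if (!is.null(montage)) rownames(out) <- montage$names
    structure(
      list(data = out, fs = fs, montage = montage,
           subject_id = model$subject_id,
           session_id = as.character(spec$session_id)),
      class = "eeg_recording"
    )
  })
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> subject ", x$subject_id, ", session ", x$session_id,
      ": ", nrow(x$data), " ch x ", ncol(x$data), " samples @ ", x$fs,
      " Hz (", round(ncol(x$data) / x$fs, 1), " s)\n", sep = "")
  invisible(x)
}

#' Generate a longitudinal multi-subject cohort
#'
#' Builds one stable [make_subject_model()] per subject (shared backbone,
#' subject-specific planted edges) and simulates every subject in every
#' session of the schedule, applying the session's drift. The whole cohort is
#' a pure function of `seed`.
#'
#' @param n_subjects Number of subjects (>= 2; default 15).
#' @param sessions A [session_specs()] data.frame (default: the six-session
#'   A-F schedule).
#' @param duration_s,fs,noise_scale Passed to [simulate_session()].
#' @param seed Master cohort seed.
#' @param ... Passed to [make_subject_model()] (e.g. `n_channels`, `order`,
#'   `n_planted`, `planted_strength`).
#' @return An object of class `eeg_cohort`: list with `recordings` (list of
#'   `eeg_recording`, subject-major order), `models` (ground-truth
#'   `subject_model`s), `sessions`, and `seed`.
#' @export
make_cohort <- function(n_subjects = 15L, sessions = session_specs(),
                        duration_s = 240, fs = 250, noise_scale = 0.5,
                        seed = 1L, ...) {
  stopifnot(n_subjects >= 2, nrow(sessions) >= 1)
  n_sess <- nrow(sessions)
  seeds <- derive_seeds(seed, 1L + n_subjects + n_subjects * n_sess)
  backbone_seed <- seeds[1]
  subj_seeds <- seeds[1 + seq_len(n_subjects)]
  sess_seeds <- matrix(seeds[-(1:(1 + n_subjects))], n_subjects, n_sess)
  montage <- NULL
  dots <- list(...)
  n_channels <- if (!is.null(dots$n_channels)) dots$n_channels else 32L
  if (n_channels == 32L) montage <- standard_montage()

  models <- lapply(seq_len(n_subjects), function(s) {
    m <- make_subject_model(seed = subj_seeds[s],
                            backbone_seed = backbone_seed, ...)
    m$subject_id <- sprintf("S%02d", s)
    m
  })
  recordings <- list()
  for (s in seq_len(n_subjects)) {
    for (j in seq_len(n_sess)) {
      recordings[[length(recordings) + 1L]] <-
        simulate_session(models[[s]], sessions[j, ], duration_s = duration_s,
                         fs = fs, noise_scale = noise_scale,
                         seed = sess_seeds[s, j], montage = montage)
    }
  }
  structure(
    list(recordings = recordings, models = models, sessions = sessions,
         seed = as.integer(seed)),
    class = "eeg_cohort"
  )
}

#' @export
print.eeg_cohort <- function(x, ...) {
  cat("<eeg_cohort> ", length(x$models), " subjects x ", nrow(x$sessions),
      " sessions = ", length(x$recordings), " recordings\n", sep = "")
  invisible(x)
}

#' Write / read a recording as plain text
#'
#' Recordings are stored as a tab-separated sample table (one column per
#' channel) next to a JSON sidecar carrying `subject_id`, `session_id`, `fs`
#' and the montage name, so a cohort round-trips through portable files.
#'
#' @param recording An `eeg_recording`.
#' @param path Path of the `.tsv` data file; the sidecar is `path` with
#'   `.json` appended.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns the `eeg_recording`.
#' @export
write_recording <- function(recording, path) {
  mat <- t(recording$data)
  colnames(mat) <- rownames(recording$data)
  utils::write.table(format(mat, trim = TRUE, digits = 10), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(subject_id = recording$subject_id,
               session_id = recording$session_id,
               fs = recording$fs,
               montage = if (is.null(recording$montage)) NULL else "10_20_32",
               n_channels = nrow(recording$data),
               n_samples = ncol(recording$data))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  mat <- t(as.matrix(utils::read.delim(path, check.names = FALSE)))
  montage <- if (identical(meta$montage, "10_20_32")) standard_montage() else NULL
  structure(
    list(data = mat, fs = meta$fs, montage = montage,
         subject_id = meta$subject_id, session_id = meta$session_id),
    class = "eeg_recording"
  )
}
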