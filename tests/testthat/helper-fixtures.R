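# Shared fixtures. Expensive objects are built once per test run and cached
# in this environment so every test file can reuse them.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# fully connected 3-electrode toy montage (each electrode has 2 neighbors),
# written through the plain-text interface so reading is exercised too
toy_montage <- function() {
  cached("toy_montage", function() {
    el <- tempfile(fileext = ".tsv")
    ad <- tempfile(fileext = ".tsv")
    writeLines(c("name\tx\ty\tregion",
                 "E1\t0\t1\tfrontal",
                 "E2\t-1\t-1\tcentral",
                 "E3\t1\t-1\tparietal"), el)
    writeLines(c("from\tto", "E1\tE2", "E1\tE3", "E2\tE3"), ad)
    read_montage(el, ad)
  })
}

# small multi-session cohort in the reduced profile regime: 4 subjects,
# 3 sessions with growing drift, 30 epochs each at 125 Hz
small_cohort <- function() {
  cached("small_cohort", function() {
    make_cohort(n_subjects = 4L,
                sessions = session_specs(c("A", "B", "C"), c(1L, 7L, 180L)),
                duration_s = 60, fs = 125, noise_scale = 0.5, seed = 11L,
                n_channels = 32L, order = 2L, base_coupling = 0.1,
                n_planted = 12L, planted_strength = 0.35)
  })
}

small_gc_features <- function() {
  cached("small_gc_features", function() {
    cfg <- quick_profile()
    cohort_features(small_cohort(), cfg, "GC")$GC
  })
}

# well-separated Gaussian-blob feature table, for identifier tests that do
# not need the connectivity stage
blob_features <- function(n_subjects = 3, n_epochs = 20, d = 12, sep = 5,
                          seed = 1, session = "A") {
  set.seed(seed)
  centers <- matrix(rnorm(n_subjects * d, sd = sep), n_subjects, d)
  values <- do.call(rbind, lapply(seq_len(n_subjects), function(s) {
    matrix(rnorm(n_epochs * d), n_epochs, d) +
      matrix(centers[s, ], n_epochs, d, byrow = TRUE)
  }))
  structure(
    list(kind = "MI", values = values,
         subject_id = rep(sprintf("S%02d", seq_len(n_subjects)),
                          each = n_epochs),
         session_id = rep(session, n_subjects * n_epochs),
         epoch_index = rep(seq_len(n_epochs), n_subjects),
         channel_names = NULL),
    class = "fc_features"
  )
}

# plain channels x samples white-noise epoch
noise_epoch <- function(n_ch, n_samp, seed = 1) {
  set.seed(seed)
  structure(list(data = matrix(rnorm(n_ch * n_samp), n_ch, n_samp),
                 fs = 125, subject_id = "S01", session_id = "A", index = 1L),
            class = "eeg_epoch")
}

sine_recording <- function(freq, fs = 250, duration_s = 8, n_ch = 2) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  structure(list(data = matrix(rep(sin(2 * pi * freq * t), each = n_ch),
                               n_ch, byrow = FALSE),
                 fs = fs, montage = NULL,
                 subject_id = "S01", session_id = "A"),
            class = "eeg_recording")
}
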