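#' Bivariate autoregressive (BVAR) fit of two channels
#'
#' Jointly models two series by regressing each on `p` lags of both,
#'
#'   x(n) = sum_k a_xx[k] x(n-k) + sum_k a_xy[k] y(n-k) + u_x(n)
#'   y(n) = sum_k a_yx[k] x(n-k) + sum_k a_yy[k] y(n-k) + u_y(n)
#'
#' by ordinary least squares (QR, no intercept — EEG channels are zero-mean
#' after band-pass filtering) over the window n = p+1..N. The residual
#' variances of the two equations, `resid_var_x_full` and `resid_var_y_full`,
#' are the "full model" variances entering the Granger-causality log-ratio;
#' they use the 1/M normalizer over the M = N - p fitted samples (mean of
#' squared residuals).
#'
#' @param x,y Numeric series of equal length (>= 5p samples).
#' @param p Model order (number of lags).
#' @return Object of class `bvar_fit`: `order`, per-lag coefficient vectors
#'   `a_xx`, `a_xy`, `a_yx`, `a_yy`, and `resid_var_x_full`,
#'   `resid_var_y_full`.
#' @export
fit_bvar <- function(x, y, p) {
  n <- length(x)
  stopifnot(length(y) == n, p >= 1)
  if (n < 5 * p) stop("series too short: ", n, " samples for order-", p,
                      " BVAR (need >= 5p)")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("singular fit: constant input series")
  }
  des <- cbind(lag_design(x, p), lag_design(y, p))
  fx <- stats::lm.fit(des, x[(p + 1):n])
  fy <- stats::lm.fit(des, y[(p + 1):n])
  if (fx$rank < 2 * p) stop("singular fit: rank-deficient lag design (collinear inputs)")
  m <- n - p
  structure(
    list(order = as.integer(p),
         a_xx = unname(fx$coefficients[1:p]),
         a_xy = unname(fx$coefficients[(p + 1):(2 * p)]),
         a_yx = unname(fy$coefficients[1:p]),
         a_yy = unname(fy$coefficients[(p + 1):(2 * p)]),
         resid_var_x_full = sum(fx$residuals^2) / m,
         resid_var_y_full = sum(fy$residuals^2) / m),
    class = "bvar_fit"
  )
}

# M x p matrix of lagged values of x over the common window n = p+1..N
lag_design <- function(x, p) {
  n <- length(x)
  vapply(1:p, function(k) x[(p + 1 - k):(n - k)], numeric(n - p))
}

#' Restricted univariate autoregressive fit
#'
#' OLS autoregression of a series on its own `p` lags over the same sample
#' window as [fit_bvar()]; its residual variance is the "restricted model"
#' variance in the Granger-causality numerator.
#'
#' @inheritParams fit_bvar
#' @return Object of class `ar_fit`: `order`, `coefficients` (length p),
#'   `resid_var`.
#' @export
fit_univariate_ar <- function(x, p) {
  n <- length(x)
  stopifnot(p >= 1)
  if (n < 3 * p) stop("series too short: ", n, " samples for order-", p,
                      " AR (need >= 3p)")
  if (stats::sd(x) == 0) stop("singular fit: constant input series")
  f <- stats::lm.fit(lag_design(x, p), x[(p + 1):n])
  if (f$rank < p) stop("singular fit: rank-deficient lag design")
  structure(
    list(order = as.integer(p),
         coefficients = unname(f$coefficients),
         resid_var = sum(f$residuals^2) / (n - p)),
    class = "ar_fit"
  )
}

#' Pairwise Granger causality
#'
#' Granger influence of `y` on `x`: the log-ratio of the restricted to the
#' full residual variance,
#'
#'   GC_{y->x} = ln( V_{x|x-past} / V_{x|x-past, y-past} ),
#'
#' zero when y's past adds nothing to the prediction of x beyond x's own
#' past. Both variances are floored at `eps` before the ratio; the result is
#' clipped at 0 from below (the exact quantity is nonnegative; tiny negative
#' estimates are numerical). The unclipped value is kept in attribute
#' `"raw"`.
#'
#' @inheritParams fit_bvar
#' @param eps Variance floor before the log-ratio (default 1e-12).
#' @return Nonnegative scalar, the influence of `y` on `x` (nats), with the
#'   pre-clip value as attribute `raw`.
#' @export
granger_causality <- function(x, y, p, eps = 1e-12) {
  full <- fit_bvar(x, y, p)
  restr <- fit_univariate_ar(x, p)
  raw <- log(max(restr$resid_var, eps) / max(full$resid_var_x_full, eps))
  structure(max(raw, 0), raw = raw)
}

#' All-pairs Granger-causality matrix of an epoch
#'
#' Entry (i, j) is the Granger influence of channel j on channel i from a
#' bivariate order-`p` fit of that channel pair; the diagonal is fixed to 0.
#' The computation runs in compiled code sharing one lag cross-product across
#' all pairs, and agrees with looping [granger_causality()] over pairs.
#'
#' @param epoch An `eeg_epoch` (or any channels x samples matrix).
#' @param p Model order (default 15).
#' @param eps Variance floor (default 1e-12).
#' @param clip Clip negative numerical estimates to 0 (default TRUE).
#' @return n_channels x n_channels matrix with zero diagonal; dimnames from
#'   the epoch's channel names. With `clip = FALSE` entries may be tiny
#'   negatives (magnitude bounded by solver round-off).
#' @export
gc_matrix <- function(epoch, p = 15, eps = 1e-12, clip = TRUE) {
  dat <- if (inherits(epoch, "eeg_epoch")) epoch$data else epoch
  out <- gc_matrix_cpp(dat, as.integer(p), eps, clip)
  dimnames(out) <- list(rownames(dat), rownames(dat))
  out
}

#' Histogram-based mutual information of two series
#'
#' Plug-in mutual information from an equal-width 2-D histogram:
#'
#'   MI(x, y) = sum_ij p(x_i, y_j) log( p(x_i, y_j) / (p(x_i) p(y_j)) )
#'
#' with each series binned into `n_bins` equal-width bins over its own
#' observed range (so MI is invariant to per-series monotone affine maps),
#' zero-count cells contributing 0, and logs in base 2 by default (bits).
#' Cell contributions are summed in sorted order, making the estimate
#' bit-identical under swapping the arguments.
#'
#' @param x,y Numeric series of equal length.
#' @param n_bins Bins per axis (default 16).
#' @param base Logarithm base (default 2, i.e. bits; use `exp(1)` for nats).
#' @return Object of class `mi_estimate`: `n_bins`, `joint_hist` (x bins in
#'   rows, y bins in columns), `marginals` (list of the two count vectors),
#'   `mi`. A constant input gives `mi = 0` with a warning (degenerate
#'   marginal); fewer than `5 * n_bins^2` samples triggers an
#'   undersampling warning.
#' @export
mutual_information <- function(x, y, n_bins = 16, base = 2) {
  n <- length(x)
  stopifnot(length(y) == n, n_bins >= 2)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input series: MI defined as 0 (degenerate marginal)")
    z <- matrix(0L, n_bins, n_bins)
    z[1, 1] <- n
    return(structure(list(n_bins = as.integer(n_bins), joint_hist = z,
                          marginals = list(x = rowSums(z), y = colSums(z)),
                          mi = 0),
                     class = "mi_estimate"))
  }
  if (n < 5 * n_bins^2) {
    warning("only ", n, " samples for ", n_bins,
            "^2 histogram cells; MI estimate may be strongly biased")
  }
  bi <- bin_indices(x, n_bins)
  bj <- bin_indices(y, n_bins)
  joint <- matrix(tabulate((bj - 1L) * n_bins + bi, n_bins * n_bins),
                  n_bins, n_bins)
  structure(
    list(n_bins = as.integer(n_bins), joint_hist = joint,
         marginals = list(x = rowSums(joint), y = colSums(joint)),
         mi = mi_from_joint(joint, n, base)),
    class = "mi_estimate"
  )
}

bin_indices <- function(x, n_bins) {
  breaks <- seq(min(x), max(x), length.out = n_bins + 1)
  findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
}

# plug-in MI from a joint count table; sorted summation makes the value
# invariant (bitwise) under transposition of the table
mi_from_joint <- function(joint, n, base = 2) {
  px <- rowSums(joint)
  py <- colSums(joint)
  nz <- which(joint > 0)
  cnt <- joint[nz]
  rx <- px[row(joint)[nz]]
  cy <- py[col(joint)[nz]]
  terms <- (cnt / n) * log((cnt * n) / (rx * cy), base = base)
  max(sum(sort(terms)), 0)
}

#' @export
print.mi_estimate <- function(x, ...) {
  cat("<mi_estimate> ", x$n_bins, " bins, MI = ", signif(x$mi, 4), " bits\n",
      sep = "")
  invisible(x)
}

#' Upper-triangle mutual-information vector of an epoch
#'
#' Mutual information for every unordered channel pair, returned as the
#' strict upper triangle of the symmetric MI matrix in row-major order:
#' (1,2), (1,3), ..., (1,C), (2,3), ... For 32 channels that is
#' 32*31/2 = 496 features. Binning is per-channel over each channel's
#' observed range; undersampling warnings are not repeated per pair.
#'
#' @param epoch An `eeg_epoch` (or channels x samples matrix).
#' @param n_bins Bins per axis (default 16).
#' @param base Log base (default 2).
#' @return Named nonnegative vector of length C*(C-1)/2.
#' @export
mi_vector <- function(epoch, n_bins = 16, base = 2) {
  dat <- if (inherits(epoch, "eeg_epoch")) epoch$data else epoch
  C <- nrow(dat)
  N <- ncol(dat)
  bins <- matrix(0L, C, N)
  const_ch <- logical(C)
  for (c in seq_len(C)) {
    if (stats::sd(dat[c, ]) == 0) const_ch[c] <- TRUE
    else bins[c, ] <- bin_indices(dat[c, ], n_bins)
  }
  pairs <- upper_pairs(C)
  out <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (const_ch[i] || const_ch[j]) { out[k] <- 0; next }
    joint <- matrix(tabulate((bins[j, ] - 1L) * n_bins + bins[i, ],
                             n_bins * n_bins), n_bins, n_bins)
    out[k] <- mi_from_joint(joint, N, base)
  }
  nm <- rownames(dat)
  if (!is.null(nm)) names(out) <- paste0(nm[pairs[, 1]], "-", nm[pairs[, 2]])
  out
}

# strict upper triangle in row-major order, as a 2-column index matrix
upper_pairs <- function(C) {
  idx <- which(upper.tri(matrix(0, C, C)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

#' Per-epoch connectivity feature table
#'
#' Computes one feature vector per epoch: for `kind = "GC"` the row-major
#' flattening of the directed Granger matrix (diagonal fixed at 0 but kept,
#' giving C^2 = 1024 features for 32 channels); for `kind = "MI"` the
#' strict-upper-triangle MI vector (C(C-1)/2 = 496 features). Epochs whose
#' matrix computation fails are skipped with a message; more than 10%
#' skipped aborts.
#'
#' @param epochs List of `eeg_epoch` (e.g. from [preprocess_recording()]),
#'   possibly pooled over recordings.
#' @param kind `"GC"` or `"MI"`.
#' @param p BVAR order for GC (default 15).
#' @param n_bins Histogram bins for MI (default 16).
#' @return Object of class `fc_features`: list with `kind`, `values`
#'   (epochs x features matrix), `subject_id`, `session_id`, `epoch_index`
#'   (per-row labels) and `channel_names`.
#' @export
connectivity_dataset <- function(epochs, kind = c("GC", "MI"), p = 15,
                                 n_bins = 16) {
  kind <- match.arg(kind)
  if (length(epochs) == 0) stop("empty epoch list")
  rows <- vector("list", length(epochs))
  ok <- logical(length(epochs))
  for (e in seq_along(epochs)) {
    rows[e] <- list(tryCatch({
      if (kind == "GC") {
        m <- gc_matrix(epochs[[e]], p = p)
        as.vector(t(m))  # row-major flattening
      } else {
        mi_vector(epochs[[e]], n_bins = n_bins)
      }
    }, error = function(err) {
      message("skipping epoch ", e, " (subject ", epochs[[e]]$subject_id,
              "): ", conditionMessage(err))
      NULL
    }))
    ok[e] <- !is.null(rows[[e]])
  }
  if (mean(!ok) > 0.10) {
    stop(sum(!ok), " of ", length(epochs),
         " epochs failed connectivity computation (> 10%)")
  }
  kept <- epochs[ok]
  values <- do.call(rbind, rows[ok])
  ch <- rownames(kept[[1]]$data)
  if (kind == "GC" && !is.null(ch)) {
    C <- length(ch)
    grid <- expand.grid(source = seq_len(C), target = seq_len(C))
    grid <- grid[order(grid$target, grid$source), ]
    colnames(values) <- paste0(ch[grid$source], ">", ch[grid$target])
  }
  structure(
    list(kind = kind,
         values = values,
         subject_id = vapply(kept, function(e) e$subject_id, character(1)),
         session_id = vapply(kept, function(e) e$session_id, character(1)),
         epoch_index = vapply(kept, function(e) as.integer(e$index), integer(1)),
         channel_names = ch),
    class = "fc_features"
  )
}

#' @export
print.fc_features <- function(x, ...) {
  cat("<fc_features> ", x$kind, ": ", nrow(x$values), " epochs x ",
      ncol(x$values), " features; ", length(unique(x$subject_id)),
      " subjects, sessions ", paste(unique(x$session_id), collapse = ","),
      "\n", sep = "")
  invisible(x)
}

#' Subset the rows (epochs) of a feature table
#' @param x An `fc_features` object.
#' @param rows Logical or integer row index.
#' @return The subsetted `fc_features`.
#' @export
features_subset <- function(x, rows) {
  x$values <- x$values[rows, , drop = FALSE]
  x$subject_id <- x$subject_id[rows]
  x$session_id <- x$session_id[rows]
  x$epoch_index <- x$epoch_index[rows]
  x
}

#' Write a feature table as tab-separated values
#'
#' One row per epoch: `subject_id`, `session_id`, `epoch_index`, then the
#' features.
#' @param features An `fc_features` object.
#' @param path Output path.
#' @export
write_features_tsv <- function(features, path) {
  df <- data.frame(subject_id = features$subject_id,
                   session_id = features$session_id,
                   epoch_index = features$epoch_index,
                   features$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map feature positions to electrode pairs
#'
#' For GC the 1024 features are the row-major flattening of the directed
#' matrix, so feature k maps to (source = column, target = row); diagonal
#' positions map to a self-pair. For MI the 496 features map to unordered
#' pairs in strict-upper-triangle row-major order.
#'
#' @param kind `"GC"` or `"MI"`.
#' @param channel_names Character vector of electrode names.
#' @return data.frame with `feature`, `from`, `to`, `self` (logical,
#'   GC diagonal positions).
#' @export
feature_pairs <- function(kind = c("GC", "MI"), channel_names) {
  kind <- match.arg(kind)
  C <- length(channel_names)
  if (kind == "GC") {
    grid <- expand.grid(source = seq_len(C), target = seq_len(C))
    grid <- grid[order(grid$target, grid$source), ]
    data.frame(feature = seq_len(C * C),
               from = channel_names[grid$source],
               to = channel_names[grid$target],
               self = grid$source == grid$target,
               stringsAsFactors = FALSE)
  } else {
    pr <- upper_pairs(C)
    data.frame(feature = seq_len(nrow(pr)),
               from = channel_names[pr[, 1]],
               to = channel_names[pr[, 2]],
               self = FALSE,
               stringsAsFactors = FALSE)
  }
}
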