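#' Score each connectivity feature's contribution to identification
#'
#' An RBF-kernel SVM has no primal per-feature weights, so the contribution
#' of each connection to identification is scored by one of two documented
#' surrogates:
#'
#' * `"linear-ovo"` (default): one binary *linear* margin classifier per
#'   subject pair on the z-scored features; each pair's primal weight vector
#'   `w = t(coefs) %*% SV` is folded in by absolute value, giving one
#'   nonnegative aggregate score per feature.
#' * `"permutation"`: permutation importance of the RBF identifier — each
#'   feature column is shuffled `r` times and the mean drop in accuracy on
#'   the provided epochs is the score (negative drops floored at 0).
#'
#' GC self-pair (diagonal) features are forced to weight 0 in either method.
#'
#' @param features An `fc_features` object (the identification training
#'   set).
#' @param method `"linear-ovo"` or `"permutation"`.
#' @param cost Regularization constant for the underlying classifiers.
#' @param r Shuffle repeats for the permutation method (default 5).
#' @param seed Seed (drives the permutation shuffles; the linear method is
#'   deterministic).
#' @return Object of class `fc_weightmap`: `weights` (nonnegative, one per
#'   feature), `pairs` (the [feature_pairs()] map), `method`, `kind`.
#' @export
feature_weights <- function(features, method = c("linear-ovo", "permutation"),
                            cost = 1, r = 5L, seed = 1L) {
  method <- match.arg(method)
  y <- factor(features$subject_id)
  if (nlevels(y) < 2) stop("need >= 2 subjects")
  if (min(table(y)) < 2) stop("need >= 2 epochs per subject")
  x <- features$values
  d <- ncol(x)
  ch <- features$channel_names
  if (is.null(ch)) ch <- paste0("ch", seq_len(infer_n_channels(features$kind, d)))
  pairs <- feature_pairs(features$kind, ch)
  if (nrow(pairs) != d) {
    # feature count does not correspond to an electrode layout (e.g. ad hoc
    # feature sets): keep the weights, drop the pair mapping
    pairs <- data.frame(feature = seq_len(d), from = NA_character_,
                        to = NA_character_, self = FALSE,
                        stringsAsFactors = FALSE)
  }

  if (method == "linear-ovo") {
    center <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    scl[scl == 0] <- 1
    xs <- scale(x, center = center, scale = scl)
    w <- numeric(d)
    lv <- levels(y)
    for (a in seq_along(lv)) {
      for (b in seq_along(lv)) {
        if (a >= b) next
        sel <- y %in% lv[c(a, b)]
        fit <- e1071::svm(x = xs[sel, , drop = FALSE], y = droplevels(y[sel]),
                          kernel = "linear", cost = cost, scale = FALSE)
        w <- w + abs(as.numeric(crossprod(fit$coefs, fit$SV)))
      }
    }
  } else {
    model <- train_identifier(features, cost = cost, seed = seed)
    base_acc <- mean(predict_identifier(model, features) == y)
    seeds <- derive_seeds(seed, r)
    w <- numeric(d)
    for (rep_i in seq_len(r)) {
      perm <- run_seeded(seeds[rep_i], sample.int(nrow(x)))
      for (f in seq_len(d)) {
        xp <- x
        xp[, f] <- x[perm, f]
        w[f] <- w[f] + (base_acc - mean(predict_identifier(model, xp) == y))
      }
    }
    w <- pmax(w / r, 0)
  }
  w[pairs$self] <- 0
  structure(list(weights = w, pairs = pairs, method = method,
                 kind = features$kind),
            class = "fc_weightmap")
}

infer_n_channels <- function(kind, d) {
  if (kind == "GC") as.integer(round(sqrt(d)))
  else as.integer(round((1 + sqrt(1 + 8 * d)) / 2))
}

#' Extract the top-fraction "major connections"
#'
#' Selects the `round(top_frac * n_valid)` highest-weight valid features
#' (GC self-pairs are never valid). Ties at the selection boundary are
#' broken by lower feature index, so the selection is deterministic.
#'
#' @param weightmap An [feature_weights()] result.
#' @param top_frac Fraction of valid features to keep (default 0.10).
#' @return Object of class `major_connections`: data.frame `pairs`
#'   (`from`, `to`, `weight`, `feature`, strongest first), plus `top_frac`
#'   and `n_valid`.
#' @export
major_connections <- function(weightmap, top_frac = 0.10) {
  stopifnot(top_frac > 0, top_frac <= 1)
  valid <- which(!weightmap$pairs$self)
  n_sel <- round(top_frac * length(valid))
  ord <- valid[order(-weightmap$weights[valid], valid)]
  sel <- ord[seq_len(n_sel)]
  structure(
    list(pairs = data.frame(from = weightmap$pairs$from[sel],
                            to = weightmap$pairs$to[sel],
                            weight = weightmap$weights[sel],
                            feature = sel,
                            stringsAsFactors = FALSE),
         top_frac = top_frac, n_valid = length(valid),
         kind = weightmap$kind),
    class = "major_connections"
  )
}

#' Tabulate major connections by scalp region
#'
#' Counts the selected connections in a 5 x 5 region matrix (frontal,
#' central, temporal, parietal, occipital; intra-region counts on the
#' diagonal) and computes the fraction of connections that are internal to
#' the frontal lobe. For undirected (MI) connections the pair of regions is
#' unordered and counted in the upper triangle; directed (GC) connections
#' count as from-region row, to-region column.
#'
#' @param major A [major_connections()] object (or a data.frame with `from`,
#'   `to` electrode columns).
#' @param montage An `eeg_montage` covering every electrode in the pairs.
#' @return Object of class `region_summary`: `counts` (5 x 5 matrix),
#'   `intra_frontal_fraction`, `n_connections`, `major_pairs`.
#' @export
region_summary <- function(major, montage = standard_montage()) {
  pairs <- if (inherits(major, "major_connections")) major$pairs else major
  directed <- if (inherits(major, "major_connections")) major$kind == "GC" else TRUE
  regions <- scalp_regions()
  unknown <- setdiff(unique(c(pairs$from, pairs$to)), montage$names)
  if (length(unknown) > 0) {
    stop("electrodes not in montage: ", paste(unknown, collapse = ", "))
  }
  counts <- matrix(0L, 5, 5, dimnames = list(from = regions, to = regions))
  rf <- match(montage$region[pairs$from], regions)
  rt <- match(montage$region[pairs$to], regions)
  if (!directed) {
    lo <- pmin(rf, rt); hi <- pmax(rf, rt)
    rf <- lo; rt <- hi
  }
  for (k in seq_along(rf)) counts[rf[k], rt[k]] <- counts[rf[k], rt[k]] + 1L
  structure(
    list(counts = counts,
         intra_frontal_fraction =
           if (nrow(pairs) == 0) NA_real_
           else counts["frontal", "frontal"] / nrow(pairs),
         n_connections = nrow(pairs),
         major_pairs = pairs),
    class = "region_summary"
  )
}

#' @export
print.region_summary <- function(x, ...) {
  cat("<region_summary> ", x$n_connections, " major connections; ",
      "intra-frontal fraction ", round(x$intra_frontal_fraction, 3), "\n",
      sep = "")
  print(x$counts)
  invisible(x)
}

#' Export the ranked edge list of a weight map
#'
#' Tab-separated table with `electrode_from`, `electrode_to`, `weight`,
#' `selected` (whether the edge is a major connection at `top_frac`).
#'
#' @param weightmap An [feature_weights()] result.
#' @param path Output path.
#' @param top_frac Selection fraction for the `selected` flag.
#' @export
write_edge_list <- function(weightmap, path, top_frac = 0.10) {
  major <- major_connections(weightmap, top_frac)
  valid <- !weightmap$pairs$self
  df <- data.frame(electrode_from = weightmap$pairs$from[valid],
                   electrode_to = weightmap$pairs$to[valid],
                   weight = weightmap$weights[valid],
                   selected = weightmap$pairs$feature[valid] %in%
                     major$pairs$feature)
  df <- df[order(-df$weight), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Top-view scalp plot of major connections
#'
#' Draws the montage on the unit disc with electrodes coloured by region and
#' sized by their major-connection degree, and the selected connections as
#' line segments (intra-frontal connections emphasized). Base-graphics
#' figure; intended as a 2-D summary of where the subject-specific
#' connectivity lives.
#'
#' @param major A [major_connections()] object.
#' @param montage An `eeg_montage`.
#' @export
plot_connectome <- function(major, montage = standard_montage()) {
  pos <- montage$positions
  regions <- scalp_regions()
  pal <- stats::setNames(c("#D62728", "#1F77B4", "#2CA02C", "#9467BD",
                           "#FF7F0E"), regions)
  deg <- table(factor(c(major$pairs$from, major$pairs$to),
                      levels = montage$names))
  graphics::plot(NA, xlim = c(-1.15, 1.15), ylim = c(-1.15, 1.15), asp = 1,
                 axes = FALSE, xlab = "", ylab = "",
                 main = "Major connections (top view)")
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(cos(th), sin(th), col = "grey60")
  frontal <- montage$region[major$pairs$from] == "frontal" &
    montage$region[major$pairs$to] == "frontal"
  graphics::segments(pos[major$pairs$from, 1], pos[major$pairs$from, 2],
                     pos[major$pairs$to, 1], pos[major$pairs$to, 2],
                     col = ifelse(frontal, pal["frontal"], "grey70"),
                     lwd = ifelse(frontal, 2, 1))
  graphics::points(pos[, 1], pos[, 2], pch = 21,
                   bg = pal[montage$region[montage$names]],
                   cex = 0.8 + 2.2 * as.numeric(deg) / max(1, max(deg)))
  graphics::text(pos[, 1], pos[, 2] + 0.07, montage$names, cex = 0.55)
  invisible(NULL)
}
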