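#' Bland-Altman agreement analysis
#'
#' Quantifies the agreement of one feature measured under two conditions
#' (e.g. with and without gaussian postfiltering) on the same subjects:
#' bias = mean of the differences B - A, their sample SD (n - 1
#' denominator) and the 95% limits of agreement `bias +/- 1.96 SD`.
#' Relative statistics (differences divided by the pair means) are also
#' reported, since for SUV-like features the differences tend to grow
#' with the magnitude.
#'
#' @param a,b numeric vectors of paired measurements (condition A and
#'   B), equal length, `n >= 2`.
#' @param labels optional length-2 condition labels.
#' @return A `bland_altman` object: `bias`, `sd_diff`, `loa_lower`,
#'   `loa_upper`, `n`, `mean_pair`, `bias_relative`, `labels`.
#' @export
bland_altman <- function(a, b, labels = c("A", "B")) {
  if (length(a) != length(b)) stop("paired measurements of unequal length")
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 2L) stop("need at least 2 complete pairs")
  d <- b - a
  bias <- mean(d)
  s <- stats::sd(d)
  mp <- (a + b) / 2
  rel <- ifelse(mp != 0, d / mp, NA_real_)
  structure(list(bias = bias, sd_diff = s,
                 loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
                 n = n, mean_pair = mp, diff = d,
                 bias_relative = mean(rel[is.finite(rel)]),
                 labels = labels),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("<bland_altman> n = ", x$n, " (", x$labels[2], " - ", x$labels[1],
      ")\n  bias ", format(x$bias, digits = 4), ", SD ",
      format(x$sd_diff, digits = 4), ", 95% LoA [",
      format(x$loa_lower, digits = 4), ", ",
      format(x$loa_upper, digits = 4), "]\n", sep = "")
  invisible(x)
}

#' @param x a `bland_altman` object.
#' @param ... passed to [graphics::plot()].
#' @rdname bland_altman
#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$mean_pair, x$diff,
                 xlab = paste0("mean of ", x$labels[1], ", ", x$labels[2]),
                 ylab = paste0(x$labels[2], " - ", x$labels[1]), ...)
  graphics::abline(h = x$bias, col = "black")
  graphics::abline(h = c(x$loa_lower, x$loa_upper), col = "red", lty = 3)
  invisible(x)
}

#' Spearman correlogram with hierarchical ordering
#'
#' Absolute Spearman rank correlations between every pair of features
#' (average ranks for ties), plus a row/column ordering from
#' complete-linkage hierarchical clustering on the distance `1 - |r|`,
#' the ordering used to draw a clustered correlogram. Constant features
#' have undefined correlations, reported as `NA` (distance 1 for the
#' clustering).
#'
#' @param table data frame or matrix, subjects x features, `>= 3`
#'   subjects and `>= 2` features.
#' @return A `spearman_matrix` object: `$r` (signed), `$r_abs`,
#'   `$order` (feature ordering), `$hclust`.
#' @export
spearman_matrix <- function(table) {
  x <- as.matrix(table)
  if (!is.numeric(x)) stop("feature table must be numeric")
  if (nrow(x) < 3L || ncol(x) < 2L)
    stop("need >= 3 subjects and >= 2 features")
  r <- suppressWarnings(stats::cor(x, method = "spearman"))
  dmat <- 1 - abs(r)
  dmat[is.na(dmat)] <- 1
  diag(dmat) <- 0
  hc <- stats::hclust(stats::as.dist(dmat), method = "complete")
  structure(list(r = r, r_abs = abs(r), order = hc$order, hclust = hc),
            class = "spearman_matrix")
}

#' @export
print.spearman_matrix <- function(x, ...) {
  cat("<spearman_matrix> ", ncol(x$r), " features; |r| range [",
      format(min(x$r_abs[upper.tri(x$r_abs)], na.rm = TRUE), digits = 3),
      ", ",
      format(max(x$r_abs[upper.tri(x$r_abs)], na.rm = TRUE), digits = 3),
      "]\n", sep = "")
  invisible(x)
}

#' @param x a `spearman_matrix` object.
#' @param ... passed to [graphics::image()].
#' @rdname spearman_matrix
#' @export
plot.spearman_matrix <- function(x, ...) {
  m <- x$r_abs[x$order, x$order]
  graphics::image(seq_len(ncol(m)), seq_len(ncol(m)), t(m[rev(seq_len(ncol(m))), ]),
                  axes = FALSE, xlab = "", ylab = "",
                  zlim = c(0, 1), ...)
  graphics::axis(1, seq_len(ncol(m)), colnames(m), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(ncol(m)), rev(colnames(m)), las = 2, cex.axis = 0.7)
  invisible(x)
}

#' One-way single-score agreement ICC
#'
#' Intraclass correlation from the one-way random-effects ANOVA
#' decomposition (subjects as the only factor), single-score agreement
#' form: `ICC(1,1) = (MSB - MSW) / (MSB + (k - 1) MSW)` with `MSB` and
#' `MSW` the between- and within-subject mean squares and `k` the number
#' of raters. Estimates `var_subject / (var_subject + var_error)`.
#'
#' @param ratings numeric matrix or data frame, subjects x raters,
#'   complete, `>= 2` subjects and `>= 2` raters.
#' @return An `icc_result`: `icc`, `msb`, `msw`, `n`, `k`, `degenerate`
#'   (both mean squares zero).
#' @export
icc_oneway <- function(ratings) {
  x <- as.matrix(ratings)
  if (anyNA(x)) stop("ratings table must be complete")
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 raters")
  df <- data.frame(y = as.vector(x),
                   subject = factor(rep(seq_len(n), times = k)))
  # F-test warnings on perfect fits are irrelevant: only mean squares used
  aov_tab <- suppressWarnings(stats::anova(stats::lm(y ~ subject, data = df)))
  msb <- aov_tab["subject", "Mean Sq"]
  msw <- aov_tab["Residuals", "Mean Sq"]
  degenerate <- msb < .Machine$double.eps && msw < .Machine$double.eps
  icc <- if (degenerate) 0 else (msb - msw) / (msb + (k - 1) * msw)
  structure(list(icc = icc, msb = msb, msw = msw, n = n, k = k,
                 degenerate = degenerate),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat("<icc_result> ICC(1,1) = ", format(x$icc, digits = 4), " (", x$n,
      " subjects, ", x$k, " raters)",
      if (x$degenerate) " [degenerate: no variance]", "\n", sep = "")
  invisible(x)
}

#' Per-feature robustness report
#'
#' Runs [bland_altman()] for every shared numeric feature of two
#' same-subject tables (condition A and condition B) and summarizes
#' agreement on a comparable scale: |bias| relative to the mean feature
#' magnitude and the relative width of the limits of agreement. This is
#' the threshold-free comparison used to ask whether displacement
#' features (NHOC/NHOP) are more robust to an image perturbation than
#' SUV-based ones.
#'
#' @param table_a,table_b data frames with identical subject order and
#'   shared numeric feature columns.
#' @param features optional character vector of features to compare
#'   (default: all shared numeric columns).
#' @return data frame: feature, bias, sd_diff, loa_lower, loa_upper,
#'   abs_bias_over_mean, loa_width_over_mean, n.
#' @export
robustness_report <- function(table_a, table_b, features = NULL) {
  if (is.null(features)) {
    features <- intersect(names(table_a), names(table_b))
    features <- features[vapply(table_a[features], is.numeric, logical(1))]
  }
  if (length(features) == 0L) stop("no shared numeric features")
  rows <- lapply(features, function(f) {
    ba <- bland_altman(table_a[[f]], table_b[[f]], labels = c("A", "B"))
    scale <- mean(abs(c(table_a[[f]], table_b[[f]])), na.rm = TRUE)
    data.frame(feature = f, bias = ba$bias, sd_diff = ba$sd_diff,
               loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
               abs_bias_over_mean = if (scale > 0) abs(ba$bias) / scale else NA,
               loa_width_over_mean = if (scale > 0)
                 (ba$loa_upper - ba$loa_lower) / scale else NA,
               n = ba$n)
  })
  do.call(rbind, rows)
}
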