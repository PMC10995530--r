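check_records <- function(records) {
  if (!is.data.frame(records)) stop("'records' must be a data frame")
  tcol <- intersect(c("time_months", "time"), names(records))[1]
  if (is.na(tcol) || !("event" %in% names(records)))
    stop("'records' needs a time ('time_months' or 'time') and an 'event' column")
  time <- records[[tcol]]
  event <- records[["event"]]
  if (any(!is.finite(time)) || any(time <= 0))
    stop("survival times must be positive and finite")
  if (!all(event %in% c(0, 1))) stop("event indicator must be 0/1")
  list(time = as.numeric(time), event = as.integer(event))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function from right-censored
#' follow-up (time from baseline scan to death or last follow-up, event
#' 1 = death, 0 = censored). Backed by [survival::survfit()].
#'
#' @param records data frame with columns `time_months` (or `time`) and
#'   `event`.
#' @return A `km_curve`: `$time` (event-time grid), `$surv`
#'   (non-increasing, starts at 1 at time 0), `$n_risk`, `$n_event`,
#'   `$median` (smallest time with survival <= 0.5, `NA` if never
#'   reached), and the underlying `$fit`.
#' @export
km_estimate <- function(records) {
  te <- check_records(records)
  fit <- survival::survfit(survival::Surv(te$time, te$event) ~ 1,
                           conf.type = "none")
  med <- unname(summary(fit)$table["median"])
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, median = med, n = length(te$time),
                 fit = fit),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("<km_curve> n = ", x$n, ", ", sum(x$n_event), " events, median ",
      if (is.na(x$median)) "not reached" else format(x$median, digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' @param x a `km_curve`.
#' @param ... passed to `plot.survfit`.
#' @rdname km_estimate
#' @export
plot.km_curve <- function(x, ...) {
  graphics::plot(x$fit, xlab = "time (months)", ylab = "survival", ...)
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard 1-degree-of-freedom log-rank test (hypergeometric variance,
#' via [survival::survdiff()]); symmetric in the group order. A
#' comparison with no events at all is degenerate and flagged.
#'
#' @param records data frame with time/event columns.
#' @param group logical or 2-level vector assigning each record to a
#'   group; both groups must be non-empty.
#' @return A `logrank_test`: `chi_square`, `p_value`, `n` per group,
#'   `degenerate`.
#' @export
logrank_test <- function(records, group) {
  te <- check_records(records)
  g <- as.factor(group)
  if (nlevels(g) != 2L) stop("'group' must have exactly 2 non-empty levels")
  if (sum(te$event) == 0L) {
    return(structure(list(chi_square = 0, p_value = 1,
                          n = table(g), degenerate = TRUE),
                     class = "logrank_test"))
  }
  sd <- survival::survdiff(survival::Surv(te$time, te$event) ~ g)
  structure(list(chi_square = sd$chisq,
                 p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
                 n = table(g), degenerate = FALSE),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat("<logrank_test> chi-square = ", format(x$chi_square, digits = 4),
      ", p = ", format(x$p_value, digits = 3),
      if (x$degenerate) " [degenerate: no events]", "\n", sep = "")
  invisible(x)
}

# log-rank scores: event - Nelson-Aalen cumulative hazard at follow-up
logrank_scores <- function(time, event) {
  n <- length(time)
  ord <- order(time)
  ts <- time[ord]; ev <- event[ord]
  grp <- cumsum(!duplicated(ts))          # unique-time group per subject
  first <- which(!duplicated(ts))         # first sorted index per group
  d <- as.vector(tapply(ev, grp, sum))    # deaths at each unique time
  n_at_risk <- n - first + 1L
  cumhaz <- cumsum(d / n_at_risk)
  scores <- numeric(n)
  scores[ord] <- ev - cumhaz[grp]
  scores
}

#' Maximally selected rank statistics cutoff
#'
#' Dichotomizes a continuous feature at the cutoff maximizing the
#' standardized two-sample log-rank statistic over all admissible
#' cutpoints (every midpoint between consecutive distinct feature
#' values keeping both groups at least `minprop` of the cohort). The
#' statistic uses log-rank scores `a_i = event_i - H(t_i)` (Nelson-Aalen
#' cumulative hazard at the follow-up time) with their exact conditional
#' permutation mean and variance. Because the cutoff is optimized, the
#' naive log-rank p-value is invalid; the p-value is computed by seeded
#' permutation of the feature values (the maximum statistic is
#' recomputed for each permutation).
#'
#' The direction sign follows which side of the cutoff has poorer
#' survival: `"+"` means values above the cutoff are associated with
#' poor survival (Kaplan-Meier medians compared; excess-mortality score
#' sign used when both medians are undefined).
#'
#' @param records data frame with time/event columns and the feature.
#' @param feature feature column name, or a numeric vector aligned with
#'   `records`.
#' @param minprop minimum fraction of subjects on each side of an
#'   admissible cutoff (default 0.10; 0 admits all cutpoints).
#' @param n_perm number of permutations for the p-value (default 1000;
#'   0 skips it).
#' @param seed integer seed for the permutation p-value.
#' @return A `cutoff_result`: `cutoff`, `statistic` (standardized,
#'   absolute), `p_value`, `direction` (`"+"`/`"-"`), `n_low`, `n_high`,
#'   `c_index` (Harrell C of the feature as an increasing risk score),
#'   `feature` name.
#' @export
maxstat_cutoff <- function(records, feature, minprop = 0.10,
                           n_perm = 1000L, seed = NULL) {
  te <- check_records(records)
  x <- if (is.character(feature)) records[[feature]] else feature
  fname <- if (is.character(feature)) feature else deparse(substitute(feature))
  if (is.null(x)) stop("feature '", fname, "' not found")
  if (length(x) != length(te$time)) stop("feature length mismatch")
  if (length(unique(x)) < 2L) stop("all feature values are equal")
  if (sum(te$event) == 0L) stop("no event; cutoff selection undefined")
  n <- length(x)
  a <- logrank_scores(te$time, te$event)
  ord <- order(x)
  xs <- x[ord]
  ks <- which(xs[-n] < xs[-1])  # group sizes at distinct-value boundaries
  ks <- ks[ks >= max(1, ceiling(minprop * n)) & ks <= n - max(1, ceiling(minprop * n))]
  if (length(ks) == 0L) stop("no admissible cutoff for minprop = ", minprop)
  stat_all <- function(asort) {
    s <- cumsum(asort)[ks]
    abar <- mean(asort)
    v <- ks * (n - ks) / (n * (n - 1)) * sum((asort - abar)^2)
    (s - ks * abar) / sqrt(v)
  }
  tk <- stat_all(a[ord])
  best <- which.max(abs(tk))
  k <- ks[best]
  cutoff <- (xs[k] + xs[k + 1]) / 2
  obs <- abs(tk[best])

  p <- NA_real_
  if (n_perm > 0L) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(seed)
    }
    perm_max <- vapply(seq_len(n_perm), function(i)
      max(abs(stat_all(sample(a)))), numeric(1))
    p <- (1 + sum(perm_max >= obs - 1e-12)) / (n_perm + 1)
  }

  low <- x <= cutoff
  med_low <- km_estimate(data.frame(time = te$time, event = te$event)[low, ])$median
  med_high <- km_estimate(data.frame(time = te$time, event = te$event)[!low, ])$median
  direction <- if (is.na(med_low) && is.na(med_high)) {
    if (tk[best] > 0) "-" else "+"  # excess mortality in the low group -> "-"
  } else if (is.na(med_high)) "-"
  else if (is.na(med_low)) "+"
  else if (med_high < med_low) "+" else "-"

  ci <- concordance_index(records, x, direction = "increasing")
  structure(list(cutoff = cutoff, statistic = obs, p_value = p,
                 direction = direction, n_low = sum(low),
                 n_high = sum(!low), c_index = ci$c_index,
                 feature = fname, minprop = minprop, n_perm = n_perm),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat("<cutoff_result> ", x$feature, ": cutoff ", format(x$cutoff, digits = 4),
      " (", x$n_low, "/", x$n_high, "), |T| = ",
      format(x$statistic, digits = 4), ", perm p = ",
      format(x$p_value, digits = 3), ", direction ", x$direction,
      ", C-index ", format(x$c_index, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Harrell concordance index
#'
#' Probability that, of two comparable subjects, the one with the
#' higher risk score fails first. Usable pairs are those where the
#' earlier follow-up time is an event; ties in the risk score count
#' 0.5. `direction = "increasing"` treats larger feature values as
#' higher risk; `"decreasing"` the opposite.
#'
#' @param records data frame with time/event columns.
#' @param feature feature column name or numeric vector.
#' @param direction `"increasing"` or `"decreasing"`.
#' @return A `concordance_result`: `c_index`, `n_pairs` (usable),
#'   `concordant`, `tied`.
#' @export
concordance_index <- function(records, feature,
                              direction = c("increasing", "decreasing")) {
  direction <- match.arg(direction)
  te <- check_records(records)
  x <- if (is.character(feature)) records[[feature]] else feature
  if (direction == "decreasing") x <- -x
  n <- length(x)
  dt <- outer(te$time, te$time, `<`)  # dt[i,j]: i fails strictly first
  usable <- dt & matrix(te$event == 1L, n, n)  # earlier time is an event
  dx <- outer(x, x, `-`)  # risk_i - risk_j
  conc <- sum(usable & dx > 0)
  tied <- sum(usable & dx == 0)
  np <- sum(usable)
  if (np == 0L) stop("no usable pair (need an event before another follow-up)")
  structure(list(c_index = (conc + 0.5 * tied) / np, n_pairs = np,
                 concordant = conc, tied = tied),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("<concordance_result> C = ", format(x$c_index, digits = 4), " over ",
      x$n_pairs, " usable pairs\n", sep = "")
  invisible(x)
}

#' Three-category bivariate risk stratification
#'
#' Combines two dichotomized features into risk categories 0, 1, 2 =
#' number of unfavorable feature states (a state is unfavorable when the
#' value lies on the poor-survival side of its cutoff, as given by the
#' direction sign). The three pairwise survival comparisons are tested
#' by log-rank with Benjamini-Hochberg adjustment of the p-values.
#'
#' @param records data frame with time/event and both features.
#' @param feature_a,feature_b feature column names.
#' @param cutoff_a,cutoff_b the dichotomizing cutoffs.
#' @param sign_a,sign_b `"+"` (high value unfavorable) or `"-"`.
#' @return A `risk_categories` result: `category` (per-subject 0/1/2),
#'   `counts`, `tests` (data frame of pairwise comparisons with raw and
#'   BH-adjusted p-values; empty-category comparisons are flagged
#'   `skipped`).
#' @export
risk_categories <- function(records, feature_a, cutoff_a, sign_a,
                            feature_b, cutoff_b, sign_b) {
  te <- check_records(records)
  unfav <- function(x, cutoff, sgn) {
    if (!sgn %in% c("+", "-")) stop("direction sign must be '+' or '-'")
    if (sgn == "+") x > cutoff else x <= cutoff
  }
  ua <- unfav(records[[feature_a]], cutoff_a, sign_a)
  ub <- unfav(records[[feature_b]], cutoff_b, sign_b)
  category <- as.integer(ua) + as.integer(ub)
  pairs <- list(c(0L, 1L), c(0L, 2L), c(1L, 2L))
  rows <- lapply(pairs, function(pr) {
    sel <- category %in% pr
    na <- sum(category == pr[1]); nb <- sum(category == pr[2])
    if (na == 0L || nb == 0L)
      return(data.frame(group_a = pr[1], group_b = pr[2], n_a = na, n_b = nb,
                        chi_square = NA, p_raw = NA, skipped = TRUE))
    lr <- logrank_test(data.frame(time = te$time, event = te$event)[sel, ],
                       category[sel] == pr[2])
    data.frame(group_a = pr[1], group_b = pr[2], n_a = na, n_b = nb,
               chi_square = lr$chi_square, p_raw = lr$p_value,
               skipped = FALSE)
  })
  tests <- do.call(rbind, rows)
  tests$p_adjusted <- stats::p.adjust(tests$p_raw, method = "BH")
  structure(list(category = category, counts = table(factor(category, 0:2)),
                 tests = tests),
            class = "risk_categories")
}

#' @export
print.risk_categories <- function(x, ...) {
  cat("<risk_categories> counts:",
      paste(paste0(names(x$counts), ":", x$counts), collapse = " "), "\n")
  print(x$tests)
  invisible(x)
}

#' Wilcoxon rank-sum group comparison
#'
#' Two-sided rank-sum test with average ranks for ties, via
#' [stats::wilcox.test()]: exact enumeration for small tie-free samples,
#' normal approximation with tie correction otherwise. Used to compare
#' feature values between lesions with and without necrotic cores.
#'
#' @param a,b numeric value vectors for the two groups (non-empty).
#' @return list with `statistic` (rank-sum W of group `a`), `p_value`,
#'   `exact` (whether the exact distribution was used).
#' @export
wilcoxon_ranksum <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  has_ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !has_ties && length(a) < 50L && length(b) < 50L
  wt <- stats::wilcox.test(a, b, exact = exact, correct = !exact)
  list(statistic = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}

#' Per-feature survival screening table
#'
#' Runs [maxstat_cutoff()] on each requested feature and assembles the
#' screening table: selected cutoff, permutation p-value, direction of
#' the unfavorable side, and Harrell C-index.
#'
#' @param records data frame with time/event and feature columns.
#' @param features character vector of feature column names.
#' @inheritParams maxstat_cutoff
#' @return data frame with one row per feature.
#' @export
survival_table <- function(records, features, minprop = 0.10,
                           n_perm = 1000L, seed = NULL) {
  rows <- lapply(seq_along(features), function(i) {
    cr <- maxstat_cutoff(records, features[i], minprop = minprop,
                         n_perm = n_perm,
                         seed = if (is.null(seed)) NULL else seed + i)
    data.frame(feature = cr$feature, cutoff = cr$cutoff,
               statistic = cr$statistic, p_value = cr$p_value,
               direction = cr$direction, c_index = cr$c_index,
               n_low = cr$n_low, n_high = cr$n_high)
  })
  do.call(rbind, rows)
}
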