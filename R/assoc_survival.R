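#' Direction concordance between qPCR and aCGH
#'
#' A sample is direction-consistent when the sign of its qPCR log2 fold
#' change equals the sign of its aCGH mean log2 ratio. Values with absolute
#' magnitude at most `epsilon` are treated as zero, and zero only matches
#' zero. The default `epsilon = 0` is the strict sign rule.
#'
#' @param log2_qpcr,log2_acgh paired finite log2 values.
#' @param epsilon non-negative dead zone around zero.
#' @return list with `n`, `n_consistent`, `n_inconsistent` and the logical
#'   per-sample `consistent` vector.
#' @export
direction_concordance <- function(log2_qpcr, log2_acgh, epsilon = 0) {
  if (epsilon < 0) stop("epsilon must be >= 0")
  stopifnot(length(log2_qpcr) == length(log2_acgh),
            all(is.finite(log2_qpcr)), all(is.finite(log2_acgh)))
  sgn <- function(x) sign(x) * (abs(x) > epsilon)
  consistent <- sgn(log2_qpcr) == sgn(log2_acgh)
  list(n = length(consistent),
       n_consistent = sum(consistent),
       n_inconsistent = sum(!consistent),
       consistent = consistent)
}

#' Pearson correlation with test
#'
#' Product-moment correlation with the two-sided t test on n - 2 degrees of
#' freedom, as used to compare platform-level log2 copy-number values.
#'
#' @param x,y paired numeric vectors.
#' @return list with `r`, `p_value`, `n`.
#' @export
pearson_cor <- function(x, y) {
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks (ties averaged); used for copy number vs
#' mRNA expression.
#'
#' @param x,y paired numeric vectors.
#' @return list with `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate via [survival::survfit()]; the returned table has
#' one row per distinct observed time.
#'
#' @param times follow-up times (months).
#' @param events event indicators (1 = event, 0 = censored).
#' @return data.frame `time`, `n_risk`, `n_event`, `n_censor`, `surv`.
#' @export
km_curve <- function(times, events) {
  fit <- survfit(Surv(times, events) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

#' Log-rank test and Mantel-Haenszel hazard ratio for two groups
#'
#' The log-rank chi-square (1 df, hypergeometric variance with ties) is
#' computed with [survival::survdiff()]. The hazard ratio is the
#' Mantel-Haenszel estimate \eqn{(O_1/E_1)/(O_2/E_2)} from the observed and
#' expected event counts, with the 95% CI
#' \eqn{\exp(\ln HR \pm 1.96 \sqrt{1/E_1 + 1/E_2})}; this matches common
#' commercial survival-analysis output. `method = "cox"` substitutes the
#' Cox proportional-hazards estimate as a sensitivity option. A group with
#' zero expected events yields a flagged, not-computable HR.
#'
#' @param time1,event1 follow-up and event indicator of group 1.
#' @param time2,event2 follow-up and event indicator of group 2.
#' @param labels group labels (group 1 first); HR is group1 / group2.
#' @param method `"mantel-haenszel"` (default) or `"cox"`.
#' @return object of class `survival_comparison`: group sizes and events,
#'   `logrank_chi2`, `logrank_p`, `hr`, `hr_ci95`, `hr_computable`, per-group
#'   KM curves.
#' @export
logrank_and_hr <- function(time1, event1, time2, event2,
                           labels = c("group1", "group2"),
                           method = c("mantel-haenszel", "cox")) {
  method <- match.arg(method)
  df <- data.frame(time = c(time1, time2), event = c(event1, event2),
                   group = factor(rep(labels, c(length(time1), length(time2))),
                                  levels = labels))
  sd_ <- survdiff(Surv(time, event) ~ group, data = df)
  chi2 <- sd_$chisq
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  O <- sd_$obs; E <- sd_$exp
  computable <- all(E > 0)
  if (computable && method == "mantel-haenszel") {
    hr <- (O[1] / E[1]) / (O[2] / E[2])
    se <- sqrt(1 / E[1] + 1 / E[2])
    ci <- exp(log(hr) + c(-1, 1) * qnorm(0.975) * se)
    if (!is.finite(hr) || hr <= 0) computable <- FALSE
  } else if (computable) {
    cx <- coxph(Surv(time, event) ~ group, data = df)
    # coxph contrasts group2 vs group1; invert to report group1/group2
    hr <- exp(-unname(coef(cx)[1]))
    se <- sqrt(unname(cx$var[1, 1]))
    ci <- exp(log(hr) + c(-1, 1) * qnorm(0.975) * se)
    if (!is.finite(hr)) computable <- FALSE
  }
  if (!computable) { hr <- NA_real_; ci <- c(NA_real_, NA_real_) }
  structure(list(
    labels = labels,
    n = c(length(time1), length(time2)),
    observed = unname(O), expected = unname(E),
    logrank_chi2 = unname(chi2), logrank_p = unname(p),
    hr = unname(hr), hr_ci95 = unname(ci), hr_computable = computable,
    method = method,
    km = list(km_curve(time1, event1), km_curve(time2, event2))),
    class = "survival_comparison")
}

#' @export
print.survival_comparison <- function(x, ...) {
  cat(sprintf("Survival comparison (%s vs %s)\n", x$labels[1], x$labels[2]))
  cat(sprintf("  n = %d vs %d; events %d vs %d\n",
              x$n[1], x$n[2], round(x$observed[1]), round(x$observed[2])))
  cat(sprintf("  log-rank chi2 = %.3f (1 df), p = %.4g\n", x$logrank_chi2, x$logrank_p))
  if (x$hr_computable) {
    cat(sprintf("  HR (%s) = %.3f, 95%% CI %.3f-%.3f\n",
                x$method, x$hr, x$hr_ci95[1], x$hr_ci95[2]))
  } else cat("  HR not computable (a group has no expected events)\n")
  invisible(x)
}

#' @export
plot.survival_comparison <- function(x, xlab = "Time (months)",
                                     ylab = "Survival probability", ...) {
  km_step <- function(km) {
    list(x = c(0, rep(km$time, each = 2)),
         y = c(1, 1, rep(km$surv, each = 2)[-(2 * nrow(km))]))
  }
  s1 <- km_step(x$km[[1]]); s2 <- km_step(x$km[[2]])
  graphics::plot(range(c(s1$x, s2$x)), c(0, 1), type = "n",
                 xlab = xlab, ylab = ylab, ...)
  graphics::lines(s1$x, s1$y, col = 2, lwd = 2)
  graphics::lines(s2$x, s2$y, col = 1, lwd = 2)
  graphics::legend("bottomleft", legend = x$labels, col = c(2, 1), lwd = 2, bty = "n")
  invisible(x)
}

#' Compare survival between two copy-state groups
#'
#' Joins copy-state calls with the clinical table and compares the two
#' requested states (default AMPLIFICATION vs DIPLOID; samples in other
#' states are excluded, mirroring an amplified-vs-diploid contrast).
#'
#' @param states data.frame with `sample_id` and `state` (e.g. a
#'   `fold_change_table` or [locus_states()] output).
#' @param clinical clinical table (see [read_clinical_table()]).
#' @param endpoint `"mfs"` (metastasis-free) or `"os"` (overall survival).
#' @param groups two states to contrast, group 1 first.
#' @param method HR estimator, see [logrank_and_hr()].
#' @return a `survival_comparison`.
#' @export
survival_by_state <- function(states, clinical, endpoint = c("mfs", "os"),
                              groups = c("AMPLIFICATION", "DIPLOID"),
                              method = "mantel-haenszel") {
  endpoint <- match.arg(endpoint)
  tcol <- paste0(endpoint, "_time"); ecol <- paste0(endpoint, "_event")
  m <- merge(states[, c("sample_id", "state")], clinical, by = "sample_id")
  g1 <- m[m$state == groups[1], , drop = FALSE]
  g2 <- m[m$state == groups[2], , drop = FALSE]
  if (nrow(g1) == 0 || nrow(g2) == 0) stop("empty copy-state group for survival")
  logrank_and_hr(g1[[tcol]], g1[[ecol]], g2[[tcol]], g2[[ecol]],
                 labels = groups, method = method)
}
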