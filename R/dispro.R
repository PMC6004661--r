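#' BCPNN prior pseudo-counts
#'
#' Priors of the original Bayesian confidence propagation neural network
#' information component: Dirichlet pseudo-counts `alpha1`, `beta1` for the
#' two margins with prior totals `alpha`, `beta`, and `gamma11` for the
#' joint cell. The defaults (1, 1, 2, 2, 1) are the classical choice that
#' shrinks the IC of an unreported pair to 0 bits.
#'
#' @param alpha1,beta1 marginal prior pseudo-counts (default 1).
#' @param alpha,beta marginal prior totals (default 2).
#' @param gamma11 joint prior pseudo-count (default 1).
#' @return A list of class `bcpnn_priors`.
#' @export
bcpnn_priors <- function(alpha1 = 1, beta1 = 1, alpha = 2, beta = 2, gamma11 = 1) {
  p <- list(alpha1 = alpha1, beta1 = beta1, alpha = alpha, beta = beta, gamma11 = gamma11)
  if (any(unlist(p) <= 0)) stop_fmt("all BCPNN prior pseudo-counts must be > 0")
  structure(p, class = "bcpnn_priors")
}

#' Reporting odds ratio with Woolf confidence interval
#'
#' `ROR = ad/bc`; the interval is the log-normal (Woolf) one,
#' `exp(log(ROR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#' Any zero cell leaves the ratio and interval undefined (`NA`), the
#' convention used when such rows are rendered as dashes.
#'
#' @param tab a [contingency_table()].
#' @param z normal quantile for the interval (default 1.96, a 95% CI).
#' @return A named list: `ror`, `lo`, `hi` (all `NA` if any cell is 0).
#' @examples
#' ror_ci(contingency_table(36, 393, 618, 37840))  # 5.61 (3.95-7.96)
#' @export
ror_ci <- function(tab, z = 1.96) {
  stopifnot(inherits(tab, "contingency_table"))
  if (min(tab$a, tab$b, tab$c, tab$d) == 0)
    return(list(ror = NA_real_, lo = NA_real_, hi = NA_real_))
  r <- (tab$a * tab$d) / (tab$b * tab$c)
  se <- sqrt(1 / tab$a + 1 / tab$b + 1 / tab$c + 1 / tab$d)
  list(ror = r, lo = exp(log(r) - z * se), hi = exp(log(r) + z * se))
}

#' Proportional reporting ratio
#'
#' `PRR = (a/(a+b)) / (c/(c+d))`. Undefined (`NA`) when the target drug has
#' no reports or the comparator has no target events.
#'
#' @inheritParams ror_ci
#' @return A single numeric, `NA` if undefined.
#' @export
prr <- function(tab) {
  stopifnot(inherits(tab, "contingency_table"))
  if (tab$a + tab$b == 0 || tab$c == 0 || tab$c + tab$d == 0) return(NA_real_)
  (tab$a / (tab$a + tab$b)) / (tab$c / (tab$c + tab$d))
}

#' Pearson chi-square statistic of the 2x2 table
#'
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`; with `yates = TRUE` the
#' continuity-corrected version replaces `|ad - bc|` by
#' `max(0, |ad - bc| - N/2)`.
#'
#' @inheritParams ror_ci
#' @param yates apply the Yates continuity correction.
#' @return The statistic (1 d.f.), `NA` when any marginal is zero.
#' @export
pearson_chi2 <- function(tab, yates = FALSE) {
  stopifnot(inherits(tab, "contingency_table"))
  m <- c(tab$a + tab$b, tab$c + tab$d, tab$a + tab$c, tab$b + tab$d)
  if (any(m == 0)) return(NA_real_)
  dev <- abs(tab$a * tab$d - tab$b * tab$c)
  if (yates) dev <- max(0, dev - tab$N / 2)
  tab$N * dev^2 / prod(m)
}

#' BCPNN information component with credible bounds
#'
#' Closed-form posterior expectation and variance of the information
#' component `IC = log2 P(drug, event) / (P(drug) P(event))` under the
#' original BCPNN Dirichlet model. With counts `cxy = a`, `cx = n1+`,
#' `cy = n+1`, `C = N` and priors as in [bcpnn_priors()]:
#'
#' `gamma = gamma11 (C+alpha)(C+beta) / ((cx+alpha1)(cy+beta1))`
#' (the data-dependent joint prior total that centres a null pair at 0),
#'
#' `E(IC) = log2 [ (cxy+gamma11)(C+alpha)(C+beta) /
#'                 ((C+gamma)(cx+alpha1)(cy+beta1)) ]`,
#'
#' and `V(IC)` is the delta-method posterior variance; the bounds are
#' `E(IC) +/- k sqrt(V(IC))` with `k = 2` posterior standard deviations.
#'
#' The shrinkage is defined for every table including zero cells; callers
#' report the IC as not evaluable when `a = 0` (dash convention).
#'
#' @inheritParams ror_ci
#' @param priors a [bcpnn_priors()].
#' @param k half-width of the credible interval in posterior s.d. units.
#' @return A named list: `ic`, `lo`, `hi` (bits).
#' @examples
#' ic_ci(contingency_table(36, 393, 618, 37840))  # 2.17 (1.66-2.67)
#' @export
ic_ci <- function(tab, priors = bcpnn_priors(), k = 2) {
  stopifnot(inherits(tab, "contingency_table"), inherits(priors, "bcpnn_priors"))
  cxy <- tab$a; cx <- tab$n1plus; cy <- tab$nplus1; C <- tab$N
  a1 <- priors$alpha1; b1 <- priors$beta1
  al <- priors$alpha;  be <- priors$beta; g11 <- priors$gamma11
  g <- g11 * (C + al) * (C + be) / ((cx + a1) * (cy + b1))
  e_ic <- log2((cxy + g11) * (C + al) * (C + be) /
                 ((C + g) * (cx + a1) * (cy + b1)))
  v_ic <- (1 / log(2)^2) * (
    (C - cxy + g - g11) / ((cxy + g11) * (1 + C + g)) +
    (C - cx + al - a1)  / ((cx + a1) * (1 + C + al)) +
    (C - cy + be - b1)  / ((cy + b1) * (1 + C + be)))
  list(ic = e_ic, lo = e_ic - k * sqrt(v_ic), hi = e_ic + k * sqrt(v_ic))
}

#' Signal value
#'
#' `ln(PRR) + ln(chi-square)`, the scalar used to compare association
#' strength between two strata. Undefined (`NA`) when the PRR is zero or
#' undefined, or the chi-square statistic is zero.
#'
#' @inheritParams pearson_chi2
#' @return A single numeric, `NA` if undefined.
#' @export
signal_value <- function(tab, yates = FALSE) {
  p <- prr(tab)
  x2 <- pearson_chi2(tab, yates = yates)
  if (is.na(p) || is.na(x2) || p <= 0 || x2 <= 0) return(NA_real_)
  log(p) + log(x2)
}

#' Compare signal values between two strata
#'
#' One stratum dominates when its signal value exceeds twice the other's
#' (strict inequality); otherwise no difference is declared. `NA` input
#' gives `"not_evaluable"`.
#'
#' @param sv_a,sv_b signal values of the two strata.
#' @return One of `"a_dominant"`, `"b_dominant"`, `"no_difference"`,
#'   `"not_evaluable"`.
#' @examples
#' compare_signal_values(7.26, 3.46)  # a_dominant
#' compare_signal_values(6.33, 4.71)  # no_difference
#' @export
compare_signal_values <- function(sv_a, sv_b) {
  if (is.na(sv_a) || is.na(sv_b)) return("not_evaluable")
  if (sv_a > 2 * sv_b) "a_dominant"
  else if (sv_b > 2 * sv_a) "b_dominant"
  else "no_difference"
}

#' Disproportionality analysis of one drug-event pair
#'
#' The central estimator: from a 2x2 case/non-case table computes the
#' reporting odds ratio with its Woolf 95% interval, the proportional
#' reporting ratio, the Pearson chi-square statistic, the BCPNN
#' information component with 2-s.d. credible bounds, the signal value,
#' and the detection flags:
#'
#' * signal: lower ROR bound > 1 (ROR criterion), lower IC bound > 0
#'   (IC criterion); "both signals" when both hold;
#' * inverse signal: upper ROR bound < 1 and upper IC bound < 0.
#'
#' Rows with a zero cell have undefined ROR/PRR/signal value and a
#' non-evaluable IC (`evaluable = FALSE`), printed as dashes.
#'
#' @param tab a [contingency_table()], e.g. from [build_table()] or
#'   [table_from_marginals()].
#' @param priors a [bcpnn_priors()].
#' @param z normal quantile for the ROR interval.
#' @param k credible half-width for the IC interval, posterior s.d. units.
#' @param yates Yates continuity correction for the chi-square used in the
#'   signal value.
#' @return An object of class `dispro` with components `table`, `ror`,
#'   `ror_lo`, `ror_hi`, `prr`, `chi2`, `ic`, `ic_lo`, `ic_hi`,
#'   `signal_value`, logical flags `signal_ror`, `signal_ic`,
#'   `inverse_ror`, `inverse_ic`, `signal_both`, and `evaluable`.
#' @examples
#' fit <- dispro(table_from_marginals(36, 429, 654, 38887, target = "GLP-1-RAs"))
#' fit
#' coef(fit)
#' @export
dispro <- function(tab, priors = bcpnn_priors(), z = 1.96, k = 2, yates = FALSE) {
  stopifnot(inherits(tab, "contingency_table"))
  r <- ror_ci(tab, z = z)
  i <- ic_ci(tab, priors = priors, k = k)
  evaluable <- tab$a > 0
  if (!evaluable) i <- list(ic = NA_real_, lo = NA_real_, hi = NA_real_)
  res <- list(
    table = tab,
    target = tab$target, event = tab$event,
    ror = r$ror, ror_lo = r$lo, ror_hi = r$hi,
    prr = prr(tab), chi2 = pearson_chi2(tab, yates = yates),
    ic = i$ic, ic_lo = i$lo, ic_hi = i$hi,
    signal_value = signal_value(tab, yates = yates),
    evaluable = evaluable,
    signal_ror = isTRUE(r$lo > 1),
    signal_ic = isTRUE(i$lo > 0),
    inverse_ror = isTRUE(r$hi < 1),
    inverse_ic = isTRUE(i$hi < 0))
  res$signal_both <- res$signal_ror && res$signal_ic
  class(res) <- "dispro"
  res
}

#' @export
print.dispro <- function(x, digits = 2, ...) {
  lab <- paste(c(x$target, x$event)[!is.na(c(x$target, x$event))], collapse = " x ")
  cat("Disproportionality analysis", if (nzchar(lab)) paste0(": ", lab), "\n", sep = "")
  cat(sprintf("  n11 = %d, n1+ = %d, n+1 = %d, N = %d\n",
              x$table$a, x$table$n1plus, x$table$nplus1, x$table$N))
  cat(sprintf("  ROR %s (%s-%s)   IC %s (%s-%s) bits\n",
              fmt_est(x$ror, digits), fmt_est(x$ror_lo, digits), fmt_est(x$ror_hi, digits),
              fmt_est(x$ic, digits), fmt_est(x$ic_lo, digits), fmt_est(x$ic_hi, digits)))
  cat(sprintf("  PRR %s, chi-square %s, signal value %s\n",
              fmt_est(x$prr, digits), fmt_est(x$chi2, digits),
              fmt_est(x$signal_value, digits)))
  flag <- if (!x$evaluable) "not evaluable (n11 = 0)"
    else if (x$signal_both) "signal detected (both ROR and IC)"
    else if (x$signal_ror) "signal detected (ROR only)"
    else if (x$signal_ic) "signal detected (IC only)"
    else if (x$inverse_ror && x$inverse_ic) "inverse signal (both ROR and IC)"
    else "no signal"
  cat("  ", flag, "\n", sep = "")
  invisible(x)
}

#' @export
summary.dispro <- function(object, ...) object

#' @export
coef.dispro <- function(object, ...) {
  c(ror = object$ror, prr = object$prr, chi2 = object$chi2, ic = object$ic,
    signal_value = object$signal_value)
}

#' @export
confint.dispro <- function(object, parm, level, ...) {
  m <- matrix(c(object$ror_lo, object$ror_hi, object$ic_lo, object$ic_hi),
              2, byrow = TRUE, dimnames = list(c("ror", "ic"), c("lo", "hi")))
  m
}

#' @export
as.data.frame.dispro <- function(x, ...) {
  data.frame(
    target = x$target, event = x$event,
    n11 = x$table$a, n1plus = x$table$n1plus, nplus1 = x$table$nplus1, N = x$table$N,
    ror = x$ror, ror_lo = x$ror_lo, ror_hi = x$ror_hi,
    prr = x$prr, chi2 = x$chi2,
    ic = x$ic, ic_lo = x$ic_lo, ic_hi = x$ic_hi,
    signal_value = x$signal_value,
    signal_ror = x$signal_ror, signal_ic = x$signal_ic,
    signal_both = x$signal_both,
    inverse_ror = x$inverse_ror, inverse_ic = x$inverse_ic,
    evaluable = x$evaluable,
    stringsAsFactors = FALSE)
}

#' Screen many targets against one preferred-term set
#'
#' Convenience wrapper producing one [dispro()] row per target, in the
#' layout of a published signal table.
#'
#' @param reports a `report_set` after [apply_exclusions()].
#' @param targets a named list of [drug_class()] objects and/or single
#'   drug names.
#' @param pts a [pt_set()].
#' @param ... passed to [dispro()].
#' @inheritParams build_table
#' @return A data.frame with one row per target.
#' @export
dispro_screen <- function(reports, targets, pts, include_concomitant = FALSE, ...) {
  rows <- lapply(targets, function(tg) {
    as.data.frame(dispro(build_table(reports, tg, pts,
                                     include_concomitant = include_concomitant), ...))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
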