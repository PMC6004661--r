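#' Derive per-report time-to-onset records
#'
#' For every report exposed to the target drug (or class), derives the
#' time in days used by the onset-profile comparison:
#'
#' * cases (a target event present): days from the earliest suspect start
#'   date of a target drug to the earliest onset date of a matching event,
#'   event indicator `TRUE`;
#' * non-cases (including cases stopping for another adverse event): days
#'   from the same start to the end of target-drug use, censored
#'   (`FALSE`);
#' * any time beyond `cap_days` becomes a censored observation at
#'   `cap_days` (administrative censoring at one year by default);
#' * zero or negative differences are clamped to 1 day (the product-limit
#'   estimator needs positive times);
#' * reports lacking the required dates are excluded and tallied in the
#'   `"n_excluded"` attribute, never silently dropped.
#'
#' @param reports a [report_set()].
#' @param target a [drug_class()] or character vector of drug names.
#' @param pts a [pt_set()] defining the event of interest.
#' @param group label attached to every record (for [logrank_test()]).
#' @param cap_days administrative censoring horizon (default 365).
#' @param include_concomitant also count concomitant drug entries as
#'   exposure.
#' @return A data.frame (`case_id`, `group`, `time`, `event`) with
#'   attribute `"n_excluded"` (reports dropped for missing dates).
#' @export
derive_times <- function(reports, target, pts, group = label_of(target),
                         cap_days = 365, include_concomitant = FALSE) {
  stopifnot(inherits(reports, "report_set"), inherits(pts, "pt_set"))
  exposed <- is_exposed(reports, target, include_concomitant = include_concomitant)
  ids <- names(exposed)[exposed]
  members <- if (inherits(target, "drug_class")) target$members else normalize_drug(target)
  dr <- reports$drug
  dr <- dr[dr$case_id %in% ids & dr$drug_name %in% members &
             (include_concomitant | dr$role == "suspect"), , drop = FALSE]
  re <- reports$reac[reports$reac$case_id %in% ids &
                       reports$reac$pt_id %in% pts$pt_ids, , drop = FALSE]

  agg_min <- function(x, id, universe) {
    out <- rep(as.Date(NA), length(universe))
    if (nrow0 <- length(x)) {
      ok <- !is.na(x)
      if (any(ok)) {
        m <- tapply(x[ok], id[ok], min)
        out[match(names(m), universe)] <- as.Date(as.numeric(m))
      }
    }
    out
  }
  start <- agg_min(dr$start_date, dr$case_id, ids)
  onset <- agg_min(re$onset_date, re$case_id, ids)
  end <- rep(as.Date(NA), length(ids))
  ok <- !is.na(dr$end_date)
  if (any(ok)) {
    m <- tapply(dr$end_date[ok], dr$case_id[ok], max)
    end[match(names(m), ids)] <- as.Date(as.numeric(m))
  }
  is_cs <- ids %in% re$case_id  # has a target event at all (dated or not)

  stopdate <- ifelse(is_cs, onset, end)
  usable <- !is.na(start) & !is.na(stopdate)
  time <- as.numeric(stopdate[usable]) - as.numeric(start[usable])
  event <- is_cs[usable]
  time <- pmax(time, 1)
  over <- time > cap_days
  time[over] <- cap_days
  event[over] <- FALSE
  out <- data.frame(case_id = ids[usable], group = group, time = as.integer(time),
                    event = event, stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- sum(!usable)
  out
}

#' Kaplan-Meier curve
#'
#' Product-limit estimate of the onset-time survival function; at tied
#' times events are processed before censorings (the standard
#' convention). Computation is delegated to [survival::survfit()].
#'
#' @param records a data.frame with `time` and logical/0-1 `event`
#'   columns, e.g. from [derive_times()].
#' @return A data.frame of class `km_curve`: one row per distinct event
#'   time with `time`, `n_risk`, `n_event`, `surv` (survival just after
#'   that time).
#' @export
km_curve <- function(records) {
  if (NROW(records) == 0) stop_fmt("km_curve: no records")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = as.data.frame(records))
  keep <- fit$n.event > 0
  out <- data.frame(time = fit$time[keep], n_risk = fit$n.risk[keep],
                    n_event = fit$n.event[keep], surv = fit$surv[keep])
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank comparison of onset-time distributions,
#' via [survival::survdiff()]; p-value from the upper tail of the 1-d.f.
#' chi-square distribution.
#'
#' @param group_a,group_b data.frames with `time` and `event` columns,
#'   e.g. two calls to [derive_times()].
#' @return A list of class `logrank_result`: `statistic`, `p_value`,
#'   `n` (per-group sizes), `events` (per-group event counts).
#' @export
logrank_test <- function(group_a, group_b) {
  if (NROW(group_a) == 0 || NROW(group_b) == 0)
    stop_fmt("logrank_test: both groups must be non-empty")
  df <- rbind(
    data.frame(time = group_a$time, event = as.logical(group_a$event), g = "a"),
    data.frame(time = group_b$time, event = as.logical(group_b$event), g = "b"))
  if (!any(df$event)) stop_fmt("logrank_test: no events in either group")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = df)
  structure(list(statistic = unname(sd$chisq),
                 p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
                 n = as.integer(sd$n), events = as.numeric(sd$obs)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank test: chi-square = %.4f (1 d.f.), p = %s\n",
              x$statistic,
              if (x$p_value < 1e-4) "< 0.0001" else formatC(x$p_value, format = "f", digits = 4)))
  cat(sprintf("  n = %d / %d, events = %d / %d\n", x$n[1], x$n[2], x$events[1], x$events[2]))
  invisible(x)
}
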