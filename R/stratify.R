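age_bucket_lower <- function(bucket) {
  v <- suppressWarnings(as.integer(sub("[-+].*$", "", bucket)))
  v
}

#' Partition a report set by sex or by an age threshold
#'
#' Age is only available in decade buckets, so the threshold must align
#' with a bucket boundary; the default 70 puts buckets 70-79 and above in
#' the older stratum. Reports must already have passed
#' [apply_exclusions()] (no missing sex or qualitative age).
#'
#' @param reports a [report_set()] after [apply_exclusions()].
#' @param axis `"sex"` or `"age"`.
#' @param age_threshold lower bound (years) of the older stratum; must be
#'   a multiple of 10.
#' @return A named list of two disjoint `report_set`s: `male`/`female` or
#'   `older`/`younger`.
#' @export
split_reports <- function(reports, axis = c("sex", "age"), age_threshold = 70) {
  stopifnot(inherits(reports, "report_set"))
  axis <- match.arg(axis)
  d <- reports$demo
  if (axis == "sex") {
    if (anyNA(d$sex)) stop_fmt("missing sex: run apply_exclusions() first")
    in_a <- d$sex == "male"
    nms <- c("male", "female")
  } else {
    if (age_threshold %% 10 != 0)
      stop_fmt("age_threshold must align with a decade bucket boundary, got %s",
               age_threshold)
    lower <- age_bucket_lower(d$age_bucket)
    if (anyNA(lower)) stop_fmt("non-decade age bucket: run apply_exclusions() first")
    in_a <- lower >= age_threshold
    nms <- c("older", "younger")
  }
  subset_ids <- function(keep) {
    ids <- d$case_id[keep]
    report_set(d[keep, , drop = FALSE],
               reports$drug[reports$drug$case_id %in% ids, , drop = FALSE],
               reports$reac[reports$reac$case_id %in% ids, , drop = FALSE],
               reports$hist[reports$hist$case_id %in% ids, , drop = FALSE])
  }
  stats::setNames(list(subset_ids(in_a), subset_ids(!in_a)), nms)
}

#' Stratified signals and signal-value comparison
#'
#' Splits the report set, builds a standalone case/non-case table in each
#' stratum (each with its own stratum total as N), fits [dispro()] in
#' each, and compares the two signal values: a stratum dominates when its
#' signal value exceeds twice the other's.
#'
#' @inheritParams split_reports
#' @inheritParams build_table
#' @param ... passed to [dispro()] (priors, `yates`, ...).
#' @return A list of class `stratified_signals`: `strata` (named list of
#'   two `dispro` fits) and `verdict` (see [compare_signal_values()]).
#' @export
stratified_signals <- function(reports, target, pts, axis = c("sex", "age"),
                               age_threshold = 70, include_concomitant = FALSE, ...) {
  halves <- split_reports(reports, axis = axis, age_threshold = age_threshold)
  fits <- lapply(halves, function(rs) {
    dispro(build_table(rs, target, pts, include_concomitant = include_concomitant), ...)
  })
  verdict <- compare_signal_values(fits[[1]]$signal_value, fits[[2]]$signal_value)
  structure(list(strata = fits, verdict = verdict, axis = match.arg(axis)),
            class = "stratified_signals")
}

#' @export
print.stratified_signals <- function(x, ...) {
  for (nm in names(x$strata)) {
    cat("--- stratum: ", nm, " ---\n", sep = "")
    print(x$strata[[nm]])
  }
  cat("signal-value verdict (", paste(names(x$strata), collapse = " vs "),
      "): ", x$verdict, "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.stratified_signals <- function(x, ...) {
  out <- do.call(rbind, lapply(names(x$strata), function(nm) {
    cbind(stratum = nm, as.data.frame(x$strata[[nm]]))
  }))
  out$verdict <- x$verdict
  rownames(out) <- NULL
  out
}
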