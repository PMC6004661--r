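#' 2x2 case/non-case contingency table
#'
#' The unit of counting is the report: `a` reports carry both the target
#' drug (or drug class) and at least one event in the target preferred-term
#' set, `b` carry the drug but no target event, `c` the event but not the
#' drug, `d` neither. Marginals follow the usual disproportionality
#' notation: `n1plus = a + b` (all reports for the target drug),
#' `nplus1 = a + c` (all reports of the target event), `N = a+b+c+d`.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @param target,event optional labels carried through to results.
#' @return An object of class `contingency_table`: a list with the four
#'   cells, the marginals `n1plus`, `nplus1`, `N`, and the labels.
#' @examples
#' contingency_table(36, 393, 618, 37840)
#' @export
contingency_table <- function(a, b, c, d, target = NA_character_, event = NA_character_) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != floor(cells)))
    stop_fmt("contingency cells must be non-negative integers, got (%s)",
             paste(cells, collapse = ", "))
  structure(
    list(a = a, b = b, c = c, d = d,
         n1plus = a + b, nplus1 = a + c, N = a + b + c + d,
         target = target, event = event),
    class = "contingency_table")
}

#' Reconstruct a 2x2 table from printed marginals
#'
#' Disproportionality papers print `n11`, the drug total `n1+`, the event
#' total `n+1` and the database size `N` rather than the four cells. This
#' inverts that: `(n11, n1+ - n11, n+1 - n11, N - n1+ - n+1 + n11)`.
#'
#' @param n11 reports with both target drug and target event.
#' @param n1plus all reports for the target drug.
#' @param nplus1 all reports of the target event.
#' @param N total reports in the (filtered) database.
#' @inheritParams contingency_table
#' @return A [contingency_table()].
#' @examples
#' table_from_marginals(36, 429, 654, 38887)  # cells (36, 393, 618, 37840)
#' @export
table_from_marginals <- function(n11, n1plus, nplus1, N,
                                 target = NA_character_, event = NA_character_) {
  if (n11 > n1plus)
    stop_fmt("inconsistent marginals: n11 (%d) exceeds drug total n1plus (%d)", n11, n1plus)
  if (n11 > nplus1)
    stop_fmt("inconsistent marginals: n11 (%d) exceeds event total nplus1 (%d)", n11, nplus1)
  if (n1plus + nplus1 - n11 > N)
    stop_fmt("inconsistent marginals: n1plus + nplus1 - n11 (%d) exceeds N (%d)",
             n1plus + nplus1 - n11, N)
  contingency_table(n11, n1plus - n11, nplus1 - n11, N - n1plus - nplus1 + n11,
                    target = target, event = event)
}

#' Build the 2x2 table from report-level data
#'
#' Counts reports, not drug or event rows: a report with three matching
#' preferred terms and two suspect drugs of the class still contributes a
#' single count to `a`. The comparator is all other reports in the
#' `report_set` passed in — class-wide analyses do not remove same-class
#' drugs from the comparator, and stratified analyses are obtained by
#' passing a stratum (see [split_reports()]) so that `N` is the stratum
#' size.
#'
#' @param reports a `report_set`, normally already passed through
#'   [apply_exclusions()].
#' @param target a [drug_class()] or character vector of drug names.
#' @param pts a [pt_set()] of MedDRA preferred-term identifiers.
#' @param include_concomitant count concomitant as well as suspect drug
#'   entries as exposure (default `FALSE`: suspect only).
#' @return A [contingency_table()] with `N` equal to the number of reports.
#' @export
build_table <- function(reports, target, pts, include_concomitant = FALSE) {
  stopifnot(inherits(reports, "report_set"))
  exp <- is_exposed(reports, target, include_concomitant = include_concomitant)
  cas <- is_case(reports, pts)
  contingency_table(sum(exp & cas), sum(exp & !cas), sum(!exp & cas), sum(!exp & !cas),
                    target = label_of(target), event = label_of(pts))
}

label_of <- function(x) {
  if (inherits(x, "drug_class")) x$class_name
  else if (inherits(x, "pt_set")) x$name
  else paste(x, collapse = "+")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("2x2 case/non-case table%s%s\n",
              if (!is.na(x$target)) paste0(": ", x$target) else "",
              if (!is.na(x$event)) paste0(" x ", x$event) else ""))
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(c("drug+", "drug-"), c("event+", "event-")))
  print(m)
  cat(sprintf("n1+ = %d, n+1 = %d, N = %d\n", x$n1plus, x$nplus1, x$N))
  invisible(x)
}

#' @export
as.data.frame.contingency_table <- function(x, ...) {
  data.frame(target = x$target, event = x$event,
             a = x$a, b = x$b, c = x$c, d = x$d,
             n1plus = x$n1plus, nplus1 = x$nplus1, N = x$N,
             stringsAsFactors = FALSE)
}
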