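fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "pvsignal")
  if (p == "") p <- file.path("inst", "extdata", file)  # pre-install fallback
  p
}

#' GERD-like symptoms preferred-term set
#'
#' The shipped composite event: 36 MedDRA preferred terms spanning reflux,
#' oesophagitis, oesophageal injury, dysmotility, nausea and vomiting,
#' used because standard MedDRA queries carry no ready-made GERD
#' definition.
#'
#' @return A [pt_set()] of 36 preferred terms.
#' @examples
#' length(gerd_pt_set()$pt_ids)  # 36
#' @export
gerd_pt_set <- function() {
  df <- utils::read.table(fixture_path("gerd_pts.tsv"), header = TRUE, sep = "\t",
                          colClasses = "character", stringsAsFactors = FALSE)
  pt_set("GERD-like symptoms", df$pt_id, df$pt_name)
}

#' Incretin-based drug classes
#'
#' The shipped drug-class fixtures: the GLP-1 receptor agonists
#' (dulaglutide, exenatide, liraglutide, lixisenatide) and the nine
#' DPP-4 inhibitors marketed in Japan during the study window.
#'
#' @return A named list of two [drug_class()] objects, `glp1` and `dpp4`.
#' @export
incretin_drug_classes <- function() {
  df <- utils::read.table(fixture_path("drug_classes.tsv"), header = TRUE, sep = "\t",
                          colClasses = "character", stringsAsFactors = FALSE)
  list(glp1 = drug_class("GLP-1-RAs", df$drug[df$class == "GLP-1-RAs"]),
       dpp4 = drug_class("DPP-4-Is", df$drug[df$class == "DPP-4-Is"]))
}

#' Published incretin/GERD 2x2 tables (counts level)
#'
#' Contingency tables reconstructed from the printed marginals of the
#' JADER diabetic-patient analysis of incretin-based drugs and GERD-like
#' symptoms: database size N = 38,887, composite-event total 654, one row
#' per drug class, individual drug, and per-PT breakdown of both classes.
#' This is a counts-level fixture — report-level data are not public — and
#' exists so the printed ROR/IC values can be recomputed exactly.
#'
#' @return A named list of [contingency_table()] objects; names are
#'   `"<target>"` for the pooled GERD-like event and `"<target> | <PT>"`
#'   for single preferred terms.
#' @examples
#' tabs <- incretin_gerd_tables()
#' dispro(tabs[["GLP-1-RAs (ALL)"]])
#' @export
incretin_gerd_tables <- function() {
  df <- utils::read.table(fixture_path("incretin_gerd_counts.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    table_from_marginals(df$n11[i], df$n1plus[i], df$nplus1[i], df$N[i],
                         target = df$target[i], event = df$event[i])
  })
  names(out) <- ifelse(df$analysis == "pt",
                       paste(df$target, df$event, sep = " | "),
                       df$target)
  out
}

#' Published demographic marginals of the analysis set
#'
#' Per-stratum composite-event case counts and report totals of the
#' filtered database (38,887 diabetic-patient reports, 654 with GERD-like
#' symptoms): sex marginals and decade age-bucket marginals.
#'
#' @return A data.frame with columns `stratum`, `level`, `cases`, `total`.
#' @export
incretin_gerd_demographics <- function() {
  utils::read.table(fixture_path("incretin_gerd_demographics.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
}
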