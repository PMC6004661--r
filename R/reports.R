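#' @rdname report_set
#' @export
AGE_BUCKETS <- c("0-9", "10-19", "20-29", "30-39", "40-49", "50-59",
                 "60-69", "70-79", "80-89", "90-99", "100+")

#' Report-level container for spontaneous adverse-event data
#'
#' A `report_set` holds the four JADER-style tables joined by a shared
#' case identifier:
#'
#' * `demo`: `case_id`, `sex` (`"male"`/`"female"`/`NA`), `age_bucket`
#'   (a decade bin from `AGE_BUCKETS`, a qualitative word such as
#'   `"elderly"`, or `NA`);
#' * `drug`: `case_id`, `drug_name` (normalised), `role`
#'   (`"suspect"`/`"concomitant"`), `start_date`, `end_date` (`Date`);
#' * `reac`: `case_id`, `pt_id` (8-digit MedDRA preferred-term id),
#'   `pt_name`, `onset_date` (`Date`);
#' * `hist`: `case_id`, `disease` (primary-disease strings).
#'
#' One report = one `case_id`; a report may carry any number of drug,
#' reaction and disease rows (including none, e.g. before filtering).
#'
#' @param demo,drug,reac,hist data.frames as described above.
#' @return An object of class `report_set`.
#' @export
report_set <- function(demo, drug, reac, hist) {
  if (anyDuplicated(demo$case_id))
    stop_fmt("duplicate case_id in demographics table: %s",
             demo$case_id[duplicated(demo$case_id)][1])
  ids <- unique(c(demo$case_id, drug$case_id, reac$case_id, hist$case_id))
  # outer-join semantics: a case id seen only in a satellite table still
  # yields a record, with missing demographics
  if (length(setdiff(ids, demo$case_id))) {
    extra <- setdiff(ids, demo$case_id)
    demo <- rbind(demo, data.frame(case_id = extra, sex = NA_character_,
                                   age_bucket = NA_character_,
                                   stringsAsFactors = FALSE))
  }
  bad_dates <- !is.na(drug$start_date) & !is.na(drug$end_date) &
    drug$end_date < drug$start_date
  if (any(bad_dates))
    stop_fmt("drug entry with end_date before start_date (case %s)",
             drug$case_id[bad_dates][1])
  structure(list(demo = demo, drug = drug, reac = reac, hist = hist),
            class = "report_set")
}

#' @rdname report_set
#' @param x a `report_set`.
#' @export
n_reports <- function(x) {
  stopifnot(inherits(x, "report_set"))
  nrow(x$demo)
}

#' @export
print.report_set <- function(x, ...) {
  cat(sprintf("report_set: %d reports, %d drug rows, %d event rows, %d disease rows\n",
              nrow(x$demo), nrow(x$drug), nrow(x$reac), nrow(x$hist)))
  invisible(x)
}

#' Preferred-term set
#'
#' A named set of MedDRA preferred-term identifiers defining a composite
#' adverse event (the "case" definition of a case/non-case analysis).
#'
#' @param name label of the composite event.
#' @param pt_ids character vector of PT identifiers.
#' @param pt_names optional parallel vector of PT names.
#' @return An object of class `pt_set`.
#' @export
pt_set <- function(name, pt_ids, pt_names = NULL) {
  pt_ids <- as.character(pt_ids)
  if (length(pt_ids) == 0) stop_fmt("pt_set '%s' must be non-empty", name)
  keep <- !duplicated(pt_ids)
  structure(list(name = name, pt_ids = pt_ids[keep],
                 pt_names = if (!is.null(pt_names)) pt_names[keep]),
            class = "pt_set")
}

#' @export
print.pt_set <- function(x, ...) {
  cat(sprintf("pt_set '%s': %d preferred terms\n", x$name, length(x$pt_ids)))
  invisible(x)
}

#' Drug class definition
#'
#' @param class_name label, e.g. `"GLP-1-RAs"`.
#' @param members character vector of generic drug names; normalised with
#'   [normalize_drug()] and de-duplicated (with a warning, mirroring class
#'   listings that repeat members).
#' @param synonyms optional named character vector mapping brand or
#'   variant names to generic names, applied during normalisation.
#' @return An object of class `drug_class`.
#' @export
drug_class <- function(class_name, members, synonyms = NULL) {
  if (length(members) == 0) stop_fmt("drug class '%s' must be non-empty", class_name)
  members <- normalize_drug(members, synonyms)
  if (anyDuplicated(members)) {
    warn_fmt("drug class '%s': duplicate members collapsed (%s)", class_name,
             paste(unique(members[duplicated(members)]), collapse = ", "))
    members <- unique(members)
  }
  structure(list(class_name = class_name, members = members, synonyms = synonyms),
            class = "drug_class")
}

#' @export
print.drug_class <- function(x, ...) {
  cat(sprintf("drug_class '%s': %s\n", x$class_name, paste(x$members, collapse = ", ")))
  invisible(x)
}

#' Normalise free-text drug names
#'
#' Lower-cases, trims whitespace, and applies an optional synonym table
#' (brand name -> generic). Spontaneous-report drug fields are free text;
#' all matching in this package happens on normalised names.
#'
#' @param x character vector of drug names.
#' @param synonyms named character vector, `names(synonyms)` are the
#'   variants and values the replacements (matched after lower-casing).
#' @return Normalised character vector.
#' @export
normalize_drug <- function(x, synonyms = NULL) {
  x <- tolower(trimws(x))
  if (!is.null(synonyms)) {
    names(synonyms) <- tolower(trimws(names(synonyms)))
    hit <- x %in% names(synonyms)
    x[hit] <- unname(synonyms[x[hit]])
    x <- tolower(trimws(x))
  }
  x
}

#' File dialect for the four-table layout
#'
#' Column names, delimiter, encoding and date format used by
#' [load_report_set()] and [write_report_tables()]. The default mirrors a
#' JADER-like layout with ISO dates; real installations rename columns
#' here rather than editing their files.
#'
#' @param sep field delimiter.
#' @param encoding file encoding.
#' @param date_format `strptime` format of date fields.
#' @param columns named list mapping the canonical column names
#'   (`case_id`, `sex`, `age_bucket`, `drug_name`, `role`, `start_date`,
#'   `end_date`, `pt_id`, `pt_name`, `onset_date`, `disease`) to the names
#'   found in the files.
#' @return A list of class `file_dialect`.
#' @export
jader_dialect <- function(sep = ",", encoding = "UTF-8", date_format = "%Y-%m-%d",
                          columns = list()) {
  canon <- list(case_id = "case_id", sex = "sex", age_bucket = "age_bucket",
                drug_name = "drug_name", role = "role",
                start_date = "start_date", end_date = "end_date",
                pt_id = "pt_id", pt_name = "pt_name", onset_date = "onset_date",
                disease = "disease")
  canon[names(columns)] <- columns
  structure(list(sep = sep, encoding = encoding, date_format = date_format,
                 columns = canon), class = "file_dialect")
}

read_dialect_table <- function(path, dialect, need) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  nf <- utils::count.fields(path, sep = dialect$sep, quote = "\"")
  if (length(unique(nf[!is.na(nf)])) > 1) {
    bad <- which(nf != nf[1])[1]
    stop_fmt("malformed row in %s at line %d: expected %d fields, found %d",
             path, bad, nf[1], nf[bad])
  }
  df <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                          quote = "\"", colClasses = "character",
                          fileEncoding = dialect$encoding,
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (canon in names(need)) {
    src <- dialect$columns[[canon]]
    if (!src %in% names(df))
      stop_fmt("%s: required column '%s' (for %s) not found", path, src, canon)
  }
  out <- df[unlist(dialect$columns[names(need)])]
  names(out) <- names(need)
  for (canon in names(need)) {
    if (need[[canon]] == "date") {
      v <- trimws(out[[canon]])
      v[v == ""] <- NA
      out[[canon]] <- as.Date(v, format = dialect$date_format)
    } else {
      out[[canon]] <- trimws(out[[canon]])
      out[[canon]][out[[canon]] == ""] <- NA
    }
  }
  out
}

#' Load a report set from the four-table layout
#'
#' Reads the demographics, drug, reaction and primary-disease tables and
#' joins them by case id with outer-join semantics (a case id absent from
#' a satellite table simply has no rows there; one present only in a
#' satellite table gets missing demographics). Missing fields are kept as
#' `NA`, never dropped — filtering is a separate, explicit step
#' ([apply_exclusions()]). Duplicate `(case_id, drug_name, role)` rows are
#' collapsed with a warning.
#'
#' @param demo_path,drug_path,reac_path,hist_path paths to delimited text
#'   files.
#' @param dialect a [jader_dialect()].
#' @return A [report_set()].
#' @export
load_report_set <- function(demo_path, drug_path, reac_path, hist_path,
                            dialect = jader_dialect()) {
  demo <- read_dialect_table(demo_path, dialect,
                             list(case_id = "chr", sex = "chr", age_bucket = "chr"))
  drug <- read_dialect_table(drug_path, dialect,
                             list(case_id = "chr", drug_name = "chr", role = "chr",
                                  start_date = "date", end_date = "date"))
  reac <- read_dialect_table(reac_path, dialect,
                             list(case_id = "chr", pt_id = "chr", pt_name = "chr",
                                  onset_date = "date"))
  hist <- read_dialect_table(hist_path, dialect,
                             list(case_id = "chr", disease = "chr"))
  drug$drug_name <- normalize_drug(drug$drug_name)
  dup <- duplicated(drug[c("case_id", "drug_name", "role")])
  if (any(dup)) {
    warn_fmt("%d duplicate (case_id, drug, role) rows collapsed in %s",
             sum(dup), drug_path)
    drug <- drug[!dup, , drop = FALSE]
  }
  report_set(demo, drug, reac, hist)
}

#' Write a report set as the four-table layout
#'
#' Inverse of [load_report_set()]; the written files round-trip.
#'
#' @param reports a [report_set()].
#' @param dir output directory (created if needed).
#' @param dialect a [jader_dialect()].
#' @return Invisibly, the four file paths (demo, drug, reac, hist).
#' @export
write_report_tables <- function(reports, dir, dialect = jader_dialect()) {
  stopifnot(inherits(reports, "report_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cols <- dialect$columns
  wr <- function(df, canon_names, file) {
    out <- df
    for (nm in canon_names) {
      if (inherits(out[[nm]], "Date")) out[[nm]] <- format(out[[nm]], dialect$date_format)
    }
    names(out) <- unlist(cols[canon_names])
    utils::write.table(out, file, sep = dialect$sep, row.names = FALSE,
                       quote = TRUE, na = "", fileEncoding = dialect$encoding)
    file
  }
  paths <- c(
    demo = wr(reports$demo, c("case_id", "sex", "age_bucket"), file.path(dir, "demo.csv")),
    drug = wr(reports$drug, c("case_id", "drug_name", "role", "start_date", "end_date"),
              file.path(dir, "drug.csv")),
    reac = wr(reports$reac, c("case_id", "pt_id", "pt_name", "onset_date"),
              file.path(dir, "reac.csv")),
    hist = wr(reports$hist, c("case_id", "disease"), file.path(dir, "hist.csv")))
  invisible(paths)
}

#' Inclusion/exclusion filtering
#'
#' Retains only reports with non-missing sex, a numeric decade age bucket
#' (qualitative entries such as "elderly" or "youth" count as missing),
#' and at least one primary-disease row; optionally additionally requires
#' the primary diseases to intersect a given set (e.g. restriction to
#' diabetic patients). Idempotent.
#'
#' @param reports a [report_set()].
#' @param require_primary_disease_in optional character vector of disease
#'   strings; when given, a report is kept only if at least one of its
#'   primary diseases is in the set.
#' @return The filtered [report_set()], with attribute `"n_excluded"`.
#' @export
apply_exclusions <- function(reports, require_primary_disease_in = NULL) {
  stopifnot(inherits(reports, "report_set"))
  d <- reports$demo
  ok <- !is.na(d$sex) & !is.na(d$age_bucket) & d$age_bucket %in% AGE_BUCKETS
  has_disease <- d$case_id %in% reports$hist$case_id[!is.na(reports$hist$disease)]
  ok <- ok & has_disease
  if (!is.null(require_primary_disease_in)) {
    hit <- reports$hist$case_id[reports$hist$disease %in% require_primary_disease_in]
    ok <- ok & d$case_id %in% hit
  }
  keep <- d$case_id[ok]
  out <- report_set(
    demo = d[ok, , drop = FALSE],
    drug = reports$drug[reports$drug$case_id %in% keep, , drop = FALSE],
    reac = reports$reac[reports$reac$case_id %in% keep, , drop = FALSE],
    hist = reports$hist[reports$hist$case_id %in% keep, , drop = FALSE])
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Case classification
#'
#' A report is a case iff at least one of its events is in the target
#' preferred-term set; multiple matching events still count once. Reports
#' without any event row are an error — spontaneous reports exist only
#' because an adverse event occurred.
#'
#' @param reports a [report_set()].
#' @param pts a [pt_set()].
#' @return Named logical vector, one element per report (demo order).
#' @export
is_case <- function(reports, pts) {
  stopifnot(inherits(reports, "report_set"), inherits(pts, "pt_set"))
  ids <- reports$demo$case_id
  no_events <- !(ids %in% reports$reac$case_id)
  if (any(no_events))
    stop_fmt("report(s) without any adverse event, e.g. case %s", ids[no_events][1])
  hit <- unique(reports$reac$case_id[reports$reac$pt_id %in% pts$pt_ids])
  stats::setNames(ids %in% hit, ids)
}

#' Exposure classification
#'
#' A report is exposed iff it has a drug entry with role `suspect`
#' (optionally also `concomitant`) whose normalised name is in the target
#' drug class or name vector.
#'
#' @param reports a [report_set()].
#' @param target a [drug_class()] or character vector of drug names.
#' @param include_concomitant also count concomitant entries.
#' @return Named logical vector, one element per report (demo order).
#' @export
is_exposed <- function(reports, target, include_concomitant = FALSE) {
  stopifnot(inherits(reports, "report_set"))
  members <- if (inherits(target, "drug_class")) target$members
             else normalize_drug(target)
  dr <- reports$drug
  role_ok <- if (include_concomitant) rep(TRUE, nrow(dr)) else dr$role == "suspect"
  hit <- unique(dr$case_id[role_ok & dr$drug_name %in% members])
  ids <- reports$demo$case_id
  stats::setNames(ids %in% hit, ids)
}
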