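#' Configuration of the synthetic report generator
#'
#' Parameterises [simulate_reports()]. Defaults emulate the filtered
#' diabetic-patient slice of a JADER-style database over 2004-2015:
#' ~61% male, the decade age distribution of that analysis set, class
#' exposure probabilities matching the printed drug totals (429/38,887
#' GLP-1 receptor agonist reports, 3,276/38,887 DPP-4 inhibitor reports),
#' a GERD-like composite event with background reporting probability
#' 654/38,887, and reporting-risk multipliers at the observed
#' disproportionality (about 5.6 for the GLP-1 class, 0.55 for the DPP-4
#' class).
#'
#' @param n_reports number of reports to generate.
#' @param seed RNG seed; generation is deterministic given the seed.
#' @param sex_split probability a report is male.
#' @param age_bucket_probs named probability vector over `AGE_BUCKETS`
#'   (missing buckets get 0); must sum to 1.
#' @param primary_disease_probs named vector: independent probability of
#'   each primary-disease string per report.
#' @param drugs data.frame with columns `name`, `class`, `exposure_prob`.
#' @param events data.frame with columns `pt_id`, `pt_name`,
#'   `baseline_prob` (per-report reporting probability when no multiplier
#'   applies).
#' @param multipliers list of entries
#'   `list(target =, pts =, multiplier =, multiplier_older = NULL)`:
#'   `target` a drug or class name, `pts` the PT ids acted on,
#'   `multiplier` the relative reporting risk for exposed reports, and
#'   optionally a different multiplier for reports in age buckets at or
#'   above `age_threshold` (for simulating age-dependent signals).
#' @param age_threshold boundary (years) for `multiplier_older`.
#' @param onset_models named list per drug class:
#'   `list(shape =, scale =)` Weibull latency (days) from drug start to a
#'   multiplier-targeted event.
#' @param background_onset Weibull `list(shape, scale)` latency for all
#'   other events.
#' @param duration_meanlog,duration_sdlog log-normal drug-exposure
#'   duration (days).
#' @param suspect_prob probability an exposure is coded `suspect` rather
#'   than `concomitant`.
#' @param missing_sex,missing_age,missing_date per-field missingness
#'   rates applied after generation.
#' @param qualitative_age_rate probability an (otherwise known) age is
#'   recorded as a subjective word ("youth"/"elderly") instead of a
#'   decade bucket.
#' @param date_window character vector of two dates bounding drug start
#'   dates.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(
    n_reports = 10000,
    seed = 1,
    sex_split = 23669 / 38887,
    age_bucket_probs = c("0-9" = 40, "10-19" = 86, "20-29" = 215, "30-39" = 748,
                         "40-49" = 1990, "50-59" = 5115, "60-69" = 11399,
                         "70-79" = 13178, "80-89" = 5568, "90-99" = 548) / 38887,
    primary_disease_probs = c("type 2 diabetes mellitus" = 0.95, hypertension = 0.3,
                              dyslipidaemia = 0.2),
    drugs = data.frame(
      name = c("exenatide", "liraglutide", "sitagliptin", "vildagliptin"),
      class = c("GLP-1-RAs", "GLP-1-RAs", "DPP-4-Is", "DPP-4-Is"),
      exposure_prob = c(122, 278, 1181, 1189) / 38887,
      stringsAsFactors = FALSE),
    events = data.frame(
      pt_id = c("10047700", "10028813", "10017885", "90000001", "90000002", "90000003"),
      pt_name = c("Vomiting", "Nausea", "Gastrooesophageal reflux disease",
                  "Hypoglycaemia", "Hepatic function abnormal", "Interstitial lung disease"),
      baseline_prob = c(344 / 38887, 310 / 38887, 24 / 38887, 0.30, 0.25, 0.20),
      stringsAsFactors = FALSE),
    multipliers = list(
      list(target = "GLP-1-RAs", pts = c("10047700", "10028813", "10017885"),
           multiplier = 5.6),
      list(target = "DPP-4-Is", pts = c("10047700", "10028813", "10017885"),
           multiplier = 0.55)),
    age_threshold = 70,
    onset_models = list("GLP-1-RAs" = list(shape = 0.9, scale = 80),
                        "DPP-4-Is" = list(shape = 0.9, scale = 150)),
    background_onset = list(shape = 1.0, scale = 90),
    duration_meanlog = log(90), duration_sdlog = 1,
    suspect_prob = 0.9,
    missing_sex = 0.05, missing_age = 0.05, missing_date = 0.28,
    qualitative_age_rate = 0.02,
    date_window = c("2004-01-01", "2015-12-31")) {
  cfg <- list(n_reports = n_reports, seed = seed, sex_split = sex_split,
              age_bucket_probs = age_bucket_probs,
              primary_disease_probs = primary_disease_probs,
              drugs = drugs, events = events, multipliers = multipliers,
              age_threshold = age_threshold, onset_models = onset_models,
              background_onset = background_onset,
              duration_meanlog = duration_meanlog, duration_sdlog = duration_sdlog,
              suspect_prob = suspect_prob,
              missing_sex = missing_sex, missing_age = missing_age,
              missing_date = missing_date,
              qualitative_age_rate = qualitative_age_rate,
              date_window = as.Date(date_window))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  required <- c("n_reports", "seed", "sex_split", "age_bucket_probs",
                "primary_disease_probs", "drugs", "events", "multipliers")
  for (f in required)
    if (is.null(cfg[[f]])) stop_fmt("sim_config: missing field '%s'", f)
  if (cfg$n_reports < 1) stop_fmt("sim_config: n_reports must be positive")
  probs <- c(cfg$sex_split, cfg$age_bucket_probs, cfg$primary_disease_probs,
             cfg$drugs$exposure_prob, cfg$events$baseline_prob,
             cfg$missing_sex %||% 0, cfg$missing_age %||% 0,
             cfg$missing_date %||% 0, cfg$qualitative_age_rate %||% 0)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1))
    stop_fmt("sim_config: all probabilities must lie in [0, 1]")
  if (abs(sum(cfg$age_bucket_probs) - 1) > 1e-8)
    stop_fmt("sim_config: age_bucket_probs must sum to 1")
  if (!all(names(cfg$age_bucket_probs) %in% AGE_BUCKETS))
    stop_fmt("sim_config: unknown age bucket '%s'",
             setdiff(names(cfg$age_bucket_probs), AGE_BUCKETS)[1])
  for (m in cfg$multipliers) {
    if (is.null(m$target) || is.null(m$pts) || is.null(m$multiplier))
      stop_fmt("sim_config: each multiplier needs 'target', 'pts', 'multiplier'")
    if (m$multiplier < 0) stop_fmt("sim_config: multipliers must be >= 0")
  }
  structure(cfg, class = "sim_config")
}

#' Read / write a simulation configuration
#'
#' YAML serialisation of a [sim_config()]; round-trips through
#' [validate_sim_config] so a hand-edited file with a missing or invalid
#' field fails loudly, naming the field.
#'
#' @param path file path.
#' @param cfg a `sim_config`.
#' @return `read_sim_config()` returns a validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- sim_config()
  for (nm in c("drugs", "events")) {
    if (!is.null(raw[[nm]]))
      raw[[nm]] <- do.call(rbind, lapply(raw[[nm]], function(r)
        as.data.frame(r, stringsAsFactors = FALSE)))
  }
  for (nm in c("age_bucket_probs", "primary_disease_probs"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  if (!is.null(raw$date_window)) raw$date_window <- as.Date(unlist(raw$date_window))
  cfg <- base
  cfg[names(raw)] <- raw
  validate_sim_config(cfg)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$date_window <- format(out$date_window)
  out$drugs <- lapply(seq_len(nrow(cfg$drugs)), function(i) as.list(cfg$drugs[i, ]))
  out$events <- lapply(seq_len(nrow(cfg$events)), function(i) as.list(cfg$events[i, ]))
  out$age_bucket_probs <- as.list(cfg$age_bucket_probs)
  out$primary_disease_probs <- as.list(cfg$primary_disease_probs)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Generate a synthetic spontaneous-report database
#'
#' Draws `n_reports` reports with known ground truth: demographics, drug
#' exposures with start/end dates inside the study window, and adverse
#' events whose per-report reporting probability is
#' `baseline_prob x multiplier` (capped at 1) when an exposed drug
#' targets that preferred term — the injected multiplier is thus the
#' estimand of the downstream disproportionality analysis. Every report
#' carries at least one event (reports exist only because an event was
#' reported): a report drawing none receives one event sampled
#' proportionally to the baseline probabilities. Onset dates of
#' multiplier-targeted events in exposed reports follow the per-class
#' Weibull latency from the drug start date; other events follow the
#' background latency. Missingness (sex, age, dates) and qualitative age
#' words are applied last. Deterministic given `cfg$seed`; the caller's
#' RNG state is left untouched.
#'
#' @param cfg a [sim_config()].
#' @return A [report_set()].
#' @export
simulate_reports <- function(cfg) {
  cfg <- validate_sim_config(unclass(cfg))
  n <- cfg$n_reports
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)

  ids <- sprintf("S%d-%06d", cfg$seed, seq_len(n))
  sex <- ifelse(stats::runif(n) < cfg$sex_split, "male", "female")
  bucket <- sample(names(cfg$age_bucket_probs), n, replace = TRUE,
                   prob = cfg$age_bucket_probs)
  older <- age_bucket_lower(bucket) >= cfg$age_threshold

  # primary diseases: independent Bernoulli per disease
  hist <- do.call(rbind, lapply(names(cfg$primary_disease_probs), function(dz) {
    has <- stats::runif(n) < cfg$primary_disease_probs[[dz]]
    if (!any(has)) return(NULL)
    data.frame(case_id = ids[has], disease = dz, stringsAsFactors = FALSE)
  }))
  if (is.null(hist))
    hist <- data.frame(case_id = character(), disease = character(),
                       stringsAsFactors = FALSE)

  # drug exposures
  win <- as.numeric(cfg$date_window)
  drug_rows <- list()
  exposure <- matrix(FALSE, n, nrow(cfg$drugs),
                     dimnames = list(NULL, cfg$drugs$name))
  start_by_drug <- matrix(NA_real_, n, nrow(cfg$drugs))
  for (j in seq_len(nrow(cfg$drugs))) {
    exp_j <- stats::runif(n) < cfg$drugs$exposure_prob[j]
    exposure[, j] <- exp_j
    k <- sum(exp_j)
    if (k == 0) next
    start <- floor(stats::runif(k, win[1], win[2] + 1))
    dur <- pmax(1, round(stats::rlnorm(k, cfg$duration_meanlog, cfg$duration_sdlog)))
    start_by_drug[exp_j, j] <- start
    drug_rows[[j]] <- data.frame(
      case_id = ids[exp_j], drug_name = cfg$drugs$name[j],
      role = ifelse(stats::runif(k) < cfg$suspect_prob, "suspect", "concomitant"),
      start_date = as.Date(start), end_date = as.Date(start + dur),
      stringsAsFactors = FALSE)
  }
  drug <- if (length(drug_rows)) do.call(rbind, drug_rows)
    else data.frame(case_id = character(), drug_name = character(),
                    role = character(), start_date = as.Date(character()),
                    end_date = as.Date(character()), stringsAsFactors = FALSE)

  # per-report event probabilities: baseline x strongest applicable multiplier
  n_ev <- nrow(cfg$events)
  pmat <- matrix(rep(cfg$events$baseline_prob, each = n), n, n_ev,
                 dimnames = list(NULL, cfg$events$pt_id))
  latent <- matrix(NA_character_, n, n_ev)  # class whose onset model applies
  for (m in cfg$multipliers) {
    in_target <- cfg$drugs$name == m$target | cfg$drugs$class == m$target
    if (!any(in_target)) next
    exp_m <- rowSums(exposure[, in_target, drop = FALSE]) > 0
    mult <- rep(m$multiplier, n)
    if (!is.null(m$multiplier_older)) mult[older] <- m$multiplier_older
    cols <- match(m$pts, cfg$events$pt_id)
    cols <- cols[!is.na(cols)]
    for (jc in cols) {
      pmat[exp_m, jc] <- pmin(1, pmat[exp_m, jc] * mult[exp_m])
      cls <- cfg$drugs$class[in_target][1]
      latent[exp_m, jc] <- cls
    }
  }
  ev <- matrix(stats::runif(n * n_ev), n, n_ev) < pmat
  none <- which(rowSums(ev) == 0)
  if (length(none)) {
    # a report exists only because an event was reported: draw one event
    # from the report's own reporting propensities (multipliers included,
    # so the injected relative risk stays the estimand), via Gumbel-max
    # categorical sampling
    w <- log(pmat[none, , drop = FALSE]) -
      log(-log(matrix(stats::runif(length(none) * n_ev), length(none), n_ev)))
    forced <- max.col(w, ties.method = "first")
    ev[cbind(none, forced)] <- TRUE
  }

  # anchor date per report: earliest drug start if exposed, else window draw
  anchor <- suppressWarnings(apply(start_by_drug, 1, min, na.rm = TRUE))
  no_anchor <- !is.finite(anchor)
  anchor[no_anchor] <- floor(stats::runif(sum(no_anchor), win[1], win[2] + 1))

  idx <- which(ev, arr.ind = TRUE)
  lat_cls <- latent[idx]
  sh <- ifelse(is.na(lat_cls), cfg$background_onset$shape,
               vapply(lat_cls, function(cl)
                 (cfg$onset_models[[cl]] %||% cfg$background_onset)$shape, 0))
  sc <- ifelse(is.na(lat_cls), cfg$background_onset$scale,
               vapply(lat_cls, function(cl)
                 (cfg$onset_models[[cl]] %||% cfg$background_onset)$scale, 0))
  delay <- pmax(1, round(stats::rweibull(nrow(idx), sh, sc)))
  reac <- data.frame(
    case_id = ids[idx[, 1]],
    pt_id = cfg$events$pt_id[idx[, 2]],
    pt_name = cfg$events$pt_name[idx[, 2]],
    onset_date = as.Date(anchor[idx[, 1]] + delay),
    stringsAsFactors = FALSE)
  reac <- reac[order(match(reac$case_id, ids), reac$pt_id), , drop = FALSE]
  rownames(reac) <- NULL

  # missingness
  sex[stats::runif(n) < cfg$missing_sex] <- NA
  qual <- stats::runif(n) < cfg$qualitative_age_rate
  bucket[qual] <- ifelse(age_bucket_lower(bucket[qual]) >= 60, "elderly", "youth")
  bucket[stats::runif(n) < cfg$missing_age] <- NA
  if (cfg$missing_date > 0) {
    drug$start_date[stats::runif(nrow(drug)) < cfg$missing_date] <- NA
    drug$end_date[stats::runif(nrow(drug)) < cfg$missing_date] <- NA
    reac$onset_date[stats::runif(nrow(reac)) < cfg$missing_date] <- NA
  }

  report_set(
    demo = data.frame(case_id = ids, sex = sex, age_bucket = bucket,
                      stringsAsFactors = FALSE),
    drug = drug, reac = reac, hist = hist)
}
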