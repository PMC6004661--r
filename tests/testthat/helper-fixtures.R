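# In-code fixture builders shared across test files.

tiny_pt_set <- function() pt_set("gerd", c("10047700", "10028813", "10017885"))

# Five hand-written reports: r1 exposed case, r2 exposed non-case,
# r3 unexposed case, r4 unexposed non-case, r5 concomitant-only exposure.
tiny_report_set <- function() {
  report_set(
    demo = data.frame(
      case_id = c("r1", "r2", "r3", "r4", "r5"),
      sex = c("male", "female", "male", "female", "male"),
      age_bucket = c("70-79", "60-69", "40-49", "80-89", "50-59"),
      stringsAsFactors = FALSE),
    drug = data.frame(
      case_id = c("r1", "r2", "r5"),
      drug_name = c("exenatide", "liraglutide", "sitagliptin"),
      role = c("suspect", "suspect", "concomitant"),
      start_date = as.Date(c("2015-01-01", "2015-01-01", "2015-02-01")),
      end_date = as.Date(c("2015-06-01", "2015-03-02", "2015-04-01")),
      stringsAsFactors = FALSE),
    reac = data.frame(
      case_id = c("r1", "r1", "r2", "r3", "r4", "r5"),
      pt_id = c("10047700", "10019211", "90000001", "10028813", "90000001", "90000002"),
      pt_name = c("Vomiting", "x", "bg", "Nausea", "bg", "bg"),
      onset_date = as.Date(c("2015-01-31", NA, "2015-02-10", "2015-05-01", NA, NA)),
      stringsAsFactors = FALSE),
    hist = data.frame(
      case_id = c("r1", "r2", "r3", "r4", "r5"),
      disease = c("diabetes", "diabetes", "hypertension", "diabetes", "diabetes"),
      stringsAsFactors = FALSE))
}

# Small simulation config with no injected association and no missingness.
null_sim_config <- function(seed, n = 10000, multiplier = 1,
                            exposure = 0.05, baseline = 0.05) {
  sim_config(
    n_reports = n, seed = seed,
    drugs = data.frame(name = "drugx", class = "X", exposure_prob = exposure,
                       stringsAsFactors = FALSE),
    events = data.frame(
      pt_id = c("10000001", "90000001", "90000002"),
      pt_name = c("Target event", "Background A", "Background B"),
      baseline_prob = c(baseline, 0.4, 0.3), stringsAsFactors = FALSE),
    multipliers = list(list(target = "X", pts = "10000001",
                            multiplier = multiplier)),
    suspect_prob = 1,
    missing_sex = 0, missing_age = 0, missing_date = 0,
    qualitative_age_rate = 0)
}

target_x <- function() drug_class("X", "drugx")
target_pt <- function() pt_set("target", "10000001")

# Brute-force 2x2 oracle: explicit double loop over reports.
brute_force_table <- function(rs, members, pt_ids, suspect_only = TRUE) {
  a <- b <- cc <- d <- 0L
  for (id in rs$demo$case_id) {
    dr <- rs$drug[rs$drug$case_id == id, , drop = FALSE]
    if (suspect_only) dr <- dr[dr$role == "suspect", , drop = FALSE]
    exposed <- FALSE
    for (nm in dr$drug_name) if (nm %in% members) exposed <- TRUE
    re <- rs$reac[rs$reac$case_id == id, , drop = FALSE]
    case <- FALSE
    for (p in re$pt_id) if (p %in% pt_ids) case <- TRUE
    if (exposed && case) a <- a + 1L
    else if (exposed) b <- b + 1L
    else if (case) cc <- cc + 1L
    else d <- d + 1L
  }
  c(a = a, b = b, c = cc, d = d)
}

# Permutation log-rank p-value: reference distribution of the chi-square
# statistic under random relabelling of group membership.
perm_logrank_p <- function(group_a, group_b, n_perm = 1000) {
  df <- rbind(data.frame(time = group_a$time, event = as.logical(group_a$event)),
              data.frame(time = group_b$time, event = as.logical(group_b$event)))
  na <- nrow(group_a)
  stat <- function(idx_a) {
    g <- rep("b", nrow(df)); g[idx_a] <- "a"
    survival::survdiff(survival::Surv(df$time, df$event) ~ g)$chisq
  }
  obs <- stat(seq_len(na))
  hits <- 0L
  for (i in seq_len(n_perm)) {
    if (stat(sample.int(nrow(df), na)) >= obs - 1e-12) hits <- hits + 1L
  }
  list(observed = obs, p = (hits + 1) / (n_perm + 1))
}

# Expand counts-level demographic marginals into a minimal report_set
# (one stratum axis at a time; each report gets a dummy event + disease).
expand_marginals <- function(levels, totals, axis = c("sex", "age")) {
  axis <- match.arg(axis)
  n <- sum(totals)
  ids <- sprintf("m%06d", seq_len(n))
  lev <- rep(levels, totals)
  demo <- data.frame(case_id = ids,
                     sex = if (axis == "sex") lev else "male",
                     age_bucket = if (axis == "age") lev else "50-59",
                     stringsAsFactors = FALSE)
  report_set(demo,
             drug = data.frame(case_id = character(), drug_name = character(),
                               role = character(), start_date = as.Date(character()),
                               end_date = as.Date(character()), stringsAsFactors = FALSE),
             reac = data.frame(case_id = ids, pt_id = "90000001", pt_name = "bg",
                               onset_date = as.Date(NA), stringsAsFactors = FALSE),
             hist = data.frame(case_id = ids, disease = "diabetes",
                               stringsAsFactors = FALSE))
}
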