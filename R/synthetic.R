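# Synthetic FAERS-like report generator with known ground truth.
#
# Each report draws sex, an age band (uniform age 18-64 or 65-95), drug
# exposures (optionally sex- or age-specific prevalence, the mechanism for
# inducing confounding), and each adverse event as a Bernoulli draw from
#   logit P(event) = b0 + sum_j b_drug[j] * exposed[j]
#                    + b_sex * I(female) + b_age * I(65+)
#                    + interaction terms
# so every conditional reporting odds ratio is known in closed form.
# Reports are written in the FAERS $-delimited ASCII layout, with ages
# re-encoded in mixed units and stale case versions injected, so the whole
# ingestion pipeline is exercised end to end.

.filler_pts <- data.frame(
  pt_name = c("Headache", "Nausea", "Vomiting", "Dizziness", "Fatigue",
              "Rash", "Insomnia", "Diarrhoea", "Pruritus", "Pyrexia"),
  pt_code = c(10019211L, 10028813L, 10047700L, 10013573L, 10016256L,
              10037844L, 10022437L, 10012735L, 10037087L, 10037660L),
  stringsAsFactors = FALSE)

.background_drugs <- c("ASPIRIN", "IBUPROFEN", "METFORMIN", "LISINOPRIL",
                       "OMEPRAZOLE", "ATORVASTATIN")

#' Build an event model for the synthetic generator
#'
#' @param intercept Baseline log-odds of the event (`NULL` uses the
#'   config's `background_event_rate`).
#' @param drug Named numeric: log odds ratio per exposed drug.
#' @param sex_f Log odds ratio for female sex.
#' @param age_over65 Log odds ratio for age 65+.
#' @param drug_age Named numeric: additional log OR for drug exposure in
#'   the 65+ band (drug-by-age interaction).
#' @param drug_sex_f Named numeric: additional log OR for drug exposure in
#'   females (drug-by-sex interaction).
#' @return A list usable inside `event_models` of [sim_config()].
#' @export
event_model <- function(intercept = NULL, drug = numeric(0), sex_f = 0,
                        age_over65 = 0, drug_age = numeric(0),
                        drug_sex_f = numeric(0)) {
  list(intercept = intercept, drug = drug, sex_f = sex_f,
       age_over65 = age_over65, drug_age = drug_age,
       drug_sex_f = drug_sex_f)
}

#' Configuration for the synthetic FAERS generator
#'
#' Defaults describe a desk-scale spontaneous-reporting database: 55%
#' female reports, 25% aged 65+, two study drugs at 5% reporting
#' prevalence, a 2% background event rate, 5% stale duplicate versions,
#' and the FAERS role-code and age-unit mixes dominated by primary-suspect
#' mentions and ages reported in years.
#'
#' @param n_reports Number of (final-version) reports.
#' @param seed Integer seed; fixes the full output stream.
#' @param p_female,p_over65 Demographic mix.
#' @param drug_prevalence Named list: per drug, a scalar exposure
#'   probability or a named vector over `F`/`M` or `under65`/`over65`
#'   (sex- or age-specific prevalence induces confounding).
#' @param event_models Named list of [event_model()]s; names must be event
#'   query names.
#' @param event_queries Named list of [event_query()]s supplying the PT
#'   vocabulary written for each event. Defaults to the matching
#'   [builtin_event_queries()] entry, or a synthetic single-PT query for
#'   names not in the builtin set.
#' @param background_event_rate Baseline event probability used when an
#'   event model has no explicit intercept.
#' @param duplicate_fraction Fraction of cases that also emit a stale
#'   earlier `caseversion` record (removed again by [deduplicate()]).
#' @param role_mix Probabilities over role codes `PS`, `SS`, `C`, `I` for
#'   study-drug mentions.
#' @param age_unit_mix Probabilities over FAERS age unit codes used when
#'   writing files.
#' @param p_missing_sex,p_missing_age Fractions of reports with sex coded
#'   `UNK` / age left empty (dropped during assembly).
#' @param period_boost Off by default (`NULL`). Optionally
#'   `list(drug =, event =, cutover = "YYYY-MM-DD", multiplier =)`: reports
#'   of that drug-event pair have their receipt dates drawn after the
#'   cutover with odds `multiplier` times the calendar share — a crude
#'   stand-in for stimulated reporting.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_reports = 50000L, seed = 1L,
                       p_female = 0.55, p_over65 = 0.25,
                       drug_prevalence = list(DRUG_A = 0.05, DRUG_B = 0.05),
                       event_models = list(
                         "Sedation" = event_model(
                           drug = c(DRUG_A = log(4)), sex_f = log(1.2),
                           age_over65 = log(1.5)),
                         "Weight gain" = event_model(sex_f = log(1.1)),
                         "Hyperprolactinaemia" = event_model(
                           drug = c(DRUG_B = log(3)), sex_f = log(1.5))),
                       event_queries = NULL,
                       background_event_rate = 0.02,
                       duplicate_fraction = 0.05,
                       role_mix = c(PS = 0.7, SS = 0.1, C = 0.15, I = 0.05),
                       age_unit_mix = c(YR = 0.85, DEC = 0.05, MON = 0.04,
                                        WK = 0.02, DY = 0.02, HR = 0.02),
                       p_missing_sex = 0.01, p_missing_age = 0.01,
                       period_boost = NULL) {
  stopifnot(n_reports >= 0, p_female >= 0, p_female <= 1,
            p_over65 >= 0, p_over65 <= 1,
            duplicate_fraction >= 0, duplicate_fraction <= 1,
            background_event_rate > 0, background_event_rate < 1,
            all(names(role_mix) %in% c("PS", "SS", "C", "I")),
            all(names(age_unit_mix) %in% names(.age_unit_years)))
  drug_names <- names(drug_prevalence)
  if (length(drug_names) == 0L) stop("at least one drug is required")
  for (ev in names(event_models)) {
    m <- event_models[[ev]]
    ref <- unique(c(names(m$drug), names(m$drug_age), names(m$drug_sex_f)))
    bad <- setdiff(ref, drug_names)
    if (length(bad)) {
      stop("event model '", ev, "' references unknown drug(s): ",
           paste(bad, collapse = ", "))
    }
  }
  if (is.null(event_queries)) {
    builtin <- builtin_event_queries()
    event_queries <- lapply(seq_along(event_models), function(i) {
      nm <- names(event_models)[i]
      if (nm %in% names(builtin) && nrow(builtin[[nm]]$terms) > 0L) {
        builtin[[nm]]
      } else {
        event_query(nm, data.frame(pt_name = paste(nm, "(synthetic PT)"),
                                   pt_code = 99000000L + i))
      }
    })
    names(event_queries) <- names(event_models)
  }
  stopifnot(setequal(names(event_queries), names(event_models)))
  structure(list(
    n_reports = as.integer(n_reports), seed = as.integer(seed),
    p_female = p_female, p_over65 = p_over65,
    drug_prevalence = drug_prevalence, event_models = event_models,
    event_queries = event_queries,
    background_event_rate = background_event_rate,
    duplicate_fraction = duplicate_fraction,
    role_mix = role_mix / sum(role_mix),
    age_unit_mix = age_unit_mix / sum(age_unit_mix),
    p_missing_sex = p_missing_sex, p_missing_age = p_missing_age,
    period_boost = period_boost), class = "sim_config")
}

# per-report exposure probability for one drug's prevalence spec
.prevalence_vector <- function(spec, female, over65) {
  if (length(spec) == 1L && is.null(names(spec))) {
    return(rep(as.numeric(spec), length(female)))
  }
  spec <- unlist(spec)
  if (all(names(spec) %in% c("F", "M"))) {
    return(unname(spec[ifelse(female, "F", "M")]))
  }
  if (all(names(spec) %in% c("under65", "over65"))) {
    return(unname(spec[ifelse(over65, "over65", "under65")]))
  }
  stop("drug prevalence must be a scalar or named over F/M or ",
       "under65/over65")
}

#' Drug queries matching the synthetic generator's drug labels
#'
#' @param config A [sim_config()].
#' @param allowed_roles Role codes counting as exposure.
#' @return Named list of `drug_query` objects, one per simulated drug.
#' @export
sim_drug_queries <- function(config, allowed_roles = c("PS", "SS", "C",
                                                       "I")) {
  qs <- lapply(names(config$drug_prevalence), function(d) {
    drug_query(d, d, allowed_roles = allowed_roles)
  })
  names(qs) <- names(config$drug_prevalence)
  qs
}

#' Generate a synthetic FAERS-like report set
#'
#' Deterministic given the config's seed. Returns both the raw record
#' tables (including injected stale case versions — what
#' [write_faers_files()] writes) and the assembled ground-truth case set,
#' plus the closed-form true log reporting odds ratios implied by the
#' event-model coefficients.
#'
#' @param config A [sim_config()].
#' @return An object of class `faers_sim`: list with `config`; raw tables
#'   `demo`, `drugs`, `reactions`; `cases` (the analyzable `faers_cases`
#'   the pipeline should recover after dedup and assembly); and `truth`, a
#'   data frame of true conditional log odds ratios per drug, event and
#'   stratum (`NA` where an interaction makes the stratum odds ratio
#'   non-constant).
#' @export
simulate_faers <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_reports
  drugs <- names(config$drug_prevalence)
  events <- names(config$event_models)

  if (n == 0L) {
    empty_demo <- data.frame(primaryid = character(0), caseid = character(0),
                             caseversion = integer(0), fda_dt = integer(0),
                             age_value = numeric(0), age_unit = character(0),
                             sex_code = character(0),
                             stringsAsFactors = FALSE)
    empty_drug <- data.frame(primaryid = character(0), drugname = character(0),
                             role_code = character(0),
                             stringsAsFactors = FALSE)
    empty_reac <- data.frame(primaryid = character(0), pt_name = character(0),
                             pt_code = integer(0), stringsAsFactors = FALSE)
    cases <- assemble_cases(empty_demo, empty_drug, empty_reac)
    return(structure(list(config = config, demo = empty_demo,
                          drugs = empty_drug, reactions = empty_reac,
                          cases = cases, truth = .sim_truth(config)),
                     class = "faers_sim"))
  }

  # latent demographics
  female <- stats::runif(n) < config$p_female
  over65 <- stats::runif(n) < config$p_over65
  age_years <- ifelse(over65, stats::runif(n, 65, 95),
                      stats::runif(n, 18, 64))
  unit <- sample(names(config$age_unit_mix), n, replace = TRUE,
                 prob = config$age_unit_mix)
  day0 <- as.Date("2003-10-01")
  day1 <- as.Date("2024-09-30")
  ndays <- as.integer(day1 - day0) + 1L
  date <- day0 + (sample.int(ndays, n, replace = TRUE) - 1L)

  # exposures and role codes
  exposed <- matrix(FALSE, n, length(drugs), dimnames = list(NULL, drugs))
  for (d in drugs) {
    p <- .prevalence_vector(config$drug_prevalence[[d]], female, over65)
    exposed[, d] <- stats::runif(n) < p
  }
  roles <- matrix(sample(names(config$role_mix), n * length(drugs),
                         replace = TRUE, prob = config$role_mix),
                  n, length(drugs), dimnames = list(NULL, drugs))

  # events
  has_event <- matrix(FALSE, n, length(events),
                      dimnames = list(NULL, events))
  for (ev in events) {
    m <- config$event_models[[ev]]
    b0 <- if (is.null(m$intercept)) {
      stats::qlogis(config$background_event_rate)
    } else m$intercept
    eta <- rep(b0, n)
    for (d in names(m$drug)) eta <- eta + m$drug[[d]] * exposed[, d]
    eta <- eta + m$sex_f * female + m$age_over65 * over65
    for (d in names(m$drug_age)) {
      eta <- eta + m$drug_age[[d]] * exposed[, d] * over65
    }
    for (d in names(m$drug_sex_f)) {
      eta <- eta + m$drug_sex_f[[d]] * exposed[, d] * female
    }
    has_event[, ev] <- stats::runif(n) < stats::plogis(eta)
  }

  # stimulated-reporting date redraw for one pair (off by default)
  pb <- config$period_boost
  if (!is.null(pb)) {
    cut <- as.Date(pb$cutover)
    idx <- which(exposed[, pb$drug] & has_event[, pb$event])
    if (length(idx)) {
      pre_days <- as.integer(cut - day0)
      post_days <- as.integer(day1 - cut) + 1L
      p_post <- pb$multiplier * post_days /
        (pb$multiplier * post_days + pre_days)
      go_post <- stats::runif(length(idx)) < p_post
      off_post <- sample.int(post_days, length(idx), replace = TRUE) - 1L
      off_pre <- sample.int(pre_days, length(idx), replace = TRUE) - 1L
      date[idx] <- as.Date(ifelse(go_post, cut + off_post,
                                  day0 + off_pre), origin = "1970-01-01")
    }
  }

  # identifiers, missingness, duplicate versions
  caseid <- as.character(10000000L + seq_len(n))
  miss_sex <- stats::runif(n) < config$p_missing_sex
  miss_age <- stats::runif(n) < config$p_missing_age
  nd <- round(config$duplicate_fraction * n)
  dup_idx <- if (nd > 0) sort(sample.int(n, nd)) else integer(0)
  version <- rep(1L, n)
  version[dup_idx] <- 2L
  primaryid <- paste0(caseid, version)
  fda_dt <- as.integer(format(date, "%Y%m%d"))

  sex_code <- ifelse(female, "F", "M")
  sex_code[miss_sex] <- "UNK"
  age_value <- age_years / .age_unit_years[unit]
  age_value[miss_age] <- NA_real_

  demo <- data.frame(primaryid = primaryid, caseid = caseid,
                     caseversion = version, fda_dt = fda_dt,
                     age_value = unname(age_value), age_unit = unit,
                     sex_code = sex_code, stringsAsFactors = FALSE)

  # drug mentions: study drugs where exposed, plus one background drug
  idx_list <- lapply(drugs, function(d) which(exposed[, d]))
  drug_tab <- data.frame(
    primaryid = c(primaryid[unlist(idx_list)], primaryid),
    drugname = c(rep(drugs, lengths(idx_list)),
                 sample(.background_drugs, n, replace = TRUE)),
    role_code = c(unlist(lapply(drugs, function(d)
      roles[exposed[, d], d])),
      sample(names(config$role_mix), n, replace = TRUE,
             prob = config$role_mix)),
    stringsAsFactors = FALSE)

  # reaction mentions: one PT per event present; filler PT otherwise
  ev_idx <- lapply(events, function(ev) which(has_event[, ev]))
  reac_parts <- lapply(seq_along(events), function(k) {
    idx <- ev_idx[[k]]
    if (!length(idx)) return(NULL)
    terms <- config$event_queries[[events[k]]]$terms
    pick <- sample.int(nrow(terms), length(idx), replace = TRUE)
    data.frame(primaryid = primaryid[idx], pt_name = terms$pt_name[pick],
               pt_code = terms$pt_code[pick], stringsAsFactors = FALSE)
  })
  no_event <- !apply(has_event, 1L, any)
  filler_pick <- sample.int(nrow(.filler_pts), n, replace = TRUE)
  reac_parts <- c(reac_parts, list(data.frame(
    primaryid = primaryid[no_event],
    pt_name = .filler_pts$pt_name[filler_pick[no_event]],
    pt_code = .filler_pts$pt_code[filler_pick[no_event]],
    stringsAsFactors = FALSE)))
  reac_tab <- do.call(rbind, reac_parts[!vapply(reac_parts, is.null,
                                                logical(1))])
  rownames(reac_tab) <- NULL

  # stale version-1 records for duplicated cases (earlier receipt date,
  # same mentions under the stale primaryid)
  if (length(dup_idx)) {
    stale_pid <- paste0(caseid[dup_idx], 1L)
    stale_date <- date[dup_idx] - sample(30:400, length(dup_idx),
                                         replace = TRUE)
    stale_demo <- demo[dup_idx, , drop = FALSE]
    stale_demo$primaryid <- stale_pid
    stale_demo$caseversion <- 1L
    stale_demo$fda_dt <- as.integer(format(stale_date, "%Y%m%d"))
    remap <- function(tab) {
      sub <- tab[tab$primaryid %in% primaryid[dup_idx], , drop = FALSE]
      sub$primaryid <- stale_pid[match(sub$primaryid, primaryid[dup_idx])]
      sub
    }
    demo <- rbind(demo, stale_demo)
    drug_tab <- rbind(drug_tab, remap(drug_tab))
    reac_tab <- rbind(reac_tab, remap(reac_tab))
    rownames(demo) <- rownames(drug_tab) <- rownames(reac_tab) <- NULL
  }

  # ground-truth analyzable case set, built from the latent values
  keep <- !miss_sex & !miss_age
  cases_demo <- data.frame(
    primaryid = primaryid[keep], caseid = caseid[keep],
    caseversion = version[keep], fda_dt = fda_dt[keep],
    age_years = age_years[keep],
    age_group = factor(ifelse(age_years[keep] >= 65, "over65", "under65"),
                       levels = c("under65", "over65")),
    sex = ifelse(female[keep], "F", "M"), stringsAsFactors = FALSE)
  kept_pid <- cases_demo$primaryid
  cases_drugs <- drug_tab[drug_tab$primaryid %in% kept_pid, , drop = FALSE]
  cases_drugs$drugname_norm <- normalize_drugname(cases_drugs$drugname)
  cases_reac <- reac_tab[reac_tab$primaryid %in% kept_pid, , drop = FALSE]
  rownames(cases_demo) <- rownames(cases_drugs) <- rownames(cases_reac) <-
    NULL
  cases <- structure(list(
    demo = cases_demo, drugs = cases_drugs, reactions = cases_reac,
    log = list(n_in = n, n_kept = nrow(cases_demo),
               n_dropped_age = sum(miss_age),
               n_dropped_sex = sum(miss_sex & !miss_age),
               n_orphan_drug = 0L, n_orphan_reac = 0L)),
    class = "faers_cases")

  structure(list(config = config, demo = demo, drugs = drug_tab,
                 reactions = reac_tab, cases = cases,
                 truth = .sim_truth(config)),
            class = "faers_sim")
}

# closed-form conditional log odds ratios implied by the coefficients
.sim_truth <- function(config) {
  drugs <- names(config$drug_prevalence)
  events <- names(config$event_models)
  rows <- list()
  for (ev in events) {
    m <- config$event_models[[ev]]
    for (d in drugs) {
      b <- if (d %in% names(m$drug)) m$drug[[d]] else 0
      ba <- if (d %in% names(m$drug_age)) m$drug_age[[d]] else 0
      bs <- if (d %in% names(m$drug_sex_f)) m$drug_sex_f[[d]] else 0
      rows[[length(rows) + 1L]] <- data.frame(
        drug = d, event = ev,
        stratum = c("all", "under65", "over65", "F", "M"),
        true_ln_or = c(
          if (ba == 0 && bs == 0) b else NA_real_,
          if (bs == 0) b else NA_real_,
          if (bs == 0) b + ba else NA_real_,
          if (ba == 0) b + bs else NA_real_,
          if (ba == 0) b else NA_real_),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.faers_sim <- function(x, ...) {
  cat("Synthetic FAERS report set: ", x$config$n_reports,
      " reports (+", nrow(x$demo) - x$config$n_reports,
      " stale versions), ", length(x$config$drug_prevalence), " drug(s), ",
      length(x$config$event_models), " event(s), seed ", x$config$seed,
      "\n", sep = "")
  invisible(x)
}

#' Write a synthetic report set as FAERS ASCII files
#'
#' Emits `DEMO.txt`, `DRUG.txt` and `REAC.txt` ($-delimited, with header
#' lines) into `dir`, ages encoded in the mixed units drawn at generation
#' time. Reading the files back with [read_faers_table()], [deduplicate()]
#' and [assemble_cases()] recovers the generator's case set.
#'
#' @param sim A `faers_sim` from [simulate_faers()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths.
#' @export
write_faers_files <- function(sim, dir) {
  stopifnot(inherits(sim, "faers_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- function(x) {
    out <- ifelse(is.na(x), "",
                  if (is.numeric(x)) sprintf("%.10g", x) else as.character(x))
    out
  }
  emit <- function(df, path) {
    lines <- c(paste(names(df), collapse = "$"),
               do.call(paste, c(lapply(df, fmt), sep = "$")))
    writeLines(lines, path)
    path
  }
  d <- sim$demo
  demo_out <- data.frame(primaryid = d$primaryid, caseid = d$caseid,
                         caseversion = d$caseversion, fda_dt = d$fda_dt,
                         age = d$age_value, age_cod = d$age_unit,
                         sex = d$sex_code, stringsAsFactors = FALSE)
  drug_out <- data.frame(primaryid = sim$drugs$primaryid,
                         drugname = sim$drugs$drugname,
                         role_cod = sim$drugs$role_code,
                         stringsAsFactors = FALSE)
  reac_out <- data.frame(primaryid = sim$reactions$primaryid,
                         pt = sim$reactions$pt_name,
                         pt_code = sim$reactions$pt_code,
                         stringsAsFactors = FALSE)
  c(DEMO = emit(demo_out, file.path(dir, "DEMO.txt")),
    DRUG = emit(drug_out, file.path(dir, "DRUG.txt")),
    REAC = emit(reac_out, file.path(dir, "REAC.txt")))
}

#' Read FAERS files from a directory and assemble cases
#'
#' Convenience wrapper: reads `DEMO*.txt`, `DRUG*.txt`, `REAC*.txt` in
#' `dir` (several quarters are concatenated), deduplicates and assembles.
#'
#' @param dir Directory of FAERS ASCII files.
#' @param dialect Optional column-map dialect (see [read_faers_table()]).
#' @return A `faers_cases` object.
#' @export
read_faers_dir <- function(dir, dialect = NULL) {
  read_kind <- function(pattern, kind) {
    paths <- list.files(dir, pattern = pattern, full.names = TRUE,
                        ignore.case = TRUE)
    if (!length(paths)) stop("no ", kind, " file found in ", dir)
    do.call(rbind, lapply(paths, read_faers_table, table_kind = kind,
                          dialect = dialect))
  }
  demo <- read_kind("^DEMO.*\\.txt$", "DEMO")
  drugs <- read_kind("^DRUG.*\\.txt$", "DRUG")
  reacs <- read_kind("^REAC.*\\.txt$", "REAC")
  assemble_cases(deduplicate(demo), drugs, reacs)
}
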