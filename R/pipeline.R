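# Orchestration: the full disproportionality analysis over a drug x event
# grid, with age/sex stratification, cross-stratum Z comparisons, Holm
# correction, signal flags, period splits and the role-code sensitivity
# analysis.
#
# Adjustment scheme: the overall estimate adjusts for sex and age group;
# age-stratum estimates adjust for sex; sex-stratum estimates adjust for
# age group.

.strata_all <- c("all", "under65", "over65", "F", "M")
.adjust_for_stratum <- list(all = c("sex", "age_group"),
                            under65 = "sex", over65 = "sex",
                            F = "age_group", M = "age_group")

#' Run the full disproportionality analysis
#'
#' For every drug-event pair: the 2x2 table, crude and covariate-adjusted
#' reporting odds ratios overall and per age/sex stratum, cross-stratum Z
#' comparisons, Holm correction within each analysis surface (the overall
#' grid, the age contrasts, the sex contrasts — each its own family,
#' counting only estimable tests), and signal flags. Heat-map style
#' matrices (events x drugs) are derived from the result table by the
#' blanking rule: the overall matrix blanks cells with adjusted ROR below
#' `ror_threshold` or Holm-corrected p at or above `alpha`; stratum
#' matrices blank on the ROR threshold alone.
#'
#' @param cases A `faers_cases` object (deduplicated, assembled), e.g. from
#'   [read_faers_dir()] or [simulate_faers()].
#' @param drug_queries Named list of [drug_query()]s.
#' @param event_queries Named list of [event_query()]s.
#' @param roles `"primary_only"` (default) or `"all_roles"`; overrides the
#'   queries' own role sets.
#' @param min_cases Minimum co-reporting cases for estimability and for the
#'   signal criterion (default 3).
#' @param ror_threshold Signal / blanking ROR threshold (default 2).
#' @param alpha Significance level (default 0.05).
#' @param signal_p `"holm"` (default) applies the signal p criterion to the
#'   family-corrected p; `"raw"` uses the unadjusted Wald p.
#' @param period_split Optional cutover date (`"YYYY-MM-DD"` or `YYYYMMDD`
#'   integer): the analysis is run separately on cases received before vs
#'   from the cutover, returning `list(pre = , post = )`.
#' @return A `result_bundle`: list with data frames `results` (one row per
#'   drug, event, stratum, kind), `comparisons`, `cohort`; matrices
#'   `matrix_overall`, `matrix_stratum` (list), `ratio_age`, `ratio_sex`
#'   with significance companions; and `log` (stage counts).
#' @export
run_analysis <- function(cases, drug_queries, event_queries,
                         roles = c("primary_only", "all_roles"),
                         min_cases = 3L, ror_threshold = 2, alpha = 0.05,
                         signal_p = c("holm", "raw"), period_split = NULL) {
  roles <- match.arg(roles)
  signal_p <- match.arg(signal_p)
  if (!is.null(period_split)) {
    halves <- split_by_period(cases, period_split)
    return(lapply(halves, run_analysis, drug_queries = drug_queries,
                  event_queries = event_queries, roles = roles,
                  min_cases = min_cases, ror_threshold = ror_threshold,
                  alpha = alpha, signal_p = signal_p))
  }
  if (n_cases(cases) == 0L) stop("no analyzable cases")
  drug_queries <- set_roles(drug_queries, roles)

  demo <- cases$demo
  drug_flags <- lapply(drug_queries, function(q) case_matches_drug(cases, q))
  event_flags <- lapply(event_queries, function(q)
    case_matches_event(cases, q))
  masks <- lapply(.strata_all, function(s) stratum_mask(demo, s))
  names(masks) <- .strata_all
  demo_sub <- lapply(masks, function(m) list(demo = demo[m, , drop = FALSE]))

  dn <- names(drug_queries)
  en <- names(event_queries)
  res_rows <- list()
  res_obj <- list()   # keyed drug|event|stratum -> adjusted dispro_result
  cohort_rows <- list()
  for (d in dn) {
    for (e in en) {
      df <- drug_flags[[d]]
      ef <- event_flags[[e]]
      hit <- df & ef
      nhit <- sum(hit)
      cohort_rows[[paste(d, e)]] <- data.frame(
        drug = d, event = e, n_cases = nhit,
        pct_female = if (nhit) 100 * sum(demo$sex[hit] == "F") / nhit
                     else NA_real_,
        pct_over65 = if (nhit)
          100 * sum(demo$age_group[hit] == "over65") / nhit else NA_real_,
        stringsAsFactors = FALSE)
      crude <- dispro_from_flags(demo_sub[["all"]], df, ef, d, e,
                                 adjust_for = NULL, stratum = "all",
                                 min_cases = min_cases)
      res_rows[[paste(d, e, "all", "crude")]] <- .result_row(crude)
      for (s in .strata_all) {
        m <- masks[[s]]
        r <- dispro_from_flags(demo_sub[[s]], df[m], ef[m], d, e,
                               adjust_for = .adjust_for_stratum[[s]],
                               stratum = s, min_cases = min_cases)
        res_rows[[paste(d, e, s, "adjusted")]] <- .result_row(r)
        res_obj[[paste(d, e, s, sep = "|")]] <- r
      }
    }
  }
  results <- do.call(rbind, res_rows)
  rownames(results) <- NULL
  cohort <- do.call(rbind, cohort_rows)
  rownames(cohort) <- NULL
  class(cohort) <- c("cohort_summary", "data.frame")

  # Holm within the overall grid, then signal flags
  ov <- results$stratum == "all" & results$kind == "adjusted"
  results$p_holm <- NA_real_
  results$p_holm[ov] <- holm_adjust(results$p_wald[ov])
  results$signal <- FALSE
  p_sig <- if (signal_p == "holm") results$p_holm[ov]
           else results$p_wald[ov]
  results$signal[ov] <- !is.na(results$ror[ov]) & results$estimable[ov] &
    results$ror[ov] >= ror_threshold & !is.na(p_sig) & p_sig < alpha &
    results$n_cases[ov] >= min_cases

  # cross-stratum comparisons, Holm per surface
  comp_rows <- list()
  for (d in dn) {
    for (e in en) {
      ca <- compare_strata(res_obj[[paste(d, e, "over65", sep = "|")]],
                           res_obj[[paste(d, e, "under65", sep = "|")]])
      cs <- compare_strata(res_obj[[paste(d, e, "F", sep = "|")]],
                           res_obj[[paste(d, e, "M", sep = "|")]])
      comp_rows[[paste(d, e, "age")]] <- data.frame(
        drug = d, event = e, comparison = "over65_vs_under65",
        ratio = ca$ratio, z = ca$z, p_raw = ca$p_raw,
        estimable = ca$estimable, stringsAsFactors = FALSE)
      comp_rows[[paste(d, e, "sex")]] <- data.frame(
        drug = d, event = e, comparison = "F_vs_M",
        ratio = cs$ratio, z = cs$z, p_raw = cs$p_raw,
        estimable = cs$estimable, stringsAsFactors = FALSE)
    }
  }
  comparisons <- do.call(rbind, comp_rows)
  rownames(comparisons) <- NULL
  comparisons$p_holm <- NA_real_
  for (surf in unique(comparisons$comparison)) {
    i <- comparisons$comparison == surf
    comparisons$p_holm[i] <- holm_adjust(comparisons$p_raw[i])
  }
  comparisons$significant <- !is.na(comparisons$p_holm) &
    comparisons$p_holm < alpha

  # heat-map style matrices (rows = events, columns = drugs)
  grid_matrix <- function(rows, value, blank) {
    m <- matrix(NA_real_, length(en), length(dn),
                dimnames = list(en, dn))
    for (i in seq_len(nrow(rows))) {
      if (!blank[i]) m[rows$event[i], rows$drug[i]] <- value[i]
    }
    m
  }
  ov_rows <- results[ov, , drop = FALSE]
  matrix_overall <- grid_matrix(
    ov_rows, ov_rows$ror,
    !ov_rows$estimable | is.na(ov_rows$ror) |
      ov_rows$ror < ror_threshold |
      is.na(ov_rows$p_holm) | ov_rows$p_holm >= alpha)
  matrix_stratum <- lapply(setdiff(.strata_all, "all"), function(s) {
    rs <- results[results$stratum == s & results$kind == "adjusted", ,
                  drop = FALSE]
    grid_matrix(rs, rs$ror,
                !rs$estimable | is.na(rs$ror) | rs$ror < ror_threshold)
  })
  names(matrix_stratum) <- setdiff(.strata_all, "all")
  ratio_matrix <- function(surf) {
    rs <- comparisons[comparisons$comparison == surf, , drop = FALSE]
    list(ratio = grid_matrix(rs, rs$ratio, !rs$estimable),
         significant = grid_matrix(rs, as.numeric(rs$significant),
                                   !rs$estimable) == 1)
  }
  ra <- ratio_matrix("over65_vs_under65")
  rs_ <- ratio_matrix("F_vs_M")

  log <- list(
    n_cases = n_cases(cases),
    assembly = cases$log,
    n_matching_drug = vapply(drug_flags, sum, numeric(1)),
    n_matching_event = vapply(event_flags, sum, numeric(1)),
    n_results = nrow(results),
    n_estimable_overall = sum(ov_rows$estimable),
    n_signals = sum(results$signal),
    roles = roles, min_cases = min_cases,
    ror_threshold = ror_threshold, alpha = alpha, signal_p = signal_p)

  structure(list(results = results, comparisons = comparisons,
                 cohort = cohort, matrix_overall = matrix_overall,
                 matrix_stratum = matrix_stratum,
                 ratio_age = ra$ratio, ratio_age_sig = ra$significant,
                 ratio_sex = rs_$ratio, ratio_sex_sig = rs_$significant,
                 log = log),
            class = "result_bundle")
}

.result_row <- function(r) {
  data.frame(
    drug = r$drug, event = r$event, stratum = r$stratum, kind = r$kind,
    adjusted_for = paste(r$adjusted_for, collapse = "+"),
    ror = r$ror, ln_ror = r$ln_ror, se_ln = r$se_ln,
    ci_low = r$ci_low, ci_high = r$ci_high, p_wald = r$p_wald,
    n_cases = r$n_cases, estimable = r$estimable,
    reason = if (is.null(r$reason)) NA_character_ else r$reason,
    stringsAsFactors = FALSE)
}

#' @export
print.result_bundle <- function(x, ...) {
  cat("Disproportionality result bundle\n")
  cat("  cases:", x$log$n_cases, " roles:", x$log$roles, "\n")
  cat("  grid:", ncol(x$matrix_overall), "drug(s) x",
      nrow(x$matrix_overall), "event(s);",
      x$log$n_estimable_overall, "estimable overall aROR(s),",
      x$log$n_signals, "signal(s)\n")
  sig <- x$results[x$results$signal, c("drug", "event", "ror", "ci_low",
                                       "ci_high", "p_holm", "n_cases")]
  if (nrow(sig)) {
    cat("  signals (aROR, 95% CI, Holm p):\n")
    sig$ror <- round(sig$ror, 2)
    sig$ci_low <- round(sig$ci_low, 2)
    sig$ci_high <- round(sig$ci_high, 2)
    sig$p_holm <- signif(sig$p_holm, 3)
    print(sig, row.names = FALSE)
  }
  invisible(x)
}

#' Split a case set at a cutover date
#'
#' Partitions by FDA receipt date: `pre` holds cases with `fda_dt` strictly
#' before the cutover, `post` those at or after it. Cases with a missing
#' receipt date are dropped with a warning.
#'
#' @param cases A `faers_cases` object.
#' @param cutover `"YYYY-MM-DD"` string or `YYYYMMDD` integer.
#' @return `list(pre = faers_cases, post = faers_cases)`.
#' @export
split_by_period <- function(cases, cutover) {
  cut <- if (is.character(cutover)) {
    as.integer(format(as.Date(cutover), "%Y%m%d"))
  } else as.integer(cutover)
  dt <- cases$demo$fda_dt
  if (anyNA(dt)) {
    warning(sum(is.na(dt)), " case(s) without receipt date dropped from ",
            "the period split")
  }
  list(pre = subset_cases(cases, !is.na(dt) & dt < cut),
       post = subset_cases(cases, !is.na(dt) & dt >= cut))
}

#' Primary-suspect vs all-roles sensitivity analysis
#'
#' Runs the adjusted estimate for every drug-event pair within each age and
#' sex subgroup twice — counting exposure only for primary-suspect (PS)
#' mentions vs for all four designation types — and tabulates the paired
#' RORs and the agreement of their signal flags (Holm-corrected within each
#' subgroup-by-mode family).
#'
#' @inheritParams run_analysis
#' @param subgroups Stratum labels to analyze (default the four age/sex
#'   subgroups).
#' @return Data frame with one row per drug, event and subgroup: the
#'   PS-only and all-roles aRORs, their signal flags and `agree`;
#'   `attr(, "agreement")` holds the per-subgroup flag-agreement rates.
#' @export
run_sensitivity <- function(cases, drug_queries, event_queries,
                            subgroups = c("under65", "over65", "F", "M"),
                            min_cases = 3L, ror_threshold = 2,
                            alpha = 0.05, signal_p = c("holm", "raw")) {
  signal_p <- match.arg(signal_p)
  one_mode <- function(roles) {
    qs <- set_roles(drug_queries, roles)
    demo <- cases$demo
    drug_flags <- lapply(qs, function(q) case_matches_drug(cases, q))
    event_flags <- lapply(event_queries, function(q)
      case_matches_event(cases, q))
    rows <- list()
    for (s in subgroups) {
      m <- stratum_mask(demo, s)
      sub <- list(demo = demo[m, , drop = FALSE])
      adj <- .adjust_for_stratum[[s]]
      for (d in names(qs)) {
        for (e in names(event_queries)) {
          r <- dispro_from_flags(sub, drug_flags[[d]][m],
                                 event_flags[[e]][m], d, e,
                                 adjust_for = adj, stratum = s,
                                 min_cases = min_cases)
          rows[[paste(d, e, s)]] <- .result_row(r)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out$p_holm <- NA_real_
    for (s in subgroups) {
      i <- out$stratum == s
      out$p_holm[i] <- holm_adjust(out$p_wald[i])
    }
    p <- if (signal_p == "holm") out$p_holm else out$p_wald
    out$signal <- out$estimable & !is.na(out$ror) &
      out$ror >= ror_threshold & !is.na(p) & p < alpha &
      out$n_cases >= min_cases
    out
  }
  ps <- one_mode("primary_only")
  al <- one_mode("all_roles")
  key <- c("drug", "event", "stratum")
  merged <- merge(ps[, c(key, "ror", "ci_low", "ci_high", "n_cases",
                         "estimable", "signal")],
                  al[, c(key, "ror", "ci_low", "ci_high", "n_cases",
                         "estimable", "signal")],
                  by = key, suffixes = c("_ps", "_all"), sort = TRUE)
  merged$agree <- merged$signal_ps == merged$signal_all
  agreement <- tapply(merged$agree, merged$stratum, mean)
  structure(merged, agreement = agreement)
}

#' Write a result bundle as TSV tables plus a JSON manifest
#'
#' Emits `results.tsv`, `comparisons.tsv`, `cohort.tsv`, the heat-map style
#' matrices (`matrix_overall.tsv`, `matrix_<stratum>.tsv`,
#' `ratio_age.tsv`, `ratio_sex.tsv`) and `manifest.json` (thresholds,
#' stage counts, package version).
#'
#' @param bundle A `result_bundle` from [run_analysis()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_result_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wm <- function(m, name) {
    df <- data.frame(event = rownames(m), m, check.names = FALSE)
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  w(bundle$results, "results.tsv")
  w(bundle$comparisons, "comparisons.tsv")
  w(as.data.frame(bundle$cohort), "cohort.tsv")
  wm(bundle$matrix_overall, "matrix_overall.tsv")
  for (s in names(bundle$matrix_stratum)) {
    wm(bundle$matrix_stratum[[s]], paste0("matrix_", s, ".tsv"))
  }
  wm(bundle$ratio_age, "ratio_age.tsv")
  wm(bundle$ratio_sex, "ratio_sex.tsv")
  manifest <- c(bundle$log[c("roles", "min_cases", "ror_threshold", "alpha",
                             "signal_p", "n_cases", "n_results",
                             "n_estimable_overall", "n_signals")],
                list(package_version =
                       as.character(utils::packageVersion("faersdispro"))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
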