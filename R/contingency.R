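# Drug-event 2x2 contingency tables against the full-database background.
#
# For one drug query and one event query, within one stratum of the case
# set:
#   A = cases matching both drug and event      B = drug only
#   C = event only                              D = neither
# The background (B, C, D) is every analyzable case in the stratum, not
# just cases on comparator drugs.

# parse a stratum label ("all", "F", "M", "under65", "over65", or crossed
# like "F:over65") into a logical mask over demo rows
stratum_mask <- function(demo, stratum) {
  if (is.null(stratum) || identical(stratum, "all")) {
    return(rep(TRUE, nrow(demo)))
  }
  parts <- strsplit(stratum, ":", fixed = TRUE)[[1L]]
  keep <- rep(TRUE, nrow(demo))
  for (p in parts) {
    if (p %in% c("F", "M")) {
      keep <- keep & demo$sex == p
    } else if (p %in% c("under65", "over65")) {
      keep <- keep & as.character(demo$age_group) == p
    } else {
      stop("unknown stratum component: ", p)
    }
  }
  keep
}

#' Filter a case set to a stratum
#'
#' @param cases A `faers_cases` object.
#' @param stratum Stratum label: `"all"`, `"F"`, `"M"`, `"under65"`,
#'   `"over65"`, or a crossed label such as `"F:over65"`.
#' @return A `faers_cases` containing only the stratum's cases.
#' @export
filter_stratum <- function(cases, stratum) {
  subset_cases(cases, stratum_mask(cases$demo, stratum))
}

# single counting path shared by build_table() and the pipeline fast path
table_from_flags <- function(drug_flag, event_flag, drug_name, event_name,
                             stratum = "all") {
  A <- sum(drug_flag & event_flag)
  B <- sum(drug_flag & !event_flag)
  C <- sum(!drug_flag & event_flag)
  D <- sum(!drug_flag & !event_flag)
  structure(list(A = A, B = B, C = C, D = D,
                 drug = drug_name, event = event_name, stratum = stratum,
                 n_total = A + B + C + D),
            class = "contingency_table")
}

#' Build a drug-event 2x2 contingency table
#'
#' Counts deduplicated cases (never PT mentions) in one stratum; the
#' background is every analyzable case in that stratum.
#'
#' @param cases A `faers_cases` object (deduplicated, assembled).
#' @param drug_q A [drug_query()].
#' @param event_q An [event_query()].
#' @param stratum Stratum label (see [filter_stratum()]).
#' @return An object of class `contingency_table` with cells `A`, `B`, `C`,
#'   `D`, the query names, the stratum label and `n_total`.
#' @examples
#' # toy: 2 cases with drug+event, 1 drug only, 1 event only, 2 neither
#' # gives (A, B, C, D) = (2, 1, 1, 2)
#' @export
build_table <- function(cases, drug_q, event_q, stratum = "all") {
  sub <- filter_stratum(cases, stratum)
  if (nrow(sub$demo) == 0L) {
    warning("empty case set in stratum '", stratum, "': table of zeros")
  }
  table_from_flags(case_matches_drug(sub, drug_q),
                   case_matches_event(sub, event_q),
                   drug_q$name, event_q$name, stratum)
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("2x2 table  %s x %s  [stratum: %s]\n", x$drug, x$event,
              x$stratum))
  m <- matrix(c(x$A, x$B, x$C, x$D), 2, byrow = TRUE,
              dimnames = list(c("drug", "no drug"),
                              c("event", "no event")))
  print(m)
  invisible(x)
}

#' Audit that stratum tables collapse to the pooled table
#'
#' When the strata partition the case set, the cellwise sums of the
#' per-stratum tables must equal the pooled table. A mismatch signals an
#' internal counting inconsistency and raises an error naming the first
#' offending cell.
#'
#' @param tables List of `contingency_table`s, one per stratum level.
#' @param pooled The pooled (`"all"`) `contingency_table`.
#' @return `TRUE` invisibly when the audit passes.
#' @export
collapse_check <- function(tables, pooled) {
  for (cell in c("A", "B", "C", "D")) {
    s <- sum(vapply(tables, `[[`, numeric(1), cell))
    if (s != pooled[[cell]]) {
      stop("collapse check failed for cell ", cell, ": strata sum ", s,
           " != pooled ", pooled[[cell]], " (", pooled$drug, " x ",
           pooled$event, ")")
    }
  }
  invisible(TRUE)
}

#' Table-2 style cohort summary for one drug-event pair
#'
#' Number of cases reporting both the drug and the event, with the
#' percentage female and the percentage aged 65 or older among them.
#' Percentages are missing when there are no cases.
#'
#' @param cases A `faers_cases` object.
#' @param drug_q A [drug_query()].
#' @param event_q An [event_query()].
#' @return An object of class `cohort_summary` (also a one-row data frame)
#'   with `drug`, `event`, `n_cases`, `pct_female`, `pct_over65`
#'   (percentages unrounded; the print method shows one decimal).
#' @export
summarize_cohort <- function(cases, drug_q, event_q) {
  hit <- case_matches_drug(cases, drug_q) & case_matches_event(cases, event_q)
  n <- sum(hit)
  out <- data.frame(
    drug = drug_q$name, event = event_q$name, n_cases = n,
    pct_female = if (n > 0) 100 * sum(cases$demo$sex[hit] == "F") / n
                 else NA_real_,
    pct_over65 = if (n > 0)
      100 * sum(cases$demo$age_group[hit] == "over65") / n else NA_real_,
    stringsAsFactors = FALSE)
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  y <- as.data.frame(x)
  y$pct_female <- round(y$pct_female, 1)
  y$pct_over65 <- round(y$pct_over65, 1)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Minimum-case inclusion gate
#'
#' A drug-event pair enters the analysis only with at least `threshold`
#' cases reporting both (cell A); the same gate marks stratum cells below
#' the threshold as not estimable.
#'
#' @param table A `contingency_table`.
#' @param threshold Minimum number of co-reporting cases (default 3).
#' @return `TRUE` iff `A >= threshold`.
#' @export
min_case_gate <- function(table, threshold = 3L) {
  stopifnot(threshold >= 1L)
  table$A >= threshold
}
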