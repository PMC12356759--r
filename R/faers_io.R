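# Reading FAERS quarterly ASCII extracts and assembling analyzable cases.
#
# FAERS distributes each quarter as $-delimited ASCII tables with a header
# line (DEMO, DRUG, REAC, ...). The post-2012Q3 layout is targeted; legacy
# LAERS files can be read by supplying a column-map dialect.

.faers_required_cols <- list(
  DEMO = c(primaryid = "primaryid", caseid = "caseid",
           caseversion = "caseversion", fda_dt = "fda_dt",
           age_value = "age", age_unit = "age_cod", sex_code = "sex"),
  DRUG = c(primaryid = "primaryid", drugname = "drugname",
           role_code = "role_cod"),
  REAC = c(primaryid = "primaryid", pt_name = "pt")
)

.faers_optional_cols <- list(
  DEMO = c(quarter = "quarter"),
  DRUG = character(0),
  REAC = c(pt_code = "pt_code")
)

#' Read one FAERS-format ASCII table
#'
#' Parses a $-delimited FAERS quarterly file (DEMO, DRUG or REAC) into a
#' data frame with standardized column names. Unknown columns are ignored;
#' empty fields become `NA`. Lines whose field count does not match the
#' header are skipped and counted (attribute `"skipped"` on the result).
#'
#' @param path Path to the ASCII file. The first line must be a `$`-delimited
#'   header naming the columns.
#' @param table_kind One of `"DEMO"`, `"DRUG"`, `"REAC"`.
#' @param dialect Optional named character vector mapping standard column
#'   names to the names used in the file, e.g. `c(sex_code = "gndr_cod")`
#'   for pre-2014 quarters. See [load_dialect()].
#' @return A data frame. For DEMO: `primaryid`, `caseid`, `caseversion`,
#'   `fda_dt`, `age_value`, `age_unit`, `sex_code` (and `quarter` when
#'   present). For DRUG: `primaryid`, `drugname`, `role_code`. For REAC:
#'   `primaryid`, `pt_name`, `pt_code` (code `NA` when the file has none).
#' @export
read_faers_table <- function(path, table_kind = c("DEMO", "DRUG", "REAC"),
                             dialect = NULL) {
  table_kind <- match.arg(table_kind)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty file (no header line): ", path)

  header <- strsplit(lines[[1L]], "$", fixed = TRUE)[[1L]]
  header <- tolower(trimws(header))

  std <- .faers_required_cols[[table_kind]]
  opt <- .faers_optional_cols[[table_kind]]
  if (!is.null(dialect)) {
    dialect <- unlist(dialect)
    known <- names(dialect) %in% c(names(std), names(opt))
    if (any(!known)) {
      warning("ignoring unknown dialect entries: ",
              paste(names(dialect)[!known], collapse = ", "))
    }
    std[names(dialect)[known & names(dialect) %in% names(std)]] <-
      dialect[known & names(dialect) %in% names(std)]
    opt[names(dialect)[known & names(dialect) %in% names(opt)]] <-
      dialect[known & names(dialect) %in% names(opt)]
  }

  idx <- match(tolower(std), header)
  if (anyNA(idx)) {
    stop("malformed ", table_kind, " header in ", path,
         ": missing required column(s) ",
         paste(std[is.na(idx)], collapse = ", "))
  }
  opt_idx <- match(tolower(opt), header)

  body <- lines[-1L]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "$", fixed = TRUE)
  # a trailing empty field is dropped by strsplit; tolerate one short
  nf <- lengths(fields)
  ok <- nf == length(header) | nf == length(header) - 1L
  n_skipped <- sum(!ok)
  if (n_skipped > 0L) {
    message(n_skipped, " malformed line(s) skipped in ", path)
  }
  fields <- fields[ok]

  pull <- function(i) {
    if (is.na(i)) return(rep(NA_character_, length(fields)))
    out <- vapply(fields, function(f) if (i <= length(f)) f[[i]] else "",
                  character(1))
    out[!nzchar(trimws(out))] <- NA_character_
    trimws(out)
  }

  out <- switch(table_kind,
    DEMO = data.frame(
      primaryid   = pull(idx[[1L]]),
      caseid      = pull(idx[[2L]]),
      caseversion = suppressWarnings(as.integer(pull(idx[[3L]]))),
      fda_dt      = suppressWarnings(as.integer(pull(idx[[4L]]))),
      age_value   = suppressWarnings(as.numeric(pull(idx[[5L]]))),
      age_unit    = toupper(pull(idx[[6L]])),
      sex_code    = toupper(pull(idx[[7L]])),
      stringsAsFactors = FALSE),
    DRUG = data.frame(
      primaryid = pull(idx[[1L]]),
      drugname  = pull(idx[[2L]]),
      role_code = toupper(pull(idx[[3L]])),
      stringsAsFactors = FALSE),
    REAC = data.frame(
      primaryid = pull(idx[[1L]]),
      pt_name   = pull(idx[[2L]]),
      pt_code   = suppressWarnings(as.integer(pull(opt_idx[[1L]]))),
      stringsAsFactors = FALSE)
  )
  if (table_kind == "DEMO") {
    q <- pull(opt_idx[[1L]])
    if (!all(is.na(q))) out$quarter <- q
  }
  bad <- is.na(out$primaryid)
  if (any(bad)) {
    message(sum(bad), " line(s) without primaryid dropped in ", path)
    out <- out[!bad, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- n_skipped
  out
}

#' Load a column-map dialect from a JSON file
#'
#' A dialect maps this package's standard column names to the column names
#' found in a particular FAERS/LAERS vintage, e.g.
#' `{"sex_code": "gndr_cod"}`.
#'
#' @param path Path to a JSON object of `standard_name: file_name` pairs.
#' @return A named character vector usable as the `dialect` argument of
#'   [read_faers_table()].
#' @export
load_dialect <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- unlist(x)
  storage.mode(out) <- "character"
  out
}

# years per unit of each FAERS age code
.age_unit_years <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.1775,
                     DY = 1 / 365.25, HR = 1 / 8766)

#' Convert FAERS age codes to years
#'
#' FAERS reports age with a unit code: `DEC` decades, `YR` years, `MON`
#' months, `WK` weeks, `DY` days, `HR` hours. Weeks, days and hours are
#' converted with Julian-year constants (365.25 days = 8766 hours per year).
#' Unknown unit codes and negative ages yield `NA` with a warning.
#'
#' @param age_value Numeric vector of reported ages (unit-encoded).
#' @param age_unit Character vector of unit codes, recycled against
#'   `age_value`.
#' @return Numeric vector of ages in years.
#' @examples
#' harmonize_age(c(5, 18, 24), c("DEC", "YR", "MON"))  # 50, 18, 2
#' @export
harmonize_age <- function(age_value, age_unit) {
  n <- max(length(age_value), length(age_unit))
  age_value <- rep_len(as.numeric(age_value), n)
  age_unit <- rep_len(toupper(as.character(age_unit)), n)
  fac <- .age_unit_years[age_unit]
  unknown <- !is.na(age_value) & !is.na(age_unit) & is.na(fac)
  if (any(unknown)) {
    warning(sum(unknown), " age value(s) with unknown unit code set to NA")
  }
  out <- age_value * as.numeric(fac)
  neg <- !is.na(out) & out < 0
  if (any(neg)) {
    warning(sum(neg), " negative age value(s) set to NA")
    out[neg] <- NA_real_
  }
  unname(out)
}

#' Remove duplicate case versions from a DEMO table
#'
#' FAERS cases are versioned: the same `caseid` reappears with increasing
#' `caseversion` as follow-up information arrives. Following the FDA's
#' recommendation, only the most recent version of each case is kept:
#' highest `caseversion`, ties broken by latest `fda_dt`, then by largest
#' `primaryid`. The operation is idempotent.
#'
#' @param demo A DEMO data frame as returned by [read_faers_table()].
#' @return The DEMO data frame with at most one row per `caseid`, in the
#'   original row order of the kept records.
#' @export
deduplicate <- function(demo) {
  if (nrow(demo) == 0L) return(demo)
  pid_num <- suppressWarnings(as.numeric(demo$primaryid))
  if (anyNA(pid_num)) pid_num <- xtfrm(demo$primaryid)  # lexicographic fallback
  ver <- ifelse(is.na(demo$caseversion), -Inf, demo$caseversion)
  dt <- ifelse(is.na(demo$fda_dt), -Inf, demo$fda_dt)
  ord <- order(demo$caseid, -ver, -dt, -pid_num)
  keep_first <- !duplicated(demo$caseid[ord])
  keep_rows <- sort(ord[keep_first])
  out <- demo[keep_rows, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble analyzable case reports
#'
#' Joins drug and reaction mentions to a deduplicated DEMO table by
#' `primaryid`, harmonizes age to years, and keeps only cases with a known
#' age and sex `F`/`M` (FAERS codes `UNK`, `NS` and empty are treated as
#' missing). Cases are grouped into age bands below 65 and 65-plus (the
#' threshold is inclusive: 65.0 years is `over65`).
#'
#' @param demo Deduplicated DEMO data frame (see [deduplicate()]).
#' @param drugs DRUG data frame.
#' @param reactions REAC data frame.
#' @return An object of class `faers_cases`: a list with data frames
#'   `demo` (one row per case: `primaryid`, `caseid`, `caseversion`,
#'   `fda_dt`, `age_years`, `age_group`, `sex`), `drugs` (mentions joined to
#'   kept cases, with a `drugname_norm` column), `reactions`, and `log`, a
#'   list of filter counts (`n_in`, `n_kept`, `n_dropped_age`,
#'   `n_dropped_sex`, `n_orphan_drug`, `n_orphan_reac`).
#' @export
assemble_cases <- function(demo, drugs, reactions) {
  n_in <- nrow(demo)
  age_years <- harmonize_age(demo$age_value, demo$age_unit)
  sex <- demo$sex_code
  sex[!sex %in% c("F", "M")] <- NA_character_
  ok_age <- is.finite(age_years)
  ok_sex <- !is.na(sex)
  keep <- ok_age & ok_sex
  out_demo <- data.frame(
    primaryid = demo$primaryid[keep],
    caseid = demo$caseid[keep],
    caseversion = demo$caseversion[keep],
    fda_dt = demo$fda_dt[keep],
    age_years = age_years[keep],
    age_group = factor(ifelse(age_years[keep] >= 65, "over65", "under65"),
                       levels = c("under65", "over65")),
    sex = sex[keep],
    stringsAsFactors = FALSE)
  rownames(out_demo) <- NULL

  known_pid <- demo$primaryid            # any demo record, kept or not
  kept_pid <- out_demo$primaryid
  orphan_drug <- !(drugs$primaryid %in% known_pid)
  orphan_reac <- !(reactions$primaryid %in% known_pid)

  out_drugs <- drugs[drugs$primaryid %in% kept_pid, , drop = FALSE]
  out_drugs$drugname_norm <- normalize_drugname(out_drugs$drugname)
  out_reac <- reactions[reactions$primaryid %in% kept_pid, , drop = FALSE]
  rownames(out_drugs) <- rownames(out_reac) <- NULL

  log <- list(
    n_in = n_in,
    n_kept = nrow(out_demo),
    n_dropped_age = sum(!ok_age),
    n_dropped_sex = sum(ok_age & !ok_sex),
    n_orphan_drug = sum(orphan_drug),
    n_orphan_reac = sum(orphan_reac))
  if (log$n_orphan_drug + log$n_orphan_reac > 0L) {
    message("dropped ", log$n_orphan_drug, " drug and ", log$n_orphan_reac,
            " reaction mention(s) with no matching case record")
  }
  structure(list(demo = out_demo, drugs = out_drugs, reactions = out_reac,
                 log = log),
            class = "faers_cases")
}

#' @export
print.faers_cases <- function(x, ...) {
  cat("FAERS case set:", nrow(x$demo), "cases,",
      nrow(x$drugs), "drug mentions,",
      nrow(x$reactions), "reaction mentions\n")
  if (nrow(x$demo) > 0L) {
    cat(sprintf("  %.1f%% female, %.1f%% aged 65+\n",
                100 * mean(x$demo$sex == "F"),
                100 * mean(x$demo$age_group == "over65")))
  }
  cat("  assembly log:", x$log$n_in, "in /", x$log$n_kept, "kept (",
      x$log$n_dropped_age, "no age,", x$log$n_dropped_sex, "no sex )\n")
  invisible(x)
}

#' Number of cases in a case set
#' @param cases A `faers_cases` object.
#' @return Integer count of case reports.
#' @export
n_cases <- function(cases) nrow(cases$demo)

# subset a faers_cases by a logical over demo rows
subset_cases <- function(cases, keep) {
  pid <- cases$demo$primaryid[keep]
  structure(list(
    demo = cases$demo[keep, , drop = FALSE],
    drugs = cases$drugs[cases$drugs$primaryid %in% pid, , drop = FALSE],
    reactions = cases$reactions[cases$reactions$primaryid %in% pid, ,
                                drop = FALSE],
    log = cases$log), class = "faers_cases")
}

#' Write / read a flat case store
#'
#' Serializes an assembled case set as a TSV with one row per case, drug and
#' reaction mentions pipe-joined (`ROLE:name`, `code:pt`) — a plain-text
#' format for inspection and small fixtures.
#'
#' @param cases A `faers_cases` object.
#' @param path Output (input) TSV path.
#' @return `write_case_store` returns `path` invisibly; `read_case_store`
#'   returns a `faers_cases` object.
#' @export
write_case_store <- function(cases, path) {
  d <- cases$demo
  join <- function(df, key, fmt) {
    s <- split(fmt(df), df$primaryid)
    out <- vapply(s, paste, character(1), collapse = "|")
    unname(out[match(key, names(s))])
  }
  drug_str <- join(cases$drugs, d$primaryid,
                   function(df) paste0(df$role_code, ":", df$drugname))
  reac_str <- join(cases$reactions, d$primaryid,
                   function(df) paste0(ifelse(is.na(df$pt_code), "NA",
                                              df$pt_code), ":", df$pt_name))
  flat <- data.frame(d[, c("primaryid", "caseid", "caseversion", "fda_dt")],
                     age_years = sprintf("%.10g", d$age_years),
                     age_group = as.character(d$age_group), sex = d$sex,
                     drugs = ifelse(is.na(drug_str), "", drug_str),
                     reactions = ifelse(is.na(reac_str), "", reac_str),
                     stringsAsFactors = FALSE)
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_case_store
#' @export
read_case_store <- function(path) {
  flat <- utils::read.delim(path, colClasses = "character")
  demo <- data.frame(
    primaryid = flat$primaryid, caseid = flat$caseid,
    caseversion = as.integer(flat$caseversion),
    fda_dt = as.integer(flat$fda_dt),
    age_years = as.numeric(flat$age_years),
    age_group = factor(flat$age_group, levels = c("under65", "over65")),
    sex = flat$sex, stringsAsFactors = FALSE)
  unpack <- function(col, two_part) {
    idx <- rep(seq_along(col), ifelse(nzchar(col), lengths(strsplit(col, "|",
                                                            fixed = TRUE)), 0))
    parts <- unlist(strsplit(col[nzchar(col)], "|", fixed = TRUE))
    m <- regmatches(parts, regexpr(":", parts), invert = TRUE)
    data.frame(primaryid = flat$primaryid[idx],
               a = vapply(m, `[`, character(1), 1L),
               b = vapply(m, `[`, character(1), 2L),
               stringsAsFactors = FALSE)
  }
  dr <- unpack(flat$drugs)
  drugs <- data.frame(primaryid = dr$primaryid, drugname = dr$b,
                      role_code = dr$a, stringsAsFactors = FALSE)
  drugs$drugname_norm <- normalize_drugname(drugs$drugname)
  re <- unpack(flat$reactions)
  reactions <- data.frame(primaryid = re$primaryid, pt_name = re$b,
                          pt_code = suppressWarnings(as.integer(re$a)),
                          stringsAsFactors = FALSE)
  structure(list(demo = demo, drugs = drugs, reactions = reactions,
                 log = list(n_in = nrow(demo), n_kept = nrow(demo),
                            n_dropped_age = 0L, n_dropped_sex = 0L,
                            n_orphan_drug = 0L, n_orphan_reac = 0L)),
            class = "faers_cases")
}
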