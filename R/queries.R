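# Drug and adverse-event queries.
#
# An event query is a set of MedDRA preferred terms (PT name + code), either
# a standardized MedDRA query (SMQ, licensed term lists supplied by the
# user) or a self-defined PT set. A drug query is a synonym dictionary plus
# the FAERS role codes it accepts (PS/SS/C/I).

#' Construct an adverse-event query
#'
#' @param name Query label, e.g. `"Sedation"`.
#' @param terms Data frame with columns `pt_name` (character) and `pt_code`
#'   (integer MedDRA PT code, may be `NA`). Required non-empty for
#'   `self_defined` queries; `standard_smq` entries may be created as
#'   placeholders with zero terms until a licensed term list is supplied.
#' @param kind `"self_defined"` or `"standard_smq"`.
#' @param smq_code Integer MedDRA SMQ code (standard SMQs only).
#' @return An object of class `event_query`.
#' @export
event_query <- function(name, terms = NULL,
                        kind = c("self_defined", "standard_smq"),
                        smq_code = NA_integer_) {
  kind <- match.arg(kind)
  if (is.null(terms)) {
    terms <- data.frame(pt_name = character(0), pt_code = integer(0))
  }
  stopifnot(is.data.frame(terms), all(c("pt_name", "pt_code") %in%
                                        names(terms)))
  terms$pt_name <- as.character(terms$pt_name)
  terms$pt_code <- as.integer(terms$pt_code)
  if (kind == "self_defined" && nrow(terms) == 0L) {
    stop("self-defined query '", name, "' must have at least one PT term")
  }
  codes <- terms$pt_code[!is.na(terms$pt_code)]
  if (anyDuplicated(codes)) {
    stop("duplicate PT codes in query '", name, "'")
  }
  structure(list(name = name, smq_code = as.integer(smq_code), kind = kind,
                 terms = terms),
            class = "event_query")
}

#' @export
print.event_query <- function(x, ...) {
  cat("Event query:", x$name,
      if (x$kind == "standard_smq") sprintf("(SMQ %d)", x$smq_code)
      else "(self-defined)", "-", nrow(x$terms), "PT term(s)\n")
  invisible(x)
}

#' Construct a drug query
#'
#' @param name Canonical drug label, e.g. `"risperidone"`.
#' @param synonyms Character vector of name strings (verbatim or already
#'   normalized; normalized internally with [normalize_drugname()]).
#' @param allowed_roles FAERS role codes that count as exposure; default
#'   `"PS"` (primary suspect). The sensitivity analysis uses all four.
#' @param match_mode `"exact"` matches normalized names against the synonym
#'   set; `"substring"` also matches when a synonym occurs inside a longer
#'   normalized name (e.g. combination products).
#' @return An object of class `drug_query`.
#' @export
drug_query <- function(name, synonyms, allowed_roles = "PS",
                       match_mode = c("exact", "substring")) {
  match_mode <- match.arg(match_mode)
  synonyms <- unique(normalize_drugname(c(name, synonyms)))
  allowed_roles <- toupper(allowed_roles)
  stopifnot(length(synonyms) > 0L, length(allowed_roles) > 0L,
            all(allowed_roles %in% c("PS", "SS", "C", "I")))
  structure(list(name = name, synonyms = synonyms,
                 allowed_roles = allowed_roles, match_mode = match_mode),
            class = "drug_query")
}

#' @export
print.drug_query <- function(x, ...) {
  cat("Drug query:", x$name, "-", length(x$synonyms), "synonym(s), roles {",
      paste(x$allowed_roles, collapse = ", "), "}\n")
  invisible(x)
}

#' Normalize a verbatim drug name
#'
#' Uppercases, trims, collapses internal whitespace and strips trailing
#' parentheticals (dose/formulation annotations).
#'
#' @param raw Character vector of verbatim FAERS drug names.
#' @return Character vector of normalized names.
#' @examples
#' normalize_drugname(" Risperidone  (2mg) ")  # "RISPERIDONE"
#' @export
normalize_drugname <- function(raw) {
  x <- toupper(trimws(as.character(raw)))
  x <- gsub("\\s+", " ", x)
  repeat {
    y <- sub("\\s*\\([^()]*\\)$", "", x)
    if (identical(y, x)) break
    x <- trimws(y)
  }
  x
}

#' Built-in adverse-event queries
#'
#' The 18 event groups analyzed for antipsychotic safety: 13 standardized
#' MedDRA queries (narrow scope; shipped as name + SMQ code placeholders —
#' MedDRA term lists are licensed and must be supplied by the user, see
#' [load_event_queries()]) and 5 self-defined PT sets (sedation, weight
#' gain, cognitive impairment, SIADH/hyponatraemia, hyperprolactinaemia)
#' shipped with their full PT name/code lists.
#'
#' @return Named list of `event_query` objects.
#' @export
builtin_event_queries <- function() {
  sd <- function(name, pt_names, pt_codes) {
    event_query(name, data.frame(pt_name = pt_names, pt_code = pt_codes),
                kind = "self_defined")
  }
  smq <- function(name, code) {
    event_query(name, kind = "standard_smq", smq_code = code)
  }
  qs <- list(
    smq("Accidents and injuries", 20000135L),
    smq("Agranulocytosis", 20000023L),
    smq("Anticholinergic syndrome", 20000048L),
    smq("Dyslipidaemia", 20000026L),
    smq("Hyperglycaemia/new onset diabetes mellitus", 20000041L),
    sd("Weight gain",
       c("Abnormal weight gain", "Obesity", "Central obesity", "Overweight",
         "Weight increased", "Body mass index increased"),
       c(10000188L, 10029883L, 10065941L, 10033307L, 10047899L, 10005897L)),
    smq("Akathisia", 20000096L),
    smq("Dyskinesia", 20000097L),
    smq("Dystonia", 20000098L),
    smq("Parkinson-like events", 20000099L),
    smq("Neuroleptic malignant syndrome", 20000044L),
    smq("Sexual dysfunction", 20000238L),
    smq("Torsade de pointes/QT prolongation", 20000001L),
    smq("Suicide/self-injury", 20000037L),
    sd("Sedation", c("Sedation", "Somnolence"), c(10039897L, 10041349L)),
    sd("Cognitive impairment",
       c("Cognitive disorder", "Memory impairment", "Amnesia",
         "Confusional state", "Dementia", "Disturbance in attention",
         "Disorientation", "Speech disorder", "Disorganised speech",
         "Aphasia", "Delirium"),
       c(10057668L, 10027175L, 10001949L, 10010305L, 10012267L, 10013496L,
         10013395L, 10041466L, 10076227L, 10002948L, 10012218L)),
    sd("SIADH/Hyponatraemia",
       c("Blood sodium decreased", "Hyponatraemia",
         "Inappropriate antidiuretic hormone secretion",
         "Hyponatraemic syndrome", "Hyponatraemic encephalopathy",
         "Hyponatraemic seizure", "Hyponatraemic coma"),
       c(10005802L, 10021036L, 10053198L, 10021037L, 10066151L, 10073183L,
         10075865L)),
    sd("Hyperprolactinaemia",
       c("Gynecomastia", "Blood prolactin abnormal",
         "Blood prolactin increased", "Galactorrhea", "Hyperprolactinaemia"),
       c(10018800L, 10005778L, 10005780L, 10017600L, 10020737L))
  )
  names(qs) <- vapply(qs, `[[`, character(1), "name")
  qs
}

#' Built-in drug queries for six antipsychotics
#'
#' Best-effort synonym dictionaries (generic + common brand names) for
#' aripiprazole, clozapine, olanzapine, quetiapine, risperidone and
#' haloperidol. Synonym sets are configurable via [load_drug_queries()].
#'
#' @param allowed_roles Role codes counting as exposure (default `"PS"`).
#' @return Named list of `drug_query` objects.
#' @export
builtin_drug_queries <- function(allowed_roles = "PS") {
  dq <- function(name, syn) drug_query(name, syn, allowed_roles)
  qs <- list(
    dq("aripiprazole", c("ABILIFY", "ABILIFY MAINTENA", "ARISTADA")),
    dq("clozapine", c("CLOZARIL", "LEPONEX", "FAZACLO", "VERSACLOZ")),
    dq("olanzapine", c("ZYPREXA", "ZYPREXA ZYDIS", "ZYPREXA RELPREVV",
                       "OLANZAPINE PAMOATE")),
    dq("quetiapine", c("SEROQUEL", "SEROQUEL XR", "QUETIAPINE FUMARATE")),
    dq("risperidone", c("RISPERDAL", "RISPERDAL CONSTA", "RISPERDAL M-TAB",
                        "PERSERIS")),
    dq("haloperidol", c("HALDOL", "HALDOL DECANOATE",
                        "HALOPERIDOL DECANOATE", "HALOPERIDOL LACTATE"))
  )
  names(qs) <- vapply(qs, `[[`, character(1), "name")
  qs
}

#' Which cases match a drug query
#'
#' A case matches when at least one of its drug mentions has a normalized
#' name in the query's synonym set and a role code among the query's
#' allowed roles. Matching is monotone in roles: a primary-suspect match is
#' also an all-roles match.
#'
#' @param cases A `faers_cases` object (a single-case set gives a scalar).
#' @param q A `drug_query`.
#' @return Logical vector aligned with `cases$demo` rows.
#' @export
case_matches_drug <- function(cases, q) {
  stopifnot(inherits(q, "drug_query"))
  d <- cases$drugs
  nm <- d$drugname_norm
  if (is.null(nm)) nm <- normalize_drugname(d$drugname)
  if (q$match_mode == "exact") {
    name_ok <- nm %in% q$synonyms
  } else {
    name_ok <- rep(FALSE, length(nm))
    for (s in q$synonyms) name_ok <- name_ok | grepl(s, nm, fixed = TRUE)
  }
  hit <- name_ok & d$role_code %in% q$allowed_roles
  cases$demo$primaryid %in% unique(d$primaryid[hit])
}

#' Which cases match an event query
#'
#' A reaction mention matches a query term by PT code when the mention
#' carries one (code match takes precedence; a code/name disagreement is
#' reported via `message`), otherwise by case-insensitive PT name. A case
#' counts once per query no matter how many of its PTs match.
#'
#' @param cases A `faers_cases` object.
#' @param q An `event_query` with a non-empty term list.
#' @return Logical vector aligned with `cases$demo` rows.
#' @export
case_matches_event <- function(cases, q) {
  stopifnot(inherits(q, "event_query"))
  if (nrow(q$terms) == 0L) {
    stop("event query '", q$name, "' has no terms; supply a term list ",
         "(standard SMQ membership is licensed and not shipped)")
  }
  r <- cases$reactions
  codes <- q$terms$pt_code[!is.na(q$terms$pt_code)]
  names_lc <- tolower(q$terms$pt_name)
  has_code <- !is.na(r$pt_code)
  code_in <- has_code & r$pt_code %in% codes
  name_in <- tolower(r$pt_name) %in% names_lc
  disagree <- has_code & (code_in != name_in)
  if (any(disagree)) {
    message(sum(disagree), " reaction mention(s) where PT code and name ",
            "disagree for query '", q$name, "'; code match used")
  }
  hit <- ifelse(has_code, code_in, name_in)
  cases$demo$primaryid %in% unique(r$primaryid[hit])
}

#' Load event queries from a JSON definition file
#'
#' Format: a JSON array of objects
#' `{"name", "kind", "smq_code"?, "terms": [{"pt_name", "pt_code"}]}` —
#' the mechanism for supplying licensed SMQ term lists.
#'
#' @param path Path to the JSON file.
#' @return Named list of `event_query` objects.
#' @export
load_event_queries <- function(path) {
  xs <- jsonlite::read_json(path)
  qs <- lapply(xs, function(x) {
    terms <- if (length(x$terms)) {
      data.frame(
        pt_name = vapply(x$terms, function(t) as.character(t$pt_name),
                         character(1)),
        pt_code = vapply(x$terms, function(t)
          if (is.null(t$pt_code)) NA_integer_ else as.integer(t$pt_code),
          integer(1)))
    } else NULL
    event_query(x$name, terms, kind = x$kind,
                smq_code = if (is.null(x$smq_code)) NA_integer_
                           else as.integer(x$smq_code))
  })
  names(qs) <- vapply(qs, `[[`, character(1), "name")
  qs
}

#' Load drug queries from a JSON dictionary file
#'
#' Format: JSON array of
#' `{"name", "synonyms": [...], "allowed_roles": [...]}`.
#'
#' @param path Path to the JSON file.
#' @return Named list of `drug_query` objects.
#' @export
load_drug_queries <- function(path) {
  xs <- jsonlite::read_json(path)
  qs <- lapply(xs, function(x) {
    drug_query(x$name, unlist(x$synonyms),
               allowed_roles = if (length(x$allowed_roles))
                 unlist(x$allowed_roles) else "PS")
  })
  names(qs) <- vapply(qs, `[[`, character(1), "name")
  qs
}

#' Set the allowed roles on a list of drug queries
#'
#' Convenience for the primary-suspect vs all-designations sensitivity
#' analysis.
#'
#' @param drug_queries Named list of `drug_query` objects.
#' @param roles `"primary_only"` (PS) or `"all_roles"` (PS/SS/C/I), or a
#'   character vector of role codes.
#' @return The list with `allowed_roles` replaced on every query.
#' @export
set_roles <- function(drug_queries, roles = c("primary_only", "all_roles")) {
  if (length(roles) <= 2L && all(roles %in% c("primary_only", "all_roles"))) {
    roles <- match.arg(roles)
    roles <- if (roles == "primary_only") "PS" else c("PS", "SS", "C", "I")
  }
  lapply(drug_queries, function(q) {
    drug_query(q$name, q$synonyms, allowed_roles = roles,
               match_mode = q$match_mode)
  })
}
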