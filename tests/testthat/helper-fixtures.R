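# Fixture builders and independent oracles shared across the test files.

# Build a faers_cases set from a per-case spec data frame with columns:
#   sex, age (years), and optionally drug (NA = none), role, pt, pt_code,
#   fda_dt. Each case gets one background drug mention; cases with a pt
# get that reaction, others a filler reaction.
toy_case_set <- function(spec) {
  n <- nrow(spec)
  if (is.null(spec$role)) spec$role <- "PS"
  if (is.null(spec$pt)) spec$pt <- NA_character_
  if (is.null(spec$pt_code)) spec$pt_code <- NA_integer_
  if (is.null(spec$fda_dt)) spec$fda_dt <- 20150601L
  pid <- as.character(seq_len(n) + 1000L)
  demo <- data.frame(
    primaryid = pid, caseid = pid, caseversion = 1L,
    fda_dt = as.integer(spec$fda_dt), age_years = as.numeric(spec$age),
    age_group = factor(ifelse(spec$age >= 65, "over65", "under65"),
                       levels = c("under65", "over65")),
    sex = spec$sex, stringsAsFactors = FALSE)
  has_drug <- !is.na(spec$drug)
  drugs <- data.frame(
    primaryid = c(pid[has_drug], pid),
    drugname = c(spec$drug[has_drug], rep("FILLER MEDICATION", n)),
    role_code = c(spec$role[has_drug], rep("C", n)),
    stringsAsFactors = FALSE)
  drugs$drugname_norm <- faersdispro::normalize_drugname(drugs$drugname)
  has_pt <- !is.na(spec$pt)
  reactions <- data.frame(
    primaryid = c(pid[has_pt], pid[!has_pt]),
    pt_name = c(spec$pt[has_pt], rep("Filler reaction", sum(!has_pt))),
    pt_code = c(as.integer(spec$pt_code[has_pt]),
                rep(88000001L, sum(!has_pt))),
    stringsAsFactors = FALSE)
  structure(list(demo = demo, drugs = drugs, reactions = reactions,
                 log = list(n_in = n, n_kept = n, n_dropped_age = 0L,
                            n_dropped_sex = 0L, n_orphan_drug = 0L,
                            n_orphan_reac = 0L)),
            class = "faers_cases")
}

simple_drug_query <- function(name = "DRUGX", roles = "PS") {
  faersdispro::drug_query(name, name, allowed_roles = roles)
}

simple_event_query <- function(pt = "Eventish reaction", code = 77000001L,
                               name = "EventX") {
  faersdispro::event_query(name, data.frame(pt_name = pt, pt_code = code))
}

# random strictly-positive 2x2 table as a contingency_table
random_table <- function(max_cell = 500L) {
  cells <- sample.int(max_cell, 4L, replace = TRUE)
  structure(list(A = cells[1], B = cells[2], C = cells[3], D = cells[4],
                 drug = "d", event = "e", stratum = "all",
                 n_total = sum(cells)),
            class = "contingency_table")
}

# independent binomial log-likelihood for logistic cells (oracle side)
oracle_loglik <- function(beta, X, events, trials) {
  eta <- drop(X %*% beta)
  sum(events * eta - trials * log(1 + exp(pmin(eta, 700))))
}

# brute-force maximizer of the same likelihood, independent of the IRLS
# path: quasi-Newton from several starts
oracle_fit <- function(X, events, trials) {
  best <- NULL
  for (start in list(rep(0, ncol(X)), rep(0.5, ncol(X)),
                     rep(-0.5, ncol(X)))) {
    o <- stats::optim(start, oracle_loglik, X = X, events = events,
                      trials = trials,
                      control = list(fnscale = -1, maxit = 2000,
                                     reltol = 1e-14), method = "BFGS")
    if (is.null(best) || o$value > best$value) best <- o
  }
  stats::setNames(best$par, colnames(X))
}

# expand collapsed cells to one row per report (for the collapsed-vs-long
# fit equivalence checks)
expand_cells <- function(cells) {
  idx <- rep(seq_len(nrow(cells)), cells$trials)
  long <- cells[idx, setdiff(names(cells), c("events", "trials")),
                drop = FALSE]
  long$events <- unlist(lapply(seq_len(nrow(cells)), function(i) {
    c(rep(1L, cells$events[i]), rep(0L, cells$trials[i] - cells$events[i]))
  }))
  long$trials <- 1L
  rownames(long) <- NULL
  long
}
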