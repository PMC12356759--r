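# Crude and adjusted reporting odds ratios, signal criteria, cross-stratum
# Z comparisons and Holm correction.
#
# Crude ROR = (A/B)/(C/D) with the Woolf log-scale standard error
# sqrt(1/A + 1/B + 1/C + 1/D) and a 95% Wald CI; the Wald chi-square
# statistic is (ln ROR / se)^2 on 1 df. Adjusted RORs come from the
# logistic model in cell_logit.R; the same Wald statistic applies to
# beta_drug there, so a covariate-free "adjusted" fit and the crude table
# give identical p-values.

.z975 <- stats::qnorm(0.975)   # 1.959964

new_dispro_result <- function(drug, event, stratum, kind, adjusted_for,
                              ror = NA_real_, ln_ror = NA_real_,
                              se_ln = NA_real_, ci_low = NA_real_,
                              ci_high = NA_real_, p_wald = NA_real_,
                              n_cases = NA_integer_, estimable = FALSE,
                              reason = NA_character_, fit = NULL,
                              table = NULL) {
  structure(list(drug = drug, event = event, stratum = stratum, kind = kind,
                 adjusted_for = adjusted_for, ror = ror, ln_ror = ln_ror,
                 se_ln = se_ln, ci_low = ci_low, ci_high = ci_high,
                 p_wald = p_wald, n_cases = as.integer(n_cases),
                 estimable = estimable, reason = reason, fit = fit,
                 table = table),
            class = "dispro_result")
}

# shared Wald machinery on the log odds-ratio scale
wald_from_lnror <- function(ln_ror, se_ln) {
  chi2 <- (ln_ror / se_ln)^2
  list(ci_low = exp(ln_ror - .z975 * se_ln),
       ci_high = exp(ln_ror + .z975 * se_ln),
       p_wald = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Crude reporting odds ratio from a 2x2 table
#'
#' ROR = (A/B)/(C/D), Woolf standard error on the log scale, 95% Wald
#' confidence interval and Wald chi-square p-value. A table with any zero
#' cell is flagged not estimable; no continuity correction is applied.
#'
#' @param table A `contingency_table` (see [build_table()]), or anything
#'   with numeric components `A`, `B`, `C`, `D`.
#' @return A `dispro_result` with `kind = "crude"`.
#' @examples
#' t1 <- structure(list(A = 20, B = 80, C = 100, D = 900, drug = "x",
#'                      event = "y", stratum = "all", n_total = 1100),
#'                 class = "contingency_table")
#' crude_ror(t1)$ror   # 2.25
#' @export
crude_ror <- function(table) {
  A <- table$A; B <- table$B; C <- table$C; D <- table$D
  drug <- if (is.null(table$drug)) NA_character_ else table$drug
  event <- if (is.null(table$event)) NA_character_ else table$event
  stratum <- if (is.null(table$stratum)) "all" else table$stratum
  if (min(A, B, C, D) == 0) {
    return(new_dispro_result(drug, event, stratum, "crude", character(0),
                             n_cases = A, estimable = FALSE,
                             reason = "zero cell", table = table))
  }
  ln_ror <- log((A / B) / (C / D))
  se_ln <- sqrt(1 / A + 1 / B + 1 / C + 1 / D)
  w <- wald_from_lnror(ln_ror, se_ln)
  new_dispro_result(drug, event, stratum, "crude", character(0),
                    ror = exp(ln_ror), ln_ror = ln_ror, se_ln = se_ln,
                    ci_low = w$ci_low, ci_high = w$ci_high,
                    p_wald = w$p_wald, n_cases = A, estimable = TRUE,
                    table = table)
}

#' Fit a disproportionality estimate for one drug-event pair
#'
#' The front-end estimator: builds the 2x2 table in the requested stratum,
#' and either reports the crude reporting odds ratio (`adjust_for = NULL`
#' and `kind = "crude"`) or fits the covariate-adjusted logistic model on
#' collapsed cells and reports the adjusted ROR `exp(beta_drug)` with its
#' Wald CI and p-value. Results with fewer than `min_cases` co-reporting
#' cases, a zero margin, or a non-converged (separated) fit are flagged not
#' estimable rather than silently corrected.
#'
#' @param cases A `faers_cases` object.
#' @param drug_q A [drug_query()].
#' @param event_q An [event_query()].
#' @param adjust_for Covariates to adjust for: subset of
#'   `c("sex", "age_group")`. `NULL` or empty gives the crude estimator.
#' @param stratum Stratum label (see [filter_stratum()]).
#' @param min_cases Minimum A-cell count for estimability (default 3).
#' @return A `dispro_result`; for adjusted fits the `cell_logit` object is
#'   attached as `$fit` and the 2x2 table as `$table`.
#' @export
dispro <- function(cases, drug_q, event_q,
                   adjust_for = c("sex", "age_group"), stratum = "all",
                   min_cases = 3L) {
  sub <- filter_stratum(cases, stratum)
  drug_flag <- case_matches_drug(sub, drug_q)
  event_flag <- case_matches_event(sub, event_q)
  dispro_from_flags(sub, drug_flag, event_flag, drug_q$name, event_q$name,
                    adjust_for = adjust_for, stratum = stratum,
                    min_cases = min_cases)
}

# pipeline fast path: flags already computed on the stratum's cases
dispro_from_flags <- function(sub, drug_flag, event_flag, drug_name,
                              event_name,
                              adjust_for = c("sex", "age_group"),
                              stratum = "all", min_cases = 3L) {
  tab <- table_from_flags(drug_flag, event_flag, drug_name, event_name,
                          stratum)
  if (is.null(adjust_for) || length(adjust_for) == 0L) {
    res <- crude_ror(tab)
    if (res$estimable && res$n_cases < min_cases) {
      res$estimable <- FALSE
      res$reason <- sprintf("fewer than %d cases", min_cases)
    }
    return(res)
  }
  if (tab$A < min_cases) {
    return(new_dispro_result(drug_name, event_name, stratum, "adjusted",
                             adjust_for, n_cases = tab$A, estimable = FALSE,
                             reason = sprintf("fewer than %d cases",
                                              min_cases),
                             table = tab))
  }
  key <- data.frame(drug = as.integer(drug_flag))
  for (cv in adjust_for) key[[cv]] <- sub$demo[[cv]]
  agg_n <- stats::aggregate(list(trials = rep(1L, nrow(key))), key, sum)
  agg_e <- stats::aggregate(list(events = as.integer(event_flag)), key, sum)
  cells <- merge(agg_n, agg_e, by = names(key), sort = TRUE)
  fit <- tryCatch(fit_adjusted(cells, covariates = adjust_for),
                  error = function(e) e)
  if (inherits(fit, "error") || !fit$converged || !is.finite(fit$se["drug"])) {
    reason <- if (inherits(fit, "error")) conditionMessage(fit)
              else "separation / non-convergence"
    return(new_dispro_result(drug_name, event_name, stratum, "adjusted",
                             adjust_for, n_cases = tab$A, estimable = FALSE,
                             reason = reason,
                             fit = if (inherits(fit, "error")) NULL else fit,
                             table = tab))
  }
  ln_ror <- unname(coef(fit)["drug"])
  se_ln <- unname(fit$se["drug"])
  w <- wald_from_lnror(ln_ror, se_ln)
  new_dispro_result(drug_name, event_name, stratum, "adjusted", adjust_for,
                    ror = exp(ln_ror), ln_ror = ln_ror, se_ln = se_ln,
                    ci_low = w$ci_low, ci_high = w$ci_high,
                    p_wald = w$p_wald, n_cases = tab$A, estimable = TRUE,
                    fit = fit, table = tab)
}

#' @export
print.dispro_result <- function(x, ...) {
  lab <- if (x$kind == "adjusted") {
    sprintf("aROR (adjusted for %s)",
            if (length(x$adjusted_for)) paste(x$adjusted_for, collapse = ", ")
            else "nothing")
  } else "crude ROR"
  cat(sprintf("%s x %s [stratum: %s]\n", x$drug, x$event, x$stratum))
  if (x$estimable) {
    cat(sprintf("  %s = %.4g (95%% CI %.4g-%.4g), Wald p = %.3g, n = %d\n",
                lab, x$ror, x$ci_low, x$ci_high, x$p_wald, x$n_cases))
  } else {
    cat(sprintf("  %s not estimable (%s), n = %d\n", lab, x$reason,
                x$n_cases))
  }
  invisible(x)
}

#' @export
summary.dispro_result <- function(object, ...) {
  print(object)
  if (!is.null(object$table)) print(object$table)
  if (!is.null(object$fit)) print(summary(object$fit))
  invisible(object)
}

#' @export
coef.dispro_result <- function(object, ...) {
  if (!is.null(object$fit)) return(coef(object$fit))
  c(drug = object$ln_ror)
}

#' @export
confint.dispro_result <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- matrix(exp(object$ln_ror + c(-1, 1) * z * object$se_ln), 1,
              dimnames = list("ror", c(sprintf("%.1f %%", 50 * (1 - level)),
                                       sprintf("%.1f %%",
                                               100 - 50 * (1 - level)))))
  m
}

#' Apply the risk-signal criteria to a disproportionality result
#'
#' A signal requires reporting odds ratio at or above `min_ror`, p-value
#' below `alpha`, and at least `min_cases` co-reporting cases; all three
#' thresholds are configurable. A non-estimable result is never a signal
#' (the reason is attached as an attribute).
#'
#' @param result A `dispro_result`.
#' @param min_ror ROR threshold (default 2; inclusive).
#' @param alpha Significance threshold on `p` (default 0.05; exclusive).
#' @param min_cases Minimum case count (default 3; inclusive).
#' @param p The p-value to test; defaults to the result's Wald p, but a
#'   multiplicity-adjusted p (e.g. from [holm_adjust()]) can be supplied.
#' @return Logical; `attr(, "reason")` explains a `FALSE`.
#' @export
evaluate_signal <- function(result, min_ror = 2, alpha = 0.05,
                            min_cases = 3L, p = NULL) {
  if (!result$estimable) {
    return(structure(FALSE, reason = paste("not estimable:", result$reason)))
  }
  if (is.null(p)) p <- result$p_wald
  ok_ror <- result$ror >= min_ror
  ok_p <- p < alpha
  ok_n <- result$n_cases >= min_cases
  if (ok_ror && ok_p && ok_n) return(structure(TRUE, reason = NA_character_))
  structure(FALSE, reason = paste(c(
    if (!ok_ror) sprintf("ROR %.3g < %.3g", result$ror, min_ror),
    if (!ok_p) sprintf("p %.3g >= %.3g", p, alpha),
    if (!ok_n) sprintf("n %d < %d", result$n_cases, min_cases)),
    collapse = "; "))
}

#' Compare two stratum-specific adjusted RORs with a Z statistic
#'
#' Standard two-independent-estimates contrast on the log scale:
#' `z = (ln ROR_a - ln ROR_b) / sqrt(se_a^2 + se_b^2)` with a two-sided
#' normal p-value; the reported ratio is `ROR_a / ROR_b`. Swapping the
#' arguments negates `z` and leaves the p-value unchanged.
#'
#' @param a,b `dispro_result`s for the same drug, event and adjustment set
#'   in different strata (e.g. 65-plus vs under-65).
#' @return An object of class `stratum_comparison` with `ratio`, `z`,
#'   `p_raw` (and slots `p_holm`, `significant` filled by the pipeline's
#'   family-wise correction). If either input is not estimable the
#'   comparison is returned with `estimable = FALSE` and `NA` statistics.
#' @export
compare_strata <- function(a, b) {
  if (!identical(a$drug, b$drug) || !identical(a$event, b$event) ||
      !setequal(a$adjusted_for, b$adjusted_for)) {
    stop("compare_strata: results must share drug, event and adjustment set")
  }
  est <- isTRUE(a$estimable) && isTRUE(b$estimable)
  if (!est) {
    return(structure(list(result_a = a, result_b = b, ratio = NA_real_,
                          z = NA_real_, p_raw = NA_real_,
                          p_holm = NA_real_, significant = NA,
                          estimable = FALSE),
                     class = "stratum_comparison"))
  }
  z <- (a$ln_ror - b$ln_ror) / sqrt(a$se_ln^2 + b$se_ln^2)
  structure(list(result_a = a, result_b = b,
                 ratio = exp(a$ln_ror - b$ln_ror), z = z,
                 p_raw = 2 * stats::pnorm(-abs(z)), p_holm = NA_real_,
                 significant = NA, estimable = TRUE),
            class = "stratum_comparison")
}

#' @export
print.stratum_comparison <- function(x, ...) {
  cat(sprintf("%s x %s: %s vs %s\n", x$result_a$drug, x$result_a$event,
              x$result_a$stratum, x$result_b$stratum))
  if (x$estimable) {
    cat(sprintf("  aROR ratio = %.4g, z = %.4g, p = %.3g",
                x$ratio, x$z, x$p_raw))
    if (!is.na(x$p_holm)) cat(sprintf(", Holm p = %.3g", x$p_holm))
    cat("\n")
  } else {
    cat("  not estimable in at least one stratum\n")
  }
  invisible(x)
}

#' Holm (step-down Bonferroni) adjusted p-values
#'
#' Sort ascending, multiply the i-th smallest by (m - i + 1), enforce the
#' running maximum, cap at 1, and return in the original order. `NA`
#' entries (non-estimable tests) are passed through without inflating the
#' family size.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]` (`NA`
#'   allowed).
#' @return Adjusted p-values, same length and order.
#' @examples
#' holm_adjust(c(0.04, 0.01, 0.03))  # 0.06 0.03 0.06
#' @export
holm_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  stopifnot(all(is.na(p_values) | (p_values >= 0 & p_values <= 1)))
  out <- rep(NA_real_, length(p_values))
  ok <- !is.na(p_values)
  out[ok] <- stats::p.adjust(p_values[ok], method = "holm")
  out
}
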