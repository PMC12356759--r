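# Binomial logistic regression on collapsed count cells by
# Newton/iteratively-reweighted least squares.
#
# The adjusted reporting odds ratio is exp(beta_drug) from the model
#   logit P(event) = b0 + b_drug * drug + b_sex * I(F) + b_age * I(65+)
# fitted to cells collapsed over covariate patterns (events/trials per
# pattern). Fitting on collapsed cells is likelihood-identical to fitting
# one row per report; the test suite asserts that equivalence.

# log(1 + exp(x)) without overflow
log1pexp <- function(x) {
  out <- numeric(length(x))
  big <- x > 30
  out[big] <- x[big]
  out[!big] <- log1p(exp(x[!big]))
  out
}

#' Weighted logistic regression on aggregated counts
#'
#' Maximizes the binomial log-likelihood of `events` successes in `trials`
#' Bernoulli draws per cell under a logistic model, by Newton iteration
#' (IRLS). Convergence when the score's max norm falls below `tol_score` or
#' the relative log-likelihood change falls below `tol_ll`; a fit that
#' exhausts `max_iter` or diverges (as under complete separation) is
#' returned with `converged = FALSE`. Standard errors come from the inverse
#' observed information (equal to Fisher information at the logit link).
#'
#' @param formula Model formula whose left side is `cbind(events,
#'   non_events)`, e.g. `cbind(events, trials - events) ~ drug + sex`.
#' @param data Data frame of collapsed cells.
#' @param tol_score Convergence tolerance on the score max-norm.
#' @param tol_ll Convergence tolerance on the relative log-likelihood
#'   change.
#' @param max_iter Iteration cap.
#' @return An object of class `cell_logit` with components `coefficients`,
#'   `se`, `vcov`, `loglik`, `iterations`, `converged`, `fitted.values`
#'   (per-cell event probabilities) and the model frame pieces needed by
#'   `predict`.
#' @export
cell_logit <- function(formula, data, tol_score = 1e-8, tol_ll = 1e-10,
                       max_iter = 100L) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (is.null(dim(y)) || ncol(y) != 2L) {
    stop("response must be a two-column matrix: cbind(events, non_events)")
  }
  events <- y[, 1L]
  trials <- rowSums(y)
  if (any(events < 0) || any(events > trials)) {
    stop("events must lie in [0, trials] for every cell")
  }
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  keep <- trials > 0
  Xk <- X[keep, , drop = FALSE]
  ev <- events[keep]
  tr <- trials[keep]
  if (sum(ev) == 0 || sum(tr - ev) == 0) {
    stop("need at least one event and one non-event overall")
  }

  p <- ncol(Xk)
  beta <- numeric(p)
  if ("(Intercept)" %in% colnames(Xk)) {
    beta[colnames(Xk) == "(Intercept)"] <- stats::qlogis(sum(ev) / sum(tr))
  }
  ll <- function(b) {
    eta <- drop(Xk %*% b)
    sum(ev * eta - tr * log1pexp(eta))
  }
  loglik <- ll(beta)
  converged <- FALSE
  diverged <- FALSE
  iter <- 0L
  info <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(Xk %*% beta)
    mu <- stats::plogis(eta)
    w <- tr * mu * (1 - mu)
    score <- drop(crossprod(Xk, ev - tr * mu))
    info <- crossprod(Xk, Xk * w)
    if (max(abs(score)) < tol_score) {
      converged <- TRUE
      break
    }
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) {
      if (iter == 1L) stop("singular information matrix")
      diverged <- TRUE
      break
    }
    # step-halving to keep the likelihood non-decreasing
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      ll_new <- ll(cand)
      if (is.finite(ll_new) && ll_new >= loglik - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) break
    }
    rel <- abs(ll_new - loglik) / (abs(loglik) + 1e-10)
    beta <- cand
    loglik <- ll_new
    if (rel < tol_ll) {
      eta <- drop(Xk %*% beta)
      mu <- stats::plogis(eta)
      info <- crossprod(Xk, Xk * (tr * mu * (1 - mu)))
      converged <- max(abs(drop(crossprod(Xk, ev - tr * mu)))) < sqrt(tol_score)
      break
    }
  }
  if (max(abs(beta)) > 30) {   # odds ratio beyond e^30: separation in practice
    converged <- FALSE
    diverged <- TRUE
  }
  vc <- tryCatch(solve(info), error = function(e)
    matrix(NA_real_, p, p, dimnames = list(colnames(Xk), colnames(Xk))))
  dimnames(vc) <- list(colnames(Xk), colnames(Xk))
  se <- sqrt(diag(vc))
  names(beta) <- colnames(Xk)
  structure(list(
    coefficients = beta, se = se, vcov = vc, loglik = loglik,
    iterations = iter, converged = converged && !diverged,
    fitted.values = stats::plogis(drop(X %*% beta)),
    events = events, trials = trials,
    terms = attr(mf, "terms"), xlevels = stats::.getXlevels(attr(mf, "terms"),
                                                            mf),
    call = match.call()), class = "cell_logit")
}

#' @export
coef.cell_logit <- function(object, ...) object$coefficients

#' @export
vcov.cell_logit <- function(object, ...) object$vcov

#' @export
logLik.cell_logit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            class = "logLik")
}

#' @export
fitted.cell_logit <- function(object, ...) object$fitted.values

#' @export
residuals.cell_logit <- function(object,
                                 type = c("deviance", "pearson"), ...) {
  type <- match.arg(type)
  mu <- object$fitted.values
  ev <- object$events
  tr <- object$trials
  if (type == "pearson") {
    return((ev - tr * mu) / sqrt(pmax(tr * mu * (1 - mu), .Machine$double.eps)))
  }
  # binomial deviance residuals on cells
  dev_part <- function(obs, exp_) {
    out <- numeric(length(obs))
    nz <- obs > 0
    out[nz] <- obs[nz] * log(obs[nz] / exp_[nz])
    out
  }
  d2 <- 2 * (dev_part(ev, tr * mu) + dev_part(tr - ev, tr * (1 - mu)))
  sign(ev - tr * mu) * sqrt(pmax(d2, 0))
}

#' @export
predict.cell_logit <- function(object, newdata = NULL,
                               type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- stats::qlogis(object$fitted.values)
  } else {
    tt <- stats::delete.response(object$terms)
    mf <- stats::model.frame(tt, newdata, xlev = object$xlevels)
    X <- stats::model.matrix(tt, mf)
    eta <- drop(X %*% object$coefficients)
  }
  if (type == "response") stats::plogis(eta) else eta
}

#' @export
print.cell_logit <- function(x, ...) {
  cat("Cell-weighted logistic fit (", sum(x$trials), " reports in ",
      length(x$trials), " cells)\n", sep = "")
  print(round(rbind(coef = x$coefficients, se = x$se), 4))
  cat("log-likelihood", format(x$loglik), "in", x$iterations,
      "iteration(s);", if (x$converged) "converged" else "NOT converged",
      "\n")
  invisible(x)
}

#' @export
summary.cell_logit <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)),
               `exp(Est.)` = exp(object$coefficients))
  structure(list(coefficients = tab, loglik = object$loglik,
                 iterations = object$iterations,
                 converged = object$converged), class = "summary.cell_logit")
}

#' @export
print.summary.cell_logit <- function(x, ...) {
  stats::printCoefmat(x$coefficients, has.Pvalue = TRUE, P.values = TRUE)
  cat("log-likelihood", format(x$loglik), ";",
      if (x$converged) "converged" else "NOT converged", "\n")
  invisible(x)
}

#' Collapse a case set into logistic-regression count cells
#'
#' Tabulates events and trials over the covariate patterns
#' (drug exposure x requested covariates) in one stratum — the input to
#' [cell_logit()] / [fit_adjusted()].
#'
#' @param cases A `faers_cases` object.
#' @param drug_q A [drug_query()].
#' @param event_q An [event_query()].
#' @param covariates Subset of `c("sex", "age_group")` to include.
#' @param stratum Stratum label (see [filter_stratum()]).
#' @return Data frame with columns `drug` (0/1), the covariates (factors),
#'   `events` and `trials`, one row per observed pattern.
#' @export
collapse_cells <- function(cases, drug_q, event_q,
                           covariates = c("sex", "age_group"),
                           stratum = "all") {
  sub <- filter_stratum(cases, stratum)
  drug <- as.integer(case_matches_drug(sub, drug_q))
  event <- as.integer(case_matches_event(sub, event_q))
  key <- data.frame(drug = drug)
  for (cv in covariates) key[[cv]] <- sub$demo[[cv]]
  agg_n <- stats::aggregate(list(trials = rep(1L, nrow(key))), key, sum)
  agg_e <- stats::aggregate(list(events = event), key, sum)
  cells <- merge(agg_n, agg_e, by = names(key), sort = TRUE)
  cells[, c(names(key), "events", "trials")]
}

#' Fit the covariate-adjusted disproportionality model
#'
#' Logistic regression of event presence on drug exposure plus the given
#' covariates, on collapsed count cells. The adjusted reporting odds ratio
#' is `exp(coef(fit)["drug"])`. With an empty covariate set the fit
#' reproduces the crude reporting odds ratio and its standard error
#' exactly (saturated 2x2 logistic identity).
#'
#' @param cells Collapsed cells from [collapse_cells()]: columns `drug`,
#'   the covariates, `events`, `trials`.
#' @param covariates Character vector of covariate column names (possibly
#'   empty).
#' @param ... Passed to [cell_logit()] (tolerances, iteration cap).
#' @return A `cell_logit` fit.
#' @export
fit_adjusted <- function(cells, covariates = c("sex", "age_group"), ...) {
  covariates <- covariates[covariates %in% names(cells)]
  rhs <- paste(c("drug", covariates), collapse = " + ")
  f <- stats::as.formula(paste("cbind(events, trials - events) ~", rhs))
  cell_logit(f, cells, ...)
}
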