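# Crude and adjusted reporting odds ratios, signal criteria, Z comparisons
# and Holm correction.

tab <- function(A, B, C, D) {
  structure(list(A = A, B = B, C = C, D = D, drug = "d", event = "e",
                 stratum = "all", n_total = A + B + C + D),
            class = "contingency_table")
}

test_that("crude ROR reproduces the closed-form worked examples", {
  expect_equal(crude_ror(tab(10, 90, 100, 900))$ror, 1.0)
  expect_equal(crude_ror(tab(20, 80, 100, 900))$ror, 2.25)

  r <- crude_ror(tab(25, 25, 25, 25))
  expect_equal(r$ror, 1.0)
  expect_equal(r$se_ln, 0.4)
  expect_equal(r$ci_low, exp(-qnorm(0.975) * 0.4), tolerance = 1e-12)
  expect_equal(r$ci_high, exp(qnorm(0.975) * 0.4), tolerance = 1e-12)
  expect_equal(round(r$ci_low, 4), 0.4566)
  expect_equal(round(r$ci_high, 4), 2.1902)
  expect_equal(r$p_wald, 1)   # ln ROR = 0
  expect_equal(r$n_cases, 25L)
})

test_that("a zero cell makes the crude ROR not estimable, uncorrected", {
  for (z in list(tab(0, 10, 10, 10), tab(10, 0, 10, 10),
                 tab(10, 10, 0, 10), tab(10, 10, 10, 0))) {
    r <- crude_ror(z)
    expect_false(r$estimable)
    expect_true(is.na(r$ror))
    expect_match(r$reason, "zero cell")
  }
})

test_that("scaling all cells by k keeps the estimate, shrinks se by sqrt(k)", {
  set.seed(31)
  for (rep in 1:20) {
    t0 <- random_table()
    k <- sample(2:9, 1)
    t1 <- tab(k * t0$A, k * t0$B, k * t0$C, k * t0$D)
    r0 <- crude_ror(t0)
    r1 <- crude_ror(t1)
    expect_equal(r1$ror, r0$ror, tolerance = 1e-12)
    expect_equal(r1$se_ln, r0$se_ln / sqrt(k), tolerance = 1e-12)
  }
})

test_that("the Wald p equals the chi-square tail of (ln ROR / se)^2", {
  r <- crude_ror(tab(20, 80, 100, 900))
  expect_equal(r$p_wald,
               pchisq((r$ln_ror / r$se_ln)^2, 1, lower.tail = FALSE))
})

test_that("a covariate-free logistic fit reproduces the crude ROR exactly", {
  set.seed(32)
  for (rep in 1:50) {
    t0 <- random_table()
    cells <- data.frame(drug = c(1L, 0L),
                        events = c(t0$A, t0$C),
                        trials = c(t0$A + t0$B, t0$C + t0$D))
    fit <- fit_adjusted(cells, covariates = character(0))
    r <- crude_ror(t0)
    expect_equal(unname(coef(fit)["drug"]), r$ln_ror, tolerance = 1e-8)
    expect_equal(unname(fit$se["drug"]), r$se_ln, tolerance = 1e-8)
  }
})

test_that("duplicating cells across a balanced covariate leaves the drug
           coefficient at the crude value", {
  t0 <- tab(30, 170, 90, 710)
  cells <- data.frame(drug = c(1L, 0L, 1L, 0L),
                      sex = rep(c("F", "M"), each = 2),
                      events = c(t0$A, t0$C, t0$A, t0$C),
                      trials = c(t0$A + t0$B, t0$C + t0$D,
                                 t0$A + t0$B, t0$C + t0$D))
  fit <- fit_adjusted(cells, covariates = "sex")
  expect_equal(unname(coef(fit)["drug"]), crude_ror(t0)$ln_ror,
               tolerance = 1e-8)
})

test_that("a confounded 8-cell fixture matches the brute-force and glm
           oracles", {
  # sex is associated with both drug exposure and the event
  cells <- data.frame(
    drug = c(1L, 1L, 0L, 0L),
    sex = c("F", "M", "F", "M"),
    events = c(40L, 5L, 220L, 40L),
    trials = c(400L, 100L, 4000L, 2600L))
  fit <- fit_adjusted(cells, covariates = "sex")
  expect_true(fit$converged)

  X <- model.matrix(~ drug + sex, cells)
  beta_oracle <- oracle_fit(X, cells$events, cells$trials)
  expect_equal(unname(coef(fit)), unname(beta_oracle), tolerance = 1e-6)

  g <- glm(cbind(events, trials - events) ~ drug + sex, binomial, cells)
  expect_equal(unname(coef(fit)), unname(coef(g)), tolerance = 1e-7)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(g)))),
               tolerance = 1e-6)
  # the cell likelihood omits the data-only lchoose(n, k) constant
  expect_equal(as.numeric(logLik(fit)) +
                 sum(lchoose(cells$trials, cells$events)),
               as.numeric(logLik(g)), tolerance = 1e-6)

  # adjustment moves the estimate off the collapsed crude value here
  crude <- crude_ror(tab(45, 455, 260, 6340))
  expect_gt(abs(coef(fit)["drug"] - crude$ln_ror), 0.05)
})

test_that("collapsed-cell and one-row-per-report fits agree", {
  set.seed(33)
  for (rep in 1:5) {
    cells <- expand.grid(drug = 0:1, sex = c("F", "M"),
                         age_group = c("under65", "over65"))
    cells$trials <- sample(50:300, 8)
    cells$events <- rbinom(8, cells$trials, 0.15)
    fit_c <- fit_adjusted(cells, covariates = c("sex", "age_group"))
    long <- expand_cells(cells)
    fit_l <- fit_adjusted(long, covariates = c("sex", "age_group"))
    expect_equal(coef(fit_c), coef(fit_l), tolerance = 1e-6)
    expect_equal(fit_c$se, fit_l$se, tolerance = 1e-6)
  }
})

test_that("cell_logit model methods are mutually consistent", {
  cells <- data.frame(drug = c(1L, 1L, 0L, 0L),
                      sex = c("F", "M", "F", "M"),
                      events = c(40L, 5L, 220L, 40L),
                      trials = c(400L, 100L, 4000L, 2600L))
  fit <- cell_logit(cbind(events, trials - events) ~ drug + sex, cells)
  g <- glm(cbind(events, trials - events) ~ drug + sex, binomial, cells)
  expect_equal(unname(fitted(fit)), unname(fitted(g)), tolerance = 1e-7)
  expect_equal(sum(residuals(fit, "deviance")^2), deviance(g),
               tolerance = 1e-6)
  expect_equal(unname(predict(fit, cells, type = "response")),
               unname(fitted(fit)), tolerance = 1e-12)
  new <- data.frame(drug = 1L, sex = "F")
  expect_equal(unname(predict(fit, new, type = "link")),
               sum(coef(fit) * c(1, 1, 0)), tolerance = 1e-12)
  s <- summary(fit)
  expect_equal(unname(s$coefficients[, "Estimate"]), unname(coef(fit)))
})

test_that("complete separation is flagged, never silently corrected", {
  cells <- data.frame(drug = c(1L, 0L), events = c(30L, 0L),
                      trials = c(30L, 500L))
  fit <- fit_adjusted(cells, covariates = character(0))
  expect_false(fit$converged)
})

test_that("dispro() flags separated or sparse strata as not estimable", {
  spec <- data.frame(
    sex = rep(c("F", "M"), each = 20),
    age = rep(c(40, 70), 20),
    drug = rep(c("DRUGX", NA), c(10, 30)),
    pt = c(rep("Eventish reaction", 10), rep(NA, 30)),
    pt_code = 77000001L, stringsAsFactors = FALSE)
  cases <- toy_case_set(spec)
  # every exposed case has the event and no background case does:
  # a separated fit
  r <- dispro(cases, simple_drug_query(), simple_event_query())
  expect_false(r$estimable)

  # fewer than min_cases co-reports
  spec2 <- spec
  spec2$pt[3:10] <- NA
  r2 <- dispro(toy_case_set(spec2), simple_drug_query(),
               simple_event_query())
  expect_false(r2$estimable)
  expect_match(r2$reason, "fewer than 3")
})

test_that("signal criteria are inclusive for ROR and cases, exclusive
           for p", {
  mk <- function(ror, p, n) {
    structure(list(drug = "d", event = "e", stratum = "all",
                   kind = "adjusted", adjusted_for = c("sex", "age_group"),
                   ror = ror, ln_ror = log(ror), se_ln = 0.1,
                   ci_low = ror * 0.9, ci_high = ror * 1.1, p_wald = p,
                   n_cases = n, estimable = TRUE, reason = NA),
              class = "dispro_result")
  }
  expect_true(evaluate_signal(mk(2.0, 0.049, 3L)))
  expect_false(evaluate_signal(mk(1.99, 0.001, 1000L)))
  expect_false(evaluate_signal(mk(50, 0.2, 10L)))
  expect_false(evaluate_signal(mk(2.5, 0.05, 3L)))     # p must be < alpha
  expect_false(evaluate_signal(mk(2.5, 0.01, 2L)))
  # a supplied adjusted p overrides the raw Wald p
  expect_false(evaluate_signal(mk(2.5, 0.01, 10L), p = 0.2))
  ne <- mk(2.5, 0.01, 10L)
  ne$estimable <- FALSE
  ne$reason <- "zero cell"
  flag <- evaluate_signal(ne)
  expect_false(flag)
  expect_match(attr(flag, "reason"), "not estimable")
})

test_that("compare_strata matches the closed-form Z contrast", {
  mk <- function(ln, se, stratum) {
    structure(list(drug = "d", event = "e", stratum = stratum,
                   kind = "adjusted", adjusted_for = "sex", ror = exp(ln),
                   ln_ror = ln, se_ln = se, ci_low = NA, ci_high = NA,
                   p_wald = 0.01, n_cases = 50L, estimable = TRUE,
                   reason = NA), class = "dispro_result")
  }
  a <- mk(1.0, 0.1, "over65")
  b <- mk(0.5, 0.1, "under65")
  cmp <- compare_strata(a, b)
  expect_equal(cmp$z, 0.5 / sqrt(0.02), tolerance = 1e-9)
  expect_equal(round(cmp$z, 4), 3.5355)
  expect_equal(cmp$p_raw, 2 * pnorm(-abs(cmp$z)), tolerance = 1e-12)
  expect_equal(cmp$p_raw, 4.07e-4, tolerance = 1e-2)
  expect_equal(cmp$ratio, exp(0.5), tolerance = 1e-9)
  expect_equal(round(cmp$ratio, 4), 1.6487)

  # identity and antisymmetry
  same <- compare_strata(a, a)
  expect_equal(same$z, 0)
  expect_equal(same$p_raw, 1)
  expect_equal(same$ratio, 1)
  rev <- compare_strata(b, a)
  expect_equal(rev$z, -cmp$z)
  expect_equal(rev$p_raw, cmp$p_raw)
  expect_equal(rev$ratio, 1 / cmp$ratio, tolerance = 1e-12)

  # mismatched pairs are a usage error; not-estimable inputs propagate
  wrong <- mk(1.0, 0.1, "over65")
  wrong$event <- "other"
  expect_error(compare_strata(a, wrong), "share drug")
  na_in <- mk(1.0, 0.1, "over65")
  na_in$estimable <- FALSE
  out <- compare_strata(na_in, b)
  expect_false(out$estimable)
  expect_true(is.na(out$z))
})

test_that("Holm adjustment follows the step-down rule", {
  expect_equal(holm_adjust(c(0.04, 0.01, 0.03)), c(0.06, 0.03, 0.06))
  expect_equal(holm_adjust(0.37), 0.37)
  # the running maximum propagates a capped smaller p onto later ones
  expect_equal(holm_adjust(c(0.5, 0.9)), c(1.0, 1.0))
  expect_equal(holm_adjust(numeric(0)), numeric(0))
  # NA (non-estimable) entries pass through without enlarging the family
  expect_equal(holm_adjust(c(0.04, NA, 0.01, 0.03)),
               c(0.06, NA, 0.03, 0.06))
})

test_that("Holm is conservative vs raw p and dominated by Bonferroni", {
  set.seed(34)
  for (rep in 1:20) {
    p <- runif(sample(2:12, 1))
    h <- holm_adjust(p)
    expect_true(all(h >= p))
    expect_true(all(h <= pmin(length(p) * p, 1) + 1e-12))  # <= Bonferroni
    # monotone: same order as the raw p-values
    expect_equal(order(h[order(p)]), seq_along(p))
    expect_true(all(h[h <= 0.05] <= 0.05))
  }
})
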