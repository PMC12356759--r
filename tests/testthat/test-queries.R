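# Event/drug query construction and matching.

test_that("builtin event queries reproduce the published PT code sets", {
  qs <- builtin_event_queries()
  expect_length(qs, 18L)

  sed <- qs[["Sedation"]]
  expect_setequal(sed$terms$pt_code, c(10039897L, 10041349L))
  expect_setequal(sed$terms$pt_name, c("Sedation", "Somnolence"))

  wg <- qs[["Weight gain"]]
  expect_equal(nrow(wg$terms), 6L)
  expect_setequal(wg$terms$pt_code,
                  c(10000188L, 10029883L, 10065941L, 10033307L, 10047899L,
                    10005897L))
  expect_true("Body mass index increased" %in% wg$terms$pt_name)

  expect_setequal(qs[["Cognitive impairment"]]$terms$pt_code,
                  c(10057668L, 10027175L, 10001949L, 10010305L, 10012267L,
                    10013496L, 10013395L, 10041466L, 10076227L, 10002948L,
                    10012218L))
  expect_setequal(qs[["SIADH/Hyponatraemia"]]$terms$pt_code,
                  c(10005802L, 10021036L, 10053198L, 10021037L, 10066151L,
                    10073183L, 10075865L))
  expect_setequal(qs[["Hyperprolactinaemia"]]$terms$pt_code,
                  c(10018800L, 10005778L, 10005780L, 10017600L, 10020737L))

  # standard SMQ placeholders carry their SMQ codes but no licensed terms
  tdp <- qs[["Torsade de pointes/QT prolongation"]]
  expect_equal(tdp$smq_code, 20000001L)
  expect_equal(tdp$kind, "standard_smq")
  expect_equal(nrow(tdp$terms), 0L)
  smq_codes <- vapply(qs, `[[`, integer(1), "smq_code")
  expect_setequal(smq_codes[!is.na(smq_codes)],
                  c(20000135L, 20000023L, 20000048L, 20000026L, 20000041L,
                    20000096L, 20000097L, 20000098L, 20000099L, 20000044L,
                    20000238L, 20000001L, 20000037L))
})

test_that("query constructors enforce their invariants", {
  expect_error(event_query("empty self-defined"), "at least one PT")
  expect_error(event_query("dup", data.frame(pt_name = c("a", "b"),
                                             pt_code = c(1L, 1L))),
               "duplicate")
  expect_error(drug_query("x", "X", allowed_roles = "ZZ"))
})

test_that("normalize_drugname uppercases, squeezes and strips dose forms", {
  expect_equal(normalize_drugname(" Risperidone  (2mg) "), "RISPERIDONE")
  expect_equal(normalize_drugname("HALDOL"), "HALDOL")
  expect_equal(normalize_drugname("olanzapine"), "OLANZAPINE")
  expect_equal(normalize_drugname("Seroquel (XR) (50 mg)"), "SEROQUEL")
})

test_that("drug matching respects synonyms, roles and monotonicity", {
  cases <- toy_case_set(data.frame(
    sex = c("F", "M", "F"), age = c(40, 70, 55),
    drug = c("RISPERDAL", "RISPERDAL", "UNRELATED"),
    role = c("PS", "SS", "PS"), stringsAsFactors = FALSE))
  q_ps <- drug_query("risperidone", "RISPERDAL", allowed_roles = "PS")
  q_all <- drug_query("risperidone", "RISPERDAL",
                      allowed_roles = c("PS", "SS", "C", "I"))
  expect_equal(case_matches_drug(cases, q_ps), c(TRUE, FALSE, FALSE))
  expect_equal(case_matches_drug(cases, q_all), c(TRUE, TRUE, FALSE))
  # monotone in roles: every PS match is an all-roles match
  expect_true(all(case_matches_drug(cases, q_all) |
                    !case_matches_drug(cases, q_ps)))
})

test_that("exact matching does not hit combination names unless asked", {
  cases <- toy_case_set(data.frame(
    sex = "F", age = 40, drug = "RISPERIDONE AND LORAZEPAM",
    stringsAsFactors = FALSE))
  q <- drug_query("risperidone", "RISPERIDONE")
  expect_false(case_matches_drug(cases, q))
  q_sub <- drug_query("risperidone", "RISPERIDONE",
                      match_mode = "substring")
  expect_true(case_matches_drug(cases, q_sub))
})

test_that("event matching works by name, is set-valued, and prefers codes", {
  sed <- builtin_event_queries()[["Sedation"]]
  cases <- toy_case_set(data.frame(
    sex = c("F", "M", "F"), age = c(40, 50, 60), drug = NA,
    pt = c("Somnolence", "Nausea", "somnolence"),
    stringsAsFactors = FALSE))
  expect_equal(case_matches_event(cases, sed), c(TRUE, FALSE, TRUE))

  # several matching PTs on one case still count it once
  dup <- toy_case_set(data.frame(sex = "F", age = 40, drug = NA,
                                 pt = "Sedation", stringsAsFactors = FALSE))
  dup$reactions <- rbind(dup$reactions,
                         data.frame(primaryid = dup$demo$primaryid,
                                    pt_name = "Somnolence",
                                    pt_code = 10041349L))
  expect_equal(sum(case_matches_event(dup, sed)), 1L)

  # a present PT code overrides a disagreeing name, with a message
  coded <- toy_case_set(data.frame(sex = "F", age = 40, drug = NA,
                                   pt = "Misspelled somnolenze",
                                   pt_code = 10041349L,
                                   stringsAsFactors = FALSE))
  expect_message(hit <- case_matches_event(coded, sed), "disagree")
  expect_true(hit)
  wrong_code <- toy_case_set(data.frame(sex = "F", age = 40, drug = NA,
                                        pt = "Somnolence",
                                        pt_code = 12345678L,
                                        stringsAsFactors = FALSE))
  expect_message(hit <- case_matches_event(wrong_code, sed), "disagree")
  expect_false(hit)

  # placeholder SMQ without terms is a configuration error
  tdp <- builtin_event_queries()[["Torsade de pointes/QT prolongation"]]
  expect_error(case_matches_event(cases, tdp), "licensed")
})

test_that("query JSON files round-trip through the loaders", {
  qfile <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    list(name = "Sedation", kind = "self_defined",
         terms = list(list(pt_name = "Sedation", pt_code = 10039897),
                      list(pt_name = "Somnolence", pt_code = 10041349))),
    list(name = "Torsade de pointes/QT prolongation",
         kind = "standard_smq", smq_code = 20000001,
         terms = list(list(pt_name = "Electrocardiogram QT prolonged",
                           pt_code = 10014387)))),
    qfile, auto_unbox = TRUE)
  qs <- load_event_queries(qfile)
  expect_setequal(qs[["Sedation"]]$terms$pt_code, c(10039897L, 10041349L))
  # a user-supplied term list turns the SMQ placeholder into a usable query
  expect_equal(nrow(qs[["Torsade de pointes/QT prolongation"]]$terms), 1L)

  dfile <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    list(name = "risperidone", synonyms = list("RISPERDAL", "PERSERIS"),
         allowed_roles = list("PS", "SS"))), dfile, auto_unbox = TRUE)
  dq <- load_drug_queries(dfile)[["risperidone"]]
  expect_true(all(c("RISPERDAL", "PERSERIS", "RISPERIDONE") %in%
                    dq$synonyms))
  expect_setequal(dq$allowed_roles, c("PS", "SS"))
})

test_that("set_roles switches between primary-only and all designations", {
  qs <- builtin_drug_queries()
  expect_equal(qs[["haloperidol"]]$allowed_roles, "PS")
  all_qs <- set_roles(qs, "all_roles")
  expect_setequal(all_qs[["haloperidol"]]$allowed_roles,
                  c("PS", "SS", "C", "I"))
})
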