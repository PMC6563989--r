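test_that("study_assessment enforces complete, valid checklists", {
  rep_ok <- stats::setNames(as.list(rep("yes", length(reporting_fields))),
                            reporting_fields)
  rob_ok <- stats::setNames(as.list(rep("low", length(rob_fields))),
                            rob_fields)
  a <- study_assessment("s1", "m", rep_ok, rob_ok, "male")
  expect_s3_class(a, "fimd_assessment")

  expect_error(study_assessment("s1", "m", rep_ok[-1], rob_ok), "missing")
  expect_error(study_assessment("s1", "m", rep_ok, rob_ok[-1]), "missing")

  rep_bad <- rep_ok
  rep_bad$any_blinding <- "maybe"
  expect_error(study_assessment("s1", "m", rep_bad, rob_ok),
               "any_blinding")

  rep_und <- rep_ok
  rep_und$sex_disclosed <- "no"
  expect_error(study_assessment("s1", "m", rep_und, rob_ok, "male"),
               "sex_disclosed")
  expect_s3_class(study_assessment("s1", "m", rep_und, rob_ok,
                                   "undisclosed"), "fimd_assessment")
})

test_that("pooled reporting cells reproduce the published DMD aggregates", {
  tab <- aggregate_reporting(dmd_assessments())
  cell <- function(p, col) tab[[col]][tab$parameter == p]
  # per-model columns give back the input marginals
  expect_equal(cell("any_blinding", "mdx mouse"), 43.8)
  expect_equal(cell("any_blinding", "GRMD dog"), 33.3)
  # pooled columns are recomputed over all 35 studies
  expect_equal(cell("any_blinding", "pooled"), 42.9)
  expect_equal(cell("any_randomisation", "pooled"), 31.4)
  expect_equal(cell("breeding_programme", "pooled"), 57.1)
  expect_equal(cell("sample_size", "pooled"), 85.7)
  expect_equal(cell("sex_disclosed", "pooled"), 45.7)
  # not-applicable parameters stay not applicable
  expect_true(is.na(cell("water_quality_fish", "pooled")))
  expect_true(is.na(cell("background_control", "mdx mouse")))
  expect_equal(unname(attr(tab, "group_n")),
               c(32L, 3L, 35L))
})

test_that("pooled risk-of-bias cells reproduce the published DMD aggregates", {
  tab <- aggregate_rob(dmd_assessments())
  cell <- function(p, col) tab[[col]][tab$parameter == p]
  expect_equal(cell("selective_outcome_reporting", "pooled_low"), 97.1)
  expect_equal(cell("selective_outcome_reporting", "pooled_unclear"), 2.9)
  expect_equal(cell("allocation_concealment", "pooled_low"), 0)
  expect_equal(cell("allocation_concealment", "pooled_unclear"), 100)
  expect_equal(cell("incomplete_outcome_data", "pooled_low"), 17.1)
  expect_equal(cell("other", "pooled_low"), 68.6)
  # per-model columns round-trip the marginals
  expect_equal(cell("selective_outcome_reporting", "mdx mouse_low"), 96.9)
  expect_equal(cell("other", "GRMD dog_low"), 33.3)
})

test_that("percentage cells are bounded and low+unclear never exceeds 100", {
  assessments <- generate_assessments(5, 40)
  rep_tab <- aggregate_reporting(assessments)
  num <- vapply(rep_tab, is.numeric, logical(1))
  vals <- unlist(rep_tab[num])
  expect_true(all(is.na(vals) | (vals >= 0 & vals <= 100)))
  rob_tab <- aggregate_rob(assessments)
  for (g in c("synthetic model", "pooled")) {
    s <- rob_tab[[paste0(g, "_low")]] + rob_tab[[paste0(g, "_unclear")]]
    expect_true(all(s <= 100 + 0.1)) # rounding slack of one decimal step
  }
})

test_that("pooled counts equal the sum of group counts before rounding", {
  assessments <- dmd_assessments()
  models <- vapply(assessments, function(a) a$model_name, character(1))
  for (f in c("any_blinding", "sample_size", "acclimatisation")) {
    yes <- vapply(assessments, function(a) a$reporting[[f]] == "yes",
                  logical(1))
    expect_equal(sum(yes), sum(yes[models == "mdx mouse"]) +
                   sum(yes[models == "GRMD dog"]))
  }
})

test_that("aggregation is invariant under study order", {
  assessments <- dmd_assessments()
  set.seed(1)
  shuffled <- assessments[sample(seq_along(assessments))]
  tab1 <- aggregate_reporting(assessments)
  tab2 <- aggregate_reporting(shuffled)
  # same cells regardless of row order (group column order may differ)
  expect_equal(tab1[order(tab1$parameter), c("parameter", "pooled")],
               tab2[order(tab2$parameter), c("parameter", "pooled")])
  expect_equal(tab1[["mdx mouse"]], tab2[["mdx mouse"]])
})

test_that("sex distribution covers disclosing studies only", {
  sx <- sex_distribution(dmd_assessments())
  expect_equal(as.numeric(sx), c(50.0, 18.8, 31.3))
  expect_equal(attr(sx, "n_disclosing"), 16L)

  rep_ok <- stats::setNames(as.list(rep("no", length(reporting_fields))),
                            reporting_fields)
  rob_ok <- stats::setNames(as.list(rep("unclear", length(rob_fields))),
                            rob_fields)
  none <- list(study_assessment("s1", "m", rep_ok, rob_ok, "undisclosed"))
  expect_true(all(is.na(sex_distribution(none))))

  rep_m <- rep_ok
  rep_m$sex_disclosed <- "yes"
  one <- list(study_assessment("s1", "m", rep_m, rob_ok, "male"))
  expect_equal(as.numeric(sex_distribution(one)), c(100, 0, 0))
})

test_that("empty assessment lists are rejected by the aggregators", {
  expect_error(aggregate_reporting(list()), "non-empty")
  expect_error(aggregate_rob(list()), "non-empty")
})

test_that("drug concordance summarises but never answers the questionnaire", {
  sh <- full_sheet("YES", drugs = list(
    drug_record("a", "effective", "effective", study_ids = c("s1", "s2")),
    drug_record("b", "effective", "ineffective"),
    drug_record("c", "ineffective", "mixed"),
    drug_record("d", "ineffective", "unknown")
  ))
  dc <- drug_concordance(sh)
  expect_equal(dc$concordance,
               c("concordant", "discordant", "mixed", "unknown"))
  expect_equal(dc$n_studies, c(2L, 0L, 0L, 0L))
  # the sheet's own 7.x answers are untouched by the evidence
  expect_equal(sheet_answer_value(sh, "7.1"), "YES")
})
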