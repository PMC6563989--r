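test_that("identical configurations generate identical sheets", {
  cfg <- sheet_gen_config(42, n_drugs = 3, exclusion_ids = "4.3")
  expect_equal(generate_sheet(cfg), generate_sheet(cfg))
  expect_false(identical(generate_sheet(sheet_gen_config(1)),
                         generate_sheet(sheet_gen_config(2))))
})

test_that("generated sheets always validate and honour their config", {
  for (seed in 1:5) {
    cfg <- sheet_gen_config(seed, exclusion_ids = c("4.3", "4.4"),
                            n_drugs = 2)
    sh <- generate_sheet(cfg)
    expect_equal(nrow(validate_sheet(sh)), 0)
    expect_length(sh$answers, 19)
    expect_length(sh$drug_records, 2)
  }
})

test_that("degenerate answer distributions hit the scale ends", {
  all_yes <- sheet_gen_config(9, answer_probs = c(YES = 1, PARTIAL = 0,
                                                  NO = 0, UNCLEAR = 0))
  s <- score_sheet(generate_sheet(all_yes))
  expect_equal(s$equivalent_score, 100)
  expect_equal(uncertainty_factor(generate_sheet(all_yes)), 0)

  all_unclear <- sheet_gen_config(9, answer_probs = c(YES = 0, PARTIAL = 0,
                                                      NO = 0, UNCLEAR = 1))
  expect_equal(uncertainty_factor(generate_sheet(all_unclear)), 100)
})

test_that("invalid generator configurations are rejected", {
  expect_error(sheet_gen_config(1, answer_probs = c(YES = 0.7, PARTIAL = 0.2,
                                                    NO = 0.2, UNCLEAR = 0.1)),
               "sum to 1")
  expect_error(sheet_gen_config(1, answer_probs = c(Y = 1)), "named over")
  expect_error(generate_sheet(sheet_gen_config(1, exclusion_ids = "9.9")),
               "unknown exclusion")
  expect_error(generate_assessments(1, 5, compliance_probs = 1.4),
               "\\[0, 1\\]")
  expect_error(generate_assessments(1, -1), "non-negative")
})

test_that("uncertainty rate is recovered from seeded sheets", {
  p_unclear <- 0.2
  cfg_for <- function(seed) sheet_gen_config(
    seed, answer_probs = c(YES = 0.5, PARTIAL = 0.2, NO = 0.1,
                           UNCLEAR = p_unclear))
  u <- vapply(1:60, function(s) uncertainty_factor(generate_sheet(cfg_for(s))),
              numeric(1))
  # 60 sheets x 21 questions = 1260 Bernoulli draws; 3 sd of the mean
  se <- sqrt(p_unclear * (1 - p_unclear) / (60 * 21))
  expect_lt(abs(mean(u) / 100 - p_unclear), 3 * se)
})

test_that("compliance rate is recovered from generated assessments", {
  assessments <- generate_assessments(11, 10000, compliance_probs = 0.4)
  tab <- aggregate_reporting(assessments)
  cell <- tab$pooled[tab$parameter == "any_blinding"]
  expect_lt(abs(cell - 40), 2)
  expect_equal(generate_assessments(11, 50), generate_assessments(11, 50))
  expect_equal(generate_assessments(3, 0), list())
})

test_that("fields with NA compliance are not applicable throughout", {
  probs <- stats::setNames(rep(0.5, length(reporting_fields)),
                           reporting_fields)
  probs["water_quality_fish"] <- NA
  assessments <- generate_assessments(2, 20, compliance_probs = probs)
  tab <- aggregate_reporting(assessments)
  expect_true(is.na(tab$pooled[tab$parameter == "water_quality_fish"]))
})

test_that("same-seed sheet pairs are fully similar", {
  for (seed in c(2, 13)) {
    a <- generate_sheet(sheet_gen_config(seed), model_name = "A")
    b <- generate_sheet(sheet_gen_config(seed), model_name = "B")
    expect_equal(similarity_factor(a, b), 100)
  }
})

test_that("marginal reconstruction reproduces its input percentages", {
  rep_pct <- stats::setNames(rep(50, length(reporting_fields)),
                             reporting_fields)
  rep_pct["water_quality_fish"] <- NA
  low <- stats::setNames(rep(25, length(rob_fields)), rob_fields)
  unc <- stats::setNames(rep(50, length(rob_fields)), rob_fields)
  assessments <- assessments_from_marginals(
    "m", 8, rep_pct, low, unc, sex_pct = c(male = 50, female = 25, both = 25))
  tab <- aggregate_reporting(assessments)
  expect_equal(tab$pooled[tab$parameter == "any_blinding"], 50)
  rob <- aggregate_rob(assessments)
  expect_equal(rob$pooled_low[rob$parameter == "other"], 25)
  expect_equal(rob$pooled_unclear[rob$parameter == "other"], 50)
  expect_equal(as.numeric(sex_distribution(assessments)), c(50, 25, 25))
})
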