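test_that("default registry has the canonical shape and weights", {
  q <- default_questionnaire()
  expect_equal(nrow(q$domains), 8)
  expect_equal(nrow(q$questions), 21)
  expect_equal(sum(q$questions$weight), 100)
  expect_equal(q$domains$weight, rep(12.5, 8))
  # questions per domain
  counts <- as.integer(table(factor(q$questions$domain_id, levels = 1:8)))
  expect_equal(counts, c(2, 5, 3, 4, 1, 1, 3, 2))
  # every domain's question weights sum exactly to its weight
  for (d in 1:8) {
    expect_identical(sum(q$questions$weight[q$questions$domain_id == d]), 12.5)
  }
  # spot weights across the four split patterns
  w <- stats::setNames(q$questions$weight, q$questions$id)
  expect_equal(unname(w["1.1"]), 6.25)
  expect_equal(unname(w["2.2.3"]), 2.5)
  expect_equal(unname(w[c("3.1", "3.2", "3.3")]), c(4.17, 4.17, 4.16))
  expect_equal(unname(w["4.1"]), 3.125)
  expect_equal(unname(w["5.1"]), 12.5)
  expect_equal(unname(w[c("7.1", "7.2", "7.3")]), c(4.17, 4.17, 4.16))
})

test_that("registry ids are unique and consistent with their domains", {
  q <- default_questionnaire()
  expect_false(anyDuplicated(q$questions$id) > 0)
  expect_equal(as.integer(sub("\\..*$", "", q$questions$id)),
               q$questions$domain_id)
})

test_that("definite answers are everything but UNCLEAR", {
  expect_equal(is_definite(c("YES", "PARTIAL", "NO", "UNCLEAR")),
               c(TRUE, TRUE, TRUE, FALSE))
  expect_error(is_definite("MAYBE"), "invalid answer")
})

test_that("validate_sheet reports each violation as data", {
  expect_equal(nrow(validate_sheet(full_sheet("YES"))), 0)

  # answered and excluded at once
  sh <- full_sheet("YES")
  sh$exclusions <- list(exclusion("8.2", "duplicated on purpose"))
  iss <- validate_sheet(sh)
  expect_equal(iss$category, "answered-and-excluded")
  expect_equal(iss$question_id, "8.2")

  # missing answer
  sh <- full_sheet("YES")
  sh$answers[["8.2"]] <- NULL
  iss <- validate_sheet(sh)
  expect_equal(iss$category, "missing-answer")
  expect_equal(iss$question_id, "8.2")

  # unknown id
  sh <- full_sheet("YES")
  sh$answers[["9.1"]] <- answer("YES")
  iss <- validate_sheet(sh)
  expect_equal(iss$category, "unknown-id")
  expect_match(iss$message, "9.1", fixed = TRUE)

  # empty justification
  sh <- full_sheet("YES", exclude = "4.3")
  sh$exclusions[[1]]$justification <- "  "
  iss <- validate_sheet(sh)
  expect_true("empty-justification" %in% iss$category)
})

test_that("validate_sheet is idempotent and gates scoring", {
  sh <- full_sheet("YES")
  sh$answers[["8.2"]] <- NULL
  expect_equal(validate_sheet(sh), validate_sheet(sh))
  expect_error(score_sheet(sh), "invalid validation sheet")
  expect_error(uncertainty_factor(sh), "invalid validation sheet")
})

test_that("validation date is the latest reference year anywhere", {
  sh <- full_sheet("YES", exclude = "4.3")
  sh$answers[["1.1"]]$references <- list(reference("older paper", 2012))
  sh$exclusions[[1]]$references <- list(reference("newer paper", 2016))
  expect_equal(validation_date(sh), 2016)

  sh$drug_records <- list(drug_record("drug-x", "effective", "effective",
                                      references = list(reference("latest", 2018))))
  expect_equal(validation_date(sh), 2018)

  expect_error(validation_date(full_sheet("YES")), "no references")
})

test_that("reference years must be plausible", {
  expect_error(reference("too old", 1502), "1800-2100")
  expect_equal(reference("ok", 2018)$year, 2018L)
})
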