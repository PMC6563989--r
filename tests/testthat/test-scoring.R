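test_that("answers earn full, half or no credit", {
  expect_equal(question_score("YES", 6.25), 6.25)
  expect_equal(question_score("PARTIAL", 6.25), 3.125)
  expect_equal(question_score("NO", 6.25), 0)
  expect_equal(question_score("UNCLEAR", 12.5), 0)
  expect_equal(question_score(c("YES", "PARTIAL"), c(4.17, 3.125)),
               c(4.17, 1.5625))
  expect_error(question_score("SOMETIMES", 1), "invalid answer")
})

test_that("extreme sheets hit the scale ends", {
  s <- score_sheet(full_sheet("YES"))
  expect_equal(s$raw_total, 100)
  expect_equal(s$max_total, 100)
  expect_equal(s$equivalent_score, 100)
  expect_equal(s$per_domain$ratio, rep(1, 8))

  s0 <- score_sheet(full_sheet("NO"))
  expect_equal(s0$raw_total, 0)
  expect_equal(s0$equivalent_score, 0)
  expect_equal(s0$per_domain$ratio, rep(0, 8))
})

test_that("equivalent score rescales raw totals over the attainable maximum", {
  expect_equal(equivalent_score(63.54, 93.75), 67.78)
  expect_equal(equivalent_score(93.75, 93.75), 100)
  expect_equal(equivalent_score(0, 93.75), 0)
  expect_error(equivalent_score(95, 93.75), "raw_total")
  expect_error(equivalent_score(10, 0), "max_total")
})

test_that("score_sheet matches brute-force re-summation on random sheets", {
  for (seed in 1:25) {
    excl <- if (seed %% 3 == 0) c("4.3", "4.4") else character()
    sh <- random_sheet(seed, exclude = excl)
    s <- score_sheet(sh)
    expect_equal(s$raw_total, brute_force_raw(sh), tolerance = 1e-12)
    expect_equal(s$max_total, 100 - length(excl) * 3.125)
    expect_equal(s$equivalent_score,
                 round_half_up(s$raw_total * 100 / s$max_total, 2))
    expect_equal(sum(s$per_question$score), s$raw_total)
    expect_true(all(s$per_question$score <= s$per_question$weight + 1e-12))
  }
})

test_that("equivalent score equals raw total when nothing is excluded", {
  for (seed in 1:10) {
    s <- score_sheet(random_sheet(seed))
    expect_equal(s$equivalent_score, round_half_up(s$raw_total, 2))
  }
})

test_that("upgrading any single answer never lowers a score", {
  ladder <- c(NO = "PARTIAL", PARTIAL = "YES", UNCLEAR = "YES")
  set.seed(99)
  for (i in 1:60) {
    sh <- random_sheet(i + 1000)
    s <- score_sheet(sh)
    qid <- sample(names(sh$answers), 1)
    cur <- sh$answers[[qid]]$value
    if (cur == "YES") next
    sh2 <- sh
    sh2$answers[[qid]]$value <- unname(ladder[cur])
    s2 <- score_sheet(sh2)
    expect_gte(s2$raw_total, s$raw_total)
    expect_gte(s2$equivalent_score, s$equivalent_score)
    d <- question_domain_of(qid)
    expect_gte(s2$per_domain$ratio[d], s$per_domain$ratio[d])
  }
})

test_that("domain ratios follow earned/available with gaps for exclusions", {
  expect_equal(domain_ratio(6.25, 12.5), 0.5)
  expect_equal(domain_ratio(12.5, 12.5), 1)
  expect_equal(domain_ratio(0, 12.5), 0)
  expect_true(is.na(domain_ratio(0, 0)))
  expect_error(domain_ratio(13, 12.5), "earned")

  s <- score_sheet(full_sheet("YES", exclude = "5.1"))
  expect_true(is.na(s$per_domain$ratio[5]))
  expect_equal(s$max_total, 87.5)
})

test_that("uncertainty factor counts UNCLEAR items", {
  expect_equal(uncertainty_factor(full_sheet("YES")), 0)
  expect_equal(uncertainty_factor(full_sheet("UNCLEAR")), 100)

  # 1 UNCLEAR of 19 non-excluded questions
  sh <- sheet_with(c("1.1" = "UNCLEAR"), exclude = c("4.3", "4.4"))
  expect_equal(uncertainty_factor(sh), 5.3)
})

test_that("expanded item mode counts pharmacological items per drug", {
  drugs <- list(
    drug_record("a", "effective", "effective"),
    drug_record("b", "effective", "unknown"),
    drug_record("c", "ineffective", "mixed")
  )
  sh <- full_sheet("YES", drugs = drugs)
  # items: 21 questions - {7.1, 7.2} + 3 drug items = 22, one unclear
  expect_equal(uncertainty_factor(sh, "expanded"), round_half_up(100 / 22, 1))
  # flat mode ignores drug records
  expect_equal(uncertainty_factor(sh, "flat"), 0)
  # without drug records both modes agree
  expect_equal(uncertainty_factor(full_sheet("UNCLEAR"), "expanded"), 100)
})

test_that("uncertainty factor is zero exactly when all answers are definite", {
  for (seed in 1:10) {
    sh <- random_sheet(seed)
    u <- uncertainty_factor(sh)
    s <- score_sheet(sh)
    expect_equal(u == 0, s$definite_pct == 100)
  }
})

test_that("validation levels band the definite percentage", {
  expect_equal(validation_level(85), "Highly validated")
  expect_equal(validation_level(50), "Slightly validated")
  expect_equal(validation_level(70), "Moderately validated")
  expect_equal(validation_level(10), "Insufficiently validated")
  # half-up to integer first: 40.4 -> 40, 40.5 -> 41
  expect_equal(validation_level(40.4), "Insufficiently validated")
  expect_equal(validation_level(40.5), "Slightly validated")
  expect_equal(validation_level(80.5), "Highly validated")
  expect_error(validation_level(101), "0, 100")
  expect_error(validation_level(-1), "0, 100")
})

test_that("level bands partition every integer percentage", {
  lv <- validation_level(0:100)
  expect_false(any(is.na(lv)))
  expect_equal(as.vector(table(factor(lv, c(
    "Insufficiently validated", "Slightly validated",
    "Moderately validated", "Highly validated")))),
    c(41, 20, 20, 20))
  # boundaries
  expect_equal(validation_level(c(40, 41, 60, 61, 80, 81)),
               c("Insufficiently validated", "Slightly validated",
                 "Slightly validated", "Moderately validated",
                 "Moderately validated", "Highly validated"))
})

test_that("score_sheet carries the level derived from its definite share", {
  sh <- full_sheet("UNCLEAR")
  s <- score_sheet(sh)
  expect_equal(s$definite_pct, 0)
  expect_equal(s$level, "Insufficiently validated")
  expect_equal(score_sheet(full_sheet("NO"))$level, "Highly validated")
})
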