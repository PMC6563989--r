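# Builders for in-code fixtures.

qspec <- default_questionnaire()

# a complete sheet answering every question with `value`
full_sheet <- function(value = "YES", model = "model A", exclude = character(),
                       drugs = list(), indication = "test indication") {
  qids <- setdiff(qspec$questions$id, exclude)
  validation_sheet(
    model_name = model, species = "test species", indication = indication,
    answers = stats::setNames(as.list(rep(value, length(qids))), qids),
    exclusions = lapply(exclude, function(id)
      exclusion(id, paste("no evidence stream for", id))),
    drug_records = drugs
  )
}

# a sheet with explicit per-question values (named vector), defaults filled
sheet_with <- function(values, model = "model A", exclude = character(),
                       drugs = list(), default = "YES") {
  qids <- setdiff(qspec$questions$id, exclude)
  ans <- stats::setNames(rep(default, length(qids)), qids)
  ans[names(values)] <- values
  validation_sheet(
    model_name = model, species = "sp", indication = "test indication",
    answers = as.list(ans),
    exclusions = lapply(exclude, function(id) exclusion(id, "justified")),
    drug_records = drugs
  )
}

random_sheet <- function(seed, p = c(YES = 0.4, PARTIAL = 0.2, NO = 0.2,
                                     UNCLEAR = 0.2), exclude = character()) {
  generate_sheet(sheet_gen_config(seed, answer_probs = p,
                                  exclusion_ids = exclude))
}

question_domain_of <- function(id) as.integer(sub("\\..*$", "", id))

sheet_answer_value <- function(sheet, id) sheet$answers[[id]]$value

# independent scoring oracle: re-sum question_score over the registry
brute_force_raw <- function(sheet, spec = qspec) {
  qids <- setdiff(spec$questions$id,
                  vapply(sheet$exclusions, `[[`, character(1), "question_id"))
  sum(vapply(qids, function(id) {
    w <- spec$questions$weight[spec$questions$id == id]
    a <- sheet$answers[[id]]$value
    if (a == "YES") w else if (a == "PARTIAL") w / 2 else 0
  }, numeric(1)))
}

# the worked two-model pair counted over expanded items: 4.3/4.4 excluded,
# 17 question items plus 16 drug items (8 human-effective, 8 -ineffective)
# shared by name across the two sheets = 33 comparable items
dmd_like_pair <- function() {
  drug_names <- sprintf("drug-%02d", 1:16)
  status <- rep(c("effective", "ineffective"), each = 8)
  make_drugs <- function(unknown_idx) {
    lapply(1:16, function(i) {
      outcome <- if (i %in% unknown_idx) "unknown" else status[i]
      drug_record(drug_names[i], status[i], outcome)
    })
  }
  excl <- c("4.3", "4.4")
  qids <- setdiff(qspec$questions$id, c(excl, "7.1", "7.2"))
  stopifnot(length(qids) == 17)
  # model A: all 17 questions YES; drugs 1-2 unknown -> 2/33 unclear items
  a <- sheet_with(stats::setNames(rep("YES", 17), qids), model = "model A",
                  exclude = excl, drugs = make_drugs(1:2))
  # model B: 4 questions agree with A, 13 differ; drugs 1-6 unknown
  # -> 6/33 unclear; same items: 4 questions + 2 both-unclear + 10 drugs = 16
  bvals <- stats::setNames(c(rep("YES", 4), rep("NO", 13)), qids)
  b <- sheet_with(bvals, model = "model B", exclude = excl,
                  drugs = make_drugs(1:6))
  list(a = a, b = b)
}
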