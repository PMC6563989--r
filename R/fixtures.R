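# Seeded synthetic sheets and study assessments. These emulate the
# statistical structure of completed validation work (answer mixes,
# exclusion patterns, per-drug evidence, checklist compliance rates), not
# the content of any real model's evidence base.

#' Configuration for the synthetic sheet generator
#'
#' Defaults describe a moderately validated model: most questions answerable
#' with a definite answer (50% yes, 20% partial, 20% no) and one in ten
#' unclear, evidence published over the last quarter century, and no
#' exclusions or drug records unless requested.
#'
#' @param seed integer seed; the generator draws from one stream derived
#'   from this seed only, so output is stable across platforms and sessions.
#' @param answer_probs named probabilities over `YES`, `PARTIAL`, `NO`,
#'   `UNCLEAR`; must be non-negative and sum to 1.
#' @param exclusion_ids question ids to exclude (with a synthetic
#'   justification).
#' @param n_drugs number of synthetic drug records; drugs alternate between
#'   human-effective and human-ineffective.
#' @param drug_outcome_probs named probabilities over model outcomes
#'   `effective`, `ineffective`, `mixed`, `unknown`.
#' @param reference_year_range inclusive year interval references are drawn
#'   from.
#' @return A list of class `fimd_sheet_gen_config`.
#' @export
sheet_gen_config <- function(seed,
                             answer_probs = c(YES = 0.5, PARTIAL = 0.2,
                                              NO = 0.2, UNCLEAR = 0.1),
                             exclusion_ids = character(),
                             n_drugs = 0,
                             drug_outcome_probs = c(effective = 0.4,
                                                    ineffective = 0.2,
                                                    mixed = 0.2,
                                                    unknown = 0.2),
                             reference_year_range = c(2000, 2025)) {
  check_probs(answer_probs, answer_values, "answer_probs")
  check_probs(drug_outcome_probs,
              c("effective", "ineffective", "mixed", "unknown"),
              "drug_outcome_probs")
  if (length(reference_year_range) != 2 ||
      reference_year_range[1] > reference_year_range[2]) {
    stop("reference_year_range must be an increasing year pair",
         call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), answer_probs = answer_probs,
         exclusion_ids = as.character(exclusion_ids),
         n_drugs = as.integer(n_drugs),
         drug_outcome_probs = drug_outcome_probs,
         reference_year_range = as.integer(reference_year_range)),
    class = "fimd_sheet_gen_config"
  )
}

check_probs <- function(p, expected_names, what) {
  if (!setequal(names(p), expected_names)) {
    stop(what, " must be named over: ",
         paste(expected_names, collapse = ", "), call. = FALSE)
  }
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop(what, " must be non-negative and sum to 1", call. = FALSE)
  }
  invisible(p)
}

#' Generate a synthetic completed validation sheet
#'
#' Answers are drawn independently per non-excluded question from
#' `answer_probs`; every answer carries one synthetic reference. The result
#' always passes [validate_sheet()] and is identical for identical
#' configurations.
#'
#' @param config a [sheet_gen_config()].
#' @param model_name,indication identity strings for the synthetic sheet.
#' @param spec questionnaire registry.
#' @return A `fimd_sheet`.
#' @examples
#' sh <- generate_sheet(sheet_gen_config(seed = 7))
#' nrow(validate_sheet(sh)) # 0
#' @export
generate_sheet <- function(config, model_name = "synthetic model",
                           indication = "synthetic indication",
                           spec = default_questionnaire()) {
  if (!inherits(config, "fimd_sheet_gen_config")) {
    stop("config must come from sheet_gen_config()", call. = FALSE)
  }
  unknown <- setdiff(config$exclusion_ids, spec$questions$id)
  if (length(unknown) > 0) {
    stop("unknown exclusion id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  withr::with_seed(config$seed, {
    qids <- setdiff(spec$questions$id, config$exclusion_ids)
    years <- config$reference_year_range
    draw_ref <- function(tag) {
      reference(paste0("Synthetic reference for ", tag),
                sample(seq(years[1], years[2]), 1))
    }
    answers <- lapply(qids, function(id) {
      answer(sample(names(config$answer_probs), 1,
                    prob = config$answer_probs),
             rationale = paste0("synthetic rationale for ", id),
             references = list(draw_ref(id)))
    })
    names(answers) <- qids
    exclusions <- lapply(config$exclusion_ids, function(id) {
      exclusion(id, paste0("synthetic justification for excluding ", id),
                references = list(draw_ref(paste0("exclusion ", id))))
    })
    drug_records <- lapply(seq_len(config$n_drugs), function(i) {
      status <- if (i %% 2 == 1) "effective" else "ineffective"
      drug_record(sprintf("drug-%02d", i), status,
                  sample(names(config$drug_outcome_probs), 1,
                         prob = config$drug_outcome_probs),
                  references = list(draw_ref(sprintf("drug-%02d", i))))
    })
    validation_sheet(
      model_name = model_name, species = "synthetic species",
      indication = indication, answers = answers, exclusions = exclusions,
      drug_records = drug_records,
      historical_background = "Synthetic sheet for pipeline testing.",
      questionnaire_version = spec$version
    )
  })
}

#' Generate synthetic study assessments
#'
#' Independent tri-state draws per checklist field: each reporting field is
#' `yes` with its compliance probability (else `no`), each risk-of-bias item
#' is drawn from `rob_probs`. Sex is disclosed according to the
#' `sex_disclosed` draw and then categorised by `sex_probs`. Deterministic
#' given the seed.
#'
#' @param seed integer seed.
#' @param n_studies number of assessments to generate.
#' @param compliance_probs probability a reporting field is `yes`: a single
#'   number or a vector named over [reporting_fields]. Fields given
#'   probability `NA` are marked `na` (not applicable) in every study.
#' @param rob_probs named probabilities over `low`, `high`, `unclear`.
#' @param sex_probs named probabilities over `male`, `female`, `both` for
#'   sex-disclosing studies.
#' @param model_name model label attached to every assessment.
#' @return List of [study_assessment()] records.
#' @export
generate_assessments <- function(seed, n_studies,
                                 compliance_probs = 0.4,
                                 rob_probs = c(low = 0.2, high = 0.1,
                                               unclear = 0.7),
                                 sex_probs = c(male = 0.5, female = 0.2,
                                               both = 0.3),
                                 model_name = "synthetic model") {
  if (n_studies < 0) stop("n_studies must be non-negative", call. = FALSE)
  if (length(compliance_probs) == 1 && is.null(names(compliance_probs))) {
    compliance_probs <- stats::setNames(
      rep(compliance_probs, length(reporting_fields)), reporting_fields)
  }
  missing <- setdiff(reporting_fields, names(compliance_probs))
  if (length(missing) > 0) {
    stop("compliance_probs missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(compliance_probs < 0 | compliance_probs > 1, na.rm = TRUE)) {
    stop("compliance probabilities must lie in [0, 1]", call. = FALSE)
  }
  check_probs(rob_probs, c("low", "high", "unclear"), "rob_probs")
  check_probs(sex_probs, c("male", "female", "both"), "sex_probs")
  if (n_studies == 0) return(list())
  withr::with_seed(seed, {
    lapply(seq_len(n_studies), function(i) {
      reporting <- lapply(reporting_fields, function(f) {
        p <- compliance_probs[[f]]
        if (is.na(p)) "na"
        else if (stats::runif(1) < p) "yes" else "no"
      })
      names(reporting) <- reporting_fields
      rob <- lapply(rob_fields, function(f)
        sample(names(rob_probs), 1, prob = rob_probs))
      names(rob) <- rob_fields
      sex <- if (reporting$sex_disclosed == "yes") {
        sample(names(sex_probs), 1, prob = sex_probs)
      } else {
        "undisclosed"
      }
      study_assessment(sprintf("synthetic-study-%03d", i), model_name,
                       reporting, rob, sex)
    })
  })
}

#' Reconstruct per-study assessments from aggregated marginals
#'
#' Builds a deterministic list of synthetic study assessments whose
#' per-field counts match published aggregated percentages for one model
#' group: each field's `yes` (or `low`/`unclear`) count is recovered as
#' `round(pct * n / 100)` and assigned to the first studies in order. The
#' rows are synthetic — fields are matched marginally, not jointly — but
#' every aggregation over them reproduces the input marginals, which is what
#' makes pooled tables recomputable from per-group summaries.
#'
#' @param model_name group label.
#' @param n number of studies in the group.
#' @param reporting_pct named percentages of `yes` answers over
#'   [reporting_fields]; `NA` marks a field not applicable to the group.
#' @param rob_low_pct,rob_unclear_pct named percentages over [rob_fields];
#'   the remainder of each item is at high risk.
#' @param sex_pct named percentages over `male`, `female`, `both` among
#'   sex-disclosing studies (the number of disclosing studies comes from
#'   `reporting_pct["sex_disclosed"]`).
#' @return List of `n` [study_assessment()] records.
#' @export
assessments_from_marginals <- function(model_name, n, reporting_pct,
                                       rob_low_pct, rob_unclear_pct,
                                       sex_pct = c(male = 0, female = 0,
                                                   both = 100)) {
  count <- function(pct, base = n) {
    if (is.na(pct)) NA_integer_ else as.integer(round_half_up(pct * base / 100))
  }
  rep_counts <- vapply(reporting_fields, function(f)
    count(reporting_pct[[f]]), integer(1))
  low_counts <- vapply(rob_fields, function(f)
    count(rob_low_pct[[f]]), integer(1))
  unc_counts <- vapply(rob_fields, function(f)
    count(rob_unclear_pct[[f]]), integer(1))
  n_disclosing <- rep_counts[["sex_disclosed"]]
  sex_counts <- vapply(c("male", "female", "both"), function(s)
    count(sex_pct[[s]], n_disclosing), integer(1))
  sexes <- rep(c("male", "female", "both", "undisclosed"),
               c(sex_counts, n - sum(sex_counts)))
  lapply(seq_len(n), function(i) {
    reporting <- lapply(reporting_fields, function(f) {
      k <- rep_counts[[f]]
      if (is.na(k)) "na" else if (i <= k) "yes" else "no"
    })
    names(reporting) <- reporting_fields
    rob <- lapply(rob_fields, function(f) {
      l <- low_counts[[f]]
      u <- unc_counts[[f]]
      if (i <= l) "low" else if (i <= l + u) "unclear" else "high"
    })
    names(rob) <- rob_fields
    study_assessment(sprintf("%s-study-%03d", model_name, i), model_name,
                     reporting, rob, sexes[i])
  })
}
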