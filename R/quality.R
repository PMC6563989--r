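# Reporting-quality (ARRIVE-adapted) and risk-of-bias (SYRCLE-adapted)
# checklists for the drug-intervention studies behind the pharmacological
# domain, with per-model and pooled percentage aggregation.

#' Checklist field names
#'
#' Field names of the per-study checklists. Reporting-quality fields are
#' tri-state `yes`/`no`/`na` (`na` = not applicable to the study, e.g. water
#' quality for non-fish species); risk-of-bias items are
#' `low`/`high`/`unclear`. These names are also the published CSV column
#' names for [read_assessments()].
#'
#' @format Character vectors.
#' @export
reporting_fields <- c(
  "type_of_facility", "type_of_cage_or_housing", "bedding_material",
  "number_of_cage_companions", "breeding_programme", "light_dark_cycle",
  "temperature_and_humidity", "water_quality_fish", "type_of_food",
  "access_to_food_and_water", "environmental_enrichment", "any_blinding",
  "any_randomisation", "sample_size", "sample_size_calculation",
  "acclimatisation", "sex_disclosed", "background_control", "background_model"
)

#' @rdname reporting_fields
#' @export
rob_fields <- c(
  "allocation_concealment", "blinded_outcome_assessment", "blinded_operations",
  "random_cage_allocation", "random_outcome_assessment", "sequence_generation",
  "baseline_characteristics", "incomplete_outcome_data",
  "selective_outcome_reporting", "other"
)

reporting_labels <- c(
  type_of_facility = "Type of Facility",
  type_of_cage_or_housing = "Type of Cage or Housing",
  bedding_material = "Bedding Material",
  number_of_cage_companions = "Number of Cage Companions",
  breeding_programme = "Breeding Programme",
  light_dark_cycle = "Light/Dark Cycle",
  temperature_and_humidity = "Temperature and Humidity",
  water_quality_fish = "Quality of the Water (fish)",
  type_of_food = "Type of Food",
  access_to_food_and_water = "Access to Food and Water",
  environmental_enrichment = "Environmental Enrichment",
  any_blinding = "Any Blinding",
  any_randomisation = "Any Randomisation",
  sample_size = "Sample Size",
  sample_size_calculation = "Sample Size Calculation",
  acclimatisation = "Acclimatisation",
  sex_disclosed = "Sex Disclosed",
  background_control = "Background Control",
  background_model = "Background Model"
)

rob_labels <- c(
  allocation_concealment = "Allocation Concealment",
  blinded_outcome_assessment = "Blinded Outcome Assessment",
  blinded_operations = "Blinded Operations",
  random_cage_allocation = "Random Cage Allocation",
  random_outcome_assessment = "Random Outcome Assessment",
  sequence_generation = "Sequence Generation",
  baseline_characteristics = "Baseline Characteristics",
  incomplete_outcome_data = "Incomplete Outcome Data",
  selective_outcome_reporting = "Selective Outcome Reporting",
  other = "Other"
)

sex_categories <- c("male", "female", "both", "undisclosed")

#' Column order of the study-assessment CSV dialect
#'
#' UTF-8, comma-separated, header row required. One row per study:
#' `study_id`, `model_name`, `sex_category`, the reporting-quality fields
#' (values `yes`/`no`/`na`) and the risk-of-bias fields
#' (values `low`/`high`/`unclear`), in this order.
#'
#' @format Character vector of column names.
#' @export
assessment_columns <- c("study_id", "model_name", "sex_category",
                        reporting_fields, rob_fields)

#' Assemble one study assessment
#'
#' One row of the quality-assessment table: a publication's
#' reporting-quality checklist and risk-of-bias checklist, plus the model it
#' used and the sex of the animals.
#'
#' @param study_id citation key of the publication.
#' @param model_name animal model the experiments used (a publication with
#'   experiments on two models is entered once per model).
#' @param reporting named list or vector over [reporting_fields], values
#'   `yes`/`no`/`na`.
#' @param rob named list or vector over [rob_fields], values
#'   `low`/`high`/`unclear`.
#' @param sex_category `male`, `female`, `both` or `undisclosed`.
#' @return A list of class `fimd_assessment`.
#' @export
study_assessment <- function(study_id, model_name, reporting, rob,
                             sex_category = "undisclosed") {
  reporting <- unlist(reporting)
  rob <- unlist(rob)
  missing_rep <- setdiff(reporting_fields, names(reporting))
  if (length(missing_rep) > 0) {
    stop("reporting checklist incomplete; missing: ",
         paste(missing_rep, collapse = ", "), call. = FALSE)
  }
  missing_rob <- setdiff(rob_fields, names(rob))
  if (length(missing_rob) > 0) {
    stop("risk-of-bias checklist incomplete; missing: ",
         paste(missing_rob, collapse = ", "), call. = FALSE)
  }
  reporting <- reporting[reporting_fields]
  rob <- rob[rob_fields]
  bad <- reporting[!reporting %in% c("yes", "no", "na")]
  if (length(bad) > 0) {
    stop("invalid reporting value '", bad[1], "' for ", names(bad)[1],
         " (allowed: yes, no, na)", call. = FALSE)
  }
  bad <- rob[!rob %in% c("low", "high", "unclear")]
  if (length(bad) > 0) {
    stop("invalid risk-of-bias value '", bad[1], "' for ", names(bad)[1],
         " (allowed: low, high, unclear)", call. = FALSE)
  }
  sex_category <- match.arg(sex_category, sex_categories)
  if (sex_category != "undisclosed" && reporting[["sex_disclosed"]] != "yes") {
    stop("sex_category '", sex_category,
         "' requires sex_disclosed = yes", call. = FALSE)
  }
  structure(
    list(study_id = as_chr1(study_id, "study_id"),
         model_name = as_chr1(model_name, "model_name"),
         reporting = as.list(reporting), rob = as.list(rob),
         sex_category = sex_category),
    class = "fimd_assessment"
  )
}

assessment_field <- function(assessments, checklist, field) {
  vapply(assessments, function(a) a[[checklist]][[field]], character(1))
}

group_models <- function(assessments) {
  vapply(assessments, `[[`, character(1), "model_name")
}

pct_cell <- function(count, n) {
  if (n == 0) NA_real_ else round_half_up(100 * count / n, 1)
}

#' Aggregate reporting-quality checklists into a percentage table
#'
#' For each reporting parameter and each model (plus a pooled column over
#' all studies): the percentage of eligible studies answering `yes`, half-up
#' to one decimal. Studies marked `na` on a parameter are removed from that
#' parameter's denominator; a parameter with no eligible study in a group is
#' not applicable (`NA`, rendered "-").
#'
#' @param assessments non-empty list of [study_assessment()] records.
#' @return A `fimd_quality_table` tibble: `parameter`, `label`, one column
#'   per model and a `pooled` column, with group sizes in the
#'   `"group_n"` attribute.
#' @export
aggregate_reporting <- function(assessments) {
  check_assessments(assessments)
  models <- group_models(assessments)
  groups <- c(split(seq_along(assessments), factor(models, unique(models))),
              list(pooled = seq_along(assessments)))
  cols <- lapply(groups, function(idx) {
    vapply(reporting_fields, function(f) {
      v <- assessment_field(assessments[idx], "reporting", f)
      pct_cell(sum(v == "yes"), sum(v != "na"))
    }, numeric(1))
  })
  out <- tibble::tibble(
    parameter = reporting_fields,
    label = unname(reporting_labels[reporting_fields])
  )
  for (g in names(cols)) out[[g]] <- unname(cols[[g]])
  attr(out, "group_n") <- vapply(groups, length, integer(1))
  class(out) <- c("fimd_quality_table", class(out))
  out
}

#' Aggregate risk-of-bias checklists into a percentage table
#'
#' For each risk-of-bias item and each model (plus pooled): the percentage
#' of studies at low risk and at unclear risk, half-up to one decimal, as
#' columns `<group>_low` / `<group>_unclear`. The high-risk share is the
#' implicit remainder to 100.
#'
#' @inheritParams aggregate_reporting
#' @return A `fimd_quality_table` tibble: `parameter`, `label`, paired
#'   low/unclear columns per group, group sizes in the `"group_n"` attribute.
#' @export
aggregate_rob <- function(assessments) {
  check_assessments(assessments)
  models <- group_models(assessments)
  groups <- c(split(seq_along(assessments), factor(models, unique(models))),
              list(pooled = seq_along(assessments)))
  out <- tibble::tibble(
    parameter = rob_fields,
    label = unname(rob_labels[rob_fields])
  )
  for (g in names(groups)) {
    idx <- groups[[g]]
    vals <- vapply(rob_fields, function(f) {
      v <- assessment_field(assessments[idx], "rob", f)
      c(pct_cell(sum(v == "low"), length(v)),
        pct_cell(sum(v == "unclear"), length(v)))
    }, numeric(2))
    out[[paste0(g, "_low")]] <- unname(vals[1, ])
    out[[paste0(g, "_unclear")]] <- unname(vals[2, ])
  }
  attr(out, "group_n") <- vapply(groups, length, integer(1))
  class(out) <- c("fimd_quality_table", class(out))
  out
}

#' Sex distribution of the assessed studies
#'
#' Percentages of male-only, female-only and both-sexes studies among the
#' studies that disclose sex, half-up to one decimal; `NA` throughout when
#' no study discloses sex.
#'
#' @param assessments list of [study_assessment()] records.
#' @return Named numeric vector (`male`, `female`, `both`) with the number
#'   of disclosing studies in the `"n_disclosing"` attribute.
#' @export
sex_distribution <- function(assessments) {
  sex <- vapply(assessments, `[[`, character(1), "sex_category")
  sex <- sex[sex != "undisclosed"]
  out <- vapply(c(male = "male", female = "female", both = "both"),
                function(s) pct_cell(sum(sex == s), length(sex)), numeric(1))
  attr(out, "n_disclosing") <- length(sex)
  out
}

check_assessments <- function(assessments) {
  if (length(assessments) == 0) {
    stop("assessments must be non-empty", call. = FALSE)
  }
  ok <- vapply(assessments, inherits, logical(1), "fimd_assessment")
  if (!all(ok)) {
    stop("all elements must be study_assessment() records", call. = FALSE)
  }
  invisible(assessments)
}

#' Per-drug concordance between human and model outcomes
#'
#' Summarises the pharmacological evidence of a sheet: for every drug, its
#' human status, its model outcome and whether the two agree. This is
#' evidence for answering the drug-response questions; it never auto-answers
#' them, because turning per-drug evidence into a single questionnaire
#' answer is the validator's judgment.
#'
#' @param sheet a `fimd_sheet`.
#' @return Tibble with `drug_name`, `human_status`, `model_outcome`,
#'   `concordance` (`concordant`, `discordant`, `mixed`, `unknown`) and
#'   `n_studies`.
#' @export
drug_concordance <- function(sheet) {
  recs <- sheet$drug_records
  tibble::tibble(
    drug_name = vapply(recs, `[[`, character(1), "drug_name"),
    human_status = vapply(recs, `[[`, character(1), "human_status"),
    model_outcome = vapply(recs, `[[`, character(1), "model_outcome"),
    concordance = vapply(recs, function(d) {
      switch(d$model_outcome,
             unknown = "unknown", mixed = "mixed",
             if (d$model_outcome == d$human_status) "concordant"
             else "discordant")
    }, character(1)),
    n_studies = vapply(recs, function(d) length(d$study_ids), integer(1))
  )
}

#' @export
print.fimd_quality_table <- function(x, ...) {
  n <- attr(x, "group_n")
  cat("FIMD quality table (",
      paste(names(n), n, sep = " N=", collapse = ", "), ")\n", sep = "")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) ifelse(is.na(v), "-",
                                                sprintf("%.1f", v)))
  print(df[, names(df) != "parameter"], row.names = FALSE, right = FALSE)
  invisible(x)
}
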