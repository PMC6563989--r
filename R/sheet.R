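# Validation sheets: one animal model x one indication.

#' Build a bibliographic reference
#'
#' @param citation free-text citation.
#' @param year publication year (1800-2100).
#' @param identifier optional DOI or PMID.
#' @return A list of class `fimd_reference`.
#' @export
reference <- function(citation, year, identifier = NULL) {
  year <- as.integer(year)
  if (is.na(year) || year < 1800 || year > 2100) {
    stop("reference year must lie in 1800-2100", call. = FALSE)
  }
  structure(
    list(citation = as_chr1(citation, "citation"), year = year,
         identifier = if (is.null(identifier)) NULL else as_chr1(identifier, "identifier")),
    class = "fimd_reference"
  )
}

#' Record an answer to one question
#'
#' @param value one of `YES`, `PARTIAL`, `NO`, `UNCLEAR`.
#' @param rationale free-text justification of the answer.
#' @param references list of [reference()] records supporting the answer.
#' @return A list of class `fimd_answer`.
#' @export
answer <- function(value, rationale = "", references = list()) {
  value <- toupper(as_chr1(value, "value"))
  check_answer(value)
  structure(
    list(value = value, rationale = as.character(rationale %||% ""),
         references = references),
    class = "fimd_answer"
  )
}

#' Record the justified exclusion of a question
#'
#' A question may be dropped from a sheet (for instance when the disease has
#' no known prognostic biomarkers), but only with a written justification;
#' its weight is then removed from the attainable maximum.
#'
#' @param question_id id of the excluded question.
#' @param justification non-empty free text.
#' @param references supporting [reference()] records.
#' @return A list of class `fimd_exclusion`.
#' @export
exclusion <- function(question_id, justification, references = list()) {
  justification <- as.character(justification %||% "")
  structure(
    list(question_id = as_chr1(question_id, "question_id"),
         justification = justification, references = references),
    class = "fimd_exclusion"
  )
}

#' Record the evidence for one drug in the pharmacological domain
#'
#' @param drug_name drug name.
#' @param human_status whether the drug is `"effective"` or `"ineffective"`
#'   in humans.
#' @param model_outcome observed outcome in the model: `"effective"`,
#'   `"ineffective"`, `"mixed"` or `"unknown"` (no or conflicting evidence).
#' @param study_ids citation keys of the intervention studies assessed for
#'   this drug (rows of the study-assessment table).
#' @param references supporting [reference()] records.
#' @return A list of class `fimd_drug_record`.
#' @export
drug_record <- function(drug_name, human_status, model_outcome = "unknown",
                        study_ids = character(), references = list()) {
  human_status <- match.arg(human_status, c("effective", "ineffective"))
  model_outcome <- match.arg(model_outcome,
                             c("effective", "ineffective", "mixed", "unknown"))
  structure(
    list(drug_name = as_chr1(drug_name, "drug_name"),
         human_status = human_status, model_outcome = model_outcome,
         study_ids = as.character(study_ids), references = references),
    class = "fimd_drug_record"
  )
}

#' Assemble a validation sheet
#'
#' A sheet records the completed questionnaire for one animal model in one
#' indication: an answer for every non-excluded question, justified
#' exclusions, per-drug pharmacological evidence and free-text background.
#'
#' @param model_name,species,indication sheet identity.
#' @param answers named list mapping question id to [answer()] records (bare
#'   strings are promoted to answers without rationale).
#' @param exclusions list of [exclusion()] records.
#' @param drug_records list of [drug_record()] entries.
#' @param historical_background free text on the model's origin.
#' @param questionnaire_version registry version the sheet is bound to.
#' @return A list of class `fimd_sheet`.
#' @examples
#' sh <- validation_sheet("mdx mouse", "Mus musculus", "DMD",
#'   answers = stats::setNames(
#'     as.list(rep("YES", 21)), default_questionnaire()$questions$id))
#' nrow(validate_sheet(sh)) # 0
#' @export
validation_sheet <- function(model_name, species = "", indication = "",
                             answers = list(), exclusions = list(),
                             drug_records = list(),
                             historical_background = "",
                             questionnaire_version = "sw-1.0") {
  answers <- lapply(answers, function(a) {
    if (inherits(a, "fimd_answer")) a else answer(a)
  })
  structure(
    list(
      model_name = as_chr1(model_name, "model_name"),
      species = as.character(species %||% ""),
      indication = as.character(indication %||% ""),
      questionnaire_version = as.character(questionnaire_version),
      answers = answers,
      exclusions = exclusions,
      drug_records = drug_records,
      historical_background = as.character(historical_background %||% "")
    ),
    class = "fimd_sheet"
  )
}

#' @export
print.fimd_sheet <- function(x, ...) {
  cat("FIMD validation sheet: ", x$model_name,
      if (nzchar(x$species)) paste0(" (", x$species, ")"),
      if (nzchar(x$indication)) paste0(" — ", x$indication), "\n", sep = "")
  cat("  questionnaire ", x$questionnaire_version, "; ",
      length(x$answers), " answers, ", length(x$exclusions), " exclusions, ",
      length(x$drug_records), " drug records\n", sep = "")
  invisible(x)
}

#' Check a sheet against its questionnaire
#'
#' Structural validation: every non-excluded question must carry exactly one
#' answer, a question id may appear among the answers or the exclusions but
#' never both, ids must exist in the registry, and every exclusion must be
#' justified. Problems are returned as data, one row per violation, so a
#' caller can report all of them at once; an empty table means the sheet is
#' scoreable.
#'
#' @param sheet a `fimd_sheet`.
#' @param spec a `fimd_questionnaire` (default registry if omitted).
#' @return A tibble with columns `question_id`, `category` (one of
#'   `missing-answer`, `answered-and-excluded`, `unknown-id`,
#'   `empty-justification`) and `message`; zero rows iff the sheet is valid.
#' @export
validate_sheet <- function(sheet, spec = default_questionnaire()) {
  issues <- list()
  add <- function(question_id, category, message) {
    issues[[length(issues) + 1]] <<- tibble::tibble(
      question_id = question_id, category = category, message = message)
  }
  ans_ids <- names(sheet$answers) %||% character()
  excl_ids <- exclusion_ids(sheet$exclusions)

  for (id in setdiff(ans_ids, spec$questions$id)) {
    add(id, "unknown-id", paste0("answered question '", id,
                                 "' is not in questionnaire ", spec$version))
  }
  for (id in setdiff(excl_ids, spec$questions$id)) {
    add(id, "unknown-id", paste0("excluded question '", id,
                                 "' is not in questionnaire ", spec$version))
  }
  for (id in intersect(ans_ids, excl_ids)) {
    add(id, "answered-and-excluded",
        paste0("question '", id, "' is both answered and excluded"))
  }
  for (id in setdiff(spec$questions$id, union(ans_ids, excl_ids))) {
    add(id, "missing-answer", paste0("question '", id, "' has no answer"))
  }
  for (e in sheet$exclusions) {
    if (!nzchar(trimws(e$justification))) {
      add(e$question_id, "empty-justification",
          paste0("exclusion of '", e$question_id, "' has no justification"))
    }
  }
  if (anyDuplicated(ans_ids)) {
    for (id in unique(ans_ids[duplicated(ans_ids)])) {
      add(id, "answered-and-excluded",
          paste0("question '", id, "' answered more than once"))
    }
  }
  if (length(issues) == 0) {
    tibble::tibble(question_id = character(), category = character(),
                   message = character())
  } else {
    do.call(rbind, issues)
  }
}

stop_if_invalid <- function(sheet, spec) {
  iss <- validate_sheet(sheet, spec)
  if (nrow(iss) > 0) {
    stop("invalid validation sheet:\n  ",
         paste(iss$message, collapse = "\n  "), call. = FALSE)
  }
  invisible(sheet)
}

sheet_references <- function(sheet) {
  refs <- list()
  for (a in sheet$answers) refs <- c(refs, a$references)
  for (e in sheet$exclusions) refs <- c(refs, e$references)
  for (d in sheet$drug_records) refs <- c(refs, d$references)
  refs
}

#' Validation date of a sheet
#'
#' The validation date is the latest publication year among all references
#' attached to the sheet's answers, exclusions and drug records: it marks how
#' current the evidence behind the validation is.
#'
#' @param sheet a `fimd_sheet`.
#' @return Integer year.
#' @export
validation_date <- function(sheet) {
  refs <- sheet_references(sheet)
  if (length(refs) == 0) {
    stop("sheet carries no references; validation date is undefined",
         call. = FALSE)
  }
  max(vapply(refs, function(r) as.integer(r$year), integer(1)))
}
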