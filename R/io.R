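# Readers and writers: sheets as YAML/JSON, study assessments as CSV.

SHEET_FORMAT_VERSION <- "1.0"

ref_to_list <- function(r) {
  out <- list(citation = r$citation, year = r$year)
  if (!is.null(r$identifier)) out$identifier <- r$identifier
  out
}

refs_to_list <- function(refs) lapply(refs, ref_to_list)

ref_from_list <- function(x) {
  reference(x$citation %||% "", x$year, x$identifier)
}

# Answer values survive YAML 1.1 bool coercion (an unquoted YES parses as
# TRUE); map logicals back rather than erroring on a hand-edited file.
coerce_answer_value <- function(v) {
  if (is.logical(v)) return(if (v) "YES" else "NO")
  toupper(as.character(v))
}

sheet_to_document <- function(sheet) {
  ans_ids <- sort(names(sheet$answers))
  answers <- lapply(ans_ids, function(id) {
    a <- sheet$answers[[id]]
    out <- list(value = a$value)
    if (nzchar(a$rationale)) out$rationale <- a$rationale
    if (length(a$references) > 0) out$references <- refs_to_list(a$references)
    out
  })
  names(answers) <- ans_ids
  excl <- sheet$exclusions[order(exclusion_ids(sheet$exclusions))]
  exclusions <- lapply(excl, function(e) {
    out <- list(question_id = e$question_id, justification = e$justification)
    if (length(e$references) > 0) out$references <- refs_to_list(e$references)
    out
  })
  drugs <- sheet$drug_records[
    order(vapply(sheet$drug_records, `[[`, character(1), "drug_name"))]
  drug_records <- lapply(drugs, function(d) {
    out <- list(drug_name = d$drug_name, human_status = d$human_status,
                model_outcome = d$model_outcome)
    if (length(d$study_ids) > 0) out$study_ids <- as.list(d$study_ids)
    if (length(d$references) > 0) out$references <- refs_to_list(d$references)
    out
  })
  doc <- list(
    format_version = SHEET_FORMAT_VERSION,
    model_name = sheet$model_name,
    species = sheet$species,
    indication = sheet$indication,
    questionnaire_version = sheet$questionnaire_version,
    historical_background = sheet$historical_background,
    answers = answers,
    exclusions = exclusions,
    drug_records = drug_records
  )
  doc
}

sheet_from_document <- function(doc, path = "<document>") {
  if (is.null(doc$format_version)) {
    stop("sheet file ", path, " declares no format_version", call. = FALSE)
  }
  if (as.character(doc$format_version) != SHEET_FORMAT_VERSION) {
    stop("unsupported sheet format_version '", doc$format_version,
         "' in ", path, " (supported: ", SHEET_FORMAT_VERSION, ")",
         call. = FALSE)
  }
  answers <- lapply(doc$answers %||% list(), function(a) {
    answer(coerce_answer_value(a$value), a$rationale %||% "",
           lapply(a$references %||% list(), ref_from_list))
  })
  exclusions <- lapply(doc$exclusions %||% list(), function(e) {
    exclusion(e$question_id, e$justification %||% "",
              lapply(e$references %||% list(), ref_from_list))
  })
  drug_records <- lapply(doc$drug_records %||% list(), function(d) {
    drug_record(d$drug_name, d$human_status, d$model_outcome %||% "unknown",
                unlist(d$study_ids) %||% character(),
                lapply(d$references %||% list(), ref_from_list))
  })
  validation_sheet(
    model_name = doc$model_name %||% "",
    species = doc$species %||% "",
    indication = doc$indication %||% "",
    answers = answers,
    exclusions = exclusions,
    drug_records = drug_records,
    historical_background = doc$historical_background %||% "",
    questionnaire_version = doc$questionnaire_version %||% "sw-1.0"
  )
}

is_json_path <- function(path) grepl("\\.json$", path, ignore.case = TRUE)

#' Write a validation sheet to YAML or JSON
#'
#' The on-disk document adds a `format_version` and serialises answers,
#' exclusions and drug records with sorted keys, so repeated writes of the
#' same sheet are byte-identical. The format is chosen from the file
#' extension: `.json` writes JSON, anything else YAML.
#'
#' @param sheet a `fimd_sheet`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sheet <- function(sheet, path) {
  doc <- sheet_to_document(sheet)
  if (is_json_path(path)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  } else {
    writeLines(yaml::as.yaml(doc), path)
  }
  invisible(path)
}

#' Read a validation sheet from YAML or JSON
#'
#' Reads a sheet document written by [write_sheet()] (or authored by hand),
#' checks its format version and validates it against the questionnaire.
#' A sheet that fails [validate_sheet()] is rejected with every issue listed.
#'
#' @param path sheet file (`.yaml`/`.yml` or `.json`).
#' @param spec questionnaire registry to validate against; `NULL` skips
#'   validation (for inspecting broken sheets).
#' @return A `fimd_sheet`.
#' @export
read_sheet <- function(path, spec = default_questionnaire()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- if (is_json_path(path)) {
    jsonlite::read_json(path)
  } else {
    yaml::read_yaml(path)
  }
  sheet <- sheet_from_document(doc, path)
  if (!is.null(spec)) stop_if_invalid(sheet, spec)
  sheet
}

# Assessments CSV --------------------------------------------------------

#' Read study assessments from CSV
#'
#' @param path CSV file in the published dialect ([assessment_columns]).
#' @return List of [study_assessment()] records (empty for an empty file).
#' @export
read_assessments <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0) return(list())
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, strip.white = TRUE)
  unknown <- setdiff(names(df), assessment_columns)
  if (length(unknown) > 0) {
    stop("unknown column(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(assessment_columns, names(df))
  if (length(missing) > 0) {
    stop("missing column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    tryCatch(
      study_assessment(
        study_id = row$study_id, model_name = row$model_name,
        reporting = as.list(row[reporting_fields]),
        rob = as.list(row[rob_fields]),
        sex_category = row$sex_category
      ),
      error = function(e) {
        stop("row ", i, " of ", path, ": ", conditionMessage(e),
             call. = FALSE)
      }
    )
  })
}

#' Write study assessments to CSV
#'
#' @param assessments list of [study_assessment()] records.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_assessments <- function(assessments, path) {
  rows <- lapply(assessments, function(a) {
    c(study_id = a$study_id, model_name = a$model_name,
      sex_category = a$sex_category,
      unlist(a$reporting), unlist(a$rob))
  })
  df <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  if (length(rows) == 0) {
    df <- as.data.frame(matrix(character(), ncol = length(assessment_columns),
                               dimnames = list(NULL, assessment_columns)))
  }
  utils::write.csv(df[assessment_columns], path, row.names = FALSE,
                   quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a quality table to CSV
#'
#' Percentage cells are written to one decimal; not-applicable cells as "-".
#'
#' @param x a `fimd_quality_table` from [aggregate_reporting()] or
#'   [aggregate_rob()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_quality_table <- function(x, path) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v)
    ifelse(is.na(v), "-", sprintf("%.1f", v)))
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
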