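#' @keywords internal
"_PACKAGE"

# Answer values ---------------------------------------------------------

#' Allowed answer values
#'
#' A questionnaire question is answered `YES`, `PARTIAL`, `NO` or `UNCLEAR`.
#' An excluded question carries no answer at all (it carries an exclusion
#' record with a justification instead). A "definite" answer is any answer
#' except `UNCLEAR`; the percentage of definite answers determines the
#' validation level of a sheet.
#'
#' @format Character vector of the four allowed values.
#' @export
answer_values <- c("YES", "PARTIAL", "NO", "UNCLEAR")

#' @rdname answer_values
#' @param answer character vector of answer values.
#' @return `is_definite()`: logical, `TRUE` for `YES`/`PARTIAL`/`NO`,
#'   `FALSE` for `UNCLEAR`.
#' @export
is_definite <- function(answer) {
  check_answer(answer)
  answer != "UNCLEAR"
}

check_answer <- function(answer) {
  bad <- setdiff(unique(answer), answer_values)
  if (length(bad) > 0) {
    stop("invalid answer value(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(answer_values, collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(answer)
}

# Questionnaire registry ------------------------------------------------

new_questionnaire <- function(version, domains, questions) {
  structure(
    list(version = version, domains = domains, questions = questions),
    class = "fimd_questionnaire"
  )
}

#' Load a questionnaire registry from a YAML spec file
#'
#' The registry is data, not code: a YAML document listing domains (id, name,
#' weight) and questions (id, owning domain, weight, prompt). Users can derive
#' variant questionnaires by editing a copy of the packaged file; the version
#' string travels with every sheet so scores are always tied to the registry
#' they were computed against.
#'
#' @param path path to a questionnaire YAML file.
#' @return A `fimd_questionnaire`: list with `version`, a `domains` tibble
#'   (`id`, `name`, `weight`) and a `questions` tibble
#'   (`id`, `domain_id`, `text`, `weight`).
#' @seealso [default_questionnaire()]
#' @export
read_questionnaire <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$version) || is.null(doc$domains) || is.null(doc$questions)) {
    stop("questionnaire file must declare version, domains and questions",
         call. = FALSE)
  }
  domains <- tibble::tibble(
    id = vapply(doc$domains, function(d) as.integer(d$id), integer(1)),
    name = vapply(doc$domains, function(d) as.character(d$name), character(1)),
    weight = vapply(doc$domains, function(d) as.numeric(d$weight), numeric(1))
  )
  questions <- tibble::tibble(
    id = vapply(doc$questions, function(q) as.character(q$id), character(1)),
    domain_id = vapply(doc$questions, function(q) as.integer(q$domain), integer(1)),
    text = vapply(doc$questions, function(q) as.character(q$text %||% ""), character(1)),
    weight = vapply(doc$questions, function(q) as.numeric(q$weight), numeric(1))
  )
  q <- new_questionnaire(as.character(doc$version), domains, questions)
  validate_questionnaire(q)
  q
}

validate_questionnaire <- function(q) {
  if (anyDuplicated(q$questions$id)) {
    stop("duplicate question ids in questionnaire", call. = FALSE)
  }
  if (anyDuplicated(q$domains$id)) {
    stop("duplicate domain ids in questionnaire", call. = FALSE)
  }
  lead <- as.integer(sub("\\..*$", "", q$questions$id))
  if (!all(lead == q$questions$domain_id)) {
    stop("question id must start with its domain id", call. = FALSE)
  }
  if (!all(q$questions$domain_id %in% q$domains$id)) {
    stop("question assigned to unknown domain", call. = FALSE)
  }
  if (any(q$questions$weight < 0)) {
    stop("question weights must be non-negative", call. = FALSE)
  }
  # per-domain question weights must sum exactly to the domain weight
  qu <- points_to_micro(q$questions$weight)
  du <- points_to_micro(q$domains$weight)
  for (i in seq_len(nrow(q$domains))) {
    s <- sum(qu[q$questions$domain_id == q$domains$id[i]])
    if (s != du[i]) {
      stop("weights of domain ", q$domains$id[i],
           " questions do not sum to the domain weight", call. = FALSE)
    }
  }
  invisible(q)
}

#' The default eight-domain questionnaire
#'
#' Returns the canonical registry under the same-weight (SW) system:
#' 100 points divided equally over eight validation domains
#' (Epidemiological, Symptomatology and Natural History, Genetic,
#' Biochemical, Aetiological, Histological, Pharmacological, Endpoint;
#' 12.5 points each) and then equally over the questions within each domain.
#' The 21 answerable questions are ids 1.1, 1.2, 2.1, 2.2.1-2.2.4, 3.1-3.3,
#' 4.1-4.4, 5.1, 6.1, 7.1-7.3, 8.1 and 8.2; where an equal split does not
#' terminate, the last question of the domain absorbs the rounding remainder
#' (4.17/4.17/4.16), so every domain sums to 12.5 exactly and the registry
#' to 100.
#'
#' @return A `fimd_questionnaire` (see [read_questionnaire()]).
#' @examples
#' q <- default_questionnaire()
#' nrow(q$questions) # 21
#' sum(q$questions$weight) # 100
#' @export
default_questionnaire <- function() {
  if (is.null(.registry_cache$default)) {
    path <- system.file("extdata", "questionnaire_sw_v1.yaml", package = "fimd")
    .registry_cache$default <- read_questionnaire(path)
  }
  .registry_cache$default
}

.registry_cache <- new.env(parent = emptyenv())

#' @export
print.fimd_questionnaire <- function(x, ...) {
  cat("FIMD questionnaire [", x$version, "]: ",
      nrow(x$domains), " domains, ", nrow(x$questions), " questions, ",
      "total weight ", format(sum(x$questions$weight)), "\n", sep = "")
  for (i in seq_len(nrow(x$domains))) {
    qs <- x$questions[x$questions$domain_id == x$domains$id[i], ]
    cat(sprintf("  %d. %s (%s): %s\n", x$domains$id[i], x$domains$name[i],
                format(x$domains$weight[i]), paste(qs$id, collapse = ", ")))
  }
  invisible(x)
}

question_domain <- function(spec, question_id) {
  i <- match(question_id, spec$questions$id)
  spec$questions$domain_id[i]
}

question_weight_u <- function(spec, question_id = NULL) {
  u <- points_to_micro(spec$questions$weight)
  names(u) <- spec$questions$id
  if (is.null(question_id)) u else u[question_id]
}
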