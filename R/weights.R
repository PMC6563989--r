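# Same-weight (SW) distribution and exclusion-adjusted maxima.

#' Split a domain weight equally over its questions
#'
#' Implements the same-weight rule: a domain's weight is divided equally over
#' its questions. When the quotient terminates within three decimal places
#' every question carries that exact value (6.25, 2.5, 3.125, 12.5). When it
#' does not, the first `n - 1` questions carry the quotient rounded half-up
#' to two decimals and the last question absorbs the remainder, so the sum is
#' exact (12.5 over three questions gives 4.17, 4.17, 4.16).
#'
#' @param domain_weight domain weight in score points (non-negative).
#' @param n_questions number of questions in the domain (positive integer).
#' @return Numeric vector of length `n_questions` summing exactly to
#'   `domain_weight`.
#' @examples
#' assign_question_weights(12.5, 2) # 6.25 6.25
#' assign_question_weights(12.5, 3) # 4.17 4.17 4.16
#' assign_question_weights(12.5, 4) # 3.125 3.125 3.125 3.125
#' @export
assign_question_weights <- function(domain_weight, n_questions) {
  if (length(n_questions) != 1 || is.na(n_questions) || n_questions < 1 ||
      n_questions != as.integer(n_questions)) {
    stop("n_questions must be a positive integer", call. = FALSE)
  }
  if (length(domain_weight) != 1 || is.na(domain_weight) || domain_weight < 0) {
    stop("domain_weight must be a single non-negative number", call. = FALSE)
  }
  w_u <- points_to_micro(domain_weight)
  n <- as.integer(n_questions)
  # quotient terminates within 3 decimals iff it is a whole number of
  # milli-points (1000 micro-points)
  if (w_u %% n == 0 && (w_u / n) %% 1000 == 0) {
    return(micro_to_points(rep(w_u / n, n)))
  }
  head_u <- round_half_up(w_u / n / 10000) * 10000 # 2-decimal half-up, micro
  last_u <- w_u - (n - 1) * head_u
  if (last_u < 0) {
    stop("rounding remainder is negative; domain weight too small for n",
         call. = FALSE)
  }
  micro_to_points(c(rep(head_u, n - 1), last_u))
}

#' Attainable weights after question exclusions
#'
#' Dropping a question removes its weight from the attainable maximum; the
#' surviving questions keep their weights unchanged (no redistribution —
#' comparability across sheets is restored later by the equivalent-score
#' rescale). Excluding the two prognostic-biomarker questions 4.3 and 4.4,
#' for example, leaves an attainable maximum of 93.75.
#'
#' @param spec a `fimd_questionnaire`.
#' @param exclusions character vector of excluded question ids, or a list of
#'   exclusion records (each with a `question_id`).
#' @return A `fimd_weight_table`: list with `per_question` (named numeric,
#'   surviving questions only), `per_domain` (named numeric over all domains;
#'   a fully excluded domain has weight 0) and `max_total`.
#' @examples
#' wt <- effective_weights(default_questionnaire(), c("4.3", "4.4"))
#' wt$max_total # 93.75
#' @export
effective_weights <- function(spec, exclusions = character()) {
  excl_ids <- exclusion_ids(exclusions)
  unknown <- setdiff(excl_ids, spec$questions$id)
  if (length(unknown) > 0) {
    stop("unknown question id(s) in exclusions: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  keep <- !(spec$questions$id %in% excl_ids)
  w_u <- question_weight_u(spec)
  per_domain_u <- vapply(
    spec$domains$id,
    function(d) sum(w_u[keep & spec$questions$domain_id == d]),
    numeric(1)
  )
  names(per_domain_u) <- as.character(spec$domains$id)
  structure(
    list(
      per_question = micro_to_points(w_u[keep]),
      per_domain = micro_to_points(per_domain_u),
      max_total = micro_to_points(sum(w_u[keep]))
    ),
    class = "fimd_weight_table"
  )
}

#' @export
print.fimd_weight_table <- function(x, ...) {
  cat("FIMD weight table: max total", format(x$max_total), "over",
      length(x$per_question), "questions\n")
  cat("  per domain:", paste(names(x$per_domain), format(x$per_domain),
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Accepts ids, exclusion records, or a sheet's exclusions list.
exclusion_ids <- function(exclusions) {
  if (is.null(exclusions) || length(exclusions) == 0) return(character())
  if (is.character(exclusions)) return(exclusions)
  vapply(exclusions, function(e) as.character(e$question_id), character(1))
}
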