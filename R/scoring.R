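# Scoring: question scores, domain ratios, totals, factors, levels.

#' Score a single answer
#'
#' `YES` earns the full question weight, `PARTIAL` earns half (the partial
#' grade for models that only partially mimic an aspect of the disease), and
#' `NO` earns nothing. `UNCLEAR` also earns nothing: evidence that is missing
#' or conflicting is scored as absent, the conservative reading, so a sheet's
#' score can never exceed what its definite answers support.
#'
#' @param answer one of `YES`, `PARTIAL`, `NO`, `UNCLEAR` (vectorised).
#' @param weight question weight in points (vectorised).
#' @return Earned score in points.
#' @examples
#' question_score("PARTIAL", 6.25) # 3.125
#' @export
question_score <- function(answer, weight) {
  check_answer(answer)
  if (any(weight < 0)) stop("weight must be non-negative", call. = FALSE)
  w_u <- points_to_micro(weight)
  f <- c(YES = 1, PARTIAL = 0.5, NO = 0, UNCLEAR = 0)[answer]
  micro_to_points(unname(w_u * f))
}

#' Rescale a raw score to the 0-100 equivalent scale
#'
#' When questions are excluded the attainable maximum shrinks below 100, so
#' raw totals of sheets with different exclusions are not comparable. The
#' equivalent score rescales the raw total back to a 0-100 scale
#' (`raw * 100 / max`), reported half-up to two decimals: a raw 63.54 against
#' an attainable 93.75 gives 67.78.
#'
#' @param raw_total earned points.
#' @param max_total attainable maximum after exclusions.
#' @return Equivalent score on 0-100, two decimals.
#' @export
equivalent_score <- function(raw_total, max_total) {
  if (any(max_total <= 0)) stop("max_total must be positive", call. = FALSE)
  if (any(raw_total < 0 | raw_total > max_total + 1e-9)) {
    stop("raw_total must lie in [0, max_total]", call. = FALSE)
  }
  round_half_up(raw_total * 100 / max_total, 2)
}

#' Per-domain score ratio for radar plots
#'
#' The ratio of a domain's earned score to its attainable (surviving) weight,
#' in `[0, 1]`; 6.25 earned of 12.5 attainable gives 0.5. A fully excluded
#' domain has no attainable weight and yields `NA` (not applicable), which
#' radar plots draw as an axis gap rather than a zero.
#'
#' @param earned earned points in the domain.
#' @param available attainable points of the domain after exclusions.
#' @return Ratio in `[0, 1]`, or `NA` when `available` is 0.
#' @export
domain_ratio <- function(earned, available) {
  out <- rep(NA_real_, length(earned))
  ok <- available > 0
  if (any(earned[ok] < -1e-12 | earned[ok] > available[ok] + 1e-9)) {
    stop("earned must lie in [0, available]", call. = FALSE)
  }
  out[ok] <- earned[ok] / available[ok]
  out
}

# Item lists ------------------------------------------------------------
#
# Factors (uncertainty, similarity, definite share) are counted over
# "items". In flat mode the items are the non-excluded questionnaire
# questions. In expanded mode the two drug-response questions (7.1:
# human-effective drugs; 7.2: human-ineffective drugs) are replaced by one
# item per drug on the matching side, each answered by the concordance of
# the drug's model outcome with its human status:
# concordant -> YES, mixed -> PARTIAL, discordant -> NO, unknown -> UNCLEAR.
# A side with no drugs keeps the question itself as a single item, so a
# sheet without drug records behaves identically in both modes.

drug_item_value <- function(human_status, model_outcome) {
  if (model_outcome == "unknown") return("UNCLEAR")
  if (model_outcome == "mixed") return("PARTIAL")
  if (model_outcome == human_status) "YES" else "NO"
}

drug_question <- function(human_status) {
  if (human_status == "effective") "7.1" else "7.2"
}

sheet_items <- function(sheet, spec, item_mode = c("flat", "expanded")) {
  item_mode <- match.arg(item_mode)
  excl <- exclusion_ids(sheet$exclusions)
  qids <- setdiff(spec$questions$id, excl)
  out <- tibble::tibble(
    item_id = qids,
    question_id = qids,
    value = vapply(qids, function(id) sheet$answers[[id]]$value, character(1))
  )
  if (item_mode == "flat" || length(sheet$drug_records) == 0) return(out)

  drugs <- tibble::tibble(
    drug_name = vapply(sheet$drug_records, `[[`, character(1), "drug_name"),
    question_id = vapply(sheet$drug_records, function(d)
      drug_question(d$human_status), character(1)),
    value = vapply(sheet$drug_records, function(d)
      drug_item_value(d$human_status, d$model_outcome), character(1))
  )
  for (q in c("7.1", "7.2")) {
    dq <- drugs[drugs$question_id == q, ]
    if (q %in% excl || nrow(dq) == 0) next
    out <- out[out$item_id != q, ]
    out <- rbind(out, tibble::tibble(
      item_id = paste0(q, ":", dq$drug_name),
      question_id = q, value = dq$value))
  }
  out[order(out$item_id), ]
}

#' Uncertainty factor of a sheet
#'
#' The percentage of items answered `UNCLEAR` — how much information is
#' missing from the validation. In `"flat"` mode items are the non-excluded
#' questionnaire questions; in `"expanded"` mode the two drug-response
#' questions are counted once per drug with evidence recorded in the sheet
#' (see [score_sheet()] for the expansion rule).
#'
#' @param sheet a valid `fimd_sheet`.
#' @param item_mode `"flat"` (default) or `"expanded"`.
#' @param spec questionnaire registry.
#' @return Percentage, half-up to one decimal.
#' @export
uncertainty_factor <- function(sheet, item_mode = c("flat", "expanded"),
                               spec = default_questionnaire()) {
  item_mode <- match.arg(item_mode)
  stop_if_invalid(sheet, spec)
  items <- sheet_items(sheet, spec, item_mode)
  if (nrow(items) == 0) stop("sheet has no items to count", call. = FALSE)
  round_half_up(100 * sum(items$value == "UNCLEAR") / nrow(items), 1)
}

#' Validation level from the definite-answer percentage
#'
#' A "definite" answer is any answer except `UNCLEAR`. The percentage of
#' definite answers is rounded half-up to the nearest integer and banded:
#' 0-40 insufficiently, 41-60 slightly, 61-80 moderately and 81-100 highly
#' validated. The bands partition every attainable percentage, so each sheet
#' maps to exactly one level.
#'
#' @param definite_pct percentage of definite answers, in `[0, 100]`
#'   (vectorised).
#' @return Character vector of levels (`"Insufficiently validated"`, ...).
#' @examples
#' validation_level(c(85, 50, 40.4))
#' @export
validation_level <- function(definite_pct) {
  if (any(is.na(definite_pct) | definite_pct < 0 | definite_pct > 100)) {
    stop("definite_pct must lie in [0, 100]", call. = FALSE)
  }
  p <- round_half_up(definite_pct)
  levels <- c("Insufficiently validated", "Slightly validated",
              "Moderately validated", "Highly validated")
  levels[findInterval(p, c(0, 41, 61, 81))]
}

#' Score a validation sheet
#'
#' Computes the complete score breakdown of a valid sheet: per-question and
#' per-domain earned scores, the raw total, the attainable maximum after
#' exclusions, the 0-100 equivalent score, per-domain ratios for the radar
#' plot, the uncertainty factor, the definite-answer percentage and the
#' resulting validation level. All sums are carried in exact fixed-point
#' arithmetic; only the reported equivalent score (two decimals) and
#' percentages (one decimal) are rounded, half-up.
#'
#' @param sheet a `fimd_sheet` that passes [validate_sheet()].
#' @param spec questionnaire registry the sheet is bound to.
#' @param item_mode item counting mode for the uncertainty factor and
#'   definite percentage; see [uncertainty_factor()].
#' @return A `fimd_scores` object: list with `model_name`, `per_question`
#'   tibble (`question_id`, `domain_id`, `weight`, `answer`, `score`),
#'   `per_domain` tibble (`domain_id`, `name`, `raw`, `available`, `ratio`),
#'   `raw_total`, `max_total`, `equivalent_score`, `uncertainty_pct`,
#'   `definite_pct`, `level`, `item_mode` and `questionnaire_version`.
#' @examples
#' q <- default_questionnaire()
#' sh <- validation_sheet("example", answers = stats::setNames(
#'   as.list(rep("YES", 21)), q$questions$id))
#' score_sheet(sh)$equivalent_score # 100
#' @export
score_sheet <- function(sheet, spec = default_questionnaire(),
                        item_mode = c("flat", "expanded")) {
  item_mode <- match.arg(item_mode)
  stop_if_invalid(sheet, spec)
  excl <- exclusion_ids(sheet$exclusions)
  keep <- !(spec$questions$id %in% excl)
  qids <- spec$questions$id[keep]
  w_u <- question_weight_u(spec)[keep]
  ans <- vapply(qids, function(id) sheet$answers[[id]]$value, character(1))
  score_u <- w_u * c(YES = 1, PARTIAL = 0.5, NO = 0, UNCLEAR = 0)[ans]

  per_question <- tibble::tibble(
    question_id = qids,
    domain_id = question_domain(spec, qids),
    weight = micro_to_points(unname(w_u)),
    answer = unname(ans),
    score = micro_to_points(unname(score_u))
  )
  raw_u <- vapply(spec$domains$id, function(d)
    sum(score_u[per_question$domain_id == d]), numeric(1))
  avail_u <- vapply(spec$domains$id, function(d)
    sum(w_u[per_question$domain_id == d]), numeric(1))
  per_domain <- tibble::tibble(
    domain_id = spec$domains$id,
    name = spec$domains$name,
    raw = micro_to_points(raw_u),
    available = micro_to_points(avail_u),
    ratio = domain_ratio(micro_to_points(raw_u), micro_to_points(avail_u))
  )
  raw_total <- micro_to_points(sum(score_u))
  max_total <- micro_to_points(sum(w_u))

  items <- sheet_items(sheet, spec, item_mode)
  definite_pct <- round_half_up(100 * sum(items$value != "UNCLEAR") /
                                  nrow(items), 1)
  structure(
    list(
      model_name = sheet$model_name,
      indication = sheet$indication,
      questionnaire_version = sheet$questionnaire_version,
      item_mode = item_mode,
      per_question = per_question,
      per_domain = per_domain,
      raw_total = raw_total,
      max_total = max_total,
      equivalent_score = equivalent_score(raw_total, max_total),
      uncertainty_pct = round_half_up(100 * sum(items$value == "UNCLEAR") /
                                        nrow(items), 1),
      definite_pct = definite_pct,
      level = validation_level(definite_pct)
    ),
    class = "fimd_scores"
  )
}

#' @export
print.fimd_scores <- function(x, ...) {
  cat("FIMD score breakdown: ", x$model_name,
      if (nzchar(x$indication)) paste0(" — ", x$indication), "\n", sep = "")
  cat(sprintf("  raw %s / %s, equivalent score %.2f\n",
              format(x$raw_total), format(x$max_total), x$equivalent_score))
  cat(sprintf("  uncertainty %.1f%%, definite %.1f%% (%s items) -> %s\n",
              x$uncertainty_pct, x$definite_pct, x$item_mode, x$level))
  r <- ifelse(is.na(x$per_domain$ratio), "-",
              sprintf("%.2f", x$per_domain$ratio))
  cat("  domain ratios:", paste(x$per_domain$domain_id, r, sep = "=",
                                collapse = ", "), "\n")
  invisible(x)
}
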