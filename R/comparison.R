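# Pairwise comparison of two sheets validated for the same indication.

comparable_items <- function(a, b, spec, item_mode) {
  ia <- sheet_items(a, spec, item_mode)
  ib <- sheet_items(b, spec, item_mode)
  shared <- intersect(ia$item_id, ib$item_id)
  # an item excluded (or, in expanded mode, absent) in either sheet has no
  # answer to match and is dropped from numerator and denominator alike
  tibble::tibble(
    item_id = shared,
    value_a = ia$value[match(shared, ia$item_id)],
    value_b = ib$value[match(shared, ib$item_id)]
  )
}

check_same_version <- function(a, b) {
  if (!identical(a$questionnaire_version, b$questionnaire_version)) {
    stop("sheets are bound to different questionnaire versions: ",
         a$questionnaire_version, " vs ", b$questionnaire_version,
         call. = FALSE)
  }
}

#' Similarity factor between two sheets
#'
#' The percentage of comparable items answered identically in both sheets —
#' how alike two models of the same indication look under the questionnaire.
#' Items excluded in either sheet are not comparable and are dropped. By
#' default two `UNCLEAR` answers count as agreement (they are the same
#' answer); `strict = TRUE` additionally drops items that are `UNCLEAR` in
#' both sheets, so agreement is then counted over definite evidence only.
#'
#' @param a,b valid `fimd_sheet`s bound to the same questionnaire version.
#' @param item_mode `"flat"` or `"expanded"`; see [uncertainty_factor()]. In
#'   expanded mode drug items are matched by drug name.
#' @param strict drop items answered `UNCLEAR` in both sheets.
#' @param spec questionnaire registry.
#' @return Percentage, half-up to one decimal.
#' @export
similarity_factor <- function(a, b, item_mode = c("flat", "expanded"),
                              strict = FALSE,
                              spec = default_questionnaire()) {
  item_mode <- match.arg(item_mode)
  check_same_version(a, b)
  stop_if_invalid(a, spec)
  stop_if_invalid(b, spec)
  items <- comparable_items(a, b, spec, item_mode)
  if (strict) {
    items <- items[!(items$value_a == "UNCLEAR" & items$value_b == "UNCLEAR"), ]
  }
  if (nrow(items) == 0) stop("no comparable items between sheets", call. = FALSE)
  round_half_up(100 * sum(items$value_a == items$value_b) / nrow(items), 1)
}

#' Compare two validation sheets
#'
#' Scores both sheets, computes their similarity factor and the per-domain
#' ratio differences, and bundles the two radar series for an overlay plot.
#'
#' @inheritParams similarity_factor
#' @return A `fimd_comparison`: list with `similarity_pct`,
#'   `comparable_items`, `per_domain` tibble (`domain_id`, `name`, `ratio_a`,
#'   `ratio_b`, `delta` = ratio_a - ratio_b), the two `fimd_scores` objects
#'   (`scores_a`, `scores_b`) and `series` (see [radar_series()]).
#' @examples
#' q <- default_questionnaire()
#' yes <- stats::setNames(as.list(rep("YES", 21)), q$questions$id)
#' no <- stats::setNames(as.list(rep("NO", 21)), q$questions$id)
#' cmp <- compare_sheets(validation_sheet("A", answers = yes),
#'                       validation_sheet("B", answers = no))
#' cmp$similarity_pct # 0
#' @export
compare_sheets <- function(a, b, item_mode = c("flat", "expanded"),
                           strict = FALSE, spec = default_questionnaire()) {
  item_mode <- match.arg(item_mode)
  sa <- score_sheet(a, spec, item_mode)
  sb <- score_sheet(b, spec, item_mode)
  items <- comparable_items(a, b, spec, item_mode)
  per_domain <- tibble::tibble(
    domain_id = sa$per_domain$domain_id,
    name = sa$per_domain$name,
    ratio_a = sa$per_domain$ratio,
    ratio_b = sb$per_domain$ratio,
    delta = sa$per_domain$ratio - sb$per_domain$ratio
  )
  structure(
    list(
      model_a = a$model_name, model_b = b$model_name,
      similarity_pct = similarity_factor(a, b, item_mode, strict, spec),
      comparable_items = nrow(items),
      per_domain = per_domain,
      scores_a = sa, scores_b = sb,
      series = radar_series(list(sa, sb))
    ),
    class = "fimd_comparison"
  )
}

#' @export
print.fimd_comparison <- function(x, ...) {
  cat("FIMD comparison: ", x$model_a, " vs ", x$model_b, "\n", sep = "")
  cat(sprintf("  similarity %.1f%% over %d comparable items\n",
              x$similarity_pct, x$comparable_items))
  cat(sprintf("  equivalent scores %.2f vs %.2f\n",
              x$scores_a$equivalent_score, x$scores_b$equivalent_score))
  d <- ifelse(is.na(x$per_domain$delta), "-",
              sprintf("%+.2f", x$per_domain$delta))
  cat("  domain ratio deltas:", paste(x$per_domain$domain_id, d, sep = "=",
                                      collapse = ", "), "\n")
  invisible(x)
}
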