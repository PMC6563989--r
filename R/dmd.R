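# The DMD worked example: published aggregated quality marginals for the
# mdx mouse and GRMD dog intervention studies, shipped as package data.

#' Published DMD quality-assessment marginals
#'
#' The aggregated reporting-quality and risk-of-bias percentages published
#' for the drug-intervention studies behind the Duchenne muscular dystrophy
#' validation case: 32 mdx mouse studies and 3 GRMD dog studies. These are
#' per-model group summaries; [dmd_assessments()] reconstructs a
#' per-study table consistent with them.
#'
#' @return List of tibbles: `sizes` (`model`, `n_studies`), `reporting`
#'   (`parameter` plus one percentage column per model; `NA` = not
#'   applicable), `rob` (`parameter` plus `<model>_low` / `<model>_unclear`
#'   columns) and `sex` (`category` plus one column per model, percentages
#'   over sex-disclosing studies).
#' @export
dmd_quality_marginals <- function() {
  read_marg <- function(file) {
    tibble::as_tibble(utils::read.csv(
      system.file("extdata", file, package = "fimd"),
      comment.char = "#", check.names = FALSE))
  }
  list(
    sizes = read_marg("dmd_group_sizes.csv"),
    reporting = read_marg("dmd_reporting_marginals.csv"),
    rob = read_marg("dmd_rob_marginals.csv"),
    sex = read_marg("dmd_sex_marginals.csv")
  )
}

#' Synthetic per-study assessments matching the DMD marginals
#'
#' Reconstructs, via [assessments_from_marginals()], a 35-study assessment
#' list (32 mdx mouse, 3 GRMD dog) whose per-model counts match the
#' published aggregated percentages: each count is recovered as
#' `round(pct * N / 100)`. The individual rows are synthetic — only the
#' group marginals are faithful — but aggregating them with
#' [aggregate_reporting()] / [aggregate_rob()] reproduces the published
#' per-model cells and yields the pooled column over all 35 studies.
#'
#' @return List of 35 [study_assessment()] records.
#' @examples
#' tab <- aggregate_reporting(dmd_assessments())
#' tab$pooled[tab$parameter == "any_blinding"] # 42.9
#' @export
dmd_assessments <- function() {
  m <- dmd_quality_marginals()
  out <- list()
  for (i in seq_len(nrow(m$sizes))) {
    model <- m$sizes$model[i]
    out <- c(out, assessments_from_marginals(
      model_name = model,
      n = m$sizes$n_studies[i],
      reporting_pct = stats::setNames(m$reporting[[model]],
                                      m$reporting$parameter),
      rob_low_pct = stats::setNames(m$rob[[paste0(model, "_low")]],
                                    m$rob$parameter),
      rob_unclear_pct = stats::setNames(m$rob[[paste0(model, "_unclear")]],
                                        m$rob$parameter),
      sex_pct = stats::setNames(m$sex[[model]], m$sex$category)
    ))
  }
  out
}
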