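# Radar plots and validation-sheet reports.

#' Radar series from score breakdowns
#'
#' One series per model: the per-domain score ratios in registry order
#' (Epidemiological first, then clockwise). Fully excluded domains carry no
#' ratio and are listed as gaps; radar renderers draw them as missing axes
#' rather than zeros, so "excluded" is never confused with "fails to mimic".
#'
#' @param breakdowns a `fimd_scores` object or list of them, all computed
#'   against the same questionnaire version.
#' @return List of `fimd_radar_series`: each a list with `label`, `values`
#'   (named ratios over non-gap domains), `gaps` (domain ids with no ratio)
#'   and `domain_names`.
#' @export
radar_series <- function(breakdowns) {
  if (inherits(breakdowns, "fimd_scores")) breakdowns <- list(breakdowns)
  versions <- unique(vapply(breakdowns, `[[`, character(1),
                            "questionnaire_version"))
  if (length(versions) > 1) {
    stop("breakdowns span questionnaire versions: ",
         paste(versions, collapse = ", "), call. = FALSE)
  }
  lapply(breakdowns, function(s) {
    pd <- s$per_domain
    gaps <- pd$domain_id[is.na(pd$ratio)]
    values <- pd$ratio[!is.na(pd$ratio)]
    names(values) <- pd$domain_id[!is.na(pd$ratio)]
    structure(
      list(label = s$model_name, values = values, gaps = gaps,
           domain_names = stats::setNames(pd$name, pd$domain_id)),
      class = "fimd_radar_series"
    )
  })
}

radar_palette <- c("#1b6ca8", "#c0392b", "#1e8449", "#7d3c98",
                   "#b7950b", "#2c3e50")

# Axis geometry: domain i of k sits at angle pi/2 - 2*pi*(i-1)/k
# (first domain at the top, then clockwise). SVG y grows downward.
radar_xy <- function(i, k, r, cx, cy) {
  a <- pi / 2 - 2 * pi * (i - 1) / k
  c(x = cx + r * cos(a), y = cy - r * sin(a))
}

fmt_xy <- function(p) sprintf("%.2f,%.2f", p[1], p[2])

#' Write a radar plot as a standalone SVG
#'
#' Emits the SVG document directly as text, so identical inputs always
#' produce byte-identical files regardless of the graphics devices compiled
#' into the R build. Axes follow registry order clockwise from the top;
#' not-applicable domains interrupt the series outline and get no axis.
#'
#' @param series list of series from [radar_series()] (or a
#'   `fimd_scores`/list of them, converted automatically).
#' @param path output `.svg` path.
#' @param size canvas size in pixels.
#' @return `path`, invisibly.
#' @export
radar_svg <- function(series, path, size = 520) {
  if (!is.list(series) || !all(vapply(series, inherits, logical(1),
                                      "fimd_radar_series"))) {
    series <- radar_series(series)
  }
  k <- length(series[[1]]$domain_names)
  cx <- size / 2
  cy <- size / 2
  r <- size * 0.33
  out <- c(
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%d" ',
                   'height="%d" viewBox="0 0 %d %d">'), size, size, size, size),
    sprintf('<rect width="%d" height="%d" fill="white"/>', size, size)
  )
  # grid rings
  for (f in c(0.25, 0.5, 0.75, 1)) {
    pts <- vapply(seq_len(k), function(i) fmt_xy(radar_xy(i, k, r * f, cx, cy)),
                  character(1))
    out <- c(out, sprintf(
      '<polygon points="%s" fill="none" stroke="#cccccc" stroke-width="1"/>',
      paste(pts, collapse = " ")))
  }
  all_gaps <- unique(unlist(lapply(series, `[[`, "gaps")))
  dom_ids <- as.integer(names(series[[1]]$domain_names))
  for (i in seq_len(k)) {
    if (dom_ids[i] %in% all_gaps) next # excluded domain: no axis
    p <- radar_xy(i, k, r, cx, cy)
    out <- c(out, sprintf(
      '<line x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f" stroke="#999999" stroke-width="1"/>',
      cx, cy, p[1], p[2]))
    lp <- radar_xy(i, k, r + 16, cx, cy)
    anchor <- if (abs(lp[1] - cx) < 1) "middle" else if (lp[1] > cx) "start" else "end"
    out <- c(out, sprintf(
      '<text x="%.2f" y="%.2f" font-family="sans-serif" font-size="12" text-anchor="%s">%s</text>',
      lp[1], lp[2] + 4, anchor,
      xml_escape(series[[1]]$domain_names[i])))
  }
  for (si in seq_along(series)) {
    s <- series[[si]]
    col <- radar_palette[(si - 1) %% length(radar_palette) + 1]
    present <- dom_ids %in% as.integer(names(s$values)) &
      !(dom_ids %in% all_gaps)
    # split the outline at gaps (cyclically) into contiguous runs
    runs <- split_runs(which(present), k)
    for (run in runs) {
      pts <- vapply(run, function(i) {
        v <- s$values[[as.character(dom_ids[i])]]
        fmt_xy(radar_xy(i, k, r * v, cx, cy))
      }, character(1))
      if (length(run) == k) {
        out <- c(out, sprintf(
          '<polygon points="%s" fill="%s" fill-opacity="0.15" stroke="%s" stroke-width="2"/>',
          paste(pts, collapse = " "), col, col))
      } else if (length(run) > 1) {
        out <- c(out, sprintf(
          '<polyline points="%s" fill="none" stroke="%s" stroke-width="2"/>',
          paste(pts, collapse = " "), col))
      }
      for (pt in pts) {
        xy <- as.numeric(strsplit(pt, ",")[[1]])
        out <- c(out, sprintf(
          '<circle cx="%.2f" cy="%.2f" r="3" fill="%s"/>', xy[1], xy[2], col))
      }
    }
    out <- c(out, sprintf(
      '<rect x="%d" y="%d" width="12" height="12" fill="%s"/>',
      16, 16 + 20 * (si - 1), col))
    out <- c(out, sprintf(
      '<text x="%d" y="%d" font-family="sans-serif" font-size="12">%s</text>',
      34, 26 + 20 * (si - 1), xml_escape(s$label)))
  }
  out <- c(out, "</svg>")
  writeLines(out, path)
  invisible(path)
}

# contiguous runs of axis indices, joined across the 1/k boundary
split_runs <- function(idx, k) {
  if (length(idx) == 0) return(list())
  breaks <- which(diff(idx) > 1)
  runs <- unname(split(idx, cumsum(c(0, diff(idx) > 1))))
  if (length(runs) > 1 && idx[1] == 1 && idx[length(idx)] == k &&
      length(idx) < k) {
    runs[[1]] <- c(runs[[length(runs)]], runs[[1]])
    runs <- runs[-length(runs)]
  }
  runs
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Radar plot as a ggplot object
#'
#' A polar-coordinate view of the per-domain ratios for interactive use;
#' [radar_svg()] is the deterministic file renderer used by reports and the
#' command line.
#'
#' @param breakdowns a `fimd_scores` or list of them.
#' @return A ggplot object.
#' @export
plot_radar <- function(breakdowns) {
  series <- radar_series(breakdowns)
  dfs <- lapply(series, function(s) {
    tibble::tibble(
      model = s$label,
      domain = factor(unname(s$domain_names),
                      levels = unname(s$domain_names)),
      ratio = as.numeric(s$values[names(s$domain_names)])
    )
  })
  df <- do.call(rbind, dfs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$domain, y = .data$ratio,
                                   group = .data$model,
                                   colour = .data$model)) +
    ggplot2::geom_polygon(fill = NA, linewidth = 0.8) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::coord_polar() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "domain score ratio", colour = NULL) +
    ggplot2::theme_minimal()
}

# Report ----------------------------------------------------------------

md_table <- function(df) {
  cells <- vapply(df, function(col) {
    if (is.numeric(col)) ifelse(is.na(col), "-", sprintf("%.1f", col))
    else ifelse(is.na(col), "-", as.character(col))
  }, FUN.VALUE = character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  c(paste0("| ", paste(names(df), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
    apply(cells, 1, function(row) paste0("| ", paste(row, collapse = " | "),
                                         " |")))
}

#' Render a validation-sheet report as Markdown
#'
#' Produces the full human-readable report of a scored sheet: the header
#' (model, indication, equivalent score, uncertainty factor, similarity
#' factor when a comparison is supplied, validation date and level), the
#' historical background, every answer with its score and rationale, the
#' exclusions with their justifications, quality tables when study
#' assessments are supplied, and a reference to the radar image. Every
#' number is taken verbatim from the score breakdown — the renderer never
#' re-rounds.
#'
#' @param sheet the `fimd_sheet` the breakdown was computed from.
#' @param breakdown matching `fimd_scores` from [score_sheet()].
#' @param comparison optional `fimd_comparison` involving this model.
#' @param assessments optional list of [study_assessment()] records.
#' @param radar path to a radar image to reference, or `NULL`.
#' @param path optional output file; the Markdown lines are also returned.
#' @return Character vector of Markdown lines, invisibly when `path` given.
#' @export
render_report <- function(sheet, breakdown, comparison = NULL,
                          assessments = NULL, radar = NULL, path = NULL) {
  if (!identical(sheet$model_name, breakdown$model_name)) {
    stop("breakdown was not computed from this sheet (model name differs)",
         call. = FALSE)
  }
  vdate <- tryCatch(as.character(validation_date(sheet)),
                    error = function(e) "not available")
  lines <- c(
    paste0("# Validation sheet: ", sheet$model_name),
    "",
    paste0("- Species: ", if (nzchar(sheet$species)) sheet$species else "-"),
    paste0("- Indication: ",
           if (nzchar(sheet$indication)) sheet$indication else "-"),
    paste0("- Questionnaire version: ", sheet$questionnaire_version),
    paste0("- Equivalent score: ", sprintf("%.2f", breakdown$equivalent_score)),
    paste0("- Uncertainty factor: ",
           sprintf("%.1f%%", breakdown$uncertainty_pct),
           " (", breakdown$item_mode, " items)"),
    if (!is.null(comparison)) {
      other <- setdiff(c(comparison$model_a, comparison$model_b),
                       sheet$model_name)
      paste0("- Similarity factor vs ", other[1], ": ",
             sprintf("%.1f%%", comparison$similarity_pct))
    },
    paste0("- Definite answers: ", sprintf("%.1f%%", breakdown$definite_pct)),
    paste0("- Validation level: ", breakdown$level),
    paste0("- Validation date: ", vdate),
    ""
  )
  if (!is.null(radar)) {
    lines <- c(lines, paste0("![Domain radar](", radar, ")"), "")
  }
  lines <- c(lines, "## Domain scores", "",
             md_table(data.frame(
               domain = breakdown$per_domain$name,
               score = sprintf("%s / %s",
                               format(breakdown$per_domain$raw),
                               format(breakdown$per_domain$available)),
               ratio = ifelse(is.na(breakdown$per_domain$ratio), "-",
                              sprintf("%.3f", breakdown$per_domain$ratio)),
               check.names = FALSE)),
             "")
  if (nzchar(sheet$historical_background)) {
    lines <- c(lines, "## Historical background", "",
               sheet$historical_background, "")
  }
  pq <- breakdown$per_question
  lines <- c(lines, "## Answers", "",
             md_table(data.frame(
               question = pq$question_id,
               answer = pq$answer,
               score = format(pq$score),
               rationale = vapply(pq$question_id, function(id)
                 sheet$answers[[id]]$rationale, character(1)),
               check.names = FALSE)),
             "")
  if (length(sheet$exclusions) > 0) {
    lines <- c(lines, "## Excluded questions", "",
               md_table(data.frame(
                 question = exclusion_ids(sheet$exclusions),
                 justification = vapply(sheet$exclusions, `[[`,
                                        character(1), "justification"),
                 check.names = FALSE)),
               "")
  }
  if (!is.null(assessments) && length(assessments) > 0) {
    rep_tab <- aggregate_reporting(assessments)
    rob_tab <- aggregate_rob(assessments)
    lines <- c(lines,
               "## Reporting quality (% of eligible studies complying)", "",
               md_table(as.data.frame(rep_tab)[, -1]), "",
               "## Risk of bias (% low / % unclear)", "",
               md_table(as.data.frame(rob_tab)[, -1]), "")
  }
  if (length(sheet$drug_records) > 0) {
    lines <- c(lines, "## Drug evidence", "",
               md_table(as.data.frame(drug_concordance(sheet))), "")
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
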