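## Group-level statistics: Mann-Whitney comparisons of per-cell metrics,
## one-way ANOVA across rotational-velocity subgroups, and an end-to-end
## report assembling the pipeline outputs. The unit of analysis is the cell,
## matching how the source summaries are reported; animal-level nesting is
## carried as metadata but not modeled.

#' Two-group comparison of a per-cell metric
#'
#' Two-sided Mann-Whitney test (exact where sample sizes permit and no ties)
#' with group means and SEMs.
#'
#' @param values numeric metric values, one per cell.
#' @param labels group label per value (two levels, >= 2 values each).
#' @param metric name of the metric, carried into the summary.
#' @return list with \code{summary} (data.frame: group, n, mean, sem),
#'   \code{test = "mann-whitney"} and \code{p}.
#' @export
compareGroups <- function(values, labels, metric = "metric") {
  lev <- unique(labels)
  if (length(lev) != 2) stop("exactly two groups required")
  v1 <- values[labels == lev[1]]; v2 <- values[labels == lev[2]]
  if (length(v1) < 2 || length(v2) < 2)
    stop("each group needs at least 2 values")
  p <- suppressWarnings(stats::wilcox.test(v1, v2)$p.value)
  list(metric = metric,
       summary = data.frame(group = lev, n = c(length(v1), length(v2)),
                            mean = c(mean(v1), mean(v2)),
                            sem = c(sem(v1), sem(v2))),
       test = "mann-whitney", p = p)
}

#' One-way ANOVA across rotational-velocity subgroups
#'
#' Ordinary one-way ANOVA of a per-cell metric across the control and
#' injury-severity subgroups (e.g. control / ~190 rad/s / ~260 rad/s).
#'
#' @param values numeric metric values.
#' @param subgroups subgroup label per value (>= 3 levels, >= 2 values each).
#' @param metric name of the metric.
#' @return list with \code{summary} (group, n, mean, sem), \code{F},
#'   \code{p} (NA with a flag if the metric is constant) and
#'   \code{degenerate}.
#' @export
velocityAnova <- function(values, subgroups, metric = "metric") {
  lev <- unique(subgroups)
  if (length(lev) < 3) stop("at least 3 subgroups required")
  ns <- table(subgroups)
  if (any(ns < 2)) stop("every subgroup needs at least 2 values")
  summ <- data.frame(
    group = lev, n = as.integer(ns[lev]),
    mean = vapply(lev, function(g) mean(values[subgroups == g]), numeric(1)),
    sem = vapply(lev, function(g) sem(values[subgroups == g]), numeric(1)))
  if (stats::var(values) == 0) {
    warning("metric is constant across all subgroups: F undefined")
    return(list(metric = metric, summary = summ, F = NA_real_,
                p = NA_real_, degenerate = TRUE))
  }
  fit <- stats::aov(values ~ factor(subgroups))
  tab <- summary(fit)[[1]]
  list(metric = metric, summary = summ, F = tab$`F value`[1],
       p = tab$`Pr(>F)`[1], degenerate = FALSE)
}

#' Assemble the end-to-end pipeline report
#'
#' Collects the outputs of the pipeline stages into one document: per-group
#' unit summaries, classification agreement, entrainment and PSD significant
#' ranges, event logs and the model scan. Missing stages are reported as
#' explicit gaps rather than silently dropped.
#'
#' @param stages named list with any of \code{unitSummaries},
#'   \code{classification}, \code{entrainment}, \code{psd}, \code{events},
#'   \code{modelScan}.
#' @param provenance optional list (seeds, config hash, versions) copied
#'   into the report.
#' @return list with the six sections, a \code{gaps} character vector and
#'   \code{complete} flag. Deterministic given deterministic stage outputs
#'   (no timestamps).
#' @export
buildReport <- function(stages, provenance = list()) {
  sections <- c("unitSummaries", "classification", "entrainment", "psd",
                "events", "modelScan")
  report <- stats::setNames(vector("list", length(sections)), sections)
  gaps <- character(0)
  for (s in sections) {
    if (is.null(stages[[s]])) gaps <- c(gaps, s)
    else report[[s]] <- stages[[s]]
  }
  if (length(gaps))
    warning("report has gaps: ", paste(gaps, collapse = ", "))
  c(report, list(gaps = gaps, complete = length(gaps) == 0,
                 provenance = provenance))
}

#' Write a report to JSON and a human-readable summary
#'
#' @param report list from \code{\link{buildReport}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeReport <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonPath <- file.path(dir, "report.json")
  jsonlite::write_json(report, jsonPath, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  mdPath <- file.path(dir, "report.md")
  lines <- c("# Pipeline report", "")
  for (s in setdiff(names(report), c("gaps", "complete", "provenance"))) {
    lines <- c(lines, paste("##", s),
               if (is.null(report[[s]])) "(missing)" else
                 utils::capture.output(utils::str(report[[s]], max.level = 2)),
               "")
  }
  if (length(report$gaps))
    lines <- c(lines, paste("MISSING STAGES:",
                            paste(report$gaps, collapse = ", ")))
  writeLines(lines, mdPath)
  invisible(c(jsonPath, mdPath))
}
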