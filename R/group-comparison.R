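#' Percent reduction of a comparison mean relative to a reference mean
#'
#' `100 * (reference - comparison) / reference`, the form used to report
#' how much lower a group mean is than a reference group mean.
#'
#' @param reference reference mean (must be positive).
#' @param comparison comparison mean.
#' @param digits decimals to round to; the conventional report precision
#'   is one decimal. Use `NULL` for full precision.
#' @return percent reduction (positive when `comparison < reference`).
#' @examples
#' percent_reduction(2365.1, 1750.2)  # 26.0
#' @export
percent_reduction <- function(reference, comparison, digits = 1) {
  stop_if(!is.numeric(reference) || !is.numeric(comparison),
          "means must be numeric")
  stop_if(any(reference <= 0), "reference mean must be positive")
  out <- 100 * (reference - comparison) / reference
  if (!is.null(digits)) out <- round_half_up(out, digits)
  out
}

#' Group summary tables with paired Wilcoxon comparisons
#'
#' Aggregates per-plan metric values from a paired cohort (each patient
#' contributing exactly one plan per group) into the standard report
#' layout: mean and standard deviation (n-1 denominator) per group, and
#' two-sided paired Wilcoxon signed-rank p-values for each group pair,
#' with significance flagged at `p < alpha`. Optionally applies a
#' Holm correction across the group pairs of each metric (off by default:
#' the conventional report tests each pair at alpha).
#'
#' @param data data.frame with columns `patient_id`, `group`, and one
#'   numeric column per metric.
#' @param metrics character vector of metric column names; default all
#'   numeric columns besides the id/group columns.
#' @param groups group labels in display order (default `c("A","B","C")`).
#' @param alpha significance level (default 0.05).
#' @param holm apply a Holm correction across group pairs per metric.
#' @return an object of class `group_comparison`: list with `summary`
#'   (data.frame: metric, mean/sd per group, p per group pair,
#'   significance flags), `values` (per-patient wide tables by metric),
#'   `groups`, `alpha`, `n`.
#' @export
summarize_and_compare <- function(data, metrics = NULL,
                                  groups = c("A", "B", "C"),
                                  alpha = 0.05, holm = FALSE) {
  stop_if(!is.data.frame(data), "data must be a data.frame")
  stop_if(!all(c("patient_id", "group") %in% names(data)),
          "data must have patient_id and group columns")
  stop_if(!all(data$group %in% groups),
          "data contains group labels outside ", paste(groups, collapse = "/"))
  if (is.null(metrics)) {
    metrics <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                       c("patient_id", "group"))
  }
  stop_if(length(metrics) == 0, "no metric columns found")
  patients <- unique(data$patient_id)
  for (p in patients) {
    for (g in groups) {
      k <- sum(data$patient_id == p & data$group == g)
      stop_if(k != 1L, sprintf(
        "patient %s has %d plans in group %s (need exactly 1)", p, k, g))
    }
  }
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  pair_names <- vapply(pairs, paste, character(1), collapse = "-")

  values <- list()
  rows <- list()
  for (m in metrics) {
    wide <- sapply(groups, function(g) {
      sub <- data[data$group == g, ]
      sub[[m]][match(patients, sub$patient_id)]
    })
    wide <- matrix(wide, ncol = length(groups),
                   dimnames = list(as.character(patients), groups))
    values[[m]] <- wide
    p_vals <- vapply(pairs, function(pr)
      wilcoxon_signed_rank(wide[, pr[1]], wide[, pr[2]])$p_value, numeric(1))
    row <- data.frame(metric = m)
    for (g in groups) {
      row[[paste0("mean_", g)]] <- mean(wide[, g])
      row[[paste0("sd_", g)]] <- stats::sd(wide[, g])
    }
    padj <- if (holm) stats::p.adjust(p_vals, "holm") else p_vals
    for (i in seq_along(pairs)) {
      row[[paste0("p_", pair_names[i])]] <- padj[i]
    }
    for (i in seq_along(pairs)) {
      row[[paste0("sig_", pair_names[i])]] <- padj[i] < alpha
    }
    rows[[m]] <- row
  }
  structure(
    list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         values = values, groups = groups, alpha = alpha,
         n = length(patients), holm = holm),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("<group_comparison> %d paired patients, groups %s%s\n",
              x$n, paste(x$groups, collapse = "/"),
              if (x$holm) " (Holm-corrected)" else ""))
  s <- x$summary
  disp <- data.frame(metric = s$metric)
  for (g in x$groups) {
    disp[[g]] <- sprintf("%.*g ± %.*g", digits, s[[paste0("mean_", g)]],
                         digits, s[[paste0("sd_", g)]])
  }
  for (nm in grep("^p_", names(s), value = TRUE)) {
    disp[[sub("p_", "p ", nm)]] <- sprintf(
      "%.3f%s", s[[nm]], ifelse(s[[sub("p_", "sig_", nm)]], "*", ""))
  }
  print(disp, row.names = FALSE)
  cat(sprintf("* p < %g\n", x$alpha))
  invisible(x)
}

#' Percent reductions of one group's means relative to reference groups
#'
#' For each metric in a [summarize_and_compare()] result, the percent by
#' which the comparison group's mean is lower than each reference group's
#' mean, at one-decimal report precision.
#'
#' @param comparison_result a `group_comparison` object.
#' @param comparison the group whose means are compared (default `"C"`).
#' @param references the reference groups (default the others).
#' @param digits decimals (default 1); `NULL` for full precision.
#' @return data.frame with `metric` and one `vs_<group>` column per
#'   reference.
#' @export
reduction_table <- function(comparison_result, comparison = "C",
                            references = NULL, digits = 1) {
  stopifnot(inherits(comparison_result, "group_comparison"))
  s <- comparison_result$summary
  references <- references %||% setdiff(comparison_result$groups, comparison)
  out <- data.frame(metric = s$metric)
  for (g in references) {
    out[[paste0("vs_", g)]] <- percent_reduction(
      s[[paste0("mean_", g)]], s[[paste0("mean_", comparison)]],
      digits = digits)
  }
  out
}

#' Published reference group means for the dual-arc head-and-neck cohort
#'
#' The printed group means and standard deviations (10 paired
#' head-and-neck patients, arc-increment groups A = 30/30, B = 15/15,
#' C = 30/15) for the dose-volumetric parameters (doses in cGy) and plan
#' complexity metrics, shipped as package data. These are reference
#' values for worked examples and cross-checks; the package does not need
#' them to analyze a cohort.
#'
#' @param table `"dose"` (PTV/OAR dose-volumetric rows) or `"complexity"`
#'   (MCSv, MU, PA, PI, PM rows).
#' @return data.frame with columns `structure` (dose table only),
#'   `metric`, `mean_A`, `sd_A`, `mean_B`, `sd_B`, `mean_C`, `sd_C`,
#'   `p_A-B`, `p_A-C`, `p_B-C`.
#' @export
reference_group_means <- function(table = c("dose", "complexity")) {
  table <- match.arg(table)
  f <- system.file("extdata",
                   sprintf("reference_group_means_%s.csv", table),
                   package = "vmatmetrics", mustWork = TRUE)
  utils::read.csv(f, check.names = FALSE)
}
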