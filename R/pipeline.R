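# Round half away from zero (integer percentage tables; base round()
# would round half to even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Cohort summary from per-cell counts
#'
#' Builds the bookkeeping table of visually responsive units: one row per
#' (treatment, hemisphere) cell, one pooled row per treatment, and a grand
#' total. Percentages are always recomputed from the counts
#' (`round_half_away(100 * count / total)`) and are `NA` for rows with no
#' responsive units.
#'
#' @param counts Data frame with columns `treatment`, `hemisphere`,
#'   `n_bilateral`, `n_contralateral` (one row per cell).
#' @return Data frame of class `cohort_summary` with columns `treatment`,
#'   `hemisphere` (including `"both"` pooled rows and an `"all"` total),
#'   `n_visually_responsive`, `n_bilateral`, `n_contralateral`,
#'   `pct_bilateral`, `pct_contralateral`.
#' @export
cohort_summary <- function(counts) {
  need <- c("treatment", "hemisphere", "n_bilateral", "n_contralateral")
  stopifnot(all(need %in% names(counts)))
  counts <- counts[order(match(counts$treatment, c("dark", "light")),
                         match(counts$hemisphere, c("left", "right"))), ]
  rows <- list()
  add <- function(treatment, hemisphere, nb, nc) {
    n <- nb + nc
    data.frame(treatment = treatment, hemisphere = hemisphere,
               n_visually_responsive = n, n_bilateral = nb,
               n_contralateral = nc,
               pct_bilateral = if (n > 0) round_half_away(100 * nb / n)
                               else NA_real_,
               pct_contralateral = if (n > 0) round_half_away(100 * nc / n)
                                   else NA_real_,
               stringsAsFactors = FALSE)
  }
  for (tr in unique(counts$treatment)) {
    sub <- counts[counts$treatment == tr, ]
    for (i in seq_len(nrow(sub))) {
      rows[[length(rows) + 1L]] <- add(tr, sub$hemisphere[i],
                                       sub$n_bilateral[i],
                                       sub$n_contralateral[i])
    }
    rows[[length(rows) + 1L]] <- add(tr, "both", sum(sub$n_bilateral),
                                     sum(sub$n_contralateral))
  }
  rows[[length(rows) + 1L]] <- add("all", "both", sum(counts$n_bilateral),
                                   sum(counts$n_contralateral))
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' Cohort summary from unit classifications
#'
#' Counts bilateral and contralateral units among the visually responsive
#' ones in each (treatment, hemisphere) cell and delegates to
#' [cohort_summary()].
#'
#' @param classifications A [classify_cohort()] table.
#' @param metas Unit metadata (the `units` slot of the dataset).
#' @return A [cohort_summary()] data frame.
#' @export
summarize_cohort <- function(classifications, metas) {
  d <- merge(classifications, metas, by = "unit_id")
  cells <- expand.grid(treatment = c("dark", "light"),
                       hemisphere = c("left", "right"),
                       stringsAsFactors = FALSE)
  cells$n_bilateral <- NA_integer_
  cells$n_contralateral <- NA_integer_
  for (i in seq_len(nrow(cells))) {
    sub <- d[d$treatment == cells$treatment[i] &
               d$hemisphere == cells$hemisphere[i], ]
    cells$n_bilateral[i] <- sum(sub$response_class == "bilateral")
    cells$n_contralateral[i] <- sum(sub$response_class == "contralateral")
  }
  cohort_summary(cells)
}

#' Compare the cohort's bilateral proportion with a reference population
#'
#' Pooled two-proportion z test of the observed share of bilateral units
#' against a reference count (e.g. from another brain area). Operand order
#' is reference minus observed, so an observed share larger than the
#' reference yields a negative z.
#'
#' @param summary A [cohort_summary()], or a list/row with `n_bilateral`
#'   and `n_visually_responsive` totals.
#' @param reference_successes,reference_total Reference bilateral count and
#'   total responsive count.
#' @return List with `z`, `p_two_sided`, `prop_observed`, `prop_reference`.
#' @export
compare_bilateral_proportion <- function(summary, reference_successes,
                                         reference_total) {
  if (inherits(summary, "cohort_summary")) {
    tot <- summary[summary$treatment == "all", ]
    obs_x <- tot$n_bilateral
    obs_n <- tot$n_visually_responsive
  } else {
    obs_x <- summary$n_bilateral
    obs_n <- summary$n_visually_responsive
  }
  stopifnot(obs_n > 0, reference_total > 0)
  test <- two_proportion_z(reference_successes, reference_total, obs_x, obs_n)
  list(z = test$z, p_two_sided = test$p_two_sided,
       prop_observed = obs_x / obs_n,
       prop_reference = reference_successes / reference_total)
}

# The dependent variables analysed per population. The bilateral population
# is analysed across all three stimulation conditions; the contralateral
# population only for the contralateral condition. Spontaneous rate is
# condition-averaged by construction.
.dependent_variables <- function(conditions) {
  vars <- data.frame(condition = "pre", variable = "spontaneous_rate",
                     column = "spontaneous_rate", stringsAsFactors = FALSE)
  for (cond in conditions) {
    for (v in c("on_peak_sub", "on_latency", "off_peak_sub", "off_latency")) {
      vars <- rbind(vars, data.frame(condition = cond, variable = v,
                                     column = paste(cond, v, sep = "_"),
                                     stringsAsFactors = FALSE))
    }
  }
  vars
}

# SRH + conditional Dunn post-hoc for one dependent variable over the four
# treatment x hemisphere cells.
.analyze_variable <- function(data, column, alpha) {
  ok <- !is.na(data[[column]])
  sub <- data[ok, ]
  cell_n <- table(sub$treatment, sub$hemisphere)
  if (nrow(sub) < 8L || any(dim(cell_n) < 2L) || any(cell_n == 0L)) {
    return(NULL)
  }
  srh <- scheirer_ray_hare(sub[[column]], sub$treatment, sub$hemisphere)
  posthoc <- NULL
  if (!is.na(srh$p[3L]) && srh$p[3L] < alpha) {
    cell <- paste(sub$treatment, sub$hemisphere, sep = "_")
    posthoc <- dunn_posthoc(
      sub[[column]], cell,
      comparisons = rbind(c("dark_left", "dark_right"),
                          c("light_left", "light_right"),
                          c("dark_left", "light_left"),
                          c("dark_right", "light_right")))
  }
  list(srh = srh, posthoc = posthoc, n = nrow(sub))
}

#' Run the full analysis pipeline
#'
#' Features -> classification -> cohort summary -> factorial statistics.
#' Bilaterally and contralaterally responsive populations are analysed
#' separately: for each dependent variable (spontaneous rate; baseline-
#' subtracted ON/OFF peak rates; ON/OFF peak latencies, per stimulation
#' condition) a Scheirer-Ray-Hare test of treatment x hemisphere is run,
#' with Dunn post-hoc comparisons of the four cells when the interaction is
#' significant. Integration counts (excitation/suppression x ON/OFF) are
#' tallied over bilateral units. Undefined latencies are dropped per
#' variable; a variable whose design loses a cell is skipped with a warning.
#'
#' All outputs are deterministic functions of the dataset and thresholds.
#' If `out_dir` is given, the report tables are written as CSV
#' (`features.csv`, `classification.csv`, `summary_table1.csv`,
#' `stats_bilateral.csv`, `stats_contralateral.csv`, `posthoc.csv`,
#' `integration_counts.csv`, `proportion_test.csv` when a reference is
#' supplied) plus a `manifest.json` with thresholds and counts.
#'
#' @param dataset A [spike_dataset()].
#' @param thresholds A [classifier_thresholds()].
#' @param reference_proportion Optional `c(successes, total)` of a reference
#'   population for the bilateral-share comparison.
#' @param out_dir Optional output directory (created if missing).
#' @param verbose Emit one progress message per stage.
#' @return An `analysis_report` list: `features`, `classification`,
#'   `summary`, `stats` (per population: data frame of SRH rows),
#'   `posthoc`, `integration_counts`, `proportion_test`, `counts`.
#' @export
run_analysis <- function(dataset, thresholds = classifier_thresholds(),
                         reference_proportion = NULL, out_dir = NULL,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  n_units <- nrow(dataset$units)
  say("features: extracting from ", n_units, " units")
  features <- extract_features_all(dataset)

  say("classify: screening and typing ", n_units, " units")
  cls <- classify_cohort(dataset, thresholds)
  n_resp <- sum(cls$visually_responsive)
  n_bi <- sum(cls$response_class == "bilateral")
  say("classify: ", n_resp, " responsive (", n_bi, " bilateral, ",
      n_resp - n_bi, " contralateral), ", n_units - n_resp, " excluded")

  summary <- summarize_cohort(cls, dataset$units)

  d <- merge(features, cls, by = "unit_id")
  stats_tabs <- list()
  posthoc_tabs <- list()
  for (pop in c("bilateral", "contralateral")) {
    conds <- if (pop == "bilateral") dataset$protocol$conditions else "contra"
    vars <- .dependent_variables(conds)
    sub <- d[d$response_class == pop, ]
    say("stats: ", pop, " population, n = ", nrow(sub))
    for (i in seq_len(nrow(vars))) {
      res <- tryCatch(
        .analyze_variable(sub, vars$column[i], thresholds$alpha),
        error = function(e) NULL)
      if (is.null(res)) {
        warning("skipping ", pop, " / ", vars$column[i],
                ": incomplete design or too few observations",
                call. = FALSE)
        next
      }
      tab <- res$srh
      tab$population <- pop
      tab$condition <- vars$condition[i]
      tab$variable <- vars$variable[i]
      tab$n <- res$n
      tab$effect <- c("treatment", "hemisphere", "interaction")
      stats_tabs[[length(stats_tabs) + 1L]] <- as.data.frame(tab)
      if (!is.null(res$posthoc)) {
        ph <- res$posthoc
        ph$population <- pop
        ph$condition <- vars$condition[i]
        ph$variable <- vars$variable[i]
        posthoc_tabs[[length(posthoc_tabs) + 1L]] <- ph
      }
    }
  }
  col_order <- c("population", "condition", "variable", "effect", "df",
                 "H", "p", "eta2", "eta2_label", "n")
  stats <- if (length(stats_tabs)) {
    do.call(rbind, stats_tabs)[col_order]
  } else {
    as.data.frame(stats::setNames(
      rep(list(character(0)), length(col_order)), col_order))
  }
  posthoc <- if (length(posthoc_tabs)) do.call(rbind, posthoc_tabs) else NULL

  bi <- cls[cls$response_class == "bilateral", ]
  integration <- data.frame(
    window = c("ON", "ON", "OFF", "OFF"),
    sign = c("excitation", "suppression", "excitation", "suppression"),
    n_units = c(sum(bi$integration_on == "excitation"),
                sum(bi$integration_on == "suppression"),
                sum(bi$integration_off == "excitation"),
                sum(bi$integration_off == "suppression")),
    stringsAsFactors = FALSE)

  prop_test <- NULL
  if (!is.null(reference_proportion) && n_resp > 0) {
    prop_test <- compare_bilateral_proportion(summary,
                                              reference_proportion[1L],
                                              reference_proportion[2L])
  }

  report <- structure(
    list(features = features, classification = cls, summary = summary,
         stats = stats, posthoc = posthoc,
         integration_counts = integration, proportion_test = prop_test,
         counts = list(total = n_units, responsive = n_resp,
                       bilateral = n_bi, contralateral = n_resp - n_bi),
         thresholds = thresholds),
    class = "analysis_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  cat(sprintf("  %d units: %d responsive (%d bilateral / %d contralateral)\n",
              x$counts$total, x$counts$responsive, x$counts$bilateral,
              x$counts$contralateral))
  cat(sprintf("  %d factorial tests, %d post-hoc tables\n",
              nrow(x$stats) %/% 3L,
              if (is.null(x$posthoc)) 0L else
                nrow(x$posthoc) %/% 4L))
  invisible(x)
}

#' Write an analysis report's tables to a directory
#'
#' @param report An [run_analysis()] result.
#' @param out_dir Output directory; created if missing.
#' @return Invisibly, `out_dir`.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(obj, name) {
    if (!is.null(obj)) {
      utils::write.csv(obj, file.path(out_dir, name), row.names = FALSE,
                       quote = FALSE)
    }
  }
  w(report$features, "features.csv")
  w(report$classification, "classification.csv")
  w(as.data.frame(report$summary), "summary_table1.csv")
  w(report$stats[report$stats$population == "bilateral", ],
    "stats_bilateral.csv")
  w(report$stats[report$stats$population == "contralateral", ],
    "stats_contralateral.csv")
  w(report$posthoc, "posthoc.csv")
  w(report$integration_counts, "integration_counts.csv")
  if (!is.null(report$proportion_test)) {
    w(as.data.frame(report$proportion_test), "proportion_test.csv")
  }
  manifest <- list(package_version =
                     as.character(utils::packageVersion("entolat")),
                   thresholds = unclass(report$thresholds),
                   counts = report$counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
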