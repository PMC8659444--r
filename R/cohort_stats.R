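#' Reference cohort of per-patient SVM performance metrics
#'
#' Ships with the package: the published per-patient test results of the
#' permutation-entropy channel-selection pipeline on 22 patients of the
#' CHB-MIT scalp EEG database — prediction rate, accuracy, sensitivity and
#' specificity, each as a (selected channels, all channels) pair in percent,
#' plus the selected channel indices and the adopted SVM optimizer. Two of
#' the database's 24 patients are absent (their recordings change montage
#' mid-session, so train/test sets cannot be matched). One patient's selected
#' set includes a referential channel ("CP2-Ref") outside the 23-channel
#' bipolar montage; it is carried verbatim and excluded from 1..23 channel
#' counts.
#'
#' @param path CSV path; defaults to the shipped fixture.
#' @return A data.frame of 22 rows with class `cohort_table`; `channels_sel`
#'   is a list-column of character vectors.
#' @export
cohort_performance <- function(path = system.file("extdata",
                                                  "cohort_performance.csv",
                                                  package = "peselect")) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "pred_sel", "pred_all", "acc_sel", "acc_all",
            "sens_sel", "sens_all", "spec_sel", "spec_all", "channels_sel")
  missing <- setdiff(need, names(tbl))
  if (length(missing))
    stop("cohort table lacks columns: ", paste(missing, collapse = ", "))
  tbl$channels_sel <- strsplit(as.character(tbl$channels_sel), ";",
                               fixed = TRUE)
  class(tbl) <- c("cohort_table", "data.frame")
  tbl
}

#' Summary statistics of a metric column
#'
#' Sample statistics as reported in cohort summary tables: `n`, the raw sum,
#' the arithmetic mean, and the sample standard deviation (n - 1 denominator).
#'
#' @param values Numeric vector of percentages (length >= 2).
#' @return List with `n`, `sum`, `mean`, `sd`.
#' @export
summarize_metric <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L || anyNA(values))
    stop("need at least two non-missing values")
  list(n = length(values), sum = sum(values), mean = mean(values),
       sd = stats::sd(values))
}

#' Relative improvement of one mean over a baseline mean
#'
#' `100 * (mean_selected - mean_all) / mean_all`, in percent of the baseline.
#'
#' @param mean_selected,mean_all Means in percent; `mean_all` must be > 0.
#' @return Relative improvement in percent.
#' @export
relative_improvement <- function(mean_selected, mean_all) {
  assert_scalar_num(mean_selected, "mean_selected")
  assert_scalar_num(mean_all, "mean_all", min = 1e-12)
  100 * (mean_selected - mean_all) / mean_all
}

#' Two-condition repeated-measures ANOVA on paired patient metrics
#'
#' One-way ANOVA with patient as the blocking (subject) factor and condition
#' (selected vs all channels) as the within-subject factor. With two
#' conditions its F statistic on (1, n - 1) degrees of freedom equals the
#' squared paired t statistic exactly.
#'
#' @param selected,all_channels Paired numeric vectors (same patients, same
#'   order), length >= 3, no missing values.
#' @return List with `F`, `p`, `df` (c(1, n - 1)).
#' @export
rm_anova_paired <- function(selected, all_channels) {
  if (length(selected) != length(all_channels))
    stop("paired vectors differ in length")
  if (length(selected) < 3L) stop("need at least 3 pairs")
  if (anyNA(selected) || anyNA(all_channels)) stop("missing pairs")
  n <- length(selected)
  if (all(selected == all_channels))
    return(list(F = 0, p = 1, df = c(1L, n - 1L)))  # no condition effect at all
  d <- data.frame(value = c(selected, all_channels),
                  cond = factor(rep(c("selected", "all"), each = n)),
                  subject = factor(rep(seq_len(n), 2L)))
  fit <- stats::aov(value ~ cond + Error(subject), data = d)
  tab <- summary(fit)[["Error: Within"]][[1L]]
  Fval <- tab["cond", "F value"]
  list(F = unname(Fval), p = unname(tab["cond", "Pr(>F)"]),
       df = c(1L, n - 1L))
}

#' Selection frequency per montage channel
#'
#' Counts, across patients, how often each channel index 1..`n_channels` was
#' selected. Tokens outside that range (e.g. a referential "CP2-Ref" entry)
#' are excluded from the counts and returned in the `extras` attribute.
#'
#' @param selections List of per-patient selected channel sets (integer
#'   indices, possibly as character tokens).
#' @param n_channels Montage size (default 23).
#' @return Integer vector of length `n_channels` (names = channel index),
#'   with attribute `extras` listing out-of-montage tokens.
#' @export
channel_frequency <- function(selections, n_channels = 23) {
  counts <- integer(n_channels)
  extras <- character(0)
  for (sel in selections) {
    sel <- as.character(sel)
    num <- suppressWarnings(as.integer(sel))
    in_range <- !is.na(num) & num >= 1L & num <= n_channels
    extras <- c(extras, sel[!in_range])
    counts[num[in_range]] <- counts[num[in_range]] + 1L
  }
  structure(stats::setNames(counts, seq_len(n_channels)), extras = extras)
}

#' Cohort summary: means, SDs, paired ANOVA, improvements
#'
#' Recomputes the cohort-level comparison between selected-channel and
#' all-channel testing from a per-patient table: per metric (accuracy,
#' sensitivity, specificity) the n/sum/mean/SD of both conditions and the
#' repeated-measures F and p; the relative improvement of each metric's mean;
#' the mean prediction rates; and the channel-selection frequencies.
#'
#' @param tbl A [cohort_performance()] table.
#' @return A list of class `cohort_summary` with elements `metrics` (named
#'   list per metric), `prediction_rate` (means for both conditions and the
#'   relative improvement), and `channel_counts`.
#' @export
summarize_cohort <- function(tbl = cohort_performance()) {
  metric_cols <- list(accuracy = c("acc_sel", "acc_all"),
                      sensitivity = c("sens_sel", "sens_all"),
                      specificity = c("spec_sel", "spec_all"))
  metrics <- lapply(metric_cols, function(cols) {
    sel <- tbl[[cols[1]]]; all <- tbl[[cols[2]]]
    an <- rm_anova_paired(sel, all)
    list(selected = summarize_metric(sel), all_channels = summarize_metric(all),
         F = an$F, p = an$p,
         improvement = relative_improvement(mean(sel), mean(all)))
  })
  pr <- list(mean_selected = mean(tbl$pred_sel),
             mean_all = mean(tbl$pred_all),
             improvement = relative_improvement(mean(tbl$pred_sel),
                                                mean(tbl$pred_all)))
  structure(list(metrics = metrics, prediction_rate = pr,
                 channel_counts = channel_frequency(tbl$channels_sel)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  for (nm in names(x$metrics)) {
    m <- x$metrics[[nm]]
    cat(sprintf(
      "  %-12s mean %6.2f vs %6.2f (sd %5.2f vs %5.2f)  F = %7.4f, p = %.6f, improvement %5.2f%%\n",
      nm, m$selected$mean, m$all_channels$mean, m$selected$sd,
      m$all_channels$sd, m$F, m$p, m$improvement))
  }
  cat(sprintf("  prediction rate mean %.2f vs %.2f (improvement %.2f%%)\n",
              x$prediction_rate$mean_selected, x$prediction_rate$mean_all,
              x$prediction_rate$improvement))
  top <- sort(x$channel_counts, decreasing = TRUE)[1:4]
  cat(sprintf("  most selected channels: %s\n",
              paste(sprintf("%s (%d)", names(top), top), collapse = ", ")))
  invisible(x)
}
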