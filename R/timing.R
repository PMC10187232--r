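#' Mitotic timing and arrest tabulation
#'
#' Per-cell duration from nuclear envelope breakdown (NEB) to anaphase onset
#' (AO): `(anaphase_frame - neb_frame) * frame_interval_min`. Cells with no
#' AO are classified by how much movie remained after NEB:
#' * at least `arrest_window_min` (default 60 min) of movie remaining and
#'   still no anaphase — "arrested" (never divides);
#' * less than that remaining — "censored": the movie ended too soon to call
#'   the cell either way, so it is excluded from both the duration and the
#'   arrest tallies.
#' Cells with no NEB on camera are dropped.
#'
#' @param events An [event_table()].
#' @param frame_interval_min Minutes per frame (e.g. 3 for imaging every
#'   3 minutes).
#' @param arrest_window_min Minimum on-camera mitotic residence (min) before
#'   a cell that never divides is called arrested.
#' @return A `"TimingResult"`: list with `per_cell` (cell_id, status in
#'   {divided, arrested, censored}, duration_min), `median_duration_min`
#'   (over divided cells), `arrest_fraction_pct` = 100 * arrested /
#'   (divided + arrested), and counts `n_divided`, `n_arrested`,
#'   `n_censored`.
#' @export
mitotic_timing <- function(events, frame_interval_min,
                           arrest_window_min = 60) {
  stopifnot(inherits(events, "EventTable"))
  if (!is.numeric(frame_interval_min) || frame_interval_min <= 0)
    stop("frame_interval_min must be positive", call. = FALSE)
  ev <- events[!is.na(events$neb_frame), , drop = FALSE]
  divided <- !is.na(ev$anaphase_frame)
  duration <- ifelse(divided,
                     (ev$anaphase_frame - ev$neb_frame) * frame_interval_min,
                     NA_real_)
  remaining_min <- (ev$movie_end_frame - ev$neb_frame) * frame_interval_min
  status <- ifelse(divided, "divided",
                   ifelse(remaining_min >= arrest_window_min,
                          "arrested", "censored"))
  per_cell <- data.frame(cell_id = ev$cell_id, status = status,
                         duration_min = duration,
                         stringsAsFactors = FALSE)
  n_div <- sum(status == "divided")
  n_arr <- sum(status == "arrested")
  n_cen <- sum(status == "censored")
  structure(list(
    per_cell = per_cell,
    median_duration_min = if (n_div) stats::median(duration[divided])
                          else NA_real_,
    arrest_fraction_pct = if (n_div + n_arr)
      100 * n_arr / (n_div + n_arr) else NA_real_,
    n_divided = n_div, n_arrested = n_arr, n_censored = n_cen),
    class = "TimingResult")
}

#' @export
print.TimingResult <- function(x, ...) {
  cat("TimingResult: ", x$n_divided, " divided, ", x$n_arrested,
      " arrested, ", x$n_censored, " censored\n", sep = "")
  cat(sprintf("  median NEB->AO duration: %.1f min\n",
              x$median_duration_min))
  cat(sprintf("  arrest fraction: %.1f%%\n", x$arrest_fraction_pct))
  invisible(x)
}

#' Compare a metric across conditions
#'
#' Thin reporting layer over the standard routines: one-way ANOVA with
#' Tukey's honest significant difference for the parametric family, or a
#' Kruskal-Wallis test with Dunn's all-pairs rank comparison (Holm-adjusted
#' by default) for the nonparametric family. Statistics are computed on
#' per-cell values; per-replicate means are reported alongside for
#' superplot-style summaries.
#'
#' @param table A [group_table()].
#' @param metric Metric name to compare.
#' @param family `"parametric"` (ANOVA + Tukey) or `"nonparametric"`
#'   (Kruskal-Wallis + Dunn).
#' @param p_adjust_method Adjustment for Dunn's pairwise p-values (Tukey
#'   carries its own familywise adjustment).
#' @return A `"GroupComparison"`: list with `omnibus` (statistic, df,
#'   p_value, method), `pairwise` (data frame: group1, group2, estimate,
#'   p_adj), `summary` (per-condition n, mean, median, sd) and
#'   `replicate_summary` (per condition x replicate means).
#' @export
compare_groups <- function(table, metric,
                           family = c("parametric", "nonparametric"),
                           p_adjust_method = "holm") {
  family <- match.arg(family)
  validate_group_table(table)
  df <- table[table$metric_name == metric, , drop = FALSE]
  if (!nrow(df)) stop("no rows for metric '", metric, "'", call. = FALSE)
  df$condition_label <- factor(df$condition_label)
  ns <- table(df$condition_label)
  if (length(ns) < 2L)
    stop("need at least 2 conditions to compare", call. = FALSE)
  if (any(ns < 3L))
    stop("each condition needs n >= 3 (got: ",
         paste(names(ns), ns, sep = "=", collapse = ", "), ")",
         call. = FALSE)

  if (family == "parametric") {
    fit <- stats::aov(value ~ condition_label, data = df)
    at <- summary(fit)[[1]]
    tuk <- stats::TukeyHSD(fit)$condition_label
    pairs <- strsplit(rownames(tuk), "-", fixed = TRUE)
    pairwise <- data.frame(
      group1 = vapply(pairs, `[`, "", 1L),
      group2 = vapply(pairs, `[`, "", 2L),
      estimate = unname(tuk[, "diff"]),
      p_adj = unname(tuk[, "p adj"]),
      stringsAsFactors = FALSE)
    omnibus <- list(statistic = at[["F value"]][1],
                    df = c(at[["Df"]][1], at[["Df"]][2]),
                    p_value = at[["Pr(>F)"]][1],
                    method = "one-way ANOVA + Tukey HSD")
  } else {
    kw <- stats::kruskal.test(value ~ condition_label, data = df)
    pairwise <- dunn_test(df$value, df$condition_label,
                          p_adjust_method = p_adjust_method)
    omnibus <- list(statistic = unname(kw$statistic),
                    df = unname(kw$parameter),
                    p_value = kw$p.value,
                    method = paste0("Kruskal-Wallis + Dunn (",
                                    p_adjust_method, ")"))
  }

  agg <- function(f) tapply(df$value, df$condition_label, f)
  summary_df <- data.frame(
    condition_label = names(ns), n = as.integer(ns),
    mean = as.numeric(agg(mean)), median = as.numeric(agg(stats::median)),
    sd = as.numeric(agg(stats::sd)), stringsAsFactors = FALSE)
  rep_means <- stats::aggregate(value ~ condition_label + replicate_id,
                                data = df, FUN = mean)
  names(rep_means)[names(rep_means) == "value"] <- "replicate_mean"
  structure(list(omnibus = omnibus, pairwise = pairwise,
                 summary = summary_df, replicate_summary = rep_means,
                 metric = metric, family = family),
            class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat("GroupComparison of '", x$metric, "' (", x$omnibus$method, ")\n",
      sep = "")
  cat(sprintf("  omnibus: statistic %.4g, p = %.4g\n",
              x$omnibus$statistic, x$omnibus$p_value))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Dunn's all-pairs rank comparison
#'
#' Post-hoc z-tests on mean ranks after a Kruskal-Wallis test, with the
#' standard tie correction, implemented here directly from the rank-sum
#' formulation (no dedicated post-hoc package is required).
#'
#' @param value Numeric response.
#' @param group Factor of group labels.
#' @param p_adjust_method Method for [stats::p.adjust()] (default Holm).
#' @return Data frame: group1, group2, estimate (mean-rank difference), z,
#'   p_adj.
#' @export
dunn_test <- function(value, group, p_adjust_method = "holm") {
  group <- droplevels(as.factor(group))
  n <- length(value)
  r <- rank(value)
  mean_ranks <- tapply(r, group, mean)
  ns <- tapply(r, group, length)
  ties <- table(value)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  lev <- levels(group)
  cmb <- utils::combn(lev, 2)
  z <- estimate <- numeric(ncol(cmb))
  for (k in seq_len(ncol(cmb))) {
    a <- cmb[1, k]; b <- cmb[2, k]
    diff_r <- mean_ranks[[a]] - mean_ranks[[b]]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) *
                 (1 / ns[[a]] + 1 / ns[[b]]))
    estimate[k] <- diff_r
    z[k] <- diff_r / se
  }
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = cmb[1, ], group2 = cmb[2, ], estimate = estimate,
             z = z, p_adj = stats::p.adjust(p, p_adjust_method),
             stringsAsFactors = FALSE)
}
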