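test_that("NEB-to-anaphase durations follow the frame arithmetic", {
  ev <- event_table("c1", 10L, 20L, 200L)
  res <- mitotic_timing(ev, frame_interval_min = 3)
  expect_equal(res$per_cell$duration_min, 30)
  expect_equal(res$median_duration_min, 30)
  # durations are invariant to a global frame offset
  ev2 <- event_table("c1", 110L, 120L, 300L)
  expect_equal(mitotic_timing(ev2, 3)$per_cell$duration_min, 30)
})

test_that("the one-hour rule separates arrest from censoring", {
  # NEB 500 min into a 600 min movie (1 min/frame), no anaphase:
  # >= 60 min remained, so the cell is arrested
  ev <- event_table("late", 500L, NA, 600L)
  res <- mitotic_timing(ev, frame_interval_min = 1)
  expect_equal(res$per_cell$status, "arrested")
  # NEB 550 min in: less than one hour remained -> censored
  ev2 <- event_table("later", 550L, NA, 600L)
  res2 <- mitotic_timing(ev2, frame_interval_min = 1)
  expect_equal(res2$per_cell$status, "censored")
  expect_equal(res2$n_censored, 1L)
  expect_true(is.na(res2$arrest_fraction_pct))
})

test_that("arrest fraction counts arrested over divided plus arrested", {
  # 10 cells: 8 divide, 2 arrest, 1 censored cell excluded from both counts
  ev <- event_table(
    cell_id = paste0("c", 1:11),
    neb_frame = c(rep(10L, 10), 190L),
    anaphase_frame = c(rep(20L, 8), NA, NA, NA),
    movie_end_frame = rep(200L, 11))
  res <- mitotic_timing(ev, frame_interval_min = 3)
  expect_equal(res$n_divided, 8L)
  expect_equal(res$n_arrested, 2L)
  expect_equal(res$n_censored, 1L)
  expect_equal(res$arrest_fraction_pct, 20)
  # arrested + divided + censored always partitions the cells
  expect_equal(res$n_divided + res$n_arrested + res$n_censored, 11L)
})

test_that("identical groups are not called different", {
  vals <- rep(c(1.1, 1.2, 1.3, 1.4, 1.5), 2)
  tab <- group_table(rep(c("a", "b"), each = 5), "r1",
                     paste0(rep(c("a", "b"), each = 5), 1:5),
                     "m", vals)
  cmp <- compare_groups(tab, "m", family = "parametric")
  expect_gt(cmp$pairwise$p_adj, 0.9)
  cmp2 <- compare_groups(tab, "m", family = "nonparametric")
  expect_gt(cmp2$pairwise$p_adj, 0.9)
})

test_that("well-separated groups give tiny adjusted p-values", {
  set.seed(123)
  vals <- c(rnorm(20, 0, 0.01), rnorm(20, 5, 0.01))
  tab <- group_table(rep(c("a", "b"), each = 20), "r1",
                     paste0(rep(c("a", "b"), each = 20), 1:20), "m", vals)
  for (fam in c("parametric", "nonparametric")) {
    cmp <- compare_groups(tab, "m", family = fam)
    expect_lt(cmp$pairwise$p_adj, 0.001)
    expect_lt(cmp$omnibus$p_value, 0.001)
  }
})

test_that("group sizes and structure are validated", {
  tab <- group_table(c("a", "a", "b"), "r", c("1", "2", "1"), "m", 1:3)
  expect_error(compare_groups(tab, "m"), "n >= 3")
  expect_error(compare_groups(tab, "missing"), "no rows")
  one <- group_table(rep("a", 5), "r", as.character(1:5), "m", 1:5)
  expect_error(compare_groups(one, "m"), "2 conditions")
})

test_that("null p-values are uniform and type-I error is controlled", {
  set.seed(2024)
  reps <- 500
  pv <- vapply(seq_len(reps), function(i) {
    vals <- rnorm(30)
    g <- rep(c("a", "b", "c"), each = 10)
    tab <- group_table(g, "r", paste0(g, 1:30), "m", vals)
    compare_groups(tab, "m", family = "parametric")$omnibus$p_value
  }, numeric(1))
  # distributional sanity: omnibus p ~ Uniform(0, 1) under the null
  expect_gt(suppressWarnings(ks.test(pv, "punif"))$p.value, 0.01)
  expect_lte(mean(pv < 0.05), 0.07)
})

test_that("Dunn's z-statistics agree with the Kruskal-Wallis machinery", {
  # two-group case: Dunn z^2 equals the Kruskal-Wallis chi-square (ties
  # correction included), an algebraic identity useful as a cross-check
  set.seed(5)
  x <- c(rnorm(12), rnorm(15, 1))
  g <- factor(rep(c("a", "b"), c(12, 15)))
  d <- dunn_test(x, g)
  kw <- kruskal.test(x, g)
  expect_equal(d$z^2, unname(kw$statistic), tolerance = 1e-10)
  # with ties
  xt <- round(x, 0)
  expect_equal(dunn_test(xt, g)$z^2,
               unname(kruskal.test(xt, g)$statistic), tolerance = 1e-10)
})

test_that("per-replicate summaries accompany per-cell statistics", {
  set.seed(9)
  g <- rep(c("ctrl", "kd"), each = 12)
  rep_id <- rep(rep(c("r1", "r2", "r3"), each = 4), 2)
  vals <- rnorm(24, ifelse(g == "kd", 5, 3))
  tab <- group_table(g, rep_id, paste0(g, rep_id, 1:24), "fwhm_um", vals)
  cmp <- compare_groups(tab, "fwhm_um")
  expect_equal(nrow(cmp$replicate_summary), 6)
  agg <- tapply(vals, paste(g, rep_id), mean)
  key <- paste(cmp$replicate_summary$condition_label,
               cmp$replicate_summary$replicate_id)
  expect_equal(cmp$replicate_summary$replicate_mean,
               as.numeric(agg[key]))
})
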