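mk_records <- function(n_young = 8, n_old = 6, seed = 1,
                       young_means = c(pc_wb = 6.6, asl_wb = 5.5,
                                       asl_gm = 5.7, asl_wm = 5.3,
                                       bold_gm = 0.33, bold_wm = 0.19),
                       old_shift = 0, sd = 0.3) {
  withr::with_seed(seed, {
    n <- n_young + n_old
    grid <- tidyr::expand_grid(
      subject_id = sprintf("s%02d", seq_len(n)),
      key = names(young_means))
    grid$group <- rep(rep(c("young", "old"), c(n_young, n_old)),
                      each = length(young_means))
    grid$sex <- rep(rep_len(c("M", "F", "F", "M"), n),
                    each = length(young_means))
    grid$site <- rep(rep_len(c("siteA", "siteB"), n),
                     each = length(young_means))
    mu <- young_means[grid$key] + ifelse(grid$group == "old", old_shift, 0)
    grid$cvr <- rnorm(nrow(grid), mu, sd)
    tidyr::separate_wider_delim(grid, "key", "_",
                                names = c("modality", "compartment"))
  })
}

test_that("adjusted group contrast equals the normal-equations oracle", {
  withr::with_seed(7, {
    n <- 14
    df <- tibble::tibble(
      y = rnorm(n, 5, 1),
      group = factor(rep(c("young", "old"), c(8, 6)),
                     levels = c("young", "old")),
      sex = rep_len(c("M", "F", "F", "M"), n),
      site = rep_len(c("siteA", "siteB"), n))
  })
  res <- group_compare_adjusted(df, "y")
  X <- cbind(1, df$group == "old", df$sex == "M", df$site == "siteB")
  beta <- ols_oracle(X, df$y)
  expect_equal(res$estimate, beta[2], tolerance = 1e-10)
  # t statistic from the brute-force residuals
  resid <- df$y - X %*% ols_oracle(X, df$y)
  s2 <- sum(resid^2) / (n - 4)
  se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  expect_equal(res$statistic, beta[2] / se, tolerance = 1e-10)
  expect_equal(res$df, n - 4)
  expect_equal(res$p_value, 2 * pt(-abs(beta[2] / se), n - 4),
               tolerance = 1e-12)
})

test_that("group contrast handles degenerate designs", {
  df <- tibble::tibble(
    y = rep(5, 10),
    group = rep(c("a", "b"), 5),
    sex = rep_len(c("M", "F", "F", "M"), 10),
    site = rep_len(c("s1", "s2", "s2", "s1", "s2", "s1"), 10))
  res <- group_compare_adjusted(df, "y")
  expect_equal(res$estimate, 0)
  expect_equal(res$p_value, 1)

  # a 49-subject cohort with intercept + group + sex + site has df 45
  co <- make_cohort(32, 17, seed = 2)
  res49 <- group_compare_adjusted(co$truth, "pc_cvr_true")
  expect_equal(res49$df, 45)

  # single-site cohort: site dropped with a message
  dfs <- df
  dfs$y <- rnorm(10)
  dfs$site <- "only"
  expect_message(res1 <- group_compare_adjusted(dfs, "y"), "dropped")
  expect_equal(res1$df, 10 - 3)

  # collinear covariate named in the error
  dfc <- df
  dfc$y <- rnorm(10)
  dfc$sex <- ifelse(dfc$group == "a", "M", "F")
  expect_error(group_compare_adjusted(dfc, "y"), "collinear")
})

test_that("Pearson correlation matches the covariance-formula oracle", {
  x <- c(1, 2, 4, 7, 11)
  y <- c(1.2, 1.9, 4.4, 6.5, 11.8)
  res <- pearson_corr(x, y)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$estimate, r, tolerance = 1e-10)
  expect_equal(res$statistic, r * sqrt(3 / (1 - r^2)), tolerance = 1e-10)
  expect_equal(res$df, 3)
  expect_equal(res$p_value, 2 * pt(-abs(res$statistic), 3),
               tolerance = 1e-12)

  expect_equal(pearson_corr(x, x)$estimate, 1)
  expect_equal(pearson_corr(x, -x)$estimate, -1)
  expect_equal(pearson_corr(x, -x)$p_value, 0)
  expect_error(pearson_corr(x, rep(1, 5)), "constant")
})

test_that("paired t test matches the textbook formula oracle", {
  a <- c(5.1, 6.0, 5.6, 5.9, 6.3, 5.4)
  b <- c(4.8, 5.7, 5.9, 5.2, 6.0, 5.1)
  res <- paired_ttest(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(6))
  expect_equal(res$estimate, mean(d), tolerance = 1e-10)
  expect_equal(res$statistic, t_hand, tolerance = 1e-10)
  expect_equal(res$df, 5)
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), 5), tolerance = 1e-12)

  same <- paired_ttest(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # constant nonzero differences: sentinel exact-effect result
  sent <- paired_ttest(a + 1, a)
  expect_equal(sent$statistic, Inf)
  expect_equal(sent$p_value, 0)
  expect_equal(sent$estimate, 1)

  expect_equal(tidy(res)$df, 5)
})

test_that("cohort summary reports group means, SEs and contrasts", {
  rec <- mk_records(n_young = 10, n_old = 8, old_shift = -1, sd = 0.2,
                    seed = 5)
  rep <- summarize_cohort(rec)
  gt <- rep$group_table
  expect_true(all(c("mean_young", "se_young", "mean_old", "se_old",
                    "estimate", "t", "df", "p") %in% names(gt)))
  expect_equal(nrow(gt), 6)
  # the injected young > old shift is reported in the right direction
  pc_row <- gt[gt$modality == "pc" & gt$compartment == "wb", ]
  expect_gt(pc_row$mean_young, pc_row$mean_old)
  expect_lt(pc_row$estimate, 0)  # old - young
  expect_lt(pc_row$p, 0.05)
  # SE convention: sd / sqrt(n)
  y_pc <- rec$cvr[rec$modality == "pc" & rec$group == "young"]
  expect_equal(pc_row$se_young, sd(y_pc) / sqrt(10), tolerance = 1e-12)

  # paired contrasts present
  expect_setequal(rep$paired_table$comparison,
                  c("pc_vs_asl_wb", "asl_gm_vs_wm", "bold_gm_vs_wm"))
  expect_error(summarize_cohort(rec[, -3]), "columns")
})

test_that("report files are written for a small cohort", {
  rec <- mk_records(seed = 6)
  rep <- summarize_cohort(rec)
  dir <- withr::local_tempdir()
  write_report(rep, dir)
  expect_true(file.exists(file.path(dir, "group_table.csv")))
  expect_true(file.exists(file.path(dir, "report.txt")))
  back <- utils::read.csv(file.path(dir, "group_table.csv"))
  expect_equal(nrow(back), 6)
})
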