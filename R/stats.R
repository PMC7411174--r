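#' Construct a test-result object
#'
#' @param estimate Effect estimate (group difference, correlation, or mean
#'   paired difference).
#' @param statistic t statistic.
#' @param df Degrees of freedom.
#' @param p_value Two-sided p value.
#' @param test_name Short label of the test.
#' @return A `cvr_test` object.
#' @export
new_cvr_test <- function(estimate, statistic, df, p_value, test_name) {
  if (df <= 0) stop("df must be > 0")
  if (!is.na(p_value) && (p_value < 0 || p_value > 1)) {
    stop("p_value must lie in [0, 1]")
  }
  structure(list(estimate = estimate, statistic = statistic, df = df,
                 p_value = p_value, test_name = test_name),
            class = "cvr_test")
}

#' @export
print.cvr_test <- function(x, ...) {
  cat(sprintf("<cvr_test> %s: estimate %.4g, t_%g = %.3g, p = %.3g\n",
              x$test_name, x$estimate, x$df, x$statistic, x$p_value))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.cvr_test <- function(x, ...) {
  tibble::tibble(test = x$test_name, estimate = x$estimate,
                 statistic = x$statistic, df = x$df, p_value = x$p_value)
}

#' Group comparison adjusted for sex and site
#'
#' Ordinary least squares of a per-subject outcome on group, sex and site
#' indicators: the reported effect is the group coefficient (second level
#' minus reference level), with its t statistic on `n - rank` degrees of
#' freedom and a two-sided p value. Covariates that are constant in the
#' data are dropped with a message (e.g. a single-site cohort); genuinely
#' collinear covariates raise an error naming the offending column.
#'
#' @param data Data frame with one row per subject.
#' @param outcome,group,sex,site Column names (strings). `group` must have
#'   exactly two levels; its reference level is the first factor level
#'   (levels are taken in the order given for factors, alphabetical for
#'   character — code `group` as a factor to control the sign).
#'
#' @return A `cvr_test` (test_name `"group_adjusted"`).
#' @export
group_compare_adjusted <- function(data, outcome, group = "group",
                                   sex = "sex", site = "site") {
  y <- data[[outcome]]
  g <- as.factor(data[[group]])
  if (nlevels(g) != 2L) stop("group must have exactly two levels")
  if (min(table(g)) < 2L) stop("need at least 2 subjects per group")
  covars <- list()
  for (cn in c(sex, site)) {
    if (is.null(cn) || is.na(cn)) next
    v <- as.factor(data[[cn]])
    if (nlevels(droplevels(v)) < 2L) {
      message("covariate '", cn, "' is constant; dropped from the model")
      next
    }
    covars[[cn]] <- droplevels(v)
  }
  df_model <- data.frame(.y = y, .group = g, covars, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = df_model)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    bad <- names(cf)[is.na(cf)]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  sm <- suppressWarnings(summary(fit))$coefficients  # perfect fits handled below
  term <- paste0(".group", levels(g)[2])
  est <- sm[term, "Estimate"]
  tv <- sm[term, "t value"]
  df <- fit$df.residual
  if (is.nan(tv) || stats::sd(y) == 0) {  # identical outcomes: no effect
    est <- 0
    tv <- 0
    p <- 1
  } else {
    p <- 2 * stats::pt(-abs(tv), df)
  }
  new_cvr_test(est, tv, df, p, "group_adjusted")
}

#' Pearson correlation test
#'
#' Pearson r with `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees
#' of freedom and a two-sided p value.
#'
#' @param x,y Numeric vectors of equal length (n >= 3, non-constant).
#' @return A `cvr_test` (test_name `"pearson"`, estimate = r).
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input")
  }
  r <- stats::cor(x, y)
  n <- length(x)
  if (abs(r) == 1) {
    return(new_cvr_test(r, sign(r) * Inf, n - 2, 0, "pearson"))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  new_cvr_test(unname(ct$estimate), unname(ct$statistic),
               unname(ct$parameter), ct$p.value, "pearson")
}

#' Paired t test
#'
#' Two-sided paired t test on `a - b` with `n - 1` degrees of freedom.
#' Degenerate zero-variance differences are handled explicitly: all-zero
#' differences give t = 0, p = 1; constant nonzero differences give a
#' signed infinite t with p = 0 (the effect is exact in the sample).
#'
#' @param a,b Numeric vectors of equal length (n >= 2).
#' @return A `cvr_test` (test_name `"paired_t"`, estimate = mean
#'   difference).
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  n <- length(a)
  if (n < 2L) stop("need at least 2 pairs")
  d <- a - b
  if (stats::sd(d) == 0) {
    m <- mean(d)
    if (m == 0) return(new_cvr_test(0, 0, n - 1, 1, "paired_t"))
    return(new_cvr_test(m, sign(m) * Inf, n - 1, 0, "paired_t"))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  new_cvr_test(unname(tt$estimate), unname(tt$statistic),
               unname(tt$parameter), tt$p.value, "paired_t")
}

#' Cohort summary report
#'
#' Reproduces the cohort-level analyses on a long CVR table: per modality
#' and compartment, young/old means with standard errors and the
#' sex/site-adjusted group contrast; plus paired whole-brain PC-vs-ASL
#' and per-modality GM-vs-WM contrasts.
#'
#' @param records Long tibble with columns `subject_id`, `group`
#'   (`young`/`old`), `sex`, `site`, `modality` (`pc`/`asl`/`bold`),
#'   `compartment` (`wb`/`gm`/`wm`), `cvr`. Additional outcomes (e.g.
#'   basal CBF) may be included as extra modality rows.
#'
#' @return A `cvr_report`: `group_table` (one row per modality x
#'   compartment: group means, SEs, adjusted estimate, t, df, p) and
#'   `paired_table` (paired contrasts: mean difference, t, df, p).
#' @export
summarize_cohort <- function(records) {
  req <- c("subject_id", "group", "sex", "site", "modality", "compartment",
           "cvr")
  if (!all(req %in% names(records))) {
    stop("records must have columns: ", paste(req, collapse = ", "))
  }
  if (anyNA(records[c("group", "sex", "site")])) {
    stop("group, sex and site must be complete")
  }
  records <- dplyr::mutate(
    records, group = factor(.data$group, levels = c("young", "old")))
  if (min(table(dplyr::distinct(
    records, .data$subject_id, .data$group)$group)) < 2L) {
    stop("need at least 2 subjects per group")
  }

  se <- function(x) stats::sd(x) / sqrt(length(x))
  group_table <- records |>
    dplyr::group_by(.data$modality, .data$compartment) |>
    dplyr::group_modify(function(df, key) {
      gt <- group_compare_adjusted(df, "cvr")
      df |>
        dplyr::group_by(.data$group) |>
        dplyr::summarise(mean = mean(.data$cvr), se = se(.data$cvr),
                         .groups = "drop") |>
        tidyr::pivot_wider(names_from = "group",
                           values_from = c("mean", "se")) |>
        dplyr::mutate(estimate = gt$estimate, t = gt$statistic, df = gt$df,
                      p = gt$p_value)
    }) |>
    dplyr::ungroup()

  wide <- records |>
    dplyr::select("subject_id", "modality", "compartment", "cvr") |>
    tidyr::pivot_wider(names_from = c("modality", "compartment"),
                       values_from = "cvr")
  paired <- list()
  if (all(c("pc_wb", "asl_wb") %in% names(wide))) {
    tt <- paired_ttest(wide$pc_wb, wide$asl_wb)
    paired$pc_vs_asl_wb <- tidy(tt)
  }
  for (m in c("asl", "bold")) {
    cg <- paste0(m, "_gm"); cw <- paste0(m, "_wm")
    if (all(c(cg, cw) %in% names(wide))) {
      tt <- paired_ttest(wide[[cg]], wide[[cw]])
      paired[[paste0(m, "_gm_vs_wm")]] <- tidy(tt)
    }
  }
  paired_table <- if (length(paired)) {
    dplyr::bind_rows(paired, .id = "comparison") |>
      dplyr::rename(mean_diff = "estimate") |>
      dplyr::select(-"test")
  } else {
    tibble::tibble()
  }
  structure(list(group_table = group_table, paired_table = paired_table),
            class = "cvr_report")
}

#' @export
print.cvr_report <- function(x, ...) {
  cat("Cohort CVR report\n")
  cat("\nGroup contrasts (adjusted for sex and site):\n")
  print(as.data.frame(x$group_table), digits = 3, row.names = FALSE)
  if (nrow(x$paired_table)) {
    cat("\nPaired contrasts:\n")
    print(as.data.frame(x$paired_table), digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' Write a cohort report to disk
#'
#' @param report A `cvr_report`.
#' @param dir Output directory (created if needed). Writes
#'   `group_table.csv`, `paired_table.csv` and `report.txt`.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$group_table, file.path(dir, "group_table.csv"),
                   row.names = FALSE)
  utils::write.csv(report$paired_table, file.path(dir, "paired_table.csv"),
                   row.names = FALSE)
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}
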