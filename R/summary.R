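#' Demographic and clinical cohort summary
#'
#' Per-group summary of clinical covariates in the style of a baseline
#' characteristics table: counts with percentages (two decimals) and a
#' chi-square test (Fisher's exact when any expected cell count is below 5)
#' for categorical covariates; mean +/- SD and a Mann-Whitney U test for
#' continuous covariates. Covariates named but absent from the table are
#' omitted with a warning.
#'
#' @param cohort data.frame with an `outcome` column plus covariates.
#' @param covariates character vector of covariate column names; defaults to
#'   every non-feature, non-id column.
#' @return list of class `cohort_summary`: `categorical` and `continuous`
#'   data.frames plus `n_favorable`, `n_unfavorable`.
#' @export
cohort_summary <- function(cohort, covariates = NULL) {
  grp <- cohort_outcome(cohort)
  if (is.null(covariates)) {
    covariates <- setdiff(names(cohort),
                          c("subject_id", "outcome", relative_feature_names()))
  }
  missing_cov <- setdiff(covariates, names(cohort))
  if (length(missing_cov)) {
    warning("omitting missing covariates: ",
            paste(missing_cov, collapse = ", "), call. = FALSE)
    covariates <- setdiff(covariates, missing_cov)
  }
  cat_rows <- list(); num_rows <- list()
  fav <- grp == "favorable"
  for (cv in covariates) {
    x <- cohort[[cv]]
    if (is.numeric(x) && length(unique(stats::na.omit(x))) > 2L) {
      m <- mann_whitney_u(x[fav], x[!fav])
      num_rows[[cv]] <- data.frame(
        covariate = cv,
        mean_favorable = mean(x[fav]), sd_favorable = stats::sd(x[fav]),
        mean_unfavorable = mean(x[!fav]), sd_unfavorable = stats::sd(x[!fav]),
        p = m$p, stringsAsFactors = FALSE)
    } else {
      xb <- if (is.logical(x)) x else as.logical(as.integer(as.factor(x)) - 1L)
      if (is.numeric(x)) xb <- x != 0
      tab <- table(factor(xb, levels = c(FALSE, TRUE)), grp)
      exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      p <- if (any(exp_counts < 5)) {
        stats::fisher.test(tab)$p.value
      } else {
        suppressWarnings(stats::chisq.test(tab, correct = TRUE)$p.value)
      }
      cat_rows[[cv]] <- data.frame(
        covariate = cv,
        count_favorable = sum(xb & fav),
        pct_favorable = round(100 * sum(xb & fav) / sum(fav), 2),
        count_unfavorable = sum(xb & !fav),
        pct_unfavorable = round(100 * sum(xb & !fav) / sum(!fav), 2),
        p = p, stringsAsFactors = FALSE)
    }
  }
  structure(list(
    categorical = if (length(cat_rows)) do.call(rbind, cat_rows) else NULL,
    continuous = if (length(num_rows)) do.call(rbind, num_rows) else NULL,
    n_favorable = sum(fav), n_unfavorable = sum(!fav)),
    class = "cohort_summary")
}

#' Whole-cohort prevalence percentages
#'
#' Counts and percentages (rounded to two decimals) of binary conditions
#' over the whole cohort, e.g. 53 of 58 hypertensive subjects is 91.38%.
#'
#' @param cohort data.frame of subjects.
#' @param conditions character vector of logical/0-1 columns.
#' @return data.frame: condition, count, n, percent.
#' @export
prevalence_table <- function(cohort, conditions) {
  missing_cov <- setdiff(conditions, names(cohort))
  if (length(missing_cov))
    stop("missing condition columns: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  n <- nrow(cohort)
  rows <- lapply(conditions, function(cv) {
    x <- cohort[[cv]]
    xb <- if (is.logical(x)) x else x != 0
    k <- sum(xb, na.rm = TRUE)
    data.frame(condition = cv, count = k, n = n,
               percent = round(100 * k / n, 2), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
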