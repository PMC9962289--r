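#' Mann-Whitney U test
#'
#' Two-sample rank test. The U statistic counts pairs where `x` exceeds `y`,
#' with ties counted one half, so `U / (n1 * n2)` is the concordance
#' probability (and equals the AUC when `x` holds the positive-class
#' scores). The two-sided p-value is exact — full enumeration of all
#' \eqn{\binom{n_1+n_2}{n_1}} labelings — when `n1 + n2 <= 16` and the data
#' carry no ties; otherwise a normal approximation with tie correction and a
#' continuity correction is used. A completely tied sample (zero variance)
#' reports p = 1.
#'
#' @param x,y numeric samples, each non-empty.
#' @param exact_limit maximum combined sample size for enumeration.
#' @return list of class `mwu_result`: `U`, `p`, `method`
#'   (`"exact"`/`"normal"`), `median_x`, `median_y`, `n1`, `n2`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(x, y, exact_limit = 16L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L)
    stop("both samples must be non-empty", call. = FALSE)
  if (any(!is.finite(c(x, y))))
    stop("samples must be finite", call. = FALSE)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L

  if (!ties && N <= exact_limit) {
    p <- mwu_exact_p(U, n1, n2)
    method <- "exact"
  } else {
    tie_tab <- table(r)
    tie_term <- sum(tie_tab^3 - tie_tab)
    v <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    if (v <= 0) {
      p <- 1
    } else {
      dev <- U - n1 * n2 / 2
      z <- (dev - sign(dev) * 0.5) / sqrt(v)  # continuity correction
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal"
  }
  structure(list(U = U, p = p, method = method,
                 median_x = stats::median(x), median_y = stats::median(y),
                 n1 = n1, n2 = n2),
            class = "mwu_result")
}

# Exact two-sided p for untied data by enumerating the null distribution of
# U over all choose(n1+n2, n1) rank assignments (dynamic programming over
# rank-sum counts; equivalent to full enumeration).
mwu_exact_p <- function(U, n1, n2) {
  counts <- mwu_null_counts(n1, n2)          # counts[u + 1] = #{labelings: U = u}
  total <- sum(counts)
  mid <- n1 * n2 / 2
  dev <- abs(U - mid)
  us <- seq_along(counts) - 1
  sum(counts[abs(us - mid) >= dev - 1e-9]) / total
}

# Number of rank labelings giving each value of U, via the classic
# recursion c(u; i, j) = c(u - j; i - 1, j) + c(u; i, j - 1) with
# c(u; 0, j) = c(u; i, 0) = [u == 0]. Column u+1 of the result counts
# labelings with U = u; the columns sum to choose(n1 + n2, n1).
mwu_null_counts <- function(n1, n2) {
  maxu <- n1 * n2
  prev <- matrix(0, n1 + 1, maxu + 1)  # j = 0
  prev[, 1] <- 1
  for (j in seq_len(n2)) {
    cur <- matrix(0, n1 + 1, maxu + 1)
    cur[1, 1] <- 1
    for (i in seq_len(n1)) {
      shifted <- c(rep(0, j), cur[i, seq_len(maxu + 1 - j)])
      cur[i + 1, ] <- shifted + prev[i + 1, ]
    }
    prev <- cur
  }
  prev[n1 + 1, ]
}

#' Screen features by Mann-Whitney tests
#'
#' Tests every feature column between the two outcome groups and flags those
#' with two-sided p below `alpha`. No multiplicity correction is applied
#' (the modelled analysis applies none). A feature constant across all
#' subjects reports p = 1 and is never flagged.
#'
#' @param cohort data.frame with an `outcome` column (two levels) and
#'   numeric feature columns.
#' @param alpha significance level, default 0.05.
#' @param features feature column names; defaults to every numeric column
#'   except `outcome`-adjacent metadata.
#' @return data.frame of class `mwu_screen`: feature, U, p, group medians,
#'   `significant`.
#' @export
screen_features <- function(cohort, alpha = 0.05, features = NULL) {
  grp <- cohort_outcome(cohort)
  if (is.null(features)) features <- cohort_feature_columns(cohort)
  res <- lapply(features, function(f) {
    x <- cohort[[f]][grp == "favorable"]
    y <- cohort[[f]][grp == "unfavorable"]
    m <- mann_whitney_u(x, y)
    data.frame(feature = f, U = m$U, p = m$p,
               median_favorable = m$median_x,
               median_unfavorable = m$median_y,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$significant <- out$p < alpha
  class(out) <- c("mwu_screen", "data.frame")
  out
}

cohort_outcome <- function(cohort) {
  if (!"outcome" %in% names(cohort))
    stop("cohort must have an `outcome` column", call. = FALSE)
  o <- cohort$outcome
  if (anyNA(o)) stop("missing outcome labels", call. = FALSE)
  o <- factor(as.character(o), levels = c("favorable", "unfavorable"))
  if (anyNA(o))
    stop("outcome must be 'favorable' or 'unfavorable'", call. = FALSE)
  if (nlevels(droplevels(o)) < 2L)
    stop("both outcome classes must be present", call. = FALSE)
  o
}

cohort_feature_columns <- function(cohort) {
  cand <- setdiff(names(cohort), c("subject_id", "outcome"))
  cand[vapply(cohort[cand], is.numeric, logical(1))]
}

#' LASSO feature selection with stratified 10-fold cross-validation
#'
#' L1-penalized logistic regression over a log-spaced lambda path, with the
#' penalty weight chosen by k-fold cross-validated binomial deviance on
#' outcome-stratified folds. Features are standardized (zero mean, unit SD)
#' before penalization. The selected set is the features with nonzero
#' coefficients at the chosen lambda (`"min"` rule by default; `"1se"`
#' available).
#'
#' @param cohort data.frame with `outcome` plus feature columns.
#' @param features candidate feature names (>= 2).
#' @param n_folds number of CV folds, default 10.
#' @param seed integer seed controlling fold assignment.
#' @param lambda_rule `"min"` (minimum mean CV deviance) or `"1se"`.
#' @return list of class `lasso_selection`: `selected`, `lambda`,
#'   `lambda_path`, `cvm` (mean CV deviance per lambda), `lambda_rule`,
#'   `foldid`, `seed`, `fit` (the cv.glmnet object).
#' @export
lasso_select <- function(cohort, features, n_folds = 10L, seed = 1L,
                         lambda_rule = c("min", "1se")) {
  lambda_rule <- match.arg(lambda_rule)
  grp <- cohort_outcome(cohort)
  if (length(features) < 2L)
    stop("need at least 2 candidate features for LASSO", call. = FALSE)
  x <- as.matrix(cohort[features])
  if (any(!is.finite(x))) stop("non-finite feature values", call. = FALSE)
  x <- scale(x)
  if (any(!is.finite(x)))
    stop("constant feature cannot be standardized: ",
         paste(features[apply(is.na(x), 2, any)], collapse = ", "),
         call. = FALSE)
  y <- as.integer(grp == "unfavorable")
  foldid <- stratified_folds(grp, n_folds, seed)
  set.seed(derive_seed(seed, 997L))
  fit <- glmnet::cv.glmnet(x, y, family = "binomial", foldid = foldid,
                           standardize = FALSE, type.measure = "deviance")
  lambda <- if (lambda_rule == "min") fit$lambda.min else fit$lambda.1se
  beta <- as.matrix(stats::coef(fit, s = lambda))[-1, 1]
  structure(list(selected = names(beta)[beta != 0],
                 lambda = lambda, lambda_path = fit$lambda, cvm = fit$cvm,
                 lambda_rule = lambda_rule, foldid = foldid,
                 seed = seed, fit = fit),
            class = "lasso_selection")
}

# Outcome-stratified fold ids: shuffle within class, deal folds cyclically.
stratified_folds <- function(grp, n_folds, seed) {
  n_folds <- as.integer(n_folds)
  tabs <- table(grp)
  if (any(tabs < n_folds))
    stop(sprintf(paste0("class '%s' has %d subjects, fewer than n_folds = ",
                        "%d; every fold must contain both classes - reduce ",
                        "n_folds"),
                 names(tabs)[which.min(tabs)], min(tabs), n_folds),
         call. = FALSE)
  foldid <- integer(length(grp))
  set.seed(derive_seed(seed, 991L))
  for (g in levels(grp)) {
    idx <- sample(which(grp == g))
    foldid[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  foldid
}

#' Fit the logistic combination model
#'
#' Maximum-likelihood logistic regression of the binary outcome
#' (unfavorable = 1) on the selected features; the combined score is each
#' subject's fitted linear predictor. Complete separation is detected and
#' raised as an error — on separable data the MLE diverges and the score is
#' not identifiable — with an optional ridge fallback (`ridge_epsilon > 0`)
#' for callers that want a penalized score anyway.
#'
#' @param cohort data.frame with `outcome` plus feature columns.
#' @param features selected feature names (>= 1).
#' @param ridge_epsilon if positive, refit with an L2 penalty of this weight
#'   instead of erroring on separation.
#' @return list of class `logistic_model`: `intercept`, `coefficients`,
#'   `scores` (linear predictor per subject), `fitted` (probabilities),
#'   `separation`, `ridged`.
#' @export
fit_logistic <- function(cohort, features, ridge_epsilon = 0) {
  grp <- cohort_outcome(cohort)
  if (length(features) < 1L)
    stop("need at least one feature", call. = FALSE)
  y <- as.integer(grp == "unfavorable")
  X <- as.data.frame(cohort[features])
  fit <- suppressWarnings(
    stats::glm(y ~ ., data = cbind(y = y, X), family = stats::binomial()))
  eta <- as.numeric(stats::predict(fit, type = "link"))
  p <- stats::plogis(eta)
  sep <- (max(p[y == 0], 0) < min(p[y == 1], 1) &&
            all(p[y == 1] > 1 - 1e-8) && all(p[y == 0] < 1e-8)) ||
    !fit$converged
  if (sep && ridge_epsilon <= 0)
    stop("complete separation: logistic MLE diverges. Use the single best ",
         "feature as the score, or refit with `ridge_epsilon > 0` for a ",
         "penalized combination", call. = FALSE)
  ridged <- FALSE
  if (sep) {
    Xm <- scale(as.matrix(X))
    # glmnet needs >= 2 columns; a zero column is inert under the penalty
    Xg <- if (ncol(Xm) == 1L) cbind(Xm, .zero = 0) else Xm
    rf <- glmnet::glmnet(Xg, y, family = "binomial", alpha = 0,
                         lambda = ridge_epsilon, standardize = FALSE)
    b <- as.matrix(stats::coef(rf))[, 1]
    b <- b[c(1L, seq_len(ncol(Xm)) + 1L)]
    eta <- as.numeric(b[1] + Xm %*% b[-1])
    coefs <- b[-1]
    intercept <- b[1]
    ridged <- TRUE
  } else {
    cf <- stats::coef(fit)
    intercept <- unname(cf[1])
    coefs <- cf[-1]
  }
  structure(list(intercept = intercept, coefficients = coefs,
                 scores = eta, fitted = stats::plogis(eta),
                 separation = sep, ridged = ridged),
            class = "logistic_model")
}

#' ROC analysis with DeLong errors and a Youden-index cutoff
#'
#' AUC by the rank (pair-counting) identity with ties counted one half;
#' standard error by the DeLong placement-variance estimator; 95% CI on the
#' logit scale (falling back to a truncated Wald interval when the AUC sits
#' on the boundary); operating cutoff maximizing the Youden index
#' J = sensitivity + specificity - 1 (`"closest01"` available). If the raw
#' AUC is below 0.5 the orientation flips (direction `"<"`), so the reported
#' AUC is always >= 0.5; `auc_raw` keeps the unoriented value, which is what
#' permutation-null controls should average.
#'
#' @param scores numeric classifier scores.
#' @param outcomes outcome labels; `positive` names the positive class.
#' @param positive the positive-class label, default `"unfavorable"`.
#' @param cutoff_rule `"youden"` or `"closest01"`.
#' @param conf_level confidence level for the CI, default 0.95.
#' @return list of class `roc_result`: `auc`, `auc_raw`, `se`, `ci`,
#'   `cutoff`, `sensitivity` and `specificity` (percent), `direction`,
#'   `curve` (data.frame threshold/fpr/tpr), `n_pos`, `n_neg`.
#' @examples
#' roc_analysis(c(0.9, 0.8, 0.7, 0.85), c("unfavorable", "unfavorable",
#'   "favorable", "favorable"))$auc  # 0.75
#' @export
roc_analysis <- function(scores, outcomes, positive = "unfavorable",
                         cutoff_rule = c("youden", "closest01"),
                         conf_level = 0.95) {
  cutoff_rule <- match.arg(cutoff_rule)
  scores <- as.numeric(scores)
  if (any(!is.finite(scores))) stop("non-finite scores", call. = FALSE)
  is_pos <- as.character(outcomes) == positive
  m <- sum(is_pos); n <- sum(!is_pos)
  if (m == 0L || n == 0L)
    stop("both classes must be present", call. = FALSE)
  sp <- scores[is_pos]; sn <- scores[!is_pos]

  auc_raw <- auc_rank(sp, sn)
  direction <- ">"
  if (auc_raw < 0.5) {
    direction <- "<"
    sp <- -sp; sn <- -sn; scores <- -scores
  }
  auc <- auc_rank(sp, sn)

  # DeLong placements.
  v10 <- vapply(sp, function(s) (sum(sn < s) + 0.5 * sum(sn == s)) / n,
                numeric(1))
  v01 <- vapply(sn, function(s) (sum(sp > s) + 0.5 * sum(sp == s)) / m,
                numeric(1))
  var_auc <- (if (m > 1) stats::var(v10) / m else 0) +
    (if (n > 1) stats::var(v01) / n else 0)
  se <- sqrt(max(var_auc, 0))

  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (se == 0 || auc <= 0 || auc >= 1) {
    ci <- c(max(0, auc - zq * se), min(1, auc + zq * se))
  } else {
    lo <- stats::qlogis(auc) - zq * se / (auc * (1 - auc))
    hi <- stats::qlogis(auc) + zq * se / (auc * (1 - auc))
    ci <- c(stats::plogis(lo), stats::plogis(hi))
  }

  # Operating points: classify positive when score >= threshold.
  thr <- sort(unique(c(scores, Inf)))
  tpr <- vapply(thr, function(t) mean(sp >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(sn >= t), numeric(1))
  j <- tpr - fpr
  best <- if (cutoff_rule == "youden") {
    which.max(j)
  } else {
    which.min((1 - tpr)^2 + fpr^2)
  }
  cutoff <- thr[best]
  if (direction == "<") cutoff <- -cutoff

  structure(list(
    auc = auc, auc_raw = auc_raw, se = se, ci = ci,
    cutoff = cutoff,
    sensitivity = 100 * tpr[best], specificity = 100 * (1 - fpr[best]),
    direction = direction,
    curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
    n_pos = m, n_neg = n, conf_level = conf_level),
    class = "roc_result")
}

# Concordance probability via midranks (ties counted one half).
auc_rank <- function(sp, sn) {
  r <- rank(c(sp, sn))
  m <- length(sp); n <- length(sn)
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Label-permutation null control for a fixed score
#'
#' Shuffles the outcome labels and recomputes the raw (unoriented)
#' pair-counting AUC of a fixed score vector; the mean over permutations is
#' 0.5 under the null. The score is deliberately NOT refit per permutation:
#' an in-sample refit is optimistically biased, and the AUC >= 0.5
#' orientation rule alone folds the null distribution upwards, so neither
#' variant centres on 0.5.
#'
#' @param scores numeric score per subject.
#' @param outcomes outcome labels.
#' @param n_perm number of permutations, default 200.
#' @param seed integer seed.
#' @param positive positive-class label.
#' @return list: `mean_auc`, `aucs` (vector of per-permutation raw AUCs).
#' @export
permutation_auc_control <- function(scores, outcomes, n_perm = 200L,
                                    seed = 1L, positive = "unfavorable") {
  is_pos <- as.character(outcomes) == positive
  if (!any(is_pos) || all(is_pos))
    stop("both classes must be present", call. = FALSE)
  set.seed(derive_seed(seed, 409L))
  aucs <- vapply(seq_len(n_perm), function(i) {
    p <- sample(is_pos)
    auc_rank(scores[p], scores[!p])
  }, numeric(1))
  list(mean_auc = mean(aucs), aucs = aucs)
}

#' Run the full prognostic analysis
#'
#' The end-to-end statistical tail on a cohort table: per-feature
#' Mann-Whitney screening, cross-validated LASSO selection (on the
#' screened-significant features by default, or all features), logistic
#' combination of the selected markers, and ROC rows — AUC, sensitivity,
#' specificity, DeLong SE and 95% CI at the Youden cutoff — for each
#' selected feature and the combined score. Deterministic given
#' `config$seed`.
#'
#' If fewer than two features survive screening, LASSO is skipped (the
#' survivors are carried forward directly); if nothing survives, the ROC
#' table is empty and the model is `NULL`.
#'
#' @param cohort data.frame with `subject_id`, `outcome` and feature
#'   columns.
#' @param config an [analysis_config()] list.
#' @return list of class `prognosis_report`: `group_summary` (mean +/- SD
#'   per feature per group plus MWU p), `screen`, `selection`, `model`,
#'   `roc_table`, `roc` (per-variable `roc_result`s), `config`.
#' @export
run_full_analysis <- function(cohort, config = analysis_config()) {
  grp <- cohort_outcome(cohort)
  feats <- cohort_feature_columns(cohort)
  screen <- screen_features(cohort, alpha = config$alpha, features = feats)

  gs <- do.call(rbind, lapply(feats, function(f) {
    xf <- cohort[[f]][grp == "favorable"]
    xu <- cohort[[f]][grp == "unfavorable"]
    data.frame(feature = f,
               mean_favorable = mean(xf), sd_favorable = stats::sd(xf),
               mean_unfavorable = mean(xu), sd_unfavorable = stats::sd(xu),
               p = screen$p[match(f, screen$feature)],
               stringsAsFactors = FALSE)
  }))

  candidates <- if (config$lasso_on == "significant") {
    screen$feature[screen$significant]
  } else {
    feats
  }

  selection <- NULL
  if (length(candidates) >= 2L) {
    selection <- lasso_select(cohort, candidates, n_folds = config$n_folds,
                              seed = config$seed,
                              lambda_rule = config$lambda_rule)
    selected <- selection$selected
    if (length(selected) == 0L) selected <- candidates  # lasso dropped all:
    # fall back to the screened set so the combination is still reportable
  } else {
    selected <- candidates
  }

  model <- NULL
  rocs <- list()
  for (f in selected)
    rocs[[f]] <- roc_analysis(cohort[[f]], grp,
                              positive = config$positive_class,
                              cutoff_rule = config$cutoff_rule)
  if (length(selected) >= 1L) {
    model <- fit_logistic(cohort, selected,
                          ridge_epsilon = config$ridge_epsilon)
    rocs[["combination"]] <- roc_analysis(model$scores, grp,
                                          positive = config$positive_class,
                                          cutoff_rule = config$cutoff_rule)
  }

  roc_table <- if (length(rocs)) {
    do.call(rbind, lapply(names(rocs), function(nm) {
      r <- rocs[[nm]]
      data.frame(variable = nm, auc = r$auc,
                 sensitivity = r$sensitivity, specificity = r$specificity,
                 se = r$se, ci_lower = r$ci[1], ci_upper = r$ci[2],
                 cutoff = r$cutoff, stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(variable = character(), auc = numeric(),
               sensitivity = numeric(), specificity = numeric(),
               se = numeric(), ci_lower = numeric(), ci_upper = numeric(),
               cutoff = numeric())
  }

  structure(list(group_summary = gs, screen = screen, selection = selection,
                 selected = selected, model = model, roc = rocs,
                 roc_table = roc_table, config = config),
            class = "prognosis_report")
}

#' Analysis configuration
#'
#' @param alpha screening significance level (no multiplicity correction).
#' @param n_folds LASSO CV folds.
#' @param seed integer seed for fold assignment and any simulation.
#' @param lasso_on `"significant"` (LASSO runs on the screened features,
#'   following the screen-then-select order) or `"all"`.
#' @param lambda_rule `"min"` or `"1se"`.
#' @param cutoff_rule `"youden"` or `"closest01"`.
#' @param positive_class ROC positive class, default `"unfavorable"`.
#' @param ridge_epsilon L2 fallback weight for separable logistic fits
#'   (0 = error on separation).
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(alpha = 0.05, n_folds = 10L, seed = 1L,
                            lasso_on = c("significant", "all"),
                            lambda_rule = c("min", "1se"),
                            cutoff_rule = c("youden", "closest01"),
                            positive_class = "unfavorable",
                            ridge_epsilon = 0) {
  stopifnot(alpha >= 0, alpha <= 1, n_folds >= 2)
  structure(list(alpha = alpha, n_folds = as.integer(n_folds),
                 seed = as.integer(seed),
                 lasso_on = match.arg(lasso_on),
                 lambda_rule = match.arg(lambda_rule),
                 cutoff_rule = match.arg(cutoff_rule),
                 positive_class = positive_class,
                 ridge_epsilon = ridge_epsilon),
            class = "analysis_config")
}
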