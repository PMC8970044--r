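# Cohort-level biomarker statistics: two-sample power, group comparison,
# ROC/AUC, and combination of the fucosylation ratio with serum AFP.

#' Power of the two-sided two-sample t-test
#'
#' Analytic power under the noncentral t distribution for unequal group
#' sizes: noncentrality delta = d * sqrt(n1 n2 / (n1 + n2)), df = n1 + n2 - 2,
#' power = P(|T'| > t(1 - alpha/2)). At d = 0 the power equals the test size
#' alpha.
#'
#' @param n1,n2 group sizes (>= 2).
#' @param d standardized effect size (Cohen's d).
#' @param alpha two-sided significance level in (0, 1).
#' @return Power in `[0, 1]`.
#' @examples
#' t_test_power(35, 27, 0.8, 0.05)  # 0.87: the study's design power
#' @export
t_test_power <- function(n1, n2, d, alpha = 0.05) {
  if (!is.finite(n1) || !is.finite(n2) || n1 < 2 || n2 < 2) {
    stop("group sizes must be >= 2")
  }
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)")
  }
  if (!is.finite(d)) stop("effect size must be finite")
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  tcrit <- stats::qt(1 - alpha / 2, df)
  (1 - stats::pt(tcrit, df, ncp)) + stats::pt(-tcrit, df, ncp)
}

#' Two-sample comparison of group values
#'
#' Two-sided two-sample t-test, pooled-variance by default (matching the
#' design power analysis family), Welch optional. The measurement scale (raw
#' ratio or -log10 ratio) is the caller's choice and is recorded in the
#' output.
#'
#' @param x,y numeric vectors (>= 2 finite values each).
#' @param var_equal pooled-variance test when TRUE (default); Welch otherwise.
#' @param scale_label label of the scale the values are on, recorded in the
#'   result (default "neg_log10_ratio").
#' @return A list with `statistic`, `p_value`, `df`, `mean_x`, `mean_y`,
#'   `method`, `scale`.
#' @export
compare_groups <- function(x, y, var_equal = TRUE,
                           scale_label = "neg_log10_ratio") {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least 2 finite values")
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_x = mean(x), mean_y = mean(y),
       method = if (var_equal) "pooled t-test" else "Welch t-test",
       scale = scale_label)
}

#' Empirical ROC curve and AUC
#'
#' Empirical ROC over all score thresholds (higher score = more positive).
#' The AUC equals the Mann-Whitney U statistic divided by n+ x n-, with tied
#' score pairs counted 0.5 — identical to the trapezoidal area under the
#' empirical curve. `sensitivity_at_spec90` is the maximal sensitivity among
#' thresholds achieving specificity >= 0.90.
#'
#' @param scores numeric scores.
#' @param labels logical (TRUE = positive class) or any 2-level vector whose
#'   second sorted level is the positive class.
#' @return A list of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `sensitivity_at_spec90`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (!is.logical(labels)) {
    lev <- sort(unique(labels))
    if (length(lev) != 2L) stop("labels must have exactly 2 classes")
    labels <- labels == lev[2L]
  }
  if (!any(labels) || all(labels)) {
    stop("both classes must be present to compute a ROC curve")
  }
  if (any(!is.finite(scores))) stop("scores must be finite")
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  # Mann-Whitney with midranks handles ties at 0.5
  r <- rank(scores)
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) sum(scores[labels] >= t) / n_pos, numeric(1))
  spec <- vapply(thr, function(t) sum(scores[!labels] < t) / n_neg, numeric(1))
  ok <- spec >= 0.90
  structure(list(
    thresholds = thr, sensitivity = sens, specificity = spec, auc = auc,
    sensitivity_at_spec90 = if (any(ok)) max(sens[ok]) else 0,
    n_pos = n_pos, n_neg = n_neg
  ), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc> AUC = ", format(x$auc, digits = 4),
      " (", x$n_pos, " pos / ", x$n_neg, " neg); sensitivity at 90% ",
      "specificity = ", format(x$sensitivity_at_spec90, digits = 4),
      "\n", sep = "")
  invisible(x)
}

# Ridge-penalized logistic regression by Newton-Raphson. The intercept is
# unpenalized; lambda is on the raw (unstandardized) feature scale. The small
# default penalty keeps coefficients finite under complete separation.
ridge_logistic <- function(X, y, lambda = 1e-6, max_iter = 100L,
                           tol = 1e-10) {
  X1 <- cbind(1, X)
  p <- ncol(X1)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- rep(0, p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X1 %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-12)
    grad <- drop(crossprod(X1, y - mu)) - drop(pen %*% beta)
    hess <- crossprod(X1 * w, X1) + pen
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
  }
  list(coefficients = drop(beta), converged = converged,
       linear_predictor = drop(cbind(1, X) %*% beta))
}

#' Combine the fucosylation ratio with AFP into one score
#'
#' Fits a two-feature binary logistic model on (log10 AFP, -log10 ratio) by
#' maximum likelihood with a small ridge penalty (lambda = 1e-6, intercept
#' unpenalized) that keeps the fit finite under complete separation. The
#' combined score is the fitted linear predictor; it is deterministic given
#' the data and invariant in ROC terms to the monotone logistic link.
#'
#' @param ratio fucosylation ratios (> 0; undefined ratios must be excluded
#'   upstream).
#' @param afp AFP concentrations in ng/mL (> 0).
#' @param labels outcome labels as in [roc_auc()] (TRUE / second level =
#'   disease).
#' @param lambda ridge penalty (default 1e-6).
#' @return A list with `score` (combined linear predictor per patient),
#'   `coefficients` (intercept, log10_afp, neg_log10_ratio), `features`, and
#'   `converged`.
#' @export
combine_with_afp <- function(ratio, afp, labels, lambda = 1e-6) {
  stopifnot(length(ratio) == length(afp), length(afp) == length(labels))
  if (any(!is.finite(ratio)) || any(ratio <= 0)) {
    stop("ratios must be positive and finite (exclude undefined ratios first)")
  }
  if (any(!is.finite(afp)) || any(afp <= 0)) {
    stop("AFP values must be positive and finite")
  }
  if (!is.logical(labels)) {
    lev <- sort(unique(labels))
    if (length(lev) != 2L) stop("labels must have exactly 2 classes")
    labels <- labels == lev[2L]
  }
  X <- cbind(log10_afp = log10(afp), neg_log10_ratio = -log10(ratio))
  fit <- ridge_logistic(X, as.numeric(labels), lambda = lambda)
  names(fit$coefficients) <- c("(Intercept)", "log10_afp", "neg_log10_ratio")
  list(score = fit$linear_predictor, coefficients = fit$coefficients,
       features = X, converged = fit$converged)
}

#' Evaluate candidate ratio markers over a cohort
#'
#' For each ratio column: a two-sided t-test between the two groups on the
#' -log10 ratio scale (undefined ratios excluded, exclusion counts reported),
#' Benjamini-Hochberg q-values across markers, the marker-alone AUC (score =
#' -log10 ratio, oriented so larger AUC-relevant scores indicate disease),
#' the AFP-alone AUC (score = log10 AFP), the combined AUC, and sensitivities
#' at 90% specificity. Raw p-values are reported alongside q-values.
#'
#' @param cohort a cohort data.frame with `group`, `afp_ng_ml` and the ratio
#'   columns; `group` must have exactly two levels, the second sorted level
#'   being the disease class.
#' @param ratio_cols names of the ratio columns to evaluate.
#' @param var_equal pooled-variance t-test when TRUE (default).
#' @return A data.frame, one row per marker, plus attribute `afp_auc`.
#' @export
evaluate_cohort <- function(cohort, ratio_cols, var_equal = TRUE) {
  lev <- sort(unique(cohort$group))
  if (length(lev) != 2L) {
    stop("cohort must contain exactly two groups (got ",
         paste(lev, collapse = ", "), ")")
  }
  disease <- cohort$group == lev[2L]
  afp_roc <- roc_auc(log10(cohort$afp_ng_ml), disease)
  rows <- lapply(ratio_cols, function(col) {
    ratio <- cohort[[col]]
    ok <- is.finite(ratio) & ratio > 0
    nl <- -log10(ratio[ok])
    grp <- disease[ok]
    cmp <- compare_groups(nl[!grp], nl[grp], var_equal = var_equal)
    # ratio increases with disease, so -log10 ratio decreases: score with the
    # ratio's own log scale oriented toward disease
    marker_roc <- roc_auc(log10(ratio[ok]), grp)
    comb <- combine_with_afp(ratio[ok], cohort$afp_ng_ml[ok], grp)
    comb_roc <- roc_auc(comb$score, grp)
    data.frame(
      marker = col, n_used = sum(ok), n_excluded = sum(!ok),
      mean_neg_log10_g1 = cmp$mean_x, mean_neg_log10_g2 = cmp$mean_y,
      t_statistic = cmp$statistic, p_value = cmp$p_value,
      auc_marker = marker_roc$auc, auc_afp = afp_roc$auc,
      auc_combined = comb_roc$auc,
      sens90_marker = marker_roc$sensitivity_at_spec90,
      sens90_afp = afp_roc$sensitivity_at_spec90,
      sens90_combined = comb_roc$sensitivity_at_spec90,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  attr(out, "afp_auc") <- afp_roc$auc
  attr(out, "groups") <- lev
  out
}
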