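#' Load the packaged 17-fistula cohort table
#'
#' Per-fistula anatomical and outflow variables of the 17 end-to-side AVFs
#' (10 radio-cephalic, 6 brachio-cephalic, 1 brachio-basilic; 13 successful,
#' 4 unsuccessful), as printed: mean feeding-artery and draining-vein
#' characteristics evaluated up to 10 cm along the centreline. Curvature
#' values are stored verbatim in the printed per-length units.
#'
#' @return `data.frame` with columns `patient_id`, `fistula_type`, `side`,
#'   `outcome`, `venous_outflow_ml_min`, `outflow_category`,
#'   `fa_diameter_mm`, `fa_curvature`, `dv_diameter_mm`, `dv_curvature`,
#'   `anastomosis_angle_deg`.
#' @export
load_avf_cohort <- function() {
  path <- system.file("extdata", "avf_cohort_17.csv", package = "avfflow",
                      mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, "8f76631ca98224f1adcb82c39abfe317"))
    stop("cohort fixture checksum mismatch: file corrupted")
  out <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(nrow(out) == 17L)
  out
}

#' Dichotomise venous outflow at a high-flow threshold
#'
#' @param cohort cohort `data.frame` with `venous_outflow_ml_min`.
#' @param threshold high-flow bound in ml/min; flows at or above it are
#'   `"High"` (the bound is inclusive).
#' @return character vector `"High"`/`"Low"` (NA where outflow missing).
#' @export
dichotomize_flow <- function(cohort, threshold = 1000) {
  q <- cohort$venous_outflow_ml_min
  ifelse(is.na(q), NA_character_, ifelse(q >= threshold, "High", "Low"))
}

cohort_numeric_vars <- function(cohort) {
  cand <- c("venous_outflow_ml_min", "fa_diameter_mm", "fa_curvature",
            "dv_diameter_mm", "dv_curvature", "anastomosis_angle_deg",
            "age", "bmi", "sbp", "hr")
  intersect(cand, names(cohort)[vapply(cohort, is.numeric, TRUE)])
}

grouping_factor <- function(cohort, grouping) {
  switch(grouping,
         outcome = factor(cohort$outcome, levels = c("S", "U")),
         outflow_category = factor(cohort$outflow_category,
                                   levels = c("High", "Low")),
         fistula_type = factor(ifelse(cohort$fistula_type == "RCF",
                                      "RCF", "other"),
                               levels = c("RCF", "other")),
         stop("grouping must be outcome, outflow_category or fistula_type"))
}

#' Per-group means and population SDs of cohort variables
#'
#' Summaries use the population SD convention (divisor n), which reproduces
#' the cohort table's printed dispersions. `fistula_type` compares
#' radio-cephalic against all other configurations.
#'
#' @param cohort cohort `data.frame`.
#' @param grouping `"outcome"`, `"outflow_category"` or `"fistula_type"`.
#' @param variables numeric columns to summarise (default: all standard).
#' @return `data.frame` of class `group_summary`: `variable`, `group`, `n`,
#'   `mean`, `sd`, and `difference` (first group minus second, repeated per
#'   variable). An extra derived variable `vein_minus_artery_diameter_mm` is
#'   included when both diameters are present.
#' @export
group_summary <- function(cohort, grouping = "outcome",
                          variables = NULL) {
  g <- grouping_factor(cohort, grouping)
  if (any(table(g) < 1L) || nlevels(g) < 2L) stop("each group needs >= 1 record")
  if (is.null(variables)) variables <- cohort_numeric_vars(cohort)
  dat <- cohort[variables]
  if (all(c("dv_diameter_mm", "fa_diameter_mm") %in% names(cohort)))
    dat$vein_minus_artery_diameter_mm <-
      cohort$dv_diameter_mm - cohort$fa_diameter_mm
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  rows <- list()
  for (v in names(dat)) {
    ms <- tapply(dat[[v]], g, mean)
    ss <- tapply(dat[[v]], g, pop_sd)
    ns <- tapply(dat[[v]], g, length)
    diff <- unname(ms[1] - ms[2])
    for (lev in levels(g)) {
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, group = lev, n = unname(ns[lev]),
        mean = unname(ms[lev]), sd = unname(ss[lev]), difference = diff,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "grouping") <- grouping
  class(out) <- c("group_summary", class(out))
  out
}

#' Mann-Whitney ROC analysis of a single variable
#'
#' AUC by exhaustive concordance: over all positive-negative pairs,
#' concordant pairs count 1 and ties 0.5 (the standard Mann-Whitney
#' convention), normalised by `n_pos * n_neg`. Orientation is chosen so the
#' reported AUC is >= 0.5, with the sign recorded (+1 when larger values
#' favour the positive class). The AUC is cross-checked against the
#' trapezoidal area under the empirical ROC curve, which it must equal.
#'
#' @param values numeric predictor.
#' @param labels binary class labels.
#' @param positive the label treated as positive (default: `"High"` if
#'   present, else the first level).
#' @param variable name recorded in the result.
#' @return object of class `roc_result`: `auc` (oriented), `auc_raw`,
#'   `orientation`, `curve` (`data.frame` of FPR/TPR), `n_pos`, `n_neg`,
#'   `n_tied_pairs`.
#' @export
mw_auc <- function(values, labels, positive = NULL, variable = "x") {
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- as.character(labels)[keep]
  ul <- unique(labels)
  if (length(ul) != 2L) stop("labels must have exactly two classes, both non-empty")
  if (is.null(positive)) positive <- if ("High" %in% ul) "High" else ul[1]
  pos <- labels == positive
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0L || nn == 0L) stop("one class is empty")
  r <- rank(values)
  u <- sum(r[pos]) - np * (np + 1) / 2
  auc_raw <- u / (np * nn)
  orientation <- if (auc_raw >= 0.5) 1L else -1L
  auc <- if (orientation == 1L) auc_raw else 1 - auc_raw
  n_tied <- sum(vapply(unique(values), function(v)
    sum(pos & values == v) * sum(!pos & values == v), 0))
  curve <- roc_curve_points(if (orientation == 1L) values else -values, pos)
  auc_trap <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                       utils::tail(curve$tpr, -1)) / 2)
  if (abs(auc_trap - auc) > 1e-10)
    stop("internal inconsistency: pairwise AUC != trapezoidal ROC area")
  structure(list(variable = variable, auc = auc, auc_raw = auc_raw,
                 orientation = orientation, curve = curve,
                 n_pos = np, n_neg = nn, n_tied_pairs = n_tied,
                 positive = positive),
            class = "roc_result")
}

roc_curve_points <- function(values, pos) {
  thr <- sort(unique(values), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) mean(values[pos] >= t), 0), 1)
  fpr <- c(0, vapply(thr, function(t) mean(values[!pos] >= t), 0), 1)
  data.frame(fpr = fpr, tpr = tpr)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC [%s]: AUC %.4f (orientation %+d, positive = %s, %d vs %d, %g tied pairs)\n",
              x$variable, x$auc, x$orientation, x$positive, x$n_pos, x$n_neg,
              x$n_tied_pairs))
  invisible(x)
}

#' Combined ROC of several variables via an in-sample logistic score
#'
#' Fits a logistic regression on standardised variables and reports the
#' Mann-Whitney AUC of its linear score. On non-convergence or separation
#' the fit falls back to a ridge-penalised logistic model (flagged in the
#' result). A seeded bootstrap percentile interval is available.
#'
#' @param cohort cohort `data.frame`.
#' @param variables character vector of >= 1 predictor columns (a single
#'   variable reduces to [mw_auc()] of that variable up to orientation).
#' @param labels binary labels (vector, or name of a cohort column).
#' @param positive positive class label.
#' @param resampling `"none"` or `"bootstrap"`.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed for the bootstrap.
#' @return a `roc_result` with extra fields `coefficients`, `penalised`,
#'   and (with bootstrap) `ci`.
#' @export
combined_auc <- function(cohort, variables, labels, positive = NULL,
                         resampling = c("none", "bootstrap"),
                         n_boot = 2000, seed = 1) {
  resampling <- match.arg(resampling)
  if (is.character(labels) && length(labels) == 1L) labels <- cohort[[labels]]
  labels <- as.character(labels)
  ul <- unique(labels)
  if (length(ul) != 2L) stop("labels must have exactly two classes")
  if (is.null(positive)) positive <- if ("High" %in% ul) "High" else ul[1]
  X <- scale(as.matrix(cohort[variables]))
  y <- as.integer(labels == positive)
  score_of <- function(X, y) {
    fit <- suppressWarnings(stats::glm.fit(cbind(1, X), y,
                                           family = stats::binomial()))
    separated <- !fit$converged || any(abs(fit$coefficients[-1]) > 15)
    if (separated) {
      if (!requireNamespace("glmnet", quietly = TRUE))
        stop("separated fit and glmnet unavailable for the penalised fallback")
      gf <- suppressWarnings(glmnet::glmnet(X, y, family = "binomial",
                                            alpha = 0, lambda = 1e-3))
      list(score = as.vector(stats::predict(gf, X)),
           coef = as.vector(stats::coef(gf)), penalised = TRUE)
    } else {
      list(score = as.vector(cbind(1, X) %*% fit$coefficients),
           coef = fit$coefficients, penalised = FALSE)
    }
  }
  sc <- score_of(X, y)
  res <- mw_auc(sc$score, labels, positive = positive,
                variable = paste(variables, collapse = "+"))
  res$coefficients <- sc$coef
  res$penalised <- sc$penalised
  if (resampling == "bootstrap") {
    set.seed(seed)
    n <- length(y)
    reps <- vapply(seq_len(n_boot), function(b) {
      repeat {
        idx <- sample.int(n, replace = TRUE)
        if (length(unique(y[idx])) == 2L) break
      }
      sb <- score_of(X[idx, , drop = FALSE], y[idx])
      mw_auc(sb$score, labels[idx], positive = positive)$auc
    }, 0)
    res$ci <- stats::quantile(reps, c(0.025, 0.975), names = FALSE)
  }
  res
}

#' Two-group comparisons of cohort variables
#'
#' Two-sided per-variable p-values by Wilcoxon rank-sum (default, with
#' normal approximation and tie correction) or Welch's t-test. The method
#' is recorded in the output; constant variables yield a missing p-value.
#'
#' @param cohort cohort `data.frame`.
#' @param grouping as in [group_summary()].
#' @param method `"ranksum"` or `"welch"`.
#' @param variables numeric columns to test.
#' @return `data.frame`: `variable`, `method`, `p_value`.
#' @export
compare_groups <- function(cohort, grouping = "outcome",
                           method = c("ranksum", "welch"),
                           variables = NULL) {
  method <- match.arg(method)
  g <- grouping_factor(cohort, grouping)
  if (method == "welch" && any(table(g) < 2L))
    stop("welch needs >= 2 records per group")
  if (is.null(variables)) variables <- cohort_numeric_vars(cohort)
  p <- vapply(variables, function(v) {
    x <- cohort[[v]][g == levels(g)[1]]
    y <- cohort[[v]][g == levels(g)[2]]
    if (stats::sd(c(x, y)) == 0) return(NA_real_)
    if (method == "ranksum")
      suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                          correct = TRUE)$p.value)
    else
      stats::t.test(x, y)$p.value
  }, 0)
  data.frame(variable = variables, method = method, p_value = unname(p),
             stringsAsFactors = FALSE)
}
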