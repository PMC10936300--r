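#' Paired ground-truth / prediction moment series
#'
#' @param y ground-truth moments in Nm.
#' @param yhat predicted moments in Nm (same length).
#' @param peak_moment normalization peak in Nm for N-RMSE; defaults to the
#'   maximum absolute ground-truth value. Conventionally the maximum
#'   ground-truth moment over a subject's prediction stance cycles.
#' @return An object of class `eval_series`.
#' @export
eval_series <- function(y, yhat, peak_moment = max(abs(y))) {
  if (length(y) != length(yhat)) {
    stop("y and yhat must have the same length", call. = FALSE)
  }
  if (length(y) < 2) stop("need at least 2 samples", call. = FALSE)
  if (!all(is.finite(y)) || !all(is.finite(yhat))) {
    stop("series must be finite", call. = FALSE)
  }
  structure(list(y = as.numeric(y), yhat = as.numeric(yhat),
                 N = length(y), peak_moment = peak_moment),
            class = "eval_series")
}

#' Regression (quadratic) loss: mean squared residual
#' @param series an [eval_series()].
#' @return `mean((y - yhat)^2)`; equals [rmse()] squared.
#' @export
regression_loss <- function(series) {
  stopifnot(inherits(series, "eval_series"))
  mean((series$y - series$yhat)^2)
}

#' Root mean square error in Nm
#' @param series an [eval_series()].
#' @return `sqrt(mean((y - yhat)^2))`.
#' @export
rmse <- function(series) {
  sqrt(regression_loss(series))
}

#' RMSE normalized to the peak ground-truth moment (N-RMSE)
#' @param series an [eval_series()] with `peak_moment > 0`.
#' @return Dimensionless `rmse / peak_moment`.
#' @export
n_rmse <- function(series) {
  stopifnot(inherits(series, "eval_series"))
  if (!is.finite(series$peak_moment) || series$peak_moment <= 0) {
    stop("peak_moment must be positive for N-RMSE", call. = FALSE)
  }
  rmse(series) / series$peak_moment
}

#' Coefficient of determination between truth and prediction
#'
#' The default (`"correlation"`) form is the squared Pearson correlation,
#' written out from the covariance sums about both series means; the
#' residual form `1 - SS_res / SS_tot` is available as an alternative. The
#' two coincide when the prediction-vs-truth fit is near the identity line.
#'
#' @param series an [eval_series()]; both series must be non-constant for
#'   the correlation form.
#' @param form `"correlation"` (default) or `"residual"`.
#' @return Dimensionless statistic (in \[0, 1\] for the correlation form).
#' @export
r_squared <- function(series, form = c("correlation", "residual")) {
  stopifnot(inherits(series, "eval_series"))
  form <- match.arg(form)
  y <- series$y; yh <- series$yhat
  if (form == "residual") {
    sst <- sum((y - mean(y))^2)
    if (sst == 0) stop("ground truth is constant", call. = FALSE)
    return(1 - sum((y - yh)^2) / sst)
  }
  dy <- y - mean(y)
  dh <- yh - mean(yh)
  sy <- sum(dy^2); sh <- sum(dh^2)
  if (sy == 0 || sh == 0) {
    stop("r_squared undefined for constant series", call. = FALSE)
  }
  sum(dy * dh)^2 / (sy * sh)
}

#' Ordinary least squares agreement of prediction with ground truth
#'
#' Regresses `yhat` on `y`; a perfect predictor gives slope 1, intercept 0
#' (the 45-degree reference line of the scatter plots).
#'
#' @param series an [eval_series()] with N >= 3 and non-constant `y`.
#' @return One-row tibble: `slope`, `slope_se`, `slope_p`, `intercept`,
#'   `intercept_se`, `intercept_p`, `r2`.
#' @export
linear_fit <- function(series) {
  stopifnot(inherits(series, "eval_series"))
  if (series$N < 3) stop("need N >= 3 for a linear fit", call. = FALSE)
  if (stats::sd(series$y) == 0) {
    stop("ground truth is constant (rank-deficient fit)", call. = FALSE)
  }
  fit <- stats::lm(yhat ~ y, data = list(y = series$y, yhat = series$yhat))
  cf <- summary(fit)$coefficients
  tibble::tibble(
    slope = cf["y", "Estimate"], slope_se = cf["y", "Std. Error"],
    slope_p = cf["y", "Pr(>|t|)"],
    intercept = cf["(Intercept)", "Estimate"],
    intercept_se = cf["(Intercept)", "Std. Error"],
    intercept_p = cf["(Intercept)", "Pr(>|t|)"],
    r2 = summary(fit)$r.squared
  )
}

#' Full evaluation report for one prediction series
#'
#' @param series an [eval_series()].
#' @param r2_form passed to [r_squared()].
#' @return One-row tibble: `n`, `loss`, `rmse`, `n_rmse`, `r2`, and the
#'   [linear_fit()] columns (the fit's own R^2 reported as `fit_r2`).
#' @export
eval_report <- function(series, r2_form = "correlation") {
  fit <- linear_fit(series)
  names(fit)[names(fit) == "r2"] <- "fit_r2"
  tibble::tibble(
    n = series$N,
    loss = regression_loss(series),
    rmse = rmse(series),
    n_rmse = n_rmse(series),
    r2 = r_squared(series, r2_form),
    fit
  )
}

sig_flag <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Normality-gated comparison of a metric across conditions
#'
#' Shapiro-Wilk tests each condition at alpha = .05; if all pass, the
#' parametric branch is used (one-way repeated-measures ANOVA + Tukey HSD
#' for 3+ conditions, paired t-test for 2), otherwise the nonparametric
#' branch (Friedman + Tukey-style mean-rank post hoc, Wilcoxon signed-rank
#' for 2). Pairwise p-values carry the usual `*`/`**`/`***` flags at
#' .05/.01/.001.
#'
#' @param metric_matrix `subjects x conditions` numeric matrix (column
#'   names name the conditions).
#' @param paired kept for interface symmetry; the design is within-subject,
#'   so comparisons are always paired.
#' @param alpha normality gate level.
#' @return An object of class `stats_report`: list with `normality`
#'   (tibble of SW p per condition), `branch`, `omnibus` (test, statistic,
#'   p), `pairwise` (tibble with p-values and flags).
#' @export
compare_groups <- function(metric_matrix, paired = TRUE, alpha = 0.05) {
  m <- as.matrix(metric_matrix)
  if (ncol(m) < 2) stop("need at least 2 conditions", call. = FALSE)
  if (nrow(m) < 3) stop("need at least 3 subjects", call. = FALSE)
  if (is.null(colnames(m))) colnames(m) <- paste0("C", seq_len(ncol(m)))
  k <- ncol(m); n <- nrow(m)

  sw <- apply(m, 2, function(col) {
    if (stats::sd(col) == 0) return(NA_real_)  # SW undefined; treat as normal
    stats::shapiro.test(col)$p.value
  })
  normality <- tibble::tibble(condition = colnames(m), sw_p = sw)
  parametric <- all(is.na(sw) | sw > alpha)

  pairs_idx <- utils::combn(k, 2)
  if (max(abs(m - m[, 1])) == 0) {
    # all conditions identical: no test statistic is defined, and no
    # difference can be declared anywhere
    pairwise <- tibble::tibble(
      a = colnames(m)[pairs_idx[1, ]], b = colnames(m)[pairs_idx[2, ]],
      estimate = 0, p = 1, flag = "")
    return(structure(list(
      normality = normality,
      branch = if (parametric) "parametric" else "nonparametric",
      omnibus = list(test = "degenerate (identical conditions)",
                     statistic = NA_real_, p = 1),
      pairwise = pairwise), class = "stats_report"))
  }
  if (k == 2) {
    if (parametric) {
      tt <- stats::t.test(m[, 1], m[, 2], paired = TRUE)
      omnibus <- list(test = "paired t-test",
                      statistic = unname(tt$statistic), p = tt$p.value)
    } else {
      tt <- stats::wilcox.test(m[, 1], m[, 2], paired = TRUE, exact = FALSE)
      omnibus <- list(test = "Wilcoxon signed-rank",
                      statistic = unname(tt$statistic), p = tt$p.value)
    }
    pairwise <- tibble::tibble(
      a = colnames(m)[1], b = colnames(m)[2],
      estimate = mean(m[, 1] - m[, 2]), p = omnibus$p,
      flag = sig_flag(omnibus$p)
    )
  } else if (parametric) {
    long <- data.frame(
      value = as.vector(m),
      condition = factor(rep(colnames(m), each = n), levels = colnames(m)),
      subject = factor(rep(seq_len(n), k))
    )
    # sum-to-zero contrasts up front so emmeans does not refit the aovlist
    old_opts <- options(contrasts = c("contr.sum", "contr.poly"))
    on.exit(options(old_opts), add = TRUE)
    fit <- stats::aov(value ~ condition + Error(subject), data = long)
    tab <- summary(fit)[["Error: Within"]][[1]]
    omnibus <- list(test = "one-way RM-ANOVA",
                    statistic = tab["condition", "F value"],
                    p = tab["condition", "Pr(>F)"])
    em <- emmeans::emmeans(fit, "condition", data = long)
    pr <- as.data.frame(emmeans::contrast(em, "pairwise", adjust = "tukey"))
    ab <- strsplit(as.character(pr$contrast), " - ", fixed = TRUE)
    pairwise <- tibble::tibble(
      a = vapply(ab, `[`, character(1), 1L),
      b = vapply(ab, `[`, character(1), 2L),
      estimate = pr$estimate, p = pr$p.value, flag = sig_flag(pr$p.value)
    )
  } else {
    fr <- stats::friedman.test(m)
    omnibus <- list(test = "Friedman",
                    statistic = unname(fr$statistic), p = fr$p.value)
    # Tukey-style comparison of mean within-subject ranks (Nemenyi)
    rk <- t(apply(m, 1, rank))
    rbar <- colMeans(rk)
    se <- sqrt(k * (k + 1) / (6 * n))
    pairwise <- tibble::tibble(
      a = colnames(m)[pairs_idx[1, ]], b = colnames(m)[pairs_idx[2, ]],
      estimate = rbar[pairs_idx[1, ]] - rbar[pairs_idx[2, ]]
    )
    q <- abs(pairwise$estimate) / se * sqrt(2)
    pairwise$p <- stats::ptukey(q, k, Inf, lower.tail = FALSE)
    pairwise$flag <- sig_flag(pairwise$p)
  }

  structure(list(normality = normality,
                 branch = if (parametric) "parametric" else "nonparametric",
                 omnibus = omnibus, pairwise = pairwise),
            class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat(sprintf("<stats_report> branch: %s; omnibus %s: stat %.4g, p %.4g\n",
              x$branch, x$omnibus$test, x$omnibus$statistic, x$omnibus$p))
  print(x$pairwise)
  invisible(x)
}
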