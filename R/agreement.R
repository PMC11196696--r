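#' Paired two-sample t-test with Cohen's d
#'
#' Tests whether two paired sets of per-walk measurements differ in
#' mean: `t = mean(a - b) / (sd(a - b) / sqrt(n))` with `n - 1` degrees
#' of freedom and a two-sided p-value (delegated to [stats::t.test()]).
#' Cohen's d for paired data is reported as the magnitude
#' `|mean(d)| / sd(d)`; a pooled-SD variant is available for comparison
#' with unpaired conventions.
#'
#' @param a,b Equal-length numeric vectors (n >= 2) of paired values.
#' @param d_method `"paired"` (default, `mean(d)/sd(d)`) or `"pooled"`
#'   (`mean(d)` over the pooled SD of `a` and `b`).
#' @return A list with `t`, `dof`, `p`, `d`, `mean_diff`, `sd_diff`,
#'   `degenerate` (TRUE when the differences have zero variance but a
#'   non-zero mean, in which case `t` is infinite).
#' @export
paired_ttest <- function(a, b, d_method = c("paired", "pooled")) {
  d_method <- match.arg(d_method)
  stopifnot(length(a) == length(b), length(a) >= 2L)
  diffs <- a - b
  n <- length(diffs)
  md <- mean(diffs)
  sdd <- stats::sd(diffs)
  if (sdd == 0) {
    if (md == 0)
      return(list(t = 0, dof = n - 1L, p = 1, d = 0, mean_diff = 0,
                  sd_diff = 0, degenerate = FALSE))
    return(list(t = sign(md) * Inf, dof = n - 1L, p = 0, d = Inf,
                mean_diff = md, sd_diff = 0, degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  denom <- if (d_method == "paired") sdd
           else sqrt((stats::var(a) + stats::var(b)) / 2)
  list(t = unname(tt$statistic), dof = unname(tt$parameter),
       p = tt$p.value, d = abs(md) / denom, mean_diff = md, sd_diff = sdd,
       degenerate = FALSE)
}

#' Simple linear regression with F-test
#'
#' Ordinary least squares of `y` on `x` via [stats::lm()]. Reports the
#' slope, intercept, coefficient of determination, and the model F-test
#' (`F = (n - 2) * R^2 / (1 - R^2)` on 1 and `n - 2` degrees of
#' freedom). For simple regression `R^2` equals the squared Pearson
#' correlation of `x` and `y`.
#'
#' @param x,y Numeric vectors, `n >= 3`, `var(x) > 0`.
#' @return A list with `slope`, `intercept`, `r_squared`, `f_stat`,
#'   `f_p`, `n`.
#' @export
simple_regression <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::var(x) == 0) stop("'x' is constant: regression undefined")
  fit <- stats::lm(y ~ x)
  # summary.lm warns on an essentially perfect fit; exact linear data
  # are a legitimate input here (r = 1 check data)
  sm <- suppressWarnings(summary(fit))
  fst <- sm$fstatistic
  fp <- if (is.null(fst)) NA_real_
        else stats::pf(fst[["value"]], fst[["numdf"]], fst[["dendf"]],
                       lower.tail = FALSE)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = sm$r.squared,
       f_stat = if (is.null(fst)) NA_real_ else unname(fst[["value"]]),
       f_p = fp, n = length(x))
}

#' Pearson correlation with Fisher confidence interval
#'
#' Product-moment correlation with a confidence interval from the
#' Fisher z-transform (`se_z = 1 / sqrt(n - 3)`), as computed by
#' [stats::cor.test()]. The standard error of r itself is reported as
#' `sqrt((1 - r^2) / (n - 2))`.
#'
#' @param x,y Numeric vectors, `n >= 4`, both non-constant.
#' @param level Confidence level (default 0.95).
#' @return A list with `r`, `se`, `ci_low`, `ci_high`, `p`, `n`.
#' @export
pearson_ci <- function(x, y, level = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 4L)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("constant input: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = level)
  r <- unname(ct$estimate)
  n <- length(x)
  list(r = r, se = sqrt((1 - r^2) / (n - 2)),
       ci_low = ct$conf.int[1L], ci_high = ct$conf.int[2L],
       p = ct$p.value, n = n)
}

#' Bland-Altman agreement analysis
#'
#' For paired measurements the differences `d = a - b` are summarized by
#' their mean (the bias) and the limits of agreement
#' `bias +/- k * sd(d)` (sample SD, `n - 1` denominator; `k = 1.96`
#' encompasses ~95% of differences under normality). The returned table
#' of per-pair means and differences is the standard Bland-Altman
#' plotting data.
#'
#' @param a,b Equal-length numeric vectors (n >= 2).
#' @param k Multiplier for the limits of agreement (default 1.96).
#' @return A list with `bias`, `loa_low`, `loa_high`, `sd_diff`, and
#'   `table` (a data.frame with columns `mean` and `diff`).
#' @export
bland_altman <- function(a, b, k = 1.96) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_low = bias - k * s, loa_high = bias + k * s,
       sd_diff = s,
       table = data.frame(mean = (a + b) / 2, diff = d))
}

#' Full agreement report for one gait parameter
#'
#' Bundles the paired t-test, simple regression, Pearson correlation and
#' Bland-Altman summaries comparing measurement system `a` against
#' reference `b` across walks.
#'
#' @param a,b Equal-length numeric vectors of per-walk values (n >= 4).
#' @param parameter_name Label for the parameter being compared.
#' @return Object of class `agreement_report`: a list with
#'   `parameter_name`, `n`, descriptive statistics (`mean_a`, `sd_a`,
#'   `mean_b`, `sd_b`), and the four analysis blocks `ttest`,
#'   `regression`, `pearson`, `bland_altman`.
#' @export
agreement_report <- function(a, b, parameter_name = "parameter") {
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  stopifnot(length(a) >= 4L)
  structure(
    list(parameter_name = parameter_name, n = length(a),
         mean_a = mean(a), sd_a = stats::sd(a),
         mean_b = mean(b), sd_b = stats::sd(b),
         ttest = paired_ttest(a, b),
         regression = simple_regression(b, a),
         pearson = pearson_ci(b, a),
         bland_altman = bland_altman(a, b)),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %s (n = %d walks)\n", x$parameter_name,
              x$n))
  cat(sprintf("  means            %0.4f vs %0.4f (SD %0.4f / %0.4f)\n",
              x$mean_a, x$mean_b, x$sd_a, x$sd_b))
  cat(sprintf("  paired t(%d)     t = %0.3f, p = %0.3f, d = %0.3f\n",
              x$ttest$dof, x$ttest$t, x$ttest$p, x$ttest$d))
  cat(sprintf("  regression       slope %0.3f, R^2 = %0.3f, F = %0.1f\n",
              x$regression$slope, x$regression$r_squared,
              x$regression$f_stat))
  cat(sprintf("  Pearson r        %0.3f [%0.3f, %0.3f]\n",
              x$pearson$r, x$pearson$ci_low, x$pearson$ci_high))
  cat(sprintf("  Bland-Altman     bias %0.4f, LoA [%0.4f, %0.4f]\n",
              x$bland_altman$bias, x$bland_altman$loa_low,
              x$bland_altman$loa_high))
  invisible(x)
}

#' Bland-Altman plot
#'
#' @param report An [agreement_report()] or the result of
#'   [bland_altman()].
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(report, title = NULL) {
  ba <- if (inherits(report, "agreement_report")) report$bland_altman
        else report
  if (is.null(title) && inherits(report, "agreement_report"))
    title <- report$parameter_name
  ggplot2::ggplot(ba$table, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = ba$bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "Mean of paired measurements",
                  y = "Difference (a - b)", title = title) +
    ggplot2::theme_minimal()
}

#' Agreement regression plot
#'
#' Scatter of system-a values against the reference with the fitted line
#' and the identity line.
#'
#' @param a,b Paired per-walk values (a = test system, b = reference).
#' @param parameter_name Axis/plot label.
#' @return A ggplot object.
#' @export
plot_agreement_regression <- function(a, b, parameter_name = "parameter") {
  df <- data.frame(reference = b, measured = a)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$reference,
                                   y = .data$measured)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(x = paste(parameter_name, "(reference)"),
                  y = paste(parameter_name, "(seismograph)"),
                  title = parameter_name) +
    ggplot2::theme_minimal()
}
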