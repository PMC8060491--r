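#' Two-tailed t-test (two-sample or paired)
#'
#' Shared statistical kernel used by all group comparisons in the package.
#' The default is the classic pooled-variance (Student) two-sample test;
#' Welch's unequal-variance form and the paired design are available.
#'
#' Degenerate inputs follow a fixed convention: when the pooled variance is
#' zero and the group means are equal the test is uninformative and returns
#' `t = 0`, `p = 1`; zero variance with unequal means is an error, since the
#' statistic is unbounded.
#'
#' @param a,b numeric vectors of observations (each length >= 2; equal
#'   lengths required for the paired design). Non-finite values are rejected.
#' @param design `"two_sample"` or `"paired"`.
#' @param variance `"pooled"` (Student) or `"welch"`; ignored for paired.
#' @return An object of class `vf_t_test`: a list with `t_statistic`,
#'   `degrees_of_freedom`, `p_two_tailed`, `design`, `variance_assumption`,
#'   and per-group `n`, `mean`, `sd`, `sem`.
#' @examples
#' t_test_groups(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))$t_statistic  # -1
#' @export
t_test_groups <- function(a, b,
                          design = c("two_sample", "paired"),
                          variance = c("pooled", "welch")) {
  design <- match.arg(design)
  variance <- match.arg(variance)
  check_finite_vector(a, "a", min_len = 2)
  check_finite_vector(b, "b", min_len = 2)
  if (design == "paired")
    vf_check(length(a) == length(b), "vascflow_pairing_error",
             "paired design requires equal-length groups")

  # treat variances at floating-point dust level as zero (the t statistic
  # would be meaningless noise amplification)
  scale_ref <- max(abs(mean(a)), abs(mean(b)), 1)
  tiny <- (1e-10 * scale_ref)^2
  degenerate <- if (design == "paired") {
    stats::var(a - b) <= tiny
  } else {
    stats::var(a) <= tiny && stats::var(b) <= tiny
  }
  if (degenerate) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      df <- if (design == "paired") length(a) - 1 else length(a) + length(b) - 2
      res <- list(t_statistic = 0, degrees_of_freedom = df, p_two_tailed = 1)
    } else {
      vf_error("vascflow_degenerate_error",
               "zero variance with unequal means: t statistic is unbounded")
    }
  } else {
    ht <- stats::t.test(a, b, paired = design == "paired",
                        var.equal = variance == "pooled",
                        alternative = "two.sided")
    res <- list(t_statistic = unname(ht$statistic),
                degrees_of_freedom = unname(ht$parameter),
                p_two_tailed = unname(ht$p.value))
  }
  structure(c(res, list(
    design = design,
    variance_assumption = if (design == "paired") "paired" else variance,
    n = c(length(a), length(b)),
    mean = c(mean(a), mean(b)),
    sd = c(stats::sd(a), stats::sd(b)),
    sem = c(stats::sd(a) / sqrt(length(a)), stats::sd(b) / sqrt(length(b)))
  )), class = "vf_t_test")
}

#' @export
print.vf_t_test <- function(x, ...) {
  cat(sprintf("%s two-tailed t-test (%s)\n", x$design, x$variance_assumption))
  cat(sprintf("  group means: %.4g vs %.4g (n = %d, %d)\n",
              x$mean[1], x$mean[2], x$n[1], x$n[2]))
  cat(sprintf("  t = %.4g, df = %.4g, p = %.4g\n",
              x$t_statistic, x$degrees_of_freedom, x$p_two_tailed))
  invisible(x)
}

#' Ordinary least squares on log-transformed data
#'
#' Fits `log(y) ~ log(x)` by OLS. The slope is the power-law exponent of
#' `y = c * x^slope`, the standard parameterization for allometric and
#' branching relations.
#'
#' @param x,y strictly positive numeric vectors of equal length (n >= 3).
#' @return list with `slope`, `intercept` (natural-log units), `stderr`
#'   (standard error of the slope), `r_squared` and `n`.
#' @examples
#' ols_loglog(1:10, (1:10)^3)$slope  # 3
#' @export
ols_loglog <- function(x, y) {
  check_finite_vector(x, "x", min_len = 3)
  check_finite_vector(y, "y", min_len = 3)
  vf_check(length(x) == length(y), "vascflow_parameter_error",
           "x and y must have equal length")
  vf_check(all(x > 0) && all(y > 0), "vascflow_domain_error",
           "log-log fit requires strictly positive x and y")
  fit <- stats::lm(log(y) ~ log(x))
  # exact power-law inputs trigger a harmless perfect-fit warning in
  # summary.lm; the zero standard error it reports is the right answer
  sm <- suppressWarnings(summary(fit))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       stderr = unname(sm$coefficients[2, "Std. Error"]),
       r_squared = sm$r.squared,
       n = length(x))
}
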