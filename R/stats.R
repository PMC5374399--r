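#' Summary statistics with confidence intervals
#'
#' Mirrors the statistical reporting style of the analysis workflow: for a
#' numeric sample, mean, sample sd, t-based 95% confidence interval and an
#' optional one-sample Student t-test against a null mean; for counts
#' `(k, n)`, the percentage with a Wilson score 95% confidence interval.
#'
#' @param values numeric sample (for mean/CI/t-test), or `NULL` when `k`
#'   and `n` are given.
#' @param k,n successes and trials for a proportion summary.
#' @param null_mean optional null hypothesis mean for a one-sample t-test.
#' @param conf confidence level.
#' @return an object of class `stat_summary`.
#' @examples
#' summary_stats(k = 22, n = 26)$percent   # 84.6% diploid embryos
#' @export
summary_stats <- function(values = NULL, k = NULL, n = NULL,
                          null_mean = NULL, conf = 0.95) {
  if (!is.null(values)) {
    stopifnot(length(values) >= 2L)
    m <- mean(values); s <- stats::sd(values)
    nn <- length(values)
    if (s == 0) {
      warning("degenerate variance: all values identical")
      ci <- c(m, m)
      t_stat <- NA_real_
      p <- if (is.null(null_mean)) NA_real_ else if (m == null_mean) 1 else 0
    } else {
      tt <- stats::t.test(values, mu = if (is.null(null_mean)) 0 else
        null_mean, conf.level = conf)
      ci <- as.numeric(tt$conf.int)
      t_stat <- if (is.null(null_mean)) NA_real_ else unname(tt$statistic)
      p <- if (is.null(null_mean)) NA_real_ else tt$p.value
    }
    out <- list(type = "mean", n = nn, mean = m, sd = s, conf = conf,
                ci = ci, null_mean = null_mean, t = t_stat, p = p)
  } else {
    stopifnot(!is.null(k), !is.null(n), k >= 0, n >= 1, k <= n)
    p_hat <- k / n
    z <- stats::qnorm(1 - (1 - conf) / 2)
    den <- 1 + z^2 / n
    centre <- (p_hat + z^2 / (2 * n)) / den
    half <- z * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2)) / den
    out <- list(type = "proportion", k = k, n = n,
                percent = 100 * p_hat, conf = conf,
                ci = 100 * c(max(0, centre - half), min(1, centre + half)))
  }
  structure(out, class = "stat_summary")
}

#' @export
print.stat_summary <- function(x, ...) {
  if (x$type == "mean") {
    cat(sprintf("<stat_summary> n = %d: mean %.4g +/- sd %.4g, %g%% CI [%.4g, %.4g]\n",
                x$n, x$mean, x$sd, 100 * x$conf, x$ci[1], x$ci[2]))
    if (!is.null(x$null_mean) && !is.na(x$p))
      cat(sprintf("  one-sample t vs %.4g: t = %.3f, p = %.4g\n",
                  x$null_mean, x$t, x$p))
  } else {
    cat(sprintf("<stat_summary> %d / %d = %.1f%%, %g%% Wilson CI [%.1f%%, %.1f%%]\n",
                x$k, x$n, x$percent, 100 * x$conf, x$ci[1], x$ci[2]))
  }
  invisible(x)
}
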