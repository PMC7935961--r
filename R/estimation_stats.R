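# Group comparison in the estimation-statistics style used for the in vivo
# colony counts and tumour volumes: a percentile bootstrap confidence
# interval of the mean difference (the Gardner-Altman effect-size panel) and
# the unpaired t-test with Welch's correction.

#' Bootstrap confidence interval of a mean difference
#'
#' Resamples each group with replacement `n_boot` times, forms the difference
#' of resampled means (B - A), and reports the percentile interval at the
#' requested level. The full resampled-difference distribution is retained
#' for estimation plots. Deterministic under `seed`.
#'
#' @param a,b numeric samples, each of size >= 2.
#' @param n_boot bootstrap resamples (default 5000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return A list of class `estimation_result`: `n_a`, `n_b`,
#'   `mean_difference` (B - A), `ci_low`, `ci_high`, `level`, `n_boot`,
#'   `ci_method` (`"percentile"`), `resamples`, `seed`.
#' @export
bootstrap_mean_difference <- function(a, b, n_boot = 5000L, level = 0.95,
                                      seed = 1L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations")
  if (n_boot < 1L) stop("n_boot must be >= 1")
  with_phantom_seed(seed, {
    deltas <- vapply(seq_len(n_boot), function(i) {
      mean(sample(b, replace = TRUE)) - mean(sample(a, replace = TRUE))
    }, numeric(1))
    alpha <- (1 - level) / 2
    ci <- unname(stats::quantile(deltas, c(alpha, 1 - alpha), type = 7))
    structure(list(n_a = length(a), n_b = length(b),
                   mean_difference = mean(b) - mean(a),
                   ci_low = ci[1L], ci_high = ci[2L],
                   level = level, n_boot = as.integer(n_boot),
                   ci_method = "percentile",
                   resamples = deltas, seed = seed),
              class = "estimation_result")
  })
}

#' @export
print.estimation_result <- function(x, ...) {
  cat(sprintf(
    "<estimation_result> mean difference (B - A) = %.4g, %.0f%% CI [%.4g, %.4g] (%s, %d resamples)\n",
    x$mean_difference, 100 * x$level, x$ci_low, x$ci_high, x$ci_method,
    x$n_boot))
  invisible(x)
}

#' Unpaired t-test with Welch's correction
#'
#' t = (mean(a) - mean(b)) / sqrt(s2a/na + s2b/nb) with sample variances,
#' degrees of freedom by Welch-Satterthwaite, two-sided p-value from the t
#' distribution (delegated to [stats::t.test()]).
#'
#' @param a,b numeric samples, each of size >= 2 and not both constant.
#' @return A list of class `welch_result`: `t`, `df`, `p_value`,
#'   `mean_difference` (A - B).
#' @export
welch_t_test <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("both groups have zero variance; the t statistic is undefined")
  ht <- stats::t.test(a, b, var.equal = FALSE)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value,
                 mean_difference = mean(a) - mean(b)),
            class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("<welch_result> t = %.4f, df = %.3f, p = %.4g\n",
              x$t, x$df, x$p_value))
  invisible(x)
}

#' Gardner-Altman style estimation plot
#'
#' Raw observations of both groups on the left, the resampled mean-difference
#' distribution with its confidence interval on the right. Presentation only;
#' all quantitative results come from [bootstrap_mean_difference()].
#'
#' @param result an `estimation_result`.
#' @param a,b the raw samples that produced it.
#' @param labels group labels.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_estimation <- function(result, a, b, labels = c("A", "B")) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_estimation requires the ggplot2 package")
  raw <- data.frame(group = rep(labels, c(length(a), length(b))),
                    value = c(a, b))
  boot <- data.frame(delta = result$resamples)
  p1 <- ggplot2::ggplot(raw, ggplot2::aes(x = group, y = value)) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.3) +
    ggplot2::labs(x = NULL, y = "value")
  p2 <- ggplot2::ggplot(boot, ggplot2::aes(x = delta)) +
    ggplot2::geom_density(fill = "grey70", alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(result$ci_low, result$ci_high),
                        linetype = 2) +
    ggplot2::geom_vline(xintercept = result$mean_difference) +
    ggplot2::labs(x = sprintf("mean difference (%s - %s)",
                              labels[2], labels[1]), y = "density")
  list(raw = p1, effect = p2)
}
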