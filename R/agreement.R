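#' Paired measurement series
#'
#' Two equal-length series of the same functional parameter measured by two
#' methods on the same subjects (e.g. semiautomatic vs. manual EDV).
#'
#' @param values_a,values_b numeric vectors of equal length (n >= 3), no
#'   missing values, same units.
#' @param label parameter name, one of `"EDV"`, `"ESV"`, `"EF"`.
#' @param units measurement units (`"mL"` or `"%"`); inferred from the label
#'   when omitted.
#' @return an object of class `paired_series`.
#' @export
paired_series <- function(values_a, values_b, label = c("EDV", "ESV", "EF"),
                          units = NULL) {
  label <- match.arg(label)
  if (length(values_a) != length(values_b))
    cardioseg_error("paired series must have equal length",
                    class = "cardioseg_stats_error")
  if (length(values_a) < 3L)
    cardioseg_error("paired series need at least 3 observations",
                    class = "cardioseg_stats_error")
  if (anyNA(values_a) || anyNA(values_b))
    cardioseg_error("paired series must not contain missing values",
                    class = "cardioseg_stats_error")
  if (is.null(units)) units <- if (label == "EF") "%" else "mL"
  structure(list(values_a = as.numeric(values_a),
                 values_b = as.numeric(values_b),
                 label = label, units = units, n = length(values_a)),
            class = "paired_series")
}

#' Pearson product-moment correlation of a paired series
#'
#' @param series a [paired_series()].
#' @return the correlation coefficient r.
#' @export
pearson_r <- function(series) {
  stopifnot(inherits(series, "paired_series"))
  if (stats::sd(series$values_a) == 0 || stats::sd(series$values_b) == 0)
    cardioseg_error("correlation is undefined for a constant series",
                    class = "cardioseg_stats_error")
  stats::cor(series$values_a, series$values_b)
}

#' Two-tailed paired t-test
#'
#' Tests the null hypothesis of no difference between the two methods,
#' `t = mean(d) / (sd(d) / sqrt(n))` with `d = a - b` and the sample
#' (n - 1) standard deviation, against Student's t with n - 1 degrees of
#' freedom.
#'
#' @param series a [paired_series()].
#' @return list with `t`, `p_two_tailed`, `df`.
#' @export
paired_t <- function(series) {
  stopifnot(inherits(series, "paired_series"))
  d <- series$values_a - series$values_b
  if (stats::sd(d) == 0)
    cardioseg_error("paired t-test is degenerate: all differences are equal",
                    class = "cardioseg_stats_error")
  ht <- stats::t.test(series$values_a, series$values_b, paired = TRUE)
  list(t = unname(ht$statistic), p_two_tailed = ht$p.value,
       df = unname(ht$parameter))
}

# Lilliefors-style KS distance of a sample from the normal with
# parameters estimated from the sample itself.
lilliefors_D <- function(values) {
  n <- length(values)
  z <- sort((values - mean(values)) / stats::sd(values))
  u <- stats::pnorm(z)
  i <- seq_len(n)
  max(i / n - u, u - (i - 1) / n)
}

#' Kolmogorov-Smirnov normality check (estimated parameters)
#'
#' One-sample KS statistic of the data against a normal distribution with
#' the sample mean and standard deviation.  Because the parameters are
#' estimated from the data, the classical KS null distribution does not
#' apply; the p-value is obtained by Monte-Carlo simulation of the null
#' (fixed internal seed, reproducible).
#'
#' @param values numeric vector, n >= 3, non-constant.
#' @param mc_reps Monte-Carlo replicates (default 10000).
#' @param mc_seed seed for the null simulation (default 1); the caller's RNG
#'   state is untouched.
#' @return list with `D` (the KS statistic) and `p`.
#' @export
ks_normality <- function(values, mc_reps = 10000L, mc_seed = 1L) {
  if (length(values) < 3L)
    cardioseg_error("normality check needs at least 3 observations",
                    class = "cardioseg_stats_error")
  if (stats::sd(values) == 0)
    cardioseg_error("normality check is undefined for constant data",
                    class = "cardioseg_stats_error")
  D <- lilliefors_D(values)
  n <- length(values)
  exceed <- with_seed(mc_seed, {
    sum(vapply(seq_len(mc_reps),
               function(i) lilliefors_D(stats::rnorm(n)) >= D,
               logical(1)))
  })
  list(D = D, p = (exceed + 1) / (mc_reps + 1))
}

#' Bland-Altman bias and 95% limits of agreement
#'
#' @param series a [paired_series()].
#' @return list with `bias` (mean of a - b), `sd_diff` (sample sd of the
#'   differences), `loa_low`, `loa_high` (bias -/+ 1.96 sd), and
#'   `coverage_fraction` (fraction of differences inside the limits).
#' @export
bland_altman <- function(series) {
  stopifnot(inherits(series, "paired_series"))
  d <- series$values_a - series$values_b
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  loa_low <- bias - 1.96 * sd_diff
  loa_high <- bias + 1.96 * sd_diff
  list(bias = bias, sd_diff = sd_diff,
       loa_low = loa_low, loa_high = loa_high,
       coverage_fraction = mean(d >= loa_low & d <= loa_high))
}

#' Clinical relevance of a measurement bias
#'
#' A difference of at least 10 mL in EDV or ESV, or at least 3 percentage
#' points in EF, is considered clinically relevant (inclusive thresholds).
#'
#' @param bias mean difference, in the parameter's units.
#' @param label `"EDV"`, `"ESV"` or `"EF"`.
#' @return logical.
#' @export
clinical_relevance <- function(bias, label) {
  if (!label %in% c("EDV", "ESV", "EF"))
    cardioseg_error(sprintf("unknown parameter label '%s'", label),
                    class = "cardioseg_stats_error")
  threshold <- if (label == "EF") 3 else 10
  abs(bias) >= threshold
}

#' Full method-agreement report for a paired series
#'
#' Bundles the normality check of both series, Pearson correlation, paired
#' t-test, Bland-Altman analysis and the clinical-relevance flag.
#'
#' @param series a [paired_series()].
#' @param mc_reps,mc_seed passed to [ks_normality()].
#' @return an `agreement_report`: list with `label`, `units`, `n`, `r`,
#'   `t_stat`, `p_two_tailed`, `df`, `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `ks_p_a`, `ks_p_b`, `clinically_relevant`.
#' @export
agreement_report <- function(series, mc_reps = 10000L, mc_seed = 1L) {
  stopifnot(inherits(series, "paired_series"))
  tt <- paired_t(series)
  ba <- bland_altman(series)
  structure(list(
    label = series$label, units = series$units, n = series$n,
    r = pearson_r(series),
    t_stat = tt$t, p_two_tailed = tt$p_two_tailed, df = tt$df,
    bias = ba$bias, sd_diff = ba$sd_diff,
    loa_low = ba$loa_low, loa_high = ba$loa_high,
    ks_p_a = ks_normality(series$values_a, mc_reps, mc_seed)$p,
    ks_p_b = ks_normality(series$values_b, mc_reps, mc_seed)$p,
    clinically_relevant = clinical_relevance(ba$bias, series$label)
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("agreement_report: %s (%s), n = %d\n", x$label, x$units, x$n))
  cat(sprintf("  r = %.3f   paired t = %.3f (df %d, p = %.3f)\n",
              x$r, x$t_stat, x$df, x$p_two_tailed))
  cat(sprintf("  bias %.2f %s, 95%% LoA [%.2f, %.2f]\n",
              x$bias, x$units, x$loa_low, x$loa_high))
  cat(sprintf("  KS normality p: %.3f / %.3f   clinically relevant: %s\n",
              x$ks_p_a, x$ks_p_b, x$clinically_relevant))
  invisible(x)
}

#' Compare two per-patient measurement tables
#'
#' Runs [agreement_report()] for EDV, ESV and EF given two data frames with
#' columns `patient_id`, `EDV_ml`, `ESV_ml`, `EF_percent` (method A and
#' method B), matched on `patient_id`.
#'
#' @param df_a,df_b data frames as described above.
#' @param mc_reps,mc_seed passed to [ks_normality()].
#' @return named list of `agreement_report`s (`EDV`, `ESV`, `EF`).
#' @export
compare_methods <- function(df_a, df_b, mc_reps = 10000L, mc_seed = 1L) {
  need <- c("patient_id", "EDV_ml", "ESV_ml", "EF_percent")
  for (nm in need)
    if (!nm %in% names(df_a) || !nm %in% names(df_b))
      cardioseg_error(sprintf("both tables need a '%s' column", nm),
                      class = "cardioseg_stats_error")
  m <- match(df_a$patient_id, df_b$patient_id)
  if (anyNA(m))
    cardioseg_error("patient_id sets do not match between the two tables",
                    class = "cardioseg_stats_error")
  df_b <- df_b[m, ]
  cols <- c(EDV = "EDV_ml", ESV = "ESV_ml", EF = "EF_percent")
  out <- lapply(names(cols), function(lab) {
    agreement_report(paired_series(df_a[[cols[[lab]]]], df_b[[cols[[lab]]]],
                                   label = lab),
                     mc_reps, mc_seed)
  })
  names(out) <- names(cols)
  out
}
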