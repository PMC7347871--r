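#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Cq on log10(input copies), replicates pooled
#' across experiments (the final curve is the average over all runs).
#' Amplification efficiency is \eqn{E = 10^{-1/slope} - 1}; the curve passes
#' QC when E is between 90 and 110 percent.
#'
#' @param dilutions A data frame with columns `copies` (known input copies)
#'   and `cq`, one row per replicate well; a `target` column is carried
#'   through if present (the frame must then contain a single target).
#' @return An object of class `standard_curve`: list with `target`, `slope`,
#'   `intercept_cq` (Cq at 1 copy), `r_squared`, `efficiency`, `qc_pass`,
#'   `n_points`, `sigma_cq` (residual SD) and the underlying `lm` fit.
#' @examples
#' d <- data.frame(copies = rep(10^(1:7), each = 3))
#' d$cq <- 37 - 3.3219 * log10(d$copies)
#' fit_standard_curve(d)
#' @export
fit_standard_curve <- function(dilutions) {
  df <- as_tibble(dilutions)
  if (!all(c("copies", "cq") %in% names(df))) {
    abort("dilutions need columns 'copies' and 'cq'")
  }
  target <- if ("target" %in% names(df)) {
    u <- unique(df$target)
    if (length(u) > 1) abort("one target per curve; filter first")
    u
  } else NA_character_
  df <- df[!is.na(df$cq), ]
  lc <- log10(df$copies)
  if (length(unique(lc)) < 3) abort("need at least 3 distinct dilution points")
  if (diff(range(lc)) < 2) abort("dilution points must span >= 2 decades")
  fit <- lm(cq ~ lc, data = tibble(cq = df$cq, lc = lc))
  slope <- unname(coef(fit)[2])
  if (slope >= 0) abort("standard curve slope must be negative")
  eff <- 10^(-1 / slope) - 1
  structure(
    list(target = target, slope = slope, intercept_cq = unname(coef(fit)[1]),
         r_squared = summary(fit)$r.squared, efficiency = eff,
         qc_pass = eff >= 0.90 & eff <= 1.10,
         n_points = length(unique(lc)), sigma_cq = summary(fit)$sigma,
         fit = fit,
         copies_range = range(df$copies)),
    class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> %s: slope %.4f, intercept %.2f, E = %.1f%%, R2 = %.4f [%s]\n",
              x$target %||% "?", x$slope, x$intercept_cq, 100 * x$efficiency,
              x$r_squared, if (x$qc_pass) "QC pass" else "QC FAIL"))
  invisible(x)
}

#' @describeIn fit_standard_curve Coefficient-level summary.
#' @param x A `standard_curve`.
#' @param ... Unused.
#' @export
tidy.standard_curve <- function(x, ...) {
  tibble(target = x$target,
         term = c("intercept_cq", "slope"),
         estimate = c(x$intercept_cq, x$slope),
         std.error = summary(x$fit)$coefficients[, 2])
}

#' @describeIn fit_standard_curve One-row model summary.
#' @export
glance.standard_curve <- function(x, ...) {
  tibble(target = x$target, slope = x$slope, intercept_cq = x$intercept_cq,
         efficiency = x$efficiency, r_squared = x$r_squared,
         qc_pass = x$qc_pass, sigma_cq = x$sigma_cq, n_points = x$n_points)
}

#' Fit one standard curve per target
#'
#' @param dilutions Data frame with `target`, `copies`, `cq`.
#' @return Named list of `standard_curve` objects.
#' @export
fit_standard_curves <- function(dilutions) {
  targets <- unique(dilutions$target)
  setNames(lapply(targets, function(t)
    fit_standard_curve(dilutions[dilutions$target == t, ])), targets)
}

#' Absolute quantification of one sample
#'
#' Inverts the standard curve: copies \eqn{= 10^{(\bar{Cq} - b)/m}} for curve
#' \eqn{Cq = b + m \log_{10}(copies)}. The confidence interval is a
#' t-interval on the replicate mean Cq propagated through the same
#' inversion. Replicates with Cq at or above the detection cutoff count as
#' non-detections; a sample with no detected replicate is flagged
#' `below_detection` and its copies set to the cutoff-implied upper bound.
#'
#' @param cq_replicates Numeric Cq values (NA = no amplification).
#' @param curve A [fit_standard_curve()] object.
#' @param sample_id,tissue,target Metadata carried into the result.
#' @param ci_level Confidence level (default 0.95).
#' @param cq_cutoff Detection cutoff (default 35 cycles).
#' @return One-row tibble: `sample_id`, `tissue`, `target`, `n_reps`,
#'   `mean_cq`, `se_cq`, `copies`, `ci_low`, `ci_high`, `below_detection`,
#'   `out_of_range`.
#' @examples
#' d <- data.frame(copies = rep(10^(1:7), each = 3))
#' d$cq <- 37 - 3.3219 * log10(d$copies)
#' quantify_sample(30.3562, fit_standard_curve(d))$copies # ~100
#' @export
quantify_sample <- function(cq_replicates, curve, sample_id = NA_character_,
                            tissue = NA_character_, target = curve$target,
                            ci_level = 0.95, cq_cutoff = 35) {
  if (length(cq_replicates) < 1) abort("need at least one Cq replicate")
  detected <- cq_replicates[!is.na(cq_replicates) & cq_replicates < cq_cutoff]
  inv <- function(cq) 10^((cq - curve$intercept_cq) / curve$slope)
  if (length(detected) == 0) {
    return(tibble(sample_id = sample_id, tissue = tissue, target = target,
                  n_reps = length(cq_replicates), mean_cq = NA_real_,
                  se_cq = NA_real_, copies = inv(cq_cutoff),
                  ci_low = 0, ci_high = inv(cq_cutoff),
                  below_detection = TRUE, out_of_range = FALSE))
  }
  m <- mean(detected)
  n <- length(detected)
  se <- if (n > 1) sd(detected) / sqrt(n) else 0
  tq <- if (n > 1) qt(1 - (1 - ci_level) / 2, n - 1) else 0
  lo_cq <- m + tq * se  # higher Cq -> fewer copies (slope < 0)
  hi_cq <- m - tq * se
  oor <- m < min(predict(curve$fit)) - 1 || m > max(predict(curve$fit)) + 1
  tibble(sample_id = sample_id, tissue = tissue, target = target,
         n_reps = n, mean_cq = m, se_cq = se, copies = inv(m),
         ci_low = inv(lo_cq), ci_high = inv(hi_cq),
         below_detection = FALSE, out_of_range = oor)
}

#' Quantify a table of sample measurements
#'
#' Table-first wrapper: takes the long replicate table (one row per well)
#' and a set of per-target curves, returns one row per sample x target.
#'
#' @param samples Data frame with `sample_id`, `tissue`, `target`, `cq`.
#' @param curves Named list from [fit_standard_curves()].
#' @param ... Passed to [quantify_sample()].
#' @return Tibble of per-sample quantifications.
#' @export
quantify_samples <- function(samples, curves, ...) {
  stopifnot(all(c("sample_id", "tissue", "target", "cq") %in% names(samples)))
  keys <- distinct(samples, .data$sample_id, .data$tissue, .data$target)
  list_rbind(pmap(keys, function(sample_id, tissue, target) {
    if (!target %in% names(curves)) {
      abort(sprintf("no standard curve for target '%s'", target))
    }
    cqs <- samples$cq[samples$sample_id == sample_id &
                        samples$tissue == tissue & samples$target == target]
    quantify_sample(cqs, curves[[target]], sample_id = sample_id,
                    tissue = tissue, target = target, ...)
  }))
}

#' Copy-number ratio of two quantifications with a propagated CI
#'
#' Ratio of the point estimates; the interval propagates both replicate-Cq
#' t-intervals through their curves by the delta method on the log10 scale
#' (Welch-Satterthwaite degrees of freedom). When the numerator is below
#' detection the ratio is reported as the upper bound implied by the
#' detection cutoff (`below_detection = TRUE`); a below-detection
#' denominator leaves the ratio undefined.
#'
#' @param num,den One-row tibbles from [quantify_sample()], same sample.
#' @param num_curve,den_curve The corresponding `standard_curve` objects.
#' @param ci_level Confidence level.
#' @return One-row tibble: `sample_id`, `tissue`, `numerator_target`,
#'   `denominator_target`, `ratio`, `ci_low`, `ci_high`, `below_detection`.
#' @export
ratio_with_ci <- function(num, den, num_curve, den_curve, ci_level = 0.95) {
  if (isTRUE(den$below_detection)) {
    return(tibble(sample_id = num$sample_id, tissue = num$tissue,
                  numerator_target = num$target, denominator_target = den$target,
                  ratio = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                  below_detection = TRUE))
  }
  ratio <- num$copies / den$copies
  if (isTRUE(num$below_detection)) {
    return(tibble(sample_id = num$sample_id, tissue = num$tissue,
                  numerator_target = num$target, denominator_target = den$target,
                  ratio = ratio, ci_low = 0, ci_high = ratio,
                  below_detection = TRUE))
  }
  # var of log10(ratio) from the two replicate-mean Cq variances
  v_num <- (num$se_cq / num_curve$slope)^2
  v_den <- (den$se_cq / den_curve$slope)^2
  se_log <- sqrt(v_num + v_den)
  df <- welch_df(num$se_cq^2, num$n_reps, den$se_cq^2, den$n_reps,
                 num_curve$slope, den_curve$slope)
  tq <- if (se_log > 0 && is.finite(df)) qt(1 - (1 - ci_level) / 2, df) else 0
  tibble(sample_id = num$sample_id, tissue = num$tissue,
         numerator_target = num$target, denominator_target = den$target,
         ratio = ratio,
         ci_low = ratio * 10^(-tq * se_log),
         ci_high = ratio * 10^(tq * se_log),
         below_detection = FALSE)
}

welch_df <- function(v1, n1, v2, n2, m1, m2) {
  a <- v1 / m1^2; b <- v2 / m2^2
  if (a + b == 0) return(Inf)
  num <- (a + b)^2
  den <- 0
  if (a > 0 && n1 > 1) den <- den + a^2 / (n1 - 1)
  if (b > 0 && n2 > 1) den <- den + b^2 / (n2 - 1)
  if (den == 0) return(Inf)
  num / den
}

#' Per-sample ratio table for two targets
#'
#' @param quants Tibble from [quantify_samples()].
#' @param curves Named curve list.
#' @param num_target,den_target Targets forming the ratio.
#' @param ci_level Confidence level.
#' @return Tibble with one ratio row per sample/tissue.
#' @export
ratio_table <- function(quants, curves, num_target, den_target,
                        ci_level = 0.95) {
  keys <- distinct(quants[quants$target %in% c(num_target, den_target), ],
                   .data$sample_id, .data$tissue)
  list_rbind(pmap(keys, function(sample_id, tissue) {
    num <- quants[quants$sample_id == sample_id & quants$tissue == tissue &
                    quants$target == num_target, ]
    den <- quants[quants$sample_id == sample_id & quants$tissue == tissue &
                    quants$target == den_target, ]
    if (nrow(num) != 1 || nrow(den) != 1) return(NULL)
    ratio_with_ci(num, den, curves[[num_target]], curves[[den_target]],
                  ci_level = ci_level)
  }))
}

#' Heteroplasmy ratio from NGS read counts
#'
#' Length-normalised read-count ratio
#' \eqn{(reads_M/len_M)/(reads_F/len_F)} with a CI from binomial
#' resampling of the read split. Mappability differences between the two
#' mitogenomes are ignored (documented assumption).
#'
#' @param reads_m,reads_f Read counts mapped to the M and F mitogenome.
#' @param len_m,len_f Genome lengths in bp.
#' @param ci_level Confidence level.
#' @param bootstrap_reps Binomial bootstrap draws (default 10,000).
#' @param seed Integer seed.
#' @return One-row tibble: `ratio`, `ci_low`, `ci_high`, `below_detection`.
#' @examples
#' ngs_ratio(200, 100, 24000, 18000, bootstrap_reps = 0)$ratio # 1.5
#' @export
ngs_ratio <- function(reads_m, reads_f, len_m, len_f, ci_level = 0.95,
                      bootstrap_reps = 10000, seed = NULL) {
  if (len_m <= 0 || len_f <= 0) abort("lengths must be positive")
  total <- reads_m + reads_f
  if (total <= 0) abort("no reads")
  if (reads_f == 0) {
    return(tibble(ratio = Inf, ci_low = (1 / len_m) / (reads_f + 1) * len_f,
                  ci_high = Inf, below_detection = TRUE))
  }
  ratio <- (reads_m / len_m) / (reads_f / len_f)
  lo <- hi <- NA_real_
  if (bootstrap_reps > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    rm_star <- rbinom(bootstrap_reps, total, reads_m / total)
    r_star <- (rm_star / len_m) / ((total - rm_star) / len_f)
    qs <- quantile(r_star[is.finite(r_star)],
                   c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2))
    lo <- qs[[1]]; hi <- qs[[2]]
  }
  tibble(ratio = ratio, ci_low = lo, ci_high = hi,
         below_detection = reads_m == 0)
}
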