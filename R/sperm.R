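#' Sperm mtDNA copy-number extrapolation model
#'
#' Male mantle tissue is a mixture of somatic cells (carrying F-type mtDNA)
#' and sperm (assumed homoplasmic for M-type mtDNA). Regressing M-mtDNA
#' copies per nuclear genome (y) on F-mtDNA copies per nuclear genome (x)
#' across male mantle samples and extrapolating to x = 0 therefore
#' estimates the M-mtDNA content of pure sperm: the intercept is the number
#' of M-mtDNA copies per sperm cell.
#'
#' The fit is unweighted OLS (`y = a + b x`). The default interval on the
#' intercept is plus/minus one standard error, the convention used for the
#' trend-line annotation this model reproduces; `interval = "confidence"`
#' gives the proper t-based interval at `ci_level` instead.
#'
#' @param points Data frame with columns `x` (F-mtDNA/nDNA) and `y`
#'   (M-mtDNA/nDNA), or `f_per_ndna`/`m_per_ndna`; optional `sample_id`,
#'   `tissue` (rows with tissue other than male mantle are rejected) and
#'   `below_detection` (excluded with a warning).
#' @param ci_level Level for `interval = "confidence"`.
#' @param interval `"se"` (plus/minus one SE, default) or `"confidence"`.
#' @param n_mito Assumed number of mitochondria per sperm cell (default 5,
#'   the textbook count for bivalve sperm).
#' @return An object of class `sperm_fit`: list with `slope`, `intercept`,
#'   `intercept_se`, `intercept_ci_low`, `intercept_ci_high`, `r_squared`,
#'   `n_points`, `n_mitochondria_assumed`, `copies_per_mitochondrion`,
#'   `fit` (the `lm`) and `points`.
#' @examples
#' fit_sperm_model(data.frame(x = c(0, 10, 20), y = c(15, 20, 25)))
#' @export
fit_sperm_model <- function(points, ci_level = 0.95,
                            interval = c("se", "confidence"), n_mito = 5) {
  interval <- match.arg(interval)
  df <- as_tibble(points)
  if (!"x" %in% names(df) && "f_per_ndna" %in% names(df)) df$x <- df$f_per_ndna
  if (!"y" %in% names(df) && "m_per_ndna" %in% names(df)) df$y <- df$m_per_ndna
  if (!all(c("x", "y") %in% names(df))) abort("points need columns x and y")
  if ("tissue" %in% names(df)) {
    bad <- !is.na(df$tissue) & !df$tissue %in% c("male_mantle")
    if (any(bad)) abort("sperm model accepts male mantle points only")
  }
  if ("below_detection" %in% names(df) && any(df$below_detection, na.rm = TRUE)) {
    warn(sprintf("excluding %d below-detection point(s)",
                 sum(df$below_detection, na.rm = TRUE)))
    df <- df[!df$below_detection, ]
  }
  if (any(df$x < 0 | df$y < 0)) abort("copy ratios must be non-negative")
  if (nrow(df) < 3) abort("need at least 3 points")
  if (length(unique(df$x)) < 2) abort("x values must not all be equal")
  fit <- lm(y ~ x, data = df)
  sm <- summary(fit)
  a <- unname(coef(fit)[1]); b <- unname(coef(fit)[2])
  a_se <- sm$coefficients[1, 2]
  half <- if (interval == "se") a_se else
    qt(1 - (1 - ci_level) / 2, nrow(df) - 2) * a_se
  structure(
    list(slope = b, intercept = a, intercept_se = a_se,
         intercept_ci_low = a - half, intercept_ci_high = a + half,
         interval = interval, ci_level = ci_level,
         r_squared = sm$r.squared, n_points = nrow(df),
         n_mitochondria_assumed = n_mito,
         copies_per_mitochondrion = a / n_mito,
         fit = fit, points = df),
    class = "sperm_fit")
}

#' Copies of M-mtDNA per sperm mitochondrion
#'
#' Divides the fitted per-cell intercept by the assumed number of
#' mitochondria per sperm cell.
#'
#' @param fit A [fit_sperm_model()] object.
#' @param n_mito Mitochondria per sperm cell (default 5).
#' @return The per-mitochondrion copy number (numeric scalar).
#' @export
copies_per_mitochondrion <- function(fit, n_mito = 5) {
  stopifnot(inherits(fit, "sperm_fit"))
  if (n_mito < 1) abort("n_mito must be >= 1")
  fit$intercept / n_mito
}

#' @export
print.sperm_fit <- function(x, ...) {
  cat(sprintf(paste0("<sperm_fit> n = %d male mantle samples\n",
                     "  M-mtDNA per sperm cell (intercept): %.2f (%.2f-%.2f)\n",
                     "  slope %.3f, R2 = %.4f\n",
                     "  per mitochondrion (assuming %d): %.2f\n"),
              x$n_points, x$intercept, x$intercept_ci_low, x$intercept_ci_high,
              x$slope, x$r_squared, x$n_mitochondria_assumed,
              x$copies_per_mitochondrion))
  invisible(x)
}

#' @describeIn fit_sperm_model Term-level coefficients.
#' @param x A `sperm_fit`.
#' @param ... Unused.
#' @export
tidy.sperm_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(term = c("intercept", "slope"), estimate = sm[, 1],
         std.error = sm[, 2], statistic = sm[, 3], p.value = sm[, 4])
}

#' @describeIn fit_sperm_model One-row fit summary.
#' @export
glance.sperm_fit <- function(x, ...) {
  tibble(intercept = x$intercept, intercept_ci_low = x$intercept_ci_low,
         intercept_ci_high = x$intercept_ci_high, slope = x$slope,
         r_squared = x$r_squared, n_points = x$n_points,
         copies_per_mitochondrion = x$copies_per_mitochondrion)
}

#' @describeIn fit_sperm_model Scatter plot with the fitted line and the
#'   extrapolated intercept.
#' @param object A `sperm_fit`.
#' @export
autoplot.sperm_fit <- function(object, ...) {
  ggplot(object$points, aes(x = .data$x, y = .data$y)) +
    geom_point() +
    geom_abline(intercept = object$intercept, slope = object$slope) +
    geom_abline(intercept = object$intercept_ci_low, slope = object$slope,
                linetype = "dotted") +
    geom_abline(intercept = object$intercept_ci_high, slope = object$slope,
                linetype = "dotted") +
    geom_point(data = tibble(x = 0, y = object$intercept), colour = "red",
               shape = 4, size = 3) +
    labs(x = "F-mtDNA / nDNA (somatic signal)",
         y = "M-mtDNA / nDNA",
         title = sprintf("Intercept %.2f M-mtDNA copies per sperm cell",
                         object$intercept)) +
    theme_minimal()
}
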