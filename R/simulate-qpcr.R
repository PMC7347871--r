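#' Simulate a qPCR heteroplasmy experiment with known truth
#'
#' Emulates the measurement tables of an F/M copy-number study: a dilution
#' series per target (3 experiments x 3 replicates x 7 ten-fold dilutions by
#' default) and per-sample Cq replicates for the three targets (F marker,
#' M marker, single-copy nuclear reference) in male and female mantle
#' tissue. The male-mantle truth follows the linear soma/sperm mixture
#' structure: with somatic signal \eqn{s_i} (F-mtDNA per nuclear genome),
#' M-mtDNA per nuclear genome is \eqn{intercept + slope \cdot s_i}, so a
#' downstream regression recovers `true_intercept` — the M-mtDNA copies per
#' sperm cell. Female mantle carries trace M contamination at a planted
#' F/M ratio. Cq values come from inverting the per-target standard curve
#' and adding Gaussian noise `sigma_cq`.
#'
#' @param n_samples Number of individuals (default 18, a realistic panel).
#' @param true_intercept M-mtDNA copies per sperm cell planted in the
#'   mixture line (default 15).
#' @param true_slope Slope of M/nDNA on F/nDNA (default 0.8).
#' @param somatic_f_levels Per-sample somatic F-mtDNA per nuclear genome;
#'   default log-uniform between 2 and 60, the spread seen across male
#'   mantles.
#' @param female_f_level F-mtDNA per nuclear genome in female mantle
#'   (default 1000).
#' @param female_fm_ratio Range of the planted F/M contamination ratio in
#'   female mantle (default `c(1e3, 1e4)`).
#' @param ndna_copies Nuclear genome copies per reaction (default 1e4).
#' @param sigma_cq Replicate Cq noise SD (default 0.1 cycles, typical
#'   instrument precision).
#' @param n_replicates,n_experiments,n_dilutions Standard-curve design
#'   (defaults 3, 3, 7).
#' @param curve_slope,curve_intercept Per-target true curve parameters;
#'   scalars are recycled. Default slope -3.3219 (100% efficiency),
#'   intercepts 37, 36.5, 37.5 cycles at one copy.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return List with `dilutions` (tibble: target, experiment, copies, cq),
#'   `samples` (tibble: sample_id, tissue, target, replicate, cq) and
#'   `truth` (list: the planted parameters plus a per-sample tibble of true
#'   copies).
#' @export
simulate_qpcr_dataset <- function(n_samples = 18, true_intercept = 15,
                                  true_slope = 0.8, somatic_f_levels = NULL,
                                  female_f_level = 1000,
                                  female_fm_ratio = c(1e3, 1e4),
                                  ndna_copies = 1e4, sigma_cq = 0.1,
                                  n_replicates = 3, n_experiments = 3,
                                  n_dilutions = 7,
                                  curve_slope = -3.3219,
                                  curve_intercept = c(37, 36.5, 37.5),
                                  seed = NULL) {
  if (sigma_cq < 0) abort("sigma_cq must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  targets <- c("F_cox1", "M_nad1", "nuclear_atpa")
  curve_slope <- rep_len(curve_slope, 3)
  curve_intercept <- rep_len(curve_intercept, 3)
  if (any(curve_slope >= 0)) abort("curve slopes must be negative")
  curves_true <- tibble(target = targets, slope = curve_slope,
                        intercept_cq = curve_intercept)
  cq_of <- function(target, copies) {
    i <- match(target, targets)
    curve_intercept[i] + curve_slope[i] * log10(copies)
  }

  dil <- tidyr::expand_grid(target = targets,
                            experiment = seq_len(n_experiments),
                            copies = 10^seq_len(n_dilutions),
                            replicate = seq_len(n_replicates))
  dil$cq <- cq_of(dil$target, dil$copies) + rnorm(nrow(dil), 0, sigma_cq)
  dil <- dil[, c("target", "experiment", "copies", "cq")]

  s_i <- somatic_f_levels %||% 10^runif(n_samples, log10(2), log10(60))
  if (length(s_i) != n_samples) abort("somatic_f_levels must have n_samples values")
  ids <- sprintf("IND%02d", seq_len(n_samples))
  male_m <- true_intercept + true_slope * s_i
  if (any(male_m < 0)) abort("planted copies negative; check intercept/slope")
  fem_ratio <- 10^runif(n_samples, log10(female_fm_ratio[1]),
                        log10(female_fm_ratio[2]))
  truth_samples <- bind_rows(
    tibble(sample_id = ids, tissue = "male_mantle",
           f_per_ndna = s_i, m_per_ndna = male_m),
    tibble(sample_id = ids, tissue = "female_mantle",
           f_per_ndna = female_f_level,
           m_per_ndna = female_f_level / fem_ratio))
  copies_of <- function(target, f, m) {
    switch(target, F_cox1 = f * ndna_copies, M_nad1 = m * ndna_copies,
           nuclear_atpa = ndna_copies)
  }
  samples <- tidyr::expand_grid(truth_samples, target = targets,
                                replicate = seq_len(n_replicates))
  samples$cq <- vapply(seq_len(nrow(samples)), function(r) {
    cp <- copies_of(samples$target[r], samples$f_per_ndna[r],
                    samples$m_per_ndna[r])
    cq_of(samples$target[r], cp)
  }, numeric(1)) + rnorm(nrow(samples), 0, sigma_cq)
  samples <- samples[, c("sample_id", "tissue", "target", "replicate", "cq")]

  list(dilutions = dil, samples = samples,
       truth = list(intercept = true_intercept, slope = true_slope,
                    sigma_cq = sigma_cq, ndna_copies = ndna_copies,
                    curves = curves_true, samples = truth_samples))
}

#' Simulate an NGS read split between two mitogenomes
#'
#' Reads split binomially with success probability
#' \eqn{p = r \, len_M / (r \, len_M + len_F)} for true copy ratio `r`, so
#' [ngs_ratio()] inverts the mapping in expectation.
#'
#' @param true_ratio True M/F copy-number ratio.
#' @param len_m,len_f Genome lengths (bp).
#' @param total_reads Total mapped reads (> 0).
#' @param seed Integer seed.
#' @return List with `reads_m`, `reads_f`, `p`.
#' @export
simulate_ngs_counts <- function(true_ratio, len_m, len_f, total_reads,
                                seed = NULL) {
  if (total_reads <= 0) abort("total_reads must be positive")
  if (!is.null(seed)) set.seed(seed)
  p <- true_ratio * len_m / (true_ratio * len_m + len_f)
  reads_m <- rbinom(1, total_reads, p)
  list(reads_m = reads_m, reads_f = total_reads - reads_m, p = p)
}

#' Assemble sperm-model input points from quantification results
#'
#' Joins the three per-target quantifications of each sample into the
#' regression input: `x` = F-mtDNA copies / nuclear copies, `y` = M-mtDNA
#' copies / nuclear copies, with the M below-detection flag carried through.
#'
#' @param quants Tibble from [quantify_samples()].
#' @param f_target,m_target,n_target Target names.
#' @param tissue Tissue to keep (default male mantle, the only tissue the
#'   mixture model applies to).
#' @return Tibble with `sample_id`, `tissue`, `x`, `y`, `below_detection`.
#' @export
sperm_points <- function(quants, f_target = "F_cox1", m_target = "M_nad1",
                         n_target = "nuclear_atpa", tissue = "male_mantle") {
  q <- quants[quants$tissue == tissue, ]
  wide <- tidyr::pivot_wider(
    q[, c("sample_id", "tissue", "target", "copies", "below_detection")],
    names_from = "target", values_from = c("copies", "below_detection"))
  tibble(sample_id = wide$sample_id, tissue = wide$tissue,
         x = wide[[paste0("copies_", f_target)]] / wide[[paste0("copies_", n_target)]],
         y = wide[[paste0("copies_", m_target)]] / wide[[paste0("copies_", n_target)]],
         below_detection = wide[[paste0("below_detection_", m_target)]])
}
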