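#' Haplotype diversity statistics
#'
#' Standard within-population summaries of an aligned haplotype set, computed
#' over gap- and ambiguity-free columns (complete deletion): number of
#' segregating sites S, number of distinct haplotypes h, haplotype diversity
#' \eqn{hd = \frac{N}{N-1}(1 - \sum p_i^2)}, Watterson's
#' \eqn{\theta_w = S/(a_1 L)} with \eqn{a_1 = \sum_{i=1}^{N-1} 1/i}, and
#' nucleotide diversity \eqn{\pi} (mean pairwise differences per site over
#' all \eqn{\binom{N}{2}} pairs).
#'
#' @param hs A haplotype set: a tibble with a `seq` column (see
#'   [simulate_haplotypes()]), or a character vector of equal-length
#'   sequences.
#' @param region Optional region name carried into the output.
#' @return A one-row tibble: `region`, `N`, `h`, `S`, `hd`,
#'   `theta_per_site`, `theta_per_seq`, `pi`, `L` (sites used).
#' @examples
#' diversity_stats(c("AAA", "AAT", "ATT"))
#' @export
diversity_stats <- function(hs, region = NA_character_) {
  seqs <- if (is.character(hs)) hs else hs$seq
  if (is.na(region) && !is.character(hs)) {
    region <- attr(hs, "region") %||% NA_character_
  }
  n <- length(seqs)
  if (n < 2) abort("need at least 2 haplotypes")
  mat <- aln_matrix(seqs)
  use <- clean_columns(mat, "nt")
  mat <- mat[, use, drop = FALSE]
  L <- ncol(mat)
  S <- sum(apply(mat, 2, function(col) length(unique(col)) > 1))
  h <- length(unique(apply(mat, 1, paste, collapse = "")))
  freqs <- table(apply(mat, 1, paste, collapse = "")) / n
  hd <- n / (n - 1) * (1 - sum(freqs^2))
  a1 <- sum(1 / seq_len(n - 1))
  pairs <- combn(n, 2)
  diffs <- vapply(seq_len(ncol(pairs)), function(k)
    sum(mat[pairs[1, k], ] != mat[pairs[2, k], ]), numeric(1))
  pi <- mean(diffs) / L
  tibble(region = region, N = n, h = h, S = as.integer(S), hd = hd,
         theta_per_site = S / (a1 * L), theta_per_seq = S / a1, pi = pi, L = L)
}

# Tajima (1989) constants for sample size n
tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Tajima's D neutrality test
#'
#' \eqn{D = (\pi L - S/a_1)/\sqrt{e_1 S + e_2 S (S-1)}} with the 1989
#' constants. Significance at p < 0.05 uses the beta-distribution
#' approximation of D's null distribution, rescaled to its theoretical
#' minimum and maximum — the convention behind starred entries in standard
#' diversity tables. With S = 0 the statistic is undefined and `NA` is
#' returned.
#'
#' @inheritParams diversity_stats
#' @return A one-row tibble: `D`, `p_value`, `significant`.
#' @export
tajimas_d <- function(hs) {
  seqs <- if (is.character(hs)) hs else hs$seq
  n <- length(seqs)
  if (n < 4) abort("Tajima's D needs at least 4 sequences")
  stats <- diversity_stats(seqs)
  S <- stats$S
  if (S < 1) {
    return(tibble(D = NA_real_, p_value = NA_real_, significant = NA))
  }
  k <- tajima_constants(n)
  D <- (stats$pi * stats$L - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
  # beta approximation on [Dmin, Dmax]
  Dmin <- (2 / n - 1 / k$a1) / sqrt(k$e2)
  Dmax <- ((n + 1) / (2 * n) - 1 / k$a1) / sqrt(k$e2)
  tmp1 <- 1 + Dmin * Dmax
  tmp2 <- Dmax - Dmin
  a <- -tmp1 * Dmax / tmp2
  b <- tmp1 * Dmin / tmp2
  p <- pbeta((D - Dmin) / tmp2, b, a)
  p <- if (is.na(p)) NA_real_ else if (p < 0.5) 2 * p else 2 * (1 - p)
  tibble(D = D, p_value = p, significant = !is.na(p) & p < 0.05)
}

#' Full per-region summary row
#'
#' Assembles the diversity statistics, Tajima's D and Nei–Gojobori Ka/Ks
#' into one row of the standard diversity-table shape. Passing a list of
#' haplotype sets concatenates the regions (rows matched by position) before
#' computing, as for a multi-gene concatamer.
#'
#' @param hs A haplotype set, or a named list of haplotype sets sharing N to
#'   concatenate.
#' @param region Region name for the output row.
#' @param frame_offset Reading-frame offset of the coding sequences.
#' @param code Genetic code.
#' @param bootstrap_reps,seed Codon-bootstrap control for the Ka/Ks SEs.
#' @return One-row tibble with columns `region`, `N`, `h`, `S`, `hd`,
#'   `theta_per_site`, `theta_per_seq`, `pi`, `tajima_D`, `D_significant`,
#'   `Ka`, `Ka_SE`, `Ks`, `Ks_SE`, `Ka_over_Ks`.
#' @export
region_summary <- function(hs, region = NULL, frame_offset = 0,
                           code = genetic_code(5), bootstrap_reps = 1000,
                           seed = NULL) {
  if (is.list(hs) && !is.data.frame(hs)) {
    lens <- vapply(hs, function(x) length(if (is.character(x)) x else x$seq),
                   numeric(1))
    if (length(unique(lens)) > 1) abort("regions differ in N; cannot concatenate")
    seq_list <- lapply(hs, function(x) if (is.character(x)) x else x$seq)
    seqs <- Reduce(paste0, seq_list)
    region <- region %||% paste(names(hs), collapse = "+")
  } else {
    seqs <- if (is.character(hs)) hs else hs$seq
    region <- region %||% (if (is_tibble(hs)) attr(hs, "region") else NULL) %||%
      NA_character_
  }
  d <- diversity_stats(seqs, region = region)
  td <- tajimas_d(seqs)
  kk <- nei_gojobori_kaks(seqs, frame_offset = frame_offset, code = code,
                          bootstrap_reps = bootstrap_reps, seed = seed)
  tibble(region = region, N = d$N, h = d$h, S = d$S, hd = d$hd,
         theta_per_site = d$theta_per_site, theta_per_seq = d$theta_per_seq,
         pi = d$pi, tajima_D = td$D, D_significant = td$significant,
         Ka = kk$Ka, Ka_SE = kk$Ka_SE, Ks = kk$Ks, Ks_SE = kk$Ks_SE,
         Ka_over_Ks = kk$Ka_over_Ks)
}
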