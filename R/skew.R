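#' Sliding-window compositional indices on a circular genome
#'
#' Computes AT-skew \eqn{(A-T)/(A+T)}, GC-skew \eqn{(G-C)/(G+C)} or GC
#' content in windows tiling the full circle: window starts at
#' \eqn{s = k \cdot step} for \eqn{k = 0, \ldots, \lceil L/step \rceil - 1},
#' windows wrap the origin, and the reported center is
#' \eqn{(s + window/2) \bmod L}. An optional site filter restricts counting
#' to positions with the given [classify_sites()] labels (e.g. the neutral
#' set). Windows with no eligible positions carry `NA`, not zero. Skews are
#' computed on the stored (gene-coding) strand; set `strand = "-"` for the
#' complement.
#'
#' @param genome A [mito_genome()].
#' @param index One of `"AT_skew"`, `"GC_skew"`, `"GC_content"`.
#' @param window,step Window length and step in bp. The defaults, 200 and
#'   25 bp, are the conventional scale for mitogenome skew profiles;
#'   neutral-site tracks are typically run at `window = 1000` to keep enough
#'   eligible positions per window.
#' @param site_filter `NULL` (all positions), a preset name understood by
#'   [site_filter()], or a vector of site-class labels.
#' @param relative For `GC_content` only: divide window values by the
#'   genome-wide GC content over the same site filter, so 1 means average.
#' @param strand `"+"` (stored strand) or `"-"`.
#' @param code Genetic code used when a filter requires site classification.
#' @return A tibble of class `skew_track` with columns `center`, `value`,
#'   `eligible` and `index`, plus attributes `window`, `step`,
#'   `genome_length`.
#' @examples
#' g <- mito_genome("AAAATTGG")
#' windowed_index(g, "AT_skew", window = 8, step = 8)$value # 0.3333
#' @export
windowed_index <- function(genome, index = c("AT_skew", "GC_skew", "GC_content"),
                           window = 200, step = 25, site_filter = NULL,
                           relative = FALSE, strand = "+",
                           code = genetic_code(5)) {
  index <- match.arg(index)
  len <- genome$length
  if (window < 1 || step < 1) abort("window and step must be >= 1")
  if (window > len) abort("window larger than the genome")
  seq_chars <- strsplit(if (strand == "-") revcomp(genome$sequence) else
    genome$sequence, "")[[1]]

  eligible <- rep(TRUE, len)
  if (!is.null(site_filter)) {
    labels <- site_filter(site_filter)
    mask <- classify_sites(genome, code)
    if (strand == "-") mask <- rev(mask)
    eligible <- mask %in% labels
  }

  # per-position indicator columns, cumulated over a doubled circle so any
  # wrapping window is one subtraction
  ind <- cbind(A = seq_chars == "A", C = seq_chars == "C",
               G = seq_chars == "G", T = seq_chars == "T")
  ind[!eligible, ] <- FALSE
  ind2 <- rbind(ind, ind)
  cums <- apply(ind2, 2, cumsum)
  cums <- rbind(0, cums)

  n_win <- ceiling(len / step)
  starts <- (seq_len(n_win) - 1L) * step
  counts <- cums[pmin(starts + window, 2L * len) + 1L, , drop = FALSE] -
    cums[starts + 1L, , drop = FALSE]
  nA <- counts[, "A"]; nC <- counts[, "C"]
  nG <- counts[, "G"]; nT <- counts[, "T"]
  elig_cum <- c(0, cumsum(c(eligible, eligible)))
  n_elig <- elig_cum[starts + window + 1L] - elig_cum[starts + 1L]

  value <- switch(index,
    AT_skew = (nA - nT) / (nA + nT),
    GC_skew = (nG - nC) / (nG + nC),
    GC_content = (nG + nC) / (nA + nC + nG + nT) # non-N bases; all-N -> NA
  )
  value <- unname(value)
  value[n_elig == 0] <- NA_real_
  value[is.nan(value)] <- NA_real_
  if (relative && index == "GC_content") {
    overall <- genome_wide_index(genome, "GC_content", site_filter = site_filter,
                                 strand = strand, code = code)
    value <- value / overall
  }
  out <- tibble(center = (starts + window / 2) %% len, value = value,
                eligible = as.integer(n_elig), index = index)
  structure(out, class = c("skew_track", class(out)),
            window = window, step = step, genome_length = len,
            relative = relative)
}

#' Genome-wide value of a compositional index
#'
#' Equivalent to [windowed_index()] with a single window covering the whole
#' circle (counts aggregated, not per-window skews averaged).
#'
#' @inheritParams windowed_index
#' @return A single numeric value (`NA` if no eligible positions).
#' @export
genome_wide_index <- function(genome, index = c("AT_skew", "GC_skew", "GC_content"),
                              site_filter = NULL, strand = "+",
                              code = genetic_code(5)) {
  index <- match.arg(index)
  tr <- windowed_index(genome, index, window = genome$length,
                       step = genome$length, site_filter = site_filter,
                       relative = FALSE, strand = strand, code = code)
  tr$value[1]
}

#' Export a skew track as TSV
#'
#' Four columns: center, value, eligible, index_name.
#' @param track A `skew_track`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_track_tsv <- function(track, path) {
  df <- as.data.frame(track)
  names(df) <- c("center", "value", "eligible", "index_name")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn windowed_index Line plot of one or more tracks.
#' @param object A `skew_track`.
#' @export
autoplot.skew_track <- function(object, ...) {
  ggplot(object, aes(x = .data$center, y = .data$value)) +
    geom_line(na.rm = TRUE) +
    geom_hline(yintercept = if (object$index[1] == "GC_content" &&
                                isTRUE(attr(object, "relative"))) 1 else 0,
               linetype = "dashed", colour = "grey50") +
    labs(x = "position (bp)", y = object$index[1]) +
    theme_minimal()
}
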