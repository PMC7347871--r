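#' Per-position site classification
#'
#' Labels every genome position with exactly one class: `codon_pos1`,
#' `codon_pos2`, `codon_pos3_2fold`, `codon_pos3_4fold` (inside protein
#' genes, with third-position degeneracy computed from the actual codon under
#' the genetic code), `rna_gene` (rRNA/tRNA/tRNA-like), or `noncoding`
#' (everything else, including AT-rich and repeat regions). Overlaps resolve
#' by priority protein > RNA gene > noncoding; two protein genes overlapping
#' in different reading frames are an error.
#'
#' "Neutral" positions, in the sense used for filtered skew tracks, are the
#' 4-fold degenerate third codon positions plus noncoding positions.
#'
#' @param genome A [mito_genome()].
#' @param code A [genetic_code()].
#' @return Character vector of length `genome$length`, one label per
#'   position, with class `site_class_mask`.
#' @export
classify_sites <- function(genome, code = genetic_code(5)) {
  len <- genome$length
  mask <- rep("noncoding", len)
  prio <- rep(0L, len) # 0 none, 1 rna, 2 protein
  frame_owner <- rep(NA_integer_, len)
  seq_chars <- strsplit(genome$sequence, "")[[1]]
  ft <- genome$features

  rna <- ft[ft$category %in% c("rRNA", "tRNA", "tRNA_like"), ]
  for (i in seq_len(nrow(rna))) {
    idx <- ((seq.int(rna$start[i], rna$end[i] - 1)) %% len) + 1
    take <- prio[idx] < 1L
    mask[idx[take]] <- "rna_gene"
    prio[idx][take] <- 1L
  }

  prot <- ft[ft$category == "protein", ]
  for (i in seq_len(nrow(prot))) {
    f <- prot[i, ]
    pos0 <- seq.int(f$start, f$end - 1) %% len    # genome positions, 0-based
    if (f$strand == "-") pos0 <- rev(pos0)
    # coding-orientation index within the feature, after frame offset
    coding_i <- seq_along(pos0) - 1L - f$frame_offset
    keep <- coding_i >= 0
    pos0 <- pos0[keep]; coding_i <- coding_i[keep]
    codon_pos <- coding_i %% 3L + 1L

    cds <- extract_feature_sequence(genome, as.list(f))
    if (f$frame_offset > 0) cds <- substr(cds, f$frame_offset + 1, nchar(cds))
    n_cod <- nchar(cds) %/% 3
    cods <- substring(cds, 3 * seq_len(n_cod) - 2, 3 * seq_len(n_cod))

    lab <- character(length(pos0))
    lab[codon_pos == 1L] <- "codon_pos1"
    lab[codon_pos == 2L] <- "codon_pos2"
    third <- which(codon_pos == 3L)
    cod_idx <- coding_i[third] %/% 3L + 1L
    ok <- cod_idx <= n_cod & !grepl("N", cods[cod_idx])
    deg <- rep(2L, length(third))
    deg[ok] <- code$degeneracy[cods[cod_idx[ok]], 3]
    lab[third] <- ifelse(deg == 4L, "codon_pos3_4fold", "codon_pos3_2fold")
    # trailing partial codon (incomplete stop): label by codon position anyway
    lab[lab == ""] <- "codon_pos1"

    gidx <- pos0 + 1L
    already <- prio[gidx] == 2L
    if (any(already & mask[gidx] != lab)) {
      abort(sprintf("protein features overlap in different frames near position %d",
                    gidx[which(already & mask[gidx] != lab)[1]]))
    }
    mask[gidx] <- lab
    prio[gidx] <- 2L
    frame_owner[gidx] <- (pos0 - codon_pos + 1L) %% 3L
  }
  structure(mask, class = "site_class_mask")
}

site_class_labels <- c("codon_pos1", "codon_pos2", "codon_pos3_2fold",
                       "codon_pos3_4fold", "rna_gene", "noncoding")

#' Named site-filter presets
#'
#' * `neutral`: 4-fold degenerate third codon positions plus noncoding —
#'   the standard operationalisation of neutrally evolving positions.
#' * `second_noncoding`: second codon positions plus noncoding, the filter
#'   used for the "filtered AT-skew" track.
#' * `noncoding`: noncoding positions only.
#'
#' @param name Preset name, or a character vector of raw labels (returned
#'   unchanged after validation).
#' @return Character vector of site-class labels.
#' @export
site_filter <- function(name) {
  presets <- list(
    neutral = c("codon_pos3_4fold", "noncoding"),
    second_noncoding = c("codon_pos2", "noncoding"),
    noncoding = "noncoding"
  )
  if (length(name) == 1 && name %in% names(presets)) return(presets[[name]])
  bad <- setdiff(name, site_class_labels)
  if (length(bad)) abort(paste0("unknown site-class label: ", bad[1]))
  name
}
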