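#' Read / write aligned FASTA with group labels
#'
#' Group labels (e.g. F and M mitotype) are encoded in headers as
#' `>name|group`; a header without `|` gets group `NA`.
#'
#' @param path FASTA file of equal-length aligned sequences.
#' @param molecule `"nt"` or `"aa"`.
#' @return A tibble with columns `name`, `group`, `seq` and attribute
#'   `molecule`.
#' @export
read_alignment <- function(path, molecule = c("nt", "aa")) {
  molecule <- match.arg(molecule)
  ss <- Biostrings::readBStringSet(path)
  nm <- names(ss)
  grp <- ifelse(grepl("\\|", nm), sub("^.*\\|", "", nm), NA_character_)
  nm <- sub("\\|.*$", "", nm)
  aln <- tibble(name = nm, group = grp,
                seq = unname(toupper(as.character(ss))))
  if (length(unique(nchar(aln$seq))) > 1) abort("aligned rows differ in length")
  attr(aln, "molecule") <- molecule
  aln
}

#' @rdname read_alignment
#' @param aln Alignment tibble (`name`, `group`, `seq`).
#' @return `write_alignment()` returns `path` invisibly.
#' @export
write_alignment <- function(aln, path) {
  hdr <- ifelse(is.na(aln$group), aln$name, paste0(aln$name, "|", aln$group))
  ss <- Biostrings::BStringSet(setNames(aln$seq, hdr))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

aln_matrix <- function(seqs) {
  do.call(rbind, strsplit(toupper(seqs), ""))
}

# columns free of gaps and ambiguity over the given rows
clean_columns <- function(mat, molecule = "nt") {
  ok_chars <- if (molecule == "nt") c("A", "C", "G", "T") else setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z"))
  apply(mat, 2, function(col) all(col %in% ok_chars))
}

#' Pairwise p-distance between two aligned sequences
#'
#' Proportion of differing sites among the sites used. `complete` deletion
#' drops alignment columns containing any gap or ambiguity across *all* rows
#' of the surrounding alignment (pass those rows via `context`); `pairwise`
#' considers only the two sequences. Ambiguity codes count as gaps.
#'
#' @param a,b Aligned strings of equal length.
#' @param deletion `"complete"` or `"pairwise"`.
#' @param context Optional character vector of all alignment rows defining
#'   complete-deletion columns; defaults to `c(a, b)`.
#' @param molecule `"nt"` or `"aa"`.
#' @return A list with `p` (NA if no usable site) and `n_sites`.
#' @examples
#' p_distance("AA-A", "ATTA")$p # 1/3 over columns 1,2,4
#' @export
p_distance <- function(a, b, deletion = c("complete", "pairwise"),
                       context = NULL, molecule = "nt") {
  deletion <- match.arg(deletion)
  if (nchar(a) != nchar(b)) abort("aligned sequences differ in length")
  rows <- if (deletion == "complete") (context %||% c(a, b)) else c(a, b)
  mat <- aln_matrix(rows)
  use <- clean_columns(mat, molecule)
  av <- strsplit(toupper(a), "")[[1]][use]
  bv <- strsplit(toupper(b), "")[[1]][use]
  n <- sum(use)
  list(p = if (n == 0) NA_real_ else sum(av != bv) / n, n_sites = n)
}

#' Mean between-group p-distance with bootstrap SE
#'
#' Averages [p_distance()] over all cross-group sequence pairs, with a
#' standard error from resampling alignment columns with replacement
#' (site bootstrap).
#'
#' @param aln Alignment tibble from [read_alignment()] or built in code.
#' @param group_a,group_b Group labels to compare.
#' @param bootstrap_reps Number of site-bootstrap replicates (default
#'   10,000, the conventional count for between-group distances).
#' @param seed Integer seed for the bootstrap.
#' @param deletion Passed to [p_distance()].
#' @param molecule `"nt"` or `"aa"`.
#' @return A list with `mean_p`, `se` (NA when fewer than 2 usable columns)
#'   and `n_sites`.
#' @export
between_group_p_distance <- function(aln, group_a = "F", group_b = "M",
                                     bootstrap_reps = 10000, seed = NULL,
                                     deletion = "complete", molecule = NULL) {
  molecule <- molecule %||% attr(aln, "molecule") %||% "nt"
  sa <- aln$seq[aln$group == group_a]
  sb <- aln$seq[aln$group == group_b]
  if (!length(sa) || !length(sb)) abort("both groups must be non-empty")
  mat <- aln_matrix(c(sa, sb))
  use <- if (deletion == "complete") clean_columns(mat, molecule) else
    rep(TRUE, ncol(mat))
  mat <- mat[, use, drop = FALSE]
  n_sites <- ncol(mat)
  if (n_sites == 0) return(list(mean_p = NA_real_, se = NA_real_, n_sites = 0L))
  ia <- seq_along(sa); ib <- length(sa) + seq_along(sb)
  # per-column mean mismatch over all cross pairs; the statistic is the mean
  # of this vector, so the site bootstrap reduces to resampling it
  pairs <- expand.grid(i = ia, j = ib)
  mm <- matrix(0, nrow(pairs), n_sites)
  for (k in seq_len(nrow(pairs))) {
    mm[k, ] <- mat[pairs$i[k], ] != mat[pairs$j[k], ]
  }
  col_mean <- colMeans(mm)
  mean_p <- mean(col_mean)
  se <- NA_real_
  if (n_sites >= 2 && bootstrap_reps > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    reps <- vapply(seq_len(bootstrap_reps), function(r) {
      mean(col_mean[sample.int(n_sites, n_sites, replace = TRUE)])
    }, numeric(1))
    se <- sd(reps)
  }
  list(mean_p = mean_p, se = se, n_sites = n_sites)
}

#' Per-gene F/M divergence table
#'
#' One row per gene shared by the two genomes: amino-acid p-distance for
#' protein genes (alignments translated in-frame), nucleotide p-distance for
#' RNA genes, and an `overall` row computed as the nucleotide p-distance on
#' the concatenation of all per-gene nucleotide alignments. Genes present in
#' only one genome are skipped with a warning.
#'
#' @param genome_f,genome_m F-type and M-type [mito_genome()]s (used for the
#'   gene catalogue and categories).
#' @param alignments Named list of *nucleotide* alignment tibbles, one per
#'   gene, with `group` column distinguishing the genomes.
#' @param bootstrap_reps,seed Bootstrap control, see
#'   [between_group_p_distance()].
#' @param code Genetic code for translating protein alignments.
#' @return A tibble with columns `gene`, `molecule`, `p_distance`,
#'   `bootstrap_se`, `n_sites_used`.
#' @export
per_gene_divergence <- function(genome_f, genome_m, alignments,
                                bootstrap_reps = 10000, seed = NULL,
                                code = genetic_code(5)) {
  cat_f <- setNames(genome_f$features$category, genome_f$features$name)
  cat_m <- setNames(genome_m$features$category, genome_m$features$name)
  genes <- names(alignments)
  missing <- genes[!(genes %in% names(cat_f) & genes %in% names(cat_m))]
  if (length(missing)) {
    warn(paste0("gene(s) missing from one genome, skipped: ",
                paste(missing, collapse = ", ")))
    genes <- setdiff(genes, missing)
  }
  rows <- list()
  nt_parts <- list()
  for (g in genes) {
    aln <- alignments[[g]]
    nt_parts[[g]] <- aln
    category <- cat_f[[g]]
    if (category == "protein") {
      aa <- aln
      aa$seq <- vapply(aln$seq, function(s)
        translate_cds(gsub("-", "", s), code, allow_internal_stop = TRUE),
        character(1))
      if (length(unique(nchar(aa$seq))) > 1) {
        # gapped codon alignments: translate codon-wise keeping gaps
        aa$seq <- vapply(aln$seq, translate_gapped_codons, character(1),
                         code = code)
      }
      res <- between_group_p_distance(aa, bootstrap_reps = bootstrap_reps,
                                      seed = seed, molecule = "aa")
      mol <- "aa"
    } else {
      res <- between_group_p_distance(aln, bootstrap_reps = bootstrap_reps,
                                      seed = seed, molecule = "nt")
      mol <- "nt"
    }
    rows[[g]] <- tibble(gene = g, molecule = mol, p_distance = res$mean_p,
                        bootstrap_se = res$se, n_sites_used = res$n_sites)
  }
  # overall: concatenated nucleotide alignment over rows shared by all genes
  concat <- NULL
  if (length(nt_parts)) {
    by_group <- lapply(nt_parts, function(a) a[order(a$group, a$name), ])
    seqs <- Reduce(function(x, y) paste0(x, y$seq), by_group[-1],
                   by_group[[1]]$seq)
    concat <- tibble(name = by_group[[1]]$name, group = by_group[[1]]$group,
                     seq = seqs)
    res <- between_group_p_distance(concat, bootstrap_reps = bootstrap_reps,
                                    seed = seed, molecule = "nt")
    rows[["overall"]] <- tibble(gene = "overall", molecule = "nt",
                                p_distance = res$mean_p, bootstrap_se = res$se,
                                n_sites_used = res$n_sites)
  }
  list_rbind(rows)
}

translate_gapped_codons <- function(s, code) {
  n_cod <- nchar(s) %/% 3
  cods <- substring(s, 3 * seq_len(n_cod) - 2, 3 * seq_len(n_cod))
  aa <- ifelse(grepl("-", cods), "-", unname(code$codons[cods]))
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' @rdname per_gene_divergence
#' @param object A divergence tibble from `per_gene_divergence()`.
#' @param ... Unused.
#' @export
plot_divergence <- function(object, ...) {
  object <- object[order(-object$p_distance), ]
  object$gene <- factor(object$gene, levels = object$gene)
  ggplot(object, aes(x = .data$gene, y = .data$p_distance, fill = .data$molecule)) +
    geom_col() +
    geom_errorbar(aes(ymin = .data$p_distance - .data$bootstrap_se,
                      ymax = .data$p_distance + .data$bootstrap_se),
                  width = 0.3, na.rm = TRUE) +
    labs(x = NULL, y = "p-distance") +
    theme_minimal()
}
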