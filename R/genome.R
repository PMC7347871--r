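#' Annotated circular mitogenome
#'
#' Container for a circular mitochondrial genome and its gene features.
#' Coordinates are 0-based half-open internally; features that wrap the
#' replication origin are stored unwrapped, i.e. with `end > length`, and all
#' consumers read positions modulo the genome length. GenBank 1-based
#' inclusive coordinates are converted at the I/O boundary only.
#'
#' @param sequence Character scalar over A/C/G/T/N (case-insensitive).
#' @param features A data frame with columns `name`, `category` (one of
#'   `protein`, `rRNA`, `tRNA`, `tRNA_like`, `noncoding`, `AT_rich`,
#'   `repeat_region`), `start`, `end` (0-based half-open, `end` may exceed
#'   the length for origin-wrapping features), `strand` (`+`/`-`),
#'   `frame_offset` (0/1/2, proteins only) and `incomplete_stop` (logical).
#'   Missing optional columns are filled with defaults.
#' @param label Genome label: `"F"`, `"M"` or `"other"`.
#' @param circular Logical; mitogenomes are circular.
#' @return An object of class `mito_genome`: a list with elements `sequence`,
#'   `length`, `circular`, `label` and `features` (a tibble).
#' @examples
#' g <- mito_genome("ATGGTATAAACC",
#'   features = data.frame(name = "orf1", category = "protein",
#'                         start = 0, end = 9, strand = "+"))
#' g$length
#' @export
mito_genome <- function(sequence, features = NULL, label = "other",
                        circular = TRUE) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) {
    abort("sequence contains characters outside A/C/G/T/N")
  }
  len <- nchar(sequence)
  features <- normalize_features(features, len)
  structure(
    list(sequence = sequence, length = len, circular = circular,
         label = match.arg(label, c("F", "M", "other")), features = features),
    class = "mito_genome"
  )
}

feature_categories <- c("protein", "rRNA", "tRNA", "tRNA_like", "noncoding",
                        "AT_rich", "repeat_region")

normalize_features <- function(features, len) {
  if (is.null(features) || nrow(as.data.frame(features)) == 0) {
    return(tibble(name = character(), category = character(),
                  start = integer(), end = integer(), strand = character(),
                  frame_offset = integer(), incomplete_stop = logical()))
  }
  ft <- as_tibble(features)
  if (!"strand" %in% names(ft)) ft$strand <- "+"
  if (!"frame_offset" %in% names(ft)) ft$frame_offset <- 0L
  if (!"incomplete_stop" %in% names(ft)) ft$incomplete_stop <- FALSE
  ft <- ft[, c("name", "category", "start", "end", "strand",
               "frame_offset", "incomplete_stop")]
  ft$start <- as.integer(ft$start); ft$end <- as.integer(ft$end)
  ft$frame_offset <- as.integer(ft$frame_offset)
  bad <- setdiff(unique(ft$category), feature_categories)
  if (length(bad)) abort(paste0("unknown feature category: ", bad[1]))
  if (any(ft$start < 0 | ft$start >= len)) abort("feature start outside genome")
  if (any(ft$end <= ft$start)) abort("feature span must be >= 1")
  if (any(ft$end - ft$start > len)) abort("feature longer than genome")
  span <- ft$end - ft$start
  prot <- ft$category == "protein" & !ft$incomplete_stop
  if (any(prot & (span - ft$frame_offset) %% 3 != 0)) {
    warn("protein feature span not a codon multiple; flagging incomplete_stop")
    ft$incomplete_stop[prot & (span - ft$frame_offset) %% 3 != 0] <- TRUE
  }
  dup <- duplicated(ft[, c("name", "category")])
  if (any(dup)) abort("feature names must be unique within a category")
  ft
}

#' @export
print.mito_genome <- function(x, ...) {
  cat(sprintf("<mito_genome> %s-type, %s bp (%s), %d features\n",
              x$label, format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear", nrow(x$features)))
  tab <- table(x$features$category)
  if (length(tab)) cat(" ", paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn mito_genome Feature table as a tibble (one row per feature,
#'   with `span` added).
#' @param x A `mito_genome`.
#' @param ... Unused.
#' @export
tidy.mito_genome <- function(x, ...) {
  mutate(x$features, span = .data$end - .data$start, .after = "end")
}

#' Extract the sequence of one feature
#'
#' Returns the feature's residues in coding orientation: origin-wrapping
#' spans concatenate the suffix and prefix of the circular sequence, and
#' minus-strand features are reverse-complemented.
#'
#' @param genome A [mito_genome()].
#' @param feature One row of `genome$features`, a feature name, or a list
#'   with `start`, `end`, `strand`.
#' @return Character scalar.
#' @examples
#' g <- mito_genome("AAACCC")
#' extract_feature_sequence(g, list(start = 4, end = 8, strand = "+")) # "CCAA"
#' @export
extract_feature_sequence <- function(genome, feature) {
  if (is.character(feature) && length(feature) == 1) {
    row <- genome$features[genome$features$name == feature, ]
    if (nrow(row) == 0) abort(sprintf("no feature named '%s'", feature))
    feature <- as.list(row[1, ])
  }
  start <- feature$start; end <- feature$end
  if (start < 0 || start >= genome$length || end <= start ||
      end - start > genome$length) {
    abort("feature does not fit the genome")
  }
  idx <- (seq.int(start, end - 1) %% genome$length) + 1
  s <- paste(strsplit(genome$sequence, "")[[1]][idx], collapse = "")
  if (identical(feature$strand, "-")) s <- revcomp(s) else s
}

#' Write genome sequence(s) to FASTA
#'
#' @param genomes A `mito_genome` or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genomes, path) {
  if (inherits(genomes, "mito_genome")) genomes <- list(genomes)
  seqs <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "sequence"))
  names(seqs) <- vapply(genomes, `[[`, "", "label")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write a feature table as TSV
#'
#' Columns: name, category, start, end, strand, span (0-based half-open).
#' @param genome A [mito_genome()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(genome, path) {
  ft <- tidy(genome)[, c("name", "category", "start", "end", "strand", "span")]
  write.table(ft, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
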