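#' Genetic-code services
#'
#' Codon translation tables and per-position degeneracy classes. The default
#' is NCBI translation table 5 (invertebrate mitochondrial), the standard
#' choice for mytilid mitogenomes: ATA = Met, TGA = Trp, AGA/AGG = Ser, and
#' only TAA/TAG are stops.
#'
#' @param table_id Integer or string id of an NCBI translation table
#'   (default `5`).
#' @return `genetic_code()` returns a list with elements `table_id`,
#'   `codons` (named character, codon to one-letter amino acid, `*` = stop)
#'   and `degeneracy` (64 x 3 integer matrix, fold-class of each codon
#'   position: 1, 2, 3 or 4).
#' @examples
#' code <- genetic_code(5)
#' code$codons[["ATA"]] # "M"
#' code$degeneracy["GTA", 3] # 4: GTN are all Val
#' @export
genetic_code <- function(table_id = 5) {
  key <- paste0("code_", table_id)
  if (!is.null(the[[key]])) return(the[[key]])
  codons <- Biostrings::getGeneticCode(as.character(table_id))
  stopifnot(length(codons) == 64)
  bases <- c("A", "C", "G", "T")
  deg <- matrix(0L, 64, 3, dimnames = list(names(codons), NULL))
  for (cod in names(codons)) {
    for (pos in 1:3) {
      variants <- vapply(bases, function(b) {
        v <- cod
        substr(v, pos, pos) <- b
        codons[[v]]
      }, character(1))
      deg[cod, pos] <- sum(variants == codons[[cod]])
    }
  }
  obj <- list(table_id = table_id, codons = codons, degeneracy = deg)
  the[[key]] <- obj
  obj
}

#' Translate a coding sequence
#'
#' Translates nucleotides with a mitochondrial genetic code. A trailing
#' incomplete codon is dropped, as is a terminal stop. Internal stops are an
#' error unless `allow_internal_stop = TRUE` (used for genes annotated with
#' incomplete stop codons or frame oddities).
#'
#' @param seq Character scalar of A/C/G/T (N tolerated, translates to `X`).
#' @param code A [genetic_code()] object.
#' @param frame_offset 0, 1 or 2 bases skipped before the first codon.
#' @param allow_internal_stop Keep internal `*` instead of erroring.
#' @return Amino-acid string.
#' @examples
#' translate_cds("ATATGA") # "MW" under table 5
#' @export
translate_cds <- function(seq, code = genetic_code(5), frame_offset = 0,
                          allow_internal_stop = FALSE) {
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- toupper(seq)
  if (frame_offset > 0) seq <- substr(seq, frame_offset + 1, nchar(seq))
  n_cod <- nchar(seq) %/% 3
  if (n_cod < 1) abort("coding span shorter than one codon after frame offset")
  cods <- substring(seq, 3 * seq_len(n_cod) - 2, 3 * seq_len(n_cod))
  aa <- unname(code$codons[cods])
  aa[is.na(aa)] <- "X"
  if (aa[n_cod] == "*") aa <- aa[-n_cod]
  internal <- which(aa == "*")
  if (length(internal) && !allow_internal_stop) {
    abort(sprintf("internal stop codon at codon %d", internal[1]))
  }
  paste(aa, collapse = "")
}

base_complement <- c(A = "T", C = "G", G = "C", T = "A", N = "N", "-" = "-")

#' Reverse complement of a nucleotide string
#' @param seq Character scalar.
#' @return Character scalar.
#' @export
revcomp <- function(seq) {
  chartr("ACGTacgt", "TGCAtgca", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}
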