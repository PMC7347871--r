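#' Read a single-record GenBank flat file
#'
#' Minimal parser for annotated mitogenomes: reads the LOCUS length and
#' topology, the ORIGIN sequence and the feature table (CDS, rRNA, tRNA,
#' misc_feature, repeat_region, D-loop). `join()` locations that span the
#' origin of a circular record are unwrapped to internal coordinates with
#' `end > length`; `complement()` sets the strand. Qualifiers used: `/gene`
#' or `/product` (feature name), `/codon_start` (frame offset), `/note`
#' containing "incomplete stop" or "tRNA-like".
#'
#' @param path Path to a GenBank flat file containing exactly one record.
#' @param label Genome label (`F`, `M`, `other`); defaults to `other`.
#' @return A [mito_genome()].
#' @export
parse_genbank <- function(path, label = "other") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) != 1) {
    abort(sprintf("expected exactly one LOCUS line, found %d", length(locus_i)))
  }
  m <- regmatches(lines[locus_i],
                  regexec("^LOCUS\\s+\\S+\\s+(\\d+)\\s+bp", lines[locus_i]))[[1]]
  if (length(m) < 2) abort(sprintf("malformed LOCUS line (line %d)", locus_i))
  locus_len <- as.integer(m[2])
  circular <- grepl("circular", lines[locus_i])

  origin_i <- grep("^ORIGIN", lines)
  if (length(origin_i) != 1) abort("missing ORIGIN section")
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[1] else length(lines) + 1
  seq_lines <- lines[seq.int(origin_i + 1, end_i - 1)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) != locus_len) {
    abort(sprintf("ORIGIN sequence length %d differs from LOCUS length %d",
                  nchar(sequence), locus_len))
  }

  feat_i <- grep("^FEATURES", lines)
  features <- NULL
  if (length(feat_i) == 1) {
    block <- lines[seq.int(feat_i + 1, origin_i - 1)]
    features <- parse_gb_features(block, locus_len, feat_i)
  }
  if (is.null(features) || nrow(features) == 0) {
    warn("GenBank record has no usable features")
  }
  mito_genome(sequence, features, label = label, circular = circular)
}

gb_key_map <- c(CDS = "protein", rRNA = "rRNA", tRNA = "tRNA",
                misc_feature = "noncoding", repeat_region = "repeat_region",
                "D-loop" = "AT_rich")

parse_gb_features <- function(block, len, offset_line) {
  starts <- grep("^\\s{5}\\S", block)
  out <- list()
  for (k in seq_along(starts)) {
    from <- starts[k]
    to <- if (k < length(starts)) starts[k + 1] - 1 else length(block)
    chunk <- block[from:to]
    key <- sub("^\\s+(\\S+).*", "\\1", chunk[1])
    if (!key %in% names(gb_key_map)) next
    loc <- sub("^\\s+\\S+\\s+", "", chunk[1])
    # location may continue on following lines until a qualifier starts
    i <- 2
    while (i <= length(chunk) && !grepl("^\\s+/", chunk[i])) {
      loc <- paste0(loc, gsub("\\s", "", chunk[i])); i <- i + 1
    }
    parsed <- tryCatch(parse_gb_location(loc, len),
                       error = function(e) {
                         abort(sprintf("malformed location '%s' near line %d: %s",
                                       loc, offset_line + from, conditionMessage(e)))
                       })
    quals <- paste(chunk[grepl("^\\s+/", chunk)], collapse = " ")
    name <- gb_qualifier(quals, "gene") %||% gb_qualifier(quals, "product") %||%
      paste0(key, "_", k)
    codon_start <- gb_qualifier(quals, "codon_start")
    frame <- if (!is.null(codon_start)) as.integer(codon_start) - 1L else 0L
    note <- tolower(gb_qualifier(quals, "note") %||% "")
    category <- gb_key_map[[key]]
    if (category == "tRNA" && grepl("trna-like", note)) category <- "tRNA_like"
    if (category == "noncoding" && grepl("at-rich|at rich", note)) category <- "AT_rich"
    span <- parsed$end - parsed$start
    incomplete <- grepl("incomplete stop", note) || parsed$partial ||
      (category == "protein" && (span - frame) %% 3 != 0)
    out[[length(out) + 1]] <- tibble(
      name = name, category = category, start = parsed$start, end = parsed$end,
      strand = parsed$strand, frame_offset = frame, incomplete_stop = incomplete)
  }
  if (length(out)) list_rbind(out) else NULL
}

gb_qualifier <- function(quals, what) {
  m <- regmatches(quals, regexec(sprintf('/%s="?([^"/]+)"?', what), quals))[[1]]
  if (length(m) < 2) NULL else trimws(m[2])
}

# GenBank location -> 0-based half-open internal coordinates.
# join(a..L,1..b) on a circular record unwraps to start = a-1, end = L + b.
parse_gb_location <- function(loc, len) {
  loc <- gsub("\\s", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  partial <- grepl("[<>]", loc)
  loc <- gsub("[<>]", "", loc)
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",")[[1]]
    rng <- lapply(parts, parse_gb_range)
    if (length(rng) == 2 && rng[[1]]$to == len && rng[[2]]$from == 1) {
      return(list(start = rng[[1]]$from - 1L, end = len + rng[[2]]$to,
                  strand = strand, partial = partial))
    }
    # contiguous join pieces (no introns in mitogenomes we model)
    from <- rng[[1]]$from; to <- rng[[length(rng)]]$to
    return(list(start = from - 1L, end = to, strand = strand, partial = partial))
  }
  r <- parse_gb_range(loc)
  list(start = r$from - 1L, end = r$to, strand = strand, partial = partial)
}

parse_gb_range <- function(txt) {
  m <- regmatches(txt, regexec("^(\\d+)\\.\\.(\\d+)$", txt))[[1]]
  if (length(m) == 3) return(list(from = as.integer(m[2]), to = as.integer(m[3])))
  if (grepl("^\\d+$", txt)) return(list(from = as.integer(txt), to = as.integer(txt)))
  stop("unrecognized range: ", txt)
}

#' Write a mitogenome as a GenBank flat file
#'
#' Inverse of [parse_genbank()]: coordinates are converted back to 1-based
#' inclusive, origin-wrapping features to `join(a..length,1..b)` and
#' minus-strand features to `complement()`. A parse of the written file
#' reproduces the genome exactly.
#'
#' @param genome A [mito_genome()].
#' @param path Output path.
#' @param accession LOCUS name to print.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path, accession = "SYNTHETIC") {
  rev_map <- c(protein = "CDS", rRNA = "rRNA", tRNA = "tRNA",
               tRNA_like = "tRNA", noncoding = "misc_feature",
               AT_rich = "D-loop", repeat_region = "repeat_region")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s   INV",
                     accession, genome$length,
                     if (genome$circular) "circular" else "linear"), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  ft <- genome$features
  for (i in seq_len(nrow(ft))) {
    f <- ft[i, ]
    loc <- if (f$end > genome$length) {
      sprintf("join(%d..%d,1..%d)", f$start + 1, genome$length,
              f$end - genome$length)
    } else sprintf("%d..%d", f$start + 1, f$end)
    if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
    key <- rev_map[[f$category]]
    writeLines(sprintf("     %-16s%s", key, loc), con)
    writeLines(sprintf('                     /gene="%s"', f$name), con)
    if (f$category == "protein") {
      writeLines(sprintf("                     /codon_start=%d",
                         f$frame_offset + 1), con)
    }
    notes <- character()
    if (f$category == "tRNA_like") notes <- c(notes, "tRNA-like")
    if (f$category == "AT_rich") notes <- c(notes, "AT rich region")
    if (f$incomplete_stop) notes <- c(notes, "incomplete stop codon")
    if (length(notes)) {
      writeLines(sprintf('                     /note="%s"',
                         paste(notes, collapse = "; ")), con)
    }
  }
  writeLines("ORIGIN", con)
  s <- tolower(genome$sequence)
  pos <- seq(1, nchar(s), by = 60)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59, nchar(s)))
    grp <- substring(chunk, seq(1, nchar(chunk), 10),
                     pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, paste(grp, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}
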