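#' Default gene catalogue for a simulated mussel mitogenome pair
#'
#' Thirteen protein-coding genes, two rRNAs, 23 tRNAs, an AT-rich region and
#' intergenic spacers, with lengths typical of an F-type mytilid mitogenome
#' (about 18 kb); all genes on one strand. The M-type variant produced by
#' [simulate_mitogenome_pair()] can carry the characteristic structural
#' differences: a relocated small-subunit rRNA, an extended atp8 (885 bp)
#' and a long repeat-rich region between the rRNAs (bringing it to about
#' 24 kb).
#'
#' @return Tibble with columns `name`, `category`, `length`.
#' @export
default_gene_table <- function() {
  prot <- tibble(
    name = c("cox1", "cox2", "cox3", "cob", "nad1", "nad2", "nad3", "nad4",
             "nad4l", "nad5", "nad6", "atp6", "atp8"),
    category = "protein",
    length = c(1536L, 690L, 786L, 1140L, 912L, 978L, 351L, 1332L, 282L,
               1671L, 501L, 708L, 369L))
  rrna <- tibble(name = c("rrnS", "rrnL"), category = "rRNA",
                 length = c(830L, 1250L))
  trna <- tibble(name = paste0("trn", LETTERS[1:23]), category = "tRNA",
                 length = 66L)
  nc <- tibble(name = c("AT_region", paste0("nc", 1:4)),
               category = c("AT_rich", rep("noncoding", 4)),
               length = c(700L, 900L, 700L, 600L, 459L))
  bind_rows(prot, rrna, trna, nc)
}

base_probs <- function(gc_content = 0.38, at_skew = 0, gc_skew = 0) {
  at <- 1 - gc_content
  p <- c(A = at * (1 + at_skew) / 2, C = gc_content * (1 - gc_skew) / 2,
         G = gc_content * (1 + gc_skew) / 2, T = at * (1 - at_skew) / 2)
  if (any(p < 0)) abort("skew/GC combination implies negative base frequency")
  p
}

random_seq <- function(len, probs) {
  paste(sample(names(probs), len, replace = TRUE, prob = probs), collapse = "")
}

# random CDS: ATG start, TAA stop, no internal stops
random_cds <- function(len, probs, code) {
  stopifnot(len %% 3 == 0, len >= 6)
  stops <- names(code$codons)[code$codons == "*"]
  n_inner <- len / 3 - 2
  inner <- character(n_inner)
  for (i in seq_len(n_inner)) {
    repeat {
      cod <- random_seq(3, probs)
      if (!cod %in% stops) break
    }
    inner[i] <- cod
  }
  paste0("ATG", paste(inner, collapse = ""), "TAA")
}

# mutate a sequence at per-site probability p (new base uniform among the
# other three); for CDS, substitutions creating a stop codon are redrawn
mutate_seq <- function(seq, p, is_cds = FALSE, code = NULL) {
  chars <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(chars)) < p)
  if (!length(hit)) return(seq)
  bases <- c("A", "C", "G", "T")
  for (s in hit) {
    orig <- chars[s]
    repeat {
      nb <- sample(setdiff(bases, orig), 1)
      chars[s] <- nb
      if (!is_cds) break
      ci <- (s - 1) %/% 3
      cod <- paste(chars[(ci * 3 + 1):(ci * 3 + 3)], collapse = "")
      if (ci == length(chars) / 3 - 1 || code$codons[[cod]] != "*") break
      # internal stop created: redraw
    }
  }
  paste(chars, collapse = "")
}

#' Simulate a divergent F/M mitogenome pair with known truth
#'
#' Builds an F-type genome gene by gene from [default_gene_table()] (or a
#' caller-supplied catalogue), then derives an M-type genome by mutating each
#' gene at its target per-gene p-distance (substitutions creating internal
#' stop codons in coding genes are redrawn). The M genome can carry the
#' structural differences characteristic of divergent paternal mitogenomes:
#' relocated rrnS, atp8 extended to 885 bp, and a long repeat region.
#' Realized per-gene divergence is binomial around the target.
#'
#' @param divergence Per-gene target p-distance: a single number or a named
#'   vector keyed by gene name. Must be in `[0, 0.75]` (beyond lies
#'   Jukes-Cantor saturation).
#' @param gene_table Gene catalogue tibble (`name`, `category`, `length`).
#' @param skew_profile Optional named list, `gene name -> list(gc_content,
#'   at_skew, gc_skew)`, controlling the base composition of that region;
#'   default composition is GC 0.38, no skew.
#' @param relocate_rrns,extend_atp8,add_repeat Structural options for the M
#'   genome.
#' @param seed Integer seed; identical seeds give identical output.
#' @param code Genetic code.
#' @return List with `genome_f`, `genome_m` ([mito_genome()]s), `alignments`
#'   (named list of gap-free two-row truth alignment tibbles, groups F/M)
#'   and `truth` (tibble of per-gene target and realized p-distance).
#' @export
simulate_mitogenome_pair <- function(divergence = 0.1,
                                     gene_table = default_gene_table(),
                                     skew_profile = NULL,
                                     relocate_rrns = TRUE, extend_atp8 = TRUE,
                                     add_repeat = TRUE, seed = NULL,
                                     code = genetic_code(5)) {
  if (!is.null(seed)) set.seed(seed)
  gt <- as_tibble(gene_table)
  div <- if (length(divergence) == 1 && is.null(names(divergence))) {
    setNames(rep(divergence, nrow(gt)), gt$name)
  } else divergence
  if (any(div < 0 | div > 0.75)) {
    abort("divergence targets must lie in [0, 0.75] (JC saturation)")
  }

  seqs_f <- seqs_m <- character(nrow(gt))
  names(seqs_f) <- names(seqs_m) <- gt$name
  truth <- list()
  alignments <- list()
  for (i in seq_len(nrow(gt))) {
    g <- gt$name[i]
    prof <- skew_profile[[g]]
    probs <- base_probs(prof$gc_content %||% 0.38, prof$at_skew %||% 0,
                        prof$gc_skew %||% 0)
    is_cds <- gt$category[i] == "protein"
    fs <- if (is_cds) random_cds(gt$length[i], probs, code) else
      random_seq(gt$length[i], probs)
    p <- unname(div[g] %||% 0)
    ms <- mutate_seq(fs, p, is_cds = is_cds, code = code)
    seqs_f[g] <- fs
    seqs_m[g] <- ms
    if (gt$category[i] %in% c("protein", "rRNA", "tRNA")) {
      af <- fs; am <- ms
      if (is_cds) { # align coding part only, stop codon excluded
        af <- substr(af, 1, nchar(af) - 3); am <- substr(am, 1, nchar(am) - 3)
      }
      alignments[[g]] <- tibble(name = c(g, g), group = c("F", "M"),
                                seq = c(af, am))
      realized <- p_distance(af, am, deletion = "pairwise")$p
    } else {
      realized <- p_distance(fs, ms, deletion = "pairwise")$p
    }
    truth[[g]] <- tibble(gene = g, category = gt$category[i],
                         target_p = p, realized_p = realized)
  }

  if (extend_atp8 && "atp8" %in% gt$name) {
    body <- substr(seqs_m[["atp8"]], 1, nchar(seqs_m[["atp8"]]) - 3)
    extra <- (885L - gt$length[gt$name == "atp8"]) / 3
    if (extra > 0) {
      probs <- base_probs()
      ext <- paste(replicate(extra, {
        repeat {
          cod <- random_seq(3, probs)
          if (code$codons[[cod]] != "*") break
        }
        cod
      }), collapse = "")
      seqs_m[["atp8"]] <- paste0(body, ext, "TAA")
    }
  }

  order_f <- gt$name
  order_m <- order_f
  if (relocate_rrns && all(c("rrnS", "rrnL") %in% order_m)) {
    order_m <- setdiff(order_m, "rrnS")
    pos <- match("rrnL", order_m)
    order_m <- append(order_m, "rrnS", after = pos)
  }
  if (add_repeat) {
    motif <- random_seq(64, base_probs(0.30))
    seqs_m[["repeat1"]] <- paste(rep(motif, 78), collapse = "")
    gt_m <- bind_rows(gt, tibble(name = "repeat1", category = "repeat_region",
                                 length = nchar(seqs_m[["repeat1"]])))
    pos <- match("rrnL", order_m) # repeat sits between the two rRNAs
    order_m <- append(order_m, "repeat1", after = pos)
  } else gt_m <- gt

  genome_f <- assemble_genome(seqs_f[order_f], gt, label = "F")
  genome_m <- assemble_genome(seqs_m[order_m], gt_m, label = "M")
  list(genome_f = genome_f, genome_m = genome_m, alignments = alignments,
       truth = list_rbind(truth))
}

assemble_genome <- function(seqs, gene_table, label) {
  cat_map <- setNames(gene_table$category, gene_table$name)
  lens <- nchar(seqs)
  ends <- cumsum(lens)
  starts <- ends - lens
  ft <- tibble(name = names(seqs), category = unname(cat_map[names(seqs)]),
               start = as.integer(starts), end = as.integer(ends),
               strand = "+", frame_offset = 0L, incomplete_stop = FALSE)
  mito_genome(paste(seqs, collapse = ""), ft, label = label)
}
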