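test_that("genbank parsing handles minimal, wrapped and malformed records", {
  gb <- tempfile(fileext = ".gb")
  seq100 <- random_circle(100, 1)
  writeLines(c(
    "LOCUS       TEST1 100 bp    DNA     circular   INV",
    "FEATURES             Location/Qualifiers",
    "     CDS             1..30",
    '                     /gene="orfA"',
    "ORIGIN",
    paste(sprintf("%9d", seq(1, 100, 60)),
          vapply(seq(1, 100, 60), function(p) tolower(substr(seq100, p, p + 59)),
                 "")),
    "//"), gb)
  g <- parse_genbank(gb)
  expect_equal(g$length, 100)
  expect_equal(g$sequence, seq100)
  expect_equal(nrow(g$features), 1)
  expect_equal(g$features$category, "protein")
  expect_equal(g$features$end - g$features$start, 30)

  # origin-wrapping join unwraps to end > length, span 31
  writeLines(c(
    "LOCUS       TEST2 100 bp    DNA     circular   INV",
    "FEATURES             Location/Qualifiers",
    "     CDS             join(95..100,1..25)",
    '                     /gene="wrap"',
    "ORIGIN",
    paste(sprintf("%9d", seq(1, 100, 60)),
          vapply(seq(1, 100, 60), function(p) tolower(substr(seq100, p, p + 59)),
                 "")),
    "//"), gb)
  gw <- parse_genbank(gb)
  expect_equal(gw$features$start, 94)
  expect_equal(gw$features$end, 125)
  expect_equal(nchar(extract_feature_sequence(gw, gw$features$name[1])), 31)

  writeLines(c("LOCUS broken", "ORIGIN", "//"), gb)
  expect_error(parse_genbank(gb), "LOCUS")
})

test_that("genbank write/parse round trip preserves coordinates and sequence", {
  pair <- simulate_mitogenome_pair(divergence = 0.05, seed = 42)
  for (g in list(pair$genome_f, pair$genome_m)) {
    tf <- tempfile(fileext = ".gb")
    write_genbank(g, tf)
    g2 <- parse_genbank(tf, label = g$label)
    expect_identical(g2$sequence, g$sequence)
    expect_identical(as.data.frame(g2$features), as.data.frame(g$features))
  }
})

test_that("feature extraction honours wrapping and strand", {
  g <- mito_genome("AAACCC")
  expect_equal(extract_feature_sequence(g, list(start = 0, end = 3, strand = "+")), "AAA")
  expect_equal(extract_feature_sequence(g, list(start = 4, end = 8, strand = "+")), "CCAA")
  expect_equal(extract_feature_sequence(g, list(start = 0, end = 3, strand = "-")), "TTT")
  expect_error(extract_feature_sequence(g, list(start = 0, end = 9, strand = "+")),
               "fit")
})

test_that("translation follows the invertebrate mitochondrial code", {
  expect_equal(translate_cds("ATGTTT"), "MF")
  expect_equal(translate_cds("ATATGA"), "MW") # ATA=Met, TGA=Trp in table 5
  expect_equal(translate_cds("ATGTT"), "M")   # incomplete terminal codon
  expect_equal(translate_cds("ATGTAA"), "M")  # terminal stop dropped
  expect_error(translate_cds("ATGTAAATG"), "codon 2")
  expect_equal(translate_cds("ATGTAAATG", allow_internal_stop = TRUE), "M*M")
})

test_that("planted peptide survives extract + translate", {
  code <- genetic_code(5)
  pep <- "MSTDEVKNALW"
  rev_map <- split(names(code$codons), unname(code$codons))
  set.seed(9)
  cds <- paste0(paste(vapply(strsplit(pep, "")[[1]],
                             function(a) sample(rev_map[[a]], 1), ""),
                      collapse = ""), "TAA")
  g <- mito_genome(paste0("AATT", cds, "GGCC"),
                   features = data.frame(name = "pep", category = "protein",
                                         start = 4, end = 4 + nchar(cds),
                                         strand = "+"))
  expect_equal(translate_cds(extract_feature_sequence(g, "pep")), pep)
})

test_that("site classification labels codon positions and degeneracy", {
  g <- mito_genome("ATGGTA",
                   features = data.frame(name = "x", category = "protein",
                                         start = 0, end = 6, strand = "+"))
  mask <- classify_sites(g)
  # ATG third position is 2-fold (ATA also Met under table 5), GTA 4-fold
  expect_equal(unclass(mask),
               c("codon_pos1", "codon_pos2", "codon_pos3_2fold",
                 "codon_pos1", "codon_pos2", "codon_pos3_4fold"))

  g0 <- mito_genome("ACGTACGT")
  expect_true(all(classify_sites(g0) == "noncoding"))

  gt <- mito_genome("ACGTACGTAC",
                    features = data.frame(name = "t", category = "tRNA",
                                          start = 2, end = 8, strand = "+"))
  expect_equal(unclass(classify_sites(gt))[3:8], rep("rna_gene", 6))
})

test_that("site classification partitions the genome", {
  pair <- simulate_mitogenome_pair(divergence = 0.1, seed = 7)
  for (g in list(pair$genome_f, pair$genome_m)) {
    mask <- classify_sites(g)
    expect_length(mask, g$length)
    expect_true(all(mask %in% c("codon_pos1", "codon_pos2", "codon_pos3_2fold",
                                "codon_pos3_4fold", "rna_gene", "noncoding")))
    # every protein position carries a codon label
    ft <- g$features[g$features$category == "protein", ]
    for (i in seq_len(nrow(ft))) {
      idx <- (seq.int(ft$start[i], ft$end[i] - 1) %% g$length) + 1
      expect_true(all(startsWith(mask[idx], "codon_pos")))
    }
  }
})

test_that("conflicting protein frames are rejected", {
  s <- paste(rep("ATGGTA", 4), collapse = "")
  g <- mito_genome(s, features = data.frame(
    name = c("a", "b"), category = "protein",
    start = c(0, 1), end = c(12, 13), strand = "+"))
  expect_error(classify_sites(g), "frames")
})

test_that("genetic code table is complete and degeneracy is consistent", {
  code <- genetic_code(5)
  expect_length(code$codons, 64)
  expect_equal(sum(code$codons == "*"), 2) # TAA, TAG only
  expect_equal(unname(code$degeneracy["GTA", ]), c(1, 1, 4))
  expect_equal(unname(code$degeneracy["ATG", 3]), 2)
})
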