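test_that("pairwise p-distance matches hand counts and ape", {
  expect_equal(p_distance("AAAA", "AAAA"), list(p = 0, n_sites = 4))
  expect_equal(p_distance("AAAA", "TTTT"), list(p = 1, n_sites = 4))
  expect_equal(p_distance("AA-A", "ATTA"), list(p = 1 / 3, n_sites = 3))
  # pairwise deletion keeps the gap column out for this pair only
  expect_equal(p_distance("AA-A", "ATTA", deletion = "pairwise"),
               list(p = 1 / 3, n_sites = 3))
  expect_true(is.na(p_distance("----", "AAAA")$p))

  skip_if_not_installed("ape")
  for (seed in 1:3) {
    seqs <- random_nt_alignment(2, 60, seed, p_gap = 0)
    ours <- p_distance(seqs[1], seqs[2])$p
    bin <- ape::as.DNAbin(strsplit(tolower(seqs), ""))
    theirs <- as.numeric(ape::dist.dna(bin, model = "raw"))
    expect_equal(ours, theirs)
  }
})

test_that("between-group mean equals the brute-force pair average", {
  aln <- tibble::tibble(name = c("f1", "f2", "m1", "m2"),
                        group = c("F", "F", "M", "M"),
                        seq = c("AAAA", "AATA", "TTAA", "ATTT"))
  res <- between_group_p_distance(aln, "F", "M", bootstrap_reps = 200, seed = 1)
  brute <- mean(c(p_distance("AAAA", "TTAA")$p, p_distance("AAAA", "ATTT")$p,
                  p_distance("AATA", "TTAA")$p, p_distance("AATA", "ATTT")$p))
  expect_equal(res$mean_p, brute)

  one <- between_group_p_distance(
    tibble::tibble(name = c("a", "b"), group = c("F", "M"),
                   seq = c("AAAA", "AATT")), bootstrap_reps = 0)
  expect_equal(one$mean_p, 0.5)
  zero <- between_group_p_distance(
    tibble::tibble(name = c("a", "b", "c"), group = c("F", "F", "M"),
                   seq = c("AAAA", "AAAA", "AAAA")),
    bootstrap_reps = 100, seed = 1)
  expect_equal(zero$mean_p, 0)
  expect_equal(zero$se, 0)
})

test_that("mean p is invariant to column permutation; bootstrap SE shrinks", {
  set.seed(14)
  seqs <- random_nt_alignment(4, 40, 21)
  aln <- tibble::tibble(name = paste0("s", 1:4), group = c("F", "F", "M", "M"),
                        seq = seqs)
  perm <- sample(40)
  aln2 <- aln
  aln2$seq <- vapply(strsplit(seqs, ""), function(ch)
    paste(ch[perm], collapse = ""), "")
  expect_equal(between_group_p_distance(aln, bootstrap_reps = 0)$mean_p,
               between_group_p_distance(aln2, bootstrap_reps = 0)$mean_p)

  # fixed-divergence synthetic pair, SE at two alignment lengths
  ses <- vapply(c(300, 4800), function(L) {
    set.seed(31)
    a <- random_circle(L, 31)
    chars <- strsplit(a, "")[[1]]
    hit <- which(runif(L) < 0.2)
    for (s in hit) chars[s] <- sample(setdiff(c("A", "C", "G", "T"), chars[s]), 1)
    aln <- tibble::tibble(name = c("f", "m"), group = c("F", "M"),
                          seq = c(a, paste(chars, collapse = "")))
    between_group_p_distance(aln, bootstrap_reps = 400, seed = 5)$se
  }, numeric(1))
  expect_lt(ses[2], ses[1] / 2) # SE ~ 1/sqrt(L)
})

test_that("per-gene divergence recovers generator truth and conventions", {
  pair <- simulate_mitogenome_pair(divergence = 0.10, seed = 101)
  div <- per_gene_divergence(pair$genome_f, pair$genome_m, pair$alignments,
                             bootstrap_reps = 200, seed = 1)
  overall <- div[div$gene == "overall", ]
  expect_equal(overall$molecule, "nt")
  expect_lt(abs(overall$p_distance - 0.10), 0.01)
  # protein rows report amino-acid distances, RNA rows nucleotide
  expect_true(all(div$molecule[div$gene %in% c("cox1", "atp8")] == "aa"))
  expect_true(all(div$molecule[div$gene %in% c("rrnS", "trnA")] == "nt"))
  # aa distance of a protein gene differs from its nt truth (synonymous sites)
  nt_p <- pair$truth$realized_p[pair$truth$gene == "cox1"]
  expect_false(isTRUE(all.equal(div$p_distance[div$gene == "cox1"], nt_p)))

  pair0 <- simulate_mitogenome_pair(divergence = 0, seed = 102)
  div0 <- per_gene_divergence(pair0$genome_f, pair0$genome_m, pair0$alignments,
                              bootstrap_reps = 10, seed = 1)
  expect_true(all(div0$p_distance == 0))
  expect_true(all(div0$bootstrap_se == 0))

  # a gene absent from one genome is skipped with a warning
  alns <- pair$alignments
  alns$ghost <- alns$cox1
  expect_warning(
    div2 <- per_gene_divergence(pair$genome_f, pair$genome_m, alns,
                                bootstrap_reps = 0),
    "ghost")
  expect_false("ghost" %in% div2$gene)
})

test_that("alignment FASTA round trip keeps names, groups, sequences", {
  aln <- tibble::tibble(name = c("hapA", "hapB"), group = c("F", "M"),
                        seq = c("ACGT-ACG", "ACGTTACG"))
  tf <- tempfile(fileext = ".fasta")
  write_alignment(aln, tf)
  back <- read_alignment(tf)
  expect_equal(back$name, aln$name)
  expect_equal(back$group, aln$group)
  expect_equal(back$seq, aln$seq)
})
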