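# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force or direct transcription of published formulas,
# by routes different from the package implementation.

# --- composition: direct character counting on a window string ---------------
oracle_window_stat <- function(seq_str, start0, window, index) {
  len <- nchar(seq_str)
  idx <- (seq.int(start0, start0 + window - 1) %% len) + 1
  chars <- strsplit(seq_str, "")[[1]][idx]
  n <- c(A = sum(chars == "A"), C = sum(chars == "C"),
         G = sum(chars == "G"), T = sum(chars == "T"))
  switch(index,
    AT_skew = (n["A"] - n["T"]) / (n["A"] + n["T"]),
    GC_skew = (n["G"] - n["C"]) / (n["G"] + n["C"]),
    GC_content = (n["G"] + n["C"]) / sum(n))
}

random_circle <- function(len, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# --- popgen: exhaustive pairwise-difference oracle ---------------------------
oracle_diversity <- function(seqs) {
  n <- length(seqs)
  mat <- do.call(rbind, strsplit(seqs, ""))
  keep <- vapply(seq_len(ncol(mat)), function(j)
    all(mat[, j] %in% c("A", "C", "G", "T")), logical(1))
  mat <- mat[, keep, drop = FALSE]
  L <- ncol(mat)
  S <- 0L
  for (j in seq_len(L)) if (length(unique(mat[, j])) > 1) S <- S + 1L
  haps <- apply(mat, 1, paste, collapse = "")
  h <- length(unique(haps))
  hd <- n / (n - 1) * (1 - sum((table(haps) / n)^2))
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    tot <- tot + sum(mat[i, ] != mat[j, ]); np <- np + 1
  }
  list(N = n, S = S, h = h, hd = hd, pi = tot / np / L, L = L,
       theta = S / (sum(1 / seq_len(n - 1)) * L))
}

# --- Tajima (1989): literal transcription of the published constants ---------
oracle_tajima_d <- function(seqs) {
  o <- oracle_diversity(seqs)
  n <- o$N; S <- o$S
  a1 <- sum(1 / 1:(n - 1)); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (o$pi * o$L - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# --- Nei-Gojobori single-codon oracle: explicit path enumeration -------------
oracle_ng_code <- function() mitodui::genetic_code(5)$codons

oracle_ng_sites <- function(codon, codons = oracle_ng_code()) {
  bases <- c("A", "C", "G", "T")
  syn_total <- 0
  for (pos in 1:3) {
    alt <- character(0)
    for (b in bases) {
      if (b == substr(codon, pos, pos)) next
      v <- codon; substr(v, pos, pos) <- b
      if (codons[[v]] != "*") alt <- c(alt, codons[[v]])
    }
    if (length(alt)) syn_total <- syn_total + mean(alt == codons[[codon]])
  }
  c(syn = syn_total, nonsyn = 3 - syn_total)
}

# all orders of the differing positions, iteratively (not recursively)
oracle_orders <- function(pos) {
  k <- length(pos)
  if (k == 1) return(list(pos))
  if (k == 2) return(list(pos, rev(pos)))
  out <- list()
  for (i in 1:3) for (j in setdiff(1:3, i)) {
    out[[length(out) + 1]] <- c(pos[i], pos[j], pos[setdiff(1:3, c(i, j))])
  }
  out
}

oracle_ng_diffs <- function(c1, c2, codons = oracle_ng_code()) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(syn = 0, nonsyn = 0))
  paths <- oracle_orders(pos)
  res <- list(); res_stop <- list()
  for (ord in paths) {
    cur <- c1; sd <- 0; nd <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur; substr(nxt, p, p) <- substr(c2, p, p)
      if (codons[[nxt]] == "*") blocked <- TRUE
      if (codons[[nxt]] == codons[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (blocked) res_stop[[length(res_stop) + 1]] <- c(sd, nd)
    else res[[length(res) + 1]] <- c(sd, nd)
  }
  use <- if (length(res)) res else res_stop
  m <- colMeans(do.call(rbind, use))
  c(syn = m[1], nonsyn = m[2])
}

# --- misc --------------------------------------------------------------------
random_nt_alignment <- function(n, L, seed, p_gap = 0.08) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T", "-"), L, replace = TRUE,
                 prob = c(rep((1 - p_gap) / 4, 4), p_gap)), collapse = ""),
    character(1))
}
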