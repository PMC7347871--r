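## Nei-Gojobori (1986) synonymous/nonsynonymous analysis with Jukes-Cantor
## correction. Site counts use per-position degeneracy fractions with
## mutations to stop codons excluded from the denominator; differences
## between codons are averaged over all minimal mutational pathways, with
## pathways passing through a stop codon disallowed (falling back to all
## pathways only when every one is blocked).

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

# fraction of synonymous changes at each position of one codon (stop-excluded)
ng_codon_sites <- function(codon, code) {
  aa <- code$codons[[codon]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0; tot <- 0
    for (bse in setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))) {
      v <- codon
      substr(v, pos, pos) <- bse
      if (code$codons[[v]] == "*") next
      tot <- tot + 1
      if (code$codons[[v]] == aa) syn <- syn + 1
    }
    s <- s + if (tot > 0) syn / tot else 0
  }
  c(syn = s, nonsyn = 3 - s)
}

# average synonymous/nonsynonymous differences between two codons over
# minimal pathways (recursive over orders of the differing positions)
ng_codon_diffs <- function(c1, c2, code) {
  diff_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(diff_pos)
  if (k == 0) return(c(syn = 0, nonsyn = 0))
  paths <- perms(diff_pos)
  acc <- matrix(NA_real_, nrow(paths), 2)
  for (p in seq_len(nrow(paths))) {
    cur <- c1; sd <- 0; nd <- 0; ok <- TRUE
    for (pos in paths[p, ]) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (code$codons[[nxt]] == "*") { ok <- FALSE; break }
      if (code$codons[[nxt]] == code$codons[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) acc[p, ] <- c(sd, nd)
  }
  if (all(is.na(acc[, 1]))) {
    # every pathway blocked by a stop: fall back to counting through stops
    for (p in seq_len(nrow(paths))) {
      cur <- c1; sd <- 0; nd <- 0
      for (pos in paths[p, ]) {
        nxt <- cur
        substr(nxt, pos, pos) <- substr(c2, pos, pos)
        if (code$codons[[nxt]] == code$codons[[cur]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      acc[p, ] <- c(sd, nd)
    }
  }
  m <- colMeans(acc, na.rm = TRUE)
  c(syn = m[1], nonsyn = m[2])
}

perms <- function(v) {
  if (length(v) == 1) return(matrix(v, 1, 1))
  out <- list()
  for (i in seq_along(v)) {
    rest <- perms(v[-i])
    out[[i]] <- cbind(v[i], rest)
  }
  do.call(rbind, out)
}

# cached lookup tables: per-codon site counts and 64x64 difference matrices
ng_tables <- function(code) {
  key <- paste0("ng_", code$table_id)
  if (!is.null(the[[key]])) return(the[[key]])
  cods <- all_codons()
  sites <- t(vapply(cods, ng_codon_sites, numeric(2), code = code))
  rownames(sites) <- cods
  Sd <- Nd <- matrix(0, 64, 64, dimnames = list(cods, cods))
  for (i in seq_len(64)) {
    for (j in seq_len(64)) {
      if (i == j) next
      d <- ng_codon_diffs(cods[i], cods[j], code)
      Sd[i, j] <- d[["syn"]]
      Nd[i, j] <- d[["nonsyn"]]
    }
  }
  obj <- list(sites = sites, Sd = Sd, Nd = Nd)
  the[[key]] <- obj
  obj
}

jc_correct <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 / 3 * p))
}

#' Nei-Gojobori Ka/Ks with Jukes-Cantor correction
#'
#' For every sequence pair, synonymous (S) and nonsynonymous (N) site counts
#' are averaged from per-position degeneracy fractions of the two sequences;
#' synonymous (Sd) and nonsynonymous (Nd) differences are averaged over all
#' minimal mutational pathways between differing codons. Proportions
#' pS = Sd/S and pN = Nd/N are Jukes-Cantor corrected,
#' \eqn{d = -\frac{3}{4}\ln(1 - \frac{4}{3} p)}, and Ka, Ks are the means of
#' the corrected values over pairs. Standard errors come from resampling
#' codon columns with replacement. Mutations to stop codons are excluded from
#' site counts and pathways through stops are disallowed; codons containing
#' gaps, N, or a stop in either sequence are skipped for that pair.
#'
#' @param hs Haplotype set (tibble with `seq`, or character vector) for
#'   within-group polymorphism mode; for divergence between groups supply
#'   `groups` labels and the two group names.
#' @param groups Optional vector of group labels, one per sequence; with
#'   `between`, only cross-group pairs are used.
#' @param between Length-2 character vector of group names to compare.
#' @param frame_offset Bases skipped before the first codon.
#' @param code A [genetic_code()].
#' @param bootstrap_reps Codon-bootstrap replicates for the SEs (default
#'   1,000).
#' @param seed Integer seed for the bootstrap.
#' @return One-row tibble: `Ka`, `Ka_SE`, `Ks`, `Ks_SE`, `Ka_over_Ks`,
#'   `n_codons`, `saturated` (TRUE when a JC correction was undefined for
#'   some pair).
#' @examples
#' nei_gojobori_kaks(c("TTTTTT", "TTATTA"), bootstrap_reps = 100, seed = 1)
#' @export
nei_gojobori_kaks <- function(hs, groups = NULL, between = NULL,
                              frame_offset = 0, code = genetic_code(5),
                              bootstrap_reps = 1000, seed = NULL) {
  seqs <- if (is.character(hs)) hs else hs$seq
  if (!is.null(frame_offset) && frame_offset > 0) {
    seqs <- substr(seqs, frame_offset + 1, nchar(seqs))
  }
  n <- length(seqs)
  if (n < 2) abort("need at least 2 sequences")
  n_cod <- min(nchar(seqs)) %/% 3
  if (n_cod < 1) abort("sequences shorter than one codon")
  tabs <- ng_tables(code)
  cod_mat <- vapply(seqs, function(s)
    substring(s, 3 * seq_len(n_cod) - 2, 3 * seq_len(n_cod)), character(n_cod))
  cod_mat <- matrix(cod_mat, n_cod, n)
  valid <- matrix(cod_mat %in% rownames(tabs$sites) &
                    !(as.vector(cod_mat) %in% names(code$codons)[code$codons == "*"]),
                  n_cod, n)

  pair_idx <- if (!is.null(groups) && !is.null(between)) {
    ga <- which(groups == between[1]); gb <- which(groups == between[2])
    if (!length(ga) || !length(gb)) abort("empty group")
    as.matrix(expand.grid(i = ga, j = gb))
  } else {
    t(combn(n, 2))
  }
  n_pairs <- nrow(pair_idx)

  # per-pair per-codon arrays for point estimate and codon bootstrap
  arr_S <- arr_N <- arr_Sd <- arr_Nd <- arr_ok <- matrix(0, n_pairs, n_cod)
  for (k in seq_len(n_pairs)) {
    i <- pair_idx[k, 1]; j <- pair_idx[k, 2]
    ok <- valid[, i] & valid[, j]
    ci <- cod_mat[ok, i]; cj <- cod_mat[ok, j]
    arr_ok[k, ok] <- 1
    arr_S[k, ok] <- (tabs$sites[ci, "syn"] + tabs$sites[cj, "syn"]) / 2
    arr_N[k, ok] <- (tabs$sites[ci, "nonsyn"] + tabs$sites[cj, "nonsyn"]) / 2
    arr_Sd[k, ok] <- tabs$Sd[cbind(ci, cj)]
    arr_Nd[k, ok] <- tabs$Nd[cbind(ci, cj)]
  }

  est <- function(cols) {
    S <- rowSums(arr_S[, cols, drop = FALSE])
    N <- rowSums(arr_N[, cols, drop = FALSE])
    Sd <- rowSums(arr_Sd[, cols, drop = FALSE])
    Nd <- rowSums(arr_Nd[, cols, drop = FALSE])
    dS <- jc_correct(ifelse(S > 0, Sd / S, 0))
    dN <- jc_correct(ifelse(N > 0, Nd / N, 0))
    c(Ka = mean(dN, na.rm = TRUE), Ks = mean(dS, na.rm = TRUE),
      sat = anyNA(dS) || anyNA(dN))
  }
  point <- est(seq_len(n_cod))

  Ka_SE <- Ks_SE <- NA_real_
  if (bootstrap_reps > 0 && n_cod >= 2) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    reps <- vapply(seq_len(bootstrap_reps), function(r)
      est(sample.int(n_cod, n_cod, replace = TRUE))[1:2], numeric(2))
    Ka_SE <- sd(reps[1, ], na.rm = TRUE)
    Ks_SE <- sd(reps[2, ], na.rm = TRUE)
  }
  Ka <- point[["Ka"]]; Ks <- point[["Ks"]]
  tibble(Ka = Ka, Ka_SE = Ka_SE, Ks = Ks, Ks_SE = Ks_SE,
         Ka_over_Ks = if (!is.na(Ks) && Ks > 0) Ka / Ks else NA_real_,
         n_codons = n_cod, saturated = as.logical(point[["sat"]]))
}
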