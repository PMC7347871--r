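## Neutral coalescent machinery. Time is scaled so that k lineages coalesce
## at rate k(k-1)/2 and mutations fall on branches at rate theta_locus/2,
## giving the standard Watterson expectation E[S] = theta_locus * a1.

# topology + branch lengths of a Kingman coalescent tree for n tips
# nodes 1..n are tips, n+1..2n-1 internal, 2n-1 the root
sim_kingman_tree <- function(n) {
  n_nodes <- 2L * n - 1L
  children <- vector("list", n_nodes)
  node_time <- numeric(n_nodes)
  active <- seq_len(n)
  nxt <- n + 1L
  t <- 0
  while (length(active) > 1) {
    k <- length(active)
    t <- t + rexp(1, k * (k - 1) / 2)
    pick <- sample(length(active), 2)
    pair <- active[pick]
    children[[nxt]] <- pair
    node_time[nxt] <- t
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
  }
  branch <- numeric(n_nodes) # length of branch above each non-root node
  parent <- integer(n_nodes)
  for (v in seq.int(n + 1L, n_nodes)) {
    for (ch in children[[v]]) {
      parent[ch] <- v
      branch[ch] <- node_time[v] - node_time[ch]
    }
  }
  tips_below <- vector("list", n_nodes)
  for (v in seq_len(n)) tips_below[[v]] <- v
  for (v in seq.int(n + 1L, n_nodes)) {
    tips_below[[v]] <- unlist(tips_below[children[[v]]])
  }
  list(n = n, children = children, parent = parent, branch = branch,
       tips_below = tips_below, total_branch = sum(branch))
}

#' Simulate haplotypes under the standard neutral coalescent
#'
#' Genealogy: exponential coalescence times at rate \eqn{\binom{k}{2}};
#' mutations Poisson on branches at \eqn{\theta L/2} per unit branch length.
#' The default infinite-sites mode places each mutation at a previously
#' untouched position (all descendant tips get the same derived base), so
#' Watterson's and Tajima's estimators apply exactly. Codon mode evolves a
#' stop-free codon sequence instead: proposed single-base changes are
#' rejected if they create a stop, accepted if synonymous, and accepted with
#' probability `omega` if nonsynonymous — giving a known Ka/Ks truth.
#'
#' @param n Number of sampled haplotypes (>= 2).
#' @param length Sequence length in bp (codon mode: a multiple of 3).
#' @param theta_per_site Population-scaled mutation rate per site.
#' @param omega `NULL` for neutral infinite sites, or the target
#'   nonsynonymous/synonymous rate ratio for codon mode.
#' @param frame_offset Carried onto the result for downstream codon stats.
#' @param region Region name attribute.
#' @param seed Integer seed.
#' @param code Genetic code (codon mode).
#' @return Tibble with columns `name`, `seq`; attributes `region`,
#'   `frame_offset`, `theta_per_site`, `omega` and `truth` (list with `S`
#'   = realized segregating mutations placed, `total_branch`,
#'   `n_substitutions` in codon mode).
#' @examples
#' hs <- simulate_haplotypes(n = 6, length = 100, theta_per_site = 0.02, seed = 1)
#' diversity_stats(hs)
#' @export
simulate_haplotypes <- function(n, length, theta_per_site, omega = NULL,
                                frame_offset = 0, region = "sim", seed = NULL,
                                code = genetic_code(5)) {
  if (n < 2) abort("n must be >= 2")
  if (theta_per_site <= 0) abort("theta_per_site must be positive")
  if (!is.null(seed)) set.seed(seed)
  tree <- sim_kingman_tree(n)
  theta_locus <- theta_per_site * length

  if (is.null(omega)) {
    # infinite sites
    n_mut <- rpois(1, theta_locus / 2 * tree$total_branch)
    n_mut <- min(n_mut, length) # cannot place more distinct sites than bp
    seqs_mat <- matrix(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                       nrow = n, ncol = length, byrow = TRUE)
    truth_S <- 0L
    if (n_mut > 0) {
      carriers <- lapply(seq_len(n_mut), function(m) {
        v <- sample.int(2L * n - 2L, 1, prob = tree$branch[seq_len(2L * n - 2L)])
        tree$tips_below[[v]]
      })
      # drop mutations carried by all or no tips (none occur: root excluded)
      sites <- sample.int(length, n_mut)
      for (m in seq_len(n_mut)) {
        anc <- seqs_mat[1, sites[m]]
        derived <- sample(setdiff(c("A", "C", "G", "T"), anc), 1)
        seqs_mat[carriers[[m]], sites[m]] <- derived
        truth_S <- truth_S + 1L
      }
    }
    seqs <- apply(seqs_mat, 1, paste, collapse = "")
    truth <- list(S = truth_S, total_branch = tree$total_branch)
  } else {
    if (length %% 3 != 0) abort("codon mode needs length divisible by 3")
    stops <- names(code$codons)[code$codons == "*"]
    non_stop <- setdiff(names(code$codons), stops)
    root <- paste(sample(non_stop, length / 3, replace = TRUE), collapse = "")
    n_sub <- 0L
    seqs <- character(n)
    evolve <- function(node, s) {
      t <- tree$branch[node]
      if (t > 0) {
        n_ev <- rpois(1, theta_locus / 2 * t)
        if (n_ev > 0) {
          chars <- strsplit(s, "")[[1]]
          for (e in seq_len(n_ev)) {
            pos <- sample.int(length, 1)
            nb <- sample(setdiff(c("A", "C", "G", "T"), chars[pos]), 1)
            ci <- (pos - 1) %/% 3
            old_cod <- paste(chars[(ci * 3 + 1):(ci * 3 + 3)], collapse = "")
            new_cod <- old_cod
            substr(new_cod, (pos - 1) %% 3 + 1, (pos - 1) %% 3 + 1) <- nb
            if (code$codons[[new_cod]] == "*") next
            syn <- code$codons[[new_cod]] == code$codons[[old_cod]]
            if (syn || runif(1) < omega) {
              chars[pos] <- nb
              n_sub <<- n_sub + 1L
            }
          }
          s <- paste(chars, collapse = "")
        }
      }
      if (node <= n) {
        seqs[node] <<- s
      } else {
        for (ch in tree$children[[node]]) evolve(ch, s)
      }
    }
    evolve(2L * n - 1L, root)
    truth <- list(S = NA_integer_, total_branch = tree$total_branch,
                  n_substitutions = n_sub)
  }
  out <- tibble(name = paste0("hap", seq_len(n)), seq = unname(seqs))
  attr(out, "region") <- region
  attr(out, "frame_offset") <- frame_offset
  attr(out, "theta_per_site") <- theta_per_site
  attr(out, "omega") <- omega
  attr(out, "truth") <- truth
  out
}
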