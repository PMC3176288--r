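# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# brute-force CpG scan: inspect every adjacent base pair
bruteCpgScan <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  which(ch[-length(ch)] == "C" & ch[-1] == "G")
}

# all n! permutations of 1..n (recursive; fine for n <= 7)
allPermutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- allPermutations(n - 1L)
  out <- list()
  for (p in sub) for (pos in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  }
  out
}

# exact permutation p-value for the Kruskal-Wallis H, with the statistic
# taken from stats::kruskal.test (independent implementation): proportion
# of all N! orderings of the pooled data whose H reaches the observed H
kwOracleExactP <- function(groups) {
  v <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  hObs <- unname(stats::kruskal.test(v, factor(g))$statistic)
  perms <- allPermutations(length(v))
  hAll <- vapply(perms, function(p)
    unname(stats::kruskal.test(v[p], factor(g))$statistic), numeric(1))
  list(h = hObs, p = mean(hAll >= hObs - 1e-8))
}

# random DNA string
randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")
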