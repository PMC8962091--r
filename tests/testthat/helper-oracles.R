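# Exhaustive-enumeration oracles for the rank statistics, independent of
# the implementation path (which goes through stats::cor.test /
# wilcox.test / the package's own permutation code).

# all permutations of 1..n (n small)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))))
}

# two-sided Spearman p by enumeration of all rank permutations
spearman_p_exhaustive <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry, method = "pearson"))
  perms <- all_permutations(length(x))
  rhos <- apply(perms, 1, function(p) cor(rx, ry[p], method = "pearson"))
  mean(abs(rhos) >= obs - 1e-12)
}

# two-sided Mann-Whitney p by enumeration of all group assignments
mann_whitney_p_exhaustive <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  u_stat <- function(ia) sum(rank(pooled)[ia]) - n1 * (n1 + 1) / 2
  obs <- u_stat(seq_len(n1))
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, u_stat)
  mu <- n1 * length(b) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}
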