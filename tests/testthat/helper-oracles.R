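# Exhaustive-enumeration oracles for the rank tests, kept independent
# of the implementation paths they check.

# Exact one-sided Mann-Whitney p-value by enumerating every assignment
# of the pooled ranks to group A.
mw_enum_p <- function(a, b, alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  w_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  subsets <- utils::combn(length(pooled), na)
  w_all <- colSums(matrix(r[subsets], nrow = na)) - na * (na + 1) / 2
  if (alternative == "less") mean(w_all <= w_obs + 1e-9)
  else mean(w_all >= w_obs - 1e-9)
}

# Exact one-sided Wilcoxon signed-rank p-value by enumerating all 2^n
# sign patterns of the absolute-difference ranks.
wsr_enum_p <- function(x, y, alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- drop(signs %*% r)
  if (alternative == "greater") mean(v_all >= v_obs - 1e-9)
  else mean(v_all <= v_obs + 1e-9)
}

# All permutations of a vector (n! rows), built by simple recursion --
# deliberately a different enumeration structure from the combination
# recursion used inside the package.
all_perms <- function(v) {
  if (length(v) <= 1) return(matrix(v, nrow = 1))
  do.call(rbind, lapply(seq_along(v), function(i) {
    cbind(v[i], all_perms(v[-i]))
  }))
}

# Kruskal-Wallis H with tie correction, written from the closed form.
kw_h <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  rj <- tapply(r, groups, sum)
  nj <- tapply(r, groups, length)
  h <- 12 / (n * (n + 1)) * sum(rj^2 / nj) - 3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Exact Kruskal-Wallis p by evaluating H over all n! orderings of the
# observed values against the fixed group-label template.
kw_enum_p <- function(values, groups) {
  h_obs <- kw_h(values, groups)
  perms <- all_perms(seq_along(values))
  h_all <- apply(perms, 1, function(idx) kw_h(values[idx], groups))
  mean(h_all >= h_obs - 1e-9)
}
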