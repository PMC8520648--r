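# Shared fixtures and brute-force oracles. Oracles here are deliberately
# independent of the package implementation: enumeration over all subsets,
# permutations, or pairs.

# Build participant records that ordinalise() maps back to the given levels.
records_from_levels <- function(levels_t, levels_c, scale,
                                with_time = TRUE) {
  k <- n_levels(scale)
  mk <- function(lev, arm) {
    event <- as.integer(lev > 0L)
    out <- data.frame(arm = arm, age = 65, sex = 0L, diabetes = 0L,
                      event = event,
                      fatal = as.integer(lev == k - 1L),
                      severity_attr = ifelse(lev > 0L & lev < k - 1L,
                                             scale$levels[lev + 1L],
                                             NA_character_),
                      stringsAsFactors = FALSE)
    if (with_time) {
      out$time <- ifelse(event == 1L, 100, 365)
      out$observed <- event
    }
    out
  }
  rbind(mk(levels_t, "treatment"), mk(levels_c, "control"))
}

dataset_from_levels <- function(levels_t, levels_c, scale, id = "fix", ...) {
  comparator_dataset(id, records_from_levels(levels_t, levels_c, scale, ...))
}

# Exact permutation distribution of the treatment rank-sum W over all
# choose(n, n1) group assignments of the pooled values.
perm_ranksum <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); n <- length(pooled)
  r <- rank(pooled)
  idx <- utils::combn(n, n1)
  list(W = colSums(matrix(r[idx], nrow = n1)), obs = sum(r[seq_len(n1)]))
}

# Conventional exact two-sided permutation p-value for the Mann-Whitney test.
exact_mwu_p <- function(x, y) {
  pd <- perm_ranksum(x, y)
  mu <- length(x) * (length(x) + length(y) + 1) / 2
  mean(abs(pd$W - mu) >= abs(pd$obs - mu) - 1e-9)
}

# Win/loss/tie counts by direct enumeration over all treatment x control pairs.
enumerate_wr <- function(levels_t, levels_c) {
  g <- expand.grid(t = levels_t, c = levels_c)
  c(Nw = sum(g$t < g$c), Nl = sum(g$t > g$c), Nt = sum(g$t == g$c))
}

# Mann-Whitney U of treatment over control (control worse counts as a win,
# ties count half), by direct enumeration.
enumerate_u <- function(levels_t, levels_c) {
  g <- expand.grid(t = levels_t, c = levels_c)
  sum(g$c > g$t) + 0.5 * sum(g$c == g$t)
}

# Exact permutation p-value for the tie-adjusted Friedman statistic on a small
# rank matrix: enumerate all (k!)^n within-row permutations.
perm_friedman_p <- function(ranks) {
  n <- nrow(ranks); k <- ncol(ranks)
  stat_of <- function(R) {
    A <- 12 * sum(colSums(R)^2) / (n * k * (k + 1)) - 3 * n * (k + 1)
    ties <- sum(apply(R, 1L, function(r) { t <- table(r); sum(t^3 - t) }))
    C <- 1 - ties / (n * k * (k^2 - 1))
    if (C <= .Machine$double.eps) 0 else A / C
  }
  obs <- stat_of(ranks)
  perms <- as.matrix(expand.grid(rep(list(seq_len(factorial(k))), n)))
  allp <- permutations_of(k)
  count <- 0L
  for (i in seq_len(nrow(perms))) {
    R <- t(vapply(seq_len(n), function(r) ranks[r, allp[perms[i, r], ]],
                  numeric(k)))
    if (stat_of(R) >= obs - 1e-9) count <- count + 1L
  }
  count / nrow(perms)
}

permutations_of <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(k - 1L)
  out <- matrix(0L, 0L, k)
  for (pos in seq_len(k)) {
    out <- rbind(out, cbind(sub[, seq_len(pos - 1L), drop = FALSE], k,
                            sub[, seq(pos, k - 1L)[seq_len(k - pos)],
                                drop = FALSE]))
  }
  out
}

# Studentized-range check of a single span on the rank-matrix scale, used as
# the all-pairs oracle for the Duncan letter display.
range_significant <- function(ranks, i, j, alpha = 0.05) {
  means <- sort(colMeans(ranks))
  n <- nrow(ranks); k <- ncol(ranks)
  mse <- sum(sweep(ranks, 2L, colMeans(ranks))^2) / ((n - 1) * (k - 1))
  p <- j - i + 1L
  alpha_p <- 1 - (1 - alpha)^(p - 1L)
  (means[j] - means[i]) > qtukey(1 - alpha_p, p, (n - 1) * (k - 1)) * sqrt(mse / n)
}
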