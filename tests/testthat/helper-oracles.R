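# Independent reference implementations used as oracles. These deliberately
# use naive loops / generic optimizers so they share no code path with the
# package.

# TOM by naive triple loop
naive_tom <- function(a) {
  n <- nrow(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    ki <- sum(a[i, -i])
    kj <- sum(a[j, -j])
    tom[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  tom
}

# average-linkage agglomeration by direct O(n^3) loops; returns the sorted
# sequence of merge heights
naive_average_linkage_heights <- function(d) {
  n <- nrow(d)
  active <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(Inf, 0, 0)
    for (i in seq_len(length(active) - 1)) for (j in (i + 1):length(active)) {
      h <- mean(d[active[[i]], active[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1])
    merged <- c(active[[best[2]]], active[[best[3]]])
    active <- active[-c(best[2], best[3])]
    active[[length(active) + 1]] <- merged
  }
  heights
}

# two-group log-rank by direct accumulation of O - E and hypergeometric
# variance at each distinct event time
direct_logrank <- function(time, event, group) {
  g1 <- group == sort(unique(group))[1]
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- o_minus_e^2 / v
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}

# Breslow partial log-likelihood for a single covariate
breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# maximize the Breslow partial likelihood by generic 1-d optimization
grid_search_cox_beta <- function(time, event, x, lower = -8, upper = 8) {
  stats::optimize(function(b) breslow_loglik(b, time, event, x),
                  c(lower, upper), maximum = TRUE, tol = 1e-10)$maximum
}

# independent scale-free power selection: own adjacency, own binning and fit
reference_power_choice <- function(expr, powers, target, n_breaks = 10) {
  cc <- abs(stats::cor(t(expr)))
  diag(cc) <- 0
  r2s <- sapply(powers, function(p) {
    k <- rowSums(cc^p)
    k <- k[k > 0]
    bins <- cut(k, n_breaks)
    f <- as.vector(table(bins))
    ctr <- tapply(k, bins, mean)
    keep <- f > 0 & !is.na(ctr)
    fm <- lm(log10(f[keep]) ~ log10(ctr[keep]))
    -sign(coef(fm)[[2]]) * summary(fm)$r.squared
  })
  if (any(r2s >= target)) powers[which(r2s >= target)[1]]
  else powers[which.max(r2s)]
}

ari_oracle <- function(a, b) {
  skip_if_not_installed("mclust")
  mclust::adjustedRandIndex(a, b)
}
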