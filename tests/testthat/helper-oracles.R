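# Independent brute-force oracles used to pin down the expected behaviour of
# the package's operations. Each one is a straight-line re-implementation of
# the underlying definition, kept deliberately naive.

# UPGMA by recomputing the full average cross-cluster dissimilarity from the
# original matrix at every step (no Lance-Williams update). Ties broken by
# the lexicographically smallest (smallest-label, larger-label) pair.
oracle_upgma <- function(S) {
  D <- 1 - S
  labels <- rownames(D)
  clusters <- lapply(seq_along(labels), identity)
  avg_d <- function(a, b) mean(D[clusters[[a]], clusters[[b]]])
  steps <- list()
  while (length(clusters) > 1L) {
    k <- length(clusters)
    best <- NULL
    for (a in 1:(k - 1)) {
      for (b in (a + 1):k) {
        d <- avg_d(a, b)
        key <- sort(c(min(labels[clusters[[a]]]), min(labels[clusters[[b]]])))
        cand <- list(a = a, b = b, d = d, key = key)
        if (is.null(best) || d < best$d ||
            (d == best$d &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- cand
        }
      }
    }
    members <- sort(c(clusters[[best$a]], clusters[[best$b]]))
    steps[[length(steps) + 1L]] <- list(members = members, height = best$d)
    clusters[[best$a]] <- members
    clusters[[best$b]] <- NULL
  }
  steps
}

# member sets of each merge of an hclust object, in merge order
hclust_merge_members <- function(hc) {
  n <- nrow(hc$merge) + 1L
  out <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    get <- function(v) if (v < 0) -v else out[[v]]
    out[[s]] <- sort(c(get(hc$merge[s, 1]), get(hc$merge[s, 2])))
  }
  out
}

# Kendall tau-b by explicit O(n^2) concordant/discordant pair counting
oracle_kendall_taub <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  tx <- sum(sapply(table(x), function(t) t * (t - 1) / 2))
  ty <- sum(sapply(table(y), function(t) t * (t - 1) / 2))
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# Exact two-sided rank-sum p-value by enumeration of all assignments of the
# pooled ranks to group x. U is symmetric about n1*n2/2 under the null, so
# the two-sided p is the null probability of |U - mu| at least as large as
# observed.
oracle_wilcoxon_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  pooled <- seq_len(n1 + n2)
  splits <- utils::combn(n1 + n2, n1)
  u_all <- apply(splits, 2, function(idx) sum(pooled[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Straight-line implementation of the curve-based fingerprint similarity:
# rasterize on the log10 grid, then loop over shifts and pick the largest
# Pearson correlation of the overlapping windows.
oracle_profile_similarity <- function(a, b, tolerance = 0.005,
                                      optimization = 0.005,
                                      min_bp = 300, max_bp = 5000,
                                      n_grid = 1000L) {
  grid <- seq(log10(min_bp), log10(max_bp), length.out = n_grid)
  sigma <- tolerance * (max(grid) - min(grid))
  curve_of <- function(p) {
    v <- numeric(n_grid)
    for (k in seq_along(p$positions)) {
      v <- v + p$intensities[k] *
        exp(-(grid - log10(p$positions[k]))^2 / (2 * sigma^2))
    }
    v
  }
  ca <- curve_of(a); cb <- curve_of(b)
  m <- round(optimization * n_grid)
  best <- -1
  for (k in -m:m) {
    if (k >= 0) {
      r <- cor(ca[(1 + k):n_grid], cb[1:(n_grid - k)])
    } else {
      r <- cor(ca[1:(n_grid + k)], cb[(1 - k):n_grid])
    }
    best <- max(best, r)
  }
  best
}

# GLS estimates through the explicit inverse of V (textbook formula)
oracle_gls <- function(y, x, V) {
  X <- cbind(1, x)
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  beta <- solve(XtVi %*% X, XtVi %*% y)
  r <- y - X %*% beta
  sigma2 <- drop(t(r) %*% Vi %*% r) / (length(y) - 2)
  se <- sqrt(diag(sigma2 * solve(XtVi %*% X)))
  list(beta = drop(beta), se = se, sigma2 = sigma2)
}

# deterministic similarity matrix with given block structure
block_similarity <- function(sizes, within, between) {
  n <- sum(sizes)
  S <- matrix(between, n, n)
  at <- 0
  for (s in sizes) {
    idx <- at + seq_len(s)
    S[idx, idx] <- within
    at <- at + s
  }
  diag(S) <- 1
  dimnames(S) <- list(sprintf("S%02d", 1:n), sprintf("S%02d", 1:n))
  S
}

# random valid similarity matrix via a correlation matrix of random data
random_similarity <- function(n, obs = n + 5) {
  X <- matrix(rnorm(obs * n), obs, n)
  S <- cor(X)
  dimnames(S) <- list(sprintf("L%02d", 1:n), sprintf("L%02d", 1:n))
  S
}

# small band profile from position/intensity vectors
bp <- function(id, pos, int = rep(1, length(pos))) band_profile(id, pos, int)
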