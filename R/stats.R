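test_result <- function(statistic, p_value, n1, n2 = NA_integer_, method) {
  stopifnot(is.finite(p_value), p_value >= 0, p_value <= 1)
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 n1 = n1, n2 = n2, method = method),
            class = "colisurf_test")
}

#' @export
print.colisurf_test <- function(x, ...) {
  cat("<", x$method, "> statistic = ", signif(x$statistic, 6),
      ", p = ", signif(x$p_value, 4), " (n = ", x$n1,
      if (!is.na(x$n2)) paste0(" vs ", x$n2), ")\n", sep = "")
  invisible(x)
}

#' Two-group rank-sum comparison of a property
#'
#' Wilcoxon rank-sum (Mann-Whitney) test between two independent groups of
#' strains, with midranks for ties. The p-value is exact (by enumeration)
#' when the combined sample is small and tie-free, otherwise a normal
#' approximation with tie and continuity corrections is used; two-sided.
#'
#' @param x,y Property values for the two groups (each of length >= 2).
#' @param exact_max Use the exact distribution when `length(x) + length(y)`
#'   is at most this and there are no ties (default 12).
#' @return A `colisurf_test` with the Mann-Whitney statistic of `x`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 12L) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least two finite values")
  }
  if (length(unique(c(x, y))) == 1L) {
    return(test_result(length(x) * length(y) / 2, 1, length(x), length(y),
                       "wilcoxon rank-sum"))
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- !ties && (length(x) + length(y)) <= exact_max
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE,
                       alternative = "two.sided")
  )
  test_result(wt$statistic, wt$p.value, length(x), length(y),
              if (use_exact) "wilcoxon rank-sum (exact)"
              else "wilcoxon rank-sum (normal approx.)")
}

#' Kendall tau-b correlation between two properties
#'
#' Rank correlation with tie corrections (tau-b). The p-value is exact for
#' small tie-free samples, otherwise from the normal approximation of the
#' tau statistic; two-sided.
#'
#' @param x,y Paired observations (length >= 3 after dropping incomplete
#'   pairs).
#' @param exact_max Use exact enumeration when `n` is at most this and there
#'   are no ties (default 8).
#' @return A `colisurf_test` whose statistic is tau-b.
#' @export
kendall_tau <- function(x, y, exact_max = 8L) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("kendall_tau needs at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("kendall_tau undefined for a constant vector")
  }
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  use_exact <- !ties && n <= exact_max
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "kendall", exact = use_exact,
                    alternative = "two.sided")
  )
  test_result(unname(ct$estimate), ct$p.value, n, NA_integer_,
              if (use_exact) "kendall tau-b (exact)"
              else "kendall tau-b (normal approx.)")
}

#' Pairwise Kendall correlation matrix of the property table
#'
#' All pairwise property tau-b values and p-values, optionally restricted to
#' one habitat. Incomplete observations are dropped pairwise; constant
#' columns yield `NA` entries.
#'
#' @param table Property table from [build_property_table()].
#' @param subset `"all"` or one habitat level.
#' @param alpha Significance level for the `significant` flags.
#' @return List of matrices `tau`, `p`, `significant`, plus `n` used.
#' @export
correlation_matrix <- function(table, subset = "all", alpha = 0.05) {
  props <- intersect(property_names(), names(table))
  if (subset != "all") table <- table[table$habitat == subset, , drop = FALSE]
  if (nrow(table) < 3L) stop("need at least 3 strains after filtering")
  k <- length(props)
  tau <- p <- matrix(NA_real_, k, k, dimnames = list(props, props))
  for (i in seq_len(k)) {
    tau[i, i] <- 1
    for (j in seq_len(k)[-seq_len(i)]) {
      res <- tryCatch(kendall_tau(table[[props[i]]], table[[props[j]]]),
                      error = function(e) NULL)
      if (!is.null(res)) {
        tau[i, j] <- tau[j, i] <- res$statistic
        p[i, j] <- p[j, i] <- res$p_value
      }
    }
  }
  list(tau = tau, p = p, significant = !is.na(p) & p < alpha,
       n = nrow(table), subset = subset)
}

#' Mantel test of genomic similarity against habitat co-membership
#'
#' Correlates the strain-pair genomic similarities with the habitat
#' co-membership indicator (`1` when both strains come from the same
#' habitat, else `0`), so a positive statistic means similarity is larger
#' within habitat than between. Significance by joint row/column
#' permutation; the permutation p-value includes the observed statistic
#' (`(1 + #{r* >= r}) / (1 + n_perm)`), one-sided greater by default.
#'
#' @param S Similarity matrix.
#' @param habitat Habitat label per strain, in `rownames(S)` order; exactly
#'   two levels must be present.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Optional integer seed for the permutation stream.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param coding `"comembership"` (same habitat = 1; default) or
#'   `"distance"` (same habitat = 0, which flips the sign of the statistic).
#' @return A `colisurf_test` whose statistic is the Mantel r.
#' @export
mantel_habitat <- function(S, habitat, n_perm = 9999L, seed = NULL,
                           alternative = c("greater", "two.sided"),
                           coding = c("comembership", "distance")) {
  alternative <- match.arg(alternative)
  coding <- match.arg(coding)
  S <- validate_similarity(S)
  n <- nrow(S)
  habitat <- as.character(habitat)
  stopifnot(length(habitat) == n)
  if (length(unique(habitat)) < 2L) {
    stop("Mantel habitat test requires two habitat levels")
  }
  # canonical strain ordering, so the permutation stream (and hence p) does
  # not depend on the incidental row order of the input
  ord <- order(rownames(S))
  S <- S[ord, ord]
  habitat <- habitat[ord]
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  ut <- upper.tri(S)
  s <- S[ut]
  same <- function(h) {
    m <- outer(h, h, "==")[ut]
    if (coding == "comembership") as.numeric(m) else as.numeric(!m)
  }
  r_obs <- stats::cor(s, same(habitat))
  r_perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    r_perm[b] <- stats::cor(s, same(habitat[sample.int(n)]))
  }
  p <- if (alternative == "greater") {
    (1 + sum(r_perm >= r_obs)) / (1 + n_perm)
  } else {
    (1 + sum(abs(r_perm) >= abs(r_obs))) / (1 + n_perm)
  }
  test_result(r_obs, p, n, NA_integer_,
              paste0("mantel (", coding, ", ", alternative, ", ",
                     n_perm, " perms)"))
}

#' Repair a similarity matrix into a symmetric positive-definite covariance
#'
#' Symmetrizes, restores the unit diagonal, and clips eigenvalues below
#' `epsilon_frac` times the largest eigenvalue up to that floor, so the
#' result is usable as a residual variance-covariance matrix in generalized
#' least squares.
#'
#' Shift-optimized curve similarities are not positive semi-definite, and
#' their spectrum decays to (slightly below) zero: a GLS fit weights each
#' eigen-contrast of `V` by the reciprocal of its eigenvalue, so clipping
#' only at a near-zero floor lets contrasts between near-identical
#' fingerprints dominate the fit, where the response carries assay
#' measurement error rather than genomic signal. The default floor of 0.01
#' caps the condition number of the repaired matrix at 100, bounding that
#' weight ratio; pass a tiny value (e.g. `1e-8`) for pure PSD repair when
#' the covariance is not used for fitting.
#'
#' @param S Similarity matrix.
#' @param epsilon_frac Eigenvalue floor as a fraction of the largest
#'   eigenvalue (default 0.01, i.e. a condition-number cap of 100).
#' @return The repaired matrix, with attribute `"conditioning"` holding the
#'   smallest eigenvalue before and after repair.
#' @export
similarity_to_covariance <- function(S, epsilon_frac = 0.01) {
  S <- validate_similarity(S)
  eg <- eigen(S, symmetric = TRUE)
  lam_max <- max(eg$values)
  if (lam_max <= 0) stop("similarity matrix is not repairable (no positive eigenvalue)")
  eps <- epsilon_frac * lam_max
  lam <- pmax(eg$values, eps)
  V <- eg$vectors %*% (lam * t(eg$vectors))
  V <- (V + t(V)) / 2
  dimnames(V) <- dimnames(S)
  attr(V, "conditioning") <- c(before = min(eg$values), after = min(lam))
  V
}

#' Generalized least squares with a fixed relatedness covariance
#'
#' Fits `y = b0 + b1 * 1{habitat == sediment} + e` with
#' `e ~ N(0, sigma^2 * V)`, where `V` is the (repaired) genomic similarity
#' matrix, so the habitat effect is estimated net of genomic relatedness.
#' Computed through the Cholesky factor of `V` (no explicit inverse):
#' the model is whitened by `L^{-1}` and fitted by ordinary least squares.
#' `sigma^2` is the residual quadratic form over `n - 2`; the habitat
#' coefficient gets a two-sided t-test on `n - 2` degrees of freedom.
#'
#' @param y Numeric response (one property).
#' @param habitat Habitat labels; the effect is coded for
#'   `reference_level`'s complement (default indicator: sediment = 1).
#' @param V SPD covariance matrix from [similarity_to_covariance()].
#' @param effect_level Habitat level coded 1 (default `"sediment"`).
#' @return Object of class `pgls_fit`: coefficients, standard errors, t and
#'   p values, `sigma2`, degrees of freedom, and the V conditioning.
#' @export
pgls_fit <- function(y, habitat, V, effect_level = "sediment") {
  habitat <- as.character(habitat)
  n <- length(y)
  stopifnot(length(habitat) == n, nrow(V) == n, ncol(V) == n)
  ok <- is.finite(y)
  if (!all(ok)) {
    y <- y[ok]; habitat <- habitat[ok]; V <- V[ok, ok, drop = FALSE]
    n <- length(y)
  }
  if (n < 3L) stop("pgls_fit needs at least 3 observations")
  x <- as.numeric(habitat == effect_level)
  if (all(x == 0) || all(x == 1)) {
    stop("one habitat level absent: habitat design is singular")
  }
  X <- cbind(intercept = 1, habitat = x)
  L <- t(chol(V))
  Xw <- forwardsolve(L, X)
  yw <- forwardsolve(L, y)
  XtX <- crossprod(Xw)
  beta <- solve(XtX, crossprod(Xw, yw))
  resid <- yw - Xw %*% beta
  df <- n - 2L
  sigma2 <- sum(resid^2) / df
  cov_beta <- sigma2 * solve(XtX)
  se <- sqrt(diag(cov_beta))
  tval <- drop(beta) / se
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  structure(list(beta = drop(beta), se = se, t = tval, p = pval,
                 sigma2 = sigma2, df = df, n = n,
                 conditioning = attr(V, "conditioning")),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("<pgls_fit> n =", x$n, " sigma2 =", signif(x$sigma2, 4), "\n")
  print(data.frame(beta = x$beta, se = x$se, t = x$t, p = x$p))
  invisible(x)
}

#' Boxplot five-number summary
#'
#' The five plotted values of the habitat-comparison boxplots: lower whisker
#' `Q25 - 1.5 IQR`, first quartile, median, third quartile, upper whisker
#' `Q75 + 1.5 IQR` (quartiles by R's default type-7 rule). Observations
#' beyond the whiskers are returned as outliers.
#'
#' @param x Numeric vector (non-finite values dropped).
#' @return List with `five` (named numeric of length 5) and `outliers`.
#' @export
boxplot_five_numbers <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("no finite observations to summarize")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3L] - q[1L]
  five <- c(lower_whisker = q[1L] - 1.5 * iqr, q25 = q[1L], median = q[2L],
            q75 = q[3L], upper_whisker = q[3L] + 1.5 * iqr)
  list(five = five, outliers = x[x < five[1L] | x > five[5L]])
}

#' Full habitat comparison report
#'
#' For every property: the per-habitat boxplot five-number summaries, the
#' rank-sum habitat comparison and the relatedness-adjusted GLS habitat
#' test; plus Kendall correlation matrices for all strains and per habitat,
#' and the hydrophobicity-vs-EPS-protein paired analysis within each
#' habitat. Raw p-values are reported (matching the per-property analysis);
#' a Benjamini-Hochberg adjusted column is emitted alongside for reference.
#'
#' @param table Property table ([build_property_table()]).
#' @param S Similarity matrix over the same strains (matched by id).
#' @param n_perm,seed,alpha Mantel permutations, seed and flag level.
#' @return Nested list (class `habitat_report`): `properties` (per-property
#'   summaries/tests), `correlations` (all/sediment/water), `mantel`,
#'   `hydrophobicity_eps_protein`, `alpha`. Per-property failures are
#'   recorded as `NULL` entries without aborting the rest.
#' @export
habitat_report <- function(table, S, n_perm = 9999L, seed = NULL,
                           alpha = 0.05) {
  S <- validate_similarity(S)
  ids <- intersect(table$strain_id, rownames(S))
  table <- table[match(ids, table$strain_id), , drop = FALSE]
  S <- S[ids, ids]
  habitat <- table$habitat
  V <- similarity_to_covariance(S)
  props <- intersect(property_names(), names(table))

  per_prop <- lapply(props, function(p) {
    tryCatch({
      x <- table[[p]][habitat == "sediment"]
      y <- table[[p]][habitat == "water"]
      list(
        property = p,
        five_numbers = list(sediment = boxplot_five_numbers(x),
                            water = boxplot_five_numbers(y)),
        wilcoxon = wilcoxon_rank_sum(x, y),
        pgls = pgls_fit(table[[p]], habitat, V)
      )
    }, error = function(e) {
      warning("property '", p, "' failed: ", conditionMessage(e))
      NULL
    })
  })
  names(per_prop) <- props

  raw_p <- vapply(per_prop, function(r) {
    if (is.null(r)) NA_real_ else r$wilcoxon$p_value
  }, numeric(1))

  fig4 <- lapply(c(sediment = "sediment", water = "water"), function(h) {
    sub <- table[habitat == h, ]
    tryCatch(kendall_tau(sub$hydrophobicity, sub$eps_protein),
             error = function(e) NULL)
  })

  structure(list(
    properties = per_prop,
    wilcoxon_p = raw_p,
    wilcoxon_p_bh = stats::p.adjust(raw_p, method = "BH"),
    correlations = list(
      all = correlation_matrix(table, "all", alpha),
      sediment = correlation_matrix(table, "sediment", alpha),
      water = correlation_matrix(table, "water", alpha)
    ),
    mantel = mantel_habitat(S, habitat, n_perm = n_perm, seed = seed),
    hydrophobicity_eps_protein = fig4,
    alpha = alpha
  ), class = "habitat_report")
}
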