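test_that("rank-sum test matches enumeration and handles degenerate inputs", {
  # exchangeable null: same multiset in both groups
  same <- wilcoxon_rank_sum(c(1, 5, 9, 13), c(13, 9, 5, 1))
  expect_gt(same$p_value, 0.9)
  # all values identical across groups
  flat <- wilcoxon_rank_sum(rep(2, 4), rep(2, 5))
  expect_equal(flat$p_value, 1)
  # full separation of two tie-free triples: 2 of the 20 splits are as extreme
  sep <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$p_value, 0.1)
  expect_equal(sep$p_value, oracle_wilcoxon_exact_p(c(1, 2, 3), c(4, 5, 6)))
  # large shift at n = 30/30 under the normal approximation
  set.seed(1)
  y <- rnorm(30)
  shift <- wilcoxon_rank_sum(y + 10, y)
  expect_lt(shift$p_value, 0.001)
})

test_that("exact rank-sum p equals enumeration across random small samples", {
  set.seed(42)
  for (rep in 1:25) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- sample(seq_len(50), n1)   # tie-free integer data
    y <- sample(setdiff(seq_len(50), x), n2)
    expect_equal(wilcoxon_rank_sum(x, y)$p_value,
                 oracle_wilcoxon_exact_p(x, y), tolerance = 1e-12)
  }
})

test_that("rank-sum p-values are uniform under the exchangeable null", {
  # The approximate p-value is discrete (the rank-sum statistic has ~400
  # support points at n = 20/20), so the empirical CDF is compared to the
  # exact discrete null CDF of that p-value, built from the exact rank-sum
  # distribution; the comparison is a KS check at alpha = 0.01.
  n1 <- 20; n2 <- 20
  u <- 0:(n1 * n2)
  mass <- dwilcox(u, n1, n2)
  mu <- n1 * n2 / 2
  sig <- sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
  z <- (u - mu - sign(u - mu) * 0.5) / sig
  p_of_u <- pmin(2 * pnorm(-abs(z)), 1)
  p_of_u[u == mu] <- 1
  o <- order(p_of_u)
  support <- p_of_u[o]
  F_exact <- cumsum(mass[o])

  set.seed(2024)
  ps <- replicate(1000, wilcoxon_rank_sum(rnorm(n1), rnorm(n2))$p_value)
  D <- max(abs(ecdf(ps)(support) - F_exact))
  expect_lt(D, 1.63 / sqrt(1000))  # KS critical value at alpha = 0.01
  # and the raw distribution is close to uniform overall
  expect_lt(abs(mean(ps) - 0.5), 0.05)
})

test_that("kendall tau equals brute-force pair counting", {
  x <- 1:6
  expect_equal(kendall_tau(x, 2 * x + 1)$statistic, 1)
  expect_equal(kendall_tau(x, -x)$statistic, -1)
  set.seed(9)
  for (rep in 1:10) {
    n <- sample(5:50, 1)
    x <- rnorm(n)
    y <- if (rep %% 2) rnorm(n) else round(rnorm(n), 1)  # exercise ties
    expect_equal(kendall_tau(x, y)$statistic, oracle_kendall_taub(x, y),
                 tolerance = 1e-12)
  }
  expect_error(kendall_tau(rnorm(9), rep(1, 9)), "constant")
})

test_that("kendall tau is antisymmetric under order reversal", {
  set.seed(13)
  x <- rnorm(12); y <- rnorm(12)
  t1 <- kendall_tau(x, y)$statistic
  t2 <- kendall_tau(x, -y)$statistic
  expect_equal(t1, -t2, tolerance = 1e-12)
})

test_that("correlation matrix flags structural correlations", {
  set.seed(5)
  n <- 40
  tab <- data.frame(
    strain_id = sprintf("S%02d", 1:n),
    habitat = rep(c("sediment", "water"), each = n / 2),
    hydrophobicity = runif(n), zeta_potential = rnorm(n),
    eps_protein = runif(n, 0.3, 0.9), eps_sugar = runif(n, 0.8, 1.7)
  )
  tab$eps_ratio <- tab$eps_protein / tab$eps_sugar
  tab$net_charge_ph8 <- rnorm(n)
  tab$total_acidity <- runif(n)
  tab$pzc <- runif(n, 4, 10)
  cm <- correlation_matrix(tab)
  expect_equal(dim(cm$tau), c(8, 8))
  expect_true(isSymmetric(cm$tau))
  # the ratio column is structurally coupled to its numerator
  expect_gt(cm$tau["eps_ratio", "eps_protein"], 0.3)
  expect_lt(cm$tau["eps_ratio", "eps_sugar"], 0)
  # identical columns correlate perfectly
  tab2 <- tab; tab2$pzc <- tab2$hydrophobicity
  cm2 <- correlation_matrix(tab2)
  expect_equal(cm2$tau["pzc", "hydrophobicity"], 1)
})

test_that("mantel r matches a hand summation on a 6-strain toy", {
  set.seed(3)
  S <- random_similarity(6)
  habitat <- c("sediment", "sediment", "sediment", "water", "water", "water")
  res <- mantel_habitat(S, habitat, n_perm = 99, seed = 1)
  # plain Pearson over the 15 upper-triangle pairs, written out longhand
  s <- S[upper.tri(S)]
  h <- outer(habitat, habitat, "==")[upper.tri(S)]
  r_hand <- sum((s - mean(s)) * (h - mean(h))) /
    sqrt(sum((s - mean(s))^2) * sum((h - mean(h))^2))
  expect_equal(res$statistic, r_hand, tolerance = 1e-12)
})

test_that("mantel detects perfect block structure at the minimal p", {
  S <- block_similarity(c(5, 5), within = 1, between = 0)
  habitat <- rep(c("sediment", "water"), each = 5)
  res <- mantel_habitat(S, habitat, n_perm = 999, seed = 7)
  # permutations that map the partition onto itself (about 1 in 126 here)
  # reproduce the observed r exactly and count as >=, so the attainable
  # minimum is slightly above 1/(1+n_perm)
  expect_lte(res$p_value, 0.02)
  expect_gte(res$p_value, 1 / 1000)
  expect_gt(res$statistic, 0.9)
})

test_that("mantel is invariant to habitat relabeling and strain reordering", {
  set.seed(8)
  S <- random_similarity(10)
  habitat <- sample(rep(c("sediment", "water"), 5))
  a <- mantel_habitat(S, habitat, n_perm = 199, seed = 11)
  swapped <- ifelse(habitat == "sediment", "water", "sediment")
  b <- mantel_habitat(S, swapped, n_perm = 199, seed = 11)
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p_value, b$p_value)
  perm <- sample(10)
  c2 <- mantel_habitat(S[perm, perm], habitat[perm], n_perm = 199, seed = 11)
  expect_equal(c2$statistic, a$statistic)
  expect_equal(c2$p_value, a$p_value)
  # distance coding flips the sign of the statistic
  d <- mantel_habitat(S, habitat, n_perm = 199, seed = 11, coding = "distance")
  expect_equal(d$statistic, -a$statistic, tolerance = 1e-12)
  expect_error(mantel_habitat(S, rep("water", 10)), "two habitat levels")
})

test_that("mantel r agrees with vegan on the same matrices", {
  skip_if_not_installed("vegan")
  set.seed(12)
  S <- random_similarity(12)
  habitat <- rep(c("sediment", "water"), 6)
  ours <- mantel_habitat(S, habitat, n_perm = 99, seed = 2)
  H <- outer(habitat, habitat, function(a, b) as.numeric(a == b))
  ref <- vegan::mantel(as.dist(S), as.dist(H), permutations = 99)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
})

test_that("similarity repair returns an SPD matrix and fixes rank deficiency", {
  I5 <- diag(5); dimnames(I5) <- list(letters[1:5], letters[1:5])
  expect_equal(unclass(similarity_to_covariance(I5)), I5,
               ignore_attr = TRUE, tolerance = 1e-12)

  # well-conditioned input (compound symmetry, condition number 7): unchanged
  S <- matrix(0.5, 6, 6); diag(S) <- 1
  dimnames(S) <- list(letters[1:6], letters[1:6])
  expect_equal(unclass(similarity_to_covariance(S)), S,
               ignore_attr = TRUE, tolerance = 1e-12)

  # three identical strains: exactly rank-deficient, floored at the cap
  Sd <- matrix(1, 3, 3); dimnames(Sd) <- list(c("a", "b", "c"), c("a", "b", "c"))
  V <- similarity_to_covariance(Sd)
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  cond <- attr(V, "conditioning")
  expect_lt(cond["before"], 1e-12)
  expect_equal(unname(cond["after"]), 0.01 * 3, tolerance = 1e-6)
  # pure PSD repair with a tiny floor is available
  V2 <- similarity_to_covariance(Sd, epsilon_frac = 1e-8)
  expect_equal(unname(attr(V2, "conditioning")["after"]), 1e-8 * 3,
               tolerance = 1e-6)
})

test_that("GLS with identity covariance reduces to ordinary least squares", {
  set.seed(6)
  n <- 24
  habitat <- sample(rep(c("sediment", "water"), n / 2))
  y <- rnorm(n)
  V <- diag(n)
  fit <- pgls_fit(y, habitat, V)
  ref <- summary(lm(y ~ I(habitat == "sediment")))
  expect_equal(unname(fit$beta), unname(coef(ref)[, 1]), tolerance = 1e-10)
  expect_equal(unname(fit$se), unname(coef(ref)[, 2]), tolerance = 1e-10)
  expect_equal(unname(fit$p), unname(coef(ref)[, 4]), tolerance = 1e-10)
})

test_that("GLS matches the explicit-inverse textbook formula on random V", {
  set.seed(16)
  for (rep in 1:10) {
    n <- sample(10:30, 1)
    habitat <- sample(rep(c("sediment", "water"), length.out = n))
    S <- random_similarity(n)
    V <- similarity_to_covariance(S)
    y <- rnorm(n)
    fit <- pgls_fit(y, habitat, V)
    ref <- oracle_gls(y, as.numeric(habitat == "sediment"), V)
    expect_equal(unname(fit$beta), unname(ref$beta), tolerance = 1e-9)
    expect_equal(unname(fit$se), unname(ref$se), tolerance = 1e-9)
    expect_equal(fit$sigma2, ref$sigma2, tolerance = 1e-9)
  }
})

test_that("GLS equivariance: location shifts move the intercept, scale scales", {
  set.seed(26)
  n <- 20
  habitat <- rep(c("sediment", "water"), 10)
  V <- similarity_to_covariance(random_similarity(n))
  y <- rnorm(n)
  f0 <- pgls_fit(y, habitat, V)
  f_shift <- pgls_fit(y + 3, habitat, V)
  expect_equal(f_shift$beta[1], f0$beta[1] + 3, tolerance = 1e-9)
  expect_equal(f_shift$beta[2], f0$beta[2], tolerance = 1e-9)
  f_scale <- pgls_fit(5 * y, habitat, V)
  expect_equal(unname(f_scale$beta), 5 * unname(f0$beta), tolerance = 1e-9)
  expect_equal(unname(f_scale$se), 5 * unname(f0$se), tolerance = 1e-9)
  expect_equal(f_scale$p, f0$p, tolerance = 1e-9)
  # constant response: zero habitat effect, intercept at the constant
  fc <- pgls_fit(rep(2.5, n), habitat, V)
  expect_equal(unname(fc$beta), c(2.5, 0), tolerance = 1e-9)
  expect_error(pgls_fit(y, rep("water", n), V), "singular")
})

test_that("naive OLS is anticonservative when relatedness tracks habitat", {
  # strong genomic effect clustered by habitat, true habitat effect zero
  set.seed(36)
  n <- 30
  habitat <- rep(c("sediment", "water"), each = n / 2)
  S <- block_similarity(c(n / 2, n / 2), within = 0.8, between = 0.2)
  V <- similarity_to_covariance(S)
  L <- t(chol(V))
  reps <- 300
  rej <- matrix(NA, reps, 2)
  for (i in seq_len(reps)) {
    y <- 0.5 * drop(L %*% rnorm(n)) + 0.02 * rnorm(n)
    rej[i, 1] <- summary(lm(y ~ I(habitat == "sediment")))$coefficients[2, 4] < 0.05
    rej[i, 2] <- pgls_fit(y, habitat, V)$p[2] < 0.05
  }
  expect_gt(mean(rej[, 1]), mean(rej[, 2]))
  expect_gt(mean(rej[, 1]), 0.15)  # OLS badly oversized here
})

test_that("boxplot five numbers follow the whisker definition", {
  res <- boxplot_five_numbers(1:8)
  q <- quantile(1:8, c(0.25, 0.5, 0.75), names = FALSE)  # 2.75, 4.5, 6.25
  expect_equal(unname(res$five),
               c(q[1] - 1.5 * (q[3] - q[1]), q[1], q[2], q[3],
                 q[3] + 1.5 * (q[3] - q[1])))
  expect_length(res$outliers, 0)
  res2 <- boxplot_five_numbers(c(1:8, 100))
  expect_equal(res2$outliers, 100)
})

test_that("habitat report assembles all components and survives bad columns", {
  co <- generate_cohort(cohort_config(n_sediment = 10, n_water = 10, seed = 2))
  tab <- build_property_table(co)
  rep_out <- habitat_report(tab, co$similarity, n_perm = 199, seed = 5)
  expect_s3_class(rep_out, "habitat_report")
  expect_named(rep_out$properties, property_names())
  expect_equal(rep_out$correlations$all$n, 20)
  expect_equal(rep_out$correlations$sediment$n, 10)
  hp <- rep_out$properties$hydrophobicity
  expect_s3_class(hp$wilcoxon, "colisurf_test")
  expect_s3_class(hp$pgls, "pgls_fit")
  expect_length(hp$five_numbers$sediment$five, 5)
  # a degenerate column must not abort the others
  tab$pzc <- NA_real_
  expect_warning(rep2 <- habitat_report(tab, co$similarity, n_perm = 99),
                 "pzc")
  expect_null(rep2$properties$pzc)
  expect_s3_class(rep2$properties$hydrophobicity$wilcoxon, "colisurf_test")
  # a constant column is handled: comparison p = 1, NA correlation entries
  tab$pzc <- 5
  rep3 <- habitat_report(tab, co$similarity, n_perm = 99)
  expect_equal(rep3$properties$pzc$wilcoxon$p_value, 1)
  expect_true(all(is.na(rep3$correlations$all$tau["pzc", -8])))
})

test_that("habitat-specific coupling reproduces the hydrophobicity-protein contrast", {
  set.seed(46)
  co <- generate_cohort(cohort_config(n_sediment = 25, n_water = 25, seed = 46))
  tab <- build_property_table(co)
  sed <- tab$habitat == "sediment"
  # couple EPS protein to hydrophobicity in sediment strains only
  tab$eps_protein[sed] <- 0.3 + 0.5 * tab$hydrophobicity[sed] +
    rnorm(sum(sed), 0, 0.02)
  tab$eps_protein[!sed] <- 0.3 + rnorm(sum(!sed), 0, 0.05)
  rep_out <- habitat_report(tab, co$similarity, n_perm = 99, seed = 1)
  k <- rep_out$hydrophobicity_eps_protein
  expect_gt(k$sediment$statistic, 0.3)
  expect_lt(k$sediment$p_value, 0.05)
  expect_lt(abs(k$water$statistic), 0.3)
})
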