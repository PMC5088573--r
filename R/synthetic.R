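#' Configuration of a synthetic cohort
#'
#' Bundles every parameter of the synthetic-cohort generator: group sizes,
#' fingerprint band-pool structure, per-property habitat effects and
#' variance components, the multi-site protonation model behind the
#' titration curves, and the seed. Defaults emulate the study design the
#' workflow targets: 44 sediment and 33 water strains, property scales
#' within the reported ranges, sediment-elevated hydrophobicity and EPS,
#' less negative net charge and slightly lower acidity in sediment.
#'
#' @param n_sediment,n_water Strains per habitat (each >= 2).
#' @param n_band_positions Number of candidate band positions in the
#'   fingerprint pool.
#' @param shared_band_fraction Fraction of the band pool shared between the
#'   two habitats, in `[0, 1]`; `1` removes all habitat structure from the
#'   fingerprints.
#' @param band_presence_prob Probability that a strain carries each band of
#'   its habitat pool.
#' @param property_means Named baseline means (water habitat) for the six
#'   directly simulated properties.
#' @param habitat_effects Named true additive sediment effects (the beta of
#'   `y = mu + beta 1{sediment} + g + eps`); missing names default to 0.
#' @param genomic_sd,residual_sd Standard deviation of the
#'   genome-correlated random effect `g ~ MVN(0, sd^2 V)` (V = realized
#'   fingerprint similarity after SPD repair) and of the iid residual.
#'   Either a single number applied to every property or a named vector.
#' @param titration_model List of `c(site_density, pKa)` pairs
#'   (density in meq per 10^8 cells); pKa values must lie strictly inside
#'   the titrated window (4, 10).
#' @param titration_c_a Initial acid concentration of the titrations
#'   (mmol/L).
#' @param titration_noise_sd Standard deviation of iid pH measurement noise
#'   added to recorded titration points (default 0: noise-free curves keep
#'   round-trip recovery exact).
#' @param seed Integer seed; the generator is bit-reproducible given the
#'   full configuration.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_sediment = 44L, n_water = 33L,
                          n_band_positions = 30L,
                          shared_band_fraction = 0.8,
                          band_presence_prob = 0.6,
                          property_means = NULL,
                          habitat_effects = NULL,
                          genomic_sd = NULL,
                          residual_sd = NULL,
                          titration_model = list(c(1.2e-4, 4.8),
                                                 c(1.0e-4, 6.9),
                                                 c(0.8e-4, 9.4)),
                          titration_c_a = 0.6,
                          titration_noise_sd = 0,
                          seed = 1L) {
  direct <- c("hydrophobicity", "zeta_potential", "eps_protein", "eps_sugar",
              "net_charge_ph8", "total_acidity")
  means <- c(hydrophobicity = 0.30, zeta_potential = -22,
             eps_protein = 0.45, eps_sugar = 1.15,
             net_charge_ph8 = -1.2e-4, total_acidity = 2.5e-4)
  betas <- c(hydrophobicity = 0.15, zeta_potential = 0,
             eps_protein = 0.10, eps_sugar = 0.12,
             net_charge_ph8 = 4e-5, total_acidity = -3e-5)
  g_sd <- c(hydrophobicity = 0.10, zeta_potential = 4,
            eps_protein = 0.06, eps_sugar = 0.10,
            net_charge_ph8 = 3e-5, total_acidity = 4e-5)
  r_sd <- c(hydrophobicity = 0.05, zeta_potential = 2,
            eps_protein = 0.03, eps_sugar = 0.05,
            net_charge_ph8 = 1.5e-5, total_acidity = 2e-5)
  override <- function(base, user) {
    if (is.null(user)) return(base)
    if (is.null(names(user)) && length(user) == 1L) {
      return(stats::setNames(rep(as.numeric(user), length(base)), names(base)))
    }
    stopifnot(all(names(user) %in% names(base)))
    base[names(user)] <- as.numeric(user)
    base
  }
  means <- override(means, property_means)
  betas <- override(betas, habitat_effects)
  g_sd <- override(g_sd, genomic_sd)
  r_sd <- override(r_sd, residual_sd)

  stopifnot(n_sediment >= 2L, n_water >= 2L, n_band_positions >= 2L,
            shared_band_fraction >= 0, shared_band_fraction <= 1,
            band_presence_prob > 0, band_presence_prob <= 1,
            all(g_sd >= 0), all(r_sd >= 0),
            titration_c_a > 0, titration_noise_sd >= 0)
  for (site in titration_model) {
    stopifnot(length(site) == 2L, site[1L] >= 0,
              site[2L] > 4, site[2L] < 10)
  }
  structure(list(
    n_sediment = as.integer(n_sediment), n_water = as.integer(n_water),
    n_band_positions = as.integer(n_band_positions),
    shared_band_fraction = shared_band_fraction,
    band_presence_prob = band_presence_prob,
    property_means = means, habitat_effects = betas,
    genomic_sd = g_sd, residual_sd = r_sd,
    direct_properties = direct,
    titration_model = titration_model,
    titration_c_a = titration_c_a,
    titration_noise_sd = titration_noise_sd,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# closed-form net charge of a multi-site protonation model (meq/10^8 cells):
# offset minus the deprotonated fraction of each site.
model_net_charge <- function(ph, sites, offset = 0) {
  q <- rep(offset, length(ph))
  for (site in sites) {
    q <- q - site[1L] / (1 + 10^(site[2L] - ph))
  }
  q
}

#' Synthesize titration records from a protonation model
#'
#' Builds the sample and blank titration curves whose acid-base balance
#' reproduces a known multi-site Henderson-Hasselbalch net-charge model, so
#' the assay-side charge computation can be validated against the closed
#' form. Cumulative base additions are chosen to satisfy the charge balance
#' exactly: the blank carries only water autoprotolysis, the sample
#' additionally the surface charge `offset - sum(d_i / (1 + 10^(pKa_i - pH)))`.
#'
#' @param sites List of `c(site_density, pKa)` pairs (density in meq per
#'   10^8 cells). An empty list yields a sample identical to the blank.
#' @param ph_grid Increasing pH values within `[4, 10]`.
#' @param n_bact Cells per mL of the sample suspension.
#' @param offset Fixed positive charge offset (meq per 10^8 cells), e.g.
#'   protonated amines, giving the model a point of zero charge.
#' @param c_a Initial acid concentration (mmol/L).
#' @param noise_sd Optional iid pH measurement noise (default 0).
#' @param pkw Water ion product exponent.
#' @return List with `sample` and `blank` [titration_curve()] objects and
#'   `model` (the closed-form net-charge function of pH).
#' @export
titration_curve_from_model <- function(sites, ph_grid = seq(4, 10, by = 0.02),
                                       n_bact = 1e8, offset = 0,
                                       c_a = 0.6, noise_sd = 0, pkw = 14) {
  stopifnot(all(diff(ph_grid) > 0), n_bact > 0)
  for (site in sites) stopifnot(length(site) == 2L, site[1L] >= 0)
  ph_s <- ph_grid
  ph_b <- ph_grid
  if (noise_sd > 0) {
    ph_s <- sort(pmin(10, pmax(4, ph_s + stats::rnorm(length(ph_s), 0, noise_sd))))
    ph_b <- sort(pmin(10, pmax(4, ph_b + stats::rnorm(length(ph_b), 0, noise_sd))))
  }
  q <- model_net_charge(ph_s, sites, offset)           # meq / 1e8 cells
  delta <- q * (n_bact / 1e8) * 1e3                    # mmol/L
  cb_sample <- c_a - proton_conc(ph_s) + hydroxide_conc(ph_s, pkw) - delta
  cb_blank <- c_a - proton_conc(ph_b) + hydroxide_conc(ph_b, pkw)
  if (any(cb_sample < 0) || any(cb_blank < 0)) {
    stop("titration model yields negative cumulative base; increase c_a")
  }
  list(
    sample = titration_curve(ph_s, rep(c_a, length(ph_s)), cb_sample,
                             n_bact = n_bact, role = "sample"),
    blank = titration_curve(ph_b, rep(c_a, length(ph_b)), cb_blank,
                            role = "blank"),
    model = function(ph) model_net_charge(ph, sites, offset)
  )
}

# phylotype frequencies used to simulate marker profiles, by habitat
phylotype_frequencies <- function() {
  list(
    sediment = c("D/E" = 0.25, "B1" = 0.23, "B2" = 0.20, "A/C" = 0.16,
                 "A" = 0.11, "E" = 0.03, "F" = 0.02),
    water = c("B1" = 0.56, "D/E" = 0.19, "A" = 0.09, "A/C" = 0.09,
              "E" = 0.04, "F" = 0.03)
  )
}

# quadruplex genotype (+ confirmation screens) that maps back to each label
phylotype_to_markers <- function(label) {
  switch(label,
    "A"   = list(arpA = TRUE, chuA = FALSE, yjaA = FALSE, tspE4 = FALSE,
                 group_c = "untested", group_e = "untested"),
    "B1"  = list(arpA = TRUE, chuA = FALSE, yjaA = FALSE, tspE4 = TRUE,
                 group_c = "untested", group_e = "untested"),
    "B2"  = list(arpA = FALSE, chuA = TRUE, yjaA = TRUE, tspE4 = FALSE,
                 group_c = "untested", group_e = "untested"),
    "F"   = list(arpA = FALSE, chuA = TRUE, yjaA = FALSE, tspE4 = FALSE,
                 group_c = "untested", group_e = "untested"),
    "A/C" = list(arpA = TRUE, chuA = TRUE, yjaA = FALSE, tspE4 = FALSE,
                 group_c = "untested", group_e = "untested"),
    "D/E" = list(arpA = TRUE, chuA = TRUE, yjaA = FALSE, tspE4 = TRUE,
                 group_c = "untested", group_e = "untested"),
    "E"   = list(arpA = TRUE, chuA = TRUE, yjaA = FALSE, tspE4 = TRUE,
                 group_c = "untested", group_e = "positive"),
    stop("no marker genotype for label ", label)
  )
}

# one draw of the trait model y = mu + beta 1{sediment} + g + eps given a
# repaired covariance V; g ~ MVN(0, sd_g^2 V) via the Cholesky factor of V.
# Physical guards clamp the realized traits into their admissible ranges;
# the guarded value is the recorded truth.
simulate_traits <- function(V, habitat, config) {
  n <- length(habitat)
  L <- t(chol(V))
  direct <- config$direct_properties
  g <- sapply(direct, function(p) {
    config$genomic_sd[[p]] * drop(L %*% stats::rnorm(n))
  })
  eps <- sapply(direct, function(p) {
    stats::rnorm(n, 0, config$residual_sd[[p]])
  })
  traits <- sapply(direct, function(p) {
    config$property_means[[p]] + config$habitat_effects[[p]] *
      (habitat == "sediment") + g[, p] + eps[, p]
  })
  traits[, "hydrophobicity"] <- pmin(pmax(traits[, "hydrophobicity"], 1e-3),
                                     0.999)
  traits[, "eps_protein"] <- pmax(traits[, "eps_protein"], 1e-3)
  traits[, "eps_sugar"] <- pmax(traits[, "eps_sugar"], 1e-3)
  traits[, "total_acidity"] <- pmax(traits[, "total_acidity"], 1e-5)
  list(traits = traits, g = g, eps = eps)
}

# 32-bit avalanche mixer (splitmix/murmur finalizer), done in doubles: R has
# no native unsigned 32-bit type but doubles hold these values exactly
mix32 <- function(x) {
  m32 <- 2^32
  xor32 <- function(a, b) {
    ba <- intToBits(as.integer(a %% m32 - 2^31))
    bb <- intToBits(as.integer(b %% m32 - 2^31))
    sum(2^(0:31) * as.integer(xor(ba, bb)))
  }
  mul32 <- function(a, b) {
    # exact 32-bit modular product via 16-bit split
    a <- a %% m32; b <- b %% m32
    ah <- floor(a / 65536); al <- a %% 65536
    (((ah * b) %% 65536) * 65536 + al * b) %% m32
  }
  x <- (x + 2654435769) %% m32
  x <- xor32(x, floor(x / 2^16))
  x <- mul32(x, 2246822507)
  x <- xor32(x, floor(x / 2^13))
  x <- mul32(x, 3266489909)
  x <- xor32(x, floor(x / 2^16))
  x
}

# derive decorrelated substream seeds (< 2^31) from the master seed: linearly
# related Mersenne-Twister seeds can carry initialization correlations, so
# each substream seed is an avalanche hash of (master, stage)
substream_seeds <- function(seed, n = 6L) {
  base <- mix32(as.numeric(seed) %% 2^32)
  vapply(seq_len(n), function(k) {
    as.integer(mix32(base + k) %% 2147483647)
  }, integer(1))
}

#' Generate a synthetic cohort with known ground truth
#'
#' Emulates the statistical structure of a two-habitat strain study:
#' fingerprints are drawn from habitat band pools mixed with a shared pool
#' (so within-habitat similarity exceeds between-habitat similarity unless
#' `shared_band_fraction = 1`); traits follow
#' `y = mu + beta 1{sediment} + g + eps` with `g ~ MVN(0, sd_g^2 V)` where
#' `V` is the realized fingerprint similarity matrix after SPD repair;
#' titration curves come from the multi-site protonation model (per-strain
#' site densities and charge offset solved from each strain's true total
#' acidity and net charge at pH 8); MATH optical densities and EPS
#' absorbances are back-computed from the true hydrophobicity and EPS
#' contents through known standard curves.
#'
#' @param config A [cohort_config()].
#' @return Object of class `cohort`: `strains` (metadata + raw assay
#'   readings), `profiles` (list of [band_profile()]), `titrations` and
#'   `blank` (long titration records), `protein_curve`/`sugar_curve`
#'   ([standard_curve()] objects) with their `standards` points,
#'   `similarity` (realized fingerprint similarity), and `truth` (the
#'   per-strain true values of all eight properties plus the latent `g`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  seeds <- substream_seeds(config$seed)

  n_s <- config$n_sediment
  n_w <- config$n_water
  n <- n_s + n_w
  habitat <- c(rep("sediment", n_s), rep("water", n_w))
  strain_id <- sprintf("S%03d", seq_len(n))

  ## --- stage 1: band pools and fingerprints -------------------------------
  set.seed(seeds[1L])
  K <- config$n_band_positions
  positions <- sort(unique(round(10^stats::runif(K, log10(350), log10(4700)))))
  while (length(positions) < K) {
    positions <- sort(unique(c(positions,
      round(10^stats::runif(K - length(positions), log10(350), log10(4700))))))
  }
  pool_idx <- sample.int(K)
  n_shared <- round(config$shared_band_fraction * K)
  shared <- pool_idx[seq_len(n_shared)]
  rest <- setdiff(pool_idx, shared)
  sed_only <- rest[seq_len(floor(length(rest) / 2))]
  wat_only <- setdiff(rest, sed_only)
  allowed <- list(sediment = sort(c(shared, sed_only)),
                  water = sort(c(shared, wat_only)))

  profiles <- vector("list", n)
  for (i in seq_len(n)) {
    pool <- allowed[[habitat[i]]]
    present <- pool[stats::runif(length(pool)) < config$band_presence_prob]
    if (length(present) == 0L) present <- sample(pool, 1L)
    present <- sort(present)
    profiles[[i]] <- band_profile(
      strain_id[i], positions[present],
      stats::rlnorm(length(present), meanlog = 0, sdlog = 0.4)
    )
  }
  names(profiles) <- strain_id

  S <- similarity_matrix(profiles)
  if (!identical(rownames(S), strain_id)) {
    stop("strains dropped during similarity computation; degenerate config")
  }

  ## --- stage 2: traits ----------------------------------------------------
  set.seed(seeds[2L])
  V <- similarity_to_covariance(S)
  sim <- simulate_traits(V, habitat, config)
  g <- sim$g
  traits <- sim$traits
  rownames(g) <- rownames(traits) <- strain_id

  ## --- stage 3: assay raw data -------------------------------------------
  set.seed(seeds[3L])
  initial_od <- rep(0.40, n)
  aqueous_od <- initial_od * (1 - traits[, "hydrophobicity"])

  eps_n_cells <- stats::runif(n, 3e10, 6e10)
  protein_std <- data.frame(concentration = seq(0, 300, by = 50))
  protein_std$absorbance <- 0.010 + 0.004 * protein_std$concentration
  sugar_std <- data.frame(concentration = seq(0, 800, by = 100))
  sugar_std$absorbance <- 0.020 + 0.0015 * sugar_std$concentration
  protein_curve <- standard_curve(protein_std$concentration,
                                  protein_std$absorbance)
  sugar_curve <- standard_curve(sugar_std$concentration, sugar_std$absorbance)
  protein_abs <- protein_curve$intercept + protein_curve$slope *
    (traits[, "eps_protein"] * eps_n_cells / 1e8)
  sugar_abs <- sugar_curve$intercept + sugar_curve$slope *
    (traits[, "eps_sugar"] * eps_n_cells / 1e8)

  # titrations: per-strain site scale and offset solved from the true
  # acidity and net charge at pH 8 of the baseline protonation model
  n_bact <- stats::runif(n, 0.8e8, 1.2e8)
  base_sites <- config$titration_model
  D <- function(ph) -model_net_charge(ph, base_sites, offset = 0)
  d_span <- D(10) - D(4)
  ph_grid <- seq(4, 10, by = 0.02)

  blank_ref <- NULL
  tit_list <- vector("list", n)
  pzc_true <- numeric(n)
  for (i in seq_len(n)) {
    c_scale <- traits[i, "total_acidity"] / d_span
    o_i <- traits[i, "net_charge_ph8"] + c_scale * D(8)
    sites_i <- lapply(base_sites, function(s) c(s[1L] * c_scale, s[2L]))
    tc <- titration_curve_from_model(sites_i, ph_grid, n_bact = n_bact[i],
                                     offset = o_i, c_a = config$titration_c_a,
                                     noise_sd = config$titration_noise_sd)
    if (is.null(blank_ref)) blank_ref <- tc$blank
    tit_list[[i]] <- data.frame(strain_id = strain_id[i],
                                ph = tc$sample$ph, c_a = tc$sample$c_a,
                                c_b = tc$sample$c_b)
    qfun <- tc$model
    pzc_true[i] <- if (qfun(4) * qfun(10) < 0) {
      stats::uniroot(qfun, c(4, 10), tol = 1e-10)$root
    } else NA_real_
  }

  ## --- stage 4: markers / phylotypes -------------------------------------
  set.seed(seeds[4L])
  freqs <- phylotype_frequencies()
  phylotype <- character(n)
  markers <- vector("list", n)
  for (i in seq_len(n)) {
    f <- freqs[[habitat[i]]]
    phylotype[i] <- sample(names(f), 1L, prob = f)
    markers[[i]] <- phylotype_to_markers(phylotype[i])
  }
  mk <- do.call(rbind, lapply(markers, function(m) {
    data.frame(arpA = m$arpA, chuA = m$chuA, yjaA = m$yjaA, tspE4 = m$tspE4,
               group_c = m$group_c, group_e = m$group_e)
  }))

  strains <- data.frame(
    strain_id = strain_id, habitat = habitat,
    initial_od = initial_od, aqueous_od = aqueous_od,
    zeta_potential = traits[, "zeta_potential"],
    n_bact = n_bact, eps_n_cells = eps_n_cells,
    protein_abs = protein_abs, sugar_abs = sugar_abs,
    mk, phylotype_true = phylotype,
    stringsAsFactors = FALSE
  )

  truth <- data.frame(
    strain_id = strain_id, habitat = habitat,
    hydrophobicity = traits[, "hydrophobicity"],
    zeta_potential = traits[, "zeta_potential"],
    eps_protein = traits[, "eps_protein"],
    eps_sugar = traits[, "eps_sugar"],
    eps_ratio = traits[, "eps_protein"] / traits[, "eps_sugar"],
    net_charge_ph8 = traits[, "net_charge_ph8"],
    total_acidity = traits[, "total_acidity"],
    pzc = pzc_true,
    stringsAsFactors = FALSE
  )

  structure(list(
    strains = strains,
    profiles = profiles,
    titrations = do.call(rbind, tit_list),
    blank = data.frame(ph = blank_ref$ph, c_a = blank_ref$c_a,
                       c_b = blank_ref$c_b),
    protein_curve = protein_curve, sugar_curve = sugar_curve,
    standards = list(protein = protein_std, sugar = sugar_std),
    similarity = S,
    truth = truth,
    g = g,
    config = config
  ), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort>", x$config$n_sediment, "sediment +", x$config$n_water,
      "water strains; seed", x$config$seed, "\n")
  invisible(x)
}

#' Write a cohort to plain-text files
#'
#' Writes `strains.csv`, `profiles.csv` (long format), `titrations.csv`,
#' `blank.csv`, `standards_protein.csv`, `standards_sugar.csv`,
#' `similarity.csv` and `truth.json` into `dir`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$strains, file.path(dir, "strains.csv"),
                   row.names = FALSE)
  prof <- do.call(rbind, lapply(cohort$profiles, function(p) {
    data.frame(strain_id = p$strain_id, position_bp = p$positions,
               intensity = p$intensities)
  }))
  utils::write.csv(prof, file.path(dir, "profiles.csv"), row.names = FALSE)
  utils::write.csv(cohort$titrations, file.path(dir, "titrations.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$blank, file.path(dir, "blank.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$standards$protein,
                   file.path(dir, "standards_protein.csv"), row.names = FALSE)
  utils::write.csv(cohort$standards$sugar,
                   file.path(dir, "standards_sugar.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(unclass(cohort$similarity)),
                   file.path(dir, "similarity.csv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Read band profiles from a long-format CSV
#'
#' @param path CSV with columns `strain_id`, `position_bp`, `intensity`.
#' @return Named list of [band_profile()] objects.
#' @export
read_profiles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("strain_id", "position_bp", "intensity") %in% names(df)))
  out <- lapply(split(df, df$strain_id), function(d) {
    d <- d[order(d$position_bp), ]
    band_profile(d$strain_id[1L], d$position_bp, d$intensity)
  })
  out[order(names(out))]
}
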