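#' MATH hydrophobic partitioning
#'
#' Fraction of cells partitioning out of the aqueous phase in the microbial
#' adhesion to hydrocarbons (MATH) assay:
#' `(initial OD546 - aqueous OD546) / initial OD546`.
#'
#' @param initial_od OD546 of the cell suspension before mixing (> 0).
#' @param aqueous_od OD546 of the aqueous phase after phase separation.
#' @return Partitioning fraction in `[0, 1]`. Readings with
#'   `aqueous_od > initial_od` (measurement noise) are clamped to 0 with a
#'   warning.
#' @export
hydrophobic_partitioning <- function(initial_od, aqueous_od) {
  stopifnot(length(initial_od) == length(aqueous_od))
  if (any(initial_od <= 0)) stop("initial_od must be positive")
  if (any(aqueous_od < 0)) stop("aqueous_od must be non-negative")
  h <- (initial_od - aqueous_od) / initial_od
  if (any(h < 0)) {
    warning("aqueous OD exceeds initial OD for ", sum(h < 0),
            " reading(s); hydrophobicity clamped to 0")
    h[h < 0] <- 0
  }
  pmin(h, 1)
}

#' Titration curve container
#'
#' Raw potentiometric titration points for one suspension: at each recorded
#' pH, the cumulative strong-acid and strong-base concentrations (mmol/L,
#' including amounts added before the titration proper).
#'
#' @param ph Recorded pH values within the titrated window `[4, 10]`.
#' @param c_a,c_b Cumulative acid / base concentrations (mmol/L),
#'   non-negative and non-decreasing along the titration direction.
#' @param n_bact Cells per mL (required for samples; ignored for blanks).
#' @param role `"sample"` or `"blank"`.
#' @return Object of class `titration_curve`.
#' @export
titration_curve <- function(ph, c_a, c_b, n_bact = NA_real_,
                            role = c("sample", "blank")) {
  role <- match.arg(role)
  stopifnot(length(ph) == length(c_a), length(ph) == length(c_b),
            length(ph) >= 2L)
  if (any(ph < 4 - 1e-9) || any(ph > 10 + 1e-9)) {
    stop("pH values must lie within the titrated window [4, 10]")
  }
  if (any(c_a < 0) || any(c_b < 0)) stop("C_A and C_B must be non-negative")
  o <- order(ph)
  ph <- ph[o]; c_a <- c_a[o]; c_b <- c_b[o]
  if (any(diff(c_b) < -1e-9) || any(diff(c_a) < -1e-9)) {
    stop("cumulative titrant concentrations must be non-decreasing along the titration")
  }
  if (role == "sample" && (!is.finite(n_bact) || n_bact <= 0)) {
    stop("sample titrations require n_bact > 0")
  }
  structure(list(ph = ph, c_a = c_a, c_b = c_b,
                 n_bact = n_bact, role = role),
            class = "titration_curve")
}

# [H+] and [OH-] in mmol/L from pH (pKw = 14 at room temperature).
proton_conc <- function(ph) 10^(-ph) * 1e3
hydroxide_conc <- function(ph, pkw = 14) 10^(ph - pkw) * 1e3

# charge-balance term of one titration record, interpolated onto `ph_grid`
# (piecewise-linear in pH); units mmol/L.
balance_term <- function(curve, ph_grid, pkw = 14, literal_sign = FALSE,
                         sample_term = TRUE) {
  rng <- range(curve$ph)
  if (min(ph_grid) < rng[1L] - 1e-9 || max(ph_grid) > rng[2L] + 1e-9) {
    stop("requested pH grid extends beyond the titrated range [",
         rng[1L], ", ", rng[2L], "]")
  }
  c_a <- stats::approx(curve$ph, curve$c_a, xout = ph_grid, rule = 2)$y
  c_b <- stats::approx(curve$ph, curve$c_b, xout = ph_grid, rule = 2)$y
  oh_sign <- if (literal_sign && sample_term) -1 else +1
  c_a - c_b - proton_conc(ph_grid) + oh_sign * hydroxide_conc(ph_grid, pkw)
}

#' Net surface charge profile from sample and blank titrations
#'
#' The number of deprotonated surface sites per 10^8 cells, as a function of
#' pH, from the acid-base balance of the cell suspension relative to the
#' cell-free blank:
#' \deqn{Q(pH) = \frac{(C_A - C_B - [H^+] + [OH^-])_{sample} -
#'   (C_A - C_B - [H^+] + [OH^-])_{blank}}{N_{bact}} \times 10^{-3}}
#' with concentrations in mmol/L, \eqn{[H^+] = 10^{-pH}},
#' \eqn{[OH^-] = 10^{pH - pK_w}} (both converted to mmol/L), and
#' \eqn{N_{bact}} expressed in units of 10^8 cells. Both terms use
#' \eqn{+[OH^-]} so that a sample identical to the blank gives zero net
#' charge; `literal_sign = TRUE` restores the variant with \eqn{-[OH^-]} in
#' the sample term only.
#'
#' @param sample,blank [titration_curve()] objects with the matching roles
#'   and overlapping pH coverage.
#' @param ph_grid Output pH grid (default 4 to 10 by 0.02).
#' @param pkw Water ion product exponent (default 14).
#' @param literal_sign Use the asymmetric hydroxide sign in the sample term.
#' @return Object of class `charge_profile`: list with `ph` and `net_charge`
#'   (meq per 10^8 cells).
#' @export
net_charge_profile <- function(sample, blank,
                               ph_grid = seq(4, 10, by = 0.02),
                               pkw = 14, literal_sign = FALSE) {
  stopifnot(inherits(sample, "titration_curve"),
            inherits(blank, "titration_curve"))
  if (sample$role != "sample") stop("first argument must have role 'sample'")
  if (blank$role != "blank") stop("second argument must have role 'blank'")
  lo <- max(min(sample$ph), min(blank$ph))
  hi <- min(max(sample$ph), max(blank$ph))
  if (lo >= hi) stop("sample and blank titrations have no overlapping pH range")
  ph_grid <- sort(unique(ph_grid))
  ph_grid <- ph_grid[ph_grid >= lo - 1e-9 & ph_grid <= hi + 1e-9]
  if (length(ph_grid) < 2L) stop("pH grid does not overlap the titrated range")

  s <- balance_term(sample, ph_grid, pkw, literal_sign, sample_term = TRUE)
  b <- balance_term(blank, ph_grid, pkw, literal_sign, sample_term = FALSE)
  n8 <- sample$n_bact / 1e8
  structure(list(ph = ph_grid, net_charge = (s - b) / n8 * 1e-3),
            class = "charge_profile")
}

#' Average replicate charge profiles
#'
#' Duplicate sample titrations are averaged after charge computation, on the
#' common pH grid.
#'
#' @param profiles List of `charge_profile` objects on identical grids.
#' @return A single `charge_profile`.
#' @export
average_charge_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  ph <- profiles[[1L]]$ph
  for (p in profiles) {
    if (!isTRUE(all.equal(p$ph, ph))) stop("profiles must share one pH grid")
  }
  q <- rowMeans(vapply(profiles, `[[`, numeric(length(ph)), "net_charge"))
  structure(list(ph = ph, net_charge = q), class = "charge_profile")
}

#' Net charge at a given pH
#'
#' Linear interpolation of a [net_charge_profile()] between the bracketing
#' grid points. No extrapolation: a pH outside the grid is an error.
#'
#' @param profile A `charge_profile`.
#' @param ph Query pH (default 8.0, the common stream condition).
#' @return Net charge in meq per 10^8 cells.
#' @export
charge_at <- function(profile, ph = 8.0) {
  stopifnot(inherits(profile, "charge_profile"), length(ph) == 1L)
  if (ph < min(profile$ph) - 1e-9 || ph > max(profile$ph) + 1e-9) {
    stop("pH ", ph, " lies outside the charge profile grid")
  }
  stats::approx(profile$ph, profile$net_charge, xout = ph, rule = 2)$y
}

#' Total titratable acidity
#'
#' Net charge at pH 4.0 minus net charge at pH 10.0 (the number of sites
#' deprotonated across the titrated window).
#'
#' @param profile A `charge_profile` whose grid covers pH 4 and pH 10.
#' @return Total acidity in meq per 10^8 cells.
#' @export
total_acidity <- function(profile) {
  stopifnot(inherits(profile, "charge_profile"))
  if (min(profile$ph) > 4 + 1e-9 || max(profile$ph) < 10 - 1e-9) {
    stop("charge profile must cover pH 4 through 10 for total acidity")
  }
  charge_at(profile, 4.0) - charge_at(profile, 10.0)
}

#' Point of zero charge
#'
#' The pH at which the net surface charge first changes sign, scanning from
#' low to high pH; located by linear interpolation between the bracketing
#' grid points. Profiles with no sign change in the window have no PZC.
#'
#' @param profile A `charge_profile`.
#' @return The PZC as a single pH, or `NA_real_` when the profile does not
#'   cross zero (absence is a value, not an error). Additional crossings, if
#'   any, are reported in attribute `"extra_crossings"`.
#' @export
point_of_zero_charge <- function(profile) {
  stopifnot(inherits(profile, "charge_profile"))
  q <- profile$net_charge
  ph <- profile$ph
  on_grid <- which(q == 0)
  sgn <- sign(q)
  cross <- which(sgn[-length(sgn)] * sgn[-1L] < 0)
  roots <- sort(c(ph[on_grid],
                  ph[cross] + (ph[cross + 1L] - ph[cross]) *
                    q[cross] / (q[cross] - q[cross + 1L])))
  if (length(roots) == 0L) return(NA_real_)
  out <- roots[1L]
  if (length(roots) > 1L) attr(out, "extra_crossings") <- roots[-1L]
  out
}

#' Fit a linear colorimetric standard curve
#'
#' Ordinary least-squares line `absorbance = intercept + slope * concentration`
#' through the standards, as used for the Lowry (BSA standard) and
#' phenol-sulfuric (xanthan standard) EPS assays.
#'
#' @param concentration Standard concentrations (at least 2 distinct).
#' @param absorbance Measured absorbances, same length.
#' @return Object of class `standard_curve` with `slope`, `intercept`,
#'   `r_squared` and the points.
#' @export
standard_curve <- function(concentration, absorbance) {
  stopifnot(length(concentration) == length(absorbance))
  if (length(unique(concentration)) < 2L) {
    stop("standard curve needs at least 2 distinct concentrations")
  }
  fit <- stats::lm(absorbance ~ concentration)
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || abs(slope) < 1e-12 * max(abs(absorbance), 1)) {
    stop("standard curve slope is zero")
  }
  tss <- sum((absorbance - mean(absorbance))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2,
                 concentration = concentration, absorbance = absorbance),
            class = "standard_curve")
}

#' EPS concentration from an absorbance reading
#'
#' Inverts the standard curve (`(absorbance - intercept) / slope`, giving
#' the total mass captured in the assay) and normalizes by the number of
#' assayed cells to micrograms per 10^8 cells.
#'
#' @param absorbance Raw absorbance reading(s).
#' @param curve A [standard_curve()].
#' @param n_cells Total cells in the assayed batch (the extraction protocol
#'   targets 3e10 to 6e10 cells).
#' @return Concentration in micrograms per 10^8 cells. Readings below the
#'   curve intercept are clamped to 0 with a warning.
#' @export
eps_concentration <- function(absorbance, curve, n_cells) {
  stopifnot(inherits(curve, "standard_curve"), n_cells > 0)
  total <- (absorbance - curve$intercept) / curve$slope
  if (any(total < 0)) {
    warning(sum(total < 0), " absorbance reading(s) below the blank intercept;",
            " concentration clamped to 0")
    total[total < 0] <- 0
  }
  total / (n_cells / 1e8)
}

#' Assemble the strain-by-property table
#'
#' Runs every per-strain assay of a cohort and collects the eight surface
#' properties: hydrophobicity, zeta potential (a pass-through instrument
#' measurement), EPS protein, EPS sugar, EPS protein/sugar ratio, net charge
#' at pH 8.0, total acidity and PZC, plus the habitat label. A strain whose
#' charge profile never crosses zero gets `NA` PZC (recorded as absent, not
#' zero).
#'
#' @param cohort A cohort as produced by [generate_cohort()] (or an
#'   equivalently shaped list: `strains` data frame, `titrations` data
#'   frame, standard curves).
#' @param ph_grid pH grid for charge profiles.
#' @return A `data.frame` with one row per strain: `strain_id`, `habitat`,
#'   then the eight property columns.
#' @export
build_property_table <- function(cohort, ph_grid = seq(4, 10, by = 0.02)) {
  st <- cohort$strains
  if (anyDuplicated(st$strain_id)) stop("duplicated strain id in cohort")

  blank <- titration_curve(cohort$blank$ph, cohort$blank$c_a,
                           cohort$blank$c_b, role = "blank")
  hydro <- hydrophobic_partitioning(st$initial_od, st$aqueous_od)
  protein <- eps_concentration(st$protein_abs, cohort$protein_curve,
                               st$eps_n_cells)
  sugar <- eps_concentration(st$sugar_abs, cohort$sugar_curve, st$eps_n_cells)

  n <- nrow(st)
  net8 <- acid <- pzc <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ti <- cohort$titrations[cohort$titrations$strain_id == st$strain_id[i], ]
    samp <- titration_curve(ti$ph, ti$c_a, ti$c_b,
                            n_bact = st$n_bact[i], role = "sample")
    prof <- net_charge_profile(samp, blank, ph_grid = ph_grid)
    net8[i] <- charge_at(prof, 8.0)
    acid[i] <- total_acidity(prof)
    pzc[i] <- as.numeric(point_of_zero_charge(prof))
  }

  data.frame(
    strain_id = st$strain_id,
    habitat = st$habitat,
    hydrophobicity = hydro,
    zeta_potential = st$zeta_potential,
    eps_protein = protein,
    eps_sugar = sugar,
    eps_ratio = protein / sugar,
    net_charge_ph8 = net8,
    total_acidity = acid,
    pzc = pzc,
    stringsAsFactors = FALSE
  )
}

#' Property column names of the strain-by-property table
#' @return Character vector of the eight property column names.
#' @export
property_names <- function() {
  c("hydrophobicity", "zeta_potential", "eps_protein", "eps_sugar",
    "eps_ratio", "net_charge_ph8", "total_acidity", "pzc")
}
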