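test_that("hydrophobic partitioning follows the MATH formula and clamps noise", {
  expect_equal(hydrophobic_partitioning(0.5, 0.5), 0)
  expect_equal(hydrophobic_partitioning(0.4, 0.0), 1)
  expect_equal(hydrophobic_partitioning(0.40, 0.04), 0.90)
  expect_warning(h <- hydrophobic_partitioning(0.4, 0.5), "clamped")
  expect_equal(h, 0)
  expect_error(hydrophobic_partitioning(0, 0.1), "positive")
  # strictly decreasing in the aqueous OD
  aq <- seq(0, 0.4, by = 0.05)
  expect_true(all(diff(hydrophobic_partitioning(rep(0.4, length(aq)), aq)) < 0))
})

toy_curves <- function() {
  ph <- c(6, 7, 8)
  list(
    sample = titration_curve(ph, rep(0.30, 3), rep(0.10, 3),
                             n_bact = 1e8, role = "sample"),
    blank = titration_curve(ph, rep(0.20, 3), rep(0.10, 3), role = "blank")
  )
}

test_that("net charge reproduces the hand-computed acid-base balance", {
  tc <- toy_curves()
  prof <- net_charge_profile(tc$sample, tc$blank, ph_grid = c(6, 7, 8))
  # at pH 7: ((0.3-0.1-1e-4+1e-4) - (0.2-0.1-1e-4+1e-4)) / 1 * 1e-3
  expect_equal(charge_at(prof, 7), 1e-4, tolerance = 1e-12)

  lit <- net_charge_profile(tc$sample, tc$blank, ph_grid = c(6, 7, 8),
                            literal_sign = TRUE)
  # literal printed form subtracts [OH-] in the sample term only
  expect_equal(charge_at(lit, 7), (0.1998 - 0.1) * 1e-3, tolerance = 1e-12)
})

test_that("a sample identical to the blank has zero net charge", {
  ph <- seq(4, 10, by = 0.1)
  c_a <- rep(0.5, length(ph))
  c_b <- 0.5 - 10^(-ph) * 1e3 + 10^(ph - 14) * 1e3
  s <- titration_curve(ph, c_a, c_b, n_bact = 2.3e8, role = "sample")
  b <- titration_curve(ph, c_a, c_b, role = "blank")
  prof <- net_charge_profile(s, b)
  expect_equal(max(abs(prof$net_charge)), 0, tolerance = 1e-15)

  # literal sign convention: profile is -2 [OH-] / N_bact * 1e-3 as printed
  lit <- net_charge_profile(s, b, literal_sign = TRUE)
  expect_equal(lit$net_charge,
               -2 * 10^(lit$ph - 14) * 1e3 / 2.3 * 1e-3,
               tolerance = 1e-12)
})

test_that("net charge profile recovers the generating protonation model", {
  sites <- list(c(1.0e-4, 5.0), c(0.7e-4, 7.5))
  tc <- titration_curve_from_model(sites, n_bact = 1.4e8, offset = 0.4e-4)
  prof <- net_charge_profile(tc$sample, tc$blank)
  expect_lt(max(abs(prof$net_charge - tc$model(prof$ph))), 1e-3 * 1e-4)
  # linearity: doubling every site density and the offset doubles the profile
  tc2 <- titration_curve_from_model(lapply(sites, function(s) c(2 * s[1], s[2])),
                                    n_bact = 1.4e8, offset = 0.8e-4)
  prof2 <- net_charge_profile(tc2$sample, tc2$blank)
  expect_equal(prof2$net_charge, 2 * prof$net_charge, tolerance = 1e-9)
})

test_that("charge_at interpolates linearly and refuses extrapolation", {
  prof <- structure(list(ph = c(7, 9), net_charge = c(0.2, -0.4)),
                    class = "charge_profile")
  expect_equal(charge_at(prof, 8), -0.1)   # midpoint of a linear profile
  expect_equal(charge_at(prof, 9), -0.4)   # exact grid point
  expect_error(charge_at(prof, 10), "outside")
})

test_that("total acidity is the pH 4 minus pH 10 charge difference", {
  ph <- seq(4, 10, by = 0.5)
  flat <- structure(list(ph = ph, net_charge = rep(0.3, length(ph))),
                    class = "charge_profile")
  expect_equal(total_acidity(flat), 0)

  lin <- structure(list(ph = ph,
                        net_charge = seq(0.2, -0.3, length.out = length(ph))),
                   class = "charge_profile")
  expect_equal(total_acidity(lin), 0.5)
  # invariant to adding a constant
  shifted <- lin; shifted$net_charge <- lin$net_charge + 1.7
  expect_equal(total_acidity(shifted), total_acidity(lin))
  # incomplete coverage fails
  short <- structure(list(ph = seq(5, 10, 0.5),
                          net_charge = rep(0, 11)), class = "charge_profile")
  expect_error(total_acidity(short), "cover")
})

test_that("single-site model acidity approximates the dissociated fraction", {
  tc <- titration_curve_from_model(list(c(1e-4, 7.0)), n_bact = 1e8)
  prof <- net_charge_profile(tc$sample, tc$blank)
  frac <- function(p) 1 / (1 + 10^(7 - p))
  expect_equal(total_acidity(prof), 1e-4 * (frac(10) - frac(4)),
               tolerance = 1e-9)
  # half-dissociation at the pKa
  expect_equal(charge_at(prof, 7.0), -0.5e-4, tolerance = 1e-9)
})

test_that("an empty site list recovers a zero charge profile", {
  tc <- titration_curve_from_model(list(), n_bact = 1e8)
  prof <- net_charge_profile(tc$sample, tc$blank)
  expect_equal(max(abs(prof$net_charge)), 0, tolerance = 1e-15)
})

test_that("point of zero charge is the first interpolated sign change", {
  neg <- structure(list(ph = seq(4, 10), net_charge = rep(-0.1, 7)),
                   class = "charge_profile")
  expect_true(is.na(point_of_zero_charge(neg)))

  cross <- structure(list(ph = c(4, 6, 7, 10),
                          net_charge = c(0.3, 0.1, -0.1, -0.5)),
                     class = "charge_profile")
  expect_equal(as.numeric(point_of_zero_charge(cross)), 6.5)

  # sign differs on either side of the reported PZC
  sites <- list(c(0.6e-4, 4.5), c(0.4e-4, 7.2))
  tc <- titration_curve_from_model(sites, n_bact = 1e8, offset = 0.5e-4)
  prof <- net_charge_profile(tc$sample, tc$blank)
  z <- as.numeric(point_of_zero_charge(prof))
  expect_true(sign(charge_at(prof, z - 0.1)) != sign(charge_at(prof, z + 0.1)))
})

test_that("PZC of the offset two-site model matches the closed-form root", {
  sites <- list(c(0.6e-4, 4.5), c(0.4e-4, 7.2))
  offset <- 0.5e-4
  tc <- titration_curve_from_model(sites, n_bact = 1e8, offset = offset)
  prof <- net_charge_profile(tc$sample, tc$blank)
  root <- uniroot(tc$model, c(4, 10), tol = 1e-12)$root
  expect_equal(as.numeric(point_of_zero_charge(prof)), root,
               tolerance = 0.05)
})

test_that("EPS quantitation inverts the standard curve", {
  curve <- standard_curve(c(0, 10), c(0.0, 1.0))
  expect_equal(eps_concentration(curve$intercept, curve, 1e8), 0)
  expect_equal(eps_concentration(0.5, curve, 1e8), 5)
  # per-cell normalization
  expect_equal(eps_concentration(0.5, curve, 5e8), 1)
  expect_warning(z <- eps_concentration(-0.2, curve, 1e8), "clamped")
  expect_equal(z, 0)
  expect_error(standard_curve(c(1, 1), c(0.1, 0.2)), "distinct")
  expect_error(standard_curve(c(1, 2, 3), rep(0.2, 3)), "slope")
})

test_that("replicate charge profiles average pointwise", {
  p1 <- structure(list(ph = c(4, 7, 10), net_charge = c(0.2, 0, -0.2)),
                  class = "charge_profile")
  p2 <- structure(list(ph = c(4, 7, 10), net_charge = c(0.4, 0.2, 0)),
                  class = "charge_profile")
  avg <- average_charge_profiles(list(p1, p2))
  expect_equal(avg$net_charge, c(0.3, 0.1, -0.1))
})

test_that("property table round-trips the generator truth at zero noise", {
  co <- generate_cohort(cohort_config(n_sediment = 8, n_water = 8, seed = 5))
  tab <- build_property_table(co)
  expect_equal(nrow(tab), 16)
  expect_equal(tab$eps_ratio, tab$eps_protein / tab$eps_sugar)
  for (p in setdiff(property_names(), c("net_charge_ph8", "total_acidity",
                                        "pzc"))) {
    expect_equal(tab[[p]], co$truth[[p]], tolerance = 1e-6)
  }
  for (p in c("net_charge_ph8", "total_acidity")) {
    expect_equal(tab[[p]], co$truth[[p]], tolerance = 1e-3)
  }
  ok <- !is.na(co$truth$pzc)
  expect_equal(tab$pzc[ok], co$truth$pzc[ok], tolerance = 1e-3)

  dup <- co
  dup$strains$strain_id[2] <- dup$strains$strain_id[1]
  expect_error(build_property_table(dup), "duplicated")
})
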