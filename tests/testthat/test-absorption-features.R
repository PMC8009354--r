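make_feature <- function(lambda1, lambda2, lambda_m, rho1, rho2, rho_m) {
  structure(list(name = "test", lambda1 = lambda1, lambda2 = lambda2,
                 lambda_m = lambda_m, rho1 = rho1, rho2 = rho2,
                 rho_m = rho_m, d = NA_real_, baseline_at_peak = NA_real_,
                 sai = NA_real_, valid = TRUE, reason = ""),
            class = "absorption_feature")
}

test_that("peak location finds constructed and analytic minima", {
  w <- default_windows()$SAI_1200
  # V-shaped dip with vertex at 1190 nm
  grid <- 1000:1350
  v <- 0.45 - pmax(0, 0.08 - abs(grid - 1190) * 0.001)
  f <- locate_feature(spectrum(grid, v), w)
  expect_equal(f$lambda_m, 1190)
  expect_true(f$valid)

  # Gaussian dip centred 1205 on a sloped continuum: within 2 nm of the
  # dense numeric minimum of the analytic product
  an <- analytic_spectrum(c(1000, 1350), c0 = 0.46, slope = -2e-5,
                          dips = list(list(centre = 1205, sigma = 25,
                                           depth = 0.12)))
  fine <- seq(1111, 1264, by = 0.01)
  oracle_min <- fine[which.min(an$fun(fine))]
  f2 <- locate_feature(an$spectrum, w)
  expect_lt(abs(f2$lambda_m - oracle_min), 2)
})

test_that("a flat window resolves ties to the edges and gives SAI 1", {
  w <- default_windows()$SAI_1200
  f <- locate_feature(flat_spectrum(0.4, c(1000, 1350)), w)
  expect_equal(f$lambda1, 1085)   # left edge of left search range
  expect_equal(f$lambda2, 1240)   # left edge of right search range
  expect_true(f$valid)
  expect_equal(as.numeric(compute_sai(f)), 1)
})

test_that("monotone windows with no dip are marked invalid", {
  w <- default_windows()$SAI_1200
  grid <- 1000:1350
  down <- spectrum(grid, 0.6 - (grid - 1000) * 5e-4)
  f <- locate_feature(down, w)
  expect_false(f$valid)
  expect_match(f$reason, "no interior dip")
  expect_error(compute_sai(f), "not valid")
  # window not covered at all
  expect_error(locate_feature(flat_spectrum(0.4, c(1100, 1200)), w),
               "does not cover")
})

test_that("the symmetry parameter is the peak's relative position", {
  expect_equal(compute_d(1085, 1265, 1175), 0.5)
  expect_equal(compute_d(1085, 1265, 1150), 115 / 180)
  expect_equal(compute_d(1085, 1265, 1264), 1 / 180)  # d -> 0 as peak -> right
  expect_error(compute_d(1085, 1265, 1085), "lambda1 < lambda_m")
  expect_error(compute_d(1085, 1265, 1300), "lambda1 < lambda_m")
})

test_that("SAI is the shoulder-line baseline over the peak reflectance", {
  f <- make_feature(1085, 1265, 1175, rho1 = 0.45, rho2 = 0.47, rho_m = 0.30)
  expect_equal(as.numeric(compute_sai(f)), (0.5 * 0.45 + 0.5 * 0.47) / 0.30)
  # no absorption: peak on the baseline gives exactly 1
  f1 <- make_feature(1085, 1265, 1175, 0.45, 0.47, 0.46)
  expect_equal(as.numeric(compute_sai(f1)), 1)
  expect_error(compute_sai(make_feature(1085, 1265, 1175, .4, .4, 0)),
               "> 0")
  # the d-weighted shoulder mix equals the explicit two-point line at the
  # peak wavelength -- the identity the weighting exists for
  set.seed(8)
  for (i in 1:25) {
    l1 <- sample(1085:1110, 1); l2 <- sample(1240:1265, 1)
    lm <- sample((l1 + 1):(l2 - 1), 1)
    r1 <- runif(1, .3, .5); r2 <- runif(1, .3, .5)
    f <- make_feature(l1, l2, lm, r1, r2, 0.3)
    slope <- (r2 - r1) / (l2 - l1)
    line_at_peak <- r1 + slope * (lm - l1)
    got <- attr(compute_sai(f), "feature")$baseline_at_peak
    expect_lt(abs(got - line_at_peak), 1e-12)
  }
})

test_that("the SAI family is scale-invariant and window-local", {
  g <- generate_leaf_spectrum(0.011, 0.60, seed = 14)
  s <- g$spectrum
  sais <- compute_sai_family(s)
  expect_true(all(sais > 1))
  half <- spectrum(s$wavelength, s$reflectance * 0.5)
  expect_lt(max(abs(compute_sai_family(half) - sais)), 1e-12)

  # removing the 1200-nm dip flattens SAI_1200 but leaves the others
  grid <- s$wavelength
  no_dip <- generate_leaf_spectrum(0.011, 0.60, seed = 14)$spectrum
  keep <- grid >= 1085 & grid <= 1265
  base <- approx(grid[!keep], s$reflectance[!keep], xout = grid[keep])$y
  no_dip$reflectance[keep] <- base
  sais2 <- compute_sai_family(no_dip)
  expect_true(is.na(sais2["SAI_1200"]) || abs(sais2["SAI_1200"] - 1) < 0.02)
  expect_equal(unname(sais2["SAI_1660"]), unname(sais["SAI_1660"]))
})

test_that("SAI_1200 increases strictly with dip depth", {
  w <- default_windows()$SAI_1200
  depths <- seq(0.02, 0.30, by = 0.04)
  sais <- sapply(depths, function(D) {
    an <- analytic_spectrum(c(1000, 1350), c0 = 0.45,
                            dips = list(list(centre = 1200, sigma = 25,
                                             depth = D)))
    as.numeric(compute_sai(locate_feature(an$spectrum, w)))
  })
  expect_true(all(diff(sais) > 0))
})

test_that("SAI_1200 tolerates a +/-10 nm peak shift within 1%", {
  w <- default_windows()$SAI_1200
  ref <- NULL
  for (shift in c(0, -10, 10)) {
    an <- analytic_spectrum(c(1000, 1350), c0 = 0.45,
                            dips = list(list(centre = 1200 + shift,
                                             sigma = 25, depth = 0.12)))
    v <- as.numeric(compute_sai(locate_feature(an$spectrum, w)))
    if (is.null(ref)) ref <- v
    expect_lt(abs(v - ref) / ref, 0.01)
  }
})

test_that("located extrema match exhaustive search on random windows", {
  w <- default_windows()$SAI_1200
  set.seed(99)
  for (i in 1:200) {
    an <- analytic_spectrum(
      c(1000, 1350), c0 = runif(1, 0.3, 0.55), slope = runif(1, -4e-5, 4e-5),
      dips = list(list(centre = runif(1, 1150, 1250),
                       sigma = runif(1, 18, 32),
                       depth = runif(1, 0.03, 0.25))))
    s <- an$spectrum
    s$reflectance <- s$reflectance + rnorm(length(s$wavelength), 0, 0.002)
    got <- locate_feature(s, w, smooth = FALSE)
    # independent brute force over all admissible (l1, lm, l2) triples
    wl <- s$wavelength; r <- s$reflectance
    best1 <- -Inf; i1 <- NA
    for (j in which(wl >= 1085 & wl <= 1110)) {
      if (r[j] > best1) { best1 <- r[j]; i1 <- j }
    }
    best2 <- -Inf; i2 <- NA
    for (j in which(wl >= 1240 & wl <= 1265)) {
      if (r[j] > best2) { best2 <- r[j]; i2 <- j }
    }
    bestm <- Inf; im <- NA
    for (j in (i1 + 1):(i2 - 1)) {
      if (r[j] < bestm) { bestm <- r[j]; im <- j }
    }
    expect_equal(got$lambda1, wl[i1])
    expect_equal(got$lambda2, wl[i2])
    expect_equal(got$lambda_m, wl[im])
  }
})
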