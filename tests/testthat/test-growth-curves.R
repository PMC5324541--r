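exactSeries <- function(A = -4, B = 1, t_mid = 15, s = 4,
                        days = c(8, 12, 16, 20, 24, 28), per_day = 2) {
  day <- rep(days, each = per_day)
  data.frame(day = day, mass = exp(logistic4(day, A, B, t_mid, s)))
}

test_that("noiseless data recover the generating parameters to 1e-6", {
  fit <- fitGrowthCurve(exactSeries())
  expect_true(fit$converged)
  expect_equal(fit$A, -4, tolerance = 1e-6)
  expect_equal(fit$B, 1, tolerance = 1e-6)
  expect_equal(fit$t_mid, 15, tolerance = 1e-6)
  expect_equal(fit$s, 4, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
})

test_that("with sigma = 0.1 log-mass noise and n = 12 the fit recovers parameters within 10% (median over 100 seeds)", {
  true <- c(A = -4, B = 1, t_mid = 15, s = 4)
  rel_err <- t(vapply(1:100, function(seed) {
    set.seed(seed)
    d <- exactSeries()
    d$mass <- exp(log(d$mass) + rnorm(nrow(d), 0, 0.1))
    f <- fitGrowthCurve(d)
    abs(c(f$A, f$B, f$t_mid, f$s) - true) / abs(true)
  }, numeric(4)))
  expect_true(all(apply(rel_err, 2, median) < 0.10))
})

test_that("degenerate series are refused rather than mis-fitted", {
  dec <- exactSeries()
  dec$mass <- rev(dec$mass)
  expect_error(fitGrowthCurve(dec, species_id = "X"), "not increasing")
  flat <- data.frame(day = c(8, 11, 14, 18, 22, 26), mass = 0.5)
  expect_error(fitGrowthCurve(flat), "flat")
  expect_error(fitGrowthCurve(exactSeries()[1:4, ]), "at least")
})

test_that("fits are deterministic despite jittered restarts", {
  set.seed(1); d <- exactSeries()
  d$mass <- exp(log(d$mass) + rnorm(nrow(d), 0, 0.1))
  f1 <- fitGrowthCurve(d)
  set.seed(99999)  # caller RNG state must not leak into the fit
  f2 <- fitGrowthCurve(d)
  expect_identical(f1[c("A", "B", "t_mid", "s", "rss")],
                   f2[c("A", "B", "t_mid", "s", "rss")])
})

test_that("RGR at the inflection equals (B - A) / (4 s) and inverts the curve", {
  fit <- fitGrowthCurve(exactSeries(A = -4, B = 1, s = 4))
  mc_mid_mg <- exp((fit$A + fit$B) / 2) * 1000
  est <- rgrAtSize(fit, mc_mid_mg)
  expect_equal(est$p_star, 0.5, tolerance = 1e-8)
  expect_equal(est$lambda_s, (fit$B - fit$A) / (4 * fit$s), tolerance = 1e-10)
  expect_equal(est$lambda_s, 5 / 16, tolerance = 1e-6)
  expect_equal(logistic4(est$t_star, fit$A, fit$B, fit$t_mid, fit$s),
               log(mc_mid_mg / 1000), tolerance = 1e-10)
})

test_that("closed-form RGR matches the numeric slope of the fitted curve at t*", {
  fit <- fitGrowthCurve(exactSeries(A = -5, B = 0.6, t_mid = 17, s = 3.2))
  for (mc in c(20, 42.1, 150)) {
    est <- rgrAtSize(fit, mc)
    h <- 1e-5
    slope <- (logistic4(est$t_star + h, fit$A, fit$B, fit$t_mid, fit$s) -
              logistic4(est$t_star - h, fit$A, fit$B, fit$t_mid, fit$s)) / (2 * h)
    expect_equal(est$lambda_s, slope, tolerance = 1e-8)
  }
})

test_that("a common size outside the fitted asymptotes is refused", {
  fit <- fitGrowthCurve(exactSeries())
  expect_error(rgrAtSize(fit, exp(fit$B) * 1000 * 1.1), "outside fitted range")
  expect_error(rgrAtSize(fit, exp(fit$A) * 1000 * 0.9), "outside fitted range")
})

test_that("lambda_s is invariant to the mass unit given a consistent common size", {
  d <- exactSeries()
  fit_g <- fitGrowthCurve(d)
  d_mg <- transform(d, mass = mass * 1000)
  fit_mg <- fitGrowthCurve(d_mg)
  # a unit change shifts both asymptotes by ln 1000
  expect_equal(fit_mg$A - fit_g$A, log(1000), tolerance = 1e-5)
  expect_equal(fit_mg$B - fit_g$B, log(1000), tolerance = 1e-5)
  ls_g <- rgrAtSize(fit_g, 42.1)$lambda_s
  p_mg <- (log(42.1) - fit_mg$A) / (fit_mg$B - fit_mg$A)  # 42.1 mg in mg units
  ls_mg <- (fit_mg$B - fit_mg$A) * p_mg * (1 - p_mg) / fit_mg$s
  expect_equal(ls_g, ls_mg, tolerance = 1e-6)
})

test_that("deep in the early phase lambda_s approaches the exponential growth rate", {
  # B - A large and target size near the floor: the logistic is locally
  # exponential with initial rate (B - A)/s at p -> 0; at small p the slope
  # is (B-A)p(1-p)/s, and the local exponential rate of mass growth at size
  # m equals that slope. Simulate a pure exponential and check recovery.
  r <- 0.25
  day <- rep(seq(4, 20, by = 2), each = 2)
  mass <- 0.001 * exp(r * day)
  fit <- fitGrowthCurve(data.frame(day = day, mass = mass))
  est <- rgrAtSize(fit, 42.1)
  expect_equal(est$lambda_s, r, tolerance = 0.03 * r)
})

test_that("common size is the largest of the species minima at first harvest", {
  ser <- data.frame(
    species = rep(c("s1", "s2", "s3"), each = 4),
    day = rep(c(8, 8, 12, 12), 3),
    mass = c(0.010, 0.012, 0.05, 0.06,
             0.0421, 0.045, 0.09, 0.10,
             0.030, 0.032, 0.07, 0.08))
  expect_equal(commonSize(ser), 42.1)
  expect_equal(commonSize(ser, species = "s1"), 10)
  expect_error(commonSize(ser, species = "nope"), "no growth observations")
  expect_equal(unname(commonSizeDefaults), c(42.1, 64.7))
})

test_that("simulated growth series recover their planted parameters and common sizes", {
  g <- simulateGrowthSeries(simConfig(seed = 8, noiseless = TRUE))
  fits <- growthAnalysis(g$series)
  expect_identical(nrow(fits), 17L)
  expect_true(all(fits$converged))
  m <- merge(fits, g$truth, by = "species")
  expect_lt(max(abs(m$A.x - m$A.y)), 1e-6)
  expect_lt(max(abs(m$s.x - m$s.y)), 1e-6)
  # noiseless: the common size equals the largest species' day-8 mass
  day8 <- g$series[g$series$day == 8, ]
  for (fam in c("grass", "legume")) {
    expected <- max(tapply(day8$mass[day8$family == fam],
                           day8$species[day8$family == fam], min)) * 1000
    expect_equal(unique(fits$common_mass_mg[fits$family == fam]), expected)
  }
})
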