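test_that("size factors recover scale and are equivariant", {
  # hand-computed toy: geometric means (4, 8, 12); ratios s1 = 0.5, s2 = 2
  cm <- matrix(c(2L, 4L, 6L, 8L, 16L, 24L), 3, 2,
               dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  sf <- size_factors(cm)
  expect_equal(unname(sf["s2"] / sf["s1"]), 4)
  expect_equal(exp(mean(log(sf))), 1)

  # doubling one sample doubles its factor (scale equivariance)
  set.seed(3)
  m <- matrix(rpois(300, 60) + 1L, 50, 6,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:6)))
  storage.mode(m) <- "integer"
  sf1 <- size_factors(m)
  m2 <- m; m2[, 3] <- m2[, 3] * 3L
  sf2 <- size_factors(m2)
  expect_equal(unname(sf2[3] / sf1[3] / (sf2[1] / sf1[1])), 3, tolerance = 1e-12)

  # single sample -> factor 1; all-zero reference -> error advising fallback
  expect_equal(unname(size_factors(m[, 1, drop = FALSE])), 1)
  mz <- m; for (j in 1:6) mz[j, j] <- 0L; mz <- mz[1:6, ]
  expect_error(size_factors(mz), "pseudo_ref")
  expect_silent(size_factors(mz, pseudo_ref = TRUE))
})

test_that("NB GLM matches the numeric-search oracle on random instances", {
  set.seed(42)
  des <- diffstab_design()
  for (i in 1:20) {
    mu <- runif(4, 10, 1000)
    y <- rnbinom(8, mu = rep(mu, each = 2), size = 1 / 0.05)
    fit <- fit_nb_glm(y, des$alt, 0.05, tol = 1e-13)
    oracle <- nb_glm_oracle(y, des$alt, 0.05)
    expect_lt(abs(fit$loglik - oracle$loglik), 1e-4)
    # saturated model: fitted means equal observed cell means
    expect_equal(fit$fitted, rep(tapply(y, rep(1:4, each = 2), mean),
                                 each = 2),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("GLM handles offsets, degenerate input and rank deficiency", {
  des <- diffstab_design()
  set.seed(9)
  y <- rnbinom(8, mu = 200, size = 20)
  off <- log(runif(8, 0.5, 2))
  fit <- fit_nb_glm(y, des$alt, 0.05, offset = off, tol = 1e-13)
  oracle <- nb_glm_oracle(y, des$alt, 0.05, offset = off)
  expect_lt(abs(fit$loglik - oracle$loglik), 1e-4)

  zero <- fit_nb_glm(rep(0L, 8), des$null, 0.1)
  expect_true(zero$degenerate)
  expect_equal(zero$loglik, 0)

  expect_error(fit_nb_glm(y, cbind(des$null, des$null[, 1]), 0.1),
               "full rank")
  expect_error(fit_nb_glm(y, des$null, -1), "dispersion")
})

test_that("null fits never beat nested alternative fits", {
  set.seed(21)
  des <- diffstab_design()
  for (i in 1:25) {
    y <- rnbinom(8, mu = exp(runif(1, 1, 7)), size = 1 / runif(1, 0.01, 0.5))
    f0 <- fit_nb_glm(y, des$null, 0.05, tol = 1e-12)
    f1 <- fit_nb_glm(y, des$alt, 0.05, tol = 1e-12)
    expect_gte(f1$loglik, f0$loglik - 1e-6)
  }
})

test_that("lrt computes the chi-squared(1) tail and clips tiny negatives", {
  r <- lrt(list(loglik = -100, df = 3L), list(loglik = -100, df = 4L))
  expect_equal(r$stat, 0)
  expect_equal(r$p, 1)
  # closed form: P(chisq1 > x) = erfc(sqrt(x/2)) = 2 pnorm(-sqrt(x))
  r2 <- lrt(list(loglik = 0, df = 3L),
            list(loglik = 3.841459 / 2, df = 4L))
  expect_equal(r2$p, 2 * pnorm(-sqrt(3.841459)), tolerance = 1e-10)
  expect_equal(r2$p, 0.05, tolerance = 1e-4)
  r3 <- lrt(list(loglik = -10 + 1e-8, df = 3L), list(loglik = -10, df = 4L))
  expect_equal(r3$stat, 0)
  expect_false(r3$flagged)
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(8)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_bruteforce(p))
  }
})

test_that("raw dispersions recover a constant truth and sit near the floor for Poisson", {
  set.seed(14)
  n <- 800
  truth <- make_truth(n, mixture = c(constitutive = 1),
                      basal_range = c(200, 2000),
                      disp_trend = c(a0 = 0.1, a1 = 0), disp_noise_sd = 0,
                      seed = 14)
  sim <- simulate_counts(truth, sim_design(times = c(0, 1, 72), seed = 15))
  dm <- estimate_dispersion(sim$counts, sim$sheet)
  # trend approx constant 0.1 within 20% over the expressed range
  pred <- dm$trend_coef[1] + dm$trend_coef[2] / c(200, 500, 2000)
  expect_true(all(abs(pred - 0.1) / 0.1 < 0.2))
  expect_lt(abs(median(dm$raw, na.rm = TRUE) - 0.1) / 0.1, 0.25)

  # Poisson data: raw dispersions concentrate near the floor
  pois <- truth
  pois$dispersion[] <- 0
  simp <- simulate_counts(pois, sim_design(times = c(0, 1, 72), seed = 16))
  dmp <- suppressWarnings(estimate_dispersion(simp$counts, simp$sheet))
  expect_gt(mean(dmp$raw <= 1e-6, na.rm = TRUE), 0.5)
})

test_that("identical genes get identical dispersions; errors are informative", {
  set.seed(17)
  y <- rnbinom(8, mu = 300, size = 10)
  cm <- matrix(rep(y, each = 30), 30, 8, byrow = FALSE,
               dimnames = list(sprintf("g%02d", 1:30), sprintf("s%d", 1:8)))
  storage.mode(cm) <- "integer"
  sheet <- data.frame(sample_id = sprintf("s%d", 1:8),
                      time_h = rep(c(1, 72), each = 4),
                      arm = rep(c("TNF", "TNF", "TNF_ACTD", "TNF_ACTD"), 2),
                      replicate = rep(1:2, 4))
  # degenerate fixture (a single mean value) provokes collinearity warnings
  dm <- suppressWarnings(
    estimate_dispersion(cm, sheet, sf = setNames(rep(1, 8), colnames(cm))))
  expect_equal(length(unique(round(dm$final, 12))), 1)

  one_rep <- sheet; one_rep$replicate <- 1:8
  one_rep$arm <- "TNF"; one_rep$time_h <- 1:8
  expect_error(estimate_dispersion(cm, one_rep), "unidentifiable")
})

test_that("full test is calibrated on a small null simulation", {
  # scaled-down version of the acceptance calibration (n = 400 genes)
  truth <- make_truth(400, mixture = c(constitutive = 1), seed = 31)
  sim <- simulate_counts(truth, sim_design(times = c(0, 1, 72), seed = 131))
  res <- differential_stability_test(sim$counts, sim$sheet, 1, 72)
  p <- res$pvalue[res$flag == ""]
  expect_gt(length(p), 250)
  expect_lt(mean(p < 0.05), 0.09)
  expect_gt(mean(p < 0.05), 0.015)
})
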