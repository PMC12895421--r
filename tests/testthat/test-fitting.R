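# Staged nonlinear fitting: initialization, recovery, statistics,
# outlier detection and residual diagnostics.

make_cinfv_pair <- function() {
  lr_system(lr_molecule("M1", "Cinfv"), lr_molecule("M2", "Cinfv"))
}

test_that("fit statistics follow their definitions", {
  expect_equal(fit_statistics(c(0, 0, 0), c(1, 2, 3)),
               c(rmse = 0, r2 = 1))
  # model identical to the data mean: R2 = 0
  obs <- c(4, 6, 8, 10)
  expect_equal(fit_statistics(obs - mean(obs), obs)[["r2"]], 0)
  # hand arithmetic: residuals {1,-1}, data {10,12}
  st <- fit_statistics(c(1, -1), c(10, 12))
  expect_equal(st[["rmse"]], 1)
  expect_equal(st[["r2"]], 0)
  # zero-variance data: R2 undefined
  expect_true(is.na(fit_statistics(c(0.1, -0.1), c(5, 5))[["r2"]]))
})

test_that("initialization recovers the asymptote of constant data", {
  sys <- make_cinfv_pair()
  set.seed(71)
  n <- 60
  df <- data.frame(R = runif(n, 15, 60), alpha = runif(n, 0, 2 * pi),
                   beta_A = acos(runif(n, -1, 1)),
                   beta_B = acos(runif(n, -1, 1)))
  dat <- lr_dataset(df, rep(0.037, n),
                    units = list(distance = "bohr", angle = "rad",
                                 energy = "hartree"))
  cf <- initialize_fit(dat, sys, lr_plan(caps = 4))
  expect_equal(cf$theta[["E_asym"]], 0.037, tolerance = 1e-8)
  other <- setdiff(names(cf$theta), "E_asym")
  expect_lt(max(abs(cf$theta[other])), 1e-6)
})

test_that("initialization recovers asymptote and charge product of an ion pair exactly", {
  ion1 <- lr_molecule("A+", "atom", charge = 2)
  ion2 <- lr_molecule("B-", "atom", charge = -1)
  sys <- lr_system(ion1, ion2)
  set.seed(72)
  n <- 40
  df <- data.frame(R = runif(n, 20, 80))
  e <- 0.0123 + 2 * (-1) / df$R
  dat <- lr_dataset(df, e, units = list(distance = "bohr", angle = "rad",
                                        energy = "hartree"))
  cf <- initialize_fit(dat, sys, lr_plan(caps = c(elec = 1, ind = 0, disp = 0)))
  expect_equal(cf$theta[["E_asym"]], 0.0123, tolerance = 1e-8)
  # the charge product is pinned, so the model must already be exact
  expect_lt(max(abs(evaluate_energy(cf, df) - e)), 1e-10)
})

test_that("far-range fraction does not matter on clean data", {
  sys <- make_cinfv_pair()
  truth <- random_coefficients(sys, c(elec = 4, ind = 0, disp = 0), seed = 73)
  dat <- synthetic_dataset(truth, 200, c(15, 60), noise_sigma = 0, seed = 73)
  c25 <- initialize_fit(dat, sys, lr_plan(caps = c(elec = 4, ind = 0, disp = 0),
                                          far_fraction = 0.25))
  c50 <- initialize_fit(dat, sys, lr_plan(caps = c(elec = 4, ind = 0, disp = 0),
                                          far_fraction = 0.50))
  scale <- max(abs(c25$theta))
  expect_lt(max(abs(c25$theta - c50$theta)) / scale, 1e-6)
})

test_that("noiseless synthetic data are recovered to high accuracy (flagship property)", {
  sys <- make_cinfv_pair()
  truth <- random_coefficients(sys, c(elec = 5, ind = 5, disp = 5), seed = 7)
  dat <- synthetic_dataset(truth, 500, c(15, 60), noise_sigma = 0, seed = 7)
  fit <- lr_fit(dat, sys, plan = lr_plan(c(elec = 5, ind = 5, disp = 5),
                                         seed = 7))
  expect_lt(tail(fit$history$rmse, 1), 1e-10)
  aligned <- gauge_align(fit, truth)
  nz <- abs(truth$theta) > 1e-10
  rel <- abs(aligned$theta - truth$theta)[nz] / abs(truth$theta)[nz]
  expect_lt(max(rel), 1e-6)
  # staged RMSE never increases
  expect_true(all(diff(fit$history$rmse) < 1e-12))
})

test_that("with Gaussian noise the final RMSE matches sigma and R2 is high", {
  sys <- make_cinfv_pair()
  truth <- random_coefficients(sys, c(elec = 4, ind = 4, disp = 0), seed = 74)
  sigma <- 2e-7
  dat <- synthetic_dataset(truth, 400, c(15, 60), noise_sigma = sigma,
                           seed = 74)
  fit <- lr_fit(dat, sys, plan = lr_plan(c(elec = 4, ind = 4, disp = 0),
                                         seed = 74))
  rmse <- tail(fit$history$rmse, 1)
  expect_gt(rmse, 0.8 * sigma)
  expect_lt(rmse, 1.2 * sigma)
})

test_that("coefficient errors shrink roughly like 1/sqrt(n)", {
  sys <- make_cinfv_pair()
  truth <- random_coefficients(sys, c(elec = 4, ind = 0, disp = 0), seed = 75)
  sigma <- 1e-7
  err_at <- function(n) {
    dat <- synthetic_dataset(truth, n, c(15, 60), noise_sigma = sigma,
                             seed = 75)
    fit <- lr_fit(dat, sys, plan = lr_plan(c(elec = 4, ind = 0, disp = 0),
                                           seed = 75))
    al <- gauge_align(fit, truth)
    nz <- abs(truth$theta) > 1e-10
    sqrt(mean((al$theta - truth$theta)[nz]^2))
  }
  e1 <- err_at(100); e2 <- err_at(1000)
  expect_lt(e2, e1 / sqrt(10) * 3)  # allow generous slack around 1/sqrt(n)
  expect_gt(e1, e2)                 # more data never hurts here
})

test_that("fixing one known coefficient triggers the cascade of determinations", {
  # an ion (pinned charge) facing a homonuclear diatomic: the known charge
  # determines the partner's quadrupole from the charge-quadrupole term
  ion <- lr_molecule("X+", "Cinfv", charge = 1)
  h2 <- lr_molecule("H2", "Dinfh")
  sys <- lr_system(ion, h2)
  truth <- random_coefficients(sys, c(elec = 5, ind = 5, disp = 0), seed = 76)
  dat <- synthetic_dataset(truth, 400, c(15, 60), noise_sigma = 0, seed = 76)
  fit <- lr_fit(dat, sys, plan = lr_plan(c(elec = 5, ind = 5, disp = 0),
                                         seed = 76))
  # Theta_B (the "20" coordinate of B) recovered without any gauge fixing
  tb_true <- truth$theta[["QB.2.1"]]
  expect_lt(abs(coef(fit)[["QB.2.1"]] - tb_true) / abs(tb_true), 1e-6)
  # fixing a molecule-A multipole to its true value is honored exactly
  mu_true <- truth$theta[["QA.1.1"]]
  fit2 <- lr_fit(dat, sys, plan = lr_plan(c(elec = 5, ind = 5, disp = 0),
                                          fixed = c(QA.1.1 = mu_true),
                                          seed = 76))
  expect_identical(coef(fit2)[["QA.1.1"]], mu_true)
  expect_lt(abs(coef(fit2)[["QB.2.1"]] - tb_true) / abs(tb_true), 1e-6)
})

test_that("identical molecules return equal coefficient blocks", {
  co <- lr_molecule("CO", "Cinfv")
  sys <- lr_system(co, co, "identical")
  truth <- random_coefficients(sys, c(elec = 5, ind = 6, disp = 6), seed = 77)
  dat <- synthetic_dataset(truth, 500, c(15, 60), noise_sigma = 0, seed = 77)
  fit <- lr_fit(dat, sys, plan = lr_plan(c(elec = 5, ind = 6, disp = 6),
                                         seed = 77))
  th <- coef(fit)
  for (l in fit$expansion$qA_ranks)
    expect_identical(th[[sprintf("QA.%d.1", l)]], th[[sprintf("QB.%d.1", l)]])
  for (k in names(fit$expansion$aA_blocks))
    for (i in seq_along(fit$expansion$patA[[k]]))
      expect_identical(th[[sprintf("aA.%s.%d", k, i)]],
                       th[[sprintf("aB.%s.%d", k, i)]])
  # and the fit still reproduces the generating model's energies
  expect_lt(tail(fit$history$rmse, 1), 1e-9)
})

test_that("the gauge rule orients the leading A multipole non-negative", {
  sys <- make_cinfv_pair()
  truth <- random_coefficients(sys, c(elec = 4, ind = 0, disp = 0), seed = 78)
  dat <- synthetic_dataset(truth, 200, c(15, 60), noise_sigma = 0, seed = 78)
  fit <- lr_fit(dat, sys, plan = lr_plan(c(elec = 4, ind = 0, disp = 0),
                                         seed = 78))
  qa <- grep("^QA\\.", names(coef(fit)), value = TRUE)
  lead <- qa[which(abs(coef(fit)[qa]) > 0)[1]]
  expect_gte(coef(fit)[[lead]], 0)
})

test_that("too few points error, and sub-5x coverage warns", {
  sys <- make_cinfv_pair()
  truth <- random_coefficients(sys, c(elec = 4, ind = 0, disp = 0), seed = 79)
  tiny <- synthetic_dataset(truth, 4, c(15, 60), seed = 79)
  expect_error(lr_fit(tiny, sys, plan = lr_plan(c(elec = 4, ind = 0, disp = 0))),
               "free parameters")
  small <- synthetic_dataset(truth, 12, c(15, 60), seed = 79)
  expect_warning(lr_fit(small, sys,
                        plan = lr_plan(c(elec = 4, ind = 0, disp = 0))),
                 "5 points")
})

test_that("duplicate geometries with differing energies are kept with a warning", {
  ion1 <- lr_molecule("A+", "atom", charge = 1)
  ion2 <- lr_molecule("B+", "atom", charge = 1)
  sys <- lr_system(ion1, ion2)
  df <- data.frame(R = c(10, 10, 12, 14, 16, 18, 20, 25, 30, 40))
  e <- 1 / df$R; e[2] <- e[2] + 1e-5
  dat <- lr_dataset(df, e, units = list(distance = "bohr", angle = "rad",
                                        energy = "hartree"))
  expect_warning(
    fit <- lr_fit(dat, sys, plan = lr_plan(c(elec = 1, ind = 0, disp = 0))),
    "duplicate")
  expect_equal(length(residuals(fit)), 10)
})

test_that("outlier detection flags relative outliers, preferentially at large R", {
  sys <- make_cinfv_pair()
  truth <- random_coefficients(sys, c(elec = 4, ind = 0, disp = 0), seed = 81)
  # clean fit: no flags
  dat <- synthetic_dataset(truth, 200, c(15, 60), noise_sigma = 1e-8,
                           seed = 81)
  fit <- lr_fit(dat, sys, plan = lr_plan(c(elec = 4, ind = 0, disp = 0),
                                         seed = 81))
  expect_equal(sum(fit$outliers), 0)
  # perturb one point by 10x its local interaction energy: flagged
  hits <- 0L
  for (rep in 1:20) {
    datp <- synthetic_dataset(truth, 200, c(15, 60), noise_sigma = 1e-8,
                              seed = 500 + rep, n_outliers = 1,
                              outlier_size = 10)
    fitp <- lr_fit(datp, sys, plan = lr_plan(c(elec = 4, ind = 0, disp = 0),
                                             seed = 1))
    if (any(fitp$outliers)) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
  # the same absolute perturbation is flagged at the largest R but not at
  # the smallest (relative weighting): a 30% relative error at the far
  # point is a sub-0.1% one at the near point of this wide R window
  base <- synthetic_dataset(truth, 200, c(15, 120), noise_sigma = 1e-9,
                            seed = 82)
  i_far <- which.max(base$geoms$R); i_near <- which.min(base$geoms$R)
  easym <- truth$theta[["E_asym"]]
  bump <- 0.3 * abs(attr(base, "model_energy")[i_far] - easym)
  e2 <- base$energy; e2[i_far] <- e2[i_far] + bump
  e3 <- base$energy; e3[i_near] <- e3[i_near] + bump
  dfar <- lr_dataset(base$geoms, e2, base$units)
  dnear <- lr_dataset(base$geoms, e3, base$units)
  ffar <- lr_fit(dfar, sys, plan = lr_plan(c(elec = 4, ind = 0, disp = 0)))
  fnear <- lr_fit(dnear, sys, plan = lr_plan(c(elec = 4, ind = 0, disp = 0)))
  expect_true(ffar$outliers[i_far])
  expect_false(fnear$outliers[i_near])
})

test_that("residual histograms behave as expected for balanced and under-fitted models", {
  sys <- make_cinfv_pair()
  truth <- random_coefficients(sys, c(elec = 5, ind = 0, disp = 0), seed = 83)
  dat <- synthetic_dataset(truth, 4000, c(15, 60), noise_sigma = 5e-8,
                           seed = 83)
  fit <- lr_fit(dat, sys, plan = lr_plan(c(elec = 5, ind = 0, disp = 0),
                                         seed = 83))
  h <- residual_histogram(fit, bins = 40)
  expect_equal(sum(h$counts), 4000)
  expect_lt(abs(skewness(residuals(fit))), 0.2)  # balanced fit
  expect_error(residual_histogram(fit, bins = 0), "bins")
  # all-zero residuals collapse to a single occupied bin
  fit0 <- fit
  fit0$residuals <- rep(0, 10)
  h0 <- residual_histogram(fit0, bins = 20)
  expect_equal(sum(h0$counts > 0), 1)
  # under-fitted model: an ion-diatomic system fitted with the leading
  # electrostatic term only misses the strictly negative induction
  # energy, leaving a one-sided, strongly skewed residual distribution
  ion <- lr_molecule("X+", "Cinfv", charge = 1)
  h2 <- lr_molecule("H2", "Dinfh")
  sysu <- lr_system(ion, h2)
  truthu <- random_coefficients(sysu, c(elec = 3, ind = 4, disp = 0),
                                seed = 86)
  datu <- synthetic_dataset(truthu, 800, c(12, 40), noise_sigma = 0,
                            seed = 86)
  fitu <- lr_fit(datu, sysu, plan = lr_plan(c(elec = 3, ind = 0, disp = 0),
                                            seed = 86))
  expect_gt(abs(skewness(residuals(fitu))), 0.5)
})

test_that("lumped electrostatic products are gauge invariants of the fit", {
  sys <- make_cinfv_pair()
  truth <- random_coefficients(sys, c(elec = 5, ind = 0, disp = 0), seed = 84)
  dat <- synthetic_dataset(truth, 300, c(15, 60), noise_sigma = 0, seed = 84)
  fit <- lr_fit(dat, sys, plan = lr_plan(c(elec = 5, ind = 0, disp = 0),
                                         seed = 84))
  qa_t <- multipole_components(truth, "A"); qb_t <- multipole_components(truth, "B")
  qa_f <- multipole_components(fit, "A"); qb_f <- multipole_components(fit, "B")
  for (la in 1:4) for (lb in 1:4) {
    if (la + lb + 1 > 5) next
    pt <- outer(qa_t[[as.character(la)]], qb_t[[as.character(lb)]])
    pf <- outer(qa_f[[as.character(la)]], qb_f[[as.character(lb)]])
    expect_lt(max(abs(pt - pf)) / max(abs(pt), 1e-12), 1e-6)
  }
})

test_that("lr_fit S3 interface: print, summary, coef, predict, residuals, simulate", {
  sys <- make_cinfv_pair()
  truth <- random_coefficients(sys, c(elec = 4, ind = 0, disp = 0), seed = 85)
  dat <- synthetic_dataset(truth, 150, c(15, 60), noise_sigma = 1e-8,
                           seed = 85)
  fit <- lr_fit(dat, sys, plan = lr_plan(c(elec = 4, ind = 0, disp = 0),
                                         seed = 85))
  expect_output(print(fit), "lr_fit")
  expect_output(print(summary(fit)), "Stage history")
  expect_named(coef(fit))
  expect_equal(fitted(fit), dat$energy + residuals(fit))
  expect_equal(predict(fit), fitted(fit))
  expect_equal(predict(fit, dat$geoms[1:5, ]), fitted(fit)[1:5],
               tolerance = 1e-12)
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sim), c(150L, 2L))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
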