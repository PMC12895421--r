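# Dataset files, unit conversion, the LeRoy filter, coefficient
# serialization and evaluator export.

test_that("unit conversions are exact inverses", {
  for (x in c(0.1, 1, 17.3)) {
    expect_equal(longrangefit:::.length_from_bohr(
      longrangefit:::.length_to_bohr(x, "angstrom"), "angstrom"), x,
      tolerance = 1e-14)
    expect_equal(longrangefit:::.energy_from_hartree(
      longrangefit:::.energy_to_hartree(x, "cm1"), "cm1"), x,
      tolerance = 1e-14)
    expect_equal(longrangefit:::.angle_from_rad(
      longrangefit:::.angle_to_rad(x, "deg"), "deg"), x, tolerance = 1e-14)
  }
})

test_that("a 4D dataset file reads with the documented units and column order", {
  sys <- lr_system(lr_molecule("CO", "Cinfv"), lr_molecule("H2", "Dinfh"))
  f <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("# comment line", "10.0 0.0 0.0 0.0 -12.5"), f)
  d <- read_dataset(f, sys)
  expect_equal(nrow(d$geoms), 1)
  expect_equal(d$geoms$R, 10 / lr_constants$bohr_angstrom, tolerance = 1e-12)
  expect_equal(d$geoms$R, 18.8973, tolerance = 1e-4)
  expect_equal(d$geoms$alpha, 0)
  expect_equal(d$energy, -12.5 / lr_constants$hartree_cm1, tolerance = 1e-15)
})

test_that("dimensionality classes fix the expected columns", {
  # linear + atom is 2D: columns R, beta_A, E
  sys2 <- lr_system(lr_molecule("CO", "Cinfv"), lr_molecule("He", "atom"))
  expect_equal(free_angles(sys2), "beta_A")
  expect_equal(system_dimension(sys2), 2L)
  f <- withr::local_tempfile()
  writeLines("12.0 90.0 -1.0", f)
  d <- read_dataset(f, sys2)
  expect_equal(d$geoms$beta_A, pi / 2, tolerance = 1e-12)
  # wrong column count names the expected dimensionality
  writeLines("12.0 0.0 0.0 -1.0", f)
  expect_error(read_dataset(f, sys2), "3 columns")
  # non-numeric field reports the line number
  writeLines(c("12.0 10.0 -1.0", "13.0 oops -1.1"), f)
  expect_error(read_dataset(f, sys2), "line 2")
  # empty file warns and returns an empty dataset
  writeLines("# only a comment", f)
  expect_warning(d0 <- read_dataset(f, sys2), "empty")
  expect_equal(length(d0), 0)
})

test_that("dataset write/read round-trips the generator output exactly", {
  sys <- lr_system(lr_molecule("M1", "Cinfv"), lr_molecule("M2", "Cinfv"))
  truth <- random_coefficients(sys, c(elec = 4, ind = 0, disp = 0), seed = 91)
  dat <- synthetic_dataset(truth, 40, c(15, 50), noise_sigma = 1e-7,
                           seed = 91)
  f <- withr::local_tempfile()
  write_dataset(dat, f, sys)  # native units: bohr / rad / hartree
  back <- read_dataset(f, sys, units = dat$units)
  expect_equal(back$geoms$R, dat$geoms$R, tolerance = 1e-14)
  expect_equal(back$geoms$beta_A, dat$geoms$beta_A, tolerance = 1e-14)
  expect_equal(back$energy, dat$energy, tolerance = 1e-14)
})

test_that("LeRoy filter: inclusive boundary, rod geometry, monotonicity", {
  ang <- lr_constants$bohr_angstrom
  # two single-site fragments: boundary equality admits
  a1 <- lr_molecule("a", "atom", sites = list(atom_site(1, c(0, 0, 0))))
  a2 <- lr_molecule("b", "atom", sites = list(atom_site(1, c(0, 0, 0))))
  sys0 <- lr_system(a1, a2)
  d0 <- lr_dataset(data.frame(R = 5), 0,
                   units = list(distance = "bohr", angle = "rad",
                                energy = "hartree"))
  expect_true(leroy_filter(d0, sys0, d_min = 5))
  expect_false(leroy_filter(d0, sys0, d_min = 5 + 1e-9))
  # an 11-site rod of length 12 Angstrom probed by an atom at R = 8:
  # end-on the closest pair sits at 2, side-on at 8
  zs <- seq(-6, 6, length.out = 11) / ang   # bohr
  rod <- lr_molecule("rod", "Dinfh",
                     sites = lapply(zs, function(z) atom_site(0.1, c(0, 0, z))))
  probe <- lr_molecule("p", "atom", sites = list(atom_site(1, c(0, 0, 0))))
  sys <- lr_system(rod, probe)
  dd <- lr_dataset(data.frame(R = rep(8 / ang, 2), beta_A = c(0, pi / 2)),
                   c(0, 0), units = list(distance = "bohr", angle = "rad",
                                         energy = "hartree"))
  mask <- leroy_filter(dd, sys, d_min = 6 / ang)
  expect_false(mask[1])  # end-on: closest pair 2 Angstrom
  expect_true(mask[2])   # side-on: closest pair 8 Angstrom
  expect_equal(attr(mask, "min_dist")[1], 2 / ang, tolerance = 1e-10)
  expect_equal(attr(mask, "min_dist")[2], 8 / ang, tolerance = 1e-10)
  # monotonicity: raising d_min never admits a previously excluded point
  set.seed(92)
  dr <- lr_dataset(data.frame(R = runif(50, 6, 40) / ang,
                              beta_A = acos(runif(50, -1, 1))),
                   numeric(50), units = list(distance = "bohr",
                                             angle = "rad",
                                             energy = "hartree"))
  prev <- rep(TRUE, 50)
  for (dmin in c(0, 2, 5, 9, 14) / ang) {
    m <- leroy_filter(dr, sys, dmin)
    expect_true(all(m <= prev))
    prev <- m
  }
  expect_true(all(leroy_filter(dr, sys, 0)))
  expect_false(any(leroy_filter(dr, sys, 1e6)))
})

test_that("coefficient files round-trip bitwise and validate on read", {
  sys <- lr_system(lr_molecule("CF+", "Cinfv", charge = 1),
                   lr_molecule("H2", "Dinfh"))
  truth <- random_coefficients(sys, 6, seed = 93)
  f <- withr::local_tempfile(fileext = ".json")
  write_coefficients(truth, f)
  back <- read_coefficients(f)
  expect_identical(back$theta, truth$theta)
  # deterministic output: two writes are byte-identical
  f2 <- withr::local_tempfile(fileext = ".json")
  write_coefficients(truth, f2)
  expect_identical(readLines(f), readLines(f2))
  # dropping a required coefficient names it in the error
  doc <- jsonlite::read_json(f)
  doc$coefficients[["QB.2.1"]] <- NULL
  jsonlite::write_json(doc, f2, auto_unbox = TRUE, digits = I(17))
  expect_error(read_coefficients(f2), "QB.2.1")
  # wrong format version
  doc2 <- jsonlite::read_json(f)
  doc2$format <- "somebody-elses-format"
  jsonlite::write_json(doc2, f2, auto_unbox = TRUE, digits = I(17))
  expect_error(read_coefficients(f2), "format")
})

test_that("flattened term lists reproduce the model energy exactly", {
  co <- lr_molecule("CO", "Cinfv")
  sys <- lr_system(co, co, "identical")
  truth <- random_coefficients(sys, 6, seed = 94)
  flat <- flatten_model(truth)
  set.seed(94)
  for (kk in 1:10) {
    gm <- rand_geometry()
    expect_equal(evaluate_flat(flat, gm), evaluate_energy(truth, gm),
                 tolerance = 1e-12)
  }
  # zero interaction coefficients: evaluator returns the asymptote
  ex0 <- lr_expansion(sys, c(elec = 3, ind = 0, disp = 0))
  cf0 <- lr_coefficients(ex0, c(E_asym = 0.5))
  flat0 <- flatten_model(cf0)
  expect_equal(nrow(flat0$singles), 0)
  expect_equal(evaluate_flat(flat0, dimer_geometry(12, 0.3, 1, 2)), 0.5)
  # charge-charge only reduces to E_asym + qq/R
  ion1 <- lr_molecule("A+", "atom", charge = 1)
  ion2 <- lr_molecule("B+", "atom", charge = 3)
  exq <- lr_expansion(lr_system(ion1, ion2), c(elec = 1, ind = 0, disp = 0))
  flq <- flatten_model(lr_coefficients(exq, c(E_asym = 0.1)))
  expect_equal(nrow(flq$singles), 1)
  expect_equal(evaluate_flat(flq, dimer_geometry(10)), 0.1 + 3 / 10)
})

test_that("the exported Fortran evaluator compiles and matches to near machine precision", {
  sys <- lr_system(lr_molecule("CF+", "Cinfv", charge = 1),
                   lr_molecule("H2", "Dinfh"))
  truth <- random_coefficients(sys, 6, seed = 95)
  dir <- withr::local_tempdir()
  paths <- export_evaluator(truth, file.path(dir, "pot"))
  expect_true(file.exists(paths[["terms"]]))
  expect_true(file.exists(paths[["source"]]))
  # the JSON artifact carries the format tag and the system declaration
  doc <- jsonlite::read_json(paths[["terms"]])
  expect_match(doc$format, "evaluator")
  expect_equal(doc$system$molA$charge, 1)
  writeLines(c(
    "program test",
    "  use lr_potential",
    "  implicit none",
    "  integer, parameter :: dp = kind(1.0d0)",
    "  integer :: i",
    "  real(dp) :: r",
    "  do i = 1, 6",
    "    r = 8.0_dp + 4 * i",
    "    write(*, \"(es24.16)\") lr_energy(r, 0.31_dp * i, 0.2_dp * i, &",
    "      0.15_dp * i, 0.0_dp, 0.0_dp)",
    "  end do",
    "end program"), file.path(dir, "main.f90"))
  status <- system2("gfortran",
                    c("-O2", shQuote(paths[["source"]]),
                      shQuote(file.path(dir, "main.f90")),
                      "-o", shQuote(file.path(dir, "test_pot")),
                      "-J", shQuote(dir)),
                    stdout = FALSE, stderr = FALSE)
  expect_equal(status, 0L)
  out <- system2(file.path(dir, "test_pot"), stdout = TRUE)
  fvals <- as.numeric(out)
  rvals <- vapply(1:6, function(i)
    evaluate_energy(truth, dimer_geometry(8 + 4 * i, 0.31 * i, 0.2 * i,
                                          0.15 * i)), numeric(1))
  expect_equal(fvals, rvals, tolerance = 1e-12)
})

test_that("the CLI covers the terms -> synth -> fit -> eval -> export workflow", {
  dir <- withr::local_tempdir()
  owd <- setwd(dir); on.exit(setwd(owd), add = TRUE)
  # terms: first active electrostatic order 3 for an ion + homonuclear pair
  out <- capture.output(
    st <- lr_cli(c("terms", "--groupA", "Cinfv", "--chargeA", "1",
                   "--groupB", "Dinfh", "--interaction", "electrostatic")))
  expect_identical(st, 0L)
  first_active <- grep("order\\s+\\d+\\s+Q", out, value = TRUE)[1]
  expect_match(first_active, "order +3")
  # synth writes a dataset plus ground truth
  expect_identical(suppressMessages(
    lr_cli(c("synth", "--groupA", "Cinfv", "--chargeA", "1",
             "--groupB", "Dinfh", "--caps", "4", "--n", "200",
             "--rmin", "8", "--rmax", "30", "--seed", "3",
             "--out", "demo"))), 0L)
  expect_true(file.exists("demo.dat"))
  expect_true(file.exists("demo_truth.json"))
  # fit reproduces a non-increasing stage RMSE table
  fit_out <- capture.output(st2 <- suppressMessages(
    lr_cli(c("fit", "--groupA", "Cinfv", "--chargeA", "1",
             "--groupB", "Dinfh", "--data", "demo.dat", "--caps", "4",
             "--seed", "3", "--out", "demofit"))))
  expect_identical(st2, 0L)
  stages <- utils::read.csv("demofit_stages.csv")
  expect_true(all(diff(stages$rmse) < 1e-12))
  # eval at a training geometry reproduces the fitted model
  cf <- read_coefficients("demofit_coefficients.json")
  grid <- utils::read.table("demo.dat")[1:3, ]
  utils::write.table(grid[, 1:4], "grid.dat", row.names = FALSE,
                     col.names = FALSE)
  expect_identical(suppressMessages(
    lr_cli(c("eval", "--coeffs", "demofit_coefficients.json",
             "--data", "grid.dat", "--out", "grid_eval.csv"))), 0L)
  ev <- utils::read.csv("grid_eval.csv")
  sys <- cf$expansion$sys
  d3 <- read_dataset("demo.dat", sys)
  expect_equal(ev$E * 1 / lr_constants$hartree_cm1,
               evaluate_energy(cf, d3$geoms[1:3, ]), tolerance = 1e-10)
  # export writes both artifacts
  expect_identical(suppressMessages(
    lr_cli(c("export", "--coeffs", "demofit_coefficients.json",
             "--out", "pot"))), 0L)
  expect_true(file.exists("pot.json") && file.exists("pot.f90"))
  # unknown flags give a usage error status
  expect_identical(suppressMessages(lr_cli(c("fit", "--nonsense"))), 1L)
  expect_identical(suppressMessages(lr_cli(character())), 2L)
})
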