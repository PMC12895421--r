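# shared fixture builders

# random small point-charge fragment in the molecule-fixed frame
rand_fragment <- function(n, seed, spread = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    atom_site(stats::runif(1, -1, 1), stats::runif(3, -spread, spread)))
}

rand_geometry <- function(Rmin = 10, Rmax = 40) {
  dimer_geometry(stats::runif(1, Rmin, Rmax),
                 stats::runif(1, 0, 2 * pi), stats::runif(1, 0, pi),
                 stats::runif(1, 0, pi), stats::runif(1, 0, 2 * pi),
                 stats::runif(1, 0, 2 * pi))
}

# coefficient set carrying the exact multipoles of two point-charge
# fragments, electrostatics only, through order cap
charge_model_coeffs <- function(sitesA, sitesB, cap) {
  qa <- multipoles_of_point_charges(sitesA, cap - 1L)
  qb <- multipoles_of_point_charges(sitesB, cap - 1L)
  molA <- lr_molecule("fragA", "C1", charge = qa[[1]], sites = sitesA)
  molB <- lr_molecule("fragB", "C1", charge = qb[[1]], sites = sitesB)
  sys <- lr_system(molA, molB)
  ex <- lr_expansion(sys, c(elec = cap, ind = 0, disp = 0))
  th <- stats::setNames(numeric(length(ex$names)), ex$names)
  for (l in ex$qA_ranks)
    th[sprintf("QA.%d.%d", l, seq_len(2 * l + 1))] <-
      as.numeric(t(ex$basisA[[as.character(l)]]) %*% qa[[l + 1L]])
  for (l in ex$qB_ranks)
    th[sprintf("QB.%d.%d", l, seq_len(2 * l + 1))] <-
      as.numeric(t(ex$basisB[[as.character(l)]]) %*% qb[[l + 1L]])
  lr_coefficients(ex, th)
}

# one representative molecule per point-group row (axis orders chosen
# small), used to sweep all symmetry families
table2_molecules <- function() {
  list(
    lr_molecule("linA", "Cinfv"), lr_molecule("linB", "Dinfh"),
    lr_molecule("c1", "C1"), lr_molecule("cs", "Cs"),
    lr_molecule("ci", "Ci"), lr_molecule("c3", "Cn", n = 3),
    lr_molecule("c3h", "Cnh", n = 3), lr_molecule("c3v", "Cnv", n = 3),
    lr_molecule("d3", "Dn", n = 3), lr_molecule("d4h", "Dnh", n = 4),
    lr_molecule("d3d", "Dnd", n = 3), lr_molecule("s4", "S2n", n = 2),
    lr_molecule("t", "T"), lr_molecule("th", "Th"), lr_molecule("td", "Td"),
    lr_molecule("o", "O"), lr_molecule("oh", "Oh"),
    lr_molecule("i", "I"), lr_molecule("ih", "Ih"),
    lr_molecule("ne", "atom"))
}

skewness <- function(x) {
  m <- mean(x); s <- stats::sd(x)
  mean((x - m)^3) / s^3
}
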