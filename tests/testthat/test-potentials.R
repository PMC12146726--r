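forms <- c("lennard_jones", "double_exponential", "buckingham", "lj_softcore")

test_that("pair potentials satisfy their algebraic identities", {
  lj <- form_params("lennard_jones")
  expect_equal(pair_energy("lennard_jones", lj$sigma, lj), 0)
  rm <- 2^(1 / 6) * lj$sigma
  expect_equal(pair_energy("lennard_jones", rm, lj), -lj$epsilon)
  expect_equal(pair_force_scalar("lennard_jones", rm, lj), 0, tolerance = 1e-12)
  de <- form_params("double_exponential")
  expect_equal(pair_energy("double_exponential", rm, de), -de$epsilon)
  expect_equal(pair_force_scalar("double_exponential", rm, de), 0,
               tolerance = 1e-9 * de$epsilon)
  # soft core reduces to plain LJ when alpha * lambda = 0, at every r
  r <- seq(0.2, 0.9, by = 0.01)
  for (p0 in list(list(alpha = 0, lambda = 0.7), list(alpha = 0.3, lambda = 0))) {
    sc <- c(form_params("lennard_jones"), p0)
    expect_equal(pair_energy("lj_softcore", r, sc),
                 pair_energy("lennard_jones", r, lj), tolerance = 1e-12)
  }
  # soft core is finite at r = 0
  sc <- form_params("lj_softcore")
  expect_true(is.finite(pair_energy("lj_softcore", 0, sc)))
  # Buckingham value against a direct scalar evaluation
  bp <- form_params("buckingham")
  expect_equal(pair_energy("buckingham", 0.34, bp),
               359999 * exp(-37.795 * 0.34) - 0.002343 / 0.34^6,
               tolerance = 1e-12)
  expect_error(pair_energy("lennard_jones", -0.1, lj), "positive")
  expect_error(pair_energy("buckingham", 0, bp), "positive")
})

test_that("scalar force and parameter gradients match finite differences", {
  h <- 1e-7
  set.seed(21)
  for (form in forms) {
    p <- form_params(form)
    rs <- runif(50, 0.26, 0.6)
    fd <- -(pair_energy(form, rs + h, p) - pair_energy(form, rs - h, p)) / (2 * h)
    expect_lt(rel_err(pair_force_scalar(form, rs, p), fd, floor = 1e-3), 1e-6)
    gg <- pair_param_grad(form, rs, p)
    for (nm in names(p)) {
      pp <- p; pm <- p
      hh <- 1e-6 * abs(p[[nm]])
      pp[[nm]] <- p[[nm]] + hh; pm[[nm]] <- p[[nm]] - hh
      fdp <- (pair_energy(form, rs, pp) - pair_energy(form, rs, pm)) / (2 * hh)
      expect_lt(rel_err(gg[[nm]], fdp, floor = 1e-6), 1e-5)
    }
  }
  # closed forms: LJ dV/deps = V/eps; Buckingham linear coefficients
  lj <- form_params("lennard_jones")
  r <- c(0.3, 0.35, 0.5)
  expect_equal(pair_param_grad("lennard_jones", r, lj)$epsilon,
               pair_energy("lennard_jones", r, lj) / lj$epsilon)
  bp <- form_params("buckingham")
  expect_equal(pair_param_grad("buckingham", r, bp)$A, exp(-bp$B * r))
  expect_equal(pair_param_grad("buckingham", r, bp)$C, -r^-6)
})

test_that("reaction-field electrostatics behave at the limits", {
  expect_equal(coulomb_rf_energy_force(0, 0.5, 0.3, 1)$energy, 0)
  expect_equal(coulomb_rf_energy_force(0.5, 0.5, 1.2, 1)$energy, 0)
  # infinite solvent dielectric: k_rf -> 1/(2 rc^3)
  rc <- 0.9; r <- 0.4
  e <- coulomb_rf_energy_force(0.3, -0.4, r, rc, Inf)
  krf <- 1 / (2 * rc^3)
  expect_equal(e$energy,
               138.935458 * 0.3 * -0.4 * (1 / r + krf * r^2 - (1 / rc + krf * rc^2)),
               tolerance = 1e-12)
  # potential is zero at the cutoff (shifted form)
  expect_equal(coulomb_rf_energy_force(0.3, -0.4, rc, rc, 78.5)$energy, 0,
               tolerance = 1e-12)
  set.seed(3)
  rs <- runif(20, 0.15, 0.85)
  h <- 1e-7
  fd <- -(coulomb_rf_energy_force(0.3, -0.4, rs + h, rc, 78.5)$energy -
          coulomb_rf_energy_force(0.3, -0.4, rs - h, rc, 78.5)$energy) / (2 * h)
  expect_lt(rel_err(coulomb_rf_energy_force(0.3, -0.4, rs, rc, 78.5)$force, fd), 1e-6)
})

test_that("bonded terms give the closed-form energies and exact forces", {
  # stretched O-H bond: V = k (0.01)^2 / 2
  st <- system_state(rbind(c(0.5, 0.5, 0.5), c(0.5 + 0.09572 + 0.01, 0.5, 0.5)),
                     matrix(0, 2, 3), c(16, 1), c(3, 3, 3))
  top <- topology(c("OW", "HW"), bonds = data.frame(i = 1, j = 2, type = "OH"),
                  molecules = list(1:2))
  ff <- tip3p_force_field()
  be <- bonded_energy_forces(st, top, ff)
  expect_equal(be$potential_energy, 462750 * 1e-4 / 2, tolerance = 1e-10)
  expect_equal(be$potential_energy, 23.1375, tolerance = 1e-10)
  # water at its equilibrium geometry: zero bonded energy and forces
  w1 <- generate_water_box(1, box = 1, seed = 1)
  be0 <- bonded_energy_forces(w1$state, w1$top, ff)
  expect_equal(be0$potential_energy, 0, tolerance = 1e-18)
  expect_equal(max(abs(be0$forces)), 0, tolerance = 1e-9)
  # distorted water: forces match finite differences of the bonded energy
  set.seed(14)
  stw <- w1$state; stw$x <- stw$x + matrix(rnorm(9, sd = 0.004), 3, 3)
  bf <- bonded_energy_forces(stw, w1$top, ff)
  h <- 1e-7
  for (a in 1:3) for (k in 1:3) {
    sp <- stw; sp$x[a, k] <- sp$x[a, k] + h
    sm <- stw; sm$x[a, k] <- sm$x[a, k] - h
    fd <- -(bonded_energy_forces(sp, w1$top, ff)$potential_energy -
            bonded_energy_forces(sm, w1$top, ff)$potential_energy) / (2 * h)
    expect_equal(bf$forces[a, k], fd, tolerance = 1e-5 * max(1, abs(fd)))
  }
})

test_that("total forces match an all-pairs reference and conserve momentum", {
  lj <- form_params("lennard_jones")
  rm <- 2^(1 / 6) * lj$sigma
  st2 <- system_state(rbind(c(1, 1, 1), c(1 + rm, 1, 1)), matrix(0, 2, 3),
                      c(40, 40), c(4, 4, 4))
  top2 <- topology(c("AR", "AR"))
  ff2 <- lj_fluid_force_field(cutoff = 1)
  nl2 <- build_neighbor_list(st2, top2, 1, 0.2)
  expect_equal(max(abs(total_forces(st2, top2, ff2, nl2)$forces)), 0,
               tolerance = 1e-10)

  fx <- fix_lj64()
  nl <- build_neighbor_list(fx$state, fx$top, fx$ff$cutoff)
  out <- total_forces(fx$state, fx$top, fx$ff, nl)
  expect_lt(max(abs(colSums(out$forces))), 1e-8 * max(abs(out$forces)))
  # O(N^2) brute-force reference (no neighbour list)
  n <- nrow(fx$state$x)
  Fref <- matrix(0, n, 3); Eref <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- minimum_image(fx$state$x[j, ], fx$state$x[i, ], fx$state$box)
    r <- sqrt(sum(d^2))
    if (r < fx$ff$cutoff) {
      Eref <- Eref + pair_energy("lennard_jones", r, lj)
      fs <- pair_force_scalar("lennard_jones", r, lj)
      Fref[i, ] <- Fref[i, ] + fs * d / r
      Fref[j, ] <- Fref[j, ] - fs * d / r
    }
  }
  expect_lt(rel_err(out$potential_energy, Eref), 1e-10)
  expect_lt(max(abs(out$forces - Fref)) / max(abs(Fref)), 1e-10)
  # overlapping atoms are reported by pair
  sto <- fx$state; sto$x[2, ] <- sto$x[1, ] + 1e-8
  nlo <- build_neighbor_list(sto, fx$top, fx$ff$cutoff)
  expect_error(total_forces(sto, fx$top, fx$ff, nlo), "overlapping atoms 1 and 2")
})

test_that("force contractions agree with finite differences on fluids and water", {
  for (sys in list(fix_lj16(), fix_water27())) {
    st <- sys$state
    nl <- build_neighbor_list(st, sys$top, sys$ff$cutoff, 0.1)
    set.seed(31)
    w <- matrix(rnorm(3 * nrow(st$x)), nrow(st$x), 3)
    expect_equal(forces_coord_vjp(st, sys$top, sys$ff, nl, 0 * w), 0 * w)
    expect_equal(unname(forces_param_vjp(st, sys$top, sys$ff, nl, 0 * w)),
                 numeric(length(trainable_names(sys$ff))))
    expect_error(forces_coord_vjp(st, sys$top, sys$ff, nl, w[-1, ]), "shape")
    h <- 1e-6
    sp <- st; sp$x <- st$x + h * w / st$m
    sm <- st; sm$x <- st$x - h * w / st$m
    fd <- (total_forces(sp, sys$top, sys$ff, nl)$forces -
           total_forces(sm, sys$top, sys$ff, nl)$forces) / (2 * h)
    u <- forces_coord_vjp(st, sys$top, sys$ff, nl, w)
    expect_lt(max(abs(u - fd)) / max(abs(u)), 1e-5)
    pv <- forces_param_vjp(st, sys$top, sys$ff, nl, w)
    for (nm in names(pv)) {
      v0 <- ff_get(sys$ff, nm); hh <- 1e-6 * max(abs(v0), 1e-3)
      fp <- total_forces(st, sys$top, ff_set(sys$ff, nm, v0 + hh), nl)$forces
      fm <- total_forces(st, sys$top, ff_set(sys$ff, nm, v0 - hh), nl)$forces
      fdv <- sum((w / st$m) * (fp - fm) / (2 * hh))
      expect_equal(pv[[nm]], fdv, tolerance = 1e-5 * max(abs(fdv), 1e-6))
    }
  }
  # linear (tether) force: d/dx (w . a) = -k w / m exactly
  ho <- generate_harmonic_oscillator(k = 37.5, n_atoms = 2, seed = 6)
  nl <- build_neighbor_list(ho$state, ho$top, ho$ff$cutoff)
  w <- matrix(rnorm(6), 2, 3)
  expect_equal(forces_coord_vjp(ho$state, ho$top, ho$ff, nl, w),
               -37.5 * w / ho$state$m, tolerance = 1e-12)
})

test_that("energy parameter gradients are exact and vanish for absent terms", {
  fx <- fix_lj16()
  nl <- build_neighbor_list(fx$state, fx$top, fx$ff$cutoff, 0.1)
  eg <- energy_param_grad(fx$state, fx$top, fx$ff, nl)
  out <- total_forces(fx$state, fx$top, fx$ff, nl)
  # pure LJ: dU/deps = U/eps
  expect_equal(eg[["epsilon_AR"]],
               out$potential_energy / ff_get(fx$ff, "epsilon_AR"),
               tolerance = 1e-10)
  for (nm in names(eg)) {
    v0 <- ff_get(fx$ff, nm); h <- 1e-6 * abs(v0)
    ep <- total_forces(fx$state, fx$top, ff_set(fx$ff, nm, v0 + h), nl)$potential_energy
    em <- total_forces(fx$state, fx$top, ff_set(fx$ff, nm, v0 - h), nl)$potential_energy
    expect_equal(eg[[nm]], (ep - em) / (2 * h), tolerance = 1e-6 * max(abs(eg[[nm]]), 1e-8))
  }
  # a trainable parameter whose term is absent from the system contributes zero
  ents <- rbind(fx$ff$entries,
                data.frame(name = "bond_ZZ_k", value = 100, unit = "",
                           trainable = TRUE, starting_value = 100))
  ff2 <- force_field(ents, "lennard_jones", cutoff = fx$ff$cutoff)
  expect_equal(energy_param_grad(fx$state, fx$top, ff2, nl)[["bond_ZZ_k"]], 0)
})
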