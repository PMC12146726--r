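# Synthetic system generators. These define the study conditions: the water
# box defaults to 895 molecules in a 3 nm cube (2685 atoms) and the gas box
# to 10 O2 in 885 waters (2675 atoms); tests and examples pass smaller sizes.

.boltzmann_velocities <- function(masses, temperature) {
  matrix(stats::rnorm(3 * length(masses)), length(masses), 3) *
    sqrt(kB_MD * temperature / masses)
}

.random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Generate a Lennard-Jones fluid
#'
#' Atoms on a jittered cubic lattice at the requested reduced density
#' `rho* = N sigma^3 / V` with Boltzmann velocities. Default: 64 argon-mass
#' atoms at reduced density 0.5, small enough that full gradient test suites
#' run in minutes on one CPU.
#'
#' @param n atoms.
#' @param reduced_density dimensionless `N sigma^3 / V`.
#' @param sigma,epsilon LJ parameters (nm, kJ/mol).
#' @param mass g/mol.
#' @param temperature K.
#' @param cutoff nonbonded cutoff (nm).
#' @param seed RNG seed (deterministic output).
#' @return list with `state`, `top`, `ff`.
#' @export
generate_lj_fluid <- function(n = 64, reduced_density = 0.5, sigma = 0.315,
                              epsilon = 0.636, mass = 39.948,
                              temperature = 120, cutoff = 0.6, seed = 1) {
  set.seed(seed)
  box_l <- (n * sigma^3 / reduced_density)^(1 / 3)
  nc <- ceiling(n^(1 / 3))
  sp <- box_l / nc
  sites <- as.matrix(expand.grid(0:(nc - 1), 0:(nc - 1), 0:(nc - 1)))[seq_len(n), ]
  x <- (sites + 0.5) * sp + matrix(stats::rnorm(3 * n, sd = 0.05 * sp), n, 3)
  m <- rep(mass, n)
  top <- topology(rep("AR", n))
  state <- system_state(x, .boltzmann_velocities(m, temperature), m, rep(box_l, 3))
  list(state = state, top = top,
       ff = lj_fluid_force_field(sigma, epsilon, cutoff = cutoff))
}

# shared molecular-box builder: specs is a list of lists with fields
# kind ("water" or "o2"), placed on a jittered lattice with random rotation
.build_molecular_box <- function(specs, box, temperature, ff_charge = -0.834,
                                 oh = 0.09572, hoh = 1.824, oo = 0.121) {
  nmol <- length(specs)
  nc <- ceiling(nmol^(1 / 3))
  sp <- box / nc
  if (sp < 0.26) stop(sprintf("box overfilled: %d molecules on a %.3g nm lattice (%.3f nm spacing)",
                              nmol, box, sp))
  sites <- (as.matrix(expand.grid(0:(nc - 1), 0:(nc - 1), 0:(nc - 1))) + 0.5) * sp
  sites <- sites[sample.int(nrow(sites), nmol), , drop = FALSE] +
    matrix(stats::rnorm(3 * nmol, sd = 0.03 * sp), nmol, 3)
  xs <- list(); types <- character(0); masses <- numeric(0); coeff <- numeric(0)
  bonds <- list(); angles <- list(); mols <- list(); tagged <- list()
  at <- 0L
  half <- hoh / 2
  local_w <- rbind(c(0, 0, 0),
                   oh * c(sin(half), cos(half), 0),
                   oh * c(-sin(half), cos(half), 0))
  local_o2 <- rbind(c(-oo / 2, 0, 0), c(oo / 2, 0, 0))
  for (mi in seq_len(nmol)) {
    R <- .random_rotation()
    if (specs[[mi]]$kind == "water") {
      xs[[mi]] <- sweep(local_w %*% t(R), 2, sites[mi, ], "+")
      types <- c(types, "OW", "HW", "HW")
      masses <- c(masses, 15.9994, 1.008, 1.008)
      coeff <- c(coeff, 1, -0.5, -0.5)
      bonds[[length(bonds) + 1L]] <- data.frame(i = at + 1L, j = at + 2L, type = "OH")
      bonds[[length(bonds) + 1L]] <- data.frame(i = at + 1L, j = at + 3L, type = "OH")
      angles[[length(angles) + 1L]] <- data.frame(i = at + 2L, j = at + 1L, k = at + 3L,
                                                  type = "HOH")
      mols[[mi]] <- at + 1:3
      at <- at + 3L
    } else {
      xs[[mi]] <- sweep(local_o2 %*% t(R), 2, sites[mi, ], "+")
      types <- c(types, "OG", "OG")
      masses <- c(masses, 15.999, 15.999)
      coeff <- c(coeff, 0, 0)
      bonds[[length(bonds) + 1L]] <- data.frame(i = at + 1L, j = at + 2L, type = "OO")
      mols[[mi]] <- at + 1:2
      tagged[[length(tagged) + 1L]] <- at + 1:2
      at <- at + 2L
    }
  }
  x <- do.call(rbind, xs)
  top <- topology(types, charges = coeff * ff_charge,
                  bonds = do.call(rbind, bonds),
                  angles = if (length(angles)) do.call(rbind, angles) else NULL,
                  molecules = mols, charge_entry = "charge_OW",
                  charge_coeff = coeff,
                  tagged_molecules = if (length(tagged)) tagged else NULL)
  state <- system_state(x, .boltzmann_velocities(masses, temperature), masses,
                        rep(box, 3))
  list(state = state, top = top)
}

#' Generate a 3-point water box
#'
#' Rigid-geometry TIP3P-like waters (O-H 0.09572 nm, H-O-H 1.824 rad) on a
#' jittered lattice with random orientations and Boltzmann velocities.
#' Default is the training condition: 895 molecules in a 3 nm cube.
#'
#' @param n_molecules molecules.
#' @param box cube edge (nm).
#' @param temperature K.
#' @param seed RNG seed.
#' @return list with `state` and `top`.
#' @export
generate_water_box <- function(n_molecules = 895, box = 3, temperature = 295.15,
                               seed = 1) {
  set.seed(seed)
  specs <- rep(list(list(kind = "water")), n_molecules)
  .build_molecular_box(specs, box, temperature)
}

#' Generate diatomic oxygen molecules in water
#'
#' Default is the gas-diffusion training condition: 10 O2 randomly placed
#' among 885 waters in a 3 nm cube (2675 atoms). Gas molecules are tagged
#' for mean-squared-displacement tracking.
#'
#' @param n_gas O2 molecules.
#' @param n_water water molecules.
#' @param box cube edge (nm).
#' @param temperature K.
#' @param seed RNG seed.
#' @return list with `state` and `top`.
#' @export
generate_gas_in_water <- function(n_gas = 10, n_water = 885, box = 3,
                                  temperature = 295.15, seed = 1) {
  set.seed(seed)
  kinds <- sample(c(rep("o2", n_gas), rep("water", n_water)))
  specs <- lapply(kinds, function(k) list(kind = k))
  .build_molecular_box(specs, box, temperature)
}

#' Generate tethered harmonic oscillators
#'
#' `n_atoms` non-interacting atoms, each harmonically restrained to its own
#' anchor site (`tether_k`, trainable): an ensemble of independent harmonic
#' oscillators with the analytic equilibrium `<(x - x0)^2> = kB T / k` per
#' coordinate. Initial conditions are drawn from the stationary distribution.
#'
#' @param k force constant (kJ mol^-1 nm^-2).
#' @param n_atoms independent oscillators.
#' @param mass g/mol.
#' @param temperature K.
#' @param seed RNG seed.
#' @return list with `state`, `top`, `ff`, `anchors` (n x 3 matrix).
#' @export
generate_harmonic_oscillator <- function(k = 100, n_atoms = 1, mass = 1,
                                         temperature = 300, seed = 1) {
  set.seed(seed)
  anchors <- cbind(5 + 2 * seq_len(n_atoms), 25, 25)
  x <- anchors + matrix(stats::rnorm(3 * n_atoms, sd = sqrt(kB_MD * temperature / k)),
                        n_atoms, 3)
  m <- rep(mass, n_atoms)
  v <- .boltzmann_velocities(m, temperature)
  top <- topology(rep("X", n_atoms),
                  tethers = data.frame(i = seq_len(n_atoms), x0 = anchors[, 1],
                                       y0 = anchors[, 2], z0 = anchors[, 3]))
  ff <- force_field(data.frame(name = "tether_k", value = k, unit = "kJ/mol/nm^2",
                               trainable = TRUE, starting_value = k),
                    "lennard_jones", cutoff = 1)
  list(state = system_state(x, v, m, c(50 + 2 * n_atoms, 50, 50)), top = top,
       ff = ff, anchors = anchors)
}

#' Hard-binned radial distribution function
#'
#' Conventional histogram RDF on the same grid convention as
#' [differentiable_rdf()] (bin centres, ideal-gas shell normalisation).
#' Serves as the non-differentiable oracle for the kernel estimator and as
#' the reference-curve generator.
#'
#' @param state A `system_state`.
#' @param pairs P x 2 pair matrix.
#' @param r_grid uniform bin centres (nm).
#' @return numeric g(r) on the grid.
#' @export
binned_rdf <- function(state, pairs, r_grid) {
  dr <- r_grid[2] - r_grid[1]
  edges <- c(r_grid - dr / 2, max(r_grid) + dr / 2)
  d <- .pair_disp(state$x, pairs[, 1], pairs[, 2], state$box)
  r <- sqrt(rowSums(d^2))
  cnt <- graphics::hist(r[r >= edges[1] & r <= edges[length(edges)]],
                        breaks = edges, plot = FALSE)$counts
  V <- prod(state$box)
  cnt * V / (nrow(pairs) * 4 * pi * r_grid^2 * dr)
}

#' Generate a synthetic reference RDF
#'
#' Runs fixed-seed forward simulations at the supplied ("true") parameters
#' and records the snapshot-averaged RDF, optionally averaged over several
#' independent replicas. Used as the training target in parameter-recovery
#' experiments, replacing experimental curves, so that recovery is
#' well-posed by construction. The default estimator is the same Gaussian
#' kernel as the loss ([differentiable_rdf()]); matching the estimator keeps
#' the self-match loss at the sampling noise floor, with the minimum at the
#' generating parameters. `estimator = "binned"` gives the conventional
#' histogram instead.
#'
#' @param state,top,ff system at the generating parameters.
#' @param cfg An `integrator_config`.
#' @param n_steps production steps.
#' @param snapshot_every snapshot interval (steps).
#' @param r_grid uniform bin centres (nm).
#' @param pair_types length-2 character, e.g. `c("AR", "AR")`.
#' @param seed thermostat seed.
#' @param equilibration_steps steps discarded first.
#' @param n_replicas independent replicas averaged (seeds seed, seed+1, ...).
#' @param estimator "kernel" or "binned".
#' @param kernel_width Gaussian kernel width for the kernel estimator (nm).
#' @return list with `r`, `g`, `pair_types` (an RDF reference).
#' @export
generate_reference_rdf <- function(state, top, ff, cfg, n_steps, snapshot_every,
                                   r_grid, pair_types, seed = 1,
                                   equilibration_steps = 0, n_replicas = 1,
                                   estimator = c("kernel", "binned"),
                                   kernel_width = 0.01) {
  estimator <- match.arg(estimator)
  pairs <- select_pairs(top, pair_types[1], pair_types[2])
  one <- function(sd0) {
    st0 <- state
    if (equilibration_steps > 0) {
      eq <- run_forward(st0, top, ff, cfg, equilibration_steps, base_seed = sd0)
      st0 <- eq$final_state
    }
    snap_steps <- seq(st0$step + snapshot_every, st0$step + n_steps,
                      by = snapshot_every)
    rec <- run_forward(st0, top, ff, cfg, n_steps, base_seed = sd0 + 1000003,
                       snapshot_steps = snap_steps)
    st <- rec$final_state
    rowMeans(vapply(rec$snapshots, function(s) {
      st$x <- s$x
      if (estimator == "kernel")
        differentiable_rdf(st, pairs, r_grid, kernel_width)$g
      else binned_rdf(st, pairs, r_grid)
    }, numeric(length(r_grid))))
  }
  g <- rowMeans(vapply(seed + seq_len(n_replicas) - 1, one,
                       numeric(length(r_grid))))
  list(r = r_grid, g = g, pair_types = pair_types)
}

#' Fit Buckingham starting parameters to a Lennard-Jones curve
#'
#' Relative-error least squares of `A exp(-B r) - C r^-6` against the LJ
#' potential on 200 points over `[r_lo, r_hi]` nm (weights `1/(|V|+1e-3)`).
#' With the TIP3P oxygen parameters this lands near A = 359999 kJ/mol,
#' B = 37.795 nm^-1, C = 0.002343 kJ mol^-1 nm^6.
#'
#' @param sigma,epsilon LJ parameters.
#' @param r_lo,r_hi fit range (nm).
#' @return named numeric `c(A, B, C)`.
#' @export
fit_buckingham_to_lj <- function(sigma = 0.315, epsilon = 0.636,
                                 r_lo = 0.30, r_hi = 0.70) {
  r <- seq(r_lo, r_hi, length.out = 200)
  y <- pair_energy("lennard_jones", r, list(sigma = sigma, epsilon = epsilon))
  w <- 1 / (abs(y) + 1e-3)
  res <- minpack.lm::nls.lm(
    par = c(A = 3e5, B = 35, C = 0.0024),
    fn = function(p) w * (p[1] * exp(-p[2] * r) - p[3] / r^6 - y),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  stats::setNames(res$par, c("A", "B", "C"))
}
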