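# Shared fixtures, built in code and cached for the session.

.fx_cache <- new.env(parent = emptyenv())

.cached <- function(key, builder) {
  if (!exists(key, envir = .fx_cache, inherits = FALSE))
    assign(key, builder(), envir = .fx_cache)
  get(key, envir = .fx_cache, inherits = FALSE)
}

rel_err <- function(a, b, floor = 1e-12) max(abs(a - b) / pmax(abs(b), floor))

# 16-atom LJ fluid in a ~1.1 nm box (cutoff 0.4, skin 0.1 fits the half box)
fix_lj16 <- function() .cached("lj16", function() {
  generate_lj_fluid(n = 16, reduced_density = 0.4, cutoff = 0.4, seed = 3)
})

# 8-atom LJ cluster (interacting, pair distances near the well minimum),
# small enough for the dense unrolled oracle
fix_lj8 <- function() .cached("lj8", function() {
  set.seed(4)
  x <- matrix(0, 8, 3)
  placed <- 1
  x[1, ] <- c(1, 1, 1)
  while (placed < 8) {
    cand <- runif(3, 0.72, 1.38)
    d <- sqrt(rowSums((x[seq_len(placed), , drop = FALSE] -
                       matrix(cand, placed, 3, byrow = TRUE))^2))
    if (all(d > 0.29)) {
      placed <- placed + 1
      x[placed, ] <- cand
    }
  }
  m <- rep(39.948, 8)
  st <- system_state(x, matrix(rnorm(24), 8, 3) *
                       sqrt(0.0083144626 * 120 / 39.948), m, c(2, 2, 2))
  list(state = st, top = topology(rep("AR", 8)),
       ff = lj_fluid_force_field(cutoff = 0.7))
})

fix_lj64 <- function() .cached("lj64", function() generate_lj_fluid(seed = 7))

# 27 waters in a 1.6 nm box, cutoff 0.6
fix_water27 <- function() .cached("water27", function() {
  wb <- generate_water_box(n_molecules = 27, box = 1.6, seed = 2)
  wb$ff <- tip3p_force_field("lennard_jones", cutoff = 0.6)
  wb
})

# three charged diatomics (types QA/QB, charges +-0.4 via trainable charge_QA),
# LJ on both types, harmonic bonds; no angles, so the dense oracle applies
fix_diatomics <- function() .cached("diatomics", function() {
  set.seed(11)
  nmol <- 3
  x <- NULL; mols <- list(); bonds <- list()
  for (k in seq_len(nmol)) {
    c0 <- runif(3, 0.4, 1.6)
    d <- rnorm(3); d <- 0.11 * d / sqrt(sum(d^2))
    x <- rbind(x, rbind(c0 - d / 2, c0 + d / 2))
    mols[[k]] <- (2 * k - 1):(2 * k)
    bonds[[k]] <- data.frame(i = 2 * k - 1, j = 2 * k, type = "QB")
  }
  coeff <- rep(c(1, -1), nmol)
  top <- topology(rep(c("QA", "QB"), nmol), charges = coeff * 0.4,
                  bonds = do.call(rbind, bonds), molecules = mols,
                  charge_entry = "charge_QA", charge_coeff = coeff)
  ents <- data.frame(
    name = c("sigma_QA", "epsilon_QA", "sigma_QB", "epsilon_QB",
             "charge_QA", "bond_QB_r0", "bond_QB_k"),
    value = c(0.30, 0.50, 0.25, 0.30, 0.4, 0.11, 80000),
    unit = "", trainable = TRUE,
    starting_value = c(0.30, 0.50, 0.25, 0.30, 0.4, 0.11, 80000))
  ff <- force_field(ents, "lennard_jones", cutoff = 0.8)
  m <- rep(c(12, 16), nmol)
  st <- system_state(x, matrix(rnorm(6 * nmol, sd = 0.3), 2 * nmol, 3),
                     m, c(2, 2, 2))
  list(state = st, top = top, ff = ff)
})

# single-type fluid force field for each alternative nonbonded form
fluid_ff <- function(form, type = "AR", cutoff = 0.4) {
  ents <- switch(form,
    lennard_jones = data.frame(
      name = paste0(c("sigma_", "epsilon_"), type),
      value = c(0.315, 0.636), starting_value = c(0.315, 0.636)),
    double_exponential = data.frame(
      name = c(paste0(c("sigma_", "epsilon_"), type), "de_alpha", "de_beta"),
      value = c(0.315, 0.636, 16.766, 4.427),
      starting_value = c(0.315, 0.636, 16.766, 4.427)),
    buckingham = data.frame(
      name = paste0("buck_", c("A_", "B_", "C_"), type),
      value = c(359999, 37.795, 0.002343),
      starting_value = c(359999, 37.795, 0.002343)),
    lj_softcore = data.frame(
      name = c(paste0(c("sigma_", "epsilon_"), type), "sc_alpha", "sc_lambda"),
      value = c(0.315, 0.636, 0.1, 0.1),
      starting_value = c(0.315, 0.636, 0.1, 0.1)))
  ents$unit <- ""; ents$trainable <- TRUE
  force_field(ents, form, cutoff = cutoff)
}

# quadratic loss in final positions and velocities with fixed random weights;
# returns the unrolled-oracle loss_fn and a matching loss_seed builder
make_quad_loss <- function(n_atoms, seed = 1, with_velocity = TRUE) {
  set.seed(seed)
  cx <- matrix(rnorm(3 * n_atoms), n_atoms, 3)
  cv <- if (with_velocity) matrix(rnorm(3 * n_atoms), n_atoms, 3) else
    matrix(0, n_atoms, 3)
  list(
    loss_fn = function(x, v) list(value = sum(cx * x^2) + sum(cv * v^2),
                                  gx = 2 * cx * x, gv = 2 * cv * v),
    seed_at = function(snap) loss_seed(snap$step, 2 * cx * snap$x, 2 * cv * snap$v),
    value_of = function(snap) sum(cx * snap$x^2) + sum(cv * snap$v^2))
}

# default pair parameter sets used in the pair-potential tests
form_params <- function(form) {
  switch(form,
    lennard_jones = list(sigma = 0.315, epsilon = 0.636),
    double_exponential = list(sigma = 0.315, epsilon = 0.636,
                              alpha = 16.766, beta = 4.427),
    buckingham = list(A = 359999, B = 37.795, C = 0.002343),
    lj_softcore = list(sigma = 0.315, epsilon = 0.636, alpha = 0.1, lambda = 0.1))
}
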