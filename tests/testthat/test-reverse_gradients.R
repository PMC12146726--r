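test_that("accumulator initialisation reduces correctly at gamma = 0", {
  cfg <- integrator_config(0.001, gamma = 0)
  gx <- matrix(rnorm(6), 2, 3)
  zero <- loss_seed(5, 0 * gx)
  a0 <- init_accumulators(zero, cfg)
  expect_equal(a0$A, 0 * gx); expect_equal(a0$B, 0 * gx)
  sd <- loss_seed(5, gx)
  acc <- init_accumulators(sd, cfg)
  expect_equal(acc$A, 2 * gx)
  expect_equal(acc$B, 2 * gx)
  # after the first reverse step the dl/df carriers C, D hold A_n, B_n
  st <- system_state(rbind(c(1, 1, 1), c(8, 8, 8)), matrix(0, 2, 3),
                     c(1, 1), c(10, 10, 10))
  top <- topology(c("F", "F"))
  ff <- force_field(data.frame(name = "dummy", value = 1, unit = "",
                               trainable = FALSE, starting_value = 1),
                    "lennard_jones", cutoff = 1)
  nl <- build_neighbor_list(st, top, 1, 0.1)
  acc1 <- reverse_accumulate_step(acc, st, top, ff, cfg, nl)
  expect_equal(acc1$C, 2 * gx)
  expect_equal(acc1$D, 2 * gx)
})

test_that("one reverse step reproduces the closed-form dl/df seed coefficients", {
  # dl/df_{n-1} = (dt^2/2m) (1+E) dl/dx + (dt/m) E dl/dv, E = exp(-gamma dt)
  cfg <- integrator_config(0.001, gamma = 1)
  E <- exp(-0.001)
  set.seed(2)
  gx <- matrix(rnorm(3), 1, 3); gv <- matrix(rnorm(3), 1, 3)
  m <- 2.7
  st <- system_state(matrix(0, 1, 3), matrix(0, 1, 3), m, c(10, 10, 10))
  top <- topology("F")
  ff <- force_field(data.frame(name = "dummy", value = 1, unit = "",
                               trainable = FALSE, starting_value = 1),
                    "lennard_jones", cutoff = 1)
  nl <- build_neighbor_list(st, top, 1, 0.1)
  acc <- init_accumulators(loss_seed(3, gx, gv), cfg)
  acc <- reverse_accumulate_step(acc, st, top, ff, cfg, nl)
  dldf <- (cfg$dt^2 / (2 * m)) * acc$C
  expect_equal(dldf, (cfg$dt^2 / (2 * m)) * (1 + E) * gx + (cfg$dt / m) * E * gv,
               tolerance = 1e-14)
})

test_that("free-particle dl/df coefficients reproduce the published series", {
  expect_equal(round(free_particle_dldf_coefficients(4, gamma = 1, dt = 0.001), 3),
               c(1.999, 3.996, 5.991, 7.984))
  expect_equal(free_particle_dldf_coefficients(4, gamma = 0, dt = 0.001),
               c(2, 4, 6, 8), tolerance = 1e-12)
})

test_that("reversible gradients equal the unrolled chain rule to 1e-10", {
  cases <- list(
    list(sys = fix_lj8(), gamma = 0, steps = c(1, 5), skin = 0.05),
    list(sys = fix_lj8(), gamma = 1, steps = c(1, 3, 5), skin = 0.05),
    list(sys = fix_diatomics(), gamma = 1, steps = 4, skin = 0.15),
    list(sys = generate_harmonic_oscillator(k = 80, n_atoms = 3, seed = 5),
         gamma = 1.5, steps = 5, skin = 0.15))
  for (form in c("double_exponential", "buckingham", "lj_softcore")) {
    sys <- fix_lj8()
    sys$ff <- fluid_ff(form, cutoff = 0.7)
    cases[[length(cases) + 1]] <- list(sys = sys, gamma = 1, steps = 3, skin = 0.05)
  }
  for (cs in cases) {
    sys <- cs$sys
    cfg <- integrator_config(0.002, gamma = cs$gamma, temperature = 120)
    ql <- make_quad_loss(nrow(sys$state$x), seed = 13)
    for (ns in cs$steps) {
      un <- unrolled_chain_rule_gradient(sys$state, sys$top, sys$ff, cfg, ns,
                                         ql$loss_fn, base_seed = 29, nl_skin = cs$skin)
      rec <- run_forward(sys$state, sys$top, sys$ff, cfg, ns, base_seed = 29,
                         snapshot_steps = ns, nl_skin = cs$skin)
      seeds <- list(ql$seed_at(rec$snapshots[[1]]))
      gr <- compute_loss_gradient(rec, seeds, sys$top, sys$ff,
                                  truncation_window = ns + 1)
      expect_lt(rel_err(gr$dl_dsigma[names(un$gradient)], un$gradient,
                        floor = 1e-8 * max(abs(un$gradient))), 1e-10)
    }
  }
})

test_that("reversible gradients match common-random-number finite differences", {
  ho <- generate_harmonic_oscillator(k = 120, seed = 3)
  cfg <- integrator_config(0.004, gamma = 1, temperature = 300)
  n_steps <- 100
  anch <- matrix(c(7, 25, 25), 1, 3)
  run_loss <- function(ff) {
    rec <- run_forward(ho$state, ho$top, ff, cfg, n_steps, base_seed = 31,
                       snapshot_steps = n_steps)
    sum((rec$snapshots[[1]]$x - anch)^2)
  }
  fd <- finite_difference_gradient(run_loss, ho$ff, h_rel = 1e-4)
  rec <- run_forward(ho$state, ho$top, ho$ff, cfg, n_steps, base_seed = 31,
                     snapshot_steps = n_steps)
  sn <- rec$snapshots[[1]]
  gr <- compute_loss_gradient(rec, list(loss_seed(n_steps, 2 * (sn$x - anch))),
                              ho$top, ho$ff, truncation_window = n_steps + 1)
  expect_lt(rel_err(gr$dl_dsigma, fd), 1e-6)
})

test_that("a sigma-only loss returns exactly its direct term", {
  fx <- fix_lj8()
  cfg <- integrator_config(0.002, gamma = 1, temperature = 120)
  rec <- run_forward(fx$state, fx$top, fx$ff, cfg, 5, base_seed = 3,
                     snapshot_steps = 5, nl_skin = 0.05)
  direct <- c(sigma_AR = 1.5, epsilon_AR = -2)
  seeds <- list(loss_seed(5, matrix(0, 8, 3), dl_dsigma_direct = direct))
  gr <- compute_loss_gradient(rec, seeds, fx$top, fx$ff)
  expect_equal(gr$dl_dsigma, direct)
})

test_that("truncated gradients converge to the full gradient", {
  ho <- generate_harmonic_oscillator(k = 120, seed = 9)
  cfg <- integrator_config(0.004, gamma = 1, temperature = 300)
  n_steps <- 200
  rec <- run_forward(ho$state, ho$top, ho$ff, cfg, n_steps, base_seed = 41,
                     snapshot_steps = n_steps, checkpoint_interval = 50)
  anch <- matrix(c(7, 25, 25), 1, 3)
  sn <- rec$snapshots[[1]]
  seeds <- list(loss_seed(n_steps, 2 * (sn$x - anch)))
  full <- compute_loss_gradient(rec, seeds, ho$top, ho$ff,
                                truncation_window = n_steps)$dl_dsigma
  errs <- vapply(c(10, 25, 50, 100, 200), function(w)
    abs(compute_loss_gradient(rec, seeds, ho$top, ho$ff,
                              truncation_window = w)$dl_dsigma - full),
    numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
  expect_equal(errs[[5]], 0)
})

test_that("gradients are invariant to the checkpoint interval", {
  fx <- fix_lj16()
  cfg <- integrator_config(0.005, gamma = 1, temperature = 120)
  ql <- make_quad_loss(16, seed = 4)
  grads <- lapply(c(1, 10, 60), function(ci) {
    rec <- run_forward(fx$state, fx$top, fx$ff, cfg, 60, base_seed = 51,
                       snapshot_steps = 60, checkpoint_interval = ci, nl_skin = 0.1)
    seeds <- list(ql$seed_at(rec$snapshots[[1]]))
    compute_loss_gradient(rec, seeds, fx$top, fx$ff,
                          truncation_window = 60)$dl_dsigma
  })
  expect_lt(rel_err(grads[[1]], grads[[3]]), 1e-9)
  expect_lt(rel_err(grads[[2]], grads[[3]]), 1e-9)
})

test_that("the truncation schedule merges windows and reports the walked fraction", {
  sch <- truncated_window_schedule(seq(2000, 20000, by = 2000), 200, 20000)
  expect_equal(attr(sch, "fraction_walked"), 0.1)
  expect_equal(nrow(sch), 10L)
  # window covering everything: one full-length segment
  sch2 <- truncated_window_schedule(100, 500, 100)
  expect_equal(nrow(sch2), 1L)
  expect_equal(c(sch2$start, sch2$stop), c(100L, 0L))
  # two seeds 100 apart with a 200 window merge into one segment
  sch3 <- truncated_window_schedule(c(900, 1000), 200, 1000)
  expect_equal(nrow(sch3), 1L)
  expect_equal(c(sch3$start, sch3$stop), c(1000L, 700L))
})

test_that("multi-snapshot gradients are the mean of single-seed gradients", {
  fx <- fix_lj16()
  cfg <- integrator_config(0.005, gamma = 1, temperature = 120)
  ql <- make_quad_loss(16, seed = 6)
  rec <- run_forward(fx$state, fx$top, fx$ff, cfg, 80, base_seed = 61,
                     snapshot_steps = c(40, 80), nl_skin = 0.1)
  g1 <- compute_loss_gradient(rec, list(ql$seed_at(rec$snapshots[[1]])),
                              fx$top, fx$ff, truncation_window = 100)$dl_dsigma
  g2 <- compute_loss_gradient(rec, list(ql$seed_at(rec$snapshots[[2]])),
                              fx$top, fx$ff, truncation_window = 100)$dl_dsigma
  # an averaged two-snapshot loss emits seeds scaled by 1/2
  half <- lapply(rec$snapshots, function(sn) {
    s <- ql$seed_at(sn); s$dl_dx <- s$dl_dx / 2; s$dl_dv <- s$dl_dv / 2; s
  })
  gm <- compute_loss_gradient(rec, half, fx$top, fx$ff,
                              truncation_window = 100)$dl_dsigma
  expect_lt(rel_err(gm, (g1 + g2) / 2), 1e-9)
})

test_that("exploding accumulators abort with a diagnostic", {
  # two nearly overlapping atoms: enormous Hessian, guaranteed blow-up
  st <- system_state(rbind(c(1, 1, 1), c(1.12, 1, 1)), matrix(0, 2, 3),
                     c(1, 1), c(3, 3, 3))
  top <- topology(c("AR", "AR"))
  ff <- lj_fluid_force_field(cutoff = 1)
  nl <- build_neighbor_list(st, top, 1, 0.2)
  cfg <- integrator_config(0.01, gamma = 0)
  acc <- init_accumulators(loss_seed(100, matrix(c(1, -1), 2, 3)), cfg,
                           truncation_window = 1000L)
  expect_error({
    for (i in 1:1000) acc <- reverse_accumulate_step(acc, st, top, ff, cfg, nl)
  }, "exploded")
})
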