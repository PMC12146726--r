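test_that("enthalpy of vapourisation arithmetic", {
  # equal per-molecule energies and no correction leave exactly RT
  RT <- 0.0083144626 * 295.15
  expect_equal(enthalpy_of_vaporisation(100 * 50, 50, 100, 295.15, 0), RT)
  expect_equal(enthalpy_of_vaporisation(100 * 50, 50, 100, 0, 0), 0)
  # the +2.8 kJ/mol flexible-model correction is applied to the liquid energy
  expect_equal(enthalpy_of_vaporisation(-2000, 100, -10, 295.15),
               -10 - (-2000 + 2.8) / 100 + RT)
  expect_error(enthalpy_of_vaporisation(0, 0), "at least one")
})

test_that("hvap loss is zero at the target and its seeds match finite differences", {
  wb <- fix_water27()
  cfg <- integrator_config(0.001, gamma = 1, temperature = 295.15)
  rec <- run_forward(wb$state, wb$top, wb$ff, cfg, 4, base_seed = 3,
                     snapshot_steps = c(2, 4), nl_skin = 0.1)
  hl <- hvap_loss(rec, wb$top, wb$ff, 27, gas_potential_energy = 0)
  expect_length(hl$seeds, 2)
  expect_gt(hl$value, 0)
  # using the observed H as the target zeroes the loss and the seeds
  hl0 <- hvap_loss(rec, wb$top, wb$ff, 27, gas_potential_energy = 0,
                   target = hl$h_vap[1])
  expect_equal(max(abs(hl0$seeds[[1]]$dl_dx)), 0)
  # finite-difference check of one seed (snapshot 1 carries weight 1/2)
  st <- rec$final_state; st$x <- rec$snapshots[[1]]$x
  lv <- function(x) {
    stt <- st; stt$x <- x
    nl2 <- build_neighbor_list(stt, wb$top, wb$ff$cutoff, 0.1)
    pe <- total_forces(stt, wb$top, wb$ff, nl2)$potential_energy
    (enthalpy_of_vaporisation(pe, 27, 0, 295.15) - 44.12)^2 / 2
  }
  h <- 1e-6
  for (idx in list(c(5, 1), c(40, 3))) {
    xp <- st$x; xp[idx[1], idx[2]] <- xp[idx[1], idx[2]] + h
    xm <- st$x; xm[idx[1], idx[2]] <- xm[idx[1], idx[2]] - h
    expect_equal(hl$seeds[[1]]$dl_dx[idx[1], idx[2]], (lv(xp) - lv(xm)) / (2 * h),
                 tolerance = 1e-5 * max(abs(hl$seeds[[1]]$dl_dx)))
  }
})

test_that("kernel RDF matches the histogram oracle on an ideal gas", {
  set.seed(15)
  n <- 200; box <- c(3, 3, 3)
  rg <- seq(0.3, 1.2, by = 0.02)
  top <- topology(rep("A", n))
  pairs <- select_pairs(top, "A", "A")
  gk <- 0; gb <- 0
  for (f in 1:50) {
    st <- system_state(matrix(runif(3 * n), n, 3) %*% diag(box),
                       matrix(0, n, 3), rep(1, n), box)
    gk <- gk + differentiable_rdf(st, pairs, rg)$g / 50
    gb <- gb + binned_rdf(st, pairs, rg) / 50
  }
  # the +-0.05 band applies to the mid-range bins; the smallest-r shells hold
  # too few pairs for that precision at this sample size
  mid <- rg >= 0.5
  expect_lt(max(abs(gk[mid] - 1)), 0.05)
  expect_lt(max(abs(gb[mid] - 1)), 0.05)
  expect_lt(max(abs(gk[mid] - gb[mid])), 0.05)
  expect_lt(mean(abs(gk - 1)), 0.05)
  expect_lt(mean(abs(gb - 1)), 0.05)
})

test_that("a single pair deposits one shell-normalised Gaussian bump", {
  box <- c(4, 4, 4)
  d0 <- 0.8
  st <- system_state(rbind(c(1, 1, 1), c(1 + d0, 1, 1)), matrix(0, 2, 3),
                     c(1, 1), box)
  rg <- seq(0.5, 1.1, by = 0.005)
  g <- differentiable_rdf(st, matrix(c(1L, 2L), 1), rg, kernel_width = 0.02)$g
  expect_equal(rg[which.max(g)], d0, tolerance = 0.005)
  w <- 0.02
  expected_peak <- prod(box) / (1 * 4 * pi * d0^2) / (w * sqrt(2 * pi))
  expect_equal(max(g), expected_peak, tolerance = 1e-6)
  expect_error(differentiable_rdf(st, matrix(integer(0), 0, 2), rg), "empty")
})

test_that("RDF coordinate gradients match finite differences", {
  fx <- fix_lj16()
  pairs <- select_pairs(fx$top, "AR", "AR")
  rg <- seq(0.28, 0.5, by = 0.01)
  set.seed(18)
  coeff <- rnorm(length(rg))
  out <- differentiable_rdf(fx$state, pairs, rg, dl_dg = coeff)
  h <- 1e-6
  for (k in 1:10) {
    a <- sample(16, 1); d <- sample(3, 1)
    sp <- fx$state; sp$x[a, d] <- sp$x[a, d] + h
    sm <- fx$state; sm$x[a, d] <- sm$x[a, d] - h
    fd <- sum(coeff * (differentiable_rdf(sp, pairs, rg)$g -
                       differentiable_rdf(sm, pairs, rg)$g)) / (2 * h)
    expect_equal(out$dl_dx[a, d], fd, tolerance = 1e-5 * max(abs(out$dl_dx)))
  }
})

test_that("rdf_loss is the sum of absolute differences with sign subgradient", {
  ref <- list(r = 1:10 / 10, g = rep(1, 10))
  expect_equal(rdf_loss(rep(1, 10), ref)$value, 0)
  expect_equal(rdf_loss(rep(1.1, 10), ref)$value, 1, tolerance = 1e-12)
  set.seed(4)
  gs <- runif(10); gr <- runif(10)
  rl <- rdf_loss(gs, list(r = ref$r, g = gr))
  expect_equal(rl$value, sum(abs(gs - gr)))
  expect_equal(rl$dl_dg, sign(gs - gr))
  expect_equal(rdf_loss(ref$g, ref)$dl_dg, rep(0, 10))   # tie subgradient is 0
  expect_error(rdf_loss(rep(1, 9), ref), "mismatch")
})

test_that("MSD diffusion estimator: trivial, ballistic and Brownian cases", {
  still <- lapply(1:20, function(i) matrix(2, 5, 3))
  expect_equal(msd_diffusion(still, 0.5)$D, 0)
  # ballistic motion x = v t: MSD over a segment is (v t_seg)^2
  v <- 0.3
  fr <- lapply(0:99, function(t) matrix(c(v * t, 0, 0), 1, 3))
  est <- msd_diffusion(fr, 1)
  expect_equal(est$D, v^2 * est$segment_time / 6 * 1e-6, tolerance = 1e-12)
  # hand-converted unit pin: one segment of 1 ps and 1 nm displacement
  two <- list(matrix(0, 1, 3), matrix(c(1, 0, 0), 1, 3))
  expect_equal(msd_diffusion(two, 1)$D, 1 / 6 * 1e-6)
  # Brownian walkers generated at the experimental target value
  D_nm <- 2.0e-3                       # 2.0e-9 m^2/s in nm^2/ps
  set.seed(1)
  nf <- 1000; nw <- 10
  frames <- vector("list", nf)
  frames[[1]] <- matrix(0, nw, 3)
  for (f in 2:nf) frames[[f]] <- frames[[f - 1]] +
    matrix(rnorm(3 * nw, sd = sqrt(2 * D_nm)), nw, 3)
  est <- msd_diffusion(frames, 1)
  expect_lt(abs(est$D - 2.0e-9) / 2.0e-9, 0.15)
  # translation invariance
  shifted <- lapply(frames, function(f) sweep(f, 2, c(3, -1, 2), "+"))
  expect_equal(msd_diffusion(shifted, 1)$D, est$D)
  # wrapped coordinates are refused
  bad <- list(matrix(0, 1, 3), matrix(c(2.9, 0, 0), 1, 3))
  expect_error(msd_diffusion(bad, 1, box = c(3, 3, 3)), "unwrapped")
})

test_that("diffusion loss seeds match finite differences of the estimator", {
  gw <- generate_gas_in_water(n_gas = 2, n_water = 14, box = 1.3, seed = 5)
  ff <- add_oxygen_gas_params(tip3p_force_field(cutoff = 0.45))
  cfg <- integrator_config(0.001, gamma = 1, temperature = 295.15)
  rec <- run_forward(gw$state, gw$top, ff, cfg, 40, base_seed = 7,
                     snapshot_steps = seq(10, 40, by = 10), nl_skin = 0.1)
  dl <- diffusion_loss(rec, gw$top, target = 2e-9, weight = 1e18)
  expect_length(dl$seeds, 4)
  # perturb a tagged atom in one stored frame and re-evaluate the loss value
  atom <- gw$top$tagged_molecules[[1]][1]
  h <- 1e-7
  for (frame in c(1, 3)) {
    rp <- rec; rp$snapshots[[frame]]$x[atom, 2] <-
      rp$snapshots[[frame]]$x[atom, 2] + h
    rm <- rec; rm$snapshots[[frame]]$x[atom, 2] <-
      rm$snapshots[[frame]]$x[atom, 2] - h
    fd <- (diffusion_loss(rp, gw$top, 2e-9, 1e18)$value -
           diffusion_loss(rm, gw$top, 2e-9, 1e18)$value) / (2 * h)
    expect_equal(dl$seeds[[frame]]$dl_dx[atom, 2], fd,
                 tolerance = 1e-4 * max(abs(fd), 1e-10))
  }
})

test_that("combine_losses merges weighted seeds by linearity", {
  s1 <- loss_seed(10, matrix(1, 2, 3), dl_dsigma_direct = c(a = 1))
  s2 <- loss_seed(10, matrix(2, 2, 3))
  s3 <- loss_seed(20, matrix(3, 2, 3))
  one <- combine_losses(list(list(value = 2, seeds = list(s1))), 1)
  expect_equal(one$value, 2)
  expect_equal(one$seeds[[1]]$dl_dx, s1$dl_dx)
  both <- combine_losses(list(list(value = 2, seeds = list(s1)),
                              list(value = 5, seeds = list(s2, s3))),
                         weights = c(2, 0.5))
  expect_equal(both$value, 2 * 2 + 0.5 * 5)
  expect_length(both$seeds, 2)
  expect_equal(both$seeds[[1]]$dl_dx, 2 * s1$dl_dx + 0.5 * s2$dl_dx)
  expect_equal(both$seeds[[1]]$dl_dsigma_direct, c(a = 2))
  expect_equal(both$seeds[[2]]$dl_dx, 0.5 * s3$dl_dx)
  # the published gas-diffusion weighting: MSE(D) x 1e18 + 0.05 x water losses
  comb <- combine_losses(list(list(value = (2.5e-9 - 2e-9)^2 * 1e18, seeds = list()),
                              list(value = 3.2, seeds = list()),
                              list(value = 1.1, seeds = list())),
                         weights = c(1, 0.05, 0.05))
  expect_equal(comb$value, 0.25 + 0.05 * 3.2 + 0.05 * 1.1)
})
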