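# Pair potential kernels. All four nonbonded forms expose V(r), -dV/dr,
# dV/dparam analytically; second derivatives (V'' and d2V/dr dparam) are
# provided for the dense-Jacobian oracle. Parameters arrive as a named list
# of (possibly per-pair, possibly complex) vectors.

.pair_forms <- c("lennard_jones", "double_exponential", "buckingham", "lj_softcore")

.de_coeffs <- function(p) {
  rm <- 2^(1/6) * p$sigma
  d <- p$alpha - p$beta
  list(rm = rm, k1 = p$beta * exp(p$alpha) / d, k2 = p$alpha * exp(p$beta) / d)
}

# V and V' = dV/dr, vectorised over r
.pair_V_V1 <- function(form, r, p) {
  switch(form,
    lennard_jones = {
      s6 <- (p$sigma / r)^6
      list(V = 4 * p$epsilon * (s6^2 - s6),
           V1 = (24 * p$epsilon / r) * (s6 - 2 * s6^2))
    },
    double_exponential = {
      cf <- .de_coeffs(p)
      E1 <- exp(-p$alpha * r / cf$rm); E2 <- exp(-p$beta * r / cf$rm)
      list(V = p$epsilon * (cf$k1 * E1 - cf$k2 * E2),
           V1 = p$epsilon * (-cf$k1 * p$alpha / cf$rm * E1 +
                              cf$k2 * p$beta / cf$rm * E2))
    },
    buckingham = {
      eb <- exp(-p$B * r)
      list(V = p$A * eb - p$C / r^6,
           V1 = -p$A * p$B * eb + 6 * p$C / r^7)
    },
    lj_softcore = {
      s6 <- p$sigma^6
      w <- r^6 + p$alpha * p$lambda^2 * s6
      u <- s6 / w
      list(V = 4 * p$epsilon * (u^2 - u),
           V1 = 24 * p$epsilon * r^5 * s6 * (w - 2 * s6) / w^3)
    },
    stop("unknown pair form ", form))
}

# V'' = d2V/dr2 (oracle support)
.pair_V2 <- function(form, r, p) {
  switch(form,
    lennard_jones = {
      s6 <- (p$sigma / r)^6
      (24 * p$epsilon / r^2) * (26 * s6^2 - 7 * s6)
    },
    double_exponential = {
      cf <- .de_coeffs(p)
      a <- p$alpha / cf$rm; b <- p$beta / cf$rm
      p$epsilon * (cf$k1 * a^2 * exp(-a * r) - cf$k2 * b^2 * exp(-b * r))
    },
    buckingham = p$A * p$B^2 * exp(-p$B * r) - 42 * p$C / r^8,
    lj_softcore = {
      s6 <- p$sigma^6
      w <- r^6 + p$alpha * p$lambda^2 * s6
      24 * p$epsilon * r^4 * s6 *
        (36 * r^6 * s6 - 2 * (6 * r^6 + 5 * s6) * w + 5 * w^2) / w^4
    },
    stop("unknown pair form ", form))
}

# dV/dparam as a named list (oracle + reweighting support; also the exported
# pair_param_grad). Parameters follow the form definitions.
.pair_dV_dp <- function(form, r, p) {
  switch(form,
    lennard_jones = {
      s6 <- (p$sigma / r)^6
      list(sigma = (24 * p$epsilon / p$sigma) * (2 * s6^2 - s6),
           epsilon = 4 * (s6^2 - s6))
    },
    double_exponential = {
      cf <- .de_coeffs(p); rm <- cf$rm
      E1 <- exp(-p$alpha * r / rm); E2 <- exp(-p$beta * r / rm)
      d <- p$alpha - p$beta
      V1 <- p$epsilon * (-cf$k1 * p$alpha / rm * E1 + cf$k2 * p$beta / rm * E2)
      dk1_da <- p$beta * exp(p$alpha) * (d - 1) / d^2
      dk2_da <- -p$beta * exp(p$beta) / d^2
      dk1_db <- p$alpha * exp(p$alpha) / d^2
      dk2_db <- p$alpha * exp(p$beta) * (d + 1) / d^2
      list(sigma = -(r / p$sigma) * V1,
           epsilon = (cf$k1 * E1 - cf$k2 * E2),
           alpha = p$epsilon * (dk1_da * E1 - cf$k1 * (r / rm) * E1 - dk2_da * E2),
           beta = p$epsilon * (dk1_db * E1 - dk2_db * E2 + cf$k2 * (r / rm) * E2))
    },
    buckingham = {
      eb <- exp(-p$B * r)
      list(A = eb, B = -p$A * r * eb, C = -1 / r^6)
    },
    lj_softcore = {
      s6 <- p$sigma^6
      q <- p$alpha * p$lambda^2 * s6
      w <- r^6 + q
      list(sigma = -24 * p$epsilon * p$sigma^5 *
             (2 * q * s6 - s6 * (p$alpha * p$lambda^2 + 2) * w + w^2) / w^3,
           epsilon = 4 * s6 * (s6 - w) / w^2,
           alpha = 4 * p$epsilon * p$lambda^2 * s6^2 * (w - 2 * s6) / w^3,
           lambda = 8 * p$alpha * p$epsilon * p$lambda * s6^2 * (w - 2 * s6) / w^3)
    },
    stop("unknown pair form ", form))
}

# d2V/(dr dparam) (oracle support): derivative of V' in each parameter
.pair_dV1_dp <- function(form, r, p) {
  switch(form,
    lennard_jones = {
      s6 <- (p$sigma / r)^6
      V1 <- (24 * p$epsilon / r) * (s6 - 2 * s6^2)
      list(sigma = (144 * p$epsilon / (p$sigma * r)) * (s6 - 4 * s6^2),
           epsilon = V1 / p$epsilon)
    },
    double_exponential = {
      cf <- .de_coeffs(p); rm <- cf$rm
      a <- p$alpha / rm; b <- p$beta / rm
      E1 <- exp(-a * r); E2 <- exp(-b * r)
      V1 <- p$epsilon * (-cf$k1 * a * E1 + cf$k2 * b * E2)
      d <- p$alpha - p$beta
      dk1_da <- p$beta * exp(p$alpha) * (d - 1) / d^2
      dk2_da <- -p$beta * exp(p$beta) / d^2
      dk1_db <- p$alpha * exp(p$alpha) / d^2
      dk2_db <- p$alpha * exp(p$beta) * (d + 1) / d^2
      list(sigma = (p$epsilon / p$sigma) *
             (cf$k1 * a * E1 * (1 - a * r) - cf$k2 * b * E2 * (1 - b * r)),
           epsilon = V1 / p$epsilon,
           alpha = p$epsilon * (-dk1_da * a * E1 - cf$k1 * E1 / rm +
                                 cf$k1 * a * (r / rm) * E1 + dk2_da * b * E2),
           beta = p$epsilon * (-dk1_db * a * E1 + dk2_db * b * E2 +
                                 cf$k2 * E2 / rm - cf$k2 * b * (r / rm) * E2))
    },
    buckingham = {
      eb <- exp(-p$B * r)
      list(A = -p$B * eb, B = p$A * (p$B * r - 1) * eb, C = 6 / r^7)
    },
    lj_softcore = {
      s6 <- p$sigma^6
      q <- p$alpha * p$lambda^2 * s6
      w <- r^6 + q
      V1 <- 24 * p$epsilon * r^5 * s6 * (w - 2 * s6) / w^3
      list(sigma = 144 * p$epsilon * r^5 * p$sigma^5 *
             (6 * q * s6 - 2 * s6 * (p$alpha * p$lambda^2 + 2) * w + w^2) / w^4,
           epsilon = V1 / p$epsilon,
           alpha = 48 * p$epsilon * p$lambda^2 * r^5 * s6^2 * (3 * s6 - w) / w^4,
           lambda = 96 * p$alpha * p$epsilon * p$lambda * r^5 * s6^2 * (3 * s6 - w) / w^4)
    },
    stop("unknown pair form ", form))
}

.check_pair_r <- function(form, r) {
  if (any(!is.finite(.re(r)))) stop("non-finite pair distance")
  if (form != "lj_softcore" && any(.re(r) <= 0))
    stop("pair distance must be positive for form ", form)
  if (form == "lj_softcore" && any(.re(r) < 0)) stop("negative pair distance")
}

#' Pair potential energy
#'
#' Evaluates the nonbonded pair potential at distance `r` (nm). Forms:
#' Lennard-Jones `4 eps ((sigma/r)^12 - (sigma/r)^6)`; double exponential
#' with minimum position `r_m = 2^(1/6) sigma` and depth `-eps` at `r_m`;
#' Buckingham `A exp(-B r) - C r^-6`; Lennard-Jones soft core, which replaces
#' `r` by `r_sc = (r^6 + alpha sigma^6 lambda^p)^(1/6)` with `p = 2` and is
#' finite at `r = 0`.
#'
#' @param form form tag (see [force_field()]).
#' @param r distance(s), nm. Must be > 0 except for the soft-core form.
#' @param params named list of form parameters (`sigma`, `epsilon`, `alpha`,
#'   `beta`, `A`, `B`, `C`, `lambda` as the form requires).
#' @return Energy in kJ/mol (vectorised over `r`).
#' @export
pair_energy <- function(form, r, params) {
  .check_pair_r(form, r)
  .pair_V_V1(form, r, params)$V
}

#' Scalar pair force -dV/dr
#'
#' @inheritParams pair_energy
#' @return Force magnitude along the pair axis, kJ mol^-1 nm^-1; positive is
#'   repulsive.
#' @export
pair_force_scalar <- function(form, r, params) {
  .check_pair_r(form, r)
  -.pair_V_V1(form, r, params)$V1
}

#' Parameter gradient of the pair energy
#'
#' @inheritParams pair_energy
#' @return Named list, one entry per form parameter, each `dV/dparam`
#'   (vectorised over `r`).
#' @export
pair_param_grad <- function(form, r, params) {
  .check_pair_r(form, r)
  .pair_dV_dp(form, r, params)
}

#' Reaction-field electrostatic pair energy and force
#'
#' Tironi reaction-field form with no self-term, shifted so the potential is
#' zero at the cutoff: `V = f q_i q_j (1/r + k_rf r^2 - c_rf)` for
#' `r <= cutoff` and exactly zero beyond, with
#' `k_rf = (eps_rf - 1) / ((2 eps_rf + 1) cutoff^3)` (limit `1/(2 cutoff^3)`
#' for an infinite solvent dielectric), `c_rf = 1/cutoff + k_rf cutoff^2` and
#' Coulomb constant f = 138.935458 kJ mol^-1 nm e^-2.
#'
#' @param q_i,q_j charges (e).
#' @param r distance(s), nm, > 0.
#' @param cutoff cutoff (nm).
#' @param solvent_dielectric relative dielectric of the surrounding medium
#'   (may be `Inf`).
#' @return list with `energy` (kJ/mol) and `force` (-dV/dr, kJ mol^-1 nm^-1).
#' @export
coulomb_rf_energy_force <- function(q_i, q_j, r, cutoff, solvent_dielectric = 78.5) {
  if (any(.re(r) <= 0)) stop("distance must be positive")
  krf <- if (is.finite(solvent_dielectric))
    (solvent_dielectric - 1) / ((2 * solvent_dielectric + 1) * cutoff^3)
  else 1 / (2 * cutoff^3)
  crf <- 1 / cutoff + krf * cutoff^2
  qq <- COULOMB_MD * q_i * q_j
  inside <- .re(r) <= cutoff
  e <- qq * (1 / r + krf * r^2 - crf) * inside
  f <- qq * (1 / r^2 - 2 * krf * r) * inside
  list(energy = e, force = f)
}

# per-type nonbonded parameter tables (complex-capable through ff_get)
.nb_type_tables <- function(top, ff) {
  ut <- sort(unique(top$atom_types))
  form <- ff$nonbonded_form
  val <- function(prefix, t, default) ff_get(ff, paste0(prefix, t), default = default)
  tab <- list(types = ut, tid = match(top$atom_types, ut))
  if (form == "buckingham") {
    tab$A <- sapply(ut, function(t) val("buck_A_", t, 0))
    tab$B <- sapply(ut, function(t) val("buck_B_", t, 30))
    tab$C <- sapply(ut, function(t) val("buck_C_", t, 0))
  } else {
    tab$sigma <- sapply(ut, function(t) val("sigma_", t, 0.1))
    tab$epsilon <- sapply(ut, function(t) val("epsilon_", t, 0))
    if (form == "double_exponential") {
      tab$alpha <- ff_get(ff, "de_alpha"); tab$beta <- ff_get(ff, "de_beta")
    }
    if (form == "lj_softcore") {
      tab$alpha <- ff_get(ff, "sc_alpha"); tab$lambda <- ff_get(ff, "sc_lambda")
    }
  }
  tab
}

# mixed per-pair parameters for pair index vectors ti, tj (type ids)
.mix_pair_params <- function(tab, form, ti, tj) {
  if (form == "buckingham") {
    list(A = sqrt(tab$A[ti] * tab$A[tj]),
         B = (tab$B[ti] + tab$B[tj]) / 2,
         C = sqrt(tab$C[ti] * tab$C[tj]))
  } else {
    p <- list(sigma = (tab$sigma[ti] + tab$sigma[tj]) / 2,
              epsilon = sqrt(tab$epsilon[ti] * tab$epsilon[tj]))
    if (form == "double_exponential") { p$alpha <- tab$alpha; p$beta <- tab$beta }
    if (form == "lj_softcore") { p$alpha <- tab$alpha; p$lambda <- tab$lambda }
    p
  }
}

.accum_forces <- function(F, idx, contrib) {
  if (is.complex(contrib) && !is.complex(F)) F <- F + 0i
  if (is.complex(F)) {
    re <- rowsum(Re(contrib), idx); im <- rowsum(Im(contrib), idx)
    ridx <- as.integer(rownames(re))
    F[ridx, ] <- F[ridx, ] + re + 1i * im
  } else {
    rs <- rowsum(contrib, idx)
    ridx <- as.integer(rownames(rs))
    F[ridx, ] <- F[ridx, ] + rs
  }
  F
}

# Full force/energy kernel shared by the forward pass, the reverse pass and
# (through complex inputs) both VJP contractions. x may be complex (coordinate
# perturbation); ff values may be complex (parameter perturbation).
.forces_impl <- function(x, top, ff, nl, check_overlap = FALSE) {
  n <- nrow(x)
  cplx <- is.complex(x) || !is.null(attr(ff, "value_override"))
  F <- matrix(if (cplx) 0 + 0i else 0, n, 3)
  br <- list(nonbonded = 0, electrostatic = 0, bond = 0, angle = 0, tether = 0)
  form <- ff$nonbonded_form
  box <- nl$box
  pr <- nl$pairs
  if (nrow(pr)) {
    i <- pr[, 1]; j <- pr[, 2]
    d <- .pair_disp(x, i, j, box)
    r2 <- d[, 1]^2 + d[, 2]^2 + d[, 3]^2
    r <- sqrt(r2)
    inside <- .re(r) < ff$cutoff
    if (any(inside)) {
      i <- i[inside]; j <- j[inside]
      d <- d[inside, , drop = FALSE]; r <- r[inside]
      if (check_overlap && form != "lj_softcore" && any(.re(r) < 1e-6)) {
        k <- which(.re(r) < 1e-6)[1]
        stop(sprintf("overlapping atoms %d and %d (r = %.2e nm)", i[k], j[k], .re(r[k])))
      }
      tab <- .nb_type_tables(top, ff)
      p <- .mix_pair_params(tab, form, tab$tid[i], tab$tid[j])
      vv <- .pair_V_V1(form, r, p)
      br$nonbonded <- sum(vv$V)
      fs <- -vv$V1 / r                       # F_i = -V'(r) * d / r
      q <- .effective_charges(top, ff)
      qq <- q[i] * q[j]
      if (any(.re(qq) != 0)) {
        rf <- coulomb_rf_energy_force(q[i], q[j], r, ff$cutoff, ff$solvent_dielectric)
        br$electrostatic <- sum(rf$energy)
        fs <- fs + rf$force / r
      }
      fv <- d * fs
      F <- .accum_forces(F, i, fv)
      F <- .accum_forces(F, j, -fv)
    }
  }
  if (!is.null(top$bonds) && nrow(top$bonds)) {
    for (bt in unique(top$bonds$type)) {
      bb <- top$bonds[top$bonds$type == bt, , drop = FALSE]
      r0 <- ff_get(ff, paste0("bond_", bt, "_r0"))
      k <- ff_get(ff, paste0("bond_", bt, "_k"))
      d <- .pair_disp(x, bb$i, bb$j, box)
      r <- sqrt(d[, 1]^2 + d[, 2]^2 + d[, 3]^2)
      br$bond <- br$bond + sum(k / 2 * (r - r0)^2)
      fv <- d * (-k * (r - r0) / r)
      F <- .accum_forces(F, bb$i, fv)
      F <- .accum_forces(F, bb$j, -fv)
    }
  }
  if (!is.null(top$angles) && nrow(top$angles)) {
    for (at in unique(top$angles$type)) {
      aa <- top$angles[top$angles$type == at, , drop = FALSE]
      th0 <- ff_get(ff, paste0("angle_", at, "_theta0"))
      k <- ff_get(ff, paste0("angle_", at, "_k"))
      u <- .pair_disp(x, aa$i, aa$j, box)
      w <- .pair_disp(x, aa$k, aa$j, box)
      ru <- sqrt(u[, 1]^2 + u[, 2]^2 + u[, 3]^2)
      rw <- sqrt(w[, 1]^2 + w[, 2]^2 + w[, 3]^2)
      cth <- (u[, 1] * w[, 1] + u[, 2] * w[, 2] + u[, 3] * w[, 3]) / (ru * rw)
      # collinear regularisation: clamp and zero the torque factor
      bad <- abs(.re(cth)) > 1 - 1e-10
      if (any(bad)) cth[bad] <- sign(.re(cth[bad])) * (1 - 1e-10)
      th <- acos(cth)
      sth <- sqrt(1 - cth^2)
      br$angle <- br$angle + sum(k / 2 * (th - th0)^2)
      fac <- k * (th - th0) / sth
      if (any(bad)) fac[bad] <- 0
      fi <- (w / (ru * rw) - u * (cth / ru^2)) * fac
      fk <- (u / (ru * rw) - w * (cth / rw^2)) * fac
      F <- .accum_forces(F, aa$i, fi)
      F <- .accum_forces(F, aa$k, fk)
      F <- .accum_forces(F, aa$j, -(fi + fk))
    }
  }
  if (!is.null(top$tethers) && nrow(top$tethers)) {
    kt <- ff_get(ff, "tether_k")
    ti <- top$tethers$i
    xt <- x[ti, , drop = FALSE] - .tether_anchors(top)
    br$tether <- sum(kt / 2 * rowSums(xt^2))
    F[ti, ] <- F[ti, ] - kt * xt
  }
  list(forces = F, energy = br$nonbonded + br$electrostatic + br$bond + br$angle + br$tether,
       breakdown = br)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.tether_anchors <- function(top) {
  tt <- top$tethers
  if (all(c("x0", "y0", "z0") %in% names(tt)))
    cbind(tt$x0, tt$y0, tt$z0)
  else matrix(0, nrow(tt), 3)
}

#' Total forces and potential energy
#'
#' Sums the nonbonded pair form (cutoff-truncated), reaction-field
#' electrostatics, harmonic bonds and angles, and tether restraints. Pairwise
#' interactions obey Newton's third law, so the net force is zero (up to
#' roundoff) in the absence of tethers.
#'
#' @param state A `system_state`.
#' @param top A `topology`.
#' @param ff A `force_field`.
#' @param nl A current `neighbor_list`.
#' @return list with `forces` (N x 3, kJ mol^-1 nm^-1), `potential_energy`
#'   (kJ/mol) and per-term `breakdown`.
#' @export
total_forces <- function(state, top, ff, nl) {
  nl$box <- state$box
  out <- .forces_impl(state$x, top, ff, nl, check_overlap = TRUE)
  if (!all(is.finite(out$forces)))
    stop(sprintf("non-finite forces at step %d", state$step))
  list(forces = out$forces, potential_energy = out$energy, breakdown = out$breakdown)
}

#' Bonded (bond + angle + tether) contribution only
#'
#' @inheritParams total_forces
#' @return Same shape as [total_forces()].
#' @export
bonded_energy_forces <- function(state, top, ff) {
  top2 <- top
  nl <- structure(list(pairs = matrix(integer(0), 0, 2), build_step = state$step,
                       cutoff = ff$cutoff, skin = 0), class = "neighbor_list")
  nl$box <- state$box
  out <- .forces_impl(state$x, top2, ff, nl)
  list(forces = out$forces, potential_energy = out$energy, breakdown = out$breakdown)
}

#' Coordinate-side force contraction (Hessian-vector product)
#'
#' Returns `d/dx (weight . a)` where `a = F(x)/m` are the accelerations and
#' the dot contracts over all atoms and components: the gradient field needed
#' by the reverse-time accumulation. Because conservative forces have a
#' symmetric Hessian, this equals the directional derivative of `F` along
#' `weight/m`, which is evaluated exactly (to machine precision) by a
#' complex-step perturbation through the shared force kernel; no automatic
#' differentiation framework is involved.
#'
#' @inheritParams total_forces
#' @param weight N x 3 matrix contracted against the accelerations.
#' @return N x 3 matrix, the gradient of `weight . a` with respect to x.
#' @export
forces_coord_vjp <- function(state, top, ff, nl, weight) {
  if (!all(dim(weight) == dim(state$x))) stop("weight shape mismatch")
  nl$box <- state$box
  h <- 1e-100
  xc <- state$x + (1i * h) * (weight / state$m)
  Im(.forces_impl(xc, top, ff, nl)$forces) / h
}

#' Parameter-side force contraction
#'
#' Returns `sum(weight . da/dsigma_j)` for every trainable parameter, where
#' `a = F/m`. Evaluated exactly by a complex step in each parameter through
#' the shared force kernel.
#'
#' @inheritParams forces_coord_vjp
#' @return Named numeric, one entry per trainable parameter.
#' @export
forces_param_vjp <- function(state, top, ff, nl, weight) {
  if (!all(dim(weight) == dim(state$x))) stop("weight shape mismatch")
  nl$box <- state$box
  wm <- weight / state$m
  nms <- trainable_names(ff)
  out <- stats::setNames(numeric(length(nms)), nms)
  for (nm in nms) {
    h <- 1e-100 * max(abs(ff_get(ff, nm)), 1e-6)
    Fc <- .forces_impl(state$x, top, .ff_perturb(ff, nm, h), nl)$forces
    out[nm] <- sum(wm * Im(Fc)) / h
  }
  out
}

#' Parameter gradient of the total potential energy
#'
#' `dU/dsigma_j` for every trainable parameter (complex-step through the
#' shared energy kernel; exact). Used by the ensemble-reweighting baseline
#' and by energy-based loss seeds.
#'
#' @inheritParams total_forces
#' @return Named numeric, one entry per trainable parameter.
#' @export
energy_param_grad <- function(state, top, ff, nl) {
  nl$box <- state$box
  nms <- trainable_names(ff)
  out <- stats::setNames(numeric(length(nms)), nms)
  for (nm in nms) {
    h <- 1e-100 * max(abs(ff_get(ff, nm)), 1e-6)
    e <- .forces_impl(state$x, top, .ff_perturb(ff, nm, h), nl)$energy
    out[nm] <- Im(e) / h
  }
  out
}
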