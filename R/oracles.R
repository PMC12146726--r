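# Independent gradient oracles. The dense forward-sensitivity oracle is built
# from the analytic scalar derivatives V', V'' and d2V/(dr dparam) of the pair
# forms (a separate code path from the complex-step contractions used by the
# reverse pass), and the finite-difference oracle re-runs the whole pipeline
# with common random numbers. Angle terms are outside the dense oracle's
# scope; finite differences cover them.

#' Central finite-difference gradient with common random numbers
#'
#' Differentiates an arbitrary simulate-then-loss pipeline by central
#' differences, one trainable parameter at a time. The pipeline closure must
#' fix its own thermostat seeds so both arms see identical noise.
#'
#' @param pipeline function(ff) returning a scalar loss.
#' @param ff the `force_field` varied.
#' @param param_names parameters to differentiate (default all trainable).
#' @param h_rel relative step size (default 1e-4 of the starting value).
#' @return named numeric gradient.
#' @export
finite_difference_gradient <- function(pipeline, ff,
                                       param_names = trainable_names(ff),
                                       h_rel = 1e-4) {
  g <- stats::setNames(numeric(length(param_names)), param_names)
  for (nm in param_names) {
    v <- ff_get(ff, nm)
    h <- h_rel * max(abs(v), 1e-3)
    lp <- pipeline(ff_set(ff, nm, v + h))
    lm <- pipeline(ff_set(ff, nm, v - h))
    if (!is.finite(lp) || !is.finite(lm)) stop("non-finite loss in finite differences")
    g[nm] <- (lp - lm) / (2 * h)
  }
  g
}

# scalar pair derivatives for every interacting pair (nonbonded within the
# cutoff + electrostatics + bonds), as rows: i, j, V1, V2 and optionally the
# per-parameter dV1/dp columns
.pair_terms_dense <- function(x, top, ff, nl, param_names = character(0)) {
  box <- nl$box
  out <- list()
  add <- function(i, j, V1, V2, dV1) {
    out[[length(out) + 1L]] <<- list(i = i, j = j, V1 = V1, V2 = V2, dV1 = dV1)
  }
  zero_d <- function(np) stats::setNames(as.list(numeric(np)), param_names)
  pr <- nl$pairs
  if (nrow(pr)) {
    i <- pr[, 1]; j <- pr[, 2]
    d <- .pair_disp(x, i, j, box)
    r <- sqrt(rowSums(d^2))
    inside <- r < ff$cutoff
    i <- i[inside]; j <- j[inside]; r <- r[inside]
    if (length(i)) {
      form <- ff$nonbonded_form
      tab <- .nb_type_tables(top, ff)
      types <- top$atom_types
      p <- .mix_pair_params(tab, form, tab$tid[i], tab$tid[j])
      vv <- .pair_V_V1(form, r, p)
      V1 <- vv$V1
      V2 <- .pair_V2(form, r, p)
      dV1p <- .pair_dV1_dp(form, r, p)
      dV1 <- stats::setNames(vector("list", length(param_names)), param_names)
      for (nm in param_names) dV1[[nm]] <- numeric(length(r))
      for (nm in param_names) {
        # chain through the mixing rules into per-type / shared parameters
        parts <- strsplit(nm, "_")[[1]]
        if (parts[1] %in% c("sigma", "epsilon") && form != "buckingham") {
          tt <- sub("^(sigma|epsilon)_", "", nm)
          ni <- (types[i] == tt) + (types[j] == tt)
          if (parts[1] == "sigma") {
            dV1[[nm]] <- dV1p$sigma * ni / 2
          } else {
            et <- tab$epsilon[match(tt, tab$types)]
            fac <- ifelse(.re(p$epsilon) > 0 & et > 0, p$epsilon * (ni / 2) / et, 0)
            v <- dV1p$epsilon * fac
            v[fac == 0] <- 0
            dV1[[nm]] <- v
          }
        } else if (parts[1] == "buck") {
          tt <- sub("^buck_[ABC]_", "", nm)
          which_p <- parts[2]
          ni <- (types[i] == tt) + (types[j] == tt)
          if (which_p == "B") {
            dV1[[nm]] <- dV1p$B * ni / 2
          } else {
            pt <- tab[[which_p]][match(tt, tab$types)]
            pv <- p[[which_p]]
            fac <- ifelse(.re(pv) > 0 & pt > 0, pv * (ni / 2) / pt, 0)
            v <- dV1p[[which_p]] * fac
            v[fac == 0] <- 0
            dV1[[nm]] <- v
          }
        } else if (nm == "de_alpha") dV1[[nm]] <- dV1p$alpha
        else if (nm == "de_beta") dV1[[nm]] <- dV1p$beta
        else if (nm == "sc_alpha") dV1[[nm]] <- dV1p$alpha
        else if (nm == "sc_lambda") dV1[[nm]] <- dV1p$lambda
      }
      # reaction-field electrostatics
      q <- .effective_charges(top, ff)
      qq <- q[i] * q[j]
      if (any(qq != 0)) {
        krf <- if (is.finite(ff$solvent_dielectric))
          (ff$solvent_dielectric - 1) / ((2 * ff$solvent_dielectric + 1) * ff$cutoff^3)
        else 1 / (2 * ff$cutoff^3)
        crf <- 1 / ff$cutoff + krf * ff$cutoff^2
        fq <- COULOMB_MD * qq
        V1 <- V1 + fq * (-1 / r^2 + 2 * krf * r)
        V2 <- V2 + fq * (2 / r^3 + 2 * krf)
        ce <- top$charge_entry
        if (!is.na(ce) && ce %in% param_names) {
          cc <- top$charge_coeff
          dqq <- COULOMB_MD * (cc[i] * q[j] + q[i] * cc[j])
          dV1[[ce]] <- dV1[[ce]] + dqq * (-1 / r^2 + 2 * krf * r)
        }
      }
      for (k in seq_along(i))
        add(i[k], j[k], V1[k], V2[k], lapply(dV1, `[`, k))
    }
  }
  if (!is.null(top$bonds) && nrow(top$bonds)) {
    for (bt in unique(top$bonds$type)) {
      bb <- top$bonds[top$bonds$type == bt, , drop = FALSE]
      r0 <- ff_get(ff, paste0("bond_", bt, "_r0"))
      kk <- ff_get(ff, paste0("bond_", bt, "_k"))
      d <- .pair_disp(x, bb$i, bb$j, box)
      r <- sqrt(rowSums(d^2))
      for (k in seq_len(nrow(bb))) {
        dV1 <- stats::setNames(as.list(numeric(length(param_names))), param_names)
        nr0 <- paste0("bond_", bt, "_r0"); nk <- paste0("bond_", bt, "_k")
        if (nr0 %in% param_names) dV1[[nr0]] <- -kk
        if (nk %in% param_names) dV1[[nk]] <- r[k] - r0
        add(bb$i[k], bb$j[k], kk * (r[k] - r0), kk, dV1)
      }
    }
  }
  out
}

# dense 3N x 3N force Jacobian dF/dx (pair terms + tethers; no angles)
.dense_force_jacobian <- function(x, top, ff, nl) {
  if (!is.null(top$angles) && nrow(top$angles))
    stop("dense oracle does not support angle terms")
  n <- nrow(x)
  J <- matrix(0, 3 * n, 3 * n)
  terms <- .pair_terms_dense(x, top, ff, nl)
  box <- nl$box
  for (tm in terms) {
    d <- as.numeric(.pair_disp(x, tm$i, tm$j, box))
    r <- sqrt(sum(d^2)); dh <- d / r
    K <- tm$V2 * outer(dh, dh) + (tm$V1 / r) * (diag(3) - outer(dh, dh))
    ii <- tm$i + n * (0:2); jj <- tm$j + n * (0:2)
    J[ii, ii] <- J[ii, ii] - K
    J[jj, jj] <- J[jj, jj] - K
    J[ii, jj] <- J[ii, jj] + K
    J[jj, ii] <- J[jj, ii] + K
  }
  if (!is.null(top$tethers) && nrow(top$tethers)) {
    kt <- ff_get(ff, "tether_k")
    for (i in top$tethers$i) {
      ii <- i + n * (0:2)
      J[ii, ii] <- J[ii, ii] - kt * diag(3)
    }
  }
  J
}

# dense 3N x P parameter gradient dF/dsigma
.dense_force_param_grad <- function(x, top, ff, nl, param_names = trainable_names(ff)) {
  n <- nrow(x)
  G <- matrix(0, 3 * n, length(param_names), dimnames = list(NULL, param_names))
  terms <- .pair_terms_dense(x, top, ff, nl, param_names)
  box <- nl$box
  for (tm in terms) {
    d <- as.numeric(.pair_disp(x, tm$i, tm$j, box))
    r <- sqrt(sum(d^2)); dh <- d / r
    ii <- tm$i + n * (0:2); jj <- tm$j + n * (0:2)
    for (nm in param_names) {
      dF <- -tm$dV1[[nm]] * dh          # force on i
      G[ii, nm] <- G[ii, nm] + dF
      G[jj, nm] <- G[jj, nm] - dF
    }
  }
  if ("tether_k" %in% param_names && !is.null(top$tethers) && nrow(top$tethers)) {
    anch <- .tether_anchors(top)
    for (w in seq_len(nrow(top$tethers))) {
      i <- top$tethers$i[w]
      ii <- i + n * (0:2)
      G[ii, "tether_k"] <- G[ii, "tether_k"] - (x[i, ] - anch[w, ])
    }
  }
  G
}

#' Unrolled chain-rule gradient (dense forward sensitivity)
#'
#' Ground-truth gradient for tiny systems over a few steps: propagates the
#' dense sensitivities `dx/dsigma`, `dv/dsigma` through the literally
#' unrolled Langevin middle integrator using analytic force Jacobians and
#' parameter gradients, then contracts with the loss seed at the final step.
#' This is the oracle that freezes the accumulation-recursion coefficients of
#' the reverse pass. Supports pair potentials, reaction-field electrostatics,
#' bonds and tethers (no angles).
#'
#' @param state starting `system_state`.
#' @param top,ff system description (N <= ~10 advised; cost is dense).
#' @param cfg An `integrator_config`.
#' @param n_steps number of forward steps (1-5 typical).
#' @param loss_fn function(x, v) returning list(value, gx, gv) at the final
#'   step (N x 3 matrices).
#' @param base_seed thermostat seed (match the run being checked).
#' @param nl_skin neighbour-list skin.
#' @return list with `gradient` (named numeric), `value`, `final_state`.
#' @export
unrolled_chain_rule_gradient <- function(state, top, ff, cfg, n_steps, loss_fn,
                                         base_seed = 1, nl_skin = 0.15) {
  n <- nrow(state$x)
  nms <- trainable_names(ff)
  P <- length(nms)
  Sx <- matrix(0, 3 * n, P); Sv <- matrix(0, 3 * n, P)
  mv <- rep(state$m, 3)
  ledger <- noise_ledger(base_seed, state$m, cfg$temperature)
  E <- exp(-cfg$gamma * cfg$dt); dt <- cfg$dt
  nl <- build_neighbor_list(state, top, ff$cutoff, nl_skin)
  nl$box <- state$box
  for (s in seq_len(n_steps)) {
    J <- .dense_force_jacobian(state$x, top, ff, nl)
    G <- .dense_force_param_grad(state$x, top, ff, nl, nms)
    f <- total_forces(state, top, ff, nl)
    Sa <- (J %*% Sx + G) / mv
    Sv1 <- Sv + dt * Sa
    Sxh <- Sx + (dt / 2) * Sv1
    Sv <- E * Sv1
    Sx <- Sxh + (dt / 2) * Sv
    state <- forward_step(state, f$forces, cfg, ledger)
    if (state$step %% 10 == 0) {
      nl <- build_neighbor_list(state, top, ff$cutoff, nl_skin)
      nl$box <- state$box
    }
  }
  lo <- loss_fn(state$x, state$v)
  g <- drop(crossprod(Sx, as.numeric(lo$gx)) + crossprod(Sv, as.numeric(lo$gv)))
  list(gradient = stats::setNames(as.numeric(g), nms), value = lo$value,
       final_state = state)
}
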