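#' Enthalpy of vapourisation
#'
#' `H_vap = U_gas - (U_liquid + correction) / n_molecules + R T` with
#' `R = kB` in kJ mol^-1 K^-1. The correction (default +2.8 kJ/mol on the
#' liquid potential energy) compensates for simulating water with flexible
#' bonds and angles while experimental reference models constrain them.
#'
#' @param liquid_potential_energy total liquid-box potential energy (kJ/mol).
#' @param n_molecules number of molecules in the liquid box.
#' @param gas_potential_energy single-molecule gas-phase potential energy
#'   (kJ/mol), pre-computed once and treated as constant during training.
#' @param temperature K.
#' @param constraint_correction kJ/mol added to the liquid potential energy.
#' @return H_vap in kJ/mol.
#' @export
enthalpy_of_vaporisation <- function(liquid_potential_energy, n_molecules,
                                     gas_potential_energy = 0,
                                     temperature = 295.15,
                                     constraint_correction = 2.8) {
  if (n_molecules < 1) stop("need at least one molecule")
  gas_potential_energy -
    (liquid_potential_energy + constraint_correction) / n_molecules +
    kB_MD * temperature
}

#' Enthalpy-of-vapourisation training loss
#'
#' Mean squared error of the per-snapshot enthalpy of vapourisation against
#' the experimental target (default 44.12 kJ/mol), averaged over the
#' snapshots of a forward record. Emits one loss seed per snapshot with
#' `dl/dx = (2/K) (H - target) F / n` (the recorded forces are `-dU/dx`) and
#' the direct parameter term through `dU_liquid/dsigma`; the gas term is a
#' pre-computed constant so contributes no seed.
#'
#' @param record forward record with snapshots.
#' @param top,ff topology and force field.
#' @param n_molecules molecules in the box.
#' @param gas_potential_energy constant gas-phase energy (kJ/mol).
#' @param target experimental H_vap (kJ/mol).
#' @param constraint_correction kJ/mol (see [enthalpy_of_vaporisation()]).
#' @return list with `value`, `seeds`, and the per-snapshot `h_vap` values.
#' @export
hvap_loss <- function(record, top, ff, n_molecules, gas_potential_energy = 0,
                      target = 44.12, constraint_correction = 2.8) {
  snaps <- record$snapshots
  if (!length(snaps)) stop("record has no snapshots")
  K <- length(snaps)
  Tk <- record$cfg$temperature
  nms <- trainable_names(ff)
  hv <- numeric(K); seeds <- vector("list", K); val <- 0
  for (s in seq_len(K)) {
    sn <- snaps[[s]]
    h <- enthalpy_of_vaporisation(sn$potential_energy, n_molecules,
                                  gas_potential_energy, Tk, constraint_correction)
    hv[s] <- h
    val <- val + (h - target)^2 / K
    st <- record$final_state
    st$x <- sn$x; st$v <- sn$v; st$step <- sn$step
    nl <- build_neighbor_list(st, top, ff$cutoff, record$nl_skin)
    dU <- energy_param_grad(st, top, ff, nl)
    seeds[[s]] <- loss_seed(sn$step,
                            dl_dx = (2 / K) * (h - target) * sn$forces / n_molecules,
                            dl_dsigma_direct = -(2 / K) * (h - target) * dU / n_molecules)
  }
  list(value = val, seeds = seeds, h_vap = hv)
}

#' Select nonbonded pairs between two atom types
#'
#' All unordered pairs with one atom of each type, excluding intramolecular
#' pairs. Used for radial distribution functions.
#'
#' @param top A `topology`.
#' @param type_a,type_b atom type labels (may be equal).
#' @return P x 2 integer matrix of pair indices.
#' @export
select_pairs <- function(top, type_a, type_b) {
  ia <- which(top$atom_types == type_a)
  ib <- which(top$atom_types == type_b)
  if (!length(ia) || !length(ib)) stop("no atoms of the requested types")
  if (type_a == type_b) {
    pr <- t(utils::combn(ia, 2))
  } else {
    pr <- as.matrix(expand.grid(i = ia, j = ib))
    sw <- pr[, 1] > pr[, 2]
    pr[sw, ] <- pr[sw, 2:1]
    pr <- unique(pr)
  }
  n <- length(top$atom_types)
  keys <- pr[, 1] * (n + 1) + pr[, 2]
  pr <- pr[!(keys %in% top$exclusions), , drop = FALSE]
  pr[order(pr[, 1], pr[, 2]), , drop = FALSE]
}

#' Differentiable radial distribution function
#'
#' Gaussian-kernel RDF: every pair distance deposits a normalised Gaussian of
#' width `kernel_width` onto the grid, and each bin is normalised by the
#' ideal-gas shell expectation `N_pairs 4 pi r^2 / V` so a uniform fluid
#' gives g(r) of about 1. Smooth in the coordinates; when `dl_dg` is given,
#' the exact coordinate gradient of `sum(dl_dg * g)` is returned as well.
#'
#' @param state A `system_state`.
#' @param pairs P x 2 pair index matrix (see [select_pairs()]).
#' @param r_grid strictly increasing, uniformly spaced bin centres (nm),
#'   within (0, min(box)/2).
#' @param kernel_width Gaussian kernel standard deviation (nm).
#' @param dl_dg optional per-bin weights for the coordinate gradient.
#' @return list with `g` (and `dl_dx`, an N x 3 matrix, when `dl_dg` given).
#' @export
differentiable_rdf <- function(state, pairs, r_grid, kernel_width = 0.01,
                               dl_dg = NULL) {
  if (!nrow(pairs)) stop("empty pair selection")
  if (kernel_width <= 0) stop("kernel_width must be positive")
  if (any(diff(r_grid) <= 0)) stop("r_grid must be strictly increasing")
  if (max(r_grid) >= min(state$box) / 2)
    stop("r_grid must stay below half the smallest box edge")
  V <- prod(state$box)
  d <- .pair_disp(state$x, pairs[, 1], pairs[, 2], state$box)
  r <- sqrt(rowSums(d^2))
  # only pairs within 5 kernel widths of the grid contribute
  keep <- r > min(r_grid) - 5 * kernel_width & r < max(r_grid) + 5 * kernel_width
  norm <- V / (nrow(pairs) * 4 * pi * r_grid^2)
  if (!any(keep)) {
    g <- numeric(length(r_grid))
    out <- list(g = g)
    if (!is.null(dl_dg)) out$dl_dx <- matrix(0, nrow(state$x), 3)
    return(out)
  }
  rk <- r[keep]
  z <- outer(rk, r_grid, function(a, b) (b - a) / kernel_width)
  phi <- exp(-z^2 / 2) / (kernel_width * sqrt(2 * pi))   # pairs x bins
  g <- colSums(phi) * norm
  out <- list(g = g)
  if (!is.null(dl_dg)) {
    # d g_b / d r_p = norm_b * phi * z / w ; chain through r to coordinates
    coeff <- ((phi * z) %*% (dl_dg * norm)) / kernel_width
    dk <- d[keep, , drop = FALSE]
    grad_pairs <- dk * as.numeric(coeff) / rk
    dl_dx <- matrix(0, nrow(state$x), 3)
    dl_dx <- .accum_forces(dl_dx, pairs[keep, 1], grad_pairs)
    dl_dx <- .accum_forces(dl_dx, pairs[keep, 2], -grad_pairs)
    out$dl_dx <- dl_dx
  }
  out
}

#' RDF loss: sum of absolute differences
#'
#' `sum_b |g_sim(b) - g_ref(b)|` on a shared grid. The subgradient at exact
#' ties is taken as 0.
#'
#' @param g_sim simulated g(r) on the reference grid.
#' @param reference list with `r` and `g` (see [read_rdf_reference()]).
#' @return list with `value` and `dl_dg` (the per-bin subgradient).
#' @export
rdf_loss <- function(g_sim, reference) {
  if (length(g_sim) != length(reference$g))
    stop("grid mismatch between simulated and reference RDF")
  dd <- g_sim - reference$g
  list(value = sum(abs(dd)), dl_dg = sign(dd))
}

#' RDF training loss over a forward record
#'
#' Averages the differentiable RDF over the record's snapshots, applies
#' [rdf_loss()] against the reference, and emits one coordinate seed per
#' snapshot (each scaled by 1/K).
#'
#' @param record forward record.
#' @param top A `topology`.
#' @param ff force field (unused in the value; kept for interface symmetry).
#' @param reference list with `r`, `g` and `pair_types` (length-2 character).
#' @param kernel_width Gaussian kernel width (nm).
#' @return list with `value`, `seeds`, `g_mean`.
#' @export
rdf_training_loss <- function(record, top, ff, reference, kernel_width = 0.01) {
  snaps <- record$snapshots
  if (!length(snaps)) stop("record has no snapshots")
  K <- length(snaps)
  pairs <- select_pairs(top, reference$pair_types[1], reference$pair_types[2])
  st <- record$final_state
  gs <- matrix(0, K, length(reference$r))
  for (s in seq_len(K)) {
    st$x <- snaps[[s]]$x
    gs[s, ] <- differentiable_rdf(st, pairs, reference$r, kernel_width)$g
  }
  g_mean <- colMeans(gs)
  rl <- rdf_loss(g_mean, reference)
  seeds <- vector("list", K)
  for (s in seq_len(K)) {
    st$x <- snaps[[s]]$x
    dd <- differentiable_rdf(st, pairs, reference$r, kernel_width,
                             dl_dg = rl$dl_dg / K)
    seeds[[s]] <- loss_seed(snaps[[s]]$step, dl_dx = dd$dl_dx)
  }
  list(value = rl$value, seeds = seeds, g_mean = g_mean)
}

#' Diffusion coefficient from the mean squared displacement
#'
#' Einstein relation: the MSD of the tagged particles is averaged over all
#' time segments of length half the trajectory (all possible starts), and
#' divided by 6 times the segment time. Input positions must be unwrapped;
#' a frame-to-frame jump larger than half a box edge triggers an error.
#' 1 nm^2/ps = 1e-6 m^2/s.
#'
#' @param frames list of M x 3 matrices (unwrapped tagged positions, nm),
#'   one per stored frame.
#' @param frame_dt time between frames (ps).
#' @param box optional box edges for the wrapped-input check.
#' @return list with `D` (m^2 s^-1), `msd` (nm^2), `segment_time` (ps).
#' @export
msd_diffusion <- function(frames, frame_dt, box = NULL) {
  nf <- length(frames)
  if (nf < 2) stop("need at least two frames")
  if (!is.null(box)) {
    for (f in 2:nf) {
      jump <- abs(frames[[f]] - frames[[f - 1]])
      if (any(sweep(jump, 2, box / 2, ">")))
        stop("frame-to-frame displacement exceeds half the box: positions must be unwrapped")
    }
  }
  L <- floor(nf / 2)
  starts <- seq_len(nf - L)
  msd <- mean(vapply(starts, function(s0)
    mean(rowSums((frames[[s0 + L]] - frames[[s0]])^2)), numeric(1)))
  t_seg <- L * frame_dt
  list(D = msd / (6 * t_seg) * 1e-6, msd = msd, segment_time = t_seg)
}

# dD/dx per frame (list of M x 3 matrices, in m^2 s^-1 per nm)
.msd_diffusion_grad <- function(frames, frame_dt) {
  nf <- length(frames)
  L <- floor(nf / 2)
  starts <- seq_len(nf - L)
  M <- nrow(frames[[1]])
  gr <- lapply(frames, function(f) matrix(0, M, 3))
  cc <- 1e-6 / (6 * L * frame_dt * length(starts) * M)
  for (s0 in starts) {
    dd <- 2 * (frames[[s0 + L]] - frames[[s0]])
    gr[[s0 + L]] <- gr[[s0 + L]] + cc * dd
    gr[[s0]] <- gr[[s0]] - cc * dd
  }
  gr
}

#' Gas diffusion training loss
#'
#' Squared deviation of the Einstein-relation diffusion coefficient of the
#' tagged molecules from an experimental target, scaled by `weight`
#' (default 1e18, bringing the squared m^2/s deviation to order one). The
#' MSD couples many time points, so one coordinate seed is emitted per
#' contributing frame; each seed gets its own independently truncated
#' accumulation state in [compute_loss_gradient()]. Tagged molecule
#' positions are centres of mass; the chain rule spreads each seed over the
#' molecule's atoms by mass fraction.
#'
#' @param record forward record whose snapshots are the MSD frames.
#' @param top topology with `tagged_molecules`.
#' @param target experimental D (m^2 s^-1).
#' @param weight loss scale.
#' @return list with `value`, `seeds`, `D`.
#' @export
diffusion_loss <- function(record, top, target = 2.0e-9, weight = 1e18) {
  snaps <- record$snapshots
  if (length(snaps) < 2) stop("need at least two snapshots")
  tm <- top$tagged_molecules
  if (is.null(tm) || !length(tm)) stop("topology has no tagged molecules")
  m <- record$final_state$m
  com <- function(x) t(vapply(tm, function(idx)
    colSums(x[idx, , drop = FALSE] * m[idx]) / sum(m[idx]), numeric(3)))
  frames <- lapply(snaps, function(s) com(s$x))
  est <- msd_diffusion(frames, diff(vapply(snaps[1:2], `[[`, integer(1), "step")) * record$cfg$dt)
  dd <- 2 * weight * (est$D - target)
  gr <- .msd_diffusion_grad(frames, diff(vapply(snaps[1:2], `[[`, integer(1), "step")) * record$cfg$dt)
  n <- nrow(record$final_state$x)
  seeds <- vector("list", length(snaps))
  for (f in seq_along(snaps)) {
    dl <- matrix(0, n, 3)
    for (w in seq_along(tm)) {
      idx <- tm[[w]]
      dl[idx, ] <- dl[idx, ] + outer(m[idx] / sum(m[idx]), dd * gr[[f]][w, ])
    }
    seeds[[f]] <- loss_seed(snaps[[f]]$step, dl_dx = dl)
  }
  list(value = weight * (est$D - target)^2, seeds = seeds, D = est$D)
}

#' Combine weighted loss components
#'
#' Weighted sum of loss values; seeds are scaled by the component weights and
#' seeds landing on the same step are merged by addition (all seed fields are
#' linear in the loss).
#'
#' @param components list of loss results, each a list with `value` and
#'   `seeds`.
#' @param weights numeric vector of multipliers, one per component.
#' @return list with `value` and merged `seeds`.
#' @export
combine_losses <- function(components, weights = rep(1, length(components))) {
  if (length(weights) != length(components)) stop("one weight per component")
  if (any(weights < 0)) stop("weights must be >= 0")
  value <- 0
  pool <- list()
  for (ci in seq_along(components)) {
    comp <- components[[ci]]; w <- weights[ci]
    value <- value + w * comp$value
    for (sd in comp$seeds) {
      key <- as.character(sd$step)
      if (is.null(pool[[key]])) {
        sd$dl_dx <- w * sd$dl_dx; sd$dl_dv <- w * sd$dl_dv
        if (!is.null(sd$dl_dsigma_direct)) sd$dl_dsigma_direct <- w * sd$dl_dsigma_direct
        pool[[key]] <- sd
      } else {
        pool[[key]]$dl_dx <- pool[[key]]$dl_dx + w * sd$dl_dx
        pool[[key]]$dl_dv <- pool[[key]]$dl_dv + w * sd$dl_dv
        if (!is.null(sd$dl_dsigma_direct)) {
          cur <- pool[[key]]$dl_dsigma_direct
          if (is.null(cur)) cur <- 0 * sd$dl_dsigma_direct
          pool[[key]]$dl_dsigma_direct <- cur + w * sd$dl_dsigma_direct
        }
      }
    }
  }
  ord <- order(as.integer(names(pool)))
  list(value = value, seeds = unname(pool[ord]))
}
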