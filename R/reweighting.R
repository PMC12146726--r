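#' Snapshot ensemble for reweighting
#'
#' Equilibrium frames with per-frame observable values and per-parameter
#' energy gradients, the ingredients of the fluctuation formula.
#'
#' @param observables F x B matrix (frames x observables).
#' @param dE_dsigma F x P matrix of per-frame `dU/dsigma`.
#' @param temperature K.
#' @param dO_dsigma_direct optional B x P matrix of explicit observable
#'   parameter dependence (zero for purely structural observables).
#' @return An object of class `snapshot_ensemble`.
#' @export
snapshot_ensemble <- function(observables, dE_dsigma, temperature,
                              dO_dsigma_direct = NULL) {
  observables <- as.matrix(observables)
  dE_dsigma <- as.matrix(dE_dsigma)
  if (nrow(observables) < 2) stop("need at least two frames (covariance undefined)")
  if (nrow(observables) != nrow(dE_dsigma)) stop("frame count mismatch")
  structure(list(O = observables, dE = dE_dsigma, temperature = temperature,
                 dO_direct = dO_dsigma_direct),
            class = "snapshot_ensemble")
}

#' Ensemble-reweighting gradient of equilibrium averages
#'
#' The fluctuation formula behind ForceBalance-style parameter fitting:
#' `d<O>/dsigma = <dO/dsigma> - beta (<O dE/dsigma> - <O><dE/dsigma>)` with
#' `beta = 1/(kB T)`. Applicable to time-independent observables only.
#'
#' @param ens A `snapshot_ensemble`.
#' @return B x P matrix of `d<O>/dsigma`.
#' @export
reweighting_gradient <- function(ens) {
  beta <- 1 / (kB_MD * ens$temperature)
  nf <- nrow(ens$O)
  Obar <- colMeans(ens$O)
  dEbar <- colMeans(ens$dE)
  cross <- crossprod(ens$O, ens$dE) / nf          # <O dE>
  fluct <- -beta * (cross - outer(Obar, dEbar))
  if (!is.null(ens$dO_direct)) fluct <- fluct + ens$dO_direct
  fluct
}

#' Build a snapshot ensemble from a forward record
#'
#' Evaluates an observable function and the analytic `dU/dsigma` on every
#' recorded snapshot.
#'
#' @param record forward record from [run_forward()].
#' @param top,ff topology and force field.
#' @param obs_fn function(state, top, ff) returning a numeric observable
#'   vector for one frame.
#' @return A `snapshot_ensemble`.
#' @export
ensemble_from_record <- function(record, top, ff, obs_fn) {
  snaps <- record$snapshots
  if (length(snaps) < 2) stop("need at least two snapshots")
  st <- record$final_state
  nms <- trainable_names(ff)
  O <- NULL
  dE <- matrix(0, length(snaps), length(nms), dimnames = list(NULL, nms))
  for (s in seq_along(snaps)) {
    st$x <- snaps[[s]]$x; st$v <- snaps[[s]]$v; st$step <- snaps[[s]]$step
    nl <- build_neighbor_list(st, top, ff$cutoff, record$nl_skin)
    ob <- obs_fn(st, top, ff)
    if (is.null(O)) O <- matrix(0, length(snaps), length(ob))
    O[s, ] <- ob
    dE[s, ] <- energy_param_grad(st, top, ff, nl)
  }
  snapshot_ensemble(O, dE, record$cfg$temperature)
}

#' Loss gradient by ensemble reweighting
#'
#' Chains a loss on mean observables through [reweighting_gradient()]:
#' `dl/dsigma = dl/d<O> . d<O>/dsigma (+ explicit dl/dsigma)`.
#'
#' @param ens A `snapshot_ensemble`.
#' @param loss_from_mean_obs function(mean_obs) returning a list with
#'   `value` and `grad` (dl/d<O>), and optionally `dl_dsigma_direct`.
#' @return A `gradient_report`-compatible list with `dl_dsigma` and `value`.
#' @export
reweighting_loss_gradient <- function(ens, loss_from_mean_obs) {
  lo <- loss_from_mean_obs(colMeans(ens$O))
  dOds <- reweighting_gradient(ens)
  g <- drop(crossprod(dOds, lo$grad))
  if (!is.null(lo$dl_dsigma_direct)) g <- g + lo$dl_dsigma_direct
  structure(list(dl_dsigma = g, value = lo$value, per_seed = list(),
                 fraction_walked = NA_real_),
            class = "gradient_report")
}
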