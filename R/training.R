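#' Adam optimiser state
#'
#' @param param_names parameter names (normalised space).
#' @param learning_rate step size.
#' @param beta1,beta2,eps standard Adam constants.
#' @return An object of class `optimizer_state`.
#' @export
optimizer_state <- function(param_names, learning_rate = 2e-3,
                            beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  z <- stats::setNames(numeric(length(param_names)), param_names)
  structure(list(m = z, v = z, t = 0L, learning_rate = learning_rate,
                 beta1 = beta1, beta2 = beta2, eps = eps),
            class = "optimizer_state")
}

#' Scale a gradient to normalised parameter space and clip it
#'
#' Training optimises `theta_j = sigma_j / sigma_j(0)` so parameters of very
#' different magnitudes take comparable steps; by the chain rule the
#' normalised gradient is `g_j * sigma_j(0)`. Each component is then clamped
#' to `[-clip, clip]` (default 1000).
#'
#' @param gradient named numeric (raw dl/dsigma) or a `gradient_report`.
#' @param ff the `force_field` (provides starting values).
#' @param clip maximum gradient magnitude per parameter.
#' @return named numeric gradient in normalised space.
#' @export
scale_and_clip <- function(gradient, ff, clip = 1000) {
  if (inherits(gradient, "gradient_report")) gradient <- gradient$dl_dsigma
  s0 <- stats::setNames(ff$entries$starting_value, ff$entries$name)[names(gradient)]
  if (any(s0 == 0)) stop("zero starting value: parameter scaling undefined")
  pmin(pmax(gradient * s0, -clip), clip)
}

#' One Adam update
#'
#' Textbook Adam with bias correction. Returns the additive step in
#' normalised parameter space (apply as `sigma <- sigma + step * sigma0`).
#'
#' @param opt An `optimizer_state`.
#' @param grad named numeric gradient in normalised space.
#' @return list with the updated `opt` and the named `step`.
#' @export
adam_update <- function(opt, grad) {
  opt$t <- opt$t + 1L
  opt$m <- opt$beta1 * opt$m + (1 - opt$beta1) * grad
  opt$v <- opt$beta2 * opt$v + (1 - opt$beta2) * grad^2
  mhat <- opt$m / (1 - opt$beta1^opt$t)
  vhat <- opt$v / (1 - opt$beta2^opt$t)
  step <- -opt$learning_rate * mhat / (sqrt(vhat) + opt$eps)
  list(opt = opt, step = step)
}

#' Training configuration
#'
#' Epoch structure mirrors the training protocol: each epoch builds (or
#' perturbs) the system, equilibrates, runs a production simulation with
#' snapshots, computes the loss gradient with the chosen method, scales and
#' clips it, and applies one Adam update.
#'
#' @param epochs number of epochs.
#' @param equilibration_steps,production_steps integrator steps per phase.
#' @param snapshot_every production snapshot interval (steps).
#' @param dt,gamma,temperature integrator settings.
#' @param learning_rate Adam step size.
#' @param clip gradient clip magnitude (normalised space).
#' @param truncation_window reverse-accumulation truncation (steps).
#' @param checkpoint_interval checkpoint spacing (steps).
#' @param base_seed integer; epoch e uses thermostat seed `base_seed + e`.
#' @param nl_skin neighbour-list skin (nm).
#' @return An object of class `training_config`.
#' @export
training_config <- function(epochs, equilibration_steps, production_steps,
                            snapshot_every, dt = 0.001, gamma = 1,
                            temperature = 295.15, learning_rate = 2e-3,
                            clip = 1000, truncation_window = 200L,
                            checkpoint_interval = max(1L, round(1 / dt)),
                            base_seed = 1, nl_skin = 0.15) {
  stopifnot(epochs >= 1, production_steps >= 1, snapshot_every >= 1)
  structure(as.list(environment()), class = "training_config")
}

#' Run a training loop
#'
#' `problem` describes the task:
#' \describe{
#'  \item{make_system(seed, ff)}{returns list(state, top) for one epoch.}
#'  \item{loss_fn(record, top, ff)}{returns list(value, seeds) — used by the
#'    reversible-simulation method.}
#'  \item{obs_fn(state, top, ff), loss_from_mean_obs(mean_obs)}{per-frame
#'    observable vector and loss on its ensemble mean — used by the
#'    ensemble-reweighting method.}
#' }
#' An epoch whose simulation goes unstable is skipped with a logged
#' diagnostic and the parameters left unchanged.
#'
#' @param problem list as described above.
#' @param ff starting `force_field` (trainable entries are optimised).
#' @param cfg A `training_config`.
#' @param method "reversible" or "reweighting".
#' @param verbose print per-epoch progress.
#' @return list with the trained `ff` and a per-epoch data.frame `log`
#'   (loss, parameter values, gradient norm, skipped flag).
#' @export
run_training <- function(problem, ff, cfg, method = c("reversible", "reweighting"),
                         verbose = FALSE) {
  method <- match.arg(method)
  nms <- trainable_names(ff)
  opt <- optimizer_state(nms, cfg$learning_rate)
  icfg <- integrator_config(cfg$dt, cfg$gamma, cfg$temperature)
  logs <- vector("list", cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    res <- tryCatch({
      sys <- problem$make_system(cfg$base_seed + ep, ff)
      eq <- run_forward(sys$state, sys$top, ff, icfg, cfg$equilibration_steps,
                        base_seed = cfg$base_seed + 7919 * ep,
                        checkpoint_interval = cfg$checkpoint_interval,
                        nl_skin = cfg$nl_skin)
      st <- eq$final_state
      snap_steps <- seq(st$step + cfg$snapshot_every,
                        st$step + cfg$production_steps, by = cfg$snapshot_every)
      rec <- run_forward(st, sys$top, ff, icfg, cfg$production_steps,
                         base_seed = cfg$base_seed + 7919 * ep + 1,
                         snapshot_steps = snap_steps,
                         checkpoint_interval = cfg$checkpoint_interval,
                         nl_skin = cfg$nl_skin)
      if (method == "reversible") {
        lo <- problem$loss_fn(rec, sys$top, ff)
        gr <- compute_loss_gradient(rec, lo$seeds, sys$top, ff,
                                    truncation_window = cfg$truncation_window)
        list(value = lo$value, grad = gr$dl_dsigma)
      } else {
        ens <- ensemble_from_record(rec, sys$top, ff, problem$obs_fn)
        gr <- reweighting_loss_gradient(ens, problem$loss_from_mean_obs)
        list(value = gr$value, grad = gr$dl_dsigma[nms])
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      logs[[ep]] <- data.frame(epoch = ep, loss = NA_real_, grad_norm = NA_real_,
                               skipped = TRUE, t(ff_values(ff)[nms]))
      if (verbose) message(sprintf("epoch %d skipped: %s", ep, conditionMessage(res)))
      next
    }
    g <- scale_and_clip(res$grad, ff, cfg$clip)
    au <- adam_update(opt, g)
    opt <- au$opt
    s0 <- stats::setNames(ff$entries$starting_value, ff$entries$name)[nms]
    vals <- ff_values(ff)[nms] + au$step * s0
    for (nm in nms) ff <- ff_set(ff, nm, vals[[nm]])
    logs[[ep]] <- data.frame(epoch = ep, loss = res$value,
                             grad_norm = sqrt(sum(g^2)), skipped = FALSE,
                             t(ff_values(ff)[nms]))
    if (verbose)
      message(sprintf("epoch %3d loss %.6g |g| %.3g", ep, res$value, sqrt(sum(g^2))))
  }
  list(ff = ff, log = do.call(rbind, logs))
}

#' Steepest-descent energy minimisation
#'
#' Backtracking line search on the total potential energy until the maximum
#' force component falls below `tol` (default 10 kJ mol^-1 nm^-1) or
#' `max_iter` is reached. Used after molecule insertion.
#'
#' @param state,top,ff system description.
#' @param tol force tolerance (kJ mol^-1 nm^-1).
#' @param max_iter iteration cap.
#' @param nl_skin neighbour-list skin (nm).
#' @return The minimised `system_state`.
#' @export
minimise_energy <- function(state, top, ff, tol = 10, max_iter = 500,
                            nl_skin = 0.15) {
  nl <- build_neighbor_list(state, top, ff$cutoff, nl_skin)
  f <- total_forces(state, top, ff, nl)
  step <- 0.01
  for (it in seq_len(max_iter)) {
    if (max(abs(f$forces)) < tol) break
    dir <- f$forces / max(abs(f$forces))
    repeat {
      trial <- state
      trial$x <- state$x + step * dir
      nl2 <- build_neighbor_list(trial, top, ff$cutoff, nl_skin)
      f2 <- tryCatch(total_forces(trial, top, ff, nl2), error = function(e) NULL)
      if (!is.null(f2) && f2$potential_energy < f$potential_energy) {
        state <- trial; nl <- nl2; f <- f2
        step <- min(step * 1.2, 0.05)
        break
      }
      step <- step / 2
      if (step < 1e-8) return(state)
    }
  }
  state
}
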