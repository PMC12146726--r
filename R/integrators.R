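#' Integrator configuration
#'
#' Time step, collision frequency and thermostat temperature for the Langevin
#' middle integrator. `gamma = 0` gives the leapfrog Verlet special case (no
#' friction, no noise).
#'
#' @param dt time step (ps).
#' @param gamma collision frequency (ps^-1), >= 0.
#' @param temperature thermostat temperature (K).
#' @return An object of class `integrator_config`.
#' @export
integrator_config <- function(dt, gamma = 1, temperature = 295.15) {
  if (dt <= 0) stop("dt must be positive")
  if (gamma < 0) stop("gamma must be >= 0")
  structure(list(dt = dt, gamma = gamma, temperature = temperature),
            class = "integrator_config")
}

#' Thermostat noise ledger
#'
#' Deterministic per-step noise: each step's random velocities are generated
#' from an integer seed derived from a stored base seed and the step index,
#' so the reverse pass regenerates bit-identical noise without storing any
#' arrays. Component standard deviation is the Boltzmann velocity scale
#' `sqrt(kB T / m)` per atom.
#'
#' @param base_seed integer base seed.
#' @param masses length-N masses (g/mol).
#' @param temperature thermostat temperature (K).
#' @return An object of class `noise_ledger` with a `regenerate(step)`
#'   function returning the N x 3 noise matrix for that step.
#' @export
noise_ledger <- function(base_seed, masses, temperature) {
  base_seed <- as.numeric(base_seed) %% 2147483647
  n <- length(masses)
  sd_atom <- sqrt(kB_MD * temperature / masses)
  regenerate <- function(step) {
    s <- (base_seed * 69069 + as.numeric(step) * 1234567) %% 2147483647
    old <- get0(".Random.seed", globalenv())
    set.seed(as.integer(s))
    z <- matrix(stats::rnorm(3 * n), n, 3)
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    z * sd_atom
  }
  structure(list(base_seed = base_seed, n_atoms = n, sd_atom = sd_atom,
                 temperature = temperature, regenerate = regenerate),
            class = "noise_ledger")
}

#' Checkpoint store
#'
#' Periodic exact snapshots of positions and velocities written by the
#' forward pass and used by the reverse pass to reset drift. Restoration is
#' bit-identical.
#'
#' @param interval_steps spacing between checkpoints in integrator steps
#'   (default corresponds to 1 ps at the configured time step).
#' @return An object of class `checkpoint_store`.
#' @export
checkpoint_store <- function(interval_steps) {
  structure(list(interval = as.integer(interval_steps), entries = new.env(parent = emptyenv())),
            class = "checkpoint_store")
}

#' @rdname checkpoint_store
#' @param store A `checkpoint_store`.
#' @param step step index at which a checkpoint exists.
#' @return `restore_checkpoint`: the stored `system_state`.
#' @export
restore_checkpoint <- function(store, step) {
  key <- as.character(step)
  if (!nchar(key) || !exists(key, envir = store$entries, inherits = FALSE)) {
    have <- as.integer(ls(store$entries))
    have <- have[have <= step]
    if (!length(have)) stop("no checkpoint at or below step ", step)
    key <- as.character(max(have))
  }
  get(key, envir = store$entries, inherits = FALSE)
}

.store_checkpoint <- function(store, state) {
  assign(as.character(state$step), state, envir = store$entries)
}

#' One forward Langevin middle step
#'
#' Applies, in order: a full-step velocity kick from the forces, a half-step
#' position drift, the thermostat scaling `exp(-gamma dt)` plus
#' Boltzmann-scale random velocities, and the second half-step drift.
#' Velocities are half-step offset from positions; positions are kept
#' unwrapped.
#'
#' @param state `system_state` at step i (forces evaluated at its positions).
#' @param forces N x 3 force matrix at the current positions.
#' @param cfg An `integrator_config`.
#' @param ledger A `noise_ledger` (ignored when `gamma = 0`).
#' @return The `system_state` at step i + 1.
#' @export
forward_step <- function(state, forces, cfg, ledger = NULL) {
  dt <- cfg$dt
  v1 <- state$v + dt * forces / state$m
  xh <- state$x + (dt / 2) * v1
  if (cfg$gamma > 0) {
    if (is.null(ledger)) stop("gamma > 0 requires a noise ledger")
    E <- exp(-cfg$gamma * dt)
    v2 <- E * v1 + sqrt(1 - E^2) * ledger$regenerate(state$step)
  } else v2 <- v1
  x2 <- xh + (dt / 2) * v2
  if (!all(is.finite(x2)) || !all(is.finite(v2)))
    stop(sprintf("integration unstable at step %d", state$step))
  state$x <- x2; state$v <- v2; state$step <- state$step + 1L
  state
}

#' One reverse Langevin middle step
#'
#' Algebraic inverse of [forward_step()]: undo the second half drift, invert
#' the thermostat line with `exp(+gamma dt)` and the regenerated noise of the
#' previous step, undo the first half drift, then recompute the forces at the
#' recovered positions to undo the velocity kick. Not bitwise reversible
#' (floating-point order differs), hence the periodic checkpoint resets in
#' [compute_loss_gradient()].
#'
#' @param state `system_state` at step i.
#' @param top,ff topology and force field (forces are re-evaluated at the
#'   recovered positions).
#' @param cfg An `integrator_config`.
#' @param ledger the `noise_ledger` of the forward pass.
#' @param nl current `neighbor_list`.
#' @return list with `state` (the `system_state` at step i - 1) and `forces`
#'   (the forces at its positions, reusable by the caller).
#' @export
reverse_step <- function(state, top, ff, cfg, ledger, nl) {
  dt <- cfg$dt
  xh <- state$x - (dt / 2) * state$v
  if (cfg$gamma > 0) {
    if (is.null(ledger)) stop("missing noise ledger for reverse step")
    E <- exp(-cfg$gamma * dt)
    v1 <- exp(cfg$gamma * dt) * (state$v - sqrt(1 - E^2) * ledger$regenerate(state$step - 1L))
  } else v1 <- state$v
  xp <- xh - (dt / 2) * v1
  state$x <- xp
  state$step <- state$step - 1L
  f <- total_forces(state, top, ff, nl)
  state$v <- v1 - dt * f$forces / state$m
  list(state = state, forces = f)
}

#' Run the forward simulation
#'
#' Advances the system `n_steps` steps, rebuilding the neighbour list every
#' `nl_every` steps, writing checkpoints every `checkpoint_interval` steps
#' and recording loss-relevant snapshots (positions, velocities, potential
#' energy, forces) at `snapshot_steps`.
#'
#' @param state starting `system_state`.
#' @param top,ff topology and force field.
#' @param cfg An `integrator_config`.
#' @param n_steps number of steps (>= 0).
#' @param base_seed integer seed for the thermostat noise ledger.
#' @param snapshot_steps integer vector of absolute step indices to record.
#' @param checkpoint_interval steps between checkpoints (default 1 ps).
#' @param nl_every neighbour-list rebuild interval (steps).
#' @param nl_skin neighbour-list skin (nm).
#' @return A forward record: list with `final_state`, `snapshots` (list of
#'   step-stamped records), `checkpoints`, `ledger`, `cfg`, plus the
#'   neighbour-list settings needed to replay the trajectory.
#' @export
run_forward <- function(state, top, ff, cfg, n_steps, base_seed = 1,
                        snapshot_steps = integer(0),
                        checkpoint_interval = max(1L, round(1 / cfg$dt)),
                        nl_every = 10L, nl_skin = 0.15) {
  ledger <- noise_ledger(base_seed, state$m, cfg$temperature)
  store <- checkpoint_store(checkpoint_interval)
  snapshot_steps <- sort(unique(as.integer(snapshot_steps)))
  snaps <- list()
  nl <- build_neighbor_list(state, top, ff$cutoff, nl_skin)
  record_snap <- function(state, f) {
    list(step = state$step, x = state$x, v = state$v,
         potential_energy = f$potential_energy, forces = f$forces)
  }
  if (state$step %% checkpoint_interval == 0) .store_checkpoint(store, state)
  f <- total_forces(state, top, ff, nl)
  if (state$step %in% snapshot_steps) snaps[[length(snaps) + 1L]] <- record_snap(state, f)
  if (n_steps >= 1) for (s in seq_len(n_steps)) {
    state <- forward_step(state, f$forces, cfg, ledger)
    if (state$step %% nl_every == 0)
      nl <- build_neighbor_list(state, top, ff$cutoff, nl_skin)
    f <- total_forces(state, top, ff, nl)
    if (state$step %% checkpoint_interval == 0) .store_checkpoint(store, state)
    if (state$step %in% snapshot_steps) snaps[[length(snaps) + 1L]] <- record_snap(state, f)
  }
  list(final_state = state, snapshots = snaps, checkpoints = store,
       ledger = ledger, cfg = cfg, n_steps = n_steps, base_seed = base_seed,
       nl_every = nl_every, nl_skin = nl_skin)
}
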