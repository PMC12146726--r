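#' Create a periodic system state
#'
#' The object advanced by the integrators: atomic positions, half-step-offset
#' velocities, masses and an orthorhombic periodic box. Positions are stored
#' unwrapped (continuous) so that reverse-time integration is exact and mean
#' squared displacements are well defined; use [wrapped_positions()] for the
#' in-box copy.
#'
#' @param positions N x 3 numeric matrix, nm.
#' @param velocities N x 3 numeric matrix, nm/ps, defined half a time step
#'   behind the positions (leapfrog offset).
#' @param masses length-N numeric, g/mol.
#' @param box length-3 numeric, box edge lengths in nm (orthorhombic).
#' @param step_index integer step counter, starts at 0.
#' @return An object of class `system_state`.
#' @export
system_state <- function(positions, velocities, masses, box, step_index = 0L) {
  positions <- unname(as.matrix(positions))
  velocities <- unname(as.matrix(velocities))
  if (!all(is.finite(positions)) || !all(is.finite(velocities)))
    stop("non-finite coordinates or velocities")
  n <- nrow(positions)
  if (!all(dim(velocities) == c(n, 3L)) || ncol(positions) != 3L)
    stop("positions and velocities must be N x 3 matrices of equal size")
  if (length(masses) != n || any(masses <= 0)) stop("need N positive masses")
  if (length(box) != 3L || any(box <= 0)) stop("box must be 3 positive edge lengths")
  structure(list(x = positions, v = velocities, m = as.numeric(masses),
                 box = as.numeric(box), step = as.integer(step_index)),
            class = "system_state")
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf("system_state: %d atoms, box %.4g x %.4g x %.4g nm, step %d\n",
              nrow(x$x), x$box[1], x$box[2], x$box[3], x$step))
  invisible(x)
}

#' Positions wrapped into the primary box
#'
#' Each coordinate is translated by an integer number of box lengths into
#' `[0, box)`. The stored positions themselves stay unwrapped; wrapped and
#' unwrapped copies differ by integer multiples of the box edges.
#'
#' @param state A `system_state`.
#' @return N x 3 matrix of wrapped coordinates (nm).
#' @export
wrapped_positions <- function(state) {
  x <- state$x
  for (k in 1:3) x[, k] <- x[, k] - state$box[k] * floor(x[, k] / state$box[k])
  x
}

#' Minimum-image displacement
#'
#' Returns the periodic image of `r_j - r_i` closest to zero, component-wise
#' in `[-box/2, box/2)`.
#'
#' @param r_i,r_j 3-vectors (nm).
#' @param box length-3 box edges (nm).
#' @return 3-vector displacement (nm).
#' @export
minimum_image <- function(r_i, r_j, box) {
  if (!all(is.finite(c(r_i, r_j)))) stop("non-finite coordinates")
  d <- r_j - r_i
  d - box * floor(d / box + 0.5)
}

# vectorised min-image of rows xi - xj (note sign: displacement of i from j)
.pair_disp <- function(x, i, j, box) {
  d <- x[i, , drop = FALSE] - x[j, , drop = FALSE]
  for (k in 1:3) {
    shift <- floor(.re(d[, k]) / box[k] + 0.5)
    d[, k] <- d[, k] - box[k] * shift
  }
  d
}

#' Molecular topology
#'
#' Connectivity and typing for a periodic molecular system: per-atom type
#' labels, fixed partial charges (or a trainable-charge pattern), harmonic
#' bonds and angles keyed by named parameter types, harmonic position tethers,
#' and the partition of atoms into molecules (used to exclude intramolecular
#' nonbonded pairs).
#'
#' If `charge_entry` names a force-field parameter (e.g. `"charge_OW"`),
#' effective charges are `charge_coeff * value(charge_entry)`, which keeps the
#' molecular charge fixed while a single charge parameter is trained (e.g.
#' water hydrogens at -q_O/2).
#'
#' @param atom_types character length-N type labels.
#' @param charges length-N charges in elementary charge units.
#' @param bonds data.frame with columns i, j, type (1-based atom indices).
#' @param angles data.frame with columns i, j, k, type; j is the vertex.
#' @param molecules list of integer vectors partitioning 1..N.
#' @param charge_entry optional name of the force-field charge parameter.
#' @param charge_coeff optional length-N multiplier pattern for that entry.
#' @param tethers optional data.frame with column i: atoms harmonically
#'   restrained to the origin with force constant `tether_k`.
#' @param tagged_molecules optional list of atom-index vectors (e.g. gas
#'   molecules tracked for mean squared displacement).
#' @param molecular_charge declared per-molecule total charge (default 0).
#' @return An object of class `topology`.
#' @export
topology <- function(atom_types, charges = NULL, bonds = NULL, angles = NULL,
                     molecules = NULL, charge_entry = NA_character_,
                     charge_coeff = NULL, tethers = NULL,
                     tagged_molecules = NULL, molecular_charge = 0) {
  n <- length(atom_types)
  if (is.null(charges)) charges <- numeric(n)
  if (length(charges) != n) stop("charges must have one entry per atom")
  if (is.null(molecules)) molecules <- as.list(seq_len(n))
  chk_idx <- function(idx, m) {
    idx <- as.matrix(idx)
    if (length(idx) && (any(idx < 1) || any(idx > n))) stop(m, ": index out of range")
    if (length(idx) && any(apply(idx, 1, anyDuplicated) > 0))
      stop(m, ": repeated atom within a term")
  }
  if (!is.null(bonds) && nrow(bonds)) chk_idx(bonds[, c("i", "j")], "bonds")
  if (!is.null(angles) && nrow(angles)) chk_idx(angles[, c("i", "j", "k")], "angles")
  part <- sort(unlist(molecules))
  if (!identical(as.integer(part), seq_len(n)))
    stop("molecules must partition the atom indices")
  if (!is.null(charge_coeff) && length(charge_coeff) != n)
    stop("charge_coeff must have one entry per atom")
  top <- structure(list(atom_types = as.character(atom_types), charges = charges,
                        bonds = bonds, angles = angles, molecules = molecules,
                        charge_entry = charge_entry, charge_coeff = charge_coeff,
                        tethers = tethers, tagged_molecules = tagged_molecules,
                        molecular_charge = molecular_charge),
                   class = "topology")
  top$exclusions <- .intramolecular_pairs(top)
  top
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("topology: %d atoms, %d molecules, %d bonds, %d angles\n",
              length(x$atom_types), length(x$molecules),
              if (is.null(x$bonds)) 0L else nrow(x$bonds),
              if (is.null(x$angles)) 0L else nrow(x$angles)))
  invisible(x)
}

# all unordered intramolecular pairs, encoded i*(N+1)+j with i<j for fast lookup
.intramolecular_pairs <- function(top) {
  n <- length(top$atom_types)
  keys <- unlist(lapply(top$molecules, function(idx) {
    if (length(idx) < 2) return(numeric(0))
    cmb <- utils::combn(sort(idx), 2)
    cmb[1, ] * (n + 1) + cmb[2, ]
  }))
  as.numeric(keys)
}

# effective per-atom charges; complex-capable through ff values
.effective_charges <- function(top, ff) {
  if (!is.na(top$charge_entry) && !is.null(top$charge_coeff) &&
      top$charge_entry %in% ff$entries$name) {
    top$charge_coeff * ff_get(ff, top$charge_entry)
  } else {
    top$charges
  }
}

#' Build a Verlet neighbour list
#'
#' All distinct pairs with minimum-image distance below `cutoff + skin`,
#' excluding intramolecular pairs, ordered lexicographically by (i, j). The
#' list is a superset of the interacting set and is treated as a constant
#' (non-differentiated) structure between rebuilds; pair interactions are
#' masked at `cutoff` inside the force kernels, so any superset list yields
#' identical forces.
#'
#' @param state A `system_state`.
#' @param top A `topology`.
#' @param cutoff interaction cutoff (nm).
#' @param skin extra shell retained beyond the cutoff (nm).
#' @return An object of class `neighbor_list` with fields `pairs` (P x 2
#'   integer matrix), `build_step`, `cutoff`, `skin`.
#' @export
build_neighbor_list <- function(state, top, cutoff, skin = 0.15) {
  box <- state$box
  if (cutoff + skin >= min(box) / 2)
    stop(sprintf("cutoff + skin (%.3f) must be < half the smallest box edge (%.3f)",
                 cutoff + skin, min(box) / 2))
  x <- wrapped_positions(state)
  n <- nrow(x)
  rc2 <- (cutoff + skin)^2
  ii <- integer(0); jj <- integer(0)
  if (n >= 2) {
    out_i <- vector("list", n - 1)
    for (a in seq_len(n - 1)) {
      js <- (a + 1):n
      d2 <- 0
      for (k in 1:3) {
        dk <- x[js, k] - x[a, k]
        dk <- dk - box[k] * floor(dk / box[k] + 0.5)
        d2 <- d2 + dk * dk
      }
      out_i[[a]] <- js[d2 < rc2]
    }
    cnt <- lengths(out_i)
    ii <- rep.int(seq_len(n - 1), cnt)
    jj <- unlist(out_i, use.names = FALSE)
  }
  if (length(ii)) {
    keys <- ii * (n + 1) + jj
    keep <- !(keys %in% top$exclusions)
    ii <- ii[keep]; jj <- jj[keep]
  }
  structure(list(pairs = cbind(i = as.integer(ii), j = as.integer(jj)),
                 build_step = state$step, cutoff = cutoff, skin = skin),
            class = "neighbor_list")
}

#' Kinetic energy and instantaneous temperature
#'
#' KE = sum m v^2 / 2 in kJ/mol; T = 2 KE / (3 N kB) in K, with all 3N
#' degrees of freedom counted (no constraints are used anywhere).
#'
#' @param state A `system_state`.
#' @return list with `kinetic_energy` (kJ/mol) and `temperature` (K).
#' @export
kinetic_energy_and_temperature <- function(state) {
  if (!all(is.finite(state$v))) stop("non-finite velocities")
  ke <- 0.5 * sum(state$m * rowSums(state$v^2))
  n <- nrow(state$x)
  list(kinetic_energy = ke, temperature = 2 * ke / (3 * n * kB_MD))
}
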