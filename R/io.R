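# Plain-text I/O: XYZ and GRO coordinates, topology, force-field parameter
# files, RDF reference curves, gradient reports. All formats round-trip.

#' Read and write XYZ coordinates
#'
#' XYZ stores Angstrom; positions are converted to/from nm.
#'
#' @param file path.
#' @param state A `system_state` (positions written wrapped = FALSE).
#' @param elements atom labels (defaults to "X").
#' @param comment second-line comment.
#' @return `read_xyz`: list with `elements` and `positions` (nm).
#' @export
write_xyz <- function(state, file, elements = NULL, comment = "") {
  x <- state$x * 10
  if (is.null(elements)) elements <- rep("X", nrow(x))
  lines <- c(as.character(nrow(x)), comment,
             sprintf("%s %.8f %.8f %.8f", elements, x[, 1], x[, 2], x[, 3]))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(file) {
  lines <- readLines(file)
  n <- suppressWarnings(as.integer(lines[1]))
  if (is.na(n)) stop("malformed XYZ: line 1 is not an atom count")
  if (length(lines) < n + 2) stop("malformed XYZ: fewer lines than declared atoms")
  parts <- strsplit(trimws(lines[3:(n + 2)]), "\\s+")
  bad <- which(lengths(parts) < 4)
  if (length(bad)) stop("malformed XYZ record at line ", bad[1] + 2)
  el <- vapply(parts, `[`, character(1), 1)
  x <- suppressWarnings(t(vapply(parts, function(p) as.numeric(p[2:4]),
                                 numeric(3)))) / 10
  if (any(!is.finite(x))) stop("malformed XYZ: non-numeric coordinates")
  list(elements = el, positions = x)
}

#' Read and write GRO coordinates with velocities
#'
#' GROMACS fixed-format: positions in nm, velocities in nm/ps, cubic box on
#' the last line. The velocity-carrying format used for integrator state.
#'
#' @param state A `system_state`.
#' @param file path.
#' @param names atom names (defaults to type-like "X").
#' @param res_names residue names.
#' @return `read_gro`: list with `positions`, `velocities`, `box`, `names`.
#' @export
write_gro <- function(state, file, names = NULL, res_names = NULL) {
  n <- nrow(state$x)
  if (is.null(names)) names <- rep("X", n)
  if (is.null(res_names)) res_names <- rep("MOL", n)
  lines <- c("revsim system", sprintf("%5d", n),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f%8.4f%8.4f%8.4f",
                     seq_len(n), substr(res_names, 1, 5), substr(names, 1, 5),
                     seq_len(n) %% 100000,
                     state$x[, 1], state$x[, 2], state$x[, 3],
                     state$v[, 1], state$v[, 2], state$v[, 3]),
             sprintf("%10.5f%10.5f%10.5f", state$box[1], state$box[2], state$box[3]))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_gro
#' @export
read_gro <- function(file) {
  lines <- readLines(file)
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop("malformed GRO: line 2 is not an atom count")
  if (length(lines) < n + 3) stop("malformed GRO: fewer lines than declared atoms")
  x <- matrix(0, n, 3); v <- matrix(0, n, 3); nm <- character(n)
  for (k in seq_len(n)) {
    ln <- lines[k + 2]
    if (nchar(ln) < 44) stop("malformed GRO line ", k + 2)
    nm[k] <- trimws(substr(ln, 11, 15))
    num <- function(a, b) {
      z <- suppressWarnings(as.numeric(substr(ln, a, b)))
      if (is.na(z)) stop("malformed GRO line ", k + 2)
      z
    }
    x[k, ] <- c(num(21, 28), num(29, 36), num(37, 44))
    if (nchar(ln) >= 68) v[k, ] <- c(num(45, 52), num(53, 60), num(61, 68))
  }
  box <- as.numeric(strsplit(trimws(lines[n + 3]), "\\s+")[[1]][1:3])
  if (any(!is.finite(box))) stop("malformed GRO box line")
  list(positions = x, velocities = v, box = box, names = nm)
}

#' Read and write the topology text format
#'
#' Sections: `[atoms]` (index, type, mass, charge, charge_coeff, molecule),
#' `[bonds]`, `[angles]`, `[tethers]`, `[tagged]`, plus a `charge_entry`
#' header line. Round-trips a [topology()] together with the masses.
#'
#' @param top A `topology`.
#' @param masses length-N masses (g/mol).
#' @param file path.
#' @return `read_topology`: list with `top` and `masses`.
#' @export
write_topology <- function(top, masses, file) {
  n <- length(top$atom_types)
  mol_of <- integer(n)
  for (mi in seq_along(top$molecules)) mol_of[top$molecules[[mi]]] <- mi
  cc <- top$charge_coeff
  if (is.null(cc)) cc <- rep(0, n)
  lines <- c("# revsim topology v1",
             paste("charge_entry", top$charge_entry),
             "[atoms]",
             sprintf("%d %s %.6f %.6f %.6f %d", seq_len(n), top$atom_types,
                     masses, top$charges, cc, mol_of))
  if (!is.null(top$bonds) && nrow(top$bonds))
    lines <- c(lines, "[bonds]",
               sprintf("%d %d %s", top$bonds$i, top$bonds$j, top$bonds$type))
  if (!is.null(top$angles) && nrow(top$angles))
    lines <- c(lines, "[angles]",
               sprintf("%d %d %d %s", top$angles$i, top$angles$j, top$angles$k,
                       top$angles$type))
  if (!is.null(top$tethers) && nrow(top$tethers)) {
    anch <- .tether_anchors(top)
    lines <- c(lines, "[tethers]",
               sprintf("%d %.6f %.6f %.6f", top$tethers$i, anch[, 1], anch[, 2],
                       anch[, 3]))
  }
  if (!is.null(top$tagged_molecules))
    lines <- c(lines, "[tagged]",
               vapply(top$tagged_molecules, function(z) paste(z, collapse = " "),
                      character(1)))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_topology
#' @export
read_topology <- function(file) {
  lines <- readLines(file)
  sec <- NA_character_
  atoms <- list(); bonds <- list(); angles <- list(); tethers <- list()
  tagged <- list(); charge_entry <- NA_character_
  for (li in seq_along(lines)) {
    ln <- trimws(lines[li])
    if (!nchar(ln) || startsWith(ln, "#")) next
    if (startsWith(ln, "charge_entry")) {
      charge_entry <- strsplit(ln, "\\s+")[[1]][2]
      next
    }
    if (startsWith(ln, "[")) { sec <- ln; next }
    p <- strsplit(ln, "\\s+")[[1]]
    err <- function() stop("malformed topology record at line ", li)
    if (identical(sec, "[atoms]")) {
      if (length(p) != 6) err()
      atoms[[length(atoms) + 1L]] <- p
    } else if (identical(sec, "[bonds]")) {
      if (length(p) != 3) err()
      bonds[[length(bonds) + 1L]] <- p
    } else if (identical(sec, "[angles]")) {
      if (length(p) != 4) err()
      angles[[length(angles) + 1L]] <- p
    } else if (identical(sec, "[tethers]")) {
      if (!length(p) %in% c(1L, 4L)) err()
      tethers[[length(tethers) + 1L]] <-
        c(as.numeric(p[1]), if (length(p) == 4) as.numeric(p[2:4]) else c(0, 0, 0))
    } else if (identical(sec, "[tagged]")) {
      tagged[[length(tagged) + 1L]] <- as.integer(p)
    } else err()
  }
  if (!length(atoms)) stop("topology file has no [atoms] section")
  am <- do.call(rbind, atoms)
  n <- nrow(am)
  mol_of <- as.integer(am[, 6])
  mols <- split(seq_len(n), mol_of)
  top <- topology(am[, 2], charges = as.numeric(am[, 4]),
                  bonds = if (length(bonds)) {
                    bm <- do.call(rbind, bonds)
                    data.frame(i = as.integer(bm[, 1]), j = as.integer(bm[, 2]),
                               type = bm[, 3], stringsAsFactors = FALSE)
                  } else NULL,
                  angles = if (length(angles)) {
                    an <- do.call(rbind, angles)
                    data.frame(i = as.integer(an[, 1]), j = as.integer(an[, 2]),
                               k = as.integer(an[, 3]), type = an[, 4],
                               stringsAsFactors = FALSE)
                  } else NULL,
                  molecules = unname(mols),
                  charge_entry = if (identical(charge_entry, "NA")) NA_character_ else charge_entry,
                  charge_coeff = if (all(as.numeric(am[, 5]) == 0)) NULL else as.numeric(am[, 5]),
                  tethers = if (length(tethers)) {
                    tm <- do.call(rbind, tethers)
                    data.frame(i = as.integer(tm[, 1]), x0 = tm[, 2], y0 = tm[, 3],
                               z0 = tm[, 4])
                  } else NULL,
                  tagged_molecules = if (length(tagged)) tagged else NULL)
  list(top = top, masses = as.numeric(am[, 3]))
}

#' Read and write force-field parameter files
#'
#' Structured text: header lines for the form, cutoff and dielectric, then
#' one `param` line per entry with name, value, unit, trainable flag and
#' starting value. Values round-trip bit-identically (full precision).
#'
#' @param ff A `force_field`.
#' @param file path.
#' @return `read_force_field`: a `force_field`.
#' @export
write_force_field <- function(ff, file) {
  e <- ff$entries
  lines <- c("# revsim force field v1",
             paste("form", ff$nonbonded_form),
             paste("cutoff", format(ff$cutoff, digits = 17)),
             paste("dielectric", format(ff$solvent_dielectric, digits = 17)),
             sprintf("param %s %s {%s} %d %s", e$name,
                     vapply(e$value, format, character(1), digits = 17), e$unit,
                     as.integer(e$trainable),
                     vapply(e$starting_value, format, character(1), digits = 17)))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_force_field
#' @export
read_force_field <- function(file) {
  lines <- readLines(file)
  form <- NULL; cutoff <- NULL; diel <- 78.5
  rows <- list()
  for (li in seq_along(lines)) {
    ln <- trimws(lines[li])
    if (!nchar(ln) || startsWith(ln, "#")) next
    p <- strsplit(ln, "\\s+")[[1]]
    if (p[1] == "form") form <- p[2]
    else if (p[1] == "cutoff") cutoff <- as.numeric(p[2])
    else if (p[1] == "dielectric") diel <- as.numeric(p[2])
    else if (p[1] == "param") {
      m <- regmatches(ln, regexec("^param (\\S+) (\\S+) \\{(.*)\\} (\\d) (\\S+)$", ln))[[1]]
      if (length(m) != 6) stop("malformed parameter line ", li)
      rows[[length(rows) + 1L]] <- data.frame(
        name = m[2], value = as.numeric(m[3]), unit = m[4],
        trainable = m[5] == "1", starting_value = as.numeric(m[6]),
        stringsAsFactors = FALSE)
    } else stop("unrecognised force-field line ", li)
  }
  if (is.null(form) || is.null(cutoff)) stop("force-field file missing form or cutoff")
  force_field(do.call(rbind, rows), form, cutoff, diel)
}

#' Read a tabulated RDF reference curve
#'
#' Two whitespace-separated columns: r (nm) and g(r). Comment lines start
#' with `#`.
#'
#' @param file path.
#' @param pair_types length-2 type labels the curve refers to.
#' @return list with `r`, `g`, `pair_types`.
#' @export
read_rdf_reference <- function(file, pair_types = c("OW", "OW")) {
  tb <- utils::read.table(file, comment.char = "#")
  if (ncol(tb) < 2) stop("reference curve needs two columns")
  if (any(diff(tb[, 1]) <= 0)) stop("reference r grid must be increasing")
  if (any(tb[, 2] < 0)) stop("reference g(r) must be nonnegative")
  list(r = tb[, 1], g = tb[, 2], pair_types = pair_types)
}

#' @rdname read_rdf_reference
#' @param reference list with `r` and `g`.
#' @export
write_rdf_reference <- function(reference, file) {
  writeLines(c("# r_nm g", sprintf("%.10g %.10g", reference$r, reference$g)), file)
  invisible(file)
}

#' Write / read a gradient report
#'
#' @param report A `gradient_report`.
#' @param file path.
#' @return `read_gradient_report`: list with `dl_dsigma`.
#' @export
write_gradient_report <- function(report, file) {
  lines <- c("# revsim gradient report",
             sprintf("grad %s %s", names(report$dl_dsigma),
                     format(report$dl_dsigma, digits = 17)))
  for (ps in report$per_seed)
    lines <- c(lines, sprintf("seed %d %s", ps$step,
                              paste(format(ps$direct + ps$trajectory, digits = 10),
                                    collapse = " ")))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_gradient_report
#' @export
read_gradient_report <- function(file) {
  lines <- grep("^grad ", readLines(file), value = TRUE)
  p <- strsplit(lines, "\\s+")
  list(dl_dsigma = stats::setNames(vapply(p, function(z) as.numeric(z[3]), numeric(1)),
                                   vapply(p, `[`, character(1), 2)))
}
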