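# Residue names recognised as water; the selector keys on the oxygen atom.
.WATER_RESNAMES <- c("HOH", "SOL", "WAT", "TIP3")

#' Default van der Waals radii
#'
#' Element-to-radius lookup (Angstrom) used when a frame is built or parsed.
#' The values are the standard Bondi-type set for the elements that occur in
#' peptide/water systems; unknown elements raise an error unless a
#' `default` radius is supplied.
#'
#' @return Named numeric vector of radii in Angstrom.
#' @export
default_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, Zn = 1.39)
}

#' Assign van der Waals radii to elements
#'
#' @param elements Character vector of element symbols.
#' @param radii Named vector overriding/extending [default_radii()].
#' @param default Fallback radius (Angstrom) for unknown elements; if `NULL`
#'   (default) an unknown element is an error.
#' @return Numeric vector of radii, one per element.
#' @export
assign_radii <- function(elements, radii = default_radii(), default = NULL) {
  table <- default_radii()
  table[names(radii)] <- radii
  r <- unname(table[elements])
  if (anyNA(r)) {
    if (is.null(default)) {
      bad <- unique(elements[is.na(r)])
      stop("no van der Waals radius for element(s): ",
           paste(bad, collapse = ", "),
           " (supply `radii` or `default`)", call. = FALSE)
    }
    r[is.na(r)] <- default
  }
  r
}

#' Construct a molecular frame
#'
#' A frame is the unit of all geometry operations: a table of atoms with
#' element/chain/residue labels and Cartesian coordinates (Angstrom) in an
#' orthorhombic periodic box.
#'
#' @param atoms `data.frame` with columns `element`, `atom_name`,
#'   `residue_name`, `residue_index`, `chain_id`, `x`, `y`, `z` and optionally
#'   `radius` (filled from `radii` when absent).
#' @param box Numeric length-3 vector of box edge lengths (Angstrom).
#' @param time Frame time in ns (default `NA`).
#' @param radii,default_radius Passed to [assign_radii()] when the atom table
#'   carries no `radius` column.
#' @param water_resnames Residue names identifying water molecules.
#' @return Object of class `molecular_frame`.
#' @export
molecular_frame <- function(atoms, box, time = NA_real_,
                            radii = default_radii(), default_radius = NULL,
                            water_resnames = .WATER_RESNAMES) {
  need <- c("element", "atom_name", "residue_name", "residue_index",
            "chain_id", "x", "y", "z")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  box <- as.numeric(box)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
    stop("box must be 3 positive finite edge lengths (Angstrom)")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  if (any(atoms$residue_index < 1))
    stop("residue_index must be >= 1")
  if (is.null(atoms$radius))
    atoms$radius <- assign_radii(atoms$element, radii, default_radius)
  if (any(!is.finite(atoms$radius)) || any(atoms$radius <= 0))
    stop("all atom radii must be positive and finite")
  structure(
    list(atoms = atoms, box = box, time = as.numeric(time),
         water_resnames = water_resnames),
    class = "molecular_frame")
}

#' @export
print.molecular_frame <- function(x, ...) {
  cat(sprintf("<molecular_frame> %d atoms, box %.1f x %.1f x %.1f A, t = %s ns\n",
              nrow(x$atoms), x$box[1], x$box[2], x$box[3],
              format(x$time)))
  invisible(x)
}

#' Coordinate matrix of a frame
#' @param frame A `molecular_frame`.
#' @return n x 3 numeric matrix (Angstrom).
#' @export
frame_coords <- function(frame) {
  as.matrix(frame$atoms[, c("x", "y", "z")])
}

#' Logical selector for water oxygen atoms
#' @param frame A `molecular_frame`.
#' @return Logical vector over atoms.
#' @export
is_water_oxygen <- function(frame) {
  frame$atoms$residue_name %in% frame$water_resnames &
    frame$atoms$element == "O"
}

#' Logical selector for peptide (non-water) atoms
#' @param frame A `molecular_frame`.
#' @return Logical vector over atoms.
#' @export
is_peptide_atom <- function(frame) {
  !(frame$atoms$residue_name %in% frame$water_resnames)
}

#' Construct a trajectory
#'
#' @param frames List of `molecular_frame` objects with identical atom count
#'   and ordering; times must be strictly increasing (missing times are
#'   replaced by the 0-based frame index).
#' @param metadata Free-text provenance.
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(frames, metadata = "") {
  if (!length(frames)) stop("trajectory needs at least one frame")
  n0 <- nrow(frames[[1]]$atoms)
  names0 <- frames[[1]]$atoms$atom_name
  for (k in seq_along(frames)) {
    if (nrow(frames[[k]]$atoms) != n0)
      stop("frame ", k, " has ", nrow(frames[[k]]$atoms),
           " atoms; expected ", n0)
    if (!identical(frames[[k]]$atoms$atom_name, names0))
      stop("frame ", k, " atom ordering differs from frame 1")
    if (is.na(frames[[k]]$time)) frames[[k]]$time <- k - 1
  }
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  structure(list(frames = frames, metadata = metadata), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms\n",
              length(x$frames), nrow(x$frames[[1]]$atoms)))
  invisible(x)
}

#' @export
length.trajectory <- function(x) length(x$frames)

#' Frame times of a trajectory
#' @param traj A `trajectory`.
#' @return Numeric vector of times (ns).
#' @export
trajectory_times <- function(traj) {
  vapply(traj$frames, function(f) f$time, numeric(1))
}
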