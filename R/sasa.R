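# Shrake-Rupley solvent-accessible surface area under periodic boundaries.

#' SASA parameters
#'
#' @param probe_radius Probe (solvent) radius in Angstrom; 1.4 is the standard
#'   water probe.
#' @param n_sphere_points Number of test points per atom (Fibonacci sphere);
#'   must be >= 32.
#' @return Object of class `sasa_parameters`.
#' @export
sasa_parameters <- function(probe_radius = 1.4, n_sphere_points = 960L) {
  if (probe_radius < 0) stop("probe_radius must be >= 0")
  if (n_sphere_points < 32) stop("n_sphere_points must be >= 32")
  structure(list(probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points)),
            class = "sasa_parameters")
}

#' Evenly distributed points on the unit sphere (Fibonacci / golden-angle)
#'
#' @param n Number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area of a frame (Shrake-Rupley)
#'
#' For each selected atom, test points on the probe-expanded sphere
#' (radius r + probe) are classified as accessible when they fall outside
#' every other selected atom's expanded sphere; the accessible fraction times
#' 4*pi*(r+probe)^2 is the atom's SASA. Distances use the minimum-image
#' convention, and neighbours are found with a cell list (brute-force
#' fallback for small boxes).
#'
#' @param frame A `molecular_frame`.
#' @param params A [sasa_parameters()] object.
#' @param selection Indices or logical vector of atoms to include; default all
#'   peptide (non-water) atoms. Only selected atoms occlude.
#' @return List with `per_atom` (SASA per selected atom, Angstrom^2), `total`,
#'   `selection` (integer indices) and `params`.
#' @export
compute_sasa <- function(frame, params = sasa_parameters(), selection = NULL) {
  if (is.null(selection)) selection <- which(is_peptide_atom(frame))
  if (is.logical(selection)) selection <- which(selection)
  if (!length(selection)) stop("empty atom selection")
  x <- frame_coords(frame)[selection, , drop = FALSE]
  r <- frame$atoms$radius[selection]
  if (anyNA(r)) stop("selected atom lacking a radius")
  box <- frame$box
  probe <- params$probe_radius
  re <- r + probe
  n <- length(selection)
  pts <- fibonacci_sphere(params$n_sphere_points)
  # neighbour list: pairs whose expanded spheres can intersect
  cutoff <- 2 * max(re)
  nb <- neighbor_pairs(x, box, cutoff)
  nb_of <- vector("list", n)
  if (nrow(nb)) {
    keep <- nb$d < re[nb$i] + re[nb$j]
    nb <- nb[keep, , drop = FALSE]
    if (nrow(nb)) {
      nb_of <- split(c(nb$j, nb$i), factor(c(nb$i, nb$j), levels = seq_len(n)))
    } else nb_of <- rep(list(integer(0)), n)
  } else nb_of <- rep(list(integer(0)), n)
  area <- numeric(n)
  for (i in seq_len(n)) {
    p <- sweep(pts * re[i], 2, x[i, ], "+")
    acc <- rep(TRUE, nrow(p))
    for (j in nb_of[[i]]) {
      if (!any(acc)) break
      d2 <- .mi_dist2_to_point(p[acc, , drop = FALSE], x[j, ], box)
      acc[acc] <- d2 > re[j]^2
    }
    area[i] <- mean(acc) * 4 * pi * re[i]^2
  }
  list(per_atom = area, total = sum(area),
       selection = selection, params = params)
}

#' Collapse-degree series over a trajectory
#'
#' The collapse degree of a frame is the ratio of the SASA of the dispersed
#' reference frame (the "fully random" initial configuration) to the SASA of
#' that frame; values above 1 indicate peptide compaction. An optional
#' equilibration window discards frames with time below `eq_time` from the
#' reported series (the reference frame is always evaluated).
#'
#' @param traj A `trajectory`.
#' @param reference Index of the reference frame (default 1, the initial
#'   dispersed state).
#' @param params A [sasa_parameters()] object.
#' @param selection Atom selection passed to [compute_sasa()] (default all
#'   peptide atoms).
#' @param eq_time Equilibration time (ns); frames with `time < eq_time` are
#'   dropped from the series. Default 0 (keep all).
#' @return Object of class `collapse_result`: list with `time`,
#'   `sasa_reference`, `sasa` and `collapse_degree` (reference frame degree is
#'   exactly 1 when retained).
#' @export
collapse_degree_series <- function(traj, reference = 1L,
                                   params = sasa_parameters(),
                                   selection = NULL, eq_time = 0) {
  nf <- length(traj$frames)
  if (reference < 1L || reference > nf)
    stop("reference frame ", reference, " does not exist (trajectory has ",
         nf, " frames)")
  times <- trajectory_times(traj)
  keep <- which(times >= eq_time)
  if (!length(keep)) stop("equilibration window discards every frame")
  sasa_ref <- compute_sasa(traj$frames[[reference]], params, selection)$total
  if (sasa_ref <= 0) stop("reference frame has zero SASA (degenerate selection)")
  sasa_t <- vapply(keep, function(k) {
    if (k == reference) return(sasa_ref)
    compute_sasa(traj$frames[[k]], params, selection)$total
  }, numeric(1))
  if (any(sasa_t <= 0)) stop("zero SASA at frame(s) ",
                             paste(keep[sasa_t <= 0], collapse = ", "),
                             " (degenerate selection)")
  structure(list(time = times[keep], frame = keep,
                 sasa_reference = sasa_ref, sasa = sasa_t,
                 collapse_degree = sasa_ref / sasa_t),
            class = "collapse_result")
}

#' @export
print.collapse_result <- function(x, ...) {
  cat(sprintf("<collapse_result> %d frames, reference SASA %.1f A^2, degree %.3f .. %.3f\n",
              length(x$sasa), x$sasa_reference,
              min(x$collapse_degree), max(x$collapse_degree)))
  invisible(x)
}
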