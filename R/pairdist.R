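# His Calpha pair distributions and low-barrier hydrogen-bond screening.

.HIS_RESNAMES <- c("HIS", "HSD", "HSE", "HSP", "HID", "HIE", "HIP")
.IMIDAZOLE_N <- c("ND1", "NE2")
.IMIDAZOLE_RING <- c("CG", "ND1", "CD2", "CE1", "NE2")

#' His Calpha pair distance distribution over a trajectory
#'
#' Tallies minimum-image distances between Calpha atoms of His residues
#' frame by frame and reports both raw bin counts and the per-pair,
#' per-frame density counts / (n_frames * n_pairs * bin_width). By default
#' only pairs on distinct chains (intermolecular) are tallied, matching the
#' condensate-contact question the distribution answers.
#'
#' @param traj A `trajectory`.
#' @param intermolecular_only Exclude same-chain pairs (default TRUE).
#' @param bin_width Histogram bin width in Angstrom (default 0.25).
#' @param r_max Histogram upper edge in Angstrom (default 15).
#' @param eq_time Discard frames with time below this (ns; default 0).
#' @param residue_names,atom_name Selection rule; defaults His Calpha.
#' @param method Distance search passed to [neighbor_pairs()].
#' @return Object of class `pair_distribution`: `bin_edges`, `bin_mid`,
#'   `counts`, `normalized_density`, `n_pairs`, `n_frames`.
#' @export
his_ca_pair_distribution <- function(traj, intermolecular_only = TRUE,
                                     bin_width = 0.25, r_max = 15,
                                     eq_time = 0,
                                     residue_names = .HIS_RESNAMES,
                                     atom_name = "CA",
                                     method = c("auto", "cell", "brute")) {
  method <- match.arg(method)
  f1 <- traj$frames[[1]]
  sel <- which(f1$atoms$residue_name %in% residue_names &
               f1$atoms$atom_name == atom_name)
  if (length(sel) < 2L)
    stop("need at least two ", atom_name, " atoms of residues ",
         paste(residue_names, collapse = "/"), " in the trajectory")
  chains <- f1$atoms$chain_id[sel]
  if (intermolecular_only && length(unique(chains)) < 2L)
    stop("intermolecular_only requires His residues on at least two chains")
  n_pairs <- if (intermolecular_only) {
    tab <- table(chains)
    (length(sel)^2 - sum(tab^2)) / 2
  } else choose(length(sel), 2)
  times <- trajectory_times(traj)
  keep <- which(times >= eq_time)
  if (!length(keep)) stop("equilibration window discards every frame")
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  counts <- numeric(length(edges) - 1L)
  for (k in keep) {
    fr <- traj$frames[[k]]
    x <- frame_coords(fr)[sel, , drop = FALSE]
    nb <- neighbor_pairs(x, fr$box, r_max, method)
    if (intermolecular_only && nrow(nb))
      nb <- nb[chains[nb$i] != chains[nb$j], , drop = FALSE]
    if (nrow(nb))
      counts <- counts + tabulate(findInterval(nb$d, edges,
                                               rightmost.closed = TRUE),
                                  nbins = length(counts))
  }
  structure(list(bin_edges = edges,
                 bin_mid = (edges[-1] + edges[-length(edges)]) / 2,
                 counts = counts,
                 normalized_density =
                   counts / (length(keep) * n_pairs * bin_width),
                 n_pairs = n_pairs, n_frames = length(keep),
                 bin_width = bin_width,
                 intermolecular_only = intermolecular_only),
            class = "pair_distribution")
}

#' @export
print.pair_distribution <- function(x, ...) {
  peak <- x$bin_mid[which.max(x$counts)]
  cat(sprintf("<pair_distribution> %d frames x %g pairs, %d bins, peak near %.2f A\n",
              x$n_frames, x$n_pairs, length(x$counts), peak))
  invisible(x)
}

# helper: imidazole ring-plane unit normal from >= 3 ring atoms, or NULL
.ring_normal <- function(xyz) {
  if (nrow(xyz) < 3L) return(NULL)
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  sv$v[, 3]
}

#' Geometric screen for low-barrier hydrogen-bond candidate His pairs
#'
#' A pair of His residues is flagged when (i) the shortest minimum-image
#' distance over all imidazole-nitrogen combinations (Ndelta/Nepsilon) is at
#' most `d_nn_max`, (ii) the Calpha-Calpha distance lies inside
#' `d_caca_range`, and (iii) where both residues carry at least three ring
#' atoms, the angle between the ring planes is at most `plane_angle_max`
#' (the near-coplanarity test is skipped for pseudo-atom models without full
#' rings). An empty result is a valid outcome.
#'
#' @param frame A `molecular_frame`.
#' @param d_nn_max Donor-acceptor N-N threshold in Angstrom (default 2.7, a
#'   screening tolerance slightly above the ~2.58 A exemplar geometry).
#' @param d_caca_range Calpha-Calpha window in Angstrom (default c(5, 11)).
#' @param plane_angle_max Maximum inter-ring-plane angle in degrees
#'   (default 30).
#' @param residue_names His residue names recognised.
#' @return `data.frame` with one row per flagged pair: chain/residue ids,
#'   `d_nn`, `d_caca`, `ring_plane_angle` (NA when untestable).
#' @export
lbhb_screen <- function(frame, d_nn_max = 2.7, d_caca_range = c(5, 11),
                        plane_angle_max = 30,
                        residue_names = .HIS_RESNAMES) {
  atoms <- frame$atoms
  box <- frame$box
  x <- frame_coords(frame)
  his_rows <- which(atoms$residue_name %in% residue_names)
  empty <- data.frame(chain_i = character(), residue_i = integer(),
                      chain_j = character(), residue_j = integer(),
                      d_nn = numeric(), d_caca = numeric(),
                      ring_plane_angle = numeric())
  if (!length(his_rows)) return(empty)
  key <- paste(atoms$chain_id[his_rows], atoms$residue_index[his_rows])
  groups <- split(his_rows, key)
  # keep residues that have a Calpha and at least one imidazole nitrogen
  info <- lapply(groups, function(rows) {
    ca <- rows[atoms$atom_name[rows] == "CA"]
    nn <- rows[atoms$atom_name[rows] %in% .IMIDAZOLE_N]
    ring <- rows[atoms$atom_name[rows] %in% .IMIDAZOLE_RING]
    if (length(ca) != 1L || !length(nn)) return(NULL)
    list(chain = atoms$chain_id[ca], resi = atoms$residue_index[ca],
         ca = ca, nn = nn, ring = ring)
  })
  info <- info[!vapply(info, is.null, logical(1))]
  info <- info[order(vapply(info, function(g) g$chain, character(1)),
                     vapply(info, function(g) g$resi, numeric(1)))]
  if (length(info) < 2L) return(empty)
  out <- empty
  for (i in seq_len(length(info) - 1L)) {
    for (j in (i + 1L):length(info)) {
      gi <- info[[i]]; gj <- info[[j]]
      dca <- min_image(x[gj$ca, ] - x[gi$ca, ], box)
      d_caca <- sqrt(sum(dca^2))
      if (d_caca < d_caca_range[1] || d_caca > d_caca_range[2]) next
      dnn <- Inf
      for (ni in gi$nn) {
        dd <- .mi_dist2_to_point(x[gj$nn, , drop = FALSE], x[ni, ], box)
        dnn <- min(dnn, sqrt(min(dd)))
      }
      if (dnn > d_nn_max) next
      angle <- NA_real_
      n1 <- .ring_normal(x[gi$ring, , drop = FALSE])
      n2 <- .ring_normal(x[gj$ring, , drop = FALSE])
      if (!is.null(n1) && !is.null(n2)) {
        cosang <- abs(sum(n1 * n2))
        angle <- acos(pmin(1, cosang)) * 180 / pi
        if (angle > plane_angle_max) next
      }
      out <- rbind(out, data.frame(
        chain_i = gi$chain, residue_i = gi$resi,
        chain_j = gj$chain, residue_j = gj$resi,
        d_nn = dnn, d_caca = d_caca, ring_plane_angle = angle))
    }
  }
  rownames(out) <- NULL
  out
}
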