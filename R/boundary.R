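# Condensate identification and boundary-enclosed water content.

# union-find with path compression
.uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Largest peptide cluster by chain-contact graph
#'
#' Two chains are linked when any pair of their heavy atoms lies within
#' `cutoff` under the minimum-image convention; the cluster is the largest
#' connected component (ties broken by atom count, then lowest chain id).
#'
#' @param frame A `molecular_frame`.
#' @param cutoff Heavy-atom contact cutoff in Angstrom (default 4.5).
#' @return List with `chains` (chain ids in the cluster), `atom_idx`
#'   (peptide atom indices of the cluster), `contacts` (data.frame of
#'   chain-linking atom pairs: `atom_i`, `atom_j`, `chain_i`, `chain_j`) and
#'   `n_components`.
#' @export
largest_cluster <- function(frame, cutoff = 4.5) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  pep <- which(is_peptide_atom(frame) & frame$atoms$element != "H")
  if (!length(pep)) stop("no peptide heavy atoms in frame")
  chains <- sort(unique(frame$atoms$chain_id[pep]))
  chain_of <- match(frame$atoms$chain_id[pep], chains)
  x <- frame_coords(frame)[pep, , drop = FALSE]
  nb <- neighbor_pairs(x, frame$box, cutoff)
  cross <- nb[chain_of[nb$i] != chain_of[nb$j], , drop = FALSE]
  parent <- seq_along(chains)
  if (nrow(cross)) {
    for (k in seq_len(nrow(cross))) {
      a <- .uf_find(parent, chain_of[cross$i[k]])
      b <- .uf_find(parent, chain_of[cross$j[k]])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_along(chains), function(i) .uf_find(parent, i), integer(1))
  comp <- split(seq_along(chains), root)
  n_atoms_chain <- tabulate(chain_of, nbins = length(chains))
  size_chains <- lengths(comp)
  size_atoms <- vapply(comp, function(m) sum(n_atoms_chain[m]), numeric(1))
  first_chain <- vapply(comp, min, numeric(1))
  ord <- order(-size_chains, -size_atoms, first_chain)
  winner <- comp[[ord[1]]]
  in_cluster <- chain_of %in% winner
  contacts <- cross[chain_of[cross$i] %in% winner &
                    chain_of[cross$j] %in% winner, , drop = FALSE]
  list(chains = chains[winner],
       atom_idx = pep[in_cluster],
       contacts = data.frame(atom_i = pep[contacts$i], atom_j = pep[contacts$j],
                             chain_i = chains[chain_of[contacts$i]],
                             chain_j = chains[chain_of[contacts$j]]),
       n_components = length(comp))
}

# Unwrap the cluster across periodic boundaries: each chain is unwrapped
# internally along its atom order, then chains are placed relative to each
# other by BFS over the contact graph. Inconsistent image shifts (a cycle
# requiring two different placements) indicate a box-spanning, percolating
# cluster and raise an error.
.unwrap_cluster <- function(frame, cluster) {
  box <- frame$box
  atoms <- frame$atoms
  x <- frame_coords(frame)
  idx <- cluster$atom_idx
  chains <- cluster$chains
  pos <- x[idx, , drop = FALSE]
  chain_of <- match(atoms$chain_id[idx], chains)
  # unwrap within each chain along atom order
  for (c in seq_along(chains)) {
    m <- which(chain_of == c)
    if (length(m) < 2L) next
    for (k in 2:length(m)) {
      step <- min_image(pos[m[k], ] - pos[m[k - 1L], ], box)
      pos[m[k], ] <- pos[m[k - 1L], ] + step
    }
  }
  # place chains by BFS over the contact graph (directed both ways)
  ci <- chain_of[match(cluster$contacts$atom_i, idx)]
  cj <- chain_of[match(cluster$contacts$atom_j, idx)]
  ai <- match(cluster$contacts$atom_i, idx)
  aj <- match(cluster$contacts$atom_j, idx)
  efrom <- c(ci, cj); eto <- c(cj, ci)
  afrom <- c(ai, aj); ato <- c(aj, ai)
  adj <- split(seq_along(efrom), efrom)
  placed <- rep(FALSE, length(chains))
  shift <- matrix(0, length(chains), 3)
  placed[1] <- TRUE
  queue <- 1L
  while (length(queue)) {
    c0 <- queue[1]; queue <- queue[-1]
    for (e in adj[[as.character(c0)]]) {
      cn <- eto[e]
      if (placed[cn]) next
      p0 <- pos[afrom[e], ] + shift[c0, ]
      raw <- pos[ato[e], ]
      shift[cn, ] <- min_image(raw - p0, box) - (raw - p0)
      placed[cn] <- TRUE
      queue <- c(queue, cn)
    }
  }
  # every contact must be reproduced without a further image shift; a
  # contradiction means the cluster wraps around the box (percolates)
  if (length(ai)) {
    pi <- pos[ai, , drop = FALSE] + shift[ci, , drop = FALSE]
    pj <- pos[aj, , drop = FALSE] + shift[cj, , drop = FALSE]
    dd <- pj - pi
    if (max(abs(dd - min_image(dd, box))) > 1e-6)
      stop("peptide cluster spans the periodic box (percolating); ",
           "re-center or enlarge the box before boundary analysis")
  }
  pos <- pos + shift[chain_of, , drop = FALSE]
  ext <- apply(pos, 2, function(v) diff(range(v)))
  if (any(ext >= box))
    stop("peptide cluster spans the periodic box (percolating); ",
         "re-center or enlarge the box before boundary analysis")
  list(pos = pos, idx = idx)
}

#' Boundary-enclosed volume and water content of a condensate
#'
#' Defines the solvent-accessible surface of the largest peptide cluster as
#' the condensate boundary on a voxel grid: voxels within (r_atom + probe) of
#' any cluster atom are solid; the exterior is flood-filled from the box faces
#' (6-connectivity, no periodic wrap — the cluster is re-centered first);
#' every voxel not reached is enclosed. The enclosed volume includes the
#' peptide-occupied voxels; `void_volume` is the interior cavity alone.
#' Water oxygens whose wrapped position falls in an enclosed voxel are
#' counted as inside.
#'
#' @param frame A `molecular_frame` containing peptide and water atoms.
#' @param grid_spacing Voxel edge length in Angstrom (default 1).
#' @param probe Probe radius added to atom radii (default 1.4).
#' @param cluster_cutoff Heavy-atom chain-contact cutoff for
#'   [largest_cluster()] (default 4.5).
#' @param keep_grid Keep the voxel classification grid in the result
#'   (needed by [classify_waters()]; default FALSE).
#' @return Object of class `boundary_result`: `enclosed_volume` and
#'   `void_volume` (Angstrom^3), `n_waters_inside`, `n_waters_total`,
#'   `water_number_density` (count per Angstrom^3 of enclosed volume),
#'   `water_mass_density_g_cm3`, `grid_spacing`, `cluster_chains`.
#' @export
condensate_water_content <- function(frame, grid_spacing = 1, probe = 1.4,
                                     cluster_cutoff = 4.5, keep_grid = FALSE) {
  if (grid_spacing <= 0) stop("grid_spacing must be > 0")
  cluster <- largest_cluster(frame, cluster_cutoff)
  uw <- .unwrap_cluster(frame, cluster)
  box <- frame$box
  centre <- colMeans(uw$pos)
  offset <- box / 2 - centre
  cpos <- wrap_coords(sweep(uw$pos, 2, offset, "+"), box)
  radii <- frame$atoms$radius[uw$idx] + probe
  nd <- pmax(2L, as.integer(round(box / grid_spacing)))
  h <- box / nd
  solid <- array(FALSE, dim = nd)
  # mark voxels whose centre lies within the expanded radius of any atom
  for (a in seq_len(nrow(cpos))) {
    r <- radii[a]
    lo <- pmax(1L, as.integer(ceiling((cpos[a, ] - r) / h + 0.5)))
    hi <- pmin(nd, as.integer(floor((cpos[a, ] + r) / h + 0.5)))
    if (any(lo > hi)) next
    gx <- (lo[1]:hi[1] - 0.5) * h[1] - cpos[a, 1]
    gy <- (lo[2]:hi[2] - 0.5) * h[2] - cpos[a, 2]
    gz <- (lo[3]:hi[3] - 0.5) * h[3] - cpos[a, 3]
    d2 <- outer(outer(gx^2, gy^2, "+"), gz^2, "+")
    solid[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
      solid[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] | (d2 <= r^2)
  }
  # exterior flood fill from the box faces, no wrap
  nvox <- prod(nd)
  dim(solid) <- NULL
  exterior <- logical(nvox)
  ix <- function(i, j, k) i + nd[1] * ((j - 1L) + nd[2] * (k - 1L))
  face <- unique(c(
    ix(rep(c(1L, nd[1]), each = nd[2] * nd[3]),
       rep(rep(seq_len(nd[2]), times = nd[3]), 2),
       rep(rep(seq_len(nd[3]), each = nd[2]), 2)),
    ix(rep(seq_len(nd[1]), times = 2 * nd[3]),
       rep(c(1L, nd[2]), each = nd[1] * nd[3]),
       rep(rep(seq_len(nd[3]), each = nd[1]), 2)),
    ix(rep(seq_len(nd[1]), times = 2 * nd[2]),
       rep(rep(seq_len(nd[2]), each = nd[1]), 2),
       rep(c(1L, nd[3]), each = nd[1] * nd[2]))))
  frontier <- face[!solid[face]]
  exterior[frontier] <- TRUE
  nx <- nd[1]; nxy <- nd[1] * nd[2]
  while (length(frontier)) {
    i0 <- (frontier - 1L) %% nx + 1L
    j0 <- ((frontier - 1L) %/% nx) %% nd[2] + 1L
    k0 <- (frontier - 1L) %/% nxy + 1L
    cand <- c(frontier[i0 > 1L] - 1L, frontier[i0 < nx] + 1L,
              frontier[j0 > 1L] - nx, frontier[j0 < nd[2]] + nx,
              frontier[k0 > 1L] - nxy, frontier[k0 < nd[3]] + nxy)
    cand <- unique(cand)
    cand <- cand[!exterior[cand] & !solid[cand]]
    exterior[cand] <- TRUE
    frontier <- cand
  }
  enclosed <- !exterior
  vvox <- prod(h)
  wat <- which(is_water_oxygen(frame))
  n_inside <- 0L
  if (length(wat)) {
    wpos <- wrap_coords(sweep(frame_coords(frame)[wat, , drop = FALSE],
                              2, offset, "+"), box)
    wi <- floor(sweep(wpos, 2, h, "/")) + 1L
    for (dcol in 1:3) wi[, dcol] <- pmin(pmax(wi[, dcol], 1L), nd[dcol])
    lin <- ix(wi[, 1], wi[, 2], wi[, 3])
    n_inside <- sum(enclosed[lin])
  }
  enc_vol <- sum(enclosed) * vvox
  void_vol <- sum(enclosed & !solid) * vvox
  structure(list(
    enclosed_volume = enc_vol,
    void_volume = void_vol,
    n_waters_inside = as.integer(n_inside),
    n_waters_total = length(wat),
    water_number_density = if (enc_vol > 0) n_inside / enc_vol else 0,
    water_mass_density_g_cm3 =
      if (enc_vol > 0) n_inside / enc_vol * 18.01528 / 0.602214076 else 0,
    grid_spacing = grid_spacing,
    probe = probe,
    cluster_chains = cluster$chains,
    offset = offset,
    grid = if (keep_grid) list(enclosed = array(enclosed, dim = nd),
                               solid = array(solid, dim = nd),
                               h = h, nd = nd, box = box) else NULL),
    class = "boundary_result")
}

#' @export
print.boundary_result <- function(x, ...) {
  cat(sprintf(paste0("<boundary_result> enclosed %.0f A^3 (void %.0f), ",
                     "%d/%d waters inside, density %.4f A^-3\n"),
              x$enclosed_volume, x$void_volume, x$n_waters_inside,
              x$n_waters_total, x$water_number_density))
  invisible(x)
}

#' Classify water oxygens against a computed condensate boundary
#'
#' Reports, per water oxygen, whether it lies in the enclosed region and
#' whether the classification is robust: a water is robust at a given
#' clearance when every voxel within that distance of its position shares
#' its own voxel's classification, i.e. the water sits at least `clearance`
#' away from the enclosed/exterior interface. Waters inside narrow solvent
#' channels or right at the boundary are flagged as not robust.
#'
#' @param result A [condensate_water_content()] result computed with
#'   `keep_grid = TRUE`.
#' @param frame The same `molecular_frame` the result was computed from.
#' @param clearance Clearance distance in Angstrom (default 2 * grid
#'   spacing).
#' @return `data.frame` with one row per water oxygen: `atom` (row index in
#'   the frame), `inside`, `robust`.
#' @export
classify_waters <- function(result, frame,
                            clearance = 2 * result$grid_spacing) {
  stopifnot(inherits(result, "boundary_result"))
  if (is.null(result$grid))
    stop("result lacks the voxel grid; rerun condensate_water_content with ",
         "keep_grid = TRUE")
  g <- result$grid
  nd <- g$nd; h <- g$h
  wat <- which(is_water_oxygen(frame))
  if (!length(wat))
    return(data.frame(atom = integer(), inside = logical(),
                      robust = logical()))
  wpos <- wrap_coords(sweep(frame_coords(frame)[wat, , drop = FALSE],
                            2, result$offset, "+"), g$box)
  wi <- floor(sweep(wpos, 2, h, "/")) + 1L
  for (dcol in 1:3) wi[, dcol] <- pmin(pmax(wi[, dcol], 1L), nd[dcol])
  # neighbourhood offsets within the clearance radius (voxel units)
  rad <- ceiling(clearance / min(h))
  offs <- as.matrix(expand.grid(dx = -rad:rad, dy = -rad:rad, dz = -rad:rad))
  dist_vox <- sqrt((offs[, 1] * h[1])^2 + (offs[, 2] * h[2])^2 +
                     (offs[, 3] * h[3])^2)
  offs <- offs[dist_vox <= clearance, , drop = FALSE]
  inside <- logical(length(wat))
  robust <- logical(length(wat))
  for (k in seq_along(wat)) {
    own <- g$enclosed[wi[k, 1], wi[k, 2], wi[k, 3]]
    inside[k] <- own
    nb <- sweep(offs, 2, wi[k, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= nd[1] & nb[, 2] >= 1 & nb[, 2] <= nd[2] &
      nb[, 3] >= 1 & nb[, 3] <= nd[3]
    nb <- nb[ok, , drop = FALSE]
    vals <- g$enclosed[cbind(nb[, 1], nb[, 2], nb[, 3])]
    robust[k] <- all(vals == own)
  }
  data.frame(atom = wat, inside = inside, robust = robust)
}
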