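# Synthetic-data generators. Every generator is deterministic given `seed`
# and returns its ground truth alongside the data; no hidden state.

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!is.na(seed) && abs(seed) >= 2^31)
      stop("seed must fit a 32-bit integer")
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

.runif_sphere <- function(n, radius, centre) {
  u <- matrix(stats::rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  r <- radius * stats::runif(n)^(1 / 3)
  sweep(u * r, 2, centre, "+")
}

.rand_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

#' Generate a synthetic peptide + water configuration with known ground truth
#'
#' Pseudo-atom peptides: one Calpha per residue (element C, spacing 3.8 A,
#' self-avoiding at `min_separation`) plus two imidazole nitrogens (ND1, NE2)
#' on each His residue. Waters are single oxygen points placed uniformly in
#' the box. In `condensed` mode every peptide atom lies within
#' `sphere_radius` of `sphere_center` and the returned truth records the
#' exact inside/outside water counts against that sphere.
#'
#' @param mode `"dispersed"` or `"condensed"`.
#' @param n_chains,chain_length Number of chains and residues per chain.
#' @param box Length-3 box edges (Angstrom) or a single cubic edge.
#' @param sphere_radius,sphere_center Condensed-mode confinement sphere
#'   (Angstrom; centre defaults to the box centre).
#' @param n_waters Number of water oxygens.
#' @param his_positions Residue indices (within each chain) carrying His with
#'   imidazole nitrogens; default two His per chain at roughly 1/3 and 2/3 of
#'   the sequence.
#' @param min_separation Self-avoidance distance between Calpha atoms
#'   (Angstrom).
#' @param water_margin Condensed mode: waters are rejected and resampled while
#'   their distance to the sphere surface is below this margin (Angstrom),
#'   keeping the inside/outside ground truth unambiguous. Default 0.
#' @param seed Integer seed (optional but recommended).
#' @param max_restarts Chain regrowth attempts before giving up.
#' @return List with `frame` (a `molecular_frame`) and `truth` (mode, counts,
#'   sphere, `n_waters_inside`, `his_positions`, seed).
#' @export
generate_configuration <- function(mode = c("dispersed", "condensed"),
                                   n_chains = 4L, chain_length = 8L,
                                   box = 120, sphere_radius = NULL,
                                   sphere_center = NULL, n_waters = 200L,
                                   his_positions = NULL,
                                   min_separation = 2.0, water_margin = 0,
                                   seed = NULL, max_restarts = 40L) {
  mode <- match.arg(mode)
  if (length(box) == 1L) box <- rep(box, 3)
  if (is.null(his_positions))
    his_positions <- unique(pmax(1L, pmin(chain_length,
      round(chain_length * c(1, 2) / 3))))
  if (mode == "condensed") {
    if (is.null(sphere_radius)) stop("condensed mode needs sphere_radius")
    if (is.null(sphere_center)) sphere_center <- box / 2
    if (any(sphere_center - sphere_radius < 0) ||
        any(sphere_center + sphere_radius > box))
      stop("confinement sphere does not fit in the box; use a larger box")
  }
  .with_seed(seed, {
    # Keep every atom's probe-expanded sphere (r_vdw + 1.4) inside the truth
    # sphere so the solvent-accessible boundary never crosses it and water
    # classification against the sphere is unambiguous.
    ca_margin <- 3.2
    n_margin <- 3.0
    placed <- matrix(numeric(0), 0, 3)
    chains <- vector("list", n_chains)
    inside_ok <- function(p) {
      if (mode != "condensed") return(TRUE)
      sqrt(sum((p - sphere_center)^2)) <= sphere_radius - ca_margin
    }
    clash <- function(p) {
      if (!nrow(placed)) return(FALSE)
      any(.mi_dist2_to_point(placed, p, box) < min_separation^2)
    }
    for (ch in seq_len(n_chains)) {
      ok <- FALSE
      for (restart in seq_len(max_restarts)) {
        pts <- matrix(NA_real_, chain_length, 3)
        start <- if (mode == "condensed")
          drop(.runif_sphere(1, max(sphere_radius - ca_margin, 1), sphere_center))
        else stats::runif(3) * box
        if (clash(start)) next
        pts[1, ] <- start
        failed <- FALSE
        for (k in seq_len(chain_length - 1L)) {
          found <- FALSE
          for (try in seq_len(100L)) {
            cand <- pts[k, ] + 3.8 * .rand_unit()
            if (!inside_ok(cand) || clash(cand)) next
            if (k >= 2L && sqrt(sum((cand - pts[k - 1L, ])^2)) < min_separation)
              next
            pts[k + 1L, ] <- cand
            found <- TRUE
            break
          }
          if (!found) { failed <- TRUE; break }
        }
        if (!failed) {
          placed <- rbind(placed, pts)
          chains[[ch]] <- pts
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not place chain ", ch, " after ", max_restarts,
                    " regrowth attempts; use a larger box or sphere")
    }
    rows <- list()
    for (ch in seq_len(n_chains)) {
      pts <- chains[[ch]]
      cid <- sprintf("C%02d", ch)
      for (k in seq_len(chain_length)) {
        is_his <- k %in% his_positions
        resn <- if (is_his) "HIS" else "GLY"
        rows[[length(rows) + 1L]] <- data.frame(
          element = "C", atom_name = "CA", residue_name = resn,
          residue_index = k, chain_id = cid,
          x = pts[k, 1], y = pts[k, 2], z = pts[k, 3])
        if (is_his) {
          ca <- pts[k, ]
          place_n <- function(dist) {
            for (try in seq_len(50L)) {
              p <- ca + dist * .rand_unit()
              if (mode != "condensed" ||
                  sqrt(sum((p - sphere_center)^2)) <= sphere_radius - n_margin)
                return(p)
            }
            # point towards the sphere centre: always inside
            ca + dist * (sphere_center - ca) /
              max(sqrt(sum((sphere_center - ca)^2)), 1e-9)
          }
          nd1 <- place_n(3.2)
          ne2 <- place_n(4.55)
          rows[[length(rows) + 1L]] <- data.frame(
            element = "N", atom_name = "ND1", residue_name = "HIS",
            residue_index = k, chain_id = cid,
            x = nd1[1], y = nd1[2], z = nd1[3])
          rows[[length(rows) + 1L]] <- data.frame(
            element = "N", atom_name = "NE2", residue_name = "HIS",
            residue_index = k, chain_id = cid,
            x = ne2[1], y = ne2[2], z = ne2[3])
        }
      }
    }
    n_inside <- NA_integer_
    if (n_waters > 0L) {
      w <- matrix(stats::runif(3 * n_waters), ncol = 3)
      w <- sweep(w, 2, box, "*")
      if (mode == "condensed" && water_margin > 0) {
        repeat {
          dsurf <- abs(sqrt(.mi_dist2_to_point(w, sphere_center, box)) -
                         sphere_radius)
          bad <- which(dsurf < water_margin)
          if (!length(bad)) break
          w[bad, ] <- sweep(matrix(stats::runif(3 * length(bad)), ncol = 3),
                            2, box, "*")
        }
      }
      if (mode == "condensed")
        n_inside <- sum(sqrt(.mi_dist2_to_point(w, sphere_center, box)) <=
                          sphere_radius)
      rows[[length(rows) + 1L]] <- data.frame(
        element = "O", atom_name = "O", residue_name = "HOH",
        residue_index = seq_len(n_waters), chain_id = "W",
        x = w[, 1], y = w[, 2], z = w[, 3])
    }
    atoms <- do.call(rbind, rows)
    frame <- molecular_frame(atoms, box, time = 0)
    truth <- list(mode = mode, n_chains = n_chains,
                  chain_length = chain_length,
                  sphere_center = if (mode == "condensed") sphere_center else NULL,
                  sphere_radius = if (mode == "condensed") sphere_radius else NULL,
                  n_waters_total = as.integer(n_waters),
                  n_waters_inside = n_inside,
                  his_positions = his_positions, seed = seed)
    list(frame = frame, truth = truth)
  })
}

#' Generate a synthetic collapse trajectory with known confinement radii
#'
#' Chains are grown once inside a sphere of `start_radius`; in later frames
#' the chain centroids are scaled radially towards the box centre so the
#' per-frame confinement radius interpolates linearly from `start_radius`
#' down to `end_radius` while each chain's internal conformation is kept
#' rigid. Frame 1 is the dispersed reference.
#'
#' @param n_frames Number of frames (>= 2).
#' @param start_radius,end_radius Confinement radii (Angstrom);
#'   `start_radius >= end_radius > 0`.
#' @param n_chains,chain_length,box,n_waters,his_positions,seed Passed to
#'   [generate_configuration()].
#' @return List with `trajectory` and `truth` (per-frame radii and scale
#'   factors plus the configuration truth).
#' @export
generate_collapse_series <- function(n_frames = 5L, start_radius = 60,
                                     end_radius = 25, n_chains = 8L,
                                     chain_length = 10L, box = 150,
                                     n_waters = 0L, his_positions = NULL,
                                     seed = NULL) {
  if (n_frames < 2L) stop("n_frames must be >= 2")
  if (end_radius <= 0 || start_radius < end_radius)
    stop("need start_radius >= end_radius > 0")
  if (length(box) == 1L) box <- rep(box, 3)
  base <- generate_configuration("condensed", n_chains, chain_length, box,
                                 sphere_radius = start_radius,
                                 n_waters = n_waters,
                                 his_positions = his_positions, seed = seed)
  centre <- box / 2
  radii <- seq(start_radius, end_radius, length.out = n_frames)
  scales <- radii / start_radius
  atoms0 <- base$frame$atoms
  pep <- !(atoms0$residue_name %in% .WATER_RESNAMES)
  key <- atoms0$chain_id
  frames <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    a <- atoms0
    for (cid in unique(key[pep])) {
      m <- which(pep & key == cid)
      xyz <- as.matrix(a[m, c("x", "y", "z")])
      cen <- colMeans(xyz)
      new_cen <- centre + scales[k] * (cen - centre)
      shift <- new_cen - cen
      a[m, c("x", "y", "z")] <- sweep(xyz, 2, shift, "+")
    }
    frames[[k]] <- molecular_frame(a, box, time = k - 1)
  }
  list(trajectory = trajectory(frames, metadata = "synthetic collapse series"),
       truth = list(radii = radii, scales = scales, config = base$truth))
}

#' Peptide concentration in a periodic box
#'
#' Converts a molecule count in a cubic box to a molar concentration:
#' c = n / (N_A * edge^3).
#'
#' @param n_molecules Number of molecules (>= 0).
#' @param box_edge_nm Box edge length in nm (> 0).
#' @return Concentration in mM.
#' @export
box_concentration <- function(n_molecules, box_edge_nm) {
  if (any(n_molecules < 0)) stop("n_molecules must be >= 0")
  if (any(box_edge_nm <= 0)) stop("box_edge_nm must be > 0")
  avogadro <- 6.02214076e23
  litres <- box_edge_nm^3 * 1e-24
  (n_molecules / avogadro) / litres * 1e3
}

#' FRAP ground-truth parameters
#'
#' Parameters of the normalized recovery model y(x) = a - b * c^x with x in
#' seconds from the bleach. Because the double-normalization pipeline pins the
#' post-bleach minimum sample to 0%, an exact channel-level round trip
#' requires the curve to start at zero, i.e. b = a; the generator therefore
#' defaults b to a and refuses other values.
#'
#' @param a Recovery plateau in percent (> 0).
#' @param c Decay base per second (0 < c < 1).
#' @param b Amplitude; must equal `a` (default).
#' @param noise_sd Gaussian channel noise, percent units (default 0).
#' @param bleach_index Index of the first post-bleach sample.
#' @param prebleach_n Number of pre-bleach samples used for the pre-bleach
#'   means.
#' @param seed Integer seed.
#' @return List of class `frap_truth`.
#' @export
frap_truth <- function(a = 80, c = 0.9, b = a, noise_sd = 0,
                       bleach_index = 6L, prebleach_n = bleach_index - 1L,
                       seed = NULL) {
  if (a <= 0 || b <= 0) stop("a and b must be > 0")
  if (c <= 0 || c >= 1) stop("c must lie in (0, 1)")
  if (abs(b - a) > 1e-12)
    stop("channel construction requires b = a (the normalization pins the ",
         "bleach sample to 0%)")
  if (bleach_index < 2L) stop("bleach_index must be >= 2")
  if (prebleach_n < 1L || prebleach_n > bleach_index - 1L)
    stop("prebleach_n must lie in [1, bleach_index - 1]")
  structure(list(a = a, b = b, c = c, noise_sd = noise_sd,
                 bleach_index = as.integer(bleach_index),
                 prebleach_n = as.integer(prebleach_n), seed = seed),
            class = "frap_truth")
}

#' Simulate three-channel FRAP traces from a known recovery curve
#'
#' Constructs background (R3), reference (R2, with optional photofading) and
#' bleached-ROI (R1) channels by algebraic inversion of the double
#' normalization, so that applying the correction and min-max normalization
#' to the noiseless channels reproduces y(t) = a - b * c^(t - t_bleach)
#' exactly. Gaussian noise (`noise_sd`, percent units) is added to R1 last.
#'
#' @param truth A [frap_truth()] object.
#' @param times Sample times in seconds (strictly increasing), at least
#'   `prebleach_n` samples before `bleach_index`.
#' @param background Background level R3 in AU (default 5).
#' @param i_pre,i_floor Corrected-trace AU anchors for 100% and 0%
#'   (default 120 and 20).
#' @param photofade Per-second multiplicative fading of the reference channel
#'   after the bleach (default 1 = none).
#' @return `data.frame` (class `timeseries_table`) with columns `time`, `R1`,
#'   `R2`, `R3`; the truth is attached as attribute `truth`.
#' @export
simulate_frap_channels <- function(truth, times, background = 5,
                                   i_pre = 120, i_floor = 20,
                                   photofade = 1) {
  stopifnot(inherits(truth, "frap_truth"))
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  if (truth$bleach_index > length(times))
    stop("bleach_index beyond the sampled times")
  t_bleach <- times[truth$bleach_index]
  post <- seq_along(times) >= truth$bleach_index
  y <- ifelse(post, truth$a - truth$b * truth$c^(times - t_bleach), 100)
  beta <- (i_pre - i_floor) / 100
  i_corr <- i_floor + beta * y
  phi <- ifelse(post, photofade^(times - t_bleach), 1)
  r3 <- rep(background, length(times))
  kappa <- 100  # reference amplitude above background, AU
  r2 <- r3 + kappa * phi
  r1 <- r3 + i_corr * phi
  .with_seed(truth$seed, {
    if (truth$noise_sd > 0)
      r1 <- r1 + stats::rnorm(length(times), sd = truth$noise_sd * beta)
    out <- data.frame(time = times, R1 = r1, R2 = r2, R3 = r3)
    attr(out, "truth") <- truth
    class(out) <- c("timeseries_table", "data.frame")
    out
  })
}

#' Kinetics ground-truth parameters
#'
#' @param v_max Maximal rate, mM/min (> 0).
#' @param k_m Michaelis constant, mM (> 0).
#' @param substrate Substrate concentrations in mM (default the assay's
#'   0.3-1.1 mM working window).
#' @param calibration_slope Product fluorescence per concentration, AU/mM.
#' @param background_slope Substrate-free drift, AU/min.
#' @param noise_sd Gaussian noise on signals, AU.
#' @param seed Integer seed.
#' @return List of class `kinetics_truth`.
#' @export
kinetics_truth <- function(v_max = 1, k_m = 0.5,
                           substrate = c(0.3, 0.5, 0.7, 0.9, 1.1),
                           calibration_slope = 2000, background_slope = 10,
                           noise_sd = 0, seed = NULL) {
  if (v_max <= 0 || k_m <= 0) stop("v_max and k_m must be > 0")
  if (any(substrate < 0)) stop("substrate concentrations must be >= 0")
  structure(list(v_max = v_max, k_m = k_m, substrate = substrate,
                 calibration_slope = calibration_slope,
                 background_slope = background_slope,
                 noise_sd = noise_sd, seed = seed),
            class = "kinetics_truth")
}

#' Simulate a fluorogenic ester-hydrolysis plate read
#'
#' Each substrate level S yields signal(t) = calibration_slope * V0(S) * t +
#' background_slope * t + noise with V0(S) = V_max * S / (K_m + S); a
#' substrate-free `control` column carries only background drift.
#'
#' @param truth A [kinetics_truth()] object.
#' @param times Sample times in minutes spanning at least 2.5 min.
#' @return `data.frame` (class `timeseries_table`) with `time`, one column
#'   per substrate level (named `S<conc>`) and `control`; truth attached as
#'   attribute `truth`.
#' @export
simulate_kinetics_plate <- function(truth, times = seq(0, 3, by = 0.25)) {
  stopifnot(inherits(truth, "kinetics_truth"))
  if (max(times) - min(times) < 2.5)
    stop("times must span at least 2.5 min")
  .with_seed(truth$seed, {
    out <- data.frame(time = times)
    for (s in truth$substrate) {
      v0 <- truth$v_max * s / (truth$k_m + s)
      sig <- truth$calibration_slope * v0 * times +
        truth$background_slope * times
      if (truth$noise_sd > 0)
        sig <- sig + stats::rnorm(length(times), sd = truth$noise_sd)
      out[[sprintf("S%g", s)]] <- sig
    }
    ctrl <- truth$background_slope * times
    if (truth$noise_sd > 0)
      ctrl <- ctrl + stats::rnorm(length(times), sd = truth$noise_sd)
    out$control <- ctrl
    attr(out, "truth") <- truth
    class(out) <- c("timeseries_table", "data.frame")
    out
  })
}

#' Ratiometric-probe ground-truth parameters
#'
#' @param r_acid,r_base Asymptotic emission ratios (must differ).
#' @param ph50 Inflection pH.
#' @param k Slope per pH unit (> 0).
#' @param ph pH value per ROI.
#' @param phase Optional phase label per ROI (`dense`/`dilute`).
#' @param image_id Optional image id per ROI.
#' @param noise_sd Relative Gaussian noise per emission channel (default 0).
#' @param i640 Mean 640 nm intensity in AU.
#' @param seed Integer seed.
#' @return List of class `ratio_truth`.
#' @export
ratio_truth <- function(r_acid = 2.0, r_base = 0.4, ph50 = 7.5, k = 1,
                        ph = seq(6.5, 9.0, by = 0.5), phase = NULL,
                        image_id = NULL, noise_sd = 0, i640 = 1000,
                        seed = NULL) {
  if (r_acid == r_base) stop("r_acid must differ from r_base")
  if (k <= 0) stop("k must be > 0")
  structure(list(r_acid = r_acid, r_base = r_base, ph50 = ph50, k = k,
                 ph = ph, phase = phase, image_id = image_id,
                 noise_sd = noise_sd, i640 = i640, seed = seed),
            class = "ratio_truth")
}

# forward 4PL model: emission ratio at a given pH
.logistic_ratio <- function(ph, r_acid, r_base, ph50, k) {
  r_acid + (r_base - r_acid) / (1 + 10^(k * (ph50 - ph)))
}

#' Simulate two-channel ratiometric emission ROIs
#'
#' Noiseless rows satisfy I580/I640 = logistic(pH) exactly; with noise both
#' channels receive independent multiplicative Gaussian perturbations.
#'
#' @param truth A [ratio_truth()] object.
#' @return `data.frame` with `image_id`, `phase`, `ph_true`, `I580`, `I640`;
#'   truth attached as attribute `truth`.
#' @export
simulate_ratiometric_rois <- function(truth) {
  stopifnot(inherits(truth, "ratio_truth"))
  n <- length(truth$ph)
  ratio <- .logistic_ratio(truth$ph, truth$r_acid, truth$r_base,
                           truth$ph50, truth$k)
  .with_seed(truth$seed, {
    e1 <- e2 <- rep(0, n)
    if (truth$noise_sd > 0) {
      e1 <- stats::rnorm(n, sd = truth$noise_sd)
      e2 <- stats::rnorm(n, sd = truth$noise_sd)
    }
    i640 <- truth$i640 * (1 + e2)
    i580 <- ratio * truth$i640 * (1 + e1)
    out <- data.frame(
      image_id = if (is.null(truth$image_id)) rep(1L, n) else truth$image_id,
      phase = if (is.null(truth$phase)) rep("dense", n) else truth$phase,
      ph_true = truth$ph, I580 = i580, I640 = i640)
    attr(out, "truth") <- truth
    out
  })
}
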