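# Synthetic-data generators: bookkeeping, determinism, constructed properties.

test_that("dispersed configurations honour chain/water bookkeeping", {
  g <- generate_configuration("dispersed", n_chains = 4, chain_length = 8,
                              box = 120, n_waters = 200, seed = 42)
  at <- g$frame$atoms
  expect_equal(length(unique(at$chain_id[is_peptide_atom(g$frame)])), 4L)
  expect_equal(sum(is_water_oxygen(g$frame)), 200L)
  expect_equal(sum(at$atom_name == "CA"), 4L * 8L)
  # consecutive Calpha spacing is the 3.8 A pseudo-bond
  ca <- at[at$atom_name == "CA" & at$chain_id == "C01", ]
  d <- sqrt(diff(ca$x)^2 + diff(ca$y)^2 + diff(ca$z)^2)
  expect_equal(d, rep(3.8, 7), tolerance = 1e-9)
  # His residues carry two imidazole nitrogens each
  n_his <- length(unique(paste(at$chain_id, at$residue_index)[at$residue_name == "HIS"]))
  expect_equal(sum(at$atom_name %in% c("ND1", "NE2")), 2L * n_his)
})

test_that("condensed configurations keep all peptide atoms inside the sphere", {
  g <- generate_configuration("condensed", n_chains = 6, chain_length = 10,
                              box = 80, sphere_radius = 25, n_waters = 100,
                              seed = 9)
  pep <- is_peptide_atom(g$frame)
  r <- sqrt(rowSums(sweep(frame_coords(g$frame)[pep, ], 2,
                          g$truth$sphere_center)^2))
  expect_true(all(r <= 25 + 1e-9))
  # truth counts match direct recount against the sphere
  w <- frame_coords(g$frame)[is_water_oxygen(g$frame), ]
  rw <- sqrt(rowSums(sweep(w, 2, g$truth$sphere_center)^2))
  expect_identical(g$truth$n_waters_inside, sum(rw <= 25))
  expect_true(g$truth$n_waters_inside <= g$truth$n_waters_total)
})

test_that("generation is deterministic given a seed", {
  g1 <- generate_configuration("condensed", n_chains = 3, chain_length = 6,
                               box = 60, sphere_radius = 20, n_waters = 50,
                               seed = 77)
  g2 <- generate_configuration("condensed", n_chains = 3, chain_length = 6,
                               box = 60, sphere_radius = 20, n_waters = 50,
                               seed = 77)
  expect_identical(g1$frame$atoms, g2$frame$atoms)
  expect_identical(g1$truth, g2$truth)
})

test_that("a sphere that does not fit the box is refused", {
  expect_error(generate_configuration("condensed", box = 40, sphere_radius = 25,
                                      seed = 1),
               "does not fit")
})

test_that("collapse series interpolates confinement radii monotonically", {
  cs <- generate_collapse_series(n_frames = 5, start_radius = 60,
                                 end_radius = 25, n_chains = 4,
                                 chain_length = 6, box = 150, seed = 4)
  expect_length(cs$trajectory, 5L)
  expect_true(all(diff(cs$truth$radii) < 0))
  expect_equal(cs$truth$radii[1], 60)
  expect_equal(cs$truth$radii[5], 25)
  # degenerate start = end gives a constant series
  cc <- generate_collapse_series(n_frames = 3, start_radius = 30,
                                 end_radius = 30, n_chains = 3,
                                 chain_length = 5, box = 100, seed = 4)
  expect_equal(cc$truth$radii, rep(30, 3))
  expect_equal(frame_coords(cc$trajectory$frames[[1]]),
               frame_coords(cc$trajectory$frames[[3]]))
  expect_error(generate_collapse_series(n_frames = 1, seed = 1), "n_frames")
})

test_that("box concentration reproduces the simulation-box value and units", {
  # 20 peptide copies in a 12.7 nm cubic box -> ~16 mM
  c20 <- box_concentration(20, 12.7)
  expect_equal(round(c20), 16)
  expect_equal(c20, 16.213, tolerance = 1e-3)
  expect_equal(box_concentration(0, 5), 0)
  # Avogadro arithmetic: 6.02214076e5 molecules = 1e-18 mol in
  # (1000 nm)^3 = 1e-15 L, i.e. 1e-3 mol/L = 1 mM
  expect_equal(box_concentration(602214.076, 1000), 1, tolerance = 1e-9)
})

test_that("FRAP channel construction inverts the correction pipeline exactly", {
  times <- seq(0, 90, by = 1.5)
  tr <- frap_truth(a = 72, c = 0.93, bleach_index = 8, seed = 1)
  ch <- simulate_frap_channels(tr, times, photofade = 0.997, background = 7)
  ft <- frap_trace(ch$time, ch$R1, ch$R2, ch$R3, bleach_index = 8)
  cn <- correct_and_normalize(ft)
  tb <- times[8]
  y <- ifelse(seq_along(times) >= 8, 72 - 72 * 0.93^(times - tb), 100)
  expect_equal(cn$I_normalized, y, tolerance = 1e-9)
  # zero photofade, zero background: R2 constant, R3 = 0
  ch0 <- simulate_frap_channels(tr, times, photofade = 1, background = 0)
  expect_equal(ch0$R3, rep(0, length(times)))
  expect_equal(diff(range(ch0$R2)), 0)
})

test_that("frap_truth validates its invariants", {
  expect_error(frap_truth(a = -1), "a and b")
  expect_error(frap_truth(c = 1.2), "c must lie")
  expect_error(frap_truth(a = 80, b = 60), "b = a")
  expect_error(frap_truth(bleach_index = 1), "bleach_index")
})

test_that("kinetics plate carries MM-shaped early slopes and a background control", {
  tr <- kinetics_truth(v_max = 1, k_m = 0.5, substrate = 0.5,
                       calibration_slope = 3, background_slope = 0.7,
                       noise_sd = 0, seed = 1)
  plate <- simulate_kinetics_plate(tr, times = seq(0, 3, by = 0.25))
  # V0(0.5) = 1*0.5/(0.5+0.5) = 0.5 -> early slope 0.5*3 + 0.7
  slope <- coef(lm(plate$S0.5 ~ plate$time))[2]
  expect_equal(unname(slope), 0.5 * 3 + 0.7, tolerance = 1e-9)
  ctrl_slope <- coef(lm(plate$control ~ plate$time))[2]
  expect_equal(unname(ctrl_slope), 0.7, tolerance = 1e-9)
  expect_error(kinetics_truth(substrate = -0.1), "substrate")
  expect_error(simulate_kinetics_plate(tr, times = seq(0, 1, by = 0.25)),
               "2.5 min")
})

test_that("ratiometric ROI simulation matches the logistic forward model", {
  tr <- ratio_truth(r_acid = 2, r_base = 0.4, ph50 = 7.5, k = 1,
                    ph = c(6.5, 7.5, 9.0), noise_sd = 0, seed = 3)
  rois <- simulate_ratiometric_rois(tr)
  ratio <- rois$I580 / rois$I640
  # midpoint of the logistic at pH50
  expect_equal(ratio[2], (2 + 0.4) / 2, tolerance = 1e-12)
  expect_error(ratio_truth(r_acid = 1, r_base = 1), "differ")
  expect_error(ratio_truth(k = 0), "k must be")
})
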