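# His Calpha pair distributions and LBHB geometric screening.

make_delta_traj <- function(sep, n_frames = 10, box = c(20, 20, 20)) {
  frames <- lapply(seq_len(n_frames), function(k) {
    at <- rbind(
      atom_row("C", "CA", "HIS", 1L, "A", 5, 5, 5),
      atom_row("C", "CA", "HIS", 1L, "B", 5 + sep, 5, 5))
    molecular_frame(at, box, time = k - 1)
  })
  trajectory(frames)
}

test_that("a fixed 7 A pair puts all mass in the containing bin", {
  pd <- his_ca_pair_distribution(make_delta_traj(7), bin_width = 0.2,
                                 r_max = 10)
  expect_equal(sum(pd$counts), 10)  # 1 pair x 10 frames
  hit <- which(pd$counts > 0)
  expect_length(hit, 1L)
  expect_true(pd$bin_edges[hit] <= 7 && 7 <= pd$bin_edges[hit + 1L])
  # normalization identity: density integrates back to the tally
  expect_equal(sum(pd$normalized_density * pd$bin_width * pd$n_pairs *
                     pd$n_frames), sum(pd$counts))
})

test_that("intermolecular-only selection requires two chains", {
  frames <- lapply(1:2, function(k) {
    at <- rbind(atom_row("C", "CA", "HIS", 1L, "A", 5, 5, 5),
                atom_row("C", "CA", "HIS", 3L, "A", 12, 5, 5))
    molecular_frame(at, c(20, 20, 20), time = k - 1)
  })
  expect_error(his_ca_pair_distribution(trajectory(frames)), "two chains")
  # same-chain pairs are tallied when the flag is off
  pd <- his_ca_pair_distribution(trajectory(frames),
                                 intermolecular_only = FALSE)
  expect_equal(sum(pd$counts), 2)
})

test_that("histogram totals are conserved under bin-width changes", {
  g <- generate_configuration("condensed", n_chains = 6, chain_length = 9,
                              box = 70, sphere_radius = 22, n_waters = 0,
                              seed = 19)
  fr <- g$frame; fr$time <- 0
  traj <- trajectory(list(fr))
  t1 <- his_ca_pair_distribution(traj, bin_width = 0.1, r_max = 12)
  t2 <- his_ca_pair_distribution(traj, bin_width = 0.7, r_max = 12)
  expect_equal(sum(t1$counts), sum(t2$counts))
})

test_that("cell-list and brute-force tallies agree on random periodic atoms", {
  set.seed(77)
  box <- c(30, 30, 30)
  xyz <- sweep(matrix(runif(150), ncol = 3), 2, box, "*")
  at <- data.frame(element = "C", atom_name = "CA", residue_name = "HIS",
                   residue_index = 1L,
                   chain_id = sprintf("C%02d", seq_len(50)),
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  fr <- molecular_frame(at, box, time = 0)
  traj <- trajectory(list(fr))
  edges <- seq(0, 10, by = 0.25)
  pd_cell <- his_ca_pair_distribution(traj, bin_width = 0.25, r_max = 10,
                                      method = "cell")
  pd_brute <- his_ca_pair_distribution(traj, bin_width = 0.25, r_max = 10,
                                       method = "brute")
  oracle <- brute_pair_histogram(xyz, box, edges)
  expect_equal(pd_cell$counts, pd_brute$counts)
  expect_equal(pd_cell$counts, oracle)
})

test_that("the exemplar LBHB geometries are flagged and counterexamples are not", {
  # short N-N with a constrained Calpha spacing inside the supportive window
  expect_equal(nrow(lbhb_screen(his_pair_frame(2.58, 7.86))), 1L)
  # the active-site Calpha spacing with a short N-N contact
  expect_equal(nrow(lbhb_screen(his_pair_frame(2.60, 6.67))), 1L)
  # too-long N-N, or Calpha spacing outside the 5-11 A window
  expect_equal(nrow(lbhb_screen(his_pair_frame(3.50, 7.86))), 0L)
  expect_equal(nrow(lbhb_screen(his_pair_frame(2.58, 12.0))), 0L)
  expect_equal(nrow(lbhb_screen(his_pair_frame(2.58, 4.0))), 0L)
  # reported geometry matches the construction
  hit <- lbhb_screen(his_pair_frame(2.58, 7.86))
  expect_equal(hit$d_nn, 2.58, tolerance = 1e-9)
  expect_equal(hit$d_caca, 7.86, tolerance = 1e-9)
})

test_that("screening uses the closest nitrogen combination and minimum image", {
  # two nitrogens per residue; only the closest combination must decide
  at <- rbind(
    atom_row("C", "CA",  "HIS", 1L, "A", 20, 20, 20),
    atom_row("N", "ND1", "HIS", 1L, "A", 23.2, 20, 20),
    atom_row("N", "NE2", "HIS", 1L, "A", 20, 24.55, 20),
    atom_row("C", "CA",  "HIS", 1L, "B", 27.5, 20, 20),
    atom_row("N", "ND1", "HIS", 1L, "B", 25.7, 20, 20),
    atom_row("N", "NE2", "HIS", 1L, "B", 27.5, 24, 20))
  fr <- molecular_frame(at, c(50, 50, 50))
  hit <- lbhb_screen(fr)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$d_nn, 2.5, tolerance = 1e-9)
  # across the periodic boundary
  at2 <- rbind(
    atom_row("C", "CA",  "HIS", 1L, "A", 1, 10, 10),
    atom_row("N", "ND1", "HIS", 1L, "A", 2.5, 10, 10),
    atom_row("C", "CA",  "HIS", 1L, "B", 24.5, 10, 10),
    atom_row("N", "NE2", "HIS", 1L, "B", 29.9, 10, 10))
  fr2 <- molecular_frame(at2, c(30, 30, 30))
  hit2 <- lbhb_screen(fr2)
  expect_equal(nrow(hit2), 1L)
  expect_equal(hit2$d_nn, 2.6, tolerance = 1e-9)   # 29.9 -> -0.1 vs 2.5
  expect_equal(hit2$d_caca, 6.5, tolerance = 1e-9) # 24.5 -> -5.5 vs 1
})

test_that("screening output is invariant to atom ordering", {
  fr <- his_pair_frame(2.58, 7.86)
  perm <- c(3, 1, 4, 2)
  fr2 <- molecular_frame(fr$atoms[perm, ], fr$box)
  a <- lbhb_screen(fr)
  b <- lbhb_screen(fr2)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("near-coplanarity is enforced when full rings are present", {
  ring_at <- function(chain, centre, normal_tilt) {
    # planar 5-ring in the xy plane, optionally tilted about x
    ang <- seq(0, 2 * pi, length.out = 6)[1:5]
    ring <- cbind(1.2 * cos(ang), 1.2 * sin(ang), 0)
    if (normal_tilt != 0) {
      ct <- cos(normal_tilt); st <- sin(normal_tilt)
      ring <- ring %*% matrix(c(1, 0, 0, 0, ct, st, 0, -st, ct), 3, 3)
    }
    ring <- sweep(ring, 2, centre, "+")
    rbind(
      atom_row("C", "CA", "HIS", 1L, chain, centre[1] - 3, centre[2], centre[3]),
      data.frame(element = c("C", "N", "C", "C", "N"),
                 atom_name = c("CG", "ND1", "CD2", "CE1", "NE2"),
                 residue_name = "HIS", residue_index = 1L, chain_id = chain,
                 x = ring[, 1], y = ring[, 2], z = ring[, 3]))
  }
  # coplanar rings with a short N-N contact: flagged
  a1 <- ring_at("A", c(20, 20, 20), 0)
  b1 <- ring_at("B", c(22.4, 20, 20), 0)
  fr_cop <- molecular_frame(rbind(a1, b1), c(50, 50, 50))
  expect_gt(nrow(lbhb_screen(fr_cop, d_nn_max = 3.5, d_caca_range = c(1, 11),
                             plane_angle_max = 30)), 0)
  # same geometry with one ring tilted by 60 degrees: rejected
  b2 <- ring_at("B", c(22.4, 20, 20), pi / 3)
  fr_tilt <- molecular_frame(rbind(a1, b2), c(50, 50, 50))
  expect_equal(nrow(lbhb_screen(fr_tilt, d_nn_max = 3.5,
                                d_caca_range = c(1, 11),
                                plane_angle_max = 30)), 0L)
})
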