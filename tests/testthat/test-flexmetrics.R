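# Distance series, exceedance probabilities, the SDRP statistic and
# two-ensemble comparison, each checked against independent oracles.

test_that("pair distances are analytic on hand-placed atoms in every mode", {
  for (mode in c("sidechain_centroid", "min_heavy")) {
    ens <- dist_ensemble(10, atom = "CB")
    s <- pair_distance_series(ens, pair_ab(mode))
    expect_equal(s$values, 10)
  }
  ens <- dist_ensemble(10, atom = "CA")
  s <- pair_distance_series(ens, pair_ab("ca"))
  expect_equal(s$values, 10)
})

test_that("planted generator distances are reproduced exactly", {
  planted <- c(20.0, 21.5, 19.0, 22.3, 20.0)
  ens <- dist_ensemble(planted)
  s <- pair_distance_series(ens, pair_ab())
  expect_equal(s$values, planted, tolerance = 1e-12)

  # and through the full generator + PDB round trip, to file precision
  sim <- simulate_breathing_ensemble(breathing_params(n_frames = 50, seed = 4),
                                     "free")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(sim$ensemble, path)
  back <- read_ensemble(path)
  for (i in 1:4) {
    truth <- sim$truth$distance[sim$truth$pair == paste0("pair", i)]
    got <- pair_distance_series(back, sim$pairs[[i]])$values
    expect_lt(max(abs(got - truth)), 0.002)
  }
})

test_that("degenerate and unresolvable selections are clear errors", {
  ens <- dist_ensemble(c(10, 0.0))   # members coincide in frame 2
  expect_error(pair_distance_series(ens, pair_ab()), "coincide")
  expect_error(pair_distance_series(dist_ensemble(10),
                                    residue_pair("A", 9, "B", 2)),
               "selection error")
  expect_error(pair_distance_series(dist_ensemble(10),
                                    pair_ab("ca")),
               "selection error")  # no CA atom in the CB-only fixture
  expect_error(residue_pair("A", 1, "A", 1), "distinct")
})

test_that("hydrogens are excluded from every distance mode", {
  # residue B carries an H atom far off-axis; distances must ignore it
  atoms <- data.frame(chain = c("A", "B", "B"), resnum = c(1L, 2L, 2L),
                      resname = "ALA",
                      atom_name = c("CB", "CB", "HB"),
                      element = c("C", "C", "H"))
  coords <- array(c(0, 10, 10, 0, 0, 99, 0, 0, 0), dim = c(3, 3, 1))
  ens <- ensemble(atoms, coords)
  for (mode in c("sidechain_centroid", "min_heavy")) {
    p <- residue_pair("A", 1, "B", 2, distance_mode = mode)
    expect_equal(pair_distance_series(ens, p)$values, 10)
  }
})

test_that("exceedance probability has the stated edge behaviour", {
  const <- pair_distance_series(dist_ensemble(rep(10, 20)), pair_ab())
  expect_equal(exceedance_probability(const, 0.5), 0)

  shifted <- pair_distance_series(dist_ensemble(c(10, rep(15, 9))), pair_ab())
  expect_equal(exceedance_probability(shifted, 2), 0.9)  # reference frame 1

  # strictly-greater comparison at the boundary
  s <- pair_distance_series(dist_ensemble(c(10, 12, 12.1)), pair_ab())
  expect_equal(exceedance_probability(s, 2), 1 / 3)
  expect_error(exceedance_probability(s, -1), "positive")
})

test_that("exceedance is monotone non-increasing in the threshold", {
  sim <- simulate_breathing_ensemble(breathing_params(n_frames = 2000,
                                                      seed = 11), "free")
  s <- pair_distance_series(sim$ensemble, sim$pairs[[2]])
  th <- seq(0.2, 4, by = 0.2)
  p <- vapply(th, function(t) exceedance_probability(s, t), 0)
  expect_true(all(diff(p) <= 0))
})

test_that("measured exceedance matches the stationary Gaussian oracle", {
  par <- breathing_params(sigma = 1.2, n_frames = 20000, seed = 1)
  sim <- simulate_breathing_ensemble(par, "free")
  s <- pair_distance_series(sim$ensemble, sim$pairs[[1]])
  expect_lt(abs(exceedance_probability(s, 2.0) - analytic_exceedance(1.2, 2.0)),
            0.01)
})

test_that("SDRP is the hand sum, permutation-invariant, and binned at
           multiples of the bin width", {
  ens1 <- four_pair_ensemble(matrix(c(20, 19, 18, 19), nrow = 1))
  prof <- sdrp_profile(ens1, four_pairs())
  expect_equal(prof$sdrp_values, 76.0)
  expect_equal(prof$modal_bin, c(76, 78))
  expect_equal(prof$representative_frames, 1L)

  perm <- sdrp_profile(ens1, four_pairs()[c(3, 1, 4, 2)])
  expect_equal(perm$sdrp_values, prof$sdrp_values)

  # hand-counted histogram: values 76.5, 77.2, 70.1 with width 2
  m <- rbind(c(19.5, 19, 19, 19), c(19.7, 19.5, 19, 19),
             c(17.1, 18, 17, 18))
  prof2 <- sdrp_profile(four_pair_ensemble(m), four_pairs())
  expect_equal(prof2$sdrp_values, c(76.5, 77.2, 70.1))
  expect_equal(prof2$modal_bin, c(76, 78))
  expect_equal(prof2$counts[c(1, length(prof2$counts))], c(1L, 2L))
  expect_equal(sum(prof2$counts), 3L)

  expect_error(sdrp_profile(ens1, four_pairs()[1:3]), "exactly 4")
})

test_that("SDRP counts conserve frames and representatives sit in the
           modal bin, nearest the midpoint first", {
  sim <- simulate_breathing_ensemble(breathing_params(n_frames = 500,
                                                      seed = 9), "free")
  prof <- sdrp_profile(sim$ensemble, sim$pairs)
  expect_equal(sum(prof$counts), 500L)
  reps <- prof$representative_frames
  expect_true(all(prof$sdrp_values[reps] >= prof$modal_bin[1] &
                    prof$sdrp_values[reps] < prof$modal_bin[2]))
  mid <- mean(prof$modal_bin)
  expect_true(all(diff(abs(prof$sdrp_values[reps] - mid)) >= 0))
})

test_that("SDRP scales linearly with the coordinates", {
  sim <- simulate_breathing_ensemble(breathing_params(n_frames = 20,
                                                      seed = 6), "free")
  ens <- sim$ensemble
  scaled <- ensemble(ens$atoms, ens$coords * 2.5)
  s1 <- sdrp_profile(ens, sim$pairs)$sdrp_values
  s2 <- sdrp_profile(scaled, sim$pairs)$sdrp_values
  expect_equal(s2, 2.5 * s1, tolerance = 1e-9)
})

test_that("vectorised distances and SDRP agree with a brute-force
           per-frame loop to 1e-9", {
  sim <- simulate_breathing_ensemble(breathing_params(n_frames = 50,
                                                      seed = 12), "free")
  ens <- sim$ensemble
  for (mode in c("sidechain_centroid", "ca", "min_heavy")) {
    pairs <- synthetic_pairs(mode)
    brute <- sapply(1:4, function(i) {
      brute_pair_distance(ens, "A", 100 + i, "B", 200 + i, mode)
    })
    fast <- sapply(pairs, function(p) pair_distance_series(ens, p)$values)
    expect_lt(max(abs(fast - brute)), 1e-9)
    expect_lt(max(abs(sdrp_profile(ens, pairs)$sdrp_values - rowSums(brute))),
              1e-9)
  }
})

test_that("pocket geometry reads off the frame distances and validates
           the frame index", {
  m <- rbind(c(12, 8, 10, 10), c(14, 9, 10, 10))
  ens <- four_pair_ensemble(m)
  pairs <- four_pairs()
  g <- pocket_geometry(ens, 1, pairs[[1]], pairs[[2]])
  expect_equal(g$length, 12)
  expect_equal(g$width, 8)
  g2 <- pocket_geometry(ens, 2, pairs[[1]], pairs[[2]])
  expect_equal(g2$length, 14)
  expect_error(pocket_geometry(ens, 3, pairs[[1]], pairs[[2]]),
               "out of range")
})

test_that("comparing an ensemble with itself gives ties; swapping
           arguments negates deltas", {
  sim <- simulate_breathing_ensemble(breathing_params(n_frames = 300,
                                                      seed = 8), "free")
  teth <- simulate_breathing_ensemble(breathing_params(n_frames = 300,
                                                       seed = 8), "tethered")
  self <- compare_ensembles(sim$ensemble, sim$ensemble, sim$pairs)
  expect_true(all(self$delta == 0))
  expect_true(all(self$verdict == "tie"))

  ab <- compare_ensembles(sim$ensemble, teth$ensemble, sim$pairs)
  ba <- compare_ensembles(teth$ensemble, sim$ensemble, sim$pairs)
  expect_equal(ab$delta, -ba$delta)
  expect_equal(ab$verdict == "A", ba$verdict == "B")
})

test_that("the free ensemble is the more flexible on all pairs under the
           planted contrast", {
  par <- breathing_params(tether_factor = 0.4, d0_shift = 1.5,
                          n_frames = 5000, seed = 1)
  free <- simulate_breathing_ensemble(par, "free")
  teth <- simulate_breathing_ensemble(par, "tethered")
  cmp <- compare_ensembles(free$ensemble, teth$ensemble, free$pairs)
  expect_true(all(cmp$verdict == "A"))
  expect_identical(cmp$overall_verdict, "A")
  expect_gt(cmp$modal_bin_a[1], cmp$modal_bin_b[1])
})
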