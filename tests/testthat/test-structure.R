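# Structure loading, chemistry attachment, centering/alignment and segment
# annotation.

test_that("a toy PDB loads with chemistry attached and survives a round trip", {
  toy <- toy_fixture()
  ch <- read_channel(toy$path, hi_source = "bfactor", hi_noise = FALSE)
  expect_equal(ch$n_atoms, nrow(toy$atoms))
  # PDB stores 3 decimals; fixture coordinates are pre-rounded, so exact
  expect_equal(ch$atoms$x, toy$atoms$x, tolerance = 1e-3)
  expect_equal(ch$atoms$y, toy$atoms$y, tolerance = 1e-3)
  expect_equal(ch$atoms$z, toy$atoms$z, tolerance = 1e-3)
  expect_equal(ch$atoms$hi, toy$atoms$hi, tolerance = 1e-9)
  expect_true(all(ch$atoms$vdw > 0))
  expect_true(all(ch$atoms$mass > 0))
})

test_that("a single-atom PDB is the identity case", {
  f <- tempfile(fileext = ".pdb")
  atoms <- data.frame(serial = 1:2, atom_name = c("C1", "HB1"),
                      res_name = "GLY", chain = "A", res_seq = 1,
                      x = c(0, 1), y = 0, z = 0, element = c("C", "H"))
  write_pdb(atoms, f)
  ch <- read_channel(f, hi_noise = FALSE)
  expect_equal(ch$n_atoms, 2)
  expect_equal(ch$atoms$vdw, c(1.70, 1.20))
  expect_equal(ch$atoms$hi, c(0.5, 0.5))   # carbon and C-bound hydrogen apolar
})

test_that("unprotonated and unknown-element structures raise hard errors", {
  f <- tempfile(fileext = ".pdb")
  atoms <- data.frame(serial = 1:3, atom_name = "C1", res_name = "GLY",
                      chain = "A", res_seq = 1:3,
                      x = c(0, 3, 6), y = 0, z = 0, element = "C")
  write_pdb(atoms, f)
  expect_error(read_channel(f), "unprotonated")

  atoms$element <- c("C", "XX", "H")
  write_pdb(atoms, f)
  expect_error(read_channel(f), "serial 2.*'XX'|'XX'")
})

test_that("table-based hydropathic indices follow the polar/apolar rule", {
  f <- tempfile(fileext = ".pdb")
  atoms <- data.frame(serial = 1:6,
                      atom_name = c("N", "CA", "C", "O", "H", "HA"),
                      res_name = "ALA", chain = "A", res_seq = 1,
                      x = seq(0, 5), y = 0, z = 0,
                      element = c("N", "C", "C", "O", "H", "H"))
  write_pdb(atoms, f)
  ch <- read_channel(f, hi_noise = FALSE)
  # backbone N, carbonyl C, O and amide H polar; CA and HA apolar
  expect_equal(ch$atoms$hi, c(-0.5, 0.5, -0.5, -0.5, -0.5, 0.5))
  # per-atom override wins
  ch2 <- read_channel(f, chem = chemistry_tables(hi_atom = c("ALA:CA" = -1)),
                      hi_noise = FALSE)
  expect_equal(ch2$atoms$hi[2], -1)
})

test_that("mass centering matches the weighted mean and is idempotent", {
  # masses 1 and 3 at z = 0 and 4 -> centroid at z = 3
  ch <- mk_channel(rbind(c(0, 0, 0), c(0, 0, 4), c(1, 0.5, 2), c(-1, -0.5, 2)),
                   mass = c(1, 3, 1e-6, 1e-6), aligned = FALSE)
  al <- align_channel(ch)
  w <- al$atoms$mass / sum(al$atoms$mass)
  expect_lt(abs(sum(w * al$atoms$z)), 1e-6)
  expect_equal(abs(al$mass_center[3]), 3, tolerance = 1e-4)

  # idempotence on a generic cloud
  ch2 <- mk_channel(rand_cloud(300, seed = 5), aligned = FALSE)
  once <- align_channel(ch2)
  twice <- align_channel(once)
  expect_equal(cbind(twice$atoms$x, twice$atoms$y, twice$atoms$z),
               cbind(once$atoms$x, once$atoms$y, once$atoms$z),
               tolerance = 1e-9)
})

test_that("two equal masses on z need no rotation", {
  ch <- mk_channel(rbind(c(0, 0, -5), c(0, 0, 5)), aligned = FALSE)
  al <- align_channel(ch)
  expect_equal(al$atoms$z, c(-5, 5), tolerance = 1e-9)
  expect_equal(abs(det(al$rotation)), 1, tolerance = 1e-9)
})

test_that("alignment recovers a randomly rotated long axis (vs brute-force inertia)", {
  xyz <- rand_cloud(400, seed = 11, spread = c(6, 8, 30))
  set.seed(99)
  th <- runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])), c(0, sin(th[1]), cos(th[1])))
  Rz <- rbind(c(cos(th[2]), -sin(th[2]), 0), c(sin(th[2]), cos(th[2]), 0), c(0, 0, 1))
  rot <- Rz %*% Rx
  ch <- mk_channel(xyz %*% t(rot), aligned = FALSE)
  al <- align_channel(ch)
  axis <- brute_principal_axis(cbind(al$atoms$x, al$atoms$y, al$atoms$z),
                               al$atoms$mass)
  angle <- acos(min(1, abs(axis[3])))
  expect_lt(angle, 1e-6)
  # rigid rotation preserves pairwise distances
  pick <- 1:40
  d0 <- dist(xyz[pick, ] %*% t(rot))
  d1 <- dist(cbind(al$atoms$x, al$atoms$y, al$atoms$z)[pick, ])
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-9)
})

test_that("degenerate inertia (ambiguous axis) raises an error", {
  # regular octahedron: all three moments equal, no unique long axis
  oct <- rbind(c(10, 0, 0), c(-10, 0, 0), c(0, 10, 0),
               c(0, -10, 0), c(0, 0, 10), c(0, 0, -10))
  expect_error(align_channel(mk_channel(oct, aligned = FALSE)), "degenerate")
})

test_that("hydropathic noise is seed-reproducible and off by default means identity", {
  toy <- toy_fixture()
  ch0 <- read_channel(toy$path, hi_source = "bfactor", hi_noise = FALSE)
  expect_identical(ch0$atoms$hi_noisy, ch0$atoms$hi)
  ch1 <- read_channel(toy$path, hi_source = "bfactor", noise_seed = 7)
  ch2 <- read_channel(toy$path, hi_source = "bfactor", noise_seed = 7)
  expect_identical(ch1$atoms$hi_noisy, ch2$atoms$hi_noisy)
  expect_false(identical(ch1$atoms$hi_noisy, ch1$atoms$hi))
  expect_equal(sd(ch1$atoms$hi_noisy - ch1$atoms$hi), 0.001, tolerance = 0.1)
})

test_that("segment annotation maps residues to segments and domains", {
  ch <- mk_channel(rand_cloud(60, seed = 3), res_seq = rep(1:60))
  map <- data.frame(chain = "*", res_start = 10, res_end = 50, segment = "S5")
  an <- annotate_segments(ch, map)
  expect_true(all(an$atoms$segment[an$atoms$res_seq %in% 10:50] == "S5"))
  expect_true(all(an$atoms$domain[an$atoms$segment == "S5"] == "PD"))
  expect_true(all(an$atoms$segment[an$atoms$res_seq < 10] == "other"))

  # empty map -> everything "other"
  an0 <- annotate_segments(ch, map[0, ])
  expect_true(all(an0$atoms$segment == "other"))

  # overlapping ranges are rejected
  bad <- rbind(map, data.frame(chain = "*", res_start = 40, res_end = 60,
                               segment = "S6"))
  expect_error(annotate_segments(ch, bad), "overlap")
})

test_that("VSD/PD fractions match an independent per-residue tally", {
  toy <- toy_fixture()
  ch <- read_channel(toy$path, hi_source = "bfactor", hi_noise = FALSE)
  ch <- annotate_segments(ch, toy$segment_map)
  m <- toy$segment_map
  vsd_res <- unlist(mapply(seq, m$res_start[m$segment %in% .vsd_labels],
                           m$res_end[m$segment %in% .vsd_labels]))
  brute <- sum(ch$atoms$res_seq %in% vsd_res)
  expect_identical(sum(ch$atoms$domain == "VSD"), brute)
})
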