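test_that("alpha-carbon distances resolve through the site map", {
  st <- two_site_structure(29.06)
  map <- tnc_map()
  expect_equal(ca_distance(st, "cTnC:13", "cTnC:51", map), 29.06,
               tolerance = 1e-6)
  # symmetric, zero on identical sites
  expect_equal(ca_distance(st, "cTnC:51", "cTnC:13", map),
               ca_distance(st, "cTnC:13", "cTnC:51", map))
  expect_identical(ca_distance(st, "cTnC:13", "cTnC:13", map), 0)
  expect_error(ca_distance(st, "cTnC:13", "cTnC:999", map), "999")

  # brute-force arithmetic on a hand-placed three-atom chain
  atoms <- data.frame(chain = "A", resno = 1:3, resid = "GLY",
                      elety = "CA",
                      x = c(0, 3, 3), y = c(0, 0, 4), z = 0,
                      stringsAsFactors = FALSE)
  toy <- structure_model(atoms)
  m2 <- site_map(copies = list(c(X = "A")))
  expect_equal(ca_distance(toy, "X:1", "X:3", m2), 5)
})

test_that("pocket openness is a threshold call on the 13-51 distance", {
  map <- tnc_map()
  open <- pocket_openness(two_site_structure(29.06), map)
  expect_identical(open$state, "open")
  closed <- pocket_openness(two_site_structure(19.21), map)
  expect_identical(closed$state, "closed")
  # boundary convention: exactly at threshold counts as open
  at <- pocket_openness(two_site_structure(24), map, threshold = 24)
  expect_identical(at$state, "open")
  # pure threshold function of ca_distance
  for (d in c(15, 22, 24.5, 31)) {
    ps <- pocket_openness(two_site_structure(d), map)
    expect_identical(ps$state,
                     if (ps$d_13_51 >= ps$threshold) "open" else "closed")
    expect_equal(ps$d_13_51, d, tolerance = 1e-6)
  }
})

test_that("an ideal helix carries the full i -> i+4 hydrogen-bond ladder", {
  h <- make_structure("ideal_helix", n_residues = 12)
  hb <- detect_hbonds(h)
  bb <- hb[hb$donor_atom == "N" & hb$acceptor_atom == "O", ]
  expect_identical(bb$acceptor_resno, 1:8)
  expect_identical(bb$donor_resno, 5:12)
  expect_true(all(bb$distance <= 3.5))
  expect_true(all(bb$angle >= 120))
})

test_that("hydrogen-bond cutoffs are sharp", {
  h <- make_structure("ideal_helix", n_residues = 8)
  d_on <- detect_hbonds(h)$distance[1]
  expect_gt(nrow(detect_hbonds(h, d_cut = d_on + 0.01)), 0)
  expect_identical(nrow(detect_hbonds(h, d_cut = d_on - 0.01)), 0L)
})

test_that("hydrogen bonds are invariant under rigid motion", {
  set.seed(21)
  h <- make_structure("ideal_helix", n_residues = 10)
  moved <- transform_structure(h, random_rotation(), rnorm(3, sd = 20))
  a <- detect_hbonds(h)
  b <- detect_hbonds(moved)
  expect_identical(a[, 1:6], b[, 1:6])
  expect_equal(a$distance, b$distance, tolerance = 1e-9)
  expect_equal(a$angle, b$angle, tolerance = 1e-8)
})

test_that("helix assignment finds one segment on an ideal helix and none on a strand", {
  h <- make_structure("ideal_helix", n_residues = 12)
  ah <- assign_helices(h)
  expect_identical(nrow(ah$segments), 1L)
  expect_identical(ah$segments$start, 2L)
  expect_identical(ah$segments$end, 12L)

  ext <- make_structure("extended_chain", n_residues = 12)
  expect_identical(nrow(assign_helices(ext)$segments), 0L)
})

test_that("helix assignment is length covariant with fixed end effects", {
  ends <- sapply(c(10, 14, 18), function(n) {
    seg <- assign_helices(make_structure("ideal_helix", n_residues = n))$segments
    c(seg$end - seg$start + 1L, n)
  })
  # interior segment length n - k for constant k
  expect_equal(unique(ends[2, ] - ends[1, ]), 1)
})

test_that("displacing the middle of a helix splits the segment", {
  h <- make_structure("ideal_helix", n_residues = 20)
  atoms <- h$atoms
  mid <- atoms$resno %in% 10:12
  atoms$x[mid] <- atoms$x[mid] + 3
  broken <- structure_model(atoms)
  segs <- assign_helices(broken)$segments
  expect_identical(nrow(segs), 2L)
  expect_true(all(segs$end - segs$start + 1L >= 4L))
})

test_that("helix axis angles reproduce constructed geometry", {
  h <- make_structure("ideal_helix", n_residues = 11)
  seg <- list(chain = "A", start = 1, end = 11)
  expect_lt(helix_axis_angle(h, seg, seg), 1e-4)

  # second helix rotated to be orthogonal
  ax <- trfret:::helix_axis(h, seg)
  perp <- c(-ax[2], ax[1], 0)
  perp <- perp / sqrt(sum(perp^2))
  # Rodrigues rotation by 90 degrees about 'perp'
  K <- matrix(c(0, -perp[3], perp[2],
                perp[3], 0, -perp[1],
                -perp[2], perp[1], 0), 3, byrow = TRUE)
  R <- diag(3) + K + K %*% K
  other <- transform_structure(h, R, c(30, 0, 0))
  other$atoms$chain <- "B"
  both <- structure_model(rbind(h$atoms, other$atoms))
  seg2 <- list(chain = "B", start = 1, end = 11)
  ang <- helix_axis_angle(both, seg, seg2)
  expect_equal(ang, 90, tolerance = 2)

  # both segments rotated together: angle unchanged
  moved <- transform_structure(both, random_rotation(), c(5, -4, 2))
  expect_equal(helix_axis_angle(moved, seg, seg2), ang, tolerance = 1e-6)
  expect_error(helix_axis_angle(h, list(chain = "A", start = 1, end = 4),
                                seg), "degenerate")
})

test_that("Kabsch RMSD is zero under rigid motion and matches closed forms", {
  set.seed(8)
  h <- make_structure("ideal_helix", n_residues = 34)  # ~100 backbone atoms
  sel <- seq_len(nrow(h$atoms))[1:100]
  base <- h$frames[1, ]
  moved <- transform_structure(h, random_rotation(), rnorm(3, sd = 15))
  frames <- rbind(base, moved$frames[1, ])
  r <- kabsch_rmsd(frames, reference = 1, selection = sel)
  expect_equal(r[1], 0, tolerance = 1e-10)
  expect_lt(r[2], 1e-8)

  # one atom displaced by 1 A among 100: RMSD ~ sqrt(1/100)
  xyz <- matrix(base, ncol = 3, byrow = TRUE)[1:100, ]
  pert <- xyz
  pert[7, 1] <- pert[7, 1] + 1
  fr2 <- rbind(as.numeric(t(xyz)), as.numeric(t(pert)))
  r2 <- kabsch_rmsd(fr2, reference = 1)
  expect_equal(r2[2], 0.1, tolerance = 0.02)
  # and it agrees exactly with the quaternion superposition oracle
  expect_equal(r2[2], quat_rmsd(pert, xyz), tolerance = 1e-8)

  expect_error(kabsch_rmsd(fr2[, 1:6, drop = FALSE]), "3 atoms")
})

test_that("Kabsch RMSD agrees with the quaternion oracle on random configurations", {
  set.seed(31)
  for (k in 1:25) {
    P <- matrix(rnorm(12, sd = 5), 4, 3)
    Q <- P + matrix(rnorm(12, sd = runif(1, 0.1, 2)), 4, 3)
    fr <- rbind(as.numeric(t(P)), as.numeric(t(Q)))
    expect_equal(kabsch_rmsd(fr, reference = 1)[2], quat_rmsd(Q, P),
                 tolerance = 1e-6)
  }
})

test_that("RMSF recovers synthetic per-residue jitter", {
  h <- make_structure("ideal_helix", n_residues = 30)
  n_res <- 30
  sig <- rep(0, n_res)
  sig[10] <- 1
  traj <- make_trajectory(h, sig, n_frames = 2000, seed = 77)
  r <- rmsf(traj)
  expect_equal(unname(r["A:10"]), sqrt(3), tolerance = 0.05)
  expect_true(all(r[-10] < 1e-9))

  # doubling the jitter doubles the RMSF (same seed, linear generator)
  traj2 <- make_trajectory(h, 2 * sig, n_frames = 2000, seed = 77)
  expect_equal(unname(rmsf(traj2)["A:10"]), 2 * unname(r["A:10"]),
               tolerance = 1e-9)

  # identical frames give zero everywhere
  still <- make_trajectory(h, 0, n_frames = 5, seed = 1)
  expect_true(all(rmsf(still) == 0))
  expect_error(rmsf(still, equilibration_frames = 4), "2 frames")
})

test_that("RMSF profile correlates with the generating amplitudes", {
  h <- make_structure("ideal_helix", n_residues = 25)
  sig <- seq(0.2, 1.2, length.out = 25)
  traj <- make_trajectory(h, sig, n_frames = 2000, seed = 13)
  r <- rmsf(traj, equilibration_frames = 1)
  expect_gt(cor(as.numeric(r), sig * sqrt(3)), 0.99)
})

test_that("structure metrics survive a PDB round trip", {
  h <- make_structure("ideal_helix", n_residues = 10)
  traj <- make_trajectory(h, 0.3, n_frames = 4, seed = 3)
  f <- tempfile(fileext = ".pdb")
  write_structure(traj, f)
  back <- read_structure(f)
  expect_identical(n_frames(back), 4L)
  expect_equal(back$frames, unname(traj$frames), tolerance = 1e-3)
  expect_identical(back$atoms$resno, traj$atoms$resno)
  hb1 <- detect_hbonds(h)
  hb2 <- detect_hbonds(structure_model(back$atoms))
  expect_identical(hb1[, 1:6], hb2[, 1:6])
  unlink(f)
})

test_that("FRET-model agreement reporting matches brute-force distances", {
  D <- matrix(c(0, 30, 50,
                30, 0, 40,
                50, 40, 0), 3, byrow = TRUE)
  st <- make_structure("two_domain_dumbbell", site_distances = D)
  # map subunits onto the three anchor clusters
  map <- site_map(copies = list(c(cTnI = "A", cTnT = "B", cTnC = "C")),
                  offsets = c(cTnI = 4 - 131, cTnT = 4 - 240,
                              cTnC = 4 - 12))
  tab <- data.frame(subunit_d = c("cTnI", "cTnI", "cTnT"),
                    res_d = c(131, 131, 240),
                    subunit_a = c("cTnT", "cTnC", "cTnC"),
                    res_a = c(240, 12, 12),
                    state = "ca_saturated",
                    rbar_A = c(30, 48, 43), hw_A = 10,
                    stringsAsFactors = FALSE)
  rep <- compare_to_fret(tab, st, map, state = "ca_saturated")
  expect_equal(rep$d_model, c(30, 50, 40), tolerance = 1e-6)
  expect_equal(rep$deviation, c(0, 2, -3), tolerance = 1e-6)
  expect_identical(rep$within_tolerance, c(TRUE, TRUE, TRUE))
  # exact agreement flags at deviation zero
  expect_identical(rep$within_tolerance[1], TRUE)
  expect_equal(attr(rep, "fraction_within"), 1)
  # tight tolerance without the linker allowance
  strict <- compare_to_fret(tab, st, map, tolerance_frac = 0.01,
                            linker_allowance = 0)
  expect_identical(strict$within_tolerance, c(TRUE, FALSE, FALSE))
  # unmapped rows are reported, not fatal
  tab$res_a[2] <- 999
  rep2 <- compare_to_fret(tab, st, map)
  expect_true(is.na(rep2$d_model[2]))
})
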