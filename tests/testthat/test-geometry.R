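test_that("point distances are Euclidean and symmetric", {
  expect_equal(point_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  set.seed(1)
  a <- rnorm(3); b <- rnorm(3)
  expect_equal(point_distance(a, b), point_distance(b, a))
  expect_error(point_distance(c(NA, 0, 0), b))
})

test_that("dihedral angles follow the IUPAC convention", {
  # planar cis and trans arrangements
  expect_equal(dihedral_angle(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0), c(2, 1, 0)), 0)
  expect_equal(abs(dihedral_angle(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0), c(2, -1, 0))), 180)
  # right-angle case: sign fixed by the convention (positive here, matching
  # the independent bio3d::torsion.xyz check below)
  expect_equal(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)), 90)
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("dihedral agrees with bio3d and transforms correctly", {
  set.seed(7)
  for (k in 1:25) {
    p <- matrix(rnorm(12, sd = 2), 4, 3)
    ours <- tryCatch(dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ]),
                     error = function(e) NULL)
    if (is.null(ours)) next
    ref <- bio3d::torsion.xyz(as.numeric(t(p)))
    expect_equal(ours, as.numeric(ref), tolerance = 1e-6)
    # rigid invariance and mirror antisymmetry
    rt <- random_rigid()
    q <- apply_rigid(p, rt)
    expect_equal(dihedral_angle(q[1, ], q[2, ], q[3, ], q[4, ]), ours,
                 tolerance = 1e-9)
    m <- p %*% diag(c(1, 1, -1))
    expect_equal(dihedral_angle(m[1, ], m[2, ], m[3, ], m[4, ]),
                 ifelse(abs(ours) == 180, ours, -ours), tolerance = 1e-9)
  }
})

test_that("Kabsch superposition recovers exact transforms", {
  set.seed(11)
  ref <- matrix(rnorm(30, sd = 3), 10, 3)
  # identity case
  s0 <- kabsch_superpose(ref, ref)
  expect_equal(s0$rmsd, 0, tolerance = 1e-9)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-9)
  # known rotation (37 deg about z) and translation
  th <- 37 * pi / 180
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
  mob <- sweep(ref %*% t(rot), 2, c(1, 2, 3), `+`)
  s1 <- kabsch_superpose(mob, ref)
  expect_equal(s1$rmsd, 0, tolerance = 1e-9)
  recovered <- sweep(mob %*% s1$rotation, 2, s1$translation, `+`)
  expect_equal(recovered, ref, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(det(s1$rotation), 1, tolerance = 1e-9)
  expect_error(kabsch_superpose(ref[1:2, ], ref[1:2, ]))
})

test_that("Kabsch RMSD equals the quaternion-eigenvalue oracle", {
  set.seed(23)
  for (k in 1:20) {
    ref <- matrix(rnorm(45, sd = 4), 15, 3)
    mob <- ref + matrix(rnorm(45, sd = 0.2), 15, 3)
    rt <- random_rigid()
    mob <- apply_rigid(mob, rt)
    ours <- kabsch_superpose(mob, ref)$rmsd
    expect_equal(ours, qcp_rmsd(mob, ref), tolerance = 1e-9)
    # symmetry and rigid invariance of the minimised RMSD
    expect_equal(kabsch_superpose(ref, mob)$rmsd, ours, tolerance = 1e-9)
    rt2 <- random_rigid()
    expect_equal(kabsch_superpose(apply_rigid(mob, rt2), apply_rigid(ref, rt2))$rmsd,
                 ours, tolerance = 1e-9)
  }
})

test_that("fit-then-measure RMSD honours its contract", {
  set.seed(3)
  fit_ref <- matrix(rnorm(30, sd = 3), 10, 3)
  meas_ref <- matrix(rnorm(12, sd = 3), 4, 3)
  expect_equal(rmsd_after_superposition(meas_ref, meas_ref, fit_ref, fit_ref), 0,
               tolerance = 1e-9)
  # displace the measured set rigidly by 2 A after a perfect fit
  meas_mob <- sweep(meas_ref, 2, c(2, 0, 0), `+`)
  expect_equal(rmsd_after_superposition(meas_mob, meas_ref, fit_ref, fit_ref), 2,
               tolerance = 1e-9)
  # equals an independent two-step recomputation under a random transform
  rt <- random_rigid()
  got <- rmsd_after_superposition(apply_rigid(meas_mob, rt), meas_ref,
                                  apply_rigid(fit_ref, rt), fit_ref)
  sup <- kabsch_superpose(apply_rigid(fit_ref, rt), fit_ref)
  moved <- sweep(apply_rigid(meas_mob, rt) %*% sup$rotation, 2,
                 sup$translation, `+`)
  expect_equal(got, sqrt(mean(rowSums((moved - meas_ref)^2))), tolerance = 1e-9)
  expect_error(rmsd_after_superposition(meas_ref[1:2, ], meas_ref, fit_ref, fit_ref))
})

test_that("helix axis fitting recovers construction parameters", {
  # exact parametric helix with known axis
  t <- seq(0, 11) * (99.5 * pi / 180)
  pts <- cbind(2.3 * cos(t), 2.3 * sin(t), seq(0, 11) * 1.52)
  fr <- fit_helix_axis(pts)
  expect_equal(abs(sum(fr$axis_dir * c(0, 0, 1))), 1, tolerance = 1e-6)
  expect_equal(fr$rise_per_residue, 1.52, tolerance = 1e-6)
  expect_equal(fr$twist_per_residue, 99.5, tolerance = 1e-6)
  # total twist accumulates over an exactly helical input
  expect_equal(fr$twist_per_residue * 11, 99.5 * 11, tolerance = 1e-5)

  # generator alpha helix: canonical (-57,-47) torsions
  mon <- helix_fixture(12)
  fra <- fit_helix_axis(monomer_coords(mon, paste0("A", 1:12), "CA"))
  expect_gt(fra$rise_per_residue, 1.4); expect_lt(fra$rise_per_residue, 1.65)
  expect_gt(fra$twist_per_residue, 97); expect_lt(fra$twist_per_residue, 101)

  # generator pi helix: wider, slower-rising
  mpi <- helix_fixture(12, -57, -70)
  frp <- fit_helix_axis(monomer_coords(mpi, paste0("A", 1:12), "CA"))
  expect_gt(frp$rise_per_residue, 0.95); expect_lt(frp$rise_per_residue, 1.25)
  expect_gt(frp$twist_per_residue, 83); expect_lt(frp$twist_per_residue, 88)
  expect_lt(frp$rise_per_residue, fra$rise_per_residue)

  expect_error(fit_helix_axis(pts[1:4, ]))
})

test_that("azimuth differences report rigid rotations about the helix axis", {
  mon <- helix_fixture(12, seq_a = "GIVEQCCTSICS")
  # against itself: all zero
  expect_equal(unname(azimuth_profile(mon, reference_monomer = mon)),
               rep(0, 5), tolerance = 1e-6)

  # rotate the A chain rigidly by 32 degrees about its own helix axis:
  # every A1-A5 azimuth difference should be ~32 deg of consistent sign
  fr <- fit_helix_axis(monomer_coords(mon, paste0("A", 1:8), "CA"))
  th <- 32 * pi / 180
  k <- fr$axis_dir
  kk <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
               byrow = TRUE)
  rot <- diag(3) + sin(th) * kk + (1 - cos(th)) * (kk %*% kk)
  rotated <- mon
  sel <- rotated$atoms$chain == "A"
  xyz <- as.matrix(rotated$atoms[sel, c("x", "y", "z")])
  xyz <- sweep(xyz, 2, fr$axis_point)
  xyz <- sweep(xyz %*% t(rot), 2, fr$axis_point, `+`)
  rotated$atoms[sel, c("x", "y", "z")] <- xyz
  dz <- azimuth_profile(rotated, reference_monomer = mon)
  expect_equal(length(dz), 5)
  expect_true(all(abs(abs(dz) - 32) < 2))
  expect_true(all(sign(dz) == sign(dz[1])))

  # the two conformational classes differ by a consistent A1-A5 rotation
  dcl <- azimuth_profile(build_class_toy("CLASS1"),
                         reference_monomer = build_class_toy("CLASS2"))
  expect_true(all(abs(dcl) > 5))
  expect_true(all(sign(dcl) == sign(dcl[1])))
})
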