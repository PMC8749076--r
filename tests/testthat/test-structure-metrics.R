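# Superposition, RMSD traces, SASA, exposure, crossing angles, contact area
# and hydrogen bonds.

test_that("superposing identical sets gives zero RMSD and the identity", {
  A <- generate_chain_ca(crick_params(r1 = 4.9, P = -140), n = 10)
  fit <- kabsch_superpose(A, A)
  expect_lt(fit$rmsd, 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)
  expect_equal(crossprod(fit$rotation), diag(3), tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
})

test_that("a known rotation is recovered exactly", {
  A <- generate_chain_ca(crick_params(r1 = 4.9, P = -140), n = 12)
  tr <- random_rigid_transform(5)
  B <- apply_rigid(A, tr)
  fit <- kabsch_superpose(A, B)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(fit$rotation, tr$R, tolerance = 1e-6)
})

test_that("noisy superposition matches a quaternion-optimizer oracle", {
  set.seed(17)
  A <- matrix(rnorm(300, sd = 6), ncol = 3)
  tr <- random_rigid_transform(6)
  B <- apply_rigid(A, tr) + matrix(rnorm(300, sd = 0.5), ncol = 3)
  fit <- kabsch_superpose(A, B)
  oracle <- quaternion_rmsd_oracle(A, B)
  expect_equal(fit$rmsd, oracle, tolerance = 1e-6)
})

test_that("no random rigid transform beats the least-squares fit", {
  set.seed(23)
  A <- matrix(rnorm(90, sd = 5), ncol = 3)
  B <- A + matrix(rnorm(90, sd = 1), ncol = 3)
  best <- kabsch_superpose(A, B)$rmsd
  for (s in 1:100) {
    tr <- random_rigid_transform(s)
    expect_gte(sqrt(mean(rowSums((apply_rigid(A, tr) - B)^2))), best - 1e-12)
  }
})

test_that("degenerate (collinear) selections are rejected", {
  A <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(A, A + 1), "degenerate")
})

test_that("rmsd traces are zero for identical or rigidly moved frames", {
  m <- build_bundle(list(chain_spec("A", strrep("A", 10), 1,
                                    crick_params(r1 = 4.9, P = -140))))
  ref <- bundle_coords(m)
  frames <- list(ref, apply_rigid(ref, random_rigid_transform(2)),
                 apply_rigid(ref, random_rigid_transform(3)))
  expect_true(all(rmsd_trace(frames, ref) < 1e-9))
})

test_that("a single displaced atom shows up as d/sqrt(n) before fitting adjustments", {
  # two frames, n atoms; frame 2 displaces one atom by d. After optimal
  # superposition the RMSD is bounded above by the rigid no-op transform
  # value d/sqrt(n), and for a large symmetric cloud approaches it.
  set.seed(31)
  n <- 400
  ref <- matrix(rnorm(3 * n, sd = 20), ncol = 3)
  d <- 2
  f2 <- ref
  f2[1, ] <- f2[1, ] + c(d, 0, 0)
  r <- rmsd_trace(list(ref, f2), ref)
  expect_equal(r[1], 0, tolerance = 1e-12)
  expect_lte(r[2], d / sqrt(n) + 1e-9)
  expect_equal(r[2], d / sqrt(n), tolerance = 0.01)
})

test_that("an isolated atom's SASA matches the sphere formula", {
  m1 <- data.frame(chain = "A", resno = 1L, resname = "ALA", elety = "CA",
                   elem = "C", x = 0, y = 0, z = 0)
  s <- sasa(m1, probe_radius = 1.4, n_points = 960)
  expect_equal(s$total, 4 * pi * (1.70 + 1.4)^2, tolerance = 0.01 * s$total)
})

test_that("two overlapping spheres match the analytic cap formula within 2%", {
  for (d in c(1.5, 2.5, 4.0)) {
    m2 <- data.frame(chain = "A", resno = 1:2, resname = "ALA",
                     elety = "CA", elem = "C", x = c(0, d), y = 0, z = 0)
    s <- sasa(m2, 1.4, 960)
    an <- two_sphere_area_oracle(1.70 + 1.4, d)
    expect_lt(abs(s$total - an) / an, 0.02)
  }
})

test_that("SASA is converged: doubling the point count moves no atom by > 2% of its sphere", {
  # buried atoms have near-zero accessible area, so convergence is measured
  # against each atom's full solvent-expanded sphere area
  m <- build_bundle(list(chain_spec("A", strrep("A", 8), 1,
                                    crick_params(r1 = 0))))
  s1 <- sasa(m, n_points = 960)
  s2 <- sasa(m, n_points = 1920)
  sphere <- 4 * pi * (coilbundle:::atom_radii(m$atoms$elem) + 1.4)^2
  expect_true(all(abs(s1$atom_area - s2$atom_area) / sphere <= 0.02))
  expect_lt(abs(s1$total - s2$total) / s2$total, 0.02)
})

test_that("SASA is invariant under rigid transforms up to sampling tolerance", {
  m <- build_bundle(list(chain_spec("A", strrep("A", 6), 1,
                                    crick_params(r1 = 0))))
  s0 <- sasa(m, n_points = 6000)$total
  m2 <- transform_model(m, random_rigid_transform(8))
  expect_lt(abs(sasa(m2, n_points = 6000)$total - s0) / s0, 1e-3)
})

test_that("group exposure is 1 for a free group and ~0 for an enclosed one", {
  free <- bundle_model(data.frame(
    chain = "A", resno = 1L, resname = "ALA", elety = "CA", elem = "C",
    x = 0, y = 0, z = 0))
  expect_equal(group_exposure(free, "A:1"), 1, tolerance = 0.01)

  # enclose one atom in a tight shell of neighbors
  pts <- coilbundle:::sphere_points(60) * 2.2
  shell <- data.frame(chain = "B", resno = 2L, resname = "ALA", elety = "CA",
                      elem = "C", x = pts[, 1], y = pts[, 2], z = pts[, 3])
  center <- data.frame(chain = "A", resno = 1L, resname = "ALA", elety = "CA",
                       elem = "C", x = 0, y = 0, z = 0)
  buried <- bundle_model(rbind(center, shell))
  expect_lt(group_exposure(buried, "A:1"), 0.01)
})

test_that("a half-occluded group agrees with a high-density reference run", {
  m <- bundle_model(data.frame(
    chain = c("A", "B", "B"), resno = c(1L, 1L, 2L), resname = "ALA",
    elety = "CA", elem = "C", x = c(0, 3.0, -3.0), y = 0, z = c(0, 0.8, -0.8)))
  f1 <- group_exposure(m, "A:1", n_points = 960)
  f2 <- group_exposure(m, "A:1", n_points = 4000)
  expect_lt(abs(f1 - f2), 0.03)
})

test_that("crossing angles: parallel is 0, a constructed right-handed 35-degree crossing is -35", {
  p <- crick_params(r1 = 0, r0 = 2.26, h = 1.51)
  A <- generate_chain_ca(p, n = 15)
  B <- sweep(A, 2, c(8, 0, 0), "+")
  expect_lt(abs(crossing_angle(A, B)), 0.5)

  # rotate helix B about the mutual perpendicular (the x axis here); a
  # negative rotation of the far helix produces a right-handed crossing,
  # which this convention reports as a negative angle
  th <- -35 * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  ctr <- colMeans(B)
  B2 <- sweep(sweep(B, 2, ctr) %*% t(Rx), 2, ctr, "+")
  expect_lt(abs(crossing_angle(A, B2) - (-35)), 1)
  expect_equal(crossing_angle(B2, A), crossing_angle(A, B2), tolerance = 1e-9)

  # cross-check the handedness convention on supercoil geometry: the two
  # chains of a right-handed (P > 0) supercoiled dimer cross negatively
  sp <- lapply(c(0, 180), function(ph)
    chain_spec("A", strrep("A", 28), 1,
               crick_params(r1 = 4.9, P = 140, phi1 = 15, phi_major0 = ph)))
  expect_lt(crossing_angle(generate_chain_ca(sp[[1]]),
                           generate_chain_ca(sp[[2]])), -10)
})

test_that("contact area vanishes for distant groups and is symmetric", {
  mk_chain <- function(chain, dx) {
    ca <- generate_chain_ca(crick_params(r1 = 0), n = 8)
    bb <- build_backbone(sweep(ca, 2, c(dx, 0, 0), "+"), strrep("A", 8), chain)
    bb
  }
  far <- bundle_model(rbind(mk_chain("A", 0), mk_chain("B", 30)))
  ca_far <- contact_area(far, chain_mask(far, "A"), chain_mask(far, "B"))
  expect_lt(abs(ca_far), 1)

  near <- bundle_model(rbind(mk_chain("A", 0), mk_chain("B", 9)))
  ab <- contact_area(near, chain_mask(near, "A"), chain_mask(near, "B"))
  ba <- contact_area(near, chain_mask(near, "B"), chain_mask(near, "A"))
  expect_gt(ab, 10)
  expect_equal(ab, ba, tolerance = 1e-9)
  expect_error(contact_area(near, chain_mask(near, "A"), chain_mask(near, c("A", "B"))),
               "overlap")
})

test_that("two packed helices' contact area agrees with high-density sampling", {
  mk_chain <- function(chain, dx) {
    ca <- generate_chain_ca(crick_params(r1 = 0), n = 10)
    build_backbone(sweep(ca, 2, c(dx, 0, 0), "+"), strrep("A", 10), chain)
  }
  m <- bundle_model(rbind(mk_chain("A", 0), mk_chain("B", 8)))
  a1 <- contact_area(m, chain_mask(m, "A"), chain_mask(m, "B"), n_points = 960)
  a2 <- contact_area(m, chain_mask(m, "A"), chain_mask(m, "B"), n_points = 4000)
  expect_lt(abs(a1 - a2) / a2, 0.03)
  expect_gte(a1, 0)
})

test_that("hydrogen bonds: geometric hits detected, distant pairs ignored, helix i->i+4 found", {
  mk2 <- function(d) bundle_model(data.frame(
    chain = c("A", "A", "B", "B", "B"),
    resno = c(1L, 1L, 5L, 5L, 5L),
    resname = "ALA", elety = c("N", "CA", "CA", "C", "O"),
    elem = c("N", "C", "C", "C", "O"),
    x = c(0, 1.4, d + 2.4, d + 1.23, d), y = 0, z = 0))
  expect_equal(nrow(hydrogen_bonds(mk2(2.9))), 1)
  expect_equal(nrow(hydrogen_bonds(mk2(5.0))), 0)

  helix <- build_bundle(list(chain_spec("A", strrep("A", 20), 1,
                                        crick_params(r1 = 0, omega1 = 100))))
  hb <- hydrogen_bonds(helix)
  i4 <- hb[hb$donor_resno == hb$acceptor_resno + 4, ]
  expect_equal(sort(i4$acceptor_resno), 1:16)
})

test_that("crossing angle and contact metrics are rigid-transform invariant", {
  sp <- lapply(c(0, 180), function(ph)
    chain_spec(if (ph == 0) "A" else "B", strrep("A", 20), 1,
               crick_params(r1 = 4.5, P = -140, phi1 = 10, phi_major0 = ph)))
  caA <- generate_chain_ca(sp[[1]]); caB <- generate_chain_ca(sp[[2]])
  x0 <- crossing_angle(caA, caB)
  tr <- random_rigid_transform(12)
  x1 <- crossing_angle(apply_rigid(caA, tr), apply_rigid(caB, tr))
  expect_equal(x1, x0, tolerance = 1e-6)
})
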