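# Crick backbone generation, symmetry, grafting and PDB round trips.

test_that("r1 = 0 degenerates to an ideal straight alpha-helix", {
  p <- crick_params(r1 = 0, r0 = 2.26, h = 1.51, omega1 = 102.857)
  ca <- generate_chain_ca(p, n = 10)
  radii <- sqrt(ca[, 1]^2 + ca[, 2]^2)
  expect_true(all(abs(radii - 2.26) < 1e-9))
  expect_true(all(abs(diff(ca[, 3]) - 1.51) < 1e-9))
  # twist about z is exactly omega1 per residue
  ang <- diff(atan2(ca[, 2], ca[, 1])) * 180 / pi
  expect_true(all(abs(((ang + 360) %% 360) - 102.857) < 1e-9))
})

test_that("consecutive Calpha spacing is physical across the parameter grid", {
  # canonical left-handed supercoils at the heptad-matched twist 102.857
  for (r1 in c(3, 5, 7, 9)) for (P in c(-250, -150, -80)) {
    ca <- generate_chain_ca(crick_params(r1 = r1, P = P), n = 30)
    d <- sqrt(rowSums((ca[-1, ] - ca[-30, ])^2))
    expect_true(all(abs(d - 3.8) <= 0.15),
                info = sprintf("r1=%g P=%g range %.3f-%.3f", r1, P, min(d), max(d)))
  }
  # right-handed supercoils pair with a smaller relative twist (11/3 repeat)
  for (P in c(150, 250)) {
    ca <- generate_chain_ca(crick_params(r1 = 6.5, P = P, omega1 = 98.18), n = 30)
    d <- sqrt(rowSums((ca[-1, ] - ca[-30, ])^2))
    expect_true(all(abs(d - 3.8) <= 0.15),
                info = sprintf("P=%g range %.3f-%.3f", P, min(d), max(d)))
  }
})

test_that("generated traces agree with an independently coded parametric curve", {
  # independent oracle: the supercoiled-helix curve written out directly from
  # its defining geometry (superhelical circle + minor circle in the local
  # tangent frame), coded separately from the package's generator
  oracle_point <- function(i, r1, P, r0, h, omega1, phi1) {
    alpha <- atan(2 * pi * r1 / P)
    dz <- h * cos(alpha)
    w0 <- 2 * pi * dz / P
    th <- w0 * i
    axis <- c(r1 * cos(th), r1 * sin(th), dz * i)
    tv <- c(-r1 * w0 * sin(th), r1 * w0 * cos(th), dz)
    tv <- tv / sqrt(sum(tv^2))
    nv <- c(-cos(th), -sin(th), 0)
    bv <- c(tv[2] * nv[3] - tv[3] * nv[2], tv[3] * nv[1] - tv[1] * nv[3],
            tv[1] * nv[2] - tv[2] * nv[1])
    ps <- (phi1 + omega1 * i) * pi / 180
    axis + r0 * (cos(ps) * nv + sin(ps) * bv)
  }
  for (case in list(c(6.5, 150), c(4.9, -140), c(9, -250))) {
    ca <- generate_chain_ca(crick_params(r1 = case[1], P = case[2], phi1 = 20),
                            n = 15)
    ora <- t(sapply(0:14, oracle_point, r1 = case[1], P = case[2], r0 = 2.26,
                    h = 1.51, omega1 = 102.857, phi1 = 20))
    expect_lt(max(abs(unname(ca) - ora)), 1e-9)
  }
})

test_that("the z-shift is a pure translation along z", {
  p0 <- crick_params(r1 = 4.9, P = -140, phi1 = 33)
  p5 <- crick_params(r1 = 4.9, P = -140, phi1 = 33, s = 5)
  ca0 <- generate_chain_ca(p0, n = 12)
  ca5 <- generate_chain_ca(p5, n = 12)
  expect_equal(unname(sweep(ca5, 2, c(0, 0, 5))), unname(ca0), tolerance = 1e-12)
})

test_that("invalid Crick parameters are rejected", {
  expect_error(crick_params(r1 = 5, P = 0), "nonzero superhelical pitch")
  expect_error(crick_params(r1 = -1, P = 100), "r1")
  expect_error(crick_params(r1 = 0, r0 = 0), "r0")
  expect_silent(crick_params(r1 = 0))   # P irrelevant in the straight limit
})

test_that("backbone reconstruction gives helical dihedrals and ideal bonds", {
  ca <- generate_chain_ca(crick_params(r1 = 0), n = 12)
  bb <- build_backbone(ca, strrep("A", 12))
  g <- function(rn, el) {
    r <- bb[bb$resno == rn & bb$elety == el, ]
    c(r$x, r$y, r$z)
  }
  tors <- coilbundle:::torsion_angle
  for (i in 4:9) {
    phi <- tors(g(i - 1, "C"), g(i, "N"), g(i, "CA"), g(i, "C"))
    psi <- tors(g(i, "N"), g(i, "CA"), g(i, "C"), g(i + 1, "N"))
    expect_lt(abs(phi - (-62)), 15)
    expect_lt(abs(psi - (-43)), 15)
  }
  expect_equal(sqrt(sum((g(5, "N") - g(5, "CA"))^2)), 1.46, tolerance = 1e-6)
  expect_equal(sqrt(sum((g(5, "CA") - g(5, "C"))^2)), 1.52, tolerance = 1e-6)
})

test_that("glycine gets no CB and other residues do", {
  ca <- generate_chain_ca(crick_params(r1 = 0), n = 8)
  bb <- build_backbone(ca, "AAAGAAAA")
  counts <- table(bb$resno)
  expect_equal(unname(counts[as.character(4)]), 4L)
  expect_true(all(counts[as.character(c(1:3, 5:8))] == 5L))
})

test_that("backbone building is translation-equivariant", {
  ca <- generate_chain_ca(crick_params(r1 = 4.9, P = -140), n = 10)
  bb1 <- build_backbone(ca, strrep("L", 10))
  t <- c(3, -2, 7)
  bb2 <- build_backbone(sweep(ca, 2, t, "+"), strrep("L", 10))
  expect_equal(as.matrix(bb2[, c("x", "y", "z")]),
               sweep(as.matrix(bb1[, c("x", "y", "z")]), 2, t, "+"),
               tolerance = 1e-9)
})

test_that("traces with clashing Calphas are rejected", {
  ca <- generate_chain_ca(crick_params(r1 = 0), n = 6)
  ca[3, ] <- ca[2, ] + c(0.5, 0, 0)
  expect_error(build_backbone(ca, strrep("A", 6)), "2.5 A")
})

test_that("C2 symmetrization is an involution that preserves rigidity", {
  m <- build_bundle(list(
    chain_spec("A", strrep("A", 10), 1,
               crick_params(r1 = 8, P = -200, phi_major0 = 0)),
    chain_spec("B", strrep("L", 10), 1,
               crick_params(r1 = 8, P = -200, phi_major0 = 90))))
  full <- apply_c2(m)
  expect_setequal(unique(full$atoms$chain), c("A", "B", "C", "D"))
  # applying C2 to the mate reproduces the original coordinates
  mate <- full$atoms[full$atoms$chain %in% c("C", "D"), ]
  mate$chain <- ifelse(mate$chain == "C", "A", "B")
  back <- apply_c2(bundle_model(mate))
  orig <- as.matrix(m$atoms[, c("x", "y", "z")])
  img <- as.matrix(back$atoms[back$atoms$chain %in% c("C", "D"), c("x", "y", "z")])
  expect_lt(max(abs(img - orig)), 1e-9)
  # rigidity: intra-chain distance sets identical between chain and image
  dA <- dist(m$atoms[m$atoms$chain == "A", c("x", "y", "z")])
  dC <- dist(full$atoms[full$atoms$chain == "C", c("x", "y", "z")])
  expect_equal(as.numeric(dA), as.numeric(dC), tolerance = 1e-9)
  # a point on the axis maps to itself
  pt <- bundle_model(data.frame(chain = "A", resno = 1, resname = "ALA",
                                elety = "CA", elem = "C", x = 0, y = 0, z = 3))
  expect_warning(img2 <- apply_c2(pt), "clash")
  expect_equal(unname(as.matrix(img2$atoms[2, c("x", "y", "z")])),
               matrix(c(0, 0, 3), 1), tolerance = 1e-12)
})

test_that("C2 clash reporting counts close inter-mate pairs without failing", {
  m <- build_bundle(list(chain_spec("A", strrep("A", 8), 1,
                                    crick_params(r1 = 0.4, P = -140))))
  expect_warning(out <- apply_c2(m), "clash")
  expect_gt(attr(out, "clashes"), 0)
})

test_that("PDB write/read round-trips coordinates, chains and numbering", {
  m <- build_bundle(list(
    chain_spec("A", strrep("A", 8), 21, crick_params(r1 = 4.9, P = -140)),
    chain_spec("B", strrep("K", 8), 52,
               crick_params(r1 = 4.9, P = -140, phi_major0 = 180))))
  tf <- tempfile(fileext = ".pdb")
  write_pdb(m, tf)
  m2 <- read_pdb(tf)
  expect_lte(max(abs(bundle_coords(m2) - bundle_coords(m))), 1e-3)
  expect_identical(m2$atoms$chain, m$atoms$chain)
  expect_identical(m2$atoms$resno, m$atoms$resno)
  expect_identical(m2$atoms$elety, m$atoms$elety)
})

test_that("multi-model PDB files round-trip as frames", {
  m <- build_bundle(list(chain_spec("A", strrep("A", 6), 1,
                                    crick_params(r1 = 0))))
  frames <- lapply(0:2, function(k) bundle_coords(m) + k)
  m$frames <- frames
  tf <- tempfile(fileext = ".pdb")
  write_pdb(m, tf)
  m2 <- read_pdb(tf)
  expect_length(bundle_frames(m2), 3)
  for (k in 1:3)
    expect_lte(max(abs(bundle_frames(m2)[[k]] - frames[[k]])), 1e-3)
})

test_that("malformed PDB records raise parse errors with line numbers", {
  tf <- tempfile(fileext = ".pdb")
  good <- sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
                  1L, 1L, 1.0, 2.0, 3.0)
  bad <- sub("   1.000", "   abcde", good)
  writeLines(c(good, bad), tf)
  expect_error(read_pdb(tf), "line 2")
})

test_that("self-grafting a fragment is exact and grafting reports flank RMSD", {
  m <- build_bundle(list(chain_spec("A", strrep("A", 20), 1,
                                    crick_params(r1 = 4.9, P = -140))))
  frag <- m$atoms[m$atoms$resno %in% 5:16, ]
  g <- graft_fragment(m, frag, list(chain = "A", start = 9, end = 12), n_flank = 4)
  expect_lt(attr(g, "flank_rmsd"), 1e-9)
  expect_lt(max(abs(bundle_coords(g) - bundle_coords(m))), 1e-9)

  # reported flank RMSD equals the independent superposition value
  tr <- random_rigid_transform(11)
  frag2 <- frag
  xyz <- apply_rigid(as.matrix(frag2[, c("x", "y", "z")]), tr)
  set.seed(42)
  xyz <- xyz + matrix(rnorm(length(xyz), sd = 0.2), ncol = 3)
  frag2$x <- xyz[, 1]; frag2$y <- xyz[, 2]; frag2$z <- xyz[, 3]
  g2 <- graft_fragment(m, frag2, list(chain = "A", start = 9, end = 12), n_flank = 4)
  anchors <- m$atoms[m$atoms$elety == "CA" & m$atoms$resno %in% c(5:8, 13:16), ]
  flanks <- frag2[frag2$elety == "CA" & frag2$resno %in% c(5:8, 13:16), ]
  oracle <- kabsch_superpose(as.matrix(flanks[, c("x", "y", "z")]),
                             as.matrix(anchors[, c("x", "y", "z")]))$rmsd
  expect_equal(attr(g2, "flank_rmsd"), oracle, tolerance = 1e-6)
})

test_that("grafting into a gap adds exactly the fragment core residues", {
  m <- build_bundle(list(chain_spec("A", strrep("A", 20), 1,
                                    crick_params(r1 = 4.9, P = -140))))
  # fragment: model flanks 7-10 and 11-14 around the insertion point, with a
  # 4-residue core (displaced copies) in between, renumbered consecutively
  renum <- function(df, new) { df$resno <- new[match(df$resno, sort(unique(df$resno)))]; df }
  pre <- renum(m$atoms[m$atoms$resno %in% 7:10, ], 1:4)
  core <- renum(m$atoms[m$atoms$resno %in% 15:18, ], 5:8)
  core$y <- core$y + 6   # arbitrary loop conformation
  post <- renum(m$atoms[m$atoms$resno %in% 11:14, ], 9:12)
  frag <- rbind(pre, core, post)
  n_before <- length(unique(m$atoms$resno))
  g <- graft_fragment(m, frag, list(chain = "A", start = 11, end = 10), n_flank = 4)
  expect_lt(attr(g, "flank_rmsd"), 1e-9)
  expect_equal(length(unique(g$atoms$resno[g$atoms$chain == "A"])), n_before + 4)
})

test_that("incompatible anchors reject the graft", {
  m <- build_bundle(list(chain_spec("A", strrep("A", 20), 1,
                                    crick_params(r1 = 4.9, P = -140))))
  frag <- m$atoms[m$atoms$resno %in% 5:16, ]
  set.seed(9)
  frag$x <- frag$x + rnorm(nrow(frag), sd = 2.5)
  expect_error(graft_fragment(m, frag, list(chain = "A", start = 9, end = 12)),
               "graft rejected")
})
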