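test_that("sphere points are unit vectors with a near-zero centroid", {
  expect_error(sphere_points(0), "positive")
  expect_equal(nrow(sphere_points(1)), 1L)
  expect_equal(sqrt(sum(sphere_points(1)^2)), 1, tolerance = 1e-12)
  p <- sphere_points(960)
  expect_equal(unname(sqrt(rowSums(p^2))), rep(1, 960), tolerance = 1e-12)
  expect_lt(sqrt(sum(colMeans(p)^2)), 1e-2)
})

test_that("an isolated atom recovers the analytic sphere area", {
  a <- single_atom_df(0, 0, 0)  # carbon, vdW 1.7
  s <- compute_sasa(a, probe_radius = 1.4, n_points = 960)
  expect_equal(s$atom_sasa, 4 * pi * 3.1^2, tolerance = 0.01)
  # two atoms beyond occlusion range are both fully exposed
  b <- rbind(a, single_atom_df(10, 0, 0, resno = 2))
  s2 <- compute_sasa(b)
  expect_equal(s2$atom_sasa, rep(4 * pi * 3.1^2, 2), tolerance = 0.01)
})

test_that("two overlapping spheres match the analytic cap area", {
  R <- 1.7 + 1.4
  for (d in c(2.0, 3.5, 5.0)) {
    atoms <- rbind(single_atom_df(0, 0, 0),
                   single_atom_df(d, 0, 0, resno = 2))
    s <- compute_sasa(atoms, n_points = 960)
    expect_equal(s$atom_sasa[1], two_sphere_accessible(R, R, d),
                 tolerance = 0.02)
  }
})

test_that("adding occluders never increases an atom's SASA", {
  set.seed(7)
  centre <- single_atom_df(0, 0, 0)
  occl <- do.call(rbind, lapply(1:6, function(i) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2)) * runif(1, 2, 4)
    single_atom_df(u[1], u[2], u[3], resno = i + 1)
  }))
  prev <- Inf
  for (k in 0:6) {
    s <- compute_sasa(rbind(centre, occl[seq_len(k), ]), n_points = 480)
    expect_lte(s$atom_sasa[1], prev + 1e-9)
    prev <- s$atom_sasa[1]
  }
})

test_that("total SASA is invariant under rigid rotation and converges in n", {
  set.seed(11)
  atoms <- do.call(rbind, lapply(1:50, function(i) {
    single_atom_df(rnorm(1, 0, 4), rnorm(1, 0, 4), rnorm(1, 0, 4),
                   resno = ceiling(i / 5))
  }))
  s1 <- compute_sasa(atoms, n_points = 960)
  # random rotation
  th <- 0.77; ph <- 1.3
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(ph), sin(ph), 0, -sin(ph), cos(ph)), 3)
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% (Rz %*% Rx)
  rot <- atoms; rot$x <- xyz[, 1]; rot$y <- xyz[, 2]; rot$z <- xyz[, 3]
  s2 <- compute_sasa(rot, n_points = 960)
  expect_equal(sum(s2$atom_sasa), sum(s1$atom_sasa), tolerance = 2e-3)
  # doubling the quadrature changes per-residue values by < 1% on a
  # 50-atom coil whose residues all have solvent-exposed surface
  i <- 1:50
  coil <- do.call(rbind, lapply(i, function(k) {
    single_atom_df(1.9 * k, 2.2 * sin(k / 1.5), 2.2 * cos(k / 1.5),
                   resno = ceiling(k / 5), atom = paste0("C", k))
  }))
  c1 <- compute_sasa(coil, n_points = 960)$residue_sasa$sasa
  c2 <- compute_sasa(coil, n_points = 1920)$residue_sasa$sasa
  expect_true(all(abs(c2 - c1) / c1 < 0.01))
})

test_that("missing radii are reported by element", {
  a <- single_atom_df(0, 0, 0)
  a$element <- "ZN"
  expect_error(compute_sasa(a), "ZN")
})

test_that("fSASA is 1 for a self-referenced residue and ~0 when caged", {
  gly <- single_atom_df(0, 0, 0, resname = "GLY")
  own <- compute_sasa(gly)$residue_sasa$sasa
  m <- toy_model(gly)
  f <- compute_fsasa(m, "A", reference = c(GLY = own))
  expect_equal(f$fsasa, 1, tolerance = 1e-12)
  # cage of single-atom residues on a 3 A sphere buries the centre
  pts <- sphere_points(200) * 3
  cage <- do.call(rbind, lapply(seq_len(nrow(pts)), function(i) {
    single_atom_df(pts[i, 1], pts[i, 2], pts[i, 3], resno = i + 1,
                   resname = "GLY")
  }))
  caged <- toy_model(rbind(single_atom_df(0, 0, 0, resname = "ALA"), cage))
  fc <- compute_fsasa(caged, "A", n_points = 480)
  expect_lt(fc$fsasa[fc$resname == "ALA"], 0.05)
})

test_that("fSASA equals native SASA over the reference, per residue", {
  set.seed(5)
  atoms <- do.call(rbind, lapply(1:3, function(i) {
    df <- do.call(rbind, lapply(1:3, function(j) {
      single_atom_df(rnorm(1, 3 * i, 1), rnorm(1), rnorm(1), resno = i,
                     resname = c("GLY", "ALA", "SER")[i],
                     atom = paste0("C", j))
    }))
    df
  }))
  m <- toy_model(atoms)
  ref <- c(GLY = 104, ALA = 129, SER = 155)
  f <- compute_fsasa(m, "A", reference = ref)
  nat <- compute_sasa(atoms)$residue_sasa$sasa
  expect_equal(f$fsasa, nat / unname(ref[f$resname]), tolerance = 1e-12)
  expect_true(all(f$fsasa >= 0 & f$fsasa <= 1.5))
  expect_error(compute_fsasa(m, "A", reference = c(GLY = 104)), "ALA")
})
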