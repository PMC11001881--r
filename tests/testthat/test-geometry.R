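all_spec <- function(chains = "A") {
  selection_spec(all = do.call(rbind, lapply(chains, sel_range)))
}

rotate_model <- function(m, axis, angle, shift = c(0, 0, 0)) {
  R <- duobasin:::rotation_about_axis(axis, angle)
  xyz <- coords(m) %*% t(R)
  m$atoms$x <- xyz[, 1] + shift[1]
  m$atoms$y <- xyz[, 2] + shift[2]
  m$atoms$z <- xyz[, 3] + shift[3]
  m
}

test_that("superposing a model on itself gives the identity transform", {
  m <- bead_chain_model(15)
  tr <- superpose(m, m, all_spec(), "all")
  expect_equal(tr$R, diag(3), tolerance = 1e-9)
  expect_lt(tr$rmsd, 1e-12)
})

test_that("a constructed rotation is recovered exactly", {
  m <- bead_chain_model(15)
  m2 <- rotate_model(m, c(0, 0, 1), 90, shift = c(3, -2, 7))
  tr <- superpose(m2, m, all_spec(), "all")
  expect_lt(tr$rmsd, 1e-9)
  expect_equal(duobasin:::rotation_angle_deg(tr$R), 90, tolerance = 1e-6)
  moved <- apply_transform(m2, tr)
  expect_lt(max(abs(coords(moved) - coords(m))), 1e-9)
})

test_that("mirrored coordinates still yield a proper rotation", {
  m <- bead_chain_model(15)
  m2 <- m
  m2$atoms$x <- -m2$atoms$x
  tr <- superpose(m2, m, all_spec(), "all")
  expect_equal(det(tr$R), 1, tolerance = 1e-9)
  expect_gt(tr$rmsd, 0.1)
})

test_that("collinear selections are rejected", {
  at <- data.frame(serial = 1:4, name = "CA", elem = "C", resname = "GLY",
                   resno = 1:4, ins = "", chain = "A",
                   x = 1:4 * 3.8, y = 0, z = 0)
  m <- mol_model(at)
  expect_error(superpose(m, m, all_spec(), "all"), "collinear")
})

test_that("swivel angle recovers a constructed domain rotation", {
  core <- bead_chain_model(20, seed = 2)
  swiv <- bead_chain_model(15, seed = 3)
  swiv$atoms$resno <- swiv$atoms$resno + 100
  swiv$atoms$serial <- swiv$atoms$serial + 100
  swiv$atoms$x <- swiv$atoms$x + 25
  mA <- mol_model(rbind(core$atoms, swiv$atoms))
  spec <- selection_spec(core = sel_range("A", 1, 20),
                         swivel = sel_range("A", 101, 115))
  axis <- c(0.36, 0.48, 0.8)
  R <- duobasin:::rotation_about_axis(axis, 10)
  ## rotate only the swivel domain about its own centroid
  mB <- mA
  idx <- which(atoms_in_group(mA, spec, "swivel"))
  xyz <- coords(mA)
  cen <- colMeans(xyz[idx, ])
  xyz[idx, ] <- sweep(sweep(xyz[idx, ], 2, cen) %*% t(R), 2, cen, "+")
  mB$atoms$x <- xyz[, 1]; mB$atoms$y <- xyz[, 2]; mB$atoms$z <- xyz[, 3]
  res <- swivel_angle(mA, mB, spec, "core", "swivel")
  expect_equal(res$angle, 10, tolerance = 1e-4)
  expect_gt(abs(sum(res$axis * axis / sqrt(sum(axis^2)))), 1 - 1e-6)
  expect_lt(res$core_rmsd, 1e-9)
  ## identity and symmetry
  expect_lt(swivel_angle(mA, mA, spec, "core", "swivel")$angle, 1e-6)
  ba <- swivel_angle(mB, mA, spec, "core", "swivel")
  expect_equal(res$angle, ba$angle, tolerance = 1e-6)
  ## invariant under a global rigid motion of either input
  mB2 <- rotate_model(mB, c(1, 2, 0), 33, shift = c(5, 5, -4))
  expect_equal(swivel_angle(mA, mB2, spec, "core", "swivel")$angle,
               res$angle, tolerance = 1e-6)
})

test_that("helix-axis fits recover the generator's ground truth", {
  d <- make_ideal_duplex(10)
  fit <- fit_helix_axis(d, attr(d, "pairing"))
  truth <- attr(d, "ground_truth")
  expect_gt(sum(fit$axis * truth$axis), cos(1 * pi / 180))   # within 1 degree
  expect_equal(fit$radius, truth$p_radius, tolerance = 0.1)
  ## translation invariance
  d2 <- d
  d2$atoms$x <- d2$atoms$x + 40; d2$atoms$z <- d2$atoms$z - 12
  fit2 <- fit_helix_axis(d2, attr(d, "pairing"))
  expect_equal(fit2$axis, fit$axis, tolerance = 1e-9)
  expect_equal(fit2$radius, fit$radius, tolerance = 1e-9)
  ## a tilted duplex reports its tilted axis
  ax <- c(1, 1, 1) / sqrt(3)
  d3 <- make_ideal_duplex(12, axis = ax)
  fit3 <- fit_helix_axis(d3, attr(d3, "pairing"))
  expect_gt(sum(fit3$axis * ax), cos(1 * pi / 180))
  expect_error(fit_helix_axis(d, attr(d, "pairing")[1:3, ]), "at least 4")
})

test_that("inter-axial angles match the bent-pair construction", {
  for (ang in c(0, 102, 129)) {
    bp <- make_bent_duplex_pair(ang)
    prs <- attr(bp, "pairings")
    f1 <- fit_helix_axis(bp, prs[[1]])
    f2 <- fit_helix_axis(bp, prs[[2]])
    expect_equal(interaxial_angle(f1, f2), ang, tolerance = 0.5)
  }
  d <- make_ideal_duplex(10)
  f <- fit_helix_axis(d, attr(d, "pairing"))
  expect_equal(interaxial_angle(f, f), 0)
})

test_that("hybrid diameter is twice the P radius and scales homogeneously", {
  d <- make_ideal_duplex(10, p_radius = 9.4)
  dia <- hybrid_diameter(d, attr(d, "pairing"))
  expect_equal(as.numeric(dia), 18.8, tolerance = 0.05)
  d2 <- d
  d2$atoms$x <- d2$atoms$x * 1.1
  d2$atoms$y <- d2$atoms$y * 1.1
  d2$atoms$z <- d2$atoms$z * 1.1
  expect_equal(as.numeric(hybrid_diameter(d2, attr(d, "pairing"))),
               1.1 * as.numeric(dia), tolerance = 1e-9)
})
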