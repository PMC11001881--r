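chain_model <- function(n) {
  mol_model(data.frame(serial = seq_len(n), name = "CA", elem = "C",
                       resname = "GLY", resno = seq_len(n), ins = "",
                       chain = "A",
                       x = 3.8 * (seq_len(n) - 1) * 0.8,
                       y = c(0, 2.2, 0, 2.2, 0, 2.2)[seq_len(n)],
                       z = 0.3 * (seq_len(n) - 1)))
}

test_that("bonded-term counts follow chain connectivity", {
  m3 <- chain_model(3)
  t3 <- build_single_basin(m3, shadow_contact_map(m3))
  expect_equal(nrow(t3$bonds), 2)
  expect_equal(nrow(t3$angles), 1)
  expect_equal(nrow(t3$dihedrals), 0)
  expect_equal(nrow(t3$contacts), 0)
  m4 <- chain_model(4)
  t4 <- build_single_basin(m4, shadow_contact_map(m4))
  expect_equal(nrow(t4$dihedrals), 1)
})

test_that("the source structure is the built-in minimum of its topology", {
  sys <- toy_system()
  e0 <- potential_energy(sys$topo_a, sys$xa)$total
  set.seed(41)
  for (q in 1:100) {
    xp <- sys$xa + matrix(rnorm(length(sys$xa), sd = 0.05 / sqrt(3)),
                          nrow(sys$xa))
    expect_lt(e0, potential_energy(sys$topo_a, xp)$total)
  }
})

test_that("merging a topology with itself yields no dual terms", {
  sys <- toy_system()
  same <- merge_dual_basin(sys$topo_a, sys$topo_a)
  expect_equal(same$divergence$n_contacts_dual, 0)
  expect_equal(same$divergence$n_dihedrals_dual, 0)
  expect_equal(same$divergence$n_contacts_shared, nrow(sys$topo_a$contacts))
})

test_that("the relative-distance threshold splits shared contacts as specified", {
  sys <- toy_system()
  ta <- sys$topo_a
  ## craft a partner topology: same terms, one contact distance shifted
  shift_contact <- function(topo, delta) {
    topo$contacts$r0a[1] <- topo$contacts$r0a[1] + delta
    topo
  }
  r0 <- ta$contacts$r0a[1]
  ## 0.30 vs 0.35 nm is ~15.4% of the mean -> dual
  tb_far <- shift_contact(ta, r0 * (0.35 / 0.30) - r0)
  dual <- merge_dual_basin(ta, tb_far)
  expect_true(dual$contacts$dual[match(paste(ta$contacts$i[1], ta$contacts$j[1]),
                                       paste(dual$contacts$i, dual$contacts$j))])
  ## 0.30 vs 0.31 nm is ~3.3% -> single basin at the state-B distance
  tb_near <- shift_contact(ta, r0 * (0.31 / 0.30) - r0)
  single <- merge_dual_basin(ta, tb_near)
  k <- match(paste(ta$contacts$i[1], ta$contacts$j[1]),
             paste(single$contacts$i, single$contacts$j))
  expect_false(single$contacts$dual[k])
  expect_equal(single$contacts$r0a[k], tb_near$contacts$r0a[1])
})

test_that("dual/single classification is symmetric in the two states", {
  sys <- toy_system()
  ab <- merge_dual_basin(sys$topo_a, sys$topo_b)
  ba <- merge_dual_basin(sys$topo_b, sys$topo_a)
  key <- function(x) paste(x$contacts$i, x$contacts$j)
  expect_equal(ab$divergence$n_contacts_dual, ba$divergence$n_contacts_dual)
  expect_equal(ab$divergence$n_dihedrals_dual, ba$divergence$n_dihedrals_dual)
  expect_setequal(key(ab)[ab$contacts$dual], key(ba)[ba$contacts$dual])
  ## dual count bounded by shared count; reports reproducible bit-exactly
  expect_lte(ab$divergence$n_contacts_dual, ab$divergence$n_contacts_shared)
  expect_identical(ab$divergence,
                   merge_dual_basin(sys$topo_a, sys$topo_b)$divergence)
})

test_that("atom-ordering mismatches are rejected with the first offender", {
  sys <- toy_system()
  tb <- sys$topo_b
  tb$atoms$name[5] <- "CB"
  expect_error(merge_dual_basin(sys$topo_a, tb), "index 5")
})

test_that("a dual-basin contact has minima at both native distances", {
  x2 <- function(r) matrix(c(0, 0, 0, r, 0, 0), 2, 3, byrow = TRUE)
  topo <- list(n = 2L,
               bonds = data.frame(i = integer(0), j = integer(0), b0 = numeric(0)),
               angles = data.frame(i = integer(0), j = integer(0), k = integer(0),
                                   theta0 = numeric(0)),
               dihedrals = data.frame(i = integer(0), j = integer(0),
                                      k = integer(0), l = integer(0),
                                      phi0a = numeric(0), phi0b = numeric(0),
                                      dual = logical(0)),
               contacts = data.frame(i = 1L, j = 2L, r0a = 0.35, r0b = 0.55,
                                     dual = TRUE),
               exclusions = matrix(c(1L, 2L), 1, 2),
               params = sbm_params(), coords_nm = x2(0.35),
               atoms = data.frame(chain = "A", resno = 1:2, name = "CA"))
  class(topo) <- "dual_basin_topology"
  vr <- function(ri) potential_energy(topo, x2(ri))$contact
  m1 <- optimize(vr, c(0.25, 0.45))
  m2 <- optimize(vr, c(0.45, 0.80))
  expect_lt(abs(m1$minimum - 0.35), 1e-3)
  expect_lt(abs(m2$minimum - 0.55), 1e-3)
  ## a barrier separates the two wells
  expect_gt(vr(0.45), max(m1$objective, m2$objective))
  ## at a basin centre the well contributes its full depth
  expect_equal(potential_energy(topo, x2(0.55))$contact, -sbm_params()$eps,
               tolerance = 0.02)
})

test_that("analytic forces match central finite differences", {
  sys <- toy_system()
  for (x in list(sys$xa, sys$xb)) {
    f <- sbm_forces(sys$dual, x)
    set.seed(7)
    idx <- sample(length(x), 15)
    h <- 1e-5
    for (q in idx) {
      xp <- x; xp[q] <- xp[q] + h
      xm <- x; xm[q] <- xm[q] - h
      fd <- -(potential_energy(sys$dual, xp)$total -
                potential_energy(sys$dual, xm)$total) / (2 * h)
      expect_lt(abs(f[q] - fd) / max(1, abs(f[q])), 1e-4)
    }
  }
})

test_that("both endpoint conformations are minima of the merged potential", {
  sys <- toy_system()
  for (x in list(sys$xa, sys$xb)) {
    relax <- minimize_sbm(sys$dual, x, max_iter = 3000)
    expect_lt(rmsd_fit(relax$coords, x), 0.05)
  }
})

test_that("non-finite coordinates and size mismatches are rejected", {
  sys <- toy_system()
  xbad <- sys$xa; xbad[1] <- NaN
  expect_error(potential_energy(sys$dual, xbad), "non-finite")
  expect_error(potential_energy(sys$dual, sys$xa[-1, ]), "match")
})

test_that("topology serialization writes all sections", {
  sys <- toy_system()
  f <- tempfile(fileext = ".txt")
  write_topology(sys$dual, f)
  txt <- readLines(f)
  for (sec in c("params", "atoms", "bonds", "angles", "dihedrals",
                "contacts", "exclusions"))
    expect_true(any(grepl(paste0("^\\[", sec, "\\]"), txt)), label = sec)
})
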