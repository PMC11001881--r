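two_atom_model <- function(d_ang) {
  mol_model(data.frame(serial = 1:2, name = c("CA", "C1'"), elem = "C",
                       resname = c("GLY", "DA"), resno = 1, ins = "",
                       chain = c("A", "B"), x = c(0, d_ang), y = 0, z = 0),
            bonds = matrix(integer(0), ncol = 2))
}

test_that("an isolated pair within the cutoff is one protein-nucleic contact", {
  map <- shadow_contact_map(two_atom_model(5))
  expect_equal(nrow(map$contacts), 1)
  expect_equal(map$contacts$category, "protein-nucleic")
  expect_equal(map$contacts$r0, 0.5)
  expect_equal(nrow(shadow_contact_map(two_atom_model(6.5))$contacts), 0)
})

test_that("the middle atom of a collinear triple occludes the outer pair", {
  m <- mol_model(data.frame(serial = 1:3, name = "CA", elem = "C",
                            resname = "GLY", resno = 1, ins = "",
                            chain = c("A", "B", "C"),
                            x = c(0, 3, 6), y = 0, z = 0),
                 bonds = matrix(integer(0), ncol = 2))
  map <- shadow_contact_map(m)
  expect_equal(nrow(map$contacts), 2)
  expect_equal(map$contacts[, c("i", "j")],
               data.frame(i = c(1L, 2L), j = c(2L, 3L)))
})

test_that("shadow map matches the ray-sampling oracle on random clouds", {
  for (case in list(c(30, 11), c(50, 12), c(80, 13))) {
    m <- random_cloud_model(case[1], seed = case[2])
    map <- shadow_contact_map(m)
    orc <- shadow_oracle(m)
    got <- map$contacts[order(map$contacts$i, map$contacts$j), c("i", "j")]
    want <- orc[order(orc[, 1], orc[, 2]), , drop = FALSE]
    expect_equal(unname(as.matrix(got)), unname(want),
                 label = sprintf("cloud n=%d seed=%d", case[1], case[2]))
  }
})

test_that("contacts respect protein sequence-separation but not across chains", {
  m <- bead_chain_model(12)          # single protein chain
  map <- shadow_contact_map(m)
  expect_true(all(abs(map$contacts$i - map$contacts$j) >= 3))
  ## tightening the rule removes the i, i+3 helical contacts
  map4 <- shadow_contact_map(m, min_seq_sep_protein = 4)
  expect_lt(nrow(map4$contacts), nrow(map$contacts))
  expect_true(all(abs(map4$contacts$i - map4$contacts$j) >= 4))
})

test_that("contact map is invariant under global rotation and translation", {
  m <- random_cloud_model(40, seed = 21)
  R <- duobasin:::rotation_about_axis(c(1, 2, 3), 37)
  m2 <- m
  xyz <- coords(m) %*% t(R)
  m2$atoms$x <- xyz[, 1] + 11; m2$atoms$y <- xyz[, 2] - 5
  m2$atoms$z <- xyz[, 3] + 2
  a <- shadow_contact_map(m)$contacts[, c("i", "j")]
  b <- shadow_contact_map(m2)$contacts[, c("i", "j")]
  expect_equal(a, b)
})

test_that("larger cutoff never removes contacts; larger shadow never adds", {
  m <- random_cloud_model(60, seed = 31)
  key <- function(map) paste(map$contacts$i, map$contacts$j)
  base <- shadow_contact_map(m, cutoff = 0.6, shadow_radius = 0.1)
  wide <- shadow_contact_map(m, cutoff = 0.8, shadow_radius = 0.1)
  dark <- shadow_contact_map(m, cutoff = 0.6, shadow_radius = 0.15)
  expect_true(all(key(base) %in% key(wide)))
  expect_true(all(key(dark) %in% key(base)))
})

test_that("coincident atoms raise an error naming them", {
  m <- two_atom_model(0.0000001)
  expect_error(shadow_contact_map(m), "degenerate|coincide")
})

test_that("group classification labels the interdomain subset", {
  toy <- make_two_state_toy()
  map <- classify_contacts(shadow_contact_map(toy$model_a), toy$groups,
                           toy$model_a)
  id <- contacts_between(map, "NGN", "KOW")
  ## brute-force filter oracle over the full map
  memb <- rep(NA_character_, n_atoms(toy$model_a))
  memb[atoms_in_group(toy$model_a, toy$groups, "NGN")] <- "NGN"
  memb[atoms_in_group(toy$model_a, toy$groups, "KOW")] <- "KOW"
  manual <- sum(!is.na(memb[map$contacts$i]) & !is.na(memb[map$contacts$j]) &
                  memb[map$contacts$i] != memb[map$contacts$j])
  expect_equal(nrow(id), manual)
  expect_gt(nrow(id), 0)
  ## all atoms in one group -> no interdomain contacts
  all_spec <- selection_spec(ALL = sel_range("A", -Inf, Inf))
  map1 <- classify_contacts(shadow_contact_map(toy$model_a), all_spec,
                            toy$model_a)
  expect_equal(nrow(contacts_between(map1, "NGN", "KOW")), 0)
})

test_that("an atom in two selection groups is rejected", {
  toy <- make_two_state_toy()
  spec <- selection_spec(G1 = sel_range("A", 1, 10), G2 = sel_range("A", 5, 15))
  expect_error(classify_contacts(shadow_contact_map(toy$model_a), spec,
                                 toy$model_a), "two selection groups")
})
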