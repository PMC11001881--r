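## Download-free synthetic fixtures.
##
## make_two_state_toy() emulates a fold-switching protein at desk scale:
## one bead-per-residue chain with a rigid anchored domain (NGN stand-in)
## and a switch segment (KOW stand-in) that packs against the anchor as a
## helix in state A and refolds into a self-paired hairpin away from the
## anchor in state B. Both conformations are built by a constant-step
## "pursuit" walk along ideal curves, so covalent bond lengths are
## identical between states by construction.
##
## make_ideal_duplex() places C1'/P pseudo-atoms on an exact helix and is
## the ground-truth oracle for the helix-axis fitting code.

#' Specification of the two-state switcher toy
#'
#' @param n_anchor beads in the rigid anchor domain (default 24).
#' @param n_switch beads in the switching segment (default 14, >= 8).
#' @param n_linker beads connecting anchor and switch (default 3).
#' @param spacing bead spacing, Angstrom (default 3.8, a C-alpha virtual
#'   bond).
#' @param seed RNG seed for the small coordinate jitter.
#' @param jitter jitter amplitude applied to ideal curve points, Angstrom.
#' @return list of class `toy_spec`.
#' @export
toy_switcher_spec <- function(n_anchor = 24L, n_switch = 14L, n_linker = 3L,
                              spacing = 3.8, seed = 1L, jitter = 0.15) {
  if (n_switch < 8) stop("n_switch must be >= 8")
  structure(list(n_anchor = as.integer(n_anchor), n_switch = as.integer(n_switch),
                 n_linker = as.integer(n_linker), spacing = spacing,
                 seed = as.integer(seed), jitter = jitter),
            class = "toy_spec")
}

## place atom D given A-B-C, bond |CD| = r, angle BCD = theta and
## torsion ABCD = phi (NeRF construction)
nerf_place <- function(A, B, C, r, theta, phi) {
  e1 <- C - B; e1 <- e1 / sqrt(sum(e1^2))
  v <- B - A
  n <- c(v[2] * e1[3] - v[3] * e1[2], v[3] * e1[1] - v[1] * e1[3],
         v[1] * e1[2] - v[2] * e1[1])
  n <- n / sqrt(sum(n^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2], n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  C + r * (-cos(theta) * e1 + sin(theta) * (cos(phi) * e2 + sin(phi) * n))
}

#' Force-field parameters for the bead-per-residue toy
#'
#' The toy rescales three constants from the all-atom defaults of
#' [sbm_params()] to residue-bead scale. One bead-bead native contact
#' stands in for the several atom-atom contacts a residue pair carries in
#' an all-atom model, so the per-contact well is deeper (eps = 2 reduced
#' units). The excluded-volume radii are bead-sized (contact core
#' r_ex = 0.35 nm, non-native r_nn = 0.38 nm, about one virtual-bond
#' length) rather than atom-sized: without a bead-scale core the chain
#' can collapse into compact non-native blobs in which distance-criterion
#' contacts of both states count as "formed" simultaneously, destroying
#' the two-state character of the model. With these choices the docked
#' state is stable at low temperature (Q_A > 0.8 at T = 0.3) and
#' switching is accessible at the toy's switching temperature (T = 1.0).
#'
#' @return an [sbm_params()] object.
#' @export
toy_sbm_params <- function() sbm_params(eps = 2, r_ex = 0.35, r_nn = 0.38)

## constant-step walk pursuing a sequence of ideal points
pursuit_walk <- function(ideal, spacing) {
  out <- ideal
  for (k in seq_len(nrow(ideal) - 1)) {
    d <- ideal[k + 1, ] - out[k, ]
    nd <- sqrt(sum(d^2))
    if (nd < 1e-9) stop("infeasible toy geometry: coincident waypoints at bead ", k)
    out[k + 1, ] <- out[k, ] + spacing * d / nd
  }
  out
}

## nl linker waypoints from p0 to p1 along a two-segment detour whose
## polyline length equals (nl + 1) * spacing, bulged away from the chain
linker_points <- function(p0, p1, nl, spacing) {
  d <- p1 - p0; nd <- sqrt(sum(d^2))
  L <- (nl + 1) * spacing
  if (L <= nd) {  # direct line is long enough
    return(sweep(outer(seq_len(nl) / (nl + 1), d), 2, p0, "+"))
  }
  w <- c(0, 0, 1) - sum(d * c(0, 0, 1)) / nd^2 * d
  if (sqrt(sum(w^2)) < 1e-6) w <- c(1, 0, 0) - sum(d * c(1, 0, 0)) / nd^2 * d
  w <- w / sqrt(sum(w^2))
  h <- sqrt((L / 2)^2 - (nd / 2)^2)
  M <- (p0 + p1) / 2 + h * w
  seg1 <- sqrt(sum((M - p0)^2)); seg2 <- sqrt(sum((p1 - M)^2))
  t(vapply(seq_len(nl) * spacing, function(arc) {
    if (arc <= seg1) p0 + (arc / seg1) * (M - p0)
    else M + ((arc - seg1) / seg2) * (p1 - M)
  }, numeric(3)))
}

helix_points <- function(n, radius = 2.3, rise = 1.5, dtheta = 100,
                         phase = 0, z0 = 0, center = c(0, 0), descending = FALSE) {
  k <- seq_len(n) - 1
  th <- (phase + dtheta * k) * pi / 180
  z <- z0 + (if (descending) -rise else rise) * k
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th), z)
}

#' Generate the two-state fold-switching toy
#'
#' @param spec a [toy_switcher_spec()].
#' @return list with `model_a` (switch packed on the anchor; many
#'   interdomain contacts), `model_b` (switch self-paired away from the
#'   anchor; interdomain contacts broken), `groups` (a [selection_spec()]
#'   with `NGN` = anchor and `KOW` = switch residues, linker excluded) and
#'   `strands` (first/second half of the switch, for strand-pair formation
#'   events).
#' @export
make_two_state_toy <- function(spec = toy_switcher_spec()) {
  stopifnot(inherits(spec, "toy_spec"))
  na <- spec$n_anchor; ns <- spec$n_switch; nl <- spec$n_linker
  s <- spec$spacing
  set.seed(spec$seed)
  jit <- function(n) matrix(stats::runif(3 * n, -spec$jitter, spec$jitter), n, 3)
  j_anchor <- jit(na); j_la <- jit(nl); j_sa <- jit(ns)

  anchor <- helix_points(na) + j_anchor
  ztop <- anchor[na, 3]

  ## state A: switch helix descends parallel to the anchor, close enough
  ## for interdomain contacts (axis separation 8.4 A)
  switch_a <- helix_points(ns, phase = 180, z0 = ztop - 1,
                           center = c(8.4, 0), descending = TRUE) + j_sa
  link_a <- linker_points(anchor[na, ], switch_a[1, ], nl, s) + j_la
  xyz_a <- pursuit_walk(rbind(anchor, link_a, switch_a), s)
  n <- na + nl + ns

  ## state B is rebuilt from state A's measured bond lengths and bend
  ## angles with redesigned torsions (NeRF chain extension), so the two
  ## conformations share all covalent internal coordinates exactly and
  ## differ only in dihedrals and nonbonded packing: the linker torsions
  ## swing the switch away from the anchor, and the switch refolds into
  ## an antiparallel hairpin (zigzag strands + 3-bead turn).
  h1 <- min(6L, ceiling((ns - 3) / 2)); h2 <- ns - 3L - h1
  torsions <- c(180, rep(c(90, 60), length.out = nl - 1), -90,
                rep(-170, h1 - 1), 105, -100, 75, rep(-170, h2)) * pi / 180
  torsions <- torsions + stats::runif(length(torsions), -2, 2) * pi / 180
  xyz_b <- xyz_a
  for (k in (na + 1):n) {
    rk <- sqrt(sum((xyz_a[k, ] - xyz_a[k - 1, ])^2))
    u <- xyz_a[k - 2, ] - xyz_a[k - 1, ]; w <- xyz_a[k, ] - xyz_a[k - 1, ]
    thk <- acos(sum(u * w) / sqrt(sum(u^2) * sum(w^2)))
    xyz_b[k, ] <- nerf_place(xyz_b[k - 3, ], xyz_b[k - 2, ], xyz_b[k - 1, ],
                             rk, thk, torsions[k - na])
  }

  build <- function(xyz) {
    d <- as.matrix(stats::dist(xyz))
    diag(d) <- Inf
    if (min(d) < 0.5 * s)
      stop("infeasible toy geometry: self-clash between beads ",
           paste(which(d == min(d), arr.ind = TRUE)[1, ], collapse = " and "))
    mol_model(data.frame(serial = seq_len(n), name = "CA", elem = "C",
                         resname = "GLY", resno = seq_len(n), ins = "",
                         chain = "A", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                         stringsAsFactors = FALSE),
              title = "two-state switcher toy")
  }
  model_a <- build(xyz_a)
  model_b <- build(xyz_b)
  sw_start <- na + nl + 1; sw_end <- na + nl + ns
  groups <- selection_spec(
    NGN = sel_range("A", 1, na),
    KOW = sel_range("A", sw_start, sw_end))
  strands <- list(
    strand1 = sw_start:(sw_start + h1 - 1),
    strand2 = (sw_start + h1 + 3):sw_end)
  list(model_a = model_a, model_b = model_b, groups = groups,
       strands = strands, spec = spec)
}

#' Generate an ideal duplex with a known helical axis
#'
#' Two antiparallel strands of C1'/P pseudo-atoms on an exact helix; the
#' paired C1' atoms are placed diametrically, so the base-pair reference
#' points lie exactly on the true axis.
#'
#' @param n_bp number of base pairs (>= 4).
#' @param twist helical twist per base pair, degrees (default 36).
#' @param rise helical rise per base pair, Angstrom (default 3.38).
#' @param p_radius radial distance of P atoms from the axis, Angstrom
#'   (default 9.4).
#' @param c1_radius radial distance of C1' atoms, Angstrom (default 5.9).
#' @param axis direction of the true helix axis (unit-normalised).
#' @param origin position of the first base-pair reference point.
#' @param chains two chain identifiers.
#' @return a `mol_model` with attribute `"ground_truth"` (true axis,
#'   origin, radii) and attribute `"pairing"` (the base-pairing table).
#' @export
make_ideal_duplex <- function(n_bp = 10L, twist = 36, rise = 3.38,
                              p_radius = 9.4, c1_radius = 5.9,
                              axis = c(0, 0, 1), origin = c(0, 0, 0),
                              chains = c("D", "E")) {
  if (n_bp < 4) stop("n_bp must be >= 4")
  axis <- axis / sqrt(sum(axis^2))
  z <- c(0, 0, 1)
  cz <- sum(axis * z)
  R <- if (cz > 1 - 1e-12) diag(3)
  else if (cz < -1 + 1e-12) rotation_about_axis(c(1, 0, 0), 180)
  else rotation_about_axis(c(z[2] * axis[3] - z[3] * axis[2],
                             z[3] * axis[1] - z[1] * axis[3],
                             z[1] * axis[2] - z[2] * axis[1]),
                           acos(cz) * 180 / pi)
  place <- function(r, th_deg, zz) {
    p <- c(r * cos(th_deg * pi / 180), r * sin(th_deg * pi / 180), zz)
    as.numeric(R %*% p) + origin
  }
  rows <- list()
  add <- function(chain, resno, name, elem, p)
    rows[[length(rows) + 1]] <<- data.frame(
      serial = 0L, name = name, elem = elem, resname = "DA",
      resno = resno, ins = "", chain = chain,
      x = p[1], y = p[2], z = p[3], stringsAsFactors = FALSE)
  for (k in seq_len(n_bp)) {
    th <- (k - 1) * twist; zz <- (k - 1) * rise
    add(chains[1], k, "C1'", "C", place(c1_radius, th, zz))
    add(chains[1], k, "P", "P", place(p_radius, th + 70, zz))
  }
  for (j in seq_len(n_bp)) {
    k <- n_bp + 1 - j  # paired residue on strand 1
    th <- (k - 1) * twist + 180; zz <- (k - 1) * rise
    add(chains[2], j, "C1'", "C", place(c1_radius, th, zz))
    add(chains[2], j, "P", "P", place(p_radius, th - 70, zz))
  }
  at <- do.call(rbind, rows)
  at$serial <- seq_len(nrow(at))
  m <- mol_model(at, bonds = matrix(integer(0), ncol = 2),
                 title = sprintf("ideal duplex | axis %.4f %.4f %.4f",
                                 axis[1], axis[2], axis[3]))
  attr(m, "ground_truth") <- list(axis = axis, origin = origin,
                                  p_radius = p_radius, c1_radius = c1_radius,
                                  twist = twist, rise = rise)
  attr(m, "pairing") <- duplex_pairing(n_bp, chains[1], chains[2])
  m
}

#' Generate two ideal duplexes whose axes meet at a known angle
#'
#' @param angle requested inter-axial angle, degrees in `[0, 180]`.
#' @param n_bp base pairs per arm.
#' @return a `mol_model` holding both duplexes (chains D/E and F/G) with
#'   attributes `"ground_truth"` (true axes and angle) and `"pairings"`
#'   (list of the two base-pairing tables).
#' @export
make_bent_duplex_pair <- function(angle, n_bp = 10L) {
  stopifnot(angle >= 0, angle <= 180)
  a1 <- c(0, 0, 1)
  th <- angle * pi / 180
  a2 <- c(sin(th), 0, cos(th))
  d1 <- make_ideal_duplex(n_bp, axis = a1, origin = c(0, 0, 0),
                          chains = c("D", "E"))
  d2 <- make_ideal_duplex(n_bp, axis = a2, origin = c(0, 40, 0),
                          chains = c("F", "G"))
  at <- rbind(d1$atoms, d2$atoms)
  at$serial <- seq_len(nrow(at))
  m <- mol_model(at, bonds = matrix(integer(0), ncol = 2),
                 title = sprintf("bent duplex pair | angle %.2f", angle))
  attr(m, "ground_truth") <- list(axis1 = a1, axis2 = a2, angle = angle)
  attr(m, "pairings") <- list(duplex_pairing(n_bp, "D", "E"),
                              duplex_pairing(n_bp, "F", "G"))
  m
}
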