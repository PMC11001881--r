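## Rigid-body geometry descriptors of elongation complexes: two-stage
## superposition swiveling angles, DNA duplex helix-axis fits,
## inter-duplex angles and RNA:DNA hybrid diameters. All Angstrom here
## (file-interface units).

match_selection <- function(mobile, reference, spec, group) {
  ma <- select_atoms(mobile, spec, group)$atoms
  ra <- select_atoms(reference, spec, group)$atoms
  key <- function(a) paste(a$chain, a$resno, a$ins, a$name)
  km <- key(ma); kr <- key(ra)
  common <- intersect(km, kr)
  un_m <- setdiff(km, kr); un_r <- setdiff(kr, km)
  if (length(common) < 3)
    stop("fewer than 3 matched atoms in selection '", group, "'; unmatched: ",
         paste(head(c(un_m, un_r), 5), collapse = "; "))
  im <- match(common, km); ir <- match(common, kr)
  list(P = cbind(ma$x[im], ma$y[im], ma$z[im]),
       Q = cbind(ra$x[ir], ra$y[ir], ra$z[ir]),
       n = length(common), n_unmatched = length(un_m) + length(un_r),
       unmatched = head(c(un_m, un_r), 5))
}

check_noncollinear <- function(P) {
  s <- svd(sweep(P, 2, colMeans(P)))$d
  if (s[2] < 1e-6 * max(s[1], 1e-12))
    stop("selection atoms are collinear; superposition is degenerate")
}

#' Rigid superposition of matched selections of two models
#'
#' Atoms are matched 1:1 by chain, residue number, insertion code and atom
#' name within the named selection group; the least-squares proper
#' rotation (reflections rejected) and translation mapping `mobile` onto
#' `reference` are returned.
#'
#' @param mobile,reference `mol_model`s.
#' @param spec a [selection_spec()] resolvable in both models.
#' @param group selection group to superpose on.
#' @return object of class `rigid_transform`: `R` (3 x 3, det +1), `t`
#'   (Angstrom), `rmsd` (Angstrom), `n_atoms` matched.
#' @export
superpose <- function(mobile, reference, spec, group) {
  m <- match_selection(mobile, reference, spec, group)
  if (m$n_unmatched > 0)
    warning("superpose: ", m$n_unmatched, " unmatched atoms dropped (e.g. ",
            paste(m$unmatched, collapse = "; "), ")")
  check_noncollinear(m$P)
  fit <- kabsch_fit(m$P, m$Q)
  structure(list(R = fit$R, t = fit$t, rmsd = fit$rmsd, n_atoms = m$n),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> %d atoms, RMSD %.3f A, rotation %.2f deg\n",
              x$n_atoms, x$rmsd, rotation_angle_deg(x$R)))
  invisible(x)
}

#' Apply a rigid transform to a model
#'
#' @param model a `mol_model`.
#' @param transform a `rigid_transform`.
#' @return the transformed model.
#' @export
apply_transform <- function(model, transform) {
  xyz <- coords(model) %*% transform$R
  model$atoms$x <- xyz[, 1] + transform$t[1]
  model$atoms$y <- xyz[, 2] + transform$t[2]
  model$atoms$z <- xyz[, 3] + transform$t[3]
  model
}

rotation_angle_deg <- function(R) {
  acos(pmax(-1, pmin(1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

rotation_axis <- function(R) {
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  nrm <- sqrt(sum(ax^2))
  if (nrm < 1e-9) c(0, 0, 1) else ax / nrm
}

#' Swiveling angle between two complexes
#'
#' Two-stage superposition: models are first aligned on the core
#' selection, then the best-fit rotation mapping A's swivel-module atoms
#' onto B's is computed; the reported angle is the axis-angle magnitude
#' `acos((trace - 1) / 2)` of that rotation.
#'
#' @param model_a,model_b `mol_model`s of the two complexes.
#' @param spec selection spec providing both groups.
#' @param core_group,swivel_group group names of the core and swivel
#'   modules.
#' @return object of class `swivel_result`: `angle` (degrees, in
#'   `[0, 180]`), `axis` (unit vector), `core_rmsd` (Angstrom).
#' @export
swivel_angle <- function(model_a, model_b, spec, core_group = "core",
                         swivel_group = "swivel") {
  core <- superpose(model_a, model_b, spec, core_group)
  a_on_b <- apply_transform(model_a, core)
  m <- match_selection(a_on_b, model_b, spec, swivel_group)
  check_noncollinear(m$P)
  fit <- kabsch_fit(m$P, m$Q)
  ## rotation axis in the row-vector convention: use transpose for the
  ## standard column-vector axis extraction
  structure(list(angle = rotation_angle_deg(fit$R),
                 axis = rotation_axis(t(fit$R)),
                 core_rmsd = core$rmsd, swivel_rmsd = fit$rmsd,
                 n_core = core$n_atoms, n_swivel = m$n),
            class = "swivel_result")
}

#' @export
print.swivel_result <- function(x, ...) {
  cat(sprintf("<swivel_result> angle %.2f deg | core RMSD %.2f A (%d atoms), swivel %d atoms\n",
              x$angle, x$core_rmsd, x$n_core, x$n_swivel))
  invisible(x)
}

#' Core and swivel module selections for bacterial RNAP
#'
#' Residue ranges of the superposition core (alpha-I, alpha-II and omega
#' subunits whole, plus segments of beta and beta-prime) and of the swivel
#' module (clamp, dock, shelf, SI3 and the C-terminal beta-prime segment)
#' used for swiveling-angle analysis of elongation complexes. Chain
#' identifiers vary between depositions and must be read from each entry's
#' entity annotation; they are therefore arguments.
#'
#' @param beta,beta_prime,alpha1,alpha2,omega chain IDs of the respective
#'   subunits in the coordinate file.
#' @return a [selection_spec()] with groups `core` and `swivel`.
#' @export
rnap_selections <- function(beta = "C", beta_prime = "D", alpha1 = "A",
                            alpha2 = "B", omega = "E") {
  core <- rbind(
    sel_range(alpha1), sel_range(alpha2), sel_range(omega),
    sel_range(beta, 1, 30), sel_range(beta, 140, 150),
    sel_range(beta, 445, 455), sel_range(beta, 513, 832),
    sel_range(beta, 1056, 1240),
    sel_range(beta_prime, 343, 368), sel_range(beta_prime, 421, 786))
  swivel <- rbind(
    sel_range(beta, 1241, 1341),
    sel_range(beta_prime, 16, 347), sel_range(beta_prime, 369, 420),
    sel_range(beta_prime, 787, 931), sel_range(beta_prime, 946, 1126),
    sel_range(beta_prime, 1135, 1373))
  selection_spec(core = core, swivel = swivel)
}

#' Base-pairing table for an ideal duplex
#'
#' Pairs residue `k` of `chain1` with residue `n_bp + 1 - k` of `chain2`.
#'
#' @param n_bp number of base pairs.
#' @param chain1,chain2 chain identifiers of the two strands.
#' @return data.frame `chain1`, `res1`, `chain2`, `res2`.
#' @export
duplex_pairing <- function(n_bp, chain1 = "D", chain2 = "E") {
  data.frame(chain1 = chain1, res1 = seq_len(n_bp),
             chain2 = chain2, res2 = rev(seq_len(n_bp)),
             stringsAsFactors = FALSE)
}

#' Fit the helical axis of a duplex
#'
#' Per base pair, the reference point is the mean of the two C1' atoms;
#' the axis is the principal direction (total least squares) of these
#' points, oriented 5'-to-3' along the first strand. The radius is the
#' mean distance of backbone P atoms from the fitted axis.
#'
#' @param duplex a `mol_model` containing the two strands.
#' @param pairing a base-pairing table as from [duplex_pairing()].
#' @return object of class `helix_fit`: `origin` (centroid, Angstrom),
#'   `axis` (unit vector), `radius` (Angstrom), `n_bp`.
#' @export
fit_helix_axis <- function(duplex, pairing) {
  if (nrow(pairing) < 4) stop("need at least 4 base pairs")
  at <- duplex$atoms
  getc1 <- function(ch, res) {
    idx <- which(at$chain == ch & at$resno == res & at$name == "C1'")
    if (!length(idx)) stop("missing C1' atom for residue ", ch, ":", res)
    c(at$x[idx[1]], at$y[idx[1]], at$z[idx[1]])
  }
  mids <- t(vapply(seq_len(nrow(pairing)), function(r)
    (getc1(pairing$chain1[r], pairing$res1[r]) +
       getc1(pairing$chain2[r], pairing$res2[r])) / 2, numeric(3)))
  origin <- colMeans(mids)
  sv <- svd(sweep(mids, 2, origin))
  axis <- sv$v[, 1]
  ## orient 5' -> 3' of the first strand (pairing row order)
  span <- mids[nrow(mids), ] - mids[1, ]
  if (sum(axis * span) < 0) axis <- -axis
  pidx <- which(at$chain %in% c(pairing$chain1, pairing$chain2) & at$name == "P" &
                  ((at$chain %in% pairing$chain1 & at$resno %in% pairing$res1) |
                   (at$chain %in% pairing$chain2 & at$resno %in% pairing$res2)))
  if (!length(pidx))
    stop("no backbone P atoms found for paired residues of chains ",
         paste(unique(c(pairing$chain1, pairing$chain2)), collapse = ","))
  pxyz <- cbind(at$x[pidx], at$y[pidx], at$z[pidx])
  rel <- sweep(pxyz, 2, origin)
  para <- rel %*% axis
  radius <- mean(sqrt(rowSums((rel - outer(as.numeric(para), axis))^2)))
  structure(list(origin = origin, axis = axis, radius = radius,
                 n_bp = nrow(pairing)),
            class = "helix_fit")
}

#' @export
print.helix_fit <- function(x, ...) {
  cat(sprintf("<helix_fit> %d bp | axis (%.3f, %.3f, %.3f), radius %.2f A\n",
              x$n_bp, x$axis[1], x$axis[2], x$axis[3], x$radius))
  invisible(x)
}

#' Angle between two fitted helix axes
#'
#' Axes are translated to a common origin; the angle between the oriented
#' axis vectors is reported in `[0, 180]` degrees.
#'
#' @param a,b `helix_fit` objects.
#' @return angle in degrees.
#' @export
interaxial_angle <- function(a, b) {
  stopifnot(inherits(a, "helix_fit"), inherits(b, "helix_fit"))
  acos(pmax(-1, pmin(1, sum(a$axis * b$axis)))) * 180 / pi
}

#' Diameter of an RNA:DNA hybrid (or any duplex)
#'
#' Twice the mean radial distance of backbone P atoms from the fitted
#' helix axis.
#'
#' @param hybrid a `mol_model` of the duplex.
#' @param pairing base-pairing table.
#' @return diameter in Angstrom, with the `helix_fit` attached as
#'   attribute `"fit"`.
#' @export
hybrid_diameter <- function(hybrid, pairing) {
  fit <- fit_helix_axis(hybrid, pairing)
  structure(2 * fit$radius, fit = fit)
}
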