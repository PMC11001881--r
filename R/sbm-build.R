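## Single- and dual-basin structure-based topologies.
##
## Reduced units throughout: length nm, energy eps = 1, mass 1. Native
## contacts are attractive Gaussian wells over an excluded-volume core;
## everything non-native is purely repulsive. Merging two single-basin
## topologies built on the same covalent topology yields the dual-basin
## model: terms whose equilibrium values diverge beyond the thresholds
## become two-well terms, all others keep the state-B values (the
## published convention: parameters from the target/active state).

#' Force-field parameter set for structure-based models
#'
#' @param kb harmonic bond constant, eps/nm^2.
#' @param ka harmonic angle constant, eps/rad^2.
#' @param kd proper-dihedral strength, eps.
#' @param eps native-contact depth, eps.
#' @param sigma Gaussian well width, nm.
#' @param r_ex contact excluded-volume radius, nm.
#' @param r_nn non-native excluded-volume radius, nm.
#' @param nn_rcut truncation radius of the (shifted) non-native repulsion, nm.
#' @return list of class `sbm_params`.
#' @export
sbm_params <- function(kb = 2e4, ka = 40, kd = 1, eps = 1, sigma = 0.05,
                       r_ex = 0.04, r_nn = 0.25, nn_rcut = 2.5 * r_nn) {
  structure(list(kb = kb, ka = ka, kd = kd, eps = eps, sigma = sigma,
                 r_ex = r_ex, r_nn = r_nn, nn_rcut = nn_rcut),
            class = "sbm_params")
}

## neighbor lists from a bond matrix
adjacency <- function(bonds, n) {
  adj <- vector("list", n)
  if (nrow(bonds)) for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1]; j <- bonds[r, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, sort)
}

#' Build a single-basin structure-based topology
#'
#' Bonds, angles and one canonical proper dihedral per rotatable bond are
#' enumerated from the model's covalent connectivity with equilibrium
#' values measured from its coordinates; each native contact of `map`
#' becomes a single-basin Gaussian well at its measured distance.
#'
#' @param model a [mol_model()] with inferred covalent bonds.
#' @param map a [shadow_contact_map()] built on the same model.
#' @param params an [sbm_params()] set.
#' @return object of class `dual_basin_topology` (all terms single-basin).
#' @export
build_single_basin <- function(model, map, params = sbm_params()) {
  stopifnot(inherits(model, "mol_model"), inherits(map, "contact_map"))
  n <- n_atoms(model)
  if (map$n_atoms != n) stop("contact map was built on a different model")
  ct <- map$contacts
  if (nrow(ct) && (max(ct$i, ct$j) > n)) stop("contact references atom absent from model")
  x <- coords(model, "nm")
  b <- model$bonds
  bonds <- data.frame(i = integer(0), j = integer(0), b0 = numeric(0))
  if (nrow(b)) {
    b0 <- sqrt(rowSums((x[b[, 1], , drop = FALSE] - x[b[, 2], , drop = FALSE])^2))
    bonds <- data.frame(i = b[, 1], j = b[, 2], b0 = b0)
  }
  adj <- adjacency(b, n)
  ## angles: every neighbor pair around each center
  ang <- list()
  for (jc in seq_len(n)) {
    nb <- adj[[jc]]
    if (length(nb) >= 2) {
      cmb <- utils::combn(nb, 2)
      ang[[length(ang) + 1]] <- cbind(cmb[1, ], jc, cmb[2, ])
    }
  }
  angles <- if (length(ang)) {
    a <- do.call(rbind, ang)
    data.frame(i = a[, 1], j = a[, 2], k = a[, 3],
               theta0 = bend_angle(x[a[, 1], , drop = FALSE],
                                   x[a[, 2], , drop = FALSE],
                                   x[a[, 3], , drop = FALSE]))
  } else data.frame(i = integer(0), j = integer(0), k = integer(0),
                    theta0 = numeric(0))
  ## one canonical proper dihedral per rotatable central bond:
  ## lowest-index flanking neighbors (deterministic, template-free)
  dih <- list()
  if (nrow(bonds)) for (r in seq_len(nrow(bonds))) {
    jc <- bonds$i[r]; kc <- bonds$j[r]
    fi <- setdiff(adj[[jc]], kc); fl <- setdiff(adj[[kc]], jc)
    if (!length(fi) || !length(fl)) next
    ia <- fi[1]; la <- fl[1]
    if (ia == la) {  # 3-ring; try next flanking atom
      if (length(fl) > 1) la <- fl[2] else if (length(fi) > 1) ia <- fi[2] else next
    }
    dih[[length(dih) + 1]] <- c(ia, jc, kc, la)
  }
  dihedrals <- if (length(dih)) {
    d <- do.call(rbind, dih)
    data.frame(i = d[, 1], j = d[, 2], k = d[, 3], l = d[, 4],
               phi0a = dihedral_angle(x[d[, 1], , drop = FALSE],
                                      x[d[, 2], , drop = FALSE],
                                      x[d[, 3], , drop = FALSE],
                                      x[d[, 4], , drop = FALSE]),
               phi0b = NA_real_, dual = FALSE)
  } else data.frame(i = integer(0), j = integer(0), k = integer(0),
                    l = integer(0), phi0a = numeric(0), phi0b = numeric(0),
                    dual = logical(0))
  contacts <- data.frame(i = ct$i, j = ct$j, r0a = ct$r0,
                         r0b = rep(NA_real_, nrow(ct)),
                         dual = rep(FALSE, nrow(ct)),
                         origin = rep("single", nrow(ct)),
                         stringsAsFactors = FALSE)
  excl <- unique(rbind(graph_pairs_within(b, n, k = 3L),
                       cbind(pmin(ct$i, ct$j), pmax(ct$i, ct$j))))
  structure(list(n = n,
                 atoms = model$atoms[, c("name", "resname", "resno", "ins",
                                         "chain", "class")],
                 coords_nm = x,
                 bonds = bonds, angles = angles, dihedrals = dihedrals,
                 contacts = contacts, exclusions = excl,
                 params = params,
                 provenance = list(title = model$title,
                                   contact_params = map$params)),
            class = "dual_basin_topology")
}

#' @export
print.dual_basin_topology <- function(x, ...) {
  cat(sprintf(paste0("<dual_basin_topology> %d atoms | %d bonds, %d angles, ",
                     "%d dihedrals (%d dual), %d contacts (%d dual)\n"),
              x$n, nrow(x$bonds), nrow(x$angles), nrow(x$dihedrals),
              sum(x$dihedrals$dual), nrow(x$contacts), sum(x$contacts$dual)))
  if (!is.null(x$divergence))
    cat(sprintf("  divergence: %d/%d shared contacts dual, %d dihedrals dual\n",
                x$divergence$n_contacts_dual, x$divergence$n_contacts_shared,
                x$divergence$n_dihedrals_dual))
  invisible(x)
}

#' Merge two single-basin topologies into a dual-basin model
#'
#' Contacts present in both maps whose relative distance difference
#' (`|r0A - r0B| / mean(r0A, r0B)`) exceeds `dist_rel_thresh` become
#' dual-basin with both distances; otherwise the state-B distance is kept.
#' Contacts unique to one state stay single-basin at that state's distance.
#' Dihedrals whose periodic angular difference exceeds
#' `dihedral_thresh * 360` degrees become dual-basin; bonds and angles
#' keep state-B parameters throughout.
#'
#' @param topo_a,topo_b single-basin topologies built on models with
#'   identical atom ordering (A = source/autoinhibited, B = target/active).
#' @param dist_rel_thresh relative contact-distance divergence threshold
#'   (default 0.10).
#' @param dihedral_thresh dihedral divergence threshold as a fraction of a
#'   full turn (default 0.20, i.e. 72 degrees).
#' @return a `dual_basin_topology` whose `divergence` element reports the
#'   dual-term counts.
#' @export
merge_dual_basin <- function(topo_a, topo_b, dist_rel_thresh = 0.10,
                             dihedral_thresh = 0.20) {
  stopifnot(inherits(topo_a, "dual_basin_topology"),
            inherits(topo_b, "dual_basin_topology"))
  if (topo_a$n != topo_b$n)
    stop("atom-count mismatch: ", topo_a$n, " vs ", topo_b$n)
  ka <- paste(topo_a$atoms$chain, topo_a$atoms$resno, topo_a$atoms$name)
  kb <- paste(topo_b$atoms$chain, topo_b$atoms$resno, topo_b$atoms$name)
  bad <- which(ka != kb)
  if (length(bad))
    stop("atom ordering mismatch at index ", bad[1], ": '", ka[bad[1]],
         "' vs '", kb[bad[1]], "'")
  out <- topo_b  # bonds, angles, coords: state B
  ## dihedrals must come from the same covalent connectivity
  dk_a <- with(topo_a$dihedrals, paste(i, j, k, l))
  dk_b <- with(topo_b$dihedrals, paste(i, j, k, l))
  if (!identical(dk_a, dk_b)) {
    first <- which(dk_a != dk_b)[1]
    stop("dihedral enumeration mismatch (covalent topologies differ) at term ",
         ifelse(is.na(first), length(dk_a), first))
  }
  dphi <- abs(wrap_pi(topo_a$dihedrals$phi0a - topo_b$dihedrals$phi0a))
  d_dual <- dphi > dihedral_thresh * 2 * pi
  out$dihedrals$dual <- d_dual
  out$dihedrals$phi0b <- ifelse(d_dual, topo_b$dihedrals$phi0a, NA_real_)
  out$dihedrals$phi0a <- ifelse(d_dual, topo_a$dihedrals$phi0a,
                                topo_b$dihedrals$phi0a)
  ## contacts keyed by atom pair
  key <- function(df) paste(df$i, df$j)
  ca <- topo_a$contacts; cb <- topo_b$contacts
  shared <- intersect(key(ca), key(cb))
  ia <- match(shared, key(ca)); ib <- match(shared, key(cb))
  rel <- abs(ca$r0a[ia] - cb$r0a[ib]) / ((ca$r0a[ia] + cb$r0a[ib]) / 2)
  c_dual <- rel > dist_rel_thresh
  shared_df <- data.frame(i = cb$i[ib], j = cb$j[ib],
                          r0a = ifelse(c_dual, ca$r0a[ia], cb$r0a[ib]),
                          r0b = ifelse(c_dual, cb$r0a[ib], NA_real_),
                          dual = c_dual, origin = "both",
                          stringsAsFactors = FALSE)
  only_a <- ca[!(key(ca) %in% shared), , drop = FALSE]
  only_a$origin <- rep("A", nrow(only_a))
  only_b <- cb[!(key(cb) %in% shared), , drop = FALSE]
  only_b$origin <- rep("B", nrow(only_b))
  out$contacts <- rbind(shared_df, only_a, only_b)
  rownames(out$contacts) <- NULL
  out$exclusions <- unique(rbind(
    graph_pairs_within(as.matrix(out$bonds[, c("i", "j")]), out$n, k = 3L),
    cbind(pmin(out$contacts$i, out$contacts$j),
          pmax(out$contacts$i, out$contacts$j))))
  out$divergence <- list(
    n_contacts_shared = length(shared),
    n_contacts_dual = sum(c_dual),
    n_contacts_a_only = nrow(only_a),
    n_contacts_b_only = nrow(only_b),
    n_dihedrals = nrow(out$dihedrals),
    n_dihedrals_dual = sum(d_dual),
    dist_rel_thresh = dist_rel_thresh,
    dihedral_thresh = dihedral_thresh)
  out$provenance <- list(state_a = topo_a$provenance, state_b = topo_b$provenance)
  out
}

## flatten a topology into the argument list of the C++ kernel
topo_arrays <- function(topo) {
  p <- topo$params
  list(n = topo$n,
       bi = as.integer(topo$bonds$i), bj = as.integer(topo$bonds$j),
       b0 = topo$bonds$b0, kb = rep(p$kb, nrow(topo$bonds)),
       ai = as.integer(topo$angles$i), aj = as.integer(topo$angles$j),
       ak = as.integer(topo$angles$k), th0 = topo$angles$theta0,
       ka = rep(p$ka, nrow(topo$angles)),
       di = as.integer(topo$dihedrals$i), dj = as.integer(topo$dihedrals$j),
       dk = as.integer(topo$dihedrals$k), dl = as.integer(topo$dihedrals$l),
       p0a = topo$dihedrals$phi0a, p0b = topo$dihedrals$phi0b,
       kd = rep(p$kd, nrow(topo$dihedrals)),
       ci = as.integer(topo$contacts$i), cj = as.integer(topo$contacts$j),
       r0a = topo$contacts$r0a, r0b = topo$contacts$r0b,
       sig = rep(p$sigma, nrow(topo$contacts)),
       rex = rep(p$r_ex, nrow(topo$contacts)),
       eps = rep(p$eps, nrow(topo$contacts)),
       ei = as.integer(topo$exclusions[, 1]),
       ej = as.integer(topo$exclusions[, 2]),
       r_nn = p$r_nn, nn_rcut = p$nn_rcut)
}

#' Potential energy of a topology at given coordinates
#'
#' @param topology a `dual_basin_topology`.
#' @param coords n x 3 coordinates, nm.
#' @return list with per-term-class energies (`bond`, `angle`, `dihedral`,
#'   `contact`, `repulsion`) and `total`, in reduced units.
#' @export
potential_energy <- function(topology, coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) != topology$n)
    stop("coordinate count (", nrow(coords), ") does not match topology (",
         topology$n, ")")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  res <- sbm_energy_cpp(topo_arrays(topology), coords)
  res[c("bond", "angle", "dihedral", "contact", "repulsion", "total")]
}

#' Analytic forces of a topology at given coordinates
#'
#' @inheritParams potential_energy
#' @return n x 3 force matrix, eps/nm.
#' @export
sbm_forces <- function(topology, coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) != topology$n) stop("coordinate count mismatch")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  sbm_energy_cpp(topo_arrays(topology), coords)$forces
}

#' Steepest-descent relaxation
#'
#' Simple adaptive-step gradient descent; used to verify that the native
#' conformations are minima of the (merged) potential.
#'
#' @inheritParams potential_energy
#' @param max_iter iteration budget.
#' @param step0 initial step, nm per unit force.
#' @param ftol stop when the maximum force component falls below this.
#' @return list with relaxed `coords`, final `energy`, iterations used.
#' @export
minimize_sbm <- function(topology, coords, max_iter = 500, step0 = 1e-4,
                         ftol = 1e-3) {
  x <- as.matrix(coords)
  arr <- topo_arrays(topology)
  res <- sbm_energy_cpp(arr, x)
  e <- res$total; f <- res$forces; step <- step0
  for (it in seq_len(max_iter)) {
    if (max(abs(f)) < ftol) break
    xn <- x + step * f
    rn <- sbm_energy_cpp(arr, xn)
    if (rn$total < e) {
      x <- xn; e <- rn$total; f <- rn$forces; step <- step * 1.2
    } else step <- step / 2
    if (step < 1e-10) break
  }
  list(coords = x, energy = e, iterations = it)
}

#' Write a topology in the package's sectioned text format
#'
#' Sections: `[atoms]`, `[bonds]`, `[angles]`, `[dihedrals]`, `[contacts]`,
#' `[exclusions]`; all lengths nm, angles radians, energies reduced.
#'
#' @param topology a `dual_basin_topology`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(topology, path) {
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# duobasin topology | reduced units (nm, eps, mass 1)")
  p <- topology$params
  w("[params] kb=%g ka=%g kd=%g eps=%g sigma=%g r_ex=%g r_nn=%g nn_rcut=%g",
    p$kb, p$ka, p$kd, p$eps, p$sigma, p$r_ex, p$r_nn, p$nn_rcut)
  w("[atoms] n=%d", topology$n)
  sec <- function(name, df) {
    w("[%s] n=%d", name, nrow(df))
    if (nrow(df)) utils::write.table(df, con, sep = "\t", quote = FALSE,
                                     row.names = FALSE, col.names = TRUE)
  }
  sec("bonds", topology$bonds)
  sec("angles", topology$angles)
  sec("dihedrals", topology$dihedrals)
  sec("contacts", topology$contacts)
  sec("exclusions", as.data.frame(topology$exclusions))
  invisible(path)
}
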