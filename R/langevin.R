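## Langevin dynamics in reduced units.
##
## BAOAB splitting with unit masses; gamma = 0 and T = 0 reduce the update
## to velocity Verlet, which the energy-conservation tests rely on. All
## randomness is drawn from R's RNG, so a single `seed` makes runs bitwise
## reproducible on one thread.

#' Simulation parameter set
#'
#' @param temperature reduced temperature (default 0.67; nucleic-acid
#'   native interactions start to melt near 0.75 in this class of models).
#' @param dt time step in reduced time tau (default 0.002).
#' @param gamma friction coefficient, 1/tau (default 1.0; not a quantity
#'   fixed by the model class, so absolute first-passage times scale with
#'   it).
#' @param sample_stride steps between stored frames (default 1000).
#' @param max_steps maximum number of integration steps.
#' @param stop_rmsd terminate when the best-fit RMSD of `stop_selection`
#'   against `stop_reference` falls below this, nm (default 0.5 nm = 5 A);
#'   `NULL` disables the stop criterion.
#' @param stop_selection integer atom indices monitored by the stop
#'   criterion.
#' @param stop_reference reference coordinates (nm) for the monitored
#'   selection, one row per selected atom.
#' @param seed integer RNG seed.
#' @param energy_bound abort when `|E_pot|` exceeds this (divergence guard).
#' @param nlist_stride steps between neighbor-list rebuilds.
#' @param skin neighbor-list skin, nm.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(temperature = 0.67, dt = 0.002, gamma = 1.0,
                       sample_stride = 1000L, max_steps = 5e6,
                       stop_rmsd = 0.5, stop_selection = NULL,
                       stop_reference = NULL, seed = 1L,
                       energy_bound = 1e8, nlist_stride = 20L, skin = 0.1) {
  stopifnot(dt > 0, temperature >= 0, sample_stride >= 1)
  structure(list(temperature = temperature, dt = dt, gamma = gamma,
                 sample_stride = as.integer(sample_stride),
                 max_steps = max_steps, stop_rmsd = stop_rmsd,
                 stop_selection = stop_selection,
                 stop_reference = stop_reference, seed = as.integer(seed),
                 energy_bound = energy_bound,
                 nlist_stride = as.integer(nlist_stride), skin = skin),
            class = "sim_params")
}

#' Integrate Langevin dynamics of a dual-basin topology
#'
#' @param topology a `dual_basin_topology`.
#' @param start n x 3 starting coordinates, nm.
#' @param params a [sim_params()] set.
#' @return object of class `sbm_trajectory`: `frames` (n x 3 x n_frames
#'   array, nm), `times` (tau), per-frame `epot`/`ekin`, `termination`
#'   (`"stop_rmsd"` or `"max_steps"`), `steps`, and the parameters used.
#' @export
run_langevin <- function(topology, start, params = sim_params()) {
  start <- as.matrix(start)
  if (nrow(start) != topology$n)
    stop("start coordinates do not match topology atom count")
  sel <- params$stop_selection
  ref <- params$stop_reference
  if (is.null(params$stop_rmsd) || is.null(sel) || is.null(ref)) {
    sel <- integer(0); ref <- matrix(0, 0, 3); stopr <- -1
  } else {
    ref <- as.matrix(ref)
    if (nrow(ref) != length(sel))
      stop("stop_reference rows must match stop_selection length")
    stopr <- params$stop_rmsd
  }
  res <- langevin_cpp(topo_arrays(topology), start, params$temperature,
                      params$dt, params$gamma, params$sample_stride,
                      params$max_steps, stopr, as.integer(sel), ref,
                      params$energy_bound, params$nlist_stride, params$skin,
                      as.double(params$seed))
  if (res$termination == "diverged")
    stop("energy divergence at frame ", length(res$epot),
         " (t = ", res$times[length(res$times)], " tau): |E| exceeded ",
         params$energy_bound)
  structure(list(frames = res$frames, times = res$times, epot = res$epot,
                 ekin = res$ekin, termination = res$termination,
                 steps = res$steps, params = params, n = topology$n),
            class = "sbm_trajectory")
}

#' @export
print.sbm_trajectory <- function(x, ...) {
  cat(sprintf("<sbm_trajectory> %d atoms, %d frames, t = 0..%.1f tau (%s)\n",
              x$n, length(x$times), max(x$times), x$termination))
  invisible(x)
}

#' Extract one frame of a trajectory
#' @param traj an `sbm_trajectory`.
#' @param f frame index.
#' @return n x 3 coordinate matrix, nm.
#' @export
traj_frame <- function(traj, f) traj$frames[, , f]

#' Number of frames
#' @param traj an `sbm_trajectory`.
#' @return integer.
#' @export
n_frames <- function(traj) length(traj$times)

#' Best-fit RMSD between a frame and a reference
#'
#' @param frame n x 3 coordinates.
#' @param reference matched coordinates (same unit).
#' @param idx optional atom indices restricting the comparison.
#' @return RMSD after optimal superposition, in the input unit.
#' @export
rmsd_fit <- function(frame, reference, idx = NULL) {
  frame <- as.matrix(frame); reference <- as.matrix(reference)
  if (!is.null(idx)) {
    frame <- frame[idx, , drop = FALSE]
    if (nrow(reference) != length(idx)) reference <- reference[idx, , drop = FALSE]
  }
  if (nrow(frame) != nrow(reference))
    stop("frame and reference selections have different sizes (",
         nrow(frame), " vs ", nrow(reference), ")")
  kabsch_fit(frame, reference)$rmsd
}

#' Curried RMSD monitor
#'
#' @param reference reference coordinates (full system or selection-sized).
#' @param selection atom indices of the monitored selection.
#' @return a function of one frame returning the best-fit RMSD.
#' @export
rmsd_to <- function(reference, selection = NULL) {
  if (!is.null(selection) && !length(selection)) stop("empty selection")
  force(reference)
  function(frame) rmsd_fit(frame, reference, selection)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj an `sbm_trajectory`.
#' @param model the `mol_model` the topology was built on (atom metadata).
#' @param path output path.
#' @param stride keep every `stride`-th frame.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, model, path, stride = 1L) {
  con <- file(path, "w"); on.exit(close(con))
  at <- model$atoms
  for (f in seq(1, n_frames(traj), by = stride)) {
    xyz <- traj_frame(traj, f) * A_PER_NM
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf("ATOM  %5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f",
                       at$serial %% 100000L, substr(at$name, 1, 3),
                       substr(at$resname, 1, 3), substr(at$chain, 1, 1),
                       at$resno %% 10000L, xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
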