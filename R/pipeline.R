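## Reproducible orchestration: batch simulation, manifests, and the
## desk-scale end-to-end pipeline on the synthetic two-state toy.

file_hash <- function(path) unname(tools::md5sum(path))

object_hash <- function(x) {
  f <- tempfile(); on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  file_hash(f)
}

#' Run a batch of independent Langevin simulations
#'
#' Replica `i` uses seed `base_seed + i - 1`; per-run failures are isolated
#' and reported, the batch continues. The summary supports the split-half
#' robustness convention (statistics on the first and second half of the
#' replica set).
#'
#' @param topology a `dual_basin_topology`.
#' @param start n x 3 start coordinates, nm (or a list of one per replica).
#' @param n_replicas number of runs (>= 1).
#' @param base_seed seed of the first replica.
#' @param params a [sim_params()] template (its `seed` is overridden).
#' @return list of class `sim_batch`: `trajectories` (NULL where a run
#'   failed), `summary` data.frame (replica, seed, termination, t_end,
#'   n_frames, error), and `split_half` summaries of termination times.
#' @export
batch_simulate <- function(topology, start, n_replicas, base_seed = 1L,
                           params = sim_params()) {
  stopifnot(n_replicas >= 1)
  starts <- if (is.list(start)) start else rep(list(start), n_replicas)
  stopifnot(length(starts) == n_replicas)
  trajs <- vector("list", n_replicas)
  rows <- vector("list", n_replicas)
  for (i in seq_len(n_replicas)) {
    p <- params; p$seed <- as.integer(base_seed + i - 1)
    res <- tryCatch(run_langevin(topology, starts[[i]], p),
                    error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(replica = i, seed = p$seed,
                              termination = "error", t_end = NA_real_,
                              n_frames = 0L,
                              error = conditionMessage(res))
    } else {
      trajs[[i]] <- res
      rows[[i]] <- data.frame(replica = i, seed = p$seed,
                              termination = res$termination,
                              t_end = max(res$times),
                              n_frames = n_frames(res), error = NA_character_)
    }
  }
  summary <- do.call(rbind, rows)
  half <- function(idx) {
    tt <- summary$t_end[idx][summary$termination[idx] == "stop_rmsd"]
    list(n = length(idx), n_switched = length(tt),
         median_t = if (length(tt)) stats::median(tt) else NA_real_)
  }
  n1 <- seq_len(floor(n_replicas / 2))
  structure(list(trajectories = trajs, summary = summary,
                 split_half = list(first = half(n1),
                                   second = half(setdiff(seq_len(n_replicas), n1)),
                                   full = half(seq_len(n_replicas)))),
            class = "sim_batch")
}

#' @export
print.sim_batch <- function(x, ...) {
  cat(sprintf("<sim_batch> %d replicas | terminations: %s\n",
              nrow(x$summary),
              paste(names(table(x$summary$termination)),
                    table(x$summary$termination), sep = "=", collapse = ", ")))
  invisible(x)
}

new_manifest <- function(config = list()) {
  list(created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
       package_version = as.character(utils::packageVersion("duobasin")),
       config = config, stages = list())
}

add_stage <- function(manifest, name, params = list(), outputs = character(0),
                      runtime = NA_real_) {
  hashes <- if (length(outputs)) vapply(outputs, file_hash, character(1))
  else character(0)
  manifest$stages[[name]] <- list(name = name, params = params,
                                  outputs = as.list(outputs),
                                  output_md5 = as.list(hashes),
                                  runtime_s = runtime)
  manifest
}

#' Write a run manifest as JSON
#' @param manifest a manifest list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Desk-scale end-to-end pipeline on the synthetic two-state toy
#'
#' Runs all stages on generated inputs: fixture generation, per-state
#' shadow contact maps, single-basin builds, the dual-basin merge,
#' a batch of switching simulations started from state A, and the
#' landscape/event analysis. Artifacts and a JSON manifest are written to
#' `outdir` when given.
#'
#' @param outdir output directory, or `NULL` to skip writing files.
#' @param spec a [toy_switcher_spec()].
#' @param temperature reduced simulation temperature (default 1.0, the
#'   toy's switching temperature; its end states are shallower than the
#'   full-size model's, so switching needs a higher temperature than the
#'   0.67 production value).
#' @param n_replicas replicas in the switching batch.
#' @param base_seed seed of the first replica.
#' @param max_steps integration budget per replica.
#' @param lambda formed-contact factor for the analysis.
#' @return list with the fixtures, maps, topologies (`topo_a`, `topo_b`,
#'   `dual`), the `batch`, per-replica `series` and `events`, the
#'   `landscape`, and the `manifest`.
#' @export
run_toy_pipeline <- function(outdir = NULL, spec = toy_switcher_spec(),
                             temperature = 1.0, n_replicas = 8L,
                             base_seed = 1L, max_steps = 4e5,
                             lambda = 1.2) {
  t0 <- proc.time()[3]
  manifest <- new_manifest(config = list(
    toy = unclass(spec), temperature = temperature, n_replicas = n_replicas,
    base_seed = base_seed, max_steps = max_steps, lambda = lambda))
  outfile <- function(name) if (is.null(outdir)) NULL else file.path(outdir, name)
  if (!is.null(outdir) && !dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  tick <- function() { t1 <- proc.time()[3]; dt <- t1 - t0; t0 <<- t1; dt }

  ## stage 1: fixtures
  toy <- make_two_state_toy(spec)
  outs <- character(0)
  if (!is.null(outdir)) {
    write_structure(toy$model_a, outfile("toy_state_a.pdb"))
    write_structure(toy$model_b, outfile("toy_state_b.pdb"))
    outs <- c(outfile("toy_state_a.pdb"), outfile("toy_state_b.pdb"))
  }
  manifest <- add_stage(manifest, "toy", unclass(spec), outs, tick())

  ## stages 2-3: shadow contact maps of both states, classified
  map_a <- classify_contacts(shadow_contact_map(toy$model_a), toy$groups,
                             toy$model_a)
  map_b <- classify_contacts(shadow_contact_map(toy$model_b), toy$groups,
                             toy$model_b)
  outs <- character(0)
  if (!is.null(outdir)) {
    write_contact_map(map_a, outfile("contacts_a.tsv"))
    write_contact_map(map_b, outfile("contacts_b.tsv"))
    outs <- c(outfile("contacts_a.tsv"), outfile("contacts_b.tsv"))
  }
  manifest <- add_stage(manifest, "contacts", map_a$params, outs, tick())

  ## stage 4: single-basin builds (toy force-field choice: deeper
  ## per-contact wells for the bead model, see toy_sbm_params())
  topo_a <- build_single_basin(toy$model_a, map_a, toy_sbm_params())
  topo_b <- build_single_basin(toy$model_b, map_b, toy_sbm_params())
  manifest <- add_stage(manifest, "build",
                        list(topo_a_hash = object_hash(topo_a),
                             topo_b_hash = object_hash(topo_b)),
                        character(0), tick())

  ## stage 5: dual-basin merge
  dual <- merge_dual_basin(topo_a, topo_b)
  outs <- character(0)
  if (!is.null(outdir)) {
    write_topology(dual, outfile("dual_topology.txt"))
    jsonlite::write_json(dual$divergence, outfile("divergence.json"),
                         auto_unbox = TRUE, digits = NA)
    outs <- c(outfile("dual_topology.txt"), outfile("divergence.json"))
  }
  manifest <- add_stage(manifest, "merge", dual$divergence, outs, tick())

  ## stage 6: switching simulations from state A with a stop criterion on
  ## the switch segment reaching state B
  sw_idx <- which(atoms_in_group(toy$model_a, toy$groups, "KOW"))
  params <- sim_params(temperature = temperature, dt = 0.001,
                       sample_stride = 500L,
                       max_steps = max_steps, stop_rmsd = 0.2,
                       stop_selection = sw_idx,
                       stop_reference = coords(toy$model_b, "nm")[sw_idx, ])
  batch <- batch_simulate(dual, coords(toy$model_a, "nm"), n_replicas,
                          base_seed, params)
  manifest <- add_stage(manifest, "simulate",
                        list(temperature = temperature,
                             n_replicas = n_replicas, base_seed = base_seed),
                        character(0), tick())

  ## stage 7: order parameters, landscape, events
  defs <- toy_op_defs(toy, map_a, map_b, lambda = lambda)
  ok <- !vapply(batch$trajectories, is.null, logical(1))
  series <- lapply(batch$trajectories[ok], order_parameters, defs = defs)
  events <- lapply(batch$trajectories[ok], detect_events,
                   formation = toy_strand_subsets(toy, map_b),
                   dissociation = defs$id, lambda = lambda)
  land <- landscape_histogram(series, "q_id", "q_diff",
                              xlim = c(0, 1), ylim = c(-1, 1))
  outs <- character(0)
  if (!is.null(outdir)) {
    for (i in seq_along(series))
      utils::write.table(series[[i]], outfile(sprintf("series_%02d.tsv", i)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(counts = land$counts, xbreaks = land$xbreaks,
                              ybreaks = land$ybreaks),
                         outfile("landscape.json"), digits = NA)
    outs <- c(outfile("landscape.json"))
  }
  manifest <- add_stage(manifest, "analyze", list(lambda = lambda), outs, tick())
  if (!is.null(outdir)) write_manifest(manifest, outfile("manifest.json"))

  list(toy = toy, map_a = map_a, map_b = map_b, topo_a = topo_a,
       topo_b = topo_b, dual = dual, batch = batch, series = series,
       events = events, landscape = land, defs = defs, manifest = manifest)
}

#' Order-parameter definitions for the two-state toy
#'
#' @param toy result of [make_two_state_toy()].
#' @param map_a,map_b classified contact maps of states A and B.
#' @param lambda formed-contact factor.
#' @return an [op_defs()] object: ID contacts from state A, state subsets
#'   from each state's intra-switch contacts, Delta-d referenced to the
#'   state-B (post-switch) domain distance.
#' @export
toy_op_defs <- function(toy, map_a, map_b, lambda = 1.2) {
  anchor_idx <- which(atoms_in_group(toy$model_a, toy$groups, "NGN"))
  switch_idx <- which(atoms_in_group(toy$model_a, toy$groups, "KOW"))
  id <- contacts_between(map_a, "NGN", "KOW")
  if (!nrow(id)) stop("toy state A has no interdomain contacts")
  op_defs(id = id,
          state_a = contacts_within(map_a, "KOW"),
          state_b = contacts_within(map_b, "KOW"),
          anchor_idx = anchor_idx, switch_idx = switch_idx,
          ref_active_dist = cog_dist(coords(toy$model_b, "nm"),
                                     anchor_idx, switch_idx),
          lambda = lambda)
}

#' Strand-pair contact subsets of the toy's hairpin state
#'
#' @param toy result of [make_two_state_toy()].
#' @param map_b classified contact map of state B.
#' @return named list with the cross-strand contact subset
#'   (`strand1-strand2`), the toy's analogue of a beta-strand pairing
#'   event.
#' @export
toy_strand_subsets <- function(toy, map_b) {
  ct <- contacts_within(map_b, "KOW")
  s1 <- toy$strands$strand1; s2 <- toy$strands$strand2
  cross <- ct[(ct$i %in% s1 & ct$j %in% s2) | (ct$i %in% s2 & ct$j %in% s1), ,
              drop = FALSE]
  if (!nrow(cross)) stop("toy state B has no cross-strand contacts")
  list(`strand1-strand2` = cross)
}
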