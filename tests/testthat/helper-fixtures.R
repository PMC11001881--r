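## Shared fixtures and independent oracles, all built in code.

## minimal hand-written PDB text (3 atoms, two chains)
tiny_pdb_text <- function() {
  c("TITLE     three-atom fixture",
    "ATOM      1  CA  GLY A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       4.500   2.000   3.000  1.00  0.00           C",
    "ATOM      3  C1' DA  B   1       1.000   6.500   3.000  1.00  0.00           C",
    "END")
}

write_tiny_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(tiny_pdb_text(), path)
  path
}

## bead chain along a helix (single-atom residues, chain "A")
bead_chain_model <- function(n, seed = 1, jitter = 0.1) {
  set.seed(seed)
  k <- seq_len(n) - 1
  th <- (100 * k) * pi / 180
  xyz <- cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * k) +
    matrix(stats::runif(3 * n, -jitter, jitter), n, 3)
  mol_model(data.frame(serial = seq_len(n), name = "CA", elem = "C",
                       resname = "GLY", resno = seq_len(n), ins = "",
                       chain = "A", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                       stringsAsFactors = FALSE))
}

## random protein-bead cloud with inter-atom spacing kept off-degenerate
random_cloud_model <- function(n, seed, box = 12) {
  set.seed(seed)
  repeat {
    xyz <- matrix(stats::runif(3 * n, 0, box), n, 3)
    if (min(stats::dist(xyz)) > 0.8) break
  }
  mol_model(data.frame(serial = seq_len(n), name = "CA", elem = "C",
                       resname = "GLY", resno = seq_len(n), ins = "",
                       chain = rep(c("A", "B"), length.out = n),
                       x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                       stringsAsFactors = FALSE),
            bonds = matrix(integer(0), ncol = 2))
}

## Brute-force shadow-map oracle: candidate pairs by distance + sequence
## separation + bonded exclusion, occlusion decided by dense sampling of
## points along the segment against every third-atom sphere whose centre
## projects strictly between the endpoints.
shadow_oracle <- function(model, cutoff = 0.6, shadow_radius = 0.1,
                          min_seq_sep_protein = 3, min_seq_sep_nucleic = 0,
                          n_samples = 400) {
  xyz <- coords(model, "nm")
  at <- model$atoms
  n <- nrow(xyz)
  excl <- duobasin:::graph_pairs_within(model$bonds, n, k = 2)
  exkey <- if (nrow(excl)) paste(excl[, 1], excl[, 2]) else character(0)
  occ <- 2 * shadow_radius
  out <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- xyz[j, ] - xyz[i, ]
    dist_ij <- sqrt(sum(d^2))
    if (dist_ij > cutoff) next
    if (paste(i, j) %in% exkey) next
    if (at$chain[i] == at$chain[j]) {
      prot <- at$class[i] == "protein" && at$class[j] == "protein"
      need <- if (prot) min_seq_sep_protein else min_seq_sep_nucleic
      if (abs(at$resno[i] - at$resno[j]) < need) next
    }
    blocked <- FALSE
    ts <- seq(0, 1, length.out = n_samples + 2)[-c(1, n_samples + 2)]
    for (k in seq_len(n)) {
      if (k == i || k == j) next
      tk <- sum((xyz[k, ] - xyz[i, ]) * d) / dist_ij^2
      if (tk <= 0 || tk >= 1) next
      pts <- outer(ts, d) + rep(xyz[i, ], each = length(ts))
      if (min(sqrt(rowSums((pts - rep(xyz[k, ], each = length(ts)))^2))) < occ) {
        blocked <- TRUE; break
      }
    }
    if (!blocked) out[[length(out) + 1]] <- c(i, j)
  }
  if (!length(out)) matrix(integer(0), ncol = 2) else do.call(rbind, out)
}

## toy + maps + merged dual-basin topology, cached per test session
toy_system <- local({
  cache <- NULL
  function(params = sbm_params()) {
    key <- paste(unlist(params), collapse = "|")
    if (!is.null(cache) && cache$key == key) return(cache$value)
    toy <- make_two_state_toy()
    map_a <- classify_contacts(shadow_contact_map(toy$model_a), toy$groups,
                               toy$model_a)
    map_b <- classify_contacts(shadow_contact_map(toy$model_b), toy$groups,
                               toy$model_b)
    topo_a <- build_single_basin(toy$model_a, map_a, params)
    topo_b <- build_single_basin(toy$model_b, map_b, params)
    dual <- merge_dual_basin(topo_a, topo_b)
    value <- list(toy = toy, map_a = map_a, map_b = map_b,
                  topo_a = topo_a, topo_b = topo_b, dual = dual,
                  xa = coords(toy$model_a, "nm"),
                  xb = coords(toy$model_b, "nm"))
    cache <<- list(key = key, value = value)
    value
  }
})

## one shared 20-replica switching campaign at the toy's switching
## temperature, computed once per test session
switching_campaign <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    res <- run_toy_pipeline(n_replicas = 20, temperature = 1.0,
                            base_seed = 1, max_steps = 1.5e6)
    stats <- switching_order_stats(
      res$series, res$events,
      res$batch$summary$termination[!is.na(res$batch$summary$t_end)])
    cache <<- list(res = res, stats = stats)
    cache
  }
})

## in-test Kabsch, kept independent of the package implementation
oracle_kabsch_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  s <- svd(crossprod(Pc, Qc))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((Pc %*% R - Qc)^2)))
}
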