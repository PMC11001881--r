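## Small numerical helpers shared across modules.

wrap_pi <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  a[a == -pi] <- pi
  a
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising
#' `||P %*% R + t - Q||` over matched rows; reflections are rejected by
#' construction (`det(R) = +1`).
#'
#' @param P,Q matched n x 3 coordinate matrices (mobile, target).
#' @return list with `R` (3 x 3), `t` (length 3), `rmsd` (same unit as the
#'   inputs).
#' @export
kabsch_fit <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  stopifnot(ncol(P) == 3, nrow(P) == nrow(Q))
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  E <- Pc %*% R - Qc
  list(R = R, t = as.numeric(cq - cp %*% R),
       rmsd = sqrt(mean(rowSums(E^2))))
}

## per-row dihedral angle (radians) for four n x 3 matrices
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  m <- cr(b1, b2); nv <- cr(b2, b3)
  rb2 <- sqrt(rowSums(b2^2))
  atan2(rowSums(cr(m, nv) * b2) / rb2, rowSums(m * nv))
}

## per-row angle (radians) at vertex j for three n x 3 matrices
bend_angle <- function(pi_, pj, pk) {
  u <- pi_ - pj; w <- pk - pj
  c <- rowSums(u * w) / (sqrt(rowSums(u^2)) * sqrt(rowSums(w^2)))
  acos(pmax(-1, pmin(1, c)))
}

## all unordered atom pairs with bond-graph distance <= k (matrix, i < j)
graph_pairs_within <- function(bonds, n, k = 3) {
  adj <- vector("list", n)
  if (nrow(bonds)) for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1]; j <- bonds[r, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  out <- vector("list", n)
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n); dist[s] <- 0L
    frontier <- s
    for (d in seq_len(k)) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[is.na(dist[nxt])]
      if (!length(nxt)) break
      dist[nxt] <- d
      frontier <- nxt
    }
    reach <- which(!is.na(dist) & seq_len(n) > s)
    if (length(reach)) out[[s]] <- cbind(s, reach)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) matrix(integer(0), ncol = 2) else res
}

rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
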