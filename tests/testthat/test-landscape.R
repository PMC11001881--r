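fake_traj <- function(frames, dt = 1) {
  n <- nrow(frames[[1]])
  arr <- array(0, c(n, 3, length(frames)))
  for (f in seq_along(frames)) arr[, , f] <- frames[[f]]
  list(frames = arr, times = (seq_along(frames) - 1) * dt,
       epot = rep(0, length(frames)), ekin = rep(0, length(frames)),
       termination = "max_steps", n = n)
}

test_that("q_fraction counts formed contacts under the lambda criterion", {
  ## 4 contacts at r0 = 0.5; construct a frame with exactly 3 formed
  x <- rbind(c(0, 0, 0), c(0.5, 0, 0), c(0, 1, 0), c(0.5, 1, 0),
             c(0, 2, 0), c(0.5, 2, 0), c(0, 3, 0), c(2.0, 3, 0))
  ct <- data.frame(i = c(1, 3, 5, 7), j = c(2, 4, 6, 8), r0 = 0.5)
  expect_equal(q_fraction(x, ct), 0.75)
  ## native frame scores 1, blown-apart frame scores 0
  xf <- x; xf[c(2, 4, 6, 8), 1] <- 0.5
  expect_equal(q_fraction(xf, ct), 1)
  expect_equal(q_fraction(x * 10, ct), 0)
  expect_error(q_fraction(x, ct[0, ]), "empty contact set")
})

test_that("Q decreases monotonically under uniform expansion", {
  sys <- toy_system()
  ct <- contacts_within(sys$map_a, "KOW")
  qs <- vapply(c(1, 1.1, 1.25, 1.5, 2), function(sc)
    q_fraction(sys$xa * sc, ct), numeric(1))
  expect_true(all(diff(qs) <= 0))
  expect_equal(qs[1], 1)
})

test_that("order parameters on a frozen native trajectory are at their bounds", {
  sys <- toy_system()
  defs <- toy_op_defs(sys$toy, sys$map_a, sys$map_b)
  tr <- fake_traj(list(sys$xa, sys$xa, sys$xa))
  s <- order_parameters(tr, defs)
  expect_equal(s$q_a, rep(1, 3))
  expect_equal(s$q_id, rep(1, 3))
  expect_true(all(s$q_diff <= 0))
  expect_equal(length(unique(round(s$q_diff, 12))), 1)
  expect_true(all(s$q_id >= 0 & s$q_id <= 1))
  expect_true(all(s$q_diff >= -1 & s$q_diff <= 1))
})

test_that("order parameters equal direct per-contact counting on built frames", {
  sys <- toy_system()
  defs <- toy_op_defs(sys$toy, sys$map_a, sys$map_b)
  tr <- fake_traj(list(sys$xa, sys$xb))
  s <- order_parameters(tr, defs)
  count_q <- function(x, ct) {
    d <- sqrt(rowSums((x[ct$i, ] - x[ct$j, ])^2))
    sum(d < 1.2 * ct$r0) / nrow(ct)
  }
  for (f in 1:2) {
    x <- tr$frames[, , f]
    expect_equal(s$q_id[f], count_q(x, defs$id))
    expect_equal(s$q_a[f], count_q(x, defs$state_a))
    expect_equal(s$q_b[f], count_q(x, defs$state_b))
  }
  ## delta-d is zero at the reference (state B) conformation
  expect_equal(s$delta_d[2], 0, tolerance = 1e-12)
})

test_that("landscape histograms conserve frame counts", {
  sys <- toy_system()
  defs <- toy_op_defs(sys$toy, sys$map_a, sys$map_b)
  s1 <- order_parameters(fake_traj(list(sys$xa)), defs)
  h1 <- landscape_histogram(s1, "q_id", "q_diff", bins = 10)
  expect_equal(sum(h1$counts), 1)
  expect_equal(max(h1$counts), 1)
  s2 <- order_parameters(fake_traj(list(sys$xa, sys$xb, sys$xb)), defs)
  h <- landscape_histogram(list(s1, s2), bins = 13)
  expect_equal(sum(h$counts), 4)
  ## concatenation order does not matter
  h2 <- landscape_histogram(list(s2, s1), bins = 13,
                            xlim = range(h$xbreaks), ylim = range(h$ybreaks))
  h3 <- landscape_histogram(list(s1, s2), bins = 13,
                            xlim = range(h$xbreaks), ylim = range(h$ybreaks))
  expect_equal(h2$counts, h3$counts)
  expect_error(landscape_histogram(list()), "empty")
})

test_that("contact probabilities are 1 inside a pure native-state window", {
  sys <- toy_system()
  defs <- toy_op_defs(sys$toy, sys$map_a, sys$map_b)
  tr <- fake_traj(list(sys$xa, sys$xa))
  s <- order_parameters(tr, defs)
  win <- state_window("alpha", "q_a", c(0.9, 1), "q_id", c(0.9, 1))
  layers <- list(alpha = contact_residue_pairs(defs$state_a, sys$map_a$atoms))
  pm <- contact_probability_map(tr, s, win, layers)
  expect_true(all(pm$alpha$prob == 1))
  ## probabilities stay within [0, 1] on mixed frames
  tr2 <- fake_traj(list(sys$xa, sys$xb))
  s2 <- order_parameters(tr2, defs)
  win2 <- state_window("all", "q_a", c(0, 1), "q_id", c(0, 1))
  pm2 <- contact_probability_map(tr2, s2, win2, layers)
  expect_true(all(pm2$alpha$prob >= 0 & pm2$alpha$prob <= 1))
  win3 <- state_window("nowhere", "q_a", c(2, 3), "q_id", c(2, 3))
  expect_error(contact_probability_map(tr2, s2, win3, layers), "nowhere")
})

test_that("events fire at the first threshold crossing or not at all", {
  ## two atoms approach each other frame by frame: contact forms at a
  ## known frame
  mk <- function(dists) fake_traj(lapply(dists, function(d)
    rbind(c(0, 0, 0), c(d, 0, 0))), dt = 2)
  ct <- data.frame(i = 1, j = 2, r0 = 0.5)
  tr <- mk(c(2, 1.5, 1.0, 0.55, 0.5))
  ev <- detect_events(tr, formation = list(pair = ct),
                      formation_threshold = 0.75)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$frame, 4)       # 0.55 < 1.2 * 0.5 first at frame 4
  expect_equal(ev$time, 6)        # sampled times start at 0, dt = 2
  none <- detect_events(mk(c(2, 1.9, 1.8)), formation = list(pair = ct))
  expect_equal(nrow(none), 0)
  ## dissociation event: fraction drops below threshold
  tr2 <- mk(c(0.5, 0.5, 2, 2))
  ev2 <- detect_events(tr2, dissociation = ct, dissociation_threshold = 0.3)
  expect_equal(ev2$event, "dissociation")
  expect_equal(ev2$frame, 3)
})

test_that("first-passage histograms conserve event counts", {
  expect_equal(sum(first_passage_histogram(c(5, 5, 5),
                                           breaks = c(0, 10, 20))$counts), 3)
  expect_equal(first_passage_histogram(c(5, 5, 5),
                                       breaks = c(0, 10, 20))$counts, c(3, 0))
  expect_true(all(first_passage_histogram(numeric(0))$counts == 0))
  set.seed(14)
  tt <- runif(57, 0, 100)
  h <- first_passage_histogram(tt, breaks = seq(0, 100, by = 7.5))
  expect_equal(sum(h$counts), sum(tt < max(seq(0, 100, by = 7.5))))
})
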