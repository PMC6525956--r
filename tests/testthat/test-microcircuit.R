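# Network builders, STP-gated current, LIF integration, direction steps.

test_that("the six-unit build is bidirectional with dense within-subpop cliques", {
  net <- build_six_unit()
  w <- net$w
  expect_equal(dim(w), c(6L, 6L))
  expect_identical(w, t(w))                       # bidirectional
  expect_true(all(diag(w) == 1L))                 # self-connections allowed
  expect_equal(sum(w[1:3, 1:3]), 9L)              # 9 within-links per subpop
  expect_equal(sum(w[4:6, 4:6]), 9L)
  same <- outer(net$labels, net$labels, "==")
  expect_gt(sum(w[same]), sum(w[!same]))          # within > between

  # no cross links: two disconnected cliques
  iso <- build_six_unit(cross_links = matrix(numeric(0), ncol = 2))
  expect_equal(sum(iso$w[1:3, 4:6]), 0L)

  expect_error(build_six_unit(matrix(c(1, 2), ncol = 2)), "same subpopulation")
  expect_error(build_six_unit(matrix(c(1, 7), ncol = 2)), "range")
})

test_that("the two-unit build is the all-ones pair", {
  net <- build_two_unit()
  expect_equal(unclass(net$w), matrix(1L, 2, 2))
  expect_equal(net$labels, c(1L, 2L))
  expect_identical(net$w[1, ], net$w[2, ])        # identical summed input rows
})

test_that("the STP-gated current is the gain-scaled efficacy sum", {
  expect_equal(compute_current(c(1, 1, 0), c(0, 0, 0.7), A = 0.039), 0)
  expect_equal(compute_current(c(1, 0), c(0.5, 0.9), A = 0.039), 0.0195)
  expect_equal(compute_current(c(1, 1), c(0.3, 0.2), A = 0.078),
               2 * compute_current(c(1, 1), c(0.3, 0.2), A = 0.039))
  expect_error(compute_current(c(1, 0), c(0.5), A = 1), "equal length")
})

test_that("LIF units rest, relax, spike and respect refractoriness", {
  p <- lif_params()
  rest <- list(V = p$V_rest, refractory_remaining = 0)
  # zero current at rest: fixed point
  s <- lif_step(rest, p, I = 0)
  expect_equal(s$state$V, p$V_rest)
  expect_false(s$spiked)
  # depolarized with no current: monotone relaxation towards rest
  V <- -60
  for (k in 1:50) {
    nxt <- lif_step(list(V = V, refractory_remaining = 0), p, I = 0)
    expect_lt(nxt$state$V, V)
    expect_gt(nxt$state$V, p$V_rest - 1e-12)
    V <- nxt$state$V
  }
  # suprathreshold current: spike, reset, refractory hold
  I_big <- (p$theta - p$V_rest + 20) / p$R_m
  st <- rest
  for (k in 1:200) {
    out <- lif_step(st, p, I_big)
    st <- out$state
    if (out$spiked) break
  }
  expect_true(out$spiked)
  expect_equal(st$V, p$V_rest)
  expect_equal(st$refractory_remaining, p$tau_arp)
  held <- lif_step(st, p, I_big)
  expect_false(held$spiked)
  expect_equal(held$state$V, p$V_rest)
  expect_equal(held$state$refractory_remaining, p$tau_arp - p$dt)
})

test_that("constant-current firing period matches the analytic LIF formula", {
  p <- lif_params()
  # one representative suprathreshold current (the acceptance suite sweeps a grid)
  delta <- 8
  I <- (p$theta - p$V_rest + delta) / p$R_m
  st <- list(V = p$V_rest, refractory_remaining = 0)
  spikes <- c()
  for (k in 1:300) {
    out <- lif_step(st, p, I)
    st <- out$state
    if (out$spiked) spikes <- c(spikes, k * p$dt)
  }
  V_inf <- p$V_rest + p$R_m * I
  period <- p$tau_arp + p$tau_m * log((V_inf - p$V_rest) / (V_inf - p$theta))
  expect_true(all(abs(diff(spikes) - period) <= p$dt))
})

test_that("a zero frame elicits no spikes and the membrane stays subthreshold", {
  net <- build_six_unit()
  zero <- matrix(0L, 6, 1000)
  res <- run_direction_step(net, lif_params(), stp_params(), zero,
                            u_pair = c(0.6, 0.05))
  expect_true(all(res$counts == 0L))
  expect_true(all(res$V_trace < lif_params()$theta))
  # the synapses idle at rest (u = U, x = 1) ...
  expect_true(all(abs(res$x_trace - 1) < 1e-12))
  expect_equal(res$u_trace[, 1000], c(0.6, 0.6, 0.6, 0.05, 0.05, 0.05))
  # ... which sustains a constant subthreshold depolarization A * Rm * sum(w) * U
  p <- lif_params(); stp <- stp_params()
  V_ss <- p$V_rest + p$R_m * stp$A * (3 * 0.6)   # units 1-2: three U=0.6 inputs
  expect_equal(res$V_trace[1, 1000], V_ss, tolerance = 1e-3)
})

test_that("the two-unit circuit is perfectly synchronous", {
  net <- build_two_unit()
  stp <- stp_params(A = 0.078)   # doubled gain of the two-unit circuit
  f <- make_bar_frame(100, 10)
  res <- run_direction_step(net, lif_params(), stp, f, u_pair = c(0.6, 0.05))
  expect_gt(res$counts[1], 0)                      # it does fire
  expect_identical(res$raster[[1]], res$raster[[2]])
  # identical summed inputs: currents agree at every sample
  expect_equal(res$I_trace[1, ], res$I_trace[2, ])
})

test_that("higher release probability drives higher rates within a step", {
  net <- build_six_unit()
  f <- make_bar_frame(100, 10)                     # identical rows
  res <- run_direction_step(net, lif_params(), stp_params(), f,
                            u_pair = c(0.6, 0.05))
  r1 <- res$counts[1:3]; r2 <- res$counts[4:6]
  expect_true(all(outer(r1, r2, ">=")))            # every subpop-1 unit >= every subpop-2 unit
  expect_gt(mean(r1), mean(r2))
})

test_that("refractoriness and the threshold bound hold across a full step", {
  net <- build_six_unit()
  p <- lif_params()
  f <- make_bar_frame(0, 10)
  res <- run_direction_step(net, p, stp_params(), f, u_pair = c(0.6, 0.4))
  expect_gt(sum(res$counts), 0)
  for (ts in res$raster) {
    if (length(ts) > 1) expect_true(all(diff(ts) >= p$tau_arp))
  }
  expect_true(all(res$V_trace < p$theta))
  expect_true(all(res$I_trace >= 0))
})

test_that("experiments are deterministic and respect sequence structure", {
  net <- build_six_unit()
  s <- make_direction_sequence(n_steps = 4)
  e1 <- run_experiment(net, lif_params(), stp_params(), s)
  e2 <- run_experiment(net, lif_params(), stp_params(), s)
  expect_identical(lapply(e1$steps, `[[`, "raster"),
                   lapply(e2$steps, `[[`, "raster"))
  expect_equal(length(e1$steps), 4L)

  empty <- structure(list(frames = list(), directions = character(0),
                          u_pairs = matrix(numeric(0), ncol = 2),
                          step_duration = 1000),
                     class = "direction_sequence")
  expect_equal(length(run_experiment(net, lif_params(), stp_params(), empty)$steps), 0L)
})

test_that("carry-over mode propagates synaptic state across steps", {
  net <- build_six_unit()
  s <- make_direction_sequence(n_steps = 2)
  reset <- run_experiment(net, lif_params(), stp_params(), s,
                          keep_traces = TRUE)
  carry <- run_experiment(net, lif_params(), stp_params(), s,
                          keep_traces = TRUE, carry_over_state = TRUE)
  # step 1 is identical; step 2 differs because (u, x, V) carry over
  expect_identical(reset$steps[[1]]$raster, carry$steps[[1]]$raster)
  expect_false(isTRUE(all.equal(reset$steps[[2]]$u_trace[, 1],
                                carry$steps[[2]]$u_trace[, 1])))
})

test_that("frame/network shape mismatches are rejected", {
  net <- build_six_unit()
  expect_error(run_direction_step(net, lif_params(), stp_params(),
                                  matrix(0L, 4, 1000), c(0.5, 0.5)),
               "4 rows")
  expect_error(run_direction_step(net, lif_params(), stp_params(),
                                  matrix(0L, 6, 500), c(0.5, 0.5)),
               "step duration")
  # a 6-row frame feeds the two-unit build through its first two rows
  two <- run_direction_step(build_two_unit(), lif_params(),
                            stp_params(A = 0.078), make_bar_frame(0, 10),
                            c(0.6, 0.05))
  expect_equal(length(two$raster), 2L)
})
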