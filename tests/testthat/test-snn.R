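test_that("network capacity and connection bounds are enforced", {
  set.seed(1)
  conn <- data.frame(source = sample(0:255, 2000, replace = TRUE),
                     target = sample(0:255, 2000, replace = TRUE),
                     weight_uv = sample(-5000:5000, 2000, replace = TRUE))
  g <- snn_globals(10, 45000, 60000, 0, 0, 1000)
  expect_s3_class(snn_network(256, g, conn), "snn_network")
  expect_error(snn_network(257, g, conn), "n_units")
  expect_error(snn_network(16, g, rbind(conn, conn[1, ])), "2000")
  expect_error(snn_network(16, g,
                           data.frame(source = -9, target = 0, weight_uv = 1)),
               "-1\\.\\.-8")
  expect_error(snn_globals(36, 45000, 60000, 0, 0, 1000), "3.5 ms")
  expect_error(snn_globals(1, 70000, 60000, 0, 0, 1000), "Q16")
})

test_that("fixed-point decay keeps the most significant 16 bits with floor", {
  expect_equal(decay_fixed_point(16384, 32768), 8192)
  expect_equal(decay_fixed_point(-16384, 32768), -8192)
  expect_equal(decay_fixed_point(16384, 65535), 16383)
  expect_equal(decay_fixed_point(123, 0), 0)
  # floor toward -inf, not truncation toward zero
  expect_equal(decay_fixed_point(-1, 32768), -1)
  expect_equal(decay_fixed_point(1, 32768), 0)
})

test_that("a single PSP drives the slow-fast difference over threshold one step later", {
  g <- snn_globals(1, fast_decay = 32768, slow_decay = 58982,
                   bias_chance = 0, threshold_uv = 300)
  net <- snn_network(1, g, data.frame(source = -1, target = 0,
                                      weight_uv = 1000))
  st <- snn_state(net)
  r1 <- step_network(net, st, c(TRUE, rep(FALSE, 7)))  # weight arrives
  expect_equal(r1$state$v_fast, 1000)
  expect_equal(r1$state$v_slow, 1000)
  expect_length(r1$fired, 0)                           # diff 0, no spike
  r2 <- step_network(net, r1$state, logical(8))
  # decayed: fast 500, slow floor(1000*58982/65536) = 900, diff 400 > 300
  expect_equal(r2$fired, 0L)
  expect_equal(r2$state$v_fast, 0)                     # reset on firing
  expect_equal(r2$state$v_slow, 0)
})

test_that("sub-threshold input and silent networks never spike", {
  g <- snn_globals(1, 32768, 58982, 0, 0, 300)
  net <- snn_network(1, g, data.frame(source = -1, target = 0,
                                      weight_uv = 400))
  # closed-form max of slow-fast for one PSP of weight W: max over k of
  # W*(floor-decayed slow_k - fast_k); with W=400 the peak diff is < 300
  r <- run_network(net, 200,
                   ext_spikes = rbind(c(TRUE, rep(FALSE, 7)),
                                      matrix(FALSE, 199, 8)))
  expect_equal(nrow(r$raster), 0)
  silent <- snn_network(8, snn_globals(1, 32768, 58982, 0, 0, 300),
                        data.frame(source = 0, target = 1, weight_uv = 0))
  r2 <- run_network(silent, 500,
                    ext_spikes = matrix(TRUE, 500, 8))
  expect_equal(nrow(r2$raster), 0)
})

test_that("the int16 engine matches the scalar reference implementation state-for-state", {
  for (seed in 1:3) {
    net <- random_net(n_units = 12, n_conn = 40, seed = seed,
                      bias_chance = 5000, delay = 1 + seed)
    set.seed(seed + 100)
    n_steps <- 400
    ext <- matrix(runif(n_steps * 8) < 0.01, n_steps, 8)
    got <- run_network(net, n_steps, ext, seed = seed)
    ref <- snn_reference_run(net, n_steps, ext, seed = seed)
    expect_equal(got$raster, ref$raster, info = paste("seed", seed))
    expect_equal(got$state$v_fast, ref$v_fast)
    expect_equal(got$state$v_slow, ref$v_slow)
  }
})

test_that("same seed reproduces the spike raster exactly", {
  net <- random_net(bias_chance = 8000)
  r1 <- run_network(net, 1000, seed = 11)
  r2 <- run_network(net, 1000, seed = 11)
  expect_identical(r1$raster, r2$raster)
  r3 <- run_network(net, 1000, seed = 12)
  expect_false(identical(r1$raster, r3$raster))
})

test_that("potentials superpose below threshold with bias off", {
  # power-of-two weights and halving decays keep the floor-rounded decay
  # exactly linear, so superposition holds to the last bit
  g <- snn_globals(1, 32768, 32768, 0, 0, 30000)  # high threshold: no firing
  net <- snn_network(1, g, data.frame(source = c(-1, -2), target = c(0, 0),
                                      weight_uv = c(4096, 8192)))
  n_steps <- 50
  both <- matrix(FALSE, n_steps, 8); both[10, 1] <- TRUE; both[10, 2] <- TRUE
  only1 <- matrix(FALSE, n_steps, 8); only1[10, 1] <- TRUE
  only2 <- matrix(FALSE, n_steps, 8); only2[10, 2] <- TRUE
  vb <- run_network(net, n_steps, both)$state
  v1 <- run_network(net, n_steps, only1)$state
  v2 <- run_network(net, n_steps, only2)$state
  expect_equal(vb$v_fast, v1$v_fast + v2$v_fast)
  expect_equal(vb$v_slow, v1$v_slow + v2$v_slow)
})

test_that("one simulated second is exactly 10,000 network updates", {
  tb <- timebase()
  expect_equal(s_to_ticks(1, tb) / tb$snn_step_ticks, 10000)
  net <- snn_network(1, snn_globals(1, 32768, 58982, 0, 0, 300),
                     data.frame(source = -1, target = 0, weight_uv = 10))
  r <- run_network(net, 10000)
  expect_equal(r$state$step, 10000)
})

test_that("generator events route to the next step boundary and spikes back out", {
  ev <- event_records(105, 0, "digital_event")   # tick 105, step ticks 10
  flags <- route_io(ev, n_steps = 20)
  expect_true(flags[12, 1])                      # 0-based step 11
  expect_equal(sum(flags), 1)
  expect_equal(sum(route_io(event_records(), 20)), 0)
  expect_error(route_io(event_records(10, 9, "digital_event"), 20),
               "generator id")
  rr <- raster_to_records(data.frame(step = c(5, 5, 6), unit = c(3, 12, 20)))
  expect_equal(nrow(rr$records), 2)              # units 0-15 recorded
  expect_equal(rr$activations$source, 3)         # units 0-7 activate generators
  expect_equal(rr$activations$timestamp, 50)
})
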