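test_that("network files load, round-trip and validate", {
  net <- toy_network()
  expect_s3_class(net, "network_definition")
  expect_equal(nrow(net$nodes), 3L)
  expect_equal(nrow(net$links), 2L)
  expect_equal(net$death_readout, "Z")

  # round trip through the sectioned text format
  tf <- tempfile(fileext = ".net")
  write_network(net, tf)
  net2 <- load_network(tf)
  expect_equal(net2$nodes, net$nodes)
  expect_equal(net2$links, net$links)
  expect_equal(net2$W, net$W)

  p53 <- p53_network()
  expect_equal(nrow(p53$nodes), 16L)
  expect_equal(p53$death_readout, "CASP3")

  # schema violations are rejected with named offenders
  bad_link <- write_net_tempfile(c(
    "[nodes]", "name\tbasal\trole", "X\t1\tinternal", "Z\t0\toutput",
    "[links]", "source\ttarget\tweight", "Q\tZ\t1",
    "[metadata]", "death_readout\tZ"))
  expect_error(load_network(bad_link), "Q", class = "therawin_schema_error")

  zero_w <- write_net_tempfile(c(
    "[nodes]", "name\tbasal\trole", "X\t1\tinternal", "Z\t0\toutput",
    "[links]", "source\ttarget\tweight", "X\tZ\t0",
    "[metadata]", "death_readout\tZ"))
  expect_error(load_network(zero_w), "weight", class = "therawin_schema_error")

  no_out <- write_net_tempfile(c(
    "[nodes]", "name\tbasal\trole", "X\t1\tinternal", "Z\t0\toutput",
    "[links]", "source\ttarget\tweight", "X\tZ\t1",
    "[metadata]", "version\t1"))
  expect_error(load_network(no_out), "death_readout",
               class = "therawin_schema_error")

  expect_error(load_network(tempfile()), "not found",
               class = "therawin_schema_error")
})

test_that("synchronous weighted-sum step matches hand evaluation", {
  net <- toy_network()
  ctrl <- control_profile(net)
  s <- c(X = 1, Y = 0, Z = 0)

  nxt <- step(net, ctrl, s)
  expect_equal(nxt[["Z"]], 1)          # sum 1 + 0 + 0 > 0
  expect_equal(nxt[["X"]], 1)          # basal 1 keeps X on

  nxt <- step(net, ctrl, s, suppressed_links = data.frame(source = "X", target = "Z"))
  expect_equal(nxt[["Z"]], 0)          # suppressed link contributes 0

  # forcing rule: a suppressed node is 0 in the successor, from any state
  for (bits in list(c(1, 1, 1), c(0, 1, 0), c(1, 0, 1))) {
    s2 <- stats::setNames(bits, c("X", "Y", "Z"))
    expect_equal(step(net, ctrl, s2, suppressed_nodes = "X")[["X"]], 0)
  }

  # clamps win over logic
  profA <- status_profile(net, c(Y = "A"))
  expect_equal(step(net, profA, s)[["Y"]], 1)
  expect_equal(step(net, profA, s)[["Z"]], 1)  # X - Y = 0 at next state? no:
  # note Z sees the *current* state (Y = 0), so Z still turns on this step
})

test_that("simulate reaches the toy fixed point and honors schedules", {
  net <- toy_network()
  ctrl <- control_profile(net)
  cfg <- sim_config()

  res <- simulate(net, ctrl, c(X = 0, Y = 1, Z = 0), cfg)
  expect_s3_class(res, "simulation_result")
  expect_equal(unname(res$activity["Z"]), 1)
  expect_true(res$death)

  # suppressing X at every step silences Z
  pert <- perturbation(target_node("X"), dose = 0.5)
  sched <- matrix(TRUE, cfg$transient_steps + cfg$steady_steps, 1L)
  res <- simulate(net, ctrl, c(X = 1, Y = 0, Z = 1), cfg, perturbation = pert,
                  schedule = sched)
  expect_equal(unname(res$activity["Z"]), 0)
  expect_false(res$death)

  expect_error(
    simulate(net, ctrl, c(X = 1, Y = 0, Z = 1), cfg, perturbation = pert,
             schedule = matrix(TRUE, 5L, 1L)),
    "schedule", class = "therawin_schema_error")
})

test_that("initial-state enumeration respects clamps, order and the cap", {
  net <- toy_network()
  cfg <- sim_config()

  st <- enumerate_initial_states(net, control_profile(net), cfg)
  expect_equal(nrow(st), 8L)
  expect_equal(ncol(st), 3L)
  # binary counting, first free node fastest
  expect_equal(unname(st[, "X"]), rep(c(0, 1), 4))
  expect_equal(nrow(unique(st)), 8L)

  stA <- enumerate_initial_states(net, status_profile(net, c(X = "A")), cfg)
  expect_equal(nrow(stA), 4L)
  expect_true(all(stA[, "X"] == 1))

  p53 <- p53_network()
  stp <- enumerate_initial_states(p53, control_profile(p53), p53_cfg_on())
  expect_equal(nrow(stp), 2^15)
  expect_true(all(stp[, "DNA_damage"] == 1))

  cfg_small <- sim_config(enumeration_cap = 2L)
  expect_error(enumerate_initial_states(net, control_profile(net), cfg_small),
               "sample", class = "therawin_enumeration_error")
  cfg_sampled <- sim_config(enumeration_cap = 2L, sample_states = 5L)
  expect_equal(nrow(enumerate_initial_states(net, control_profile(net), cfg_sampled)), 5L)
})

test_that("basin of apoptosis matches the attractor landscape", {
  net <- toy_network()
  cfg <- sim_config()
  expect_equal(basin_of_apoptosis(net, control_profile(net), cfg), 1)
  expect_equal(basin_of_apoptosis(net, status_profile(net, c(X = "I")), cfg), 0)
  # deterministic: repeated evaluation is identical
  prof <- status_profile(net, c(Y = "A"))
  expect_identical(basin_of_apoptosis(net, prof, cfg),
                   basin_of_apoptosis(net, prof, cfg))
  # memory network: basin = 1 - 2^-k exactly
  expect_equal(basin_of_apoptosis(memory_net(1L), control_profile(memory_net(1L)), cfg), 0.5)
  expect_equal(basin_of_apoptosis(memory_net(2L), control_profile(memory_net(2L)), cfg), 0.75)
})

test_that("ergodic sets span the perturbed and unperturbed attractor", {
  net <- toy_network()
  ctrl <- control_profile(net)
  cfg <- sim_config(seed = 7L)

  # dose 0: the deterministic fixed point only
  es <- ergodic_set(net, ctrl, perturbation(target_node("X"), 0), c(X = 0, Y = 0, Z = 0), cfg)
  expect_equal(nrow(es), 1L)
  expect_equal(unname(es[1L, ]), c(1, 0, 1))

  # dose 1: every member state has the suppressed bit OFF
  es1 <- ergodic_set(net, ctrl, perturbation(target_node("X"), 1), c(X = 1, Y = 0, Z = 1), cfg)
  expect_true(all(es1[, "X"] == 0))

  # intermediate dose: both death-readout values are visited
  es5 <- ergodic_set(net, ctrl, perturbation(target_node("X"), 0.5), c(X = 1, Y = 0, Z = 1), cfg)
  expect_setequal(unique(es5[, "Z"]), c(0, 1))
})

test_that("dose-0 is bit-identical to the unperturbed trajectory", {
  net <- toy_network()
  ctrl <- control_profile(net)
  cfg <- sim_config(seed = 2L)
  init <- c(X = 0, Y = 1, Z = 1)
  base <- simulate(net, ctrl, init, cfg, keep_trajectory = TRUE)
  pert0 <- simulate(net, ctrl, init, cfg,
                    perturbation = perturbation(target_node("X"), 0),
                    keep_trajectory = TRUE)
  expect_identical(base$trajectory, pert0$trajectory)
  expect_identical(base$activity, pert0$activity)
})

test_that("dose-1 node suppression is equivalent to an I-status clamp", {
  net <- toy_network()
  cfg <- sim_config()
  ctrl <- control_profile(net)
  profI <- status_profile(net, c(X = "I"))
  # all 8 initial states: steady activities and death agree bit for bit
  st <- enumerate_initial_states(net, ctrl, cfg)
  for (i in seq_len(nrow(st))) {
    s <- st[i, ]
    d1 <- simulate(net, ctrl, s, cfg,
                   perturbation = perturbation(target_node("X"), 1))
    sI <- simulate(net, profI, s, cfg)
    expect_identical(d1$activity, sI$activity)
    expect_identical(d1$death, sI$death)
  }

  # p53 fixture: death-phenotype ratio over all initial states agrees exactly
  p53 <- p53_network()
  cfg_on <- p53_cfg_on()
  d1 <- death_ratio(p53, control_profile(p53),
                    perturbation(target_node("AKT"), 1), cfg_on)
  bI <- basin_of_apoptosis(p53, status_profile(p53, c(AKT = "I")), cfg_on)
  expect_identical(d1, bI)
})

test_that("reproducibility: identical seed and config give identical results", {
  net <- toy_network()
  ctrl <- control_profile(net)
  pert <- perturbation(target_node("X"), 0.4)
  r1 <- death_ratio(net, ctrl, pert, sim_config(seed = 42L))
  r2 <- death_ratio(net, ctrl, pert, sim_config(seed = 42L))
  expect_identical(r1, r2)
  # and the RNG state of the session is left untouched
  set.seed(1); before <- stats::runif(1)
  set.seed(1); invisible(death_ratio(net, ctrl, pert, sim_config(seed = 9L)))
  expect_identical(stats::runif(1), before)
})

test_that("activity bounds hold and deterministic attractor activities are 0/1", {
  net <- toy_network()
  res <- simulate(net, control_profile(net), c(X = 0, Y = 1, Z = 0), sim_config())
  expect_true(all(res$activity >= 0 & res$activity <= 1))
  expect_true(all(res$activity %in% c(0, 1)))  # fixed-point attractor
})

test_that("the packaged p53 fixture satisfies its structural contract", {
  p53 <- p53_network()
  expect_equal(nrow(p53$nodes), 16L)
  out_deg <- table(factor(p53$links$source, levels = p53$nodes$name))
  expect_equal(sum(out_deg[p53_target_nodes()]), 27L)
  # every trajectory reaches its attractor within the 100-step transient
  expect_true(therawin:::converges_within_transient(p53, control_profile(p53), p53_cfg_on()))
  expect_true(therawin:::converges_within_transient(p53, control_profile(p53), p53_cfg_off()))
})
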