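test_that("event extraction yields T chained events, including non-changes", {
  w <- flip_flop_world()
  s <- events(evolve(w, c(bit = "0"), 2), "bit")
  expect_equal(nrow(s), 2L)
  expect_equal(s$from, c("0", "1"))
  expect_equal(s$to, c("1", "0"))
  expect_equal(s$to[-nrow(s)], s$from[-1L])

  const <- world(cognizer("k", "same", function(self, env) self))
  sc <- events(evolve(const, c(k = "same"), 5), "k")
  expect_true(all(sc$from == "same" & sc$to == "same"))

  expect_error(events(evolve(w, c(bit = "0"), 2), "nope"), "unknown cognizer")
})

test_that("coin observers register the trial cycle in their event streams", {
  cw <- coin_world_with(seed = 3, demon = TRUE, human = TRUE)
  traj <- evolve(cw$world, cw$u0, 40)
  hs <- events(traj, "human")
  # human's registrations lag the coin's outcome events by one tick
  outcomes <- events(traj, "coin")$to %in% c("H", "T")
  expect_equal(hs$to %in% c("sawH", "sawT"),
               c(FALSE, outcomes[-length(outcomes)]))
  # demon alternates prediction and registration
  ds <- events(traj, "demon")
  preds <- grepl("^pred", ds$to)
  expect_true(all(grepl("^obs", ds$to[which(preds) + 1L]), na.rm = TRUE))
})

test_that("induced partitions match pairwise grouping of the rule table", {
  # an observer that ignores its object: one block per observer state
  w_ign <- world(
    cognizer("obj", c("s1", "s2", "s3"), function(self, env) self),
    cognizer("eo", c("w1", "w2"), function(self, env)
      if (self == "w1") "w2" else "w1"))
  p <- induced_partition(w_ign, "eo", "obj")
  expect_true(all(vapply(p$blocks, length, integer(1)) == 1L))
  expect_false(is_perfect_discrimination(p))

  # a perfectly discriminating observer: all-singleton blocks
  w_demon <- world(
    cognizer("obj", c("s1", "s2", "s3"), function(self, env) self),
    cognizer("eo", c("m1", "m2", "m3"), function(self, env)
      sub("^s", "m", env[["obj"]])))
  expect_true(is_perfect_discrimination(induced_partition(w_demon, "eo", "obj")))

  # a coarse observer mapping n object states into one block
  w_coarse <- world(
    cognizer("obj", as.character(1:6), function(self, env) self),
    cognizer("eo", c("low", "high"), function(self, env)
      if (as.integer(env[["obj"]]) <= 4L) "low" else "high"))
  p <- induced_partition(w_coarse, "eo", "obj")
  expect_equal(sort(unname(lengths(p$blocks$low))), c(2L, 4L))

  # agreement with the brute-force grouping oracle on random worlds
  for (seed in 1:5) {
    rw <- random_world(n_cogs = 2L, n_states = 4L, seed = seed)
    got <- induced_partition(rw$world, "a", "b")
    want <- brute_force_partition(rw$world, "a", "b", context = character(0))
    for (cs in names(want)) {
      norm <- function(b) sort(unname(vapply(b, paste, character(1),
                                             collapse = ",")))
      expect_equal(norm(got$blocks[[cs]]), norm(want[[cs]]))
    }
  }
})

test_that("external observers never perturb the observed subsystem", {
  ct <- coin_toss_world(bias = 0.5, seed = 5)
  base <- evolve(ct$world, ct$u0, 60)
  for (obs in list(demon_observer(0.5), human_observer(),
                   cognizer("constant", "z", function(self, env) "z"))) {
    w2 <- attach_external_observer(ct$world, obs)
    u0 <- world_state(w2, c(ct$u0, stats::setNames(
      if (obs$name == "constant") "z" else "idle", obs$name)))
    with_obs <- evolve(w2, u0, 60)
    expect_identical(raw_states(base), raw_states(with_obs, colnames(base)))
  }
  # constant-rule observer performs only non-change cognitions
  w2 <- attach_external_observer(ct$world,
                                 cognizer("constant", "z",
                                          function(self, env) "z"))
  tr <- evolve(w2, world_state(w2, c(ct$u0, constant = "z")), 20)
  sc <- events(tr, "constant")
  expect_true(all(sc$from == sc$to))
  # a name clash would let existing rules read the newcomer: rejected
  expect_error(attach_external_observer(ct$world, cognizer("coin", "x",
                                                           function(s, e) "x")),
               "already")
})

test_that("sensor-memory observer follows the two-tick measurement cycle", {
  obs <- sensor_memory_observer(c(s1 = "1", s2 = "2"))
  run <- run_sensor_memory(obs, c("s1", "s2"))
  expect_equal(run$full$sensor, c("0", "1", "0", "2", "0"))
  expect_equal(run$full$memory, c("mu0", "mu0", "mu1", "mu1", "mu2"))
  expect_equal(run$collapsed$sensor, rep("0", 3L))
  expect_equal(run$collapsed$memory, c("mu0", "mu1", "mu2"))

  # degenerate single-valued sensor with two memory states: memory cycles
  tiny <- sensor_memory_observer(c(s = "1"), memory_size = 2)
  r <- run_sensor_memory(tiny, rep("s", 4L))
  expect_equal(r$collapsed$memory, c("mu0", "mu1", "mu0", "mu1", "mu0"))

  # collapsed stream synchronizes one state per object tick
  set.seed(42)
  objs <- sample(c("s1", "s2"), 20, replace = TRUE)
  obs2 <- sensor_memory_observer(c(s1 = "1", s2 = "2"))
  r2 <- run_sensor_memory(obs2, objs)
  expect_equal(nrow(r2$collapsed), 21L)
  expect_equal(r2$n_measurements, 20L)
  expect_equal(nrow(r2$full), 41L)

  expect_error(run_sensor_memory(obs, character(0)), "non-empty")
  expect_error(run_sensor_memory(obs, "s9"), "outside the measurement rule")
})
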