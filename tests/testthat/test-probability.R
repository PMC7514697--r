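test_that("probability estimates are exact reduced fractions", {
  e <- prob_estimate(6, 8)
  expect_equal(e$numerator, 6)
  expect_equal(e$denominator, 8)
  expect_equal(e$value, 0.75)
  expect_equal(as.numeric(e), 0.75)
  expect_error(prob_estimate(3, 0), "positive")
  expect_error(prob_estimate(5, 4), "numerator")
})

test_that("meta-observer probability counts states, flagging revisits", {
  traj <- evolve(flip_flop_world(), c(bit = "0"), 4)
  everything <- p_meta(traj, A = function(u) TRUE)
  expect_equal(everything$value, 1)

  zeros <- p_meta(traj, A = "0")
  expect_equal(zeros$numerator, 3)
  expect_equal(zeros$denominator, 5)
  # the cycle revisits states, so occurrence counts exceed distinct counts
  expect_equal(zeros$distinct_A, 1L)
  expect_false(zeros$all_distinct)

  # on a transient (no revisit), #A equals |A|
  cnt <- world(cognizer("n", as.character(0:9), function(self, env)
    as.character(min(as.integer(self) + 1L, 9L))))
  t2 <- evolve(cnt, c(n = "0"), 5)
  m <- p_meta(t2, A = as.character(0:3))
  expect_equal(m$numerator, 4)
  expect_equal(m$distinct_A, 4L)
  expect_true(m$all_distinct)

  expect_error(p_meta(traj, A = "0", X = "nope"), "matches no")
  expect_error(p_meta(traj, A = "0", X = "1"), "subset")
})

test_that("overall probability is a count ratio over the reference population", {
  s <- events(c("a", "a", "a", "a"))
  expect_equal(p_overall(s, event_pattern(from = "a", to = "a"))$value, 1)
  expect_equal(p_overall(s, event_pattern(to = "z"))$value, 0)

  # hand-counted 7-event stream
  s7 <- events(c("a", "b", "a", "b", "b", "c", "a", "b"))
  est <- p_overall(s7, event_pattern(from = "a", to = "b"))
  expect_equal(est$numerator, 3)
  expect_equal(est$denominator, 7)

  # restricted reference population
  est2 <- p_overall(s7, event_pattern(from = "b", to = "b"),
                    population = event_pattern(from = "b"))
  expect_equal(c(est2$numerator, est2$denominator), c(1, 3))
  expect_error(p_overall(s7, event_pattern(to = "a"),
                         population = event_pattern(from = "q")),
               "empty reference population")
})

test_that("conditioned probability implements the certainty mechanism", {
  # condition always followed by the target
  s <- events(rep(c("x", "y"), 6L))
  expect_equal(p_cog(s, event_pattern(to = "x"), event_pattern(to = "y"))$value, 1)

  # cyclic-environment mechanism: 3 of 10 hidden states yield cz1
  cw <- certainty_world(n_env = 10L, outcome_states = c(1L, 2L, 3L))
  stream <- events(evolve(cw$world, cw$u0, 300), "obs")
  est <- p_cog(stream, event_pattern(to = "cz1"),
               event_pattern(from = "cx", to = "cy"))
  expect_equal(est$numerator / est$denominator, 3 / 10)

  # an absent condition is undefined, not zero
  expect_error(p_cog(s, event_pattern(to = "x"), event_pattern(to = "q")),
               "undefined conditional")
})

test_that("a perfectly discriminating observer has only certain conditionals", {
  cw <- coin_world_with(seed = 9, demon = TRUE)
  ds <- events(evolve(cw$world, cw$u0, 400), "demon")
  for (b in c("predH", "predT")) {
    for (a in c("obsH", "obsT")) {
      est <- p_cog(ds, event_pattern(to = a), event_pattern(to = b))
      expect_true(est$value %in% c(0, 1))
    }
  }
})

test_that("total probability decomposes exactly, with zero rational error", {
  # a single all-covering condition degenerates to the overall probability
  s7 <- events(c("a", "b", "a", "b", "b", "c", "a", "b"))
  d <- total_probability(s7, event_pattern(to = "b"),
                         conditions = list(event_pattern()))
  expect_true(d$exact_match)
  # with one condition the sum is P_overall(A) over the slots that have a
  # conditioning slot (all but the first event)
  expect_identical(d$sum$num / d$sum$den,
                   sum(match_events(s7, event_pattern(to = "b"))[-1L]) /
                     (nrow(s7) - 1L))

  # random small worlds and random valid condition partitions
  for (seed in 1:40) {
    rw <- random_world(n_cogs = 2L, n_states = 3L, seed = seed)
    traj <- evolve(rw$world, rw$u0, 30L)
    stream <- events(traj, sample(rw$world$names, 1L))
    conditions <- random_condition_partition(rw$states, k = sample(2:4, 1L))
    target <- event_pattern(from = sample(rw$states, 1L),
                            to = sample(rw$states, 1L))
    d <- total_probability(stream, target, conditions)
    expect_true(d$exact_match)
    # and the sum agrees with a direct recount over eligible slots
    n <- nrow(stream)
    direct <- sum(match_events(stream, target)[-1L]) / (n - 1L)
    expect_identical(d$sum$num / d$sum$den, direct)
  }

  # overlapping conditions are rejected with the offending slots
  expect_error(
    total_probability(s7, event_pattern(to = "b"),
                      conditions = list(event_pattern(), event_pattern(to = "b"))),
    "partition")
})

test_that("conditioning-event frequencies are reproducible from the config", {
  # P(B_i) is fixed by the whole world and u0: identical runs, identical counts
  for (run in 1:2) {
    cw <- coin_world_with(seed = 21, demon = TRUE)
    ds <- events(evolve(cw$world, cw$u0, 300), "demon")
    pb <- p_overall(ds, event_pattern(to = "predH"),
                    population = event_pattern(to = c("predH", "predT")))
    if (run == 1L) first <- pb
  }
  expect_identical(first$numerator, pb$numerator)
  expect_identical(first$denominator, pb$denominator)
})
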