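test_that("Shannon entropy has its closed-form values and symmetries", {
  expect_equal(shannon_entropy(1), 0)
  expect_equal(shannon_entropy(c(0.5, 0.5)), 1)
  expect_equal(shannon_entropy(c(0.8, 0.2)), shannon_entropy(c(0.2, 0.8)))
  expect_equal(shannon_entropy(c(1, 0)), 0)
  expect_error(shannon_entropy(c(0.5, 0.4)), "sum to 1")

  # exact sum check for rational inputs
  expect_equal(shannon_entropy(list(prob_estimate(1, 3), prob_estimate(2, 3))),
               -(1/3) * log2(1/3) - (2/3) * log2(2/3))
  expect_error(shannon_entropy(list(prob_estimate(1, 3), prob_estimate(1, 3))),
               "sum to 1")

  # bounds and permutation invariance over random distributions
  set.seed(7)
  for (k in c(2L, 4L, 7L)) {
    p <- as.vector(stats::rmultinom(1, 60, rep(1, k))) / 60
    H <- shannon_entropy(p)
    expect_gte(H, 0)
    expect_lte(H, log2(k) + 1e-12)
    expect_equal(shannon_entropy(sample(p)), H)
  }
})

test_that("conditioned entropy tracks the observer's discriminability", {
  outcomes <- list(event_pattern(to = "cz1"), event_pattern(to = "cz2"))
  cond <- event_pattern(from = "cx", to = "cy")

  # fully discriminative conditioning: a single certain outcome, 0 bits
  dw <- certainty_world(trigger_states = 0:2, outcome_states = 1:3)
  s <- events(evolve(dw$world, dw$u0, 150), "obs")
  expect_equal(h_cog(s, cond, outcomes)$H, 0)

  # the 3-of-10 mechanism gives the closed-form binary entropy of 0.3
  cw <- certainty_world(n_env = 10L, outcome_states = 1:3)
  s2 <- events(evolve(cw$world, cw$u0, 300), "obs")
  expect_equal(h_cog(s2, cond, outcomes)$H,
               -0.3 * log2(0.3) - 0.7 * log2(0.7), tolerance = 1e-12)

  # a non-discriminating observer of a fair coin is maximally uncertain:
  # the human's conditioning event before an outcome carries no information
  hw <- coin_world_with(seed = 2, human = TRUE)
  traj <- evolve(hw$world, hw$u0, 20000)
  hs <- events(traj, "human")
  rep_h <- h_cog(hs, event_pattern(from = c("sawH", "sawT"), to = "idle"),
                 list(event_pattern(to = "sawH"), event_pattern(to = "sawT")))
  expect_equal(rep_h$H, 1, tolerance = 5e-4)
})

test_that("overall entropy ignores conditioning and observer refinement", {
  const <- events(rep("k", 8L))
  expect_equal(h_overall(const, list(event_pattern(to = "k")))$H, 0)

  # fair-coin outcome entropy is about 1 bit from any observer's stream
  cw <- coin_world_with(seed = 4, demon = TRUE, human = TRUE)
  traj <- evolve(cw$world, cw$u0, 20000)
  pats <- coin_patterns()
  h_coin <- h_overall(events(traj, "coin"),
                      list(pats$heads, pats$tails), population = pats$outcome)
  h_demon <- h_overall(events(traj, "demon"),
                       list(event_pattern(to = "obsH"), event_pattern(to = "obsT")),
                       population = event_pattern(to = c("obsH", "obsT")))
  h_human <- h_overall(events(traj, "human"),
                       list(event_pattern(to = "sawH"), event_pattern(to = "sawT")),
                       population = event_pattern(to = c("sawH", "sawT")))
  expect_equal(h_coin$H, 1, tolerance = 1e-3)
  # outcome events stay distinguishable for both observers, so the overall
  # entropy is the same and the information from switching observers is zero
  expect_identical(h_demon$H, h_coin$H)
  expect_identical(h_human$H, h_coin$H)
  expect_equal(info_amount(h_demon, h_human), 0)
})

test_that("information amounts are signed entropy differences of like type", {
  outcomes <- list(event_pattern(to = "cz1"), event_pattern(to = "cz2"))
  cond <- event_pattern(from = "cx", to = "cy")
  cw <- certainty_world(n_env = 10L, outcome_states = 1:3)
  coarse <- h_cog(events(evolve(cw$world, cw$u0, 300), "obs"), cond, outcomes)
  dw <- certainty_world(trigger_states = 0:2, outcome_states = 1:3)
  fine <- h_cog(events(evolve(dw$world, dw$u0, 150), "obs"), cond, outcomes)
  expect_equal(info_amount(coarse, fine), coarse$H)
  expect_equal(info_amount(fine, coarse), -coarse$H)
  expect_equal(info_amount(coarse, coarse), 0)

  wrong <- h_overall(events(rep(c("a", "b"), 5)),
                     list(event_pattern(to = "a"), event_pattern(to = "b")))
  expect_error(info_amount(coarse, wrong), "types differ")
})

test_that("averaged conditional entropy never increases under refinement", {
  # demon partition: every conditional is degenerate, average is 0
  cw <- coin_world_with(seed = 6, demon = TRUE)
  ds <- events(evolve(cw$world, cw$u0, 400), "demon")
  obs_outcomes <- list(event_pattern(to = "obsH"), event_pattern(to = "obsT"),
                       event_pattern(to = c("idle", "predH", "predT")))
  fine <- list(event_pattern(to = "predH"), event_pattern(to = "predT"),
               event_pattern(to = c("idle", "obsH", "obsT")))
  coarse <- list(event_pattern(to = c("predH", "predT")),
                 event_pattern(to = c("idle", "obsH", "obsT")))
  h_fine <- expected_h_cog(ds, fine, obs_outcomes)
  h_coarse <- expected_h_cog(ds, coarse, obs_outcomes)
  expect_lte(h_fine, h_coarse + 1e-12)

  # random worlds: refine a random partition by splitting one block
  for (seed in 1:10) {
    rw <- random_world(n_cogs = 2L, n_states = 3L, seed = seed + 100L)
    stream <- events(evolve(rw$world, rw$u0, 40L), "a")
    pairs <- as.vector(outer(rw$states, rw$states,
                             function(a, b) paste0(a, "->", b)))
    set.seed(seed)
    g <- sample(1:2, length(pairs), replace = TRUE)
    coarse <- lapply(1:2, function(i) event_pattern(pairs = pairs[g == i]))
    # split group 1 into two non-empty parts where possible
    idx <- which(g == 1L)
    if (length(idx) < 2L) next
    cut <- seq_along(idx) <= length(idx) %/% 2L
    fine <- list(event_pattern(pairs = pairs[idx[cut]]),
                 event_pattern(pairs = pairs[idx[!cut]]),
                 event_pattern(pairs = pairs[g == 2L]))
    outcomes <- lapply(rw$states, function(s) event_pattern(to = s))
    expect_lte(expected_h_cog(stream, fine, outcomes),
               expected_h_cog(stream, coarse, outcomes) + 1e-12)
  }

  # single condition equals the plain conditional entropy
  s7 <- events(c("a", "b", "a", "b", "b", "a", "b"))
  outcomes <- list(event_pattern(to = "a"), event_pattern(to = "b"))
  expect_equal(as.numeric(expected_h_cog(s7, list(event_pattern()), outcomes)),
               h_cog(s7, event_pattern(), outcomes)$H)
})
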