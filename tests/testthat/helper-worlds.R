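# Small worlds and generators shared across the suite.

flip_flop_world <- function() {
  world(cognizer("bit", c("0", "1"),
                 function(self, env) if (self == "0") "1" else "0"))
}

# two-cognizer world with explicit transition tables: observer C1 and
# environment E, both on {x, y}, each mapping the joint state (x, x) onwards
fig_pair_world <- function() {
  c1 <- rule_table(data.frame(self = c("cx", "cx", "cy"),
                              E = c("ex", "*", "*"),
                              "next" = c("cy", "cx", "cx"),
                              check.names = FALSE))
  e <- rule_table(data.frame(self = c("ex", "ey"),
                             "next" = c("ey", "ex"), check.names = FALSE))
  world(cognizer("C1", c("cx", "cy"), c1),
        cognizer("E", c("ex", "ey"), e))
}

# three cognizers on {0,1,2}; each copies its right neighbour (cyclically)
cyclic_shift_world <- function() {
  sts <- c("0", "1", "2")
  world(cognizer("a", sts, function(self, env) env[["b"]]),
        cognizer("b", sts, function(self, env) env[["c"]]),
        cognizer("c", sts, function(self, env) env[["a"]]))
}

# a random total world: each cognizer's rule is a random lookup over the full
# joint space, reproducible from the seed
random_world <- function(n_cogs = 2L, n_states = 3L, seed = 1L) {
  set.seed(seed)
  nms <- letters[seq_len(n_cogs)]
  sts <- as.character(seq_len(n_states) - 1L)
  grid <- expand.grid(rep(list(sts), n_cogs), stringsAsFactors = FALSE)
  names(grid) <- nms
  keys <- apply(as.matrix(grid), 1L, paste, collapse = "\r")
  cogs <- lapply(seq_len(n_cogs), function(i) {
    map <- stats::setNames(sample(sts, nrow(grid), replace = TRUE), keys)
    force(map)
    cognizer(nms[i], sts, function(self, env) {
      full <- character(n_cogs)
      full[i] <- self
      full[-i] <- env[nms[-i]]
      map[[paste(full, collapse = "\r")]]
    })
  })
  w <- world(cogs)
  u0 <- stats::setNames(sample(sts, n_cogs, replace = TRUE), nms)
  list(world = w, u0 = u0, states = sts)
}

# random partition of all possible event types of a state set into 1..k
# condition patterns (pairs-based, hence disjoint and covering)
random_condition_partition <- function(states, k = 3L) {
  pairs <- as.vector(outer(states, states, function(a, b) paste0(a, "->", b)))
  g <- sample(seq_len(k), length(pairs), replace = TRUE)
  lapply(unique(g), function(i) event_pattern(pairs = pairs[g == i]))
}

coin_world_with <- function(seed, bias = 0.5, demon = FALSE, human = FALSE) {
  ct <- coin_toss_world(bias = bias, seed = seed)
  w <- ct$world
  u0 <- ct$u0
  if (demon) {
    w <- attach_external_observer(w, demon_observer(bias))
    u0 <- c(u0, demon = "idle")
  }
  if (human) {
    w <- attach_external_observer(w, human_observer())
    u0 <- c(u0, human = "idle")
  }
  list(world = w, u0 = world_state(w, u0))
}

# independent pairwise-grouping oracle for discriminability: group object
# states by equality of the successor the observer's rule assigns them
brute_force_partition <- function(w, observer, object, context) {
  obj_states <- cognisys::space_labels(w$cognizers[[object]]$states)
  rule <- w$cognizers[[observer]]$rule
  obs_states <- cognisys::space_labels(w$cognizers[[observer]]$states)
  lapply(stats::setNames(obs_states, obs_states), function(cs) {
    succ <- vapply(obj_states, function(os) {
      env <- c(stats::setNames(os, object), context)
      rule(cs, env)
    }, character(1))
    unname(split(obj_states, succ))
  })
}

# plain state matrix of a trajectory, attributes stripped, for comparisons
raw_states <- function(traj, cols = colnames(traj)) {
  m <- unclass(traj)[, cols, drop = FALSE]
  attr(m, "world") <- NULL
  m
}
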