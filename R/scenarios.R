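# Canonical worlds: repeated coin tosses and a Maxwell's-demon lattice gas.
#
# Pseudo-randomness lives INSIDE the deterministic world: a hidden microstate
# cognizer runs a fixed Lehmer permutation x -> a*x mod m on a large finite
# state set, so the whole system stays a pure function of its initial state.
# The external seed only selects the initial microstate u0.

.LEHMER_M <- 2147483647      # 2^31 - 1, prime
.LEHMER_A <- 16807           # full-period multiplier on 1..m-1

.lehmer_next <- function(x) as.character((as.numeric(x) * .LEHMER_A) %% .LEHMER_M)

# map a user seed to a microstate in 1..m-2, with a few scrambling steps so
# that small consecutive seeds land far apart
.seed_to_microstate <- function(seed) {
  x <- (abs(as.numeric(seed)) %% (.LEHMER_M - 1)) + 1
  for (i in 1:8) x <- (x * .LEHMER_A) %% .LEHMER_M
  if (x == 0) x <- 1
  as.character(x)
}

#' Repeated coin-toss world
#'
#' A deterministic world realizing repeated coin tosses as one continuous
#' state transition.  Members:
#'
#' * `micro` -- the hidden "rest of the world": a Lehmer permutation on a large
#'   finite state set, advancing every tick.  Its state at a toss tick is the
#'   microscopic initial condition of that trial.
#' * `tosser` -- the internal observer, alternating `toss` / `idle`; every
#'   second tick is a toss.
#' * `coin` -- reads the tosser and the microstate: on a toss tick its next
#'   state is `H` or `T` (the microstate decides, thresholded by `bias`),
#'   otherwise `rest`.
#'
#' Two external observers can be attached with [attach_external_observer()]:
#'
#' * [demon_observer()] -- reads the microstate directly and predicts the
#'   outcome before it happens (`pred*`), then registers it (`obs*`): perfect
#'   discriminability, so every conditional probability of the outcome given
#'   its prediction is 0 or 1.
#' * [human_observer()] -- reads only the coin's face: it registers outcomes
#'   (`sawH`/`sawT`) but its conditioning cognitions carry no information about
#'   the upcoming toss.
#'
#' @param bias probability of heads, in `[0, 1]`; thresholds the microstate
#'   (`bias = 1` means every trial heads).
#' @param seed integer selecting the initial microstate; everything else about
#'   the world is fixed.
#' @return A list with `world` (a [world()]) and `u0` (initial joint state).
#'   Run `trials` trials with `evolve(world, u0, 2 * trials)`.
#' @examples
#' ct <- coin_toss_world(bias = 0.5, seed = 1)
#' traj <- evolve(ct$world, ct$u0, 20)
#' @export
coin_toss_world <- function(bias = 0.5, seed = 1L) {
  bias <- as.numeric(bias)
  if (is.na(bias) || bias < 0 || bias > 1) stop("'bias' must lie in [0, 1]")
  threshold <- bias * (.LEHMER_M - 1)   # heads iff microstate - 1 < threshold

  micro <- cognizer("micro", state_space_range(.LEHMER_M - 1),
                    function(self, env) .lehmer_next(self))
  tosser <- cognizer("tosser", c("toss", "idle"),
                     function(self, env) if (self == "toss") "idle" else "toss")
  coin <- cognizer("coin", c("rest", "H", "T"), function(self, env) {
    if (env[["tosser"]] == "toss") {
      if (as.numeric(env[["micro"]]) - 1 < threshold) "H" else "T"
    } else "rest"
  })
  list(world = world(micro, tosser, coin),
       u0 = c(micro = .seed_to_microstate(seed), tosser = "toss", coin = "rest"))
}

#' @rdname coin_toss_world
#' @param bias as in `coin_toss_world`; the demon embodies the same
#'   deterministic outcome map, read off the microstate one tick early.
#' @export
demon_observer <- function(bias = 0.5) {
  threshold <- bias * (.LEHMER_M - 1)
  cognizer("demon", c("idle", "predH", "predT", "obsH", "obsT"),
           function(self, env) {
             if (env[["tosser"]] == "toss") {
               if (as.numeric(env[["micro"]]) - 1 < threshold) "predH" else "predT"
             } else if (env[["coin"]] == "H") "obsH"
             else if (env[["coin"]] == "T") "obsT"
             else "idle"
           })
}

#' @rdname coin_toss_world
#' @export
human_observer <- function() {
  cognizer("human", c("idle", "sawH", "sawT"),
           function(self, env) {
             if (env[["coin"]] == "H") "sawH"
             else if (env[["coin"]] == "T") "sawT"
             else "idle"
           })
}

#' Outcome patterns of the coin-toss world
#'
#' Convenience patterns for the coin's event stream: outcome events are the
#' transitions into a face (`rest -> H` / `rest -> T`).
#'
#' @return A list with patterns `heads`, `tails`, `outcome`.
#' @export
coin_patterns <- function() {
  list(heads = event_pattern(from = "rest", to = "H"),
       tails = event_pattern(from = "rest", to = "T"),
       outcome = event_pattern(from = "rest", to = c("H", "T")))
}

#' Maxwell's-demon lattice gas world
#'
#' Non-interacting particles bounce on a 1-D lattice of `lattice` cells split
#' into two chambers by a wall between cells `lattice/2` and `lattice/2 + 1`.
#' The wall has a hole, itself a cognizer with states `open`/`closed`.  Each
#' particle's state is `"position:velocity"` with velocity `+1` or `-1`; it
#' reverses at the lattice ends and at the wall when the hole is closed, and
#' passes through when open.
#'
#' With `demon = FALSE` the hole is always open and the gas spreads over both
#' chambers.  With `demon = TRUE` the hole's rule is the demon's discriminative
#' and selective cognition: it opens only when a particle approaches the wall
#' from the left and none approaches from the right, so particles accumulate in
#' the right chamber -- the demon's cognition generates a non-uniform
#' distribution, lowering the overall entropy of chamber occupancy.
#'
#' A hidden `kick` cognizer (a Lehmer permutation register, as in
#' [coin_toss_world()]) thermally agitates the gas: each tick each particle
#' reverses its velocity with relative frequency about 1/61, each particle
#' reading a different residue of the register.  Without it the
#' non-interacting particles would be strictly periodic and phase-locked,
#' which is not the disordered gas the scenario is meant to emulate.  The
#' whole system remains a pure function of its initial state.
#'
#' @param n_particles number of particles (`>= 2`).
#' @param lattice even number of cells (`>= 4`); capacity is two particles per
#'   cell (one per velocity slot), so `n_particles <= 2 * lattice`.
#' @param demon logical: demon-controlled hole, or always open.
#' @param seed integer selecting the initial particle placement (drawn with
#'   R's RNG from this seed; the world itself is deterministic).
#' @return A list with `world`, `u0`, and `particles` (the particle cognizer
#'   names).
#' @export
maxwell_world <- function(n_particles = 20L, lattice = 16L, demon = TRUE,
                          seed = 1L) {
  n_particles <- as.integer(n_particles)
  lattice <- as.integer(lattice)
  if (n_particles < 2L) stop("'n_particles' must be >= 2")
  if (lattice < 4L || lattice %% 2L != 0L) stop("'lattice' must be even and >= 4")
  # particles do not collide, so capacity is one per (cell, velocity) slot
  if (n_particles > 2L * lattice) {
    stop("overcrowded lattice: at most 2 * lattice particles")
  }
  wall_left <- lattice %/% 2L          # wall sits between wall_left and wall_left+1

  pnames <- paste0("p", seq_len(n_particles))
  pspace <- state_space(as.vector(outer(seq_len(lattice), c("+1", "-1"),
                                        function(p, v) paste0(p, ":", v))))
  kick <- cognizer("kick", state_space_range(.LEHMER_M - 1),
                   function(self, env) .lehmer_next(self))
  make_particle_rule <- function(i) {
    force(i)
    function(self, env) {
      parts <- strsplit(self, ":", fixed = TRUE)[[1L]]
      pos <- as.integer(parts[1L]); vel <- as.integer(parts[2L])
      # thermal agitation: particle i reads its own residue of the register
      if ((as.numeric(env[["kick"]]) + 37 * i) %% 61 == 0) vel <- -vel
      open <- env[["hole"]] == "open"
      nxt <- pos + vel
      crossing <- (pos == wall_left && vel == 1L) ||
                  (pos == wall_left + 1L && vel == -1L)
      if (nxt < 1L || nxt > lattice || (crossing && !open)) {
        vel <- -vel                     # reflect at ends and at a closed hole
        nxt <- pos
      }
      paste0(nxt, ":", if (vel > 0) "+1" else "-1")
    }
  }
  particles <- lapply(seq_len(n_particles), function(i)
    cognizer(pnames[i], pspace, make_particle_rule(i)))

  hole_rule <- if (demon) {
    function(self, env) {
      pos <- integer(0); vel <- integer(0)
      for (nm in pnames) {
        parts <- strsplit(env[[nm]], ":", fixed = TRUE)[[1L]]
        pos <- c(pos, as.integer(parts[1L])); vel <- c(vel, as.integer(parts[2L]))
      }
      approaching_left <- any(pos %in% c(wall_left - 1L, wall_left) & vel == 1L)
      approaching_right <- any(pos %in% c(wall_left + 1L, wall_left + 2L) & vel == -1L)
      if (approaching_left && !approaching_right) "open" else "closed"
    }
  } else {
    function(self, env) "open"
  }
  hole <- cognizer("hole", c("open", "closed"), hole_rule)

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  slots <- sample(2L * lattice, n_particles)     # distinct (cell, velocity) slots
  cells <- (slots - 1L) %/% 2L + 1L
  vels <- c("+1", "-1")[(slots - 1L) %% 2L + 1L]
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)

  u0 <- c(stats::setNames(paste0(cells, ":", vels), pnames),
          hole = if (demon) "closed" else "open",
          kick = .seed_to_microstate(seed + 7919))
  list(world = world(c(particles, list(hole, kick))), u0 = u0,
       particles = pnames)
}

#' Chamber occupancy events of a Maxwell world trajectory
#'
#' Pools every particle's per-tick chamber (left `L` / right `R` of the wall)
#' into one event stream, suitable for [h_overall()] with outcomes `to = "L"` /
#' `to = "R"`.
#'
#' @param traj trajectory of a [maxwell_world()].
#' @param particles particle cognizer names.
#' @param lattice lattice length used to build the world.
#' @return An [events()] stream of chamber labels pooled over particles.
#' @export
chamber_events <- function(traj, particles, lattice) {
  wall_left <- as.integer(lattice) %/% 2L
  streams <- lapply(particles, function(nm) {
    pos <- as.integer(sub(":.*$", "", unclass(traj)[, nm]))
    events(ifelse(pos <= wall_left, "L", "R"))
  })
  out <- do.call(rbind, streams)
  attr(out, "cognizer") <- "chamber"
  class(out) <- c("event_stream", "data.frame")
  out
}

#' Occupancy entropy of a Maxwell world run
#'
#' Runs the world and computes the overall entropy (bits) of pooled chamber
#' occupancy.
#'
#' @param mw result of [maxwell_world()].
#' @param steps ticks to simulate.
#' @param lattice lattice length (defaults to the length recoverable from the
#'   particle state space).
#' @return The `entropy_report` of chamber occupancy.
#' @export
occupancy_entropy <- function(mw, steps, lattice = NULL) {
  if (is.null(lattice)) {
    lab <- space_labels(mw$world$cognizers[[mw$particles[1L]]]$states)
    lattice <- max(as.integer(sub(":.*$", "", lab)))
  }
  traj <- evolve(mw$world, mw$u0, steps)
  stream <- chamber_events(traj, mw$particles, lattice)
  h_overall(stream, outcomes = list(event_pattern(to = "L"),
                                    event_pattern(to = "R")))
}

#' Conditional-certainty mechanism world
#'
#' A two-cognizer world instantiating the conditioned-probability mechanism: a
#' cyclic environment and an observer whose observational cognition
#' `cx -> cy` is followed by one of two resultant cognitions `cy -> cz1` or
#' `cy -> cz2`, depending on the environment state the observer cannot
#' discriminate at observation time.
#'
#' The environment steps through `e0 ... e{n_env-1}` cyclically.  The observer
#' leaves `cx` for `cy` when the environment is in `trigger_states` (default:
#' always), then moves to `cz1` if the environment has entered
#' `outcome_states`, else to `cz2`, and returns to `cx`.
#'
#' * With `trigger_states = NULL` and `k` outcome states, the conditioned
#'   probability of `cy -> cz1` given `cx -> cy` is exactly `k / n_env`
#'   provided `gcd(3, n_env) = 1` (the 3-tick observer cycle then samples every
#'   environment phase equally).
#' * With `trigger_states = s` and `outcome_states = s + 1 (mod n_env)` the
#'   observation is fully discriminative for the outcome: every conditioning
#'   cognition is followed by `cy -> cz1`, so its conditioned entropy is 0
#'   bits.
#'
#' @param n_env number of environment states.
#' @param outcome_states integer vector (0-based labels) of environment states
#'   that yield resultant cognition `cz1`.
#' @param trigger_states optional integer vector of environment states that
#'   release the observation `cx -> cy`; `NULL` means any.
#' @param e0 initial environment phase (0-based).
#' @return A list with `world` and `u0`.
#' @export
certainty_world <- function(n_env = 10L, outcome_states = c(1L, 2L, 3L),
                            trigger_states = NULL, e0 = 0L) {
  n_env <- as.integer(n_env)
  if (n_env < 2L) stop("'n_env' must be >= 2")
  elab <- function(i) paste0("e", as.integer(i) %% n_env)
  outcome <- elab(outcome_states)
  trigger <- if (is.null(trigger_states)) NULL else elab(trigger_states)
  env <- cognizer("env", elab(0:(n_env - 1L)), function(self, env) {
    elab(as.integer(sub("^e", "", self)) + 1L)
  })
  obs <- cognizer("obs", c("cx", "cy", "cz1", "cz2"), function(self, env) {
    switch(self,
           cx = if (is.null(trigger) || env[["env"]] %in% trigger) "cy" else "cx",
           cy = if (env[["env"]] %in% outcome) "cz1" else "cz2",
           cz1 = ,
           cz2 = "cx")
  })
  list(world = world(env, obs),
       u0 = c(env = elab(e0), obs = "cx"))
}
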