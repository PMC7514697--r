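#' State spaces for cognizers
#'
#' A state space is an ordered collection of distinct symbolic state labels.
#' Labels are case-sensitive strings and their declared order is stable: it is
#' used for deterministic iteration and for serialization.  For very large
#' spaces (e.g. a hidden microstate register) an implicit integer range
#' `"1" ... "n"` avoids materialising the labels.
#'
#' @param labels character vector of distinct labels (coerced with
#'   `as.character()`).
#' @return An object of class `state_space`.
#' @examples
#' state_space(c("heads", "tails"))
#' state_space_range(1000)
#' @export
state_space <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) == 0L) stop("a state space must be non-empty")
  if (anyDuplicated(labels)) {
    stop("state labels must be pairwise distinct: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  structure(list(kind = "explicit", labels = labels, n = length(labels)),
            class = "state_space")
}

#' @rdname state_space
#' @param n size of the implicit range space (states are `"1"` to `"n"`).
#' @export
state_space_range <- function(n) {
  n <- as.numeric(n)
  if (length(n) != 1L || is.na(n) || n < 1) stop("'n' must be a positive count")
  structure(list(kind = "range", labels = NULL, n = n), class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  if (x$kind == "explicit") {
    shown <- utils::head(x$labels, 8L)
    cat("<state_space> ", x$n, " states: ", paste(shown, collapse = ", "),
        if (x$n > 8L) ", ..." else "", "\n", sep = "")
  } else {
    cat("<state_space> implicit integer range 1..", format(x$n, scientific = FALSE),
        "\n", sep = "")
  }
  invisible(x)
}

#' Size and membership of a state space
#'
#' @param space a [state_space()].
#' @return `space_size()` the number of states; `space_labels()` the label
#'   vector (an error for implicit ranges above `max_enumerate`);
#'   `space_contains()` a logical vector.
#' @param x character vector of candidate labels.
#' @export
space_size <- function(space) space$n

#' @rdname space_size
#' @param max_enumerate refuse to materialise implicit ranges larger than this.
#' @export
space_labels <- function(space, max_enumerate = 1e6) {
  if (space$kind == "explicit") return(space$labels)
  if (space$n > max_enumerate) {
    stop("refusing to enumerate an implicit range of size ",
         format(space$n, scientific = FALSE))
  }
  as.character(seq_len(space$n))
}

#' @rdname space_size
#' @export
space_contains <- function(space, x) {
  if (space$kind == "explicit") return(x %in% space$labels)
  i <- suppressWarnings(as.numeric(x))
  !is.na(i) & i >= 1 & i <= space$n & i == trunc(i)
}

#' Define a cognizer
#'
#' A cognizer is a named finite-state entity whose next state is a function of
#' its own current state and the current states of every other cognizer in the
#' world (its environment).  All cognizers update simultaneously, so no rule
#' ever sees another cognizer's next state.  The same construct models physical
#' entities and observers; an "observation" is simply a state change related to
#' the states of others.
#'
#' @param name identifier, unique within a world.
#' @param states a [state_space()] or a character vector of labels.
#' @param rule a function `function(self, env)` returning the successor label;
#'   `self` is the cognizer's own current label, `env` a named character vector
#'   of all other cognizers' current labels.  See [rule_table()] for a tabular
#'   alternative.
#' @return An object of class `cognizer`.
#' @examples
#' flip <- cognizer("bit", c("0", "1"),
#'                  function(self, env) if (self == "0") "1" else "0")
#' @export
cognizer <- function(name, states, rule) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("'name' must be a non-empty string")
  }
  if (!inherits(states, "state_space")) states <- state_space(states)
  if (!is.function(rule)) stop("'rule' must be a function(self, env)")
  structure(list(name = name, states = states, rule = rule),
            class = "cognizer")
}

#' @export
print.cognizer <- function(x, ...) {
  cat("<cognizer> ", x$name, " (", format(x$states$n, scientific = FALSE),
      " states)\n", sep = "")
  invisible(x)
}

#' Build a motion rule from a lookup table
#'
#' Compiles a data frame of transition rows into a motion-rule function.  The
#' table must have a `self` column (the cognizer's own current state), a `next`
#' column (the successor), and optionally one column per environment cognizer.
#' `"*"` in any condition cell is a wildcard.  Rows are matched top to bottom;
#' the first matching row wins, which makes specific rows + a wildcard default
#' row a convenient idiom.
#'
#' @param table a data frame with columns `self`, optional environment-name
#'   columns, and `next` (backtick it or use `next.` when constructing).
#' @return A function usable as the `rule` of [cognizer()].
#' @examples
#' tab <- data.frame(self = c("0", "1"), next. = c("1", "0"))
#' names(tab)[2] <- "next"
#' rule_table(tab)
#' @export
rule_table <- function(table) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  names(table)[names(table) == "next."] <- "next"
  if (!all(c("self", "next") %in% names(table))) {
    stop("rule table needs 'self' and 'next' columns")
  }
  cond_cols <- setdiff(names(table), "next")
  table[] <- lapply(table, as.character)
  force(table); force(cond_cols)
  function(self, env) {
    for (r in seq_len(nrow(table))) {
      ok <- TRUE
      for (col in cond_cols) {
        want <- table[[col]][r]
        if (want == "*") next
        have <- if (col == "self") self else env[[col]]
        if (is.null(have) || want != have) { ok <- FALSE; break }
      }
      if (ok) return(table[["next"]][r])
    }
    stop("motion rule table has no row matching self=", self,
         " env=(", paste(names(env), env, sep = "=", collapse = ", "), ")")
  }
}

#' Assemble a world of cognizers
#'
#' The world is the whole system: an ordered list of cognizers whose joint
#' state evolves deterministically in discrete, global, synchronous ticks.  The
#' induced global motion applies every member's rule to the same current joint
#' state.
#'
#' @param ... cognizers, or a single list of cognizers.
#' @return An object of class `cs_world`.
#' @seealso [cs_step()], [evolve()], [validate_world()]
#' @export
world <- function(...) {
  cogs <- list(...)
  if (length(cogs) == 1L && !inherits(cogs[[1L]], "cognizer")) cogs <- cogs[[1L]]
  if (length(cogs) == 0L) stop("a world needs at least one cognizer")
  ok <- vapply(cogs, inherits, logical(1), what = "cognizer")
  if (!all(ok)) stop("all members must be cognizer objects")
  nms <- vapply(cogs, function(c) c$name, character(1))
  if (anyDuplicated(nms)) {
    stop("cognizer names must be unique: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  names(cogs) <- nms
  structure(list(cognizers = cogs, names = nms), class = "cs_world")
}

#' @export
print.cs_world <- function(x, ...) {
  sizes <- vapply(x$cognizers, function(c) c$states$n, numeric(1))
  cat("<cs_world> ", length(x$cognizers), " cognizers: ",
      paste0(x$names, " (", format(sizes, scientific = FALSE, trim = TRUE), ")",
             collapse = ", "), "\n", sep = "")
  cat("  joint state space size: ",
      format(prod(sizes), scientific = TRUE, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Validate a world state
#'
#' @param w a [world()].
#' @param u named or unnamed character vector, one label per cognizer in
#'   declared order.
#' @return The state as a named character vector in declared cognizer order.
#' @export
world_state <- function(w, u) {
  u <- stats::setNames(as.character(u), names(u))  # as.character drops names
  if (length(u) != length(w$names)) {
    stop("state has ", length(u), " components, world has ", length(w$names))
  }
  if (!is.null(names(u)) && all(nzchar(names(u)))) {
    missing <- setdiff(w$names, names(u))
    if (length(missing)) stop("state missing components: ",
                              paste(missing, collapse = ", "))
    u <- u[w$names]
  } else {
    names(u) <- w$names
  }
  for (nm in w$names) {
    if (!space_contains(w$cognizers[[nm]]$states, u[[nm]])) {
      stop("unknown state label '", u[[nm]], "' for cognizer '", nm, "'")
    }
  }
  u
}

#' Advance the world one tick
#'
#' Applies every cognizer's motion rule to the current joint state
#' simultaneously: cognizer i's successor depends on its own time-t state and
#' the others' time-t states only.
#'
#' @param w a [world()].
#' @param u current joint state (validated with [world_state()]).
#' @param validate check the input state (and that each rule's output lies in
#'   its own state space).  Turn off inside long loops.
#' @return The successor joint state, a named character vector.
#' @export
cs_step <- function(w, u, validate = TRUE) {
  if (validate) u <- world_state(w, u)
  nms <- w$names
  out <- u
  for (i in seq_along(nms)) {
    cog <- w$cognizers[[i]]
    nxt <- cog$rule(u[[i]], u[-i])
    if (validate && !space_contains(cog$states, nxt)) {
      stop("rule of cognizer '", nms[i], "' produced label '", nxt,
           "' outside its state space")
    }
    out[[i]] <- nxt
  }
  out
}

#' Generate a trajectory
#'
#' Iterates the global motion from an initial state for `steps` ticks, giving a
#' trajectory of `steps + 1` joint states.  The world is deterministic: two
#' calls with identical inputs yield identical trajectories.
#'
#' @param w a [world()].
#' @param u0 initial joint state.
#' @param steps number of ticks (`>= 0`).
#' @return An object of class `cs_trajectory`: a character matrix with one row
#'   per tick (0-based tick in attribute-free row order) and one column per
#'   cognizer, carrying the world in attribute `world`.
#' @examples
#' flip <- cognizer("bit", c("0", "1"),
#'                  function(self, env) if (self == "0") "1" else "0")
#' evolve(world(flip), c(bit = "0"), 4)
#' @export
evolve <- function(w, u0, steps) {
  steps <- as.integer(steps)
  if (is.na(steps) || steps < 0L) stop("'steps' must be a non-negative count")
  u <- world_state(w, u0)
  # validate the first transition fully, then trust the rules for speed
  m <- matrix(NA_character_, nrow = steps + 1L, ncol = length(w$names),
              dimnames = list(NULL, w$names))
  m[1L, ] <- u
  if (steps > 0L) {
    u <- cs_step(w, u, validate = TRUE)
    m[2L, ] <- u
    if (steps > 1L) {
      for (t in seq.int(2L, steps)) {
        u <- cs_step(w, u, validate = FALSE)
        m[t + 1L, ] <- u
      }
    }
  }
  structure(m, class = c("cs_trajectory", "matrix", "array"), world = w)
}

#' @export
print.cs_trajectory <- function(x, n = 10L, ...) {
  total <- nrow(x)
  cat("<cs_trajectory> ", total, " states (ticks 0..", total - 1L, "), ",
      ncol(x), " cognizers\n", sep = "")
  shown <- utils::head(seq_len(total), n)
  df <- data.frame(t = shown - 1L, unclass(x)[shown, , drop = FALSE],
                   check.names = FALSE)
  print(df, row.names = FALSE)
  if (total > n) cat("  ... ", total - n, " more ticks\n", sep = "")
  invisible(x)
}

#' @export
summary.cs_trajectory <- function(object, ...) {
  w <- attr(object, "world")
  cat("Trajectory of", nrow(object) - 1L, "ticks over",
      length(w$names), "cognizers\n")
  for (nm in w$names) {
    vals <- unique(object[, nm])
    cat("  ", nm, ": ", length(vals), " distinct states visited\n", sep = "")
  }
  invisible(object)
}

#' Plot a trajectory
#'
#' Draws each cognizer's state sequence as a step line, with states mapped to
#' their index in the declared state order (or in order of first appearance for
#' implicit ranges).
#'
#' @param x a `cs_trajectory`.
#' @param cognizers which columns to draw (default all).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.cs_trajectory <- function(x, cognizers = colnames(x), ...) {
  w <- attr(x, "world")
  idx <- sapply(cognizers, function(nm) {
    sp <- w$cognizers[[nm]]$states
    lv <- if (sp$kind == "explicit") sp$labels else unique(x[, nm])
    match(x[, nm], lv)
  })
  graphics::matplot(0:(nrow(x) - 1L), idx, type = "s", lty = 1,
                    xlab = "tick", ylab = "state index", ...)
  graphics::legend("topright", legend = cognizers, lty = 1,
                   col = seq_along(cognizers), bty = "n", cex = 0.8)
  invisible(x)
}

#' Exhaustively validate a world's motion rules
#'
#' Checks totality and closure: every rule, applied to every joint state in the
#' product space, returns a label inside its own state space.  Only feasible
#' for small worlds; refuses above `max_states` joint states.
#'
#' @param w a [world()].
#' @param max_states upper bound on the joint space size to enumerate.
#' @return `TRUE` invisibly, or an error naming the cognizer and offending
#'   state.
#' @export
validate_world <- function(w, max_states = 1e6) {
  sizes <- vapply(w$cognizers, function(c) c$states$n, numeric(1))
  if (prod(sizes) > max_states) {
    stop("joint state space too large to enumerate (",
         format(prod(sizes), scientific = TRUE, digits = 3), " states)")
  }
  grids <- lapply(w$cognizers, function(c) space_labels(c$states))
  joint <- expand.grid(grids, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  names(joint) <- w$names
  for (r in seq_len(nrow(joint))) {
    u <- unlist(joint[r, , drop = FALSE])
    names(u) <- w$names
    cs_step(w, u, validate = TRUE)
  }
  invisible(TRUE)
}

#' Composite cognizers
#'
#' A composite cognizer groups an ordered subset of a world's members; its
#' state at any tick is the tuple of member states, an element of the product
#' of member state spaces.  A pattern -- a subset of that product -- represents
#' a configuration the members can jointly form, and composite state changes
#' are the pattern-transmission (ontic) face of cognition.
#'
#' @param w a [world()].
#' @param members character vector of member names (non-empty, in the order the
#'   composite tuple should use).
#' @param pattern optional subset of the product space: a character matrix or
#'   data frame with one column per member.
#' @return An object of class `cs_composite`.
#' @export
compose <- function(w, members, pattern = NULL) {
  members <- as.character(members)
  if (length(members) == 0L) stop("composite needs at least one member")
  unknown <- setdiff(members, w$names)
  if (length(unknown)) stop("unknown cognizer(s): ", paste(unknown, collapse = ", "))
  if (!is.null(pattern)) {
    pattern <- as.matrix(pattern)
    if (ncol(pattern) != length(members)) {
      stop("pattern must have one column per member")
    }
    colnames(pattern) <- members
    for (nm in members) {
      bad <- !space_contains(w$cognizers[[nm]]$states, pattern[, nm])
      if (any(bad)) stop("pattern contains label(s) outside the state space of '",
                         nm, "'")
    }
  }
  structure(list(world = w, members = members, pattern = pattern),
            class = "cs_composite")
}

#' @export
print.cs_composite <- function(x, ...) {
  cat("<cs_composite> members: ", paste(x$members, collapse = ", "), "\n", sep = "")
  if (!is.null(x$pattern)) cat("  pattern of", nrow(x$pattern), "joint states\n")
  invisible(x)
}

#' Project a trajectory onto a composite cognizer
#'
#' @param traj a [evolve()] trajectory of the composite's world.
#' @param composite a [compose()] composite (or a character vector of names).
#' @param collapse if `TRUE` (default) return a single character vector of
#'   composite labels (member labels joined with `"|"`); otherwise the member
#'   sub-matrix.
#' @return Composite state sequence, one entry per tick.
#' @export
composite_states <- function(traj, composite, collapse = TRUE) {
  members <- if (inherits(composite, "cs_composite")) composite$members
             else as.character(composite)
  missing <- setdiff(members, colnames(traj))
  if (length(missing)) stop("trajectory lacks cognizer(s): ",
                            paste(missing, collapse = ", "))
  sub <- unclass(traj)[, members, drop = FALSE]
  if (!collapse) return(sub)
  apply(sub, 1L, paste, collapse = "|")
}
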