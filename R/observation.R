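#' Extract the cognition events of one cognizer
#'
#' A cognition is a related state change `from -> to` of one cognizer over one
#' tick; a change to the same state counts as a (non-change) cognition.  A
#' trajectory of `T + 1` states yields `T` events, and consecutive events chain
#' (`to` of event t equals `from` of event t+1).
#'
#' @param traj a [evolve()] trajectory, or any matrix/data frame of state
#'   labels with named columns; a composite label vector from
#'   [composite_states()] also works.
#' @param cognizer name of the cognizer (ignored when `traj` is already a
#'   single state sequence).
#' @return An object of class `event_stream`: a data frame with columns `t`
#'   (0-based tick of the transition start), `from`, `to`.
#' @examples
#' flip <- cognizer("bit", c("0", "1"),
#'                  function(self, env) if (self == "0") "1" else "0")
#' events(evolve(world(flip), c(bit = "0"), 3), "bit")
#' @export
events <- function(traj, cognizer = NULL) {
  if (is.character(traj) && is.null(dim(traj))) {
    seqv <- traj
  } else {
    m <- as.matrix(traj)
    if (is.null(cognizer)) {
      if (ncol(m) != 1L) stop("'cognizer' must name one column of the trajectory")
      seqv <- m[, 1L]
    } else {
      if (!cognizer %in% colnames(m)) {
        stop("unknown cognizer '", cognizer, "'; trajectory has: ",
             paste(colnames(m), collapse = ", "))
      }
      seqv <- m[, cognizer]
    }
  }
  n <- length(seqv)
  if (n < 2L) stop("need at least two states to extract events")
  out <- data.frame(t = 0:(n - 2L),
                    from = seqv[-n], to = seqv[-1L],
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "cognizer") <- cognizer
  class(out) <- c("event_stream", "data.frame")
  out
}

#' @export
print.event_stream <- function(x, n = 10L, ...) {
  cat("<event_stream>", nrow(x), "cognition events",
      if (!is.null(attr(x, "cognizer"))) paste0("of '", attr(x, "cognizer"), "'"),
      "\n")
  print.data.frame(utils::head(x, n), row.names = FALSE)
  if (nrow(x) > n) cat("  ...", nrow(x) - n, "more\n")
  invisible(x)
}

#' Write / read an event stream as TSV
#'
#' Columns `t`, `cognizer`, `from`, `to`, tab-separated with a header row.
#'
#' @param stream an [events()] stream.
#' @param path file path.
#' @export
write_events <- function(stream, path) {
  df <- data.frame(t = stream$t,
                   cognizer = attr(stream, "cognizer") %||% NA_character_,
                   from = stream$from, to = stream$to)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  out <- data.frame(t = as.integer(df$t), from = df$from, to = df$to,
                    stringsAsFactors = FALSE)
  attr(out, "cognizer") <- if (all(df$cognizer == df$cognizer[1L])) df$cognizer[1L]
  class(out) <- c("event_stream", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Discriminability partition induced by an observer
#'
#' For each observer state, object states are grouped by the successor state
#' they induce in the observer: two object states land in the same block
#' exactly when the observer's motion rule cannot tell them apart.  Singleton
#' blocks everywhere mean perfect discriminability (a Laplace's demon); a
#' single block means the observer does not discriminate the object at all.
#'
#' The observer's rule may in general read cognizers other than the object;
#' those are pinned at `context` (defaulting to the first label of each state
#' space).  With `check_context = TRUE` the partition is verified to be
#' independent of that pinning over the full joint space of the remaining
#' cognizers (feasible for small worlds only).
#'
#' @param w a [world()] containing observer and object.
#' @param observer name of the observing cognizer.
#' @param object name of the observed cognizer, or a character vector of names
#'   (a composite object; blocks then contain composite labels joined with
#'   `"|"`).
#' @param context named character vector pinning non-object, non-observer
#'   cognizers.
#' @param check_context verify independence from `context` exhaustively.
#' @return An object of class `discriminability`: a list with one element per
#'   observer state, each a named list of blocks (names = induced successor
#'   observer state, entries = character vectors of object labels).
#' @export
induced_partition <- function(w, observer, object,
                              context = NULL, check_context = FALSE) {
  if (!observer %in% w$names) stop("unknown observer '", observer, "'")
  object <- as.character(object)
  unknown <- setdiff(object, w$names)
  if (length(unknown)) stop("unknown object cognizer(s): ",
                            paste(unknown, collapse = ", "))
  if (observer %in% object) stop("observer cannot be part of the observed object")

  obs_states <- space_labels(w$cognizers[[observer]]$states)
  obj_grid <- expand.grid(lapply(object, function(nm)
    space_labels(w$cognizers[[nm]]$states)),
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  names(obj_grid) <- object
  obj_labels <- apply(as.matrix(obj_grid), 1L, paste, collapse = "|")

  others <- setdiff(w$names, c(observer, object))
  base_ctx <- vapply(others, function(nm) {
    sp <- w$cognizers[[nm]]$states
    if (sp$kind == "explicit") sp$labels[1L] else "1"
  }, character(1))
  if (!is.null(context)) base_ctx[names(context)] <- as.character(context)

  contexts <- list(base_ctx)
  if (check_context && length(others)) {
    grid <- expand.grid(lapply(others, function(nm)
      space_labels(w$cognizers[[nm]]$states)),
      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    names(grid) <- others
    contexts <- lapply(seq_len(nrow(grid)), function(r) {
      v <- unlist(grid[r, , drop = FALSE]); names(v) <- others; v
    })
  }

  rule <- w$cognizers[[observer]]$rule
  succ_for <- function(ctx) {
    vapply(obs_states, function(cs) {
      vapply(seq_len(nrow(obj_grid)), function(r) {
        env <- c(unlist(obj_grid[r, , drop = FALSE]), ctx)
        names(env) <- c(object, names(ctx))
        rule(cs, env)
      }, character(1))
    }, character(nrow(obj_grid)))
  }

  succ <- succ_for(contexts[[1L]])
  if (length(contexts) > 1L) {
    for (ctx in contexts[-1L]) {
      if (!identical(succ_for(ctx), succ)) {
        stop("induced partition depends on the states of: ",
             paste(others, collapse = ", "),
             " -- supply an explicit 'context'")
      }
    }
  }

  succ <- matrix(succ, nrow = nrow(obj_grid),
                 dimnames = list(obj_labels, obs_states))
  blocks <- lapply(obs_states, function(cs) {
    split(obj_labels, succ[, cs])
  })
  names(blocks) <- obs_states
  structure(list(observer = observer, object = object, blocks = blocks),
            class = "discriminability")
}

#' @export
print.discriminability <- function(x, ...) {
  cat("<discriminability> observer '", x$observer, "' on object ",
      paste(x$object, collapse = "+"), "\n", sep = "")
  for (cs in names(x$blocks)) {
    b <- x$blocks[[cs]]
    cat("  observer state ", cs, ": ", length(b), " block(s), sizes ",
        paste(lengths(b), collapse = "/"), "\n", sep = "")
  }
  invisible(x)
}

#' Is a partition perfectly discriminating?
#'
#' @param partition an [induced_partition()] result.
#' @return `TRUE` if every block under every observer state is a singleton
#'   (the Laplace's-demon limit).
#' @export
is_perfect_discrimination <- function(partition) {
  all(vapply(partition$blocks,
             function(b) all(lengths(b) == 1L), logical(1)))
}

#' Attach an external observer to a world
#'
#' An external observer is one-way coupled: its motion rule may read the
#' observed cognizers, but no pre-existing cognizer's rule can read it (their
#' rules are functions of the original member names only).  Consequently the
#' projection of any trajectory onto the original members is identical with and
#' without the observer -- observation "without affecting" the system, the
#' idealised zero-back-action limit.  Back-action is modelled by making the
#' observer an ordinary (internal) member instead.
#'
#' @param w a [world()].
#' @param obs a [cognizer()]; its name must not clash with existing members.
#' @param observed names the observer reads (informational; membership is
#'   checked).
#' @return A new `cs_world` with the observer appended.
#' @export
attach_external_observer <- function(w, obs, observed = w$names) {
  if (!inherits(obs, "cognizer")) stop("'obs' must be a cognizer")
  if (obs$name %in% w$names) {
    stop("cannot attach '", obs$name, "': a cognizer with that name already ",
         "exists, so existing rules could read it (it would be internal)")
  }
  unknown <- setdiff(observed, w$names)
  if (length(unknown)) stop("observed cognizer(s) not in world: ",
                            paste(unknown, collapse = ", "))
  world(c(w$cognizers, list(obs)))
}

#' Sensor--memory observer
#'
#' An observer made of two sub-cognizers: a sensor with a basal state `"0"`
#' that deflects to a measurement value and returns to basal on the next tick
#' (like a neuron firing), and a memory that advances only when the sensor is
#' deflected.  Each measurement is a two-tick cycle
#' `(0, mu_i) -> (k, mu_i) -> (0, mu_{i+1})`; the deflection `0 -> k` is the
#' discriminative cognition that realizes one measurement of the object.
#'
#' @param measure named character vector mapping object state labels to
#'   non-basal sensor values (`"1"`, `"2"`, ...).
#' @param memory_size number of memory states `mu_0 ... mu_{memory_size-1}`;
#'   the memory index advances modulo this (default: unbounded counter).
#' @return An object of class `sensor_memory_observer`.
#' @export
sensor_memory_observer <- function(measure, memory_size = Inf) {
  measure <- vapply(measure, as.character, character(1))
  if (is.null(names(measure)) || any(!nzchar(names(measure)))) {
    stop("'measure' must be a named vector: object state -> sensor value")
  }
  if (any(measure == "0")) stop("sensor value '0' is reserved for the basal state")
  structure(list(measure = measure, memory_size = memory_size),
            class = "sensor_memory_observer")
}

#' Run a sensor--memory observer over an object state sequence
#'
#' Produces the full micro-tick stream, in which every measurement is the
#' two-tick deflect-and-return cycle, and the collapsed stream obtained by
#' removing the non-basal intermediate sensor states so that the observer's
#' states synchronize one-to-one with the object's ticks.
#'
#' @param obs a [sensor_memory_observer()].
#' @param object_states non-empty character vector of object state labels, each
#'   in the domain of the measurement rule.
#' @return A list with `full` and `collapsed` data frames (columns `sensor`,
#'   `memory`), and `n_measurements`.
#' @export
run_sensor_memory <- function(obs, object_states) {
  object_states <- as.character(object_states)
  if (length(object_states) == 0L) stop("object state sequence must be non-empty")
  bad <- setdiff(object_states, names(obs$measure))
  if (length(bad)) {
    stop("object state(s) outside the measurement rule's domain: ",
         paste(unique(bad), collapse = ", "))
  }
  mem_label <- function(i) {
    if (is.finite(obs$memory_size)) i <- i %% obs$memory_size
    paste0("mu", i)
  }
  sensor <- "0"; mem <- 0L
  full <- data.frame(sensor = "0", memory = mem_label(0L),
                     stringsAsFactors = FALSE)
  collapsed <- full
  for (s in object_states) {
    k <- obs$measure[[s]]
    full <- rbind(full, data.frame(sensor = k, memory = mem_label(mem)))
    mem <- mem + 1L
    full <- rbind(full, data.frame(sensor = "0", memory = mem_label(mem)))
    collapsed <- rbind(collapsed,
                       data.frame(sensor = "0", memory = mem_label(mem)))
  }
  list(full = full, collapsed = collapsed,
       n_measurements = length(object_states))
}
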