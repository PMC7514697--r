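# World configuration files, trajectory TSV serialization, scenario bundles.

.config_fail <- function(key, msg) {
  stop("world config error at '", key, "': ", msg, call. = FALSE)
}

#' Read a world from a config file
#'
#' The config is a YAML (or JSON -- YAML is a superset) document:
#'
#' ```yaml
#' cognizers:
#'   - name: bit
#'     states: ["0", "1"]
#'     rule:
#'       - {self: "0", next: "1"}
#'       - {self: "1", next: "0"}
#' initial_state: {bit: "0"}
#' steps: 10
#' ```
#'
#' Each rule row gives the cognizer's own state under `self`, optionally one
#' key per other cognizer, and the successor under `next`; `"*"` is a
#' wildcard and rows match top to bottom.  Rule tables are validated
#' exhaustively for totality and closure at load time (for joint spaces up to
#' `max_validate` states).
#'
#' @param path config file path.
#' @param max_validate joint-space size limit for exhaustive validation; larger
#'   worlds are loaded unvalidated.
#' @return A list with `world`, `u0` (or `NULL`), `steps` (or `NULL`).
#' @export
read_world <- function(path, max_validate = 1e5) {
  if (!file.exists(path)) stop("config file not found: ", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$cognizers)) .config_fail("cognizers", "missing key")
  if (!is.list(doc$cognizers) || length(doc$cognizers) == 0L) {
    .config_fail("cognizers", "must be a non-empty list")
  }
  cogs <- lapply(seq_along(doc$cognizers), function(i) {
    entry <- doc$cognizers[[i]]
    key <- paste0("cognizers[", i, "]")
    if (is.null(entry$name)) .config_fail(paste0(key, ".name"), "missing key")
    if (is.null(entry$states)) .config_fail(paste0(key, ".states"), "missing key")
    if (is.null(entry$rule)) .config_fail(paste0(key, ".rule"), "missing key")
    states <- as.character(unlist(entry$states))
    rows <- lapply(entry$rule, function(r) {
      r <- lapply(r, as.character)
      if (is.null(r[["next"]])) {
        .config_fail(paste0(key, ".rule"), "every row needs a 'next' value")
      }
      if (is.null(r[["self"]])) r[["self"]] <- "*"
      r
    })
    all_cols <- unique(unlist(lapply(rows, names)))
    tab <- as.data.frame(
      lapply(stats::setNames(all_cols, all_cols), function(col)
        vapply(rows, function(r) r[[col]] %||% "*", character(1))),
      check.names = FALSE, stringsAsFactors = FALSE)
    cognizer(as.character(entry$name), states, rule_table(tab))
  })
  w <- world(cogs)
  u0 <- NULL
  if (!is.null(doc$initial_state)) {
    u0 <- vapply(doc$initial_state, as.character, character(1))
    u0 <- tryCatch(world_state(w, u0),
                   error = function(e) .config_fail("initial_state",
                                                   conditionMessage(e)))
  }
  sizes <- vapply(w$cognizers, function(c) c$states$n, numeric(1))
  if (prod(sizes) <= max_validate) {
    tryCatch(validate_world(w, max_states = max_validate),
             error = function(e) .config_fail("cognizers",
                                              conditionMessage(e)))
  }
  steps <- if (!is.null(doc$steps)) {
    s <- suppressWarnings(as.integer(doc$steps))
    if (is.na(s) || s < 0L) .config_fail("steps", "must be a non-negative integer")
    s
  }
  list(world = w, u0 = u0, steps = steps)
}

#' Write / read a trajectory as TSV
#'
#' Tab-separated with a header row: column `t` (0-based tick) then one column
#' per cognizer in declared order.
#'
#' @param traj a [evolve()] trajectory.
#' @param path file path.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(t = 0:(nrow(traj) - 1L), unclass(traj), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @return `read_trajectory()` returns a character matrix with cognizer
#'   columns, usable directly with [events()].
#' @export
read_trajectory <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  if (!"t" %in% names(df)) stop("trajectory TSV lacks a 't' column")
  m <- as.matrix(df[setdiff(names(df), "t")])
  rownames(m) <- NULL
  m
}

#' Run a canonical scenario and write its artifact bundle
#'
#' A scenario config (list or YAML file) names a scenario and its parameters:
#'
#' * `scenario: coin` -- `trials`, `bias`, `seed`, `demon` (attach the
#'   perfectly discriminating observer), `human` (attach the coarse observer).
#' * `scenario: maxwell` -- `n_particles`, `lattice`, `steps`, `demon`, `seed`.
#'
#' The bundle written to `out_dir`: `trajectory.tsv`, `report.json`
#' (probability and entropy estimates), and `run.log` (config echo and counts).
#' Identical configs produce identical bundles.
#'
#' @param config list or path to a YAML config.
#' @param out_dir output directory (created if needed).
#' @return The report list, invisibly.
#' @export
run_scenario <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$scenario)) .config_fail("scenario", "missing key")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)

  if (config$scenario == "coin") {
    trials <- as.integer(config$trials %||% 1000L)
    if (is.na(trials) || trials < 1L) .config_fail("trials", "must be >= 1")
    bias <- as.numeric(config$bias %||% 0.5)
    ct <- coin_toss_world(bias = bias, seed = seed)
    w <- ct$world
    if (isTRUE(config$demon)) w <- attach_external_observer(w, demon_observer(bias))
    if (isTRUE(config$human)) w <- attach_external_observer(w, human_observer())
    u0 <- world_state(w, c(ct$u0, if (isTRUE(config$demon)) c(demon = "idle"),
                           if (isTRUE(config$human)) c(human = "idle")))
    traj <- evolve(w, u0, 2L * trials)
    coin_stream <- events(traj, "coin")
    pats <- coin_patterns()
    p_heads <- p_overall(coin_stream, pats$heads, population = pats$outcome)
    report <- list(scenario = "coin", trials = trials, bias = bias, seed = seed,
                   p_overall_heads = list(numerator = p_heads$numerator,
                                          denominator = p_heads$denominator,
                                          value = p_heads$value))
    if (isTRUE(config$demon)) {
      dstream <- events(traj, "demon")
      pc <- lapply(c("predH", "predT"), function(b) {
        est <- tryCatch(
          p_cog(dstream, event_pattern(to = "obsH"), event_pattern(to = b)),
          error = function(e) NULL)
        if (is.null(est)) NULL
        else list(condition = b, numerator = est$numerator,
                  denominator = est$denominator, value = est$value)
      })
      report$demon_p_cog_heads <- Filter(Negate(is.null), pc)
    }
  } else if (config$scenario == "maxwell") {
    steps <- as.integer(config$steps %||% 2000L)
    mw <- maxwell_world(n_particles = as.integer(config$n_particles %||% 20L),
                        lattice = as.integer(config$lattice %||% 16L),
                        demon = isTRUE(config$demon %||% TRUE), seed = seed)
    traj <- evolve(mw$world, mw$u0, steps)
    lattice <- as.integer(config$lattice %||% 16L)
    stream <- chamber_events(traj, mw$particles, lattice)
    hrep <- h_overall(stream, outcomes = list(event_pattern(to = "L"),
                                              event_pattern(to = "R")))
    report <- list(scenario = "maxwell", steps = steps, seed = seed,
                   demon = isTRUE(config$demon %||% TRUE),
                   h_overall_chamber_bits = hrep$H,
                   p_left = hrep$probabilities[[1L]]$value)
  } else {
    .config_fail("scenario", paste0("unknown scenario '", config$scenario, "'"))
  }

  write_trajectory(traj, file.path(out_dir, "trajectory.tsv"))
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA),
             file.path(out_dir, "report.json"))
  log_lines <- c(
    paste0("cognisys ", as.character(utils::packageVersion("cognisys"))),
    paste0("R ", R.version$major, ".", R.version$minor),
    paste0("config: ", jsonlite::toJSON(config, auto_unbox = TRUE)),
    paste0("trajectory states: ", nrow(traj)),
    paste0("cognizers: ", paste(colnames(traj), collapse = ", ")))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(report)
}
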