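# Exact rational helpers.  Counts from finite trajectories stay far below
# 2^53, so integer arithmetic in doubles is exact here.
.gcd <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

.rational <- function(num, den) {
  if (den == 0) stop("zero denominator")
  g <- .gcd(num, den)
  if (g == 0) g <- 1
  list(num = num / g, den = den / g)
}

.rat_add <- function(x, y) .rational(x$num * y$den + y$num * x$den, x$den * y$den)
.rat_mul <- function(x, y) .rational(x$num * y$num, x$den * y$den)
.rat_eq  <- function(x, y) x$num * y$den == y$num * x$den

#' Probability estimates as exact count ratios
#'
#' Every probability in this package is a relative frequency: a ratio of two
#' event (or state) counts, stored as a reduced integer fraction alongside its
#' floating-point value.  `ptype` records the observer standpoint of the
#' estimate: the meta-observer's state-count ratio, or an external/internal
#' observer's conditioned (`cog`) or pooled (`overall`) event frequency.
#'
#' @param numerator,denominator non-negative counts, `numerator <= denominator`;
#'   kept as the raw counts (not reduced), so the sample size stays visible.
#' @param ptype one of `"meta"`, `"external_cog"`, `"external_overall"`,
#'   `"internal_cog"`, `"internal_overall"`.
#' @return An object of class `prob_estimate` with fields `numerator`,
#'   `denominator`, `value`, `ptype`.
#' @export
prob_estimate <- function(numerator, denominator, ptype = "external_overall") {
  ptype <- match.arg(ptype, c("meta", "external_cog", "external_overall",
                              "internal_cog", "internal_overall"))
  if (denominator <= 0) stop("denominator must be a positive count")
  if (numerator < 0 || numerator > denominator) {
    stop("numerator must lie in [0, denominator]")
  }
  structure(list(numerator = numerator, denominator = denominator,
                 value = numerator / denominator, ptype = ptype),
            class = "prob_estimate")
}

#' @export
print.prob_estimate <- function(x, ...) {
  cat("<prob_estimate ", x$ptype, "> ", format(x$numerator, scientific = FALSE),
      "/", format(x$denominator, scientific = FALSE), " = ",
      format(x$value, digits = 6), "\n", sep = "")
  invisible(x)
}

#' @export
as.double.prob_estimate <- function(x, ...) x$value

#' Event patterns
#'
#' A pattern picks out cognition events `from -> to` in a stream.  Either give
#' `from` / `to` (vectors allowed; `NA` is a wildcard matching anything), or
#' give `pairs`, explicit `"from->to"` codes, for arbitrary event sets (as
#' needed for condition partitions).
#'
#' @param from,to state labels (or `NA` for any).
#' @param pairs character vector of `"from->to"` codes; overrides `from`/`to`.
#' @return An object of class `event_pattern`.
#' @examples
#' event_pattern(to = "H")              # any event ending in H
#' event_pattern(pairs = c("a->b", "c->b"))
#' @export
event_pattern <- function(from = NA, to = NA, pairs = NULL) {
  structure(list(from = from, to = to, pairs = pairs), class = "event_pattern")
}

#' @export
print.event_pattern <- function(x, ...) {
  if (!is.null(x$pairs)) {
    cat("<event_pattern> {", paste(x$pairs, collapse = ", "), "}\n")
  } else {
    f <- if (all(is.na(x$from))) "*" else paste(x$from, collapse = "|")
    t <- if (all(is.na(x$to))) "*" else paste(x$to, collapse = "|")
    cat("<event_pattern> ", f, " -> ", t, "\n", sep = "")
  }
  invisible(x)
}

#' Match events against a pattern
#'
#' @param stream an [events()] stream (or data frame with `from`, `to`).
#' @param pattern an [event_pattern()] (a bare `"from->to"` string or character
#'   vector of such codes is also accepted).
#' @return Logical vector, one entry per event.
#' @export
match_events <- function(stream, pattern) {
  if (is.character(pattern)) pattern <- event_pattern(pairs = pattern)
  if (!inherits(pattern, "event_pattern")) stop("'pattern' must be an event_pattern")
  if (!is.null(pattern$pairs)) {
    return(paste0(stream$from, "->", stream$to) %in% pattern$pairs)
  }
  ok <- rep(TRUE, nrow(stream))
  if (!all(is.na(pattern$from))) ok <- ok & stream$from %in% pattern$from
  if (!all(is.na(pattern$to)))   ok <- ok & stream$to %in% pattern$to
  ok
}

#' Meta-observer probability of a state set
#'
#' The meta-observer discriminates every joint state, so its events are the
#' world's states themselves.  The probability of state set A within reference
#' set X along a trajectory is the count ratio `#A / #X`.  In a deterministic
#' world on a transient (no revisited states) `#A` equals the number of
#' distinct A-states; on a cycle states recur, so the distinct-state counts are
#' reported together with an `all_distinct` flag rather than assumed equal.
#'
#' @param traj a [evolve()] trajectory.
#' @param A,X predicates over joint states: a function taking a named character
#'   vector and returning `TRUE`/`FALSE`, or a character vector of composite
#'   labels (components joined with `"|"` in declared cognizer order).  `A`
#'   must select a subset of what `X` selects.
#' @return A `prob_estimate` of ptype `"meta"` with extra fields
#'   `distinct_A`, `distinct_X`, `all_distinct`.
#' @export
p_meta <- function(traj, A, X = function(u) TRUE) {
  m <- unclass(traj)
  labels <- apply(m, 1L, paste, collapse = "|")
  sel <- function(pred) {
    if (is.function(pred)) {
      vapply(seq_len(nrow(m)), function(r) isTRUE(pred(m[r, ])), logical(1))
    } else {
      labels %in% as.character(pred)
    }
  }
  inA <- sel(A); inX <- sel(X)
  nX <- sum(inX)
  if (nX == 0L) stop("reference set X matches no trajectory state")
  if (any(inA & !inX)) stop("A must be a subset of X")
  est <- prob_estimate(sum(inA), nX, ptype = "meta")
  est$distinct_A <- length(unique(labels[inA]))
  est$distinct_X <- length(unique(labels[inX]))
  est$all_distinct <- (est$distinct_X == nX)
  est
}

#' Overall-cognitions probability of an event
#'
#' `P_overall` of a focal event is the ratio of the number of matching events
#' to the total number of events in a reference population, irrespective of any
#' conditioning cognition.  The reference population defaults to all events in
#' the stream; pass `population` to restrict it (e.g. to the outcome ticks of a
#' repeated-trial cycle).
#'
#' @param stream an [events()] stream.
#' @param target an [event_pattern()].
#' @param population optional [event_pattern()] defining the reference
#'   population; the target is counted within it.
#' @param ptype standpoint tag for the estimate (the estimator itself is
#'   standpoint-agnostic; the tag records how the stream's observer is
#'   attached).
#' @return A `prob_estimate`.
#' @export
p_overall <- function(stream, target, population = NULL,
                      ptype = "external_overall") {
  if (nrow(stream) == 0L) stop("empty event stream")
  pop <- if (is.null(population)) rep(TRUE, nrow(stream))
         else match_events(stream, population)
  if (!any(pop)) stop("empty reference population")
  hit <- match_events(stream, target) & pop
  prob_estimate(sum(hit), sum(pop), ptype = ptype)
}

#' Cognition-conditioned probability of an event
#'
#' `P_cog` of a resultant cognition given an earlier conditioning cognition:
#' the ratio of the number of condition occurrences followed (after `offset`
#' transitions, default the immediately next one) by a matching target, to the
#' number of condition occurrences with a successor slot.  A condition that
#' never occurs leaves the conditional undefined and raises an error -- it is
#' neither 0 nor `NaN`.
#'
#' @param stream an [events()] stream.
#' @param target resultant [event_pattern()].
#' @param condition conditioning [event_pattern()].
#' @param offset positive integer: the target slot follows the condition slot
#'   by this many transitions.
#' @param ptype standpoint tag (`"external_cog"` or `"internal_cog"`).
#' @return A `prob_estimate` with extra field `n_condition`.
#' @export
p_cog <- function(stream, target, condition, offset = 1L,
                  ptype = "external_cog") {
  offset <- as.integer(offset)
  if (is.na(offset) || offset < 1L) stop("'offset' must be >= 1")
  n <- nrow(stream)
  cond <- match_events(stream, condition)
  slots <- which(cond & seq_len(n) + offset <= n)
  if (length(slots) == 0L) {
    stop("undefined conditional: the conditioning cognition never occurs ",
         "(with a successor slot) in the stream")
  }
  hits <- match_events(stream, target)[slots + offset]
  est <- prob_estimate(sum(hits), length(slots), ptype = ptype)
  est$n_condition <- length(slots)
  est
}

#' Total-probability decomposition of an overall probability
#'
#' Decomposes `P_overall(A)` over a family of mutually exclusive, jointly
#' covering conditioning cognitions `B_i`:
#' `sum_i P(A | B_i) P(B_i) = P(A)`.
#' All quantities are exact count ratios over the same reference population
#' (the condition slots that have a target slot `offset` transitions later), so
#' the identity holds with zero rational-arithmetic error, not merely to
#' floating-point tolerance.
#'
#' @param stream an [events()] stream.
#' @param target resultant [event_pattern()].
#' @param conditions list of [event_pattern()]s; over the conditioning slots
#'   they must be pairwise exclusive and jointly exhaustive (validated; slots
#'   violating this are reported).
#' @param offset as in [p_cog()].
#' @return An object of class `total_probability` with the per-condition terms
#'   (each `P(A|B_i)`, `P(B_i)` and their product as reduced fractions), the
#'   exact sum, the directly counted `P_overall(A)`, and `exact_match`.
#' @export
total_probability <- function(stream, target, conditions, offset = 1L) {
  offset <- as.integer(offset)
  n <- nrow(stream)
  if (n <= offset) stop("stream too short for the given offset")
  slots <- seq_len(n - offset)          # conditioning slots with a target slot
  hit_mat <- vapply(conditions, function(p) match_events(stream, p)[slots],
                    logical(length(slots)))
  hit_mat <- matrix(hit_mat, nrow = length(slots))
  cover <- rowSums(hit_mat)
  if (any(cover != 1L)) {
    bad <- slots[cover != 1L]
    stop("conditions must partition the conditioning slots; offending slot(s) t = ",
         paste(utils::head(stream$t[bad], 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "",
         " (matched by ", paste(unique(cover[cover != 1L]), collapse = "/"),
         " conditions)")
  }
  N <- length(slots)
  tgt <- match_events(stream, target)[slots + offset]

  terms <- lapply(seq_along(conditions), function(i) {
    in_i <- hit_mat[, i]
    b <- sum(in_i)
    p_b <- .rational(b, N)
    if (b > 0L) {
      a <- sum(tgt & in_i)
      p_ab <- .rational(a, b)
    } else {
      a <- 0
      p_ab <- NULL                      # conditional undefined, weight zero
    }
    prod <- .rational(a, N)
    list(condition = conditions[[i]], n_condition = b, n_joint = a,
         p_cond = if (!is.null(p_ab)) p_ab, p_b = p_b, product = prod)
  })
  total <- Reduce(.rat_add, lapply(terms, `[[`, "product"), .rational(0, 1))
  p_all <- .rational(sum(tgt), N)
  structure(list(terms = terms, sum = total, p_overall = p_all,
                 n_slots = N, offset = offset,
                 exact_match = .rat_eq(total, p_all)),
            class = "total_probability")
}

#' @export
print.total_probability <- function(x, ...) {
  cat("<total_probability> over", x$n_slots, "conditioning slots (offset",
      x$offset, ")\n")
  for (i in seq_along(x$terms)) {
    tm <- x$terms[[i]]
    pc <- if (is.null(tm$p_cond)) "undef"
          else paste0(tm$p_cond$num, "/", tm$p_cond$den)
    cat(sprintf("  B_%d: P(A|B)=%s  P(B)=%s/%s  term=%s/%s\n", i, pc,
                tm$p_b$num, tm$p_b$den, tm$product$num, tm$product$den))
  }
  cat("  sum = ", x$sum$num, "/", x$sum$den,
      "   P_overall(A) = ", x$p_overall$num, "/", x$p_overall$den,
      "   exact match: ", x$exact_match, "\n", sep = "")
  invisible(x)
}

#' Serialize a probability report to JSON
#'
#' @param x a `prob_estimate` or `total_probability`.
#' @param path optional file; if `NULL` the JSON string is returned.
#' @export
probability_report <- function(x, path = NULL) {
  if (inherits(x, "prob_estimate")) {
    doc <- list(ptype = x$ptype, numerator = x$numerator,
                denominator = x$denominator, value = x$value)
  } else if (inherits(x, "total_probability")) {
    doc <- list(
      ptype = "total_probability",
      numerator = x$sum$num, denominator = x$sum$den,
      value = x$sum$num / x$sum$den,
      terms = lapply(x$terms, function(tm) list(
        n_condition = tm$n_condition, n_joint = tm$n_joint,
        p_b = c(tm$p_b$num, tm$p_b$den),
        product = c(tm$product$num, tm$product$den))),
      exact_match = x$exact_match)
  } else stop("unsupported report object")
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}
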