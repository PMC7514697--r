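#' Annotated symbol sequences
#'
#' The inverse-causality machinery works on sequences of base symbols (the
#' subject's raw percepts) that may carry *foreign* annotation symbols
#' introduced by realization.  An element's identity is its base symbol
#' together with its annotations; the base-symbol projection always equals the
#' original percept sequence (annotations only decorate).
#'
#' @param base character vector of base symbols.
#' @param ann list of character vectors (one per element) of foreign symbols,
#'   in order of introduction; default none.
#' @return An object of class `ic_sequence`.
#' @export
ic_sequence <- function(base, ann = NULL) {
  base <- as.character(base)
  if (length(base) == 0L) stop("sequence must be non-empty")
  if (is.null(ann)) ann <- rep(list(character(0)), length(base))
  if (length(ann) != length(base)) stop("'ann' must have one entry per element")
  structure(list(base = base, ann = ann), class = "ic_sequence")
}

#' @export
length.ic_sequence <- function(x) length(x$base)

# whole-element identities
.ic_ids <- function(x) {
  if (inherits(x, "ic_sequence")) {
    has <- lengths(x$ann) > 0L
    ids <- x$base
    if (any(has)) {
      ids[has] <- mapply(function(b, a)
        paste0("(", b, "|", paste(a, collapse = ","), ")"),
        x$base[has], x$ann[has])
    }
    ids
  } else {
    as.character(x)
  }
}

#' @export
format.ic_sequence <- function(x, ...) .ic_ids(x)

#' @export
as.character.ic_sequence <- function(x, ...) .ic_ids(x)

#' @export
print.ic_sequence <- function(x, ...) {
  cat("<ic_sequence> ", paste(.ic_ids(x), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Parse rendered annotated tokens
#'
#' Inverse of `format.ic_sequence`: accepts tokens like `m0` or `(m1|e0*,e2*)`.
#'
#' @param tokens character vector of rendered tokens.
#' @return An `ic_sequence`.
#' @export
parse_ic_tokens <- function(tokens) {
  base <- character(length(tokens))
  ann <- vector("list", length(tokens))
  for (i in seq_along(tokens)) {
    tk <- tokens[i]
    if (grepl("^\\(.*\\)$", tk)) {
      inner <- sub("^\\((.*)\\)$", "\\1", tk)
      parts <- strsplit(inner, "|", fixed = TRUE)[[1L]]
      if (length(parts) != 2L) stop("malformed annotated token: ", tk)
      base[i] <- parts[1L]
      ann[[i]] <- strsplit(parts[2L], ",", fixed = TRUE)[[1L]]
    } else {
      base[i] <- tk
      ann[[i]] <- character(0)
    }
  }
  ic_sequence(base, ann)
}

#' Check the unique-successor principle
#'
#' Every element of a causal temporal sequence has a unique successor: the
#' element-to-successor relation is a function.  Different elements sharing a
#' successor is allowed (`F(a) = F(b)` with `a != b` does not violate
#' causality); only one element followed by different successors does.  The
#' final element has no successor and can never trigger a violation.
#'
#' @param x a character vector of symbols or an [ic_sequence()]; for annotated
#'   sequences the check runs on whole-element identities.
#' @return A list of violations (empty if the principle holds), each a list
#'   with `element`, its distinct `successors`, and the 1-based `positions` of
#'   its occurrences that have a successor.  Sequences shorter than 2 are
#'   vacuously causal; the result then carries attribute `vacuous = TRUE`.
#' @examples
#' check_unique_successor(c("a", "b", "a", "b"))          # causal
#' check_unique_successor(c("m0", "m1", "m2", "m0", "m1", "m3"))
#' @export
check_unique_successor <- function(x) {
  ids <- .ic_ids(x)
  n <- length(ids)
  if (n < 2L) {
    out <- list()
    attr(out, "vacuous") <- TRUE
    return(out)
  }
  pred <- ids[-n]
  succ <- ids[-1L]
  out <- list()
  for (el in unique(pred)) {
    pos <- which(pred == el)
    ss <- unique(succ[pos])
    if (length(ss) > 1L) {
      out[[length(out) + 1L]] <- list(element = el, successors = ss,
                                      positions = pos)
    }
  }
  out
}

.fresh_symbol <- function(k) paste0("e", k, "*")

# One annotation pass: annotate occurrences of violating elements, grouping
# occurrences that share a successor under one fresh symbol.  Scanning is
# left-to-right, so fresh symbols are numbered in order of introduction.
# Returns NULL when the sequence is already causal at the whole level.
.ic_pass <- function(x, counter) {
  viol <- check_unique_successor(x)
  if (length(viol) == 0L) return(NULL)
  ids <- .ic_ids(x)
  n <- length(ids)
  bad <- unique(vapply(viol, `[[`, character(1), "element"))
  groups <- new.env(parent = emptyenv())
  new_syms <- character(0)
  ann <- x$ann
  for (i in seq_len(n - 1L)) {
    if (!(ids[i] %in% bad)) next
    key <- paste0(ids[i], " ↦ ", ids[i + 1L])
    if (is.null(groups[[key]])) {
      sym <- .fresh_symbol(counter)
      counter <- counter + 1L
      groups[[key]] <- sym
      new_syms <- c(new_syms, sym)
    }
    ann[[i]] <- c(ann[[i]], groups[[key]])
  }
  list(sequence = ic_sequence(x$base, ann), new_symbols = new_syms,
       counter = counter)
}

#' Inverse causality on the percept level (ICM)
#'
#' If the base-symbol sequence violates the unique-successor principle, foreign
#' symbols are introduced so that every annotated element is a unique successor
#' of its predecessor: occurrences of a violating symbol that lead to different
#' successors receive distinct foreign symbols; occurrences sharing a successor
#' share one.  A sequence that already satisfies the principle is returned
#' untouched with an empty reality set.  The derived symbols constitute the
#' directly measured external reality, level 0.
#'
#' @param x character vector of base symbols (or an unannotated
#'   [ic_sequence()]).
#' @return A list with `sequence` (the annotated `ic_sequence`) and `reality`
#'   (character vector of level-0 foreign symbols in introduction order).
#' @examples
#' icm(c("m0", "m1", "m2", "m0", "m1", "m3"))
#' @export
icm <- function(x) {
  if (!inherits(x, "ic_sequence")) x <- ic_sequence(x)
  if (any(lengths(x$ann) > 0L)) stop("icm() expects an unannotated sequence")
  res <- .ic_pass(x, counter = 0L)
  if (is.null(res)) return(list(sequence = x, reality = character(0)))
  list(sequence = res$sequence, reality = res$new_symbols)
}

#' Inverse causality at the whole level (ICW)
#'
#' Repeats the inverse-causality operation on whole elements (base symbol plus
#' annotations) until the sequence satisfies the unique-successor principle at
#' the whole level.  Each pass annotates the elements whose whole identities
#' have non-unique successors, so violations propagate backwards towards the
#' start of the sequence; the first element has no predecessor, which bounds
#' the number of passes by the sequence length.  The full reality set (level 1)
#' contains the level-0 symbols plus everything ICW introduces -- the
#' device-mediated, it-from-bit constitution of reality.
#'
#' @param x an annotated [ic_sequence()] (normally ICM output).
#' @return A list with `sequence` (causal at the whole level) and `reality`
#'   (all foreign symbols present after completion, introduction order).
#' @export
icw <- function(x) {
  if (!inherits(x, "ic_sequence")) x <- ic_sequence(x)
  existing <- unique(unlist(x$ann))
  counter <- length(existing)
  for (pass in seq_len(length(x$base) + 1L)) {
    res <- .ic_pass(x, counter)
    if (is.null(res)) break
    x <- res$sequence
    counter <- res$counter
  }
  if (length(check_unique_successor(x)) > 0L) {
    stop("internal error: ICW failed to terminate on a causal sequence")
  }
  list(sequence = x, reality = c(existing, setdiff(unique(unlist(x$ann)), existing)))
}

#' Realize an internal model from a percept sequence
#'
#' The composition of [icm()] and [icw()]: annotates the sequence until it is
#' causal at the whole level, returning the realized sequence and both reality
#' state sets.  Idempotent -- realizing an already realized sequence changes
#' nothing.
#'
#' @param x character vector of base symbols.
#' @return An object of class `ic_realization`: list with `sequence`
#'   (`ic_sequence`), `reality0` (ICM-derived symbols) and `reality1` (all
#'   foreign symbols, a superset of `reality0`).
#' @examples
#' r <- realize(c("m0", "m1", "m2", "m0", "m1", "m3"))
#' format(r$sequence)
#' @export
realize <- function(x) {
  step1 <- icm(x)
  step2 <- icw(step1$sequence)
  structure(list(sequence = step2$sequence,
                 reality0 = step1$reality,
                 reality1 = step2$reality),
            class = "ic_realization")
}

#' @export
print.ic_realization <- function(x, ...) {
  cat("<ic_realization>\n  sequence: ",
      paste(.ic_ids(x$sequence), collapse = " "), "\n", sep = "")
  cat("  E0* (ICM): {", paste(x$reality0, collapse = ", "), "}\n", sep = "")
  cat("  E1* (ICW): {", paste(x$reality1, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' JSON report of a realization's reality sets
#'
#' @param x an `ic_realization`.
#' @param path optional file; if `NULL` the JSON string is returned.
#' @export
realization_report <- function(x, path = NULL) {
  doc <- list(sequence = .ic_ids(x$sequence),
              reality_level0 = x$reality0,
              reality_level1 = x$reality1)
  json <- jsonlite::toJSON(doc, auto_unbox = FALSE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}
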