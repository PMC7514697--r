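#' Shannon entropy of an event distribution
#'
#' `H = sum_i p_i log2(1/p_i)` in bits, with `0 * log(1/0) := 0`.  The
#' distribution may be numeric probabilities or a list of
#' [prob_estimate()]s; in the latter case the sum-to-one check is exact
#' (rational), otherwise it uses a `1e-9` tolerance.
#'
#' @param p numeric vector of probabilities, or a list of `prob_estimate`s.
#' @return Entropy in bits.
#' @examples
#' shannon_entropy(c(0.5, 0.5))   # 1 bit
#' shannon_entropy(c(1))          # 0 bits
#' @export
shannon_entropy <- function(p) {
  if (is.list(p) && all(vapply(p, inherits, logical(1), "prob_estimate"))) {
    num <- vapply(p, function(e) e$numerator, numeric(1))
    den <- vapply(p, function(e) e$denominator, numeric(1))
    tot <- Reduce(.rat_add, Map(.rational, num, den), .rational(0, 1))
    if (!(tot$num == tot$den)) {
      stop("probabilities must sum to 1 (got ", tot$num, "/", tot$den, ")")
    }
    p <- num / den
  } else {
    p <- as.numeric(p)
    if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
    if (abs(sum(p) - 1) > 1e-9) {
      stop("probabilities must sum to 1 (got ", format(sum(p)), ")")
    }
  }
  pos <- p > 0
  H <- -sum(p[pos] * log2(p[pos]))
  if (H == 0) 0 else H        # avoid IEEE negative zero for degenerate p
}

.entropy_report <- function(H, probs, outcomes, htype, condition = NULL) {
  structure(list(H = H, probabilities = probs, outcomes = outcomes,
                 htype = htype, condition = condition),
            class = "entropy_report")
}

#' @export
print.entropy_report <- function(x, ...) {
  cat("<entropy_report ", x$htype, "> H = ", format(x$H, digits = 6),
      " bits over ", length(x$outcomes), " outcomes\n", sep = "")
  p <- vapply(x$probabilities, function(e) e$value, numeric(1))
  cat("  p = (", paste(format(p, digits = 4), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

.check_outcomes <- function(stream, outcomes, slot_idx) {
  hit <- vapply(outcomes, function(p) match_events(stream, p)[slot_idx],
                logical(length(slot_idx)))
  hit <- matrix(hit, nrow = length(slot_idx))
  cover <- rowSums(hit)
  if (any(cover != 1L)) {
    stop("outcome patterns must be mutually exclusive and exhaustive over ",
         "the relevant slots; offending slot(s) t = ",
         paste(utils::head(stream$t[slot_idx[cover != 1L]], 10L), collapse = ", "))
  }
  hit
}

#' Conditioned entropy of resultant events (H_cog)
#'
#' Shannon entropy of the `P_cog` distribution of resultant events given one
#' particular conditioning cognition: the uncertainty an observer faces under a
#' specific kind of observation (or, for an internal observer, action).  With a
#' perfectly discriminating condition every `P_cog` is 0 or 1 and `H_cog = 0`.
#'
#' @param stream an [events()] stream.
#' @param condition conditioning [event_pattern()].
#' @param outcomes list of [event_pattern()]s, mutually exclusive and
#'   exhaustive over the slots following the condition.
#' @param offset as in [p_cog()].
#' @param htype `"external_cog"` or `"internal_cog"`.
#' @return An `entropy_report`.
#' @export
h_cog <- function(stream, condition, outcomes, offset = 1L,
                  htype = "external_cog") {
  n <- nrow(stream)
  cond <- match_events(stream, condition)
  slots <- which(cond & seq_len(n) + offset <= n)
  if (length(slots) == 0L) {
    stop("undefined conditional: the conditioning cognition never occurs ",
         "(with a successor slot) in the stream")
  }
  hit <- .check_outcomes(stream, outcomes, slots + offset)
  probs <- lapply(seq_along(outcomes), function(i) {
    est <- prob_estimate(sum(hit[, i]), length(slots), ptype = htype)
    est$n_condition <- length(slots)
    est
  })
  .entropy_report(shannon_entropy(probs), probs, outcomes, htype, condition)
}

#' Overall entropy of events (H_overall)
#'
#' Shannon entropy of the `P_overall` distribution of events over a reference
#' population, irrespective of conditioning: the diversity (disorder) of what
#' the observer experiences across all its cognitions.
#'
#' @param stream an [events()] stream.
#' @param outcomes list of [event_pattern()]s, mutually exclusive and
#'   exhaustive over the reference population.
#' @param population optional [event_pattern()] restricting the reference
#'   population (default: all events).
#' @param htype `"external_overall"` or `"internal_overall"`.
#' @return An `entropy_report`.
#' @export
h_overall <- function(stream, outcomes, population = NULL,
                      htype = "external_overall") {
  pop <- if (is.null(population)) rep(TRUE, nrow(stream))
         else match_events(stream, population)
  slots <- which(pop)
  if (length(slots) == 0L) stop("empty reference population")
  hit <- .check_outcomes(stream, outcomes, slots)
  probs <- lapply(seq_along(outcomes), function(i)
    prob_estimate(sum(hit[, i]), length(slots), ptype = htype))
  .entropy_report(shannon_entropy(probs), probs, outcomes, htype)
}

#' Amount of information as an entropy difference
#'
#' `I = H_ref - H_new`: the entropy reduction achieved by the second cognition
#' (observation, or altered cognitive property) relative to the first.  The
#' sign is kept -- a coarser second cognition yields negative information.
#'
#' @param H_ref,H_new two `entropy_report`s of the same `htype`.
#' @return Information in bits.
#' @export
info_amount <- function(H_ref, H_new) {
  if (!inherits(H_ref, "entropy_report") || !inherits(H_new, "entropy_report")) {
    stop("arguments must be entropy_report objects")
  }
  if (H_ref$htype != H_new$htype) {
    stop("entropy types differ (", H_ref$htype, " vs ", H_new$htype,
         "); amounts of information compare like with like")
  }
  H_ref$H - H_new$H
}

#' Condition-averaged conditional entropy
#'
#' `sum_i P(B_i) H_cog(. | B_i)` over a covering family of conditioning
#' cognitions: the average remaining uncertainty about resultant events once
#' the conditioning cognition is known.  Refining the condition partition never
#' increases this value (conditioning reduces average uncertainty); in the
#' all-singleton (Laplace's demon) limit it reaches 0.
#'
#' @param stream an [events()] stream.
#' @param conditions list of [event_pattern()]s partitioning the conditioning
#'   slots (validated as in [total_probability()]).
#' @param outcomes list of exhaustive, exclusive outcome patterns.
#' @param offset as in [p_cog()].
#' @return Average conditional entropy in bits, with attribute `"terms"`.
#' @export
expected_h_cog <- function(stream, conditions, outcomes, offset = 1L) {
  n <- nrow(stream)
  slots <- seq_len(n - offset)
  if (length(slots) == 0L) stop("stream too short for the given offset")
  hit <- vapply(conditions, function(p) match_events(stream, p)[slots],
                logical(length(slots)))
  hit <- matrix(hit, nrow = length(slots))
  cover <- rowSums(hit)
  if (any(cover != 1L)) {
    stop("conditions must partition the conditioning slots (",
         sum(cover != 1L), " slot(s) covered ",
         paste(unique(cover[cover != 1L]), collapse = "/"), " times)")
  }
  N <- length(slots)
  terms <- lapply(seq_along(conditions), function(i) {
    b <- sum(hit[, i])
    if (b == 0L) return(list(weight = 0, H = 0))
    rep_i <- h_cog(stream, conditions[[i]], outcomes, offset = offset)
    list(weight = b / N, H = rep_i$H)
  })
  val <- sum(vapply(terms, function(tm) tm$weight * tm$H, numeric(1)))
  attr(val, "terms") <- terms
  val
}

#' Serialize an entropy report to JSON
#'
#' @param x an `entropy_report`.
#' @param path optional file; if `NULL` the JSON string is returned.
#' @export
entropy_report_json <- function(x, path = NULL) {
  doc <- list(htype = x$htype, H_bits = x$H,
              probabilities = lapply(x$probabilities, function(e)
                list(numerator = e$numerator, denominator = e$denominator,
                     value = e$value)))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}
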