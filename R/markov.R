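#' Fit a two-state Markov chain to binary quiescence sequences
#'
#' Maximum-likelihood transition probabilities from pooled transition counts
#' across animals, optionally regularized with a pseudocount added to each of
#' the four counts. This is the surrogate-null generator: a hidden Markov
#' model with identity emissions on a binary observable is exactly a
#' first-order two-state chain, so fitting transition counts retains the
#' temporal bout structure of the real behavior.
#'
#' @param data A data frame with a binary state column, one sequence per
#'   animal (rows in time order within `animal_id`); a bare annotation from
#'   [annotate_quiescence()] works directly. A data frame without
#'   `animal_id` is one sequence.
#' @param state Binary state column (default `quiescent`).
#' @param pseudocount Non-negative count added to each transition cell.
#'   Default 0: a state never visited is then a degenerate-fit error rather
#'   than being silently regularized.
#' @param n_sims Default number of null replicates carried by the fit.
#' @param seed Seed recorded for downstream simulation.
#' @return A `markov_null` object with `transition_matrix` (2x2,
#'   row-stochastic, states ordered active then quiescent), `p_enter`,
#'   `p_exit`, `stationary`, `counts`, `n_sims`, `seed`.
#' @examples
#' fit_markov_chain(tibble::tibble(quiescent = c(0, 0, 1, 1, 0)))
#' @export
fit_markov_chain <- function(data, state = quiescent, pseudocount = 0,
                             n_sims = 10000, seed = NULL) {
  st <- enquo(state)
  if (pseudocount < 0) {
    abort("`pseudocount` must be >= 0.", class = "quiescreen_parameter_error")
  }
  if (!"animal_id" %in% names(data)) data$animal_id <- "animal_1"
  seqs <- lapply(split(data, data$animal_id, drop = TRUE),
                 function(df) state_to_int(dplyr::pull(df, !!st)))
  if (!any(vapply(seqs, length, integer(1)) >= 2L)) {
    abort("need at least one sequence with >= 2 time points.",
          class = "quiescreen_input_error")
  }
  counts <- matrix(pseudocount, 2L, 2L,
                   dimnames = list(from = c("active", "quiescent"),
                                   to = c("active", "quiescent")))
  for (s in seqs) {
    if (length(s) < 2L || anyNA(s)) s <- s[!is.na(s)]
    if (length(s) < 2L) next
    from <- s[-length(s)] + 1L
    to <- s[-1L] + 1L
    for (k in seq_along(from)) counts[from[k], to[k]] <- counts[from[k], to[k]] + 1
  }
  if (any(rowSums(counts) == 0)) {
    missing_state <- rownames(counts)[rowSums(counts) == 0][1L]
    abort(sprintf("degenerate fit: state `%s` never observed and pseudocount is 0.",
                  missing_state),
          class = "quiescreen_degenerate_fit_error")
  }
  tm <- counts / rowSums(counts)
  p_enter <- tm[1L, 2L]
  p_exit <- tm[2L, 1L]
  # closed-form stationary distribution of the 2-state chain
  stationary <- c(active = p_exit, quiescent = p_enter) / (p_enter + p_exit)
  structure(list(transition_matrix = tm, p_enter = p_enter, p_exit = p_exit,
                 stationary = stationary, counts = counts,
                 n_sims = as.integer(n_sims), seed = seed),
            class = "markov_null")
}

#' @export
print.markov_null <- function(x, ...) {
  cat("<markov_null> two-state quiescence chain\n")
  cat(sprintf("  p_enter = %.4g, p_exit = %.4g, stationary quiescent fraction = %.4g\n",
              x$p_enter, x$p_exit, x$stationary["quiescent"]))
  invisible(x)
}

#' @rdname fit_markov_chain
#' @param x A `markov_null` object.
#' @param ... Unused.
#' @method tidy markov_null
#' @export
tidy.markov_null <- function(x, ...) {
  tibble::tibble(
    from = rep(rownames(x$transition_matrix), each = 2L),
    to = rep(colnames(x$transition_matrix), 2L),
    probability = as.vector(t(x$transition_matrix)),
    n = as.vector(t(x$counts)))
}

# Draw one synthetic binary vector from a fitted chain on the current stream.
draw_null_vector <- function(null, n_steps) {
  generate_state_sequence(null$p_enter, null$p_exit, n_steps)
}

# Re-apply the minimum-bout-duration rule to a synthetic state vector so it
# is a bona fide quiescence annotation: quiescent runs not strictly longer
# than min_duration_s are set active, exactly as in bout detection.
filter_short_bouts <- function(s, sample_rate_hz, min_duration_s) {
  r <- rle(s == 1L)
  keep <- r$values & (r$lengths / sample_rate_hz > min_duration_s * (1 + 1e-9))
  as.integer(rep.int(keep, r$lengths))
}
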