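# Scalar QMI primitive: mean normalized fluorescence over quiescent points
# minus the mean over active points. NA trace values are excluded points.
qmi_vec <- function(f_norm, state) {
  state <- state_to_int(state)
  if (length(f_norm) != length(state)) {
    abort("trace and state must be aligned on the same time base.",
          class = "quiescreen_input_error")
  }
  inc <- !is.na(f_norm) & !is.na(state)
  q <- sum(inc & state == 1L)
  a <- sum(inc & state == 0L)
  qmi <- if (q >= 1L && a >= 1L) {
    mean(f_norm[inc & state == 1L]) - mean(f_norm[inc & state == 0L])
  } else NA_real_
  list(qmi = qmi, n_quiescent = q, n_active = a)
}

#' Quiescence-modulation index (QMI)
#'
#' The QMI of a neuron in one recording is the mean of its mean-normalized
#' fluorescence over time points inside quiescent bouts minus the mean over
#' active time points:
#' \deqn{QMI = \frac{1}{Q}\sum_{q} F_q - \frac{1}{A}\sum_{a} F_a}
#' where \eqn{Q} and \eqn{A} count quiescent and active time points. Neurons
#' consistently more active during quiescence have positive QMI; neurons
#' inhibited during quiescence have negative QMI. The index is invariant to
#' positive rescaling of the raw fluorescence (via mean normalization) and
#' changes sign when the state labels are inverted.
#'
#' @param data Data frame holding (per group, if grouped) one normalized
#'   trace and its aligned binary quiescence state.
#' @param value Normalized trace column (default `f_norm`).
#' @param state Binary state column, 1 = quiescent (default `quiescent`).
#' @return One row per group: `qmi`, `n_quiescent`, `n_active`. Observations
#'   with no quiescent or no active time points are dropped with a warning
#'   (their QMI is undefined).
#' @examples
#' compute_qmi(tibble::tibble(f_norm = c(2, 0), quiescent = c(1, 0)))
#' @export
compute_qmi <- function(data, value = f_norm, state = quiescent) {
  val <- enquo(value); st <- enquo(state)
  grouped <- if (dplyr::is_grouped_df(data)) data else dplyr::group_by(data)
  out <- grouped |>
    dplyr::summarise(.res = list(qmi_vec(!!val, !!st)), .groups = "drop") |>
    tidyr::unnest_wider(".res")
  bad <- is.na(out$qmi) & (out$n_quiescent == 0L | out$n_active == 0L)
  if (any(bad)) {
    warn(sprintf("%d observation(s) dropped: QMI undefined (no quiescent or no active time points).",
                 sum(bad)))
    out <- out[!bad, , drop = FALSE]
  }
  out
}
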