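#' Empirical p-value from the rank among simulated statistics
#'
#' Two-tailed rank-based p-value: the smaller of the two tail counts
#' (simulations at least / at most as extreme as the real value, ties
#' inclusive), floored at one count, divided by the number of simulations. A
#' real value more extreme than all 10,000 simulations therefore gets
#' p = 0.0001. The doubled-tail variant (`tail = "doubled"`) multiplies this
#' by two, capped at 1.
#'
#' Under a continuous null the min-tail p-value is uniform on (0, 1/2], i.e.
#' anti-conservative by a factor of two relative to a nominal uniform;
#' calibration checks in this package account for that.
#'
#' @param real Observed statistic(s); vectorized.
#' @param sims Numeric vector of simulated statistics under the null.
#' @param tail `"min"` (default) or `"doubled"`.
#' @return Numeric p-value(s) in `[1/length(sims), 1]`.
#' @examples
#' empirical_pvalue(11, sims = 1:10 / 10)   # more extreme than all sims
#' empirical_pvalue(8.5, sims = 1:10)       # min(2, 8) / 10
#' @export
empirical_pvalue <- function(real, sims, tail = c("min", "doubled")) {
  tail <- match.arg(tail)
  if (length(sims) < 1L) {
    abort("`sims` must contain at least one simulated value.",
          class = "quiescreen_input_error")
  }
  if (anyNA(sims) || anyNA(real)) {
    abort("`real` and `sims` must not contain NA.", class = "quiescreen_input_error")
  }
  n <- length(sims)
  p <- vapply(real, function(r) {
    ge <- sum(sims >= r)
    le <- sum(sims <= r)
    max(1L, min(ge, le)) / n
  }, numeric(1))
  if (tail == "doubled") p <- pmin(1, 2 * p)
  p
}

#' Benjamini-Hochberg adjustment with significance flags
#'
#' Standard step-up false-discovery-rate control: p-values are sorted
#' ascending, `q_i = min_{j >= i} (p_j * m / j)` clipped at 1, and a test is
#' flagged significant iff its q-value is at most the FDR level.
#'
#' @param p P-values, all in (0, 1].
#' @param fdr FDR level (default 0.05).
#' @return A tibble `p_value`, `q_value`, `significant`, in input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p, fdr = 0.05) {
  if (length(p) == 0L) {
    return(tibble::tibble(p_value = numeric(), q_value = numeric(),
                          significant = logical()))
  }
  if (anyNA(p) || any(p <= 0 | p > 1)) {
    abort("p-values must lie in (0, 1].", class = "quiescreen_input_error")
  }
  stopifnot(fdr > 0, fdr < 1)
  q <- p.adjust(p, method = "BH")
  tibble::tibble(p_value = p, q_value = q, significant = q <= fdr)
}

#' Configuration of the quiescence-modulation screen
#'
#' @param min_observations Minimum number of per-animal units a class needs
#'   to be tested. Default 4 — classes observed more than 3 times across
#'   animals.
#' @param min_confidence Minimum identification confidence (1-5 scale);
#'   observations below it are excluded. Default 3.
#' @param fdr False-discovery-rate level for the flags. Default 0.05.
#' @param n_sims Number of surrogate replicates. Default 10,000.
#' @param seed Root seed for the surrogate simulation.
#' @param pseudocount Pseudocount for the Markov-chain fit.
#' @param lr_merge `"mean"` or `"separate"`, see [merge_lr()].
#' @param tail `"min"` or `"doubled"`, see [empirical_pvalue()].
#' @param max_retries Bound on redraws of degenerate surrogate vectors per
#'   replicate and animal.
#' @return A `screen_config` list.
#' @export
screen_config <- function(min_observations = 4, min_confidence = 3,
                          fdr = 0.05, n_sims = 10000, seed = NULL,
                          pseudocount = 0, lr_merge = c("mean", "separate"),
                          tail = c("min", "doubled"), max_retries = 100) {
  stopifnot(fdr > 0, fdr < 1)
  structure(list(min_observations = assert_count(min_observations, "min_observations"),
                 min_confidence = assert_count(min_confidence, "min_confidence"),
                 fdr = fdr, n_sims = assert_count(n_sims, "n_sims"),
                 seed = seed, pseudocount = pseudocount,
                 lr_merge = match.arg(lr_merge), tail = match.arg(tail),
                 max_retries = assert_count(max_retries, "max_retries")),
            class = "screen_config")
}

# ---- internal machinery ---------------------------------------------------

# Per-animal unit matrices: list(animal -> list(U = units x T matrix of
# normalized traces (NA = excluded point), units = tibble(unit_id,
# class_name, dv))), plus per-animal state vectors from the annotation.
build_unit_matrices <- function(units) {
  lapply(split(units, units$animal_id, drop = TRUE), function(df) {
    wide <- df |>
      dplyr::arrange(.data$unit_id, .data$t_index) |>
      tidyr::pivot_wider(id_cols = "unit_id", names_from = "t_index",
                         values_from = "f_norm")
    U <- as.matrix(wide[, -1L, drop = FALSE])
    rownames(U) <- wide$unit_id
    key <- df |> dplyr::distinct(.data$unit_id, .data$class_name, .data$dv)
    list(U = U[key$unit_id, , drop = FALSE], units = key)
  })
}

# Draw n_sims valid surrogate vectors for one animal as a T x n_sims matrix.
# When a sampling rate is supplied, each raw chain draw is post-processed
# with the minimum-bout-duration rule so synthetic vectors have the same
# bout structure a real annotation can have. A vector is valid when every
# unit retains >= 1 quiescent and >= 1 active included time point; invalid
# draws (including filtered vectors left with no bout) are redrawn
# immediately (bounded).
draw_null_matrix <- function(null, n_steps, n_sims, W, max_retries, animal_id,
                             sample_rate_hz = NULL,
                             criteria = bout_criteria()) {
  S <- matrix(0L, n_steps, n_sims)
  need_mask <- !is.null(W)
  for (r in seq_len(n_sims)) {
    tries <- 0L
    repeat {
      s <- draw_null_vector(null, n_steps)
      if (!is.null(sample_rate_hz)) {
        s <- filter_short_bouts(s, sample_rate_hz, criteria$min_duration_s)
      }
      ok <- if (need_mask) {
        q <- as.vector(W %*% s)
        all(q >= 1) && all(rowSums(W) - q >= 1)
      } else {
        sum(s) >= 1L && sum(s) <= n_steps - 1L
      }
      if (ok) break
      tries <- tries + 1L
      if (tries > max_retries) {
        abort(sprintf("surrogate simulation failed for animal `%s`: %d consecutive degenerate vectors.",
                      animal_id, max_retries),
              class = "quiescreen_simulation_error")
      }
    }
    S[, r] <- s
  }
  S
}

# QMI of every unit against every surrogate column, as a units x n_sims matrix.
qmi_against_states <- function(U, S) {
  na <- is.na(U)
  U0 <- U; U0[na] <- 0
  W <- 1 - na
  M <- U0 %*% S           # units x n_sims sums over quiescent points
  QU <- W %*% S           # included quiescent counts
  AU <- rowSums(W) - QU
  M / QU - (rowSums(U0) - M) / AU
}

#' Simulate the surrogate-null distribution of per-class mean QMIs
#'
#' For each replicate, one synthetic binary quiescence vector is drawn per
#' animal from the fitted chain (initial state from its stationary
#' distribution) and shared by all classes — preserving cross-class
#' dependence. Each unit's QMI is recomputed against its animal's synthetic
#' vector and averaged across the class's units, giving one simulated mean
#' QMI per class per replicate. Replicates in which any unit would have zero
#' quiescent or zero active time points are redrawn for that animal, up to
#' `max_retries` consecutive redraws.
#'
#' Reproducibility contract: the vectors for the i-th animal (animals in
#' sorted `animal_id` order) are drawn sequentially from a stream seeded
#' `sub_seed(seed, i)`.
#'
#' When `sample_rate_hz` is supplied, every raw chain draw is post-processed
#' with the same strict minimum-bout-duration rule as the real annotation
#' (quiescent runs not exceeding `criteria$min_duration_s` are set active),
#' so the synthetic vectors are bona fide quiescence annotations with the
#' bout structure the detection rule permits; a filtered vector left with no
#' quiescent point is redrawn like any other degenerate draw. Without a
#' sampling rate the raw chain vectors are used.
#'
#' @param units Long unit-trace tibble from [merge_lr()] (columns
#'   `animal_id`, `unit_id`, `class_name`, `dv`, `t_index`, `f_norm`).
#' @param null A `markov_null` fit from [fit_markov_chain()].
#' @param n_sims Number of replicates (default: the fit's `n_sims`).
#' @param seed Root seed (default: the fit's `seed`).
#' @param max_retries Redraw bound per replicate and animal.
#' @param sample_rate_hz Sampling rate of the trace time base — a single
#'   value or a named per-animal vector — enabling the bout-duration filter;
#'   `NULL` (default) disables it.
#' @param criteria [bout_criteria()] whose `min_duration_s` the filter uses.
#' @return A tibble `class_name`, `dv`, `sim`, `mean_qmi` with
#'   `n_sims` rows per class.
#' @export
simulate_null_qmis <- function(units, null, n_sims = NULL, seed = NULL,
                               max_retries = 100, sample_rate_hz = NULL,
                               criteria = bout_criteria()) {
  stopifnot(inherits(null, "markov_null"))
  n_sims <- assert_count(n_sims %||% null$n_sims, "n_sims")
  seed <- seed %||% null$seed
  sims <- simulate_null_qmis_matrix(units, null, n_sims, seed, max_retries,
                                    sample_rate_hz, criteria)
  tibble::tibble(class_name = rep(sims$classes$class_name, each = n_sims),
                 dv = rep(sims$classes$dv, each = n_sims),
                 sim = rep(seq_len(n_sims), nrow(sims$classes)),
                 mean_qmi = as.vector(t(sims$mat)))
}

# Matrix core shared with run_screen: returns list(classes = tibble(class_name,
# dv, n_units), mat = classes x n_sims matrix of simulated mean QMIs).
simulate_null_qmis_matrix <- function(units, null, n_sims, seed, max_retries,
                                      sample_rate_hz = NULL,
                                      criteria = bout_criteria()) {
  assert_columns(units, c("animal_id", "unit_id", "class_name", "dv",
                          "t_index", "f_norm"), "unit table")
  by_animal <- build_unit_matrices(units)
  animal_ids <- sort(names(by_animal))
  acc <- NULL  # running sum of per-unit QMIs aggregated by class
  all_units <- list()
  per_animal_qmis <- list()
  for (i in seq_along(animal_ids)) {
    a <- animal_ids[i]
    ua <- by_animal[[a]]
    n_steps <- ncol(ua$U)
    W <- if (anyNA(ua$U)) (1 - is.na(ua$U)) else NULL
    rate_a <- if (is.null(sample_rate_hz)) NULL else if
      (length(sample_rate_hz) == 1L && is.null(names(sample_rate_hz)))
      unname(sample_rate_hz) else unname(sample_rate_hz[a])
    S <- with_seed_or_not(if (is.null(seed)) NULL else sub_seed(seed, i),
                          draw_null_matrix(null, n_steps, n_sims, W,
                                           max_retries, a, rate_a, criteria))
    per_animal_qmis[[a]] <- qmi_against_states(ua$U, S)
    all_units[[a]] <- ua$units
  }
  units_tbl <- dplyr::bind_rows(all_units)
  qmi_mat <- do.call(rbind, per_animal_qmis)
  cls <- paste(units_tbl$class_name, units_tbl$dv, sep = "|")
  sums <- rowsum(qmi_mat, cls)
  counts <- as.vector(table(cls)[rownames(sums)])
  mat <- sums / counts
  key <- units_tbl |>
    dplyr::mutate(.cls = cls) |>
    dplyr::distinct(.data$.cls, .data$class_name, .data$dv)
  key <- key[match(rownames(sums), key$.cls), ]
  classes <- tibble::tibble(class_name = key$class_name, dv = key$dv,
                            n_units = counts)
  list(classes = classes, mat = mat)
}
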