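# Delimited-text interchange formats. All tables are comma-separated with a
# header row, "NA" as the missing-value token, and time in seconds as floats.

#' Read and write per-animal behavior tables
#'
#' The behavior table has columns `animal_id`, `time_s`, `speed_mm_s`,
#' `curvature_deriv_rad_s`, `pumping_hz`, one row per time point. On read,
#' each animal's timestamps are validated for strictly increasing, regular
#' sampling; offending rows are named in the error.
#'
#' @param path File path.
#' @return `read_behavior_table()` returns a validated behavior tibble.
#' @export
read_behavior_table <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE, na = "NA")
  assert_columns(tbl, c("animal_id", "time_s", "speed_mm_s", "pumping_hz"),
                 sprintf("behavior table `%s`", path))
  if (!"curvature_deriv_rad_s" %in% names(tbl)) tbl$curvature_deriv_rad_s <- 0
  for (col in c("time_s", "speed_mm_s", "curvature_deriv_rad_s", "pumping_hz")) {
    if (!is.numeric(tbl[[col]])) {
      abort(sprintf("column `%s` of `%s` is not numeric.", col, path),
            class = "quiescreen_format_error")
    }
  }
  for (id in unique(tbl$animal_id)) {
    ts <- tbl$time_s[tbl$animal_id == id]
    if (anyDuplicated(ts)) {
      abort(sprintf("duplicate timestamps for animal `%s` in `%s`.", id, path),
            class = "quiescreen_format_error")
    }
    check_regular_times(ts, what = sprintf("behavior of animal `%s` in `%s`", id, path))
  }
  tibble::as_tibble(tbl)
}

#' @rdname read_behavior_table
#' @param data Behavior tibble to write.
#' @export
write_behavior_table <- function(data, path) {
  assert_columns(data, c("animal_id", "time_s", "speed_mm_s",
                         "curvature_deriv_rad_s", "pumping_hz"),
                 "behavior table")
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Read and write trace matrices with their label tables
#'
#' One matrix file per animal: rows are neurons, columns are time points
#' (header `t0, t1, ...`), first column `neuron_id`. The label table has one
#' row per neuron: `neuron_id`, `class_name`, `lr`, `dv`, `confidence`
#' (1-5, `NA` for unidentified neurons). Every label row must reference a
#' matrix row. Raw traces are returned; normalization happens downstream.
#'
#' @param matrix_path,label_path File paths.
#' @param animal_id Identifier attached to the observations.
#' @return `read_trace_matrix()` returns a list with `traces` (long tibble
#'   `animal_id`, `neuron_id`, `t_index`, `f`) and `labels`.
#' @export
read_trace_matrix <- function(matrix_path, label_path, animal_id = "animal_1") {
  mat <- readr::read_csv(matrix_path, show_col_types = FALSE, progress = FALSE,
                          na = "NA")
  assert_columns(mat, "neuron_id", sprintf("trace matrix `%s`", matrix_path))
  labels <- readr::read_csv(label_path, show_col_types = FALSE, progress = FALSE,
                            na = "NA",
                            col_types = readr::cols(
                              class_name = readr::col_character(),
                              lr = readr::col_character(),
                              dv = readr::col_character()))
  assert_columns(labels, c("neuron_id", "class_name", "lr", "dv", "confidence"),
                 sprintf("label table `%s`", label_path))
  bad <- setdiff(labels$neuron_id, mat$neuron_id)
  if (length(bad) > 0L) {
    abort(sprintf("label table `%s` references neuron(s) absent from the matrix: %s.",
                  label_path, paste(head(bad, 5L), collapse = ", ")),
          class = "quiescreen_format_error")
  }
  conf <- labels$confidence[!is.na(labels$confidence)]
  if (length(conf) > 0L && (!is.numeric(labels$confidence) || any(!conf %in% 1:5))) {
    abort(sprintf("confidence scores in `%s` must be integers 1-5.", label_path),
          class = "quiescreen_format_error")
  }
  n_t <- ncol(mat) - 1L
  traces <- tibble::tibble(
    animal_id = animal_id,
    neuron_id = rep(mat$neuron_id, each = n_t),
    t_index = rep(seq_len(n_t) - 1L, times = nrow(mat)),
    f = as.vector(t(as.matrix(mat[, -1L]))))
  labels$animal_id <- animal_id
  list(traces = traces,
       labels = tibble::as_tibble(labels)[, c("animal_id", "neuron_id",
                                              "class_name", "lr", "dv",
                                              "confidence")])
}

#' @rdname read_trace_matrix
#' @param traces Long trace tibble for one animal (`neuron_id`, `t_index`, `f`).
#' @param labels Label tibble for the same neurons.
#' @export
write_trace_matrix <- function(traces, labels, matrix_path, label_path) {
  wide <- traces |>
    dplyr::mutate(t = paste0("t", .data$t_index)) |>
    dplyr::select("neuron_id", "t", "f") |>
    tidyr::pivot_wider(names_from = "t", values_from = "f")
  readr::write_csv(wide, matrix_path, progress = FALSE)
  readr::write_csv(labels[, c("neuron_id", "class_name", "lr", "dv", "confidence")],
                   label_path, progress = FALSE)
  invisible(matrix_path)
}

#' Write and re-read a full dataset directory
#'
#' Lays a dataset out as `behavior.csv`, per-animal `traces_<animal>.csv` /
#' `labels_<animal>.csv`, and a `config.json` sidecar echoing the generating
#' parameters and seed, so synthetic runs exercise the same I/O path as real
#' data.
#'
#' @param dataset A `quiescence_dataset`.
#' @param dir Output directory (created if needed).
#' @return `write_dataset()` returns `dir`; `read_dataset()` a list with
#'   `behavior`, `traces`, `labels` (annotation is recomputed from behavior
#'   with [annotate_quiescence()], not stored).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_behavior_table(dataset$behavior, file.path(dir, "behavior.csv"))
  for (id in unique(dataset$labels$animal_id)) {
    tr <- dataset$traces[dataset$traces$animal_id == id, ]
    lb <- dataset$labels[dataset$labels$animal_id == id, ]
    write_trace_matrix(tr, lb,
                       file.path(dir, sprintf("traces_%s.csv", id)),
                       file.path(dir, sprintf("labels_%s.csv", id)))
  }
  cfg <- dataset$config
  if (!is.null(cfg)) {
    echo <- cfg[c("n_animals", "duration_s", "sample_rate_hz",
                  "behavior_upsample", "p_enter", "p_exit", "noise_sd",
                  "baseline_mean", "seed")]
    echo$effect_map <- cfg$effect_map
    jsonlite::write_json(echo, file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  behavior <- read_behavior_table(file.path(dir, "behavior.csv"))
  ids <- sort(unique(behavior$animal_id))
  parts <- lapply(ids, function(id) {
    read_trace_matrix(file.path(dir, sprintf("traces_%s.csv", id)),
                      file.path(dir, sprintf("labels_%s.csv", id)),
                      animal_id = id)
  })
  list(behavior = behavior,
       traces = dplyr::bind_rows(lapply(parts, `[[`, "traces")),
       labels = dplyr::bind_rows(lapply(parts, `[[`, "labels")))
}

#' Write screen outputs
#'
#' Writes the per-class result table (`screen_results.csv`), the
#' class-by-animal QMI heatmap matrix (`qmi_matrix.csv`, explicit `NA` for
#' unobserved cells) and a JSON sidecar echoing the configuration (seed,
#' n_sims, thresholds).
#'
#' @param screen A `quiescence_screen`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_screen_results <- function(screen, dir) {
  stopifnot(inherits(screen, "quiescence_screen"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(screen$results, file.path(dir, "screen_results.csv"),
                   progress = FALSE)
  readr::write_csv(screen$qmi_matrix, file.path(dir, "qmi_matrix.csv"),
                   na = "NA", progress = FALSE)
  cfg <- screen$config
  jsonlite::write_json(
    list(min_observations = cfg$min_observations,
         min_confidence = cfg$min_confidence, fdr = cfg$fdr,
         n_sims = cfg$n_sims, seed = cfg$seed, tail = cfg$tail,
         lr_merge = cfg$lr_merge,
         p_enter = screen$null$p_enter, p_exit = screen$null$p_exit),
    file.path(dir, "screen_config.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}
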