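# broom-style tidiers for the result objects.

#' Tidy an RZ screen
#'
#' @param x `rz_screen` tibble.
#' @param ... Unused.
#' @return Plain tibble, one row per model x threshold.
#' @export
tidy.rz_screen <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "rz_screen")
  out
}

#' One-row summary of an RZ screen
#'
#' @inheritParams tidy.rz_screen
#' @return Tibble with the model count, threshold count and the best
#'   model/threshold by RZ score.
#' @export
glance.rz_screen <- function(x, ...) {
  d <- as_tibble(x)
  best <- d[which.max(d$rz), ]
  tibble(n_models = length(unique(d$model_id)),
         n_thresholds = length(unique(d$threshold_position)),
         best_model_id = best$model_id,
         best_pattern = best$pattern,
         best_threshold = best$threshold_position,
         best_rz = best$rz)
}

#' Tidy an interdependency test
#'
#' @param x `interdep_test` tibble.
#' @param ... Unused.
#' @return Plain tibble, one row per hypothesis.
#' @export
tidy.interdep_test <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "interdep_test")
  out
}

#' One-row summary of an interdependency test
#'
#' @inheritParams tidy.interdep_test
#' @return Tibble with hypothesis count, null-set count and the number of
#'   two-tailed significant hypotheses at each flagged level.
#' @export
glance.interdep_test <- function(x, ...) {
  d <- as_tibble(x)
  sig_cols <- grep("^sig_", names(d), value = TRUE)
  out <- tibble(n_hypotheses = nrow(d), n_sets = attr(x, "n_sets"),
                n_sites = attr(x, "n_sites"))
  for (s in sig_cols) out[[paste0("n_", s)]] <- sum(d[[s]])
  out
}

#' Tidy leave-parts-out trials
#'
#' @param x `lpo_result`.
#' @param ... Unused.
#' @return Long tibble: `trial`, `model_id`, `pattern`,
#'   `mean_true_hit_ratio`.
#' @export
tidy.lpo_result <- function(x, ...) {
  x$trials
}

#' One-row summary of a leave-parts-out run
#'
#' @inheritParams tidy.lpo_result
#' @return Tibble with the run parameters and the best model by average
#'   mean true hit ratio.
#' @export
glance.lpo_result <- function(x, ...) {
  avg <- x$trials |>
    group_by(.data$model_id, .data$pattern) |>
    summarise(avg = mean(.data$mean_true_hit_ratio, na.rm = TRUE),
              .groups = "drop")
  best <- avg[which.max(avg$avg), ]
  tibble(n_trials = x$n_trials, catalog = x$catalog,
         train_size = x$train_size, p_value = x$p_value,
         best_model_id = best$model_id, best_pattern = best$pattern,
         best_avg_ratio = best$avg)
}

#' Tidy a scan evaluation
#'
#' @param x `scan_eval`.
#' @param ... Unused.
#' @return Per-record tibble.
#' @export
tidy.scan_eval <- function(x, ...) {
  x$per_record
}

#' One-row summary of a scan evaluation
#'
#' @inheritParams tidy.scan_eval
#' @return Tibble with the mean true hit ratio, undefined-record count,
#'   pooled PPV and p-value threshold.
#' @export
glance.scan_eval <- function(x, ...) {
  tibble(mean_true_hit_ratio = x$mean_true_hit_ratio,
         n_records = nrow(x$per_record),
         n_undefined = x$n_undefined,
         ppv = x$ppv, p_value = x$p_value)
}
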