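#' Evaluate one classifier parameter over a grid
#'
#' For each candidate value of `parameter_name` ("window_size" or
#' "pa_threshold"), every recording of the cohort is classified with
#' that value substituted into `base_params`, per-participant PE/APE per
#' class are computed against the gold-standard annotations, and the
#' per-class median and 95% CI are recorded. The objective of a grid
#' value is the sum over classes of the median APE (classes weighted
#' equally); the best value is the one minimizing the objective, ties
#' broken toward the smaller parameter value. The filter branches are
#' computed once per recording, since neither parameter affects them.
#'
#' @param cohort list of participants, each a list with `recording` and
#'   `annotation` components (as in [compute_agreement()]).
#' @param base_params an [algorithm_parameters()] object giving the
#'   values of the parameters not swept.
#' @param parameter_name `"window_size"` or `"pa_threshold"`.
#' @param values numeric vector of candidate parameter values.
#' @param objective `"sum"` (default) sums the three per-class median
#'   APEs; `"max"` takes their maximum.
#' @return object of class `parameter_grid_result`: the per-value,
#'   per-class summary table (`grid`), the per-value `objective` table
#'   and `best_value`.
#' @export
evaluate_grid <- function(cohort, base_params, parameter_name, values,
                          objective = c("sum", "max")) {
  objective <- match.arg(objective)
  parameter_name <- match.arg(parameter_name, c("window_size", "pa_threshold"))
  if (length(cohort) == 0L) stop("empty cohort", call. = FALSE)
  if (length(values) == 0L) stop("empty value grid", call. = FALSE)
  branches <- lapply(cohort, function(part) {
    filter_branches(part$recording, base_params$filter_constants)
  })
  gold <- lapply(cohort, function(part) annotation_totals(part$annotation))
  grid_rows <- list()
  obj <- numeric(length(values))
  for (v in seq_along(values)) {
    params <- base_params
    params[[parameter_name]] <- values[v]
    per_part <- do.call(rbind, lapply(seq_along(cohort), function(i) {
      series <- classify_filtered(branches[[i]], params)
      .agreement_rows(cohort[[i]]$recording$subject_id, gold[[i]],
                      class_totals(series))
    }))
    rep_v <- agreement_report(per_part)
    rep_v <- cbind(value = values[v], rep_v)
    grid_rows[[v]] <- rep_v
    obj[v] <- switch(objective,
                     sum = sum(rep_v$median_ape),
                     max = max(rep_v$median_ape))
  }
  best <- min(values[obj == min(obj)])
  structure(
    list(parameter_name = parameter_name,
         grid = do.call(rbind, grid_rows),
         objective = data.frame(value = values, objective = obj),
         objective_rule = objective,
         best_value = best),
    class = "parameter_grid_result"
  )
}

#' @export
print.parameter_grid_result <- function(x, ...) {
  cat(sprintf("<parameter_grid_result> %s over %d values; best = %g (objective %.3g)\n",
              x$parameter_name, nrow(x$objective), x$best_value,
              min(x$objective$objective)))
  invisible(x)
}

#' Sequential window-size then activity-threshold optimization
#'
#' Stage 1 sweeps the segmentation window size at the base activity
#' threshold; stage 2 sweeps the activity threshold at the stage-1
#' winner. The orientation threshold is never varied. Base parameters
#' default to WS = 1 s, PA Th = 5 cps, SO Th = 0.8 g, the settings this
#' optimization starts from; the default sweep ranges are 1-10 s and
#' 3-12 cps in unit steps.
#'
#' @inheritParams evaluate_grid
#' @param ws_values candidate window sizes in seconds.
#' @param pa_values candidate activity thresholds in cps.
#' @return list with `best_ws`, `best_pa`, and the two
#'   `parameter_grid_result` objects (`ws_result`, `pa_result`).
#' @export
optimize_sequential <- function(cohort, ws_values = 1:10, pa_values = 3:12,
                                base_params = algorithm_parameters(
                                  window_size = 1, pa_threshold = 5,
                                  so_threshold = 0.8),
                                objective = c("sum", "max")) {
  objective <- match.arg(objective)
  if (length(ws_values) == 0L) stop("empty ws_values", call. = FALSE)
  if (length(pa_values) == 0L) stop("empty pa_values", call. = FALSE)
  ws_result <- evaluate_grid(cohort, base_params, "window_size", ws_values,
                             objective = objective)
  stage2 <- base_params
  stage2$window_size <- ws_result$best_value
  pa_result <- evaluate_grid(cohort, stage2, "pa_threshold", pa_values,
                             objective = objective)
  list(best_ws = ws_result$best_value, best_pa = pa_result$best_value,
       ws_result = ws_result, pa_result = pa_result)
}

#' Exhaustive two-dimensional parameter grid
#'
#' Joint sweep of window size and activity threshold; unlike the
#' sequential procedure it cannot miss a joint optimum, at quadratic
#' cost. Off the main path; provided for sensitivity analyses.
#'
#' @inheritParams optimize_sequential
#' @return data frame `ws, pa, objective`, with attributes `best_ws`,
#'   `best_pa`.
#' @export
optimize_joint <- function(cohort, ws_values = 1:10, pa_values = 3:12,
                           base_params = algorithm_parameters(
                             window_size = 1, pa_threshold = 5,
                             so_threshold = 0.8),
                           objective = c("sum", "max")) {
  objective <- match.arg(objective)
  rows <- list()
  for (ws in ws_values) {
    params <- base_params
    params$window_size <- ws
    res <- evaluate_grid(cohort, params, "pa_threshold", pa_values,
                         objective = objective)
    rows[[length(rows) + 1L]] <-
      data.frame(ws = ws, pa = res$objective$value,
                 objective = res$objective$objective)
  }
  out <- do.call(rbind, rows)
  best <- out[order(out$objective, out$ws, out$pa)[1L], ]
  attr(out, "best_ws") <- best$ws
  attr(out, "best_pa") <- best$pa
  out
}

#' Write a parameter grid result to CSV
#'
#' One row per (value, class) with medians and CIs of PE and APE.
#'
#' @param result a `parameter_grid_result`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(result, path) {
  stopifnot(inherits(result, "parameter_grid_result"))
  cols <- c("value", "class", "median_pe", "pe_ci_low", "pe_ci_high",
            "median_ape", "ape_ci_low", "ape_ci_high")
  utils::write.csv(result$grid[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
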