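# Backward elimination by AIC over biomarkers and clinical variables.

#' Backward model selection by AIC
#'
#' Starts from the full Cox model over `variables` and repeatedly removes
#' the single variable whose removal yields the lowest AIC, as long as
#' that AIC is strictly lower than the current model's. Categorical
#' variables are removed as whole blocks (all their contrasts together).
#' The complete-case sample is fixed once from the full variable set, so
#' AICs are comparable across nested models. Candidates are scanned in
#' alphabetical order and ties broken by AIC then variable name, making
#' the trace invariant to the order `variables` is given in. Removal down
#' to the empty (null) model is allowed; its AIC is `-2 * loglik_null`.
#'
#' @param data Cohort data frame.
#' @param time,event Column names of follow-up time and 0/1 event flag.
#' @param variables Character vector of candidate variable columns
#'   (dichotomized biomarkers should already carry their endpoint-specific
#'   cutoff grouping).
#' @param ties Tie correction passed to [fit_cox()].
#'
#' @return Object of class `selection_trace`: a `steps` tibble
#'   (`removed`, `aic_before`, `aic_after`), `final_variables`,
#'   `final_fit` (a `cox_fit`, or NULL for the empty model), and the full
#'   model's AIC.
#' @export
backward_aic <- function(data, time, event, variables,
                         ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (length(variables) == 0) abort("`variables` must be non-empty")
  variables <- sort(unique(variables))
  data <- as.data.frame(data)

  used <- c(time, event, variables)
  miss <- setdiff(used, names(data))
  if (length(miss) > 0)
    abort(paste0("columns not in data: ", paste(miss, collapse = ", ")))
  cc <- complete.cases(data[used])
  if (sum(!cc) > 0)
    inform(sprintf("backward_aic: fixed complete-case sample drops %d row(s)",
                   sum(!cc)))
  d <- data[cc, , drop = FALSE]

  fit_subset <- function(vars) {
    if (length(vars) == 0) return(NULL)
    fit_cox(d, time = time, event = event, terms = vars, ties = ties)
  }

  full_fit <- fit_subset(variables) # errors here abort before selection
  null_aic <- -2 * full_fit$loglik_null

  current_vars <- variables
  current_fit <- full_fit
  current_aic <- full_fit$aic
  steps <- list()

  repeat {
    cand <- lapply(current_vars, function(v) {
      rest <- setdiff(current_vars, v)
      f <- if (length(rest) == 0) NULL else
        tryCatch(fit_subset(rest), error = function(e) NA)
      aic <- if (length(rest) == 0) null_aic
      else if (identical(f, NA) || !isTRUE(f$converged)) Inf
      else f$aic
      list(removed = v, fit = f, aic = aic)
    })
    aics <- vapply(cand, `[[`, numeric(1), "aic")
    best <- which.min(aics) # first minimum = alphabetical tie-break
    if (!is.finite(aics[best]) || aics[best] >= current_aic) break
    steps[[length(steps) + 1]] <- tibble(removed = cand[[best]]$removed,
                                         aic_before = current_aic,
                                         aic_after = aics[best])
    current_vars <- setdiff(current_vars, cand[[best]]$removed)
    current_fit <- if (identical(cand[[best]]$fit, NA)) NULL else
      cand[[best]]$fit
    current_aic <- aics[best]
    if (length(current_vars) == 0) break
  }

  structure(
    list(steps = if (length(steps)) dplyr::bind_rows(steps) else
      tibble(removed = character(), aic_before = numeric(),
             aic_after = numeric()),
         final_variables = current_vars,
         final_fit = current_fit,
         aic_full = full_fit$aic,
         aic_final = current_aic,
         time = time, event = event),
    class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("<selection_trace> %d removal(s): AIC %.2f -> %.2f\n",
              nrow(x$steps), x$aic_full, x$aic_final))
  if (nrow(x$steps) > 0)
    cat("  removed:", paste(x$steps$removed, collapse = ", "), "\n")
  cat("  final:",
      if (length(x$final_variables)) paste(x$final_variables, collapse = ", ")
      else "(empty model)", "\n")
  invisible(x)
}

#' @export
tidy.selection_trace <- function(x, ...) x$steps

#' @export
glance.selection_trace <- function(x, ...) {
  tibble(n_removed = nrow(x$steps), aic_full = x$aic_full,
         aic_final = x$aic_final,
         n_final = length(x$final_variables))
}

#' Serialize a selection trace (TSV steps + JSON final model)
#'
#' @param trace A `selection_trace`.
#' @param prefix Output path prefix.
#' @return The input, invisibly.
#' @export
write_selection <- function(trace, prefix) {
  readr::write_tsv(trace$steps, paste0(prefix, "_trace.tsv"))
  payload <- list(final_variables = trace$final_variables,
                  aic_full = trace$aic_full, aic_final = trace$aic_final)
  if (!is.null(trace$final_fit))
    payload$final_model <- list(terms = tidy(trace$final_fit),
                                model = glance(trace$final_fit))
  jsonlite::write_json(payload, paste0(prefix, "_final.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(trace)
}
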