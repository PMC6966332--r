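# Cox proportional-hazards fitting surface over the compiled Newton
# engine, with broom-style tidy()/glance() accessors and Wald inference.

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Efron (default) or Breslow tie-corrected partial
#' likelihood by Newton-Raphson with step-halving, to a score sup-norm
#' below `tol`. Categorical terms are expanded with the most frequent
#' level of each variable as the reference level. Rows with missing values
#' in any used column are dropped (complete-case) and the count reported.
#' A coefficient escaping `bound` in absolute value marks the fit
#' non-converged (separation) rather than returning a silent estimate.
#'
#' @param data Data frame or tibble holding all columns.
#' @param time,event Column names (strings) of the follow-up time and the
#'   0/1 event indicator.
#' @param terms Character vector of covariate column names. Character,
#'   factor and logical columns are treated as categorical.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param reference Optional named list overriding the reference level for
#'   specific categorical terms (e.g. a dichotomized marker whose low
#'   group must stay the reference regardless of group sizes).
#' @param tol Convergence tolerance on the score sup-norm.
#' @param maxit Maximum Newton iterations.
#' @param bound Divergence bound on |beta|.
#'
#' @return Object of class `cox_fit`; see [tidy.cox_fit()] and
#'   [glance.cox_fit()].
#' @export
fit_cox <- function(data, time, event, terms,
                    ties = c("efron", "breslow"), reference = list(),
                    tol = 1e-7, maxit = 100, bound = 15) {
  ties <- match.arg(ties)
  data <- as.data.frame(data)
  used <- c(time, event, terms)
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols) > 0)
    abort(paste0("columns not in data: ", paste(missing_cols, collapse = ", ")))
  if (length(terms) == 0) abort("`terms` must name at least one covariate")

  cc <- complete.cases(data[used])
  n_dropped <- sum(!cc)
  if (n_dropped > 0)
    inform(sprintf("fit_cox: dropped %d row(s) with missing values", n_dropped))
  d <- data[cc, used, drop = FALSE]

  tvec <- as.numeric(d[[time]])
  evec <- d[[event]]
  if (is.logical(evec)) evec <- as.integer(evec)
  if (!all(evec %in% c(0, 1))) abort("`event` must be 0/1")
  evec <- as.integer(evec)
  if (any(!is.finite(tvec)) || any(tvec < 0))
    abort("`time` must be non-negative and finite")
  if (sum(evec) == 0) abort("no events in the data")
  if (length(unique(tvec[evec == 1])) < 2)
    abort("fewer than 2 distinct event times")

  # expand design: most frequent level as reference for categoricals
  ref_levels <- list()
  for (v in terms) {
    col <- d[[v]]
    if (is.character(col) || is.factor(col) || is.logical(col)) {
      f <- if (!is.null(reference[[v]]))
        stats::relevel(droplevels(as.factor(col)), ref = reference[[v]])
      else relevel_most_frequent(col)
      f <- droplevels(f)
      if (nlevels(f) < 2)
        abort(sprintf("term '%s' has fewer than 2 observed levels (non-identifiable)", v))
      d[[v]] <- f
      ref_levels[[v]] <- levels(f)[1]
    } else {
      if (sd(col) == 0)
        abort(sprintf("term '%s' is constant (non-identifiable)", v))
      ref_levels[[v]] <- NA_character_
    }
  }
  form <- stats::as.formula(paste("~", paste(sprintf("`%s`", terms),
                                             collapse = " + ")))
  X <- model.matrix(form, data = d)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]

  assign_map <- attr(model.matrix(form, data = d), "assign")
  assign_map <- assign_map[assign_map != 0]

  res <- .cox_fit_cpp(tvec, evec, X, efron = (ties == "efron"),
                      maxit = maxit, tol = tol, bound = bound)
  if (res$singular)
    abort("model is non-identifiable (singular information matrix)")
  if (!res$converged)
    warn("fit_cox: model did not converge (possible separation); estimates are unreliable")

  beta <- as.numeric(res$beta)
  se <- sqrt(pmax(diag(as.matrix(res$var)), 0))
  term_variable <- terms[assign_map]
  term_tbl <- tibble(
    term = colnames(X),
    variable = term_variable,
    reference = unname(vapply(term_variable, function(v) ref_levels[[v]],
                              character(1))),
    estimate = beta,
    std.error = se
  )

  k <- length(beta)
  structure(
    list(terms = term_tbl,
         var = as.matrix(res$var),
         loglik = res$loglik, loglik_null = res$loglik_null,
         aic = -2 * res$loglik + 2 * k,
         n = res$n, n_events = res$n_events, n_dropped = n_dropped,
         iterations = res$iterations, converged = res$converged,
         score_max = res$score_max, ties = ties,
         time = time, event = event, variables = terms),
    class = "cox_fit")
}

#' Tidy a Cox fit
#'
#' One row per estimated coefficient, with hazard ratios and Wald
#' confidence limits from the observed information.
#'
#' @param x A `cox_fit`.
#' @param conf.level Confidence level (default 0.95).
#' @param ... Unused.
#'
#' @return Tibble with columns `term`, `variable`, `reference`,
#'   `estimate`, `std.error`, `statistic`, `p.value`, `hr`, `conf.low`,
#'   `conf.high`.
#' @export
tidy.cox_fit <- function(x, conf.level = 0.95, ...) {
  z <- qnorm(1 - (1 - conf.level) / 2)
  dplyr::mutate(
    x$terms,
    statistic = .data$estimate / .data$std.error,
    p.value = 2 * pnorm(-abs(.data$statistic)),
    hr = exp(.data$estimate),
    conf.low = exp(.data$estimate - z * .data$std.error),
    conf.high = exp(.data$estimate + z * .data$std.error)
  )
}

#' Model-level summary of a Cox fit
#'
#' @param x A `cox_fit`.
#' @param ... Unused.
#' @return One-row tibble: sample size, events, partial log-likelihoods,
#'   AIC, iteration count, convergence flag and final score sup-norm.
#' @export
glance.cox_fit <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, n_dropped = x$n_dropped,
         loglik_null = x$loglik_null, loglik = x$loglik, AIC = x$aic,
         iterations = x$iterations, converged = x$converged,
         score_max = x$score_max)
}

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<cox_fit> n = %d, events = %d, AIC = %.2f%s\n", x$n,
              x$n_events, x$aic,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  print(as.data.frame(tidy(x)[, c("term", "hr", "conf.low", "conf.high",
                                  "p.value")]), digits = digits,
        row.names = FALSE)
  invisible(x)
}

#' Wald significance of a model term
#'
#' TRUE when the term's two-sided Wald p-value is below `alpha`
#' (default 0.05, strict inequality). `term` may be a coefficient label or
#' a variable name; for a categorical variable with several contrasts, the
#' variable counts as significant when any contrast is. Non-converged fits
#' always return FALSE (with a message).
#'
#' @param fit A `cox_fit`.
#' @param term Coefficient label or variable name.
#' @param alpha Significance level.
#' @return Logical scalar.
#' @export
significance <- function(fit, term, alpha = 0.05) {
  stopifnot(inherits(fit, "cox_fit"))
  if (!fit$converged) {
    inform("significance: non-converged fit, returning FALSE")
    return(FALSE)
  }
  td <- tidy(fit)
  rows <- td[td$term == term | td$variable == term, ]
  if (nrow(rows) == 0)
    abort(sprintf("term '%s' not in the fit", term))
  any(rows$p.value < alpha)
}

#' Forest plot of a Cox fit
#'
#' @param object A `cox_fit`.
#' @param ... Unused.
#' @return A ggplot object (hazard ratios with Wald CIs, log-scaled axis).
#' @export
autoplot.cox_fit <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$hr, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Hazard ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Serialize a Cox fit to JSON
#'
#' @param fit A `cox_fit`.
#' @param path File path.
#' @return The input, invisibly.
#' @export
write_cox_fit <- function(fit, path) {
  stopifnot(inherits(fit, "cox_fit"))
  payload <- list(terms = tidy(fit), model = glance(fit), ties = fit$ties)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(fit)
}
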