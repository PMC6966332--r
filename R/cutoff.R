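# Bootstrap-based robust dichotomization cutoff selection: for each
# candidate cutoff the marker is dichotomized and a multivariable Cox
# model (marker group + the endpoint's clinical covariates) is fit on each
# of B with-replacement resamples; the fraction of resamples in which the
# marker term is Wald-significant is recorded per cutoff, smoothed with a
# 9-point moving average, and the cutoff with the highest smoothed
# fraction is selected. Cutoffs leaving fewer than 10% of patients on
# either side are excluded up front.

#' Admissible dichotomization cutoffs
#'
#' Midpoints between consecutive distinct sorted marker values whose
#' induced low/high split leaves at least `ceiling(min_group_frac * n)`
#' patients on each side.
#'
#' @param values Per-patient marker scores (>= 20 values).
#' @param min_group_frac Minimum group fraction (default 0.10).
#' @return Sorted numeric vector of admissible cutoffs.
#' @export
candidate_cutoffs <- function(values, min_group_frac = 0.10) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 20) abort("need at least 20 marker values")
  v <- sort(unique(values))
  if (length(v) < 2) abort("no admissible cutoffs (constant marker)")
  mids <- (v[-1] + v[-length(v)]) / 2
  min_n <- ceiling(min_group_frac * n)
  n_low <- vapply(mids, function(cut) sum(values <= cut), numeric(1))
  ok <- n_low >= min_n & (n - n_low) >= min_n
  if (!any(ok)) abort("no admissible cutoffs")
  mids[ok]
}

#' Moving-average smoothing of significance fractions
#'
#' Centered moving average over `window` adjacent cutoffs; near the edges
#' the window truncates to the available neighbors (no reflection or
#' padding). Missing entries are ignored within each window.
#'
#' @param frac Numeric vector of per-cutoff fractions.
#' @param window Odd window size (default 9).
#' @return Smoothed vector, same length as `frac`.
#' @export
smooth_fractions <- function(frac, window = 9) {
  if (window < 1 || window %% 2 == 0) abort("`window` must be odd and >= 1")
  h <- (window - 1) / 2
  n <- length(frac)
  vapply(seq_len(n), function(i) {
    idx <- max(1, i - h):min(n, i + h)
    vals <- frac[idx]
    if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  }, numeric(1))
}

#' Bootstrap cutoff scan for one marker and endpoint
#'
#' Draws `B` with-replacement resamples of the full (complete-case)
#' cohort; all candidate cutoffs are evaluated against the same B
#' resampled cohorts. Each fit is a multivariable Cox model of the
#' dichotomized marker plus the endpoint's clinical covariates; resample
#' fits that degenerate (empty group, no events, non-convergence or a
#' singular information matrix) are excluded from the denominator and
#' counted separately.
#'
#' @param cohort Cohort tibble with marker, covariate and
#'   `time_<endpoint>` / `event_<endpoint>` columns.
#' @param marker Marker column name.
#' @param endpoint An [endpoint_spec()] or endpoint name (`"LRC"`, `"DM"`,
#'   `"OS"`, `"PFS"`).
#' @param B Number of bootstrap cohorts (default 10000).
#' @param window Smoothing window (odd, default 9).
#' @param min_group_frac Minimum group fraction for admissible cutoffs.
#' @param seed Seed making the scan reproducible.
#' @param ties,alpha Tie correction and the per-fit significance level.
#'
#' @return Object of class `cutoff_scan` with a per-cutoff tibble
#'   (`cutoff`, `n_low`, `n_high`, `frac_significant`, `frac_smoothed`,
#'   `n_significant`, `n_failed`), the selected cutoff and scan metadata.
#' @export
bootstrap_scan <- function(cohort, marker, endpoint, B = 10000, window = 9,
                           min_group_frac = 0.10, seed = NULL,
                           ties = c("efron", "breslow"), alpha = 0.05) {
  ties <- match.arg(ties)
  if (B < 1) abort("`B` must be at least 1")
  spec <- as_endpoint_spec(endpoint)
  prep <- prepare_endpoint_data(cohort, marker, spec)

  cuts <- candidate_cutoffs(prep$marker, min_group_frac = min_group_frac)
  n <- length(prep$marker)
  counts <- withr::with_seed(
    if (is.null(seed)) sample.int(.Machine$integer.max, 1) else
      op_seed(seed, paste0("scan_", marker, "_", spec$name)),
    .cutoff_scan_cpp(prep$time, prep$event, prep$Z, prep$marker, cuts,
                     as.integer(B), efron = (ties == "efron"),
                     alpha = alpha)
  )
  n_sig <- counts[, 1]
  n_failed <- counts[, 2]
  valid <- B - n_failed
  frac <- ifelse(valid > 0, n_sig / valid, NA_real_)
  frac_sm <- smooth_fractions(frac, window = window)
  n_low <- vapply(cuts, function(cut) sum(prep$marker <= cut), numeric(1))

  scan <- structure(
    list(table = tibble(cutoff = cuts, n_low = n_low, n_high = n - n_low,
                        frac_significant = frac, frac_smoothed = frac_sm,
                        n_significant = n_sig, n_failed = n_failed),
         marker = marker, endpoint = spec, B = as.integer(B),
         window = window, min_group_frac = min_group_frac, seed = seed,
         n = n, marker_median = median(prep$marker),
         selected_cutoff = NA_real_),
    class = "cutoff_scan")
  scan$selected_cutoff <- select_cutoff(scan)
  scan
}

# complete-case extraction + covariate design for one endpoint
prepare_endpoint_data <- function(cohort, marker, spec) {
  cohort <- as.data.frame(cohort)
  tcol <- paste0("time_", spec$name)
  ecol <- paste0("event_", spec$name)
  need <- c(marker, spec$covariates, tcol, ecol)
  miss <- setdiff(need, names(cohort))
  if (length(miss) > 0)
    abort(paste0("cohort lacks columns: ", paste(miss, collapse = ", ")))
  cc <- complete.cases(cohort[need])
  d <- cohort[cc, need, drop = FALSE]
  if (sum(!cc) > 0)
    inform(sprintf("dropped %d row(s) with missing values", sum(!cc)))

  if (length(spec$covariates) > 0) {
    for (v in spec$covariates) {
      col <- d[[v]]
      if (is.character(col) || is.factor(col) || is.logical(col))
        d[[v]] <- droplevels(relevel_most_frequent(col))
    }
    form <- stats::as.formula(paste("~", paste(sprintf("`%s`", spec$covariates),
                                               collapse = " + ")))
    Z <- model.matrix(form, data = d)
    Z <- Z[, colnames(Z) != "(Intercept)", drop = FALSE]
  } else {
    Z <- matrix(numeric(0), nrow = nrow(d), ncol = 0)
  }
  list(time = as.numeric(d[[tcol]]), event = as.integer(d[[ecol]]),
       Z = Z, marker = as.numeric(d[[marker]]), data = d)
}

#' Select the scan's optimal cutoff
#'
#' The argmax of the smoothed significance fraction; exact ties are broken
#' toward the cutoff nearest the cohort's median marker value (then by
#' order, deterministically).
#'
#' @param scan A `cutoff_scan`.
#' @return The selected cutoff value.
#' @export
select_cutoff <- function(scan) {
  stopifnot(inherits(scan, "cutoff_scan"))
  frac <- scan$table$frac_smoothed
  if (all(is.na(frac))) abort("all smoothed fractions are missing")
  best <- max(frac, na.rm = TRUE)
  idx <- which(!is.na(frac) & frac == best)
  if (length(idx) > 1) {
    dist_med <- abs(scan$table$cutoff[idx] - scan$marker_median)
    idx <- idx[order(dist_med, idx)][1]
  }
  scan$table$cutoff[idx]
}

#' Final multivariable fit at a fixed cutoff
#'
#' Dichotomizes the marker on the original (non-resampled) cohort at
#' `cutoff` — the low group is the reference level — and fits the Cox
#' model with the endpoint's clinical covariates.
#'
#' @inheritParams bootstrap_scan
#' @param cutoff Cutoff value; must leave at least `min_group_frac` of the
#'   cohort on each side.
#' @return A [fit_cox()] `cox_fit`; the marker term is named
#'   `<marker>_grouphigh`.
#' @export
final_fit <- function(cohort, marker, cutoff, endpoint,
                      min_group_frac = 0.10, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  spec <- as_endpoint_spec(endpoint)
  prep <- prepare_endpoint_data(cohort, marker, spec)
  n <- length(prep$marker)
  n_low <- sum(prep$marker <= cutoff)
  min_n <- ceiling(min_group_frac * n)
  if (n_low < min_n || (n - n_low) < min_n)
    abort(sprintf("cutoff %.4g is outside the admissible range (splits %d/%d)",
                  cutoff, n_low, n - n_low))
  d <- prep$data
  grp <- paste0(marker, "_group")
  d[[grp]] <- factor(ifelse(prep$marker > cutoff, "high", "low"),
                     levels = c("low", "high"))
  fit <- fit_cox(d, time = paste0("time_", spec$name),
                 event = paste0("event_", spec$name),
                 terms = c(grp, spec$covariates), ties = ties,
                 reference = setNames(list("low"), grp))
  fit$marker <- marker
  fit$cutoff <- cutoff
  fit$endpoint <- spec$name
  fit
}

#' @export
print.cutoff_scan <- function(x, ...) {
  cat(sprintf("<cutoff_scan> %s on %s: %d cutoffs, B = %d\n", x$marker,
              x$endpoint$name, nrow(x$table), x$B))
  cat(sprintf("  selected cutoff %.4g (smoothed fraction %.3f)\n",
              x$selected_cutoff,
              x$table$frac_smoothed[x$table$cutoff == x$selected_cutoff]))
  invisible(x)
}

#' @export
tidy.cutoff_scan <- function(x, ...) x$table

#' @export
glance.cutoff_scan <- function(x, ...) {
  tibble(marker = x$marker, endpoint = x$endpoint$name, n = x$n, B = x$B,
         n_cutoffs = nrow(x$table), selected_cutoff = x$selected_cutoff,
         max_frac_smoothed = max(x$table$frac_smoothed, na.rm = TRUE),
         total_failed = sum(x$table$n_failed))
}

#' Cutoff-scan curve
#'
#' Raw and smoothed significance fractions against the candidate cutoff,
#' with the selected cutoff marked.
#'
#' @param object A `cutoff_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cutoff_scan <- function(object, ...) {
  long <- tidyr::pivot_longer(object$table,
                              c("frac_significant", "frac_smoothed"),
                              names_to = "series", values_to = "fraction")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cutoff, y = .data$fraction,
                                     linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$selected_cutoff,
                        colour = "red", linetype = "dotted") +
    ggplot2::scale_linetype_manual(
      values = c(frac_significant = "solid", frac_smoothed = "longdash"),
      labels = c("raw", "smoothed")) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = paste(object$marker, "cutoff"),
                  y = "fraction of significant bootstrap fits",
                  linetype = NULL,
                  title = paste(object$marker, "on", object$endpoint$name)) +
    ggplot2::theme_minimal()
}

#' Serialize a cutoff scan to TSV (curve) and JSON (selection)
#'
#' @param scan A `cutoff_scan`.
#' @param prefix Output path prefix; writes `<prefix>_scan.tsv` and
#'   `<prefix>_selected.json`.
#' @return The input, invisibly.
#' @export
write_scan <- function(scan, prefix) {
  readr::write_tsv(scan$table, paste0(prefix, "_scan.tsv"))
  jsonlite::write_json(
    list(marker = scan$marker, endpoint = scan$endpoint$name, B = scan$B,
         window = scan$window, min_group_frac = scan$min_group_frac,
         n = scan$n, selected_cutoff = scan$selected_cutoff),
    paste0(prefix, "_selected.json"), auto_unbox = TRUE, digits = NA)
  invisible(scan)
}
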