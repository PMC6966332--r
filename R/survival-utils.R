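# Endpoint construction, endpoint specifications, Spearman correlation,
# variance inflation factors, marker clustering and Kaplan-Meier curves.

#' Endpoint specification
#'
#' An endpoint name plus the clinical covariates adjusted for whenever
#' that endpoint is modelled. The default sets are those significantly
#' associated with each outcome in the reference cohort: sex and
#' cumulative cisplatin dose for LRC; sex, subsite and cisplatin for OS;
#' stage, subsite and cisplatin for PFS; sex and alcohol use for DM.
#'
#' @param name One of `"LRC"`, `"DM"`, `"OS"`, `"PFS"`.
#' @param covariates Character vector of clinical covariate columns.
#' @param event_definition Free-text tag describing the event.
#' @return An object of class `endpoint_spec`.
#' @export
endpoint_spec <- function(name, covariates, event_definition = "") {
  if (!name %in% c("LRC", "DM", "OS", "PFS"))
    abort("endpoint name must be one of LRC, DM, OS, PFS")
  structure(list(name = name, covariates = as.character(covariates),
                 event_definition = event_definition),
            class = "endpoint_spec")
}

#' @export
print.endpoint_spec <- function(x, ...) {
  cat(sprintf("<endpoint_spec> %s ~ marker + %s\n", x$name,
              paste(x$covariates, collapse = " + ")))
  invisible(x)
}

#' @rdname endpoint_spec
#' @export
default_endpoint_specs <- function() {
  list(
    LRC = endpoint_spec("LRC", c("sex", "cisplatin"),
                        "recurrence in the irradiated head-and-neck region"),
    DM = endpoint_spec("DM", c("sex", "alcohol"),
                       "recurrence outside the head-and-neck area"),
    OS = endpoint_spec("OS", c("sex", "subsite", "cisplatin"),
                       "death from any cause"),
    PFS = endpoint_spec("PFS", c("stage", "subsite", "cisplatin"),
                        "first of death, locoregional recurrence or distant metastasis")
  )
}

as_endpoint_spec <- function(x) {
  if (inherits(x, "endpoint_spec")) return(x)
  if (is.character(x) && length(x) == 1) {
    specs <- default_endpoint_specs()
    if (!x %in% names(specs)) abort(sprintf("unknown endpoint '%s'", x))
    return(specs[[x]])
  }
  abort("`endpoint` must be an endpoint_spec or an endpoint name")
}

#' Build endpoint time/event columns from per-patient records
#'
#' Times are years from the first day of treatment. LRC and DM: event at
#' the recurrence date; a death occurring first censors them at the death
#' date; otherwise censoring at last follow-up. OS: death from any cause.
#' PFS: the earliest of death, locoregional recurrence or distant
#' metastasis.
#'
#' @param records Data frame with columns `treatment_start`,
#'   `last_followup`, and optional (NA-allowed) `death_date`,
#'   `lrc_event_date`, `dm_event_date`. Columns may be `Date`s or numeric
#'   day offsets.
#' @param days_per_year Conversion factor to years (default 365.25).
#'
#' @return `records` with `time_*`/`event_*` columns appended for LRC,
#'   DM, OS, PFS.
#' @export
build_endpoints <- function(records, days_per_year = 365.25) {
  records <- as_tibble(records)
  need <- c("treatment_start", "last_followup")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0)
    abort(paste0("missing columns: ", paste(miss, collapse = ", ")))

  yrs <- function(col) {
    if (is.null(records[[col]])) return(rep(NA_real_, nrow(records)))
    as.numeric(records[[col]] - records$treatment_start) / days_per_year
  }
  fu <- yrs("last_followup")
  death <- yrs("death_date")
  lrc <- yrs("lrc_event_date")
  dm <- yrs("dm_event_date")

  if (any(fu < 0, na.rm = TRUE)) abort("negative follow-up time")
  if (any(fu <= 0, na.rm = TRUE)) abort("follow-up must be after treatment start")
  for (v in list(death = death, lrc = lrc, dm = dm))
    if (any(v <= 0, na.rm = TRUE))
      abort("event date on or before treatment start")

  censor_at <- ifelse(!is.na(death), death, fu)
  ep <- function(event_time) {
    has <- !is.na(event_time)
    tibble(time = ifelse(has, event_time, censor_at),
           event = as.integer(has))
  }
  lrc_ep <- ep(lrc)
  dm_ep <- ep(dm)
  os_time <- ifelse(!is.na(death), death, fu)
  os_event <- as.integer(!is.na(death))
  prog <- pmin(lrc, dm, death, na.rm = TRUE)
  prog[is.infinite(prog)] <- NA
  has_prog <- !is.na(lrc) | !is.na(dm) | !is.na(death)
  pfs_time <- ifelse(has_prog, prog, fu)
  pfs_event <- as.integer(has_prog)

  dplyr::bind_cols(records,
                   tibble(time_LRC = lrc_ep$time, event_LRC = lrc_ep$event,
                          time_DM = dm_ep$time, event_DM = dm_ep$event,
                          time_OS = os_time, event_OS = os_event,
                          time_PFS = pfs_time, event_PFS = pfs_event))
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of average ranks; the p-value uses the
#' t approximation `t = r sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of
#' freedom.
#'
#' @param x,y Numeric vectors of equal length (>= 3); ties allowed.
#' @return One-row tibble with `r`, `statistic`, `p.value`, `n`.
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) abort("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    abort("Spearman correlation undefined for a constant vector")
  r <- cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
  if (abs(r) >= 1) {
    stat <- sign(r) * Inf
    p <- 0
  } else {
    stat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(stat), df = n - 2)
  }
  tibble(r = r, statistic = stat, p.value = p, n = n)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing each column on all others.
#' Exact collinearity is reported as `Inf`.
#'
#' @param design Numeric matrix or data frame of numeric columns (>= 2).
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(design) {
  X <- as.matrix(design)
  if (ncol(X) < 2) abort("VIF needs at least 2 columns")
  if (!is.numeric(X)) abort("`design` must be numeric")
  nm <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  out <- vapply(seq_len(ncol(X)), function(j) {
    fit <- lm(X[, j] ~ X[, -j, drop = FALSE])
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  setNames(out, nm)
}

#' Hierarchical clustering of markers and samples
#'
#' Selected columns (by default tumor volume and EGFR, whose raw scales
#' are dominated by a few extreme samples) are log2(x + 1) transformed,
#' all columns are z-scored, and both axes are clustered agglomeratively
#' with Euclidean distance and complete linkage. Constant columns are
#' dropped with a warning. Ordering is deterministic.
#'
#' @param scores Samples x markers data frame (numeric marker columns;
#'   non-numeric columns such as sample identifiers are ignored).
#' @param log_transform Columns to log2(x + 1) transform first.
#' @return Object of class `marker_clustering`: `row_order`, `col_order`,
#'   `row_hclust`, `col_hclust`, and the scaled matrix.
#' @export
cluster_markers <- function(scores,
                            log_transform = c("tumor_volume", "EGFR")) {
  df <- as.data.frame(scores)
  num <- df[vapply(df, is.numeric, logical(1))]
  if (nrow(num) < 2) abort("clustering needs at least 2 samples")
  if (ncol(num) < 2) abort("clustering needs at least 2 markers")
  for (v in intersect(log_transform, names(num))) {
    if (any(num[[v]] < 0)) abort(sprintf("cannot log-transform negative values in '%s'", v))
    num[[v]] <- log2(num[[v]] + 1)
  }
  sds <- vapply(num, sd, numeric(1))
  if (any(sds == 0)) {
    warn(paste0("dropping constant column(s): ",
                paste(names(num)[sds == 0], collapse = ", ")))
    num <- num[sds > 0]
    if (ncol(num) < 2) abort("fewer than 2 non-constant markers")
  }
  Z <- scale(as.matrix(num))
  col_hc <- hclust(dist(t(Z)), method = "complete")
  row_hc <- hclust(dist(Z), method = "complete")
  structure(list(row_order = row_hc$order, col_order = col_hc$order,
                 row_hclust = row_hc, col_hclust = col_hc, scaled = Z),
            class = "marker_clustering")
}

#' @export
print.marker_clustering <- function(x, ...) {
  cat("<marker_clustering>", nrow(x$scaled), "samples x", ncol(x$scaled),
      "markers\ncolumn order:",
      paste(colnames(x$scaled)[x$col_order], collapse = ", "), "\n")
  invisible(x)
}

#' Kaplan-Meier product-limit estimator
#'
#' Wraps [survival::survfit()]; the median is the earliest time at which
#' the survival curve drops to 0.5 or below (undefined when the curve
#' never does).
#'
#' @param time,event Follow-up times and 0/1 event flags.
#' @return Object of class `km_fit`: a `steps` tibble (`time`, `n.risk`,
#'   `n.event`, `survival`) and `median`.
#' @export
kaplan_meier <- function(time, event) {
  if (length(time) == 0) abort("empty input")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  steps <- tibble(time = sf$time, n.risk = sf$n.risk, n.event = sf$n.event,
                  survival = sf$surv)
  drop <- steps$time[steps$survival <= 0.5]
  structure(list(steps = steps,
                 median = if (length(drop)) min(drop) else NA_real_,
                 n = length(time), n_events = sum(event)),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("<km_fit> n = %d, events = %d, median = %s\n", x$n,
              x$n_events,
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' @export
tidy.km_fit <- function(x, ...) x$steps
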