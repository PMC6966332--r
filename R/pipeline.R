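# End-to-end orchestration: scoring (or simulation), correlation and
# clustering reports, per-marker per-endpoint cutoff scans and final fits,
# backward selection, and hazard-ratio profiles, with deterministic seeded
# reruns and optional TSV/JSON artifact output.

#' Pipeline run configuration
#'
#' @param mode `"synthetic"` (simulate a cohort) or `"real"` (score an
#'   expression matrix and join a clinical table).
#' @param sim A [sim_config()] (synthetic mode).
#' @param expression_path,gmt_path,clinical_path Input files (real mode):
#'   tab-separated gene x sample expression (first column gene id), GMT
#'   gene sets, and a clinical table with `time_*`/`event_*` columns.
#' @param markers Marker columns to analyse; NULL = all simulated markers
#'   (synthetic) or all GMT signatures (real).
#' @param endpoints Named list of [endpoint_spec()]s.
#' @param B,window,min_group_frac Bootstrap scan parameters.
#' @param profile_endpoints Two endpoints compared in the spider table.
#' @param run_selection Run backward-AIC selection per endpoint.
#' @param keep_going Skip (with a warning) marker/endpoint stages that
#'   fail instead of aborting.
#' @param out_dir Directory for TSV/JSON artifacts; NULL = no files.
#' @param seed Global seed; all stage seeds derive from it.
#'
#' @return Object of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "real"), sim = sim_config(),
                       expression_path = NULL, gmt_path = NULL,
                       clinical_path = NULL, markers = NULL,
                       endpoints = default_endpoint_specs(), B = 200,
                       window = 9, min_group_frac = 0.10,
                       profile_endpoints = c("LRC", "DM"),
                       run_selection = TRUE, keep_going = FALSE,
                       out_dir = NULL, seed = 1) {
  mode <- match.arg(mode)
  if (B < 1) abort("`B` must be at least 1")
  if (window %% 2 == 0) abort("`window` must be odd")
  if (mode == "real") {
    for (p in c(expression_path, gmt_path, clinical_path))
      if (is.null(p) || !file.exists(p))
        abort(sprintf("real mode input missing: %s",
                      if (is.null(p)) "(unset path)" else p))
  }
  structure(list(mode = mode, sim = sim, expression_path = expression_path,
                 gmt_path = gmt_path, clinical_path = clinical_path,
                 markers = markers, endpoints = endpoints, B = B,
                 window = window, min_group_frac = min_group_frac,
                 profile_endpoints = profile_endpoints,
                 run_selection = run_selection, keep_going = keep_going,
                 out_dir = out_dir, seed = seed),
            class = "run_config")
}

config_hash <- function(config) {
  rlang::hash(config[setdiff(names(config), "out_dir")])
}

#' Pairwise Spearman correlation report
#'
#' Full symmetric Spearman correlation matrix over the marker columns,
#' with unadjusted t-approximation p-values (deliberately not corrected
#' for multiple testing). Constant markers are reported as missing rows /
#' columns with a warning.
#'
#' @param scores Samples x markers data frame; non-numeric columns are
#'   ignored.
#' @return Tibble in long format (`marker_a`, `marker_b`, `r`,
#'   `p.value`), one row per unordered pair plus the unit diagonal;
#'   attributes `"r_matrix"` and `"p_matrix"` carry the symmetric
#'   matrices.
#' @export
correlation_report <- function(scores) {
  df <- as.data.frame(scores)
  num <- df[vapply(df, is.numeric, logical(1))]
  if (nrow(num) < 3) abort("need at least 3 samples")
  m <- names(num)
  constant <- vapply(num, function(x) sd(x, na.rm = TRUE) == 0, logical(1))
  if (any(constant))
    warn(paste0("constant marker(s) reported as missing: ",
                paste(m[constant], collapse = ", ")))
  p <- length(m)
  R <- matrix(NA_real_, p, p, dimnames = list(m, m))
  P <- R
  diag(R) <- ifelse(constant, NA_real_, 1)
  rows <- list()
  for (i in seq_len(p)) {
    rows[[length(rows) + 1]] <- tibble(marker_a = m[i], marker_b = m[i],
                                       r = if (constant[i]) NA_real_ else 1,
                                       p.value = NA_real_)
    if (i == p) next
    for (j in seq((i + 1), p)) {
      if (constant[i] || constant[j]) {
        r <- NA_real_; pv <- NA_real_
      } else {
        sc <- spearman_corr(num[[i]], num[[j]])
        r <- sc$r; pv <- sc$p.value
      }
      R[i, j] <- R[j, i] <- r
      P[i, j] <- P[j, i] <- pv
      rows[[length(rows) + 1]] <- tibble(marker_a = m[i], marker_b = m[j],
                                         r = r, p.value = pv)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "r_matrix") <- R
  attr(out, "p_matrix") <- P
  out
}

#' Correlation heatmap
#'
#' @param report Output of [correlation_report()].
#' @return A ggplot tile plot of the Spearman matrix.
#' @export
plot_correlation <- function(report) {
  R <- attr(report, "r_matrix")
  long <- as_tibble(as.data.frame.table(R, responseName = "r"))
  names(long)[1:2] <- c("marker_a", "marker_b")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$marker_a, y = .data$marker_b,
                                     fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Run the full multifactorial biomarker analysis
#'
#' Executes scoring (or simulation), the correlation/clustering report,
#' bootstrap cutoff scans and final dichotomized fits for every marker and
#' endpoint, backward-AIC selection per endpoint over all dichotomized
#' markers plus clinical covariates, and hazard-ratio profiles with the
#' two-endpoint spider table. Reruns with the same config and seed are
#' bit-identical. When `config$out_dir` is set, every stage writes its
#' TSV/JSON artifact plus a `run_log.json` with the seed, parameters and
#' config hash.
#'
#' @param config A [run_config()].
#' @return List with `cohort`, `correlation`, `clustering`, `scans`,
#'   `final_fits`, `selected_cutoffs`, `selection`, `profiles`,
#'   `spider`, and `log`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, marker = NULL, endpoint = NULL, code) {
    tryCatch(code, error = function(e) {
      ctx <- paste(c(name, marker, endpoint), collapse = " / ")
      if (config$keep_going) {
        warn(sprintf("stage failed, skipping [%s]: %s", ctx,
                     conditionMessage(e)))
        NULL
      } else {
        abort(sprintf("pipeline stage failed [%s]: %s", ctx,
                      conditionMessage(e)))
      }
    })
  }
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  path <- function(...) file.path(out_dir, paste0(...))

  # --- cohort ---------------------------------------------------------
  if (config$mode == "synthetic") {
    cohort <- stage("simulate", code = simulate_cohort(config$sim,
                                                       seed = config$seed))
    markers <- config$markers %||% config$sim$marker_names
  } else {
    cohort <- stage("score", code = {
      expr_df <- readr::read_tsv(config$expression_path,
                                 show_col_types = FALSE)
      expr <- as.matrix(expr_df[, -1])
      rownames(expr) <- expr_df[[1]]
      gmt <- read_gmt(config$gmt_path)
      sigs <- purrr::pmap(gmt, function(name, description, genes)
        gene_signature(name, genes))
      scores <- score_signatures(expr, sigs)
      clinical <- readr::read_tsv(config$clinical_path,
                                  show_col_types = FALSE)
      dplyr::inner_join(clinical, scores, by = "sample")
    })
    markers <- config$markers %||%
      setdiff(names(cohort), names(cohort)[!vapply(cohort, is.numeric,
                                                   logical(1))])
  }
  if (is.null(cohort)) abort("pipeline stage failed [cohort]")
  if (!is.null(out_dir)) write_cohort(cohort, path("cohort.tsv"))

  # --- correlation & clustering --------------------------------------
  corr <- stage("correlation", code =
                  correlation_report(cohort[, markers, drop = FALSE]))
  clust <- stage("clustering", code = {
    cols <- c(markers, intersect("tumor_volume", names(cohort)))
    d <- cohort[, cols, drop = FALSE]
    # log-compression only applies to non-negative (expression/volume)
    # scales; synthetic scores are already standardized
    log_cols <- intersect(c("tumor_volume", "EGFR"), cols)
    log_cols <- log_cols[vapply(log_cols, function(v)
      all(d[[v]] >= 0, na.rm = TRUE), logical(1))]
    cluster_markers(d, log_transform = log_cols)
  })
  if (!is.null(out_dir) && !is.null(corr))
    readr::write_tsv(corr, path("correlation.tsv"))

  # --- cutoff scans and final fits -----------------------------------
  scans <- list()
  final_fits <- list()
  selected <- list()
  for (ep in names(config$endpoints)) {
    for (mk in markers) {
      key <- paste(mk, ep, sep = ".")
      scan <- stage("scan", mk, ep, code =
        bootstrap_scan(cohort, mk, config$endpoints[[ep]], B = config$B,
                       window = config$window,
                       min_group_frac = config$min_group_frac,
                       seed = config$seed))
      if (is.null(scan)) next
      scans[[key]] <- scan
      selected[[key]] <- scan$selected_cutoff
      fit <- stage("final_fit", mk, ep, code =
        final_fit(cohort, mk, scan$selected_cutoff, config$endpoints[[ep]],
                  min_group_frac = config$min_group_frac))
      if (!is.null(fit)) final_fits[[key]] <- fit
      if (!is.null(out_dir)) {
        write_scan(scan, path(key))
        if (!is.null(fit)) write_cox_fit(fit, path(key, "_fit.json"))
      }
    }
  }

  # --- backward selection per endpoint -------------------------------
  selection <- list()
  if (config$run_selection) {
    for (ep in names(config$endpoints)) {
      selection[[ep]] <- stage("backward_selection", endpoint = ep, code = {
        d <- as.data.frame(cohort)
        grp_vars <- character()
        for (mk in markers) {
          cut <- selected[[paste(mk, ep, sep = ".")]]
          if (is.null(cut)) next
          g <- paste0(mk, "_group")
          d[[g]] <- factor(ifelse(d[[mk]] > cut, "high", "low"),
                           levels = c("low", "high"))
          grp_vars <- c(grp_vars, g)
        }
        vars <- c(grp_vars, config$endpoints[[ep]]$covariates)
        tr <- backward_aic(d, time = paste0("time_", ep),
                           event = paste0("event_", ep), variables = vars)
        if (!is.null(out_dir)) write_selection(tr, path("selection_", ep))
        tr
      })
    }
  }

  # --- HR profiles and spider table ----------------------------------
  profiles <- list()
  for (ep in config$profile_endpoints) {
    for (mk in markers) {
      key <- paste(mk, ep, sep = ".")
      pr <- stage("hr_profile", mk, ep, code =
        hr_across_cutoffs(cohort, mk, config$endpoints[[ep]],
                          min_group_frac = config$min_group_frac))
      if (!is.null(pr)) profiles[[key]] <- pr
    }
  }
  spider <- stage("spider_table", code =
    if (length(profiles) > 0) spider_table(profiles) else NULL)
  if (!is.null(out_dir) && !is.null(spider))
    readr::write_tsv(spider, path("spider.tsv"))

  log <- list(
    seed = config$seed, mode = config$mode, B = config$B,
    window = config$window, min_group_frac = config$min_group_frac,
    n_patients = nrow(cohort), markers = markers,
    endpoints = names(config$endpoints),
    config_hash = config_hash(config),
    package_version = as.character(utils::packageVersion("markerscan")),
    r_version = as.character(getRversion()),
    n_scans = length(scans),
    n_failed_fits_total = sum(vapply(scans, function(s)
      sum(s$table$n_failed), numeric(1)))
  )
  if (!is.null(out_dir))
    jsonlite::write_json(log, path("run_log.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)

  list(cohort = cohort, correlation = corr, clustering = clust,
       scans = scans, final_fits = final_fits,
       selected_cutoffs = selected, selection = selection,
       profiles = profiles, spider = spider, log = log)
}
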