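# Synthetic cohort generator: correlated biomarker scores via a Gaussian
# copula, clinical covariates from marginal frequencies, and exponential
# (optionally Weibull) proportional-hazards event times for the LRC / DM /
# OS / PFS endpoint family with death-censoring semantics.

#' Default biomarker panel
#'
#' The twelve tumor-biology scores the pipeline ships with: chronic and
#' acute hypoxia signature scores, the stem-cell related single genes
#' SLC3A2 and CD44, EGFR expression, a proliferation signature, the T-cell
#' infiltration score (TIS), CD8 T-cell and CD56dim NK-cell abundance, the
#' CD8/Treg ratio score, an EMT score and a DNA crosslink-repair defect
#' score.
#'
#' @return Character vector of twelve marker names.
#' @export
default_markers <- function() {
  c("chronic_hypoxia", "acute_hypoxia", "SLC3A2", "CD44", "EGFR",
    "proliferation", "TIS", "CD8", "NK_CD56dim", "CD8_Treg_ratio",
    "EMT", "DNA_repair")
}

#' Default target Spearman correlations between marker scores
#'
#' Unit-diagonal symmetric matrix over [default_markers()]. The headline
#' entries are the cross-marker correlations reported for HPV-negative
#' HNSCC cohorts: CD44-SLC3A2 0.57, acute hypoxia vs proliferation 0.58,
#' vs TIS 0.51, vs CD8 0.54, acute vs chronic hypoxia 0.26 and
#' EGFR-proliferation 0.26. The immune markers' mutual correlations
#' (TIS-CD8 0.65, TIS-NK 0.40, CD8-NK 0.35, proliferation with TIS/CD8
#' 0.35, CD8/Treg ratio 0.30 with CD8 and mildly negative with TIS and
#' NK) are reported only qualitatively in such cohorts; the values chosen
#' here reproduce that pattern and make the target matrix comfortably
#' positive definite — the acute-hypoxia correlations alone would form an
#' infeasible "star". All other pairs are uncorrelated.
#'
#' @return A 12 x 12 named numeric matrix of target Spearman correlations.
#' @export
default_marker_corr <- function() {
  m <- default_markers()
  R <- diag(length(m))
  dimnames(R) <- list(m, m)
  set_pair <- function(R, a, b, r) {
    R[a, b] <- r
    R[b, a] <- r
    R
  }
  R <- set_pair(R, "CD44", "SLC3A2", 0.57)
  R <- set_pair(R, "acute_hypoxia", "proliferation", 0.58)
  R <- set_pair(R, "acute_hypoxia", "TIS", 0.51)
  R <- set_pair(R, "acute_hypoxia", "CD8", 0.54)
  R <- set_pair(R, "acute_hypoxia", "chronic_hypoxia", 0.26)
  R <- set_pair(R, "EGFR", "proliferation", 0.26)
  R <- set_pair(R, "TIS", "CD8", 0.65)
  R <- set_pair(R, "TIS", "NK_CD56dim", 0.40)
  R <- set_pair(R, "CD8", "NK_CD56dim", 0.35)
  R <- set_pair(R, "proliferation", "TIS", 0.35)
  R <- set_pair(R, "proliferation", "CD8", 0.35)
  R <- set_pair(R, "CD8_Treg_ratio", "CD8", 0.30)
  R <- set_pair(R, "CD8_Treg_ratio", "TIS", -0.10)
  R <- set_pair(R, "CD8_Treg_ratio", "NK_CD56dim", -0.20)
  R
}

#' Default clinical covariate specification
#'
#' Marginal category frequencies of an advanced-stage HPV-negative HNSCC
#' chemo-radiotherapy cohort (n = 197): sex 142 male / 55 female; alcohol
#' use 146 yes / 22 former / 22 never; tobacco 156 yes / 30 former /
#' 5 never; subsite 85 oropharynx / 78 hypopharynx / 34 larynx; AJCC stage
#' 135 IVA / 40 III / 20 IVB / 2 II; cumulative cisplatin 126 at or above
#' 200 mg/m2 vs 67 below. Frequencies are taken over non-missing patients.
#' Tumor volume is log-normal around a median of 23.2 cm3.
#'
#' @return Named list: one frequency vector per categorical covariate plus
#'   a `tumor_volume` entry with `meanlog`/`sdlog` of a log-normal law.
#' @export
default_clinical_spec <- function() {
  list(
    sex = c(Male = 142, Female = 55) / 197,
    alcohol = c(Yes = 146, Former = 22, No = 22) / 190,
    tobacco = c(Yes = 156, Former = 30, Never = 5) / 191,
    subsite = c(Oropharynx = 85, Hypopharynx = 78, Larynx = 34) / 197,
    stage = c(IVA = 135, III = 40, IVB = 20, II = 2) / 197,
    cisplatin = c(">=200" = 126, "<200" = 67) / 193,
    tumor_volume = list(type = "lognormal", meanlog = log(23.2), sdlog = 1.1)
  )
}

#' Default ground-truth effects for the generator
#'
#' Log-hazard coefficients per endpoint. Marker effects act on the
#' dichotomized score (above/below the `true_cutoffs` quantile); clinical
#' effects are keyed `"variable:level"` and act as level indicators.
#' Magnitudes follow hazard ratios reported for this disease setting
#' (chronic hypoxia 3.9 and acute hypoxia 1.9 on locoregional control,
#' EMT 3.14 and acute hypoxia 2.44 on distant metastasis, cumulative
#' cisplatin below 200 mg/m2 HR 2.57 and female sex HR 0.52 on LRC, and
#' moderate prognostic effects on overall survival).
#'
#' @return Named list with `LRC`, `DM` and `OS` coefficient vectors
#'   (PFS is derived, not simulated; see [simulate_cohort()]).
#' @export
default_true_effects <- function() {
  list(
    LRC = c(chronic_hypoxia = log(3.9), acute_hypoxia = log(1.9),
            "cisplatin:<200" = log(2.57), "sex:Female" = log(0.52),
            "alcohol:Yes" = log(2.16)),
    DM = c(EMT = log(3.14), acute_hypoxia = log(2.44),
           "sex:Female" = log(0.52), "alcohol:Yes" = log(1.8)),
    OS = c(EMT = log(2.15), DNA_repair = log(1.97), acute_hypoxia = log(1.62),
           "cisplatin:<200" = log(1.8), "sex:Female" = log(0.6),
           "subsite:Hypopharynx" = log(1.4), "stage:IVB" = log(1.6))
  )
}

#' Simulation configuration
#'
#' Validates and assembles all generator parameters. The target Spearman
#' correlation matrix is converted to a Pearson copula correlation with the
#' `2 sin(pi r / 6)` transform and repaired to the nearest positive
#' semi-definite matrix by eigenvalue clipping; if the repair changes any
#' entry by more than `psd_tol` the configuration is rejected.
#'
#' @param n_patients Cohort size (at least 20). Default 197.
#' @param marker_names Marker identifiers; columns of the score matrix.
#' @param target_corr Symmetric unit-diagonal matrix of target Spearman
#'   correlations between marker scores.
#' @param clinical_spec Named list of category-frequency vectors (must each
#'   sum to 1) plus optional continuous entries such as `tumor_volume`.
#' @param true_effects Per-endpoint named log-hazard coefficient vectors,
#'   keys `LRC`, `DM`, `OS`. See [default_true_effects()].
#' @param true_cutoffs Named vector of quantiles in (0, 1) at which each
#'   marker effect switches on, or the string `"linear"` for a linear
#'   effect of the raw score. Markers with effects default to 0.5.
#' @param baseline_hazard Events per year for the `LRC` and `DM` latent
#'   processes.
#' @param death_rate Background death hazard (per year); death censors
#'   LRC and DM and defines the OS endpoint.
#' @param censor_rate Administrative censoring rate (per year).
#' @param follow_up_years Hard administrative follow-up horizon (years).
#' @param weibull_shape Shape of the event-time law (1 = exponential).
#' @param seed Default seed used by the simulate functions.
#' @param psd_tol Largest tolerated entry change during nearest-PSD repair.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 197,
                       marker_names = default_markers(),
                       target_corr = default_marker_corr(),
                       clinical_spec = default_clinical_spec(),
                       true_effects = default_true_effects(),
                       true_cutoffs = NULL,
                       baseline_hazard = c(LRC = 0.011, DM = 0.015),
                       death_rate = 0.04,
                       censor_rate = 0.10,
                       follow_up_years = 9,
                       weibull_shape = 1,
                       seed = NULL,
                       psd_tol = 0.1) {
  assert_scalar_number(n_patients, "n_patients", lower = 20)
  n_patients <- as.integer(n_patients)
  p <- length(marker_names)
  if (p < 1 || anyDuplicated(marker_names))
    abort("`marker_names` must be non-empty and unique")

  target_corr <- as.matrix(target_corr)
  if (!all(dim(target_corr) == c(p, p)))
    abort("`target_corr` must be a square matrix matching `marker_names`")
  if (is.null(dimnames(target_corr)))
    dimnames(target_corr) <- list(marker_names, marker_names)
  if (max(abs(target_corr - t(target_corr))) > 1e-8)
    abort("`target_corr` must be symmetric")
  if (any(abs(diag(target_corr) - 1) > 1e-8))
    abort("`target_corr` must have unit diagonal")
  if (any(abs(target_corr) > 1))
    abort("`target_corr` entries must lie in [-1, 1]")

  # Spearman -> Pearson copula correlation, then nearest-PSD repair
  pearson <- 2 * sin(pi * target_corr / 6)
  diag(pearson) <- 1
  repaired <- nearest_psd(pearson)
  if (max(abs(repaired - pearson)) > psd_tol)
    abort("`target_corr` is too far from positive semi-definite to repair")

  cat_spec <- clinical_spec[vapply(clinical_spec, is.numeric, logical(1))]
  for (v in names(cat_spec)) {
    fr <- cat_spec[[v]]
    if (is.null(names(fr)) || any(fr < 0) || abs(sum(fr) - 1) > 1e-6)
      abort(sprintf("frequencies for clinical covariate '%s' must be named, non-negative and sum to 1", v))
  }

  for (ep in names(true_effects)) {
    if (!ep %in% c("LRC", "DM", "OS"))
      abort(sprintf("true_effects endpoint '%s' unknown (LRC, DM, OS; PFS is derived)", ep))
    eff <- true_effects[[ep]]
    for (key in names(eff)) {
      var <- sub(":.*$", "", key)
      known <- var %in% marker_names || var %in% names(clinical_spec)
      if (!known)
        abort(sprintf("true_effects[%s]: '%s' references unknown variable '%s'", ep, key, var))
      if (grepl(":", key)) {
        lev <- sub("^[^:]*:", "", key)
        if (var %in% names(cat_spec) && !lev %in% names(cat_spec[[var]]))
          abort(sprintf("true_effects[%s]: unknown level '%s' for '%s'", ep, lev, var))
      }
    }
  }

  effect_markers <- unique(unlist(lapply(true_effects, function(e) {
    keys <- names(e)
    keys[!grepl(":", keys) & keys %in% marker_names]
  })))
  cutoffs <- as.list(setNames(rep(0.5, length(effect_markers)),
                              effect_markers))
  if (!is.null(true_cutoffs)) {
    for (m in names(true_cutoffs)) {
      val <- true_cutoffs[[m]]
      if (!identical(val, "linear")) {
        val <- suppressWarnings(as.numeric(val))
        if (!is.finite(val) || val <= 0 || val >= 1)
          abort(sprintf("true_cutoffs['%s'] must be a quantile in (0,1) or \"linear\"", m))
      }
      cutoffs[[m]] <- val
    }
  }

  for (nm in c("death_rate", "censor_rate"))
    assert_scalar_number(get(nm), nm, lower = 0)
  assert_scalar_number(follow_up_years, "follow_up_years", lower = 1e-8)
  assert_scalar_number(weibull_shape, "weibull_shape", lower = 1e-8)
  if (!all(c("LRC", "DM") %in% names(baseline_hazard)))
    abort("`baseline_hazard` needs named `LRC` and `DM` rates")

  structure(
    list(n_patients = n_patients, marker_names = marker_names,
         target_corr = target_corr, copula_corr = repaired,
         clinical_spec = clinical_spec, true_effects = true_effects,
         true_cutoffs = cutoffs, baseline_hazard = baseline_hazard,
         death_rate = death_rate, censor_rate = censor_rate,
         follow_up_years = follow_up_years, weibull_shape = weibull_shape,
         seed = seed),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> n_patients:", x$n_patients,
      "| markers:", length(x$marker_names),
      "| endpoints: LRC DM OS (+ derived PFS)\n")
  invisible(x)
}

# nearest PSD correlation matrix by eigenvalue clipping, rescaled to unit
# diagonal
nearest_psd <- function(S, eps = 1e-8) {
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) >= eps) return(S)
  vals <- pmax(e$values, eps)
  R <- e$vectors %*% diag(vals, length(vals)) %*% t(e$vectors)
  d <- sqrt(diag(R))
  R <- R / tcrossprod(d)
  diag(R) <- 1
  dimnames(R) <- dimnames(S)
  R
}

#' Simulate correlated biomarker scores
#'
#' Draws standard-normal marker scores through a Gaussian copula whose
#' Pearson correlation is chosen (via `2 sin(pi r / 6)`) so that the
#' empirical Spearman correlation converges to the configured targets.
#'
#' @param config A [sim_config()].
#' @param n Number of patients (defaults to `config$n_patients`).
#' @param seed Seed for this operation (defaults to `config$seed`).
#'
#' @return Tibble with one standard-normal column per marker.
#' @export
simulate_scores <- function(config, n = config$n_patients,
                            seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  p <- length(config$marker_names)
  L <- chol(config$copula_corr + diag(1e-10, p))
  Z <- with_op_seed(seed, "scores",
                    matrix(rnorm(n * p), nrow = n) %*% L)
  colnames(Z) <- config$marker_names
  as_tibble(as.data.frame(Z))
}

# linear predictor for one endpoint on the simulated columns
endpoint_lp <- function(config, endpoint, scores, clinical) {
  eff <- config$true_effects[[endpoint]]
  n <- nrow(scores)
  lp <- numeric(n)
  for (key in names(eff)) {
    beta <- eff[[key]]
    if (grepl(":", key)) {
      var <- sub(":.*$", "", key)
      lev <- sub("^[^:]*:", "", key)
      lp <- lp + beta * as.numeric(clinical[[var]] == lev)
    } else if (key %in% config$marker_names) {
      cut <- config$true_cutoffs[[key]]
      x <- scores[[key]]
      if (identical(cut, "linear")) lp <- lp + beta * x
      else lp <- lp + beta * as.numeric(x > qnorm(as.numeric(cut)))
    } else {
      lp <- lp + beta * clinical[[key]]
    }
  }
  lp
}

# PH event times: T = (E / rate)^(1/shape), E ~ Exp(1); shape 1 = exponential
ph_times <- function(n, rate, shape) {
  t <- ifelse(rate > 0, (rexp(n) / rate)^(1 / shape), Inf)
  t
}

#' Simulate a full cohort table
#'
#' Generates marker scores, clinical covariates (multinomial draws from the
#' configured marginal frequencies, independent of the scores) and
#' proportional-hazards event times. Locoregional (LRC) and distant
#' metastasis (DM) latent times compete with an independent background
#' death time: death occurring first censors them. Overall survival is the
#' death process itself; progression-free survival is the minimum of the
#' LRC, DM and death times with its own event flag. Administrative
#' censoring (exponential plus a hard follow-up horizon) is applied last.
#'
#' @inheritParams simulate_scores
#' @return A cohort tibble: `patient_id`, clinical covariates, one column
#'   per marker, and `time_*` / `event_*` columns for LRC, DM, OS and PFS.
#' @export
simulate_cohort <- function(config, n = config$n_patients,
                            seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  scores <- simulate_scores(config, n = n, seed = seed)

  cat_spec <- config$clinical_spec[vapply(config$clinical_spec, is.numeric,
                                          logical(1))]
  clinical <- with_op_seed(seed, "clinical", {
    out <- lapply(cat_spec, function(fr) {
      factor(sample(names(fr), n, replace = TRUE, prob = fr),
             levels = names(fr))
    })
    vol <- config$clinical_spec$tumor_volume
    if (!is.null(vol))
      out$tumor_volume <- rlnorm(n, meanlog = vol$meanlog, sdlog = vol$sdlog)
    out
  })

  times <- with_op_seed(seed, "events", {
    shape <- config$weibull_shape
    lp_lrc <- endpoint_lp(config, "LRC", scores, clinical)
    lp_dm <- endpoint_lp(config, "DM", scores, clinical)
    lp_os <- endpoint_lp(config, "OS", scores, clinical)
    t_lrc <- ph_times(n, config$baseline_hazard[["LRC"]] * exp(lp_lrc), shape)
    t_dm <- ph_times(n, config$baseline_hazard[["DM"]] * exp(lp_dm), shape)
    t_death <- ph_times(n, config$death_rate * exp(lp_os), shape)
    cens <- if (config$censor_rate > 0) rexp(n, config$censor_rate) else
      rep(Inf, n)
    cens <- pmin(cens, config$follow_up_years)
    list(t_lrc = t_lrc, t_dm = t_dm, t_death = t_death, cens = cens)
  })

  t_lrc <- times$t_lrc; t_dm <- times$t_dm
  t_death <- times$t_death; cens <- times$cens

  time_lrc <- pmin(t_lrc, t_death, cens)
  event_lrc <- as.integer(t_lrc <= pmin(t_death, cens))
  time_dm <- pmin(t_dm, t_death, cens)
  event_dm <- as.integer(t_dm <= pmin(t_death, cens))
  time_os <- pmin(t_death, cens)
  event_os <- as.integer(t_death <= cens)
  t_prog <- pmin(t_lrc, t_dm, t_death)
  time_pfs <- pmin(t_prog, cens)
  event_pfs <- as.integer(t_prog <= cens)

  dplyr::bind_cols(
    tibble(patient_id = sprintf("P%04d", seq_len(n))),
    if (length(clinical) > 0) as_tibble(clinical) else NULL,
    scores,
    tibble(time_LRC = time_lrc, event_LRC = event_lrc,
           time_DM = time_dm, event_DM = event_dm,
           time_OS = time_os, event_OS = event_os,
           time_PFS = time_pfs, event_PFS = event_pfs)
  )
}

#' Simulate an expression matrix consistent with target signature scores
#'
#' Builds a log-normal background count matrix and shifts the per-sample
#' log-mean of each signature member gene monotonically in the target
#' score (up-genes up, down-genes down), so that rank-based set scoring
#' recovers the target ordering. Used for end-to-end validation of the
#' scoring module against known truth.
#'
#' @param signatures List of [gene_signature()] objects (or character
#'   vectors of up-genes).
#' @param scores Numeric matrix or tibble, samples x signatures (columns
#'   matched to signatures by position).
#' @param n_background_genes Number of unrelated background genes.
#' @param amplitude Log2 shift per standard deviation of the target score.
#' @param base_meanlog,base_sdlog Background log-normal abundance law.
#' @param noise_sd Per-gene-per-sample log-scale noise.
#' @param seed Seed for this operation.
#'
#' @return Integer gene x sample count matrix with rownames.
#' @export
simulate_expression <- function(signatures, scores, n_background_genes = 200,
                                amplitude = 2, base_meanlog = log(100),
                                base_sdlog = 1, noise_sd = 0.25, seed = NULL) {
  if (!is.list(signatures) || length(signatures) == 0)
    abort("`signatures` must be a non-empty list")
  signatures <- lapply(signatures, as_gene_signature)
  scores <- as.matrix(scores)
  if (!all(is.finite(scores))) abort("`scores` must be finite")
  if (ncol(scores) != length(signatures))
    abort("`scores` needs one column per signature")
  n <- nrow(scores)

  sig_genes <- unique(unlist(lapply(signatures, function(s)
    c(s$genes_up, s$genes_down))))
  if (length(sig_genes) == 0) abort("signatures contain no genes")
  bg <- sprintf("BG%05d", seq_len(n_background_genes))
  if (any(sig_genes %in% bg))
    abort("signature genes overlap background gene names")
  genes <- c(sig_genes, bg)

  with_op_seed(seed, "expression", {
    base <- rnorm(length(genes), base_meanlog, base_sdlog)
    names(base) <- genes
    logmu <- matrix(base, nrow = length(genes), ncol = n,
                    dimnames = list(genes, NULL))
    for (k in seq_along(signatures)) {
      s <- signatures[[k]]
      z <- scores[, k]
      z <- if (sd(z) > 0) (z - mean(z)) / sd(z) else z * 0
      shift <- amplitude * z * log(2)
      for (g in s$genes_up) logmu[g, ] <- logmu[g, ] + shift
      for (g in s$genes_down) logmu[g, ] <- logmu[g, ] - shift
    }
    noise <- matrix(rnorm(length(logmu), 0, noise_sd), nrow = nrow(logmu))
    counts <- round(exp(logmu + noise))
    counts[counts < 0] <- 0
    storage.mode(counts) <- "integer"
    colnames(counts) <- if (!is.null(rownames(scores))) rownames(scores) else
      sprintf("S%03d", seq_len(n))
    counts
  })
}

#' Read / write a simulation configuration file
#'
#' Plain JSON (or YAML, when the yaml package is installed) mirroring the
#' [sim_config()] field names; unspecified fields take the defaults.
#' `true_cutoffs` values may be quantiles or the string `"linear"`.
#'
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @param config A `sim_config` (writer; always written as JSON fields).
#' @return `read_sim_config()` returns a validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file '%s' does not exist", path))
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      abort("reading YAML configs needs the yaml package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  args <- list()
  for (f in c("n_patients", "marker_names", "death_rate", "censor_rate",
              "follow_up_years", "weibull_shape", "seed"))
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  if (!is.null(raw$target_corr)) {
    tc <- as.matrix(raw$target_corr)
    storage.mode(tc) <- "double"
    args$target_corr <- tc
  }
  if (!is.null(raw$baseline_hazard))
    args$baseline_hazard <- unlist(raw$baseline_hazard)
  if (!is.null(raw$clinical_spec)) {
    args$clinical_spec <- lapply(raw$clinical_spec, function(x)
      if (is.list(x) && !is.null(x$type)) x else unlist(x))
  }
  if (!is.null(raw$true_effects))
    args$true_effects <- lapply(raw$true_effects, unlist)
  if (!is.null(raw$true_cutoffs)) args$true_cutoffs <- raw$true_cutoffs
  do.call(sim_config, args)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  payload <- config[c("n_patients", "marker_names", "target_corr",
                      "clinical_spec", "true_effects", "true_cutoffs",
                      "baseline_hazard", "death_rate", "censor_rate",
                      "follow_up_years", "weibull_shape", "seed")]
  # named atomic vectors serialize as bare arrays; lists keep their names
  payload$true_cutoffs <- as.list(payload$true_cutoffs)
  payload$baseline_hazard <- as.list(payload$baseline_hazard)
  payload$true_effects <- lapply(payload$true_effects, as.list)
  payload$clinical_spec <- lapply(payload$clinical_spec, function(x)
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", pretty = TRUE)
  invisible(config)
}

#' Write / read a cohort table as tab-separated text
#'
#' Plain TSV with a single header line; missing values are written as
#' empty fields.
#'
#' @param cohort A cohort tibble.
#' @param path File path.
#' @return `read_cohort()` returns a tibble; `write_cohort()` its input,
#'   invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_tsv(cohort, path, na = "")
  invisible(cohort)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  readr::read_tsv(path, na = "", show_col_types = FALSE)
}
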