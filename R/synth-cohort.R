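#' Configuration for the synthetic biomarker cohort generator
#'
#' Two-group (control vs case) cohorts of CSF analyte concentrations,
#' cognitive scores and regional brain volumes, with targeted Pearson
#' correlations between analytes and scores imposed through a Gaussian
#' copula within each group.
#'
#' Defaults reproduce the reported CSF NPTX2 group means (control
#' 1067 pg/ml vs AD 296 pg/ml) with SDs chosen for moderate overlap,
#' companion tau/p-tau markers at literature-typical levels, a Dementia
#' Rating Scale score, and an NPTX2-DRS within-group correlation target
#' of 0.467.
#'
#' @param n_control,n_case Group sizes (>= 0).
#' @param analyte_params Named list; each element
#'   `c(control_mean, control_sd, case_mean, case_sd)` in pg/ml.
#' @param score_params Named list; each element `c(mean, sd)` in points
#'   (scores share moments across groups).
#' @param target_correlations Named list of named vectors:
#'   `target_correlations$NPTX2["DRS"] = rho` sets the within-group
#'   Pearson correlation between that analyte and score; `|rho| <= 1`.
#' @param volume_params List with `hippocampal` and `temporal_horn`,
#'   each a named list of `control`/`case` vectors `c(mean, sd)` in mm³.
#' @param seed Integer seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_control = 36,
                          n_case = 30,
                          analyte_params = list(
                            NPTX2 = c(control_mean = 1067, control_sd = 350,
                                      case_mean = 296, case_sd = 150),
                            tau = c(control_mean = 300, control_sd = 100,
                                    case_mean = 600, case_sd = 200),
                            ptau181 = c(control_mean = 50, control_sd = 15,
                                        case_mean = 85, case_sd = 25),
                            abeta42 = c(control_mean = 800, control_sd = 200,
                                        case_mean = 450, case_sd = 150)
                          ),
                          score_params = list(DRS = c(mean = 120, sd = 12)),
                          target_correlations = list(NPTX2 = c(DRS = 0.467)),
                          volume_params = list(
                            hippocampal = list(control = c(mean = 7000, sd = 700),
                                               case = c(mean = 5800, sd = 800)),
                            temporal_horn = list(control = c(mean = 1200, sd = 400),
                                                 case = c(mean = 2200, sd = 700))
                          ),
                          seed = 1) {
  cfg <- list(
    n_control = n_control, n_case = n_case,
    analyte_params = analyte_params, score_params = score_params,
    target_correlations = target_correlations,
    volume_params = volume_params, seed = seed
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) stop(sprintf("%s: %s", field, msg), call. = FALSE)
  }
  chk(cfg$n_control >= 0 && cfg$n_case >= 0, "n_control/n_case",
      "group sizes must be >= 0")
  for (a in names(cfg$analyte_params)) {
    p <- cfg$analyte_params[[a]]
    chk(length(p) == 4 && all(p[c(2, 4)] > 0),
        paste0("analyte_params$", a),
        "need (control_mean, control_sd, case_mean, case_sd) with sds > 0")
  }
  for (s in names(cfg$score_params)) {
    p <- cfg$score_params[[s]]
    chk(length(p) == 2 && p[2] > 0, paste0("score_params$", s),
        "need (mean, sd) with sd > 0")
  }
  for (a in names(cfg$target_correlations)) {
    rho <- cfg$target_correlations[[a]]
    chk(all(abs(rho) <= 1), paste0("target_correlations$", a),
        "|rho| must be <= 1")
    chk(a %in% names(cfg$analyte_params),
        paste0("target_correlations$", a), "unknown analyte")
    chk(all(names(rho) %in% names(cfg$score_params)),
        paste0("target_correlations$", a), "unknown score name")
  }
  invisible(cfg)
}

# PSD square root by eigendecomposition (tolerates |rho| = 1 exactly).
psd_sqrt <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < -1e-8) {
    stop("target_correlations: correlation matrix is not positive semidefinite",
         call. = FALSE)
  }
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(R)) %*% t(e$vectors)
}

#' Generate a synthetic two-group biomarker cohort
#'
#' Draws, within each group, a multivariate Gaussian over all analytes
#' and scores whose correlation matrix carries the configured
#' analyte-score correlations (zero elsewhere), then scales each margin
#' to its group mean/SD. Analyte concentrations are truncated at zero.
#' Hippocampal and temporal-horn volumes are drawn independently per
#' group.
#'
#' @param config A [cohort_config()].
#' @return A data frame of class `synthetic_cohort` with columns
#'   `subject_id`, `group` (`control`/`case`), one column per analyte
#'   (pg/ml) and score, `hippocampal_volume` and `temporal_horn_volume`
#'   (mm³).
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_control = 5, n_case = 5, seed = 2))
#' table(coh$group)
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    config <- do.call(cohort_config, config)
  }
  validate_cohort_config(config)
  set.seed(config$seed)
  analytes <- names(config$analyte_params)
  scores <- names(config$score_params)
  vars <- c(analytes, scores)
  p <- length(vars)
  R <- diag(p)
  dimnames(R) <- list(vars, vars)
  for (a in names(config$target_correlations)) {
    rho <- config$target_correlations[[a]]
    for (s in names(rho)) {
      R[a, s] <- R[s, a] <- rho[[s]]
    }
  }
  Rh <- psd_sqrt(R)

  draw_group <- function(n, group) {
    if (n == 0) {
      out <- data.frame(subject_id = character(0), group = character(0))
      for (v in vars) out[[v]] <- numeric(0)
      out$hippocampal_volume <- numeric(0)
      out$temporal_horn_volume <- numeric(0)
      return(out)
    }
    Z <- matrix(stats::rnorm(n * p), n, p) %*% Rh
    colnames(Z) <- vars
    out <- data.frame(
      subject_id = sprintf("%s%03d", if (group == "control") "C" else "A",
                           seq_len(n)),
      group = rep(group, n), stringsAsFactors = FALSE
    )
    for (a in analytes) {
      pp <- config$analyte_params[[a]]
      m <- if (group == "control") pp[[1]] else pp[[3]]
      s <- if (group == "control") pp[[2]] else pp[[4]]
      out[[a]] <- pmax(m + s * Z[, a], 0)
    }
    for (sc in scores) {
      pp <- config$score_params[[sc]]
      out[[sc]] <- pp[[1]] + pp[[2]] * Z[, sc]
    }
    vh <- config$volume_params$hippocampal[[group]]
    vt <- config$volume_params$temporal_horn[[group]]
    out$hippocampal_volume <- pmax(stats::rnorm(n, vh[[1]], vh[[2]]), 0)
    out$temporal_horn_volume <- pmax(stats::rnorm(n, vt[[1]], vt[[2]]), 0)
    out
  }

  cohort <- rbind(draw_group(config$n_control, "control"),
                  draw_group(config$n_case, "case"))
  rownames(cohort) <- NULL
  class(cohort) <- c("synthetic_cohort", "data.frame")
  cohort
}
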