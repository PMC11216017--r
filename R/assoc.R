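# Association battery: standardized CPET exposures against smartwatch
# outcomes under two covariate models, Benjamini-Hochberg FDR within
# result families, multiplicative-interaction and stratified analyses,
# and the sensitivity variants (effort-restricted, step-adjusted,
# expanded step sample, role-swapped).

# population (ddof 0) standard deviation
sd_pop <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

#' Transform and standardize an exposure
#'
#' Optional natural log, then centering and scaling to mean 0, SD 1.
#' The SD is the population SD (denominator n) of the supplied values,
#' which are expected to be the complete-case analysis sample of the
#' model being fitted.
#'
#' @param values Numeric vector; must be positive when `log_transform`.
#' @param log_transform Apply `log()` first.
#' @return Standardized vector.
#' @export
transform_standardize <- function(values, log_transform = FALSE) {
  stopifnot(is.numeric(values), all(!is.na(values)))
  if (log_transform) {
    if (any(values <= 0)) {
      stop("nonpositive values cannot be log-transformed", call. = FALSE)
    }
    values <- log(values)
  }
  s <- sd_pop(values)
  if (s == 0) stop("zero variance: cannot standardize", call. = FALSE)
  (values - mean(values)) / s
}

#' Benjamini-Hochberg FDR adjustment within families
#'
#' Step-up adjustment: within each family the i-th smallest p-value is
#' mapped to min over j >= i of p_(j) * m / j, capped at 1, and results
#' are returned in the original order.
#'
#' @param p Numeric p-values in \[0, 1\].
#' @param family Optional grouping vector (same length); adjustment is
#'   applied within each family separately.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p, family = NULL) {
  stopifnot(is.numeric(p))
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(family)) return(p.adjust(p, method = "BH"))
  stopifnot(length(family) == length(p))
  out <- numeric(length(p))
  for (f in unique(family)) {
    ix <- family == f
    out[ix] <- p.adjust(p[ix], method = "BH")
  }
  out
}

# the six CPET exposures and their transform flags
cpet_exposures <- function() {
  tibble::tibble(
    exposure = c("peak_vo2", "pct_predicted_peak_vo2", "vat_vo2",
                 "ve_vco2_nadir", "pct_predicted_max_hr", "sbp_w_slope"),
    log_transform = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
}

#' Covariate set for an outcome-model combination
#'
#' `model1` adjusts for age, sex and race. `model2` adds the
#' cardiometabolic covariates, treatment flags, season and state, plus
#' HR-lowering treatment for the nonactive-HR outcome only and watch
#' wear time for the daily-steps outcome only.
#'
#' @param outcome `"nonactive_hr"` or `"daily_steps"`.
#' @param model `"model1"` or `"model2"`.
#' @return Character vector of covariate column names.
#' @export
model_covariates <- function(outcome, model) {
  base <- c("age", "sex", "race")
  if (model == "model1") return(base)
  full <- c(base, "bmi", "current_smoker", "total_chol", "hdl", "glucose",
            "diabetes", "rest_sbp", "prevalent_cvd", "lipid_med", "htn_med",
            "season", "state")
  if (outcome == "nonactive_hr") c(full, "hr_lowering_med")
  else if (outcome == "daily_steps") c(full, "median_wear_hours")
  else full
}

#' Analysis configuration for the association battery
#'
#' @param outcomes Smartwatch outcomes to analyse.
#' @param models Covariate models (`model1`: age, sex, race; `model2`:
#'   adds cardiometabolic covariates, treatment flags, season and state,
#'   plus HR-lowering treatment only for the nonactive-HR outcome and
#'   watch wear time only for the daily-steps outcome).
#' @param exposures Tibble of exposures and log-transform flags
#'   (defaults to the six CPET measures, with peak VO2 and VO2 at the
#'   ventilatory threshold log-transformed).
#' @param rer_sensitivity Also run the battery restricted to sessions
#'   with peak RER at or above `rer_cut`.
#' @param rer_cut Effort cut (inclusive).
#' @param adjust_steps_in_hr_model Also run the nonactive-HR model-2
#'   analyses with daily steps as an additional covariate.
#' @param expanded_step_sample Also run the daily-steps analyses on the
#'   larger sample meeting only the step-inclusion criterion.
#' @param role_swap Also run the confirmatory analysis with daily steps
#'   as the standardized independent variable and each CPET measure as
#'   the dependent variable.
#' @param min_days Inclusion cut in contributing days (inclusive).
#' @param state_pool_min States with fewer participants are pooled into
#'   `"other"`.
#' @param extra_covariates Named list (`nonactive_hr`, `daily_steps`) of
#'   additional model-2 covariates. Requesting the HR-lowering treatment
#'   flag for the steps outcome, or watch wear time for the HR outcome,
#'   is a configuration error.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(outcomes = c("nonactive_hr", "daily_steps"),
                            models = c("model1", "model2"),
                            exposures = cpet_exposures(),
                            rer_sensitivity = FALSE, rer_cut = 1.05,
                            adjust_steps_in_hr_model = FALSE,
                            expanded_step_sample = FALSE,
                            role_swap = FALSE,
                            min_days = 30,
                            state_pool_min = 10,
                            extra_covariates = list()) {
  outcomes <- match.arg(outcomes, c("nonactive_hr", "daily_steps"),
                        several.ok = TRUE)
  models <- match.arg(models, c("model1", "model2"), several.ok = TRUE)
  if ("hr_lowering_med" %in% extra_covariates[["daily_steps"]]) {
    stop(paste("invalid config: HR-lowering treatment is a covariate only",
               "in the nonactive-HR analysis"), call. = FALSE)
  }
  if ("median_wear_hours" %in% extra_covariates[["nonactive_hr"]]) {
    stop(paste("invalid config: watch wear time is a covariate only in the",
               "daily-steps analysis"), call. = FALSE)
  }
  structure(list(outcomes = outcomes, models = models, exposures = exposures,
                 rer_sensitivity = rer_sensitivity, rer_cut = rer_cut,
                 adjust_steps_in_hr_model = adjust_steps_in_hr_model,
                 expanded_step_sample = expanded_step_sample,
                 role_swap = role_swap, min_days = min_days,
                 state_pool_min = state_pool_min,
                 extra_covariates = extra_covariates),
            class = "analysis_config")
}

# pool rare factor levels into "other"
pool_small_levels <- function(x, min_n) {
  tab <- table(x)
  rare <- names(tab)[tab < min_n]
  x[x %in% rare] <- "other"
  x
}

# covariates that are constant in the sample carry no information and
# would make the design singular; drop them before fitting
drop_constant_covars <- function(d, covars) {
  keep <- vapply(covars, function(v) length(unique(d[[v]])) > 1, logical(1))
  covars[keep]
}

#' Fit one exposure-outcome multivariable linear model
#'
#' Ordinary least squares of the outcome on the standardized exposure
#' plus covariates, with complete-case deletion. The exposure is
#' (optionally log-transformed and) standardized to mean 0, SD 1 within
#' the complete-case sample of this model, so the coefficient is in
#' outcome units per SD of exposure.
#'
#' @param data Analysis tibble holding outcome, exposure and covariates.
#' @param outcome,exposure Column names.
#' @param covariates Character vector of covariate columns.
#' @param log_exposure Natural-log the exposure before standardizing.
#' @param model_tag Label stored in the result.
#' @return One-row tibble: `exposure`, `outcome`, `model`, `beta`, `se`,
#'   `p_raw`, `n`, `adj_r2`.
#' @export
fit_model <- function(data, outcome, exposure, covariates,
                      log_exposure = FALSE, model_tag = "model") {
  vars <- c(outcome, exposure, covariates)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0) {
    stop(sprintf("columns not in data: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  d <- data[complete.cases(data[vars]), vars, drop = FALSE]
  n <- nrow(d)
  if (n < length(covariates) + 2) {
    stop(sprintf("only %d complete cases for %d covariates", n,
                 length(covariates)), call. = FALSE)
  }
  covariates <- drop_constant_covars(d, covariates)
  d$.z <- transform_standardize(d[[exposure]], log_transform = log_exposure)
  rhs <- paste(c(".z", covariates), collapse = " + ")
  fml <- as.formula(paste0("`", outcome, "` ~ ", rhs))
  fit <- lm(fml, data = d)
  cf <- coef(fit)
  if (any(is.na(cf))) {
    stop(sprintf("rank-deficient design; collinear term(s): %s",
                 paste(names(cf)[is.na(cf)], collapse = ", ")),
         call. = FALSE)
  }
  sm <- summary(fit)
  est <- sm$coefficients[".z", ]
  tibble::tibble(exposure = exposure, outcome = outcome, model = model_tag,
                 beta = unname(est["Estimate"]),
                 se = unname(est["Std. Error"]),
                 p_raw = unname(est["Pr(>|t|)"]),
                 n = n, adj_r2 = sm$adj.r.squared)
}

#' Derive the effect-modifier columns
#'
#' Adds `age_group` (median split; ages at the median go to the younger
#' group) and `bmi_cat` (under 25 normal, 25 to under 30 overweight, 30
#' and above obese; boundaries belong to the upper category).
#'
#' @param data Tibble with `age` and `bmi` columns.
#' @return The input with `age_group` and `bmi_cat` appended.
#' @export
derive_modifiers <- function(data) {
  med_age <- median(data$age, na.rm = TRUE)
  data$age_group <- ifelse(data$age > med_age, "older", "younger")
  data$bmi_cat <- cut(data$bmi, breaks = c(-Inf, 25, 30, Inf),
                      labels = c("normal", "overweight", "obese"),
                      right = FALSE)
  data$bmi_cat <- as.character(data$bmi_cat)
  data
}

#' Effect-modification (interaction) and stratified analysis
#'
#' Adds exposure-by-modifier multiplicative interaction term(s) to the
#' fully adjusted model and reports the joint interaction p-value from
#' an F-test comparing the models with and without the interaction.
#' Also refits the model within each stratum of the modifier (the
#' modifier itself is dropped from the covariate list when stratifying).
#'
#' @param data Analysis tibble (with `age_group` and `bmi_cat` already
#'   derived, or derivable from `age` and `bmi`).
#' @param exposure,outcome Column names.
#' @param modifier One of the modifier columns (e.g. `"sex"`,
#'   `"age_group"`, `"bmi_cat"`).
#' @param log_exposure Natural-log the exposure before standardizing.
#' @param min_stratum Strata with fewer complete cases are reported
#'   missing.
#' @return List `interaction` (one-row tibble with `p_interaction`) and
#'   `strata` (per-stratum model results; strata too small to fit are
#'   returned with `NA` estimates).
#' @export
interaction_analysis <- function(data, exposure, outcome, modifier,
                                 log_exposure = FALSE, min_stratum = 30) {
  if (!modifier %in% names(data)) data <- derive_modifiers(data)
  covars <- model_covariates(outcome, "model2")
  if (!modifier %in% covars) covars <- c(covars, modifier)
  vars <- c(outcome, exposure, covars)
  d <- data[complete.cases(data[vars]), vars, drop = FALSE]
  levs <- unique(d[[modifier]])
  if (length(levs) < 2) {
    stop(sprintf("modifier '%s' has fewer than 2 nonempty levels", modifier),
         call. = FALSE)
  }
  covars <- drop_constant_covars(d, covars)
  d$.z <- transform_standardize(d[[exposure]], log_transform = log_exposure)
  rhs0 <- paste(c(".z", covars), collapse = " + ")
  f0 <- lm(as.formula(paste0("`", outcome, "` ~ ", rhs0)), data = d)
  f1 <- lm(as.formula(paste0("`", outcome, "` ~ ", rhs0, " + .z:", modifier)),
           data = d)
  p_int <- anova(f0, f1)[2, "Pr(>F)"]

  strat_covars <- setdiff(covars, modifier)
  strata <- lapply(sort(levs), function(lv) {
    ds <- data[!is.na(data[[modifier]]) & data[[modifier]] == lv, ,
               drop = FALSE]
    ds <- ds[complete.cases(ds[c(outcome, exposure, strat_covars)]), ,
             drop = FALSE]
    if (nrow(ds) < max(min_stratum, length(strat_covars) + 2)) {
      return(tibble::tibble(exposure = exposure, outcome = outcome,
                            model = "model2", beta = NA_real_, se = NA_real_,
                            p_raw = NA_real_, n = nrow(ds),
                            adj_r2 = NA_real_, stratum = as.character(lv)))
    }
    res <- fit_model(ds, outcome, exposure, strat_covars,
                     log_exposure = log_exposure, model_tag = "model2")
    res$stratum <- as.character(lv)
    res
  })
  list(
    interaction = tibble::tibble(exposure = exposure, outcome = outcome,
                                 modifier = modifier, p_interaction = p_int,
                                 n = nrow(d)),
    strata = dplyr::bind_rows(strata))
}

#' Build the joined analysis table
#'
#' Joins watch summaries, CPET results and covariates on participant id
#' and derives the effect-modifier columns. States with fewer than
#' `state_pool_min` participants are pooled into `"other"`.
#'
#' @param watch_summaries,cpet_results,covariates Stage-output tibbles.
#' @param state_pool_min Pooling cut for the state factor.
#' @return One row per participant with all analysis columns.
#' @export
build_analysis_table <- function(watch_summaries, cpet_results, covariates,
                                 state_pool_min = 10) {
  d <- dplyr::inner_join(watch_summaries, cpet_results,
                         by = "participant_id")
  d <- dplyr::inner_join(d, covariates, by = "participant_id",
                         suffix = c("", ".cov"))
  d$nonactive_hr <- d$nonactive_hr_mean
  d$daily_steps <- d$mean_daily_steps
  d$state <- pool_small_levels(d$state, state_pool_min)
  derive_modifiers(d)
}

#' Run the full association battery
#'
#' Fits the exposure-outcome grid (six CPET exposures by two smartwatch
#' outcomes by two covariate models) on the primary joint-inclusion
#' sample, adjusts p-values by Benjamini-Hochberg within each
#' outcome-by-model family, and appends each enabled sensitivity
#' variant: the effort-restricted sample (peak RER at or above the
#' cut), the step-adjusted nonactive-HR models, the expanded
#' step-inclusion sample, and the role-swapped confirmatory analysis
#' (standardized daily steps as the independent variable).
#'
#' @param watch_summaries,cpet_results,covariates Stage outputs, or pass
#'   a prebuilt table via `analysis_table`.
#' @param config An [analysis_config()].
#' @param analysis_table Optional prebuilt [build_analysis_table()]
#'   output.
#' @return Tidy tibble of model results with columns `analysis`,
#'   `outcome`, `model`, `exposure`, `beta`, `se`, `p_raw`, `p_fdr`,
#'   `n`, `adj_r2`.
#' @export
run_battery <- function(watch_summaries = NULL, cpet_results = NULL,
                        covariates = NULL, config = analysis_config(),
                        analysis_table = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  d <- analysis_table %||%
    build_analysis_table(watch_summaries, cpet_results, covariates,
                         state_pool_min = config$state_pool_min)

  grid_fit <- function(dat, analysis_tag, outcomes, models,
                       extra = list()) {
    rows <- list()
    for (oc in outcomes) {
      for (md in models) {
        covars <- c(model_covariates(oc, md),
                    if (md == "model2") config$extra_covariates[[oc]],
                    if (md == "model2") extra[[oc]])
        for (k in seq_len(nrow(config$exposures))) {
          ex <- config$exposures$exposure[k]
          lg <- config$exposures$log_transform[k]
          rows[[length(rows) + 1L]] <-
            fit_model(dat, oc, ex, covars, log_exposure = lg,
                      model_tag = md)
        }
      }
    }
    out <- dplyr::bind_rows(rows)
    out$analysis <- analysis_tag
    out$p_fdr <- bh_adjust(out$p_raw,
                           family = paste(out$outcome, out$model))
    out
  }

  primary <- d[d$include_primary, , drop = FALSE]
  res <- list(grid_fit(primary, "primary", config$outcomes, config$models))

  if (config$rer_sensitivity) {
    eff <- primary[primary$peak_rer >= config$rer_cut, , drop = FALSE]
    res[[length(res) + 1L]] <-
      grid_fit(eff, "rer_sensitivity", config$outcomes, config$models)
  }
  if (config$adjust_steps_in_hr_model &&
      "nonactive_hr" %in% config$outcomes) {
    res[[length(res) + 1L]] <-
      grid_fit(primary, "step_adjusted", "nonactive_hr", "model2",
               extra = list(nonactive_hr = "daily_steps"))
  }
  if (config$expanded_step_sample && "daily_steps" %in% config$outcomes) {
    expanded <- d[d$include_steps, , drop = FALSE]
    res[[length(res) + 1L]] <-
      grid_fit(expanded, "expanded_steps", "daily_steps", config$models)
  }
  if (config$role_swap) {
    res[[length(res) + 1L]] <- role_swap_battery(primary, config)
  }
  out <- dplyr::bind_rows(res)
  out[c("analysis", "outcome", "model", "exposure", "beta", "se",
        "p_raw", "p_fdr", "n", "adj_r2")]
}

# confirmatory analysis with daily steps as the standardized exposure
# and each CPET measure (log-transformed where flagged) as the outcome
role_swap_battery <- function(primary, config) {
  rows <- list()
  d <- primary
  for (k in seq_len(nrow(config$exposures))) {
    oc <- config$exposures$exposure[k]
    lg <- config$exposures$log_transform[k]
    d$.y <- if (lg) log(d[[oc]]) else d[[oc]]
    covars <- model_covariates("daily_steps", "model2")
    r <- fit_model(d, ".y", "daily_steps", covars, log_exposure = FALSE,
                   model_tag = "model2")
    r$outcome <- oc
    r$exposure <- "daily_steps"
    rows[[length(rows) + 1L]] <- r
  }
  out <- dplyr::bind_rows(rows)
  out$analysis <- "role_swap"
  out$p_fdr <- bh_adjust(out$p_raw, family = paste(out$model))
  out
}
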