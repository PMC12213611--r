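# End-to-end driver: tables -> stocks -> aggregates -> beta -> accrual ->
# model selection. Thin glue over the stage functions so scripts,
# simulations and tests all run the same path.

#' Run the full FRC-SOC analysis pipeline
#'
#' @param tables a `site_tables` object.
#' @param status root rows entering FRC (`"all"` or `"live"`).
#' @param group standardization grouping for accrual records.
#' @param min_points minimum cumulative points for a beta fit.
#' @return List with `stocks`, `aggregates`, `beta`, `accrual`, and
#'   `excluded` (site exclusion flags).
#' @export
run_pipeline <- function(tables, status = "all", group = "pooled",
                         min_points = 3) {
  stocks <- site_layer_stocks(tables, status = status)
  increments <- root_increment_stocks(tables, status = status)
  aggregates <- site_aggregates(tables, status = status)
  aggregates$depth_bin <- depth_bin(aggregates$max_profile_depth)
  list(stocks = stocks,
       aggregates = aggregates,
       beta = beta_table(stocks, increments, min_points = min_points),
       accrual = accrual_records(aggregates, group = group),
       excluded = tables$excluded)
}

#' Whole-profile (or by-horizon) model selection analysis
#'
#' Builds the candidate set around the full model `SOC ~ FRC + MAT + MAP +
#' clay + ecosystem class` (with a random intercept for the profile-depth
#' bin when `random` is given), fits every candidate on complete cases, and
#' selects by AIC/AICc.
#'
#' @param aggregates site-aggregate data frame (with `depth_bin` when
#'   `random = "depth_bin"`).
#' @param response response column (e.g. `"soc_total"`, `"soc_organic"`,
#'   `"soc_mineral"`).
#' @param fixed candidate fixed-effect columns.
#' @param random optional grouping-factor column.
#' @return List with `selected` (a `rootsoc_fit`), `criterion`, `table`
#'   (candidate comparison), and `full` (the full-model fit).
#' @export
select_soc_model <- function(aggregates,
                             response = "soc_total",
                             fixed = c("frc_total", "mat", "map",
                                       "clay_profile", "ecosystem_class"),
                             random = NULL) {
  # a constant column cannot enter the design (single-ecosystem cohorts)
  fixed <- fixed[vapply(fixed, function(v) {
    x <- aggregates[[v]]
    length(unique(x[!is.na(x)])) > 1
  }, logical(1))]
  full <- model_spec(response, fixed, random)
  specs <- candidate_set(full)
  fits <- lapply(specs, fit_model, data = aggregates)
  best <- select_model(fits)
  full_fit <- fits[[which(vapply(specs, function(s) isTRUE(s$is_full),
                                 logical(1)))[1]]]
  list(selected = best, criterion = attr(best, "criterion"),
       table = attr(best, "table"), full = full_fit)
}

#' Structured model report
#'
#' JSON-ready summary of one selection analysis: the candidate table and the
#' selected fit's coefficients and fit statistics.
#'
#' @param analysis result of [select_soc_model()].
#' @return A plain list suitable for `jsonlite::write_json()`.
#' @export
model_report <- function(analysis) {
  f <- analysis$selected
  list(
    criterion = analysis$criterion,
    candidates = analysis$table,
    selected = list(
      response = f$spec$response,
      fixed = f$spec$fixed,
      random = f$spec$random,
      n = f$n, k = f$k, aic = f$aic, aicc = f$aicc,
      adj_r2 = f$adj_r2, marginal_pseudo_r2 = f$marginal_pseudo_r2,
      singular = f$singular,
      coefficients = f$coefficients))
}
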