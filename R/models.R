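# Regression and mixed-effects model specification, fitting and selection.
#
# Responses are site aggregates (whole-profile / organic / mineral SOC),
# beta coefficients, or 1:1-line residuals; candidate fixed effects are FRC
# (or beta_FRC), climate, clay, and ecosystem class, with an optional random
# intercept for a profile-depth grouping factor. Models are compared by AIC,
# or AICc when n < 40, with the full model ineligible to win.

#' Specify a model
#'
#' @param response response column name.
#' @param fixed character vector of fixed-effect column names (possibly
#'   empty: the null model).
#' @param random optional name of a grouping-factor column for a random
#'   intercept (see [depth_bin()]).
#' @return A `model_spec` object.
#' @export
model_spec <- function(response, fixed = character(0), random = NULL) {
  stopifnot(is.character(response), length(response) == 1)
  fixed <- as.character(fixed)
  if (response %in% fixed)
    stop("model_spec: response cannot appear among fixed effects",
         call. = FALSE)
  if (anyDuplicated(fixed))
    stop("model_spec: duplicated fixed effects", call. = FALSE)
  structure(list(response = response, fixed = sort(fixed), random = random,
                 is_full = FALSE),
            class = "model_spec")
}

#' Bin maximum profile depth into a grouping factor
#'
#' A continuous sampled depth cannot serve as a grouping factor for a random
#' intercept, so it is binned: `<=100`, `(100, 150]`, `>150` cm.
#'
#' @param max_profile_depth numeric, cm.
#' @return Factor with levels `d<=100`, `d100-150`, `d>150`.
#' @export
depth_bin <- function(max_profile_depth) {
  cut(max_profile_depth, breaks = c(-Inf, 100, 150, Inf),
      labels = c("d<=100", "d100-150", "d>150"))
}

#' Small-sample corrected AIC
#'
#' `AICc = AIC + 2k(k+1)/(n - k - 1)`, undefined for `n <= k + 1`.
#'
#' @param aic AIC value.
#' @param k number of estimated parameters.
#' @param n number of observations.
#' @return AICc.
#' @export
aicc <- function(aic, k, n) {
  if (any(n <= k + 1))
    stop("aicc undefined for n <= k + 1", call. = FALSE)
  aic + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit a specified model
#'
#' Ordinary least squares when the spec has no random term; otherwise a
#' linear mixed model (REML) with a random intercept, with coefficient
#' p-values by Satterthwaite's method. For mixed models the AIC/AICc used in
#' selection come from a maximum-likelihood refit, since REML criteria are
#' not comparable across fixed-effect sets; a singular random-effect
#' variance is flagged, not treated as an error. Rows are complete cases
#' over the variables used.
#'
#' @param spec a `model_spec`.
#' @param data data frame holding all referenced columns.
#' @return A `rootsoc_fit`: list with `spec`, `coefficients` (term,
#'   estimate, se, p), `n`, `k` (estimated parameters, from the log
#'   likelihood), `aic`, `aicc` (NA when undefined), `adj_r2` (OLS) or
#'   `marginal_pseudo_r2` (mixed), `singular` flag, and the underlying fit.
#' @export
fit_model <- function(spec, data) {
  vars <- c(spec$response, spec$fixed, spec$random)
  d <- data[stats::complete.cases(data[, vars, drop = FALSE]), ,
            drop = FALSE]
  n <- nrow(d)
  rhs_fixed <- if (length(spec$fixed)) paste(spec$fixed, collapse = " + ")
               else "1"
  if (is.null(spec$random)) {
    X <- stats::model.matrix(
      stats::as.formula(paste("~", rhs_fixed)), d)
    if (qr(X)$rank < ncol(X))
      stop("fit_model: rank-deficient fixed-effect design", call. = FALSE)
    if (n < ncol(X) + 2)
      stop(sprintf("fit_model: n = %d too small for %d parameters",
                   n, ncol(X)), call. = FALSE)
    fit <- stats::lm(
      stats::as.formula(paste(spec$response, "~", rhs_fixed)), data = d)
    sm <- summary(fit)
    k <- as.integer(attr(stats::logLik(fit), "df"))
    aic <- stats::AIC(fit)
    out <- list(spec = spec,
                coefficients = data.frame(
                  term = rownames(sm$coefficients),
                  estimate = sm$coefficients[, 1],
                  se = sm$coefficients[, 2],
                  p = sm$coefficients[, 4], row.names = NULL),
                n = n, k = k, aic = aic,
                aicc = if (n > k + 1) aicc(aic, k, n) else NA_real_,
                adj_r2 = sm$adj.r.squared,
                marginal_pseudo_r2 = NA_real_,
                singular = FALSE, fit = fit)
  } else {
    if (length(unique(d[[spec$random]])) < 2)
      stop("fit_model: random grouping factor has < 2 levels", call. = FALSE)
    form <- stats::as.formula(paste(
      spec$response, "~", rhs_fixed, "+ (1 |", spec$random, ")"))
    # a singular random-effect variance is reported via the `singular`
    # flag, so the fitter's boundary chatter is silenced here
    fit <- suppressMessages(lmerTest::lmer(form, data = d, REML = TRUE))
    sm <- stats::coef(summary(fit))   # Satterthwaite df and p
    ml <- lme4::refitML(fit)
    k <- as.integer(attr(stats::logLik(ml), "df"))
    aic <- stats::AIC(ml)
    fe <- lme4::fixef(fit)
    pred_fixed <- as.numeric(stats::model.matrix(fit) %*% fe)
    vc <- lme4::VarCorr(fit)
    var_rand <- sum(vapply(vc, function(v) v[1, 1], numeric(1)))
    var_resid <- attr(vc, "sc")^2
    var_fixed <- stats::var(pred_fixed)
    out <- list(spec = spec,
                coefficients = data.frame(
                  term = rownames(sm), estimate = sm[, "Estimate"],
                  se = sm[, "Std. Error"], p = sm[, "Pr(>|t|)"],
                  row.names = NULL),
                n = n, k = k, aic = aic,
                aicc = if (n > k + 1) aicc(aic, k, n) else NA_real_,
                adj_r2 = NA_real_,
                marginal_pseudo_r2 =
                  var_fixed / (var_fixed + var_rand + var_resid),
                singular = lme4::isSingular(fit), fit = fit)
  }
  structure(out, class = "rootsoc_fit")
}

#' @export
print.rootsoc_fit <- function(x, ...) {
  cat(sprintf("rootsoc_fit: %s ~ %s%s  (n = %d, AIC = %.2f%s)\n",
              x$spec$response,
              if (length(x$spec$fixed)) paste(x$spec$fixed, collapse = " + ")
              else "1",
              if (!is.null(x$spec$random))
                paste0(" + (1|", x$spec$random, ")") else "",
              x$n, x$aic,
              if (!is.na(x$aicc)) sprintf(", AICc = %.2f", x$aicc) else ""))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Candidate model set: null, full, and all reductions
#'
#' All subsets of the full model's fixed effects (recursive single-term
#' deletions down to the null model), each keeping the full spec's random
#' term; the full model itself is marked ineligible for selection.
#'
#' @param full_spec the full `model_spec`.
#' @return List of `model_spec`s (length `2^length(fixed)`), deduplicated,
#'   with `is_full = TRUE` on the complete spec.
#' @export
candidate_set <- function(full_spec) {
  fx <- full_spec$fixed
  specs <- list()
  for (m in 0:(2^length(fx) - 1)) {
    keep <- fx[bitwAnd(m, 2^(seq_along(fx) - 1)) > 0]
    s <- model_spec(full_spec$response, keep, full_spec$random)
    s$is_full <- length(keep) == length(fx) && length(fx) > 0
    specs[[length(specs) + 1]] <- s
  }
  specs
}

#' Select the best model by AIC/AICc
#'
#' Uses AICc when `n < 40`, AIC otherwise. The full model is ineligible (a
#' guard against overparameterization); ties are broken by fewer estimated
#' parameters, then lexicographic fixed-term order, so selection is
#' deterministic.
#'
#' @param fits list of `rootsoc_fit` objects from a common candidate set.
#' @param n number of observations (defaults to the fits' common n).
#' @return The selected `rootsoc_fit`, with attributes `criterion`
#'   (`"aic"`/`"aicc"`) and `table` (the candidate comparison table).
#' @export
select_model <- function(fits, n = NULL) {
  if (length(fits) < 2)
    stop("select_model: need at least 2 candidate fits", call. = FALSE)
  if (is.null(n)) n <- fits[[1]]$n
  crit <- if (n < 40) "aicc" else "aic"
  tab <- data.frame(
    terms = vapply(fits, function(f)
      paste(f$spec$fixed, collapse = "+"), character(1)),
    k = vapply(fits, function(f) f$k, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)),
    aicc = vapply(fits, function(f) f$aicc, numeric(1)),
    is_full = vapply(fits, function(f) isTRUE(f$spec$is_full), logical(1)),
    stringsAsFactors = FALSE)
  elig <- which(!tab$is_full)
  if (!length(elig))
    stop("select_model: no eligible (non-full) candidates", call. = FALSE)
  val <- tab[[crit]][elig]
  if (all(is.na(val)))
    stop("select_model: criterion undefined for all candidates",
         call. = FALSE)
  ord <- order(val, tab$k[elig], tab$terms[elig], na.last = TRUE)
  best <- fits[[elig[ord[1]]]]
  attr(best, "criterion") <- crit
  attr(best, "table") <- tab
  best
}

#' Rank-sum check of the fine-root diameter protocols
#'
#' Two-sided Wilcoxon rank-sum test of FRC-SOC relationship residuals
#' between sites sampled with the 2-mm and 4-mm fine-root diameter cutoffs —
#' a check that the protocol difference does not drive the observed
#' relationship.
#'
#' @param residuals numeric residuals, one per site.
#' @param protocols character/factor of `"2mm"` / `"4mm"`, same length.
#' @return List with `statistic` (rank-sum W), `z` (normal approximation),
#'   `p.value`, and per-group counts.
#' @export
diameter_protocol_check <- function(residuals, protocols) {
  g1 <- residuals[protocols == "2mm"]
  g2 <- residuals[protocols == "4mm"]
  if (!length(g1) || !length(g2))
    stop("diameter_protocol_check: both protocol groups must be non-empty",
         call. = FALSE)
  n1 <- length(g1); n2 <- length(g2)
  no_ties <- !any(duplicated(c(g1, g2)))
  wt <- suppressWarnings(stats::wilcox.test(
    g1, g2, exact = no_ties && n1 < 50 && n2 < 50, correct = FALSE))
  z <- (unname(wt$statistic) - n1 * n2 / 2) /
    sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
  list(statistic = unname(wt$statistic), z = z, p.value = wt$p.value,
       n_2mm = n1, n_4mm = n2)
}
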