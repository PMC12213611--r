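# Standardized 1:1-line residuals: inferred SOC accrual vs. priming.
#
# Within a standardization group (by default all sites sharing a depth
# class, pooled across ecosystems), FRC and SOC stocks are z-scored and each
# site's residual from the 1:1 line (z_soc - z_frc) taken as a proxy for net
# SOC accrual (above the line) or net priming (below it).

#' z-score a vector within one standardization group
#'
#' `(x - mean) / sd` with the sample (n-1) standard deviation.
#'
#' @param x numeric values (one variable, one group).
#' @param group label used in error messages.
#' @return z-scores with mean 0 and sd 1.
#' @export
standardize <- function(x, group = "group") {
  if (length(x) < 2)
    stop(sprintf("standardize: group '%s' has fewer than 2 values", group),
         call. = FALSE)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop(sprintf("standardize: zero variance in group '%s'", group),
         call. = FALSE)
  (x - mean(x)) / s
}

#' 1:1-line residuals from standardized pairs
#'
#' @param site_id,ecosystem,depth_class identifiers, recycled as needed.
#' @param z_frc,z_soc standardized stocks paired by site.
#' @return Data frame of accrual records: `site_id`, `ecosystem`,
#'   `depth_class`, `z_frc`, `z_soc`, `residual` (= `z_soc - z_frc`), and
#'   `label` (`"accrual"` if residual > 0, `"priming"` if < 0, `"neutral"`
#'   at exactly 0).
#' @export
one_to_one_residuals <- function(site_id, ecosystem, depth_class,
                                 z_frc, z_soc) {
  if (length(z_frc) != length(z_soc))
    stop("one_to_one_residuals: unpaired inputs", call. = FALSE)
  r <- z_soc - z_frc
  data.frame(site_id = site_id, ecosystem = ecosystem,
             depth_class = depth_class, z_frc = z_frc, z_soc = z_soc,
             residual = r,
             label = ifelse(r > 0, "accrual",
                            ifelse(r < 0, "priming", "neutral")),
             stringsAsFactors = FALSE)
}

#' Accrual/priming records from site aggregates
#'
#' Builds the shallow and deep standardized FRC-SOC pairs and their 1:1-line
#' residuals. Standardization grouping is per depth class, either pooled
#' across ecosystems (default, so all ecosystems share one 1:1 line) or
#' within ecosystem class.
#'
#' @param aggregates site-aggregate data frame from [site_aggregates()].
#' @param group `"pooled"` or `"by-ecosystem"`.
#' @return Data frame of accrual records, one row per site x depth class.
#' @export
accrual_records <- function(aggregates, group = c("pooled", "by-ecosystem")) {
  group <- match.arg(group)
  eco <- if ("ecosystem_class" %in% names(aggregates))
    aggregates$ecosystem_class else aggregates$ecosystem
  out <- list()
  for (cls in c("shallow", "deep")) {
    fcol <- paste0("frc_", cls); scol <- paste0("soc_", cls)
    gid <- if (group == "pooled") rep(cls, nrow(aggregates))
           else paste(eco, cls, sep = ":")
    for (g in unique(gid)) {
      i <- gid == g
      out[[length(out) + 1]] <- one_to_one_residuals(
        aggregates$site_id[i], eco[i], cls,
        standardize(aggregates[[fcol]][i], group = paste0(g, "/FRC")),
        standardize(aggregates[[scol]][i], group = paste0(g, "/SOC")))
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$depth_class, res$site_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Shallow vs. deep standardized FRC-SOC slopes within an ecosystem
#'
#' Ordinary least squares of `z_soc` on `z_frc` per depth class among the
#' sites of one ecosystem class. A class with fewer than 3 sites is reported
#' excluded rather than fitted.
#'
#' @param records accrual-record data frame from [accrual_records()].
#' @param ecosystem ecosystem class to subset to (e.g. `"grassland"`).
#' @return Data frame with one row per depth class: `depth_class`, `slope`,
#'   `se`, `p`, `n`, `excluded`, `reason`.
#' @export
depth_slope_contrast <- function(records, ecosystem) {
  rows <- lapply(c("shallow", "deep"), function(cls) {
    d <- records[records$ecosystem == ecosystem &
                   records$depth_class == cls, , drop = FALSE]
    if (nrow(d) < 3)
      return(data.frame(depth_class = cls, slope = NA_real_, se = NA_real_,
                        p = NA_real_, n = nrow(d), excluded = TRUE,
                        reason = "insufficient_n", stringsAsFactors = FALSE))
    fit <- stats::lm(z_soc ~ z_frc, data = d)
    cf <- summary(fit)$coefficients
    data.frame(depth_class = cls, slope = cf["z_frc", 1],
               se = cf["z_frc", 2], p = cf["z_frc", 4], n = nrow(d),
               excluded = FALSE, reason = NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Multiple regression of 1:1-line residuals on environmental covariates
#'
#' Explores what predicts inferred accrual/priming within one ecosystem x
#' depth class: `residual ~ covariates` by OLS on complete cases.
#'
#' @param records accrual-record data frame.
#' @param covariates data frame with `site_id` plus covariate columns
#'   (typically aridity, MAP, clay, and a micronutrient proxy); usually the
#'   site-aggregate table.
#' @param terms character vector of covariate column names to use.
#' @param ecosystem,depth_class subset selectors; `NULL` keeps all rows.
#' @return List with `coefficients` (estimate, se, p per term), `adj_r2`,
#'   `p` (overall F), `n`, and the `lm` fit.
#' @export
explain_residuals <- function(records, covariates,
                              terms = c("aridity", "map", "clay_profile",
                                        "micronutrient"),
                              ecosystem = NULL, depth_class = NULL) {
  d <- records
  if (!is.null(ecosystem)) d <- d[d$ecosystem == ecosystem, , drop = FALSE]
  if (!is.null(depth_class))
    d <- d[d$depth_class == depth_class, , drop = FALSE]
  m <- merge(d[, c("site_id", "residual")],
             covariates[, c("site_id", terms), drop = FALSE],
             by = "site_id")
  m <- m[stats::complete.cases(m), , drop = FALSE]
  X <- stats::model.matrix(~ ., data = m[, terms, drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("explain_residuals: rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm(stats::reformulate(terms, response = "residual"), data = m)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  list(coefficients = data.frame(term = rownames(sm$coefficients),
                                 estimate = sm$coefficients[, 1],
                                 se = sm$coefficients[, 2],
                                 p = sm$coefficients[, 4],
                                 row.names = NULL),
       adj_r2 = sm$adj.r.squared,
       p = if (!is.null(fstat))
         stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
       else NA_real_,
       n = nrow(m), fit = fit)
}
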