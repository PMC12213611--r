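# Stock computation and depth alignment.
#
# Roots are sampled on a fixed 10/20-cm increment grid while soils are
# sampled once per taxonomic horizon, so fine-root carbon has to be
# apportioned onto horizon geometry before the two stocks can be compared
# layer by layer.

#' Soil organic carbon stock of one layer
#'
#' `soc = (oc_pct/100) * bulk_density * thickness * 10`, i.e. an organic C
#' mass fraction times a dry mass per volume integrated over the layer, with
#' the g cm^-2 to kg m^-2 conversion folded into the factor 10.
#'
#' @param oc_pct organic carbon concentration, % of dry mass.
#' @param bulk_density g cm^-3.
#' @param thickness layer thickness, cm.
#' @return SOC stock, kg C m^-2. Vectorized.
#' @examples
#' soc_stock(1, 1, 10)     # 1 kg C m^-2
#' soc_stock(2.5, 1.2, 20) # 6 kg C m^-2
#' @export
soc_stock <- function(oc_pct, bulk_density, thickness) {
  if (any(oc_pct < 0 | bulk_density < 0 | thickness < 0, na.rm = TRUE))
    stop("soc_stock: all arguments must be >= 0", call. = FALSE)
  (oc_pct / 100) * bulk_density * thickness * 10
}

#' Fine-root carbon stock of one depth increment
#'
#' `frc = biomass * (root_c_pct/100) / 1000`: root biomass per area times its
#' carbon concentration, converted g m^-2 to kg m^-2.
#'
#' @param biomass root biomass in the increment, g m^-2.
#' @param root_c_pct root carbon concentration, %.
#' @return FRC stock, kg C m^-2. Vectorized.
#' @export
frc_stock <- function(biomass, root_c_pct) {
  if (any(biomass < 0, na.rm = TRUE))
    stop("frc_stock: biomass must be >= 0", call. = FALSE)
  biomass * (root_c_pct / 100) / 1000
}

#' Aridity index
#'
#' `MAP / (MAT + 13)`; the offset keeps the denominator positive for sites
#' with mean annual temperature down to just above -13 degC. Lower values are
#' more arid. Undefined (returned as `NA` with a warning) for `mat <= -13`.
#'
#' @param map mean annual precipitation, mm yr^-1.
#' @param mat mean annual temperature, degC.
#' @return mm degC^-1. Vectorized.
#' @export
aridity_index <- function(map, mat) {
  out <- map / (mat + 13)
  bad <- !is.na(mat) & mat <= -13
  if (any(bad)) {
    warning("aridity_index undefined for mat <= -13; returning NA")
    out[bad] <- NA_real_
  }
  out
}

#' Apportion root increments onto soil horizons
#'
#' Distributes each fixed-depth root increment's carbon stock across the
#' taxonomic horizons it overlaps, proportionally to overlap length (uniform
#' density within an increment). Total apportioned stock equals total input
#' stock over the jointly covered depth range; any root carbon lying below
#' the deepest horizon is reported in a remainder bucket, never dropped.
#'
#' @param increments data frame of root increments for one site (columns
#'   `top`, `bottom`, `biomass`, `root_c_pct`), sorted and non-overlapping,
#'   with any live/dead status filter already applied (rows sharing a depth
#'   interval are summed).
#' @param horizons data frame of soil horizons for one site (columns `top`,
#'   `bottom`, `is_organic`, `oc_pct`, `bulk_density`, `clay_pct`), sorted
#'   and non-overlapping.
#' @return A data frame of per-horizon layer stocks with columns `top`,
#'   `bottom`, `is_organic`, `frc`, `soc`, `clay_pct`, carrying attribute
#'   `frc_below_coverage` (kg C m^-2 of root carbon below the deepest
#'   horizon bottom).
#' @export
align_roots_to_horizons <- function(increments, horizons) {
  if (is.null(horizons) || nrow(horizons) == 0)
    stop("align_roots_to_horizons: horizon list is empty", call. = FALSE)
  horizons <- horizons[order(horizons$top), , drop = FALSE]
  inc_frc <- frc_stock(increments$biomass, increments$root_c_pct)
  # collapse duplicate depth intervals (e.g. live + dead rows)
  if (nrow(increments)) {
    key <- paste(increments$top, increments$bottom)
    agg <- rowsum(inc_frc, key, reorder = FALSE)
    uniq <- !duplicated(key)
    inc <- data.frame(top = increments$top[uniq],
                      bottom = increments$bottom[uniq],
                      frc = agg[match(key[uniq], rownames(agg)), 1])
    inc <- inc[order(inc$top), , drop = FALSE]
  } else {
    inc <- data.frame(top = numeric(0), bottom = numeric(0),
                      frc = numeric(0))
  }
  nh <- nrow(horizons)
  frc_h <- numeric(nh)
  below <- 0
  if (nrow(inc)) {
    # overlap length between increment i and horizon j
    lo <- outer(inc$top, horizons$top, pmax)
    hi <- outer(inc$bottom, horizons$bottom, pmin)
    w <- pmax(hi - lo, 0) / (inc$bottom - inc$top)   # fraction of increment i in horizon j
    frc_h <- as.numeric(crossprod(w, inc$frc))
    deepest <- max(horizons$bottom)
    below <- sum(inc$frc * pmax(inc$bottom - pmax(inc$top, deepest), 0) /
                   (inc$bottom - inc$top))
  }
  out <- data.frame(
    top = horizons$top, bottom = horizons$bottom,
    is_organic = horizons$is_organic,
    frc = frc_h,
    soc = soc_stock(horizons$oc_pct, horizons$bulk_density,
                    horizons$bottom - horizons$top),
    clay_pct = horizons$clay_pct
  )
  attr(out, "frc_below_coverage") <- below
  out
}

#' Aggregate layer stocks for one site
#'
#' Sums FRC and SOC over the whole profile, by organic/mineral horizon class,
#' and by the 30-cm shallow/deep split (`[0, 30)` cm shallow, `[30, 200]` cm
#' deep; a layer straddling 30 cm is split proportionally to length). Also
#' computes depth-weighted mean clay per depth class and the aridity index.
#'
#' @param layers layer-stock data frame from [align_roots_to_horizons()].
#' @param meta one-row data frame of site metadata (columns `site_id`,
#'   `ecosystem`, `mat`, `map`, `litterfall`, `max_profile_depth`, optionally
#'   `micronutrient`).
#' @param shallow_depth split depth in cm (default 30).
#' @return One-row data frame of site aggregates.
#' @export
aggregate_site <- function(layers, meta, shallow_depth = 30) {
  th <- layers$bottom - layers$top
  # fraction of each layer above the split depth
  f_sh <- pmax(pmin(layers$bottom, shallow_depth) - layers$top, 0) / th
  wclay <- function(sel_w) {
    w <- th * sel_w
    if (sum(w) <= 0) return(NA_real_)
    sum(layers$clay_pct * w) / sum(w)
  }
  data.frame(
    site_id = meta$site_id,
    ecosystem = meta$ecosystem,
    frc_total = sum(layers$frc),
    soc_total = sum(layers$soc),
    frc_organic = sum(layers$frc[layers$is_organic]),
    soc_organic = sum(layers$soc[layers$is_organic]),
    frc_mineral = sum(layers$frc[!layers$is_organic]),
    soc_mineral = sum(layers$soc[!layers$is_organic]),
    frc_shallow = sum(layers$frc * f_sh),
    soc_shallow = sum(layers$soc * f_sh),
    frc_deep = sum(layers$frc * (1 - f_sh)),
    soc_deep = sum(layers$soc * (1 - f_sh)),
    clay_profile = wclay(rep(1, nrow(layers))),
    clay_shallow = wclay(f_sh),
    clay_deep = wclay(1 - f_sh),
    mat = meta$mat,
    map = meta$map,
    aridity = aridity_index(meta$map, meta$mat),
    litterfall = if ("litterfall" %in% names(meta)) meta$litterfall else NA_real_,
    micronutrient = if ("micronutrient" %in% names(meta)) meta$micronutrient else NA_real_,
    max_profile_depth = meta$max_profile_depth,
    stringsAsFactors = FALSE
  )
}

#' Layer stocks for every retained site
#'
#' Runs [align_roots_to_horizons()] per site over a `site_tables` object.
#'
#' @param tables a `site_tables` object.
#' @param status which root rows enter FRC: `"all"` (live + dead standing
#'   stock, the default) or `"live"`.
#' @return Data frame of layer stocks (`site_id`, `top`, `bottom`,
#'   `is_organic`, `frc`, `soc`, `clay_pct`) for all non-excluded sites, with
#'   attribute `frc_below_coverage`, a named vector per site.
#' @export
site_layer_stocks <- function(tables, status = c("all", "live")) {
  status <- match.arg(status)
  roots <- tables$roots
  if (status == "live")
    roots <- roots[roots$status == "live", , drop = FALSE]
  keep <- analysis_sites(tables)
  out <- vector("list", length(keep))
  below <- numeric(length(keep))
  for (i in seq_along(keep)) {
    s <- keep[i]
    lay <- align_roots_to_horizons(
      roots[roots$site_id == s, , drop = FALSE],
      tables$horizons[tables$horizons$site_id == s, , drop = FALSE])
    below[i] <- attr(lay, "frc_below_coverage")
    out[[i]] <- cbind(site_id = s, lay)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "frc_below_coverage") <- stats::setNames(below, keep)
  res
}

#' Root-increment FRC stocks at sampling resolution
#'
#' FRC stock per original depth increment (live/dead rows summed per the
#' status filter), before any alignment onto horizons. This is the natural
#' resolution for the FRC depth-distribution (beta) fit, which the coarser
#' horizon-aligned layers would degrade.
#'
#' @inheritParams site_layer_stocks
#' @return Data frame `site_id`, `top`, `bottom`, `frc` for all retained
#'   sites.
#' @export
root_increment_stocks <- function(tables, status = c("all", "live")) {
  status <- match.arg(status)
  roots <- tables$roots
  if (status == "live")
    roots <- roots[roots$status == "live", , drop = FALSE]
  roots <- roots[roots$site_id %in% analysis_sites(tables), , drop = FALSE]
  frc <- frc_stock(roots$biomass, roots$root_c_pct)
  key <- paste(roots$site_id, roots$top, roots$bottom)
  agg <- rowsum(frc, key, reorder = FALSE)
  uniq <- !duplicated(key)
  out <- data.frame(site_id = roots$site_id[uniq], top = roots$top[uniq],
                    bottom = roots$bottom[uniq],
                    frc = agg[match(key[uniq], rownames(agg)), 1],
                    stringsAsFactors = FALSE)
  out <- out[order(out$site_id, out$top), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Site aggregates for every retained site
#'
#' @inheritParams site_layer_stocks
#' @param tundra_class ecosystem class under which tundra sites are analyzed
#'   (default `"grassland"`); the original tag is kept in `ecosystem`, the
#'   analysis class in `ecosystem_class`.
#' @param shallow_depth shallow/deep split depth, cm.
#' @return Data frame, one row per retained site, with stock aggregates,
#'   climate covariates, aridity, depth-weighted clay, and `ecosystem_class`.
#' @export
site_aggregates <- function(tables, status = c("all", "live"),
                            tundra_class = "grassland", shallow_depth = 30) {
  status <- match.arg(status)
  stocks <- site_layer_stocks(tables, status = status)
  keep <- analysis_sites(tables)
  rows <- lapply(keep, function(s) {
    aggregate_site(stocks[stocks$site_id == s, , drop = FALSE],
                   tables$sites[tables$sites$site_id == s, , drop = FALSE],
                   shallow_depth = shallow_depth)
  })
  agg <- do.call(rbind, rows)
  rownames(agg) <- NULL
  agg$ecosystem_class <- ifelse(agg$ecosystem == "tundra", tundra_class,
                                agg$ecosystem)
  agg
}
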