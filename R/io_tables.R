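#' rootsoc: fine-root and soil organic carbon stock profiles
#'
#' Tools for linking fine-root carbon (FRC) stocks to soil organic carbon
#' (SOC) stocks across megapit-style soil profiles: depth alignment of
#' fixed-increment root samples onto taxonomic horizons, stock computation,
#' exponential depth-distribution (beta) fitting, standardized 1:1-line
#' residual scoring of inferred SOC accrual vs. priming, and AIC/AICc model
#' selection, plus a synthetic site generator with known ground truth.
#'
#' @section Depth convention:
#' Depths are in cm, positive downward, with 0 at the top of the uppermost
#' horizon (organic horizons included on the same axis). All depth intervals
#' are half-open `[top, bottom)`.
#'
#' @name rootsoc-package
#' @keywords internal
"_PACKAGE"

# ---- schemas -------------------------------------------------------------

.sites_cols <- c("site_id", "ecosystem", "mat", "map", "litterfall",
                 "max_profile_depth")
.horizons_cols <- c("site_id", "horizon_label", "top", "bottom", "is_organic",
                    "oc_pct", "bulk_density", "clay_pct")
.roots_cols <- c("site_id", "top", "bottom", "biomass", "root_c_pct",
                 "status", "diameter_protocol")

.ecosystems <- c("forest", "grassland", "shrubland", "cultivated", "tundra")

.check_cols <- function(df, needed, what) {
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}

.check_layers <- function(df, what) {
  # per-site: 0 <= top < bottom, sorted, non-overlapping
  bad <- which(!(df$top >= 0 & df$bottom > df$top))
  if (length(bad))
    stop(sprintf("%s: invalid depth bounds (need 0 <= top < bottom) in row(s): %s",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  for (s in unique(df$site_id)) {
    d <- df[df$site_id == s, , drop = FALSE]
    d <- d[order(d$top), , drop = FALSE]
    if (nrow(d) > 1 && any(d$top[-1] < d$bottom[-nrow(d)] - 1e-9)) {
      ov <- which(d$top[-1] < d$bottom[-nrow(d)] - 1e-9)
      stop(sprintf("%s: overlapping layers at site %s (rows starting at top = %s)",
                   what, s, paste(d$top[ov + 1], collapse = ", ")),
           call. = FALSE)
    }
  }
  invisible(df)
}

.validate_sites <- function(sites) {
  .check_cols(sites, .sites_cols, "sites")
  if (anyDuplicated(sites$site_id))
    stop("sites: duplicated site_id", call. = FALSE)
  if (any(!sites$ecosystem %in% .ecosystems))
    stop("sites: unknown ecosystem value(s): ",
         paste(setdiff(unique(sites$ecosystem), .ecosystems), collapse = ", "),
         call. = FALSE)
  if (any(sites$map < 0, na.rm = TRUE))
    stop("sites: map must be >= 0", call. = FALSE)
  ok_depth <- sites$max_profile_depth > 0 & sites$max_profile_depth <= 200
  if (any(!ok_depth, na.rm = TRUE))
    stop("sites: max_profile_depth must be in (0, 200]", call. = FALSE)
  invisible(sites)
}

.validate_horizons <- function(horizons) {
  .check_cols(horizons, .horizons_cols, "horizons")
  .check_layers(horizons, "horizons")
  if (any(horizons$oc_pct < 0 | horizons$oc_pct > 60, na.rm = TRUE))
    stop("horizons: oc_pct must be in [0, 60]", call. = FALSE)
  if (any(horizons$bulk_density <= 0, na.rm = TRUE))
    stop("horizons: bulk_density must be > 0", call. = FALSE)
  if (any(horizons$clay_pct < 0 | horizons$clay_pct > 100, na.rm = TRUE))
    stop("horizons: clay_pct must be in [0, 100]", call. = FALSE)
  invisible(horizons)
}

.validate_roots <- function(roots) {
  .check_cols(roots, .roots_cols, "roots")
  if (any(roots$biomass < 0, na.rm = TRUE))
    stop("roots: biomass must be >= 0", call. = FALSE)
  if (any(roots$root_c_pct <= 0 | roots$root_c_pct > 100, na.rm = TRUE))
    stop("roots: root_c_pct must be in (0, 100]", call. = FALSE)
  if (any(!roots$status %in% c("live", "dead")))
    stop("roots: status must be 'live' or 'dead'", call. = FALSE)
  if (any(!roots$diameter_protocol %in% c("2mm", "4mm")))
    stop("roots: diameter_protocol must be '2mm' or '4mm'", call. = FALSE)
  # increments may repeat a depth interval across statuses; check overlap
  # within site x status only
  key <- paste(roots$site_id, roots$status)
  for (k in unique(key)) {
    d <- roots[key == k, c("site_id", "top", "bottom"), drop = FALSE]
    .check_layers(d, sprintf("roots (site %s)", d$site_id[1]))
  }
  invisible(roots)
}

# ---- reading -------------------------------------------------------------

#' Read the three flat site tables
#'
#' Reads `sites.csv`, `horizons.csv` and `roots.csv` (comma-separated, UTF-8,
#' `.` decimal, empty cell = missing), validates every row against the schema
#' invariants, and flags — never silently drops — sites that cannot enter the
#' analysis (e.g. sites with metadata but no root records, mirroring megapit
#' sites where roots were not collected).
#'
#' @param sites_path,horizons_path,roots_path paths to the three CSV files.
#' @return An object of class `site_tables`: a list with elements `sites`,
#'   `horizons`, `roots` (validated data frames) and `excluded`, a data frame
#'   of `site_id` and machine-readable `reason` codes
#'   (`"no_root_data"`, `"no_horizon_data"`).
#' @export
read_site_tables <- function(sites_path, horizons_path, roots_path) {
  for (p in c(sites_path, horizons_path, roots_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  sites <- utils::read.csv(sites_path, stringsAsFactors = FALSE)
  horizons <- utils::read.csv(horizons_path, stringsAsFactors = FALSE)
  roots <- utils::read.csv(roots_path, stringsAsFactors = FALSE)
  site_tables(sites, horizons, roots)
}

#' Assemble and validate site tables already in memory
#'
#' Same contract as [read_site_tables()] but starting from data frames; this
#' is the entry point used by the synthetic generator and by simulations that
#' never touch disk.
#'
#' @param sites,horizons,roots data frames following the flat-table schemas.
#' @return A `site_tables` object; see [read_site_tables()].
#' @export
site_tables <- function(sites, horizons, roots) {
  .validate_sites(sites)
  if (is.character(horizons$is_organic))
    horizons$is_organic <- as.logical(horizons$is_organic)
  .validate_horizons(horizons)
  .validate_roots(roots)
  orphan <- unique(c(setdiff(horizons$site_id, sites$site_id),
                     setdiff(roots$site_id, sites$site_id)))
  if (length(orphan))
    stop("rows reference site_id absent from sites table: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  flag <- function(ids, reason) {
    if (!length(ids))
      return(data.frame(site_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE))
    data.frame(site_id = ids, reason = reason, stringsAsFactors = FALSE)
  }
  excluded <- rbind(
    flag(setdiff(sites$site_id, roots$site_id), "no_root_data"),
    flag(setdiff(sites$site_id, horizons$site_id), "no_horizon_data"))
  excluded <- excluded[order(excluded$site_id, excluded$reason), ,
                       drop = FALSE]
  rownames(excluded) <- NULL
  structure(list(sites = sites, horizons = horizons, roots = roots,
                 excluded = excluded),
            class = "site_tables")
}

#' @export
print.site_tables <- function(x, ...) {
  cat(sprintf("site_tables: %d sites (%d excluded), %d horizons, %d root rows\n",
              nrow(x$sites), nrow(x$excluded), nrow(x$horizons),
              nrow(x$roots)))
  if (nrow(x$excluded))
    cat("  excluded:", paste(sprintf("%s [%s]", x$excluded$site_id,
                                     x$excluded$reason), collapse = ", "),
        "\n")
  invisible(x)
}

#' Site identifiers retained for analysis
#'
#' @param tables a `site_tables` object.
#' @return Character vector of site ids not flagged excluded.
#' @export
analysis_sites <- function(tables) {
  setdiff(tables$sites$site_id, tables$excluded$site_id)
}

# ---- writing -------------------------------------------------------------

#' Write derived products to CSV / JSON
#'
#' Serializes pipeline products with a deterministic column order so that
#' identical inputs produce byte-identical files. Numeric values survive a
#' write/read round trip to better than 1e-12 relative. An empty result
#' writes a header-only file.
#'
#' @param results named list; recognized names are `stocks`, `aggregates`,
#'   `beta`, `accrual` (data frames, written as `<name>.csv`) and `models`
#'   (a list, written as `models.json`).
#' @param dir output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(results, dir) {
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  col_order <- list(
    stocks = c("site_id", "top", "bottom", "is_organic", "frc", "soc",
               "clay_pct"),
    beta = c("site_id", "quantity", "beta", "sse", "n_points", "excluded",
             "reason"),
    accrual = c("site_id", "ecosystem", "depth_class", "z_frc", "z_soc",
                "residual", "label")
  )
  paths <- character(0)
  for (nm in intersect(c("stocks", "aggregates", "beta", "accrual"),
                       names(results))) {
    df <- results[[nm]]
    ord <- col_order[[nm]]
    if (!is.null(ord))
      df <- df[, c(intersect(ord, names(df)),
                   setdiff(names(df), ord)), drop = FALSE]
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(format_for_csv(df), p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  if ("models" %in% names(results)) {
    p <- file.path(dir, "models.json")
    jsonlite::write_json(results$models, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

# full-precision, locale-independent numeric formatting for CSV output
format_for_csv <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]]))
      df[[j]] <- formatC(df[[j]], digits = 17, format = "g")
  }
  df
}
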