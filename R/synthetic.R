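# Synthetic megapit-like site generator with known ground truth.
#
# Emulates the sampling design the pipeline is built for: root biomass on a
# fixed grid of 10-cm increments to 1 m then 20-cm increments to 2 m (or to
# bedrock), soil chemistry by taxonomic horizon with boundaries drawn
# independently of the increment grid, stocks declining with depth along
# Y = 1 - beta^d curves, and a linear FRC -> SOC coupling with
# ecosystem-specific slope and noise. Everything is driven by one integer
# seed so runs are exactly reproducible.

#' Fixed root-sampling increment grid
#'
#' 10-cm increments to 1 m, then 20-cm increments down to `depth`.
#'
#' @param depth profile depth, cm (<= 200).
#' @return Data frame with columns `top`, `bottom`.
#' @export
megapit_increment_grid <- function(depth) {
  b <- c(seq(10, min(100, depth), by = 10),
         if (depth > 100) seq(120, depth, by = 20))
  data.frame(top = c(0, b[-length(b)]), bottom = b)
}

#' Generator configuration
#'
#' Defaults emulate the study conditions: 25 forests, 15 grasslands (of
#' which `outlier_tundra` are high-FRC tundra sites analyzed under the
#' grassland class), 2 shrublands and 1 cultivated site; MAT spanning -12 to
#' 25 degC and MAP 100 to 2500 mm with grassland MAP centred near half the
#' forest mean; grassland whole-profile coupling `SOC = 8.5 + 15.5 FRC + e`
#' and no forest coupling; organic horizons mostly in forests and tundra.
#'
#' @param n_sites named integer vector of sites per ecosystem.
#' @param coupling per-ecosystem list of `a` (intercept, kg m^-2), `b`
#'   (slope, kg SOC per kg FRC) and `sigma` (site-level sd, kg m^-2) for
#'   `SOC_total = a + b * FRC_total + N(0, sigma^2)`. Tundra sites use the
#'   grassland coupling.
#' @param depth_slopes `NULL` (default: depth distributions follow the beta
#'   curves) or a list with `shallow`, `deep`, `sigma`, `tau`, `rho` to
#'   generate shallow/deep stocks with known standardized-scale slopes in
#'   grasslands against a forest background (see the methods vignette).
#' @param noise_cv multiplicative layer-level noise (lognormal CV).
#' @param outlier_tundra number of grassland-class sites tagged tundra whose
#'   observed FRC is inflated by `outlier_factor` after the SOC coupling is
#'   applied (high-latitude high-root-biomass outliers).
#' @param outlier_factor FRC inflation factor for tundra outliers.
#' @param organic_prob per-ecosystem probability of a surface organic
#'   horizon.
#' @param depth_weights sampling weights for bedrock-truncated profile
#'   depths 100, 140, 200 cm.
#' @param ... named overrides for the remaining defaults (`climate`,
#'   `beta_range`, `frc_lognorm`, `root_c_range`, `protocol_4mm_prob`,
#'   `dead_fraction_range`).
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_sites = c(forest = 25, grassland = 15,
                                     shrubland = 2, cultivated = 1),
                         coupling = NULL, depth_slopes = NULL,
                         noise_cv = 0.10, outlier_tundra = 2,
                         outlier_factor = 2.5, organic_prob = NULL,
                         depth_weights = c(`100` = 0.15, `140` = 0.15,
                                           `200` = 0.70),
                         ...) {
  cfg <- list(
    n_sites = n_sites,
    climate = list(   # mat range (degC), map range (mm)
      forest     = list(mat = c(0, 25),  map = c(600, 2500)),
      grassland  = list(mat = c(-5, 22), map = c(100, 1300)),
      shrubland  = list(mat = c(5, 25),  map = c(100, 600)),
      cultivated = list(mat = c(5, 15),  map = c(400, 1000)),
      tundra     = list(mat = c(-12, -2), map = c(100, 500))),
    beta_range = list(  # true beta ranges per ecosystem (frc, soc)
      forest     = list(frc = c(0.94, 0.97), soc = c(0.95, 0.985)),
      grassland  = list(frc = c(0.91, 0.95), soc = c(0.94, 0.98)),
      shrubland  = list(frc = c(0.92, 0.96), soc = c(0.94, 0.98)),
      cultivated = list(frc = c(0.91, 0.95), soc = c(0.94, 0.98)),
      tundra     = list(frc = c(0.90, 0.94), soc = c(0.93, 0.97))),
    frc_lognorm = list( # whole-profile FRC totals, kg C m^-2
      forest = c(meanlog = log(0.5), sdlog = 0.4),
      grassland = c(meanlog = log(0.6), sdlog = 0.4),
      shrubland = c(meanlog = log(0.3), sdlog = 0.4),
      cultivated = c(meanlog = log(0.4), sdlog = 0.3),
      tundra = c(meanlog = log(0.6), sdlog = 0.4)),
    coupling = list(
      forest = list(a = 12, b = 0, sigma = 6),
      grassland = list(a = 8.5, b = 15.5, sigma = 2),
      shrubland = list(a = 6, b = 0, sigma = 3),
      cultivated = list(a = 8, b = 0, sigma = 3)),
    organic_prob = c(forest = 0.6, grassland = 0.13, shrubland = 0,
                     cultivated = 0, tundra = 1),
    depth_slopes = depth_slopes,
    noise_cv = noise_cv,
    outlier_tundra = outlier_tundra,
    outlier_factor = outlier_factor,
    depth_weights = depth_weights,
    root_c_range = c(42, 50),
    protocol_4mm_prob = 0.3,
    dead_fraction_range = c(0.1, 0.3)
  )
  if (!is.null(coupling))
    cfg$coupling[names(coupling)] <- coupling
  if (!is.null(organic_prob))
    cfg$organic_prob[names(organic_prob)] <- organic_prob
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "synth_config")
}

#' Canonical depth-coupled cohort design
#'
#' The frozen design for generating shallow/deep stocks with known
#' standardized-scale FRC-SOC slopes: grassland deep slope 1.2 and shallow
#' slope 0.9 on the pooled-standardization scale, grassland z-spread `tau`,
#' disturbance sd `sigma`, and shallow-deep correlation `rho` (site-level
#' drivers are largely shared between depths). Forest background variances
#' are solved inside [synth_generate()] so the pooled standardization group
#' has unit variance by design, which is what makes the stated slopes the
#' true estimands.
#'
#' @param shallow,deep standardized-scale slopes in grasslands.
#' @param sigma sd of the z-scale SOC disturbance in grasslands.
#' @param tau sd of the grassland z-scale FRC spread.
#' @param rho shallow-deep correlation of both FRC spread and disturbance.
#' @return List usable as `depth_slopes` in [synth_config()].
#' @export
depth_slope_design <- function(shallow = 0.9, deep = 1.2, sigma = 0.65,
                               tau = 0.6, rho = 0.85) {
  list(shallow = shallow, deep = deep, sigma = sigma, tau = tau, rho = rho)
}

.rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# beta-curve weights of depth intervals [top, bottom), normalized on support
.beta_weights <- function(beta, top, bottom) {
  w <- beta^top - beta^bottom
  w / sum(w)
}

# correlated standard-normal pair columns
.rbvn <- function(n, rho) {
  u <- stats::rnorm(n); v <- stats::rnorm(n)
  cbind(u, rho * u + sqrt(1 - rho^2) * v)
}

# random horizon boundaries: optional organic cap, then mineral cuts drawn
# independently of the increment grid; `force` depths become boundaries
.horizon_bounds <- function(depth, o_thick, force = numeric(0)) {
  n_cut <- sample(2:6, 1)
  inner <- sort(stats::runif(n_cut, o_thick + 4, depth - 4))
  inner <- round(inner)
  b <- sort(unique(c(0, if (o_thick > 0) o_thick, inner, force, depth)))
  # enforce a minimum 3-cm horizon thickness, keeping forced boundaries
  keep <- c(TRUE, diff(b) >= 3)
  keep[b %in% c(0, o_thick, force, depth)] <- TRUE
  b <- b[keep]
  while (any(diff(b) < 3)) {
    i <- which(diff(b) < 3)[1] + 1
    if (b[i] %in% c(force, depth)) i <- i - 1
    if (i == 1) break
    b <- b[-i]
  }
  b
}

#' Generate a synthetic site collection
#'
#' @param config a [synth_config()].
#' @param seed integer seed; fully determines the output.
#' @return A list of class `synth_data` with elements `tables` (a validated
#'   `site_tables` object: `sites`, `horizons`, `roots`) and `truth` (a data
#'   frame of per-site true parameters: betas, totals, coupling, noise draw,
#'   and accrual/priming regime). `truth` is emitted alongside the data and
#'   is never consumed by pipeline stages.
#' @export
synth_generate <- function(config = synth_config(), seed = 1) {
  set.seed(as.integer(seed))
  ds <- config$depth_slopes
  if (!is.null(ds) &&
      !all(names(config$n_sites) %in% c("forest", "grassland")))
    stop("depth_slopes mode supports forest + grassland cohorts only",
         call. = FALSE)

  # per-site ecosystem tags, tundra replacing leading grassland slots
  tags <- unlist(lapply(names(config$n_sites), function(e)
    rep(e, config$n_sites[[e]])), use.names = FALSE)
  is_tundra <- logical(length(tags))
  gi <- which(tags == "grassland")
  if (config$outlier_tundra > 0 && length(gi) && is.null(ds)) {
    tt <- gi[seq_len(min(config$outlier_tundra, length(gi)))]
    tags[tt] <- "tundra"; is_tundra[tt] <- TRUE
  }
  n <- length(tags)
  cls <- ifelse(tags == "tundra", "grassland", tags)
  id <- sprintf("%s%02d", toupper(substr(tags, 1, 3)), seq_len(n))

  # designed z-scale shallow/deep stocks (depth-coupled mode)
  if (!is.null(ds)) {
    n_g <- sum(cls == "grassland"); n_f <- sum(cls == "forest")
    nn <- n_g + n_f
    vfx <- (nn - n_g * ds$tau^2) / n_f
    vfs <- c(shallow = (nn - n_g * (ds$shallow^2 * ds$tau^2 + ds$sigma^2)) / n_f,
             deep = (nn - n_g * (ds$deep^2 * ds$tau^2 + ds$sigma^2)) / n_f)
    if (any(vfs <= 0) || vfx <= 0)
      stop("depth_slopes: infeasible design (negative background variance)",
           call. = FALSE)
    zf <- zs <- matrix(NA_real_, n, 2, dimnames = list(NULL,
                                                       c("shallow", "deep")))
    g <- cls == "grassland"
    x <- .rbvn(n_g, ds$rho) * ds$tau
    e <- .rbvn(n_g, ds$rho) * ds$sigma
    zf[g, ] <- x
    zs[g, ] <- cbind(ds$shallow * x[, 1] + e[, 1],
                     ds$deep * x[, 2] + e[, 2])
    zf[!g, ] <- .rbvn(n_f, ds$rho) * sqrt(vfx)
    zs[!g, ] <- .rbvn(n_f, ds$rho) %*% diag(sqrt(vfs))
    # affine map to positive raw stocks (standardization is affine-invariant)
    frc_band <- cbind(pmax(1.0 + 0.20 * zf[, 1], 0.01),
                      pmax(0.6 + 0.12 * zf[, 2], 0.01))
    soc_band <- cbind(pmax(8 + 2.0 * zs[, 1], 0.05),
                      pmax(10 + 2.5 * zs[, 2], 0.05))
  }

  sites <- horizons <- roots <- truth <- list()
  for (i in seq_len(n)) {
    eco <- tags[i]
    clim <- config$climate[[eco]]
    mat <- stats::runif(1, clim$mat[1], clim$mat[2])
    map <- stats::runif(1, clim$map[1], clim$map[2])
    depth <- as.numeric(sample(names(config$depth_weights), 1,
                               prob = config$depth_weights))
    br <- config$beta_range[[eco]]
    beta_frc <- stats::runif(1, br$frc[1], br$frc[2])
    beta_soc <- stats::runif(1, br$soc[1], br$soc[2])
    organic <- stats::runif(1) < config$organic_prob[[eco]]
    o_thick <- if (organic) round(stats::runif(1, 3, 8)) else 0
    root_c <- stats::runif(1, config$root_c_range[1], config$root_c_range[2])
    dead_f <- stats::runif(1, config$dead_fraction_range[1],
                           config$dead_fraction_range[2])
    proto <- if (stats::runif(1) < config$protocol_4mm_prob) "4mm" else "2mm"
    clay_base <- stats::runif(1, 5, 45)
    micronutrient <- stats::rlnorm(1, 0, 0.4)
    litterfall <- if (eco == "forest") round(stats::runif(1, 200, 600))
                  else NA_real_

    cp <- config$coupling[[if (eco %in% names(config$coupling)) eco
                           else "grassland"]]

    if (is.null(ds)) {
      # whole-profile coupling, depth shape from the beta curves
      ln <- config$frc_lognorm[[eco]]
      frc_pre <- stats::rlnorm(1, ln["meanlog"], ln["sdlog"])
      eps <- NA_real_
      for (try in 1:100) {
        eps <- stats::rnorm(1, 0, cp$sigma)
        if (cp$a + cp$b * frc_pre + eps > 0.5) break
        if (try == 100) {
          warning("synth_generate: clamping non-positive SOC total")
          eps <- 0.5 - cp$a - cp$b * frc_pre
        }
      }
      soc_total <- cp$a + cp$b * frc_pre + eps
      frc_total <- if (is_tundra[i]) frc_pre * config$outlier_factor
                   else frc_pre
      bounds <- .horizon_bounds(depth, o_thick)
      grid <- megapit_increment_grid(depth)
      wf <- .beta_weights(beta_frc, grid$top, grid$bottom) *
        .rlnorm_cv(nrow(grid), config$noise_cv)
      frc_inc <- frc_total * wf / sum(wf)
      htop <- bounds[-length(bounds)]; hbot <- bounds[-1]
      ws <- .beta_weights(beta_soc, htop, hbot) *
        .rlnorm_cv(length(htop), config$noise_cv)
      soc_h <- soc_total * ws / sum(ws)
    } else {
      # designed shallow/deep band stocks with a boundary forced at 30 cm
      frc_total <- sum(frc_band[i, ]); soc_total <- sum(soc_band[i, ])
      frc_pre <- frc_total; eps <- NA_real_
      bounds <- .horizon_bounds(depth, o_thick, force = 30)
      grid <- megapit_increment_grid(depth)
      frc_inc <- numeric(nrow(grid))
      htop <- bounds[-length(bounds)]; hbot <- bounds[-1]
      soc_h <- numeric(length(htop))
      for (band in 1:2) {
        bi <- if (band == 1) grid$bottom <= 30 else grid$top >= 30
        w <- .beta_weights(beta_frc, grid$top[bi], grid$bottom[bi]) *
          .rlnorm_cv(sum(bi), config$noise_cv)
        frc_inc[bi] <- frc_band[i, band] * w / sum(w)
        hj <- if (band == 1) hbot <= 30 else htop >= 30
        w <- .beta_weights(beta_soc, htop[hj], hbot[hj]) *
          .rlnorm_cv(sum(hj), config$noise_cv)
        soc_h[hj] <- soc_band[i, band] * w / sum(w)
      }
    }

    # horizon chemistry consistent with the target stocks
    th <- hbot - htop
    is_org <- htop < o_thick
    bd <- ifelse(is_org, stats::runif(length(th), 0.15, 0.35),
                 pmin(pmax(0.9 + 0.0035 * (htop + hbot) / 2 +
                             stats::rnorm(length(th), 0, 0.05), 0.5), 1.8))
    oc <- 10 * soc_h / (bd * th)
    over <- oc > 60   # raise bulk density rather than lose stock
    bd[over] <- 10 * soc_h[over] / (60 * th[over])
    oc[over] <- 60
    clay <- pmin(pmax(clay_base + 0.02 * (htop + hbot) / 2 +
                        stats::rnorm(length(th), 0, 3), 1), 60)
    clay[is_org] <- pmin(clay[is_org], 10)

    biomass <- frc_inc * 1e5 / root_c
    sites[[i]] <- data.frame(
      site_id = id[i], ecosystem = eco, mat = mat, map = map,
      litterfall = litterfall, max_profile_depth = depth,
      micronutrient = micronutrient, stringsAsFactors = FALSE)
    horizons[[i]] <- data.frame(
      site_id = id[i],
      horizon_label = paste0(ifelse(is_org, "O", "M"),
                             seq_along(htop)),
      top = htop, bottom = hbot, is_organic = is_org, oc_pct = oc,
      bulk_density = bd, clay_pct = clay, stringsAsFactors = FALSE)
    roots[[i]] <- rbind(
      data.frame(site_id = id[i], top = grid$top, bottom = grid$bottom,
                 biomass = biomass * (1 - dead_f), root_c_pct = root_c,
                 status = "live", diameter_protocol = proto,
                 stringsAsFactors = FALSE),
      data.frame(site_id = id[i], top = grid$top, bottom = grid$bottom,
                 biomass = biomass * dead_f, root_c_pct = root_c,
                 status = "dead", diameter_protocol = proto,
                 stringsAsFactors = FALSE))
    truth[[i]] <- data.frame(
      site_id = id[i], ecosystem = eco, ecosystem_class = cls[i],
      beta_frc = beta_frc, beta_soc = beta_soc,
      frc_total = frc_total, frc_pre_outlier = frc_pre,
      soc_total = soc_total,
      coupling_a = cp$a, coupling_b = cp$b, coupling_sigma = cp$sigma,
      eps = eps,
      regime = if (is.na(eps)) NA_character_
               else if (eps > 0) "accrual" else "priming",
      z_frc_shallow = if (!is.null(ds)) zf[i, 1] else NA_real_,
      z_frc_deep = if (!is.null(ds)) zf[i, 2] else NA_real_,
      z_soc_shallow = if (!is.null(ds)) zs[i, 1] else NA_real_,
      z_soc_deep = if (!is.null(ds)) zs[i, 2] else NA_real_,
      stringsAsFactors = FALSE)
  }
  tables <- site_tables(do.call(rbind, sites), do.call(rbind, horizons),
                        do.call(rbind, roots))
  structure(list(tables = tables, truth = do.call(rbind, truth),
                 seed = as.integer(seed)),
            class = "synth_data")
}

#' Tiny deterministic fixtures
#'
#' Hand-built datasets (at most 5 sites) exercising specific pipeline
#' geometry:
#' \describe{
#'   \item{`perfect-1to1`}{four sites whose SOC is exactly proportional to
#'     FRC, so every standardized 1:1 residual is 0.}
#'   \item{`all-accrual`}{grassland sites above, forest sites below the
#'     pooled 1:1 line: every grassland record classifies accrual.}
#'   \item{`two-horizon-misaligned`}{one site where the increment
#'     `[20, 30)` straddles a horizon boundary at 25 cm and must split
#'     50/50.}
#'   \item{`no-roots-site`}{two sites, one with no root rows, which must be
#'     flagged excluded.}
#' }
#'
#' @param name fixture name.
#' @return A `site_tables` object.
#' @export
make_fixture <- function(name = c("perfect-1to1", "all-accrual",
                                  "two-horizon-misaligned",
                                  "no-roots-site")) {
  name <- match.arg(name)
  meta <- function(id, eco) data.frame(
    site_id = id, ecosystem = eco, mat = 10, map = 800,
    litterfall = NA_real_, max_profile_depth = 100,
    stringsAsFactors = FALSE)
  hz <- function(id, oc) data.frame(
    site_id = id, horizon_label = "M1", top = 0, bottom = 100,
    is_organic = FALSE, oc_pct = oc, bulk_density = 1.0, clay_pct = 20,
    stringsAsFactors = FALSE)
  rt <- function(id, biomass) data.frame(
    site_id = id, top = 0, bottom = 100, biomass = biomass,
    root_c_pct = 50, status = "live", diameter_protocol = "2mm",
    stringsAsFactors = FALSE)
  if (name == "perfect-1to1") {
    ids <- c("G01", "G02", "F01", "F02")
    eco <- c("grassland", "grassland", "forest", "forest")
    frc <- c(0.2, 0.4, 0.6, 0.8)                   # kg m^-2
    soc <- 10 * frc
    return(site_tables(
      do.call(rbind, Map(meta, ids, eco)),
      do.call(rbind, Map(hz, ids, soc / 10)),      # oc% over 100 cm, bd 1
      do.call(rbind, Map(rt, ids, frc * 1e5 / 50))))
  }
  if (name == "all-accrual") {
    ids <- c("G01", "G02", "F01", "F02")
    eco <- c("grassland", "grassland", "forest", "forest")
    frc <- c(0.2, 0.8, 0.4, 0.6)
    soc <- 10 * frc + c(3, 3, -3, -3)
    return(site_tables(
      do.call(rbind, Map(meta, ids, eco)),
      do.call(rbind, Map(hz, ids, soc / 10)),
      do.call(rbind, Map(rt, ids, frc * 1e5 / 50))))
  }
  if (name == "two-horizon-misaligned") {
    s <- meta("M01", "grassland")
    h <- data.frame(site_id = "M01", horizon_label = c("M1", "M2"),
                    top = c(0, 25), bottom = c(25, 100),
                    is_organic = FALSE, oc_pct = c(2, 1),
                    bulk_density = c(1.0, 1.2), clay_pct = c(15, 25),
                    stringsAsFactors = FALSE)
    r <- data.frame(site_id = "M01", top = c(0, 10, 20),
                    bottom = c(10, 20, 30), biomass = c(200, 100, 100),
                    root_c_pct = 50, status = "live",
                    diameter_protocol = "2mm", stringsAsFactors = FALSE)
    return(site_tables(s, h, r))
  }
  # no-roots-site
  s <- rbind(meta("A01", "forest"), meta("B01", "forest"))
  h <- rbind(hz("A01", 2), hz("B01", 2))
  r <- rt("A01", 500)
  site_tables(s, h, r)
}
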