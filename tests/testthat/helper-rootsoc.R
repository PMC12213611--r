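# Shared test utilities: independent oracles and small profile builders.

# OLS slope/intercept by explicit normal equations (independent of lm)
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# noiseless layer stocks following Y = 1 - beta^d on given boundaries
beta_layers <- function(beta, bounds, total = 1) {
  top <- bounds[-length(bounds)]
  bottom <- bounds[-1]
  w <- beta^top - beta^bottom
  data.frame(top = top, bottom = bottom,
             frc = total * w / sum(w), soc = total * w / sum(w))
}

# cumulative profile straight from a layer table (frc column)
profile_from_layers <- function(layers, quantity = "FRC", site = "T1") {
  cumulative_profile(layers, quantity, site_id = site)
}

# a noisy profile on the fixed increment grid (multiplicative lognormal)
noisy_profile <- function(beta, cv, depth = 200, site = "T1") {
  g <- megapit_increment_grid(depth)
  w <- (beta^g$top - beta^g$bottom) *
    exp(stats::rnorm(nrow(g), 0, sqrt(log(1 + cv^2))))
  lay <- data.frame(top = g$top, bottom = g$bottom,
                    frc = w / sum(w), soc = w / sum(w))
  cumulative_profile(lay, "FRC", site_id = site)
}

# profile whose points follow Y = 1 - beta^d exactly (no truncation
# normalization), for clean round-trip checks of the fit itself
direct_profile <- function(beta, depths = seq(10, 200, by = 10),
                           site = "T1") {
  structure(list(site_id = site, quantity = "FRC",
                 points = data.frame(d = depths, Y = 1 - beta^depths),
                 excluded = FALSE, reason = NA_character_),
            class = "cumulative_profile")
}

# random contiguous layer boundaries from 0 to `depth`
random_bounds <- function(depth, n_cuts) {
  sort(unique(c(0, round(stats::runif(n_cuts, 1, depth - 1), 1), depth)))
}
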