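# Shared fixtures, built in code at test time.

# A small but complete synthetic world for one month.
tiny_config <- function(seed = 11, months = "2019-06", ...) {
  study_config(train_months = months, shape = c(24, 24), cell_size = 500,
               seed = seed, n_presences = 60, n_tours = 20,
               knots_per_covariate = 6, k = 5,
               mlp = mlp_config(seed = seed, max_iterations = 200), ...)
}

tiny_world <- function(seed = 11, month = "2019-06") {
  cfg <- tiny_config(seed, month)
  static <- gen_static_layers(cfg$shape, cfg$cell_size, cfg$seed)
  w <- simulate_month(static, month, cfg, 1)
  w$static <- static
  w$config <- cfg
  w
}

# Independent AUC oracle: enumerate every presence/absence pair.
auc_by_enumeration <- function(sp, sa) {
  wins <- 0
  for (p in sp) for (a in sa)
    wins <- wins + if (p > a) 1 else if (p == a) 0.5 else 0
  wins / (length(sp) * length(sa))
}

# A one-covariate training table with a controllable signal: presences drawn
# from the upper part of the sst range, absences from the lower.
toy_table <- function(m = 20, n = 30, shift = 2, seed = 1) {
  set.seed(seed)
  df <- data.frame(
    sst = c(stats::rnorm(m, mean = shift), stats::rnorm(n, mean = 0)),
    chlorophyll_a = stats::rnorm(m + n), salinity = stats::rnorm(m + n),
    depth = stats::rnorm(m + n), slope = stats::rnorm(m + n),
    dist_shore = stats::rnorm(m + n),
    label = c(rep(1L, m), rep(0L, n)), month_id = "2019-06")
  df
}

# Manual hinge basis with explicit knots, for hand-arithmetic oracles.
manual_basis <- function(features) {
  structure(list(features = features,
                 covariates = unique(vapply(features, `[[`, character(1),
                                            "covariate")),
                 dropped = character(0)),
            class = "hinge_basis")
}

# A constant six-layer stack on a small grid (values chosen per layer).
constant_stack <- function(vals = c(sst = 5, chlorophyll_a = 2,
                                    salinity = 34, depth = -40, slope = 3,
                                    dist_shore = 2000),
                           nr = 6, nc = 6, cell = 500) {
  layers <- lapply(vals, function(v)
    raster_grid(matrix(v, nr, nc), cell))
  env_stack("2019-06", layers)
}
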