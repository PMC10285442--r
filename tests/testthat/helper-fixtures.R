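# shared fixtures: everything is generated in code, sized for speed

# a small brain for unit tests: 6^3 voxels, central 3^3 planted region
small_spec <- function(...) {
  brain_spec(grid_dims = c(6L, 6L, 6L), ...)
}

# spec with no planted response at all (inside == outside, flat baselines)
null_spec <- function(dims = c(6L, 6L, 6L), ...) {
  brain_spec(grid_dims = dims,
             baseline_amplitudes = list(outside = 0.5, inside = NULL), ...)
}

# configuration with no group structure anywhere
null_config <- function(n_phobic = 4L, n_control = 4L, seed = 1L, ...) {
  effect_config(n_phobic = n_phobic, n_control = n_control,
                trait_means = c(phobic = 0, control = 0),
                activation_gain = 0,
                rating_weights = stats::setNames(rep(0, 6), fear_categories()),
                rating_snake_weights = stats::setNames(rep(0, 6), fear_categories()),
                seed = seed, ...)
}

# hand-built volume series on an arbitrary grid
make_series <- function(data, tr_s = 1.5, id = "T001") {
  structure(list(data = data, tr_s = tr_s, subject_id = id),
            class = "volume_series")
}

# hand-built stat map from a t-value array (effect defaults to t)
make_stat_map <- function(tvalues, df = 10L, effect = tvalues,
                          name = "toy", id = "T001") {
  structure(list(tvalues = tvalues, effect = effect, df = df,
                 contrast_name = name, subject_id = id),
            class = "stat_map")
}
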