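# Shared fixtures: all synthetic, built in code at test time.

# small, fast phantom spec used throughout the unit tests
small_phantom_spec <- function(fraction = 0.3, noise_sd = 30, seed = 1,
                               grid = c(64L, 64L, 8L), ...) {
  phantom_spec(grid_shape = grid, target_fibrotic_fraction = fraction,
               noise_sd = noise_sd, seed = seed, ...)
}

# a bare volume with every voxel at `hu`
uniform_volume <- function(hu, dims = c(8L, 8L, 3L)) {
  ct_volume(array(hu, dims))
}

# a volume + full mask carrying a prescribed multiset of HU values
volume_with_values <- function(values) {
  n <- length(values)
  dims <- c(n, 1L, 1L)
  list(volume = ct_volume(array(values, dims)),
       mask = lung_mask(array(TRUE, dims)))
}

# Mann-Whitney AUC oracle: exhaustive pair counting, ties counted one half
mw_auc_oracle <- function(scores, labels) {
  sp <- scores[labels]; sn <- scores[!labels]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# the default published cohort spec is expensive enough to build once
default_cohort_spec <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- cohort_spec(seed = 1)
    cache
  }
})
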