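# shared small-scale fixtures, built once per test run

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# desk-scale spec: small grid, shortened run; any field can be overridden
small_spec <- function(...) {
  args <- list(grid_shape = c(20L, 20L, 20L), n_timepoints = 120L, seed = 11L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(phantom_spec, args)
}

small_geometry <- function() cached("geo20", function() build_geometry(small_spec()))

# a clean phantom: intrinsic fluctuations only, no nuisance at all
clean_subject <- function() cached("clean_sub", function() {
  sp <- small_spec(drift_slope_frac_per_scan = 0,
                   physio_amp_frac = c(GM = 0, WM = 0, CSF = 0),
                   thermal_sd_frac = 0)
  synth_bold(sp, pve = small_geometry(), physio = synth_physio(sp))
})

# a fully loaded phantom: drift + physio + thermal noise
noisy_subject <- function() cached("noisy_sub", function() {
  sp <- small_spec(seed = 12L)
  synth_bold(sp, pve = small_geometry(), physio = synth_physio(sp))
})

# single-"voxel" bold series from a plain time course
voxel_series <- function(x, tr_s = 2) {
  bold_series(array(rep(x, each = 8), c(2, 2, 2, length(x))), tr_s = tr_s)
}

all_mask <- function(d = c(2, 2, 2)) tissue_mask(array(1, d), "threshold")

# independent brute-force rank-sum oracle: enumerate all label assignments
brute_force_ranksum_p <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  sums <- apply(utils::combn(length(r), n1), 2, function(i) sum(r[i]))
  eps <- 1e-9
  min(1, 2 * min(mean(sums <= w + eps), mean(sums >= w - eps)))
}
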