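# Shared fixtures, built in code.

# Small, fast cohort for module tests: 2 x 3 subjects, 250 Hz, 24 s
# (four 6 s segments after splitting).
tiny_spec <- function(seed = 42, n_per_group = 3, fs = 250, duration = 24,
                      ...) {
  cohort_spec(n_per_group = n_per_group, fs = fs, duration = duration,
              seed = seed, ...)
}

# Coupling structure with a single nonzero pair in one band, for targeted
# phase-coupling tests.
single_pair_coupling <- function(channels, band, i, j, weight) {
  zero <- matrix(0, length(channels), length(channels),
                 dimnames = list(channels, channels))
  cp <- lapply(eeg_bands()$name, function(b) zero)
  names(cp) <- eeg_bands()$name
  cp[[band]][i, j] <- cp[[band]][j, i] <- weight
  list(SCZ = cp, HC = cp)
}

# Band power putting all energy into one band.
single_band_power <- function(band, amp = 1) {
  bp <- c(delta = 0, theta = 0, alpha = 0, beta1 = 0, beta2 = 0)
  bp[band] <- amp
  list(SCZ = bp, HC = bp)
}

# Erdos-Renyi binary network on n nodes.
random_network <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  a <- a + t(a)
  binary_network(a)
}

# The study-scale synthetic cohort features, computed once per test run and
# memoized (several acceptance properties share them).
.plvnet_test_cache <- new.env(parent = emptyenv())

default_cohort_features <- function() {
  if (!is.null(.plvnet_test_cache$tabs)) return(.plvnet_test_cache)
  spec <- cohort_spec(seed = 1)          # 2 x 20 subjects, 1000 Hz, 80 s
  cohort <- generate_cohort(spec)
  cc <- cohort_connectivity(cohort)
  .plvnet_test_cache$cc_samples <- cc$samples
  .plvnet_test_cache$weights <- cc$weights
  .plvnet_test_cache$tabs <- feature_tables(cc, threshold = 0.71)
  .plvnet_test_cache
}
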