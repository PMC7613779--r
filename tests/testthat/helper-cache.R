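## Expensive shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

## the default confluent-tissue phantom shared by segmentation and spatial
## tests
default_phantom <- function() {
  cached("default_phantom", generate_phantom(phantom_spec(), seed = 7))
}

## its segmentation with the documented phantom configuration
default_segmentation <- function() {
  cached("default_segmentation", {
    ph <- default_phantom()
    segment_nuclei(ph$stack$data$Ir191,
                   preprocess_params(background_cutoff = 31500),
                   watershed_params())
  })
}

## a small blob image usable as a registration target
blob_image <- function(seed = 5, n = 45, d = 130, amp = 60) {
  set.seed(seed)
  img <- matrix(0, d, d)
  cx <- runif(n, 8, d - 8); cy <- runif(n, 8, d - 8)
  s <- runif(n, 1.8, 3.2); a <- runif(n, 0.4, 1) * amp
  xs <- seq_len(d)
  for (i in seq_len(n))
    img <- img + a[i] * outer(exp(-(xs - cy[i])^2 / (2 * s[i]^2)),
                              exp(-(xs - cx[i])^2 / (2 * s[i]^2)))
  img
}
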