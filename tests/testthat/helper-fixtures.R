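# Shared test fixtures: tiny scene sets and lazily trained test-scale models.
# Everything is seeded; expensive artefacts are computed once per test run.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

overfit_scenes <- function() memo("overfit_scenes", {
  lapply(1:4, function(i) generate_scene(scene_spec(
    seed = 100 + i, canvas = c(64L, 64L),
    nominal_browning_ratio = c(0.05, 0.4, 0.5, 0.8)[i],
    stage = c("pre", "mid", "mid", "post")[i])))
})

test_contour_config <- function(...) {
  contour_model_config(width_multiplier = 0.25, input_size = c(64L, 64L),
                       activation = "relu", ...)
}

test_rsunet_config <- function(...) {
  rsunet_config(width_multiplier = 0.125, ...)
}

# random boxes for detection-metric tests
random_box <- function(lim = 50) {
  x1 <- runif(1, 0, lim - 5); y1 <- runif(1, 0, lim - 5)
  c(x1, y1, x1 + runif(1, 2, 15), y1 + runif(1, 2, 15))
}

# independent brute-force even-odd point-in-polygon (scalar crossing count)
pip_oracle <- function(px, py, poly) {
  n <- nrow(poly)
  crossings <- 0L
  for (e in seq_len(n)) {
    a <- poly[e, ]
    b <- poly[if (e == n) 1L else e + 1L, ]
    if ((a[2] > py) != (b[2] > py)) {
      xint <- a[1] + (py - a[2]) * (b[1] - a[1]) / (b[2] - a[2])
      if (px < xint) crossings <- crossings + 1L
    }
  }
  crossings %% 2L == 1L
}
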