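# Shared fixtures, built lazily and cached for the test session.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

reduced_params <- function() default_params("reduced")

desk_grid <- function(kind = "compact") {
  fixture(paste0("grid_", kind), function() {
    p <- reduced_params()
    suppressWarnings(build_grid(desk_layout(kind), n = p$grid$n,
                                dx_nm = p$grid$dx_nm))
  })
}

toy_grid_11 <- function() {
  fixture("grid_toy11", function() {
    lay <- build_layout(positions = data.frame(x_nm = 36 * c(0, 1, 0, 1),
                                               y_nm = 36 * c(0, 0, 1, 1)))
    suppressWarnings(build_grid(lay, n = 11, dx_nm = 36))
  })
}

# deterministic gating block (channels frozen in their initial state)
frozen_gating <- function(params) {
  params$gating$k_plus_min <- 0
  params$gating$k_plus_max <- 0
  params$gating$k_minus_min <- 0
  params$gating$k_minus_max <- 0
  params
}

# brute-force 3D Gaussian convolution at a single voxel (zero padding),
# independent of the separable implementation
brute_blur_at <- function(field, n, sigma, radius, at) {
  w <- lapply(1:3, function(a) {
    k <- exp(-0.5 * ((-radius):radius)^2 / sigma[a]^2)
    k / sum(k)
  })
  acc <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    di <- at[1] - i; dj <- at[2] - j; dk <- at[3] - k
    if (abs(di) > radius || abs(dj) > radius || abs(dk) > radius) next
    acc <- acc + field[i + n * ((j - 1) + n * (k - 1))] *
      w[[1]][di + radius + 1] * w[[2]][dj + radius + 1] * w[[3]][dk + radius + 1]
  }
  acc
}

# minimal hand-built spark record for the metrics layer
toy_record <- function(times, dFF0, termination, intervals = list()) {
  structure(list(times = times, F = 1 + dFF0, dFF0 = dFF0,
                 open_intervals = intervals,
                 termination_time = termination, capped = FALSE,
                 initiating_channel = 1L, seed = NA_integer_),
            class = "spark_record")
}
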