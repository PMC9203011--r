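#' Calcium-dependent channel transition rates
#'
#' Two-state RyR gating: the opening rate rises with the local free
#' calcium concentration through a saturating power law
#' `k(x) = k_min + (k_max - k_min) x^eta / (1 + x^eta)` with `x = c / K`,
#' so it equals `k_min` at `c = 0` and approaches `k_max` as calcium
#' saturates the activation site.  The closing rate uses the same law with
#' its own bounds (constant when the bounds coincide, the default).
#' Lowering a channel's `K_plus` (phosphorylation) shifts the opening
#' curve to lower calcium and never decreases the rate.
#'
#' @param c local free calcium, uM (vectorized; must be nonnegative).
#' @param gating gating parameter block (see [default_params()]).
#' @param K_plus half-saturation of the opening rate for this channel, uM.
#' @return list with vectors `k_plus` and `k_minus` (1/ms).
#' @export
transition_rates <- function(c, gating, K_plus) {
  if (any(c < 0)) stop("negative calcium concentration")
  stopifnot(K_plus > 0, gating$K_minus > 0)
  list(
    k_plus = cpp_rate_law(c / K_plus, gating$k_plus_min, gating$k_plus_max,
                          gating$eta_plus),
    k_minus = cpp_rate_law(c / gating$K_minus, gating$k_minus_min,
                           gating$k_minus_max, gating$eta_minus)
  )
}

#' Create channel states
#'
#' @param n_ryr number of channels.
#' @param open optionally, indices of initially open channels.
#' @param t time of the initial openings (ms).
#' @return a `channel_states` object: `open` (logical), `open_intervals`
#'   (per-channel two-column matrices `t_open`, `t_close`; an open channel
#'   has `NA` in its last `t_close`).
#' @export
channel_states <- function(n_ryr, open = integer(0), t = 0) {
  iv <- replicate(n_ryr,
                  matrix(numeric(0), 0, 2,
                         dimnames = list(NULL, c("t_open", "t_close"))),
                  simplify = FALSE)
  st <- structure(list(open = rep(FALSE, n_ryr), open_intervals = iv, t = t),
                  class = "channel_states")
  for (k in open) st <- record_opening(st, k, t)
  st
}

record_opening <- function(states, k, t) {
  states$open[k] <- TRUE
  states$open_intervals[[k]] <- rbind(states$open_intervals[[k]],
                                      c(t_open = t, t_close = NA_real_))
  states
}

record_closing <- function(states, k, t) {
  states$open[k] <- FALSE
  iv <- states$open_intervals[[k]]
  iv[nrow(iv), 2] <- t
  states$open_intervals[[k]] <- iv
  states
}

#' Advance channel states by one gating step
#'
#' Each closed channel opens with probability `1 - exp(-k_plus dt)` and
#' each open channel closes with probability `1 - exp(-k_minus dt)`
#' (exact for rates held constant over the step).  One uniform draw is
#' consumed per channel, in fixed channel order, so seeded runs are
#' reproducible.
#'
#' @param states a [channel_states()] object.
#' @param local_c per-channel local calcium, uM.
#' @param dt_gate gating step, ms.
#' @param gating gating parameter block.
#' @param K_plus per-channel half-saturation values, uM.
#' @return updated `channel_states` (time advanced by `dt_gate`).
#' @export
step_channels <- function(states, local_c, dt_gate, gating, K_plus) {
  stopifnot(inherits(states, "channel_states"), dt_gate > 0,
            length(local_c) == length(states$open),
            length(K_plus) == length(states$open))
  t_new <- states$t + dt_gate
  u <- stats::runif(length(states$open))
  for (k in seq_along(states$open)) {
    r <- transition_rates(local_c[k], gating, K_plus[k])
    if (states$open[k]) {
      if (u[k] < 1 - exp(-r$k_minus * dt_gate))
        states <- record_closing(states, k, t_new)
    } else {
      if (u[k] < 1 - exp(-r$k_plus * dt_gate))
        states <- record_opening(states, k, t_new)
    }
  }
  states$t <- t_new
  states
}

#' Local calcium seen by a channel
#'
#' Mean free calcium over the cytosolic cleft voxels facing the channel's
#' membrane footprint.
#'
#' @param state a field state (see [init_state()]).
#' @param channel channel index.
#' @param grid the simulation grid.
#' @return concentration in uM.
#' @export
local_calcium <- function(state, channel, grid) {
  vox <- grid$ryr_cyt[[channel]]
  if (length(vox) == 0) stop("channel footprint has no cleft voxel")
  mean(state$c[vox])
}
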