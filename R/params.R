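#' Default model parameters
#'
#' Returns the full nested parameter list consumed by [run_spark()] and
#' the batch runner.  Units are uM for concentrations, ms for time, um for
#' length; diffusion constants in um^2/ms; on-rates in 1/(uM ms).
#'
#' Buffers (cytosol: ATP, calmodulin, troponin C, Fluo-4; SR:
#' calsequestrin) follow the common-coin values used across dyadic-cleft
#' models; the calcium-sensing gating law and the RyR permeability are
#' exposed as plain config entries whose defaults were calibrated with
#' [calibrate_ttp()] on the desk-scale reference setup so that compact
#' unphosphorylated clusters peak around 7 ms (see the methods vignette).
#'
#' @param preset `"reference"` for the 84^3, 12-nm production domain or
#'   `"reduced"` for the coarse desk-scale numerics block used by the test
#'   and verification batches.
#' @return nested list with blocks `buffers`, `transport` (incl. `serca`),
#'   `gating`, `numerics` and `grid`.
#' @export
default_params <- function(preset = c("reference", "reduced")) {
  preset <- match.arg(preset)
  p <- list(
    buffers = list(
      # ATP, calmodulin, troponin C, Fluo-4, calsequestrin
      name = c("ATP", "CaM", "TnC", "Fluo4", "CSQ"),
      kon  = c(0.225, 0.100, 0.039, 0.100, 0.100),   # 1/(uM ms)
      koff = c(45.0, 0.038, 0.020, 0.110, 63.0),     # 1/ms
      Btot = c(455, 24, 70, 25, 30000),              # uM
      D    = c(0.14, 0.025, 0.0, 0.042, 0.0)         # um^2/ms
    ),
    transport = list(
      D_c = 0.22,          # free cytosolic calcium, um^2/ms
      D_s = 0.073,         # free luminal calcium
      nu_ryr = 0.001,      # open-channel permeability, um^3/ms
      resting_c = 0.1,     # uM
      resting_s = 1300,    # uM
      serca = list(
        # three-state cycle; forward path binds 2 cytosolic Ca, backward
        # path 2 luminal Ca; rates in 1/ms (k1p in 1/(uM^2 ms), k2m in
        # 1/(uM^2 ms)); vmax scales the cycle to a flux density (uM um/ms)
        k1p = 0.026, k2p = 2.54, k3p = 20.0,
        k1m = 1e-3, k2m = 1e-9, k3m = 0.78,
        vmax = 2e-4
      )
    ),
    gating = list(
      k_plus_min = 0.0,    # 1/ms; no spontaneous opening at c = 0
      k_plus_max = 0.7,    # 1/ms, saturating bound of the opening rate
      eta_plus = 2.2,      # Hill-type steepness of the opening law
      K_minus = 1.0,       # uM; closing rate is constant by default
      k_minus_min = 0.5,   # 1/ms (mean open time 2 ms)
      k_minus_max = 0.5,
      eta_minus = 1.0
    ),
    numerics = list(
      dt = 0.001,            # operator-splitting step, ms
      dt_gate = 0.001,       # channel clock, ms
      record_dt = 0.1,       # fluorescence sampling, ms
      t_max = 500,           # hard cap, ms
      terminate_after = 1.0, # all-closed hold before termination, ms
      boundary = "clamped",  # "clamped" (open cytosol) or "sealed"
      diffusion = "explicit",# or "cn" (Crank-Nicolson, desk grids)
      psf = list(enabled = TRUE, fwhm_nm = c(410, 410, 800)),
      store_fields = FALSE   # keep raw per-frame c and bound-dye fields
    ),
    grid = list(n = 84L, dx_nm = 12)
  )
  if (preset == "reduced") {
    p$grid <- list(n = 17L, dx_nm = 36)
    p$numerics$t_max <- 50
  }
  p
}

# numeric boundary code for the C++ core
boundary_code <- function(numerics) {
  match(match.arg(numerics$boundary, c("sealed", "clamped")),
        c("sealed", "clamped")) - 1L
}

# PSF standard deviation/radius in voxels for a given grid
psf_voxels <- function(numerics, grid) {
  psf <- numerics$psf
  if (!isTRUE(psf$enabled))
    return(list(on = FALSE, sigma = c(0, 0, 0), radius = c(0L, 0L, 0L)))
  sigma <- psf$fwhm_nm / (2 * sqrt(2 * log(2))) / grid$dx_nm
  list(on = TRUE, sigma = sigma, radius = as.integer(ceiling(3 * sigma)))
}
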