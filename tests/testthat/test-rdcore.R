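test_that("the resting state is a fixed point of the reaction terms", {
  grid <- desk_grid("compact")
  p <- reduced_params()
  st <- init_state(grid, p)
  bf <- p$buffers
  cyt <- which(grid$labels == 0L)
  for (i in 1:4) {
    R <- bf$kon[i] * st$c[cyt] * (bf$Btot[i] - st$b[[i]][cyt]) -
      bf$koff[i] * st$b[[i]][cyt]
    expect_lt(max(abs(R)), 1e-12)
  }
  sr <- which(grid$labels == 1L | grid$labels == 2L)
  R5 <- bf$kon[5] * st$s[sr] * (bf$Btot[5] - st$b[[5]][sr]) -
    bf$koff[5] * st$b[[5]][sr]
  expect_lt(max(abs(R5)), 1e-9)  # calsequestrin carries ~2e4 uM bound

  # no ligand, no binding
  p0 <- p; p0$transport$resting_c <- 0
  st0 <- init_state(grid, p0)
  for (i in 1:4) expect_true(all(st0$b[[i]] == 0))

  # equilibrium bound concentration is linear in Btot
  p2 <- p; p2$buffers$Btot <- 2 * p$buffers$Btot
  st2 <- init_state(grid, p2)
  expect_equal(st2$b[[1]][cyt], 2 * st$b[[1]][cyt])
})

test_that("diffusion leaves uniform fields unchanged and conserves sealed mass", {
  grid <- desk_grid("compact")
  p <- reduced_params(); p$numerics$boundary <- "sealed"
  st <- init_state(grid, p)
  st2 <- diffusion_step(st, grid, p, dt = 0.01)
  expect_equal(st2$c, st$c, tolerance = 1e-13)
  expect_equal(st2$s, st$s, tolerance = 1e-13)

  # non-uniform field: per-species mass conserved by the conservative stencil
  set.seed(8)
  cyt <- which(grid$labels == 0L)
  st$c[cyt] <- st$c[cyt] + runif(length(cyt))
  m0 <- sum(st$c)
  st3 <- diffusion_step(st, grid, p, dt = 0.01)
  expect_lt(abs(sum(st3$c) - m0) / m0, 1e-10)
  expect_false(isTRUE(all.equal(st3$c, st$c)))
})

test_that("the Crank-Nicolson branch matches a matrix-exponential oracle on a sealed 5^3 box", {
  g <- box_grid(5, dx_nm = 100)
  D <- 0.22
  f <- numeric(125); f[63] <- 1          # delta at the centre
  tend <- 0.02; dt <- 1e-6
  for (i in seq_len(round(tend / dt)))
    f <- crusparks:::cn_diffuse(f, g, 0L, D, dt, 0L, 0)
  L <- crusparks:::domain_laplacian(g, 0L, 0L)
  r <- D / g$dx_um^2
  ref <- as.numeric(Matrix::expm(r * tend * L$L) %*%
                      replace(numeric(125), 63, 1))
  expect_lt(max(abs(f - ref)) / max(abs(ref)), 1e-8)
})

test_that("reaction step conserves per-voxel totals and matches an adaptive ODE oracle", {
  skip_if_not_installed("deSolve")
  p <- default_params()
  bf <- p$buffers
  g1 <- box_grid(1)
  st <- init_state(g1, p)
  st$c[1] <- st$c[1] + 0.5               # perturb free calcium

  tot0 <- st$c[1] + sum(vapply(st$b, `[`, numeric(1), 1))
  st_one <- reaction_step(st, g1, p, dt = 0.01)
  tot1 <- st_one$c[1] + sum(vapply(st_one$b, `[`, numeric(1), 1))
  expect_lt(abs(tot1 - tot0), 1e-12)

  # equilibrium is a fixed point
  steq <- init_state(g1, p)
  steq2 <- reaction_step(steq, g1, p, dt = 0.1)
  expect_equal(steq2$c, steq$c, tolerance = 1e-12)

  y0 <- c(c = st$c[1], b1 = st$b[[1]][1], b2 = st$b[[2]][1],
          b3 = st$b[[3]][1], b4 = st$b[[4]][1])
  rhs <- function(t, y, parms) {
    R <- bf$kon[1:4] * y[1] * (bf$Btot[1:4] - y[2:5]) - bf$koff[1:4] * y[2:5]
    list(c(-sum(R), R))
  }
  ref <- deSolve::lsoda(y0, c(0, 1), rhs, NULL, rtol = 1e-12, atol = 1e-12)[2, -1]
  st2 <- reaction_step(st, g1, p, dt = 1, n_sub = 1e4)
  got <- c(st2$c[1], st2$b[[1]][1], st2$b[[2]][1], st2$b[[3]][1], st2$b[[4]][1])
  expect_lt(max(abs(got - unname(ref))), 1e-6)
})

test_that("the SERCA cycle vanishes on its equilibrium locus, pumps uphill and is monotone in c", {
  serca <- default_params()$transport$serca
  s <- c(200, 700, 1300)
  ceq <- serca_equilibrium_c(s, serca)
  expect_lt(max(abs(serca_flux(ceq, s, serca))), 1e-12)
  expect_gt(serca_flux(0.1, 1000, serca), 0)     # uptake-positive at rest
  cs <- 10^seq(-2, 2, length.out = 80)
  J <- serca_flux(cs, 1000, serca)
  expect_true(all(diff(J) > 0))
})

test_that("membrane exchange is analytic, conservative and correctly signed", {
  grid <- desk_grid("compact")
  p <- reduced_params()
  st <- init_state(grid, p)

  # all channels closed, pump off: nothing moves
  st1 <- membrane_flux_step(st, grid, open = rep(FALSE, 16), p, dt = 0.01,
                            serca_on = FALSE)
  expect_identical(st1$c, st$c)
  expect_identical(st1$s, st$s)

  # one open channel: the pair difference decays at the analytic rate
  faces_c <- grid$ryr_cyt[[1]]; faces_s <- grid$ryr_sr[[1]]
  g <- p$transport$nu_ryr / (grid$dx_um^3 * length(faces_c))
  d0 <- st$s[faces_s[1]] - st$c[faces_c[1]]
  open1 <- replace(rep(FALSE, 16), 1, TRUE)
  nstep <- 5; dt <- 0.004
  st2 <- st
  for (i in seq_len(nstep))
    st2 <- membrane_flux_step(st2, grid, open1, p, dt, serca_on = FALSE)
  d_exp <- d0 * exp(-2 * g * nstep * dt)
  expect_equal(st2$s[faces_s[1]] - st2$c[faces_c[1]], d_exp,
               tolerance = 1e-10)
  # SR loses what the cytosol gains, channel open with s > c
  expect_gt(st2$c[faces_c[1]], st$c[faces_c[1]])
  expect_lt(st2$s[faces_s[1]], st$s[faces_s[1]])
  expect_lt(abs((sum(st2$c) + sum(st2$s)) - (sum(st$c) + sum(st$s))) /
              (sum(st$c) + sum(st$s)), 1e-10)

  # with the pump on, total calcium is still conserved across the membrane
  st3 <- membrane_flux_step(st, grid, open1, p, dt = 0.01, serca_on = TRUE)
  expect_lt(abs((sum(st3$c) + sum(st3$s)) - (sum(st$c) + sum(st$s))) /
              (sum(st$c) + sum(st$s)), 1e-10)
})

test_that("a spark starts with exactly one forced opening and failure gives a short record", {
  grid <- toy_grid_11()
  p <- reduced_params(); p$numerics$t_max <- 30
  set.seed(21)
  rec <- run_spark(grid, NULL, p)
  starts0 <- vapply(rec$open_intervals,
                    function(iv) nrow(iv) > 0 && iv[1, 1] == 0, logical(1))
  expect_equal(sum(starts0), 1L)
  expect_equal(which(starts0), rec$initiating_channel)
  expect_equal(rec$dFF0[1], 0)

  # no reopening, fast closing: duration is first closure + 1 ms
  p2 <- p
  p2$gating$k_plus_max <- 0; p2$gating$k_plus_min <- 0
  p2$gating$k_minus_min <- 5; p2$gating$k_minus_max <- 5
  set.seed(1)
  rec2 <- run_spark(grid, NULL, p2)
  iv <- rec2$open_intervals[[rec2$initiating_channel]]
  expect_equal(nrow(iv), 1L)
  expect_equal(rec2$termination_time, unname(iv[1, 2]) + 1)
  expect_false(evaluate_spark(rec2)$success)

  # duration always exceeds the last closure by the hold time
  last_close <- max(unlist(lapply(rec$open_intervals, function(m) m[, 2])),
                    na.rm = TRUE)
  expect_gte(rec$termination_time, last_close + 1 - 1e-9)
})

test_that("without release flux no spark ever passes threshold", {
  grid <- toy_grid_11()
  p <- reduced_params(); p$transport$nu_ryr <- 0; p$numerics$t_max <- 20
  for (seed in 1:3) {
    set.seed(seed)
    m <- evaluate_spark(run_spark(grid, NULL, p))
    expect_false(m$success)
    expect_lt(m$amplitude, 1e-9)
  }
})

test_that("sealed full-spark simulations conserve total calcium", {
  grid <- toy_grid_11()
  p <- reduced_params(); p$numerics$boundary <- "sealed"; p$numerics$t_max <- 30
  tot0 <- total_calcium(init_state(grid, p), grid)
  set.seed(7)
  rec <- run_spark(grid, NULL, p)
  tot1 <- total_calcium(rec$final_state, grid)
  expect_lt(abs(tot1 - tot0) / tot0, 1e-8)
})

test_that("stored per-frame fields align with the trace and its read-out", {
  grid <- toy_grid_11()
  p <- reduced_params(); p$numerics$t_max <- 5
  p$numerics$store_fields <- TRUE
  set.seed(13)
  rec <- run_spark(grid, NULL, p)
  expect_length(rec$fields$c, length(rec$times))
  expect_length(rec$fields$b4, length(rec$times))
  # the recorded F is exactly the fluorescence of the stored dye frame
  i <- which.max(rec$dFF0)
  F_re <- fluorescence_trace(rec$fields$b4[i], grid, psf = p$numerics$psf)
  expect_equal(F_re, rec$F[i], tolerance = 1e-12)
  # frames are full-grid concentration vectors
  expect_length(rec$fields$c[[1]], grid$n^3)
  expect_equal(max(abs(rec$fields$c[[1]][grid$labels == 0L] -
                         p$transport$resting_c)), 0)
})

test_that("halving the splitting step barely changes a deterministic trace", {
  grid <- toy_grid_11()
  p <- frozen_gating(reduced_params())
  p$numerics$t_max <- 3
  set.seed(1)
  a <- run_spark(grid, NULL, p, init_channel = 1)
  p2 <- p; p2$numerics$dt <- 5e-4; p2$numerics$dt_gate <- 5e-4
  set.seed(1)
  b <- run_spark(grid, NULL, p2, init_channel = 1)
  expect_equal(length(a$dFF0), length(b$dFF0))
  expect_lt(max(abs(a$dFF0 - b$dFF0)), 0.02 * max(a$dFF0))
  expect_true(a$capped)    # held-open channel: the cap is flagged, not fatal
})
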