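test_that("seeded batches are deterministic and runs re-creatable from their seed", {
  p <- reduced_params()
  cfg <- spark_config(geometry = desk_layout("compact"), pattern = "none",
                      n_runs = 4, base_seed = 100, params = p,
                      grid_n = p$grid$n, grid_dx_nm = p$grid$dx_nm)
  grid <- desk_grid("compact")
  b1 <- run_batch(cfg, grid = grid)
  b2 <- run_batch(cfg, grid = grid, keep_records = FALSE)
  expect_identical(b1$summary, b2$summary)
  expect_equal(b1$metrics$seed, 100 + 1:4)
  # any single run is re-creatable from (config, seed)
  set.seed(103)
  r3 <- run_spark(grid, NULL, p)
  expect_identical(r3$dFF0, b1$records[[3]]$dFF0)
  expect_identical(r3$open_intervals, b1$records[[3]]$open_intervals)
})

test_that("summaries average amplitude/TTP/duration over successful sparks only", {
  ok <- toy_record(0:6, c(0, .2, .45, .3, .2, .1, 0), 6,
                   list(cbind(t_open = 0, t_close = 2)))
  bad <- toy_record(0:3, c(0, .1, .05, 0), 3,
                    list(cbind(t_open = 0, t_close = 1)))
  sm <- summarize_batch(list(ok, bad, ok))
  expect_equal(sm$n_success, 2)
  expect_equal(sm$amplitude_mean, 0.45)
  expect_equal(sm$ttp_mean_ms, 2)
  ci <- agresti_coull(2, 3)
  expect_equal(sm$fidelity_pct, 100 * ci$p_tilde)

  # all-failure batch: fidelity CI still reported, metrics unavailable
  sm0 <- summarize_batch(list(bad, bad))
  expect_false(sm0$metrics_available)
  expect_true(is.na(sm0$amplitude_mean))
  expect_equal(sm0$fidelity_pct, 100 * agresti_coull(0, 2)$p_tilde)
})

test_that("a single forced-failure run yields the (0, 1) fidelity interval", {
  p <- reduced_params()
  p$gating$k_plus_max <- 0; p$gating$k_plus_min <- 0
  p$gating$k_minus_min <- 5; p$gating$k_minus_max <- 5
  cfg <- spark_config(geometry = desk_layout("compact"), pattern = "none",
                      n_runs = 1, base_seed = 7, params = p,
                      grid_n = p$grid$n, grid_dx_nm = p$grid$dx_nm)
  b <- run_batch(cfg, grid = desk_grid("compact"))
  expect_equal(b$summary$n_success, 0)
  expect_equal(b$summary$fidelity_pct, 100 * agresti_coull(0, 1)$p_tilde)
})

test_that("the standard matrix enumerates 8 setups per geometry (40 configurations)", {
  su <- standard_setups()
  expect_equal(nrow(su), 8)
  expect_setequal(unique(as.character(su$pattern)),
                  c("none", "inner", "outer", "uniform", "blanket"))
  expect_equal(nrow(su) * 5, 40)
  # the uniform-versus-blanket comparison expands blanket into both levels
  su2 <- standard_setups(blanket_levels = c(0.2, 0.5))
  expect_equal(nrow(su2), 9)
})

test_that("run_matrix produces one labelled row per configuration and isolates failures", {
  p <- reduced_params()
  su <- rbind(data.frame(pattern = "none", fraction = 0, blanket_vs = NA),
              data.frame(pattern = "blanket", fraction = 1, blanket_vs = 0.5))
  out <- suppressWarnings(
    run_matrix(geometries = list(desk_layout("compact")), setups = su,
               n_runs = 2, base_seed = 3, params = p,
               grid_n = p$grid$n, grid_dx_nm = p$grid$dx_nm))
  expect_equal(nrow(out), 2)
  expect_true(all(c("fidelity_pct", "configuration") %in% names(out)))
  expect_true(all(is.na(out$error)))

  # empty geometry list: empty result, no error
  out0 <- run_matrix(geometries = list(), setups = su, n_runs = 1, params = p)
  expect_null(out0)
})

test_that("TTP calibration reports the nearest scale and a usable config", {
  p <- reduced_params()
  cfg <- spark_config(geometry = desk_layout("compact"), pattern = "none",
                      n_runs = 6, base_seed = 50, params = p,
                      grid_n = p$grid$n, grid_dx_nm = p$grid$dx_nm)
  cal <- suppressWarnings(calibrate_ttp(cfg, target_ttp = 5,
                                        scales = c(0.8, 1.2)))
  expect_true(cal$scale %in% c(0.8, 1.2))
  expect_true(is.finite(cal$achieved_ttp))
  expect_equal(nrow(cal$scan), 2)
  expect_equal(cal$config$params$gating$k_plus_max,
               p$gating$k_plus_max * cal$scale)
  expect_error(calibrate_ttp(cfg, scales = 1), "bracketing")
})

test_that("batch outputs are written as CSV and JSON", {
  p <- reduced_params()
  cfg <- spark_config(geometry = desk_layout("compact"), pattern = "none",
                      n_runs = 2, base_seed = 100, params = p,
                      grid_n = p$grid$n, grid_dx_nm = p$grid$dx_nm)
  b <- run_batch(cfg, grid = desk_grid("compact"), keep_records = FALSE)
  d <- withr::local_tempdir()
  write_batch(b, d, prefix = "t")
  expect_true(file.exists(file.path(d, "t_summary.csv")))
  expect_true(file.exists(file.path(d, "t_metrics.csv")))
  js <- jsonlite::read_json(file.path(d, "t_summary.json"))
  expect_equal(js$n_runs, 2)
})
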