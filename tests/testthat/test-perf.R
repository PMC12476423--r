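test_that("the packaged fixture derives the remaining times by subtraction", {
  d <- timing_samples()
  expect_equal(nrow(d), 7L)
  expect_equal(d$t4c_ms[d$label == "Mesh 1"], 5.1, tolerance = 1e-12)
  expect_equal(d$t4g_ms[d$label == "Case 1"], 5.3, tolerance = 1e-12)
  expect_true(all(abs(d$t4c_ms - (d$Tc_ms - d$t2_ms - d$t3c_ms)) < 1e-12))
  expect_true(all(abs(d$t4g_ms - (d$Tg_ms - d$t2_ms)) < 1e-12))
  # without deduplication the shared sample appears twice
  path <- system.file("extdata", "timing_samples.csv", package = "octodeform")
  expect_equal(nrow(load_timing_samples(path, dedup = FALSE)), 8L)
  # the alternative vertex count for the second mesh barely moves the fit
  a_table <- fit_cost_plane(timing_samples("table"), "cpu_map")
  a_text <- fit_cost_plane(timing_samples("text"), "cpu_map")
  expect_lt(abs(a_table$a - a_text$a) / a_table$a, 0.01)
  expect_lt(abs(a_table$c - a_text$c), 0.02)
})

test_that("all-zero and malformed timing tables are handled", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(n_v = c(10, 20, 30, 40), n_c = c(1, 5, 2, 8),
                       t2_ms = 0, t3c_ms = 0, Tc_ms = 0, Tg_ms = 0),
            f, row.names = FALSE)
  d <- load_timing_samples(f, dedup = FALSE)
  expect_true(all(d$t4c_ms == 0) && all(d$t4g_ms == 0))
  write.csv(data.frame(n_v = 1:4, n_c = 1, t2_ms = -1, t3c_ms = 0,
                       Tc_ms = 0, Tg_ms = 0), f, row.names = FALSE)
  expect_error(load_timing_samples(f, dedup = FALSE), "negative")
  write.csv(data.frame(n_v = 1:4, n_c = 1, t3c_ms = 0, Tc_ms = 0, Tg_ms = 0),
            f, row.names = FALSE)
  expect_error(load_timing_samples(f, dedup = FALSE), "t2_ms")
  unlink(f)
})

test_that("noiseless planar data is recovered exactly with R^2 = 1", {
  set.seed(31)
  a0 <- 4e-5; b0 <- 3e-3; c0 <- 2.5
  d <- data.frame(n_v = round(runif(8, 1e4, 3e5)),
                  n_c = round(runif(8, 100, 5000)))
  t <- a0 * d$n_v + b0 * d$n_c + c0
  d$t2_ms <- 1; d$t3c_ms <- t / 2
  d$Tc_ms <- d$t2_ms + d$t3c_ms + t / 2   # so t3c + t4c = t
  d$Tg_ms <- d$t2_ms + t                  # so t4g = t
  d <- load_timing_samples({f <- tempfile(fileext = ".csv")
                            write.csv(d, f, row.names = FALSE); f},
                           dedup = FALSE)
  for (resp in c("cpu_map", "gpu_remaining")) {
    fit <- fit_cost_plane(d, resp)
    expect_lt(abs(fit$a - a0), 1e-9)
    expect_lt(abs(fit$b - b0), 1e-9)
    expect_lt(abs(fit$c - c0), 1e-9)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  }
})

test_that("collinear designs are rejected", {
  d <- data.frame(n_v = c(1e4, 2e4, 3e4, 4e4), n_c = c(100, 200, 300, 400),
                  t2_ms = 1, t3c_ms = 2, Tc_ms = 5, Tg_ms = 4)
  class(d) <- c("timing_samples", "data.frame")
  d$t4c_ms <- d$Tc_ms - d$t2_ms - d$t3c_ms
  d$t4g_ms <- d$Tg_ms - d$t2_ms
  expect_error(fit_cost_plane(d, "cpu_map"), "collinear")
  expect_error(fit_cost_plane(d[1:3, ], "cpu_map"), "at least 4")
})

test_that("the crossover condition subtracts planes and is antisymmetric", {
  mk <- function(a, b, c) structure(list(a = a, b = b, c = c), class = "cost_plane")
  x <- crossover_condition(mk(2, 0, 5), mk(1, 3, 4))
  expect_equal(c(x$beta_c, x$beta_v, x$beta_0), c(3, 1, 1))
  same <- crossover_condition(mk(1, 2, 3), mk(1, 2, 3))
  expect_equal(c(same$beta_c, same$beta_v, same$beta_0), c(0, 0, 0))
  fwd <- crossover_condition(mk(2, 0.1, 5), mk(1, 3, 4))
  bwd <- crossover_condition(mk(1, 3, 4), mk(2, 0.1, 5))
  expect_equal(c(fwd$beta_c, fwd$beta_v, fwd$beta_0),
               -c(bwd$beta_c, bwd$beta_v, bwd$beta_0))
})

test_that("the maximum batched-favourable cube count uses the strict inequality", {
  x <- structure(list(beta_c = 1, beta_v = 0, beta_0 = 10),
                 class = "crossover_condition")
  expect_equal(max_cubes_for_gpu(x, n_v = 12345), 9)  # strictly below 10
  x2 <- structure(list(beta_c = 1, beta_v = 0, beta_0 = 10.7),
                  class = "crossover_condition")
  expect_equal(max_cubes_for_gpu(x2, n_v = 0), 10)
  xneg <- structure(list(beta_c = -1, beta_v = 0, beta_0 = 1),
                    class = "crossover_condition")
  expect_message(res <- max_cubes_for_gpu(xneg, 10), "always faster")
  expect_identical(res, Inf)
  model <- fit_cost_planes()
  expect_equal(max_cubes_for_gpu(model, 0),
               floor(model$crossover$beta_0 / model$crossover$beta_c))
})

test_that("the fitted model predicts which path wins", {
  model <- fit_cost_planes()
  pr <- predict(model, data.frame(n_v = c(256904, 256904),
                                  n_c = c(500, 10000)))
  expect_true(pr$batched_faster[1])
  expect_false(pr$batched_faster[2])
  expect_equal(pr$cpu_ms[1],
               model$cpu$a * 256904 + model$cpu$b * 500 + model$cpu$c)
  cm <- coef(model)
  expect_equal(dim(cm), c(2L, 3L))
})

test_that("the local benchmark emits the timing schema the loader reads", {
  m <- make_synthetic_organ("blob", 400, seed = 13)
  lat <- build_octree(m, 1)
  pieces <- split_mesh(m, lat)
  row <- benchmark_mapping(m, lat, pieces, repeats = 3)
  expect_identical(names(row), c("n_v", "n_c", "t2_ms", "t3c_ms", "Tc_ms", "Tg_ms"))
  expect_true(all(is.finite(as.numeric(row))))
  expect_true(all(as.numeric(row) >= 0))
  expect_equal(row$n_v, nrow(m$vertices))
  expect_equal(row$n_c, lat$n_c)
  f <- tempfile(fileext = ".csv")
  write.csv(rbind(row, row, row, row), f, row.names = FALSE)
  expect_equal(nrow(load_timing_samples(f, dedup = FALSE)), 4L)
  unlink(f)
})
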