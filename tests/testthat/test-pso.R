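domain_box <- function(lower, upper) {
  ref <- (lower + upper) / 2
  d <- parameter_domain(ref, 0)
  d$lower <- lower
  d$upper <- upper
  d
}

test_that("the swarm finds the minimum of a smooth 1-D objective", {
  d <- domain_box(c(x = 0), c(x = 1))
  r <- pso_minimize(function(p) (p[["x"]] - 0.3)^2, d,
                    swarm_settings(10, 19, seed = 3))
  expect_equal(r$status, "ok")
  expect_equal(r$evaluations, 200L)
  expect_lt(r$value, 1e-4) # brute-force grid at step 1e-3 gives <= 2.5e-7
  expect_lt(abs(r$par[["x"]] - 0.3), 0.02)
})

test_that("a degenerate domain returns the reference in one evaluation", {
  toy <- make_bimodal_control_toy()
  d <- parameter_domain(toy$model, 0)
  r <- pso_minimize(function(p) sum(p), d, swarm_settings(20, 100, seed = 1))
  expect_equal(r$evaluations, 1L)
  expect_equal(r$value, sum(reference_params(toy$model)))
})

test_that("the swarm solves Rastrigin in 2-D for most seeds", {
  rast <- function(p) {
    20 + p[["a"]]^2 + p[["b"]]^2 -
      10 * cos(2 * pi * p[["a"]]) - 10 * cos(2 * pi * p[["b"]])
  }
  d <- domain_box(c(a = -5.12, b = -5.12), c(a = 5.12, b = 5.12))
  hits <- 0
  for (s in 1:10) {
    r <- pso_minimize(rast, d, swarm_settings(20, 500, seed = s))
    if (r$value < 1) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("undefined objectives are worst-fitness, and counted", {
  d <- domain_box(c(x = -1), c(x = 1))
  # objective undefined on the left half-line
  r <- pso_minimize(function(p) if (p[["x"]] < 0) NA_real_
                                else (p[["x"]] - 0.5)^2,
                    d, swarm_settings(10, 50, seed = 2))
  expect_equal(r$status, "ok")
  expect_gt(r$n_undefined, 0)
  expect_lt(r$value, 1e-3)
  # everywhere-undefined objective fails cleanly
  r2 <- pso_minimize(function(p) NA_real_, d, swarm_settings(5, 5, seed = 1))
  expect_equal(r2$status, "failed")
})

test_that("structurally constant coefficients give tight bounds", {
  m <- two_step()$model
  d <- parameter_domain(m, 0.5)
  b <- sensitivity_bounds(m, d, output_spec("flux", "step2"), "k1",
                          swarm_settings(8, 10, seed = 4))
  expect_equal(b$lower, 1, tolerance = 1e-6)
  expect_equal(b$upper, 1, tolerance = 1e-6)
  # S* spec, k2: scaled coefficient is constant at -1 (up to the forward
  # finite-difference bias of the 0.1% objective step)
  b2 <- sensitivity_bounds(m, d, output_spec("concentration", "S1"), "k2",
                           swarm_settings(8, 10, seed = 4))
  expect_equal(b2$lower, -1, tolerance = 2e-3)
  expect_equal(b2$upper, -1, tolerance = 2e-3)
  expect_lt(abs(b2$upper - b2$lower), 1e-6)
})

test_that("swarm bounds match a grid oracle on the 2-parameter chain", {
  rv <- make_reversible_chain(2, kf = c(2, 3), kr = c(1, 1), x0 = 1,
                              x1 = 0.5)
  m <- rv$model
  ref <- reference_params(m)
  pin <- list(kr1 = c(1, 1), kr2 = c(1, 1))
  d <- parameter_domain(m, 0.5, overrides = pin)
  b <- sensitivity_bounds(m, d, output_spec("flux", "step2"), "kf1",
                          swarm_settings(15, 40, seed = 11))
  # independent exhaustive grid through the linear-algebra oracle
  kf1 <- seq(1, 3, length.out = 60)
  kf2 <- seq(1.5, 4.5, length.out = 60)
  vals <- outer(kf1, kf2, Vectorize(function(a, b2) {
    p <- ref
    p["kf1"] <- a
    p["kf2"] <- b2
    rv$oracle$response(p, "flux", "kf1")
  }))
  expect_equal(b$lower, min(vals), tolerance = 0.01)
  expect_equal(b$upper, max(vals), tolerance = 0.01)
})

test_that("reported bounds replay exactly from their argument points", {
  rv <- make_reversible_chain(2, kf = c(2, 3), kr = c(1, 1), x0 = 1,
                              x1 = 0.5)
  d <- parameter_domain(rv$model, 0.3)
  b <- sensitivity_bounds(rv$model, d, output_spec("flux", "step2"), "kf1",
                          swarm_settings(10, 15, seed = 21))
  expect_true(all(b$argmin >= d$lower - 1e-12 & b$argmin <= d$upper + 1e-12))
  expect_true(all(b$argmax >= d$lower - 1e-12 & b$argmax <= d$upper + 1e-12))
  expect_equal(b$objective(b$argmin), b$lower, tolerance = 1e-9)
  expect_equal(b$objective(b$argmax), b$upper, tolerance = 1e-9)
  expect_lte(b$lower, b$upper)
})

test_that("bounds widen weakly with the band at fixed settings", {
  rv <- make_reversible_chain(2, kf = c(2, 3), kr = c(1, 1), x0 = 1,
                              x1 = 0.5)
  m <- rv$model
  sp <- output_spec("flux", "step2")
  widths <- vapply(c(0.1, 0.3, 0.5), function(band) {
    b <- sensitivity_bounds(m, parameter_domain(m, band), sp, "kf1",
                            swarm_settings(10, 25, seed = 8))
    c(b$lower, b$upper)
  }, numeric(2))
  expect_true(all(diff(widths[1, ]) <= 1e-9)) # lower bound non-increasing
  expect_true(all(diff(widths[2, ]) >= -1e-9)) # upper bound non-decreasing
})

test_that("the bounds-versus-sampling comparison is reported both ways", {
  toy <- make_bimodal_control_toy()
  m <- toy$model
  sp <- output_spec("flux", "branch1")
  d <- parameter_domain(m, 0.5)
  b <- sensitivity_bounds(m, d, sp, "V1", swarm_settings(12, 30, seed = 6))
  g <- run_sampling_gsa(m, d, sp, n = 150, seed = 6, parameters = "V1")
  dist <- summarize_distribution(g, "V1")
  cmp <- compare_bounds_sampling(b, dist)
  expect_true(is.finite(cmp$lower_shortfall))
  expect_true(is.finite(cmp$upper_shortfall))
  expect_true(is.logical(cmp$dominated))
  # whichever direction holds, the comparison must be self-consistent
  expect_equal(cmp$dominated,
               cmp$lower_shortfall <= 0 && cmp$upper_shortfall <= 0)
})
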