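test_that("domain sampling is uniform, deterministic and resumable", {
  d <- parameter_domain(c(a = 2), band = 0.5)
  x <- sample_domain(d, 1e5, seed = 7)
  expect_true(all(x >= 1 & x <= 3))
  expect_equal(mean(x), 2, tolerance = 0.01)
  # same seed -> identical stream
  expect_identical(sample_domain(d, 100, seed = 7),
                   sample_domain(d, 100, seed = 7))
  # resuming mid-stream reproduces the same rows
  full <- sample_domain(d, 100, seed = 7)
  tail50 <- sample_domain(d, 50, seed = 7, start = 51)
  expect_identical(full[51:100, , drop = FALSE], tail50)
  # degenerate band: every draw is the reference
  d0 <- parameter_domain(c(a = 2, b = -1), band = 0)
  x0 <- sample_domain(d0, 10, seed = 1)
  expect_true(all(x0[, "a"] == 2 & x0[, "b"] == -1))
})

test_that("structural control is recovered at every sampled point", {
  m <- two_step()$model
  d <- parameter_domain(m, 0.5)
  g <- run_sampling_gsa(m, d, output_spec("flux", "step2"), n = 50,
                        seed = 3)
  k1 <- g$records[g$records$parameter == "k1", ]
  k2 <- g$records[g$records$parameter == "k2", ]
  expect_true(all(k1$status == "ok"))
  # tolerance: the 0.1% finite difference amplifies the steady-state
  # residual tolerance by 1/rel_step
  expect_equal(k1$value, rep(1, 50), tolerance = 1e-6)
  expect_equal(k2$value, rep(0, 50), tolerance = 1e-6)
})

test_that("a zero band collapses sampling onto the local spectrum", {
  rv <- make_reversible_chain(2, kf = c(2, 3), kr = c(1, 1), x0 = 1,
                              x1 = 0.5)
  m <- rv$model
  sp <- output_spec("flux", "step2")
  local <- sensitivity_spectrum(m, spec = sp)
  g <- run_sampling_gsa(m, parameter_domain(m, 0), sp, n = 5, seed = 1)
  for (pid in m$parameters$id) {
    vals <- g$records$value[g$records$parameter == pid]
    expect_equal(vals, rep(local$value[local$parameter == pid], 5),
                 tolerance = 1e-9)
  }
})

test_that("results are invariant to the chunk partitioning", {
  toy <- make_bimodal_control_toy()
  d <- parameter_domain(toy$model, 0.5)
  sp <- output_spec("flux", "branch1")
  g1 <- run_sampling_gsa(toy$model, d, sp, n = 60, seed = 11,
                         chunk_size = 7, parameters = "V1")
  g2 <- run_sampling_gsa(toy$model, d, sp, n = 60, seed = 11,
                         chunk_size = 60, parameters = "V1")
  expect_identical(g1$records, g2$records)
  expect_identical(g1$samples, g2$samples)
})

test_that("sampled ranges nest as the band grows, at matched seeds", {
  toy <- make_bimodal_control_toy()
  sp <- output_spec("flux", "branch1")
  vals <- function(band, n = 200) {
    g <- run_sampling_gsa(toy$model, parameter_domain(toy$model, band),
                          sp, n = n, seed = 5, parameters = "V1")
    r <- g$records
    r$value[r$status == "ok"]
  }
  v1 <- vals(0.1)
  v2 <- vals(0.5)
  expect_gte(min(v1), min(v2))
  expect_lte(max(v1), max(v2))
})

test_that("shrinking bands converge on the local coefficient", {
  toy <- make_bimodal_control_toy()
  sp <- output_spec("flux", "branch1")
  local <- scaled_sensitivity(toy$model, reference_params(toy$model), sp,
                              "V1")$value
  g <- run_sampling_gsa(toy$model, parameter_domain(toy$model, 1e-4), sp,
                        n = 200, seed = 9, parameters = "V1")
  d <- summarize_distribution(g, "V1")
  expect_equal(d$peak, local, tolerance = 0.01)
  expect_lt(d$max - d$min, 0.01 * abs(local))
})

test_that("undefined samples are counted, never silently dropped", {
  toy <- make_bimodal_control_toy()
  sp <- output_spec("flux", "branch1")
  g <- run_sampling_gsa(toy$model, parameter_domain(toy$model, 0.9), sp,
                        n = 400, seed = 13, parameters = "V1")
  rec <- g$records[g$records$parameter == "V1", ]
  n_undef <- sum(rec$status == "undefined")
  expect_gt(n_undef, 0) # wide band loses the steady state sometimes
  expect_equal(nrow(rec), 400)
  d <- summarize_distribution(g, "V1")
  expect_equal(d$n_ok + d$n_undefined, 400)
  expect_true(all(rec$reason[rec$status == "undefined"] ==
                    "no-steady-state"))
})

test_that("distribution summaries are unit-area with correct peaks", {
  set.seed(42)
  x <- stats::rnorm(1e5)
  d <- summarize_distribution(x, n_bins = 50)
  widths <- diff(d$breaks)
  expect_equal(sum(widths * d$density), 1, tolerance = 1e-9)
  expect_equal(d$peak, 0, tolerance = 0.1)
  expect_gt(d$shapiro_W, 0.99)
  # bimodal mixture: unit area still, and both modes recovered downstream
  xb <- c(stats::rnorm(5e3, 0, 0.1), stats::rnorm(5e3, 5, 0.1))
  db <- summarize_distribution(xb)
  expect_equal(sum(diff(db$breaks) * db$density), 1, tolerance = 1e-9)
  expect_lt(db$shapiro_W, 0.9)
})

test_that("degenerate distributions collapse onto the local value", {
  m <- two_step()$model
  g <- run_sampling_gsa(m, parameter_domain(m, 0),
                        output_spec("flux", "step2"), n = 20, seed = 2)
  d <- summarize_distribution(g, "k1", local_value = 1)
  expect_equal(d$peak, 1, tolerance = 1e-9)
  expect_equal(d$peak_height, 1)
  expect_equal(sum(diff(d$breaks) * d$density), 1, tolerance = 1e-9)
})

test_that("the normality test behaves across distribution shapes", {
  set.seed(8)
  norm <- shapiro_wilk(stats::rnorm(500))
  expect_gt(norm$W, 0.99)
  expo <- shapiro_wilk(stats::rexp(500))
  expect_lt(expo$W, 0.95)
  expect_error(shapiro_wilk(c(1, 2)), "at least 3")
  const <- shapiro_wilk(rep(1, 100))
  expect_true(const$constant)
  expect_true(is.na(const$W))
  # subsampling cap keeps the test within its validity range
  big <- shapiro_wilk(stats::rnorm(2e4), cap = 5000)
  expect_lte(big$n_used, 5000)
  expect_gt(big$W, 0.99)
})
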