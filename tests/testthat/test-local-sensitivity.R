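test_that("chain response coefficients match the closed forms", {
  m <- two_step()$model
  p <- reference_params(m)
  fl <- output_spec("flux", "step2")
  cc <- output_spec("concentration", "S1")
  # J = k1*X0 is exactly linear in k1: even a forward difference is exact
  expect_equal(scaled_sensitivity(m, p, fl, "k1")$value, 1,
               tolerance = 1e-6)
  expect_equal(scaled_sensitivity(m, p, fl, "k2")$value, 0,
               tolerance = 1e-6)
  # S* = k1*X0/k2: the forward difference of 1/k2 carries its O(h) bias
  fwd <- scaled_sensitivity(m, p, cc, "k2", rel_step = 0.001)
  expect_equal(fwd$value, -1, tolerance = 2e-3)
  ctr <- scaled_sensitivity(m, p, cc, "k2", rel_step = 5e-4,
                            method = "central")
  expect_equal(ctr$value, -1, tolerance = 1e-6)
  expect_equal(scaled_sensitivity(m, p, cc, "k1")$value, 1,
               tolerance = 1e-6)
})

test_that("zero parameters and zero outputs are handled as unscalable", {
  m <- two_step()$model
  p <- reference_params(m)
  expect_error(scaled_sensitivity(m, c(k1 = 0, k2 = 4),
                                  output_spec("flux", "step2"), "k1"),
               "cannot be relatively perturbed")
  # a parameter whose reference value is 0 appears in the spectrum as
  # undefined/unscalable instead of being dropped or crashing the run
  mz <- kinetic_model(
    species = data.frame(id = c("X0", "S"), initial = c(1, 0),
                         boundary = c(TRUE, FALSE)),
    reactions = list(reaction("in", c(S = 1), "k1*X0 + c0"),
                     reaction("out", c(S = -1), "k2*S")),
    parameters = c(k1 = 2, c0 = 0, k2 = 4))
  sp <- sensitivity_spectrum(mz, spec = output_spec("flux", "out"))
  expect_equal(sp$status[sp$parameter == "c0"], "undefined")
  expect_equal(sp$reason[sp$parameter == "c0"], "unscalable")
  expect_equal(sp$value[sp$parameter == "k1"], 1, tolerance = 1e-6)
})

test_that("spectra report every parameter, with undefined never omitted", {
  m <- two_step()$model
  sp <- sensitivity_spectrum(m, spec = output_spec("flux", "step2"))
  expect_equal(sp$parameter, c("k1", "k2"))
  expect_equal(sp$value, c(1, 0), tolerance = 1e-6)
  sp2 <- sensitivity_spectrum(m, spec = output_spec("concentration", "S1"),
                              rel_step = 5e-4, method = "central")
  expect_equal(sp2$value, c(1, -1), tolerance = 1e-6)
  # period spectrum on a damped oscillator: all undefined, still present
  dmp <- damped_oscillator()
  sp3 <- sensitivity_spectrum(dmp, spec = output_spec("period", "u",
                                                      t_end = 60))
  expect_equal(nrow(sp3), 1)
  expect_equal(sp3$status, "undefined")
})

test_that("forward and central differences agree within the step bound", {
  rv <- make_reversible_chain(2, kf = c(2, 3), kr = c(1, 1),
                              x0 = 1, x1 = 0.5)
  m <- rv$model
  p <- reference_params(m)
  fl <- output_spec("flux", "step2")
  for (pid in m$parameters$id) {
    f <- scaled_sensitivity(m, p, fl, pid, rel_step = 0.001)$value
    c2 <- scaled_sensitivity(m, p, fl, pid, rel_step = 5e-4,
                             method = "central")$value
    expect_lt(abs(f - c2), max(1e-3, 0.01 * abs(c2)))
  }
})

test_that("unscaled times p/y reproduces the scaled coefficient", {
  rv <- make_reversible_chain(2, kf = c(2, 3), kr = c(1, 1),
                              x0 = 1, x1 = 0.5)
  m <- rv$model
  p <- reference_params(m)
  fl <- output_spec("flux", "step2")
  h <- 0.001
  base <- evaluate_output(m, p, fl)
  y0 <- base$value
  p2 <- p
  p2["kf1"] <- p["kf1"] * (1 + h)
  y1 <- evaluate_output(m, p2, fl, x0 = base$state)$value
  unscaled <- (y1 - y0) / (h * p[["kf1"]])
  scaled <- scaled_sensitivity(m, p, fl, "kf1", rel_step = h)$value
  expect_equal(unscaled * p[["kf1"]] / y0, scaled, tolerance = 1e-9)
})

test_that("control coefficients obey the summation theorems everywhere", {
  fixtures <- list(
    two_step()$model,
    make_irreversible_chain(4, k = c(2, 4, 3, 5))$model,
    make_reversible_chain(3, kf = c(2, 3, 1.5), kr = c(1, 0.5, 2),
                          x0 = 1, x1 = 0.25)$model,
    make_bimodal_control_toy()$model)
  for (m in fixtures) {
    cm <- control_coefficients(m)
    expect_equal(cm$status, "ok")
    expect_true(all(abs(rowSums(cm$fcc) - 1) < 1e-4))
    expect_true(all(abs(rowSums(cm$ccc)) < 1e-4))
  }
  # and on randomly perturbed parameter sets
  rv <- make_reversible_chain(2, kf = c(2, 3), kr = c(1, 1), x0 = 1,
                              x1 = 0.5)
  ref <- reference_params(rv$model)
  set.seed(33)
  for (i in 1:100) {
    p <- ref * runif(length(ref), 0.6, 1.4)
    cm <- control_coefficients(rv$model, p)
    expect_true(all(abs(rowSums(cm$fcc) - 1) < 1e-4))
    expect_true(all(abs(rowSums(cm$ccc)) < 1e-4))
  }
})

test_that("chain control coefficients are exact: 1, 0 and -1 cases", {
  ch <- two_step()
  cm <- control_coefficients(ch$model)
  expect_equal(unname(cm$fcc["step2", ]), c(1, 0), tolerance = 1e-6)
  expect_equal(unname(cm$ccc["S1", ]), c(1, -1), tolerance = 1e-6)
})

test_that("control matrices match the reversible-chain oracle", {
  rv <- make_reversible_chain(3, kf = c(2, 1, 3), kr = c(0.5, 1, 0.25),
                              x0 = 2, x1 = 0.1)
  cm <- control_coefficients(rv$model)
  orc <- rv$oracle$control()
  expect_equal(unname(cm$fcc["step3", ]), unname(orc$fcc),
               tolerance = 1e-5)
  expect_equal(unname(cm$ccc), unname(orc$ccc), tolerance = 1e-5)
  # symmetric two-step chain splits flux control equally
  sym <- make_reversible_chain(2, kf = c(1, 1), kr = c(1, 1), x0 = 1,
                               x1 = 0)
  expect_equal(unname(sym$oracle$control()$fcc), c(0.5, 0.5),
               tolerance = 1e-12)
  cms <- control_coefficients(sym$model)
  expect_equal(unname(cms$fcc["step2", ]), c(0.5, 0.5), tolerance = 1e-5)
  # making one step much faster strips it of flux control
  fast <- make_reversible_chain(2, kf = c(1, 100), kr = c(1, 100), x0 = 1,
                                x1 = 0)
  expect_lt(fast$oracle$control()$fcc[["step2"]], 0.05)
})

test_that("limiting-rate parameters are identified by homogeneity", {
  toy <- make_bimodal_control_toy()
  lr <- limiting_rate_parameters(toy$model)
  expect_equal(unname(lr[c("supply", "branch1", "branch2")]),
               c("V0", "V1", "V2"))
  # K parameters are not linear handles
  expect_false(any(c("K1", "K2") %in% lr))
})

test_that("a steady-state-free model yields an undefined control matrix", {
  prod <- kinetic_model(
    species = data.frame(id = "S", initial = 0),
    reactions = list(reaction("make", c(S = 1), "k")),
    parameters = c(k = 1))
  cm <- control_coefficients(prod)
  expect_equal(cm$status, "undefined")
})

test_that("published T. brucei control values match when files are present", {
  path <- biomodels_file("trypanosoma_albert.xml")
  skip_if_not(file.exists(path),
              paste("no BioModels SBML files under", biomodels_dir()))
  m <- suppressWarnings(load_sbml(path))
  cm <- control_coefficients(m)
  expect_equal(cm$status, "ok")
  # glucose transport on glycosomal ADP concentration
  expect_equal(cm$ccc["ADPg", "vGlcTr"], 7.1, tolerance = 0.1 / 7.1)
  # glycerol transport and glycerol kinase on glycerol concentration
  expect_equal(cm$ccc["Glycerol", "vGlyTr"], 0.99, tolerance = 0.02 / 0.99)
  expect_equal(cm$ccc["Glycerol", "vGK"], 0.65, tolerance = 0.05 / 0.65)
})
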