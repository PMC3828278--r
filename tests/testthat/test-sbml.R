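sbml_fixture <- function() {
  system.file("extdata", "two_step_chain_synthetic.xml", package = "kingsa")
}

# minimal SBML document with injectable extra elements, for error-path tests
sbml_doc <- function(extra = "") {
  paste0('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
 <model id="mini">
  <listOfCompartments><compartment id="cell" size="1"/></listOfCompartments>
  <listOfSpecies>
   <species id="A" compartment="cell" initialConcentration="1"/>
  </listOfSpecies>
  <listOfParameters><parameter id="k" value="2"/></listOfParameters>',
  extra, '
  <listOfReactions>
   <reaction id="r1">
    <listOfReactants><speciesReference species="A"/></listOfReactants>
    <kineticLaw>
     <math xmlns="http://www.w3.org/1998/Math/MathML">
      <apply><times/><ci>k</ci><ci>A</ci></apply>
     </math>
    </kineticLaw>
   </reaction>
  </listOfReactions>
 </model>
</sbml>')
}

write_sbml <- function(txt) {
  f <- withr::local_tempfile(fileext = ".xml",
                             .local_envir = parent.frame())
  writeLines(txt, f)
  f
}

test_that("the synthetic SBML fixture loads with flattened parameters", {
  m <- load_sbml(sbml_fixture())
  # local parameter lifted as <reaction>.<name>; assignment-ruled entity
  # inlined and removed from the parameter list
  expect_setequal(m$parameters$id, c("k1", "k2_scale", "step2.kcat"))
  expect_true(m$species$boundary[m$species$id == "X0"])
  expect_false("k2_eff" %in% m$parameters$id)
  # function definition inlined: step1 rate is k1 * X0
  ss <- find_steady_state(m)
  expect_equal(ss$status, "ok")
  expect_equal(unname(ss$concentrations["S1"]), 0.5, tolerance = 1e-8)
  expect_equal(unname(ss$fluxes["step2"]), 2, tolerance = 1e-8)
})

test_that("a loaded model round-trips parameters into identical dynamics", {
  m <- load_sbml(sbml_fixture())
  p <- reference_params(m)
  m2 <- apply_parameters(m, p)
  rhs1 <- build_rhs(m)
  rhs2 <- build_rhs(m2)
  set.seed(3)
  for (i in 1:10) {
    s <- setNames(runif(nrow(m$species)), m$species$id)
    expect_equal(rhs1(s, p), rhs2(s, p), tolerance = 1e-12)
  }
})

test_that("malformed files give format errors without partial models", {
  empty <- write_sbml("")
  expect_error(load_sbml(empty), "format error")
  notsbml <- write_sbml("<notes><para>hello</para></notes>")
  expect_error(load_sbml(notsbml), "not <sbml>")
  expect_error(load_sbml(file.path(tempdir(), "no-such-file.xml")),
               "not found")
})

test_that("unsupported constructs are named; events only warn", {
  alg <- write_sbml(sbml_doc(
    '<listOfRules><algebraicRule><math xmlns="http://www.w3.org/1998/Math/MathML"><ci>A</ci></math></algebraicRule></listOfRules>'))
  expect_error(load_sbml(alg), "algebraicRule")
  ev <- write_sbml(sbml_doc(
    '<listOfEvents><event id="e1"><trigger><math xmlns="http://www.w3.org/1998/Math/MathML"><apply><gt/><ci>A</ci><cn>1</cn></apply></math></trigger></event></listOfEvents>'))
  expect_warning(m <- load_sbml(ev), "events are ignored")
  expect_equal(length(m$reactions), 1L)
})

test_that("MathML numeric and operator forms translate correctly", {
  m2r <- function(s) {
    node <- xml2::read_xml(paste0(
      '<math xmlns="http://www.w3.org/1998/Math/MathML">', s, "</math>"))
    eval(str2lang(kingsa:::mathml_to_r(node)))
  }
  expect_equal(m2r("<cn type='e-notation'>1.5<sep/>3</cn>"), 1500)
  expect_equal(m2r("<cn type='rational'>3<sep/>4</cn>"), 0.75)
  expect_equal(m2r("<apply><power/><cn>2</cn><cn>5</cn></apply>"), 32)
  expect_equal(
    m2r("<apply><log/><logbase><cn>2</cn></logbase><cn>8</cn></apply>"), 3)
  expect_equal(m2r("<apply><root/><degree><cn>3</cn></degree><cn>27</cn></apply>"),
               3, tolerance = 1e-12)
  expect_equal(m2r("<apply><minus/><cn>7</cn></apply>"), -7)
  expect_equal(
    m2r(paste0("<piecewise><piece><cn>1</cn><apply><lt/><cn>2</cn><cn>1</cn>",
               "</apply></piece><otherwise><cn>9</cn></otherwise></piecewise>")),
    9)
})

test_that("rate rules on parameters become dynamic variables", {
  f <- write_sbml(sbml_doc(
    '<listOfRules><rateRule variable="k"><math xmlns="http://www.w3.org/1998/Math/MathML"><cn>0.5</cn></math></rateRule></listOfRules>'))
  m <- load_sbml(f)
  expect_true("k" %in% m$species$id)
  expect_false("k" %in% m$parameters$id)
  tr <- simulate(m, t_end = 2, n_points = 50)
  expect_equal(tr$status, "ok")
  expect_equal(unname(tr$states[nrow(tr$states), "k"]), 3,
               tolerance = 1e-6) # k(0)=2 growing at 0.5/time
})

test_that("published-model parameter counts match when files are present", {
  files <- c(mapk = "mapk_huang_ferrell.xml",
             nfkb = "nfkb_ashall.xml",
             cellcycle = "cellcycle_chen.xml")
  counts <- c(mapk = 30, nfkb = 27, cellcycle = 142)
  paths <- vapply(files, biomodels_file, "")
  skip_if_not(any(file.exists(paths)),
              paste("no BioModels SBML files under", biomodels_dir()))
  for (k in names(files)) {
    if (!file.exists(paths[[k]])) next
    m <- suppressWarnings(load_sbml(paths[[k]]))
    expect_equal(nrow(m$parameters), unname(counts[k]))
  }
})
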