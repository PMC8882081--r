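test_that("shipped dasatinib record carries the published inputs", {
  das <- dasatinib_record()
  expect_equal(das$molecular_weight, 488.01)
  expect_equal(das$fu_plasma, 0.04)
  expect_equal(das$blood_plasma_ratio, 1.8)
  expect_equal(das$fa, 0.9996)
  expect_equal(das$ka, 4.226)
  expect_equal(das$clpo, 338)
  expect_equal(unname(das$cyp_clint["CYP3A4"]), 11.635)
  expect_equal(das$renal_cl, 0.4)
  expect_true(is_victim_capable(das))
  expect_true(is_perpetrator_capable(das))
  oct2 <- Filter(function(ip) ip$target == "OCT2", das$interaction_set)[[1]]
  expect_equal(oct2$ki, 0.034)
})

test_that("save/load round-trip is lossless on every field", {
  das <- dasatinib_record()
  path <- withr::local_tempfile(fileext = ".yaml")
  save_compound(das, path)
  das2 <- load_compound(path)
  expect_equal(das2, das, tolerance = 1e-12)

  met <- metformin_record()
  path2 <- withr::local_tempfile(fileext = ".yaml")
  save_compound(met, path2)
  expect_equal(load_compound(path2)$kidney_model$ps_oct2, met$kidney_model$ps_oct2)
})

test_that("schema violations name the offending field", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(name = "x", molecular_weight = 100, logP = 1,
                        fa = 0.5, ka = 1), path)
  expect_error(load_compound(path), "fu_plasma")

  expect_error(
    compound_record("bad", molecular_weight = 100, logP = 1,
                    fu_plasma = 1.5, fa = 0.5, ka = 1),
    "fu_plasma"
  )
  expect_error(
    compound_record("bad", molecular_weight = -1, logP = 1,
                    fu_plasma = 0.5, fa = 0.5, ka = 1),
    "molecular_weight"
  )
})

test_that("interaction parameters require exactly the fields of their mechanism", {
  expect_error(interaction_param("OCT2", "reversible"), "ki")
  expect_error(interaction_param("CYP3A4", "mechanism_based", kapp = 1.9), "kinact")
  expect_error(interaction_param("CYP3A4", "reversible", ki = 5, kapp = 1.9), "kapp")
  expect_error(interaction_param("CYP3A4", "reversible", ki = -1), "ki")
  ok <- interaction_param("CYP3A4", "mechanism_based", kapp = 1.9, kinact = 0.022)
  expect_s3_class(ok, "interaction_param")
})

test_that("library clearance scaling reproduces the simvastatin 40% reduction", {
  simva <- pbpk_example_compound("simvastatin")
  scaled <- scale_library_clearance(simva, 0.6)
  # printed values 1370 and 152 are the rounded results of the 0.6 factor
  expect_equal(unname(scaled$cyp_clint["CYP3A4"]), 1370.4)
  expect_equal(round(unname(scaled$cyp_clint["CYP3A4"])), 1370)
  expect_equal(scaled$additional_hlm_clint, 152.4)
  expect_equal(round(scaled$additional_hlm_clint), 152)
  # untouched fields
  expect_equal(scaled$fu_plasma, simva$fu_plasma)
  expect_equal(scaled$ka, simva$ka)
  # identity and composition
  expect_equal(scale_library_clearance(simva, 1), simva)
  ab <- scale_library_clearance(simva, 0.8 * 0.9)
  ba <- scale_library_clearance(scale_library_clearance(simva, 0.8), 0.9)
  expect_equal(ab, ba, tolerance = 1e-12)
  expect_error(scale_library_clearance(simva, 0), "factor")
  expect_error(scale_library_clearance(simva, -0.2), "factor")
})

test_that("all seven shipped compound fixtures load and validate", {
  for (nm in c("dasatinib", "metformin", "pravastatin", "rosuvastatin",
               "simvastatin", "ketoconazole", "rifampin")) {
    rec <- pbpk_example_compound(nm)
    expect_s3_class(rec, "compound_record")
    expect_identical(rec$name, nm)
  }
  expect_error(pbpk_example_compound("nosuchdrug"), "nosuchdrug")
})

test_that("physiology system is internally consistent", {
  sys <- ref_system()
  d <- derived_flows(sys)
  expect_equal(d[["q_liver"]],
               d[["q_portal"]] + sys$flows[["hepatic_artery"]])
  expect_equal(d[["q_portal"]], sys$flows[["gut"]] + sys$flows[["spleen"]])
  # cardiac output covers every tissue flow
  expect_gt(d[["co"]], d[["q_liver"]])
  expect_true(all(sys$volumes > 0) && all(sys$flows > 0))
})
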