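# Shared lazily-built fixtures: models are assembled once per test run.
.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .cache)) {
    assign(name, force(expr), envir = .cache)
  }
  get(name, envir = .cache)
}

ref_system <- function() cached("system", physiology_system())

dasatinib_record <- function() cached("das_rec", pbpk_example_compound("dasatinib"))
dasatinib_model <- function() cached("das_mod", pbpk_model(dasatinib_record(), system = ref_system()))

metformin_record <- function() cached("met_rec", pbpk_example_compound("metformin"))
metformin_model <- function() cached("met_mod", pbpk_model(metformin_record(), system = ref_system()))

pravastatin_model <- function() {
  cached("prava_mod", pbpk_model(pbpk_example_compound("pravastatin"), system = ref_system()))
}
rosuvastatin_model <- function() {
  cached("rosu_mod", pbpk_model(pbpk_example_compound("rosuvastatin"), system = ref_system()))
}

dasatinib_single_dose <- function() {
  cached("das_prof", simulate_pk(dasatinib_model(), dosing_regimen(100), end_time = 48))
}

# a clearance-free neutral test compound for conservation/oracle tests
inert_compound <- function(renal_cl = 0) {
  compound_record("inertin", molecular_weight = 300, logP = 1,
                  pKa_list = numeric(0), compound_type = "neutral",
                  blood_plasma_ratio = 1, fu_plasma = 0.5,
                  fa = 0.9, ka = 1.5, fu_gut = 1, kp_scalar = 1,
                  renal_cl = renal_cl)
}

pbpk_tissues_names <- function() {
  c("adipose", "bone", "brain", "gut", "heart", "kidney", "liver",
    "lung", "muscle", "skin", "spleen")
}

# random valid compound records for property-style loops
random_base_record <- function() {
  compound_record(
    name = "randomide",
    molecular_weight = stats::runif(1, 150, 600),
    logP = stats::runif(1, 0.5, 4),
    pKa_list = sort(stats::runif(2, 4, 10), decreasing = TRUE),
    compound_type = "diprotic base",
    blood_plasma_ratio = stats::runif(1, 0.8, 2),
    fu_plasma = stats::runif(1, 0.02, 0.9),
    fa = stats::runif(1, 0.3, 1),
    ka = stats::runif(1, 0.3, 3),
    fu_gut = 1, kp_scalar = 1
  )
}
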