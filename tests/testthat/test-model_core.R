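# Formulas, model container, IO, and the validation battery

test_that("formula parsing, serialisation and molecular weight behave", {
  f <- parse_formula("C10H12N5O13P3")
  expect_equal(f[["C"]], 10)
  expect_equal(f[["P"]], 3)
  expect_equal(deparse_formula(f), "C10H12N5O13P3")
  # two-letter elements and fractional counts
  expect_equal(parse_formula("Fe")[["Fe"]], 1)
  expect_equal(parse_formula("C3.5H7")[["C"]], 3.5)
  expect_equal(deparse_formula(parse_formula("C3.5H7")), "C3.5H7")
  # empty formula permitted but mass undefined
  expect_length(parse_formula(""), 0)
  expect_error(molecular_weight(""), "unknown")
  # generic side group carries no mass
  expect_error(molecular_weight("C2R"), "side group")
  expect_error(parse_formula("C2Qq3"), "unknown element")
  # glucose to 2 decimals
  expect_equal(molecular_weight("C6H12O6"), 180.156, tolerance = 1e-3)
})

test_that("model constructors enforce the container invariants", {
  expect_error(reaction("r", c(A = 1), lb = 2, ub = 1), "lower_bound")
  expect_error(reaction("r", numeric(0)), "non-empty")
  expect_error(reaction("r", c(A = -1, B = 1), kind = "exchange"),
               "exactly one")
  mets <- list(metabolite("A"), metabolite("B"))
  expect_error(
    metabolic_model(mets, list(reaction("r1", c(A = -1, X = 1))),
                    objective_id = "r1"),
    "X")
  expect_error(
    metabolic_model(mets, list(reaction("r1", c(A = -1, B = 1))),
                    objective_id = "nope"),
    "objective_id")
  expect_error(
    metabolic_model(list(metabolite("A"), metabolite("A")),
                    list(reaction("r1", c(A = 1))), objective_id = "r1"),
    "duplicated")
  # genes declared must cover GPR genes
  expect_error(
    metabolic_model(mets, list(reaction("r1", c(A = -1, B = 1), gpr = "gX")),
                    genes = "gY", objective_id = "r1"),
    "gX")
})

test_that("a small JSON fixture loads with the expected counts", {
  fx <- tempfile(fileext = ".json")
  writeLines('{
    "id": "toy3",
    "metabolites": [
      {"id": "A_c", "compartment": "c", "formula": "CH4", "charge": 0},
      {"id": "B_c", "compartment": "c", "formula": "CH4", "charge": 0}
    ],
    "reactions": [
      {"id": "EX_A", "metabolites": {"A_c": -1}, "lower_bound": -10},
      {"id": "R1", "metabolites": {"A_c": -1, "B_c": 1},
       "gene_reaction_rule": "g1", "lower_bound": 0},
      {"id": "EX_B", "metabolites": {"B_c": -1}, "lower_bound": 0,
       "objective_coefficient": 1}
    ],
    "genes": [{"id": "g1"}]
  }', fx)
  m <- read_model(fx)
  expect_equal(nrow(m$rxns), 3)
  expect_equal(nrow(m$mets), 2)
  expect_equal(m$genes, "g1")
  expect_equal(m$objective_id, "EX_B")
  # bounds absent in the file default to +/- 1000
  expect_equal(m$rxns$ub[m$rxns$id == "R1"], 1000)
  # a reaction citing an undeclared metabolite errors naming it
  fx2 <- tempfile(fileext = ".json")
  writeLines('{
    "metabolites": [{"id": "A_c", "compartment": "c"}],
    "reactions": [{"id": "r", "metabolites": {"X": -1},
                   "objective_coefficient": 1}]
  }', fx2)
  expect_error(read_model(fx2), "X")
})

test_that("models round-trip through both dialects field-by-field", {
  m <- toy_cache()$model
  for (fmt in c("json", "sbml")) {
    path <- tempfile(fileext = if (fmt == "json") ".json" else ".xml")
    write_model(m, path, fmt)
    m2 <- read_model(path, fmt)
    expect_equal(m2$mets, m$mets)
    expect_equal(m2$rxns, m$rxns)
    expect_equal(m2$stoich, m$stoich)
    expect_setequal(m2$genes, m$genes)
    expect_equal(m2$objective_id, m$objective_id)
  }
})

test_that("SBML output omits empty gene associations and JSON keeps schema keys", {
  m <- chain_model(gpr_r1 = "g1")
  xml <- tempfile(fileext = ".xml")
  write_model(m, xml)
  txt <- paste(readLines(xml), collapse = "\n")
  # one GPR'd reaction -> exactly one association element
  expect_equal(lengths(regmatches(txt, gregexpr("<fbc:geneProductAssociation>", txt))), 1L)
  js <- tempfile(fileext = ".json")
  write_model(m, js)
  doc <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_true(all(c("metabolites", "reactions", "genes") %in% names(doc)))
  expect_null(doc$reactions[[1]]$gene_reaction_rule)  # empty GPR omitted
  expect_equal(doc$reactions[[2]]$gene_reaction_rule, "g1")
})

test_that("mass/charge balance flags exactly the planted defect", {
  mets <- list(metabolite("A", formula = "CH4"),
               metabolite("B", formula = "CH4"),
               metabolite("C", formula = "CH3"),
               metabolite("U", formula = ""))
  rxns <- list(reaction("ok", c(A = -1, B = 1)),
               reaction("bad", c(A = -1, C = 1)),
               reaction("unk", c(A = -1, U = 1)),
               reaction("EX_A", c(A = -1), kind = "exchange"))
  m <- metabolic_model(mets, rxns, objective_id = "EX_A")
  bal <- check_mass_charge_balance(m)
  expect_equal(bal$status[bal$id == "ok"], "balanced")
  expect_identical(bal$element_residuals[[which(bal$id == "ok")]],
                   stats::setNames(numeric(0), character(0)))
  expect_equal(bal$status[bal$id == "bad"], "unbalanced")
  expect_equal(bal$element_residuals[[which(bal$id == "bad")]][["H"]], -1)
  expect_equal(bal$status[bal$id == "unk"], "unchecked")
  expect_false("EX_A" %in% bal$id)  # exchanges exempt
})

test_that("generic side groups must cancel for a reaction to balance", {
  mets <- list(metabolite("X", formula = "C2R"),
               metabolite("Y", formula = "C2R"),
               metabolite("Z", formula = "C2"))
  m <- metabolic_model(
    mets,
    list(reaction("keepR", c(X = -1, Y = 1)),
         reaction("dropR", c(X = -1, Z = 1)),
         reaction("EX_X", c(X = -1), kind = "exchange")),
    objective_id = "EX_X")
  bal <- check_mass_charge_balance(m)
  expect_equal(bal$status[bal$id == "keepR"], "balanced")
  expect_equal(bal$status[bal$id == "dropR"], "unbalanced")
  expect_equal(bal$element_residuals[[which(bal$id == "dropR")]][["R"]], -1)
})

test_that("balance soundness: a +1 perturbation unbalances exactly that reaction", {
  m <- toy_cache()$model
  bal0 <- check_mass_charge_balance(m)
  balanced <- bal0$id[bal0$status == "balanced"]
  for (rid in balanced[c(1, 4, 8)]) {  # spot-check a spread of reactions
    m2 <- m
    st <- m2$stoich[[rid]]
    st[[1]] <- st[[1]] + 1
    m2$stoich[[rid]] <- st
    bal <- check_mass_charge_balance(m2)
    now_bad <- bal$id[bal$status == "unbalanced"]
    expect_equal(now_bad, rid)
  }
})

test_that("stoichiometric consistency detects mass creation and recovers", {
  m <- metabolic_model(
    list(metabolite("A"), metabolite("B")),
    list(reaction("r1", c(A = -1, B = 1), lb = -1000),
         reaction("EX_A", c(A = -1), kind = "exchange")),
    objective_id = "r1")
  res <- check_stoichiometric_consistency(m)
  expect_true(res$consistent)

  m_bad <- metabolic_model(
    list(metabolite("A"), metabolite("B")),
    list(reaction("r1", c(A = -1, B = 1), lb = -1000),
         reaction("dup", c(A = 1), kind = "internal"),  # A -> 2A net
         reaction("EX_A", c(A = -1), kind = "exchange")),
    objective_id = "r1")
  res_bad <- check_stoichiometric_consistency(m_bad)
  expect_false(res_bad$consistent)
  expect_true("A" %in% res_bad$unconserved_metabolites)

  # monotonicity: adding a mass-creating reaction to the consistent toy
  # always flips the flag; removing it restores consistency
  toy <- toy_cache()$model
  expect_true(check_stoichiometric_consistency(toy)$consistent)
  toy_bad <- metabolic_model(
    symbflux:::met_records(toy),
    c(symbflux:::rxn_records(toy),
      list(reaction("free_lunch", c(mal__L_c = 1), kind = "internal"))),
    genes = toy$genes, objective_id = toy$objective_id)
  expect_false(check_stoichiometric_consistency(toy_bad)$consistent)
  expect_warning(
    check_stoichiometric_consistency(
      metabolic_model(list(metabolite("A")),
                      list(reaction("EX_A", c(A = -1), kind = "exchange")),
                      objective_id = "EX_A")),
    "trivially")
})

test_that("energy-generating cycles are detected iff the cycle exists", {
  # the synthase is written in the hydrolysis direction; making it
  # reversible lets it regenerate ATP with no driving force -- paired with
  # the independent dissipation probe that is an energy-generating cycle
  mk_pump <- function(synthase_reversible) {
    metabolic_model(
      list(metabolite("atp_c", formula = "C10H12N5O13P3", charge = -4),
           metabolite("adp_c", formula = "C10H12N5O10P2", charge = -3),
           metabolite("pi_c", formula = "HO4P", charge = -2),
           metabolite("h_c", formula = "H", charge = 1),
           metabolite("h2o_c", formula = "H2O")),
      list(reaction("SYNTH", c(atp_c = -1, h2o_c = -1,
                               adp_c = 1, pi_c = 1, h_c = 1),
                    lb = if (synthase_reversible) -1000 else 0, ub = 1000),
           reaction("HYDR", c(atp_c = -1, h2o_c = -1,
                              adp_c = 1, pi_c = 1, h_c = 1),
                    lb = 0, ub = 1000),
           reaction("EX_h", c(h_c = -1), kind = "exchange")),
      objective_id = "HYDR")
  }
  egc <- detect_energy_generating_cycles(mk_pump(TRUE))
  expect_true(egc$egc_detected)
  expect_true("SYNTH" %in% egc$witness)
  expect_false(detect_energy_generating_cycles(mk_pump(FALSE))$egc_detected)
  expect_false(detect_energy_generating_cycles(toy_cache()$model)$egc_detected)
  expect_error(detect_energy_generating_cycles(chain_model()), "absent")
})

test_that("EGC detector agrees with exhaustive enumeration on tiny networks", {
  for (rev in c(TRUE, FALSE)) {
    m <- metabolic_model(
      list(metabolite("atp_c"), metabolite("adp_c"), metabolite("pi_c"),
           metabolite("h_c"), metabolite("h2o_c")),
      list(reaction("SYNTH", c(adp_c = -1, pi_c = -1, h_c = -1,
                               atp_c = 1, h2o_c = 1),
                    lb = if (rev) -1000 else 0, ub = 1000),
           reaction("EX_h", c(h_c = -1), kind = "exchange"),
           reaction("EX_w", c(h2o_c = -1), kind = "exchange")),
      objective_id = "SYNTH")
    det <- detect_energy_generating_cycles(m)
    # oracle: maximise the dissipation flux over the closed network by
    # vertex enumeration
    closed <- m
    shut <- closed$rxns$kind %in% c("exchange", "objective")
    closed$rxns$lb[shut] <- 0; closed$rxns$ub[shut] <- 0
    probe <- metabolic_model(
      symbflux:::met_records(closed),
      c(symbflux:::rxn_records(closed),
        list(reaction("DISS", c(atp_c = -1, h2o_c = -1, adp_c = 1,
                                pi_c = 1, h_c = 1), lb = 0, ub = 1000))),
      objective_id = "DISS")
    S <- stoich_matrix(probe)
    ora <- oracle_lp_max(as.numeric(probe$rxns$id == "DISS"), S,
                         probe$rxns$lb, probe$rxns$ub)
    expect_equal(det$egc_detected, ora$objective > 1e-6)
  }
})

test_that("validation reports serialise to TSV and YAML", {
  toy <- toy_cache()
  dir <- tempfile(); dir.create(dir)
  rep <- run_validation(toy$model, dir)
  expect_true(rep$ok)
  expect_true(file.exists(file.path(dir, "validation_residuals.tsv")))
  y <- yaml::read_yaml(file.path(dir, "validation_summary.yaml"))
  expect_true(y$overall_pass)
  expect_equal(y$unbalanced, 0)
  expect_false(y$egc_detected)
})
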