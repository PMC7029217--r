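# Symbiosis composition, objective construction, and yields

test_that("composition scaling reaches unit product MW exactly", {
  comp <- symbiosis_composition(
    component = c("x_c", "y_c"),
    coefficient = c(2, 1),
    formula = c("C6H12O6", "H2O"),
    charge = c(0, 0))
  # oracle: hand arithmetic on sum(coeff * MW)
  mw_x <- molecular_weight("C6H12O6") / 1000
  mw_y <- molecular_weight("H2O") / 1000
  s <- 1 / (2 * mw_x + 1 * mw_y)
  scaled <- scale_to_unit_molecular_weight(comp)
  expect_equal(scaled$coefficient, c(2, 1) * s, tolerance = 1e-12)
  expect_equal(composition_product_mw(scaled), 1, tolerance = 1e-12)
  # proportions preserved
  expect_equal(scaled$coefficient[1] / scaled$coefficient[2], 2)
  # fixed point: scaling an already-scaled composition changes nothing
  expect_equal(scale_to_unit_molecular_weight(scaled)$coefficient,
               scaled$coefficient, tolerance = 1e-14)
  # unknown formulas are refused
  comp_bad <- symbiosis_composition("x_c", 1, "", 0)
  expect_error(scale_to_unit_molecular_weight(comp_bad), "unknown formula")
  expect_error(symbiosis_composition(character(0), numeric(0),
                                     character(0), numeric(0)), "empty")
  expect_error(symbiosis_composition("x", -1, "C", 0), "> 0")
})

test_that("composition TSVs round-trip", {
  comp <- scale_to_unit_molecular_weight(toy_cache()$composition)
  path <- tempfile(fileext = ".tsv")
  write_composition(comp, path)
  back <- read_composition(path)
  expect_equal(back$component, comp$component)
  expect_equal(back$coefficient, comp$coefficient, tolerance = 1e-12)
  expect_error(read_composition({
    p <- tempfile(); writeLines("a\tb", p); p
  }), "columns")
})

test_that("the built symbiosis reaction is balanced by construction", {
  toy <- toy_cache()
  m <- toy$model
  # the generator used build_symbiosis_reaction: one pseudo-metabolite,
  # the reaction, and its sink
  expect_true("symbiosis_product_c" %in% m$mets$id)
  expect_true(all(c("SYMBIOSIS", "SK_symbiosis_product") %in% m$rxns$id))
  expect_equal(m$objective_id, "SK_symbiosis_product")
  bal <- check_mass_charge_balance(m)
  expect_equal(bal$status[bal$id == "SYMBIOSIS"], "balanced")
  # oracle: independent elemental summation over the composition table
  comp <- toy$composition
  acc <- list()
  for (k in seq_len(nrow(comp))) {
    f <- parse_formula(comp$formula[k])
    for (e in names(f)) {
      acc[[e]] <- (if (is.null(acc[[e]])) 0 else acc[[e]]) +
        comp$coefficient[k] * f[[e]]
    }
  }
  prod_formula <- parse_formula(m$mets$formula[m$mets$id == "symbiosis_product_c"])
  for (e in names(acc)) {
    # the stored formula string rounds counts to six decimals
    expect_equal(prod_formula[[e]], acc[[e]], tolerance = 1e-4)
  }
  # flux of 1 through the sink moves 1 g of product: MW = 1 g/mmol
  expect_equal(molecular_weight(prod_formula) / 1000, 1, tolerance = 1e-6)

  small <- chain_model()
  expect_error(
    build_symbiosis_reaction(small, scale_to_unit_molecular_weight(
      symbiosis_composition("missing_c", 1, "C", 0))),
    "absent")
  expect_error(
    build_symbiosis_reaction(small, data.frame(component = "x")),
    "symbiosis_composition")
  # unscaled compositions are refused
  unscaled <- toy$composition
  unscaled$coefficient <- unscaled$coefficient * 2
  expect_error(build_symbiosis_reaction(toy$model, unscaled), "not scaled")
})

test_that("cross-model rescaling equalises mass per flux unit", {
  base <- metabolic_model(
    list(metabolite("A_c", formula = "C6H12O6"),
         metabolite("B_c", formula = "H2O")),
    list(reaction("EX_A", c(A_c = -1), lb = -10, kind = "exchange"),
         reaction("EX_B", c(B_c = -1), lb = -10, kind = "exchange")),
    objective_id = "EX_A", id = "base")
  comp1 <- scale_to_unit_molecular_weight(
    symbiosis_composition(c("A_c", "B_c"), c(1, 2),
                          c("C6H12O6", "H2O"), c(0, 0)))
  m1 <- build_symbiosis_reaction(base, comp1)
  # model 2: same composition but symbiosis reaction doubled by hand,
  # moving 2 g per flux unit
  m2 <- m1
  st <- m2$stoich[["SYMBIOSIS"]]
  st[names(st) != "symbiosis_product_c"] <-
    2 * st[names(st) != "symbiosis_product_c"]
  m2$stoich[["SYMBIOSIS"]] <- st
  out <- rescale_for_cross_model_comparison(list(m1, m2))
  # oracle: mass moved per unit flux is 1 g in both after rescaling
  for (m in out) {
    stm <- m$stoich[["SYMBIOSIS"]]
    comp_ids <- setdiff(names(stm), "symbiosis_product_c")
    idx <- match(comp_ids, m$mets$id)
    mass <- sum(-stm[comp_ids] *
                  vapply(m$mets$formula[idx],
                         function(f) molecular_weight(f) / 1000, 0))
    expect_equal(mass, 1, tolerance = 1e-9)
  }
  # idempotence on an already-unit model
  again <- rescale_for_cross_model_comparison(list(m1))[[1]]
  expect_equal(again$stoich[["SYMBIOSIS"]], m1$stoich[["SYMBIOSIS"]],
               tolerance = 1e-12)
  expect_error(rescale_for_cross_model_comparison(list(base)), "lacks")
})

test_that("yields divide product flux by elemental uptake", {
  m <- metabolic_model(
    list(metabolite("glc_c", formula = "C6H12O6"),
         metabolite("n_c", formula = "N2"),
         metabolite("p_c", formula = "C3H3O3")),
    list(reaction("EX_glc", c(glc_c = -1), lb = -10, kind = "exchange"),
         reaction("EX_n", c(n_c = -1), lb = -5, kind = "exchange"),
         reaction("conv", c(glc_c = -2, n_c = -1, p_c = 4), lb = 0),
         reaction("EX_p", c(p_c = -1), lb = 0, kind = "exchange")),
    objective_id = "EX_p")
  fit <- solve_fba(m)
  y <- compute_symbiosis_yields(m, fit)
  # 10 glc -> 20 fluxes... oracle: objective 20, C uptake 60, N uptake 10
  expect_equal(y$objective, 20)
  expect_equal(y$carbon_uptake, 60)
  expect_equal(y$nitrogen_uptake, 10)
  expect_equal(y$carbon_yield, 20 / 60)
  expect_equal(y$c_to_n, (20 / 60) / (20 / 10))
  # zero nitrogen uptake errors
  m2 <- set_bounds(m, "EX_n", lb = 0)
  m2$stoich[["conv"]] <- c(glc_c = -1, p_c = 2)
  f2 <- solve_fba(m2)
  expect_error(compute_symbiosis_yields(m2, f2), "nitrogen")
  # zero carbon uptake errors
  m3 <- set_bounds(m, "EX_glc", lb = 0)
  m3 <- set_bounds(m3, "EX_n", lb = 0)
  f3 <- solve_fba(m3)
  expect_error(compute_symbiosis_yields(m3, f3), "carbon")
})

test_that("carbon is conserved through the optimal flux vector", {
  toy <- toy_cache()
  m <- toy_std_model()
  fit <- solve_fba(m)
  fml <- lapply(m$mets$formula, parse_formula)
  names(fml) <- m$mets$id
  carbon <- function(met) {
    f <- fml[[met]]
    if ("C" %in% names(f)) f[["C"]] else 0
  }
  # net elemental flow over all exchanges and the product sink must vanish
  flow <- 0
  for (id in m$rxns$id[m$rxns$kind %in% c("exchange", "objective")]) {
    met <- names(m$stoich[[id]])[1]
    flow <- flow + fit$fluxes[[id]] * m$stoich[[id]][[1]] * carbon(met)
  }
  expect_equal(flow, 0, tolerance = 1e-6)
})

test_that("optimal yield is invariant to symbiosis-reaction rescaling", {
  toy <- toy_cache()
  m <- toy_std_model()
  y0 <- compute_symbiosis_yields(m, solve_fba(m))
  # rescale the symbiosis reaction by 3x, then normalise back
  m3 <- m
  st <- m3$stoich[["SYMBIOSIS"]]
  st[names(st) != "symbiosis_product_c"] <-
    3 * st[names(st) != "symbiosis_product_c"]
  m3$stoich[["SYMBIOSIS"]] <- st
  m3n <- rescale_for_cross_model_comparison(list(m3))[[1]]
  y3 <- compute_symbiosis_yields(m3n, solve_fba(m3n))
  expect_equal(y3$carbon_yield, y0$carbon_yield, tolerance = 1e-6)
  expect_equal(y3$c_to_n, y0$c_to_n, tolerance = 1e-6)
})

test_that("raising the malate uptake never lowers the optimum", {
  toy <- toy_cache()
  m <- toy_std_model()
  prev <- -Inf
  for (u in c(0.5, 1, 1.44, 2, 4)) {
    f <- solve_fba(set_bounds(m, "EX_mal__L_e", lb = -u))
    expect_gte(f$objective_value, prev - 1e-8)
    prev <- f$objective_value
  }
})
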