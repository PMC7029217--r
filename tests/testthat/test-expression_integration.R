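# E-Flux: scores, condition bounds, condition models

test_that("expression profiles validate their values", {
  expect_error(expression_profile("c", c(g1 = NaN)), "NA")
  expect_error(expression_profile("c", c(g1 = -0.5)), "sentinel")
  p <- expression_profile("c", c(g1 = 2, g2 = -1, g3 = 0))
  expect_equal(p$condition, "c")
  path <- tempfile(fileext = ".tsv")
  write_expression_tsv(p, path)
  back <- read_expression_tsv(path, "c")
  expect_equal(back$values, p$values)
})

test_that("reaction scores implement min-over-and, sum-over-or with -1 rules", {
  ex <- c(g1 = 5, g2 = 3, g3 = 2, gm = -1)
  expect_equal(gpr_expression_score(parse_gpr("g1 and g2"), ex), 3)
  expect_equal(gpr_expression_score(parse_gpr("g3 or g2"), ex), 5)
  # a -1 subunit is ignored when a sibling is scored
  expect_equal(gpr_expression_score(parse_gpr("gm and g2"), ex), 3)
  expect_equal(gpr_expression_score(parse_gpr("gm or g3"), ex), 2)
  expect_equal(gpr_expression_score(parse_gpr("gm and gunknown"), ex), -1)
  expect_equal(gpr_expression_score(NULL, ex), -1)       # orphan reaction
  expect_equal(gpr_expression_score(parse_gpr("g1 or g2 and g3"), ex), 7)
  # on a model: orphan exchanges score -1
  m <- toy_std_model()
  sc <- reaction_expression_scores(
    m, expression_profile("x", stats::setNames(rep(1, length(m$genes)),
                                               m$genes)))
  expect_true(all(sc[startsWith(names(sc), "EX_")] == -1))
  expect_equal(unname(sc[["ATPM"]]), -1)
})

test_that("E-Flux bounds scale the envelope by relative activity", {
  m <- toy_std_model()
  baseline <- flux_variability(m, 0)
  ones <- stats::setNames(rep(7, length(m$genes)), m$genes)
  sc1 <- reaction_expression_scores(m, expression_profile("A", ones))
  sc2 <- reaction_expression_scores(m, expression_profile("B", ones))
  bnds <- eflux_bounds(m, list(A = sc1, B = sc2), baseline)
  # identical profiles: both conditions agree, and the max-scoring
  # reactions (isozyme pairs score 2x the singletons) hit the envelope
  expect_equal(bnds$A$lb, bnds$B$lb, tolerance = 1e-12)
  expect_equal(bnds$A$ub, bnds$B$ub, tolerance = 1e-12)
  top <- names(sc1)[sc1 == max(sc1)]
  k <- match(top, bnds$A$id); l <- match(top, baseline$id)
  expect_equal(bnds$A$ub[k], baseline$max[l], tolerance = 1e-9)
  # half the global max -> half the envelope
  half <- sc1
  half[half >= 0] <- max(sc1) / 2
  bnds2 <- eflux_bounds(m, list(A = half, B = sc1), baseline)
  hk <- which(bnds2$A$id == "CYOO")
  expect_equal(bnds2$A$ub[hk], baseline$max[baseline$id == "CYOO"] / 2,
               tolerance = 1e-9)
  # -1 in one condition only: unconstrained (condition bounds) there only
  miss <- sc1; miss[["CYOO"]] <- -1
  bnds3 <- eflux_bounds(m, list(A = miss, B = sc1), baseline)
  expect_equal(bnds3$A$ub[hk], m$rxns$ub[m$rxns$id == "CYOO"])
  expect_lt(bnds3$B$ub[hk], m$rxns$ub[m$rxns$id == "CYOO"])
  # all -1 in both conditions: nothing to constrain
  none <- sc1; none[] <- -1
  expect_error(eflux_bounds(m, list(A = none, B = none), baseline),
               "no constraining")
})

test_that("zero expression closes a reaction; condition models are local", {
  m <- toy_std_model()
  baseline <- flux_variability(m, 0)
  vals <- stats::setNames(rep(10, length(m$genes)), m$genes)
  vals[c("nifH")] <- 0
  sc <- reaction_expression_scores(m, expression_profile("A", vals))
  expect_equal(unname(sc[["NIT"]]), 0)
  bnds <- eflux_bounds(m, list(A = sc), baseline)$A
  i <- which(bnds$id == "NIT")
  expect_equal(c(bnds$lb[i], bnds$ub[i]), c(0, 0))

  # build_condition_model: empty bounds = identity; single bound = locality
  empty <- structure(data.frame(id = character(0), lb = numeric(0),
                                ub = numeric(0)),
                     class = c("condition_bounds", "data.frame"))
  expect_equal(build_condition_model(m, empty), m)
  one <- structure(data.frame(id = "CYOO", lb = 0, ub = 1.5),
                   class = c("condition_bounds", "data.frame"))
  m2 <- build_condition_model(m, one)
  expect_equal(m2$rxns$ub[m2$rxns$id == "CYOO"], 1.5)
  changed <- m2$rxns$ub != m$rxns$ub | m2$rxns$lb != m$rxns$lb
  expect_equal(m$rxns$id[changed], "CYOO")
  bad <- structure(data.frame(id = "NOPE", lb = 0, ub = 1),
                   class = c("condition_bounds", "data.frame"))
  expect_error(build_condition_model(m, bad), "NOPE")
})

test_that("lowering one gene's expression never widens any bound", {
  m <- toy_std_model()
  baseline <- flux_variability(m, 0)
  vals <- stats::setNames(rep(10, length(m$genes)), m$genes)
  b0 <- eflux_bounds(m, list(A = reaction_expression_scores(
    m, expression_profile("A", vals))), baseline)$A
  for (g in c("ctaD", "mdh1", "nifH", "iolT")) {
    v2 <- vals; v2[[g]] <- 2
    b1 <- eflux_bounds(m, list(A = reaction_expression_scores(
      m, expression_profile("A", v2))), baseline)$A
    expect_true(all(abs(b1$ub) <= abs(b0$ub) + 1e-9))
    expect_true(all(abs(b1$lb) <= abs(b0$lb) + 1e-9))
  }
})

test_that("condition optima never exceed the unconstrained optimum, and the
           -1 sentinel is neutral", {
  toy <- toy_cache()
  m <- toy_std_model()
  full <- solve_fba(m)$objective_value
  baseline <- flux_variability(m, 0)
  profs <- generate_expression_profiles(toy$model)
  sc <- lapply(profs, function(p) reaction_expression_scores(m, p))
  bnds <- eflux_bounds(m, sc, baseline)
  for (nm in names(bnds)) {
    f <- solve_fba(build_condition_model(m, bnds[[nm]]))
    expect_lte(f$objective_value, full + 1e-6)
  }
  # sentinel neutrality: with (almost) every value -1 the unconstrained
  # optimum is reproduced exactly (one scored isozyme keeps the bounds
  # table non-degenerate; its own relative activity is 1)
  allmiss <- stats::setNames(rep(-1, length(m$genes)), m$genes)
  vals <- allmiss; vals[["mdh1"]] <- 5
  scx <- reaction_expression_scores(m, expression_profile("one", vals))
  bn <- eflux_bounds(m, list(A = scx), baseline)$A
  mm <- build_condition_model(m, bn)
  # only the MDH bound can differ; with mdh1 the sole scored gene its
  # relative activity is 1, so the optimum is preserved exactly
  expect_equal(solve_fba(mm)$objective_value, full, tolerance = 1e-9)
})

test_that("a k-fold bottleneck reduction shows up as a k-fold optimum ratio", {
  # chain whose only scaled reaction is the bottleneck: the condition
  # optimum then scales exactly with the planted fold change
  m <- chain_model(gpr_r1 = "gB")
  m <- set_bounds(m, "R1", ub = 10)
  baseline <- flux_variability(m, 0)
  for (k in c(0.2, 0.5, 0.8)) {
    scA <- reaction_expression_scores(
      m, expression_profile("A", c(gB = 100)))
    scB <- reaction_expression_scores(
      m, expression_profile("B", c(gB = 100 * k)))
    bnds <- eflux_bounds(m, list(A = scA, B = scB), baseline)
    fA <- solve_fba(build_condition_model(m, bnds$A))
    fB <- solve_fba(build_condition_model(m, bnds$B))
    expect_equal(fB$objective_value / fA$objective_value, k,
                 tolerance = 1e-8)
  }
})

test_that("an oxidase down-shift lowers the shifted condition's yield", {
  toy <- toy_cache()
  # a moderate down-shift: a drastic one would leave too little ATP
  # capacity to pay the fixed maintenance at all (infeasible, not just low)
  sc <- expression_scenario(fold_changes = c(oxphos = 0.85),
                            sigma = 0, missing_fraction = 0)
  profs <- generate_expression_profiles(toy$model, sc)
  m <- toy_std_model()
  baseline <- flux_variability(m, 0)
  scores <- lapply(profs, function(p) reaction_expression_scores(m, p))
  bnds <- eflux_bounds(m, scores, baseline)
  fA <- solve_fba(build_condition_model(m, bnds$A))
  fB <- solve_fba(build_condition_model(m, bnds$B))
  expect_lt(fB$objective_value, fA$objective_value)
})
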