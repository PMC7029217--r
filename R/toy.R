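# Toy bacteroid network generator ---------------------------------------------
#
# A small, fully mass- and charge-balanced bacteroid network that exercises
# every stage of the pipeline without external data: C4-dicarboxylate
# (malate/succinate) uptake feeding a lumped TCA cycle, oxidative
# phosphorylation limited by microaerobic O2, the canonical nitrogenase
# reaction, PHB and glycogen storage (glycogen either cheaply from
# myo-inositol or expensively by gluconeogenesis), ammonium / alanine /
# aspartate export, an ATP maintenance drain, and a balanced symbiosis
# objective. Real elemental formulas are used throughout so the validation
# battery applies unmodified. The network is an abstraction (single lumped
# oxidative-phosphorylation reaction, residue formulas for polymers): a
# test fixture, not a biological claim.

#' Parameters of the toy bacteroid generator
#'
#' @param include_inositol_pathway include myo-inositol uptake and its
#'   direct conversion to glycogen units (the cheap storage route).
#' @param n_isozyme_pairs 0..4; how many of the candidate reactions
#'   (malate dehydrogenase, malic enzyme, PHB synthesis, alanine
#'   transaminase, in that order) carry two-gene `or` rules.
#' @param nitrogenase_atp_per_n2 ATP hydrolysed per N2 fixed (canonical 16;
#'   must be >= 6 for the reaction to balance with a non-negative proton
#'   term).
#' @param capacity named multipliers applied to the default flux capacity
#'   (1000 mmol/gDW/h) of each pathway's reactions.
#' @param seed generator seed (the network is deterministic; the seed is
#'   recorded and used by downstream profile generation defaults).
#' @return object of class `toy_bacteroid_params`.
#' @export
toy_bacteroid_params <- function(include_inositol_pathway = TRUE,
                                 n_isozyme_pairs = 2L,
                                 nitrogenase_atp_per_n2 = 16,
                                 capacity = list(),
                                 seed = 1L) {
  if (nitrogenase_atp_per_n2 < 6) {
    stop("nitrogenase_atp_per_n2 must be >= 6")
  }
  if (n_isozyme_pairs < 0L || n_isozyme_pairs > 4L) {
    stop("n_isozyme_pairs must be between 0 and 4")
  }
  cap <- list(central = 1, tca = 1, oxphos = 1, nitrogenase = 1,
              storage = 1, inositol = 1, amino = 1, transport = 1,
              iron_transport = 1)
  cap[names(capacity)] <- capacity
  if (any(unlist(cap) <= 0)) stop("capacity scalars must be > 0")
  structure(list(include_inositol_pathway = include_inositol_pathway,
                 n_isozyme_pairs = as.integer(n_isozyme_pairs),
                 nitrogenase_atp_per_n2 = nitrogenase_atp_per_n2,
                 capacity = cap, seed = as.integer(seed)),
            class = "toy_bacteroid_params")
}

# metabolite table of the toy (BiGG-style ids, real formulas/charges)
toy_metabolites <- function(include_inositol) {
  m <- list(
    c("mal__L_c", "L-malate", "C4H4O5", -2, "c"),
    c("succ_c", "succinate", "C4H4O4", -2, "c"),
    c("oaa_c", "oxaloacetate", "C4H2O5", -2, "c"),
    c("akg_c", "2-oxoglutarate", "C5H4O5", -2, "c"),
    c("pyr_c", "pyruvate", "C3H3O3", -1, "c"),
    c("accoa_c", "acetyl-CoA", "C23H34N7O17P3S", -4, "c"),
    c("coa_c", "coenzyme A", "C21H32N7O16P3S", -4, "c"),
    c("glu__L_c", "L-glutamate", "C5H8NO4", -1, "c"),
    c("ala__L_c", "L-alanine", "C3H7NO2", 0, "c"),
    c("asp__L_c", "L-aspartate", "C4H6NO4", -1, "c"),
    c("phb_c", "PHB residue", "C4H6O2", 0, "c"),
    c("glycogen_c", "glycogen residue", "C6H10O5", 0, "c"),
    c("atp_c", "ATP", "C10H12N5O13P3", -4, "c"),
    c("adp_c", "ADP", "C10H12N5O10P2", -3, "c"),
    c("pi_c", "phosphate", "HO4P", -2, "c"),
    c("h_c", "proton", "H", 1, "c"),
    c("h2o_c", "water", "H2O", 0, "c"),
    c("nad_c", "NAD+", "C21H26N7O14P2", -1, "c"),
    c("nadh_c", "NADH", "C21H27N7O14P2", -2, "c"),
    c("o2_c", "oxygen", "O2", 0, "c"),
    c("co2_c", "carbon dioxide", "CO2", 0, "c"),
    c("n2_c", "dinitrogen", "N2", 0, "c"),
    c("nh4_c", "ammonium", "H4N", 1, "c"),
    c("h2_c", "dihydrogen", "H2", 0, "c"),
    c("fe2_c", "Fe(II)", "Fe", 2, "c"),
    c("mal__L_e", "L-malate (plant)", "C4H4O5", -2, "e"),
    c("succ_e", "succinate (plant)", "C4H4O4", -2, "e"),
    c("glu__L_e", "L-glutamate (plant)", "C5H8NO4", -1, "e"),
    c("nh4_e", "ammonium (plant)", "H4N", 1, "e"),
    c("ala__L_e", "L-alanine (plant)", "C3H7NO2", 0, "e"),
    c("asp__L_e", "L-aspartate (plant)", "C4H6NO4", -1, "e"),
    c("fe2_e", "Fe(II) (plant)", "Fe", 2, "e")
  )
  if (include_inositol) {
    m <- c(m, list(c("inost_c", "myo-inositol", "C6H12O6", 0, "c"),
                   c("inost_e", "myo-inositol (plant)", "C6H12O6", 0, "e")))
  }
  lapply(m, function(x) metabolite(x[[1]], x[[2]], x[[3]],
                                   as.numeric(x[[4]]), x[[5]]))
}

#' Generate the toy bacteroid model
#'
#' @param params a [toy_bacteroid_params()].
#' @param check run the full validation battery and a standard-condition
#'   feasibility probe on the generated model (on by default; generation
#'   fails loudly with a diagnosis if the parameters break the network).
#' @return list with elements `model` (a [metabolic_model()] whose
#'   objective is the symbiosis product sink, with the gene->pathway map
#'   attached as `attr(model, "gene_pathways")`), `composition` (the scaled
#'   [symbiosis_composition()]), `condition` (the matching standard
#'   nitrogen-fixation condition), and `params`.
#' @export
generate_toy_bacteroid_model <- function(params = toy_bacteroid_params(),
                                         check = TRUE) {
  stopifnot(inherits(params, "toy_bacteroid_params"))
  inc_ino <- params$include_inositol_pathway
  a <- params$nitrogenase_atp_per_n2
  cap <- params$capacity

  iso <- function(k, pair, single) {
    if (params$n_isozyme_pairs >= k) pair else single
  }
  ub_of <- function(pw) 1000 * cap[[pw]]

  # canonical nitrogenase, ATP coefficient `a` configurable; the proton
  # term (a - 6) keeps hydrogen and charge balanced for any a >= 6
  nit_st <- c(n2_c = -1, nadh_c = -4, atp_c = -a, h2o_c = -a,
              nh4_c = 2, h2_c = 1, nad_c = 4, adp_c = a, pi_c = a,
              h_c = a - 6)
  nit_st <- nit_st[nit_st != 0]

  rxn_specs <- list(
    # internal core (pathway, stoichiometry, lb, ub, gpr)
    list("MDH", c(mal__L_c = -1, nad_c = -1, oaa_c = 1, nadh_c = 1, h_c = 1),
         -ub_of("tca"), ub_of("tca"), iso(1L, "mdh1 or mdh2", "mdh1"),
         "internal", "tca", "malate dehydrogenase"),
    list("SUCDHL", c(succ_c = -1, nad_c = -1, h2o_c = -1,
                     mal__L_c = 1, nadh_c = 1, h_c = 1),
         0, ub_of("tca"), "sdhA and sdhB", "internal", "tca",
         "succinate oxidation to malate (lumped)"),
    list("ME", c(mal__L_c = -1, nad_c = -1, pyr_c = 1, co2_c = 1, nadh_c = 1),
         0, ub_of("central"), iso(2L, "mae1 or mae2", "mae1"),
         "internal", "central", "malic enzyme"),
    list("PDH", c(pyr_c = -1, coa_c = -1, nad_c = -1,
                  accoa_c = 1, co2_c = 1, nadh_c = 1),
         0, ub_of("central"), "pdhA and pdhB", "internal", "central",
         "pyruvate dehydrogenase"),
    list("CSICD", c(accoa_c = -1, oaa_c = -1, h2o_c = -1, nad_c = -1,
                    akg_c = 1, co2_c = 1, coa_c = 1, nadh_c = 1, h_c = 1),
         0, ub_of("tca"), "gltA", "internal", "tca",
         "citrate synthase + isocitrate dehydrogenase (lumped)"),
    list("AKGDH", c(akg_c = -1, nad_c = -1, adp_c = -1, pi_c = -1,
                    succ_c = 1, co2_c = 1, nadh_c = 1, atp_c = 1),
         0, ub_of("tca"), "sucA and sucB", "internal", "tca",
         "2-oxoglutarate dehydrogenase + succinyl-CoA synthetase (lumped)"),
    list("CYOO", c(nadh_c = -1, h_c = -4, o2_c = -0.5, adp_c = -3, pi_c = -3,
                   nad_c = 1, h2o_c = 4, atp_c = 3),
         0, ub_of("oxphos"), "ctaD and ctaE", "internal", "oxphos",
         "respiratory chain + cytochrome oxidase (lumped, P/O = 3)"),
    list("NIT", nit_st,
         0, ub_of("nitrogenase"), "nifH and nifD and nifK", "internal",
         "nitrogenase", "nitrogenase complex"),
    list("ALATA", c(pyr_c = -1, glu__L_c = -1, ala__L_c = 1, akg_c = 1),
         0, ub_of("amino"), iso(4L, "alaA or alaB", "alaA"),
         "internal", "amino", "alanine transaminase"),
    list("ASPTA", c(oaa_c = -1, glu__L_c = -1, asp__L_c = 1, akg_c = 1),
         0, ub_of("amino"), "aspB", "internal", "amino",
         "aspartate transaminase"),
    list("PHAB", c(accoa_c = -2, nadh_c = -1, h_c = -1,
                   phb_c = 1, coa_c = 2, nad_c = 1),
         0, ub_of("storage"), iso(3L, "phaB1 or phaB2", "phaB1"),
         "internal", "storage", "PHB synthesis (per residue)"),
    list("GNG", c(pyr_c = -2, atp_c = -4, nadh_c = -2, h2o_c = -3,
                  glycogen_c = 1, adp_c = 4, pi_c = 4, nad_c = 2),
         0, ub_of("storage"), "ppdK", "internal", "storage",
         "gluconeogenic glycogen synthesis (lumped)"),
    list("ATPM", c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1, h_c = 1),
         0, 1000, "", "internal", "maintenance",
         "non-growth ATP maintenance"),
    # transports
    list("MALt", c(mal__L_e = -1, mal__L_c = 1), 0, ub_of("transport"),
         "malT", "transport", "transport", "malate uptake"),
    list("SUCCt", c(succ_e = -1, succ_c = 1), 0, ub_of("transport"),
         "sucT", "transport", "transport", "succinate uptake"),
    list("GLUt", c(glu__L_e = -1, glu__L_c = 1), 0, ub_of("transport"),
         "gluT", "transport", "transport", "glutamate uptake"),
    list("FE2t", c(fe2_e = -1, fe2_c = 1), 0, ub_of("iron_transport"),
         "afuA and afuB and afuC", "transport", "iron_transport",
         "ABC iron(II) import"),
    list("NH4t", c(nh4_c = -1, nh4_e = 1), 0, ub_of("transport"),
         "amtB", "transport", "transport", "ammonium export"),
    list("ALAt", c(ala__L_c = -1, ala__L_e = 1), 0, ub_of("transport"),
         "alaT", "transport", "transport", "alanine export"),
    list("ASPt", c(asp__L_c = -1, asp__L_e = 1), 0, ub_of("transport"),
         "aspT", "transport", "transport", "aspartate export")
  )
  if (inc_ino) {
    rxn_specs <- c(rxn_specs, list(
      list("INOSTt", c(inost_e = -1, inost_c = 1), 0, ub_of("inositol"),
           "iolT", "transport", "inositol", "myo-inositol uptake"),
      # downstream conversion is classed with storage so the transporter is
      # the single expression-limited step of the inositol route; a serial
      # chain with identical scaled caps would deadlock any single-reaction
      # greedy adoption
      list("GLYCS", c(inost_c = -1, glycogen_c = 1, h2o_c = 1),
           0, ub_of("inositol"), "iolG", "internal", "storage",
           "glycogen residue from myo-inositol (lumped)")
    ))
  }
  ex_mets <- c("mal__L_e", "succ_e", "glu__L_e", "nh4_e", "ala__L_e",
               "asp__L_e", "fe2_e", "o2_c", "n2_c", "co2_c", "h_c",
               "h2o_c", "pi_c", "h2_c")
  if (inc_ino) ex_mets <- c(ex_mets, "inost_e")
  for (m in ex_mets) {
    rxn_specs <- c(rxn_specs, list(
      list(paste0("EX_", m), stats::setNames(-1, m), -1000, 1000, "",
           "exchange", "exchange", paste0("exchange of ", m))))
  }

  reactions <- lapply(rxn_specs, function(s) {
    reaction(s[[1]], s[[2]], name = s[[8]], lb = s[[3]], ub = s[[4]],
             gpr = s[[5]], kind = s[[6]])
  })
  pathways <- stats::setNames(vapply(rxn_specs, `[[`, "", 7),
                              vapply(rxn_specs, `[[`, "", 1))

  model <- metabolic_model(toy_metabolites(inc_ino), reactions,
                           objective_id = rxn_specs[[1]][[1]],
                           id = "toy_bacteroid")
  comp <- scale_to_unit_molecular_weight(symbiosis_composition(
    component = c("phb_c", "glycogen_c", "glu__L_c", "nh4_c", "pi_c", "fe2_c"),
    coefficient = c(6.0, 1.5, 0.8, 1.0, 0.1, 0.02),
    formula = c("C4H6O2", "C6H10O5", "C5H8NO4", "H4N", "HO4P", "Fe"),
    charge = c(0, 0, -1, 1, -2, 2)))
  model <- build_symbiosis_reaction(model, comp)

  # gene -> pathway map (for expression scenarios)
  gp <- character(0)
  for (i in seq_len(nrow(model$rxns))) {
    g <- gpr_genes(parse_gpr(model$rxns$gpr[i]))
    if (length(g)) {
      gp[g] <- pathways[[model$rxns$id[i]]]
    }
  }
  attr(model, "gene_pathways") <- gp
  attr(model, "reaction_pathways") <- pathways
  # genes acting as isozymes (leaves of a top-level `or`)
  iso_genes <- character(0)
  for (g in model$rxns$gpr) {
    ast <- parse_gpr(g)
    if (!is.null(ast) && !is.null(ast$op) && ast$op == "or") {
      iso_genes <- c(iso_genes, unlist(lapply(ast$args, gpr_genes)))
    }
  }
  attr(model, "isozyme_genes") <- unique(iso_genes)

  condition <- standard_condition(include_inositol = inc_ino)
  if (check) {
    rep <- validate_model(model)
    if (!rep$ok) {
      print(rep)
      stop("generated toy model fails the validation battery")
    }
    fit <- solve_fba(apply_standard_condition(model, condition))
    if (fit$status != "optimal" || fit$objective_value <= 1e-9) {
      stop("toy model has no positive symbiotic optimum under the ",
           "standard condition (status ", fit$status, ", objective ",
           format(fit$objective_value), "); adjust the parameters")
    }
  }
  list(model = model, composition = comp, condition = condition,
       params = params)
}

#' The standard bacteroid nitrogen-fixation condition
#'
#' Exchange bounds of the microaerobic, plant-fed bacteroid: malate and
#' succinate uptake at 1.44 and 1.38 mmol/gDW/h, O2 limited to 1.26
#' mmol/gDW/h, ATP maintenance fixed at 4 mmol/gDW/h, unlimited uptake of
#' ions/cofactors (lower bounds -1000), glutamate and inositol uptakes from
#' the configurable defaults (0.18 and 0.05 mmol/gDW/h).
#'
#' @param include_inositol include the inositol uptake entry.
#' @param glutamate_uptake,inositol_uptake uptake limits, mmol/gDW/h.
#' @return a condition list with a `bounds` element (reaction id ->
#'   `c(lb, ub)`), writable with [write_condition_yaml()].
#' @export
standard_condition <- function(include_inositol = TRUE,
                               glutamate_uptake = 0.18,
                               inositol_uptake = 0.05) {
  bounds <- list(
    EX_mal__L_e = c(-1.44, 1000),
    EX_succ_e = c(-1.38, 1000),
    EX_glu__L_e = c(-glutamate_uptake, 1000),
    EX_o2_c = c(-1.26, 0),
    EX_n2_c = c(-1000, 0),
    EX_h_c = c(-1000, 1000),
    EX_h2o_c = c(-1000, 1000),
    EX_pi_c = c(-1000, 1000),
    EX_fe2_e = c(-1000, 0),
    EX_nh4_e = c(0, 1000),
    EX_ala__L_e = c(0, 1000),
    EX_asp__L_e = c(0, 1000),
    EX_co2_c = c(0, 1000),
    EX_h2_c = c(0, 1000),
    ATPM = c(4, 4)
  )
  if (include_inositol) bounds$EX_inost_e <- c(-inositol_uptake, 1000)
  list(name = "standard_nitrogen_fixation", bounds = bounds)
}

#' Apply a condition's exchange bounds to a model
#'
#' @param model a [metabolic_model()].
#' @param condition a condition list as from [standard_condition()] or
#'   [read_condition_yaml()].
#' @return the bounded model.
#' @export
apply_standard_condition <- function(model, condition = standard_condition()) {
  ids <- names(condition$bounds)
  absent <- setdiff(ids, model$rxns$id)
  if (length(absent)) {
    stop("condition names reaction(s) absent from the model: ",
         paste(absent, collapse = ", "))
  }
  for (id in ids) {
    b <- condition$bounds[[id]]
    model <- set_bounds(model, id, lb = b[1], ub = b[2])
  }
  model
}

#' Read / write a condition YAML
#' @param path file path.
#' @return a condition list.
#' @export
read_condition_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$bounds)) stop("condition YAML lacks a 'bounds' mapping")
  y$bounds <- lapply(y$bounds, as.numeric)
  y
}

#' @rdname read_condition_yaml
#' @param condition a condition list.
#' @export
write_condition_yaml <- function(condition, path) {
  yaml::write_yaml(condition, path)
  invisible(condition)
}

#' Two-condition expression scenario parameters
#'
#' @param fold_changes named per-pathway fold changes applied to the gene
#'   means of condition B relative to condition A (> 1 = up in B). The
#'   default up-regulates oxidative phosphorylation and the inositol route
#'   in B, making A the low-yield condition.
#' @param sigma lognormal noise sd (log scale) of per-gene expression.
#' @param missing_fraction fraction of genes reported as missing (-1) in
#'   both conditions.
#' @param condition_names names of the two conditions.
#' @param seed RNG seed for profile generation.
#' @return object of class `expression_scenario`.
#' @export
expression_scenario <- function(fold_changes = c(oxphos = 1.5, inositol = 1.8),
                                sigma = 0.08, missing_fraction = 0.1,
                                condition_names = c("A", "B"), seed = 42L) {
  if (any(fold_changes <= 0)) stop("fold changes must be > 0")
  if (missing_fraction < 0 || missing_fraction >= 1) {
    stop("missing_fraction must be in [0, 1)")
  }
  if (sigma < 0) stop("sigma must be >= 0")
  stopifnot(length(condition_names) == 2L)
  structure(list(fold_changes = fold_changes, sigma = sigma,
                 missing_fraction = missing_fraction,
                 condition_names = condition_names, seed = as.integer(seed)),
            class = "expression_scenario")
}

# typical expression levels (log scale, RPKM-like units). Non-planted
# pathways share a high mean so that after shared-max normalisation their
# relative activities stay near 1 and the fixed ATP maintenance remains
# satisfiable; the respiratory chain and the inositol route sit lower, so
# the scenario's fold changes genuinely move the bottleneck between
# conditions. Genes of an isozyme pair get half the pathway mean, keeping
# `or`-sum reaction scores on the same scale as single-gene reactions.
.pathway_meanlog <- c(
  tca = log(1500), central = log(1500), oxphos = log(1000),
  nitrogenase = log(1500), storage = log(1500), inositol = log(800),
  amino = log(1500), transport = log(1500), iron_transport = log(1500),
  maintenance = log(1500), other = log(1500)
)

#' Generate matched two-condition expression profiles
#'
#' Baseline expression of each gene is lognormal around its pathway's
#' typical level; condition B multiplies the means of the pathways named in
#' the scenario's fold changes. A `missing_fraction` of genes is reported
#' as `-1` (no data) in both conditions. Deterministic given the scenario
#' seed.
#'
#' @param model a toy model carrying `attr(model, "gene_pathways")`, or any
#'   model plus an explicit `gene_pathways` map.
#' @param scenario an [expression_scenario()].
#' @param gene_pathways named character vector gene -> pathway; defaults to
#'   the attribute attached by [generate_toy_bacteroid_model()].
#' @return list of two [expression_profile()]s named by the scenario's
#'   condition names.
#' @export
generate_expression_profiles <- function(model,
                                         scenario = expression_scenario(),
                                         gene_pathways = attr(model, "gene_pathways")) {
  stopifnot(inherits(scenario, "expression_scenario"))
  genes <- model$genes
  if (!length(genes)) stop("model declares no genes")
  pw <- if (is.null(gene_pathways)) rep("other", length(genes)) else {
    out <- gene_pathways[genes]
    out[is.na(out)] <- "other"
    out
  }
  mu <- .pathway_meanlog[pw]
  mu[is.na(mu)] <- .pathway_meanlog[["other"]]
  iso <- attr(model, "isozyme_genes")
  if (!is.null(iso)) mu[genes %in% iso] <- mu[genes %in% iso] - log(2)
  fold <- scenario$fold_changes[pw]
  fold[is.na(fold)] <- 1

  set.seed(scenario$seed)
  a_vals <- stats::rlnorm(length(genes), meanlog = mu, sdlog = scenario$sigma)
  b_vals <- stats::rlnorm(length(genes), meanlog = mu + log(fold),
                          sdlog = scenario$sigma)
  n_missing <- floor(scenario$missing_fraction * length(genes))
  if (n_missing > 0) {
    miss <- sample.int(length(genes), n_missing)
    a_vals[miss] <- -1
    b_vals[miss] <- -1
  }
  out <- list(
    expression_profile(scenario$condition_names[1],
                       stats::setNames(a_vals, genes)),
    expression_profile(scenario$condition_names[2],
                       stats::setNames(b_vals, genes)))
  names(out) <- scenario$condition_names
  out
}
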