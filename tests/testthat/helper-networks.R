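# Small fixture networks and independent LP oracles, built in code.

# linear chain: EX_A (uptake, lb -10) -> R1: A -> B -> EX_B (objective)
chain_model <- function(uptake = 10, gpr_r1 = "") {
  metabolic_model(
    metabolites = list(metabolite("A", formula = "CH4"),
                       metabolite("B", formula = "CH4")),
    reactions = list(
      reaction("EX_A", c(A = -1), lb = -uptake, ub = 1000, kind = "exchange"),
      reaction("R1", c(A = -1, B = 1), lb = 0, ub = 1000, gpr = gpr_r1),
      reaction("EX_B", c(B = -1), lb = 0, ub = 1000, kind = "exchange")),
    objective_id = "EX_B", id = "chain")
}

# two parallel paths with capacities 3 and 4; knocking out g_half removes P1
parallel_model <- function(cap1 = 3, cap2 = 4) {
  metabolic_model(
    metabolites = list(metabolite("A"), metabolite("B")),
    reactions = list(
      reaction("EX_A", c(A = -1), lb = -1000, ub = 1000, kind = "exchange"),
      reaction("P1", c(A = -1, B = 1), lb = 0, ub = cap1, gpr = "g_half"),
      reaction("P2", c(A = -1, B = 1), lb = 0, ub = cap2, gpr = "g_other"),
      reaction("EX_B", c(B = -1), lb = 0, ub = 1000, kind = "exchange")),
    objective_id = "EX_B", id = "parallel")
}

# Independent LP oracle: enumerate candidate vertices of
# {v : S v = 0, lb <= v <= ub} by fixing n - rank(S) variables at bounds and
# solving for the rest; returns the maximal objective among feasible points.
# Exact for networks of <= ~6 reactions.
oracle_lp_max <- function(obj, S, lb, ub, tol = 1e-9) {
  n <- ncol(S)
  r <- if (nrow(S)) qr(S)$rank else 0L
  nf <- n - r
  best <- -Inf
  best_v <- NULL
  consider <- function(v) {
    if (any(v < lb - 1e-7) || any(v > ub + 1e-7)) return()
    if (nrow(S) && max(abs(S %*% v)) > 1e-7) return()
    val <- sum(obj * v)
    if (val > best + tol) { best <<- val; best_v <<- v }
  }
  if (nf == 0L) {
    v <- rep(0, n)  # only candidate with S square of full rank
    consider(v)
  } else {
    sets <- utils::combn(n, nf, simplify = FALSE)
    for (fixed in sets) {
      free <- setdiff(seq_len(n), fixed)
      Sb <- S[, free, drop = FALSE]
      if (qr(Sb)$rank < length(free)) next
      grid <- expand.grid(rep(list(c(1L, 2L)), nf))
      for (g in seq_len(nrow(grid))) {
        v <- rep(NA_real_, n)
        v[fixed] <- ifelse(unlist(grid[g, ]) == 1L, lb[fixed], ub[fixed])
        if (any(!is.finite(v[fixed]))) next
        rhs <- -S[, fixed, drop = FALSE] %*% v[fixed]
        sol <- tryCatch(qr.solve(Sb, rhs), error = function(e) NULL)
        if (is.null(sol)) next
        v[free] <- sol
        consider(v)
      }
    }
  }
  list(objective = best, v = best_v)
}

# strong-duality certificate for max c'v s.t. S v = 0, lb <= v <= ub:
# with the returned metabolite duals y, the reduced costs d = c - S'y give
# the Lagrangian bound sum(d+ * ub) + sum(d- * lb), which equals the optimum
# iff (v, y) is an optimal primal/dual pair.
dual_gap <- function(model, fit) {
  S <- stoich_matrix(model)
  cvec <- as.numeric(model$rxns$id == model$objective_id)
  y <- -fit$duals[rownames(S)]  # duals are reported as -y
  d <- cvec - as.numeric(crossprod(S, y))
  bound <- sum(pmax(d, 0) * model$rxns$ub) + sum(pmin(d, 0) * model$rxns$lb)
  bound - fit$objective_value
}

# random small flux network with a drain objective; always feasible (v = 0)
random_small_model <- function(seed, n_mets = 3, n_rxns = 6) {
  set.seed(seed)
  S <- matrix(sample(-2:2, n_mets * n_rxns, replace = TRUE), n_mets, n_rxns)
  lb <- round(runif(n_rxns, -10, 0), 1)
  ub <- round(runif(n_rxns, 0, 10), 1)
  mets <- lapply(seq_len(n_mets), function(i) metabolite(paste0("m", i)))
  rxns <- lapply(seq_len(n_rxns), function(j) {
    st <- S[, j]
    names(st) <- paste0("m", seq_len(n_mets))
    st <- st[st != 0]
    if (!length(st)) st <- stats::setNames(1, "m1")
    reaction(paste0("r", j), st, lb = lb[j], ub = ub[j],
             kind = if (length(st) == 1L) "exchange" else "internal")
  })
  metabolic_model(mets, rxns, objective_id = "r1", id = paste0("rand", seed))
}

# cached default toy (generation + validation is not free; reuse across tests)
toy_cache <- local({
  env <- new.env()
  function() {
    if (is.null(env$toy)) env$toy <- generate_toy_bacteroid_model()
    env$toy
  }
})

toy_std_model <- function() {
  toy <- toy_cache()
  apply_standard_condition(toy$model, toy$condition)
}

# random GPR tree over gene ids g1..g4 for truth-table property tests
random_gpr_string <- function(n_genes = 4, depth = 3) {
  genes <- paste0("g", seq_len(n_genes))
  build <- function(d) {
    if (d == 0 || stats::runif(1) < 0.4) return(sample(genes, 1))
    op <- sample(c("and", "or"), 1)
    k <- sample(2:3, 1)
    parts <- vapply(seq_len(k), function(i) build(d - 1), "")
    paste0("(", paste(parts, collapse = paste0(" ", op, " ")), ")")
  }
  build(depth)
}
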