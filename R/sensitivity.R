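# Evolutionary sensitivity analysis ------------------------------------------
#
# Which expression-derived bound changes explain the yield gap between two
# conditions? Starting from the low-yield condition's bounds, reactions are
# picked uniformly at random and their bounds moved a random fraction of
# the way toward the high-yield condition's bounds; a move is kept only if
# the optimal symbiotic objective strictly improves. Reactions that are
# adopted in nearly every randomized trajectory are the determinants of the
# phenotype difference.

#' Randomized greedy bound-adoption analysis between two conditions
#'
#' @param model the base [metabolic_model()] (reaction set and objective).
#' @param bounds_low,bounds_high `condition_bounds` data.frames for the
#'   low- and high-yield conditions (see [eflux_bounds()]).
#' @param n_runs number of independent randomized trajectories (the
#'   full-scale analysis uses 10,000; scaled-down runs are appropriate for
#'   testing).
#' @param seed master seed; run `k` uses `seed + k - 1`, so trajectories
#'   are reproducible independently of one another.
#' @param stall_limit a run stops after this many consecutive rejected
#'   proposals; default `50 *` the number of reactions whose bounds differ
#'   between the conditions.
#' @param move `"interpolate"` draws `lambda ~ U(0,1)` and moves both
#'   bounds `lambda` of the way toward the high condition;  `"replace"`
#'   adopts the high-condition bounds outright.
#' @param improve_tol minimum objective increase for a move to be kept;
#'   also the tolerance for declaring the high-condition optimum reached.
#' @return object of class `sensitivity_runs`: list of runs, each with
#'   `seed`, `steps` (data.frame: `iteration`, `reaction`, `lb`, `ub`,
#'   `accepted`, `objective`), `final_objective`, `iterations`,
#'   `converged`; attributes `low_optimum`, `high_optimum`.
#' @export
evolutionary_sensitivity <- function(model, bounds_low, bounds_high,
                                     n_runs = 10000L, seed = 1L,
                                     stall_limit = NULL,
                                     move = c("interpolate", "replace"),
                                     improve_tol = 1e-6) {
  move <- match.arg(move)
  if (n_runs < 1L) stop("n_runs must be >= 1")
  low <- build_condition_model(model, bounds_low)
  high <- build_condition_model(model, bounds_high)
  S <- stoich_matrix(model)
  obj <- as.numeric(model$rxns$id == model$objective_id)
  b0 <- rep(0, nrow(S))
  fba_quick <- function(lb, ub) {
    r <- solve_lp(obj, S, b0, "=", lb, ub, maximize = TRUE)
    if (r$status != "optimal") -Inf else r$objective
  }
  low_opt <- fba_quick(low$rxns$lb, low$rxns$ub)
  high_opt <- fba_quick(high$rxns$lb, high$rxns$ub)
  if (!is.finite(low_opt) || !is.finite(high_opt)) {
    stop("low/high condition model is infeasible")
  }
  if (low_opt > high_opt + improve_tol) {
    stop("low-condition optimum exceeds high-condition optimum; ",
         "swap the conditions")
  }
  lb_lo <- low$rxns$lb; ub_lo <- low$rxns$ub
  lb_hi <- high$rxns$lb; ub_hi <- high$rxns$ub
  differ <- which(abs(lb_lo - lb_hi) > 1e-9 | abs(ub_lo - ub_hi) > 1e-9)
  if (is.null(stall_limit)) stall_limit <- 50L * max(1L, length(differ))
  if (stall_limit < 1L) stop("stall_limit must be >= 1")
  rids <- model$rxns$id

  runs <- vector("list", n_runs)
  for (k in seq_len(n_runs)) {
    set.seed(seed + k - 1L)
    lb <- lb_lo; ub <- ub_lo
    cur <- low_opt
    it <- 0L; stall <- 0L
    st_it <- integer(0); st_rx <- character(0)
    st_lb <- st_ub <- st_obj <- numeric(0); st_acc <- logical(0)
    converged <- cur >= high_opt - improve_tol
    while (!converged && length(differ) && stall < stall_limit) {
      it <- it + 1L
      j <- differ[sample.int(length(differ), 1L)]
      lam <- if (move == "interpolate") stats::runif(1L) else 1
      plb <- lb[j] + lam * (lb_hi[j] - lb[j])
      pub <- ub[j] + lam * (ub_hi[j] - ub[j])
      old_lb <- lb[j]; old_ub <- ub[j]
      lb[j] <- plb; ub[j] <- pub
      cand <- fba_quick(lb, ub)
      acc <- is.finite(cand) && cand > cur + improve_tol
      if (acc) {
        cur <- cand; stall <- 0L
      } else {
        lb[j] <- old_lb; ub[j] <- old_ub
        stall <- stall + 1L
      }
      st_it <- c(st_it, it); st_rx <- c(st_rx, rids[j])
      st_lb <- c(st_lb, plb); st_ub <- c(st_ub, pub)
      st_acc <- c(st_acc, acc); st_obj <- c(st_obj, cur)
      converged <- cur >= high_opt - improve_tol
    }
    runs[[k]] <- list(
      seed = seed + k - 1L,
      steps = data.frame(iteration = st_it, reaction = st_rx, lb = st_lb,
                         ub = st_ub, accepted = st_acc, objective = st_obj,
                         stringsAsFactors = FALSE),
      final_objective = cur, iterations = it, converged = converged)
  }
  structure(runs, class = "sensitivity_runs",
            low_optimum = low_opt, high_optimum = high_opt,
            reaction_ids = rids[differ], seed = seed, move = move)
}

#' @export
print.sensitivity_runs <- function(x, ...) {
  fin <- vapply(x, `[[`, 0, "final_objective")
  cat("Evolutionary sensitivity analysis: ", length(x), " runs\n", sep = "")
  cat("  low/high optima: ", format(attr(x, "low_optimum"), digits = 6),
      " / ", format(attr(x, "high_optimum"), digits = 6), "\n", sep = "")
  cat("  converged runs:  ", sum(vapply(x, `[[`, NA, "converged")),
      "\n", sep = "")
  cat("  final objective: median ", format(stats::median(fin), digits = 6),
      "\n", sep = "")
  invisible(x)
}

#' Summarize determinant reactions across sensitivity runs
#'
#' A reaction's acceptance frequency is the fraction of runs in which at
#' least one proposal for it was accepted; reactions at or above
#' `frequency_threshold` are flagged determinants. `mean_gain` is the mean
#' objective increment credited to the reaction's accepted moves.
#'
#' @param runs a [evolutionary_sensitivity()] result.
#' @param frequency_threshold determinant cutoff (default 0.9).
#' @return object of class `determinant_report`: data.frame with columns
#'   `reaction`, `frequency`, `mean_gain`, `determinant`, ordered by
#'   decreasing frequency.
#' @export
summarize_determinants <- function(runs, frequency_threshold = 0.9) {
  stopifnot(inherits(runs, "sensitivity_runs"), length(runs) >= 1L)
  rids <- attr(runs, "reaction_ids")
  hit <- stats::setNames(numeric(length(rids)), rids)
  gain_sum <- stats::setNames(numeric(length(rids)), rids)
  gain_n <- stats::setNames(numeric(length(rids)), rids)
  for (run in runs) {
    st <- run$steps
    if (!nrow(st)) next
    acc <- st[st$accepted, , drop = FALSE]
    if (!nrow(acc)) next
    hit[unique(acc$reaction)] <- hit[unique(acc$reaction)] + 1
    prev <- c(attr(runs, "low_optimum"),
              st$objective[-nrow(st)])[which(st$accepted)]
    inc <- acc$objective - prev
    for (i in seq_len(nrow(acc))) {
      r <- acc$reaction[i]
      gain_sum[r] <- gain_sum[r] + inc[i]
      gain_n[r] <- gain_n[r] + 1
    }
  }
  freq <- hit / length(runs)
  out <- data.frame(reaction = rids, frequency = unname(freq),
                    mean_gain = unname(ifelse(gain_n > 0, gain_sum / gain_n, 0)),
                    determinant = unname(freq >= frequency_threshold),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$reaction), ]
  rownames(out) <- NULL
  attr(out, "frequency_threshold") <- frequency_threshold
  attr(out, "n_runs") <- length(runs)
  class(out) <- c("determinant_report", "data.frame")
  out
}

#' Serialise sensitivity runs as JSON-lines (one run per line)
#'
#' @param runs a `sensitivity_runs` object.
#' @param path output file.
#' @export
write_sensitivity_jsonl <- function(runs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (run in runs) {
    writeLines(jsonlite::toJSON(run, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(runs)
}

#' @rdname summarize_determinants
#' @param report a `determinant_report`.
#' @param path output TSV path.
#' @export
write_determinant_tsv <- function(report, path) {
  utils::write.table(
    data.frame(reaction_id = report$reaction, frequency = report$frequency,
               mean_gain = report$mean_gain),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(report)
}
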