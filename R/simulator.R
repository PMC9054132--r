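# Agent-based evolution of karyotype populations under chromosomal
# instability. Cells carry 46-arm integer karyotypes; divisions mis-segregate
# whole-chromosome copies (optionally breaking into single arms), viability
# culls karyotypes outside [copy_min, copy_max], and population size is
# limited either by a pseudo-Moran random halving at a cap (exponential
# growth) or by Wright-Fisher re-initiation at constant size.

#' Simulation parameters
#'
#' Collects every knob of the agent-based model. Probabilities are per
#' chromosome copy per division.
#'
#' @param p_misseg Probability a chromosome copy mis-segregates at division.
#' @param p_break Probability a mis-segregated copy breaks so that only one
#'   randomly chosen arm transfers (a reciprocal arm-level alteration).
#' @param S Selection scaling exponent (>= 0); fitness acts as \eqn{F^S}.
#' @param selection_model \code{"abundance"}, \code{"driver"},
#'   \code{"hybrid"} or \code{"neutral"}.
#' @param growth_model \code{"pseudo_moran"} (exponential growth, random
#'   halving at \code{pop_cap}) or \code{"wright_fisher"} (constant size,
#'   per-arm marginal resampling each step).
#' @param founder_ploidy Integer founder ploidy (2 or 4).
#' @param n_founders Founder cells; defaults to 100 (pseudo-Moran) or 4500
#'   (Wright-Fisher).
#' @param n_steps Number of discrete time steps (default 100).
#' @param pop_cap Pseudo-Moran census cap (default 3000): when the living
#'   population reaches the cap a uniformly random half is deleted.
#' @param copy_min,copy_max Viability bounds on every arm copy number
#'   (defaults 1 and 6); outside them the cell dies.
#' @param seed RNG seed (integer) or \code{NULL} to leave the RNG state alone.
#' @return A list of class \code{"sim_params"}.
#' @export
sim_params <- function(p_misseg = 0.001, p_break = 0, S = 1,
                       selection_model = c("abundance", "driver", "hybrid",
                                           "neutral"),
                       growth_model = c("pseudo_moran", "wright_fisher"),
                       founder_ploidy = 2L,
                       n_founders = NULL, n_steps = 100L, pop_cap = 3000L,
                       copy_min = 1L, copy_max = 6L, seed = NULL) {
  selection_model <- match.arg(selection_model)
  growth_model <- match.arg(growth_model)
  if (is.null(n_founders))
    n_founders <- if (growth_model == "wright_fisher") 4500L else 100L
  p <- list(p_misseg = p_misseg, p_break = p_break, S = S,
            selection_model = selection_model, growth_model = growth_model,
            founder_ploidy = as.integer(founder_ploidy),
            n_founders = as.integer(n_founders),
            n_steps = as.integer(n_steps), pop_cap = as.integer(pop_cap),
            copy_min = as.integer(copy_min), copy_max = as.integer(copy_max),
            seed = seed)
  stopifnot(p$p_misseg >= 0, p$p_misseg <= 1, p$p_break >= 0, p$p_break <= 1,
            p$S >= 0, p$n_steps >= 1, p$pop_cap >= 2, p$n_founders >= 1,
            p$copy_min >= 1, p$copy_min <= p$copy_max)
  class(p) <- "sim_params"
  p
}

#' Karyotype viability
#'
#' A cell is viable iff every arm copy number lies within
#' \code{[copy_min, copy_max]} (defaults 1 and 6): nullisomy of any arm or
#' more than six copies is lethal.
#'
#' @param karyotype Integer vector of 46 arm copies.
#' @param copy_min,copy_max Inclusive viability bounds.
#' @return Logical scalar.
#' @export
check_viability <- function(karyotype, copy_min = 1L, copy_max = 6L) {
  all(karyotype >= copy_min & karyotype <= copy_max)
}

# rows of pop (cells x 46) within bounds
viable_rows <- function(pop, copy_min, copy_max) {
  rowSums(pop < copy_min | pop > copy_max) == 0L
}

# per-chromosome trial counts: a chromosome's copy count is max(p-arm, q-arm)
# once arms have diverged after breaks (the trial unit is the whole copy)
.p_idx <- seq(1L, 45L, by = 2L)
.q_idx <- seq(2L, 46L, by = 2L)
chrom_trials <- function(karyotype) {
  pmax(karyotype[.p_idx], karyotype[.q_idx])
}

#' Divide a cell with probabilistic chromosome mis-segregation
#'
#' Each whole-chromosome copy (23 chromosomes; 46 copies in a diploid)
#' independently mis-segregates with probability \code{p_misseg}. On an
#' event, with probability \code{p_break} the copy breaks and only one
#' randomly chosen arm transfers (a reciprocal arm-level alteration);
#' otherwise both arms of the copy transfer together. The gaining daughter
#' is chosen equiprobably and independently per event. Material is conserved:
#' arm-wise, \code{daughter_a + daughter_b == 2 * parent}.
#'
#' When p- and q-arm copy numbers of a chromosome have diverged after earlier
#' breaks, the number of copy trials is the maximum of the two arm counts and
#' a transfer moves only the arms the copy actually carries.
#'
#' @param parent Integer vector of 46 arm copies.
#' @param p_misseg,p_break Event probabilities in [0, 1].
#' @return A list of class \code{"division_outcome"}: \code{daughter_a},
#'   \code{daughter_b} (integer vectors), \code{n_misseg_events},
#'   \code{n_break_events}.
#' @export
#' @examples
#' d <- divide_with_missegregation(rep(2L, 46), 0.05, 0)
#' all(d$daughter_a + d$daughter_b == 4L)
divide_with_missegregation <- function(parent, p_misseg, p_break = 0) {
  check_karyotype(parent)
  stopifnot(p_misseg >= 0, p_misseg <= 1, p_break >= 0, p_break <= 1)
  trials <- chrom_trials(parent)
  total <- sum(trials)
  n_events <- stats::rbinom(1L, total, p_misseg)
  delta <- integer(46L)
  n_break <- 0L
  if (n_events > 0L) {
    trial_chrom <- rep.int(seq_len(23L), trials)
    trial_copy <- sequence(trials)
    ev <- sample.int(total, n_events)
    np <- parent[.p_idx]; nq <- parent[.q_idx]
    for (e in ev) {
      ch <- trial_chrom[e]; cp <- trial_copy[e]
      dir <- if (stats::runif(1) < 0.5) 1L else -1L
      has_p <- cp <= np[ch]; has_q <- cp <= nq[ch]
      if (stats::runif(1) < p_break) {
        n_break <- n_break + 1L
        arms <- c(if (has_p) 2L * ch - 1L, if (has_q) 2L * ch)
        a <- if (length(arms) == 1L) arms else arms[sample.int(2L, 1L)]
        delta[a] <- delta[a] + dir
      } else {
        if (has_p) delta[2L * ch - 1L] <- delta[2L * ch - 1L] + dir
        if (has_q) delta[2L * ch] <- delta[2L * ch] + dir
      }
    }
  }
  structure(list(daughter_a = parent + delta, daughter_b = parent - delta,
                 n_misseg_events = n_events, n_break_events = n_break),
            class = "division_outcome")
}

# divide all rows of pop at once; returns matrix with 2 daughters per parent
# (rows interleaved: a_1, b_1, a_2, b_2, ...) plus parent index of each row
divide_population <- function(pop, p_misseg, p_break) {
  n <- nrow(pop)
  trials <- matrix(pmax(pop[, .p_idx, drop = FALSE],
                        pop[, .q_idx, drop = FALSE]), nrow = n)
  totals <- rowSums(trials)
  n_events <- stats::rbinom(n, totals, p_misseg)
  out <- matrix(0L, nrow = 2L * n, ncol = 46L)
  ai <- seq(1L, 2L * n, by = 2L)
  out[ai, ] <- pop
  out[ai + 1L, ] <- pop
  hit <- which(n_events > 0L)
  for (i in hit) {
    d <- divide_cell_events(pop[i, ], trials[i, ], n_events[i], p_break)
    out[2L * i - 1L, ] <- d$a
    out[2L * i, ] <- d$b
  }
  list(daughters = out, parent = rep(seq_len(n), each = 2L),
       n_events = n_events)
}

# apply a known number of mis-segregation events to one parent
divide_cell_events <- function(parent, trials, n_events, p_break) {
  total <- sum(trials)
  trial_chrom <- rep.int(seq_len(23L), trials)
  trial_copy <- sequence(trials)
  ev <- if (n_events == total) seq_len(total) else
    sample.int(total, n_events)
  np <- parent[.p_idx]; nq <- parent[.q_idx]
  delta <- integer(46L)
  for (e in ev) {
    ch <- trial_chrom[e]; cp <- trial_copy[e]
    dir <- if (stats::runif(1) < 0.5) 1L else -1L
    has_p <- cp <= np[ch]; has_q <- cp <= nq[ch]
    if (stats::runif(1) < p_break) {
      arms <- c(if (has_p) 2L * ch - 1L, if (has_q) 2L * ch)
      a <- if (length(arms) == 1L) arms else arms[sample.int(2L, 1L)]
      delta[a] <- delta[a] + dir
    } else {
      if (has_p) delta[2L * ch - 1L] <- delta[2L * ch - 1L] + dir
      if (has_q) delta[2L * ch] <- delta[2L * ch] + dir
    }
  }
  list(a = parent + delta, b = parent - delta)
}

#' Probability of death under the Wright-Fisher fitness rule
#'
#' In the constant-size regime every cell divides each step and death is
#' fitness-dependent: a cell dies iff \eqn{1/(F^S + 0.001) > R} with
#' \eqn{R \sim U[0, 5]}. A euploid cell (\eqn{F = 1}) therefore has baseline
#' death probability \eqn{(1/1.001)/5 \approx 0.1998}, about 20%; death
#' probability vanishes as \eqn{F^S \to \infty} and is 1 for \eqn{F \le 0}.
#'
#' @param F_val Cellular fitness F.
#' @param S Selection scaling exponent.
#' @return Death probability in [0, 1].
#' @export
#' @examples
#' wf_death_prob(1, 1)  # ~0.1998
wf_death_prob <- function(F_val, S = 1) {
  fm <- scale_fitness(F_val, S)
  pmin(1, (1 / (fm + 0.001)) / 5)
}

# one pseudo-Moran step; state: list(pop, lineage, next_id)
step_pseudo_moran <- function(state, params, scores) {
  pop <- state$pop
  n_start <- nrow(pop)
  xbar <- mean_ploidy(pop)
  F_all <- population_fitness(pop, params$selection_model, xbar, scores)
  fm <- scale_fitness(F_all, params$S)
  keep <- viable_rows(pop, params$copy_min, params$copy_max)
  pop <- pop[keep, , drop = FALSE]
  lin <- state$lineage[keep]
  fm <- fm[keep]
  F_keep <- F_all[keep]
  n_cull <- nrow(pop)
  if (n_cull == 0L)
    return(list(state = state, extinct = TRUE,
                rec = step_record(state$step + 1L, n_start, 0L, 0L, 0L, 0L,
                                  xbar, NA_real_, NA_real_)))
  if (n_cull >= params$pop_cap) {
    keep2 <- sort(sample.int(n_cull, n_cull - n_cull %/% 2L))
    pop <- pop[keep2, , drop = FALSE]
    lin <- lin[keep2]
    fm <- fm[keep2]
    F_keep <- F_keep[keep2]
  }
  n_cap <- nrow(pop)
  dividing <- fm > stats::runif(n_cap, 0, 2)
  n_div <- sum(dividing)
  if (n_div > 0L) {
    div <- divide_population(pop[dividing, , drop = FALSE],
                             params$p_misseg, params$p_break)
    new_ids <- state$next_id + seq_len(2L * n_div) - 1L
    pop <- rbind(pop[!dividing, , drop = FALSE], div$daughters)
    lin <- c(lin[!dividing], new_ids)
    state$next_id <- state$next_id + 2L * n_div
  }
  state$pop <- pop
  state$lineage <- lin
  state$step <- state$step + 1L
  list(state = state, extinct = FALSE,
       rec = step_record(state$step, n_start, n_cull, n_cap, n_div,
                         nrow(pop), xbar, mean(F_keep), mean(fm)))
}

# one Wright-Fisher step: divide all, cull, fitness-dependent death,
# re-initiate n_founders cells from per-arm marginals of the survivors
step_wright_fisher <- function(state, params, scores) {
  pop <- state$pop
  n_start <- nrow(pop)
  div <- divide_population(pop, params$p_misseg, params$p_break)
  pop <- div$daughters
  xbar <- mean_ploidy(pop)
  F_all <- population_fitness(pop, params$selection_model, xbar, scores)
  keep <- viable_rows(pop, params$copy_min, params$copy_max)
  pop <- pop[keep, , drop = FALSE]
  F_all <- F_all[keep]
  n_cull <- nrow(pop)
  if (n_cull > 0L) {
    dies <- wf_death_prob(F_all, params$S) * 5 > stats::runif(n_cull, 0, 5)
    pop <- pop[!dies, , drop = FALSE]
    F_surv <- F_all[!dies]
  }
  n_surv <- nrow(pop)
  if (n_surv == 0L)
    return(list(state = state, extinct = TRUE,
                rec = step_record(state$step + 1L, n_start, n_cull, 0L, 0L,
                                  0L, xbar, NA_real_, NA_real_)))
  # re-initiation: each arm's copy number drawn independently from the
  # survivors' stored marginal distribution for that arm
  nf <- params$n_founders
  newpop <- matrix(0L, nrow = nf, ncol = 46L)
  for (a in seq_len(46L))
    newpop[, a] <- pop[sample.int(n_surv, nf, replace = TRUE), a]
  state$pop <- newpop
  state$lineage <- state$next_id + seq_len(nf) - 1L
  state$next_id <- state$next_id + nf
  state$step <- state$step + 1L
  list(state = state, extinct = FALSE,
       rec = step_record(state$step, n_start, n_cull, n_surv, n_start, nf,
                         xbar, mean(F_surv), mean(scale_fitness(F_surv,
                                                                params$S))))
}

step_record <- function(step, n_start, n_after_cull, n_after_limit,
                        n_divisions, n_end, mean_ploidy, mean_F, mean_FM) {
  data.frame(step = step, n_start = n_start, n_after_cull = n_after_cull,
             n_after_limit = n_after_limit, n_divisions = n_divisions,
             n_end = n_end, mean_ploidy = mean_ploidy, mean_F = mean_F,
             mean_FM = mean_FM)
}

#' Run an agent-based CIN simulation
#'
#' Initializes \code{n_founders} euploid cells at \code{founder_ploidy} and
#' iterates the chosen population-dynamics step \code{n_steps} times:
#' \describe{
#'   \item{pseudo_moran}{per step: mean ploidy and scaled fitness
#'     \eqn{F_M = F^S} are computed for every cell; non-viable cells are
#'     culled; if the census reaches \code{pop_cap} a uniformly random half
#'     is deleted; each surviving cell divides iff \eqn{F_M > R},
#'     \eqn{R \sim U[0, 2]} (euploid cells divide with probability 0.5);
#'     dividing cells produce reciprocal daughters via
#'     [divide_with_missegregation()].}
#'   \item{wright_fisher}{per step: every cell divides regardless of fitness;
#'     non-viable daughters are culled; cells die with the fitness-dependent
#'     probability of [wf_death_prob()]; the survivors' per-arm copy-number
#'     marginals are stored and a fresh population of \code{n_founders}
#'     cells is drawn from them, arm by arm.}
#' }
#' Extinction (no living cell) terminates the run with a flagged record
#' rather than an error. Identical parameters and seed give identical
#' trajectories.
#'
#' @param params A [sim_params()] object.
#' @param snapshot_steps Integer vector of steps at which to store the full
#'   population karyotype matrix (end-of-step census); step 0 is the founder
#'   population.
#' @param scores Arm-score table (defaults to the embedded one).
#' @return An object of class \code{"cin_sim"}: list with \code{params},
#'   \code{records} (one row per executed step), \code{population} (final
#'   cells-by-46 integer matrix, arm ids as column names), \code{lineage}
#'   (final lineage ids), \code{snapshots} (named list of matrices),
#'   \code{extinct} flag.
#' @seealso [sample_cells()], [summarize_population()]
#' @export
#' @examples
#' sim <- run_simulation(sim_params(p_misseg = 0, n_steps = 5, seed = 1))
#' sim$records$n_end
run_simulation <- function(params, snapshot_steps = integer(),
                           scores = load_arm_scores()) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  pop <- matrix(as.integer(params$founder_ploidy), nrow = params$n_founders,
                ncol = 46L)
  state <- list(pop = pop, lineage = seq_len(params$n_founders),
                next_id = params$n_founders + 1L, step = 0L)
  stepper <- switch(params$growth_model,
                    pseudo_moran = step_pseudo_moran,
                    wright_fisher = step_wright_fisher)
  records <- vector("list", params$n_steps)
  snapshots <- list()
  # exported censuses contain living cells only: daughters born in the
  # current step whose karyotype already violates the viability bounds are
  # culled at the start of the next step and are never observed alive
  living <- function(pop) named_pop(pop[viable_rows(pop, params$copy_min,
                                                    params$copy_max), ,
                                        drop = FALSE])
  if (0L %in% snapshot_steps) snapshots[["0"]] <- living(state$pop)
  extinct <- FALSE
  for (i in seq_len(params$n_steps)) {
    res <- stepper(state, params, scores)
    state <- res$state
    records[[i]] <- res$rec
    if (res$extinct) { extinct <- TRUE; break }
    if (i %in% snapshot_steps) snapshots[[as.character(i)]] <-
        living(state$pop)
  }
  records <- do.call(rbind, records[!vapply(records, is.null, logical(1))])
  records$extinct <- FALSE
  if (extinct) records$extinct[nrow(records)] <- TRUE
  final <- if (extinct) named_pop(state$pop[integer(), , drop = FALSE]) else
    living(state$pop)
  structure(list(params = params, records = records,
                 population = final, lineage = state$lineage,
                 snapshots = snapshots, extinct = extinct),
            class = "cin_sim")
}

named_pop <- function(pop) {
  colnames(pop) <- .arm_ids
  pop
}

#' Sample cells from a simulated population
#'
#' Uniform sampling without replacement of rows (cells) from a simulation's
#' final population or any karyotype matrix.
#'
#' @param x A \code{cin_sim} object or a cells-by-features matrix.
#' @param n Number of cells to draw; must not exceed the population size.
#' @return Integer matrix of n sampled karyotypes.
#' @export
sample_cells <- function(x, n) {
  pop <- if (inherits(x, "cin_sim")) x$population else x
  if (n > nrow(pop))
    stop("cannot sample ", n, " cells from a population of ", nrow(pop),
         call. = FALSE)
  pop[sort(sample.int(nrow(pop), n)), , drop = FALSE]
}

#' @export
print.cin_sim <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "Agent-based CIN simulation (%s growth, %s selection)\n",
    p$growth_model, p$selection_model))
  cat(sprintf("  P_misseg = %g, P_break = %g, S = %g, founder ploidy %d\n",
              p$p_misseg, p$p_break, p$S, p$founder_ploidy))
  cat(sprintf("  %d step(s) run; final population %d cell(s)%s\n",
              nrow(x$records), nrow(x$population),
              if (x$extinct) " [EXTINCT]" else ""))
  invisible(x)
}

#' @export
summary.cin_sim <- function(object, ...) {
  r <- object$records
  out <- list(params = object$params,
              n_steps = nrow(r),
              final_size = nrow(object$population),
              extinct = object$extinct,
              final_mean_ploidy = mean_ploidy(object$population),
              mean_F_last = r$mean_F[nrow(r)])
  class(out) <- "summary.cin_sim"
  out
}

#' @export
print.summary.cin_sim <- function(x, ...) {
  cat(sprintf("CIN simulation: %d steps, final size %d%s\n", x$n_steps,
              x$final_size, if (x$extinct) " [EXTINCT]" else ""))
  cat(sprintf("  final mean ploidy %.3f, last-step mean fitness %.4f\n",
              x$final_mean_ploidy, x$mean_F_last))
  invisible(x)
}

#' @export
plot.cin_sim <- function(x, which = c("size", "ploidy"), ...) {
  which <- match.arg(which)
  r <- x$records
  if (which == "size") {
    graphics::plot(r$step, r$n_end, type = "l", xlab = "step",
                   ylab = "population size", ...)
  } else {
    graphics::plot(r$step, r$mean_ploidy, type = "l", xlab = "step",
                   ylab = "mean ploidy", ...)
  }
  invisible(x)
}
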