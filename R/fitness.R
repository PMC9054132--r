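# Cellular fitness under the four karyotype-selection models.
#
# A karyotype is an integer vector of 46 arm copy numbers in the canonical
# arm order. Per-arm contextual fitness scores (CFS) are summed to a cellular
# fitness F, then scaled to F_M = F^S by the selection exponent S.

.selection_models <- c("abundance", "driver", "hybrid", "neutral")

check_karyotype <- function(k) {
  if (length(k) != 46L || any(is.na(k)) || any(k < 0))
    stop("a karyotype is a vector of 46 non-negative arm copy numbers",
         call. = FALSE)
  invisible(k)
}

#' Mean ploidy of a cell population
#'
#' Ploidy of one cell is its total arm copy number divided by 46 (equivalently
#' the mean copy number over arms); the population mean ploidy
#' \eqn{\bar{X}_p} averages this over cells. It is the reference against which
#' the abundance-model penalty and the driver-density normalization are
#' computed, and is re-evaluated from the living population at each
#' simulation step.
#'
#' @param karyotypes A matrix of cells (rows) by copy-number features
#'   (columns), or a single karyotype vector, or a list of karyotype vectors.
#' @return Scalar mean ploidy.
#' @export
#' @examples
#' mean_ploidy(matrix(2L, 10, 46))  # 2
mean_ploidy <- function(karyotypes) {
  if (is.list(karyotypes)) karyotypes <- do.call(rbind, karyotypes)
  if (is.null(dim(karyotypes))) karyotypes <- matrix(karyotypes, nrow = 1)
  if (nrow(karyotypes) == 0L)
    stop("mean ploidy of an empty population is undefined", call. = FALSE)
  mean(rowMeans(karyotypes))
}

#' Fitness of a karyotype under a selection model
#'
#' Computes the per-arm contextual fitness scores (CFS), the cellular fitness
#' \eqn{F} (their sum) and the selection-scaled fitness \eqn{F_M = F^S} for a
#' single karyotype:
#' \describe{
#'   \item{abundance}{\eqn{CFS_c = f_c (1 - |n_c - \bar{X}_p| / \bar{X}_p)}:
#'     fitness declines as an arm diverges from the population mean ploidy,
#'     weighted by the arm's gene abundance (stabilizing selection).}
#'   \item{driver}{\eqn{CFS_c = n_c \, TOE_c / \bar{X}_p}: arms carrying net
#'     oncogene/essential-gene excess reward gains, tumor-suppressor-rich
#'     arms reward losses (directional selection).}
#'   \item{hybrid}{the arm-wise average of the two, so
#'     \eqn{F_{hybrid} = (F_{GA} + F_{TOE})/2}.}
#'   \item{neutral}{\eqn{F = 1} for every karyotype.}
#' }
#' A euploid cell at the population mean ploidy has \eqn{F = 1} under every
#' model. \eqn{S = 0} removes selection (\eqn{F_M = 1}); large \eqn{S}
#' amplifies fitness differences. Negative or zero \eqn{F} (possible under
#' the driver and hybrid models for extreme karyotypes, since TOE scores can
#' be negative) yields \eqn{F_M = 0}, i.e. a cell that never divides;
#' \eqn{F^S} is not defined for negative bases and real exponents.
#'
#' @param karyotype Integer vector of 46 arm copy numbers.
#' @param model One of \code{"abundance"}, \code{"driver"}, \code{"hybrid"},
#'   \code{"neutral"}.
#' @param mean_ploidy Population mean ploidy \eqn{\bar{X}_p} (> 0).
#' @param scores An \code{arm_scores} table; defaults to the embedded one.
#' @param S Selection scaling exponent (>= 0).
#' @return A list of class \code{"fitness_result"} with elements
#'   \code{per_arm_cfs} (length 46), \code{F}, \code{F_M}, \code{model},
#'   \code{S}.
#' @export
#' @examples
#' k <- rep(2L, 46)
#' karyotype_fitness(k, "abundance", 2)$F  # 1
#' k[1:2] <- 3L  # trisomy 1 (both arms)
#' round(karyotype_fitness(k, "abundance", 2, S = 50)$F_M, 3)
karyotype_fitness <- function(karyotype, model = .selection_models,
                              mean_ploidy, scores = load_arm_scores(),
                              S = 1) {
  model <- match.arg(model)
  check_karyotype(karyotype)
  if (!is.numeric(mean_ploidy) || mean_ploidy <= 0)
    stop("mean_ploidy must be positive", call. = FALSE)
  if (S < 0) stop("S must be >= 0", call. = FALSE)
  cfs <- switch(model,
    abundance = scores$gene_abundance *
      (1 - abs(karyotype - mean_ploidy) / mean_ploidy),
    driver = karyotype * scores$driver_density / mean_ploidy,
    hybrid = (scores$gene_abundance *
                (1 - abs(karyotype - mean_ploidy) / mean_ploidy) +
              karyotype * scores$driver_density / mean_ploidy) / 2,
    neutral = NULL)
  F_val <- if (model == "neutral") 1 else sum(cfs)
  structure(list(per_arm_cfs = cfs, F = F_val,
                 F_M = scale_fitness(F_val, S), model = model, S = S),
            class = "fitness_result")
}

# F_M = F^S with the F <= 0 guard; S = 0 gives 1 for any F > 0
scale_fitness <- function(F_val, S) {
  ifelse(F_val > 0, F_val^S, 0)
}

# vectorized fitness over a population matrix (cells x 46); returns F vector
population_fitness <- function(pop, model, xbar, scores) {
  if (model == "neutral") return(rep(1, nrow(pop)))
  ga <- function() sum(scores$gene_abundance) -
    as.vector(abs(pop - xbar) %*% scores$gene_abundance) / xbar
  toe <- function() as.vector(pop %*% scores$driver_density) / xbar
  switch(model,
    abundance = ga(),
    driver = toe(),
    hybrid = (ga() + toe()) / 2)
}

#' @export
print.fitness_result <- function(x, ...) {
  cat(sprintf("Karyotype fitness (%s model): F = %.6f, F_M = F^%g = %.6f\n",
              x$model, x$F, x$S, x$F_M))
  invisible(x)
}
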