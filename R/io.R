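# Copy-number matrix I/O and the synthetic fixture generator emulating the
# experimental inputs: an acute mis-segregation experiment (one aberrant
# division from a near-diploid modal karyotype), steady-state simulated
# populations, and clonal controls.

feature_level_of <- function(ids) {
  if (all(grepl("^([0-9]+|X)[pq]$", ids))) return("arm")
  if (all(grepl("^(X|[0-9]+)$", ids))) return("chromosome")
  NA_character_
}

#' Read a single-cell copy-number matrix from delimited text
#'
#' Expects a header row of feature identifiers (chromosome arms such as
#' \code{1p, 1q, ...} or bare chromosome names \code{1..22, X}) and one row
#' per cell with the cell identifier in the first column. The delimiter is
#' chosen by extension (\code{.csv} comma, otherwise tab). Entries must be
#' non-negative integers with no missing values.
#'
#' @param path File path.
#' @return Integer matrix (cells x features) with cell ids as row names,
#'   feature ids as column names and the detected level in
#'   \code{attr(, "feature_level")} (\code{"arm"} or \code{"chromosome"}).
#' @export
read_copy_number_matrix <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1L]])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  level <- feature_level_of(colnames(vals))
  if (is.na(level))
    stop("unrecognized feature headers (need arm ids like '1p' or ",
         "chromosome names like '1', 'X'): ",
         paste(utils::head(colnames(vals), 3), collapse = ", "),
         call. = FALSE)
  if (any(is.na(vals)))
    stop("missing values in copy-number matrix", call. = FALSE)
  bad <- which(vals < 0 | vals != round(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf(
      "invalid copy number for cell '%s', feature '%s': %s",
      ids[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]],
      vals[bad[1L, , drop = FALSE]]), call. = FALSE)
  out <- matrix(as.integer(vals), nrow = nrow(vals),
                dimnames = list(ids, colnames(vals)))
  attr(out, "feature_level") <- level
  out
}

#' Write a copy-number matrix as delimited text
#'
#' @param mat Integer matrix, cells x features, with dimnames.
#' @param path Output path; \code{.csv} writes comma-separated, anything
#'   else tab-separated.
#' @return \code{path}, invisibly.
#' @export
write_copy_number_matrix <- function(mat, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  if (is.null(rownames(mat))) rownames(mat) <- paste0("cell", seq_len(nrow(mat)))
  df <- data.frame(cell_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' A near-diploid modal karyotype with 44 chromosomes (synthetic)
#'
#' A synthetic stand-in for a sub-diploid breast-cancer-line modal karyotype
#' (44 total chromosomes): chromosomes 1--21 at two copies, chromosomes 22
#' and X at one. Used as the default reference of the acute fixture.
#'
#' @return Named integer vector of 23 chromosome copy numbers summing to 44.
#' @export
modal_karyotype_44 <- function() {
  k <- c(rep(2L, 21L), 1L, 1L)
  names(k) <- c(as.character(1:22), "X")
  k
}

#' Generate a synthetic copy-number fixture
#'
#' Emulates the package's observed-data modalities without external data:
#' \describe{
#'   \item{acute_missegregation}{\code{n_cells} copies of the modal
#'     karyotype each undergo exactly one division at the given per-copy
#'     mis-segregation probability and one daughter per division is kept
#'     (the sequenced cell); there is no selection or viability culling, as
#'     in a 48-hour drug pulse that precedes selection. Gain/loss direction
#'     is drawn once per chromosome per division, so sister copies
#'     co-segregate (as on a multipolar spindle) and the kept daughter's
#'     absolute deviation from the modal karyotype equals its event count;
#'     the population mean deviation is therefore
#'     p x total modal copies.}
#'   \item{steady_state_population}{wraps [run_simulation()] and samples
#'     cells from the final population (arm-level features).}
#'   \item{clonal}{identical rows of the modal karyotype.}
#' }
#'
#' @param kind One of \code{"acute_missegregation"},
#'   \code{"steady_state_population"}, \code{"clonal"}.
#' @param modal_karyotype Integer vector of chromosome-level copy numbers
#'   (default [modal_karyotype_44()]); used by the acute and clonal kinds.
#' @param p_misseg Per-copy mis-segregation probability (acute and
#'   steady-state kinds).
#' @param n_cells Cells in the fixture.
#' @param seed Integer RNG seed.
#' @param params A [sim_params()] object for the steady-state kind
#'   (its seed is overridden by \code{seed}; \code{p_misseg} is taken from
#'   the argument).
#' @return Integer matrix, cells x features, with a \code{"feature_level"}
#'   attribute.
#' @export
#' @examples
#' f <- generate_fixture("clonal", n_cells = 5, seed = 1)
#' nrow(f)
generate_fixture <- function(kind = c("acute_missegregation",
                                      "steady_state_population", "clonal"),
                             modal_karyotype = modal_karyotype_44(),
                             p_misseg = 0, n_cells = 100L, seed = 1L,
                             params = NULL) {
  kind <- match.arg(kind)
  stopifnot(n_cells >= 1L, p_misseg >= 0, p_misseg <= 1)
  set.seed(seed)
  if (kind == "steady_state_population") {
    if (is.null(params)) params <- sim_params()
    params$p_misseg <- p_misseg
    params$seed <- seed
    sim <- run_simulation(params)
    out <- sample_cells(sim, min(n_cells, nrow(sim$population)))
    rownames(out) <- paste0("cell", seq_len(nrow(out)))
    attr(out, "feature_level") <- "arm"
    return(out)
  }
  k <- as.integer(modal_karyotype)
  nf <- length(k)
  out <- matrix(rep(k, each = n_cells), nrow = n_cells)
  if (kind == "acute_missegregation" && p_misseg > 0) {
    for (i in seq_len(n_cells)) {
      # one division: each copy mis-segregates independently; direction
      # shared within a chromosome (sister co-segregation)
      events <- stats::rbinom(nf, k, p_misseg)
      dir <- ifelse(stats::runif(nf) < 0.5, 1L, -1L)
      out[i, ] <- k + dir * events
    }
  }
  rownames(out) <- paste0("cell", seq_len(n_cells))
  colnames(out) <- names(modal_karyotype)
  attr(out, "feature_level") <-
    if (is.null(names(modal_karyotype))) "chromosome" else
      feature_level_of(names(modal_karyotype))
  out
}

#' Observed mis-segregations relative to a modal karyotype
#'
#' Per cell, the absolute sum of copy-number deviations from a reference
#' modal karyotype, \eqn{\sum_f |n_f - modal_f|}; summarized as mean and
#' standard error over cells. This is the imaging-free counterpart of
#' counting segregation errors after an acute perturbation.
#'
#' @param mat Cells-by-features integer matrix.
#' @param reference Reference modal karyotype (same features as \code{mat}).
#' @return List with \code{per_cell} (integer vector), \code{mean},
#'   \code{se}.
#' @export
observed_missegregations <- function(mat, reference) {
  mat <- as.matrix(mat)
  if (ncol(mat) != length(reference))
    stop("matrix and reference use different feature conventions (",
         ncol(mat), " vs ", length(reference), " features)", call. = FALSE)
  dev <- as.integer(rowSums(abs(sweep(mat, 2L, as.numeric(reference)))))
  list(per_cell = dev, mean = mean(dev),
       se = if (length(dev) > 1L) stats::sd(dev) / sqrt(length(dev)) else 0)
}
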