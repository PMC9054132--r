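# Rejection-sampling approximate Bayesian computation over the simulator:
# prior library construction, posterior inference of (P_misseg, S),
# Bayesian model selection, sliding-window time-step tuning and sample-size
# sufficiency analysis.

#' Build a prior library of simulated summary statistics
#'
#' Runs the agent-based simulator over a grid of parameter sets theta (the
#' uniform prior), samples cells at the requested snapshot steps, and stores
#' one record (theta, summary statistics) per simulation x snapshot. The
#' paper-scale priors are grids such as P_misseg in {0, 0.001, ..., 0.05}
#' and S in {0, 2, ..., 100} over steps 40..80; reduced grids give
#' desk-scale libraries.
#'
#' Simulations that go extinct (or end with fewer cells than requested)
#' contribute records with missing statistics; these are excluded from
#' distance computations downstream.
#'
#' @param grid Data frame of parameter combinations; recognized columns are
#'   \code{p_misseg}, \code{S}, \code{p_break}, \code{selection_model},
#'   \code{growth_model}, \code{founder_ploidy} (missing columns fall back
#'   to \code{base_params}).
#' @param replicates Simulations per grid point (the paper used 3--8).
#' @param snapshot_steps Steps at which populations are sampled and
#'   summarized.
#' @param base_params A [sim_params()] object supplying every field the grid
#'   does not vary.
#' @param n_cells Cells sampled per snapshot (paper: 300 for topology work,
#'   200 recommended for inference); capped at the census size.
#' @param seed Integer seed; per-run seeds are derived deterministically.
#' @param feature_level Level at which statistics are computed:
#'   \code{"arm"} (native simulation state, 46 features) or
#'   \code{"chromosome"} (collapsed with [collapse_to_chromosomes()] mean
#'   rule, 23 features, matching whole-chromosome scDNAseq calls). Observed
#'   data must share the library's level.
#' @return Data frame of class \code{"prior_library"}: theta columns
#'   (\code{p_misseg}, \code{S}, \code{step}, \code{selection_model},
#'   \code{growth_model}, \code{founder_ploidy}, \code{replicate},
#'   \code{feature_level}) plus the [summarize_population()] statistic
#'   columns.
#' @export
build_prior_library <- function(grid, replicates = 1L,
                                snapshot_steps = 60L,
                                base_params = sim_params(),
                                n_cells = 200L, seed = 1L,
                                feature_level = c("arm", "chromosome")) {
  feature_level <- match.arg(feature_level)
  stopifnot(nrow(grid) >= 1L, replicates >= 1L)
  recs <- list()
  run_i <- 0L
  for (g in seq_len(nrow(grid))) {
    for (r in seq_len(replicates)) {
      run_i <- run_i + 1L
      p <- base_params
      for (f in intersect(names(grid),
                          c("p_misseg", "S", "p_break", "selection_model",
                            "growth_model", "founder_ploidy")))
        p[[f]] <- if (is.factor(grid[[f]])) as.character(grid[g, f]) else
          grid[g, f]
      p$seed <- (seed * 10007L + run_i) %% .Machine$integer.max
      sim <- run_simulation(sim_params(
        p_misseg = p$p_misseg, p_break = p$p_break, S = p$S,
        selection_model = p$selection_model, growth_model = p$growth_model,
        founder_ploidy = p$founder_ploidy, n_founders = p$n_founders,
        n_steps = max(snapshot_steps), pop_cap = p$pop_cap,
        copy_min = p$copy_min, copy_max = p$copy_max, seed = p$seed),
        snapshot_steps = snapshot_steps)
      for (st in snapshot_steps) {
        snap <- sim$snapshots[[as.character(st)]]
        theta <- data.frame(p_misseg = p$p_misseg, S = p$S, step = st,
                            selection_model = p$selection_model,
                            growth_model = p$growth_model,
                            founder_ploidy = p$founder_ploidy,
                            replicate = r, feature_level = feature_level,
                            stringsAsFactors = FALSE)
        if (is.null(snap) || nrow(snap) < 4L) {
          stats_row <- data.frame(aneuploidy = NA_real_, mkv = NA_real_,
                                  colless = NA_real_, sackin = NA_real_,
                                  cherries = NA_real_, pitchforks = NA_real_,
                                  mean_ploidy = NA_real_, n_cells = 0L)
        } else {
          cells <- sample_cells(snap, min(n_cells, nrow(snap)))
          if (feature_level == "chromosome")
            cells <- collapse_to_chromosomes(cells)
          stats_row <- as.data.frame(summarize_population(cells))
        }
        recs[[length(recs) + 1L]] <- cbind(theta, stats_row)
      }
    }
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  class(out) <- c("prior_library", "data.frame")
  out
}

#' Read or write a prior library as delimited text
#'
#' @param library A \code{prior_library} data frame.
#' @param path File path (tab-separated).
#' @return \code{write_prior_library} returns \code{path} invisibly;
#'   \code{read_prior_library} returns the \code{prior_library}.
#' @export
write_prior_library <- function(library, path) {
  utils::write.table(as.data.frame(library), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_prior_library
#' @export
read_prior_library <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  class(out) <- c("prior_library", "data.frame")
  out
}

# observed -> named numeric feature vector
observed_features <- function(observed, features) {
  if (is.matrix(observed) ||
      (is.data.frame(observed) && !inherits(observed, "cin_stats") &&
       nrow(observed) > 1L))
    observed <- summarize_population(as.matrix(observed))
  df <- as.data.frame(observed)[1L, , drop = FALSE]
  missing <- setdiff(features, names(df))
  if (length(missing))
    stop("observed statistics lack ABC feature(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  vapply(features, function(f) as.numeric(df[[f]]), numeric(1))
}

# per-feature dispersion for distance standardization: MAD across the
# library, falling back to SD then 1 when degenerate
feature_scale <- function(lib, features) {
  vapply(features, function(f) {
    v <- lib[[f]]
    s <- stats::mad(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) s <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) s <- 1
    s
  }, numeric(1))
}

abc_distances <- function(obs, lib, features, standardize = TRUE) {
  scl <- if (standardize) feature_scale(lib, features) else
    rep(1, length(features))
  z <- sweep(as.matrix(lib[, features, drop = FALSE]), 2L, obs, "-")
  z <- sweep(z, 2L, scl, "/")
  sqrt(rowSums(z^2))
}

#' Infer mis-segregation rate and selection by rejection ABC
#'
#' The core fitting function: compares the observed population's summary
#' statistics with a prior library of simulated statistics, accepts the
#' \code{tolerance}-quantile of nearest records under a per-feature
#' standardized Euclidean distance, and reports the accepted parameters as
#' the posterior. The point estimate of each parameter is the mean of
#' accepted values, with its standard error \eqn{sd/\sqrt{n}}.
#'
#' Features are standardized by their median absolute deviation across the
#' library before distances are computed (set \code{standardize = FALSE} for
#' raw-scale distances). \code{tolerance = 1} accepts the whole library, so
#' the posterior means equal the prior means.
#'
#' @param observed A cells-by-features copy-number matrix, or a
#'   \code{cin_stats} row from [summarize_population()]. It must be computed
#'   with the same feature-level conventions as the library.
#' @param library A \code{prior_library} from [build_prior_library()].
#' @param tolerance Acceptance quantile T in (0, 1]; default 0.05.
#' @param features Statistic names used for the distance; default
#'   [abc_features()].
#' @param standardize Standardize features by library MAD before the
#'   Euclidean distance (default TRUE).
#' @return An object of class \code{"cin_abc"}: list with \code{accepted}
#'   (data frame of accepted records with distances), \code{estimates}
#'   (means of accepted \code{p_misseg} and \code{S}), \code{se} (their
#'   standard errors), \code{tolerance}, \code{features}, \code{n_library},
#'   \code{n_accepted}, \code{observed} (the feature vector), \code{call}.
#' @seealso [model_selection()], [sliding_window_inference()]
#' @export
infer_cin <- function(observed, library, tolerance = 0.05,
                      features = abc_features(), standardize = TRUE) {
  stopifnot(tolerance > 0, tolerance <= 1)
  if (is.matrix(observed) && !is.null(library$feature_level)) {
    lvl <- attr(observed, "feature_level")
    if (is.null(lvl))
      lvl <- switch(as.character(ncol(observed)), "46" = "arm",
                    "23" = "chromosome", NULL)
    if (!is.null(lvl) && !identical(lvl, library$feature_level[[1L]]))
      stop("feature-level mismatch: observed matrix is ", lvl,
           "-level but the library was built at the ",
           library$feature_level[[1L]], " level", call. = FALSE)
  }
  obs <- observed_features(observed, features)
  lib <- as.data.frame(library)
  ok <- stats::complete.cases(lib[, features, drop = FALSE])
  lib <- lib[ok, , drop = FALSE]
  if (nrow(lib) == 0L)
    stop("prior library has no usable records", call. = FALSE)
  d <- abc_distances(obs, lib, features, standardize)
  n_acc <- ceiling(tolerance * nrow(lib))
  ord <- order(d)
  acc <- lib[ord[seq_len(n_acc)], , drop = FALSE]
  acc$distance <- d[ord[seq_len(n_acc)]]
  est <- c(p_misseg = mean(acc$p_misseg), S = mean(acc$S))
  se <- c(p_misseg = stats::sd(acc$p_misseg) / sqrt(n_acc),
          S = stats::sd(acc$S) / sqrt(n_acc))
  structure(list(accepted = acc, estimates = est, se = se,
                 tolerance = tolerance, features = features,
                 n_library = nrow(lib), n_accepted = n_acc,
                 observed = obs, call = match.call()),
            class = "cin_abc")
}

#' @export
print.cin_abc <- function(x, ...) {
  cat("Rejection-ABC inference of chromosomal instability\n")
  cat(sprintf("  library: %d records; tolerance %g -> %d accepted\n",
              x$n_library, x$tolerance, x$n_accepted))
  cat(sprintf("  P_misseg = %.5f (SE %.5f)\n", x$estimates["p_misseg"],
              x$se["p_misseg"]))
  cat(sprintf("  S        = %.2f (SE %.2f)\n", x$estimates["S"], x$se["S"]))
  invisible(x)
}

#' @export
coef.cin_abc <- function(object, ...) object$estimates

#' @export
summary.cin_abc <- function(object, ...) {
  q <- function(v) stats::quantile(v, c(0.025, 0.25, 0.5, 0.75, 0.975))
  out <- list(estimates = object$estimates, se = object$se,
              quantiles = rbind(p_misseg = q(object$accepted$p_misseg),
                                S = q(object$accepted$S)),
              tolerance = object$tolerance, features = object$features,
              n_library = object$n_library, n_accepted = object$n_accepted,
              max_distance = max(object$accepted$distance))
  class(out) <- "summary.cin_abc"
  out
}

#' @export
print.summary.cin_abc <- function(x, ...) {
  cat("Rejection-ABC posterior summary\n")
  cat(sprintf("  features: %s\n", paste(x$features, collapse = ", ")))
  cat(sprintf("  accepted %d / %d records (T = %g, max distance %.4f)\n",
              x$n_accepted, x$n_library, x$tolerance, x$max_distance))
  cat(sprintf("  P_misseg: mean %.5f, SE %.5f\n", x$estimates["p_misseg"],
              x$se["p_misseg"]))
  cat(sprintf("  S:        mean %.2f, SE %.2f\n", x$estimates["S"],
              x$se["S"]))
  cat("  posterior quantiles:\n")
  print(round(x$quantiles, 5))
  invisible(x)
}

#' @export
plot.cin_abc <- function(x, ...) {
  graphics::plot(x$accepted$p_misseg, x$accepted$S,
                 xlab = "P_misseg", ylab = "S",
                 main = "Accepted parameter sets", ...)
  graphics::points(x$estimates["p_misseg"], x$estimates["S"], pch = 3,
                   cex = 2, col = "red")
  invisible(x)
}

#' Bayesian selection-model comparison by rejection sampling
#'
#' Pools prior-library records tagged by selection model, accepts the
#' tolerance-quantile of records nearest the observed statistics, and
#' reports each model's posterior probability PP (its share of the accepted
#' records) and its Bayes factor against neutral selection,
#' \eqn{BF = PP(model)/PP(neutral)}. \eqn{BF > 5} is conventionally treated
#' as substantial evidence; when PP(neutral) = 0 the Bayes factor is
#' reported as \code{Inf}.
#'
#' @param observed As in [infer_cin()].
#' @param library A \code{prior_library} containing a
#'   \code{selection_model} column with records from every compared model,
#'   including \code{"neutral"}; or a list of per-model libraries, which
#'   are pooled.
#' @param tolerance,features,standardize As in [infer_cin()].
#' @return Object of class \code{"cin_modelsel"}: list with
#'   \code{posterior_prob} (named, sums to 1), \code{bayes_factor} (vs
#'   neutral; \code{BF(neutral) = 1}), \code{substantial} (models with
#'   BF > 5), \code{n_accepted}.
#' @export
model_selection <- function(observed, library, tolerance = 0.05,
                            features = abc_features(), standardize = TRUE) {
  if (is.list(library) && !is.data.frame(library))
    library <- do.call(rbind, lapply(library, as.data.frame))
  lib <- as.data.frame(library)
  models <- unique(lib$selection_model)
  if (!"neutral" %in% models)
    stop("model selection requires a neutral-model library as the null",
         call. = FALSE)
  obs <- observed_features(observed, features)
  ok <- stats::complete.cases(lib[, features, drop = FALSE])
  lib <- lib[ok, , drop = FALSE]
  d <- abc_distances(obs, lib, features, standardize)
  n_acc <- ceiling(tolerance * nrow(lib))
  acc <- lib[order(d)[seq_len(n_acc)], , drop = FALSE]
  pp <- table(factor(acc$selection_model, levels = models)) / n_acc
  pp <- stats::setNames(as.numeric(pp), names(pp))
  bf <- if (pp[["neutral"]] > 0) pp / pp[["neutral"]] else
    ifelse(pp > 0, Inf, NaN)
  bf[["neutral"]] <- 1
  structure(list(posterior_prob = pp, bayes_factor = bf,
                 substantial = names(bf)[is.finite(bf) & bf > 5 |
                                           is.infinite(bf)],
                 n_accepted = n_acc, tolerance = tolerance),
            class = "cin_modelsel")
}

#' @export
print.cin_modelsel <- function(x, ...) {
  cat("ABC selection-model comparison (neutral null)\n")
  tab <- data.frame(PP = round(x$posterior_prob, 4),
                    BF = round(x$bayes_factor, 3))
  print(tab)
  if (length(x$substantial))
    cat("  substantial evidence (BF > 5):",
        paste(x$substantial, collapse = ", "), "\n")
  invisible(x)
}

#' Sliding-window inference over prior time steps
#'
#' Repeats rejection ABC using only library records whose snapshot step
#' falls inside a sliding window (default width 11 steps: [0-10], [10-20],
#' ..., [90-100]), to check whether the posterior stabilizes over simulated
#' time and to choose the prior step range (the original analysis settled on
#' steps 40--80).
#'
#' @param observed,library,tolerance,features,standardize As [infer_cin()].
#' @param window_width Window width in steps (default 11, i.e. s..s+10).
#' @param starts Window start steps (default \code{seq(0, 90, 10)}).
#' @return Object of class \code{"cin_windows"}: \code{results} data frame
#'   (window bounds, posterior means and SEs, records used), \code{fits}
#'   list of \code{cin_abc} objects, and \code{stability}, the maximum
#'   absolute change of the posterior mean P_misseg between consecutive
#'   windows.
#' @export
sliding_window_inference <- function(observed, library,
                                     window_width = 11L,
                                     starts = seq(0L, 90L, by = 10L),
                                     tolerance = 0.05,
                                     features = abc_features(),
                                     standardize = TRUE) {
  lib <- as.data.frame(library)
  fits <- list()
  rows <- list()
  for (s in starts) {
    hi <- s + window_width - 1L
    sub <- lib[lib$step >= s & lib$step <= hi, , drop = FALSE]
    if (nrow(sub) == 0L)
      stop("no library records in window [", s, ", ", hi, "]", call. = FALSE)
    class(sub) <- c("prior_library", "data.frame")
    fit <- infer_cin(observed, sub, tolerance, features, standardize)
    fits[[length(fits) + 1L]] <- fit
    rows[[length(rows) + 1L]] <- data.frame(
      window_start = s, window_end = hi, n_records = nrow(sub),
      p_misseg_mean = fit$estimates[["p_misseg"]],
      p_misseg_se = fit$se[["p_misseg"]],
      S_mean = fit$estimates[["S"]], S_se = fit$se[["S"]])
  }
  res <- do.call(rbind, rows)
  drift <- if (nrow(res) > 1L) max(abs(diff(res$p_misseg_mean))) else 0
  structure(list(results = res, fits = fits, stability = drift),
            class = "cin_windows")
}

#' @export
print.cin_windows <- function(x, ...) {
  cat("Sliding-window ABC inference\n")
  print(round(x$results, 5), row.names = FALSE)
  cat(sprintf("  max consecutive-window drift of P_misseg: %.5f\n",
              x$stability))
  invisible(x)
}

#' Sample-size sufficiency analysis
#'
#' Draws replicate random subsamples of a cell population at each candidate
#' sample size, infers P_misseg from each by rejection ABC, and reports the
#' mean percent accuracy \eqn{100 (1 - |\hat{p} - p|/p)} against the known
#' truth together with the standard error of the inferred values across
#' replicates. Used to decide how many cells must be sequenced (the original
#' analysis recommends 200 cells for >= 90% accuracy at biologically
#' relevant rates).
#'
#' @param population Cells-by-features matrix (the full population to
#'   subsample).
#' @param sizes Integer vector of sample sizes (each <= population size).
#' @param replicates Subsamples per size.
#' @param library,tolerance,features,standardize As [infer_cin()].
#' @param truth True P_misseg (> 0) used for the accuracy computation.
#' @param seed Integer seed for subsampling.
#' @return Data frame with one row per size: \code{size},
#'   \code{mean_accuracy} (percent), \code{se_p_misseg} (SE of inferred
#'   values across replicates; 0 when replicates coincide),
#'   \code{mean_p_misseg}.
#' @export
sample_size_analysis <- function(population, sizes, replicates, library,
                                 truth, tolerance = 0.05,
                                 features = abc_features(),
                                 standardize = TRUE, seed = 1L) {
  if (!is.numeric(truth) || truth <= 0)
    stop("truth must be a positive mis-segregation rate", call. = FALSE)
  population <- as.matrix(population)
  if (max(sizes) > nrow(population))
    stop("largest sample size exceeds the population size", call. = FALSE)
  set.seed(seed)
  rows <- lapply(sizes, function(sz) {
    inferred <- vapply(seq_len(replicates), function(r) {
      cells <- if (sz == nrow(population)) population else
        population[sort(sample.int(nrow(population), sz)), , drop = FALSE]
      infer_cin(cells, library, tolerance, features,
                standardize)$estimates[["p_misseg"]]
    }, numeric(1))
    acc <- 100 * (1 - abs(inferred - truth) / truth)
    data.frame(size = sz, mean_accuracy = mean(acc),
               se_p_misseg = if (replicates > 1L)
                 stats::sd(inferred) / sqrt(replicates) else 0,
               mean_p_misseg = mean(inferred))
  })
  do.call(rbind, rows)
}

#' Predicted incidence of observable segregation errors
#'
#' Converts an inferred per-copy mis-segregation rate into the percentage of
#' divisions expected to show at least one error under the
#' one-chromosome-per-error assumption:
#' rate x mean chromosomes per cell x 100.
#'
#' @param p_misseg Per chromosome-copy mis-segregation probability.
#' @param mean_chromosomes Mean number of chromosomes observed per cell.
#' @return Percent of divisions with an expected error.
#' @export
#' @examples
#' predicted_error_incidence(0.005, 46)  # 23
predicted_error_incidence <- function(p_misseg, mean_chromosomes) {
  stopifnot(p_misseg >= 0, mean_chromosomes >= 0)
  p_misseg * mean_chromosomes * 100
}

#' Approximate a per-chromosome rate from an observed error frequency
#'
#' Inverts reported imaging-based error frequencies: the observed percent of
#' divisions with a segregation error, divided by 100 and by the modal
#' chromosome number of the sample, assuming one chromosome per error.
#'
#' @param frequency_percent Observed error frequency per division, percent.
#' @param modal_chromosomes Modal chromosome number (>= 1).
#' @return Per-chromosome mis-segregation rate.
#' @export
#' @examples
#' approximate_rate_from_frequency(31.3, 46)  # ~0.0068
approximate_rate_from_frequency <- function(frequency_percent,
                                            modal_chromosomes) {
  stopifnot(frequency_percent >= 0, frequency_percent <= 100)
  if (any(modal_chromosomes < 1))
    stop("modal chromosome number must be >= 1", call. = FALSE)
  frequency_percent / 100 / modal_chromosomes
}
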