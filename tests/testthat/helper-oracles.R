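# Shared helpers: independent brute-force tree-statistic oracle on nested
# pair structures, exhaustive shape enumeration, and small population
# builders. The oracle never touches the package's traversal code.

# all ordered full-binary-tree shapes with n leaves, as nested lists
enumerate_shapes <- function(n) {
  if (n == 1L) return(list("leaf"))
  out <- list()
  for (k in seq_len(n - 1L)) {
    for (l in enumerate_shapes(k)) {
      for (r in enumerate_shapes(n - k)) {
        out[[length(out) + 1L]] <- list(l, r)
      }
    }
  }
  out
}

shape_leaves <- function(s) {
  if (identical(s, "leaf")) 1L else shape_leaves(s[[1]]) + shape_leaves(s[[2]])
}

# brute-force counts by direct recursion over the nested structure
oracle_stats <- function(s, depth = 0L) {
  if (identical(s, "leaf"))
    return(list(leaves = 1L, colless = 0L, cherries = 0L, pitchforks = 0L,
                sackin = depth))
  a <- oracle_stats(s[[1]], depth + 1L)
  b <- oracle_stats(s[[2]], depth + 1L)
  n <- a$leaves + b$leaves
  list(leaves = n,
       colless = a$colless + b$colless + abs(a$leaves - b$leaves),
       cherries = a$cherries + b$cherries +
         as.integer(a$leaves == 1L && b$leaves == 1L),
       pitchforks = a$pitchforks + b$pitchforks + as.integer(n == 3L),
       sackin = a$sackin + b$sackin)
}

shape_to_newick <- function(s) {
  counter <- new.env()
  counter$i <- 0L
  rec <- function(s) {
    if (identical(s, "leaf")) {
      counter$i <- counter$i + 1L
      paste0("t", counter$i)
    } else {
      paste0("(", rec(s[[1]]), ",", rec(s[[2]]), ")")
    }
  }
  paste0(rec(s), ";")
}

caterpillar_newick <- function(n) {
  s <- "t1"
  for (i in 2:n) s <- paste0("(", s, ",t", i, ")")
  paste0(s, ";")
}

diploid_pop <- function(n) matrix(2L, nrow = n, ncol = 46L,
                                  dimnames = list(NULL, cinabc::arm_ids()))

random_karyotype <- function(min = 1L, max = 6L) {
  sample.int(max - min + 1L, 46L, replace = TRUE) + min - 1L
}

# a tiny synthetic prior library (statistics invented, not simulated) for
# unit tests of the rejection machinery itself
fake_library <- function(n = 40L, seed = 1L, models = "abundance") {
  set.seed(seed)
  lib <- data.frame(
    p_misseg = stats::runif(n, 0.001, 0.05),
    S = sample(seq(0, 100, 2), n, replace = TRUE),
    step = sample(0:100, n, replace = TRUE),
    selection_model = sample(models, n, replace = TRUE),
    growth_model = "pseudo_moran", founder_ploidy = 2L,
    replicate = 1L, feature_level = "arm",
    aneuploidy = stats::runif(n, 0, 0.5), mkv = stats::runif(n, 0, 0.5),
    colless = stats::runif(n), sackin = stats::runif(n),
    cherries = stats::runif(n, 0.1, 0.5),
    pitchforks = stats::runif(n, 0, 0.3),
    mean_ploidy = stats::runif(n, 1.8, 3.2), n_cells = 200L,
    stringsAsFactors = FALSE)
  class(lib) <- c("prior_library", "data.frame")
  lib
}

stats_of_record <- function(lib, i) {
  out <- lib[i, c("aneuploidy", "mkv", "colless", "sackin", "cherries",
                  "pitchforks", "mean_ploidy", "n_cells")]
  class(out) <- c("cin_stats", "data.frame")
  out
}
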