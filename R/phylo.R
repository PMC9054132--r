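# Phylogenies from copy-number profiles and the diversity / tree-topology
# summary statistics used as ABC features.
#
# Trees are rooted binary dendrograms: pairwise Euclidean distances between
# cells' copy-number profiles, complete-linkage agglomeration (stats::hclust),
# converted to an ape "phylo". Topology statistics (Colless, Sackin,
# cherries, pitchforks) are computed here and normalized: Colless by its
# caterpillar maximum (n-1)(n-2)/2, Sackin by its caterpillar maximum
# n(n+1)/2 - 1, cherries and pitchforks by the number of tips.

#' Build a phylogeny from a copy-number matrix
#'
#' Computes the pairwise Euclidean distance matrix between cells (rows) and
#' performs complete-linkage hierarchical clustering; the resulting
#' dendrogram is returned as a rooted binary \code{ape::phylo} tree with
#' merge heights as branch lengths. The agglomeration is deterministic for a
#' given row order; populations with many identical karyotypes (zero
#' distances) are resolved by the agglomerator's fixed candidate order.
#'
#' @param mat Integer matrix, cells x features (46 arms or 23 chromosomes).
#'   Row names become tip labels (cells are numbered when absent).
#' @return An \code{ape} \code{phylo} object with \code{nrow(mat)} tips.
#' @export
#' @examples
#' m <- rbind(a = rep(2L, 46), b = rep(2L, 46), c = rep(4L, 46))
#' build_tree(m)
build_tree <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L)
    stop("need at least 2 cells to build a tree", call. = FALSE)
  if (is.null(rownames(mat))) rownames(mat) <- paste0("cell", seq_len(nrow(mat)))
  hc <- stats::hclust(stats::dist(mat, method = "euclidean"),
                      method = "complete")
  ape::as.phylo(hc)
}

# children of each internal node and per-node tip-descendant counts,
# computed by one pass over the edge matrix (post-order via node numbering)
tree_clade_sizes <- function(phy) {
  n <- length(phy$tip.label)
  m <- phy$Nnode
  sizes <- c(rep(1L, n), integer(m))
  edge <- phy$edge
  # postorder guarantees every child subtree is complete before its parent
  for (i in ape::postorder(phy))
    sizes[edge[i, 1L]] <- sizes[edge[i, 1L]] + sizes[edge[i, 2L]]
  sizes
}

#' Topology statistics of a binary tree
#'
#' Counts cherries (internal nodes whose two children are both tips),
#' pitchforks (three-tip clades), the Colless imbalance index (sum over
#' internal nodes of |left tips - right tips|) and the Sackin index (sum of
#' tip depths in edges from the root), each raw and normalized:
#' Colless by \eqn{(n-1)(n-2)/2} and Sackin by \eqn{n(n+1)/2 - 1} (their
#' caterpillar maxima, giving a [0, 1] range with 1 = fully imbalanced);
#' cherries and pitchforks by the number of tips \eqn{n}.
#'
#' @param tree An \code{ape} \code{phylo} object; must be binary with at
#'   least 3 tips.
#' @return Named list with \code{colless}, \code{sackin}, \code{cherries},
#'   \code{pitchforks} (normalized) and \code{colless_raw},
#'   \code{sackin_raw}, \code{cherries_raw}, \code{pitchforks_raw},
#'   \code{n_tips}.
#' @export
#' @examples
#' cat51 <- ape::read.tree(text = "((((a,b),c),d),e);")  # caterpillar, n = 5
#' tree_topology_stats(cat51)$colless  # 1
tree_topology_stats <- function(tree) {
  n <- length(tree$tip.label)
  if (n < 3L) stop("topology statistics need at least 3 tips", call. = FALSE)
  if (!ape::is.binary(tree))
    stop("tree must be binary (every internal node has 2 children)",
         call. = FALSE)
  sizes <- tree_clade_sizes(tree)
  internal <- n + seq_len(tree$Nnode)
  # children per internal node
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  colless_raw <- 0L
  cherries <- 0L
  pitchforks <- 0L
  for (nd in internal) {
    ch <- kids[[as.character(nd)]]
    s <- sizes[ch]
    colless_raw <- colless_raw + abs(s[1L] - s[2L])
    if (all(s == 1L)) cherries <- cherries + 1L
    if (sizes[nd] == 3L) pitchforks <- pitchforks + 1L
  }
  depths <- ape::node.depth.edgelength(
    ape::compute.brlen(tree, 1))[seq_len(n)]
  sackin_raw <- sum(depths)
  list(colless = if (n > 2L) colless_raw / ((n - 1) * (n - 2) / 2) else 0,
       sackin = sackin_raw / (n * (n + 1) / 2 - 1),
       cherries = cherries / n,
       pitchforks = pitchforks / n,
       colless_raw = as.integer(colless_raw),
       sackin_raw = as.integer(round(sackin_raw)),
       cherries_raw = cherries, pitchforks_raw = pitchforks, n_tips = n)
}

#' Karyotype diversity statistics
#'
#' Computes, at the native feature level of the matrix:
#' \describe{
#'   \item{aneuploidy}{mean over cells of the variance within one cell's
#'     karyotype (across features) — intra-karyotype heterogeneity.}
#'   \item{mkv}{mean karyotype variance: per-feature variance across cells,
#'     averaged over features, normalized by the population mean ploidy —
#'     inter-karyotype heterogeneity.}
#'   \item{mean_ploidy}{mean over cells of (total copies / number of
#'     features), i.e. /46 at arm level and /23 at chromosome level.}
#' }
#' All variances are sample variances (n - 1 denominator, as in
#' \code{stats::var}).
#'
#' @param mat Integer matrix, cells x features.
#' @return Named list with \code{aneuploidy}, \code{mkv}, \code{mean_ploidy}.
#' @export
#' @examples
#' diversity_stats(rbind(rep(2L, 46), rep(4L, 46)))  # mkv = 2/3
diversity_stats <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 1L) stop("empty copy-number matrix", call. = FALSE)
  mp <- mean(rowMeans(mat))
  within_cell <- apply(mat, 1L, stats::var)
  per_feature <- if (nrow(mat) > 1L) apply(mat, 2L, stats::var) else
    rep(0, ncol(mat))
  list(aneuploidy = mean(within_cell),
       mkv = mean(per_feature) / mp,
       mean_ploidy = mp)
}

#' Summary statistics of a cell population
#'
#' Composes [build_tree()], [tree_topology_stats()] and [diversity_stats()]
#' into the statistic vector used for approximate Bayesian computation. The
#' default ABC feature subset is \code{aneuploidy}, \code{mkv},
#' \code{colless}, \code{cherries}.
#'
#' @param mat Integer matrix, cells x features, at least 4 cells.
#' @return One-row data frame of class \code{"cin_stats"} with columns
#'   \code{aneuploidy}, \code{mkv}, \code{colless}, \code{sackin},
#'   \code{cherries}, \code{pitchforks}, \code{mean_ploidy}, \code{n_cells}.
#' @export
summarize_population <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 4L)
    stop("population summary statistics need at least 4 cells", call. = FALSE)
  d <- diversity_stats(mat)
  t <- tree_topology_stats(build_tree(mat))
  out <- data.frame(aneuploidy = d$aneuploidy, mkv = d$mkv,
                    colless = t$colless, sackin = t$sackin,
                    cherries = t$cherries, pitchforks = t$pitchforks,
                    mean_ploidy = d$mean_ploidy, n_cells = nrow(mat))
  class(out) <- c("cin_stats", "data.frame")
  out
}

#' Default ABC feature names
#' @return Character vector: aneuploidy, mkv, colless, cherries.
#' @export
abc_features <- function() c("aneuploidy", "mkv", "colless", "cherries")

#' Collapse an arm-level matrix to whole chromosomes
#'
#' Arm-level simulations are matched to chromosome-level observed calls by
#' collapsing each chromosome's two arms to one value: the rounded mean
#' (round-half-to-even, the default), the minimum, or the p-arm value.
#'
#' @param mat Integer matrix with 46 arm columns in canonical order.
#' @param rule \code{"mean"}, \code{"min"} or \code{"p"}.
#' @return Integer matrix with 23 chromosome columns named
#'   \code{1..22, X}.
#' @export
collapse_to_chromosomes <- function(mat, rule = c("mean", "min", "p")) {
  rule <- match.arg(rule)
  mat <- as.matrix(mat)
  if (ncol(mat) != 46L)
    stop("matrix is not arm-level (46 columns expected)", call. = FALSE)
  p <- mat[, .p_idx, drop = FALSE]
  q <- mat[, .q_idx, drop = FALSE]
  out <- switch(rule,
                mean = round((p + q) / 2),
                min = pmin(p, q),
                p = p)
  out <- matrix(as.integer(out), nrow = nrow(mat))
  colnames(out) <- c(as.character(1:22), "X")
  rownames(out) <- rownames(mat)
  out
}

#' Export a tree to Newick
#'
#' @param tree An \code{ape} \code{phylo}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 9)
  invisible(path)
}
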