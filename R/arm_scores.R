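# Chromosome-arm fitness scores for the karyotype-selection models.
#
# 46 autosomal + X arms (1p..22q, Xp, Xq). Three score columns:
#   gene_abundance  f_c   : genes on arm / all genes (stabilizing selection)
#   driver_density  TOE_c : normalized tumor-suppressor/oncogene/essential-gene
#                           balance (directional selection; may be negative)
#   hybrid                : (f_c + TOE_c) / 2
# Each column sums to 1 up to printed rounding; columns are renormalized to
# sum to exactly 1 at load so a euploid cell always has fitness 1.

.arm_ids <- c(
  "1p", "1q", "2p", "2q", "3p", "3q", "4p", "4q", "5p", "5q",
  "6p", "6q", "7p", "7q", "8p", "8q", "9p", "9q", "10p", "10q",
  "11p", "11q", "12p", "12q", "13p", "13q", "14p", "14q", "15p", "15q",
  "16p", "16q", "17p", "17q", "18p", "18q", "19p", "19q", "20p", "20q",
  "21p", "21q", "22p", "22q", "Xp", "Xq")

.gene_abundance_raw <- c(
  0.04780162, 0.04340321, 0.02733655, 0.04244054, 0.02310412, 0.02997560,
  0.01238195, 0.03181796, 0.01178443, 0.03787615, 0.02557719, 0.02554399,
  0.01795880, 0.03231589, 0.01591728, 0.02549420, 0.01301266, 0.02572657,
  0.01122010, 0.02750253, 0.01961858, 0.03629936, 0.01425750, 0.03659812,
  0.00000000, 0.02333649, 0.00001660, 0.03792594, 0.00000000, 0.03701306,
  0.02383442, 0.01900446, 0.01548573, 0.03553586, 0.00627396, 0.01434049,
  0.02159372, 0.02813325, 0.00896280, 0.01526996, 0.00232369, 0.01233215,
  0.00013278, 0.02297134, 0.01555213, 0.02499627)

.driver_density_raw <- c(
  -0.00240180, 0.03244362, 0.02935717, 0.03943267, 0.03289695, 0.05416736,
   0.01784909, 0.02901324, 0.04281166, 0.01949934, 0.02398619, 0.00011625,
   0.09889284, 0.06933314, 0.02769564, 0.05861427, -0.00129410, 0.04702681,
  -0.03642180, 0.01142688, 0.03818621, 0.01898784, 0.05515510, 0.06273786,
   0.00000000, -0.01015390, 0.00000000, 0.02557439, 0.00000000, 0.02065660,
   0.04334736, -0.00714440, -0.00859750, 0.04363474, 0.00533697, -0.02636320,
   0.05371416, 0.00550338, 0.04351025, 0.04993593, 0.00000000, -0.00330920,
   0.00000000, -0.00515810, 0.00000000, 0.00000000)

.hybrid_raw <- c(
  0.02269992, 0.03792341, 0.02834686, 0.04093660, 0.02800053, 0.04207148,
  0.01511552, 0.03041560, 0.02729805, 0.02868775, 0.02478169, 0.01283012,
  0.05842582, 0.05082451, 0.02180646, 0.04205423, 0.00585929, 0.03637669,
  -0.01260080, 0.01946471, 0.02890240, 0.02764360, 0.03470630, 0.04966799,
  0.00000000, 0.00659128, 0.00000830, 0.03175016, 0.00000000, 0.02883483,
  0.03359089, 0.00593005, 0.00344414, 0.03958530, 0.00580547, -0.00601130,
  0.03765394, 0.01681831, 0.02623653, 0.03260295, 0.00116185, 0.00451147,
  0.00006640, 0.00890660, 0.00777606, 0.01249813)

#' Chromosome-arm fitness score table
#'
#' Returns the base per-arm fitness contribution scores used by the
#' karyotype-selection models: gene abundance (\eqn{f_c}), driver density
#' (TOE), and their hybrid average, for the 46 arms of chromosomes 1--22 and
#' X in the fixed order \code{1p, 1q, ..., 22q, Xp, Xq}.
#'
#' Each column sums to 1 so that a euploid cell at the population mean ploidy
#' has fitness exactly 1; columns are renormalized at load to remove the
#' residue of printed rounding (at most 1e-6). The unnormalized values are
#' kept in the \code{"raw"} attribute. Arms with no recorded genes
#' (\code{13p}, \code{15p}) have gene-abundance score 0; arms with no
#' published driver score (\code{13p}, \code{14p}, \code{15p}, \code{21p},
#' \code{22p}, \code{Xp}, \code{Xq}) have driver-density score 0.
#'
#' @return A data frame of class \code{"arm_scores"} with columns
#'   \code{arm_id}, \code{gene_abundance}, \code{driver_density},
#'   \code{hybrid} and 46 rows; row names are the arm ids.
#' @seealso [karyotype_fitness()], [write_arm_scores()]
#' @export
#' @examples
#' sc <- load_arm_scores()
#' sc["1p", "gene_abundance"]
#' colSums(sc[, -1])
load_arm_scores <- function() {
  raw <- data.frame(
    arm_id = .arm_ids,
    gene_abundance = .gene_abundance_raw,
    driver_density = .driver_density_raw,
    hybrid = .hybrid_raw,
    stringsAsFactors = FALSE)
  # embedded-data integrity: printed columns must already sum to 1 (+-1e-6)
  # and the hybrid column must be the rowwise mean of the other two
  sums <- colSums(raw[, c("gene_abundance", "driver_density", "hybrid")])
  if (any(abs(sums - 1) > 1e-6) ||
      max(abs(raw$hybrid - (raw$gene_abundance + raw$driver_density) / 2)) > 1e-6)
    stop("embedded arm-score table is corrupted", call. = FALSE)
  rownames(raw) <- raw$arm_id
  tab <- raw
  for (col in c("gene_abundance", "driver_density", "hybrid"))
    tab[[col]] <- tab[[col]] / sum(tab[[col]])
  attr(tab, "raw") <- raw
  class(tab) <- c("arm_scores", "data.frame")
  tab
}

#' Write or read an arm-score table as delimited text
#'
#' Custom selection landscapes can be supplied through the same four-column
#' format (\code{arm_id}, \code{gene_abundance}, \code{driver_density},
#' \code{hybrid}), tab-separated with a header row.
#'
#' @param scores An \code{arm_scores} table, as from [load_arm_scores()].
#' @param path File path; extension \code{.csv} selects comma separation,
#'   anything else tab separation.
#' @return \code{write_arm_scores} returns \code{path} invisibly;
#'   \code{read_arm_scores} returns an \code{arm_scores} data frame.
#' @export
write_arm_scores <- function(scores, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(as.data.frame(scores), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_arm_scores
#' @export
read_arm_scores <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("arm_id", "gene_abundance", "driver_density", "hybrid")
  if (!all(need %in% names(tab)))
    stop("arm-score file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(tab) != 46L)
    stop("arm-score table must have exactly 46 arms, got ", nrow(tab),
         call. = FALSE)
  rownames(tab) <- tab$arm_id
  class(tab) <- c("arm_scores", "data.frame")
  tab
}

#' Arm identifiers in canonical order
#'
#' @return Character vector of the 46 arm labels \code{1p, 1q, ..., Xp, Xq}.
#' @export
arm_ids <- function() .arm_ids
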