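# Eight-state high/low co-expression classification, per-region class
# fractions, the cutoff sweep, and pairwise co-expression counting.

# Fixed class layout: the 3-bit (ndl3-hi, ptk7-hi, wntP2-hi) pattern maps to
#   1 wntP2-hi only          2 ptk7-hi & wntP2-hi     3 ptk7-hi only
#   4 all three hi           5 ptk7-hi & ndl3-hi      6 wntP2-hi & ndl3-hi
#   7 ndl3-hi only           8 all three low
classLookup <- c("001" = 1L, "011" = 2L, "010" = 3L, "111" = 4L,
                 "110" = 5L, "101" = 6L, "100" = 7L, "000" = 8L)

#' Human-readable labels of the eight expression classes
#'
#' @return Named character vector, names "1".."8".
#' @export
expressionClassLabels <- function() {
  c("1" = "wntP2-hi only", "2" = "ptk7-hi wntP2-hi", "3" = "ptk7-hi only",
    "4" = "ptk7-hi wntP2-hi ndl3-hi", "5" = "ptk7-hi ndl3-hi",
    "6" = "wntP2-hi ndl3-hi", "7" = "ndl3-hi only", "8" = "all low")
}

#' Assign axial regions to cells
#'
#' Region index is \code{floor(u * n_regions) + 1} with the last bin closed:
#' R1 is the most anterior region, R\code{n} the most posterior.
#'
#' @param cells cell table with a \code{u} column in \code{[0, 1]}.
#' @param n_regions number of equal axial regions (default 8).
#' @return The cell table with an integer \code{region} column appended.
#' @examples
#' assignRegion(data.frame(u = c(0.05, 1)), 8)$region  # 1, 8
#' @export
assignRegion <- function(cells, n_regions = 8L) {
  stopifnot("u" %in% names(cells))
  if (nrow(cells) && (any(!is.finite(cells$u)) ||
                      any(cells$u < 0 | cells$u > 1)))
    stop("assignRegion: u must lie in [0, 1]")
  cells$region <- pmin(as.integer(floor(cells$u * n_regions)) + 1L,
                       as.integer(n_regions))
  cells
}

#' Classify cells into the eight high/low expression states
#'
#' A cell is "hi" for a gene iff its mean intensity is greater than or equal
#' to the cutoff (ties count as hi); the three hi/lo calls map to one of
#' eight classes (see \code{\link{expressionClassLabels}}).
#'
#' @param cells cell table with \code{mean_ndl3}, \code{mean_ptk7},
#'   \code{mean_wntP2} columns.
#' @param params a \code{\linkS4class{ClassificationParams}} (or a numeric
#'   cutoff).
#' @return The cell table with an integer \code{class} column appended.
#' @examples
#' classifyCells(data.frame(mean_ndl3 = 10, mean_ptk7 = 10,
#'                          mean_wntP2 = 80), 55)$class  # 1
#' @export
classifyCells <- function(cells, params = ClassificationParams()) {
  if (is.numeric(params)) params <- ClassificationParams(cutoff = params)
  need <- c("mean_ndl3", "mean_ptk7", "mean_wntP2")
  if (!all(need %in% names(cells)))
    stop("classifyCells: missing channel mean column(s): ",
         paste(setdiff(need, names(cells)), collapse = ", "))
  if (nrow(cells) && anyNA(cells[need]))
    stop("classifyCells: missing channel values")
  key <- paste0(as.integer(cells$mean_ndl3 >= params@cutoff),
                as.integer(cells$mean_ptk7 >= params@cutoff),
                as.integer(cells$mean_wntP2 >= params@cutoff))
  cells$class <- unname(classLookup[key])
  cells
}

#' Per-region class fractions
#'
#' Fraction of cells of each class within each axial region. Rows are
#' regions, columns classes; occupied rows sum to 1; regions with no cells
#' are reported as missing (\code{NA}), never as zero.
#'
#' @param cells cell table with \code{region} and \code{class} columns.
#' @param n_regions,n_classes table extent (defaults 8 and 8).
#' @return Numeric \code{n_regions x n_classes} matrix, dimnames
#'   \code{R1..Rn} and class ids; attribute \code{n_cells} holds per-region
#'   counts.
#' @export
classFractions <- function(cells, n_regions = 8L, n_classes = 8L) {
  stopifnot(all(c("region", "class") %in% names(cells)))
  counts <- table(factor(cells$region, levels = seq_len(n_regions)),
                  factor(cells$class, levels = seq_len(n_classes)))
  counts <- matrix(as.numeric(counts), n_regions, n_classes,
                   dimnames = list(paste0("R", seq_len(n_regions)),
                                   as.character(seq_len(n_classes))))
  n <- rowSums(counts)
  frac <- counts / ifelse(n > 0, n, NA_real_)
  attr(frac, "n_cells") <- n
  frac
}

#' Class fractions across a sweep of cutoffs
#'
#' Repeats the classification for \code{sweep_count} evenly spaced cutoffs
#' across \code{sweep_range}, reporting each cutoff's per-region class
#' fractions and the whole-animal totals of class 4 (all hi) and class 8
#' (all low). Because the per-gene hi rule is monotone in the cutoff, the
#' class-8 total is non-increasing and the class-4 total non-decreasing as
#' the cutoff decreases.
#'
#' @param cells cell table with channel means and \code{region}.
#' @param params a \code{\linkS4class{ClassificationParams}}.
#' @return A list: \code{cutoffs}, \code{fractions} (list of matrices), and
#'   \code{totals} (data.frame with \code{cutoff}, \code{n_class4},
#'   \code{n_class8}).
#' @export
thresholdSweep <- function(cells, params = ClassificationParams()) {
  stopifnot(is(params, "ClassificationParams"))
  cutoffs <- seq(params@sweep_range[1], params@sweep_range[2],
                 length.out = params@sweep_count)
  res <- lapply(cutoffs, function(ct) {
    cl <- classifyCells(cells, ClassificationParams(cutoff = ct,
                                                    n_regions = params@n_regions))
    list(frac = classFractions(cl, n_regions = params@n_regions),
         n4 = sum(cl$class == 4L), n8 = sum(cl$class == 8L))
  })
  list(cutoffs = cutoffs,
       fractions = lapply(res, `[[`, "frac"),
       totals = data.frame(cutoff = cutoffs,
                           n_class4 = vapply(res, `[[`, integer(1), "n4"),
                           n_class8 = vapply(res, `[[`, integer(1), "n8")))
}

#' Pairwise co-expression counts and conditional fractions
#'
#' Counts cells positive for each of two genes (mean intensity >= cutoff)
#' and both, reporting the two conditional fractions with their
#' denominators — the "a-positive cells that are also b-positive" numbers
#' of double-FISH scoring.
#'
#' @param cells cell table with channel mean columns.
#' @param gene_a,gene_b gene names (\code{ndl3}, \code{ptk7}, \code{wntP2}),
#'   or any pair of \code{mean_*} column suffixes present in \code{cells}.
#' @param cutoff per-channel positivity cutoff; length 1 or 2 (default 55).
#' @return A list: \code{n_a}, \code{n_b}, \code{n_both},
#'   \code{frac_b_given_a}, \code{frac_a_given_b} (NA when the denominator
#'   is zero).
#' @export
coexpressionCounts <- function(cells, gene_a, gene_b, cutoff = 55) {
  ca <- paste0("mean_", gene_a); cb <- paste0("mean_", gene_b)
  stopifnot(all(c(ca, cb) %in% names(cells)))
  cutoff <- rep_len(cutoff, 2L)
  pa <- cells[[ca]] >= cutoff[1]
  pb <- cells[[cb]] >= cutoff[2]
  n_a <- sum(pa); n_b <- sum(pb); n_both <- sum(pa & pb)
  list(n_a = n_a, n_b = n_b, n_both = n_both,
       frac_b_given_a = if (n_a > 0) n_both / n_a else NA_real_,
       frac_a_given_b = if (n_b > 0) n_both / n_b else NA_real_)
}
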