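# RNAi enhancement-screen statistics: penetrance, the exact 2x2 test,
# Benjamini-Hochberg correction, and the screen decision rule (each
# condition tested against the designated control condition).

#' Phenotype penetrance per condition
#'
#' @param table \code{data.frame} with integer columns \code{n_affected}
#'   and \code{n_scored} (one row per RNAi condition).
#' @return Numeric vector \code{n_affected / n_scored}.
#' @examples
#' penetrance(data.frame(n_affected = c(28, 0), n_scored = c(35, 46)))
#' @export
penetrance <- function(table) {
  stopifnot(all(c("n_affected", "n_scored") %in% names(table)))
  a <- table$n_affected; n <- table$n_scored
  if (any(n <= 0)) stop("penetrance: n_scored must be positive")
  if (any(a < 0) || any(a > n))
    stop("penetrance: need 0 <= n_affected <= n_scored")
  a / n
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value for the table \code{rbind(c(a, b), c(c, d))} by
#' full hypergeometric enumeration: the sum of the probabilities of all
#' tables with the observed margins whose point probability does not exceed
#' that of the observed table (minimum-likelihood method, with a relative
#' tie tolerance of 1e-7, the dominant convention for 2x2 exact tests).
#'
#' @param a,b,c,d nonnegative integer cell counts, rows = groups, columns =
#'   affected/unaffected.
#' @return Two-sided p-value in \code{(0, 1]}.
#' @examples
#' fisherExact(41, 22, 7, 25)   # < 1e-4
#' fisherExact(3, 0, 0, 3)      # 0.1
#' @export
fisherExact <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("fisherExact: cell counts must be nonnegative integers")
  m <- a + b          # row 1 margin
  n2 <- c + d         # row 2 margin
  k <- a + c          # column 1 margin
  if (m + n2 == 0)
    stop("fisherExact: empty table (all-zero margins)")
  if (m == 0 || n2 == 0 || k == 0 || (b + d) == 0) return(1)
  x <- max(0, k - n2):min(k, m)
  dens <- dhyper(x, m, n2, k)
  d_obs <- dhyper(a, m, n2, k)
  min(1, sum(dens[dens <= d_obs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Adjusted p-value of the i-th test is \code{min over j >= rank(i) of
#' p_(j) * m / j}, capped at 1 and mapped back to the input order — the
#' standard FDR-controlling step-up procedure.
#'
#' @param p_values numeric vector of raw p-values in \code{[0, 1]}.
#' @return Adjusted p-values, same length and order.
#' @examples
#' bhCorrect(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhCorrect <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  stopifnot(all(p_values >= 0 & p_values <= 1))
  p.adjust(p_values, method = "BH")
}

#' RNAi enhancement-screen statistics
#'
#' For every non-control condition, a two-sided \code{\link{fisherExact}}
#' test of (affected, unaffected) against the control condition's counts,
#' Benjamini-Hochberg correction across all tested conditions, and a
#' significance flag at \code{alpha}. Conditions scored on fewer than
#' \code{min_scored} animals are still tested but flagged low-power.
#'
#' @param table \code{data.frame} with columns \code{condition},
#'   \code{n_affected}, \code{n_scored} and a logical \code{is_control}
#'   marking exactly one row (the comparator, e.g. the control + ptk7
#'   dsRNA condition).
#' @param alpha significance level after correction (default 0.05).
#' @param min_scored minimum animals per condition before the low-power
#'   flag (default 5).
#' @return \code{data.frame}: one row per condition with \code{penetrance},
#'   \code{p_raw}, \code{p_adj}, \code{significant}, \code{low_power}
#'   (control row has NA test fields).
#' @export
enhancementScreen <- function(table, alpha = 0.05, min_scored = 5L) {
  need <- c("condition", "n_affected", "n_scored", "is_control")
  stopifnot(all(need %in% names(table)))
  if (sum(table$is_control) != 1L)
    stop("enhancementScreen: exactly one control row is required")
  ctrl <- table[table$is_control, ]
  out <- data.frame(condition = table$condition,
                    penetrance = penetrance(table),
                    p_raw = NA_real_, p_adj = NA_real_,
                    significant = NA, low_power = table$n_scored < min_scored)
  test_rows <- which(!table$is_control)
  p <- vapply(test_rows, function(i)
    fisherExact(table$n_affected[i], table$n_scored[i] - table$n_affected[i],
                ctrl$n_affected, ctrl$n_scored - ctrl$n_affected),
    numeric(1))
  out$p_raw[test_rows] <- p
  out$p_adj[test_rows] <- bhCorrect(p)
  out$significant[test_rows] <- out$p_adj[test_rows] < alpha
  out
}
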