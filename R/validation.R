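#' Positive predictive value
#'
#' `tp / (tp + fp)`: the fraction of phenotype-positive records confirmed
#' by the gold standard. The chart-review sampling design supports PPV
#' only (no sensitivity/specificity/NPV).
#'
#' @param tp,fp true- and false-positive counts; `tp + fp` must be > 0.
#' @return proportion in [0, 1].
#' @examples
#' ppv(89, 11)
#' @export
ppv <- function(tp, fp) {
  if (tp < 0 || fp < 0) stop("counts must be non-negative")
  if (tp + fp == 0) stop("ppv undefined: tp + fp = 0")
  tp / (tp + fp)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement for a square cross-tabulation:
#' \eqn{\kappa = (p_o - p_e) / (1 - p_e)} with observed agreement
#' \eqn{p_o = \sum n_{ii}/N} and expected agreement
#' \eqn{p_e = \sum (r_i c_i)/N^2} from the marginals. Unweighted, any k x k
#' table. Defined as 1 when both raters agree perfectly on a single
#' category (\eqn{p_o = p_e = 1}); flagged undefined when \eqn{p_e = 1}
#' with \eqn{p_o < 1}.
#'
#' @param tab square matrix/table of counts.
#' @return list: `kappa`, `po`, `pe`, `n`.
#' @examples
#' cohensKappa(matrix(c(45, 5, 5, 45), 2))$kappa
#' @export
cohensKappa <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) != ncol(tab)) stop("table must be square")
  if (any(tab < 0)) stop("counts must be non-negative")
  n <- sum(tab)
  if (n == 0) stop("table must contain at least one observation")
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else if (po == 1) 1 else {
    warning("kappa undefined: expected agreement is 1")
    NA_real_
  }
  list(kappa = kappa, po = po, pe = pe, n = n)
}

#' Validate phenotype calls against a gold standard
#'
#' Cross-tabulates binary phenotype calls against adjudicated gold-standard
#' labels and reports the PPV among phenotype-positive records, together
#' with Cohen's kappa if two raters' adjudications are supplied.
#'
#' @param phenotypePositive logical vector: participant called case by the
#'   phenotype.
#' @param gold logical vector: gold-standard NAFLD yes/no (e.g. the
#'   consensus adjudication).
#' @param rater1,rater2 optional logical vectors of per-rater calls for the
#'   inter-rater kappa.
#' @return list: `table` (phenotype x gold 2x2, ordered yes/no), `ppv`,
#'   and when raters are given `kappa` plus the full [cohensKappa()]
#'   breakdown in `kappa_detail`.
#' @export
validateCalls <- function(phenotypePositive, gold, rater1 = NULL,
                          rater2 = NULL) {
  lev <- c("yes", "no")
  f <- function(x) factor(ifelse(x, "yes", "no"), levels = lev)
  tab <- table(phenotype = f(phenotypePositive), gold = f(gold))
  tp <- tab["yes", "yes"]; fp <- tab["yes", "no"]
  out <- list(table = unclass(tab), ppv = ppv(tp, fp))
  if (!is.null(rater1) && !is.null(rater2)) {
    kd <- cohensKappa(table(f(rater1), f(rater2)))
    out$kappa <- kd$kappa
    out$kappa_detail <- kd
  }
  out
}
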