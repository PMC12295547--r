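#' @importFrom stats pchisq
NULL

#' Chi-square goodness-of-fit test for a segregation ratio
#'
#' Tests observed phenotype class counts against an expected small-integer
#' ratio (1:1 for a monogenic haploid cross, 3:1, ...). No continuity
#' correction is applied by default; with `correct = TRUE` the Yates
#' correction `(|O - E| - 1/2)^2 / E` is used instead.
#'
#' @param observed integer vector of class counts (>= 2 classes).
#' @param ratio expected ratio, one positive integer per class.
#' @param correct apply the Yates continuity correction.
#' @return an object of class `SegregationTest`: a list with `observed`,
#'   `expected`, `ratio`, `chiSquare`, `df` and `pValue`.
#' @examples
#' segregationChiSquare(c(74, 82), c(1, 1))  # chi^2 = 0.41, p > 0.05
#' @export
segregationChiSquare <- function(observed, ratio = c(1, 1),
                                 correct = FALSE) {
  if (length(observed) < 2L)
    stop("need at least two phenotype classes")
  if (length(ratio) != length(observed))
    stop(sprintf("ratio has %d classes but observed has %d",
                 length(ratio), length(observed)))
  if (any(ratio <= 0)) stop("ratio terms must be positive")
  total <- sum(observed)
  if (total <= 0) stop("total observed count must be positive")
  expected <- total * ratio / sum(ratio)
  if (any(expected <= 0)) stop("expected count per class must be positive")
  dev <- abs(observed - expected)
  if (correct) dev <- pmax(dev - 0.5, 0)
  chi <- sum(dev^2 / expected)
  df <- length(observed) - 1L
  structure(list(observed = observed, expected = expected, ratio = ratio,
                 chiSquare = chi, df = df,
                 pValue = pchisq(chi, df, lower.tail = FALSE)),
            class = "SegregationTest")
}

#' @export
print.SegregationTest <- function(x, ...) {
  cat(sprintf("Segregation chi-square test (%s ratio)\n",
              paste(x$ratio, collapse = ":")))
  cat("  observed:", paste(x$observed, collapse = " / "), "\n")
  cat(sprintf("  chi^2 = %.4f, df = %d, p = %.4g\n",
              x$chiSquare, x$df, x$pValue))
  invisible(x)
}

#' Tally phenotype classes
#'
#' @param phenotypes character vector (or `data.frame` with a
#'   `phenotype` column) over the closed vocabulary `"fruiting"` /
#'   `"non_fruiting"`.
#' @return `data.frame` with `phenotype`, `count` and `percent` (one
#'   decimal; percentages sum to 100 up to rounding).
#' @examples
#' traitTally(rep(c("fruiting", "non_fruiting"), c(60, 20)))
#' @export
traitTally <- function(phenotypes) {
  if (is.data.frame(phenotypes)) phenotypes <- phenotypes$phenotype
  if (!length(phenotypes)) stop("empty phenotype table")
  bad <- setdiff(unique(phenotypes), .phenoLevels)
  if (length(bad))
    stop("unknown phenotype label(s): ", paste(bad, collapse = ", "))
  counts <- table(factor(phenotypes, levels = .phenoLevels))
  data.frame(phenotype = names(counts),
             count = as.integer(counts),
             percent = round(100 * as.integer(counts) / length(phenotypes),
                             1),
             row.names = NULL)
}
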