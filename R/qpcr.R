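#' @include utils.R
NULL

# The quantification arithmetic of the validation assays: ChIP-qPCR
# percent-input enrichment, 2^(-ddCt) relative expression, and the unpaired
# Student t-test with star annotation.

#' ChIP-qPCR enrichment by the percent-input method
#'
#' The input Ct is first adjusted for the dilution of the input aliquot:
#' `adjusted = mean(ctInput) - log2(1 / inputFraction)`. Enrichment is then
#' `percentInput = 100 * 2^(adjusted - mean(ctIp))`. The replicate SD is
#' propagated through the exponent by the first-order delta method using
#' the standard errors of both Ct means.
#'
#' @param ctIp numeric vector of replicate Ct values of the IP sample.
#' @param ctInput numeric vector of replicate Ct values of the input sample.
#' @param inputFraction fraction of chromatin used as the input aliquot,
#'   in (0, 1].
#' @return A list with `percentInput` (%), `sd` (propagated SD, `NA` with
#'   single replicates), `adjustedInputCt`.
#' @examples
#' percentInput(ctIp = 12, ctInput = 10, inputFraction = 0.01)  # ~0.25%
#' @export
percentInput <- function(ctIp, ctInput, inputFraction) {
  stopf(is.numeric(inputFraction) && length(inputFraction) == 1L &&
          inputFraction > 0 && inputFraction <= 1,
        "inputFraction must lie in (0, 1]")
  stopf(length(ctIp) >= 1L && all(is.finite(ctIp)) && all(ctIp > 0),
        "ctIp must contain finite positive Ct values")
  stopf(length(ctInput) >= 1L && all(is.finite(ctInput)) && all(ctInput > 0),
        "ctInput must contain finite positive Ct values")
  adj <- mean(ctInput) - log2(1 / inputFraction)
  pct <- 100 * 2^(adj - mean(ctIp))
  seExp <- sqrt(var(ctIp) / length(ctIp) + var(ctInput) / length(ctInput))
  list(percentInput = pct, sd = pct * log(2) * seExp, adjustedInputCt = adj)
}

#' Fold enrichment over a gene-desert control amplicon
#'
#' @param target,desertControl results from [percentInput()]; the control
#'   amplicon sits in a gene desert, so its percent input approximates the
#'   no-binding baseline.
#' @return The ratio of percent-input values.
#' @export
foldOverControl <- function(target, desertControl) {
  stopf(desertControl$percentInput > 0,
        "control percent input must be positive")
  target$percentInput / desertControl$percentInput
}

#' Relative expression by the 2^(-ddCt) method
#'
#' `dCt = mean(target Ct) - mean(reference Ct)` per condition;
#' `ddCt = dCt(treated) - dCt(control)`; fold change `2^(-ddCt)` (the
#' standard Livak sign convention: a target Ct one cycle lower in the
#' treated condition means a two-fold induction).
#'
#' @param ctTargetTreated,ctRefTreated,ctTargetControl,ctRefControl numeric
#'   vectors of replicate Ct values.
#' @return A list with `ddCt` and `fold`.
#' @examples
#' # knockdown: target up 2 cycles, reference unchanged -> fold 0.25
#' deltaDeltaCt(22, 15, 20, 15)$fold
#' @export
deltaDeltaCt <- function(ctTargetTreated, ctRefTreated, ctTargetControl,
                         ctRefControl) {
  for (x in list(ctTargetTreated, ctRefTreated, ctTargetControl,
                 ctRefControl)) {
    stopf(length(x) >= 1L && all(is.finite(x)),
          "all four Ct measurements must be present and finite")
  }
  ddCt <- (mean(ctTargetTreated) - mean(ctRefTreated)) -
    (mean(ctTargetControl) - mean(ctRefControl))
  list(ddCt = ddCt, fold = 2^(-ddCt))
}

#' Unpaired Student t-test with star annotation
#'
#' Classic pooled-variance two-sided unpaired t-test (`welch = TRUE` for
#' the unequal-variance variant). Stars: `*` p < 0.05, `**` p < 0.01,
#' `***` p < 0.001. Two identical constant groups are reported as t = 0,
#' p = 1 (the no-evidence limit).
#'
#' @param groupA,groupB numeric vectors, each of length >= 2.
#' @param welch use the Welch unequal-variance test instead.
#' @return A list with `t`, `p`, `stars`, `df`.
#' @examples
#' ttestUnpaired(c(1, 2, 3), c(101, 102, 103))$stars  # "***"
#' @export
ttestUnpaired <- function(groupA, groupB, welch = FALSE) {
  stopf(length(groupA) >= 2L && length(groupB) >= 2L,
        "each group needs at least 2 values")
  if (sd(groupA) == 0 && sd(groupB) == 0) {
    # degenerate: t.test() refuses constant data; take the defined limits
    if (mean(groupA) == mean(groupB)) {
      return(list(t = 0, p = 1, stars = "",
                  df = length(groupA) + length(groupB) - 2L))
    }
    return(list(t = sign(mean(groupA) - mean(groupB)) * Inf, p = 0,
                stars = "***",
                df = length(groupA) + length(groupB) - 2L))
  }
  ht <- t.test(groupA, groupB, var.equal = !welch)
  p <- ht$p.value
  list(t = unname(ht$statistic), p = p, stars = pStars(p),
       df = unname(ht$parameter))
}
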