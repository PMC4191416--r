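#' Standard-curve qPCR quantification
#'
#' `fitStandardCurve` fits the least-squares line of Ct on
#' log10(relative template amount) over a serial-dilution series and
#' reports the slope, intercept, amplification efficiency
#' (\eqn{10^{-1/slope} - 1}) and r-squared. Replicate points are fitted
#' jointly, without pre-averaging, so r2 reflects replicate scatter.
#' `quantifyRelative` inverts the line: `amount = 10^((ct - intercept) /
#' slope)`.
#'
#' @param relativeAmount positive relative template amounts of the
#'   dilution points (at least 3 points, at least 2 distinct amounts).
#' @param ct observed threshold cycles, parallel to `relativeAmount`.
#' @param primerPair label carried onto the curve.
#' @return `fitStandardCurve`: a [StandardCurve-class].
#' @examples
#' sc <- fitStandardCurve(c(1, 0.1, 0.01), c(20, 23.32, 26.64))
#' sc
#' quantifyRelative(21.66, sc)
#' @name qpcr
#' @export
fitStandardCurve <- function(relativeAmount, ct, primerPair = "") {
  if (length(relativeAmount) != length(ct))
    stop("relativeAmount and ct must be parallel")
  if (length(ct) < 3L) stop("a standard curve needs at least 3 points")
  if (any(relativeAmount <= 0))
    stop("relative amounts must be strictly positive")
  if (length(unique(relativeAmount)) < 2L)
    stop("degenerate design: all dilution amounts are equal")
  fit <- stats::lm(ct ~ log10(relativeAmount))
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  ss_tot <- sum((ct - mean(ct))^2)  # avoid summary.lm's perfect-fit warning
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::resid(fit)^2) / ss_tot
  pos <- slope > 0
  if (pos)
    warning("positive standard-curve slope for '", primerPair,
            "': Ct should fall as template rises")
  new("StandardCurve", primerPair = primerPair, slope = slope,
      intercept = intercept, efficiency = 10^(-1 / slope) - 1,
      r2 = r2, positiveSlope = pos)
}

#' @rdname qpcr
#' @param curve a [StandardCurve-class].
#' @return `quantifyRelative`: relative template amount(s).
#' @export
quantifyRelative <- function(ct, curve) {
  stopifnot(is(curve, "StandardCurve"))
  if (!is.finite(curve@slope) || curve@slope == 0)
    stop("degenerate standard curve (zero or non-finite slope)")
  10^((ct - curve@intercept) / curve@slope)
}

#' act1-normalized relative expression, reference sample set to 1
#'
#' Each sample's target amount is normalized to its act1 (reference
#' locus) amount, then to the same quotient in the reference sample, so
#' the reference maps to exactly 1 and common rescaling of all act1
#' amounts cancels.
#'
#' @param targetAmt,act1Amt named numeric vectors of relative amounts
#'   per sample (all > 0), with matching names.
#' @param reference name of the reference sample (conventionally the
#'   wild type).
#' @return named numeric vector of relative expression values.
#' @examples
#' relativeExpression(c(wt = 1, mut = 3), c(wt = 1, mut = 1.5), "wt")
#' @export
relativeExpression <- function(targetAmt, act1Amt, reference) {
  if (!reference %in% names(targetAmt) || !reference %in% names(act1Amt))
    stop("reference sample '", reference, "' not found")
  act1Amt <- act1Amt[names(targetAmt)]
  if (anyNA(act1Amt)) stop("act1 amount missing for some sample")
  if (any(targetAmt <= 0) || any(act1Amt <= 0))
    stop("amounts must be strictly positive")
  q <- targetAmt / act1Amt
  q / q[[reference]]
}

#' ChIP enrichment at a target locus
#'
#' The double ratio
#' \deqn{\frac{ChIP_{target} / WCE_{target}}{ChIP_{act1} / WCE_{act1}}}
#' immunoprecipitate signal over input at the target, normalized by the
#' same quotient at the act1 control locus. Invariant under any common
#' positive scaling of both ChIP amounts, or of both WCE amounts.
#'
#' @param chipTarget,wceTarget,chipAct1,wceAct1 strictly positive
#'   relative concentrations (vectors recycle as usual).
#' @return enrichment value(s).
#' @examples
#' chipEnrichment(5, 2, 3, 4)
#' @export
chipEnrichment <- function(chipTarget, wceTarget, chipAct1, wceAct1) {
  vals <- c(chipTarget, wceTarget, chipAct1, wceAct1)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all four quantities must be strictly positive")
  (chipTarget / wceTarget) / (chipAct1 / wceAct1)
}

#' Mean and standard deviation across experiment replicates
#'
#' Error-bar summary over repeated measurements of the same quantity
#' (relative expression or ChIP enrichment), e.g. three independent
#' experiments.
#'
#' @param values numeric replicate values.
#' @return a `data.frame` with `mean`, `sd`, `n`.
#' @export
summarizeReplicates <- function(values) {
  values <- values[!is.na(values)]
  data.frame(mean = mean(values),
             sd = if (length(values) > 1L) stats::sd(values) else NA_real_,
             n = length(values))
}

#' qPCR table readers
#'
#' `readDilutionSeries` reads a TSV with columns `primer_pair`,
#' `relative_amount`, `ct` and fits one standard curve per primer pair.
#' `readSampleCts` reads a TSV with columns `sample`, `primer_pair`,
#' `ct` and optionally `fraction` (`ChIP`/`WCE`) and returns it as a
#' data.frame for quantification against the fitted curves.
#'
#' @param path TSV path.
#' @return `readDilutionSeries`: named list of [StandardCurve-class],
#'   one per primer pair.
#' @name qpcrTables
#' @export
readDilutionSeries <- function(path) {
  df <- .read_tsv(path, c("primer_pair", "relative_amount", "ct"))
  lapply(split(df, df$primer_pair), function(d)
    fitStandardCurve(d$relative_amount, d$ct, d$primer_pair[1L]))
}

#' @rdname qpcrTables
#' @export
readSampleCts <- function(path) {
  .read_tsv(path, c("sample", "primer_pair", "ct"))
}
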