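#' Estimate steady-state abundance from the time-0 arrays
#'
#' Per transcript and condition, the mean of the 0-minute intensities across
#' replicates; abundance fold change is perturbed over reference, with the
#' signed +/- convention alongside. The 30-minute Act-D pretreatment
#' slightly depresses short-lived transcripts in both conditions; as both
#' conditions are treated identically this largely cancels in the ratio.
#'
#' @param x a \linkS4class{ChaseExperiment}.
#' @param conditions character(2): (reference, perturbed); defaults to the
#'   design stored in \code{x}.
#' @return data.frame: transcript_id, mean_t0_<ref>, mean_t0_<perturbed>,
#'   fc_abundance, signed_fc_abundance.
#' @export
abundanceAtT0 <- function(x, conditions = NULL) {
  cd <- SummarizedExperiment::colData(x)
  if (is.null(conditions)) {
    d <- chaseDesign(x)
    conditions <- if (!is.null(d)) conditionLabels(d) else unique(cd$condition)
  }
  if (!any(cd$time_min == 0)) stop("no time-0 arrays present")
  m <- intensities(x)
  means <- sapply(conditions, function(cc) {
    j <- which(cd$condition == cc & cd$time_min == 0)
    if (!length(j)) stop("no time-0 arrays for condition ", cc)
    rowMeans(m[, j, drop = FALSE], na.rm = TRUE)
  })
  fc <- means[, 2] / means[, 1]
  out <- data.frame(transcript_id = rownames(m),
                    ref = means[, 1], kd = means[, 2],
                    fc_abundance = fc,
                    signed_fc_abundance = signedFoldChange(fc),
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out)[2:3] <- paste0("mean_t0_", conditions)
  out
}

#' Census of abundance changes at a fold-change threshold
#'
#' Counts transcripts whose signed abundance fold change has magnitude at
#' least \code{threshold}, split into up- and down-regulated, and reports
#' the down-regulated fraction among the affected transcripts.
#'
#' @param results output of \code{\link{abundanceAtT0}}.
#' @param threshold fold-change magnitude threshold (>= 1).
#' @return list: threshold, n_total, n_affected, n_up, n_down,
#'   down_fraction.
#' @export
abundanceCensus <- function(results, threshold = 1.5) {
  if (!is.numeric(threshold) || threshold < 1)
    stop("threshold must be >= 1")
  s <- results$signed_fc_abundance
  up <- sum(s >= threshold, na.rm = TRUE)
  down <- sum(s <= -threshold, na.rm = TRUE)
  aff <- up + down
  list(threshold = threshold, n_total = sum(!is.na(s)), n_affected = aff,
       n_up = up, n_down = down,
       down_fraction = if (aff > 0) down / aff else NA_real_)
}

#' Infer the synthesis-rate fold change from abundance and half-life changes
#'
#' Under the first-order steady-state balance A = s * t1/2 / ln(2), the
#' synthesis-rate fold change is fc_s = fc_A / fc_t1/2. This is an
#' interpretive model: it converts a measured abundance change and half-life
#' change into the transcription-rate change required to explain them.
#'
#' @param fcAbundance positive abundance fold change(s).
#' @param fcThalf positive half-life fold change(s).
#' @return inferred synthesis fold change(s), vectorized.
#' @examples
#' inferSynthesisChange(1, 2)    # perfect buffering: synthesis halved
#' inferSynthesisChange(2, 2)    # stabilization fully explains abundance
#' @export
inferSynthesisChange <- function(fcAbundance, fcThalf) {
  if (any(!is.finite(fcAbundance) | fcAbundance <= 0) ||
      any(!is.finite(fcThalf) | fcThalf <= 0))
    stop("fold changes must be positive and finite")
  fcAbundance / fcThalf
}

#' Relate half-life changes to abundance changes across transcripts
#'
#' Joins the differential-stability comparisons with the time-0 abundance
#' table, computes the per-transcript inferred synthesis fold change, and
#' the Spearman rank correlation between half-life fold change and abundance
#' fold change over transcripts with a significant stability change (the
#' scatter-plot cohort). With fewer than 3 significant transcripts, or
#' degenerate (constant) fold changes, the correlation is reported as
#' undefined.
#'
#' @param comparisons output of \code{\link{compareHalfLives}}.
#' @param abundance output of \code{\link{abundanceAtT0}}.
#' @param alpha significance threshold defining the correlation cohort.
#' @param censusThreshold fold-change threshold for the abundance census.
#' @return a \linkS4class{CouplingResult}.
#' @export
couplingScatter <- function(comparisons, abundance, alpha = 0.05,
                            censusThreshold = 1.5) {
  idx <- match(comparisons$transcript_id, abundance$transcript_id)
  tab <- data.frame(
    transcript_id = comparisons$transcript_id,
    fc_thalf = comparisons$fc_thalf,
    fc_abundance = abundance$fc_abundance[idx],
    class_label = comparisons$class_label,
    ttest_p = comparisons$ttest_p,
    stringsAsFactors = FALSE)
  ok <- is.finite(tab$fc_thalf) & is.finite(tab$fc_abundance)
  tab$inferred_fc_synthesis <- NA_real_
  tab$inferred_fc_synthesis[ok] <-
    inferSynthesisChange(tab$fc_abundance[ok], tab$fc_thalf[ok])
  sig <- ok & !is.na(tab$ttest_p) & tab$ttest_p < alpha &
    tab$class_label %in% c("stabilized", "destabilized")
  corr <- list(rho = NA_real_, p = NA_real_, n = sum(sig),
               method = "spearman")
  if (sum(sig) >= 3 &&
      sd(log(tab$fc_thalf[sig])) > 0 &&
      sd(log(tab$fc_abundance[sig])) > 0) {
    ct <- suppressWarnings(
      cor.test(log(tab$fc_thalf[sig]), log(tab$fc_abundance[sig]),
               method = "spearman", exact = FALSE))
    corr$rho <- unname(ct$estimate)
    corr$p <- ct$p.value
  }
  new("CouplingResult", table = tab, correlation = corr,
      census = abundanceCensus(abundance, censusThreshold))
}

#' @rdname couplingScatter
#' @param x a \code{CouplingResult}.
#' @export
setMethod("couplingTable", "CouplingResult", function(x) x@table)

#' @rdname couplingScatter
#' @export
setMethod("couplingCorrelation", "CouplingResult", function(x) x@correlation)

#' @rdname couplingScatter
#' @export
setMethod("couplingCensus", "CouplingResult", function(x) x@census)

setMethod("show", "CouplingResult", function(object) {
  co <- object@correlation
  ce <- object@census
  cat("CouplingResult:", nrow(object@table), "transcripts\n")
  if (is.na(co$rho)) {
    cat("  rank correlation (significant cohort): undefined (n =",
        co$n, ")\n")
  } else {
    cat(sprintf("  Spearman rho = %.3f (p = %.3g, n = %d significant)\n",
                co$rho, co$p, co$n))
  }
  cat(sprintf("  >= %.2g-fold abundance changes: %d of %d (%d up, %d down; down fraction %.3f)\n",
              ce$threshold, ce$n_affected, ce$n_total, ce$n_up, ce$n_down,
              ifelse(is.na(ce$down_fraction), NaN, ce$down_fraction)))
})

#' Scatter plot of abundance versus half-life fold changes
#'
#' Log-log scatter of the per-transcript abundance fold change against the
#' half-life fold change, highlighting stabilized and destabilized
#' transcripts.
#'
#' @param x a \linkS4class{CouplingResult}.
#' @param ... passed to \code{plot}.
#' @return invisibly, the plotted table.
#' @export
plotCoupling <- function(x, ...) {
  tab <- x@table
  ok <- is.finite(tab$fc_thalf) & is.finite(tab$fc_abundance)
  tab <- tab[ok, ]
  col <- c(stabilized = "darkorange", destabilized = "forestgreen",
           unchanged = "grey60", unmatched = "grey85")[tab$class_label]
  graphics::plot(log2(tab$fc_thalf), log2(tab$fc_abundance), col = col,
                 pch = 16, xlab = "log2 fold change t1/2",
                 ylab = "log2 fold change abundance", ...)
  graphics::abline(h = 0, v = 0, lty = 3)
  invisible(tab)
}

#' Pre-mRNA consistency check for inferred transcription changes
#'
#' For each measured transcript, a two-sided two-sample t-test compares the
#' reference-normalized pre-mRNA quantities (a proxy for transcription rate)
#' between conditions, and the measured pre-mRNA fold change is compared in
#' sign with the synthesis fold change inferred from the steady-state model.
#' Agreement is \code{"agree"}/\code{"disagree"} when the test is
#' significant and both ratios move off 1, otherwise \code{"indeterminate"}.
#' With a single replicate per condition the test is skipped and only the
#' fold change reported.
#'
#' @param pre pre-mRNA table: transcript_id, condition, replicate,
#'   relative_quantity (see \code{\link{simulatePreMrna}}).
#' @param coupling a \linkS4class{CouplingResult}.
#' @param alpha significance threshold.
#' @param conditions character(2): (reference, perturbed); defaults to order
#'   of appearance.
#' @return data.frame: transcript_id, fc_premrna, premrna_p,
#'   inferred_fc_synthesis, agreement.
#' @export
premrnaConsistency <- function(pre, coupling, alpha = 0.05,
                               conditions = NULL) {
  if (any(!is.finite(pre$relative_quantity) | pre$relative_quantity <= 0))
    stop("relative_quantity must be positive")
  if (is.null(conditions)) conditions <- unique(pre$condition)
  ct <- couplingTable(coupling)
  ids <- unique(pre$transcript_id)
  res <- lapply(ids, function(id) {
    a <- pre$relative_quantity[pre$transcript_id == id &
                                 pre$condition == conditions[1]]
    b <- pre$relative_quantity[pre$transcript_id == id &
                                 pre$condition == conditions[2]]
    fc <- mean(b) / mean(a)
    p <- if (length(a) >= 2 && length(b) >= 2) {
      if (sd(a) == 0 && sd(b) == 0) {
        if (isTRUE(all.equal(mean(a), mean(b), tolerance = 1e-8))) 1 else 0
      } else t.test(a, b, var.equal = TRUE)$p.value
    } else NA_real_
    fcS <- ct$inferred_fc_synthesis[match(id, ct$transcript_id)]
    agree <- if (is.na(p) || p >= alpha || is.na(fcS) || fc == 1 || fcS == 1)
      "indeterminate"
    else if ((fc < 1) == (fcS < 1)) "agree" else "disagree"
    data.frame(transcript_id = id, fc_premrna = fc, premrna_p = p,
               inferred_fc_synthesis = fcS, agreement = agree,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
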