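#' Signed fold change
#'
#' Symmetric +/- convention for reporting ratios: ratios >= 1 are reported
#' as +ratio, ratios < 1 as -1/ratio, so the magnitude is always >= 1
#' (e.g. 0.5 becomes -2).
#'
#' @param ratio positive ratio(s).
#' @return signed fold change(s), vectorized.
#' @examples
#' signedFoldChange(c(2, 1, 0.5))
#' @export
signedFoldChange <- function(ratio) {
  if (any(!is.finite(ratio) | ratio <= 0))
    stop("ratio must be positive and finite")
  ifelse(ratio >= 1, ratio, -1 / ratio)
}

#' Compare half-lives between two conditions per transcript
#'
#' For transcripts with at least \code{minReliable} reliable replicate
#' half-lives in both conditions, runs a two-sided two-sample Student t-test
#' (pooled variance; Welch available) on the reliable replicate half-lives
#' and reports the fold change as the ratio of per-condition mean half-lives
#' (perturbed / reference). Transcripts lacking reliable half-lives in
#' either condition are classed \code{"unmatched"}. Degenerate zero-variance
#' groups follow the rule: equal means give p = 1, unequal means p = 0 (with
#' a warning). A Benjamini-Hochberg adjusted p-value is emitted for
#' information only; classification uses the raw p-value, mirroring the
#' original selection.
#'
#' @param fits per-replicate fit table from \code{\link{fitAll}}.
#' @param conditions character(2): (reference, perturbed); defaults to the
#'   order of appearance in \code{fits}.
#' @param alpha significance threshold for classification.
#' @param minReliable minimum reliable replicates per condition.
#' @param welch use Welch's t-test instead of pooled-variance Student.
#' @return data.frame with one row per transcript: ctrl_thalf, kd_thalf,
#'   fc_thalf (perturbed/reference), ttest_p, padj_bh, n_ctrl, n_kd,
#'   class_label in stabilized/destabilized/unchanged/unmatched.
#' @export
compareHalfLives <- function(fits, conditions = NULL, alpha = 0.05,
                             minReliable = 2, welch = FALSE) {
  if (is.null(conditions)) conditions <- unique(fits$condition)
  if (length(conditions) != 2)
    stop("need exactly two conditions; got ",
         paste(conditions, collapse = ", "))
  ids <- unique(fits$transcript_id)
  rel <- fits[fits$reliable & is.finite(fits$t_half), ]
  grpA <- split(rel$t_half[rel$condition == conditions[1]],
                rel$transcript_id[rel$condition == conditions[1]])
  grpB <- split(rel$t_half[rel$condition == conditions[2]],
                rel$transcript_id[rel$condition == conditions[2]])
  nDegenerate <- 0L
  one <- function(id) {
    a <- grpA[[id]]; b <- grpB[[id]]
    if (is.null(a) || is.null(b) || length(a) < minReliable ||
        length(b) < minReliable)
      return(list(NA_real_, NA_real_, NA_real_, NA_real_, length(a),
                  length(b), "unmatched"))
    ma <- mean(a); mb <- mean(b)
    fc <- mb / ma
    if (sd(a) == 0 && sd(b) == 0) {
      equal <- isTRUE(all.equal(ma, mb, tolerance = 1e-8))
      p <- if (equal) 1 else 0
      if (!equal) nDegenerate <<- nDegenerate + 1L
    } else {
      p <- tryCatch(
        t.test(a, b, var.equal = !welch)$p.value,
        error = function(e) if (isTRUE(all.equal(ma, mb, tolerance = 1e-8)))
          1 else 0)
    }
    cls <- if (p < alpha && fc > 1) "stabilized"
           else if (p < alpha && fc < 1) "destabilized"
           else "unchanged"
    list(ma, mb, fc, p, length(a), length(b), cls)
  }
  res <- lapply(ids, one)
  out <- data.frame(
    transcript_id = ids,
    ctrl_thalf = vapply(res, `[[`, numeric(1), 1),
    kd_thalf = vapply(res, `[[`, numeric(1), 2),
    fc_thalf = vapply(res, `[[`, numeric(1), 3),
    ttest_p = vapply(res, `[[`, numeric(1), 4),
    n_ctrl = vapply(res, function(r) as.integer(r[[5]]), integer(1)),
    n_kd = vapply(res, function(r) as.integer(r[[6]]), integer(1)),
    class_label = vapply(res, `[[`, character(1), 7),
    stringsAsFactors = FALSE)
  if (nDegenerate > 0)
    warning(nDegenerate, " transcript(s) had zero replicate variance with ",
            "unequal means; p reported as 0")
  out$padj_bh <- NA_real_
  tested <- !is.na(out$ttest_p)
  out$padj_bh[tested] <- p.adjust(out$ttest_p[tested], method = "BH")
  out[order(out$transcript_id), ]
}

#' Stabilized / destabilized transcript tables
#'
#' Splits significant comparisons into a stabilized and a destabilized
#' table, sorted by transcript id, with half-life fold changes reported to
#' two decimals (computed from the unrounded means) and, when an abundance
#' table is supplied, the signed abundance fold change.
#'
#' @param comparisons output of \code{\link{compareHalfLives}}.
#' @param abundance optional output of \code{\link{abundanceAtT0}}.
#' @param alpha significance threshold.
#' @return list with elements \code{stabilized}, \code{destabilized}
#'   (data.frames) and \code{counts}.
#' @export
stabilityTable <- function(comparisons, abundance = NULL, alpha = 0.05) {
  sig <- comparisons[!is.na(comparisons$ttest_p) &
                       comparisons$ttest_p < alpha &
                       comparisons$class_label %in%
                         c("stabilized", "destabilized"), ]
  fmt <- function(sub) {
    tab <- data.frame(transcript_id = sub$transcript_id,
                      ctrl_thalf = sub$ctrl_thalf,
                      kd_thalf = sub$kd_thalf,
                      ttest_p = sub$ttest_p,
                      fc_thalf = round(sub$fc_thalf, 2),
                      stringsAsFactors = FALSE)
    if (!is.null(abundance)) {
      idx <- match(tab$transcript_id, abundance$transcript_id)
      tab$signed_fc_abundance <-
        round(abundance$signed_fc_abundance[idx], 2)
    }
    tab[order(tab$transcript_id), ]
  }
  out <- list(stabilized = fmt(sig[sig$class_label == "stabilized", ]),
              destabilized = fmt(sig[sig$class_label == "destabilized", ]),
              counts = list(
                n_compared = sum(comparisons$class_label != "unmatched"),
                n_significant = nrow(sig),
                n_stabilized = sum(sig$class_label == "stabilized"),
                n_destabilized = sum(sig$class_label == "destabilized")))
  out
}
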