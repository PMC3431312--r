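#' Convert a qPCR Ct table to reference-normalized relative abundances
#'
#' Delta-Ct quantification: quantity = efficiency^-(Ct_target -
#' Ct_reference), with the reference gene playing the role of a stable
#' internal standard. Each (transcript, condition) series is then rescaled
#' so that the mean time-0 quantity over replicates equals 1, putting qPCR
#' series on the same footing as array series for the shared decay fitter.
#' Adding a constant to every Ct (target and reference alike) leaves all
#' quantities unchanged.
#'
#' @param ct data.frame with columns transcript_id, condition, replicate,
#'   time_min, ct_target, ct_reference.
#' @param efficiency amplification factor per cycle; 2 = perfect doubling.
#' @return data.frame: transcript_id, condition, replicate, time_min,
#'   relative_quantity.
#' @export
relativeAbundance <- function(ct, efficiency = 2.0) {
  if (!is.numeric(efficiency) || efficiency <= 1)
    stop("efficiency must be > 1")
  need <- c("transcript_id", "condition", "replicate", "time_min",
            "ct_target", "ct_reference")
  miss <- setdiff(need, names(ct))
  if (length(miss))
    stop("Ct table is missing column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(ct$ct_reference)))
    stop("missing or non-finite reference Ct")
  if (any(!is.finite(ct$ct_target)))
    stop("missing or non-finite target Ct")
  q <- efficiency^(-(ct$ct_target - ct$ct_reference))
  out <- data.frame(transcript_id = ct$transcript_id,
                    condition = ct$condition,
                    replicate = ct$replicate,
                    time_min = ct$time_min,
                    relative_quantity = q,
                    stringsAsFactors = FALSE)
  key <- paste(out$transcript_id, out$condition, sep = "\r")
  t0mean <- tapply(out$relative_quantity[out$time_min == 0],
                   key[out$time_min == 0], mean)
  out$relative_quantity <- out$relative_quantity / as.numeric(t0mean[key])
  out
}

#' Estimate half-lives from qPCR relative-abundance series
#'
#' Each (transcript, condition, replicate) series is fitted with the shared
#' first-order decay fitter; replicate fits are aggregated with the same
#' reliability rule as the array pipeline, reporting the per-condition mean
#' half-life with its standard error over the reliable replicates.
#'
#' @param series output of \code{\link{relativeAbundance}}.
#' @param alpha fit p-value threshold for reliability.
#' @param minReliable minimum reliable replicates per condition.
#' @return list with \code{fits} (per-replicate table as in
#'   \code{\link{fitAll}}) and \code{summary} (per transcript/condition:
#'   mean_thalf, se_thalf, n_reliable, condition_reliable).
#' @export
qpcrHalfLife <- function(series, alpha = 0.05, minReliable = 2) {
  key <- paste(series$transcript_id, series$condition, series$replicate,
               sep = "\r")
  sp <- split(seq_len(nrow(series)), key)
  rows <- lapply(sp, function(ii) {
    tt <- series$time_min[ii]
    yy <- series$relative_quantity[ii]
    ok <- is.finite(tt) & is.finite(yy) & yy > 0
    base <- data.frame(transcript_id = series$transcript_id[ii[1]],
                       condition = series$condition[ii[1]],
                       replicate = series$replicate[ii[1]],
                       stringsAsFactors = FALSE)
    if (sum(ok) < 3 || length(unique(tt[ok])) < 3)
      return(cbind(base, y0 = NA_real_, k = NA_real_, se_k = NA_real_,
                   t_half = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                   fit_p = NA_real_, converged = FALSE, reliable = FALSE))
    fr <- .fitSeries(tt[ok], yy[ok])
    p <- .fitP(fr$k, fr$seK, fr$n)
    ci <- .ciThalf(fr$k, fr$seK, fr$n)
    th <- if (is.finite(fr$k) && fr$k > 0) log(2) / fr$k else Inf
    cbind(base, y0 = fr$y0, k = fr$k, se_k = fr$seK, t_half = th,
          ci_lo = ci[1], ci_hi = ci[2], fit_p = p, converged = fr$converged,
          reliable = .reliable(fr$converged, p, ci[1], ci[2], th, alpha))
  })
  fits <- do.call(rbind, rows)
  rownames(fits) <- NULL
  fits <- fits[order(fits$transcript_id, fits$condition, fits$replicate), ]
  skey <- paste(fits$transcript_id, fits$condition, sep = "\r")
  sm <- lapply(split(seq_len(nrow(fits)), skey), function(ii) {
    rel <- fits$reliable[ii]
    th <- fits$t_half[ii][rel]
    data.frame(transcript_id = fits$transcript_id[ii[1]],
               condition = fits$condition[ii[1]],
               n_reliable = sum(rel),
               condition_reliable = sum(rel) >= minReliable,
               mean_thalf = if (length(th)) mean(th) else NA_real_,
               se_thalf = if (length(th) > 1) sd(th) / sqrt(length(th))
                          else NA_real_,
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, sm)
  rownames(summary) <- NULL
  list(fits = fits,
       summary = summary[order(summary$transcript_id, summary$condition), ])
}
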