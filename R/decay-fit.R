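# Core nonlinear least-squares machinery for y(t) = y0 * exp(-k t), k >= 0.
#
# The two-parameter model is fitted by profiling: for fixed k the optimal
# y0 has the closed form sum(y e)/sum(e^2) with e = exp(-k t), so the
# problem reduces to a 1-D minimization over k (golden-section/parabolic
# search on [0, kmax]), followed by full Gauss-Newton polishing with the
# analytic Jacobian. Standard errors come from the usual NLS curvature
# estimate s^2 (J'J)^-1 at the solution.

.profileSSE <- function(k, t, y) {
  e <- exp(-k * t)
  y0 <- sum(y * e) / sum(e * e)
  sum((y - y0 * e)^2)
}

.fitSeries <- function(t, y) {
  n <- length(y)
  # log-linear init; guard against non-positive values for the log only
  sl <- tryCatch(-lm.fit(cbind(1, t), log(pmax(y, 1e-12)))$coefficients[2],
                 error = function(e) NA_real_)
  k0 <- if (is.finite(sl)) max(sl, 1e-6) else 1e-3
  kmax <- max(4 * k0, log(2) / 1)  # allow half-lives down to 1 min
  op <- tryCatch(stats::optimize(.profileSSE, c(0, kmax), t = t, y = y,
                                 tol = 1e-9),
                 error = function(e) NULL)
  if (is.null(op))
    return(list(y0 = NA_real_, k = NA_real_, seK = NA_real_, rss = NA_real_,
                n = n, converged = FALSE))
  k <- op$minimum
  if (.profileSSE(0, t, y) <= op$objective + 1e-300) k <- 0
  e <- exp(-k * t)
  y0 <- sum(y * e) / sum(e * e)
  if (k > 0) {
    # Gauss-Newton polish
    for (it in 1:50) {
      e <- exp(-k * t); f <- y0 * e; r <- y - f
      J <- cbind(e, -y0 * t * e)
      step <- tryCatch(solve(crossprod(J), crossprod(J, r)),
                       error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
      y0n <- y0 + step[1]; kn <- k + step[2]
      if (kn < 0) { kn <- 0; y0n <- mean(y) }
      if (sum((y - y0n * exp(-kn * t))^2) <= sum(r^2) + 1e-300) {
        relstep <- max(abs(step[2]) / max(k, 1e-12),
                       abs(step[1]) / max(abs(y0), 1e-12))
        y0 <- y0n; k <- kn
        if (k == 0 || relstep < 1e-12) break
      } else break
    }
  }
  e <- exp(-k * t)
  if (k == 0) y0 <- mean(y)
  rss <- sum((y - y0 * e)^2)
  s2 <- rss / (n - 2)
  seK <- NA_real_
  if (k > 0) {
    J <- cbind(e, -y0 * t * e)
    V <- tryCatch(solve(crossprod(J)), error = function(e) NULL)
    if (!is.null(V) && is.finite(V[2, 2]) && V[2, 2] >= 0)
      seK <- sqrt(s2 * V[2, 2])
  }
  list(y0 = y0, k = k, seK = seK, rss = rss, n = n, converged = TRUE)
}

# one-sided Wald p for decay: H0 k = 0 vs k > 0, t distribution, n - 2 df
.fitP <- function(k, seK, n, warn = FALSE) {
  if (!is.finite(k)) return(NA_real_)
  if (k <= 0) return(1)
  if (is.na(seK)) return(NA_real_)
  if (seK == 0) {
    if (warn) warning("zero standard error with k > 0; p-value reported as 0")
    return(0)
  }
  pt(k / seK, df = n - 2, lower.tail = FALSE)
}

# Wald CI on k inverted to the half-life scale
.ciThalf <- function(k, seK, n, confidence = 0.95) {
  if (!is.finite(k) || k <= 0 || is.na(seK)) return(c(NA_real_, NA_real_))
  th <- log(2) / k
  if (seK == 0) return(c(th, th))
  tc <- qt(1 - (1 - confidence) / 2, df = n - 2)
  klo <- k - tc * seK
  khi <- k + tc * seK
  c(log(2) / khi, if (klo > 0) log(2) / klo else Inf)
}

.reliable <- function(converged, fitP, ciLo, ciHi, tHalf, alpha = 0.05) {
  isTRUE(converged) && is.finite(fitP) && fitP < alpha &&
    is.finite(ciLo) && is.finite(ciHi) && (ciHi - ciLo) < 2 * tHalf
}

#' Fit first-order decay to one time series
#'
#' Least-squares fit of y(t) = y0 * exp(-k t) in linear intensity space with
#' the decay rate constrained non-negative. A non-decaying series lands at
#' the k = 0 boundary with half-life +Inf (and is later treated as
#' unreliable). The standard error of k comes from the local curvature of
#' the least-squares objective at the solution.
#'
#' @param times sampling times in minutes (>= 3 distinct values).
#' @param values positive intensities, same length.
#' @param confidence confidence level for the half-life interval.
#' @param alpha significance threshold used only for printing reliability.
#' @return a \linkS4class{DecayFit}.
#' @examples
#' f <- fitDecay(c(0, 10, 50, 110, 230), 200 * 2^(-c(0, 10, 50, 110, 230) / 58))
#' halfLife(f)
#' @export
fitDecay <- function(times, values, confidence = 0.95, alpha = 0.05) {
  if (length(times) != length(values))
    stop("times and values must have the same length")
  ok <- is.finite(times) & is.finite(values)
  if (any(!ok)) stop("non-finite times or values")
  if (length(unique(times)) < 3)
    stop("need at least 3 distinct time points")
  if (any(values <= 0)) stop("values must be positive")
  fr <- .fitSeries(as.numeric(times), as.numeric(values))
  p <- .fitP(fr$k, fr$seK, fr$n, warn = TRUE)
  ci <- .ciThalf(fr$k, fr$seK, fr$n, confidence)
  new("DecayFit",
      y0 = fr$y0, k = fr$k,
      tHalf = if (is.finite(fr$k) && fr$k > 0) log(2) / fr$k else Inf,
      seK = fr$seK, ci95Thalf = ci, fitP = p, converged = fr$converged,
      nPoints = as.integer(fr$n), residualSS = fr$rss)
}

#' @rdname fitDecay
#' @param x a \code{DecayFit}.
#' @export
setMethod("halfLife", "DecayFit", function(x) x@tHalf)

#' @rdname fitDecay
#' @export
setMethod("decayRate", "DecayFit", function(x) x@k)

setMethod("show", "DecayFit", function(object) {
  cat(sprintf("DecayFit: t1/2 = %s min (k = %.4g/min, se_k = %.3g)\n",
              format(object@tHalf, digits = 4), object@k,
              object@seK))
  cat(sprintf("  95%% CI (%s, %s) min, fit p = %.3g, n = %d, converged = %s\n",
              format(object@ci95Thalf[1], digits = 4),
              format(object@ci95Thalf[2], digits = 4),
              object@fitP, object@nPoints, object@converged))
})

#' One-sided p-value for decay
#'
#' Tests H0: k = 0 against decay using the Wald statistic k/se_k referred to
#' a t distribution with n - 2 degrees of freedom. A fit at the k = 0
#' boundary has p = 1; a zero standard error with k > 0 gives p = 0 with a
#' warning.
#'
#' @param fit a \linkS4class{DecayFit}.
#' @param ... unused.
#' @return a probability.
#' @export
setMethod("fitPvalue", "DecayFit", function(fit, ...) {
  .fitP(fit@k, fit@seK, fit@nPoints, warn = TRUE)
})

#' Confidence interval for the half-life
#'
#' Wald interval on the decay rate k (k +/- t_crit * se_k, n - 2 df),
#' inverted to the half-life scale as (ln2/k_high, ln2/k_low). If the lower
#' rate bound is non-positive the upper half-life bound is +Inf. The
#' interval is built on k rather than directly on t1/2 because the half-life
#' sampling distribution is heavily right-skewed at n = 5.
#'
#' @param fit a \linkS4class{DecayFit}.
#' @param confidence confidence level.
#' @param ... unused.
#' @return numeric(2): (low, high) in minutes.
#' @export
setMethod("halfLifeCI", "DecayFit", function(fit, confidence = 0.95, ...) {
  .ciThalf(fit@k, fit@seK, fit@nPoints, confidence)
})

#' Reliability of a fitted half-life
#'
#' A fit is reliable iff it converged, its fit p-value is below \code{alpha},
#' and the 95% confidence interval for the half-life is narrower than two
#' times the half-life (an infinite upper bound fails).
#'
#' @param fit a \linkS4class{DecayFit}.
#' @param alpha fit p-value threshold.
#' @param ... unused.
#' @return logical.
#' @export
setMethod("isReliable", "DecayFit", function(fit, alpha = 0.05, ...) {
  .reliable(fit@converged, fit@fitP, fit@ci95Thalf[1], fit@ci95Thalf[2],
            fit@tHalf, alpha)
})

#' Fit decay to every transcript, condition and replicate
#'
#' Fits each series independently (per-series failures are recorded as
#' unreliable, never abort the batch), applies the reliability criteria, and
#' records the per-condition census of transcripts with reliable half-lives
#' as the \code{"census"} attribute of the result. Respects per-condition
#' \code{expressed_<condition>} flags left by \code{\link{detectionFilter}}:
#' a transcript is fitted only in conditions where it is expressed.
#'
#' @param x a \linkS4class{ChaseExperiment}.
#' @param alpha fit p-value threshold for reliability.
#' @param confidence confidence level for half-life intervals.
#' @return data.frame with one row per (transcript, condition, replicate):
#'   y0, k, se_k, t_half, ci_lo, ci_hi, fit_p, converged, reliable.
#' @export
fitAll <- function(x, alpha = 0.05, confidence = 0.95) {
  m <- intensities(x)
  cd <- SummarizedExperiment::colData(x)
  rd <- SummarizedExperiment::rowData(x)
  conds <- unique(cd$condition)
  reps <- sort(unique(cd$replicate))
  ids <- rownames(m)
  series <- list()
  for (cc in conds) for (rr in reps) {
    j <- which(cd$condition == cc & cd$replicate == rr)
    series[[paste(cc, rr)]] <- list(cond = cc, rep = rr,
                                    j = j[order(cd$time_min[j])],
                                    t = sort(cd$time_min[j]))
  }
  expressed <- sapply(conds, function(cc) {
    col <- paste0("expressed_", cc)
    if (col %in% names(rd)) rd[[col]] else rep(TRUE, nrow(m))
  })
  colnames(expressed) <- conds

  nOut <- sum(sapply(conds, function(cc) sum(expressed[, cc]))) * length(reps)
  out <- data.frame(transcript_id = character(nOut), condition = character(nOut),
                    replicate = integer(nOut), y0 = numeric(nOut),
                    k = numeric(nOut), se_k = numeric(nOut),
                    t_half = numeric(nOut), ci_lo = numeric(nOut),
                    ci_hi = numeric(nOut), fit_p = numeric(nOut),
                    converged = logical(nOut), reliable = logical(nOut),
                    stringsAsFactors = FALSE)
  nZeroSE <- 0L
  row <- 0L
  for (s in series) {
    keep <- which(expressed[, s$cond])
    for (i in keep) {
      y <- m[i, s$j]
      ok <- is.finite(y) & y > 0
      row <- row + 1L
      if (sum(ok) < 3 || length(unique(s$t[ok])) < 3) {
        out[row, ] <- list(ids[i], s$cond, s$rep, NA_real_, NA_real_,
                           NA_real_, NA_real_, NA_real_, NA_real_, NA_real_,
                           FALSE, FALSE)
        next
      }
      fr <- .fitSeries(s$t[ok], y[ok])
      if (isTRUE(fr$converged) && fr$k > 0 && identical(fr$seK, 0))
        nZeroSE <- nZeroSE + 1L
      p <- .fitP(fr$k, fr$seK, fr$n)
      ci <- .ciThalf(fr$k, fr$seK, fr$n, confidence)
      th <- if (is.finite(fr$k) && fr$k > 0) log(2) / fr$k else Inf
      out[row, ] <- list(ids[i], s$cond, s$rep, fr$y0, fr$k, fr$seK, th,
                         ci[1], ci[2], p,
                         fr$converged,
                         .reliable(fr$converged, p, ci[1], ci[2], th, alpha))
    }
  }
  out <- out[seq_len(row), ]
  if (nZeroSE > 0)
    warning(nZeroSE, " series had zero residual error (se_k = 0); ",
            "fit p-values reported as 0")
  relByCond <- lapply(conds, function(cc) {
    sub <- out[out$condition == cc, ]
    tapply(sub$reliable, sub$transcript_id, sum) >= 2
  })
  names(relByCond) <- conds
  common <- Reduce(intersect, lapply(relByCond, function(v) names(v)[v]))
  census <- c(setNames(lapply(relByCond, sum),
                       paste0("n_reliable_", conds)),
              list(n_reliable_both = length(common)))
  attr(out, "census") <- census
  out
}

#' Summarize replicate fits per transcript and condition
#'
#' Applies the replicate rule: a condition's half-life is accepted when at
#' least \code{minReliable} replicates have reliable fits; the condition
#' half-life is the mean over the reliable replicates only.
#'
#' @param fits output of \code{\link{fitAll}}.
#' @param minReliable minimum reliable replicates per condition.
#' @return data.frame with one row per (transcript, condition): n_fits,
#'   n_reliable, condition_reliable, mean_thalf, sd_thalf.
#' @export
summarizeStability <- function(fits, minReliable = 2) {
  key <- paste(fits$transcript_id, fits$condition, sep = "\r")
  sp <- split(seq_len(nrow(fits)), key)
  res <- lapply(sp, function(ii) {
    rel <- fits$reliable[ii]
    th <- fits$t_half[ii][rel]
    data.frame(transcript_id = fits$transcript_id[ii[1]],
               condition = fits$condition[ii[1]],
               n_fits = length(ii),
               n_reliable = sum(rel),
               condition_reliable = sum(rel) >= minReliable,
               mean_thalf = if (length(th)) mean(th) else NA_real_,
               sd_thalf = if (length(th) > 1) sd(th) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$transcript_id, out$condition), ]
}
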