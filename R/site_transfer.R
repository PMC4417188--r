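#' Apparent site-transfer probability from band fractions at one timepoint
#'
#' The apparent intramolecular transfer probability computed from the molar
#' band fractions of a dual-end-labelled two-site substrate:
#' \deqn{P_{trans}^{obs} = \frac{A + C - AB - BC}{A + C + AB + BC}}
#' The full-length band cancels by construction and does not enter. The
#' estimator is invariant to rescaling all fractions at a timepoint by a
#' common factor (so lane-to-lane loading differences drop out).
#'
#' @param A,C,AB,BC Band fractions (or volumes on a common scale); may be
#'   vectors over timepoints.
#' @return `P_trans_obs`, `NA` where all four fragments are zero (undefined,
#'   reported as missing rather than zero).
#' @export
#' @examples
#' compute_ptrans_obs(A = 0.3, C = 0.3, AB = 0.1, BC = 0.1)  # 0.5
compute_ptrans_obs <- function(A, C, AB, BC) {
  denom <- A + C + AB + BC
  out <- (A + C - AB - BC) / denom
  out[denom <= 0] <- NA_real_
  out
}

#' Zero-time extrapolation of apparent transfer probabilities
#'
#' Unweighted ordinary least-squares line of `P_trans_obs` against time;
#' the intercept is the transfer probability free of inflation by
#' independent enzyme rebinding, the slope a diagnostic of that inflation.
#' An alternative regressor — fraction of substrate consumed — is available
#' via `regressor = "extent"` (requires `extent`), but time is the default.
#'
#' @param p_obs Apparent transfer probabilities per timepoint. Negative
#'   values from noise are retained (clamping before regression would bias
#'   the intercept).
#' @param times Times in seconds.
#' @param regressor `"time"` (default) or `"extent"`.
#' @param extent Fraction of substrate consumed per timepoint (used when
#'   `regressor = "extent"`).
#' @return List with `P_trans` (intercept), `se`, `slope`, `slope_se`,
#'   `n_used`, `fit` (the `lm` object), and `P_trans_clamped` (intercept
#'   clamped to \[0, 1\]; the raw value is preserved in `P_trans`).
#' @export
#' @examples
#' extrapolate_zero_time(c(0.30, 0.35, 0.40), times = c(1, 2, 3))$P_trans
extrapolate_zero_time <- function(p_obs, times, regressor = c("time", "extent"),
                                  extent = NULL) {
  regressor <- match.arg(regressor)
  x <- if (regressor == "time") times else {
    if (is.null(extent)) stop("extent required when regressor = 'extent'")
    extent
  }
  stopifnot(length(p_obs) == length(x))
  ok <- is.finite(p_obs) & is.finite(x)
  if (any(!ok)) warning(sum(!ok), " non-finite point(s) excluded")
  if (sum(ok) < 3) stop("need at least 3 valid timepoints for extrapolation")
  fit <- lm(y ~ x, data = data.frame(y = p_obs[ok], x = x[ok]))
  # exactly-linear input triggers summary.lm's perfect-fit warning
  cf <- suppressWarnings(summary(fit)$coefficients)
  list(P_trans = unname(cf[1, 1]), se = unname(cf[1, 2]),
       slope = unname(cf[2, 1]), slope_se = unname(cf[2, 2]),
       n_used = sum(ok), fit = fit,
       P_trans_clamped = min(max(cf[1, 1], 0), 1))
}

#' Full transfer analysis of a fragment timecourse
#'
#' Convenience wrapper: Eq.-1-style apparent transfer probabilities per
#' timepoint, then zero-time extrapolation.
#'
#' @param tc A [fragment_timecourse()].
#' @param n_molecules Number of substrate molecules behind the band
#'   fractions (defaults to the simulation config attribute when present).
#'   When known, a binomial Monte-Carlo standard error of the intercept
#'   (`se_mc`) is computed by propagating the per-timepoint counting
#'   variance `p(1-p)/m_reacted` through the OLS intercept weights; the
#'   regression `se` alone understates the sampling error of correlated
#'   cumulative counts.
#' @inheritParams extrapolate_zero_time
#' @return A `transfer_result` list: `p_obs`, `times`, the extrapolation
#'   fields of [extrapolate_zero_time()], `se_mc` (NA when `n_molecules`
#'   unknown), `trap_on`, `site_spacing`, `condition`.
#' @export
transfer_analysis <- function(tc, regressor = c("time", "extent"),
                              n_molecules = NULL) {
  stopifnot(inherits(tc, "fragment_timecourse"))
  regressor <- match.arg(regressor)
  p_obs <- compute_ptrans_obs(tc$A, tc$C, tc$AB, tc$BC)
  # molecule total on the band scale: intact + singles + doubles
  # = full_length + AB + A (since doubles = A - BC and singles = AB + BC)
  tot <- tc$full_length + tc$A + tc$AB
  ext <- ifelse(tot > 0, 1 - tc$full_length / tot, NA_real_)
  res <- extrapolate_zero_time(p_obs, tc$time_s, regressor = regressor,
                               extent = ext)
  if (is.null(n_molecules)) {
    n_molecules <- attr(tc, "config")$n_molecules
  }
  se_mc <- NA_real_
  if (!is.null(n_molecules) && is.finite(n_molecules)) {
    reacted <- ifelse(tot > 0, (tc$A + tc$AB) / tot, NA_real_)
    m <- pmax(round(n_molecules * reacted), 1)
    x <- if (regressor == "time") tc$time_s else ext
    ok <- is.finite(p_obs) & is.finite(x) & is.finite(m)
    if (sum(ok) >= 3) {
      xo <- x[ok]; po <- pmin(pmax(p_obs[ok], 1e-6), 1 - 1e-6)
      cw <- 1 / sum(ok) - mean(xo) * (xo - mean(xo)) / sum((xo - mean(xo))^2)
      se_mc <- sqrt(sum(cw^2 * po * (1 - po) / m[ok]))
    }
  }
  structure(c(list(p_obs = p_obs, times = tc$time_s), res,
              list(se_mc = se_mc,
                   trap_on = attr(tc, "trap_on"),
                   site_spacing = attr(tc, "site_spacing"),
                   condition = attr(tc, "condition"))),
            class = "transfer_result")
}

#' Partition the overall transfer probability into pathways
#'
#' The overall transfer probability (trap-off) is the sum of the
#' associative and dissociative pathway probabilities; the saturating
#' molecular-clock trap isolates the associative pathway, so
#' `P_diss = P_trans - P_assoc`, with standard errors propagated in
#' quadrature. Values are reported unclamped; a `P_assoc` exceeding
#' `P_trans` beyond the propagated error triggers a warning, not an error.
#'
#' @param P_trans Zero-time intercept from the trap-off series.
#' @param P_assoc Zero-time intercept from the matched trap-on series.
#' @param se_trans,se_assoc Standard errors of the two intercepts.
#' @return List with `P_diss`, `se`, and the inputs.
#' @export
#' @examples
#' partition_pathways(P_trans = 0.8, P_assoc = 0.7)$P_diss  # 0.1
partition_pathways <- function(P_trans, P_assoc, se_trans = 0, se_assoc = 0) {
  P_diss <- P_trans - P_assoc
  se <- sqrt(se_trans^2 + se_assoc^2)
  if (P_diss < -se && se >= 0) {
    warning("P_assoc exceeds P_trans beyond propagated error; ",
            "reporting the unclamped difference")
  }
  list(P_diss = P_diss, se = se, P_trans = P_trans, P_assoc = P_assoc)
}

#' Correct an observed transfer probability for excision efficiency
#'
#' Observed transfer probabilities are attenuated by the per-encounter
#' excision efficiency: `P_trans_obs = E * P_trans_true`, so
#' `P_trans_true = P_trans / E`. A corrected value above 1 indicates an
#' inconsistent efficiency estimate and is flagged.
#'
#' @param P_trans Observed (zero-time) transfer probability.
#' @param E Excision efficiency, 0 < E <= 1.
#' @return List with `P_trans_true`, `flagged` (TRUE if > 1), and inputs.
#' @export
#' @examples
#' correct_efficiency(0.4, E = 0.81)$P_trans_true  # 0.494
correct_efficiency <- function(P_trans, E) {
  if (!(E > 0 && E <= 1)) stop("E must lie in (0, 1]")
  val <- P_trans / E
  flagged <- val > 1
  if (flagged) warning("corrected P_trans exceeds 1: efficiency inconsistent")
  list(P_trans_true = val, flagged = flagged, P_trans = P_trans, E = E)
}

#' @export
print.transfer_result <- function(x, ...) {
  cat("Site transfer analysis (", x$condition, ", spacing ",
      x$site_spacing, " bp, trap ", if (isTRUE(x$trap_on)) "on" else "off",
      ")\n", sep = "")
  cat(sprintf("  P_trans (zero-time) = %.4f +/- %.4f  (slope %.2e /s)\n",
              x$P_trans, x$se, x$slope))
  invisible(x)
}
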