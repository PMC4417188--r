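# Nonlinear fitting of stopped-flow, steady-state, binding and ISE data.
# All nonlinear fits go through Levenberg-Marquardt least squares
# (minpack.lm::nls.lm) on residual functions with analytic starting values,
# positivity bounds on rates, and dimensionless internal parameter scaling
# so the Jacobian stays well conditioned when parameters span many orders
# of magnitude (k_on ~ 1e9 M^-1 s^-1 next to signal offsets ~ 1).

lm_least_squares <- function(resid_fn, start, lower = NULL, upper = NULL,
                             maxiter = 1000) {
  if (is.null(lower)) lower <- rep(-Inf, length(start))
  if (is.null(upper)) upper <- rep(Inf, length(start))
  nls_out <- minpack.lm::nls.lm(
    par = start, fn = resid_fn, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = maxiter,
                                         ftol = 1e-12, ptol = 1e-12))
  if (nls_out$info %in% c(0, 5)) {
    stop("nonlinear fit did not converge (", nls_out$message,
         "); starting values were: ",
         paste(names(start), signif(unlist(start), 4),
               sep = " = ", collapse = ", "))
  }
  est <- unlist(nls_out$par)
  rss <- sum(nls_out$fvec^2)
  n <- length(nls_out$fvec); np <- length(est)
  sigma2 <- rss / max(n - np, 1)
  # eigen pseudo-inverse of J'J: robust where a perfect (zero-residual)
  # fit leaves the Hessian numerically semi-definite
  ev <- eigen(nls_out$hessian, symmetric = TRUE)
  pos <- ev$values > max(abs(ev$values)) * 1e-12
  pinv_diag <- rowSums((ev$vectors[, pos, drop = FALSE]^2) %*%
                         diag(1 / ev$values[pos], nrow = sum(pos)))
  se <- sqrt(pmax(sigma2 * pinv_diag, 0))
  names(se) <- names(est)
  list(estimate = est, se = se, rss = rss, obj = nls_out)
}

aicc <- function(rss, n, p) {
  # p counts mean-function parameters; +1 for sigma
  k <- p + 1
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# Floor the RSS at the square of a tiny fraction of the signal range so
# that model selection on effectively-noiseless data (RSS at rounding
# level for every candidate) falls back to the simpler model instead of
# comparing numerical noise.
rss_floor <- function(y, n) n * (1e-8 * diff(range(y)))^2

#' Fit an equal-concentration second-order association trace
#'
#' Fits the irreversible equal-concentration second-order binding signal
#' \deqn{Y(t) = Y_f - \frac{Y_f - Y_0}{k_{on} P_0 t + 1}}
#' for `k_on`, `Y0` and `Yf` by Levenberg-Marquardt least squares.
#' Internally the pseudo-first-order rate `kappa = k_on * P0` (s^-1) is
#' fitted and converted back. Starting values: `Y0`, `Yf` from the trace
#' endpoints, `kappa` from the half-signal crossing time.
#'
#' @param trace A [kinetic_trace()] with attribute `P0`, or a data frame
#'   with `time_s` and `signal` plus `P0` supplied here.
#' @param P0 Molar concentration of each partner; defaults to the trace
#'   attribute.
#' @return A `fit_result` list: `model = "second_order"`, `parameters`
#'   (`k_on` in M^-1 s^-1, `Y0`, `Yf`), `se`, `rss`, `fitted`.
#' @export
#' @examples
#' tr <- simulate_association_trace(2.7e9, 200e-9, 0, 1,
#'                                  times = seq(0, 0.02, length.out = 200))
#' fit_second_order(tr)$parameters["k_on"]
fit_second_order <- function(trace, P0 = attr(trace, "P0")) {
  t <- trace$time_s; y <- trace$signal
  if (is.null(P0) || !is.finite(P0) || P0 <= 0) stop("P0 must be known and > 0")
  amp <- y[length(y)] - y[1]
  if (abs(amp) < 1e-12 * max(abs(y), 1e-300)) {
    stop("zero-amplitude trace: k_on unidentifiable (Y0 = Yf)")
  }
  y0s <- y[1]; yfs <- y[length(y)]
  half <- which.min(abs(y - (y0s + yfs) / 2))
  th <- max(t[half], t[t > 0][1])
  model <- function(p) p[["Yf"]] - (p[["Yf"]] - p[["Y0"]]) / (p[["kappa"]] * t + 1)
  fit <- lm_least_squares(function(p) y - model(p),
                          start = c(kappa = 1 / th, Y0 = y0s, Yf = yfs),
                          lower = c(0, -Inf, -Inf))
  est <- fit$estimate; se <- fit$se
  est[["kappa"]] <- est[["kappa"]] / P0
  se[["kappa"]] <- se[["kappa"]] / P0
  names(est)[names(est) == "kappa"] <- names(se)[names(se) == "kappa"] <- "k_on"
  if (est[["k_on"]] <= 0) warning("k_on at bound; fit suspect")
  structure(list(model = "second_order", parameters = est, se = se,
                 rss = fit$rss, fitted = y - fit$obj$fvec, P0 = P0),
            class = "fit_result")
}

est_decay_rate <- function(t, y, baseline) {
  z <- y - baseline
  keep <- z > max(z, na.rm = TRUE) * 0.02
  if (sum(keep) < 3) return(1 / max(t[t > 0]))
  -unname(coef(lm(log(z[keep]) ~ t[keep]))[2])
}

#' Fit single- and double-exponential decays with AICc model selection
#'
#' Fits \eqn{Y = a_1 e^{-k_1 t} + c} and (if `max_components = 2`)
#' \eqn{Y = a_f e^{-k_{fast} t} + a_s e^{-k_{slow} t} + c}, selects between
#' them by AICc, and reports both fits. Components are labelled so that
#' `k_fast > k_slow`; the slow-phase amplitude fraction
#' `a_slow / (a_fast + a_slow)` is reported for the biphasic model. A
#' selected biphasic fit with rate separation below 3-fold triggers an
#' identifiability warning.
#'
#' @param trace A [kinetic_trace()] (or data frame with `time_s`, `signal`).
#' @param max_components 1 or 2.
#' @return A `fit_result` list with `model` (`"exp1"` or `"exp2"`, the AICc
#'   winner), `parameters`, `se`, `rss`, `aicc` (both candidates),
#'   `selected_components`, and `slow_fraction` (biphasic winner only).
#' @export
#' @examples
#' tr <- simulate_dissociation_trace(1.01, 1, times = seq(0, 6, length.out = 300))
#' fit_exponentials(tr)$parameters["k1"]
fit_exponentials <- function(trace, max_components = 2) {
  t <- trace$time_s; y <- trace$signal
  n <- length(y)
  if (n < 10) stop("need >= 10 points per decay phase")
  amp <- y[1] - y[length(y)]
  if (abs(amp) < 1e-12 * max(abs(y), 1e-300) || diff(range(y)) == 0) {
    stop("zero-amplitude (flat) trace: no decay to fit")
  }
  c0 <- mean(tail(y, max(3, n %/% 20)))
  k10 <- est_decay_rate(t, y, c0)
  f1 <- lm_least_squares(
    function(p) y - (p[["a1"]] * exp(-p[["k1"]] * t) + p[["c"]]),
    start = c(a1 = amp, k1 = k10, c = c0),
    lower = c(-Inf, 1e-12, -Inf))
  rssf <- rss_floor(y, n)
  a1c <- aicc(max(f1$rss, rssf), n, 3)

  out <- list(model = "exp1", selected_components = 1L,
              parameters = f1$estimate, se = f1$se,
              rss = f1$rss, aicc = c(exp1 = a1c),
              fits = list(exp1 = f1))

  if (max_components >= 2) {
    k1hat <- f1$estimate[["k1"]]
    f2 <- tryCatch(lm_least_squares(
      function(p) y - (p[["af"]] * exp(-p[["kf"]] * t) +
                         p[["as"]] * exp(-p[["ks"]] * t) + p[["c"]]),
      start = c(af = amp / 2, kf = k1hat * 5, as = amp / 2,
                ks = k1hat / 5, c = c0),
      lower = c(-Inf, 1e-12, -Inf, 1e-12, -Inf)),
      error = function(e) NULL)
    if (!is.null(f2)) {
      a2c <- aicc(max(f2$rss, rssf), n, 5)
      out$aicc <- c(exp1 = a1c, exp2 = a2c)
      out$fits$exp2 <- f2
      cf <- f2$estimate; se2 <- f2$se
      # enforce k_fast > k_slow labelling (ties broken by amplitude)
      ord <- if (cf[["kf"]] >= cf[["ks"]]) c("kf", "ks", "af", "as", "c")
             else c("ks", "kf", "as", "af", "c")
      cf <- cf[ord]; se2 <- se2[ord]
      names(cf) <- names(se2) <-
        c("k_fast", "k_slow", "a_fast", "a_slow", "offset")
      if (a2c < a1c) {
        sep <- cf[["k_fast"]] / cf[["k_slow"]]
        if (is.finite(sep) && sep < 3) {
          warning("rate separation < 3-fold: biphasic fit weakly identifiable")
        }
        out$model <- "exp2"
        out$selected_components <- 2L
        out$parameters <- cf
        out$se <- se2
        out$rss <- f2$rss
        out$slow_fraction <-
          unname(cf[["a_slow"]] / (cf[["a_fast"]] + cf[["a_slow"]]))
      }
    }
  }
  class(out) <- "fit_result"
  out
}

#' Michaelis-Menten steady-state fit and relative parameters
#'
#' Full mode fits \eqn{v = k_{cat} [E]_0 [S] / (K_m + [S])} to an
#' initial-rate table (>= 5 substrate concentrations). `kcat_only` mode
#' averages rates at saturating substrate (>= 2 determinations that must
#' agree within `sat_tol`, mirroring the experimental check that the rate
#' is concentration-independent at saturation).
#'
#' @param rates Data frame with `conc_M` (substrate, M) and `rate_Ms` (M/s).
#' @param E0 Enzyme concentration, M.
#' @param mode `"full"` or `"kcat_only"`.
#' @param sat_tol Maximum fractional disagreement of saturating rates
#'   tolerated in `kcat_only` mode (default 0.2).
#' @return An `mm_result` list: `k_cat` (s^-1), `K_m` (M),
#'   `k_cat_over_K_m` (M^-1 s^-1), per-parameter `se`.
#' @export
fit_michaelis_menten <- function(rates, E0, mode = c("full", "kcat_only"),
                                 sat_tol = 0.2) {
  mode <- match.arg(mode)
  S <- rates$conc_M; v <- rates$rate_Ms
  stopifnot(E0 > 0, all(S > 0))
  if (mode == "kcat_only") {
    if (length(v) < 2) stop("kcat_only mode needs >= 2 saturating rates")
    if (max(v) / min(v) - 1 > sat_tol) {
      stop("saturating rates disagree by more than ", sat_tol * 100,
           "%: not at saturation; kcat_only mode refuses")
    }
    kcat <- mean(v) / E0
    return(structure(list(k_cat = kcat,
                          K_m = NA_real_, k_cat_over_K_m = NA_real_,
                          se = c(k_cat = stats::sd(v / E0) / sqrt(length(v))),
                          mode = mode), class = "mm_result"))
  }
  if (length(S) < 5) stop("full MM fit needs >= 5 substrate concentrations")
  # dimensionless parameterization: vmax in units of the max observed rate,
  # Km in units of the half-max substrate guess
  vs <- max(v)
  km0 <- S[which.min(abs(v - max(v) / 2))]
  fit <- lm_least_squares(
    function(p) v / vs - p[["vmaxs"]] * S / (p[["Kms"]] * km0 + S),
    start = c(vmaxs = 1, Kms = 1), lower = c(0, 1e-12))
  kcat <- fit$estimate[["vmaxs"]] * vs / E0
  km <- fit$estimate[["Kms"]] * km0
  if (km > 5 * max(S)) {
    warning("K_m exceeds the substrate range: K_m unidentifiable ",
            "(all [S] << K_m)")
  }
  structure(list(k_cat = kcat, K_m = km, k_cat_over_K_m = kcat / km,
                 se = c(k_cat = fit$se[["vmaxs"]] * vs / E0,
                        K_m = fit$se[["Kms"]] * km0),
                 mode = mode, rss = fit$rss * vs^2),
            class = "mm_result")
}

#' @rdname fit_michaelis_menten
#' @param crowded,buffer `mm_result` objects for the matched crowded and
#'   dilute-buffer conditions.
#' @return `relative_params` returns the element-wise crowded/buffer ratios
#'   `k_cat_rel`, `K_m_rel`, `k_cat_over_K_m_rel`.
#' @export
relative_params <- function(crowded, buffer) {
  stopifnot(inherits(crowded, "mm_result"), inherits(buffer, "mm_result"))
  list(k_cat_rel = crowded$k_cat / buffer$k_cat,
       K_m_rel = crowded$K_m / buffer$K_m,
       k_cat_over_K_m_rel = crowded$k_cat_over_K_m / buffer$k_cat_over_K_m)
}

#' Fit a 1:1 binding isotherm to an anisotropy titration
#'
#' \deqn{r = r_{free} + (r_{bound} - r_{free}) [P] / (K_D + [P])} with an
#' optional ligand-depletion correction (quadratic free-protein solution at
#' labelled-DNA concentration `L0`). `K_D` is fitted internally in units of
#' its half-saturation starting guess for Jacobian conditioning.
#'
#' @param curve Data frame with `conc_M` (protein, M) and `anisotropy`.
#' @param L0 Labelled DNA concentration, M; 0 fits the no-depletion isotherm.
#' @return A `fit_result` list with `K_D` (M), `r_free`, `r_bound`, `se`.
#' @export
fit_titration <- function(curve, L0 = 0) {
  p <- curve$conc_M; r <- curve$anisotropy
  stopifnot(all(p > 0))
  if (diff(range(r)) < 1e-12 * max(abs(r), 1e-300)) {
    stop("zero-amplitude titration: K_D unidentifiable")
  }
  kd0 <- p[which.min(abs(r - (min(r) + max(r)) / 2))]
  frac_bound <- function(P, KD) {
    if (L0 > 0) {
      b <- KD + L0 - P
      pf <- (-b + sqrt(b^2 + 4 * KD * P)) / 2
      pf / (KD + pf)
    } else P / (KD + P)
  }
  fit <- lm_least_squares(
    function(th) r - (th[["rf"]] + (th[["rb"]] - th[["rf"]]) *
                        frac_bound(p, th[["KDs"]] * kd0)),
    start = c(rf = min(r), rb = max(r), KDs = 1),
    lower = c(-Inf, -Inf, 1e-12))
  kd <- fit$estimate[["KDs"]] * kd0
  if (max(p) < 5 * kd) {
    warning("titration does not reach saturation; K_D confidence wide")
  }
  structure(list(model = "isotherm_1to1", K_D = kd,
                 r_free = fit$estimate[["rf"]],
                 r_bound = fit$estimate[["rb"]],
                 se = c(K_D = fit$se[["KDs"]] * kd0),
                 rss = fit$rss),
            class = "fit_result")
}

#' Ion-selective electrode semi-log calibration and activity ratio
#'
#' Fits the Nernstian semi-log response mV = b + m log10(conc) by OLS.
#' `fit_ise_pair` returns both slopes and the crowded/dilute slope ratio,
#' which reports the ion activity-coefficient ratio between conditions.
#' Slopes are per decade of concentration.
#'
#' @param series Data frame with `conc` (> 0) and `mV` (>= 4 standards).
#' @return `fit_ise`: list with `slope` (mV/decade), `slope_se`,
#'   `intercept`, `fit`.
#' @export
fit_ise <- function(series) {
  stopifnot(all(series$conc > 0))
  if (nrow(series) < 4) stop("need >= 4 ISE standards")
  fit <- lm(mV ~ log10(conc), data = series)
  # noiseless calibrations trigger summary.lm's perfect-fit warning
  cf <- suppressWarnings(summary(fit)$coefficients)
  list(slope = unname(cf[2, 1]), slope_se = unname(cf[2, 2]),
       intercept = unname(cf[1, 1]), fit = fit)
}

#' @rdname fit_ise
#' @param dilute,crowded ISE standard data frames for the two conditions.
#' @return `fit_ise_pair`: list with both slope fits and
#'   `activity_ratio` = crowded slope / dilute slope.
#' @export
fit_ise_pair <- function(dilute, crowded) {
  fd <- fit_ise(dilute); fc <- fit_ise(crowded)
  list(dilute = fd, crowded = fc,
       activity_ratio = fc$slope / fd$slope)
}

#' Kinetic dissociation constant from rate constants
#'
#' Thermodynamic consistency utility: `K_D = k_off / k_on` with
#' first-order error propagation.
#'
#' @param k_off Dissociation rate constant, s^-1.
#' @param k_on Association rate constant, M^-1 s^-1.
#' @param se_k_off,se_k_on Standard errors (default 0).
#' @return List with `K_D` (M) and `se`.
#' @export
#' @examples
#' kd_kinetic(1.01, 2.7e9)$K_D * 1e9  # ~0.37 nM
kd_kinetic <- function(k_off, k_on, se_k_off = 0, se_k_on = 0) {
  stopifnot(k_on > 0, k_off > 0)
  kd <- k_off / k_on
  se <- kd * sqrt((se_k_off / k_off)^2 + (se_k_on / k_on)^2)
  list(K_D = kd, se = se)
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Model:", x$model, "\n")
  if (!is.null(x$parameters)) {
    print(signif(x$parameters, 6))
  } else if (!is.null(x$K_D)) {
    cat(sprintf("  K_D = %.4g M\n", x$K_D))
  }
  invisible(x)
}

#' @export
print.mm_result <- function(x, ...) {
  cat(sprintf(
    "Michaelis-Menten: k_cat = %.4g s^-1, K_m = %.4g M, kcat/Km = %.4g M^-1 s^-1\n",
    x$k_cat, x$K_m, x$k_cat_over_K_m))
  invisible(x)
}
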