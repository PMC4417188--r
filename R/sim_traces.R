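#' Kinetic trace container
#'
#' Time/signal series with the metadata the stopped-flow fitters need.
#'
#' @param times Times in seconds, strictly increasing.
#' @param signal Fluorescence signal (arbitrary units).
#' @param P0 Molar concentration of each binding partner (equal-concentration
#'   second-order conditions), or `NA` for dissociation traces.
#' @param condition Free-text condition label.
#' @return A `kinetic_trace` data frame with metadata attributes.
#' @export
kinetic_trace <- function(times, signal, P0 = NA_real_, condition = "buffer") {
  stopifnot(length(times) == length(signal))
  if (length(times) >= 2 && is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing")
  }
  structure(data.frame(time_s = as.numeric(times), signal = as.numeric(signal)),
            P0 = P0, condition = as.character(condition),
            class = c("kinetic_trace", "data.frame"))
}

#' Simulate an equal-concentration second-order association trace
#'
#' Signal for irreversible bimolecular association with equal reactant
#' concentrations `P0`:
#' \deqn{Y(t) = Y_f - \frac{Y_f - Y_0}{k_{on} P_0 t + 1}}
#' plus optional Gaussian noise. Deterministic at `noise_sd = 0`.
#'
#' @param k_on Association rate constant, M^-1 s^-1 (> 0).
#' @param P0 Concentration of each partner, M (> 0).
#' @param Y0,Yf Initial and final signal.
#' @param times Times in seconds, strictly increasing.
#' @param noise_sd Gaussian noise SD in signal units (>= 0).
#' @param seed Integer RNG seed (used only when `noise_sd > 0`).
#' @return A [kinetic_trace()].
#' @export
#' @examples
#' tr <- simulate_association_trace(2.7e9, 200e-9, Y0 = 0, Yf = 1,
#'                                  times = seq(0, 0.02, length.out = 200))
#' tr$signal[1]  # Y0 exactly at t = 0
simulate_association_trace <- function(k_on, P0, Y0, Yf, times,
                                       noise_sd = 0, seed = 1L) {
  stopifnot(k_on > 0, P0 > 0)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(times) >= 2 && is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing")
  }
  y <- Yf - (Yf - Y0) / (k_on * P0 * times + 1)
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + rnorm(length(y), sd = noise_sd)
  }
  kinetic_trace(times, y, P0 = P0)
}

#' Simulate a single- or multi-exponential dissociation trace
#'
#' Sum-of-exponentials decay
#' \deqn{Y(t) = \mathrm{offset} + \sum_i a_i e^{-k_i t}}
#' plus optional Gaussian noise; models trap-chase stopped-flow dissociation
#' (single phase in dilute buffer, biphasic in crowded solutions).
#'
#' @param rates Decay rate constants in s^-1 (length 1 or 2, > 0).
#' @param amplitudes Signal amplitudes, one per rate.
#' @param offset Signal offset (baseline at t = Inf).
#' @param times Times in seconds.
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param seed Integer RNG seed.
#' @return A [kinetic_trace()].
#' @export
simulate_dissociation_trace <- function(rates, amplitudes, offset = 0,
                                        times = seq(0, 6, length.out = 300),
                                        noise_sd = 0, seed = 1L) {
  stopifnot(length(rates) == length(amplitudes), all(rates > 0))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  y <- offset + rowSums(vapply(seq_along(rates), function(i) {
    amplitudes[i] * exp(-rates[i] * times)
  }, numeric(length(times))))
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + rnorm(length(y), sd = noise_sd)
  }
  kinetic_trace(times, y)
}

#' Simulate an anisotropy titration (1:1 binding isotherm)
#'
#' \deqn{r([P]) = r_{free} + (r_{bound} - r_{free}) \frac{[P]}{K_D + [P]}}
#' with optional ligand-depletion correction (quadratic solution for the
#' free protein concentration at labelled-DNA concentration `L0`).
#'
#' @param K_D Equilibrium dissociation constant, M (> 0).
#' @param conc Total protein concentrations, M (positive, increasing).
#' @param r_free,r_bound Anisotropy endpoints.
#' @param L0 Labelled DNA concentration, M; 0 disables depletion.
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param seed Integer RNG seed.
#' @return A `titration_curve` data frame (conc_M, anisotropy).
#' @export
simulate_titration <- function(K_D, conc, r_free = 0.05, r_bound = 0.20,
                               L0 = 0, noise_sd = 0, seed = 1L) {
  if (K_D <= 0) stop("K_D must be > 0")
  if (any(conc <= 0)) stop("concentrations must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (L0 > 0) {
    # free protein from the quadratic: Pf^2 + (KD + L0 - P)Pf - KD*P = 0
    b <- K_D + L0 - conc
    pf <- (-b + sqrt(b^2 + 4 * K_D * conc)) / 2
    fb <- pf / (K_D + pf)
  } else {
    fb <- conc / (K_D + conc)
  }
  r <- r_free + (r_bound - r_free) * fb
  if (noise_sd > 0) {
    set.seed(seed)
    r <- r + rnorm(length(r), sd = noise_sd)
  }
  structure(data.frame(conc_M = conc, anisotropy = r),
            class = c("titration_curve", "data.frame"))
}

#' Simulate a Michaelis-Menten initial-rate table
#'
#' \deqn{v = k_{cat} [E] [S] / (K_m + [S])} with optional Gaussian noise.
#'
#' @param k_cat Turnover number, s^-1 (> 0).
#' @param K_m Michaelis constant, M (> 0).
#' @param E0 Enzyme concentration, M (> 0).
#' @param S Substrate concentrations, M (positive).
#' @param noise_sd Gaussian noise SD on the rates, M/s (>= 0).
#' @param seed Integer RNG seed.
#' @return A data frame (conc_M, rate_Ms).
#' @export
simulate_initial_rates <- function(k_cat, K_m, E0, S, noise_sd = 0, seed = 1L) {
  if (K_m <= 0) stop("K_m must be > 0")
  stopifnot(k_cat > 0, E0 > 0)
  if (any(S <= 0)) stop("substrate concentrations must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  v <- k_cat * E0 * S / (K_m + S)
  if (noise_sd > 0) {
    set.seed(seed)
    v <- v + rnorm(length(v), sd = noise_sd)
  }
  data.frame(conc_M = S, rate_Ms = v)
}

#' Simulate ion-selective-electrode calibration standards
#'
#' Linear semi-log (Nernstian) electrode response:
#' mV = intercept + slope * log10(concentration).
#'
#' @param slope Semi-log slope, mV per decade of concentration.
#' @param intercept mV at 1 concentration unit.
#' @param conc Standard concentrations (positive).
#' @param noise_sd Gaussian noise SD in mV (>= 0).
#' @param seed Integer RNG seed.
#' @return A data frame (conc, mV).
#' @export
simulate_ise_standards <- function(slope, intercept = 0,
                                   conc = c(2, 10, 50, 200, 1000),
                                   noise_sd = 0, seed = 1L) {
  if (any(conc <= 0)) stop("concentrations must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  mv <- intercept + slope * log10(conc)
  if (noise_sd > 0) {
    set.seed(seed)
    mv <- mv + rnorm(length(mv), sd = noise_sd)
  }
  data.frame(conc = conc, mV = mv)
}
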