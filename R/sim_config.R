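#' Simulation configuration for the lattice walker and population sampler
#'
#' Bundles every parameter of the stochastic site-transfer simulator: the
#' geometry of the two-site DNA lattice, the per-step kinetics of the
#' sliding/hopping walker, the molecular-clock trap, excision efficiency,
#' and the laboratory-time parameters of the population reaction sampler.
#'
#' Time is modelled in two layers: dimensionless lattice steps inside one
#' binding event (the walker), and laboratory seconds for the population
#' sampler (first arrivals and rebinding). The walker's transfer
#' probability is time-scale-free, so no step-to-seconds mapping is needed
#' unless the caller wants one; `steps_per_second` provides it.
#'
#' @param dna_length_bp Integer, length of the DNA lattice in base pairs.
#' @param site1_pos,site2_pos 0-based bp indices of the two lesion sites;
#'   `site1_pos < site2_pos`.
#' @param q Per-lattice-step microscopic dissociation probability.
#' @param p_return Probability that a dissociative excursion re-lands on the
#'   chain rather than escaping to bulk (the rate ratio
#'   k_return / (k_return + k_bulk)).
#' @param hop_scale Mean bp displacement of a returned hop (two-sided
#'   geometric law, truncated to the chain).
#' @param trap_on Logical; is the small-molecule active-site trap present?
#' @param trap_capture_prob Probability a dissociative excursion is captured
#'   by the trap when `trap_on` (default 1: saturating trap).
#' @param E Excision efficiency: probability of excision per site encounter.
#' @param first_hit_rate Per-molecule rate (s^-1) of the first productive
#'   enzyme arrival from bulk in the population sampler.
#' @param rebind_rate Per-molecule rate (s^-1) of independent fresh-enzyme
#'   arrivals that convert singly-cleaved substrates to doubly-cleaved ones
#'   (the source of the late-time inflation of apparent transfer).
#' @param n_molecules Number of substrate molecules to simulate.
#' @param timepoints Strictly increasing vector of quench times in seconds.
#' @param rng_seed Integer seed; identical config + seed gives bit-identical
#'   output.
#' @param steps_per_second Optional lattice-step to laboratory-seconds
#'   conversion (not used by the estimators).
#' @param chemistry_instantaneous Fixed `TRUE`: the chemical step
#'   (k_cl = 240 s^-1) is far faster than dissociation, so excision upon a
#'   successful encounter is treated as instantaneous.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(site1_pos = 40, site2_pos = 60, q = 0.005)
#' cfg$site2_pos - cfg$site1_pos  # site spacing in bp
sim_config <- function(dna_length_bp = 90L,
                       site1_pos = 30L,
                       site2_pos = 50L,
                       q = 0.005,
                       p_return = 0.5,
                       hop_scale = 3,
                       trap_on = FALSE,
                       trap_capture_prob = 1.0,
                       E = 1.0,
                       first_hit_rate = 0.01,
                       rebind_rate = 0.0,
                       n_molecules = 10000L,
                       timepoints = c(15, 30, 45, 60, 75),
                       rng_seed = 1L,
                       steps_per_second = NULL,
                       chemistry_instantaneous = TRUE) {
  cfg <- list(
    dna_length_bp = as.integer(dna_length_bp),
    site1_pos = as.integer(site1_pos),
    site2_pos = as.integer(site2_pos),
    q = q, p_return = p_return, hop_scale = hop_scale,
    trap_on = isTRUE(trap_on), trap_capture_prob = trap_capture_prob,
    E = E, first_hit_rate = first_hit_rate, rebind_rate = rebind_rate,
    n_molecules = as.integer(n_molecules),
    timepoints = as.numeric(timepoints),
    rng_seed = as.integer(rng_seed),
    steps_per_second = steps_per_second,
    chemistry_instantaneous = isTRUE(chemistry_instantaneous)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param x A `sim_config` object.
#' @export
validate_sim_config <- function(x) {
  stopifnot(inherits(x, "sim_config"))
  probs <- c(q = x$q, p_return = x$p_return,
             trap_capture_prob = x$trap_capture_prob, E = x$E)
  bad <- probs < 0 | probs > 1 | !is.finite(probs)
  if (any(bad)) {
    stop("probabilities out of [0, 1]: ", paste(names(probs)[bad], collapse = ", "))
  }
  if (!(0L <= x$site1_pos && x$site1_pos < x$site2_pos &&
        x$site2_pos < x$dna_length_bp)) {
    stop("need 0 <= site1_pos < site2_pos < dna_length_bp")
  }
  if (x$site2_pos == x$site1_pos) stop("site spacing of 0 is not allowed")
  if (x$n_molecules < 1L) stop("n_molecules must be >= 1")
  if (length(x$timepoints) > 0 &&
      (any(x$timepoints <= 0) || is.unsorted(x$timepoints, strictly = TRUE))) {
    stop("timepoints must be strictly increasing and positive")
  }
  if (x$q == 0 && x$p_return == 1) {
    stop("q = 0 with p_return = 1: walker can never terminate")
  }
  if (x$hop_scale < 1) stop("hop_scale must be >= 1 bp")
  if (x$first_hit_rate < 0 || x$rebind_rate < 0) {
    stop("first_hit_rate and rebind_rate must be non-negative")
  }
  x
}

#' Write / read a simulation configuration as YAML
#'
#' @param cfg A `sim_config`.
#' @param path File path.
#' @return `write_sim_config` returns `path` invisibly; `read_sim_config`
#'   returns a validated `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(sim_config, x[!vapply(x, is.null, logical(1))])
}
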