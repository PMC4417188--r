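#' Simulate the sliding/hopping walker for intramolecular site transfer
#'
#' Releases `n_molecules` enzyme molecules at site 1 (immediately after a
#' first excision) and follows each along the facilitated-diffusion search
#' pathway — unbiased 1-bp sliding, microscopic dissociative excursions
#' that either re-land (hop), escape to bulk, or are captured by the
#' molecular-clock trap — until the molecule excises site 2, escapes, or is
#' trapped. Paths that reach site 2 with no hop are associative transfers;
#' paths containing at least one returned hop are dissociative transfers.
#' With the trap on at capture probability 1, every dissociative excursion
#' is intercepted, so only associative transfers can succeed.
#'
#' @param config A [sim_config()].
#' @param record_events Logical; keep the full per-molecule event log
#'   (slide/hop/escape/trap_capture/excision with positions). Memory-heavy;
#'   intended for small `n_molecules`.
#' @param max_steps Per-molecule step budget safeguard.
#' @return A `walker_result` list: `molecules` (per-molecule data frame with
#'   `outcome`, `n_hops`, `n_encounters`, `n_steps`, `transferred`,
#'   `pathway`), summary statistics `p_transfer`, `p_assoc`, `p_diss` (each
#'   with a binomial standard error), `events` (if recorded), and the config.
#' @export
#' @examples
#' cfg <- sim_config(site1_pos = 40, site2_pos = 45, q = 0.01,
#'                   n_molecules = 2000, rng_seed = 7)
#' res <- simulate_walker(cfg)
#' res$p_transfer
simulate_walker <- function(config, record_events = FALSE,
                            max_steps = 10000000L) {
  config <- validate_sim_config(config)
  spacing <- config$site2_pos - config$site1_pos
  if (spacing < 1) stop("site spacing of 0 is not allowed")

  set.seed(config$rng_seed)
  raw <- walk_molecules_cpp(
    n = config$n_molecules, start = config$site1_pos,
    site2 = config$site2_pos, chain_len = config$dna_length_bp,
    q = config$q, p_return = config$p_return, hop_scale = config$hop_scale,
    trap_on = config$trap_on, trap_capture_prob = config$trap_capture_prob,
    E = config$E, max_steps = as.integer(max_steps),
    record_events = isTRUE(record_events))

  outcome <- factor(raw$outcome, levels = 0:3,
                    labels = c("escape", "trap_capture", "excision", "maxed"))
  if (any(outcome == "maxed")) {
    warning(sum(outcome == "maxed"), " molecule(s) hit the step budget")
  }
  transferred <- outcome == "excision"
  pathway <- ifelse(!transferred, NA_character_,
                    ifelse(raw$n_hops > 0, "dissociative", "associative"))
  mols <- data.frame(outcome = outcome, n_hops = raw$n_hops,
                     n_encounters = raw$n_encounters, n_steps = raw$n_steps,
                     transferred = transferred, pathway = pathway)
  n <- config$n_molecules
  binom_se <- function(p) sqrt(p * (1 - p) / n)
  p_tr <- mean(transferred)
  p_as <- mean(transferred & pathway == "associative", na.rm = TRUE)
  p_di <- mean(transferred & pathway == "dissociative", na.rm = TRUE)

  structure(list(
    molecules = mols,
    p_transfer = c(estimate = p_tr, se = binom_se(p_tr)),
    p_assoc = c(estimate = p_as, se = binom_se(p_as)),
    p_diss = c(estimate = p_di, se = binom_se(p_di)),
    events = raw$events,
    config = config
  ), class = "walker_result")
}

#' @export
print.walker_result <- function(x, ...) {
  cfg <- x$config
  cat("Lattice walker:", cfg$n_molecules, "molecules, spacing",
      cfg$site2_pos - cfg$site1_pos, "bp, q =", cfg$q,
      if (cfg$trap_on) "(trap on)" else "(trap off)", "\n")
  cat(sprintf("  P(transfer)     = %.4f (SE %.4f)\n",
              x$p_transfer["estimate"], x$p_transfer["se"]))
  cat(sprintf("  associative     = %.4f\n", x$p_assoc["estimate"]))
  cat(sprintf("  dissociative    = %.4f\n", x$p_diss["estimate"]))
  invisible(x)
}
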