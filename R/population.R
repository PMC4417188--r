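#' Fragment timecourse from a two-site transfer reaction
#'
#' Container for per-timepoint molar band fractions of the five labelled
#' species produced by a dual-end-labelled two-site substrate: `A` (5'
#' end to site 1, 5' label), `C` (site 2 to 3' end, 3' label), `AB` (5' end
#' to site 2), `BC` (site 1 to 3' end), and the uncut full-length substrate.
#' Single-site excision at site 1 yields A + BC; at site 2, AB + C; a
#' double event (successful intramolecular transfer) yields A + C.
#'
#' @param times Quench times in seconds, strictly increasing.
#' @param A,C,AB,BC,full_length Molar fractions (>= 0) per timepoint.
#' @param trap_on Logical condition flag (molecular-clock trap present).
#' @param site_spacing Site spacing in bp.
#' @param condition Free-text condition label (crowder, % w/v).
#' @return A `fragment_timecourse`: a data frame with one row per timepoint
#'   and the condition metadata as attributes.
#' @export
fragment_timecourse <- function(times, A, C, AB, BC, full_length,
                                trap_on = FALSE, site_spacing = NA_integer_,
                                condition = "buffer") {
  df <- data.frame(time_s = as.numeric(times), A = A, C = C, AB = AB,
                   BC = BC, full_length = full_length)
  if (nrow(df) >= 2 && is.unsorted(df$time_s, strictly = TRUE)) {
    stop("times must be strictly increasing")
  }
  frac <- as.matrix(df[, c("A", "C", "AB", "BC", "full_length")])
  if (any(frac < 0)) stop("band fractions must be non-negative")
  structure(df, trap_on = isTRUE(trap_on),
            site_spacing = as.integer(site_spacing),
            condition = as.character(condition),
            class = c("fragment_timecourse", "data.frame"))
}

#' Simulate a population-level site-transfer experiment
#'
#' Emulates the gel-based molecular-clock assay: `n_molecules` two-site
#' substrates exposed to enzyme arriving from bulk. The first productive
#' arrival (rate `first_hit_rate`, thinned by excision efficiency `E`)
#' excises a random site; with probability `true_P_trans * E` the same
#' binding event also excises the partner site (a double event, fragments
#' A + C), otherwise a single event. Independent fresh-enzyme rebinding
#' (rate `rebind_rate`, also thinned by `E`) later converts singly-cleaved
#' molecules to doubly-cleaved ones, which inflates the apparent transfer
#' probability at later times — the reason the assay extrapolates to zero
#' time.
#'
#' @param config A [sim_config()]; uses `E`, `first_hit_rate`,
#'   `rebind_rate`, `n_molecules`, `timepoints`, `rng_seed` and the site
#'   geometry.
#' @param true_P_trans The true per-binding-event probability of reaching
#'   the partner site, or `"from_walker"` to obtain it by running
#'   [simulate_walker()] on the same config.
#' @return A [fragment_timecourse()] with attributes `truth` (the hidden
#'   per-timepoint counts of intact, single-site and double-site molecules),
#'   `true_P_trans`, `consumed` (logical per timepoint: full-length substrate
#'   exhausted; later timepoints carry no extrapolation information), and
#'   `config`.
#' @export
#' @examples
#' cfg <- sim_config(n_molecules = 5000, rebind_rate = 0.002, rng_seed = 11)
#' tc <- simulate_population(cfg, true_P_trans = 0.34)
#' head(tc)
simulate_population <- function(config, true_P_trans = "from_walker") {
  config <- validate_sim_config(config)
  if (identical(true_P_trans, "from_walker")) {
    wr <- simulate_walker(config)
    true_P_trans <- unname(wr$p_transfer["estimate"])
  }
  stopifnot(is.numeric(true_P_trans), length(true_P_trans) == 1,
            true_P_trans >= 0, true_P_trans <= 1)
  if (config$E <= 0) stop("E must be > 0 for the population sampler")
  if (config$first_hit_rate <= 0) stop("first_hit_rate must be > 0")

  set.seed(config$rng_seed)
  n <- config$n_molecules
  t1 <- rexp(n, rate = config$E * config$first_hit_rate)
  first_site <- sample(c(1L, 2L), n, replace = TRUE)
  is_double <- runif(n) < true_P_trans * config$E
  # molecular-clock trap blocks dissociative rebinding-independent pathway
  # only inside the walker; at population level rebinding is an independent
  # bulk process and proceeds regardless of the trap.
  t2 <- if (config$rebind_rate > 0) {
    t1 + rexp(n, rate = config$E * config$rebind_rate)
  } else {
    rep(Inf, n)
  }

  rows <- lapply(config$timepoints, function(tp) {
    reacted <- t1 <= tp
    dbl <- reacted & (is_double | t2 <= tp)
    sgl <- reacted & !dbl
    s1 <- sum(sgl & first_site == 1L)
    s2 <- sum(sgl & first_site == 2L)
    d <- sum(dbl)
    intact <- n - sum(reacted)
    c(intact = intact, s1 = s1, s2 = s2, d = d)
  })
  cnt <- do.call(rbind, rows)
  stopifnot(all(rowSums(cnt) == n))  # fragment conservation

  tc <- fragment_timecourse(
    times = config$timepoints,
    A = (cnt[, "s1"] + cnt[, "d"]) / n,
    C = (cnt[, "s2"] + cnt[, "d"]) / n,
    AB = cnt[, "s2"] / n,
    BC = cnt[, "s1"] / n,
    full_length = cnt[, "intact"] / n,
    trap_on = config$trap_on,
    site_spacing = config$site2_pos - config$site1_pos,
    condition = "synthetic")
  attr(tc, "truth") <- as.data.frame(cnt)
  attr(tc, "true_P_trans") <- true_P_trans
  attr(tc, "consumed") <- cnt[, "intact"] == 0
  attr(tc, "config") <- config
  tc
}
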