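#' Radius of gyration of a PEG polymer
#'
#' Light-scattering power law for poly(ethylene glycol) random coils:
#' \deqn{R_g = 0.0215\, M_w^{0.583}\ \mathrm{nm}}
#' Valid for PEG molecular weights between 200 and 1e6 g/mol.
#'
#' @param molecular_weight PEG molecular weight, g/mol.
#' @return Radius of gyration in nm.
#' @export
#' @examples
#' rg_peg(8000)  # ~4.1 nm
#' rg_peg(600)   # ~0.9 nm
rg_peg <- function(molecular_weight) {
  if (any(molecular_weight < 200 | molecular_weight > 1e6)) {
    stop("rg_peg law calibrated for PEG with M_w in [200, 1e6] g/mol")
  }
  0.0215 * molecular_weight^0.583
}

#' Polymer crowder specification
#'
#' @param name Crowder name (e.g. "PEG 8K").
#' @param molecular_weight g/mol.
#' @param percent_wv Concentration, % w/v.
#' @param eta_rel Relative viscosity eta_crowder/eta_buffer (>= 1); from the
#'   literature viscosity table, not computed.
#' @param R_g Radius of gyration, nm; default from [rg_peg()].
#' @return A `polymer_spec` list with the depletion layer `delta` (nm) set
#'   equal to `R_g` (dilute-regime assumption, flagged in the field
#'   `regime`).
#' @export
polymer_spec <- function(name, molecular_weight, percent_wv = NA_real_,
                         eta_rel = NA_real_, R_g = rg_peg(molecular_weight)) {
  if (!is.na(eta_rel) && eta_rel < 1) stop("eta_rel must be >= 1")
  if (R_g <= 0) stop("R_g must be > 0")
  structure(list(name = name, molecular_weight = molecular_weight,
                 percent_wv = percent_wv, eta_rel = eta_rel, R_g = R_g,
                 delta = R_g, regime = "dilute"),
            class = "polymer_spec")
}

#' Depletion layer and effective encounter distance
#'
#' In the dilute regime the polymer-depleted solvent shell around protein
#' and DNA has thickness equal to the polymer's radius of gyration,
#' `delta = R_g`. The effective centre-of-mass encounter distance is
#' reconstructed as the sum of the two depletion layers and the two
#' hydrodynamic radii:
#' \deqn{d = \delta_{protein} + \delta_{DNA} + r_{protein} + r_{DNA}}
#' This sum-of-layers formula is a reconstruction of the published ~11 nm
#' figure, and the result is labelled as such.
#'
#' @param spec A [polymer_spec()].
#' @return `depletion_layer`: thickness in nm.
#' @export
#' @examples
#' depletion_layer(polymer_spec("PEG 8K", 8000))  # ~4.1 nm
depletion_layer <- function(spec) {
  stopifnot(inherits(spec, "polymer_spec"))
  spec$delta
}

#' @rdname depletion_layer
#' @param r_protein,r_dna Hydrodynamic radii in nm.
#' @return `encounter_distance`: list with `distance_nm` and a `formula`
#'   label marking the reconstruction.
#' @export
encounter_distance <- function(spec, r_protein = 2.0, r_dna = 1.0) {
  d <- depletion_layer(spec)
  list(distance_nm = 2 * d + r_protein + r_dna,
       formula = "reconstruction: delta_protein + delta_DNA + r_protein + r_DNA",
       regime = spec$regime)
}

#' Kinetic partitioning of the dissociative transfer probability
#'
#' Two-term kinetic definition of the dissociative transfer probability:
#' \deqn{P_{diss} = \frac{k_{off}}{k_{off} + k_{assoc}} \cdot
#'       \frac{k_{return}}{k_{return} + k_{bulk}}}
#' The first bracket is the chance a bound enzyme dissociates rather than
#' taking another associative step; the second the chance a dissociated
#' enzyme returns to the chain rather than being lost to bulk. Crowding
#' moves the two brackets in opposite directions, which is why `P_diss`
#' can stay nearly constant while each term changes substantially.
#'
#' @param k_off,k_assoc,k_return,k_bulk Non-negative rates (any consistent
#'   units).
#' @return Probability in \[0, 1\].
#' @export
#' @examples
#' pdiss_partition(k_off = 2, k_assoc = 8, k_return = 9, k_bulk = 1)  # 0.18
pdiss_partition <- function(k_off, k_assoc, k_return, k_bulk) {
  stopifnot(all(c(k_off, k_assoc, k_return, k_bulk) >= 0))
  if (k_off + k_assoc == 0 || k_return + k_bulk == 0) {
    stop("undefined: a partition denominator is zero")
  }
  (k_off / (k_off + k_assoc)) * (k_return / (k_return + k_bulk))
}

#' Stokes-Einstein deviation table for association kinetics
#'
#' Converts per-condition association rate constants to relative
#' association times `tau_rel = tau_crowder / tau_buffer` (tau = 1/k_on)
#' and compares them with the relative viscosities. Stokes-Einstein
#' behaviour predicts `tau_rel = eta_rel`; the deviation
#' `delta = tau_rel - eta_rel` classifies each condition as `negative`
#' (faster association than viscosity alone predicts), `SE-ideal`
#' (|delta| <= `tol_frac * eta_rel`), or `positive` (slower).
#'
#' @param conditions Data frame with columns `condition`, `k_on`
#'   (M^-1 s^-1) and `eta_rel`; must contain a row whose `condition` equals
#'   `buffer_label`.
#' @param buffer_label Name of the dilute-buffer reference row.
#' @param tol_frac Classification tolerance as a fraction of `eta_rel`
#'   (default 0.15).
#' @return The input with `tau_rel`, `deviation` and `class` columns added.
#' @export
se_deviation <- function(conditions, buffer_label = "buffer", tol_frac = 0.15) {
  stopifnot(all(c("condition", "k_on", "eta_rel") %in% names(conditions)))
  ref <- conditions$condition == buffer_label
  if (!any(ref)) stop("no buffer reference row '", buffer_label, "'")
  k_buf <- conditions$k_on[ref][1]
  tau_rel <- k_buf / conditions$k_on
  dev <- tau_rel - conditions$eta_rel
  tol <- tol_frac * conditions$eta_rel
  cls <- ifelse(abs(dev) <= tol, "SE-ideal",
                ifelse(dev < 0, "negative", "positive"))
  out <- conditions
  out$tau_rel <- tau_rel
  out$deviation <- dev
  out$class <- cls
  out
}

#' Literature relative-viscosity table
#'
#' Reads the editable YAML table of relative viscosities keyed by
#' (polymer, percent w/v). The packaged default ships literature values,
#' including 13 for 20% w/v PEG 8K.
#'
#' @param path YAML file; default the packaged table.
#' @return Data frame with `polymer`, `percent_wv`, `eta_rel`.
#' @export
read_viscosity_table <- function(path = system.file("extdata",
                                                    "viscosity_table.yaml",
                                                    package = "glycoslide")) {
  tab <- yaml::read_yaml(path)
  df <- do.call(rbind, lapply(tab$viscosities, as.data.frame))
  stopifnot(all(c("polymer", "percent_wv", "eta_rel") %in% names(df)))
  if (any(df$eta_rel < 1)) stop("eta_rel must be >= 1")
  df
}
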