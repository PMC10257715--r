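#' Forster distance/efficiency mapping
#'
#' Converts between inter-fluorophore distance and FRET efficiency through
#' `E = 1 / (1 + (r / R0)^6)`, where the Forster radius `R0` is the
#' dye-pair-specific distance at which `E = 0.5`. The default `R0 = 54`
#' angstroms is typical for the sulfo-Cy3/Cy5 pair; orientation-factor and
#' refractive-index corrections are considered absorbed into `R0`.
#'
#' @param R0 Forster radius, angstroms (> 0).
#' @return object of class `forster_params`.
#' @export
forster_params <- function(R0 = 54) {
  if (!is.numeric(R0) || R0 <= 0) stop("R0 must be > 0")
  structure(list(R0 = R0), class = "forster_params")
}

#' @rdname forster_params
#' @param r inter-fluorophore distance, angstroms (> 0).
#' @param params a [forster_params()] object.
#' @return `fe_from_distance()`: FRET efficiency in (0, 1), strictly
#'   decreasing in `r`.
#' @export
fe_from_distance <- function(r, params = forster_params()) {
  if (any(r <= 0)) stop("distance must be > 0")
  1 / (1 + (r / params$R0)^6)
}

#' @rdname forster_params
#' @param E FRET efficiency, strictly inside (0, 1).
#' @return `distance_from_fe()`: distance in angstroms; exact inverse of
#'   [fe_from_distance()].
#' @export
distance_from_fe <- function(E, params = forster_params()) {
  if (any(E <= 0 | E >= 1)) stop("FRET efficiency must lie in (0, 1)")
  params$R0 * (1 / E - 1)^(1 / 6)
}

#' Structural state assignments over FRET-efficiency windows
#'
#' Default windows follow the structural interpretation of the closed/open
#' conformations: the closed state (labels 30-40 angstroms apart) maps to
#' FE 0.8-1, the open state (70-80 angstroms) to FE 0.2-0.5. The distance
#' window of each assignment is derived from its FE window via
#' [distance_from_fe()].
#'
#' @param assignments named list of FE intervals `c(lo, hi)`; names are the
#'   structural labels.
#' @param params a [forster_params()].
#' @return data.frame with `label`, `fe_lo`, `fe_hi`, `r_lo`, `r_hi`
#'   (angstroms, from the FE window).
#' @export
state_assignments <- function(assignments = list(closed = c(0.8, 1),
                                                 open = c(0.2, 0.5)),
                              params = forster_params()) {
  fe_lo <- vapply(assignments, `[`, numeric(1), 1)
  fe_hi <- vapply(assignments, `[`, numeric(1), 2)
  if (any(fe_lo >= fe_hi)) stop("assignment intervals must be non-empty")
  if (any(fe_lo < 0) || any(fe_hi > 1))
    stop("assignment FE intervals must lie inside [0, 1]")
  ord <- order(fe_lo)
  if (any(utils::head(fe_hi[ord], -1) > utils::tail(fe_lo[ord], -1)))
    stop("assignment FE intervals must be disjoint")
  clamp <- function(E) pmin(pmax(E, 1e-9), 1 - 1e-9)
  data.frame(label = names(assignments), fe_lo = fe_lo, fe_hi = fe_hi,
             r_lo = distance_from_fe(clamp(fe_hi), params),
             r_hi = distance_from_fe(clamp(fe_lo), params),
             row.names = NULL)
}

#' Classify HMM states against structural FE windows
#'
#' Each fitted state is labeled by the assignment interval containing its
#' mean FE; means outside all intervals are labeled `"intermediate"`
#' (e.g. a partially open conformation between the closed and open windows).
#'
#' @param model a `fret_hmm` or `fe_mixture` (anything with `means`).
#' @param assignments a [state_assignments()] table (or the list form).
#' @param params a [forster_params()] (used if `assignments` is a list).
#' @return data.frame with `state`, `mean_fe`, `label`, and the distance
#'   window implied by each state's FE mean.
#' @export
classify_states <- function(model, assignments = state_assignments(),
                            params = forster_params()) {
  if (!is.data.frame(assignments))
    assignments <- state_assignments(assignments, params)
  means <- model$means
  labels <- vapply(means, function(m) {
    hit <- which(m >= assignments$fe_lo & m <= assignments$fe_hi)
    if (length(hit) == 1) assignments$label[hit] else "intermediate"
  }, character(1))
  r_est <- ifelse(means > 0 & means < 1,
                  distance_from_fe(pmin(pmax(means, 1e-9), 1 - 1e-9), params),
                  NA_real_)
  data.frame(state = seq_along(means), mean_fe = means, label = labels,
             distance_estimate = r_est)
}
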