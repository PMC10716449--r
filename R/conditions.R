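#' Reference study conditions for CENP-B binding kinetics
#'
#' Ground-truth parameter sets used by the package's simulation-based
#' validation: one row per substrate, with the bi-exponential residence-time
#' mixture (fast non-specific component `tau_off_1`, slow sequence-specific
#' component `tau_off_2`, slow-component amplitude fraction `frac2`) of
#' full-length CENP-B on naked 601 DNA with and without a B-Box, on H3 and
#' CENP-A mononucleosomes (MN), and on 12-mer H3 and CENP-A chromatin
#' fibers (CF). Where a published value exists it is used directly. The
#' fiber fast components and the naked-DNA amplitude splits are not
#' individually published: amplitudes default to an equal split, and the
#' fast components are set inside the published non-specific range
#' (1.6-6.9 s) subject to keeping the two components at least 4-fold
#' separated, the regime in which a bi-exponential amplitude/lifetime
#' decomposition of a few thousand events is statistically identifiable
#' (for the H3 fiber, whose slow component is 17.6 s, this gives 4.0 s).
#'
#' @return data.frame with columns `condition`, `frac2`, `tau_off_1`,
#'   `tau_off_2`.
#' @export
cenpb_binding_conditions <- function() {
  data.frame(
    condition = c("bbox_dna", "non_bbox_dna", "h3_mn", "cenpa_mn",
                  "h3_cf", "cenpa_cf"),
    frac2 = c(0.5, 0.5, 0.34, 0.49, 0.5, 0.5),
    tau_off_1 = c(6.9, 1.6, 6.9, 6.8, 4.0, 6.9),
    tau_off_2 = c(61, 20, 48, 50, 17.6, 51.4))
}

#' Reference study conditions for CENP-B FRAP in cells
#'
#' Recovery time constant and immobile fraction of centromeric CENP-B with
#' CENP-A present (`ca_plus`) and after CENP-A depletion (`ca_kd`), used as
#' simulation ground truth.
#'
#' @return data.frame with columns `condition`, `tau`, `immobile_fraction`.
#' @export
cenpb_frap_conditions <- function() {
  data.frame(condition = c("ca_plus", "ca_kd"),
             tau = c(971, 381),
             immobile_fraction = c(0.43, 0.42))
}

#' Reference relaxation time of CENP-A chromatin fiber dynamics
#'
#' The donor-acceptor cross-correlation relaxation time of CENP-A chromatin
#' fibers under compacting (4 mM Mg2+) conditions, used as the generative
#' ground truth (`k12 = k21 = 1 / (2 tau_R)`) for the two-state exchange
#' simulations.
#'
#' @return Relaxation time in seconds.
#' @export
cenpa_relaxation_time <- function() 1.69
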