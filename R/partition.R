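#' Partition coefficient from raw extraction quantities
#'
#' The MCF/mixture partition coefficient is the ratio of the equilibrium
#' solute concentration in the membrane coating, `Cpe = n0/Vm`, to the
#' equilibrium concentration remaining in the formulation,
#' `Cme = C0 - n0/Vd`:
#'
#'   K = n0 * Vd / (Vm * (C0 * Vd - n0))
#'
#' Units are fixed: `n0` in ug, `C0` in ug/mL, `Vd` and `Vm` in mL. No
#' default membrane volume is assumed; `Vm` depends on the fiber geometry
#' and must be supplied.
#'
#' @param n0 Amount of solute extracted from the MCF (ug), `0 <= n0 < C0*Vd`.
#' @param C0 Initial solute concentration in the formulation (ug/mL), > 0.
#' @param Vd Volume of formulation in the vial (mL), > 0.
#' @param Vm Volume of the membrane coating (mL), > 0.
#' @return A data frame with columns `k` (dimensionless) and `log_k`
#'   (base-10 log; `NA` when `k = 0`, i.e. no extraction).
#' @examples
#' partition_coefficient(n0 = 0.5, C0 = 1, Vd = 9, Vm = 6.12e-4)
#' @export
partition_coefficient <- function(n0, C0, Vd, Vm) {
  n <- max(length(n0), length(C0), length(Vd), length(Vm))
  n0 <- rep_len(as.numeric(n0), n); C0 <- rep_len(as.numeric(C0), n)
  Vd <- rep_len(as.numeric(Vd), n); Vm <- rep_len(as.numeric(Vm), n)
  if (any(Vm <= 0) || any(Vd <= 0)) {
    stop("Vm and Vd must be positive volumes (mL)", call. = FALSE)
  }
  if (any(C0 <= 0)) stop("C0 must be positive (ug/mL)", call. = FALSE)
  if (any(n0 < 0)) stop("n0 must be nonnegative (ug)", call. = FALSE)
  if (any(n0 >= C0 * Vd)) {
    stop("n0 >= C0*Vd: equilibrium concentration in the formulation ",
         "would be <= 0", call. = FALSE)
  }
  k <- n0 * Vd / (Vm * (C0 * Vd - n0))
  data.frame(k = k, log_k = ifelse(k > 0, log10(k), NA_real_))
}

#' Partition coefficient implied by the partition theory
#'
#' Under the partition theory the extracted amount is proportional to the
#' starting concentration, `n0 = p * C0` with proportionality constant `p`
#' unaffected by `C0`. Substituting into the measurement formula cancels
#' `C0`:
#'
#'   K = p * Vd / (Vm * (Vd - p))
#'
#' so the coefficient is independent of the starting solute concentration.
#' The model-based tests in [test_partition_global()] probe exactly this
#' independence.
#'
#' @param p Proportionality constant, `0 <= p < Vd`.
#' @param Vd Formulation volume (mL), > 0.
#' @param Vm Membrane volume (mL), > 0.
#' @return Dimensionless partition coefficient(s).
#' @examples
#' theoretical_partition(p = 0.1, Vd = 9, Vm = 6.12e-4)
#' @export
theoretical_partition <- function(p, Vd, Vm) {
  n <- max(length(p), length(Vd), length(Vm))
  p <- rep_len(as.numeric(p), n)
  Vd <- rep_len(as.numeric(Vd), n); Vm <- rep_len(as.numeric(Vm), n)
  if (any(Vm <= 0) || any(Vd <= 0)) {
    stop("Vm and Vd must be positive volumes (mL)", call. = FALSE)
  }
  if (any(p < 0)) stop("p must be nonnegative", call. = FALSE)
  if (any(Vd - p <= 0)) {
    stop("require Vd - p > 0", call. = FALSE)
  }
  p * Vd / (Vm * (Vd - p))
}
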