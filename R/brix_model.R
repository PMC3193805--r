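#' Brix two-compartment enhancement model
#'
#' Relative signal enhancement of a tissue voxel after a bolus of
#' contrast agent, under the Brix two-compartment pharmacokinetic model:
#' the agent exchanges between blood plasma and the extracellular
#' extravascular space (EES) at rate `kep` (per minute) and is cleared
#' from plasma at rate `kel` (per minute), with `A` a dimensionless
#' amplitude related to the size of the EES:
#'
#' \deqn{RSI(t) = \frac{A\,k_{ep}}{k_{el} - k_{ep}}
#'   \left(e^{-k_{ep} t} - e^{-k_{el} t}\right)}
#'
#' When `kep` and `kel` coincide (relative difference below `tie_tol`)
#' the analytic limit \eqn{A\,k_{ep}\,t\,e^{-k_{ep} t}} is used, so the
#' model is continuous across the `kep = kel` diagonal.
#'
#' @param t time since injection, minutes; vectorized, must be >= 0.
#' @param A amplitude (dimensionless, >= 0).
#' @param kep plasma-EES exchange rate constant, per minute (>= 0).
#' @param kel plasma elimination rate constant, per minute (>= 0).
#' @param tie_tol relative tolerance below which `kep` and `kel` are
#'   treated as equal and the limit form is used.
#' @return enhancement values, same length as `t`; 0 at `t = 0`.
#' @examples
#' brix_model(2.558, A = 2, kep = 1, kel = 0.1)  # ~1.549, the curve peak
#' @export
brix_model <- function(t, A, kep, kel, tie_tol = 1e-8) {
  if (any(t < 0)) stopf("brix_model: t must be >= 0")
  if (A < 0 || kep < 0 || kel < 0) {
    stopf("brix_model: A, kep, kel must be >= 0")
  }
  if (abs(kel - kep) <= tie_tol * max(kep, kel, .Machine$double.eps)) {
    A * kep * t * exp(-kep * t)
  } else {
    A * kep / (kel - kep) * (exp(-kep * t) - exp(-kel * t))
  }
}

#' Peak time of the Brix enhancement curve
#'
#' The unique interior maximum of the curve,
#' \eqn{t^* = \ln(k_{ep}/k_{el}) / (k_{ep} - k_{el})}, independent of the
#' amplitude; reduces to \eqn{1/k_{ep}} when the two rates coincide.
#'
#' @inheritParams brix_model
#' @return peak time in minutes.
#' @export
brix_peak_time <- function(kep, kel, tie_tol = 1e-8) {
  if (kep <= 0 || kel <= 0) stopf("brix_peak_time: rates must be > 0")
  if (abs(kel - kep) <= tie_tol * max(kep, kel)) return(1 / kep)
  log(kep / kel) / (kep - kel)
}

# Canonical branch of the model's swap symmetry: (A, kep, kel) and
# (A*kep/kel, kel, kep) produce identical curves, so fits are reported
# on the kep >= kel branch (fast in-wash, slow plasma clearance -- the
# physiological regime of these tumors) whenever the swapped amplitude
# stays inside the fitting bounds.
canonicalize_brix <- function(A, kep, kel, A_max = Inf) {
  if (kel > kep && kel > 0) {
    A2 <- A * kep / kel
    if (A2 <= A_max) return(c(A = A2, kep = kel, kel = kep))
  }
  c(A = A, kep = kep, kel = kel)
}
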