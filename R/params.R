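#' Model parameters of the SIRS-with-migration dynamics
#'
#' The six per-unit-time proportions governing the degree-block dynamics,
#' all strictly inside (0,1) (the stability theory requires strict
#' positivity):
#' \describe{
#'   \item{b}{immigration: empty sites are re-occupied by undisturbed
#'     immigrants at proportion `b`.}
#'   \item{mu}{emigration: every compartment loses mass at proportion `mu`.}
#'   \item{gamma}{disturbance-induced loss: disturbed species additionally
#'     disappear at proportion `gamma`.}
#'   \item{sigma}{recovery: disturbed -> recovered.}
#'   \item{delta}{loss of immunity memory: recovered -> undisturbed.}
#'   \item{beta}{per-contact transmission probability along a trophic link.}
#'   \item{alpha}{transmissibility coefficient in \eqn{\varphi(k) = \alpha k}
#'     (default 1); it rescales the edge pressure \eqn{\theta} and hence all
#'     reproduction numbers uniformly.}
#' }
#'
#' @param b,mu,gamma,sigma,delta,beta rates in (0,1).
#' @param alpha transmissibility coefficient in (0,1].
#' @return list of class `sirs_params`.
#' @examples
#' sirs_params(b = 0.1, mu = 0.1, gamma = 0.1, sigma = 0.5, delta = 0.5, beta = 0.8)
#' @export
sirs_params <- function(b, mu, gamma, sigma, delta, beta, alpha = 1) {
  vals <- c(b = b, mu = mu, gamma = gamma, sigma = sigma, delta = delta, beta = beta)
  if (any(!is.finite(vals)) || any(vals <= 0) || any(vals >= 1))
    stop("b, mu, gamma, sigma, delta, beta must all lie strictly in (0, 1)")
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]")
  structure(list(b = b, mu = mu, gamma = gamma, sigma = sigma,
                 delta = delta, beta = beta, alpha = alpha),
            class = "sirs_params")
}

#' @export
print.sirs_params <- function(x, ...) {
  cat(sprintf("SIRS-with-migration parameters: b=%.3g mu=%.3g gamma=%.3g sigma=%.3g delta=%.3g beta=%.3g alpha=%.3g\n",
              x$b, x$mu, x$gamma, x$sigma, x$delta, x$beta, x$alpha))
  cat(sprintf("  disturbance-free occupancy b/(b+mu) = %.4f\n", x$b / (x$b + x$mu)))
  invisible(x)
}

#' @export
format.sirs_params <- function(x, ...) {
  sprintf("sirs_params(b=%g, mu=%g, gamma=%g, sigma=%g, delta=%g, beta=%g, alpha=%g)",
          x$b, x$mu, x$gamma, x$sigma, x$delta, x$beta, x$alpha)
}

# Effective per-class rates once a protection scheme is applied.
# Returns lambda_k = beta * (1 - phi_transmission_k) * k (coefficient on
# theta * S_k in the infection term) and s_out = sigma + extra removal from I
# (active protection). The base model is scheme = NULL.
.effective_rates <- function(params, kmax, scheme = NULL) {
  k <- seq_len(kmax)
  phi_trans <- numeric(kmax)
  s_out <- params$sigma
  if (!is.null(scheme)) {
    stopifnot(inherits(scheme, "immunization_scheme"))
    if (scheme$kind %in% c("uniform", "targeted")) {
      phi_trans <- .scheme_phi_k(scheme, kmax)
    } else if (scheme$kind == "active") {
      s_out <- params$sigma + scheme$phi_bar_k
    } else stop("unknown scheme kind: ", scheme$kind)
  }
  list(lambda = params$beta * (1 - phi_trans) * k, s_out = s_out)
}
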