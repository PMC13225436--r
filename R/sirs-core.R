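#' Per-degree-class state of the disturbance model
#'
#' Densities of undisturbed (`S`), disturbed (`I`) and recovered (`R`)
#' species in each degree class `k = 1..kmax`. Densities are fractions of the
#' sites in a class, so `S_k + I_k + R_k <= 1`; the remainder is empty sites
#' left by emigration and disturbance-induced loss.
#'
#' @param S,I,R numeric vectors of equal length `kmax` with entries in [0,1].
#' @return list of class `sirs_state`.
#' @export
sirs_state <- function(S, I, R) {
  kmax <- length(S)
  if (length(I) != kmax || length(R) != kmax)
    stop("S, I, R must have the same length (one entry per degree class)")
  if (any(!is.finite(c(S, I, R))) || any(c(S, I, R) < 0) || any(c(S, I, R) > 1))
    stop("densities must lie in [0, 1]")
  if (any(S + I + R > 1 + 1e-9))
    stop("S_k + I_k + R_k must not exceed 1 in any class")
  structure(list(kmax = kmax, S = S, I = I, R = R), class = "sirs_state")
}

#' Default initial condition: uniform disturbance background
#'
#' Every class starts with disturbed density `i0` (default 0.1), no recovered
#' species, and undisturbed density `b/(b+mu) - i0` so that each class sits at
#' the equilibrium total occupancy `N_k = b/(b+mu)`.
#'
#' @param params [sirs_params()].
#' @param kmax number of degree classes (or a [degree_dist()]).
#' @param i0 initial disturbed density per class.
#' @return a [sirs_state()].
#' @export
default_init <- function(params, kmax, i0 = 0.1) {
  if (inherits(kmax, "degree_dist")) kmax <- kmax$kmax
  n0 <- params$b / (params$b + params$mu)
  if (i0 < 0 || i0 > n0) stop(sprintf("i0 must lie in [0, b/(b+mu) = %.4f]", n0))
  sirs_state(S = rep(n0 - i0, kmax), I = rep(i0, kmax), R = rep(0, kmax))
}

#' Edge infection pressure theta
#'
#' Probability that a randomly chosen trophic link points at a disturbed
#' species: \eqn{\theta = \alpha \sum_k k P(k) I_k / \langle k \rangle}
#' (with transmissibility \eqn{\varphi(k) = \alpha k}). This is the coupling
#' through which all degree classes interact in the annealed approximation.
#'
#' @param state a [sirs_state()] (or a bare vector of `I_k` densities).
#' @param dist a [degree_dist()] with the same `kmax`.
#' @param alpha transmissibility coefficient (default 1).
#' @return scalar in `[0, alpha]`.
#' @export
infection_pressure <- function(state, dist, alpha = 1) {
  I <- if (inherits(state, "sirs_state")) state$I else state
  stopifnot(inherits(dist, "degree_dist"))
  if (length(I) != dist$kmax)
    stop(sprintf("state has %d classes but distribution has kmax = %d", length(I), dist$kmax))
  k <- seq_len(dist$kmax)
  m <- degree_moments(dist)
  alpha * sum(k * dist$p * I) / m$mean_k
}

#' Right-hand side of the degree-block SIRS-with-migration system
#'
#' For each class `k`:
#' \deqn{S_k' = b(1 - N_k) - \beta k \theta S_k - \mu S_k + \delta R_k}
#' \deqn{I_k' = \beta k \theta S_k - (\mu + \gamma + \sigma) I_k}
#' \deqn{R_k' = \sigma I_k - (\mu + \delta) R_k}
#' with \eqn{N_k = S_k + I_k + R_k}. A protection `scheme` modifies the
#' rates: uniform/targeted protection multiplies the transmission term by
#' \eqn{1 - \varphi_k}; active protection adds the link-weighted budget
#' \eqn{\bar\varphi_k} to the outflow of `I` (into `R`).
#'
#' @param state a [sirs_state()].
#' @param params [sirs_params()].
#' @param dist [degree_dist()].
#' @param scheme optional [immunization scheme][uniform_scheme].
#' @return list with vectors `dS`, `dI`, `dR`.
#' @export
sirs_rhs <- function(state, params, dist, scheme = NULL) {
  stopifnot(inherits(state, "sirs_state"), inherits(params, "sirs_params"))
  if (state$kmax != dist$kmax) stop("state and distribution kmax differ")
  th <- infection_pressure(state, dist, params$alpha)
  er <- .effective_rates(params, dist$kmax, scheme)
  N <- state$S + state$I + state$R
  inf <- er$lambda * th * state$S
  list(
    dS = params$b * (1 - N) - inf - params$mu * state$S + params$delta * state$R,
    dI = inf - (params$mu + params$gamma + er$s_out) * state$I,
    dR = er$s_out * state$I - (params$mu + params$delta) * state$R
  )
}

#' Basic reproduction number on a heterogeneous network
#'
#' \deqn{\rho = \frac{\alpha\, b \beta}{(b+\mu)(\mu+\gamma+\sigma)}
#'   \frac{\langle k^2 \rangle}{\langle k \rangle}}
#' The product of the per-contact transmission probability, the
#' disturbance-free occupancy `b/(b+mu)`, the mean time spent disturbed
#' `1/(mu+gamma+sigma)`, and the effective connectivity
#' `<k^2>/<k>`. The disturbance dies out when `rho < 1` and becomes endemic
#' when `rho > 1`.
#'
#' @param params [sirs_params()].
#' @param dist a [degree_dist()] or [degree_moments()] pair.
#' @return scalar `rho > 0`.
#' @examples
#' p <- sirs_params(0.1, 0.1, 0.1, 0.5, 0.5, 0.8)
#' basic_reproduction_number(p, degree_moments(5.36, 62.66))  # ~6.68
#' @export
basic_reproduction_number <- function(params, dist) {
  m <- degree_moments(dist)
  params$alpha * params$b * params$beta * m$mean_k2 /
    ((params$b + params$mu) * (params$mu + params$gamma + params$sigma) * m$mean_k)
}

#' Critical transmission probability
#'
#' The threshold \eqn{\beta_c = (b+\mu)(\mu+\gamma+\sigma)\langle k \rangle /
#' (\alpha\, b \langle k^2 \rangle)} at which `rho = 1`: below it the
#' disturbance-free state is stable, above it an endemic state exists
#' (transcritical bifurcation).
#'
#' @inheritParams basic_reproduction_number
#' @return scalar `beta_c` (may exceed 1 for weakly connected networks, in
#'   which case no admissible `beta` can sustain the disturbance).
#' @export
critical_beta <- function(params, dist) {
  m <- degree_moments(dist)
  (params$b + params$mu) * (params$mu + params$gamma + params$sigma) * m$mean_k /
    (params$alpha * params$b * m$mean_k2)
}

#' Disturbance-free equilibrium E0
#'
#' Every class at `S_k = b/(b+mu)`, `I_k = R_k = 0`: immigration balances
#' emigration and no disturbance circulates.
#'
#' @param params [sirs_params()].
#' @param kmax number of classes (or a [degree_dist()]).
#' @return a [sirs_state()].
#' @export
disease_free_equilibrium <- function(params, kmax) {
  if (inherits(kmax, "degree_dist")) kmax <- kmax$kmax
  n0 <- params$b / (params$b + params$mu)
  sirs_state(S = rep(n0, kmax), I = rep(0, kmax), R = rep(0, kmax))
}

# Generalized endemic closed forms at a given edge pressure theta.
# lambda_k and s_out come from .effective_rates(); the base model has
# lambda_k = beta*k, s_out = sigma. Returns per-class S, I, R.
.endemic_closed_form <- function(theta, params, kmax, scheme = NULL) {
  er <- .effective_rates(params, kmax, scheme)
  b <- params$b; mu <- params$mu; gam <- params$gamma; del <- params$delta
  s <- er$s_out
  out <- mu + gam + s
  den <- (b + mu) * (mu + del) * out +
    ((out + b) * (mu + del) + (b - del) * s) * er$lambda * theta
  list(
    S = b * (mu + del) * out / den,
    I = b * er$lambda * theta * (mu + del) / den,
    R = s * b * er$lambda * theta / den
  )
}

#' Endemic self-consistency map f(theta)
#'
#' Substituting the stationary closed forms into the definition of the edge
#' pressure yields a scalar fixed-point problem \eqn{\theta = f(\theta)}.
#' `f` is zero at zero, strictly increasing, concave, bounded by 1 on (0,1],
#' and `f'(0) = rho`, so a positive root exists iff `rho > 1`.
#'
#' @param theta_val scalar in [0,1].
#' @param params [sirs_params()].
#' @param dist [degree_dist()].
#' @param scheme optional protection scheme (modifies the map the same way it
#'   modifies the dynamics).
#' @return scalar `f(theta_val)`.
#' @export
self_consistency <- function(theta_val, params, dist, scheme = NULL) {
  stopifnot(theta_val >= 0, theta_val <= 1)
  eq <- .endemic_closed_form(theta_val, params, dist$kmax, scheme)
  infection_pressure(eq$I, dist, params$alpha)
}

#' Stationary edge pressure theta_inf
#'
#' Unique positive root of `f(theta) - theta` on (0,1], located by bisection
#' (`f` is concave with `f'(0) = rho > 1` and `f(1) < 1`, so the root is
#' bracketed and simple). Errors when `rho <= 1`, in which case no endemic
#' state exists.
#'
#' @inheritParams self_consistency
#' @param tol residual tolerance on `|f(theta) - theta|`.
#' @return scalar `theta_inf` in (0, 1].
#' @export
endemic_theta <- function(params, dist, scheme = NULL, tol = 1e-12) {
  rho <- .scheme_rho(params, dist, scheme)
  if (rho <= 1)
    stop(sprintf("no endemic equilibrium: reproduction number %.4f <= 1", rho))
  g <- function(th) self_consistency(th, params, dist, scheme) - th
  lo <- 1e-12
  if (g(lo) <= 0) stop("failed to bracket the endemic root near 0")  # cannot happen when rho > 1
  hi <- 1
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-16 && abs(g(mid)) < tol) break
  }
  th <- (lo + hi) / 2
  if (abs(g(th)) > tol * 10)
    warning(sprintf("endemic root residual %.3e above tolerance", abs(g(th))))
  th
}

#' Endemic equilibrium E+
#'
#' Per-class stationary densities evaluated from the closed forms at
#' `theta_inf`. Exists (and is then globally stable) iff the reproduction
#' number exceeds 1. `I_k` increases with `k`: better-connected species carry
#' more standing disturbance. The ratio `R_k/I_k = sigma/(mu+delta)` is
#' degree-independent.
#'
#' @inheritParams self_consistency
#' @return list of class `endemic_equilibrium`: `theta_inf`, vectors
#'   `S_inf`, `I_inf`, `R_inf`, and population aggregates `S`, `I`, `R`
#'   (probability-weighted sums over classes).
#' @export
endemic_equilibrium <- function(params, dist, scheme = NULL) {
  th <- endemic_theta(params, dist, scheme)
  eq <- .endemic_closed_form(th, params, dist$kmax, scheme)
  structure(list(
    theta_inf = th,
    S_inf = eq$S, I_inf = eq$I, R_inf = eq$R,
    S = sum(dist$p * eq$S), I = sum(dist$p * eq$I), R = sum(dist$p * eq$R)
  ), class = "endemic_equilibrium")
}

#' @export
print.endemic_equilibrium <- function(x, ...) {
  cat(sprintf("Endemic equilibrium: theta_inf = %.6f, aggregates S = %.4f, I = %.4f, R = %.4f\n",
              x$theta_inf, x$S, x$I, x$R))
  invisible(x)
}

#' Integrate the degree-block dynamics
#'
#' Adaptive stiff-capable integration (lsoda) of the `3 kmax` coupled
#' equations. Stored states are lightly clipped to `[0,1]` only when solver
#' error takes them within tolerance outside the admissible box.
#'
#' @param params [sirs_params()].
#' @param dist [degree_dist()].
#' @param init initial [sirs_state()]; default [default_init()] with
#'   `i0 = 0.1`.
#' @param t_end final time.
#' @param times storage grid (default 401 points on `[0, t_end]`, with
#'   `t_end - 50` inserted for the convergence check).
#' @param scheme optional protection scheme.
#' @param reltol,abstol solver tolerances.
#' @return object of class `sirs_trajectory`: `times`, matrices `S`, `I`, `R`
#'   (time by class), data frame `aggregates` with columns `t, S, I, R`
#'   (probability-weighted), and `converged` (sup-norm change below 1e-10
#'   over the last 50 time units).
#' @export
simulate_sirs <- function(params, dist, init = NULL, t_end = 2000,
                          times = NULL, scheme = NULL,
                          reltol = 1e-9, abstol = 1e-11) {
  stopifnot(inherits(params, "sirs_params"), inherits(dist, "degree_dist"))
  if (is.null(init)) init <- default_init(params, dist$kmax)
  stopifnot(inherits(init, "sirs_state"))
  if (init$kmax != dist$kmax) stop("init and distribution kmax differ")
  if (is.null(times)) times <- seq(0, t_end, length.out = 401L)
  if (t_end > 50 && !any(abs(times - (t_end - 50)) < 1e-9))
    times <- sort(c(times, t_end - 50))
  kmax <- dist$kmax
  er <- .effective_rates(params, kmax, scheme)
  k <- seq_len(kmax)
  m <- degree_moments(dist)
  wk <- params$alpha * k * dist$p / m$mean_k  # theta weights
  b <- params$b; mu <- params$mu; gam <- params$gamma; del <- params$delta
  out_I <- mu + gam + er$s_out
  deriv <- function(t, y, parms) {
    S <- y[k]; I <- y[kmax + k]; R <- y[2 * kmax + k]
    th <- sum(wk * I)
    inf <- er$lambda * th * S
    dS <- b * (1 - S - I - R) - inf - mu * S + del * R
    dI <- inf - out_I * I
    dR <- er$s_out * I - (mu + del) * R
    list(c(dS, dI, dR))
  }
  sol <- deSolve::ode(y = c(init$S, init$I, init$R), times = times,
                      func = deriv, parms = NULL, method = "lsoda",
                      rtol = reltol, atol = abstol)
  if (attr(sol, "istate")[1] < 0) stop("integration failed; tighten tolerances or shorten t_end")
  S <- sol[, 1 + k, drop = FALSE]
  I <- sol[, 1 + kmax + k, drop = FALSE]
  R <- sol[, 1 + 2 * kmax + k, drop = FALSE]
  agg <- data.frame(t = sol[, 1],
                    S = as.vector(S %*% dist$p),
                    I = as.vector(I %*% dist$p),
                    R = as.vector(R %*% dist$p))
  converged <- FALSE
  i50 <- which(abs(sol[, 1] - (t_end - 50)) < 1e-9)
  if (length(i50) == 1L) {
    last <- nrow(sol)
    converged <- max(abs(sol[last, -1] - sol[i50, -1])) < 1e-10
  }
  structure(list(times = sol[, 1], S = S, I = I, R = R, aggregates = agg,
                 converged = converged, params = params, dist = dist,
                 scheme = scheme),
            class = "sirs_trajectory")
}

#' @export
print.sirs_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("SIRS trajectory: %d classes, t in [%g, %g] (%d stored states)%s\n",
              ncol(x$I), x$times[1], x$times[n], n,
              if (x$converged) ", converged" else ""))
  cat(sprintf("  final aggregates: S = %.6f, I = %.6f, R = %.6f\n",
              x$aggregates$S[n], x$aggregates$I[n], x$aggregates$R[n]))
  invisible(x)
}

#' Tidy per-class trajectory
#'
#' @param x a `sirs_trajectory`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data frame with columns `t, k, S_k, I_k, R_k`.
#' @export
as.data.frame.sirs_trajectory <- function(x, row.names = NULL, optional = FALSE, ...) {
  kmax <- ncol(x$I)
  data.frame(
    t = rep(x$times, times = kmax),
    k = rep(seq_len(kmax), each = length(x$times)),
    S_k = as.vector(x$S), I_k = as.vector(x$I), R_k = as.vector(x$R)
  )
}

#' Local stability of the disturbance-free state
#'
#' Builds the `2 kmax x 2 kmax` Jacobian of the reduced (I, R) system at the
#' disturbance-free equilibrium and returns its spectrum. The spectrum
#' consists of `-(mu+delta)` (multiplicity `kmax`), `-(mu+gamma+sigma)`
#' (multiplicity `kmax - 1`) and the single nontrivial root
#' \eqn{\alpha\beta b \langle k^2\rangle / ((b+\mu)\langle k\rangle) -
#' (\mu+\gamma+\sigma)}, whose sign agrees with the sign of `rho - 1`.
#'
#' @param params [sirs_params()].
#' @param dist [degree_dist()].
#' @return list: `leading` (maximal real part), `stable` (`leading < 0`),
#'   `analytic_root` (the closed-form nontrivial eigenvalue), `eigenvalues`
#'   (full spectrum, complex).
#' @export
dfe_stability <- function(params, dist) {
  kmax <- dist$kmax
  k <- seq_len(kmax)
  m <- degree_moments(dist)
  b <- params$b; mu <- params$mu
  s0 <- b / (b + mu)
  # dI_k = beta k theta S_k - (mu+gamma+sigma) I_k, theta = alpha sum jP(j)I_j/<k>
  JII <- outer(params$beta * k * s0, params$alpha * k * dist$p / m$mean_k)
  diag(JII) <- diag(JII) - (params$mu + params$gamma + params$sigma)
  JRI <- diag(params$sigma, kmax)
  JRR <- diag(-(params$mu + params$delta), kmax)
  J <- rbind(cbind(JII, matrix(0, kmax, kmax)),
             cbind(JRI, JRR))
  ev <- eigen(J, only.values = TRUE)$values
  analytic <- params$alpha * params$beta * b * m$mean_k2 / ((b + mu) * m$mean_k) -
    (params$mu + params$gamma + params$sigma)
  list(leading = max(Re(ev)), stable = max(Re(ev)) < 0,
       analytic_root = analytic, eigenvalues = ev)
}
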