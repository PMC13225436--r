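#' Canned parameter regimes and topologies
#'
#' Named fixtures reproducing the numerical-experiment setups used throughout
#' the package's documentation and tests. All dynamic regimes share
#' `b = mu = gamma = 0.1` and the truncated inverse-degree topology
#' `P(k) = 0.26/k`, `k = 1..31` (renormalized; the raw masses sum to about
#' 1.047):
#' \describe{
#'   \item{`"fig5"`}{outbreak regime: `beta = 0.8, sigma = delta = 0.5`
#'     (reproduction number well above 1).}
#'   \item{`"fig6"`}{extinction regime: `beta = 0.05, sigma = delta = 0.5`
#'     (reproduction number below 1).}
#'   \item{`"fig7"`}{sweep of `beta` in 0.2..0.8 at
#'     `sigma = delta = 0.5` (focal class `k = 5`).}
#'   \item{`"fig8"`}{sweep of `sigma` in 0.1..0.9 at `beta = 0.8,
#'     delta = 0.5`.}
#'   \item{`"fig9"`}{sweep of `delta` in 0.2..0.8 at `beta = 0.8,
#'     sigma = 0.5`.}
#'   \item{`"otago-moments"`}{published degree statistics of the 85-species
#'     Otago pine-forest food web: `<k> = 5.36`, `<k^2> = 62.66`,
#'     `kmax = 31` — a [degree_moments()] object for threshold arithmetic.}
#'   \item{`"regular-k"`}{degenerate delta distribution `P(k) = 1`
#'     (argument `k`, default 5).}
#'   \item{`"star-n"`}{star network on `n` nodes (argument `n`, default 5):
#'     `P(1) = (n-1)/n`, `P(n-1) = 1/n`.}
#' }
#'
#' @param name fixture identifier.
#' @param k degree of the regular fixture.
#' @param n size of the star fixture.
#' @return list with (as applicable) `params` ([sirs_params()]), `dist`
#'   ([degree_dist()] or [degree_moments()]), `sweep` (named list of the
#'   swept parameter values), `focal_k`.
#' @examples
#' fixture("fig5")$params$beta   # 0.8
#' fixture("fig6")$params$beta   # 0.05
#' @export
fixture <- function(name, k = 5, n = 5) {
  base <- function(beta, sigma = 0.5, delta = 0.5)
    sirs_params(b = 0.1, mu = 0.1, gamma = 0.1, sigma = sigma,
                delta = delta, beta = beta)
  dist <- inverse_degree_dist(a = 0.26, kmax = 31)
  switch(name,
    "fig5" = list(params = base(0.8), dist = dist),
    "fig6" = list(params = base(0.05), dist = dist),
    "fig7" = list(params = base(0.8), dist = dist, focal_k = 5,
                  sweep = list(beta = seq(0.2, 0.8, by = 0.1))),
    "fig8" = list(params = base(0.8), dist = dist, focal_k = 5,
                  sweep = list(sigma = seq(0.1, 0.9, by = 0.2))),
    "fig9" = list(params = base(0.8), dist = dist, focal_k = 5,
                  sweep = list(delta = seq(0.2, 0.8, by = 0.1))),
    "otago-moments" = list(dist = degree_moments(5.36, 62.66),
                           n_nodes = 85, kmax = 31),
    "regular-k" = list(dist = degree_dist(stats::setNames(1, k))),
    "star-n" = list(dist = degree_dist(stats::setNames(c((n - 1) / n, 1 / n),
                                                       c(1, n - 1)))),
    stop("unknown fixture '", name, "'; available: fig5, fig6, fig7, fig8, fig9, ",
         "otago-moments, regular-k, star-n")
  )
}

#' Run a configured experiment and write its artifacts
#'
#' Thin driver over the package's engines used by the command-line front
#' end: resolves the distribution source, dispatches on the experiment kind,
#' writes the outputs plus a JSON manifest (package version, seed, config)
#' into `out_dir`.
#'
#' @param kind one of `"rho"`, `"endemic"`, `"simulate"`, `"compare"`,
#'   `"qsim"`, `"scan"`.
#' @param params [sirs_params()].
#' @param dist a [degree_dist()] / [degree_moments()] (annealed kinds) or an
#'   `igraph` network (`qsim`/`scan`).
#' @param out_dir output directory (created if needed).
#' @param seed integer seed recorded in the manifest and used by stochastic
#'   kinds.
#' @param ... forwarded to the dispatched engine (e.g. `t_end`, `phi_bar`,
#'   `beta_grid`, `steps`).
#' @return (invisibly) the result object; files are written to `out_dir`.
#' @export
run_experiment <- function(kind, params, dist, out_dir, seed = 1L, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- switch(kind,
    rho = {
      out <- list(rho = basic_reproduction_number(params, dist),
                  beta_c = critical_beta(params, dist))
      jsonlite::write_json(out, file.path(out_dir, "rho.json"),
                           auto_unbox = TRUE, digits = NA)
      out
    },
    endemic = {
      eq <- endemic_equilibrium(params, dist, ...)
      jsonlite::write_json(
        list(theta_inf = eq$theta_inf, S = eq$S, I = eq$I, R = eq$R,
             S_k = eq$S_inf, I_k = eq$I_inf, R_k = eq$R_inf),
        file.path(out_dir, "endemic.json"), auto_unbox = TRUE, digits = NA)
      eq
    },
    simulate = {
      tr <- simulate_sirs(params, dist, ...)
      utils::write.csv(as.data.frame(tr),
                       file.path(out_dir, "trajectory_classes.csv"), row.names = FALSE)
      utils::write.csv(tr$aggregates,
                       file.path(out_dir, "trajectory_aggregates.csv"), row.names = FALSE)
      tr
    },
    compare = {
      cmp <- compare_strategies(params, dist, ...)
      jsonlite::write_json(
        cmp[c("phi_bar", "rho", "rho1", "rho2", "rho3")] |>
          c(list(I_star = as.list(cmp$I_star))),
        file.path(out_dir, "compare.json"), auto_unbox = TRUE, digits = NA)
      cmp
    },
    qsim = {
      run <- quenched_run(dist, params, seed = seed, ...)
      utils::write.csv(run$densities, file.path(out_dir, "qsim_densities.csv"),
                       row.names = FALSE)
      jsonlite::write_json(list(I_inf = run$I_inf, I_inf_se = run$I_inf_se),
                           file.path(out_dir, "qsim.json"), auto_unbox = TRUE, digits = NA)
      run
    },
    scan = {
      sc <- bifurcation_scan(dist, params, seed = seed, ...)
      utils::write.csv(sc$table, file.path(out_dir, "scan.csv"), row.names = FALSE)
      jsonlite::write_json(list(critical_beta_estimate = sc$critical_beta),
                           file.path(out_dir, "scan.json"), auto_unbox = TRUE, digits = NA)
      sc
    },
    stop("unknown experiment kind: ", kind)
  )
  manifest <- list(
    package = "sirsnet",
    version = as.character(utils::packageVersion("sirsnet")),
    kind = kind, seed = seed,
    params = unclass(params),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
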