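#' Degree distribution over classes k = 1..kmax
#'
#' A `degree_dist` stores the probability \eqn{P(k)} that a randomly chosen
#' species has `k` trophic links, on the integer support `1..kmax`. It is the
#' topological input of the degree-block mean-field model: the dynamics and
#' all thresholds depend on the network only through \eqn{P(k)} (in fact only
#' through the moments \eqn{\langle k \rangle} and \eqn{\langle k^2 \rangle}).
#'
#' @param p numeric vector of probabilities. Either unnamed (taken as
#'   `P(1), P(2), ...`) or named by the degree class (`"1"`, `"2"`, ...;
#'   missing classes get probability 0).
#' @param normalize if `TRUE`, rescale `p` to sum to 1 (useful for truncated
#'   analytic laws); if `FALSE` (default), `p` must already sum to 1 within
#'   `1e-8`.
#'
#' @return An object of class `degree_dist`: list with `kmax` and the
#'   probability vector `p` (length `kmax`, entry `k` is `P(k)`). The trailing
#'   class always has positive mass.
#' @examples
#' degree_dist(c(0.8, 0, 0, 0.2))      # star on 5 nodes: P(1)=4/5, P(4)=1/5
#' degree_dist(c("4" = 1))             # 4-regular graph
#' @export
degree_dist <- function(p, normalize = FALSE) {
  if (!is.numeric(p) || length(p) == 0L) stop("'p' must be a non-empty numeric vector")
  if (!is.null(names(p))) {
    ks <- suppressWarnings(as.integer(names(p)))
    if (anyNA(ks) || any(ks < 1L)) stop("names of 'p' must be positive integer degrees")
    full <- numeric(max(ks))
    full[ks] <- p
    p <- full
  }
  if (any(!is.finite(p)) || any(p < 0)) stop("probabilities must be finite and non-negative")
  if (normalize) {
    if (sum(p) <= 0) stop("cannot normalize: total mass is zero")
    p <- p / sum(p)
  } else if (abs(sum(p) - 1) > 1e-8) {
    stop(sprintf("probabilities must sum to 1 (got %.10f); use normalize = TRUE for truncated laws", sum(p)))
  } else {
    p <- p / sum(p)  # snap to machine precision
  }
  kmax <- max(which(p > 0))
  p <- p[seq_len(kmax)]
  structure(list(kmax = kmax, p = p), class = "degree_dist")
}

#' @export
print.degree_dist <- function(x, ...) {
  m <- degree_moments(x)
  cat(sprintf("Degree distribution on k = 1..%d (%d classes with mass)\n",
              x$kmax, sum(x$p > 0)))
  cat(sprintf("  <k> = %.4f   <k^2> = %.4f   <k^2>/<k> = %.4f\n",
              m$mean_k, m$mean_k2, m$mean_k2 / m$mean_k))
  invisible(x)
}

#' First and second moments of a degree distribution
#'
#' \eqn{\langle k \rangle = \sum_k k P(k)} and
#' \eqn{\langle k^2 \rangle = \sum_k k^2 P(k)}. The ratio
#' \eqn{\langle k^2 \rangle / \langle k \rangle} is the effective (excess)
#' connectivity that enters the outbreak threshold.
#'
#' `degree_moments(mean_k, mean_k2)` with two scalars builds a moments-only
#' object; threshold functions ([basic_reproduction_number()],
#' [critical_beta()]) accept it in place of a full distribution when only the
#' published moments of a network are known.
#'
#' @param x a `degree_dist`, or the scalar \eqn{\langle k \rangle}.
#' @param mean_k2 scalar \eqn{\langle k^2 \rangle} when `x` is scalar.
#' @return list of class `degree_moments` with `mean_k`, `mean_k2`.
#' @examples
#' degree_moments(degree_dist(c("4" = 1)))   # <k>=4, <k^2>=16
#' degree_moments(5.36, 62.66)               # moments-only container
#' @export
degree_moments <- function(x, mean_k2 = NULL) {
  if (inherits(x, "degree_moments")) return(x)
  if (inherits(x, "degree_dist")) {
    k <- seq_len(x$kmax)
    out <- list(mean_k = sum(k * x$p), mean_k2 = sum(k^2 * x$p))
  } else if (is.numeric(x) && length(x) == 1L && is.numeric(mean_k2)) {
    if (x <= 0 || mean_k2 < x^2) stop("need mean_k > 0 and mean_k2 >= mean_k^2")
    out <- list(mean_k = x, mean_k2 = mean_k2)
  } else {
    stop("'x' must be a degree_dist or a pair of scalar moments")
  }
  structure(out, class = "degree_moments")
}

#' Truncated inverse-degree law P(k) = a/k
#'
#' Builds the analytic degree distribution \eqn{P(k) = a/k} on `1..kmax`.
#' With the default `a = 0.26`, `kmax = 31` this is the law fitted to the
#' 85-species Otago pine-forest food web; the raw masses sum to about 1.047,
#' so the distribution is renormalized by default (set `renormalize = FALSE`
#' to keep the raw coefficient and get an error from the constructor).
#'
#' @param a coefficient of the law (dimensionless).
#' @param kmax largest degree class.
#' @param renormalize rescale to sum to one (default `TRUE`).
#' @return a [degree_dist()].
#' @export
inverse_degree_dist <- function(a = 0.26, kmax = 31, renormalize = TRUE) {
  if (a <= 0 || kmax < 1) stop("need a > 0 and kmax >= 1")
  degree_dist(a / seq_len(kmax), normalize = renormalize)
}

#' Read / write degree distributions
#'
#' JSON layout: `{"kmax": n, "p": {"1": P1, ...}}` (classes may be sparse).
#' CSV layout: two columns `k, P` with a header.
#'
#' @param path file path; format chosen by extension (`.json` else CSV).
#' @param x a `degree_dist`.
#' @name degree_dist_io
#' @export
read_degree_dist <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    p <- unlist(obj$p)
    names(p) <- names(obj$p)
    d <- degree_dist(p)
    if (!is.null(obj$kmax) && obj$kmax != d$kmax)
      warning(sprintf("declared kmax %d != largest class with mass %d", obj$kmax, d$kmax))
    d
  } else {
    tab <- utils::read.csv(path, comment.char = "#")
    if (ncol(tab) < 2) stop("degree distribution CSV needs columns k, P")
    p <- tab[[2]]
    names(p) <- tab[[1]]
    degree_dist(p)
  }
}

#' @rdname degree_dist_io
#' @export
write_degree_dist <- function(x, path) {
  stopifnot(inherits(x, "degree_dist"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    nz <- which(x$p > 0)
    jsonlite::write_json(
      list(kmax = x$kmax, p = as.list(stats::setNames(x$p[nz], nz))),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(data.frame(k = seq_len(x$kmax), P = x$p), path, row.names = FALSE)
  }
  invisible(path)
}
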