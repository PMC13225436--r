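#' Load a food-web edge list as a simple undirected graph
#'
#' Reads a two-column text file of species identifiers (whitespace- or
#' comma-delimited, `#` comments allowed) into an undirected [igraph] graph.
#' Trophic links are treated as bidirectional disturbance pathways, so any
#' direction implied by column order is ignored (a note is emitted). Self
#' loops are dropped with a warning and parallel records are collapsed.
#'
#' @param path edge-list file.
#' @param delim field separator regular expression (default splits on commas
#'   and/or whitespace).
#' @param node_file optional one-column file naming nodes, used to retain
#'   isolated species that appear in no edge.
#' @return an undirected simple `igraph` graph.
#' @examples
#' f <- tempfile()
#' writeLines(c("# a triangle", "A B", "B C", "C A"), f)
#' g <- load_edge_list(f)
#' igraph::vcount(g); igraph::ecount(g)
#' @export
load_edge_list <- function(path, delim = "[,[:space:]]+", node_file = NULL) {
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  keep <- nzchar(lines)
  if (!any(keep)) stop("empty edge list: ", path)
  fields <- strsplit(lines[keep], delim)
  nf <- lengths(fields)
  if (any(nf < 2)) {
    bad <- which(keep)[which(nf < 2)[1]]
    stop(sprintf("malformed edge on line %d of %s: need two endpoints", bad, path))
  }
  if (any(nf > 2)) message("extra columns beyond the two endpoints are ignored (undirected, unweighted)")
  ends <- t(vapply(fields, function(x) x[1:2], character(2)))
  loops <- ends[, 1] == ends[, 2]
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop(s)", sum(loops)))
    ends <- ends[!loops, , drop = FALSE]
  }
  if (nrow(ends) == 0L) stop("no valid edges after removing self-loops")
  nodes <- unique(c(ends))
  if (!is.null(node_file)) {
    extra <- trimws(readLines(node_file, warn = FALSE))
    extra <- extra[nzchar(extra) & !startsWith(extra, "#")]
    nodes <- unique(c(nodes, extra))
  }
  g <- igraph::graph_from_data_frame(as.data.frame(ends), directed = FALSE,
                                     vertices = data.frame(name = nodes))
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Empirical degree distribution of a network
#'
#' `P(k)` = fraction of species with `k` trophic links, on support
#' `k = 1..kmax`. Degree-0 (isolated) species are excluded from the support
#' (the degree-block model indexes classes from k = 1); their count is
#' reported via a message.
#'
#' @param net an undirected simple `igraph` graph.
#' @return a [degree_dist()].
#' @export
degree_distribution_net <- function(net) {
  stopifnot(inherits(net, "igraph"))
  deg <- igraph::degree(net)
  n0 <- sum(deg == 0)
  if (n0 > 0) message(sprintf("excluding %d degree-0 node(s) from the distribution", n0))
  deg <- deg[deg > 0]
  if (length(deg) == 0L) stop("all nodes have degree 0; no degree distribution")
  counts <- tabulate(deg)
  degree_dist(counts / sum(counts))
}

#' Summary statistics of a network
#'
#' @param net an undirected simple `igraph` graph.
#' @return list of class `network_summary`: `n_nodes`, `n_edges`, `kmax`,
#'   `mean_degree`, `second_moment` (moments over all nodes, including any
#'   isolated ones, so that `mean_degree = 2 e / n`).
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "igraph"))
  deg <- igraph::degree(net)
  structure(list(
    n_nodes = igraph::vcount(net),
    n_edges = igraph::ecount(net),
    kmax = max(deg),
    mean_degree = mean(deg),
    second_moment = mean(deg^2)
  ), class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("Network: %d nodes, %d edges, kmax = %d, <k> = %.4f, <k^2> = %.4f\n",
              x$n_nodes, x$n_edges, x$kmax, x$mean_degree, x$second_moment))
  invisible(x)
}

#' Fit the inverse-degree law P(k) = a/k
#'
#' Least-squares fit of \eqn{P(k) = a/k} over the observed degree classes
#' with positive mass, unweighted in `P`. The model is linear in `a`, so the
#' least-squares problem is solved exactly by regression through the origin
#' on the predictor `1/k`; the 95% confidence interval comes from the
#' linearized standard error and R-squared is the usual
#' \eqn{1 - SS_{res}/SS_{tot}} about the mean observed `P`.
#'
#' @param dist a [degree_dist()] (needs at least 3 classes with mass), or an
#'   `igraph` graph (its empirical distribution is fitted).
#' @return list of class `inverse_degree_fit`: `a`, `ci_low`, `ci_high`
#'   (95%), `r_squared`, `n_classes`.
#' @examples
#' fit_inverse_degree(inverse_degree_dist(a = 0.26, kmax = 31))  # exact: R^2 = 1
#' @export
fit_inverse_degree <- function(dist) {
  if (inherits(dist, "igraph")) dist <- degree_distribution_net(dist)
  stopifnot(inherits(dist, "degree_dist"))
  keep <- which(dist$p > 0)
  if (length(keep) < 3L) stop("need at least 3 degree classes with positive mass to fit a/k")
  dat <- data.frame(P = dist$p[keep], invk = 1 / keep)
  fit <- stats::lm(P ~ 0 + invk, data = dat)
  a <- unname(stats::coef(fit)[1])
  # noiseless input makes summary.lm warn about a perfect fit; the zero
  # standard error is exactly what we want to report then
  se <- suppressWarnings(summary(fit)$coefficients[1, 2])
  tq <- stats::qt(0.975, df = length(keep) - 1L)
  ssres <- sum(stats::residuals(fit)^2)
  sstot <- sum((dat$P - mean(dat$P))^2)
  r2 <- if (sstot > 0) 1 - ssres / sstot else 1
  structure(list(a = a, ci_low = a - tq * se, ci_high = a + tq * se,
                 r_squared = r2, n_classes = length(keep)),
            class = "inverse_degree_fit")
}

#' @export
print.inverse_degree_fit <- function(x, ...) {
  cat(sprintf("P(k) = a/k fit over %d classes: a = %.4f (95%% CI %.4f, %.4f), R^2 = %.4f\n",
              x$n_classes, x$a, x$ci_low, x$ci_high, x$r_squared))
  invisible(x)
}

#' Generate a configuration-model network with a given degree distribution
#'
#' Samples a degree sequence i.i.d. from `dist` (the last entry is resampled
#' until the total degree is even) and wires it into a *simple* undirected
#' graph by stub matching with rejection of self-loops and multi-edges
#' (igraph's restarting heuristic). Realized degrees match the sampled
#' sequence exactly, so the realized distribution converges to `dist` as `n`
#' grows. Deterministic for a fixed `seed`.
#'
#' @param dist a [degree_dist()].
#' @param n_nodes number of nodes (>= 2).
#' @param seed integer seed.
#' @param max_retries attempts at drawing a realizable sequence / wiring.
#' @return an undirected simple `igraph` graph with `n_nodes` vertices.
#' @export
generate_configuration_network <- function(dist, n_nodes, seed, max_retries = 100L) {
  stopifnot(inherits(dist, "degree_dist"), n_nodes >= 2)
  ks <- seq_len(dist$kmax)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  for (try in seq_len(max_retries)) {
    deg <- sample(ks, n_nodes, replace = TRUE, prob = dist$p)
    while (sum(deg) %% 2L == 1L)
      deg[n_nodes] <- sample(ks, 1L, prob = dist$p)
    g <- tryCatch(
      igraph::sample_degseq(deg, method = "fast.heur.simple"),
      error = function(e) NULL)
    if (!is.null(g)) {
      igraph::V(g)$name <- paste0("v", seq_len(n_nodes))
      return(g)
    }
  }
  stop(sprintf("could not realize a simple graph from the sampled degree sequence in %d attempts", max_retries))
}
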