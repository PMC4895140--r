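#' Build a configuration-model population
#'
#' Draws a degree sequence from the degree law, wires it as a configuration
#' model (stub matching, then erasure of self-loops and multi-edges so the
#' substrate is a simple graph), and decorates nodes with the static
#' attributes of the contagion model: a fraction `r` of immune nodes that
#' never adopt (placed uniformly at random, exactly `round(r * n)` of them)
#' and i.i.d. behavioural thresholds for the rest, independent of degree.
#'
#' An odd stub sum is resolved by adding one stub to the first node, as is
#' standard for configuration-model samplers.
#'
#' @param degree A [degree_model()].
#' @param threshold A [threshold_model()].
#' @param n Number of nodes (at least 2).
#' @param r Fraction of immune nodes in `[0, 1]`.
#' @return An object of class `population`: a list with `graph` (igraph),
#'   `nodes` (tibble: `node`, `degree` (realised), `immune`, `threshold`),
#'   `n`, `r`, and the generating models.
#' @examples
#' set.seed(1)
#' pop <- build_population(degree_model(1.09, 1.39), threshold_model(-2, 1),
#'                         n = 500, r = 0.5)
#' @export
build_population <- function(degree, threshold, n, r) {
  stopifnot(inherits(degree, "degree_model"),
            inherits(threshold, "threshold_model"))
  if (n < 2) stop("`n` must be >= 2", call. = FALSE)
  if (r < 0 || r > 1) stop("`r` must lie in [0, 1]", call. = FALSE)
  deg <- sample_degrees(degree, n)
  if (sum(deg) %% 2 == 1) deg[1] <- deg[1] + 1L
  g <- igraph::sample_degseq(deg, method = "configuration")
  g <- igraph::simplify(g)
  realised <- igraph::degree(g)
  n_imm <- round(r * n)
  immune <- logical(n)
  if (n_imm > 0) immune[sample.int(n, n_imm)] <- TRUE
  phi <- rep(NA_real_, n)
  if (n_imm < n) phi[!immune] <- sample_thresholds(threshold, n - n_imm)
  nodes <- tibble::tibble(
    node = seq_len(n),
    degree = as.integer(realised),
    immune = immune,
    threshold = phi
  )
  structure(
    list(graph = g, nodes = nodes, n = n, r = r,
         degree_model = degree, threshold_model = threshold),
    class = "population"
  )
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf(
    "<population> %d nodes, %d edges, mean degree %.2f, immune fraction %.3f\n",
    x$n, igraph::ecount(x$graph), mean(x$nodes$degree), mean(x$nodes$immune)))
  invisible(x)
}

#' Discretise the threshold law into M types
#'
#' The continuous threshold distribution is replaced by M discrete types
#' with equal masses 1/M, located at the quantile midpoints of the
#' truncated law (type c sits at the ((c - 1/2)/M)-quantile). Quantile
#' placement makes the discretised mean converge to the true truncated mean
#' as M grows. Type c = 0 is reserved for immune nodes and carries no
#' threshold.
#'
#' @param threshold A [threshold_model()].
#' @param M Number of non-zero types (at least 1).
#' @return An object of class `type_scheme`: tibble with columns `type`
#'   (1..M), `phi`, `prob`.
#' @export
discretise_types <- function(threshold, M) {
  stopifnot(inherits(threshold, "threshold_model"), M >= 1)
  phi <- threshold_quantile(threshold, (seq_len(M) - 0.5) / M)
  out <- tibble::tibble(type = seq_len(M), phi = phi, prob = rep(1 / M, M))
  class(out) <- c("type_scheme", class(out))
  out
}

#' Geometric degree classes for the AME
#'
#' Reduces the degree support to `n_classes` representative degrees spaced
#' geometrically on `[k_lo, k_hi]`. Probability mass of degrees outside the
#' class range, and between classes, is folded onto the nearest class on
#' the log scale (boundary classes absorb the tails).
#'
#' @param model A [degree_model()].
#' @param k_lo,k_hi Smallest / largest class degree.
#' @param n_classes Number of classes.
#' @param n Population size used for the structural cutoff of the base pmf.
#' @return A tibble with columns `k` (class degrees) and `p` (folded mass).
#' @export
degree_classes <- function(model, k_lo = 3, k_hi = 150, n_classes = 25,
                           n = 1e4) {
  stopifnot(inherits(model, "degree_model"), k_lo >= 1, k_hi > k_lo)
  cls <- unique(round(exp(seq(log(k_lo), log(k_hi), length.out = n_classes))))
  pmf <- degree_pmf(model, n)
  idx <- vapply(pmf$k, function(k) which.min(abs(log(k) - log(cls))), 1L)
  p <- vapply(seq_along(cls), function(i) sum(pmf$p[idx == i]), 1.0)
  tibble::tibble(k = as.integer(cls), p = p)
}

#' Export / import a population as plain-text files
#'
#' The substrate is written as a two-column whitespace edge list and node
#' attributes as a CSV (`node, degree, immune, threshold`). The reader
#' reassembles a `population` object (generating models are not preserved).
#'
#' @param pop A `population`.
#' @param edge_file,node_file File paths.
#' @return `write_population()` invisibly returns `pop`; `read_population()`
#'   returns a `population`.
#' @export
write_population <- function(pop, edge_file, node_file) {
  stopifnot(inherits(pop, "population"))
  write_edge_list(pop$graph, edge_file)
  utils::write.csv(pop$nodes, node_file, row.names = FALSE)
  invisible(pop)
}

#' @rdname write_population
#' @export
read_population <- function(edge_file, node_file) {
  nodes <- tibble::as_tibble(utils::read.csv(node_file))
  g <- read_edge_list(edge_file, n = max(nodes$node))
  structure(
    list(graph = g, nodes = nodes, n = nrow(nodes),
         r = mean(nodes$immune),
         degree_model = NULL, threshold_model = NULL),
    class = "population"
  )
}
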