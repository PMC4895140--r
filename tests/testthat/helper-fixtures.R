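# Build a population on an explicit graph with explicit thresholds,
# bypassing the random generators (for hand-computable cases).
make_population <- function(graph, thresholds, immune = NULL) {
  n <- igraph::vcount(graph)
  if (is.null(immune)) immune <- rep(FALSE, n)
  thresholds <- rep_len(thresholds, n)
  thresholds[immune] <- NA_real_
  structure(
    list(
      graph = graph,
      nodes = tibble::tibble(node = seq_len(n),
                             degree = as.integer(igraph::degree(graph)),
                             immune = immune, threshold = thresholds),
      n = n, r = mean(immune),
      degree_model = NULL, threshold_model = NULL
    ),
    class = "population"
  )
}

events_tbl <- function(node, t) tibble::tibble(node = as.integer(node),
                                               t = as.integer(t))

# Independent flood-fill component oracle: multiset of component sizes.
flood_fill_sizes <- function(n, edges) {
  adj <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- logical(n)
  sizes <- integer(0)
  for (v in seq_len(n)) {
    if (seen[v]) next
    queue <- v
    seen[v] <- TRUE
    sz <- 0L
    while (length(queue) > 0) {
      u <- queue[[1]]
      queue <- queue[-1]
      sz <- sz + 1L
      for (w in adj[[u]]) if (!seen[w]) {
        seen[w] <- TRUE
        queue <- c(queue, w)
      }
    }
    sizes <- c(sizes, sz)
  }
  sort(sizes, decreasing = TRUE)
}

# A small Erdos-Renyi style random substrate plus a random event log.
random_toy <- function(n = 30, p_edge = 0.12, t_max = 6,
                       adopt_frac = 0.7) {
  g <- igraph::sample_gnp(n, p_edge)
  adopters <- sort(sample.int(n, max(1, round(adopt_frac * n))))
  list(graph = g,
       events = events_tbl(adopters,
                           sample.int(t_max, length(adopters),
                                      replace = TRUE)))
}

ref_degree <- function() degree_model(1.09, 1.39)
ref_threshold <- function() threshold_model(-2, 1)
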