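as_substrate <- function(x) {
  if (inherits(x, "population")) return(x$graph)
  if (igraph::is_igraph(x)) return(x)
  stop("substrate must be a `population` or an igraph graph", call. = FALSE)
}

check_events <- function(graph, events) {
  stopifnot(all(c("node", "t") %in% names(events)))
  if (anyDuplicated(events$node))
    stop("duplicate adoption record for node(s): ",
         paste(unique(events$node[duplicated(events$node)]), collapse = ", "),
         call. = FALSE)
  bad <- events$node[events$node < 1 | events$node > igraph::vcount(graph)]
  if (length(bad) > 0)
    stop("adopter(s) absent from substrate: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  invisible(events)
}

# Integer thresholds for all adopters: number of neighbours with strictly
# earlier adoption time. Same-time adopters are mutually invisible.
phi_k_counts <- function(graph, events) {
  n <- igraph::vcount(graph)
  times <- rep(NA_real_, n)
  times[events$node] <- events$t
  el <- igraph::as_edgelist(graph, names = FALSE)
  ta <- times[el[, 1]]
  tb <- times[el[, 2]]
  keep <- !is.na(ta) & !is.na(tb) & ta != tb
  a_first <- ta[keep] < tb[keep]
  tabulate(c(el[keep, 2][a_first], el[keep, 1][!a_first]), n)
}

#' Classify adopters as innovator, vulnerable or stable
#'
#' For each adopter, the integer threshold Phi_k is the number of its
#' substrate neighbours whose adoption time is strictly earlier than its
#' own; neighbours adopting at the same time are excluded, because
#' same-time (group) adoptions carry no evidence of social influence.
#' Classes: innovator (Phi_k = 0), vulnerable (Phi_k = 1), stable
#' (Phi_k > 1).
#'
#' @param substrate A `population` or igraph graph.
#' @param events Event log tibble with columns `node`, `t`.
#' @return A tibble with columns `node`, `t`, `degree`, `phi_k`, `class`.
#' @export
classify_adopters <- function(substrate, events) {
  graph <- as_substrate(substrate)
  check_events(graph, events)
  phik <- phi_k_counts(graph, events)
  deg <- igraph::degree(graph)
  tibble::tibble(
    node = events$node,
    t = events$t,
    degree = as.integer(deg[events$node]),
    phi_k = phik[events$node],
    class = dplyr::case_when(
      phik[events$node] == 0L ~ "innovator",
      phik[events$node] == 1L ~ "vulnerable",
      TRUE ~ "stable"
    )
  )
}

adoption_edges <- function(graph, events, at = Inf) {
  n <- igraph::vcount(graph)
  times <- rep(NA_real_, n)
  times[events$node] <- events$t
  el <- igraph::as_edgelist(graph, names = FALSE)
  ta <- times[el[, 1]]
  tb <- times[el[, 2]]
  keep <- !is.na(ta) & !is.na(tb) & ta != tb & ta <= at & tb <= at
  el[keep, , drop = FALSE]
}

graph_on <- function(nodes, edges) {
  igraph::graph_from_data_frame(
    d = data.frame(from = as.character(as.integer(edges[, 1])),
                   to = as.character(as.integer(edges[, 2]))),
    directed = FALSE,
    vertices = data.frame(name = as.character(as.integer(nodes)))
  )
}

#' Build the adoption network at time t
#'
#' Vertex set: all nodes adopted at or before `at`. Edge set: substrate
#' edges between adopters with distinct adoption times (same-time links are
#' excluded). Vertex names carry the original node ids.
#'
#' @inheritParams classify_adopters
#' @param at Evaluation time (default: whole log).
#' @return An igraph graph.
#' @export
build_adoption_network <- function(substrate, events, at = Inf) {
  graph <- as_substrate(substrate)
  check_events(graph, events)
  adopters <- events$node[events$t <= at]
  graph_on(adopters, adoption_edges(graph, events, at))
}

#' Induced subgraph of stable adopters
#'
#' Restriction of the adoption network at time `at` to stable adopters
#' (Phi_k > 1); the same-time edge exclusion applies. In the rapid-cascade
#' regime this subgraph develops a percolating cluster that holds the
#' global adoption component together.
#'
#' @inheritParams build_adoption_network
#' @return An igraph graph on the stable adopters.
#' @export
stable_subnetwork <- function(substrate, events, at = Inf) {
  graph <- as_substrate(substrate)
  ev <- events[events$t <= at, , drop = FALSE]
  cls <- classify_adopters(graph, ev)
  stable <- cls$node[cls$class == "stable"]
  ed <- adoption_edges(graph, ev)
  sel <- ed[, 1] %in% stable & ed[, 2] %in% stable
  graph_on(stable, ed[sel, , drop = FALSE])
}

#' Connected-component statistics
#'
#' Exact connected components with the sizes of the largest (LC) and second
#' largest (LC2) components and the full component-size distribution.
#' Relative sizes are reported against both the graph's own node count and,
#' when supplied, a reference total (typically the substrate size N).
#'
#' @param graph An igraph graph.
#' @param n_total Optional reference denominator (substrate N).
#' @return An object of class `component_stats`: list with `lc`, `lc2`,
#'   `n_nodes`, `n_total`, `lc_frac` (vs `n_total` when given, else vs
#'   `n_nodes`), and `sizes` (tibble `size`, `count`).
#' @export
component_stats <- function(graph, n_total = NULL) {
  if (igraph::vcount(graph) == 0) {
    sizes <- tibble::tibble(size = integer(0), count = integer(0))
    out <- list(lc = 0L, lc2 = 0L, n_nodes = 0L, n_total = n_total,
                lc_frac = 0, sizes = sizes)
    class(out) <- "component_stats"
    return(out)
  }
  cs <- igraph::components(graph)$csize
  srt <- sort(cs, decreasing = TRUE)
  lc <- srt[1]
  lc2 <- if (length(srt) >= 2) srt[2] else 0L
  denom <- if (is.null(n_total)) igraph::vcount(graph) else n_total
  sizes <- tibble::as_tibble(as.data.frame(table(size = cs),
                                           stringsAsFactors = FALSE)) |>
    dplyr::mutate(size = as.integer(.data$size),
                  count = as.integer(.data$Freq)) |>
    dplyr::select("size", "count") |>
    dplyr::arrange(.data$size)
  out <- list(lc = as.integer(lc), lc2 = as.integer(lc2),
              n_nodes = igraph::vcount(graph), n_total = n_total,
              lc_frac = lc / denom, sizes = sizes)
  class(out) <- "component_stats"
  out
}

#' @export
print.component_stats <- function(x, ...) {
  cat(sprintf("<component_stats> %d nodes, LC = %d, LC2 = %d (LC frac %.4f)\n",
              x$n_nodes, x$lc, x$lc2, x$lc_frac))
  invisible(x)
}

#' Decompose the adoption process into vulnerable trees
#'
#' Every vulnerable adopter (Phi_k = 1) is assigned a unique parent: its
#' earliest strictly-earlier adopting neighbour, ties broken by smallest
#' node id. Parent chains are followed through vulnerable nodes up to a
#' non-vulnerable root (an innovator or a stable adopter), giving a
#' node-disjoint forest of trees whose adoption times increase strictly
#' along root-to-leaf paths. Tree size `s_v` counts the vulnerable members
#' (the root is not a member); depth `d` is the maximum hop distance from
#' the root, so a single vulnerable node hanging off its root has d = 1.
#'
#' @inheritParams classify_adopters
#' @return An object of class `vulnerable_forest`: list with `trees`
#'   (tibble: `root`, `root_class`, `root_degree`, `size`, `depth`),
#'   `members` (tibble: `node`, `root`, `parent`, `depth`), and `n_orphans`
#'   (vulnerable nodes without a strictly-earlier neighbour; only possible
#'   on inconsistent inputs, excluded from the forest).
#' @export
vulnerable_forest <- function(substrate, events) {
  graph <- as_substrate(substrate)
  cls <- classify_adopters(graph, events)
  n <- igraph::vcount(graph)
  times <- rep(NA_real_, n)
  times[events$node] <- events$t
  vuln <- cls$node[cls$class == "vulnerable"]
  is_vuln <- logical(n)
  is_vuln[vuln] <- TRUE

  # candidate parent links: (child = vulnerable, parent strictly earlier)
  el <- igraph::as_edgelist(graph, names = FALSE)
  ta <- times[el[, 1]]
  tb <- times[el[, 2]]
  ok <- !is.na(ta) & !is.na(tb)
  child <- c(el[ok & is_vuln[el[, 2]] & ta < tb, 2],
             el[ok & is_vuln[el[, 1]] & tb < ta, 1])
  parent <- c(el[ok & is_vuln[el[, 2]] & ta < tb, 1],
              el[ok & is_vuln[el[, 1]] & tb < ta, 2])
  if (length(child) > 0) {
    ord <- order(child, times[parent], parent)
    child <- child[ord]
    parent <- parent[ord]
    first <- !duplicated(child)
    child <- child[first]
    parent <- parent[first]
  }
  par_of <- rep(NA_integer_, n)
  par_of[child] <- parent
  orphans <- vuln[is.na(par_of[vuln])]
  if (length(orphans) > 0)
    warning(length(orphans),
            " vulnerable node(s) without a strictly-earlier neighbour; excluded",
            call. = FALSE)
  members <- setdiff(vuln, orphans)

  root <- rep(NA_integer_, n)
  depth <- rep(NA_integer_, n)
  for (v in members[order(times[members])]) { # parents adopt strictly earlier
    p <- par_of[v]
    if (is_vuln[p] && !is.na(root[p])) {
      root[v] <- root[p]
      depth[v] <- depth[p] + 1L
    } else {
      root[v] <- p
      depth[v] <- 1L
    }
  }
  mem_tbl <- tibble::tibble(
    node = members,
    root = root[members],
    parent = par_of[members],
    depth = depth[members]
  )
  deg <- igraph::degree(graph)
  root_class <- stats::setNames(cls$class, cls$node)
  trees <- mem_tbl |>
    dplyr::group_by(root = .data$root) |>
    dplyr::summarise(size = dplyr::n(), depth = max(.data$depth)) |>
    dplyr::mutate(
      root_class = unname(root_class[as.character(.data$root)]),
      root_degree = as.integer(deg[.data$root])
    ) |>
    dplyr::select("root", "root_class", "root_degree", "size", "depth")
  structure(list(trees = trees, members = mem_tbl,
                 n_orphans = length(orphans)),
            class = "vulnerable_forest")
}

#' @export
print.vulnerable_forest <- function(x, ...) {
  cat(sprintf(
    "<vulnerable_forest> %d trees, %d vulnerable members, max depth %s\n",
    nrow(x$trees), nrow(x$members),
    if (nrow(x$trees)) max(x$trees$depth) else "-"))
  invisible(x)
}

#' Mean vulnerable-tree size by innovator degree
#'
#' The correlation <s_v>(k) between the substrate degree of an innovator
#' and the average size of the vulnerable trees it induces; only trees
#' rooted at innovators enter.
#'
#' @param forest A [vulnerable_forest()] result.
#' @return A tibble with columns `k` (root degree), `mean_size`, `n_trees`.
#' @export
innovator_tree_correlation <- function(forest) {
  stopifnot(inherits(forest, "vulnerable_forest"))
  forest$trees |>
    dplyr::filter(.data$root_class == "innovator") |>
    dplyr::group_by(k = .data$root_degree) |>
    dplyr::summarise(mean_size = mean(.data$size), n_trees = dplyr::n()) |>
    dplyr::arrange(.data$k)
}

#' Maximum relative growth rate (RGR) of cumulative adoption
#'
#' The maximum over calendar years of the yearly adoption count divided by
#' the final cumulative adoption number; 0 means no cascade, 1 an
#' instantaneous cascade. Event times are months; year j spans months
#' `(j-1)*months_per_year + 1 .. j*months_per_year`.
#'
#' @param x An event log tibble (columns `node`, `t`) or a numeric vector
#'   of yearly adoption counts.
#' @param months_per_year Months per calendar year (default 12).
#' @return A single number in `[0, 1]`.
#' @export
max_relative_growth_rate <- function(x, months_per_year = 12) {
  if (is.data.frame(x)) {
    if (nrow(x) == 0) stop("empty event log: RGR undefined", call. = FALSE)
    yr <- (x$t - 1) %/% months_per_year + 1
    counts <- tabulate(yr)
  } else {
    counts <- as.numeric(x)
  }
  total <- sum(counts)
  if (total <= 0) stop("zero total adoptions: RGR undefined", call. = FALSE)
  max(counts) / total
}
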