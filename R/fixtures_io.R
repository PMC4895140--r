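read_lines_clean <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- sub("\r$", "", x) # CRLF tolerance
  keep <- !grepl("^\\s*(#|$)", x)
  list(lines = x[keep], lineno = which(keep))
}

#' Read and write adoption event logs
#'
#' Event logs are CSV files with columns `node`, `t`: one record per
#' adopter, integer adoption times (months) in `[1, T]`. Comment lines
#' (`#`) and CRLF endings are tolerated; malformed lines and duplicate
#' node records are rejected with their line numbers.
#'
#' @param path File path.
#' @param events A tibble with columns `node`, `t`.
#' @return `read_event_log()` returns a tibble (`node`, `t`);
#'   `write_event_log()` invisibly returns `events`.
#' @export
read_event_log <- function(path) {
  lc <- read_lines_clean(path)
  lines <- lc$lines
  if (length(lines) > 0 && grepl("^\\s*node\\s*,", lines[1])) {
    lc$lineno <- lc$lineno[-1]
    lines <- lines[-1]
  }
  if (length(lines) == 0) return(tibble::tibble(node = integer(0),
                                                t = integer(0)))
  parts <- strsplit(lines, ",")
  bad <- which(lengths(parts) != 2)
  node <- suppressWarnings(as.integer(trimws(vapply(parts, `[`, "", 1))))
  t <- suppressWarnings(as.numeric(trimws(vapply(parts, function(p)
    if (length(p) >= 2) p[2] else NA_character_, ""))))
  bad <- sort(union(bad, which(is.na(node) | is.na(t) | t < 0 |
                                 t != floor(t))))
  if (length(bad) > 0)
    stop("malformed event-log line(s): ",
         paste(lc$lineno[bad], collapse = ", "), call. = FALSE)
  if (anyDuplicated(node))
    stop("duplicate adoption record for node(s): ",
         paste(unique(node[duplicated(node)]), collapse = ", "),
         call. = FALSE)
  tibble::tibble(node = node, t = as.integer(t))
}

#' @rdname read_event_log
#' @export
write_event_log <- function(events, path) {
  stopifnot(all(c("node", "t") %in% names(events)))
  utils::write.csv(events[, c("node", "t")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(events)
}

#' Read and write substrate edge lists
#'
#' Edge lists are two-column whitespace-separated files of unordered node
#' pairs; duplicates are collapsed and self-loops rejected. Node ids are
#' positive integers; `n` fixes the vertex count when isolated nodes exist
#' beyond the largest id seen in an edge.
#'
#' @param path File path.
#' @param graph An igraph graph.
#' @param n Number of vertices (default: largest id in the file).
#' @return `read_edge_list()` returns an igraph graph;
#'   `write_edge_list()` invisibly returns `graph`.
#' @export
read_edge_list <- function(path, n = NULL) {
  lc <- read_lines_clean(path)
  if (length(lc$lines) == 0) {
    return(igraph::make_empty_graph(n = if (is.null(n)) 0 else n,
                                    directed = FALSE))
  }
  parts <- strsplit(trimws(lc$lines), "\\s+")
  bad <- which(lengths(parts) != 2)
  a <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1)))
  b <- suppressWarnings(as.integer(vapply(parts, function(p)
    if (length(p) >= 2) p[2] else NA_character_, "")))
  bad <- sort(union(bad, which(is.na(a) | is.na(b) | a < 1 | b < 1)))
  if (length(bad) > 0)
    stop("malformed edge-list line(s): ",
         paste(lc$lineno[bad], collapse = ", "), call. = FALSE)
  if (any(a == b))
    stop("self-loop(s) at line(s): ",
         paste(lc$lineno[a == b], collapse = ", "), call. = FALSE)
  if (is.null(n)) n <- max(a, b)
  g <- igraph::graph_from_edgelist(cbind(a, b), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::simplify(g)
}

#' @rdname read_edge_list
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_edgelist(graph, names = FALSE)
  utils::write.table(el, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE, sep = " ")
  invisible(graph)
}

#' Default configuration of the adoption model
#'
#' The model-side parameterisation of the empirical service-adoption
#' setting: lognormal degrees (mu_D = 1.09, sigma_D = 1.39, k_min = 1,
#' matching z = 8.56 at n = 1e4 with the structural cutoff), lognormal
#' thresholds (mu_T = -2, sigma_T = 1, average threshold w = 0.19),
#' spontaneous rate p_n = 0.00019 per node per month, and an 89-month
#' observation window.
#'
#' @return A nested list with `population`, `dynamics`, and `fixture`
#'   sections.
#' @export
default_config <- function() {
  list(
    population = list(n = 10000L, r = 0.73, mu_D = 1.09, sigma_D = 1.39,
                      k_min = 1L, mu_T = -2, sigma_T = 1),
    dynamics = list(p_n = 0.00019, steps = 89L, update = "sweep"),
    fixture = list(collision_rate = 0)
  )
}

#' Read a YAML model configuration
#'
#' Unknown fields are rejected; missing fields fall back to
#' [default_config()].
#'
#' @param path Path to a YAML file with (a subset of) the sections of
#'   [default_config()].
#' @return The merged configuration list.
#' @export
read_config <- function(path) {
  # identity handlers keep short keys like "n" from being coerced to
  # YAML 1.1 booleans
  cfg <- yaml::yaml.load_file(path,
                              handlers = list("bool#yes" = function(v) v,
                                              "bool#no" = function(v) v))
  base <- default_config()
  bad <- character(0)
  for (sec in names(cfg)) {
    if (!sec %in% names(base)) {
      bad <- c(bad, sec)
      next
    }
    for (f in names(cfg[[sec]])) {
      if (!f %in% names(base[[sec]])) bad <- c(bad, paste(sec, f, sep = "."))
      else base[[sec]][[f]] <- cfg[[sec]][[f]]
    }
  }
  if (length(bad) > 0)
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  base
}

#' Generate a synthetic adoption fixture with known ground truth
#'
#' Builds a configuration-model substrate, runs the Monte Carlo dynamics,
#' and returns the event log together with the generating parameters and
#' per-node ground-truth classes, so every analysis-side routine can be
#' validated without external data. Optionally a fraction of adopters is
#' reassigned the timestamp of a random earlier-adopting neighbour,
#' emulating instantaneous group adoptions (same-time collisions evidently
#' not driven by social influence).
#'
#' @param config A configuration list as from [default_config()] /
#'   [read_config()].
#' @param seed Integer seed; all randomness flows through it.
#' @return An object of class `fixture_bundle`: list with `pop`, `events`
#'   (tibble `node`, `t` after collision injection), `truth` (list:
#'   generating parameters, seed, and tibble `classes` with the pre-
#'   collision `node`, `t`, `channel`, `m_at_adoption`, `class`),
#'   `collision_rate`, `n_collided`.
#' @export
generate_fixture <- function(config = default_config(), seed = 1) {
  base <- default_config()
  for (sec in names(base))
    for (f in names(base[[sec]]))
      if (is.null(config[[sec]][[f]])) config[[sec]][[f]] <- base[[sec]][[f]]
  pc <- config$population
  dc <- config$dynamics
  rate <- config$fixture$collision_rate
  if (rate < 0 || rate > 1)
    stop("invalid config: fixture.collision_rate must lie in [0, 1]",
         call. = FALSE)
  set.seed(seed)
  pop <- build_population(
    degree_model(pc$mu_D, pc$sigma_D, pc$k_min),
    threshold_model(pc$mu_T, pc$sigma_T),
    n = pc$n, r = pc$r
  )
  sim <- simulate_adoption(pop, dc$p_n, dc$steps, update = dc$update)
  classes <- sim$events |>
    dplyr::mutate(class = dplyr::case_when(
      .data$m_at_adoption == 0L ~ "innovator",
      .data$m_at_adoption == 1L ~ "vulnerable",
      TRUE ~ "stable"
    ))
  events <- sim$events[, c("node", "t")]
  n_coll <- 0L
  if (rate > 0 && nrow(events) > 0) {
    csr <- build_csr(pop$graph, pop$n)
    times <- rep(NA_integer_, pop$n)
    times[events$node] <- events$t
    eligible <- events$node[vapply(events$node, function(v) {
      nb <- csr_neighbours(csr, v)
      any(!is.na(times[nb]) & times[nb] < times[v])
    }, TRUE)]
    pick <- eligible[stats::runif(length(eligible)) < rate]
    for (v in pick) {
      nb <- csr_neighbours(csr, v)
      nb <- nb[!is.na(times[nb]) & times[nb] < times[v]]
      times[v] <- times[sample(rep(nb, 2), 1)] # rep guards length-1 sample
    }
    n_coll <- length(pick)
    events$t <- times[events$node]
  }
  truth <- c(pc, dc, list(seed = seed, classes = classes))
  structure(
    list(pop = pop, events = events, truth = truth,
         collision_rate = rate, n_collided = n_coll),
    class = "fixture_bundle"
  )
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat(sprintf(
    "<fixture_bundle> n = %d, r = %g, p_n = %g, %d adopters, %d collided\n",
    x$pop$n, x$truth$r, x$truth$p_n, nrow(x$events), x$n_collided))
  invisible(x)
}

#' Write a fixture bundle to plain-text files
#'
#' Writes `substrate.tsv` (edge list), `events.csv` (post-collision event
#' log), `nodes.csv` (node attributes) and `truth.yaml` (generating
#' parameters and collision count) into `dir`.
#'
#' @param bundle A [generate_fixture()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_fixture <- function(bundle, dir) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- file.path(dir, c("substrate.tsv", "events.csv", "nodes.csv",
                        "truth.yaml"))
  write_edge_list(bundle$pop$graph, f[1])
  write_event_log(bundle$events, f[2])
  utils::write.csv(bundle$pop$nodes, f[3], row.names = FALSE)
  tr <- bundle$truth
  tr$classes <- NULL
  tr$n_collided <- bundle$n_collided
  yaml::write_yaml(tr, f[4])
  invisible(f)
}
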