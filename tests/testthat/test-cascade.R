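test_that("classification follows the strictly-earlier rule", {
  tri <- igraph::make_full_graph(3)
  cls <- classify_adopters(tri, events_tbl(1:3, 1:3))
  expect_equal(cls$class, c("innovator", "vulnerable", "stable"))
  expect_equal(cls$phi_k, c(0L, 1L, 2L))

  # same-time adopters exclude each other
  pair <- igraph::make_full_graph(2)
  cls2 <- classify_adopters(pair, events_tbl(1:2, c(4, 4)))
  expect_equal(cls2$phi_k, c(0L, 0L))
  expect_true(all(cls2$class == "innovator"))

  expect_error(classify_adopters(pair, events_tbl(5, 1)), "absent")
  expect_error(classify_adopters(pair, events_tbl(c(1, 1), c(1, 2))),
               "duplicate")
})

test_that("adoption network honours the same-time exclusion", {
  g <- igraph::make_full_graph(4)
  # all adopters share one timestamp: edgeless network
  an <- build_adoption_network(g, events_tbl(1:4, rep(2, 4)))
  expect_equal(igraph::vcount(an), 4)
  expect_equal(igraph::ecount(an), 0)

  # sequential chain: a single path component
  path <- igraph::make_ring(5, circular = FALSE)
  an2 <- build_adoption_network(path, events_tbl(1:5, 1:5))
  expect_equal(igraph::ecount(an2), 4)
  expect_equal(component_stats(an2)$lc, 5)

  # time-restricted evaluation
  an3 <- build_adoption_network(path, events_tbl(1:5, 1:5), at = 3)
  expect_equal(igraph::vcount(an3), 3)
})

test_that("component routines agree with a flood-fill oracle on random toys", {
  set.seed(17)
  for (i in 1:25) {
    toy <- random_toy(n = sample(10:50, 1))
    an <- build_adoption_network(toy$graph, toy$events)
    cs <- component_stats(an)
    # oracle on the same qualifying edge set
    times <- rep(NA_real_, igraph::vcount(toy$graph))
    times[toy$events$node] <- toy$events$t
    el <- igraph::as_edgelist(toy$graph, names = FALSE)
    keep <- !is.na(times[el[, 1]]) & !is.na(times[el[, 2]]) &
      times[el[, 1]] != times[el[, 2]]
    id <- match(seq_len(igraph::vcount(toy$graph)), toy$events$node)
    oe <- cbind(id[el[keep, 1]], id[el[keep, 2]])
    sizes <- flood_fill_sizes(nrow(toy$events), oe)
    got <- rep(tidy(cs)$size, tidy(cs)$count)
    expect_equal(sort(got, decreasing = TRUE), sizes)
    expect_equal(cs$lc, sizes[1])
    expect_equal(cs$lc2, if (length(sizes) > 1) sizes[2] else 0L)
  }
})

test_that("component stats handle empty graphs and known partitions", {
  empty <- igraph::make_empty_graph(0, directed = FALSE)
  expect_equal(component_stats(empty)$lc, 0)

  two <- igraph::disjoint_union(igraph::make_full_graph(5),
                                igraph::make_full_graph(3))
  cs <- component_stats(two, n_total = 100)
  expect_equal(cs$lc, 5)
  expect_equal(cs$lc2, 3)
  expect_equal(cs$lc_frac, 0.05)
  expect_equal(sum(tidy(cs)$size * tidy(cs)$count), 8)
})

test_that("stable subnetwork is contained in the adoption network", {
  set.seed(23)
  pop <- build_population(ref_degree(), ref_threshold(), n = 3000,
                          r = 0.3)
  sim <- simulate_adoption(pop, 0.002, 40)
  an <- build_adoption_network(pop, sim$events)
  sn <- stable_subnetwork(pop, sim$events)
  expect_true(all(igraph::V(sn)$name %in% igraph::V(an)$name))
  cls <- classify_adopters(pop, sim$events)
  expect_equal(igraph::vcount(sn), sum(cls$class == "stable"))

  # no stable adopters: empty graph
  pair <- igraph::make_full_graph(2)
  sn0 <- stable_subnetwork(pair, events_tbl(1:2, 1:2))
  expect_equal(igraph::vcount(sn0), 0)
})

test_that("vulnerable forest matches hand-computed star and path cases", {
  star <- igraph::make_star(7, mode = "undirected", center = 1)
  fo <- vulnerable_forest(star, events_tbl(1:7, c(1, 2:7)))
  expect_equal(nrow(fo$trees), 1)
  expect_equal(fo$trees$size, 6)
  expect_equal(fo$trees$depth, 1)
  expect_equal(fo$trees$root, 1)
  expect_equal(fo$trees$root_class, "innovator")

  path <- igraph::make_ring(6, circular = FALSE)
  fo2 <- vulnerable_forest(path, events_tbl(1:6, 1:6))
  expect_equal(nrow(fo2$trees), 1)
  expect_equal(fo2$trees$size, 5)
  expect_equal(fo2$trees$depth, 5)
})

test_that("vulnerable forest is node-disjoint, acyclic and time-increasing", {
  set.seed(31)
  for (i in 1:15) {
    toy <- random_toy(n = 40, p_edge = 0.1)
    fo <- vulnerable_forest(toy$graph, toy$events)
    cls <- classify_adopters(toy$graph, toy$events)
    vuln <- cls$node[cls$class == "vulnerable"]
    # every vulnerable node sits in exactly one tree
    expect_setequal(fo$members$node, vuln)
    expect_equal(anyDuplicated(fo$members$node), 0)
    # roots are never vulnerable; sizes add up
    expect_true(all(!fo$trees$root %in% vuln))
    expect_equal(sum(fo$trees$size), length(vuln))
    # parent adoption times strictly earlier
    times <- rep(NA_real_, igraph::vcount(toy$graph))
    times[toy$events$node] <- toy$events$t
    expect_true(all(times[fo$members$parent] < times[fo$members$node]))
    # independent recomputation of tree sizes by following parents
    if (nrow(fo$members) > 0) {
      root_of <- function(v) {
        repeat {
          p <- fo$members$parent[match(v, fo$members$node)]
          if (is.na(p)) return(v) # v itself not vulnerable: it is a root
          v <- p
        }
      }
      roots <- vapply(fo$members$node, function(v) as.integer(root_of(v)),
                      integer(1))
      expect_equal(sort(as.integer(table(roots))),
                   sort(fo$trees$size))
    }
  }
})

test_that("innovator tree correlation aggregates by root degree", {
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  fo <- vulnerable_forest(star, events_tbl(1:5, c(1, 2, 2, 2, 2)))
  cor_tbl <- innovator_tree_correlation(fo)
  expect_equal(cor_tbl$k, 4L)
  expect_equal(cor_tbl$mean_size, 4)

  # all trees of size one: flat curve at 1 (two separate dyads)
  g <- igraph::disjoint_union(igraph::make_full_graph(2),
                              igraph::make_full_graph(2))
  fo2 <- vulnerable_forest(g, events_tbl(1:4, c(1, 2, 1, 2)))
  ct2 <- innovator_tree_correlation(fo2)
  expect_true(all(ct2$mean_size == 1))

  # group-by oracle
  man <- fo2$trees[fo2$trees$root_class == "innovator", ]
  agg <- tapply(man$size, man$root_degree, mean)
  expect_equal(ct2$mean_size, unname(agg[as.character(ct2$k)]))
})

test_that("outputs only ever use substrate edges with distinct times", {
  set.seed(41)
  for (i in 1:10) {
    toy <- random_toy(n = 35, t_max = 3) # many same-time collisions
    times <- rep(NA_real_, 35)
    times[toy$events$node] <- toy$events$t
    in_substrate <- function(h) {
      if (igraph::ecount(h) == 0) return(TRUE)
      el <- igraph::as_edgelist(h)
      a <- as.integer(el[, 1]); b <- as.integer(el[, 2])
      adj <- vapply(seq_along(a), function(j)
        igraph::are_adjacent(toy$graph, a[j], b[j]), TRUE)
      all(adj) && all(times[a] != times[b])
    }
    expect_true(in_substrate(build_adoption_network(toy$graph, toy$events)))
    expect_true(in_substrate(stable_subnetwork(toy$graph, toy$events)))
  }
})

test_that("maximum relative growth rate matches hand computations", {
  expect_equal(max_relative_growth_rate(c(2, 8, 10)), 0.5)
  expect_equal(max_relative_growth_rate(rep(7, 5)), 1 / 5)
  # all adoptions within one calendar year: instantaneous cascade
  expect_equal(max_relative_growth_rate(events_tbl(1:30, sample(1:12, 30,
                                                                TRUE))), 1)
  # month 12 and 13 straddle a year boundary
  expect_equal(max_relative_growth_rate(events_tbl(1:2, c(12, 13))), 0.5)
  expect_error(max_relative_growth_rate(events_tbl(integer(0), integer(0))),
               "empty")
  expect_error(max_relative_growth_rate(c(0, 0)), "zero")
})
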