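test_that("edge-list construction validates DAG invariants with informative errors", {
  expect_s3_class(as_network(data.frame(from = c("1", "2"), to = c("2", "3"))),
                  "obsremedy_network")
  expect_error(as_network(data.frame(from = c("1", "2"), to = c("2", "1"))),
               class = "obsremedy_invalid_edge", regexp = "bidirectional")
  expect_error(as_network(data.frame(from = c("1", "2", "3"), to = c("2", "3", "1"))),
               class = "obsremedy_cycle_error", regexp = "cycle")
  expect_error(as_network(data.frame(from = "1", to = "1")),
               class = "obsremedy_invalid_edge", regexp = "self-loop")
  expect_error(as_network(data.frame(from = c("1", "1"), to = c("2", "2"))),
               class = "obsremedy_invalid_edge", regexp = "duplicate")
})

test_that("canonical node order is first appearance; N_u equals edge count", {
  net <- as_network(data.frame(from = c("b", "a", "c"), to = c("c", "b", "d")))
  expect_equal(network_nodes(net), c("b", "c", "a", "d"))
  expect_equal(nrow(network_edges(net)), 3L)
  # explicit node order admits isolated nodes
  net2 <- as_network(data.frame(from = "1", to = "2"), nodes = c("1", "2", "3"))
  expect_equal(network_nodes(net2), c("1", "2", "3"))
})

test_that("neighborhoods partition the remaining nodes and flag boundary ancestors", {
  nb <- node_neighborhoods(network_fixture("diamond4"), "4")
  expect_setequal(nb$node[nb$relation == "ancestor"], c("1", "2", "3"))
  expect_equal(sum(nb$relation != "ancestor"), 0L)
  expect_false(any(nb$boundary))

  nb2 <- node_neighborhoods(network_fixture("chain3"), "2")
  expect_equal(nb2$relation[nb2$node == "1"], "ancestor")
  expect_equal(nb2$relation[nb2$node == "3"], "descendant")

  nb3 <- node_neighborhoods(network_fixture("collider5"), "K")
  expect_setequal(nb3$node[nb3$relation == "ancestor"], c("I", "U"))
  expect_setequal(nb3$node[nb3$relation == "descendant"], "J")
  expect_setequal(nb3$node[nb3$relation == "relative"], "W")
  expect_setequal(nb3$node[nb3$boundary], "U")

  expect_error(node_neighborhoods(network_fixture("chain3"), "zz"),
               class = "obsremedy_unknown_node")
})

test_that("anc/des/rel partition and topological order hold on random DAGs", {
  for (s in 1:12) {
    net <- random_dag(4 + s %% 5, 0.4, seed = s)
    nodes <- network_nodes(net)
    topo <- topological_order(net)
    ed <- network_edges(net)
    if (nrow(ed)) {
      expect_true(all(match(ed$from, topo) < match(ed$to, topo)))
    }
    for (v in nodes) {
      nb <- node_neighborhoods(net, v)
      expect_equal(nrow(nb), length(nodes) - 1L)
      expect_equal(anyDuplicated(nb$node), 0L)
    }
  }
})

test_that("network files round-trip in every supported format", {
  net <- network_fixture("diamond4")
  for (fmt in c("tsv", "sif", "graphml")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_network(net, path, format = fmt)
    back <- read_network(path, format = fmt)
    expect_equal(network_nodes(back), network_nodes(net))
    expect_equal(network_edges(back)[1:2], network_edges(net)[1:2])
    # load -> write -> load is the identity
    path2 <- tempfile(fileext = paste0(".", fmt))
    write_network(back, path2, format = fmt)
    again <- read_network(path2, format = fmt)
    expect_equal(network_edges(again), network_edges(back))
    unlink(c(path, path2))
  }
})

test_that("TSV/SIF parsing honours comments and reports offending lines", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("# comment", "1\t2", "", "2\t3"), path)
  net <- read_network(path)
  expect_equal(nrow(network_edges(net)), 2L)
  writeLines(c("1\t2", "bad-line"), path)
  expect_error(read_network(path), class = "obsremedy_parse_error",
               regexp = "line 2")
  unlink(path)
  expect_error(read_network(tempfile()), class = "obsremedy_io_error")
})

test_that("strategy files require full node coverage unless defaulting is requested", {
  net <- network_fixture("chain3")
  path <- tempfile(fileext = ".tsv")
  writeLines(c("1\t1", "2\t0", "3\t1"), path)
  st <- read_strategy(path, net)
  expect_equal(st$observed, c(TRUE, FALSE, TRUE))
  writeLines(c("1\t1"), path)
  expect_error(read_strategy(path, net), class = "obsremedy_parse_error",
               regexp = "missing nodes")
  st2 <- read_strategy(path, net, default_unobserved = TRUE)
  expect_equal(st2$observed, c(TRUE, FALSE, FALSE))
  writeLines(c("1\t1", "9\t0", "2\t0", "3\t0"), path)
  expect_error(read_strategy(path, net), class = "obsremedy_parse_error")
  # write and read back
  write_strategy(st, net, path)
  expect_equal(read_strategy(path, net), st)
  unlink(path)
})

test_that("strategy coercion accepts all documented forms and rejects mismatches", {
  net <- network_fixture("star4")
  expect_equal(unname(as_strategy(net, c("2", "4"))), c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(unname(as_strategy(net, NULL)), rep(FALSE, 4))
  expect_equal(unname(as_strategy(net, c(1, 0, 0, 1))), c(TRUE, FALSE, FALSE, TRUE))
  expect_error(as_strategy(net, c(1, 0)), class = "obsremedy_strategy_error")
  expect_error(as_strategy(net, data.frame(node = c("1", "2"), observed = c(1, 0))),
               class = "obsremedy_strategy_error")
})
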