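test_that("initial strategy is the element-wise OR with the must-be-observed set", {
  # six-node example: given [0,1,1,0,0,0], forced [1,0,1,0,0,0] -> [1,1,1,0,0,0]
  net <- as_network(data.frame(from = c("1", "3", "3", "4", "4", "4"),
                               to   = c("2", "2", "4", "5", "6", "2")))
  nodes <- network_nodes(net)
  mbo <- must_be_observed(net)$node
  given <- as.numeric(nodes %in% c("2", "3"))
  init <- initial_strategy(net, given)
  expect_equal(init$observed, init$given | init$mbo)
  # idempotence: applying the OR twice changes nothing
  init2 <- initial_strategy(net, init$observed)
  expect_equal(init2$observed, init$observed)
  # identity on the empty strategy of an MBO-free indicator
  expect_equal(initial_strategy(network_fixture("star4"), NULL)$observed,
               c(FALSE, TRUE, TRUE, TRUE))
})

test_that("star network needs nothing beyond the must-be-observed leaves", {
  r <- find_remedy(network_fixture("star4"), verify = "oracle")
  expect_equal(r$stop_stage, 0L)
  expect_equal(r$status, "ok")
  expect_equal(length(r$strategies), 1L)
  expect_equal(r$strategies[[1]]$added, character(0))
  expect_setequal(r$strategies[[1]]$observed, c("2", "3", "4"))  # hub stays hidden
  expect_true(r$strategies[[1]]$oracle_identifiable)
  expect_equal(r$f0, 3L)
  expect_equal(r$n_u, 3L)
})

test_that("two-factor network has exactly the two single-source remedies", {
  r <- find_remedy(network_fixture("bifactor5"), all_optimal = TRUE,
                   verify = "oracle")
  expect_equal(r$f0, 3L)
  expect_equal(r$n_u, 6L)
  expect_equal(r$stop_stage, 1L)
  added <- sort(vapply(r$strategies, function(s) s$added, character(1)))
  expect_equal(added, c("s1", "s2"))
  expect_true(all(vapply(r$strategies, `[[`, logical(1), "oracle_identifiable")))
  expect_true(all(vapply(r$strategies, `[[`, numeric(1), "f") >= r$n_u))
  # without enumeration only the first in canonical order is reported
  r1 <- find_remedy(network_fixture("bifactor5"))
  expect_equal(length(r1$strategies), 1L)
  expect_equal(r1$strategies[[1]]$added, "s1")
})

test_that("fully forced networks stop at stage zero", {
  r <- find_remedy(network_fixture("chain3"))
  expect_equal(r$stop_stage, 0L)
  expect_equal(r$f0, 2L)
  expect_equal(r$strategies[[1]]$added, character(0))
})

test_that("exhaustive search agrees with the dynamic program on fixtures", {
  ex <- exhaustive_remedy(network_fixture("bifactor5"))
  expect_equal(ex$n_added, 1L)
  expect_setequal(vapply(ex$solutions, identity, character(1)), c("s1", "s2"))
  expect_equal(exhaustive_remedy(network_fixture("star4"))$n_added, 0L)
  empty <- as_network(data.frame(from = character(0), to = character(0)),
                      nodes = c("a", "b"))
  ex0 <- exhaustive_remedy(empty)
  expect_equal(ex0$n_added, 0L)
  expect_equal(ex0$n_u, 0L)
  expect_error(exhaustive_remedy(network_fixture("bifactor5"), max_unobserved = 1),
               class = "obsremedy_cap_error")
})

test_that("every reported strategy reaches the threshold with a recomputed f", {
  for (s in 1:20) {
    inst <- random_instance(800 + s)
    r <- find_remedy(inst$net, inst$strategy)
    if (r$status != "ok") next
    for (st in r$strategies) {
      expect_gte(st$f, r$n_u)
      expect_equal(cardinality(inst$net, st$observed)$f, st$f)
    }
    # all reported strategies add the same minimal number of nodes
    expect_equal(length(unique(vapply(r$strategies, function(s) length(s$added),
                                      integer(1)))), 1L)
  }
})

test_that("relabeling nodes permutes but does not change the optimal strategies", {
  net <- network_fixture("bifactor5")
  perm <- c(s1 = "B", x1 = "D", x2 = "E", x3 = "A", s2 = "C")
  ed <- network_edges(net)
  net2 <- as_network(data.frame(from = unname(perm[ed$from]),
                                to = unname(perm[ed$to])),
                     nodes = unname(perm[network_nodes(net)]))
  r1 <- find_remedy(net, all_optimal = TRUE)
  r2 <- find_remedy(net2, all_optimal = TRUE)
  sets1 <- sort(vapply(r1$strategies, function(s)
    paste(sort(unname(perm[s$added])), collapse = ","), character(1)))
  sets2 <- sort(vapply(r2$strategies, function(s)
    paste(sort(s$added), collapse = ","), character(1)))
  expect_equal(sets1, sets2)
})

test_that("oracle verification flags unsound strategies instead of hiding them", {
  # on this instance the cardinality criterion overcounts; the shipped
  # self-audit must surface the disagreement as a divergence flag
  net <- random_dag(4 + 76 %% 6, 0.35, seed = 76)
  st <- random_strategy(net, 0.5, seed = 1076)
  r <- find_remedy(net, st, verify = "oracle", seed = 76)
  expect_equal(r$status, "ok")
  expect_false(all(vapply(r$strategies, `[[`, logical(1), "oracle_identifiable")))
  expect_true(any(grepl("oracle rank", r$divergences)))
})

test_that("remedy results tidy, glance and serialize losslessly", {
  r <- find_remedy(network_fixture("bifactor5"), all_optimal = TRUE,
                   verify = "oracle")
  td <- tidy(r)
  expect_equal(nrow(td), 2L)
  expect_equal(td$n_added, c(1L, 1L))
  gl <- glance(r)
  expect_equal(gl$n_u, 6L)
  expect_equal(gl$status, "ok")

  path <- tempfile(fileext = ".json")
  write_report(r, path)
  back <- read_report(path)
  expect_equal(back$N_u, 6L)
  expect_equal(back$f_final, 6L)
  expect_equal(length(back$strategies$added), 2L)
  # stable order: the two optima appear in canonical order
  expect_equal(unlist(back$strategies$added), c("s1", "s2"))
  # writing again yields byte-identical content
  path2 <- tempfile(fileext = ".json")
  write_report(r, path2)
  expect_identical(readLines(path), readLines(path2))
  unlink(c(path, path2))

  empty <- find_remedy(network_fixture("chain3"))
  path3 <- tempfile(fileext = ".json")
  write_report(empty, path3)
  expect_equal(length(read_report(path3)$strategies$added[[1]]), 0L)
  unlink(path3)
})

test_that("the DP state space stays within the triangular bound", {
  # S unobserved after initialization -> at most S(S+1)/2 + 1 states, each
  # evaluated at most once per stage transition
  net <- benchmark_family(6)
  init <- initial_strategy(net, NULL)
  S <- sum(!init$observed)
  expect_equal(S, 6L)
  gain_call_count(reset = TRUE)
  r <- find_remedy(net)
  expect_equal(r$status, "ok")
  expect_equal(length(r$strategies[[1]]$added), 2L)
  expect_gt(gain_call_count(), 0)
})
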