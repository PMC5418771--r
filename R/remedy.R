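# Stage/state dynamic program for the minimum observation remedy, the
# exhaustive verifier, and the remedy result type.
#
# Stages k = 0 .. S add one observed node each; the states of stage k are
# indexed by the unobserved nodes of the initial strategy in canonical
# order, with state j at stage k reachable from states i < j at stage
# k - 1 (a triangular layout that avoids duplicate subsets). Each state
# keeps the best accumulated cardinality
#   f(state j, stage k) = max_i [ g(u_j, strategy_i) + f(state i, k - 1) ]
# and the search stops at the first stage where some state reaches
# f >= N_u.

#' Search for minimum observation remedies (dynamic program)
#'
#' Starting from the element-wise OR of the given strategy with the
#' must-be-observed nodes, adds unobserved nodes one stage at a time,
#' always propagating the maximum identifiability gain, and stops at the
#' first stage where the cardinality reaches the number of unknown edge
#' coefficients N_u. All reported strategies observe the same (minimal)
#' number of added nodes.
#'
#' @param net A network (anything accepted by [as_network()]).
#' @param observed The given (possibly empty) observation strategy, any
#'   form accepted by [as_strategy()].
#' @param all_optimal If `TRUE`, enumerate every optimal strategy found at
#'   the stopping stage (tie back-pointers included); otherwise report the
#'   first in canonical order.
#' @param verify `"none"`, `"oracle"` (run the Jacobian-rank oracle on
#'   every reported strategy), or `"exhaustive"` (also compare the added
#'   count against [exhaustive_remedy()]).
#' @param method Gain route passed to the gain engine: `"removal"`
#'   (default), `"lemmas"`, or `"both"` (strict dual-path self-audit that
#'   errors on any route divergence).
#' @param seed Seed for the oracle draws when `verify != "none"`.
#' @return An object of class `obsremedy_remedy`; see [tidy.obsremedy_remedy()],
#'   [glance.obsremedy_remedy()] and [autoplot.obsremedy_remedy()].
#' @examples
#' find_remedy(network_fixture("bifactor5"), all_optimal = TRUE)
#' @export
find_remedy <- function(net, observed = NULL, all_optimal = FALSE,
                        verify = c("none", "oracle", "exhaustive"),
                        method = c("removal", "lemmas", "both"),
                        seed = 1L) {
  net <- as_network(net)
  verify <- match.arg(verify)
  method <- match.arg(method)
  given <- as_strategy(net, observed)
  init <- initial_strategy(net, given)
  O0 <- init$observed
  names(O0) <- net$nodes
  n_u <- net$n_edges
  f0 <- cardinality_int(net, O0, method = method)$f

  U <- which(!O0)
  S <- length(U)
  stage_trace <- tibble::tibble(stage = 0L, best_f = f0)
  strategies <- list()
  stop_stage <- 0L
  status <- "ok"
  dp_diverg <- character(0)

  if (f0 >= n_u || S == 0L) {
    if (f0 < n_u) status <- "infeasible"
    strategies <- list(list(added = integer(0), obs = O0, f = f0))
  } else {
    # states: one row per unobserved node position; columns evolve by stage
    f_prev <- rep(NA_real_, S)
    obs_prev <- vector("list", S)
    sets_prev <- vector("list", S)   # added-node index sets (for ties)
    done <- FALSE
    for (k in seq_len(S)) {
      f_cur <- rep(NA_real_, S)
      obs_cur <- vector("list", S)
      sets_cur <- vector("list", S)
      for (j in seq.int(k, S)) {
        if (k == 1L) {
          acc <- f0 + gain_int(net, O0, U[j], method)$gain
          ob <- O0
          ob[U[j]] <- TRUE
          obs_cur[[j]] <- ob
          sets_cur[[j]] <- list(U[j])
        } else {
          preds <- seq.int(k - 1L, j - 1L)
          preds <- preds[!is.na(f_prev[preds])]
          if (!length(preds)) next
          vals <- vapply(preds, function(i) {
            gain_int(net, obs_prev[[i]], U[j], method)$gain + f_prev[i]
          }, numeric(1))
          acc <- max(vals)
          arg <- preds[vals == acc]
          ob <- obs_prev[[arg[1]]]
          ob[U[j]] <- TRUE
          obs_cur[[j]] <- ob
          if (all_optimal) {
            sets_cur[[j]] <- unique(lapply(
              unlist(lapply(arg, function(i) sets_prev[[i]]), recursive = FALSE),
              function(s) c(s, U[j])))
          } else {
            sets_cur[[j]] <- list(c(sets_prev[[arg[1]]][[1]], U[j]))
          }
        }
        # state value: cardinality of the realized set recomputed from
        # scratch (canonical insertion), so states measure the strategy
        # itself rather than one accumulation path
        f_cur[j] <- cardinality_int(net, obs_cur[[j]], method = method)$f
        if (f_cur[j] != acc) {
          dp_diverg <- c(dp_diverg, paste0(
            "stage ", k, " state ", net$nodes[U[j]], ": accumulated f ", acc,
            " vs from-scratch f ", f_cur[j]))
        }
      }
      stage_trace <- dplyr::bind_rows(
        stage_trace,
        tibble::tibble(stage = k, best_f = max(f_cur, na.rm = TRUE)))
      hits <- which(!is.na(f_cur) & f_cur >= n_u)
      if (length(hits)) {
        cand_sets <- list()
        for (j in hits) {
          sets_j <- if (all_optimal) sets_cur[[j]] else sets_cur[[j]][1]
          cand_sets <- c(cand_sets, sets_j)
          if (!all_optimal) break
        }
        cand_sets <- unique(lapply(cand_sets, sort))
        for (s in cand_sets) {
          ob <- O0
          ob[s] <- TRUE
          f_chk <- cardinality_int(net, ob, method = method)$f
          if (f_chk >= n_u) {
            strategies[[length(strategies) + 1L]] <-
              list(added = s, obs = ob, f = f_chk)
          } else {
            dp_diverg <- c(dp_diverg, paste0(
              "stage ", k, ": DP-accumulated f reached ", n_u,
              " for {", paste(net$nodes[s], collapse = ","),
              "} but from-scratch f = ", f_chk))
          }
        }
        if (length(strategies)) {
          stop_stage <- k
          done <- TRUE
          break
        }
      }
      f_prev <- f_cur
      obs_prev <- obs_cur
      sets_prev <- sets_cur
    }
    if (!done) {
      status <- "infeasible"
      stop_stage <- S
      ob <- rep(TRUE, net$n)
      names(ob) <- net$nodes
      strategies <- list(list(added = U, obs = ob,
                              f = cardinality_int(net, ob, method = method)$f))
    }
  }

  # oracle verdicts / divergence flags
  oracle_ok <- rep(NA, length(strategies))
  divergence <- dp_diverg
  if (verify %in% c("oracle", "exhaustive")) {
    for (s in seq_along(strategies)) {
      v <- jacobian_identifiable(net, strategies[[s]]$obs, trials = 3L, seed = seed)
      oracle_ok[s] <- v$identifiable
      if (status == "ok" && !v$identifiable) {
        divergence <- c(divergence, paste0(
          "strategy ", s, ": f = ", strategies[[s]]$f, " >= N_u but oracle rank ",
          v$rank, " < ", v$n_u))
      }
    }
  }
  if (verify == "exhaustive" && status == "ok") {
    ex <- exhaustive_remedy(net, observed, method = method)
    if (ex$n_added != length(strategies[[1]]$added)) {
      divergence <- c(divergence, paste0(
        "DP added ", length(strategies[[1]]$added), " nodes but exhaustive ",
        "minimum is ", ex$n_added))
    }
  }

  structure(
    list(
      network = net,
      given = net$nodes[which(given)],
      mbo = init$node[init$mbo],
      initial_observed = init$node[init$observed],
      f0 = f0,
      n_u = n_u,
      stop_stage = stop_stage,
      status = status,
      stage_trace = stage_trace,
      strategies = lapply(seq_along(strategies), function(s) {
        st <- strategies[[s]]
        list(added = net$nodes[st$added],
             observed = net$nodes[which(st$obs)],
             f = st$f,
             oracle_identifiable = oracle_ok[s])
      }),
      divergences = divergence
    ),
    class = "obsremedy_remedy"
  )
}

#' Exhaustive minimum-remedy search
#'
#' Enumerates supersets of the initial strategy by increasing added-node
#' count and returns every minimum-cardinality strategy whose cardinality
#' reaches N_u (the same criterion the dynamic program uses). With
#' `criterion = "oracle"` the Jacobian-rank verdict replaces the
#' cardinality criterion, giving an implementation-independent reference.
#'
#' @inheritParams find_remedy
#' @param max_unobserved Safety cap on the number of unobserved nodes in
#'   the initial strategy (the search is exponential).
#' @param criterion `"cardinality"` (f >= N_u) or `"oracle"` (Jacobian
#'   rank equals N_u).
#' @return A list with `n_added`, `solutions` (list of character vectors
#'   of added nodes), `f0` and `n_u`.
#' @export
exhaustive_remedy <- function(net, observed = NULL, max_unobserved = 15L,
                              criterion = c("cardinality", "oracle"),
                              method = c("removal", "lemmas", "both"),
                              seed = 1L) {
  net <- as_network(net)
  criterion <- match.arg(criterion)
  method <- match.arg(method)
  given <- as_strategy(net, observed)
  init <- initial_strategy(net, given)
  O0 <- init$observed
  names(O0) <- net$nodes
  U <- which(!O0)
  if (length(U) > max_unobserved) {
    rlang::abort(paste0("exhaustive search capped at ", max_unobserved,
                        " unobserved nodes (", length(U), " present)"),
                 class = "obsremedy_cap_error")
  }
  n_u <- net$n_edges
  f0 <- cardinality_int(net, O0, method = method)$f
  meets <- function(obs_vec) {
    if (criterion == "cardinality") {
      cardinality_int(net, obs_vec, method = method)$f >= n_u
    } else {
      jacobian_identifiable(net, obs_vec, trials = 3L, seed = seed)$identifiable
    }
  }
  for (size in 0:length(U)) {
    sols <- list()
    if (size == 0L) {
      if (meets(O0)) sols <- list(integer(0))
    } else {
      sets <- utils::combn(U, size, simplify = FALSE)
      for (s in sets) {
        ob <- O0
        ob[s] <- TRUE
        if (meets(ob)) sols[[length(sols) + 1L]] <- s
      }
    }
    if (length(sols)) {
      return(list(
        n_added = size,
        solutions = lapply(sols, function(s) net$nodes[s]),
        f0 = f0,
        n_u = n_u
      ))
    }
  }
  list(n_added = NA_integer_, solutions = list(), f0 = f0, n_u = n_u)
}

#' @export
print.obsremedy_remedy <- function(x, ...) {
  cat("<obsremedy_remedy> N_u = ", x$n_u, ", f(O0) = ", x$f0,
      ", stopped at stage ", x$stop_stage, " (", x$status, ")\n", sep = "")
  cat("initial observed (given | must-be-observed): ",
      paste(x$initial_observed, collapse = ", "), "\n", sep = "")
  for (s in seq_along(x$strategies)) {
    st <- x$strategies[[s]]
    cat("strategy ", s, ": add {",
        paste(st$added, collapse = ", "), "}  f = ", st$f,
        if (!is.na(st$oracle_identifiable)) {
          paste0("  oracle: ", if (st$oracle_identifiable) "identifiable"
                 else "NOT identifiable")
        } else "",
        "\n", sep = "")
  }
  if (length(x$divergences)) {
    cat("DIVERGENCES:\n", paste0("  ", x$divergences, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Tidy a remedy result
#'
#' @param x An `obsremedy_remedy`.
#' @param ... Unused.
#' @return One row per optimal strategy: `strategy`, `n_added`, `added`
#'   (list column), `observed` (list column), `f`, `oracle_identifiable`.
#' @method tidy obsremedy_remedy
#' @export
tidy.obsremedy_remedy <- function(x, ...) {
  tibble::tibble(
    strategy = seq_along(x$strategies),
    n_added = vapply(x$strategies, function(s) length(s$added), integer(1)),
    added = lapply(x$strategies, `[[`, "added"),
    observed = lapply(x$strategies, `[[`, "observed"),
    f = vapply(x$strategies, function(s) as.integer(s$f), integer(1)),
    oracle_identifiable = vapply(x$strategies, function(s)
      as.logical(s$oracle_identifiable), logical(1))
  )
}

#' Summarize a remedy result
#'
#' @param x An `obsremedy_remedy`.
#' @param ... Unused.
#' @return A one-row tibble: problem size, f(O0), N_u, stages run, number
#'   of optimal strategies, added-node count and status.
#' @method glance obsremedy_remedy
#' @export
glance.obsremedy_remedy <- function(x, ...) {
  tibble::tibble(
    n_nodes = x$network$n,
    n_edges = x$network$n_edges,
    n_u = x$n_u,
    f0 = x$f0,
    stages_run = x$stop_stage,
    n_strategies = length(x$strategies),
    n_added = if (length(x$strategies)) length(x$strategies[[1]]$added)
      else NA_integer_,
    status = x$status
  )
}

#' Serialize a remedy result to JSON
#'
#' Writes the strategies, the stage cardinality trace and the oracle
#' verdicts in a stable JSON schema that [read_report()] round-trips.
#'
#' @param result An `obsremedy_remedy`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  if (!inherits(result, "obsremedy_remedy")) {
    rlang::abort("`result` must be an obsremedy_remedy",
                 class = "obsremedy_param_error")
  }
  payload <- list(
    initial_observed = result$initial_observed,
    given = result$given,
    mbo = result$mbo,
    stages_run = result$stop_stage,
    status = result$status,
    f0 = result$f0,
    f_final = if (length(result$strategies)) result$strategies[[1]]$f else result$f0,
    N_u = result$n_u,
    stage_trace = result$stage_trace,
    strategies = lapply(result$strategies, function(s) {
      list(added = s$added, observed = s$observed, f = s$f,
           oracle_identifiable = s$oracle_identifiable)
    }),
    divergences = result$divergences
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read back a serialized remedy report
#'
#' @param path Path written by [write_report()].
#' @return The report as a list (strategies, stage trace, verdicts).
#' @export
read_report <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "obsremedy_io_error")
  }
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
}
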