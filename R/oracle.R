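# Independent ground-truth machinery: numeric SEM parameterization,
# implied covariance and generic local structural identifiability via the
# rank of the coefficient-to-covariance Jacobian.
#
# The model is the standardized linear recursive SEM
#   Y_i = sum_j c_ij Y_j + eps_i,  errors independent,
# with every node variable scaled to unit variance (the setting of
# Wright's path coefficient method: the c_ij are path coefficients and
# the observable correlations are sums over simple collider-free paths).
# The implied correlations satisfy the exact recursion
#   r_ab = sum_{p in parents(b)} c_bp r_ap  (a before b topologically),
# with r_aa = 1, which this module evaluates and differentiates directly;
# it never touches the trek-enumeration code path, so it can serve as an
# independent oracle for it.

# Run code with a private, restored RNG state.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Draw a random SEM parameterization
#'
#' Edge coefficients are drawn uniformly from \[0.5, 1.5\] with independent
#' random signs (bounded away from zero to avoid measure-zero
#' degeneracies); error variances are fixed at one (standardized model).
#'
#' @param net A network (anything accepted by [as_network()]).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A list of class `obsremedy_params` with `coefficients` (a tibble
#'   `from`, `to`, `coef`, `value`), `values` (numeric vector in edge
#'   order) and `sigma` (the implied covariance matrix over all nodes).
#' @export
sample_parameters <- function(net, seed = 1L) {
  net <- as_network(net)
  vals <- with_local_seed(seed, {
    stats::runif(net$n_edges, 0.5, 1.5) *
      sample(c(-1, 1), net$n_edges, replace = TRUE)
  })
  structure(
    list(
      coefficients = tibble::tibble(
        from = net$nodes[net$from],
        to = net$nodes[net$to],
        coef = coef_names(net),
        value = vals
      ),
      values = vals,
      sigma = implied_covariance(net, vals),
      seed = as.integer(seed)
    ),
    class = "obsremedy_params"
  )
}

#' Implied covariance (correlation) of the standardized SEM
#'
#' In the standardized model every node variable has unit variance, so the
#' implied covariance matrix is the correlation matrix of the path
#' coefficients. It is computed by the exact recursion
#' `r[a, b] = sum over parents p of b of c[b, p] * r[a, p]` in topological
#' order with unit diagonal; its off-diagonal entries equal the Wright
#' simple-trek monomial sums of [build_equation()].
#'
#' @param net A network (anything accepted by [as_network()]).
#' @param values Numeric vector of edge-coefficient values in edge order
#'   (or a tibble as produced by [sample_parameters()]).
#' @return The n-by-n implied correlation matrix, dimnames set to the node
#'   identifiers.
#' @export
implied_covariance <- function(net, values) {
  net <- as_network(net)
  if (is.data.frame(values)) values <- values$value
  if (length(values) != net$n_edges) {
    rlang::abort("need one coefficient value per edge",
                 class = "obsremedy_param_error")
  }
  n <- net$n
  S <- diag(n)
  for (b in net$topo) {
    pars <- net$adj_in[[b]]
    if (!length(pars)) next
    cb <- values[net$eid[cbind(pars, b)]]
    v <- S[, pars, drop = FALSE] %*% cb
    v[b] <- 1
    S[, b] <- v
    S[b, ] <- v
  }
  dimnames(S) <- list(net$nodes, net$nodes)
  S
}

# Jacobian of the map from edge coefficients to the off-diagonal implied
# correlations of observed pairs, evaluated at `values`. Rows indexed by
# observed pairs (a < b canonical), columns by edges. Obtained by
# differentiating the correlation recursion (exact, no finite
# differences), independently of trek enumeration.
sem_jacobian <- function(net, obs_idx, values) {
  n <- net$n
  m <- net$n_edges
  obs_idx <- sort(unname(obs_idx))
  pairs <- if (length(obs_idx) >= 2) utils::combn(obs_idx, 2) else
    matrix(integer(0), nrow = 2)
  np <- ncol(pairs)
  J <- matrix(0, np, m)
  if (np == 0 || m == 0) return(list(J = J, pairs = pairs))
  S <- diag(n)
  dS <- array(0, dim = c(n, n, m))
  for (b in net$topo) {
    pars <- net$adj_in[[b]]
    if (!length(pars)) next
    eids <- net$eid[cbind(pars, b)]
    cb <- values[eids]
    v <- S[, pars, drop = FALSE] %*% cb
    v[b] <- 1
    S[, b] <- v
    S[b, ] <- v
    # d r[, b] = S[, pars] d c_b + (d S[, pars]) c_b
    for (e in seq_len(m)) {
      dv <- matrix(dS[, pars, e], n, length(pars)) %*% cb
      hit <- match(e, eids)
      if (!is.na(hit)) dv <- dv + S[, pars[hit]]
      dv[b] <- 0
      dS[, b, e] <- dv
      dS[b, , e] <- dv
    }
  }
  for (e in seq_len(m)) {
    J[, e] <- dS[, , e][cbind(pairs[1, ], pairs[2, ])]
  }
  list(J = J, pairs = pairs)
}

#' Generic local identifiability verdict from the Jacobian rank
#'
#' Builds the map from the edge coefficients to the off-diagonal
#' observed-pair covariances, evaluates its Jacobian at `trials` random
#' parameter points (coefficients bounded away from zero) and takes the
#' maximum numerical rank (singular values above `1e-8` times the
#' largest). All coefficients are generically locally identifiable iff
#' that rank equals the number of unknown parameters N_u.
#'
#' @param net A network (anything accepted by [as_network()]).
#' @param observed An observation strategy (see [as_strategy()]).
#' @param trials Number of random parameter draws (rank is taken as the
#'   maximum across draws; the generic rank is attained almost surely).
#' @param seed Integer seed.
#' @return An object of class `obsremedy_verdict`: `rank`, `n_u`,
#'   `identifiable` (`rank == n_u`), `status` (named 0/1 vector per edge
#'   coefficient: 0 when the coefficient's column participates in the
#'   Jacobian null space, i.e. is locally undetermined) and `trials`.
#' @examples
#' jacobian_identifiable(network_fixture("diamond4"), c("1", "2", "3", "4"))
#' @export
jacobian_identifiable <- function(net, observed, trials = 3L, seed = 1L) {
  net <- as_network(net)
  obs <- as_strategy(net, observed)
  if (trials < 1) rlang::abort("`trials` must be at least 1",
                               class = "obsremedy_param_error")
  obs_idx <- which(obs)
  m <- net$n_edges
  best_rank <- 0L
  best_sv <- NULL
  best_J <- NULL
  for (tr in seq_len(trials)) {
    vals <- with_local_seed(seed + tr - 1L, {
      stats::runif(m, 0.5, 1.5) * sample(c(-1, 1), m, replace = TRUE)
    })
    jj <- sem_jacobian(net, obs_idx, vals)
    if (nrow(jj$J) == 0 || m == 0) {
      rk <- 0L
      sv <- numeric(0)
    } else {
      sv <- svd(jj$J, nu = 0, nv = 0)$d
      rk <- sum(sv > 1e-8 * max(sv, 0))
    }
    if (rk >= best_rank) {
      best_rank <- as.integer(rk)
      best_sv <- sv
      best_J <- jj$J
    }
    if (best_rank == m) break
  }
  status <- rep(1L, m)
  if (m > 0 && best_rank < m) {
    if (is.null(best_J) || nrow(best_J) == 0) {
      status <- rep(0L, m)
    } else {
      dec <- svd(best_J, nu = 0, nv = m)
      null_basis <- dec$v[, seq.int(best_rank + 1L, m), drop = FALSE]
      status[rowSums(abs(null_basis) > 1e-6) > 0] <- 0L
    }
  }
  names(status) <- coef_names(net)
  structure(
    list(rank = best_rank, n_u = m, identifiable = best_rank == m,
         status = status, trials = as.integer(trials),
         singular_values = best_sv),
    class = "obsremedy_verdict"
  )
}

#' @export
print.obsremedy_verdict <- function(x, ...) {
  cat("<obsremedy_verdict> rank ", x$rank, " / N_u ", x$n_u, ": ",
      if (x$identifiable) "all coefficients locally identifiable"
      else "NOT identifiable", "\n", sep = "")
  if (!x$identifiable && x$n_u > 0) {
    cat("undetermined coefficients: ",
        paste(names(x$status)[x$status == 0L], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @method tidy obsremedy_verdict
#' @export
tidy.obsremedy_verdict <- function(x, ...) {
  tibble::tibble(coef = names(x$status), identifiable = x$status == 1L)
}

#' @method glance obsremedy_verdict
#' @export
glance.obsremedy_verdict <- function(x, ...) {
  tibble::tibble(rank = x$rank, n_u = x$n_u, identifiable = x$identifiable,
                 trials = x$trials)
}
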