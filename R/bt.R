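#' Bradley-Terry preference estimation by maximum likelihood
#'
#' Fits the Bradley-Terry paired-comparison model to a win-count matrix:
#' condition strengths `p` (constrained to the unit simplex) such that
#' `P(i chosen over j) = p_i / (p_i + p_j)`.  The maximum-likelihood
#' estimate satisfies the stationarity conditions
#' \deqn{T_i / p_i = \sum_{j \ne i} n_{ij} / (p_i + p_j), \qquad \sum_i p_i = 1,}
#' where `T_i` is the total number of wins of condition `i` and `n_ij` the
#' number of comparisons of the pair.  They are solved by the classical
#' Zermelo/Ford minorization fixed-point iteration
#' `p_i <- T_i / sum_j n_ij / (p_i + p_j)` with renormalization each sweep,
#' which increases the log-likelihood monotonically.
#'
#' The MLE does not exist when some condition never wins (its strength sits
#' on the simplex boundary) or when the comparison graph is disconnected.
#' A disconnected graph is an error; a zero-win condition triggers a
#' regularized fall-back in which 0.5 pseudo-counts are added to every
#' compared pair (flagged via `regularized` and a warning).
#'
#' @param table A `choice_table` from [tabulate_choices()], a plain `k x k`
#'   win-count matrix, or a choice-record data frame (tabulated
#'   internally).
#' @param tol Convergence tolerance on the maximum absolute change of `p`
#'   between sweeps; default 1e-10.
#' @param max_iter Maximum number of sweeps; default 1e5.
#' @return An object of class `bt_fit` with components `p` (unit-sum
#'   strengths), `loglik`, `iterations`, `converged`, `regularized`, `T`
#'   and `n_ij`.
#' @examples
#' tab <- matrix(c(0, 3, 1, 0), 2, 2, byrow = TRUE)
#' fit <- bt_fit(tab)
#' coef(fit)  # 0.75, 0.25
#' @export
bt_fit <- function(table, tol = 1e-10, max_iter = 1e5) {
  if (is.data.frame(table)) {
    table <- tabulate_choices(table, max(table$left, table$right))
  }
  tab <- unclass(table)
  attr(tab, "n_ij") <- NULL
  if (!is.matrix(tab) || nrow(tab) != ncol(tab)) {
    stopf("win-count table must be a square matrix")
  }
  if (any(tab < 0) || any(diag(tab) != 0)) {
    stopf("win counts must be non-negative with a zero diagonal")
  }
  k <- nrow(tab)
  n_ij <- tab + t(tab)
  check_connected(n_ij)
  wins <- rowSums(tab)
  regularized <- FALSE
  if (any(wins == 0)) {
    warning(paste("some conditions never won a comparison; the MLE lies on",
                  "the simplex boundary -- adding 0.5 pseudo-counts to every",
                  "compared pair"), call. = FALSE)
    tab <- tab + 0.5 * (n_ij > 0)
    n_ij <- tab + t(tab)
    wins <- rowSums(tab)
    regularized <- TRUE
  }
  p <- rep(1 / k, k)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    denom <- vapply(seq_len(k), function(i) {
      sum(n_ij[i, -i] / (p[i] + p[-i]))
    }, numeric(1))
    p_new <- wins / denom
    p_new <- p_new / sum(p_new)
    if (max(abs(p_new - p)) < tol) {
      p <- p_new
      converged <- TRUE
      break
    }
    p <- p_new
  }
  names(p) <- rownames(tab) %||% paste0("c", seq_len(k))
  structure(list(p = p, loglik = bt_loglik(p, tab),
                 iterations = iter, converged = converged,
                 regularized = regularized, T = tab, n_ij = n_ij),
            class = "bt_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Log-likelihood of strengths p under win counts tab (upper+lower kept
# separately, so each directed win contributes log(p_win/(p_win+p_lose))).
bt_loglik <- function(p, tab) {
  k <- nrow(tab)
  ll <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j && tab[i, j] > 0) {
        ll <- ll + tab[i, j] * log(p[i] / (p[i] + p[j]))
      }
    }
  }
  ll
}

# Error if the comparison graph (edges where n_ij > 0) is disconnected.
check_connected <- function(n_ij) {
  k <- nrow(n_ij)
  seen <- logical(k)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    i <- queue[1L]
    queue <- queue[-1L]
    nb <- which(n_ij[i, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  if (!all(seen)) {
    stopf("comparison graph is disconnected: conditions %s share no comparisons with condition 1",
          paste(which(!seen), collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.bt_fit <- function(x, digits = 4, ...) {
  cat("Bradley-Terry maximum-likelihood preference fit\n")
  print(round(x$p, digits))
  cat(sprintf("log-likelihood %.4f after %d iterations (%s%s)\n",
              x$loglik, x$iterations,
              if (x$converged) "converged" else "NOT converged",
              if (x$regularized) ", regularized" else ""))
  invisible(x)
}

#' @export
summary.bt_fit <- function(object, ...) {
  rank <- rank(-object$p, ties.method = "min")
  out <- data.frame(condition = names(object$p), p = unname(object$p),
                    rank = rank)
  structure(list(table = out, loglik = object$loglik,
                 converged = object$converged,
                 regularized = object$regularized,
                 n_comparisons = sum(object$n_ij) / 2),
            class = "summary.bt_fit")
}

#' @export
print.summary.bt_fit <- function(x, ...) {
  cat(sprintf("Bradley-Terry fit on %d comparisons (loglik %.3f)\n",
              x$n_comparisons, x$loglik))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
coef.bt_fit <- function(object, ...) object$p

#' @export
logLik.bt_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$p) - 1L, class = "logLik")
}

#' Pairwise choice probabilities from a Bradley-Terry fit
#'
#' `predict()` returns the full matrix of modeled probabilities
#' `P(row chosen over column) = p_i / (p_i + p_j)`;
#' `pairwise_preference()` a single entry.
#'
#' @param object A [bt_fit].
#' @param ... Unused.
#' @return A `k x k` probability matrix with `NA` on the diagonal.
#' @export
predict.bt_fit <- function(object, ...) {
  p <- object$p
  m <- outer(p, p, function(a, b) a / (a + b))
  diag(m) <- NA_real_
  m
}

#' @rdname predict.bt_fit
#' @param est A [bt_fit] (or anything with a `p` component).
#' @param i,j Distinct condition indices.
#' @export
pairwise_preference <- function(est, i, j) {
  p <- if (inherits(est, "bt_fit")) est$p else est
  if (i == j) stopf("i and j must differ")
  if (i < 1 || j < 1 || i > length(p) || j > length(p)) {
    stopf("condition index out of range")
  }
  p[[i]] / (p[[i]] + p[[j]])
}

#' Simulate choice records from a fitted Bradley-Terry model
#'
#' Parametric simulation: each replicate runs one synthetic observer with
#' the fitted strengths over a freshly shuffled full schedule.
#'
#' @param object A [bt_fit].
#' @param nsim Number of simulated subjects.
#' @param seed RNG seed.
#' @param ... Unused.
#' @return A list of `nsim` choice-record data frames.
#' @export
simulate.bt_fit <- function(object, nsim = 1, seed = NULL, ...) {
  k <- length(object$p)
  obs <- observer_spec(strengths = object$p)
  seeds <- derive_seeds(seed, 2L * nsim)
  lapply(seq_len(nsim), function(s) {
    sched <- build_schedule(k, seed = seeds[2L * s - 1L])
    simulate_observer(sched, obs, subject = s, seed = seeds[2L * s])
  })
}

#' @export
plot.bt_fit <- function(x, ...) {
  graphics::plot(seq_along(x$p), x$p, type = "b", xlab = "condition",
                 ylab = "preference strength p", ...)
  invisible(x)
}
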