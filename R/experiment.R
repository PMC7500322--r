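# Paired-comparison (two-alternative forced choice) machinery: balanced
# side-by-side schedules, synthetic observers, and win-count tabulation.

#' Balanced paired-comparison schedule
#'
#' All ordered pairs of `k` conditions — every unordered pair appears
#' exactly twice, once per left-right arrangement — presented in random
#' order.  For `k = 9` this is the 72-trial comparison game.
#'
#' @param k Number of conditions (>= 2).
#' @param seed RNG seed for the trial-order shuffle.
#' @return A data frame of class `comparison_schedule` with columns
#'   `trial`, `left`, `right` (condition indices, 1-based).
#' @examples
#' sched <- build_schedule(9, seed = 1)
#' nrow(sched)  # 72
#' @export
build_schedule <- function(k, seed = NULL) {
  if (!is.numeric(k) || length(k) != 1L || k < 2) {
    stopf("k must be an integer >= 2")
  }
  k <- as.integer(k)
  pairs <- expand.grid(left = seq_len(k), right = seq_len(k))
  pairs <- pairs[pairs$left != pairs$right, , drop = FALSE]
  ord <- with_seed(seed, sample.int(nrow(pairs)))
  sched <- pairs[ord, , drop = FALSE]
  sched <- data.frame(trial = seq_len(nrow(sched)), left = sched$left,
                      right = sched$right)
  class(sched) <- c("comparison_schedule", "data.frame")
  sched
}

#' Synthetic observer
#'
#' Describes a simulated subject whose choices follow the Bradley-Terry
#' rule `P(i over j) = p_i / (p_i + p_j)`.  Strengths are either given
#' directly (`strengths`) or derived from a latent jerk-preference curve
#' via the link `p_i = exp(beta * f(x_i))`, where `f` is a [pref_model]
#' evaluated at each condition's jerk and `beta` sets decision
#' determinism.
#'
#' @param strengths Optional vector of positive condition strengths.
#' @param model Optional [pref_model] giving the latent preference curve.
#' @param beta Inverse-temperature of the exponential link; default 1.
#' @return An object of class `observer_spec`.
#' @export
observer_spec <- function(strengths = NULL, model = NULL, beta = 1) {
  if (is.null(strengths) && is.null(model)) {
    stopf("supply either strengths or a preference model")
  }
  if (!is.null(strengths) && any(strengths <= 0)) {
    stopf("observer strengths must be strictly positive")
  }
  structure(list(strengths = strengths, model = model, beta = beta),
            class = "observer_spec")
}

observer_strengths <- function(observer, k, jerks = NULL) {
  if (!is.null(observer$strengths)) {
    p <- observer$strengths
    if (length(p) != k) stopf("observer defines %d strengths for %d conditions",
                              length(p), k)
  } else {
    if (is.null(jerks)) stopf("model-based observers need per-condition jerks")
    if (length(jerks) != k) stopf("need one jerk value per condition")
    p <- exp(observer$beta * predict(observer$model, jerks))
  }
  if (any(!is.finite(p)) || any(p <= 0)) {
    stopf("observer strengths must be finite and strictly positive")
  }
  p
}

#' Simulate an observer's choices over a schedule
#'
#' Each trial is a Bernoulli draw with
#' `P(choose left) = p_left / (p_left + p_right)`; presentation side does
#' not enter the probability.
#'
#' @param schedule A [build_schedule()] data frame.
#' @param observer An [observer_spec].
#' @param jerks Per-condition average absolute jerk values (deg/s^3),
#'   required for model-based observers.
#' @param subject Subject identifier stored with each record.
#' @param seed RNG seed.
#' @return A data frame of choice records with columns `subject`, `trial`,
#'   `left`, `right`, `choice` (`"left"` or `"right"`).
#' @export
simulate_observer <- function(schedule, observer, jerks = NULL,
                              subject = 1L, seed = NULL) {
  stopifnot(inherits(schedule, "comparison_schedule") ||
              all(c("left", "right") %in% names(schedule)))
  k <- max(schedule$left, schedule$right)
  p <- observer_strengths(observer, k, jerks)
  prob_left <- p[schedule$left] / (p[schedule$left] + p[schedule$right])
  u <- with_seed(seed, stats::runif(nrow(schedule)))
  data.frame(subject = subject, trial = schedule$trial,
             left = schedule$left, right = schedule$right,
             choice = ifelse(u < prob_left, "left", "right"),
             stringsAsFactors = FALSE)
}

#' Simulate a pooled group of observers
#'
#' Runs [simulate_observer()] for `n_subjects` independent subjects, each
#' with a freshly shuffled schedule, and returns the stacked records.
#'
#' @inheritParams simulate_observer
#' @param k Number of conditions.
#' @param n_subjects Number of simulated subjects.
#' @param seed Master seed; per-subject schedule and choice seeds derive
#'   from it.
#' @return A data frame of pooled choice records.
#' @export
simulate_group <- function(k, observer, jerks = NULL, n_subjects = 1L,
                           seed = NULL) {
  seeds <- derive_seeds(seed, 2L * n_subjects)
  do.call(rbind, lapply(seq_len(n_subjects), function(s) {
    sched <- build_schedule(k, seed = seeds[2L * s - 1L])
    simulate_observer(sched, observer, jerks, subject = s,
                      seed = seeds[2L * s])
  }))
}

#' Tabulate choice records into a win-count matrix
#'
#' Builds the `k x k` matrix `T` with `T[i, j]` the number of times
#' condition `i` was chosen over condition `j`; `T[i, j] + T[j, i]` equals
#' the number of trials pairing `i` and `j`.
#'
#' @param records Choice records as from [simulate_observer()] (or read
#'   back via [read_choices()]).
#' @param k Number of conditions.
#' @return An object of class `choice_table`: the integer win matrix, with
#'   the pair-count matrix in attribute `n_ij`.
#' @export
tabulate_choices <- function(records, k) {
  need <- c("left", "right", "choice")
  miss <- setdiff(need, names(records))
  if (length(miss)) stopf("choice records lack columns: %s",
                          paste(miss, collapse = ", "))
  k <- as.integer(k)
  tab <- matrix(0L, k, k)
  if (nrow(records)) {
    bad <- which(!(records$choice %in% c("left", "right")) |
                   records$left < 1 | records$left > k |
                   records$right < 1 | records$right > k |
                   records$left == records$right)
    if (length(bad)) stopf("malformed choice record at row %d", bad[1L])
    winner <- ifelse(records$choice == "left", records$left, records$right)
    loser <- ifelse(records$choice == "left", records$right, records$left)
    for (r in seq_along(winner)) {
      tab[winner[r], loser[r]] <- tab[winner[r], loser[r]] + 1L
    }
  }
  structure(tab, n_ij = tab + t(tab), class = "choice_table")
}

#' @export
print.choice_table <- function(x, ...) {
  cat(sprintf("Choice table: %d conditions, %d comparisons\n",
              nrow(x), sum(unclass(x))))
  print(unclass(x)[seq_len(nrow(x)), seq_len(ncol(x))])
  invisible(x)
}

#' Read or write choice records as CSV
#'
#' Plain CSV with header `subject,trial,left,right,choice`.
#'
#' @param records Choice-record data frame.
#' @param path File path.
#' @return `write_choices()` returns `path` invisibly; `read_choices()` the
#'   records data frame.
#' @export
write_choices <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_choices
#' @export
read_choices <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "trial", "left", "right", "choice")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("choice CSV lacks columns: %s",
                          paste(miss, collapse = ", "))
  df
}
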