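#' Sample random memory-one opponents
#'
#' Draws `N` strategies i.i.d. uniformly from the unit 4-cube — the
#' maximum-entropy model of "randomly generated" memory-one opponents used
#' throughout the experiment harnesses.
#'
#' @param N Number of opponents.
#' @param seed Integer seed.
#' @return An `N x 4` matrix, one strategy per row.
#' @export
sample_opponents <- function(N, seed = 1L) {
  stopifnot(N >= 1L)
  withr::with_seed(seed, matrix(stats::runif(4L * N), nrow = N, byrow = TRUE))
}

#' Summary statistics of a sample
#'
#' The statistics reported for experiment distributions: sample mean,
#' sample standard deviation (n-1 denominator), 5%/50%/95% empirical
#' quantiles (linear interpolation), maximum, bias-corrected sample skewness
#' and bias-corrected excess kurtosis.
#'
#' @param values Numeric vector with at least 4 values (kurtosis needs 4).
#' @return Named list of class `summary_statistics` with elements `mean`,
#'   `std`, `q05`, `median`, `q95`, `max`, `skewness`, `kurtosis`.
#' @export
summary_statistics <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 4L || anyNA(values)) {
    stop("insufficient data: need at least 4 non-missing values",
         call. = FALSE)
  }
  qs <- stats::quantile(values, c(0.05, 0.5, 0.95), names = FALSE)
  structure(list(
    mean = mean(values),
    std = stats::sd(values),
    q05 = qs[1], median = qs[2], q95 = qs[3],
    max = max(values),
    skewness = e1071::skewness(values, type = 2),
    kurtosis = e1071::kurtosis(values, type = 2)
  ), class = "summary_statistics")
}

#' @export
print.summary_statistics <- function(x, ...) {
  v <- unlist(unclass(x))
  print(round(v, 4))
  invisible(x)
}

# Independent sub-seeds for each trial, derived reproducibly from one seed.
trial_seeds <- function(seed, trials) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, trials))
}

#' Distribution of ZD distance over best responses (tournament experiment)
#'
#' For each trial: draw `N` uniform-random memory-one opponents, solve for
#' the best-response memory-one strategy, and record its [sse()] (squared
#' distance from the nearest zero-determinant strategy). The distribution of
#' this statistic shows how (non-)extortionate optimal play is.
#'
#' @param trials Number of trials.
#' @param N Opponents per trial (default 2, the tournament setting).
#' @param payoffs A [pd_payoffs()] object.
#' @param method `"candidates"` (exact candidate-set search, default) or
#'   `"bayesian"`.
#' @param seed Integer seed.
#' @param control [solver_control()] for the candidate search.
#' @param budget Evaluation budget for the Bayesian method.
#' @return List with `records` (data.frame: trial, opponent coordinates,
#'   best-response vector, objective, sse, method, seed), `summary`
#'   (a [summary_statistics()] of the SSE values) and `failures`.
#' @export
run_sse_experiment <- function(trials, N = 2L, payoffs = pd_payoffs(),
                               method = c("candidates", "bayesian"),
                               seed = 1L, control = solver_control(),
                               budget = 64L) {
  stopifnot(trials >= 1L)
  method <- match.arg(method)
  seeds <- trial_seeds(seed, trials)
  rows <- vector("list", trials)
  failures <- 0L
  for (tr in seq_len(trials)) {
    rows[[tr]] <- tryCatch({
      opp <- sample_opponents(N, seeds[tr])
      br <- withr::with_seed(seeds[tr], switch(
        method,
        candidates = best_response_candidates(opp, payoffs, control),
        bayesian = best_response_bayesian(opp, payoffs, budget, seeds[tr])))
      opp_cols <- as.list(as.vector(t(opp)))
      names(opp_cols) <- paste0("o", rep(seq_len(N), each = 4L), "_p", 1:4)
      cbind(data.frame(trial = tr),
            as.data.frame(opp_cols),
            data.frame(p1 = br$p_star[1], p2 = br$p_star[2],
                       p3 = br$p_star[3], p4 = br$p_star[4],
                       objective = br$objective,
                       sse = sse(br$p_star, payoffs),
                       method = method, seed = seeds[tr]))
    }, error = function(e) {
      failures <<- failures + 1L
      NULL
    })
  }
  records <- do.call(rbind, rows)
  list(records = records, summary = summary_statistics(records$sse),
       failures = failures)
}

#' Dynamic Moran-process experiment over random opponents
#'
#' For each trial: draw one uniform-random resident opponent, run
#' [dynamic_moran_experiment()] for all compositions `K = 1, ..., n-1`, and
#' record the dynamic and static fixation probabilities, their ratio, and the
#' [sse()] of every dynamic best-response strategy.
#'
#' @param trials Number of trials.
#' @param n Population size (default 4).
#' @param seed Integer seed.
#' @param payoffs A [pd_payoffs()] object.
#' @param ... Passed to [dynamic_moran_experiment()].
#' @return List with `records` (data.frame: trial, K, opponent coordinates,
#'   x_dynamic, x_static, ratio, sse), `ratio_mean`, `sse_mean`, and
#'   `failures`.
#' @export
run_moran_experiment <- function(trials, n = 4L, seed = 1L,
                                 payoffs = pd_payoffs(), ...) {
  stopifnot(trials >= 1L)
  seeds <- trial_seeds(seed, trials)
  rows <- vector("list", trials)
  failures <- 0L
  for (tr in seq_len(trials)) {
    rows[[tr]] <- tryCatch({
      q <- as.vector(sample_opponents(1L, seeds[tr]))
      res <- dynamic_moran_experiment(q, n = n, payoffs = payoffs,
                                      seed = seeds[tr], ...)
      sses <- vapply(res$strategies, sse, numeric(1), payoffs = payoffs)
      cbind(data.frame(trial = tr),
            data.frame(q1 = q[1], q2 = q[2], q3 = q[3], q4 = q[4]),
            res$table, data.frame(sse = sses))
    }, error = function(e) {
      failures <<- failures + 1L
      NULL
    })
  }
  records <- do.call(rbind, rows)
  list(records = records,
       ratio_mean = mean(records$ratio),
       sse_mean = mean(records$sse),
       failures = failures)
}

#' Gambler versus memory-one best response over random opponent pairs
#'
#' For each trial: draw 2 uniform-random memory-one opponents, compute the
#' analytic memory-one best response and an optimised Gambler, and record the
#' ratio of their utilities (see [utility_ratio_trial()]).
#'
#' @param trials Number of trials.
#' @param turns,repetitions,budget Simulation/optimisation scale per trial
#'   (fast-profile defaults 100 x 20, 60 evaluations; paper scale is
#'   500 x 200).
#' @param seed Integer seed.
#' @param payoffs A [pd_payoffs()] object.
#' @param control [solver_control()] for the memory-one best response.
#' @return List with `records` (data.frame: trial, opponent coordinates,
#'   ratio, gambler and memory-one objectives) and `failures`.
#' @export
run_gambler_experiment <- function(trials, turns = 100L, repetitions = 20L,
                                   budget = 60L, seed = 1L,
                                   payoffs = pd_payoffs(),
                                   control = solver_control()) {
  stopifnot(trials >= 1L)
  seeds <- trial_seeds(seed, trials)
  rows <- vector("list", trials)
  failures <- 0L
  for (tr in seq_len(trials)) {
    rows[[tr]] <- tryCatch({
      opp <- sample_opponents(2L, seeds[tr])
      res <- utility_ratio_trial(opp, payoffs, turns, repetitions, budget,
                                 seed = seeds[tr], control = control)
      data.frame(trial = tr,
                 o1_p1 = opp[1, 1], o1_p2 = opp[1, 2],
                 o1_p3 = opp[1, 3], o1_p4 = opp[1, 4],
                 o2_p1 = opp[2, 1], o2_p2 = opp[2, 2],
                 o2_p3 = opp[2, 3], o2_p4 = opp[2, 4],
                 ratio = res$ratio,
                 gambler_objective = res$gambler_objective,
                 memone_objective = res$memory_one$objective,
                 seed = seeds[tr])
    }, error = function(e) {
      failures <<- failures + 1L
      NULL
    })
  }
  records <- do.call(rbind, rows)
  list(records = records, failures = failures)
}
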