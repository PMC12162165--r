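#' Hyperparameter search space
#'
#' A search space is a named list of parameter domains built with
#' `param_num()` (continuous, optionally log-scaled) and `param_int()`
#' (integer).
#'
#' @param low,high Domain bounds (`low < high`; strictly positive when
#'   `log = TRUE`).
#' @param log Sample and model the parameter on the log scale.
#' @return A parameter-domain object.
#' @examples
#' space <- list(eta = param_num(0.01, 0.5, log = TRUE),
#'               max_depth = param_int(2, 8))
#' @export
param_num <- function(low, high, log = FALSE) {
  if (!(low < high)) stop("low must be < high", call. = FALSE)
  if (log && low <= 0) stop("log-scale domain must be positive", call. = FALSE)
  structure(list(type = "num", low = low, high = high, log = log),
            class = "param_domain")
}

#' @rdname param_num
#' @export
param_int <- function(low, high) {
  if (!(low < high)) stop("low must be < high", call. = FALSE)
  structure(list(type = "int", low = as.integer(low),
                 high = as.integer(high), log = FALSE),
            class = "param_domain")
}

.sample_uniform <- function(dom) {
  if (dom$type == "int") {
    sample(dom$low:dom$high, 1)
  } else if (dom$log) {
    exp(stats::runif(1, log(dom$low), log(dom$high)))
  } else {
    stats::runif(1, dom$low, dom$high)
  }
}

.kde_bw <- function(o, span) {
  # Silverman with a generous floor: a collapsed bandwidth turns the
  # sampler into a pure exploiter that crawls (no exploration)
  bw <- max(stats::sd(o) * 1.06 * length(o)^(-0.2), span / 20,
            na.rm = TRUE)
  if (!is.finite(bw) || bw <= 0) bw <- span / 20
  bw
}

# 1-D Parzen density with a uniform-prior component mixed in (weight of
# one pseudo-observation), evaluated at `at`. The prior keeps density
# ratios bounded and preserves exploration, as in standard TPE practice.
.kde_density <- function(obs, at, dom) {
  tf <- if (dom$log) log else identity
  o <- tf(obs); a <- tf(at)
  span <- tf(dom$high) - tf(dom$low)
  bw <- .kde_bw(o, span)
  n <- length(o)
  vapply(a, function(v) {
    (sum(stats::dnorm(v, o, bw)) + 1 / span) / (n + 1)
  }, 0)
}

.sample_from_good <- function(obs, dom, n) {
  tf <- if (dom$log) log else identity
  itf <- if (dom$log) exp else identity
  o <- tf(obs)
  span <- tf(dom$high) - tf(dom$low)
  lo <- tf(dom$low)
  bw <- .kde_bw(o, span)
  # mixture: each observation and one uniform prior component
  comp <- sample.int(length(o) + 1, n, replace = TRUE)
  z <- ifelse(comp > length(o),
              stats::runif(n, lo, lo + span),
              stats::rnorm(n, o[pmin(comp, length(o))], bw))
  x <- itf(pmin(pmax(z, lo), lo + span))
  if (dom$type == "int") x <- as.integer(round(x))
  x
}

#' Hyperparameter search with a TPE-style or random sampler
#'
#' Runs `n_trials` evaluations of `objective` over `space`. The `"random"`
#' sampler draws every trial uniformly from the domains. The `"tpe"`
#' sampler reproduces the tree-structured Parzen estimator idea in a
#' simplified, per-parameter form: after `n_startup` random trials the
#' history is split into the best `good_quantile` fraction ("good") and
#' the rest ("bad"); independent 1-D kernel densities `l` (good) and `g`
#' (bad) are fitted per parameter; `n_candidates` candidates are drawn
#' from `l` and the one maximizing `sum(log l - log g)` is evaluated.
#' Trials with non-finite objective values are marked failed and excluded
#' from the density models. The whole search is reproducible from `seed`.
#'
#' @param space Named list of [param_num()] / [param_int()] domains.
#' @param objective Function taking a named list of parameter values and
#'   returning a scalar score.
#' @param n_trials Number of trials (>= 1).
#' @param sampler `"tpe"` (default) or `"random"`.
#' @param direction `"maximize"` (default) or `"minimize"`.
#' @param seed Integer seed.
#' @param n_startup Random trials before the TPE model kicks in.
#' @param good_quantile Fraction of history treated as "good".
#' @param n_candidates Candidates scored per TPE step.
#' @return Object of class `"trial_log"`: data frame of trials (columns
#'   `trial`, `value`, `failed`, one column per parameter) with attributes
#'   `best_index`, `best_params`, `best_value`, `sampler`, `direction`,
#'   `seed`.
#' @export
tune <- function(space, objective, n_trials = 50,
                 sampler = c("tpe", "random"),
                 direction = c("maximize", "minimize"), seed = 1,
                 n_startup = 10, good_quantile = 0.25, n_candidates = 24) {
  sampler <- match.arg(sampler)
  direction <- match.arg(direction)
  if (!length(space)) stop("empty search space", call. = FALSE)
  if (is.null(names(space)) || any(names(space) == "")) {
    stop("search space must be a named list", call. = FALSE)
  }
  stopifnot(n_trials >= 1)
  rs <- .save_rng_state()
  on.exit(.restore_rng_state(rs))
  set.seed(as.integer(seed))

  hist_params <- vector("list", n_trials)
  values <- rep(NA_real_, n_trials)
  failed <- rep(FALSE, n_trials)
  sign <- if (direction == "maximize") 1 else -1

  for (k in seq_len(n_trials)) {
    ok <- which(!failed[seq_len(k - 1)] & !is.na(values[seq_len(k - 1)]))
    use_tpe <- sampler == "tpe" && length(ok) >= n_startup
    cand <- if (!use_tpe) {
      lapply(space, .sample_uniform)
    } else {
      v <- sign * values[ok]
      n_good <- max(1L, ceiling(good_quantile * length(ok)))
      ord <- order(v, decreasing = TRUE)
      good <- ok[ord[seq_len(n_good)]]
      bad <- ok[ord[-seq_len(n_good)]]
      if (!length(bad)) {
        lapply(space, .sample_uniform)
      } else {
        cands <- lapply(names(space), function(pn) {
          .sample_from_good(vapply(hist_params[good], `[[`, 0, pn),
                            space[[pn]], n_candidates)
        })
        names(cands) <- names(space)
        score <- numeric(n_candidates)
        for (pn in names(space)) {
          gobs <- vapply(hist_params[good], `[[`, 0, pn)
          bobs <- vapply(hist_params[bad], `[[`, 0, pn)
          l <- .kde_density(gobs, cands[[pn]], space[[pn]])
          g <- .kde_density(bobs, cands[[pn]], space[[pn]])
          score <- score + log(pmax(l, 1e-300)) - log(pmax(g, 1e-300))
        }
        j <- which.max(score)
        lapply(cands, `[[`, j)
      }
    }
    hist_params[[k]] <- cand
    val <- tryCatch(objective(cand), error = function(e) NaN)
    if (!is.finite(val)) {
      failed[k] <- TRUE
      values[k] <- NA_real_
    } else {
      values[k] <- val
    }
  }

  tab <- data.frame(trial = seq_len(n_trials), value = values,
                    failed = failed)
  for (pn in names(space)) {
    tab[[pn]] <- vapply(hist_params, `[[`, 0, pn)
  }
  ok <- which(!failed)
  if (!length(ok)) stop("all trials failed", call. = FALSE)
  best <- ok[which.max(sign * values[ok])]
  structure(tab, class = c("trial_log", "data.frame"),
            best_index = best, best_params = hist_params[[best]],
            best_value = values[best], sampler = sampler,
            direction = direction, seed = seed)
}

#' @export
print.trial_log <- function(x, ...) {
  cat(sprintf("Hyperparameter search (%s, %s): %d trials, %d failed\n",
              attr(x, "sampler"), attr(x, "direction"), nrow(x),
              sum(x$failed)))
  bp <- attr(x, "best_params")
  cat(sprintf("  best value %.6g at trial %d\n", attr(x, "best_value"),
              attr(x, "best_index")))
  cat("  best params:",
      paste(names(bp), signif(unlist(bp), 4), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Best-so-far curve of a trial log
#'
#' @param log A [tune()] result.
#' @return Numeric vector: the running optimum of the objective
#'   (maximization: running max) with failed trials carried forward.
#' @export
best_so_far <- function(log) {
  sign <- if (attr(log, "direction") == "maximize") 1 else -1
  v <- ifelse(log$failed, NA, log$value)
  run <- v
  cur <- -Inf
  for (i in seq_along(v)) {
    if (!is.na(v[i])) cur <- max(cur, sign * v[i])
    run[i] <- sign * cur
  }
  run
}
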