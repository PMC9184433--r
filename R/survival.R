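# Survival machinery used to evaluate the grading systems, implemented
# from first principles: Kaplan-Meier product-limit estimation, the
# k-group log-rank test, univariate Cox proportional-hazards regression
# (Newton-Raphson on the partial likelihood with Efron tie handling),
# Harrell's concordance index with bootstrap confidence intervals, the
# sparse-group merging rule, and median imputation.

.check_surv <- function(time, event, what = "survival input") {
  if (length(time) != length(event))
    stop(what, ": time and event must have equal length", call. = FALSE)
  if (length(time) == 0) stop(what, ": empty input", call. = FALSE)
  if (!is.numeric(time) || anyNA(time) || any(!is.finite(time)) ||
      any(time <= 0))
    stop(what, ": time must be strictly positive and finite", call. = FALSE)
  if (anyNA(event)) stop(what, ": event must be TRUE/FALSE", call. = FALSE)
  invisible(as.logical(event))
}

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Kaplan-Meier product-limit estimator
#'
#' At each distinct event time t the survival estimate is updated as
#' S(t) = S(t-) (1 - d_t / n_t), with d_t events among the n_t patients
#' still at risk; times with only censorings reduce the risk set but do
#' not change S.
#'
#' @param time Positive follow-up times (months).
#' @param event Logical (or 0/1): event observed vs right-censored.
#' @return An object of class `km_curve`: data.frame with one row per
#'   distinct event time and columns `time`, `n_risk`, `n_event`,
#'   `survival`.
#' @export
km_estimate <- function(time, event) {
  event <- .check_surv(time, event, "km_estimate")
  ut <- sort(unique(time[event]))
  n_risk <- vapply(ut, function(t) sum(time >= t), 0L)
  n_event <- vapply(ut, function(t) sum(time == t & event), 0L)
  surv <- cumprod(1 - n_event / n_risk)
  structure(data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                       survival = surv),
            class = c("km_curve", "data.frame"))
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve:", nrow(x), "event times\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' k-group log-rank test
#'
#' Compares observed event counts per group with those expected under the
#' hypergeometric null at each distinct event time; the quadratic form of
#' the first k-1 components of O - E against their covariance gives a
#' chi-square statistic on k - 1 degrees of freedom.
#'
#' @inheritParams km_estimate
#' @param group Group membership (coerced to factor); at least two
#'   non-empty groups.
#' @return List with `chisq`, `df`, `p_value`, and the per-group
#'   `observed` and `expected` event counts.
#' @export
logrank_test <- function(time, event, group) {
  event <- .check_surv(time, event, "logrank_test")
  g <- factor(group)
  if (nlevels(g) < 2)
    stop("logrank_test: need at least two groups", call. = FALSE)
  if (!any(event))
    stop("logrank_test: no events in any group", call. = FALSE)
  k <- nlevels(g)
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in sort(unique(time[event]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    nj <- vapply(seq_len(k), function(j) sum(at_risk & g == levels(g)[j]), 0L)
    dj <- vapply(seq_len(k), function(j)
      sum(time == t & event & g == levels(g)[j]), 0L)
    d <- sum(dj)
    O <- O + dj
    E <- E + d * nj / n
    if (n > 1) {
      p <- nj / n
      V <- V + d * (n - d) / (n - 1) * (diag(p, k) - tcrossprod(p))
    }
  }
  i <- seq_len(k - 1)
  chisq <- tryCatch(
    drop(t(O[i] - E[i]) %*% solve(V[i, i, drop = FALSE], O[i] - E[i])),
    error = function(e)
      stop("logrank_test: singular covariance (degenerate groups)",
           call. = FALSE))
  names(O) <- names(E) <- levels(g)
  list(chisq = chisq, df = k - 1,
       p_value = stats::pchisq(chisq, k - 1, lower.tail = FALSE),
       observed = O, expected = E)
}

# Partial log-likelihood, score and observed information for the Cox
# model at beta. Inputs must be pre-sorted by increasing time. Efron or
# Breslow handling of tied event times.
.cox_derivs <- function(beta, time, event, x, ties) {
  n <- nrow(x); p <- ncol(x)
  eta <- drop(x %*% beta)
  w <- exp(eta)
  # reverse cumulative risk-set sums
  S0 <- rev(cumsum(rev(w)))
  xw <- x * w
  S1 <- apply(xw, 2, function(col) rev(cumsum(rev(col))))
  S1 <- matrix(S1, nrow = n)
  S2 <- array(0, c(n, p, p))
  for (a in seq_len(p)) for (b in a:p) {
    s <- rev(cumsum(rev(x[, a] * xw[, b])))
    S2[, a, b] <- s
    S2[, b, a] <- s
  }
  ev_times <- unique(time[event])
  first <- match(ev_times, time)          # first index with time >= t
  ev_idx <- which(event)
  tied_list <- split(ev_idx, match(time[ev_idx], ev_times))

  ll <- 0; U <- numeric(p); I <- matrix(0, p, p)
  for (m in seq_along(ev_times)) {
    tied <- tied_list[[m]]
    dk <- length(tied)
    r0 <- S0[first[m]]
    r1 <- S1[first[m], ]
    r2 <- S2[first[m], , ]
    xt <- x[tied, , drop = FALSE]
    wt <- w[tied]
    s0t <- sum(wt)
    s1t <- colSums(xt * wt)
    s2t <- crossprod(xt, xt * wt)
    ll <- ll + sum(eta[tied])
    U <- U + colSums(xt)
    fr <- if (ties == "efron") (seq_len(dk) - 1) / dk else rep(0, dk)
    for (f in fr) {
      den <- r0 - f * s0t
      num1 <- r1 - f * s1t
      num2 <- r2 - f * s2t
      ll <- ll - log(den)
      U <- U - num1 / den
      I <- I + num2 / den - tcrossprod(num1) / den^2
    }
  }
  list(loglik = ll, U = U, I = I)
}

#' Univariate Cox proportional-hazards regression
#'
#' Maximises the Cox partial log-likelihood by Newton-Raphson (with step
#' halving), using Efron's approximation for tied event times by default.
#' Convergence is declared when the change in partial log-likelihood
#' falls below `tol` (default 1e-9); standard errors come from the
#' inverse observed information and 95% confidence intervals are Wald
#' intervals exp(coef +/- 1.96 se). The score test at beta = 0 is also
#' returned; for a single binary covariate it reproduces the two-group
#' log-rank statistic.
#'
#' @inheritParams km_estimate
#' @param x Numeric covariate vector or matrix (one column per
#'   covariate); columns must not be constant.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param tol Convergence tolerance on the partial log-likelihood.
#' @param max_iter Iteration cap (default 100).
#' @return An object of class `cox_fit`: list with `coef`, `se`, `hr`,
#'   `ci_low`, `ci_high`, `p_values`, `linear_predictor`, `loglik`,
#'   `score_chisq`, `score_df`, `n`, `n_events`, `iter`, `ties`.
#' @export
cox_fit <- function(time, event, x, ties = c("efron", "breslow"),
                    tol = 1e-9, max_iter = 100L) {
  ties <- match.arg(ties)
  event <- .check_surv(time, event, "cox_fit")
  x <- as.matrix(x)
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop("cox_fit: covariates must be finite numeric", call. = FALSE)
  if (nrow(x) != length(time))
    stop("cox_fit: covariate rows must match number of patients",
         call. = FALSE)
  if (ncol(x) == 0)
    stop("cox_fit: empty design matrix", call. = FALSE)
  if (!any(event)) stop("cox_fit: zero events", call. = FALSE)
  cst <- apply(x, 2, function(col) diff(range(col)) == 0)
  if (any(cst))
    stop("cox_fit: constant covariate: ",
         paste(colnames(x)[cst], collapse = ", "), call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))

  ord <- order(time)
  ts <- time[ord]; es <- event[ord]; xs <- x[ord, , drop = FALSE]
  p <- ncol(x)

  beta <- numeric(p)
  der <- .cox_derivs(beta, ts, es, xs, ties)
  score0 <- der  # derivatives at beta = 0 for the score test
  ll <- der$loglik
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(der$I, der$U), error = function(e)
      stop("cox_fit: singular information matrix (possible separation)",
           call. = FALSE))
    beta_new <- beta + step
    der_new <- .cox_derivs(beta_new, ts, es, xs, ties)
    halvings <- 0L
    while ((!is.finite(der_new$loglik) || der_new$loglik < ll) &&
           halvings < 30L) {
      halvings <- halvings + 1L
      beta_new <- (beta + beta_new) / 2
      der_new <- .cox_derivs(beta_new, ts, es, xs, ties)
    }
    done <- abs(der_new$loglik - ll) < tol
    beta <- beta_new; der <- der_new; ll <- der_new$loglik
    # a linear predictor spanning > 40 on the log scale means some
    # relative risks exceed e^40: the partial likelihood is monotone
    if (diff(range(xs %*% beta)) > 40)
      stop("cox_fit: monotone partial likelihood (complete separation)",
           call. = FALSE)
    if (done) { converged <- TRUE; break }
  }
  if (!converged)
    stop("cox_fit: Newton-Raphson failed to converge in ", max_iter,
         " iterations", call. = FALSE)

  vcov <- solve(der$I)
  se <- sqrt(diag(vcov))
  z <- beta / se
  score_chisq <- drop(t(score0$U) %*% solve(score0$I, score0$U))
  structure(list(
    coef = stats::setNames(beta, colnames(x)),
    se = stats::setNames(se, colnames(x)),
    hr = exp(beta),
    ci_low = exp(beta - 1.96 * se),
    ci_high = exp(beta + 1.96 * se),
    p_values = 2 * stats::pnorm(-abs(z)),
    vcov = vcov,
    linear_predictor = drop(x %*% beta),
    loglik = ll,
    loglik_null = score0$loglik,
    score_chisq = score_chisq,
    score_df = p,
    n = length(time), n_events = sum(event),
    iter = iter, ties = ties), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit (%s ties): n = %d, events = %d\n",
              x$ties, x$n, x$n_events))
  tab <- data.frame(coef = x$coef, se = x$se, HR = x$hr,
                    ci_low = x$ci_low, ci_high = x$ci_high, p = x$p_values)
  print(signif(tab, 4))
  invisible(x)
}

#' Harrell's concordance index
#'
#' Over all comparable patient pairs -- pairs where the patient with the
#' shorter follow-up had an event, plus equal-time pairs where exactly one
#' patient had the event (the event-bearing patient counts as earlier) --
#' the pair is concordant when the earlier-event patient carries the
#' strictly higher risk score; tied scores contribute 1/2. Pairs of
#' events at identical times are not comparable.
#'
#' @inheritParams km_estimate
#' @param score Per-patient risk score (higher = higher predicted risk).
#' @return List with `c` (the index) and `n_comparable_pairs`.
#' @export
harrell_c <- function(time, event, score) {
  event <- .check_surv(time, event, "harrell_c")
  if (length(score) != length(time) || anyNA(score) || any(!is.finite(score)))
    stop("harrell_c: score must be finite numeric matching patients",
         call. = FALSE)
  if (!any(event)) stop("harrell_c: no events", call. = FALSE)
  num <- 0; den <- 0
  for (i in which(event)) {
    later <- time > time[i] | (time == time[i] & !event)
    m <- sum(later)
    if (m == 0) next
    s <- score[later]
    num <- num + sum(score[i] > s) + 0.5 * sum(score[i] == s)
    den <- den + m
  }
  if (den == 0)
    stop("harrell_c: no comparable pairs", call. = FALSE)
  list(c = num / den, n_comparable_pairs = den)
}

# Shared engine: compute bootstrap c replicates for one or more scorers
# on identical patient resamples. scorers is a named list of functions
# data.frame -> numeric score vector.
.bootstrap_c_multi <- function(data, scorers, n_boot, seed) {
  stopifnot(is.data.frame(data), all(c("time", "event") %in% names(data)))
  if (n_boot < 2) stop("n_boot must be >= 2", call. = FALSE)
  n <- nrow(data)
  est <- lapply(scorers, function(f)
    harrell_c(data$time, data$event, f(data)))
  idx <- with_seed(seed,
    matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n))
  reps <- matrix(NA_real_, n_boot, length(scorers),
                 dimnames = list(NULL, names(scorers)))
  for (b in seq_len(n_boot)) {
    db <- data[idx[, b], , drop = FALSE]
    for (s in seq_along(scorers)) {
      reps[b, s] <- tryCatch(
        harrell_c(db$time, db$event, scorers[[s]](db))$c,
        error = function(e) NA_real_)
    }
  }
  bad <- apply(reps, 1, anyNA)
  if (any(bad))
    warning(sum(bad), " bootstrap replicate(s) discarded ",
            "(no comparable pairs or degenerate resample)", call. = FALSE)
  if (sum(bad) > 0.1 * n_boot)
    stop("more than 10% of bootstrap replicates unusable", call. = FALSE)
  list(estimates = est, replicates = reps[!bad, , drop = FALSE],
       n_boot = n_boot, seed = seed)
}

#' Bootstrap confidence interval for Harrell's c
#'
#' Resamples patients with replacement, recomputes the risk score on each
#' replicate (a Cox-based scorer is refit inside the resample), and
#' returns the full-cohort point estimate with the percentile 2.5/97.5
#' interval. Replicates with no comparable pairs are discarded with a
#' warning; if more than 10% are unusable, an error is raised. Fully
#' reproducible given `seed`.
#'
#' @param data data.frame with columns `time` and `event` plus whatever
#'   `scorer` needs.
#' @param scorer Function mapping such a data.frame to per-patient risk
#'   scores.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer seed for the resampling.
#' @param train_scorer Optional trainable scorer for a Harrell-style
#'   optimism correction: a function taking a training data.frame and
#'   returning a prediction function `newdata -> scores`. When supplied,
#'   the optimism `mean_b [c(fit_b, resample_b) - c(fit_b, full data)]`
#'   is subtracted from the apparent estimate and reported as
#'   `estimate_corrected` (the CI stays percentile).
#' @return Object of class `cindex_result`: list with `estimate`,
#'   `ci_low`, `ci_high`, `n_comparable_pairs`, `n_boot`, `seed`,
#'   `replicates`, and (with `train_scorer`) `optimism` and
#'   `estimate_corrected`.
#' @export
bootstrap_c <- function(data, scorer, n_boot = 1000L, seed = 1L,
                        train_scorer = NULL) {
  res <- .bootstrap_c_multi(data, list(s = scorer), n_boot, seed)
  ci <- stats::quantile(res$replicates[, 1], c(0.025, 0.975), names = FALSE)
  out <- list(estimate = res$estimates[[1]]$c,
              ci_low = ci[1], ci_high = ci[2],
              n_comparable_pairs = res$estimates[[1]]$n_comparable_pairs,
              n_boot = n_boot, seed = seed,
              replicates = res$replicates[, 1])
  if (!is.null(train_scorer)) {
    n <- nrow(data)
    idx <- with_seed(seed,
      matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n))
    opt <- vapply(seq_len(n_boot), function(b) {
      db <- data[idx[, b], , drop = FALSE]
      pred <- train_scorer(db)
      tryCatch(
        harrell_c(db$time, db$event, pred(db))$c -
          harrell_c(data$time, data$event, pred(data))$c,
        error = function(e) NA_real_)
    }, 0)
    opt <- opt[!is.na(opt)]
    out$optimism <- mean(opt)
    out$estimate_corrected <- out$estimate - out$optimism
  }
  structure(out, class = "cindex_result")
}

#' @export
print.cindex_result <- function(x, ...) {
  cat(sprintf("Harrell's c = %.3f (95%% CI %.3f-%.3f; %d bootstrap replicates, seed %d)\n",
              x$estimate, x$ci_low, x$ci_high, x$n_boot, as.integer(x$seed)))
  invisible(x)
}

#' Merge event-sparse low groups
#'
#' While the lowest grade category has fewer than `min_events` observed
#' events it is merged into the next category upward (as done when no
#' metastases occur in the lowest groups, producing a combined "1 & 2"
#' reference). The merged lowest group becomes the Cox reference.
#'
#' @param group_labels Integer categories 1-5.
#' @param events Logical event indicators, same length.
#' @param min_events Minimum events required in the lowest group
#'   (default 1).
#' @return List with `labels` (new consecutive integer labels),
#'   `group_names` (e.g. `"1 & 2"`, `"3"`, ...), and `map` (named vector
#'   original label -> new label).
#' @export
merge_sparse_groups <- function(group_labels, events, min_events = 1L) {
  if (anyNA(group_labels) || any(group_labels != as.integer(group_labels)) ||
      any(group_labels < 1 | group_labels > 5))
    stop("group_labels must be integers in 1..5", call. = FALSE)
  if (length(events) != length(group_labels))
    stop("events must match group_labels in length", call. = FALSE)
  events <- as.logical(events)
  if (sum(events) < min_events)
    stop("all groups have fewer than min_events events even after merging",
         call. = FALSE)
  sets <- lapply(sort(unique(as.integer(group_labels))), identity)
  ev_in <- function(set) sum(events[group_labels %in% set])
  # merge upward while the reference-to-be lacks events, but never merge
  # away the last comparison group
  while (length(sets) > 2 && ev_in(sets[[1]]) < min_events) {
    sets[[2]] <- c(sets[[1]], sets[[2]])
    sets <- sets[-1]
  }
  map <- integer(0)
  for (j in seq_along(sets)) map[as.character(sets[[j]])] <- j
  list(labels = unname(map[as.character(group_labels)]),
       group_names = vapply(sets, function(s)
         paste(sort(s), collapse = " & "), ""),
       map = map)
}

#' Median imputation
#'
#' Replaces missing entries by the median of the non-missing entries,
#' leaving observed values unchanged (used for missing PSA).
#'
#' @param values Numeric vector, possibly with `NA`s.
#' @return The completed vector.
#' @export
median_impute <- function(values) {
  if (all(is.na(values)))
    stop("median_impute: all values missing", call. = FALSE)
  values[is.na(values)] <- stats::median(values, na.rm = TRUE)
  values
}
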