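#' @title Survival stratification machinery
#' @description
#' Median stratification, Kaplan-Meier product-limit estimation, the
#' log-rank test and Cox proportional-hazards regression (Breslow partial
#' likelihood, Newton-Raphson), written from first principles so every step
#' of the outcome analysis is explicit and testable.
#' @name survival_module
NULL

#' Stratify values at their median
#'
#' Values at or below the median go to the `low` group (exact-median ties
#' are assigned low), the rest to `high`. Used to split cohorts by stromal
#' content or enrichment scores.
#'
#' @param values Numeric vector.
#' @return Factor with levels `low`, `high`.
#' @export
stratify_by_median <- function(values) {
  med <- stats::median(values)
  if (all(values == med)) warning("all values equal the median; single group")
  factor(ifelse(values <= med, "low", "high"), levels = c("low", "high"))
}

check_surv <- function(time, event) {
  if (length(time) == 0) stop("empty survival table")
  if (any(time <= 0)) stop("times must be positive")
  if (!all(event %in% c(0, 1))) stop("event flags must be 0/1")
}

#' Kaplan-Meier product-limit estimator
#'
#' `S(t) = prod over event times t_i <= t of (1 - d_i / n_i)`; `S(0) = 1`,
#' right-continuous and non-increasing.
#'
#' @param time Positive follow-up times.
#' @param event 1 = event observed, 0 = censored.
#' @return Data frame of class `km_fit`: `time` (distinct event times),
#'   `n_risk`, `n_event`, `surv`.
#' @export
km_estimator <- function(time, event) {
  check_surv(time, event)
  tt <- sort(unique(time[event == 1]))
  n_risk <- vapply(tt, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(tt, function(t) sum(time == t & event == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(data.frame(time = tt, n_risk = n_risk, n_event = n_event,
                       surv = surv),
            class = c("km_fit", "data.frame"))
}

#' Evaluate a Kaplan-Meier curve
#'
#' @param fit A [km_estimator()] result.
#' @param t Times at which to evaluate the step function.
#' @return `S(t)`, right-continuous.
#' @export
km_surv <- function(fit, t) {
  vapply(t, function(ti) {
    i <- sum(fit$time <= ti)
    if (i == 0) 1 else fit$surv[i]
  }, numeric(1))
}

#' Log-rank test
#'
#' Observed-minus-expected statistic over the pooled distinct event times
#' with the standard hypergeometric variance (ties included); chi-square
#' with k - 1 degrees of freedom for k groups.
#'
#' @param time,event As in [km_estimator()].
#' @param group Group labels (2 or more non-empty groups).
#' @return List: `statistic`, `df`, `p_value`, `observed`, `expected` per
#'   group.
#' @export
logrank_test <- function(time, event, group) {
  check_surv(time, event)
  group <- factor(group)
  if (any(table(group) == 0) || nlevels(group) < 2) {
    stop("need at least two non-empty groups")
  }
  k <- nlevels(group)
  tt <- sort(unique(time[event == 1]))
  G <- stats::model.matrix(~ group - 1)  # n x k indicators
  O <- as.vector(tapply(event, group, sum))
  E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in tt) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    d_t <- sum(time == t & event == 1)
    n_gt <- colSums(G[at_risk, , drop = FALSE])
    E <- E + d_t * n_gt / n_t
    if (n_t > 1) {
      f <- d_t * (n_t - d_t) / (n_t - 1)
      V <- V + f * (diag(n_gt * n_t, k) - outer(n_gt, n_gt)) / n_t^2
    }
  }
  i <- seq_len(k - 1)
  omE <- (O - E)[i]
  stat <- drop(omE %*% solve(V[i, i, drop = FALSE], omE))
  list(statistic = stat, df = k - 1,
       p_value = stats::pchisq(stat, k - 1, lower.tail = FALSE),
       observed = O, expected = E)
}

# Breslow partial-likelihood value, gradient and Hessian at beta.
# X sorted by decreasing time together with time/event.
cox_quantities <- function(beta, time, event, X) {
  n <- nrow(X); p <- ncol(X)
  lp <- drop(X %*% beta)
  w <- exp(lp)
  S0 <- cumsum(w)
  S1 <- apply(X * w, 2, cumsum)
  S1 <- matrix(S1, nrow = n)
  # unique event times with their last index in the risk-ordered data
  ev <- which(event == 1)
  d_time <- time[ev]
  ut <- unique(d_time)
  loglik <- sum(lp[ev])
  grad <- colSums(X[ev, , drop = FALSE])
  H <- matrix(0, p, p)
  for (t in ut) {
    r <- max(which(time >= t))  # risk set = first r rows (sorted desc)
    d <- sum(d_time == t)
    s0 <- S0[r]
    s1 <- S1[r, ]
    rows <- seq_len(r)
    S2 <- crossprod(X[rows, , drop = FALSE] * sqrt(w[rows]))
    loglik <- loglik - d * log(s0)
    grad <- grad - d * s1 / s0
    H <- H - d * (S2 / s0 - tcrossprod(s1 / s0))
  }
  list(loglik = loglik, grad = grad, hessian = H)
}

#' Cox proportional-hazards regression
#'
#' Newton-Raphson maximization of the Breslow partial likelihood (ties
#' handled by the Breslow approximation). Standard errors come from the
#' inverse observed information; confidence intervals are Wald
#' `exp(beta +/- 1.96 SE)`.
#'
#' @param time,event As in [km_estimator()]; at least one event required.
#' @param covariates Data frame of covariates. Factors are expanded with
#'   `stats::model.matrix()` (first level = reference).
#' @param max_iter,tol Newton-Raphson controls.
#' @return List of class `cox_fit`: `coef` (log-HR), `se`, `hr`, `ci_lower`,
#'   `ci_upper`, `z`, `p_value`, `loglik`, `iter`, `converged`.
#' @export
cox_fit <- function(time, event, covariates, max_iter = 25, tol = 1e-9) {
  check_surv(time, event)
  if (sum(event) < 1) stop("need at least one event")
  covariates <- as.data.frame(covariates)
  X <- stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
  if (any(apply(X, 2, stats::sd) == 0)) stop("constant covariate column")
  ord <- order(-time, -event)
  X <- X[ord, , drop = FALSE]
  time_s <- time[ord]; event_s <- event[ord]
  p <- ncol(X)
  beta <- rep(0, p)
  q <- cox_quantities(beta, time_s, event_s, X)
  converged <- FALSE; iter <- 0
  for (iter in seq_len(max_iter)) {
    step <- solve(q$hessian, -q$grad)
    # monotone ascent with step halving
    for (half in 0:20) {
      beta_new <- beta + step / 2^half
      q_new <- cox_quantities(beta_new, time_s, event_s, X)
      if (is.finite(q_new$loglik) && q_new$loglik >= q$loglik - 1e-12) break
    }
    delta <- abs(q_new$loglik - q$loglik)
    beta <- beta_new; q <- q_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop("Cox Newton-Raphson did not converge after ", max_iter,
         " iterations (|grad| = ", format(max(abs(q$grad))),
         "); possible separation or degenerate design")
  }
  if (any(abs(beta) > 15)) warning("extreme coefficient; possible complete separation")
  info <- -q$hessian
  se <- sqrt(diag(solve(info)))
  z <- beta / se
  structure(list(coef = stats::setNames(beta, colnames(X)), se = se,
                 hr = exp(beta),
                 ci_lower = exp(beta - 1.96 * se),
                 ci_upper = exp(beta + 1.96 * se),
                 z = z, p_value = 2 * stats::pnorm(-abs(z)),
                 loglik = q$loglik, iter = iter, converged = converged),
            class = "cox_fit")
}

#' Cox score test at beta = 0
#'
#' `U(0)' I(0)^-1 U(0)`; for a single binary covariate without tied event
#' times this equals the log-rank chi-square.
#'
#' @inheritParams cox_fit
#' @return List: `statistic`, `df`, `p_value`.
#' @export
cox_score_test <- function(time, event, covariates) {
  check_surv(time, event)
  covariates <- as.data.frame(covariates)
  X <- stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
  ord <- order(-time, -event)
  q <- cox_quantities(rep(0, ncol(X)), time[ord], event[ord],
                      X[ord, , drop = FALSE])
  stat <- drop(q$grad %*% solve(-q$hessian, q$grad))
  list(statistic = stat, df = ncol(X),
       p_value = stats::pchisq(stat, ncol(X), lower.tail = FALSE))
}
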