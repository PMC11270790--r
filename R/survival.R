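#' Kaplan-Meier product-limit estimator
#'
#' Estimates the survival function S(t) = prod over event times t_i <= t of
#' (1 - d_i / n_i), where d_i is the number of events and n_i the number at
#' risk at t_i. Censored records leave the risk set without stepping the
#' curve. Records with time 0 are allowed (at risk only instantaneously).
#'
#' @param time numeric vector of follow-up times (months), finite, >= 0.
#' @param event 0/1 (or logical) event indicators, 1 = event occurred.
#' @return An object of class `km_curve`: `time` (distinct event times),
#'   `surv` (S at each event time), `n_risk`, `n_event`, and `n` (records).
#' @examples
#' km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
#' survival_at(km, 2)   # (3/4)(2/3) = 0.5
#' @export
km_estimate <- function(time, event) {
  time <- as.numeric(time)
  event <- as.integer(as.logical(event))
  if (!length(time)) stop("at least one record is required", call. = FALSE)
  if (length(event) != length(time))
    stop("'time' and 'event' lengths differ", call. = FALSE)
  if (anyNA(time) || any(!is.finite(time)) || any(time < 0))
    stop("times must be finite and non-negative", call. = FALSE)
  if (anyNA(event)) stop("event indicators must be 0/1", call. = FALSE)

  etimes <- sort(unique(time[event == 1L]))
  n_risk <- vapply(etimes, function(t) sum(time >= t), numeric(1L))
  n_event <- vapply(etimes, function(t) sum(time == t & event == 1L),
                    numeric(1L))
  surv <- cumprod(1 - n_event / n_risk)
  structure(list(time = etimes, surv = surv, n_risk = n_risk,
                 n_event = n_event, n = length(time)),
            class = "km_curve")
}

#' @rdname km_estimate
#' @param curve a `km_curve`.
#' @param t time(s) at which to evaluate the right-continuous step function.
#' @return `survival_at()` returns the estimated survival probability at
#'   each `t` (1 before the first event time).
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  vapply(as.numeric(t), function(tt) {
    k <- sum(curve$time <= tt)
    if (k == 0L) 1 else curve$surv[k]
  }, numeric(1L))
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d records, %d event times\n",
              x$n, length(x$time)))
  if (length(x$time)) {
    show <- utils::head(data.frame(time = x$time, n_risk = x$n_risk,
                                   n_event = x$n_event,
                                   surv = round(x$surv, 4)), 10L)
    print(show, row.names = FALSE)
    if (length(x$time) > 10L) cat("  ...\n")
  }
  invisible(x)
}

#' Two-group log-rank test
#'
#' The standard observed-minus-expected test over the shared distinct event
#' times, with hypergeometric variance at each time:
#' E_j = d_j n_{1j} / n_j and
#' V_j = d_j (n_{1j}/n_j) (1 - n_{1j}/n_j) (n_j - d_j) / (n_j - 1).
#' The statistic (O - E)^2 / V is referred to a chi-squared distribution
#' with one degree of freedom.
#'
#' @param time1,event1 follow-up times and indicators for group 1.
#' @param time2,event2 follow-up times and indicators for group 2.
#' @return A list with `chisq`, `p`, `df` (= 1), and the totals `observed`,
#'   `expected` (group 1) over the shared event times.
#' @export
logrank <- function(time1, event1, time2, event2) {
  if (!length(time1) || !length(time2))
    stop("each group needs at least one record", call. = FALSE)
  time <- c(time1, time2)
  event <- as.integer(as.logical(c(event1, event2)))
  grp1 <- c(rep(TRUE, length(time1)), rep(FALSE, length(time2)))
  if (!any(event == 1L))
    stop("the log-rank test is undefined with zero events", call. = FALSE)

  etimes <- sort(unique(time[event == 1L]))
  O <- 0; E <- 0; V <- 0
  for (t in etimes) {
    at_risk <- time >= t
    nj <- sum(at_risk)
    n1j <- sum(at_risk & grp1)
    dj <- sum(time == t & event == 1L)
    d1j <- sum(time == t & event == 1L & grp1)
    O <- O + d1j
    E <- E + dj * n1j / nj
    if (nj > 1L)
      V <- V + dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1)
  }
  chisq <- if (V > 0) (O - E)^2 / V else 0
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       df = 1L, observed = O, expected = E)
}

# Breslow / Efron partial log-likelihood, score and information for a Cox
# model. X: n x p matrix, sorted jointly with time/event by increasing time.
# Works over distinct event times; risk sets are suffixes of the sorted
# order so sums are cumulative from the largest time down.
.cox_loglik <- function(beta, X, time, event, ties = "breslow") {
  n <- nrow(X); p <- ncol(X)
  lp <- drop(X %*% beta)
  w <- exp(lp)
  wX <- X * w
  # cumulative (from the end) risk-set sums
  rs_w <- rev(cumsum(rev(w)))
  rs_wX <- apply(wX, 2L, function(col) rev(cumsum(rev(col))))
  rs_wX <- matrix(rs_wX, n, p)
  rs_wXX <- array(0, c(n, p, p))
  for (a in seq_len(p)) for (b in a:p) {
    cs <- rev(cumsum(rev(w * X[, a] * X[, b])))
    rs_wXX[, a, b] <- cs
    rs_wXX[, b, a] <- cs
  }

  ll <- 0
  score <- numeric(p)
  info <- matrix(0, p, p)
  i <- 1L
  while (i <= n) {
    t <- time[i]
    j <- i
    while (j < n && time[j + 1L] == t) j <- j + 1L
    ev <- i:j
    ev <- ev[event[ev] == 1L]
    d <- length(ev)
    if (d > 0L) {
      sx <- colSums(X[ev, , drop = FALSE])
      ll <- ll + sum(lp[ev])
      S0 <- rs_w[i]
      S1 <- rs_wX[i, ]
      S2 <- rs_wXX[i, , ]
      if (p == 1L) S2 <- matrix(S2, 1L, 1L)
      if (ties == "breslow" || d == 1L) {
        ll <- ll - d * log(S0)
        score <- score + sx - d * S1 / S0
        info <- info + d * (S2 / S0 - tcrossprod(S1 / S0))
      } else {                               # Efron
        wD <- sum(w[ev])
        s1D <- colSums(wX[ev, , drop = FALSE])
        s2D <- matrix(0, p, p)
        for (k in ev) s2D <- s2D + w[k] * tcrossprod(X[k, ])
        score <- score + sx
        for (r in seq_len(d) - 1L) {
          f <- r / d
          S0r <- S0 - f * wD
          S1r <- S1 - f * s1D
          S2r <- S2 - f * s2D
          ll <- ll - log(S0r)
          score <- score - S1r / S0r
          info <- info + S2r / S0r - tcrossprod(S1r / S0r)
        }
      }
    }
    i <- j + 1L
  }
  list(loglik = ll, score = score, info = info)
}

#' Cox proportional-hazards regression
#'
#' Maximises the partial likelihood by Newton-Raphson with step-halving,
#' using Breslow's tie approximation by default (Efron available).
#' Convergence is declared when the largest score component falls below
#' `1e-8` or the log-likelihood changes by less than `1e-10`, within 100
#' iterations. Standard errors come from the inverse observed information;
#' Wald 95% confidence intervals are exp(beta +/- 1.96 SE). A monotone
#' likelihood (complete separation) is reported through `converged = FALSE`
#' and a diagnostic message rather than a silent estimate.
#'
#' @param x covariate matrix or data frame (n x p, numeric, no constant or
#'   linearly dependent columns).
#' @param time,event follow-up times (months) and 0/1 event indicators.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return An object of class `cox_fit`: `coef`, `hr`, `se`, `ci_lower`,
#'   `ci_upper`, `z`, `p`, `loglik` (at the estimate), `loglik_null`,
#'   `iterations`, `converged`, `message`, `n`, `n_event`.
#' @examples
#' coh <- simulate_cohort(cohort_spec(
#'   n = 200, seed = 3, beta_pfs = c(trt = log(2)),
#'   extra_covariates = list(trt = list(dist = "binary", p = 0.5))))
#' fit <- cox_fit(coh["trt"], coh$pfs_months, coh$pfs_event)
#' fit$hr
#' @export
cox_fit <- function(x, time, event, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  time <- as.numeric(time)
  event <- as.integer(as.logical(event))
  n <- nrow(X); p <- ncol(X)
  if (n != length(time) || n != length(event))
    stop("covariates and survival records differ in length", call. = FALSE)
  if (n <= p)
    stop("more covariates than informative records", call. = FALSE)
  if (!any(event == 1L))
    stop("at least one event is required", call. = FALSE)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0))
    stop("degenerate covariate: column(s) ",
         paste(colnames(X)[sds == 0], collapse = ", "), " are constant",
         call. = FALSE)
  if (qr(scale(X, scale = FALSE))$rank < p)
    stop("degenerate covariate: columns are linearly dependent",
         call. = FALSE)

  ord <- order(time)
  X <- X[ord, , drop = FALSE]; time <- time[ord]; event <- event[ord]

  beta <- numeric(p)
  prev <- .cox_loglik(beta, X, time, event, ties)
  ll0 <- prev$loglik
  converged <- FALSE
  msg <- "converged"
  iter <- 0L
  while (iter < 100L) {
    iter <- iter + 1L
    step <- tryCatch(solve(prev$info, prev$score), error = function(e) NULL)
    if (is.null(step)) {
      msg <- "singular information matrix"
      break
    }
    new_beta <- beta + step
    cur <- .cox_loglik(new_beta, X, time, event, ties)
    halvings <- 0L
    while (cur$loglik < prev$loglik && halvings < 30L) {
      step <- step / 2
      new_beta <- beta + step
      cur <- .cox_loglik(new_beta, X, time, event, ties)
      halvings <- halvings + 1L
    }
    delta_ll <- cur$loglik - prev$loglik
    beta <- new_beta
    prev <- cur
    if (max(abs(cur$score)) < 1e-8 || abs(delta_ll) < 1e-10) {
      converged <- TRUE
      break
    }
  }
  if (converged && max(abs(beta)) > 15) {
    converged <- FALSE
    msg <- "monotone partial likelihood (possible complete separation)"
  } else if (!converged && msg == "converged") {
    msg <- if (max(abs(beta)) > 15)
      "monotone partial likelihood (possible complete separation)"
    else "iteration limit reached"
  }

  vcov <- tryCatch(solve(prev$info), error = function(e)
    matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(vcov), 0))
  z <- beta / se
  structure(list(coef = stats::setNames(beta, colnames(X)),
                 hr = exp(beta), se = se,
                 ci_lower = exp(beta - 1.96 * se),
                 ci_upper = exp(beta + 1.96 * se),
                 z = z, p = 2 * stats::pnorm(-abs(z)),
                 loglik = prev$loglik, loglik_null = ll0,
                 iterations = iter, converged = converged, message = msg,
                 ties = ties, vcov = vcov,
                 n = n, n_event = sum(event)),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit (%s ties): n = %d, events = %d\n",
              x$ties, x$n, x$n_event))
  if (!x$converged)
    cat("  NOT CONVERGED: ", x$message, "\n", sep = "")
  tab <- data.frame(coef = round(x$coef, 4), HR = round(x$hr, 3),
                    `CI 2.5%` = round(x$ci_lower, 3),
                    `CI 97.5%` = round(x$ci_upper, 3),
                    p = format_p(x$p), check.names = FALSE)
  print(tab)
  invisible(x)
}

# p-value presentation used in report tables: 3 decimals with a <0.0001
# floor.
format_p <- function(p) {
  ifelse(p < 1e-4, "<0.0001", sprintf("%.3f", p))
}
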