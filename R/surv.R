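#' Right-censor survival data at a horizon
#'
#' Times beyond the horizon are set to the horizon with the event recoded as
#' censored; an event exactly at the horizon keeps its event status.
#'
#' @param data data.frame with \code{os_days} and \code{os_event} columns.
#' @param horizon censoring horizon in days (default 1200).
#' @return the data.frame with times/events recoded.
#' @export
applyCensorHorizon <- function(data, horizon = 1200) {
  stopifnot(horizon > 0)
  if (any(data$os_days < 0)) stop("negative survival time")
  over <- data$os_days > horizon
  data$os_days[over] <- horizon
  if (is.integer(data$os_event)) data$os_event[over] <- 0L
  else data$os_event[over] <- 0
  data
}

#' Kaplan-Meier curves and log-rank test across strata
#'
#' Product-limit estimates per stratum and the standard log-rank chi-square
#' statistic across strata.
#'
#' @param data data.frame with \code{os_days}, \code{os_event}.
#' @param strata vector of stratum labels, one per row of \code{data}.
#' @return list: \code{fit} (a \code{survfit} object), \code{chisq},
#'   \code{df}, \code{p}.
#' @export
kmLogrank <- function(data, strata) {
  strata <- factor(strata)
  if (nlevels(strata) < 2) stop("need >= 2 strata")
  if (any(table(strata) == 0)) stop("empty stratum")
  df <- data.frame(time = data$os_days, event = data$os_event,
                   stratum = strata)
  fit <- survival::survfit(survival::Surv(time, event) ~ stratum, data = df)
  sd <- survival::survdiff(survival::Surv(time, event) ~ stratum, data = df)
  df_chi <- length(sd$n) - 1
  list(fit = fit, chisq = unname(sd$chisq), df = df_chi,
       p = stats::pchisq(sd$chisq, df_chi, lower.tail = FALSE))
}

# Efron-tie Cox partial log-likelihood with analytic score and information
coxPartial <- function(beta, time, event, X) {
  n <- length(time)
  p <- ncol(X)
  eta <- drop(X %*% beta)
  w <- exp(eta)
  ord <- order(time, decreasing = TRUE)
  tS <- time[ord]
  wS <- w[ord]
  XS <- X[ord, , drop = FALSE]
  cw <- cumsum(wS)
  cwx <- apply(wS * XS, 2, cumsum)
  if (p == 1) cwx <- matrix(cwx, ncol = 1)
  # cumulative weighted second moments, upper-triangle columns
  pair_i <- rep(seq_len(p), times = seq_len(p))
  pair_j <- unlist(lapply(seq_len(p), seq_len))
  cwxx <- apply(wS * XS[, pair_i, drop = FALSE] * XS[, pair_j, drop = FALSE],
                2, cumsum)
  if (length(pair_i) == 1) cwxx <- matrix(cwxx, ncol = 1)
  getS2 <- function(row) {
    m <- matrix(0, p, p)
    m[cbind(pair_i, pair_j)] <- cwxx[row, ]
    m[cbind(pair_j, pair_i)] <- cwxx[row, ]
    m
  }
  dtimes <- sort(unique(time[event == 1]))
  ll <- 0
  U <- numeric(p)
  I <- matrix(0, p, p)
  for (t in dtimes) {
    at_risk_last <- sum(tS >= t)       # positions 1..at_risk_last in ord
    D <- which(time == t & event == 1)
    dj <- length(D)
    S0 <- cw[at_risk_last]
    S1 <- cwx[at_risk_last, ]
    S2 <- getS2(at_risk_last)
    s0 <- sum(w[D])
    s1 <- colSums(w[D] * X[D, , drop = FALSE])
    s2 <- crossprod(sqrt(w[D]) * X[D, , drop = FALSE])
    ll <- ll + sum(eta[D])
    U <- U + colSums(X[D, , drop = FALSE])
    for (l in seq_len(dj) - 1) {
      f <- l / dj
      Z0 <- S0 - f * s0
      Z1 <- S1 - f * s1
      Z2 <- S2 - f * s2
      ll <- ll - log(Z0)
      U <- U - Z1 / Z0
      I <- I + Z2 / Z0 - tcrossprod(Z1 / Z0)
    }
  }
  list(loglik = ll, score = U, info = I)
}

# penalized partial log-likelihood: ll + 0.5 * logdet(information)
coxPenLik <- function(beta, time, event, X) {
  cp <- coxPartial(beta, time, event, X)
  dt <- determinant(cp$info, logarithm = TRUE)
  if (dt$sign <= 0) return(-1e10)
  cp$loglik + 0.5 * as.numeric(dt$modulus)
}

coxFirthMax <- function(time, event, X, fixed_idx = NULL, fixed_val = NULL,
                        start = NULL) {
  p <- ncol(X)
  free <- setdiff(seq_len(p), fixed_idx)
  assemble <- function(par) {
    b <- numeric(p)
    b[free] <- par
    if (length(fixed_idx)) b[fixed_idx] <- fixed_val
    b
  }
  if (!length(free)) {
    b <- assemble(numeric(0))
    return(list(beta = b, value = coxPenLik(b, time, event, X)))
  }
  par0 <- if (is.null(start)) numeric(length(free)) else start[free]
  opt <- stats::optim(par0, function(par)
    -coxPenLik(assemble(par), time, event, X),
    method = "BFGS", control = list(maxit = 500, reltol = 1e-10))
  list(beta = assemble(opt$par), value = -opt$value)
}

#' Cox proportional-hazards fit with optional Firth-type penalization
#'
#' \code{method = "standard"} fits the usual partial likelihood via
#' \code{survival::coxph} (Efron tie handling, Wald confidence intervals).
#' \code{method = "firth"} maximizes the penalized partial likelihood
#' \eqn{\ell(\beta) + \frac{1}{2}\log\det I(\beta)} (Efron ties), which
#' yields finite estimates under monotone likelihood / perfect separation;
#' its confidence intervals are profile penalized-likelihood intervals and
#' p-values come from the penalized likelihood-ratio test. A monotone
#' likelihood under the standard method is an error advising
#' \code{method = "firth"}.
#'
#' @param data data.frame with \code{os_days}, \code{os_event} and the
#'   covariate columns.
#' @param covariates character vector of covariate column names (factors are
#'   expanded to treatment contrasts; encode ordinal stage numerically
#'   beforehand if desired).
#' @param method \code{"standard"} or \code{"firth"}.
#' @param conf level for confidence intervals (default 0.95).
#' @return data.frame: term, estimate (log hazard ratio), hr, lower, upper,
#'   p, method.
#' @export
coxFit <- function(data, covariates, method = c("standard", "firth"),
                   conf = 0.95) {
  method <- match.arg(method)
  mf <- data[covariates]
  X <- stats::model.matrix(~ ., mf)[, -1, drop = FALSE]
  keep_const <- apply(X, 2, function(v) stats::sd(v) > 0)
  if (!all(keep_const))
    stop("constant covariate(s): ",
         paste(colnames(X)[!keep_const], collapse = ", "))
  time <- data$os_days
  event <- data$os_event
  if (sum(event) < ncol(X))
    stop("fewer events than covariates")
  if (method == "standard") {
    fit <- survival::coxph(
      survival::Surv(time, event) ~ X, ties = "efron")
    se <- sqrt(diag(stats::vcov(fit)))
    if (any(!is.finite(se)) || any(se > 50) || any(abs(stats::coef(fit)) > 15))
      stop("monotone likelihood (a covariate separates events); ",
           "refit with method = 'firth'")
    zq <- stats::qnorm(1 - (1 - conf) / 2)
    est <- unname(stats::coef(fit))
    return(data.frame(
      term = colnames(X), estimate = est, hr = exp(est),
      lower = exp(est - zq * se), upper = exp(est + zq * se),
      p = 2 * stats::pnorm(-abs(est / se)), method = "standard",
      stringsAsFactors = FALSE, row.names = NULL))
  }
  full <- coxFirthMax(time, event, X)
  bhat <- full$beta
  plmax <- full$value
  info <- coxPartial(bhat, time, event, X)$info
  se <- sqrt(diag(solve(info)))
  drop_chi <- stats::qchisq(conf, 1) / 2
  p <- ncol(X)
  lower <- upper <- pval <- numeric(p)
  prof <- function(r, val)
    coxFirthMax(time, event, X, fixed_idx = r, fixed_val = val,
                start = bhat)$value
  for (r in seq_len(p)) {
    f <- function(val) prof(r, val) - (plmax - drop_chi)
    bound <- function(dir) {
      step <- max(se[r], 0.25)
      lo <- bhat[r]
      hi <- bhat[r] + dir * step
      for (iter in 1:40) {
        if (f(hi) < 0) break
        lo <- hi
        hi <- hi + dir * step
        step <- step * 1.6
      }
      if (f(hi) >= 0) return(dir * Inf)
      stats::uniroot(f, sort(c(lo, hi)), tol = 1e-5)$root
    }
    lower[r] <- bound(-1)
    upper[r] <- bound(+1)
    pval[r] <- stats::pchisq(2 * (plmax - prof(r, 0)), 1, lower.tail = FALSE)
  }
  data.frame(term = colnames(X), estimate = bhat, hr = exp(bhat),
             lower = exp(lower), upper = exp(upper), p = pval,
             method = "firth", stringsAsFactors = FALSE, row.names = NULL)
}
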