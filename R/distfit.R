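#' Log-logistic distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the log-logistic distribution, parameterized on the log scale: if
#' `X` is log-logistic with location `mu` and scale `s`, then `log(X)` is
#' logistic with the same location and scale. (Equivalently, the common
#' scale/shape parameterization has scale `exp(mu)` and shape `1/s`.)
#'
#' @param x,q,p,n usual distribution-function arguments.
#' @param mu location of `log(X)`.
#' @param s positive scale of `log(X)`.
#' @param log,lower.tail usual flags.
#' @return numeric vector.
#' @name loglogistic
NULL

#' @rdname loglogistic
#' @export
dloglogis <- function(x, mu = 0, s = 1, log = FALSE) {
  out <- rep(if (log) -Inf else 0, length(x))
  pos <- x > 0
  lx <- base::log(x[pos])
  ld <- stats::dlogis(lx, mu, s, log = TRUE) - lx
  out[pos] <- if (log) ld else exp(ld)
  out
}

#' @rdname loglogistic
#' @export
ploglogis <- function(q, mu = 0, s = 1, lower.tail = TRUE) {
  out <- rep(if (lower.tail) 0 else 1, length(q))
  pos <- q > 0
  out[pos] <- stats::plogis(base::log(q[pos]), mu, s, lower.tail = lower.tail)
  out
}

#' @rdname loglogistic
#' @export
qloglogis <- function(p, mu = 0, s = 1) {
  exp(stats::qlogis(p, mu, s))
}

#' @rdname loglogistic
#' @export
rloglogis <- function(n, mu = 0, s = 1) {
  exp(stats::rlogis(n, mu, s))
}

fit_families <- c("lognormal", "loglogistic", "gamma", "normal")
log_domain_families <- c("lognormal", "loglogistic")

family_npar <- function(family) 2L   # all supported families have 2 parameters

family_density <- function(family) {
  switch(family,
    lognormal = function(x, par) stats::dlnorm(x, par[1], par[2]),
    loglogistic = function(x, par) dloglogis(x, par[1], par[2]),
    gamma = function(x, par) stats::dgamma(x, shape = par[1], rate = par[2]),
    normal = function(x, par) stats::dnorm(x, par[1], par[2]))
}

family_cdf <- function(family) {
  switch(family,
    lognormal = function(q, par) stats::plnorm(q, par[1], par[2]),
    loglogistic = function(q, par) ploglogis(q, par[1], par[2]),
    gamma = function(q, par) stats::pgamma(q, shape = par[1], rate = par[2]),
    normal = function(q, par) stats::pnorm(q, par[1], par[2]))
}

family_quantile <- function(family) {
  switch(family,
    lognormal = function(p, par) stats::qlnorm(p, par[1], par[2]),
    loglogistic = function(p, par) qloglogis(p, par[1], par[2]),
    gamma = function(p, par) stats::qgamma(p, shape = par[1], rate = par[2]),
    normal = function(p, par) stats::qnorm(p, par[1], par[2]))
}

# Weighted maximum-likelihood estimators per family (M-steps of the EM).
# Weights w >= 0, sum > 0. Return named parameter vector.
family_wmle <- function(family) {
  switch(family,
    lognormal = function(x, w, start = NULL) {
      lx <- log(x); sw <- sum(w)
      mu <- sum(w * lx) / sw
      sg <- sqrt(sum(w * (lx - mu)^2) / sw)
      c(meanlog = mu, sdlog = max(sg, 1e-8))
    },
    normal = function(x, w, start = NULL) {
      sw <- sum(w)
      mu <- sum(w * x) / sw
      sg <- sqrt(sum(w * (x - mu)^2) / sw)
      c(mean = mu, sd = max(sg, 1e-8))
    },
    loglogistic = function(x, w, start = NULL) {
      lx <- log(x)
      if (is.null(start)) {
        sw <- sum(w)
        mu0 <- sum(w * lx) / sw
        s0 <- sqrt(sum(w * (lx - mu0)^2) / sw) * sqrt(3) / pi
        start <- c(mu0, max(s0, 1e-6))
      }
      nll <- function(par) {
        s <- exp(par[2])
        -sum(w * (stats::dlogis(lx, par[1], s, log = TRUE) - lx))
      }
      o <- stats::optim(c(start[1], log(start[2])), nll, method = "Nelder-Mead")
      c(mu = o$par[1], s = exp(o$par[2]))
    },
    gamma = function(x, w, start = NULL) {
      sw <- sum(w)
      mx <- sum(w * x) / sw
      vx <- sum(w * (x - mx)^2) / sw
      if (is.null(start)) start <- c(max(mx^2 / max(vx, 1e-12), 1e-3),
                                     max(mx / max(vx, 1e-12), 1e-8))
      nll <- function(par) {
        sh <- exp(par[1]); rt <- exp(par[2])
        -sum(w * stats::dgamma(x, shape = sh, rate = rt, log = TRUE))
      }
      o <- stats::optim(log(start), nll, method = "Nelder-Mead")
      c(shape = exp(o$par[1]), rate = exp(o$par[2]))
    })
}

new_fit_result <- function(components, loglik, n, converged,
                           n_restarts_used = 0L, degenerate = FALSE,
                           leaderboard = NULL) {
  k <- sum(vapply(components, function(co) length(co$parameters), integer(1))) +
    (length(components) - 1L)          # free mixture weights
  structure(list(components = components, loglik = loglik, n = n,
                 criterion = k * log(n) - 2 * loglik,   # BIC
                 n_parameters = k, converged = converged,
                 n_restarts_used = n_restarts_used, degenerate = degenerate,
                 leaderboard = leaderboard),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", if (!x$converged) "(NOT converged)", "\n")
  for (co in x$components) {
    cat(sprintf("  %-12s w = %.4f  (%s)\n", co$family, co$weight,
                paste(sprintf("%s = %.4g", names(co$parameters),
                              co$parameters), collapse = ", ")))
  }
  cat(sprintf("  loglik = %.2f, BIC = %.2f, n = %d\n",
              x$loglik, x$criterion, x$n))
  invisible(x)
}

fit_density <- function(fit, x) {
  dens <- 0
  for (co in fit$components) {
    dens <- dens + co$weight * family_density(co$family)(x, co$parameters)
  }
  dens
}

fit_cdf <- function(fit, q) {
  p <- 0
  for (co in fit$components) {
    p <- p + co$weight * family_cdf(co$family)(q, co$parameters)
  }
  p
}

is_log_domain <- function(fit) {
  all(vapply(fit$components, function(co) co$family %in% log_domain_families,
             logical(1)))
}

check_fit_sample <- function(x, families, min_n = 50L) {
  x <- as.numeric(x)
  if (length(x) < min_n) {
    stop(sprintf("need at least %d observations", min_n), call. = FALSE)
  }
  if (any(!is.finite(x))) stop("sample must be finite", call. = FALSE)
  if (any(families %in% c(log_domain_families, "gamma")) && any(x <= 0)) {
    stop("log-domain / positive-support families need strictly positive data",
         call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("constant sample: zero variance, no maximum-likelihood fit exists",
         call. = FALSE)
  }
  x
}

#' Maximum-likelihood fit of a single distribution family
#'
#' Fits one of `lognormal`, `loglogistic`, `gamma`, `normal` by maximum
#' likelihood. Lognormal and normal have closed-form MLEs; the gamma fit
#' uses \pkg{fitdistrplus}; the log-logistic is fit as a logistic law on
#' the log scale by direct likelihood optimization. Deterministic given
#' the sample.
#'
#' @param sample numeric vector (`n >= 50`; strictly positive for
#'   log-domain and gamma families).
#' @param family one of `"lognormal"`, `"loglogistic"`, `"gamma"`,
#'   `"normal"`.
#' @return a `fit_result` with a single component of weight 1.
#' @export
fit_single <- function(sample, family = fit_families) {
  family <- match.arg(family)
  x <- check_fit_sample(sample, family)
  n <- length(x)
  converged <- TRUE
  par <- switch(family,
    lognormal = family_wmle("lognormal")(x, rep(1, n)),
    normal = family_wmle("normal")(x, rep(1, n)),
    loglogistic = family_wmle("loglogistic")(x, rep(1, n)),
    gamma = {
      fd <- tryCatch(fitdistrplus::fitdist(x, "gamma"), error = function(e) NULL)
      if (is.null(fd)) {
        converged <- FALSE
        family_wmle("gamma")(x, rep(1, n))
      } else {
        c(shape = unname(fd$estimate["shape"]), rate = unname(fd$estimate["rate"]))
      }
    })
  ll <- sum(log(family_density(family)(x, par)))
  if (!is.finite(ll)) converged <- FALSE
  new_fit_result(list(list(family = family, parameters = par, weight = 1)),
                 loglik = ll, n = n, converged = converged)
}

#' Two-component mixture fit by EM with random restarts
#'
#' Fits a two-component mixture (any pair from `lognormal`,
#' `loglogistic`, `gamma`, `normal`) by expectation-maximization with
#' weighted maximum-likelihood M-steps, using `restarts` random
#' initializations (each splits the sample at a random quantile and
#' initializes each component from its own side). The best log-likelihood
#' over restarts is returned; components are sorted by descending weight.
#' Convergence: relative log-likelihood change below `tol` or `max_iter`
#' iterations. Fully deterministic given `sample`, `families`, `restarts`
#' and `seed`.
#'
#' A fit in which a component's weight collapses below 0.01 is flagged
#' `degenerate` (still a valid maximum); if no restart converges the
#' result carries `converged = FALSE`.
#'
#' @param sample numeric vector (`n >= 50`).
#' @param families character vector of length 2.
#' @param restarts number of random initializations (default 10).
#' @param seed integer seed controlling the restarts.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap.
#' @return a `fit_result` with two components.
#' @export
fit_mixture <- function(sample, families = c("lognormal", "lognormal"),
                        restarts = 10, seed = 1, tol = 1e-8,
                        max_iter = 500) {
  if (length(families) != 2L || !all(families %in% fit_families)) {
    stop("families must be a pair from: ",
         paste(fit_families, collapse = ", "), call. = FALSE)
  }
  x <- check_fit_sample(sample, families)
  n <- length(x)
  dens1 <- family_density(families[1]); dens2 <- family_density(families[2])
  wmle1 <- family_wmle(families[1]); wmle2 <- family_wmle(families[2])
  best <- NULL
  n_used <- 0L
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      n_used <- n_used + 1L
      thr <- stats::quantile(x, stats::runif(1, 0.05, 0.95))
      grp <- x > thr
      if (sum(grp) < 5L || sum(!grp) < 5L) grp <- x > stats::median(x)
      par1 <- tryCatch(wmle1(x[!grp], rep(1, sum(!grp))), error = function(e) NULL)
      par2 <- tryCatch(wmle2(x[grp], rep(1, sum(grp))), error = function(e) NULL)
      if (is.null(par1) || is.null(par2)) next
      w <- c(mean(!grp), mean(grp))
      ll_prev <- -Inf
      converged <- FALSE
      for (it in seq_len(max_iter)) {
        D <- cbind(w[1] * dens1(x, par1), w[2] * dens2(x, par2))
        rs <- rowSums(D)
        if (any(rs <= 0) || any(!is.finite(rs))) break
        ll <- sum(log(rs))
        resp <- D / rs
        w <- colMeans(resp)
        # guard against full collapse; a small floor keeps the M-step defined
        w <- pmax(w, 1e-10); w <- w / sum(w)
        par1 <- tryCatch(wmle1(x, resp[, 1], start = unname(par1)),
                         error = function(e) par1)
        par2 <- tryCatch(wmle2(x, resp[, 2], start = unname(par2)),
                         error = function(e) par2)
        if (is.finite(ll) && abs(ll - ll_prev) < tol * (abs(ll) + 1)) {
          converged <- TRUE
          ll_prev <- ll
          break
        }
        ll_prev <- ll
      }
      if (!is.finite(ll_prev)) next
      cand <- list(w = w, par1 = par1, par2 = par2, loglik = ll_prev,
                   converged = converged)
      if (is.null(best) || cand$loglik > best$loglik) best <- cand
    }
  })
  if (is.null(best)) {
    stop("all restarts failed to produce a valid mixture fit", call. = FALSE)
  }
  comps <- list(
    list(family = families[1], parameters = best$par1, weight = best$w[1]),
    list(family = families[2], parameters = best$par2, weight = best$w[2]))
  ord <- order(vapply(comps, `[[`, numeric(1), "weight"), decreasing = TRUE)
  new_fit_result(comps[ord], loglik = best$loglik, n = n,
                 converged = best$converged, n_restarts_used = n_used,
                 degenerate = min(best$w) < 0.01)
}

#' Unbiased model selection over a candidate library
#'
#' Fits every candidate (single families and two-component mixtures) and
#' returns the one minimizing an information criterion (BIC by default:
#' \eqn{k \log n - 2 \ell}). "Unbiased" here means no target family is
#' pre-specified — the winner is chosen purely by penalized likelihood over
#' a fixed library. Ties are broken in favour of fewer parameters. Failed
#' candidates are excluded (and noted in the leaderboard).
#'
#' @param sample numeric vector.
#' @param candidates list of candidates, each either a single family name
#'   or a character pair for a mixture. Default: the four singles plus
#'   `lognormal+lognormal`, `lognormal+loglogistic`, `lognormal+gamma`.
#' @param restarts,seed passed to [fit_mixture()].
#' @return the winning `fit_result`; the full leaderboard (a data.frame
#'   with model, loglik, npar, criterion) is in `$leaderboard`.
#' @export
select_best_model <- function(sample, candidates = NULL, restarts = 10,
                              seed = 1) {
  if (is.null(candidates)) {
    candidates <- c(as.list(fit_families),
                    list(c("lognormal", "lognormal"),
                         c("lognormal", "loglogistic"),
                         c("lognormal", "gamma")))
  }
  if (!length(candidates)) stop("candidate set is empty", call. = FALSE)
  fits <- list()
  rows <- list()
  for (cand in candidates) {
    label <- paste(cand, collapse = "+")
    f <- tryCatch({
      if (length(cand) == 1L) fit_single(sample, cand)
      else fit_mixture(sample, cand, restarts = restarts, seed = seed)
    }, error = function(e) NULL)
    if (is.null(f) || !is.finite(f$criterion)) {
      rows[[label]] <- data.frame(model = label, loglik = NA, npar = NA,
                                  criterion = NA, converged = FALSE)
      next
    }
    fits[[label]] <- f
    rows[[label]] <- data.frame(model = label, loglik = f$loglik,
                                npar = f$n_parameters,
                                criterion = f$criterion,
                                converged = f$converged)
  }
  if (!length(fits)) stop("every candidate failed", call. = FALSE)
  lb <- do.call(rbind, rows)
  rownames(lb) <- NULL
  ok <- !is.na(lb$criterion)
  ord <- order(lb$criterion[ok], lb$npar[ok])
  winner_label <- lb$model[ok][ord[1]]
  winner <- fits[[winner_label]]
  winner$leaderboard <- lb[order(lb$criterion, lb$npar), ]
  winner
}

resolve_reference <- function(sample, reference) {
  if (inherits(reference, "fit_result")) return(reference)
  if (is.character(reference) && length(reference) == 1L) {
    return(fit_single(sample, reference))
  }
  stop("reference must be a fit_result or a family name", call. = FALSE)
}

#' Paired theoretical/empirical quantiles (Q-Q data)
#'
#' Returns the quantile pairs underlying a Q-Q plot: the sorted sample
#' (empirical quantiles) against the reference distribution's quantiles at
#' plotting positions \eqn{p_k = (k - 1/2)/n}. When the reference is
#' log-domain (lognormal / log-logistic components) both axes are
#' log-transformed, so a perfect fit lies on the line `y = x`.
#'
#' @param sample numeric vector (`n >= 10`).
#' @param reference a `fit_result` (single or mixture) or a family name
#'   (which is then fit to the sample by [fit_single()]).
#' @return data.frame with columns `p`, `theoretical`, `empirical` (on the
#'   log scale when the reference is log-domain; attribute `"log_scale"`
#'   records which).
#' @export
qq_points <- function(sample, reference) {
  x <- sort(as.numeric(sample))
  n <- length(x)
  if (n < 10L) stop("need at least 10 observations", call. = FALSE)
  fit <- resolve_reference(sample, reference)
  p <- (seq_len(n) - 0.5) / n
  theo <- quantile_fit(fit, p)
  logd <- is_log_domain(fit)
  emp <- x
  if (logd) { theo <- log(theo); emp <- log(emp) }
  out <- data.frame(p = p, theoretical = theo, empirical = emp)
  attr(out, "log_scale") <- logd
  out
}

# Quantile function of a (possibly mixture) fit. Single components use the
# family's exact quantile; mixtures invert the CDF by monotone bisection.
quantile_fit <- function(fit, p) {
  if (length(fit$components) == 1L) {
    co <- fit$components[[1]]
    return(family_quantile(co$family)(p, co$parameters))
  }
  qs <- vapply(fit$components, function(co) {
    family_quantile(co$family)(c(1e-9, 1 - 1e-9), co$parameters)
  }, numeric(2))
  lo <- rep(min(qs[1, ]), length(p))
  hi <- rep(max(qs[2, ]), length(p))
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    below <- fit_cdf(fit, mid) < p
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
    if (max(hi - lo) < 1e-12 * max(abs(hi), 1)) break
  }
  (lo + hi) / 2
}

#' Tail-deviation diagnostics of a fitted distribution
#'
#' Quantifies the central-fit / tail-departure contrast of a fit via its
#' Q-Q residuals (empirical minus theoretical quantiles, log scale for
#' log-domain references): the mean signed residual over the outer 5% of
#' quantiles on each side, plus the RMS residual over the inner 90% as a
#' central-fit score. A heavy right tail relative to the fit yields a
#' positive `upper` statistic.
#'
#' @param sample numeric vector.
#' @param fit a `fit_result` (or family name, fit to the sample first).
#' @return list with `lower`, `upper` (mean signed tail residuals) and
#'   `central_rms`.
#' @export
tail_deviation_metric <- function(sample, fit) {
  qq <- qq_points(sample, fit)
  r <- qq$empirical - qq$theoretical
  lower <- mean(r[qq$p <= 0.05])
  upper <- mean(r[qq$p >= 0.95])
  central <- sqrt(mean(r[qq$p > 0.05 & qq$p < 0.95]^2))
  list(lower = lower, upper = upper, central_rms = central)
}
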