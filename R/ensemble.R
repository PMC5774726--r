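#' Recipe for sampling an ensemble of rate profiles
#'
#' Describes how per-codon rate constants are drawn for a population of
#' `n_templates` mRNA templates of length `d`. Rates are drawn
#' independently per site and per template from a named family unless a
#' correlation structure is requested. Because the distribution of tRNAs
#' around each transcript differs slightly, rates at a given position vary
#' from template to template — this between-template randomness is what
#' generates the population-level protein distribution.
#'
#' @param family one of `"gamma"` (params `shape`, `scale`), `"normal"`
#'   (`mean`, `sd`), `"exponential"` (`mean`), `"lognormal"` (`meanlog`,
#'   `sdlog` of the underlying normal), `"fixed"` (params `value`, or
#'   `per_site_means` alone).
#' @param params named list of family parameters (see `family`).
#' @param d codon count (`>= 2`).
#' @param n_templates ensemble size (`>= 1`).
#' @param seed integer seed; sampling is fully deterministic given the spec.
#' @param reinit_prob reinitiation probability shared by all templates
#'   (default 1: the circular template used throughout the steady-state
#'   analyses).
#' @param per_site_means optional length-`d` vector of per-site mean rates
#'   overriding the family's global mean (the family's shape/spread
#'   parameter is retained and its location rescaled per site).
#' @param slow_sites optional list of `list(site =, mean =)` overrides,
#'   e.g. a near-zero mean at one codon to model a stalling site.
#' @param correlation optional list `list(mode = "along_sites"` or
#'   `"across_templates", strength =, length_scale =)`; see
#'   [apply_spatial_correlation()].
#' @param truncation rule for non-positive draws from unbounded families:
#'   `"resample"` (rejection, the default; preserves independence and the
#'   positive support) or `"error"`.
#' @return object of class `rate_ensemble_spec`.
#' @export
rate_ensemble_spec <- function(family = c("gamma", "normal", "exponential",
                                          "lognormal", "fixed"),
                               params = list(), d, n_templates, seed,
                               reinit_prob = 1, per_site_means = NULL,
                               slow_sites = NULL, correlation = NULL,
                               truncation = c("resample", "error")) {
  family <- match.arg(family)
  truncation <- match.arg(truncation)
  if (missing(seed) || is.null(seed)) {
    stop("an integer seed is required (reproducibility is mandatory)",
         call. = FALSE)
  }
  d <- as.integer(d); n_templates <- as.integer(n_templates)
  if (is.na(d) || d < 2L) stop("d must be >= 2", call. = FALSE)
  if (is.na(n_templates) || n_templates < 1L) {
    stop("n_templates must be >= 1", call. = FALSE)
  }
  check_family_params(family, params)
  if (!is.null(per_site_means)) {
    per_site_means <- as.numeric(per_site_means)
    if (length(per_site_means) != d || any(per_site_means <= 0)) {
      stop("per_site_means must be d positive values", call. = FALSE)
    }
  }
  if (!is.null(slow_sites)) {
    if (!is.list(slow_sites) || !length(slow_sites)) {
      stop("slow_sites must be a non-empty list of list(site=, mean=)",
           call. = FALSE)
    }
    for (ss in slow_sites) {
      if (is.null(ss$site) || is.null(ss$mean) ||
          ss$site < 1 || ss$site > d || ss$mean <= 0) {
        stop("each slow site needs a site index in 1..d and a positive mean",
             call. = FALSE)
      }
    }
  }
  if (!is.null(correlation)) {
    if (is.null(correlation$mode) ||
        !correlation$mode %in% c("along_sites", "across_templates")) {
      stop("correlation$mode must be 'along_sites' or 'across_templates'",
           call. = FALSE)
    }
    if (is.null(correlation$strength)) {
      if (is.null(correlation$length_scale)) {
        stop("correlation needs strength in [0, 1) or a length_scale",
             call. = FALSE)
      }
      correlation$strength <- exp(-1 / correlation$length_scale)
    }
    if (correlation$strength < 0 || correlation$strength >= 1) {
      stop("correlation strength must lie in [0, 1)", call. = FALSE)
    }
  }
  structure(list(family = family, params = params, d = d,
                 n_templates = n_templates, seed = as.integer(seed),
                 reinit_prob = reinit_prob, per_site_means = per_site_means,
                 slow_sites = slow_sites, correlation = correlation,
                 truncation = truncation),
            class = "rate_ensemble_spec")
}

check_family_params <- function(family, params) {
  need <- switch(family,
    gamma = c("shape", "scale"),
    normal = c("mean", "sd"),
    exponential = "mean",
    lognormal = c("meanlog", "sdlog"),
    fixed = character())
  missing_p <- setdiff(need, names(params))
  if (length(missing_p)) {
    stop(sprintf("family '%s' needs parameter(s): %s", family,
                 paste(missing_p, collapse = ", ")), call. = FALSE)
  }
  if (family == "normal") {
    # reject parameter sets with substantial sub-zero mass: the
    # positive-truncated law would no longer resemble a normal
    if (stats::pnorm(0, params$mean, params$sd) > 0.4) {
      stop(paste("over half of the normal's mass lies at or below zero;",
                 "the truncated sample would not resemble the named family"),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

family_mean <- function(family, params) {
  switch(family,
    gamma = params$shape * params$scale,
    normal = params$mean,
    exponential = params$mean,
    lognormal = exp(params$meanlog + params$sdlog^2 / 2),
    fixed = params$value)
}

# Per-site family quantile functions with the site mean rescaled to m,
# keeping the family's dispersion parameter:
#   gamma: shape kept, scale = m / shape
#   normal: sd kept, mean = m
#   exponential: mean = m
#   lognormal: sdlog kept, meanlog = log(m) - sdlog^2 / 2
#   fixed: point mass at m
site_quantile_fun <- function(family, params, m) {
  switch(family,
    gamma = function(u) stats::qgamma(u, shape = params$shape,
                                      scale = m / params$shape),
    normal = function(u) stats::qnorm(u, mean = m, sd = params$sd),
    exponential = function(u) stats::qexp(u, rate = 1 / m),
    lognormal = function(u) stats::qlnorm(u, meanlog = log(m) - params$sdlog^2 / 2,
                                          sdlog = params$sdlog),
    fixed = function(u) rep(m, length(u)))
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Sample an ensemble of rate profiles
#'
#' Draws the `n_templates x d` matrix of per-codon rate constants described
#' by a [rate_ensemble_spec()]. Draws are independent across sites and
#' templates unless the spec carries a `correlation` entry, in which case
#' sampling goes through the Gaussian-copula field of
#' [apply_spatial_correlation()] (marginals preserved). Non-positive draws
#' from unbounded families are rejected and redrawn (or raise an error,
#' per the spec's truncation rule). Deterministic under the spec's seed.
#'
#' @param spec a [rate_ensemble_spec()].
#' @return object of class `rate_ensemble`: list with the rate matrix
#'   `epsilons` (`n_templates x d`), the `spec`, per-site target means
#'   `site_means`, and (when correlated) the realized lag-1 autocorrelation
#'   `lag1`.
#' @export
sample_rate_profiles <- function(spec) {
  stopifnot(inherits(spec, "rate_ensemble_spec"))
  if (!is.null(spec$correlation)) return(apply_spatial_correlation(spec))
  m <- resolve_site_means(spec)
  eps <- with_seed(spec$seed, {
    E <- matrix(0, spec$n_templates, spec$d)
    for (i in seq_len(spec$d)) {
      qf <- site_quantile_fun(spec$family, spec$params, m[i])
      x <- qf(stats::runif(spec$n_templates))
      if (spec$family == "normal") {
        bad <- which(x <= 0)
        guard <- 0L
        while (length(bad)) {                     # rejection: resample until positive
          x[bad] <- qf(stats::runif(length(bad)))
          bad <- bad[x[bad] <= 0]
          guard <- guard + 1L
          if (guard > 1000L) {
            if (spec$truncation == "error") {
              stop("non-positive draws persisted", call. = FALSE)
            }
            x[bad] <- .Machine$double.eps; bad <- integer()
          }
        }
      }
      if (spec$truncation == "error" && any(x <= 0)) {
        stop("non-positive rate drawn and truncation = 'error'", call. = FALSE)
      }
      E[, i] <- x
    }
    E
  })
  structure(list(epsilons = eps, spec = spec, site_means = m, lag1 = NA_real_),
            class = "rate_ensemble")
}

resolve_site_means <- function(spec) {
  m <- spec$per_site_means
  if (is.null(m)) {
    gm <- family_mean(spec$family, spec$params)
    if (is.null(gm)) stop("family 'fixed' needs params$value or per_site_means",
                          call. = FALSE)
    m <- rep(gm, spec$d)
  }
  for (ss in spec$slow_sites) m[ss$site] <- ss$mean
  m
}

#' Sample rate profiles with spatial or between-template correlation
#'
#' Generates the rate field through a Gaussian copula: a latent standard
#' normal AR(1) field with lag-1 autocorrelation equal to the requested
#' `strength` is transformed site-wise through each site's marginal
#' quantile function, so the marginal family and parameters are preserved
#' exactly while successive sites (`mode = "along_sites"`) or successive
#' templates at a fixed site (`mode = "across_templates"`) become
#' positively dependent. The realized lag-1 autocorrelation of the rates
#' themselves is reported in the result's `lag1` field.
#'
#' @param spec a [rate_ensemble_spec()] whose `correlation` field is set.
#' @return a `rate_ensemble` (see [sample_rate_profiles()]).
#' @export
apply_spatial_correlation <- function(spec) {
  stopifnot(inherits(spec, "rate_ensemble_spec"))
  if (is.null(spec$correlation)) {
    stop("spec has no correlation entry", call. = FALSE)
  }
  phi <- spec$correlation$strength
  along_sites <- spec$correlation$mode == "along_sites"
  m <- resolve_site_means(spec)
  n <- spec$n_templates; d <- spec$d
  eps <- with_seed(spec$seed, {
    Z <- matrix(stats::rnorm(n * d), n, d)
    if (phi > 0) {
      if (along_sites) {
        for (i in 2:d) Z[, i] <- phi * Z[, i - 1] + sqrt(1 - phi^2) * Z[, i]
      } else if (n > 1) {
        for (j in 2:n) Z[j, ] <- phi * Z[j - 1, ] + sqrt(1 - phi^2) * Z[j, ]
      }
    }
    U <- stats::pnorm(Z)
    E <- matrix(0, n, d)
    for (i in seq_len(d)) {
      qf <- site_quantile_fun(spec$family, spec$params, m[i])
      x <- qf(U[, i])
      if (any(x <= 0)) x[x <= 0] <- qf(stats::runif(sum(x <= 0)) * 0.5 + 0.5)
      E[, i] <- x
    }
    E
  })
  lag1 <- if (along_sites) {
    stats::cor(as.vector(eps[, -d]), as.vector(eps[, -1]))
  } else if (n > 1) {
    stats::cor(as.vector(eps[-n, ]), as.vector(eps[-1, ]))
  } else NA_real_
  structure(list(epsilons = eps, spec = spec, site_means = m, lag1 = lag1),
            class = "rate_ensemble")
}

#' @export
print.rate_ensemble <- function(x, ...) {
  cat(sprintf("<rate_ensemble> %d templates x %d codons, family = %s, seed = %d\n",
              nrow(x$epsilons), ncol(x$epsilons), x$spec$family, x$spec$seed))
  if (!is.na(x$lag1)) cat(sprintf("  correlated (%s), realized lag-1 = %.3f\n",
                                  x$spec$correlation$mode, x$lag1))
  invisible(x)
}

#' Extract one template's rate profile from an ensemble
#'
#' @param ensemble a `rate_ensemble`.
#' @param j template index.
#' @return a [rate_profile()].
#' @export
ensemble_profile <- function(ensemble, j) {
  stopifnot(inherits(ensemble, "rate_ensemble"))
  rate_profile(ensemble$epsilons[j, ], reinit_prob = ensemble$spec$reinit_prob)
}

#' Characteristic traversal time of an ensemble
#'
#' One mean traversal of the chain, `d / mean(epsilon)`, used as the time
#' unit for ensemble simulations ("late" times are a few multiples of it).
#'
#' @param ensemble a `rate_ensemble` (or a [rate_ensemble_spec()]).
#' @return a single time.
#' @export
time_unit <- function(ensemble) {
  if (inherits(ensemble, "rate_ensemble_spec")) {
    return(ensemble$d / mean(resolve_site_means(ensemble)))
  }
  stopifnot(inherits(ensemble, "rate_ensemble"))
  ncol(ensemble$epsilons) / mean(ensemble$epsilons)
}

#' Evolve the occupancy of every template in an ensemble
#'
#' Propagates each template's occupancy vector over a common time grid.
#' The default method is the matrix exponential, applied stepwise (one
#' exponential per distinct grid spacing per template). `method =
#' "steady"` short-circuits the dynamics and fills every requested time
#' with the template's stationary distribution (valid for
#' `reinit_prob = 1` at late times). Completed-protein production is
#' accumulated alongside: the completion flux \eqn{\epsilon_d V_d(t)} is
#' integrated over the grid (trapezoid), with optional first-order decay
#' of the completed pool.
#'
#' Templates whose propagation produces non-finite values are dropped and
#' counted; the run aborts if more than `max_drop_frac` of templates drop.
#'
#' @param ensemble a `rate_ensemble`.
#' @param time_grid strictly increasing nonnegative times.
#' @param v0 `"init"` (lead ribosome at the initiation site, the protocol
#'   used throughout), `"uniform"`, or a length-`d` probability vector.
#' @param method `"auto"` (= `"expm"`), `"expm"`, `"spectral"`,
#'   `"divdiff"`, `"closed"`, or `"steady"`.
#' @param protein_decay_rate first-order decay rate of the completed
#'   protein pool (default 0).
#' @param max_drop_frac abort threshold on the dropped-template fraction.
#' @return object of class `ensemble_trajectories`: list with `V` (array
#'   `n_kept x d x n_times`), `protein` (matrix `n_kept x n_times`,
#'   cumulative completed protein), `times`, `ensemble`, `kept` (indices),
#'   `n_dropped`, `protein_decay_rate`.
#' @export
simulate_occupancy <- function(ensemble, time_grid, v0 = "init",
                               method = c("auto", "expm", "spectral",
                                          "divdiff", "closed", "steady"),
                               protein_decay_rate = 0,
                               max_drop_frac = 0.01) {
  stopifnot(inherits(ensemble, "rate_ensemble"))
  method <- match.arg(method)
  time_grid <- as.numeric(time_grid)
  if (any(time_grid < 0) || is.unsorted(time_grid, strictly = TRUE)) {
    stop("time_grid must be strictly increasing and nonnegative", call. = FALSE)
  }
  n <- nrow(ensemble$epsilons)
  d <- ncol(ensemble$epsilons)
  nt <- length(time_grid)
  v0v <- resolve_v0(if (is.character(v0)) v0 else v0, d)
  V <- array(NA_real_, dim = c(n, d, nt))
  P <- matrix(0, n, nt)
  ok <- rep(TRUE, n)
  delta <- protein_decay_rate
  for (j in seq_len(n)) {
    pr <- rate_profile(ensemble$epsilons[j, ],
                       reinit_prob = ensemble$spec$reinit_prob)
    res <- tryCatch({
      if (method == "steady") {
        pi_j <- steady_state_distribution(pr)$probs
        Vj <- matrix(pi_j, d, nt)
      } else {
        mth <- if (method == "auto") "expm" else method
        Vj <- matrix(0, d, nt)
        v <- v0v
        prev_t <- 0
        steps <- list()
        for (k in seq_len(nt)) {
          dt <- time_grid[k] - prev_t
          if (dt > 0) {
            key <- sprintf("%.15g", dt)
            if (is.null(steps[[key]])) {
              steps[[key]] <- propagator_matrix(pr, dt, method = mth)
            }
            v <- as.numeric(steps[[key]] %*% v)
          }
          Vj[, k] <- v
          prev_t <- time_grid[k]
        }
      }
      Vj
    }, error = function(e) {
      if (inherits(e, "ribowalk_confluent_rates") ||
          inherits(e, "ribowalk_spectral_failure")) {
        return(NULL)   # out-of-bound / method failure: drop the template
      }
      stop(e)
    })
    if (is.null(res) || any(!is.finite(res))) { ok[j] <- FALSE; next }
    V[j, , ] <- res
    # cumulative completed protein: dP/dt = eps_d V_d - delta P, trapezoid flux
    flux <- pr$epsilons[d] * res[d, ]
    p <- 0
    t_prev <- time_grid[1]
    P[j, 1] <- 0
    if (nt > 1) for (k in 2:nt) {
      dt <- time_grid[k] - t_prev
      decay <- exp(-delta * dt)
      p <- p * decay + dt * (flux[k - 1] * decay + flux[k]) / 2
      P[j, k] <- p
      t_prev <- time_grid[k]
    }
  }
  n_dropped <- sum(!ok)
  if (n_dropped > max_drop_frac * n) {
    stop(sprintf("%d of %d templates dropped (> %.1f%%); aborting",
                 n_dropped, n, 100 * max_drop_frac), call. = FALSE)
  }
  structure(list(V = V[ok, , , drop = FALSE], protein = P[ok, , drop = FALSE],
                 times = time_grid, ensemble = ensemble,
                 kept = which(ok), n_dropped = n_dropped,
                 protein_decay_rate = delta),
            class = "ensemble_trajectories")
}

#' @export
print.ensemble_trajectories <- function(x, ...) {
  cat(sprintf("<ensemble_trajectories> %d templates, d = %d, %d times (%g..%g), %d dropped\n",
              dim(x$V)[1], dim(x$V)[2], length(x$times),
              min(x$times), max(x$times), x$n_dropped))
  invisible(x)
}

#' Across-template protein-output sample
#'
#' Extracts, at one grid time, the per-template value of a protein-output
#' metric: `"terminal_occupancy"` (\eqn{V_d(t)}, the default readout for
#' population histograms), `"completion_flux"` (\eqn{\epsilon_d V_d(t)}),
#' or `"cumulative_count"` (the integrated, optionally decayed, completed
#' protein).
#'
#' @param trajectories an `ensemble_trajectories`.
#' @param metric one of the three metrics above.
#' @param time a time on the simulation grid (default: last).
#' @return numeric vector (one value per kept template), with summary
#'   statistics attached as attribute `"summary"`.
#' @export
protein_output_distribution <- function(trajectories,
                                        metric = c("terminal_occupancy",
                                                   "completion_flux",
                                                   "cumulative_count"),
                                        time = NULL) {
  stopifnot(inherits(trajectories, "ensemble_trajectories"))
  metric <- match.arg(metric)
  if (is.null(time)) time <- trajectories$times[length(trajectories$times)]
  k <- match(TRUE, abs(trajectories$times - time) < 1e-12)
  if (is.na(k)) stop("requested time is not on the simulation grid", call. = FALSE)
  d <- dim(trajectories$V)[2]
  x <- switch(metric,
    terminal_occupancy = trajectories$V[, d, k],
    completion_flux = trajectories$ensemble$epsilons[trajectories$kept, d] *
      trajectories$V[, d, k],
    cumulative_count = trajectories$protein[, k])
  attr(x, "summary") <- c(mean = mean(x), sd = stats::sd(x),
                          median = stats::median(x), n = length(x))
  x
}

#' Steady-state protein sample straight from the stationary law
#'
#' Convenience for late-time population distributions on circular
#' templates: per template, the stationary terminal occupancy
#' \eqn{\pi_d = (1/\epsilon_d)/\sum_k (1/\epsilon_k)} or the stationary
#' completion flux \eqn{\epsilon_d \pi_d = 1/\sum_k(1/\epsilon_k)}.
#'
#' @param ensemble a `rate_ensemble` with `reinit_prob = 1`.
#' @param metric `"terminal_occupancy"` or `"completion_flux"`.
#' @return numeric vector, one value per template.
#' @export
steady_state_protein_sample <- function(ensemble,
                                        metric = c("terminal_occupancy",
                                                   "completion_flux")) {
  stopifnot(inherits(ensemble, "rate_ensemble"))
  metric <- match.arg(metric)
  if (ensemble$spec$reinit_prob < 1) {
    stop("stationary sample requires reinit_prob = 1", call. = FALSE)
  }
  E <- ensemble$epsilons
  hsum <- rowSums(1 / E)
  switch(metric,
    terminal_occupancy = (1 / E[, ncol(E)]) / hsum,
    completion_flux = 1 / hsum)
}

#' Site-occupancy summary for ensembles with slow codons
#'
#' Simulates the ensemble (which should carry at least one slow site) and
#' returns the time-resolved ensemble-mean occupancy per site plus the
#' site at which the late-time mean occupancy peaks — the stalling
#' signature: ribosomes accumulate just at the slow codon.
#'
#' @param ensemble a `rate_ensemble` whose spec has `slow_sites`.
#' @param time_grid times at which to evaluate (default: `c(1, 2, 3)` mean
#'   traversals).
#' @param method propagation method, as in [simulate_occupancy()].
#' @return list with `mean_occupancy` (matrix `n_times x d`), `times`,
#'   `argmax_site` (argmax of the final-time mean occupancy), and the
#'   `trajectories`.
#' @export
slow_codon_profile <- function(ensemble, time_grid = NULL,
                               method = "auto") {
  stopifnot(inherits(ensemble, "rate_ensemble"))
  if (is.null(ensemble$spec$slow_sites)) {
    stop("the ensemble spec has no slow_sites configured", call. = FALSE)
  }
  if (is.null(time_grid)) time_grid <- c(1, 2, 3) * time_unit(ensemble)
  traj <- simulate_occupancy(ensemble, time_grid, method = method)
  mo <- apply(traj$V, c(3, 2), mean)   # n_times x d
  list(mean_occupancy = mo, times = time_grid,
       argmax_site = which.max(mo[nrow(mo), ]), trajectories = traj)
}

#' Transient-phase statistics of an ensemble
#'
#' Computes (i) the ensemble-mean expected chain length
#' \eqn{L(t) = \langle \sum_i i V_i(t) \rangle} over the time grid — in the
#' transient phase this grows linearly with time — and (ii) the per-site,
#' per-time variance across templates of \eqn{\log V_i(t)}, the
#' log-variance used to track how site-to-site dispersion converges and
#' shrinks as the ensemble approaches steady state. Zero (or tiny)
#' occupancies are excluded from the log-variance with their count
#' reported.
#'
#' For open chains (`reinit_prob < 1`) completed proteins count toward the
#' chain length at full length `d` (set `count_completed = FALSE` to track
#' only elongating chains); when the trajectories were simulated with
#' protein decay, the decayed mass is thereby lost from `L`, which is what
#' bends `L(t)` below its early linear growth.
#'
#' @param trajectories an `ensemble_trajectories` with at least 2 templates.
#' @param count_completed include `d * protein` in `L` (default `TRUE`).
#' @param floor occupancies at or below this value are excluded from the
#'   log-variance.
#' @return list with `L` (data.frame `time`, `L`), `log_variance` (matrix
#'   `n_times x d`), `n_excluded` (count of excluded entries).
#' @export
transient_statistics <- function(trajectories, count_completed = TRUE,
                                 floor = 1e-300) {
  stopifnot(inherits(trajectories, "ensemble_trajectories"))
  n <- dim(trajectories$V)[1]
  if (n < 2L) stop("need at least 2 templates", call. = FALSE)
  d <- dim(trajectories$V)[2]
  nt <- dim(trajectories$V)[3]
  sites <- seq_len(d)
  Lmat <- apply(trajectories$V, c(1, 3), function(v) sum(sites * v))
  if (count_completed) Lmat <- Lmat + d * trajectories$protein
  Lser <- colMeans(Lmat)
  logvar <- matrix(NA_real_, nt, d)
  n_excluded <- 0L
  for (k in seq_len(nt)) for (i in sites) {
    v <- trajectories$V[, i, k]
    keep <- v > floor
    n_excluded <- n_excluded + sum(!keep)
    if (sum(keep) >= 2L) logvar[k, i] <- stats::var(log(v[keep]))
  }
  list(L = data.frame(time = trajectories$times, L = Lser),
       log_variance = logvar, n_excluded = n_excluded)
}

#' Moving average of rates at a fixed site across adjacent templates
#'
#' Diagnostic for visualizing between-template correlation: the moving
#' average (window of `window` templates) of the rate constants at one
#' codon across the template index.
#'
#' @param ensemble a `rate_ensemble`.
#' @param site codon index.
#' @param window window width in templates.
#' @return data.frame `template`, `rate_moving_average`.
#' @export
site_moving_average <- function(ensemble, site, window = 100) {
  stopifnot(inherits(ensemble, "rate_ensemble"))
  x <- ensemble$epsilons[, site]
  n <- length(x)
  if (window > n) stop("window exceeds ensemble size", call. = FALSE)
  cs <- c(0, cumsum(x))
  idx <- seq_len(n - window + 1L)
  data.frame(template = idx,
             rate_moving_average = (cs[idx + window] - cs[idx]) / window)
}
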