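#' Propagators of the elongation walk
#'
#' The occupancy of the lead ribosome evolves as
#' \eqn{V(t) = Q(t) V(0)} with \eqn{Q(t) = e^{tT}} for the generator `T`
#' of [build_generator()]. Four independent algorithms compute `Q(t)`:
#'
#' * [expm_propagator()] — general matrix exponential (Pad\'e, via
#'   \pkg{Matrix}); the reference for all others.
#' * [closed_form_propagator()] — the explicit alternating-sign sum of
#'   exponentials over the poles for the open chain (\eqn{\lambda = 0},
#'   pairwise distinct rates).
#' * [divdiff_propagator()] — the same entries expressed as products of
#'   rates times divided differences of \eqn{e^{-t\epsilon}}, evaluated
#'   stably through the Opitz bidiagonal form; handles tied and nearly tied
#'   rates where the closed form loses all precision.
#' * [spectral_propagator()] — partial-fraction/residue expansion over the
#'   roots of the circular-chain denominator polynomial
#'   \eqn{\prod_k (s + \epsilon_k) - \lambda \prod_m \epsilon_m}
#'   (\eqn{0 < \lambda \le 1}); for \eqn{\lambda = 1} the root at
#'   \eqn{s = 0} contributes the stationary distribution.
#'
#' [poisson_propagator()] is the equal-rate special case, where the walk
#' reduces to a pure Poisson counting process.
#'
#' @name propagators
NULL

#' Matrix-exponential propagator (reference)
#'
#' @param profile a [rate_profile()].
#' @param t nonnegative time.
#' @return `d x d` matrix `Q(t) = exp(t T)`.
#' @seealso [propagators]
#' @export
expm_propagator <- function(profile, t) {
  stopifnot_profile(profile)
  if (t < 0) stop("t must be nonnegative", call. = FALSE)
  Q <- as.matrix(Matrix::expm(build_generator(profile) * t))
  unname(Q)
}

#' Propagate an occupancy state by the matrix exponential
#'
#' @param profile a [rate_profile()].
#' @param t nonnegative time.
#' @param v0 initial state: an [occupancy_vector()], a numeric vector, or
#'   `NULL` for the pure initiation state `(1, 0, ..., 0)`.
#' @return an [occupancy_vector()] at time `t` (entries clipped to `[0, 1]`).
#' @export
expm_propagate <- function(profile, t, v0 = NULL) {
  stopifnot_profile(profile)
  v <- resolve_v0(v0, profile$d)
  Q <- expm_propagator(profile, t)
  occupancy_vector(as.numeric(Q %*% v), time = t)
}

resolve_v0 <- function(v0, d) {
  if (is.null(v0)) return(c(1, rep(0, d - 1L)))
  if (inherits(v0, "occupancy_vector")) v0 <- v0$probs
  if (identical(v0, "init")) return(c(1, rep(0, d - 1L)))
  if (identical(v0, "uniform")) return(rep(1 / d, d))
  v0 <- as.numeric(v0)
  if (length(v0) != d) stop("v0 has the wrong length", call. = FALSE)
  if (any(v0 < 0) || sum(v0) > 1 + 1e-8) {
    stop("v0 must be a sub-probability vector", call. = FALSE)
  }
  v0
}

#' Closed-form propagator for the open chain
#'
#' For \eqn{\lambda = 0} and pairwise distinct rates the propagator is
#' lower triangular with
#' \deqn{Q(t)_{ij} = (-1)^{i+j} \prod_{m=j}^{i-1}\epsilon_m \sum_{k=j}^{i}
#'   \frac{e^{-t\epsilon_k}}
#'        {\prod_{p=1}^{i-k}(\epsilon_k-\epsilon_{k+p})
#'         \prod_{q=j}^{k-1}(\epsilon_k-\epsilon_q)}, \quad i \ge j,}
#' and \eqn{Q_{ii} = e^{-t\epsilon_i}}. The denominators are singular at
#' tied rates: when two rates within a needed block are closer than
#' `confluence_tol` (relative), a condition of class
#' `ribowalk_confluent_rates` is raised and the caller should switch to
#' [divdiff_propagator()].
#'
#' @param profile a [rate_profile()] with `reinit_prob = 0`.
#' @param t nonnegative time.
#' @param confluence_tol relative node-distance below which rates are
#'   declared confluent.
#' @return `d x d` lower-triangular matrix.
#' @export
closed_form_propagator <- function(profile, t, confluence_tol = 1e-6) {
  stopifnot_profile(profile)
  if (profile$reinit_prob != 0) {
    stop("closed_form_propagator applies to the open chain (lambda = 0)",
         call. = FALSE)
  }
  if (t < 0) stop("t must be nonnegative", call. = FALSE)
  eps <- profile$epsilons
  d <- profile$d
  gaps <- abs(diff(sort(eps))) / max(eps)
  if (any(gaps < confluence_tol)) {
    cond <- structure(
      class = c("ribowalk_confluent_rates", "error", "condition"),
      list(message = paste("confluent (tied or nearly tied) rates: the",
                           "closed-form denominators are singular;",
                           "use divdiff_propagator()"),
           call = sys.call(-1)))
    stop(cond)
  }
  Q <- matrix(0, d, d)
  e_t <- exp(-t * eps)
  for (j in seq_len(d)) {
    Q[j, j] <- e_t[j]
    for (i in seq((j + 1L), d, length.out = max(0L, d - j))) {
      ks <- j:i
      terms <- vapply(ks, function(k) {
        den <- prod(eps[k] - eps[setdiff(ks, k)])
        e_t[k] / den
      }, numeric(1))
      Q[i, j] <- (-1)^(i + j) * prod(eps[j:(i - 1L)]) * sum(terms)
    }
  }
  Q
}

#' Poisson propagator for equal rates
#'
#' When every codon has the same rate \eqn{\epsilon} and \eqn{\lambda = 0},
#' the number of completed steps in time `t` is Poisson and
#' \deqn{Q(t)_{ij} = e^{-t\epsilon} (t\epsilon)^{i-j} / (i-j)!, \quad
#'   i \ge j.}
#'
#' @param epsilon common positive rate.
#' @param d codon count.
#' @param t nonnegative time.
#' @return `d x d` lower-triangular matrix.
#' @export
poisson_propagator <- function(epsilon, d, t) {
  if (epsilon <= 0) stop("epsilon must be positive", call. = FALSE)
  if (t < 0) stop("t must be nonnegative", call. = FALSE)
  Q <- matrix(0, d, d)
  for (j in seq_len(d)) {
    n <- 0:(d - j)
    Q[j:d, j] <- stats::dpois(n, lambda = t * epsilon)
  }
  Q
}

# Divided differences of exp() over consecutive node ranges via the Opitz
# bidiagonal form: for Z with the nodes on the diagonal and ones on the
# subdiagonal, [exp(Z)]_{ij} = dd[x_j, ..., x_i] exp for i >= j. Computed by
# a diagonal shift, truncated Taylor series and repeated squaring. All
# entries of exp(Z) are positive (divided differences of exp are), so the
# squaring phase involves no cancellation; this is accurate in double
# precision even for tied or nearly tied nodes, where naive recursive
# differencing fails.
dd_exp_table <- function(nodes) {
  d <- length(nodes)
  mu <- mean(nodes)
  Z <- diag(nodes - mu, d)
  if (d > 1L) Z[cbind(2:d, 1:(d - 1L))] <- 1
  nrm <- max(colSums(abs(Z)))
  s <- if (nrm > 0.5) ceiling(log2(nrm / 0.5)) else 0L
  A <- Z / 2^s
  Fm <- diag(d)
  term <- diag(d)
  for (k in 1:40) {
    term <- term %*% A / k
    Fm <- Fm + term
    if (max(abs(term)) < 1e-18 * max(abs(Fm))) break
  }
  for (r in seq_len(s)) Fm <- Fm %*% Fm
  Fm * exp(mu)
}

#' Divided-difference propagator for the open chain
#'
#' Expresses the open-chain (\eqn{\lambda = 0}) propagator entries as
#' \deqn{Q(t)_{ij} = \Big(\prod_{m=j}^{i-1} \epsilon_m\Big)\, t^{i-j}\,
#'   \Delta[-t\epsilon_j, \ldots, -t\epsilon_i]\, e^{x},}
#' the divided difference of the exponential over the (negated, scaled)
#' rate nodes. Divided differences are obtained from the exponential of the
#' Opitz bidiagonal node matrix — a formulation whose confluent limit
#' (repeated nodes, derivative rule \eqn{f^{(n)}/n!}) is automatic — so
#' tied and nearly tied rates are handled at full accuracy. This is the
#' fallback path for configurations where the closed-form sum is unstable.
#'
#' @param profile a [rate_profile()] with `reinit_prob = 0`.
#' @param t nonnegative time.
#' @return `d x d` lower-triangular matrix.
#' @export
divdiff_propagator <- function(profile, t) {
  stopifnot_profile(profile)
  if (profile$reinit_prob != 0) {
    stop("divdiff_propagator applies to the open chain (lambda = 0)",
         call. = FALSE)
  }
  if (t < 0) stop("t must be nonnegative", call. = FALSE)
  eps <- profile$epsilons
  d <- profile$d
  dd <- dd_exp_table(-t * eps)            # dd[i, j] = Delta exp over nodes j..i
  logeps <- log(eps)
  cum <- c(0, cumsum(logeps))             # cum[i] = sum log eps_1..eps_{i-1}
  Q <- matrix(0, d, d)
  logt <- if (t > 0) log(t) else -Inf
  for (j in seq_len(d)) {
    Q[j, j] <- dd[j, j]
    if (j < d) {
      i <- (j + 1L):d
      scale <- exp(cum[i] - cum[j] + (i - j) * logt)  # prod eps_{j..i-1} t^{i-j}
      if (t == 0) scale <- 0
      Q[i, j] <- scale * dd[cbind(i, j)]
    }
  }
  Q
}

# Coefficients (ascending powers) of the monic polynomial prod (s + eps_k).
poly_from_rates <- function(eps) {
  coefs <- 1
  for (e in eps) coefs <- c(0, coefs) + e * c(coefs, 0)
  coefs
}

poly_eval <- function(coefs, s) {
  # Horner in complex arithmetic; coefs ascending
  out <- 0 + 0i
  for (k in rev(seq_along(coefs))) out <- out * s + coefs[k]
  out
}

#' Spectral (residue) propagator for the circular chain
#'
#' For \eqn{0 < \lambda \le 1} the propagator entries are contour integrals
#' of rational functions whose denominator is
#' \eqn{P(s) = \prod_k (s + \epsilon_k) - \lambda \prod_m \epsilon_m}.
#' They are evaluated here as the mathematically identical residue sums:
#' \deqn{Q(t)_{ij} = \sum_r e^{t s_r} \frac{N_{ij}(s_r)}{P'(s_r)},}
#' over the (simple) roots \eqn{s_r} of `P`, with numerators
#' \deqn{N_{ij}(s) = \lambda \prod_{k=i+1}^{j-1}(s+\epsilon_k)
#'   \prod_{m=j}^{d}\epsilon_m \prod_{m=1}^{i-1}\epsilon_m \quad (i < j),}
#' \deqn{N_{ij}(s) = \prod_{k=1}^{j-1}(s+\epsilon_k)
#'   \prod_{k=i+1}^{d}(s+\epsilon_k) \prod_{m=j}^{i-1}\epsilon_m \quad
#'   (i \ge j).}
#' Roots are the companion-matrix eigenvalues of the expanded denominator
#' (they lie near \eqn{s = -\epsilon_k}), each polished by one Newton step.
#' For \eqn{\lambda = 1} the root at \eqn{s = 0} contributes the stationary
#' distribution in every column.
#'
#' @param profile a [rate_profile()] with `reinit_prob` in `(0, 1]`.
#' @param t nonnegative time.
#' @param root_tol relative residual above which root-finding is declared
#'   failed (condition class `ribowalk_spectral_failure`; callers may fall
#'   back to [expm_propagator()]).
#' @return `d x d` matrix.
#' @export
spectral_propagator <- function(profile, t, root_tol = 1e-6) {
  stopifnot_profile(profile)
  lam <- profile$reinit_prob
  if (lam <= 0) {
    stop("spectral_propagator needs 0 < lambda <= 1 (use the open-chain propagators for lambda = 0)",
         call. = FALSE)
  }
  if (t < 0) stop("t must be nonnegative", call. = FALSE)
  eps <- profile$epsilons
  d <- profile$d
  coefs <- poly_from_rates(eps)
  coefs[1] <- coefs[1] - lam * prod(eps)      # P(s) = prod(s+eps) - lam prod(eps)
  dcoefs <- coefs[-1] * seq_len(d)            # P'(s), ascending
  roots <- polyroot(coefs)
  # one Newton polish per root; the roots lie near s = -eps_k
  for (it in 1:2) roots <- roots - poly_eval(coefs, roots) / poly_eval(dcoefs, roots)
  scale <- max(abs(coefs))
  resid <- abs(poly_eval(coefs, roots)) / (scale * pmax(abs(roots), 1))
  # a converged simple root has a vanishing Newton step; near-multiple roots
  # keep a large step even after polishing
  step <- abs(poly_eval(coefs, roots) / poly_eval(dcoefs, roots)) /
    pmax(abs(roots), 1)
  sep <- outer(roots, roots, function(a, b) Mod(a - b))
  diag(sep) <- Inf
  if (any(!is.finite(resid)) || any(resid > root_tol) ||
      any(step > 1e-8) || min(sep) < 1e-5 * max(eps)) {
    cond <- structure(
      class = c("ribowalk_spectral_failure", "error", "condition"),
      list(message = paste("denominator root-finding failed (large residual",
                           "or repeated roots); fall back to expm_propagator()"),
           call = sys.call(-1)))
    stop(cond)
  }
  dP <- poly_eval(dcoefs, roots)
  ets <- exp(t * roots)
  Q <- matrix(0, d, d)
  for (jj in seq_len(d)) {
    for (ii in seq_len(d)) {
      if (ii < jj) {
        num <- lam * prod(eps[seq_len(d) >= jj | seq_len(d) < ii])
        if (jj - ii >= 2L) {
          ks <- (ii + 1L):(jj - 1L)
          num <- num * vapply(seq_along(roots),
                              function(r) prod(roots[r] + eps[ks]), complex(1))
        }
      } else {
        num <- prod(eps[seq_len(d) >= jj & seq_len(d) < ii])
        ks <- c(seq_len(jj - 1L), seq(ii + 1L, d, length.out = max(0L, d - ii)))
        if (length(ks)) {
          num <- num * vapply(seq_along(roots),
                              function(r) prod(roots[r] + eps[ks]), complex(1))
        }
      }
      Q[ii, jj] <- Re(sum(ets * num / dP))
    }
  }
  Q
}

#' Laplace-domain propagator for a decaying transcript
#'
#' For a transcript with exponential lifetime (first-order decay, rate
#' `c`), the expected occupancy over the transcript's life is the
#' lifetime-weighted time integral \eqn{\int_0^\infty c e^{-ct} Q(t) dt},
#' which has the closed form (for \eqn{i < j})
#' \deqn{\frac{c \lambda \prod_{k=i+1}^{j-1}(c+\epsilon_k)
#'   \prod_{m=j}^{d}\epsilon_m \prod_{m=1}^{i-1}\epsilon_m}
#'   {\prod_{k=1}^{d}(c+\epsilon_k) - \lambda \prod_{m=1}^{d}\epsilon_m}}
#' and the analogous expression with numerator
#' \eqn{c \prod_{k=1}^{j-1}(c+\epsilon_k) \prod_{k=i+1}^{d}(c+\epsilon_k)
#' \prod_{m=j}^{i-1}\epsilon_m} for \eqn{i \ge j}. All products evaluated
#' in log space. For \eqn{\lambda = 1} every column sums to exactly 1; for
#' \eqn{\lambda < 1} the column-sum deficit is the probability that the
#' walk terminates (leaves for the free pool) before the transcript decays.
#'
#' @param profile a [rate_profile()].
#' @param decay a [decay_model()] with `mrna_decay_rate > 0`.
#' @return `d x d` matrix of lifetime-averaged occupancies.
#' @export
laplace_propagator <- function(profile, decay) {
  stopifnot_profile(profile)
  stopifnot(inherits(decay, "decay_model"))
  cc <- decay$mrna_decay_rate
  lam <- profile$reinit_prob
  if (cc <= 0) {
    stop("laplace_propagator needs c > 0",
         if (lam >= 1) " (c = 0 with lambda = 1 is degenerate)" else "",
         call. = FALSE)
  }
  eps <- profile$epsilons
  d <- profile$d
  le <- log(eps)
  lce <- log(cc + eps)
  cum_e <- c(0, cumsum(le))     # cum_e[i+1] = sum le[1..i]
  cum_ce <- c(0, cumsum(lce))
  log_den_main <- cum_ce[d + 1L]
  den_factor <- 1 - lam * exp(cum_e[d + 1L] - log_den_main)
  if (den_factor <= 0) stop("degenerate denominator", call. = FALSE)
  Q <- matrix(0, d, d)
  for (jj in seq_len(d)) {
    for (ii in seq_len(d)) {
      if (ii < jj) {
        if (lam == 0) next
        lognum <- log(lam) +
          (cum_ce[jj] - cum_ce[ii + 1L]) +          # prod_{k=i+1..j-1}(c+eps)
          (cum_e[d + 1L] - cum_e[jj]) +             # prod_{m=j..d} eps
          cum_e[ii]                                 # prod_{m=1..i-1} eps
      } else {
        lognum <- cum_ce[jj] +                      # prod_{k=1..j-1}(c+eps)
          (cum_ce[d + 1L] - cum_ce[ii + 1L]) +      # prod_{k=i+1..d}(c+eps)
          (cum_e[ii] - cum_e[jj])                   # prod_{m=j..i-1} eps
      }
      Q[ii, jj] <- exp(log(cc) + lognum - log_den_main) / den_factor
    }
  }
  Q
}

#' Compute the propagator by a chosen method
#'
#' Dispatches to one of the propagator algorithms. `"auto"` selects the
#' matrix exponential, falling back to it as well when a specialised method
#' signals failure (confluent rates for the closed form, root-finding
#' failure for the spectral path).
#'
#' @param profile a [rate_profile()].
#' @param t nonnegative time.
#' @param method one of `"expm"`, `"closed"`, `"divdiff"`, `"spectral"`,
#'   `"poisson"`, `"auto"`.
#' @return `d x d` matrix `Q(t)`.
#' @export
propagator_matrix <- function(profile, t,
                              method = c("auto", "expm", "closed", "divdiff",
                                         "spectral", "poisson")) {
  method <- match.arg(method)
  switch(method,
    auto = expm_propagator(profile, t),
    expm = expm_propagator(profile, t),
    closed = closed_form_propagator(profile, t),
    divdiff = divdiff_propagator(profile, t),
    spectral = spectral_propagator(profile, t),
    poisson = {
      eps <- profile$epsilons
      if (diff(range(eps)) > 0) {
        stop("poisson method needs equal rates", call. = FALSE)
      }
      poisson_propagator(eps[1], profile$d, t)
    })
}
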