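#' Discrete transition matrix of the elongation walk
#'
#' Builds the column-stochastic-structured matrix `U` of the per-step walk:
#' diagonal entries \eqn{1 - p_i}, subdiagonal entries \eqn{p_i} (movement
#' from codon `i` to `i + 1`), and corner entry
#' \eqn{U_{1,d} = \lambda p_d} carrying a terminating ribosome back to the
#' initiation site with reinitiation probability \eqn{\lambda}. Step
#' probabilities are \eqn{p_i = \epsilon_i / \alpha}. For
#' \eqn{\lambda = 1} every column sums to 1; for \eqn{\lambda < 1} column
#' `d` sums to \eqn{1 - (1 - \lambda) p_d}, the deficit being the mass that
#' leaves for the free-ribosome pool.
#'
#' @param profile a [rate_profile()].
#' @return a `d x d` numeric matrix acting on occupancy column vectors.
#' @export
build_transition_matrix <- function(profile) {
  stopifnot_profile(profile)
  d <- profile$d
  p <- profile$epsilons / profile$alpha
  U <- diag(1 - p)
  U[cbind(2:d, 1:(d - 1))] <- p[1:(d - 1)]
  U[1, d] <- profile$reinit_prob * p[d]
  U
}

#' Continuous-time generator of the elongation walk
#'
#' Returns \eqn{T = \alpha (U - I)}: diagonal \eqn{-\epsilon_i},
#' subdiagonal \eqn{\epsilon_i}, corner \eqn{T_{1,d} = \lambda \epsilon_d}.
#' The occupancy evolves as \eqn{V(t) = e^{tT} V(0)} (a compound-Poisson
#' semigroup); columns sum to zero exactly when \eqn{\lambda = 1}.
#'
#' @param profile a [rate_profile()].
#' @return a `d x d` numeric generator matrix.
#' @export
build_generator <- function(profile) {
  stopifnot_profile(profile)
  d <- profile$d
  eps <- profile$epsilons
  Tm <- diag(-eps)
  Tm[cbind(2:d, 1:(d - 1))] <- eps[1:(d - 1)]
  Tm[1, d] <- profile$reinit_prob * eps[d]
  Tm
}

#' Stationary ribosome-position distribution on a circular template
#'
#' For a fully recycling template (\eqn{\lambda = 1}) the walk is a
#' conservative cycle and has the stationary distribution
#' \deqn{\pi_i = \frac{1/\epsilon_i}{\sum_k 1/\epsilon_k},}
#' i.e. occupancy inversely proportional to the local rate: ribosomes
#' accumulate where elongation is slow.
#'
#' @param profile a [rate_profile()] with `reinit_prob = 1`.
#' @return an [occupancy_vector()] holding the stationary probabilities
#'   (its `time` field is 0 by convention; the distribution is
#'   time-invariant).
#' @export
steady_state_distribution <- function(profile) {
  stopifnot_profile(profile)
  if (profile$reinit_prob < 1) {
    stop(paste("the stationary distribution exists only for the conservative",
               "chain (reinit_prob = 1); for lambda < 1 the walk is absorbing",
               "into the free-ribosome pool"), call. = FALSE)
  }
  w <- 1 / profile$epsilons
  occupancy_vector(w / sum(w), time = 0)
}

#' Steady circulation flux on a circular template
#'
#' The stationary rate at which ribosomes pass any given codon (and hence
#' the steady protein completion rate) on a \eqn{\lambda = 1} template:
#' \eqn{J = 1 / \sum_k (1/\epsilon_k)} — the harmonic-sum bottleneck rate.
#'
#' @param profile a [rate_profile()].
#' @return a single nonnegative rate.
#' @export
steady_flux <- function(profile) {
  stopifnot_profile(profile)
  1 / sum(1 / profile$epsilons)
}

#' Mean number of polypeptides produced per mRNA template
#'
#' For a template undergoing first-order decay with rate constant `c`, the
#' expected number of completed proteins over the template's life is
#' \deqn{N = \frac{c \prod_m \epsilon_m}
#'            {\prod_k (c + \epsilon_k) - \lambda \prod_m \epsilon_m}.}
#' Products are evaluated as chains of per-site ratios
#' \eqn{\epsilon_k/(c+\epsilon_k) < 1}, so templates of any length (d = 30
#' and far beyond, rates of order 10-100) neither overflow nor underflow
#' prematurely.
#'
#' With `lifetime_weighted = FALSE` the leading factor `c` is dropped,
#' giving the expected number of completions of a single initiated ribosome
#' before transcript decay (this tends to 1 as `c -> 0` on an open chain,
#' whereas the lifetime-weighted form tends to the steady flux over `c`
#' normalisation; see the package vignette for the distinction).
#'
#' @param profile a [rate_profile()].
#' @param decay a [decay_model()] with `mrna_decay_rate > 0`.
#' @param lifetime_weighted keep the leading factor `c` (default `TRUE`).
#' @return a single nonnegative count.
#' @export
polypeptides_per_template <- function(profile, decay,
                                      lifetime_weighted = TRUE) {
  stopifnot_profile(profile)
  stopifnot(inherits(decay, "decay_model"))
  cc <- decay$mrna_decay_rate
  lam <- profile$reinit_prob
  if (cc <= 0) {
    stop("polypeptides_per_template needs mrna_decay_rate c > 0",
         if (lam >= 1) " (with lambda = 1 the c = 0 denominator vanishes)" else "",
         call. = FALSE)
  }
  eps <- profile$epsilons
  # prod eps / prod (c + eps) as a product of per-site ratios: every factor
  # lies in (0, 1), so arbitrary chain lengths neither overflow nor lose
  # precision to log round-trips
  ratio <- prod(eps / (cc + eps))
  den_factor <- 1 - lam * ratio
  if (den_factor <= 0) {
    stop("degenerate denominator: prod(c + eps) - lambda * prod(eps) <= 0",
         call. = FALSE)
  }
  pref <- if (lifetime_weighted) cc else 1
  pref * ratio / den_factor
}

#' Mean number of ribosomes per template over its life
#'
#' For an open chain (reinitiation neglected) with transcript decay rate
#' `c` and mean ribosome spacing `R`, the expected ribosome load is
#' \deqn{\langle n \rangle = \sum_{i=1}^{d} \frac{i}{R}\,
#'   \frac{c \prod_{m<i} \epsilon_m}{\prod_{k \le i} (c + \epsilon_k)},}
#' the lead ribosome's decay-weighted mean progress divided by the spacing.
#' Evaluated as stable per-site ratio products.
#'
#' @param profile a [rate_profile()]; `reinit_prob` is ignored (the formula
#'   is for the elongation-limited open chain).
#' @param decay a [decay_model()] with `mrna_decay_rate > 0` and spacing `R`.
#' @return a single nonnegative count.
#' @export
mean_ribosomes_per_template <- function(profile, decay) {
  stopifnot_profile(profile)
  stopifnot(inherits(decay, "decay_model"))
  cc <- decay$mrna_decay_rate
  R <- decay$ribosome_spacing
  if (cc <= 0) stop("mean_ribosomes_per_template needs c > 0", call. = FALSE)
  eps <- profile$epsilons
  d <- profile$d
  # term_i = (i/R) c/(c+eps_i) prod_{m<i} eps_m/(c+eps_m): ratio products,
  # every factor below 1, stable at any chain length
  lead <- cumprod(c(1, eps[-d] / (cc + eps[-d])))
  i <- seq_len(d)
  sum(i / R * cc / (cc + eps) * lead)
}

#' Expected polypeptide chain length
#'
#' The mean extent of chain formation implied by an occupancy state:
#' \eqn{L = \sum_i i \, V_i(t)} with 1-based site index.
#'
#' @param V an [occupancy_vector()] or plain numeric vector of occupancies.
#' @return a single nonnegative length (codons).
#' @export
mean_chain_length <- function(V) {
  probs <- if (inherits(V, "occupancy_vector")) V$probs else as.numeric(V)
  sum(seq_along(probs) * probs)
}

#' Greedy optimization of rate-limiting codons
#'
#' Repeatedly finds the slowest codon (the current rate-limiting step), and
#' if a faster synonymous substitution is available (its `achievable_max`
#' exceeds the current rate), replaces the rate by that maximum, recording
#' the resulting steady circulation flux \eqn{1/\sum_k (1/\epsilon_k)}.
#' Stops when the limiting codon is already at its achievable maximum (no
#' substitution can help) or after `steps` substitutions. The recorded flux
#' sequence is non-decreasing.
#'
#' @param profile a [rate_profile()] (flux evaluation uses the circular
#'   steady state, `reinit_prob = 1` semantics).
#' @param achievable_max numeric vector of length `d`, the fastest rate
#'   achievable at each site; must be `>= epsilons` elementwise.
#' @param steps maximum number of substitutions (default unlimited).
#' @return a data.frame with one row per substitution: `site`, `old_rate`,
#'   `new_rate`, `flux` (steady circulation flux after the substitution).
#'   Zero rows when the profile is already fully optimized. The final
#'   profile is attached as attribute `"profile"`.
#' @export
optimize_limiting_codons <- function(profile, achievable_max, steps = Inf) {
  stopifnot_profile(profile)
  achievable_max <- as.numeric(achievable_max)
  if (length(achievable_max) != profile$d) {
    stop("achievable_max must have one entry per codon", call. = FALSE)
  }
  if (any(achievable_max < profile$epsilons)) {
    bad <- which(achievable_max < profile$epsilons)[1L]
    stop(sprintf("achievable_max at site %d is below the current rate", bad),
         call. = FALSE)
  }
  eps <- profile$epsilons
  out <- list()
  k <- 0L
  while (k < steps) {
    site <- which.min(eps)
    if (eps[site] >= achievable_max[site]) break  # limiting codon unimprovable
    k <- k + 1L
    old <- eps[site]
    eps[site] <- achievable_max[site]
    out[[k]] <- data.frame(site = site, old_rate = old, new_rate = eps[site],
                           flux = 1 / sum(1 / eps))
  }
  res <- if (k > 0L) do.call(rbind, out) else
    data.frame(site = integer(), old_rate = numeric(), new_rate = numeric(),
               flux = numeric())
  attr(res, "profile") <- rate_profile(eps, profile$reinit_prob)
  res
}
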