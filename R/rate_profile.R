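#' Per-codon elongation rate profile for one mRNA template
#'
#' A `rate_profile` bundles the per-codon first-order rate constants
#' \eqn{\epsilon_1 \ldots \epsilon_d} (units 1/time) of a single template
#' with the reinitiation probability \eqn{\lambda} (the chance that a
#' ribosome reaching the termination codon re-enters the same template at
#' the initiation site, modelling the circular/closed-loop configuration of
#' eukaryotic polysomes) and a scale \eqn{\alpha} (1/time) that converts
#' rates into per-step transition probabilities via
#' \eqn{\alpha p_i = \epsilon_i}.
#'
#' Sites are numbered 1-based: site 1 is the initiation codon, site `d` the
#' termination codon. Continuous-time quantities (propagators, steady
#' states, fluxes) do not depend on `alpha`; it only enters the discrete
#' transition matrix representation.
#'
#' @param epsilons numeric vector of `d >= 2` positive rates.
#' @param reinit_prob reinitiation probability \eqn{\lambda} in `[0, 1]`.
#'   `0` describes an open (prokaryotic / short-lived) template, `1` a fully
#'   circular template with ribosome recycling.
#' @param alpha positive scale with `epsilons / alpha <= 1`. Defaults to
#'   `1.2 * max(epsilons)` so that every step probability is below 1.
#' @return an object of class `rate_profile` with fields `epsilons`,
#'   `reinit_prob`, `alpha` and the derived codon count `d`.
#' @examples
#' pr <- rate_profile(c(2, 3), reinit_prob = 1)
#' build_generator(pr)
#' @export
rate_profile <- function(epsilons, reinit_prob = 0, alpha = NULL) {
  epsilons <- as.numeric(epsilons)
  if (length(epsilons) < 2L) {
    stop("a rate profile needs at least d = 2 codons", call. = FALSE)
  }
  if (any(!is.finite(epsilons)) || any(epsilons <= 0)) {
    bad <- which(!is.finite(epsilons) | epsilons <= 0)[1L]
    stop(sprintf("epsilon at site %d must be a positive finite rate", bad),
         call. = FALSE)
  }
  if (!is.numeric(reinit_prob) || length(reinit_prob) != 1L ||
      is.na(reinit_prob) || reinit_prob < 0 || reinit_prob > 1) {
    stop("reinit_prob (lambda) must be a single value in [0, 1]",
         call. = FALSE)
  }
  if (is.null(alpha)) alpha <- 1.2 * max(epsilons)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0) {
    stop("alpha must be a single positive rate", call. = FALSE)
  }
  p <- epsilons / alpha
  if (any(p > 1)) {
    bad <- which(p > 1)[1L]
    stop(sprintf(
      "step probability p_%d = %.4g exceeds 1: alpha = %.4g is too small for epsilon_%d = %.4g",
      bad, p[bad], alpha, bad, epsilons[bad]), call. = FALSE)
  }
  structure(
    list(epsilons = epsilons, reinit_prob = reinit_prob, alpha = alpha,
         d = length(epsilons)),
    class = "rate_profile"
  )
}

#' @export
print.rate_profile <- function(x, ...) {
  cat(sprintf("<rate_profile> d = %d codons, lambda = %g, alpha = %g\n",
              x$d, x$reinit_prob, x$alpha))
  cat("  epsilons: ", paste(signif(utils::head(x$epsilons, 8L), 4),
                            collapse = ", "),
      if (x$d > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

is_rate_profile <- function(x) inherits(x, "rate_profile")

stopifnot_profile <- function(profile) {
  if (!is_rate_profile(profile)) {
    stop("expected a rate_profile object; see ?rate_profile", call. = FALSE)
  }
  invisible(profile)
}

#' Probability state vector of the lead ribosome
#'
#' `occupancy_vector` stores \eqn{V_i(t)}, the probability that the lead
#' ribosome of a template sits at codon `i` at time `t`. When
#' `reinit_prob = 1` the chain is conservative and the entries sum to 1;
#' for `reinit_prob < 1` probability mass leaks to the free-ribosome pool
#' at termination, so the sum may be below 1.
#'
#' @param probs numeric vector of `d` nonnegative probabilities (entries in
#'   `[-tol, 1 + tol]` are accepted and clipped to `[0, 1]`).
#' @param time nonnegative time at which the state was evaluated.
#' @param tol numerical slack for validation.
#' @return object of class `occupancy_vector` with fields `probs`, `time`,
#'   `d`.
#' @export
occupancy_vector <- function(probs, time = 0, tol = 1e-8) {
  probs <- as.numeric(probs)
  if (length(probs) < 2L) stop("need d >= 2 entries", call. = FALSE)
  if (any(!is.finite(probs))) stop("occupancy entries must be finite", call. = FALSE)
  if (any(probs < -tol)) {
    stop("occupancy entries must be nonnegative (within tolerance)", call. = FALSE)
  }
  if (sum(probs) > 1 + tol) {
    stop("occupancy entries must sum to at most 1 (within tolerance)", call. = FALSE)
  }
  if (!is.numeric(time) || length(time) != 1L || is.na(time) || time < 0) {
    stop("time must be a single nonnegative value", call. = FALSE)
  }
  probs <- pmin(pmax(probs, 0), 1)
  structure(list(probs = probs, time = time, d = length(probs)),
            class = "occupancy_vector")
}

#' @export
print.occupancy_vector <- function(x, ...) {
  cat(sprintf("<occupancy_vector> d = %d, t = %g, total mass = %.6g\n",
              x$d, x$time, sum(x$probs)))
  invisible(x)
}

#' Transcript and protein decay parameters
#'
#' First-order decay of the mRNA template with rate constant `c`
#' (`mrna_decay_rate`), optional first-order decay of the completed-protein
#' pool, and the mean ribosome spacing `R` (codons between successive
#' ribosomes) used to convert lead-ribosome progress into ribosome loading.
#'
#' @param mrna_decay_rate nonnegative rate `c` (1/time).
#' @param protein_decay_rate nonnegative rate (1/time) at which fully
#'   formed proteins decay.
#' @param ribosome_spacing spacing `R >= 1` in codons.
#' @return object of class `decay_model`.
#' @export
decay_model <- function(mrna_decay_rate = 0, protein_decay_rate = 0,
                        ribosome_spacing = 1) {
  vals <- c(mrna_decay_rate, protein_decay_rate, ribosome_spacing)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("decay rates must be finite and nonnegative", call. = FALSE)
  }
  if (ribosome_spacing < 1) stop("ribosome_spacing R must be >= 1", call. = FALSE)
  structure(list(mrna_decay_rate = mrna_decay_rate,
                 protein_decay_rate = protein_decay_rate,
                 ribosome_spacing = ribosome_spacing),
            class = "decay_model")
}

#' @export
print.decay_model <- function(x, ...) {
  cat(sprintf("<decay_model> c = %g, protein decay = %g, R = %g\n",
              x$mrna_decay_rate, x$protein_decay_rate, x$ribosome_spacing))
  invisible(x)
}

#' Read / write a rate profile
#'
#' Two plain-text serializations are supported: a JSON object
#' `{"epsilons": [...], "lambda": x, "alpha": x}` and a one-column CSV of
#' rate constants with header `epsilon` (in which case `lambda` and `alpha`
#' take their constructor defaults).
#'
#' @param path file to read or write; format chosen by extension
#'   (`.json` vs `.csv`).
#' @param profile a [rate_profile()].
#' @return `read_rate_profile` returns a `rate_profile`;
#'   `write_rate_profile` returns `path` invisibly.
#' @export
read_rate_profile <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    unknown <- setdiff(names(obj), c("epsilons", "lambda", "alpha"))
    if (length(unknown)) {
      stop(sprintf("unknown profile fields: %s", paste(unknown, collapse = ", ")),
           call. = FALSE)
    }
    rate_profile(obj$epsilons,
                 reinit_prob = if (is.null(obj$lambda)) 0 else obj$lambda,
                 alpha = obj$alpha)
  } else {
    tab <- utils::read.csv(path)
    if (!"epsilon" %in% names(tab)) {
      stop("profile CSV must have a column named 'epsilon'", call. = FALSE)
    }
    rate_profile(tab$epsilon)
  }
}

#' @rdname read_rate_profile
#' @export
write_rate_profile <- function(profile, path) {
  stopifnot_profile(profile)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(epsilons = profile$epsilons, lambda = profile$reinit_prob,
           alpha = profile$alpha),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(data.frame(epsilon = profile$epsilons), path,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
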