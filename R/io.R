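#' Load and validate a run configuration
#'
#' Reads a JSON configuration describing a simulation or fitting run and
#' validates it field by field. Unknown keys are rejected, defaults are
#' filled, and a seed is mandatory (every stochastic entry point in the
#' package is seed-controlled). The recognized top-level keys are:
#'
#' * `family`, `params`, `d`, `n`, `seed` — the rate-ensemble recipe
#'   (see [rate_ensemble_spec()]); optional `reinit_prob`,
#'   `per_site_means`, `slow_sites`, `correlation`, `truncation`.
#' * `decay` — optional object with `mrna_decay_rate`,
#'   `protein_decay_rate`, `ribosome_spacing`.
#' * `times` — optional simulation time grid (default `c(1, 2, 3)` mean
#'   traversals, filled at run time).
#' * `method` — propagation method (default `"auto"`).
#' * `metric` — protein-output metric (default `"terminal_occupancy"`).
#' * `out` — optional output prefix.
#'
#' @param path path to a JSON file.
#' @return a validated list with class `ribowalk_config`; its `$spec`
#'   element is a ready [rate_ensemble_spec()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- c("family", "params", "d", "n", "seed", "reinit_prob",
               "per_site_means", "slow_sites", "correlation", "truncation",
               "decay", "times", "method", "metric", "out")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(cfg$seed)) {
    stop("config field 'seed' is required (reproducibility is mandatory)",
         call. = FALSE)
  }
  if (!is.null(cfg$reinit_prob) &&
      (cfg$reinit_prob < 0 || cfg$reinit_prob > 1)) {
    stop("config field 'reinit_prob' (lambda) must lie in [0, 1]",
         call. = FALSE)
  }
  slow <- cfg$slow_sites
  if (!is.null(slow) && is.data.frame(slow)) {
    slow <- lapply(seq_len(nrow(slow)),
                   function(i) list(site = slow$site[i], mean = slow$mean[i]))
  }
  corr <- cfg$correlation
  if (!is.null(corr)) corr <- as.list(corr)
  spec <- rate_ensemble_spec(
    family = cfg$family,
    params = as.list(cfg$params),
    d = cfg$d, n_templates = cfg$n, seed = cfg$seed,
    reinit_prob = if (is.null(cfg$reinit_prob)) 1 else cfg$reinit_prob,
    per_site_means = cfg$per_site_means,
    slow_sites = slow, correlation = corr,
    truncation = if (is.null(cfg$truncation)) "resample" else cfg$truncation)
  decay <- if (is.null(cfg$decay)) decay_model() else {
    dl <- as.list(cfg$decay)
    do.call(decay_model, dl[names(dl) %in% c("mrna_decay_rate",
                                             "protein_decay_rate",
                                             "ribosome_spacing")])
  }
  structure(list(spec = spec, decay = decay,
                 times = cfg$times,
                 method = if (is.null(cfg$method)) "auto" else cfg$method,
                 metric = if (is.null(cfg$metric)) "terminal_occupancy" else cfg$metric,
                 out = cfg$out),
            class = "ribowalk_config")
}

#' Write a run configuration
#'
#' @param config a `ribowalk_config` or plain list of config fields.
#' @param path output JSON path.
#' @return `path` invisibly.
#' @export
write_config <- function(config, path) {
  if (inherits(config, "ribowalk_config")) {
    sp <- config$spec
    config <- list(family = sp$family, params = sp$params, d = sp$d,
                   n = sp$n_templates, seed = sp$seed,
                   reinit_prob = sp$reinit_prob,
                   per_site_means = sp$per_site_means,
                   slow_sites = sp$slow_sites, correlation = sp$correlation,
                   truncation = sp$truncation,
                   decay = unclass(config$decay), times = config$times,
                   method = config$method, metric = config$metric,
                   out = config$out)
  }
  config <- config[!vapply(config, is.null, logical(1))]
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Generate deterministic test fixtures
#'
#' Writes small, fully deterministic input files used by examples, tests
#' and the command-line interface:
#'
#' * `tiny_profile` — a `d = 5` one-column rate CSV (header `epsilon`).
#' * `steady_small` — a JSON ensemble config: gamma(shape 10, scale 5)
#'   rates, `d = 30`, 500 templates, circular boundary.
#' * `slow_codon` — the stalling construction: per-site means drawn
#'   uniformly in `[50, 150]` except site 20 whose mean is set near zero
#'   (1.0), `d = 30`.
#' * `mixture_sample` — a one-column CSV of 5,000 draws from a known
#'   0.7/0.3 two-lognormal mixture, for exercising the fitting layer.
#'
#' Outputs are bit-identical across runs at a fixed seed.
#'
#' @param kind one of the four fixture kinds.
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @return the path(s) written, invisibly.
#' @export
generate_fixtures <- function(kind = c("tiny_profile", "steady_small",
                                       "slow_codon", "mixture_sample"),
                              seed = 1, dir = ".") {
  kind <- match.arg(kind)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, paste0(kind, switch(kind,
    tiny_profile = ".csv", mixture_sample = ".csv", ".json")))
  with_seed(seed, {
    switch(kind,
      tiny_profile = {
        eps <- round(stats::rgamma(5, shape = 10, scale = 5), 6)
        utils::write.csv(data.frame(epsilon = eps), path,
                         row.names = FALSE, quote = FALSE)
      },
      steady_small = {
        jsonlite::write_json(
          list(family = "gamma", params = list(shape = 10, scale = 5),
               d = 30, n = 500, seed = seed, reinit_prob = 1),
          path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      },
      slow_codon = {
        means <- round(stats::runif(30, 50, 150), 6)
        means[20] <- 1.0
        jsonlite::write_json(
          list(family = "gamma", params = list(shape = 10, scale = 5),
               d = 30, n = 500, seed = seed, reinit_prob = 1,
               per_site_means = means,
               slow_sites = list(list(site = 20, mean = 1.0))),
          path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      },
      mixture_sample = {
        n <- 5000L
        comp <- stats::runif(n) < 0.7
        x <- ifelse(comp, stats::rlnorm(n, 0, 0.5), stats::rlnorm(n, 2.5, 0.4))
        utils::write.csv(data.frame(value = signif(x, 12)), path,
                         row.names = FALSE, quote = FALSE)
      })
  })
  invisible(path)
}

#' Write result tables and a run manifest
#'
#' Writes each table in `tables` as `<prefix>_<name>.csv` (header-only
#' when empty) and a JSON manifest `<prefix>_manifest.json` recording the
#' seed, configuration hash, package and R versions, and any counts passed
#' in `extra` (e.g. dropped templates). Every run is reproducible from its
#' manifest plus the config it hashes.
#'
#' @param tables named list of data.frames.
#' @param prefix output path prefix.
#' @param config optional config (list) to hash into the manifest.
#' @param seed seed to record.
#' @param extra named list of extra manifest entries.
#' @return character vector of paths written, invisibly.
#' @export
write_results <- function(tables, prefix, config = NULL, seed = NULL,
                          extra = list()) {
  stopifnot(is.list(tables))
  dir <- dirname(prefix)
  if (nzchar(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (nm in names(tables)) {
    p <- paste0(prefix, "_", nm, ".csv")
    utils::write.csv(tables[[nm]], p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  cfg_hash <- if (is.null(config)) NA_character_ else {
    # stable content hash of the serialized config
    sum_ <- sum(utf8ToInt(jsonlite::toJSON(config, auto_unbox = TRUE,
                                           digits = NA)) *
                  seq_along(utf8ToInt(jsonlite::toJSON(config,
                                                       auto_unbox = TRUE,
                                                       digits = NA))))
    sprintf("%x", sum_)
  }
  manifest <- c(list(seed = seed, config_hash = cfg_hash,
                     package = "ribowalk",
                     package_version = as.character(utils::packageVersion("ribowalk")),
                     r_version = R.version.string,
                     tables = names(tables)),
                extra)
  mp <- paste0(prefix, "_manifest.json")
  jsonlite::write_json(manifest[!vapply(manifest, is.null, logical(1))], mp,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, mp))
}
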