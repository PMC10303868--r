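#' Configuration for the synthetic-cohort generator
#'
#' Bundles and validates the parameters of [simulate_cohort()]. The
#' defaults describe a mid-sized retrospective transcriptomic cohort:
#' 200 patients, 1000 genes, 100 gene sets of 15-25 genes, unit latent
#' pathway activity and gene noise, an exponential baseline hazard, and
#' 30% independent censoring.
#'
#' @param n_samples Number of patients (default 200).
#' @param n_genes Number of genes (default 1000).
#' @param n_sets Number of gene sets (default 100).
#' @param set_size Integer range `c(min, max)` of set sizes (default
#'   `c(15, 25)`).
#' @param planted_sets Named numeric vector mapping planted set indices
#'   (as character or integer positions 1..n_sets) to their
#'   activity-to-hazard log-hazard coefficients beta; empty for a global
#'   null.
#' @param activity_sd SD of the latent per-sample pathway activity
#'   (default 1).
#' @param loading Loading of member-gene expression on the latent
#'   activity (default 1).
#' @param noise_sd SD of gene-level Gaussian noise (default 1).
#' @param baseline_hazard Exponential baseline rate lambda (default 0.1,
#'   i.e. median null survival ~ 6.9 time units).
#' @param censoring_rate Target fraction of censored patients, in
#'   \[0, 1) (default 0.3).
#' @param shape Weibull shape of the baseline hazard; 1 (default) gives
#'   the exponential model.
#' @param covariate Optional list `list(type = "binary"|"continuous",
#'   beta = <log-HR>)` adding a clinical confounder with its own effect.
#' @param seed Integer seed driving all randomness.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 200, n_genes = 1000, n_sets = 100,
                       set_size = c(15, 25), planted_sets = numeric(),
                       activity_sd = 1, loading = 1, noise_sd = 1,
                       baseline_hazard = 0.1, censoring_rate = 0.3,
                       shape = 1, covariate = NULL, seed = 1) {
  stopifnot(n_samples >= 2, n_genes >= 2, n_sets >= 1,
            length(set_size) == 2, set_size[1] >= 2,
            set_size[2] >= set_size[1], set_size[2] <= n_genes,
            activity_sd > 0, noise_sd >= 0, baseline_hazard > 0,
            censoring_rate >= 0, censoring_rate < 1, shape > 0)
  if (length(planted_sets) > 0) {
    idx <- as.integer(names(planted_sets) %||% seq_along(planted_sets))
    if (is.null(names(planted_sets))) {
      stop_ps("planted_sets must be a named vector: names are set indices")
    }
    idx <- as.integer(names(planted_sets))
    if (anyNA(idx) || any(idx < 1) || any(idx > n_sets)) {
      stop_ps("planted set index out of range 1..", n_sets)
    }
  }
  structure(list(n_samples = n_samples, n_genes = n_genes, n_sets = n_sets,
                 set_size = as.integer(set_size), planted_sets = planted_sets,
                 activity_sd = activity_sd, loading = loading,
                 noise_sd = noise_sd, baseline_hazard = baseline_hazard,
                 censoring_rate = censoring_rate, shape = shape,
                 covariate = covariate, seed = as.integer(seed)),
            class = "sim_config")
}

# Solve for the censoring rate c of an independent exponential censoring
# time such that the expected censored fraction over the cohort equals the
# target. For exponential event times with per-sample rate r_i,
# P(censored_i) = c / (c + r_i); the mean over i is monotone in c.
solve_censoring_rate <- function(rates, target) {
  if (target <= 0) return(0)
  f <- function(cr) mean(cr / (cr + rates)) - target
  lo <- min(rates) * 1e-8
  hi <- max(rates) * 1e8
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Simulate a cohort with planted pathway-hazard structure
#'
#' Generates a gene-set collection, an expression matrix and a clinical
#' table under a known proportional-hazards model. Each planted set has a
#' per-sample latent activity `a_s ~ N(0, activity_sd)`; its member genes
#' follow `expression = baseline + loading * a_s + N(0, noise_sd)` while
#' all other genes are pure noise around their baseline. Gene baselines
#' are log-normal so the matrix resembles linear-scale RNA abundance.
#' Event times are drawn from a Weibull (default exponential)
#' proportional-hazards model with linear predictor
#' `sum_s beta_s * a_s` plus any covariate term; censoring times are
#' independent exponentials with their rate solved numerically so that
#' the expected censored fraction matches `censoring_rate`. Everything is
#' driven by `config$seed`, so a fixed config reproduces the cohort
#' bit-identically.
#'
#' @param config A `sim_config`.
#' @return List with `cohort` (a [build_cohort()]-style `cohort`), `sets`
#'   (the `gene_set_collection`) and `truth` (planted set names and betas,
#'   the latent activity matrix, and the realized censored fraction).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  with_seed(cf$seed, {
    genes <- sprintf("g%04d", seq_len(cf$n_genes))
    samples <- sprintf("s%04d", seq_len(cf$n_samples))
    set_names <- sprintf("SET%04d", seq_len(cf$n_sets))
    size_range <- seq(cf$set_size[1], cf$set_size[2])
    sizes <- if (length(size_range) == 1) {
      rep(size_range, cf$n_sets)  # avoid sample()'s scalar expansion
    } else {
      sample(size_range, cf$n_sets, replace = TRUE)
    }
    sets <- lapply(sizes, function(k) sample(genes, k))
    names(sets) <- set_names

    planted_idx <- if (length(cf$planted_sets) > 0)
      as.integer(names(cf$planted_sets)) else integer()
    betas <- as.numeric(cf$planted_sets)

    baseline <- stats::rlnorm(cf$n_genes, meanlog = 3, sdlog = 1)
    expr <- matrix(stats::rnorm(cf$n_genes * cf$n_samples, sd = cf$noise_sd),
                   cf$n_genes, cf$n_samples,
                   dimnames = list(genes, samples)) + baseline

    activity <- matrix(0, length(planted_idx), cf$n_samples,
                       dimnames = list(set_names[planted_idx], samples))
    eta <- rep(0, cf$n_samples)
    for (p in seq_along(planted_idx)) {
      a <- stats::rnorm(cf$n_samples, sd = cf$activity_sd)
      activity[p, ] <- a
      members <- match(sets[[planted_idx[p]]], genes)
      expr[members, ] <- expr[members, ] +
        cf$loading * matrix(a, length(members), cf$n_samples, byrow = TRUE)
      eta <- eta + betas[p] * a
    }

    clinical <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
    if (!is.null(cf$covariate)) {
      x <- if (cf$covariate$type == "binary") {
        stats::rbinom(cf$n_samples, 1, 0.5)
      } else {
        stats::rnorm(cf$n_samples)
      }
      eta <- eta + cf$covariate$beta * x
      clinical$covariate <- x
    }

    rates <- cf$baseline_hazard * exp(eta)
    # inverse-CDF Weibull PH sampling; shape 1 reduces to the exponential
    u <- stats::runif(cf$n_samples)
    t_event <- (-log(u) / rates)^(1 / cf$shape)
    if (cf$censoring_rate > 0) {
      # calibrate on the event-time distribution scale
      eff_rates <- 1 / vapply(seq_len(cf$n_samples), function(i) {
        (1 / rates[i])^(1 / cf$shape) * gamma(1 + 1 / cf$shape)
      }, numeric(1))
      c_rate <- solve_censoring_rate(eff_rates, cf$censoring_rate)
      t_cens <- stats::rexp(cf$n_samples, rate = c_rate)
    } else {
      t_cens <- rep(Inf, cf$n_samples)
    }
    clinical$time <- pmin(t_event, t_cens)
    clinical$event <- as.numeric(t_event <= t_cens)

    clinical <- clinical[, c("sample_id", "time", "event",
                             setdiff(colnames(clinical),
                                     c("sample_id", "time", "event")))]
    cohort <- structure(list(expression = expr, clinical = clinical),
                        class = "cohort")
    truth <- list(planted_sets = set_names[planted_idx], betas = betas,
                  activity = activity,
                  censored_fraction = mean(clinical$event == 0),
                  config = cf)
    list(cohort = cohort,
         sets = new_gene_set_collection(sets, source_label = "synthetic"),
         truth = truth)
  })
}

#' Null screen p-values across simulation replicates
#'
#' Simulates cohorts with no planted hazard structure, scores the sets,
#' runs the median-cutoff screen and pools the raw likelihood-ratio
#' p-values. Used to check the type-I calibration of the screen: under
#' the global null the pooled p-values should be approximately
#' Uniform(0, 1).
#'
#' @param config A `sim_config` with empty `planted_sets`; its seed seeds
#'   replicate `r` as `seed + r`.
#' @param n_replicates Number of simulation replicates.
#' @param method Scoring method passed to [pathway_scores()].
#' @return Numeric matrix, replicates x features, of raw `lr_p` values.
#' @export
simulate_null_pvalues <- function(config, n_replicates = 50,
                                  method = "ssgsea") {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$planted_sets) > 0) {
    stop_ps("null calibration requires a config without planted sets")
  }
  out <- NULL
  for (r in seq_len(n_replicates)) {
    cf <- config
    cf$seed <- config$seed + r
    sim <- simulate_cohort(cf)
    scores <- suppressWarnings(
      pathway_scores(sim$cohort$expression, sim$sets, method = method))
    tab <- screen_features(sim$cohort, unclass(scores),
                           feature_kind = "pathway")
    p <- stats::setNames(tab$lr_p, tab$feature)[rownames(scores)]
    if (is.null(out)) {
      out <- matrix(NA_real_, n_replicates, length(p),
                    dimnames = list(NULL, names(p)))
    }
    out[r, names(p)] <- p
  }
  out
}
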