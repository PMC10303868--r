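#' Kaplan-Meier product-limit estimates per patient group
#'
#' @param time Non-negative survival/follow-up times.
#' @param event Event indicator (1 = event observed, 0 = censored).
#' @param labels Group label per sample (factor or vector), e.g. from
#'   [dichotomize()]. A single shared group is allowed.
#' @return A list of `km_estimate` objects, one per group, each with
#'   `time` (ordered distinct observed times), `surv` (product-limit
#'   S(t)), `n_risk`, `n_event`, `n_censor`, `greenwood_se` and `group`.
#' @export
km_estimate <- function(time, event, labels = NULL) {
  check_surv_args(time, event)
  if (is.null(labels)) labels <- rep("all", length(time))
  labels <- as.factor(labels)
  if (length(labels) != length(time)) stop_ps("labels length must match time")
  if (any(table(labels) == 0)) stop_ps("empty group in labels")
  out <- lapply(levels(labels), function(g) {
    idx <- labels == g
    sf <- survival::survfit(survival::Surv(time[idx], event[idx]) ~ 1,
                            conf.type = "none")
    structure(list(time = sf$time, surv = sf$surv, n_risk = sf$n.risk,
                   n_event = sf$n.event, n_censor = sf$n.censor,
                   greenwood_se = sf$surv * sf$std.err,  # std.err is SE of log S
                   group = g),
              class = "km_estimate")
  })
  names(out) <- levels(labels)
  out
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("km_estimate (group %s): %d time points, %d events\n",
              dQuote(x$group), length(x$time), sum(x$n_event)))
  invisible(x)
}

#' Mantel-Haenszel log-rank test between groups
#'
#' @inheritParams km_estimate
#' @return List with `statistic` (chi-square), `df` (groups - 1) and `p`.
#' @export
logrank_test <- function(time, event, labels) {
  check_surv_args(time, event)
  labels <- as.factor(as.vector(labels))
  if (nlevels(droplevels(labels)) < 2) stop_ps("log-rank test needs >= 2 groups")
  if (sum(event) < 1) stop_ps("log-rank test needs >= 1 event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ labels)
  df <- length(sd$n) - 1
  list(statistic = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

check_surv_args <- function(time, event) {
  if (length(time) != length(event)) stop_ps("time and event lengths differ")
  if (anyNA(time) || anyNA(event)) stop_ps("time/event must not contain NA")
  if (any(time < 0)) stop_ps("times must be >= 0")
  if (!all(event %in% c(0, 1))) stop_ps("event must be coded 0/1")
}

#' Dichotomize (or quartile-split) a score vector
#'
#' Median rule: samples with score <= median are labelled `"low"`, the rest
#' `"high"` (ties at the boundary go to the low group). Quartile rule: four
#' ordered groups `Q1`-`Q4` by the 25/50/75% quantile boundaries, boundary
#' ties assigned downward. Value rule: a user threshold with the same `<=`
#' convention.
#'
#' The median and quartile rules depend on scores only through their ranks,
#' so they are invariant to strictly monotone transforms.
#'
#' @param scores Numeric score per sample (named vector names are kept).
#' @param rule One of `"median"`, `"quartile"`, `"value"`.
#' @param threshold Numeric threshold, required for `rule = "value"`.
#' @return A `group_assignment`: factor of labels with attributes `rule`
#'   and `thresholds`.
#' @export
dichotomize <- function(scores, rule = c("median", "quartile", "value"),
                        threshold = NULL) {
  rule <- match.arg(rule)
  if (anyNA(scores)) stop_ps("scores must not contain NA")
  if (rule != "value" && length(unique(scores)) < 2) {
    stop_ps("cannot split constant scores")
  }
  if (rule == "median") {
    thr <- stats::median(scores)
    labels <- factor(ifelse(scores <= thr, "low", "high"),
                     levels = c("low", "high"))
    if (nlevels(droplevels(labels)) < 2) {
      stop_ps("median split leaves an empty group (scores too tied)")
    }
  } else if (rule == "quartile") {
    thr <- stats::quantile(scores, c(0.25, 0.5, 0.75), names = FALSE)
    labels <- cut(scores, breaks = c(-Inf, thr, Inf),
                  labels = c("Q1", "Q2", "Q3", "Q4"), right = TRUE)
    if (any(table(labels) == 0)) {
      stop_ps("quartile split produces an empty group (too many ties)")
    }
  } else {
    if (is.null(threshold)) stop_ps("rule 'value' requires a threshold")
    thr <- threshold
    labels <- factor(ifelse(scores <= thr, "low", "high"),
                     levels = c("low", "high"))
    if (nlevels(droplevels(labels)) < 2) {
      stop_ps("threshold places all samples in one group")
    }
  }
  names(labels) <- names(scores)
  structure(labels, rule = rule, thresholds = thr,
            class = c("group_assignment", "factor"))
}

#' Maximally selected log-rank cutpoint
#'
#' Evaluates the standardized log-rank statistic at every candidate split
#' between consecutive distinct score values whose resulting groups both
#' contain at least `ceil(minprop * n)` samples, and returns the midpoint of
#' the maximizing gap. The associated naive p-value is biased by the
#' selection of the maximum and is flagged as such; no selection-bias
#' correction is applied.
#'
#' @inheritParams km_estimate
#' @param scores Numeric score per sample.
#' @param minprop Minimum proportion of samples on each side of any
#'   candidate cutpoint (default 0.1).
#' @return List with `threshold` (midpoint of the best gap), `statistic`
#'   (maximal chi-square), `p_naive` (uncorrected, selection-biased),
#'   `selection_biased = TRUE`, and the full `candidates` table.
#' @export
optimal_cutpoint <- function(scores, time, event, minprop = 0.1) {
  check_surv_args(time, event)
  if (length(scores) != length(time)) stop_ps("scores length must match time")
  if (minprop <= 0 || minprop >= 0.5) stop_ps("minprop must be in (0, 0.5)")
  n <- length(scores)
  min_n <- ceiling(minprop * n)
  sv <- sort(unique(scores))
  if (length(sv) < 2) stop_ps("cannot place a cutpoint in constant scores")
  cand <- (sv[-length(sv)] + sv[-1]) / 2
  n_low <- vapply(cand, function(ct) sum(scores <= ct), integer(1))
  admissible <- n_low >= min_n & (n - n_low) >= min_n
  if (!any(admissible)) stop_ps("no admissible cutpoint under minprop = ", minprop)
  cand <- cand[admissible]
  stat <- vapply(cand, function(ct) {
    g <- factor(scores <= ct, levels = c(TRUE, FALSE))
    sd <- survival::survdiff(survival::Surv(time, event) ~ g)
    unname(sd$chisq)
  }, numeric(1))
  best <- which.max(stat)  # ties resolved to the smallest threshold
  list(threshold = cand[best], statistic = stat[best],
       p_naive = stats::pchisq(stat[best], df = 1, lower.tail = FALSE),
       selection_biased = TRUE,
       candidates = data.frame(threshold = cand, statistic = stat))
}

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Cox partial likelihood (Efron tie correction by default)
#' over the supplied design columns. Categorical columns are expanded to
#' treatment contrasts with the first level as reference. Optional
#' multiplicative interactions add product terms between named column
#' pairs. Rows with missing design values are dropped for this fit only,
#' with a message.
#'
#' @inheritParams km_estimate
#' @param design Data frame of covariates (numeric, factor or character),
#'   one row per sample; group indicators go in as factors.
#' @param ties Tie-handling method, `"efron"` (default) or `"breslow"`.
#' @param interactions Optional character vector of `"a:b"` column pairs to
#'   add as product terms (multiplicative model).
#' @return A `cox_result`: list with `coefficients`, `hazard_ratios`,
#'   `se`, `wald_z`, `wald_p`, `ci_low`/`ci_high` (95%, HR scale),
#'   `loglik_null`, `loglik_full`, `lr_statistic`, `lr_p`, `n`, `n_events`,
#'   `ties`, `iter`, and the underlying `survival::coxph` fit in `$fit`.
#' @export
cox_fit <- function(time, event, design, ties = c("efron", "breslow"),
                    interactions = NULL) {
  ties <- match.arg(ties)
  check_surv_args(time, event)
  if (!is.data.frame(design)) design <- as.data.frame(design)
  if (nrow(design) != length(time)) stop_ps("design rows must match time length")
  if (sum(event) < 1) stop_ps("no events observed; Cox model is not estimable")

  df <- design
  df[] <- lapply(df, function(x) if (is.character(x)) factor(x) else x)
  complete <- stats::complete.cases(df)
  if (!all(complete)) {
    message(sprintf("cox_fit: dropped %d sample(s) with missing covariate values",
                    sum(!complete)))
    df <- df[complete, , drop = FALSE]
    time <- time[complete]
    event <- event[complete]
  }
  const <- vapply(df, function(x) length(unique(x)) < 2, logical(1))
  if (any(const)) {
    stop_ps("constant design column(s): ",
            paste(colnames(df)[const], collapse = ", "))
  }
  mm <- stats::model.matrix(~ ., data = df)
  if (qr(mm)$rank < ncol(mm)) stop_ps("design columns are collinear")

  terms <- colnames(df)
  if (!is.null(interactions)) {
    for (ia in interactions) {
      pair <- strsplit(ia, ":", fixed = TRUE)[[1]]
      if (length(pair) != 2 || !all(pair %in% colnames(df))) {
        stop_ps("interaction must name two design columns as 'a:b': ", ia)
      }
    }
    terms <- c(terms, interactions)
  }
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(terms, collapse = " + ")))
  df$time <- time
  df$event <- event
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = ties,
                    model = TRUE, x = TRUE, y = TRUE),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be infinite|out of iterations",
                conditionMessage(w), ignore.case = TRUE)) {
        stop_ps("Cox fit not estimable (monotone likelihood or non-convergence): ",
                conditionMessage(w))
      }
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  if (anyNA(beta)) stop_ps("Cox fit produced NA coefficients (singular design)")
  if (any(abs(beta) > 15)) {
    stop_ps("Cox fit diverging (|beta| > 15); likely perfect separation")
  }
  se <- sqrt(diag(fit$var))
  z <- beta / se
  df_model <- length(beta)
  lr <- 2 * (fit$loglik[2] - fit$loglik[1])
  structure(list(
    coefficients = beta,
    hazard_ratios = exp(beta),
    se = stats::setNames(se, names(beta)),
    wald_z = z,
    wald_p = 2 * stats::pnorm(-abs(z)),
    ci_low = exp(beta - stats::qnorm(0.975) * se),
    ci_high = exp(beta + stats::qnorm(0.975) * se),
    loglik_null = fit$loglik[1],
    loglik_full = fit$loglik[2],
    lr_statistic = lr,
    lr_p = stats::pchisq(lr, df = df_model, lower.tail = FALSE),
    df = df_model,
    n = fit$n,
    n_events = fit$nevent,
    ties = ties,
    iter = fit$iter,
    fit = fit
  ), class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("cox_result: n = %d, events = %d, ties = %s\n",
              x$n, x$n_events, x$ties))
  tab <- data.frame(coef = x$coefficients, HR = x$hazard_ratios,
                    se = x$se, z = x$wald_z, p = x$wald_p)
  print(tab, digits = 4)
  cat(sprintf("LR test: %.4g on %d df, p = %.4g\n",
              x$lr_statistic, x$df, x$lr_p))
  invisible(x)
}

#' Proportional-hazards and linearity diagnostics
#'
#' Tests the proportional-hazards assumption by correlating scaled
#' Schoenfeld residuals against a transform of event time (Kaplan-Meier
#' transform by default), per term and globally. For continuous design
#' columns it also summarizes martingale-residual linearity: the
#' correlation of the null-extended martingale residuals with the
#' covariate and with its square.
#'
#' @param fit A `cox_result` from [cox_fit()].
#' @param transform Time transform for the Schoenfeld test: `"km"`
#'   (default) or `"identity"`.
#' @return A `ph_diagnostics` list with `schoenfeld` (per-term and GLOBAL
#'   chi-square table) and `linearity` (per continuous covariate).
#' @export
ph_diagnostics <- function(fit, transform = c("km", "identity")) {
  stopifnot(inherits(fit, "cox_result"))
  transform <- match.arg(transform)
  if (fit$n_events < 3) stop_ps("PH diagnostics need >= 3 events")
  zph <- survival::cox.zph(fit$fit, transform = transform, global = TRUE)
  sch <- as.data.frame(zph$table)
  colnames(sch) <- c("chisq", "df", "p")

  mresid <- stats::residuals(fit$fit, type = "martingale")
  mf <- stats::model.frame(fit$fit)
  num_cols <- names(mf)[vapply(mf, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, c("time", "event"))
  num_cols <- num_cols[!vapply(mf[num_cols], inherits, logical(1), "Surv")]
  lin <- lapply(num_cols, function(v) {
    x <- mf[[v]]
    c(cor_linear = stats::cor(mresid, x),
      cor_quadratic = stats::cor(mresid, x^2))
  })
  names(lin) <- num_cols
  structure(list(schoenfeld = sch,
                 global_chisq = sch["GLOBAL", "chisq"],
                 global_p = sch["GLOBAL", "p"],
                 linearity = lin,
                 transform = transform),
            class = "ph_diagnostics")
}

#' @export
print.ph_diagnostics <- function(x, ...) {
  cat(sprintf("Schoenfeld PH test (time transform: %s)\n", x$transform))
  print(x$schoenfeld, digits = 4)
  invisible(x)
}
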