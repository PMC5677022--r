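# Survival analysis of score groups and the rank-adjacency matched-group
# selection that disentangles the score from raw mutation burden.
# KM/log-rank/Cox delegate to the survival package (Efron ties).

#' Kaplan-Meier product-limit estimate
#'
#' @param times follow-up times (years, >= 0).
#' @param events event indicators (TRUE/1 = death observed).
#' @return list of class `"survival_curve"`: `times`, `survival`,
#'   `at_risk`, `events` (the curve starts implicitly at S(0) = 1).
#' @export
km_estimate <- function(times, events) {
  if (!length(times)) stop("empty survival input", call. = FALSE)
  if (any(times < 0, na.rm = TRUE)) stop("negative times", call. = FALSE)
  events <- as.integer(as.logical(events))
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(list(times = sf$time, survival = sf$surv,
                 at_risk = sf$n.risk, events = sf$n.event, n = sf$n),
            class = "survival_curve")
}

#' Evaluate a survival curve at a time point
#'
#' Right-continuous step-function evaluation; S(0) = 1. A query beyond the
#' last observed time returns the last value with attribute
#' `extrapolated = TRUE`.
#'
#' @param curve [km_estimate()] result.
#' @param t time (years, >= 0).
#' @return survival probability at `t`.
#' @export
survival_rate_at <- function(curve, t) {
  if (t < 0) stop("t must be >= 0", call. = FALSE)
  idx <- which(curve$times <= t)
  val <- if (length(idx)) curve$survival[max(idx)] else 1
  extrap <- t > max(curve$times)
  structure(val, extrapolated = extrap)
}

#' Log-rank test across survival groups
#'
#' Standard observed-vs-expected log-rank over the pooled event times;
#' supports k groups (chi-squared reference with k - 1 df).
#'
#' @param group_labels group membership per subject (>= 2 groups).
#' @param times,events survival data as in [km_estimate()].
#' @return list with `statistic`, `df`, `p_value`, per-group `observed`
#'   and `expected` event counts.
#' @export
logrank_test <- function(group_labels, times, events) {
  g <- factor(group_labels)
  if (nlevels(g) < 2L)
    stop("log-rank test needs at least 2 groups", call. = FALSE)
  events <- as.integer(as.logical(events))
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ g)
  df <- nlevels(g) - 1L
  list(statistic = unname(sd_$chisq), df = df,
       p_value = stats::pchisq(sd_$chisq, df, lower.tail = FALSE),
       observed = sd_$obs, expected = sd_$exp, groups = levels(g))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization (Newton-type, Efron tie handling) with
#' Wald confidence intervals and p-values. Constant covariates are
#' rejected; non-convergence and likely separation (diverging
#' coefficients) are flagged, never silent.
#'
#' @param covariates data.frame or matrix of covariates (one column per
#'   covariate; factors allowed in a data.frame).
#' @param times,events survival data.
#' @param ties tie-handling method (default `"efron"`).
#' @return list of class `"cox_fit"`: `coefficients`, `hazard_ratios`,
#'   `ci_low`, `ci_high` (95%), `p_values`, `n`, `n_events`, `converged`,
#'   `separation`, and the underlying `fit`.
#' @export
cox_fit <- function(covariates, times, events, ties = "efron") {
  cov <- as.data.frame(covariates)
  if (!nrow(cov)) stop("no covariate rows", call. = FALSE)
  const <- vapply(cov, function(x) length(unique(x[!is.na(x)])) < 2L,
                  logical(1))
  if (any(const))
    stop("constant covariate(s): ",
         paste(colnames(cov)[const], collapse = ", "), call. = FALSE)
  events <- as.integer(as.logical(events))
  if (sum(events) < 1L) stop("no events observed", call. = FALSE)
  dat <- cbind(.time = times, .event = events, cov)
  warns <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(.time, .event) ~ ., data = dat,
                    ties = ties),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  separation <- any(grepl("infinite|did not converge", warns,
                          ignore.case = TRUE))
  if (separation)
    warning("possible separation: a coefficient may be diverging",
            call. = FALSE)
  sm <- summary(fit)
  ci <- suppressMessages(exp(stats::confint(fit)))
  structure(list(
    covariates = rownames(sm$coefficients),
    coefficients = sm$coefficients[, "coef"],
    hazard_ratios = exp(sm$coefficients[, "coef"]),
    ci_low = ci[, 1], ci_high = ci[, 2],
    p_values = sm$coefficients[, "Pr(>|z|)"],
    n = fit$n, n_events = fit$nevent,
    converged = !separation && fit$iter < 25L,
    separation = separation, fit = fit),
    class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (", x$n, " subjects, ", x$n_events,
      " events)\n", sep = "")
  tab <- data.frame(HR = round(x$hazard_ratios, 3),
                    `95% low` = round(x$ci_low, 3),
                    `95% high` = round(x$ci_high, 3),
                    p = signif(x$p_values, 3), check.names = FALSE)
  rownames(tab) <- x$covariates
  print(tab)
  if (!x$converged) cat("WARNING: fit did not converge cleanly\n")
  invisible(x)
}

#' Rank-adjacency matched-group selection
#'
#' Samples are ordered by the matching covariate (ascending, ties broken by
#' sample id for determinism) and scanned left to right: whenever two
#' consecutive still-unconsumed samples carry different group labels, the
#' pair is kept (one sample to each output group) and consumed. Unconsumed
#' samples are discarded. The result is two equal-size groups with nearly
#' identical covariate distributions, so group membership can be tested for
#' prognostic value independently of the covariate. By default adjacent
#' pairs are accepted in either label order; `direction = "a_first"`
#' restricts to pairs where the first-level label precedes the second.
#'
#' @param group_labels two-level labels per sample.
#' @param covariate matching covariate per sample.
#' @param sample_ids optional sample identifiers (default `S1..Sn`).
#' @param direction `"either"` (default) or `"a_first"`.
#' @return list of class `"matched_groups"`: `kept_group_a`,
#'   `kept_group_b` (sample ids, equal sizes), `discarded`, `pairs`,
#'   `balance_p` (two-sided Mann-Whitney on the kept covariates; `NA` when
#'   nothing is kept).
#' @export
matched_group_selection <- function(group_labels, covariate,
                                    sample_ids = NULL,
                                    direction = c("either", "a_first")) {
  direction <- match.arg(direction)
  g <- if (is.factor(group_labels)) group_labels else factor(group_labels)
  if (nlevels(g) != 2L)
    stop("matching needs exactly two group labels", call. = FALSE)
  n <- length(g)
  if (length(covariate) != n)
    stop("covariate must align with group labels", call. = FALSE)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  ord <- order(covariate, sample_ids)
  lab <- g[ord]; ids <- sample_ids[ord]; cv <- covariate[ord]
  consumed <- rep(FALSE, n)
  pair_of <- integer(0)
  i <- 1L
  while (i < n) {
    if (!consumed[i] && !consumed[i + 1L] && lab[i] != lab[i + 1L] &&
        (direction == "either" || lab[i] == levels(g)[1L])) {
      consumed[i] <- consumed[i + 1L] <- TRUE
      pair_of <- c(pair_of, i, i + 1L)
      i <- i + 2L
    } else i <- i + 1L
  }
  kept <- consumed
  a_idx <- which(kept & lab == levels(g)[1L])
  b_idx <- which(kept & lab == levels(g)[2L])
  balance_p <- NA_real_
  if (!any(kept)) {
    warning("no cross-label adjacency; matched groups are empty",
            call. = FALSE)
  } else {
    balance_p <- mw_test(cv[a_idx], cv[b_idx])$p_two
  }
  structure(list(kept_group_a = ids[a_idx], kept_group_b = ids[b_idx],
                 discarded = ids[!kept],
                 pairs = matrix(ids[pair_of], ncol = 2L, byrow = TRUE),
                 labels = stats::setNames(as.character(lab), ids),
                 covariate = stats::setNames(cv, ids),
                 group_levels = levels(g), balance_p = balance_p),
            class = "matched_groups")
}

#' Covariate balance test of matched groups
#'
#' Two-sided Mann-Whitney test of a covariate between the two kept groups
#' of a [matched_group_selection()] result.
#'
#' @param groups `matched_groups` object.
#' @param covariate named vector (names = sample ids); defaults to the
#'   matching covariate recorded in `groups`.
#' @return two-sided p-value.
#' @export
balance_test <- function(groups, covariate = NULL) {
  if (!length(groups$kept_group_a) || !length(groups$kept_group_b))
    stop("both kept groups must be non-empty", call. = FALSE)
  cv <- covariate %||% groups$covariate
  mw_test(cv[groups$kept_group_a], cv[groups$kept_group_b])$p_two
}
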