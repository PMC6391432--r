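#' Propensity model for relative-versus-control membership
#'
#' Logistic regression of group membership on age, age squared and a male
#' indicator; the fitted probabilities are the propensity scores used to
#' balance the nonlinear age and sex imbalances between sampled pedigree
#' relatives and population controls. Under complete (or quasi-complete)
#' separation the unpenalized fit is replaced by a Firth fit, which always
#' yields finite coefficients.
#'
#' @param age numeric ages (years).
#' @param sex `"male"`/`"female"` (or a factor / 1-2 coding as in PED
#'   files).
#' @param group logical or two-level vector; `TRUE`/`"relative"` is the
#'   modeled event.
#' @return list with `coefficients`, `scores` (per-individual propensity in
#'   (0,1)), and `method` (`"ml"` or `"firth"`).
#' @export
estimate_propensity <- function(age, sex, group) {
  g <- as_group01(group)
  male <- as_male01(sex)
  stopifnot(length(age) == length(g), length(male) == length(g))
  if (any(!is.finite(age))) stopf("estimate_propensity: non-finite ages")
  if (!any(g == 1) || !any(g == 0))
    stopf("estimate_propensity: both groups must be non-empty")
  X <- cbind(intercept = 1, age = age, age2 = age^2, male = male)
  fit <- suppressWarnings(stats::glm.fit(X, g, family = stats::binomial()))
  separated <- !fit$converged || any(abs(fit$coefficients) > 15) ||
    any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8)
  if (separated) {
    ff <- firth_logistic(X, g)
    beta <- stats::setNames(ff$coefficients$estimate, ff$coefficients$term)
    list(coefficients = beta,
         scores = stats::plogis(drop(X %*% beta)), method = "firth")
  } else {
    list(coefficients = fit$coefficients,
         scores = fit$fitted.values, method = "ml")
  }
}

as_group01 <- function(group) {
  if (is.logical(group)) return(as.integer(group))
  if (is.numeric(group)) { stopifnot(all(group %in% 0:1)); return(as.integer(group)) }
  g <- as.character(group)
  lev <- sort(unique(g))
  if (setequal(lev, c("control", "relative"))) return(as.integer(g == "relative"))
  if (length(lev) != 2) stopf("group must have exactly two levels")
  as.integer(g == lev[2])
}

as_male01 <- function(sex) {
  if (is.numeric(sex)) return(as.integer(sex == 1))
  as.integer(tolower(as.character(sex)) %in% c("male", "m", "1"))
}

#' Optimal propensity-score matching
#'
#' Pairs each member of the smaller group with a distinct member of the
#' larger group so that the total absolute propensity-score distance is
#' minimized over all feasible pairings ("optimal match selection", as
#' opposed to greedy nearest-neighbour matching). Because the cost is an
#' absolute difference of scalar scores, the optimal assignment is
#' non-crossing in sorted score order, and an exact O(nm) dynamic program
#' over the two sorted score sequences solves the assignment problem
#' exactly. With `exact_on_sex` the assignment is solved within each sex
#' stratum.
#'
#' @param scores numeric propensity scores.
#' @param group_labels two-level group vector (see [estimate_propensity()]).
#' @param sex optional sex vector, required when `exact_on_sex = TRUE`.
#' @param exact_on_sex match only within sex strata (default `FALSE`).
#' @return list with `pairs` (data frame: `relative`, `control` -- indices
#'   into the input vectors -- and `distance`) and `total_distance`.
#' @export
optimal_match <- function(scores, group_labels, sex = NULL,
                          exact_on_sex = FALSE) {
  g <- as_group01(group_labels)
  stopifnot(length(scores) == length(g))
  strata <- if (exact_on_sex) {
    if (is.null(sex)) stopf("optimal_match: sex required when exact_on_sex = TRUE")
    as_male01(sex)
  } else rep(0L, length(g))
  pairs <- NULL
  for (s in unique(strata)) {
    rel <- which(g == 1 & strata == s)
    ctl <- which(g == 0 & strata == s)
    if (!length(rel) || !length(ctl)) {
      warnf("optimal_match: stratum %s has an empty group; skipped", s)
      next
    }
    pr <- match_stratum(scores, rel, ctl)
    pairs <- rbind(pairs, pr)
  }
  if (is.null(pairs)) stopf("optimal_match: no matchable stratum")
  pairs <- pairs[order(pairs$relative), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs, total_distance = sum(pairs$distance))
}

# exact min-cost matching of the smaller set into the larger along sorted
# scores; f[i, j] = cost of matching the first i "small" units using the
# first j "large" units
match_stratum <- function(scores, rel, ctl) {
  swap <- length(rel) > length(ctl)
  small <- if (swap) ctl else rel
  large <- if (swap) rel else ctl
  so <- small[order(scores[small])]
  lo <- large[order(scores[large])]
  ns <- length(so); nl <- length(lo)
  f <- matrix(Inf, ns + 1, nl + 1)
  f[1, ] <- 0
  for (i in seq_len(ns)) {
    for (j in i:nl) {
      take <- f[i, j] + abs(scores[so[i]] - scores[lo[j]])
      skip <- if (j > i) f[i + 1, j] else Inf
      f[i + 1, j + 1] <- min(take, skip)
    }
  }
  # backtrack
  sel <- integer(ns)
  j <- nl
  for (i in ns:1) {
    while (j > i && f[i + 1, j + 1] == f[i + 1, j]) j <- j - 1
    sel[i] <- j
    j <- j - 1
  }
  rel_idx <- if (swap) lo[sel] else so
  ctl_idx <- if (swap) so else lo[sel]
  data.frame(relative = rel_idx, control = ctl_idx,
             distance = abs(scores[rel_idx] - scores[ctl_idx]))
}

wald_row <- function(term, est, se, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(term = term, estimate = est, se = se,
             ci_lower = est - z * se, ci_upper = est + z * se,
             p = 2 * stats::pnorm(-abs(est / se)), row.names = NULL)
}

#' Propensity-score-adjusted linear model for a polyclonal Ig variable
#'
#' Ordinary least squares of the quantitative variable on the group
#' indicator with the propensity score entered as a covariate. The group
#' coefficient is the adjusted difference in serum levels (mg/dL) in
#' relatives versus controls, with Wald (normal-quantile) confidence
#' interval and p-value. A propensity score that is constant or collinear
#' with the group indicator is dropped with a warning, in which case the
#' estimate reduces to the two-sample difference in means.
#'
#' @param y numeric outcome (mg/dL).
#' @param group two-level group vector.
#' @param ps propensity scores; `NULL` fits the unadjusted two-sample
#'   model (used on matched cohorts, where the matching itself does the
#'   balancing).
#' @param level confidence level.
#' @return one-row data frame: term, estimate, se, ci_lower, ci_upper, p.
#' @export
ps_adjusted_linear <- function(y, group, ps = NULL, level = 0.95) {
  g <- as_group01(group)
  stopifnot(length(y) == length(g), is.null(ps) || length(ps) == length(g))
  X <- if (is.null(ps)) cbind(1, g) else cbind(1, g, ps)
  fit <- stats::lm.fit(X, y)
  if (any(is.na(fit$coefficients))) {
    warnf("ps_adjusted_linear: propensity score collinear with group; dropped")
    X <- cbind(1, g)
    fit <- stats::lm.fit(X, y)
  }
  res <- fit$residuals
  df <- length(y) - fit$rank
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * XtXinv[2, 2])
  wald_row("group", unname(fit$coefficients[2]), se, level)
}

#' Multivariable Firth model of group on Ig phenotypes, age and sex
#'
#' Tests independence of elevated polyclonal IgM and abnormal FLC ratio as
#' predictors of at-risk relative status, with correction for age and sex:
#' a Firth logistic regression of group membership on `e_igm`, `aflc`, age
#' and a male indicator. Results are reported per predictor as odds ratios
#' `exp(estimate)` with Wald intervals. A phenotype flag that is constant
#' in the data is inestimable and is dropped with a warning.
#'
#' @param group two-level group vector (relative = event).
#' @param e_igm,aflc logical phenotype flags.
#' @param age,sex covariates.
#' @param encoding `"binary"` enters the flags as 0/1; `"standardized"`
#'   centers and scales them (both conventions are found in practice for
#'   biomarker flags; the default is binary).
#' @param level confidence level.
#' @return data frame per predictor: term, estimate (log-odds), se,
#'   ci_lower, ci_upper, p, or, or_ci_lower, or_ci_upper.
#' @export
multivariable_model <- function(group, e_igm, aflc, age, sex,
                                encoding = c("binary", "standardized"),
                                level = 0.95) {
  encoding <- match.arg(encoding)
  g <- as_group01(group)
  enc <- function(v, nm) {
    v <- as.numeric(v)
    if (length(unique(v[!is.na(v)])) < 2) {
      warnf("multivariable_model: '%s' is constant; dropped", nm)
      return(NULL)
    }
    if (encoding == "standardized") as.numeric(scale(v)) else v
  }
  cols <- list(intercept = rep(1, length(g)),
               e_igm = enc(e_igm, "e_igm"), aflc = enc(aflc, "aflc"),
               age = age, male = as_male01(sex))
  cols <- cols[!vapply(cols, is.null, logical(1))]
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  fit <- firth_logistic(X, g, level = level)
  out <- fit$coefficients
  out$or <- exp(out$estimate)
  out$or_ci_lower <- exp(out$ci_lower)
  out$or_ci_upper <- exp(out$ci_upper)
  out[out$term != "intercept", , drop = FALSE]
}

#' Age trend of the FLC ratio by group
#'
#' Per-group least-squares regression of the FLC kappa/lambda ratio on age
#' at sampling. Slopes are reported per 10 years with Wald p-values, along
#' with the fold-ratio of the relative slope over the control slope (the
#' "rate of increase" comparison); the fold-ratio is `NA` (flagged) when
#' the reference slope is zero.
#'
#' @param flc_ratio numeric FLC ratios.
#' @param age numeric ages.
#' @param group two-level group vector.
#' @param level confidence level.
#' @return list with `slopes` (data frame per group: group, slope_per_10y,
#'   se_per_10y, ci_lower, ci_upper, p, n) and `fold_ratio`
#'   (relative slope / control slope).
#' @export
age_trend <- function(flc_ratio, age, group, level = 0.95) {
  g <- as_group01(group)
  stopifnot(length(flc_ratio) == length(age), length(age) == length(g))
  one <- function(rows, label) {
    yy <- flc_ratio[rows]; aa <- age[rows]
    ok <- !is.na(yy) & !is.na(aa)
    yy <- yy[ok]; aa <- aa[ok]
    if (length(yy) < 3) stopf("age_trend: fewer than 3 individuals in group '%s'", label)
    if (stats::sd(aa) == 0) stopf("age_trend: zero age variance in group '%s'", label)
    fit <- stats::lm.fit(cbind(1, aa), yy)
    sigma2 <- sum(fit$residuals^2) / (length(yy) - 2)
    se <- sqrt(sigma2 / sum((aa - mean(aa))^2))
    r <- wald_row(label, 10 * unname(fit$coefficients[2]), 10 * se, level)
    names(r)[names(r) == "term"] <- "group"
    names(r)[names(r) == "estimate"] <- "slope_per_10y"
    names(r)[names(r) == "se"] <- "se_per_10y"
    r$n <- length(yy)
    r
  }
  rel <- one(which(g == 1), "relative")
  ctl <- one(which(g == 0), "control")
  fold <- if (abs(ctl$slope_per_10y) < 1e-12) {
    warnf("age_trend: control slope is zero; fold-ratio undefined")
    NA_real_
  } else rel$slope_per_10y / ctl$slope_per_10y
  list(slopes = rbind(rel, ctl), fold_ratio = fold)
}
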