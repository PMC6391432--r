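#' Relative-versus-control association analysis of the serum Ig panel
#'
#' The full comparison pipeline for a phenotype table: derive the four
#' polyclonal sums and four kappa/lambda ratios, exclude >5 SD outliers
#' within group, derive control reference ranges and the eIgM threshold,
#' classify abnormal phenotypes, fit the propensity model on age, age
#' squared and sex, optionally restrict to the optimal matched cohort, and
#' fit per-variable models: propensity-adjusted linear regression for each
#' polyclonal sum (difference in mg/dL), Firth logistic regression for each
#' abnormality flag (fold difference, i.e., odds ratio), the multivariable
#' Firth model of group on eIgM + aFLC + age + sex, and the per-group
#' least-squares FLC-ratio age trend.
#'
#' @param phenotypes data frame in the [read_ig_panel()] layout (or a path
#'   to such a CSV).
#' @param ps_form `"covariate"` adjusts on the full cohort with the score
#'   as a covariate; `"matched"` first restricts to optimally matched
#'   pairs; `"both"` does the covariate adjustment on the matched cohort.
#' @param exact_sex_match match within sex strata (default `TRUE`).
#' @param multivariable_encoding passed to [multivariable_model()].
#' @param level confidence level.
#' @return object of class `"ig_association"`: list with `polyclonal` and
#'   `monoclonal` result tables (variable, estimate, se, ci_lower,
#'   ci_upper, p; monoclonal rows also carry `or` columns),
#'   `multivariable`, `age_trend`, `ranges`, `eigm_threshold`, `profiles`,
#'   and a `log` of record counts per stage.
#' @export
run_association <- function(phenotypes,
                            ps_form = c("covariate", "matched", "both"),
                            exact_sex_match = TRUE,
                            multivariable_encoding = "binary",
                            level = 0.95) {
  ps_form <- match.arg(ps_form)
  if (is.character(phenotypes)) phenotypes <- read_ig_panel(phenotypes)
  if (length(unique(phenotypes$group)) < 2)
    stopf("run_association: need both relatives and controls")
  n0 <- nrow(phenotypes)
  vars <- derive_ig_variables(phenotypes)
  keep <- exclude_outliers(vars, phenotypes$group)
  phenotypes <- phenotypes[keep, , drop = FALSE]
  vars <- vars[keep, , drop = FALSE]
  ctl <- phenotypes$group == "control"

  ranges <- list(flc = FLC_DIAGNOSTIC_RANGE,
                 iga = reference_range_95(vars$iga_ratio[ctl]),
                 igg = reference_range_95(vars$igg_ratio[ctl]),
                 igm = reference_range_95(vars$igm_ratio[ctl]))
  thr <- eigm_threshold(vars$igm_sum[ctl])
  prof <- classify_abnormal(vars, ranges, thr)
  prof$individual_id <- phenotypes$individual_id

  ps <- estimate_propensity(phenotypes$age_at_sampling, phenotypes$sex,
                            phenotypes$group)
  scores <- ps$scores
  sel <- seq_len(nrow(phenotypes))
  n_matched <- NA_integer_
  if (ps_form %in% c("matched", "both")) {
    mm <- optimal_match(scores, phenotypes$group, phenotypes$sex,
                        exact_on_sex = exact_sex_match)
    sel <- sort(c(mm$pairs$relative, mm$pairs$control))
    n_matched <- nrow(mm$pairs)
  }
  adj_ps <- if (ps_form == "matched") NULL else scores[sel]
  grp <- phenotypes$group[sel]

  poly <- do.call(rbind, lapply(c("flc_sum", "iga_sum", "igg_sum", "igm_sum"),
    function(v) {
      r <- ps_adjusted_linear(vars[[v]][sel], grp, adj_ps, level)
      r$term <- v
      names(r)[1] <- "variable"
      r
    }))

  mono <- do.call(rbind, lapply(c(flc = "aflc", iga = "a_iga", igg = "a_igg",
                                  igm = "a_igm"),
    function(fl) {
      y <- as.integer(prof[[fl]][sel])
      ok <- !is.na(y)
      X <- cbind(intercept = 1, group = as_group01(grp)[ok])
      if (!is.null(adj_ps) && length(unique(adj_ps[ok])) > 1)
        X <- cbind(X, ps = adj_ps[ok])
      fit <- firth_logistic(X, y[ok], level = level)
      r <- fit$coefficients[fit$coefficients$term == "group", , drop = FALSE]
      r$term <- fl
      names(r)[1] <- "variable"
      r$or <- exp(r$estimate)
      r$or_ci_lower <- exp(r$ci_lower)
      r$or_ci_upper <- exp(r$ci_upper)
      r
    }))
  rownames(mono) <- NULL

  multi <- multivariable_model(phenotypes$group, prof$e_igm, prof$aflc,
                               phenotypes$age_at_sampling, phenotypes$sex,
                               encoding = multivariable_encoding, level = level)
  trend <- age_trend(vars$flc_ratio, phenotypes$age_at_sampling,
                     phenotypes$group, level)

  structure(list(
    polyclonal = poly, monoclonal = mono, multivariable = multi,
    age_trend = trend, ranges = ranges, eigm_threshold = thr,
    profiles = prof, ps_method = ps$method,
    log = c(n_input = n0, n_excluded_outlier = n0 - sum(keep),
            n_relatives = sum(!ctl), n_controls = sum(ctl),
            n_matched_pairs = n_matched)),
    class = "ig_association")
}

#' @export
print.ig_association <- function(x, ...) {
  cat(sprintf("Ig association analysis: %d relatives vs %d controls (%d outlier(s) excluded)\n",
              x$log[["n_relatives"]], x$log[["n_controls"]],
              x$log[["n_excluded_outlier"]]))
  cat("\nPolyclonal (difference in mg/dL, relatives vs controls):\n")
  print(x$polyclonal, digits = 3)
  cat("\nMonoclonal (fold difference = odds ratio):\n")
  print(x$monoclonal[c("variable", "or", "or_ci_lower", "or_ci_upper", "p")],
        digits = 3)
  cat(sprintf("\neIgM threshold: %.1f mg/dL\n", x$eigm_threshold))
  cat(sprintf("FLC-ratio slope per 10 years: relatives %.3f (p=%.2g), controls %.3f (p=%.2g), fold %.2f\n",
              x$age_trend$slopes$slope_per_10y[1], x$age_trend$slopes$p[1],
              x$age_trend$slopes$slope_per_10y[2], x$age_trend$slopes$p[2],
              x$age_trend$fold_ratio))
  invisible(x)
}

#' Pedigree cancer-configuration comparison
#'
#' The pedigree-only analysis: classify abnormal phenotypes among sampled
#' relatives (reusing the control-derived reference ranges), categorize
#' pedigrees by the phenotypes they harbor, build the eIgM, aFLC and
#' normal cohorts (index individuals plus unique first- to third-degree
#' bloodline relatives), count cancers under the comparison-table
#' denominator rules, and compute Fisher exact conditional-MLE odds ratios
#' for each cancer category against the normal cohort -- with and without
#' the index individuals' personal cancer history.
#'
#' @param peds list of `"pedigree"` objects (or a path to a PED file).
#' @param phenotypes phenotype table or CSV path ([read_ig_panel()]
#'   layout); controls are used for reference ranges, sampled relatives
#'   for profiles.
#' @param diagnoses diagnosis table or CSV path ([read_diagnoses()]).
#' @param max_degree maximum relationship degree (default 3).
#' @param level confidence level.
#' @return object of class `"ig_ped_comparison"`: list with `categories`
#'   (pedigree flags), `cohorts`, and per-phenotype comparison tables
#'   `eigm`, `aflc`, plus `eigm_no_index_history`,
#'   `aflc_no_index_history`.
#' @export
run_pedigree_comparison <- function(peds, phenotypes, diagnoses,
                                    max_degree = 3L, level = 0.95) {
  if (is.character(peds)) peds <- read_ped(peds)
  if (is.character(phenotypes)) phenotypes <- read_ig_panel(phenotypes)
  if (is.character(diagnoses)) diagnoses <- read_diagnoses(diagnoses)

  vars <- derive_ig_variables(phenotypes)
  keep <- exclude_outliers(vars, phenotypes$group)
  phenotypes <- phenotypes[keep, , drop = FALSE]
  vars <- vars[keep, , drop = FALSE]
  ctl <- phenotypes$group == "control"
  ranges <- list(flc = FLC_DIAGNOSTIC_RANGE,
                 iga = reference_range_95(vars$iga_ratio[ctl]),
                 igg = reference_range_95(vars$igg_ratio[ctl]),
                 igm = reference_range_95(vars$igm_ratio[ctl]))
  prof <- classify_abnormal(vars, ranges, eigm_threshold(vars$igm_sum[ctl]))
  prof$individual_id <- phenotypes$individual_id
  prof <- prof[!ctl, , drop = FALSE]

  cats <- categorize_pedigrees(peds, prof)
  if (!any(cats$normal))
    stopf("run_pedigree_comparison: no 'normal' pedigree to compare against")
  cohorts <- list(eigm = build_cohort(peds, prof, "eigm", max_degree),
                  aflc = build_cohort(peds, prof, "aflc", max_degree),
                  normal = build_cohort(peds, prof, "normal", max_degree))
  out <- list(categories = cats, cohorts = cohorts)
  for (ph in c("eigm", "aflc")) {
    out[[ph]] <- compare_cohorts(cohorts[[ph]], cohorts$normal, diagnoses,
                                 exclude_index_history = FALSE, level = level)
    out[[paste0(ph, "_no_index_history")]] <-
      compare_cohorts(cohorts[[ph]], cohorts$normal, diagnoses,
                      exclude_index_history = TRUE, level = level)
  }
  class(out) <- "ig_ped_comparison"
  out
}

#' @export
print.ig_ped_comparison <- function(x, ...) {
  cat(sprintf("Pedigree comparison: %d pedigrees (%d eIgM, %d aFLC, %d normal)\n",
              nrow(x$categories), sum(x$categories$harbors_eigm),
              sum(x$categories$harbors_aflc), sum(x$categories$normal)))
  for (ph in c("eigm", "aflc")) {
    co <- x$cohorts[[ph]]
    cat(sprintf("\n%s cohort: %d index + %d relatives vs normal %d + %d\n",
                ph, length(co$index_ids), co$n_relatives,
                length(x$cohorts$normal$index_ids), x$cohorts$normal$n_relatives))
    print(x[[ph]][c("category", "cohort_count", "cohort_pct", "normal_count",
                    "normal_pct", "or", "ci_lower", "ci_upper", "note")],
          digits = 3)
  }
  invisible(x)
}

#' Write a result table as CSV with a provenance header
#'
#' Prepends comment lines recording the package version, the seed and a
#' short configuration fingerprint, so every emitted file is auditable and
#' reruns are comparable.
#'
#' @param df data frame.
#' @param path output path.
#' @param seed seed to record (may be `NA`).
#' @param config any R object describing the run configuration; hashed
#'   into a short fingerprint.
#' @param digits optional rounding applied to numeric columns (full
#'   precision when `NULL`).
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(df, path, seed = NA, config = NULL,
                             digits = NULL) {
  if (!is.null(digits)) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], round, digits = digits)
  }
  ver <- as.character(utils::packageVersion("igfam"))
  hash <- config_hash(paste(deparse(config), collapse = ""))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# igfam %s | seed=%s | config=%s", ver, seed, hash), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = TRUE)
  invisible(path)
}
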