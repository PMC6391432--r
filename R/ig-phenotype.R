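#' Established diagnostic range for the serum free light chain ratio
#'
#' The clinically established diagnostic interval for the FLC kappa/lambda
#' ratio; values strictly outside it are classified as abnormal (aFLC).
#' @format numeric length 2, `c(lower, upper)`.
#' @export
FLC_DIAGNOSTIC_RANGE <- c(lower = 0.26, upper = 1.65)

ANALYTE_PAIRS <- list(
  flc = c("flc_kappa", "flc_lambda"),
  iga = c("iga_kappa", "iga_lambda"),
  igg = c("igg_kappa", "igg_lambda"),
  igm = c("igm_kappa", "igm_lambda"))

#' Derive polyclonal and monoclonal Ig variables from an eight-analyte panel
#'
#' For each analyte class (free light chains and the IgA/IgG/IgM heavy/light
#' chain pairs) computes the polyclonal variable as the kappa + lambda sum
#' (mg/dL) and the monoclonal variable as the kappa/lambda ratio (unitless).
#' Missing analytes are allowed and propagate `NA` into the derived
#' variables; non-positive concentrations are an error (the ratio is
#' undefined at lambda = 0).
#'
#' @param panel data frame with columns `flc_kappa`, `flc_lambda`,
#'   `iga_kappa`, `iga_lambda`, `igg_kappa`, `igg_lambda`, `igm_kappa`,
#'   `igm_lambda` (mg/dL, each > 0).
#' @return data frame with `flc_sum`, `iga_sum`, `igg_sum`, `igm_sum`,
#'   `flc_ratio`, `iga_ratio`, `igg_ratio`, `igm_ratio`.
#' @examples
#' derive_ig_variables(data.frame(
#'   flc_kappa = 1.5, flc_lambda = 1.5, iga_kappa = 100, iga_lambda = 110,
#'   igg_kappa = 600, igg_lambda = 500, igm_kappa = 60, igm_lambda = 30))
#' @export
derive_ig_variables <- function(panel) {
  cols <- unlist(ANALYTE_PAIRS, use.names = FALSE)
  miss <- setdiff(cols, names(panel))
  if (length(miss))
    stopf("derive_ig_variables: missing columns: %s", paste(miss, collapse = ", "))
  for (cl in cols) {
    v <- panel[[cl]]
    if (any(!is.na(v) & (!is.finite(v) | v <= 0)))
      stopf("derive_ig_variables: '%s' must be strictly positive and finite", cl)
  }
  out <- data.frame(row.names = seq_len(nrow(panel)))
  for (nm in names(ANALYTE_PAIRS)) {
    kap <- panel[[ANALYTE_PAIRS[[nm]][1]]]
    lam <- panel[[ANALYTE_PAIRS[[nm]][2]]]
    out[[paste0(nm, "_sum")]] <- kap + lam
    out[[paste0(nm, "_ratio")]] <- kap / lam
  }
  out
}

#' Flag individuals with any derived Ig value more than 5 SDs from its
#' group mean
#'
#' Quality-control rule: within each group (relatives vs controls) and for
#' each derived variable, the mean and standard deviation are computed on
#' all individuals, then any individual with at least one value outside
#' mean +/- 5 SD is excluded. The rule is applied in a single pass (the
#' statistics are not recomputed after exclusion). A variable with zero
#' variance in a group excludes nobody.
#'
#' @param values data frame or matrix of derived variables (rows =
#'   individuals); `NA`s never trigger exclusion.
#' @param group_labels vector defining the groups.
#' @param n_sd exclusion threshold in standard deviations (default 5).
#' @return logical vector, `TRUE` for retained individuals.
#' @export
exclude_outliers <- function(values, group_labels, n_sd = 5) {
  values <- as.data.frame(values)
  stopifnot(nrow(values) == length(group_labels))
  keep <- rep(TRUE, nrow(values))
  for (g in unique(group_labels)) {
    rows <- which(group_labels == g)
    if (length(rows) < 2)
      stopf("exclude_outliers: group '%s' has fewer than 2 individuals", g)
    for (cl in names(values)) {
      v <- values[rows, cl]
      mu <- mean(v, na.rm = TRUE)
      sdv <- stats::sd(v, na.rm = TRUE)
      if (!is.finite(sdv) || sdv == 0) next
      out <- !is.na(v) & abs(v - mu) > n_sd * sdv
      keep[rows[out]] <- FALSE
    }
  }
  keep
}

#' 95% reference range from a control sample
#'
#' The 2.5th-97.5th percentile interval of the control distribution,
#' computed with the type-7 (linear interpolation between order statistics)
#' percentile convention.
#'
#' @param control_values numeric vector, at least 40 non-missing values.
#' @return list with `lower`, `upper`, `basis = "control_95pct"`.
#' @export
reference_range_95 <- function(control_values) {
  x <- control_values[!is.na(control_values)]
  if (length(x) < 40)
    stopf("reference_range_95: need at least 40 control values, got %d", length(x))
  q <- stats::quantile(x, c(0.025, 0.975), type = 7, names = FALSE)
  if (q[1] >= q[2])
    stopf("reference_range_95: degenerate control distribution (lower >= upper)")
  list(lower = q[1], upper = q[2], basis = "control_95pct")
}

#' Elevated-IgM threshold from control polyclonal IgM
#'
#' The 95th percentile (type-7 convention) of the control IgM(kappa+lambda)
#' distribution; values at or above it are classified as elevated IgM
#' (eIgM).
#'
#' @param control_igm_sums numeric vector, at least 40 non-missing values.
#' @return threshold in mg/dL.
#' @export
eigm_threshold <- function(control_igm_sums) {
  x <- control_igm_sums[!is.na(control_igm_sums)]
  if (length(x) < 40)
    stopf("eigm_threshold: need at least 40 control values, got %d", length(x))
  stats::quantile(x, 0.95, type = 7, names = FALSE)
}

#' Classify abnormal Ig phenotypes
#'
#' Ratio abnormality means strictly outside the closed reference interval
#' (a value exactly on a boundary is normal): the FLC ratio against its
#' diagnostic range, the three HLC ratios against control-derived 95%
#' reference ranges. Elevated IgM (eIgM) means IgM(kappa+lambda) at or
#' above (`>=`) the control 95th-percentile threshold.
#'
#' @param vars derived variables from [derive_ig_variables()] (needs the
#'   four `_ratio` columns and `igm_sum`).
#' @param ranges named list of ranges with elements `flc`, `iga`, `igg`,
#'   `igm`, each a list/vector with `lower` and `upper`. Default FLC range
#'   is [FLC_DIAGNOSTIC_RANGE].
#' @param eigm_thr eIgM threshold in mg/dL (from [eigm_threshold()]).
#' @return data frame of logicals: `aflc`, `a_iga`, `a_igg`, `a_igm`,
#'   `e_igm` (`NA` where the input variable is missing).
#' @export
classify_abnormal <- function(vars, ranges, eigm_thr) {
  need <- c("flc", "iga", "igg", "igm")
  if (!all(need %in% names(ranges)))
    stopf("classify_abnormal: ranges must contain %s", paste(need, collapse = ", "))
  outside <- function(v, r) {
    r <- unlist(r)[c(1, 2)]
    ifelse(is.na(v), NA, v < r[1] | v > r[2])
  }
  data.frame(
    aflc = outside(vars$flc_ratio, ranges$flc),
    a_iga = outside(vars$iga_ratio, ranges$iga),
    a_igg = outside(vars$igg_ratio, ranges$igg),
    a_igm = outside(vars$igm_ratio, ranges$igm),
    e_igm = ifelse(is.na(vars$igm_sum), NA, vars$igm_sum >= eigm_thr))
}

#' Read a per-individual serum Ig phenotype file
#'
#' CSV with columns `individual_id`, `group` (`relative` or `control`),
#' `age_at_sampling`, `sex`, and the eight analyte concentrations in mg/dL
#' (`flc_kappa` ... `igm_lambda`). Missing analytes are allowed.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_ig_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("individual_id", "group", "age_at_sampling", "sex",
            unlist(ANALYTE_PAIRS, use.names = FALSE))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("read_ig_panel: missing columns: %s", paste(miss, collapse = ", "))
  if (!all(df$group %in% c("relative", "control")))
    stopf("read_ig_panel: group must be 'relative' or 'control'")
  df
}
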