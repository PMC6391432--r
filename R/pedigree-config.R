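#' Cancer categories used in pedigree configuration comparisons
#'
#' CLL/SLL covers ICD-O-3 9823/3 and 9670/3 (the same B-cell malignancy
#' diagnosed in blood versus lymph nodes). Prostate is male-specific;
#' breast and gynecological are female-specific. MBL (monoclonal B-cell
#' lymphocytosis) is a screen-detected phenotype and is only observable in
#' sampled individuals.
#' @format character vector of category codes.
#' @export
CANCER_CATEGORIES <- c("CLL_SLL", "MBL", "b_cell_lymphoid_other",
                       "heme_other", "prostate", "melanoma", "colorectal",
                       "breast", "urinary", "gynecological", "lung",
                       "pancreas", "other")

SEX_SPECIFIC <- c(prostate = "male", breast = "female",
                  gynecological = "female")

CLL_SLL_ICDO3 <- c("9823/3", "9670/3")

#' Read a cancer-diagnosis file
#'
#' CSV with columns `individual_id`, `category` (one of
#' [CANCER_CATEGORIES]) and optionally `icd_o3_code`; rows whose ICD-O-3
#' code is 9823/3 or 9670/3 are coerced to category `CLL_SLL`. An
#' individual may carry several diagnoses (one row each).
#'
#' @param path file path.
#' @return data frame with `individual_id`, `category`.
#' @export
read_diagnoses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("individual_id", "category") %in% names(df)))
  if ("icd_o3_code" %in% names(df)) {
    cll <- !is.na(df$icd_o3_code) & df$icd_o3_code %in% CLL_SLL_ICDO3
    df$category[cll] <- "CLL_SLL"
  }
  bad <- setdiff(unique(df$category), CANCER_CATEGORIES)
  if (length(bad))
    stopf("read_diagnoses: unknown categories: %s", paste(bad, collapse = ", "))
  df[c("individual_id", "category")]
}

#' Classify pedigrees by the abnormal Ig phenotypes they harbor
#'
#' A pedigree harbors eIgM (or aFLC) when at least one of its sampled
#' members carries that phenotype. A pedigree is "normal" when none of its
#' sampled members has any abnormal Ig phenotype considered in the study
#' (aFLC, eIgM, or an abnormal HLC ratio). The harbors flags are not
#' mutually exclusive: a pedigree may appear in both the eIgM and the aFLC
#' comparison cohorts.
#'
#' @param peds list of `"pedigree"` objects.
#' @param profiles data frame with `individual_id` plus the columns of
#'   [classify_abnormal()] (`aflc`, `a_iga`, `a_igg`, `a_igm`, `e_igm`) for
#'   every sampled member.
#' @return data frame per pedigree: `pedigree_id`, `n_sampled`,
#'   `harbors_eigm`, `harbors_aflc`, `normal`. Pedigrees without sampled
#'   members are dropped with a warning.
#' @export
categorize_pedigrees <- function(peds, profiles) {
  if (inherits(peds, "pedigree")) peds <- list(peds)
  flags <- c("aflc", "a_iga", "a_igg", "a_igm", "e_igm")
  stopifnot(all(c("individual_id", flags) %in% names(profiles)))
  rows <- lapply(peds, function(p) {
    samp <- p$id[p$sampled]
    pr <- profiles[profiles$individual_id %in% samp, , drop = FALSE]
    if (!nrow(pr)) {
      warnf("categorize_pedigrees: pedigree '%s' has no sampled members with profiles; excluded",
            p$pedigree_id)
      return(NULL)
    }
    any_flag <- function(col) any(pr[[col]], na.rm = TRUE)
    data.frame(pedigree_id = p$pedigree_id, n_sampled = nrow(pr),
               harbors_eigm = any_flag("e_igm"), harbors_aflc = any_flag("aflc"),
               normal = !any(vapply(flags, any_flag, logical(1))))
  })
  do.call(rbind, rows)
}

#' Build a phenotype-defined cohort of index individuals and their unique
#' first- to third-degree relatives
#'
#' For `"eigm"` and `"aflc"` the index set is every sampled member carrying
#' the phenotype (in any pedigree); for `"normal"` it is the sampled
#' members with fully normal profiles residing in "normal" pedigrees. The
#' relative set is the deduplicated union of bloodline first- to
#' third-degree relatives of the index individuals, excluding the index
#' individuals themselves and all marry-ins.
#'
#' Denominators follow the bookkeeping of the comparison table: CLL
#' percentages use the relatives-only denominator, every other category
#' the combined (index + relatives) denominator, and sex-specific
#' categories the male/female splits of the combined set (unknown sex is
#' excluded with a warning).
#'
#' @param peds list of `"pedigree"` objects.
#' @param profiles per-sampled-member phenotype profiles (see
#'   [categorize_pedigrees()]).
#' @param phenotype `"eigm"`, `"aflc"` or `"normal"`.
#' @param max_degree maximum relationship degree (default 3).
#' @return object of class `"ig_cohort"`: list with `phenotype`,
#'   `index_ids`, `relative_ids`, `n_relatives`, `n_combined`, `n_male`,
#'   `n_female`, `sex` (named vector over index + relatives), and
#'   `pedigree_ids`.
#' @export
build_cohort <- function(peds, profiles, phenotype = c("eigm", "aflc", "normal"),
                         max_degree = 3L) {
  phenotype <- match.arg(phenotype)
  if (inherits(peds, "pedigree")) peds <- list(peds)
  cats <- categorize_pedigrees(peds, profiles)
  flags <- c("aflc", "a_iga", "a_igg", "a_igm", "e_igm")
  index_ids <- character(0)
  ped_ids <- character(0)
  for (p in peds) {
    samp <- p$id[p$sampled]
    pr <- profiles[profiles$individual_id %in% samp, , drop = FALSE]
    if (!nrow(pr)) next
    sel <- switch(phenotype,
      eigm = pr$individual_id[!is.na(pr$e_igm) & pr$e_igm],
      aflc = pr$individual_id[!is.na(pr$aflc) & pr$aflc],
      normal = {
        in_normal <- cats$normal[cats$pedigree_id == p$pedigree_id]
        if (isTRUE(in_normal)) {
          all_norm <- apply(pr[flags], 1, function(r) !any(r, na.rm = TRUE))
          pr$individual_id[all_norm]
        } else character(0)
      })
    if (length(sel)) {
      index_ids <- c(index_ids, sel)
      ped_ids <- c(ped_ids, p$pedigree_id)
    }
  }
  index_ids <- unique(index_ids)
  if (!length(index_ids))
    warnf("build_cohort: empty index set for phenotype '%s'", phenotype)
  relative_ids <- enumerate_relatives(peds, index_ids, max_degree)
  everyone <- c(index_ids, relative_ids)
  sex <- character(0)
  for (p in peds) {
    hit <- everyone[everyone %in% p$id]
    sex[hit] <- as.character(p$sex[ped_index(p, hit)])
  }
  if (any(sex == "unknown"))
    warnf("build_cohort: %d individual(s) of unknown sex excluded from sex-specific denominators",
          sum(sex == "unknown"))
  structure(list(
    phenotype = phenotype, index_ids = index_ids,
    relative_ids = relative_ids,
    n_relatives = length(relative_ids),
    n_combined = length(index_ids) + length(relative_ids),
    n_male = sum(sex == "male"), n_female = sum(sex == "female"),
    sex = sex, pedigree_ids = sort(unique(ped_ids))),
    class = "ig_cohort")
}

#' @export
print.ig_cohort <- function(x, ...) {
  cat(sprintf("Cohort '%s': %d pedigree(s), %d index, %d unique 1st-3rd degree relatives (combined %d; %d male, %d female)\n",
              x$phenotype, length(x$pedigree_ids), length(x$index_ids),
              x$n_relatives, x$n_combined, x$n_male, x$n_female))
  invisible(x)
}

#' Count cancers in a cohort under the comparison-table denominator rules
#'
#' CLL/SLL is counted over relatives only (index individuals were sampled
#' CLL-free by design); every other category over index + relatives;
#' sex-specific categories only among cohort members of the matching sex.
#' An individual contributes at most once to a given category but may
#' contribute to several categories. With `exclude_index_history` the index
#' members' own diagnoses are dropped from the numerators (denominators are
#' kept, matching a sensitivity analysis that removes personal cancer
#' history from the comparison).
#'
#' @param cohort an `"ig_cohort"`.
#' @param diagnoses data frame `individual_id`, `category` (see
#'   [read_diagnoses()]); diagnoses of non-members are ignored with a
#'   warning.
#' @param exclude_index_history drop index members' own diagnoses from
#'   numerators (default `FALSE`).
#' @return data frame per category: `category`, `count`, `denominator`.
#' @export
count_cancers <- function(cohort, diagnoses, exclude_index_history = FALSE) {
  stopifnot(inherits(cohort, "ig_cohort"))
  members <- c(cohort$index_ids, cohort$relative_ids)
  dx <- unique(diagnoses[c("individual_id", "category")])
  outside <- setdiff(unique(dx$individual_id), members)
  dx <- dx[dx$individual_id %in% members, , drop = FALSE]
  rows <- lapply(CANCER_CATEGORIES, function(cat) {
    if (cat == "CLL_SLL") {
      pool <- cohort$relative_ids
      denom <- cohort$n_relatives
    } else if (cat %in% names(SEX_SPECIFIC)) {
      want <- SEX_SPECIFIC[[cat]]
      pool <- members[cohort$sex[members] == want]
      denom <- if (want == "male") cohort$n_male else cohort$n_female
    } else {
      pool <- members
      denom <- cohort$n_combined
    }
    if (exclude_index_history) pool <- setdiff(pool, cohort$index_ids)
    data.frame(category = cat,
               count = sum(dx$category == cat & dx$individual_id %in% pool),
               denominator = denom)
  })
  counts <- do.call(rbind, rows)
  attr(counts, "ignored_ids") <- outside
  counts
}

#' Compare cancer configurations between a phenotype cohort and the
#' normal cohort
#'
#' For each cancer category, forms the 2x2 table (cohort count, cohort
#' denominator - count; normal count, normal denominator - count) and
#' computes the Fisher conditional-MLE odds ratio with exact tail-inversion
#' confidence limits and exact p-value. Categories with a zero denominator
#' on either side are marked `"nd"` (not determined).
#'
#' @param cohort,normal_cohort `"ig_cohort"` objects (typically eIgM or
#'   aFLC versus normal).
#' @param diagnoses diagnosis data frame.
#' @param exclude_index_history see [count_cancers()].
#' @param level confidence level.
#' @return data frame per category: counts, denominators, percentages,
#'   `or`, `ci_lower`, `ci_upper`, `p`, `note` (`""` or `"nd"`).
#' @export
compare_cohorts <- function(cohort, normal_cohort, diagnoses,
                            exclude_index_history = FALSE, level = 0.95) {
  cc <- count_cancers(cohort, diagnoses, exclude_index_history)
  nc <- count_cancers(normal_cohort, diagnoses, exclude_index_history)
  rows <- lapply(seq_len(nrow(cc)), function(i) {
    a <- cc$count[i]; na_ <- cc$denominator[i]
    c_ <- nc$count[i]; nn <- nc$denominator[i]
    base <- data.frame(
      category = cc$category[i],
      cohort_count = a, cohort_denominator = na_,
      cohort_pct = if (na_ > 0) 100 * a / na_ else NA_real_,
      normal_count = c_, normal_denominator = nn,
      normal_pct = if (nn > 0) 100 * c_ / nn else NA_real_)
    est <- tryCatch({
      if (na_ == 0 || nn == 0) stop("nd")
      exact_or(c(a, na_ - a, c_, nn - c_), level)
    }, error = function(e) NULL)
    if (is.null(est)) {
      cbind(base, or = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
            p = NA_real_, note = "nd")
    } else {
      cbind(base, or = est$or, ci_lower = est$ci_lower,
            ci_upper = est$ci_upper, p = est$p, note = "")
    }
  })
  do.call(rbind, rows)
}
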