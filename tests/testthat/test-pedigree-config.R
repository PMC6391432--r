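# two small pedigrees with known phenotype structure:
# toy (index s1 carries the phenotype), plus a clean "normal" pedigree
make_profiles <- function(ids, eigm = character(0), aflc = character(0)) {
  data.frame(individual_id = ids,
             aflc = ids %in% aflc, a_iga = FALSE, a_igg = FALSE,
             a_igm = FALSE, e_igm = ids %in% eigm)
}

normal_pedigree <- function() {
  pedigree(data.frame(
    individual_id = c("nf", "nm", "n1", "n2"),
    father_id = c("0", "0", "nf", "nf"),
    mother_id = c("0", "0", "nm", "nm"),
    sex = c(1, 2, 1, 2),
    sampled = c(0, 0, 1, 1)), pedigree_id = "norm")
}

sampled_toy <- function() {
  ped <- toy_pedigree()
  ped$sampled[match(c("s1", "s2"), ped$id)] <- TRUE
  ped
}

test_that("pedigrees are categorized by harbored phenotypes, non-exclusively", {
  peds <- list(sampled_toy(), normal_pedigree())
  prof <- make_profiles(c("s1", "s2", "n1", "n2"),
                        eigm = "s1", aflc = "s1")
  cats <- categorize_pedigrees(peds, prof)
  expect_true(cats$harbors_eigm[cats$pedigree_id == "toy"])
  expect_true(cats$harbors_aflc[cats$pedigree_id == "toy"]) # both flags
  expect_false(cats$normal[cats$pedigree_id == "toy"])
  expect_true(cats$normal[cats$pedigree_id == "norm"])
  # an abnormal HLC ratio alone also disqualifies "normal"
  prof2 <- make_profiles(c("s1", "s2", "n1", "n2"))
  prof2$a_igg[prof2$individual_id == "n1"] <- TRUE
  cats2 <- categorize_pedigrees(peds, prof2)
  expect_false(cats2$normal[cats2$pedigree_id == "norm"])
  expect_false(cats2$harbors_eigm[cats2$pedigree_id == "norm"])
  # pedigree without sampled members is excluded with a warning
  unsampled <- toy_pedigree()
  expect_warning(categorize_pedigrees(list(unsampled), prof), "no sampled")
})

test_that("cohorts assemble index + unique relatives with the table's denominators", {
  peds <- list(sampled_toy(), normal_pedigree())
  prof <- make_profiles(c("s1", "s2", "n1", "n2"), eigm = "s1")
  co <- build_cohort(peds, prof, "eigm")
  expect_identical(co$index_ids, "s1")
  expect_identical(co$relative_ids, brute_force_relatives(toy_pedigree(), "s1"))
  expect_equal(co$n_combined, length(co$index_ids) + co$n_relatives)
  expect_equal(co$n_male + co$n_female, co$n_combined)
  # sibling index members never appear in the relative set
  prof_sib <- make_profiles(c("s1", "s2", "n1", "n2"), eigm = c("s1", "s2"))
  co2 <- build_cohort(peds, prof_sib, "eigm")
  expect_false(any(c("s1", "s2") %in% co2$relative_ids))
  # normal cohort: only fully-normal members of normal pedigrees
  con <- build_cohort(peds, prof, "normal")
  expect_setequal(con$index_ids, c("n1", "n2"))
  expect_setequal(con$relative_ids, c("nf", "nm"))
})

test_that("cancer counts follow category-specific denominators and dedup rules", {
  peds <- list(sampled_toy(), normal_pedigree())
  prof <- make_profiles(c("s1", "s2", "n1", "n2"), eigm = "s1")
  co <- build_cohort(peds, prof, "eigm")
  dx <- data.frame(
    individual_id = c("fa", "fa", "gf1", "c1", "s1", "zz", "mo"),
    category = c("melanoma", "colorectal", "prostate", "CLL_SLL",
                 "b_cell_lymphoid_other", "melanoma", "breast"))
  counts <- count_cancers(co, dx)
  get <- function(cat) counts[counts$category == cat, ]
  # multiple cancers in one individual count once per category
  expect_equal(get("melanoma")$count, 1)
  expect_equal(get("colorectal")$count, 1)
  # CLL over relatives only
  expect_equal(get("CLL_SLL")$count, 1)
  expect_equal(get("CLL_SLL")$denominator, co$n_relatives)
  # sex-specific denominators
  expect_equal(get("prostate")$denominator, co$n_male)
  expect_equal(get("breast")$denominator, co$n_female)
  # diagnosis for a non-member is ignored
  expect_identical(attr(counts, "ignored_ids"), "zz")
  # index personal history removal zeroes index-held non-CLL counts only
  counts2 <- count_cancers(co, dx, exclude_index_history = TRUE)
  expect_equal(counts2[counts2$category == "b_cell_lymphoid_other", "count"], 0)
  expect_equal(counts2[counts2$category == "CLL_SLL", "count"],
               get("CLL_SLL")$count)
  expect_equal(counts2[counts2$category == "melanoma", "count"], 1)
})

test_that("cohort comparisons delegate to exact inference and mark nd cells", {
  peds <- list(sampled_toy(), normal_pedigree())
  prof <- make_profiles(c("s1", "s2", "n1", "n2"), eigm = "s1")
  co <- build_cohort(peds, prof, "eigm")
  nco <- build_cohort(peds, prof, "normal")
  dx <- data.frame(individual_id = c("fa", "nf"),
                   category = c("melanoma", "melanoma"))
  cmp <- compare_cohorts(co, nco, dx)
  mel <- cmp[cmp$category == "melanoma", ]
  oracle <- exact_or(c(mel$cohort_count, mel$cohort_denominator - mel$cohort_count,
                       mel$normal_count, mel$normal_denominator - mel$normal_count))
  expect_equal(mel$or, oracle$or)
  expect_equal(mel$ci_lower, oracle$ci_lower)
  # identical cohorts give OR 1 everywhere estimable
  self <- compare_cohorts(co, co, dx)
  mel_self <- self[self$category == "melanoma", ]
  expect_equal(mel_self$or, 1, tolerance = 1e-6)
  # a category with no events on either side has a degenerate event margin:
  # marked nd rather than reported as a number
  none <- self[self$category == "other", ]
  expect_identical(none$note, "nd")
  expect_true(is.na(none$or))
})

test_that("counts are invariant to input ordering", {
  peds <- list(sampled_toy(), normal_pedigree())
  prof <- make_profiles(c("s1", "s2", "n1", "n2"), eigm = "s1")
  co <- build_cohort(peds, prof, "eigm")
  dx <- data.frame(individual_id = c("fa", "gf1", "c1", "mo"),
                   category = c("melanoma", "prostate", "CLL_SLL", "breast"))
  c1 <- count_cancers(co, dx)
  c2 <- count_cancers(co, dx[sample.int(nrow(dx)), ])
  expect_equal(c1, c2, ignore_attr = TRUE)
  co_rev <- build_cohort(rev(peds), prof, "eigm")
  expect_identical(co$relative_ids, co_rev$relative_ids)
})

test_that("diagnosis files map ICD-O-3 CLL/SLL codes and reject unknowns", {
  tf <- tempfile(fileext = ".csv")
  write.csv(data.frame(individual_id = c("a", "b", "c"),
                       category = c("other", "melanoma", "MBL"),
                       icd_o3_code = c("9823/3", "", "9670/3")),
            tf, row.names = FALSE)
  dx <- read_diagnoses(tf)
  expect_identical(dx$category, c("CLL_SLL", "melanoma", "CLL_SLL"))
  tf2 <- tempfile(fileext = ".csv")
  write.csv(data.frame(individual_id = "a", category = "nonsense"),
            tf2, row.names = FALSE)
  expect_error(read_diagnoses(tf2), "unknown categories")
})
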