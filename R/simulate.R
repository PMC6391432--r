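#' Configuration for the synthetic pedigree/phenotype/cancer generator
#'
#' The defaults emulate the study conditions the pipeline was designed for:
#' 23 multi-generational high-risk pedigrees (2-8 generations), about 117
#' sampled bloodline relatives and 160 population controls, serum Ig sums
#' drawn from lognormals calibrated so the control medians and 95% ranges
#' match the reported control distributions (e.g., IgM(kappa+lambda) median
#' 68 mg/dL, 95% range 22-220), kappa/lambda ratios calibrated to the
#' control-derived HLC reference ranges, an FLC-ratio mean drifting
#' linearly with age (0.010/year in relatives, 0.0038/year in controls),
#' designated abnormal-FLC prevalences (6.8% of relatives, 1.3% of
#' controls), and per-category cancer rates by pedigree cohort. Elevated
#' IgM is emergent from the calibrated group lognormals (relative rate
#' about 11%), not injected.
#'
#' Lognormal calibration from a median `m` and 95% range `(l, u)` uses
#' `meanlog = log(m)`, `sdlog = log(u/l) / (2 * 1.96)` -- a symmetric-on-log
#' compromise, since reported ranges are not exactly log-symmetric.
#'
#' @param seed integer seed recorded in the configuration (the generator
#'   functions set it).
#' @param n_pedigrees number of pedigrees (default 23).
#' @param generations_range inclusive range of generations per pedigree.
#' @param mean_offspring mean children per married couple.
#' @param marriage_prob probability a bloodline member marries (gains a
#'   marry-in spouse and may reproduce).
#' @param n_sampled_relatives target number of sampled relatives across
#'   pedigrees.
#' @param n_controls number of population controls.
#' @param ig_sums per-group calibration of the four polyclonal sums:
#'   list(control, relative), each a list of `c(median, lo95, hi95)` per
#'   analyte class, mg/dL.
#' @param hlc_ratio_ranges central 95% ranges of the three HLC
#'   kappa/lambda ratios (both groups share the control ratio
#'   distribution).
#' @param aflc_prevalence designated abnormal-FLC prevalence per group.
#' @param flc_ratio_slope FLC-ratio drift per year of age, per group.
#' @param flc_ratio_sd residual SD of the FLC ratio around its age trend.
#'   The default 0.2 is calibrated for consistency with the reported
#'   control abnormality rate: with a larger scatter the natural
#'   out-of-range mass of the control ratio distribution would by itself
#'   exceed the 1.3% of controls observed to be abnormal.
#' @param flc_ratio_at60 FLC-ratio mean at age 60 (both groups).
#' @param control_age mean and SD of control ages (years, truncated to
#'   20-95).
#' @param first_degree_sampling probability a sampled relative is drawn
#'   from the first-degree relatives of a CLL case.
#' @param cancer_rates data frame with columns `category`, `normal`,
#'   `aflc`, `eigm`: per-individual diagnosis probability by pedigree
#'   cohort. MBL rates apply to sampled members only (screen-detected);
#'   CLL applies to non-sampled bloodline members (sampled relatives are
#'   CLL-free by design); sex-specific categories are gated on sex.
#' @return object of class `"sim_config"` (a validated list).
#' @export
simulation_config <- function(
    seed = 1L,
    n_pedigrees = 23L,
    generations_range = c(2L, 8L),
    mean_offspring = 2.5,
    marriage_prob = 0.8,
    n_sampled_relatives = 117L,
    n_controls = 160L,
    ig_sums = list(
      control = list(flc = c(3.04, 1.55, 6.30), iga = c(210, 77, 497),
                     igg = c(1116, 682, 1586), igm = c(68, 22, 220)),
      relative = list(flc = c(2.62, 1.61, 5.14), iga = c(207, 60, 428),
                      igg = c(1108, 613, 1526), igm = c(92, 33, 286))),
    hlc_ratio_ranges = list(iga = c(0.84, 1.91), igg = c(1.02, 2.87),
                            igm = c(1.00, 2.90)),
    aflc_prevalence = c(control = 0.013, relative = 0.068),
    flc_ratio_slope = c(control = 0.0038, relative = 0.010),
    flc_ratio_sd = 0.2,
    flc_ratio_at60 = 0.95,
    control_age = c(mean = 66, sd = 15),
    first_degree_sampling = 0.98,
    cancer_rates = default_cancer_rates()) {
  cfg <- list(seed = as.integer(seed), n_pedigrees = as.integer(n_pedigrees),
              generations_range = as.integer(generations_range),
              mean_offspring = mean_offspring, marriage_prob = marriage_prob,
              n_sampled_relatives = as.integer(n_sampled_relatives),
              n_controls = as.integer(n_controls), ig_sums = ig_sums,
              hlc_ratio_ranges = hlc_ratio_ranges,
              aflc_prevalence = aflc_prevalence,
              flc_ratio_slope = flc_ratio_slope,
              flc_ratio_sd = flc_ratio_sd, flc_ratio_at60 = flc_ratio_at60,
              control_age = control_age,
              first_degree_sampling = first_degree_sampling,
              cancer_rates = cancer_rates)
  stopifnot(cfg$n_pedigrees >= 1,
            length(cfg$generations_range) == 2,
            cfg$generations_range[1] >= 2,
            cfg$generations_range[2] >= cfg$generations_range[1],
            cfg$mean_offspring > 0, cfg$marriage_prob > 0,
            cfg$marriage_prob <= 1,
            all(cfg$aflc_prevalence >= 0 & cfg$aflc_prevalence <= 1),
            cfg$flc_ratio_sd >= 0,
            all(c("category", "normal", "aflc", "eigm") %in% names(cfg$cancer_rates)))
  rates <- as.matrix(cfg$cancer_rates[c("normal", "aflc", "eigm")])
  stopifnot(all(rates >= 0 & rates <= 1))
  for (g in c("control", "relative"))
    for (cl in names(cfg$ig_sums[[g]])) {
      v <- cfg$ig_sums[[g]][[cl]]
      stopifnot(length(v) == 3, v[2] < v[1], v[1] < v[3])
    }
  class(cfg) <- "sim_config"
  cfg
}

default_cancer_rates <- function() {
  data.frame(
    category = c("CLL_SLL", "MBL", "b_cell_lymphoid_other", "heme_other",
                 "prostate", "melanoma", "colorectal", "breast", "urinary",
                 "gynecological", "lung", "pancreas"),
    normal = c(0.148, 0.304, 0.010, 0.007, 0.080, 0.023, 0.026, 0.046,
               0.003, 0.020, 0.007, 0.003),
    aflc   = c(0.076, 0.375, 0.040, 0.010, 0.218, 0.030, 0.010, 0.067,
               0.030, 0.044, 0.000, 0.000),
    eigm   = c(0.114, 0.077, 0.048, 0.007, 0.059, 0.041, 0.007, 0.033,
               0.028, 0.017, 0.007, 0.014))
}

# meanlog/sdlog from median and central 95% range
lnorm_calib <- function(mlu) {
  c(meanlog = log(mlu[1]), sdlog = log(mlu[3] / mlu[2]) / (2 * stats::qnorm(0.975)))
}

#' Simulate multi-generational high-risk pedigrees
#'
#' Each pedigree starts from an apical founder couple; descendants marry in
#' spouses with probability `marriage_prob` and couples have a Poisson
#' number of children, down to the pedigree's sampled generation depth.
#' Sexes are Bernoulli(1/2); ages decrease by about a generation length of
#' 26 years from founders to leaves. A handful of bloodline members per
#' pedigree are designated CLL cases, and sampled relatives (CLL-free
#' bloodline members of plausible sampling age) are drawn mostly (98% by
#' default) from the first-degree relatives of CLL cases.
#'
#' @param config a [simulation_config()].
#' @return list with `pedigrees` (named list of `"pedigree"` objects,
#'   sampled flags set), `members` (PED-style data frame), `sampled` (data
#'   frame: individual_id, pedigree_id, sex, age_at_sampling) and
#'   `cll_ids` (designated CLL cases).
#' @export
simulate_pedigrees <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gens <- sample(seq(config$generations_range[1], config$generations_range[2]),
                 config$n_pedigrees, replace = TRUE)
  all_rows <- list()
  for (pi in seq_len(config$n_pedigrees)) {
    pid <- sprintf("P%02d", pi)
    all_rows[[pi]] <- sim_one_pedigree(pid, gens[pi], config)
  }
  members <- do.call(rbind, all_rows)

  # designate CLL cases and draw sampled relatives per pedigree
  members$cll <- FALSE
  members$sampled <- FALSE
  by_ped <- split(seq_len(nrow(members)), members$pedigree_id)
  eligible <- lapply(by_ped, function(rows) {
    rows[members$bloodline[rows] & !is.na(members$age[rows]) &
           members$age[rows] >= 25 & members$age[rows] <= 95]
  })
  for (pid in names(by_ped)) {
    rows <- by_ped[[pid]]
    pool <- rows[members$bloodline[rows] & members$generation[rows] >= 2]
    if (!length(pool)) pool <- rows[members$bloodline[rows]]
    n_cll <- min(length(pool), 1 + stats::rpois(1, 1.5))
    members$cll[sample_safe(pool, n_cll)] <- TRUE
  }
  # quotas: one sampled relative per pedigree where possible (every study
  # pedigree contributed serum), remainder proportional to eligible pool
  sizes <- vapply(eligible, function(r) sum(!members$cll[r]), numeric(1))
  base <- as.numeric(sizes > 0)
  quota <- base + largest_remainder(pmax(sizes - base, 0),
                                    max(config$n_sampled_relatives - sum(base), 0))
  for (pid in names(by_ped)) {
    el <- eligible[[pid]]
    el <- el[!members$cll[el]]
    q <- min(quota[[pid]], length(el))
    if (q == 0) next
    first_deg <- first_degree_of(members, by_ped[[pid]],
                                 which(members$cll & members$pedigree_id == pid))
    first_deg <- intersect(first_deg, el)
    chosen <- integer(0)
    for (k in seq_len(q)) {
      from_fd <- length(setdiff(first_deg, chosen)) > 0 &&
        stats::runif(1) < config$first_degree_sampling
      pool <- if (from_fd) setdiff(first_deg, chosen) else setdiff(el, chosen)
      chosen <- c(chosen, sample_safe(pool, 1))
    }
    members$sampled[chosen] <- TRUE
  }

  peds <- lapply(split(members, members$pedigree_id), function(sub) {
    pedigree(data.frame(
      pedigree_id = sub$pedigree_id, individual_id = sub$individual_id,
      father_id = sub$father_id, mother_id = sub$mother_id,
      sex = sub$sex, sampled = sub$sampled,
      age_at_sampling = ifelse(sub$sampled, pmin(pmax(sub$age, 25), 95), NA)))
  })
  sampled <- members[members$sampled, , drop = FALSE]
  list(pedigrees = peds,
       members = members,
       sampled = data.frame(individual_id = sampled$individual_id,
                            pedigree_id = sampled$pedigree_id,
                            sex = sampled$sex,
                            age_at_sampling = pmin(pmax(sampled$age, 25), 95),
                            stringsAsFactors = FALSE),
       cll_ids = members$individual_id[members$cll])
}

# sample() without the scalar-x surprise
sample_safe <- function(x, n) if (length(x) <= n) x else x[sample.int(length(x), n)]

largest_remainder <- function(sizes, total) {
  if (sum(sizes) == 0) return(stats::setNames(rep(0, length(sizes)), names(sizes)))
  raw <- total * sizes / sum(sizes)
  q <- pmin(floor(raw), sizes)
  left <- total - sum(q)
  ord <- order(raw - floor(raw), decreasing = TRUE)
  for (i in ord) {
    if (left <= 0) break
    if (q[i] < sizes[i]) { q[i] <- q[i] + 1; left <- left - 1 }
  }
  stats::setNames(q, names(sizes))
}

first_degree_of <- function(members, rows, cases) {
  ids <- members$individual_id
  out <- integer(0)
  for (ci in cases) {
    pids <- c(members$father_id[ci], members$mother_id[ci])
    kids <- rows[members$father_id[rows] %in% ids[ci] |
                   members$mother_id[rows] %in% ids[ci]]
    sibs <- rows[(members$father_id[rows] %in% pids[pids != "0"] |
                    members$mother_id[rows] %in% pids[pids != "0"]) ]
    out <- c(out, rows[ids[rows] %in% pids], kids, sibs)
  }
  setdiff(unique(out), cases)
}

sim_one_pedigree <- function(pid, g, cfg) {
  nid <- 0
  new_id <- function() { nid <<- nid + 1; sprintf("%s_I%03d", pid, nid) }
  rows <- list()
  add <- function(id, f, m, sex, gen, bloodline) {
    rows[[length(rows) + 1]] <<- data.frame(
      pedigree_id = pid, individual_id = id, father_id = f, mother_id = m,
      sex = sex, generation = gen, bloodline = bloodline,
      stringsAsFactors = FALSE)
    id
  }
  f0 <- add(new_id(), "0", "0", 1L, 1L, TRUE)
  m0 <- add(new_id(), "0", "0", 2L, 1L, TRUE)
  couples <- list(c(f0, m0))
  for (t in seq(2, g)) {
    nxt <- list()
    for (cp in couples) {
      nk <- if (t == 2) 1 + stats::rpois(1, max(cfg$mean_offspring - 1, 0.1))
            else stats::rpois(1, cfg$mean_offspring)
      nk <- min(nk, 6L)
      for (k in seq_len(nk)) {
        sex <- sample(1:2, 1)
        child <- add(new_id(), cp[1], cp[2], sex, t, TRUE)
        if (t < g && stats::runif(1) < cfg$marriage_prob) {
          sp_sex <- if (sex == 1L) 2L else 1L
          spouse <- add(new_id(), "0", "0", sp_sex, t, FALSE)
          nxt[[length(nxt) + 1]] <- if (sex == 1L) c(child, spouse) else c(spouse, child)
        }
      }
    }
    if (length(nxt) > 40) nxt <- nxt[sample.int(length(nxt), 40)]
    couples <- nxt
    if (!length(couples)) break
  }
  df <- do.call(rbind, rows)
  df$age <- 28 + 26 * (g - df$generation) + stats::rnorm(nrow(df), 0, 7)
  df
}

#' Simulate eight-analyte serum Ig panels
#'
#' Draws each polyclonal sum from the group-calibrated lognormal, a
#' kappa/lambda ratio from the calibrated HLC ratio distributions, and the
#' FLC ratio from its linear age trend plus Gaussian noise; individuals
#' designated abnormal-FLC (Bernoulli at the configured group prevalence)
#' have their ratio replaced by an out-of-range value, and non-designated
#' FLC ratios are confined to the diagnostic range so the designated
#' prevalence is exact. Kappa and lambda are then recovered from each
#' (sum, ratio) pair.
#'
#' @param sim output of [simulate_pedigrees()].
#' @param config the same [simulation_config()].
#' @return list with `phenotypes` (data frame in the [read_ig_panel()]
#'   layout: sampled relatives plus `n_controls` controls) and `truth`
#'   (list: designated aFLC ids, true eIgM threshold and relative eIgM
#'   rate, age-trend parameters).
#' @export
simulate_ig_panels <- function(sim, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  rel <- sim$sampled
  ctl_age <- pmin(pmax(stats::rnorm(config$n_controls, config$control_age[["mean"]],
                                    config$control_age[["sd"]]), 20), 95)
  ind <- data.frame(
    individual_id = c(rel$individual_id,
                      sprintf("CTRL_%03d", seq_len(config$n_controls))),
    group = c(rep("relative", nrow(rel)), rep("control", config$n_controls)),
    age_at_sampling = c(rel$age_at_sampling, ctl_age),
    sex = c(rel$sex, sample(1:2, config$n_controls, replace = TRUE)),
    stringsAsFactors = FALSE)
  n <- nrow(ind)
  is_rel <- ind$group == "relative"

  sums <- sapply(c("flc", "iga", "igg", "igm"), function(cl) {
    v <- numeric(n)
    for (g in c("control", "relative")) {
      cal <- lnorm_calib(config$ig_sums[[g]][[cl]])
      rowsel <- which(ind$group == g)
      v[rowsel] <- stats::rlnorm(length(rowsel), cal["meanlog"], cal["sdlog"])
    }
    v
  })

  ratios <- sapply(c("iga", "igg", "igm"), function(cl) {
    r <- config$hlc_ratio_ranges[[cl]]
    stats::rlnorm(n, log(sqrt(r[1] * r[2])), log(r[2] / r[1]) / (2 * stats::qnorm(0.975)))
  })

  # FLC ratio: linear age trend + noise, confined to the diagnostic range
  # unless designated abnormal
  slope <- ifelse(is_rel, config$flc_ratio_slope[["relative"]],
                  config$flc_ratio_slope[["control"]])
  center <- config$flc_ratio_at60 + slope * (ind$age_at_sampling - 60)
  flc_ratio <- stats::rnorm(n, center, config$flc_ratio_sd)
  lo <- FLC_DIAGNOSTIC_RANGE[["lower"]]; hi <- FLC_DIAGNOSTIC_RANGE[["upper"]]
  for (rep in 1:50) {
    out <- flc_ratio <= lo | flc_ratio >= hi
    if (!any(out)) break
    flc_ratio[out] <- stats::rnorm(sum(out), center[out], config$flc_ratio_sd)
  }
  flc_ratio <- pmin(pmax(flc_ratio, lo + 0.01), hi - 0.01)
  prev <- ifelse(is_rel, config$aflc_prevalence[["relative"]],
                 config$aflc_prevalence[["control"]])
  designated <- stats::runif(n) < prev
  des_idx <- which(designated)
  side_low <- stats::runif(length(des_idx)) < 0.2 # ~1:4 low:high skewing
  flc_ratio[des_idx[side_low]] <- stats::runif(sum(side_low), 0.05, 0.24)
  flc_ratio[des_idx[!side_low]] <- stats::runif(sum(!side_low), 1.80, 3.50)

  split_kl <- function(s, r) list(kappa = s * r / (1 + r), lambda = s / (1 + r))
  pheno <- ind
  for (cl in c("flc", "iga", "igg", "igm")) {
    r <- if (cl == "flc") flc_ratio else ratios[, cl]
    kl <- split_kl(sums[, cl], r)
    pheno[[paste0(cl, "_kappa")]] <- kl$kappa
    pheno[[paste0(cl, "_lambda")]] <- kl$lambda
  }

  ctl_igm <- lnorm_calib(config$ig_sums$control$igm)
  rel_igm <- lnorm_calib(config$ig_sums$relative$igm)
  thr_true <- stats::qlnorm(0.95, ctl_igm["meanlog"], ctl_igm["sdlog"])
  lnorm_mean <- function(cal) exp(cal[["meanlog"]] + cal[["sdlog"]]^2 / 2)
  # the marginal (observable) age-trend slope is diluted by the designated
  # out-of-range fraction, whose values are age-independent
  slope_marg <- (1 - config$aflc_prevalence) *
    config$flc_ratio_slope[c("control", "relative")]
  truth <- list(
    seed = config$seed,
    aflc_designated = ind$individual_id[designated],
    aflc_prevalence = as.list(config$aflc_prevalence),
    eigm_threshold_true = unname(thr_true),
    eigm_rate_relative_true = unname(
      stats::plnorm(thr_true, rel_igm["meanlog"], rel_igm["sdlog"],
                    lower.tail = FALSE)),
    flc_ratio_slope = as.list(config$flc_ratio_slope),
    flc_ratio_slope_marginal = as.list(slope_marg),
    flc_ratio_sd = config$flc_ratio_sd,
    igm_sum_mean_diff = unname(lnorm_mean(rel_igm) - lnorm_mean(ctl_igm)),
    igm_sum_median = list(control = config$ig_sums$control$igm[1],
                          relative = config$ig_sums$relative$igm[1]))
  list(phenotypes = pheno, truth = truth)
}

#' Simulate cancer diagnoses across pedigree members
#'
#' Pedigrees are first classified by the abnormal phenotypes their sampled
#' members harbor (using the supplied profiles); every bloodline member of
#' a pedigree then draws each cancer category as an independent Bernoulli
#' at that cohort's configured rate (precedence eIgM > aFLC > normal when
#' a pedigree harbors both). CLL is drawn only for non-sampled bloodline
#' members (sampled relatives are CLL-free by design), MBL only for
#' sampled members (screen-detected), and sex-specific categories only for
#' the matching sex. Marry-ins receive no diagnoses.
#'
#' @param sim output of [simulate_pedigrees()].
#' @param profiles per-sampled-member abnormality profiles (from
#'   [classify_abnormal()], with an `individual_id` column).
#' @param config the same [simulation_config()].
#' @return list with `diagnoses` (data frame: individual_id, category) and
#'   `truth` (cohort rate table and the per-pedigree cohort assignment).
#' @export
simulate_cancers <- function(sim, profiles, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  cats <- categorize_pedigrees(sim$pedigrees, profiles)
  cohort_of <- stats::setNames(
    ifelse(cats$harbors_eigm, "eigm", ifelse(cats$harbors_aflc, "aflc", "normal")),
    cats$pedigree_id)
  rates <- config$cancer_rates
  members <- sim$members
  rows <- list()
  for (i in seq_len(nrow(members))) {
    if (!members$bloodline[i]) next
    pid <- members$pedigree_id[i]
    if (!pid %in% names(cohort_of)) next
    coh <- cohort_of[[pid]]
    if (is.na(coh)) next
    for (j in seq_len(nrow(rates))) {
      cat_ <- rates$category[j]
      if (cat_ == "CLL_SLL" && members$sampled[i]) next
      if (cat_ == "MBL" && !members$sampled[i]) next
      sex_need <- SEX_SPECIFIC[cat_]
      if (!is.na(sex_need) &&
          members$sex[i] != c(male = 1L, female = 2L)[[sex_need]]) next
      if (stats::runif(1) < rates[[coh]][j])
        rows[[length(rows) + 1]] <- data.frame(
          individual_id = members$individual_id[i], category = cat_,
          stringsAsFactors = FALSE)
    }
  }
  dx <- if (length(rows)) do.call(rbind, rows) else
    data.frame(individual_id = character(0), category = character(0))
  list(diagnoses = dx,
       truth = list(cohort_of = as.list(cohort_of), rates = rates))
}

#' Generate a complete named input bundle
#'
#' Scenarios: `"paper_like"` (the default study-like conditions),
#' `"null"` (no group differences anywhere: identical Ig distributions,
#' equal FLC slopes, equal aFLC prevalence, cancer rates independent of
#' cohort), `"enriched"` (stronger group effects), and
#' `"separation_stress"` (a small cohort in which abnormal FLC occurs only
#' among relatives, so unpenalized logistic fits separate).
#'
#' @param name scenario name.
#' @param seed integer seed; the bundle is a deterministic function of
#'   (name, seed).
#' @param dir optional directory; when given, writes `pedigrees.ped`,
#'   `phenotypes.csv`, `diagnoses.csv` and `truth.json` there.
#' @return (invisibly when writing) list with `config`, `pedigrees`,
#'   `phenotypes`, `diagnoses`, `truth`.
#' @export
make_scenario <- function(name = c("paper_like", "null", "enriched",
                                   "separation_stress"),
                          seed = 1L, dir = NULL) {
  name <- match.arg(name)
  cfg <- switch(name,
    paper_like = simulation_config(seed = seed),
    null = {
      base <- simulation_config(seed = seed)
      rates <- base$cancer_rates
      rates$aflc <- rates$normal
      rates$eigm <- rates$normal
      simulation_config(
        seed = seed,
        ig_sums = list(control = base$ig_sums$control,
                       relative = base$ig_sums$control),
        aflc_prevalence = c(control = 0.013, relative = 0.013),
        flc_ratio_slope = c(control = 0.0038, relative = 0.0038),
        cancer_rates = rates)
    },
    enriched = {
      base <- simulation_config(seed = seed)
      ig <- base$ig_sums
      ig$relative$igm <- c(120, 40, 380)
      simulation_config(seed = seed, ig_sums = ig,
                        aflc_prevalence = c(control = 0.013, relative = 0.15))
    },
    separation_stress = simulation_config(
      seed = seed, n_pedigrees = 4L, n_sampled_relatives = 20L,
      n_controls = 45L, generations_range = c(3L, 5L),
      aflc_prevalence = c(control = 0, relative = 0.5)))

  sim <- simulate_pedigrees(cfg)
  panels <- simulate_ig_panels(sim, cfg)
  pheno <- panels$phenotypes
  # profiles of sampled relatives, for cancer assignment: classify against
  # control-derived ranges exactly as the pipeline will
  vars <- derive_ig_variables(pheno)
  ctl <- pheno$group == "control"
  ranges <- list(flc = FLC_DIAGNOSTIC_RANGE,
                 iga = reference_range_95(vars$iga_ratio[ctl]),
                 igg = reference_range_95(vars$igg_ratio[ctl]),
                 igm = reference_range_95(vars$igm_ratio[ctl]))
  prof <- classify_abnormal(vars, ranges, eigm_threshold(vars$igm_sum[ctl]))
  prof$individual_id <- pheno$individual_id
  cancers <- simulate_cancers(sim, prof[pheno$group == "relative", ], cfg)

  truth <- c(list(scenario = name), panels$truth, cancers$truth)
  bundle <- list(config = cfg, pedigrees = sim$pedigrees,
                 phenotypes = pheno, diagnoses = cancers$diagnoses,
                 truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_ped(sim$pedigrees, file.path(dir, "pedigrees.ped"))
    utils::write.csv(pheno, file.path(dir, "phenotypes.csv"), row.names = FALSE)
    utils::write.csv(cancers$diagnoses, file.path(dir, "diagnoses.csv"),
                     row.names = FALSE)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(bundle))
  }
  bundle
}
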