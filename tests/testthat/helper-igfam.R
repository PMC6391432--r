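# shared fixtures and independent oracles, built in code

# three-generation pedigree with two apical founder couples:
# paternal grandparents gf1/gm1, maternal grandparents gf2/gm2,
# parents fa/mo, children s1 (index), s2; uncle un + marry-in usp with
# children c1, c2 (first cousins of s1)
toy_pedigree <- function() {
  pedigree(data.frame(
    individual_id = c("gf1", "gm1", "gf2", "gm2", "fa", "un", "mo",
                      "usp", "s1", "s2", "c1", "c2"),
    father_id = c("0", "0", "0", "0", "gf1", "gf1", "gf2",
                  "0", "fa", "fa", "un", "un"),
    mother_id = c("0", "0", "0", "0", "gm1", "gm1", "gm2",
                  "0", "mo", "mo", "usp", "usp"),
    sex = c(1, 2, 1, 2, 1, 1, 2, 2, 1, 2, 1, 2)),
    pedigree_id = "toy")
}

# pedigree with a half-sibling pair (shared father, different mothers)
halfsib_pedigree <- function() {
  pedigree(data.frame(
    individual_id = c("f", "m1", "m2", "h1", "h2"),
    father_id = c("0", "0", "0", "f", "f"),
    mother_id = c("0", "0", "0", "m1", "m2"),
    sex = c(1, 2, 2, 1, 2)),
    pedigree_id = "half", founders = c("f", "m1"))
}

# Monte-Carlo gene-dropping oracle for the kinship coefficient: every
# parentless individual gets two unique alleles; children inherit one
# random allele from each parent; phi(i,j) is the probability a random
# allele of i equals a random allele of j
gene_drop_kinship <- function(ped, i, j, n_rep = 1e5) {
  n <- length(ped$id)
  ord <- order(ped$generation)
  a1 <- matrix(0L, n_rep, n)
  a2 <- matrix(0L, n_rep, n)
  next_allele <- 0L
  for (k in ord) {
    f <- ped$father[k]; m <- ped$mother[k]
    a1[, k] <- if (is.na(f)) { next_allele <- next_allele + 1L
      rep(next_allele, n_rep)
    } else ifelse(stats::runif(n_rep) < 0.5, a1[, f], a2[, f])
    a2[, k] <- if (is.na(m)) { next_allele <- next_allele + 1L
      rep(next_allele, n_rep)
    } else ifelse(stats::runif(n_rep) < 0.5, a1[, m], a2[, m])
  }
  ii <- match(i, ped$id); jj <- match(j, ped$id)
  ibd <- ((a1[, ii] == a1[, jj]) + (a1[, ii] == a2[, jj]) +
            (a2[, ii] == a1[, jj]) + (a2[, ii] == a2[, jj])) / 4
  c(phi = mean(ibd), se = stats::sd(ibd) / sqrt(n_rep))
}

# brute-force relative enumeration oracle: all bloodline members whose
# kinship-derived degree to any index is within max_degree
brute_force_relatives <- function(ped, index_ids, max_degree = 3) {
  K <- kinship(ped)
  out <- character(0)
  for (one in index_ids) {
    for (other in ped$id[ped$bloodline]) {
      if (other == one) next
      phi <- K[one, other]
      if (phi <= 0) next
      d <- -log2(2 * phi)
      if (abs(d - round(d)) < 1e-9 && round(d) <= max_degree)
        out <- c(out, other)
    }
  }
  sort(setdiff(unique(out), index_ids))
}

# exhaustive assignment oracle: minimum total |score difference| over all
# ways to pair the smaller group into the larger (feasible up to ~7x7)
brute_force_match <- function(rel_scores, ctl_scores) {
  nr <- length(rel_scores); nc <- length(ctl_scores)
  if (nr > nc) return(brute_force_match(ctl_scores, rel_scores))
  perms <- function(v, k) {
    if (k == 0) return(list(integer(0)))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i], k - 1)) out <- c(out, list(c(v[i], rest)))
    out
  }
  best <- Inf
  for (p in perms(seq_len(nc), nr))
    best <- min(best, sum(abs(rel_scores - ctl_scores[p])))
  best
}

# greedy nearest-neighbour matching (for the optimality comparison)
greedy_match_distance <- function(rel_scores, ctl_scores) {
  if (length(rel_scores) > length(ctl_scores))
    return(greedy_match_distance(ctl_scores, rel_scores))
  avail <- seq_along(ctl_scores)
  tot <- 0
  for (s in rel_scores) {
    k <- avail[which.min(abs(ctl_scores[avail] - s))]
    tot <- tot + abs(ctl_scores[k] - s)
    avail <- setdiff(avail, k)
  }
  tot
}

# grid/optimize oracle for the conditional MLE: maximize the conditional
# log-likelihood over log(psi) directly (uses stats::dhyper weights, an
# implementation independent of nchg_pmf)
cmle_grid_oracle <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  sup <- max(0, k - n):min(k, m)
  lw <- stats::dhyper(sup, m, n, k, log = TRUE)
  ll <- function(lpsi) {
    t <- lw + sup * lpsi
    a * lpsi - max(t) - log(sum(exp(t - max(t))))
  }
  exp(stats::optimize(ll, c(-35, 35), maximum = TRUE, tol = 1e-10)$maximum)
}

# minimal "sim" stub so simulate_ig_panels can run without pedigrees:
# n relatives with ages/sex drawn outside the generator
panel_stub <- function(n_rel, seed) {
  set.seed(seed)
  data.frame(
    individual_id = sprintf("R%04d", seq_len(n_rel)),
    pedigree_id = "stub",
    sex = sample(1:2, n_rel, replace = TRUE),
    age_at_sampling = pmin(pmax(stats::rnorm(n_rel, 60, 15), 25), 95),
    stringsAsFactors = FALSE)
}

expect_round2 <- function(x, target) {
  expect_equal(round(x, 2), target, tolerance = 1e-12)
}
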