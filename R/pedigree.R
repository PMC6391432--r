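#' Construct a pedigree object
#'
#' Builds a validated genealogy graph from per-individual records. A pedigree
#' is a directed acyclic graph in which each individual has at most one
#' recorded father and one recorded mother; individuals with no recorded
#' parents are either apical founders or marry-in spouses. The bloodline is
#' the set of designated founders together with all their descendants;
#' everyone else (spouses who married into the family) is excluded from
#' familial cancer counts downstream.
#'
#' Founders can be designated explicitly via `founders`. By default they are
#' inferred as the parentless members whose downward descendant depth (length
#' of the longest child-chain below them) equals the maximum over all
#' parentless members: an apical founder couple both attain the maximum,
#' whereas a spouse marrying in at a later generation sits at least one
#' level lower.
#'
#' @param members data frame with columns `individual_id`, `father_id`,
#'   `mother_id`, `sex` (`"male"`, `"female"`, `"unknown"`, or 1/2/0),
#'   and optionally `sampled` (logical or 0/1) and `age_at_sampling`.
#'   `"0"`, `""` and `NA` in the parent columns mean "no recorded parent".
#' @param pedigree_id identifier for the pedigree; taken from a
#'   `pedigree_id` column if present.
#' @param founders optional character vector of founder individual ids;
#'   overrides the heuristic.
#' @return An object of class `"pedigree"`: a list with elements `id`
#'   (character), `father`/`mother` (integer indices or `NA`), `sex`
#'   (factor), `sampled` (logical), `age_at_sampling` (numeric),
#'   `generation` (1 = parentless), `founders` (integer indices) and
#'   `bloodline` (logical).
#' @examples
#' ped <- pedigree(data.frame(
#'   individual_id = c("f", "m", "c1", "c2"),
#'   father_id = c("0", "0", "f", "f"),
#'   mother_id = c("0", "0", "m", "m"),
#'   sex = c(1, 2, 1, 2)))
#' is_bloodline(ped, "c1")
#' @export
pedigree <- function(members, pedigree_id = NULL, founders = NULL) {
  req <- c("individual_id", "father_id", "mother_id", "sex")
  miss <- setdiff(req, names(members))
  if (length(miss)) stopf("pedigree: missing columns: %s", paste(miss, collapse = ", "))
  id <- as.character(members$individual_id)
  if (anyDuplicated(id)) stopf("pedigree: duplicated individual ids")
  n <- length(id)
  if (n == 0L) stopf("pedigree: no members")

  absent <- function(x) is.na(x) | x == "0" | x == ""
  fid <- as.character(members$father_id); fid[absent(fid)] <- NA
  mid <- as.character(members$mother_id); mid[absent(mid)] <- NA

  bad_f <- !is.na(fid) & !(fid %in% id)
  bad_m <- !is.na(mid) & !(mid %in% id)
  if (any(bad_f | bad_m))
    stopf("pedigree: parent id(s) not among members: %s",
          paste(unique(c(fid[bad_f], mid[bad_m])), collapse = ", "))

  sex_raw <- members$sex
  sex <- if (is.numeric(sex_raw)) {
    c("0" = "unknown", "1" = "male", "2" = "female")[as.character(sex_raw)]
  } else {
    s <- tolower(as.character(sex_raw))
    s[s %in% c("0", "u", "unknown", "")] <- "unknown"
    s[s %in% c("1", "m")] <- "male"
    s[s %in% c("2", "f")] <- "female"
    s
  }
  if (any(is.na(sex) | !sex %in% c("male", "female", "unknown")))
    stopf("pedigree: unrecognized sex codes")
  sex <- factor(sex, levels = c("male", "female", "unknown"))

  father <- match(fid, id)
  mother <- match(mid, id)
  if (any(sex[stats::na.omit(father)] == "female"))
    stopf("pedigree: a recorded father has sex 'female'")
  if (any(sex[stats::na.omit(mother)] == "male"))
    stopf("pedigree: a recorded mother has sex 'male'")
  if (any(!is.na(father) & father == seq_len(n)) ||
      any(!is.na(mother) & mother == seq_len(n)))
    stopf("pedigree: an individual is its own parent")

  # generation numbering doubles as cycle detection: generation(i) =
  # 1 + max(generation(parents)), parentless = 1; no fixpoint => cycle
  gen <- rep(NA_integer_, n)
  gen[is.na(father) & is.na(mother)] <- 1L
  repeat {
    todo <- which(is.na(gen))
    if (!length(todo)) break
    progressed <- FALSE
    for (i in todo) {
      pg <- c(if (!is.na(father[i])) gen[father[i]] else 0L,
              if (!is.na(mother[i])) gen[mother[i]] else 0L)
      if (!anyNA(pg)) {
        gen[i] <- 1L + max(pg)
        progressed <- TRUE
      }
    }
    if (!progressed)
      stopf("pedigree: cycle detected (an individual is its own ancestor)")
  }

  sampled <- if ("sampled" %in% names(members)) {
    s <- members$sampled
    if (is.numeric(s)) s != 0 else as.logical(s)
  } else rep(FALSE, n)
  age <- if ("age_at_sampling" %in% names(members))
    as.numeric(members$age_at_sampling) else rep(NA_real_, n)

  pid <- pedigree_id %||%
    (if ("pedigree_id" %in% names(members)) as.character(members$pedigree_id[1]) else "ped")

  obj <- structure(list(
    pedigree_id = pid, id = id, father = father, mother = mother,
    sex = sex, sampled = sampled, age_at_sampling = age,
    generation = gen), class = "pedigree")

  f_idx <- if (!is.null(founders)) {
    fi <- match(as.character(founders), id)
    if (anyNA(fi)) stopf("pedigree: unknown founder id(s)")
    fi
  } else {
    infer_founders(obj)
  }
  obj$founders <- sort(f_idx)
  obj$bloodline <- bloodline_mask(obj, obj$founders)
  obj
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("Pedigree '%s': %d members (%d bloodline, %d marry-in), %d generation(s), %d founder(s), %d sampled\n",
              x$pedigree_id, length(x$id), sum(x$bloodline),
              sum(!x$bloodline), max(x$generation), length(x$founders),
              sum(x$sampled)))
  invisible(x)
}

ped_index <- function(ped, who) {
  i <- match(as.character(who), ped$id)
  if (anyNA(i))
    stopf("pedigree '%s': unknown individual id(s): %s", ped$pedigree_id,
          paste(as.character(who)[is.na(i)], collapse = ", "))
  i
}

# longest child-chain below each individual (0 for childless)
descendant_depth <- function(ped) {
  n <- length(ped$id)
  depth <- rep(0L, n)
  for (i in order(ped$generation, decreasing = TRUE)) {
    for (p in c(ped$father[i], ped$mother[i])) {
      if (!is.na(p)) depth[p] <- max(depth[p], depth[i] + 1L)
    }
  }
  depth
}

infer_founders <- function(ped) {
  parentless <- which(is.na(ped$father) & is.na(ped$mother))
  depth <- descendant_depth(ped)
  which(is.na(ped$father) & is.na(ped$mother) & depth == max(depth[parentless]))
}

bloodline_mask <- function(ped, founder_idx) {
  n <- length(ped$id)
  bl <- rep(FALSE, n)
  bl[founder_idx] <- TRUE
  for (i in order(ped$generation)) {
    if (bl[i]) next
    f <- ped$father[i]; m <- ped$mother[i]
    bl[i] <- (!is.na(f) && bl[f]) || (!is.na(m) && bl[m])
  }
  bl
}

#' Kinship coefficients within a pedigree
#'
#' Computes the kinship coefficient \eqn{\phi(i,j)} -- the probability that a
#' randomly chosen allele from `i` and one from `j` are identical by descent
#' -- by the standard recursion over individuals ordered so that parents
#' precede children: \eqn{\phi(i,i) = (1 + \phi(f_i, m_i))/2} and, for `j`
#' already processed, \eqn{\phi(i,j) = (\phi(f_i,j) + \phi(m_i,j))/2}, with a
#' missing parent contributing 0 (an unrecorded parent is treated as an
#' unrelated, unrecorded marry-in).
#'
#' @param ped a `"pedigree"` object.
#' @param i,j optional individual ids; if omitted the full symmetric matrix
#'   is returned.
#' @return The full kinship matrix (ids as dimnames), or the scalar
#'   \eqn{\phi(i,j)} when `i` and `j` are given.
#' @examples
#' ped <- pedigree(data.frame(
#'   individual_id = c("f", "m", "c"),
#'   father_id = c("0", "0", "f"), mother_id = c("0", "0", "m"),
#'   sex = c(1, 2, 1)))
#' kinship(ped, "f", "c")  # parent-child: 0.25
#' @export
kinship <- function(ped, i = NULL, j = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  n <- length(ped$id)
  K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  ord <- order(ped$generation)
  done <- integer(0)
  for (k in ord) {
    f <- ped$father[k]; m <- ped$mother[k]
    kfm <- if (!is.na(f) && !is.na(m)) K[f, m] else 0
    if (length(done)) {
      row <- 0.5 * ((if (!is.na(f)) K[f, done] else 0) +
                    (if (!is.na(m)) K[m, done] else 0))
      K[k, done] <- row
      K[done, k] <- row
    }
    K[k, k] <- 0.5 * (1 + kfm)
    done <- c(done, k)
  }
  if (is.null(i)) return(K)
  K[ped_index(ped, i), ped_index(ped, j)]
}

#' Relationship degree between two pedigree members
#'
#' Degree is defined from expected relatedness: a pair is degree \eqn{d}
#' when \eqn{2\phi = 2^{-d}} (first degree: parent/child and full siblings;
#' second: grandparents, aunts/uncles, half-siblings; third: first cousins
#' and great-grandparents). `NA` means unrelated, related only by marriage,
#' or more distant than `max_degree`.
#'
#' In inbred pedigrees \eqn{2\phi} need not be a power of 1/2; such pairs
#' fall back to a minimum-meioses classification through common ancestors
#' (with the usual reduction by one when the closest link runs through a
#' full ancestral couple) and are flagged with a warning.
#'
#' @param ped a `"pedigree"` object.
#' @param i,j distinct individual ids.
#' @param max_degree degrees beyond this return `NA` (default 3, i.e., out
#'   to first cousins).
#' @return integer degree in `1:max_degree`, or `NA_integer_`.
#' @export
relationship_degree <- function(ped, i, j, max_degree = 3L) {
  ii <- ped_index(ped, i); jj <- ped_index(ped, j)
  if (ii == jj) stopf("relationship_degree: i and j must differ")
  phi <- kinship(ped)[ii, jj]
  degree_from_phi(ped, ii, jj, phi, max_degree)
}

degree_from_phi <- function(ped, ii, jj, phi, max_degree = 3L) {
  if (phi <= 0) return(NA_integer_)
  d <- -log2(2 * phi)
  if (abs(d - round(d)) < 1e-9) {
    d <- as.integer(round(d))
    if (d >= 1L && d <= max_degree) return(d) else return(NA_integer_)
  }
  # inbred pair: 2*phi not a power of 1/2 -- classify by minimum meioses
  d <- min_meiosis_degree(ped, ii, jj)
  warnf("pedigree '%s': inbred pair (%s, %s) classified by minimum meiotic path (degree %d)",
        ped$pedigree_id, ped$id[ii], ped$id[jj], d)
  if (d >= 1L && d <= max_degree) d else NA_integer_
}

# minimum generations from an individual up to every ancestor (incl. self);
# names are member indices as strings
ancestor_depths <- function(ped, i) {
  depth <- integer(0)
  depth[as.character(i)] <- 0L
  frontier <- i
  while (length(frontier)) {
    nxt <- integer(0)
    for (k in frontier) {
      dk <- depth[[as.character(k)]]
      for (p in c(ped$father[k], ped$mother[k])) {
        if (!is.na(p)) {
          key <- as.character(p)
          if (!(key %in% names(depth)) || depth[[key]] > dk + 1L) {
            depth[key] <- dk + 1L
            nxt <- c(nxt, p)
          }
        }
      }
    }
    frontier <- unique(nxt)
  }
  depth
}

min_meiosis_degree <- function(ped, ii, jj) {
  di <- ancestor_depths(ped, ii)
  dj <- ancestor_depths(ped, jj)
  common <- intersect(names(di), names(dj))
  if (!length(common)) return(NA_integer_)
  tot <- di[common] + dj[common]
  m <- min(tot)
  # two ancestors attaining the minimum = a full ancestral couple => the
  # doubled path halves the degree-equivalent (siblings: 2 meioses, degree 1)
  as.integer(if (sum(tot == m) >= 2L) m - 1L else m)
}

#' Is an individual in the bloodline?
#'
#' Bloodline members are the designated founders and all their descendants;
#' spouses who married into the pedigree (parentless members that are not
#' founders) are not bloodline and are excluded from familial cancer counts.
#'
#' @param ped a `"pedigree"` object.
#' @param i individual id(s).
#' @return logical vector.
#' @export
is_bloodline <- function(ped, i) {
  ped$bloodline[ped_index(ped, i)]
}

#' Enumerate unique first- to `max_degree`-degree bloodline relatives
#'
#' Given one or several pedigrees and a set of index individuals, returns the
#' deduplicated union of their bloodline relatives of relationship degree 1
#' to `max_degree` (default: out to first cousins). Index individuals are
#' never included in the result, even when two index members are relatives of
#' each other; marry-in spouses are excluded.
#'
#' @param peds a `"pedigree"` or a list of them.
#' @param index_ids character vector of index individual ids (must be
#'   bloodline members).
#' @param max_degree maximum relationship degree (default 3).
#' @return sorted character vector of unique relative ids.
#' @export
enumerate_relatives <- function(peds, index_ids, max_degree = 3L) {
  if (inherits(peds, "pedigree")) peds <- list(peds)
  index_ids <- unique(as.character(index_ids))
  if (!length(index_ids)) return(character(0))
  out <- character(0)
  seen <- character(0)
  for (ped in peds) {
    idx <- index_ids[index_ids %in% ped$id]
    seen <- c(seen, idx)
    if (!length(idx)) next
    if (!all(is_bloodline(ped, idx)))
      stopf("enumerate_relatives: index individual(s) not bloodline in pedigree '%s'",
            ped$pedigree_id)
    K <- kinship(ped)
    for (one in idx) {
      ii <- ped_index(ped, one)
      for (jj in which(ped$bloodline)) {
        if (jj == ii) next
        d <- suppressWarnings(degree_from_phi(ped, ii, jj, K[ii, jj], max_degree))
        if (!is.na(d)) out <- c(out, ped$id[jj])
      }
    }
  }
  missing <- setdiff(index_ids, seen)
  if (length(missing))
    stopf("enumerate_relatives: index id(s) not found in any pedigree: %s",
          paste(missing, collapse = ", "))
  sort(setdiff(unique(out), index_ids))
}
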