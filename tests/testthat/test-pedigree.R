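test_that("kinship matches its defining values on standard relationships", {
  ped <- toy_pedigree()
  expect_equal(kinship(ped, "fa", "s1"), 0.25)    # parent-child
  expect_equal(kinship(ped, "s1", "s1"), 0.5)     # outbred self
  expect_equal(kinship(ped, "s1", "s2"), 0.25)    # full siblings
  expect_equal(kinship(ped, "gf1", "s1"), 0.125)  # grandparent
  expect_equal(kinship(ped, "s1", "c1"), 0.0625)  # first cousins
  expect_equal(kinship(ped, "fa", "mo"), 0)       # spouses
  expect_equal(kinship(ped, "usp", "s1"), 0)      # marry-in vs bloodline
  K <- kinship(ped)
  expect_true(isSymmetric(K))
})

test_that("kinship agrees with a gene-dropping Monte-Carlo oracle", {
  set.seed(101)
  ped <- toy_pedigree()
  for (pair in list(c("s1", "s2"), c("s1", "c1"), c("gf1", "c2"),
                    c("un", "s1"), c("mo", "c1"))) {
    mc <- gene_drop_kinship(ped, pair[1], pair[2], n_rep = 1e5)
    expect_lt(abs(kinship(ped, pair[1], pair[2]) - mc["phi"]),
              3 * mc["se"] + 1e-12)
  }
})

test_that("relationship degree follows expected relatedness out to cousins", {
  ped <- toy_pedigree()
  expect_identical(relationship_degree(ped, "fa", "s1"), 1L)
  expect_identical(relationship_degree(ped, "s1", "s2"), 1L)
  expect_identical(relationship_degree(ped, "gf1", "s1"), 2L)
  expect_identical(relationship_degree(ped, "un", "s1"), 2L)
  expect_identical(relationship_degree(ped, "s1", "c1"), 3L)
  expect_identical(relationship_degree(ped, "fa", "mo"), NA_integer_) # spouses
  expect_identical(relationship_degree(ped, "usp", "s1"), NA_integer_)
  # symmetry
  for (pair in list(c("s1", "c1"), c("gf1", "s2"), c("un", "c1")))
    expect_identical(relationship_degree(ped, pair[1], pair[2]),
                     relationship_degree(ped, pair[2], pair[1]))
  # half-siblings are second degree under the kinship rule
  expect_identical(relationship_degree(halfsib_pedigree(), "h1", "h2"), 2L)
})

test_that("inbred pairs fall back to minimum-meioses classification with a flag", {
  # parents are first cousins, so the child-parent pair has 2*phi off the
  # power-of-1/2 grid
  ped <- pedigree(data.frame(
    individual_id = c("gf", "gm", "p1", "p2", "w1", "w2", "k1", "k2", "kid"),
    father_id = c("0", "0", "gf", "gf", "0", "0", "p1", "p2", "k1"),
    mother_id = c("0", "0", "gm", "gm", "0", "0", "w1", "w2", "k2"),
    sex = c(1, 2, 1, 1, 2, 2, 1, 2, 1)))
  phi <- kinship(ped, "k1", "kid")
  expect_equal(phi, 9 / 32)  # parent-child with first-cousin parents
  expect_false(abs(-log2(2 * phi) - round(-log2(2 * phi))) < 1e-9)
  expect_warning(d <- relationship_degree(ped, "k1", "kid"),
                 "minimum meiotic path")
  expect_identical(d, 1L)
})

test_that("bloodline excludes marry-ins and the founder heuristic finds the apex", {
  ped <- toy_pedigree()
  expect_true(all(is_bloodline(ped, c("gf1", "gm1", "gf2", "gm2", "fa",
                                      "mo", "un", "s1", "c1"))))
  expect_false(is_bloodline(ped, "usp"))
  # explicit founder designation narrows the bloodline
  ped2 <- pedigree(data.frame(
    individual_id = c("gf1", "gm1", "gf2", "gm2", "fa", "mo", "s1"),
    father_id = c("0", "0", "0", "0", "gf1", "gf2", "fa"),
    mother_id = c("0", "0", "0", "0", "gm1", "gm2", "mo"),
    sex = c(1, 2, 1, 2, 1, 2, 1)), founders = c("gf1", "gm1"))
  expect_false(is_bloodline(ped2, "mo"))
  expect_true(is_bloodline(ped2, "s1"))
})

test_that("pedigree validation rejects malformed structures", {
  base <- data.frame(individual_id = c("a", "b", "c"),
                     father_id = c("0", "0", "a"),
                     mother_id = c("0", "0", "b"),
                     sex = c(1, 2, 1))
  expect_s3_class(pedigree(base), "pedigree")
  bad_sex <- base; bad_sex$sex <- c(2, 2, 1)     # female father
  expect_error(pedigree(bad_sex), "father")
  bad_parent <- base; bad_parent$father_id[3] <- "zz"
  expect_error(pedigree(bad_parent), "not among members")
  cyc <- data.frame(individual_id = c("a", "b", "c"),
                    father_id = c("c", "0", "a"),
                    mother_id = c("0", "0", "b"),
                    sex = c(1, 2, 1))
  expect_error(pedigree(cyc), "cycle|own parent")
})

test_that("enumerate_relatives deduplicates, excludes index and marry-ins", {
  ped <- toy_pedigree()
  # brute-force oracle count for the toy pedigree: parents, sibling, four
  # grandparents, uncle, two cousins
  oracle <- brute_force_relatives(ped, "s1")
  expect_identical(enumerate_relatives(ped, "s1"), oracle)
  expect_length(oracle, 10)
  expect_false("usp" %in% oracle)
  # two sibling index members: excluded from each other's relatives,
  # shared kin counted once
  both <- enumerate_relatives(ped, c("s1", "s2"))
  expect_identical(both, brute_force_relatives(ped, c("s1", "s2")))
  expect_false(any(c("s1", "s2") %in% both))
  expect_identical(both, sort(unique(both)))
  # invariant to index ordering
  expect_identical(enumerate_relatives(ped, c("s2", "s1")), both)
  # empty index
  expect_identical(enumerate_relatives(ped, character(0)), character(0))
  # max_degree = 1 keeps only nuclear-family links
  expect_identical(enumerate_relatives(ped, "s1", max_degree = 1),
                   sort(c("fa", "mo", "s2")))
})

test_that("degree grows by one per added meiosis along a lineal chain", {
  # founder couple -> child -> grandchild -> great-grandchild ...
  chain <- pedigree(data.frame(
    individual_id = c("f0", "m0", "g1", "w1", "g2", "w2", "g3", "w3", "g4"),
    father_id = c("0", "0", "f0", "0", "g1", "0", "g2", "0", "g3"),
    mother_id = c("0", "0", "m0", "0", "w1", "0", "w2", "0", "w3"),
    sex = c(1, 2, 1, 2, 1, 2, 1, 2, 1)))
  expect_identical(relationship_degree(chain, "f0", "g1"), 1L)
  expect_identical(relationship_degree(chain, "f0", "g2"), 2L)
  expect_identical(relationship_degree(chain, "f0", "g3"), 3L)
  # beyond the third degree: reported as none
  expect_identical(relationship_degree(chain, "f0", "g4"), NA_integer_)
  expect_identical(relationship_degree(chain, "f0", "g4", max_degree = 4L), 4L)
})

test_that("PED round-trip preserves structure and detects headers", {
  ped <- toy_pedigree()
  tf <- tempfile(fileext = ".ped")
  write_ped(ped, tf)
  back <- read_ped(tf)
  expect_length(back, 1)
  p2 <- back[[1]]
  expect_setequal(p2$id, ped$id)
  expect_equal(kinship(p2)[ped$id, ped$id], kinship(ped))
  expect_identical(sort(p2$id[p2$bloodline]), sort(ped$id[ped$bloodline]))
  # headerless variant
  tf2 <- tempfile(fileext = ".ped")
  writeLines(readLines(tf)[-1], tf2)
  expect_setequal(read_ped(tf2)[[1]]$id, ped$id)
})
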