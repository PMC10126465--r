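test_that("self-alignment gives 100% identity and coverage", {
  for (s in c("M", "ACDEFGHIKLMNPQRSTVWY", duf_prototypes()[["yetf"]])) {
    al <- global_align(s, s)
    expect_equal(al$percent_identity, 100)
    expect_equal(al$query_coverage, 100)
    expect_equal(al$aligned_a, toupper(s))
  }
})

test_that("a single substitution yields 3/4 identity without gaps", {
  al <- global_align("AAAA", "AATA")
  expect_equal(al$percent_identity, 75)
  expect_equal(al$query_coverage, 100)
  expect_equal(al$aligned_a, "AAAA")
  expect_equal(al$aligned_b, "AATA")
})

test_that("identity is symmetric and terminal gaps are excluded", {
  a <- "MKVLAT"; b <- "KVLATWQERT"
  f <- global_align(a, b)
  r <- global_align(b, a)
  expect_equal(f$percent_identity, r$percent_identity)
  # prototype pair: symmetric under the symmetric BLOSUM62 table
  p <- duf_prototypes()
  expect_equal(global_align(p[["yetf"]], p[["duf2"]])$percent_identity,
               global_align(p[["duf2"]], p[["yetf"]])$percent_identity)
})

test_that("unknown residues are rejected, X is tolerated", {
  expect_error(global_align("ACDB", "ACDE"), "unknown residue")
  expect_silent(al <- global_align("ACXE", "ACDE"))
  expect_equal(al$n_columns, 4)
})

test_that("linear-gap scores match exhaustive enumeration on tiny pairs", {
  sub <- matrix(c(2, -3, -3, 2), 2, 2,
                dimnames = list(c("A", "R"), c("A", "R")))
  gap <- 2.5
  seqs4 <- all_seqs(c("A", "R"), 4)
  set.seed(14)
  pairs <- cbind(sample(seqs4, 150, replace = TRUE),
                 sample(seqs4, 150, replace = TRUE))
  for (i in seq_len(nrow(pairs))) {
    got <- global_align(pairs[i, 1], pairs[i, 2], substitution = sub,
                        gap_open = 0, gap_extend = gap)$score
    expect_equal(got, enum_align_score(pairs[i, 1], pairs[i, 2], sub, gap))
  }
})

test_that("affine-gap scores agree with the Biostrings aligner", {
  p <- duf_prototypes()
  set.seed(15)
  seqs <- c(p[["yetf"]], p[["duf2"]],
            generate_protein_set(3, 0, 3, seed = 15)$sequence)
  for (i in 1:4) {
    a <- sample(seqs, 1); b <- sample(seqs, 1)
    ours <- global_align(a, b, gap_open = 10, gap_extend = 0.5)$score
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
      type = "global", scoreOnly = TRUE)
    expect_equal(ours, ref)
  }
})

test_that("length classification follows the two census ranges", {
  expect_equal(classify_length(231), "YetF-like")
  expect_equal(classify_length(286), "2Duf-like")
  expect_equal(classify_length(400), "unclassified")
  expect_equal(classify_length(c(210, 253, 285, 290, 254, 284, 100)),
               c("YetF-like", "YetF-like", "2Duf-like", "2Duf-like",
                 "unclassified", "unclassified", "unclassified"))
  expect_error(classify_length(231, ranges = list(yetf = c(210, 286),
                                                  duf2 = c(285, 290))),
               "overlap")
})

test_that("census counts generated classes exactly and is order-invariant", {
  ps <- generate_protein_set(8, 5, 3, seed = 19)
  calls <- call_homologs(ps)
  cz <- census(calls)
  expect_equal(unname(cz$totals["n_yetf_like"]), 8)
  expect_equal(unname(cz$totals["n_2duf_like"]), 5)
  expect_equal(unname(cz$totals["n_unclassified"]), 3)

  perm <- sample(nrow(calls))
  cz2 <- census(calls[perm, ])
  expect_equal(cz2$totals, cz$totals)
  expect_equal(cz2$by_species[order(cz2$by_species$species), ],
               cz$by_species[order(cz$by_species$species), ])
})

test_that("multi-protein species are tabulated per class", {
  calls <- data.frame(
    id = c("p1", "p2", "p3"), species = "sp1",
    length = c(231, 235, 286),
    class = c("YetF-like", "YetF-like", "2Duf-like"),
    query = c("YetF", "YetF", "2Duf"),
    percent_identity = c(60, 55, 50), query_coverage = c(99, 98, 97))
  cz <- census(calls)
  expect_equal(cz$by_species$n_yetf_like, 2)
  expect_equal(cz$by_species$n_2duf_like, 1)
  # best YetF hit is the higher-identity protein
  bh <- cz$best_hits[cz$best_hits$query == "YetF", ]
  expect_equal(bh$id, "p1")
})

test_that("the coverage and E-value filters exclude weak hits", {
  calls <- data.frame(
    id = c("p1", "p2"), species = c("sp1", "sp2"),
    length = c(231, 231), class = "YetF-like", query = "YetF",
    percent_identity = c(60, 60), query_coverage = c(99, 80))
  cz <- census(calls)
  expect_equal(unname(cz$totals["n_yetf_like"]), 1)   # 80% coverage fails >85
  expect_false(cz$calls$passes_filter[2])

  hits <- data.frame(id = c("p1", "p2"), evalue = c(1e-50, 1e-20),
                     coverage = c(99, 99))
  cz2 <- census(calls, hits = hits)
  expect_true(cz2$calls$passes_filter[1])
  expect_false(cz2$calls$passes_filter[2])    # e-value above 1e-30 fails
})

test_that("best-hit selection follows the E-value rule and its literal variant", {
  calls <- data.frame(
    id = c("a", "b"), species = "sp1", length = 231,
    class = "YetF-like", query = "YetF",
    percent_identity = c(50, 60), query_coverage = 99)
  hits <- data.frame(id = c("a", "b"), evalue = c(1e-80, 1e-40))
  most <- census(calls, hits = hits)
  expect_equal(most$best_hits$id, "a")
  lit <- census(calls, hits = hits, best_hit = "literal_max")
  expect_equal(lit$best_hits$id, "b")
})
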