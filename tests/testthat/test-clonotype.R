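kt <- function(...) {
  x <- c(...)
  tibble::tibble(key = names(x), count = as.integer(x))
}

test_that("Hamming distance counts mismatches and rejects unequal lengths", {
  expect_equal(hamming_distance("ARDYW", "ARDYW"), 0L)
  expect_equal(hamming_distance("ARDYW", "ARDFW"), 1L)
  expect_equal(hamming_distance(c("AAAA", "AAAA"), c("AAAT", "TTTT")), c(1L, 4L))
  expect_error(hamming_distance("ARD", "ARDYW"), "unequal length")
})

test_that("Levenshtein distance matches the classic DP values", {
  expect_equal(levenshtein_distance("kitten", "sitting"), 3L)
  expect_equal(levenshtein_distance("abc", "abc"), 0L)
  expect_equal(levenshtein_distance("", "AB"), 2L)
  # pairwise matrix agrees with the scalar function
  x <- c("ARDY", "ARDFW", "GGGG", "ARDY")
  pw <- pairwise_levenshtein(x)
  for (r in seq_len(nrow(pw))) {
    expect_equal(pw$distance[r], levenshtein_distance(x[pw$i[r]], x[pw$j[r]]))
  }
})

test_that("singleton rescue follows the hierarchical algorithm", {
  # singleton within h of an abundant key is absorbed; distant one is kept
  ct <- hierarchical_clonotype(kt(AAAA = 5, AAAT = 1, CCCC = 1), h = 1)
  expect_equal(nrow(ct), 2L)
  expect_equal(ct$count[ct$clonotype == "AAAA"], 6L)
  expect_equal(ct$count[ct$clonotype == "CCCC"], 1L)
  expect_setequal(ct$members[ct$clonotype == "AAAA"][[1]], c("AAAA", "AAAT"))
  # h = 0 keeps every unique key
  expect_equal(nrow(hierarchical_clonotype(kt(AAAA = 5, AAAT = 1), h = 0)), 2L)
  # N >= 2 drops all singletons
  ab <- hierarchical_clonotype(kt(AAAA = 5, CCCC = 1), criterion = "abundance_only")
  expect_equal(nrow(ab), 1L)
  expect_equal(ab$clonotype, "AAAA")
  expect_error(hierarchical_clonotype(kt(AAAA = 2), h = 4), "0..3")
})

test_that("singletons of unequal length are never absorbed", {
  ct <- hierarchical_clonotype(kt(AAAA = 5, AAA = 1), h = 3)
  expect_equal(nrow(ct), 2L)
})

test_that("absorption ties go to the most abundant, then smallest key", {
  ct <- hierarchical_clonotype(kt(AAAA = 5, AAAG = 9, AAAT = 1), h = 1)
  expect_equal(ct$count[ct$clonotype == "AAAG"], 10L)  # higher count wins
  ct2 <- hierarchical_clonotype(kt(AAAA = 5, AAAG = 5, AAAT = 1), h = 1)
  expect_equal(ct2$count[ct2$clonotype == "AAAA"], 6L)  # lexicographic tie-break
})

test_that("key schemes build the documented composite keys", {
  ann <- tibble::tibble(
    sequence_id = c("a", "b", "c"),
    v_call = c("IGHV3-23", "IGHV1-69", "IGHV3-23"),
    cdr1_aa = "GFTFS", cdr2_aa = NA_character_,
    cdr3_aa = c("ARDYW", "ARDYW", "ARDYW"),
    junction_in_frame = TRUE, productive = TRUE, pass_filter = TRUE)
  k3 <- make_clonotype_keys(ann, "cdr3")
  expect_equal(k3$key, "ARDYW")
  expect_equal(k3$count, 3L)
  k13 <- make_clonotype_keys(ann, "cdr1_cdr3")
  expect_equal(k13$key, "GFTFS|ARDYW")
  kg <- make_clonotype_keys(ann, "cdr3_germline")
  expect_setequal(kg$key, c("IGHV3-23|ARDYW", "IGHV1-69|ARDYW"))
  # identical CDR3 under different germlines stays distinct at any h
  ct <- hierarchical_clonotype(kg, h = 1)
  expect_equal(nrow(ct), 2L)
})

test_that("germline-scheme rescue requires the same V call", {
  keys <- kt(`IGHV3-23|ARDYW` = 4, `IGHV3-23|ARDFW` = 1, `IGHV1-69|ARDYQ` = 1)
  attr(keys, "scheme") <- "cdr3_germline"
  ct <- hierarchical_clonotype(keys, h = 1)
  expect_equal(nrow(ct), 2L)
  expect_equal(ct$count[ct$clonotype == "IGHV3-23|ARDYW"], 5L)
})

test_that("dominance, cumulative rank and overlap match hand computation", {
  t1 <- hierarchical_clonotype(kt(A = 8, B = 2), h = 0)
  expect_equal(clonal_dominance(t1), 0.8)
  expect_equal(clonal_dominance(hierarchical_clonotype(kt(A = 3), h = 0)), 1.0)
  u <- kt(setNames(rep(1, 100), paste0("K", 1:100)))
  expect_equal(clonal_dominance(hierarchical_clonotype(u, h = 0)), 0.01)

  cr <- cumulative_rank(hierarchical_clonotype(kt(A = 5, B = 3, C = 2), h = 0))
  expect_equal(cr$clones_to_half, 1L)
  cr2 <- cumulative_rank(hierarchical_clonotype(
    kt(setNames(rep(1, 10), paste0("K", 1:10))), h = 0))
  expect_equal(cr2$clones_to_half, 5L)
  sp <- cumulative_rank(hierarchical_clonotype(kt(A = 1, B = 1, C = 2), h = 0))
  expect_equal(sp$spectrum$fraction[sp$spectrum$copies == 1], 2 / 3)

  tA <- hierarchical_clonotype(kt(A = 2, B = 2), h = 0)
  tB <- hierarchical_clonotype(kt(B = 2, C = 2), h = 0)
  expect_equal(clonotype_overlap(tA, tA)$jaccard, 1.0)
  expect_equal(clonotype_overlap(tA, tB)$jaccard, 1 / 3)
  tC <- hierarchical_clonotype(kt(D = 2), h = 0)
  expect_equal(clonotype_overlap(tA, tC)$jaccard, 0.0)
})

test_that("clonotype counts are monotone non-increasing in h and conserve reads", {
  set.seed(77)
  for (rep in 1:5) {
    keys <- random_key_table(120)
    ns <- vapply(0:3, function(h)
      nrow(hierarchical_clonotype(keys, h = h)), integer(1))
    expect_true(all(diff(ns) <= 0))
    n_ab <- nrow(hierarchical_clonotype(keys, criterion = "abundance_only"))
    expect_lte(n_ab, min(ns))
    for (h in 0:3) {
      ct <- hierarchical_clonotype(keys, h = h)
      expect_equal(sum(ct$count), sum(keys$count))  # read conservation
    }
  }
})

test_that("implementation agrees with the brute-force all-pairs oracle", {
  set.seed(123)
  for (rep in 1:8) {
    keys <- random_key_table(sample(20:200, 1))
    h <- sample(1:3, 1)
    got <- hierarchical_clonotype(keys, h = h)
    want <- brute_clonotype(keys, h = h)
    expect_equal(got$clonotype, want$key)
    expect_equal(got$count, want$count)
  }
})

test_that("clonotyping result is independent of input order", {
  set.seed(42)
  keys <- random_key_table(80)
  shuffled <- keys[sample.int(nrow(keys)), ]
  a <- hierarchical_clonotype(keys, h = 2)
  b <- hierarchical_clonotype(shuffled, h = 2)
  expect_equal(a$clonotype, b$clonotype)
  expect_equal(a$count, b$count)
})

test_that("on clean well-separated data clonotype count equals true richness", {
  fx <- small_clean_annotations()
  truth_keys <- unique(fx$clones$cdr3_aa[match(fx$reads$clone_id,
                                               fx$clones$clone_id)])
  ct0 <- clonotype_reads(fx$ann, h = 0)
  expect_equal(nrow(ct0), length(truth_keys))
})
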