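test_that("IUPAC Hamming matches on nucleotide-set intersection", {
  expect_equal(iupac_hamming("K", "G"), 0L)   # K = {G,T} contains G
  expect_equal(iupac_hamming("K", "C"), 1L)   # {G,T} and {C} are disjoint
  expect_equal(iupac_hamming("CAGGTK", "CAGGTK"), 0L)
  expect_equal(iupac_hamming("RY", "GA"), 1L) # R~G matches, Y~A does not
  expect_error(iupac_hamming("AC", "ACG"), "equal length")
  expect_error(iupac_hamming("AX", "AC"), "IUPAC")
  # symmetry on the published panel
  m <- iupac_hamming_matrix(read_primer_panel())
  expect_true(isSymmetric(m))
  expect_true(all(diag(m) == 0))
  expect_true(all(m <= 18))
})

test_that("Ward clustering handles degenerate panels deterministically", {
  dup <- c(p1 = "CAGGTG", p2 = "CAGGTG", p3 = "TTTTTT")
  wc <- ward_cluster(dup, k = 2)
  cl <- setNames(wc$clusters$cluster, wc$clusters$primer_id)
  expect_equal(cl[["p1"]], cl[["p2"]])      # identical primers merge at height 0
  expect_equal(min(wc$hclust$height), 0)
  wc_n <- ward_cluster(dup, k = 3)
  expect_equal(length(unique(wc_n$clusters$cluster)), 3L)  # k = n singletons
  expect_error(ward_cluster(c(a = "ACGT")), "at least two")
  expect_error(ward_cluster(c(a = "ACGT", b = "ACG")), "equal length")
})

test_that("primer clustering is invariant to input order", {
  p <- read_primer_panel()
  shuffled <- p[c(7, 2, 11, 4, 1, 12, 3, 9, 5, 10, 6, 8), ]
  a <- cluster_members(ward_cluster(p, k = 3))
  b <- cluster_members(ward_cluster(shuffled, k = 3))
  expect_setequal(unname(vapply(a, paste, "", collapse = ",")),
                  unname(vapply(b, paste, "", collapse = ",")))
})

test_that("on-target rates separate intended from off-target families", {
  fx <- small_clean_annotations()
  primer <- read_primer_panel()[read_primer_panel()$primer_id == "IGHV3a", ]
  # pool built from generator truth: 70% IGHV3 family, 30% other
  ann3 <- fx$ann[fx$ann$v_family == "IGHV3", ]
  annO <- fx$ann[fx$ann$v_family != "IGHV3", ]
  n3 <- 140L
  pool <- dplyr::bind_rows(head(ann3, n3), head(annO, 60L))
  rep <- on_target_rate(pool, primer)
  expect_equal(rep$family_level_fraction, 0.7)
  expect_lte(rep$gene_level_fraction, rep$family_level_fraction)
  expect_equal(sum(rep$off_target[[1]]$fraction), 1)
  # all-intended pool
  rep1 <- on_target_rate(head(ann3, 50), primer)
  expect_equal(rep1$family_level_fraction, 1.0)
  expect_error(on_target_rate(fx$ann[0, ], primer), "no passing reads")
})

test_that("per-primer normalisation equalises pool weights", {
  t1 <- tibble::tibble(key = c("A", "B"), count = c(60, 40))
  t2 <- tibble::tibble(key = c("C", "D"), count = c(540, 360))
  norm <- normalize_by_primer(list(p1 = t1, p2 = t2))
  w <- tapply(norm$weight, norm$pool, sum)
  expect_equal(unname(w[["p1"]]), 0.5)
  expect_equal(unname(w[["p2"]]), 0.5)
  # within-pool proportions preserved
  expect_equal(norm$weight[norm$key == "A"] / norm$weight[norm$key == "B"],
               60 / 40)
  single <- normalize_by_primer(list(only = t1))
  expect_equal(single$weight, c(0.6, 0.4))
  expect_error(normalize_by_primer(list()), "at least one")
})

test_that("match simulation weights abundance times primer similarity", {
  p <- read_primer_panel()
  sim <- primer_match_simulation(heavy, p)
  # a primer realised from one gene's 5' region concentrates on that gene
  expect_equal(unname(which.max(sim$matrix["IGHV2a", ])),
               unname(which(colnames(sim$matrix) == "IGHV2-5")))
  # closed form: equal distance (both 0 via the degenerate R), 9:1 abundance
  # -> 0.9/0.1 split
  p5 <- p[p$primer_id == "IGHV5a", ]  # GARGTGCAGCTGGTGCAG
  tiny <- tibble::tibble(
    name = c("gA", "gG"), segment = "V",
    nt_sequence = paste0(c("GAAGTGCAGCTGGTGCAG", "GAGGTGCAGCTGGTGCAG"),
                         strrep("ACG", 20)))
  sim2 <- primer_match_simulation(tiny, p5, abundance = c(gA = 0.9, gG = 0.1))
  expect_equal(unname(sim2$matrix[1, "gA"]), 0.9, tolerance = 1e-6)
  expect_equal(unname(sim2$matrix[1, "gG"]), 0.1, tolerance = 1e-6)
  # a 3'-terminal mismatch to every gene collapses total capture
  bad <- p5
  bad$sequence <- paste0(substr(bad$sequence, 1, 15), "TTT")
  sim3 <- primer_match_simulation(heavy, bad)
  expect_lt(sim3$total_capture[1], 0.01 * max(sim$total_capture))
})

test_that("family-level on-target fraction dominates gene-level fraction", {
  fx <- small_clean_annotations()
  p <- read_primer_panel()
  for (pid in c("IGHV1a", "IGHV3c", "IGHV6a")) {
    primer <- p[p$primer_id == pid, ]
    rep <- on_target_rate(fx$ann, primer)
    expect_gte(rep$family_level_fraction, rep$gene_level_fraction)
  }
})
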