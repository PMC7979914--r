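test_that("net charge follows Henderson-Hasselbalch on the packaged pK scale", {
  expect_equal(net_charge("GGGG"), 0.0)
  expect_equal(round(net_charge("K"), 2), 1.00)   # Lys pK 10.53 at pH 7
  expect_equal(round(net_charge("D"), 2), -1.00)  # Asp pK 3.65 at pH 7
  # His is ionizable: small positive contribution at pH 7 (pK 6.0)
  expect_equal(net_charge("H"), 1 / (1 + 10^(7 - 6)), tolerance = 1e-12)
  expect_error(net_charge("AXZ"), "non-standard")
})

test_that("charge is additive, order-independent, and pH-dependent", {
  set.seed(21)
  for (rep in 1:5) {
    a <- paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P",
                        "Q","R","S","T","V","W","Y"), 12, replace = TRUE),
               collapse = "")
    b <- paste(sample(c("K","R","D","E","G","S"), 8, replace = TRUE),
               collapse = "")
    expect_equal(net_charge(paste0(a, b)), net_charge(a) + net_charge(b))
    rev_a <- paste(rev(strsplit(a, "")[[1]]), collapse = "")
    expect_equal(net_charge(rev_a), net_charge(a))
  }
  # acidic residues are more negative at higher pH
  expect_lt(net_charge("DE", pH = 10), net_charge("DE", pH = 3))
  # termini add the two Henderson-Hasselbalch terminal-group terms
  expect_equal(net_charge("G", include_termini = TRUE),
               1 / (1 + 10^(7 - 9.69)) - 1 / (1 + 10^(2.34 - 7)))
})

test_that("GRAVY is the mean Kyte-Doolittle hydropathy", {
  expect_equal(gravy("V"), 4.2)
  expect_equal(gravy("VR"), -0.15)  # mean of 4.2 and -4.5
  expect_error(gravy(""), "empty")
  # mean invariance under duplication
  set.seed(22)
  s <- paste(sample(names(kyte_doolittle()), 9, replace = TRUE), collapse = "")
  expect_equal(gravy(paste0(s, s)), gravy(s))
  kd <- kyte_doolittle()
  expect_true(all(gravy(c("IVLF", "DENQ", s)) >= min(kd)))
  expect_true(all(gravy(c("IVLF", "DENQ", s)) <= max(kd)))
})

test_that("length summaries are deterministic and range-checked", {
  prof <- tibble::tibble(length = c(10L, 14L, 20L))
  s <- length_distribution(prof)
  expect_equal(s$median, 14)
  s2 <- length_distribution(tibble::tibble(length = rep(12L, 6)))
  expect_equal(s2$sigma, 0)
  expect_error(length_distribution(tibble::tibble(length = c(2L, 14L))))
})

test_that("synthetic heavy repertoires recover the configured CDR3 length law", {
  spec <- repertoire_spec(n_clones = 4000, chain = "heavy", seed = 71,
                          cdr3_len_median = 14, cdr3_len_sigma = 3.73,
                          nonproductive_fraction = 0)
  cl <- generate_repertoire(spec, heavy)
  lens <- nchar(cl$cdr3_aa)
  expect_lte(abs(median(lens) - 14), 1)
  expect_lt(abs(sd(lens) - 3.73), 0.5)
  expect_true(all(lens >= 3 & lens <= 42))
})

test_that("V/J pairing matrix normalises and recovers configured J usage", {
  single <- tibble::tibble(v_family = "IGHV3", j_gene = "IGHJ4")
  m1 <- vj_pairing_matrix(single)
  expect_equal(as.numeric(m1), 1.0)

  spec <- repertoire_spec(n_clones = 6000, chain = "heavy", seed = 72,
                          nonproductive_fraction = 0)
  cl <- generate_repertoire(spec, heavy)
  prof <- tibble::tibble(v_family = gene_family(cl$v_gene), j_gene = cl$j_gene)
  m <- vj_pairing_matrix(prof)
  expect_equal(sum(m), 1.0)
  jw <- default_j_weights("heavy")
  jm <- attr(m, "j_marginal")
  for (j in names(jw)) {
    se <- sqrt(jw[[j]] * (1 - jw[[j]]) / nrow(cl))
    expect_lt(abs(jm[[j]] - jw[[j]]), 4 * se)
  }
  # independence of V and J draws: pairing ~ outer product of marginals
  chi <- suppressWarnings(stats::chisq.test(table(prof$v_family, prof$j_gene)))
  expect_gt(chi$p.value, 1e-4)
})

test_that("developability summary reflects the generating scaffold mix", {
  fx <- small_clean_annotations()
  prof <- biophys_profile(fx$ann)
  expect_true(all(prof$length == nchar(prof$cdr3_aa)))
  s <- developability_summary(prof)
  expect_equal(sum(s$fraction), 1.0)
  # pure IGHV3-23 input is entirely 'desirable'
  p23 <- prof[prof$v_gene == "IGHV3-23", ]
  s23 <- developability_summary(p23)
  expect_equal(s23$fraction[s23$developability == "desirable"], 1.0)
  expect_error(developability_summary(prof[0, ]), "empty")
  # a constructed 44% desirable mix is recovered exactly
  mix <- tibble::tibble(developability = c(rep("desirable", 44),
                                           rep("neutral", 56)))
  sm <- developability_summary(mix)
  expect_equal(sm$fraction[sm$developability == "desirable"], 0.44)
})
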