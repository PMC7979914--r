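# Build a read from germline parts with a known junction.
build_read <- function(v, j, junction_nt, id = "r1") {
  vres <- heavy[heavy$name == v, ]
  jres <- heavy[heavy$name == j, ]
  seq <- paste0(substr(vres$nt_sequence, 1, vres$anchor + 3), junction_nt,
                substr(jres$nt_sequence, jres$anchor + 1,
                       nchar(jres$nt_sequence)))
  tibble::tibble(read_id = id, nt_sequence = seq,
                 quality = strrep("I", nchar(seq)))
}

mutate_positions <- function(seq, pos) {
  ch <- strsplit(seq, "")[[1]]
  ch[pos] <- vapply(ch[pos], function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], "")
  paste(ch, collapse = "")
}

test_that("an exact germline read is called with identity 1 and passes", {
  rd <- build_read("IGHV3-23", "IGHJ4", "GCTAGGGATGGTTACTGG")  # ARDGYW
  ann <- annotate_reads(rd, heavy)
  expect_equal(ann$v_call, "IGHV3-23")
  expect_equal(ann$v_family, "IGHV3")
  expect_equal(ann$j_call, "IGHJ4")
  expect_equal(ann$v_identity, 1.0)
  expect_equal(ann$cdr3_aa, "ARDGYW")
  expect_true(ann$pass_filter)
  expect_true(ann$productive)
})

test_that("15% substitutions across the V body push identity below 0.90", {
  rd <- build_read("IGHV3-23", "IGHJ4", "GCTAGGGATGGTTACTGG")
  v <- heavy[heavy$name == "IGHV3-23", ]
  set.seed(1)
  pos <- sample(seq_len(v$anchor), round(0.15 * v$anchor))
  rd$nt_sequence <- mutate_positions(rd$nt_sequence, pos)
  ann <- annotate_reads(rd, heavy)
  expect_lt(ann$v_identity, 0.90)
  expect_false(ann$pass_filter)
  expect_equal(ann$reason, "identity")
})

test_that("unrelated random sequence is reported unalignable", {
  set.seed(2)
  rd <- tibble::tibble(read_id = "junk",
                       nt_sequence = paste(sample(c("A", "C", "G", "T"), 350,
                                                  replace = TRUE), collapse = ""),
                       quality = strrep("I", 350))
  ann <- annotate_reads(rd, heavy)
  expect_false(ann$pass_filter)
  expect_equal(ann$reason, "unalignable")
})

test_that("CDRs are read off the V alignment at the reference bounds", {
  v <- heavy[heavy$name == "IGHV1-46", ]
  rd <- build_read("IGHV1-46", "IGHJ6", "GCAAGAGATTGG")
  ann <- annotate_reads(rd, heavy)
  b <- v$cdr_bounds[[1]]
  cdr1_manual <- translate_nt(substr(v$nt_sequence, b["CDR1", "start"] + 1,
                                     b["CDR1", "end"]))
  cdr2_manual <- translate_nt(substr(v$nt_sequence, b["CDR2", "start"] + 1,
                                     b["CDR2", "end"]))
  expect_equal(ann$cdr1_aa, cdr1_manual)
  expect_equal(ann$cdr2_aa, cdr2_manual)
  expect_equal(ann$cdr3_aa, "ARDW")
  # short-read mode drops CDR2
  ann_sr <- annotate_reads(rd, heavy, annotate_config(short_read = TRUE))
  expect_true(is.na(ann_sr$cdr2_aa))
  expect_equal(ann_sr$cdr1_aa, cdr1_manual)
})

test_that("productivity requires an in-frame, stop-free junction", {
  out_of_frame <- build_read("IGHV3-23", "IGHJ4", "GCTAGGGATGGTTACTG")  # 17 nt
  ann <- annotate_reads(out_of_frame, heavy)
  expect_false(ann$junction_in_frame)
  expect_false(ann$productive)
  expect_true(is.na(ann$cdr3_aa))
  with_stop <- build_read("IGHV3-23", "IGHJ4", "GCTAGGTAAGGTTACTGG")
  ann2 <- annotate_reads(with_stop, heavy)
  expect_true(ann2$junction_in_frame)
  expect_false(ann2$productive)
})

test_that("assignment is perfect on error-free synthetic reads", {
  fx <- small_clean_annotations()
  truth <- fx$clones[match(fx$reads$clone_id, fx$clones$clone_id), ]
  expect_true(all(fx$ann$v_call == truth$v_gene))
  expect_true(all(fx$ann$j_call == truth$j_gene))
  expect_true(all(fx$ann$v_identity == 1))
  expect_identical(fx$ann$cdr3_aa, truth$cdr3_aa)
})

test_that("simulated non-productive fraction is recovered at clone level", {
  spec <- repertoire_spec(n_clones = 2000, chain = "heavy", seed = 31,
                          nonproductive_fraction = 0.11)
  cl <- generate_repertoire(spec, heavy)
  rd <- simulate_reads(cl, 3000, sub_rate = 0, weighting = "uniform", seed = 31)
  ann <- annotate_reads(rd, heavy)
  p <- productivity_rate(ann)
  se <- sqrt(0.89 * 0.11 / nrow(ann))
  expect_lt(abs(p - 0.89), 4 * se + 0.01)
})

test_that("tightening the e-value threshold never admits more reads", {
  spec <- repertoire_spec(n_clones = 150, chain = "heavy", seed = 13)
  rd <- simulate_reads(generate_repertoire(spec, heavy), 300,
                       sub_rate = 0.02, seed = 13)
  n_pass <- vapply(c(1e-2, 1e-12, 1e-14, 1e-200), function(thr)
    sum(annotate_reads(rd, heavy,
                       annotate_config(evalue_threshold = thr))$pass_filter),
    integer(1))
  expect_true(all(diff(n_pass) <= 0))
})

test_that("rearrangement TSV round-trips annotations", {
  fx <- small_clean_annotations()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_rearrangements(head(fx$ann, 50), f)
  back <- read_rearrangements(f)
  expect_equal(back$v_call, head(fx$ann$v_call, 50))
  expect_equal(back$junction_aa, head(fx$ann$cdr3_aa, 50))
  expect_equal(back$v_identity, head(fx$ann$v_identity, 50))
})
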