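# Germline V/J assignment: a deliberately simple ungapped aligner standing in
# for IgBLAST, around the published acceptance thresholds (e-value and >=90%
# framework/CDR1-2 identity), plus CDR extraction and productivity calling.

#' Configure germline annotation
#'
#' @param evalue_threshold maximum e-value-like score for acceptance. The
#'   published pipeline used 1e-12 (NovaSeq analysis) with 1e-14 quoted for
#'   the MiSeq runs; default 1e-12.
#' @param identity_threshold minimum nucleotide identity over the germline
#'   framework + CDR1/2 region (CDR3 excluded); default 0.90.
#' @param max_shift maximum V start offset scanned within the read.
#' @param j_max_shift maximum end-trim scanned when anchoring J at the 3' end.
#' @param min_overlap minimum V overlap for an alignment to be considered.
#' @param min_score minimum ungapped score (+1 match / -1 mismatch) below
#'   which a read is reported unalignable.
#' @param lambda,K Karlin-Altschul-style constants of the e-value transform
#'   `E = K * m * n * exp(-lambda * S)`.
#' @param short_read short-read mode: CDR2 is not reported (150 bp reads do
#'   not cover it).
#' @return an `annotate_config` list.
#' @export
annotate_config <- function(evalue_threshold = 1e-12, identity_threshold = 0.90,
                            max_shift = 24L, j_max_shift = 6L,
                            min_overlap = 30L, min_score = 0L,
                            lambda = 1.33, K = 0.621, short_read = FALSE) {
  structure(list(evalue_threshold = evalue_threshold,
                 identity_threshold = identity_threshold,
                 max_shift = as.integer(max_shift),
                 j_max_shift = as.integer(j_max_shift),
                 min_overlap = as.integer(min_overlap),
                 min_score = as.integer(min_score),
                 lambda = lambda, K = K, short_read = short_read),
            class = "annotate_config")
}

#' Assign germline V/J genes and extract CDRs
#'
#' For each read, every reference V gene is aligned without gaps over
#' candidate start offsets (`0..max_shift`) and the best-scoring gene is
#' called (+1 match / -1 mismatch; ties broken by higher identity, then
#' lexicographic gene name). Identity is computed over the framework and
#' CDR1/2 germline region only (the CDR3 is excluded), an e-value-like
#' statistic is derived from the score, and the published acceptance
#' thresholds set `pass_filter`. J genes are called by end-anchored alignment
#' of the region from the J anchor codon onward. CDR1/2 are read off the V
#' alignment via the reference CDR bounds; CDR3 is the translation of the
#' read strictly between the V 2nd-Cys codon and the J Trp/Phe codon.
#' A read is productive when its junction is in frame and the aligned ORF
#' carries no stop codon.
#'
#' @param reads read tibble (`read_id`, `nt_sequence`; `quality` ignored).
#' @param germline germline reference from [read_germline_reference()]
#'   (V and J genes of one chain, or several chains at once).
#' @param cfg an [annotate_config()].
#' @return annotation tibble: `sequence_id`, `v_call`, `v_family`, `j_call`,
#'   `v_identity`, `score`, `evalue_like`, `cdr1_aa`, `cdr2_aa`, `cdr3_aa`,
#'   `junction_in_frame`, `productive`, `pass_filter`, `reason`.
#' @export
annotate_reads <- function(reads, germline = read_germline_reference(),
                           cfg = annotate_config()) {
  vref <- germline[germline$segment == "V", ]
  jref <- germline[germline$segment == "J", ]
  stopifnot(nrow(vref) > 0, nrow(jref) > 0, nrow(reads) > 0)

  # V: align the germline region up to (excluding) the anchor codon, so the
  # identity denominator is exactly FR1-FR3 + CDR1/2.
  v_body <- substr(vref$nt_sequence, 1L, vref$anchor)
  al <- best_ungapped_cpp(reads$nt_sequence, v_body,
                          cfg$max_shift, cfg$min_overlap)
  identity <- 1 - al$mismatch / al$overlap
  # best V per read: score, then identity, then gene name
  name_rank <- rank(vref$name)
  pick <- function(i) {
    s <- al$score[i, ]
    if (all(is.na(s))) return(NA_integer_)
    cand <- which(s == max(s, na.rm = TRUE))
    if (length(cand) > 1) {
      cand <- cand[identity[i, cand] == max(identity[i, cand])]
      cand <- cand[which.min(name_rank[cand])]
    }
    cand[1]
  }
  vi <- vapply(seq_len(nrow(reads)), pick, integer(1))

  # J: end-anchored alignment of the suffix from the anchor codon onward.
  j_suffix <- substr(jref$nt_sequence, jref$anchor + 1L, nchar(jref$nt_sequence))
  jl <- align_tail_cpp(reads$nt_sequence, j_suffix, cfg$j_max_shift)
  j_rank <- rank(jref$name)
  jpick <- vapply(seq_len(nrow(reads)), function(i) {
    m <- jl$mismatch[i, ]
    if (all(is.na(m))) return(NA_integer_)
    cand <- which(m == min(m, na.rm = TRUE))
    if (length(cand) > 1) cand <- cand[which.min(j_rank[cand])]
    cand[1]
  }, integer(1))

  n <- nrow(reads)
  idx <- cbind(seq_len(n), vi)
  v_off <- al$offset[idx]          # 0-based V start within read
  v_score <- al$score[idx]
  v_ident <- identity[idx]
  anchor <- vref$anchor[vi]
  jdx <- cbind(seq_len(n), jpick)
  j_start <- jl$start[jdx]         # 1-based start of J anchor codon in read

  unalignable <- is.na(vi) | is.na(jpick) | v_score < cfg$min_score
  m_len <- nchar(reads$nt_sequence)
  evalue <- cfg$K * m_len * sum(nchar(v_body)) * exp(-cfg$lambda * v_score)

  # CDR extraction off the V alignment
  cdr_aa <- function(region) {
    out <- rep(NA_character_, n)
    ok <- which(!unalignable)
    if (!length(ok)) return(out)
    b <- t(vapply(vi[ok], function(g) vref$cdr_bounds[[g]][region, ], c(start = 0, end = 0)))
    nt <- substr(reads$nt_sequence[ok], v_off[ok] + b[, 1] + 1L, v_off[ok] + b[, 2])
    out[ok] <- translate_nt(nt)
    out
  }
  cdr1 <- cdr_aa("CDR1")
  cdr2 <- if (cfg$short_read) rep(NA_character_, n) else cdr_aa("CDR2")

  cdr3_start <- v_off + anchor + 3L + 1L  # 1-based, after the Cys codon
  cdr3_end <- j_start - 1L                # before the J anchor codon
  junction_len <- cdr3_end - cdr3_start + 1L
  in_frame <- !unalignable & !is.na(junction_len) & junction_len >= 3L &
    junction_len %% 3L == 0L
  cdr3 <- rep(NA_character_, n)
  ok3 <- which(in_frame)
  if (length(ok3)) {
    cdr3[ok3] <- translate_nt(substr(reads$nt_sequence[ok3],
                                     cdr3_start[ok3], cdr3_end[ok3]))
  }
  # productivity: in-frame junction, no stop across the aligned ORF
  productive <- in_frame
  if (length(ok3)) {
    orf <- translate_nt(substr(reads$nt_sequence[ok3], v_off[ok3] + 1L,
                               m_len[ok3]), truncate = TRUE)
    productive[ok3] <- !grepl("*", orf, fixed = TRUE)
  }

  pass <- !unalignable & evalue <= cfg$evalue_threshold &
    v_ident >= cfg$identity_threshold
  reason <- dplyr::case_when(
    unalignable ~ "unalignable",
    evalue > cfg$evalue_threshold ~ "evalue",
    v_ident < cfg$identity_threshold ~ "identity",
    TRUE ~ "pass")

  tibble::tibble(
    sequence_id = reads$read_id,
    v_call = ifelse(unalignable, NA_character_, vref$name[vi]),
    v_family = ifelse(unalignable, NA_character_, vref$family[vi]),
    j_call = ifelse(unalignable, NA_character_, jref$name[jpick]),
    v_identity = ifelse(unalignable, NA_real_, v_ident),
    score = v_score, evalue_like = evalue,
    cdr1_aa = cdr1, cdr2_aa = cdr2, cdr3_aa = cdr3,
    junction_in_frame = in_frame, productive = productive,
    pass_filter = pass, reason = reason)
}

#' Fraction of productive rearrangements
#'
#' @param annotations annotation tibble from [annotate_reads()].
#' @param passing_only restrict to reads passing the alignment filters.
#' @return fraction of reads whose ORF is in frame and stop-free.
#' @export
productivity_rate <- function(annotations, passing_only = TRUE) {
  a <- if (passing_only) annotations[annotations$pass_filter, ] else annotations
  if (!nrow(a)) stop("no annotations to summarise")
  mean(a$productive)
}

#' Write annotations as an AIRR-style rearrangement TSV
#'
#' Columns follow AIRR Rearrangement naming where they apply
#' (`sequence_id`, `v_call`, `j_call`, `junction_aa` carrying the CDR3,
#' `cdr1_aa`, `cdr2_aa`, `productive`, `v_identity`); `pass_filter` and
#' `reason` record the acceptance thresholds.
#'
#' @param annotations annotation tibble.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_rearrangements <- function(annotations, path) {
  out <- dplyr::transmute(annotations,
    sequence_id = .data$sequence_id, v_call = .data$v_call,
    j_call = .data$j_call, junction_aa = .data$cdr3_aa,
    cdr1_aa = .data$cdr1_aa, cdr2_aa = .data$cdr2_aa,
    productive = .data$productive, v_identity = .data$v_identity,
    pass_filter = .data$pass_filter, reason = .data$reason)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_rearrangements
#' @export
read_rearrangements <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sequence_id = "c", v_call = "c", j_call = "c", junction_aa = "c",
    cdr1_aa = "c", cdr2_aa = "c", productive = "l", v_identity = "d",
    pass_filter = "l", reason = "c"))
}
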