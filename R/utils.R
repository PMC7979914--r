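# Shared low-level helpers: IUPAC sets, codon translation, Phred codecs,
# seeded evaluation.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

is_iupac <- function(x) {
  !grepl(paste0("[^", paste(names(IUPAC_SETS), collapse = ""), "]"), x)
}

#' Translate nucleotide sequences to amino acids
#'
#' Translates in frame 0 using the standard genetic code; stop codons are
#' rendered as `*`. Sequences whose length is not a multiple of 3 are an
#' error unless `truncate = TRUE`, in which case trailing bases are dropped.
#'
#' @param nt character vector of nucleotide sequences (A/C/G/T).
#' @param truncate drop trailing bases that do not complete a codon?
#' @return character vector of amino-acid sequences.
#' @export
translate_nt <- function(nt, truncate = FALSE) {
  n <- nchar(nt)
  if (!truncate && any(n %% 3L != 0L)) {
    stop("sequence length not a multiple of 3; use truncate = TRUE to trim")
  }
  nt <- substr(nt, 1L, n - n %% 3L)
  out <- character(length(nt))
  nz <- nchar(nt) > 0L
  if (any(nz)) {
    out[nz] <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(nt[nz]),
      if.fuzzy.codon = "error", no.init.codon = TRUE
    ))
  }
  out
}

# Phred+33 codecs; qualities as integer vectors 0..93.
phred_to_int <- function(qual) lapply(qual, function(q) utf8ToInt(q) - 33L)
int_to_phred <- function(q) vapply(q, function(v) intToUtf8(v + 33L), "")

# Evaluate `expr` under a fixed RNG stream without disturbing the caller's
# RNG state. All package randomness flows through this helper.
with_rng <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr,
                   .rng_kind = "Mersenne-Twister",
                   .rng_sample_kind = "Rejection")
}

# Derive a distinct 31-bit sub-seed from a master seed and a stream label.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) *
             131^(seq_len(nchar(as.character(stream))) %% 7))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

random_dna <- function(n_bases) {
  paste(sample(c("A", "C", "G", "T"), n_bases, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
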