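# Synthetic single-donor repertoire generator: ground-truth clones with
# power-law abundance and configurable V/J usage, plus an error-bearing FASTQ
# read simulator. Everything downstream of sequencing is testable against the
# generator's truth tables.

#' Default J-segment usage weights
#'
#' The mixing proportions used when pooling J-segment amplicons, as stated for
#' the library construction: heavy IGHJ1/2 5%, IGHJ3 10%, IGHJ4/5 60%, IGHJ6
#' 25%; kappa IGKJ1-5 29/26/10/26/9%; lambda IGLJ1 21%, IGLJ2+3 77%, IGLJ7 2%
#' (split evenly between J2 and J3).
#'
#' @param chain `"heavy"`, `"kappa"` or `"lambda"`.
#' @return named numeric vector of gene weights summing to 1.
#' @export
default_j_weights <- function(chain = c("heavy", "kappa", "lambda")) {
  switch(match.arg(chain),
    heavy  = c(IGHJ1 = 0.025, IGHJ2 = 0.025, IGHJ3 = 0.10,
               IGHJ4 = 0.30,  IGHJ5 = 0.30,  IGHJ6 = 0.25),
    kappa  = c(IGKJ1 = 0.29, IGKJ2 = 0.26, IGKJ3 = 0.10,
               IGKJ4 = 0.26, IGKJ5 = 0.09),
    lambda = c(IGLJ1 = 0.21, IGLJ2 = 0.385, IGLJ3 = 0.385, IGLJ7 = 0.02))
}

#' Specify a synthetic repertoire
#'
#' Bundles and validates the generative parameters of a synthetic library:
#' clone count, V-gene and J-gene usage weights, the power-law exponent of the
#' clone copy-number distribution, the CDR3 length distribution (discretised
#' normal, median 14 aa, sigma 3.73 aa, truncated to 3-42 aa for the heavy
#' chain), and the non-productive fraction.
#'
#' @param n_clones number of ground-truth clones (>= 1).
#' @param chain `"heavy"`, `"kappa"` or `"lambda"`.
#' @param v_weights named weights over V genes; `NULL` = uniform over the
#'   reference genes of the chain.
#' @param j_weights named weights over J genes; `NULL` = [default_j_weights()].
#' @param abundance_alpha power-law exponent (> 1) of the copy-number law.
#' @param cdr3_len_median,cdr3_len_sigma CDR3 amino-acid length location and
#'   spread.
#' @param nonproductive_fraction fraction of clones carrying a stop codon or
#'   out-of-frame junction.
#' @param seed integer seed; all generator randomness derives from it.
#' @return a `repertoire_spec` list.
#' @export
repertoire_spec <- function(n_clones = 5000, chain = c("heavy", "kappa", "lambda"),
                            v_weights = NULL, j_weights = NULL,
                            abundance_alpha = 2, cdr3_len_median = 14,
                            cdr3_len_sigma = 3.73,
                            nonproductive_fraction = 0.11, seed = 1L) {
  chain <- match.arg(chain)
  stopifnot(n_clones >= 1, abundance_alpha > 1, cdr3_len_sigma > 0,
            cdr3_len_median >= 3,
            nonproductive_fraction >= 0, nonproductive_fraction < 1)
  j_weights <- j_weights %||% default_j_weights(chain)
  for (w in list(v_weights, j_weights)) {
    if (!is.null(w) && abs(sum(w) - 1) > 1e-9) {
      stop("usage weights must sum to 1")
    }
  }
  structure(list(n_clones = as.integer(n_clones), chain = chain,
                 v_weights = v_weights, j_weights = j_weights,
                 abundance_alpha = abundance_alpha,
                 cdr3_len_median = cdr3_len_median,
                 cdr3_len_sigma = cdr3_len_sigma,
                 nonproductive_fraction = nonproductive_fraction,
                 seed = as.integer(seed)),
            class = "repertoire_spec")
}

# Discrete power law on 1..kmax: P(k) proportional to k^-alpha.
rzipf <- function(n, alpha, kmax = 10000L) {
  p <- (1:kmax)^(-alpha)
  sample.int(kmax, n, replace = TRUE, prob = p)
}

# CDR3 aa lengths: rounded normal, truncated to [3, 42].
rcdr3_len <- function(n, med, sigma) {
  len <- round(stats::rnorm(n, mean = med, sd = sigma))
  while (any(bad <- len < 3 | len > 42)) {
    len[bad] <- round(stats::rnorm(sum(bad), mean = med, sd = sigma))
  }
  as.integer(len)
}

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

# Reverse-translate an aa string picking uniform synonymous codons.
codon_choices <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})
reverse_translate <- function(aa) {
  ch <- strsplit(aa, "")[[1]]
  paste(vapply(ch, function(a) sample(codon_choices[[a]], 1L), ""), collapse = "")
}

#' Generate a ground-truth synthetic repertoire
#'
#' Draws clones from a [repertoire_spec()]: V and J genes by the configured
#' weights, copy numbers from a discrete power law (so that most clones are
#' singletons), CDR3 junctions as random in-frame amino-acid sequences between
#' the V 2nd-Cys anchor and the J Trp/Phe anchor, and a configurable
#' non-productive fraction (in-junction stop codon or frameshift). The full
#' nucleotide sequence is the V gene up to and including its anchor codon,
#' the junction, and the J gene from its anchor codon onward.
#'
#' @param spec a [repertoire_spec()].
#' @param germline germline reference tibble from [read_germline_reference()];
#'   filtered to `spec$chain`.
#' @return tibble of clones: `clone_id`, `v_gene`, `j_gene`, `cdr3_aa`,
#'   `cdr3_nt`, `full_nt`, `true_count`, `productive`.
#' @export
generate_repertoire <- function(spec, germline = read_germline_reference()) {
  stopifnot(inherits(spec, "repertoire_spec"))
  ref <- germline[germline$chain == spec$chain, ]
  vref <- ref[ref$segment == "V", ]
  jref <- ref[ref$segment == "J", ]
  vw <- spec$v_weights %||% setNames(rep(1 / nrow(vref), nrow(vref)), vref$name)
  jw <- spec$j_weights
  unknown <- setdiff(c(names(vw), names(jw)), ref$name)
  if (length(unknown)) {
    stop("usage weight references unknown gene(s): ",
         paste(unknown, collapse = ", "))
  }
  v_prefix <- setNames(substr(vref$nt_sequence, 1L, vref$anchor + 3L), vref$name)
  j_suffix <- setNames(substr(jref$nt_sequence, jref$anchor + 1L,
                              nchar(jref$nt_sequence)), jref$name)
  with_rng(derive_seed(spec$seed, "clones"), {
    n <- spec$n_clones
    v <- sample(names(vw), n, replace = TRUE, prob = vw)
    j <- sample(names(jw), n, replace = TRUE, prob = jw)
    len <- rcdr3_len(n, spec$cdr3_len_median, spec$cdr3_len_sigma)
    cdr3_aa <- vapply(len, function(L)
      paste(sample(AA20, L, replace = TRUE), collapse = ""), "")
    cdr3_nt <- vapply(cdr3_aa, reverse_translate, "", USE.NAMES = FALSE)
    productive <- stats::runif(n) >= spec$nonproductive_fraction
    for (i in which(!productive)) {
      if (stats::runif(1) < 0.5) {   # internal stop codon
        pos <- sample.int(len[i], 1L)
        substr(cdr3_nt[i], 3L * pos - 2L, 3L * pos) <- "TAA"
        cdr3_aa[i] <- translate_nt(cdr3_nt[i])
      } else {                       # frameshift: clip 1-2 junction bases
        cdr3_nt[i] <- substr(cdr3_nt[i], 1L,
                             nchar(cdr3_nt[i]) - sample(1:2, 1L))
        cdr3_aa[i] <- NA_character_
      }
    }
    tibble::tibble(
      clone_id = sprintf("clone%06d", seq_len(n)),
      v_gene = v, j_gene = j,
      cdr3_aa = cdr3_aa, cdr3_nt = cdr3_nt,
      full_nt = paste0(v_prefix[v], cdr3_nt, j_suffix[j]),
      true_count = rzipf(n, spec$abundance_alpha),
      productive = productive)
  })
}

#' Two-regime Phred quality model
#'
#' A mixture of good reads (bases Q40/Q37) and bad reads (a fraction of bases
#' dropped to a low quality), so that both the 90%-of-bases Q>=25 filter and
#' the lower-quartile Q>=37 filter discriminate.
#'
#' @param p_bad fraction of reads drawn from the low-quality regime.
#' @param q_high,q_mid,q_low quality values of the regimes.
#' @param bad_frac fraction of low-quality bases within a bad read.
#' @return a `phred_model` list.
#' @export
phred_model <- function(p_bad = 0.08, q_high = 40L, q_mid = 37L, q_low = 12L,
                        bad_frac = 0.4) {
  stopifnot(p_bad >= 0, p_bad <= 1, bad_frac > 0, bad_frac <= 1)
  structure(list(p_bad = p_bad, q_high = q_high, q_mid = q_mid,
                 q_low = q_low, bad_frac = bad_frac), class = "phred_model")
}

#' Simulate sequencing reads from a clone table
#'
#' Samples reads from clones proportionally to `true_count`, introduces
#' substitution-only errors at a per-base rate, and assigns per-base Phred
#' scores from a two-regime quality model. The true source clone of every
#' read is retained.
#'
#' @param clones tibble from [generate_repertoire()].
#' @param n_reads number of reads to emit (> 0).
#' @param sub_rate per-base substitution probability.
#' @param model a [phred_model()].
#' @param weighting `"true_count"` samples reads proportionally to clone
#'   copy number (sequencing a pooled library); `"uniform"` draws each read
#'   from a uniformly chosen clone, which measures per-molecule usage
#'   without the very heavy-tailed copy-number noise.
#' @param seed integer seed.
#' @return tibble of reads: `read_id`, `nt_sequence`, `quality` (Phred+33
#'   string), `clone_id`.
#' @export
simulate_reads <- function(clones, n_reads, sub_rate = 0.002,
                           model = phred_model(),
                           weighting = c("true_count", "uniform"), seed = 1L) {
  weighting <- match.arg(weighting)
  if (n_reads <= 0) stop("n_reads must be positive")
  stopifnot(sum(clones$true_count) > 0)
  with_rng(derive_seed(seed, "reads"), {
    idx <- sample.int(nrow(clones), n_reads, replace = TRUE,
                      prob = switch(weighting, true_count = clones$true_count,
                                    uniform = NULL))
    seqs <- clones$full_nt[idx]
    if (sub_rate > 0) {
      seqs <- vapply(seqs, function(s) {
        n <- nchar(s)
        k <- rbinom(1L, n, sub_rate)
        if (k == 0L) return(s)
        pos <- sample.int(n, k)
        ch <- strsplit(s, "")[[1]]
        ch[pos] <- vapply(ch[pos], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
        paste(ch, collapse = "")
      }, "", USE.NAMES = FALSE)
    }
    lens <- nchar(seqs)
    bad <- stats::runif(n_reads) < model$p_bad
    quality <- vapply(seq_len(n_reads), function(i) {
      L <- lens[i]
      q <- sample(c(model$q_high, model$q_mid), L, replace = TRUE,
                  prob = c(0.7, 0.3))
      if (bad[i]) {
        drop <- stats::runif(L) < model$bad_frac
        q[drop] <- model$q_low
      }
      intToUtf8(q + 33L)
    }, "")
    tibble::tibble(read_id = sprintf("read%07d", seq_len(n_reads)),
                   nt_sequence = seqs, quality = quality,
                   clone_id = clones$clone_id[idx])
  })
}

#' Read and write FASTQ as read tibbles
#'
#' Standard 4-line FASTQ; qualities are Phred+33 strings. The ground-truth
#' clone of simulated reads travels separately (see `truth` column handling
#' in [simulate_reads()]).
#'
#' @param reads tibble with `read_id`, `nt_sequence`, `quality`.
#' @param path file path.
#' @return `read_fastq()`: a read tibble; `write_fastq()`: `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$read_id, "\n", reads$nt_sequence, "\n+\n",
                    reads$quality), con)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  # Biostrings warns that FASTQ metadata columns are dropped; nothing is lost
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  tibble::tibble(read_id = sub("\\s.*$", "", names(x)),
                 nt_sequence = unname(as.character(x)),
                 quality = unname(as.character(Biostrings::quality(x))))
}
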