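# Degenerate-primer specificity: IUPAC-aware Hamming distances, Ward
# minimum-variance clustering of primer 5' regions, on-/off-target
# amplification rates, per-primer normalisation, and a qualitative
# abundance x similarity amplification model.

#' IUPAC-aware Hamming distance
#'
#' Positions match when the nucleotide sets encoded by the two IUPAC
#' characters intersect (a degenerate primer base anneals to any member of
#' its set, so e.g. K matches G); the distance is the count of non-matching
#' positions. Symmetric with zero diagonal, but not a metric: set
#' intersection breaks the triangle inequality.
#'
#' @param a,b equal-length IUPAC strings (vectors recycled).
#' @return integer vector of distances.
#' @export
#' @examples
#' iupac_hamming("CAGGTK", "CAGGTG")  # 0
iupac_hamming <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  if (any(nchar(a) != nchar(b))) stop("sequences must have equal length")
  if (any(!is_iupac(c(a, b)))) stop("non-IUPAC character in input")
  vapply(seq_len(n), function(i) {
    x <- strsplit(a[i], "")[[1]]; y <- strsplit(b[i], "")[[1]]
    sum(!mapply(function(p, q)
      length(intersect(IUPAC_SETS[[p]], IUPAC_SETS[[q]])) > 0, x, y))
  }, integer(1))
}

#' @rdname iupac_hamming
#' @param seqs named character vector or a primer panel tibble
#'   (`primer_id`, `sequence`).
#' @return `iupac_hamming_matrix()`: symmetric integer distance matrix.
#' @export
iupac_hamming_matrix <- function(seqs) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$sequence, seqs$primer_id)
  n <- length(seqs)
  m <- matrix(0L, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i) m[i, j] <- m[j, i] <- iupac_hamming(seqs[[i]], seqs[[j]])
  }
  m
}

#' Ward minimum-variance clustering of a primer panel
#'
#' Agglomerates the IUPAC-Hamming distance matrix of the primer sequences
#' under Ward's minimum-variance criterion (Lance-Williams recurrence on
#' squared distances, i.e. `stats::hclust(method = "ward.D")` on d^2).
#' Primers are ordered lexicographically before clustering so the result is
#' independent of input order. The tree is cut either at a requested number
#' of clusters `k` or, when `k` is `NULL`, below the largest merge-height
#' gap.
#'
#' @param primers primer panel tibble ([read_primer_panel()]) or named
#'   character vector of equal-length sequences.
#' @param k number of clusters, or `NULL` for the largest-gap heuristic.
#' @return a `primer_clustering`: list with the `hclust` tree, the distance
#'   matrix, `k`, and `clusters` (tibble `primer_id`, `cluster`).
#' @export
ward_cluster <- function(primers, k = NULL) {
  seqs <- if (is.data.frame(primers)) setNames(primers$sequence, primers$primer_id)
          else primers
  if (length(seqs) < 2) stop("need at least two primers to cluster")
  if (length(unique(nchar(seqs))) != 1) stop("primer sequences must have equal length")
  seqs <- seqs[order(names(seqs))]
  d <- iupac_hamming_matrix(seqs)
  hc <- stats::hclust(stats::as.dist(d^2), method = "ward.D")
  if (is.null(k)) {
    gaps <- diff(hc$height)
    k <- length(seqs) - which.max(gaps) - 1L + 1L  # cut inside largest gap
    k <- max(k, 2L)
  }
  cl <- stats::cutree(hc, k = k)
  structure(list(hclust = hc, dist = d, k = as.integer(k),
                 clusters = tibble::tibble(primer_id = names(cl),
                                           cluster = unname(cl))),
            class = "primer_clustering")
}

#' @export
print.primer_clustering <- function(x, ...) {
  cat("Ward clustering of", nrow(x$clusters), "primers into", x$k, "clusters\n")
  print(split(x$clusters$primer_id, x$clusters$cluster))
  invisible(x)
}

#' @method tidy primer_clustering
#' @export
tidy.primer_clustering <- function(x, ...) x$clusters

#' Cluster membership as character sets
#'
#' @param x a `primer_clustering`.
#' @return list of character vectors, one per cluster, each sorted.
#' @export
cluster_members <- function(x) {
  lapply(split(x$clusters$primer_id, x$clusters$cluster), sort)
}

#' On-/off-target amplification report for one primer pool
#'
#' Given the annotations of reads amplified by one primer, computes the
#' share of passing reads whose V-family call matches the primer's intended
#' family, the share whose V-gene call is among the intended genes, and the
#' off-target family histogram.
#'
#' @param annotations annotation tibble for the pool.
#' @param primer one row of a primer panel tibble.
#' @return tibble with `primer_id`, `family_level_fraction`,
#'   `gene_level_fraction`, `n_reads`, and an `off_target` list column
#'   (family histogram over non-intended families, summing to 1 unless
#'   there is no off-target read).
#' @export
on_target_rate <- function(annotations, primer) {
  a <- annotations[annotations$pass_filter, ]
  if (!nrow(a)) stop("no passing reads in pool")
  fam_frac <- mean(a$v_family == primer$intended_family)
  genes <- unlist(primer$intended_genes)
  gene_frac <- mean(a$v_call %in% genes)
  off <- a$v_family[a$v_family != primer$intended_family]
  hist <- if (length(off)) {
    tibble::tibble(family = names(table(off)),
                   fraction = as.numeric(table(off) / length(off)))
  } else tibble::tibble(family = character(), fraction = numeric())
  tibble::tibble(primer_id = primer$primer_id,
                 family_level_fraction = fam_frac,
                 gene_level_fraction = gene_frac,
                 n_reads = nrow(a), off_target = list(hist))
}

#' Normalise per-primer clonotype tables to equal pool weight
#'
#' PCR pools are sequenced at unequal depth; before pooling, each pool's
#' counts are rescaled so every pool contributes the same total weight while
#' within-pool proportions are preserved.
#'
#' @param tables named list of tibbles with a `count` column (one per pool).
#' @return single tibble with `pool`, the original columns, and a `weight`
#'   column; weights sum to 1 within each pool divided by the pool count.
#' @export
normalize_by_primer <- function(tables) {
  if (!length(tables)) stop("need at least one pool table")
  keep <- Filter(function(t) nrow(t) > 0, tables)
  if (!length(keep)) stop("all pool tables are empty")
  purrr::imap_dfr(keep, function(t, nm) {
    dplyr::mutate(tibble::as_tibble(t), pool = nm,
                  weight = .data$count / sum(.data$count) / length(keep))
  })
}

#' Predicted amplification matrix of a primer panel
#'
#' Qualitative model of promiscuous amplification: the predicted capture
#' weight of gene g by primer p is proportional to `abundance(g) *
#' match_score(p, g)`, where the match score decays exponentially with the
#' weighted IUPAC mismatch count of the primer against the gene's 5' region
#' and mismatches in the 3'-terminal positions (the primer extension end)
#' are up-weighted. Rows (primers) are normalised to 1.
#'
#' @param germline germline reference tibble (V genes are used).
#' @param primers forward primer panel tibble.
#' @param abundance named gene abundances; `NULL` = uniform.
#' @param beta decay per weighted mismatch.
#' @param end_weight multiplicative weight of the 3'-terminal `end_n`
#'   positions.
#' @param end_n number of 3'-terminal positions up-weighted.
#' @return list with `matrix` (primers x genes, rows normalised) and
#'   `total_capture` (row sums before normalisation).
#' @export
primer_match_simulation <- function(germline, primers, abundance = NULL,
                                    beta = 2, end_weight = 3, end_n = 3L) {
  vref <- germline[germline$segment == "V", ]
  ab <- abundance %||% setNames(rep(1 / nrow(vref), nrow(vref)), vref$name)
  ab <- ab / sum(ab)
  L <- nchar(primers$sequence[1])
  g5 <- setNames(substr(vref$nt_sequence, 1L, L), vref$name)
  w <- rep(1, L); w[(L - end_n + 1L):L] <- end_weight
  score <- matrix(0, nrow(primers), length(g5),
                  dimnames = list(primers$primer_id, names(g5)))
  for (i in seq_len(nrow(primers))) {
    p <- strsplit(primers$sequence[i], "")[[1]]
    for (g in names(g5)) {
      q <- strsplit(g5[[g]], "")[[1]]
      mis <- !mapply(function(x, y)
        length(intersect(IUPAC_SETS[[x]], IUPAC_SETS[[y]])) > 0, p, q)
      score[i, g] <- exp(-beta * sum(w[mis])) * ab[[g]]
    }
  }
  total <- rowSums(score)
  normalized <- sweep(score, 1, ifelse(total > 0, total, 1), "/")
  list(matrix = normalized, total_capture = total)
}
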