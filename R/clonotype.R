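# Hierarchical clonotyping: abundance filtering (N >= 2) combined with
# Hamming-distance rescue of singletons, under three clonotype key schemes
# (CDR3; merged CDR1+CDR3; CDR3 with germline identity), plus the dominance,
# cumulative-rank and overlap statistics used to characterise the library.

#' Hamming distance between equal-length strings
#'
#' Number of mismatching positions. Distances between strings of unequal
#' length are undefined and raise an error, per the definition used for
#' clonotyping (comparisons are made at equal length only).
#'
#' @param a,b character vectors (recycled to common length).
#' @return integer vector of distances.
#' @export
#' @examples
#' hamming_distance("ARDYW", "ARDFW")  # 1
hamming_distance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  if (any(nchar(a) != nchar(b))) {
    stop("Hamming distance is undefined for sequences of unequal length")
  }
  mapply(hamming_cpp, a, b, USE.NAMES = FALSE)
}

#' Levenshtein edit distance
#'
#' Unit-cost insertions, deletions and substitutions (via [utils::adist()]).
#'
#' @param a,b character vectors (recycled).
#' @return integer vector of distances.
#' @export
levenshtein_distance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  vapply(seq_len(n), function(i) as.integer(adist(a[i], b[i])), integer(1))
}

#' Pairwise Levenshtein distances within a set of sequences
#'
#' @param x character vector.
#' @return tibble of the upper-triangle pairs (`i`, `j`, `distance`).
#' @export
pairwise_levenshtein <- function(x) {
  m <- levenshtein_matrix_cpp(x)
  ut <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(i = ut[, 1], j = ut[, 2], distance = m[ut])
}

#' Build clonotype keys from annotations
#'
#' Keys reads that passed the alignment filters and are productive.
#' Schemes: `"cdr3"` uses the CDR3 amino-acid sequence; `"cdr1_cdr3"`
#' concatenates CDR1 and CDR3 (separator `|`); `"cdr3_germline"` pairs the
#' CDR3 with the called V gene (Hamming comparisons then apply to the CDR3
#' part only, and clonotypes never merge across germlines).
#'
#' @param annotations annotation tibble from [annotate_reads()].
#' @param scheme key scheme.
#' @return tibble (`key`, `count`) of unique keys with read counts, carrying
#'   the scheme as an attribute.
#' @export
make_clonotype_keys <- function(annotations,
                                scheme = c("cdr3", "cdr1_cdr3", "cdr3_germline")) {
  scheme <- match.arg(scheme)
  a <- annotations[annotations$pass_filter & annotations$productive &
                     !is.na(annotations$cdr3_aa), ]
  key <- switch(scheme,
    cdr3 = a$cdr3_aa,
    cdr1_cdr3 = paste(a$cdr1_aa, a$cdr3_aa, sep = "|"),
    cdr3_germline = paste(a$v_call, a$cdr3_aa, sep = "|"))
  out <- tibble::tibble(key = key) |>
    dplyr::count(.data$key, name = "count") |>
    dplyr::arrange(.data$key)
  attr(out, "scheme") <- scheme
  out
}

# Split a composite key into its (germline, comparable-sequence) parts.
key_parts <- function(key, scheme) {
  if (scheme == "cdr3_germline") {
    pos <- regexpr("|", key, fixed = TRUE)
    list(group = substr(key, 1L, pos - 1L),
         seq = substr(key, pos + 1L, nchar(key)))
  } else {
    # for cdr1_cdr3 the whole merged string is compared positionally
    list(group = rep("", length(key)), seq = sub("|", "", key, fixed = TRUE))
  }
}

#' Hierarchical clonotyping with singleton rescue
#'
#' The clustering used to count clonotypes: (1) keys are split into abundant
#' (count >= 2) and singletons (count = 1); (2) every abundant key seeds its
#' own clonotype; (3) each singleton is absorbed into an abundant clonotype
#' when some abundant key of equal length lies within Hamming distance `h`
#' (ties: the most abundant key, then the lexicographically smallest);
#' otherwise it is retained as a "true singleton" clonotype. Singletons are
#' never merged with one another, which makes the result independent of
#' input order. With `criterion = "abundance_only"` all singletons are
#' dropped instead (the N >= 2 rows of the diversity grid). `h = 0` leaves
#' every unique key as its own clonotype.
#'
#' Under the `cdr3_germline` scheme the Hamming comparison applies to the
#' CDR3 part only and absorption additionally requires an identical V call.
#'
#' @param keys tibble (`key`, `count`), e.g. from [make_clonotype_keys()].
#' @param h Hamming criterion, 0-3.
#' @param criterion `"hamming"` (singleton rescue at distance `h`) or
#'   `"abundance_only"` (drop all singletons).
#' @param scheme key scheme of `keys` (defaults to the attribute set by
#'   [make_clonotype_keys()]).
#' @return a `clonotype_tbl`: tibble (`clonotype`, `count`, `n_members`,
#'   `members` list column), sorted by descending count; the criterion and
#'   scheme are attached as attributes.
#' @export
hierarchical_clonotype <- function(keys, h = 1L,
                                   criterion = c("hamming", "abundance_only"),
                                   scheme = NULL) {
  criterion <- match.arg(criterion)
  scheme <- scheme %||% attr(keys, "scheme") %||% "cdr3"
  if (criterion == "hamming" && (h < 0 || h > 3)) {
    stop("Hamming criterion h must lie in 0..3")
  }
  stopifnot(all(keys$count >= 1), !anyDuplicated(keys$key))
  abundant <- keys[keys$count >= 2L, ]
  single <- keys[keys$count == 1L, ]

  if (criterion == "abundance_only" || nrow(single) == 0L || h == 0L) {
    kept <- if (criterion == "abundance_only") abundant else keys
    out <- tibble::tibble(clonotype = kept$key, count = kept$count,
                          n_members = 1L, members = as.list(kept$key))
  } else {
    absorb <- rep(NA_integer_, nrow(single))
    if (nrow(abundant)) {
      sp <- key_parts(single$key, scheme)
      ap <- key_parts(abundant$key, scheme)
      sg <- split(seq_len(nrow(single)), list(sp$group, nchar(sp$seq)), drop = TRUE)
      ag <- split(seq_len(nrow(abundant)), list(ap$group, nchar(ap$seq)), drop = TRUE)
      for (bucket in intersect(names(sg), names(ag))) {
        si <- sg[[bucket]]; ai <- ag[[bucket]]
        hit <- absorb_singletons_cpp(sp$seq[si], ap$seq[ai],
                                     abundant$count[ai], as.integer(h))
        absorb[si] <- ai[hit]
      }
    }
    add <- tapply(rep(1L, sum(!is.na(absorb))), absorb[!is.na(absorb)], sum)
    counts <- abundant$count
    counts[as.integer(names(add))] <- counts[as.integer(names(add))] + as.integer(add)
    members <- as.list(abundant$key)
    for (i in which(!is.na(absorb))) {
      members[[absorb[i]]] <- c(members[[absorb[i]]], single$key[i])
    }
    true_single <- single[is.na(absorb), ]
    out <- tibble::tibble(
      clonotype = c(abundant$key, true_single$key),
      count = c(counts, true_single$count),
      n_members = lengths(c(members, as.list(true_single$key))),
      members = c(members, as.list(true_single$key)))
  }
  out <- dplyr::arrange(out, dplyr::desc(.data$count), .data$clonotype)
  structure(out, class = c("clonotype_tbl", class(out)),
            criterion = if (criterion == "hamming") paste0("hamming_", h)
                        else "abundance_only",
            scheme = scheme)
}

#' Clonotype reads end-to-end
#'
#' Convenience wrapper: [make_clonotype_keys()] then
#' [hierarchical_clonotype()].
#'
#' @inheritParams make_clonotype_keys
#' @inheritParams hierarchical_clonotype
#' @export
clonotype_reads <- function(annotations, h = 1L,
                            scheme = c("cdr3", "cdr1_cdr3", "cdr3_germline"),
                            criterion = c("hamming", "abundance_only")) {
  scheme <- match.arg(scheme)
  hierarchical_clonotype(make_clonotype_keys(annotations, scheme), h = h,
                         criterion = criterion, scheme = scheme)
}

#' Clonal dominance
#'
#' Fraction of all reads carried by the single most abundant clonotype.
#'
#' @param t a `clonotype_tbl` (or any tibble with a `count` column).
#' @return fraction in \[0, 1\].
#' @export
clonal_dominance <- function(t) {
  stopifnot(nrow(t) > 0)
  max(t$count) / sum(t$count)
}

#' Cumulative clonal rank and copy-number spectrum
#'
#' Clonotypes are ranked by descending abundance; the cumulative read
#' fraction, the number of clones needed to cover half the reads, and the
#' copy-number spectrum (fraction of clonotypes observed 1x, 2x, ...) are
#' returned.
#'
#' @param t a `clonotype_tbl`.
#' @return list with `curve` (rank, count, cumulative_fraction),
#'   `clones_to_half`, and `spectrum` (copy number, fraction of clonotypes).
#' @export
cumulative_rank <- function(t) {
  cnt <- sort(t$count, decreasing = TRUE)
  cum <- cumsum(cnt) / sum(cnt)
  spectrum <- tibble::tibble(copies = as.integer(names(table(cnt))),
                             n_clonotypes = as.integer(table(cnt))) |>
    dplyr::arrange(.data$copies) |>
    dplyr::mutate(fraction = .data$n_clonotypes / sum(.data$n_clonotypes))
  list(curve = tibble::tibble(rank = seq_along(cnt), count = cnt,
                              cumulative_fraction = cum),
       clones_to_half = which(cum >= 0.5)[1],
       spectrum = spectrum)
}

#' Clonotype overlap between two tables
#'
#' Exact-key Jaccard overlap plus the two directional shares.
#'
#' @param tA,tB `clonotype_tbl`s or key tibbles.
#' @return tibble with `jaccard`, `share_A_in_B`, `share_B_in_A`.
#' @export
clonotype_overlap <- function(tA, tB) {
  key_of <- function(t) if ("clonotype" %in% names(t)) t$clonotype else t$key
  ka <- unique(key_of(tA))
  kb <- unique(key_of(tB))
  i <- length(intersect(ka, kb))
  tibble::tibble(jaccard = i / length(union(ka, kb)),
                 share_A_in_B = i / length(ka),
                 share_B_in_A = i / length(kb))
}

#' @method tidy clonotype_tbl
#' @export
tidy.clonotype_tbl <- function(x, ...) {
  tibble::tibble(clonotype = x$clonotype, count = x$count,
                 n_members = x$n_members,
                 frequency = x$count / sum(x$count))
}

#' @method glance clonotype_tbl
#' @export
glance.clonotype_tbl <- function(x, ...) {
  cr <- cumulative_rank(x)
  tibble::tibble(
    n_clonotypes = nrow(x),
    n_reads = sum(x$count),
    dominance = clonal_dominance(x),
    singleton_fraction = mean(x$count == 1L),
    clones_to_half = cr$clones_to_half,
    shannon_hill = hill_diversity(x$count, 1),
    simpson_hill = hill_diversity(x$count, 2),
    criterion = attr(x, "criterion"),
    scheme = attr(x, "scheme"))
}
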