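# CDR biophysical profiling: Henderson-Hasselbalch net charge on the
# Lehninger pK scale, Kyte-Doolittle GRAVY, length distributions, V/J
# pairing, and developability summaries over germline scaffolds.

count_residues <- function(seq, residues) {
  m <- vapply(residues, function(r)
    stringr::str_count(seq, stringr::fixed(r)), integer(length(seq)))
  if (length(seq) == 1L) m <- matrix(m, nrow = 1, dimnames = list(NULL, residues))
  m
}

#' Net charge of a peptide at a given pH
#'
#' Sum of signed Henderson-Hasselbalch fractional charges over ionizable
#' side chains: basic groups (K, R, H) contribute `+1/(1+10^(pH-pK))`,
#' acidic groups (D, E, C, Y) `-1/(1+10^(pK-pH))`. Terminal groups are
#' excluded by default because CDRs are internal segments of the antibody
#' chain; set `include_termini = TRUE` for free peptides. Charge is additive
#' over concatenation and independent of residue order.
#'
#' @param seq character vector of amino-acid sequences (standard residues).
#' @param pH pH; default 7.0.
#' @param pk pK table from [lehninger_pk()] (columns `group`, `pk`, `sign`).
#' @param include_termini add the alpha-amino and alpha-carboxyl group
#'   contributions?
#' @return numeric vector of net charges (elementary charge units).
#' @export
#' @examples
#' net_charge("K")  # ~ +1.00
net_charge <- function(seq, pH = 7.0, pk = lehninger_pk(),
                       include_termini = FALSE) {
  if (any(grepl(paste0("[^", paste(AA20, collapse = ""), "]"), seq))) {
    stop("non-standard residue in sequence")
  }
  side <- pk[pk$group %in% AA20, ]
  frac <- ifelse(side$sign > 0,
                 1 / (1 + 10^(pH - side$pk)),
                 -1 / (1 + 10^(side$pk - pH)))
  counts <- count_residues(seq, side$group)
  charge <- as.numeric(counts %*% frac)
  if (include_termini) {
    term <- pk[!pk$group %in% AA20, ]
    tfrac <- ifelse(term$sign > 0,
                    1 / (1 + 10^(pH - term$pk)),
                    -1 / (1 + 10^(term$pk - pH)))
    charge <- charge + sum(tfrac)
  }
  charge
}

#' GRAVY hydropathy index
#'
#' Grand average of hydropathy: the arithmetic mean of per-residue
#' Kyte-Doolittle values. Negative values indicate hydrophilic sequences.
#'
#' @param seq character vector of non-empty amino-acid sequences.
#' @param scale named hydropathy values over the 20 standard residues.
#' @return numeric vector of GRAVY indices.
#' @export
#' @examples
#' gravy("V")  # 4.2
gravy <- function(seq, scale = kyte_doolittle()) {
  if (any(!nzchar(seq) | is.na(seq))) stop("empty sequence has no GRAVY index")
  if (any(grepl(paste0("[^", paste(names(scale), collapse = ""), "]"), seq))) {
    stop("residue outside the hydropathy scale")
  }
  counts <- count_residues(seq, names(scale))
  as.numeric(counts %*% scale) / nchar(seq)
}

#' Biophysical profile of clonotyped CDR3 sequences
#'
#' One row per passing productive read (or per clonotype if a
#' `clonotype_tbl` is supplied upstream): CDR3 length, net charge at pH 7,
#' GRAVY, V/J calls and the developability class of the V gene.
#'
#' @param annotations annotation tibble from [annotate_reads()].
#' @param map developability map ([read_developability_map()]).
#' @param pH pH for the charge computation.
#' @return tibble with `cdr3_aa`, `length`, `net_charge`, `gravy`,
#'   `v_gene`, `v_family`, `j_gene`, `developability`.
#' @export
biophys_profile <- function(annotations, map = read_developability_map(),
                            pH = 7.0) {
  a <- annotations[annotations$pass_filter & annotations$productive &
                     !is.na(annotations$cdr3_aa), ]
  if (!nrow(a)) stop("no usable annotations")
  tibble::tibble(
    cdr3_aa = a$cdr3_aa,
    length = nchar(a$cdr3_aa),
    net_charge = net_charge(a$cdr3_aa, pH = pH),
    gravy = gravy(a$cdr3_aa),
    v_gene = a$v_call, v_family = a$v_family, j_gene = a$j_call,
    developability = classify_developability(a$v_call, map))
}

#' Length distribution summaries
#'
#' Deterministic per-stratum summaries of CDR3 amino-acid lengths: median,
#' sample standard deviation (n-1), and nearest-rank lower/upper 10%
#' quantiles; lengths are checked against the observable 3-42 aa range.
#'
#' @param profiles tibble from [biophys_profile()] (needs `length`, and the
#'   stratifier columns when `by` is given).
#' @param by optional stratifier column names, e.g. `c("v_family",
#'   "j_gene")`.
#' @return tibble of per-stratum summaries.
#' @export
length_distribution <- function(profiles, by = NULL) {
  stopifnot(all(profiles$length >= 3), all(profiles$length <= 42))
  grouped <- if (is.null(by)) profiles else
    dplyr::group_by(profiles, dplyr::across(dplyr::all_of(by)))
  dplyr::summarise(grouped,
    n = dplyr::n(),
    median = median(.data$length),
    sigma = sd(.data$length),
    q10 = quantile(.data$length, 0.10, type = 1, names = FALSE),
    q90 = quantile(.data$length, 0.90, type = 1, names = FALSE),
    .groups = "drop")
}

#' V-family x J-gene pairing matrix
#'
#' Read-fraction matrix over V families (rows) and J genes (columns);
#' entries sum to 1, marginals are attached as attributes.
#'
#' @param profiles tibble with `v_family` and `j_gene` columns.
#' @return numeric matrix of read fractions with `v_marginal` and
#'   `j_marginal` attributes.
#' @export
vj_pairing_matrix <- function(profiles) {
  tab <- table(profiles$v_family, profiles$j_gene)
  m <- unclass(tab / sum(tab))
  attr(m, "v_marginal") <- rowSums(m)
  attr(m, "j_marginal") <- colSums(m)
  m
}

#' Developability class composition of a library
#'
#' Class fractions over the scaffold developability classes, optionally
#' after per-primer normalisation (each primer pool contributing equal
#' weight, see [normalize_by_primer()]).
#'
#' @param profiles tibble from [biophys_profile()]; when `weights` is given
#'   it must also carry the column named in `pool_col`.
#' @param weights optional named per-pool weights (summing to 1); `NULL`
#'   weights every read equally.
#' @param pool_col column of `profiles` holding the pool id.
#' @return tibble (`developability`, `fraction`), fractions summing to 1.
#' @export
developability_summary <- function(profiles, weights = NULL,
                                   pool_col = "pool") {
  if (!nrow(profiles)) stop("empty profile table")
  w <- if (is.null(weights)) rep(1, nrow(profiles)) else {
    pools <- profiles[[pool_col]]
    per_pool_n <- table(pools)
    unname(weights[pools] / as.numeric(per_pool_n[pools]))
  }
  out <- tibble::tibble(developability = profiles$developability, w = w) |>
    dplyr::group_by(.data$developability) |>
    dplyr::summarise(fraction = sum(.data$w), .groups = "drop") |>
    dplyr::mutate(fraction = .data$fraction / sum(.data$fraction))
  out
}
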