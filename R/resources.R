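# Packaged reference data and validated readers: synthetic germline V/J set,
# published primer panels, developability class map, physicochemical scales.

#' Path to a packaged reference file
#'
#' @param file file name under the package's `extdata/` directory.
#' @return absolute path to the file.
#' @export
naiverep_example <- function(file) {
  p <- system.file("extdata", file, package = "naiverep", mustWork = FALSE)
  if (!nzchar(p)) stop("no packaged file named '", file, "'")
  p
}

#' Canonicalise an immunoglobulin gene name
#'
#' Published tables mix dash glyphs and drop the locus prefix (e.g. "3–23"
#' for IGHV3-23). Dashes are normalised to ASCII hyphens, whitespace stripped,
#' and a locus prefix (e.g. `"IGHV"`) prepended when the name starts with a
#' digit.
#'
#' @param x character vector of gene names.
#' @param locus prefix used when the name carries none, e.g. `"IGHV"`.
#' @return character vector of canonical names.
#' @export
#' @examples
#' normalize_gene_name("3–23", "IGHV")  # "IGHV3-23"
normalize_gene_name <- function(x, locus = "") {
  x <- gsub("[–—−]", "-", x)
  x <- gsub("\\s+", "", x)
  bare <- grepl("^[0-9]", x)
  x[bare] <- paste0(locus, x[bare])
  # "1-02" -> "1-2" style zero trimming within allele-free names
  gsub("-0([0-9])", "-\\1", x)
}

#' Family of an immunoglobulin gene name
#'
#' @param name character vector of canonical gene names.
#' @return the family prefix, e.g. `"IGHV3"` for `"IGHV3-23"`.
#' @export
gene_family <- function(name) sub("^((IG[HKL][VJ])[0-9]+D?).*$", "\\1", name)

parse_cdr_bounds <- function(x) {
  if (is.na(x) || !nzchar(x)) return(NULL)
  v <- as.integer(strsplit(x, ",")[[1]])
  if (length(v) != 10L) stop("cdr_bounds must hold 5 half-open intervals (10 ints)")
  m <- matrix(v, ncol = 2, byrow = TRUE,
              dimnames = list(c("FR1", "CDR1", "FR2", "CDR2", "FR3"),
                              c("start", "end")))
  m
}

validate_germline <- function(genes) {
  stopifnot(is.data.frame(genes))
  if (anyDuplicated(genes$name)) {
    stop("duplicate germline gene name(s): ",
         paste(unique(genes$name[duplicated(genes$name)]), collapse = ", "))
  }
  bad_fam <- !startsWith(genes$name, genes$family)
  if (any(bad_fam)) stop("family is not a prefix of gene name: ",
                         paste(genes$name[bad_fam], collapse = ", "))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    n <- nchar(g$nt_sequence)
    if (grepl("[^ACGT]", g$nt_sequence)) stop("non-ACGT base in ", g$name)
    if (g$anchor %% 3L != 0L || g$anchor + 3L > n)
      stop("anchor of ", g$name, " is not a codon start within the sequence")
    aa <- translate_nt(substr(g$nt_sequence, g$anchor + 1L, g$anchor + 3L))
    if (g$segment == "V") {
      if (aa != "C") stop("V gene ", g$name, " anchor codon translates to '",
                          aa, "', expected conserved Cys")
      b <- g$cdr_bounds[[1]]
      if (is.null(b)) stop("V gene ", g$name, " lacks cdr_bounds")
      if (any(diff(as.vector(t(b))) < 0) || b[1, 1] != 0L || max(b) > n)
        stop("cdr_bounds of ", g$name, " are not ascending within the sequence")
      if (any(b %% 3L != 0L))
        stop("cdr_bounds of ", g$name, " are not codon-aligned")
    } else if (!aa %in% c("W", "F")) {
      stop("J gene ", g$name, " anchor codon translates to '", aa,
           "', expected conserved Trp/Phe")
    }
  }
  invisible(genes)
}

#' Load a germline V/J reference
#'
#' Reads a nucleotide FASTA plus a tab-separated metadata table (columns
#' `name`, `family`, `chain`, `segment`, `cdr_bounds`, `anchor`; coordinates
#' 0-based half-open) and returns one validated record per gene. Validation
#' enforces unique names, family/name consistency, codon-aligned CDR bounds,
#' and the conserved anchor residue (2nd-Cys for V, J-Trp/Phe for J).
#'
#' @param fasta path to the nucleotide FASTA; ids must match metadata names.
#' @param metadata path to the metadata TSV.
#' @param chain optional filter: one of `"heavy"`, `"kappa"`, `"lambda"`.
#' @return a tibble with one row per gene; `cdr_bounds` is a list column of
#'   5x2 integer matrices (NULL for J genes).
#' @export
read_germline_reference <- function(fasta = naiverep_example("germline_synthetic.fasta"),
                                    metadata = naiverep_example("germline_synthetic.tsv"),
                                    chain = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  meta <- readr::read_tsv(metadata, col_types = readr::cols(
    name = "c", family = "c", chain = "c", segment = "c",
    cdr_bounds = "c", anchor = "i"))
  missing_meta <- setdiff(names(seqs), meta$name)
  if (length(missing_meta)) {
    stop("FASTA entr", if (length(missing_meta) > 1) "ies" else "y",
         " with no metadata row: ", paste(missing_meta, collapse = ", "))
  }
  missing_seq <- setdiff(meta$name, names(seqs))
  if (length(missing_seq)) {
    stop("metadata row(s) with no FASTA entry: ",
         paste(missing_seq, collapse = ", "))
  }
  genes <- meta |>
    dplyr::mutate(nt_sequence = as.character(seqs[.data$name]),
                  cdr_bounds = purrr::map(.data$cdr_bounds, parse_cdr_bounds)) |>
    dplyr::relocate("name", "family", "chain", "segment")
  validate_germline(genes)
  if (!is.null(chain)) {
    chain <- match.arg(chain, c("heavy", "kappa", "lambda"))
    genes <- genes[genes$chain == chain, ]
  }
  genes
}

#' Load a primer panel
#'
#' Reads a tab-separated panel (`primer_id`, `sequence`, `intended_family`,
#' `intended_genes` comma-separated, `orientation`) and validates that every
#' sequence is drawn from the IUPAC nucleotide alphabet and that forward V
#' primers are 18 nt long.
#'
#' @param path panel TSV path; defaults to the published heavy-chain panel.
#' @return tibble with `intended_genes` as a list column.
#' @export
read_primer_panel <- function(path = naiverep_example("primers_ighv.tsv")) {
  p <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  need <- c("primer_id", "sequence", "intended_family", "intended_genes",
            "orientation")
  if (!all(need %in% names(p))) {
    stop("primer panel must have columns: ", paste(need, collapse = ", "))
  }
  bad <- !is_iupac(p$sequence)
  if (any(bad)) {
    stop("non-IUPAC character in primer ", paste(p$primer_id[bad], collapse = ", "))
  }
  short <- p$orientation == "forward" & grepl("V", p$primer_id) &
    nchar(p$sequence) != 18L
  if (any(short)) {
    stop("forward V primers must be 18 nt: ",
         paste(p$primer_id[short], collapse = ", "))
  }
  p$intended_genes <- strsplit(p$intended_genes, ",")
  tibble::as_tibble(p)
}

#' Load the germline developability class map
#'
#' @param path TSV with columns `gene`, `class`; defaults to the packaged map
#'   of published scaffold classes.
#' @return tibble (gene, class) with class one of desirable,
#'   common_in_natural, neutral, poorly_developable.
#' @export
read_developability_map <- function(path = naiverep_example("developability_map.tsv")) {
  m <- readr::read_tsv(path, col_types = "cc")
  classes <- c("desirable", "common_in_natural", "neutral", "poorly_developable")
  bad <- !m$class %in% classes
  if (any(bad)) stop("unknown developability class: ",
                     paste(unique(m$class[bad]), collapse = ", "))
  if (anyDuplicated(m$gene)) stop("gene mapped to more than one class: ",
                                  paste(m$gene[duplicated(m$gene)], collapse = ", "))
  m
}

#' Developability class of germline genes
#'
#' Deterministic lookup into a developability map; names are canonicalised
#' first, and any gene absent from the map is classed `"unclassified"`.
#'
#' @param gene character vector of gene names (dash glyph and prefix tolerant).
#' @param map tibble from [read_developability_map()].
#' @param locus prefix for bare names, e.g. `"IGHV"`.
#' @return character vector of classes.
#' @export
#' @examples
#' classify_developability("IGHV3-23")  # "desirable"
classify_developability <- function(gene, map = read_developability_map(),
                                    locus = "") {
  key <- normalize_gene_name(gene, locus)
  cls <- map$class[match(key, normalize_gene_name(map$gene))]
  cls[is.na(cls)] <- "unclassified"
  cls
}

#' Physicochemical scale tables
#'
#' `read_scale()` reads a two-column residue/value TSV. `kyte_doolittle()`
#' returns the packaged Kyte-Doolittle hydropathy scale as a named vector
#' over the 20 standard residues; `lehninger_pk()` returns the packaged
#' Lehninger pK table for ionizable side chains and the terminal groups,
#' with the sign of the fully-protonated/deprotonated charge.
#'
#' @param path scale TSV path.
#' @return `read_scale()`/`lehninger_pk()`: a tibble; `kyte_doolittle()`:
#'   a named numeric vector.
#' @export
read_scale <- function(path) {
  s <- readr::read_tsv(path, col_types = readr::cols())
  if (ncol(s) < 2) stop("scale table needs at least two columns")
  s
}

#' @rdname read_scale
#' @export
kyte_doolittle <- function() {
  s <- read_scale(naiverep_example("kyte_doolittle.tsv"))
  stopifnot(nrow(s) == 20L)
  setNames(s$value, s$residue)
}

#' @rdname read_scale
#' @export
lehninger_pk <- function() {
  read_scale(naiverep_example("lehninger_pk.tsv"))
}

#' Enumerate PCR and assembly pool combinatorics of a primer panel set
#'
#' Counts the forward x reverse PCR combinations per locus and the scFv
#' assembly pools (heavy forward primers crossed with the light-chain loci).
#'
#' @param forward_heavy,forward_light,reverse primer panel tibbles.
#' @return tibble with one row per combination class and its count.
#' @export
enumerate_pool_combinations <- function(
    forward_heavy = read_primer_panel(naiverep_example("primers_ighv.tsv")),
    forward_light = read_primer_panel(naiverep_example("primers_light.tsv")),
    reverse = read_primer_panel(naiverep_example("primers_reverse_synthetic.tsv"))) {
  rev_locus <- substr(reverse$primer_id, 1, 3)
  n_h_fwd <- sum(forward_heavy$orientation == "forward")
  n_h_rev <- sum(rev_locus == "IGH")
  n_k_fwd <- sum(startsWith(forward_light$primer_id, "IGK"))
  n_k_rev <- sum(rev_locus == "IGK")
  n_l_fwd <- sum(startsWith(forward_light$primer_id, "IGL"))
  n_l_rev <- sum(rev_locus == "IGL")
  tibble::tibble(
    pool = c("heavy_pcr", "kappa_pcr", "lambda_pcr", "scfv_assembly"),
    n_forward = c(n_h_fwd, n_k_fwd, n_l_fwd, n_h_fwd),
    n_reverse = c(n_h_rev, n_k_rev, n_l_rev, 2L),
    n_combinations = c(n_h_fwd * n_h_rev, n_k_fwd * n_k_rev,
                       n_l_fwd * n_l_rev, n_h_fwd * 2L)
  )
}
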