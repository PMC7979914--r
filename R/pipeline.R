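# End-to-end orchestration: simulated (or imported) reads -> QC -> germline
# annotation -> clonotype/diversity grid -> dominance, biophysics and primer
# reports, with deterministic seeding and machine-readable output.

# Extra internal key scheme used by the diversity grid: CDR1 alone.
keys_from_cdr1 <- function(annotations) {
  a <- annotations[annotations$pass_filter & annotations$productive &
                     !is.na(annotations$cdr1_aa), ]
  out <- tibble::tibble(key = a$cdr1_aa) |>
    dplyr::count(.data$key, name = "count") |>
    dplyr::arrange(.data$key)
  attr(out, "scheme") <- "cdr3"  # plain positional comparison
  out
}

#' Clonotype diversity grid
#'
#' The library-QC diversity grid: one row per clonotyping criterion
#' (Hamming 0-3 and abundance-only N >= 2), with the unique-CDR1 measure,
#' the unique-CDR3 measure, the asymptotic CDR3 estimate from the
#' negative-exponential accumulation fit, and the merged CDR1+CDR3 total.
#'
#' @param annotations annotation tibble from [annotate_reads()].
#' @param h_list Hamming criteria (subset of 0:3).
#' @param abundance_only also include the N >= 2 row?
#' @param estimate fit the accumulation model for the CDR3 estimate column?
#'   (subsampling cost grows with read count).
#' @param grid_points number of accumulation grid points.
#' @param n_reps accumulation replicates per grid point.
#' @param seed integer seed for the subsampling.
#' @return tibble with columns `criterion`, `cdr1_measure`, `cdr3_measure`,
#'   `cdr3_estimate`, `cdr1_cdr3_total`.
#' @export
diversity_grid <- function(annotations, h_list = 0:3, abundance_only = TRUE,
                           estimate = TRUE, grid_points = 6L, n_reps = 2L,
                           seed = 1L) {
  stopifnot(all(h_list %in% 0:3))
  keys3 <- make_clonotype_keys(annotations, "cdr3")
  keys13 <- make_clonotype_keys(annotations, "cdr1_cdr3")
  keys1 <- keys_from_cdr1(annotations)
  n_usable <- sum(keys3$count)
  grid <- unique(round(seq(max(2, n_usable / grid_points), n_usable,
                           length.out = grid_points)))
  one_row <- function(label, h, crit) {
    est <- NA_real_
    if (estimate && n_usable >= 10) {
      cv <- accumulation_curve(annotations, grid = grid, h = h,
                               scheme = "cdr3", criterion = crit,
                               n_reps = n_reps,
                               seed = derive_seed(seed, label))
      ft <- fit_accumulation(cv)
      est <- ft$S_max
    }
    m1 <- nrow(hierarchical_clonotype(keys1, h = h, criterion = crit))
    m3 <- nrow(hierarchical_clonotype(keys3, h = h, criterion = crit))
    m13 <- nrow(hierarchical_clonotype(keys13, h = h, criterion = crit))
    tibble::tibble(criterion = label, cdr1_measure = m1, cdr3_measure = m3,
                   cdr3_estimate = est, cdr1_cdr3_total = m13)
  }
  rows <- purrr::map_dfr(sort(h_list), function(h)
    one_row(paste0("hamming_", h), h, "hamming"))
  if (abundance_only) {
    rows <- dplyr::bind_rows(rows, one_row("abundance_only", 0L, "abundance_only"))
  }
  rows
}

#' Combine heavy- and light-chain diversity grids
#'
#' Heavy/light pairing during library assembly is combinatorial, so the
#' combined diversity at each criterion is the product of the chain
#' diversities (e.g. heavy CDR3 x kappa CDR3).
#'
#' @param heavy,light diversity grids from [diversity_grid()] (or any
#'   tibbles with a `criterion` column and numeric measure columns).
#' @return tibble of per-criterion products over the shared numeric columns.
#' @export
combined_diversity <- function(heavy, light) {
  shared <- intersect(names(heavy), names(light))
  num <- shared[vapply(heavy[shared], is.numeric, logical(1))]
  out <- dplyr::inner_join(heavy, light, by = "criterion",
                           suffix = c("_h", "_l"))
  for (col in num) {
    out[[col]] <- out[[paste0(col, "_h")]] * out[[paste0(col, "_l")]]
  }
  dplyr::select(out, "criterion", dplyr::all_of(num))
}

#' Configure the analysis pipeline
#'
#' @param spec [repertoire_spec()] used when simulating input (ignored when
#'   `fastq` is given).
#' @param fastq optional path to a FASTQ file to analyse instead of
#'   simulating.
#' @param n_reads reads to simulate.
#' @param sub_rate per-base substitution error rate for simulation.
#' @param qc a [qc_config()].
#' @param annotate an [annotate_config()].
#' @param h_list Hamming criteria for the diversity grid.
#' @param estimate fit accumulation models in the grid?
#' @param grid_points,n_reps accumulation-curve settings.
#' @param seed master integer seed recorded in every output.
#' @param outdir optional output directory for report files.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(spec = repertoire_spec(), fastq = NULL,
                            n_reads = 20000L, sub_rate = 0.002,
                            qc = qc_config(), annotate = annotate_config(),
                            h_list = 0:3, estimate = TRUE, grid_points = 6L,
                            n_reps = 2L, seed = 1L, outdir = NULL) {
  structure(list(spec = spec, fastq = fastq, n_reads = as.integer(n_reads),
                 sub_rate = sub_rate, qc = qc, annotate = annotate,
                 h_list = h_list, estimate = estimate,
                 grid_points = as.integer(grid_points),
                 n_reps = as.integer(n_reps), seed = as.integer(seed),
                 outdir = outdir), class = "pipeline_config")
}

#' Run the full library-QC pipeline
#'
#' Simulates (or loads) reads, applies the Phred filter, annotates against
#' the germline reference, and assembles the library-QC report: the
#' diversity grid over clonotyping criteria, dominance/cumulative-rank
#' statistics, the CDR3 biophysical summary, the developability composition
#' and the primer clustering. Identical config and seed give identical
#' reports.
#'
#' @param cfg a [pipeline_config()].
#' @param germline germline reference tibble.
#' @param primers forward primer panel used for the primer report.
#' @return a `naiverep_report` list; written to `cfg$outdir` as JSON/TSV
#'   when set.
#' @export
run_pipeline <- function(cfg = pipeline_config(),
                         germline = read_germline_reference(),
                         primers = read_primer_panel()) {
  reads <- if (!is.null(cfg$fastq)) read_fastq(cfg$fastq) else {
    clones <- generate_repertoire(cfg$spec, germline)
    simulate_reads(clones, cfg$n_reads, sub_rate = cfg$sub_rate,
                   seed = cfg$seed)
  }
  passed <- filter_by_phred(reads, cfg$qc)
  ann <- annotate_reads(passed, germline, cfg$annotate)
  grid <- diversity_grid(ann, h_list = cfg$h_list, estimate = cfg$estimate,
                         grid_points = cfg$grid_points, n_reps = cfg$n_reps,
                         seed = cfg$seed)
  ct1 <- clonotype_reads(ann, h = 1L)
  rank <- cumulative_rank(ct1)
  prof <- biophys_profile(ann)
  report <- structure(list(
    seed = cfg$seed,
    config_hash = rlang::hash(cfg),
    qc = qc_stats(passed),
    annotation = tibble::tibble(
      reads_annotated = nrow(ann),
      pass_filter = sum(ann$pass_filter),
      productivity = productivity_rate(ann)),
    diversity_grid = grid,
    dominance = clonal_dominance(ct1),
    clones_to_half = rank$clones_to_half,
    copy_spectrum = rank$spectrum,
    hill = diversity_spectrum(ct1),
    biophys = length_distribution(prof),
    charge_summary = tibble::tibble(
      median_charge = median(prof$net_charge),
      sigma_charge = sd(prof$net_charge),
      median_gravy = median(prof$gravy)),
    developability = developability_summary(prof),
    primer_clusters = tidy(ward_cluster(primers, k = 3L))),
    class = "naiverep_report")
  if (!is.null(cfg$outdir)) write_report(report, cfg$outdir)
  report
}

#' Write a pipeline report bundle
#'
#' @param report a `naiverep_report` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(seed = report$seed, config_hash = report$config_hash,
         dominance = report$dominance,
         clones_to_half = report$clones_to_half,
         annotation = report$annotation, qc = report$qc,
         charge_summary = report$charge_summary),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  readr::write_tsv(report$diversity_grid, file.path(dir, "diversity_grid.tsv"))
  readr::write_tsv(report$copy_spectrum, file.path(dir, "copy_spectrum.tsv"))
  readr::write_tsv(report$hill, file.path(dir, "hill_numbers.tsv"))
  readr::write_tsv(report$biophys, file.path(dir, "biophys.tsv"))
  readr::write_tsv(report$developability, file.path(dir, "developability.tsv"))
  readr::write_tsv(report$primer_clusters, file.path(dir, "primer_clusters.tsv"))
  invisible(dir)
}

#' @export
print.naiverep_report <- function(x, ...) {
  cat("naiverep library-QC report (seed ", x$seed, ")\n", sep = "")
  cat("  reads passing QC: ", x$qc$reads_passed, "/", x$qc$reads_in, "\n", sep = "")
  cat("  productivity: ", sprintf("%.3f", x$annotation$productivity), "\n", sep = "")
  cat("  clonal dominance (Hamming 1): ", sprintf("%.4f", x$dominance), "\n", sep = "")
  cat("  diversity grid:\n")
  print(x$diversity_grid)
  invisible(x)
}
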