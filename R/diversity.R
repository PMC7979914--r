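# Hill-number diversity, species-accumulation curves by rarefaction, and
# asymptotic richness estimation with a negative-exponential model.

#' Hill-number diversity of order q
#'
#' `qD = (sum p_i^q)^(1/(1-q))` with `p_i` the read proportion of clonotype
#' i; q = 0 is richness, q = 1 the exponential of Shannon entropy (taken as
#' the limit, where the closed form is singular), q = 2 the inverse Simpson
#' index. `qD` is non-increasing in q and equals the number of clones for a
#' uniform table.
#'
#' @param counts positive clonotype read counts.
#' @param q order(s), non-negative reals.
#' @return numeric vector of diversities, one per `q`.
#' @export
#' @examples
#' hill_diversity(c(2, 1, 1), 0)  # 3 (richness)
hill_diversity <- function(counts, q = 0) {
  if (length(counts) == 0) stop("empty count table")
  stopifnot(all(counts >= 1), all(q >= 0))
  p <- counts / sum(counts)
  vapply(q, function(qq) {
    if (abs(qq - 1) < 1e-12) exp(-sum(p * log(p)))
    else sum(p^qq)^(1 / (1 - qq))
  }, numeric(1))
}

#' @rdname hill_diversity
#' @param t a `clonotype_tbl` or tibble with a `count` column.
#' @export
diversity_spectrum <- function(t, q = c(0, 1, 2)) {
  tibble::tibble(q = q, qD = hill_diversity(t$count, q))
}

#' Species-accumulation curve by rarefaction
#'
#' For each subsample size `n`, draws `n` reads without replacement from the
#' annotated reads, clonotypes them at the requested Hamming criterion, and
#' records the clonotype count; replicates are averaged (per-replicate values
#' are retained).
#'
#' @param annotations annotation tibble from [annotate_reads()].
#' @param grid subsample sizes (each <= number of usable reads).
#' @param h Hamming criterion passed to [hierarchical_clonotype()].
#' @param scheme clonotype key scheme.
#' @param criterion `"hamming"` or `"abundance_only"`.
#' @param n_reps replicates per grid point.
#' @param seed integer seed for the subsampling.
#' @return tibble (`n`, `rep`, `S_obs`); the replicate average is in
#'   attribute-free form via `dplyr::summarise`.
#' @export
accumulation_curve <- function(annotations, grid, h = 1L, scheme = "cdr3",
                               criterion = "hamming", n_reps = 3L, seed = 1L) {
  usable <- annotations[annotations$pass_filter & annotations$productive &
                          !is.na(annotations$cdr3_aa), ]
  if (any(grid > nrow(usable))) {
    stop("grid point exceeds the ", nrow(usable), " usable reads")
  }
  if (any(grid < 1)) stop("grid points must be positive")
  with_rng(derive_seed(seed, "accum"), {
    purrr::map_dfr(sort(unique(grid)), function(n) {
      purrr::map_dfr(seq_len(n_reps), function(r) {
        sub <- usable[sample.int(nrow(usable), n), ]
        ct <- clonotype_reads(sub, h = h, scheme = scheme,
                              criterion = criterion)
        tibble::tibble(n = n, rep = r, S_obs = nrow(ct))
      })
    })
  })
}

#' Fit a negative-exponential accumulation model
#'
#' Least-squares fit of `S(n) = S_max * (1 - exp(-n / tau))` to the
#' replicate-averaged accumulation curve. Initialisation: `S_max` at 1.1x
#' the largest observed richness, `tau` at the sample size nearest half of
#' it; convergence at relative parameter change < 1e-8 within 500
#' iterations. Non-convergence is flagged on the result rather than raised.
#'
#' @param curve tibble with columns `n` and `S_obs` (replicates allowed;
#'   they are averaged per `n`).
#' @return an `accum_fit` with elements `S_max`, `tau`, `rss`, `converged`,
#'   `curve` (the averaged curve with fitted values) and the underlying
#'   `nls` fit (`NULL` when the optimiser failed).
#' @export
fit_accumulation <- function(curve) {
  avg <- curve |>
    dplyr::group_by(.data$n) |>
    dplyr::summarise(S_obs = mean(.data$S_obs), .groups = "drop") |>
    dplyr::arrange(.data$n)
  if (nrow(avg) < 3) stop("need >= 3 distinct sample sizes to fit")
  # saturated limit: an (effectively) flat curve needs no optimiser
  if (diff(range(avg$S_obs)) <= 1e-9 * max(avg$S_obs)) {
    avg$S_fit <- mean(avg$S_obs)
    return(structure(list(S_max = mean(avg$S_obs), tau = NA_real_,
                          rss = sum((avg$S_obs - mean(avg$S_obs))^2),
                          converged = TRUE, curve = avg, fit = NULL),
                     class = "accum_fit"))
  }
  s_max0 <- 1.1 * max(avg$S_obs)
  tau0 <- avg$n[which.min(abs(avg$S_obs - s_max0 / 2))]
  fit <- tryCatch(
    minpack.lm::nlsLM(S_obs ~ S_max * (1 - exp(-n / tau)),
                      data = avg,
                      start = list(S_max = s_max0, tau = max(tau0, 1)),
                      lower = c(S_max = 0, tau = 1e-6),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ptol = 1e-8)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- list(S_max = NA_real_, tau = NA_real_, rss = NA_real_,
                converged = FALSE, curve = avg, fit = NULL)
  } else {
    cf <- stats::coef(fit)
    avg$S_fit <- stats::predict(fit)
    out <- list(S_max = unname(cf["S_max"]), tau = unname(cf["tau"]),
                rss = sum(stats::resid(fit)^2),
                converged = fit$convInfo$isConv %||% TRUE,
                curve = avg, fit = fit)
  }
  structure(out, class = "accum_fit")
}

#' @export
print.accum_fit <- function(x, ...) {
  cat("Negative-exponential accumulation fit\n")
  cat(sprintf("  S_max = %.6g, tau = %.6g, rss = %.4g, converged: %s\n",
              x$S_max, x$tau, x$rss, x$converged))
  invisible(x)
}

#' @method tidy accum_fit
#' @export
tidy.accum_fit <- function(x, ...) {
  tibble::tibble(term = c("S_max", "tau"), estimate = c(x$S_max, x$tau))
}

#' @method glance accum_fit
#' @export
glance.accum_fit <- function(x, ...) {
  tibble::tibble(S_max = x$S_max, tau = x$tau, rss = x$rss,
                 converged = x$converged, n_points = nrow(x$curve),
                 S_obs_max = max(x$curve$S_obs))
}
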