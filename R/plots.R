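# ggplot2 views of the main result types.

#' Rank-abundance plot of a clonotype table
#'
#' @param object a `clonotype_tbl`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot clonotype_tbl
#' @export
autoplot.clonotype_tbl <- function(object, ...) {
  cr <- cumulative_rank(object)
  ggplot2::ggplot(cr$curve, ggplot2::aes(x = .data$rank, y = .data$count)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "clonotype rank", y = "read count",
                  title = paste0("Rank-abundance (", attr(object, "criterion"), ")"))
}

#' Accumulation curve with its negative-exponential fit
#'
#' @param object an `accum_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot accum_fit
#' @export
autoplot.accum_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$n, y = .data$S_obs)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "reads sampled", y = "unique clonotypes")
  if (!is.na(object$S_max)) {
    p <- p +
      ggplot2::geom_line(ggplot2::aes(y = .data$S_fit), colour = "steelblue") +
      ggplot2::geom_hline(yintercept = object$S_max, linetype = "dashed")
  }
  p
}

#' Heatmap of the V-family x J-gene pairing fractions
#'
#' @param m matrix from [vj_pairing_matrix()].
#' @return a ggplot.
#' @export
plot_vj_pairing <- function(m) {
  df <- as.data.frame.table(unclass(m), responseName = "fraction")
  names(df)[1:2] <- c("v_family", "j_gene")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j_gene, y = .data$v_family,
                                   fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "J gene", y = "V family", fill = "read fraction")
}

#' Dendrogram of a primer clustering
#'
#' @param x a `primer_clustering` from [ward_cluster()].
#' @param ... passed to [plot()].
#' @export
plot_primer_dendrogram <- function(x, ...) {
  plot(stats::as.dendrogram(x$hclust),
       main = paste("Ward clustering,", x$k, "clusters"), ...)
}
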