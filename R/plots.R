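#' Diagnostic figures for curated collections
#'
#' Writes three PNG panels: a histogram of the number of test years per
#' accession (the non-orthogonality fingerprint of regeneration data), a bar
#' panel of heritability estimates per dataset, and the distribution of BLUEs
#' per dataset on the trait scale.  Empty slices are skipped with a warning.
#'
#' @param results List of `pipeline_result` objects from [run_pipeline()].
#' @param dir Output directory for the figure files.
#' @return Invisibly, the paths of the files written.
#' @export
plot_reports <- function(results, dir = ".") {
  stopifnot(is.list(results))
  if (inherits(results, "pipeline_result")) results <- list(results)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  labels <- vapply(results, function(r) r$report$label, character(1))

  # years-per-accession histogram over non-empty curated slices
  inc <- do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    if (is.null(r$curated) || !n_records(r$curated)) return(NULL)
    data.frame(dataset = labels[i], years = years_per_accession(r$curated))
  }))
  if (!is.null(inc) && nrow(inc)) {
    p <- ggplot2::ggplot(inc, ggplot2::aes(x = .data$years)) +
      ggplot2::geom_bar(fill = "grey35") +
      ggplot2::facet_wrap(~dataset, scales = "free_y") +
      ggplot2::labs(x = "Years with data per accession", y = "Accessions") +
      ggplot2::theme_minimal()
    f <- file.path(dir, "years_per_accession.png")
    ggplot2::ggsave(f, p, width = 7, height = 5, dpi = 120)
    written <- c(written, f)
  } else warning("no non-empty curated dataset; years-per-accession panel skipped")

  # heritability bars
  h <- do.call(rbind, lapply(results, function(r) {
    rep <- r$report
    if (!identical(rep$status, "ok")) return(NULL)
    data.frame(dataset = rep$label, h2 = rep$heritability)
  }))
  if (!is.null(h) && nrow(h)) {
    p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$dataset, y = .data$h2)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::coord_cartesian(ylim = c(0, 1)) +
      ggplot2::labs(x = NULL, y = "Heritability") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
    f <- file.path(dir, "heritability.png")
    ggplot2::ggsave(f, p, width = 6, height = 4, dpi = 120)
    written <- c(written, f)
  } else warning("no heritability estimates; heritability panel skipped")

  # BLUE distributions
  b <- do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    if (is.null(r$blues) || !nrow(r$blues)) return(NULL)
    data.frame(dataset = labels[i], blue = r$blues$blue)
  }))
  if (!is.null(b) && nrow(b)) {
    p <- ggplot2::ggplot(b, ggplot2::aes(x = .data$blue)) +
      ggplot2::geom_histogram(bins = 40, fill = "grey35") +
      ggplot2::facet_wrap(~dataset, scales = "free") +
      ggplot2::labs(x = "BLUE (trait scale)", y = "Accessions") +
      ggplot2::theme_minimal()
    f <- file.path(dir, "blue_distributions.png")
    ggplot2::ggsave(f, p, width = 7, height = 5, dpi = 120)
    written <- c(written, f)
  } else warning("no BLUE tables; BLUE panel skipped")

  invisible(written)
}
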