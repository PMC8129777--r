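#' Run the full tetrad inheritance analysis
#'
#' Chains the pipeline stages on a genotype experiment with metadata:
#' site/call filtering ([filterSites()]), per-cross mitochondrial marker
#' derivation ([deriveMarkers()]), self-mating exclusion from nuclear
#' markers when non-mitochondrial sites are present ([flagSelfMating()]),
#' fraction profiles, heteroplasmy quantification, recombination calls,
#' crossover intervals, and spore/tetrad/cross summaries. Stage counts are
#' logged as key=value messages.
#'
#' @param x a [MitoTetradExperiment] with colony metadata and cross design
#'   attached (see [addSampleMetadata()]).
#' @param mito_contig mitochondrial contig name (default `"MT"`).
#' @param params site/call filter parameters ([filterParams()]).
#' @param purity parental-control purity threshold (default 0.95).
#' @param het_threshold heteroplasmy minor-fraction threshold
#'   (default 0.05).
#' @param maf_threshold recombination minor-parent fraction threshold
#'   (default 0.10).
#' @param rule recombination rule, `"sample"` (default) or `"site"`; see
#'   [classifyRecombinant()].
#' @param predominance_cutoff hard-assignment cutoff for crossover calls
#'   (default 0.5).
#' @param min_informative_selfing minimum informative nuclear calls per
#'   tetrad for the self-mating test (default 10).
#' @return a `TetradAnalysis` list: `experiment` (filtered, with
#'   exclusions applied), `markers`, `nuclear_markers` (or `NULL`),
#'   `self_mating`, `profiles`, `heteroplasmy`, `recombinants`,
#'   `crossovers`, `spores`, `tetrads`, `crosses`, and the thresholds used
#'   (`params`).
#' @examples
#' sim <- simulateDataset(simConfig(n_tetrads = 2, seed = 7))
#' res <- analyzeTetrads(asExperiment(sim))
#' res$crosses
#' @export
analyzeTetrads <- function(x, mito_contig = "MT",
                           params = filterParams(), purity = 0.95,
                           het_threshold = 0.05, maf_threshold = 0.10,
                           rule = c("sample", "site"),
                           predominance_cutoff = 0.5,
                           min_informative_selfing = 10) {
  rule <- match.arg(rule)
  ctgs <- as.character(seqnames(rowRanges(x)))
  if (!mito_contig %in% ctgs)
    stop("VCF contains no records on mitochondrial contig '", mito_contig, "'")
  xf <- filterSites(x, params)
  ctgs <- as.character(seqnames(rowRanges(xf)))
  mito <- xf[ctgs == mito_contig, ]
  markers <- deriveMarkers(mito, purity)
  if (!nrow(markers)) stop("no mitochondrial markers derivable for any cross")
  for (cid in crossDesign(x)$cross_id)
    if (!any(markers$cross_id == cid))
      stop("no mitochondrial markers derivable for cross ", cid)

  nuclear_markers <- NULL
  self_mating <- NULL
  if (any(ctgs != mito_contig)) {
    nuc <- xf[ctgs != mito_contig, ]
    nuclear_markers <- tryCatch(deriveMarkers(nuc, purity),
                                error = function(e) {
                                  warning("nuclear markers unavailable (",
                                          conditionMessage(e),
                                          "); self-mating not assessed")
                                  NULL
                                })
    if (!is.null(nuclear_markers) && nrow(nuclear_markers)) {
      xf <- flagSelfMating(xf, nuclear_markers, min_informative_selfing)
      self_mating <- metadata(xf)$selfMating
    }
  }

  profiles <- fractionProfiles(xf, markers)
  het <- heteroplasmySummary(xf, markers, het_threshold)
  rec <- classifyRecombinants(profiles, maf_threshold, rule)
  xo <- lapply(split(profiles, profiles$sample_id), function(pr) {
    pr <- pr[order(pr$pos), , drop = FALSE]
    iv <- suppressWarnings(
      countCrossovers(pr$parent1_fraction, pr$pos, predominance_cutoff))
    if (nrow(iv)) cbind(sample_id = pr$sample_id[1], iv) else NULL
  })
  xo <- do.call(rbind, xo[!vapply(xo, is.null, logical(1))])
  if (is.null(xo))
    xo <- data.frame(sample_id = character(), start_pos = numeric(),
                     end_pos = numeric())
  rownames(xo) <- NULL

  spores <- summarizeSpores(profiles, rec)
  tetrads <- classifyTetrads(spores, self_mating)
  crosses <- summarizeCrosses(spores, tetrads)
  logStage("analyze", markers = nrow(markers),
           spores = nrow(spores),
           recombinant = sum(rec$is_recombinant, na.rm = TRUE),
           deviating_tetrads = sum(tetrads$deviates_2_2, na.rm = TRUE))
  structure(list(experiment = xf, markers = markers,
                 nuclear_markers = nuclear_markers,
                 self_mating = self_mating, profiles = profiles,
                 heteroplasmy = het, recombinants = rec, crossovers = xo,
                 spores = spores, tetrads = tetrads, crosses = crosses,
                 params = list(filter = params, purity = purity,
                               het_threshold = het_threshold,
                               maf_threshold = maf_threshold, rule = rule,
                               predominance_cutoff = predominance_cutoff,
                               mito_contig = mito_contig)),
            class = "TetradAnalysis")
}

#' @export
print.TetradAnalysis <- function(x, ...) {
  cat("TetradAnalysis\n")
  cat(sprintf("  markers: %d (cross,site) pairs over %d distinct sites\n",
              nrow(x$markers), length(unique(x$markers$pos))))
  cat(sprintf("  heteroplasmy: %.1f%% of %d calls above threshold\n",
              100 * x$heteroplasmy$fraction_above_threshold,
              x$heteroplasmy$n_evaluable))
  cat(sprintf("  spores: %d analyzed, %d recombinant\n", nrow(x$spores),
              sum(x$recombinants$is_recombinant, na.rm = TRUE)))
  cat(sprintf("  tetrads: %d, %d deviating from 2:2\n", nrow(x$tetrads),
              sum(x$tetrads$deviates_2_2, na.rm = TRUE)))
  for (i in seq_len(nrow(x$crosses)))
    cat(sprintf("  %s: %.0f%% of %d spores from parent1 (binomial p = %.3g)\n",
                x$crosses$cross_id[i],
                100 * x$crosses$fraction_from_parent1[i],
                x$crosses$n_spores_analyzed[i],
                x$crosses$binomial_p_two_sided[i]))
  invisible(x)
}

#' Write result tables and figures
#'
#' Writes `spores.tsv`, `tetrads.tsv`, `crosses.tsv` and
#' `heteroplasmy.tsv` (byte-stable for identical analyses) plus three
#' figures: the minor-observation-fraction histogram, per-colony parent-1
#' fraction profiles along the mitochondrial genome, and per-tetrad mean
#' fraction dot strips.
#'
#' @param res a `TetradAnalysis` from [analyzeTetrads()].
#' @param outdir output directory (created if needed).
#' @return (invisibly) the vector of files written.
#' @export
buildReport <- function(res, outdir) {
  stopifnot(inherits(res, "TetradAnalysis"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    writeTsv(res$spores, file.path(outdir, "spores.tsv")),
    writeTsv(res$tetrads, file.path(outdir, "tetrads.tsv")),
    writeTsv(res$crosses, file.path(outdir, "crosses.tsv")),
    writeTsv(res$heteroplasmy$calls, file.path(outdir, "heteroplasmy.tsv")))

  het <- res$heteroplasmy$calls
  p1 <- ggplot2::ggplot(het, ggplot2::aes(x = minor_obs_fraction)) +
    ggplot2::geom_histogram(bins = 50, boundary = 0, fill = "grey30") +
    ggplot2::labs(x = "minor observation fraction", y = "calls",
                  title = "Heteroplasmy across all marker calls") +
    ggplot2::theme_bw()
  prof <- res$profiles
  p2 <- ggplot2::ggplot(prof,
                        ggplot2::aes(x = pos, y = parent1_fraction,
                                     group = sample_id,
                                     colour = tetrad_id)) +
    ggplot2::geom_vline(ggplot2::aes(xintercept = pos), colour = "grey80") +
    ggplot2::geom_line(alpha = 0.6, na.rm = TRUE) +
    ggplot2::geom_point(size = 0.8, na.rm = TRUE) +
    ggplot2::facet_wrap(~cross_id, ncol = 1) +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = "mitochondrial position (bp)",
                  y = "fraction assigned to parent 1") +
    ggplot2::theme_bw()
  sp <- res$spores
  p3 <- ggplot2::ggplot(sp,
                        ggplot2::aes(x = tetrad_id,
                                     y = mean_parent1_fraction,
                                     colour = tetrad_id)) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::facet_grid(~cross_id, scales = "free_x", space = "free_x") +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = NULL, y = "mean fraction from parent 1") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
  figs <- c(heteroplasmy = "fig_heteroplasmy_hist.png",
            profiles = "fig_fraction_profiles.png",
            tetrads = "fig_tetrad_means.png")
  for (nm in names(figs)) {
    f <- file.path(outdir, figs[[nm]])
    p <- switch(nm, heteroplasmy = p1, profiles = p2, tetrads = p3)
    suppressMessages(ggplot2::ggsave(f, p, width = 7, height = 5, dpi = 150))
    files <- c(files, f)
  }
  logStage("report", dir = outdir, files = length(files))
  invisible(files)
}

#' Human-readable run summary
#'
#' Aggregates an analysis into the headline numbers: heteroplasmy rate,
#' recombinant colonies per cross, tetrads deviating from 2:2, and
#' per-cross transmission bias with its exact binomial p-value.
#'
#' @param res a `TetradAnalysis`.
#' @return a character vector of summary lines (also printed).
#' @export
summarizeRun <- function(res) {
  stopifnot(inherits(res, "TetradAnalysis"))
  lines <- c(
    sprintf("calls with minor observation fraction > %g%%: %.1f%% (%d of %d)",
            100 * res$params$het_threshold,
            100 * res$heteroplasmy$fraction_above_threshold,
            res$heteroplasmy$n_above, res$heteroplasmy$n_evaluable),
    sprintf("tetrads deviating from 2:2 segregation: %d of %d",
            sum(res$tetrads$deviates_2_2, na.rm = TRUE), nrow(res$tetrads)))
  for (i in seq_len(nrow(res$crosses))) {
    cr <- res$crosses[i, ]
    lines <- c(lines, sprintf(
      "%s: %d spores, %d recombinant; %.0f%% from parent1 (binomial p = %.3g)",
      cr$cross_id, cr$n_spores_analyzed, cr$n_recombinant,
      100 * cr$fraction_from_parent1, cr$binomial_p_two_sided))
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
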