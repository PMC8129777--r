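#' Site and call quality-filter parameters
#'
#' Bundles the post-call filters applied before any inheritance analysis:
#' only biallelic SNPs are kept; sites with phred-scaled quality below
#' `min_qual`, sites within `snp_gap_bp` of an indel record, and sites where
#' more than `max_missing_fraction` of the samples are uncalled are dropped.
#' Per-call masking re-expresses the caller's minimum-evidence settings
#' post hoc: calls with total depth (RO + sum AO) below `min_call_depth`,
#' and alternate calls supported by fewer than `min_alt_obs` alternate
#' observations, are set to missing before the missingness test.
#'
#' @param min_qual phred site-quality threshold (default 30).
#' @param max_missing_fraction drop a site when the missing-call fraction
#'   strictly exceeds this (default 0.5; exactly half missing is retained).
#' @param snp_gap_bp drop SNPs whose position lies within this distance
#'   (inclusive) of any base spanned by an indel's reference allele
#'   (default 3, mirroring `bcftools filter --SnpGap 3`).
#' @param min_call_depth per-call minimum RO + sum(AO) (default 3).
#' @param min_alt_obs minimum alternate observations supporting an
#'   alternate call (default 3).
#' @return a `FilterParams` list.
#' @export
filterParams <- function(min_qual = 30, max_missing_fraction = 0.5,
                         snp_gap_bp = 3, min_call_depth = 3,
                         min_alt_obs = 3) {
  p <- list(min_qual = min_qual,
            max_missing_fraction = max_missing_fraction,
            snp_gap_bp = snp_gap_bp,
            min_call_depth = min_call_depth,
            min_alt_obs = min_alt_obs)
  if (any(unlist(p) < 0)) stop("all filter thresholds must be >= 0")
  structure(p, class = "FilterParams")
}

#' Apply site and call quality filters
#'
#' Masks low-evidence calls, then drops sites failing the retention rules
#' (see [filterParams()]). Each dropped site is recorded with exactly one
#' primary rejection reason, the first failing rule in the fixed order
#' `not-SNP`, `multiallelic`, `qual`, `snp-gap`, `missingness`, so the
#' rejection table is deterministic. Indel proximity is measured from the
#' SNP position to the nearest position spanned by the indel's reference
#' allele, inclusive. The operation is idempotent.
#'
#' @param x a [MitoTetradExperiment] sorted by position.
#' @param params a [filterParams()] list.
#' @return the filtered experiment; the rejection table (`contig`, `pos`,
#'   `reason`) is stored in `metadata()$rejectedSites` and available via
#'   [rejectedSites()].
#' @export
filterSites <- function(x, params = filterParams()) {
  stopifnot(methods::is(x, "MitoTetradExperiment"),
            inherits(params, "FilterParams"))
  gt <- calledAllele(x); ro <- roCounts(x); ao <- aoCounts(x)
  ao_sum <- matrix(vapply(ao, function(v) sum(v, na.rm = TRUE), integer(1)),
                   nrow = nrow(ao))
  depth <- ro + ao_sum
  gt[depth < params$min_call_depth] <- NA_integer_
  # alternate calls need min_alt_obs supporting observations
  if (nrow(x) && ncol(x)) {
    alt_called <- !is.na(gt) & gt > 0L
    if (any(alt_called)) {
      idx <- which(alt_called)
      supp <- vapply(idx, function(i) {
        v <- ao[[i]]
        k <- gt[[i]]
        if (k <= length(v)) as.integer(v[k]) else 0L
      }, integer(1))
      gt[idx[supp < params$min_alt_obs]] <- NA_integer_
    }
  }

  rd <- rowData(x)
  rr <- rowRanges(x)
  pos <- GenomicRanges::start(rr)
  ctg <- as.character(seqnames(rr))
  is_indel <- rd$varClass == "indel"

  reason <- rep(NA_character_, nrow(x))
  reason[rd$varClass != "SNP"] <- "not-SNP"
  multi <- is.na(reason) & lengths(rd$alt) > 1L
  reason[multi] <- "multiallelic"
  lowq <- is.na(reason) & (is.na(rd$qual) | rd$qual < params$min_qual)
  reason[lowq] <- "qual"
  if (any(is_indel)) {
    ind <- GRanges(ctg[is_indel],
                   IRanges::IRanges(pos[is_indel],
                                    pos[is_indel] + nchar(rd$ref[is_indel]) - 1L))
    cand <- which(is.na(reason))
    if (length(cand)) {
      # inclusive distance <= gap  <=>  indel span intersects pos +/- gap
      win <- GRanges(ctg[cand],
                     IRanges::IRanges(pmax(1L, pos[cand] - params$snp_gap_bp),
                                      pos[cand] + params$snp_gap_bp))
      hit <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(win, ind)))
      reason[cand[hit]] <- "snp-gap"
    }
  }
  if (ncol(x)) {
    miss_frac <- rowMeans(is.na(gt))
    reason[is.na(reason) & miss_frac > params$max_missing_fraction] <- "missingness"
  }

  keep <- is.na(reason)
  rej <- data.frame(contig = ctg[!keep], pos = pos[!keep],
                    reason = reason[!keep], stringsAsFactors = FALSE)
  out <- x[keep, ]
  SummarizedExperiment::assay(out, "GT") <- gt[keep, , drop = FALSE]
  metadata(out)$rejectedSites <- rej
  metadata(out)$filterParams <- params
  logStage("filter_sites", retained = sum(keep), rejected = sum(!keep))
  out
}
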