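#' Parent-1 observation fraction at a marker
#'
#' The fraction of sequencing observations assigned to the cross's parent 1
#' at one marker site: observations of the parent-1 allele divided by the
#' observations assigned to either parental allele (RO + AO at a biallelic
#' marker; reads supporting neither allele never enter RO/AO and are thereby
#' excluded from the denominator). `NA` when the denominator is zero.
#'
#' @param ro,ao reference / alternate observation counts (vectorized).
#' @param parent1_allele `"reference"` or `"alternate"` per element.
#' @return numeric vector of fractions in `[0, 1]`, `NA` where depth is 0.
#' @export
parent1Fraction <- function(ro, ao, parent1_allele) {
  if (!all(parent1_allele %in% c("reference", "alternate")))
    stop("marker orientation must be 'reference' or 'alternate' ",
         "(marker not defined for this cross?)")
  den <- ro + ao
  num <- ifelse(parent1_allele == "reference", ro, ao)
  ifelse(den > 0, num / den, NA_real_)
}

#' Minor observation fraction of a call (heteroplasmy quantification)
#'
#' For a called site, the observation fraction of the allele *not* called:
#' `AO/(AO+RO)` for reference-allele calls and `RO/(AO+RO)` for
#' alternate-allele calls. A value of 0 indicates a pure call; values near
#' 0.5 indicate both alleles equally abundant in the colony.
#'
#' @param ro,ao observation counts (vectorized).
#' @param called integer called allele (0 reference, 1 alternate, `NA`
#'   missing).
#' @return numeric vector in `[0, 1]`.
#' @export
minorObservationFraction <- function(ro, ao, called) {
  if (any(is.na(called)))
    stop("uncallable: minor observation fraction requires a non-missing call")
  den <- ro + ao
  if (any(den == 0))
    stop("uncallable: zero observations at a called site")
  ifelse(called == 0L, ao / den, ro / den)
}

#' Per-spore parent-1 fraction profiles across markers
#'
#' Builds the long table of parent-1 observation fractions for every
#' non-excluded spore colony at every marker site of its cross, ordered by
#' genomic position. Fractions are `NA` where the underlying call is
#' missing or no informative observations exist.
#'
#' @param x a filtered [MitoTetradExperiment] with metadata attached.
#' @param markers marker table from [deriveMarkers()].
#' @param include_excluded keep excluded spores (default `FALSE`).
#' @return a `data.frame`: `sample_id`, `cross_id`, `tetrad_id`,
#'   `spore_index`, `contig`, `pos`, `called_allele`, `ro`, `ao`,
#'   `informative_obs`, `parent1_fraction`, `minor_fraction`.
#' @export
fractionProfiles <- function(x, markers, include_excluded = FALSE) {
  cd <- colData(x)
  rr <- rowRanges(x)
  key <- paste(as.character(seqnames(rr)), GenomicRanges::start(rr))
  gt <- calledAllele(x); ro <- roCounts(x); ao <- altObsCounts(x)
  spores <- which(cd$role == "spore" &
                    (include_excluded | !cd$excluded))
  out <- vector("list", length(spores))
  for (j in seq_along(spores)) {
    s <- spores[j]
    cid <- cd$strain_or_cross[s]
    mk <- markers[markers$cross_id == cid, , drop = FALSE]
    mk <- mk[order(mk$contig, mk$pos), , drop = FALSE]
    row_ix <- match(paste(mk$contig, mk$pos), key)
    ok <- !is.na(row_ix)
    mk <- mk[ok, , drop = FALSE]; row_ix <- row_ix[ok]
    r <- ro[row_ix, s]; a <- ao[row_ix, s]; g <- gt[row_ix, s]
    inf <- r + a
    f <- parent1Fraction(r, a, mk$parent1_allele)
    f[is.na(g)] <- NA_real_
    out[[j]] <- data.frame(
      sample_id = colnames(x)[s], cross_id = cid,
      tetrad_id = cd$tetrad_id[s], spore_index = cd$spore_index[s],
      contig = mk$contig, pos = mk$pos,
      called_allele = alleleLabel(g), ro = r, ao = a,
      informative_obs = inf,
      parent1_fraction = f,
      minor_fraction = pmin(f, 1 - f),
      stringsAsFactors = FALSE)
  }
  df <- if (length(out)) do.call(rbind, out) else
    data.frame(sample_id = character(), cross_id = character(),
               tetrad_id = character(), spore_index = integer(),
               contig = character(), pos = integer(),
               called_allele = character(), ro = integer(), ao = integer(),
               informative_obs = integer(), parent1_fraction = numeric(),
               minor_fraction = numeric())
  rownames(df) <- NULL
  df
}

#' Summarize heteroplasmy across all spore calls at marker sites
#'
#' Computes each evaluable call's minor observation fraction (see
#' [minorObservationFraction()]) and the overall fraction of calls whose
#' minor fraction *strictly* exceeds `threshold` — the headline
#' "calls showing alternate observation fractions above 5%" statistic.
#' Evaluable calls are those of non-excluded spores at marker sites of
#' their cross with a non-missing call and non-zero depth.
#'
#' @param x a filtered [MitoTetradExperiment] with metadata attached.
#' @param markers marker table from [deriveMarkers()].
#' @param threshold minor-fraction threshold (default 0.05).
#' @return a list: `calls` (per-call table with `minor_obs_fraction`),
#'   `n_evaluable`, `n_above`, `fraction_above_threshold`.
#' @export
heteroplasmySummary <- function(x, markers, threshold = 0.05) {
  prof <- fractionProfiles(x, markers)
  ev <- prof[prof$called_allele %in% c("reference", "alternate") &
               prof$informative_obs > 0, , drop = FALSE]
  if (!nrow(ev)) stop("no evaluable calls for heteroplasmy quantification")
  called <- ifelse(ev$called_allele == "reference", 0L, 1L)
  ev$minor_obs_fraction <- minorObservationFraction(ev$ro, ev$ao, called)
  n_above <- sum(ev$minor_obs_fraction > threshold)
  res <- list(calls = ev, n_evaluable = nrow(ev), n_above = n_above,
              fraction_above_threshold = n_above / nrow(ev))
  logStage("heteroplasmy", evaluable = nrow(ev), above = n_above,
           fraction = sprintf("%.4f", res$fraction_above_threshold))
  res
}

#' Classify a spore colony as recombinant
#'
#' A colony is recombinant when the parent that is overall in the minority
#' still contributes more than `maf_threshold` of the observations at one
#' or more marker sites. Under the default sample-level rule the colony's
#' major parent is the one with the larger mean parent-1 fraction across
#' non-missing markers (ties resolve to parent 1, with a message), and the
#' evidence sites are those where the *other* parent's fraction strictly
#' exceeds the threshold — so a clean crossover colony (fractions 1,1,0,0)
#' is recombinant. The per-site rule (`rule = "site"`) instead requires
#' `min(f, 1-f) > maf_threshold` at some site, i.e. within-site mixing, and
#' is exposed for sensitivity analysis.
#'
#' @param fractions numeric parent-1 fractions at the ordered markers
#'   (`NA` = missing).
#' @param positions marker positions (same length).
#' @param maf_threshold minor-parent fraction threshold (default 0.10,
#'   strict).
#' @param rule `"sample"` (default) or `"site"`.
#' @return a list: `is_recombinant`, `major_parent` (`"parent1"` or
#'   `"parent2"`), `evidence_pos` (positions supporting the call).
#' @export
classifyRecombinant <- function(fractions, positions = seq_along(fractions),
                                maf_threshold = 0.10,
                                rule = c("sample", "site")) {
  rule <- match.arg(rule)
  ok <- !is.na(fractions)
  if (!any(ok)) stop("uninformative sample: all marker fractions missing")
  f <- fractions[ok]; p <- positions[ok]
  m <- mean(f)
  if (m == 0.5) message("mean fraction exactly 0.5; major parent set to parent1")
  major <- if (m >= 0.5) "parent1" else "parent2"
  minor_frac <- if (rule == "sample") {
    if (major == "parent1") 1 - f else f
  } else pmin(f, 1 - f)
  hit <- minor_frac > maf_threshold
  list(is_recombinant = any(hit), major_parent = major,
       evidence_pos = p[hit])
}

#' Classify every spore colony in a profile table
#'
#' Applies [classifyRecombinant()] per colony; colonies with no informative
#' markers are returned with `NA` and a warning.
#'
#' @param profiles table from [fractionProfiles()].
#' @inheritParams classifyRecombinant
#' @return a `data.frame`: `sample_id`, `cross_id`, `tetrad_id`,
#'   `is_recombinant`, `major_parent`, `n_evidence_sites`.
#' @export
classifyRecombinants <- function(profiles, maf_threshold = 0.10,
                                 rule = c("sample", "site")) {
  rule <- match.arg(rule)
  ids <- unique(profiles$sample_id)
  res <- lapply(ids, function(id) {
    pr <- profiles[profiles$sample_id == id, , drop = FALSE]
    if (!any(!is.na(pr$parent1_fraction))) {
      warning("sample ", id, " has no informative markers; skipped")
      return(data.frame(sample_id = id, cross_id = pr$cross_id[1],
                        tetrad_id = pr$tetrad_id[1],
                        is_recombinant = NA, major_parent = NA_character_,
                        n_evidence_sites = NA_integer_))
    }
    cl <- classifyRecombinant(pr$parent1_fraction, pr$pos,
                              maf_threshold, rule)
    data.frame(sample_id = id, cross_id = pr$cross_id[1],
               tetrad_id = pr$tetrad_id[1],
               is_recombinant = cl$is_recombinant,
               major_parent = cl$major_parent,
               n_evidence_sites = length(cl$evidence_pos))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Crossover breakpoint intervals along a fraction profile
#'
#' Hard-assigns each marker to parent 1 when its fraction strictly exceeds
#' `hard_cutoff` and to parent 2 when strictly below (exactly at the cutoff
#' the marker is unassigned and skipped). A breakpoint is reported between
#' each pair of consecutive *assigned* markers with different parents; the
#' interval endpoints are the flanking marker positions.
#'
#' @param fractions numeric parent-1 fractions at ordered markers.
#' @param positions marker positions (increasing).
#' @param hard_cutoff assignment cutoff (default 0.5).
#' @return a `data.frame` of intervals (`start_pos`, `end_pos`); zero rows
#'   when no breakpoint. Fewer than two assigned markers yields zero rows
#'   with a warning.
#' @export
countCrossovers <- function(fractions, positions = seq_along(fractions),
                            hard_cutoff = 0.5) {
  ok <- !is.na(fractions) & fractions != hard_cutoff
  f <- fractions[ok]; p <- positions[ok]
  empty <- data.frame(start_pos = numeric(), end_pos = numeric())
  if (length(f) < 2L) {
    warning("fewer than two assigned markers; no crossover call possible")
    return(empty)
  }
  par <- f > hard_cutoff                        # TRUE = parent1
  sw <- which(par[-1] != par[-length(par)])
  if (!length(sw)) return(empty)
  data.frame(start_pos = p[sw], end_pos = p[sw + 1L])
}
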