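#' Derive parental marker orientations per cross
#'
#' A retained biallelic SNP becomes a marker for a cross when the cross's
#' two parental controls are both confidently called for *different*
#' alleles. Confidence requires the control's major-allele observation
#' fraction to reach `purity` (parents are expected to be homoplasmic;
#' lower purity suggests contamination and the site is skipped for that
#' cross with a warning). Sites at which the two parents carry the same
#' allele are non-segregating for that cross and yield no marker; a site
#' may be a marker in some crosses and not others. Multiple controls of the
#' same strain are pooled by summing their observation counts.
#'
#' @param x a filtered [MitoTetradExperiment] (see [filterSites()]) with
#'   cross design metadata attached.
#' @param purity minimum major-allele observation fraction for a parental
#'   control call to fix the marker orientation (default 0.95).
#' @return a `data.frame` with one row per (cross, marker site):
#'   `cross_id`, `contig`, `pos`, `ref`, `alt`, `parent1_allele`
#'   (`"reference"` or `"alternate"`) and `parent2_allele` (the other).
#' @export
deriveMarkers <- function(x, purity = 0.95) {
  crosses <- crossDesign(x)
  if (is.null(crosses) || !nrow(crosses))
    stop("no cross design attached; see addSampleMetadata()")
  keep <- rowData(x)$varClass == "SNP" & lengths(rowData(x)$alt) == 1L
  xs <- x[keep, ]
  rr <- rowRanges(xs)
  ro <- roCounts(xs); ao <- altObsCounts(xs)
  role <- sampleRole(xs)
  strain <- colData(xs)$strain_or_cross

  # pooled counts per parental strain
  strainCounts <- function(s) {
    cols <- which(role == "parent" & strain == s)
    if (!length(cols)) return(NULL)
    list(ro = rowSums(ro[, cols, drop = FALSE]),
         ao = rowSums(ao[, cols, drop = FALSE]))
  }
  # confident parental allele per site: "reference"/"alternate"/NA
  confAllele <- function(cnt) {
    dep <- cnt$ro + cnt$ao
    frac_major <- pmax(cnt$ro, cnt$ao) / dep
    allele <- ifelse(cnt$ro >= cnt$ao, "reference", "alternate")
    allele[dep == 0] <- NA
    impure <- dep > 0 & frac_major < purity
    list(allele = ifelse(impure, NA, allele), impure = impure,
         present = dep > 0)
  }

  out <- list()
  for (i in seq_len(nrow(crosses))) {
    cid <- crosses$cross_id[i]
    c1 <- strainCounts(crosses$parent1_strain[i])
    c2 <- strainCounts(crosses$parent2_strain[i])
    if (is.null(c1) || is.null(c2))
      stop("cross ", cid, " lacks a parental control sample")
    a1 <- confAllele(c1); a2 <- confAllele(c2)
    if (nrow(xs) && !any(a1$present & a2$present))
      stop("cross ", cid,
           ": parental controls uncalled at every retained site")
    n_impure <- sum((a1$impure | a2$impure), na.rm = TRUE)
    if (n_impure)
      warning("cross ", cid, ": ", n_impure, " site(s) skipped, parental ",
              "major-allele fraction below ", purity,
              " (possible contamination)")
    is_marker <- !is.na(a1$allele) & !is.na(a2$allele) &
      a1$allele != a2$allele
    if (any(is_marker)) {
      out[[cid]] <- data.frame(
        cross_id = cid,
        contig = as.character(seqnames(rr))[is_marker],
        pos = GenomicRanges::start(rr)[is_marker],
        ref = rowData(xs)$ref[is_marker],
        alt = vapply(rowData(xs)$alt[is_marker], `[`, character(1), 1L),
        parent1_allele = a1$allele[is_marker],
        parent2_allele = a2$allele[is_marker],
        stringsAsFactors = FALSE)
    }
  }
  mk <- if (length(out)) do.call(rbind, out) else
    data.frame(cross_id = character(), contig = character(),
               pos = integer(), ref = character(), alt = character(),
               parent1_allele = character(), parent2_allele = character())
  rownames(mk) <- NULL
  logStage("derive_markers", markers = nrow(mk),
           distinct_sites = length(unique(mk$pos)))
  mk
}

#' Flag self-mated tetrads from nuclear marker calls
#'
#' In a genuine cross every spore's nuclear genome is a recombinant of both
#' parents, so nuclear marker calls split between them. A tetrad is flagged
#' as self-mated when, across all its spores and all informative nuclear
#' marker sites with non-missing calls, every call matches the same single
#' parent. The test requires at least `min_informative` such calls;
#' tetrads with fewer are left unflagged with a warning. Flagged tetrads'
#' spores are marked `excluded = TRUE` with reason `"self-mating"`.
#'
#' @param x a [MitoTetradExperiment] containing the *nuclear* (and possibly
#'   mitochondrial) sites of all samples, with metadata attached.
#' @param nuclearMarkers a marker table from [deriveMarkers()] computed on
#'   the nuclear contigs.
#' @param min_informative minimum number of informative non-missing spore
#'   calls per tetrad (default 10).
#' @return `x` with updated exclusions; the per-tetrad flag table is stored
#'   in `metadata(x)$selfMating` (`tetrad_id`, `cross_id`,
#'   `n_informative_calls`, `self_mated`).
#' @export
flagSelfMating <- function(x, nuclearMarkers, min_informative = 10) {
  cd <- colData(x)
  gt <- calledAllele(x)
  rr <- rowRanges(x)
  key <- paste(as.character(seqnames(rr)), GenomicRanges::start(rr))
  spores <- which(cd$role == "spore")
  tetrads <- unique(data.frame(tetrad_id = cd$tetrad_id[spores],
                               cross_id = cd$strain_or_cross[spores],
                               stringsAsFactors = FALSE))
  res <- vector("list", nrow(tetrads))
  for (i in seq_len(nrow(tetrads))) {
    tid <- tetrads$tetrad_id[i]; cid <- tetrads$cross_id[i]
    mk <- nuclearMarkers[nuclearMarkers$cross_id == cid, , drop = FALSE]
    row_ix <- match(paste(mk$contig, mk$pos), key)
    ok <- !is.na(row_ix)
    mk <- mk[ok, , drop = FALSE]; row_ix <- row_ix[ok]
    cols <- spores[cd$tetrad_id[spores] == tid]
    calls <- gt[row_ix, cols, drop = FALSE]          # 0 ref / 1 alt / NA
    # map each call to the matching parent
    p1_is_alt <- mk$parent1_allele == "alternate"
    from_p1 <- sweep(calls == 1L, 1L, p1_is_alt, `==`)
    from_p1[is.na(calls)] <- NA
    n_inf <- sum(!is.na(from_p1))
    if (n_inf < min_informative) {
      warning("tetrad ", tid, ": only ", n_inf,
              " informative nuclear calls (need ", min_informative,
              "); self-mating left unassessed")
      flag <- FALSE
    } else {
      v <- from_p1[!is.na(from_p1)]
      flag <- all(v) || all(!v)
    }
    res[[i]] <- data.frame(tetrad_id = tid, cross_id = cid,
                           n_informative_calls = n_inf, self_mated = flag,
                           stringsAsFactors = FALSE)
  }
  flags <- do.call(rbind, res)
  if (is.null(flags))
    flags <- data.frame(tetrad_id = character(), cross_id = character(),
                        n_informative_calls = integer(),
                        self_mated = logical())
  bad <- flags$tetrad_id[flags$self_mated]
  if (length(bad)) {
    hit <- cd$role == "spore" & cd$tetrad_id %in% bad
    cd$excluded[hit] <- TRUE
    cd$exclusion_reason[hit] <- "self-mating"
    colData(x) <- cd
  }
  metadata(x)$selfMating <- flags
  logStage("flag_self_mating", tetrads = nrow(flags),
           flagged = sum(flags$self_mated))
  x
}
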