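#' Read a multi-sample VCF of tetrad genotype calls
#'
#' Parses a VCF 4.x (plain or bgzipped) whose per-sample FORMAT carries the
#' freebayes-style `GT`, `RO` (reference observation count) and `AO`
#' (alternate observation counts, one per alternate allele) fields, as
#' produced by haploid variant calling on pooled colony sequencing. Records
#' are returned sorted by (contig, position); multi-allelic records are kept
#' (site filtering, not I/O, owns the biallelic rule — see [filterSites()]).
#'
#' @param path path to the VCF file.
#' @param contig optional contig name; when given, only that contig's
#'   records are returned (e.g. `"MT"` for the mitochondrial genome).
#' @return a [MitoTetradExperiment] with placeholder colony metadata; attach
#'   the real metadata with [addSampleMetadata()].
#' @examples
#' sim <- emitDataset(simConfig(n_tetrads = 1), tempfile("simdir"))
#' x <- readTetradVcf(sim$vcf)
#' x
#' @export
readTetradVcf <- function(path, contig = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  have <- rownames(VariantAnnotation::geno(VariantAnnotation::header(vcf)))
  for (f in c("GT", "RO", "AO"))
    if (!f %in% have)
      stop(sprintf("VCF FORMAT lacks the required '%s' field", f))
  rr <- rowRanges(vcf)
  refs <- as.character(VariantAnnotation::ref(vcf))
  alts <- VariantAnnotation::alt(vcf)
  alts <- lapply(seq_along(alts), function(i) as.character(alts[[i]]))
  g <- VariantAnnotation::geno(vcf)

  gt_raw <- g$GT
  gt <- matrix(NA_integer_, nrow(gt_raw), ncol(gt_raw),
               dimnames = dimnames(gt_raw))
  tok <- sub("[/|].*$", "", gt_raw)             # haploid calls; keep 1st allele
  ok <- !is.na(tok) & tok != "." & tok != ""
  gt[ok] <- as.integer(tok[ok])

  ro <- g$RO
  storage.mode(ro) <- "integer"
  ao <- g$AO
  if (!is.list(ao)) {                           # single-alt-only VCFs parse flat
    ao <- matrix(lapply(seq_along(ao), function(i) as.integer(ao[[i]])),
                 nrow = nrow(ro), dimnames = dimnames(ro))
  } else {
    ao <- matrix(lapply(ao, function(v) as.integer(v)),
                 nrow = nrow(ro), dimnames = dimnames(ro))
  }
  ro[is.na(ro)] <- 0L
  ao[] <- lapply(ao, function(v) { v[is.na(v)] <- 0L; v })

  sites <- GRanges(seqnames = seqnames(rr), ranges = IRanges::ranges(rr))
  mcols(sites) <- S4Vectors::DataFrame(
    ref = refs,
    alt = methods::as(alts, "CharacterList"),
    qual = as.numeric(VariantAnnotation::qual(vcf)),
    varClass = vapply(seq_along(refs),
                      function(i) classifyVariant(refs[i], alts[[i]]),
                      character(1)))
  names(sites) <- NULL
  dimnames(gt) <- dimnames(ro) <- dimnames(ao) <-
    list(NULL, colnames(gt_raw))

  x <- MitoTetradExperiment(sites, gt, ro, ao)
  if (!is.null(contig)) {
    keep <- as.character(seqnames(rowRanges(x))) == contig
    x <- x[keep, ]
  }
  # "sorted" means the VCF's own (header) contig order, then position
  lev <- GenomeInfoDb::seqlevels(rowRanges(x))
  o <- order(match(as.character(seqnames(rowRanges(x))), lev),
             GenomicRanges::start(rowRanges(x)))
  if (any(o != seq_along(o))) {
    warning("VCF records were not sorted by (contig, pos); sorting")
    x <- x[o, ]
  }
  logStage("read_vcf", file = basename(path), sites = nrow(x),
           samples = ncol(x))
  x
}

#' Read the colony metadata table
#'
#' Reads a tab-separated table describing every sequenced colony. Required
#' columns: `sample_id`, `role` (`parent` or `spore`), `strain_or_cross`
#' (parental strain name for controls, cross identifier for spores),
#' `tetrad_id` and `spore_index` (spores only), `parent1` and `parent2`
#' (the cross's parental strains, on spore rows). The cross design table is
#' deduplicated from the spore rows.
#'
#' @param path path to the metadata TSV.
#' @return a list with `samples` (a `DataFrame`, one row per colony) and
#'   `crosses` (a `data.frame` with `cross_id`, `parent1_strain`,
#'   `parent2_strain`).
#' @export
readSampleMetadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  tb <- utils::read.delim(path, colClasses = "character")
  req <- c("sample_id", "role", "strain_or_cross", "tetrad_id", "spore_index")
  miss <- setdiff(req, colnames(tb))
  if (length(miss))
    stop("metadata lacks required column(s): ", paste(miss, collapse = ", "))
  tb[tb == ""] <- NA
  sp <- tb$role == "spore"
  if (any(sp & (is.na(tb$strain_or_cross) | is.na(tb$tetrad_id))))
    stop("every spore row needs a cross identifier and a tetrad_id")
  key <- paste(tb$tetrad_id[sp], tb$spore_index[sp])
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)]
    stop("duplicate (tetrad_id, spore_index): ", paste(unique(d), collapse = "; "))
  }
  samples <- S4Vectors::DataFrame(
    role = tb$role,
    strain_or_cross = tb$strain_or_cross,
    tetrad_id = tb$tetrad_id,
    spore_index = suppressWarnings(as.integer(tb$spore_index)),
    excluded = FALSE,
    exclusion_reason = NA_character_,
    row.names = tb$sample_id)
  crosses <- NULL
  if (all(c("parent1", "parent2") %in% colnames(tb))) {
    cr <- unique(tb[sp, c("strain_or_cross", "parent1", "parent2")])
    cr <- cr[!is.na(cr$parent1) & !is.na(cr$parent2), , drop = FALSE]
    crosses <- data.frame(cross_id = cr$strain_or_cross,
                          parent1_strain = cr$parent1,
                          parent2_strain = cr$parent2,
                          stringsAsFactors = FALSE)
    if (any(crosses$parent1_strain == crosses$parent2_strain))
      stop("a cross must have two distinct parental strains")
    if (anyDuplicated(crosses$cross_id))
      stop("conflicting parental strains listed for the same cross")
  }
  logStage("read_metadata", samples = nrow(samples),
           crosses = if (is.null(crosses)) 0L else nrow(crosses))
  list(samples = samples, crosses = crosses)
}

#' Attach colony metadata to a genotype experiment
#'
#' Joins the metadata read by [readSampleMetadata()] onto the VCF samples.
#' Every metadata sample must exist in the VCF; VCF samples without metadata
#' are dropped with a warning (e.g. extra controls). Each cross must have
#' both parental-control strains present among the VCF samples.
#'
#' @param x a [MitoTetradExperiment] from [readTetradVcf()].
#' @param meta the list returned by [readSampleMetadata()].
#' @return `x` with colony metadata in `colData` and the cross design in
#'   `metadata(x)$crosses`, columns ordered as in the metadata table.
#' @export
addSampleMetadata <- function(x, meta) {
  samples <- meta$samples
  orphans <- setdiff(rownames(samples), colnames(x))
  if (length(orphans))
    stop("metadata names sample(s) absent from the VCF: ",
         paste(orphans, collapse = ", "))
  extra <- setdiff(colnames(x), rownames(samples))
  if (length(extra)) {
    warning("dropping ", length(extra), " VCF sample(s) without metadata: ",
            paste(extra, collapse = ", "))
    x <- x[, setdiff(colnames(x), extra)]
  }
  x <- x[, rownames(samples)]
  colData(x) <- samples
  crosses <- meta$crosses
  if (!is.null(crosses)) {
    pstrain <- samples$strain_or_cross[samples$role == "parent"]
    for (i in seq_len(nrow(crosses))) {
      p <- c(crosses$parent1_strain[i], crosses$parent2_strain[i])
      if (!all(p %in% pstrain))
        stop("cross ", crosses$cross_id[i],
             " has no parental control in the VCF for strain(s): ",
             paste(setdiff(p, pstrain), collapse = ", "))
    }
    metadata(x)$crosses <- crosses
  }
  methods::validObject(x)
  x
}

alleleLabel <- function(k) {
  ifelse(is.na(k), "missing",
         ifelse(k == 0L, "reference",
                ifelse(k == 1L, "alternate", paste0("alternate", k))))
}

#' Long-format genotype-call table
#'
#' One row per (site, sample): `contig`, `pos`, `ref`, `alt` (comma-joined
#' for multi-allelic sites), `qual`, `sample_id`, `called_allele`
#' (`reference`/`alternate`/`alternate<k>`/`missing`), `ro`, `ao`
#' (comma-joined per alternate allele).
#'
#' @param x a [MitoTetradExperiment].
#' @return a `data.frame` in site-major order.
#' @export
genotypeTable <- function(x) {
  rr <- rowRanges(x)
  n_site <- nrow(x); n_samp <- ncol(x)
  gt <- calledAllele(x); ro <- roCounts(x); ao <- aoCounts(x)
  site_ix <- rep(seq_len(n_site), times = n_samp)
  samp_ix <- rep(seq_len(n_samp), each = n_site)
  data.frame(
    contig = as.character(seqnames(rr))[site_ix],
    pos = GenomicRanges::start(rr)[site_ix],
    ref = rowData(x)$ref[site_ix],
    alt = vapply(rowData(x)$alt, paste, character(1), collapse = ",")[site_ix],
    qual = rowData(x)$qual[site_ix],
    sample_id = colnames(x)[samp_ix],
    called_allele = alleleLabel(as.vector(gt)),
    ro = as.vector(ro),
    ao = vapply(as.vector(ao), paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)
}

#' Write the genotype-call table to a TSV file
#'
#' Writes [genotypeTable()] output as a tab-separated file; byte-stable for
#' identical input. An experiment with zero sites yields a header-only file.
#'
#' @param x a [MitoTetradExperiment].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeGenotypeTable <- function(x, path) {
  writeTsv(genotypeTable(x), path)
  logStage("write_genotype_table", file = basename(path),
           rows = nrow(x) * ncol(x))
  invisible(path)
}
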