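#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges
#'   rowData colData colData<-
#' @importFrom GenomicRanges GRanges
#' @importFrom GenomeInfoDb seqnames
#' @importFrom IRanges IRanges
NULL

#' Container for multi-sample tetrad genotype calls
#'
#' `MitoTetradExperiment` extends `RangedSummarizedExperiment`: rows are
#' variant sites (with `ref`, `alt`, `qual` and `varClass` row metadata, the
#' range spanning the reference allele), columns are sequenced colonies
#' (parental controls and spore colonies), and three assays hold the
#' per-sample genotype calls:
#'
#' * `GT` — integer called-allele index: `0` reference, `k` the k-th
#'   alternate allele, `NA` missing;
#' * `RO` — integer reference observation counts;
#' * `AO` — a list-matrix of integer vectors, one alternate observation
#'   count per alternate allele (multi-allelic sites are kept at I/O level
#'   and removed by [filterSites()]).
#'
#' `colData` carries the colony metadata (`role`, `strain_or_cross`,
#' `tetrad_id`, `spore_index`, `excluded`, `exclusion_reason`) and
#' `metadata(x)$crosses` the cross design table
#' (`cross_id`, `parent1_strain`, `parent2_strain`).
#'
#' @seealso [readTetradVcf()], [readSampleMetadata()],
#'   [addSampleMetadata()], [filterSites()]
#' @export
setClass("MitoTetradExperiment",
         contains = "RangedSummarizedExperiment")

.required_coldata <- c("role", "strain_or_cross", "tetrad_id",
                       "spore_index", "excluded", "exclusion_reason")

setValidity("MitoTetradExperiment", function(object) {
  msgs <- character()
  an <- SummarizedExperiment::assayNames(object)
  for (a in c("GT", "RO", "AO"))
    if (!a %in% an) msgs <- c(msgs, sprintf("assay '%s' is required", a))
  rd <- rowData(object)
  for (f in c("ref", "alt", "qual", "varClass"))
    if (!f %in% colnames(rd)) msgs <- c(msgs, sprintf("rowData column '%s' is required", f))
  cd <- colData(object)
  for (f in .required_coldata)
    if (!f %in% colnames(cd)) msgs <- c(msgs, sprintf("colData column '%s' is required", f))
  if (!length(msgs) && nrow(object)) {
    if (any(rd$qual < 0, na.rm = TRUE)) msgs <- c(msgs, "qual must be non-negative")
    if (any(!nzchar(rd$ref))) msgs <- c(msgs, "ref alleles must be non-empty")
    if (any(lengths(rd$alt) < 1)) msgs <- c(msgs, "each site needs at least one alt allele")
    ro <- assay(object, "RO")
    if (any(ro < 0, na.rm = TRUE)) msgs <- c(msgs, "RO counts must be non-negative")
  }
  if (!length(msgs) && ncol(object)) {
    sp <- !is.na(cd$role) & cd$role == "spore"
    if (any(sp & (is.na(cd$tetrad_id) | is.na(cd$strain_or_cross))))
      msgs <- c(msgs, "every spore needs a cross id and a tetrad_id")
    key <- paste(cd$tetrad_id[sp], cd$spore_index[sp])
    if (anyDuplicated(key))
      msgs <- c(msgs, "spore_index must be unique within a tetrad")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn MitoTetradExperiment construct from component parts
#'   (normally produced by [readTetradVcf()]).
#' @param rowRanges `GRanges` of variant sites with `ref`, `alt`, `qual`,
#'   `varClass` metadata columns.
#' @param GT,RO,AO genotype assays (see class description).
#' @param colData colony metadata `DataFrame`.
#' @param crosses cross design `data.frame` stored in `metadata()$crosses`.
#' @export
MitoTetradExperiment <- function(rowRanges, GT, RO, AO, colData = NULL,
                                 crosses = NULL) {
  if (is.null(colData)) {
    ids <- colnames(GT)
    colData <- S4Vectors::DataFrame(
      role = rep(NA_character_, length(ids)),
      strain_or_cross = NA_character_, tetrad_id = NA_character_,
      spore_index = NA_integer_, excluded = FALSE,
      exclusion_reason = NA_character_, row.names = ids)
  }
  se <- SummarizedExperiment(
    assays = list(GT = GT, RO = RO, AO = AO),
    rowRanges = rowRanges, colData = colData)
  x <- methods::new("MitoTetradExperiment", se)
  if (!is.null(crosses)) metadata(x)$crosses <- crosses
  x
}

setMethod("show", "MitoTetradExperiment", function(object) {
  cd <- colData(object)
  cat(sprintf("MitoTetradExperiment: %d sites x %d samples\n",
              nrow(object), ncol(object)))
  ctg <- table(as.character(seqnames(rowRanges(object))))
  if (length(ctg))
    cat("  contigs:", paste(sprintf("%s (%d)", names(ctg), ctg), collapse = ", "), "\n")
  if (ncol(object)) {
    cat(sprintf("  samples: %d parents, %d spores (%d excluded)\n",
                sum(cd$role == "parent", na.rm = TRUE),
                sum(cd$role == "spore", na.rm = TRUE),
                sum(cd$excluded, na.rm = TRUE)))
  }
  cr <- crossDesign(object)
  if (!is.null(cr) && nrow(cr))
    cat("  crosses:", paste(cr$cross_id, collapse = ", "), "\n")
  rej <- metadata(object)$rejectedSites
  if (!is.null(rej))
    cat(sprintf("  site filter applied: %d sites rejected\n", nrow(rej)))
  invisible(NULL)
})
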