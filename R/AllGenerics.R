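#' Accessors for MitoTetradExperiment components
#'
#' Small accessors that avoid direct slot/assay access in user code:
#' `calledAllele()` returns the integer called-allele matrix (`0` reference,
#' `k` the k-th alternate, `NA` missing), `roCounts()` the reference
#' observation counts, `aoCounts()` the per-alternate observation list-matrix,
#' `altObsCounts()` the first-alternate counts as a plain integer matrix
#' (biallelic shortcut), `sampleRole()`, `crossId()`, `tetradId()`,
#' `sporeIndex()` and `isExcluded()` the per-colony metadata columns,
#' `crossDesign()` the cross table, and `rejectedSites()` the site-filter
#' rejection table recorded by [filterSites()].
#'
#' @param x a [MitoTetradExperiment].
#' @return matrices, vectors or data.frames as described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("calledAllele", function(x) standardGeneric("calledAllele"))
#' @rdname accessors
#' @export
setGeneric("roCounts", function(x) standardGeneric("roCounts"))
#' @rdname accessors
#' @export
setGeneric("aoCounts", function(x) standardGeneric("aoCounts"))
#' @rdname accessors
#' @export
setGeneric("altObsCounts", function(x) standardGeneric("altObsCounts"))
#' @rdname accessors
#' @export
setGeneric("sampleRole", function(x) standardGeneric("sampleRole"))
#' @rdname accessors
#' @export
setGeneric("crossId", function(x) standardGeneric("crossId"))
#' @rdname accessors
#' @export
setGeneric("tetradId", function(x) standardGeneric("tetradId"))
#' @rdname accessors
#' @export
setGeneric("sporeIndex", function(x) standardGeneric("sporeIndex"))
#' @rdname accessors
#' @export
setGeneric("isExcluded", function(x) standardGeneric("isExcluded"))
#' @rdname accessors
#' @export
setGeneric("crossDesign", function(x) standardGeneric("crossDesign"))
#' @rdname accessors
#' @export
setGeneric("rejectedSites", function(x) standardGeneric("rejectedSites"))

#' @rdname accessors
setMethod("calledAllele", "MitoTetradExperiment",
          function(x) assay(x, "GT"))
#' @rdname accessors
setMethod("roCounts", "MitoTetradExperiment",
          function(x) assay(x, "RO"))
#' @rdname accessors
setMethod("aoCounts", "MitoTetradExperiment",
          function(x) assay(x, "AO"))
#' @rdname accessors
setMethod("altObsCounts", "MitoTetradExperiment", function(x) {
  ao <- assay(x, "AO")
  m <- matrix(vapply(ao, function(v) as.integer(v[1L]), integer(1)),
              nrow = nrow(ao), dimnames = dimnames(ao))
  m
})
#' @rdname accessors
setMethod("sampleRole", "MitoTetradExperiment",
          function(x) stats::setNames(colData(x)$role, colnames(x)))
#' @rdname accessors
setMethod("crossId", "MitoTetradExperiment", function(x) {
  cd <- colData(x)
  out <- ifelse(cd$role == "spore", cd$strain_or_cross, NA_character_)
  stats::setNames(out, colnames(x))
})
#' @rdname accessors
setMethod("tetradId", "MitoTetradExperiment",
          function(x) stats::setNames(colData(x)$tetrad_id, colnames(x)))
#' @rdname accessors
setMethod("sporeIndex", "MitoTetradExperiment",
          function(x) stats::setNames(colData(x)$spore_index, colnames(x)))
#' @rdname accessors
setMethod("isExcluded", "MitoTetradExperiment",
          function(x) stats::setNames(colData(x)$excluded, colnames(x)))
#' @rdname accessors
setMethod("crossDesign", "MitoTetradExperiment",
          function(x) metadata(x)$crosses)
#' @rdname accessors
setMethod("rejectedSites", "MitoTetradExperiment",
          function(x) metadata(x)$rejectedSites)
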