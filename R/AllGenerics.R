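#' Accessors for gastroPDX containers
#'
#' \code{variants()} returns the underlying per-variant data.frame of a
#' \linkS4class{VariantSet}; \code{nVariants()} its row count;
#' \code{variantKeys()} the canonical "chrom:pos:ref>alt" keys.
#' \code{cnGenes()} returns the per-gene table of a
#' \linkS4class{CopyNumberProfile}. \code{stages()}, \code{afMatrix()} and
#' \code{depthMatrix()} access a \linkS4class{PassageSeries};
#' \code{patients()} the per-patient table of a \linkS4class{CohortTable}.
#'
#' @param x the container object.
#' @return the slot content described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))
#' @rdname accessors
#' @export
setMethod("variants", "VariantSet", function(x) x@variants)

#' @rdname accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))
#' @rdname accessors
#' @export
setMethod("nVariants", "VariantSet", function(x) nrow(x@variants))

#' @rdname accessors
#' @export
setGeneric("variantKeys", function(x) standardGeneric("variantKeys"))
#' @rdname accessors
#' @export
setMethod("variantKeys", "VariantSet", function(x) {
  v <- x@variants
  if (nrow(v) == 0) return(character())
  paste0(v$chrom, ":", v$pos, ":", v$ref, ">", v$alt)
})

#' @rdname accessors
#' @export
setGeneric("cnGenes", function(x) standardGeneric("cnGenes"))
#' @rdname accessors
#' @export
setMethod("cnGenes", "CopyNumberProfile", function(x) x@genes)

#' @rdname accessors
#' @export
setGeneric("stages", function(x) standardGeneric("stages"))
#' @rdname accessors
#' @export
setMethod("stages", "PassageSeries", function(x) x@stages)

#' @rdname accessors
#' @export
setGeneric("afMatrix", function(x) standardGeneric("afMatrix"))
#' @rdname accessors
#' @export
setMethod("afMatrix", "PassageSeries", function(x) x@af)

#' @rdname accessors
#' @export
setGeneric("depthMatrix", function(x) standardGeneric("depthMatrix"))
#' @rdname accessors
#' @export
setMethod("depthMatrix", "PassageSeries", function(x) x@depth)

#' @rdname accessors
#' @export
setGeneric("patients", function(x) standardGeneric("patients"))
#' @rdname accessors
#' @export
setMethod("patients", "CohortTable", function(x) x@patients)
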