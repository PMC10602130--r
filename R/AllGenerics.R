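#' Subject identifiers of a data object
#' @param x a GenotypeMatrix or StructuredCovariance.
#' @return Character vector of subject ids, in object order.
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' Dosage matrix of a GenotypeMatrix
#' @param x a GenotypeMatrix.
#' @return Numeric subjects-by-markers matrix of counted-allele dosages.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' Marker metadata of a GenotypeMatrix
#' @param x a GenotypeMatrix.
#' @return data.frame with one row per marker.
#' @export
setGeneric("markerInfo", function(x) standardGeneric("markerInfo"))

#' Covariance matrix of a StructuredCovariance
#' @param x a StructuredCovariance.
#' @return The symmetric numeric matrix.
#' @export
setGeneric("covMatrix", function(x) standardGeneric("covMatrix"))

#' Kind tag of a StructuredCovariance
#' @param x a StructuredCovariance.
#' @return One of "grm", "mutation_sharing", "pedigree_kinship".
#' @export
setGeneric("covKind", function(x) standardGeneric("covKind"))

#' Variance components of a VCFit
#' @param x a VCFit.
#' @return Named numeric vector (structured components plus residual "e").
#' @export
setGeneric("varComponents", function(x) standardGeneric("varComponents"))

#' Fixed effects of a VCFit
#' @param x a VCFit.
#' @return Named numeric vector of GLS coefficient estimates.
#' @export
setGeneric("fixedEffects", function(x) standardGeneric("fixedEffects"))

#' @describeIn subjectIds subject ids of a GenotypeMatrix
#' @export
setMethod("subjectIds", "GenotypeMatrix", function(x) rownames(x@dosages))

#' @describeIn subjectIds subject ids of a StructuredCovariance
#' @export
setMethod("subjectIds", "StructuredCovariance", function(x) rownames(x@matrix))

#' @describeIn dosages accessor
#' @export
setMethod("dosages", "GenotypeMatrix", function(x) x@dosages)

#' @describeIn markerInfo accessor
#' @export
setMethod("markerInfo", "GenotypeMatrix", function(x) x@markers)

#' @describeIn covMatrix accessor
#' @export
setMethod("covMatrix", "StructuredCovariance", function(x) x@matrix)

#' @describeIn covKind accessor
#' @export
setMethod("covKind", "StructuredCovariance", function(x) x@kind)

#' @describeIn varComponents accessor
#' @export
setMethod("varComponents", "VCFit", function(x) x@sigma2)

#' @describeIn fixedEffects accessor
#' @export
setMethod("fixedEffects", "VCFit", function(x) x@beta)

setMethod("show", "GenotypeMatrix", function(object) {
  d <- object@dosages
  cat("GenotypeMatrix:", nrow(d), "subjects x", ncol(d), "markers\n")
  miss <- mean(is.na(d))
  cat(sprintf("  missing dosage rate: %.3f\n", miss))
  g <- object@markers$gene
  if (any(!is.na(g)))
    cat("  markers with gene assignment:", sum(!is.na(g)), "\n")
  invisible(NULL)
})

setMethod("show", "StructuredCovariance", function(object) {
  m <- object@matrix
  cat(sprintf("StructuredCovariance <%s>: %d x %d subjects\n",
              object@kind, nrow(m), ncol(m)))
  off <- m[upper.tri(m)]
  cat(sprintf("  diag mean %.4f; off-diag mean %.4f, range [%.4f, %.4f]\n",
              mean(diag(m)), mean(off), min(off), max(off)))
  invisible(NULL)
})

setMethod("show", "VCFit", function(object) {
  cat("VCFit (", if (object@converged) "converged" else "NOT converged",
      "), n = ", object@n, "\n", sep = "")
  s2 <- object@sigma2
  cat("  variance components:\n")
  for (nm in names(s2))
    cat(sprintf("    sigma2_%s = %.5f (%.1f%%)\n", nm, s2[nm],
                100 * s2[nm] / sum(s2)))
  cat(sprintf("  restricted logLik = %.4f; ML logLik = %.4f\n",
              object@loglikREML, object@loglikML))
  cat("  fixed effects:", paste(sprintf("%s=%.4f", names(object@beta),
                                        object@beta), collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "HeritabilityReport", function(object) {
  cat(sprintf("HeritabilityReport (%s scale%s)\n", object@scale,
              if (object@scale == "liability")
                sprintf(", prevalence %.3f", object@prevalence) else ""))
  cat(sprintf("  h2_g = %.4f (LRT p = %s)\n", object@h2_g,
              format(object@lrt_p_g, digits = 3)))
  cat(sprintf("  h2_m = %.4f (LRT p = %s)\n", object@h2_m,
              format(object@lrt_p_m, digits = 3)))
  cat(sprintf("  mutation share of total heritability = %.4f\n",
              object@mutation_share))
  invisible(NULL)
})
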