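#' Construct a CoarseModel
#'
#' Builds the three-sites-per-residue representation (Calpha, Cbeta except
#' glycine, backbone O) from coordinate matrices. This is the container every
#' metric and preparation step in the package operates on.
#'
#' @param resno integer vector of 1-based residue numbers, strictly increasing.
#' @param resid character vector of 3-letter residue codes (same length).
#' @param ca n x 3 matrix of Calpha coordinates (Angstrom).
#' @param cb n x 3 matrix of Cbeta coordinates; rows for glycine (or residues
#'   lacking the atom) must be NA. Default: all absent.
#' @param o n x 3 matrix of carbonyl-O coordinates; NA rows allowed.
#' @param bfac per-atom B factors (Angstrom^2): either a single number applied
#'   to every atom, a length-n vector applied residue-wise, or an n x 3 matrix
#'   with columns (ca, cb, o). Entries for absent atoms are ignored.
#' @param chain single chain identifier.
#' @param label free-text label.
#' @return A \linkS4class{CoarseModel}.
#' @examples
#' m <- CoarseModel(resno = 1:3, resid = c("ALA", "GLY", "SER"),
#'                  ca = matrix(rnorm(9), 3))
#' nResidues(m)
#' @export
CoarseModel <- function(resno, resid, ca, cb = NULL, o = NULL, bfac = 0,
                        chain = "A", label = "") {
  n <- length(resno)
  ca <- .as_coord_matrix(ca, n, "ca")
  cb <- if (is.null(cb)) matrix(NA_real_, n, 3L) else .as_coord_matrix(cb, n, "cb")
  o  <- if (is.null(o))  matrix(NA_real_, n, 3L) else .as_coord_matrix(o, n, "o")
  if (is.matrix(bfac)) {
    b <- bfac
  } else if (length(bfac) == 1L) {
    b <- matrix(bfac, n, 3L)
  } else if (length(bfac) == n) {
    b <- matrix(rep(bfac, 3L), n, 3L)
  } else {
    stop("'bfac' must be a scalar, a per-residue vector or an n x 3 matrix")
  }
  colnames(b) <- c("ca", "cb", "o")
  b[, 2L][.is_na_row(cb)] <- NA_real_
  b[, 3L][.is_na_row(o)] <- NA_real_
  new("CoarseModel", resno = as.integer(resno), resid = as.character(resid),
      chain = chain, ca = ca, cb = cb, o = o, bfac = b, label = label)
}

.as_coord_matrix <- function(m, n, what) {
  m <- as.matrix(m)
  if (nrow(m) != n || ncol(m) != 3L)
    stop(sprintf("'%s' must be a %d x 3 coordinate matrix", what, n))
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}

#' Construct a CoarseEnsemble
#'
#' @param frames list of \linkS4class{CoarseModel} sharing one residue roster.
#' @param energies optional numeric model energy per frame (model units);
#'   lower is better.
#' @param source free-text provenance.
#' @return A \linkS4class{CoarseEnsemble}.
#' @export
CoarseEnsemble <- function(frames, energies = numeric(0), source = "") {
  new("CoarseEnsemble", frames = frames, energies = as.numeric(energies),
      source = source)
}

#' Build an AlignmentMap from index pairs
#'
#' @param model integer residue numbers on the model side.
#' @param template integer residue numbers on the template side (same length).
#' @return An \linkS4class{AlignmentMap}.
#' @export
AlignmentMap <- function(model, template) {
  p <- cbind(model = as.integer(model), template = as.integer(template))
  new("AlignmentMap", pairs = p)
}

#' @describeIn AlignmentMap identity alignment over a model's full roster.
#' @param x a \linkS4class{CoarseModel}.
#' @export
fullAlignment <- function(x) {
  stopifnot(is(x, "CoarseModel"))
  AlignmentMap(residueIndices(x), residueIndices(x))
}

# ---- accessors ---------------------------------------------------------

#' Number of residues
#' @param x a CoarseModel (or object with a roster).
#' @return integer count.
#' @export
setMethod("nResidues", "CoarseModel", function(x) length(x@resno))

#' Roster and coordinate accessors
#'
#' @param x a \linkS4class{CoarseModel}.
#' @name accessors
#' @aliases residueIndices residueNames chainID caCoords cbCoords oCoords bFactors
NULL

#' @rdname accessors
#' @export
setMethod("residueIndices", "CoarseModel", function(x) x@resno)

#' @rdname accessors
#' @export
setMethod("residueNames", "CoarseModel", function(x) x@resid)

#' @rdname accessors
#' @export
setMethod("chainID", "CoarseModel", function(x) x@chain)

#' @rdname accessors
#' @export
setMethod("caCoords", "CoarseModel", function(x) x@ca)

#' @rdname accessors
#' @export
setMethod("cbCoords", "CoarseModel", function(x) x@cb)

#' @rdname accessors
#' @export
setMethod("oCoords", "CoarseModel", function(x) x@o)

#' @rdname accessors
#' @export
setMethod("bFactors", "CoarseModel", function(x) x@bfac)

#' Ensemble accessors
#'
#' @param x a \linkS4class{CoarseEnsemble}.
#' @param i frame index.
#' @name ensemble-accessors
#' @aliases nFrames frames frameEnergies getFrame
NULL

#' @rdname ensemble-accessors
#' @export
setMethod("nFrames", "CoarseEnsemble", function(x) length(x@frames))

#' @rdname ensemble-accessors
#' @export
setMethod("frames", "CoarseEnsemble", function(x) x@frames)

#' @rdname ensemble-accessors
#' @export
setMethod("frameEnergies", "CoarseEnsemble", function(x) {
  if (length(x@energies)) x@energies else NULL
})

#' @rdname ensemble-accessors
#' @export
setMethod("getFrame", "CoarseEnsemble", function(x, i) x@frames[[i]])

#' @rdname ensemble-accessors
#' @export
setMethod("nResidues", "CoarseEnsemble", function(x) nResidues(x@frames[[1L]]))

#' Fluctuation-profile accessors
#' @param x a \linkS4class{FluctuationProfile}.
#' @name rmsfValues
#' @aliases bfactorValues
NULL

#' @rdname rmsfValues
#' @export
setMethod("rmsfValues", "FluctuationProfile", function(x) {
  structure(x@rmsf, names = x@resno)
})

#' @rdname rmsfValues
#' @export
setMethod("bfactorValues", "FluctuationProfile", function(x) {
  structure(x@bfactor, names = x@resno)
})

#' Trim-report accessors
#' @param x a \linkS4class{TrimReport}.
#' @name trim-accessors
#' @aliases removedResidues keptResidues fractionRemoved
NULL

#' @rdname trim-accessors
#' @export
setMethod("removedResidues", "TrimReport", function(x) x@removed)

#' @rdname trim-accessors
#' @export
setMethod("keptResidues", "TrimReport", function(x) x@kept)

#' @rdname trim-accessors
#' @export
setMethod("fractionRemoved", "TrimReport", function(x) x@fractionRemoved)

#' Cluster-result accessors
#' @param x a \linkS4class{ClusterResult}.
#' @name cluster-accessors
#' @aliases clusterLabels clusterSizes qMatrix
NULL

#' @rdname cluster-accessors
#' @export
setMethod("clusterLabels", "ClusterResult", function(x) x@labels)

#' @rdname cluster-accessors
#' @export
setMethod("clusterSizes", "ClusterResult", function(x) {
  as.integer(table(x@labels))
})

#' @rdname cluster-accessors
#' @export
setMethod("qMatrix", "ClusterResult", function(x) x@qMatrix)

#' Contact-map accessors
#' @param x a \linkS4class{ContactMap}.
#' @name contact-accessors
#' @aliases contactPairs nContacts
NULL

#' @rdname contact-accessors
#' @export
setMethod("contactPairs", "ContactMap", function(x) x@contacts)

#' @rdname contact-accessors
#' @export
setMethod("nContacts", "ContactMap", function(x) nrow(x@contacts))

#' @rdname contact-accessors
#' @export
setMethod("nResidues", "ContactMap", function(x) x@nResidues)

#' @rdname alignmentPairs
#' @param x an \linkS4class{AlignmentMap}.
#' @export
setMethod("alignmentPairs", "AlignmentMap", function(x) x@pairs)

# ---- show methods ------------------------------------------------------

setMethod("show", "CoarseModel", function(object) {
  n <- nResidues(object)
  ncb <- sum(!.is_na_row(object@cb))
  no <- sum(!.is_na_row(object@o))
  cat(sprintf("CoarseModel: %d residues, chain %s (%d Cbeta, %d O atoms)\n",
              n, object@chain, ncb, no))
  if (nzchar(object@label)) cat("  label:", object@label, "\n")
})

setMethod("show", "CoarseEnsemble", function(object) {
  cat(sprintf("CoarseEnsemble: %d frames x %d residues%s\n",
              nFrames(object), nResidues(object),
              if (length(object@energies)) ", with frame energies" else ""))
  if (nzchar(object@source)) cat("  source:", object@source, "\n")
})

setMethod("show", "FluctuationProfile", function(object) {
  cat(sprintf("FluctuationProfile: %d residues, frames %d-%d\n",
              length(object@resno), object@window[1L], object@window[2L]))
  cat(sprintf("  rmsf [A]: min %.3f / median %.3f / max %.3f\n",
              min(object@rmsf), stats::median(object@rmsf), max(object@rmsf)))
})

setMethod("show", "TrimReport", function(object) {
  cat(sprintf("TrimReport: cutoff %.2f A; removed %d of %d residues (%.1f%%)\n",
              object@cutoff, length(object@removed),
              length(object@removed) + length(object@kept),
              100 * object@fractionRemoved))
})

setMethod("show", "ContactMap", function(object) {
  cat(sprintf("ContactMap: %d contacts over %d residues (cutoff %.1f A, |i-j| >= %d)\n",
              nrow(object@contacts), object@nResidues, object@cutoff,
              object@minSeqSep))
})

setMethod("show", "ClusterResult", function(object) {
  sz <- sort(clusterSizes(object), decreasing = TRUE)
  cat(sprintf("ClusterResult: %d frames, %d cluster(s) [%s], pattern '%s'\n",
              length(object@labels), length(sz),
              paste(sz, collapse = ", "), object@pattern))
  cat(sprintf("  linkage %s, Q threshold %.2f\n", object@linkage, object@threshold))
})

setMethod("show", "AlignmentMap", function(object) {
  cat(sprintf("AlignmentMap: %d aligned residue pairs\n", nrow(object@pairs)))
})

setMethod("show", "FixtureSpec", function(object) {
  cat(sprintf("FixtureSpec: %s, %d residues x %d frames, seed %d\n",
              object@topology, object@nResidues, object@nFrames, object@seed))
})
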