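#' @import methods
NULL

# B = (8*pi^2/3) * rmsf^2 ; the isotropic displacement relation used
# throughout (Kuzmanic-Zagrovic). Kept as one constant so the profile
# validity check and the conversion cannot drift apart.
.B_COEF <- 8 * pi^2 / 3

.is_finite_row <- function(m) apply(m, 1L, function(r) all(is.finite(r)))
.is_na_row <- function(m) apply(m, 1L, function(r) all(is.na(r)))

#' CoarseModel: one coarse-grained protein structure
#'
#' A single structure in the three-sites-per-residue representation used by
#' coarse-grained prediction models: every residue carries a Calpha atom,
#' a Cbeta atom (absent for glycine) and a backbone carbonyl O (may be
#' absent, e.g. for chain termini in crystal references). Coordinates are in
#' Angstrom; per-atom isotropic B factors in Angstrom^2.
#'
#' @slot resno integer, 1-based residue numbers, strictly increasing.
#' @slot resid character, 3-letter residue codes.
#' @slot chain single chain identifier.
#' @slot ca,cb,o n x 3 coordinate matrices; \code{cb} rows are all-NA for
#'   glycine, \code{o} rows may be all-NA where the atom is missing.
#' @slot bfac n x 3 matrix (columns ca, cb, o) of B factors, NA where the
#'   atom is absent.
#' @slot label free-text description.
#' @exportClass CoarseModel
setClass("CoarseModel",
  representation(
    resno = "integer",
    resid = "character",
    chain = "character",
    ca = "matrix",
    cb = "matrix",
    o = "matrix",
    bfac = "matrix",
    label = "character"
  ),
  prototype(
    resno = integer(0), resid = character(0), chain = "A",
    ca = matrix(numeric(0), 0L, 3L), cb = matrix(numeric(0), 0L, 3L),
    o = matrix(numeric(0), 0L, 3L),
    bfac = matrix(numeric(0), 0L, 3L, dimnames = list(NULL, c("ca", "cb", "o"))),
    label = ""
  )
)

setValidity("CoarseModel", function(object) {
  n <- length(object@resno)
  msgs <- character(0)
  if (length(object@resid) != n) msgs <- c(msgs, "resid length != resno length")
  for (nm in c("ca", "cb", "o", "bfac")) {
    m <- slot(object, nm)
    if (!is.numeric(m) || ncol(m) != 3L || nrow(m) != n)
      msgs <- c(msgs, sprintf("slot '%s' must be a numeric %d x 3 matrix", nm, n))
  }
  if (length(msgs)) return(msgs)
  if (n > 0L) {
    if (any(diff(object@resno) <= 0L))
      msgs <- c(msgs, "residue numbers must be strictly increasing")
    if (!all(.is_finite_row(object@ca)))
      msgs <- c(msgs, "every residue must have a finite Calpha position")
    for (nm in c("cb", "o")) {
      m <- slot(object, nm)
      ok <- .is_finite_row(m) | .is_na_row(m)
      if (!all(ok))
        msgs <- c(msgs, sprintf("'%s' rows must be fully finite or fully NA", nm))
    }
    gly <- object@resid == "GLY"
    if (any(gly) && !all(.is_na_row(object@cb[gly, , drop = FALSE])))
      msgs <- c(msgs, "glycine residues must not carry a Cbeta atom")
    b <- object@bfac
    if (any(b < 0, na.rm = TRUE)) msgs <- c(msgs, "B factors must be >= 0")
    # B present exactly where the atom is present
    for (k in seq_len(3L)) {
      present <- .is_finite_row(slot(object, c("ca", "cb", "o")[k])[, , drop = FALSE])
      if (any(is.na(b[present, k])))
        msgs <- c(msgs, "B factor missing for an atom that is present")
    }
  }
  if (length(object@chain) != 1L || nchar(object@chain) != 1L)
    msgs <- c(msgs, "chain must be a single character")
  if (length(msgs)) msgs else TRUE
})

#' CoarseEnsemble: an ordered set of frames over one residue roster
#'
#' Holds the frames of a prediction ensemble (annealing-trajectory snapshots
#' or the per-job best structures), all sharing the same residue roster, with
#' optional per-frame model energies.
#'
#' @slot frames list of \linkS4class{CoarseModel}.
#' @slot energies numeric, one value per frame, or length 0 when absent.
#' @slot source free text provenance.
#' @exportClass CoarseEnsemble
setClass("CoarseEnsemble",
  representation(frames = "list", energies = "numeric", source = "character"),
  prototype(frames = list(), energies = numeric(0), source = "")
)

.roster_signature <- function(m) {
  paste(m@chain, paste(m@resno, m@resid, .is_na_row(m@cb), collapse = ";"))
}

setValidity("CoarseEnsemble", function(object) {
  if (length(object@frames) < 1L) return("ensemble must hold at least one frame")
  if (!all(vapply(object@frames, is, logical(1), "CoarseModel")))
    return("all frames must be CoarseModel objects")
  sig <- vapply(object@frames, .roster_signature, character(1))
  if (length(unique(sig)) != 1L) {
    bad <- which(sig != sig[1L])[1L]
    return(sprintf("frame %d has a different residue roster from frame 1", bad))
  }
  ne <- length(object@energies)
  if (ne != 0L && ne != length(object@frames))
    return("energies must be absent or have one value per frame")
  TRUE
})

#' FluctuationProfile: per-residue r.m.s.f. and derived B factor
#'
#' @slot resno residue numbers covered (the roster of the source ensemble).
#' @slot rmsf root-mean-square fluctuation per residue, Angstrom.
#' @slot bfactor (8 pi^2 / 3) * rmsf^2, Angstrom^2.
#' @slot window integer pair: first and last frame index used.
#' @exportClass FluctuationProfile
setClass("FluctuationProfile",
  representation(resno = "integer", rmsf = "numeric", bfactor = "numeric",
                 window = "integer")
)

setValidity("FluctuationProfile", function(object) {
  n <- length(object@resno)
  if (length(object@rmsf) != n || length(object@bfactor) != n)
    return("rmsf and bfactor must have one entry per residue")
  if (any(!is.finite(object@rmsf)) || any(object@rmsf < 0))
    return("rmsf must be finite and >= 0")
  if (max(abs(object@bfactor - .B_COEF * object@rmsf^2)) > 1e-6)
    return("bfactor must equal (8*pi^2/3) * rmsf^2")
  if (length(object@window) != 2L || object@window[1L] > object@window[2L])
    return("window must be (first, last) with first <= last")
  TRUE
})

#' TrimReport: outcome of r.m.s.f.-based trimming
#'
#' @slot cutoff r.m.s.f. cutoff in Angstrom (residues strictly above it are
#'   removed).
#' @slot removed,kept sorted residue numbers on each side of the cut.
#' @slot fractionRemoved length(removed) / roster size.
#' @exportClass TrimReport
setClass("TrimReport",
  representation(cutoff = "numeric", removed = "integer", kept = "integer",
                 fractionRemoved = "numeric")
)

setValidity("TrimReport", function(object) {
  if (length(intersect(object@removed, object@kept)))
    return("removed and kept residue sets must be disjoint")
  if (is.unsorted(object@removed) || is.unsorted(object@kept))
    return("removed and kept must be sorted")
  n <- length(object@removed) + length(object@kept)
  fr <- if (n == 0L) 0 else length(object@removed) / n
  if (abs(object@fractionRemoved - fr) > 1e-12)
    return("fractionRemoved inconsistent with the index sets")
  TRUE
})

#' AlignmentMap: residue correspondence between a model and a template
#'
#' An injective map between 1-based residue numbers of two structures,
#' typically the aligned regions from a template search. Used to restrict
#' the distance-difference metrics to aligned residue pairs.
#'
#' @slot pairs m x 2 integer matrix, columns (model, template).
#' @exportClass AlignmentMap
setClass("AlignmentMap", representation(pairs = "matrix"))

setValidity("AlignmentMap", function(object) {
  p <- object@pairs
  if (!is.numeric(p) || ncol(p) != 2L) return("pairs must be an m x 2 matrix")
  if (nrow(p) > 0L) {
    if (any(p != round(p)) || any(p < 1L)) return("indices must be 1-based integers")
    if (anyDuplicated(p[, 1L]) || anyDuplicated(p[, 2L]))
      return("alignment must be injective on both sides")
  }
  TRUE
})

#' ContactMap: Calpha contacts of one structure
#'
#' @slot nResidues roster size.
#' @slot contacts m x 2 matrix of position pairs (i < j).
#' @slot cutoff distance cutoff in Angstrom.
#' @slot minSeqSep minimum |i - j| for a pair to count.
#' @exportClass ContactMap
setClass("ContactMap",
  representation(nResidues = "integer", contacts = "matrix", cutoff = "numeric",
                 minSeqSep = "integer")
)

setValidity("ContactMap", function(object) {
  p <- object@contacts
  if (!is.numeric(p) || ncol(p) != 2L) return("contacts must be an m x 2 matrix")
  if (nrow(p) > 0L) {
    if (any(p < 1L) || any(p > object@nResidues)) return("contact index out of range")
    if (any(p[, 1L] >= p[, 2L])) return("contacts must be stored as i < j")
    if (any(p[, 2L] - p[, 1L] < object@minSeqSep))
      return("contact violates the minimum sequence separation")
  }
  TRUE
})

setOldClass("hclust")

#' ClusterResult: mutual-Q clustering of a prediction ensemble
#'
#' @slot qMatrix symmetric pairwise Qw matrix, unit diagonal.
#' @slot labels integer cluster id per frame (renumbered by first appearance).
#' @slot linkage agglomeration method used.
#' @slot threshold the Q threshold; the tree is cut at distance 1 - threshold.
#' @slot pattern one of "single_dominant", "multi_cluster", "dispersed".
#' @slot dendro the underlying \code{hclust} object (drives clustergram order).
#' @exportClass ClusterResult
setClass("ClusterResult",
  representation(qMatrix = "matrix", labels = "integer", linkage = "character",
                 threshold = "numeric", pattern = "character", dendro = "hclust")
)

setValidity("ClusterResult", function(object) {
  q <- object@qMatrix
  if (nrow(q) != ncol(q)) return("qMatrix must be square")
  if (max(abs(q - t(q))) > 1e-12) return("qMatrix must be symmetric (1e-12)")
  if (max(abs(diag(q) - 1)) > 1e-12) return("qMatrix diagonal must be 1")
  if (length(object@labels) != nrow(q)) return("one cluster label per frame")
  if (!object@pattern %in% c("single_dominant", "multi_cluster", "dispersed"))
    return("unknown pattern")
  TRUE
})

#' FixtureSpec: recipe for a synthetic test ensemble
#'
#' @slot nResidues chain length (>= 4).
#' @slot sigmaProfile per-residue Gaussian noise s.d. in Angstrom.
#' @slot nFrames number of frames to generate.
#' @slot seed RNG seed fixing all randomness.
#' @slot topology "helix", "strand" or "two_fold".
#' @exportClass FixtureSpec
setClass("FixtureSpec",
  representation(nResidues = "integer", sigmaProfile = "numeric",
                 nFrames = "integer", seed = "integer", topology = "character")
)

setValidity("FixtureSpec", function(object) {
  if (object@nResidues < 4L) return("nResidues must be >= 4")
  if (length(object@sigmaProfile) != object@nResidues)
    return("sigmaProfile must have one value per residue")
  if (any(object@sigmaProfile < 0)) return("sigma must be >= 0")
  if (object@nFrames < 1L) return("nFrames must be >= 1")
  if (!object@topology %in% c("helix", "strand", "two_fold"))
    return("topology must be helix, strand or two_fold")
  TRUE
})
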