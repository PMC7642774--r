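# sigma_ij = (1 + |i-j|)^0.15 Angstrom: the sequence-separation-dependent
# width used by the Q-family metrics (Eastwood et al. convention).
.q_sigma <- function(sep) (1 + sep)^0.15

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation (determinant +1) and translation that minimise
#' the r.m.s.d. between two equal-length Calpha coordinate sets under the
#' given one-to-one correspondence, via the SVD of the covariance matrix.
#'
#' @param mobile,target n x 3 coordinate matrices, n >= 3.
#' @return list with \code{rotation} (3 x 3), \code{translation} (length 3)
#'   and \code{rmsd}; the transform maps \code{mobile} onto \code{target} as
#'   \code{x \%*\% t(rotation) + translation} (see
#'   \code{\link{applyTransform}}).
#' @examples
#' x <- matrix(rnorm(12), 4)
#' kabschSuperpose(x, x)$rmsd
#' @export
kabschSuperpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (nrow(mobile) != nrow(target))
    stop("consistency error: coordinate sets differ in length")
  if (nrow(mobile) < 3L)
    stop("precondition error: need >= 3 points for superposition")
  cm <- colMeans(mobile); ct <- colMeans(target)
  P <- sweep(mobile, 2L, cm); Q <- sweep(target, 2L, ct)
  H <- crossprod(P, Q)                 # 3 x 3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rotated <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((rotated - Q)^2)))
  list(rotation = R, translation = as.numeric(ct - R %*% cm), rmsd = rmsd)
}

#' Apply a rigid-body transform to coordinates
#'
#' @param xyz n x 3 matrix.
#' @param fit a transform as returned by \code{\link{kabschSuperpose}}.
#' @return transformed n x 3 matrix.
#' @export
applyTransform <- function(xyz, fit) {
  sweep(xyz %*% t(fit$rotation), 2L, fit$translation, "+")
}

.aligned_ca <- function(a, b, alignment) {
  if (is.null(alignment)) {
    if (!identical(residueIndices(a), residueIndices(b)))
      stop("consistency error: rosters differ; supply an AlignmentMap")
    list(a = caCoords(a), b = caCoords(b), resno = residueIndices(a))
  } else {
    stopifnot(is(alignment, "AlignmentMap"))
    p <- alignmentPairs(alignment)
    ia <- match(p[, 1L], residueIndices(a))
    ib <- match(p[, 2L], residueIndices(b))
    if (any(is.na(ia)) || any(is.na(ib)))
      stop("consistency error: alignment references residues absent from a model")
    list(a = caCoords(a)[ia, , drop = FALSE],
         b = caCoords(b)[ib, , drop = FALSE],
         resno = p[, 1L])
  }
}

#' Qw: distance-difference structural similarity
#'
#' The Gaussian-weighted fraction-of-native-contacts measure over Calpha
#' pairs,
#' \deqn{Q_w = \frac{2}{(N-2)(N-3)} \sum_{j > i+2}
#'   \exp\!\left[-\frac{(r_{ij} - r'_{ij})^2}{2\sigma_{ij}^2}\right],}
#' with \eqn{\sigma_{ij} = (1 + |i-j|)^{0.15}} Angstrom. It compares internal
#' pairwise distances, so it needs no superposition and is invariant under
#' rigid motion of either structure; it is 1 exactly when all qualifying
#' pairwise distances agree and decays towards 0 as they diverge.
#'
#' @param a,b \linkS4class{CoarseModel}s on the same roster (or restricted
#'   through \code{alignment}).
#' @param alignment optional \linkS4class{AlignmentMap}; pairs are then
#'   formed among aligned residues only.
#' @param minSeqSep minimum residue-number separation |i - j| for a pair to
#'   enter the sum (default 3, excluding trivially constrained neighbours).
#' @return similarity in (0, 1].
#' @seealso \code{\link{qTemplate}}, \code{\link{gdtTS}}
#' @export
qw <- function(a, b, alignment = NULL, minSeqSep = 3L) {
  al <- .aligned_ca(a, b, alignment)
  n <- nrow(al$a)
  if (n < 4L) stop("precondition error: need >= 4 residues for Qw")
  da <- as.matrix(dist(al$a))
  db <- as.matrix(dist(al$b))
  sep <- abs(outer(al$resno, al$resno, "-"))
  use <- upper.tri(sep) & sep >= minSeqSep
  if (!any(use)) stop("precondition error: no residue pairs qualify")
  g <- exp(-(da[use] - db[use])^2 / (2 * .q_sigma(sep[use])^2))
  mean(g)
}

#' Q over template-aligned regions
#'
#' The collective variable used to bias a simulation towards an input
#' template: the same Gaussian distance-difference form as \code{\link{qw}},
#' but summed only over residue pairs (i, j) that are both aligned to the
#' template, with |i - j| >= \code{minSeqSep}, and whose template distance
#' \eqn{r^N_{ij}} is at least 2 Angstrom (a step function excludes closer
#' template pairs as unphysical). The normalisation counts exactly the pairs
#' that survive these filters, keeping the score in (0, 1].
#'
#' @param model the simulation snapshot (\linkS4class{CoarseModel}).
#' @param template the template structure.
#' @param alignment \linkS4class{AlignmentMap} from model to template
#'   residue numbers; defaults to the identity over the shared roster.
#' @param minSeqSep minimum model residue-number separation.
#' @param minTemplateDist template-distance exclusion threshold (Angstrom);
#'   pairs with \eqn{r^N_{ij} <} this contribute nothing and are excluded
#'   from the normalisation.
#' @return similarity in (0, 1].
#' @export
qTemplate <- function(model, template, alignment = NULL, minSeqSep = 3L,
                      minTemplateDist = 2) {
  if (is.null(alignment))
    alignment <- AlignmentMap(residueIndices(model), residueIndices(model))
  al <- .aligned_ca(model, template, alignment)
  if (nrow(al$a) < 2L)
    stop("precondition error: need >= 2 aligned residues")
  dm <- as.matrix(dist(al$a))   # model distances r_ij
  dt <- as.matrix(dist(al$b))   # template distances r^N_ij
  sep <- abs(outer(al$resno, al$resno, "-"))
  use <- upper.tri(sep) & sep >= minSeqSep & dt >= minTemplateDist
  if (!any(use))
    stop("precondition error: no aligned pairs survive the filters")
  g <- exp(-(dm[use] - dt[use])^2 / (2 * .q_sigma(sep[use])^2))
  mean(g)
}

#' GDT-TS: global distance test total score
#'
#' The mean, over the distance thresholds 1, 2, 4 and 8 Angstrom, of the
#' fraction of (aligned) Calpha atoms whose deviation from the reference is
#' within the threshold. A single all-residue Kabsch superposition is
#' applied first when \code{presuperpose} is set (the default); pass
#' \code{FALSE} to score coordinates in a frame you have already aligned.
#'
#' @param model,reference \linkS4class{CoarseModel}s.
#' @param alignment optional \linkS4class{AlignmentMap}.
#' @param presuperpose superpose model onto reference before measuring.
#' @param thresholds distance thresholds in Angstrom.
#' @return score in [0, 1].
#' @export
gdtTS <- function(model, reference, alignment = NULL, presuperpose = TRUE,
                  thresholds = c(1, 2, 4, 8)) {
  al <- .aligned_ca(model, reference, alignment)
  if (nrow(al$a) == 0L) stop("precondition error: empty alignment")
  x <- al$a
  if (presuperpose) {
    fit <- kabschSuperpose(x, al$b)
    x <- applyTransform(x, fit)
  }
  dev <- sqrt(rowSums((x - al$b)^2))
  mean(vapply(thresholds, function(th) mean(dev <= th), numeric(1)))
}

#' Calpha contact map of a structure
#'
#' A contact is an unordered residue pair with Calpha-Calpha distance at
#' most \code{cutoff} (9.5 Angstrom by default) and sequence separation
#' |i - j| at least \code{minSeqSep}.
#'
#' @param model a \linkS4class{CoarseModel} with >= 2 residues.
#' @param cutoff contact distance cutoff in Angstrom.
#' @param minSeqSep minimum residue-position separation.
#' @return A \linkS4class{ContactMap} (pairs stored as roster positions).
#' @export
contactMap <- function(model, cutoff = 9.5, minSeqSep = 3L) {
  stopifnot(is(model, "CoarseModel"))
  n <- nResidues(model)
  if (n < 2L) stop("precondition error: need >= 2 residues")
  d <- as.matrix(dist(caCoords(model)))
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  hit <- which(upper.tri(d) & sep >= minSeqSep & d <= cutoff, arr.ind = TRUE)
  hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
  dimnames(hit) <- NULL
  new("ContactMap", nResidues = n, contacts = hit, cutoff = cutoff,
      minSeqSep = as.integer(minSeqSep))
}

#' Overlap statistics between two contact maps
#'
#' Quantifies how well a predicted structure reproduces the reference's
#' contacts: precision = |P & R| / |P|, recall = |P & R| / |R|, and the
#' Jaccard index |P & R| / |P | R|. An empty predicted map makes precision
#' undefined (NA, with a warning).
#'
#' @param predicted,reference \linkS4class{ContactMap}s built with the same
#'   roster size, cutoff and separation rule.
#' @return named numeric vector: precision, recall, jaccard.
#' @export
contactOverlap <- function(predicted, reference) {
  stopifnot(is(predicted, "ContactMap"), is(reference, "ContactMap"))
  if (predicted@nResidues != reference@nResidues ||
      predicted@cutoff != reference@cutoff ||
      predicted@minSeqSep != reference@minSeqSep)
    stop("consistency error: contact maps built with different parameters")
  key <- function(m) m@contacts[, 1L] * (m@nResidues + 1L) + m@contacts[, 2L]
  p <- key(predicted); r <- key(reference)
  both <- length(intersect(p, r))
  union_n <- length(union(p, r))
  precision <- if (length(p) == 0L) {
    warning("empty predicted contact map: precision undefined")
    NA_real_
  } else both / length(p)
  recall <- if (length(r) == 0L) NA_real_ else both / length(r)
  jaccard <- if (union_n == 0L) NA_real_ else both / union_n
  c(precision = precision, recall = recall, jaccard = jaccard)
}
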