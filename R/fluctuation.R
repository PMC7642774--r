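#' Convert an r.m.s.f. value to an isotropic B factor
#'
#' Uses the relation between the crystallographic temperature factor and the
#' mean-square positional fluctuation of an atom,
#' \deqn{B = \frac{8\pi^2}{3}\,\mathrm{r.m.s.f.}^2,}
#' so an r.m.s.f. of 1 Angstrom corresponds to about 26.32 Angstrom^2.
#'
#' @param rmsf non-negative r.m.s.f. in Angstrom (vectorised).
#' @return B factor(s) in Angstrom^2.
#' @examples
#' rmsfToBfactor(c(0, 0.5, 1))
#' @export
rmsfToBfactor <- function(rmsf) {
  if (any(rmsf < 0)) stop("domain error: rmsf must be >= 0")
  .B_COEF * rmsf^2
}

#' Per-residue r.m.s.f. over the tail of a trajectory
#'
#' Computes, for each residue, the root-mean-square deviation of its Calpha
#' position in each frame from that residue's mean position over the window.
#' Because annealing trajectories only equilibrate near the end, the window
#' is the last \code{ceiling(windowFraction * nFrames)} frames (default the
#' last quarter). With \code{superpose = TRUE} (the default) every window
#' frame is first rigid-body superposed (Kabsch, all Calpha) onto the
#' window-mean structure, iterated twice, so that global drift and tumbling
#' do not inflate the per-residue fluctuations.
#'
#' @param ensemble a \linkS4class{CoarseEnsemble} with >= 2 frames in the
#'   window.
#' @param windowFraction fraction of trailing frames to use, in (0, 1].
#' @param superpose remove rigid-body motion before measuring deviations.
#' @return A \linkS4class{FluctuationProfile} (r.m.s.f. in Angstrom plus the
#'   derived B factor per residue).
#' @seealso \code{\link{trimByRMSF}}, \code{\link{assignBfactors}}
#' @export
computeRMSF <- function(ensemble, windowFraction = 0.25, superpose = TRUE) {
  stopifnot(is(ensemble, "CoarseEnsemble"))
  if (windowFraction <= 0 || windowFraction > 1)
    stop("windowFraction must be in (0, 1]")
  nf <- nFrames(ensemble)
  nw <- ceiling(windowFraction * nf)
  first <- nf - nw + 1L
  if (nw < 2L)
    stop("precondition error: need >= 2 frames in the r.m.s.f. window")
  n <- nResidues(ensemble)
  coords <- array(NA_real_, c(nw, n, 3L))
  for (t in seq_len(nw))
    coords[t, , ] <- caCoords(getFrame(ensemble, first + t - 1L))
  if (superpose) {
    ref <- apply(coords, c(2L, 3L), mean)
    for (pass in 1:2) {
      for (t in seq_len(nw)) {
        fit <- kabschSuperpose(coords[t, , ], ref)
        coords[t, , ] <- applyTransform(coords[t, , ], fit)
      }
      ref <- apply(coords, c(2L, 3L), mean)
    }
  }
  mean_pos <- apply(coords, c(2L, 3L), mean)
  dev2 <- matrix(0, nw, n)
  for (t in seq_len(nw))
    dev2[t, ] <- rowSums((coords[t, , ] - mean_pos)^2)
  rmsf <- sqrt(colMeans(dev2))
  new("FluctuationProfile",
      resno = residueIndices(getFrame(ensemble, 1L)),
      rmsf = rmsf, bfactor = rmsfToBfactor(rmsf),
      window = as.integer(c(first, nf)))
}

#' Trim flexible residues from a search model
#'
#' Removes every residue whose r.m.s.f. is strictly greater than the cutoff
#' (1.5 Angstrom by default, which delineates the most flexible coil
#' regions); a residue exactly at the cutoff is kept. Removal is whole
#' residues — all their atoms — and the surviving residues keep their
#' original numbering, so the trimmed model aligns against the full-length
#' one without renumbering.
#'
#' @param model a \linkS4class{CoarseModel}.
#' @param profile a \linkS4class{FluctuationProfile} covering the model's
#'   roster.
#' @param cutoff r.m.s.f. cutoff in Angstrom.
#' @return A list with elements \code{model} (trimmed
#'   \linkS4class{CoarseModel}) and \code{report} (\linkS4class{TrimReport}).
#' @export
trimByRMSF <- function(model, profile, cutoff = 1.5) {
  stopifnot(is(model, "CoarseModel"), is(profile, "FluctuationProfile"))
  idx <- match(residueIndices(model), profile@resno)
  if (any(is.na(idx)))
    stop("consistency error: profile does not cover the model roster")
  rmsf <- profile@rmsf[idx]
  drop <- rmsf > cutoff
  keep <- which(!drop)
  report <- new("TrimReport", cutoff = cutoff,
                removed = residueIndices(model)[drop],
                kept = residueIndices(model)[!drop],
                fractionRemoved = if (nResidues(model)) mean(drop) else 0)
  if (length(keep) == 0L) {
    warning("all residues trimmed: the model is empty")
    trimmed <- new("CoarseModel", chain = model@chain, label = model@label)
  } else {
    trimmed <- CoarseModel(
      resno = model@resno[keep], resid = model@resid[keep],
      ca = model@ca[keep, , drop = FALSE], cb = model@cb[keep, , drop = FALSE],
      o = model@o[keep, , drop = FALSE],
      bfac = model@bfac[keep, , drop = FALSE],
      chain = model@chain, label = model@label)
  }
  list(model = trimmed, report = report)
}

#' Secondary-structure composition of the trimmed residues
#'
#' Given per-residue secondary-structure labels (H helix, E strand, C coil,
#' U unstructured, i.e. not resolved in the reference crystal structure),
#' reports which classes the trimming removed: for each class the fraction
#' of removed residues carrying that label. Fractions sum to 1 whenever
#' anything was removed and are all 0 otherwise.
#'
#' @param report a \linkS4class{TrimReport}.
#' @param ssLabels character vector of labels in \{H, E, C, U\}, one per
#'   roster residue, ordered by residue number (roster = removed + kept).
#' @return named numeric vector with entries H, E, C, U.
#' @export
stratifyTrimmed <- function(report, ssLabels) {
  stopifnot(is(report, "TrimReport"))
  classes <- c("H", "E", "C", "U")
  if (!all(ssLabels %in% classes))
    stop("domain error: labels must be in {H, E, C, U}")
  roster <- sort(c(report@removed, report@kept))
  if (length(ssLabels) != length(roster))
    stop("need exactly one label per roster residue")
  out <- setNames(numeric(4L), classes)
  if (length(report@removed)) {
    lab <- ssLabels[match(report@removed, roster)]
    tab <- table(factor(lab, levels = classes))
    out[] <- as.numeric(tab) / length(report@removed)
  }
  out
}
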