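# Run expr under a fixed seed without disturbing the caller's RNG stream.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Specify a synthetic test ensemble
#'
#' @param nResidues chain length (>= 4).
#' @param sigmaProfile per-residue isotropic noise s.d. in Angstrom (scalar
#'   recycled).
#' @param nFrames number of frames.
#' @param seed integer seed fixing all randomness.
#' @param topology base geometry: "helix", "strand" or "two_fold".
#' @return A \linkS4class{FixtureSpec}.
#' @export
fixtureSpec <- function(nResidues, sigmaProfile = 0, nFrames = 1L, seed = 1L,
                        topology = "helix") {
  if (length(sigmaProfile) == 1L) sigmaProfile <- rep(sigmaProfile, nResidues)
  new("FixtureSpec", nResidues = as.integer(nResidues),
      sigmaProfile = as.numeric(sigmaProfile), nFrames = as.integer(nFrames),
      seed = as.integer(seed), topology = topology)
}

#' Ideal alpha-helix fixture
#'
#' Calpha atoms on the textbook helix (1.5 Angstrom rise, 100 degree twist,
#' 2.3 Angstrom radius per residue), which gives ~3.8 Angstrom consecutive
#' Calpha spacing and the familiar i,i+4 contacts; Cbeta is placed 1.5
#' Angstrom radially outward and O 2 Angstrom along the chain direction.
#' Fully deterministic.
#'
#' @param n number of residues (>= 4).
#' @param resid residue code used for every position (default "ALA", so all
#'   residues carry a Cbeta).
#' @return A \linkS4class{CoarseModel}.
#' @export
makeIdealHelix <- function(n, resid = "ALA") {
  if (n < 4L) stop("precondition error: need n >= 4")
  i <- seq_len(n) - 1L
  theta <- i * 100 * pi / 180
  ca <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
  cb <- cbind(3.8 * cos(theta), 3.8 * sin(theta), 1.5 * i)
  o <- .place_o(ca)
  CoarseModel(resno = seq_len(n), resid = rep(resid, n), ca = ca, cb = cb,
              o = o, label = sprintf("ideal helix n=%d", n))
}

#' Extended-strand fixture
#'
#' A zig-zag extended chain with ~3.8 Angstrom Calpha spacing (3.3 Angstrom
#' along x, alternating +/- 0.95 Angstrom in y), deliberately a different
#' fold from \code{\link{makeIdealHelix}} at the same length; Cbeta is
#' offset 1.5 Angstrom in z.
#'
#' @inheritParams makeIdealHelix
#' @return A \linkS4class{CoarseModel}.
#' @export
makeExtendedStrand <- function(n, resid = "ALA") {
  if (n < 4L) stop("precondition error: need n >= 4")
  i <- seq_len(n) - 1L
  ca <- cbind(3.3 * i, 0.95 * (-1)^i, rep(0, n))
  cb <- ca + matrix(rep(c(0, 0, 1.5), each = n), n, 3L)
  o <- .place_o(ca)
  CoarseModel(resno = seq_len(n), resid = rep(resid, n), ca = ca, cb = cb,
              o = o, label = sprintf("extended strand n=%d", n))
}

# O placed 2 A from Calpha along the local chain direction (last residue
# reuses the previous direction) — any self-consistent geometry serves the
# metrics, which are Calpha-based.
.place_o <- function(ca) {
  n <- nrow(ca)
  dirs <- rbind(ca[-1L, , drop = FALSE] - ca[-n, , drop = FALSE],
                ca[n, ] - ca[n - 1L, ])
  dirs <- dirs / sqrt(rowSums(dirs^2))
  ca + 2 * dirs
}

.random_rotation <- function() {
  # uniform random rotation from a normalised quaternion
  q <- rnorm(4L)
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

.perturb_frames <- function(model, sigma, nFrames, rigidMotions,
                            translationSd = 5) {
  n <- nResidues(model)
  lapply(seq_len(nFrames), function(t) {
    disp <- matrix(rnorm(n * 3L), n, 3L) * sigma
    ca <- model@ca + disp
    cb <- model@cb + disp
    o <- model@o + disp
    if (rigidMotions) {
      R <- .random_rotation()
      tr <- rnorm(3L, sd = translationSd)
      mv <- function(m) sweep(m %*% t(R), 2L, tr, "+")
      ca <- mv(ca); cb <- mv(cb); o <- mv(o)
    }
    CoarseModel(resno = model@resno, resid = model@resid, ca = ca, cb = cb,
                o = o, bfac = model@bfac, chain = model@chain,
                label = sprintf("%s frame %d", model@label, t))
  })
}

#' Noisy ensemble around one structure
#'
#' Generates \code{nFrames} copies of the base model with an independent
#' per-frame, per-residue isotropic Gaussian displacement of s.d.
#' \code{sigmaProfile[k]} per axis added to all atoms of residue k (the
#' residue moves as a unit). Under this noise model the expected Calpha
#' r.m.s.f. of residue k is \eqn{\sqrt{3}\,\sigma_k}, which makes parameter
#' recovery by \code{\link{computeRMSF}} exactly checkable. With
#' \code{rigidMotions}, each frame is additionally given a random global
#' rotation and translation — useful for verifying that superposition
#' removes rigid-body motion.
#'
#' @param model base \linkS4class{CoarseModel}.
#' @param spec a \linkS4class{FixtureSpec} matching the model's length.
#' @param rigidMotions apply a random rigid-body motion per frame.
#' @return A \linkS4class{CoarseEnsemble}; same seed, same ensemble.
#' @export
perturbEnsemble <- function(model, spec, rigidMotions = FALSE) {
  stopifnot(is(model, "CoarseModel"), is(spec, "FixtureSpec"))
  if (spec@nResidues != nResidues(model))
    stop("consistency error: spec length does not match the model")
  frames <- .with_seed(spec@seed,
    .perturb_frames(model, spec@sigmaProfile, spec@nFrames, rigidMotions))
  CoarseEnsemble(frames, source = sprintf("synthetic (seed %d)", spec@seed))
}

#' Planted two-fold ensemble for clustering tests
#'
#' Builds an ensemble whose frames come from two distinct folds on one
#' roster — half noisy copies of an ideal helix, half of an extended strand
#' — so the mutual-Q matrix has a planted two-block structure: within-fold
#' Qw is high (near 1 for small noise), between-fold Qw is low. An odd frame
#' count is rounded down per fold with a warning.
#'
#' @param spec a \linkS4class{FixtureSpec} with \code{topology = "two_fold"}.
#' @return A \linkS4class{CoarseEnsemble}: the first half of the frames are
#'   fold A (helix), the second half fold B (strand).
#' @export
makeTwoFoldEnsemble <- function(spec) {
  stopifnot(is(spec, "FixtureSpec"))
  if (spec@topology != "two_fold")
    stop("spec topology must be 'two_fold'")
  per <- spec@nFrames %/% 2L
  if (spec@nFrames %% 2L != 0L)
    warning("odd nFrames: using ", per, " frames per fold")
  if (per < 1L) stop("need at least 2 frames")
  a <- makeIdealHelix(spec@nResidues)
  b <- makeExtendedStrand(spec@nResidues)
  frames <- .with_seed(spec@seed, c(
    .perturb_frames(a, spec@sigmaProfile, per, FALSE),
    .perturb_frames(b, spec@sigmaProfile, per, FALSE)))
  CoarseEnsemble(frames,
                 source = sprintf("synthetic two-fold (seed %d)", spec@seed))
}
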