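#' Read a PDB file into a coarse-grained ensemble
#'
#' Parses a single- or multi-model PDB file (MODEL/ENDMDL blocks, one frame
#' each; a file without MODEL records yields a one-frame ensemble) and
#' extracts the coarse-grained representation: the Calpha, Cbeta and
#' carbonyl-O atom of every residue. Column-level parsing is delegated to
#' \code{bio3d::read.pdb}; this wrapper enforces the conventions the
#' downstream pipeline relies on:
#' \itemize{
#'   \item only ATOM records are used; HETATM (cofactors, waters) are ignored;
#'   \item alternate locations other than ' ' or 'A' are discarded, so the
#'     model is a single deterministic conformer;
#'   \item insertion codes are rejected (the roster must be plain integers);
#'   \item residues lacking a Calpha are dropped with a warning (predicted
#'     models are Calpha-complete; crystal references may not be);
#'   \item one chain per model: multi-chain files require \code{chain}.
#' }
#' All frames must share one residue roster; a mismatch is an error naming
#' the first offending frame.
#'
#' @param path PDB file path.
#' @param chain chain identifier to select from a multi-chain file; may be
#'   omitted for single-chain files.
#' @param label free-text label stored on each frame (default: file name).
#' @return A \linkS4class{CoarseEnsemble} with one frame per MODEL block.
#' @seealso \code{\link{writeCoarsePDB}}, \code{\link{selectLowestEnergyFrame}}
#' @export
readCoarsePDB <- function(path, chain = NULL, label = basename(path)) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^ATOM  ", lines)))
    stop("format error: no ATOM records in ", path)
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  blocks <- if (length(starts) == 0L) {
    list(lines)
  } else {
    if (length(ends) != length(starts))
      stop("format error: unbalanced MODEL/ENDMDL records")
    mapply(function(s, e) lines[s:e], starts, ends, SIMPLIFY = FALSE)
  }
  frames <- lapply(seq_along(blocks), function(i) {
    .parse_pdb_block(blocks[[i]], chain = chain, label = label, frame = i)
  })
  sig <- vapply(frames, .roster_signature, character(1))
  bad <- which(sig != sig[1L])
  if (length(bad))
    stop(sprintf(
      "consistency error: frame %d has a different residue roster from frame 1",
      bad[1L]))
  CoarseEnsemble(frames, source = path)
}

.parse_pdb_block <- function(lines, chain, label, frame) {
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pdb <- suppressWarnings(bio3d::read.pdb(tf, verbose = FALSE))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L)
    stop(sprintf("format error: frame %d contains no ATOM records", frame))
  ins <- at$insert
  if (any(!is.na(ins) & ins != ""))
    stop("format error: insertion codes are not supported")
  alt <- at$alt
  at <- at[is.na(alt) | alt %in% c("", "A"), , drop = FALSE]
  ch <- unique(at$chain)
  ch[is.na(ch)] <- " "
  if (!is.null(chain)) {
    at <- at[at$chain %in% chain | (chain == " " & is.na(at$chain)), ,
             drop = FALSE]
    if (nrow(at) == 0L)
      stop(sprintf("chain '%s' not found (file has: %s)", chain,
                   paste(ch, collapse = ", ")))
  } else if (length(ch) > 1L) {
    stop(sprintf("multiple chains present (%s); select one with 'chain='",
                 paste(ch, collapse = ", ")))
  }
  at <- at[at$elety %in% c("CA", "CB", "O"), , drop = FALSE]
  resno <- sort(unique(at$resno))
  has_ca <- resno %in% at$resno[at$elety == "CA"]
  if (any(!has_ca)) {
    warning(sprintf("dropping %d residue(s) without a Calpha atom (e.g. %d)",
                    sum(!has_ca), resno[!has_ca][1L]))
    resno <- resno[has_ca]
  }
  n <- length(resno)
  if (n == 0L) stop("format error: no residues with a Calpha atom")
  pick <- function(elety) {
    m <- matrix(NA_real_, n, 3L)
    b <- rep(NA_real_, n)
    sel <- at[at$elety == elety, , drop = FALSE]
    sel <- sel[!duplicated(sel$resno), , drop = FALSE]
    idx <- match(sel$resno, resno)
    ok <- !is.na(idx)
    m[idx[ok], ] <- as.matrix(sel[ok, c("x", "y", "z")])
    b[idx[ok]] <- sel$b[ok]
    list(xyz = m, b = b)
  }
  ca <- pick("CA"); cb <- pick("CB"); o <- pick("O")
  resid <- at$resid[at$elety == "CA"][match(resno, at$resno[at$elety == "CA"])]
  bfac <- cbind(ca = ca$b, cb = cb$b, o = o$b)
  bfac[is.na(bfac)] <- 0
  chain_out <- if (!is.null(chain)) chain else if (is.na(ch[1L])) "A" else ch[1L]
  CoarseModel(resno = resno, resid = resid, ca = ca$xyz, cb = cb$xyz,
              o = o$xyz, bfac = bfac, chain = chain_out, label = label)
}

#' Write a coarse-grained model as a PDB file
#'
#' Emits standard fixed-column ATOM records (coordinates with 3 decimals,
#' occupancy 1.00, B factor with 2 decimals, element symbol populated), the
#' format Phaser and the rebuilding programs consume as a search model. The
#' write/read round trip preserves coordinates to 0.001 Angstrom and B
#' factors to 0.01 Angstrom^2 (the PDB field precisions).
#'
#' @param model a valid \linkS4class{CoarseModel}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeCoarsePDB <- function(model, path) {
  stopifnot(is(model, "CoarseModel"))
  validObject(model)
  n <- nResidues(model)
  if (n == 0L) stop("cannot write an empty model")
  rows <- list()
  add <- function(elety, xyz, b, elesy) {
    present <- which(.is_finite_row(xyz))
    if (length(present))
      rows[[length(rows) + 1L]] <<- data.frame(
        resno = model@resno[present], resid = model@resid[present],
        elety = elety, x = xyz[present, 1L], y = xyz[present, 2L],
        z = xyz[present, 3L], b = b[present], elesy = elesy)
    invisible(NULL)
  }
  add("CA", model@ca, model@bfac[, 1L], "C")
  add("CB", model@cb, model@bfac[, 2L], "C")
  add("O",  model@o,  model@bfac[, 3L], "O")
  at <- do.call(rbind, rows)
  if (any(at$b > 999.99))
    stop("range error: B factor exceeds 999.99 and overflows the PDB field")
  # order by residue, then CA < CB < O within the residue
  at <- at[order(at$resno, match(at$elety, c("CA", "CB", "O"))), , drop = FALSE]
  xyz <- as.vector(t(as.matrix(at[, c("x", "y", "z")])))
  na <- nrow(at)
  bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", na),
                   resno = at$resno, resid = at$resid,
                   eleno = seq_len(na), elety = at$elety,
                   chain = rep(model@chain, na), o = rep(1, na), b = at$b,
                   elesy = at$elesy)
  invisible(path)
}

#' Attach per-frame model energies to an ensemble
#'
#' @param x a \linkS4class{CoarseEnsemble}.
#' @param value numeric, one energy per frame (model units; lower = better).
#' @return the updated ensemble.
#' @export
`frameEnergies<-` <- function(x, value) {
  stopifnot(is(x, "CoarseEnsemble"))
  x@energies <- as.numeric(value)
  validObject(x)
  x
}

#' Pick the lowest-energy frame of an ensemble
#'
#' The frame carried forward for trimming is the one with the minimum model
#' energy; ties are broken by the earliest frame index.
#'
#' @param ensemble a \linkS4class{CoarseEnsemble} with energies attached.
#' @return the selected \linkS4class{CoarseModel}.
#' @export
selectLowestEnergyFrame <- function(ensemble) {
  stopifnot(is(ensemble, "CoarseEnsemble"))
  e <- frameEnergies(ensemble)
  if (is.null(e))
    stop("precondition error: ensemble has no frame energies")
  getFrame(ensemble, which.min(e))
}
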