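#' Assign B factors to a search model
#'
#' Two schemes are supported, matching the two ways a predicted model can be
#' handed to a molecular-replacement program: a flat value for every atom
#' (\code{uniform}, default 20 Angstrom^2), or the per-residue value derived
#' from the trajectory fluctuations (\code{rmsf}), where every atom of
#' residue k receives \eqn{(8\pi^2/3)\,\mathrm{rmsf}_k^2}. Coordinates are
#' never touched.
#'
#' @param model a \linkS4class{CoarseModel}.
#' @param scheme "uniform" or "rmsf".
#' @param profile a \linkS4class{FluctuationProfile} covering the roster
#'   (required for \code{scheme = "rmsf"}).
#' @param uniformValue the flat B factor in Angstrom^2.
#' @return the model with updated B factors.
#' @export
assignBfactors <- function(model, scheme = c("uniform", "rmsf"),
                           profile = NULL, uniformValue = 20) {
  stopifnot(is(model, "CoarseModel"))
  scheme <- match.arg(scheme)
  n <- nResidues(model)
  if (scheme == "uniform") {
    b <- rep(uniformValue, n)
  } else {
    if (is.null(profile))
      stop("precondition error: the rmsf scheme requires a FluctuationProfile")
    idx <- match(residueIndices(model), profile@resno)
    if (any(is.na(idx)))
      stop("consistency error: profile does not cover the model roster")
    b <- profile@bfactor[idx]
  }
  bm <- matrix(rep(b, 3L), n, 3L, dimnames = list(NULL, c("ca", "cb", "o")))
  bm[, 2L][.is_na_row(model@cb)] <- NA_real_
  bm[, 3L][.is_na_row(model@o)] <- NA_real_
  model@bfac <- bm
  validObject(model)
  model
}

#' Judge one molecular-replacement trial
#'
#' Success is defined strictly by the cross-validation R factor: the trial
#' succeeded if and only if R_free is present and below the cutoff (0.45 by
#' default, the value that usually indicates a correct coordinate
#' refinement). The translation-function Z-score never decides success —
#' incorrect solutions with very high TFZ (>= 8) do occur — but a high TFZ
#' without a confirming rebuild triggers an advisory note. Map correlation
#' advisories: below 0.1 usually means a failed search, above 0.25 usually a
#' correct solution.
#'
#' @param record one trial: a list or one-row data frame with any of
#'   \code{tfz}, \code{llg}, \code{r_free}, \code{map_cc} (NA = absent).
#' @param rFreeCutoff success threshold on R_free (strict \code{<}).
#' @param tfzConfident TFZ level treated as a confident placement signal.
#' @return list with \code{success} (logical) and \code{notes} (character
#'   vector of advisories, possibly empty).
#' @export
evaluateTrial <- function(record, rFreeCutoff = 0.45, tfzConfident = 8) {
  g <- function(f) {
    v <- record[[f]]
    if (is.null(v) || length(v) == 0L || is.na(v)) NA_real_ else as.numeric(v)
  }
  tfz <- g("tfz"); rfree <- g("r_free"); cc <- g("map_cc")
  if (all(is.na(c(tfz, g("llg"), rfree, cc))))
    stop("record must carry at least one statistic")
  success <- !is.na(rfree) && rfree < rFreeCutoff
  notes <- character(0)
  if (!is.na(tfz) && tfz >= tfzConfident && !success)
    notes <- c(notes, "high TFZ without confirmed rebuild")
  if (!is.na(cc)) {
    if (cc < 0.1) notes <- c(notes, "map CC < 0.1: likely failed search")
    else if (cc > 0.25) notes <- c(notes, "map CC > 0.25: likely correct solution")
  }
  list(success = success, notes = notes)
}

#' Summarise a set of molecular-replacement trials
#'
#' @param records data frame of trials (columns \code{trial_id}, \code{tfz},
#'   \code{llg}, \code{r_free}, \code{map_cc}; NA = statistic absent), e.g.
#'   from \code{\link{readTrialsTSV}}.
#' @param rFreeCutoff success threshold passed to \code{\link{evaluateTrial}}.
#' @return list: \code{nTrials}, \code{nSuccess}, \code{nFailure},
#'   \code{successFraction}, \code{bestRfree} (lowest present, NA if none),
#'   \code{bestTFZ} (highest present), and the per-trial \code{verdicts}
#'   data frame ordered by trial id.
#' @export
summarizeTrials <- function(records, rFreeCutoff = 0.45) {
  if (!is.data.frame(records) || nrow(records) < 1L)
    stop("precondition error: need at least one trial record")
  records <- records[order(records$trial_id), , drop = FALSE]
  verdicts <- vapply(seq_len(nrow(records)), function(i) {
    evaluateTrial(records[i, , drop = FALSE], rFreeCutoff)$success
  }, logical(1))
  best_min <- function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE)
  best_max <- function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  list(nTrials = nrow(records),
       nSuccess = sum(verdicts),
       nFailure = sum(!verdicts),
       successFraction = mean(verdicts),
       bestRfree = best_min(records$r_free),
       bestTFZ = best_max(records$tfz),
       verdicts = data.frame(trial_id = records$trial_id, success = verdicts))
}

.TRIAL_COLS <- c("trial_id", "tfz", "llg", "r_free", "map_cc")

#' Read a molecular-replacement trial table
#'
#' Expects a TSV with header \code{trial_id  tfz  llg  r_free  map_cc};
#' empty cells mean the statistic is absent. A non-numeric cell is a format
#' error naming the row and column.
#'
#' @param path TSV file path.
#' @return data frame with the five columns (numeric statistics, NA where
#'   absent).
#' @export
readTrialsTSV <- function(path) {
  if (!file.exists(path)) stop("cannot read trial table: ", path)
  raw <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                           na.strings = NULL)
  if (!all(.TRIAL_COLS %in% names(raw)))
    stop("format error: header must contain columns ",
         paste(.TRIAL_COLS, collapse = ", "))
  out <- data.frame(trial_id = raw$trial_id)
  for (col in .TRIAL_COLS[-1L]) {
    v <- trimws(raw[[col]])
    num <- suppressWarnings(as.numeric(v))
    bad <- which(nzchar(v) & v != "NA" & is.na(num))
    if (length(bad))
      stop(sprintf("format error: non-numeric value '%s' at row %d, column %s",
                   v[bad[1L]], bad[1L], col))
    num[!nzchar(v)] <- NA_real_
    out[[col]] <- num
  }
  out
}

#' Write a molecular-replacement trial table
#'
#' Inverse of \code{\link{readTrialsTSV}}: absent statistics become empty
#' cells.
#'
#' @param records trial data frame.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeTrialsTSV <- function(records, path) {
  stopifnot(all(.TRIAL_COLS %in% names(records)))
  out <- records[, .TRIAL_COLS, drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
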