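#' Count TCW-motif cytosine mutations per sample
#'
#' APOBEC deaminates cytosines in a TCW context (W = A or T), producing
#' C>T transitions and C>G transversions; the reverse-strand mirror of
#' TCW is WGA. After pyrimidine normalization, \code{n_c_mut} counts
#' every C>T or C>G SNV (C>A is excluded by the score's definition) and
#' \code{n_tcw_mut} the subset with upstream T and downstream A or T.
#'
#' @param muts A [MutationTable-class] with contexts attached.
#' @return data.frame with one row per sample (first-appearance order):
#'   \code{sample_id}, \code{n_tcw_mut}, \code{n_c_mut}.
#' @export
countTcwMutations <- function(muts) {
  rec <- mutationRecords(muts)
  sids <- unique(rec$sample_id)
  canon <- normalizePyrimidine(muts)
  cMut <- canon$usable & canon$ref == "C" & canon$alt %in% c("T", "G")
  tcw <- cMut & canon$upstream == "T" & canon$downstream %in% c("A", "T")
  cMut[is.na(cMut)] <- FALSE
  tcw[is.na(tcw)] <- FALSE
  data.frame(
    sample_id = sids,
    n_tcw_mut = as.integer(tapply(tcw, factor(rec$sample_id, sids), sum,
                                  default = 0L)),
    n_c_mut = as.integer(tapply(cMut, factor(rec$sample_id, sids), sum,
                                default = 0L)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Count background cytosines and TCW motifs around mutated bases
#'
#' For each C>T/C>G mutation (pyrimidine-normalized, the same records
#' counted by [countTcwMutations()]), scans the reference window
#' pos-window .. pos+window. \code{n_background_c} accumulates the number
#' of C and G bases in the window; \code{n_background_tcw} the number of
#' TCW (forward: TCA, TCT) and WGA (forward: AGA, TGA) motif occurrences
#' whose start lies within the window and which fit entirely on the
#' contig. Windows of distinct mutations are summed independently, so
#' bases shared by overlapping windows are counted once per mutation --
#' the background is a per-mutation weighting, and a union would
#' under-weight clustered mutations.
#'
#' @param muts A [MutationTable-class] with contexts attached.
#' @param reference Reference sequence (see [attachContext()]).
#' @param window Half-width in bp of the background window (default 20).
#' @param chrTolerant If TRUE, contig matching ignores a "chr" prefix.
#' @return data.frame with one row per sample: \code{sample_id},
#'   \code{n_background_c}, \code{n_background_tcw}.
#' @export
countBackground <- function(muts, reference, window = 20L,
                            chrTolerant = FALSE) {
  if (window < 1L) stop("window must be >= 1")
  ref <- .asReference(reference)
  rec <- mutationRecords(muts)
  sids <- unique(rec$sample_id)
  canon <- normalizePyrimidine(muts)
  counted <- canon$usable & canon$ref == "C" & canon$alt %in% c("T", "G")
  counted[is.na(counted)] <- FALSE

  bgC <- bgTcw <- numeric(nrow(rec))
  if (any(counted)) {
    idx <- .matchContig(rec$chrom[counted], names(ref), chrTolerant)
    refChar <- as.character(ref)
    w <- nchar(refChar)[idx]
    pos <- rec$pos[counted]
    lo <- pmax(1L, pos - window)
    hi <- pmin(w, pos + window)
    nWin <- hi - lo + 1L
    # motifs may start anywhere in the window and extend up to 2 bases
    # past its end, provided they fit on the contig
    s <- substring(refChar[idx], lo, pmin(w, pos + window + 2L))
    winStr <- substring(s, 1L, nWin)
    cg <- nchar(winStr) - nchar(gsub("[CG]", "", winStr))
    motifs <- c("TCA", "TCT", "AGA", "TGA")
    tcw <- integer(length(s))
    for (o in seq_len(2L * window + 1L)) {
      tri <- substring(s, o, o + 2L)
      tcw <- tcw + (nchar(tri) == 3L & o <= nWin & tri %in% motifs)
    }
    bgC[counted] <- cg
    bgTcw[counted] <- tcw
  }
  f <- factor(rec$sample_id, sids)
  data.frame(
    sample_id = sids,
    n_background_c = as.integer(tapply(bgC, f, sum, default = 0L)),
    n_background_tcw = as.integer(tapply(bgTcw, f, sum, default = 0L)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' The APOBEC mutagenesis enrichment score
#'
#' AMES = (n_tcw_mut / n_c_mut) * (n_background_c / n_background_tcw):
#' the fraction of mutated cytosines falling in a TCW motif, weighted by
#' the inverse background TCW/C fraction in the +/-window around the
#' mutated bases. A score of 1 means motif mutations occur at exactly the
#' rate the local sequence composition predicts. The score is undefined
#' (NA, never 0) when n_c_mut or n_background_tcw is 0.
#'
#' @param n_tcw_mut,n_c_mut,n_background_c,n_background_tcw The four
#'   counts (vectorized).
#' @return Numeric score vector; NA where undefined.
#' @examples
#' computeAmes(6, 10, 100, 60)  # == 1: no enrichment
#' @export
computeAmes <- function(n_tcw_mut, n_c_mut, n_background_c,
                        n_background_tcw) {
  score <- (n_tcw_mut / n_c_mut) * (n_background_c / n_background_tcw)
  score[n_c_mut == 0 | n_background_tcw == 0] <- NA_real_
  score
}

#' Stratify AMES scores into categorical levels
#'
#' Samples are categorized by ascending cutoffs into length(cutoffs)+1
#' levels; the default cutoffs 1 and 2 give low/moderate/high enrichment.
#' Intervals are left-closed at each cutoff: score < c1 -> first label,
#' c1 <= score < c2 -> second, score >= c2 -> third. Undefined (NA)
#' scores get a missing level.
#'
#' @param scores Numeric score vector.
#' @param cutoffs Strictly ascending cutoff values (default c(1, 2)).
#' @param labels One label per interval (default c("L", "M", "H")).
#' @return Factor of levels, same length as scores.
#' @examples
#' stratifyAmes(c(0.5, 1.5, 2.5))
#' @export
stratifyAmes <- function(scores, cutoffs = c(1, 2),
                         labels = c("L", "M", "H")) {
  if (is.unsorted(cutoffs, strictly = TRUE))
    stop("cutoffs must be strictly ascending")
  if (length(labels) != length(cutoffs) + 1L)
    stop("need length(cutoffs) + 1 labels")
  cut(scores, breaks = c(-Inf, cutoffs, Inf), labels = labels,
      right = FALSE)
}

#' Per-sample AMES scoring pipeline
#'
#' Attaches contexts if absent, counts TCW and total C>T/C>G mutations,
#' counts the local background, computes the score and stratifies it.
#' Samples with fewer than \code{minCMut} counted mutations get an NA
#' score (default 0: no filtering).
#'
#' @param muts A [MutationTable-class].
#' @param reference Reference sequence (see [attachContext()]).
#' @param window Background half-width in bp (default 20).
#' @param cutoffs,labels Passed to [stratifyAmes()].
#' @param minCMut Minimum n_c_mut for a defined score (default 0).
#' @param chrTolerant If TRUE, contig matching ignores a "chr" prefix.
#' @return data.frame with columns sample_id, n_tcw_mut, n_c_mut,
#'   n_background_c, n_background_tcw, ames, level.
#' @export
amesScore <- function(muts, reference, window = 20L, cutoffs = c(1, 2),
                      labels = c("L", "M", "H"), minCMut = 0L,
                      chrTolerant = FALSE) {
  rec <- mutationRecords(muts)
  if (nrow(rec) && !any(!is.na(rec$context)))
    muts <- attachContext(muts, reference, flank = max(window, 1L),
                          chrTolerant = chrTolerant)
  counts <- countTcwMutations(muts)
  bg <- countBackground(muts, reference, window = window,
                        chrTolerant = chrTolerant)
  out <- merge(counts, bg, by = "sample_id", sort = FALSE)
  out$ames <- computeAmes(out$n_tcw_mut, out$n_c_mut,
                          out$n_background_c, out$n_background_tcw)
  out$ames[out$n_c_mut < minCMut] <- NA_real_
  out$level <- stratifyAmes(out$ames, cutoffs, labels)
  out
}
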