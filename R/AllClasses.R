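#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

.MUT_COLS <- c("sample_id", "chrom", "pos", "ref_allele", "alt_allele",
               "variant_classification", "gene_symbol", "context",
               "ref_mismatch")

#' MutationTable: per-sample somatic mutation records
#'
#' Holds MAF-style somatic variant calls: sample barcode, 1-based
#' coordinate, reference/alternate alleles, variant classification and
#' gene symbol, plus an optional reference context string (attached by
#' [attachContext()]) and a reference-mismatch flag. Indels are retained
#' (for burden and DDR accounting) but only SNVs participate in motif and
#' signature analysis.
#'
#' @slot records A [S4Vectors::DataFrame] with one row per variant call.
#' @export
setClass("MutationTable", slots = c(records = "DataFrame"))

setValidity("MutationTable", function(object) {
  rec <- object@records
  missing <- setdiff(.MUT_COLS, colnames(rec))
  if (length(missing))
    return(paste("missing record columns:", paste(missing, collapse = ", ")))
  if (nrow(rec) == 0L) return(TRUE)
  if (any(is.na(rec$pos)) || any(rec$pos < 1L))
    return("pos must be >= 1 and non-missing")
  if (any(!nzchar(rec$ref_allele)))
    return("ref_allele must be non-empty")
  snv <- .isSNV(rec$ref_allele, rec$alt_allele)
  ctx <- rec$context[snv]
  has <- !is.na(ctx)
  if (any(has)) {
    mid <- substr(ctx[has], (nchar(ctx[has]) + 1L) %/% 2L,
                  (nchar(ctx[has]) + 1L) %/% 2L)
    bad <- mid != rec$ref_allele[snv][has] & !rec$ref_mismatch[snv][has]
    if (any(bad))
      return("context middle base disagrees with ref_allele on unflagged records")
  }
  TRUE
})

.isSNV <- function(ref, alt) {
  nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% .BASES & alt %in% .BASES & ref != alt
}

#' Construct a MutationTable
#'
#' @param sample_id,chrom,pos,ref_allele,alt_allele Character/integer
#'   vectors of equal length describing each call (pos is 1-based).
#' @param variant_classification MAF classification terms
#'   (default "Missense_Mutation").
#' @param gene_symbol Gene symbols (default NA).
#' @param context Optional reference context strings centered on pos.
#' @return A [MutationTable-class] object.
#' @examples
#' mutationTable("S1", "chr1", 5L, "C", "T")
#' @export
mutationTable <- function(sample_id, chrom, pos, ref_allele, alt_allele,
                          variant_classification = "Missense_Mutation",
                          gene_symbol = NA_character_,
                          context = NA_character_) {
  n <- length(pos)
  rec <- DataFrame(
    sample_id = rep_len(as.character(sample_id), n),
    chrom = rep_len(as.character(chrom), n),
    pos = as.integer(pos),
    ref_allele = rep_len(toupper(as.character(ref_allele)), n),
    alt_allele = rep_len(toupper(as.character(alt_allele)), n),
    variant_classification = rep_len(as.character(variant_classification), n),
    gene_symbol = rep_len(as.character(gene_symbol), n),
    context = rep_len(as.character(context), n),
    ref_mismatch = rep_len(FALSE, n))
  new("MutationTable", records = rec)
}

#' @describeIn MutationTable-class records accessor
#' @param x,object A MutationTable.
#' @export
mutationRecords <- function(x) x@records

#' @describeIn MutationTable-class distinct sample identifiers, in
#'   first-appearance order
#' @export
sampleIds <- function(x) {
  if (is(x, "MutationTable")) unique(x@records$sample_id)
  else if (is(x, "ContextMatrix96")) rownames(x@counts)
  else stop("no sampleIds method for class ", class(x))
}

#' @describeIn MutationTable-class number of records
#' @export
setMethod("length", "MutationTable", function(x) nrow(x@records))

setMethod("show", "MutationTable", function(object) {
  rec <- object@records
  cat("MutationTable with", nrow(rec), "records in",
      length(unique(rec$sample_id)), "sample(s)\n")
  if (nrow(rec)) {
    snv <- sum(.isSNV(rec$ref_allele, rec$alt_allele))
    cat("  SNVs:", snv, " other:", nrow(rec) - snv,
        " contexts attached:", sum(!is.na(rec$context)),
        " ref mismatches:", sum(rec$ref_mismatch), "\n")
  }
})

#' ContextMatrix96: samples x 96 substitution-channel counts
#'
#' Nonnegative integer counts of pyrimidine-normalized single-base
#' substitutions per sample and trinucleotide channel, in the fixed
#' ordering of [channelLabels()]. Row sums equal each sample's usable SNV
#' count; records excluded during construction (non-SNV, missing context,
#' N in the triplet, reference mismatch) are tallied in \code{excluded}.
#'
#' @slot counts Integer matrix, samples x 96.
#' @slot excluded Named integer vector of exclusion tallies.
#' @export
setClass("ContextMatrix96",
         slots = c(counts = "matrix", excluded = "integer"))

setValidity("ContextMatrix96", function(object) {
  m <- object@counts
  if (ncol(m) != 96L) return("counts must have 96 columns")
  if (!identical(colnames(m), channelLabels()))
    return("column names must equal channelLabels()")
  if (any(m < 0)) return("counts must be nonnegative")
  TRUE
})

#' @describeIn ContextMatrix96-class counts accessor
#' @param x,object A ContextMatrix96.
#' @export
contextCounts <- function(x) x@counts

#' @describeIn ContextMatrix96-class exclusion tallies
#' @export
excludedCounts <- function(x) x@excluded

setMethod("show", "ContextMatrix96", function(object) {
  cat("ContextMatrix96:", nrow(object@counts), "sample(s) x 96 channels;",
      sum(object@counts), "substitutions,",
      sum(object@excluded), "excluded\n")
})

#' SignatureSet: column-stochastic mutational signature profiles
#'
#' A rank-k factorization of a [ContextMatrix96-class]: k signature
#' profiles over the 96 channels (each column sums to 1), the cophenetic
#' correlation of the consensus clustering at this rank, and optional
#' annotations against a reference SBS catalog.
#'
#' @slot profiles 96 x k nonnegative matrix, columns summing to 1.
#' @slot cophenetic Cophenetic correlation coefficient in [0, 1].
#' @slot annotations DataFrame with columns \code{signature},
#'   \code{best_match}, \code{cosine} (zero rows until
#'   [annotateSignatures()] is called).
#' @export
setClass("SignatureSet",
         slots = c(profiles = "matrix", cophenetic = "numeric",
                   annotations = "DataFrame"))

setValidity("SignatureSet", function(object) {
  p <- object@profiles
  if (nrow(p) != 96L) return("profiles must have 96 rows")
  if (ncol(p) < 1L) return("rank must be >= 1")
  if (any(p < 0)) return("profiles must be nonnegative")
  cs <- colSums(p)
  if (any(abs(cs - 1) > 1e-6 & cs > 0))
    return("profile columns must sum to 1")
  TRUE
})

#' @describeIn SignatureSet-class profile matrix accessor
#' @param x,object A SignatureSet.
#' @export
signatureProfiles <- function(x) x@profiles

#' @describeIn SignatureSet-class number of signatures (the rank k)
#' @export
nSignatures <- function(x) ncol(x@profiles)

#' @describeIn SignatureSet-class cophenetic correlation at this rank
#' @export
copheneticCoefficient <- function(x) x@cophenetic

#' @describeIn SignatureSet-class catalog annotations (may be empty)
#' @export
signatureAnnotations <- function(x) x@annotations

setMethod("show", "SignatureSet", function(object) {
  cat("SignatureSet with", ncol(object@profiles), "signature(s);",
      "cophenetic =", format(object@cophenetic, digits = 3), "\n")
  if (nrow(object@annotations)) {
    a <- object@annotations
    cat(paste0("  ", a$signature, " -> ", a$best_match,
               " (cos ", format(a$cosine, nsmall = 3), ")", collapse = "\n"),
        "\n")
  }
})

#' ExposureMatrix: per-sample signature exposures
#'
#' Nonnegative per-sample signature activities in mutation-count units,
#' fitted by non-negative least squares against fixed profiles, plus the
#' per-sample Euclidean reconstruction residual.
#'
#' @slot exposures samples x k nonnegative matrix.
#' @slot residual Per-sample residual norms.
#' @export
setClass("ExposureMatrix",
         slots = c(exposures = "matrix", residual = "numeric"))

setValidity("ExposureMatrix", function(object) {
  if (any(object@exposures < -1e-12)) return("exposures must be nonnegative")
  if (length(object@residual) != nrow(object@exposures))
    return("one residual per sample required")
  TRUE
})

#' @describeIn ExposureMatrix-class exposures accessor
#' @param x,object An ExposureMatrix.
#' @export
exposures <- function(x) x@exposures

#' @describeIn ExposureMatrix-class per-sample reconstruction residuals
#' @export
exposureResiduals <- function(x) x@residual

setMethod("show", "ExposureMatrix", function(object) {
  cat("ExposureMatrix:", nrow(object@exposures), "sample(s) x",
      ncol(object@exposures), "signature(s); median residual",
      format(stats::median(object@residual), digits = 3), "\n")
})
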