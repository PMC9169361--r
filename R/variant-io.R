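#' Default MAF column mapping
#'
#' Maps MutationTable record fields to the conventional MAF header names.
#' Override individual entries to read files with non-standard headers.
#'
#' @param ... Named overrides, e.g. \code{sample_id = "Sample"}.
#' @return Named character vector field -> column name.
#' @export
mafColumns <- function(...) {
  cols <- c(sample_id = "Tumor_Sample_Barcode",
            chrom = "Chromosome",
            pos = "Start_Position",
            ref_allele = "Reference_Allele",
            alt_allele = "Tumor_Seq_Allele2",
            variant_classification = "Variant_Classification",
            gene_symbol = "Hugo_Symbol")
  ov <- c(...)
  cols[names(ov)] <- ov
  cols
}

#' Read MAF-format somatic mutation calls
#'
#' Parses a tab-separated MAF file (header row; lines starting with '#'
#' skipped). gene_symbol is optional in the file; all other mapped
#' columns are required. Rows whose coordinate cannot be parsed as a
#' positive integer are rejected with their row numbers in a warning.
#'
#' @param path Path to the MAF file.
#' @param columns Column mapping as produced by [mafColumns()].
#' @return A [MutationTable-class]; an empty file yields an empty table.
#' @examples
#' maf <- system.file("extdata", "example.maf", package = "ApobecSig")
#' readMAF(maf)
#' @export
readMAF <- function(path, columns = mafColumns()) {
  raw <- utils::read.delim(path, comment.char = "#",
                           colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  required <- setdiff(names(columns), "gene_symbol")
  absent <- columns[required][!(columns[required] %in% colnames(raw))]
  if (length(absent))
    stop("MAF file is missing required column(s): ",
         paste(absent, collapse = ", "))
  if (nrow(raw) == 0L)
    return(mutationTable(character(), character(), integer(),
                         character(), character()))
  pos <- suppressWarnings(as.integer(raw[[columns["pos"]]]))
  bad <- is.na(pos) | pos < 1L
  if (any(bad)) {
    warning("rejected ", sum(bad), " row(s) with unparseable coordinates: ",
            paste(utils::head(which(bad), 10L), collapse = ", "))
    raw <- raw[!bad, , drop = FALSE]
    pos <- pos[!bad]
  }
  gene <- if (columns["gene_symbol"] %in% colnames(raw))
    raw[[columns["gene_symbol"]]] else NA_character_
  mutationTable(sample_id = raw[[columns["sample_id"]]],
                chrom = raw[[columns["chrom"]]],
                pos = pos,
                ref_allele = raw[[columns["ref_allele"]]],
                alt_allele = raw[[columns["alt_allele"]]],
                variant_classification = raw[[columns["variant_classification"]]],
                gene_symbol = gene)
}

#' Write a MutationTable as MAF-format text
#'
#' @param muts A [MutationTable-class].
#' @param path Output file path.
#' @param columns Column mapping as produced by [mafColumns()].
#' @return Invisibly, the path.
#' @export
writeMAF <- function(muts, path, columns = mafColumns()) {
  rec <- mutationRecords(muts)
  out <- data.frame(rec$gene_symbol, rec$sample_id, rec$chrom, rec$pos,
                    rec$ref_allele, rec$alt_allele,
                    rec$variant_classification,
                    stringsAsFactors = FALSE, check.names = FALSE)
  colnames(out) <- columns[c("gene_symbol", "sample_id", "chrom", "pos",
                             "ref_allele", "alt_allele",
                             "variant_classification")]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Resolve a reference argument to a named DNAStringSet
#' @noRd
.asReference <- function(reference) {
  if (is(reference, "DNAStringSet")) ref <- reference
  else if (is.character(reference) && length(reference) == 1L &&
           file.exists(reference))
    ref <- Biostrings::readDNAStringSet(reference)
  else if (is.character(reference))
    ref <- Biostrings::DNAStringSet(reference)
  else stop("reference must be a DNAStringSet, a FASTA path, ",
            "or a named character vector of sequences")
  if (is.null(names(ref)) || any(!nzchar(names(ref))))
    stop("reference contigs must be named")
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}

#' Match record contigs against reference names
#' @noRd
.matchContig <- function(chrom, refNames, chrTolerant = FALSE) {
  idx <- match(chrom, refNames)
  if (chrTolerant) {
    miss <- is.na(idx)
    idx[miss] <- match(sub("^chr", "", chrom[miss]),
                       sub("^chr", "", refNames))
  }
  if (anyNA(idx)) {
    bad <- unique(chrom[is.na(idx)])
    stop("contig(s) absent from reference: ", paste(bad, collapse = ", "))
  }
  idx
}

#' Attach reference sequence context to SNV records
#'
#' For every SNV, extracts the reference window pos-flank .. pos+flank
#' (1-based, inclusive) as a context string of length 2*flank+1; windows
#' truncated at contig ends are padded with 'N'. Records whose reference
#' base disagrees with the recorded ref_allele are flagged
#' (\code{ref_mismatch}) and excluded from all downstream motif counting
#' rather than silently corrected; the flagged count is reported in a
#' message. Indels and multi-nucleotide variants keep an NA context.
#'
#' @param muts A [MutationTable-class].
#' @param reference A [Biostrings::DNAStringSet], FASTA path, or named
#'   character vector of contig sequences.
#' @param flank Number of bases on each side (default 20).
#' @param chrTolerant If TRUE, contig matching ignores a "chr" prefix.
#' @return The MutationTable with contexts attached.
#' @export
attachContext <- function(muts, reference, flank = 20L, chrTolerant = FALSE) {
  stopifnot(flank >= 1L)
  ref <- .asReference(reference)
  rec <- mutationRecords(muts)
  if (nrow(rec) == 0L) return(muts)
  idx <- .matchContig(rec$chrom, names(ref), chrTolerant)
  snv <- .isSNV(rec$ref_allele, rec$alt_allele)
  refChar <- as.character(ref)
  widths <- nchar(refChar)

  ctx <- rep(NA_character_, nrow(rec))
  i <- which(snv)
  if (length(i)) {
    pos <- rec$pos[i]
    w <- widths[idx[i]]
    if (any(pos > w)) {
      bad <- which(pos > w)[1]
      stop("position ", pos[bad], " beyond end of contig ",
           rec$chrom[i][bad])
    }
    lo <- pmax(1L, pos - flank)
    hi <- pmin(w, pos + flank)
    ctx[i] <- paste0(strrep("N", lo - (pos - flank)),
                     substring(refChar[idx[i]], lo, hi),
                     strrep("N", (pos + flank) - hi))
  }
  mid <- flank + 1L
  refBase <- substr(ctx, mid, mid)
  mismatch <- snv & !is.na(ctx) & refBase != rec$ref_allele
  if (any(mismatch))
    message(sum(mismatch),
            " record(s) flagged: reference base disagrees with ref_allele;",
            " excluded from motif counting")
  rec$context <- ctx
  rec$ref_mismatch <- mismatch
  new("MutationTable", records = rec)
}

#' Canonical substitutions for all eligible SNV records
#'
#' Applies pyrimidine normalization to every SNV with an attached context
#' and no reference mismatch. Records whose triplet contains an N are
#' excluded and tallied.
#'
#' @param muts A [MutationTable-class] with contexts attached.
#' @return A data.frame with one row per record of \code{muts}: columns
#'   of [canonicalSubstitution()] plus \code{usable} (logical) and an
#'   attribute \code{"excluded"} with tallies (non_snv, no_context,
#'   ref_mismatch, n_in_triplet).
#' @export
normalizePyrimidine <- function(muts) {
  rec <- mutationRecords(muts)
  n <- nrow(rec)
  snv <- .isSNV(rec$ref_allele, rec$alt_allele)
  hasCtx <- !is.na(rec$context)
  eligible <- snv & hasCtx & !rec$ref_mismatch

  up <- dn <- rep(NA_character_, n)
  if (any(eligible)) {
    mid <- (nchar(rec$context[eligible]) + 1L) %/% 2L
    up[eligible] <- substr(rec$context[eligible], mid - 1L, mid - 1L)
    dn[eligible] <- substr(rec$context[eligible], mid + 1L, mid + 1L)
  }
  canon <- canonicalSubstitution(rec$ref_allele, rec$alt_allele, up, dn)
  canon$usable <- eligible & !is.na(canon$channel)
  attr(canon, "excluded") <- c(
    non_snv = sum(!snv),
    no_context = sum(snv & !hasCtx),
    ref_mismatch = sum(snv & hasCtx & rec$ref_mismatch),
    n_in_triplet = sum(eligible & is.na(canon$channel)))
  canon
}
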