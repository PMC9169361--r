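#' The 96 trinucleotide substitution channels
#'
#' Somatic single-base substitutions are represented on the pyrimidine
#' strand (reference base C or T); purine-reference calls are
#' reverse-complemented before channel assignment. Channels are ordered
#' substitution-major -- C>A, C>G, C>T, T>A, T>C, T>G -- and, within each
#' substitution, by upstream base A,C,G,T then downstream base A,C,G,T.
#' This is the de-facto catalog ordering, so externally supplied reference
#' catalogs with 96 rows align row-wise without reshuffling.
#'
#' @return Character vector of length 96 with labels of the form
#'   \code{"A[C>A]A"}.
#' @examples
#' head(channelLabels())
#' @export
channelLabels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  out <- character(96L)
  i <- 0L
  for (s in subs) for (up in bases) for (dn in bases) {
    i <- i + 1L
    out[i] <- paste0(up, "[", s, "]", dn)
  }
  out
}

.BASES <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse-complement a base vector
#' @noRd
.compBase <- function(x) unname(.COMP[x])

#' Canonical (pyrimidine-strand) form of single-base substitutions
#'
#' Substitutions with a purine reference base (A or G) are
#' reverse-complemented -- reference, alternate and both flanking bases --
#' so that every substitution is expressed with a C or T reference. The
#' channel index is the 1-based position in [channelLabels()].
#'
#' All four arguments are recycled to a common length. Entries whose
#' triplet contains an N (or a non-ACGT base) get \code{NA} throughout;
#' callers tally such exclusions rather than guessing.
#'
#' @param ref,alt Reference and alternate alleles (single bases).
#' @param upstream,downstream The immediate 5' and 3' neighbours of the
#'   reference base on the same strand as \code{ref}.
#' @return A \code{data.frame} with columns \code{ref} (C or T),
#'   \code{alt}, \code{upstream}, \code{downstream}, \code{channel}
#'   (integer 1..96) and \code{label}.
#' @examples
#' canonicalSubstitution("G", "A", "T", "A")  # WGA forward == TCW reverse
#' @export
canonicalSubstitution <- function(ref, alt, upstream, downstream) {
  n <- max(length(ref), length(alt), length(upstream), length(downstream))
  ref <- rep_len(toupper(ref), n)
  alt <- rep_len(toupper(alt), n)
  upstream <- rep_len(toupper(upstream), n)
  downstream <- rep_len(toupper(downstream), n)

  ok <- ref %in% .BASES & alt %in% .BASES &
    upstream %in% .BASES & downstream %in% .BASES & ref != alt
  flip <- ok & ref %in% c("A", "G")

  cref <- ref; calt <- alt; cup <- upstream; cdn <- downstream
  cref[flip] <- .compBase(ref[flip])
  calt[flip] <- .compBase(alt[flip])
  # reverse complement swaps the flanks
  cup[flip] <- .compBase(downstream[flip])
  cdn[flip] <- .compBase(upstream[flip])

  subIdx <- rep(NA_integer_, n)
  subKey <- paste0(cref, ">", calt)
  subIdx[ok] <- match(subKey[ok],
                      c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"))
  upIdx <- match(cup, .BASES)
  dnIdx <- match(cdn, .BASES)
  channel <- (subIdx - 1L) * 16L + (upIdx - 1L) * 4L + dnIdx
  channel[!ok] <- NA_integer_

  bad <- is.na(channel)
  cref[bad] <- NA_character_; calt[bad] <- NA_character_
  cup[bad] <- NA_character_; cdn[bad] <- NA_character_

  data.frame(ref = cref, alt = calt, upstream = cup, downstream = cdn,
             channel = channel,
             label = ifelse(bad, NA_character_, channelLabels()[channel]),
             stringsAsFactors = FALSE)
}
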