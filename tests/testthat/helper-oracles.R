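# Independent brute-force oracles used to cross-check the package.
# These deliberately share no code with the implementation: plain
# character vectors, explicit loops, and closed-form enumeration.

.oracleComp <- c(A = "T", C = "G", G = "C", T = "A")

# Naive per-record AMES counts: rescans every record and the reference
# character-by-character.
naiveAmesCounts <- function(muts, refSeq, window = 20L) {
  rec <- as.data.frame(mutationRecords(muts))
  bases <- strsplit(refSeq, "")[[1]]
  n <- length(bases)
  out <- list()
  for (sid in unique(rec$sample_id)) {
    rr <- rec[rec$sample_id == sid, ]
    nTcw <- nC <- bgC <- bgTcw <- 0L
    for (i in seq_len(nrow(rr))) {
      ref <- rr$ref_allele[i]; alt <- rr$alt_allele[i]; pos <- rr$pos[i]
      if (nchar(ref) != 1 || nchar(alt) != 1) next
      if (!ref %in% names(.oracleComp) || !alt %in% names(.oracleComp)) next
      if (bases[pos] != ref) next               # reference mismatch
      # pyrimidine-normalize by hand
      if (ref %in% c("G", "A")) {
        cref <- .oracleComp[[ref]]; calt <- .oracleComp[[alt]]
        up <- if (pos < n) .oracleComp[[bases[pos + 1]]] else "N"
        dn <- if (pos > 1) .oracleComp[[bases[pos - 1]]] else "N"
      } else {
        cref <- ref; calt <- alt
        up <- if (pos > 1) bases[pos - 1] else "N"
        dn <- if (pos < n) bases[pos + 1] else "N"
      }
      if (up == "N" || dn == "N") next          # N in triplet: excluded
      if (!(cref == "C" && calt %in% c("T", "G"))) next
      nC <- nC + 1L
      if (up == "T" && dn %in% c("A", "T")) nTcw <- nTcw + 1L
      # background window
      for (p in max(1, pos - window):min(n, pos + window)) {
        if (bases[p] %in% c("C", "G")) bgC <- bgC + 1L
        if (p + 2 <= n) {
          tri <- paste(bases[p:(p + 2)], collapse = "")
          if (tri %in% c("TCA", "TCT", "AGA", "TGA")) bgTcw <- bgTcw + 1L
        }
      }
    }
    out[[sid]] <- c(n_tcw_mut = nTcw, n_c_mut = nC,
                    n_background_c = bgC, n_background_tcw = bgTcw)
  }
  do.call(rbind, out)
}

# Naive 96-channel tally: enumerates the ordering from first principles.
naiveChannelIndex <- function(up, ref, alt, dn) {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  if (ref %in% c("G", "A")) {
    tmp <- up
    up <- .oracleComp[[dn]]; dn <- .oracleComp[[tmp]]
    ref <- .oracleComp[[ref]]; alt <- .oracleComp[[alt]]
  }
  s <- match(paste0(ref, ">", alt), subs)
  (s - 1) * 16 + (match(up, bases) - 1) * 4 + match(dn, bases)
}

naiveContextMatrix <- function(muts, refSeq) {
  rec <- as.data.frame(mutationRecords(muts))
  bases <- strsplit(refSeq, "")[[1]]
  sids <- unique(rec$sample_id)
  m <- matrix(0L, length(sids), 96, dimnames = list(sids, channelLabels()))
  for (i in seq_len(nrow(rec))) {
    ref <- rec$ref_allele[i]; alt <- rec$alt_allele[i]; pos <- rec$pos[i]
    if (nchar(ref) != 1 || nchar(alt) != 1) next
    if (bases[pos] != ref) next
    if (pos == 1 || pos == length(bases)) next
    up <- bases[pos - 1]; dn <- bases[pos + 1]
    if (any(!c(up, ref, alt, dn) %in% names(.oracleComp))) next
    ch <- naiveChannelIndex(up, ref, alt, dn)
    m[rec$sample_id[i], ch] <- m[rec$sample_id[i], ch] + 1L
  }
  m
}

# Two-sided Fisher exact p by direct hypergeometric enumeration.
enumFisherP <- function(both, onlyA, onlyB, neither) {
  n <- both + onlyA + onlyB + neither
  mA <- both + onlyA          # samples mutated in A
  mB <- both + onlyB          # samples mutated in B
  kRange <- max(0, mA + mB - n):min(mA, mB)
  probs <- stats::dhyper(kRange, mB, n - mB, mA)
  pObs <- stats::dhyper(both, mB, n - mB, mA)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Greedy best-pair cosine matching of recovered vs planted profiles.
greedyMatchCosines <- function(Q, P) {
  cs <- outer(seq_len(ncol(Q)), seq_len(ncol(P)),
              Vectorize(function(i, j) cosineSimilarity(Q[, i], P[, j])))
  k <- min(ncol(Q), ncol(P))
  out <- numeric(k)
  for (t in seq_len(k)) {
    ij <- which(cs == max(cs), arr.ind = TRUE)[1, ]
    out[t] <- cs[ij[1], ij[2]]
    cs[ij[1], ] <- -1; cs[, ij[2]] <- -1
  }
  out
}

# Reverse complement of a sequence string.
revcompSeq <- function(s) {
  paste(rev(.oracleComp[strsplit(s, "")[[1]]]), collapse = "")
}
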