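#' Simulate an i.i.d. reference contig
#'
#' Bases are drawn independently with P(C) = P(G) = gc/2 and
#' P(A) = P(T) = (1-gc)/2. The contig is named "chr1" and can be written
#' to FASTA with [Biostrings::writeXStringSet()].
#'
#' @param length Contig length in bases (>= 200, so background windows
#'   have room).
#' @param gcFraction GC content in (0, 1); the degenerate ends 0 and 1
#'   are allowed for testing.
#' @param seed Integer seed; identical seeds give identical sequences.
#' @return A [Biostrings::DNAStringSet] with one contig.
#' @export
simReference <- function(length, gcFraction = 0.5, seed = 1L) {
  if (length < 200L) stop("length must be >= 200")
  if (gcFraction < 0 || gcFraction > 1)
    stop("gcFraction must be in [0, 1]")
  set.seed(as.integer(seed))
  p <- c(A = (1 - gcFraction) / 2, C = gcFraction / 2,
         G = gcFraction / 2, T = (1 - gcFraction) / 2)
  s <- paste(sample(names(p), length, replace = TRUE, prob = p),
             collapse = "")
  ref <- Biostrings::DNAStringSet(s)
  names(ref) <- "chr1"
  ref
}

#' TCW cytosine site positions on both strands
#'
#' Positions (1-based, on the forward strand) of cytosines in a TCW
#' context: forward-strand TCA/TCT (the C mutates) and forward-strand
#' AGA/TGA, i.e. WGA, whose central G is a reverse-strand TCW cytosine.
#'
#' @param reference Reference (see [attachContext()]); first contig used.
#' @return Integer vector of positions.
#' @export
tcwSites <- function(reference) {
  ref <- .asReference(reference)
  s <- strsplit(as.character(ref[[1]]), "", fixed = TRUE)[[1]]
  n <- length(s)
  if (n < 3L) return(integer())
  i <- 2:(n - 1L)
  fwd <- s[i] == "C" & s[i - 1L] == "T" & s[i + 1L] %in% c("A", "T")
  rev <- s[i] == "G" & s[i - 1L] %in% c("A", "T") & s[i + 1L] == "A"
  i[fwd | rev]
}

#' Plant APOBEC-weighted cytosine mutations on a reference
#'
#' Each mutation is, with probability \code{apobecWeight}, placed on a
#' uniformly chosen TCW-context cytosine (either strand) and otherwise
#' on a uniformly chosen cytosine (either strand); in both cases it is a
#' C>T or C>G change (equal odds) on the pyrimidine strand, written with
#' forward-strand alleles. Positions are sampled without replacement
#' within each sample. At weight 0 the motif fraction of mutations
#' matches the genomic background, so the expected enrichment score is
#' approximately 1; the score increases monotonically with the weight.
#'
#' @param reference Reference contig(s); first contig is used.
#' @param nSamples Number of samples (default 50).
#' @param mutsPerSample Mutations per sample (default 200).
#' @param apobecWeight Probability a mutation targets a TCW site
#'   (default 0).
#' @param seed Integer seed.
#' @param samplePrefix Sample-id prefix (default "S").
#' @param nGenes Number of pseudo-genes tiled across the contig for
#'   gene-level bookkeeping (default 20).
#' @return List with \code{muts} (a [MutationTable-class], Missense
#'   classification) and \code{truth} (the planted weight, per-record
#'   TCW flags, and site pools).
#' @export
plantMutations <- function(reference, nSamples = 50L,
                           mutsPerSample = 200L, apobecWeight = 0,
                           seed = 1L, samplePrefix = "S", nGenes = 20L) {
  stopifnot(apobecWeight >= 0, apobecWeight <= 1)
  ref <- .asReference(reference)
  s <- strsplit(as.character(ref[[1]]), "", fixed = TRUE)[[1]]
  contig <- names(ref)[1]
  tcw <- tcwSites(ref)
  allC <- which(s %in% c("C", "G"))
  if (length(allC) == 0L) stop("reference contains no cytosines")
  if (apobecWeight > 0 && length(tcw) == 0L)
    stop("reference contains no TCW sites")
  if (mutsPerSample > length(allC))
    stop("requested mutations exceed available cytosine sites")

  set.seed(as.integer(seed))
  recs <- vector("list", nSamples)
  isTcwPick <- vector("list", nSamples)
  for (k in seq_len(nSamples)) {
    fromTcw <- stats::runif(mutsPerSample) < apobecWeight
    pos <- integer(mutsPerSample)
    chosen <- integer(0)
    nT <- sum(fromTcw)
    if (nT > 0) {
      avail <- tcw
      if (nT > length(avail))
        stop("requested TCW mutations exceed available TCW sites")
      pick <- sample(avail, nT)
      pos[fromTcw] <- pick
      chosen <- pick
    }
    if (nT < mutsPerSample) {
      avail <- setdiff(allC, chosen)
      if (mutsPerSample - nT > length(avail))
        stop("requested mutations exceed available cytosine sites")
      pos[!fromTcw] <- sample(avail, mutsPerSample - nT)
    }
    refBase <- s[pos]
    # pyrimidine-strand alt: C>T or C>G with equal odds
    pyrAlt <- sample(c("T", "G"), mutsPerSample, replace = TRUE)
    alt <- ifelse(refBase == "C", pyrAlt, .compBase(pyrAlt))
    gene <- paste0("G", pmin(nGenes, 1L + (pos - 1L) %/%
                               ceiling(length(s) / nGenes)))
    recs[[k]] <- data.frame(
      sample_id = sprintf("%s%03d", samplePrefix, k),
      chrom = contig, pos = pos, ref = refBase, alt = alt, gene = gene,
      stringsAsFactors = FALSE)
    isTcwPick[[k]] <- fromTcw
  }
  all <- do.call(rbind, recs)
  muts <- mutationTable(all$sample_id, all$chrom, all$pos, all$ref,
                        all$alt, "Missense_Mutation", all$gene)
  list(muts = muts,
       truth = list(apobecWeight = apobecWeight,
                    fromTcw = unlist(isTcwPick),
                    tcwSites = tcw, cytosineSites = allC))
}

#' Simulate 96-channel counts from planted signatures
#'
#' Sample s draws multinomial(N_s, P %*% H[s, ] / N_s) counts over the
#' 96 channels, where N_s = sum of the sample's exposures.
#'
#' @param P 96 x k column-stochastic signature profile matrix.
#' @param H samples x k nonnegative integer exposure matrix.
#' @param seed Integer seed.
#' @return A [ContextMatrix96-class].
#' @export
simSignatureCounts <- function(P, H, seed = 1L) {
  if (nrow(P) != 96L) stop("P must have 96 rows")
  if (ncol(H) != ncol(P)) stop("H columns must match P signatures")
  if (any(abs(colSums(P) - 1) > 1e-6)) stop("P must be column-stochastic")
  if (any(H < 0)) stop("H must be nonnegative")
  set.seed(as.integer(seed))
  m <- matrix(0L, nrow(H), 96L,
              dimnames = list(rownames(H) %||%
                                sprintf("S%03d", seq_len(nrow(H))),
                              channelLabels()))
  for (sIdx in seq_len(nrow(H))) {
    N <- sum(H[sIdx, ])
    if (N == 0) next
    probs <- as.numeric(P %*% H[sIdx, ]) / N
    m[sIdx, ] <- as.integer(stats::rmultinom(1L, round(N), probs))
  }
  new("ContextMatrix96", counts = m,
      excluded = c(non_snv = 0L, no_context = 0L, ref_mismatch = 0L,
                   n_in_triplet = 0L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a log2-scale expression matrix with planted group shifts
#'
#' Gene baselines are Normal(baselineMean, baselineSd); per-cell noise
#' is Normal(0, noiseSd). Genes in each shifted set are raised by
#' \code{effect} log2 units in the first group.
#'
#' @param nGenes Number of genes (named G0001...).
#' @param groupSizes Integer vector of length 2: samples per group (A
#'   gets the shift).
#' @param shiftSets Named list of gene-name vectors to shift (must be
#'   subsets of the gene universe).
#' @param effect Shift in log2 units (default 2).
#' @param noiseSd Per-cell noise SD (default 1).
#' @param baselineMean,baselineSd Gene baseline distribution (5, 2).
#' @param seed Integer seed.
#' @return List: \code{expr} (matrix genes x samples, "scale" = log2),
#'   \code{groups} (character vector "A"/"B" per sample), \code{truth}
#'   (shifted sets and effect).
#' @export
simExpression <- function(nGenes = 500L, groupSizes = c(25L, 25L),
                          shiftSets = list(), effect = 2,
                          noiseSd = 1, baselineMean = 5, baselineSd = 2,
                          seed = 1L) {
  stopifnot(length(groupSizes) == 2L, all(groupSizes >= 1L))
  genes <- sprintf("G%04d", seq_len(nGenes))
  bad <- unlist(lapply(shiftSets, setdiff, y = genes))
  if (length(bad))
    stop("shifted set gene(s) outside the universe: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  set.seed(as.integer(seed))
  nS <- sum(groupSizes)
  groups <- rep(c("A", "B"), groupSizes)
  base <- stats::rnorm(nGenes, baselineMean, baselineSd)
  expr <- matrix(base, nGenes, nS) +
    matrix(stats::rnorm(nGenes * nS, 0, noiseSd), nGenes, nS)
  dimnames(expr) <- list(genes, sprintf("%s%03d", groups,
                                        seq_len(nS)))
  for (set in shiftSets)
    expr[set, groups == "A"] <- expr[set, groups == "A"] + effect
  attr(expr, "scale") <- "log2"
  list(expr = expr, groups = groups,
       truth = list(shiftSets = shiftSets, effect = effect))
}

#' Simulate planted exposure matrices
#'
#' Assigns each sample a primary signature (round-robin over the k
#' signatures) carrying \code{primaryWeight} of its mutations, the
#' remainder split evenly over the other signatures. This reproduces the
#' dominant-signature structure of real cohorts, which consensus-based
#' rank selection relies on.
#'
#' @param nSamples Number of samples.
#' @param k Number of signatures.
#' @param totalMutations Mutations per sample (default 2000).
#' @param primaryWeight Weight of the primary signature (default 0.7).
#' @param seed Integer seed (shuffles the primary assignment).
#' @return List: \code{H} (samples x k integer exposures), \code{primary}
#'   (per-sample primary signature index).
#' @export
simExposures <- function(nSamples, k, totalMutations = 2000L,
                         primaryWeight = 0.7, seed = 1L) {
  stopifnot(k >= 1L, primaryWeight >= 0, primaryWeight <= 1)
  set.seed(as.integer(seed))
  primary <- sample(rep_len(seq_len(k), nSamples))
  H <- matrix(if (k > 1L) totalMutations * (1 - primaryWeight) / (k - 1L)
              else 0, nSamples, k)
  H[cbind(seq_len(nSamples), primary)] <- totalMutations * primaryWeight
  H <- round(H)
  list(H = H, primary = primary)
}
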