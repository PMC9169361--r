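#' Build a 96-channel context matrix from mutation calls
#'
#' Every usable SNV (context attached, no reference mismatch, no N in the
#' triplet) increments exactly one (sample, channel) cell after
#' pyrimidine normalization. Excluded records are tallied.
#'
#' @param muts A [MutationTable-class] with contexts attached.
#' @return A [ContextMatrix96-class].
#' @export
buildContextMatrix <- function(muts) {
  rec <- mutationRecords(muts)
  sids <- unique(rec$sample_id)
  canon <- normalizePyrimidine(muts)
  m <- matrix(0L, nrow = length(sids), ncol = 96L,
              dimnames = list(sids, channelLabels()))
  use <- canon$usable
  if (any(use)) {
    tab <- table(factor(rec$sample_id[use], sids),
                 factor(canon$channel[use], seq_len(96L)))
    m[] <- as.integer(tab)
  }
  new("ContextMatrix96", counts = m, excluded = attr(canon, "excluded"))
}

# ---- NMF with Kullback-Leibler objective ---------------------------------

#' One multiplicative-update NMF run (KL objective)
#' @noRd
.nmfRun <- function(X, k, maxIter = 2000L, tol = 1e-6, eps = 1e-10) {
  m <- nrow(X); n <- ncol(X)
  W <- matrix(stats::runif(m * k, 0.1, 1), m, k)
  H <- matrix(stats::runif(k * n, 0.1, 1), k, n)
  obj <- Inf
  for (it in seq_len(maxIter)) {
    WH <- W %*% H + eps
    H <- H * (crossprod(W, X / WH)) / (colSums(W) + eps)
    WH <- W %*% H + eps
    W <- W * ((X / WH) %*% t(H)) /
      matrix(rowSums(H), m, k, byrow = TRUE)
    if (it %% 10L == 0L || it == maxIter) {
      WH <- W %*% H + eps
      newObj <- sum(X * log((X + eps) / WH) - X + WH)
      if (is.finite(obj) && abs(obj - newObj) < tol * max(1, abs(obj)))
        { obj <- newObj; break }
      obj <- newObj
    }
  }
  # absorb scale into H so profile columns sum to 1
  cs <- colSums(W)
  cs[cs == 0] <- 1
  W <- sweep(W, 2L, cs, "/")
  H <- H * cs
  list(W = W, H = H, objective = obj)
}

#' Cophenetic correlation of a consensus matrix
#' @noRd
.copheneticFromConsensus <- function(consensus) {
  d <- stats::as.dist(1 - consensus)
  if (max(d) < 1e-12) return(1)           # perfect consensus
  hc <- stats::hclust(d, method = "average")
  r <- stats::cor(d, stats::cophenetic(hc))
  if (is.na(r)) 1 else r
}

#' Extract de novo mutational signatures by NMF
#'
#' Factorizes the channels x samples count matrix V ~ P H for each rank
#' k in \code{kRange}, using multiplicative-update NMF under the
#' Kullback-Leibler objective with \code{nRestarts} seeded random
#' initializations per rank. The best-objective factorization is
#' retained; profiles are column-normalized to sum 1 with the scale
#' absorbed into the exposures. Rank stability is measured Brunet-style:
#' each restart assigns every sample to its dominant signature, the
#' consensus matrix averages co-assignment over restarts, and the
#' cophenetic correlation compares consensus distances with
#' average-linkage dendrogram distances (defined as 1 at k = 1 and for a
#' perfect consensus).
#'
#' @param cm A [ContextMatrix96-class].
#' @param kRange Integer vector of candidate ranks (default 2:6).
#' @param nRestarts Random restarts per rank (default 10, minimum 2).
#' @param seed Master seed; per-(k, restart) streams are derived from it
#'   deterministically, so identical inputs give identical outputs.
#' @return Named list (one element per k, names "k") of
#'   [SignatureSet-class] candidates, each carrying its cophenetic
#'   coefficient; attribute \code{"exposures"} holds the best-fit raw
#'   exposure matrices per rank.
#' @export
extractSignatures <- function(cm, kRange = 2:6, nRestarts = 10L,
                              seed = 1L) {
  stopifnot(is(cm, "ContextMatrix96"))
  if (nRestarts < 2L) stop("nRestarts must be >= 2")
  V <- t(contextCounts(cm))                 # 96 x samples
  nonzero <- colSums(V) > 0
  if (max(kRange) > min(96L, sum(nonzero)))
    stop("max(kRange) exceeds min(96, number of samples with mutations)")
  storage.mode(V) <- "double"

  out <- vector("list", length(kRange))
  names(out) <- as.character(kRange)
  expo <- vector("list", length(kRange))
  for (ki in seq_along(kRange)) {
    k <- kRange[ki]
    best <- NULL
    consensus <- matrix(0, ncol(V), ncol(V))
    for (r in seq_len(nRestarts)) {
      set.seed((as.integer(seed) + 7919L * k + 104729L * r) %%
                 .Machine$integer.max)
      fit <- if (k == 1L) {
        W <- matrix(rowSums(V) / sum(V), ncol = 1)
        H <- matrix(colSums(V), nrow = 1)
        list(W = W, H = H,
             objective = sum(V * log((V + 1e-10) / (W %*% H + 1e-10)) -
                               V + W %*% H))
      } else .nmfRun(V, k)
      dom <- apply(fit$H, 2L, which.max)
      consensus <- consensus + outer(dom, dom, "==")
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
    consensus <- consensus / nRestarts
    coph <- if (k == 1L) 1 else .copheneticFromConsensus(consensus)
    P <- best$W
    colnames(P) <- paste0("Sig", seq_len(k))
    rownames(P) <- channelLabels()
    out[[ki]] <- new("SignatureSet", profiles = P, cophenetic = coph,
                     annotations = DataFrame(signature = character(),
                                             best_match = character(),
                                             cosine = numeric()))
    E <- t(best$H)
    dimnames(E) <- list(colnames(V), colnames(P))
    expo[[ki]] <- E
  }
  attr(out, "exposures") <- stats::setNames(expo, names(out))
  out
}

#' Cophenetic coefficients of a candidate list
#'
#' @param candidates The list returned by [extractSignatures()].
#' @return Named numeric vector, names = ranks.
#' @export
copheneticScores <- function(candidates) {
  vapply(candidates, copheneticCoefficient, numeric(1))
}

#' Select the factorization rank from cophenetic coefficients
#'
#' The optimal rank is taken where the cophenetic correlation begins to
#' drop: the function returns the largest k immediately before the first
#' successive drop exceeding \code{dropThreshold}. When no drop exceeds
#' the threshold it falls back to the argmax (ties broken toward the
#' smaller rank).
#'
#' @param cophenetics Named numeric vector of cophenetic coefficients
#'   over a contiguous rank range (names = ranks), or the candidate list
#'   from [extractSignatures()].
#' @param dropThreshold Minimum successive drop treated as significant
#'   (default 0.05).
#' @return The selected rank (integer).
#' @examples
#' selectRank(c(`2` = 0.99, `3` = 0.98, `4` = 0.80, `5` = 0.78))
#' @export
selectRank <- function(cophenetics, dropThreshold = 0.05) {
  if (is.list(cophenetics)) cophenetics <- copheneticScores(cophenetics)
  ks <- as.integer(names(cophenetics))
  if (anyNA(ks)) ks <- seq_along(cophenetics)
  o <- order(ks)
  ks <- ks[o]; cph <- unname(cophenetics[o])
  if (length(ks) < 2L) {
    warning("fewer than 2 ranks supplied; returning the single rank")
    return(ks[1])
  }
  drops <- cph[-length(cph)] - cph[-1]
  hit <- which(drops > dropThreshold)
  if (length(hit)) ks[hit[1]] else ks[which.max(cph)]
}

#' Cosine similarity between two nonnegative vectors
#'
#' @param a,b Numeric vectors of equal length.
#' @return Cosine similarity in [0, 1] for nonnegative inputs; 0 when
#'   either vector is all-zero.
#' @export
cosineSimilarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Annotate de novo signatures against a reference catalog
#'
#' Each signature is labeled with the catalog profile of maximal cosine
#' similarity; matches below \code{minCosine} are labeled "unassigned".
#' Similarities are reported to 3 decimals.
#'
#' @param sigs A [SignatureSet-class].
#' @param catalog 96 x m numeric matrix of reference profiles (columns
#'   named, rows in the [channelLabels()] ordering), e.g. from
#'   [readSignatureCatalog()] or [exampleCatalog()].
#' @param minCosine Minimum similarity for an assignment (default 0.8).
#' @return The SignatureSet with its annotations slot filled.
#' @export
annotateSignatures <- function(sigs, catalog, minCosine = 0.8) {
  stopifnot(is(sigs, "SignatureSet"), ncol(catalog) >= 1L,
            nrow(catalog) == 96L)
  P <- signatureProfiles(sigs)
  best <- character(ncol(P)); sim <- numeric(ncol(P))
  for (j in seq_len(ncol(P))) {
    cs <- apply(catalog, 2L, cosineSimilarity, a = P[, j])
    i <- which.max(cs)
    sim[j] <- round(cs[i], 3L)
    best[j] <- if (cs[i] >= minCosine) colnames(catalog)[i] else "unassigned"
  }
  sigs@annotations <- DataFrame(signature = colnames(P),
                                best_match = best, cosine = sim)
  sigs
}

# ---- non-negative least squares ------------------------------------------

#' Lawson-Hanson active-set NNLS: min ||A x - b||_2 s.t. x >= 0
#' @noRd
.nnls <- function(A, b, tol = 1e-10) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  w <- as.vector(crossprod(A, b))
  iter <- 0L
  while (any(!passive) &&
         max(w[!passive]) > tol * max(1, max(abs(w))) &&
         iter < 30L * n) {
    iter <- iter + 1L
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      s <- numeric(n)
      s[passive] <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      s[is.na(s)] <- 0
      if (all(s[passive] > tol)) { x <- s; break }
      neg <- passive & s <= tol
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    w <- as.vector(crossprod(A, b - A %*% x))
  }
  x
}

#' Fit per-sample signature exposures by NNLS
#'
#' For each sample's 96-channel count vector v, solves
#' min ||v - P h||_2 subject to h >= 0 with fixed column-stochastic
#' profiles P (Lawson-Hanson active set). Exposures are in
#' mutation-count units, so rowSums approximate each sample's SNV count
#' when the fit is good; zero-count samples get all-zero exposures and
#' zero residual.
#'
#' @param cm A [ContextMatrix96-class] (or a samples x 96 matrix).
#' @param sigs A [SignatureSet-class] (or a 96 x k profile matrix).
#' @return An [ExposureMatrix-class].
#' @export
fitExposuresNNLS <- function(cm, sigs) {
  V <- if (is(cm, "ContextMatrix96")) contextCounts(cm) else cm
  P <- if (is(sigs, "SignatureSet")) signatureProfiles(sigs) else sigs
  stopifnot(ncol(V) == 96L, nrow(P) == 96L)
  E <- matrix(0, nrow(V), ncol(P),
              dimnames = list(rownames(V), colnames(P)))
  res <- numeric(nrow(V))
  for (s in seq_len(nrow(V))) {
    v <- as.numeric(V[s, ])
    if (sum(v) == 0) next
    h <- .nnls(P, v)
    E[s, ] <- h
    res[s] <- sqrt(sum((v - as.vector(P %*% h))^2))
  }
  new("ExposureMatrix", exposures = E, residual = res)
}

#' Read a reference signature catalog from TSV
#'
#' Expects 96 data rows in the fixed [channelLabels()] ordering: a first
#' column of channel labels and one column per named signature, each
#' summing to 1 (tolerance 1e-6).
#'
#' @param path TSV path.
#' @return 96 x m numeric matrix, rownames = channel labels.
#' @export
readSignatureCatalog <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(tab) != 96L) stop("catalog must have 96 rows")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  if (!identical(rownames(m), channelLabels()))
    stop("catalog rows must follow channelLabels() ordering")
  if (any(abs(colSums(m) - 1) > 1e-6))
    stop("catalog profiles must each sum to 1")
  m
}

#' A small synthetic reference catalog
#'
#' Four synthetic column-stochastic profiles for testing and examples:
#' an APOBEC-like profile concentrated on T[C>T]W and T[C>G]W channels,
#' a deamination-like profile on N[C>T]G channels, a flat profile, and a
#' T>C-heavy profile. These are constructed in code and are not COSMIC
#' signatures; supply a real SBS table via [readSignatureCatalog()] for
#' production annotation.
#'
#' @return 96 x 4 matrix with columns SynAPOBEC, SynDeamination, SynFlat,
#'   SynTC.
#' @export
exampleCatalog <- function() {
  lab <- channelLabels()
  mk <- function(weights) weights / sum(weights)
  apobec <- numeric(96)
  apobec[lab %in% c("T[C>T]A", "T[C>T]T")] <- 0.3
  apobec[lab %in% c("T[C>G]A", "T[C>G]T")] <- 0.2
  deam <- numeric(96)
  deam[grepl("\\[C>T\\]G$", lab)] <- 1
  flat <- rep(1, 96)
  tc <- numeric(96)
  tc[grepl("\\[T>C\\]", lab)] <- 1
  m <- cbind(SynAPOBEC = mk(apobec), SynDeamination = mk(deam),
             SynFlat = mk(flat), SynTC = mk(tc))
  rownames(m) <- lab
  m
}
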