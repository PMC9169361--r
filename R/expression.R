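#' Read a gene-by-sample expression matrix from TSV
#'
#' First column = gene identifiers (uppercased, must be unique after
#' uppercasing), remaining columns = samples. The scale tag records
#' whether values are log2-transformed or linear.
#'
#' @param path TSV path with header row.
#' @param scale "log2" (default) or "linear".
#' @return Numeric matrix genes x samples with attribute "scale".
#' @export
readExpressionMatrix <- function(path, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  genes <- toupper(tab[[1]])
  if (anyDuplicated(genes)) stop("gene identifiers must be unique")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- genes
  if (any(apply(m, 1L, function(r) all(is.na(r)))))
    stop("all-missing gene rows are not allowed")
  attr(m, "scale") <- scale
  m
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path.
#' @return Named list of gene-symbol character vectors.
#' @export
readGMT <- function(path) {
  fgsea::gmtPathways(path)
}

#' Read a linear signature (gene, coefficient) from TSV
#'
#' @param path TSV path with columns \code{gene} and \code{coefficient}.
#' @return Named numeric vector of coefficients.
#' @export
readLinearSignature <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "coefficient") %in% colnames(tab)))
    stop("signature file needs columns 'gene' and 'coefficient'")
  coefs <- stats::setNames(as.numeric(tab$coefficient),
                           toupper(tab$gene))
  if (any(!is.finite(coefs)) || any(coefs == 0))
    stop("coefficients must be finite and nonzero")
  coefs
}

#' Single-sample gene set enrichment (ssGSEA)
#'
#' For each sample, genes are ordered by decreasing expression and the
#' enrichment score is the sum over that ordering of the difference
#' between the weighted in-set empirical CDF (weights rank^alpha, the
#' top gene carrying the largest rank) and the uniform out-of-set CDF.
#' Ties are broken by stable input gene order, so results are
#' deterministic. Scores are rank-based and therefore invariant to any
#' strictly monotone per-sample transform of expression.
#'
#' @param expr Numeric matrix genes x samples.
#' @param sets Named list of gene-symbol vectors (e.g. [readGMT()]).
#' @param alpha Rank-weighting exponent (default 0.25).
#' @param normalize If TRUE, divide all scores by the overall
#'   max - min range across the result (default FALSE: raw enrichment).
#' @return Numeric matrix sets x samples. Sets with fewer than 2 genes
#'   matched in the matrix are skipped with a warning.
#' @export
ssgseaScore <- function(expr, sets, alpha = 0.25, normalize = FALSE) {
  genes <- rownames(expr)
  n <- length(genes)
  matched <- lapply(sets, function(s) which(genes %in% s))
  sizes <- lengths(matched)
  if (any(sizes < 2L)) {
    warning("skipping gene set(s) with < 2 matched genes: ",
            paste(names(sets)[sizes < 2L], collapse = ", "))
    matched <- matched[sizes >= 2L]
  }
  if (!length(matched)) stop("no usable gene sets")
  out <- matrix(NA_real_, length(matched), ncol(expr),
                dimnames = list(names(matched), colnames(expr)))
  for (j in seq_len(ncol(expr))) {
    ord <- order(expr[, j], decreasing = TRUE)   # stable: ties keep input order
    w <- (n - seq_len(n) + 1L)^alpha             # rank weight along the ordering
    inSet <- matrix(FALSE, n, length(matched))
    for (k in seq_along(matched)) inSet[match(matched[[k]], ord), k] <- TRUE
    for (k in seq_along(matched)) {
      hit <- inSet[, k]
      m <- sum(hit)
      ecdfIn <- cumsum(w * hit) / sum(w[hit])
      # degenerate all-genes set: no out-of-set mass
      ecdfOut <- if (m < n) cumsum(!hit) / (n - m) else rep(0, n)
      out[k, j] <- sum(ecdfIn - ecdfOut)
    }
  }
  if (normalize) {
    rng <- max(out) - min(out)
    if (rng > 0) out <- out / rng
  }
  out
}

#' Cytolytic activity (CYT) score
#'
#' Geometric mean of PRF1 and GZMA expression on the linear scale:
#' sqrt((PRF1 + eps) * (GZMA + eps)) with eps = 0.01. Log2 input is
#' back-transformed to linear before scoring.
#'
#' @param expr Numeric matrix genes x samples; scale taken from the
#'   matrix's "scale" attribute unless given.
#' @param scale "linear" or "log2".
#' @param eps Offset floor (default 0.01).
#' @return Named numeric vector of per-sample CYT scores.
#' @export
cytScore <- function(expr, scale = attr(expr, "scale"), eps = 0.01) {
  if (is.null(scale)) scale <- "linear"
  for (g in c("PRF1", "GZMA"))
    if (!g %in% rownames(expr)) stop("gene ", g, " absent from matrix")
  v <- expr[c("PRF1", "GZMA"), , drop = FALSE]
  if (scale == "log2") v <- 2^v
  stats::setNames(sqrt((v[1, ] + eps) * (v[2, ] + eps)), colnames(expr))
}

#' Apply a linear (Cox-coefficient) risk signature
#'
#' Per-sample score = sum over signature genes of coefficient x
#' expression (log2 scale assumed, as fitted). Signature genes absent
#' from the matrix contribute 0 with a warning. The categorical split is
#' at the cohort median by default, or at a fixed threshold.
#'
#' @param expr Numeric matrix genes x samples.
#' @param signature Named numeric vector gene -> coefficient (e.g.
#'   [readLinearSignature()]).
#' @param split "median" or a numeric threshold.
#' @return data.frame: sample_id, score, group ("high"/"low"; high is
#'   score > threshold).
#' @export
applyLinearSignature <- function(expr, signature, split = "median") {
  present <- names(signature) %in% rownames(expr)
  if (!any(present)) stop("no signature genes present in matrix")
  if (any(!present))
    warning("signature gene(s) absent, contributing 0: ",
            paste(names(signature)[!present], collapse = ", "))
  sig <- signature[present]
  score <- as.numeric(crossprod(expr[names(sig), , drop = FALSE], sig))
  thr <- if (identical(split, "median")) stats::median(score)
         else as.numeric(split)
  data.frame(sample_id = colnames(expr), score = score,
             group = ifelse(score > thr, "high", "low"),
             stringsAsFactors = FALSE)
}
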