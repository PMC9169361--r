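#' Variant classification policy
#'
#' The default non-synonymous set covers frameshift and in-frame indels,
#' missense, nonsense, nonstop, splice-site and translation-start-site
#' changes (with the common MAF "_Mutation" spelling aliases); every
#' other observed classification term is treated as synonymous.
#'
#' @param nonsynonymous Character vector of classification terms counted
#'   as non-synonymous.
#' @return Object of class \code{VariantClassPolicy}.
#' @export
variantClassPolicy <- function(nonsynonymous = c(
    "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
    "Missense", "Missense_Mutation", "Nonsense", "Nonsense_Mutation",
    "Nonstop", "Nonstop_Mutation", "Splice_Site",
    "Translation_Start_Site")) {
  structure(list(nonsynonymous = nonsynonymous),
            class = "VariantClassPolicy")
}

#' Classify variants as synonymous / non-synonymous
#'
#' @param muts A [MutationTable-class].
#' @param policy A [variantClassPolicy()].
#' @return Logical vector, TRUE where the record is non-synonymous.
#'   Terms outside the common MAF vocabulary fall through to synonymous
#'   with a warning.
#' @export
classifyVariants <- function(muts, policy = variantClassPolicy()) {
  vc <- mutationRecords(muts)$variant_classification
  known <- c(policy$nonsynonymous, "Silent", "Synonymous", "3'UTR", "5'UTR",
             "3'Flank", "5'Flank", "Intron", "IGR", "RNA",
             "Nonsense_Mediated_Decay", "lincRNA", "Splice_Region",
             "Targeted_Region", "De_novo_Start_InFrame",
             "De_novo_Start_OutOfFrame")
  unknown <- setdiff(unique(vc), known)
  if (length(unknown))
    warning("unknown classification term(s) treated as synonymous: ",
            paste(unknown, collapse = ", "))
  vc %in% policy$nonsynonymous
}

#' Tumor mutational burden per sample
#'
#' TMB = non-synonymous mutation count / exome size, in mutations per
#' megabase, with 38 Mb as the default whole-exome size estimate.
#'
#' @param muts A [MutationTable-class].
#' @param policy A [variantClassPolicy()].
#' @param exomeSizeMb Captured exome size in Mb (default 38).
#' @return data.frame: sample_id, n_nonsyn, n_syn, tmb. Only samples
#'   present in the table appear.
#' @examples
#' # 38 non-synonymous calls over 38 Mb -> exactly 1 mutation/Mb
#' @export
computeTMB <- function(muts, policy = variantClassPolicy(),
                       exomeSizeMb = 38) {
  if (exomeSizeMb <= 0) stop("exomeSizeMb must be > 0")
  rec <- mutationRecords(muts)
  sids <- unique(rec$sample_id)
  ns <- classifyVariants(muts, policy)
  f <- factor(rec$sample_id, sids)
  nNon <- as.integer(tapply(ns, f, sum, default = 0L))
  nSyn <- as.integer(tapply(!ns, f, sum, default = 0L))
  data.frame(sample_id = sids, n_nonsyn = nNon, n_syn = nSyn,
             tmb = nNon / exomeSizeMb,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' DDR pathway -> gene starter map
#'
#' Gene-to-pathway assignments across the seven DNA damage response
#' pathways (BER, NER, MMR, HRR, NHEJ, FA, TLS). The bundled starter map
#' covers ten frequently mutated DDR genes and is deliberately partial;
#' supply a complete map via [readPathwayMap()] for production use.
#'
#' @return Named list pathway -> character vector of gene symbols.
#' @export
defaultDdrPathways <- function() {
  readPathwayMap(system.file("extdata", "ddr_pathways.tsv",
                             package = "ApobecSig"))
}

#' Read a pathway->gene map from TSV (columns: pathway, gene)
#'
#' @param path TSV path with a header row.
#' @return Named list pathway -> character vector of gene symbols.
#' @export
readPathwayMap <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("pathway", "gene") %in% colnames(tab)))
    stop("pathway map needs columns 'pathway' and 'gene'")
  split(tab$gene, tab$pathway)
}

#' DDR mutation status per sample
#'
#' A pathway is flagged mutated in a sample when any of its genes
#' carries at least one non-silent (non-synonymous) mutation; a sample
#' is DDR-Mut when any pathway is flagged, DDR-WT otherwise. Genes may
#' belong to multiple pathways.
#'
#' @param muts A [MutationTable-class] with gene symbols.
#' @param pathways Named list pathway -> gene symbols
#'   (default [defaultDdrPathways()]).
#' @param policy A [variantClassPolicy()].
#' @return data.frame: sample_id, overall ("DDR-Mut"/"DDR-WT"), and one
#'   logical column per pathway.
#' @export
ddrStatus <- function(muts, pathways = defaultDdrPathways(),
                      policy = variantClassPolicy()) {
  if (length(pathways) == 0L) stop("pathway map is empty")
  rec <- mutationRecords(muts)
  sids <- unique(rec$sample_id)
  ns <- classifyVariants(muts, policy)
  flags <- sapply(pathways, function(genes) {
    hit <- ns & rec$gene_symbol %in% genes
    as.logical(tapply(hit, factor(rec$sample_id, sids), any,
                      default = FALSE))
  })
  flags <- matrix(flags, nrow = length(sids),
                  dimnames = list(NULL, names(pathways)))
  overall <- ifelse(rowSums(flags) > 0, "DDR-Mut", "DDR-WT")
  cbind(data.frame(sample_id = sids, overall = overall,
                   stringsAsFactors = FALSE),
        as.data.frame(flags))
}

#' Binary gene-by-sample mutation matrix
#'
#' Collapses records to binary presence of a non-synonymous mutation per
#' gene and sample (multiple hits in one gene count once).
#'
#' @param muts A [MutationTable-class] with gene symbols.
#' @param policy A [variantClassPolicy()].
#' @return Logical matrix genes x samples.
#' @export
mutationMatrix <- function(muts, policy = variantClassPolicy()) {
  rec <- mutationRecords(muts)
  ns <- classifyVariants(muts, policy)
  keep <- ns & !is.na(rec$gene_symbol)
  genes <- unique(rec$gene_symbol[keep])
  sids <- unique(rec$sample_id)
  m <- matrix(FALSE, length(genes), length(sids),
              dimnames = list(genes, sids))
  if (any(keep))
    m[cbind(match(rec$gene_symbol[keep], genes),
            match(rec$sample_id[keep], sids))] <- TRUE
  m
}

#' Pairwise mutation co-occurrence / exclusivity testing
#'
#' For every pair of genes mutated in at least \code{minMutated} samples,
#' builds the 2x2 table (both, only A, only B, neither), applies a
#' two-sided Fisher exact test, adjusts across all tested pairs by
#' Benjamini-Hochberg, and calls the direction from the sample odds
#' ratio: above 1 co-occurrence, otherwise exclusivity.
#'
#' @param geneBySample Logical/binary matrix genes x samples, e.g. from
#'   [mutationMatrix()].
#' @param minMutated Minimum mutated-sample count for a gene to be
#'   tested (default 3).
#' @return data.frame: gene_a, gene_b, n_both, n_only_a, n_only_b,
#'   n_neither, odds_ratio, p_value, q_value, direction.
#' @export
pairwiseCooccurrence <- function(geneBySample, minMutated = 3L) {
  m <- geneBySample > 0
  keep <- rowSums(m) >= minMutated
  m <- m[keep, , drop = FALSE]
  genes <- rownames(m)
  if (length(genes) < 2L)
    return(data.frame(gene_a = character(), gene_b = character(),
                      n_both = integer(), n_only_a = integer(),
                      n_only_b = integer(), n_neither = integer(),
                      odds_ratio = numeric(), p_value = numeric(),
                      q_value = numeric(), direction = character()))
  pairs <- utils::combn(length(genes), 2L)
  res <- apply(pairs, 2L, function(ij) {
    a <- m[ij[1], ]; b <- m[ij[2], ]
    tab <- c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b))
    ft <- stats::fisher.test(matrix(tab, 2L, byrow = TRUE))
    orr <- (tab[1] * tab[4]) / (tab[2] * tab[3])
    c(tab, orr, ft$p.value)
  })
  out <- data.frame(gene_a = genes[pairs[1, ]], gene_b = genes[pairs[2, ]],
                    n_both = as.integer(res[1, ]),
                    n_only_a = as.integer(res[2, ]),
                    n_only_b = as.integer(res[3, ]),
                    n_neither = as.integer(res[4, ]),
                    odds_ratio = res[5, ], p_value = res[6, ],
                    stringsAsFactors = FALSE)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$direction <- ifelse(out$odds_ratio > 1, "co-occurrence",
                          "exclusivity")
  out
}
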