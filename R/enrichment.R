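#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability that a random
#' draw of n genes from a universe of N genes containing K disease-associated
#' genes contains at least k disease-associated genes. Computed by summing
#' log-space terms (lchoose) for numerical stability.
#'
#' @param k observed number of disease-associated targets.
#' @param K disease-associated genes in the universe.
#' @param n number of targets drawn (the miRNA's target-set size).
#' @param N universe size.
#' @return tail probability in [0, 1].
#' @examples
#' hypergeomTailP(2, 4, 3, 10)  # 1/3
#' @export
hypergeomTailP <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || k > n || n > N || K > N)
    stop("inconsistent counts: need 0 <= k <= n <= N and 0 <= K <= N")
  if (k == 0) return(1)
  hi <- min(n, K)
  if (k > hi) return(0)
  j <- k:hi
  logTerms <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
  m <- max(logTerms)
  min(1, exp(m) * sum(exp(logTerms - m)))
}

#' Build a miRNA-target interaction table
#'
#' @param mirna,gene character vectors of equal length (interaction pairs);
#'   duplicate pairs are collapsed.
#' @param support optional evidence annotation per pair (e.g.
#'   "Functional MTI" vs "Functional MTI (Weak)"); kept for filtering.
#' @return data.frame of class \code{c("targetTable", "data.frame")} with
#'   columns \code{mirna}, \code{gene} and optionally \code{support}. The
#'   gene universe is the set of distinct target genes.
#' @export
targetTable <- function(mirna, gene, support = NULL) {
  if (length(mirna) != length(gene))
    stop("mirna and gene must have equal length")
  if (any(!nzchar(mirna)) || any(!nzchar(gene)))
    stop("identifiers must be non-empty")
  df <- data.frame(mirna = as.character(mirna), gene = as.character(gene),
                   stringsAsFactors = FALSE)
  if (!is.null(support)) df$support <- as.character(support)
  df <- df[!duplicated(df[c("mirna", "gene")]), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("targetTable", "data.frame")
  df
}

#' Read a miRTarBase-layout interaction file
#'
#' Accepts tab- or comma-separated files with at least a miRNA and a target
#' gene column (header names containing "miRNA" and "Target Gene", as in
#' the hsa_MTI export; "Support Type" is carried through when present).
#'
#' @param path file path.
#' @param sep field separator; guessed from the extension when NULL
#'   (".tsv"/".txt" = tab, otherwise comma).
#' @return a [targetTable()].
#' @export
readTargetTable <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE)
  nm <- names(df)
  mcol <- grep("miRNA", nm, ignore.case = TRUE)[1]
  gcol <- grep("Target[ ._]?Gene", nm, ignore.case = TRUE)[1]
  scol <- grep("Support[ ._]?Type", nm, ignore.case = TRUE)[1]
  if (is.na(mcol) || is.na(gcol))
    stop("file must contain miRNA and Target Gene columns")
  targetTable(df[[mcol]], df[[gcol]],
              support = if (!is.na(scol)) df[[scol]] else NULL)
}

#' Read a one-gene-per-row disease gene list
#'
#' @param path file path (plain text, one gene identifier per line; a
#'   header line equal to "gene" is skipped).
#' @param label set label.
#' @return character vector of class \code{"diseaseGeneSet"} with a
#'   \code{label} attribute.
#' @export
readDiseaseGenes <- function(path, label = "disease") {
  x <- readLines(path)
  x <- trimws(x)
  x <- x[nzchar(x)]
  if (length(x) && tolower(x[1]) == "gene") x <- x[-1]
  if (!length(x)) stop("disease gene list is empty")
  structure(unique(x), label = label, class = "diseaseGeneSet")
}

#' Filter miRNAs by disease-target count
#'
#' Retains only miRNAs whose target sets include more than one
#' disease-associated gene (i.e. at least 2).
#'
#' @param table a [targetTable()].
#' @param diseaseGenes character vector of disease-associated genes.
#' @param minDiseaseTargets minimum disease-target count (default 2).
#' @return the filtered [targetTable()].
#' @export
filterMirnas <- function(table, diseaseGenes, minDiseaseTargets = 2L) {
  hits <- tapply(table$gene %in% diseaseGenes, table$mirna, sum)
  keep <- names(hits)[hits >= minDiseaseTargets]
  out <- table[table$mirna %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("targetTable", "data.frame")
  out
}

#' Adjust p-values for multiple testing
#'
#' Benjamini-Hochberg step-up adjustment by default (monotonicity
#' enforced); Bonferroni available as an option.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param method \code{"BH"} or \code{"bonferroni"}.
#' @return adjusted p-values, elementwise >= the raw values.
#' @export
adjustPvalues <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = method)
}

#' Rank miRNAs by enrichment of disease-associated targets
#'
#' The full prioritisation pipeline: the gene universe is the set of all
#' distinct target genes in the table (or a supplied universe), miRNAs with
#' fewer than two disease-associated targets are filtered out, each
#' remaining miRNA's target set is tested for enrichment of disease genes
#' with the upper-tail hypergeometric test, p-values are corrected for
#' multiple testing, and miRNAs are ranked by adjusted p-value (ties: higher
#' enrichment ratio first, then lexicographic identifier).
#'
#' @param table a [targetTable()].
#' @param diseaseGenes character vector of disease-associated genes
#'   (entries outside the universe are ignored for the test).
#' @param universe optional explicit gene universe; default all distinct
#'   target genes in \code{table}.
#' @param method multiple-testing correction, see [adjustPvalues()].
#' @param supportFilter optional regular expression on the \code{support}
#'   column; by default all interactions are included whether evidence is
#'   strong or weak.
#' @param filter apply the >1-disease-target filter (default TRUE).
#' @return data.frame with one row per miRNA: \code{mirna, n_targets,
#'   n_disease_targets, universe_size, disease_in_universe, expected,
#'   enrichment_ratio, p_raw, p_adjusted, rank}, sorted by rank.
#' @export
rankMirnas <- function(table, diseaseGenes, universe = NULL,
                       method = c("BH", "bonferroni"),
                       supportFilter = NULL, filter = TRUE) {
  method <- match.arg(method)
  if (!is.null(supportFilter) && "support" %in% names(table))
    table <- table[grepl(supportFilter, table$support), , drop = FALSE]
  if (is.null(universe)) universe <- unique(table$gene)
  N <- length(universe)
  disease <- intersect(unique(diseaseGenes), universe)
  K <- length(disease)
  if (filter) table <- filterMirnas(table, disease)
  if (!nrow(table))
    return(data.frame(mirna = character(0), n_targets = integer(0),
                      n_disease_targets = integer(0),
                      universe_size = integer(0),
                      disease_in_universe = integer(0),
                      expected = numeric(0), enrichment_ratio = numeric(0),
                      p_raw = numeric(0), p_adjusted = numeric(0),
                      rank = integer(0)))
  bySets <- split(table$gene, table$mirna)
  n <- vapply(bySets, length, integer(1))
  k <- vapply(bySets, function(g) sum(g %in% disease), integer(1))
  expected <- n * K / N
  pRaw <- mapply(hypergeomTailP, k = k, n = n,
                 MoreArgs = list(K = K, N = N))
  res <- data.frame(
    mirna = names(bySets), n_targets = n, n_disease_targets = k,
    universe_size = N, disease_in_universe = K,
    expected = expected,
    enrichment_ratio = ifelse(expected > 0, k / expected, 0),
    p_raw = pRaw,
    p_adjusted = adjustPvalues(pRaw, method = method),
    row.names = NULL)
  ord <- order(res$p_adjusted, -res$enrichment_ratio, res$mirna)
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

#' Write a ranked enrichment table as CSV
#'
#' @param ranked output of [rankMirnas()].
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeEnrichmentTable <- function(ranked, path) {
  write.csv(ranked, path, row.names = FALSE)
  invisible(path)
}
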