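## Expression statistics: housekeeping normalization, log2 fold changes,
## comparative delta-delta-CT, DE threshold filtering, target-list
## intersection and the miRNA target CDF-shift (Mann-Whitney) test.

#' Normalize a count matrix to housekeeping genes
#'
#' Per-sample scale factor = grand geometric mean of the housekeeping counts
#' divided by the sample's geometric mean of the housekeeping counts; all
#' counts are multiplied by their sample's factor, equalizing the
#' housekeeping geometric means across samples. The operation is idempotent.
#'
#' @param counts genes x samples numeric matrix (rownames = gene ids).
#' @param hk_genes housekeeping gene ids (default Actb, Tubb5, Vinculin);
#'   must be present with positive counts in every sample.
#' @return normalized matrix with attribute `scale_factors`.
#' @export
housekeeping_normalize <- function(counts,
                                   hk_genes = c("Actb", "Tubb5", "Vinculin")) {
  missing <- setdiff(hk_genes, rownames(counts))
  if (length(missing))
    stop("housekeeping gene(s) absent: ", paste(missing, collapse = ", "))
  hk <- counts[hk_genes, , drop = FALSE]
  bad <- colnames(counts)[colSums(hk <= 0) > 0]
  if (length(bad))
    stop("non-positive housekeeping counts in sample(s): ",
         paste(bad, collapse = ", "))
  sample_gm <- exp(colMeans(log(hk)))
  grand_gm <- exp(mean(log(hk)))
  f <- grand_gm / sample_gm
  out <- sweep(counts, 2, f, "*")
  attr(out, "scale_factors") <- f
  out
}

#' Per-gene log2 fold change between two sample groups
#'
#' `log2((mean_a + pseudocount) / (mean_b + pseudocount))`.
#'
#' @param norm genes x samples matrix (normalized counts/abundances).
#' @param group_a,group_b disjoint non-empty sample (column) selections.
#' @param pseudocount added to both group means (default 1).
#' @return named numeric vector, one log2FC per gene (a vs b).
#' @export
log2_fold_change <- function(norm, group_a, group_b, pseudocount = 1) {
  .assert(length(group_a) > 0 && length(group_b) > 0, "empty group")
  a <- norm[, group_a, drop = FALSE]
  b <- norm[, group_b, drop = FALSE]
  if (is.character(group_a) || is.character(group_b))
    .assert(!any(colnames(a) %in% colnames(b)), "groups must be disjoint")
  log2((rowMeans(a) + pseudocount) / (rowMeans(b) + pseudocount))
}

#' Relative quantification by the comparative delta-delta-CT method
#'
#' `dCT = CT_gene - CT_reference` per sample; `ddCT = dCT - mean(dCT)` over
#' the control samples; relative quantity `RQ = 2^(-ddCT)`.
#'
#' @param ct genes x samples matrix of CT values (no missing values).
#' @param reference_gene row id of the reference (housekeeping) gene.
#' @param control_samples column ids/indices of the control group.
#' @return data.frame `gene`, `sample`, `dct`, `ddct`, `rq` for every
#'   non-reference gene.
#' @export
ddct <- function(ct, reference_gene, control_samples) {
  .assert(reference_gene %in% rownames(ct), "reference gene not measured")
  if (anyNA(ct)) stop("missing CT value")
  genes <- setdiff(rownames(ct), reference_gene)
  samples <- colnames(ct) %||% as.character(seq_len(ncol(ct)))
  out <- lapply(genes, function(g) {
    dct <- ct[g, ] - ct[reference_gene, ]
    dd <- dct - mean(dct[control_samples])
    data.frame(gene = g, sample = samples, dct = as.numeric(dct),
               ddct = as.numeric(dd), rq = 2^(-as.numeric(dd)))
  })
  do.call(rbind, out)
}

## gene-id normalization: case-fold + strip trailing version suffixes
.norm_gene_ids <- function(x) toupper(sub("\\.\\d+$", "", x))

#' Intersect two predicted target lists
#'
#' Keeps only genes listed in both sources (e.g. TargetScan and miRDB),
#' matching ids case-insensitively and ignoring trailing version suffixes.
#'
#' @param list_a,list_b character vectors (or lists with a `genes` element).
#' @return list of class `target_set` with `genes` (ids as spelled in
#'   `list_a`) and `provenance = "intersection"`; warns when empty.
#' @export
intersect_targets <- function(list_a, list_b) {
  ga <- if (is.list(list_a)) list_a$genes else list_a
  gb <- if (is.list(list_b)) list_b$genes else list_b
  keep <- .norm_gene_ids(ga) %in% .norm_gene_ids(gb)
  genes <- unique(ga[keep])
  if (!length(genes)) warning("empty target intersection")
  structure(list(genes = genes, provenance = "intersection"),
            class = "target_set")
}

#' Mann-Whitney CDF-shift test of miRNA targets vs background genes
#'
#' Tests whether the log2 fold changes of predicted targets are shifted
#' relative to genes lacking predicted sites, with a two-sided Mann-Whitney
#' U test (exact for small tie-free groups, normal approximation with tie
#' correction otherwise). Empirical CDF supports for both groups are
#' returned for plotting the cumulative curves.
#'
#' @param de data.frame with `gene` and `log2fc` columns (one row per gene).
#' @param targets a [intersect_targets()] result or character vector.
#' @param background `"all"` (default; all genes lacking sites) or
#'   `"de_only"` (restrict non-targets to significant genes, using `padj`
#'   and `log2fc` with the 0.05 / 0.5 thresholds).
#' @param min_group minimal group size (default 10).
#' @return list of class `shift_test_result`: `u`, `p_value`, `n_targets`,
#'   `n_nontargets`, `cdf` (sorted log2FCs per group).
#' @export
target_shift_test <- function(de, targets, background = c("all", "de_only"),
                              min_group = 10) {
  background <- match.arg(background)
  tg <- .norm_gene_ids(if (is.list(targets)) targets$genes else targets)
  is_t <- .norm_gene_ids(de$gene) %in% tg
  x <- de$log2fc[is_t]
  bg <- de[!is_t, , drop = FALSE]
  if (background == "de_only")
    bg <- bg[bg$padj < 0.05 & abs(bg$log2fc) > 0.5, , drop = FALSE]
  y <- bg$log2fc
  if (length(x) < min_group || length(y) < min_group)
    stop("group below minimum size (", min_group, ")")
  wt <- wilcox.test(x, y, alternative = "two.sided")
  structure(list(u = unname(wt$statistic), p_value = wt$p.value,
                 n_targets = length(x), n_nontargets = length(y),
                 cdf = list(targets = sort(x), nontargets = sort(y))),
            class = "shift_test_result")
}

#' Filter a DE table at the significance thresholds
#'
#' Up = adjusted p strictly below `padj_max` and log2FC strictly above
#' `lfc_min`; down symmetric.
#'
#' @param de data.frame with `gene`, `log2fc`, `padj`.
#' @param padj_max adjusted-p threshold (default 0.05).
#' @param lfc_min absolute log2FC threshold (default 0.5).
#' @return list with character vectors `up` and `down`.
#' @export
de_filter <- function(de, padj_max = 0.05, lfc_min = 0.5) {
  list(up = de$gene[de$padj < padj_max & de$log2fc > lfc_min],
       down = de$gene[de$padj < padj_max & de$log2fc < -lfc_min])
}

#' Simple differential-expression test with a batch covariate
#'
#' Per-gene linear model of `log2(normalized + pseudocount)` on the
#' condition contrast, optionally adjusting for batch, fitted with limma;
#' p-values are Benjamini-Hochberg adjusted. This is deliberately a plain
#' linear-model stage (no count-specific dispersion modeling) so the
#' downstream target-shift and network steps are self-contained.
#'
#' @param norm genes x samples matrix of normalized counts.
#' @param metadata data.frame, one row per sample (same order as columns).
#' @param condition_col metadata column with exactly two levels; the second
#'   level (alphabetically last, or factor level order) is compared against
#'   the first.
#' @param batch_col optional metadata column used as a blocking covariate.
#' @param pseudocount added before the log (default 1).
#' @param padj_max,lfc_min thresholds for the significance flag.
#' @return data.frame of class `de_table`: `gene`, `log2fc`, `p`, `padj`,
#'   `significant`.
#' @export
simple_de_test <- function(norm, metadata, condition_col = "condition",
                           batch_col = NULL, pseudocount = 1,
                           padj_max = 0.05, lfc_min = 0.5) {
  cond <- factor(metadata[[condition_col]])
  .assert(nlevels(cond) == 2, "condition must have exactly two levels")
  .assert(min(table(cond)) >= 2, "need >= 2 samples per group")
  design <- if (is.null(batch_col)) stats::model.matrix(~cond)
            else stats::model.matrix(~cond + factor(metadata[[batch_col]]))
  if (qr(design)$rank < ncol(design)) stop("singular design matrix")
  fit <- limma::lmFit(log2(norm + pseudocount), design)
  fit <- limma::eBayes(fit)
  tab <- limma::topTable(fit, coef = 2, number = Inf, sort.by = "none")
  out <- data.frame(gene = rownames(norm), log2fc = tab$logFC,
                    p = tab$P.Value, padj = p.adjust(tab$P.Value, "BH"))
  out$significant <- out$padj < padj_max & abs(out$log2fc) > lfc_min
  class(out) <- c("de_table", "data.frame")
  out
}
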