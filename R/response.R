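# Transcriptional-response scoring from a gene-level count matrix:
# filtering, median-of-ratios normalization, a variance-stabilizing log
# transform, PCA over the most variable genes, threshold-based differential
# expression, and regressions of the response on editing rate.

# Accept either a genes x samples numeric matrix with rownames or a tibble
# whose first column (or a column named `gene`) holds gene ids.
.as_count_matrix <- function(counts) {
  if (is.matrix(counts)) {
    stopifnot(!is.null(rownames(counts)))
    storage.mode(counts) <- "double"
    return(counts)
  }
  df <- as.data.frame(counts)
  gene_col <- if ("gene" %in% names(df)) "gene" else names(df)[1]
  m <- as.matrix(df[setdiff(names(df), gene_col)])
  rownames(m) <- df[[gene_col]]
  if (anyDuplicated(rownames(m))) {
    rlang::abort("duplicate gene symbols in count matrix",
                 class = "guidescreen_invariant_error")
  }
  storage.mode(m) <- "double"
  m
}

#' Filter genes by mean count
#'
#' Keeps genes whose mean count across all samples is at least `min_mean`
#' (boundary inclusive: a gene averaging exactly `min_mean` is kept).
#'
#' @param counts Genes x samples count matrix (rownames = genes) or tibble
#'   with a `gene` column.
#' @param min_mean Mean-count threshold (default 10).
#' @return Filtered count matrix.
#' @export
filter_genes <- function(counts, min_mean = 10) {
  m <- .as_count_matrix(counts)
  if (ncol(m) < 2) rlang::abort("need at least 2 samples", class = "guidescreen_parameter_error")
  keep <- rowMeans(m) >= min_mean
  if (!any(keep)) {
    rlang::abort("no genes pass the mean-count filter", class = "guidescreen_parameter_error")
  }
  m[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over genes of the ratio of its count to the
#' gene's geometric mean across samples; genes with a zero count in any
#' sample are excluded from the median. Factors are normalized to geometric
#' mean 1.
#'
#' @param counts Genes x samples count matrix or tibble.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  m <- .as_count_matrix(counts)
  nonzero <- rowSums(m == 0) == 0
  if (!any(nonzero)) {
    rlang::abort("no gene has nonzero counts in every sample",
                 class = "guidescreen_parameter_error")
  }
  logm <- log(m[nonzero, , drop = FALSE])
  log_geo <- rowMeans(logm)
  f <- apply(logm, 2, function(col) exp(stats::median(col - log_geo)))
  f / exp(mean(log(f)))
}

#' Variance-stabilizing log transform
#'
#' `log2(count / factor + 1)` per cell — a documented simplification of the
#' blind variance-stabilizing transform, monotone in counts and mapping 0
#' to 0.
#'
#' @param counts Genes x samples count matrix or tibble.
#' @param factors Size factors from [size_factors()].
#' @return Real-valued matrix of the same shape.
#' @export
vst_transform <- function(counts, factors = size_factors(counts)) {
  m <- .as_count_matrix(counts)
  stopifnot(all(factors > 0), length(factors) == ncol(m))
  log2(sweep(m, 2, factors, "/") + 1)
}

#' PCA of the transformed expression matrix
#'
#' Genes are ranked by variance across samples and the top `n_top_genes`
#' kept; rows are centered per gene and components computed by singular
#' value decomposition. The sign of PC1 is arbitrary in SVD, so it is
#' oriented so that the mean coordinate of target-gene-editing samples is
#' at least that of negative controls when sample groups are supplied.
#'
#' @param transformed Matrix from [vst_transform()].
#' @param meta Optional tibble with `sample_id` and `group` columns
#'   (`negative_control` vs editing groups) used to orient PC1 and carried
#'   into the scores table.
#' @param n_top_genes Number of most-variable genes to use (default 500).
#' @param n_components Number of components to return (default 2).
#' @param n_top_loadings How many top-|loading| genes to report (default
#'   20).
#' @return An `editing_pca` object with `samples` (tibble of `sample_id`
#'   and `PC1..PCk`), `loadings` (all genes x components),
#'   `top_loadings`, and `var_explained`.
#' @export
run_pca <- function(transformed, meta = NULL, n_top_genes = 500L,
                    n_components = 2L, n_top_loadings = 20L) {
  stopifnot(is.matrix(transformed))
  if (is.null(colnames(transformed))) {
    colnames(transformed) <- paste0("sample", seq_len(ncol(transformed)))
  }
  if (n_top_genes > nrow(transformed)) n_top_genes <- nrow(transformed)
  if (n_components >= ncol(transformed)) {
    rlang::abort("need more samples than components",
                 class = "guidescreen_parameter_error")
  }
  vars <- apply(transformed, 1, stats::var)
  top <- utils::head(order(vars, decreasing = TRUE), n_top_genes)
  x <- transformed[top, , drop = FALSE]
  x <- x - rowMeans(x)
  sv <- svd(t(x), nu = n_components, nv = n_components)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  loadings <- sv$v
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(n_components))
  rownames(loadings) <- rownames(x)
  samples <- tibble::tibble(sample_id = colnames(transformed))
  samples <- dplyr::bind_cols(samples, tibble::as_tibble(scores))
  if (!is.null(meta) && all(c("sample_id", "group") %in% names(meta))) {
    samples <- dplyr::left_join(samples, meta, by = "sample_id")
    is_ctrl <- samples$group == "negative_control"
    if (any(is_ctrl) && any(!is_ctrl) &&
        mean(samples$PC1[!is_ctrl]) < mean(samples$PC1[is_ctrl])) {
      samples$PC1 <- -samples$PC1
      loadings[, 1] <- -loadings[, 1]
    }
  }
  total_var <- sum(apply(t(x), 2, stats::var))
  comp_var <- sv$d[seq_len(n_components)]^2 / (ncol(transformed) - 1)
  top_load <- tibble::tibble(
    gene = rownames(loadings),
    loading = loadings[, 1]
  )
  top_load <- utils::head(top_load[order(abs(top_load$loading), decreasing = TRUE), ],
                          n_top_loadings)
  structure(
    list(samples = samples, loadings = loadings, top_loadings = top_load,
         var_explained = comp_var / total_var, n_top_genes = n_top_genes),
    class = "editing_pca"
  )
}

#' @export
print.editing_pca <- function(x, ...) {
  cat("<editing_pca>", nrow(x$samples), "samples,", x$n_top_genes, "genes;",
      "variance explained:",
      paste(sprintf("%s %.1f%%", colnames(x$loadings), 100 * x$var_explained),
            collapse = ", "), "\n")
  invisible(x)
}

#' Threshold-based differential expression between two sample groups
#'
#' Per gene: `base_mean` is the mean normalized count over both arms;
#' `log2fc` the log2 ratio of group means of normalized counts with a 0.5
#' pseudocount; `p` a two-sided Welch t test on `log2(normalized + 0.5)`
#' replicate values; `padj` Benjamini-Hochberg. A gene is differentially
#' expressed iff `|log2fc| >= lfc`, `padj < alpha` and
#' `base_mean >= min_base_mean`. With a single replicate in either arm, p
#' is reported `NA` and the gene is never flagged.
#'
#' @param counts Genes x samples count matrix or tibble (filtered).
#' @param treat,control Character vectors of sample ids for the two arms.
#' @param factors Size factors (default computed from `counts`).
#' @param lfc Absolute log2-fold-change threshold (default 0.58, a
#'   1.5-fold change).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param min_base_mean Base-mean floor (default 3).
#' @return Tibble per gene: `gene`, `base_mean`, `log2fc`, `p`, `padj`,
#'   `de_flag`, `direction`.
#' @export
differential_expression <- function(counts, treat, control,
                                    factors = size_factors(counts),
                                    lfc = 0.58, alpha = 0.05, min_base_mean = 3) {
  m <- .as_count_matrix(counts)
  stopifnot(all(c(treat, control) %in% colnames(m)))
  norm <- sweep(m, 2, factors[colnames(m)], "/")
  nt <- norm[, treat, drop = FALSE]
  nc <- norm[, control, drop = FALSE]
  base_mean <- rowMeans(cbind(nt, nc))
  log2fc <- log2((rowMeans(nt) + 0.5) / (rowMeans(nc) + 0.5))
  if (length(treat) >= 2 && length(control) >= 2) {
    lt <- log2(nt + 0.5); lc <- log2(nc + 0.5)
    p <- vapply(seq_len(nrow(m)), function(i) {
      if (stats::sd(lt[i, ]) == 0 && stats::sd(lc[i, ]) == 0) {
        return(if (mean(lt[i, ]) == mean(lc[i, ])) 1 else 0)
      }
      tryCatch(stats::t.test(lt[i, ], lc[i, ])$p.value, error = function(e) NA_real_)
    }, numeric(1))
  } else {
    p <- rep(NA_real_, nrow(m))
  }
  padj <- stats::p.adjust(p, method = "BH")
  tibble::tibble(
    gene = rownames(m),
    base_mean = base_mean,
    log2fc = log2fc,
    p = p,
    padj = padj,
    de_flag = !is.na(padj) & abs(log2fc) >= lfc & padj < alpha &
      base_mean >= min_base_mean,
    direction = dplyr::case_when(log2fc > 0 ~ "up", log2fc < 0 ~ "down",
                                 .default = "flat")
  )
}

#' Regress a transcriptional response on editing rate
#'
#' Ordinary least squares of a per-sample response — a principal-component
#' coordinate or a gene's expression — on the sample's frameshift editing
#' rate, optionally after excluding guides (e.g. those 5' of an in-frame
#' near-cognate start codon, which edit without ablating the protein).
#'
#' @param data Tibble with one row per sample containing `frameshift_rate`,
#'   the response column, and (if exclusions are used) `guide_id`.
#' @param response Column (tidy-eval) holding the response, e.g. `PC1`.
#' @param exclude_guides Character vector of guide ids to drop.
#' @return An `editing_regression` object; see [tidy()][generics::tidy] and
#'   [glance()][generics::glance].
#' @export
regress_response_on_editing <- function(data, response, exclude_guides = character(0)) {
  if (length(exclude_guides) > 0) {
    stopifnot("guide_id" %in% names(data))
    data <- data[!(data$guide_id %in% exclude_guides), ]
  }
  yv <- dplyr::pull(data, {{ response }})
  xv <- data$frameshift_rate
  ok <- stats::complete.cases(xv, yv)
  if (sum(ok) < 3) {
    rlang::abort("need at least 3 samples after exclusion",
                 class = "guidescreen_parameter_error")
  }
  d <- tibble::tibble(frameshift_rate = xv[ok], response = yv[ok])
  fit <- stats::lm(response ~ frameshift_rate, data = d)
  structure(
    list(fit = fit, data = d,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = summary(fit)$r.squared,
         n = nrow(d)),
    class = "editing_regression"
  )
}

#' @export
print.editing_regression <- function(x, ...) {
  cat(sprintf("<editing_regression> n = %d, slope = %.3f, r^2 = %.3f\n",
              x$n, x$slope, x$r_squared))
  invisible(x)
}

#' Aggregate transcript-level counts to gene level
#'
#' @param counts Transcripts x samples count matrix or tibble (first /
#'   `gene` column = transcript ids).
#' @param tx2gene Tibble with `transcript` and `gene` columns.
#' @return Gene-level count matrix (transcript counts summed per gene).
#' @export
aggregate_transcripts <- function(counts, tx2gene) {
  m <- .as_count_matrix(counts)
  stopifnot(all(c("transcript", "gene") %in% names(tx2gene)))
  gene <- tx2gene$gene[match(rownames(m), tx2gene$transcript)]
  if (anyNA(gene)) {
    rlang::abort(paste0("transcript without gene mapping: ",
                        rownames(m)[which(is.na(gene))[1]]),
                 class = "guidescreen_parameter_error")
  }
  agg <- rowsum(m, group = gene)
  agg[order(rownames(agg)), , drop = FALSE]
}
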