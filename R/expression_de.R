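#' Expression filter and test parameters
#'
#' @param pseudocount added to RPM before taking log2 (default 1, so a zero
#'   count maps to 0)
#' @param alpha adjusted-p significance threshold (default 0.05)
#' @param lfc_min minimum absolute log2 fold change (default 1)
#' @param iqr_min minimum interquartile range for the variability filter
#'   (default 0.5)
#' @param apply_sample_filter whether the pipeline drops samples with total
#'   expression at or below the median (default TRUE)
#' @return a `filter_params` list
#' @export
filter_params <- function(pseudocount = 1, alpha = 0.05, lfc_min = 1,
                          iqr_min = 0.5, apply_sample_filter = TRUE) {
  stopifnot(alpha > 0, alpha < 1, pseudocount >= 0, lfc_min >= 0)
  structure(list(pseudocount = pseudocount, alpha = alpha, lfc_min = lfc_min,
                 iqr_min = iqr_min, apply_sample_filter = apply_sample_filter),
            class = "filter_params")
}

#' Convert counts to log2 reads-per-million
#'
#' `log2(count * 1e6 / library_size + pseudocount)`.
#'
#' @param counts numeric matrix, features x samples, non-negative
#' @param library_sizes per-sample totals (positive, recycled by name when
#'   named); defaults to the column sums of `counts`
#' @param pseudocount value added before log2
#' @return numeric matrix of the same shape
#' @export
to_log2_rpm <- function(counts, library_sizes = colSums(counts),
                        pseudocount = 1) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!is.null(names(library_sizes)) && !is.null(colnames(counts)))
    library_sizes <- library_sizes[colnames(counts)]
  if (length(library_sizes) != ncol(counts))
    stop("library_sizes must have one entry per sample")
  if (any(!is.finite(library_sizes)) || any(library_sizes <= 0))
    stop("library sizes must be positive")
  log2(sweep(counts, 2L, library_sizes / 1e6, "/") + pseudocount)
}

#' Quantile-normalize a matrix across columns
#'
#' After normalization every column's sorted values equal the row-wise means
#' of the column-sorted input (the reference distribution); tied values within
#' a column receive the mean of the reference values at the tied ranks
#' (fractional average ranks are mapped by linear interpolation).
#'
#' @param x complete numeric matrix, features x samples
#' @return matrix of the same shape and dimnames
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("matrix must be complete")
  n <- nrow(x)
  if (n == 0L || ncol(x) == 0L) return(x)
  ref <- rowMeans(apply(x, 2L, sort))
  out <- apply(x, 2L, function(col) {
    r <- rank(col, ties.method = "average")
    if (n == 1L) rep(ref, length(col)) else approx(seq_len(n), ref, xout = r)$y
  })
  out <- matrix(out, nrow = n, dimnames = dimnames(x))
  out
}

#' Drop samples with low total expression
#'
#' Per-sample totals are summed over all features; samples whose total is
#' strictly greater than the median total are retained (with an even number
#' of distinct totals this keeps exactly half). When all totals are equal the
#' filter is degenerate: every sample is retained with a warning.
#'
#' @param x numeric matrix, features x samples (>= 2 samples)
#' @return matrix restricted to retained samples
#' @export
filter_samples <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("at least two samples are required")
  totals <- colSums(x)
  if (length(unique(totals)) == 1L) {
    warning("all per-sample totals are equal; retaining all samples")
    return(x)
  }
  x[, totals > median(totals), drop = FALSE]
}

#' Keep features with variable expression
#'
#' A row is retained iff its interquartile range (Q3 - Q1, quartiles by
#' linear interpolation, i.e. `quantile(type = 7)`) exceeds `iqr_min`.
#'
#' @param x numeric matrix with >= 4 samples
#' @param iqr_min IQR threshold (strict)
#' @return matrix restricted to retained rows
#' @export
filter_variable <- function(x, iqr_min = 0.5) {
  x <- as.matrix(x)
  if (ncol(x) < 4L) stop("at least four samples are required")
  iqr <- apply(x, 1L, function(v) {
    q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    q[2L] - q[1L]
  })
  x[iqr > iqr_min, , drop = FALSE]
}

# Two-sided Wilcoxon rank-sum p-value by normal approximation with tie
# correction (no continuity correction; documented numerical choice).
wilcox_p_normal <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  N <- n1 + n2
  ties <- table(r)
  sigma2 <- (n1 * n2 / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  z <- (W - n1 * n2 / 2) / sqrt(sigma2)
  min(1, 2 * pnorm(-abs(z)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of raw p-values
#' @return adjusted p-values in the input order
#' @export
bh_adjust <- function(p) {
  n <- length(p)
  if (n == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / seq(n, 1) * p[o]))[ro]
}

#' Per-feature differential expression
#'
#' Two-sided Wilcoxon rank-sum test per row (normal approximation with tie
#' correction), Benjamini-Hochberg adjustment across all tested rows, and a
#' significance flag requiring both `p_adj < alpha` and
#' `|log2fc| >= lfc_min`. `log2fc` is `mean(cancer) - mean(normal)` on the
#' (already log2) expression scale.
#'
#' @param x numeric matrix of log2 expression, features x samples
#' @param groups character/factor vector per sample with levels containing
#'   `"cancer"` and `"normal"` (named vectors are matched to the columns)
#' @param params a [filter_params()] object
#' @return data.frame: `id`, `log2fc`, `p`, `p_adj`, `significant`
#' @export
differential_expression <- function(x, groups, params = filter_params()) {
  x <- as.matrix(x)
  if (!is.null(names(groups)) && !is.null(colnames(x)))
    groups <- groups[colnames(x)]
  if (length(groups) != ncol(x))
    stop("groups must have one entry per sample")
  groups <- as.character(groups)
  ic <- which(groups == "cancer")
  im <- which(groups == "normal")
  if (length(ic) < 2L || length(im) < 2L)
    stop("both groups need at least two samples")
  ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  p <- vapply(seq_len(nrow(x)),
              function(i) wilcox_p_normal(x[i, ic], x[i, im]), numeric(1))
  lfc <- rowMeans(x[, ic, drop = FALSE]) - rowMeans(x[, im, drop = FALSE])
  p_adj <- bh_adjust(p)
  data.frame(id = ids, log2fc = unname(lfc), p = p, p_adj = p_adj,
             significant = p_adj < params$alpha & abs(lfc) >= params$lfc_min,
             stringsAsFactors = FALSE)
}

#' Volcano-plot data table
#'
#' One row per tested feature with the three-way colour classification used
#' in volcano plots: `"significant"` (passes both gates), `"low_lfc"`
#' (adjusted p below alpha but |log2FC| under the gate), `"not_significant"`
#' (adjusted p above alpha).
#'
#' @param de data.frame from [differential_expression()]
#' @param params a [filter_params()] object
#' @return data.frame: `id`, `log2fc`, `neg_log10_padj`, `class`
#' @export
volcano_table <- function(de, params = filter_params()) {
  cls <- ifelse(de$p_adj >= params$alpha, "not_significant",
                ifelse(abs(de$log2fc) < params$lfc_min, "low_lfc",
                       "significant"))
  data.frame(id = de$id, log2fc = de$log2fc,
             neg_log10_padj = -log10(pmax(de$p_adj, .Machine$double.xmin)),
             class = cls, stringsAsFactors = FALSE)
}
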