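#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Point-probability method: with margins fixed, the two-sided p-value is the
#' sum of hypergeometric probabilities of all tables whose point probability
#' does not exceed that of the observed table (with a relative slack of 1e-7
#' for floating-point ties). Degenerate margins (an empty row or column)
#' return p = 1 with a warning.
#'
#' @param a,b,c,d non-negative integer cell counts, laid out as
#'   `rbind(c(a, b), c(c, d))`
#' @return two-sided p-value
#' @export
fisher_two_tailed <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers")
  m <- a + b      # row 1 total
  n <- c + d      # row 2 total
  k <- a + c      # column 1 total
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) {
    warning("degenerate margins; returning p = 1")
    return(1)
  }
  lo <- max(0, k - n)
  hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Category over-representation analysis
#'
#' For each category: the observed member count in `gene_list`, the expected
#' count `list_size * category_size / background_size`, the fold enrichment
#' `obs / exp`, a Fisher p-value (one-sided "greater" by default, matching an
#' enrichment question; two-sided by flag), and a Benjamini-Hochberg FDR over
#' all tested categories. Categories with zero observed members are reported
#' but carry `enriched = FALSE` regardless of FDR.
#'
#' @param gene_list character vector, a subset of `background`
#' @param background character vector of all eligible genes
#' @param category_map data.frame with columns `gene`, `category`
#' @param alternative `"greater"` (default) or `"two.sided"`
#' @param fdr_max FDR threshold for the `enriched` flag (default 0.05)
#' @return data.frame: `category`, `obs`, `exp`, `fold`, `p`, `fdr`, `enriched`
#' @export
overrepresentation <- function(gene_list, background, category_map,
                               alternative = c("greater", "two.sided"),
                               fdr_max = 0.05) {
  alternative <- match.arg(alternative)
  gene_list <- unique(gene_list)
  background <- unique(background)
  outside <- setdiff(gene_list, background)
  if (length(outside))
    stop("genes outside the background: ", paste(outside, collapse = ", "))
  stopifnot(all(c("gene", "category") %in% names(category_map)))
  category_map <- unique(category_map[category_map$gene %in% background,
                                      c("gene", "category")])
  if (length(gene_list) == 0L || nrow(category_map) == 0L) {
    return(data.frame(category = character(0), obs = integer(0),
                      exp = numeric(0), fold = numeric(0), p = numeric(0),
                      fdr = numeric(0), enriched = logical(0)))
  }
  N <- length(background)
  n_list <- length(gene_list)
  cats <- split(category_map$gene, category_map$category)
  rows <- lapply(names(cats), function(cat) {
    members <- unique(cats[[cat]])
    K <- length(members)
    obs <- length(intersect(gene_list, members))
    expd <- n_list * K / N
    p <- if (alternative == "greater") {
      stats::phyper(obs - 1L, K, N - K, n_list, lower.tail = FALSE)
    } else {
      fisher_two_tailed(obs, n_list - obs, K - obs, N - K - n_list + obs)
    }
    data.frame(category = cat, obs = obs, exp = expd,
               fold = if (expd > 0) obs / expd else NA_real_, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  out$enriched <- out$obs > 0L & out$fdr < fdr_max
  out[order(out$fdr, out$p, out$category), , drop = FALSE]
}

#' Intersect circRNA windows with m6A peaks
#'
#' Intervals are 0-based half-open; a circRNA is flagged iff at least one peak
#' shares at least one base with its window (so touching half-open intervals
#' do not overlap). Chromosome names are normalized by stripping an optional
#' `"chr"` prefix on either side. Malformed intervals (`start >= end`) are
#' dropped with a warning.
#'
#' @param circ_intervals data.frame with columns `id`, `chrom`, `start`, `end`
#'   (0-based half-open)
#' @param peaks data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open); may have zero rows
#' @return list: `flags` (named logical per circRNA id) and `n_overlapping`
#' @export
m6a_overlap <- function(circ_intervals, peaks) {
  stopifnot(all(c("id", "chrom", "start", "end") %in% names(circ_intervals)))
  norm_chr <- function(x) sub("^chr", "", as.character(x))
  bad <- circ_intervals$start >= circ_intervals$end
  if (any(bad)) {
    warning(sum(bad), " malformed circRNA interval(s) dropped")
    circ_intervals <- circ_intervals[!bad, , drop = FALSE]
  }
  flags <- setNames(rep(FALSE, nrow(circ_intervals)), circ_intervals$id)
  if (!is.null(peaks) && nrow(peaks) > 0L) {
    badp <- peaks$start >= peaks$end
    if (any(badp)) {
      warning(sum(badp), " malformed peak(s) dropped")
      peaks <- peaks[!badp, , drop = FALSE]
    }
  }
  if (is.null(peaks) || nrow(peaks) == 0L || nrow(circ_intervals) == 0L) {
    return(list(flags = flags, n_overlapping = 0L))
  }
  cg <- GenomicRanges::GRanges(
    norm_chr(circ_intervals$chrom),
    IRanges::IRanges(circ_intervals$start + 1L, circ_intervals$end))
  pg <- GenomicRanges::GRanges(
    norm_chr(peaks$chrom),
    IRanges::IRanges(peaks$start + 1L, peaks$end))
  hits <- GenomicRanges::countOverlaps(cg, pg, minoverlap = 1L)
  flags[] <- hits > 0L
  list(flags = flags, n_overlapping = sum(flags))
}

#' Match novel terminus peptides against a peptide database
#'
#' A "perfect overlap" is containment in either direction: the extension
#' occurring inside a database peptide, or the database peptide occurring
#' inside the extension. Every occurrence is reported with its 1-based offset
#' within the containing sequence.
#'
#' @param extensions named character vector of novel terminus peptides
#' @param db named character vector of database peptide sequences
#' @return data.frame: `extension_id`, `db_entry`, `direction`
#'   (`"ext_in_db"` or `"db_in_ext"`), `offset` (1-based within the container)
#' @export
match_peptides <- function(extensions, db) {
  if (length(extensions) == 0L || length(db) == 0L) {
    return(data.frame(extension_id = character(0), db_entry = character(0),
                      direction = character(0), offset = integer(0)))
  }
  if (is.null(names(extensions)))
    names(extensions) <- paste0("ext", seq_along(extensions))
  if (is.null(names(db)))
    names(db) <- paste0("db", seq_along(db))
  rows <- list()
  for (ei in names(extensions)) {
    ext <- extensions[[ei]]
    if (!nzchar(ext)) next
    for (di in names(db)) {
      pep <- db[[di]]
      if (!nzchar(pep)) next
      hit <- regexpr(ext, pep, fixed = TRUE)
      if (hit > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          extension_id = ei, db_entry = di, direction = "ext_in_db",
          offset = as.integer(hit), stringsAsFactors = FALSE)
      } else {
        hit2 <- regexpr(pep, ext, fixed = TRUE)
        if (hit2 > 0L) {
          rows[[length(rows) + 1L]] <- data.frame(
            extension_id = ei, db_entry = di, direction = "db_in_ext",
            offset = as.integer(hit2), stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(extension_id = character(0), db_entry = character(0),
                      direction = character(0), offset = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
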