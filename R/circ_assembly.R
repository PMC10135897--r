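#' Selection thresholds for backsplice records
#'
#' @param min_samples minimum number of samples a circRNA must be expressed in
#'   (default 40, the pan-cancer compendium convention; synthetic runs use a
#'   scaled-down stand-in)
#' @param min_len_nt minimum spliced-sequence length in nucleotides
#'   (default 150)
#' @param exclude_intergenic reject records whose gene symbol is absent from
#'   the annotation
#' @param exclude_readthrough reject records whose backsplice window spans
#'   more than one annotated gene
#' @return a `selection_thresholds` list
#' @export
selection_thresholds <- function(min_samples = 40L, min_len_nt = 150L,
                                 exclude_intergenic = TRUE,
                                 exclude_readthrough = TRUE) {
  stopifnot(min_len_nt >= 3L, min_samples >= 0L)
  structure(list(min_samples = as.integer(min_samples),
                 min_len_nt = as.integer(min_len_nt),
                 exclude_intergenic = exclude_intergenic,
                 exclude_readthrough = exclude_readthrough),
            class = "selection_thresholds")
}

#' Read a backsplice TSV (MiOncoCirc column dialect)
#'
#' Expected columns: `chr`, `start`, `end`, `reads`, `symbol`, `sample`, one
#' row per (circRNA, sample) observation. Coordinates are interpreted as
#' 1-based inclusive.
#'
#' @param path TSV path
#' @return data.frame of per-sample observations
#' @export
read_backsplice <- function(path) {
  df <- read_tsv(path)
  need <- c("chr", "start", "end", "reads", "symbol", "sample")
  if (!all(need %in% names(df)))
    stop("backsplice TSV must have columns: ", paste(need, collapse = ", "))
  df[need]
}

#' Aggregate per-sample backsplice observations into circRNA records
#'
#' @param obs data.frame from [read_backsplice()]
#' @return data.frame with one row per circRNA: `circ_id`
#'   (`symbol|chr:start-end`), `gene`, `chrom`, `start`, `end`,
#'   `samples_expressed`
#' @export
backsplice_records <- function(obs) {
  if (nrow(obs) == 0L) {
    return(data.frame(circ_id = character(0), gene = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), samples_expressed = integer(0)))
  }
  key <- paste0(obs$symbol, "|", obs$chr, ":", obs$start, "-", obs$end)
  first <- !duplicated(key)
  expressed <- tapply(obs$reads > 0, key, sum)
  out <- data.frame(
    circ_id = key[first],
    gene = obs$symbol[first], chrom = obs$chr[first],
    start = as.integer(obs$start[first]), end = as.integer(obs$end[first]),
    samples_expressed = as.integer(expressed[key[first]]),
    stringsAsFactors = FALSE)
  out[order(out$chrom, out$start, out$end, out$gene), , drop = FALSE]
}

#' Per-circRNA read-count matrix
#'
#' @param obs data.frame from [read_backsplice()]
#' @param samples optional character vector fixing the sample (column) order;
#'   samples without observations get zero counts
#' @return integer matrix, circRNA x sample, rownames as in
#'   [backsplice_records()]
#' @export
backsplice_counts <- function(obs, samples = NULL) {
  samples <- samples %||% sort(unique(obs$sample))
  if (nrow(obs) == 0L)
    return(matrix(0L, 0L, length(samples),
                  dimnames = list(character(0), samples)))
  obs$circ_id <- paste0(obs$symbol, "|", obs$chr, ":", obs$start, "-", obs$end)
  ids <- sort(unique(obs$circ_id))
  m <- matrix(0L, length(ids), length(samples),
              dimnames = list(ids, samples))
  keep <- obs$sample %in% samples
  obs <- obs[keep, , drop = FALSE]
  m[cbind(match(obs$circ_id, ids), match(obs$sample, samples))] <-
    as.integer(obs$reads)
  m
}

#' Read gene annotation from a GTF file
#'
#' @param path GTF path (exon and CDS features are used; gene extents are
#'   derived from the union of a gene's exons)
#' @return list: `exons` (data.frame chrom/start/end/strand/gene/transcript),
#'   `cds` (same shape), `genes` (data.frame gene/chrom/start/end/strand)
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  gene_col <- if ("gene_name" %in% names(df) &&
                  !all(is.na(df$gene_name))) "gene_name" else "gene_id"
  pick <- function(type) {
    sel <- df[df$type == type, , drop = FALSE]
    data.frame(chrom = as.character(sel$seqnames),
               start = sel$start, end = sel$end,
               strand = as.character(sel$strand),
               gene = as.character(sel[[gene_col]]),
               transcript = as.character(sel$transcript_id),
               stringsAsFactors = FALSE)
  }
  exons <- pick("exon")
  cds <- pick("CDS")
  genes <- do.call(rbind, lapply(split(exons, exons$gene), function(e) {
    data.frame(gene = e$gene[1L], chrom = e$chrom[1L],
               start = min(e$start), end = max(e$end),
               strand = e$strand[1L], stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL
  list(exons = exons, cds = cds, genes = genes)
}

#' Apply the circRNA selection filters
#'
#' A record is retained only if it passes every enabled predicate; the first
#' failing predicate (in the order few-samples, intergenic/unannotated,
#' read-through) is logged as its rejection reason. The spliced-length filter
#' cannot be evaluated here and is applied by [splice_circ()].
#'
#' @param records data.frame from [backsplice_records()]
#' @param thresholds a [selection_thresholds()] object
#' @param annotation list from [read_annotation()]
#' @return list: `retained` (records subset) and `rejected` (records subset
#'   with a `reason` column)
#' @export
select_circrnas <- function(records, thresholds, annotation) {
  reasons <- rep(NA_character_, nrow(records))
  genes <- annotation$genes
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (r$samples_expressed < thresholds$min_samples) {
      reasons[i] <- sprintf("expressed in %d < %d samples",
                            r$samples_expressed, thresholds$min_samples)
    } else if (thresholds$exclude_intergenic &&
               !(r$gene %in% genes$gene)) {
      reasons[i] <- "intergenic/unannotated"
    } else if (thresholds$exclude_readthrough) {
      hit <- genes$chrom == r$chrom & genes$start <= r$end &
        genes$end >= r$start
      if (sum(hit) > 1L) reasons[i] <- "read-through (spans >1 gene)"
    }
  }
  rejected <- records[!is.na(reasons), , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reasons[!is.na(reasons)]
  else rejected$reason <- character(0)
  list(retained = records[is.na(reasons), , drop = FALSE],
       rejected = rejected)
}

#' Extract circularized spliced sequences for one circRNA record
#'
#' For every annotated transcript of the record's gene with at least one exon
#' overlapping the backsplice window, the exon segments are clipped to the
#' window (1-based inclusive), concatenated in genomic order and, for
#' minus-strand genes, reverse-complemented into transcript orientation.
#' Isoforms shorter than `min_len_nt` are dropped.
#'
#' @param record single-row data.frame (one circRNA) from
#'   [backsplice_records()]
#' @param annotation list from [read_annotation()]
#' @param genome a named `DNAStringSet` (one entry per chromosome)
#' @param min_len_nt minimum spliced length (default 150)
#' @return data.frame with one row per retained isoform: `circ_id`,
#'   `isoform_id`, `spliced_seq`, `length_nt`; zero rows (with a warning) if
#'   no transcript overlaps the window
#' @export
splice_circ <- function(record, annotation, genome, min_len_nt = 150L) {
  stopifnot(nrow(record) == 1L)
  ex <- annotation$exons
  ex <- ex[ex$gene == record$gene & ex$chrom == record$chrom, , drop = FALSE]
  if (!record$chrom %in% names(genome))
    stop("chromosome ", record$chrom, " absent from the genome")
  chrom_seq <- genome[[record$chrom]]
  out <- list()
  for (tx in unique(ex$transcript)) {
    te <- ex[ex$transcript == tx, , drop = FALSE]
    ov <- te$start <= record$end & te$end >= record$start
    if (!any(ov)) next
    seg <- te[ov, , drop = FALSE]
    seg$start <- pmax(seg$start, record$start)
    seg$end <- pmin(seg$end, record$end)
    seg <- seg[order(seg$start), , drop = FALSE]
    pieces <- vapply(seq_len(nrow(seg)), function(k)
      as.character(Biostrings::subseq(chrom_seq, seg$start[k], seg$end[k])),
      character(1))
    s <- paste(pieces, collapse = "")
    if (seg$strand[1L] == "-") s <- revcomp(s)
    if (nchar(s) < min_len_nt) next
    out[[length(out) + 1L]] <- data.frame(
      circ_id = record$circ_id, isoform_id = tx, spliced_seq = s,
      length_nt = nchar(s), stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    warning("no exon of any transcript of ", record$gene,
            " overlaps window, or all isoforms are shorter than min_len_nt")
    return(data.frame(circ_id = character(0), isoform_id = character(0),
                      spliced_seq = character(0), length_nt = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$isoform_id), , drop = FALSE]
}
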