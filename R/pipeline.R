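#' Pipeline configuration
#'
#' All thresholds from the underlying analysis recipe are configuration
#' defaults, never hard-coded in the stages, so they remain visible and
#' overridable: the minimum-sample and minimum-length selection filters, the
#' 50-aa ORF floor, the BLOSUM62/11/1 alignment scoring with its 1e-10
#' E-value gate, the quantile/IQR/BH expression filters, and the pass-through
#' IRES probability threshold of 0.3 (this package does not predict IRES; it
#' only carries an optional `prob_IRES` column through if present).
#'
#' @param genome,gtf,proteins,backsplice,sample_sheet required input paths
#' @param domains,m6a_bed,peptides,category_map optional input paths (the
#'   corresponding stages are skipped when `NULL`)
#' @param out_dir output directory
#' @param min_samples,min_len_nt,exclude_intergenic,exclude_readthrough see
#'   [selection_thresholds()]
#' @param min_orf_aa,cycle_cap see [orf_params()]
#' @param matrix,gap_open,gap_extend,lambda,K alignment scoring; see
#'   [align_local()] and [evalue()]
#' @param evalue_max cognate-match E-value gate (default 1e-10)
#' @param pseudocount,alpha,lfc_min,iqr_min,apply_sample_filter see
#'   [filter_params()]
#' @param prob_ires_min pass-through annotation threshold (default 0.3)
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(genome, gtf, proteins, backsplice, sample_sheet,
                            domains = NULL, m6a_bed = NULL, peptides = NULL,
                            category_map = NULL, out_dir = tempfile("circorf"),
                            min_samples = 40L, min_len_nt = 150L,
                            exclude_intergenic = TRUE,
                            exclude_readthrough = TRUE,
                            min_orf_aa = 50L, cycle_cap = 3L,
                            matrix = "BLOSUM62", gap_open = 11,
                            gap_extend = 1, lambda = 0.267, K = 0.041,
                            evalue_max = 1e-10,
                            pseudocount = 1, alpha = 0.05, lfc_min = 1,
                            iqr_min = 0.5, apply_sample_filter = TRUE,
                            prob_ires_min = 0.3) {
  cfg <- list(genome = genome, gtf = gtf, proteins = proteins,
              backsplice = backsplice, sample_sheet = sample_sheet,
              domains = domains, m6a_bed = m6a_bed, peptides = peptides,
              category_map = category_map, out_dir = out_dir,
              min_samples = as.integer(min_samples),
              min_len_nt = as.integer(min_len_nt),
              exclude_intergenic = exclude_intergenic,
              exclude_readthrough = exclude_readthrough,
              min_orf_aa = as.integer(min_orf_aa),
              cycle_cap = as.integer(cycle_cap),
              matrix = matrix, gap_open = gap_open, gap_extend = gap_extend,
              lambda = lambda, K = K, evalue_max = evalue_max,
              pseudocount = pseudocount, alpha = alpha, lfc_min = lfc_min,
              iqr_min = iqr_min, apply_sample_filter = apply_sample_filter,
              prob_ires_min = prob_ires_min)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration as flat-key JSON
#' @param config a `pipeline_config`
#' @param path JSON file path
#' @return the path (write) or a `pipeline_config` (read)
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(pipeline_config, vals[!vapply(vals, is.null, logical(1))])
  cfg
}

read_fasta_named <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Run the full circRNA coding-potential pipeline
#'
#' Stages, in order: parse inputs; select backsplice records; splice
#' circularized isoforms; call circular ORFs and keep the longest per
#' circRNA; classify terminus novelty against cognate proteins; compare
#' domain architectures; quantile-normalized differential expression of the
#' novelty set; m6A interval overlap of the DE hits and peptide-database
#' matching of the novel extensions. Every stage writes a TSV into
#' `config$out_dir` and the record counts are conserved
#' (input = retained + rejected, with per-record reasons).
#'
#' @param config a [pipeline_config()] object (or a path to a JSON config)
#' @return a `run_summary` list; see [report_summary()]
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  for (p in c("genome", "gtf", "proteins", "backsplice", "sample_sheet")) {
    if (!file.exists(config[[p]]))
      stop("input file for '", p, "' does not exist: ", config[[p]])
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  genome <- Biostrings::readDNAStringSet(config$genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  annotation <- read_annotation(config$gtf)
  cognates_all <- read_fasta_named(config$proteins)
  obs <- read_backsplice(config$backsplice)
  records <- backsplice_records(obs)
  sample_sheet <- read_tsv(config$sample_sheet)
  thresholds <- selection_thresholds(config$min_samples, config$min_len_nt,
                                     config$exclude_intergenic,
                                     config$exclude_readthrough)
  oparams <- orf_params(config$min_orf_aa, config$cycle_cap)
  fparams <- filter_params(config$pseudocount, config$alpha, config$lfc_min,
                           config$iqr_min, config$apply_sample_filter)

  ## ---- selection
  sel <- select_circrnas(records, thresholds, annotation)
  rejections <- if (nrow(sel$rejected))
    data.frame(circ_id = sel$rejected$circ_id, stage = "selection",
               reason = sel$rejected$reason, stringsAsFactors = FALSE)
  else data.frame(circ_id = character(0), stage = character(0),
                  reason = character(0))

  ## ---- splicing + ORF calling
  orf_rows <- list()
  rolling_rows <- list()
  transcript_rows <- list()
  for (i in seq_len(nrow(sel$retained))) {
    rec <- sel$retained[i, ]
    iso <- withCallingHandlers(
      splice_circ(rec, annotation, genome, config$min_len_nt),
      warning = function(w) invokeRestart("muffleWarning"))
    if (nrow(iso) == 0L) {
      rejections <- rbind(rejections, data.frame(
        circ_id = rec$circ_id, stage = "splice",
        reason = "no overlapping exons or spliced length < min_len_nt"))
      next
    }
    transcript_rows[[length(transcript_rows) + 1L]] <-
      iso[, c("circ_id", "isoform_id", "length_nt")]
    best <- NULL
    for (k in seq_len(nrow(iso))) {
      orfs <- enumerate_circorfs(iso$spliced_seq[k], oparams)
      if (any(orfs$rolling_circle)) {
        rc <- orfs[orfs$rolling_circle, , drop = FALSE]
        rolling_rows[[length(rolling_rows) + 1L]] <- data.frame(
          circ_id = rec$circ_id, isoform_id = iso$isoform_id[k],
          start_nt = rc$start_nt, length_aa = rc$length_aa,
          stringsAsFactors = FALSE)
      }
      cand <- longest_circorf(orfs)
      if (!is.null(cand) &&
          (is.null(best) || cand$length_aa > best$length_aa)) {
        best <- cand
        best$isoform_id <- iso$isoform_id[k]
      }
    }
    if (is.null(best)) {
      rejections <- rbind(rejections, data.frame(
        circ_id = rec$circ_id, stage = "orf",
        reason = "no qualifying (non-rolling) ORF"))
      next
    }
    best$circ_id <- rec$circ_id
    best$gene <- rec$gene
    orf_rows[[length(orf_rows) + 1L]] <- best
  }
  orfs_df <- if (length(orf_rows)) do.call(rbind, orf_rows) else NULL
  rolling_df <- if (length(rolling_rows)) do.call(rbind, rolling_rows) else
    data.frame(circ_id = character(0), isoform_id = character(0),
               start_nt = integer(0), length_aa = integer(0))

  ## ---- terminus novelty
  novelty_rows <- list()
  if (!is.null(orfs_df)) {
    cog_gene <- sub("\\.[^.]*$", "", names(cognates_all))
    for (i in seq_len(nrow(orfs_df))) {
      row <- orfs_df[i, ]
      cogs <- cognates_all[cog_gene == row$gene]
      hit <- best_cognate(row$protein, cogs, config$matrix, config$gap_open,
                          config$gap_extend, config$lambda, config$K)
      if (is.null(hit) || hit$evalue > config$evalue_max) {
        rejections <- rbind(rejections, data.frame(
          circ_id = row$circ_id, stage = "novelty",
          reason = "no cognate match at the E-value threshold"))
        next
      }
      ann <- annotate_termini(nchar(row$protein), hit$cognate_len, hit$aln,
                              row$protein)
      novelty_rows[[length(novelty_rows) + 1L]] <- data.frame(
        circ_id = row$circ_id, gene = row$gene, cognate_id = hit$cognate_id,
        evalue = hit$evalue, n_class = ann$n_class, c_class = ann$c_class,
        n_ext = ann$n_ext, c_ext = ann$c_ext, annotation = ann$annotation,
        protein = row$protein, stringsAsFactors = FALSE)
    }
  }
  novelty_df <- if (length(novelty_rows)) do.call(rbind, novelty_rows) else
    data.frame(circ_id = character(0), gene = character(0),
               cognate_id = character(0), evalue = numeric(0),
               n_class = character(0), c_class = character(0),
               n_ext = character(0), c_ext = character(0),
               annotation = character(0), protein = character(0))
  novelty_df$has_primary_novelty <-
    !(novelty_df$n_class == "canonicalMet" &
      novelty_df$c_class == "canonicalSTOP")

  ## ---- domain architecture comparison
  domain_df <- data.frame(circ_id = character(0), class = character(0),
                          vs_isoform = character(0))
  if (!is.null(config$domains) && nrow(novelty_df) > 0L) {
    dom <- read_tsv(config$domains)
    dom_by_prot <- split(dom, dom$protein_id)
    rows <- list()
    for (i in seq_len(nrow(novelty_df))) {
      gene <- novelty_df$gene[i]
      circ_pid <- paste0("CIRC", gene)
      circ_arch <- domain_architecture(circ_pid, dom_by_prot[[circ_pid]])
      iso_ids <- grep(paste0("^", gene, "\\."), names(dom_by_prot),
                      value = TRUE)
      if (!length(iso_ids)) next
      isoforms <- lapply(iso_ids, function(id)
        domain_architecture(id, dom_by_prot[[id]]))
      cls <- classify_vs_all(circ_arch, isoforms)
      rows[[length(rows) + 1L]] <- data.frame(
        circ_id = novelty_df$circ_id[i], class = cls$class,
        vs_isoform = cls$vs_isoform, stringsAsFactors = FALSE)
    }
    if (length(rows)) domain_df <- do.call(rbind, rows)
  }

  ## ---- differential expression on the novelty set
  has_domain_novelty <- setNames(
    domain_df$class != "conservedStructure", domain_df$circ_id)
  in_novelty_set <- novelty_df$has_primary_novelty |
    (novelty_df$circ_id %in% names(has_domain_novelty)[has_domain_novelty])
  de_ids <- novelty_df$circ_id[in_novelty_set]

  groups <- setNames(sample_sheet$group, sample_sheet$sample)
  counts <- backsplice_counts(obs, samples = sample_sheet$sample)
  de_df <- NULL
  volcano <- NULL
  n_var <- 0L
  if (length(de_ids) > 0L) {
    lib <- colSums(counts)
    mat <- to_log2_rpm(counts, lib, fparams$pseudocount)
    mat <- quantile_normalize(mat)
    if (fparams$apply_sample_filter)
      mat <- withCallingHandlers(filter_samples(mat),
                                 warning = function(w)
                                   invokeRestart("muffleWarning"))
    mat <- mat[rownames(mat) %in% de_ids, , drop = FALSE]
    mat <- filter_variable(mat, fparams$iqr_min)
    n_var <- nrow(mat)
    if (nrow(mat) > 0L) {
      de_df <- differential_expression(mat, groups, fparams)
      volcano <- volcano_table(de_df, fparams)
    }
  }

  ## ---- overlap analyses
  m6a_res <- NULL
  if (!is.null(config$m6a_bed) && !is.null(de_df)) {
    sig_ids <- de_df$id[de_df$significant]
    de_recs <- records[records$circ_id %in% de_df$id, , drop = FALSE]
    peaks <- read_bed3(config$m6a_bed)
    m6a_res <- m6a_overlap(
      data.frame(id = de_recs$circ_id, chrom = de_recs$chrom,
                 start = de_recs$start - 1L, end = de_recs$end),
      peaks)
    m6a_res$n_significant_overlapping <-
      sum(m6a_res$flags[names(m6a_res$flags) %in% sig_ids])
  }
  peptide_res <- NULL
  if (!is.null(config$peptides) && nrow(novelty_df) > 0L) {
    db <- read_fasta_named(config$peptides)
    exts <- c(setNames(novelty_df$n_ext,
                       paste0(novelty_df$circ_id, ":n_ext")),
              setNames(novelty_df$c_ext,
                       paste0(novelty_df$circ_id, ":c_ext")))
    exts <- exts[nzchar(exts)]
    peptide_res <- match_peptides(exts, db)
  }
  enr_res <- NULL
  if (!is.null(config$category_map) && !is.null(de_df)) {
    cmap <- read_tsv(config$category_map)
    sig_genes <- unique(records$gene[records$circ_id %in%
                                       de_df$id[de_df$significant]])
    bg_genes <- unique(records$gene[records$circ_id %in% de_df$id])
    enr_res <- overrepresentation(sig_genes, bg_genes, cmap,
                                  fdr_max = fparams$alpha)
  }

  ## ---- summary + outputs
  grid <- extension_stats(apply(novelty_df, 1L, function(r)
    structure(as.list(r), class = "terminus_annotation")))
  summary <- structure(list(
    config = config,
    n_input = nrow(records),
    n_selected = nrow(sel$retained),
    n_with_orf = if (is.null(orfs_df)) 0L else nrow(orfs_df),
    n_classified = nrow(novelty_df),
    n_primary_novelty = sum(novelty_df$has_primary_novelty),
    n_domain_novelty = sum(has_domain_novelty),
    n_novelty_set = length(de_ids),
    n_variable = n_var,
    n_de_tested = if (is.null(de_df)) 0L else nrow(de_df),
    n_de_significant = if (is.null(de_df)) 0L else sum(de_df$significant),
    terminus_grid = grid$counts,
    extension_means = c(n_ext = grid$n_ext_mean, c_ext = grid$c_ext_mean),
    domain_tally = table(factor(domain_df$class, levels = DOMAIN_CLASSES)),
    rejections = rejections,
    rolling = rolling_df,
    novelty = novelty_df,
    domain_diff = domain_df,
    de = de_df,
    volcano = volcano,
    m6a = m6a_res,
    peptides = peptide_res,
    enrichment = enr_res), class = "run_summary")

  out <- config$out_dir
  write_tsv(novelty_df[, setdiff(names(novelty_df), "protein")],
            file.path(out, "novelty.tsv"))
  write_tsv(domain_df, file.path(out, "domain_diff.tsv"))
  if (!is.null(de_df)) write_tsv(de_df, file.path(out, "de.tsv"))
  if (!is.null(volcano)) write_tsv(volcano, file.path(out, "volcano.tsv"))
  write_tsv(rejections, file.path(out, "rejections.tsv"))
  if (!is.null(peptide_res))
    write_tsv(peptide_res, file.path(out, "peptide_matches.tsv"))
  if (!is.null(enr_res))
    write_tsv(enr_res, file.path(out, "enrichment.tsv"))
  if (!is.null(m6a_res))
    write_tsv(data.frame(circ_id = names(m6a_res$flags),
                         m6a_overlap = unname(m6a_res$flags)),
              file.path(out, "m6a_overlap.tsv"))
  if (!is.null(orfs_df)) {
    fa <- setNames(as.list(orfs_df$protein),
                   sprintf("%s|start:%d|frame:%d|junction:%s",
                           orfs_df$circ_id, orfs_df$start_nt, orfs_df$frame,
                           ifelse(orfs_df$crosses_junction, "yes", "no")))
    write_fasta(fa, file.path(out, "circorf_proteins.fa"))
  }
  summary
}

read_bed3 <- function(path) {
  if (file.size(path) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  df <- as.data.frame(data.table::fread(path, header = FALSE,
                                        data.table = FALSE))
  data.frame(chrom = as.character(df[[1]]), start = as.integer(df[[2]]),
             end = as.integer(df[[3]]), stringsAsFactors = FALSE)
}

#' Human-readable run report
#'
#' Prints the per-stage record counts, the 3x3 terminus grid, the domain
#' category tally, DE counts and overlap results of a pipeline run.
#'
#' @param summary a `run_summary` from [run_pipeline()]
#' @param file optional path; when given the report is also written there
#' @return the report lines, invisibly
#' @export
report_summary <- function(summary, file = NULL) {
  stopifnot(inherits(summary, "run_summary"))
  fmt_table <- function(tab) {
    out <- utils::capture.output(print(tab))
    paste0("  ", out)
  }
  lines <- c(
    "circORF pipeline run summary",
    "============================",
    sprintf("backsplice records in:          %d", summary$n_input),
    sprintf("passing selection filters:      %d", summary$n_selected),
    sprintf("with a qualifying circORF:      %d", summary$n_with_orf),
    sprintf("with a cognate match:           %d", summary$n_classified),
    sprintf("with novel primary structure:   %d", summary$n_primary_novelty),
    sprintf("with novel domain composition:  %d", summary$n_domain_novelty),
    sprintf("novelty set (union):            %d", summary$n_novelty_set),
    sprintf("variable (IQR filter):          %d", summary$n_variable),
    sprintf("DE tested / significant:        %d / %d",
            summary$n_de_tested, summary$n_de_significant),
    "",
    "terminus class grid (N x C):",
    fmt_table(summary$terminus_grid),
    "",
    "domain category tally:",
    fmt_table(summary$domain_tally))
  if (!is.null(summary$m6a))
    lines <- c(lines, "", sprintf(
      "DE-significant circRNAs overlapping m6A peaks: %d",
      summary$m6a$n_significant_overlapping))
  if (!is.null(summary$peptides))
    lines <- c(lines, sprintf(
      "novel terminus peptides matched in the database: %d",
      length(unique(summary$peptides$extension_id))))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' @export
print.run_summary <- function(x, ...) {
  writeLines(report_summary(x))
  invisible(x)
}
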