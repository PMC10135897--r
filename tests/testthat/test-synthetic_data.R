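test_that("config validation rejects impossible worlds", {
  expect_error(synthetic_config(frac_cancer = 0), "frac_cancer")
  expect_error(synthetic_config(de_effect = -1), "de_effect")
  expect_error(synthetic_config(exon_len = c(10L, 30L)), "50-aa ORF")
  expect_error(synthetic_config(n_circ = 5L, n_decoys = 4L),
               "cannot realize")
  expect_error(synthetic_config(planted_classes = "weirdLabel",
                                n_circ = 5L, n_decoys = 0L, n_genes = 9L),
               "unknown planted scenario")
})

test_that("identical configs produce byte-identical fixture files", {
  cfg <- synthetic_config(seed = 99L)
  d1 <- tempfile(); d2 <- tempfile()
  f1 <- simulate_fixtures(cfg, d1)
  f2 <- simulate_fixtures(cfg, d2)
  for (p in names(f1$paths)) {
    expect_equal(unname(tools::md5sum(f1$paths[[p]])),
                 unname(tools::md5sum(f2$paths[[p]])), info = p)
  }
})

test_that("every planted scenario label is realized and counts are conserved", {
  fx <- noiseless_run()$fx
  truth <- fx$truth
  cfg <- noiseless_run()$cfg
  for (lab in cfg$planted_classes)
    expect_true(lab %in% truth$scenario, info = lab)
  # TSV circRNA count equals n_circ
  obs <- read_backsplice(fx$paths$backsplice)
  expect_equal(nrow(backsplice_records(obs)), cfg$n_circ)
  # every gene symbol except the planted intergenic decoy is annotated
  ann <- read_annotation(fx$paths$gtf)
  syms <- unique(obs$symbol)
  expect_setequal(setdiff(syms, ann$genes$gene), "UNANNOT1")
})

test_that("cognate proteins translate exactly from the annotated CDS", {
  fx <- noiseless_run()$fx
  ann <- read_annotation(fx$paths$gtf)
  genome <- Biostrings::readDNAStringSet(fx$paths$genome)
  for (tx in unique(ann$cds$transcript)) {
    ce <- ann$cds[ann$cds$transcript == tx, , drop = FALSE]
    ce <- ce[order(ce$start), , drop = FALSE]
    nt <- paste(vapply(seq_len(nrow(ce)), function(k)
      as.character(Biostrings::subseq(genome[[ce$chrom[k]]],
                                      ce$start[k], ce$end[k])),
      character(1)), collapse = "")
    if (ce$strand[1] == "-")
      nt <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(nt)))
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt)))
    expect_equal(aa, unname(fx$ref$proteins[[tx]]), info = tx)
  }
})

test_that("the planted rolling circle is stop-free in its reading frame", {
  run <- noiseless_run()
  truth <- run$fx$truth
  roll <- truth[truth$scenario == "rollingCircle", ]
  expect_equal(nrow(roll), 1L)
  rec <- toy_record(roll$gene, roll$chrom, roll$start, roll$end)
  ann <- read_annotation(run$fx$paths$gtf)
  genome <- Biostrings::readDNAStringSet(run$fx$paths$genome)
  iso <- splice_circ(rec, ann, genome, 150)
  s <- iso$spliced_seq
  expect_equal(nchar(s) %% 3L, 0L)
  atg <- gregexpr("ATG", paste0(s, substr(s, 1, 2)), fixed = TRUE)[[1]]
  expect_equal(length(atg), 1L)
  # scan every codon of the frame defined by the lone ATG: no stop anywhere
  p <- atg[1] - 1L
  doubled <- paste0(s, s)
  codons <- vapply(seq_len(nchar(s) %/% 3L) - 1L, function(k)
    substr(doubled, p + 3L * k + 1L, p + 3L * k + 3L), character(1))
  expect_false(any(codons %in% c("TAA", "TAG", "TGA")))
})

test_that("expression planting is exact before noise and refuses tiny designs", {
  cfg <- synthetic_config(seed = 3L, noise_sd = 0, de_effect = 2)
  ref <- make_reference(cfg)
  ex <- make_expression(cfg, ref$truth)
  groups <- setNames(ex$sample_sheet$group, ex$sample_sheet$sample)
  mu <- ex$log2_means
  dif <- rowMeans(mu[, groups == "cancer"]) - rowMeans(mu[, groups == "normal"])
  up <- ex$truth$de_status == "up"
  dn <- ex$truth$de_status == "down"
  expect_true(any(up) && any(dn))
  expect_equal(unname(dif[up]), rep(2, sum(up)))
  expect_equal(unname(dif[dn]), rep(-2, sum(dn)))
  expect_equal(unname(dif[!up & !dn]), rep(0, sum(!up & !dn)))
  # de_effect = 0 -> no planted DE rows at all
  cfg0 <- synthetic_config(seed = 3L, de_effect = 0)
  ex0 <- make_expression(cfg0, make_reference(cfg0)$truth)
  expect_true(all(ex0$truth$de_status == "null"))
  # n_samples < 4 is refused
  expect_error(make_expression(synthetic_config(n_samples = 3L), ref$truth),
               "at least 4")
  # the few-samples decoy is expressed below the selection floor
  obs <- ex$observations
  few <- ex$truth$gene[ex$truth$scenario == "decoy:few_samples"]
  expect_lt(sum(obs$symbol == few & obs$reads > 0),
            cfg$min_samples_expressed)
})

test_that("annotation tracks agree with the planted m6A and peptide truth", {
  run <- noiseless_run()
  tracks <- make_annotation_tracks(run$cfg, run$fx$ref)
  truth <- tracks$truth
  peaks <- tracks$m6a_peaks
  coding <- truth[truth$kind == "coding", ]
  for (i in seq_len(nrow(coding))) {
    w <- c(coding$start[i] - 1L, coding$end[i])
    hit <- any(peaks$chrom == coding$chrom[i] &
                 peaks$start < w[2] & peaks$end > w[1])
    expect_equal(hit, coding$m6a[i], info = coding$circ_id[i])
  }
  db <- tracks$peptides
  flagged_c <- truth$c_ext[truth$pep_c_in_db]
  unflagged_c <- setdiff(truth$c_ext[nzchar(truth$c_ext)], flagged_c)
  expect_true(all(flagged_c %in% db))
  for (u in unflagged_c)
    expect_false(any(vapply(db, function(p)
      grepl(u, p, fixed = TRUE) || grepl(p, u, fixed = TRUE), logical(1))))
  # decoy database entries match no extension in either direction
  exts <- c(truth$n_ext, truth$c_ext)
  exts <- exts[nzchar(exts)]
  for (d in db[grepl("DECOY", names(db))])
    expect_false(any(vapply(exts, function(e)
      grepl(d, e, fixed = TRUE) || grepl(e, d, fixed = TRUE), logical(1))))
})
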