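test_that("splice_circ performs the exon arithmetic of the window", {
  ref <- toy_reference()
  # window covering exons 2 and 3 exactly -> their concatenation, length 200
  rec <- toy_record("G1", "chr1", 301, 600)
  iso <- splice_circ(rec, ref$annotation, ref$genome, min_len_nt = 150)
  expect_equal(nrow(iso), 1L)
  expect_equal(iso$length_nt, 200L)
  expect_equal(iso$spliced_seq,
               paste0(substr(ref$chr1, 301, 400), substr(ref$chr1, 501, 600)))
  # partial exon overlap is clipped to the window
  rec2 <- toy_record("G1", "chr1", 351, 600)
  iso2 <- splice_circ(rec2, ref$annotation, ref$genome, min_len_nt = 100)
  expect_equal(iso2$length_nt, 150L)
  expect_equal(substr(iso2$spliced_seq, 1, 50), substr(ref$chr1, 351, 400))
  # a single 100-nt exon window fails the 150-nt filter
  expect_warning(
    short <- splice_circ(toy_record("G1", "chr1", 301, 400), ref$annotation,
                         ref$genome, min_len_nt = 150),
    "min_len_nt")
  expect_equal(nrow(short), 0L)
})

test_that("minus-strand splicing is the reverse complement of its mirror", {
  ref <- toy_reference()
  plus <- splice_circ(toy_record("G1", "chr1", 301, 600), ref$annotation,
                      ref$genome, 150)
  minus <- splice_circ(toy_record("G2", "chr2", 301, 600), ref$annotation,
                       ref$genome, 150)
  expect_equal(minus$spliced_seq,
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(plus$spliced_seq))))
  # length conservation: sum of clipped exon lengths
  expect_equal(minus$length_nt, plus$length_nt)
})

test_that("select_circrnas applies each filter with a logged reason", {
  ref <- toy_reference()
  th <- selection_thresholds(min_samples = 40, exclude_intergenic = TRUE,
                             exclude_readthrough = TRUE)
  # boundary case: 39 samples is rejected, 40 is kept
  r39 <- toy_record("G1", "chr1", 301, 600, samples_expressed = 39)
  r40 <- toy_record("G1", "chr1", 301, 600, samples_expressed = 40)
  s <- select_circrnas(rbind(r39, r40), th, ref$annotation)
  expect_equal(nrow(s$retained), 1L)
  expect_match(s$rejected$reason, "39 < 40")
  # zero samples rejected regardless
  s0 <- select_circrnas(toy_record("G1", "chr1", 301, 600, 0),
                        selection_thresholds(min_samples = 0),
                        ref$annotation)
  expect_equal(nrow(s0$retained), 1L)  # min_samples 0 admits it...
  s0b <- select_circrnas(toy_record("G1", "chr1", 301, 600, 0), th,
                         ref$annotation)
  expect_equal(nrow(s0b$retained), 0L) # ...but any positive floor rejects
  # unannotated gene
  si <- select_circrnas(toy_record("NOGENE", "chr1", 10, 90), th,
                        ref$annotation)
  expect_equal(si$rejected$reason, "intergenic/unannotated")
  # window spanning G1 and G3
  sr <- select_circrnas(toy_record("G1", "chr1", 550, 750), th,
                        ref$annotation)
  expect_match(sr$rejected$reason, "read-through")
})

test_that("ten records with three single-filter violations keep seven", {
  ref <- toy_reference()
  th <- selection_thresholds(min_samples = 40)
  good <- do.call(rbind, lapply(1:7, function(i)
    toy_record("G1", "chr1", 300 + i, 600, samples_expressed = 40 + i)))
  bad <- rbind(toy_record("G1", "chr1", 310, 600, samples_expressed = 39),
               toy_record("NOGENE", "chr1", 10, 90),
               toy_record("G1", "chr1", 550, 750))
  s <- select_circrnas(rbind(good, bad), th, ref$annotation)
  expect_equal(nrow(s$retained), 7L)
  expect_equal(nrow(s$rejected), 3L)
  expect_equal(sort(unique(s$rejected$reason)),
               sort(c("expressed in 39 < 40 samples",
                      "intergenic/unannotated",
                      "read-through (spans >1 gene)")))
  # idempotence: selecting the retained set again changes nothing
  s2 <- select_circrnas(s$retained, th, ref$annotation)
  expect_equal(s2$retained, s$retained)
  expect_equal(nrow(s2$rejected), 0L)
})

test_that("backsplice observations aggregate into records and counts", {
  obs <- data.frame(chr = "chr1", start = 301L, end = 600L,
                    reads = c(5L, 0L, 7L), symbol = "G1",
                    sample = c("s1", "s2", "s3"))
  rec <- backsplice_records(obs)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$samples_expressed, 2L)
  expect_equal(rec$circ_id, "G1|chr1:301-600")
  cm <- backsplice_counts(obs, samples = c("s1", "s2", "s3", "s4"))
  expect_equal(unname(cm["G1|chr1:301-600", ]), c(5L, 0L, 7L, 0L))
})
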