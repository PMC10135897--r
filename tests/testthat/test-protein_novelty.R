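test_that("align_local reproduces hand-computable BLOSUM62 scores", {
  # M:M (5) + three A:A (4 each) = 17
  a <- align_local("MAAA", "MAAA")
  expect_equal(a$score, 17)
  expect_equal(unlist(a[c("q_start", "q_end", "s_start", "s_end")]),
               c(q_start = 1L, q_end = 4L, s_start = 1L, s_end = 4L))
  # classic textbook pair, affine gaps 11/1; value frozen from an
  # independent DP run
  expect_equal(align_local("HEAGAWGHEE", "PAWHEAE")$score, 17)
  expect_error(align_local("", "MAAA"), "non-empty")
  expect_error(align_local("MAAA", "MA4A"), "absent")
})

test_that("self-alignment spans the whole sequence with the diagonal score", {
  set.seed(21)
  b62 <- get_blosum62()
  for (i in 1:10) {
    x <- random_peptide(sample(5:25, 1))
    cs <- strsplit(x, "")[[1]]
    a <- align_local(x, x)
    expect_equal(a$score, sum(b62[cbind(cs, cs)]))
    expect_equal(c(a$q_start, a$q_end), c(a$s_start, a$s_end))
    expect_equal(c(a$q_start, a$q_end), c(1L, nchar(x)))
  }
})

test_that("align_local score equals the independent Biostrings oracle", {
  set.seed(22)
  for (i in 1:30) {
    q <- random_peptide(sample(5:30, 1))
    s <- random_peptide(sample(5:30, 1))
    expect_equal(align_local(q, s)$score, oracle_sw_score(q, s),
                 info = paste(q, s))
  }
})

test_that("evalue follows the Karlin-Altschul closed form", {
  expect_equal(evalue(0, 100, 100, lambda = 0.267, K = 0.041), 410)
  # monotone decreasing in score
  sc <- seq(0, 500, by = 50)
  ev <- vapply(sc, evalue, numeric(1), query_len = 100, db_len = 1e4)
  expect_true(all(diff(ev) < 0))
  # linear in database length
  expect_equal(evalue(30, 50, 2000), 2 * evalue(30, 50, 1000))
  expect_error(evalue(10, 100, 100, lambda = -1), "positive")
  expect_error(evalue(10, 0, 100), ">= 1")
})

test_that("annotate_termini implements the 3x3 classification grid", {
  aln <- function(qs, qe, ss, se)
    structure(list(score = 100, q_start = qs, q_end = qe,
                   s_start = ss, s_end = se), class = "local_alignment")
  q80 <- strrep("A", 80)
  # aligned prefix + novel tail
  ann <- annotate_termini(80, 100, aln(1, 60, 1, 60), q80)
  expect_equal(ann$n_class, "canonicalMet")
  expect_equal(ann$c_class, "C-term")
  expect_equal(nchar(ann$c_ext), 20)
  expect_equal(ann$n_ext, "")
  expect_equal(ann$annotation, "C-term|canonicalMet")
  # full identity
  ann2 <- annotate_termini(80, 80, aln(1, 80, 1, 80), q80)
  expect_equal(c(ann2$n_class, ann2$c_class),
               c("canonicalMet", "canonicalSTOP"))
  expect_equal(c(ann2$n_ext, ann2$c_ext), c("", ""))
  # internal start + premature stop: truncated protein, no extensions
  ann3 <- annotate_termini(50, 100, aln(1, 50, 31, 80), strrep("A", 50))
  expect_equal(c(ann3$n_class, ann3$c_class),
               c("internalMet", "prematureTerm"))
  expect_equal(c(ann3$n_ext, ann3$c_ext), c("", ""))
  expect_error(annotate_termini(50, 40, aln(1, 50, 31, 80), strrep("A", 50)),
               "inconsistent")
})

test_that("the terminus grid is total and the concatenation identity holds", {
  set.seed(23)
  n_levels <- c("canonicalMet", "internalMet", "N-term")
  c_levels <- c("canonicalSTOP", "prematureTerm", "C-term")
  for (i in 1:500) {
    qlen <- sample(3:40, 1)
    slen <- sample(3:40, 1)
    qs <- sample.int(qlen, 1)
    qe <- qs + sample.int(qlen - qs + 1L, 1) - 1L
    ss <- sample.int(slen, 1)
    se <- ss + sample.int(slen - ss + 1L, 1) - 1L
    q <- random_peptide(qlen)
    ann <- annotate_termini(qlen, slen,
                            structure(list(score = 1, q_start = qs,
                                           q_end = qe, s_start = ss,
                                           s_end = se),
                                      class = "local_alignment"), q)
    expect_true(ann$n_class %in% n_levels)
    expect_true(ann$c_class %in% c_levels)
    expect_equal(paste0(ann$n_ext, substr(q, qs, qe), ann$c_ext), q)
    expect_equal(nzchar(ann$n_ext), ann$n_class == "N-term")
    expect_equal(nzchar(ann$c_ext), ann$c_class == "C-term")
  }
})

test_that("best_cognate minimizes E-value with deterministic tie-breaks", {
  q <- "MKWVRDELAAGGHI"
  cogs <- c(iso_b = "MKWVRDELAAGGHI", iso_a = "MKWVRDEL",
            iso_c = "WWWWWWWW")
  hit <- best_cognate(q, cogs)
  expect_equal(hit$cognate_id, "iso_b")
  # exact tie on two identical cognates -> lexicographic id
  hit2 <- best_cognate(q, c(z = q, a = q))
  expect_equal(hit2$cognate_id, "a")
  expect_null(best_cognate(q, character(0)))
  expect_error(best_cognate(q, c("MKWV")), "named")
})

test_that("extension_stats summarises class pairs and extension lengths", {
  mk <- function(n_class, c_class, n_ext = "", c_ext = "")
    structure(list(n_class = n_class, c_class = c_class,
                   n_ext = n_ext, c_ext = c_ext),
              class = "terminus_annotation")
  empty <- extension_stats(list())
  expect_equal(sum(empty$counts), 0)
  expect_true(is.na(empty$c_ext_mean))
  st <- extension_stats(list(
    mk("canonicalMet", "C-term", c_ext = strrep("W", 10)),
    mk("canonicalMet", "C-term", c_ext = strrep("W", 20)),
    mk("N-term", "C-term", n_ext = "MWPY", c_ext = strrep("W", 30))))
  expect_equal(st$c_ext_mean, 20)
  expect_equal(st$n_ext_mean, 4)
  expect_equal(sum(st$counts), 3)
  expect_equal(unname(st$counts["canonicalMet", "C-term"]), 2)
})
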