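make_read <- function(template, peptide, quals = 35L) {
  bases <- construct_dna(template, peptide)
  q <- if (length(quals) == 1L) rep(quals, nchar(bases)) else quals
  read_record("r1", bases, q)
}

test_that("orient_read recognises both strands and rejects junk", {
  r <- make_read(loop_tpl, "YLTIRLM")
  sense <- orient_read(r, loop_tpl)
  expect_identical(sense$orientation, "sense")
  expect_identical(sense$bases, r$bases)

  flipped <- read_record("r2", revcomp(r$bases), rev(r$quals))
  anti <- orient_read(flipped, loop_tpl)
  expect_identical(anti$orientation, "antisense")
  expect_identical(anti$bases, r$bases)  # reverse-transcribed in silico

  set.seed(1)
  junk <- read_record("r3", paste(sample(c("A", "C", "G", "T"), 200,
                                         replace = TRUE), collapse = ""),
                      rep(35L, 200))
  expect_identical(orient_read(junk, loop_tpl)$fate, "unoriented")
})

test_that("orientation is idempotent under reverse complementation", {
  set.seed(2)
  for (pep in random_peptides(5, 7)) {
    r <- make_read(loop_tpl, pep)
    once <- orient_read(r, loop_tpl)
    twice <- orient_read(read_record(r$read_id, revcomp(r$bases),
                                     rev(r$quals)), loop_tpl)
    expect_identical(once$bases, twice$bases)
  }
})

test_that("quality filter applies the N and Phred-21 rules", {
  r <- make_read(loop_tpl, "YLTIRLM", quals = 30L)
  expect_true(is.na(quality_filter(r)$fate))

  q <- rep(40L, nchar(r$bases)); q[10] <- 20L
  expect_identical(quality_filter(read_record("r", r$bases, q))$fate,
                   "low_quality")
  q[10] <- 21L  # boundary: score 21 is acceptable
  expect_true(is.na(quality_filter(read_record("r", r$bases, q))$fate))

  bn <- r$bases; substr(bn, 10, 10) <- "N"
  expect_identical(quality_filter(read_record("r", bn, rep(40L, nchar(bn))))$fate,
                   "contains_N")
  expect_error(quality_filter(r, min_phred = -1), "non-negative")
})

test_that("frame and constant checks extract the variable codons", {
  r <- orient_read(make_read(loop_tpl, "YLTIRLM"), loop_tpl)
  chk <- frame_and_constant_check(r, loop_tpl)
  expect_true(is.na(chk$read$fate))
  expect_identical(chk$codons, "TATCTGACCATTCGTCTGATG")
  expect_identical(translate_variable_region(chk$codons)$peptide, "YLTIRLM")

  # substitution inside the 5' flank
  bad <- r
  f5 <- regexpr(loop_tpl$dna_flank_5p, bad$bases, fixed = TRUE)[1]
  substr(bad$bases, f5 + 1L, f5 + 1L) <-
    setdiff(c("A", "C", "G", "T"), substr(bad$bases, f5 + 1L, f5 + 1L))[1]
  expect_identical(frame_and_constant_check(bad, loop_tpl)$read$fate,
                   "flank_mismatch")

  # truncation before the 3' flank
  trunc <- r
  trunc$bases <- substr(trunc$bases, 1, f5 + nchar(loop_tpl$dna_flank_5p) + 10L)
  trunc$quals <- trunc$quals[seq_len(nchar(trunc$bases))]
  expect_identical(frame_and_constant_check(trunc, loop_tpl)$read$fate,
                   "flank_mismatch")
})

test_that("side-library constant-region deviations are caught", {
  r <- orient_read(make_read(side_tpl, "VIWIDD"), side_tpl)
  chk <- frame_and_constant_check(r, side_tpl)
  expect_true(is.na(chk$read$fate))
  expect_identical(nchar(chk$codons), 18L)
  expect_identical(translate_variable_region(chk$codons)$peptide, "VIWIDD")

  # mutate a constant base between two variable pairs ("EL" after pair 1)
  bad <- r
  off <- var_region_offset(side_tpl) + 6L  # first base of the EL codons
  substr(bad$bases, off, off) <-
    setdiff(c("A", "C", "G", "T"), substr(bad$bases, off, off))[1]
  expect_identical(frame_and_constant_check(bad, side_tpl)$read$fate,
                   "constant_mismatch")
})

test_that("translation uses the amber-suppressed genetic code", {
  expect_identical(translate_variable_region("TATCTGACCATTCGTCTGATG")$peptide,
                   "YLTIRLM")
  expect_identical(translate_variable_region("TAGCTGACCATTCGTCTGATG")$peptide,
                   "QLTIRLM")
  expect_identical(translate_variable_region("TAACTGACCATTCGTCTGATG")$status,
                   "in_frame_stop")
  expect_identical(translate_variable_region("TGACTGACC")$status,
                   "in_frame_stop")
  expect_identical(translate_variable_region("TATCTGAC")$status, "frame_error")
})

test_that("run_qc retains perfect reads and attributes planted failures", {
  set.seed(4)
  peps <- random_peptides(100, 7)
  reads <- lapply(peps, function(p) perfect_read(loop_tpl, p))
  path <- write_manual_fastq(reads)
  res <- run_qc(path, loop_tpl)
  expect_equal(res$report$retention, 1.0)
  expect_identical(res$peptides$peptide, peps)

  # 10% of reads get one qual-20 base, a different 10% an in-frame TAA
  voff <- var_region_offset(loop_tpl)
  reads2 <- reads
  for (i in 1:10) reads2[[i]]$quals <- {
    q <- rep(35L, nchar(reads2[[i]]$bases)); q[50] <- 20L; q
  }
  for (i in 11:20) substr(reads2[[i]]$bases, voff, voff + 2L) <- "TAA"
  res2 <- run_qc(write_manual_fastq(reads2), loop_tpl)
  expect_equal(res2$report$retention, 0.8)
  expect_equal(res2$report$counts$low_quality, 10L)
  expect_equal(res2$report$counts$in_frame_stop, 10L)
  expect_equal(res2$report$total, 100L)
})

test_that("run_qc handles empty input and reports totals that add up", {
  empty <- tempfile(fileext = ".fastq")
  writeLines(character(0), empty)
  res <- run_qc(empty, loop_tpl)
  expect_equal(res$report$total, 0L)
  expect_equal(nrow(res$peptides), 0L)

  set.seed(9)
  cfg <- sim_config(n_reads = 300, error_rate = 0.01, n_rate = 0.002,
                    seed = NULL)
  path <- tempfile(fileext = ".fastq.gz")
  write_reads_fastq(random_peptides(300, 7), loop_tpl, cfg, path = path)
  rep300 <- run_qc(path, loop_tpl)$report
  expect_equal(Reduce(`+`, rep300$counts), rep300$total)
  expect_equal(rep300$total, 300L)
})

test_that("the filter cascade is order-stable under read permutation", {
  set.seed(5)
  peps <- random_peptides(30, 7)
  reads <- lapply(peps, function(p) perfect_read(loop_tpl, p))
  substr(reads[[3]]$bases, 5, 5) <- "N"
  reads[[7]]$quals <- c(rep(35L, 20), 5L,
                        rep(35L, nchar(reads[[7]]$bases) - 21L))
  perm <- sample(length(reads))
  res_a <- run_qc(write_manual_fastq(reads), loop_tpl)
  res_b <- run_qc(write_manual_fastq(reads[perm]), loop_tpl)
  merged <- res_b$peptides[match(res_a$peptides$read_id,
                                 res_b$peptides$read_id), ]
  expect_identical(merged$peptide, res_a$peptides$peptide)
  expect_identical(res_a$report$counts, res_b$report$counts)
})

test_that("vectorized run_qc agrees with the single-read operations", {
  # mixed fixture: clean sense, clean antisense, flank-mutant, low-qual,
  # N-containing, amber codon, in-frame stop, junk
  set.seed(6)
  voff <- var_region_offset(loop_tpl)
  mk <- function(id, pep) {
    r <- perfect_read(loop_tpl, pep); r$id <- id; r
  }
  reads <- list(mk("clean", "YLTIRLM"), mk("amber", "QLTIRLM"),
                mk("stop", "AAAAAAA"), mk("lowq", "WFDEKHP"),
                mk("hasN", "MNHEYST"), mk("flank", "DDDDDDD"),
                list(id = "junk",
                     bases = paste(sample(c("A", "C", "G", "T"), 250, TRUE),
                                   collapse = ""), quals = 35L))
  substr(reads[[2]]$bases, voff, voff + 2L) <- "TAG"
  substr(reads[[3]]$bases, voff + 3L, voff + 5L) <- "TGA"
  reads[[4]]$quals <- {
    q <- rep(35L, nchar(reads[[4]]$bases)); q[100] <- 3L; q
  }
  substr(reads[[5]]$bases, 60, 60) <- "N"
  f5 <- regexpr(loop_tpl$dna_flank_5p, reads[[6]]$bases, fixed = TRUE)[1]
  substr(reads[[6]]$bases, f5 + 2L, f5 + 2L) <- "A"
  # antisense version of the clean read
  reads <- c(reads, list(list(id = "anti", bases = revcomp(reads[[1]]$bases),
                              quals = 35L)))

  res <- run_qc(write_manual_fastq(reads), loop_tpl)

  # oracle: compose the documented per-read operations
  oracle_fate <- vapply(reads, function(rr) {
    q <- rr$quals
    if (length(q) == 1L) q <- rep(q, nchar(rr$bases))
    r <- read_record(rr$id, rr$bases, q)
    r <- quality_filter(r)
    if (!is.na(r$fate)) return(r$fate)
    r <- orient_read(r, loop_tpl)
    if (!is.na(r$fate)) return(r$fate)
    chk <- frame_and_constant_check(r, loop_tpl)
    if (!is.na(chk$read$fate)) return(chk$read$fate)
    translate_variable_region(chk$codons)$status
  }, character(1))
  expect_identical(res$report$counts$passed, sum(oracle_fate == "passed"))
  expect_identical(sort(res$peptides$read_id),
                   sort(vapply(reads, `[[`, character(1), "id")[
                     oracle_fate == "passed"]))
  expect_setequal(res$peptides$peptide[res$peptides$read_id == "amber"],
                  "QLTIRLM")
})
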