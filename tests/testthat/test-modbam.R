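# Independent oracle for MM delta expansion on a toy forward read:
# deltas (d1, d2, ...) address the (d1+1)-th occurrence of the base, then
# skip d2 more, etc., in original molecule orientation.
expand_deltas_oracle <- function(seq, deltas, base = "A") {
  occ <- which(strsplit(seq, "")[[1]] == base)
  occ[cumsum(deltas + 1)]
}

test_that("MM delta skips address the correct A occurrences", {
  # read with As at query positions (1-based) 1,2,4,6,7,9: MM skip of 2
  # lands on the 3rd A, then delta 1 skips one more
  seq <- "AACACAACA"
  sam <- write_sam(paste0("r1\t0\tref1\t11\t60\t9M\t*\t0\t0\t", seq,
                          "\t*\tMM:Z:A+a?,2,1;\tML:B:C,200,100"))
  calls <- read_modbam(sam)
  oracle_q <- expand_deltas_oracle(seq, c(2, 1))  # 1-based query positions
  expect_equal(calls$pos, 10L + oracle_q - 1L)     # 0-based ref = 10 + q - 1
  expect_equal(nrow(calls), 2)
  expect_equal(calls$modProb, (c(200, 100) + 0.5) / 256)
})

test_that("call count equals ML entry count on a simple read", {
  sam <- write_sam("r1\t0\tref1\t1\t60\t6M\t*\t0\t0\tAAACCA\t*\tMM:Z:A+a?,0,0,1;\tML:B:C,10,20,30")
  expect_equal(nrow(read_modbam(sam)), 3)
})

test_that("reverse-strand reads report forward reference coordinates", {
  # molecule (sense): AACGTAAGGT with As at original 0-based 0,1,5,6;
  # stored SEQ is the reverse complement; deltas 0,1 pick As #1 and #3
  # (original positions 0 and 5), i.e. SEQ indices 9 and 4,
  # i.e. 0-based reference positions 2+9=11 and 2+4=6.
  sam <- write_sam(paste0("r1\t16\tref1\t3\t60\t10M\t*\t0\t0\tACCTTACGTT\t*\t",
                          "MM:Z:A+a?,0,1;\tML:B:C,200,100"))
  calls <- read_modbam(sam)
  expect_equal(sort(calls$pos), c(6L, 11L))
  expect_true(all(calls$strand == "-"))
  expect_true(all(calls$base == "A"))
})

test_that("deletions shift reference coordinates and insertions yield no call", {
  # CIGAR 3M2D3M2I3M over read AAACCAAAAAA; As at query 0,1,2,5,6,7,8,9,10
  # query->ref (pos=1): q0..2 -> 0..2; q3..5 -> 5..7; q6,7 ins -> NA; q8..10 -> 8..10
  # deltas 0,0,0,1,0 address As #1,#2,#3,#5,#6 = q 0,1,2,6,7; q6/q7 are
  # inserted bases and are dropped, leaving ref 0,1,2
  sam <- write_sam(paste0("r1\t0\tref1\t1\t60\t3M2D3M2I3M\t*\t0\t0\t",
                          "AAACCAAAAAA\t*\tMM:Z:A+a?,0,0,0,1,0;\tML:B:C,10,20,30,40,50"))
  calls <- read_modbam(sam)
  expect_equal(calls$pos, c(0L, 1L, 2L))
  # the deletion shifts the post-D block: delta 0,0,0,0 addresses q5 -> ref 7
  sam2 <- write_sam(paste0("r1\t0\tref1\t1\t60\t3M2D3M2I3M\t*\t0\t0\t",
                           "AAACCAAAAAA\t*\tMM:Z:A+a?,0,0,0,0;\tML:B:C,10,20,30,40"))
  expect_equal(read_modbam(sam2)$pos, c(0L, 1L, 2L, 7L))
})

test_that("MM without matching ML length is a tag-consistency error", {
  sam <- write_sam("r1\t0\tref1\t1\t60\t6M\t*\t0\t0\tAAAAAA\t*\tMM:Z:A+a?,0,0;\tML:B:C,10")
  expect_error(read_modbam(sam), "ML")
})

test_that("unmapped reads are skipped and counted", {
  sam <- write_sam(c(
    "r1\t0\tref1\t1\t60\t3M\t*\t0\t0\tAAA\t*\tMM:Z:A+a?,0;\tML:B:C,200",
    "r2\t4\t*\t0\t0\t*\t*\t0\t0\tAAA\t*"))
  calls <- read_modbam(sam)
  expect_equal(nrow(calls), 1)
  expect_equal(attr(calls, "skipped_unmapped"), 1L)
})

test_that("write/read round trip is identity on coordinates and within 1/256 on probabilities", {
  withr::with_seed(11, {
    cfg <- generator_config(seed = 11, stoichiometry = 0.5)
    sim <- simulate_modprob_dataset(cfg, n_refs = 2, coverage = 10)
    reads <- unique(sim$calls$read_id)[1:20]
    calls <- sim$calls %>% filter(read_id %in% reads)
    template <- tibble(
      read_id = reads,
      ref_id = sub("_read.*", "", reads),
      pos = 0L, strand = "+",
      seq = unname(sim$sequences[sub("_read.*", "", reads)]))
    f <- tempfile(fileext = ".sam")
    write_modbam(calls, template, f)
    back <- read_modbam(f)
    m <- inner_join(calls, back, by = c("read_id", "ref_id", "pos"),
                    suffix = c("", ".rt"))
    expect_equal(nrow(m), nrow(calls))  # identity on coordinates
    expect_lte(max(abs(m$modProb - m$modProb.rt)), 1 / 256)
  })
})

test_that("BAM output round-trips through Rsamtools", {
  withr::with_seed(12, {
    cfg <- generator_config(seed = 12, stoichiometry = 0.5)
    sim <- simulate_modprob_dataset(cfg, n_refs = 1, coverage = 5)
    template <- tibble(
      read_id = unique(sim$calls$read_id),
      ref_id = "tx01", pos = 0L, strand = "+",
      seq = unname(sim$sequences["tx01"]))
    f <- file.path(tempdir(), "permod_roundtrip.bam")
    write_modbam(sim$calls, template, f)
    back <- read_modbam(f)
    m <- inner_join(sim$calls, back, by = c("read_id", "ref_id", "pos"),
                    suffix = c("", ".rt"))
    expect_equal(nrow(m), nrow(sim$calls))
    expect_lte(max(abs(m$modProb - m$modProb.rt)), 1 / 256)
    unlink(f)
  })
})

test_that("a call at a position not aligned in the template is an error", {
  calls <- tibble(read_id = "r1", ref_id = "ref1", pos = 50L, modProb = 0.9)
  template <- tibble(read_id = "r1", ref_id = "ref1", pos = 0L,
                     strand = "+", seq = "AAAA")
  expect_error(write_modbam(calls, template, tempfile(fileext = ".sam")),
               "not aligned")
})

test_that("an empty call set writes a header-only file", {
  calls <- tibble(read_id = character(), ref_id = character(),
                  pos = integer(), modProb = numeric())
  template <- tibble(read_id = "r1", ref_id = "ref1", pos = 0L,
                     strand = "+", seq = "AAAA")
  f <- tempfile(fileext = ".sam")
  write_modbam(calls, template, f)
  expect_equal(nrow(read_modbam(f)), 0)
})
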