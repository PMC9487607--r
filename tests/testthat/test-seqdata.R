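test_that("FASTA parsing takes ids up to whitespace and preserves order", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a first record", "KKLL", ">b", "AAAA"), f)
  rec <- read_fasta(f)
  expect_equal(rec$id, c("a", "b"))
  expect_equal(rec$residues, c("KKLL", "AAAA"))
  expect_equal(attr(rec, "n_dropped"), 0L)
})

test_that("records with non-standard residues are dropped and counted", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "KKXLL", ">b", "AAAA"), f)
  expect_warning(rec <- read_fasta(f), "non-standard")
  expect_equal(rec$id, "b")
  expect_equal(attr(rec, "n_dropped"), 1L)
})

test_that("empty files and malformed headers behave per contract", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(), f)
  expect_equal(nrow(read_fasta(f)), 0L)
  writeLines(c("KKLL", ">a", "AAAA"), f)
  expect_error(read_fasta(f), "line 1")
})

test_that("FASTA round trip preserves ids and sequences", {
  rec <- amp_records(c("p1", "p2", "p3"),
                     c("KWKLFKKIEK", "GIGKFLHSAK", "MKT"))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(rec, f)
  back <- read_fasta(f)
  expect_equal(back$id, rec$id)
  expect_equal(back$residues, rec$residues)
})

test_that("annotation tables attach lower-cased keyword/localization sets", {
  rec <- amp_records(c("a", "b"), c("KKKK", "LLLL"))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tkeywords\tlocalization",
               "a\tAntimicrobial;secreted\tcytoplasm",
               "b\t\t"), f)
  out <- read_annotations(f, rec)
  expect_setequal(out$keywords[[1]], c("antimicrobial", "secreted"))
  expect_equal(out$localization[[1]], "cytoplasm")
  expect_length(out$keywords[[2]], 0)

  writeLines(c("id\tkeywords\tlocalization", "a\tx\t", "a\ty\t"), f)
  expect_error(read_annotations(f, rec), "duplicated")
  writeLines(c("id\tkeywords\tlocalization", "zz\tx\t"), f)
  expect_warning(read_annotations(f, rec), "not present")
})

test_that("split_positive uses floor(n*f + 0.5) and is a seeded partition", {
  rec <- amp_records(sprintf("r%02d", 1:10), rep("KKKKK", 10))
  sp <- split_positive(rec, 0.8, seed = 3)
  expect_equal(nrow(sp$train), 8L)
  expect_equal(nrow(sp$bench), 2L)
  expect_length(intersect(sp$train$id, sp$bench$id), 0)
  expect_setequal(c(sp$train$id, sp$bench$id), rec$id)
  sp2 <- split_positive(rec, 0.8, seed = 3)
  expect_identical(sp$train$id, sp2$train$id)
  # the paper-scale count under this rounding rule
  expect_equal(floor(0.8 * 5190 + 0.5), 4152)
  expect_error(split_positive(rec[1, ], 0.8, 1), "at least 2")
})

test_that("every record lands in the bench fold at close to rate 1 - f", {
  rec <- amp_records(sprintf("r%02d", 1:10), rep("KKKKK", 10))
  hits <- numeric(10)
  for (s in 1:200) {
    sp <- split_positive(rec, 0.8, seed = s)
    hits <- hits + rec$id %in% sp$bench$id
  }
  expect_true(all(abs(hits / 200 - 0.2) <= 0.1))
})

test_that("positive redundancy reduction clusters near-identical sequences", {
  rec <- amp_records(c("a", "b", "c"),
                     c("KKKKKKKKKK", "KKKKKKKKKR", "LLLLLLLLLL"))
  expect_equal(nrow(reduce_redundancy_positive(rec, 0.9)), 2L)
  dup <- amp_records(c("a", "b"), c("KWKLFKKIEK", "KWKLFKKIEK"))
  expect_equal(nrow(reduce_redundancy_positive(dup, 0.9)), 1L)
  far <- amp_records(c("a", "b"), c("KKKKKKKKKK", "LLLLLLLLLL"))
  expect_equal(nrow(reduce_redundancy_positive(far, 0.05)), 2L)
})
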