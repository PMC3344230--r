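test_that("maximal gap runs are reported with terminal flags", {
  a <- alignment(c(s1 = "AC--GT", s2 = "ACTTGT"))
  r <- find_gap_runs(a)
  expect_equal(nrow(r), 1)
  expect_equal(r$seq_id, "s1")
  expect_equal(c(r$start, r$end), c(2L, 4L))
  expect_false(r$terminal)

  b <- alignment(c(s1 = "--ACGT", s2 = "CCACGT"))
  rb <- find_gap_runs(b)
  expect_equal(c(rb$start, rb$end), c(0L, 2L))
  expect_true(rb$terminal)

  c0 <- alignment(c(s1 = "ACGT", s2 = "ACGA"))
  expect_equal(nrow(find_gap_runs(c0)), 0)
})

test_that("simple indel coding scores exact extent 1, no overlap 0, partial missing", {
  a <- alignment(c(A = "AC--GT", B = "ACTTGT", C = "A---GT"))
  ch <- simple_indel_coding(a)
  expect_equal(nrow(ch), 2)
  expect_equal(ch$start, c(1L, 2L))
  expect_equal(ch$end, c(4L, 4L))
  # character (1,4): C carries it, B lacks gaps, A's (2,4) run overlaps
  expect_equal(unlist(ch[1, c("A", "B", "C")], use.names = FALSE),
               c("?", "0", "1"))
  # character (2,4): A carries it, B lacks gaps, C's run overlaps
  expect_equal(unlist(ch[2, c("A", "B", "C")], use.names = FALSE),
               c("1", "0", "?"))
  # matches the independent column-wise oracle
  orc <- indel_oracle(c(A = "AC--GT", B = "ACTTGT", C = "A---GT"))
  expect_equal(as.data.frame(ch), orc)
})

test_that("gap-free alignments code zero characters", {
  a <- alignment(c(A = "ACGTAC", B = "ACGAAC"))
  expect_equal(nrow(simple_indel_coding(a)), 0)
})

test_that("a single long deletion codes one character with carrier state 1", {
  carrier <- paste0("ACGTA", strrep("-", 15), "TTGCA")
  other <- paste0("ACGTA", strrep("G", 15), "TTGCA")
  a <- alignment(c(y = carrier, x = other))
  ch <- simple_indel_coding(a)
  expect_equal(nrow(ch), 1)
  expect_equal(ch$end - ch$start, 15L)
  expect_equal(ch$y, "1")
  expect_equal(ch$x, "0")
})

test_that("terminal gaps are not coded and blank overlapping characters", {
  a <- alignment(c(A = "--CCGT", B = "T-CCGT", C = "TACCGT"))
  ch <- simple_indel_coding(a)  # only B's internal (1,2) run is codable
  expect_equal(nrow(ch), 1)
  expect_equal(c(ch$start, ch$end), c(1L, 2L))
  expect_equal(c(ch$A, ch$B, ch$C), c("?", "1", "0"))
  ch2 <- simple_indel_coding(a, treat_terminal_gaps_as = "coded")
  expect_equal(nrow(ch2), 2)
})

test_that("diagnostic indel detection uses reciprocal overlap", {
  win_start <- 5L; win_end <- 20L
  carrier <- paste0("ACGTA", strrep("-", 15), "TTGCA")
  clean <- paste0("ACGTA", strrep("G", 15), "TTGCA")
  partial <- paste0("ACGTA", "GGGG", strrep("-", 7), "GGGG", "TTGCA")
  a <- alignment(c(carrier = carrier, clean = clean, partial = partial))
  expect_equal(detect_diagnostic_indel("carrier", a, c(win_start, win_end)), "carrier")
  expect_equal(detect_diagnostic_indel("clean", a, c(win_start, win_end)), "non_carrier")
  # 7/15 < 0.8 reciprocal overlap
  expect_equal(detect_diagnostic_indel("partial", a, c(win_start, win_end)), "ambiguous")
  expect_error(detect_diagnostic_indel("nope", a, c(win_start, win_end)), "unknown")
})

test_that("coding is idempotent and equivariant under column shifts", {
  set.seed(21)
  for (i in 1:20) {
    seqs <- random_gappy_alignment(sample(3:6, 1), sample(20:40, 1))
    # anchor both ends so no run is terminal: prepending columns must not
    # change the internal/terminal status of any run
    seqs[] <- paste0("A", substr(seqs, 2, nchar(seqs) - 1), "T")
    a <- alignment(seqs)
    c1 <- simple_indel_coding(a)
    c2 <- simple_indel_coding(a)
    expect_identical(c1, c2)
    k <- sample(1:5, 1)
    shifted <- alignment(setNames(paste0(strrep("A", k), seqs), names(seqs)))
    cs <- simple_indel_coding(shifted)
    expect_equal(cs$start, c1$start + k)
    expect_equal(cs$end, c1$end + k)
    for (id in names(seqs)) expect_equal(cs[[id]], c1[[id]])
  }
})

test_that("all state-1 sequences share the exact coded extent", {
  set.seed(22)
  for (i in 1:20) {
    seqs <- random_gappy_alignment(sample(3:8, 1), sample(20:60, 1))
    ch <- simple_indel_coding(alignment(seqs))
    runs <- find_gap_runs(alignment(seqs))
    for (r in seq_len(nrow(ch))) {
      ones <- setdiff(names(ch), c("start", "end"))[ch[r, -(1:2)] == "1"]
      for (id in ones) {
        rr <- runs[runs$seq_id == id, ]
        expect_true(any(rr$start == ch$start[r] & rr$end == ch$end[r]))
      }
    }
  }
})

test_that("coding agrees with the column-wise oracle on random alignments", {
  set.seed(23)
  for (i in 1:60) {
    seqs <- random_gappy_alignment(sample(2:8, 1), sample(15:60, 1))
    got <- as.data.frame(simple_indel_coding(alignment(seqs)))
    expect_equal(got, indel_oracle(seqs), info = paste("case", i))
  }
})

test_that("column masks shift coding as expected and write out cleanly", {
  a <- alignment(c(A = "ACGT--AC", B = "ACGTTTAC"))
  m <- mask_columns(a, 1:2)  # drop the first two columns
  expect_equal(m$length, 6)
  ch <- simple_indel_coding(m)
  expect_equal(c(ch$start, ch$end), c(2L, 4L))
  f <- tempfile(fileext = ".tsv")
  write_indel_matrix(ch, f)
  back <- read.delim(f)
  expect_equal(back$start, 3)  # 1-based inclusive at the boundary
  f2 <- tempfile(fileext = ".nex")
  write_indel_matrix(ch, f2, format = "nexus")
  expect_true(any(grepl("NTAX=2", readLines(f2))))
})
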