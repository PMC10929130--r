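# Bidirectional index: suffix arrays, BWTs, extension, enumeration,
# run counting, bitvector and RMQ reporter.

test_that("suffix arrays list suffixes in lexicographic order", {
  idx <- build_index("A")
  expect_equal(idx$sa_fwd, c(2L, 1L))  # "$" < "A$"

  # brute force: sort all suffixes of AGAAAG$; the suffix array spells them
  txt <- "AGAAAG$"
  sufs <- vapply(1:7, function(i) substr(txt, i, 7), character(1))
  expect_equal(sufs[build_index("AGAAAG")$sa_fwd], sort(sufs, method = "radix"))

  set.seed(11)
  for (r in 1:20) {
    s <- rand_seq(sample(2:40, 1))
    idx <- build_index(s)
    txt <- paste0(s, "$")
    sufs <- vapply(seq_len(nchar(txt)), function(i)
      substr(txt, i, nchar(txt)), character(1))
    expect_equal(sufs[idx$sa_fwd], sort(sufs, method = "radix"))
  }
})

test_that("the BWT matches the rotation-sort oracle, circular convention included", {
  set.seed(12)
  for (s in c("GAAT", "AGAAAG", "AAAA", "A", replicate(10, rand_seq(sample(1:30, 1))))) {
    idx <- build_index(s)
    expect_equal(paste(idx$symtab[idx$bwt_fwd], collapse = ""), oracle_bwt(s))
  }
})

test_that("build_index rejects bad inputs", {
  expect_error(build_index("ACGX"), "outside the alphabet")
  expect_error(build_index("AC$G"), "outside the alphabet|end marker")
  expect_error(build_index(character(0)), "nonempty|length")
})

test_that("extension and enumeration follow occurrence semantics", {
  idx <- build_index("AGAAAG")
  root <- root_interval(idx)
  ivA <- extend_left(idx, "A", root)
  expect_equal(interval_width(ivA), 4L)          # A occurs 4 times
  ivGA <- extend_left(idx, "G", ivA)
  expect_equal(interval_width(ivGA), 1L)         # GA occurs once
  expect_null(extend_left(idx, "T", root))       # T absent

  # enumerate: GA preceded only by A; A preceded by {$, G, A}; whole text by $
  expect_setequal(enumerate_left(idx, ivGA), "A")
  expect_false(is_left_maximal(idx, ivGA))
  expect_setequal(enumerate_left(idx, ivA), c("$", "G", "A"))
  expect_true(is_left_maximal(idx, ivA))
  full <- root
  for (c in rev(strsplit("AGAAAG", "")[[1]])) full <- extend_left(idx, c, full)
  expect_equal(enumerate_left(idx, full), "$")
  expect_false(is_left_maximal(idx, full))
})

test_that("extend_left and extend_right commute when both succeed", {
  set.seed(13)
  for (r in 1:20) {
    s <- rand_seq(30)
    idx <- build_index(s)
    at <- sample(10:20, 1)
    core <- substr(s, at, at + 3)
    iv <- root_interval(idx)
    for (c in rev(strsplit(core, "")[[1]])) iv <- extend_left(idx, c, iv)
    a <- substr(s, at - 1, at - 1); b <- substr(s, at + 4, at + 4)
    lr <- extend_right(idx, b, extend_left(idx, a, iv))
    rl <- extend_left(idx, a, extend_right(idx, b, iv))
    expect_equal(lr$fwd, rl$fwd)
    expect_equal(lr$rev, rl$rev)
  }
})

test_that("backward search counts match naive scanning, fwd/rev synchronized", {
  set.seed(14)
  for (r in 1:50) {
    s <- rand_seq(sample(5:40, 1))
    idx <- build_index(s)
    idx_r <- build_index(paste(rev(strsplit(s, "")[[1]]), collapse = ""))
    subs <- unique(unlist(lapply(seq_len(nchar(s)), function(x)
      vapply(x:min(nchar(s), x + 6), function(y) substr(s, x, y), character(1)))))
    for (p in sample(subs, min(20, length(subs)))) {
      iv <- root_interval(idx)
      for (c in rev(strsplit(p, "")[[1]])) iv <- extend_left(idx, c, iv)
      expect_equal(interval_width(iv), naive_count(p, s))
      # synchronization: rev interval equals the fwd interval of the
      # reversed pattern in the reversed text
      pr <- paste(rev(strsplit(p, "")[[1]]), collapse = "")
      iv2 <- root_interval(idx_r)
      for (c in rev(strsplit(pr, "")[[1]])) iv2 <- extend_left(idx_r, c, iv2)
      expect_equal(iv$rev, iv2$fwd)
    }
    for (r2 in 1:5) {
      absent <- rand_seq(nchar(s) + 2)
      expect_equal(count_occurrences(build_index(s), absent), 0L)
    }
  }
})

test_that("BWT run counts match the rotation oracle and the n+1 bound", {
  expect_equal(count_bwt_runs(build_index("AAAA")), count_runs_str(oracle_bwt("AAAA")))
  expect_equal(count_bwt_runs(build_index("AAAA")), 2L)
  expect_equal(count_bwt_runs(build_index("A")), 2L)
  set.seed(15)
  for (r in 1:20) {
    s <- rand_seq(sample(1:40, 1))
    idx <- build_index(s)
    expect_equal(count_bwt_runs(idx, "fwd"), count_runs_str(oracle_bwt(s)))
    expect_lte(count_bwt_runs(idx, "fwd"), nchar(s) + 1L)
    expect_lte(count_bwt_runs(idx, "rev"), nchar(s) + 1L)
  }
})

test_that("rank/select bitvector invariants hold", {
  set.seed(16)
  for (r in 1:20) {
    bits <- sample(0:1, sample(5:50, 1), replace = TRUE)
    if (sum(bits) == 0L) bits[1] <- 1L
    b <- rs_bitvector(bits)
    for (i in seq_along(bits)) {
      rk <- bv_rank(b, i)
      expect_equal(rk, sum(bits[1:i]))
      if (rk >= 1L) expect_lte(bv_select(b, rk), i)
    }
    for (rr in seq_len(sum(bits))) expect_equal(bv_rank(b, bv_select(b, rr)), rr)
  }
})

test_that("RMQ threshold reporting equals linear scan with bounded probes", {
  rep <- rmq_reporter(c(5, 1, 7, 3))
  got <- rmq_report_leq(rep, 1, 4, 3)
  expect_setequal(as.integer(got), c(2L, 4L))

  # threshold below the range minimum: nothing, one probe
  got <- rmq_report_leq(rep, 1, 4, 0)
  expect_length(got, 0L)
  expect_equal(attr(got, "rmq_calls"), 1L)

  # huge threshold: everything
  expect_setequal(as.integer(rmq_report_leq(rep, 1, 4, .Machine$integer.max - 1)),
                  1:4)
  # empty range
  expect_length(rmq_report_leq(rep, 3, 2, 100), 0L)
  # rmq_min returns an index of a minimum
  expect_equal(rep$values[rmq_min(rep, 1, 4)], 1L)
  expect_equal(rep$values[rmq_min(rep, 3, 4)], 3L)
})
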