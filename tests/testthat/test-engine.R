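test_that("a perfect unique substring scores 0 under zero-match semiglobal scoring", {
  ref <- "ACGGTTCATGCAGTACCTGAAGTCCTAGGA"
  g <- build_graph(ref)
  m <- scoring_preset("sg-default")
  read <- substr(ref, 11, 20)  # unique 10-mer
  res <- align_batch(g, read_batch(read), m)
  expect_equal(res$best_score, 0)
  expect_equal(res$best_pos, 20)   # anchored rightmost aligned base
  expect_equal(res$best_count, 1)
})

test_that("one mismatching base costs exactly its quality-scaled penalty", {
  set.seed(13)
  ref <- simulate_genome(60)
  g <- build_graph(ref)
  m <- scoring_preset("sg-default")
  for (q in c(0, 10, 20, 40)) {
    read <- substr(ref, 21, 40)
    base <- substr(read, 8, 8)
    substr(read, 8, 8) <- setdiff(c("A", "C", "G", "T"), base)[1]
    quals <- rep(40L, 20); quals[8] <- q
    res <- align_batch(g, read_batch(read, list(quals)), m)
    expect_equal(res$best_score, -mismatch_penalty(m, q))
  }
})

test_that("engine scores equal the path-enumeration oracle on random instances", {
  set.seed(17)
  for (mode in c("semiglobal", "local")) {
    for (k in 1:40) {
      g <- rand_graph()
      m <- rand_model(mode)
      rd <- rand_read()
      batch <- read_batch(rd$seq,
                          quals = if (is.null(rd$quals)) NULL else list(rd$quals))
      eng <- align_batch(g, batch, m)
      expect_equal(eng$best_score,
                   oracle_align(g, rd$seq, rd$quals, m),
                   info = sprintf("mode=%s k=%d", mode, k))
    }
  }
})

test_that("co-optimal locations cluster greedily at one read-length separation", {
  expect_equal(count_cooptimal(c(100), 100), 1L)
  expect_equal(count_cooptimal(c(100, 150, 400), 100), 2L)
  expect_equal(count_cooptimal(c(1, 101, 201), 100), 3L)  # exactly one length apart
  expect_equal(count_cooptimal(integer(0), 100), 0L)
  expect_error(count_cooptimal(c(5, 1), 10), "sorted")
})

test_that("a two-copy repeat is reported with best_count 2 and the leftmost position", {
  set.seed(19)
  unit <- simulate_genome(20)
  spacer <- simulate_genome(40)
  ref <- paste0(unit, spacer, unit, simulate_genome(10))
  g <- build_graph(ref)
  res <- align_batch(g, read_batch(unit), scoring_preset("sg-default"))
  expect_equal(res$best_score, 0)
  expect_equal(res$best_count, 2)
  expect_equal(res$best_pos, 20)
  # second stratum must lie >= one read-length from both copies
  expect_true(is.na(res$second_pos) ||
                (min(abs(res$second_pos - c(20, 80))) >= 20))
})

test_that("tied ref and alt columns anchored to one coordinate count once", {
  g <- fig1_graph()
  m <- scoring_model("semiglobal", match = 0, ambig_penalty = 1)
  # N never matches: both branch columns (ref A, alt T at coordinate 5) tie
  res <- align_batch(g, read_batch("GTN"), m)
  expect_equal(res$best_score, -1)
  expect_equal(res$best_pos, 5)
  expect_equal(res$best_count, 1)
})

test_that("second-best stratum respects the read-length separation rule", {
  set.seed(23)
  scores <- c(5, 5, 3, 4, 1)
  coords <- c(100, 100, 150, 400, 401)
  st <- track_optima(scores, coords, 100)
  expect_equal(st$best_score, 5)
  expect_equal(st$best_count, 1)
  # 150 is within a read length of 100: not a valid runner-up location
  expect_equal(st$second_score, 4)
  expect_equal(st$second_pos, 400)
})

test_that("traceback reproduces identity, deletion and soft-clip alignments", {
  sg <- scoring_preset("sg-default")
  t1 <- traceback_linear("ACGTACGT", "ACGTACGT", model = sg)
  expect_equal(t1[c("cigar", "pos", "score")],
               list(cigar = "8M", pos = 1L, score = 0))
  t2 <- traceback_linear("ACGTACGT", "ACGTCGT", model = sg)
  expect_equal(t2[c("cigar", "pos", "score")],
               list(cigar = "4M1D3M", pos = 1L, score = -8))
  set.seed(29)
  target <- simulate_genome(20)
  ref <- paste0("AAAAAAAAAA", target, "AAAAAAAAAA")
  read <- paste0("TTT", target)
  t3 <- traceback_linear(ref, read, model = scoring_preset("local-default"))
  expect_equal(t3$cigar, "3S20M")
  expect_equal(t3$score, 40)
  expect_equal(t3$pos, 11L)
})

test_that("traceback refuses multi-node graphs", {
  expect_error(traceback_linear(fig1_graph(), "ACG", model = scoring_preset("sg-default")),
               "unsupported.*linear")
  expect_error(align_file(fig1_graph(), tempfile(), scoring_preset("sg-default"),
                          traceback = TRUE),
               "unsupported.*linear")
})

test_that("results are invariant to the batch partition", {
  set.seed(37)
  g <- rand_graph(L = 40)
  m <- scoring_preset("sg-default")
  reads <- vapply(1:12, function(i) simulate_genome(8), "")
  quals <- lapply(1:12, function(i) sample(10:40, 8, replace = TRUE))
  whole <- align_batch(g, read_batch(reads, quals), m)
  single <- do.call(rbind, lapply(1:12, function(i) {
    r <- align_batch(g, read_batch(reads[i], quals[i], ids = paste0("read", i)), m)
    r
  }))
  rownames(single) <- NULL
  for (col in c("best_score", "best_pos", "best_count", "second_score",
                "second_pos", "second_count"))
    expect_equal(whole[[col]], single[[col]], info = col)
})

test_that("narrow and wide score cells agree bit-for-bit when narrow is legal", {
  set.seed(41)
  for (k in 1:10) {
    g <- rand_graph()
    m <- rand_model()
    len <- sample(4:8, 1)
    if (select_cell_width(m, len) == "wide") m <- scoring_preset("sg-default")
    reads <- vapply(1:5, function(i) simulate_genome(len), "")
    narrow <- align_batch(g, read_batch(reads), m, width = "narrow")
    wide <- align_batch(g, read_batch(reads), m, width = "wide")
    narrow_w <- attr(narrow, "width"); attr(narrow, "width") <- NULL
    attr(wide, "width") <- NULL
    expect_identical(narrow, wide)
  }
})

test_that("adding variants never lowers the optimal score (reference path preserved)", {
  set.seed(43)
  for (k in 1:15) {
    genome <- simulate_genome(sample(20:40, 1))
    vars <- simulate_variants(genome, snp_rate = 0.1, indel_rate = 0.08,
                              max_indel = 2)
    g_lin <- build_graph(genome)
    g_var <- build_graph(genome, vars)
    m <- rand_model()
    rd <- rand_read()
    b <- read_batch(rd$seq, if (is.null(rd$quals)) NULL else list(rd$quals))
    expect_gte(align_batch(g_var, b, m)$best_score,
               align_batch(g_lin, b, m)$best_score)
  }
})

test_that("local mode dominates semiglobal at identical parameters", {
  set.seed(47)
  for (k in 1:15) {
    g <- rand_graph()
    args <- list(match = sample(1:3, 1), mismatch_min = 1, mismatch_max = 6,
                 gap_open = sample(2:6, 1), gap_extend = sample(1:3, 1))
    sg <- do.call(scoring_model, c(list(mode = "semiglobal"), args))
    lc <- do.call(scoring_model, c(list(mode = "local"), args))
    rd <- rand_read(with_quals = FALSE)
    expect_gte(align_batch(g, read_batch(rd$seq), lc)$best_score,
               align_batch(g, read_batch(rd$seq), sg)$best_score)
  }
})

test_that("every emitted CIGAR reproduces the engine's optimal score", {
  set.seed(53)
  for (k in 1:30) {
    mode <- sample(c("semiglobal", "local"), 1)
    m <- rand_model(mode)
    ref <- simulate_genome(sample(20:60, 1))
    rd <- rand_read(len = sample(5:15, 1))
    g <- build_graph(ref)
    eng <- align_batch(g, read_batch(rd$seq,
                                     if (is.null(rd$quals)) NULL else list(rd$quals)), m)
    tb <- traceback_linear(ref, rd$seq, rd$quals, m)
    if (!eng$aligned) {
      expect_true(is.na(tb$cigar))
      next
    }
    expect_equal(tb$score, eng$best_score)
    sc <- score_cigar(ref, rd$seq, tb$cigar, tb$pos, rd$quals, m)
    expect_equal(sc$score, eng$best_score)
    expect_equal(sc$read_consumed, nchar(rd$seq))
    if (mode == "semiglobal") expect_false(grepl("S", tb$cigar))
  }
})

test_that("align_file preserves input order, groups mixed lengths, handles empty input", {
  set.seed(59)
  ref <- simulate_genome(200)
  g <- build_graph(ref)
  m <- scoring_preset("sg-default")
  n <- 20
  lens <- sample(c(15L, 25L), n, replace = TRUE)
  starts <- vapply(lens, function(l) sample(nchar(ref) - l, 1), 1L)
  seqs <- substring(ref, starts, starts + lens - 1L)
  quals <- lapply(lens, function(l) sample(20:40, l, replace = TRUE))
  ids <- paste0("r", 1:n)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(ids, seqs, quals, fq)

  res <- align_file(g, fq, m)
  expect_equal(res$id, ids)
  expect_equal(res$best_score, rep(0, n))
  res1 <- align_file(g, fq, m, batch_size = 1)
  expect_equal(res, res1)

  empty <- tempfile(fileext = ".fastq")
  file.create(empty)
  expect_equal(nrow(align_file(g, empty, m)), 0L)
})

test_that("invalid reads and mixed-length batches are rejected", {
  expect_error(read_batch(c("ACGT", "ACG")), "same length")
  expect_error(read_batch("ACXT", ids = "badread"), "badread")
  expect_error(read_batch(character(0)), "at least one")
  expect_error(read_batch("ACGT", list(c(30L, 30L))), "length")
})
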