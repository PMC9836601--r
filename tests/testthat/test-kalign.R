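test_that("seed index enumerates k-mers, wraps circular queries, skips Ns", {
  # linear toy: enumerable positions
  idx <- build_index(named_seq("q", "ACGTACGT"), k = 8)
  expect_equal(index_positions(idx, "ACGTACGT"), 0L)

  idx <- build_index(named_seq("q", "ACGTACGTACGT"), k = 8)
  expect_equal(index_positions(idx, "ACGTACGT"), c(0L, 4L))
  expect_equal(index_positions(idx, "CGTACGTA"), 1L)
  expect_length(index_positions(idx, "AAAAAAAA"), 0L)

  # circular: a k-mer spanning the origin is indexed at its wrapped position
  idxc <- build_index(named_seq("q", "ACGTACGTTGCA", circular = TRUE), k = 8)
  # position 8 (0-based): TGCA + wrap ACGT
  expect_equal(index_positions(idxc, "TGCAACGT"), 8L)

  # degenerate query
  expect_warning(build_index(named_seq("q", strrep("N", 50)), k = 8), "empty")
  expect_error(build_index(named_seq("q", "ACGT"), k = 8), "exceeds")
  expect_error(build_index(named_seq("q", strrep("A", 100)), k = 4), ">= 8")
})

test_that("exact reads align full-length on both strands at identity 1", {
  set.seed(101)
  q <- random_genome(1200, id = "q", circular = TRUE)
  idx <- build_index(q, 11)
  preset <- align_preset("low")

  pl <- plant_read(q$residues, 300, 150)
  a <- align_read(pl$read, idx, preset)
  expect_equal(a$strand, "+")
  expect_equal(a$identity, 1)
  expect_equal(a$query_start, 300L)
  expect_equal(a$query_end, 450L)
  expect_equal(a$matches, 150L)

  # reverse complement: same interval, minus strand
  b <- align_read(reverse_complement(pl$read), idx, preset)
  expect_equal(b$strand, "-")
  expect_equal(b$query_start, 300L)
  expect_equal(b$query_end, 450L)
  expect_equal(b$identity, 1)
})

test_that("strand symmetry holds for mutated reads", {
  set.seed(102)
  q <- random_genome(1500, id = "q", circular = TRUE)
  idx <- build_index(q, 11)
  preset <- align_preset("low")
  for (i in 1:15) {
    pl <- plant_read(q$residues, sample(0:1350, 1), 120, n_subs = 4)
    a <- align_read(pl$read, idx, preset)
    b <- align_read(reverse_complement(pl$read), idx, preset)
    expect_false(is.null(a))
    expect_false(is.null(b))
    expect_equal(b$query_start, a$query_start)
    expect_equal(b$query_end, a$query_end)
    expect_equal(b$identity, a$identity)
    expect_equal(b$strand, if (a$strand == "+") "-" else "+")
  }
})

test_that("emitted scores match the exhaustive Smith-Waterman oracle", {
  set.seed(103)
  preset <- align_preset("low", k = 8, min_identity = 0.01, min_aln_len = 10)
  for (i in 1:25) {
    qlen <- sample(200:400, 1)
    q <- random_genome(qlen, id = "q", circular = FALSE)
    rl <- sample(60:100, 1)
    pl <- plant_read(q$residues, sample(0:(qlen - rl), 1), rl,
                     n_subs = rbinom(1, rl, runif(1, 0, 0.05)),
                     rc = runif(1) < 0.5)
    idx <- build_index(q, 8, read_len = rl)
    a <- align_read(pl$read, idx, preset)
    oracle <- sw_oracle_score(pl$read, q$residues)
    expect_equal(if (is.null(a)) 0 else a$score, oracle, label = paste("case", i))
  }
})

test_that("stringency presets separate by identity threshold", {
  set.seed(104)
  q <- random_genome(2000, id = "q", circular = TRUE)
  # 150 bp read with 13 substitutions in the first 120 bp: identity 0.913,
  # below the high threshold (0.92) but above the low one (0.80); the clean
  # 3' 30 bp guarantees seeds for both k = 11 and k = 16
  read <- substr(q$residues, 501, 650)
  ch <- strsplit(read, "")[[1L]]
  for (p in seq(3, 119, by = 10)[1:12]) ch[p] <- chartr("ACGT", "CATG", ch[p])
  ch[60] <- chartr("ACGT", "GTAC", ch[60])
  read <- paste(ch, collapse = "")

  lo <- align_read(read, build_index(q, 11), align_preset("low"))
  expect_false(is.null(lo))
  expect_lt(lo$identity, 0.92)
  expect_gte(lo$identity, 0.80)

  hi <- align_read(read, build_index(q, 16), align_preset("high"))
  expect_null(hi)
})

test_that("origin-spanning reads align at full identity for any rotation", {
  set.seed(105)
  q <- random_genome(900, id = "q", circular = TRUE)
  # read crossing the origin: last 70 bases + first 50
  read <- paste0(substr(q$residues, 831, 900), substr(q$residues, 1, 50))
  idx <- build_index(q, 11)
  a <- align_read(read, idx, align_preset("low"))
  expect_equal(a$identity, 1)
  expect_equal(a$query_start, 830L)
  expect_equal(a$query_end %% 900L, 50L)

  for (rot in c(100, 457, 899)) {
    qr <- named_seq("q", paste0(substr(q$residues, rot + 1, 900),
                                substr(q$residues, 1, rot)),
                    circular = TRUE)
    ar <- align_read(read, build_index(qr, 11), align_preset("low"))
    expect_equal(ar$identity, 1, label = paste("rotation", rot))
    expect_equal(ar$matches, 120L)
  }
})

test_that("align_library summarises endogenous fraction and handles edge cases", {
  g <- random_genome(3000, seed = 111)
  lib <- simulate_library(g, library_params(n_pairs = 1000,
                                            endogenous_fraction = 0.05,
                                            seq_error = 0, seed = 112))
  aset <- align_library(c(lib$reads1, lib$reads2), g, align_preset("low"))
  truth_frac <- mean(lib$truth$source == "mito")
  expect_lt(abs(aset$summary$aligned_fraction - truth_frac), 0.01)

  # pure endogenous clean library aligns essentially completely
  lib1 <- simulate_library(g, library_params(n_pairs = 100,
                                             endogenous_fraction = 1,
                                             seq_error = 0, seed = 113))
  aset1 <- align_library(c(lib1$reads1, lib1$reads2), g, align_preset("low"))
  expect_gte(aset1$summary$aligned_fraction, 0.99)

  # empty input
  aset0 <- align_library(setNames(character(0), character(0)), g)
  expect_equal(aset0$summary$n_reads, 0L)
  expect_equal(aset0$summary$n_aligned, 0L)

  # FASTQ path input round-trips through the aligner
  p <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(lib1$reads1[1:5], p)
  asetf <- align_library(p, g, align_preset("low"))
  expect_equal(asetf$summary$n_reads, 5L)
  expect_equal(asetf$summary$n_aligned, 5L)
  expect_error(align_library("/nonexistent/file.fastq", g), "I/O error")
})

test_that("reads aligning equally well at two loci are dropped as ambiguous", {
  set.seed(114)
  core <- random_genome(400, id = "x")$residues
  dup <- substr(core, 101, 200)
  q <- named_seq("q", paste0(core, strrep("A", 40), dup), circular = FALSE)
  idx <- build_index(q, 11)
  a <- align_read(dup, idx, align_preset("low"))
  expect_null(a)
  # a unique read still aligns
  b <- align_read(substr(core, 1, 80), idx, align_preset("low"))
  expect_false(is.null(b))
})
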