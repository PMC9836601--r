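test_that("mutate_genome realizes the requested divergence", {
  g <- random_genome(16000, seed = 1)

  expect_equal(mutate_genome(g, 0, seed = 2)$residues, g$residues)
  expect_error(mutate_genome(g, 0.3), "divergence")

  m <- mutate_genome(g, 0.05, seed = 3)
  a <- strsplit(g$residues, "")[[1L]]
  b <- strsplit(m$residues, "")[[1L]]
  obs <- mean(a == b)
  # 95% binomial band around 0.95 for n = 16000
  se <- sqrt(0.05 * 0.95 / 16000)
  expect_gt(obs, 0.95 - 3 * se)
  expect_lt(obs, 0.95 + 3 * se)
  # within the congeneric identity band on average
  expect_gt(obs, 0.94)
  expect_lt(obs, 0.965)

  # transitions favoured ~2:1 by default
  diff <- a != b
  ts <- sum((a == "A" & b == "G") | (a == "G" & b == "A") |
            (a == "C" & b == "T") | (a == "T" & b == "C"))
  expect_gt(ts / sum(diff), 0.55)
})

test_that("fragment sampling is uniform on the circle and deterministic", {
  g <- random_genome(8000, seed = 5)
  f1 <- simulate_fragments(g, 5000, insert_mean = 100, insert_sd = 40, seed = 9)
  f2 <- simulate_fragments(g, 5000, insert_mean = 100, insert_sd = 40, seed = 9)
  expect_identical(f1$fragments, f2$fragments)
  expect_identical(f1$truth, f2$truth)

  # analytic mean of N(100, 40) truncated to [30, 200]
  a <- (30 - 100) / 40; b <- (200 - 100) / 40
  z <- pnorm(b) - pnorm(a)
  mu_trunc <- 100 + 40 * (dnorm(a) - dnorm(b)) / z
  se <- 40 / sqrt(5000)
  expect_lt(abs(mean(f1$truth$insert) - mu_trunc), 4 * se + 0.5)
  expect_true(all(f1$truth$insert >= 30 & f1$truth$insert <= 200))

  # origin-spanning fraction ~ E[insert]/L
  span <- mean(f1$truth$end > 8000)
  expected <- mean(f1$truth$insert) / 8000
  se <- sqrt(expected * (1 - expected) / 5000)
  expect_lt(abs(span - expected), 4 * se)

  # wrapped fragments really wrap
  w <- which(f1$truth$end > 8000 & f1$truth$strand == "+")[1L]
  expect_false(is.na(w))
  s <- f1$truth$start[w]
  expect_equal(f1$fragments[w],
               paste0(substr(g$residues, s + 1, 8000),
                      substr(g$residues, 1, f1$truth$end[w] - 8000)))

  expect_error(simulate_fragments(g, 10, insert_mean = 0), "insert_mean")
})

test_that("apply_damage follows the geometric positional model", {
  frags <- c("ACGTCCGG", "CCCC")
  off <- apply_damage(frags, damage_params(0, 0.5, 0), seed = 1)
  expect_identical(off$fragments, frags)
  expect_identical(off$damaged_positions, list(integer(0), integer(0)))

  # limit case: every C (and complementary-strand C, i.e. G) converts
  all_on <- apply_damage(frags, damage_params(1, 1, 1), seed = 1)
  expect_false(any(grepl("[CG]", all_on$fragments)))
  expect_equal(all_on$fragments, chartr("CG", "TA", frags))

  # positional C->T frequency: d_max at the 5' terminus, halving per position
  set.seed(11)
  n <- 20000
  base <- strrep("C", 12)
  d <- apply_damage(rep(base, n), damage_params(0.3, 0.5, 0))
  first <- substr(d$fragments, 1, 1) == "T"
  second <- substr(d$fragments, 2, 2) == "T"
  expect_equal(mean(first), 0.3, tolerance = 0.035)
  expect_equal(mean(second), 0.15, tolerance = 0.07)
})

test_that("simulate_library obeys the stated endogenous fraction and coverage", {
  g <- random_genome(2000, seed = 21)
  lp <- library_params(n_pairs = 20000, endogenous_fraction = 0.002,
                       seq_error = 0, seed = 22)
  lib <- simulate_library(g, lp)
  n_mito <- sum(lib$truth$source == "mito")
  expect_lt(abs(n_mito - 40), 3 * sqrt(20000 * 0.002 * 0.998) + 1)

  # determinism under the seed
  lib2 <- simulate_library(g, lp)
  expect_identical(lib$reads1, lib2$reads1)
  expect_identical(lib$truth, lib2$truth)

  # empty library is valid
  lib0 <- simulate_library(g, library_params(n_pairs = 0, seed = 1))
  expect_length(lib0$reads1, 0L)
  expect_equal(nrow(lib0$truth), 0L)

  expect_error(library_params(n_pairs = 10, read_len = 20), "read_len")
  expect_error(library_params(n_pairs = 10, insert_mean = 10), "insert_mean")
})

test_that("clean reads are exact substrings of their source circle", {
  g <- random_genome(2000, seed = 31)
  lp <- library_params(n_pairs = 50, endogenous_fraction = 1, seq_error = 0,
                       seed = 32)
  lib <- simulate_library(g, lp)
  circle <- strrep(g$residues, 2)
  rc_circle <- reverse_complement(circle)
  for (i in seq_len(50)) {
    for (r in c(lib$reads1[i], lib$reads2[i])) {
      expect_true(grepl(r, circle, fixed = TRUE) ||
                  grepl(r, rc_circle, fixed = TRUE))
    }
  }
  # coverage arithmetic: total read bases / L matches the truth table
  depth <- sum(pmin(lib$truth$insert, 150) * 2) / 2000
  expect_equal(depth, sum(nchar(c(lib$reads1, lib$reads2))) / 2000)
})

test_that("damage asymmetry is visible in read-vs-truth mismatch classes", {
  g <- random_genome(4000, seed = 41)
  lp <- library_params(n_pairs = 400, endogenous_fraction = 1, seq_error = 0,
                       seed = 42)
  mismatch_classes <- function(lib) {
    counts <- matrix(0L, 4, 4, dimnames = list(c("A","C","G","T"),
                                               c("A","C","G","T")))
    circle <- strrep(g$residues, 3)
    for (i in seq_len(nrow(lib$truth))) {
      tr <- lib$truth[i, ]
      frag_truth <- substr(circle, tr$start + 1, tr$end)
      if (tr$strand == "-") frag_truth <- reverse_complement(frag_truth)
      r1 <- lib$reads1[i]
      t1 <- substr(frag_truth, 1, nchar(r1))
      a <- strsplit(t1, "")[[1L]]; b <- strsplit(r1, "")[[1L]]
      d <- which(a != b)
      for (j in d) counts[a[j], b[j]] <- counts[a[j], b[j]] + 1L
    }
    counts
  }
  on <- mismatch_classes(simulate_library(g, lp, damage = damage_params(0.3, 0.5, 0.01)))
  expect_gt(on["C", "T"] + on["G", "A"], 10 * (sum(on) - on["C", "T"] - on["G", "A"] + 1))

  off <- mismatch_classes(simulate_library(
    g, library_params(n_pairs = 400, endogenous_fraction = 1,
                      seq_error = 0.02, seed = 42)))
  # all 12 classes populated and no gross asymmetry without damage
  expect_true(all(off[row(off) != col(off)] > 0))
  frac_ct_ga <- (off["C", "T"] + off["G", "A"]) / sum(off)
  expect_lt(frac_ct_ga, 0.35) # 2/12 expected ~ 0.17
})
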