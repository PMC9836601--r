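test_that("pileup aggregates strand-normalized bases at query coordinates", {
  set.seed(201)
  q <- random_genome(200, id = "q", circular = FALSE)
  idx <- build_index(q, 11, read_len = 200)
  preset <- align_preset("low")

  # one exact full-cover read: depth 1 everywhere, zero mismatch columns
  a <- align_read(q$residues, idx, preset, read_id = "full")
  pile <- build_pileup(list(a), q)
  expect_true(all(pile$depth == 1L))
  qb <- strsplit(q$residues, "")[[1L]]
  expect_true(all(pile$counts[cbind(1:200, match(qb, c("A","C","G","T")))] == 1L))

  # plus and minus strand reads over the same C site both count as C
  read_p <- substr(q$residues, 41, 140)
  read_m <- reverse_complement(read_p)
  ap <- align_read(read_p, idx, preset, read_id = "p")
  am <- align_read(read_m, idx, preset, read_id = "m")
  expect_equal(am$strand, "-")
  pile2 <- build_pileup(list(ap, am), q)
  c_sites <- which(qb == "C" & seq_along(qb) >= 41 & seq_along(qb) <= 140)
  expect_true(all(pile2$counts[c_sites, "C"] == 2L))
  expect_true(all(pile2$depth[41:140] == 2L))

  # consistency check against read ids
  expect_error(build_pileup(list(ap), q, reads = c(other = "ACGT")),
               "consistency error")
})

test_that("pileup counts equal an independent recount from the truth table", {
  g <- random_genome(2000, seed = 202)
  lib <- simulate_library(g, library_params(n_pairs = 25,
                                            endogenous_fraction = 1,
                                            seq_error = 0, seed = 203))
  aset <- align_library(c(lib$reads1, lib$reads2), g, align_preset("low"))
  expect_equal(aset$summary$n_aligned, 50L)
  pile <- build_pileup(aset, g)

  # oracle: per-position coverage recomputed directly from fragment intervals
  L <- 2000L
  cover <- integer(L)
  for (i in seq_len(nrow(lib$truth))) {
    tr <- lib$truth[i, ]
    m <- min(150L, tr$insert)
    for (iv in list(c(tr$start, tr$start + m),
                    c(tr$end - m, tr$end))) {
      posn <- (seq.int(iv[1L], iv[2L] - 1L) %% L) + 1L
      cover[posn] <- cover[posn] + 1L
    }
  }
  expect_equal(pile$depth, cover)
  # with clean reads and query = truth, every count sits on the truth base
  qb <- strsplit(g$residues, "")[[1L]]
  expect_equal(pile$counts[cbind(1:L, match(qb, c("A","C","G","T")))], cover)
  expect_equal(rowSums(pile$counts), as.numeric(cover))
})

test_that("call_site implements the IUPAC ambiguity policy", {
  pol <- call_policy()

  r <- call_site(c(C = 3, T = 2), "C", pol)
  expect_equal(r$call, "Y"); expect_equal(r$status, "ambiguous")

  r <- call_site(c(), "A", pol)
  expect_equal(r$call, "N"); expect_equal(r$status, "missing")

  r <- call_site(c(A = 1, G = 1), "G", pol)
  expect_equal(r$call, "R"); expect_equal(r$status, "ambiguous")

  r <- call_site(c(G = 4), "A", pol)
  expect_equal(r$call, "G"); expect_equal(r$status, "substituted")

  # 12.5% minor allele filtered by the 25% floor
  r <- call_site(c(C = 7, T = 1), "C", pol)
  expect_equal(r$call, "C"); expect_equal(r$status, "concordant")

  r <- call_site(c(A = 2, C = 2, T = 2), "A", pol)
  expect_equal(r$call, "H"); expect_equal(r$status, "ambiguous")

  # inclusive thresholds: exactly 25% is kept (two-base call at depth 4)
  r <- call_site(c(C = 3, T = 1), "C", pol)
  expect_equal(r$call, "Y")

  # depth gate
  r <- call_site(c(G = 1), "G", call_policy(min_depth_call = 2))
  expect_equal(r$call, "N"); expect_equal(r$status, "missing")
})

test_that("reconstruct keeps the query frame and accounts for every site", {
  set.seed(204)
  q <- random_genome(1500, id = "q", circular = TRUE)

  # zero alignments: all-N genome
  empty <- build_pileup(list(), q)
  rec0 <- reconstruct(empty, q)
  expect_equal(rec0$tally$n_fraction, 1)
  expect_equal(rec0$seq$residues, strrep("N", 1500))

  # clean 20x library with query = truth: nothing substituted or ambiguous
  out <- quick_reconstruction(q, q, depth = 20, seed = 205)
  rec <- out$recon
  expect_equal(nchar(rec$seq$residues), 1500L)
  expect_equal(rec$tally$substituted, 0L)
  expect_equal(rec$tally$ambiguous, 0L)

  # status partition and support invariants
  t <- rec$tally
  expect_equal(t$missing + t$concordant + t$substituted + t$ambiguous, t$length)
  called <- rec$calls[rec$calls$call %in% c("A", "C", "G", "T"), ]
  cm <- as.matrix(called[, c("A", "C", "G", "T")])
  support <- cm[cbind(seq_len(nrow(called)), match(called$call, colnames(cm)))]
  expect_true(all(support >= 1))

  # consistency errors
  q2 <- random_genome(1000, id = "q2")
  expect_error(reconstruct(empty, q2), "consistency error")
})

test_that("non-N calls recover the truth against a diverged query", {
  truth <- random_genome(3000, seed = 206)
  query <- mutate_genome(truth, 0.05, seed = 207)
  query$id <- "query"
  out <- quick_reconstruction(truth, query, depth = 15, seed = 208)
  rec <- out$recon
  tr <- strsplit(truth$residues, "")[[1L]]
  rc <- strsplit(rec$seq$residues, "")[[1L]]
  nn <- rc != "N"
  expect_gt(sum(nn) / 3000, 0.95)
  expect_gte(mean(rc[nn] == tr[nn]), 0.999)
  # substituted sites sit where truth and query differ
  qb <- strsplit(query$residues, "")[[1L]]
  sub_pos <- which(rec$calls$status == "substituted")
  expect_gt(length(sub_pos), 50)
  expect_gte(mean(tr[sub_pos] != qb[sub_pos]), 0.99)
})

test_that("N fraction decreases with depth", {
  truth <- random_genome(1500, seed = 209)
  query <- mutate_genome(truth, 0.05, seed = 210)
  query$id <- "query"
  nf <- vapply(c(1, 5, 20), function(d)
    quick_reconstruction(truth, query, depth = d, seed = 211)$recon$tally$n_fraction,
    0)
  expect_true(all(diff(nf) <= 0))
  expect_lt(nf[3], nf[1])
})
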