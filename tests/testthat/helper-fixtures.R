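# shared helpers: small deterministic fixtures built in code

fixture_annotation_path <- function() {
  system.file("extdata", "synthetic_vertebrate_mito_annotation.tsv",
              package = "mitoanchor")
}

# plant a read inside a linear query with a given number of substitutions;
# returns list(read, start0, positions)
plant_read <- function(query_res, start0, len, n_subs = 0L, rc = FALSE) {
  read <- substr(query_res, start0 + 1L, start0 + len)
  pos <- integer(0)
  if (n_subs > 0L) {
    ch <- strsplit(read, "", fixed = TRUE)[[1L]]
    pos <- sample(len, n_subs)
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    read <- paste(ch, collapse = "")
  }
  if (rc) read <- reverse_complement(read)
  list(read = read, start0 = start0, positions = sort(pos))
}

# independent Smith-Waterman oracle (Biostrings), both orientations
sw_oracle_score <- function(read, query_res,
                            match = 1, mismatch = -2,
                            gap_open = 4, gap_ext = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  s1 <- Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::DNAString(read), Biostrings::DNAString(query_res),
    type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_ext))
  s2 <- Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::reverseComplement(Biostrings::DNAString(read)),
    Biostrings::DNAString(query_res),
    type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_ext))
  max(s1, s2)
}

# simulate + align + reconstruct in one go (clean endogenous library)
quick_reconstruction <- function(truth, query, depth, seed,
                                 seq_error = 0, damage = NULL,
                                 preset = align_preset("low"),
                                 policy = call_policy(), read_len = 150L) {
  L <- nchar(truth$residues)
  n_pairs <- max(1L, as.integer(ceiling(depth * L / (2 * read_len))))
  lib <- simulate_library(truth,
                          library_params(n_pairs = n_pairs, read_len = read_len,
                                         endogenous_fraction = 1,
                                         seq_error = seq_error, seed = seed),
                          damage = damage)
  aset <- align_library(c(lib$reads1, lib$reads2), query, preset)
  list(lib = lib, aset = aset,
       recon = reconstruct(build_pileup(aset, query), query, policy))
}
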