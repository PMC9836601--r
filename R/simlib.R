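# Synthetic degraded-library simulator.
#
# Emulates the data regime of historical-DNA shotgun sequencing: a circular
# mitochondrial truth genome, a congeneric (diverged) query genome, short
# inserts, terminal cytosine deamination producing C->T (and, read against
# the plus strand, G->A) substitutions, a tiny endogenous fraction among
# random background reads, and per-base sequencing error. Every fragment is
# recorded in a truth table so downstream accuracy is measurable.

#' Random i.i.d. nucleotide genome
#'
#' @param length genome length in bp.
#' @param gc GC content (default 0.45, typical for teleost mitogenomes).
#' @param id sequence id.
#' @param circular logical (default TRUE).
#' @param seed optional RNG seed.
#' @return [named_seq].
#' @export
random_genome <- function(length, gc = 0.45, id = "truth", circular = TRUE,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  named_seq(id, paste(sample(names(p), length, replace = TRUE, prob = p),
                      collapse = ""), circular = circular)
}

#' Deamination damage parameters
#'
#' Geometric positional model of single-stranded-overhang deamination: a C at
#' distance `i` from a physical strand's 5' end converts to T with
#' probability `d_max * decay^i + floor` (capped at 1).
#'
#' @param d_max conversion probability at the 5'-terminal position.
#' @param decay geometric decay per position into the fragment.
#' @param floor residual internal conversion probability.
#' @return List of class `damage_params`.
#' @export
damage_params <- function(d_max = 0.3, decay = 0.5, floor = 0.01) {
  v <- c(d_max = d_max, decay = decay, floor = floor)
  if (any(v < 0) || any(v > 1)) stop("damage parameters must lie in [0, 1]")
  if (d_max < floor) stop("d_max must be >= floor")
  structure(list(d_max = d_max, decay = decay, floor = floor),
            class = "damage_params")
}

#' Library simulation parameters
#'
#' Defaults state the emulated world: 150 bp paired-end reads and a 0.2%
#' endogenous (mitochondrial) fraction, with short historical-DNA style
#' inserts (mean 100 bp, sd 40, truncated to \[30, 2*mean\]).
#'
#' @param n_pairs number of read pairs.
#' @param read_len read length in bp (>= 30).
#' @param insert_mean,insert_sd insert-size distribution (truncated normal).
#' @param endogenous_fraction probability a pair originates from the
#'   mitochondrial genome rather than background.
#' @param seq_error per-base sequencing error probability.
#' @param seed RNG seed; the whole library is deterministic given the seed.
#' @return List of class `library_params`.
#' @export
library_params <- function(n_pairs, read_len = 150L, insert_mean = 100,
                           insert_sd = 40, endogenous_fraction = 0.002,
                           seq_error = 0.001, seed = 1L) {
  if (n_pairs < 0) stop("n_pairs must be >= 0")
  if (read_len < 30) stop("read_len must be >= 30")
  if (insert_mean <= 0) stop("parameter error: insert_mean must be > 0")
  if (insert_mean < read_len / 2)
    stop("parameter error: insert_mean must be >= read_len / 2")
  if (endogenous_fraction < 0 || endogenous_fraction > 1)
    stop("endogenous_fraction must lie in [0, 1]")
  if (seq_error < 0 || seq_error > 1) stop("seq_error must lie in [0, 1]")
  structure(list(n_pairs = as.integer(n_pairs), read_len = as.integer(read_len),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 endogenous_fraction = endogenous_fraction,
                 seq_error = seq_error, seed = as.integer(seed)),
            class = "library_params")
}

#' Mutate a genome by random substitutions
#'
#' Substitution-only (no indels), so the mutated genome stays in the same
#' coordinate frame -- it plays the role of the congeneric query whose
#' distance to the truth mirrors the ~95% identity of closely related
#' species. Transitions (A<->G, C<->T) are favoured by `ts_tv_ratio`.
#'
#' @param genome [named_seq] over A,C,G,T.
#' @param divergence per-site substitution probability in \[0, 0.25\].
#' @param ts_tv_ratio transition:transversion odds (default 2).
#' @param seed optional RNG seed.
#' @return Mutated [named_seq].
#' @export
mutate_genome <- function(genome, divergence, ts_tv_ratio = 2, seed = NULL) {
  if (divergence < 0 || divergence > 0.25)
    stop("parameter error: divergence must lie in [0, 0.25]")
  if (!is.null(seed)) set.seed(seed)
  chars <- strsplit(genome$residues, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(chars)) < divergence)
  if (length(hit)) {
    transition <- c(A = "G", G = "A", C = "T", T = "C")
    tv1 <- c(A = "C", G = "C", C = "A", T = "A")
    tv2 <- c(A = "T", G = "T", C = "G", T = "G")
    p_ts <- ts_tv_ratio / (ts_tv_ratio + 1)
    u <- runif(length(hit))
    new <- ifelse(u < p_ts, transition[chars[hit]],
                  ifelse(u < p_ts + (1 - p_ts) / 2,
                         tv1[chars[hit]], tv2[chars[hit]]))
    chars[hit] <- new
  }
  named_seq(paste0(genome$id, "_mut"), paste(chars, collapse = ""),
            circular = genome$circular)
}

# truncated-normal insert sizes on [lo, hi] by rejection
rtrunc_insert <- function(n, mean, sd, lo = 30, hi = 2 * mean) {
  lo <- max(lo, 1)
  out <- numeric(0)
  while (length(out) < n) {
    x <- round(rnorm(2L * (n - length(out)) + 10L, mean, sd))
    out <- c(out, x[x >= lo & x <= hi])
  }
  as.integer(out[seq_len(n)])
}

#' Sample fragments uniformly from a circular genome
#'
#' Start positions are uniform on the circle, fragments crossing the origin
#' wrap, and the strand is chosen uniformly. Returned fragments are written
#' 5'->3' on their own strand (minus-strand fragments reverse-complemented).
#'
#' @param genome [named_seq].
#' @param n_fragments number of fragments.
#' @param insert_mean,insert_sd insert-size distribution (truncated normal on
#'   \[30, 2*insert_mean\]).
#' @param seed optional RNG seed.
#' @return List with `fragments` (character vector) and `truth` data.frame
#'   (`start` 0-based, `end` = start + insert, possibly > genome length for
#'   origin-spanning fragments, `insert`, `strand`).
#' @export
simulate_fragments <- function(genome, n_fragments, insert_mean = 100,
                               insert_sd = 40, seed = NULL) {
  if (insert_mean <= 0) stop("parameter error: insert_mean must be > 0")
  if (!is.null(seed)) set.seed(seed)
  L <- nchar(genome$residues)
  n <- as.integer(n_fragments)
  starts <- as.integer(floor(runif(n) * L))
  ins <- rtrunc_insert(n, insert_mean, insert_sd)
  strand <- ifelse(runif(n) < 0.5, "+", "-")
  g_rep <- strrep(genome$residues, ceiling(max(c(ins, 1)) / L) + 1L)
  frags <- substring(g_rep, starts + 1L, starts + ins)
  minus <- strand == "-"
  if (any(minus)) frags[minus] <- rc_acgt(frags[minus])
  list(fragments = frags,
       truth = data.frame(start = starts, end = starts + ins, insert = ins,
                          strand = strand, stringsAsFactors = FALSE))
}

#' Apply terminal deamination damage to fragments
#'
#' Each C on each physical strand of the double-stranded fragment converts to
#' T independently with probability `d_max * decay^i + floor` at distance `i`
#' from that strand's 5' end. On the written (read) strand this appears as
#' C->T near the 5' end and G->A near the 3' end; no other bases change.
#'
#' @param fragments character vector of fragments over A,C,G,T (5'->3').
#' @param damage [damage_params].
#' @param seed optional RNG seed.
#' @return List with `fragments` (damaged) and `damaged_positions` (list of
#'   1-based positions changed within each fragment).
#' @export
apply_damage <- function(fragments, damage, seed = NULL) {
  stopifnot(inherits(damage, "damage_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(fragments)
  dmg_pos <- rep(list(integer(0)), n)
  if (!n || (damage$d_max == 0 && damage$floor == 0))
    return(list(fragments = fragments, damaged_positions = dmg_pos))
  lens <- nchar(fragments)
  chars <- strsplit(fragments, "", fixed = TRUE)
  ul <- unlist(chars, use.names = FALSE)
  fi <- rep.int(seq_len(n), lens)
  pos <- unlist(lapply(lens, seq_len), use.names = FALSE)
  len_at <- lens[fi]
  p <- rep(0, length(ul))
  isC <- ul == "C"
  isG <- ul == "G"
  p[isC] <- pmin(1, damage$d_max * damage$decay^(pos[isC] - 1L) + damage$floor)
  p[isG] <- pmin(1, damage$d_max * damage$decay^(len_at[isG] - pos[isG]) + damage$floor)
  conv <- (isC | isG) & runif(length(ul)) < p
  if (any(conv)) {
    ul[conv & isC] <- "T"
    ul[conv & isG] <- "A"
    touched <- unique(fi[conv])
    frag_new <- fragments
    frag_new[touched] <- vapply(split(ul, fi)[as.character(touched)],
                                paste, character(1L), collapse = "")
    hits <- split(pos[conv], fi[conv])
    dmg_pos[as.integer(names(hits))] <- hits
    fragments <- frag_new
  }
  list(fragments = fragments, damaged_positions = dmg_pos)
}

# sparse per-base substitution errors; each erroneous base becomes one of the
# three other bases uniformly
apply_seq_error <- function(reads, error_rate) {
  if (error_rate <= 0 || !length(reads)) return(reads)
  lens <- nchar(reads)
  total <- sum(lens)
  err <- which(runif(total) < error_rate)
  if (!length(err)) return(reads)
  bases <- c("A", "C", "G", "T")
  offsets <- c(0L, cumsum(lens))
  ri <- findInterval(err - 1L, offsets, rightmost.closed = FALSE)
  pin <- err - offsets[ri]
  shift <- sample.int(3L, length(err), replace = TRUE)
  for (k in seq_along(err)) {
    old <- substr(reads[ri[k]], pin[k], pin[k])
    oi <- match(old, bases)
    if (is.na(oi)) next
    substr(reads[ri[k]], pin[k], pin[k]) <- bases[(oi - 1L + shift[k]) %% 4L + 1L]
  }
  reads
}

#' Simulate a paired-end degraded shotgun library
#'
#' Each pair is drawn from the mitochondrial genome with probability
#' `endogenous_fraction`, else from the background genome. Reads are the
#' first `read_len` bases of each fragment end (truncated, adapter-free, when
#' the insert is shorter than the read length); deamination damage is applied
#' to the fragment before sequencing error is applied to the reads. Fully
#' deterministic given `params$seed`.
#'
#' @param mito_genome circular [named_seq] truth genome.
#' @param lib_params [library_params].
#' @param damage [damage_params] or NULL for no damage.
#' @param background_genome [named_seq] or NULL to generate an i.i.d. uniform
#'   random background of `background_length` bp.
#' @param background_length length of the generated default background.
#' @return List of class `sim_library`: `reads1`, `reads2` (named character
#'   vectors), `truth` data.frame (pair id, source, start, end, insert,
#'   strand, damaged positions), and the parameter objects.
#' @export
simulate_library <- function(mito_genome, lib_params, damage = NULL,
                             background_genome = NULL,
                             background_length = 50000L) {
  stopifnot(inherits(lib_params, "library_params"))
  set.seed(lib_params$seed)
  n <- lib_params$n_pairs
  rl <- lib_params$read_len
  if (is.null(background_genome) && lib_params$endogenous_fraction < 1 && n > 0)
    background_genome <- random_genome(background_length, gc = 0.5,
                                       id = "background")
  if (n == 0L) {
    empty <- setNames(character(0), character(0))
    return(structure(list(reads1 = empty, reads2 = empty,
                          truth = data.frame(pair_id = character(0),
                                             source = character(0),
                                             start = integer(0), end = integer(0),
                                             insert = integer(0),
                                             strand = character(0),
                                             damaged = character(0),
                                             stringsAsFactors = FALSE),
                          lib_params = lib_params, damage = damage),
                     class = "sim_library"))
  }
  src <- ifelse(runif(n) < lib_params$endogenous_fraction, "mito", "background")
  L_src <- ifelse(src == "mito", nchar(mito_genome$residues),
                  if (is.null(background_genome)) NA_integer_
                  else nchar(background_genome$residues))
  starts <- as.integer(floor(runif(n) * L_src))
  ins <- rtrunc_insert(n, lib_params$insert_mean, lib_params$insert_sd)
  strand <- ifelse(runif(n) < 0.5, "+", "-")

  extract <- function(genome, idx) {
    if (!length(idx)) return(character(0))
    g_rep <- strrep(genome$residues,
                    ceiling(max(ins[idx]) / nchar(genome$residues)) + 1L)
    substring(g_rep, starts[idx] + 1L, starts[idx] + ins[idx])
  }
  frags <- character(n)
  frags[src == "mito"] <- extract(mito_genome, which(src == "mito"))
  frags[src == "background"] <- extract(background_genome, which(src == "background"))
  minus <- strand == "-"
  if (any(minus)) frags[minus] <- rc_acgt(frags[minus])

  dmg_pos <- rep(list(integer(0)), n)
  if (!is.null(damage)) {
    d <- apply_damage(frags, damage)
    frags <- d$fragments
    dmg_pos <- d$damaged_positions
  }

  reads1 <- substring(frags, 1L, pmin(rl, ins))
  rc_frags <- rc_acgt(frags)
  reads2 <- substring(rc_frags, 1L, pmin(rl, ins))
  reads1 <- apply_seq_error(reads1, lib_params$seq_error)
  reads2 <- apply_seq_error(reads2, lib_params$seq_error)

  ids <- sprintf("pair%06d", seq_len(n))
  names(reads1) <- paste0(ids, "/1")
  names(reads2) <- paste0(ids, "/2")
  truth <- data.frame(pair_id = ids, source = src, start = starts,
                      end = starts + ins, insert = ins, strand = strand,
                      damaged = vapply(dmg_pos, paste, character(1L),
                                       collapse = ","),
                      stringsAsFactors = FALSE)
  structure(list(reads1 = reads1, reads2 = reads2, truth = truth,
                 lib_params = lib_params, damage = damage),
            class = "sim_library")
}

#' @export
print.sim_library <- function(x, ...) {
  cat(sprintf("<sim_library> %d pairs (%d mito, %d background), read_len %d\n",
              nrow(x$truth), sum(x$truth$source == "mito"),
              sum(x$truth$source == "background"), x$lib_params$read_len))
  invisible(x)
}

#' Write a simulated library to paired FASTQ plus a truth table
#'
#' @param lib `sim_library` from [simulate_library()].
#' @param prefix output path prefix; writes `<prefix>_1.fastq`,
#'   `<prefix>_2.fastq` and `<prefix>_truth.tsv`.
#' @return The three paths, invisibly.
#' @export
write_library <- function(lib, prefix) {
  p1 <- paste0(prefix, "_1.fastq")
  p2 <- paste0(prefix, "_2.fastq")
  pt <- paste0(prefix, "_truth.tsv")
  write_fastq(lib$reads1, p1)
  write_fastq(lib$reads2, p2)
  write.table(lib$truth, pt, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2, pt))
}
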