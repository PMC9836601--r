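# Read placement on the circular query genome: k-mer seeding, per-diagonal
# chaining, and banded local extension (Gotoh, in C++). Two stringency
# presets stand in for the high- and moderate-similarity passes of a web
# nucleotide search.

#' Alignment stringency preset
#'
#' `high` (k = 16, min identity 0.92, min alignment length 40) emulates a
#' highly-similar-sequences search; `low` (k = 11, 0.80, 30) a
#' somewhat-similar-sequences search. Scores: match +1, mismatch -2, gap
#' open -4, gap extend -2, band width 8. All fields can be overridden.
#'
#' @param name `"high"` or `"low"`.
#' @param ... named overrides for any preset field (`k`, `min_identity`,
#'   `min_aln_len`, `band`, `match`, `mismatch`, `gap_open`, `gap_ext`).
#' @return List of class `align_preset`.
#' @export
align_preset <- function(name = c("low", "high"), ...) {
  name <- match.arg(name)
  p <- list(name = name,
            k = if (name == "high") 16L else 11L,
            min_identity = if (name == "high") 0.92 else 0.80,
            min_aln_len = if (name == "high") 40L else 30L,
            band = 8L, match = 1, mismatch = -2, gap_open = 4, gap_ext = 2)
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown preset field(s): ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  if (p$min_identity <= 0 || p$min_identity > 1)
    stop("min_identity must lie in (0, 1]")
  if (p$k < 8) stop("k must be >= 8")
  structure(p, class = "align_preset")
}

#' Build a k-mer seed index over a query genome
#'
#' Circular queries are indexed on the sequence extended by its first
#' `k - 1 + read_len` bases so seeds spanning the origin exist; positions are
#' reported modulo the query length. K-mers containing N or ambiguity
#' symbols are skipped.
#'
#' @param query [named_seq].
#' @param k k-mer size (>= 8, <= query length).
#' @param read_len longest read expected (controls the circular extension).
#' @return Object of class `seed_index`.
#' @export
build_index <- function(query, k, read_len = 150L) {
  k <- as.integer(k)
  L <- nchar(query$residues)
  if (k > L) stop("parameter error: k (", k, ") exceeds query length (", L, ")")
  if (k < 8L) stop("parameter error: k must be >= 8")
  ext_len <- if (query$circular) min(L, k - 1L + as.integer(read_len)) else 0L
  s <- paste0(query$residues, substr(query$residues, 1L, ext_len))
  n <- nchar(s)
  starts <- seq_len(n - k + 1L)
  kmers <- substring(s, starts, starts + k - 1L)
  keep <- !grepl("[^ACGT]", kmers)
  env <- new.env(parent = emptyenv())
  if (any(keep)) {
    pos0 <- (starts[keep] - 1L) %% L
    km <- kmers[keep]
    dup <- duplicated(paste0(km, "@", pos0))
    idx <- split(pos0[!dup], km[!dup])
    list2env(lapply(idx, sort), envir = env)
  } else {
    warning("seed index is empty: no unambiguous ", k, "-mers in query '",
            query$id, "'")
  }
  structure(list(k = k, env = env, query_length = L,
                 circular = query$circular, query_id = query$id,
                 query_residues = query$residues, read_len = as.integer(read_len)),
            class = "seed_index")
}

#' Look up the indexed positions of a k-mer
#'
#' @param index `seed_index`.
#' @param kmer k-mer string.
#' @return Sorted 0-based query positions (empty if absent).
#' @export
index_positions <- function(index, kmer) {
  v <- get0(toupper(kmer), envir = index$env, ifnotfound = NULL)
  if (is.null(v)) integer(0) else v
}

# cluster seed diagonals; returns list of (diag, n_hits) ordered by support
seed_clusters <- function(diags, band, L, circular) {
  tab <- table(diags)
  d <- as.integer(names(tab))
  cnt <- as.integer(tab)
  o <- order(d)
  d <- d[o]; cnt <- cnt[o]
  if (circular && length(d) > 1L && (d[1L] + L - d[length(d)]) <= band) {
    # wrap-adjacent diagonals: shift the high end below zero and re-sort
    hi <- d > L / 2 & (d - L + band) >= min(d)
    d[hi] <- d[hi] - L
    o <- order(d)
    d <- d[o]; cnt <- cnt[o]
  }
  grp <- cumsum(c(1L, diff(d) > band))
  res <- lapply(split(seq_along(d), grp), function(ii) {
    best <- ii[which.max(cnt[ii])]
    list(diag = d[best], n_hits = sum(cnt[ii]))
  })
  res[order(vapply(res, `[[`, 0L, "n_hits"), decreasing = TRUE)]
}

# extend one candidate diagonal by banded local alignment
extend_candidate <- function(r, diag, index, preset) {
  L <- index$query_length
  n_r <- nchar(r)
  band <- preset$band
  if (index$circular) {
    ws0 <- ((diag - band) %% L + L) %% L
    wlen <- n_r + 2L * band
    window <- circ_substr(index$query_residues, ws0, wlen)
  } else {
    ws0 <- max(0L, diag - band)
    wend <- min(L, diag + n_r + band)
    if (wend - ws0 < 1L) return(NULL)
    window <- substr(index$query_residues, ws0 + 1L, wend)
  }
  res <- .sw_align_cpp(window, r, preset$match, preset$mismatch,
                       preset$gap_open, preset$gap_ext)
  if (res$score <= 0) return(NULL)
  qstart0 <- ws0 + res$a_start - 1L
  if (index$circular) qstart0 <- qstart0 %% L
  list(score = res$score, qstart0 = qstart0,
       qspan = res$a_end - res$a_start + 1L,
       b_start = res$b_start, b_end = res$b_end,
       cols_q0 = if (index$circular) (ws0 + res$q_cols - 1L) %% L
                 else ws0 + res$q_cols - 1L,
       cols_r = res$r_cols,
       del_q0 = if (index$circular) (ws0 + res$del_cols - 1L) %% L
                else ws0 + res$del_cols - 1L,
       matches = res$matches, mismatches = res$mismatches,
       gap_columns = res$gap_columns)
}

#' Align one read against an indexed query
#'
#' Both orientations are tried; seed hits are chained per diagonal, the
#' best-supported diagonals are extended by banded local alignment, and the
#' highest-scoring alignment meeting the preset's identity and length
#' thresholds is emitted. Ties are broken by (score, leftmost query start,
#' plus strand); reads aligning equally well at two distinct query loci are
#' dropped as ambiguous.
#'
#' @param read read sequence (IUPAC; ambiguity symbols score as mismatches).
#' @param index `seed_index` from [build_index()].
#' @param preset [align_preset()].
#' @param read_id identifier recorded in the result.
#' @return A `local_alignment` list, or NULL when no acceptable placement
#'   exists.
#' @export
align_read <- function(read, index, preset = align_preset("low"),
                       read_id = "read") {
  read <- canonicalize_residues(read, what = paste0("read '", read_id, "'"))
  n_r <- nchar(read)
  if (n_r < preset$min_aln_len || n_r < index$k) return(NULL)
  L <- index$query_length
  k <- index$k
  max_clusters <- 8L
  cands <- list()
  for (strand in c("+", "-")) {
    r <- if (strand == "+") read else reverse_complement(read)
    starts <- seq_len(n_r - k + 1L)
    kmers <- substring(r, starts, starts + k - 1L)
    ok <- !grepl("[^ACGT]", kmers)
    if (!any(ok)) next
    hits_per <- mget(kmers[ok], envir = index$env, ifnotfound = list(NULL))
    nh <- lengths(hits_per)
    if (!sum(nh)) next
    qpos <- unlist(hits_per, use.names = FALSE)
    rpos0 <- rep.int(starts[ok] - 1L, nh)
    diags <- if (index$circular) ((qpos - rpos0) %% L + L) %% L else qpos - rpos0
    clusters <- seed_clusters(diags, preset$band, L, index$circular)
    for (cl in clusters[seq_len(min(length(clusters), max_clusters))]) {
      cand <- extend_candidate(r, cl$diag, index, preset)
      if (is.null(cand)) next
      cand$strand <- strand
      cands[[length(cands) + 1L]] <- cand
    }
  }
  if (!length(cands)) return(NULL)
  scores <- vapply(cands, `[[`, 0, "score")
  qstarts <- vapply(cands, `[[`, 0L, "qstart0")
  strands <- vapply(cands, `[[`, "", "strand")
  ord <- order(-scores, qstarts, strands != "+")
  best <- cands[[ord[1L]]]
  top <- which(scores == max(scores))
  if (length(top) > 1L) {
    dist <- abs(qstarts[top] - best$qstart0)
    if (index$circular) dist <- pmin(dist, L - dist)
    if (any(dist > n_r)) return(NULL) # equally good at two loci: ambiguous
  }
  aln_len <- best$matches + best$mismatches + best$gap_columns
  identity <- best$matches / aln_len
  if (aln_len < preset$min_aln_len || identity < preset$min_identity)
    return(NULL)
  if (best$strand == "+") {
    rs0 <- best$b_start - 1L; re0 <- best$b_end
  } else {
    rs0 <- n_r - best$b_end; re0 <- n_r - best$b_start + 1L
  }
  r_oriented <- if (best$strand == "+") read else reverse_complement(read)
  structure(list(read_id = read_id, strand = best$strand,
                 query_start = best$qstart0,
                 query_end = best$qstart0 + best$qspan,
                 read_start = rs0, read_end = re0,
                 matches = best$matches, mismatches = best$mismatches,
                 gap_columns = best$gap_columns, identity = identity,
                 score = best$score,
                 cols_qpos = best$cols_q0,
                 cols_base = substring(r_oriented, best$cols_r, best$cols_r),
                 del_qpos = best$del_q0),
            class = "local_alignment")
}

#' @export
print.local_alignment <- function(x, ...) {
  cat(sprintf("<local_alignment> %s %s q[%d,%d) r[%d,%d) id=%.3f score=%g\n",
              x$read_id, x$strand, x$query_start, x$query_end,
              x$read_start, x$read_end, x$identity, x$score))
  invisible(x)
}

#' Align a read library against a query genome
#'
#' Mates are treated as independent single-end reads. One best alignment is
#' kept per read (or none); output order follows input order.
#'
#' @param reads named character vector of reads, or a character vector of
#'   FASTQ paths to read and concatenate.
#' @param query [named_seq] query genome.
#' @param preset [align_preset()].
#' @param index optional prebuilt `seed_index` (must match `preset$k`).
#' @return List of class `alignment_set` with `alignments` (list of
#'   `local_alignment`) and `summary` (reads in / aligned / fraction).
#' @export
align_library <- function(reads, query, preset = align_preset("low"),
                          index = NULL) {
  if (is.character(reads) && is.null(names(reads)) && length(reads)) {
    # unnamed character input is interpreted as FASTQ path(s)
    missing <- reads[!file.exists(reads)]
    if (length(missing))
      stop("FASTQ I/O error: no such file: ", missing[1L])
    reads <- do.call(c, lapply(reads, read_fastq))
  }
  if (is.null(index)) {
    rl <- if (length(reads)) max(nchar(reads)) else 150L
    index <- build_index(query, preset$k, read_len = rl)
  } else if (index$k != preset$k) {
    stop("index k (", index$k, ") does not match preset k (", preset$k, ")")
  }
  alns <- vector("list", length(reads))
  for (i in seq_along(reads))
    alns[[i]] <- align_read(reads[[i]], index, preset, read_id = names(reads)[i])
  alns <- alns[!vapply(alns, is.null, TRUE)]
  structure(list(alignments = alns,
                 summary = list(n_reads = length(reads),
                                n_aligned = length(alns),
                                aligned_fraction =
                                  if (length(reads)) length(alns) / length(reads)
                                  else 0),
                 preset = preset, query_id = query$id),
            class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  cat(sprintf("<alignment_set> vs %s (preset %s): %d/%d reads aligned (%.1f%%)\n",
              x$query_id, x$preset$name, x$summary$n_aligned,
              x$summary$n_reads, 100 * x$summary$aligned_fraction))
  invisible(x)
}

#' Write alignments as TSV
#'
#' @param aset `alignment_set` (or plain list of `local_alignment`).
#' @param path output file.
#' @export
write_alignments <- function(aset, path) {
  alns <- if (inherits(aset, "alignment_set")) aset$alignments else aset
  df <- do.call(rbind, lapply(alns, function(a)
    data.frame(read_id = a$read_id, strand = a$strand,
               query_start = a$query_start, query_end = a$query_end,
               read_start = a$read_start, read_end = a$read_end,
               matches = a$matches, mismatches = a$mismatches,
               gaps = a$gap_columns, identity = a$identity,
               stringsAsFactors = FALSE)))
  if (is.null(df))
    df <- data.frame(read_id = character(0), strand = character(0),
                     query_start = integer(0), query_end = integer(0),
                     read_start = integer(0), read_end = integer(0),
                     matches = integer(0), mismatches = integer(0),
                     gaps = integer(0), identity = numeric(0))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
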