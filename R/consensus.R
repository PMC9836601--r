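# Query-anchored pileup and per-site IUPAC consensus.
#
# This is the heart of the reconstruction: reads are aggregated into a
# per-query-position base-count matrix (minus-strand reads already
# complemented into query orientation by the aligner), and each site is
# called as N (uncovered), the single supported base (concordant with or
# substituted against the query), or the IUPAC code of the supported base
# set (ambiguous). Read insertions are skipped and deletions only counted,
# so the reconstruction always has exactly the query's length.

#' Consensus calling policy
#'
#' @param min_depth_call minimum depth to call a base at all (default 1:
#'   single-read evidence is accepted, matching a very-low-coverage regime).
#' @param min_minor_count minimum absolute count for an allele.
#' @param min_minor_frac minimum frequency for an allele (default 0.25; this
#'   suppresses lone damaged or erroneous bases at well-covered sites).
#'   Threshold comparisons are inclusive.
#' @param max_alleles allele sets larger than this are treated as
#'   uninformative and called N.
#' @return List of class `call_policy`.
#' @export
call_policy <- function(min_depth_call = 1L, min_minor_count = 1L,
                        min_minor_frac = 0.25, max_alleles = 4L) {
  if (min_depth_call < 1) stop("min_depth_call must be >= 1")
  if (min_minor_frac < 0 || min_minor_frac > 1)
    stop("min_minor_frac must lie in [0, 1]")
  if (min_minor_count < 0) stop("min_minor_count must be >= 0")
  structure(list(min_depth_call = as.integer(min_depth_call),
                 min_minor_count = as.integer(min_minor_count),
                 min_minor_frac = min_minor_frac,
                 max_alleles = as.integer(max_alleles)),
            class = "call_policy")
}

#' Build a query-anchored pileup from alignments
#'
#' Every aligned (match or mismatch) column contributes the strand-normalized
#' read base to that query position's count; read deletions increment a
#' deletion counter only; positions wrap modulo the query length for circular
#' queries (the aligner already reports them mod length).
#'
#' @param alignments an `alignment_set` from [align_library()] or a list of
#'   `local_alignment` objects.
#' @param query [named_seq] the alignments were made against.
#' @param reads optional named read vector; when supplied, every alignment's
#'   read id must be present (consistency check).
#' @return Object of class `pileup`: `counts` (length x 4 matrix, columns
#'   A,C,G,T), `del`, `depth`.
#' @export
build_pileup <- function(alignments, query, reads = NULL) {
  if (inherits(alignments, "alignment_set")) {
    if (!is.null(alignments$query_id) && alignments$query_id != query$id)
      stop("consistency error: alignments were made against '",
           alignments$query_id, "', not '", query$id, "'")
    alignments <- alignments$alignments
  }
  if (!is.null(reads)) {
    ids <- vapply(alignments, `[[`, "", "read_id")
    missing <- setdiff(ids, names(reads))
    if (length(missing))
      stop("consistency error: alignment read id(s) not in reads: ",
           paste(utils::head(missing, 3L), collapse = ", "))
  }
  L <- nchar(query$residues)
  bases <- c("A", "C", "G", "T")
  qidx <- unlist(lapply(alignments, `[[`, "cols_qpos"), use.names = FALSE)
  bchr <- unlist(lapply(alignments, `[[`, "cols_base"), use.names = FALSE)
  counts <- matrix(0L, nrow = L, ncol = 4L, dimnames = list(NULL, bases))
  if (length(qidx)) {
    bi <- match(bchr, bases)
    keep <- !is.na(bi)
    counts[] <- tabulate((bi[keep] - 1L) * L + (qidx[keep] %% L) + 1L,
                         nbins = 4L * L)
  }
  didx <- unlist(lapply(alignments, `[[`, "del_qpos"), use.names = FALSE)
  del <- if (length(didx)) tabulate((didx %% L) + 1L, nbins = L) else integer(L)
  structure(list(query_id = query$id, length = L, counts = counts,
                 del = as.integer(del), depth = as.integer(rowSums(counts))),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("<pileup> %s: %d bp, mean depth %.2f, %d covered sites\n",
              x$query_id, x$length, mean(x$depth), sum(x$depth > 0)))
  invisible(x)
}

# vectorised caller over a counts matrix; returns call/status/depth
call_sites_matrix <- function(counts, query_bases, policy) {
  depth <- rowSums(counts)
  thr <- pmax(policy$min_minor_count, policy$min_minor_frac * depth - 1e-9)
  mask <- counts >= thr & counts > 0
  mask[depth < policy$min_depth_call, ] <- FALSE
  n_alleles <- rowSums(mask)
  code <- as.integer(mask %*% c(1L, 2L, 4L, 8L))
  call <- rep("N", nrow(counts))
  nz <- code > 0L & n_alleles <= policy$max_alleles
  call[nz] <- IUPAC_FROM_MASK[code[nz]]
  status <- rep("missing", nrow(counts))
  single <- call != "N" & n_alleles == 1L
  status[single & call == query_bases] <- "concordant"
  status[single & call != query_bases] <- "substituted"
  status[call != "N" & n_alleles > 1L] <- "ambiguous"
  status[call == "N"] <- "missing"
  data.frame(call = call, status = status, depth = as.integer(depth),
             stringsAsFactors = FALSE)
}

#' Call a single site
#'
#' Depth below `min_depth_call` gives N/missing. Alleles are the bases with
#' count >= `min_minor_count` and frequency >= `min_minor_frac` (inclusive);
#' a single allele is called directly (concordant if it equals the query
#' base, substituted otherwise), two or more alleles give the IUPAC code
#' denoting exactly that base set (ambiguous).
#'
#' @param counts named counts, e.g. `c(C = 3, T = 2)` (missing bases are 0).
#' @param query_base query base at the site.
#' @param policy [call_policy()].
#' @return List with `call`, `status`, `depth`.
#' @export
call_site <- function(counts, query_base, policy = call_policy()) {
  full <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  if (length(counts)) {
    if (is.null(names(counts)) || !all(names(counts) %in% names(full)))
      stop("counts must be named with bases A, C, G, T")
    if (any(counts < 0)) stop("counts must be non-negative")
    full[names(counts)] <- as.integer(counts)
  }
  res <- call_sites_matrix(matrix(full, nrow = 1L,
                                  dimnames = list(NULL, names(full))),
                           toupper(query_base), policy)
  list(call = res$call, status = res$status, depth = res$depth)
}

#' Reconstruct a genome from a pileup
#'
#' Applies the calling policy at every query position. The output sequence
#' always has exactly the query's length (query-anchored coordinate
#' contract; indels relative to the query are not called).
#'
#' @param pileup [build_pileup()] result for this query.
#' @param query [named_seq].
#' @param policy [call_policy()].
#' @param provenance named list merged into the recorded provenance
#'   (e.g. preset name, seed).
#' @return Object of class `reconstruction`: `seq` ([named_seq]), `calls`
#'   (per-site data.frame), `tally`, `provenance`.
#' @export
reconstruct <- function(pileup, query, policy = call_policy(),
                        provenance = list()) {
  if (!inherits(pileup, "pileup")) stop("pileup must come from build_pileup()")
  L <- nchar(query$residues)
  if (pileup$length != L)
    stop("consistency error: pileup length ", pileup$length,
         " != query length ", L)
  if (pileup$query_id != query$id)
    stop("consistency error: pileup was built against '", pileup$query_id,
         "', not '", query$id, "'")
  qb <- strsplit(query$residues, "", fixed = TRUE)[[1L]]
  res <- call_sites_matrix(pileup$counts, qb, policy)
  calls <- data.frame(pos = seq_len(L), query_base = qb, pileup$counts,
                      del = pileup$del, depth = res$depth, call = res$call,
                      status = res$status, stringsAsFactors = FALSE)
  sym_counts <- vapply(TWOPLUS_CODES, function(s) sum(res$call == s), 0L)
  tally <- list(length = L,
                n_count = sum(res$call == "N"),
                n_fraction = sum(res$call == "N") / L,
                ambiguity_counts = as.list(sym_counts),
                concordant = sum(res$status == "concordant"),
                substituted = sum(res$status == "substituted"),
                ambiguous = sum(res$status == "ambiguous"),
                missing = sum(res$status == "missing"))
  prov <- utils::modifyList(list(query_id = query$id,
                                 policy = unclass(policy)), provenance)
  structure(list(seq = named_seq(paste0(query$id, "_reconstruction"),
                                 paste(res$call, collapse = ""),
                                 circular = query$circular),
                 calls = calls, tally = tally, provenance = prov),
            class = "reconstruction")
}

#' @export
print.reconstruction <- function(x, ...) {
  t <- x$tally
  amb <- unlist(t$ambiguity_counts)
  amb <- amb[amb > 0]
  cat(sprintf("<reconstruction> %s: %d bp, %d N (%.1f%%), %d substituted%s\n",
              x$seq$id, t$length, t$n_count, 100 * t$n_fraction, t$substituted,
              if (length(amb)) paste0(", ambiguous: ",
                                      paste(sprintf("%s=%d", names(amb), amb),
                                            collapse = " "))
              else ""))
  invisible(x)
}

#' Write reconstruction artifacts (FASTA + per-site TSV + tally JSON)
#'
#' @param recon [reconstruct()] result.
#' @param prefix output path prefix.
#' @return Paths written, invisibly.
#' @export
write_reconstruction <- function(recon, prefix) {
  pf <- paste0(prefix, ".fasta")
  pc <- paste0(prefix, "_calls.tsv")
  pt <- paste0(prefix, "_tally.json")
  write_fasta(recon$seq, pf)
  write.table(recon$calls, pc, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(c(recon$tally, list(provenance = recon$provenance)),
                       pt, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(pf, pc, pt))
}
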