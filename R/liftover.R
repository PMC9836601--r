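# Annotation transfer onto the reconstruction and per-feature recovery.
#
# Because the consensus contract guarantees the reconstruction has exactly
# the query's length, the liftover is the identity map on coordinates: the
# query's features are reused unchanged on the reconstructed genome, and
# recovery is then reported per feature (a short gene entirely uncovered by
# reads is flagged fully missing).

#' Transfer an annotation onto a reconstruction
#'
#' @param query_annotation [annotation] of the query genome.
#' @param recon [reconstruct()] result of the same length.
#' @return [annotation] on the reconstruction's id, identical coordinates
#'   and strands.
#' @export
liftover_annotation <- function(query_annotation, recon) {
  if (query_annotation$genome_length != recon$tally$length)
    stop("consistency error: annotation genome_length ",
         query_annotation$genome_length, " != reconstruction length ",
         recon$tally$length)
  annotation(recon$seq$id, query_annotation$genome_length,
             query_annotation$features)
}

#' Per-feature missing-data report
#'
#' Ambiguity codes count as recovered sequence; only N is missing. A feature
#' whose entire interval is N is flagged `fully_missing`.
#'
#' @param recon [reconstruct()] result.
#' @param ann [annotation] with the same genome length (query or lifted).
#' @return Object of class `missingness_report`: `features` data.frame
#'   (name, ftype, strand, length, n_count, pct_n, ambiguous, fully_missing)
#'   plus a genome-wide `genome` roll-up.
#' @export
feature_missingness <- function(recon, ann) {
  if (ann$genome_length != recon$tally$length)
    stop("consistency error: annotation genome_length != reconstruction length")
  chars <- strsplit(recon$seq$residues, "", fixed = TRUE)[[1L]]
  f <- ann$features
  per <- lapply(seq_len(nrow(f)), function(i) {
    seg <- chars[(f$start[i] + 1L):f$end[i]]
    nn <- sum(seg == "N")
    len <- length(seg)
    data.frame(name = f$name[i], ftype = f$ftype[i], strand = f$strand[i],
               length = len, n_count = nn, pct_n = round(100 * nn / len, 1L),
               ambiguous = sum(seg %in% TWOPLUS_CODES),
               fully_missing = nn == len, stringsAsFactors = FALSE)
  })
  features <- do.call(rbind, per)
  genome <- list(length = length(chars), n_count = sum(chars == "N"),
                 pct_n = round(100 * mean(chars == "N"), 1L),
                 n_features = nrow(features),
                 n_fully_missing = sum(features$fully_missing))
  structure(list(features = features, genome = genome),
            class = "missingness_report")
}

#' @export
print.missingness_report <- function(x, ...) {
  g <- x$genome
  cat(sprintf("<missingness_report> %d bp, %d N (%.1f%%); %d/%d features fully missing\n",
              g$length, g$n_count, g$pct_n, g$n_fully_missing, g$n_features))
  flagged <- x$features[x$features$fully_missing, "name"]
  if (length(flagged)) cat("  fully missing:", paste(flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Extract per-feature sequences from a reconstruction
#'
#' Minus-strand features are reverse-complemented.
#'
#' @param recon [reconstruct()] result.
#' @param ann [annotation] of the same length.
#' @param path optional FASTA output path.
#' @return List of [named_seq], one per feature.
#' @export
extract_feature_seqs <- function(recon, ann, path = NULL) {
  if (ann$genome_length != recon$tally$length)
    stop("consistency error: annotation genome_length != reconstruction length")
  f <- ann$features
  seqs <- lapply(seq_len(nrow(f)), function(i) {
    s <- substr(recon$seq$residues, f$start[i] + 1L, f$end[i])
    if (f$strand[i] == "-") s <- reverse_complement(s)
    named_seq(f$name[i], s)
  })
  if (!is.null(path)) write_fasta(seqs, path)
  seqs
}
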