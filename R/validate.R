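# Robustness checks: completeness accounting and query-independence of the
# reconstruction (reconstructing the same library against different related
# queries should give the same calls at co-covered sites).

#' Completeness report for a reconstruction
#'
#' @param recon [reconstruct()] result.
#' @return Object of class `completeness_report`: length, N count and
#'   percent (1 decimal), per-ambiguity-symbol counts, substituted count,
#'   mean depth over non-N sites.
#' @export
completeness_report <- function(recon) {
  t <- recon$tally
  non_n <- recon$calls$call != "N"
  structure(list(length = t$length,
                 n_count = t$n_count,
                 n_percent = round(100 * t$n_fraction, 1L),
                 symbol_counts = t$ambiguity_counts,
                 substituted = t$substituted,
                 concordant = t$concordant,
                 mean_depth_non_n = if (any(non_n))
                   mean(recon$calls$depth[non_n]) else 0),
            class = "completeness_report")
}

#' @export
print.completeness_report <- function(x, ...) {
  amb <- unlist(x$symbol_counts)
  amb <- amb[amb > 0]
  cat(sprintf("Reconstruction completeness: %d bp, %d N (%.1f%%)\n",
              x$length, x$n_count, x$n_percent))
  if (length(amb))
    cat("  ambiguity symbols:",
        paste(sprintf("%s=%d", names(amb), amb), collapse = " "), "\n")
  cat(sprintf("  substituted vs query: %d; mean depth over called sites: %.2f\n",
              x$substituted, x$mean_depth_non_n))
  invisible(x)
}

# map positions of q1 onto qi via a global pairwise alignment of the two
# query sequences; NA where an indel column prevents a 1:1 mapping
map_query_coords <- function(q1, qi) {
  pa <- Biostrings::pairwiseAlignment(Biostrings::DNAString(qi$residues),
                                      Biostrings::DNAString(q1$residues),
                                      type = "global")
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  map <- rep(NA_integer_, nchar(q1$residues))
  ip <- 0L; is <- 0L
  for (k in seq_along(p)) {
    cp <- p[k] != "-"; cs <- s[k] != "-"
    if (cp) ip <- ip + 1L
    if (cs) is <- is + 1L
    if (cp && cs) map[is] <- ip
  }
  map
}

#' Query-independence check
#'
#' Reconstructs the same read library once per query and compares the calls
#' over sites called (non-N) in all reconstructions. Queries of unequal
#' length are reconciled by a global pairwise alignment of the queries
#' themselves; indel columns are excluded. Reported both over full IUPAC
#' symbols and restricted to unambiguous (A/C/G/T) calls.
#'
#' @param reads named character vector of reads (or FASTQ paths).
#' @param queries list of two or more [named_seq] queries.
#' @param preset [align_preset()].
#' @param policy [call_policy()].
#' @param min_overlap minimum number of co-called sites below which the
#'   comparison is reported as `insufficient-overlap` rather than pass/fail.
#' @return Object of class `independence_report`: `status` (`pass`, `fail`,
#'   `insufficient-overlap`), counts, and the discordant positions with the
#'   per-query calls.
#' @export
query_independence <- function(reads, queries, preset = align_preset("low"),
                               policy = call_policy(), min_overlap = 50L) {
  if (!is.list(queries) || length(queries) < 2L)
    stop("parameter error: query_independence needs >= 2 queries")
  recons <- lapply(queries, function(q) {
    aset <- align_library(reads, q, preset)
    reconstruct(build_pileup(aset, q), q, policy,
                provenance = list(preset = preset$name))
  })
  L1 <- nchar(queries[[1L]]$residues)
  lens <- vapply(queries, function(q) nchar(q$residues), 0L)
  maps <- vector("list", length(queries))
  maps[[1L]] <- seq_len(L1)
  for (i in seq_along(queries)[-1L]) {
    maps[[i]] <- if (lens[i] == L1) seq_len(L1)
                 else map_query_coords(queries[[1L]], queries[[i]])
  }
  callmat <- matrix(NA_character_, nrow = L1, ncol = length(queries))
  for (i in seq_along(queries)) {
    ok <- !is.na(maps[[i]])
    callmat[ok, i] <- recons[[i]]$calls$call[maps[[i]][ok]]
  }
  co_called <- rowSums(is.na(callmat) | callmat == "N") == 0L
  n_compared <- sum(co_called)
  agree <- rep(TRUE, L1)
  agree[co_called] <- apply(callmat[co_called, , drop = FALSE], 1L,
                            function(z) all(z == z[1L]))
  discordant_pos <- which(co_called & !agree)
  unamb <- co_called &
    apply(callmat, 1L, function(z) all(z %in% c("A", "C", "G", "T")))
  n_disc_unamb <- sum(unamb & !agree)
  status <- if (n_compared < min_overlap) "insufficient-overlap"
            else if (length(discordant_pos) == 0L) "pass" else "fail"
  disc <- data.frame(pos = discordant_pos)
  for (i in seq_along(queries))
    disc[[paste0("call_q", i)]] <- callmat[discordant_pos, i]
  structure(list(status = status, n_compared = n_compared,
                 n_discordant = length(discordant_pos),
                 n_compared_unambiguous = sum(unamb),
                 n_discordant_unambiguous = n_disc_unamb,
                 discordant = disc,
                 aligned_fractions = vapply(recons, function(r)
                   1 - r$tally$n_fraction, 0)),
            class = "independence_report")
}

#' @export
print.independence_report <- function(x, ...) {
  cat(sprintf("Query-independence: %s (%d discordant of %d co-called sites)\n",
              x$status, x$n_discordant, x$n_compared))
  invisible(x)
}

#' Write an independence report (JSON summary + discordance TSV)
#'
#' @param report [query_independence()] result.
#' @param prefix output path prefix.
#' @export
write_independence_report <- function(report, prefix) {
  pj <- paste0(prefix, ".json")
  pt <- paste0(prefix, "_discordant.tsv")
  jsonlite::write_json(unclass(report)[c("status", "n_compared", "n_discordant",
                                         "n_compared_unambiguous",
                                         "n_discordant_unambiguous")],
                       pj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write.table(report$discordant, pt, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(pj, pt))
}
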