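# Deamination damage profiling from the reconstruction's ambiguity spectrum.
#
# Hydrolytic deamination of cytosine in degrading DNA reads out as C->T
# (and, against the plus strand, G->A). In a query-anchored reconstruction
# this surfaces as an excess of Y calls at query-C sites and R calls at
# query-G sites over all other two-base ambiguity classes; this module
# counts that excess and attaches an exact binomial test.

#' Classify ambiguous calls by their query base
#'
#' @param recon [reconstruct()] result.
#' @param query the [named_seq] the reconstruction is anchored on.
#' @return Object of class `ambiguity_summary`: a counts matrix indexed by
#'   query base (A,C,G,T,N) x ambiguity symbol. Concordant, substituted and
#'   missing sites are excluded.
#' @export
summarize_ambiguities <- function(recon, query) {
  if (nchar(query$residues) != recon$tally$length)
    stop("consistency error: query length != reconstruction length")
  rows <- c("A", "C", "G", "T", "N")
  mat <- matrix(0L, nrow = 5L, ncol = length(TWOPLUS_CODES),
                dimnames = list(rows, TWOPLUS_CODES))
  amb <- recon$calls[recon$calls$status == "ambiguous", , drop = FALSE]
  if (nrow(amb)) {
    qb <- amb$query_base
    qb[!qb %in% rows] <- "N"
    t <- table(factor(qb, levels = rows),
               factor(amb$call, levels = TWOPLUS_CODES))
    mat[] <- as.integer(t)
  }
  structure(list(matrix = mat, n_ambiguous = sum(mat)),
            class = "ambiguity_summary")
}

#' @export
print.ambiguity_summary <- function(x, ...) {
  cat("<ambiguity_summary>", x$n_ambiguous, "ambiguous calls\n")
  m <- x$matrix[, colSums(x$matrix) > 0, drop = FALSE]
  if (ncol(m)) print(m[rowSums(x$matrix) > 0, , drop = FALSE])
  invisible(x)
}

#' Deamination-consistency statistic
#'
#' Counts deamination-consistent ambiguity calls (Y at query-C plus R at
#' query-G) against all other two-or-more-base calls, forming
#' `asymmetry_ratio = n_consistent / (n_other + pseudocount)`, and tests
#' `n_consistent` among ambiguous calls at C/G query sites against a null
#' proportion of 1/3 with a one-sided exact binomial test (each of C and G
#' admits three two-base codes, of which deamination explains exactly one;
#' Y at a non-C site counts as "other" because deamination cannot create a
#' C/T mixture where no C existed).
#'
#' @param summary [summarize_ambiguities()] result.
#' @param pseudocount denominator guard (default 1).
#' @param null_prop binomial null proportion (default 1/3).
#' @return Object of class `damage_report` with `n_consistent`, `n_other`,
#'   `asymmetry_ratio`, `binom_p`.
#' @export
deamination_asymmetry <- function(summary, pseudocount = 1, null_prop = 1 / 3) {
  stopifnot(inherits(summary, "ambiguity_summary"))
  m <- summary$matrix
  n_consistent <- m["C", "Y"] + m["G", "R"]
  n_other <- sum(m) - n_consistent
  n_cg <- sum(m[c("C", "G"), ])
  p <- if (n_cg == 0) 1
       else binom.test(n_consistent, n_cg, p = null_prop,
                       alternative = "greater")$p.value
  structure(list(n_consistent = as.integer(n_consistent),
                 n_other = as.integer(n_other),
                 asymmetry_ratio = n_consistent / (n_other + pseudocount),
                 binom_p = p, pseudocount = pseudocount,
                 null_prop = null_prop, n_cg_sites = as.integer(n_cg)),
            class = "damage_report")
}

#' @export
print.damage_report <- function(x, ...) {
  cat("Deamination damage report\n",
      sprintf("  consistent (Y@C + R@G): %d\n", x$n_consistent),
      sprintf("  other ambiguity calls : %d\n", x$n_other),
      sprintf("  asymmetry ratio       : %.2f (pseudocount %g)\n",
              x$asymmetry_ratio, x$pseudocount),
      sprintf("  exact binomial p      : %.3g (null %.3f over %d C/G sites)\n",
              x$binom_p, x$null_prop, x$n_cg_sites), sep = "")
  invisible(x)
}

#' Write the damage report (JSON) and ambiguity matrix (TSV)
#'
#' @param report [deamination_asymmetry()] result.
#' @param summary [summarize_ambiguities()] result.
#' @param prefix output path prefix.
#' @export
write_damage_report <- function(report, summary, prefix) {
  pj <- paste0(prefix, ".json")
  pm <- paste0(prefix, "_matrix.tsv")
  jsonlite::write_json(unclass(report), pj, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  write.table(as.data.frame(summary$matrix), pm, sep = "\t", quote = FALSE,
              col.names = NA)
  invisible(c(pj, pm))
}
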