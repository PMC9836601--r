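#' Named nucleotide sequence
#'
#' Lightweight container for a (possibly circular) nucleotide sequence over
#' the IUPAC alphabet. Residues are canonicalized to upper case and U is
#' mapped to T on construction.
#'
#' @param id sequence identifier.
#' @param residues IUPAC nucleotide string.
#' @param circular logical; circular sequences wrap across the origin in
#'   downstream coordinate arithmetic (indexing, fragment sampling, seeding).
#' @return Object of class `named_seq` with fields `id`, `residues`,
#'   `circular`.
#' @export
named_seq <- function(id, residues, circular = FALSE) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("id must be a non-empty string")
  residues <- canonicalize_residues(residues, what = sprintf("sequence '%s'", id))
  if (!nzchar(residues)) stop("sequence '", id, "' is empty")
  structure(list(id = id, residues = residues, circular = isTRUE(circular)),
            class = "named_seq")
}

#' @export
print.named_seq <- function(x, ...) {
  cat(sprintf("<named_seq> %s: %d bp%s\n", x$id, nchar(x$residues),
              if (x$circular) " (circular)" else ""))
  invisible(x)
}

#' @export
length.named_seq <- function(x) nchar(x$residues)

#' Read a multi-record FASTA file
#'
#' @param path FASTA file. Must contain at least one record; malformed headers
#'   raise a parse error naming the line, illegal residues a validation error
#'   naming the position.
#' @param circular logical applied to every returned sequence.
#' @return List of [named_seq] objects.
#' @export
read_fasta <- function(path, circular = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty FASTA file: ", path)
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1L])
    stop(sprintf("FASTA parse error in %s at line 1: expected '>' header, got '%s'",
                 path, substr(lines[1L], 1L, 40L)))
  rec <- cumsum(is_hdr)
  headers <- sub("^>", "", lines[is_hdr])
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1L), 1L)
  if (any(!nzchar(ids))) {
    ln <- which(is_hdr)[which(!nzchar(ids))[1L]]
    stop(sprintf("FASTA parse error in %s at line %d: empty header", path, ln))
  }
  bodies <- vapply(split(lines[!is_hdr], rec[!is_hdr]), paste, character(1L),
                   collapse = "")
  seqs <- character(max(rec))
  seqs[as.integer(names(bodies))] <- bodies
  lapply(seq_along(ids), function(i) named_seq(ids[i], seqs[i], circular))
}

#' Write sequences to FASTA
#'
#' @param seqs a [named_seq] or list of them.
#' @param path output file.
#' @param line_width wrap width for residue lines (default 70).
#' @export
write_fasta <- function(seqs, path, line_width = 70L) {
  if (inherits(seqs, "named_seq")) seqs <- list(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seqs) {
    writeLines(paste0(">", s$id), con)
    n <- nchar(s$residues)
    starts <- seq(1L, n, by = line_width)
    writeLines(substring(s$residues, starts, pmin(starts + line_width - 1L, n)), con)
  }
  invisible(path)
}

#' Read a FASTQ file as a named character vector
#'
#' @param path FASTQ file (uncompressed or gzip).
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- tryCatch(Biostrings::readDNAStringSet(path, format = "fastq"),
                error = function(e) stop("FASTQ I/O error for ", path, ": ",
                                         conditionMessage(e)))
  setNames(as.character(x),
           vapply(strsplit(names(x), "\\s+"), `[`, character(1L), 1L))
}

#' Write reads to FASTQ with constant quality
#'
#' Base qualities are unused downstream, so a constant Q37 string is emitted.
#'
#' @param reads named character vector of read sequences.
#' @param path output file.
#' @param qual_char quality character (default `"F"`, Q37).
#' @export
write_fastq <- function(reads, path, qual_char = "F") {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(reads)) {
    quals <- vapply(nchar(reads), function(n) strrep(qual_char, n), character(1L))
    writeLines(as.vector(rbind(paste0("@", names(reads)), unname(reads),
                               "+", quals)), con)
  }
  invisible(path)
}

FEATURE_TYPES <- c("CDS", "tRNA", "rRNA", "D-loop")

#' Annotation of a (mito)genome
#'
#' @param genome_id genome identifier.
#' @param genome_length genome length in bp.
#' @param features data.frame with columns `name`, `ftype` (one of CDS, tRNA,
#'   rRNA, D-loop), `start`, `end` (0-based half-open), `strand` (`+`/`-`).
#' @return Object of class `annotation`.
#' @export
annotation <- function(genome_id, genome_length, features) {
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  need <- c("name", "ftype", "start", "end", "strand")
  if (!all(need %in% names(features)))
    stop("features must have columns: ", paste(need, collapse = ", "))
  features <- features[, need]
  if (anyDuplicated(features$name))
    stop("duplicate feature names: ",
         paste(unique(features$name[duplicated(features$name)]), collapse = ", "))
  bad_t <- setdiff(unique(features$ftype), FEATURE_TYPES)
  if (length(bad_t)) stop("unknown feature type(s): ", paste(bad_t, collapse = ", "))
  if (!all(features$strand %in% c("+", "-")))
    stop("strand must be '+' or '-' for every feature")
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  ok <- features$start >= 0L & features$start < features$end &
    features$end <= genome_length
  if (!all(ok))
    stop("feature interval out of range [0, ", genome_length, "): ",
         paste(features$name[!ok], collapse = ", "))
  rownames(features) <- NULL
  structure(list(genome_id = genome_id,
                 genome_length = as.integer(genome_length),
                 features = features),
            class = "annotation")
}

#' @export
print.annotation <- function(x, ...) {
  cat(sprintf("<annotation> %s (%d bp): %d features [%s]\n",
              x$genome_id, x$genome_length, nrow(x$features),
              paste(sprintf("%s:%d", names(table(x$features$ftype)),
                            as.integer(table(x$features$ftype))), collapse = " ")))
  invisible(x)
}

#' Read an annotation from TSV
#'
#' Expects tab-separated columns name, type, start, end, strand with 1-based
#' inclusive coordinates (converted to 0-based half-open internally). Lines
#' starting with `#` are comments; a `#genome_id=<id> genome_length=<n>`
#' comment supplies genome metadata, otherwise pass the arguments.
#'
#' @param path TSV file.
#' @param genome_id,genome_length overrides for the genome metadata comment.
#' @return [annotation] object.
#' @export
read_annotation <- function(path, genome_id = NULL, genome_length = NULL) {
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^#\\s*genome_id=", lines, value = TRUE)
  if (length(meta)) {
    if (is.null(genome_id))
      genome_id <- sub(".*genome_id=(\\S+).*", "\\1", meta[1L])
    if (is.null(genome_length))
      genome_length <- as.integer(sub(".*genome_length=(\\d+).*", "\\1", meta[1L]))
  }
  if (is.null(genome_id) || is.null(genome_length))
    stop("genome_id and genome_length must be given (argument or #genome_id= comment)")
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(body) && grepl("^name\\t", body[1L])) body <- body[-1L]
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) < 5L))
    stop("annotation TSV parse error: expected 5 tab-separated columns")
  df <- data.frame(name = vapply(parts, `[`, "", 1L),
                   ftype = vapply(parts, `[`, "", 2L),
                   start = as.integer(vapply(parts, `[`, "", 3L)) - 1L,
                   end = as.integer(vapply(parts, `[`, "", 4L)),
                   strand = vapply(parts, `[`, "", 5L),
                   stringsAsFactors = FALSE)
  annotation(genome_id, genome_length, df)
}

#' Write an annotation as TSV (1-based inclusive coordinates)
#'
#' @param ann [annotation] object.
#' @param path output file.
#' @export
write_annotation <- function(ann, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#genome_id=%s genome_length=%d", ann$genome_id,
                     ann$genome_length), con)
  writeLines("name\ttype\tstart\tend\tstrand", con)
  f <- ann$features
  writeLines(sprintf("%s\t%s\t%d\t%d\t%s", f$name, f$ftype, f$start + 1L,
                     f$end, f$strand), con)
  invisible(path)
}

#' Write a GenBank 5-column feature table (.tbl)
#'
#' Emits the submission dialect: 1-based inclusive coordinates, minus-strand
#' features written with start and end swapped. CDS features carry a `gene`
#' qualifier, RNA features a `product` qualifier, the control region a `note`.
#'
#' @param ann [annotation] object.
#' @param path optional output file; omitted, the text is only returned.
#' @return Character vector of .tbl lines, invisibly if written to `path`.
#' @export
write_feature_table <- function(ann, path = NULL) {
  f <- ann$features
  lines <- c(paste0(">Feature ", ann$genome_id))
  for (i in seq_len(nrow(f))) {
    a <- f$start[i] + 1L
    b <- f$end[i]
    if (f$strand[i] == "-") { tmp <- a; a <- b; b <- tmp }
    key <- f$ftype[i]
    qual <- switch(key, CDS = "gene", `D-loop` = "note", "product")
    lines <- c(lines,
               sprintf("%d\t%d\t%s", a, b, key),
               sprintf("\t\t\t%s\t%s", qual, f$name[i]))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Read a 5-column feature table written by [write_feature_table()]
#'
#' @param path .tbl file.
#' @param genome_length genome length for validation.
#' @return [annotation] object.
#' @export
read_feature_table <- function(path, genome_length) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !startsWith(lines[1L], ">Feature "))
    stop(".tbl parse error at line 1: expected '>Feature <id>'")
  genome_id <- sub("^>Feature ", "", lines[1L])
  coord <- grep("^\\d+\t\\d+\t", lines)
  recs <- lapply(coord, function(i) {
    p <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    q <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1L]]
    a <- as.integer(p[1L]); b <- as.integer(p[2L])
    strand <- if (a <= b) "+" else "-"
    if (strand == "-") { tmp <- a; a <- b; b <- tmp }
    data.frame(name = q[length(q)], ftype = p[3L], start = a - 1L, end = b,
               strand = strand, stringsAsFactors = FALSE)
  })
  annotation(genome_id, genome_length, do.call(rbind, recs))
}
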