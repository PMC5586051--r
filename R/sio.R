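# Sequence I/O and the shared in-memory data model.
#
# Conventions used throughout the package:
#   * sequences are stored in the DNA alphabet (T, never U); conversion to
#     RNA happens only at display and energy-model boundaries
#   * coordinates are 1-based and inclusive at every interface

VALID_ANNOTATIONS <- c("unassigned", "rRNA", "tRNA", "snRNA", "snoRNA",
                       "repeat", "exon", "intron", "known_miRNA",
                       "novel_miRNA")

#' Normalise a nucleotide sequence to the internal DNA alphabet
#'
#' Upper-cases and converts U to T. Characters outside `A,C,G,T,N` raise an
#' error.
#'
#' @param x character vector of sequences.
#' @return character vector, upper-case DNA.
#' @export
normalize_seq <- function(x) {
  x <- chartr("u", "t", toupper(x))
  x <- chartr("U", "T", x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop("invalid nucleotide characters in sequence(s): ",
         paste(utils::head(which(bad), 3L), collapse = ", "))
  }
  x
}

#' Reverse complement (DNA alphabet)
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1L), USE.NAMES = FALSE)
}

#' Construct a small-RNA tag record
#'
#' A `tag_record` is one distinct small-RNA sequence together with its
#' per-library read counts and a sequence-class annotation. It is the unit
#' of all quantification downstream.
#'
#' @param sequence DNA string (U is normalised to T).
#' @param counts named numeric vector of non-negative integer read counts,
#'   names are library ids.
#' @param annotation one of `"unassigned"`, `"rRNA"`, `"tRNA"`, `"snRNA"`,
#'   `"snoRNA"`, `"repeat"`, `"exon"`, `"intron"`, `"known_miRNA"`,
#'   `"novel_miRNA"`.
#' @return object of class `tag_record`.
#' @export
tag_record <- function(sequence, counts, annotation = "unassigned") {
  sequence <- normalize_seq(sequence)
  stopifnot(nchar(sequence) >= 1L)
  counts <- unlist(counts)
  if (is.null(names(counts)) || any(names(counts) == "")) {
    stop("counts must be named by library id")
  }
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers")
  }
  if (sum(counts) < 1) stop("total count across libraries must be >= 1")
  annotation <- match.arg(annotation, VALID_ANNOTATIONS)
  structure(list(sequence = sequence, counts = counts,
                 annotation = annotation),
            class = "tag_record")
}

#' @export
print.tag_record <- function(x, ...) {
  cat(sprintf("<tag %s (%d nt) total=%d [%s]>\n", x$sequence,
              nchar(x$sequence), sum(x$counts), x$annotation))
  invisible(x)
}

#' Read a FASTA file
#'
#' Sequences are upper-cased and U is normalised to T. Duplicate ids are
#' made unique by appending `.1`, `.2`, ... with a warning.
#'
#' @param path file path (plain or gzipped).
#' @return named character vector of sequences (names are record ids).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  keep <- !grepl("^\\s*$", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(stats::setNames(character(0), character(0)))
  hdr <- startsWith(lines, ">")
  if (!hdr[1L]) {
    stop("malformed FASTA at line ", lineno[1L], ": expected '>' header")
  }
  rec <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  seqs <- vapply(split(lines[!hdr], rec[!hdr]), paste, character(1L),
                 collapse = "")
  out <- stats::setNames(rep("", sum(hdr)), ids)
  out[unique(rec[!hdr])] <- seqs
  empty <- !nzchar(out)
  if (any(empty)) {
    stop("malformed FASTA at line ", lineno[hdr][empty][1L],
         ": record '", ids[empty][1L], "' has no sequence")
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    warning("duplicate FASTA ids made unique: ",
            paste(utils::head(dup, 5L), collapse = ", "))
    names(out) <- make.unique(ids, sep = ".")
  }
  vapply(out, normalize_seq, character(1L))
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file path.
#' @param width line-wrap width; `Inf` writes one line per sequence.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = Inf) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    if (is.finite(width) && nchar(s) > width) {
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
                 con)
    } else {
      writeLines(s, con)
    }
  }
  invisible(path)
}

#' Read collapsed (dereplicated) small-RNA FASTA
#'
#' Headers must follow the `id_xCOUNT` dialect, e.g. `>t1_x5`. Records with
#' identical sequences are merged by summing their counts.
#'
#' @param path file path.
#' @param library_id library label used for the single count column.
#' @return list of [tag_record] objects, one per distinct sequence.
#' @export
read_collapsed_fasta <- function(path, library_id = "lib1") {
  seqs <- read_fasta(path)
  if (length(seqs) == 0L) return(list())
  m <- regmatches(names(seqs), regexec("_x([0-9]+)$", names(seqs)))
  counts <- vapply(m, function(g) {
    if (length(g) < 2L) NA_real_ else as.numeric(g[2L])
  }, numeric(1L))
  if (anyNA(counts)) {
    stop("collapsed-FASTA header without '_x<count>' suffix: ",
         names(seqs)[which(is.na(counts))[1L]])
  }
  if (any(counts < 1)) stop("collapsed-FASTA counts must be >= 1")
  agg <- tapply(counts, seqs, sum)
  # deterministic order: by sequence
  agg <- agg[order(names(agg))]
  lapply(seq_along(agg), function(i) {
    tag_record(names(agg)[i], stats::setNames(unname(agg[i]), library_id))
  })
}

#' Write tag records as collapsed FASTA
#'
#' Counts are summed across libraries; ids are `t<i>_x<count>` with records
#' ordered by sequence, so output is deterministic.
#'
#' @param tags list of [tag_record].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_collapsed_fasta <- function(tags, path) {
  seqs <- vapply(tags, function(t) t$sequence, character(1L))
  tot <- vapply(tags, function(t) sum(t$counts), numeric(1L))
  agg <- tapply(tot, seqs, sum)
  agg <- agg[order(names(agg))]
  ids <- sprintf("t%d_x%d", seq_along(agg), as.integer(agg))
  write_fasta(stats::setNames(names(agg), ids), path)
}

#' Read a FASTQ file
#'
#' Minimal 4-line-record FASTQ reader; qualities are returned as Phred+33
#' integer scores.
#'
#' @param path file path.
#' @return data.frame with columns `id`, `sequence`, `quality` (list column
#'   of integer vectors).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ: ", length(lines), " lines is not a multiple of 4")
  }
  n <- length(lines) %/% 4L
  idx <- seq_len(n)
  ids <- lines[4L * idx - 3L]
  if (!all(startsWith(ids, "@"))) {
    bad <- which(!startsWith(ids, "@"))[1L]
    stop("malformed FASTQ at line ", 4L * bad - 3L, ": expected '@' header")
  }
  seqs <- toupper(lines[4L * idx - 2L])
  quals <- lines[4L * idx]
  if (any(nchar(seqs) != nchar(quals))) {
    bad <- which(nchar(seqs) != nchar(quals))[1L]
    stop("malformed FASTQ at line ", 4L * bad, ": quality length mismatch")
  }
  data.frame(
    id = sub("^@", "", sub("\\s.*$", "", ids)),
    sequence = chartr("U", "T", seqs),
    quality = I(lapply(quals, function(q) utf8ToInt(q) - 33L)),
    stringsAsFactors = FALSE
  )
}

#' Build a count matrix from tag records
#'
#' @param tags list of [tag_record].
#' @param library_totals optional named vector of total clean reads per
#'   library; defaults to the column sums.
#' @return object of class `count_matrix`: an integer matrix
#'   (tags x libraries, rownames are sequences) with attribute
#'   `library_totals`.
#' @export
count_matrix <- function(tags, library_totals = NULL) {
  libs <- sort(unique(unlist(lapply(tags, function(t) names(t$counts)))))
  m <- matrix(0L, nrow = length(tags), ncol = length(libs),
              dimnames = list(vapply(tags, function(t) t$sequence,
                                     character(1L)), libs))
  for (i in seq_along(tags)) {
    m[i, names(tags[[i]]$counts)] <- as.integer(tags[[i]]$counts)
  }
  if (is.null(library_totals)) library_totals <- colSums(m)
  if (any(library_totals[libs] < colSums(m))) {
    stop("library_totals must be >= column sums")
  }
  structure(m, library_totals = library_totals[libs],
            class = c("count_matrix", class(m)))
}

#' Read / write a tag-by-library count table (TSV)
#'
#' First column `sequence`, one column per library; a trailing comment line
#' `# library_totals:` preserves totals.
#'
#' @param path file path.
#' @return a `count_matrix`.
#' @export
read_count_table <- function(path) {
  lines <- readLines(path)
  tot_line <- grep("^#\\s*library_totals:", lines, value = TRUE)
  tab <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                           stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- tab[[1L]]
  totals <- colSums(m)
  if (length(tot_line)) {
    kv <- strsplit(sub("^#\\s*library_totals:\\s*", "", tot_line[1L]),
                   ",", fixed = TRUE)[[1L]]
    kv <- strsplit(trimws(kv), "=", fixed = TRUE)
    totals <- stats::setNames(vapply(kv, function(p) as.numeric(p[2L]),
                                     numeric(1L)),
                              vapply(kv, `[`, character(1L), 1L))
  }
  structure(m, library_totals = totals[colnames(m)],
            class = c("count_matrix", class(m)))
}

#' @rdname read_count_table
#' @param mat a `count_matrix`.
#' @export
write_count_table <- function(mat, path) {
  tab <- data.frame(sequence = rownames(mat), unclass(mat)[, , drop = FALSE],
                    check.names = FALSE, stringsAsFactors = FALSE)
  tab <- tab[order(tab$sequence), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  tot <- attr(mat, "library_totals")
  writeLines(paste0("# library_totals: ",
                    paste(sprintf("%s=%d", names(tot), as.integer(tot)),
                          collapse = ",")), con)
  invisible(path)
}

#' Read a gene-to-term assignment table
#'
#' Two tab-separated columns, `gene<TAB>term`, one assignment per line.
#'
#' @param path file path.
#' @return named list mapping gene id to character vector of term ids.
#' @export
read_term_table <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("gene", "term"))
  split(tab$term, tab$gene)
}

SITE_REPORT_COLS <- c("mirna_id", "transcript_id", "start", "end",
                      "expected_cut", "mismatch_total", "mismatch_5p_1_12",
                      "energy", "energy_ratio", "validated", "category",
                      "peak_position", "peak_count", "other_peaks")

#' Write a target-site / degradome report
#'
#' Tab-separated, one row per site, deterministically ordered by
#' (transcript id, start, miRNA id). Columns mirror the binding-site and
#' cleavage-site layout of published degradome tables (1-based inclusive
#' coordinates on the transcript/CDS).
#'
#' @param sites data.frame of sites as produced by [scan_transcript()] /
#'   [report_validated_pairs()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_site_report <- function(sites, path) {
  cols <- intersect(SITE_REPORT_COLS, names(sites))
  if (nrow(sites)) {
    stopifnot(all(sites$start <= sites$end),
              all(sites$expected_cut >= sites$start),
              all(sites$expected_cut <= sites$end))
    sites <- sites[order(sites$transcript_id, sites$start, sites$mirna_id),
                   cols, drop = FALSE]
  } else {
    sites <- sites[, cols, drop = FALSE]
  }
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read degradome 5'-tag libraries
#'
#' Accepts either a collapsed FASTA (`id_xN` headers) or a two-column TSV
#' (`sequence<TAB>count`).
#'
#' @param path file path.
#' @return data.frame with columns `sequence`, `count`, merged over
#'   duplicate sequences.
#' @export
read_degradome_tags <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) && startsWith(first, ">")) {
    tags <- read_collapsed_fasta(path)
    df <- data.frame(
      sequence = vapply(tags, function(t) t$sequence, character(1L)),
      count = vapply(tags, function(t) sum(t$counts), numeric(1L)),
      stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                            col.names = c("sequence", "count"))
    df$sequence <- normalize_seq(df$sequence)
    agg <- tapply(df$count, df$sequence, sum)
    df <- data.frame(sequence = names(agg), count = unname(agg),
                     stringsAsFactors = FALSE)
  }
  df[order(df$sequence), , drop = FALSE]
}
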