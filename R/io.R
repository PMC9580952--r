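# Readers/writers for on-disk artifacts (annotated FASTA dialect, zOTU
# table, mapping files, config) and the alignment coverage/region
# utilities. All writers use a fixed ordering and Unix newlines so reruns
# are byte-identical.
#
# Header dialect (SINTAX-style): `>seqid;size=N;tax=d:...,p:...,g:...`
# (semicolon-separated key fields; absent ranks omitted; size defaults 1).

#' Read an annotated FASTA file
#'
#' Parses the taxonomy header dialect: the first `;`-separated token is the
#' sequence id, `size=` the total abundance (default 1) and `tax=` the
#' taxonomy (see [parse_taxonomy()]). Sequences are uppercased; characters
#' outside the IUPAC nucleotide alphabet and duplicate ids are errors.
#'
#' @param path FASTA file path.
#' @return zOTU data frame: columns `id`, `seq`, `size` and the seven rank
#'   columns of [tax_ranks()].
#' @export
read_annotated_fasta <- function(path) {
  set <- withCallingHandlers(
    tryCatch(Biostrings::readDNAStringSet(path),
             error = function(e) stop_ticlust("not a valid FASTA file: ",
                                              path, " (", conditionMessage(e), ")")),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        stop_ticlust("illegal (non-IUPAC) characters in FASTA: ", path)
      invokeRestart("muffleWarning")
    })
  headers <- names(set)
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTMRWSYKVHDBN]", seqs)
  if (any(bad))
    stop_ticlust("illegal (non-IUPAC) characters in sequence of record: ",
                 strsplit(headers[bad][1L], ";", fixed = TRUE)[[1L]][1L])
  fields <- strsplit(headers, ";", fixed = TRUE)
  id <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(id))
    stop_ticlust("duplicate sequence id in FASTA: ", id[duplicated(id)][1L])
  size <- rep(1L, length(id))
  tax <- matrix(NA_character_, nrow = length(id), ncol = 7L,
                dimnames = list(NULL, .RANKS))
  for (i in seq_along(fields)) {
    for (f in fields[[i]][-1L]) {
      if (grepl("^size=", f)) {
        v <- suppressWarnings(as.integer(sub("^size=", "", f)))
        if (is.na(v) || v < 1L) stop_ticlust("invalid size field in header: ", headers[i])
        size[i] <- v
      } else if (grepl("^tax=", f)) {
        tax[i, ] <- parse_taxonomy(f)
      }
    }
  }
  out <- data.frame(id = id, seq = unname(seqs), size = size,
                    as.data.frame(tax, stringsAsFactors = FALSE),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a zOTU data frame as annotated FASTA
#'
#' Inverse of [read_annotated_fasta()]; records are written sorted by id so
#' output is byte-stable regardless of input row order.
#'
#' @param x zOTU data frame.
#' @param path Output file path.
#' @param sort Sort records by id (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_annotated_fasta <- function(x, path, sort = TRUE) {
  if (sort) x <- x[order(x$id, method = "radix"), , drop = FALSE]
  tax_str <- vapply(seq_len(nrow(x)), function(i)
    format_taxonomy(x[i, .RANKS]), character(1))
  hdr <- paste0(x$id, ";size=", x$size,
                ifelse(nzchar(tax_str), paste0(";tax=", tax_str), ""))
  set <- Biostrings::DNAStringSet(x$seq)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Write the full TIC result to a directory
#'
#' Produces: `zotus_annotated.fasta` (sequences with their updated full
#' taxonomic paths, including novel names), `zotu_table.tsv` (rows =
#' zOTUs, one column per sample, final column the taxonomy string),
#' `sotu_to_gotu.tsv` and `gotu_to_fotu.tsv` (two-column mappings).
#' Consistency is verified before any file is written; output is
#' byte-stable across reruns.
#'
#' @param result A `tic_result` from [run_tic()].
#' @param x The input zOTU data frame.
#' @param counts Optional abundance matrix (rows = sequence ids); when
#'   absent, the `size` column is written as a single-sample table.
#' @param outdir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_result <- function(result, x, counts = NULL, outdir) {
  stopifnot(inherits(result, "tic_result"))
  if (!setequal(names(result$seq_to_sotu), x$id))
    stop_ticlust("result does not cover the input sequence ids")
  if (!all(result$seq_to_sotu %in% result$sotus$id) ||
      !all(result$sotu_to_gotu %in% result$gotus$id) ||
      !all(result$gotu_to_fotu %in% result$fotus$id))
    stop_ticlust("inconsistent cluster mappings in result")
  if (!is.null(counts) && !setequal(rownames(counts), x$id))
    stop_ticlust("'counts' rows do not match the input sequence ids")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  upd <- result$updated_taxonomy  # already sorted by id
  seqs <- x[match(upd$id, x$id), c("id", "seq", "size")]
  fa <- cbind(seqs, upd[, .RANKS])
  f1 <- file.path(outdir, "zotus_annotated.fasta")
  write_annotated_fasta(fa, f1, sort = FALSE)

  tax_str <- vapply(seq_len(nrow(upd)), function(i)
    format_taxonomy(upd[i, .RANKS]), character(1))
  tab <- if (is.null(counts)) {
    data.frame(zotu = upd$id, size = seqs$size, taxonomy = tax_str,
               stringsAsFactors = FALSE)
  } else {
    cbind(data.frame(zotu = upd$id, stringsAsFactors = FALSE),
          as.data.frame(counts[upd$id, , drop = FALSE]),
          data.frame(taxonomy = tax_str, stringsAsFactors = FALSE))
  }
  f2 <- file.path(outdir, "zotu_table.tsv")
  write.table(tab, f2, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")

  f3 <- file.path(outdir, "sotu_to_gotu.tsv")
  write.table(data.frame(sotu = names(result$sotu_to_gotu),
                         gotu = unname(result$sotu_to_gotu)),
              f3, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  f4 <- file.path(outdir, "gotu_to_fotu.tsv")
  write.table(data.frame(gotu = names(result$gotu_to_fotu),
                         fotu = unname(result$gotu_to_fotu)),
              f4, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(c(f1, f2, f3, f4))
}

read_alignment <- function(path) {
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop_ticlust("not a valid FASTA file: ",
                                                   path, " (", conditionMessage(e), ")"))
  w <- Biostrings::width(set)
  if (length(unique(w)) > 1L)
    stop_ticlust("ragged alignment: records have differing lengths")
  set
}

#' Column coverage of a multiple sequence alignment
#'
#' Counts the non-gap characters (`-` and `.` are gaps) in each alignment
#' column, the profile used to choose the best-covered amplicon region.
#'
#' @param aligned_fasta Path to an aligned multi-FASTA (equal record
#'   lengths).
#' @return Integer vector of per-column non-gap counts (length = alignment
#'   length), with attribute `n_seq`.
#' @export
coverage_profile <- function(aligned_fasta) {
  set <- read_alignment(aligned_fasta)
  m <- do.call(rbind, strsplit(as.character(set), ""))
  prof <- colSums(matrix(!(m %in% c("-", ".")), nrow = nrow(m)))
  structure(as.integer(prof), n_seq = length(set))
}

#' Trim an alignment to a column region
#'
#' Slices alignment columns `start..end` (1-based, inclusive), removes gap
#' characters, and discards sequences left with fewer than `min_bases`
#' bases. Optionally dereplicates identical post-trim sequences (sizes
#' summed, lexicographically smallest id kept).
#'
#' @param aligned_fasta Path to an aligned multi-FASTA; headers may use the
#'   annotation dialect.
#' @param start,end Column bounds, `1 <= start <= end <= alignment length`.
#' @param min_bases Minimum number of remaining bases (default 1).
#' @param dereplicate Merge identical trimmed sequences (default `FALSE`).
#' @return zOTU data frame of the kept sequences, with attributes `kept`
#'   and `discarded` (record counts).
#' @export
trim_to_region <- function(aligned_fasta, start, end, min_bases = 1L,
                           dereplicate = FALSE) {
  set <- read_alignment(aligned_fasta)
  alen <- unique(Biostrings::width(set))
  if (start < 1L || end > alen || start > end)
    stop_ticlust("region bounds must satisfy 1 <= start <= end <= ", alen)
  sub <- substr(toupper(as.character(set)), start, end)
  sub <- gsub("[-.]", "", sub)
  headers <- names(set)
  fields <- strsplit(headers, ";", fixed = TRUE)
  id <- vapply(fields, `[[`, character(1), 1L)
  size <- rep(1L, length(id))
  tax <- matrix(NA_character_, nrow = length(id), ncol = 7L,
                dimnames = list(NULL, .RANKS))
  for (i in seq_along(fields)) {
    for (f in fields[[i]][-1L]) {
      if (grepl("^size=", f)) size[i] <- as.integer(sub("^size=", "", f))
      else if (grepl("^tax=", f)) tax[i, ] <- parse_taxonomy(f)
    }
  }
  keep <- nchar(sub) >= min_bases
  out <- data.frame(id = id[keep], seq = unname(sub[keep]), size = size[keep],
                    as.data.frame(tax[keep, , drop = FALSE], stringsAsFactors = FALSE),
                    stringsAsFactors = FALSE)
  if (dereplicate && nrow(out) > 0L) {
    out <- out[order(out$id, method = "radix"), , drop = FALSE]
    grp <- split(seq_len(nrow(out)), out$seq)
    rows <- lapply(grp, function(ix) {
      r <- out[ix[1L], , drop = FALSE]  # smallest id (sorted)
      r$size <- sum(out$size[ix])
      r
    })
    out <- do.call(rbind, rows)
    out <- out[order(out$id, method = "radix"), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "kept") <- sum(keep)
  attr(out, "discarded") <- sum(!keep)
  out
}

#' Read a key=value config file
#'
#' Plain-text configuration: one `key=value` pair per line; blank lines and
#' lines starting with `#` are ignored.
#'
#' @param path Config file path.
#' @return Named character vector.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(setNames(character(0), character(0)))
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) stop_ticlust("malformed config line: ", lines[bad][1L])
  setNames(vapply(kv, `[[`, character(1), 3L),
           trimws(vapply(kv, `[[`, character(1), 2L)))
}

#' Write the planted truth of a synthetic benchmark as TSV
#'
#' @param truth A `synthetic_truth`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  write.table(truth$taxonomy, path, sep = "\t", quote = FALSE,
              row.names = FALSE, eol = "\n")
  invisible(path)
}
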