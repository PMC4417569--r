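#' Read a multi-FASTA file into a read set
#'
#' Sequences are uppercased; reads containing characters outside
#' \{A,C,G,T\} cannot be 2-bit encoded and are skipped with a warning
#' (`strict = TRUE` turns the warning into an error).
#'
#' @param path path to a (multi-)FASTA file.
#' @param strict error instead of warn-and-skip on non-ACGT reads.
#' @return A [read_set()] in file order, headers preserved.
#' @export
read_fasta <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(ss))
  bad <- !grepl("^[ACGT]+$", seqs)
  if (any(bad)) {
    msg <- sprintf(
      "%d read(s) contain non-ACGT characters (or are empty): %s",
      sum(bad), paste(head(names(ss)[bad], 5L), collapse = ", "))
    if (strict) stop(msg)
    warning(msg, "; skipping them")
    seqs <- seqs[!bad]
    if (length(seqs) == 0L) stop("no valid ACGT reads left in ", path)
  }
  read_set(seqs, headers = names(ss)[!bad])
}

#' Write a read set as FASTA
#'
#' @param rs a [read_set()].
#' @param path output path.
#' @export
write_fasta <- function(rs, path) {
  stopifnot(inherits(rs, "read_set"))
  x <- Biostrings::DNAStringSet(setNames(rs$reads$sequence, rs$reads$header))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write overlap records as TSV
#'
#' One record per line, `query<TAB>target<TAB>overlap_length`, preceded by a
#' `#` header line recording the mode, minimum length, k, n and total match
#' count.  Mode `none` writes the header only.  By default reads are named
#' by their FASTA headers; `raw_ids = TRUE` writes internal lexicographic
#' ids instead.
#'
#' @param result an `overlap_result`.
#' @param trie the `cpt_trie` the result came from (for header lookup).
#' @param path output path.
#' @param raw_ids write internal ids instead of headers.
#' @return `path`, invisibly.
#' @export
write_overlaps <- function(result, trie, path, raw_ids = FALSE) {
  stopifnot(inherits(result, "overlap_result"), inherits(trie, "cpt_trie"))
  hdr <- sprintf("# mode=%s min_len=%d k=%d n=%.0f matches=%.0f",
                 result$mode, result$min_len, result$k, result$n,
                 result$counts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (result$mode != "none" && nrow(result$records)) {
    r <- result$records
    if (raw_ids) {
      q <- r$query_id
      t <- r$target_id
    } else {
      headers <- trie$read_set$reads$header
      q <- headers[match(r$query_orig, trie$read_set$reads$original_index)]
      t <- headers[match(r$target_orig, trie$read_set$reads$original_index)]
    }
    writeLines(paste(q, t, r$length, sep = "\t"), con)
  }
  invisible(path)
}

#' Write a containment-removal report
#'
#' TSV of `read_header<TAB>reason` for every removed read.
#'
#' @param mask a `removed_mask`.
#' @param rs the [read_set()] the mask refers to.
#' @param path output path.
#' @export
write_removal_report <- function(mask, rs, path) {
  stopifnot(inherits(mask, "removed_mask"), inherits(rs, "read_set"))
  idx <- which(mask$bits)
  hdr <- rs$reads$header[match(idx, rs$reads$original_index)]
  writeLines(paste(hdr, mask$reason[idx], sep = "\t"), path)
  invisible(path)
}

#' Write a work-plan dump
#'
#' TSV of `read_index<TAB>worker`.
#'
#' @param plan a `work_plan`.
#' @param path output path.
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "work_plan"))
  writeLines(paste(seq_along(plan$r), plan$r, sep = "\t"), path)
  invisible(path)
}
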