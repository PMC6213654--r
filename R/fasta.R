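# FASTA input/output with strict validation.
#
# All sequences are held internally on the DNA alphabet: RNA input (U/u) is
# normalized to T on read, lowercase is uppercased, and every parse error
# names the offending line. Records are plain data frames so the rest of the
# pipeline is free of file-format concerns.

IUPAC_STRICT <- c("A", "C", "G", "T")

#' Read a FASTA file into a record table
#'
#' Parses a (possibly gzipped) FASTA file into a data frame of sequence
#' records, normalizing the RNA alphabet (U -> T) and lowercase to
#' uppercase. Duplicate record identifiers and non-nucleotide characters
#' are errors that name the offending line.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"dna"` or `"rna"`; both are normalized to DNA
#'   internally, the value only documents the expected input dialect.
#' @param allow_n Logical; whether ambiguity code `N` is tolerated
#'   (transcript sequences) or rejected (miRNA and tag sequences, where
#'   perfect-match semantics must be unambiguous).
#' @return A data frame with columns `id`, `sequence` and `length` (nt),
#'   in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">m1", "UGGACGU"), fa)
#' read_fasta(fa)$sequence  # "TGGACGT"
#' @export
read_fasta <- function(path, alphabet = c("dna", "rna"), allow_n = TRUE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  ids <- character(0)
  seqs <- character(0)
  cur_id <- NULL
  cur_chunks <- character(0)
  cur_line <- 0L
  flush <- function() {
    if (is.null(cur_id)) return()
    s <- paste(cur_chunks, collapse = "")
    if (!nzchar(s)) stopf("empty sequence for record '%s' (line %d)",
                          cur_id, cur_line)
    ids[[length(ids) + 1L]] <<- cur_id
    seqs[[length(seqs) + 1L]] <<- s
  }
  ok <- if (allow_n) "ACGTN" else "ACGT"
  pat <- sprintf("^[%s]*$", ok)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (startsWith(ln, ">")) {
      flush()
      hdr <- trimws(sub("^>", "", ln))
      # record id = first whitespace-delimited token
      id <- strsplit(hdr, "[ \t]+")[[1]][1]
      if (is.na(id) || !nzchar(id)) {
        stopf("malformed FASTA header at line %d of %s", i, path)
      }
      cur_id <- id
      cur_chunks <- character(0)
      cur_line <- i
    } else {
      if (is.null(cur_id)) {
        if (!nzchar(trimws(ln))) next
        stopf("sequence data before any header at line %d of %s", i, path)
      }
      s <- toupper(chartr("Uu", "Tt", trimws(ln)))
      if (!grepl(pat, s)) {
        stopf("non-nucleotide character at line %d of %s", i, path)
      }
      cur_chunks[[length(cur_chunks) + 1L]] <- s
    }
  }
  flush()
  if (anyDuplicated(ids)) {
    stopf("duplicate FASTA record id '%s' in %s",
          ids[duplicated(ids)][1], path)
  }
  data.frame(id = ids, sequence = seqs, length = nchar(seqs),
             stringsAsFactors = FALSE)
}

#' Write sequence records to FASTA
#'
#' Inverse of [read_fasta()] on the internal DNA alphabet.
#'
#' @param records Data frame with columns `id` and `sequence`.
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con)
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con)
  }
  invisible(path)
}

#' Read a transcriptome FASTA
#'
#' Transcript sequences tolerate `N` (positions containing `N` never match
#' any tag or miRNA base).
#'
#' @inheritParams read_fasta
#' @return Data frame of transcript records (`id`, `sequence`, `length`).
#' @export
read_transcript_fasta <- function(path, alphabet = "dna") {
  read_fasta(path, alphabet, allow_n = TRUE)
}

#' Read mature miRNA sequences
#'
#' Mature miRNA records outside the canonical plant length range 18--25 nt
#' raise a warning and are kept; records shorter than 15 or longer than
#' 30 nt are rejected. Ambiguity codes are rejected.
#'
#' @inheritParams read_fasta
#' @return Data frame of miRNA records (`id`, `sequence`, `length`).
#' @export
read_mirna_fasta <- function(path, alphabet = "rna") {
  rec <- read_fasta(path, alphabet, allow_n = FALSE)
  bad <- rec$length < 15L | rec$length > 30L
  if (any(bad)) {
    stopf("miRNA '%s' has length %d nt (outside 15-30)",
          rec$id[bad][1], rec$length[bad][1])
  }
  odd <- rec$length < 18L | rec$length > 25L
  if (any(odd)) {
    warning(sprintf("%d miRNA(s) outside the canonical 18-25 nt range (kept)",
                    sum(odd)), call. = FALSE)
  }
  rec
}

#' Read degradome 5' tags with read counts
#'
#' Degradome libraries are usually distributed collapsed: one FASTA entry
#' per distinct sequence with the read count in the header suffix `_xN`
#' (e.g. `>t1_x5`). Identical sequences are merged by summing their counts,
#' so total read count is conserved.
#'
#' @param path Path to a tag FASTA file.
#' @param count_convention `"suffix_xN"` (default; count parsed from the
#'   `_xN` header suffix) or `"all_ones"` (every entry counts one read).
#' @param min_len,max_len Permitted tag lengths in nt (degradome protocols
#'   sequence short 5' fragments; the default window is 15--36 nt).
#' @return A data frame of tag records with columns `sequence` and `count`,
#'   one row per distinct sequence, in order of first appearance.
#' @export
read_tag_fasta <- function(path, count_convention = c("suffix_xN", "all_ones"),
                           min_len = 15L, max_len = 36L) {
  count_convention <- match.arg(count_convention)
  rec <- read_fasta(path, "dna", allow_n = FALSE)
  if (!nrow(rec)) {
    return(data.frame(sequence = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  if (count_convention == "suffix_xN") {
    m <- regmatches(rec$id, regexpr("_x[0-9]+$", rec$id))
    if (length(m) != nrow(rec) || any(!nzchar(m))) {
      bad <- which(!grepl("_x[0-9]+$", rec$id))[1]
      stopf("tag header '%s' lacks the _x<count> suffix", rec$id[bad])
    }
    counts <- as.integer(sub("^_x", "", m))
  } else {
    counts <- rep(1L, nrow(rec))
  }
  if (any(counts < 1L)) stopf("tag read counts must be >= 1")
  bad <- rec$length < min_len | rec$length > max_len
  if (any(bad)) {
    stopf("tag '%s' has length %d nt (outside %d-%d)",
          rec$id[bad][1], rec$length[bad][1], min_len, max_len)
  }
  agg <- rowsum(counts, group = rec$sequence, reorder = FALSE)
  data.frame(sequence = rownames(agg), count = as.integer(agg[, 1]),
             stringsAsFactors = FALSE)
}
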