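# Count-matrix container and TSV round-trip.
#
# A count matrix is an integer feature x sample table with unique row and
# column identifiers; transcript matrices additionally carry feature
# lengths (nt) for RPKM normalization.

#' Construct a count matrix
#'
#' @param counts Integer matrix (features x samples) with unique, non-empty
#'   dimnames; all entries must be non-negative integers.
#' @param feature_lengths Optional named numeric vector of feature lengths
#'   in nt (required later for RPKM normalization); names must cover all
#'   features.
#' @return An object of class `count_matrix` (a list with elements
#'   `counts` and `feature_lengths`).
#' @export
count_matrix <- function(counts, feature_lengths = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stopf("count matrix needs feature and sample ids as dimnames")
  }
  if (anyDuplicated(rownames(counts))) stopf("duplicate feature ids")
  if (anyDuplicated(colnames(counts))) stopf("duplicate sample ids")
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts))) {
    stopf("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  if (!is.null(feature_lengths)) {
    miss <- setdiff(rownames(counts), names(feature_lengths))
    if (length(miss)) {
      stopf("feature_lengths missing for %d feature(s), e.g. '%s'",
            length(miss), miss[1])
    }
    feature_lengths <- feature_lengths[rownames(counts)]
    if (any(feature_lengths <= 0)) stopf("feature lengths must be > 0")
  }
  structure(list(counts = counts, feature_lengths = feature_lengths),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d features x %d samples%s\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$feature_lengths)) "" else " (with lengths)"))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a count matrix from TSV
#'
#' Expects a tab-separated table whose header row holds the sample ids
#' (with or without a corner label over the feature-id column) and whose
#' first column holds feature ids. Every cell must be a plain non-negative
#' integer; violations are reported with their coordinates.
#'
#' @param path Path to a TSV file.
#' @param feature_lengths Optional named vector of feature lengths to attach.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, feature_lengths = NULL) {
  if (!file.exists(path)) stopf("count matrix file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stopf("count matrix %s has no data rows", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  hdr <- cells[[1]]
  body_width <- length(cells[[2]])
  if (length(hdr) == body_width) {
    samples <- hdr[-1]            # corner label present over feature column
  } else if (length(hdr) == body_width - 1L) {
    samples <- hdr                # headerless feature-id column
  } else {
    stopf("header of %s has %d fields but data rows have %d",
          path, length(hdr), body_width)
  }
  if (anyDuplicated(samples)) stopf("duplicate sample id in %s", path)
  n <- length(lines) - 1L
  ids <- character(n)
  mat <- matrix(0L, nrow = n, ncol = length(samples))
  for (i in seq_len(n)) {
    row <- cells[[i + 1L]]
    if (length(row) != body_width) {
      stopf("ragged row %d of %s (%d fields, expected %d)",
            i + 1L, path, length(row), body_width)
    }
    ids[i] <- row[1]
    vals <- row[-1]
    bad <- !grepl("^[0-9]+$", vals)
    if (any(bad)) {
      j <- which(bad)[1]
      stopf("non-integer cell '%s' at row %d, column %d of %s",
            vals[j], i + 1L, j + 1L, path)
    }
    mat[i, ] <- as.integer(vals)
  }
  if (anyDuplicated(ids)) {
    stopf("duplicate feature id '%s' in %s", ids[duplicated(ids)][1], path)
  }
  dimnames(mat) <- list(ids, samples)
  count_matrix(mat, feature_lengths)
}

#' Write a count matrix to TSV
#'
#' Bit-identical round-trip partner of [read_count_matrix()]; the corner
#' cell is labelled `feature_id`.
#'
#' @param cm A [count_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(cm, path) {
  df <- data.frame(feature_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a gene annotation table
#'
#' Left-outer annotation source joined onto integrated pair tables. The
#' TSV must have columns `gene_id`, `description`, `go` and `kegg`; `go`
#' holds `;`-separated GO terms and `kegg` holds `;`-separated
#' `koNNNNN:Pathway name` entries. Pathway ids are validated against the
#' `ko\\d{5}` form.
#'
#' @param path Path to the annotation TSV.
#' @return Data frame with columns `gene_id`, `description`, `go_terms`
#'   and `kegg_pathways` (the latter two are list-columns).
#' @export
read_annotation_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          check.names = FALSE)
  need <- c("gene_id", "description", "go", "kegg")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("annotation table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  split_semi <- function(x) {
    lapply(x, function(s) {
      if (is.na(s) || !nzchar(s)) character(0)
      else trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    })
  }
  kegg <- lapply(split_semi(df$kegg), function(entries) {
    if (!length(entries)) {
      return(data.frame(pathway_id = character(0),
                        pathway_name = character(0)))
    }
    id <- sub(":.*$", "", entries)
    nm <- ifelse(grepl(":", entries), sub("^[^:]*:", "", entries), "")
    bad <- !grepl("^ko[0-9]{5}$", id)
    if (any(bad)) stopf("malformed KEGG pathway id '%s'", id[bad][1])
    data.frame(pathway_id = id, pathway_name = nm,
               stringsAsFactors = FALSE)
  })
  data.frame(gene_id = df$gene_id,
             description = df$description,
             go_terms = I(split_semi(df$go)),
             kegg_pathways = I(kegg),
             stringsAsFactors = FALSE)
}
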