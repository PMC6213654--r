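# Degradome (PARE) tag mapping, cleavage-site category classification and
# duplex validation.
#
# Tags are mapped by exact, full-length, sense-strand string match only;
# a multi-mapping tag contributes its full read count at the 5' coordinate
# of every occurrence. Per-position abundances stay on the raw-count scale
# throughout: the five-category key is defined on raw reads.

#' Map degradome tags onto a transcriptome
#'
#' Builds one 5'-end read-depth profile per transcript. A tag contributes
#' its count to `depth[p]` at the 5' coordinate `p` of every exact
#' full-length occurrence in every transcript; tags matching nowhere are
#' counted as unmapped.
#'
#' @param tags Data frame of tag records (`sequence`, `count`), e.g. from
#'   [read_tag_fasta()].
#' @param transcripts Data frame of transcript records (`id`, `sequence`).
#' @return A list with `profiles` (named list of per-transcript profiles:
#'   `transcript_id`, integer `depth` of transcript length, `total_reads`,
#'   `occupied_positions`) and `stats` (`total_reads`, `mapped_reads`,
#'   `unmapped_reads` counting each read once; `assigned_reads` summing
#'   multi-mapped contributions; `transcripts_with_reads`).
#' @export
map_tags <- function(tags, transcripts) {
  subject <- Biostrings::DNAStringSet(setNames(transcripts$sequence,
                                               transcripts$id))
  depth <- lapply(transcripts$length, function(n) integer(n))
  names(depth) <- transcripts$id
  mapped <- 0L; unmapped <- 0L; assigned <- 0L
  for (i in seq_len(nrow(tags))) {
    hits <- Biostrings::vmatchPattern(tags$sequence[i], subject)
    starts <- Biostrings::startIndex(hits)
    hit_any <- FALSE
    for (j in seq_along(starts)) {
      st <- starts[[j]]
      if (is.null(st) || !length(st)) next
      hit_any <- TRUE
      tx <- transcripts$id[j]
      for (p in st) depth[[tx]][p] <- depth[[tx]][p] + tags$count[i]
      assigned <- assigned + tags$count[i] * length(st)
    }
    if (hit_any) mapped <- mapped + tags$count[i]
    else unmapped <- unmapped + tags$count[i]
  }
  profiles <- lapply(transcripts$id, function(tx) {
    d <- depth[[tx]]
    structure(list(transcript_id = tx, depth = d,
                   total_reads = sum(d),
                   occupied_positions = which(d > 0L)),
              class = "degradome_profile")
  })
  names(profiles) <- transcripts$id
  stats <- list(total_reads = mapped + unmapped, mapped_reads = mapped,
                unmapped_reads = unmapped, assigned_reads = assigned,
                transcripts_with_reads =
                  sum(vapply(profiles, function(p) p$total_reads > 0L,
                             logical(1))))
  list(profiles = profiles, stats = stats)
}

#' @export
print.degradome_profile <- function(x, ...) {
  cat(sprintf("<degradome_profile> %s: %d reads at %d position(s)\n",
              x$transcript_id, x$total_reads,
              length(x$occupied_positions)))
  invisible(x)
}

#' Classify a cleavage position into abundance categories 0-4
#'
#' Applies the five-rule t-plot key to the raw read abundance at one
#' occupied transcript position: category 4 if only one raw read sits
#' there; otherwise category 0 if its abundance equals a uniquely attained
#' transcript-wide maximum, category 1 if it equals a maximum attained at
#' two or more positions, category 2 if it lies strictly between the
#' transcript median and maximum, and category 3 if it is no more than the
#' median. The singleton rule (category 4) is checked first, so a
#' transcript whose only signal is one read is category 4 even though that
#' read is also the maximum.
#'
#' @param profile A degradome profile (see [map_tags()]).
#' @param position 1-based transcript coordinate with `depth >= 1`.
#' @param median_include_zeros Whether the transcript median is taken over
#'   all positions (including unoccupied zeros) or, by default, over
#'   occupied positions only. On long transcripts an all-position median
#'   is almost always zero, which would empty category 3.
#' @return Integer category in `0:4`.
#' @export
classify_category <- function(profile, position,
                              median_include_zeros = FALSE) {
  d <- profile$depth
  if (position < 1L || position > length(d)) {
    stopf("position %d outside transcript %s", position,
          profile$transcript_id)
  }
  x <- d[position]
  if (x < 1L) {
    stopf("position %d of %s has no degradome signal", position,
          profile$transcript_id)
  }
  if (x == 1L) return(4L)
  mx <- max(d)
  if (x == mx) {
    return(if (sum(d == mx) == 1L) 0L else 1L)
  }
  med <- if (median_include_zeros) median(d) else median(d[d > 0L])
  if (x > med) 2L else 3L
}

#' Validate one predicted duplex against degradome signal
#'
#' Examines positions `cleavage_expect` +/- `window` of the duplex's
#' transcript profile and returns the call at the highest-abundance
#' position (ties: smallest absolute offset, then smallest coordinate) if
#' any position carries signal.
#'
#' @param duplex One-row data frame from [scan_transcript()] /
#'   [predict_targets()].
#' @param profiles Named list of degradome profiles from [map_tags()].
#' @param window Non-negative integer search half-width (default 1).
#' @param median_include_zeros Passed to [classify_category()].
#' @return A one-row data frame (`mirna_id`, `transcript_id`, `site_start`,
#'   `site_end`, `score`, `cleavage_expect`, `position`, `abundance`,
#'   `offset`, `category`), or `NULL` when the window is empty of signal.
#' @export
validate_cleavage <- function(duplex, profiles, window = 1L,
                              median_include_zeros = FALSE) {
  if (window < 0L) stopf("window must be >= 0")
  prof <- profiles[[duplex$transcript_id]]
  if (is.null(prof)) {
    stopf("no degradome profile for transcript '%s'", duplex$transcript_id)
  }
  ce <- duplex$cleavage_expect
  pos <- (ce - window):(ce + window)
  pos <- pos[pos >= 1L & pos <= length(prof$depth)]
  if (!length(pos)) return(NULL)
  ab <- prof$depth[pos]
  if (all(ab < 1L)) return(NULL)
  ord <- order(-ab, abs(pos - ce), pos)
  p <- pos[ord[1]]
  data.frame(mirna_id = duplex$mirna_id,
             transcript_id = duplex$transcript_id,
             site_start = duplex$site_start, site_end = duplex$site_end,
             score = duplex$score, cleavage_expect = ce,
             position = p, abundance = prof$depth[p],
             offset = p - ce,
             category = classify_category(prof, p, median_include_zeros),
             stringsAsFactors = FALSE)
}

#' Validate a table of predicted duplexes
#'
#' Applies [validate_cleavage()] to every row and binds the surviving
#' calls, preserving the deterministic input order.
#'
#' @param duplexes Data frame from [predict_targets()].
#' @inheritParams validate_cleavage
#' @return Data frame of validated pairs (possibly zero rows).
#' @export
validate_targets <- function(duplexes, profiles, window = 1L,
                             median_include_zeros = FALSE) {
  out <- lapply(seq_len(nrow(duplexes)), function(i) {
    validate_cleavage(duplexes[i, ], profiles, window,
                      median_include_zeros)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(mirna_id = character(0), transcript_id = character(0),
                      site_start = integer(0), site_end = integer(0),
                      score = numeric(0), cleavage_expect = integer(0),
                      position = integer(0), abundance = integer(0),
                      offset = integer(0), category = integer(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Tally validated pairs by cleavage category
#'
#' @param validated Data frame of validated pairs (with a `category`
#'   column), e.g. from [validate_targets()].
#' @return Named list: `counts` (length-5 integer vector named "0".."4")
#'   and `total`. The counts partition the input.
#' @export
summarize_categories <- function(validated) {
  counts <- vapply(0:4, function(k) sum(validated$category == k),
                   integer(1))
  names(counts) <- as.character(0:4)
  list(counts = counts, total = sum(counts))
}

#' Degradome mapping summary with percentages
#'
#' @param stats Mapping summary from [map_tags()] (needs `mapped_reads`
#'   and `transcripts_with_reads`).
#' @param n_input_transcripts Total transcripts supplied to mapping.
#' @param n_raw_reads Total raw degradome reads in the library.
#' @return List with raw counts plus `transcript_pct` and `read_pct`
#'   (rounded half-up to two decimals for reporting) and their
#'   full-precision `*_exact` counterparts.
#' @export
mapping_report <- function(stats, n_input_transcripts, n_raw_reads) {
  if (n_input_transcripts <= 0 || n_raw_reads <= 0) {
    stopf("mapping_report needs positive denominators")
  }
  tpct <- 100 * stats$transcripts_with_reads / n_input_transcripts
  rpct <- 100 * stats$mapped_reads / n_raw_reads
  list(transcripts_with_reads = stats$transcripts_with_reads,
       n_input_transcripts = n_input_transcripts,
       mapped_reads = stats$mapped_reads,
       n_raw_reads = n_raw_reads,
       transcript_pct = round_half_up(tpct, 2),
       read_pct = round_half_up(rpct, 2),
       transcript_pct_exact = tpct,
       read_pct_exact = rpct)
}
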