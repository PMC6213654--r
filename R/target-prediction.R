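# miRNA target-site scanning with position-weighted complementarity
# penalties (the plant-specific "Allen" scheme): mismatches cost 1, G:U
# wobbles 0.5, bulged nucleotides 1 each, and every penalty is doubled
# inside the functionally critical miRNA positions 2-13 (counted from the
# miRNA 5' end). Antisense-oriented slicing places the degradome tag 5'
# end opposite miRNA nucleotide 10.

BASES <- c("A", "C", "G", "T", "N")

# penalty lookup: rows = miRNA base, cols = target (sense-strand) base.
# Watson-Crick pairs score 0; G:U wobble (miRNA G vs target T, or miRNA
# U vs target G) takes the wobble penalty; everything else, including any
# pairing with N, is a mismatch.
pen_matrix <- function(weights) {
  m <- matrix(weights$mismatch, 5, 5, dimnames = list(BASES, BASES))
  m["A", "T"] <- 0; m["T", "A"] <- 0; m["G", "C"] <- 0; m["C", "G"] <- 0
  m["G", "T"] <- weights$gu_wobble
  m["T", "G"] <- weights$gu_wobble
  m
}

#' Duplex penalty weights
#'
#' Scoring configuration for miRNA:target duplexes. Defaults follow the
#' plant target-prediction convention: mismatch 1, G:U wobble 0.5, bulge 1
#' per bulged nucleotide, all doubled within miRNA positions 2--13.
#'
#' @param mismatch Penalty for a non-complementary pair.
#' @param gu_wobble Penalty for a G:U wobble pair.
#' @param bulge Penalty per bulged (unpaired) nucleotide.
#' @param core_multiplier Multiplier applied inside the core window.
#' @param core_start,core_end Bounds (miRNA positions, 1 = 5' terminus) of
#'   the doubled core window.
#' @return A list of class `duplex_weights`.
#' @export
duplex_weights <- function(mismatch = 1, gu_wobble = 0.5, bulge = 1,
                           core_multiplier = 2, core_start = 2L,
                           core_end = 13L) {
  if (min(mismatch, gu_wobble, bulge) < 0 || core_multiplier < 1) {
    stopf("penalties must be >= 0 and core_multiplier >= 1")
  }
  structure(list(mismatch = mismatch, gu_wobble = gu_wobble, bulge = bulge,
                 core_multiplier = core_multiplier,
                 core_start = as.integer(core_start),
                 core_end = as.integer(core_end)),
            class = "duplex_weights")
}

pos_weight <- function(p, weights) {
  ifelse(p >= weights$core_start & p <= weights$core_end,
         weights$core_multiplier, 1)
}

encode_seq <- function(x) {
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  codes <- match(ch, BASES)
  codes[is.na(codes)] <- 5L
  codes
}

# Score one explicit pairing register. `type` is "none", "target" (one
# bulged target nucleotide between miRNA positions g and g+1) or "mirna"
# (miRNA position g unpaired). Site indices run 5'->3' on the sense strand
# of the target; miRNA position p pairs antiparallel with site index
# L - p + 1 (plus the register shift caused by a bulge).
duplex_register <- function(mcodes, scodes, type, g, weights, pen) {
  L <- length(mcodes)
  W <- length(scodes)
  pairs_site <- integer(L)        # site index paired with each miRNA pos
  if (type == "none") {
    stopifnot(W == L)
    pairs_site <- L - seq_len(L) + 1L
  } else if (type == "target") {
    stopifnot(W == L + 1L, g >= 1L, g <= L - 1L)
    p <- seq_len(L)
    pairs_site <- ifelse(p <= g, L + 2L - p, L + 1L - p)
  } else {                        # mirna-side bulge at position g
    stopifnot(W == L - 1L, g >= 2L, g <= L - 1L)
    p <- seq_len(L)
    pairs_site <- ifelse(p > g, L - p + 1L, L - p)
    pairs_site[g] <- NA_integer_
  }
  state <- character(L)
  score <- 0
  for (p in seq_len(L)) {
    j <- pairs_site[p]
    if (is.na(j)) {
      state[p] <- "mirna_bulge"
      score <- score + weights$bulge * pos_weight(p, weights)
    } else {
      pp <- pen[mcodes[p], scodes[j]]
      # state is classified from the base pair itself, not the penalty
      # value, so degenerate weight settings (wobble == mismatch) still
      # label columns correctly
      mb <- BASES[mcodes[p]]; tb <- BASES[scodes[j]]
      wc <- (mb == "A" && tb == "T") || (mb == "T" && tb == "A") ||
            (mb == "G" && tb == "C") || (mb == "C" && tb == "G")
      gu <- (mb == "G" && tb == "T") || (mb == "T" && tb == "G")
      state[p] <- if (wc) "match" else if (gu) "gu_wobble" else "mismatch"
      score <- score + pp * pos_weight(p, weights)
    }
  }
  # duplex columns 5'->3' along the miRNA; a bulged target nucleotide adds
  # a column between positions g and g+1 and is charged at position g+1
  if (type == "target") {
    score <- score + weights$bulge * pos_weight(g + 1L, weights)
    state <- append(state, "target_bulge", after = g)
  }
  # expected slice position: site index opposite miRNA nucleotide 10
  ce <- if (L >= 10L) {
    j10 <- pairs_site[10L]
    if (is.na(j10)) pairs_site[11L] + 1L else j10
  } else NA_integer_
  list(score = score, pair_states = state, pairs_site = pairs_site,
       cleavage_site_index = ce)
}

#' Score a miRNA:target duplex
#'
#' Computes the position-weighted penalty of the duplex between a miRNA
#' and a candidate target site. The site is given 5'->3' on the sense
#' strand and is aligned antiparallel to the miRNA. If the site is one
#' nucleotide longer (shorter) than the miRNA, every placement of a single
#' target-side (miRNA-side) bulge is tried and the best register returned.
#'
#' @param mirna_seq miRNA sequence, 5'->3' (DNA or RNA alphabet).
#' @param site_seq Target-site sequence, 5'->3' sense strand.
#' @param weights A [duplex_weights()] configuration.
#' @param max_bulges Maximum number of single-nucleotide bulges (0 or 1).
#' @return A list with `score` (non-negative penalty; 0 iff perfect
#'   complement) and `pair_states` (per duplex column, over
#'   `match`, `gu_wobble`, `mismatch`, `target_bulge`, `mirna_bulge`).
#' @examples
#' score_duplex("TGGAGCTCCCTTCATTCCAAT",
#'              revcomp("TGGAGCTCCCTTCATTCCAAT"))$score  # 0
#' @export
score_duplex <- function(mirna_seq, site_seq, weights = duplex_weights(),
                         max_bulges = 1L) {
  mcodes <- encode_seq(toupper(chartr("Uu", "Tt", mirna_seq)))
  scodes <- encode_seq(toupper(chartr("Uu", "Tt", site_seq)))
  L <- length(mcodes); W <- length(scodes)
  pen <- pen_matrix(weights)
  d <- W - L
  if (d == 0L) {
    regs <- list(list(type = "none", g = NA_integer_))
  } else if (d == 1L && max_bulges >= 1L && L >= 2L) {
    regs <- lapply(seq_len(L - 1L), function(g) list(type = "target", g = g))
  } else if (d == -1L && max_bulges >= 1L && L >= 3L) {
    regs <- lapply(2:(L - 1L), function(g) list(type = "mirna", g = g))
  } else {
    stopf("site length %d incompatible with miRNA length %d under %d bulge(s)",
          W, L, max_bulges)
  }
  best <- NULL
  for (r in regs) {
    cand <- duplex_register(mcodes, scodes, r$type, r$g, weights, pen)
    if (is.null(best) || cand$score < best$score) best <- cand
  }
  best[c("score", "pair_states", "pairs_site", "cleavage_site_index")]
}

empty_alignments <- function() {
  data.frame(mirna_id = character(0), transcript_id = character(0),
             site_start = integer(0), site_end = integer(0),
             score = numeric(0), n_bulges = integer(0),
             cleavage_expect = integer(0), pair_states = character(0),
             stringsAsFactors = FALSE)
}

# Vectorized per-window best scores for one miRNA over one transcript.
# Returns candidate windows (start, width, register) with score <= cutoff.
scan_candidates <- function(mcodes, xcodes, cutoff, weights) {
  L <- length(mcodes)
  Tn <- length(xcodes)
  pen <- pen_matrix(weights)
  wpos <- pos_weight(seq_len(L), weights)
  # C[p, t]: weighted penalty of pairing miRNA position p with transcript
  # base t
  C <- matrix(0, nrow = L, ncol = Tn)
  for (p in seq_len(L)) C[p, ] <- wpos[p] * pen[mcodes[p], xcodes]
  out <- list()
  # ungapped windows [s, s+L-1]: miRNA pos p pairs transcript s + L - p
  n0 <- Tn - L + 1L
  if (n0 >= 1L) {
    S0 <- numeric(n0)
    for (p in seq_len(L)) S0 <- S0 + C[p, (L - p + 1L):(Tn - p + 1L)]
    keep <- which(S0 <= cutoff)
    if (length(keep)) {
      out[[length(out) + 1L]] <-
        data.frame(start = keep, width = L, type = "none", g = NA_integer_,
                   score = S0[keep], stringsAsFactors = FALSE)
    }
  }
  U <- upper.tri(diag(L), diag = TRUE) * 1   # cumulative-sum operator
  # one bulged target nucleotide: windows [s, s+L] of width L+1
  ns <- Tn - L
  if (ns >= 1L && L >= 2L) {
    A <- matrix(0, ns, L); B <- matrix(0, ns, L)
    for (p in seq_len(L)) {
      A[, p] <- C[p, seq_len(ns) + L - p]
      B[, p] <- C[p, seq_len(ns) + L + 1L - p]
    }
    cumA <- A %*% U; cumB <- B %*% U
    tot <- cumA[, L]
    gs <- seq_len(L - 1L)
    bp <- weights$bulge * pos_weight(gs + 1L, weights)
    S <- cumB[, gs, drop = FALSE] - cumA[, gs, drop = FALSE] + tot
    S <- sweep(S, 2L, bp, "+")
    gbest <- max.col(-S, ties.method = "first")
    sbest <- S[cbind(seq_len(ns), gbest)]
    keep <- which(sbest <= cutoff)
    if (length(keep)) {
      out[[length(out) + 1L]] <-
        data.frame(start = keep, width = L + 1L, type = "target",
                   g = gs[gbest[keep]], score = sbest[keep],
                   stringsAsFactors = FALSE)
    }
  }
  # one bulged miRNA nucleotide (interior): windows of width L-1
  ns2 <- Tn - L + 2L
  if (ns2 >= 1L && L >= 3L) {
    A2 <- matrix(0, ns2, L); B2 <- matrix(0, ns2, L)
    for (p in 2:L) A2[, p] <- C[p, seq_len(ns2) + L - p]
    for (p in seq_len(L - 2L)) B2[, p] <- C[p, seq_len(ns2) + L - 1L - p]
    cumA2 <- A2 %*% U; cumB2 <- B2 %*% U
    bs <- 2:(L - 1L)
    bp <- weights$bulge * pos_weight(bs, weights)
    S <- cumB2[, bs - 1L, drop = FALSE] +
      (cumA2[, L] - cumA2[, bs, drop = FALSE])
    S <- sweep(S, 2L, bp, "+")
    bbest <- max.col(-S, ties.method = "first")
    sbest <- S[cbind(seq_len(ns2), bbest)]
    keep <- which(sbest <= cutoff)
    if (length(keep)) {
      out[[length(out) + 1L]] <-
        data.frame(start = keep, width = L - 1L, type = "mirna",
                   g = bs[bbest[keep]], score = sbest[keep],
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Scan one transcript for target sites of one miRNA
#'
#' Every transcript window (allowing at most one single-nucleotide bulge
#' on either side) whose best duplex penalty is at or below `cutoff`
#' yields a candidate site; overlapping candidates are collapsed keeping
#' the lowest score, ties broken by smallest start coordinate, then by
#' fewest bulges. Coordinates are 1-based and inclusive on the transcript
#' sense strand. `cleavage_expect` is the transcript position paired with
#' miRNA nucleotide 10, where guide-directed slicing deposits the
#' degradome tag 5' end.
#'
#' @param mirna One-row data frame (or list) with `id` and `sequence`.
#' @param transcript One-row data frame (or list) with `id` and `sequence`.
#' @param cutoff Maximum penalty score retained (> 0; default 4).
#' @param weights A [duplex_weights()] configuration.
#' @param max_bulges Maximum bulged nucleotides per duplex (0 or 1).
#' @return Data frame of duplex alignments with columns `mirna_id`,
#'   `transcript_id`, `site_start`, `site_end`, `score`, `n_bulges`,
#'   `cleavage_expect`, `pair_states` (comma-separated states per duplex
#'   column). Transcripts shorter than the miRNA yield zero rows.
#' @export
scan_transcript <- function(mirna, transcript, cutoff = 4,
                            weights = duplex_weights(), max_bulges = 1L) {
  if (cutoff <= 0) stopf("cutoff must be > 0")
  mseq <- toupper(chartr("Uu", "Tt", mirna$sequence))
  xseq <- toupper(chartr("Uu", "Tt", transcript$sequence))
  L <- nchar(mseq)
  if (nchar(xseq) < L) return(empty_alignments())
  mcodes <- encode_seq(mseq)
  xcodes <- encode_seq(xseq)
  cand <- scan_candidates(mcodes, xcodes, cutoff, weights)
  if (max_bulges < 1L && !is.null(cand)) cand <- cand[cand$type == "none", ]
  if (is.null(cand) || !nrow(cand)) return(empty_alignments())
  # deduplicate overlapping windows: lowest score wins, then smallest
  # start, then the register closest to ungapped
  ord <- order(cand$score, cand$start, abs(cand$width - L), cand$width)
  cand <- cand[ord, , drop = FALSE]
  kept <- logical(nrow(cand))
  ends <- cand$start + cand$width - 1L
  kstart <- integer(0); kend <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!any(cand$start[i] <= kend & ends[i] >= kstart)) {
      kept[i] <- TRUE
      kstart <- c(kstart, cand$start[i]); kend <- c(kend, ends[i])
    }
  }
  cand <- cand[kept, , drop = FALSE]
  pen <- pen_matrix(weights)
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    s <- cand$start[i]; w <- cand$width[i]
    det <- duplex_register(mcodes, xcodes[s:(s + w - 1L)], cand$type[i],
                           cand$g[i], weights, pen)
    data.frame(mirna_id = mirna$id, transcript_id = transcript$id,
               site_start = s, site_end = s + w - 1L,
               score = det$score, n_bulges = as.integer(w != L),
               cleavage_expect = s + det$cleavage_site_index - 1L,
               pair_states = paste(det$pair_states, collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res[order(res$site_start), , drop = FALSE]
}

#' Predict candidate targets for a miRNA set over a transcriptome
#'
#' All-vs-all union of [scan_transcript()], in deterministic
#' (`mirna_id`, `transcript_id`, `site_start`) order.
#'
#' @param mirnas Data frame of miRNA records (`id`, `sequence`).
#' @param transcripts Data frame of transcript records (`id`, `sequence`).
#' @inheritParams scan_transcript
#' @return Data frame of duplex alignments (see [scan_transcript()]).
#' @export
predict_targets <- function(mirnas, transcripts, cutoff = 4,
                            weights = duplex_weights(), max_bulges = 1L) {
  if (!nrow(mirnas) || !nrow(transcripts)) {
    stopf("predict_targets needs non-empty miRNA and transcript sets")
  }
  out <- list()
  for (i in seq_len(nrow(mirnas))) {
    for (j in seq_len(nrow(transcripts))) {
      h <- scan_transcript(mirnas[i, ], transcripts[j, ], cutoff, weights,
                           max_bulges)
      if (nrow(h)) out[[length(out) + 1L]] <- h
    }
  }
  if (!length(out)) return(empty_alignments())
  res <- do.call(rbind, out)
  res <- res[order(res$mirna_id, res$transcript_id, res$site_start), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}
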