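# Independent reference implementations used to verify the package.
# Each oracle is written as a direct, naive transcription of the rule it
# checks and shares no code with the implementation under test.

oracle_comp <- c(A = "T", C = "G", G = "C", T = "A")

oracle_pair_penalty <- function(mb, tb, weights) {
  if (!is.na(oracle_comp[mb]) && oracle_comp[[mb]] == tb) return(0)
  if ((mb == "G" && tb == "T") || (mb == "T" && tb == "G")) {
    return(weights$gu_wobble)
  }
  weights$mismatch
}

oracle_pos_w <- function(p, weights) {
  if (p >= weights$core_start && p <= weights$core_end) {
    weights$core_multiplier
  } else 1
}

# ungapped duplex score: miRNA position p pairs with site position
# length(site) - p + 1 (antiparallel)
oracle_score_ungapped <- function(mirna, site, weights = duplex_weights()) {
  m <- strsplit(mirna, "")[[1]]
  s <- strsplit(site, "")[[1]]
  stopifnot(length(m) == length(s))
  total <- 0
  for (p in seq_along(m)) {
    total <- total +
      oracle_pair_penalty(m[p], s[length(s) - p + 1], weights) *
      oracle_pos_w(p, weights)
  }
  total
}

# best duplex score over all registers with <= 1 single-nucleotide bulge,
# by naive enumeration of bulge placements
oracle_score_duplex <- function(mirna, site, weights = duplex_weights()) {
  m <- strsplit(mirna, "")[[1]]
  s <- strsplit(site, "")[[1]]
  L <- length(m); W <- length(s)
  if (W == L) return(oracle_score_ungapped(mirna, site, weights))
  best <- Inf
  if (W == L + 1) {
    # drop one interior site nucleotide (bulged target base between
    # miRNA positions g and g+1, i.e. site index W - g), charged at g + 1
    for (g in 1:(L - 1)) {
      sub <- s[-(W - g)]
      sc <- oracle_score_ungapped(mirna, paste(sub, collapse = ""),
                                  weights) +
        weights$bulge * oracle_pos_w(g + 1, weights)
      best <- min(best, sc)
    }
  } else if (W == L - 1) {
    # drop one interior miRNA nucleotide (unpaired miRNA position b)
    for (b in 2:(L - 1)) {
      sub <- m[-b]
      base <- 0
      for (p in seq_along(sub)) {
        # positional weight follows the original miRNA numbering
        orig_p <- if (p < b) p else p + 1
        base <- base +
          oracle_pair_penalty(sub[p], s[length(s) - p + 1], weights) *
          oracle_pos_w(orig_p, weights)
      }
      sc <- base + weights$bulge * oracle_pos_w(b, weights)
      best <- min(best, sc)
    }
  } else {
    stop("length gap beyond one bulge")
  }
  best
}

# brute-force scan: best score over every window of width L-1, L, L+1
oracle_scan_hits <- function(mirna, transcript, cutoff,
                             weights = duplex_weights()) {
  Tn <- nchar(transcript)
  L <- nchar(mirna)
  hits <- list()
  for (w in c(L - 1, L, L + 1)) {
    if (w < 1 || w > Tn || (w == L - 1 && L < 3) || (w == L + 1 && L < 2))
      next
    for (s in 1:(Tn - w + 1)) {
      sc <- oracle_score_duplex(mirna, substring(transcript, s, s + w - 1),
                                weights)
      if (sc <= cutoff) {
        hits[[length(hits) + 1]] <-
          data.frame(start = s, width = w, score = sc)
      }
    }
  }
  if (!length(hits)) return(NULL)
  do.call(rbind, hits)
}

# literal transcription of the five-category abundance key
oracle_category <- function(depth, position, median_include_zeros = FALSE) {
  x <- depth[position]
  stopifnot(x >= 1)
  if (x == 1) return(4L)                       # only one raw read here
  mx <- max(depth)
  n_max <- sum(depth == mx)
  if (x == mx && n_max == 1) return(0L)        # equal to a unique maximum
  if (x == mx && n_max > 1) return(1L)         # equal to a shared maximum
  med <- if (median_include_zeros) stats::median(depth)
         else stats::median(depth[depth > 0])
  if (x > med && x < mx) return(2L)            # between median and maximum
  3L                                           # no more than the median
}

# exhaustive two-sided exact test by direct enumeration of all tables
# with the observed margins, using log-binomial coefficients only
oracle_fisher <- function(a, ta, b, tb) {
  k <- a + b
  n <- ta + tb
  lo <- max(0, k - tb)
  hi <- min(k, ta)
  logp <- vapply(lo:hi, function(x) {
    lchoose(ta, x) + lchoose(tb, k - x) - lchoose(n, k)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[(lo:hi) == a]
  min(1, sum(p[p <= obs * (1 + 1e-7)]))
}

# deterministic toy records
rec <- function(id, seq) list(id = id, sequence = seq, length = nchar(seq))

make_profile <- function(depth, id = "tx") {
  structure(list(transcript_id = id, depth = as.integer(depth),
                 total_reads = sum(depth),
                 occupied_positions = which(depth > 0)),
            class = "degradome_profile")
}

random_mirna_seq <- function(len = 21) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
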