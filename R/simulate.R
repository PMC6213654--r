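# Synthetic experiment generator with planted ground truth.
#
# Emulates the structure of a 4-condition x 2-replicate drought study
# (CK_L, D18d_L, CK_R, D18d_R): an assembled transcriptome, a mature
# miRNA set, target sites planted as exact (optionally mutated) reverse
# complements, degradome tags piling at the position opposite miRNA
# nucleotide 10, and negative-binomial count matrices with planted fold
# changes in both the miRNA and mRNA layers. Every generator is a pure
# function of its arguments and seed.

#' Study design constants
#'
#' The four condition labels and the four condition contrasts of the
#' emulated leaf/root drought design.
#'
#' @return `default_design()`: named character vector sample -> condition
#'   for 4 conditions x 2 replicates. `default_comparisons()`: list of
#'   `c(numerator, denominator)` label pairs.
#' @export
default_design <- function() {
  conds <- c("CK_L", "D18d_L", "CK_R", "D18d_R")
  samples <- as.vector(t(outer(conds, c("r1", "r2"), paste, sep = "_")))
  setNames(rep(conds, each = 2), samples)
}

#' @rdname default_design
#' @export
default_comparisons <- function() {
  list(c("D18d_L", "CK_L"), c("D18d_R", "CK_R"),
       c("CK_L", "CK_R"), c("D18d_L", "D18d_R"))
}

random_seq <- function(n, gc) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(probs), n, replace = TRUE, prob = probs),
        collapse = "")
}

#' Simulate a transcriptome
#'
#' i.i.d. nucleotides at a fixed GC content, lengths uniform over
#' `length_range`.
#'
#' @param n Number of transcripts.
#' @param length_range `c(min, max)` transcript length in nt.
#' @param gc GC fraction in (0, 1).
#' @param seed Integer seed; output is reproducible per seed.
#' @return Data frame of transcript records (`id`, `sequence`, `length`).
#' @export
simulate_transcriptome <- function(n, length_range = c(300L, 1500L),
                                   gc = 0.5, seed = 1L) {
  if (n < 1L) stopf("n must be >= 1")
  if (gc <= 0 || gc >= 1) stopf("gc must be in (0, 1)")
  with_seed(seed, {
    lens <- sample(length_range[1]:length_range[2], n, replace = TRUE)
    seqs <- vapply(lens, random_seq, character(1), gc = gc)
    data.frame(id = sprintf("synth_comp%04d_c0", seq_len(n)),
               sequence = seqs, length = lens, stringsAsFactors = FALSE)
  })
}

#' Simulate a mature miRNA set
#'
#' @param n Number of miRNAs.
#' @param length_range Length range in nt (plant mature miRNAs cluster at
#'   20--24 nt, most at 21).
#' @inheritParams simulate_transcriptome
#' @return Data frame of miRNA records (`id`, `sequence`, `length`).
#' @export
simulate_mirnas <- function(n, length_range = c(20L, 24L), gc = 0.5,
                            seed = 1L) {
  with_seed(seed, {
    lens <- sample(length_range[1]:length_range[2], n, replace = TRUE)
    seqs <- vapply(lens, random_seq, character(1), gc = gc)
    data.frame(id = sprintf("syn-miR%03d", seq_len(n)),
               sequence = seqs, length = lens, stringsAsFactors = FALSE)
  })
}

#' Plant miRNA target sites into transcripts
#'
#' Inserts (by substitution, so transcript lengths are unchanged) the
#' reverse complement of each miRNA at non-overlapping coordinates,
#' optionally with random point substitutions placed outside miRNA
#' positions 9--11 so the slicing register is never disrupted. The
#' expected cleavage position (transcript nucleotide opposite miRNA
#' position 10) is recorded per site.
#'
#' @param transcripts Data frame of transcript records.
#' @param mirnas Data frame of miRNA records.
#' @param sites_per_mirna Sites planted per miRNA.
#' @param mutations Point substitutions per planted site.
#' @param seed Integer seed.
#' @param hosts Optional character vector (one transcript id per miRNA,
#'   recycled over sites) fixing which transcript hosts each miRNA's
#'   site(s); default draws hosts at random.
#' @param reserve_3p Nucleotides kept free downstream of the cleavage
#'   position so degradome tags fit inside the transcript.
#' @return List with `transcripts` (modified) and `sites`, a data frame
#'   (`mirna_id`, `transcript_id`, `site_start`, `site_end`,
#'   `cleavage_position`, `n_mutations`).
#' @export
plant_sites <- function(transcripts, mirnas, sites_per_mirna = 1L,
                        mutations = 0L, seed = 1L, hosts = NULL,
                        reserve_3p = 40L) {
  if (sites_per_mirna < 0L) stopf("sites_per_mirna must be >= 0")
  sites <- data.frame(mirna_id = character(0), transcript_id = character(0),
                      site_start = integer(0), site_end = integer(0),
                      cleavage_position = integer(0),
                      n_mutations = integer(0), stringsAsFactors = FALSE)
  if (sites_per_mirna == 0L || !nrow(mirnas)) {
    return(list(transcripts = transcripts, sites = sites))
  }
  with_seed(seed, {
    seqs <- setNames(transcripts$sequence, transcripts$id)
    occupied <- setNames(vector("list", nrow(transcripts)), transcripts$id)
    add_site <- function(mir_id, mir_seq, tx_id) {
      L <- nchar(mir_seq)
      Tn <- nchar(seqs[[tx_id]])
      smax <- Tn - L + 1L - reserve_3p
      if (smax < 1L) stopf("transcript %s too short to host a site", tx_id)
      for (try in seq_len(100L)) {
        s <- sample.int(smax, 1L)
        iv <- c(s, s + L - 1L)
        clash <- any(vapply(occupied[[tx_id]],
                            function(o) iv[1] <= o[2] && iv[2] >= o[1],
                            logical(1)))
        if (!clash) {
          insert <- revcomp(mir_seq)
          if (mutations > 0L) {
            mpos <- sample(setdiff(seq_len(L), 9:11),
                           min(mutations, L - 3L))
            for (p in mpos) {
              # transcript coordinate opposite miRNA position p
              tpos_local <- L - p + 1L
              old <- substring(insert, tpos_local, tpos_local)
              substr(insert, tpos_local, tpos_local) <-
                sample(setdiff(c("A", "C", "G", "T"), old), 1L)
            }
          }
          substr(seqs[[tx_id]], s, s + L - 1L) <<- insert
          occupied[[tx_id]] <<- c(occupied[[tx_id]], list(iv))
          return(data.frame(mirna_id = mir_id, transcript_id = tx_id,
                            site_start = s, site_end = s + L - 1L,
                            cleavage_position = s + L - 10L,
                            n_mutations = as.integer(mutations),
                            stringsAsFactors = FALSE))
        }
      }
      stopf("could not place a non-overlapping site on %s in 100 attempts",
            tx_id)
    }
    if (is.null(hosts)) {
      hosts <- sample(transcripts$id, nrow(mirnas), replace = TRUE)
    }
    rows <- list()
    for (i in seq_len(nrow(mirnas))) {
      for (k in seq_len(sites_per_mirna)) {
        rows[[length(rows) + 1L]] <-
          add_site(mirnas$id[i], mirnas$sequence[i], hosts[[i]])
      }
    }
    out <- transcripts
    out$sequence <- unname(seqs[out$id])
    list(transcripts = out, sites = do.call(rbind, rows))
  })
}

#' Simulate a degradome tag library
#'
#' For every planted site, emits `signal_reads` reads of the tag whose 5'
#' end sits exactly at the expected cleavage position; `noise_reads`
#' additional single-read tags start at uniformly random transcript
#' positions. All tags are exact substrings of the (post-planting)
#' transcriptome.
#'
#' @param sites Site table from [plant_sites()].
#' @param transcripts Post-planting transcript records.
#' @param signal_reads Reads per planted cleavage position.
#' @param noise_reads Total number of uniform background reads.
#' @param tag_len Tag length in nt (within the 15--36 library window).
#' @param seed Integer seed.
#' @return Data frame of tag records (`sequence`, `count`), identical
#'   sequences merged.
#' @export
simulate_degradome <- function(sites, transcripts, signal_reads = 50L,
                               noise_reads = 0L, tag_len = 20L, seed = 1L) {
  if (tag_len > min(transcripts$length)) {
    stopf("tag_len exceeds the shortest transcript")
  }
  seqs <- setNames(transcripts$sequence, transcripts$id)
  tag_seq <- character(0)
  tag_cnt <- integer(0)
  if (signal_reads > 0L && nrow(sites)) {
    for (i in seq_len(nrow(sites))) {
      ce <- sites$cleavage_position[i]
      s <- seqs[[sites$transcript_id[i]]]
      if (ce + tag_len - 1L > nchar(s)) {
        stopf("tag at %s:%d would run off the transcript",
              sites$transcript_id[i], ce)
      }
      tag_seq <- c(tag_seq, substring(s, ce, ce + tag_len - 1L))
      tag_cnt <- c(tag_cnt, as.integer(signal_reads))
    }
  }
  if (noise_reads > 0L) {
    noise <- with_seed(seed, {
      tx <- sample(transcripts$id, noise_reads, replace = TRUE)
      vapply(tx, function(t) {
        s <- seqs[[t]]
        p <- sample.int(nchar(s) - tag_len + 1L, 1L)
        substring(s, p, p + tag_len - 1L)
      }, character(1))
    })
    tag_seq <- c(tag_seq, unname(noise))
    tag_cnt <- c(tag_cnt, rep(1L, noise_reads))
  }
  if (!length(tag_seq)) {
    return(data.frame(sequence = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  agg <- rowsum(tag_cnt, group = tag_seq, reorder = FALSE)
  data.frame(sequence = rownames(agg), count = as.integer(agg[, 1]),
             stringsAsFactors = FALSE)
}

#' Simulate a replicated count matrix with planted fold changes
#'
#' Baseline feature abundances are log-normal; each condition's expected
#' value is the baseline scaled by the planted per-condition multiplier;
#' replicates are i.i.d. Counts are negative-binomial by default
#' (`size = 1/dispersion`), or multinomial at exactly the expected
#' proportions with fixed library size `depth` (`model = "multinomial"`,
#' the calibration null for the exact test).
#'
#' @param features Character vector of feature ids.
#' @param design Named vector sample -> condition (see
#'   [default_design()]).
#' @param planted_fc Optional numeric matrix (features x conditions) of
#'   mean multipliers; missing rows/entries default to 1.
#' @param depth Expected library size per sample.
#' @param dispersion Negative-binomial dispersion (> 0); variance is
#'   `mu + dispersion * mu^2`.
#' @param seed Integer seed.
#' @param model `"nb"` or `"multinomial"`.
#' @param abundance_sdlog Spread (log scale) of baseline abundances.
#' @param rel_weights Optional named numeric vector pinning the relative
#'   baseline weight of specific features (on the same scale as the
#'   log-normal draws, whose mean is ~1.3). The experiment generator uses
#'   this to keep planted features a small fraction of each library, so
#'   their fold changes stay identifiable on the relative (RPKM /
#'   common-set) expression scale.
#' @return List with `counts` (a [count_matrix()]), `mu` (true mean
#'   matrix features x conditions) and `true_log2fc` (function of a
#'   comparison label pair).
#' @export
simulate_counts <- function(features, design = default_design(),
                            planted_fc = NULL, depth = 1e4,
                            dispersion = 0.1, seed = 1L,
                            model = c("nb", "multinomial"),
                            abundance_sdlog = 0.7, rel_weights = NULL) {
  model <- match.arg(model)
  if (dispersion <= 0) stopf("dispersion must be > 0")
  if (depth <= 0) stopf("depth must be > 0")
  conds <- unique(unname(design))
  nf <- length(features)
  mult <- matrix(1, nf, length(conds), dimnames = list(features, conds))
  if (!is.null(planted_fc)) {
    ok_f <- intersect(rownames(planted_fc), features)
    ok_c <- intersect(colnames(planted_fc), conds)
    mult[ok_f, ok_c] <- planted_fc[ok_f, ok_c]
  }
  with_seed(seed, {
    rel <- rlnorm(nf, meanlog = 0, sdlog = abundance_sdlog)
    names(rel) <- features
    if (!is.null(rel_weights)) {
      pin <- intersect(names(rel_weights), features)
      rel[pin] <- rel_weights[pin]
    }
    base <- depth * rel / sum(rel)
    mu <- base * mult                     # features x conditions
    counts <- matrix(0L, nf, length(design),
                     dimnames = list(features, names(design)))
    for (s in names(design)) {
      m <- mu[, design[[s]]]
      counts[, s] <- if (model == "nb") {
        rnbinom(nf, mu = m, size = 1 / dispersion)
      } else {
        as.integer(rmultinom(1, size = round(depth), prob = m))
      }
    }
    list(counts = count_matrix(counts),
         mu = mu,
         true_log2fc = function(comparison) {
           log2(mu[, comparison[1]] / mu[, comparison[2]])
         })
  })
}

# per-condition multiplier rows for one planted feature: `fc` applied to
# the numerator condition of its focal comparison
focal_multiplier <- function(conds, comparison, direction, fold) {
  m <- setNames(rep(1, length(conds)), conds)
  m[comparison[1]] <- if (direction == "up") fold else 1 / fold
  m
}

#' Generate a complete synthetic experiment
#'
#' Builds every input of the pipeline plus its ground truth under one of
#' three scenario presets:
#' \describe{
#'   \item{baseline}{near-noiseless: 8-fold planted effects, deep
#'     libraries (1e5), tight dispersion (0.01), exact target sites, 50
#'     degradome reads per site, no background tags. The pipeline must
#'     recover the planted pair set exactly.}
#'   \item{noisy}{4-fold effects, depth 1e4, dispersion 0.1, one point
#'     mutation per site, 20 signal reads per site against a 10:1
#'     signal:background tag ratio.}
#'   \item{null}{no planted effects or sites; background tags only.}
#' }
#' Planted pairs cycle over the four condition contrasts; three of every
#' four pairs are reversed (miRNA and target moving oppositely). The
#' ground truth is derived from the true mean matrices: a pair is
#' expected in every comparison where the miRNA's true means differ and
#' the target's true |log2 ratio| clears the gene threshold -- an effect
#' planted for one contrast also surfaces in contrasts sharing the
#' perturbed condition, and the truth accounts for that.
#'
#' @param preset `"baseline"`, `"noisy"` or `"null"`.
#' @param seed Integer seed driving every stochastic choice.
#' @param n_transcripts,n_pairs,n_null_mirnas Scenario sizes.
#' @param params Optional named list overriding preset parameters
#'   (`tx_len`, `gc`, `effect_fold`, `depth`, `dispersion`,
#'   `signal_reads`, `noise_reads_per_site`, `mutations`, `tag_len`).
#' @return List with `transcripts`, `mirnas`, `tags`, `gene_counts`,
#'   `mirna_counts` (both [count_matrix()]), `design`, `comparisons`,
#'   `truth` (see [write_ground_truth()]) and `params`.
#' @export
simulate_experiment <- function(preset = c("baseline", "noisy", "null"),
                                seed = 1L, n_transcripts = 80L,
                                n_pairs = 16L, n_null_mirnas = 24L,
                                params = list()) {
  preset <- match.arg(preset)
  p <- list(tx_len = c(400L, 900L), gc = 0.5, effect_fold = 8,
            depth = 1e5, dispersion = 0.01, signal_reads = 50L,
            noise_reads_per_site = 0L, mutations = 0L, tag_len = 20L,
            planted_rel_weight = 0.4)
  if (preset == "noisy") {
    p[c("effect_fold", "depth", "dispersion", "signal_reads",
        "noise_reads_per_site", "mutations")] <-
      list(4, 1e4, 0.1, 20L, 2L, 1L)
  }
  if (preset == "null") {
    p[c("effect_fold", "signal_reads", "noise_reads_per_site")] <-
      list(1, 0L, 2L)
    n_pairs <- 0L
  }
  p[names(params)] <- params
  seed <- as.integer(seed)
  design <- default_design()
  comparisons <- default_comparisons()
  conds <- unique(unname(design))

  transcripts <- simulate_transcriptome(n_transcripts, p$tx_len, p$gc,
                                        seed = seed)
  n_mirnas <- n_pairs + n_null_mirnas
  mirnas <- simulate_mirnas(n_mirnas, seed = seed + 1L)

  # pair i: miRNA i targets transcript i; focal contrasts cycle; miRNA
  # direction alternates; every fourth pair moves with its target
  # (non-reversed), the rest against it
  if (n_pairs > 0L) {
    focal <- comparisons[((seq_len(n_pairs) - 1L) %% 4L) + 1L]
    mdir <- ifelse(seq_len(n_pairs) %% 2L == 0L, "up", "down")
    gdir <- ifelse(seq_len(n_pairs) %% 4L == 0L, mdir,
                   ifelse(mdir == "up", "down", "up"))
    planted <- plant_sites(transcripts, mirnas[seq_len(n_pairs), ],
                           sites_per_mirna = 1L, mutations = p$mutations,
                           seed = seed + 2L,
                           hosts = transcripts$id[seq_len(n_pairs)],
                           reserve_3p = p$tag_len + 20L)
    transcripts <- planted$transcripts
    sites <- planted$sites
    mir_fc <- do.call(rbind, lapply(seq_len(n_pairs), function(i) {
      focal_multiplier(conds, focal[[i]], mdir[i], p$effect_fold)
    }))
    rownames(mir_fc) <- mirnas$id[seq_len(n_pairs)]
    gene_fc <- do.call(rbind, lapply(seq_len(n_pairs), function(i) {
      focal_multiplier(conds, focal[[i]], gdir[i], p$effect_fold)
    }))
    rownames(gene_fc) <- transcripts$id[seq_len(n_pairs)]
  } else {
    sites <- plant_sites(transcripts, mirnas[0, ], 0L, seed = seed)$sites
    mir_fc <- NULL
    gene_fc <- NULL
  }

  noise_total <- p$noise_reads_per_site * max(n_pairs, 10L)
  tags <- simulate_degradome(sites, transcripts,
                             signal_reads = p$signal_reads,
                             noise_reads = noise_total,
                             tag_len = p$tag_len, seed = seed + 3L)

  gene_w <- if (n_pairs > 0L) {
    setNames(rep(p$planted_rel_weight, n_pairs),
             transcripts$id[seq_len(n_pairs)])
  } else NULL
  mir_w <- if (n_pairs > 0L) {
    setNames(rep(p$planted_rel_weight, n_pairs),
             mirnas$id[seq_len(n_pairs)])
  } else NULL
  gene_sim <- simulate_counts(transcripts$id, design, gene_fc,
                              depth = p$depth, dispersion = p$dispersion,
                              seed = seed + 4L, rel_weights = gene_w)
  gene_sim$counts$feature_lengths <- setNames(transcripts$length,
                                              transcripts$id)
  mirna_sim <- simulate_counts(mirnas$id, design, mir_fc,
                               depth = p$depth, dispersion = p$dispersion,
                               seed = seed + 5L, rel_weights = mir_w)

  truth <- derive_ground_truth(sites, gene_sim$mu, mirna_sim$mu,
                               comparisons, seed)
  list(transcripts = transcripts, mirnas = mirnas, tags = tags,
       gene_counts = gene_sim$counts, mirna_counts = mirna_sim$counts,
       design = design, comparisons = comparisons, truth = truth,
       params = p)
}

# Ground truth from the true mean matrices: planted DE per layer and the
# expected pair set per comparison. Expression is measured on the
# relative scale (RPKM, common-set scaling, exact tests on proportions),
# so truth is derived from per-condition *proportions*: an effect planted
# on an absolute mean also shifts every other feature's proportion
# slightly, and the derivation accounts for that instead of ignoring it.
derive_ground_truth <- function(sites, gene_mu, mirna_mu, comparisons,
                                seed, gene_min_lfc = 1) {
  tol <- 1e-9
  gene_prop <- sweep(gene_mu, 2L, colSums(gene_mu), "/")
  mirna_prop <- sweep(mirna_mu, 2L, colSums(mirna_mu), "/")
  de_rows <- list()
  pair_rows <- list()
  for (comp in comparisons) {
    lbl <- paste(comp, collapse = "_vs_")
    glfc <- log2(gene_prop[, comp[1]] / gene_prop[, comp[2]])
    mlfc <- log2(mirna_prop[, comp[1]] / mirna_prop[, comp[2]])
    g_sig <- abs(glfc) >= gene_min_lfc - tol
    m_sig <- abs(mlfc) > tol
    for (f in names(glfc)[g_sig]) {
      de_rows[[length(de_rows) + 1L]] <-
        data.frame(feature_id = f, layer = "gene", comparison = lbl,
                   true_log2fc = unname(glfc[f]),
                   stringsAsFactors = FALSE)
    }
    for (f in names(mlfc)[m_sig]) {
      de_rows[[length(de_rows) + 1L]] <-
        data.frame(feature_id = f, layer = "mirna", comparison = lbl,
                   true_log2fc = unname(mlfc[f]),
                   stringsAsFactors = FALSE)
    }
    if (nrow(sites)) {
      for (i in seq_len(nrow(sites))) {
        m <- sites$mirna_id[i]; g <- sites$transcript_id[i]
        if (m_sig[m] && g_sig[g]) {
          pair_rows[[length(pair_rows) + 1L]] <-
            data.frame(comparison = lbl, mirna_id = m, gene_id = g,
                       mirna_direction = if (mlfc[m] > 0) "up" else "down",
                       gene_direction = if (glfc[g] > 0) "up" else "down",
                       reversed = (mlfc[m] > 0) != (glfc[g] > 0),
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  empty_de <- data.frame(feature_id = character(0), layer = character(0),
                         comparison = character(0),
                         true_log2fc = numeric(0), stringsAsFactors = FALSE)
  empty_pr <- data.frame(comparison = character(0), mirna_id = character(0),
                         gene_id = character(0),
                         mirna_direction = character(0),
                         gene_direction = character(0), reversed = logical(0),
                         stringsAsFactors = FALSE)
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else empty_pr
  pairs <- unique(pairs)
  de <- if (length(de_rows)) do.call(rbind, de_rows) else empty_de
  rownames(sites) <- NULL
  rownames(de) <- NULL
  rownames(pairs) <- NULL
  list(planted_sites = sites,
       planted_de = de,
       planted_pairs = pairs,
       seed = as.integer(seed))
}

#' Serialize / reload ground truth
#'
#' Ground truth round-trips losslessly through JSON (full-precision
#' numerics).
#'
#' @param truth Ground-truth list from [simulate_experiment()].
#' @param path JSON path.
#' @return `write_ground_truth()`: `path`, invisibly;
#'   `read_ground_truth()`: the ground-truth list.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "columns", digits = NA,
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fix_df <- function(d, cols) {
    d <- as.data.frame(d, stringsAsFactors = FALSE)
    if (!nrow(d) && !ncol(d)) {
      d <- as.data.frame(setNames(rep(list(character(0)), length(cols)),
                                  cols), stringsAsFactors = FALSE)
    }
    d
  }
  list(planted_sites = fix_df(x$planted_sites,
                              c("mirna_id", "transcript_id", "site_start",
                                "site_end", "cleavage_position",
                                "n_mutations")),
       planted_de = fix_df(x$planted_de,
                           c("feature_id", "layer", "comparison",
                             "true_log2fc")),
       planted_pairs = fix_df(x$planted_pairs,
                              c("comparison", "mirna_id", "gene_id",
                                "mirna_direction", "gene_direction",
                                "reversed")),
       seed = as.integer(x$seed))
}

#' Precision and recall of recovered pairs against planted truth
#'
#' Pairs are keyed by (comparison, miRNA, gene). Precision is 1 when
#' nothing was recovered and recall is 1 when nothing was planted.
#'
#' @param recovered Pair table from [join_pairs()] (rows across
#'   comparisons).
#' @param planted `truth$planted_pairs` from [simulate_experiment()].
#' @return List with `precision`, `recall`, `n_recovered`, `n_planted`,
#'   `n_correct`.
#' @export
pair_precision_recall <- function(recovered, planted) {
  key <- function(d) paste(d$comparison, d$mirna_id, d$gene_id, sep = "|")
  r <- unique(key(recovered))
  t <- unique(key(planted))
  hit <- length(intersect(r, t))
  list(precision = if (length(r)) hit / length(r) else 1,
       recall = if (length(t)) hit / length(t) else 1,
       n_recovered = length(r), n_planted = length(t), n_correct = hit)
}
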