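# The synthetic experiment generator: determinism, composition, planted
# sites, degradome signatures, count models and ground-truth round-trips.

test_that("transcriptome simulation is deterministic and GC-calibrated", {
  tx1 <- simulate_transcriptome(150, c(300, 1500), gc = 0.5, seed = 7)
  tx2 <- simulate_transcriptome(150, c(300, 1500), gc = 0.5, seed = 7)
  expect_identical(tx1, tx2)
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(tx1, f1); write_fasta(tx2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  bases <- paste(tx1$sequence, collapse = "")
  expect_gte(nchar(bases), 1e5)
  gc_obs <- mean(strsplit(bases, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc_obs - 0.5), 0.01)

  expect_equal(nrow(simulate_transcriptome(1, c(50, 60), 0.4, 1)), 1L)
  expect_true(all(tx1$length >= 300 & tx1$length <= 1500))
})

test_that("planted sites are exact reverse complements found at score 0", {
  tx <- simulate_transcriptome(10, c(400, 600), 0.5, seed = 8)
  mirs <- simulate_mirnas(5, seed = 9)
  planted <- plant_sites(tx, mirs, sites_per_mirna = 1, mutations = 0,
                         seed = 10)
  expect_equal(nrow(planted$sites), 5L)
  for (i in seq_len(nrow(planted$sites))) {
    s <- planted$sites[i, ]
    host <- planted$transcripts[planted$transcripts$id == s$transcript_id, ]
    mir <- mirs[mirs$id == s$mirna_id, ]
    expect_equal(substring(host$sequence, s$site_start, s$site_end),
                 revcomp(mir$sequence))
    expect_equal(s$cleavage_position, s$site_start + mir$length - 10L)
    hits <- scan_transcript(mir, host, cutoff = 4)
    hit <- hits[hits$site_start == s$site_start, ]
    expect_equal(hit$score, 0)
    expect_equal(hit$cleavage_expect, s$cleavage_position)
  }
  # zero sites leaves transcripts untouched
  untouched <- plant_sites(tx, mirs, sites_per_mirna = 0, seed = 10)
  expect_identical(untouched$transcripts, tx)
})

test_that("mutated sites stay under the default cutoff and are found", {
  tx <- simulate_transcriptome(10, c(400, 600), 0.5, seed = 11)
  mirs <- simulate_mirnas(6, seed = 12)
  planted <- plant_sites(tx, mirs, sites_per_mirna = 1, mutations = 2,
                         seed = 13)
  for (i in seq_len(nrow(planted$sites))) {
    s <- planted$sites[i, ]
    host <- planted$transcripts[planted$transcripts$id == s$transcript_id, ]
    mir <- mirs[mirs$id == s$mirna_id, ]
    # two substitutions cost at most 2 x 2 (doubled core weight)
    hits <- scan_transcript(mir, host, cutoff = 4)
    hit <- hits[abs(hits$site_start - s$site_start) <= 1, ]
    expect_gte(nrow(hit), 1L)
    expect_lte(min(hit$score), 4)
  }
})

test_that("degradome simulation writes signatures at cleavage positions", {
  tx <- simulate_transcriptome(8, c(400, 600), 0.5, seed = 14)
  mirs <- simulate_mirnas(4, seed = 15)
  planted <- plant_sites(tx, mirs, 1, 0, seed = 16)
  tags <- simulate_degradome(planted$sites, planted$transcripts,
                             signal_reads = 10, noise_reads = 0,
                             tag_len = 20, seed = 17)
  prof <- map_tags(tags, planted$transcripts)$profiles
  for (i in seq_len(nrow(planted$sites))) {
    s <- planted$sites[i, ]
    expect_gte(prof[[s$transcript_id]]$depth[s$cleavage_position], 10L)
    expect_equal(classify_category(prof[[s$transcript_id]],
                                   s$cleavage_position), 0L)
  }
  # single-read signatures classify as category 4
  tags1 <- simulate_degradome(planted$sites, planted$transcripts,
                              signal_reads = 1, noise_reads = 0,
                              tag_len = 20, seed = 18)
  prof1 <- map_tags(tags1, planted$transcripts)$profiles
  cats <- vapply(seq_len(nrow(planted$sites)), function(i) {
    s <- planted$sites[i, ]
    classify_category(prof1[[s$transcript_id]], s$cleavage_position)
  }, integer(1))
  expect_true(all(cats == 4L))
  # no signal, no noise: empty library
  none <- simulate_degradome(planted$sites[0, ], planted$transcripts,
                             signal_reads = 0, noise_reads = 0,
                             tag_len = 20, seed = 19)
  expect_equal(nrow(none), 0L)
})

test_that("count simulation is seed-deterministic with calibrated nulls
           and powered planted effects", {
  ids <- sprintf("f%04d", 1:1000)
  s1 <- simulate_counts(ids, depth = 1e5, dispersion = 0.1, seed = 20)
  s2 <- simulate_counts(ids, depth = 1e5, dispersion = 0.1, seed = 20)
  expect_identical(s1$counts$counts, s2$counts$counts)
  # library sizes within 2x of the nominal depth
  expect_true(all(colSums(s1$counts$counts) > 5e4 &
                  colSums(s1$counts$counts) < 2e5))

  # all-null fold changes: <= 6% of features called significant in gene
  # mode (fold-change gate plus exact test)
  design <- default_design()
  cm <- s1$counts
  cm$feature_lengths <- setNames(rep(500, 1000), ids)
  de <- call_de(cm, design, c("D18d_R", "CK_R"), mode = "gene")
  expect_lte(mean(de$significant), 0.06)

  # planted 8-fold features at high depth: >= 95% recovered, right sign
  conds <- unique(unname(design))
  fc <- matrix(1, 100, 4, dimnames = list(ids[1:100], conds))
  fc[, "D18d_R"] <- rep(c(8, 0.125), 50)
  sp <- simulate_counts(ids, design, fc, depth = 1e5, dispersion = 0.1,
                        seed = 21)
  cmp <- sp$counts
  cmp$feature_lengths <- setNames(rep(500, 1000), ids)
  dep <- call_de(cmp, design, c("D18d_R", "CK_R"), mode = "gene")
  planted <- dep[match(ids[1:100], dep$feature_id), ]
  expect_gte(mean(planted$significant), 0.95)
  want <- rep(c("up", "down"), 50)
  ok <- planted$significant
  expect_equal(planted$direction[ok], want[ok])
})

test_that("ground truth round-trips losslessly through JSON", {
  exp <- simulate_experiment("baseline", seed = 23)
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(exp$truth, path)
  back <- read_ground_truth(path)
  expect_equal(back$planted_sites, exp$truth$planted_sites)
  expect_equal(back$planted_de, exp$truth$planted_de)
  expect_equal(back$planted_pairs, exp$truth$planted_pairs)
  expect_identical(back$seed, exp$truth$seed)
})

test_that("experiment generation is a pure function of the seed", {
  e1 <- simulate_experiment("noisy", seed = 24)
  e2 <- simulate_experiment("noisy", seed = 24)
  expect_identical(e1$transcripts, e2$transcripts)
  expect_identical(e1$tags, e2$tags)
  expect_identical(e1$gene_counts$counts, e2$gene_counts$counts)
  expect_identical(e1$mirna_counts$counts, e2$mirna_counts$counts)
  expect_equal(e1$truth, e2$truth)
  e3 <- simulate_experiment("noisy", seed = 25)
  expect_false(identical(e1$gene_counts$counts, e3$gene_counts$counts))
})

test_that("every planted pair's members appear in the planted DE table", {
  exp <- simulate_experiment("baseline", seed = 26)
  tr <- exp$truth
  de_key <- paste(tr$planted_de$feature_id, tr$planted_de$comparison)
  expect_true(all(paste(tr$planted_pairs$mirna_id,
                        tr$planted_pairs$comparison) %in% de_key))
  expect_true(all(paste(tr$planted_pairs$gene_id,
                        tr$planted_pairs$comparison) %in% de_key))
  # every planted site is an exact reverse-complement insert
  for (i in seq_len(nrow(tr$planted_sites))) {
    s <- tr$planted_sites[i, ]
    host <- exp$transcripts[exp$transcripts$id == s$transcript_id, ]
    mir <- exp$mirnas[exp$mirnas$id == s$mirna_id, ]
    expect_equal(substring(host$sequence, s$site_start, s$site_end),
                 revcomp(mir$sequence))
  }
})
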