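# Joining DE calls with validated sites, reversed-regulation flags, set
# accounting and annotation joins.

de_row <- function(id, lbl, lfc, sig = TRUE) {
  data.frame(feature_id = id, comparison = lbl, mean_expr_num = 1,
             mean_expr_den = 1, log2fc = lfc, p_value = 0.001,
             direction = if (!sig) "unchanged" else if (lfc > 0) "up"
                         else "down",
             significant = sig, stringsAsFactors = FALSE)
}

val_row <- function(mir, gene, category = 0L, abundance = 10L) {
  data.frame(mirna_id = mir, transcript_id = gene, site_start = 10L,
             site_end = 30L, score = 1, cleavage_expect = 20L,
             position = 20L, abundance = abundance, offset = 0L,
             category = category, stringsAsFactors = FALSE)
}

test_that("pairs require joint significance and a validated site", {
  comp <- c("D18d_R", "CK_R")
  lbl <- "D18d_R_vs_CK_R"
  demirs <- rbind(de_row("miR-a", lbl, -2), de_row("miR-b", lbl, 1.5),
                  de_row("miR-c", lbl, 0, sig = FALSE))
  degs <- rbind(de_row("gene1", lbl, 2.5), de_row("gene2", lbl, 0.2,
                                                  sig = FALSE))
  validated <- rbind(val_row("miR-a", "gene1"), val_row("miR-b", "gene2"),
                     val_row("miR-c", "gene1"))
  pairs <- join_pairs(demirs, degs, validated, comp)
  # only miR-a/gene1 has both members significant and a validated site
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$mirna_id, "miR-a")
  expect_equal(pairs$gene_id, "gene1")
  expect_true(pairs$reversed)

  expect_equal(nrow(join_pairs(demirs, degs, validated[0, ], comp)), 0L)
  expect_error(join_pairs(demirs, degs, validated, c("CK_L", "CK_R")),
               "not")
})

test_that("multi-site pairs collapse to the best category", {
  comp <- c("D18d_R", "CK_R"); lbl <- "D18d_R_vs_CK_R"
  demirs <- de_row("miR-a", lbl, -2)
  degs <- de_row("gene1", lbl, 2.5)
  validated <- rbind(val_row("miR-a", "gene1", category = 2L,
                             abundance = 99L),
                     val_row("miR-a", "gene1", category = 0L,
                             abundance = 5L),
                     val_row("miR-a", "gene1", category = 0L,
                             abundance = 50L))
  pairs <- join_pairs(demirs, degs, validated, comp)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$category, 0L)
  expect_equal(pairs$abundance, 50L)   # tie on category -> max abundance
})

test_that("join_pairs is invariant to input row order", {
  comp <- c("CK_L", "CK_R"); lbl <- "CK_L_vs_CK_R"
  demirs <- rbind(de_row("m1", lbl, -1), de_row("m2", lbl, 2))
  degs <- rbind(de_row("g1", lbl, 1.2), de_row("g2", lbl, -3))
  validated <- rbind(val_row("m1", "g1"), val_row("m2", "g2"),
                     val_row("m2", "g1"))
  ref <- join_pairs(demirs, degs, validated, comp)
  set.seed(71)
  shuf <- join_pairs(demirs[2:1, ], degs[2:1, ],
                     validated[sample(3), ], comp)
  expect_equal(shuf, ref)
})

test_that("reversed flags mirror miRNA-mediated repression semantics", {
  # the canonical drought-root case: miRNA down while its HSP70 target
  # is up, and a same-direction (down/down) pair between organs
  pairs <- rbind(
    data.frame(comparison = "D18dR_vs_CKR", mirna_id = "ata-miR164c-3p",
               mirna_direction = "down", gene_id = "comp59407_c0",
               gene_direction = "up", reversed = NA,
               category = 0L, abundance = 10L, score = 1,
               annotation = NA_character_, kegg = NA_character_),
    data.frame(comparison = "CKL_vs_CKR", mirna_id = "PC-3p-68901_67",
               mirna_direction = "down", gene_id = "comp50628_c0",
               gene_direction = "down", reversed = NA,
               category = 0L, abundance = 4L, score = 2,
               annotation = NA_character_, kegg = NA_character_))
  parts <- flag_reversed(pairs)
  expect_equal(parts$reversed$mirna_id, "ata-miR164c-3p")
  expect_equal(parts$same_direction$mirna_id, "PC-3p-68901_67")
  expect_equal(nrow(parts$reversed) + nrow(parts$same_direction),
               nrow(pairs))
  empty <- flag_reversed(pairs[0, ])
  expect_equal(nrow(empty$reversed), 0L)
  expect_equal(nrow(empty$same_direction), 0L)
})

test_that("venn accounting satisfies inclusion-exclusion", {
  v <- venn_counts(c("a"), c("b"))
  expect_equal(unlist(v), c(only_a = 1, only_b = 1, shared = 0,
                            union_total = 2))
  v <- venn_counts(letters[1:5], letters[1:5])
  expect_equal(unlist(v), c(only_a = 0, only_b = 0, shared = 5,
                            union_total = 5))
  set.seed(72)
  for (rep in 1:50) {
    a <- sample(letters, sample(0:20, 1))
    b <- sample(letters, sample(0:20, 1))
    v <- venn_counts(a, b)
    expect_equal(v$union_total, length(union(a, b)))
    expect_equal(v$only_a + v$only_b + v$shared, v$union_total)
    expect_equal(v$only_a + v$shared, length(unique(a)))
  }
  expect_equal(venn_union_total(1872, 3778, 378), 5272)
  expect_error(venn_union_total(3, 5, 4), "exceeds")
})

test_that("annotations join left-outer preserving order", {
  pairs <- rbind(
    data.frame(comparison = "c", mirna_id = "m1", mirna_direction = "down",
               gene_id = "comp59407_c0", gene_direction = "up",
               reversed = TRUE, category = 0L, abundance = 10L, score = 1,
               annotation = NA_character_, kegg = NA_character_),
    data.frame(comparison = "c", mirna_id = "m2", mirna_direction = "up",
               gene_id = "unknown_gene", gene_direction = "down",
               reversed = TRUE, category = 2L, abundance = 3L, score = 2,
               annotation = NA_character_, kegg = NA_character_))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tdescription\tgo\tkegg",
               paste0("comp59407_c0\tHeat shock 70kda protein 5\t",
                      "GO:0005524 ATP binding\tko03060:Protein export")),
             path)
  ann <- read_annotation_table(path)
  out <- attach_annotations(pairs, ann)
  expect_equal(out$annotation,
               c("Heat shock 70kda protein 5", NA_character_))
  expect_equal(out$kegg, c("ko03060:Protein export", NA_character_))
  expect_equal(out$gene_id, pairs$gene_id)
  expect_equal(nrow(attach_annotations(pairs[0, ], ann)), 0L)
})

test_that("catalog and coding-fraction arithmetic", {
  expect_equal(catalog_summary(486, 33)$total, 519)
  expect_equal(catalog_summary(0, 0)$total, 0)
  expect_equal(catalog_summary(7, 0)$total, 7)
  expect_equal(coding_fraction(34077, 55366), 61.55)
  expect_error(coding_fraction(1, 0), "n_total")
})

test_that("the pairs table writes sorted rows and a header-only file for
           empty input", {
  pairs <- rbind(
    data.frame(comparison = "B", mirna_id = "m1", mirna_direction = "down",
               gene_id = "g2", gene_direction = "up", reversed = TRUE,
               category = 0L, abundance = 10L, score = 1,
               annotation = NA_character_, kegg = NA_character_),
    data.frame(comparison = "B", mirna_id = "m1", mirna_direction = "down",
               gene_id = "g1", gene_direction = "up", reversed = TRUE,
               category = 0L, abundance = 10L, score = 1,
               annotation = NA_character_, kegg = NA_character_),
    data.frame(comparison = "A", mirna_id = "m2", mirna_direction = "up",
               gene_id = "g3", gene_direction = "down", reversed = TRUE,
               category = 1L, abundance = 2L, score = 3,
               annotation = NA_character_, kegg = NA_character_))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pairs_table(pairs, path)
  lines <- readLines(path)
  expect_equal(length(lines), 4L)
  got <- do.call(rbind, strsplit(lines[-1], "\t"))[, 1:4]
  expect_equal(got[, 1], c("A", "B", "B"))
  expect_equal(got[, 4], c("g3", "g1", "g2"))

  write_pairs_table(pairs[0, ], path)
  expect_equal(length(readLines(path)), 1L)
})
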