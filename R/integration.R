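# Integration of differentially expressed miRNAs, degradome-validated
# target sites and differentially expressed transcripts into per-
# comparison pair tables, with reversed-regulation flags, set accounting
# and annotation joins.

#' Join DE miRNAs, DE genes and validated sites into pair records
#'
#' A pair record exists iff the miRNA is significant, the gene is
#' significant, and the (miRNA, gene) combination carries a validated
#' cleavage site. A pair validated at several sites collapses to a single
#' record keeping the best (lowest) category, ties broken by highest
#' abundance. Output is sorted by (`mirna_id`, `gene_id`).
#'
#' @param demirs [call_de()] table for the miRNA layer.
#' @param degs [call_de()] table for the transcript layer.
#' @param validated Validated-pair table from [validate_targets()].
#' @param comparison Character vector `c(numerator, denominator)`; both DE
#'   tables must have been computed for this comparison.
#' @return Data frame with columns `comparison`, `mirna_id`,
#'   `mirna_direction`, `gene_id`, `gene_direction`, `reversed`,
#'   `category`, `abundance`, `score`, `annotation`, `kegg`.
#' @export
join_pairs <- function(demirs, degs, validated, comparison) {
  lbl <- paste(comparison, collapse = "_vs_")
  for (de in list(demirs, degs)) {
    if (nrow(de) && !all(de$comparison == lbl)) {
      stopf("DE table computed for '%s', not '%s'",
            de$comparison[1], lbl)
    }
  }
  sig_mir <- demirs[demirs$significant, , drop = FALSE]
  sig_deg <- degs[degs$significant, , drop = FALSE]
  if (!nrow(sig_mir) || !nrow(sig_deg) || !nrow(validated)) {
    return(empty_pairs())
  }
  v <- validated[validated$mirna_id %in% sig_mir$feature_id &
                 validated$transcript_id %in% sig_deg$feature_id, ,
                 drop = FALSE]
  if (!nrow(v)) return(empty_pairs())
  # one record per (miRNA, gene): best category, then highest abundance
  v <- v[order(v$mirna_id, v$transcript_id, v$category, -v$abundance), ,
         drop = FALSE]
  v <- v[!duplicated(v[c("mirna_id", "transcript_id")]), , drop = FALSE]
  mdir <- setNames(sig_mir$direction, sig_mir$feature_id)
  gdir <- setNames(sig_deg$direction, sig_deg$feature_id)
  out <- data.frame(comparison = lbl,
                    mirna_id = v$mirna_id,
                    mirna_direction = unname(mdir[v$mirna_id]),
                    gene_id = v$transcript_id,
                    gene_direction = unname(gdir[v$transcript_id]),
                    category = v$category,
                    abundance = v$abundance,
                    score = v$score,
                    annotation = NA_character_,
                    kegg = NA_character_,
                    stringsAsFactors = FALSE)
  out$reversed <- out$mirna_direction != out$gene_direction
  out <- out[order(out$mirna_id, out$gene_id),
             c("comparison", "mirna_id", "mirna_direction", "gene_id",
               "gene_direction", "reversed", "category", "abundance",
               "score", "annotation", "kegg")]
  rownames(out) <- NULL
  out
}

empty_pairs <- function() {
  data.frame(comparison = character(0), mirna_id = character(0),
             mirna_direction = character(0), gene_id = character(0),
             gene_direction = character(0), reversed = logical(0),
             category = integer(0), abundance = integer(0),
             score = numeric(0), annotation = character(0),
             kegg = character(0), stringsAsFactors = FALSE)
}

#' Partition pairs by reversed regulation
#'
#' A pair is reversed iff its miRNA and target change in opposite
#' directions, the pattern consistent with miRNA-mediated repression.
#'
#' @param pairs Pair table from [join_pairs()].
#' @return List with data frames `reversed` and `same_direction`; the two
#'   partition the input exhaustively and exclusively.
#' @export
flag_reversed <- function(pairs) {
  rev_flag <- pairs$mirna_direction != pairs$gene_direction
  list(reversed = pairs[rev_flag, , drop = FALSE],
       same_direction = pairs[!rev_flag, , drop = FALSE])
}

#' Two-set Venn accounting
#'
#' @param set_a,set_b Character vectors of feature ids (duplicates
#'   ignored).
#' @return List `only_a`, `only_b`, `shared`, `union_total` satisfying
#'   inclusion-exclusion.
#' @export
venn_counts <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  shared <- length(intersect(a, b))
  list(only_a = length(a) - shared, only_b = length(b) - shared,
       shared = shared, union_total = length(a) + length(b) - shared)
}

#' Inclusion-exclusion union size from set sizes
#'
#' `|A union B| = |A| + |B| - |A intersect B>`, for reconciling reported
#' per-organ DE counts with their combined total.
#'
#' @param n_a,n_b,n_shared Set and intersection sizes.
#' @return Union size.
#' @export
venn_union_total <- function(n_a, n_b, n_shared) {
  if (n_shared > min(n_a, n_b)) stopf("intersection exceeds a set size")
  n_a + n_b - n_shared
}

#' Attach gene annotations to pair records
#'
#' Left-outer join of an annotation table (see [read_annotation_table()])
#' onto the `gene_id` column; genes absent from the table keep empty
#' annotation. Input order is preserved.
#'
#' @param pairs Pair table from [join_pairs()].
#' @param annotations Data frame from [read_annotation_table()].
#' @return The pair table with `annotation` and `kegg` populated where a
#'   match exists (`kegg` rendered as `;`-separated `id:name` entries).
#' @export
attach_annotations <- function(pairs, annotations) {
  if (!nrow(pairs)) return(pairs)
  idx <- match(pairs$gene_id, annotations$gene_id)
  hit <- !is.na(idx)
  pairs$annotation[hit] <- annotations$description[idx[hit]]
  pairs$kegg[hit] <- vapply(idx[hit], function(i) {
    kp <- annotations$kegg_pathways[[i]]
    if (!nrow(kp)) return(NA_character_)
    paste(paste0(kp$pathway_id, ":", kp$pathway_name), collapse = ";")
  }, character(1))
  pairs
}

#' miRNA catalog total
#'
#' @param conserved,novel Non-negative counts of conserved and novel
#'   miRNAs.
#' @return List with `conserved`, `novel` and their `total`.
#' @export
catalog_summary <- function(conserved, novel) {
  conserved <- assert_count(conserved, "conserved")
  novel <- assert_count(novel, "novel")
  list(conserved = conserved, novel = novel, total = conserved + novel)
}

#' Coding-sequence fraction
#'
#' Percentage of assembled transcripts with a predicted coding sequence,
#' rounded half-up to two decimals.
#'
#' @param n_coding,n_total Transcript counts.
#' @return Percentage.
#' @export
coding_fraction <- function(n_coding, n_total) {
  if (n_total <= 0) stopf("n_total must be > 0")
  round_half_up(100 * n_coding / n_total, 2)
}

#' Write the integrated pair table
#'
#' Tab-separated output mirroring the field's pair-table shape
#' (comparison, miRNA, its regulation, target gene, annotation, its
#' regulation) extended with the reversed flag, cleavage category,
#' abundance and duplex score; rows sorted by (`comparison`, `mirna_id`,
#' `gene_id`). An empty pair list yields a header-only file.
#'
#' @param pairs Pair table from [join_pairs()] (optionally annotated).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs_table <- function(pairs, path) {
  cols <- c("comparison", "mirna_id", "mirna_direction", "gene_id",
            "annotation", "gene_direction", "reversed", "category",
            "abundance", "score", "kegg")
  out <- pairs[order(pairs$comparison, pairs$mirna_id, pairs$gene_id),
               cols, drop = FALSE]
  write_tsv(out, path)
}
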