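#' Validate a facial-descriptor set
#'
#' A descriptor set is the image representation of one patient: 12 vectors
#' of 512 dimensions (model ensemble x test-time augmentation), each of unit
#' Euclidean norm.
#'
#' @param m Numeric matrix, 12 x 512, unit-norm rows (tolerance 1e-6).
#' @return The matrix, invisibly, with class `phenodx_descriptors`.
#' @export
descriptor_set <- function(m) {
  if (!is.matrix(m) || nrow(m) != 12L || ncol(m) != 512L) {
    stop("a descriptor set must be a 12 x 512 matrix (got ",
         paste(dim(m), collapse = " x "), ")")
  }
  nrm <- sqrt(rowSums(m^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("descriptor rows must have unit norm")
  class(m) <- c("phenodx_descriptors", class(m))
  invisible(m)
}

#' Average cosine distance between two descriptor sets
#'
#' The 12 descriptors are paired by index (ensemble member i of one image
#' against ensemble member i of the other) and the cosine distances
#' `1 - cos(a_i, b_i)` are averaged, giving a distance in `[0, 2]`:
#' 0 for identical sets, 1 for orthogonal pairs, 2 for antipodal pairs.
#'
#' @param a,b 12 x 512 unit-row matrices.
#' @return Scalar distance in `[0, 2]`.
#' @export
image_distance <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("descriptor dimension mismatch")
  mean(1 - rowSums(a * b))
}

#' Gestalt gene scores from a solved-case gallery
#'
#' For a test patient's descriptor set and a gallery of previously solved
#' patients (each labelled with their causal gene), computes a per-gene
#' similarity score `1 - min(image_distance)` over that gene's gallery
#' patients, i.e. each gene scores as its most similar representative
#' (max-similarity aggregation). Genes in the vocabulary without any gallery
#' patient get `NA` (no gestalt evidence).
#'
#' Because the descriptor pairing is index-matched and the rows have unit
#' norm, the mean cosine similarity between two sets equals their flattened
#' inner product divided by 12, so the gallery is scored with a single
#' matrix product.
#'
#' @param test 12 x 512 descriptor matrix of the test patient.
#' @param gallery List of entries, each a list with `descriptors`
#'   (12 x 512 matrix) and `gene` (character).
#' @param vocabulary Character vector of genes to score (default: the genes
#'   present in the gallery).
#' @return Named numeric vector over `vocabulary`; `NA` where the gallery
#'   has no patient for the gene.
#' @export
gestalt_gene_scores <- function(test, gallery, vocabulary = NULL) {
  if (!length(gallery)) stop("gallery must be non-empty")
  genes <- vapply(gallery, `[[`, character(1), "gene")
  gmat <- t(vapply(gallery, function(g) as.vector(g$descriptors), numeric(12L * 512L)))
  sim <- drop(gmat %*% as.vector(test)) / 12  # mean index-matched cosine
  best <- tapply(sim, genes, max)
  if (is.null(vocabulary)) vocabulary <- sort(unique(genes))
  out <- stats::setNames(rep(NA_real_, length(vocabulary)), vocabulary)
  hit <- intersect(names(best), vocabulary)
  out[hit] <- best[hit]
  out
}

#' Molecular gene scores from a variant table
#'
#' Drops common variants (population allele frequency above the cutoff) and
#' takes the highest deleteriousness score per gene among the survivors.
#' Genes with no surviving variant get `NA`.
#'
#' @param variants Data frame with columns `gene`, `af` (allele frequency,
#'   `>= 0`) and `score` (e.g. a CADD-style deleteriousness score).
#' @param af_cutoff Allele-frequency cutoff (default 0.01).
#' @param vocabulary Optional gene vocabulary for the output vector.
#' @return Named numeric vector; `NA` for genes without surviving variants.
#' @export
molecular_gene_scores <- function(variants, af_cutoff = 0.01, vocabulary = NULL) {
  stopifnot(all(c("gene", "af", "score") %in% names(variants)))
  if (any(variants$af < 0)) stop("negative allele frequency")
  keep <- variants[variants$af <= af_cutoff, , drop = FALSE]
  best <- if (nrow(keep)) tapply(keep$score, keep$gene, max) else numeric(0)
  if (is.null(vocabulary)) vocabulary <- sort(unique(variants$gene))
  out <- stats::setNames(rep(NA_real_, length(vocabulary)), vocabulary)
  hit <- intersect(names(best), vocabulary)
  out[hit] <- best[hit]
  out
}

#' Phenotype feature scores per gene
#'
#' Scores each gene by the best-match-average semantic similarity between
#' the patient's terms and the gene's phenotype annotations (see
#' [patient_similarity()]). Externally computed feature scores can be used
#' instead anywhere a named score vector is accepted.
#'
#' @param terms Patient term ids.
#' @param gene_annotations Named list: gene -> character vector of term ids.
#' @param index A `phenodx_ontology` with IC attached.
#' @param vocabulary Optional gene vocabulary for the output vector.
#' @return Named numeric vector; `NA` for genes without annotations.
#' @export
feature_gene_scores <- function(terms, gene_annotations, index, vocabulary = NULL) {
  if (is.null(vocabulary)) vocabulary <- names(gene_annotations)
  out <- stats::setNames(rep(NA_real_, length(vocabulary)), vocabulary)
  for (g in intersect(vocabulary, names(gene_annotations))) {
    ann <- gene_annotations[[g]]
    if (length(ann)) out[g] <- patient_similarity(index, terms, ann)
  }
  out
}

#' Fuse score channels into a single per-gene score
#'
#' Each channel is min-max normalized to `[0, 1]` across the patient's gene
#' list; missing scores become 0 after normalization (absent evidence is a
#' neutral floor, never a penalty below no-evidence genes); a degenerate
#' (constant) channel normalizes to all zeros. The fused score is the
#' weighted sum of the normalized channels (equal weights by default). The
#' fusion is therefore invariant to affine rescaling of any input channel.
#'
#' @param table Data frame with a `gene` column and one numeric column per
#'   channel (`NA` = missing).
#' @param weights Named numeric weights, names matching channel columns
#'   (default: equal weight 1 for every channel present).
#' @return The input with normalized channel columns (`<channel>_norm`) and
#'   a `fused` column appended.
#' @export
fuse_scores <- function(table, weights = NULL) {
  channels <- setdiff(names(table), "gene")
  channels <- channels[vapply(table[channels], is.numeric, logical(1))]
  if (!length(channels) || all(vapply(table[channels], function(x) all(is.na(x)), logical(1)))) {
    stop("at least one score channel must contain a value")
  }
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(channels)), channels)
  fused <- numeric(nrow(table))
  for (ch in channels) {
    v <- table[[ch]]
    rng <- range(v, na.rm = TRUE)
    norm <- if (!is.finite(rng[1]) || rng[2] - rng[1] < .Machine$double.eps) {
      rep(0, length(v))  # degenerate or all-missing channel
    } else {
      (v - rng[1]) / (rng[2] - rng[1])
    }
    norm[is.na(norm)] <- 0
    table[[paste0(ch, "_norm")]] <- norm
    w <- if (ch %in% names(weights)) weights[[ch]] else 0
    fused <- fused + w * norm
  }
  table$fused <- fused
  table
}

#' Rank genes by descending fused score
#'
#' Ties receive the worst (largest) rank of the tie group, so a tied causal
#' gene is never flattered by an optimistic tie-break.
#'
#' @param scores Named numeric vector, or a data frame with `gene` and
#'   `fused` columns.
#' @return Data frame with `gene`, `score`, `rank`, ordered by rank.
#' @export
rank_genes <- function(scores) {
  if (is.data.frame(scores)) {
    scores <- stats::setNames(scores$fused, scores$gene)
  }
  rk <- rank(-scores, ties.method = "max")
  out <- data.frame(gene = names(scores), score = unname(scores),
                    rank = as.integer(rk), row.names = NULL)
  out[order(out$rank, out$gene), , drop = FALSE]
}

#' Top-k accuracy curve with bootstrap confidence intervals
#'
#' The fraction of benchmark cases whose causal gene is ranked within the
#' top k, for each requested k, with case-level percentile bootstrap CIs.
#' Cases whose causal gene is outside the vocabulary (rank `NA`) count as
#' never hit and are flagged.
#'
#' @param causal_ranks Integer vector: the rank of each case's causal gene
#'   (`NA` = causal gene not in the vocabulary).
#' @param ks Integer vector of k values (default `1:100`).
#' @param B Bootstrap replicates (default 1000); `B = 0` skips CIs.
#' @param seed Bootstrap seed (default 1).
#' @param conf Confidence level (default 0.95).
#' @return An object of class `phenodx_accuracy`: data frame with `k`,
#'   `accuracy`, `lo`, `hi`; attributes `n`, `B`, `seed`, `n_missing`.
#' @export
topk_accuracy <- function(causal_ranks, ks = 1:100, B = 1000, seed = 1L,
                          conf = 0.95) {
  n <- length(causal_ranks)
  if (!n) stop("no benchmark cases")
  n_missing <- sum(is.na(causal_ranks))
  if (n_missing) {
    warning(n_missing, " case(s) have a causal gene outside the vocabulary; counted as never hit")
  }
  r <- ifelse(is.na(causal_ranks), Inf, causal_ranks)
  acc <- vapply(ks, function(k) mean(r <= k), numeric(1))
  lo <- hi <- rep(NA_real_, length(ks))
  if (B > 0) {
    set.seed(seed)
    boot <- replicate(B, {
      ri <- r[sample.int(n, n, replace = TRUE)]
      vapply(ks, function(k) mean(ri <= k), numeric(1))
    })
    if (length(ks) == 1L) boot <- matrix(boot, nrow = 1L)
    a <- (1 - conf) / 2
    qs <- apply(boot, 1, stats::quantile, probs = c(a, 1 - a))
    lo <- qs[1, ]
    hi <- qs[2, ]
  }
  structure(data.frame(k = ks, accuracy = acc, lo = lo, hi = hi),
            class = c("phenodx_accuracy", "data.frame"),
            n = n, B = B, seed = as.integer(seed), n_missing = n_missing)
}

#' Score and rank all genes for one case
#'
#' Assembles the three evidence channels into a gene score table, fuses them
#' and ranks the vocabulary.
#'
#' @param gestalt,feature,molecular Named numeric score vectors (any may be
#'   `NULL` to drop the channel); names are gene symbols.
#' @param vocabulary Gene vocabulary (default: union of channel names).
#' @param weights Fusion weights passed to [fuse_scores()].
#' @return List with `table` (gene score table incl. fused scores) and
#'   `ranking` (output of [rank_genes()]).
#' @export
prioritize_case <- function(gestalt = NULL, feature = NULL, molecular = NULL,
                            vocabulary = NULL, weights = NULL) {
  chans <- Filter(Negate(is.null),
                  list(gestalt = gestalt, feature = feature, molecular = molecular))
  if (!length(chans)) stop("at least one score channel is required")
  if (is.null(vocabulary)) {
    vocabulary <- sort(unique(unlist(lapply(chans, names), use.names = FALSE)))
  }
  tab <- data.frame(gene = vocabulary)
  for (nm in names(chans)) {
    v <- stats::setNames(rep(NA_real_, length(vocabulary)), vocabulary)
    hit <- intersect(names(chans[[nm]]), vocabulary)
    v[hit] <- chans[[nm]][hit]
    tab[[nm]] <- unname(v)
  }
  tab <- fuse_scores(tab, weights)
  list(table = tab, ranking = rank_genes(tab))
}
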