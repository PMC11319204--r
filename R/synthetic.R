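#' Default simulation parameters
#'
#' The defaults encode the study conditions the package's analyses assume:
#' cohort size 1,577 with 268 adults; five sequencing sites; six disease
#' categories with neurodevelopmental disorders most frequent; on average
#' five phenotype terms per patient; overall diagnostic yield calibrated to
#' 32%; consanguinity fraction 144/1,577 with autozygosity above the 2%
#' threshold; de novo variants the dominant cause in the low-autozygosity
#' stratum (hazard 0.54 versus 0.14 recessive); a planted sevenfold
#' recessive-hazard multiplier in the high-autozygosity stratum; a 2%
#' dual-diagnosis rate among solved cases and a 1.3% parental-mosaicism rate
#' among de novo diagnoses; a gene vocabulary of 816 disease genes for
#' prioritization benchmarks.
#'
#' @param n Cohort size.
#' @param seed Master seed; the seed fully determines every output.
#' @param ... Overrides for any default listed below.
#' @return A list of class `phenodx_sim_params`.
#' @export
sim_params <- function(n = 1577, seed = 1L, ...) {
  p <- list(
    n = n,
    seed = as.integer(seed),
    adult_fraction = 268 / 1577,
    sites = paste0("lab", 1:5),
    categories = c("neurodevelopmental", "neuromuscular", "organ",
                   "metabolic", "immune_hematologic", "cardiovascular"),
    category_prevalence = c(0.45, 0.20, 0.12, 0.10, 0.08, 0.05),
    pedia_fraction = 224 / 1577,
    mean_terms = 5,
    pool_purity = 0.8,
    consanguinity_fraction = 144 / 1577,
    yield_target = 499 / 1577,
    intercept = NULL,             # calibrated to yield_target when NULL
    beta = NULL,                  # planted subcategory coefficients; default below
    n_causal_subcats = 8,
    beta_magnitude = 1,
    conf_effects = c(age_adult = -0.2, sex_male = 0, consent_image = 0.3),
    moi_hazard = c(AD = 0.24, AD_denovo = 0.54, AR = 0.14, XL = 0.06, MT = 0.02),
    recessive_multiplier = 7,
    ar_hom_fraction_low = 0.15,
    ar_hom_fraction_high = 0.9,
    dual_rate = 0.02,
    mosaic_rate = 0.013,
    novel_rate = 0.12,
    plp_prob = 0.8,
    lof_given_nonplp = 0.5,
    nmd_escape_given_lof = 0.3,
    year_range = c(1960, 2020),
    recency_skew = 2,
    vocab_size = 816,
    gallery_genes = 150,
    gallery_per_gene = 3,
    descriptor_noise = 0.1,
    gestalt_boost = 0.8,
    feature_boost = 2,
    molecular_boost = 15,
    background_genes_per_case = 30,
    af_common_fraction = 0.3,
    af_cutoff = 0.01
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  if (is.null(p$beta)) {
    b <- numeric(49)
    idx <- seq_len(p$n_causal_subcats)
    sgn <- rep(c(1, 1, 1, -1), length.out = p$n_causal_subcats)
    b[idx] <- sgn * p$beta_magnitude
    p$beta <- b
  }
  structure(p, class = "phenodx_sim_params")
}

#' Generate a synthetic phenotype ontology, group map and gene catalog
#'
#' Builds a random single-rooted DAG with 12 higher-order-group nodes under
#' the root and 49 subcategory nodes under those, then hangs the remaining
#' terms below the subcategory subtrees (with occasional second parents
#' inside the same subtree). The term-to-subcategory mapping covers most but
#' not all terms (a held-out share exercises closure-based assignment). Each
#' gene in the catalog is annotated with terms drawn mainly from one
#' subcategory subtree. The ontology is emitted as OBO text and re-read
#' through the package's own parser, so every generated ontology round-trips
#' the file interface.
#'
#' @param n_terms Total number of terms (>= 62; default 400).
#' @param branching Mean extra-children factor controlling subtree sizes
#'   (default 3; retained for interface symmetry).
#' @param seed Seed (default 1).
#' @param n_genes Catalog size (default 816).
#' @param mapped_fraction Share of subtree terms included in the mapping
#'   table (default 0.9).
#' @return List with `index` (`phenodx_ontology`), `map`
#'   (`phenodx_groupmap`), `genes` (named list of annotation term sets),
#'   `gene_subcat` (named character: gene -> primary subcategory) and
#'   `obo_text` (character vector of the OBO serialization).
#' @export
make_ontology <- function(n_terms = 400, branching = 3, seed = 1L,
                          n_genes = 816, mapped_fraction = 0.9) {
  if (n_terms < 62) stop("need at least 62 terms to host 12 groups and 49 subcategories")
  if (branching < 1) stop("branching must be >= 1")
  set.seed(seed)
  id <- function(i) sprintf("HP:%07d", i)
  root <- id(1)
  groups <- id(2:13)
  subcats <- id(14:62)
  sub_parent <- sample(rep_len(groups, length(subcats)))
  parents <- list()
  parents[[root]] <- character(0)
  for (g in groups) parents[[g]] <- root
  for (k in seq_along(subcats)) parents[[subcats[k]]] <- sub_parent[k]

  # descendant terms: primary parent from the already-built subtree
  subtree_of <- stats::setNames(subcats, subcats)
  rest <- if (n_terms > 62) id(63:n_terms) else character(0)
  for (t in rest) {
    host <- sample(names(subtree_of), 1)
    parents[[t]] <- host
    if (stats::runif(1) < 0.2) {  # occasional second parent, same subtree
      same <- names(subtree_of)[subtree_of == subtree_of[[host]]]
      extra <- setdiff(same, host)
      if (length(extra)) parents[[t]] <- c(parents[[t]], sample(extra, 1))
    }
    subtree_of[[t]] <- subtree_of[[host]]
  }

  obo <- c("format-version: 1.2", "")
  for (t in names(parents)) {
    isa <- if (length(parents[[t]])) paste0("is_a: ", parents[[t]]) else character(0)
    obo <- c(obo, "[Term]", paste0("id: ", t), paste0("name: term ", t), isa, "")
  }
  index <- read_obo(textConnection(obo))

  sub_labels <- stats::setNames(paste0("subcat_", sprintf("%02d", seq_along(subcats))), subcats)
  grp_labels <- stats::setNames(paste0("group_", sprintf("%02d", seq_along(groups))), groups)
  mappable <- names(subtree_of)  # subcategory nodes and their descendants
  held_out <- sample(setdiff(mappable, subcats),
                     round((1 - mapped_fraction) * (length(mappable) - length(subcats))))
  listed <- setdiff(mappable, held_out)
  term2sub <- stats::setNames(unname(sub_labels[subtree_of[listed]]), listed)
  sub2group <- stats::setNames(unname(grp_labels[sub_parent]), unname(sub_labels))
  map <- group_map(term2sub, sub2group)

  genes <- vector("list", n_genes)
  gene_names <- sprintf("GENE%04d", seq_len(n_genes))
  names(genes) <- gene_names
  gene_subcat <- character(n_genes)
  by_sub <- split(names(subtree_of), unname(sub_labels[subtree_of]))
  for (i in seq_len(n_genes)) {
    sc <- sample(names(by_sub), 1)
    pool <- by_sub[[sc]]
    k <- min(length(pool), sample(3:8, 1))
    ann <- sample(pool, k)
    if (stats::runif(1) < 0.5) ann <- c(ann, sample(mappable, 1))
    genes[[i]] <- unique(ann)
    gene_subcat[i] <- sc
  }
  names(gene_subcat) <- gene_names

  list(index = index, map = map, genes = genes,
       gene_subcat = gene_subcat, obo_text = obo)
}

# higher-order group -> disease category (round-robin, deterministic)
group_category <- function(map, categories) {
  stats::setNames(categories[(seq_along(map$groups) - 1L) %% length(categories) + 1L],
                  map$groups)
}

#' Simulate a complete synthetic cohort
#'
#' Draws covariates, phenotype terms (group-specific pools), solved status
#' from a planted logistic model on the subcategory indicators, and for
#' solved cases one (or, at the dual-diagnosis rate, two) molecular
#' diagnoses whose mode of inheritance is drawn conditional on the
#' autozygosity stratum: the de novo hazard is identical in both strata
#' while the recessive hazard is multiplied by the planted burden
#' multiplier, and the homozygous share within recessive diagnoses is much
#' larger under consanguinity. Compound-heterozygous diagnoses carry two
#' variant records; parental mosaicism is injected into de novo diagnoses
#' at its target rate.
#'
#' @param params A `phenodx_sim_params`.
#' @param ontology Output of [make_ontology()]; generated from
#'   `params$seed` when `NULL`.
#' @return An object of class `phenodx_cohort`: list with `patients`
#'   (data frame incl. a `terms` list column), `diagnoses`, `variants`,
#'   `subcat` and `higher_group` indicator matrices, `ontology`, `params`.
#' @export
simulate_cohort <- function(params = sim_params(), ontology = NULL) {
  if (is.null(ontology)) ontology <- make_ontology(seed = params$seed,
                                                   n_genes = params$vocab_size)
  set.seed(params$seed)
  n <- params$n
  map <- ontology$map
  index <- ontology$index

  patients <- data.frame(
    id = sprintf("P%05d", seq_len(n)),
    age_class = ifelse(stats::runif(n) < params$adult_fraction, "adult", "child"),
    sex = ifelse(stats::runif(n) < 0.5, "m", "f"),
    site = sample(params$sites, n, replace = TRUE),
    category = sample(params$categories, n, replace = TRUE,
                      prob = params$category_prevalence),
    pedia = stats::runif(n) < params$pedia_fraction,
    stringsAsFactors = FALSE
  )
  consang <- stats::runif(n) < params$consanguinity_fraction
  patients$autozygosity <- ifelse(
    consang,
    pmin(0.25, 0.02 + stats::rexp(n, rate = 25)),
    pmin(0.02, stats::rbeta(n, 1, 150))
  )

  gcat <- group_category(map, params$categories)
  term_by_group <- split(names(map$term2sub),
                         unname(map$sub2group[map$term2sub]))
  all_listed <- names(map$term2sub)
  patients$terms <- lapply(seq_len(n), function(i) {
    pool <- unlist(term_by_group[names(gcat)[gcat == patients$category[i]]],
                   use.names = FALSE)
    nt <- 1L + stats::rpois(1, params$mean_terms - 1)
    src <- ifelse(stats::runif(nt) < params$pool_purity, "pool", "any")
    unique(c(sample(pool, sum(src == "pool"), replace = TRUE),
             sample(all_listed, sum(src == "any"), replace = TRUE)))
  })

  gm <- assign_groups_matrix(patients$terms, map, index)
  colnames(gm$subcategory) <- map$subcategories
  eta0 <- drop(gm$subcategory %*% params$beta) +
    params$conf_effects["age_adult"] * (patients$age_class == "adult") +
    params$conf_effects["sex_male"] * (patients$sex == "m") +
    params$conf_effects["consent_image"] * patients$pedia
  intercept <- params$intercept
  if (is.null(intercept)) {
    intercept <- stats::uniroot(
      function(c) mean(stats::plogis(c + eta0)) - params$yield_target,
      interval = c(-15, 15)
    )$root
  }
  patients$solved <- as.integer(stats::runif(n) < stats::plogis(intercept + eta0))

  # diagnoses, MOI conditional on autozygosity stratum
  hz <- params$moi_hazard
  draw_moi <- function(high) {
    h <- hz
    if (high) h["AR"] <- h["AR"] * params$recessive_multiplier
    cat6 <- sample(names(h), 1, prob = h / sum(h))
    if (cat6 == "AR") {
      phom <- if (high) params$ar_hom_fraction_high else params$ar_hom_fraction_low
      if (stats::runif(1) < phom) "AR_hom" else "AR_comphet"
    } else cat6
  }
  sample_year <- function(k) {
    yrs <- params$year_range[1]:params$year_range[2]
    u <- (yrs - min(yrs)) / diff(range(yrs))
    sample(yrs, k, replace = TRUE, prob = exp(params$recency_skew * u))
  }
  genes_by_cat <- split(names(ontology$genes),
                        unname(gcat[map$sub2group[ontology$gene_subcat]]))

  dx_rows <- list()
  var_rows <- list()
  dx_id <- 0L
  for (i in which(patients$solved == 1L)) {
    high <- patients$autozygosity[i] > 0.02
    ndx <- 1L + (stats::runif(1) < params$dual_rate)
    pool <- genes_by_cat[[patients$category[i]]]
    if (is.null(pool) || length(pool) < 2L) pool <- names(ontology$genes)
    gsel <- sample(pool, ndx)
    for (d in seq_len(ndx)) {
      dx_id <- dx_id + 1L
      moi <- draw_moi(high)
      mosaic <- moi == "AD_denovo" && stats::runif(1) < params$mosaic_rate
      novel <- stats::runif(1) < params$novel_rate
      yr <- sample_year(1)
      if (novel) yr <- max(yr, params$year_range[2] - 5L)
      dx_rows[[dx_id]] <- data.frame(
        dx_id = dx_id, patient_id = patients$id[i], gene = gsel[d], moi = moi,
        de_novo = moi == "AD_denovo", mosaic = mosaic,
        year = yr, novel = novel, stringsAsFactors = FALSE
      )
      nv <- if (moi == "AR_comphet") 2L else 1L
      cls <- ifelse(stats::runif(nv) < params$plp_prob,
                    sample(c("P", "LP"), nv, replace = TRUE), "VUS")
      lof <- stats::runif(nv) < ifelse(cls == "VUS", params$lof_given_nonplp, 0.5)
      var_rows[[dx_id]] <- data.frame(
        dx_id = dx_id, class = cls, lof = lof,
        nmd_escape = lof & stats::runif(nv) < params$nmd_escape_given_lof,
        af = stats::runif(nv, 0, 0.004), stringsAsFactors = FALSE
      )
    }
  }
  diagnoses <- if (length(dx_rows)) do.call(rbind, dx_rows) else
    data.frame(dx_id = integer(0), patient_id = character(0), gene = character(0),
               moi = character(0), de_novo = logical(0), mosaic = logical(0),
               year = integer(0), novel = logical(0))
  variants <- if (length(var_rows)) do.call(rbind, var_rows) else
    data.frame(dx_id = integer(0), class = character(0), lof = logical(0),
               nmd_escape = logical(0), af = numeric(0))

  structure(list(
    patients = patients, diagnoses = diagnoses, variants = variants,
    subcat = gm$subcategory, higher_group = gm$higher_group,
    ontology = ontology, params = params, intercept = intercept
  ), class = "phenodx_cohort")
}

#' @export
print.phenodx_cohort <- function(x, ...) {
  cat("<phenodx_cohort> ", nrow(x$patients), " patients, ",
      sum(x$patients$solved), " solved, ", nrow(x$diagnoses),
      " diagnoses (seed ", x$params$seed, ")\n", sep = "")
  invisible(x)
}

# draw one unit vector per row
unit_rows <- function(m) m / sqrt(rowSums(m^2))

#' Simulate prioritization inputs for a benchmark
#'
#' For solved benchmark cases, generates the three evidence channels over
#' the fixed gene vocabulary: facial descriptor sets for a solved-case
#' gallery clustered by causal gene (each disorder has a unit-norm center;
#' gallery and test descriptors are Gaussian perturbations of it,
#' renormalized) from which the gestalt channel is computed; a per-case
#' variant table with a controlled share of common variants (exercising the
#' allele-frequency filter) from which the molecular channel is computed;
#' and a feature channel drawn from a null distribution. The causal gene is
#' boosted in each channel: additively for the feature and molecular
#' channels, and via resemblance of the test image to the causal disorder
#' center (to within `descriptor_noise`) for the gestalt channel. Setting a
#' boost to 0 switches the channel off and leaves the causal gene fully
#' exchangeable with background genes (its evidence coverage is then not
#' forced), so a zero-boost benchmark has no-information top-k accuracy.
#'
#' @param cohort A `phenodx_cohort`.
#' @param params Defaults to `cohort$params`.
#' @param n_cases Number of benchmark cases (default: all solved patients,
#'   capped at 200).
#' @return An object of class `phenodx_benchmark`: list with `cases`
#'   (data frame: `patient_id`, `causal_gene`, per-channel and fused causal
#'   ranks), `tables` (per-case gene score tables), `gallery`,
#'   `descriptors` (per-case test descriptor sets), `variant_tables`,
#'   `vocabulary`, `seed`.
#' @export
simulate_scores <- function(cohort, params = cohort$params, n_cases = NULL) {
  set.seed(params$seed + 1L)
  vocab <- names(cohort$ontology$genes)
  solved_ids <- cohort$patients$id[cohort$patients$solved == 1L]
  first_dx <- cohort$diagnoses[!duplicated(cohort$diagnoses$patient_id), ]
  rownames(first_dx) <- first_dx$patient_id
  if (is.null(n_cases)) n_cases <- min(200L, length(solved_ids))
  ids <- solved_ids[seq_len(min(n_cases, length(solved_ids)))]
  causal <- first_dx[ids, "gene"]

  centers <- unit_rows(matrix(stats::rnorm(length(vocab) * 512), ncol = 512,
                              dimnames = list(vocab, NULL)))
  # evidence coverage: under a zero boost the causal gene is not forced into
  # the gallery/variant tables, keeping it exchangeable with background genes
  gal_genes <- sample(vocab, min(params$gallery_genes, length(vocab)))
  if (params$gestalt_boost > 0) gal_genes <- unique(c(causal, gal_genes))
  gallery <- list()
  for (g in gal_genes) {
    for (r in seq_len(params$gallery_per_gene)) {
      noise <- matrix(stats::rnorm(12 * 512, sd = params$descriptor_noise), 12, 512)
      d <- unit_rows(matrix(centers[g, ], nrow = 12, ncol = 512, byrow = TRUE) + noise)
      gallery[[length(gallery) + 1L]] <- list(descriptors = d, gene = g)
    }
  }

  tables <- vector("list", length(ids))
  descr <- vector("list", length(ids))
  vtabs <- vector("list", length(ids))
  ranks <- matrix(NA_integer_, length(ids), 4,
                  dimnames = list(ids, c("gestalt", "feature", "molecular", "fused")))
  for (k in seq_along(ids)) {
    if (params$gestalt_boost > 0) {
      # test image resembles the causal disorder up to descriptor noise
      ctr <- matrix(centers[causal[k], ], nrow = 12, ncol = 512, byrow = TRUE)
      test <- unit_rows(ctr + matrix(stats::rnorm(12 * 512, sd = params$descriptor_noise), 12, 512))
    } else {
      test <- unit_rows(matrix(stats::rnorm(12 * 512), 12, 512))
    }
    descr[[k]] <- test
    gestalt <- gestalt_gene_scores(test, gallery, vocab)

    genes_v <- sample(vocab, params$background_genes_per_case)
    if (params$molecular_boost > 0) genes_v <- unique(c(genes_v, causal[k]))
    common <- stats::runif(length(genes_v)) < params$af_common_fraction
    vt <- data.frame(
      patient = ids[k], gene = genes_v,
      af = ifelse(common, stats::runif(length(genes_v), 0.02, 0.5),
                  stats::runif(length(genes_v), 0, 0.005)),
      score = stats::runif(length(genes_v), 0, 30)
    )
    ci <- which(genes_v == causal[k])
    if (params$molecular_boost > 0 && length(ci)) {
      vt$af[ci] <- stats::runif(1, 0, 0.005)  # causal variant is rare
      vt$score[ci] <- vt$score[ci] + params$molecular_boost
    }
    vtabs[[k]] <- vt
    molecular <- molecular_gene_scores(vt, params$af_cutoff, vocab)

    feature <- stats::setNames(stats::runif(length(vocab)), vocab)
    feature[causal[k]] <- feature[causal[k]] + params$feature_boost

    pc <- prioritize_case(gestalt = gestalt, feature = feature,
                          molecular = molecular, vocabulary = vocab)
    tables[[k]] <- pc$table
    ranks[k, "fused"] <- causal_rank(pc$ranking, causal[k])
    for (ch in c("gestalt", "feature", "molecular")) {
      wts <- stats::setNames(as.numeric(c("gestalt", "feature", "molecular") == ch),
                             c("gestalt", "feature", "molecular"))
      ranks[k, ch] <- causal_rank(
        prioritize_case(gestalt = gestalt, feature = feature,
                        molecular = molecular, vocabulary = vocab,
                        weights = wts)$ranking, causal[k])
    }
  }
  structure(list(
    cases = data.frame(patient_id = ids, causal_gene = causal,
                       rank_gestalt = ranks[, "gestalt"],
                       rank_feature = ranks[, "feature"],
                       rank_molecular = ranks[, "molecular"],
                       rank_fused = ranks[, "fused"], row.names = NULL),
    tables = tables, gallery = gallery, descriptors = descr,
    variant_tables = vtabs, vocabulary = vocab, seed = params$seed
  ), class = "phenodx_benchmark")
}

#' Rank of a given gene in a ranking table
#'
#' @param ranking Output of [rank_genes()].
#' @param gene Gene symbol.
#' @return Integer rank, or `NA` if the gene is absent.
#' @export
causal_rank <- function(ranking, gene) {
  i <- match(gene, ranking$gene)
  if (is.na(i)) NA_integer_ else ranking$rank[i]
}

#' Simulate a long-tailed gene submission-count table
#'
#' Submission counts follow a rank-based power law (Zipf exponent `alpha`)
#' with mild lognormal jitter; first gene-disease-association years are
#' drawn with a configurable recency skew (larger values put more mass on
#' recent years).
#'
#' @param n_genes Number of genes (>= 100).
#' @param zipf_alpha Power-law exponent (default 1.5).
#' @param year_range Length-2 year interval (default 1990-2020).
#' @param seed Seed (default 1).
#' @param recency_skew Exponential tilt of the year distribution (default 2).
#' @param top_count Expected count of the top-ranked gene (default 10000).
#' @return Data frame with `gene`, `plp_submissions`, `first_assoc_year`.
#' @export
simulate_clinvar <- function(n_genes = 1000, zipf_alpha = 1.5,
                             year_range = c(1990, 2020), seed = 1L,
                             recency_skew = 2, top_count = 10000) {
  if (n_genes < 100) stop("need at least 100 genes")
  set.seed(seed)
  i <- seq_len(n_genes)
  counts <- pmax(1, round(top_count * i^(-zipf_alpha) *
                            exp(stats::rnorm(n_genes, sd = 0.3))))
  yrs <- year_range[1]:year_range[2]
  u <- (yrs - min(yrs)) / diff(range(yrs))
  data.frame(
    gene = sprintf("CVG%05d", i),
    plp_submissions = counts,
    first_assoc_year = sample(yrs, n_genes, replace = TRUE,
                              prob = exp(recency_skew * u))
  )
}
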