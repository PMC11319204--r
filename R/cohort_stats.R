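#' Mode-of-inheritance categories used throughout the package
#'
#' `AD` (autosomal dominant, inherited or of unknown origin), `AD_denovo`
#' (autosomal dominant with a de novo variant), `AR_hom` (autosomal
#' recessive, homozygous), `AR_comphet` (autosomal recessive, compound
#' heterozygous), `XL` (X-linked), `MT` (mitochondrial).
#'
#' @export
moi_levels <- function() c("AD", "AD_denovo", "AR_hom", "AR_comphet", "XL", "MT")

# percent formatting convention: integer percent for rates >= 5%, one
# decimal below 5%
round_percent <- function(x) {
  p <- 100 * x
  ifelse(p < 5, round(p, 1), round(p))
}

#' Diagnostic yield per group with pairwise Fisher tests
#'
#' Per-group solved counts and yield fractions plus all pairwise two-sided
#' Fisher's exact tests on the 2x2 solved-by-group tables, Bonferroni
#' corrected over the number of pairwise tests.
#'
#' @param solved 0/1 vector (one entry per case).
#' @param group Factor/character group assignment of each case.
#' @return List of class `phenodx_yield_table` with `groups` (data frame:
#'   `group`, `solved`, `total`, `yield`, `yield_percent`) and `pairwise`
#'   (data frame: `group_a`, `group_b`, `odds_ratio`, `p`, `p_adjusted`).
#' @export
yield_table <- function(solved, group) {
  solved <- as.numeric(solved)
  group <- as.character(group)
  tab <- tapply(solved, group, function(s) c(sum(s), length(s)))
  empty <- vapply(tab, function(x) x[2] == 0L, logical(1))
  if (any(empty)) {
    warning("excluding empty group(s): ", paste(names(tab)[empty], collapse = ", "))
    tab <- tab[!empty]
  }
  g <- names(tab)
  groups <- data.frame(
    group = g,
    solved = vapply(tab, `[`, numeric(1), 1),
    total = vapply(tab, `[`, numeric(1), 2),
    row.names = NULL
  )
  groups$yield <- groups$solved / groups$total
  groups$yield_percent <- round_percent(groups$yield)

  pairwise <- NULL
  if (length(g) >= 2L) {
    cmb <- utils::combn(seq_along(g), 2)
    rows <- apply(cmb, 2, function(ij) {
      a <- groups[ij[1], ]
      b <- groups[ij[2], ]
      m <- matrix(c(a$solved, a$total - a$solved,
                    b$solved, b$total - b$solved), 2, byrow = TRUE)
      ft <- stats::fisher.test(m)
      data.frame(group_a = a$group, group_b = b$group,
                 odds_ratio = unname(ft$estimate), p = ft$p.value)
    })
    pairwise <- do.call(rbind, rows)
    m <- nrow(pairwise)
    pairwise$p_adjusted <- pmin(1, m * pairwise$p)
  }
  structure(list(groups = groups, pairwise = pairwise),
            class = "phenodx_yield_table")
}

#' @export
print.phenodx_yield_table <- function(x, ...) {
  print(x$groups)
  if (!is.null(x$pairwise)) {
    cat("\nPairwise two-sided Fisher tests (Bonferroni over",
        nrow(x$pairwise), "tests):\n")
    print(x$pairwise, digits = 3)
  }
  invisible(x)
}

#' Mode-of-inheritance composition of a diagnosis table
#'
#' Fractions are over all diagnoses (dual diagnoses count individually, not
#' per patient). The de novo share is reported separately.
#'
#' @param diagnoses Data frame with a `moi` column (levels of
#'   [moi_levels()]).
#' @return List with `table` (data frame: `moi`, `count`, `fraction`,
#'   `percent`), `n` and `de_novo_share`.
#' @export
moi_distribution <- function(diagnoses) {
  if (!nrow(diagnoses)) stop("diagnosis table is empty")
  bad <- setdiff(unique(diagnoses$moi), moi_levels())
  if (length(bad)) stop("unknown MOI category: ", paste(bad, collapse = ", "))
  cnt <- table(factor(diagnoses$moi, levels = moi_levels()))
  frac <- as.numeric(cnt) / nrow(diagnoses)
  list(
    table = data.frame(moi = names(cnt), count = as.integer(cnt),
                       fraction = frac, percent = round_percent(frac)),
    n = nrow(diagnoses),
    de_novo_share = frac[match("AD_denovo", names(cnt))]
  )
}

#' Stratify a cohort by autozygosity
#'
#' Splits cases at the autozygosity threshold (high means strictly greater
#' than the threshold; a case at exactly the threshold is low) and reports
#' per-stratum diagnostic yields and mode-of-inheritance compositions.
#' Cases with unknown autozygosity are excluded with a warning.
#'
#' @param patients Data frame with `id`, `solved`, `autozygosity`.
#' @param diagnoses Data frame with `patient_id`, `moi`.
#' @param threshold Autozygosity threshold (default 0.02, i.e. 2%).
#' @return List with `stratum` (named "high"/"low" per retained case),
#'   `yields` (data frame per stratum) and `composition` (list of MOI
#'   fraction vectors, one per stratum).
#' @export
autozygosity_stratify <- function(patients, diagnoses, threshold = 0.02) {
  keep <- !is.na(patients$autozygosity)
  if (any(!keep)) {
    warning("excluding ", sum(!keep), " case(s) with unknown autozygosity")
    patients <- patients[keep, , drop = FALSE]
  }
  stratum <- stats::setNames(ifelse(patients$autozygosity > threshold, "high", "low"),
                             patients$id)
  yields <- do.call(rbind, lapply(c("low", "high"), function(s) {
    p <- patients[stratum[as.character(patients$id)] == s, , drop = FALSE]
    data.frame(stratum = s, solved = sum(p$solved), total = nrow(p),
               yield = if (nrow(p)) mean(p$solved) else NA_real_)
  }))
  composition <- lapply(stats::setNames(c("low", "high"), c("low", "high")), function(s) {
    ids <- patients$id[stratum[as.character(patients$id)] == s]
    dx <- diagnoses[diagnoses$patient_id %in% ids, , drop = FALSE]
    if (!nrow(dx)) return(stats::setNames(rep(NA_real_, length(moi_levels())), moi_levels()))
    cnt <- table(factor(dx$moi, levels = moi_levels()))
    stats::setNames(as.numeric(cnt) / nrow(dx), moi_levels())
  })
  list(stratum = stratum, yields = yields, composition = composition)
}

#' De-novo-normalized recessive disease burden
#'
#' The de novo mutation rate depends on parental age but not on parental
#' relatedness, so the de novo fraction of diagnoses provides a common
#' denominator across autozygosity strata. The burden ratio
#' `R = (AR/denovo)_high / (AR/denovo)_low` estimates how many times higher
#' the recessive disease burden is in the high-autozygosity stratum; under a
#' planted multiplicative recessive hazard it recovers that multiplier.
#'
#' @param high,low Named MOI fraction vectors (as from
#'   [autozygosity_stratify()]`$composition`).
#' @param ar_categories Categories counted as recessive (default homozygous
#'   plus compound heterozygous).
#' @param denovo_category Normalizing category (default `"AD_denovo"`).
#' @return Scalar ratio R.
#' @export
denovo_normalized_burden <- function(high, low,
                                     ar_categories = c("AR_hom", "AR_comphet"),
                                     denovo_category = "AD_denovo") {
  dn_h <- sum(high[denovo_category])
  dn_l <- sum(low[denovo_category])
  if (!isTRUE(dn_h > 0) || !isTRUE(dn_l > 0)) {
    stop("de novo fraction must be positive in both strata")
  }
  (sum(high[ar_categories], na.rm = TRUE) / dn_h) /
    (sum(low[ar_categories], na.rm = TRUE) / dn_l)
}

#' Is a recessive diagnosis amenable to carrier screening?
#'
#' A recessive diagnosis could have been anticipated by expanded carrier
#' screening if its variants would have been reportable in a healthy
#' carrier: a homozygous variant qualifies if it was classified
#' pathogenic/likely pathogenic (P/LP) at the reference date, or is a
#' predicted loss-of-function variant not predicted to escape
#' nonsense-mediated decay. For compound-heterozygous diagnoses the strict
#' reading requires both variants individually P/LP (default); with
#' `strict_comphet = FALSE` each variant may instead qualify via the
#' LoF-without-NMD-escape route.
#'
#' @param moi `"AR_hom"` or `"AR_comphet"` (anything else is an error).
#' @param variant_class Character vector of reference-date classifications
#'   (`"P"`, `"LP"`, `"VUS"`, ...), one per variant (1 for hom, 2 for
#'   comp-het).
#' @param lof Logical vector: predicted loss of function.
#' @param nmd_escape Logical vector: predicted to escape nonsense-mediated
#'   decay.
#' @param strict_comphet Require both comp-het variants to be P/LP
#'   (default TRUE).
#' @return Logical scalar.
#' @export
carrier_amenable <- function(moi, variant_class, lof, nmd_escape,
                             strict_comphet = TRUE) {
  if (!moi %in% c("AR_hom", "AR_comphet")) {
    stop("carrier-screening amenability is defined for recessive diagnoses only")
  }
  plp <- variant_class %in% c("P", "LP")
  lof_ok <- as.logical(lof) & !as.logical(nmd_escape)
  if (moi == "AR_hom") {
    if (length(plp) != 1L) stop("homozygous diagnosis must carry exactly one variant record")
    plp[1] || lof_ok[1]
  } else {
    if (length(plp) != 2L) stop("compound-heterozygous diagnosis must carry exactly two variant records")
    if (strict_comphet) all(plp) else all(plp | lof_ok)
  }
}

#' Headline cohort rates
#'
#' Dual-diagnosis rate (patients with more than one molecular diagnosis, as
#' a share of solved cases), parental-mosaicism rate (as a share of de novo
#' diagnoses), carrier-screening amenability (share of recessive diagnoses)
#' and, when a `treated` flag is available, the share of solved cases with
#' an initiated targeted therapy. Percentages follow the reporting
#' convention of integer percent at or above 5% and one decimal below.
#'
#' @param cohort List with `patients` (columns `id`, `solved`, optionally
#'   `treated`), `diagnoses` (columns `patient_id`, `dx_id`, `moi`,
#'   `mosaic`) and `variants` (columns `dx_id`, `class`, `lof`,
#'   `nmd_escape`).
#' @param strict_comphet Passed to [carrier_amenable()].
#' @return Data frame with `rate`, `numerator`, `denominator`, `fraction`,
#'   `percent`.
#' @export
rate_summary <- function(cohort, strict_comphet = TRUE) {
  patients <- cohort$patients
  dx <- cohort$diagnoses
  n_solved <- sum(patients$solved)
  per_patient <- table(dx$patient_id)
  n_dual <- sum(per_patient >= 2L)
  dn <- dx[dx$moi == "AD_denovo", , drop = FALSE]
  n_dn <- nrow(dn)
  n_mosaic <- sum(dn$mosaic)
  ar <- dx[dx$moi %in% c("AR_hom", "AR_comphet"), , drop = FALSE]
  n_ar <- nrow(ar)
  n_amenable <- if (n_ar) sum(vapply(seq_len(n_ar), function(i) {
    v <- cohort$variants[cohort$variants$dx_id == ar$dx_id[i], , drop = FALSE]
    carrier_amenable(ar$moi[i], v$class, v$lof, v$nmd_escape, strict_comphet)
  }, logical(1))) else 0L

  # reporting digits follow the field's style per rate: whole-cohort shares
  # as integer percent, fine-grained rates with one decimal
  rows <- list(
    list("dual_diagnoses", n_dual, n_solved, 0L),
    list("parental_mosaicism", n_mosaic, n_dn, 1L),
    list("carrier_amenable", n_amenable, n_ar, 1L)
  )
  if (!is.null(patients$treated)) {
    rows <- c(rows, list(list("treated", sum(patients$treated & patients$solved),
                              n_solved, 0L)))
  }
  out <- data.frame(
    rate = vapply(rows, function(r) r[[1]], character(1)),
    numerator = vapply(rows, function(r) as.numeric(r[[2]]), numeric(1)),
    denominator = vapply(rows, function(r) as.numeric(r[[3]]), numeric(1))
  )
  out$fraction <- ifelse(out$denominator > 0, out$numerator / out$denominator, NA_real_)
  if (any(out$denominator == 0)) {
    warning("rate(s) with zero denominator left undefined: ",
            paste(out$rate[out$denominator == 0], collapse = ", "))
  }
  out$percent <- round(100 * out$fraction,
                       vapply(rows, function(r) r[[4]], integer(1)))
  out
}

#' Assign genes to ClinVar submission quartiles
#'
#' Genes are ranked by descending counts of pathogenic/likely pathogenic
#' submissions (after removing an exclusion list, e.g. the ACMG secondary
#' findings genes, to counteract submission bias). Each gene occupies an
#' interval of the cumulative submission fraction; it is assigned to the
#' quartile bin (Q1 = most submissions) containing its interval midpoint, so
#' each quartile carries approximately one quarter of the submission mass
#' (up to the largest single-gene fraction). Cohort diagnoses are then
#' tallied per quartile.
#'
#' @param counts Data frame with `gene` and `plp_submissions` (> 0).
#' @param exclude Character vector of genes to drop before ranking.
#' @param diagnoses Optional data frame with a `gene` column (one row per
#'   cohort diagnosis/variant) to tally per quartile.
#' @return List with `gene_quartile` (named integer 1-4), `quartiles` (data
#'   frame: `quartile`, `n_genes`, `submissions`, `submission_fraction`,
#'   plus `cohort_variants` and `cohort_genes` when `diagnoses` is given)
#'   and `unassigned` (cohort genes absent from the count table).
#' @export
clinvar_quartiles <- function(counts, exclude = character(0), diagnoses = NULL) {
  stopifnot(all(c("gene", "plp_submissions") %in% names(counts)))
  counts <- counts[!counts$gene %in% exclude, , drop = FALSE]
  if (any(counts$plp_submissions <= 0)) stop("submission counts must be positive")
  ord <- order(-counts$plp_submissions, counts$gene)  # deterministic tie-break
  counts <- counts[ord, , drop = FALSE]
  frac <- counts$plp_submissions / sum(counts$plp_submissions)
  hi <- cumsum(frac)
  lo <- c(0, hi[-length(hi)])
  mid <- (lo + hi) / 2
  q <- pmin(4L, pmax(1L, as.integer(ceiling(mid * 4))))
  gene_quartile <- stats::setNames(q, counts$gene)

  quartiles <- data.frame(
    quartile = 1:4,
    n_genes = as.integer(table(factor(q, levels = 1:4))),
    submissions = as.numeric(tapply(counts$plp_submissions, factor(q, levels = 1:4), sum, default = 0))
  )
  quartiles$submission_fraction <- quartiles$submissions / sum(counts$plp_submissions)

  unassigned <- character(0)
  if (!is.null(diagnoses)) {
    known <- diagnoses$gene %in% names(gene_quartile)
    unassigned <- sort(unique(diagnoses$gene[!known]))
    if (length(unassigned)) {
      warning(length(unassigned), " cohort gene(s) absent from the submission table")
    }
    dq <- gene_quartile[diagnoses$gene[known]]
    quartiles$cohort_variants <- as.integer(table(factor(dq, levels = 1:4)))
    quartiles$cohort_genes <- vapply(1:4, function(k) {
      length(unique(diagnoses$gene[known][dq == k]))
    }, integer(1))
  }
  list(gene_quartile = gene_quartile, quartiles = quartiles, unassigned = unassigned)
}

#' Compare two year-of-first-association distributions
#'
#' Two-sample two-sided Kolmogorov-Smirnov test on the years in which the
#' causal gene was first associated with disease, plus a shared histogram in
#' fixed-width (default decade-style 5-year) intervals.
#'
#' @param years_a,years_b Numeric vectors of years (non-empty).
#' @param bin_width Histogram bin width in years (default 5).
#' @return List with `statistic` (KS D), `p_value`, and `histogram`
#'   (data frame: `interval`, `count_a`, `count_b`).
#' @export
year_comparison <- function(years_a, years_b, bin_width = 5) {
  if (!length(years_a) || !length(years_b)) stop("both samples must be non-empty")
  ks <- suppressWarnings(stats::ks.test(years_a, years_b, alternative = "two.sided"))
  lo <- floor(min(years_a, years_b) / bin_width) * bin_width
  hi <- ceiling((max(years_a, years_b) + 1) / bin_width) * bin_width
  brk <- seq(lo, hi, by = bin_width)
  ca <- table(cut(years_a, breaks = brk, right = FALSE))
  cb <- table(cut(years_b, breaks = brk, right = FALSE))
  list(
    statistic = unname(ks$statistic),
    p_value = ks$p.value,
    histogram = data.frame(
      interval = paste0("[", utils::head(brk, -1), ",", brk[-1], ")"),
      count_a = as.integer(ca), count_b = as.integer(cb)
    )
  )
}
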