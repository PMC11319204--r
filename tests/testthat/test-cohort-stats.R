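test_that("yield tables reproduce worked-example fractions and trivial comparisons", {
  solved <- rep(c(1, 0), c(499, 1577 - 499))
  yt <- yield_table(solved, rep("all", 1577))
  expect_equal(yt$groups$yield_percent, 32)
  expect_equal(yt$groups$solved, 499)

  # two identical groups: OR 1, p 1
  yt2 <- yield_table(c(rep(1, 10), rep(0, 10), rep(1, 10), rep(0, 10)),
                     rep(c("a", "b"), each = 20))
  expect_equal(yt2$pairwise$odds_ratio, 1, tolerance = 1e-6)
  expect_equal(yt2$pairwise$p, 1)
  expect_equal(yt2$pairwise$p_adjusted, 1)
})

test_that("Fisher p-values equal exhaustive hypergeometric enumeration for small tables", {
  m <- matrix(c(8, 2, 3, 7), 2, byrow = TRUE)
  ft <- fisher.test(m)
  expect_equal(ft$p.value, bf_fisher_p(m), tolerance = 1e-10)

  set.seed(9)
  for (i in 1:30) {
    n <- sample(8:30, 1)
    a <- sample(0:n, 1)
    m <- matrix(c(a, n - a, sample(0:n, 1), sample(0:n, 1)), 2, byrow = TRUE)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(fisher.test(m)$p.value, bf_fisher_p(m), tolerance = 1e-9)
  }
})

test_that("MOI composition is reported over diagnoses, not patients", {
  dx <- data.frame(moi = rep(c("AD_denovo", "AD", "AR_hom", "AR_comphet", "XL", "MT"),
                             c(228, 162, 51, 60, 7, 2)))
  md <- moi_distribution(dx)
  expect_equal(md$n, 510)
  expect_equal(round(100 * md$de_novo_share), 45)
  expect_equal(sum(md$table$fraction), 1)

  all_dn <- moi_distribution(data.frame(moi = rep("AD_denovo", 12)))
  expect_equal(all_dn$de_novo_share, 1)
  expect_error(moi_distribution(data.frame(moi = character(0))), "empty")
  expect_error(moi_distribution(data.frame(moi = "weird")), "unknown MOI")
})

test_that("autozygosity stratification uses a strict 2% boundary", {
  patients <- data.frame(id = paste0("P", 1:4), solved = c(1, 1, 0, 1),
                         autozygosity = c(0.02, 0.021, 0, NA))
  dx <- data.frame(dx_id = 1:2, patient_id = c("P1", "P2"),
                   moi = c("AD_denovo", "AR_hom"))
  expect_warning(st <- autozygosity_stratify(patients, dx), "unknown autozygosity")
  expect_equal(unname(st$stratum[c("P1", "P2", "P3")]), c("low", "high", "low"))

  st0 <- autozygosity_stratify(data.frame(id = "a", solved = 0, autozygosity = 0),
                               dx[0, ])
  expect_equal(st0$yields$total[st0$yields$stratum == "high"], 0)
})

test_that("high-autozygosity cohort size tracks the planted consanguinity rate", {
  params <- sim_params(n = 2000, seed = 444, consanguinity_fraction = 0.1)
  co <- simulate_cohort(params)
  n_high <- sum(co$patients$autozygosity > 0.02)
  band <- qbinom(c(0.025, 0.975), 2000, 0.1)
  expect_gte(n_high, band[1])
  expect_lte(n_high, band[2])
})

test_that("the de-novo-normalized burden ratio follows its arithmetic definition", {
  comp <- function(ar_hom, ar_ch, dn) {
    v <- c(AD = 1 - ar_hom - ar_ch - dn, AD_denovo = dn, AR_hom = ar_hom,
           AR_comphet = ar_ch, XL = 0, MT = 0)
    v
  }
  expect_equal(denovo_normalized_burden(comp(0.2, 0.1, 0.3), comp(0.2, 0.1, 0.3)), 1)
  high <- comp(0.6, 0.1, 0.1)   # AR .70, de novo .10
  low <- comp(0.1, 0.1, 0.5)    # AR .20, de novo .50
  expect_equal(denovo_normalized_burden(high, low), 7 / 0.4)
  expect_error(denovo_normalized_burden(comp(0.2, 0.1, 0), comp(0.2, 0.1, 0.3)),
               "positive")
})

test_that("a planted sevenfold recessive multiplier is recovered by the burden statistic", {
  rs <- vapply(1:10, function(s) {
    co <- simulate_cohort(sim_params(n = 5000, seed = 500 + s))
    st <- autozygosity_stratify(co$patients, co$diagnoses)
    denovo_normalized_burden(st$composition$high, st$composition$low)
  }, numeric(1))
  expect_gte(mean(rs), 5)
  expect_lte(mean(rs), 9)
  expect_true(all(rs > 3 & rs < 13))  # per-seed sanity around the planted value
})

test_that("carrier-screening amenability implements the classification rules", {
  expect_true(carrier_amenable("AR_hom", "P", lof = FALSE, nmd_escape = FALSE))
  expect_true(carrier_amenable("AR_hom", "VUS", lof = TRUE, nmd_escape = FALSE))
  expect_false(carrier_amenable("AR_hom", "VUS", lof = TRUE, nmd_escape = TRUE))
  expect_false(carrier_amenable("AR_comphet", c("P", "VUS"),
                                lof = c(FALSE, FALSE), nmd_escape = c(FALSE, FALSE)))
  expect_true(carrier_amenable("AR_comphet", c("P", "LP"),
                               lof = c(FALSE, FALSE), nmd_escape = c(FALSE, FALSE)))
  # relaxed reading lets a LoF non-escaping allele qualify
  expect_true(carrier_amenable("AR_comphet", c("P", "VUS"), lof = c(FALSE, TRUE),
                               nmd_escape = c(FALSE, FALSE), strict_comphet = FALSE))
  expect_error(carrier_amenable("AD", "P", FALSE, FALSE), "recessive")

  # monotone under reclassification VUS -> P
  for (lof in c(TRUE, FALSE)) for (nmd in c(TRUE, FALSE)) {
    before <- carrier_amenable("AR_hom", "VUS", lof, nmd)
    after <- carrier_amenable("AR_hom", "P", lof, nmd)
    expect_true(after >= before)
  }
})

test_that("headline rates reproduce the worked-example percentages", {
  co <- cohort_from_counts(n_total = 1577, n_solved = 499, n_diag = 510,
                           n_denovo = 228, n_mosaic = 3, n_dual = 11,
                           n_ar = 125, n_ar_hom = 60, n_amenable = 94)
  rs <- rate_summary(co)
  expect_equal(rs$percent[rs$rate == "dual_diagnoses"], 2)
  expect_equal(rs$percent[rs$rate == "parental_mosaicism"], 1.3)
  expect_equal(rs$numerator[rs$rate == "carrier_amenable"], 94)
  expect_equal(rs$denominator[rs$rate == "carrier_amenable"], 125)
  expect_gte(rs$fraction[rs$rate == "carrier_amenable"], 0.75)

  # bookkeeping invariants: diagnoses >= solved; dual cases counted per patient
  expect_gte(nrow(co$diagnoses), sum(co$patients$solved))
  expect_equal(length(unique(co$diagnoses$patient_id)), sum(co$patients$solved))
})

test_that("submission quartiles balance mass and follow the midpoint boundary rule", {
  q4 <- clinvar_quartiles(data.frame(gene = letters[1:4], plp_submissions = rep(5, 4)))
  expect_equal(unname(q4$gene_quartile[letters[1:4]]), 1:4)

  q1 <- clinvar_quartiles(data.frame(gene = "solo", plp_submissions = 100))
  expect_equal(unname(q1$gene_quartile[["solo"]]), 2L)  # spans all bins, midpoint in Q2

  cv <- simulate_clinvar(n_genes = 1000, zipf_alpha = 1.5, seed = 3)
  qq <- clinvar_quartiles(cv)
  delta <- max(cv$plp_submissions) / sum(cv$plp_submissions)
  expect_true(all(abs(qq$quartiles$submission_fraction - 0.25) <= delta + 1e-12))

  # exclusion list applied before ranking; unassigned cohort genes flagged
  dx <- data.frame(gene = c(cv$gene[1], "UNKNOWN"))
  expect_warning(q2 <- clinvar_quartiles(cv, exclude = cv$gene[2], diagnoses = dx),
                 "absent")
  expect_false(cv$gene[2] %in% names(q2$gene_quartile))
  expect_equal(q2$unassigned, "UNKNOWN")
  expect_equal(sum(q2$quartiles$cohort_variants), 1L)
})

test_that("year-of-association comparison equals the sup-difference oracle", {
  same <- year_comparison(c(2000, 2005, 2010), c(2000, 2005, 2010))
  expect_equal(same$statistic, 0)
  disj <- year_comparison(c(1990, 1991), c(2010, 2012))
  expect_equal(disj$statistic, 1)

  set.seed(77)
  a <- sample(1980:2020, 50, replace = TRUE)
  b <- sample(1990:2020, 50, replace = TRUE)
  yc <- year_comparison(a, b)
  expect_equal(yc$statistic, bf_ks(a, b), tolerance = 1e-12)
  expect_equal(sum(yc$histogram$count_a), 50)
  expect_error(year_comparison(numeric(0), 2000), "non-empty")
})
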