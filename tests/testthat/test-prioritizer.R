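unit12 <- function(seed) {
  set.seed(seed)
  m <- matrix(rnorm(12 * 512), 12, 512)
  m / sqrt(rowSums(m^2))
}

test_that("image distance hits its closed-form anchors and is symmetric", {
  a <- unit12(1)
  expect_equal(image_distance(a, a), 0)

  b <- unit12(2)
  expect_equal(image_distance(a, b), image_distance(b, a))
  expect_gte(image_distance(a, b), 0)
  expect_lte(image_distance(a, b), 2)
  expect_equal(image_distance(a, -a), 2)

  # exactly orthogonal pairs via disjoint coordinate support
  a1 <- matrix(0, 12, 512); a1[, 1:256] <- a[, 1:256] / sqrt(rowSums(a[, 1:256]^2))
  b1 <- matrix(0, 12, 512); b1[, 257:512] <- a[, 257:512] / sqrt(rowSums(a[, 257:512]^2))
  expect_equal(image_distance(a1, b1), 1)

  expect_error(image_distance(a, a[, 1:100]), "mismatch")
  expect_error(descriptor_set(a[1:11, ]), "12 x 512")
})

test_that("gestalt scores take the best gallery representative per gene", {
  set.seed(3)
  genes <- paste0("G", 1:10)
  gallery <- list()
  for (g in genes) for (r in 1:2) {
    gallery[[length(gallery) + 1L]] <- list(descriptors = unit12(100 * match(g, genes) + r),
                                            gene = g)
  }
  test <- gallery[[5]]$descriptors  # exact duplicate of a G3 gallery member
  sc <- gestalt_gene_scores(test, gallery, vocabulary = c(genes, "ABSENT"))
  expect_equal(unname(sc["G3"]), 1)
  expect_equal(unname(which.max(sc[genes])), 3L)
  expect_true(is.na(sc["ABSENT"]))

  # max-similarity aggregation equals a per-pair loop oracle
  oracle <- sapply(genes, function(g) {
    ds <- Filter(function(e) e$gene == g, gallery)
    max(vapply(ds, function(e) 1 - image_distance(test, e$descriptors), numeric(1)))
  })
  expect_equal(unname(sc[genes]), unname(oracle), tolerance = 1e-12)
})

test_that("disorder-clustered descriptors put the causal gene in the gestalt top 5", {
  set.seed(10)
  genes <- paste0("G", 1:10)
  centers <- lapply(genes, function(g) {
    v <- matrix(rnorm(12 * 512), 12, 512); v / sqrt(rowSums(v^2))
  })
  names(centers) <- genes
  perturb <- function(c0, sd) {
    m <- c0 + matrix(rnorm(12 * 512, sd = sd), 12, 512)
    m / sqrt(rowSums(m^2))
  }
  gallery <- list()
  for (g in genes) for (r in 1:5) {
    gallery[[length(gallery) + 1L]] <- list(descriptors = perturb(centers[[g]], 0.1),
                                            gene = g)
  }
  hit <- vapply(1:100, function(i) {
    g <- sample(genes, 1)
    sc <- gestalt_gene_scores(perturb(centers[[g]], 0.1), gallery, genes)
    rk <- rank(-sc, ties.method = "max")
    rk[[g]] <= 5
  }, logical(1))
  expect_gte(mean(hit), 0.9)
})

test_that("molecular scores apply the frequency filter then a per-gene max", {
  v <- data.frame(gene = c("A", "A", "B"), af = c(0.001, 0.002, 0.2),
                  score = c(10.2, 25.7, 40))
  sc <- molecular_gene_scores(v, af_cutoff = 0.01)
  expect_equal(unname(sc["A"]), 25.7)
  expect_true(is.na(sc["B"]))  # only variant is common
  expect_error(molecular_gene_scores(data.frame(gene = "A", af = -0.1, score = 1)),
               "negative")

  # 50-variant table vs group-by-max oracle
  set.seed(20)
  tab <- data.frame(gene = sample(paste0("G", 1:12), 50, replace = TRUE),
                    af = runif(50, 0, 0.05), score = runif(50, 0, 40))
  got <- molecular_gene_scores(tab, 0.01)
  keep <- tab[tab$af <= 0.01, ]
  oracle <- tapply(keep$score, keep$gene, max)
  expect_equal(unname(got[names(oracle)]), as.numeric(oracle))
  expect_true(all(is.na(got[setdiff(names(got), names(oracle))])))
})

test_that("feature scores rank genes exactly as the exhaustive similarity oracle", {
  dag <- random_dag(20, seed = 30)
  set.seed(31)
  ann <- replicate(20, random_term_set(dag, sample(2:4, 1)), simplify = FALSE)
  names(ann) <- paste0("G", 1:20)
  dag <- information_content(dag, ann)
  pt <- ann[["G5"]]

  sc <- feature_gene_scores(pt, ann, dag)
  oracle <- vapply(ann, function(a) bf_bma(dag, dag$ic, pt, a), numeric(1))
  expect_equal(sc[names(oracle)], oracle)
  expect_equal(names(which.max(sc)), "G5")  # exact annotation match is maximal

  sc2 <- feature_gene_scores(pt, c(ann, list(EMPTY = character(0))), dag)
  expect_true(is.na(sc2[["EMPTY"]]))
})

test_that("fusion normalizes per channel, tolerates missing scores and preserves dominance", {
  tab <- data.frame(gene = c("A", "B", "C"),
                    gestalt = c(0.9, 0.1, NA),
                    feature = c(3, 1, 2),
                    molecular = c(30, 10, 20))
  f1 <- fuse_scores(tab, weights = c(gestalt = 1, feature = 0, molecular = 0))
  expect_equal(order(-f1$fused)[1:2], order(-tab$gestalt, na.last = TRUE)[1:2])
  expect_equal(f1$gestalt_norm[3], 0)  # missing maps to the neutral floor

  # gene maximal in all channels is fused-maximal
  f3 <- fuse_scores(tab)
  expect_equal(f3$gene[which.max(f3$fused)], "A")

  # affine rescaling of a channel leaves normalized values untouched
  tab2 <- tab
  tab2$molecular <- 5 + 100 * tab2$molecular
  expect_equal(fuse_scores(tab2)$molecular_norm, f3$molecular_norm)

  # removing one channel leaves the others' normalized values unchanged
  f_no_g <- fuse_scores(tab[, c("gene", "feature", "molecular")])
  expect_equal(f_no_g$feature_norm, f3$feature_norm)
  expect_equal(f_no_g$molecular_norm, f3$molecular_norm)

  # degenerate constant channel contributes nothing
  tabc <- data.frame(gene = c("A", "B"), feature = c(1, 1), molecular = c(2, 1))
  fc <- fuse_scores(tabc)
  expect_equal(fc$feature_norm, c(0, 0))

  expect_error(fuse_scores(data.frame(gene = "A", feature = NA_real_)), "at least one")
})

test_that("ranking is descending with worst-rank ties and matches a sort oracle", {
  r <- rank_genes(c(A = 3, B = 2, C = 1))
  expect_equal(r$rank, 1:3)
  r2 <- rank_genes(c(A = 5, B = 5, C = 1))
  expect_equal(r2$rank[r2$gene %in% c("A", "B")], c(2L, 2L))

  set.seed(40)
  sc <- stats::setNames(runif(100), paste0("G", 1:100))
  r3 <- rank_genes(sc)
  expect_equal(r3$gene, names(sort(sc, decreasing = TRUE)))
})

test_that("top-k accuracy is a monotone counting statistic with bootstrap CIs", {
  acc1 <- topk_accuracy(rep(1L, 10), ks = c(1, 5), B = 100)
  expect_equal(acc1$accuracy, c(1, 1))

  set.seed(50)
  ranks <- sample(1:200, 94, replace = TRUE)
  acc <- topk_accuracy(ranks, ks = 1:100, B = 200, seed = 2)
  expect_true(all(diff(acc$accuracy) >= 0))
  # per-case counting oracle
  expect_equal(acc$accuracy, vapply(1:100, function(k) sum(ranks <= k) / 94, numeric(1)))
  expect_true(all(acc$lo <= acc$accuracy + 1e-12 & acc$accuracy <= acc$hi + 1e-12))

  expect_warning(accm <- topk_accuracy(c(1L, NA), ks = 5, B = 0), "never hit")
  expect_equal(accm$accuracy, 0.5)
})

test_that("fused prioritization dominates single channels on planted multimodal cases", {
  top10 <- matrix(NA_real_, 10, 4,
                  dimnames = list(NULL, c("gestalt", "feature", "molecular", "fused")))
  for (s in 1:10) {
    params <- sim_params(n = 150, seed = 300 + s, vocab_size = 150,
                         gallery_genes = 40, gallery_per_gene = 2)
    co <- simulate_cohort(params)
    b <- simulate_scores(co, n_cases = 25)
    for (ch in colnames(top10)) {
      top10[s, ch] <- mean(b$cases[[paste0("rank_", ch)]] <= 10)
    }
  }
  means <- colMeans(top10)
  expect_gte(means["fused"], means["molecular"])
  expect_gte(means["fused"], means["gestalt"] - 1e-12)
  expect_gte(means["fused"], means["feature"] - 1e-12)
})
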