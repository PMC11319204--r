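# Shared fixtures and independent brute-force oracles.

obo_from_edges <- function(ids, parents, extra = character(0)) {
  # parents: named list id -> character vector of parent ids
  out <- c("format-version: 1.2", "")
  for (t in ids) {
    isa <- if (length(parents[[t]])) paste0("is_a: ", parents[[t]]) else character(0)
    out <- c(out, "[Term]", paste0("id: ", t), paste0("name: ", t), isa,
             if (t %in% names(attr(parents, "tags"))) attr(parents, "tags")[[t]] else character(0),
             "")
  }
  c(out, extra)
}

read_obo_text <- function(text) read_obo(textConnection(text))

# linear chain T1 -> T2 -> ... -> Tn (T1 root)
chain_ontology <- function(n = 5) {
  ids <- paste0("T", seq_len(n))
  parents <- stats::setNames(c(list(character(0)), as.list(ids[-n])), ids)
  read_obo_text(obo_from_edges(ids, parents))
}

# small diamond: R; A,B children of R; C child of both A and B
diamond_ontology <- function() {
  ids <- c("R", "A", "B", "C")
  parents <- list(R = character(0), A = "R", B = "R", C = c("A", "B"))
  read_obo_text(obo_from_edges(ids, parents))
}

# random single-rooted DAG with n terms; returns index
random_dag <- function(n, seed, p_extra = 0.3) {
  set.seed(seed)
  ids <- paste0("T", seq_len(n))
  parents <- list()
  parents[[ids[1]]] <- character(0)
  for (i in 2:n) {
    ps <- ids[sample.int(i - 1, 1)]
    if (i > 2 && stats::runif(1) < p_extra) {
      ps <- unique(c(ps, ids[sample.int(i - 1, 1)]))
    }
    parents[[ids[i]]] <- ps
  }
  read_obo_text(obo_from_edges(ids, parents))
}

random_term_set <- function(index, k) sample(index$terms, k)

# ---- brute-force oracles (independent of the package's closure machinery) ----

# ancestors by repeated parent expansion straight from the parent lists
bf_ancestors <- function(index, t) {
  seen <- t
  frontier <- t
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(index$parents[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

# IC by exhaustive descendant-or-self enumeration per term
bf_ic <- function(index, corpus) {
  n <- length(corpus)
  sapply(index$terms, function(t) {
    cnt <- sum(vapply(corpus, function(ts) {
      any(vapply(ts, function(s) t %in% bf_ancestors(index, s), logical(1)))
    }, logical(1)))
    if (cnt == 0) NA_real_ else -log(cnt / n)
  })
}

bf_resnik <- function(index, ic, t1, t2) {
  max(ic[intersect(bf_ancestors(index, t1), bf_ancestors(index, t2))])
}

bf_bma <- function(index, ic, a, b) {
  m <- outer(a, b, Vectorize(function(x, y) bf_resnik(index, ic, x, y)))
  (mean(apply(m, 1, max)) + mean(apply(m, 2, max))) / 2
}

# two-sided Fisher p by exhaustive hypergeometric tail enumeration
bf_fisher_p <- function(m) {
  x <- m[1, 1]
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(support, r1, n - r1, c1)
  p_obs <- stats::dhyper(x, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# two-sample KS statistic as the sup over empirical CDF differences
bf_ks <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}

# minimal cohort bookkeeping structure built from exact counts; diagnosis
# attributes beyond what each rate needs are filled deterministically
cohort_from_counts <- function(n_total, n_solved, n_diag, n_denovo, n_mosaic,
                               n_dual, n_ar, n_ar_hom, n_amenable) {
  patients <- data.frame(
    id = sprintf("P%04d", seq_len(n_total)),
    solved = rep(c(1L, 0L), c(n_solved, n_total - n_solved)),
    autozygosity = 0
  )
  # one diagnosis per solved case; dual cases get a second one
  stopifnot(n_diag == n_solved + n_dual)
  owner <- c(seq_len(n_solved), seq_len(n_dual))
  moi <- character(n_diag)
  moi[seq_len(n_denovo)] <- "AD_denovo"
  ar_idx <- n_denovo + seq_len(n_ar)
  moi[ar_idx] <- rep(c("AR_hom", "AR_comphet"), c(n_ar_hom, n_ar - n_ar_hom))
  moi[moi == ""] <- "AD"
  diagnoses <- data.frame(
    dx_id = seq_len(n_diag), patient_id = patients$id[owner],
    gene = sprintf("G%04d", seq_len(n_diag)), moi = moi,
    de_novo = moi == "AD_denovo",
    mosaic = c(rep(TRUE, n_mosaic), rep(FALSE, n_denovo - n_mosaic),
               rep(FALSE, n_diag - n_denovo)),
    year = 2010L, novel = FALSE
  )
  # variants: amenable AR diagnoses get P/LP on all alleles, rest VUS
  vrows <- lapply(seq_len(n_diag), function(i) {
    nv <- if (moi[i] == "AR_comphet") 2L else 1L
    amen <- i %in% ar_idx && (i - n_denovo) <= n_amenable
    data.frame(dx_id = rep(i, nv), class = if (amen) "P" else "VUS",
               lof = FALSE, nmd_escape = FALSE, af = 0.001)
  })
  list(patients = patients, diagnoses = diagnoses,
       variants = do.call(rbind, vrows))
}
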