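#' Validate a cohort bundle against the package's invariants
#'
#' Checks the structural contracts the analysis stages rely on: solved
#' status consistent with the diagnosis table (a case is solved iff it has
#' at least one diagnosis), autozygosity within `[0, 1]`, known
#' mode-of-inheritance categories, exactly two variant records per
#' compound-heterozygous diagnosis (one otherwise), and — when an ontology
#' is attached — that patient terms resolve in it (unknown terms are a
#' warning, matching the term-validation policy, not an error).
#'
#' @param cohort A `phenodx_cohort`-like list (`patients`, `diagnoses`,
#'   `variants`, optionally `ontology`).
#' @return Data frame with columns `level` (`"error"`/`"warning"`), `check`
#'   and `message`; zero rows means a clean bundle.
#' @export
validate_inputs <- function(cohort) {
  findings <- list()
  note <- function(level, check, message) {
    findings[[length(findings) + 1L]] <<- data.frame(
      level = level, check = check, message = message, stringsAsFactors = FALSE)
  }
  p <- cohort$patients
  dx <- cohort$diagnoses

  with_dx <- unique(dx$patient_id)
  bad_solved <- p$id[(p$solved == 1L) != (p$id %in% with_dx)]
  if (length(bad_solved)) {
    note("error", "solved_consistency",
         paste0("solved flag inconsistent with diagnosis table for: ",
                paste(utils::head(bad_solved, 5), collapse = ", ")))
  }
  if (any(p$autozygosity < 0 | p$autozygosity > 1, na.rm = TRUE)) {
    note("error", "autozygosity_range", "autozygosity outside [0, 1]")
  }
  bad_moi <- setdiff(unique(dx$moi), moi_levels())
  if (length(bad_moi)) {
    note("error", "moi_categories",
         paste0("unknown MOI category: ", paste(bad_moi, collapse = ", ")))
  }
  nvar <- table(cohort$variants$dx_id)
  expect2 <- dx$dx_id[dx$moi == "AR_comphet"]
  wrong2 <- expect2[nvar[as.character(expect2)] != 2L | is.na(nvar[as.character(expect2)])]
  if (length(wrong2)) {
    note("error", "comphet_variants",
         paste0(length(wrong2), " compound-heterozygous diagnosis(es) without exactly 2 variant records"))
  }
  if (!is.null(cohort$ontology)) {
    idx <- cohort$ontology$index
    unknown <- unique(unlist(lapply(p$terms, function(ts) {
      ts2 <- ts
      is_alt <- ts2 %in% names(idx$alt)
      ts2[is_alt] <- idx$alt[ts2[is_alt]]
      ts[!(ts2 %in% idx$terms)]
    }), use.names = FALSE))
    if (length(unknown)) {
      note("warning", "unknown_terms",
           paste0(length(unknown), " term(s) not in the ontology, e.g. ",
                  paste(utils::head(unknown, 3), collapse = ", ")))
    }
  }
  if (length(findings)) do.call(rbind, findings) else
    data.frame(level = character(0), check = character(0), message = character(0))
}

#' Validate a list of descriptor sets
#'
#' @param descriptors List of matrices.
#' @return Invisibly `TRUE`; stops citing the 12 x 512 unit-norm invariant
#'   on the first violation.
#' @export
validate_descriptors <- function(descriptors) {
  for (i in seq_along(descriptors)) {
    tryCatch(descriptor_set(descriptors[[i]]),
             error = function(e) stop("descriptor set ", i, ": ", conditionMessage(e)))
  }
  invisible(TRUE)
}

#' Run the full analysis pipeline on a (synthetic) cohort
#'
#' Executes the stages in dependency order: cohort generation (or
#' ingestion), group assignment, diagnostic-yield model fitting and
#' evaluation on a held-out split, prioritization benchmark, and cohort
#' statistics. When `outdir` is given, the stage outputs are written as
#' TSV/JSON files, each carrying the seed and a configuration hash in a
#' `run_metadata.json` sidecar.
#'
#' @param params A `phenodx_sim_params` (thresholds and seeds travel here).
#' @param cohort Optional pre-built `phenodx_cohort`; simulated from
#'   `params` when `NULL`.
#' @param outdir Optional output directory (created if needed).
#' @param test_fraction Held-out fraction for yield-model evaluation
#'   (default 321/1577, the canonical 1,256/321 split ratio).
#' @param topk k values for the accuracy curve (default
#'   `c(1, 5, 10, 30, 100)`).
#' @param n_benchmark_cases Cases in the prioritization benchmark
#'   (default 100).
#' @return List with `cohort`, `split` (train/test ids), `model`,
#'   `auc` (held-out ROC), `benchmark`, `accuracy`, `yields`,
#'   `moi`, `strata`, `burden_ratio`, `rates`, `metadata`.
#' @export
run_pipeline <- function(params = sim_params(), cohort = NULL, outdir = NULL,
                         test_fraction = 321 / 1577,
                         topk = c(1, 5, 10, 30, 100),
                         n_benchmark_cases = 100) {
  if (is.null(cohort)) cohort <- simulate_cohort(params)
  issues <- validate_inputs(cohort)
  if (any(issues$level == "error")) {
    stop("input validation failed: ", paste(issues$message[issues$level == "error"],
                                            collapse = "; "))
  }

  # train/test split and yield model
  n <- nrow(cohort$patients)
  set.seed(params$seed + 2L)
  test_idx <- sort(sample.int(n, round(test_fraction * n)))
  train_idx <- setdiff(seq_len(n), test_idx)
  design_all <- build_design(cohort$patients, cohort$subcat)
  design_tr <- build_design(cohort$patients[train_idx, , drop = FALSE],
                            cohort$subcat[train_idx, , drop = FALSE])
  model <- fit_yield_model(design_tr, seed = params$seed)
  p_test <- predict(model, design_all$x[test_idx, , drop = FALSE])
  auc <- roc_auc(p_test, design_all$y[test_idx], seed = params$seed)

  # prioritization benchmark
  benchmark <- simulate_scores(cohort, params, n_cases = n_benchmark_cases)
  accuracy <- topk_accuracy(benchmark$cases$rank_fused, ks = topk,
                            seed = params$seed)

  # cohort statistics
  yields <- yield_table(cohort$patients$solved, cohort$patients$category)
  moi <- moi_distribution(cohort$diagnoses)
  strata <- autozygosity_stratify(cohort$patients, cohort$diagnoses)
  burden <- denovo_normalized_burden(strata$composition$high, strata$composition$low)
  rates <- rate_summary(cohort)

  metadata <- list(
    seed = params$seed,
    thresholds = list(autozygosity = 0.02, af_cutoff = params$af_cutoff,
                      path_prevalence = 0.05, topk = topk),
    n_patients = n, n_train = length(train_idx), n_test = length(test_idx),
    n_diagnoses = nrow(cohort$diagnoses),
    config_hash = sprintf("%08x", sum(utf8ToInt(paste(
      params$seed, params$n, params$yield_target, sep = ":"))))
  )

  result <- list(cohort = cohort, split = list(train = train_idx, test = test_idx),
                 model = model, auc = auc, benchmark = benchmark,
                 accuracy = accuracy, yields = yields, moi = moi,
                 strata = strata, burden_ratio = burden, rates = rates,
                 metadata = metadata)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    w <- function(df, f) utils::write.table(df, file.path(outdir, f), sep = "\t",
                                            quote = FALSE, row.names = FALSE)
    pat <- cohort$patients
    pat$terms <- vapply(pat$terms, paste, character(1), collapse = ",")
    w(pat, "cohort.tsv")
    w(cohort$diagnoses, "diagnoses.tsv")
    w(cohort$variants, "variants.tsv")
    w(yields$groups, "yield_by_category.tsv")
    w(moi$table, "moi_distribution.tsv")
    w(rates, "rate_summary.tsv")
    w(as.data.frame(accuracy), "topk_accuracy.tsv")
    w(export_paths(model), "coefficient_paths.tsv")
    write_yield_model(model, file.path(outdir, "yield_model.json"))
    jsonlite::write_json(metadata, file.path(outdir, "run_metadata.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}
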