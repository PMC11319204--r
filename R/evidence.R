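#' Load a nine-criterion evidence weight configuration
#'
#' The candidate-gene evidence score is a weighted sum over nine criterion
#' indicators with a maximum of 8 for an autosomal dominant (AD) candidate.
#' Three criteria (de novo status and the two gnomAD constraint metrics)
#' apply only to AD candidates and are masked for recessive or X-linked
#' inheritance. The weights are configuration data, not code: the default
#' table shipped with the package can be replaced by any curated scoring
#' table with the same columns. A configuration whose AD-applicable weights
#' do not sum to 8 is rejected.
#'
#' In the default table, one general criterion (tissue expression / pathway
#' plausibility) is treated as supportive-only and carries weight 0; it is
#' recorded but contributes no points.
#'
#' @param path TSV with columns `criterion`, `label`, `ad_only` (logical),
#'   `weight` (non-negative integer). Default: the configuration shipped
#'   with the package.
#' @return Data frame of class `phenodx_evidence_weights`.
#' @export
read_evidence_weights <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "evidence_weights.tsv", package = "phenodx")
  }
  w <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("criterion", "ad_only", "weight") %in% names(w)))
  if (nrow(w) != 9L) stop("evidence configuration must define exactly nine criteria")
  if (any(w$weight < 0) || any(w$weight != round(w$weight))) {
    stop("criterion weights must be non-negative integers")
  }
  if (sum(w$weight) != 8L) {
    stop("configuration error: the AD-applicable weights must sum to 8 (got ",
         sum(w$weight), ")")
  }
  w$ad_only <- as.logical(w$ad_only)
  class(w) <- c("phenodx_evidence_weights", "data.frame")
  w
}

#' Check the mandatory candidate-gene criteria
#'
#' Scoring is only defined for candidates that pass all four mandatory
#' gates: (1) no previous robust gene-phenotype association, (2) no other
#' clearly causative disease explanation, (3) variant allele frequency below
#' the minor-allele-frequency cutoff (or absent from controls), (4)
#' inheritance consistent with the phenotype in the family (or
#' co-segregation in multiple affected relatives).
#'
#' @param mandatory Logical vector of length 4 (names `m1..m4` optional);
#'   `NA` or a missing flag is an error.
#' @return `TRUE` iff all four hold.
#' @export
check_mandatory <- function(mandatory) {
  if (length(mandatory) != 4L || anyNA(mandatory)) {
    stop("all four mandatory criterion flags must be supplied")
  }
  all(as.logical(mandatory))
}

#' Candidate-gene evidence score
#'
#' Weighted sum of the applicable criterion indicators under the loaded
#' weight configuration. For autosomal recessive (AR) and X-linked (XL)
#' candidates the AD-only criteria contribute nothing, so the attainable
#' maximum is `8 - sum(AD-only weights)`.
#'
#' @param criteria Named logical vector of criterion indicators; names must
#'   match `weights$criterion` (missing names count as `FALSE`).
#' @param moi `"AD"`, `"AR"` or `"XL"`.
#' @param weights A `phenodx_evidence_weights` (default configuration if
#'   omitted).
#' @return Integer score in `[0, 8]`.
#' @export
evidence_score <- function(criteria, moi = c("AD", "AR", "XL"), weights = NULL) {
  moi <- match.arg(moi)
  if (is.null(weights)) weights <- read_evidence_weights()
  ind <- stats::setNames(rep(FALSE, nrow(weights)), weights$criterion)
  known <- intersect(names(criteria), weights$criterion)
  if (length(known) < length(criteria)) {
    stop("unknown criterion name(s): ",
         paste(setdiff(names(criteria), weights$criterion), collapse = ", "))
  }
  ind[known] <- as.logical(criteria[known])
  applicable <- if (moi == "AD") rep(TRUE, nrow(weights)) else !weights$ad_only
  as.integer(sum(weights$weight[applicable] * ind[weights$criterion][applicable]))
}

#' Classify the evidence level of a scored candidate
#'
#' AD candidates: score 4 and above is high evidence, 1-3 medium. AR (and,
#' by the package's convention, XL) candidates: score 3 and above is high,
#' below 3 medium. An AD score of 0 falls below the defined medium band and
#' is classified medium with a warning.
#'
#' @param score Integer in `[0, 8]`.
#' @param moi `"AD"`, `"AR"` or `"XL"`.
#' @return `"medium"` or `"high"`.
#' @export
classify_evidence <- function(score, moi = c("AD", "AR", "XL")) {
  moi <- match.arg(moi)
  if (score < 0 || score > 8) stop("score must lie in [0, 8]")
  if (moi == "AD") {
    if (score == 0) warning("AD candidate with score 0: below the defined medium band")
    if (score >= 4) "high" else "medium"
  } else {
    if (score >= 3) "high" else "medium"
  }
}

#' Score a table of candidate genes
#'
#' Applies the mandatory gate, the evidence score and the classification to
#' a candidate table. Candidates failing the mandatory gate get `NA` score
#' and class `"ineligible"`.
#'
#' @param candidates Data frame with columns `gene`, `moi`, `m1..m4`
#'   (logical) and one logical column per criterion in the configuration.
#' @param weights A `phenodx_evidence_weights` (default configuration if
#'   omitted).
#' @return The input with `eligible`, `score` and `class` columns appended.
#' @export
score_candidates <- function(candidates, weights = NULL) {
  if (is.null(weights)) weights <- read_evidence_weights()
  need <- c("gene", "moi", paste0("m", 1:4))
  stopifnot(all(need %in% names(candidates)))
  crit_cols <- intersect(weights$criterion, names(candidates))
  out <- candidates
  out$eligible <- NA
  out$score <- NA_integer_
  out$class <- NA_character_
  for (i in seq_len(nrow(candidates))) {
    elig <- check_mandatory(unlist(candidates[i, paste0("m", 1:4)]))
    out$eligible[i] <- elig
    if (!elig) {
      out$class[i] <- "ineligible"
      next
    }
    cr <- stats::setNames(as.logical(unlist(candidates[i, crit_cols])), crit_cols)
    sc <- evidence_score(cr, candidates$moi[i], weights)
    out$score[i] <- sc
    out$class[i] <- suppressWarnings(classify_evidence(sc, candidates$moi[i]))
  }
  out
}
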