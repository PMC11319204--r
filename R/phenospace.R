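#' Pairwise semantic-similarity matrix over entities
#'
#' Builds the symmetric entity-by-entity matrix of best-match-average Resnik
#' similarities. Entities are term sets; reference diseases are treated
#' exactly like patients, so a patient cohort can be co-embedded with a
#' disease catalog by concatenating the two lists.
#'
#' Entities with empty term sets are dropped with a warning.
#'
#' @param index A `phenodx_ontology` with IC attached.
#' @param entities Named list of character term-set vectors (>= 2 entries).
#' @return Symmetric numeric matrix with entity names on both dimensions.
#' @export
similarity_matrix <- function(index, entities) {
  keep <- vapply(entities, length, integer(1)) > 0L
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " entity(ies) with empty term sets")
    entities <- entities[keep]
  }
  n <- length(entities)
  if (n < 2L) stop("need at least two non-empty entities")
  if (is.null(names(entities))) names(entities) <- paste0("entity", seq_len(n))
  s <- matrix(0, n, n, dimnames = list(names(entities), names(entities)))
  for (i in seq_len(n)) {
    for (j in i:n) {
      s[i, j] <- s[j, i] <- patient_similarity(index, entities[[i]], entities[[j]])
    }
  }
  s
}

#' Convert a similarity matrix to a dissimilarity matrix
#'
#' Default transform `D = max(S) - S` with the diagonal forced to zero;
#' `"inverse"` uses `D = 1/(1+S) - 1/(1+diag)` rescaled to zero diagonal.
#'
#' @param s Symmetric similarity matrix.
#' @param method `"max_minus"` (default) or `"inverse"`.
#' @return Symmetric non-negative matrix with zero diagonal.
#' @export
similarity_to_distance <- function(s, method = c("max_minus", "inverse")) {
  method <- match.arg(method)
  if (!isSymmetric(unname(s), tol = 1e-8)) stop("similarity matrix must be symmetric")
  d <- switch(method,
    max_minus = max(s) - s,
    inverse = 1 / (1 + s)
  )
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d[d < 0] <- 0
  d
}

#' Embed the phenotype space from a similarity matrix
#'
#' Converts similarities to distances and embeds the entities into a
#' low-dimensional Euclidean space (default 4 dimensions; downstream plots
#' typically use the first two). The embedding is classical multidimensional
#' scaling (principal-coordinates analysis) on the precomputed distance
#' matrix, which is deterministic: repeated runs give identical coordinates.
#' The `seed` is carried through to the result metadata so pipelines relying
#' on seeded provenance stay uniform.
#'
#' @param s Symmetric similarity matrix (entities x entities).
#' @param dims Number of output dimensions (>= 2, default 4).
#' @param seed Integer recorded in the result metadata.
#' @param distance Transform passed to [similarity_to_distance()].
#' @return An object of class `phenodx_embedding`: list with `coordinates`
#'   (n x dims matrix, columns `dim1..dimk`), `dims`, `seed`, `distance`,
#'   `provenance` (hash of the distance matrix).
#' @export
embed_phenospace <- function(s, dims = 4, seed = 1L,
                             distance = c("max_minus", "inverse")) {
  if (dims < 2) stop("dims must be >= 2")
  d <- similarity_to_distance(s, match.arg(distance))
  k <- min(dims, nrow(d) - 1L)
  # degenerate geometries (fewer positive eigenvalues than dims) are padded
  # with zero coordinates rather than warned about
  xy <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = k))
  if (ncol(xy) < dims) {
    xy <- cbind(xy, matrix(0, nrow(xy), dims - ncol(xy)))
  }
  # fix sign convention so the result does not depend on eigenvector sign
  for (j in seq_len(ncol(xy))) {
    i0 <- which.max(abs(xy[, j]))
    if (length(i0) && xy[i0, j] < 0) xy[, j] <- -xy[, j]
  }
  dimnames(xy) <- list(rownames(d), paste0("dim", seq_len(dims)))
  structure(list(
    coordinates = xy, dims = dims, seed = as.integer(seed),
    distance = match.arg(distance),
    provenance = sprintf("%.8e", sum(d) + sum(d * d))
  ), class = "phenodx_embedding")
}

#' @export
print.phenodx_embedding <- function(x, ...) {
  cat("<phenodx_embedding> ", nrow(x$coordinates), " entities in ",
      x$dims, "-D (PCoA, distance = ", x$distance, ")\n", sep = "")
  invisible(x)
}

#' Export embedding coordinates as TSV
#'
#' @param embedding A `phenodx_embedding`.
#' @param path Output file path.
#' @param labels Optional named character vector of entity labels.
#' @return The written data frame, invisibly.
#' @export
write_embedding <- function(embedding, path, labels = NULL) {
  df <- data.frame(entity_id = rownames(embedding$coordinates),
                   embedding$coordinates, check.names = FALSE)
  if (!is.null(labels)) df$label <- unname(labels[df$entity_id])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
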