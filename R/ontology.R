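#' Read a phenotype ontology from an OBO file
#'
#' Parses the subset of the OBO flat-file format needed for semantic
#' similarity work: `[Term]` stanzas with `id`, `name`, `is_a`, `alt_id` and
#' `is_obsolete` tags. Obsolete terms are dropped; `alt_id`s are kept as a
#' lookup table so that records annotated with superseded identifiers can be
#' resolved to the primary id. The transitive ancestor closure (including the
#' term itself) is precomputed for every term.
#'
#' The term graph must be a DAG with a single root (a term without parents);
#' a cycle, a missing root or an `is_a` reference to an unknown term is a
#' structural error.
#'
#' @param path Path to an OBO file (or a connection).
#' @return An object of class `phenodx_ontology`: a list with elements
#'   `terms` (character vector of primary ids), `name` (named character),
#'   `parents`, `children`, `ancestors` (named lists of character vectors;
#'   `ancestors` includes the term itself), `root` (single id), `alt` (named
#'   character mapping alternative to primary ids) and `ic` (information
#'   content in nats, `NULL` until [information_content()] is called).
#' @seealso [information_content()], [resnik_pair()], [patient_similarity()]
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)

  # stanza boundaries
  starts <- which(lines == "[Term]")
  if (length(starts) == 0L) stop("no [Term] stanzas found in OBO input")
  other <- which(startsWith(lines, "[") & lines != "[Term]")
  ends <- vapply(starts, function(s) {
    nxt <- c(starts[starts > s], other[other > s], length(lines) + 1L)
    min(nxt) - 1L
  }, integer(1))

  ids <- character(0)
  nms <- character(0)
  parent_list <- list()
  alt_from <- character(0)
  alt_to <- character(0)

  tag_value <- function(block, tag) {
    hit <- block[startsWith(block, paste0(tag, ":"))]
    val <- sub(paste0("^", tag, ":\\s*"), "", hit)
    val <- sub("\\s*!.*$", "", val)  # strip trailing comments
    val[nzchar(val)]
  }

  for (k in seq_along(starts)) {
    block <- lines[starts[k]:ends[k]]
    id <- tag_value(block, "id")
    if (length(id) == 0L) next
    id <- id[1]
    obso <- tag_value(block, "is_obsolete")
    if (length(obso) && any(tolower(obso) == "true")) next
    nm <- tag_value(block, "name")
    isa <- tag_value(block, "is_a")
    alts <- tag_value(block, "alt_id")
    ids <- c(ids, id)
    nms <- c(nms, if (length(nm)) nm[1] else NA_character_)
    parent_list[[id]] <- unique(isa)
    if (length(alts)) {
      alt_from <- c(alt_from, alts)
      alt_to <- c(alt_to, rep(id, length(alts)))
    }
  }
  if (anyDuplicated(ids)) stop("duplicate term ids in OBO input")
  names(nms) <- ids

  all_parents <- unique(unlist(parent_list, use.names = FALSE))
  unknown <- setdiff(all_parents, ids)
  if (length(unknown)) {
    stop("is_a references unknown (or obsolete) terms: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }

  roots <- ids[vapply(parent_list[ids], length, integer(1)) == 0L]
  if (length(roots) == 0L) stop("ontology has no root term (cycle or malformed input)")
  if (length(roots) > 1L) {
    stop("ontology has multiple roots: ", paste(roots, collapse = ", "))
  }

  children <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) for (p in parent_list[[id]]) children[[p]] <- c(children[[p]], id)

  # ancestor closure by memoized traversal; cycle detection via visit states
  anc <- stats::setNames(vector("list", length(ids)), ids)
  state <- stats::setNames(integer(length(ids)), ids)  # 0 new, 1 in progress, 2 done
  stack_closure <- function(id) {
    todo <- id
    while (length(todo)) {
      t <- todo[[length(todo)]]
      if (state[[t]] == 2L) { todo <- todo[-length(todo)]; next }
      ps <- parent_list[[t]]
      pending <- ps[state[ps] != 2L]
      if (length(pending)) {
        if (any(state[pending] == 1L)) stop("cycle detected in ontology at term ", t)
        state[[t]] <<- 1L
        todo <- c(todo, pending)
      } else {
        anc[[t]] <<- unique(c(t, unlist(anc[ps], use.names = FALSE)))
        state[[t]] <<- 2L
        todo <- todo[-length(todo)]
      }
    }
  }
  for (id in ids) stack_closure(id)

  structure(list(
    terms = ids, name = nms, parents = parent_list, children = children,
    ancestors = anc, root = roots,
    alt = stats::setNames(alt_to, alt_from), ic = NULL
  ), class = "phenodx_ontology")
}

#' @export
print.phenodx_ontology <- function(x, ...) {
  cat("<phenodx_ontology> ", length(x$terms), " terms, root ", x$root,
      if (!is.null(x$ic)) ", IC attached" else ", no IC", "\n", sep = "")
  invisible(x)
}

#' Resolve term identifiers against an ontology
#'
#' Maps alternative ids to their primary id and drops (with a warning)
#' identifiers unknown to the ontology.
#'
#' @param index A `phenodx_ontology`.
#' @param terms Character vector of term ids.
#' @param warn Warn about unknown terms (default `TRUE`).
#' @return Character vector of primary ids (possibly shorter than input).
#' @export
resolve_terms <- function(index, terms, warn = TRUE) {
  is_alt <- terms %in% names(index$alt)
  terms[is_alt] <- index$alt[terms[is_alt]]
  known <- terms %in% index$terms
  if (warn && any(!known)) {
    warning("dropping ", sum(!known), " term(s) not in the ontology: ",
            paste(utils::head(terms[!known], 5), collapse = ", "))
  }
  unique(terms[known])
}

#' Compute information content from an annotation corpus
#'
#' Each corpus entity (a disease, a gene or a patient) annotates a set of
#' terms; annotations propagate to all ancestors. The information content of
#' a term is `-ln(n_t / N)` where `n_t` is the number of entities annotated
#' to the term or any of its descendants and `N` the corpus size. The root is
#' reached by every entity, so `ic(root) = 0`, and IC is monotone
#' non-decreasing from parent to child.
#'
#' Terms that annotate no corpus entity have undefined IC; they are assigned
#' the maximum IC observed in the corpus (so similarities stay finite) and
#' recorded in the `"ic_flagged"` attribute of the returned index.
#'
#' @param index A `phenodx_ontology`.
#' @param corpus A list of character vectors (entity term sets, primary ids).
#' @return The index with `$ic` populated (named numeric, nats).
#' @export
information_content <- function(index, corpus) {
  if (!length(corpus)) stop("corpus must contain at least one entity")
  n <- length(corpus)
  counts <- stats::setNames(integer(length(index$terms)), index$terms)
  for (ts in corpus) {
    bad <- setdiff(ts, index$terms)
    if (length(bad)) stop("corpus term(s) not in ontology: ",
                          paste(utils::head(bad, 5), collapse = ", "))
    reach <- unique(unlist(index$ancestors[ts], use.names = FALSE))
    counts[reach] <- counts[reach] + 1L
  }
  ic <- ifelse(counts > 0L, -log(counts / n), NA_real_)
  flagged <- names(ic)[is.na(ic)]
  if (length(flagged)) ic[flagged] <- max(ic, na.rm = TRUE)
  names(ic) <- index$terms
  index$ic <- ic
  attr(index$ic, "ic_flagged") <- flagged
  index
}

#' Resnik similarity between two terms
#'
#' The information content of the most informative common ancestor (MICA).
#' The root is a common ancestor of every pair, so the similarity is bounded
#' below by 0.
#'
#' @param index A `phenodx_ontology` with IC attached.
#' @param t1,t2 Term ids.
#' @return Similarity in nats (non-negative scalar).
#' @export
resnik_pair <- function(index, t1, t2) {
  if (is.null(index$ic)) stop("information content not attached; call information_content() first")
  if (!(t1 %in% index$terms) || !(t2 %in% index$terms)) {
    stop("term not in ontology: ", paste(setdiff(c(t1, t2), index$terms), collapse = ", "))
  }
  common <- intersect(index$ancestors[[t1]], index$ancestors[[t2]])
  max(index$ic[common])
}

#' Best-match-average semantic similarity between two term sets
#'
#' Symmetric best-match-average of Resnik pair similarities: for each term in
#' one set take the best match in the other set, average within each
#' direction, then average the two directions. Symmetric by construction.
#'
#' @param index A `phenodx_ontology` with IC attached.
#' @param set_a,set_b Non-empty character vectors of term ids.
#' @return Similarity in nats.
#' @export
patient_similarity <- function(index, set_a, set_b) {
  if (!length(set_a) || !length(set_b)) stop("term sets must be non-empty")
  m <- cross_resnik(index, set_a, set_b)
  (mean(apply(m, 1, max)) + mean(apply(m, 2, max))) / 2
}

# all-pairs Resnik matrix (|A| x |B|)
cross_resnik <- function(index, set_a, set_b) {
  if (is.null(index$ic)) stop("information content not attached; call information_content() first")
  m <- matrix(0, length(set_a), length(set_b), dimnames = list(set_a, set_b))
  anc_b <- index$ancestors[set_b]
  for (i in seq_along(set_a)) {
    a_anc <- index$ancestors[[set_a[i]]]
    for (j in seq_along(set_b)) {
      m[i, j] <- max(index$ic[intersect(a_anc, anc_b[[j]])])
    }
  }
  m
}

#' Read the term-to-subcategory and subcategory-to-group mapping
#'
#' The phenotype categorization used throughout: ontology terms are assigned
#' by expert curation to non-overlapping subcategories (49 in the reference
#' categorization), each of which belongs to exactly one higher-order group
#' (12 in the reference categorization).
#'
#' @param term_file TSV with columns `term_id`, `subcategory`.
#' @param group_file TSV with columns `subcategory`, `higher_group`.
#' @return An object of class `phenodx_groupmap`: list with `term2sub`
#'   (named character), `sub2group` (named character), `subcategories`,
#'   `groups` (level vectors, in file order).
#' @export
read_group_map <- function(term_file, group_file) {
  tm <- utils::read.delim(term_file, stringsAsFactors = FALSE)
  gm <- utils::read.delim(group_file, stringsAsFactors = FALSE)
  stopifnot(all(c("term_id", "subcategory") %in% names(tm)),
            all(c("subcategory", "higher_group") %in% names(gm)))
  if (anyDuplicated(tm$term_id)) stop("a term maps to more than one subcategory")
  if (anyDuplicated(gm$subcategory)) stop("a subcategory maps to more than one higher-order group")
  missing_sub <- setdiff(unique(tm$subcategory), gm$subcategory)
  if (length(missing_sub)) stop("subcategories without a higher-order group: ",
                                paste(missing_sub, collapse = ", "))
  group_map(stats::setNames(tm$subcategory, tm$term_id),
            stats::setNames(gm$higher_group, gm$subcategory))
}

#' Construct a group map from in-memory vectors
#'
#' @param term2sub Named character: term id -> subcategory label.
#' @param sub2group Named character: subcategory -> higher-order group label.
#' @return A `phenodx_groupmap`.
#' @export
group_map <- function(term2sub, sub2group) {
  orphan <- setdiff(unique(unname(term2sub)), names(sub2group))
  if (length(orphan)) stop("subcategories without a higher-order group: ",
                           paste(orphan, collapse = ", "))
  structure(list(
    term2sub = term2sub, sub2group = sub2group,
    subcategories = names(sub2group),
    groups = unique(unname(sub2group))
  ), class = "phenodx_groupmap")
}

#' Assign a patient's terms to phenotype subcategories and higher-order groups
#'
#' A subcategory indicator is set when the patient carries at least one term
#' belonging to it. With `use_closure = TRUE` (default) a term absent from
#' the mapping table is assigned via its nearest mapped ancestor (the mapped
#' ancestor with the largest ancestor closure, i.e. the most specific one),
#' so that terms newer or more specific than the curated table do not drop a
#' patient; with `use_closure = FALSE` only exact matches count. The
#' higher-order group vector is the OR over its subcategories. A patient may
#' legitimately hit several subcategories and groups.
#'
#' @param terms Character vector of the patient's (validated) term ids.
#' @param map A `phenodx_groupmap`.
#' @param index A `phenodx_ontology` (needed for closure and validation).
#' @param use_closure Assign unmapped terms via nearest mapped ancestor.
#' @return List with `subcategory` and `higher_group`: named 0/1 integer
#'   vectors over all subcategory / group levels. Patients with no mappable
#'   terms get all-zero vectors with a warning.
#' @export
assign_groups <- function(terms, map, index, use_closure = TRUE) {
  terms <- resolve_terms(index, terms)
  hit <- character(0)
  for (t in terms) {
    if (t %in% names(map$term2sub)) {
      hit <- c(hit, map$term2sub[[t]])
    } else if (use_closure) {
      cand <- setdiff(intersect(index$ancestors[[t]], names(map$term2sub)), t)
      if (length(cand)) {
        depth <- vapply(index$ancestors[cand], length, integer(1))
        best <- cand[depth == max(depth)]
        hit <- c(hit, map$term2sub[[sort(best)[1]]])
      }
    }
  }
  sub <- stats::setNames(integer(length(map$subcategories)), map$subcategories)
  grp <- stats::setNames(integer(length(map$groups)), map$groups)
  if (!length(hit)) {
    warning("patient has no terms mappable to any subcategory")
  } else {
    sub[unique(hit)] <- 1L
    grp[unique(map$sub2group[unique(hit)])] <- 1L
  }
  list(subcategory = sub, higher_group = grp)
}

#' Subcategory indicator matrix for a list of patients
#'
#' Convenience wrapper applying [assign_groups()] across a cohort.
#'
#' @param term_sets List of character vectors (one per patient).
#' @param map A `phenodx_groupmap`.
#' @param index A `phenodx_ontology`.
#' @param use_closure Passed to [assign_groups()].
#' @return List with `subcategory` (n x 49 matrix) and `higher_group`
#'   (n x 12 matrix) 0/1 matrices.
#' @export
assign_groups_matrix <- function(term_sets, map, index, use_closure = TRUE) {
  res <- lapply(term_sets, function(ts) {
    suppressWarnings(assign_groups(ts, map, index, use_closure = use_closure))
  })
  list(
    subcategory = do.call(rbind, lapply(res, `[[`, "subcategory")),
    higher_group = do.call(rbind, lapply(res, `[[`, "higher_group"))
  )
}
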