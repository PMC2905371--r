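# Evaluation protocol: Bader-style overlap matching against a known-complex
# catalog, precision/recall, the same-function ratio, false-negative
# accounting for the exclusivity assumption, and function suggestion for
# uncharacterized proteins.

#' Bader-style overlap score between two complexes
#'
#' `V = |Np ∩ Nk|^2 / (|Np| * |Nk|)` for the member sets of a predicted and
#' a known complex. Symmetric, in `[0, 1]`, and 1 exactly when the sets are
#' identical.
#'
#' @param predicted,known Non-empty character vectors of protein ids.
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' overlap_score(c("a", "b", "c", "d"), letters[1:8])  # 16/32 = 0.5
overlap_score <- function(predicted, known) {
  p <- unique(as.character(predicted))
  k <- unique(as.character(known))
  if (length(p) == 0 || length(k) == 0) {
    abort("overlap_score() needs two non-empty protein sets.")
  }
  length(intersect(p, k))^2 / (length(p) * length(k))
}

#' Precision and recall against a known-complex catalog
#'
#' A prediction matches a known complex when their overlap score is strictly
#' greater than `threshold` (default 0.25). Precision is the fraction of
#' predictions matching at least one known complex; recall is the fraction of
#' known complexes matched by at least one prediction — several predictions
#' may match the same known complex.
#'
#' @param predicted Verified-complex tibble, `candidate_set`, or list of
#'   member vectors.
#' @param known A `complex_catalog`.
#' @param threshold Match cutoff on the overlap score V, strict. Default
#'   0.25.
#'
#' @return A `complex_eval`: list with `matches` (per prediction: best known
#'   complex, best V, matched flag) and `summary` (predicted / known /
#'   matched counts, precision, recall). [tidy()] returns `matches`,
#'   [glance()] the summary row.
#' @export
precision_recall <- function(predicted, known, threshold = 0.25) {
  stopifnot(inherits(known, "complex_catalog"))
  pred_sets <- member_sets(predicted)
  known_sets <- member_sets(known)
  if (length(pred_sets) == 0 || length(known_sets) == 0) {
    if (length(pred_sets) == 0) {
      warn("precision_recall: no predictions; precision and recall are 0.")
    }
    matches <- tibble(prediction = seq_along(pred_sets),
                      best_known = rep(NA_character_, length(pred_sets)),
                      best_v = rep(NA_real_, length(pred_sets)),
                      matched = rep(FALSE, length(pred_sets)))
    matched_known <- 0L
  } else {
    vmat <- vapply(known_sets,
                   function(k) map_dbl(pred_sets, overlap_score, known = k),
                   numeric(length(pred_sets)))
    vmat <- matrix(vmat, nrow = length(pred_sets))
    best <- apply(vmat, 1, which.max)
    matches <- tibble(
      prediction = seq_along(pred_sets),
      best_known = known$complex_id[best],
      best_v = vmat[cbind(seq_along(pred_sets), best)],
      matched = vmat[cbind(seq_along(pred_sets), best)] > threshold
    )
    matched_known <- sum(apply(vmat, 2, max) > threshold)
  }
  n_pred <- length(pred_sets)
  n_known <- length(known_sets)
  summary <- tibble(
    predicted = n_pred, known = n_known,
    matched_predicted = sum(matches$matched),
    matched_known = matched_known,
    precision = if (n_pred > 0) sum(matches$matched) / n_pred else 0,
    recall = if (n_known > 0) matched_known / n_known else 0,
    threshold = threshold
  )
  structure(list(matches = matches, summary = summary), class = "complex_eval")
}

#' @export
print.complex_eval <- function(x, ...) {
  s <- x$summary
  cat(sprintf("# Complex evaluation (V > %g): precision %.3f (%d/%d), recall %.3f (%d/%d)\n",
              s$threshold, s$precision, s$matched_predicted, s$predicted,
              s$recall, s$matched_known, s$known))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.complex_eval <- function(x, ...) x$matches

#' @exportS3Method generics::glance
glance.complex_eval <- function(x, ...) x$summary

# molecular-function terms of a gene, with the "function unknown" terms
# removed; a gene is characterized iff this is non-empty
known_function_terms <- function(go) {
  go[!go$term %in% go_unknown_terms, , drop = FALSE]
}

#' Ratio of within-complex protein pairs sharing a molecular function
#'
#' Over all unordered within-complex protein pairs in which both members
#' carry at least one informative molecular-function GO term, the fraction
#' that share at least one identical term id (flat comparison, no ontology
#' traversal). Pairs involving unannotated or unknown-function proteins
#' (GO:0003674 / GO:0005554) are excluded from the denominator.
#'
#' @param complexes Verified-complex tibble, `candidate_set`, catalog, or
#'   list of member vectors.
#' @param go A `go_annotation`.
#' @return A number in `[0, 1]`, or `NA` when no pair is eligible.
#' @export
same_function_ratio <- function(complexes, go) {
  stopifnot(inherits(go, "go_annotation"))
  informative <- known_function_terms(go)
  terms_of <- split(informative$term, informative$gene)
  n_pairs <- 0L
  n_shared <- 0L
  for (mem in member_sets(complexes)) {
    annotated <- mem[mem %in% names(terms_of)]
    if (length(annotated) < 2) next
    cmb <- utils::combn(annotated, 2)
    for (c in seq_len(ncol(cmb))) {
      n_pairs <- n_pairs + 1L
      if (length(intersect(terms_of[[cmb[1, c]]], terms_of[[cmb[2, c]]])) > 0) {
        n_shared <- n_shared + 1L
      }
    }
  }
  if (n_pairs == 0) NA_real_ else n_shared / n_pairs
}

#' False-negative accounting for the exclusivity assumption
#'
#' Verification filters the candidates of an existing method, so any known
#' complex recovered by the existing method but lost after verification is a
#' "net" false negative of the filter. Known complexes whose members carry
#' no cognate DDI annotation at all could never be verified regardless of
#' exclusivity, so they are subtracted; what remains (`alpha`) estimates the
#' complexes lost specifically to the one-DDI-per-interface assumption,
#' reported relative to the existing method's true positives (`beta`).
#'
#' @param existing_predictions Candidate predictions from the existing
#'   method (any member-set container).
#' @param our_predictions The verified predictions derived from them.
#' @param known A `complex_catalog`.
#' @param domains A `domain_annotation`.
#' @param ddis A `ddi_catalog`.
#' @param threshold Match cutoff on the overlap score V, strict. Default
#'   0.25.
#'
#' @return A one-row tibble: `fn_existing`, `fn_ours`, `net_fn`,
#'   `no_ddi_excluded`, `alpha`, `beta`, `ratio` (`alpha / beta`).
#' @export
false_negative_report <- function(existing_predictions, our_predictions,
                                  known, domains, ddis, threshold = 0.25) {
  stopifnot(inherits(known, "complex_catalog"))
  known_sets <- member_sets(known)
  matched_by <- function(preds) {
    sets <- member_sets(preds)
    if (length(sets) == 0) return(rep(FALSE, length(known_sets)))
    map_lgl(known_sets, function(k) {
      any(map_dbl(sets, overlap_score, known = k) > threshold)
    })
  }
  m_exist <- matched_by(existing_predictions)
  m_ours <- matched_by(our_predictions)
  net_fn_idx <- which(m_exist & !m_ours)

  cat_keys <- pair_key(ddis$domain_a, ddis$domain_b)
  has_ddi_annotation <- function(mem) {
    inst <- domains[domains$protein %in% mem, , drop = FALSE]
    types <- split(inst$domain_type, inst$protein)
    if (length(types) < 2) return(FALSE)
    prs <- utils::combn(names(types), 2)
    for (c in seq_len(ncol(prs))) {
      grid <- expand.grid(a = types[[prs[1, c]]], b = types[[prs[2, c]]],
                          stringsAsFactors = FALSE)
      if (any(pair_key(grid$a, grid$b) %in% cat_keys)) return(TRUE)
    }
    FALSE
  }
  no_ddi <- sum(!map_lgl(known_sets[net_fn_idx], has_ddi_annotation))

  beta <- sum(m_exist)
  alpha <- length(net_fn_idx) - no_ddi
  tibble(
    fn_existing = sum(!m_exist),
    fn_ours = sum(!m_ours),
    net_fn = length(net_fn_idx),
    no_ddi_excluded = as.integer(no_ddi),
    alpha = as.integer(alpha),
    beta = as.integer(beta),
    ratio = if (beta > 0) alpha / beta else NA_real_
  )
}

#' Suggest functions for uncharacterized proteins in predicted complexes
#'
#' Proteins in a complex tend to share function, so a complex containing
#' exactly one uncharacterized protein (no informative molecular-function
#' term, or annotated "molecular function unknown") whose remaining members
#' all share at least one common molecular-function term suggests that
#' shared function for the uncharacterized member.
#'
#' @param complexes Verified-complex tibble or any member-set container.
#' @param go A `go_annotation`.
#' @return A tibble: `complex` (index or id), `members` (list),
#'   `uncharacterized`, `suggested_terms` (list). Zero rows when no complex
#'   qualifies.
#' @export
suggest_functions <- function(complexes, go) {
  stopifnot(inherits(go, "go_annotation"))
  informative <- known_function_terms(go)
  terms_of <- split(informative$term, informative$gene)
  sets <- member_sets(complexes)
  ids <- if (is.data.frame(complexes) && "complex_id" %in% names(complexes)) {
    complexes$complex_id
  } else {
    as.character(seq_along(sets))
  }
  out <- list()
  for (i in seq_along(sets)) {
    mem <- sets[[i]]
    unchar <- mem[!mem %in% names(terms_of)]
    if (length(unchar) != 1 || length(mem) < 2) next
    others <- setdiff(mem, unchar)
    shared <- Reduce(intersect, terms_of[others])
    if (length(shared) == 0) next
    out[[length(out) + 1]] <- tibble(
      complex = ids[i], members = list(mem), uncharacterized = unchar,
      suggested_terms = list(sort(shared))
    )
  }
  if (length(out) == 0) {
    tibble(complex = character(), members = list(),
           uncharacterized = character(), suggested_terms = list())
  } else {
    bind_rows(out)
  }
}
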