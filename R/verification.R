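#' Extract verified complexes from a solved candidate
#'
#' Builds the graph of active PPIs chosen by the solver and accepts every
#' connected component with at least `min_size` proteins as one verified
#' complex: three or more proteins connected by simultaneously feasible,
#' DDI-mediated interactions. A component of size 3 is necessarily held
#' together by at least two active DDIs, which is the acceptance rule for a
#' final prediction. A single candidate can yield zero, one, or several
#' verified complexes.
#'
#' @param candidate Character vector of candidate members (or a one-row
#'   `candidate_set` slice); used for provenance only.
#' @param solution A `binding_solution` for that candidate's model.
#' @param min_size Minimum component size to accept. Default 3.
#' @param source_candidate Provenance label recorded on each output row.
#'
#' @return A verified-complex tibble: `complex_id`, `members` (list),
#'   `n_proteins`, `objective`, `source_candidate`, `ppi_edges` (list of
#'   tibbles), `ddi_edges` (list of tibbles).
#' @export
extract_verified <- function(candidate, solution, min_size = 3,
                             source_candidate = NA_character_) {
  stopifnot(inherits(solution, "binding_solution"))
  pp <- solution$active_ppis
  if (nrow(pp) == 0) return(empty_verified())
  g <- igraph::graph_from_data_frame(as.data.frame(pp), directed = FALSE)
  comp <- igraph::components(g)
  keep <- which(comp$csize >= min_size)
  if (length(keep) == 0) return(empty_verified())
  dd <- solution$active_ddis
  out <- map(keep, function(ci) {
    mem <- sort(igraph::V(g)$name[comp$membership == ci])
    p_in <- pp[pp$protein_a %in% mem & pp$protein_b %in% mem, , drop = FALSE]
    d_in <- dd[dd$protein_i %in% mem & dd$protein_j %in% mem, , drop = FALSE]
    tibble(complex_id = NA_character_,
           members = list(mem),
           n_proteins = length(mem),
           objective = solution$objective,
           source_candidate = source_candidate,
           ppi_edges = list(arrange(p_in, .data$protein_a, .data$protein_b)),
           ddi_edges = list(select(arrange(d_in, .data$ddi_id),
                                   "protein_i", "domain_i", "copy_i",
                                   "protein_j", "domain_j", "copy_j")))
  })
  out <- bind_rows(out)
  out <- out[order(map_chr(out$members, paste, collapse = " ")), , drop = FALSE]
  out$complex_id <- sprintf("V%03d", seq_len(nrow(out)))
  out
}

#' Verify a set of candidate complexes
#'
#' Runs build-model / solve / extract for every candidate with at least
#' `min_size` members, deduplicates verified complexes that share an
#' identical member set (keeping the record with the higher solver
#' objective), and reports summary accounting: candidate and verified
#' counts, the reduction rate, and the verified size distribution.
#'
#' @param candidates A `candidate_set` tibble ([mcl_cluster()],
#'   [cc_cluster()], [import_clusters()]).
#' @param network A [ppi_network()].
#' @param domains A `domain_annotation`.
#' @param ddis A `ddi_catalog`.
#' @param min_size Minimum verified complex size. Default 3.
#'
#' @return A `verification_result`: list with `verified` (tibble as in
#'   [extract_verified()]), `per_candidate` (one row per input candidate
#'   with model sizes, objective and acceptance), and `summary`. [tidy()]
#'   returns the verified tibble, [glance()] the one-row summary.
#' @export
verify_all <- function(candidates, network, domains, ddis, min_size = 3) {
  n_cand <- nrow(candidates)
  per <- vector("list", n_cand)
  ver <- vector("list", n_cand)
  for (i in seq_len(n_cand)) {
    id <- candidates$candidate_id[i]
    mem <- candidates$members[[i]]
    if (length(mem) < min_size) {
      per[[i]] <- tibble(candidate_id = id, n_members = length(mem),
                         n_ppi_vars = NA_integer_, n_ddi_vars = NA_integer_,
                         objective = NA_integer_, n_verified = 0L,
                         accepted = FALSE, note = "skipped: too small")
      next
    }
    res <- tryCatch({
      model <- build_binding_model(mem, network, domains, ddis)
      sol <- solve_binding(model)
      vc <- extract_verified(mem, sol, min_size = min_size,
                             source_candidate = id)
      list(model = model, sol = sol, vc = vc)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warn(sprintf("verify_all: candidate %s failed (%s); skipped.",
                   id, conditionMessage(res)))
      per[[i]] <- tibble(candidate_id = id, n_members = length(mem),
                         n_ppi_vars = NA_integer_, n_ddi_vars = NA_integer_,
                         objective = NA_integer_, n_verified = 0L,
                         accepted = FALSE, note = "error")
      next
    }
    per[[i]] <- tibble(candidate_id = id, n_members = length(mem),
                       n_ppi_vars = nrow(res$model$ppi_vars),
                       n_ddi_vars = nrow(res$model$ddi_vars),
                       objective = res$sol$objective,
                       n_verified = nrow(res$vc),
                       accepted = nrow(res$vc) > 0, note = NA_character_)
    ver[[i]] <- res$vc
  }
  per <- bind_rows(per)
  if (nrow(per) == 0) {
    per <- tibble(candidate_id = character(), n_members = integer(),
                  n_ppi_vars = integer(), n_ddi_vars = integer(),
                  objective = integer(), n_verified = integer(),
                  accepted = logical(), note = character())
  }
  verified <- bind_rows(ver)
  if (nrow(verified) == 0) verified <- empty_verified()

  # dedup on member set, keeping the higher-objective provenance
  if (nrow(verified) > 0) {
    key <- map_chr(verified$members, paste, collapse = "\x1f")
    ord <- order(key, -verified$objective)
    verified <- verified[ord, , drop = FALSE]
    verified <- verified[!duplicated(key[ord]), , drop = FALSE]
    verified$complex_id <- sprintf("V%03d", seq_len(nrow(verified)))
  }

  sizes <- verified$n_proteins
  summary <- tibble(
    n_candidates = n_cand,
    n_considered = sum(is.na(per$note) | per$note == "error"),
    n_verified = nrow(verified),
    reduction_rate = if (n_cand > 0) 1 - nrow(verified) / n_cand else NA_real_,
    mean_size = if (length(sizes) > 0) mean(sizes) else NA_real_,
    max_size = if (length(sizes) > 0) max(sizes) else NA_integer_
  )
  structure(list(verified = verified, per_candidate = per, summary = summary),
            class = "verification_result")
}

#' @export
print.verification_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("# Verification: %d candidates -> %d verified complexes (reduction %.1f%%)\n",
              s$n_candidates, s$n_verified, 100 * s$reduction_rate))
  if (s$n_verified > 0) {
    cat(sprintf("#   mean size %.2f, max size %d\n", s$mean_size, s$max_size))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.verification_result <- function(x, ...) x$verified

#' @exportS3Method generics::glance
glance.verification_result <- function(x, ...) x$summary
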