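# Exact 0/1 optimization of the binding model. Candidates are small (a few
# proteins, tens of DDI variables), so an exact depth-first branch and bound
# in R is both fast enough and fully deterministic; solve_bruteforce() is the
# independent enumeration oracle used by the test suite.

# shared deterministic tie-break: DDI variables are explored in the model's
# canonical order (protein pair, then instance pair), 0 before 1, and an
# incumbent is replaced only on strict improvement — so the returned optimum
# is the lexicographically smallest optimal assignment.

make_solution <- function(model, values, status = "optimal") {
  dv <- model$ddi_vars
  active <- dv[values == 1L, , drop = FALSE]
  pairs <- model$ppi_vars[!model$ppi_vars$fixed_zero &
                            model$ppi_vars$pair_id %in% active$pair_id, ,
                          drop = FALSE]
  structure(
    list(status = status,
         objective = nrow(pairs),
         assignment = tibble(ddi_id = dv$ddi_id, value = as.integer(values)),
         active_ppis = tibble(protein_a = pairs$protein_i,
                              protein_b = pairs$protein_j),
         active_ddis = select(active, "ddi_id", "pair_id", "protein_i",
                              "domain_i", "copy_i", "protein_j", "domain_j",
                              "copy_j")),
    class = "binding_solution"
  )
}

#' @export
print.binding_solution <- function(x, ...) {
  cat(sprintf("# Binding solution (%s): objective %d (active PPIs), %d active DDIs\n",
              x$status, x$objective, nrow(x$active_ddis)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.binding_solution <- function(x, ...) {
  left_join(x$assignment,
            tibble(ddi_id = x$active_ddis$ddi_id, active = TRUE),
            by = "ddi_id") |>
    mutate(active = !is.na(.data$active))
}

#' @exportS3Method generics::glance
glance.binding_solution <- function(x, ...) {
  tibble(status = x$status, objective = x$objective,
         n_active_ppis = nrow(x$active_ppis),
         n_active_ddis = nrow(x$active_ddis))
}

# per-variable indices used by both solvers
solver_indices <- function(model) {
  dv <- model$ddi_vars
  inst_i <- paste0(dv$protein_i, ":", dv$domain_i, "/", dv$copy_i)
  inst_j <- paste0(dv$protein_j, ":", dv$domain_j, "/", dv$copy_j)
  insts <- unique(c(inst_i, inst_j))
  pairs <- unique(dv$pair_id)
  list(n = nrow(dv),
       inst_a = match(inst_i, insts), inst_b = match(inst_j, insts),
       n_inst = length(insts),
       pair = match(dv$pair_id, pairs), n_pair = length(pairs))
}

#' Solve a binding model exactly
#'
#' Maximizes the number of simultaneously realizable PPIs subject to the
#' pair-equality and exclusivity constraints, by deterministic depth-first
#' branch and bound over the DDI variables in canonical order (0-branch
#' first, incumbent replaced only on strict improvement), so among co-optimal
#' solutions the lexicographically smallest DDI assignment is returned —
#' identical to [solve_bruteforce()] on every instance. The all-zero
#' assignment is always feasible, so the program is never infeasible.
#'
#' @param model A `binding_model` from [build_binding_model()].
#' @return A `binding_solution`: `status`, `objective` (number of active
#'   PPIs), `assignment` (0/1 per DDI variable), `active_ppis`,
#'   `active_ddis`. [tidy()] returns the assignment, [glance()] a one-row
#'   summary.
#' @export
#' @examples
#' fx <- worked_example_fixture()
#' m <- build_binding_model(c("p1", "p2", "p3"), fx$network, fx$domains, fx$ddis)
#' solve_binding(m)
solve_binding <- function(model) {
  stopifnot(inherits(model, "binding_model"))
  ix <- solver_indices(model)
  n <- ix$n
  if (n == 0) return(make_solution(model, integer(0)))

  # for the bound: over variables idx..n, which pairs can still be covered
  remaining_pairs <- vapply(seq_len(n + 1), function(k) {
    if (k > n) 0L else length(unique(ix$pair[k:n]))
  }, integer(1))

  best_val <- -1L
  best_assign <- integer(n)
  cur <- integer(n)
  inst_used <- logical(ix$n_inst)
  pair_used <- logical(ix$n_pair)

  recurse <- function(k, obj) {
    # bound: every still-uncovered pair among the remaining vars could be won
    if (obj + min(remaining_pairs[k], sum(!pair_used)) <= best_val) return()
    if (k > n) {
      if (obj > best_val) {
        best_val <<- obj
        best_assign <<- cur
      }
      return()
    }
    # 0-branch first: lexicographic preference for switching variables off
    cur[k] <<- 0L
    recurse(k + 1L, obj)
    a <- ix$inst_a[k]; b <- ix$inst_b[k]; p <- ix$pair[k]
    if (!inst_used[a] && !inst_used[b] && !pair_used[p]) {
      cur[k] <<- 1L
      inst_used[a] <<- TRUE; inst_used[b] <<- TRUE; pair_used[p] <<- TRUE
      recurse(k + 1L, obj + 1L)
      inst_used[a] <<- FALSE; inst_used[b] <<- FALSE; pair_used[p] <<- FALSE
      cur[k] <<- 0L
    }
  }
  recurse(1L, 0L)
  make_solution(model, best_assign)
}

#' Solve a binding model by exhaustive enumeration
#'
#' The independent oracle: enumerates all `2^n` DDI assignments, discards the
#' infeasible ones, and returns the maximum-objective assignment under the
#' same tie-break rule as [solve_binding()] (lexicographically smallest over
#' the canonically ordered DDI variables). Exponential by construction; use
#' only on small models.
#'
#' @param model A `binding_model`.
#' @param max_vars Refuse models with more DDI variables than this.
#'   Default 20.
#' @return A `binding_solution`.
#' @export
solve_bruteforce <- function(model, max_vars = 20) {
  stopifnot(inherits(model, "binding_model"))
  ix <- solver_indices(model)
  n <- ix$n
  if (n > max_vars) {
    abort(sprintf("Model has %d DDI variables (> max_vars = %d); use solve_binding().",
                  n, max_vars))
  }
  if (n == 0) return(make_solution(model, integer(0)))

  # all assignments as a 2^n x n 0/1 matrix; row order = lexicographic with
  # variable 1 as the most significant bit
  codes <- 0:(2^n - 1)
  bits <- vapply(seq_len(n), function(j) codes %/% 2^(n - j) %% 2, numeric(length(codes)))
  bits <- matrix(bits, ncol = n)

  # exclusivity over ALL domain instances (instances inside a single pair are
  # also checked here; for feasible assignments this is implied by the pair
  # cap, so the oracle is deliberately stricter than it needs to be)
  inc_inst <- matrix(0, ix$n_inst, n)
  inc_inst[cbind(ix$inst_a, seq_len(n))] <- 1
  inc_inst[cbind(ix$inst_b, seq_len(n))] <- inc_inst[cbind(ix$inst_b, seq_len(n))] + 1
  inc_pair <- matrix(0, ix$n_pair, n)
  inc_pair[cbind(ix$pair, seq_len(n))] <- 1

  inst_load <- bits %*% t(inc_inst)
  pair_load <- bits %*% t(inc_pair)
  feasible <- rowSums(inst_load > 1) == 0 & rowSums(pair_load > 1) == 0
  obj <- rowSums(pair_load == 1)
  obj[!feasible] <- -1
  best <- which(obj == max(obj))[1]   # first index = lexicographically smallest
  make_solution(model, as.integer(bits[best, ]))
}
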