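# Optimal feature-subset selection.
#
# The selection problem maximizes
#     sum_{i in S} MI_i  -  lambda * sum_{(i,j) in P, i,j in S} |corr_ij|
# over subsets S with |S| <= c.  In the integer-program form each feature
# carries a binary w_i, each candidate pair a binary z_ij with
# z_ij >= w_i + w_j - 1; with non-negative penalties the optimum has
# z_ij = w_i * w_j, so the objective above is the exact combinatorial
# equivalent.  It is solved here exactly by branch and bound with an
# admissible bound (pair penalties among undecided features are
# ignored), plus connected-component decomposition of the pair graph
# when the cardinality constraint is slack.  Ties between subsets with
# equal objective are broken deterministically: smaller subset first,
# then lexicographically smallest sorted id tuple.

TIE_TOL <- 1e-9

#' Define a feature-selection problem
#'
#' @param relevance named numeric vector: mutual information (bits) per
#'   candidate feature, typically the MI-filtered relevance table.
#' @param pairs a `candidate_pairs` data.frame from
#'   [build_candidate_pairs()] (columns `i`, `j`, `abs_corr`); every
#'   endpoint must be a named feature.
#' @param lam non-negative redundancy weight (lambda), default 1.
#' @param max_features cap on the number of selected features; `Inf`
#'   leaves the subset size free so the optimizer picks it.
#' @param time_limit_s wall-clock limit for the exact search; on timeout
#'   the incumbent is returned with status `feasible-time-limit`.
#' @return an object of class `selection_problem`.
#' @export
selection_problem <- function(relevance, pairs = NULL, lam = 1,
                              max_features = Inf, time_limit_s = Inf) {
  stopifnot(lam >= 0, max_features >= 0)
  ids <- sort(names(relevance))
  if (is.null(ids) || anyDuplicated(ids)) stop("features must have unique names")
  if (is.null(pairs))
    pairs <- data.frame(i = character(), j = character(),
                        corr = numeric(), abs_corr = numeric())
  bad <- setdiff(unique(c(pairs$i, pairs$j)), ids)
  if (length(bad)) stop("pair endpoint is not a feature: ",
                        paste(bad, collapse = ", "))
  # canonical order: i < j by id
  if (nrow(pairs)) {
    flip <- pairs$i > pairs$j
    tmp <- pairs$i[flip]; pairs$i[flip] <- pairs$j[flip]; pairs$j[flip] <- tmp
    pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  structure(list(ids = ids, mi = unname(relevance[ids]), pairs = pairs,
                 lam = lam, max_features = max_features,
                 time_limit_s = time_limit_s),
            class = "selection_problem")
}

#' Evaluate the selection objective for a given subset
#'
#' The combinatorial objective: total mutual information of the selected
#' features minus `lambda` times the total absolute correlation over
#' candidate pairs fully inside the selection.
#'
#' @param selected character vector of selected feature ids.
#' @param problem a [selection_problem()].
#' @return numeric objective value.
#' @export
objective_value <- function(selected, problem) {
  selected <- sort(unique(as.character(selected)))
  unknown <- setdiff(selected, problem$ids)
  if (length(unknown)) stop("unknown feature id: ",
                            paste(unknown, collapse = ", "))
  mi_sum <- sum(problem$mi[match(selected, problem$ids)])
  pen <- 0
  if (nrow(problem$pairs)) {
    inside <- problem$pairs$i %in% selected & problem$pairs$j %in% selected
    pen <- sum(problem$pairs$abs_corr[inside])
  }
  mi_sum - problem$lam * pen
}

# deterministic preference between two complete solutions
better_solution <- function(obj_a, set_a, obj_b, set_b) {
  if (obj_a > obj_b + TIE_TOL) return(TRUE)
  if (obj_a < obj_b - TIE_TOL) return(FALSE)
  if (length(set_a) != length(set_b)) return(length(set_a) < length(set_b))
  for (k in seq_along(set_a)) {
    if (set_a[k] < set_b[k]) return(TRUE)
    if (set_a[k] > set_b[k]) return(FALSE)
  }
  FALSE
}

#' Exhaustive-enumeration oracle for small selection problems
#'
#' Enumerates every subset within the cardinality cap and returns the
#' best under the same objective and tie-breaking rules as the exact
#' solver.  Refuses more than 20 features.
#'
#' @param problem a [selection_problem()].
#' @return a `selection_result` list: `selected`, `objective`, `status`.
#' @export
brute_force_select <- function(problem) {
  n <- length(problem$ids)
  if (n > 20L) stop("brute force limited to 20 features")
  cmax <- min(problem$max_features, n)
  masks <- 0:(2^n - 1)
  sizes <- integer(length(masks))
  mi_tot <- numeric(length(masks))
  for (i in seq_len(n)) {
    has <- bitwAnd(masks, bitwShiftL(1L, i - 1L)) != 0L
    sizes <- sizes + has
    mi_tot <- mi_tot + has * problem$mi[i]
  }
  pen <- numeric(length(masks))
  if (nrow(problem$pairs)) {
    ia <- match(problem$pairs$i, problem$ids)
    ib <- match(problem$pairs$j, problem$ids)
    for (p in seq_along(ia)) {
      both <- bitwAnd(masks, bitwShiftL(1L, ia[p] - 1L)) != 0L &
              bitwAnd(masks, bitwShiftL(1L, ib[p] - 1L)) != 0L
      pen <- pen + both * problem$pairs$abs_corr[p]
    }
  }
  obj <- mi_tot - problem$lam * pen
  obj[sizes > cmax] <- -Inf
  cand <- which(obj >= max(obj) - TIE_TOL)
  best_set <- NULL; best_obj <- -Inf
  for (mk in masks[cand]) {
    sel <- problem$ids[bitwAnd(mk, bitwShiftL(1L, seq_len(n) - 1L)) != 0L]
    o <- objective_value(sel, problem)
    if (is.null(best_set) || better_solution(o, sel, best_obj, best_set)) {
      best_set <- sel; best_obj <- o
    }
  }
  list(selected = best_set, objective = best_obj, status = "optimal")
}

#' Solve the selection problem exactly
#'
#' Exact branch-and-bound maximization of the selection objective, with
#' deterministic tie-breaking (smaller subset, then lexicographically
#' smallest id tuple).  When the cardinality constraint is slack and no
#' solutions are excluded, the pair graph decomposes into connected
#' components that are solved independently; isolated features are
#' selected exactly when their mutual information is positive.
#'
#' @param problem a [selection_problem()].
#' @param exclude optional list of previously found selections (character
#'   vectors) that may not be returned again (no-good cuts).
#' @return a `selection_result`: `selected` (sorted ids), `objective`,
#'   `status` (`optimal` or `feasible-time-limit`), or `NULL` when every
#'   feasible subset is excluded.
#' @export
solve_selection <- function(problem, exclude = list()) {
  n <- length(problem$ids)
  deadline <- if (is.finite(problem$time_limit_s))
    Sys.time() + problem$time_limit_s else NULL
  if (n == 0L)
    return(list(selected = character(), objective = 0, status = "optimal"))
  if (!length(exclude) && problem$max_features >= n)
    return(solve_by_components(problem, deadline))
  res <- bnb_search(problem, exclude, deadline)
  if (is.null(res$selected) && is.null(res$timeout)) return(NULL)
  res
}

solve_by_components <- function(problem, deadline) {
  ids <- problem$ids
  pr <- problem$pairs
  memb <- stats::setNames(seq_along(ids), ids)
  if (nrow(pr)) {
    ig <- igraph::graph_from_data_frame(
      pr[, c("i", "j")], directed = FALSE,
      vertices = data.frame(name = ids))
    memb <- igraph::components(ig)$membership[ids]
  }
  selected <- character(); objective <- 0; status <- "optimal"
  for (comp in unique(memb)) {
    comp_ids <- ids[memb == comp]
    if (length(comp_ids) == 1L) {
      mi <- problem$mi[match(comp_ids, ids)]
      if (mi > TIE_TOL) {              # at a tie with 0, parsimony wins
        selected <- c(selected, comp_ids); objective <- objective + mi
      }
      next
    }
    sub <- selection_problem(
      stats::setNames(problem$mi[match(comp_ids, ids)], comp_ids),
      pr[pr$i %in% comp_ids & pr$j %in% comp_ids, , drop = FALSE],
      lam = problem$lam, max_features = Inf,
      time_limit_s = problem$time_limit_s)
    res <- bnb_search(sub, list(), deadline)
    selected <- c(selected, res$selected)
    objective <- objective + res$objective
    if (res$status != "optimal") status <- res$status
  }
  selected <- sort(selected)
  list(selected = selected,
       objective = objective_value(selected, problem), status = status)
}

bnb_search <- function(problem, exclude, deadline) {
  ids <- problem$ids
  n <- length(ids)
  cmax <- min(problem$max_features, n)
  lam <- problem$lam
  # branch on features in decreasing-MI order (ties by id for determinism)
  ord <- order(-problem$mi, ids)
  mi <- problem$mi[ord]
  pos_of <- match(seq_len(n), ord)       # original index -> branch position
  nbr <- vector("list", n); wts <- vector("list", n)
  if (nrow(problem$pairs)) {
    ia <- pos_of[match(problem$pairs$i, ids)]
    ib <- pos_of[match(problem$pairs$j, ids)]
    for (p in seq_along(ia)) {
      nbr[[ia[p]]] <- c(nbr[[ia[p]]], ib[p])
      wts[[ia[p]]] <- c(wts[[ia[p]]], problem$pairs$abs_corr[p])
      nbr[[ib[p]]] <- c(nbr[[ib[p]]], ia[p])
      wts[[ib[p]]] <- c(wts[[ib[p]]], problem$pairs$abs_corr[p])
    }
  }
  exclude_keys <- vapply(exclude, function(s)
    paste(sort(s), collapse = "\r"), character(1))

  env <- new.env(parent = emptyenv())
  env$best_set <- NULL; env$best_obj <- -Inf; env$timeout <- FALSE
  chosen <- logical(n)

  consider <- function(val) {
    sel <- sort(ids[ord[which(chosen)]])
    if (paste(sel, collapse = "\r") %in% exclude_keys) return()
    obj <- objective_value(sel, problem)
    if (is.null(env$best_set) ||
        better_solution(obj, sel, env$best_obj, env$best_set)) {
      env$best_set <- sel; env$best_obj <- obj
    }
  }

  recurse <- function(pos, k, val) {
    if (env$timeout) return()
    if (!is.null(deadline) && Sys.time() > deadline) {
      env$timeout <- TRUE
      return()
    }
    if (pos > n) { consider(val); return() }
    # admissible bound: best-case gains of undecided features, ignoring
    # penalties among themselves
    rest <- pos:n
    gains <- vapply(rest, function(q) {
      g <- mi[q]
      if (length(nbr[[q]])) {
        hit <- chosen[nbr[[q]]]
        if (any(hit)) g <- g - lam * sum(wts[[q]][hit])
      }
      g
    }, numeric(1))
    gains <- sort(gains[gains > 0], decreasing = TRUE)
    room <- cmax - k
    bound <- val + sum(gains[seq_len(min(room, length(gains)))])
    if (bound < env$best_obj - TIE_TOL) return()
    # include branch first (greedy on high-MI ordering)
    if (k < cmax) {
      pen <- if (length(nbr[[pos]])) sum(wts[[pos]][chosen[nbr[[pos]]]]) else 0
      chosen[pos] <<- TRUE
      recurse(pos + 1L, k + 1L, val + mi[pos] - lam * pen)
      chosen[pos] <<- FALSE
    }
    recurse(pos + 1L, k, val)
  }
  recurse(1L, 0L, 0)
  list(selected = env$best_set,
       objective = if (is.null(env$best_set)) -Inf else env$best_obj,
       status = if (env$timeout) "feasible-time-limit" else "optimal",
       timeout = if (env$timeout) TRUE else NULL)
}

#' Enumerate alternate optimal selections
#'
#' Repeatedly re-solves with a no-good cut excluding every selection
#' found so far, collecting up to `k` selections whose objective ties
#' the first optimum (within `1e-9`); stops early once the objective
#' drops.
#'
#' @param problem a [selection_problem()].
#' @param k maximum number of solutions to return.
#' @return list of `selection_result`s (possibly length < `k`).
#' @export
enumerate_alternate_optima <- function(problem, k) {
  if (k <= 0L) return(list())
  first <- solve_selection(problem)
  sols <- list(first)
  while (length(sols) < k) {
    nxt <- solve_selection(problem,
                           exclude = lapply(sols, `[[`, "selected"))
    if (is.null(nxt) || nxt$objective < first$objective - TIE_TOL) break
    sols <- c(sols, list(nxt))
  }
  sols
}
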