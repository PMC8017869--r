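#' Evaluation plan for repeated hold-out assessment
#'
#' @param holdout_fraction fraction of samples set aside per permutation
#'   (default 0.30).
#' @param folds cross-validation folds on the training portion
#'   (default 5; recorded for provenance, the holdout AUC is the primary
#'   metric).
#' @param permutations number of independent train/holdout permutations
#'   (default 10).
#' @param classifier one of `logistic_regression`, `random_forest_100`,
#'   `svm_rbf`.
#' @param seed integer seed controlling all splits and stochastic
#'   classifiers.
#' @return an `eval_plan` list.
#' @export
eval_plan <- function(holdout_fraction = 0.30, folds = 5L,
                      permutations = 10L,
                      classifier = c("logistic_regression",
                                     "random_forest_100", "svm_rbf"),
                      seed = 1L) {
  if (!(holdout_fraction > 0 && holdout_fraction < 1))
    stop("holdout_fraction must be in (0, 1)")
  if (folds < 2L) stop("folds must be at least 2")
  structure(list(holdout_fraction = holdout_fraction, folds = folds,
                 permutations = as.integer(permutations),
                 classifier = match.arg(classifier),
                 seed = as.integer(seed)), class = "eval_plan")
}

#' Stratified train/holdout permutations
#'
#' Each permutation is a stratified split: the holdout takes
#' `round(holdout_fraction * n)` samples overall, allocated across label
#' classes by largest remainder so class proportions are preserved.
#' Train and holdout are disjoint and exhaustive; an error is raised if
#' any label class would vanish from the training side.
#'
#' @param cohort a [cohort()] with at least 10 samples.
#' @param plan an [eval_plan()].
#' @return list of length `plan$permutations`, each a list with
#'   `train_ids` and `holdout_ids`.
#' @export
split_permutations <- function(cohort, plan) {
  n <- length(cohort$sample_ids)
  if (n < 10L) stop("need at least 10 samples")
  m <- round(plan$holdout_fraction * n)
  classes <- split(cohort$sample_ids, cohort$labels)
  withr::with_seed(plan$seed, {
    lapply(seq_len(plan$permutations), function(p) {
      k <- vapply(classes, function(s) plan$holdout_fraction * length(s),
                  numeric(1))
      base <- floor(k)
      rem <- m - sum(base)
      if (rem > 0) {
        extra <- order(k - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1L
      }
      holdout <- unlist(lapply(seq_along(classes), function(ci)
        sample(classes[[ci]], base[ci])), use.names = FALSE)
      train <- setdiff(cohort$sample_ids, holdout)
      lab_train <- cohort$labels[match(train, cohort$sample_ids)]
      if (length(unique(lab_train)) < length(classes))
        stop("a label class is absent from the training split")
      list(train_ids = train, holdout_ids = holdout)
    })
  })
}

#' Subset a variant set or cohort to given samples
#'
#' @param x a `variant_set` or [cohort()].
#' @param sample_ids samples to keep, in the requested order.
#' @return object of the same class restricted to those samples.
#' @export
subset_samples <- function(x, sample_ids) {
  if (inherits(x, "variant_set")) {
    missing <- setdiff(sample_ids, x$sample_ids)
    if (length(missing)) stop("unknown sample: ", paste(missing, collapse = ", "))
    x$presence <- x$presence[, sample_ids, drop = FALSE]
    x$sample_ids <- sample_ids
    x
  } else if (inherits(x, "cohort")) {
    idx <- match(sample_ids, x$sample_ids)
    if (anyNA(idx)) stop("unknown sample: ",
                         paste(sample_ids[is.na(idx)], collapse = ", "))
    cohort(sample_ids, x$labels[idx])
  } else stop("unsupported class")
}

#' Fit a feature selector on a training cohort
#'
#' Runs the sample-dependent half of the pipeline strictly on the given
#' (training) samples: leaf encoding, GO enrichment thresholds,
#' OR-propagation, collapsing, MI filtering, candidate-pair construction
#' and selection.  Nothing about the held-out samples -- not even their
#' variant counts -- influences any statistic computed here, so applying
#' the fit to new samples is leakage-safe.
#'
#' @param graph the structural [feature_graph()] (built from annotations
#'   and variant loci; sample-independent).
#' @param variants `variant_set` restricted to the training samples.
#' @param cohort training [cohort()] in the same sample order.
#' @param selector one of `ilp`, `shsel`, `threshold`.
#' @param mi_threshold MI pre-filter `t` in bits (default 0.05).
#' @param pair_gate absolute-correlation gate for candidate pairs
#'   (default 0.3).
#' @param lam redundancy weight lambda (default 1).
#' @param max_features cardinality cap `c` (default `Inf`, i.e. the
#'   optimizer chooses the count).
#' @param similarity_threshold redundancy cutoff for the greedy
#'   baseline (default 0.99).
#' @return an `hfs_fit` list: `selected`, `collapsed` (encoded collapsed
#'   graph), `relevance`, `retained`, `cutoffs` (GO thresholds learned
#'   on training data), `selector`, and for the optimal selector the
#'   `result` with objective and status.
#' @export
fit_selector <- function(graph, variants, cohort,
                         selector = c("ilp", "shsel", "threshold"),
                         mi_threshold = 0.05, pair_gate = 0.3, lam = 1,
                         max_features = Inf, similarity_threshold = 0.99) {
  selector <- match.arg(selector)
  enc <- assign_vectors(graph, variants, cohort)
  collapsed <- collapse_redundant(enc)
  flt <- mi_filter(collapsed, cohort, mi_threshold)
  result <- NULL
  selected <- switch(selector,
    threshold = threshold_select(flt$relevance, mi_threshold),
    shsel = shsel_select(collapsed, flt$relevance,
                         similarity_threshold = similarity_threshold,
                         nodes = flt$retained),
    ilp = {
      pairs <- build_candidate_pairs(collapsed, flt$retained,
                                     pair_gate = pair_gate)
      prob <- selection_problem(flt$relevance[flt$retained], pairs,
                                lam = lam, max_features = max_features)
      result <- solve_selection(prob)
      result$selected
    })
  cutoffs <- vapply(collapsed$go_stats, `[[`, numeric(1), "cutoff")
  structure(list(selected = sort(selected), collapsed = collapsed,
                 relevance = flt$relevance, retained = flt$retained,
                 cutoffs = cutoffs, selector = selector,
                 mi_threshold = mi_threshold, result = result),
            class = "hfs_fit")
}

#' Feature matrix for (new) samples under a fitted selector
#'
#' Re-encodes the structural graph for the given samples, applying the
#' GO enrichment cutoffs learned at fit time rather than re-estimating
#' them, and returns the selected features as columns.
#'
#' @param fit an `hfs_fit` from [fit_selector()].
#' @param graph the structural [feature_graph()] used at fit time.
#' @param variants `variant_set` restricted to the samples of interest.
#' @param cohort matching [cohort()].
#' @return numeric matrix, samples x selected features.
#' @export
feature_matrix <- function(fit, graph, variants, cohort) {
  enc <- assign_vectors(graph, variants, cohort, cutoffs = fit$cutoffs)
  t(enc$vectors[fit$selected, , drop = FALSE])
}

#' Hold-out evaluation of a feature-selection strategy
#'
#' For each stratified permutation, feature selection (including MI
#' filtering, GO thresholds and correlations) runs on the training
#' samples only; a classifier is trained on the training features and
#' the AUC is reported on the untouched holdout.  If a permutation
#' selects zero features its AUC is recorded as 0.5 with a warning.
#'
#' @param graph structural [feature_graph()].
#' @param variants full-cohort `variant_set`.
#' @param cohort full [cohort()].
#' @param selector one of `ilp`, `shsel`, `threshold`.
#' @param plan an [eval_plan()].
#' @param ... selector parameters passed to [fit_selector()].
#' @return data.frame with one row per permutation: `permutation`,
#'   `selector`, `n_selected`, `auc`.
#' @export
evaluate_selection <- function(graph, variants, cohort, selector, plan, ...) {
  splits <- split_permutations(cohort, plan)
  rows <- lapply(seq_along(splits), function(p) {
    sp <- splits[[p]]
    tr_var <- subset_samples(variants, sp$train_ids)
    tr_coh <- subset_samples(cohort, sp$train_ids)
    ho_var <- subset_samples(variants, sp$holdout_ids)
    ho_coh <- subset_samples(cohort, sp$holdout_ids)
    fit <- fit_selector(graph, tr_var, tr_coh, selector = selector, ...)
    if (!length(fit$selected)) {
      warning("permutation ", p, ": no features selected; AUC recorded as 0.5")
      return(data.frame(permutation = p, selector = selector,
                        n_selected = 0L, auc = 0.5))
    }
    Xtr <- feature_matrix(fit, graph, tr_var, tr_coh)
    Xho <- feature_matrix(fit, graph, ho_var, ho_coh)
    auc <- classifier_auc(Xtr, tr_coh$labels, Xho, ho_coh$labels,
                          plan$classifier, seed = plan$seed + p)
    data.frame(permutation = p, selector = selector,
               n_selected = length(fit$selected), auc = auc)
  })
  do.call(rbind, rows)
}

# train one classifier, return holdout AUC (macro one-vs-rest for
# multi-class labels)
classifier_auc <- function(Xtr, ytr, Xho, yho, classifier, seed = 1L) {
  ytr <- factor(ytr); yho <- factor(yho, levels = levels(ytr))
  multi <- nlevels(ytr) > 2L
  dtr <- data.frame(Xtr, check.names = TRUE)
  dho <- data.frame(Xho, check.names = TRUE)
  colnames(dho) <- colnames(dtr)
  prob <- withr::with_seed(seed, switch(classifier,
    logistic_regression = {
      if (multi) {
        fit <- nnet::multinom(y ~ ., data = cbind(dtr, y = ytr),
                              trace = FALSE, maxit = 200)
        p <- stats::predict(fit, dho, type = "probs")
        if (is.null(dim(p))) p <- cbind(1 - p, p,
                                        deparse.level = 0)
        p
      } else {
        fit <- suppressWarnings(
          stats::glm(y ~ ., data = cbind(dtr, y = ytr), family = stats::binomial()))
        p1 <- suppressWarnings(stats::predict(fit, dho, type = "response"))
        cbind(1 - p1, p1)
      }
    },
    random_forest_100 = {
      if (!requireNamespace("randomForest", quietly = TRUE))
        stop("randomForest not installed")
      fit <- randomForest::randomForest(Xtr, ytr, ntree = 100)
      stats::predict(fit, Xho, type = "prob")
    },
    svm_rbf = {
      if (!requireNamespace("e1071", quietly = TRUE))
        stop("e1071 not installed")
      fit <- e1071::svm(Xtr, ytr, kernel = "radial", probability = TRUE)
      attr(stats::predict(fit, Xho, probability = TRUE), "probabilities")[
        , levels(ytr), drop = FALSE]
    },
    stop("unknown classifier: ", classifier)))
  colnames(prob) <- levels(ytr)
  if (!multi) {
    as.numeric(pROC::auc(pROC::roc(
      response = yho, predictor = prob[, 2L],
      levels = levels(ytr), direction = "<", quiet = TRUE)))
  } else {
    aucs <- vapply(levels(ytr), function(cl) {
      resp <- factor(yho == cl, levels = c(FALSE, TRUE))
      if (length(unique(resp)) < 2L) return(NA_real_)
      as.numeric(pROC::auc(pROC::roc(
        response = resp, predictor = prob[, cl],
        levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)))
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }
}
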