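## Two-step random-forest gene-regulatory-network inference.
##
## Step 1 regresses each phenotype-related gene on a candidate regulator
## pool, keeps the top-k predictors per response and retains candidates
## appearing in the top-k of at least `min_overlap` phenotype genes
## ("intermediate regulators"). Step 2 regresses each intermediate on the
## miR-7 target list with the same top-k + overlap rule. Leave-one-sample-out
## cross-validation scores each retained response by RMSE and by the cosine
## similarity of prediction- and truth-differences relative to the
## training-fold mean.

## ranger regression with fixed settings; deterministic under seed.
## mtry follows the classical regression-forest default (p/3), which lets
## trees condition on strong predictors instead of ranking by marginal
## correlation alone. Out-of-bag permutation importance is used for ranking:
## impurity importance carries a sample-variance bias that promotes the same
## spurious features across unrelated responses, which corrupts the top-k
## overlap rule.
.rf_fit <- function(x, y, n_trees, seed, importance = "permutation") {
  ranger::ranger(x = x, y = y, num.trees = n_trees, importance = importance,
                 seed = seed, num.threads = 1,
                 mtry = max(1, floor(ncol(x) / 3)))
}

#' Rank candidate predictors of a response gene by random-forest importance
#'
#' Random-forest regression of the response gene's expression on the
#' candidate genes across samples; impurity importances are returned in
#' decreasing order, ties broken alphabetically.
#'
#' @param expr genes x samples numeric matrix.
#' @param response response gene id (not among candidates).
#' @param candidates non-empty candidate gene ids.
#' @param n_trees trees per forest (default 1000).
#' @param seed integer seed (forest is deterministic given it).
#' @return named numeric vector of importances, decreasing.
#' @export
rank_predictors <- function(expr, response, candidates, n_trees = 1000,
                            seed = 1) {
  .assert(!(response %in% candidates), "response must not be a candidate")
  .assert(length(candidates) >= 1, "candidates must be non-empty")
  .assert(ncol(expr) >= 5, "need >= 5 samples")
  y <- expr[response, ]
  if (sd(y) == 0) stop("constant response: cannot rank predictors")
  x <- as.data.frame(t(expr[candidates, , drop = FALSE]))
  imp <- .rf_fit(x, y, n_trees, seed)$variable.importance
  imp[order(-imp, names(imp))]
}

## shared top-k + overlap machinery for both steps
.overlap_step <- function(expr, responses, candidates_of, top_k, min_overlap,
                          n_trees, seed, step) {
  tops <- vector("list", length(responses))
  names(tops) <- responses
  edges <- vector("list", length(responses))
  for (i in seq_along(responses)) {
    r <- responses[i]
    imp <- rank_predictors(expr, r, candidates_of(r), n_trees,
                           .sub_seed(seed, i + 100 * step))
    top <- head(imp, top_k)
    tops[[i]] <- names(top)
    edges[[i]] <- data.frame(predictor = names(top), response = r,
                             importance = unname(top), step = step)
  }
  tally <- table(unlist(tops))
  kept <- sort(names(tally)[tally >= min_overlap])
  edges <- do.call(rbind, edges)
  edges <- edges[edges$predictor %in% kept, , drop = FALSE]
  rownames(edges) <- NULL
  list(kept = kept, edges = edges)
}

#' Step 1: intermediate regulators of the phenotype-related genes
#'
#' For each phenotype-related gene the top `top_k` predictive genes are
#' taken from the candidate pool; candidates appearing in the top-k lists of
#' at least `min_overlap` phenotype genes are kept as intermediate
#' regulators.
#'
#' @param expr genes x samples matrix.
#' @param phenotype_genes >= 2 response gene ids (the study used 15
#'   synaptic-activity genes).
#' @param candidates candidate regulator pool; defaults to all genes except
#'   the phenotype genes.
#' @param top_k predictors kept per response (default 10).
#' @param min_overlap minimal number of top-k lists a kept candidate must
#'   appear in (default 2).
#' @param n_trees,seed forest settings.
#' @return list with `intermediates` (kept gene ids) and `edges`
#'   (data.frame `predictor`, `response`, `importance`, `step = 1`); empty
#'   result warns rather than errors.
#' @export
step1_regulators <- function(expr, phenotype_genes, candidates = NULL,
                             top_k = 10, min_overlap = 2, n_trees = 1000,
                             seed = 1) {
  .assert(length(phenotype_genes) >= 2, "need >= 2 phenotype genes")
  candidates <- candidates %||% setdiff(rownames(expr), phenotype_genes)
  res <- .overlap_step(expr, phenotype_genes,
                       function(r) setdiff(candidates, r),
                       top_k, min_overlap, n_trees, seed, step = 1L)
  if (!length(res$kept)) warning("no overlapping step-1 regulators")
  list(intermediates = res$kept, edges = res$edges)
}

#' Step 2: connect intermediate regulators to miR-7 targets
#'
#' Each intermediate regulator is regressed on the miR-7 target genes; the
#' top `top_k` targets per intermediate are taken and targets appearing for
#' at least `min_overlap` intermediates are kept. Edges point
#' target -> intermediate by default; `direction` flips the regression.
#'
#' @param expr genes x samples matrix.
#' @param intermediates non-empty gene ids from [step1_regulators()].
#' @param mir7_targets a `target_set` or character vector; targets also
#'   listed as intermediates are dropped before the regression.
#' @param top_k,min_overlap,n_trees,seed as in [step1_regulators()].
#' @param direction `"targets_predict_intermediates"` (default) or
#'   `"intermediates_predict_targets"`.
#' @return list with `targets_kept` and `edges` (`step = 2`).
#' @export
step2_connect <- function(expr, intermediates, mir7_targets, top_k = 10,
                          min_overlap = 2, n_trees = 1000, seed = 1,
                          direction = c("targets_predict_intermediates",
                                        "intermediates_predict_targets")) {
  direction <- match.arg(direction)
  .assert(length(intermediates) >= 1, "intermediates must be non-empty")
  tg <- if (is.list(mir7_targets)) mir7_targets$genes else mir7_targets
  tg <- setdiff(tg, intermediates)
  tg <- intersect(tg, rownames(expr))
  if (!length(tg)) stop("no miR-7 targets present in the expression matrix")
  if (direction == "targets_predict_intermediates") {
    res <- .overlap_step(expr, intermediates, function(r) tg,
                         top_k, min_overlap, n_trees, seed, step = 2L)
  } else {
    res <- .overlap_step(expr, tg, function(r) intermediates,
                         top_k, min_overlap, n_trees, seed, step = 2L)
  }
  list(targets_kept = res$kept, edges = res$edges)
}

#' Cross-validation scores from per-fold predictions
#'
#' RMSE over folds, plus the cosine similarity of the prediction-difference
#' and truth-difference vectors, where each fold's difference is taken
#' relative to the mean of that fold's training responses. Cosine is 1 for
#' consistent patterns, -1 for opposite patterns, and `NA` when either
#' difference vector is identically zero.
#'
#' @param predictions,truth per-fold predicted and observed response values.
#' @param train_means per-fold means of the training-fold response values.
#' @return list with `rmse` and `cosine`.
#' @export
cv_scores <- function(predictions, truth, train_means) {
  .assert(length(predictions) == length(truth) &&
            length(truth) == length(train_means), "length mismatch")
  list(rmse = sqrt(mean((predictions - truth)^2)),
       cosine = .cosine(predictions - train_means, truth - train_means))
}

#' Leave-one-sample-out cross-validation of a random-forest model
#'
#' For each sample, a forest is trained on the remaining samples and
#' predicts the held-out one; scoring via [cv_scores()].
#'
#' @param expr genes x samples matrix (>= 3 samples).
#' @param response response gene id.
#' @param predictors predictor gene ids.
#' @param n_trees,seed forest settings.
#' @return list of class `cv_report_entry`: `response`, `rmse`, `cosine`,
#'   `folds` (data.frame `sample`, `prediction`, `truth`, `train_mean`).
#' @export
loso_cv <- function(expr, response, predictors, n_trees = 1000, seed = 1) {
  n <- ncol(expr)
  .assert(n >= 3, "need >= 3 samples")
  y <- expr[response, ]
  x <- as.data.frame(t(expr[predictors, , drop = FALSE]))
  pred <- tm <- numeric(n)
  for (s in seq_len(n)) {
    fit <- .rf_fit(x[-s, , drop = FALSE], y[-s], n_trees, .sub_seed(seed, s))
    pred[s] <- predict(fit, x[s, , drop = FALSE])$predictions
    tm[s] <- mean(y[-s])
  }
  sc <- cv_scores(pred, y, tm)
  structure(list(response = response, rmse = sc$rmse, cosine = sc$cosine,
                 folds = data.frame(sample = colnames(expr) %||% seq_len(n),
                                    prediction = pred, truth = y,
                                    train_mean = tm)),
            class = "cv_report_entry")
}

#' Build the full two-step regulatory network with cross-validation
#'
#' Runs [step1_regulators()], [step2_connect()] and [loso_cv()] for every
#' retained response (phenotype genes with kept step-1 predictors;
#' intermediates with kept step-2 predictors).
#'
#' @param expr genes x samples matrix.
#' @param phenotype_genes non-empty phenotype-related gene ids.
#' @param mir7_targets miR-7 target ids (`target_set` or character).
#' @param step1_candidates optional explicit step-1 candidate pool.
#' @param top_k,min_overlap,n_trees,seed forwarded to both steps.
#' @return list of class `grn_fit` with `network` (a [gene_network()]-style
#'   list of `nodes` and `edges`), `cv` (data.frame `response`, `rmse`,
#'   `cosine`), `intermediates`, `targets_kept`.
#' @export
build_network <- function(expr, phenotype_genes, mir7_targets,
                          step1_candidates = NULL, top_k = 10,
                          min_overlap = 2, n_trees = 1000, seed = 1) {
  .assert(length(phenotype_genes) >= 1, "empty phenotype gene list")
  s1 <- step1_regulators(expr, phenotype_genes, step1_candidates, top_k,
                         min_overlap, n_trees, seed)
  if (length(s1$intermediates)) {
    s2 <- step2_connect(expr, s1$intermediates, mir7_targets, top_k,
                        min_overlap, n_trees, seed)
  } else {
    s2 <- list(targets_kept = character(0),
               edges = data.frame(predictor = character(0),
                                  response = character(0),
                                  importance = numeric(0), step = integer(0)))
  }
  edges <- rbind(s1$edges, s2$edges)
  tgv <- if (is.list(mir7_targets)) mir7_targets$genes else mir7_targets
  nodes <- data.frame(
    gene = c(phenotype_genes, s1$intermediates, s2$targets_kept),
    role = rep(c("phenotype", "intermediate", "mir7_target"),
               c(length(phenotype_genes), length(s1$intermediates),
                 length(s2$targets_kept))))
  # validated responses: those with at least one retained predictor
  cv_resp <- unique(edges$response)
  cv <- lapply(seq_along(cv_resp), function(i) {
    r <- cv_resp[i]
    preds <- edges$predictor[edges$response == r]
    e <- loso_cv(expr, r, preds, n_trees, .sub_seed(seed, 500 + i))
    data.frame(response = r, rmse = e$rmse, cosine = e$cosine)
  })
  cv <- if (length(cv)) do.call(rbind, cv)
        else data.frame(response = character(0), rmse = numeric(0),
                        cosine = numeric(0))
  structure(list(network = list(nodes = nodes, edges = edges), cv = cv,
                 intermediates = s1$intermediates,
                 targets_kept = s2$targets_kept,
                 mir7_targets = tgv),
            class = "grn_fit")
}

#' Edge precision and recall against a reference network
#'
#' Compares inferred directed edges (predictor regulating response; i.e.
#' `predictor -> response`) with a reference edge list such as the planted
#' network of [gen_regulatory_expression()] (`from -> to`).
#'
#' @param edges data.frame with `predictor` and `response` columns.
#' @param true_edges data.frame with `from` and `to` columns.
#' @return list with `precision`, `recall`, `n_inferred`, `n_true`.
#' @export
edge_recovery <- function(edges, true_edges) {
  inf <- unique(paste(edges$predictor, edges$response, sep = "->"))
  tru <- unique(paste(true_edges$from, true_edges$to, sep = "->"))
  tp <- length(intersect(inf, tru))
  list(precision = if (length(inf)) tp / length(inf) else NA_real_,
       recall = if (length(tru)) tp / length(tru) else NA_real_,
       n_inferred = length(inf), n_true = length(tru))
}
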