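## Kernel registry ------------------------------------------------------

.kernel_registry <- new.env(parent = emptyenv())

#' Register a kernel by name
#'
#' A kernel is registered as an explicit feature-map function
#' `function(instance, config) -> named numeric vector`; kernel values are
#' dot products of these vectors, which keeps every Gram matrix positive
#' semi-definite by construction.
#'
#' @param name kernel name (e.g. `"asm"`, `"apg"`).
#' @param features the feature-map function.
#' @export
register_kernel <- function(name, features) {
  assign(name, features, envir = .kernel_registry)
  invisible(name)
}

get_kernel <- function(name) {
  if (!exists(name, envir = .kernel_registry))
    stop("unknown kernel: ", name, " (registered: ",
         paste(ls(.kernel_registry), collapse = ", "), ")")
  get(name, envir = .kernel_registry)
}

register_builtin_kernels <- function() {
  register_kernel("asm", function(inst, config = list())
    asm_feature_vector(inst$graph,
                       include_diagonal = isTRUE(config$include_diagonal)))
  register_kernel("apg", function(inst, config = list())
    apg_instance_features(inst,
                          w_linear = config$w_linear %||% 0.3,
                          position_tags = config$position_tags %||% TRUE,
                          convergence = config$convergence %||% "rescale"))
}

# Sparse feature matrix (features x instances) from a list of named vectors.
feature_matrix <- function(vecs) {
  all_names <- unique(unlist(lapply(vecs, names)))
  i <- unlist(lapply(vecs, function(v) match(names(v), all_names)))
  j <- rep(seq_along(vecs), vapply(vecs, length, integer(1)))
  x <- unlist(vecs, use.names = FALSE)
  Matrix::sparseMatrix(i = i, j = j, x = x,
                       dims = c(length(all_names), length(vecs)))
}

instance_features <- function(instances, kernel, config = list()) {
  fn <- get_kernel(kernel)
  lapply(instances, fn, config = config)
}

#' Gram matrix over a set of relation instances
#'
#' Computes the pairwise kernel matrix for a registered kernel. With
#' `normalized = TRUE` (the default) cosine normalization is applied, so the
#' diagonal is 1; instances whose self-kernel is 0 get zero rows/columns.
#'
#' @param instances list of `relation_instance`s.
#' @param kernel registered kernel name (`"asm"` or `"apg"`).
#' @param normalized apply cosine normalization.
#' @param config kernel configuration list (e.g. `include_diagonal`,
#'   `w_linear`, `position_tags`, `convergence`).
#' @return A `gram_matrix`: list with `values` (symmetric matrix), `kernel`,
#'   `normalized` and the feature vectors (reused by [cross_gram()]).
#' @export
gram <- function(instances, kernel = c("asm", "apg"), normalized = TRUE,
                 config = list()) {
  kernel <- match.arg(kernel)
  vecs <- instance_features(instances, kernel, config)
  X <- feature_matrix(vecs)
  K <- as.matrix(Matrix::crossprod(X))
  if (normalized) K <- cosine_normalize(K)
  K <- (K + t(K)) / 2   # remove floating-point asymmetry
  structure(list(values = K, kernel = kernel, normalized = normalized,
                 config = config, features = vecs),
            class = "gram_matrix")
}

cosine_normalize <- function(K) {
  s <- sqrt(pmax(diag(K), 0))
  s[s == 0] <- Inf
  K / outer(s, s)
}

#' Cross-kernel matrix between test and training instances
#'
#' @param test_instances,train_gram test instances and the training
#'   [gram()] object (its kernel, config and normalization are reused).
#' @return A `length(test) x length(train)` matrix.
#' @export
cross_gram <- function(test_instances, train_gram) {
  vecs_te <- instance_features(test_instances, train_gram$kernel,
                               train_gram$config)
  all_vecs <- c(vecs_te, train_gram$features)
  X <- feature_matrix(all_vecs)
  nte <- length(vecs_te)
  Xte <- X[, seq_len(nte), drop = FALSE]
  Xtr <- X[, nte + seq_along(train_gram$features), drop = FALSE]
  K <- as.matrix(Matrix::crossprod(Xte, Xtr))
  if (train_gram$normalized) {
    ste <- sqrt(Matrix::colSums(Xte^2)); ste[ste == 0] <- Inf
    str <- sqrt(Matrix::colSums(Xtr^2)); str[str == 0] <- Inf
    K <- K / outer(ste, str)
  }
  K
}

#' @export
print.gram_matrix <- function(x, ...) {
  cat(sprintf("<gram_matrix %s: %d x %d%s>\n", x$kernel, nrow(x$values),
              ncol(x$values), if (x$normalized) ", normalized" else ""))
  invisible(x)
}

## SVM ------------------------------------------------------------------

#' Train a kernel SVM on a precomputed Gram matrix
#'
#' Soft-margin C-SVM over the precomputed kernel, untuned regularization
#' `C = 1` by default.
#'
#' @param train_gram a [gram()] object.
#' @param labels character or factor labels (`"positive"`/`"negative"`), one
#'   per training instance.
#' @param C regularization parameter.
#' @return A `relkern_model`.
#' @export
train_svm <- function(train_gram, labels, C = 1) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L)
    stop("training labels contain a single class")
  y <- factor(labels, levels = c("negative", "positive"))
  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(train_gram$values), y,
                       type = "C-svc", C = C)
  # orient the decision function so that positives score high
  dec_tr <- kernlab::predict(
    fit, kernlab::as.kernelMatrix(
      train_gram$values[, kernlab::SVindex(fit), drop = FALSE]),
    type = "decision")[, 1]
  resp_tr <- kernlab::predict(
    fit, kernlab::as.kernelMatrix(
      train_gram$values[, kernlab::SVindex(fit), drop = FALSE]))
  flip <- mean(dec_tr[resp_tr == "positive"]) <
    mean(dec_tr[resp_tr == "negative"])
  if (is.na(flip)) flip <- FALSE
  structure(list(fit = fit, gram = train_gram, flip = flip),
            class = "relkern_model")
}

#' Predict with a trained kernel SVM
#'
#' @param model a [train_svm()] model.
#' @param cross test-by-train kernel matrix from [cross_gram()] (columns in
#'   training order).
#' @return A list with `labels` (character) and `scores` (real decision
#'   values, higher = more positive).
#' @export
predict_svm <- function(model, cross) {
  sv <- kernlab::SVindex(model$fit)
  Ksv <- kernlab::as.kernelMatrix(cross[, sv, drop = FALSE])
  labels <- as.character(kernlab::predict(model$fit, Ksv))
  scores <- kernlab::predict(model$fit, Ksv, type = "decision")[, 1]
  if (model$flip) scores <- -scores
  list(labels = labels, scores = scores)
}

## Aggregation and metrics ---------------------------------------------

#' Aggregate instance predictions to document-level concept pairs
#'
#' A concept pair is predicted positive iff any of its instances (from
#' either the sentence-level or the cross-sentence subsystem) is predicted
#' positive; the final document-level relation set is the union over both
#' subsystems. The pair's score is the maximum instance score.
#'
#' @param instances the list of `relation_instance`s.
#' @param labels predicted instance labels (`"positive"`/`"negative"`).
#' @param scores optional decision scores.
#' @return data.frame `doc_id`, `c1`, `c2`, `level`, `positive`, `score`,
#'   one row per (document, concept pair).
#' @export
aggregate_document <- function(instances, labels, scores = NULL) {
  if (is.null(scores)) scores <- rep(NA_real_, length(instances))
  df <- data.frame(
    doc_id = vapply(instances, `[[`, "", "doc_id"),
    c1 = vapply(instances, function(i) i$concepts[1], ""),
    c2 = vapply(instances, function(i) i$concepts[2], ""),
    level = vapply(instances, `[[`, "", "level"),
    positive = labels == "positive",
    score = scores, stringsAsFactors = FALSE)
  agg <- do.call(rbind, lapply(
    split(df, paste(df$doc_id, df$c1, df$c2, sep = "\x1f")),
    function(d) data.frame(doc_id = d$doc_id[1], c1 = d$c1[1], c2 = d$c2[1],
                           level = d$level[1], positive = any(d$positive),
                           score = suppressWarnings(max(d$score)),
                           stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  agg[order(agg$doc_id, agg$c1, agg$c2), ]
}

#' Precision/recall/F1 over predicted vs gold pair sets
#'
#' @param gold,predicted character vectors of pair keys (any unique encoding
#'   of (document, concept pair)).
#' @param universe optional full candidate universe, enabling `tn`.
#' @return An `eval_result`: counts `tp`, `fp`, `fn` (`tn` when `universe`
#'   given) and `precision`, `recall`, `f1` (0, flagged `undefined`, when a
#'   denominator is empty).
#' @export
evaluate_pairs <- function(gold, predicted, universe = NULL) {
  gold <- unique(gold); predicted <- unique(predicted)
  tp <- length(intersect(gold, predicted))
  fp <- length(setdiff(predicted, gold))
  fn <- length(setdiff(gold, predicted))
  tn <- if (is.null(universe)) NA_integer_
        else length(setdiff(setdiff(universe, gold), predicted))
  eval_result(tp, fp, fn, tn)
}

#' Precision/recall/F1 over aligned binary label vectors
#'
#' @param truth,predicted aligned vectors; `"positive"` (or `TRUE`) is the
#'   positive class.
#' @return An `eval_result`.
#' @export
evaluate_labels <- function(truth, predicted) {
  t <- truth == "positive" | truth == TRUE
  p <- predicted == "positive" | predicted == TRUE
  eval_result(sum(t & p), sum(!t & p), sum(t & !p), sum(!t & !p))
}

eval_result <- function(tp, fp, fn, tn = NA_integer_) {
  undefined <- (tp + fp) == 0L || (tp + fn) == 0L
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, precision = precision,
                 recall = recall, f1 = f1, undefined = undefined),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("P=%.3f R=%.3f F1=%.3f (tp=%d fp=%d fn=%d)\n",
              x$precision, x$recall, x$f1, x$tp, x$fp, x$fn))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC of decision scores against binary labels:
#' the probability that a random positive outscores a random negative, ties
#' counted one half. Invariant under strictly monotone score transforms.
#'
#' @param scores numeric decision scores.
#' @param labels `"positive"`/`"negative"` (or logical) labels.
#' @return AUC in `[0, 1]`; 0.5 when all scores tie.
#' @export
auc_score <- function(scores, labels) {
  pos <- labels == "positive" | labels == TRUE
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("auc_score needs both classes")
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' McNemar's paired significance test
#'
#' Tests the null hypothesis that two classifiers are equally accurate from
#' their discordant prediction counts `b` (A right, B wrong) and `c`
#' (A wrong, B right). For `b + c < 25` the exact two-sided binomial
#' p-value is used; otherwise the chi-square approximation with continuity
#' correction, statistic `(|b - c| - 1)^2 / (b + c)`.
#'
#' @param correct_a,correct_b aligned logical vectors of per-example
#'   correctness for the two classifiers.
#' @return A `mcnemar_result`: `b`, `c`, `statistic` (NA for the exact
#'   branch), `p_value`, `method`.
#' @export
mcnemar_test <- function(correct_a, correct_b) {
  stopifnot(length(correct_a) == length(correct_b))
  b <- sum(correct_a & !correct_b)
  c_ <- sum(!correct_a & correct_b)
  n <- b + c_
  if (n == 0L) {
    res <- list(b = b, c = c_, statistic = NA_real_, p_value = 1,
                method = "degenerate")
  } else if (n < 25L) {
    p <- stats::binom.test(b, n, p = 0.5)$p.value
    res <- list(b = b, c = c_, statistic = NA_real_, p_value = p,
                method = "exact binomial")
  } else {
    stat <- (abs(b - c_) - 1)^2 / n
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    res <- list(b = b, c = c_, statistic = stat, p_value = p,
                method = "chi-square with continuity correction")
  }
  structure(res, class = "mcnemar_result")
}

#' @export
print.mcnemar_result <- function(x, ...) {
  cat(sprintf("McNemar (%s): b=%d c=%d p=%.4g\n", x$method, x$b, x$c,
              x$p_value))
  invisible(x)
}
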