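#' Per-sample subnetwork activity
#'
#' Summarizes each subnetwork's member-gene expression into one activity
#' value per sample. Member genes are z-scored across all samples first (so
#' high-magnitude genes do not dominate), then aggregated by the sample-wise
#' mean, median, or the first principal component of the member-gene
#' profiles. PCA rows are sign-anchored to correlate non-negatively with the
#' same subnetwork's mean-activity row (principal components are otherwise
#' sign-ambiguous).
#'
#' @param subnetworks A `dc_subnetwork_set`, or a named list of gene-id
#'   vectors.
#' @param ds An [expr_dataset()] containing the member genes.
#' @param method `"mean"`, `"median"` or `"pca"`.
#' @return An object of class `activity_matrix`: subnetworks x samples
#'   numeric matrix plus `method`; `tidy()` gives the long view.
#' @export
activity_matrix <- function(subnetworks, ds, method = c("mean", "median", "pca")) {
  method <- match.arg(method)
  stopifnot(inherits(ds, "expr_dataset"))
  sets <- if (inherits(subnetworks, "dc_subnetwork_set")) {
    purrr::map(unclass(subnetworks), "nodes")
  } else if (inherits(subnetworks, "dc_subnetwork")) {
    setNames(list(subnetworks$nodes), subnetworks$seed)
  } else {
    subnetworks
  }
  if (is.null(names(sets))) names(sets) <- paste0("S", seq_along(sets))
  z <- t(scale(t(ds$exprs)))
  constant <- apply(ds$exprs, 1L, sd) == 0
  z[constant, ] <- 0

  rows <- purrr::imap(sets, function(genes, id) {
    present <- intersect(genes, rownames(z))
    if (length(present) == 0L) {
      abort(sprintf("Subnetwork '%s' has no genes in the dataset.", id))
    }
    sub <- z[present, , drop = FALSE]
    if (method == "mean") return(colMeans(sub))
    if (method == "median") return(apply(sub, 2L, median))
    if (nrow(sub) == 1L) return(sub[1L, ])
    pc <- prcomp(t(sub), center = FALSE, scale. = FALSE)
    act <- pc$x[, 1L]
    ref <- colMeans(sub)
    if (sum(act * ref) < 0) act <- -act
    act
  })
  values <- do.call(rbind, rows)
  rownames(values) <- names(sets)
  colnames(values) <- colnames(ds$exprs)
  structure(
    list(values = values, method = method, samples = ds$samples),
    class = "activity_matrix"
  )
}

#' @export
print.activity_matrix <- function(x, ...) {
  cat(sprintf(
    "<activity_matrix: %s> %d subnetworks x %d samples\n",
    x$method, nrow(x$values), ncol(x$values)
  ))
  invisible(x)
}

#' @export
tidy.activity_matrix <- function(x, ...) {
  as_tibble(x$values, rownames = "subnetwork") %>%
    tidyr::pivot_longer(-"subnetwork", names_to = "sample_id",
                        values_to = "activity") %>%
    left_join(x$samples, by = "sample_id")
}

#' Cluster samples on subnetwork activity
#'
#' Complete-linkage agglomerative clustering with 1 - Pearson correlation
#' between sample activity vectors as the distance.
#'
#' @param activity An [activity_matrix()].
#' @param k Number of clusters for the cut.
#' @return A list: `labels` tibble (`sample_id`, `cluster`, with condition
#'   and pair columns joined in), and the `hclust` merge `tree`.
#' @export
hierarchical_cluster <- function(activity, k = 2L) {
  stopifnot(inherits(activity, "activity_matrix"))
  n <- ncol(activity$values)
  if (k > n) abort("`k` cannot exceed the number of samples.")
  d <- as.dist(1 - cor(activity$values))
  tree <- hclust(d, method = "complete")
  cl <- cutree(tree, k = k)
  labels <- tibble(sample_id = colnames(activity$values),
                   cluster = unname(cl)) %>%
    left_join(activity$samples, by = "sample_id")
  list(labels = labels, tree = tree)
}

#' Select marker subnetworks by lasso-logistic classification
#'
#' Fits an L1-penalized logistic regression of the condition label on the
#' training activity matrix (penalty chosen by internal cross-validation),
#' reports the subnetworks with nonzero coefficients as markers, and
#' evaluates AUC on the training and test sets.
#'
#' @param activity_train,activity_test [activity_matrix()] objects over the
#'   same subnetworks.
#' @param labels_train,labels_test Condition labels (`"normal"`/`"tumour"`,
#'   or any 2-level factor; the second level is the positive class). Taken
#'   from the activity objects' sample metadata when `NULL`.
#' @param seed RNG seed for the cross-validation folds.
#' @return A list: `selected` (marker subnetwork ids), `coefficients`
#'   tibble, `auc_train`, `auc_test`, and the fitted `cv.glmnet` model.
#' @export
classify_subnetworks <- function(activity_train, activity_test,
                                 labels_train = NULL, labels_test = NULL,
                                 seed = 1L) {
  stopifnot(inherits(activity_train, "activity_matrix"),
            inherits(activity_test, "activity_matrix"))
  labels_train <- labels_train %||% activity_train$samples$condition
  labels_test <- labels_test %||% activity_test$samples$condition
  y_tr <- factor(labels_train)
  y_te <- factor(labels_test, levels = levels(y_tr))
  if (nlevels(y_tr) != 2L) abort("Labels must have exactly two classes.")
  x_tr <- t(activity_train$values)
  x_te <- t(activity_test$values)
  set.seed(seed)
  fit <- glmnet::cv.glmnet(x_tr, y_tr, family = "binomial", alpha = 1,
                           nfolds = 5L)
  beta <- coef(fit, s = "lambda.min")
  nz <- rownames(beta)[as.numeric(beta) != 0]
  selected <- setdiff(nz, "(Intercept)")
  score_tr <- as.numeric(predict(fit, x_tr, s = "lambda.min", type = "response"))
  score_te <- as.numeric(predict(fit, x_te, s = "lambda.min", type = "response"))
  list(
    selected = selected,
    coefficients = tibble(
      subnetwork = setdiff(rownames(beta), "(Intercept)"),
      coefficient = as.numeric(beta)[-1L]
    ),
    auc_train = rank_auc(score_tr, y_tr == levels(y_tr)[2L]),
    auc_test = rank_auc(score_te, y_te == levels(y_tr)[2L]),
    model = fit
  )
}
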