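# Grade-predictive-vector machinery: assemble the per-lesion PET + MRI
# feature table, fit an L1-penalised (LASSO) logistic classifier with
# cross-validated penalty selection, score new lesions with the stored
# standardisation, and evaluate by ROC/AUC.

# Column inventories per vector variant. The static vector combines static
# PET with MRI parameters only; the dynamic vector adds the tracer-kinetic
# PET constants.
gpv_static_columns <- c("SUVmax", "SUVmean", "TBRmax", "TBRmean",
                        "Ktrans", "Kep", "Ve", "Vp", "Taui",
                        "CBF", "CBV", "CBVlc", "MTT", "TTP",
                        "ASL_CBF", "ADC")
gpv_dynamic_columns <- c(gpv_static_columns,
                         c("Ki_std", "Ki_mod", "K1", "k2", "k3", "vb"))

#' Column set for a grade-predictive-vector variant
#' @param variant "GpVs" (static PET + MRI), "GpVd" (adds dynamic PET), or
#'   "custom".
#' @export
gpv_columns <- function(variant = c("GpVs", "GpVd")) {
  switch(match.arg(variant), GpVs = gpv_static_columns,
         GpVd = gpv_dynamic_columns)
}

#' Assemble and standardise a per-lesion feature table
#'
#' Selects the variant's column set, refuses missing values (optional
#' median imputation, flagged in the result), and standardises each column
#' to mean 0 / SD 1, storing the transform so new lesions can be projected
#' onto the same scale.
#'
#' @param df data.frame of per-lesion quantification outputs.
#' @param variant "GpVs", "GpVd", or "custom" with \code{columns} given.
#' @param columns explicit column names when \code{variant = "custom"}.
#' @param impute "refuse" (default) or "median".
#' @return a \code{gpv_feature_table}: standardised data.frame plus the
#'   per-column center/scale record.
#' @export
assemble_features <- function(df, variant = c("GpVs", "GpVd", "custom"),
                              columns = NULL,
                              impute = c("refuse", "median")) {
  variant <- match.arg(variant)
  impute <- match.arg(impute)
  cols <- if (variant == "custom") {
    if (is.null(columns)) stop("custom variant requires explicit columns")
    columns
  } else gpv_columns(variant)
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  x <- df[, cols, drop = FALSE]
  imputed <- FALSE
  if (anyNA(x)) {
    if (impute == "refuse")
      stop("feature table contains missing values (set impute = 'median')")
    for (j in seq_along(x))
      x[[j]][is.na(x[[j]])] <- median(x[[j]], na.rm = TRUE)
    imputed <- TRUE
  }
  center <- vapply(x, mean, numeric(1L))
  scale_ <- vapply(x, sd, numeric(1L))
  scale_[scale_ == 0] <- 1
  xs <- as.data.frame(Map(function(v, m, s) (v - m) / s, x, center, scale_))
  names(xs) <- cols
  structure(list(features = xs, center = center, scale = scale_,
                 variant = variant, imputed = imputed),
            class = "gpv_feature_table")
}

#' Project a new lesion table onto a stored standardisation
#' @param table a \code{gpv_feature_table} (supplies center/scale).
#' @param df new per-lesion data with the same columns.
#' @export
project_features <- function(table, df) {
  stopifnot(inherits(table, "gpv_feature_table"))
  cols <- names(table$center)
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  as.data.frame(Map(function(cn) (df[[cn]] - table$center[[cn]]) /
                      table$scale[[cn]], setNames(cols, cols)))
}

#' Invert a stored standardisation (round-trip check helper)
#' @param table a \code{gpv_feature_table}.
#' @export
unstandardise_features <- function(table) {
  as.data.frame(Map(function(cn) table$features[[cn]] * table$scale[[cn]] +
                      table$center[[cn]],
                    setNames(names(table$center), names(table$center))))
}

#' Fit an L1-penalised logistic classifier with cross-validated penalty
#'
#' LASSO logistic regression over a log-spaced penalty grid (100 values
#' spanning four decades below the smallest all-zero penalty), with
#' seeded k-fold cross-validation; the penalty minimising CV deviance is
#' selected by default ("1se" selectable). The full coefficient path and
#' CV record are retained.
#'
#' @param x feature matrix/data.frame (already standardised) or a
#'   \code{gpv_feature_table}.
#' @param labels binary 0/1 vector.
#' @param n_folds CV folds (default 10); seed fixes fold assignment.
#' @param rule "min" or "1se".
#' @param variant stored on the model for provenance.
#' @param seed integer seed for the fold assignment.
#' @return a \code{gpv_model}: selected features, weights (standardised
#'   scale), intercept, lambda, cv record, path sparsity, standardisation.
#' @export
fit_lasso_classifier <- function(x, labels, n_folds = 10,
                                 rule = c("min", "1se"), variant = "custom",
                                 seed = 1) {
  rule <- match.arg(rule)
  std <- NULL
  if (inherits(x, "gpv_feature_table")) {
    std <- list(center = x$center, scale = x$scale)
    variant <- x$variant
    x <- x$features
  }
  xm <- as.matrix(x)
  if (length(unique(labels)) < 2L)
    stop("labels contain a single class")
  # class-stratified fold assignment keeps both classes in every training
  # split, which matters for the small cohorts this is applied to
  foldid <- integer(nrow(xm))
  foldid <- with_seed(seed, {
    for (cl in unique(labels)) {
      ix <- which(labels == cl)
      foldid[ix] <- sample(rep_len(seq_len(n_folds), length(ix)))
    }
    foldid
  })
  cv <- glmnet::cv.glmnet(xm, labels, family = "binomial", alpha = 1,
                          nlambda = 100, lambda.min.ratio = 1e-4,
                          foldid = foldid, standardize = FALSE)
  lam <- if (rule == "min") cv$lambda.min else cv$lambda.1se
  cf <- as.numeric(coef(cv$glmnet.fit, s = lam))
  names(cf) <- c("(Intercept)", colnames(xm))
  w <- cf[-1L]
  nz <- colSums(as.matrix(cv$glmnet.fit$beta) != 0)
  structure(list(selected_features = names(w)[w != 0],
                 weights = w[w != 0], intercept = unname(cf[1L]),
                 lambda = lam, rule = rule, variant = variant,
                 cv_record = data.frame(lambda = cv$lambda,
                                        deviance = cv$cvm, se = cv$cvsd),
                 path_nonzero = data.frame(lambda = cv$glmnet.fit$lambda,
                                           nonzero = unname(nz)),
                 standardisation = std, seed = seed, n_folds = n_folds),
            class = "gpv_model")
}

#' @export
print.gpv_model <- function(x, ...) {
  cat(sprintf("<gpv_model> %s: %d features at lambda = %.4g (%s rule)\n",
              x$variant, length(x$selected_features), x$lambda, x$rule))
  if (length(x$weights)) {
    w <- sort(x$weights, decreasing = TRUE)
    for (nm in names(w)) cat(sprintf("  %-10s %+.4f\n", nm, w[[nm]]))
  }
  cat(sprintf("  intercept %+.4f\n", x$intercept))
  invisible(x)
}

#' @export
coef.gpv_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$weights)
}

#' Score lesions with a fitted grade-predictive vector
#'
#' Linear predictor \eqn{score = intercept + \sum w_j z_j} on the model's
#' standardised scale. Raw (unstandardised) tables are projected through
#' the model's stored standardisation, so a vector trained on one cohort
#' can be applied unmodified to unseen lesions.
#'
#' @param df lesion table: standardised if \code{standardised = TRUE},
#'   else raw columns projected via the model's stored transform.
#' @param model a \code{gpv_model}.
#' @param standardised is \code{df} already on the model's z-scale?
#' @return numeric score per lesion.
#' @export
compute_gpv <- function(df, model, standardised = TRUE) {
  stopifnot(inherits(model, "gpv_model"))
  if (inherits(df, "gpv_feature_table")) df <- df$features
  if (!standardised) {
    if (is.null(model$standardisation))
      stop("model carries no standardisation record")
    cn <- names(model$standardisation$center)
    missing_cols <- setdiff(cn, names(df))
    if (length(missing_cols))
      stop("missing required columns: ",
           paste(missing_cols, collapse = ", "))
    df <- as.data.frame(Map(function(nm)
      (df[[nm]] - model$standardisation$center[[nm]]) /
        model$standardisation$scale[[nm]], setNames(cn, cn)))
  }
  missing_cols <- setdiff(model$selected_features, names(df))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  s <- rep(model$intercept, nrow(df))
  for (nm in model$selected_features)
    s <- s + model$weights[[nm]] * df[[nm]]
  s
}

#' Serialise / load a grade-predictive vector as JSON
#'
#' Stores features, weights, intercept, penalty and the standardisation so
#' a published vector can be loaded verbatim and applied to new data.
#'
#' @param model a \code{gpv_model}; path JSON file.
#' @param path JSON file path.
#' @export
write_gpv_json <- function(model, path) {
  stopifnot(inherits(model, "gpv_model"))
  jsonlite::write_json(
    list(variant = model$variant, selected_features = model$selected_features,
         weights = as.list(model$weights), intercept = model$intercept,
         lambda = model$lambda, rule = model$rule, seed = model$seed,
         standardisation = if (!is.null(model$standardisation))
           list(center = as.list(model$standardisation$center),
                scale = as.list(model$standardisation$scale)) else NULL),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gpv_json
#' @export
read_gpv_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  std <- if (!is.null(j$standardisation))
    list(center = unlist(j$standardisation$center),
         scale = unlist(j$standardisation$scale)) else NULL
  structure(list(selected_features = j$selected_features,
                 weights = unlist(j$weights), intercept = j$intercept,
                 lambda = j$lambda, rule = j$rule, variant = j$variant,
                 cv_record = NULL, path_nonzero = NULL,
                 standardisation = std, seed = j$seed),
            class = "gpv_model")
}

#' ROC curve, AUC and threshold metrics for a binary score
#'
#' Empirical ROC over all score thresholds; AUC by the trapezoid rule
#' (equal to the Mann-Whitney concordance probability); accuracy, TPR and
#' FPR reported at the Youden-optimal threshold by default or at a supplied
#' one.
#'
#' @param scores numeric; higher = more likely class 1.
#' @param labels 0/1 vector with both classes present.
#' @param threshold optional fixed threshold (score >= threshold predicts 1).
#' @return a \code{classifier_eval}: roc (data.frame fpr/tpr/threshold),
#'   auc, threshold, accuracy, tpr, fpr.
#' @export
evaluate_classifier <- function(scores, labels, threshold = NULL) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("labels must contain both classes")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pos <- sum(labels == 1L); neg <- sum(labels == 0L)
  tpr <- vapply(thr, function(th) sum(scores >= th & labels == 1L) / pos,
                numeric(1L))
  fpr <- vapply(thr, function(th) sum(scores >= th & labels == 0L) / neg,
                numeric(1L))
  auc <- trapz_int(fpr, tpr)
  if (is.null(threshold)) threshold <- thr[which.max(tpr - fpr)]
  pred <- as.integer(scores >= threshold)
  structure(list(roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
                 auc = auc, threshold = threshold,
                 accuracy = mean(pred == labels),
                 tpr = sum(pred == 1L & labels == 1L) / pos,
                 fpr = sum(pred == 1L & labels == 0L) / neg),
            class = "classifier_eval")
}

#' @export
print.classifier_eval <- function(x, ...) {
  cat(sprintf("<classifier_eval> AUC = %.4f; at threshold %.4g: accuracy %.3f, TPR %.3f, FPR %.3f\n",
              x$auc, x$threshold, x$accuracy, x$tpr, x$fpr))
  invisible(x)
}
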