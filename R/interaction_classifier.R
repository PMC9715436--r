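# SVM classification of miRNA-mRNA candidate pairs: RBF-kernel SVM on the
# (ES, PS) features, sigmoid probability calibration on a held-out fold, a
# strict 60% probability cutoff, and the cross-species consistency
# intersection.

#' Train the interaction classifier
#'
#' Fits an RBF-kernel support vector machine on labeled feature vectors with
#' fixed hyperparameters (cost 1, kernel width 1/n_features) and inverse-
#' frequency class weights, then calibrates decision values to probabilities
#' with a Platt sigmoid fitted on a held-out calibration fold. Features are
#' standardized with statistics from the training fold only. The whole
#' procedure is deterministic given (data, kernel, seed).
#'
#' @param data data.frame of labeled interactions: the feature columns plus a
#'   `label` column with values `"positive"`/`"negative"` (factor or
#'   character)
#' @param feature_cols feature column names (default `c("ES", "PS")`)
#' @param kernel SVM kernel (default `"radial"`)
#' @param seed integer seed pinning the calibration-fold split
#' @param cost SVM cost parameter
#' @param calibration_fraction fraction of examples (per class) held out for
#'   the sigmoid fit
#' @return object of class `interaction_model`
#' @export
train_classifier <- function(data, feature_cols = c("ES", "PS"),
                             kernel = "radial", seed = 42L, cost = 1,
                             calibration_fraction = 0.2) {
  label <- factor(as.character(data$label), levels = c("negative", "positive"))
  if (anyNA(label)) stop("labels must be 'positive' or 'negative'")
  if (nlevels(droplevels(label)) < 2) {
    stop("training data contains a single class")
  }
  if (min(table(label)) < 10) {
    stop("at least 10 examples per class are required")
  }
  x <- as.matrix(data[, feature_cols, drop = FALSE])
  if (any(!is.finite(x))) stop("features must be finite")

  idx <- withr::with_seed(as.integer(seed), {
    unlist(lapply(levels(label), function(lv) {
      i <- which(label == lv)
      sample(i, max(2L, round(calibration_fraction * length(i))))
    }))
  })
  x_tr <- x[-idx, , drop = FALSE]; y_tr <- label[-idx]
  x_cal <- x[idx, , drop = FALSE];  y_cal <- label[idx]

  center <- colMeans(x_tr)
  scale <- apply(x_tr, 2, sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  std <- function(m) sweep(sweep(m, 2, center), 2, scale, "/")

  wts <- rev(as.numeric(table(y_tr))) / length(y_tr) * 2
  names(wts) <- levels(y_tr)
  fit <- e1071::svm(std(x_tr), y_tr, kernel = kernel, cost = cost,
                    gamma = 1 / ncol(x), scale = FALSE, class.weights = wts)

  dvmat <- attr(predict(fit, std(x_cal), decision.values = TRUE),
                "decision.values")
  # libsvm decision values are positive for the class named first in the
  # column label; orient so larger always means more positive
  orient <- if (startsWith(colnames(dvmat)[1], "positive")) 1 else -1
  dv_cal <- orient * dvmat[, 1]
  platt <- suppressWarnings(
    glm((y_cal == "positive") ~ dv_cal, family = binomial()))

  structure(list(
    svm = fit, kernel = kernel, cost = cost, feature_cols = feature_cols,
    center = center, scale = scale, orient = orient,
    platt = unname(coef(platt)), seed = as.integer(seed),
    fingerprint = fingerprint(list(dim(x), feature_cols,
                                   round(colSums(x), 6), table(label))),
    n_train = nrow(x_tr), n_calibration = nrow(x_cal)),
    class = "interaction_model")
}

#' @export
print.interaction_model <- function(x, ...) {
  cat("Interaction classifier (", x$kernel, "-kernel SVM)\n", sep = "")
  cat("  features:", paste(x$feature_cols, collapse = ", "), "\n")
  cat("  training/calibration examples:", x$n_train, "/", x$n_calibration, "\n")
  cat("  seed:", x$seed, "  fingerprint:", x$fingerprint, "\n")
  invisible(x)
}

# Calibrated probability of the positive class for a feature matrix.
model_probability <- function(model, x) {
  x <- as.matrix(x[, model$feature_cols, drop = FALSE])
  if (any(!is.finite(x))) stop("features must be finite")
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  dv <- model$orient *
    attr(predict(model$svm, xs, decision.values = TRUE), "decision.values")[, 1]
  plogis(model$platt[1] + model$platt[2] * dv)
}

#' Predict miRNA-mRNA interactions
#'
#' Applies the trained classifier to feature vectors and labels a pair a
#' predicted target when its calibrated probability strictly exceeds the
#' cutoff (default 0.60).
#'
#' @param model an `interaction_model` from [train_classifier()]
#' @param features data.frame of feature vectors (must carry the model's
#'   feature columns; `mirna_id`, `gene_symbol`, `species` are carried
#'   through when present)
#' @param cutoff probability cutoff, strict `>` (default 0.60)
#' @return data.frame of target predictions: `mirna_id`, `gene_symbol`,
#'   `species`, `probability`, `predicted_target`, `cutoff`
#' @export
predict_interaction <- function(model, features, cutoff = 0.60) {
  missing_cols <- setdiff(model$feature_cols, names(features))
  if (length(missing_cols)) {
    stop("feature columns missing from input: ",
         paste(missing_cols, collapse = ", "))
  }
  p <- model_probability(model, features)
  get_col <- function(nm) {
    if (nm %in% names(features)) features[[nm]] else NA_character_
  }
  data.frame(mirna_id = get_col("mirna_id"),
             gene_symbol = get_col("gene_symbol"),
             species = get_col("species"),
             probability = unname(p),
             predicted_target = unname(p > cutoff),
             cutoff = cutoff, stringsAsFactors = FALSE)
}

#' Evaluate the classifier on a labeled test set
#'
#' @param model an `interaction_model`
#' @param test data.frame of labeled interactions (feature columns +
#'   `label`); must contain both classes and be disjoint from training
#'   (caller contract)
#' @param cutoff probability above which a pair is assigned to the positive
#'   class for accuracy/confusion (default 0.5, i.e. the most probable class)
#' @return list: `accuracy`, `auc`, `confusion` (2x2 table), `n`
#' @export
evaluate_classifier <- function(model, test, cutoff = 0.5) {
  if (is.null(test) || nrow(test) == 0) stop("test set is empty")
  label <- factor(as.character(test$label), levels = c("negative", "positive"))
  if (nlevels(droplevels(label)) < 2) stop("test set contains a single class")
  p <- model_probability(model, test)
  pred <- factor(ifelse(p > cutoff, "positive", "negative"),
                 levels = c("negative", "positive"))
  confusion <- table(truth = label, predicted = pred)
  auc <- as.numeric(pROC::auc(pROC::roc(
    response = label, predictor = as.numeric(p),
    levels = c("negative", "positive"), direction = "<", quiet = TRUE)))
  list(accuracy = mean(pred == label), auc = auc, confusion = confusion,
       n = length(label))
}

#' Cross-species consistent target genes
#'
#' Intersects the predicted-target gene sets of two species
#' (case-insensitive symbols, reported uppercase, sorted alphabetically) and
#' attaches the supporting miRNAs from each species.
#'
#' @param preds_a,preds_b data.frames of target predictions from
#'   [predict_interaction()]
#' @return data.frame: `gene_symbol`, `mirnas_a`, `mirnas_b` (each a
#'   `;`-collapsed string of supporting miRNA ids)
#' @export
cross_species_consistent_targets <- function(preds_a, preds_b) {
  pick <- function(p) {
    p <- p[p$predicted_target, , drop = FALSE]
    p$gene_symbol <- toupper(p$gene_symbol)
    p
  }
  a <- pick(preds_a); b <- pick(preds_b)
  genes <- sort(intersect(unique(a$gene_symbol), unique(b$gene_symbol)))
  support <- function(p, g) {
    paste(sort(unique(p$mirna_id[p$gene_symbol == g])), collapse = ";")
  }
  data.frame(gene_symbol = genes,
             mirnas_a = vapply(genes, support, "", p = a),
             mirnas_b = vapply(genes, support, "", p = b),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Save / load a trained interaction model
#'
#' Single-file serialized bundle; a reloaded model reproduces probabilities
#' exactly.
#'
#' @param model an `interaction_model`
#' @param path file path
#' @return `path` (save) or the model (load)
#' @export
save_interaction_model <- function(model, path) {
  stopifnot(inherits(model, "interaction_model"))
  saveRDS(list(format = "mircross_interaction_model", version = 1L,
               model = model), path)
  invisible(path)
}

#' @rdname save_interaction_model
#' @export
load_interaction_model <- function(path) {
  bundle <- readRDS(path)
  if (!identical(bundle$format, "mircross_interaction_model")) {
    stop("not a serialized interaction model: ", path)
  }
  bundle$model
}
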