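#' Classifier configuration
#'
#' @param model `"rf"` (random forest, the default), `"svm"` (RBF kernel) or
#'   `"lr"` (multinomial logistic regression) — the latter two are
#'   comparators.
#' @param n_trees Number of trees for the random forest (default 1000).
#' @param seed Integer seed for training.
#' @param vector_strategy Complex-vector pooling strategy, see
#'   [complex_vector()].
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(model = c("rf", "svm", "lr"), n_trees = 1000L,
                              seed = 1L, vector_strategy = "max") {
  model <- match.arg(model)
  stopifnot(n_trees >= 1)
  structure(list(model = model, n_trees = as.integer(n_trees),
                 seed = as.integer(seed),
                 vector_strategy = vector_strategy),
            class = "classifier_config")
}

#' Build the complex-vector training matrix
#'
#' One row per training complex: its pooled [complex_vector()]. Complexes
#' with unembedded members are skipped with a warning and count.
#'
#' @param train A [labeled_complex_set()].
#' @param emb Embedding matrix.
#' @param strategy Pooling strategy (`"max"`, `"min"`, `"average"`).
#' @return List with `rows` (numeric matrix) and `labels` (factor with
#'   levels positive/intermediate/negative).
#' @export
build_training_matrix <- function(train, emb, strategy = "max") {
  stopifnot(inherits(train, "labeled_complex_set"))
  all_cx <- c(train$positives, train$intermediates, train$negatives)
  labels <- rep(c("positive", "intermediate", "negative"),
                c(length(train$positives), length(train$intermediates),
                  length(train$negatives)))
  ok <- vapply(all_cx, function(cx) all(cx %in% rownames(emb)), logical(1))
  if (any(!ok)) {
    warning(sum(!ok), " training complex(es) with unembedded members skipped")
    all_cx <- all_cx[ok]
    labels <- labels[ok]
  }
  rows <- t(vapply(all_cx, complex_vector, numeric(ncol(emb)),
                   emb = emb, strategy = strategy))
  list(rows = rows,
       labels = factor(labels,
                       levels = c("positive", "intermediate", "negative")))
}

#' Train the three-class complex classifier
#'
#' The default is a random forest with 1000 trees; support-vector machine
#' (RBF kernel) and multinomial logistic regression are available as
#' comparators. Out-of-bag (RF) accuracy is reported via [message()].
#'
#' @param rows Numeric feature matrix (one complex vector per row).
#' @param labels Factor or character vector of class labels, same length as
#'   `nrow(rows)`.
#' @param config A [classifier_config()].
#' @return An object of class `complex_classifier`.
#' @export
train_classifier <- function(rows, labels, config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"))
  if (nrow(rows) != length(labels)) stop("rows/labels length mismatch")
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) stop("need at least 2 classes, got ",
                                nlevels(labels))
  colnames(rows) <- paste0("V", seq_len(ncol(rows)))
  set.seed(config$seed)
  model <- switch(config$model,
    rf = {
      m <- randomForest::randomForest(x = rows, y = labels,
                                      ntree = config$n_trees)
      message("random-forest OOB accuracy: ",
              round(1 - m$err.rate[config$n_trees, "OOB"], 4))
      m
    },
    svm = {
      if (!requireNamespace("e1071", quietly = TRUE)) {
        stop("the 'e1071' package is required for the SVM comparator")
      }
      e1071::svm(x = rows, y = labels, kernel = "radial")
    },
    lr = {
      if (!requireNamespace("nnet", quietly = TRUE)) {
        stop("the 'nnet' package is required for the LR comparator")
      }
      df <- data.frame(rows, .label = labels)
      nnet::multinom(.label ~ ., data = df, trace = FALSE, maxit = 200)
    })
  structure(list(model = model, config = config, classes = levels(labels),
                 n_features = ncol(rows)),
            class = "complex_classifier")
}

#' Predict classes for complex vectors
#'
#' @param object A `complex_classifier`.
#' @param newdata Numeric matrix of complex vectors.
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.complex_classifier <- function(object, newdata, ...) {
  colnames(newdata) <- paste0("V", seq_len(ncol(newdata)))
  if (object$config$model == "lr") {
    as.character(predict(object$model, newdata = data.frame(newdata)))
  } else {
    as.character(predict(object$model, newdata))
  }
}

#' Keep candidates the classifier labels positive
#'
#' Computes each candidate's complex vector, predicts its class, and returns
#' (in input order) exactly the candidates labelled `"positive"` — the final
#' predicted complexes. Candidates with unembedded members are excluded with
#' a warning. Per-class prediction counts are reported via [message()].
#'
#' @param candidates List of character vectors (e.g. from
#'   [detect_candidates()]).
#' @param emb Embedding matrix.
#' @param model A trained `complex_classifier`.
#' @param strategy Pooling strategy; defaults to the one used at training.
#' @return Sub-list of `candidates`.
#' @export
filter_candidates <- function(candidates, emb, model, strategy = NULL) {
  stopifnot(inherits(model, "complex_classifier"))
  if (is.null(strategy)) strategy <- model$config$vector_strategy
  if (length(candidates) == 0) return(list())
  ok <- vapply(candidates, function(cx) all(cx %in% rownames(emb)),
               logical(1))
  if (any(!ok)) {
    warning(sum(!ok), " candidate(s) with unembedded members excluded")
  }
  kept <- candidates[ok]
  if (length(kept) == 0) return(list())
  rows <- t(vapply(kept, complex_vector, numeric(ncol(emb)), emb = emb,
                   strategy = strategy))
  cls <- predict(model, rows)
  counts <- table(factor(cls, levels = model$classes))
  message("classifier labels: ",
          paste(names(counts), as.integer(counts), sep = "=",
                collapse = ", "))
  kept[cls == "positive"]
}
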