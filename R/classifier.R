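#' Fit a non-parametric discriminant model
#'
#' Non-parametric discriminant analysis: each class's feature distribution is
#' estimated without distributional assumptions and prediction combines the
#' class-conditional estimates with class priors via Bayes' rule. Two
#' variants are provided:
#'
#' * `method = "kde"` (default): product-Gaussian-kernel density estimate per
#'   class with per-dimension Silverman bandwidths
#'   `h = 1.06 * sigma_hat * m^(-1/5)` (`sigma_hat` the class's sample SD in
#'   that dimension, `m` the class row count), floored at
#'   `bandwidth_floor_rel` times the dimension's global SD (or at
#'   `bandwidth_floor_rel` absolutely when that SD is zero). Features are not
#'   standardized: per-dimension bandwidths absorb scale.
#' * `method = "knn"`: majority vote among the `k` nearest training rows by
#'   Euclidean distance on features standardized to the training mean/SD;
#'   shipped as a sensitivity alternative.
#'
#' @param features Feature tibble (see [sequence_features()]) or a numeric
#'   matrix/data frame containing at least the columns in `combination`.
#' @param labels Character vector of mode labels, one per row.
#' @param combination Character vector of 1-3 metric names (a subset of
#'   [METRIC_NAMES]) spanning the feature space.
#' @param method `"kde"` or `"knn"`.
#' @param priors `"equal"` (default) or `"proportional"` to class
#'   frequencies, or a named numeric vector.
#' @param bandwidth_floor_rel Relative bandwidth floor (KDE only).
#' @param k Neighbour count (kNN only).
#' @return An object of class `"kde_da"` or `"knn_da"` with a common
#'   interface: [posterior()] and [predict()][predict.kde_da].
#' @export
fit_discriminant <- function(features, labels, combination,
                             method = c("kde", "knn"),
                             priors = "equal",
                             bandwidth_floor_rel = 1e-6,
                             k = 5L) {
  method <- match.arg(method)
  if (length(combination) < 1L || length(combination) > 3L) {
    abort("`combination` must contain 1 to 3 metric names.",
          class = "modeshift_config_error")
  }
  x <- as.matrix(as.data.frame(features)[, combination, drop = FALSE])
  storage.mode(x) <- "double"
  labels <- as.character(labels)
  if (nrow(x) != length(labels)) {
    abort("`features` and `labels` lengths differ.",
          class = "modeshift_shape_error")
  }
  classes <- class_sort(unique(labels))
  if (length(classes) < 2L) {
    abort("Need at least 2 distinct classes to fit a discriminant.",
          class = "modeshift_degenerate_class_error")
  }
  counts <- vapply(classes, function(cl) sum(labels == cl), integer(1))
  if (any(counts == 0L)) {
    abort(paste0("Class with zero training rows: ",
                 paste(classes[counts == 0L], collapse = ", ")),
          class = "modeshift_degenerate_class_error")
  }
  pr <- resolve_priors(priors, classes, counts)
  split_x <- lapply(classes, function(cl) x[labels == cl, , drop = FALSE])
  names(split_x) <- classes
  if (method == "kde") {
    global_sd <- apply(x, 2, sd)
    global_sd[!is.finite(global_sd)] <- 0
    floor_h <- ifelse(global_sd > 0, bandwidth_floor_rel * global_sd,
                      bandwidth_floor_rel)
    bw <- lapply(split_x, function(mat) {
      m <- nrow(mat)
      sig <- if (m >= 2L) apply(mat, 2, sd) else
        setNames(rep(0, ncol(mat)), colnames(mat))
      sig[!is.finite(sig)] <- 0
      pmax(1.06 * sig * m^(-1 / 5), floor_h)
    })
    structure(
      list(classes = classes, priors = pr, train = split_x, bandwidths = bw,
           combination = combination,
           config = list(bandwidth_floor_rel = bandwidth_floor_rel)),
      class = "kde_da"
    )
  } else {
    ctr <- colMeans(x)
    scl <- apply(x, 2, sd)
    scl[!is.finite(scl) | scl == 0] <- 1
    structure(
      list(classes = classes, priors = pr,
           x = scale(x, center = ctr, scale = scl), labels = labels,
           center = ctr, scale = scl, k = as.integer(k),
           combination = combination),
      class = "knn_da"
    )
  }
}

# order labels by the canonical class order, unknown labels last
class_sort <- function(labels) {
  known <- CLASS_ORDER[CLASS_ORDER %in% labels]
  c(known, sort(setdiff(labels, known)))
}

resolve_priors <- function(priors, classes, counts) {
  if (identical(priors, "equal")) {
    p <- rep(1 / length(classes), length(classes))
  } else if (identical(priors, "proportional")) {
    p <- counts / sum(counts)
  } else if (is.numeric(priors)) {
    if (!all(classes %in% names(priors))) {
      abort("Named `priors` must cover every class.",
            class = "modeshift_config_error")
    }
    p <- priors[classes] / sum(priors[classes])
  } else {
    abort("`priors` must be 'equal', 'proportional' or a named vector.",
          class = "modeshift_config_error")
  }
  setNames(as.numeric(p), classes)
}

query_matrix <- function(model, newdata) {
  df <- as.data.frame(newdata)
  d <- length(model$combination)
  if (all(model$combination %in% names(df))) {
    df <- df[, model$combination, drop = FALSE]
  } else if (ncol(df) != d) {
    abort(sprintf("Query has %d columns; model expects %d (%s).",
                  ncol(df), d, paste(model$combination, collapse = ", ")),
          class = "modeshift_shape_error")
  }
  x <- as.matrix(df)
  storage.mode(x) <- "double"
  x
}

#' Posterior class scores
#'
#' Per-class scores `score_c` proportional to `prior_c * fhat_c(x)`,
#' normalized to sum to 1 per query row; computed in log space for numerical
#' stability.
#'
#' @param model A fitted `"kde_da"` or `"knn_da"` model.
#' @param newdata Matrix/data frame of query points over the model's metric
#'   combination.
#' @return Numeric matrix, one row per query, one column per class.
#' @export
posterior <- function(model, newdata) UseMethod("posterior")

#' @export
posterior.kde_da <- function(model, newdata) {
  logs <- log_scores_kde(model, query_matrix(model, newdata))
  norm <- apply(logs, 1, logsumexp)
  p <- exp(logs - norm)
  colnames(p) <- model$classes
  p
}

# q x K matrix of log(prior_c) + log fhat_c(x): the unnormalized log scores
log_scores_kde <- function(model, x) {
  q <- nrow(x)
  d <- ncol(x)
  out <- matrix(NA_real_, q, length(model$classes))
  for (ci in seq_along(model$classes)) {
    mat <- model$train[[ci]]
    h <- model$bandwidths[[ci]]
    m <- nrow(mat)
    acc <- matrix(0, q, m)
    for (j in seq_len(d)) {
      z <- outer(x[, j], mat[, j], "-") / h[j]
      acc <- acc + dnorm(z, log = TRUE) - log(h[j])
    }
    logf <- apply(acc, 1, logsumexp) - log(m)
    out[, ci] <- log(model$priors[ci]) + logf
  }
  out
}

#' @export
posterior.knn_da <- function(model, newdata) {
  x <- query_matrix(model, newdata)
  x <- scale(x, center = model$center, scale = model$scale)
  p <- matrix(0, nrow(x), length(model$classes),
              dimnames = list(NULL, model$classes))
  for (i in seq_len(nrow(x))) {
    d2 <- colSums((t(model$x) - x[i, ])^2)
    nn <- order(d2)[seq_len(min(model$k, length(d2)))]
    votes <- table(factor(model$labels[nn], levels = model$classes))
    p[i, ] <- as.numeric(votes) / sum(votes)
  }
  p
}

#' Predict mode labels
#'
#' Argmax of [posterior()]; exact ties are broken by the fixed class order
#' walk < bike < train < bus < car < motorized for reproducibility.
#'
#' @param object Fitted discriminant model.
#' @param newdata Query features.
#' @param ... Unused.
#' @return Character vector of predicted mode labels.
#' @export
predict.kde_da <- function(object, newdata, ...) {
  logs <- log_scores_kde(object, query_matrix(object, newdata))
  object$classes[max.col(logs, ties.method = "first")]
}

#' @rdname predict.kde_da
#' @export
predict.knn_da <- function(object, newdata, ...) {
  p <- posterior(object, newdata)
  object$classes[max.col(p, ties.method = "first")]
}

#' Serialize a discriminant model to JSON (and back)
#'
#' Full-precision, exact round trip of classes, priors, bandwidths, training
#' matrices, metric combination and configuration.
#'
#' @param model Fitted model.
#' @param json A JSON string produced by `model_to_json()`.
#' @return `model_to_json()` returns a JSON string; `model_from_json()`
#'   returns the reconstructed model.
#' @export
model_to_json <- function(model) {
  if (inherits(model, "kde_da")) {
    payload <- list(
      type = "kde_da", classes = model$classes, priors = model$priors,
      combination = model$combination, config = model$config,
      bandwidths = model$bandwidths,
      train = lapply(model$train, function(m) unclass(as.data.frame(m)))
    )
  } else {
    payload <- list(
      type = "knn_da", classes = model$classes, priors = model$priors,
      combination = model$combination, k = model$k,
      center = as.list(model$center), scale = as.list(model$scale),
      labels = model$labels,
      x = unclass(as.data.frame(unclass(model$x)))
    )
  }
  jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE)
}

#' @rdname model_to_json
#' @export
model_from_json <- function(json) {
  p <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  if (identical(p$type, "kde_da")) {
    train <- lapply(p$train, function(df) {
      m <- as.matrix(as.data.frame(df))
      colnames(m) <- p$combination
      m
    })
    bw <- lapply(p$bandwidths, function(b) setNames(as.numeric(b), p$combination))
    structure(
      list(classes = p$classes,
           priors = setNames(as.numeric(p$priors), p$classes),
           train = train[p$classes], bandwidths = bw[p$classes],
           combination = p$combination, config = as.list(p$config)),
      class = "kde_da"
    )
  } else {
    xm <- as.matrix(as.data.frame(p$x))
    colnames(xm) <- p$combination
    structure(
      list(classes = p$classes,
           priors = setNames(as.numeric(p$priors), p$classes),
           x = xm, labels = p$labels,
           center = setNames(as.numeric(unlist(p$center)), p$combination),
           scale = setNames(as.numeric(unlist(p$scale)), p$combination),
           k = as.integer(p$k), combination = p$combination),
      class = "knn_da"
    )
  }
}
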