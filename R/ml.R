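# Kernel ridge regression over one-hot composition encodings, plain or as a
# delta-ML layer on top of the additive Hammett baseline. The representation
# deliberately contains no Cartesian information: which group sits at which
# position, and which reaction (or nucleophile/leaving-group pair) is run.

# Evaluate code under a private, seeded RNG stream; the caller's RNG state is
# untouched.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Build a one-hot encoding for a reaction table
#'
#' One indicator block per scaffold position (vocabulary = the table's group
#' labels) plus reaction-descriptor blocks: either a single block over the
#' reaction ids, or — when `reaction_id_split` is given — one block per
#' component of the split ids (e.g. nucleophile and leaving group for ids
#' like `"F_Cl"`). Every encoded vector has exactly one 1 per block.
#'
#' @param table a `reaction_table`.
#' @param reaction_id_split optional separator; reaction ids are split on it
#'   into parallel descriptor blocks.
#' @return object of class `one_hot_encoding` with `blocks` (named list of
#'   level vectors) and `vector_length`.
#' @export
one_hot_encoding <- function(table, reaction_id_split = NULL) {
  blocks <- lapply(table$positions, function(p) table$groups)
  names(blocks) <- paste0("position:", table$positions)
  if (is.null(reaction_id_split)) {
    blocks[["reaction"]] <- table$reactions
  } else {
    parts <- strsplit(table$reactions, reaction_id_split, fixed = TRUE)
    k <- unique(lengths(parts))
    if (length(k) != 1L) {
      stop("encoding error: reaction ids split into unequal arities")
    }
    pm <- do.call(rbind, parts)
    for (i in seq_len(k)) {
      blocks[[paste0("reaction:", i)]] <- sort(unique(pm[, i]))
    }
  }
  structure(list(blocks = blocks, positions = table$positions,
                 reaction_id_split = reaction_id_split,
                 vector_length = sum(lengths(blocks))),
            class = "one_hot_encoding")
}

#' Encode records as binary one-hot vectors
#'
#' @param table a `reaction_table` (or a records data.frame with the same
#'   columns).
#' @param encoding a `one_hot_encoding`.
#' @return binary matrix, one row per record, `encoding$vector_length`
#'   columns.
#' @export
encode_records <- function(table, encoding) {
  records <- if (inherits(table, "reaction_table")) table$records else table
  n <- nrow(records)
  cols <- vector("list", length(encoding$blocks))
  for (bi in seq_along(encoding$blocks)) {
    bname <- names(encoding$blocks)[bi]
    levels <- encoding$blocks[[bi]]
    labels <- if (startsWith(bname, "position:")) {
      records[[sub("^position:", "", bname)]]
    } else if (bname == "reaction") {
      records$reaction_id
    } else {
      i <- as.integer(sub("^reaction:", "", bname))
      vapply(strsplit(records$reaction_id, encoding$reaction_id_split,
                      fixed = TRUE), `[[`, "", i)
    }
    idx <- match(labels, levels)
    if (anyNA(idx)) {
      stop("encoding error: label(s) outside vocabulary of block '", bname,
           "': ", paste(unique(labels[is.na(idx)]), collapse = ", "))
    }
    M <- matrix(0, nrow = n, ncol = length(levels))
    M[cbind(seq_len(n), idx)] <- 1
    cols[[bi]] <- M
  }
  do.call(cbind, cols)
}

# Pairwise distances: L1 (Manhattan) or squared L2, between rows of X and Z.
.cross_dist <- function(X, Z, type = c("l1", "l2sq")) {
  type <- match.arg(type)
  if (type == "l2sq") {
    sx <- rowSums(X^2); sz <- rowSums(Z^2)
    D <- outer(sx, sz, "+") - 2 * tcrossprod(X, Z)
    D[D < 0] <- 0
    return(D)
  }
  D <- matrix(0, nrow(X), nrow(Z))
  for (k in seq_len(ncol(X))) D <- D + abs(outer(X[, k], Z[, k], "-"))
  D
}

.kernel_matrix <- function(X, Z, kernel, width) {
  switch(kernel,
         laplacian = exp(-.cross_dist(X, Z, "l1") / width),
         gaussian = exp(-.cross_dist(X, Z, "l2sq") / (2 * width^2)),
         stop("unknown kernel '", kernel, "'"))
}

#' Train a kernel ridge regression model
#'
#' Solves \eqn{(K + \lambda I)\, a = y} for the dual coefficients, with the
#' Laplacian kernel \eqn{\exp(-\lVert x - x'\rVert_1 / w)} (the default:
#' natural for binary fingerprints) or the Gaussian kernel
#' \eqn{\exp(-\lVert x - x'\rVert_2^2 / 2w^2)}. Deterministic given inputs.
#'
#' @param X numeric matrix of training vectors (rows).
#' @param y numeric response vector.
#' @param kernel `"laplacian"` or `"gaussian"`.
#' @param width kernel width (> 0).
#' @param regularization ridge term (>= 0).
#' @return object of class `krr_model` with `training_vectors`,
#'   `dual_coefficients`, and the kernel spec; `target_kind` is
#'   `"response"`.
#' @export
krr_train <- function(X, y, kernel = c("laplacian", "gaussian"), width,
                      regularization = 1e-10) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), length(y) >= 1L, width > 0,
            regularization >= 0)
  K <- .kernel_matrix(X, X, kernel, width)
  diag(K) <- diag(K) + regularization
  a <- tryCatch(solve(K, y), error = function(e) {
    stop("solver error: kernel system is singular (duplicate rows at ",
         "regularization 0?); increase the regularization. [",
         conditionMessage(e), "]")
  })
  structure(list(kernel = kernel, kernel_width = width,
                 regularization = regularization,
                 training_vectors = X, dual_coefficients = as.numeric(a),
                 target_kind = "response"),
            class = "krr_model")
}

#' Predict with a kernel ridge regression model
#'
#' \eqn{\hat y(x) = \sum_i a_i\, k(x, x_i)}. For residual-target models
#' (delta-ML) the caller adds the baseline; see [delta_train()].
#'
#' @param model a `krr_model`.
#' @param X_new numeric matrix of query vectors (rows).
#' @return numeric predictions.
#' @export
krr_predict <- function(model, X_new) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != ncol(model$training_vectors)) {
    stop("encoding error: query dimension ", ncol(X_new),
         " != training dimension ", ncol(model$training_vectors))
  }
  Kn <- .kernel_matrix(X_new, model$training_vectors, model$kernel,
                       model$kernel_width)
  as.numeric(Kn %*% model$dual_coefficients)
}

# seeded fold assignment: shuffled permutation then contiguous split
.cv_folds <- function(n, n_folds, seed) {
  perm <- with_seed(seed, sample.int(n))
  split(perm, cut(seq_len(n), breaks = n_folds, labels = FALSE))
}

#' Cross-validated grid search for KRR hyperparameters
#'
#' Exhaustive evaluation of every (width, regularization) cell by k-fold
#' cross validation (seeded shuffle, contiguous folds), scored by mean
#' held-out MAE. Ties are broken toward larger regularization, then larger
#' width (the smoother model).
#'
#' @param X,y training data.
#' @param kernel `"laplacian"` or `"gaussian"`.
#' @param width_grid,reg_grid numeric candidate grids (defaults: powers of 2
#'   from 0.25 to 64; regularization 1e-10 to 1e-2 by decades).
#' @param n_folds folds (default 5).
#' @param seed integer seed for the fold shuffle.
#' @return list with `width`, `regularization`, and the full `cv_table`
#'   (data.frame of width, regularization, cv_mae).
#' @export
grid_search_cv <- function(X, y, kernel = "laplacian",
                           width_grid = 2^(-2:6),
                           reg_grid = 10^c(-10, -8, -6, -4, -2),
                           n_folds = 5L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= n_folds)
  if (length(width_grid) == 0L || length(reg_grid) == 0L) {
    stop("configuration error: empty hyperparameter grid")
  }
  folds <- .cv_folds(n, n_folds, seed)
  D <- .cross_dist(X, X, if (kernel == "laplacian") "l1" else "l2sq")
  grid <- expand.grid(width = width_grid, regularization = reg_grid)
  cv_mae <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    w <- grid$width[g]; lam <- grid$regularization[g]
    K <- if (kernel == "laplacian") exp(-D / w) else exp(-D / (2 * w^2))
    fold_mae <- vapply(folds, function(test) {
      train <- setdiff(seq_len(n), test)
      Kt <- K[train, train, drop = FALSE]
      diag(Kt) <- diag(Kt) + lam
      a <- solve(Kt, y[train])
      mean(abs(K[test, train, drop = FALSE] %*% a - y[test]))
    }, numeric(1))
    cv_mae[g] <- mean(fold_mae)
  }
  # ties toward larger regularization then larger width
  ord <- order(cv_mae, -grid$regularization, -grid$width)
  best <- ord[1L]
  list(width = grid$width[best], regularization = grid$regularization[best],
       cv_table = cbind(grid, cv_mae = cv_mae))
}

#' Fit a KRR model directly on a reaction table
#'
#' Convenience wrapper: encodes the records and trains on the responses.
#'
#' @param table a `reaction_table`.
#' @param encoding a `one_hot_encoding` (default built from the table).
#' @param ... passed to [krr_train()] (`kernel`, `width`, `regularization`).
#' @return a `krr_model` carrying its encoding; predict with
#'   [predict.krr_model()] on a table.
#' @export
fit_krr <- function(table, encoding = NULL, ...) {
  if (is.null(encoding)) encoding <- one_hot_encoding(table)
  m <- krr_train(encode_records(table, encoding), table$records$response, ...)
  m$encoding <- encoding
  m
}

#' @export
predict_table.krr_model <- function(params, table) {
  if (is.null(params$encoding)) {
    stop("this krr_model was trained on raw matrices; use krr_predict()")
  }
  p <- krr_predict(params, encode_records(table, params$encoding))
  if (!is.null(params$baseline)) {
    p <- p + predict_table(params$baseline, table)
  }
  p
}

#' @export
predict.krr_model <- function(object, newdata, ...) {
  if (inherits(newdata, "reaction_table") || is.data.frame(newdata)) {
    if (is.data.frame(newdata) && !inherits(newdata, "reaction_table")) {
      stop("newdata must be a reaction_table or an encoded matrix")
    }
    predict_table(object, newdata)
  } else {
    krr_predict(object, newdata)
  }
}

#' Train a delta-ML model over the additive Hammett baseline
#'
#' The KRR layer learns only the residuals \eqn{r = y - \hat y_{baseline}};
#' predictions add the baseline back. Because the residual surface is
#' smoother than the raw response, the learning curve starts at a much lower
#' offset than plain KRR.
#'
#' @param table a `reaction_table` of training records.
#' @param baseline a fitted `alpha_hammett` model (must cover every training
#'   record).
#' @param encoding a `one_hot_encoding` (default built from the table).
#' @param ... passed to [krr_train()].
#' @return a `krr_model` with `target_kind = "residual"` and the baseline
#'   attached; [predict.krr_model()] on a table returns baseline + residual.
#' @export
delta_train <- function(table, baseline, encoding = NULL, ...) {
  if (is.null(encoding)) encoding <- one_hot_encoding(table)
  base_pred <- predict_table(baseline, table)
  if (anyNA(base_pred)) {
    stop("baseline failure on record(s) ",
         paste(which(is.na(base_pred)), collapse = ", "))
  }
  r <- table$records$response - base_pred
  m <- krr_train(encode_records(table, encoding), r, ...)
  m$target_kind <- "residual"
  m$encoding <- encoding
  m$baseline <- baseline
  m
}

.subset_table <- function(table, rows) {
  reaction_table(table$records[rows, , drop = FALSE],
                 positions = table$positions,
                 reference_set = table$reference_set, validate = FALSE)
}

.fit_lc_method <- function(method, train_tbl, geometry, hyper) {
  switch(method,
         sigma_hammett = fit_sigma_hammett(train_tbl),
         alpha_hammett = fit_alpha_hammett(train_tbl, geometry,
                                           form = hyper$alpha_form,
                                           joint = hyper$alpha_joint),
         ml = fit_krr(train_tbl, encoding = hyper$encoding,
                      kernel = hyper$kernel, width = hyper$width,
                      regularization = hyper$regularization),
         delta_ml = {
           base <- fit_alpha_hammett(train_tbl, geometry,
                                     form = hyper$alpha_form,
                                     joint = hyper$alpha_joint)
           delta_train(train_tbl, base, encoding = hyper$encoding,
                       kernel = hyper$kernel, width = hyper$width,
                       regularization = hyper$regularization)
         },
         stop("unknown learning-curve method '", method, "'"))
}

#' Learning curves for the Hammett and ML models
#'
#' For each training-set size and repeat, draws a seeded subsample from the
#' non-holdout pool, fits the requested method, and scores MAE on a fixed
#' disjoint holdout. Identical seeds give identical curves. Hammett-family
#' fits that fail on a too-sparse subsample (e.g. a disconnected reaction
#' graph) yield `NA` for that repeat and are excluded from the summary.
#'
#' @param table a `reaction_table`.
#' @param method one of `"sigma_hammett"`, `"alpha_hammett"`, `"ml"`,
#'   `"delta_ml"`.
#' @param train_sizes integer vector of training sizes (default geometric
#'   25..1600, capped at the available pool).
#' @param n_repeats repeats per size (default 10).
#' @param holdout_fraction fraction of records reserved as the common
#'   holdout (default 0.2).
#' @param seed integer; drives holdout selection and all subsamples.
#' @param geometry `scaffold_geometry` for the additive baseline.
#' @param hyper list of ML hyperparameters: `kernel`, `width`,
#'   `regularization`, `alpha_form`, `encoding`.
#' @return data.frame with columns `size`, `mean_mae`, `sd_mae`,
#'   `n_effective`.
#' @export
learning_curve <- function(table, method,
                           train_sizes = c(25, 50, 100, 200, 400, 800, 1600),
                           n_repeats = 10L, holdout_fraction = 0.2,
                           seed = 1L, geometry = NULL,
                           hyper = list()) {
  hyper <- modifyList(list(kernel = "laplacian", width = 4,
                           regularization = 1e-8, alpha_form = "power",
                           alpha_joint = TRUE, encoding = NULL), hyper)
  if (is.null(hyper$encoding)) hyper$encoding <- one_hot_encoding(table)
  n <- nrow(table$records)
  holdout <- with_seed(seed, sample.int(n, size = max(2L, round(holdout_fraction * n))))
  pool <- setdiff(seq_len(n), holdout)
  train_sizes <- train_sizes[train_sizes <= length(pool)]
  if (length(train_sizes) == 0L) {
    stop("configuration error: no training size fits the available pool (",
         length(pool), " records)")
  }
  holdout_tbl <- .subset_table(table, sort(holdout))
  out <- lapply(train_sizes, function(sz) {
    maes <- vapply(seq_len(n_repeats), function(rep) {
      rows <- with_seed(seed * 10000L + sz * 100L + rep,
                        sample(pool, size = sz))
      tryCatch(suppressWarnings({
        train_tbl <- .subset_table(table, sort(rows))
        fit <- .fit_lc_method(method, train_tbl, geometry, hyper)
        as.numeric(evaluate_mae(fit, holdout_tbl, per = "global"))
      }), error = function(e) NA_real_)
    }, numeric(1))
    ok <- maes[!is.na(maes)]
    data.frame(size = sz,
               mean_mae = if (length(ok)) mean(ok) else NA_real_,
               sd_mae = if (length(ok) > 1L) sd(ok) else NA_real_,
               n_effective = length(ok))
  })
  do.call(rbind, out)
}
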