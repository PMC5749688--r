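# Participant-independent nested 3-fold cross-validation with a linear
# maximum-margin classifier.
#
# The solver is deterministic dual coordinate descent on the standard
# box-constrained dual (0 <= alpha_i <= C); the decision rule is
# sign(w.x + b). Ternary problems are handled one-vs-one with majority
# voting, ties broken by declared class order.

#' Partition participants into k folds
#'
#' Seeded random partition into near-equal groups (sizes differ by at most
#' one); every fold serves as test set exactly once in the rotation.
#'
#' @param participant_ids vector of unique participant ids.
#' @param k number of folds (default 3).
#' @param seed integer seed.
#' @return object of class `fold_plan`: `k` and a named integer vector
#'   mapping participant id to fold index.
#' @export
make_folds <- function(participant_ids, k = 3, seed = 1L) {
  ids <- unique(participant_ids)
  n <- length(ids)
  if (k > n) stop2("make_folds: k = ", k, " exceeds ", n, " participants")
  perm <- with_seed(seed, sample(ids))
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  fold <- rep(seq_len(k), times = sizes)
  structure(list(k = k,
                 assignment = stats::setNames(fold, perm)[as.character(sort(ids))]),
            class = "fold_plan")
}

#' Standardize feature sets to training statistics
#'
#' Each column is z-scored using the training set's mean and standard
#' deviation; constant training columns are centered but not scaled
#' (divisor 1). The same transform is applied to every other set, so no
#' test-set statistics ever leak into the model.
#'
#' @param train training feature matrix (rows = instances).
#' @param others named list of further matrices to transform with the
#'   training statistics.
#' @return list with `train`, the transformed `others`, and the `center` /
#'   `scale` vectors used.
#' @export
standardize <- function(train, others = list()) {
  stopifnot(is.matrix(train), nrow(train) >= 1)
  center <- colMeans(train)
  scale <- apply(train, 2, sd)
  scale[is.na(scale) | scale == 0] <- 1
  tf <- function(m) sweep(sweep(m, 2, center), 2, scale, "/")
  c(list(train = tf(train), center = center, scale = scale),
    lapply(others, tf))
}

#' Upsample minority classes by whole-set replication
#'
#' Every minority class is replicated in whole copies, the copy count chosen
#' to bring its size as close as possible to the majority class (ties go to
#' fewer copies); the majority class is untouched. Output order is
#' deterministic: the original instances followed by the extra copies in
#' class order.
#'
#' @param X feature matrix.
#' @param y class labels (one per row of X).
#' @return list with the balanced `X` and `y` and the `copies` used per
#'   class.
#' @export
upsample_minority <- function(X, y) {
  counts <- table(y)
  if (any(counts == 0) || length(counts) < 1)
    stop2("upsample_minority: empty class")
  maj <- max(counts)
  copies <- vapply(counts, function(cnt) {
    lo <- max(1L, floor(maj / cnt))
    cand <- c(lo, lo + 1L)
    dev <- abs(cand * cnt - maj)
    cand[which.min(dev)]  # ties resolve to fewer copies (first candidate)
  }, numeric(1))
  extra <- unlist(lapply(names(counts), function(cl) {
    rep(which(y == cl), times = copies[[cl]] - 1L)
  }))
  idx <- c(seq_along(y), extra)
  list(X = X[idx, , drop = FALSE], y = y[idx],
       copies = stats::setNames(as.integer(copies), names(counts)))
}

#' Train a linear maximum-margin classifier
#'
#' Binary problems train one weight vector; multi-class problems train all
#' one-vs-one pairs and predict by majority vote (ties broken by class
#' order). Training is deterministic given the data and C.
#'
#' @param X feature matrix.
#' @param y labels; at least two classes present.
#' @param C complexity (box-constraint) parameter.
#' @param class_order optional declared class order used for pair
#'   construction and tie-breaking; defaults to order of first appearance.
#' @return object of class `model_spec`.
#' @export
train_linear <- function(X, y, C, class_order = NULL) {
  stopifnot(is.matrix(X), all(is.finite(X)), C > 0)
  y <- as.character(y)
  classes <- class_order %||% unique(y)
  classes <- classes[classes %in% y]
  if (length(classes) < 2) stop2("train_linear: need >= 2 classes, got ",
                                 length(classes))
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  models <- lapply(pairs, function(pr) {
    sel <- y %in% pr
    yy <- ifelse(y[sel] == pr[1], 1, -1)
    fit <- svm_dcd_train(t(X[sel, , drop = FALSE]), yy, C)
    list(pos = pr[1], neg = pr[2], w = fit$w, b = fit$b)
  })
  structure(list(kernel = "linear", C = C, classes = classes,
                 models = models, d = ncol(X)),
            class = "model_spec")
}

#' Predict with a linear model
#'
#' @param model a `model_spec` from [train_linear()].
#' @param X feature matrix with the training dimensionality.
#' @return character vector of predicted labels.
#' @export
predict_linear <- function(model, X) {
  stopifnot(inherits(model, "model_spec"), ncol(X) == model$d)
  votes <- matrix(0L, nrow(X), length(model$classes),
                  dimnames = list(NULL, model$classes))
  for (m in model$models) {
    f <- as.vector(X %*% m$w) + m$b
    pos <- f > 0
    votes[, m$pos] <- votes[, m$pos] + pos
    votes[, m$neg] <- votes[, m$neg] + !pos
  }
  model$classes[apply(votes, 1, which.max)]  # first max = class-order tie-break
}

#' Decision values of a binary linear model
#' @param model binary `model_spec`.
#' @param X feature matrix.
#' @return numeric vector w.x + b.
#' @export
decision_values <- function(model, X) {
  stopifnot(length(model$models) == 1L)
  as.vector(X %*% model$models[[1]]$w) + model$models[[1]]$b
}

#' Default complexity-parameter grid
#' @return numeric vector 1e-5 ... 1e-1.
#' @export
c_grid <- function() 10^seq(-5, -1)

#' Select C on a validation set
#'
#' Trains one model per grid value and returns the value maximizing the
#' validation UAR; ties resolve to the smallest C (strongest
#' regularization).
#'
#' @param X_train,y_train standardized, upsampled training data.
#' @param X_val,y_val standardized validation data.
#' @param grid candidate C values (default [c_grid()]).
#' @param class_order declared class order.
#' @return list with `C`, and `uar_by_C` for auditability.
#' @export
tune_C <- function(X_train, y_train, X_val, y_val, grid = c_grid(),
                   class_order = NULL) {
  grid <- sort(grid)
  uars <- vapply(grid, function(C) {
    m <- train_linear(X_train, y_train, C, class_order)
    uar(y_val, predict_linear(m, X_val))
  }, numeric(1))
  list(C = grid[which.max(uars)],  # first max = smallest C on ties
       uar_by_C = stats::setNames(uars, format(grid, scientific = TRUE)))
}

#' Run the participant-independent nested cross-validation protocol
#'
#' For each of the 3 fold rotations (fold i test, next fold validation,
#' remainder training): standardize all sets to training statistics,
#' upsample minority classes in the training set, select C on the
#' validation set, retrain on the concatenated training + validation data
#' (re-standardized to that concatenation, reusing the selected C), and
#' predict the held-out fold's test set plus `n_boot` bootstrap resamples
#' of it (uniform with replacement, same size, seeded per fold). With the
#' defaults this emits 3 + 3 x 9 = 30 test evaluations.
#'
#' @param ft a `feature_table`.
#' @param seed integer seed driving fold assignment and bootstraps.
#' @param grid C grid (default [c_grid()]).
#' @param n_boot bootstrap resamples per fold (default 9).
#' @param k number of folds (default 3).
#' @return object of class `sicv_result`: `evals` (list of
#'   truth/pred/fold/bootstrap), `plan`, `C_by_fold`, `check`.
#' @export
run_sicv <- function(ft, seed = 1L, grid = c_grid(), n_boot = 9, k = 3) {
  stopifnot(inherits(ft, "feature_table"))
  pp <- ft$meta$participant
  plan <- make_folds(pp, k = k, seed = derive_seed(seed, 1))
  fold_of <- plan$assignment[as.character(pp)]
  class_order <- ft$levels
  evals <- list()
  C_by_fold <- numeric(k)
  for (i in seq_len(k)) {
    i_val <- i %% k + 1L
    te <- fold_of == i
    va <- fold_of == i_val
    tr <- !te & !va
    y_tr <- ft$meta$label[tr]; y_va <- ft$meta$label[va]
    y_te <- ft$meta$label[te]
    if (length(unique(y_tr)) < 2)
      stop2("run_sicv: training partition of rotation ", i,
            " holds a single class")
    s1 <- standardize(ft$X[tr, , drop = FALSE],
                      list(val = ft$X[va, , drop = FALSE]))
    up1 <- upsample_minority(s1$train, y_tr)
    C_star <- tune_C(up1$X, up1$y, s1$val, y_va, grid, class_order)$C
    C_by_fold[i] <- C_star
    # development done: fold the validation set into training, reuse C
    X_tv <- rbind(ft$X[tr, , drop = FALSE], ft$X[va, , drop = FALSE])
    y_tv <- c(y_tr, y_va)
    s2 <- standardize(X_tv, list(test = ft$X[te, , drop = FALSE]))
    up2 <- upsample_minority(s2$train, y_tv)
    model <- train_linear(up2$X, up2$y, C_star, class_order)
    pred <- predict_linear(model, s2$test)
    evals[[length(evals) + 1L]] <-
      list(truth = y_te, pred = pred, fold = i, bootstrap = FALSE)
    n_te <- length(y_te)
    for (b in seq_len(n_boot)) {
      idx <- with_seed(derive_seed(seed, 100L + i, b),
                       sample.int(n_te, n_te, replace = TRUE))
      evals[[length(evals) + 1L]] <-
        list(truth = y_te[idx], pred = pred[idx], fold = i, bootstrap = TRUE)
    }
  }
  structure(list(evals = evals, plan = plan, C_by_fold = C_by_fold,
                 check = ft$check, n_classes = length(class_order),
                 seed = seed),
            class = "sicv_result")
}

#' @export
print.sicv_result <- function(x, ...) {
  cat(sprintf("sicv_result: check '%s', %d evaluations over %d folds, C = {%s}\n",
              x$check, length(x$evals), x$plan$k,
              paste(format(x$C_by_fold), collapse = ", ")))
  invisible(x)
}

#' End-to-end decoding of one configuration
#'
#' Convenience wrapper chaining [relabel()], [average_trials()],
#' [select_channels()], [extract_feature_table()], [run_sicv()] and
#' [eval_report()].
#'
#' @param epochs an `epoch_set`.
#' @param check check to decode.
#' @param avg trial-averaging T (default 1).
#' @param channels channel labels or set name (default: all channels).
#' @param seed integer seed.
#' @param params optional [feature_params()].
#' @param ... passed to [run_sicv()].
#' @return list with `report` (an `eval_report`) and `result`
#'   (the `sicv_result`).
#' @export
decode_check <- function(epochs, check, avg = 1, channels = NULL, seed = 1L,
                         params = NULL, ...) {
  inst <- relabel(epochs, check)
  if (!identical(avg, 1) && !identical(avg, 1L))
    inst <- average_trials(inst, avg)
  if (!is.null(channels)) inst <- select_channels(inst, channels)
  ft <- extract_feature_table(inst, params)
  res <- run_sicv(ft, seed = seed, ...)
  list(report = eval_report(res$evals, n_classes = length(ft$levels)),
       result = res)
}
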