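#' Trial tensor of post-stimulus population responses
#'
#' Container for decoding: a trials x cells x frames array of dF/F
#' snippets (the 20 s post-stimulus window) with complete per-trial
#' labels (`animal`, `condition`, `stimulus_type`, and `recording` for
#' recording-wise cross-validation).
#'
#' @param snippets 3-D numeric array, trials x cells x frames.
#' @param labels data.frame with one row per trial.
#' @param frame_rate frames per second.
#' @return list of class `trial_tensor`.
#' @export
trial_tensor <- function(snippets, labels, frame_rate = 30) {
  stopifnot(length(dim(snippets)) == 3L)
  if (nrow(labels) != dim(snippets)[1L])
    stop("labels (", nrow(labels), ") do not match trials (",
         dim(snippets)[1L], ")")
  need <- c("animal", "condition", "stimulus_type")
  miss <- setdiff(need, names(labels))
  if (length(miss)) stop("labels missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyNA(labels[need])) stop("labels must be complete (no NA)")
  structure(list(snippets = snippets, labels = labels,
                 frame_rate = frame_rate), class = "trial_tensor")
}

#' @rdname trial_tensor
#' @param dff a `dff_recording`.
#' @param stim_log a [stimulus_log()].
#' @param window_s post-stimulus snippet length, seconds.
#' @param labels per-recording label values recycled across trials
#'   (`animal`, `condition`, `recording`).
#' @export
extract_trial_tensor <- function(dff, stim_log, window_s = 20,
                                 labels = list(animal = "a1",
                                               condition = "control",
                                               recording = "r1")) {
  fs <- dff$frame_rate
  post_f <- round(window_s * fs)
  n_t <- ncol(dff$dff)
  keep <- stim_log$onset_frame + post_f <= n_t
  if (!any(keep)) stop("no stimulus window fits the recording")
  onsets <- stim_log$onset_frame[keep]
  snips <- array(0, c(length(onsets), nrow(dff$dff), post_f))
  for (i in seq_along(onsets))
    snips[i, , ] <- dff$dff[, (onsets[i] + 1L):(onsets[i] + post_f)]
  trial_tensor(snips,
               data.frame(animal = labels$animal,
                          condition = labels$condition,
                          recording = labels$recording %||% "r1",
                          stimulus_type = stim_log$stimulus_type[keep],
                          stringsAsFactors = FALSE),
               fs)
}

#' Build per-time-bin decoding features
#'
#' For each time bin of the post-stimulus window (default 500 ms, i.e. 40
#' bins of a 20 s window at 30 Hz), every trial yields a feature vector
#' of per-cell bin-mean dF/F for `n_cells` randomly selected cells
#' (default 500; all cells are used, with a message, when fewer are
#' available). The cell subset is drawn once per seed and shared across
#' bins and trials.
#'
#' @param tensor a [trial_tensor()].
#' @param n_cells number of cells to sample.
#' @param bin_ms time-bin length, milliseconds.
#' @param seed RNG seed for the cell subset.
#' @return list of class `decoding_features`: `features` (array trials x
#'   n_cells x bins), `cells` (selected 0-based indices), `labels`,
#'   `bin_ms`.
#' @export
build_condition_features <- function(tensor, n_cells = 500L, bin_ms = 500,
                                     seed = 1L) {
  stopifnot(inherits(tensor, "trial_tensor"))
  d <- dim(tensor$snippets)
  bin_f <- round(bin_ms / 1000 * tensor$frame_rate)
  if (bin_f < 1L || d[3L] < bin_f)
    stop("snippet (", d[3L], " frames) shorter than one ", bin_ms, " ms bin")
  n_bins <- d[3L] %/% bin_f
  if (n_cells > d[2L]) {
    message("build_condition_features: only ", d[2L],
            " cells available; using all")
    cells <- seq_len(d[2L])
  } else {
    cells <- with_seed(substream_seed(seed, "cell_subset"),
                       sort(sample.int(d[2L], n_cells)))
  }
  feats <- array(0, c(d[1L], length(cells), n_bins))
  for (b in seq_len(n_bins)) {
    idx <- ((b - 1L) * bin_f + 1L):(b * bin_f)
    x <- tensor$snippets[, cells, idx, drop = FALSE]
    dim(x) <- c(d[1L] * length(cells), bin_f)
    feats[, , b] <- rowMeans(x)
  }
  structure(list(features = feats, cells = cells - 1L,
                 labels = tensor$labels, bin_ms = bin_ms),
            class = "decoding_features")
}

# ---- ridge logistic wrapper -------------------------------------------------

#' L2-penalised logistic regression
#'
#' Binary (or one-vs-rest multinomial) logistic regression with an L2
#' penalty of weight `lambda` on the coefficients (intercept
#' unpenalised), fitted by damped Newton iterations; exact dual solve
#' when features outnumber trials. `penalty = "C"` accepts the inverse
#' convention (`lambda = 1 / C`).
#'
#' @param x trials x features matrix.
#' @param y label vector (2 or more classes).
#' @param lambda penalty weight (default 0.001).
#' @param penalty `"lambda"` or `"C"` (inverse strength).
#' @param tol gradient convergence tolerance.
#' @param max_iter iteration cap.
#' @return list of class `ridge_logistic` with per-class `coef`,
#'   `intercept`, `classes`.
#' @export
ridge_logistic <- function(x, y, lambda = 0.001,
                           penalty = c("lambda", "C"),
                           tol = 1e-6, max_iter = 5000L) {
  penalty <- match.arg(penalty)
  if (penalty == "C") lambda <- 1 / lambda
  x <- as.matrix(x)
  classes <- sort(unique(as.character(y)))
  if (length(classes) < 2L) stop("need >= 2 classes, got ", length(classes))
  fits <- if (length(classes) == 2L) {
    list(ridge_logistic_fit_cpp(x, as.numeric(y == classes[2L]),
                                lambda, tol, max_iter))
  } else {
    lapply(classes, function(cl)
      ridge_logistic_fit_cpp(x, as.numeric(y == cl), lambda, tol, max_iter))
  }
  structure(list(fits = fits, classes = classes, lambda = lambda),
            class = "ridge_logistic")
}

#' @rdname ridge_logistic
#' @param object a fitted `ridge_logistic`.
#' @param newdata trials x features matrix.
#' @param ... unused.
#' @export
predict.ridge_logistic <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (length(object$classes) == 2L) {
    s <- drop(newdata %*% object$fits[[1L]]$coef) +
      object$fits[[1L]]$intercept
    object$classes[(s > 0) + 1L]
  } else {
    sc <- vapply(object$fits, function(f)
      drop(newdata %*% f$coef) + f$intercept, numeric(nrow(newdata)))
    if (is.null(dim(sc))) sc <- matrix(sc, nrow = 1L)
    object$classes[max.col(sc, ties.method = "first")]
  }
}

# ---- condition decoding -----------------------------------------------------

# per-bin trial x feature matrices, built once and shared by refits
bin_matrices <- function(features) {
  n_bins <- dim(features$features)[3L]
  d12 <- dim(features$features)[1:2]
  lapply(seq_len(n_bins), function(b) {
    xb <- features$features[, , b, drop = FALSE]
    dim(xb) <- d12
    xb
  })
}

# per-bin test accuracies for one labelling and one split; lean two-class
# path calling the fit routine directly (this sits inside the permutation
# loop, where wrapper overhead would dominate the actual fitting)
bins_max_accuracy <- function(xb_list, cond, tr, te, lambda, penalty,
                              tol, max_iter) {
  classes <- sort(unique(cond))
  if (penalty == "C") lambda <- 1 / lambda
  if (length(classes) == 2L) {
    y_tr <- as.numeric(cond[tr] == classes[2L])
    y_te <- cond[te]
    vapply(xb_list, function(xb) {
      f <- ridge_logistic_fit_cpp(xb[tr, , drop = FALSE], y_tr,
                                  lambda, tol, max_iter)
      s <- xb[te, , drop = FALSE] %*% f$coef + f$intercept
      mean(classes[(s > 0) + 1L] == y_te)
    }, 0)
  } else {
    vapply(xb_list, function(xb) {
      fit <- ridge_logistic(xb[tr, , drop = FALSE], cond[tr], lambda,
                            "lambda", tol, max_iter)
      mean(predict(fit, xb[te, , drop = FALSE]) == cond[te])
    }, 0)
  }
}

draw_subject_split <- function(animals, conditions, split, max_retry = 50L) {
  ua <- unique(animals)
  amap <- conditions[match(ua, animals)]
  if (any(table(amap) < 2L))
    stop("subject-wise split impossible: need >= 2 animals per condition")
  n_train <- max(1L, round(split[1L] * length(ua)))
  for (r in seq_len(max_retry)) {
    train_a <- sample(ua, n_train)
    test_a <- setdiff(ua, train_a)
    if (length(unique(amap[ua %in% train_a])) == length(unique(amap)) &&
        length(unique(amap[ua %in% test_a])) == length(unique(amap)))
      return(list(train = train_a, test = test_a))
  }
  stop("could not draw a split with every condition in train and test")
}

#' Train condition classifiers per time bin (subject-wise split)
#'
#' Fits one L2-penalised logistic classifier per time bin on the features
#' of [build_condition_features()], predicting the animal-level condition
#' label. The 60/40 train/test split assigns whole animals to one side
#' (subject-wise cross-validation), so no animal contributes trials to
#' both; the decoding accuracy of a feature set is the maximum test
#' accuracy over time bins.
#'
#' @param features a `decoding_features` object.
#' @param split train/test fractions over animals.
#' @param lambda,penalty,tol,max_iter see [ridge_logistic()].
#' @param seed RNG seed for the split draw.
#' @param labels optional replacement condition labels (used by the
#'   permutation machinery); defaults to `features$labels$condition`.
#' @return list of class `decoding_result`: `bin_accuracy`,
#'   `max_accuracy`, `best_bin`, `train_animals`, `test_animals`,
#'   `n_test_trials`.
#' @export
train_condition_classifier <- function(features, split = c(0.6, 0.4),
                                       lambda = 0.001,
                                       penalty = "lambda",
                                       tol = 1e-6, max_iter = 5000L,
                                       seed = 1L, labels = NULL) {
  stopifnot(inherits(features, "decoding_features"))
  cond <- labels %||% features$labels$condition
  animal <- features$labels$animal
  sp <- with_seed(substream_seed(seed, "split"),
                  draw_subject_split(animal, cond, split))
  tr <- animal %in% sp$train
  te <- animal %in% sp$test
  stopifnot(!any(tr & te))           # subject-wise integrity
  acc <- bins_max_accuracy(bin_matrices(features), cond, tr, te,
                           lambda, penalty, tol, max_iter)
  structure(list(bin_accuracy = acc, max_accuracy = max(acc),
                 best_bin = which.max(acc) - 1L,
                 train_animals = sp$train, test_animals = sp$test,
                 n_test_trials = sum(te)),
            class = "decoding_result")
}

#' Permutation-derived significance threshold for decoding accuracy
#'
#' Refits the full per-bin classification pipeline on data whose
#' condition labels were permuted at the animal level (each animal's
#' trials keep a common, reassigned label, preserving within-animal
#' correlation), recording the max-over-bins test accuracy of each
#' permuted fit. The significance threshold is the `(1 - alpha)` quantile
#' of this null sample; an observed accuracy is significant when it
#' exceeds the threshold.
#'
#' @param features a `decoding_features` object.
#' @param n_perm number of label permutations (7000 in full runs; a
#'   warning is issued below 100, where the quantile is unstable).
#' @param alpha significance level (threshold quantile `1 - alpha`).
#' @param seed RNG seed; permutation `i` and its split derive from it.
#' @inheritParams train_condition_classifier
#' @return list: `null_accuracy` (length `n_perm`), `threshold`.
#' @export
permutation_significance <- function(features, n_perm = 7000L,
                                     alpha = 0.05, split = c(0.6, 0.4),
                                     lambda = 0.001, penalty = "lambda",
                                     tol = 1e-6, max_iter = 5000L,
                                     seed = 1L) {
  stopifnot(inherits(features, "decoding_features"))
  if (n_perm < 100L)
    warning("n_perm = ", n_perm, " gives an unstable threshold quantile")
  animal <- features$labels$animal
  cond <- features$labels$condition
  ua <- unique(animal)
  amap <- cond[match(ua, animal)]
  xb_list <- bin_matrices(features)
  null_acc <- vapply(seq_len(n_perm), function(i) {
    perm <- with_seed(substream_seed(seed, paste0("perm", i)),
                      sample(amap))
    plab <- perm[match(animal, ua)]
    sp <- with_seed(substream_seed(seed + i, "split"),
                    draw_subject_split(animal, plab, split))
    tr <- animal %in% sp$train
    te <- animal %in% sp$test
    max(bins_max_accuracy(xb_list, plab, tr, te, lambda, penalty,
                          tol, max_iter))
  }, 0)
  list(null_accuracy = null_acc,
       threshold = stats::quantile(null_acc, 1 - alpha, names = FALSE,
                                   type = 1))
}

#' Full condition-decoding analysis for one stimulus type
#'
#' Convenience wrapper: builds features, trains the observed per-bin
#' classifiers, derives the permutation threshold and reports the
#' accuracy-minus-threshold margin (positive margin = significant
#' decoding).
#'
#' @inheritParams build_condition_features
#' @inheritParams permutation_significance
#' @return list: `observed` (a `decoding_result`), `threshold`, `margin`,
#'   `significant`, `null_accuracy`.
#' @export
decode_condition <- function(tensor, n_cells = 500L, bin_ms = 500,
                             split = c(0.6, 0.4), lambda = 0.001,
                             penalty = "lambda", n_perm = 7000L,
                             alpha = 0.05, tol = 1e-6, max_iter = 5000L,
                             seed = 1L) {
  features <- build_condition_features(tensor, n_cells, bin_ms, seed)
  obs <- train_condition_classifier(features, split, lambda, penalty,
                                    tol, max_iter, seed)
  perm <- permutation_significance(features, n_perm, alpha, split, lambda,
                                   penalty, tol, max_iter, seed)
  margin <- obs$max_accuracy - perm$threshold
  list(observed = obs, threshold = perm$threshold, margin = margin,
       significant = obs$max_accuracy > perm$threshold,
       null_accuracy = perm$null_accuracy)
}

#' Per-animal stimulus-type decoder
#'
#' Decodes stimulus identity from single-trial population responses of
#' one animal: each trial's 20 s post-stimulus window of `n_cells`
#' randomly selected cells is flattened into one feature vector (500
#' cells x 600 frames = 300,000 features at full scale); a single
#' one-vs-rest L2 logistic classifier per animal is assessed by
#' leave-one-recording-out cross-validation.
#'
#' @param tensor a [trial_tensor()] for one animal, with a `recording`
#'   label column.
#' @param n_cells cells to sample into the feature vector.
#' @inheritParams ridge_logistic
#' @param seed RNG seed for the cell subset.
#' @return list: `accuracy` (overall CV accuracy), `per_recording`
#'   held-out accuracies, `n_features`.
#' @export
stimulus_type_decoder <- function(tensor, n_cells = 500L, lambda = 0.001,
                                  penalty = "lambda", tol = 1e-6,
                                  max_iter = 5000L, seed = 1L) {
  stopifnot(inherits(tensor, "trial_tensor"))
  if (is.null(tensor$labels$recording))
    stop("tensor labels need a 'recording' column for recording-wise CV")
  recs <- unique(tensor$labels$recording)
  if (length(recs) < 2L)
    stop("need >= 2 recordings for leave-one-recording-out CV")
  per_type <- table(tensor$labels$recording, tensor$labels$stimulus_type)
  d <- dim(tensor$snippets)
  cells <- if (n_cells >= d[2L]) seq_len(d[2L]) else
    with_seed(substream_seed(seed, "cell_subset"),
              sort(sample.int(d[2L], n_cells)))
  X <- matrix(aperm(tensor$snippets[, cells, , drop = FALSE], c(1, 3, 2)),
              nrow = d[1L])          # trial x (frames*cells), fixed order
  y <- tensor$labels$stimulus_type
  correct <- logical(d[1L])
  per_rec <- stats::setNames(numeric(length(recs)), recs)
  for (r in recs) {
    te <- tensor$labels$recording == r
    if (length(unique(y[!te])) < 2L)
      stop("training folds must contain >= 2 stimulus types")
    fit <- ridge_logistic(X[!te, , drop = FALSE], y[!te], lambda, penalty,
                          tol, max_iter)
    pred <- predict(fit, X[te, , drop = FALSE])
    correct[te] <- pred == y[te]
    per_rec[r] <- mean(pred == y[te])
  }
  list(accuracy = mean(correct), per_recording = per_rec,
       n_features = ncol(X))
}
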