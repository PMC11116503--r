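# Stacking classifier: three base learners (random forest, gradient-boosted
# trees, multilayer perceptron) tuned by 5-fold CV, combined by a logistic
# meta-learner fitted on out-of-fold base probabilities only (no leakage).

make_folds <- function(n, k, seed) {
  set.seed(derive_seed(seed, "folds"))
  sample(rep(seq_len(k), length.out = n))
}

class_weights <- function(y) {
  n <- length(y); n1 <- sum(y == 1); n0 <- n - n1
  ifelse(y == 1, n / (2 * n1), n / (2 * n0))
}

#' Default hyperparameter grids for the base learners
#'
#' Small fixed grids keep 5-fold cross-validation desk-scale; every grid is
#' exposed here so it can be replaced wholesale.
#'
#' @return named list of parameter-set lists per learner.
#' @export
default_grids <- function() {
  list(
    rf = list(list(num.trees = 300, mtry = 5),
              list(num.trees = 300, mtry = 10)),
    xgb = list(list(eta = 0.1, max_depth = 4, nrounds = 150),
               list(eta = 0.05, max_depth = 8, nrounds = 150)),
    mlp = list(list(size = 8, decay = 0.01, maxit = 200),
               list(size = 16, decay = 0.01, maxit = 200))
  )
}

# learner interface: fit(X, y, w, params, seed) -> model; prob(model, X) -> p.
# svm and plain logistic are available behind the same interface but are not
# part of the default stack.
learner_defs <- function() {
  list(
    rf = list(
      fit = function(X, y, w, params, seed) {
        ranger::ranger(
          x = as.data.frame(X), y = factor(y, levels = c(0, 1)),
          probability = TRUE, num.trees = params$num.trees,
          mtry = min(params$mtry, ncol(X)), case.weights = w,
          seed = derive_seed(seed, "rf"), num.threads = 1)
      },
      prob = function(model, X) {
        predict(model, data = as.data.frame(X),
                num.threads = 1)$predictions[, "1"]
      }),
    xgb = list(
      fit = function(X, y, w, params, seed) {
        set.seed(derive_seed(seed, "xgb"))
        xgboost::xgb.train(
          params = list(objective = "binary:logistic",
                        eta = params$eta, max_depth = params$max_depth,
                        nthread = 1,
                        scale_pos_weight = sum(y == 0) / max(1, sum(y == 1))),
          data = xgboost::xgb.DMatrix(X, label = y),
          nrounds = params$nrounds, verbose = 0)
      },
      prob = function(model, X) {
        predict(model, xgboost::xgb.DMatrix(X))
      }),
    mlp = list(
      fit = function(X, y, w, params, seed) {
        ctr <- colMeans(X)
        scl <- apply(X, 2, sd)
        scl[scl == 0 | !is.finite(scl)] <- 1
        Xs <- scale(X, center = ctr, scale = scl)
        set.seed(derive_seed(seed, "mlp"))
        fit <- nnet::nnet(x = Xs, y = y, size = params$size,
                          decay = params$decay, maxit = params$maxit,
                          weights = w, entropy = TRUE, trace = FALSE,
                          MaxNWts = 5000)
        list(fit = fit, center = ctr, scale = scl)
      },
      prob = function(model, X) {
        Xs <- scale(X, center = model$center, scale = model$scale)
        as.numeric(predict(model$fit, Xs))
      }),
    logistic = list(
      fit = function(X, y, w, params, seed) {
        df <- as.data.frame(X); df$.y <- y
        suppressWarnings(glm(.y ~ ., data = df, family = binomial(),
                             weights = w))
      },
      prob = function(model, X) {
        as.numeric(predict(model, newdata = as.data.frame(X),
                           type = "response"))
      }),
    svm = list(
      fit = function(X, y, w, params, seed) {
        if (!requireNamespace("e1071", quietly = TRUE)) {
          abort("the 'svm' learner needs the e1071 package")
        }
        set.seed(derive_seed(seed, "svm"))
        e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
                   probability = TRUE, kernel = "radial")
      },
      prob = function(model, X) {
        attr(predict(model, X, probability = TRUE), "probabilities")[, "1"]
      })
  )
}

#' Train the base learners with 5-fold CV hyperparameter selection
#'
#' For each learner, every parameter set in the grid is scored by k-fold
#' out-of-fold ROC-AUC; the best set is kept, its out-of-fold probabilities
#' are retained for the meta-learner (no leakage) and the learner is refitted
#' on the full data.
#'
#' @param X numeric feature matrix (columns in [feature_names()] order for
#'   the default pipeline).
#' @param y 0/1 labels (1 = DNA-backed somatic mutation).
#' @param seed integer seed controlling folds and learner randomness.
#' @param k number of CV folds.
#' @param grids hyperparameter grids, as [default_grids()].
#' @param learners which learners to train.
#' @return list with `learners` (fitted models), `oof` (tibble of
#'   out-of-fold probabilities per learner), `cv` (tibble of per-parameter-set
#'   CV AUCs), `params` (chosen parameter sets), `folds`.
#' @export
train_base_learners <- function(X, y, seed = 1, k = 5,
                                grids = default_grids(),
                                learners = c("rf", "xgb", "mlp")) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) abort("training labels contain a single class")
  if (nrow(X) < 50) abort("need at least 50 training rows")
  defs <- learner_defs()[learners]
  folds <- make_folds(nrow(X), k, seed)
  w <- class_weights(y)
  cv_rows <- list()
  fitted <- list()
  oof <- list()
  chosen <- list()
  for (ln in learners) {
    grid <- grids[[ln]]
    best_auc <- -Inf
    best_oof <- NULL
    best_params <- NULL
    for (gi in seq_along(grid)) {
      params <- grid[[gi]]
      p_oof <- rep(NA_real_, nrow(X))
      for (f in seq_len(k)) {
        tr <- folds != f
        m <- defs[[ln]]$fit(X[tr, , drop = FALSE], y[tr], w[tr], params,
                            derive_seed(seed, paste(ln, gi, f)))
        p_oof[!tr] <- defs[[ln]]$prob(m, X[!tr, , drop = FALSE])
      }
      auc <- roc_auc(y, p_oof)
      cv_rows[[length(cv_rows) + 1]] <- tibble(
        learner = ln, param_set = gi,
        params = paste(names(params), unlist(params), sep = "=",
                       collapse = ","),
        cv_auc = auc)
      if (auc > best_auc) {
        best_auc <- auc; best_oof <- p_oof; best_params <- params
      }
    }
    fitted[[ln]] <- defs[[ln]]$fit(X, y, w, best_params,
                                   derive_seed(seed, paste(ln, "final")))
    oof[[ln]] <- best_oof
    chosen[[ln]] <- best_params
  }
  list(learners = fitted, oof = as_tibble(oof), cv = bind_rows(cv_rows),
       params = chosen, folds = folds)
}

#' Fit the logistic meta-learner on out-of-fold base probabilities
#'
#' @param base output of [train_base_learners()].
#' @param y 0/1 labels used for the base learners.
#' @param feature_manifest feature-column names the model expects at
#'   prediction time.
#' @param seed training seed recorded in the model metadata.
#' @return an `rnasm_stacking` model.
#' @export
train_stacking <- function(base, y, feature_manifest = feature_names(),
                           seed = NA_integer_) {
  oof <- base$oof
  if (any(vapply(oof, function(p) sd(p) == 0, logical(1)))) {
    warn("a base learner produced constant out-of-fold probabilities")
  }
  df <- as.data.frame(oof); df$.y <- as.integer(y)
  meta <- suppressWarnings(glm(.y ~ ., data = df, family = binomial(),
                               weights = class_weights(y)))
  structure(
    list(base = base$learners, meta = meta,
         base_names = names(base$learners),
         features = feature_manifest,
         metadata = list(seed = seed, k = length(unique(base$folds)),
                         params = base$params, cv = base$cv)),
    class = "rnasm_stacking")
}

#' Train the full stacking classifier from a feature table
#'
#' Convenience wrapper: [extract_features()] output in, fitted
#' `rnasm_stacking` out.
#'
#' @param features feature tibble from [extract_features()].
#' @param labels 0/1 vector (1 = DNA-backed).
#' @param seed integer seed.
#' @param ... passed to [train_base_learners()].
#' @return an `rnasm_stacking` model.
#' @export
train_classifier <- function(features, labels, seed = 1, ...) {
  X <- as.matrix(features[, feature_names()])
  base <- train_base_learners(X, labels, seed = seed, ...)
  train_stacking(base, labels, seed = seed)
}

base_probabilities <- function(model, X) {
  defs <- learner_defs()
  out <- lapply(model$base_names, function(ln) {
    defs[[ln]]$prob(model$base[[ln]], X)
  })
  names(out) <- model$base_names
  as_tibble(out)
}

#' Score candidates with a fitted stacking model
#'
#' @param model an `rnasm_stacking`.
#' @param features feature tibble (or numeric matrix) whose feature columns
#'   match the model manifest in order.
#' @param threshold probability cut-off for the positive (DNA-backed) label.
#' @return tibble with `prob_dna` and `label` (1 iff `prob_dna >= threshold`).
#' @export
classify <- function(model, features, threshold = 0.5) {
  stopifnot(inherits(model, "rnasm_stacking"))
  X <- if (is.matrix(features)) features else {
    missing <- setdiff(model$features, names(features))
    if (length(missing) > 0) {
      abort(sprintf("feature column(s) missing or misnamed: %s",
                    paste(missing, collapse = ", ")))
    }
    as.matrix(features[, model$features])
  }
  if (!identical(colnames(X), model$features)) {
    abort(sprintf("feature columns must match the model manifest: %s",
                  paste(model$features, collapse = ", ")))
  }
  bp <- base_probabilities(model, X)
  p <- as.numeric(predict(model$meta, newdata = as.data.frame(bp),
                          type = "response"))
  tibble(prob_dna = p, label = as.integer(p >= threshold))
}

#' @export
print.rnasm_stacking <- function(x, ...) {
  cat("<rnasm_stacking> base learners:",
      paste(x$base_names, collapse = ", "),
      "+ logistic meta-learner\n")
  invisible(x)
}

#' @export
tidy.rnasm_stacking <- function(x, ...) {
  co <- stats::coef(x$meta)
  tibble(term = names(co), estimate = unname(co))
}

#' @export
glance.rnasm_stacking <- function(x, ...) {
  cv <- x$metadata$cv |>
    group_by(.data$learner) |>
    summarise(cv_auc = max(.data$cv_auc), .groups = "drop")
  tidyr::pivot_wider(cv, names_from = "learner", values_from = "cv_auc",
                     names_prefix = "cv_auc_") |>
    mutate(seed = x$metadata$seed, k_folds = x$metadata$k)
}

#' Save / load a fitted stacking model
#'
#' The gradient-boosting booster is stored as its raw byte serialization so a
#' reloaded bundle reproduces probabilities exactly.
#'
#' @param model an `rnasm_stacking`.
#' @param path file path for the bundle.
#' @return `write_model_bundle` returns `path`; `read_model_bundle` the model.
#' @export
write_model_bundle <- function(model, path) {
  stopifnot(inherits(model, "rnasm_stacking"))
  if ("xgb" %in% model$base_names) {
    model$base$xgb <- xgboost::xgb.save.raw(model$base$xgb)
    attr(model$base$xgb, "rnasm_raw_xgb") <- TRUE
  }
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model_bundle
#' @export
read_model_bundle <- function(path) {
  model <- readRDS(path)
  if ("xgb" %in% model$base_names &&
      isTRUE(attr(model$base$xgb, "rnasm_raw_xgb"))) {
    model$base$xgb <- xgboost::xgb.load.raw(model$base$xgb)
  }
  model
}
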