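# Uniform adapter contract for regressors.  An adapter is any list with
# `fit(X, y, hyperparameters, seed) -> handle`,
# `predict(handle, X) -> numeric`, a capability flag
# `internal_uq` in {"none", "tree_variance", "mc_dropout"}, and (when the
# flag is not "none") `uq(handle, X, ...) -> list(prediction, uncertainty)`.
# The five named techniques ship as reference adapters; additional ones
# can be plugged in with register_adapter() (used, e.g., by
# instrumented test adapters).

adapter_registry <- new.env(parent = emptyenv())

#' Register a regressor adapter
#'
#' Extends the ensembling engine with a new modeling technique.  The
#' adapter contract is the unit of extension: anything with a fit and a
#' predict function participates in subsampling, aggregation, and the
#' growth analysis exactly like the built-in techniques.
#'
#' @param technique name under which the adapter is addressed.
#' @param fit function `(X, y, hyperparameters, seed)` returning an
#'   opaque handle.
#' @param predict function `(handle, X)` returning a numeric vector.
#' @param internal_uq capability flag: `"none"`, `"tree_variance"` or
#'   `"mc_dropout"`.
#' @param uq optional function implementing the built-in uncertainty
#'   mechanism, `(handle, X, ...)` returning
#'   `list(prediction, uncertainty)`.
#' @return The technique name, invisibly.
#' @export
register_adapter <- function(technique, fit, predict,
                             internal_uq = c("none", "tree_variance",
                                             "mc_dropout"),
                             uq = NULL) {
  internal_uq <- match.arg(internal_uq)
  assign(technique,
         list(fit = fit, predict = predict, internal_uq = internal_uq,
              uq = uq),
         envir = adapter_registry)
  invisible(technique)
}

get_adapter <- function(technique) {
  if (!exists(technique, envir = adapter_registry, inherits = FALSE)) {
    stopf("unknown modeling technique '%s' (registered: %s)", technique,
          paste(ls(adapter_registry), collapse = ", "))
  }
  get(technique, envir = adapter_registry, inherits = FALSE)
}

#' List registered modeling techniques
#' @return Character vector of technique names.
#' @export
list_adapters <- function() ls(adapter_registry)

#' Specify a regressor
#'
#' Pairs a technique with (default-only) hyperparameters and a seed.  No
#' tuning schedule is attached anywhere in the pipeline: models are
#' compared at their baseline settings.
#'
#' @param technique a registered technique name; built-ins are `"rf"`
#'   (random forest), `"xgb"` (gradient-boosted trees), `"svm"`
#'   (epsilon-regression SVM, RBF kernel), `"snn"` (one hidden layer of
#'   128 ReLU units) and `"dnn"` (hidden layers 256-128-16, 20% dropout).
#' @param hyperparameters named list overriding adapter defaults.
#' @param seed integer seed consumed by stochastic fits.
#' @return A `regressor_spec`.
#' @export
regressor_spec <- function(technique, hyperparameters = list(), seed = 1L) {
  get_adapter(technique)  # validates
  structure(list(technique = technique, hyperparameters = hyperparameters,
                 seed = as.integer(seed)),
            class = "regressor_spec")
}

#' Fit a regressor
#'
#' Dispatches to the registered adapter, records the training-target
#' range (used later by the prediction-outlier filter), and returns an
#' opaque fitted model.  Fits are deterministic given the spec's seed
#' for the rf/xgb/svm adapters; network fits record their seed.
#'
#' @param spec a [regressor_spec()].
#' @param X numeric matrix of training features (rows >= 2).
#' @param y numeric vector of training targets, finite.
#' @return A `fitted_model` with fields `technique`, `y_range`, `p`.
#' @export
fit_model <- function(spec, X, y) {
  stopifnot(inherits(spec, "regressor_spec"))
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stopf("X has %d rows for %d targets",
                                  nrow(X), length(y))
  if (nrow(X) < 2L) stopf("need at least 2 training rows")
  if (any(!is.finite(y))) stopf("non-finite training targets")
  adapter <- get_adapter(spec$technique)
  handle <- tryCatch(
    adapter$fit(X, y, spec$hyperparameters, spec$seed),
    error = function(e) stopf("fit of technique '%s' failed: %s",
                              spec$technique, conditionMessage(e))
  )
  structure(list(handle = handle, technique = spec$technique,
                 y_range = range(y), p = ncol(X), spec = spec),
            class = "fitted_model")
}

#' Predict from a fitted model
#'
#' @param object a `fitted_model` from [fit_model()].
#' @param newdata numeric matrix with the training column count.
#' @param ... unused.
#' @return Numeric vector of length `nrow(newdata)`.
#' @export
predict.fitted_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0L) return(numeric(0))
  if (ncol(newdata) != object$p) {
    stopf("model trained on %d features, newdata has %d",
          object$p, ncol(newdata))
  }
  adapter <- get_adapter(object$technique)
  as.numeric(adapter$predict(object$handle, newdata))
}

#' Built-in random-forest uncertainty (per-tree spread)
#'
#' For a fitted random forest, the prediction is the mean over the
#' individual decision trees and the uncertainty the population standard
#' deviation of the per-tree predictions -- the forest's native
#' uncertainty measure.
#'
#' @param model a `fitted_model` with technique `"rf"`.
#' @param X numeric matrix of compounds to predict.
#' @return List with numeric vectors `prediction` and `uncertainty`
#'   (class `internal_uq_result`).
#' @export
rf_internal_uq <- function(model, X) {
  stopifnot(inherits(model, "fitted_model"))
  adapter <- get_adapter(model$technique)
  if (adapter$internal_uq != "tree_variance") {
    stopf("technique '%s' has no tree-variance uncertainty", model$technique)
  }
  adapter$uq(model$handle, as.matrix(X))
}

#' Monte Carlo dropout uncertainty
#'
#' Predicts every compound `n_passes` times with a different random
#' dropout mask active in every hidden layer; the mean of the passes is
#' the prediction and their population standard deviation the
#' uncertainty.  Reproducible given `seed`.
#'
#' @param model a `fitted_model` whose technique has the `mc_dropout`
#'   capability (`"snn"`, `"dnn"`).
#' @param X numeric matrix of compounds to predict.
#' @param n_passes number of stochastic forward passes (>= 2), default
#'   100.
#' @param dropout_rate dropout probability per hidden unit; defaults to
#'   the rate the network was configured with (0.2).
#' @param seed integer seed for the mask sequence.
#' @return List with `prediction` and `uncertainty` (class
#'   `internal_uq_result`).
#' @export
mc_dropout_uq <- function(model, X, n_passes = 100L, dropout_rate = NULL,
                          seed = 1L) {
  stopifnot(inherits(model, "fitted_model"))
  adapter <- get_adapter(model$technique)
  if (adapter$internal_uq != "mc_dropout") {
    stopf("technique '%s' has no MC-dropout uncertainty", model$technique)
  }
  if (n_passes < 2L) stopf("n_passes must be >= 2 (std undefined otherwise)")
  adapter$uq(model$handle, as.matrix(X), n_passes = as.integer(n_passes),
             dropout_rate = dropout_rate, seed = as.integer(seed))
}

internal_uq_result <- function(prediction, uncertainty) {
  structure(list(prediction = as.numeric(prediction),
                 uncertainty = as.numeric(uncertainty)),
            class = "internal_uq_result")
}

# ---- built-in adapters -----------------------------------------------

register_builtin_adapters <- function() {
  register_adapter(
    "rf",
    fit = function(X, y, hp, seed) {
      with_seed(seed, randomForest::randomForest(
        x = X, y = y,
        ntree = hp$ntree %||% 100L,
        mtry = hp$mtry %||% max(floor(ncol(X) / 3), 1L)
      ))
    },
    predict = function(handle, X) unname(predict(handle, X)),
    internal_uq = "tree_variance",
    uq = function(handle, X, ...) {
      trees <- predict(handle, X, predict.all = TRUE)$individual
      internal_uq_result(rowMeans(trees), apply(trees, 1L, pop_sd))
    }
  )

  register_adapter(
    "xgb",
    fit = function(X, y, hp, seed) {
      params <- list(objective = "reg:squarederror",
                     nthread = 1L, seed = seed,
                     max_depth = hp$max_depth %||% 6L,
                     eta = hp$eta %||% 0.3)
      xgboost::xgb.train(params = params,
                         data = xgboost::xgb.DMatrix(X, label = y),
                         nrounds = hp$nrounds %||% 100L)
    },
    predict = function(handle, X) {
      as.numeric(predict(handle, xgboost::xgb.DMatrix(X)))
    }
  )

  register_adapter(
    "svm",
    fit = function(X, y, hp, seed) {
      # features are scaled by the pipeline; epsilon-SVR, RBF kernel
      e1071::svm(x = X, y = y, scale = FALSE,
                 kernel = hp$kernel %||% "radial",
                 cost = hp$cost %||% 1,
                 epsilon = hp$epsilon %||% 0.1)
    },
    predict = function(handle, X) unname(predict(handle, X))
  )

  mlp_adapter <- function(default_hidden) {
    list(
      fit = function(X, y, hp, seed) {
        mlp_fit(X, y,
                hidden = hp$hidden %||% default_hidden,
                dropout_rate = hp$dropout_rate %||% 0.2,
                epochs = hp$epochs %||% 1000L,
                batch_size = hp$batch_size %||% 32L,
                learning_rate = hp$learning_rate %||% 1e-3,
                seed = seed)
      },
      predict = function(handle, X) mlp_forward(handle, X),
      uq = function(handle, X, n_passes = 100L, dropout_rate = NULL,
                    seed = 1L) {
        rate <- dropout_rate %||% handle$dropout_rate
        if (rate <= 0) {
          pred <- mlp_forward(handle, X)
          return(internal_uq_result(pred, rep(0, length(pred))))
        }
        passes <- vapply(seq_len(n_passes), function(t) {
          mlp_forward(handle, X, dropout_rate = rate,
                      mask_seed = child_seed(seed, t))
        }, numeric(nrow(as.matrix(X))))
        passes <- matrix(passes, nrow = nrow(as.matrix(X)))
        internal_uq_result(rowMeans(passes), apply(passes, 1L, pop_sd))
      }
    )
  }

  snn <- mlp_adapter(c(128L))
  register_adapter("snn", fit = snn$fit, predict = snn$predict,
                   internal_uq = "mc_dropout", uq = snn$uq)
  dnn <- mlp_adapter(c(256L, 128L, 16L))
  register_adapter("dnn", fit = dnn$fit, predict = dnn$predict,
                   internal_uq = "mc_dropout", uq = dnn$uq)
}

.onLoad <- function(libname, pkgname) {
  register_builtin_adapters()
}
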