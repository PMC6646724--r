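## Hyper-parameter dimension helpers. Each dimension is a list
## (type = "real"|"integer", lo, hi, scale = "linear"|"log"). Configurations
## are sampled in the unit hypercube and mapped through these descriptors,
## which is also the space the Gaussian-process surrogate works in.
dim_real <- function(lo, hi, scale = "linear") list(type = "real", lo = lo, hi = hi, scale = scale)
dim_int  <- function(lo, hi, scale = "linear") list(type = "integer", lo = lo, hi = hi, scale = scale)

unit_to_value <- function(d, u) {
  v <- if (d$scale == "log") exp(log(d$lo) + u * (log(d$hi) - log(d$lo)))
       else d$lo + u * (d$hi - d$lo)
  if (d$type == "integer") as.integer(round(v)) else v
}

config_from_unit <- function(space, u) {
  stats::setNames(lapply(seq_along(space),
                         function(j) unit_to_value(space[[j]], u[j])),
                  names(space))
}

subset_design <- function(X, cols) {
  info <- attr(X, "column_info")
  out <- X[, cols, drop = FALSE]
  attr(out, "column_info") <- info[match(cols, info$name), , drop = FALSE]
  out
}

nb_frame <- function(X) {
  info <- attr(X, "column_info")
  df <- as.data.frame(X)
  if (!is.null(info)) {
    for (j in which(info$type == "indicator"))
      df[[j]] <- factor(df[[j]], levels = c(0, 1))
  }
  df
}

#' Registry of the supervised learning techniques
#'
#' Thirteen techniques, each with a documented default hyper-parameter search
#' space (overridable): logistic regression (LR), Gaussian/Bernoulli naive
#' Bayes (NB), elastic net (EN), support vector machines with linear, RBF and
#' polynomial kernels (Platt-scaled probability outputs), k-nearest
#' neighbours, four multi-layer perceptrons (1 or 2 hidden layers, full-batch
#' gradient descent or Adam), random forest, and gradient tree boosting.
#' All emit continuous prediction scores in [0, 1].
#'
#' @param names Optional subset of technique names to return.
#' @return Named list of technique descriptors
#'   (`name`, `space`, `fit(X, y, config)`, `predict(model, X)`).
#' @export
technique_registry <- function(names = NULL) {
  mk_mlp <- function(layers, optimizer) {
    space <- c(
      stats::setNames(rep(list(dim_int(4, 128, "log")), layers),
                      paste0("width", seq_len(layers))),
      list(learning_rate = dim_real(1e-3, 1, "log"),
           l2 = dim_real(1e-6, 1e-1, "log"))
    )
    list(space = space,
         fit = function(X, y, config) {
           hidden <- unlist(config[paste0("width", seq_len(layers))])
           mlp_fit(X, y, hidden = hidden, optimizer = optimizer,
                   learning_rate = config$learning_rate, l2 = config$l2)
         },
         predict = function(model, X) mlp_predict(model, X))
  }
  svm_fit <- function(kernel) function(X, y, config) {
    args <- list(x = X, y = factor(y, levels = c(0, 1)), kernel = kernel,
                 cost = config$cost, probability = TRUE, scale = FALSE)
    if (kernel == "radial") args$gamma <- config$gamma
    if (kernel == "polynomial") { args$degree <- config$degree; args$coef0 <- 1 }
    do.call(e1071::svm, args)
  }
  svm_predict <- function(model, X) {
    pr <- stats::predict(model, X, probability = TRUE)
    attr(pr, "probabilities")[, "1"]
  }
  reg <- list(
    LR = list(space = list(),
      fit = function(X, y, config) {
        d <- data.frame(y = y, X, check.names = FALSE)
        suppressWarnings(stats::glm(y ~ ., data = d, family = stats::binomial()))
      },
      predict = function(model, X) {
        suppressWarnings(stats::predict(model, data.frame(X, check.names = FALSE),
                                        type = "response"))
      }),
    NB = list(space = list(laplace = dim_real(0, 1)),
      fit = function(X, y, config) {
        e1071::naiveBayes(nb_frame(X), factor(y, levels = c(0, 1)),
                          laplace = config$laplace)
      },
      predict = function(model, X) {
        stats::predict(model, nb_frame(X), type = "raw")[, "1"]
      }),
    EN = list(space = list(alpha = dim_real(0, 1),
                           lambda = dim_real(1e-4, 1e2, "log")),
      fit = function(X, y, config) {
        glmnet::glmnet(X, y, family = "binomial", alpha = config$alpha,
                       lambda = config$lambda, standardize = FALSE)
      },
      predict = function(model, X) {
        as.numeric(stats::predict(model, X, type = "response"))
      }),
    `SVM-Linear` = list(space = list(cost = dim_real(1e-3, 1e3, "log")),
      fit = svm_fit("linear"), predict = svm_predict),
    `SVM-RBF` = list(space = list(cost = dim_real(1e-3, 1e3, "log"),
                                  gamma = dim_real(1e-4, 1e1, "log")),
      fit = svm_fit("radial"), predict = svm_predict),
    `SVM-Poly` = list(space = list(cost = dim_real(1e-3, 1e3, "log"),
                                   degree = dim_int(2, 5)),
      fit = svm_fit("polynomial"), predict = svm_predict),
    kNN = list(space = list(k = dim_int(1, 50)),
      fit = function(X, y, config) {
        list(X = X, y = y, k = config$k)
      },
      predict = function(model, X) {
        k <- min(model$k, nrow(model$X))
        pr <- class::knn(model$X, X, factor(model$y, levels = c(0, 1)),
                         k = k, prob = TRUE)
        p <- attr(pr, "prob")
        ifelse(pr == "1", p, 1 - p)
      }),
    `MLP1-Batch` = mk_mlp(1, "batch"),
    `MLP2-Batch` = mk_mlp(2, "batch"),
    `MLP1-Adam` = mk_mlp(1, "adam"),
    `MLP2-Adam` = mk_mlp(2, "adam"),
    RF = list(space = list(ntree = dim_int(100, 1000),
                           mtry_frac = dim_real(0.1, 1)),
      fit = function(X, y, config) {
        mtry <- max(1L, min(ncol(X), as.integer(round(config$mtry_frac * ncol(X)))))
        randomForest::randomForest(X, factor(y, levels = c(0, 1)),
                                   ntree = config$ntree, mtry = mtry)
      },
      predict = function(model, X) {
        stats::predict(model, X, type = "prob")[, "1"]
      }),
    GTB = list(space = list(eta = dim_real(1e-3, 0.3, "log"),
                            max_depth = dim_int(1, 6),
                            nrounds = dim_int(50, 1000)),
      fit = function(X, y, config) {
        dtrain <- xgboost::xgb.DMatrix(unclass(X), label = y, nthread = 1)
        xgboost::xgb.train(params = list(objective = "binary:logistic",
                                         eta = config$eta,
                                         max_depth = config$max_depth,
                                         nthread = 1),
                           data = dtrain, nrounds = config$nrounds,
                           verbose = 0)
      },
      predict = function(model, X) {
        stats::predict(model, xgboost::xgb.DMatrix(unclass(X), nthread = 1))
      })
  )
  for (nm in names(reg)) reg[[nm]]$name <- nm
  if (!is.null(names)) {
    missing <- setdiff(names, base::names(reg))
    if (length(missing)) stop("unknown technique(s): ", paste(missing, collapse = ", "))
    reg <- reg[names]
  }
  reg
}
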