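#' Base-learner specification
#'
#' The ensemble treats its base suitability models as a pluggable registry:
#' every algorithm is fitted through \code{fit_model()} and scored through
#' \code{predict_model()}, returning suitabilities in [0, 1]. The ensemble
#' framework — selection, weighting, combination — is the contribution; the
#' learners themselves are standard.
#'
#' @param algorithm One of \code{"GLM"} (logistic regression with quadratic
#'   terms), \code{"CTA"} (classification tree), \code{"GBM"} (gradient-boosted
#'   trees), \code{"RF"} (random forest), \code{"ANN"} (small feed-forward
#'   network), \code{"SRE"} (rectilinear surface-range envelope) — or any
#'   label registered with a custom \code{fit} function.
#' @param params Named list of hyperparameters overriding the defaults.
#' @param seed Integer seed used when fitting stochastic learners.
#' @return Object of class \code{model_spec}.
#' @export
model_spec <- function(algorithm, params = list(), seed = 1) {
  structure(list(algorithm = algorithm, params = params, seed = seed),
            class = "model_spec")
}

#' Default model registry
#'
#' @param seed Base seed; learner k gets \code{seed + k}.
#' @param algorithms Subset of algorithm labels to include.
#' @return Named list of \code{model_spec}s.
#' @export
model_registry <- function(seed = 1,
                           algorithms = c("GLM", "CTA", "GBM", "RF", "ANN",
                                          "SRE")) {
  specs <- lapply(seq_along(algorithms), function(k)
    model_spec(algorithms[k], seed = seed + k))
  names(specs) <- algorithms
  specs
}

#' Fit one base learner
#'
#' @param spec A \code{model_spec}.
#' @param table Model table with predictor columns and binary \code{pa}.
#' @param variables Predictor column names.
#' @return Fitted member of class \code{sdm_member} (carries the algorithm
#'   label, the fit object and anything needed to predict).
#' @export
fit_model <- function(spec, table, variables) {
  stopifnot(inherits(spec, "model_spec"),
            all(c(variables, "pa") %in% colnames(table)))
  x <- table[, variables, drop = FALSE]
  y <- table$pa
  p <- spec$params
  fit <- withr::with_seed(spec$seed, switch(
    spec$algorithm,
    GLM = {
      trms <- unlist(lapply(variables, function(v)
        c(v, sprintf("I(%s^2)", v))))
      stats::glm(stats::reformulate(trms, response = "pa"),
                 data = cbind(x, pa = y), family = stats::binomial())
    },
    CTA = rpart::rpart(
      stats::reformulate(variables, response = "pa"),
      data = cbind(x, pa = factor(y)), method = "class",
      control = rpart::rpart.control(
        cp = p$cp %||% 0.001, minbucket = p$minbucket %||% 10)),
    GBM = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    eta = p$eta %||% 0.1,
                    max_depth = p$max_depth %||% 3,
                    nthread = 1, seed = spec$seed),
      data = xgboost::xgb.DMatrix(as.matrix(x), label = y, nthread = 1),
      nrounds = p$nrounds %||% 150, verbose = 0),
    RF = ranger::ranger(
      x = x, y = factor(y), probability = TRUE,
      num.trees = p$num.trees %||% 300, seed = spec$seed,
      num.threads = 1),
    ANN = {
      ctr <- lapply(x, function(col) c(mean(col), stats::sd(col)))
      xs <- as.data.frame(mapply(function(col, cs) (col - cs[1]) / cs[2],
                                 x, ctr, SIMPLIFY = FALSE))
      net <- nnet::nnet(xs, y, size = p$size %||% 5,
                        decay = p$decay %||% 0.01,
                        maxit = p$maxit %||% 300, entropy = TRUE,
                        trace = FALSE)
      list(net = net, center = ctr)
    },
    SRE = {
      q <- p$quantile %||% 0.025
      env <- lapply(x[y == 1, , drop = FALSE], stats::quantile,
                    probs = c(q, 1 - q), names = FALSE)
      list(envelope = env)
    },
    stop(sprintf("unknown algorithm '%s'", spec$algorithm), call. = FALSE)
  ))
  structure(list(algorithm = spec$algorithm, fit = fit,
                 variables = variables, seed = spec$seed),
            class = "sdm_member")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict suitability from a fitted member
#'
#' @param member An \code{sdm_member}.
#' @param table data.frame containing the member's predictor columns.
#' @return Numeric suitability scores in [0, 1].
#' @export
predict_model <- function(member, table) {
  stopifnot(inherits(member, "sdm_member"))
  # make sure the learner's S3 predict method is registered even when the
  # member was restored into a fresh session (e.g. via readRDS)
  ns <- switch(member$algorithm, CTA = "rpart", RF = "ranger", ANN = "nnet")
  if (!is.null(ns)) requireNamespace(ns, quietly = TRUE)
  x <- table[, member$variables, drop = FALSE]
  out <- switch(
    member$algorithm,
    GLM = as.numeric(stats::predict(member$fit, newdata = x,
                                    type = "response")),
    CTA = as.numeric(stats::predict(member$fit, newdata = x,
                                    type = "prob")[, "1"]),
    GBM = as.numeric(stats::predict(
      member$fit, xgboost::xgb.DMatrix(as.matrix(x), nthread = 1))),
    RF = as.numeric(stats::predict(member$fit, data = x,
                                   num.threads = 1)$predictions[, "1"]),
    ANN = {
      xs <- as.data.frame(mapply(function(col, cs) (col - cs[1]) / cs[2],
                                 x, member$fit$center, SIMPLIFY = FALSE))
      as.numeric(stats::predict(member$fit$net, newdata = xs))
    },
    SRE = {
      inside <- rep(TRUE, nrow(x))
      for (v in member$variables) {
        e <- member$fit$envelope[[v]]
        inside <- inside & x[[v]] >= e[1] & x[[v]] <= e[2]
      }
      as.numeric(inside)
    },
    stop(sprintf("unknown algorithm '%s'", member$algorithm), call. = FALSE)
  )
  pmin(pmax(out, 0), 1)
}
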