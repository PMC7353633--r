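# One-class classification of genuine milk: KNN, SIMCA and one-class SVM on
# the autoscaled seven-variable space, with thresholds calibrated by repeated
# leave-30%-out cross-validation at a 1% significance level. Scores are
# oriented so that larger = more anomalous; a sample is inside the class when
# its score does not exceed the calibrated threshold.

.svm_gamma_grid <- c(10^(-9:-1), 1)

#' Specify a one-class classifier
#'
#' Hyperparameter grids follow the screening design: KNN neighbour count
#' k in 1..10, SIMCA factor count in 1..7, SVM RBF gamma in
#' \{1e-9, ..., 1e-1, 1\}. Thresholds are calibrated at significance `alpha`
#' from `repetitions` rounds of leave-`holdout_fraction`-out cross-validation.
#'
#' @param kind `"knn"`, `"simca"` or `"svm"`.
#' @param k,n_factors,gamma the hyperparameter for the chosen kind.
#' @param alpha significance level for the classification threshold.
#' @param holdout_fraction fraction held out per cross-validation repetition.
#' @param repetitions number of cross-validation repetitions.
#' @return object of class `occ_spec`.
#' @export
occ_spec <- function(kind, k = 3, n_factors = 3, gamma = 0.1, alpha = 0.01,
                     holdout_fraction = 0.30, repetitions = 100) {
  kind <- match.arg(kind, c("knn", "simca", "svm"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  if (repetitions < 1) stop("repetitions must be >= 1", call. = FALSE)
  if (holdout_fraction <= 0 || holdout_fraction >= 1) {
    stop("holdout_fraction must be in (0,1)", call. = FALSE)
  }
  if (kind == "knn" && !(k %in% 1:10)) stop("k must be in 1..10", call. = FALSE)
  if (kind == "simca" && !(n_factors %in% 1:7)) {
    stop("n_factors must be in 1..7", call. = FALSE)
  }
  if (kind == "svm" && !any(abs(log10(gamma) - log10(.svm_gamma_grid)) < 1e-9)) {
    stop("gamma must be one of 1e-9..1e-1, 1", call. = FALSE)
  }
  structure(list(kind = kind, k = k, n_factors = n_factors, gamma = gamma,
                 alpha = alpha, holdout_fraction = holdout_fraction,
                 repetitions = repetitions),
            class = "occ_spec")
}

.spec_param <- function(spec) {
  switch(spec$kind, knn = spec$k, simca = spec$n_factors, svm = spec$gamma)
}

#' Autoscaling: fit and apply
#'
#' Per-variable centring to mean 0 and scaling to SD 1 using training-set
#' statistics. Test data are always scaled with the training parameters,
#' never re-centred.
#'
#' @param train composition table (training set).
#' @return `autoscale_fit`: list with `center` and `scale` named vectors;
#'   `autoscale_apply`: numeric matrix (rows = samples, columns =
#'   [composition_vars]).
#' @export
autoscale_fit <- function(train) {
  center <- vapply(composition_vars, function(v) mean(train[[v]]), 0)
  scale <- vapply(composition_vars, function(v) stats::sd(train[[v]]), 0)
  if (any(scale <= 0)) {
    stop("zero-SD column in training data: autoscaling undefined", call. = FALSE)
  }
  list(center = center, scale = scale)
}

#' @rdname autoscale_fit
#' @param scaling result of `autoscale_fit`.
#' @param table composition table to transform.
#' @export
autoscale_apply <- function(scaling, table) {
  m <- as.matrix(table[, composition_vars, drop = FALSE])
  scale(m, center = scaling$center[composition_vars],
        scale = scaling$scale[composition_vars])[, , drop = FALSE]
}

# ---- classifier internals (operate on autoscaled matrices) ----

.fit_state <- function(spec, X) {
  switch(spec$kind,
    knn = {
      if (spec$k > nrow(X)) stop("k exceeds training size", call. = FALSE)
      list(train = X, k = spec$k)
    },
    simca = {
      Xc <- scale(X, center = TRUE, scale = FALSE)
      sv <- svd(Xc)
      rank <- sum(sv$d > max(sv$d) * 1e-10)
      if (spec$n_factors > rank) {
        stop("n_factors exceeds the rank of the training data", call. = FALSE)
      }
      a <- spec$n_factors
      V <- sv$v[, seq_len(a), drop = FALSE]
      scores <- Xc %*% V
      lambda <- sv$d[seq_len(a)]^2 / (nrow(X) - 1)
      # training distances, used to normalize both components
      T2 <- rowSums(sweep(scores^2, 2, lambda, "/"))
      resid <- Xc - scores %*% t(V)
      od <- sqrt(rowSums(resid^2))
      sd_dist <- sqrt(T2)
      list(center = attr(Xc, "scaled:center"), V = V, lambda = lambda,
           od_mean = mean(od), sd_mean = mean(sd_dist))
    },
    svm = {
      fit <- e1071::svm(x = X, type = "one-classification", kernel = "radial",
                        gamma = spec$gamma, nu = spec$alpha, scale = FALSE)
      list(svm = fit)
    }
  )
}

.score_state <- function(spec, state, X) {
  switch(spec$kind,
    knn = {
      Tm <- state$train
      d2 <- outer(rowSums(X^2), rowSums(Tm^2), "+") - 2 * X %*% t(Tm)
      d2[d2 < 0] <- 0
      apply(sqrt(d2), 1, function(dd) mean(sort(dd)[seq_len(state$k)]))
    },
    simca = {
      Xc <- sweep(X, 2, state$center)
      scores <- Xc %*% state$V
      T2 <- rowSums(sweep(scores^2, 2, state$lambda, "/"))
      resid <- Xc - scores %*% t(state$V)
      od <- sqrt(rowSums(resid^2))
      sd_dist <- sqrt(T2)
      od_n <- if (state$od_mean > 1e-10) od / state$od_mean else 0 * od
      sd_n <- if (state$sd_mean > 1e-10) sd_dist / state$sd_mean else 0 * sd_dist
      sqrt(od_n^2 + sd_n^2)
    },
    svm = {
      dv <- attr(stats::predict(state$svm, X, decision.values = TRUE),
                 "decision.values")
      -as.numeric(dv)
    }
  )
}

.holdout_size <- function(n, fraction) {
  max(1L, as.integer(floor(fraction * n + 0.5)))
}

#' Calibrate a one-class classifier by repeated cross-validation
#'
#' Per repetition, a random `holdout_fraction` share of the training samples
#' (round-half-up) is held out, the classifier is fitted (with autoscaling
#' refitted) on the remainder, and the held-out genuine samples are scored.
#' The classification threshold is the (1 - alpha) empirical quantile of the
#' pooled held-out scores, so at alpha = 0.01 at least 99\% of the pooled
#' cross-validation scores fall within it by construction. The returned model
#' is refitted on the full training set with full-data autoscaling.
#'
#' @param spec an [occ_spec].
#' @param train composition table of genuine samples (>= 5 rows).
#' @param seed integer seed; calibration is deterministic given the seed.
#' @return object of class `occ_model`: `spec`, `scaling`, fitted `state`,
#'   `threshold`, `cv_accuracy` (\% of pooled held-out scores within the
#'   threshold) and the pooled `cv_scores`.
#' @export
calibrate_threshold <- function(spec, train, seed) {
  stopifnot(inherits(spec, "occ_spec"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  n <- nrow(train)
  if (n < 5) stop("need at least 5 training samples", call. = FALSE)
  m <- .holdout_size(n, spec$holdout_fraction)

  cv_scores <- withr::with_seed(seed, {
    unlist(lapply(seq_len(spec$repetitions), function(r) {
      hold <- sample.int(n, m)
      tr <- train[-hold, , drop = FALSE]
      sc <- autoscale_fit(tr)
      st <- .fit_state(spec, autoscale_apply(sc, tr))
      .score_state(spec, st, autoscale_apply(sc, train[hold, , drop = FALSE]))
    }))
  })
  threshold <- stats::quantile(cv_scores, 1 - spec$alpha, names = FALSE, type = 7)

  scaling <- autoscale_fit(train)
  state <- .fit_state(spec, autoscale_apply(scaling, train))
  structure(list(spec = spec, scaling = scaling, state = state,
                 threshold = threshold,
                 cv_accuracy = 100 * mean(cv_scores <= threshold),
                 cv_scores = cv_scores),
            class = "occ_model")
}

#' @export
print.occ_model <- function(x, ...) {
  cat(sprintf("One-class %s model (%s = %s): threshold %.4f, CV accuracy %.1f%%\n",
              toupper(x$spec$kind),
              switch(x$spec$kind, knn = "k", simca = "n_factors", svm = "gamma"),
              format(.spec_param(x$spec)), x$threshold, x$cv_accuracy))
  invisible(x)
}

#' Score and classify new samples with a fitted one-class model
#'
#' @param object an `occ_model` from [calibrate_threshold].
#' @param newdata composition table.
#' @param ... unused.
#' @return data.frame with `sample_id`, `score` (larger = more anomalous) and
#'   logical `inside`.
#' @export
predict.occ_model <- function(object, newdata, ...) {
  if (nrow(newdata) == 0L) stop("empty test set", call. = FALSE)
  sc <- .score_state(object$spec, object$state,
                     autoscale_apply(object$scaling, newdata))
  ids <- if ("sample_id" %in% names(newdata)) {
    as.character(newdata$sample_id)
  } else {
    as.character(seq_len(nrow(newdata)))
  }
  data.frame(sample_id = ids, score = as.numeric(sc),
             inside = as.numeric(sc) <= object$threshold,
             stringsAsFactors = FALSE)
}

#' Evaluate a fitted model on a test table
#'
#' Percentage of records scoring within the threshold (assigned to the
#' genuine class). For adulterated test sets the complement is the
#' specificity: the share correctly flagged outside.
#'
#' @param model an `occ_model`.
#' @param table composition table (non-empty).
#' @param by optional column name to compute per-group percentages (e.g.
#'   adulterant `category`).
#' @return list with `pct_inside`, `pct_outside`, and when `by` is given a
#'   data.frame `per_group` of group-wise percentages.
#' @export
evaluate_occ <- function(model, table, by = NULL) {
  pr <- predict(model, table)
  out <- list(pct_inside = 100 * mean(pr$inside),
              pct_outside = 100 * mean(!pr$inside))
  if (!is.null(by)) {
    g <- table[[by]]
    agg <- stats::aggregate(pr$inside, list(group = g),
                            function(z) 100 * mean(!z))
    names(agg)[2] <- "pct_flagged"
    out$per_group <- agg
  }
  out
}

#' Evaluate a hyperparameter grid for one classifier kind
#'
#' Fits and calibrates every grid value, scores the adulterant test set, and
#' reports the cross-validation accuracy, the adulterant percentage correctly
#' assigned (flagged outside), and their average -- the overall-performance
#' measure used for model selection.
#'
#' @param kind classifier kind.
#' @param train genuine training table.
#' @param adulterated adulterant test table.
#' @param seed integer seed (each grid point derives its own sub-seed).
#' @param alpha,holdout_fraction,repetitions calibration settings.
#' @return list with `results` (data.frame `kind`, `param`, `cv_pct`,
#'   `adulterant_pct`, `overall`) and `models` (list of `occ_model`s).
#' @export
occ_grid <- function(kind, train, adulterated, seed, alpha = 0.01,
                     holdout_fraction = 0.30, repetitions = 100) {
  params <- switch(kind, knn = 1:10, simca = 1:7, svm = .svm_gamma_grid)
  models <- vector("list", length(params))
  rows <- lapply(seq_along(params), function(i) {
    spec <- switch(kind,
      knn = occ_spec("knn", k = params[i], alpha = alpha,
                     holdout_fraction = holdout_fraction,
                     repetitions = repetitions),
      simca = occ_spec("simca", n_factors = params[i], alpha = alpha,
                       holdout_fraction = holdout_fraction,
                       repetitions = repetitions),
      svm = occ_spec("svm", gamma = params[i], alpha = alpha,
                     holdout_fraction = holdout_fraction,
                     repetitions = repetitions)
    )
    model <- calibrate_threshold(spec, train, seed = seed + i)
    models[[i]] <<- model
    ev <- evaluate_occ(model, adulterated)
    data.frame(kind = kind, param = params[i], cv_pct = model$cv_accuracy,
               adulterant_pct = ev$pct_outside,
               overall = (model$cv_accuracy + ev$pct_outside) / 2,
               stringsAsFactors = FALSE)
  })
  list(results = do.call(rbind, rows), models = models)
}

#' Select the best hyperparameter per classifier kind
#'
#' Argmax of the overall performance (mean of the cross-validation and
#' adulterant percentages); ties broken in favour of the simpler model
#' (smaller k, fewer factors, smaller gamma).
#'
#' @param results data.frame as produced by [occ_grid] (possibly rbind-ed
#'   over kinds), columns `kind`, `param`, `cv_pct`, `adulterant_pct`.
#' @return data.frame with one row per kind: the selected `param` and its
#'   performance figures.
#' @export
select_model <- function(results) {
  if (is.null(results) || nrow(results) == 0L) stop("empty grid", call. = FALSE)
  if (!"overall" %in% names(results)) {
    results$overall <- (results$cv_pct + results$adulterant_pct) / 2
  }
  picked <- lapply(split(results, results$kind), function(d) {
    d <- d[order(-d$overall, d$param), ]
    d[1, ]
  })
  out <- do.call(rbind, picked)
  rownames(out) <- NULL
  out
}

#' Serialize a fitted one-class model to JSON
#'
#' Stores the spec, autoscaling parameters, threshold and a flattened model
#' state. SVM models store the support vectors and coefficients needed to
#' re-evaluate the decision function.
#'
#' @param model an `occ_model`.
#' @param path optional file path.
#' @return JSON string (invisibly when written).
#' @export
occ_to_json <- function(model, path = NULL) {
  st <- model$state
  state_obj <- switch(model$spec$kind,
    knn = list(train = unclass(st$train), k = st$k),
    simca = list(center = st$center, V = st$V, lambda = st$lambda,
                 od_mean = st$od_mean, sd_mean = st$sd_mean),
    svm = list(SV = unclass(st$svm$SV), coefs = as.numeric(st$svm$coefs),
               rho = st$svm$rho, gamma = model$spec$gamma)
  )
  obj <- list(spec = unclass(model$spec), scaling = model$scaling,
              threshold = model$threshold, cv_accuracy = model$cv_accuracy,
              state = state_obj)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
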