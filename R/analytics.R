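# Analytics: Spearman screening, VIF multicollinearity filter, split +
# standardize, linear-kernel epsilon-SVR with cross-validated grid search,
# evaluation, 0-100 importance scaling, and closed-form Shapley attribution.

#' Analytics configuration
#'
#' @param train_fraction fraction of rows in the training split (default
#'   0.85; the training count is `round(n * fraction)` half-up).
#' @param cv_folds number of cross-validation folds (>= 2; default 5).
#' @param split_seed seed for the train/test split and fold assignment.
#' @param grid_C,grid_epsilon hyperparameter grid for the SVR: `C > 0`
#'   regularization costs and `epsilon >= 0` tube widths.
#' @param vif_threshold features with a variance inflation factor above this
#'   are removed (default 10).
#' @param significance_alpha features whose Spearman p-value exceeds this are
#'   dropped at screening (default 0.05).
#' @return An object of class `analytics_config`.
#' @export
analytics_config <- function(train_fraction = 0.85, cv_folds = 5,
                             split_seed = 1,
                             grid_C = c(0.25, 0.5, 1, 2, 4),
                             grid_epsilon = c(0.01, 0.1, 0.2, 0.5),
                             vif_threshold = 10, significance_alpha = 0.05) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  if (cv_folds < 2) stop("cv_folds must be >= 2", call. = FALSE)
  if (any(grid_C <= 0) || any(grid_epsilon < 0)) {
    stop("grid requires C > 0 and epsilon >= 0", call. = FALSE)
  }
  structure(list(train_fraction = train_fraction, cv_folds = as.integer(cv_folds),
                 split_seed = as.integer(split_seed), grid_C = grid_C,
                 grid_epsilon = grid_epsilon, vif_threshold = vif_threshold,
                 significance_alpha = significance_alpha),
            class = "analytics_config")
}

#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of midranks; the p-value comes from the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` with `n - 2`
#' degrees of freedom (two-sided).
#'
#' @param x,y numeric vectors of equal length `>= 3`; ties get midranks.
#' @return A list with `rho` and `p_value`.
#' @export
spearman <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  if (var(x) == 0 || var(y) == 0) {
    stop("Spearman correlation is undefined for a constant vector",
         call. = FALSE)
  }
  rho <- cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p_value = p)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` is from the least-squares
#' regression of feature `j` on all other features plus an intercept.
#' Exactly collinear features get `VIF = Inf` and are never retained.
#'
#' @param table data.frame containing the feature columns.
#' @param features character vector of `>= 2` feature names.
#' @param threshold retention threshold (features with `vif <= threshold`
#'   are retained, input order preserved).
#' @return A list with named numeric `vif` and character `retained`.
#' @export
compute_vif <- function(table, features, threshold = 10) {
  p <- length(features)
  if (p < 2) stop("VIF needs at least 2 features", call. = FALSE)
  if (nrow(table) <= p + 1) {
    stop("VIF needs more rows than features + 1", call. = FALSE)
  }
  X <- as.matrix(table[, features, drop = FALSE])
  vif <- setNames(numeric(p), features)
  for (j in seq_len(p)) {
    fit <- lm(X[, j] ~ X[, -j, drop = FALSE])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    vif[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  list(vif = vif, retained = apply_vif_threshold(vif, threshold))
}

#' Apply a VIF retention threshold
#'
#' @param vifs named numeric vector of VIF values.
#' @param threshold features with `vif <= threshold` are retained, in input
#'   order.
#' @return Character vector of retained feature names.
#' @export
apply_vif_threshold <- function(vifs, threshold = 10) {
  names(vifs)[!is.na(vifs) & vifs <= threshold]
}

#' Split a table and standardize features on training statistics
#'
#' Rows are split at random (seeded) into a training portion of size
#' `round(n * train_fraction)` (half-up) and a test remainder. Features are
#' centred/scaled using the training mean and SD only; the outcome is left
#' on its natural scale so predictions stay in percent units.
#'
#' @param table tract data.frame.
#' @param outcome outcome column name.
#' @param features feature column names.
#' @param config an [analytics_config()].
#' @return List with matrices `X_train`, `X_test`, vectors `y_train`,
#'   `y_test`, integer `train_idx`, and `scaling` (a list of per-feature
#'   `mean` and `sd` computed on the training portion).
#' @export
split_standardize <- function(table, outcome, features, config = analytics_config()) {
  n <- nrow(table)
  n_train <- floor(n * config$train_fraction + 0.5)
  if (n_train >= n) stop("test split is empty", call. = FALSE)
  if (n_train < 2) stop("training split too small", call. = FALSE)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$split_seed)
  train_idx <- sort(sample.int(n, n_train))
  X <- as.matrix(table[, features, drop = FALSE])
  mu <- colMeans(X[train_idx, , drop = FALSE])
  sdev <- apply(X[train_idx, , drop = FALSE], 2, sd)
  if (any(sdev <= 0)) {
    stop("feature constant on the training split: ",
         features[which(sdev <= 0)[1]], call. = FALSE)
  }
  Xs <- sweep(sweep(X, 2, mu, `-`), 2, sdev, `/`)
  list(X_train = Xs[train_idx, , drop = FALSE],
       X_test = Xs[-train_idx, , drop = FALSE],
       y_train = table[[outcome]][train_idx],
       y_test = table[[outcome]][-train_idx],
       train_idx = train_idx,
       scaling = list(mean = mu, sd = sdev))
}

#' Fit a linear-kernel epsilon-insensitive support vector regression
#'
#' Minimizes `0.5 * ||w||^2 + C * sum(max(0, |y - w.x - b| - epsilon))`. The
#' optimization is delegated to the libsvm solver (via e1071) with a tight
#' convergence tolerance; the degenerate zero-loss case (outcome range within
#' the epsilon tube) is solved directly as `w = 0`, `b` = midrange.
#'
#' @param X numeric matrix of (standardized) features.
#' @param y numeric outcome vector.
#' @param C cost parameter (> 0).
#' @param epsilon tube half-width (>= 0).
#' @param scaling optional per-feature training `mean`/`sd` list recorded on
#'   the model for later unstandardized use.
#' @return An object of class `svr_model` with `weights` (named, in
#'   standardized space), `intercept`, `C`, `epsilon`, `scaling_stats`.
#' @export
fit_svr_linear <- function(X, y, C, epsilon, scaling = NULL) {
  X <- as.matrix(X)
  if (C <= 0) stop("C must be > 0", call. = FALSE)
  if (diff(range(y)) <= 2 * epsilon) {
    w <- setNames(numeric(ncol(X)), colnames(X))
    b <- mean(range(y))
  } else {
    fit <- e1071::svm(X, y, type = "eps-regression", kernel = "linear",
                      cost = C, epsilon = epsilon, scale = FALSE,
                      tolerance = 1e-6, fitted = FALSE)
    # SV keeps all p columns, so this is the full weight vector in column order
    w <- setNames(as.numeric(t(fit$coefs) %*% fit$SV), colnames(X))
    b <- -fit$rho
  }
  structure(list(weights = w, intercept = b, C = C, epsilon = epsilon,
                 scaling_stats = scaling), class = "svr_model")
}

#' @export
predict.svr_model <- function(object, newdata, standardized = TRUE, ...) {
  X <- as.matrix(newdata)
  if (!standardized) {
    if (is.null(object$scaling_stats)) {
      stop("model carries no scaling statistics", call. = FALSE)
    }
    X <- sweep(sweep(X[, names(object$weights), drop = FALSE], 2,
                     object$scaling_stats$mean[names(object$weights)], `-`),
               2, object$scaling_stats$sd[names(object$weights)], `/`)
  }
  drop(X %*% object$weights) + object$intercept
}

#' @export
coef.svr_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$weights)
}

#' @export
print.svr_model <- function(x, ...) {
  cat("<svr_model> linear kernel, C =", x$C, ", epsilon =", x$epsilon, "\n")
  print(coef(x))
  invisible(x)
}

# SVR primal objective (used by tests against an independent dual solve).
svr_objective <- function(model, X, y) {
  res <- abs(y - predict(model, X)) - model$epsilon
  0.5 * sum(model$weights^2) + model$C * sum(pmax(0, res))
}

# Seeded fold assignment: shuffle indices, contiguous blocks, remainder rows
# distributed one per leading fold.
.cv_folds <- function(n, k, seed) {
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  idx <- sample.int(n)
  base <- n %/% k
  extra <- n %% k
  sizes <- rep(base, k) + c(rep(1, extra), rep(0, k - extra))
  split(idx, rep(seq_len(k), times = sizes))
}

#' Cross-validated grid search for the SVR hyperparameters
#'
#' For every `(C, epsilon)` grid point, computes the mean RMSE over seeded
#' contiguous-after-shuffle folds and returns the point with minimal mean CV
#' RMSE; ties break toward smaller `C`, then smaller `epsilon`.
#'
#' @param X,y training matrix and outcome.
#' @param config an [analytics_config()] providing the grid, fold count and
#'   seed.
#' @return List with `best` (named vector `C`, `epsilon`) and `cv_table`
#'   (data.frame of `C`, `epsilon`, `mean_rmse`).
#' @export
grid_search_cv <- function(X, y, config = analytics_config()) {
  n <- nrow(X)
  folds <- .cv_folds(n, config$cv_folds, config$split_seed)
  if (any(vapply(folds, length, 0L) < 2)) {
    stop("a cross-validation fold has fewer than 2 observations", call. = FALSE)
  }
  grid <- expand.grid(C = config$grid_C, epsilon = config$grid_epsilon,
                      KEEP.OUT.ATTRS = FALSE)
  if (!nrow(grid)) stop("hyperparameter grid is empty", call. = FALSE)
  grid$mean_rmse <- vapply(seq_len(nrow(grid)), function(g) {
    rmses <- vapply(folds, function(hold) {
      fit <- fit_svr_linear(X[-hold, , drop = FALSE], y[-hold],
                            grid$C[g], grid$epsilon[g])
      pred <- predict(fit, X[hold, , drop = FALSE])
      sqrt(mean((y[hold] - pred)^2))
    }, 0)
    mean(rmses)
  }, 0)
  ord <- order(grid$mean_rmse, grid$C, grid$epsilon)
  best <- grid[ord[1], ]
  list(best = c(C = best$C, epsilon = best$epsilon), cv_table = grid)
}

#' Evaluate predictions by RMSE and R-squared
#'
#' `RMSE = sqrt(mean((y - yhat)^2))`;
#' `R^2 = 1 - SS_res / SS_tot` with `SS_tot` about the sample mean of `y`.
#'
#' @param model an `svr_model`.
#' @param X feature matrix (standardized space).
#' @param y observed outcome.
#' @return List with `rmse` and `r2`.
#' @export
evaluate <- function(model, X, y) {
  if (var(y) == 0) stop("R-squared is undefined for zero-variance y", call. = FALSE)
  pred <- predict(model, X)
  rmse <- sqrt(mean((y - pred)^2))
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  list(rmse = rmse, r2 = r2)
}

#' Feature importance on a 0-100 scale
#'
#' Raw importance is the absolute standardized coefficient `|w_j|` of the
#' linear-kernel model; scaled importance is min-max rescaled so the largest
#' is exactly 100 and the smallest exactly 0. If all raw importances are
#' equal the scaled values are all 0 (with a warning).
#'
#' @param model an `svr_model` fitted on standardized features.
#' @return data.frame with `feature`, `raw`, `scaled`.
#' @export
importance <- function(model) {
  raw <- abs(model$weights)
  spread <- max(raw) - min(raw)
  if (spread == 0) {
    warning("all feature importances are equal; scaled importances set to 0")
    scaled <- rep(0, length(raw))
  } else {
    scaled <- 100 * ((raw - min(raw)) / spread) # ratio first: extremes exact
  }
  data.frame(feature = names(raw), raw = as.numeric(raw),
             scaled = as.numeric(scaled), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Closed-form Shapley attribution for a linear model
#'
#' For a linear model with an interventional (independent-feature) value
#' function, the Shapley value of feature `j` at instance `x` is
#' `phi_j = w'_j * (x_j - mean(background_j))`, where `w'_j` is the model
#' weight expressed in unstandardized units. Efficiency
#' (`sum(phi) = f(x) - f(background mean)`) holds exactly.
#'
#' @param model an `svr_model` with scaling statistics.
#' @param instance named numeric vector or one-row data.frame in the natural
#'   (unstandardized) feature space.
#' @param background data.frame of background rows in the same space.
#' @return List with `phi` (named numeric), `baseline_prediction`,
#'   `instance_prediction`.
#' @export
shapley_linear <- function(model, instance, background) {
  feats <- names(model$weights)
  if (is.data.frame(instance)) instance <- unlist(instance[1, , drop = TRUE])
  missing <- setdiff(feats, names(instance))
  if (length(missing)) {
    stop("instance is missing feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- as.numeric(instance[feats])
  bg_mean <- colMeans(as.matrix(background[, feats, drop = FALSE]))
  w_unstd <- model$weights / model$scaling_stats$sd[feats]
  phi <- setNames(w_unstd * (x - bg_mean), feats)
  baseline <- predict(model, matrix(bg_mean, 1, dimnames = list(NULL, feats)),
                      standardized = FALSE)
  list(phi = phi, baseline_prediction = unname(baseline),
       instance_prediction = unname(baseline + sum(phi)))
}

#' Run the full analytics pipeline
#'
#' Executes, in order: Spearman screening (features whose correlation with
#' the outcome has `p > significance_alpha` are dropped), VIF filtering,
#' seeded train/test split with training-set standardization, grid-search
#' cross-validation, a final fit on the full training portion, train/test
#' evaluation, 0-100 importance scaling, and (when `focus_geoid` is given)
#' Shapley attribution of the focus tract against the full table as
#' background.
#'
#' @param table tract data.frame (see [generate_tracts()] / [read_tracts()]).
#' @param outcome outcome column name (default `"obesity_prev"`).
#' @param features candidate feature names (default: all known features
#'   present in the table).
#' @param focus_geoid optional geoid of the neighborhood to attribute.
#' @param config an [analytics_config()].
#' @return An object of class `upho_analytics`; see [print.upho_analytics()],
#'   [coef.upho_analytics()], [predict.upho_analytics()],
#'   [plot.upho_analytics()].
#' @examples
#' tab <- generate_tracts(generator_config(n_tracts = 120, seed = 7))
#' fit <- run_analytics(tab, config = analytics_config(split_seed = 7))
#' fit
#' @export
run_analytics <- function(table, outcome = "obesity_prev",
                          features = intersect(tract_features(), names(table)),
                          focus_geoid = NULL, config = analytics_config()) {
  validate_tracts(table)
  if (!outcome %in% names(table)) {
    stop("outcome column not found: ", outcome, call. = FALSE)
  }

  screen <- lapply(features, function(f) spearman(table[[f]], table[[outcome]]))
  correlations <- data.frame(
    feature = features,
    rho = vapply(screen, `[[`, 0, "rho"),
    p_value = vapply(screen, `[[`, 0, "p_value"),
    stringsAsFactors = FALSE)
  correlations$kept <- correlations$p_value <= config$significance_alpha
  screened <- correlations$feature[correlations$kept]
  if (length(screened) < 2) {
    stop("fewer than 2 features survive Spearman screening", call. = FALSE)
  }

  vif <- compute_vif(table, screened, config$vif_threshold)
  retained <- vif$retained
  if (length(retained) < 2) {
    stop("fewer than 2 features survive the VIF filter", call. = FALSE)
  }

  split <- split_standardize(table, outcome, retained, config)
  gs <- grid_search_cv(split$X_train, split$y_train, config)
  model <- fit_svr_linear(split$X_train, split$y_train,
                          gs$best[["C"]], gs$best[["epsilon"]],
                          scaling = split$scaling)
  eval_train <- evaluate(model, split$X_train, split$y_train)
  eval_test <- evaluate(model, split$X_test, split$y_test)
  imp <- importance(model)

  attribution <- NULL
  if (!is.null(focus_geoid)) {
    i <- match(focus_geoid, table$geoid)
    if (is.na(i)) stop("focus geoid not present in table: ", focus_geoid,
                       call. = FALSE)
    sh <- shapley_linear(model, table[i, retained, drop = FALSE], table)
    attribution <- c(list(geoid = focus_geoid), sh)
  }

  structure(list(
    outcome = outcome, features = features, correlations = correlations,
    screened_features = screened, vif = vif$vif, retained_features = retained,
    split = list(train_idx = split$train_idx,
                 n_train = length(split$train_idx),
                 n_test = nrow(table) - length(split$train_idx)),
    cv = gs, model = model,
    evaluation = list(rmse_train = eval_train$rmse, rmse_test = eval_test$rmse,
                      r2_train = eval_train$r2, r2_test = eval_test$r2),
    importance = imp, attribution = attribution, config = config
  ), class = "upho_analytics")
}

#' @describeIn run_analytics Compact display of the fitted pipeline.
#' @param x,object an `upho_analytics` object.
#' @param ... unused.
#' @export
print.upho_analytics <- function(x, ...) {
  cat("Explainable SVR analytics over", length(x$retained_features),
      "retained features\n")
  cat(sprintf("  split: %d train / %d test; best C = %g, epsilon = %g\n",
              x$split$n_train, x$split$n_test,
              x$cv$best[["C"]], x$cv$best[["epsilon"]]))
  cat(sprintf("  RMSE train/test: %.3f / %.3f;  R2 train/test: %.3f / %.3f\n",
              x$evaluation$rmse_train, x$evaluation$rmse_test,
              x$evaluation$r2_train, x$evaluation$r2_test))
  imp <- x$importance[order(-x$importance$scaled), ]
  cat("  importance (0-100):",
      paste(sprintf("%s=%.1f", imp$feature, imp$scaled), collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn run_analytics Fuller summary: correlations, VIFs, CV table.
#' @export
summary.upho_analytics <- function(object, ...) {
  structure(list(fit = object), class = "summary.upho_analytics")
}

#' @export
print.summary.upho_analytics <- function(x, ...) {
  print(x$fit)
  cat("\nSpearman screening:\n")
  print(x$fit$correlations, digits = 3)
  cat("\nVariance inflation factors (threshold ",
      x$fit$config$vif_threshold, "):\n", sep = "")
  print(round(x$fit$vif, 2))
  cat("\nCross-validation (mean RMSE by grid point):\n")
  print(x$fit$cv$cv_table, digits = 4)
  invisible(x)
}

#' @describeIn run_analytics Standardized model coefficients.
#' @export
coef.upho_analytics <- function(object, ...) coef(object$model)

#' @describeIn run_analytics Predict outcome (percent units) for new tracts
#'   on the natural feature scale.
#' @param newdata data.frame with the retained feature columns.
#' @export
predict.upho_analytics <- function(object, newdata, ...) {
  predict(object$model, newdata[, object$retained_features, drop = FALSE],
          standardized = FALSE)
}

#' @describeIn run_analytics Barplot of scaled importances (and, when an
#'   attribution is present, per-feature Shapley contributions).
#' @param which `"importance"` or `"attribution"`.
#' @export
plot.upho_analytics <- function(x, which = c("importance", "attribution"), ...) {
  which <- match.arg(which)
  if (which == "importance") {
    imp <- x$importance[order(x$importance$scaled), ]
    graphics::barplot(imp$scaled, names.arg = imp$feature, horiz = TRUE,
                      las = 1, xlab = "scaled importance (0-100)", ...)
  } else {
    if (is.null(x$attribution)) stop("no attribution in this fit", call. = FALSE)
    phi <- sort(x$attribution$phi)
    graphics::barplot(phi, names.arg = names(phi), horiz = TRUE, las = 1,
                      xlab = "Shapley contribution (percent outcome units)", ...)
  }
  invisible(x)
}

#' Serialize an analytics result bundle to JSON
#'
#' Single JSON document with correlations, VIFs, hyperparameters, evaluation,
#' importance and the optional attribution; consumed by the graph builder and
#' the report driver.
#'
#' @param res an `upho_analytics` object.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
analytics_to_json <- function(res, path) {
  vif <- res$vif
  vif[!is.finite(vif)] <- NA # JSON has no Inf; NA encodes removal-by-collinearity
  out <- list(
    outcome = res$outcome,
    correlations = res$correlations,
    vif = as.list(vif),
    retained_features = res$retained_features,
    split = res$split[c("n_train", "n_test")],
    hyperparameters = list(C = unname(res$cv$best[["C"]]),
                           epsilon = unname(res$cv$best[["epsilon"]])),
    coefficients = as.list(coef(res$model)),
    evaluation = res$evaluation,
    importance = res$importance,
    attribution = if (is.null(res$attribution)) NULL else list(
      geoid = res$attribution$geoid,
      phi = as.list(res$attribution$phi),
      baseline_prediction = res$attribution$baseline_prediction,
      instance_prediction = res$attribution$instance_prediction)
  )
  jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}
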