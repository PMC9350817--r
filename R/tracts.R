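# Synthetic census-tract tables: generator, validation, CSV round-trip.

# Registry of the tract-level variables the pipeline knows about: the outcome
# (crude obesity prevalence) plus eight SDoH/behavioural features. Marginal
# means/SDs are the published Memphis summary statistics the generator
# reproduces by default; `rho` is the default target Spearman correlation of
# each feature with the outcome. `measures` links a feature's metric concept
# to the risk-factor/characteristic concept it quantifies (NA where the
# concept scheme has no such concept).
.upho_variables <- data.frame(
  feature = c("obesity_prev", "lack_physical_activity", "poverty",
              "no_hs_diploma", "pct_black", "unemployment", "lack_insurance",
              "low_access_supermarket", "crime_rate"),
  metric = c("HIO:%ObesityPrevalence", "HIO:%PopWLackOfPhysicalActivity",
             "HIO:%UnderPovertyLine", "HIO:%PopNoHighSchoolDiploma",
             "HIO:%BlackPopulation", "HIO:%Unemployment",
             "HIO:%NoHealthInsurance", "HIO:LowAccessToSupermarket",
             "HIO:CrimeRate"),
  label = c("obesity prevalence", "lack of physical activity",
            "population below the poverty line",
            "population without a high-school diploma", "Black population",
            "unemployed population", "population lacking health insurance",
            "low-income population with low supermarket access",
            "crime rate per 1000 people"),
  kind = c("percent", "percent", "percent", "percent", "percent", "percent",
           "percent", "count", "rate"),
  measures = c(NA, "COPE:LackOfPhysicalActivity", "COPE:Poverty",
               "COPE:LowEducation", NA, "COPE:Unemployment", NA,
               "COPE:FoodDesert", NA),
  mean = c(37.50, 36.16, 28.65, 10.38, 63.17, 15.73, 20.21, 1382.20, 350.20),
  sd = c(7.84, 9.80, 16.28, 6.59, 32.70, 9.31, 6.78, 108.37, 126.26),
  rho = c(NA, 0.92, 0.83, 0.81, 0.77, 0.73, 0.60, 0.37, 0.37),
  stringsAsFactors = FALSE
)

#' Names of the tract features known to the pipeline
#'
#' @return Character vector of the eight SDoH/behavioural feature names
#'   (the outcome column `obesity_prev` is not included).
#' @export
tract_features <- function() {
  .upho_variables$feature[.upho_variables$feature != "obesity_prev"]
}

# Internal lookup: rows of the variable registry for given feature names.
.var_info <- function(features) {
  i <- match(features, .upho_variables$feature)
  if (anyNA(i)) {
    stop("unknown tract variable(s): ",
         paste(features[is.na(i)], collapse = ", "), call. = FALSE)
  }
  .upho_variables[i, , drop = FALSE]
}

# Spearman target -> latent Pearson correlation under a Gaussian copula.
.latent_r <- function(rho_s) 2 * sin(pi * rho_s / 6)

#' Configuration for the synthetic tract-table generator
#'
#' Builds a fully resolved generator configuration. Defaults reproduce the
#' marginal means/SDs of the Memphis census-tract summary table and target
#' the published Spearman correlations between each SDoH feature and obesity
#' prevalence. Feature-feature dependence follows a single-factor Gaussian
#' copula (latent loadings equal to the latent transforms of the
#' feature-outcome targets), which is always positive semi-definite.
#'
#' When `outcome_weights` is `NULL`, the weights, intercept and noise SD are
#' derived in closed form so that the linear outcome model reproduces the
#' configured feature-outcome rank correlations: in latent standardized space
#' `w = R^{-1} r` and `noise_sd = sqrt(1 - r' R^{-1} r)`, where `R` is the
#' latent feature correlation matrix and `r` the latent feature-outcome
#' correlations. If you supply `outcome_weights` yourself, also supply
#' `outcome_noise_sd` (it defaults to 0) and `outcome_intercept` (defaults to
#' centring the outcome at `outcome_mean`).
#'
#' @param n_tracts number of tracts to generate (>= 2).
#' @param seed integer RNG seed; a fixed seed gives a byte-identical table.
#' @param marginal_means,marginal_sds named numeric vectors over the features
#'   in [tract_features()]; defaults are the published summary statistics.
#' @param rank_correlations named numeric vector of target Spearman
#'   correlations between each feature and the outcome, in `[-1, 1]`.
#' @param outcome_weights optional named numeric vector of linear-model
#'   weights on the natural (percent/count) feature scale.
#' @param outcome_intercept optional intercept of the outcome model.
#' @param outcome_noise_sd optional Gaussian noise SD of the outcome model.
#' @param outcome_mean,outcome_sd target mean/SD of the outcome margin used
#'   when deriving default weights.
#' @return An object of class `tract_generator_config`.
#' @seealso [generate_tracts()]
#' @export
generator_config <- function(n_tracts = 178, seed = 1,
                             marginal_means = NULL, marginal_sds = NULL,
                             rank_correlations = NULL,
                             outcome_weights = NULL,
                             outcome_intercept = NULL,
                             outcome_noise_sd = NULL,
                             outcome_mean = 37.50, outcome_sd = 7.84) {
  feats <- tract_features()
  info <- .var_info(feats)
  means <- setNames(info$mean, feats)
  sds <- setNames(info$sd, feats)
  rhos <- setNames(info$rho, feats)
  if (!is.null(marginal_means)) means[names(marginal_means)] <- marginal_means
  if (!is.null(marginal_sds)) sds[names(marginal_sds)] <- marginal_sds
  if (!is.null(rank_correlations)) rhos[names(rank_correlations)] <- rank_correlations

  if (!is.numeric(n_tracts) || length(n_tracts) != 1 || n_tracts < 2) {
    stop("n_tracts must be a single integer >= 2", call. = FALSE)
  }
  if (any(sds <= 0) || outcome_sd <= 0) {
    stop("marginal SDs must be strictly positive", call. = FALSE)
  }
  if (any(abs(rhos) > 1)) {
    stop("rank-correlation targets must lie in [-1, 1]", call. = FALSE)
  }

  r <- .latent_r(rhos)                       # latent loadings
  R <- tcrossprod(r) ; diag(R) <- 1          # one-factor latent correlation

  if (is.null(outcome_weights)) {
    w_std <- drop(solve(R, r))
    resid_var <- 1 - sum(r * w_std)
    if (resid_var < -1e-8) {
      stop("rank-correlation targets are jointly infeasible ",
           "(latent correlation matrix not positive definite)", call. = FALSE)
    }
    resid_var <- max(resid_var, 0)
    outcome_weights <- setNames(outcome_sd * w_std / sds, feats)
    if (is.null(outcome_noise_sd)) outcome_noise_sd <- outcome_sd * sqrt(resid_var)
  } else {
    w <- setNames(numeric(length(feats)), feats)
    w[names(outcome_weights)] <- outcome_weights
    outcome_weights <- w
    if (is.null(outcome_noise_sd)) outcome_noise_sd <- 0
  }
  if (is.null(outcome_intercept)) {
    outcome_intercept <- outcome_mean - sum(outcome_weights * means)
  }
  if (outcome_noise_sd < 0) stop("outcome_noise_sd must be >= 0", call. = FALSE)

  structure(list(
    n_tracts = as.integer(n_tracts), seed = as.integer(seed),
    features = feats, marginal_means = means, marginal_sds = sds,
    rank_correlations = rhos, latent_correlation = R,
    outcome_weights = outcome_weights, outcome_intercept = outcome_intercept,
    outcome_noise_sd = outcome_noise_sd,
    outcome_mean = outcome_mean, outcome_sd = outcome_sd
  ), class = "tract_generator_config")
}

# Cholesky factor with nearest-positive-definite repair. Errors if the
# repair moves the matrix by more than `tol` in max-abs terms.
.chol_repaired <- function(R, tol = 0.1) {
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  fixed <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
  if (max(abs(fixed - R)) > tol) {
    stop("latent correlation target is not positive definite and lies ",
         "beyond the repair tolerance", call. = FALSE)
  }
  chol(fixed)
}

#' Generate a synthetic census-tract table
#'
#' Draws a latent multivariate Gaussian with the configured one-factor
#' correlation structure, rescales each margin to its target mean/SD, clips
#' to the field's valid range (percents to `[0, 100]`, counts/rates to
#' `>= 0`), then sets the outcome as
#' `intercept + sum(outcome_weights * features) + N(0, outcome_noise_sd)`,
#' clipped to `[0, 100]`. Clipping happens after noise addition, so extreme
#' margins are slightly biased toward the interior; rank-correlation targets
#' are imposed on the latent Gaussian and are therefore approximate at the
#' clipped margins.
#'
#' Tract GEOIDs are synthesized as the Shelby County, TN prefix `47157`
#' followed by a six-digit tract sequence.
#'
#' @param config a [generator_config()] object.
#' @return A `data.frame` with character column `geoid`, numeric outcome
#'   column `obesity_prev`, and one numeric column per feature. Deterministic
#'   for a fixed `config$seed`.
#' @examples
#' tab <- generate_tracts(generator_config(n_tracts = 20, seed = 42))
#' summary(tab$obesity_prev)
#' @export
generate_tracts <- function(config = generator_config()) {
  if (!inherits(config, "tract_generator_config")) {
    stop("config must be created by generator_config()", call. = FALSE)
  }
  n <- config$n_tracts
  feats <- config$features
  p <- length(feats)
  if (n > 999999) stop("at most 999999 tracts fit the county geoid scheme",
                       call. = FALSE)

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  ch <- .chol_repaired(config$latent_correlation)
  Z <- matrix(rnorm(n * p), n, p) %*% ch
  colnames(Z) <- feats

  X <- sweep(sweep(Z, 2, config$marginal_sds[feats], `*`), 2,
             config$marginal_means[feats], `+`)
  info <- .var_info(feats)
  for (j in seq_len(p)) {
    X[, j] <- if (info$kind[j] == "percent") pmin(pmax(X[, j], 0), 100)
              else pmax(X[, j], 0)
  }

  y <- config$outcome_intercept + drop(X %*% config$outcome_weights[feats]) +
    rnorm(n, 0, config$outcome_noise_sd)
  y <- pmin(pmax(y, 0), 100)

  out <- data.frame(
    geoid = sprintf("47157%06d", seq_len(n)),
    obesity_prev = y, X, stringsAsFactors = FALSE, check.names = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Validate a tract table against the record invariants
#'
#' Checks that `geoid` is an 11-digit string unique within the table, percent
#' fields lie in `[0, 100]`, and count/rate fields are non-negative. Errors
#' name the first offending row.
#'
#' @param table a tract `data.frame` with a `geoid` column.
#' @return The table, invisibly, if valid.
#' @export
validate_tracts <- function(table) {
  if (!"geoid" %in% names(table)) {
    stop("tract table is missing the geoid column", call. = FALSE)
  }
  g <- as.character(table$geoid)
  bad <- which(!grepl("^[0-9]{11}$", g))
  if (length(bad)) {
    stop(sprintf("row %d: geoid '%s' is not an 11-digit tract FIPS code",
                 bad[1], g[bad[1]]), call. = FALSE)
  }
  dup <- which(duplicated(g))
  if (length(dup)) {
    stop(sprintf("row %d: duplicate geoid '%s'", dup[1], g[dup[1]]),
         call. = FALSE)
  }
  known <- intersect(names(table), .upho_variables$feature)
  info <- .var_info(known)
  for (k in seq_along(known)) {
    v <- table[[known[k]]]
    if (!is.numeric(v)) {
      stop(sprintf("column %s must be numeric", known[k]), call. = FALSE)
    }
    bad <- if (info$kind[k] == "percent") which(v < 0 | v > 100) else which(v < 0)
    if (length(bad)) {
      stop(sprintf("row %d: %s value %g outside its valid range",
                   bad[1], known[k], v[bad[1]]), call. = FALSE)
    }
  }
  invisible(table)
}

#' Read a census-tract table from CSV
#'
#' @param path CSV file with a header row.
#' @param column_map optional named character vector renaming source columns
#'   to tract-record fields: names are source column names, values are the
#'   target field names (e.g. `c(TractFIPS = "geoid", OBESITY = "obesity_prev")`).
#' @return A validated tract `data.frame` (`geoid` kept as character to
#'   preserve leading zeros).
#' @export
read_tracts <- function(path, column_map = NULL) {
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  if (!is.null(column_map)) {
    i <- match(names(column_map), names(raw))
    if (anyNA(i)) {
      stop("column_map names absent from file: ",
           paste(names(column_map)[is.na(i)], collapse = ", "), call. = FALSE)
    }
    names(raw)[i] <- unname(column_map)
  }
  if (!"geoid" %in% names(raw)) {
    stop("tract table is missing the geoid column", call. = FALSE)
  }
  keep <- c("geoid", intersect(.upho_variables$feature, names(raw)))
  out <- raw[, keep, drop = FALSE]
  for (nm in setdiff(keep, "geoid")) out[[nm]] <- as.numeric(out[[nm]])
  validate_tracts(out)
  out
}

#' Write a census-tract table to CSV
#'
#' UTF-8 CSV with a header row; the `geoid` column is quoted so leading
#' zeros survive spreadsheet round-trips.
#'
#' @param table a tract `data.frame`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tracts <- function(table, path) {
  validate_tracts(table)
  write.csv(table, path, row.names = FALSE, quote = which(names(table) == "geoid"),
            fileEncoding = "UTF-8")
  invisible(path)
}
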