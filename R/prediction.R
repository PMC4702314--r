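#' Train an RR-BLUP ridge prediction equation
#'
#' Marker columns are centered by their training means and effects
#' solve the ridge problem `min ||y - 1*mu - X*beta||^2 + lambda*||beta||^2`
#' with `lambda = m * (1 - h2) / h2` (m markers) unless overridden. The
#' system is solved in the dual (n x n) when n < m, and in the primal
#' otherwise; the two are algebraically identical.
#'
#' @param genotypes a `genotype_matrix` or a plain dosage matrix.
#' @param phenotypes numeric phenotype vector, aligned 1:1 with the
#'   genotype rows (the genotype belongs to the parent seed; the
#'   phenotype to its testcross).
#' @param h2 heritability used for the shrinkage rule.
#' @param lambda optional explicit shrinkage; `lambda = 0` gives OLS
#'   (only sensible when n > m and the design has full rank).
#' @param training_id label stamped on the equation (e.g. "discovery").
#' @return an object of class `prediction_equation` with `intercept`,
#'   `effects`, `centers`, `lambda`, `markers`, and `training_id`.
#' @export
train_ridge <- function(genotypes, phenotypes, h2, lambda = NULL,
                        training_id = "discovery") {
  X <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosage else genotypes
  markers <- if (inherits(genotypes, "genotype_matrix")) genotypes$markers else NULL
  y <- as.numeric(phenotypes)
  n <- nrow(X)
  m <- ncol(X)
  if (n != length(y)) stop("genotype rows and phenotypes are misaligned")
  if (n < 2) stop("at least two training records are required")
  if (is.null(lambda)) {
    if (h2 <= 0 || h2 > 1) stop("h2 must be in (0, 1]")
    lambda <- m * (1 - h2) / h2
  }
  centers <- colMeans(X)
  Xc <- sweep(X, 2, centers)
  mu <- mean(y)
  yc <- y - mu
  if (var(y) == 0) {
    beta <- numeric(m)
  } else if (n < m) {
    K <- tcrossprod(Xc)
    alpha <- solve(K + diag(lambda, n), yc)
    beta <- as.numeric(crossprod(Xc, alpha))
  } else {
    G <- crossprod(Xc)
    beta <- as.numeric(solve(G + diag(lambda, m), crossprod(Xc, yc)))
  }
  structure(list(intercept = mu, effects = beta, centers = centers,
                 lambda = lambda, markers = markers,
                 training_id = training_id),
            class = "prediction_equation")
}

#' Predict estimated breeding values
#'
#' `EBV = intercept + (X - centers) %*% effects`; deterministic given
#' the equation and genotypes.
#'
#' @param eq a `prediction_equation`.
#' @param genotypes a `genotype_matrix` or dosage matrix with columns
#'   matching the equation's markers.
#' @return numeric vector of EBVs.
#' @export
predict_ebv <- function(eq, genotypes) {
  X <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosage else genotypes
  if (ncol(X) != length(eq$effects)) stop("marker panels do not match")
  as.numeric(eq$intercept + sweep(X, 2, eq$centers) %*% eq$effects)
}

#' Retrain the prediction equation on one improvement cycle
#'
#' Fits the same ridge estimator on the cycle's synthetic-seed
#' genotypes and testcross phenotypes only (discovery data excluded).
#' With zero phenotypes no update happens and a `no_update` sentinel is
#' returned, so the previous equation persists. The cycle lag (an
#' updated equation is usable only in the next cycle) is enforced by
#' the breeding program, not here.
#'
#' @param cycle_genotypes genotypes of the phenotyped synthetic seeds.
#' @param cycle_phenotypes their testcross phenotypes.
#' @param h2 heritability for the shrinkage rule.
#' @param cycle cycle label stamped on the equation.
#' @return a `prediction_equation`, or a `no_update` sentinel when
#'   there are no phenotypes.
#' @export
retrain_on_cycle <- function(cycle_genotypes, cycle_phenotypes, h2,
                             cycle = "C1") {
  if (length(cycle_phenotypes) == 0) {
    return(structure(list(), class = "no_update"))
  }
  train_ridge(cycle_genotypes, cycle_phenotypes, h2,
              training_id = paste0("cycle_", cycle))
}

#' Serialize a prediction equation to JSON
#'
#' @param eq a `prediction_equation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_equation <- function(eq, path) {
  jsonlite::write_json(unclass(eq), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_equation
#' @export
read_equation <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$effects <- as.numeric(x$effects)
  x$centers <- as.numeric(x$centers)
  structure(x, class = "prediction_equation")
}
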