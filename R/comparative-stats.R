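#' Phylogenetic covariance matrix from a tree
#'
#' The species-by-species matrix of shared branch lengths: under Brownian
#' motion, Cov(y_i, y_j) is proportional to the depth of the most recent
#' common ancestor of tips i and j. On an ultrametric tree the diagonal is
#' constant (the root-to-tip depth).
#'
#' @param tree a rooted \code{phylo} with branch lengths.
#' @return symmetric positive-definite matrix with tip labels as dimnames.
#' @export
phyloCovariance <- function(tree) {
  checkPhylogeny(tree)
  ape::vcv(tree)
}

#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies the off-diagonal entries of C by lambda, leaving the diagonal
#' untouched. lambda = 1 returns the Brownian expectation, lambda = 0 a star
#' phylogeny (independent species); intermediate values measure the strength
#' of phylogenetic signal in the residuals. On an ultrametric tree the result
#' stays positive definite for lambda in \[0, 1\].
#'
#' @param C base covariance matrix from [phyloCovariance()].
#' @param lambda signal strength in \[0, 1\].
#' @return the rescaled matrix V(lambda).
#' @export
pagelTransform <- function(C, lambda) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  if (length(lambda) != 1L || is.na(lambda) || lambda < 0 || lambda > 1) {
    stop("lambda must be a single value in [0, 1]")
  }
  d <- diag(C)
  V <- C * lambda
  diag(V) <- d
  V
}

#' Generalized least squares with a fixed covariance matrix
#'
#' Fits y = X beta + e, e ~ N(0, sigma2 V), by whitening with the Cholesky
#' factor of V (no explicit inversion). Returns the ML variance estimate
#' (residual quadratic form / n) and the Gaussian log-likelihood, plus the
#' usual degrees-of-freedom-corrected coefficient standard errors.
#'
#' @param y response vector (species means), aligned with rows of V.
#' @param X design matrix with intercept; rows aligned with y.
#' @param V covariance matrix (SPD).
#' @return list with \code{beta}, \code{se}, \code{sigma2_ml},
#'   \code{sigma2_resid} (RSS/(n-p)), \code{loglik}, \code{rss_white},
#'   \code{n}, \code{p}, \code{XtViX_inv}.
#' @export
glsFit <- function(y, X, V) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(V) == n, ncol(V) == n)
  L <- tryCatch(chol(V), error = function(e) stop("V is not positive definite"))
  # whiten: solve t(L) z = y  (V = t(L) %*% L)
  yw <- backsolve(L, y, transpose = TRUE)
  Xw <- backsolve(L, X, transpose = TRUE)
  qrX <- qr(Xw)
  if (qrX$rank < ncol(X)) stop("design matrix is singular (single-level factor?)")
  beta <- qr.coef(qrX, yw)
  resid_w <- yw - Xw %*% beta
  rss <- sum(resid_w^2)
  p <- ncol(X)
  sigma2_ml <- rss / n
  sigma2_resid <- rss / (n - p)
  R <- qr.R(qrX)
  XtViX_inv <- chol2inv(R)
  dimnames(XtViX_inv) <- list(colnames(X), colnames(X))
  se <- sqrt(sigma2_resid * diag(XtViX_inv))
  logdetV <- 2 * sum(log(diag(L)))
  loglik <- -0.5 * (n * log(2 * pi) + n * log(sigma2_ml) + logdetV + n)
  list(beta = stats::setNames(as.numeric(beta), colnames(X)),
       se = stats::setNames(se, colnames(X)),
       sigma2_ml = sigma2_ml, sigma2_resid = sigma2_resid,
       loglik = loglik, rss_white = rss, n = n, p = p,
       XtViX_inv = XtViX_inv)
}

#' Phylogenetic GLS of a species trait on domestication status
#'
#' Fits trait ~ status by generalized least squares with residual covariance
#' V(lambda), profiling the Gaussian likelihood over Pagel's lambda in
#' \[0, 1\] (Brent-style bounded optimization, tolerance 1e-6, with both
#' endpoints evaluated as well). The crop-versus-progenitor contrast is the
#' coefficient of status; for traits analysed on the log scale the effect
#' back-transforms to a crop:progenitor ratio with a Wald confidence interval
#' exponentiated from the log scale. The F statistic is the squared t of the
#' contrast on (1, n - 2) degrees of freedom.
#'
#' @param y species trait means on the analysis scale, named by species or
#'   aligned with \code{status}.
#' @param status factor/character of \code{"crop"}/\code{"progenitor"} per
#'   species; progenitor is the reference level.
#' @param tree phylogeny covering the species, or a precomputed base
#'   covariance matrix. Rows are aligned by species names when both sides
#'   carry them.
#' @param species optional species labels (needed when \code{y} is unnamed
#'   and \code{tree} is a tree).
#' @param log_scale is \code{y} on the natural-log scale? Governs the ratio
#'   back-transform. Default \code{TRUE}.
#' @param tol optimizer tolerance on lambda.
#' @return object of class \code{pgls_fit}: the status effect \code{beta}
#'   with \code{se} and \code{ci95}, \code{lambda}, \code{sigma2} (ML),
#'   \code{F}, \code{df}, \code{p}, \code{ratio} and \code{ratio_ci95} (log
#'   traits), \code{intercept} (progenitor mean), \code{loglik},
#'   \code{lambda_flat} flag, \code{n}.
#' @export
pglsML <- function(y, status, tree, species = NULL, log_scale = TRUE,
                   tol = 1e-6) {
  if (inherits(tree, "phylo")) C <- phyloCovariance(tree) else C <- as.matrix(tree)
  if (is.null(species)) {
    species <- if (!is.null(names(y))) names(y) else rownames(C)[seq_along(y)]
  }
  keep <- !is.na(y)
  y <- y[keep]; status <- status[keep]; species <- species[keep]
  if (!all(species %in% rownames(C))) {
    stop("species absent from the phylogenetic covariance: ",
         paste(setdiff(species, rownames(C)), collapse = ", "))
  }
  C <- C[species, species]
  status <- factor(as.character(status), levels = c("progenitor", "crop"))
  if (nlevels(droplevels(status)) < 2L) stop("need both crop and progenitor species")
  X <- stats::model.matrix(~ status)
  colnames(X) <- c("(Intercept)", "statuscrop")
  n <- length(y)

  prof <- function(lambda) glsFit(y, X, pagelTransform(C, lambda))$loglik
  opt <- stats::optimize(prof, interval = c(0, 1), maximum = TRUE, tol = tol)
  cand <- rbind(c(0, prof(0)), c(opt$maximum, opt$objective), c(1, prof(1)))
  lambda_hat <- cand[which.max(cand[, 2]), 1]
  ll_range <- diff(range(cand[, 2]))
  lambda_flat <- ll_range < 1e-8

  fit <- glsFit(y, X, pagelTransform(C, lambda_hat))
  beta <- fit$beta[["statuscrop"]]
  se <- fit$se[["statuscrop"]]
  df2 <- n - 2L
  tq <- stats::qt(0.975, df2)
  ci <- beta + c(-1, 1) * tq * se
  Fstat <- (beta / se)^2
  pval <- stats::pf(Fstat, 1, df2, lower.tail = FALSE)
  out <- list(beta = beta, se = se, ci95 = ci,
              lambda = lambda_hat, lambda_flat = lambda_flat,
              sigma2 = fit$sigma2_ml, loglik = max(cand[, 2]),
              F = Fstat, df = c(1L, df2), p = pval,
              intercept = fit$beta[["(Intercept)"]],
              log_scale = log_scale, n = n)
  if (log_scale) {
    out$ratio <- exp(beta)
    out$ratio_ci95 <- exp(ci)
  }
  class(out) <- "pgls_fit"
  out
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("PGLS crop-vs-progenitor contrast (n = %d species)\n", x$n))
  cat(sprintf("  effect = %.4f (SE %.4f), 95%% CI [%.4f, %.4f]\n",
              x$beta, x$se, x$ci95[1], x$ci95[2]))
  if (isTRUE(x$log_scale)) {
    cat(sprintf("  crop:progenitor ratio = %.2f, 95%% CI [%.2f, %.2f]\n",
                x$ratio, x$ratio_ci95[1], x$ratio_ci95[2]))
  }
  cat(sprintf("  Pagel's lambda (ML) = %.3f%s, F(%d,%d) = %.2f, p = %.4g\n",
              x$lambda, if (x$lambda_flat) " [flat likelihood]" else "",
              x$df[1], x$df[2], x$F, x$p))
  invisible(x)
}

#' PGLS contrasts for the full trait table
#'
#' Runs [pglsML()] on every trait of a species-mean table, on the scale given
#' by [traitTransforms()], and assembles the results into one row per trait:
#' effect, ratio (log traits) or absolute difference plus percent of the
#' progenitor mean (untransformed traits), confidence interval, lambda, F,
#' degrees of freedom and p. Traits carried only by one family (the
#' per-infructescence counts exist for cereals) are fitted on that family's
#' species subset.
#'
#' @param means species-mean table from [speciesMeans()].
#' @param tree phylogeny covering the species.
#' @param traits optional subset of trait column names to analyse.
#' @return data frame, one row per trait.
#' @export
pglsTable <- function(means, tree, traits = NULL) {
  C <- phyloCovariance(tree)
  trait_cols <- setdiff(names(means), c("species", "status", "family", "n_plants"))
  if (!is.null(traits)) trait_cols <- intersect(trait_cols, traits)
  rows <- lapply(trait_cols, function(tc) {
    y <- means[[tc]]
    ok <- !is.na(y)
    if (sum(ok) < 4L) return(NULL)
    log_scale <- startsWith(tc, "ln_")
    fit <- tryCatch(
      pglsML(y[ok], means$status[ok], C, species = means$species[ok],
             log_scale = log_scale),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    prog_mean <- fit$intercept
    data.frame(
      trait = tc,
      n_species = fit$n,
      effect = fit$beta, se = fit$se,
      ci_lo = fit$ci95[1], ci_hi = fit$ci95[2],
      ratio = if (log_scale) fit$ratio else NA_real_,
      ratio_lo = if (log_scale) fit$ratio_ci95[1] else NA_real_,
      ratio_hi = if (log_scale) fit$ratio_ci95[2] else NA_real_,
      pct_of_progenitor = if (!log_scale && prog_mean != 0) {
        -100 * fit$beta / prog_mean
      } else NA_real_,
      lambda = fit$lambda, lambda_flat = fit$lambda_flat,
      F = fit$F, df1 = fit$df[1], df2 = fit$df[2], p = fit$p,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Phylogenetically controlled correlation between two species traits
#'
#' GLS slope fit of one trait on another under the ML-lambda covariance, with
#' R-squared computed as the squared correlation of the V-whitened variables
#' (equivalently, of the whitened fitted and observed responses).
#'
#' @param y,x species trait vectors on their analysis scales.
#' @param tree phylogeny or base covariance matrix.
#' @param species species labels aligned with \code{y} and \code{x}.
#' @return list with \code{slope}, \code{se}, \code{r_squared},
#'   \code{lambda}, \code{F}, \code{df}, \code{p}.
#' @export
pglsCorrelation <- function(y, x, tree, species = NULL) {
  if (inherits(tree, "phylo")) C <- phyloCovariance(tree) else C <- as.matrix(tree)
  if (is.null(species)) species <- names(y)
  ok <- !is.na(y) & !is.na(x)
  y <- y[ok]; x <- x[ok]; species <- species[ok]
  C <- C[species, species]
  X <- cbind("(Intercept)" = 1, x = x)
  prof <- function(l) glsFit(y, X, pagelTransform(C, l))$loglik
  opt <- stats::optimize(prof, c(0, 1), maximum = TRUE, tol = 1e-6)
  cand <- rbind(c(0, prof(0)), c(opt$maximum, opt$objective), c(1, prof(1)))
  lambda_hat <- cand[which.max(cand[, 2]), 1]
  V <- pagelTransform(C, lambda_hat)
  fit <- glsFit(y, X, V)
  L <- chol(V)
  yw <- backsolve(L, y, transpose = TRUE)
  xw <- backsolve(L, x, transpose = TRUE)
  # squared correlation of the whitened variables, centred with GLS weights
  onew <- backsolve(L, rep(1, length(y)), transpose = TRUE)
  proj <- function(v) v - onew * sum(onew * v) / sum(onew^2)
  r2 <- stats::cor(proj(yw), proj(xw))^2
  n <- length(y)
  tstat <- fit$beta[["x"]] / fit$se[["x"]]
  list(slope = fit$beta[["x"]], se = fit$se[["x"]], r_squared = r2,
       lambda = lambda_hat, F = tstat^2, df = c(1L, n - 2L),
       p = stats::pf(tstat^2, 1, n - 2, lower.tail = FALSE))
}
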