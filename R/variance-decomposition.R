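#' Analytic gradient of yield with respect to its components
#'
#' Partial derivatives of Y evaluated at a component mean vector, used by the
#' first-order (delta-method) variance decomposition. For the
#' growth/allocation decomposition, with Y = Ms exp(lambda d) Ar (1 - c):
#' dY/dMs = Y/Ms, dY/dlambda = Y d, dY/dd = Y lambda, dY/dAr = Y/Ar,
#' dY/dc = -Y/(1 - c). For the packaging decomposition Y = Ms Ns Ni the
#' partials are the complementary products; the two-trait pulse variant
#' Y = Ms N has gradient (N, Ms).
#'
#' @param theta named numeric vector of component means. Decomposition 1
#'   requires \code{Ms}, \code{lambda}, \code{d}, \code{Ar}, \code{c};
#'   decomposition 2 requires \code{Ms}, \code{Ns}, \code{Ni} or \code{Ms},
#'   \code{N}.
#' @param decomposition 1 (growth/allocation) or 2 (packaging).
#' @return named numeric gradient vector in the order of \code{theta}, with
#'   attribute \code{"Y"} holding yield at \code{theta}.
#' @export
yieldGradient <- function(theta, decomposition = 1) {
  decomposition <- match.arg(as.character(decomposition), c("1", "2"))
  theta <- unlist(theta)
  if (decomposition == "1") {
    need <- c("Ms", "lambda", "d", "Ar", "c")
    if (!all(need %in% names(theta))) {
      stop("decomposition 1 needs components: ", paste(need, collapse = ", "))
    }
    th <- theta[need]
    if (th["Ms"] <= 0) stop("Ms must be positive")
    if (th["Ar"] <= 0 || th["Ar"] > 1) stop("Ar must lie in (0, 1]")
    if (th["c"] < 0 || th["c"] >= 1) {
      stop("c must lie in [0, 1): gradient is singular at c = 1")
    }
    y <- unname(th["Ms"] * exp(th["lambda"] * th["d"]) * th["Ar"] * (1 - th["c"]))
    g <- c(Ms = y / th[["Ms"]],
           lambda = y * th[["d"]],
           d = y * th[["lambda"]],
           Ar = y / th[["Ar"]],
           c = -y / (1 - th[["c"]]))
  } else {
    if (all(c("Ms", "Ns", "Ni") %in% names(theta))) {
      th <- theta[c("Ms", "Ns", "Ni")]
      y <- unname(th["Ms"] * th["Ns"] * th["Ni"])
      g <- c(Ms = th[["Ns"]] * th[["Ni"]],
             Ns = th[["Ms"]] * th[["Ni"]],
             Ni = th[["Ms"]] * th[["Ns"]])
    } else if (all(c("Ms", "N") %in% names(theta))) {
      th <- theta[c("Ms", "N")]
      y <- unname(th["Ms"] * th["N"])
      g <- c(Ms = th[["N"]], N = th[["Ms"]])
    } else {
      stop("decomposition 2 needs components Ms, Ns, Ni (cereals) or Ms, N")
    }
    if (th["Ms"] <= 0) stop("Ms must be positive")
  }
  attr(g, "Y") <- y
  g
}

#' Delta-method contribution matrix for the variance in yield
#'
#' Approximates Var(Y) to first order as sum_ij Cov(theta_i, theta_j) g_i g_j,
#' with g the analytic gradient of Y at the sample mean of the components and
#' Cov the sample covariance (n - 1 denominator) over analysis units (species
#' means by default; any row set works). The terms define a square
#' contribution matrix; each trait's contribution to the variance is its row
#' sum divided by the grand total, so the shares sum to one by construction
#' and can be negative when a trait covaries negatively with others.
#'
#' @param theta matrix or data frame of component values, one row per analysis
#'   unit, columns named as in [yieldGradient()].
#' @param decomposition 1 or 2.
#' @return object of class \code{contribution_table}: list with the
#'   contribution matrix \code{C}, per-trait \code{shares}, \code{total}
#'   (delta-method Var(Y)), the gradient, the mean vector, and \code{n}.
#' @export
contributionTable <- function(theta, decomposition = 1) {
  theta <- as.matrix(as.data.frame(theta))
  if (anyNA(theta)) stop("theta sample contains missing values")
  if (nrow(theta) < 3L) stop("need at least 3 analysis units, got ", nrow(theta))
  mu <- colMeans(theta)
  g <- yieldGradient(mu, decomposition)
  attr(g, "Y") <- NULL
  theta <- theta[, names(g), drop = FALSE]
  S <- stats::cov(theta)
  C <- S * tcrossprod(g)
  total <- sum(C)
  if (total == 0) stop("total variance is zero; shares undefined")
  shares <- rowSums(C) / total
  structure(list(C = C, shares = shares, total = total, gradient = g,
                 mean = mu[names(g)], n = nrow(theta),
                 decomposition = as.integer(decomposition)),
            class = "contribution_table")
}

#' @export
print.contribution_table <- function(x, ...) {
  cat(sprintf("Delta-method variance decomposition of yield (decomposition %d, n = %d units)\n",
              x$decomposition, x$n))
  cat(sprintf("Approximated Var(Y): %.6g\n", x$total))
  cat("Per-trait contributions (row sums / total):\n")
  print(round(x$shares, 2))
  invisible(x)
}

#' Accuracy diagnostic for the first-order variance approximation
#'
#' Compares the delta-method total to the empirical variance of Y computed
#' directly per analysis unit from its own component row. The first-order
#' approximation is accurate when trait coefficients of variation are small;
#' with large CVs the multiplicative model's curvature makes it depart, which
#' this diagnostic flags.
#'
#' @param theta component sample as in [contributionTable()].
#' @param decomposition 1 or 2.
#' @param flag_beyond flag the report when the ratio leaves
#'   \code{[1/flag_beyond, flag_beyond]} (default 1.25).
#' @return list with \code{delta_total}, \code{empirical_var}, \code{ratio}
#'   (delta/empirical; \code{NA} with \code{degenerate = TRUE} when both are
#'   zero), and \code{flagged}.
#' @export
deltaAccuracy <- function(theta, decomposition = 1, flag_beyond = 1.25) {
  theta <- as.matrix(as.data.frame(theta))
  per_unit_y <- apply(theta, 1L, function(row) {
    g <- yieldGradient(row, decomposition)
    attr(g, "Y")
  })
  emp <- stats::var(per_unit_y)
  delta_total <- tryCatch(contributionTable(theta, decomposition)$total,
                          error = function(e) {
                            if (emp == 0) 0 else stop(e)
                          })
  if (emp == 0 && delta_total == 0) {
    return(list(delta_total = 0, empirical_var = 0, ratio = NA_real_,
                degenerate = TRUE, flagged = FALSE))
  }
  ratio <- delta_total / emp
  list(delta_total = delta_total, empirical_var = emp, ratio = ratio,
       degenerate = FALSE,
       flagged = !is.finite(ratio) || ratio > flag_beyond || ratio < 1 / flag_beyond)
}

#' Component sample for the variance decomposition, by species group
#'
#' Builds the theta matrix for [contributionTable()] from per-plant yield
#' components: species means on the measurement (not log) scale, since the
#' delta method differentiates Y in natural units. Decomposition 1 uses
#' (Ms_sown, lambda, d, Ar, c) for every group; decomposition 2 uses
#' (Ms_harvest, Ns, Ni) for cereals, which carry per-infructescence counts,
#' and (Ms_harvest, N_total) for pulses and for all species pooled.
#'
#' @param components a \code{yield_components} table from
#'   [deriveComponents()].
#' @param decomposition 1 or 2.
#' @param group \code{"all"}, \code{"cereals"} or \code{"pulses"}.
#' @param per_plant use individual plants rather than species means as the
#'   analysis units.
#' @return numeric matrix, one row per analysis unit, columns named for
#'   [yieldGradient()].
#' @export
thetaSample <- function(components, decomposition = 1,
                        group = c("all", "cereals", "pulses"),
                        per_plant = FALSE) {
  group <- match.arg(group)
  df <- as.data.frame(components)
  df <- switch(group,
               all = df,
               cereals = df[df$family == "grass", , drop = FALSE],
               pulses = df[df$family == "legume", , drop = FALSE])
  if (nrow(df) == 0L) stop("no records in group '", group, "'")
  cols <- if (decomposition == 1) {
    c(Ms = "Ms_sown", lambda = "lambda_bar", d = "d", Ar = "Ar", c = "c")
  } else if (group == "cereals") {
    c(Ms = "Ms_harvest", Ns = "Ns", Ni = "Ni")
  } else {
    c(Ms = "Ms_harvest", N = "N_total")
  }
  m <- as.matrix(df[, cols])
  colnames(m) <- names(cols)
  if (!per_plant) {
    m <- apply(m, 2L, function(v) {
      tapply(v, df$species, mean, na.rm = TRUE)
    })
  }
  m <- m[stats::complete.cases(m), , drop = FALSE]
  m
}

#' Variance-decomposition summary across species groups
#'
#' Runs [contributionTable()] for all species, cereals only and pulses only,
#' and returns one row of per-trait shares per group, mirroring the layout in
#' which multiplicative yield decompositions are usually reported. Groups
#' whose trait sets differ (cereals carry packaging counts) contribute their
#' own columns; absent trait/group combinations are \code{NA}.
#'
#' @param components a \code{yield_components} table.
#' @param decomposition 1 or 2.
#' @param per_plant passed to [thetaSample()].
#' @return list with \code{shares} (data frame, one row per group) and
#'   \code{tables} (the three \code{contribution_table} objects).
#' @export
contributionSummary <- function(components, decomposition = 1,
                                per_plant = FALSE) {
  groups <- c("all", "cereals", "pulses")
  tables <- lapply(groups, function(gr) {
    theta <- thetaSample(components, decomposition, gr, per_plant)
    contributionTable(theta, decomposition)
  })
  names(tables) <- groups
  all_traits <- unique(unlist(lapply(tables, function(t) names(t$shares))))
  shares <- do.call(rbind, lapply(groups, function(gr) {
    row <- setNames(rep(NA_real_, length(all_traits)), all_traits)
    row[names(tables[[gr]]$shares)] <- tables[[gr]]$shares
    as.data.frame(as.list(row))
  }))
  shares <- cbind(group = groups, shares)
  rownames(shares) <- NULL
  list(shares = shares, tables = tables)
}
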