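# Average-information REML for linear-covariance models, and the bivariate
# cross-population wrappers built on it.
#
# The model is y = X b + u, u ~ N(0, V(theta)), V(theta) = sum_i theta_i K_i.
# REML maximises
#   logL = -1/2 [ log|V| + log|X' V^-1 X| + y' P y ],
#   P = V^-1 - V^-1 X (X' V^-1 X)^-1 X' V^-1.
# Updates are Newton steps with the average-information matrix
#   AI_ij = 1/2 y' P K_i P K_j P y,
# gradient dlogL/dtheta_i = -1/2 [ tr(P K_i) - y' P K_i P y ]. A step that
# leaves the feasible region or decreases logL is halved (up to 5 times) and
# then replaced by an EM-type step. Variance components are bounded below at
# 1e-6 of the phenotypic variance; covariance components are unconstrained.
# The inverse AI matrix at convergence is the sampling covariance of the
# estimates.

reml_objective <- function(theta, K, y, X) {
  V <- Reduce(`+`, Map(`*`, K, theta))
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  Vinv <- chol2inv(ch)
  VinvX <- Vinv %*% X
  XtVX <- crossprod(X, VinvX)
  chX <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(chX)) return(NULL)
  P <- Vinv - VinvX %*% chol2inv(chX) %*% t(VinvX)
  Py <- P %*% y
  logL <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chX))) +
                  sum(y * Py))
  list(P = P, Py = Py, logL = as.numeric(logL))
}

reml_grad_ai <- function(state, theta, K, y) {
  q <- length(K)
  Py <- state$Py
  U <- vapply(K, function(Kk) as.numeric(Kk %*% Py), numeric(length(y)))
  PU <- state$P %*% U
  AI <- 0.5 * crossprod(U, PU)
  trPK <- vapply(K, function(Kk) sum(state$P * Kk), numeric(1))
  yPKPy <- as.numeric(crossprod(Py, U))
  grad <- -0.5 * (trPK - yPKPy)
  list(grad = grad, AI = AI, yPKPy = yPKPy, trPK = trPK)
}

solve_psd <- function(A, b = NULL) {
  out <- tryCatch(if (is.null(b)) solve(A) else solve(A, b),
                  error = function(e) NULL)
  if (is.null(out)) {
    ridge <- diag(1e-8 * max(abs(diag(A)), 1), nrow(A))
    out <- if (is.null(b)) solve(A + ridge) else solve(A + ridge, b)
  }
  out
}

#' Fit a linear-covariance model by average-information REML
#'
#' Low-level engine used by [bivariate_greml()] and [univariate_greml()]. The
#' covariance structure is V = sum_i theta_i K_i.
#'
#' @param y Numeric response (no missing values).
#' @param X Fixed-effect design matrix; reduced to a full-column-rank basis
#'   (first linearly independent columns) internally.
#' @param K Named list of symmetric n x n covariance structure matrices.
#' @param is_variance Logical per parameter: `TRUE` for variance components
#'   (bounded below), `FALSE` for unconstrained covariances.
#' @param init Starting values for theta.
#' @param max_iter Maximum iterations (default 100).
#' @param tol Convergence tolerance on the log-likelihood change and the
#'   maximum relative parameter change (default 1e-4).
#' @param verbose Print the iteration trace.
#' @return A list of class `greml_fit` with `estimates`, `sampling_cov`
#'   (inverse AI at the optimum), `logL`, `logL_trace`, `iterations`,
#'   `converged`, `boundary`.
#' @export
aireml <- function(y, X, K, is_variance, init, max_iter = 100L, tol = 1e-4,
                   verbose = FALSE) {
  n <- length(y)
  stopifnot(nrow(X) == n, all(vapply(K, nrow, 1L) == n),
            length(init) == length(K), length(is_variance) == length(K))
  qx <- qr(X)
  if (qx$rank < ncol(X)) X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  if (n <= ncol(X) + length(K)) stop("too few observations for the model")
  vp <- stats::var(y)
  vfloor <- 1e-6 * vp
  theta <- init
  theta[is_variance] <- pmax(theta[is_variance], vfloor)
  state <- reml_objective(theta, K, y, X)
  if (is.null(state)) stop("V is not positive definite at the starting values")
  trace <- state$logL
  converged <- FALSE
  iter <- 0L
  ga <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    ga <- reml_grad_ai(state, theta, K, y)
    # active-set reduction: variances pinned at the floor whose gradient
    # points outward stay fixed; the Newton system is solved for the rest
    free <- !(is_variance & theta <= vfloor * (1 + 1e-8) & ga$grad < 0)
    if (!any(free)) break
    delta <- numeric(length(theta))
    delta[free] <- as.numeric(solve_psd(ga$AI[free, free, drop = FALSE],
                                        ga$grad[free]))
    accepted <- FALSE
    new_theta <- theta; new_state <- NULL
    step <- delta
    for (h in 0:5) {                   # AI step with up to 5 halvings
      cand <- theta + step
      cand[is_variance] <- pmax(cand[is_variance], vfloor)
      st <- reml_objective(cand, K, y, X)
      if (!is.null(st) && st$logL >= state$logL - 1e-9) {
        new_theta <- cand; new_state <- st; accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) {                   # Levenberg-Marquardt damped fallback
      lam0 <- mean(abs(diag(ga$AI)))
      for (lam in lam0 * c(0.1, 1, 10, 100, 1000)) {
        dlm <- numeric(length(theta))
        Ad <- ga$AI[free, free, drop = FALSE] +
          diag(lam, sum(free))
        dlm[free] <- as.numeric(solve_psd(Ad, ga$grad[free]))
        cand <- theta + dlm
        cand[is_variance] <- pmax(cand[is_variance], vfloor)
        st <- reml_objective(cand, K, y, X)
        if (!is.null(st) && st$logL >= state$logL - 1e-9) {
          new_theta <- cand; new_state <- st; accepted <- TRUE
          break
        }
      }
    }
    if (!accepted) {                   # EM-type fallback step
      scale2 <- pmax(abs(theta), 1e-3 * vp)^2
      em_step <- scale2 / n * (ga$yPKPy - ga$trPK)
      for (h in 0:10) {
        cand <- theta + em_step
        cand[is_variance] <- pmax(cand[is_variance], vfloor)
        st <- reml_objective(cand, K, y, X)
        if (!is.null(st) && st$logL >= state$logL - 1e-9) {
          new_theta <- cand; new_state <- st; accepted <- TRUE
          break
        }
        em_step <- em_step / 2
      }
    }
    if (!accepted) break               # cannot improve further
    dlog <- new_state$logL - state$logL
    dpar <- max(abs(new_theta - theta) / pmax(abs(theta), 1e-2 * vp))
    theta <- new_theta; state <- new_state
    trace <- c(trace, state$logL)
    if (verbose) {
      message(sprintf("iter %d: logL = %.6f, max rel change = %.2e",
                      iter, state$logL, dpar))
    }
    if (dlog < tol && (dpar < tol || dlog < 1e-8)) {
      converged <- TRUE
      break
    }
  }
  if (!converged && iter >= max_iter) {
    warning(sprintf("AI-REML did not converge in %d iterations", max_iter),
            call. = FALSE)
  }
  ga <- reml_grad_ai(state, theta, K, y)
  sampling_cov <- solve_psd(ga$AI)
  sampling_cov <- (sampling_cov + t(sampling_cov)) / 2
  dimnames(sampling_cov) <- list(names(K), names(K))
  boundary <- is_variance & theta <= vfloor * (1 + 1e-8)
  # a V whose Cholesky pivots collapse signals an unbounded likelihood ridge
  # (V approaching singularity); estimates there are not an interior optimum
  ch <- chol(Reduce(`+`, Map(`*`, K, theta)))
  degenerate <- (min(diag(ch)) / max(diag(ch)))^2 < 1e-10
  if (degenerate) {
    warning("REML likelihood appears unbounded: V approaches singularity; estimates lie on a boundary ridge",
            call. = FALSE)
  }
  structure(list(estimates = stats::setNames(theta, names(K)),
                 sampling_cov = sampling_cov, logL = state$logL,
                 logL_trace = trace, iterations = iter, converged = converged,
                 boundary = stats::setNames(boundary, names(K)),
                 degenerate = degenerate, n = n),
            class = "greml_fit")
}

# Build the block structure matrices for a bivariate model from a full GRM.
bivariate_blocks <- function(A, i1, i2) {
  n <- nrow(A)
  B11 <- matrix(0, n, n); B11[i1, i1] <- A[i1, i1]
  B22 <- matrix(0, n, n); B22[i2, i2] <- A[i2, i2]
  B12 <- matrix(0, n, n)
  B12[i1, i2] <- A[i1, i2]; B12[i2, i1] <- A[i2, i1]
  list(B11 = B11, B22 = B22, B12 = B12)
}

#' Bivariate (cross-population) GREML
#'
#' Treats the phenotype in the two populations as two traits and fits, for
#' each GRM component k, a genetic variance per population (Vg1_k, Vg2_k) and
#' a cross-population genetic covariance (C_k), plus one residual variance per
#' population. No individual may appear in both populations, so the
#' cross-population residual covariance is identically zero. Genetic
#' correlations r_g = C / sqrt(Vg1 Vg2) and SNP heritabilities with standard
#' errors are derived from the fit.
#'
#' @param phenotype Numeric vector aligned with the GRM sample order (`NA`
#'   entries are dropped with a message).
#' @param pop Population label per sample (2 levels; first level = population 1).
#' @param grms A `grm` object, a list of them (one per SNP-set component), or
#'   plain matrices.
#' @param covariates Optional numeric covariate matrix (e.g. 20 PCs).
#'   Population-specific intercepts are always included.
#' @param max_iter,tol,verbose Passed to [aireml()].
#' @return A `greml_fit` with additional elements `rg` (per component:
#'   estimate, SE) and `h2` (per population: estimate, SE).
#' @export
bivariate_greml <- function(phenotype, pop, grms, covariates = NULL,
                            max_iter = 100L, tol = 1e-4, verbose = FALSE) {
  if (inherits(grms, "grm") || (is.matrix(grms) && !is.list(grms))) {
    grms <- list(grms)
  }
  mats <- lapply(grms, function(g) if (inherits(g, "grm")) g$matrix else as.matrix(g))
  n_all <- length(phenotype)
  stopifnot(length(pop) == n_all,
            all(vapply(mats, nrow, 1L) == n_all))
  keep <- !is.na(phenotype)
  if (!all(keep)) {
    message(sprintf("dropping %d samples without phenotype", sum(!keep)))
    phenotype <- phenotype[keep]
    pop <- pop[keep]
    mats <- lapply(mats, function(A) A[keep, keep, drop = FALSE])
    if (!is.null(covariates)) covariates <- as.matrix(covariates)[keep, , drop = FALSE]
  }
  pop <- factor(pop)
  if (nlevels(pop) != 2L) stop("exactly two populations are required")
  i1 <- which(pop == levels(pop)[1]); i2 <- which(pop == levels(pop)[2])
  ncomp <- length(mats)
  comp_names <- names(mats)
  if (is.null(comp_names)) comp_names <- sprintf("set%d", seq_len(ncomp))
  K <- list(); is_var <- logical(0); init <- numeric(0)
  vp1 <- stats::var(phenotype[i1]); vp2 <- stats::var(phenotype[i2])
  for (k in seq_len(ncomp)) {
    b <- bivariate_blocks(mats[[k]], i1, i2)
    K[[sprintf("Vg1_%s", comp_names[k])]] <- b$B11
    K[[sprintf("Vg2_%s", comp_names[k])]] <- b$B22
    K[[sprintf("C_%s", comp_names[k])]] <- b$B12
    is_var <- c(is_var, TRUE, TRUE, FALSE)
    init <- c(init, vp1 / (2 * ncomp), vp2 / (2 * ncomp), 0)
  }
  n <- length(phenotype)
  D1 <- diag(as.numeric(pop == levels(pop)[1]), n)
  D2 <- diag(as.numeric(pop == levels(pop)[2]), n)
  K$Ve1 <- D1; K$Ve2 <- D2
  is_var <- c(is_var, TRUE, TRUE)
  init <- c(init, vp1 / 2, vp2 / 2)
  X <- stats::model.matrix(~ 0 + pop)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  fit <- aireml(phenotype, X, K, is_var, init, max_iter = max_iter, tol = tol,
                verbose = verbose)
  fit$type <- "bivariate"
  fit$components <- comp_names
  fit$pop_levels <- levels(pop)
  derive_rg(fit)
}

#' Univariate GREML
#'
#' Single-population variance-component fit: V = sum_k Vg_k A_k + Ve I. With
#' no GRM supplied, a residual-only model is fitted (h2 undefined).
#'
#' @inheritParams bivariate_greml
#' @param grms A `grm`, matrix, or list of them; may be empty.
#' @return A `greml_fit` with an `h2` element.
#' @export
univariate_greml <- function(phenotype, grms = list(), covariates = NULL,
                             max_iter = 100L, tol = 1e-4, verbose = FALSE) {
  if (inherits(grms, "grm") || (is.matrix(grms) && !is.list(grms))) grms <- list(grms)
  mats <- lapply(grms, function(g) if (inherits(g, "grm")) g$matrix else as.matrix(g))
  keep <- !is.na(phenotype)
  if (!all(keep)) {
    message(sprintf("dropping %d samples without phenotype", sum(!keep)))
    phenotype <- phenotype[keep]
    mats <- lapply(mats, function(A) A[keep, keep, drop = FALSE])
    if (!is.null(covariates)) covariates <- as.matrix(covariates)[keep, , drop = FALSE]
  }
  n <- length(phenotype)
  ncomp <- length(mats)
  comp_names <- names(mats)
  if (is.null(comp_names) && ncomp) comp_names <- sprintf("set%d", seq_len(ncomp))
  K <- list(); is_var <- logical(0); init <- numeric(0)
  vp <- stats::var(phenotype)
  for (k in seq_len(ncomp)) {
    K[[sprintf("Vg_%s", comp_names[k])]] <- mats[[k]]
    is_var <- c(is_var, TRUE)
    init <- c(init, vp / (2 * max(ncomp, 1)))
  }
  K$Ve <- diag(n)
  is_var <- c(is_var, TRUE)
  init <- c(init, vp / 2)
  X <- matrix(1, n, 1)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  fit <- aireml(phenotype, X, K, is_var, init, max_iter = max_iter, tol = tol,
                verbose = verbose)
  fit$type <- "univariate"
  fit$components <- comp_names
  if (ncomp) {
    vg_idx <- seq_len(ncomp)
    ve_idx <- ncomp + 1L
    S <- sum(fit$estimates[vg_idx]); Ve <- fit$estimates[ve_idx]
    h2 <- S / (S + Ve)
    g <- numeric(length(fit$estimates))
    g[vg_idx] <- Ve / (S + Ve)^2
    g[ve_idx] <- -S / (S + Ve)^2
    se <- sqrt(max(0, as.numeric(t(g) %*% fit$sampling_cov %*% g)))
    fit$h2 <- data.frame(h2 = as.numeric(h2), se = se)
  }
  fit
}

#' Derive genetic correlations and heritabilities from a bivariate fit
#'
#' r_g = C / sqrt(Vg1 Vg2) per component, with its sampling variance from the
#' variance-component sampling covariances ([rg_sampling_var()]); h2 per
#' population from the summed genetic variances, with delta-method SEs.
#' Components whose genetic variance is pinned at the lower bound yield `NA`
#' correlations (flagged in `boundary`).
#'
#' @param fit A bivariate `greml_fit`.
#' @return The fit, with `rg` and `h2` data frames filled in.
#' @export
derive_rg <- function(fit) {
  stopifnot(inherits(fit, "greml_fit"), fit$type == "bivariate")
  comp <- fit$components
  ncomp <- length(comp)
  est <- fit$estimates; S <- fit$sampling_cov
  rg <- data.frame(component = comp, rg = NA_real_, se = NA_real_)
  for (k in seq_len(ncomp)) {
    nm <- c(sprintf("Vg1_%s", comp[k]), sprintf("Vg2_%s", comp[k]),
            sprintf("C_%s", comp[k]))
    v1 <- est[nm[1]]; v2 <- est[nm[2]]; cc <- est[nm[3]]
    if (fit$boundary[nm[1]] || fit$boundary[nm[2]] || v1 <= 0 || v2 <= 0) next
    rg$rg[k] <- as.numeric(cc / sqrt(v1 * v2))
    vr <- rg_sampling_var(v1, v2, cc, S[nm, nm])
    rg$se[k] <- sqrt(max(0, vr))
  }
  h2 <- data.frame(pop = fit$pop_levels, h2 = NA_real_, se = NA_real_)
  for (pidx in 1:2) {
    vg_nm <- sprintf("Vg%d_%s", pidx, comp)
    ve_nm <- sprintf("Ve%d", pidx)
    Ssum <- sum(est[vg_nm]); Ve <- est[ve_nm]
    h2$h2[pidx] <- Ssum / (Ssum + Ve)
    g <- stats::setNames(numeric(length(est)), names(est))
    g[vg_nm] <- Ve / (Ssum + Ve)^2
    g[ve_nm] <- -Ssum / (Ssum + Ve)^2
    h2$se[pidx] <- sqrt(max(0, as.numeric(t(g) %*% S %*% g)))
  }
  fit$rg <- rg
  fit$h2 <- h2
  fit
}

#' Wald test of an estimate against a null value
#'
#' chi-squared = ((estimate - null) / se)^2, P from the upper tail of the
#' 1-df chi-squared distribution. Used e.g. to test r_g = 1.
#'
#' @param estimate Point estimate.
#' @param se Standard error (> 0).
#' @param null Null value (default 1).
#' @return List with `chisq` and `p`.
#' @export
wald_test <- function(estimate, se, null = 1) {
  stopifnot(se > 0)
  chisq <- ((estimate - null) / se)^2
  list(chisq = as.numeric(chisq),
       p = stats::pchisq(as.numeric(chisq), df = 1, lower.tail = FALSE))
}

#' @export
print.greml_fit <- function(x, ...) {
  cat(sprintf("%s GREML fit: logL = %.4f, %d iterations, converged = %s\n",
              x$type %||% "generic", x$logL, x$iterations, x$converged))
  print(round(x$estimates, 6))
  if (!is.null(x$rg)) { cat("genetic correlation(s):\n"); print(x$rg) }
  if (!is.null(x$h2)) { cat("heritability:\n"); print(x$h2) }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
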