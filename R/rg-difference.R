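# Sampling variance/covariance of estimated genetic correlations and the
# chi-squared test for a difference in r_g between two SNP sets.
#
# With r_g = C / sqrt(Vg1 Vg2), the sampling variance of the estimate is
#
#   var(rg^) = rg^2 [ var(Vg1^)/(4 Vg1^2) + var(Vg2^)/(4 Vg2^2) + var(C^)/C^2
#                     + cov(Vg1^,Vg2^)/(2 Vg1 Vg2)
#                     - cov(Vg1^,C^)/(Vg1 C) - cov(Vg2^,C^)/(Vg2 C) ]
#
# and for two SNP sets s1, s2 (writing V11 = Vg(p1,s1), V21 = Vg(p2,s1),
# V12 = Vg(p1,s2), V22 = Vg(p2,s2), C1, C2):
#
#   cov(rg1^, rg2^) = rg1 rg2 [ cov(V11,V12)/(4 V11 V12) + cov(V11,V22)/(4 V11 V22)
#                               - cov(V11,C2)/(2 V11 C2)
#                               + cov(V21,V12)/(4 V21 V12) + cov(V21,V22)/(4 V21 V22)
#                               - cov(V21,C2)/(2 V21 C2)
#                               - cov(V12,C1)/(2 V12 C1) - cov(V22,C1)/(2 V22 C1)
#                               + cov(C1,C2)/(C1 C2) ].
#
# Parameters are replaced by their estimates in practice. Both expressions are
# the exact first-order delta-method forms; C = 0 is handled by the analytic
# limit (the 1/C factors cancel against rg).

#' Sampling variance of a genetic-correlation estimate
#'
#' Evaluates the six-term bracket above from the variance-component estimates
#' of one SNP set and their 3x3 sampling covariance. At C = 0 the analytic
#' limit var(C^)/(Vg1 Vg2) is used.
#'
#' @param Vg1,Vg2 Genetic variance estimates per population (> 0).
#' @param C Cross-population genetic covariance estimate.
#' @param S 3x3 sampling covariance of (Vg1, Vg2, C), in that order.
#' @return The sampling variance of r_g.
#' @export
rg_sampling_var <- function(Vg1, Vg2, C, S) {
  stopifnot(Vg1 > 0, Vg2 > 0, is.matrix(S), all(dim(S) == 3L))
  if (C == 0) {
    message("C = 0: using the analytic limit var(C)/(Vg1*Vg2) for var(rg)")
    return(as.numeric(S[3, 3] / (Vg1 * Vg2)))
  }
  rg2 <- C^2 / (Vg1 * Vg2)
  as.numeric(
    rg2 * (S[1, 1] / (4 * Vg1^2) + S[2, 2] / (4 * Vg2^2) + S[3, 3] / C^2 +
           S[1, 2] / (2 * Vg1 * Vg2) -
           S[1, 3] / (Vg1 * C) - S[2, 3] / (Vg2 * C)))
}

#' Variance-component moments of a joint two-set fit
#'
#' Bundles the six variance/covariance estimates of a two-component bivariate
#' fit (set 1: Vg1, Vg2, C; set 2: Vg1, Vg2, C) with their full 6x6 sampling
#' covariance, as needed by [var_rg()], [cov_rg_pair()] and [rg_diff_test()].
#'
#' @param estimates Named length-6 vector in the order
#'   `Vg1_s1, Vg2_s1, C_s1, Vg1_s2, Vg2_s2, C_s2`.
#' @param vcov 6x6 sampling covariance matrix of the estimates.
#' @return An object of class `component_moments`.
#' @export
component_moments <- function(estimates, vcov) {
  estimates <- as.numeric(estimates)
  vcov <- as.matrix(vcov)
  stopifnot(length(estimates) == 6L, all(dim(vcov) == 6L),
            all(is.finite(estimates)), all(is.finite(vcov)))
  if (max(abs(vcov - t(vcov))) > 1e-8 * max(abs(vcov), 1)) {
    stop("sampling covariance matrix must be symmetric")
  }
  names(estimates) <- c("Vg1_s1", "Vg2_s1", "C_s1", "Vg1_s2", "Vg2_s2", "C_s2")
  dimnames(vcov) <- list(names(estimates), names(estimates))
  structure(list(estimates = estimates, vcov = (vcov + t(vcov)) / 2),
            class = "component_moments")
}

#' Extract the two-set moments from a two-component bivariate fit
#'
#' @param fit A bivariate `greml_fit` with exactly two GRM components.
#' @return A `component_moments` object.
#' @export
as_component_moments <- function(fit) {
  stopifnot(inherits(fit, "greml_fit"), fit$type == "bivariate",
            length(fit$components) == 2L)
  nm <- c(sprintf(c("Vg1_%s", "Vg2_%s", "C_%s"), fit$components[1]),
          sprintf(c("Vg1_%s", "Vg2_%s", "C_%s"), fit$components[2]))
  component_moments(fit$estimates[nm], fit$sampling_cov[nm, nm])
}

#' Sampling variance of r_g for one SNP set of a joint fit
#'
#' @param moments A `component_moments`.
#' @param set 1 or 2.
#' @return Sampling variance of that set's r_g.
#' @export
var_rg <- function(moments, set = 1L) {
  stopifnot(inherits(moments, "component_moments"), set %in% c(1L, 2L))
  i <- if (set == 1L) 1:3 else 4:6
  e <- moments$estimates[i]
  rg_sampling_var(e[1], e[2], e[3], moments$vcov[i, i])
}

#' Sampling covariance of the r_g estimates of two SNP sets
#'
#' Evaluates the nine-term bracket (see the header of this file) term by term.
#' When one set's C is zero, the analytic limit is used: the terms involving
#' that set's 1/C cancel against its r_g factor.
#'
#' @param moments A `component_moments`.
#' @return The sampling covariance cov(rg1^, rg2^).
#' @export
cov_rg_pair <- function(moments) {
  stopifnot(inherits(moments, "component_moments"))
  e <- moments$estimates; S <- moments$vcov
  V11 <- e[["Vg1_s1"]]; V21 <- e[["Vg2_s1"]]; C1 <- e[["C_s1"]]
  V12 <- e[["Vg1_s2"]]; V22 <- e[["Vg2_s2"]]; C2 <- e[["C_s2"]]
  if (any(c(V11, V21, V12, V22) <= 0)) stop("genetic variances must be positive")
  cv <- function(a, b) S[a, b]
  if (C1 != 0 && C2 != 0) {
    rg1 <- C1 / sqrt(V11 * V21); rg2 <- C2 / sqrt(V12 * V22)
    bracket <-
      cv("Vg1_s1", "Vg1_s2") / (4 * V11 * V12) +
      cv("Vg1_s1", "Vg2_s2") / (4 * V11 * V22) -
      cv("Vg1_s1", "C_s2")   / (2 * V11 * C2) +
      cv("Vg2_s1", "Vg1_s2") / (4 * V21 * V12) +
      cv("Vg2_s1", "Vg2_s2") / (4 * V21 * V22) -
      cv("Vg2_s1", "C_s2")   / (2 * V21 * C2) -
      cv("Vg1_s2", "C_s1")   / (2 * V12 * C1) -
      cv("Vg2_s2", "C_s1")   / (2 * V22 * C1) +
      cv("C_s1", "C_s2")     / (C1 * C2)
    return(as.numeric(rg1 * rg2 * bracket))
  }
  # analytic limit: evaluate with the 1/C cancellations performed, valid for
  # any C (including 0) and identical to the bracket when both C != 0
  message("C = 0 in at least one set: using the analytic limit for cov(rg1, rg2)")
  rg1 <- C1 / sqrt(V11 * V21); rg2 <- C2 / sqrt(V12 * V22)
  as.numeric(
    rg1 * rg2 * (cv("Vg1_s1", "Vg1_s2") / (4 * V11 * V12) +
                 cv("Vg1_s1", "Vg2_s2") / (4 * V11 * V22) +
                 cv("Vg2_s1", "Vg1_s2") / (4 * V21 * V12) +
                 cv("Vg2_s1", "Vg2_s2") / (4 * V21 * V22)) -
    rg1 / sqrt(V12 * V22) * (cv("Vg1_s1", "C_s2") / (2 * V11) +
                             cv("Vg2_s1", "C_s2") / (2 * V21)) -
    rg2 / sqrt(V11 * V21) * (cv("Vg1_s2", "C_s1") / (2 * V12) +
                             cv("Vg2_s2", "C_s1") / (2 * V22)) +
    cv("C_s1", "C_s2") / sqrt(V11 * V21 * V12 * V22))
}

#' Chi-squared test for a difference in r_g between two SNP sets
#'
#' chi-squared = (rg1^ - rg2^)^2 / var(rg1^ - rg2^) with
#' var(rg1^ - rg2^) = var(rg1^) + var(rg2^) - 2 cov(rg1^, rg2^), compared to
#' the 1-df chi-squared upper tail.
#'
#' @param rg1,rg2 The two genetic-correlation estimates.
#' @param var1,var2 Their sampling variances.
#' @param cov12 Their sampling covariance.
#' @return List with `chisq`, `p` and `var_diff`.
#' @export
chisq_diff_test <- function(rg1, rg2, var1, var2, cov12) {
  var_diff <- var1 + var2 - 2 * cov12
  if (!is.finite(var_diff) || var_diff <= 0) {
    stop("var(rg1 - rg2) must be positive; inconsistent moments supplied")
  }
  chisq <- (rg1 - rg2)^2 / var_diff
  list(chisq = as.numeric(chisq),
       p = stats::pchisq(as.numeric(chisq), df = 1, lower.tail = FALSE),
       var_diff = as.numeric(var_diff))
}

#' Full r_g difference test from joint two-set moments
#'
#' Convenience wrapper computing both sets' r_g with SEs, their sampling
#' covariance, and the difference test.
#'
#' @param moments A `component_moments` (or a two-component bivariate
#'   `greml_fit`, which is converted).
#' @return List with `rg1`, `rg2`, `se1`, `se2`, `cov12`, `chisq`, `p`.
#' @export
rg_diff_test <- function(moments) {
  if (inherits(moments, "greml_fit")) moments <- as_component_moments(moments)
  e <- moments$estimates
  rg1 <- e[["C_s1"]] / sqrt(e[["Vg1_s1"]] * e[["Vg2_s1"]])
  rg2 <- e[["C_s2"]] / sqrt(e[["Vg1_s2"]] * e[["Vg2_s2"]])
  v1 <- var_rg(moments, 1L); v2 <- var_rg(moments, 2L)
  c12 <- cov_rg_pair(moments)
  ct <- chisq_diff_test(rg1, rg2, v1, v2, c12)
  list(rg1 = as.numeric(rg1), rg2 = as.numeric(rg2),
       se1 = sqrt(max(0, v1)), se2 = sqrt(max(0, v2)), cov12 = c12,
       chisq = ct$chisq, p = ct$p)
}
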