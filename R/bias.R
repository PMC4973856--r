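# Adaptive quadrature on the real line for integrands built from a normal
# density times a normal cdf. stats::integrate handles the infinite limits;
# if it fails to converge we retry on a finite window of +/- 10 combined SDs
# around the density's centre, where the integrand has all its mass.
.quad <- function(f, center, spread, abs.tol = 1e-10) {
  # integrate in a coordinate centered on the density so the infinite-range
  # transformation used by stats::integrate never misses a distant mode
  g <- function(s) f(s + center)
  r <- tryCatch(
    stats::integrate(g, -Inf, Inf, abs.tol = abs.tol, rel.tol = abs.tol,
                     stop.on.error = TRUE),
    error = function(e) NULL)
  if (is.null(r) || r$message != "OK") {
    r <- stats::integrate(f, center - 10 * spread, center + 10 * spread,
                          abs.tol = abs.tol, rel.tol = abs.tol,
                          subdivisions = 500L)
    if (!identical(r$message, "OK"))
      stop("quadrature failed to converge: ", r$message, call. = FALSE)
  }
  r$value
}

#' Probability that the subpopulation is selected at the interim
#'
#' \eqn{\Pr(X > Y^*)} with \eqn{Y^* = Y + b/(1-p_S)}, computed by adaptive
#' quadrature of
#' \deqn{\int \frac{1}{\sigma_X}\phi\!\Big(\frac{t-\theta_S}{\sigma_X}\Big)
#'   \Phi\!\Big(\frac{t-\theta_{S^c}^*}{\sigma_Y}\Big)\,dt,}
#' where \eqn{\theta_{S^c}^* = \theta_{S^c} + b/(1-p_S)}.
#'
#' @param theta_S,theta_Sc true mean differences in S and its complement.
#' @param sigma_X,sigma_Y standard deviations of the stage-1 mean differences.
#' @param b selection margin.
#' @param p_S prevalence of S, in (0, 1).
#' @param abs.tol absolute quadrature tolerance.
#' @return The selection probability for S.
#' @examples
#' prob_select_s(0, 0, 1, 1, b = 0, p_S = 0.5)  # 0.5 by symmetry
#' @export
prob_select_s <- function(theta_S, theta_Sc, sigma_X, sigma_Y, b = 0, p_S,
                          abs.tol = 1e-10) {
  stopifnot(sigma_X > 0, sigma_Y > 0)
  tc <- theta_Sc + b / (1 - p_S)
  f <- function(t) stats::dnorm(t, theta_S, sigma_X) *
    stats::pnorm((t - tc) / sigma_Y)
  .quad(f, theta_S, sigma_X + sigma_Y, abs.tol)
}

#' Restricted first moment of X on the selection event
#'
#' \eqn{E[X\,1(X > Y^*)]} by the quadrature
#' \eqn{\int t\,\sigma_X^{-1}\phi((t-\theta_S)/\sigma_X)
#' \Phi((t-\theta_{S^c}^*)/\sigma_Y)\,dt}. The complementary moment is
#' available exactly as \eqn{E[X\,1(X \le Y^*)] = \theta_S - E[X\,1(X>Y^*)]}.
#'
#' @inheritParams prob_select_s
#' @param complement if \code{TRUE}, return \eqn{E[X\,1(X \le Y^*)]} instead.
#' @return The restricted moment.
#' @export
trunc_moment_x_select_s <- function(theta_S, theta_Sc, sigma_X, sigma_Y,
                                    b = 0, p_S, complement = FALSE,
                                    abs.tol = 1e-10) {
  stopifnot(sigma_X > 0, sigma_Y > 0)
  tc <- theta_Sc + b / (1 - p_S)
  f <- function(t) t * stats::dnorm(t, theta_S, sigma_X) *
    stats::pnorm((t - tc) / sigma_Y)
  m <- .quad(f, theta_S, sigma_X + sigma_Y, abs.tol)
  if (complement) theta_S - m else m
}

# E[Y 1(X <= Y*)] = int t/sigma_Y phi((t-theta_Sc)/sigma_Y) Phi((t-theta_S^*)/sigma_X) dt,
# theta_S^* = theta_S - b/(1-p_S); and Pr(X <= Y*) by the same integrand without t.
.trunc_moment_y_select_f <- function(theta_S, theta_Sc, sigma_X, sigma_Y,
                                     b = 0, p_S, abs.tol = 1e-10,
                                     moment = TRUE) {
  ts <- theta_S - b / (1 - p_S)
  f <- function(t) {
    g <- stats::dnorm(t, theta_Sc, sigma_Y) * stats::pnorm((t - ts) / sigma_X)
    if (moment) t * g else g
  }
  .quad(f, theta_Sc, sigma_X + sigma_Y, abs.tol)
}

#' Exact conditional bias of the naive estimator when S is selected
#'
#' \deqn{\mathrm{Bias}(D_{S,N}) = t_S\Big(\frac{E[X\,1(X>Y^*)]}{\Pr(X>Y^*)}
#'   - \theta_S\Big),}
#' by the quadratures of \code{\link{prob_select_s}} and
#' \code{\link{trunc_moment_x_select_s}}.
#'
#' @param design an \code{\link{asd_design}} with known prevalence.
#' @param theta_S,theta_Sc true mean differences.
#' @param abs.tol absolute quadrature tolerance.
#' @return The conditional bias (an error if the selection probability is
#'   numerically negligible, when the conditional bias is undefined).
#' @export
bias_naive_s <- function(design, theta_S, theta_Sc, abs.tol = 1e-10) {
  stopifnot(inherits(design, "asd_design"), design$prevalence_known)
  s_X <- design$p_S * design$n1
  q <- derive_quantities(design, s_X, s_V = design$p_S * design$n2)
  sx <- sqrt(q$sigma2_X); sy <- sqrt(q$sigma2_Y)
  pr <- prob_select_s(theta_S, theta_Sc, sx, sy, design$b, design$p_S, abs.tol)
  if (pr < 1e-12)
    stop("selection probability for S underflows; conditional bias undefined",
         call. = FALSE)
  mom <- trunc_moment_x_select_s(theta_S, theta_Sc, sx, sy, design$b,
                                 design$p_S, abs.tol = abs.tol)
  q$t_S * (mom / pr - theta_S)
}

#' Exact conditional biases of the naive estimators when F is selected
#'
#' Component biases
#' \deqn{\mathrm{Bias}(D_{S,N}^F) = t_S^F\Big(\frac{E[X\,1(X\le Y^*)]}
#'   {\Pr(X\le Y^*)} - \theta_S\Big), \quad
#'   \mathrm{Bias}(D_{S^c,N}^F) = t_{S^c}^F\Big(\frac{E[Y\,1(X\le Y^*)]}
#'   {\Pr(X\le Y^*)} - \theta_{S^c}\Big),}
#' and the exact combination
#' \eqn{\mathrm{Bias}(D_{F,N}) = p_S\,\mathrm{Bias}(D_{S,N}^F) +
#' (1-p_S)\,\mathrm{Bias}(D_{S^c,N}^F)}. Under proportional allocation
#' (\code{s_X = p_S n1}, \code{s_V = p_S n2}) the combination is zero: the
#' naive full-population estimator is conditionally unbiased.
#'
#' @inheritParams bias_naive_s
#' @return A list with \code{bias_D_S_N_F}, \code{bias_D_Sc_N_F},
#'   \code{bias_D_F_N} and \code{prob_F}.
#' @export
bias_components_f <- function(design, theta_S, theta_Sc, abs.tol = 1e-10) {
  stopifnot(inherits(design, "asd_design"), design$prevalence_known)
  p <- design$p_S
  s_X <- p * design$n1; s_V <- p * design$n2
  q <- derive_quantities(design, s_X, s_V)
  sx <- sqrt(q$sigma2_X); sy <- sqrt(q$sigma2_Y)
  pr_F <- .trunc_moment_y_select_f(theta_S, theta_Sc, sx, sy, design$b, p,
                                   abs.tol, moment = FALSE)
  if (pr_F < 1e-12)
    stop("selection probability for F underflows; conditional bias undefined",
         call. = FALSE)
  ex_le <- trunc_moment_x_select_s(theta_S, theta_Sc, sx, sy, design$b, p,
                                   complement = TRUE, abs.tol = abs.tol)
  ey_le <- .trunc_moment_y_select_f(theta_S, theta_Sc, sx, sy, design$b, p,
                                    abs.tol, moment = TRUE)
  b_s  <- q$t_S_F  * (ex_le / pr_F - theta_S)
  b_sc <- q$t_Sc_F * (ey_le / pr_F - theta_Sc)
  list(bias_D_S_N_F = b_s, bias_D_Sc_N_F = b_sc,
       bias_D_F_N = p * b_s + (1 - p) * b_sc, prob_F = pr_F)
}

# SE normalizers used throughout the bias and MSE reports. "pooled" is the
# exact SE of the pooled two-stage mean difference in the selected population;
# "printed" divides the S-branch variance across the whole of stage 2.
.se_norm <- function(design, se_mode = c("pooled", "printed")) {
  se_mode <- match.arg(se_mode)
  s2 <- design$sigma^2; p <- design$p_S
  list(SE_S = if (se_mode == "pooled")
         sqrt(4 * s2 / (p * design$n1 + design$n2))
       else sqrt(4 * s2 / (p * (design$n1 + design$n2))),
       SE_F = sqrt(4 * s2 / (design$n1 + design$n2)))
}

#' Conditional-bias curves of the naive estimators over a grid of effects
#'
#' Evaluates the exact (quadrature) conditional biases of \code{D_S,N} (given
#' S selected) and of \code{D_S,N^F}, \code{D_Sc,N^F}, \code{D_F,N} (given F
#' selected) over a grid of subpopulation effects \code{theta_S} at fixed
#' \code{theta_Sc}, together with the selection probability and the biases
#' normalized by the approximate standard errors of the respective
#' full two-stage estimates.
#'
#' @param design an \code{\link{asd_design}} with known prevalence.
#' @param theta_S_grid numeric vector of subpopulation effects.
#' @param theta_Sc complement effect (scalar).
#' @param se_mode \code{"pooled"} (default) normalizes the S-branch by
#'   \code{sqrt(4 sigma^2/(p_S n1 + n2))}, the exact variance of the pooled
#'   two-stage mean in S; \code{"printed"} uses
#'   \code{sqrt(4 sigma^2/(p_S (n1 + n2)))}. The F-branch always uses
#'   \code{sqrt(4 sigma^2/(n1 + n2))}.
#' @param abs.tol absolute quadrature tolerance.
#' @return A data frame with one row per grid point: \code{theta_s},
#'   \code{prob_S}, raw biases \code{bias_s_n}, \code{bias_s_n_f},
#'   \code{bias_sc_n_f}, \code{bias_f_n}, and normalized twins suffixed
#'   \code{_std}.
#' @examples
#' d <- asd_design(200, 200, sigma = 1, p_S = 0.5)
#' bias_curve(d, theta_S_grid = c(-0.2, 0, 0.2), theta_Sc = 0)
#' @export
bias_curve <- function(design, theta_S_grid, theta_Sc = 0,
                       se_mode = c("pooled", "printed"), abs.tol = 1e-10) {
  stopifnot(length(theta_S_grid) >= 1)
  se <- .se_norm(design, se_mode)
  rows <- lapply(theta_S_grid, function(th) {
    q <- derive_quantities(design, design$p_S * design$n1)
    pr <- prob_select_s(th, theta_Sc, sqrt(q$sigma2_X), sqrt(q$sigma2_Y),
                        design$b, design$p_S, abs.tol)
    bs <- bias_naive_s(design, th, theta_Sc, abs.tol)
    bf <- bias_components_f(design, th, theta_Sc, abs.tol)
    data.frame(theta_s = th, prob_S = pr,
               bias_s_n = bs, bias_s_n_f = bf$bias_D_S_N_F,
               bias_sc_n_f = bf$bias_D_Sc_N_F, bias_f_n = bf$bias_D_F_N,
               bias_s_n_std = bs / se$SE_S,
               bias_s_n_f_std = bf$bias_D_S_N_F / se$SE_F,
               bias_sc_n_f_std = bf$bias_D_Sc_N_F / se$SE_F,
               bias_f_n_std = bf$bias_D_F_N / se$SE_F)
  })
  do.call(rbind, rows)
}
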