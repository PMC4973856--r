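#' Numerically stable Mills ratio
#'
#' Computes \code{dnorm(f) / pnorm(f)} on the log scale, so the ratio remains
#' finite and accurate for arbitrarily negative \code{f} where the naive
#' quotient underflows to 0/0.
#'
#' @param f numeric vector.
#' @return \code{phi(f) / Phi(f)}, elementwise.
#' @export
mills_ratio <- function(f) {
  exp(stats::dnorm(f, log = TRUE) - stats::pnorm(f, log.p = TRUE))
}

#' Naive two-stage estimator when the subpopulation is selected
#'
#' The pooled two-stage sample mean difference for S,
#' \code{D_S,N = t_S x + (1 - t_S) u}, with \code{t_S = s_X / (s_X + n2)} the
#' proportion of S-patients recruited in stage 1.
#'
#' @param x stage-1 mean difference in S.
#' @param u stage-2 mean difference in S.
#' @param t_S stage-1 pooling weight in (0, 1).
#' @return The naive estimate.
#' @examples
#' naive_selected_s(6.5, 7.42, 1/3)  # 7.11
#' @export
naive_selected_s <- function(x, u, t_S) {
  if (t_S <= 0 || t_S >= 1) stop("'t_S' must lie in (0, 1)", call. = FALSE)
  t_S * x + (1 - t_S) * u
}

#' Naive two-stage estimators when the full population is selected
#'
#' Component two-stage means \code{D_S,N^F = t_S^F x + (1 - t_S^F) v} and
#' \code{D_Sc,N^F = t_Sc^F y + (1 - t_Sc^F) w}, combined into the
#' full-population estimate \code{D_F,N = p D_S,N^F + (1 - p) D_Sc,N^F}. With
#' known prevalence \code{p = p_S}; with estimated prevalence the pooled
#' estimate \code{p = (s_X + s_V) / (n1 + n2)} is used for the combination.
#'
#' @param x,y stage-1 mean differences in S and its complement.
#' @param v,w stage-2 mean differences in S and its complement.
#' @param q an \code{\link{derive_quantities}} result with valid
#'   \code{t_S_F}, \code{t_Sc_F}.
#' @param p_combine combination weight in (0, 1).
#' @return A list with \code{D_S_N_F}, \code{D_Sc_N_F}, \code{D_F_N}.
#' @examples
#' d <- asd_design(200, 200, sigma = 13.2, p_S = 0.5)
#' q <- derive_quantities(d, s_X = 100, s_V = 100)
#' naive_selected_f(5.4, 6.0, 7.42, 3.82, q, 0.5)
#' @export
naive_selected_f <- function(x, y, v, w, q, p_combine) {
  if (p_combine <= 0 || p_combine >= 1)
    stop("'p_combine' must lie in (0, 1)", call. = FALSE)
  if (!is.finite(q$t_S_F) || !is.finite(q$t_Sc_F))
    stop("stage-2 weights undefined: was 's_V' supplied to derive_quantities()?",
         call. = FALSE)
  dS  <- q$t_S_F  * x + (1 - q$t_S_F)  * v
  dSc <- q$t_Sc_F * y + (1 - q$t_Sc_F) * w
  list(D_S_N_F = dS, D_Sc_N_F = dSc,
       D_F_N = p_combine * dS + (1 - p_combine) * dSc)
}

# b-margin term of the selection threshold, with the prevalence replaced by
# its stage-1 estimate s_X/n1 so the same expression serves the known- and
# unknown-prevalence cases (they coincide when s_X = p_S n1).
.margin <- function(b, s_X, n1) b / (1 - s_X / n1)

#' Conditionally unbiased (UMVUE) estimator when S is selected
#'
#' Rao-Blackwell closed form
#' \deqn{D_{S,U} = D_{S,N} - \frac{\tau_U^2}{\sqrt{\sigma_X^2+\tau_U^2}}
#'   \frac{\phi(f_U)}{\Phi(f_U)},}
#' with \eqn{f_U = \sqrt{\sigma_X^2+\tau_U^2}/\sigma_X^2 \,
#' (D_{S,N} - y - b/(1 - s_X/n_1))}. The correction is strictly positive, so
#' the UMVUE always lies below the naive estimate; it vanishes as the observed
#' separation between S and its complement grows.
#'
#' @param x,y stage-1 mean differences.
#' @param u stage-2 mean difference in S.
#' @param q a \code{\link{derive_quantities}} result.
#' @param b selection margin.
#' @param B optional futility bound: when supplied (and the trial continued),
#'   the truncation threshold inside \code{f_U} becomes
#'   \code{max(B, y + b/(1 - s_X/n1))}.
#' @return A list with \code{D_S_U}, \code{f_U} and \code{D_S_N}.
#' @examples
#' d <- asd_design(200, 200, sigma = 13.2, p_S = 0.5)
#' q <- derive_quantities(d, s_X = 100)
#' umvue_selected_s(6.5, 5.6, 7.42, q, b = 0)  # D_S_U = 6.67
#' @export
umvue_selected_s <- function(x, y, u, q, b = 0, B = NULL) {
  d_n <- naive_selected_s(x, u, q$t_S)
  rt <- sqrt(q$sigma2_X + q$tau2_U)
  thr <- y + .margin(b, q$s_X, q$n1)
  if (!is.null(B)) thr <- max(B, thr)
  f_U <- rt / q$sigma2_X * (d_n - thr)
  list(D_S_U = d_n - q$tau2_U / rt * mills_ratio(f_U),
       f_U = f_U, D_S_N = d_n)
}

#' Conditionally unbiased (UMVUE) estimators when F is selected
#'
#' Rao-Blackwell closed forms for the two stratum effects and their
#' combination:
#' \deqn{D_{S,U}^F = D_{S,N}^F + \frac{\tau_V^2}{\sqrt{\sigma_X^2+\tau_V^2}}
#'   \frac{\phi(f_V)}{\Phi(f_V)}, \quad
#'   D_{S^c,U}^F = D_{S^c,N}^F - \frac{\tau_W^2}{\sqrt{\sigma_Y^2+\tau_W^2}}
#'   \frac{\phi(f_W)}{\Phi(f_W)},}
#' with \eqn{f_V = \sqrt{\sigma_X^2+\tau_V^2}/\sigma_X^2\,(y + m - D_{S,N}^F)}
#' and \eqn{f_W = \sqrt{\sigma_Y^2+\tau_W^2}/\sigma_Y^2\,(D_{S^c,N}^F - x - m)},
#' \eqn{m = b/(1 - s_X/n_1)}. The S-component is corrected upward (selection
#' against S makes its naive estimate pessimistic) and the complement
#' component downward. The combination \code{D_F_U} uses weight
#' \code{p_combine} (\code{p_S} known, or \code{s_X/n1} estimated).
#'
#' With a futility bound \code{B} the continuation region doubly truncates the
#' S-component conditioning,
#' \deqn{D_{S,U}^F = D_{S,N}^F + \frac{\tau_V^2}{\sqrt{\sigma_X^2+\tau_V^2}}
#'   \frac{\phi(f_V)-\phi(f_V^B)}{\Phi(f_V)-\Phi(f_V^B)},}
#' with \eqn{f_V^B} built from the lower threshold
#' \eqn{(B - (1-p) y)/p}, and the \eqn{f_W} threshold becomes
#' \eqn{\max\{x - m,\ (B - p x)/(1-p)\}}. Futility variants require known
#' prevalence. Under a futility rule the naive combination \code{D_F_N} is no
#' longer unbiased; the returned \code{futility_adjusted} flag records that
#' the adjusted forms were used.
#'
#' @param x,y stage-1 mean differences.
#' @param v,w stage-2 mean differences in S and its complement.
#' @param q a \code{\link{derive_quantities}} result with \code{s_V} set.
#' @param b selection margin.
#' @param p_combine weight for the full-population combination, in (0, 1).
#' @param B optional futility bound (known prevalence only).
#' @param p_S known prevalence; required with \code{B}.
#' @return A list with \code{D_S_U_F}, \code{D_Sc_U_F}, \code{D_F_U},
#'   \code{f_V}, \code{f_W}, the naive components, and, under futility,
#'   \code{f_V_B} and \code{futility_adjusted = TRUE}.
#' @examples
#' d <- asd_design(200, 200, sigma = 13.2, p_S = 0.5)
#' q <- derive_quantities(d, s_X = 100, s_V = 100)
#' umvue_selected_f(5.4, 6.0, 7.42, 3.82, q, b = 0, p_combine = 0.5)
#' @export
umvue_selected_f <- function(x, y, v, w, q, b = 0, p_combine,
                             B = NULL, p_S = NULL) {
  nv <- naive_selected_f(x, y, v, w, q, p_combine)
  m <- .margin(b, q$s_X, q$n1)
  rtV <- sqrt(q$sigma2_X + q$tau2_V)
  rtW <- sqrt(q$sigma2_Y + q$tau2_W)
  f_V <- rtV / q$sigma2_X * (y + m - nv$D_S_N_F)
  if (is.null(B)) {
    d_s_u  <- nv$D_S_N_F + q$tau2_V / rtV * mills_ratio(f_V)
    f_W <- rtW / q$sigma2_Y * (nv$D_Sc_N_F - x - m)
    d_sc_u <- nv$D_Sc_N_F - q$tau2_W / rtW * mills_ratio(f_W)
    out <- list(D_S_U_F = d_s_u, D_Sc_U_F = d_sc_u,
                D_F_U = p_combine * d_s_u + (1 - p_combine) * d_sc_u,
                f_V = f_V, f_W = f_W,
                D_S_N_F = nv$D_S_N_F, D_Sc_N_F = nv$D_Sc_N_F,
                D_F_N = nv$D_F_N, futility_adjusted = FALSE)
    return(out)
  }
  if (is.null(p_S))
    stop("futility-adjusted estimators require known prevalence 'p_S'",
         call. = FALSE)
  # continuation region given Q_F: x in ((B - (1-p)y)/p, y + m]; non-empty iff
  # the observed data lie inside it
  f_V_B <- rtV / q$sigma2_X * ((B - (1 - p_S) * y) / p_S - nv$D_S_N_F)
  denom <- stats::pnorm(f_V) - stats::pnorm(f_V_B)
  if (denom <= 0)
    stop(paste0("empty truncation interval under futility bound B = ", B,
                ": observed data lie outside the continuation region"),
         call. = FALSE)
  d_s_u <- nv$D_S_N_F + q$tau2_V / rtV *
    (stats::dnorm(f_V) - stats::dnorm(f_V_B)) / denom
  thrW <- max(x - m, (B - p_S * x) / (1 - p_S))
  f_W <- rtW / q$sigma2_Y * (nv$D_Sc_N_F - thrW)
  d_sc_u <- nv$D_Sc_N_F - q$tau2_W / rtW * mills_ratio(f_W)
  list(D_S_U_F = d_s_u, D_Sc_U_F = d_sc_u,
       D_F_U = p_combine * d_s_u + (1 - p_combine) * d_sc_u,
       f_V = f_V, f_V_B = f_V_B, f_W = f_W,
       D_S_N_F = nv$D_S_N_F, D_Sc_N_F = nv$D_Sc_N_F,
       D_F_N = nv$D_F_N, futility_adjusted = TRUE)
}

#' Naive and conditionally unbiased estimates for an observed trial
#'
#' Applies the interim rule to the observed stage-1 data and computes, for the
#' selected branch, the naive two-stage estimate(s) and the Rao-Blackwell
#' conditionally unbiased estimate(s), with all intermediate quantities. When
#' the prevalence is unknown, \code{p_hat = s_X/n1} enters the selection
#' threshold and the unbiased combination, and the pooled estimate
#' \code{p_hat_star = (s_X + s_V)/(n1 + n2)} enters the naive combination.
#' With a futility bound set on the design (known prevalence only), the
#' futility-adjusted closed forms are used and \code{D_F_U} carries a warning
#' flag: unbiasedness of the combination is not claimed under futility.
#'
#' @param design an \code{\link{asd_design}}.
#' @param summaries an \code{\link{stage_summaries}} object.
#' @return An object of class \code{"asd_estimates"}: a list with
#'   \code{selected}, the branch estimates, intermediates (\code{f_U} or
#'   \code{f_V}/\code{f_W}), and \code{prevalence_used}.
#' @examples
#' d <- asd_design(200, 200, sigma = 13.2, p_S = 0.5)
#' estimate_trial(d, stage_summaries(d, x = 6.5, y = 5.6, u = 7.42))
#' @export
estimate_trial <- function(design, summaries) {
  stopifnot(inherits(design, "asd_design"), inherits(summaries, "asd_summaries"))
  if (!is.null(design$B) && !design$prevalence_known)
    stop("futility rule with unknown prevalence is unsupported", call. = FALSE)
  s <- summaries
  dec <- interim_decision(design, s$x, s$y, s$s_X)
  if (dec$outcome == "STOP_FUTILITY")
    stop("observed stage-1 data fall below the futility bound; no stage-2 estimate",
         call. = FALSE)
  q <- derive_quantities(design, s$s_X, s$s_V)
  prev <- list(p_S = design$p_S, p_hat = s$p_hat,
               p_hat_star = if (!is.null(s$s_V))
                 (s$s_X + s$s_V) / (design$n1 + design$n2) else NA_real_)
  if (dec$outcome == "SELECT_S") {
    if (is.null(s$u))
      stop("S was selected but no stage-2 summary 'u' was supplied", call. = FALSE)
    est <- umvue_selected_s(s$x, s$y, s$u, q, b = design$b, B = design$B)
    out <- c(list(selected = "SELECT_S"), est,
             list(futility_adjusted = !is.null(design$B)))
  } else {
    if (is.null(s$v))
      stop("F was selected but no stage-2 summaries 'v','w' were supplied",
           call. = FALSE)
    p_naive <- if (design$prevalence_known) design$p_S else prev$p_hat_star
    p_unb   <- if (design$prevalence_known) design$p_S else prev$p_hat
    est <- umvue_selected_f(s$x, s$y, s$v, s$w, q, b = design$b,
                            p_combine = p_unb, B = design$B,
                            p_S = if (design$prevalence_known) design$p_S else NULL)
    # naive combination uses the pooled prevalence estimate when unknown
    nv <- naive_selected_f(s$x, s$y, s$v, s$w, q, p_naive)
    est$D_F_N <- nv$D_F_N
    out <- c(list(selected = "SELECT_F"), est)
    if (isTRUE(est$futility_adjusted))
      out$warning <- "D_F_N and D_F_U are not guaranteed unbiased under a futility rule"
  }
  out$prevalence_used <- prev
  out$derived <- q
  class(out) <- "asd_estimates"
  out
}

#' @export
print.asd_estimates <- function(x, digits = 4, ...) {
  cat("Estimates after adaptive seamless subpopulation-selection trial\n")
  cat("  selected:", x$selected, "\n")
  fmt <- function(v) formatC(v, digits = digits, format = "g")
  if (x$selected == "SELECT_S") {
    cat(sprintf("  D_S,N = %s   D_S,U = %s   (f_U = %s)\n",
                fmt(x$D_S_N), fmt(x$D_S_U), fmt(x$f_U)))
  } else {
    cat(sprintf("  D_S,N^F = %s   D_Sc,N^F = %s   D_F,N = %s\n",
                fmt(x$D_S_N_F), fmt(x$D_Sc_N_F), fmt(x$D_F_N)))
    cat(sprintf("  D_S,U^F = %s   D_Sc,U^F = %s   D_F,U = %s\n",
                fmt(x$D_S_U_F), fmt(x$D_Sc_U_F), fmt(x$D_F_U)))
    cat(sprintf("  f_V = %s   f_W = %s\n", fmt(x$f_V), fmt(x$f_W)))
  }
  if (!is.null(x$warning)) cat("  note:", x$warning, "\n")
  invisible(x)
}
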