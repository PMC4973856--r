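#' Trial design for a two-stage adaptive seamless subpopulation-selection trial
#'
#' Fixes the design constants of a two-stage adaptive seamless design (ASD) in
#' which stage 1 recruits \code{n1} patients from the full population F (a
#' proportion \code{p_S} of whom belong to the pre-specified subpopulation S),
#' and the interim analysis selects either S or F to carry into stage 2, where
#' \code{n2} further patients are recruited from the selected population.
#' Randomization is stratified 1:1 within each of S and its complement, and
#' outcomes are normal with known common standard deviation \code{sigma}.
#'
#' The interim rule continues with S when the observed stage-1 mean difference
#' in S exceeds the full-population difference by more than the margin
#' \code{b}, i.e. \code{x > z + b}, equivalently \code{x > y + b/(1 - p_S)};
#' otherwise the trial continues with F. An optional futility bound \code{B}
#' stops the trial at the interim when \code{max(x, z) < B}.
#'
#' @param n1,n2 stage-1 and stage-2 total sample sizes (integers, >= 2).
#' @param sigma known outcome standard deviation (> 0).
#' @param p_S subpopulation prevalence in (0, 1), or the string
#'   \code{"unknown"} when the prevalence is to be estimated from the observed
#'   stage counts (the stage-1 count from S is then Binomial(\code{n1},
#'   \code{p_S}) in simulations).
#' @param b selection margin (any real; default 0).
#' @param B futility bound, or \code{NULL} (default) for no futility rule.
#' @param seed optional integer RNG seed carried along for simulation runs.
#'
#' @return An object of class \code{"asd_design"}: a list with the validated
#'   fields above plus \code{prevalence_known} (logical).
#' @examples
#' asd_design(n1 = 200, n2 = 200, sigma = 13.2, p_S = 0.5)
#' @export
asd_design <- function(n1, n2, sigma, p_S, b = 0, B = NULL, seed = NULL) {
  if (!is.numeric(n1) || length(n1) != 1L || n1 < 2 || n1 != round(n1))
    stop("'n1' must be a single integer >= 2", call. = FALSE)
  if (!is.numeric(n2) || length(n2) != 1L || n2 < 2 || n2 != round(n2))
    stop("'n2' must be a single integer >= 2", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("'sigma' must be a single positive number", call. = FALSE)
  prevalence_known <- !(identical(p_S, "unknown"))
  if (prevalence_known) {
    if (!is.numeric(p_S) || length(p_S) != 1L || p_S <= 0 || p_S >= 1)
      stop("'p_S' must be in (0, 1) or the string \"unknown\"", call. = FALSE)
  } else {
    p_S <- NA_real_
  }
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b))
    stop("'b' must be a single finite number", call. = FALSE)
  if (!is.null(B)) {
    if (!is.numeric(B) || length(B) != 1L || !is.finite(B))
      stop("'B' must be a single finite number or NULL", call. = FALSE)
  }
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(
    list(n1 = as.integer(n1), n2 = as.integer(n2), sigma = sigma,
         p_S = p_S, b = b, B = B, seed = seed,
         prevalence_known = prevalence_known),
    class = "asd_design")
}

#' @export
print.asd_design <- function(x, ...) {
  cat("Two-stage adaptive seamless design (subpopulation selection)\n")
  cat(sprintf("  n1 = %d, n2 = %d, sigma = %g\n", x$n1, x$n2, x$sigma))
  cat(sprintf("  prevalence p_S = %s, selection margin b = %g\n",
              if (x$prevalence_known) format(x$p_S) else "unknown", x$b))
  if (!is.null(x$B)) cat(sprintf("  futility bound B = %g\n", x$B))
  invisible(x)
}

#' Observed stage-wise summary statistics
#'
#' Collects the observed mean treatment differences of a completed (or
#' interim-complete) trial: stage-1 differences \code{x} (in S) and \code{y}
#' (in the complement), the stage-1 count \code{s_X} of patients from S, and
#' either the stage-2 difference \code{u} (S carried forward) or the pair
#' \code{v}, \code{w} with count \code{s_V} (F carried forward). The pooled
#' stage-1 difference \code{z} is derived as \code{p_hat * x + (1 - p_hat) * y}
#' with \code{p_hat = s_X / n1}.
#'
#' @param design an \code{\link{asd_design}}.
#' @param x,y observed stage-1 mean differences in S and its complement.
#' @param s_X stage-1 count of patients from S, strictly between 0 and
#'   \code{n1}. Defaults to \code{p_S * n1} when the prevalence is known.
#' @param u stage-2 mean difference in S when S was selected.
#' @param v,w stage-2 mean differences in S and its complement when F was
#'   selected.
#' @param s_V stage-2 count from S when F was selected; defaults to
#'   \code{p_S * n2} when the prevalence is known.
#'
#' @return An object of class \code{"asd_summaries"} with fields \code{x},
#'   \code{y}, \code{s_X}, \code{z}, \code{p_hat}, and exactly one of
#'   \code{u} or \code{v}/\code{w}/\code{s_V} populated.
#' @examples
#' d <- asd_design(200, 200, sigma = 13.2, p_S = 0.5)
#' stage_summaries(d, x = 6.5, y = 5.6, u = 7.42)
#' @export
stage_summaries <- function(design, x, y, s_X = NULL,
                            u = NULL, v = NULL, w = NULL, s_V = NULL) {
  stopifnot(inherits(design, "asd_design"))
  if (is.null(s_X)) {
    if (!design$prevalence_known)
      stop("'s_X' is required when the prevalence is unknown", call. = FALSE)
    s_X <- design$p_S * design$n1
  }
  if (s_X <= 0 || s_X >= design$n1)
    stop("'s_X' must lie strictly between 0 and n1", call. = FALSE)
  has_u <- !is.null(u)
  has_f <- !is.null(v) || !is.null(w)
  if (has_u && has_f)
    stop("supply either 'u' (S selected) or 'v','w' (F selected), not both",
         call. = FALSE)
  if (has_f && (is.null(v) || is.null(w)))
    stop("both 'v' and 'w' are required when F was selected", call. = FALSE)
  if (has_f) {
    if (is.null(s_V)) {
      if (!design$prevalence_known)
        stop("'s_V' is required when the prevalence is unknown", call. = FALSE)
      s_V <- design$p_S * design$n2
    }
    if (s_V <= 0 || s_V >= design$n2)
      stop("'s_V' must lie strictly between 0 and n2", call. = FALSE)
  } else {
    s_V <- NULL
  }
  p_hat <- s_X / design$n1
  structure(
    list(x = x, y = y, s_X = s_X, p_hat = p_hat,
         z = pooled_stage1(x, y, p_hat),
         u = u, v = v, w = w, s_V = s_V),
    class = "asd_summaries")
}

#' Variances, weights and sufficient statistics implied by the observed counts
#'
#' With 1:1 randomization within stratum, a stratum contributing \code{m}
#' patients yields a mean-difference variance of \code{4 sigma^2 / m}. This
#' returns every such variance together with the stage-1 pooling weights and
#' (when the stage-2 summaries are available) the scalar components of the
#' complete sufficient statistics used by the Rao-Blackwell estimators.
#'
#' @param design an \code{\link{asd_design}}.
#' @param s_X stage-1 count from S, strictly between 0 and \code{n1}. May be
#'   non-integral (expected count) in summary-level analytic work.
#' @param s_V stage-2 count from S when F is selected, strictly between 0 and
#'   \code{n2}, or \code{NULL} when S is selected.
#'
#' @return A list of class \code{"asd_derived"} with elements
#'   \code{sigma2_X}, \code{sigma2_Y}, \code{tau2_U}, \code{tau2_V},
#'   \code{tau2_W} (the last two \code{NA} without \code{s_V}), the weights
#'   \code{t_S}, \code{t_S_F}, \code{t_Sc_F}, \code{t_F}, and the counts.
#' @examples
#' d <- asd_design(200, 200, sigma = 13.2, p_S = 0.5)
#' q <- derive_quantities(d, s_X = 100, s_V = 100)
#' q$sigma2_X  # 4 * 13.2^2 / 100
#' @export
derive_quantities <- function(design, s_X, s_V = NULL) {
  stopifnot(inherits(design, "asd_design"))
  n1 <- design$n1; n2 <- design$n2; s2 <- design$sigma^2
  if (s_X <= 0 || s_X >= n1)
    stop(sprintf(
      "s_X = %g leaves an empty stratum in stage 1: sigma2_X or sigma2_Y undefined",
      s_X), call. = FALSE)
  if (!is.null(s_V) && (s_V <= 0 || s_V >= n2))
    stop(sprintf(
      "s_V = %g leaves an empty stratum in stage 2: tau2_V or tau2_W undefined",
      s_V), call. = FALSE)
  out <- list(
    sigma2_X = 4 * s2 / s_X,
    sigma2_Y = 4 * s2 / (n1 - s_X),
    tau2_U   = 4 * s2 / n2,
    tau2_V   = if (is.null(s_V)) NA_real_ else 4 * s2 / s_V,
    tau2_W   = if (is.null(s_V)) NA_real_ else 4 * s2 / (n2 - s_V),
    t_S      = s_X / (s_X + n2),
    t_S_F    = if (is.null(s_V)) NA_real_ else s_X / (s_X + s_V),
    t_Sc_F   = if (is.null(s_V)) NA_real_ else
                 (n1 - s_X) / (n1 + n2 - s_X - s_V),
    t_F      = n1 / (n1 + n2),
    s_X = s_X, s_V = s_V, n1 = n1, n2 = n2)
  class(out) <- "asd_derived"
  out
}

#' Pooled stage-1 mean difference
#'
#' The full-population stage-1 difference \code{z = p_hat x + (1 - p_hat) y},
#' the prevalence-weighted combination of the stratum differences.
#'
#' @param x,y stage-1 mean differences in S and its complement.
#' @param p_hat proportion of stage-1 patients from S, in (0, 1).
#' @return The pooled difference \code{z}.
#' @examples
#' pooled_stage1(6.5, 5.6, 0.5)  # 6.05
#' @export
pooled_stage1 <- function(x, y, p_hat) {
  if (any(p_hat <= 0) || any(p_hat >= 1))
    stop("'p_hat' must lie in (0, 1)", call. = FALSE)
  p_hat * x + (1 - p_hat) * y
}

#' Interim population-selection rule
#'
#' Continue with S iff \code{x > y + b/(1 - p_hat)} (equivalently
#' \code{x > z + b}); otherwise continue with F. Equality at the threshold
#' selects F, matching the rule's \code{<=} statement for F.
#'
#' @param x,y stage-1 mean differences in S and its complement.
#' @param p_hat proportion of stage-1 patients from S, in (0, 1).
#' @param b selection margin.
#' @return A list of class \code{"asd_selection"} with \code{outcome}
#'   (\code{"SELECT_S"} or \code{"SELECT_F"}) and \code{threshold_used}
#'   (\code{y + b/(1 - p_hat)}).
#' @examples
#' select_population(6.5, 5.6, 0.5, b = 0)$outcome  # "SELECT_S"
#' @export
select_population <- function(x, y, p_hat, b = 0) {
  if (p_hat <= 0 || p_hat >= 1)
    stop("'p_hat' must lie in (0, 1)", call. = FALSE)
  threshold <- y + b / (1 - p_hat)
  structure(
    list(outcome = if (x > threshold) "SELECT_S" else "SELECT_F",
         threshold_used = threshold),
    class = "asd_selection")
}

#' Interim futility rule
#'
#' Stop the trial at the interim when \code{max(x, z) < B}; continue (to the
#' population-selection rule) otherwise, including at equality.
#'
#' @param x stage-1 mean difference in S.
#' @param z pooled stage-1 mean difference.
#' @param B futility bound; \code{NULL} or \code{-Inf} disables the rule.
#' @return \code{"STOP_FUTILITY"} or \code{"CONTINUE"}.
#' @examples
#' apply_futility(6.5, 6.05, B = 7)  # "STOP_FUTILITY"
#' @export
apply_futility <- function(x, z, B = NULL) {
  if (is.null(B) || B == -Inf) return("CONTINUE")
  if (max(x, z) < B) "STOP_FUTILITY" else "CONTINUE"
}

#' Full interim decision: futility then selection
#'
#' @param design an \code{\link{asd_design}}.
#' @param x,y stage-1 mean differences.
#' @param s_X stage-1 count from S (defaults to \code{p_S * n1} when the
#'   prevalence is known).
#' @return An \code{"asd_selection"} whose \code{outcome} may additionally be
#'   \code{"STOP_FUTILITY"}; carries \code{futility_stat = max(x, z)} when a
#'   futility bound is set.
#' @export
interim_decision <- function(design, x, y, s_X = NULL) {
  stopifnot(inherits(design, "asd_design"))
  if (is.null(s_X)) {
    if (!design$prevalence_known)
      stop("'s_X' is required when the prevalence is unknown", call. = FALSE)
    s_X <- design$p_S * design$n1
  }
  p_hat <- s_X / design$n1
  z <- pooled_stage1(x, y, p_hat)
  if (identical(apply_futility(x, z, design$B), "STOP_FUTILITY")) {
    return(structure(list(outcome = "STOP_FUTILITY",
                          threshold_used = NA_real_,
                          futility_stat = max(x, z)),
                     class = "asd_selection"))
  }
  sel <- select_population(x, y, p_hat, design$b)
  sel$futility_stat <- if (is.null(design$B)) NA_real_ else max(x, z)
  sel
}
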