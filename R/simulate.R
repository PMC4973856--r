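# Vectorized closed-form estimators over per-replicate vectors. These mirror
# umvue_selected_s()/umvue_selected_f() but accept vectors of counts so the
# unknown-prevalence mode (random s_X, s_V) runs without per-rep loops.
.est_s_vec <- function(x, y, u, s_X, design) {
  s2 <- design$sigma^2; n1 <- design$n1; n2 <- design$n2
  s2X <- 4 * s2 / s_X; t2U <- 4 * s2 / n2
  t_S <- s_X / (s_X + n2)
  d_n <- t_S * x + (1 - t_S) * u
  rt <- sqrt(s2X + t2U)
  f_U <- rt / s2X * (d_n - y - design$b / (1 - s_X / n1))
  list(D_S_N = d_n, D_S_U = d_n - t2U / rt * mills_ratio(f_U))
}

.est_f_vec <- function(x, y, v, w, s_X, s_V, design) {
  s2 <- design$sigma^2; n1 <- design$n1; n2 <- design$n2
  s2X <- 4 * s2 / s_X; s2Y <- 4 * s2 / (n1 - s_X)
  t2V <- 4 * s2 / s_V; t2W <- 4 * s2 / (n2 - s_V)
  tSF <- s_X / (s_X + s_V); tScF <- (n1 - s_X) / (n1 + n2 - s_X - s_V)
  dS <- tSF * x + (1 - tSF) * v
  dSc <- tScF * y + (1 - tScF) * w
  m <- design$b / (1 - s_X / n1)
  rtV <- sqrt(s2X + t2V); rtW <- sqrt(s2Y + t2W)
  f_V <- rtV / s2X * (y + m - dS)
  f_W <- rtW / s2Y * (dSc - x - m)
  p_hat <- s_X / n1
  p_hat_star <- (s_X + s_V) / (n1 + n2)
  dSU <- dS + t2V / rtV * mills_ratio(f_V)
  dScU <- dSc - t2W / rtW * mills_ratio(f_W)
  p_n <- if (design$prevalence_known) design$p_S else p_hat_star
  p_u <- if (design$prevalence_known) design$p_S else p_hat
  list(D_S_N_F = dS, D_Sc_N_F = dSc,
       D_F_N = p_n * dS + (1 - p_n) * dSc,
       D_S_U_F = dSU, D_Sc_U_F = dScU,
       D_F_U = p_u * dSU + (1 - p_u) * dScU)
}

# Binomial stage counts with degenerate draws (0 or n) resampled; the event
# is vanishingly rare at the sample sizes studied, but an empty stratum makes
# the stratum variance undefined, so conditioning on a valid trial is made
# explicit and the number of resampled draws is reported.
.rbinom_nondegenerate <- function(n_draws, size, prob) {
  s <- stats::rbinom(n_draws, size, prob)
  resampled <- 0L
  bad <- which(s == 0L | s == size)
  while (length(bad)) {
    resampled <- resampled + length(bad)
    s[bad] <- stats::rbinom(length(bad), size, prob)
    bad <- bad[s[bad] == 0L | s[bad] == size]
  }
  list(counts = s, resampled = resampled)
}

#' Simulate two-stage adaptive seamless trials at the summary-statistic level
#'
#' Draws, for each replicate, the stage-1 mean differences
#' \code{X ~ N(theta_S, 4 sigma^2/s_X)} and
#' \code{Y ~ N(theta_Sc, 4 sigma^2/(n1 - s_X))}, applies the futility rule
#' (if any) and then the selection rule, and draws the appropriate stage-2
#' summary: \code{U} when S continues, or \code{V}, \code{W} when F
#' continues. With known prevalence \code{s_X = p_S n1} and
#' \code{s_V = p_S n2} are fixed; in \code{"unknown"} mode they are
#' Binomial(\code{n1}, \code{p_S}) and Binomial(\code{n2}, \code{p_S}) draws
#' (degenerate draws resampled and counted).
#'
#' @param design an \code{\link{asd_design}} (its \code{p_S} is the true
#'   prevalence in either mode).
#' @param theta_S,theta_Sc true mean differences.
#' @param n_reps number of replicates.
#' @param seed integer seed; defaults to the design's seed.
#' @param prevalence_mode \code{"known"} (fixed counts) or \code{"unknown"}
#'   (binomial counts).
#' @return A data frame with one row per replicate: \code{s_X}, \code{x},
#'   \code{y}, \code{z}, \code{selected} (\code{"SELECT_S"},
#'   \code{"SELECT_F"} or \code{"STOP_FUTILITY"}), \code{u}, \code{s_V},
#'   \code{v}, \code{w} (\code{NA} off-branch). Attribute
#'   \code{"resampled_draws"} counts resampled degenerate binomials.
#' @examples
#' d <- asd_design(200, 200, sigma = 1, p_S = 0.5, seed = 1)
#' head(simulate_trials(d, theta_S = 0.2, theta_Sc = 0, n_reps = 5))
#' @export
simulate_trials <- function(design, theta_S, theta_Sc, n_reps,
                            seed = design$seed,
                            prevalence_mode = c("known", "unknown")) {
  stopifnot(inherits(design, "asd_design"), n_reps >= 1)
  prevalence_mode <- match.arg(prevalence_mode)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n1 <- design$n1; n2 <- design$n2; s2 <- design$sigma^2
  p <- design$p_S
  if (!design$prevalence_known || is.na(p))
    stop("simulation requires the true prevalence 'p_S' on the design",
         call. = FALSE)
  resampled <- 0L
  if (prevalence_mode == "unknown") {
    rb <- .rbinom_nondegenerate(n_reps, n1, p)
    s_X <- rb$counts; resampled <- rb$resampled
  } else {
    s_X <- rep(p * n1, n_reps)
  }
  x <- stats::rnorm(n_reps, theta_S, sqrt(4 * s2 / s_X))
  y <- stats::rnorm(n_reps, theta_Sc, sqrt(4 * s2 / (n1 - s_X)))
  p_hat <- s_X / n1
  z <- p_hat * x + (1 - p_hat) * y
  selected <- ifelse(x > y + design$b / (1 - p_hat), "SELECT_S", "SELECT_F")
  if (!is.null(design$B)) selected[pmax(x, z) < design$B] <- "STOP_FUTILITY"
  u <- v <- w <- rep(NA_real_, n_reps)
  s_V <- rep(NA_real_, n_reps)
  iS <- which(selected == "SELECT_S")
  iF <- which(selected == "SELECT_F")
  if (length(iS))
    u[iS] <- stats::rnorm(length(iS), theta_S, sqrt(4 * s2 / n2))
  if (length(iF)) {
    if (prevalence_mode == "unknown") {
      rb <- .rbinom_nondegenerate(length(iF), n2, p)
      s_V[iF] <- rb$counts; resampled <- resampled + rb$resampled
    } else {
      s_V[iF] <- p * n2
    }
    v[iF] <- stats::rnorm(length(iF), theta_S, sqrt(4 * s2 / s_V[iF]))
    w[iF] <- stats::rnorm(length(iF), theta_Sc, sqrt(4 * s2 / (n2 - s_V[iF])))
  }
  out <- data.frame(s_X = s_X, x = x, y = y, z = z, selected = selected,
                    u = u, s_V = s_V, v = v, w = w)
  attr(out, "resampled_draws") <- resampled
  out
}

.mc_row <- function(branch, estimator, est, truth, SE) {
  n <- length(est)
  err <- est - truth
  mse <- mean(err^2)
  mse_mcse <- stats::sd(err^2) / sqrt(n)
  data.frame(branch = branch, estimator = estimator, n = n,
             mean = mean(est), bias = mean(err),
             bias_mcse = stats::sd(est) / sqrt(n),
             mse = mse, mse_mcse = mse_mcse,
             rmse_over_se = sqrt(mse) / SE,
             rmse_over_se_mcse = mse_mcse / (2 * sqrt(mse)) / SE)
}

#' Monte Carlo study of conditional bias and MSE of all estimators
#'
#' Simulates \code{n_reps} trials at a fixed truth and reports, conditional on
#' each selection branch, the mean, bias, MSE and \code{sqrt(MSE)/SE} of the
#' naive and conditionally unbiased estimators, each with its Monte Carlo
#' standard error. The S-branch estimand is \code{theta_S}; the F-branch
#' estimand is \code{theta_F = p_S theta_S + (1 - p_S) theta_Sc} (true
#' prevalence in either mode). SE normalizers are those of
#' \code{\link{bias_curve}}.
#'
#' @inheritParams simulate_trials
#' @param se_mode passed to the SE normalizer (see \code{\link{bias_curve}}).
#' @return An object of class \code{"asd_mc"}: a long data frame with one row
#'   per (branch, estimator), plus attributes \code{selection_freq},
#'   \code{futility_freq}, \code{resampled_draws}, \code{seed},
#'   \code{theta_S}, \code{theta_Sc}, \code{theta_F}. Branches never selected
#'   are absent, not zero-filled.
#' @examples
#' d <- asd_design(200, 200, sigma = 1, p_S = 0.5, seed = 1)
#' run_mc_study(d, theta_S = 0.2, theta_Sc = 0, n_reps = 2000)
#' @export
run_mc_study <- function(design, theta_S, theta_Sc, n_reps,
                         seed = design$seed,
                         prevalence_mode = c("known", "unknown"),
                         se_mode = c("pooled", "printed")) {
  prevalence_mode <- match.arg(prevalence_mode)
  if (n_reps < 1e4)
    warning("n_reps < 10^4: Monte Carlo standard errors will be large")
  sims <- simulate_trials(design, theta_S, theta_Sc, n_reps, seed,
                          prevalence_mode)
  se <- .se_norm(design, match.arg(se_mode))
  p <- design$p_S
  theta_F <- p * theta_S + (1 - p) * theta_Sc
  rows <- list()
  iS <- sims$selected == "SELECT_S"
  iF <- sims$selected == "SELECT_F"
  if (any(iS)) {
    es <- .est_s_vec(sims$x[iS], sims$y[iS], sims$u[iS], sims$s_X[iS], design)
    rows <- c(rows, list(
      .mc_row("S", "D_S_N", es$D_S_N, theta_S, se$SE_S),
      .mc_row("S", "D_S_U", es$D_S_U, theta_S, se$SE_S)))
  }
  if (any(iF)) {
    ef <- .est_f_vec(sims$x[iF], sims$y[iF], sims$v[iF], sims$w[iF],
                     sims$s_X[iF], sims$s_V[iF], design)
    rows <- c(rows, list(
      .mc_row("F", "D_S_N_F", ef$D_S_N_F, theta_S, se$SE_F),
      .mc_row("F", "D_Sc_N_F", ef$D_Sc_N_F, theta_Sc, se$SE_F),
      .mc_row("F", "D_F_N", ef$D_F_N, theta_F, se$SE_F),
      .mc_row("F", "D_S_U_F", ef$D_S_U_F, theta_S, se$SE_F),
      .mc_row("F", "D_Sc_U_F", ef$D_Sc_U_F, theta_Sc, se$SE_F),
      .mc_row("F", "D_F_U", ef$D_F_U, theta_F, se$SE_F)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "selection_freq") <- c(S = mean(iS), F = mean(iF))
  attr(out, "futility_freq") <- mean(sims$selected == "STOP_FUTILITY")
  attr(out, "resampled_draws") <- attr(sims, "resampled_draws")
  attr(out, "seed") <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  attr(out, "theta_S") <- theta_S
  attr(out, "theta_Sc") <- theta_Sc
  attr(out, "theta_F") <- theta_F
  class(out) <- c("asd_mc", "data.frame")
  out
}

#' Generate patient-level records for one trial stage
#'
#' Emits one row per patient with a normal outcome, stratified 1:1
#' randomization within stratum, and stratum means differing by the true
#' treatment effect. Summarizing the table with
#' \code{\link{summarize_patient_data}} reproduces the summary-level
#' distributional model exactly (stratum mean difference with variance
#' \code{4 sigma^2 / m} for \code{m} patients).
#'
#' @param design an \code{\link{asd_design}} with known prevalence such that
#'   the per-stratum arm counts are even integers.
#' @param theta_S,theta_Sc true mean differences.
#' @param stage 1 or 2.
#' @param selection for stage 2: \code{"S"} or \code{"F"}.
#' @param seed integer seed.
#' @return A data frame with columns \code{patient_id}, \code{stage},
#'   \code{stratum} (\code{"S"}/\code{"Sc"}), \code{arm}
#'   (\code{"control"}/\code{"experimental"}), \code{outcome}.
#' @export
generate_patient_data <- function(design, theta_S, theta_Sc, stage = 1,
                                  selection = c("S", "F"),
                                  seed = design$seed) {
  stopifnot(inherits(design, "asd_design"), design$prevalence_known,
            stage %in% c(1, 2))
  selection <- match.arg(selection)
  if (!is.null(seed)) set.seed(as.integer(seed))
  p <- design$p_S; sigma <- design$sigma
  counts <- if (stage == 1) {
    c(S = p * design$n1, Sc = (1 - p) * design$n1)
  } else if (selection == "S") {
    c(S = design$n2, Sc = 0)
  } else {
    c(S = p * design$n2, Sc = (1 - p) * design$n2)
  }
  rows <- list()
  id0 <- 0L
  for (st in names(counts)) {
    m <- counts[[st]]
    if (m == 0) next
    if (m != round(m) || (m %% 2) != 0)
      stop(sprintf("stratum %s count %g is not an even integer; patient-level mode needs even per-stratum arm splits", st, m),
           call. = FALSE)
    theta <- if (st == "S") theta_S else theta_Sc
    arm <- rep(c("control", "experimental"), each = m / 2)
    mu <- ifelse(arm == "control", 0, theta)
    rows[[st]] <- data.frame(
      patient_id = id0 + seq_len(m), stage = stage, stratum = st,
      arm = arm, outcome = stats::rnorm(m, mu, sigma))
    id0 <- id0 + m
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Summarize patient-level records into stage-wise mean differences
#'
#' @param patients a data frame in the format of
#'   \code{\link{generate_patient_data}} (both stages may be concatenated).
#' @return A list with \code{x}, \code{y}, \code{s_X} from stage 1, and from
#'   stage 2 either \code{u} (only S present) or \code{v}, \code{w},
#'   \code{s_V}.
#' @export
summarize_patient_data <- function(patients) {
  stopifnot(all(c("stage", "stratum", "arm", "outcome") %in% names(patients)))
  diff_of_means <- function(d) {
    mean(d$outcome[d$arm == "experimental"]) -
      mean(d$outcome[d$arm == "control"])
  }
  s1 <- patients[patients$stage == 1, ]
  out <- list(
    x = diff_of_means(s1[s1$stratum == "S", ]),
    y = diff_of_means(s1[s1$stratum == "Sc", ]),
    s_X = sum(s1$stratum == "S"))
  s2 <- patients[patients$stage == 2, ]
  if (nrow(s2)) {
    if (any(s2$stratum == "Sc")) {
      out$v <- diff_of_means(s2[s2$stratum == "S", ])
      out$w <- diff_of_means(s2[s2$stratum == "Sc", ])
      out$s_V <- sum(s2$stratum == "S")
    } else {
      out$u <- diff_of_means(s2)
    }
  }
  out
}

#' Brute-force Rao-Blackwell oracle when S is selected
#'
#' Recomputes the conditional expectation \eqn{E[U \mid Y = y, Z_S = z_S,
#' X > c]} defining the UMVUE by 1-D quadrature over \code{U}, with
#' \eqn{Z_S = (\tau_U/\sigma_X) X + (\sigma_X/\tau_U) U} the sufficient
#' statistic and \eqn{c = \max\{B,\ y + b/(1 - s_X/n_1)\}} the selection
#' (and, optionally, futility) threshold. Used as an independent check of the
#' closed form: the result must be invariant to the probe mean
#' \code{theta_probe} placed in the integrand (sufficiency).
#'
#' @param y observed stage-1 complement difference.
#' @param z_S observed value of the sufficient statistic.
#' @param q a \code{\link{derive_quantities}} result.
#' @param b selection margin.
#' @param theta_probe mean placed in the Gaussian integrand; the answer must
#'   not depend on it.
#' @param B optional futility bound.
#' @param abs.tol quadrature tolerance.
#' @return The conditional expectation.
#' @export
rb_oracle_selected_s <- function(y, z_S, q, b = 0, theta_probe = 0,
                                 B = NULL, abs.tol = 1e-12) {
  sx <- sqrt(q$sigma2_X); tu <- sqrt(q$tau2_U)
  thr <- y + .margin(b, q$s_X, q$n1)
  if (!is.null(B)) thr <- max(B, thr)
  x_of_u <- function(uu) (sx / tu) * z_S - (q$sigma2_X / q$tau2_U) * uu
  wfun <- function(uu) stats::dnorm(uu, theta_probe, tu) *
    stats::dnorm(x_of_u(uu), theta_probe, sx)
  # X decreases in U along fixed Z_S, so X > thr corresponds to U < u_max
  u_max <- ((sx / tu) * z_S - thr) * q$tau2_U / q$sigma2_X
  den <- stats::integrate(wfun, -Inf, u_max, abs.tol = abs.tol)$value
  if (den <= 0) stop("empty truncation region in oracle", call. = FALSE)
  num <- stats::integrate(function(uu) uu * wfun(uu), -Inf, u_max,
                          abs.tol = abs.tol)$value
  num / den
}

#' Brute-force Rao-Blackwell oracle for the S-component when F is selected
#'
#' Quadrature version of \eqn{E[V \mid Y, Z_S^F, \text{continuation}]} with
#' \eqn{Z_S^F = (\tau_V/\sigma_X) X + (\sigma_X/\tau_V) V}; the continuation
#' region is \eqn{X \le y + b/(1 - s_X/n_1)} intersected, under a futility
#' bound, with \eqn{X \ge (B - (1 - p_S) y)/p_S}.
#'
#' @param y observed stage-1 complement difference.
#' @param z_SF observed sufficient statistic.
#' @param q a \code{\link{derive_quantities}} result with \code{s_V} set.
#' @param b selection margin.
#' @param theta_probe probe mean (answer must be invariant to it).
#' @param B optional futility bound; requires \code{p_S}.
#' @param p_S known prevalence (only needed with \code{B}).
#' @param abs.tol quadrature tolerance.
#' @return The conditional expectation.
#' @export
rb_oracle_selected_f <- function(y, z_SF, q, b = 0, theta_probe = 0,
                                 B = NULL, p_S = NULL, abs.tol = 1e-12) {
  sx <- sqrt(q$sigma2_X); tv <- sqrt(q$tau2_V)
  R <- y + .margin(b, q$s_X, q$n1)
  x_of_v <- function(vv) (sx / tv) * z_SF - (q$sigma2_X / q$tau2_V) * vv
  wfun <- function(vv) stats::dnorm(vv, theta_probe, tv) *
    stats::dnorm(x_of_v(vv), theta_probe, sx)
  v_lo <- ((sx / tv) * z_SF - R) * q$tau2_V / q$sigma2_X
  if (is.null(B)) {
    v_hi <- Inf
  } else {
    if (is.null(p_S)) stop("'p_S' required with a futility bound", call. = FALSE)
    L <- (B - (1 - p_S) * y) / p_S
    v_hi <- ((sx / tv) * z_SF - L) * q$tau2_V / q$sigma2_X
    if (v_hi <= v_lo) stop("empty truncation region in oracle", call. = FALSE)
  }
  den <- stats::integrate(wfun, v_lo, v_hi, abs.tol = abs.tol)$value
  if (den <= 0) stop("empty truncation region in oracle", call. = FALSE)
  num <- stats::integrate(function(vv) vv * wfun(vv), v_lo, v_hi,
                          abs.tol = abs.tol)$value
  num / den
}
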