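#' Read a trial design from a JSON or YAML file
#'
#' Accepts keys \code{n1}, \code{n2}, \code{sigma}, \code{p_S} (a number in
#' (0,1) or the string \code{"unknown"}), and optionally \code{b} (default 0),
#' \code{B} and \code{seed}. Validation errors name the offending field.
#'
#' @param path path to a \code{.json}, \code{.yaml} or \code{.yml} file.
#' @return An \code{\link{asd_design}}.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (k in c("n1", "n2", "sigma", "p_S"))
    if (is.null(cfg[[k]]))
      stop("design config is missing required field '", k, "'", call. = FALSE)
  asd_design(n1 = cfg$n1, n2 = cfg$n2, sigma = cfg$sigma, p_S = cfg$p_S,
             b = if (is.null(cfg$b)) 0 else cfg$b,
             B = cfg$B, seed = cfg$seed)
}

#' Read observed trial summaries from JSON or patient-level CSV
#'
#' A JSON file must hold \code{x}, \code{y}, optionally \code{s_X}, and
#' either \code{u} or \code{v}, \code{w} (and \code{s_V}). A CSV file is
#' taken to be patient-level records with columns \code{stage},
#' \code{stratum}, \code{arm}, \code{outcome} and is summarized internally.
#'
#' @param path input file path.
#' @param design the matching \code{\link{asd_design}}.
#' @return An \code{\link{stage_summaries}} object.
#' @export
read_trial_summaries <- function(path, design) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    s <- summarize_patient_data(utils::read.csv(path))
  } else {
    s <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  stage_summaries(design, x = s$x, y = s$y, s_X = s$s_X,
                  u = s$u, v = s$v, w = s$w, s_V = s$s_V)
}

#' Flatten an estimate set into a long data frame
#'
#' One row per reported quantity (estimates, f-arguments, prevalences), with
#' stable names matching the estimator notation; the standard long format
#' written by \code{\link{write_results}}.
#'
#' @param x an \code{"asd_estimates"} object.
#' @param ... unused.
#' @return A data frame with columns \code{quantity} and \code{value}.
#' @export
as.data.frame.asd_estimates <- function(x, ...) {
  keep <- c("D_S_N", "D_S_U", "f_U", "D_S_N_F", "D_Sc_N_F", "D_F_N",
            "D_S_U_F", "D_Sc_U_F", "D_F_U", "f_V", "f_V_B", "f_W")
  vals <- x[intersect(keep, names(x))]
  prev <- x$prevalence_used
  vals <- c(vals, list(p_S = prev$p_S, p_hat = prev$p_hat,
                       p_hat_star = prev$p_hat_star))
  data.frame(quantity = names(vals), value = unlist(vals, use.names = FALSE),
             row.names = NULL)
}

#' Write results to CSV or JSON
#'
#' Estimate sets are flattened to the long format of
#' \code{\link{as.data.frame.asd_estimates}}; data frames (bias curves, Monte
#' Carlo tables) are written as-is. Floats are serialized at full precision;
#' \code{precision = "paper"} rounds estimates to 2 decimal places and
#' f-arguments starting with \code{f_U} to 1, the display convention of the
#' worked examples.
#'
#' @param result an \code{"asd_estimates"} object or a data frame.
#' @param path output path.
#' @param format \code{"csv"} or \code{"json"}.
#' @param precision \code{"full"} (default) or \code{"paper"}.
#' @return \code{path}, invisibly.
#' @export
write_results <- function(result, path, format = c("csv", "json"),
                          precision = c("full", "paper")) {
  format <- match.arg(format)
  precision <- match.arg(precision)
  df <- if (inherits(result, "asd_estimates")) as.data.frame(result)
        else as.data.frame(result)
  if (precision == "paper" && all(c("quantity", "value") %in% names(df))) {
    dp <- ifelse(df$quantity == "f_U", 1L, 2L)
    df$value <- round(df$value, dp)
  }
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  invisible(path)
}
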