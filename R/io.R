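#' Read and validate a count-data table
#'
#' Reads a CSV with a header, checks that the response column is a
#' non-negative integer count, converts character columns to factors, and
#' drops rows with missing values (reporting how many).
#'
#' @param path CSV file path.
#' @param response name of the count response column.
#' @param strict logical; if `FALSE`, responses within `1e-8` of an integer
#'   are coerced instead of rejected.
#' @return a validated data frame.
#' @export
read_count_data <- function(path, response, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = TRUE)
  if (!response %in% names(d))
    stop("response column '", response, "' not found", call. = FALSE)
  n0 <- nrow(d)
  d <- stats::na.omit(d)
  if (nrow(d) < n0)
    message("dropped ", n0 - nrow(d), " row(s) with missing values")
  y <- d[[response]]
  if (!is.numeric(y))
    stop("response column must be numeric counts", call. = FALSE)
  off <- abs(y - round(y))
  if (any(off > 0)) {
    bad <- which(off > if (strict) 0 else 1e-8)
    if (length(bad))
      stop("non-integer response in row(s): ",
           paste(utils::head(bad, 5), collapse = ", "),
           if (length(bad) > 5) " ...", call. = FALSE)
    d[[response]] <- round(y)
    y <- d[[response]]
  }
  if (any(y < 0)) stop("negative response values", call. = FALSE)
  d
}

#' Fit, diagnose and report on a count dataset
#'
#' End-to-end workflow: read (or accept) the data, fit the requested
#' family, compute the requested residual types, run the Shapiro-Wilk
#' goodness-of-fit diagnostics (replicated for RQR), optionally build a
#' simulated-envelope QQ payload, and write a JSON report plus a residual
#' CSV. Every random step is controlled by `seed`, which is echoed into the
#' report together with the package version and the configuration.
#'
#' @param data a data frame or a CSV path (then read via
#'   [read_count_data()]).
#' @param response response column name.
#' @param family model family.
#' @param formula count-part formula; defaults to the response against all
#'   other columns.
#' @param zero_formula zero-part formula (ZI families).
#' @param residual_types residual types to compute and test.
#' @param R RQR replicates for the replicated SW summary.
#' @param n_sim envelope simulations; `0` skips the envelope.
#' @param alpha level for the proportion-above-alpha summary.
#' @param seed integer seed.
#' @param out_json,out_csv optional output paths for the JSON report and
#'   the residual CSV.
#' @return invisibly, the report list (also serialized to `out_json` when
#'   given).
#' @export
run_diagnose <- function(data, response, family = "poisson",
                         formula = NULL, zero_formula = ~1,
                         residual_types = c("rqr", "pearson", "deviance",
                                            "mqr"),
                         R = 1000L, n_sim = 100L, alpha = 0.05,
                         seed = 1L,
                         out_json = NULL, out_csv = NULL) {
  if (is.character(data)) data <- read_count_data(data, response)
  if (is.null(formula))
    formula <- stats::reformulate(setdiff(names(data), response),
                                  response = response)
  residual_types <- match.arg(residual_types, several.ok = TRUE)
  fit <- fit_count_model(formula, data, family = family,
                         zero_formula = zero_formula)
  res <- list()
  gof <- list()
  for (rt in residual_types) {
    if (rt == "rqr") {
      res[[rt]] <- rqr(fit, seed = seed)
      gof[[rt]] <- replicated_sw(fit, R = R, alpha = alpha, seed = seed)
    } else {
      res[[rt]] <- residuals(fit, type = rt)
      gof[[rt]] <- sw_gof(res[[rt]])
    }
  }
  env <- if (n_sim >= 20L)
    qq_envelope(fit, type = residual_types[1], n_sim = n_sim, seed = seed)
  report <- list(
    package = "rqrdiag",
    version = as.character(utils::packageVersion("rqrdiag")),
    seed = seed,
    config = list(family = family,
                  count_formula = deparse(formula),
                  zero_formula = if (family %in% c("zip", "zinb"))
                    deparse(zero_formula),
                  residual_types = residual_types, R = R,
                  n_sim = n_sim, alpha = alpha),
    n = fit$n,
    converged = fit$converged,
    loglik = fit$loglik,
    aic = aic(fit),
    coefficients = list(estimate = as.list(fit$theta),
                        se = as.list(fit$se)),
    gof = lapply(gof, function(g)
      g[intersect(names(g), c("sw_pvalue", "mean_pvalue",
                              "prop_above_alpha", "alpha", "rtype",
                              "moments", "n"))]),
    envelope = if (!is.null(env))
      list(rtype = env$rtype, n_sim = env$n_sim,
           prop_outside = env$prop_outside)
  )
  if (!is.null(out_json))
    jsonlite::write_json(report, out_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(out_csv)) {
    tab <- data.frame(row = seq_len(fit$n), y = fit$y,
                      mu_hat = fit$mu_hat)
    for (rt in residual_types) tab[[rt]] <- as.numeric(res[[rt]])
    utils::write.csv(tab, out_csv, row.names = FALSE)
  }
  invisible(report)
}

#' Run a simulation scenario and write a tidy power table
#'
#' Thin wrapper around [count_scenario()] + [run_type1_power()] that
#' optionally writes the tidy result as CSV (with the seed and package
#' version recorded as comment-free columns).
#'
#' @param name scenario name (see [count_scenario()]).
#' @param n vector of sample sizes.
#' @param param scenario parameter (effect size, NB shape or `p_zero`).
#' @param reps replicates per cell.
#' @param alpha test level.
#' @param seed master seed.
#' @param models,residuals passed to [run_type1_power()].
#' @param out_csv optional output CSV path.
#' @return the tidy rejection-rate data frame.
#' @export
run_simulate <- function(name, n = 400L, param = NULL, reps = 1000L,
                         alpha = 0.05, seed = 1L,
                         models = c("true", "wrong"),
                         residuals = c("rqr", "mqr", "deviance", "pearson"),
                         out_csv = NULL) {
  sc <- count_scenario(name, n = n, param = param, reps = reps,
                       alpha = alpha, seed = seed)
  out <- run_type1_power(sc, models = models, residuals = residuals)
  out$seed <- seed
  out$version <- as.character(utils::packageVersion("rqrdiag"))
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}
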