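#' @include AllClasses.R synthetic-data.R
NULL

#' Normalize a dose-response panel
#'
#' Three conventions used across the assay readouts:
#' \describe{
#'   \item{reference_max_100}{the reference ligand's maximal observed
#'     response, per pathway, maps to 100 (luminescence-complementation
#'     convention: responses are expressed as \% of the reference ligand's
#'     maximum on the wild-type receptor).}
#'   \item{fold_over_lowest_dose}{each (ligand, pathway, experiment) trace is
#'     divided by its own response at the lowest concentration on the grid
#'     and rescaled to percent (resonance-transfer / fold-change convention).}
#'   \item{untreated_100}{the no-ligand control (records whose ligand id is
#'     \code{reference}) maps to 100 per (pathway, experiment)
#'     (endocytosis convention).}
#' }
#'
#' @param panel a \linkS4class{DoseResponsePanel}.
#' @param mode one of the three conventions above.
#' @param reference reference ligand id (for \code{reference_max_100}) or
#'   control id (for \code{untreated_100}).
#' @return a normalized \linkS4class{DoseResponsePanel}.
#' @export
normalizePanel <- function(panel,
                           mode = c("reference_max_100",
                                    "fold_over_lowest_dose",
                                    "untreated_100"),
                           reference = NULL) {
  mode <- match.arg(mode)
  df <- records(panel)
  if (mode == "reference_max_100") {
    if (is.null(reference))
      stop("mode 'reference_max_100' requires a reference ligand id")
    if (!reference %in% df$ligand)
      stop("reference ligand '", reference, "' not present in the panel")
    for (pw in unique(df$pathway)) {
      ref_max <- max(df$response[df$ligand == reference & df$pathway == pw])
      if (!is.finite(ref_max) || ref_max <= 0)
        stop("reference ligand '", reference, "' has non-positive maximum in ",
             "pathway '", pw, "'")
      sel <- df$pathway == pw
      df$response[sel] <- 100 * df$response[sel] / ref_max
    }
  } else if (mode == "fold_over_lowest_dose") {
    cmin <- min(df$concentration_M)
    key <- interaction(df$ligand, df$pathway, df$experiment, drop = TRUE)
    for (k in levels(key)) {
      sel <- key == k
      anchor <- df$response[sel & df$concentration_M == cmin]
      if (!length(anchor))
        stop("trace ", k, " lacks the lowest-dose anchor (",
             format(cmin), " M)")
      if (anchor[1] == 0)
        stop("trace ", k, " has a zero lowest-dose anchor")
      df$response[sel] <- 100 * df$response[sel] / anchor[1]
    }
  } else { # untreated_100
    if (is.null(reference))
      stop("mode 'untreated_100' requires the control id as 'reference'")
    ctl <- df$ligand == reference
    if (!any(ctl))
      stop("no-ligand control '", reference, "' not present in the panel")
    key <- interaction(df$pathway, df$experiment, drop = TRUE)
    for (k in levels(key)) {
      sel <- key == k
      c0 <- mean(df$response[sel & ctl])
      if (!is.finite(c0) || c0 == 0)
        stop("control '", reference, "' missing or zero for group ", k)
      df$response[sel] <- 100 * df$response[sel] / c0
    }
  }
  new("DoseResponsePanel", records = df, normalization = mode)
}

.fit_one <- function(df, ligand, pathway, experiment = NA_character_,
                     model = "hill_fixed_1", start = NULL, flat_tol = 1e-6) {
  n_expt <- length(unique(df$experiment))
  mk <- function(est = c(baseline = NA_real_, emax = NA_real_,
                         log10_ec50 = NA_real_, hill = NA_real_),
                 se = est * NA_real_, rss = NA_real_, converged = FALSE,
                 degenerate = FALSE) {
    new("FitResult", ligand = ligand, pathway = pathway,
        experiment = experiment, estimates = est, se = se, rss = rss,
        converged = converged, degenerate = degenerate,
        n_experiments_used = n_expt, model = model)
  }
  if (length(unique(df$concentration_M)) < 4L)
    stop("fitting requires >= 4 distinct concentrations (",
         ligand, " / ", pathway, ")")
  if (diff(range(df$response)) < flat_tol)
    return(mk(degenerate = TRUE))
  logc <- log10(df$concentration_M)
  lo <- min(logc) - 2
  hi <- max(logc) + 2
  if (is.null(start))
    start <- c(baseline = min(df$response), emax = max(df$response),
               log10_ec50 = mean(range(logc)), hill = 1)
  dat <- data.frame(logc = logc, y = df$response)
  free_hill <- model == "hill_free"
  form <- if (free_hill)
    y ~ baseline + (emax - baseline) / (1 + 10^(hill * (log10_ec50 - logc)))
  else
    y ~ baseline + (emax - baseline) / (1 + 10^(log10_ec50 - logc))
  pnames <- c("baseline", "emax", "log10_ec50", if (free_hill) "hill")
  fit <- tryCatch(
    minpack.lm::nlsLM(
      form, data = dat, start = as.list(start[pnames]),
      lower = c(-Inf, -Inf, lo, if (free_hill) 0.1),
      upper = c(Inf, Inf, hi, if (free_hill) 10),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(mk())
  cf <- stats::coef(fit)
  est <- c(baseline = unname(cf["baseline"]), emax = unname(cf["emax"]),
           log10_ec50 = unname(cf["log10_ec50"]),
           hill = if (free_hill) unname(cf["hill"]) else 1)
  se <- c(baseline = NA_real_, emax = NA_real_, log10_ec50 = NA_real_,
          hill = NA_real_)
  sm <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
  if (!is.null(sm)) se[rownames(sm)] <- sm[, "Std. Error"]
  rss <- sum(stats::residuals(fit)^2)
  conv <- isTRUE(fit$convInfo$isConv) ||
    is.null(fit$convInfo)  # nlsLM reports via convInfo when available
  mk(est = est, se = se, rss = rss, converged = conv)
}

#' Fit sigmoidal dose-response curves
#'
#' Nonlinear least-squares fit of the 4PL model on the log10-concentration
#' scale, per (ligand, pathway) in the panel. The default model fixes the
#' Hill slope at 1 (three estimated parameters); \code{"hill_free"} also
#' estimates the slope. \code{pooling = "combined"} fits all experiments of a
#' trace jointly; \code{"per_experiment"} fits each experiment separately,
#' reusing the combined estimates as starting values. log10 EC50 is bounded
#' to the concentration grid plus/minus 2 log units to prevent runaway
#' estimates on partial curves. Non-convergence and flat (degenerate) data
#' are flagged on the returned objects, never silently dropped.
#'
#' @param panel a \linkS4class{DoseResponsePanel}.
#' @param model \code{"hill_fixed_1"} (default) or \code{"hill_free"}.
#' @param pooling \code{"combined"} (default) or \code{"per_experiment"}.
#' @param flat_tol absolute response range below which a trace is flagged
#'   degenerate.
#' @return a named list of \linkS4class{FitResult} objects; names are
#'   \code{"ligand|pathway"} (combined) or
#'   \code{"ligand|pathway|experiment"} (per experiment).
#' @export
fitDoseResponse <- function(panel, model = c("hill_fixed_1", "hill_free"),
                            pooling = c("combined", "per_experiment"),
                            flat_tol = 1e-6) {
  model <- match.arg(model)
  pooling <- match.arg(pooling)
  df <- records(panel)
  out <- list()
  for (lig in unique(df$ligand)) {
    for (pw in unique(df$pathway[df$ligand == lig])) {
      sub <- df[df$ligand == lig & df$pathway == pw, ]
      comb <- .fit_one(sub, lig, pw, model = model, flat_tol = flat_tol)
      if (pooling == "combined") {
        out[[paste(lig, pw, sep = "|")]] <- comb
      } else {
        start <- if (comb@converged && !comb@degenerate) comb@estimates
                 else NULL
        for (ex in unique(sub$experiment)) {
          out[[paste(lig, pw, ex, sep = "|")]] <-
            .fit_one(sub[sub$experiment == ex, ], lig, pw, experiment = ex,
                     model = model, start = start, flat_tol = flat_tol)
        }
      }
    }
  }
  out
}

#' Tabulate fit results
#'
#' @param fits list of \linkS4class{FitResult} objects as returned by
#'   \code{\link{fitDoseResponse}}.
#' @return data.frame with one row per fit.
#' @export
fitTable <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    data.frame(ligand = f@ligand, pathway = f@pathway,
               experiment = f@experiment,
               baseline = f@estimates[["baseline"]],
               emax = f@estimates[["emax"]],
               log10_ec50 = f@estimates[["log10_ec50"]],
               hill = f@estimates[["hill"]],
               se_log10_ec50 = f@se[["log10_ec50"]],
               rss = f@rss, converged = f@converged,
               degenerate = f@degenerate,
               n_experiments = f@n_experiments_used,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
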