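#' @include AllClasses.R dose-response.R
NULL

.check_fit <- function(fit, label) {
  if (fit@degenerate)
    stop("fit ", label, " is degenerate (flat data); cannot compute bias")
  if (!fit@converged)
    stop("fit ", label, " did not converge; cannot compute bias")
  if (!is.finite(fit@estimates[["emax"]]) || fit@estimates[["emax"]] <= 0)
    stop("fit ", label, " has non-positive Emax; cannot compute bias")
  invisible(TRUE)
}

# delta-log(Emax/EC50) for one fit: log10(Emax) - log10(EC50[M])
.dlog <- function(fit) {
  log10(fit@estimates[["emax"]]) - fit@estimates[["log10_ec50"]]
}

#' Bias factor (beta value) from four dose-response fits
#'
#' Computes the delta-delta-log(Emax/EC50) bias statistic
#' \deqn{\beta = \log_{10}\!\left(
#'   \left[\frac{E_{max,P1}}{EC_{50,P1}}\,\frac{EC_{50,P2}}{E_{max,P2}}\right]_{lig}
#'   \times
#'   \left[\frac{E_{max,P2}}{EC_{50,P2}}\,\frac{EC_{50,P1}}{E_{max,P1}}\right]_{ref}
#' \right)}
#' with EC50 on the molar scale. Pathway 1 is G-protein dissociation and
#' pathway 2 beta-arrestin recruitment by convention, so beta > 0 denotes a
#' G-protein-biased ligand and beta < 0 an arrestin-biased one. All four fits
#' must be converged and non-degenerate with positive Emax.
#'
#' @param lig_p1,lig_p2 \linkS4class{FitResult} of the ligand in pathways 1/2.
#' @param ref_p1,ref_p2 \linkS4class{FitResult} of the reference ligand.
#' @return beta, in log10 units.
#' @export
biasFactor <- function(lig_p1, lig_p2, ref_p1, ref_p2) {
  .check_fit(lig_p1, "ligand/pathway-1")
  .check_fit(lig_p2, "ligand/pathway-2")
  .check_fit(ref_p1, "reference/pathway-1")
  .check_fit(ref_p2, "reference/pathway-2")
  (.dlog(lig_p1) - .dlog(lig_p2)) - (.dlog(ref_p1) - .dlog(ref_p2))
}

#' Bias factor directly from true 4PL parameters
#'
#' Convenience for computing beta from known generating parameters (e.g. a
#' \linkS4class{LigandProfile}) rather than fitted values.
#'
#' @param ligand,reference \linkS4class{LigandProfile} objects.
#' @param pair character(2): pathway 1 then pathway 2 ids.
#' @return beta, in log10 units.
#' @export
trueBias <- function(ligand, reference,
                     pair = c("gi_dissociation", "arrestin_recruitment")) {
  dl <- function(prof, pw) {
    p <- prof@pathways[[pw]]
    log10(p[["emax"]]) - p[["log10_ec50"]]
  }
  (dl(ligand, pair[1]) - dl(ligand, pair[2])) -
    (dl(reference, pair[1]) - dl(reference, pair[2]))
}

#' Per-experiment bias factors with mean and s.e.m.
#'
#' Computes one beta per matched experiment from per-experiment fits of the
#' ligand and the reference in both pathways, then summarizes as mean and
#' standard error of the mean. Classification follows the sign of the mean
#' when a one-sample t-test against zero is significant at \code{alpha}, and
#' \code{"balanced"} otherwise; a ligand whose per-experiment betas are all
#' exactly zero (the reference against itself) is always balanced.
#'
#' @param fits named list of per-experiment \linkS4class{FitResult} objects
#'   (names \code{"ligand|pathway|experiment"}), as from
#'   \code{fitDoseResponse(..., pooling = "per_experiment")}.
#' @param ligand,reference ligand ids present in \code{fits}.
#' @param pair character(2): pathway 1 then pathway 2 ids.
#' @param alpha significance level for the classification rule.
#' @return a \linkS4class{BiasResult}
#' @export
perExperimentBias <- function(fits, ligand, reference,
                              pair = c("gi_dissociation",
                                       "arrestin_recruitment"),
                              alpha = 0.05) {
  tab <- fitTable(fits)
  pick <- function(lig, pw) {
    sel <- tab$ligand == lig & tab$pathway == pw
    stats::setNames(which(sel), tab$experiment[sel])
  }
  idx <- list(lp1 = pick(ligand, pair[1]), lp2 = pick(ligand, pair[2]),
              rp1 = pick(reference, pair[1]), rp2 = pick(reference, pair[2]))
  common <- Reduce(intersect, lapply(idx, names))
  missing <- setdiff(unique(unlist(lapply(idx, names))), common)
  if (length(missing))
    stop("experiment ids not matched across all four ligand/pathway ",
         "combinations: ", paste(sort(missing), collapse = ", "))
  if (length(common) < 2L)
    stop("per-experiment bias requires >= 2 matched experiments")
  betas <- vapply(common, function(ex) {
    biasFactor(fits[[idx$lp1[[ex]]]], fits[[idx$lp2[[ex]]]],
               fits[[idx$rp1[[ex]]]], fits[[idx$rp2[[ex]]]])
  }, numeric(1))
  m <- mean(betas)
  s <- stats::sd(betas) / sqrt(length(betas))
  cls <- "balanced"
  if (stats::sd(betas) == 0) {
    if (m != 0) cls <- if (m > 0) "gi_biased" else "arrestin_biased"
  } else {
    p <- stats::t.test(betas, mu = 0)$p.value
    if (p < alpha) cls <- if (m > 0) "gi_biased" else "arrestin_biased"
  }
  new("BiasResult", ligand = ligand, reference = reference,
      pathway_pair = pair, beta = m, per_experiment_betas = betas,
      mean = m, sem = s, classification = cls)
}

.beta_groups <- function(x) {
  if (is(x, "BiasResult")) return(x@per_experiment_betas)
  as.numeric(x)
}

#' Many-vs-one comparison of bias factors (one-way ANOVA + Dunnett)
#'
#' One-way ANOVA across ligand groups of per-experiment betas, followed by
#' per-ligand comparisons against the reference group with Dunnett-style
#' multiplicity adjustment (\code{adjust = "none"} gives the unadjusted
#' per-comparison t-tests from the same linear model).
#'
#' @param bias_results named list: ligand id -> \linkS4class{BiasResult} or
#'   numeric vector of per-experiment betas. Must include the reference.
#' @param reference name of the reference group.
#' @param adjust \code{"dunnett"} (default) or \code{"none"}.
#' @return a \linkS4class{BiasComparison} with the ANOVA F statistic and
#'   adjusted per-ligand p-values.
#' @export
compareVsReference <- function(bias_results, reference,
                               adjust = c("dunnett", "none")) {
  adjust <- match.arg(adjust)
  if (!reference %in% names(bias_results))
    stop("reference group '", reference, "' absent from bias_results")
  groups <- lapply(bias_results, .beta_groups)
  sizes <- lengths(groups)
  if (any(sizes < 2L))
    stop("every group needs >= 2 observations; offending: ",
         paste(names(groups)[sizes < 2L], collapse = ", "))
  if (length(groups) < 3L)
    stop("need >= 2 ligand groups plus the reference")
  df <- data.frame(
    beta = unlist(groups, use.names = FALSE),
    ligand = factor(rep(names(groups), sizes),
                    levels = c(reference,
                               setdiff(names(groups), reference))))
  fit <- stats::aov(beta ~ ligand, data = df)
  fstat <- summary(fit)[[1]]$`F value`[1]
  if (adjust == "dunnett") {
    glht <- multcomp::glht(fit, linfct = multcomp::mcp(ligand = "Dunnett"))
    sm <- summary(glht)
    p <- as.numeric(sm$test$pvalues)
    names(p) <- sub(" - .*$", "", names(sm$test$coefficients))
  } else {
    cf <- summary.lm(fit)$coefficients
    rows <- grep("^ligand", rownames(cf))
    p <- cf[rows, "Pr(>|t|)"]
    names(p) <- sub("^ligand", "", rownames(cf)[rows])
  }
  new("BiasComparison", test = "anova_dunnett", statistic = fstat,
      p_values = p, reference = reference)
}

#' Two-group comparison of bias factors (two-tailed Student's t-test)
#'
#' Two-sample t-test on per-experiment betas; pooled-variance ("Student's")
#' by default, Welch available. When the pooled variance is zero with unequal
#' means, p is reported as 0 with a degenerate-variance warning; identical
#' constant groups give t = 0, p = 1.
#'
#' @param group_a,group_b numeric vectors of betas, or
#'   \linkS4class{BiasResult} objects (their per-experiment betas are used).
#' @param welch use the Welch (unequal-variance) test instead of pooled.
#' @return a \linkS4class{BiasComparison}
#' @export
compareTwo <- function(group_a, group_b, welch = FALSE) {
  a <- .beta_groups(group_a)
  b <- .beta_groups(group_b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs >= 2 observations")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      t <- 0; p <- 1
    } else {
      warning("zero pooled variance with unequal means; p reported as 0")
      t <- sign(mean(a) - mean(b)) * Inf; p <- 0
    }
  } else {
    tt <- stats::t.test(a, b, var.equal = !welch)
    t <- unname(tt$statistic); p <- tt$p.value
  }
  new("BiasComparison", test = "t_test_two_tailed", statistic = t,
      p_values = c(group_a_vs_group_b = p), reference = "group_b")
}

#' Tabulate bias results
#'
#' @param bias_results list of \linkS4class{BiasResult} objects.
#' @param comparison optional \linkS4class{BiasComparison} supplying
#'   per-ligand adjusted p-values.
#' @return data.frame: ligand, mean beta, sem, n, adjusted p, classification.
#' @export
biasTable <- function(bias_results, comparison = NULL) {
  do.call(rbind, lapply(bias_results, function(b) {
    p <- if (!is.null(comparison) && b@ligand %in% names(comparison@p_values))
      comparison@p_values[[b@ligand]] else NA_real_
    data.frame(ligand = b@ligand, reference = b@reference,
               mean_beta = b@mean, sem = b@sem,
               n = length(b@per_experiment_betas), p_adjusted = p,
               classification = b@classification,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
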