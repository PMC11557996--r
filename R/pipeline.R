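# End-to-end evolutionary-allometry workflow: specimen filtering, species
# aggregation, model-set fitting and AICc selection, bootstrap intervals,
# allometry classification and rate-distribution comparison.

#' Formula interface for phylogenetic (or ordinary) least squares
#'
#' Convenience wrapper that aligns a species-level trait table with a dated
#' tree, prunes the tree to the complete cases of the model variables,
#' builds the design matrix and calls [fit_pgls()] (lambda estimated) or
#' [gls_fit_fixed()] with `lambda = 0` for an OLS fit.
#'
#' @param formula model formula, e.g. `log10_scl ~ log10_hl + terrestrial`.
#' @param data data frame with one row per species and a `species` column
#'   matching tree tip labels.
#' @param tree a `"phylo"` object covering (at least) the species in `data`.
#' @param method `"lambda"` for PGLS with ML lambda, `"ols"` for ordinary
#'   least squares (lambda fixed at 0, independent residuals).
#' @param grid lambda profile grid passed to [fit_pgls()].
#' @param species_col name of the species column in `data`.
#' @return a `"pgls_fit"`.
#' @export
pgls <- function(formula, data, tree, method = c("lambda", "ols"),
                 grid = seq(0, 1, by = 0.01), species_col = "species") {
  method <- match.arg(method)
  vars <- all.vars(formula)
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars))
    stop("variables not in data: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  keep <- stats::complete.cases(data[vars])
  data <- data[keep, , drop = FALSE]
  sp <- as.character(data[[species_col]])
  unknown <- setdiff(sp, tree$tip.label)
  if (length(unknown))
    stop("species not in tree: ", paste(head(unknown, 5), collapse = ", "),
         call. = FALSE)
  tree <- prune_to_taxa(tree, sp)
  C <- vcv_matrix(tree, order = sp)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  label <- paste(deparse(formula), collapse = " ")
  if (method == "ols") {
    # true iid residuals: identity covariance, not the lambda = 0 transform
    # (whose diagonal varies when fossil tips shorten root-to-tip paths)
    I <- diag(nrow(C))
    dimnames(I) <- dimnames(C)
    fit <- gls_fit_fixed(y, X, I, lambda = 0, model = label,
                         correlation = "independent")
    fit$k_aicc <- fit$k + 1L  # no lambda parameter for OLS
    if (is.finite(fit$loglik)) fit$aicc <- aicc(fit$loglik, fit$k_aicc, fit$n)
  } else {
    fit <- fit_pgls(y, X, C, grid = grid, model = label)
  }
  fit$formula <- formula
  fit$species <- sp
  fit$mean_tip_depth <- mean(diag(C))
  fit
}

#' Filter specimens to (sexually) mature individuals
#'
#' Retains a specimen if its straight carapace length reaches a fraction
#' (default 60 percent) of the maximum recorded SCL for its species and sex.
#' Unsexed specimens are held to the threshold of the *larger* sex, so that
#' sexual size dimorphism cannot admit subadults of the larger sex.
#' Specimens flagged as somatically immature are excluded regardless;
#' specimens flagged with `include_override` are retained (unless somatically
#' immature), the escape hatch used for rare large-bodied species whose
#' available material sits just below the threshold. Every exclusion is
#' logged with the rule that caused it.
#'
#' @param specimens data frame with columns `species`, `specimen_id`,
#'   `scl_mm`, and optionally `sex` (`"female"`, `"male"`, anything else is
#'   treated as unsexed), `somatic_mature` (logical, default TRUE),
#'   `include_override` (logical, default FALSE).
#' @param maxima data frame of reference maxima: columns `species`, `sex`,
#'   `max_scl_mm`. Every species present in `specimens` must appear.
#' @param threshold maturity threshold as a fraction of maximum SCL
#'   (default 0.6).
#' @return list of class `"maturity_filter"`: `retained` (the surviving rows
#'   of `specimens`), `exclusions` (specimen, species, scl, rule), and the
#'   `threshold` used.
#' @export
apply_maturity_filter <- function(specimens, maxima, threshold = 0.6) {
  stopifnot(all(c("species", "specimen_id", "scl_mm") %in% names(specimens)),
            all(c("species", "sex", "max_scl_mm") %in% names(maxima)))
  missing_max <- setdiff(unique(specimens$species), unique(maxima$species))
  if (length(missing_max))
    stop("no species maximum for: ", paste(missing_max, collapse = ", "),
         call. = FALSE)
  sex <- if ("sex" %in% names(specimens))
    tolower(as.character(specimens$sex)) else rep("unknown", nrow(specimens))
  sex[!sex %in% c("female", "male")] <- "unknown"
  somatic <- if ("somatic_mature" %in% names(specimens))
    !isFALSE_vec(specimens$somatic_mature) else rep(TRUE, nrow(specimens))
  override <- if ("include_override" %in% names(specimens))
    isTRUE_vec(specimens$include_override) else rep(FALSE, nrow(specimens))

  rule <- character(nrow(specimens))
  for (i in seq_len(nrow(specimens))) {
    mx <- maxima[maxima$species == specimens$species[i], ]
    larger <- max(mx$max_scl_mm)
    if (!somatic[i]) {
      rule[i] <- "somatically_immature"
    } else if (override[i]) {
      rule[i] <- ""
    } else if (is.na(specimens$scl_mm[i])) {
      rule[i] <- "missing_scl"
    } else if (sex[i] %in% c("female", "male")) {
      sx <- mx$max_scl_mm[tolower(mx$sex) == sex[i]]
      sexmax <- if (length(sx) && !all(is.na(sx))) max(sx, na.rm = TRUE) else larger
      rule[i] <- if (specimens$scl_mm[i] >= threshold * sexmax) "" else
        "below_threshold_sexed"
    } else {
      rule[i] <- if (specimens$scl_mm[i] >= threshold * larger) "" else
        "below_threshold_unsexed_larger_sex"
    }
  }
  keep <- rule == ""
  structure(list(
    retained = specimens[keep, , drop = FALSE],
    exclusions = data.frame(specimen_id = specimens$specimen_id[!keep],
                            species = specimens$species[!keep],
                            scl_mm = specimens$scl_mm[!keep],
                            rule = rule[!keep],
                            row.names = NULL, stringsAsFactors = FALSE),
    threshold = threshold
  ), class = "maturity_filter")
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)
isFALSE_vec <- function(x) !is.na(x) & !as.logical(x)

#' Aggregate specimens to species mean traits
#'
#' Arithmetic means are taken per species on the raw millimetre scale and
#' then log10-transformed (set `geometric = TRUE` to average on the log
#' scale instead, i.e. a geometric mean). Missingness propagates per trait:
#' a species' mean for a trait uses only the specimens measured for it.
#'
#' @param specimens data frame with `species` and any of `scl_mm`, `hl_mm`,
#'   `fl_mm`.
#' @param geometric use geometric instead of arithmetic means.
#' @return data frame with one row per species: `species`, `log10_scl`,
#'   `log10_hl`, `log10_fl` (NA where a species has no measurement).
#' @export
aggregate_species <- function(specimens, geometric = FALSE) {
  stopifnot("species" %in% names(specimens), nrow(specimens) > 0)
  traits <- c(scl_mm = "log10_scl", hl_mm = "log10_hl", fl_mm = "log10_fl")
  present <- intersect(names(traits), names(specimens))
  sp <- sort(unique(as.character(specimens$species)))
  out <- data.frame(species = sp, stringsAsFactors = FALSE)
  for (tr in present) {
    m <- vapply(sp, function(s) {
      v <- specimens[[tr]][specimens$species == s]
      v <- v[!is.na(v)]
      if (!length(v)) return(NA_real_)
      if (geometric) mean(log10(v)) else log10(mean(v))
    }, numeric(1))
    out[[traits[[tr]]]] <- unname(m)
  }
  out
}

#' Build the candidate model set for one allometric relationship
#'
#' The set comprises the purely allometric PGLS model, one PGLS model per
#' binary covariate, the intercept-only null model (the likelihood-R2
#' reference) and an OLS copy of the purely allometric model for the
#' PGLS-vs-OLS comparison. Covariates that are constant within the supplied
#' data are dropped with a warning.
#'
#' @param response,predictor trait column names (log10 scale).
#' @param covariates character vector of binary (0/1) covariate columns.
#' @param data optional data frame used to detect constant covariates.
#' @return named list of model specifications (`response`, `predictors`,
#'   `correlation`, `formula`).
#' @export
build_model_set <- function(response, predictor, covariates = character(),
                            data = NULL) {
  if (!is.null(data)) {
    keep_rows <- stats::complete.cases(data[c(response, predictor)])
    drop <- vapply(covariates, function(cv) {
      !cv %in% names(data) ||
        length(unique(stats::na.omit(data[[cv]][keep_rows]))) < 2
    }, logical(1))
    if (any(drop)) {
      warning("dropping constant or absent covariates: ",
              paste(covariates[drop], collapse = ", "), call. = FALSE)
      covariates <- covariates[!drop]
    }
  }
  spec <- function(predictors, correlation) {
    rhs <- if (length(predictors)) paste(predictors, collapse = " + ") else "1"
    list(response = response, predictors = predictors,
         correlation = correlation,
         formula = stats::as.formula(paste(response, "~", rhs)))
  }
  out <- list()
  out[[paste(response, "~", predictor)]] <-
    spec(predictor, "phylogenetic-lambda")
  for (cv in covariates)
    out[[paste(response, "~", predictor, "+", cv)]] <-
      spec(c(predictor, cv), "phylogenetic-lambda")
  out[[paste(response, "~ 1")]] <- spec(character(), "phylogenetic-lambda")
  out[[paste(response, "~", predictor, "[OLS]")]] <-
    spec(predictor, "independent")
  out
}

#' Fit a model set on a common species sample
#'
#' All models are fitted on the complete cases of the union of variables in
#' the set, so their AICc values are comparable. Likelihood R2 is computed
#' for every non-null model against the set's intercept-only fit.
#'
#' @param specs model set from [build_model_set()].
#' @param data species-level trait table with a `species` column.
#' @param tree dated phylogeny.
#' @param grid lambda profile grid.
#' @return named list of `"pgls_fit"` objects (the null model included).
#' @export
fit_model_set <- function(specs, data, tree, grid = seq(0, 1, by = 0.01)) {
  vars <- unique(unlist(lapply(specs, function(s) c(s$response, s$predictors))))
  data <- data[stats::complete.cases(data[vars]), , drop = FALSE]
  fits <- lapply(specs, function(s) {
    pgls(s$formula, data, tree, grid = grid,
         method = if (s$correlation == "independent") "ols" else "lambda")
  })
  null_name <- names(specs)[vapply(specs, function(s)
    length(s$predictors) == 0, logical(1))]
  if (length(null_name)) {
    null_fit <- fits[[null_name[1]]]
    for (nm in names(fits))
      if (nm != null_name[1])
        fits[[nm]]$r2 <- likelihood_r2(fits[[nm]], null_fit)
  }
  for (nm in names(fits)) fits[[nm]]$model <- nm
  fits
}

#' Select the best supported model with significant coefficients
#'
#' Ranks candidate models by AICc and returns the lowest-AICc model whose
#' every non-intercept coefficient is significant at `alpha`; intercept-only
#' null models are not candidates (they exist as the R2 reference). If no
#' model qualifies, the purely allometric model (fewest predictors,
#' phylogenetic correlation) is returned with `fallback = TRUE`. AICc
#' weights are computed over all candidates.
#'
#' @param fits named list of `"pgls_fit"` objects.
#' @param alpha significance level for the coefficient screen (default 0.05).
#' @return list: `best` (a `"pgls_fit"`), `fallback` (logical), `table`
#'   (ranked data frame with AICc, delta, weight, coefficient significance).
#' @export
select_best_model <- function(fits, alpha = 0.05) {
  if (!length(fits)) stop("empty model list", call. = FALSE)
  is_null_model <- vapply(fits, function(f) f$k == 1L, logical(1))
  cand <- fits[!is_null_model]
  if (!length(cand)) stop("no candidate models with predictors", call. = FALSE)
  av <- vapply(cand, function(f) f$aicc, numeric(1))
  ok <- is.finite(av)
  w <- rep(NA_real_, length(cand))
  if (sum(ok) >= 2) w[ok] <- aicc_weights(av[ok])
  else if (sum(ok) == 1) w[ok] <- 1
  all_sig <- vapply(cand, function(f) {
    ct <- f$coefficients
    nonint <- ct$term != "(Intercept)"
    all(ct$p[nonint] < alpha)
  }, logical(1))
  ord <- order(av)
  tab <- data.frame(model = names(cand)[ord],
                    correlation = vapply(cand, function(f) f$correlation,
                                         character(1))[ord],
                    n = vapply(cand, function(f) f$n, numeric(1))[ord],
                    lambda = vapply(cand, function(f) f$lambda, numeric(1))[ord],
                    sigma2 = vapply(cand, function(f) f$sigma2, numeric(1))[ord],
                    loglik = vapply(cand, function(f) f$loglik, numeric(1))[ord],
                    aicc = av[ord],
                    delta = av[ord] - min(av, na.rm = TRUE),
                    weight = w[ord],
                    r2 = vapply(cand, function(f) f$r2, numeric(1))[ord],
                    all_coefs_significant = all_sig[ord],
                    row.names = NULL, stringsAsFactors = FALSE)
  qualifying <- ord[all_sig[ord]]
  if (length(qualifying)) {
    best <- cand[[qualifying[1]]]
    fallback <- FALSE
  } else {
    phylo <- which(vapply(cand, function(f)
      f$correlation == "phylogenetic-lambda", logical(1)))
    npred <- vapply(cand[phylo], function(f) f$k, numeric(1))
    best <- cand[[phylo[which.min(npred)]]]
    fallback <- TRUE
  }
  list(best = best, fallback = fallback, table = tab)
}

#' Bootstrap percentile confidence intervals for regression coefficients
#'
#' Resamples species rows with replacement; the phylogenetic covariance of a
#' resample is the corresponding row/column selection of the full-data
#' matrix, so duplicated species enter as repeated observations at their
#' tips. Each resample is refitted with lambda re-estimated (on `grid`), and
#' per-coefficient 95 percent percentile intervals are taken over the
#' replicate estimates. Resamples with fewer than 3 unique species (or a
#' degenerate refit) are discarded and redrawn, and counted.
#'
#' @inheritParams pgls
#' @param B number of bootstrap replicates (a warning is issued below the
#'   1000 conventionally used for reported intervals).
#' @param seed integer seed making the resampling reproducible.
#' @param grid lambda profile grid for the refits (coarser than the
#'   full-data default; the profile is still refined between grid points).
#' @param level interval coverage (default 0.95).
#' @return list of class `"pgls_boot"`: `point` (the full-data fit), `ci`
#'   (term, lower, upper), `draws` (B x k coefficient matrix), `sigma2`,
#'   `lambda` (replicate vectors), `B`, `n_redrawn`.
#' @export
bootstrap_cis <- function(formula, data, tree, B = 1000, seed = NULL,
                          grid = seq(0, 1, by = 0.05), level = 0.95,
                          species_col = "species") {
  if (B < 1000)
    warning("B = ", B, " is below the 1000 replicates conventionally used ",
            "for reported intervals", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  full <- pgls(formula, data, tree, grid = seq(0, 1, by = 0.01),
               species_col = species_col)
  vars <- all.vars(formula)
  data <- data[stats::complete.cases(data[vars]), , drop = FALSE]
  sp <- as.character(data[[species_col]])
  tree <- prune_to_taxa(tree, sp)
  C <- unclass(vcv_matrix(tree, order = sp))
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- length(y); k <- ncol(X)
  draws <- matrix(NA_real_, B, k, dimnames = list(NULL, colnames(X)))
  s2 <- lam <- numeric(B)
  n_redrawn <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(idx)) < 3) { n_redrawn <- n_redrawn + 1L; next }
      res <- tryCatch(
        cpp_pgls_ml(y[idx], X[idx, , drop = FALSE], C[idx, idx],
                    grid = grid, refine = TRUE, tol = 1e-8),
        error = function(e) NULL)
      if (is.null(res) || isTRUE(res$degenerate) || !is.finite(res$loglik)) {
        n_redrawn <- n_redrawn + 1L
        next
      }
      draws[b, ] <- drop(res$beta)
      s2[b] <- res$sigma2
      lam[b] <- res$lambda
      break
    }
  }
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qs <- apply(draws, 2, quantile, probs = probs, names = FALSE)
  structure(list(
    point = full,
    ci = data.frame(term = colnames(X), lower = qs[1, ], upper = qs[2, ],
                    row.names = NULL, stringsAsFactors = FALSE),
    draws = draws, sigma2 = s2, lambda = lam, B = B,
    level = level, n_redrawn = n_redrawn
  ), class = "pgls_boot")
}

#' Classify the strength of an allometric slope
#'
#' Log-log slope bands relative to isometry (slope 1): below 0.7 strong,
#' 0.7-0.85 moderate and 0.85-0.99 weak negative allometry; 1.01-1.15 weak,
#' 1.15-1.3 moderate and above 1.3 strong positive allometry; slopes
#' strictly between 0.99 and 1.01 are near-isometric. Edges are assigned to
#' the band they are conventionally quoted in (0.85 and 0.99 to weak
#' negative, 0.7 to moderate negative, 1.01 and 1.15 to weak positive, 1.3
#' to moderate positive).
#'
#' @param slope numeric vector of fitted log-log slopes.
#' @return character vector of band labels.
#' @export
classify_allometry <- function(slope) {
  stopifnot(all(is.finite(slope)))
  out <- character(length(slope))
  out[slope < 0.7] <- "strong negative"
  out[slope >= 0.7 & slope < 0.85] <- "moderate negative"
  out[slope >= 0.85 & slope <= 0.99] <- "weak negative"
  out[slope > 0.99 & slope < 1.01] <- "near-isometric"
  out[slope >= 1.01 & slope <= 1.15] <- "weak positive"
  out[slope > 1.15 & slope <= 1.3] <- "moderate positive"
  out[slope > 1.3] <- "strong positive"
  out
}

#' Compare two bootstrap distributions of evolutionary rates
#'
#' Welch two-sample t-test between two samples of sigma-squared values
#' (e.g. the bootstrap rate distributions of two allometric relationships
#' or two clades).
#'
#' @param sigma2_a,sigma2_b numeric vectors (length >= 2 each).
#' @return list with `t`, `df`, two-sided `p`, and the two sample means.
#' @export
compare_rate_distributions <- function(sigma2_a, sigma2_b) {
  if (length(sigma2_a) < 2 || length(sigma2_b) < 2)
    stop("each sample needs at least 2 values", call. = FALSE)
  if (stats::sd(sigma2_a) == 0 && stats::sd(sigma2_b) == 0)
    stop("zero variance in both samples", call. = FALSE)
  tt <- t.test(sigma2_a, sigma2_b)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_a = mean(sigma2_a), mean_b = mean(sigma2_b))
}

#' Tabulate fitted models in the standard report layout
#'
#' One row per coefficient, grouped by model, in the column order used for
#' published PGLS summaries: Model, N, lambda, sigma2, AICc, AICc weight,
#' R2, Variable, Coef (95 percent CI), SE, t, p.
#'
#' @param fits named list of `"pgls_fit"` objects.
#' @param cis optional named list of `"pgls_boot"` objects (per model) whose
#'   percentile intervals fill the CI column.
#' @return a data frame; write it with [utils::write.table()] for the TSV
#'   report.
#' @export
fit_table <- function(fits, cis = NULL) {
  av <- vapply(fits, function(f) f$aicc, numeric(1))
  ok <- is.finite(av)
  w <- rep(NA_real_, length(fits))
  if (sum(ok) >= 2) w[ok] <- aicc_weights(av[ok])
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    ct <- f$coefficients
    ci_txt <- rep(NA_character_, nrow(ct))
    if (!is.null(cis) && names(fits)[i] %in% names(cis)) {
      bc <- cis[[names(fits)[i]]]$ci
      m <- match(ct$term, bc$term)
      ci_txt <- ifelse(is.na(m), NA_character_,
                       sprintf("(%.3g, %.3g)", bc$lower[m], bc$upper[m]))
    }
    data.frame(Model = c(names(fits)[i], rep("", nrow(ct) - 1)),
               N = c(f$n, rep(NA, nrow(ct) - 1)),
               lambda = c(f$lambda, rep(NA, nrow(ct) - 1)),
               sigma2 = c(f$sigma2, rep(NA, nrow(ct) - 1)),
               AICc = c(f$aicc, rep(NA, nrow(ct) - 1)),
               AICc_w = c(w[i], rep(NA, nrow(ct) - 1)),
               R2 = c(f$r2, rep(NA, nrow(ct) - 1)),
               Variable = ct$term,
               Coef = ct$estimate,
               CI95 = ci_txt,
               SE = ct$se,
               t = ct$t,
               p = ct$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
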