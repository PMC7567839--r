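## Predictor importance: deviance explained by single-covariate
## negative-binomial penalized-spline regressions of CPUE, and the
## "strongest predictor" (argmax of deviance explained) per species.
##
## The spline engine is mgcv (thin-plate penalized regression splines,
## REML smoothness selection with an outer Newton optimizer, basis
## dimension 10, NB family with log link, theta estimated alongside the
## smoothing parameter).  The deviance computations that define the score
## are owned here and cross-checked against the engine at fit time.

COVARIATES <- c("btemp", "bsalin", "depth", "grainsize")

#' Specification of the single-covariate smooth fits
#'
#' @param basis_dim spline basis dimension `k` (default 10).
#' @param max_null_dev_rel maximum tolerated relative disagreement between
#'   the engine's deviance and [nb_deviance()] before a fit is flagged.
#' @return a `smooth_fit_spec` list.
#' @export
smooth_fit_spec <- function(basis_dim = 10L, max_null_dev_rel = 1e-6) {
  if (basis_dim < 3) stop("basis_dim must be >= 3")
  structure(list(basis_dim = as.integer(basis_dim),
                 max_null_dev_rel = max_null_dev_rel),
            class = "smooth_fit_spec")
}

#' Negative-binomial deviance
#'
#' `D = 2 * sum(y*log(y/mu) - (y + theta)*log((y + theta)/(mu + theta)))`
#' with the convention `y*log(y/mu) = 0` when `y = 0`.  Valid for
#' non-integer nonnegative `y` (quasi-likelihood form); `D >= 0`, and `D`
#' equals twice the saturated-minus-model NB log-likelihood difference.
#'
#' @param y observed nonnegative responses.
#' @param mu fitted means (> 0), recycled if scalar.
#' @param theta NB size parameter (> 0).
#' @return total deviance (scalar).
#' @export
nb_deviance <- function(y, mu, theta) {
  if (length(mu) == 1) mu <- rep(mu, length(y))
  stopifnot(length(y) == length(mu))
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("mu must be positive")
  if (!is.finite(theta) || theta <= 0) stop("theta must be positive")
  if (any(y < 0)) stop("y must be nonnegative")
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  t2 <- (y + theta) * log((y + theta) / (mu + theta))
  2 * sum(t1 - t2)
}

#' Fraction of null deviance explained
#'
#' `(D_null - D_model) / D_null`, clipped to `[0, 1]` (clipping is
#' reported via `message()`); `NA` when the null deviance is zero.
#'
#' @param null_deviance,model_deviance total deviances (>= 0).
#' @return fraction in `[0, 1]`, or `NA`.
#' @export
deviance_explained <- function(null_deviance, model_deviance) {
  if (!is.finite(null_deviance) || null_deviance <= 0) return(NA_real_)
  de <- (null_deviance - model_deviance) / null_deviance
  if (de < 0 || de > 1) {
    message("deviance_explained: value ", signif(de, 4), " clipped to [0, 1]")
    de <- min(1, max(0, de))
  }
  de
}

#' Fit a single-covariate NB smooth of CPUE
#'
#' Fits `cpue ~ s(x, k = basis_dim)` under the NB family with log link,
#' REML smoothness selection and an outer Newton optimizer; rows with a
#' missing covariate are dropped.  The model and null (intercept-only,
#' same theta) deviances are recomputed with [nb_deviance()] and verified
#' against the engine's values.
#'
#' @param records hauls of one species-season, with `cpue` and the
#'   covariate column.
#' @param covariate one of `"btemp"`, `"bsalin"`, `"depth"`, `"grainsize"`.
#' @param spec a [smooth_fit_spec()].
#' @return a `covariate_fit` list (`dev_model`, `dev_null`, `dev_expl`,
#'   `theta`, `n_obs`, `edf`, `converged`, `skipped`, `reason`, `fitted`).
#' @export
fit_single_covariate <- function(records, covariate,
                                 spec = smooth_fit_spec()) {
  stopifnot(inherits(spec, "smooth_fit_spec"))
  covariate <- match.arg(covariate, COVARIATES)
  d <- data.frame(cpue = records$cpue, x = records[[covariate]])
  d <- d[is.finite(d$cpue) & is.finite(d$x), , drop = FALSE]
  skip <- function(reason) {
    structure(list(covariate = covariate, n_obs = nrow(d),
                   dev_model = NA_real_, dev_null = NA_real_,
                   dev_expl = NA_real_, theta = NA_real_, edf = NA_real_,
                   converged = FALSE, skipped = TRUE, reason = reason,
                   fitted = NULL),
              class = "covariate_fit")
  }
  if (nrow(d) < spec$basis_dim + 5) {
    return(skip(sprintf("insufficient data (%d complete rows)", nrow(d))))
  }
  if (length(unique(d$x)) < 3) {
    return(skip("covariate has fewer than 3 distinct values"))
  }
  fit <- tryCatch(
    mgcv::gam(cpue ~ s(x, k = spec$basis_dim, bs = "tp"),
              family = mgcv::nb(link = "log"), data = d, method = "REML",
              optimizer = c("outer", "newton")),
    error = function(e) NULL)
  if (is.null(fit) || !isTRUE(fit$converged)) {
    return(skip("fit did not converge"))
  }
  theta <- fit$family$getTheta(TRUE)
  mu <- as.numeric(stats::fitted(fit))
  dev_model <- nb_deviance(d$cpue, mu, theta)
  dev_null <- nb_deviance(d$cpue, mean(d$cpue), theta)
  rel <- function(a, b) abs(a - b) / max(abs(b), 1e-12)
  ok <- rel(dev_model, stats::deviance(fit)) <= spec$max_null_dev_rel &&
    rel(dev_null, fit$null.deviance) <= spec$max_null_dev_rel
  if (!ok) {
    warning("engine deviance disagrees with nb_deviance beyond tolerance ",
            "for covariate ", covariate)
  }
  structure(list(covariate = covariate, n_obs = nrow(d),
                 dev_model = dev_model, dev_null = dev_null,
                 dev_expl = deviance_explained(dev_null, dev_model),
                 theta = theta, edf = sum(fit$edf), converged = TRUE,
                 skipped = FALSE, reason = "ok", fitted = mu),
            class = "covariate_fit")
}

#' Strongest predictor from a set of deviance-explained scores
#'
#' Argmax over the fixed covariate order `btemp, bsalin, depth, grainsize`;
#' on an exact tie the earlier covariate in that order wins.  `NA` when
#' every score is missing.
#'
#' @param scores named numeric vector of deviance-explained values (names
#'   from the covariate set; missing entries allowed).
#' @return covariate label, or `NA_character_`.
#' @export
strongest_predictor <- function(scores) {
  s <- scores[COVARIATES[COVARIATES %in% names(scores)]]
  s <- s[!is.na(s)]
  if (!length(s)) return(NA_character_)
  names(s)[which.max(s)]
}

#' Deviance-explained table for retained species
#'
#' Runs [fit_single_covariate()] for every species x season x covariate
#' cell and assigns each species-season its strongest predictor.
#'
#' @param records filtered survey rows.
#' @param species,seasons optional subsets (default: all present).
#' @param spec a [smooth_fit_spec()].
#' @return list with `table` (species, season, covariate, dev_expl, n_obs,
#'   theta, converged) and `strongest` (species, season,
#'   strongest_predictor).
#' @export
deviance_table <- function(records, species = NULL, seasons = NULL,
                           spec = smooth_fit_spec()) {
  species <- species %||% sort(unique(records$species))
  seasons <- seasons %||% sort(unique(records$season))
  rows <- list(); strong <- list()
  for (se in seasons) {
    for (sp in species) {
      d <- records[records$species == sp & records$season == se, ,
                   drop = FALSE]
      fits <- lapply(COVARIATES, function(cv) {
        fit_single_covariate(d, cv, spec)
      })
      de <- vapply(fits, `[[`, 0, "dev_expl")
      names(de) <- COVARIATES
      rows[[length(rows) + 1]] <- data.frame(
        species = sp, season = se, covariate = COVARIATES,
        dev_expl = de, n_obs = vapply(fits, `[[`, 0L, "n_obs"),
        theta = vapply(fits, `[[`, 0, "theta"),
        converged = vapply(fits, `[[`, TRUE, "converged"))
      strong[[length(strong) + 1]] <- data.frame(
        species = sp, season = se,
        strongest_predictor = strongest_predictor(de))
    }
  }
  tab <- do.call(rbind, rows); rownames(tab) <- NULL
  st <- do.call(rbind, strong); rownames(st) <- NULL
  list(table = tab, strongest = st)
}
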