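# Registry of kinetic rate laws. Each entry: a rate function
# v(S, pars), the parameter names, and a deterministic multi-start grid
# generator startGrid(S, v) returning a list of named start vectors.
.kineticModels <- new.env(parent = emptyenv())

.registerBuiltinModels <- function() {
  registerKineticModel(
    "michaelis_menten",
    rate = function(S, pars) pars[["kcat"]] * S / (pars[["KM"]] + S),
    parameters = c("kcat", "KM"),
    startGrid = function(S, v) {
      kmStarts <- unique(c(min(S[S > 0]), stats::median(S), max(S)))
      vm <- max(v)
      out <- list()
      for (km in kmStarts) for (f in c(1, 1.5))
        out[[length(out) + 1L]] <- c(kcat = vm * f, KM = km)
      out
    }
  )
  registerKineticModel(
    "substrate_inhibition",
    rate = function(S, pars)
      pars[["kcat"]] * S / (pars[["KM"]] + S + S^2 / pars[["Ki"]]),
    parameters = c("kcat", "KM", "Ki"),
    startGrid = function(S, v) {
      kmStarts <- unique(c(min(S[S > 0]), stats::median(S), max(S)))
      vm <- max(v)
      out <- list()
      for (km in kmStarts) for (f in c(1, 1.5))
        out[[length(out) + 1L]] <- c(kcat = vm * f, KM = km, Ki = max(S))
      out
    }
  )
  registerKineticModel(
    "hill",
    rate = function(S, pars)
      pars[["kcat"]] * S^pars[["n"]] / (pars[["KM"]]^pars[["n"]] +
                                          S^pars[["n"]]),
    parameters = c("kcat", "KM", "n"),
    startGrid = function(S, v) {
      kmStarts <- unique(c(min(S[S > 0]), stats::median(S), max(S)))
      vm <- max(v)
      out <- list()
      for (km in kmStarts) for (f in c(1, 1.5))
        out[[length(out) + 1L]] <- c(kcat = vm * f, KM = km, n = 1)
      out
    }
  )
}

#' Register a kinetic rate law
#'
#' Extends [fitKinetics()] with a user model. The start grid must be a
#' deterministic function of the data so that fits are reproducible.
#'
#' @param name model name.
#' @param rate function `(S, pars)` returning rates; `pars` is a named
#'   vector over `parameters`.
#' @param parameters character vector of parameter names.
#' @param startGrid function `(S, v)` returning a list of named start
#'   vectors, tried in order.
#' @return `name`, invisibly.
#' @export
registerKineticModel <- function(name, rate, parameters, startGrid) {
  stopifnot(is.function(rate), is.character(parameters),
            is.function(startGrid))
  assign(name, list(rate = rate, parameters = parameters,
                    startGrid = startGrid), envir = .kineticModels)
  invisible(name)
}

#' Available kinetic models
#'
#' @return character vector of registered model names.
#' @export
kineticModels <- function() sort(ls(.kineticModels))

#' Fit a kinetic rate law to rate-vs-concentration data
#'
#' Nonlinear least squares (Levenberg-Marquardt via
#' [minpack.lm::nlsLM()]) of the chosen rate law against observed rates.
#' Shipped models: Michaelis-Menten `v = kcat*S/(KM+S)`, substrate
#' inhibition `v = kcat*S/(KM+S+S^2/Ki)`, and Hill
#' `v = kcat*S^n/(KM^n+S^n)`; more can be added with
#' [registerKineticModel()]. Starts are taken from a fixed data-derived
#' grid (KM from the min/median/max concentration, kcat from max(v) and
#' 1.5*max(v)) in a fixed order, and the converged fit with the lowest
#' residual sum of squares wins, so the result is deterministic for given
#' data. Standard errors come from the curvature at the optimum.
#'
#' Units at the interface are fixed: concentrations in uM, rates in s^-1.
#'
#' @param concentration substrate concentrations in uM (>= 0); at least
#'   `#parameters + 1` distinct values.
#' @param rate observed rates in s^-1, parallel to `concentration`.
#' @param model one of [kineticModels()].
#' @return a [KineticFit-class] object.
#' @examples
#' S <- c(5, 10, 20, 50, 100, 200, 500, 1000)
#' v <- 18 * S / (33 + S)
#' fitKinetics(S, v, "michaelis_menten")
#' @export
fitKinetics <- function(concentration, rate,
                        model = c("michaelis_menten",
                                  "substrate_inhibition", "hill")) {
  if (length(model) > 1L || !model %in% kineticModels())
    model <- match.arg(model)
  spec <- get(model, envir = .kineticModels)
  S <- as.numeric(concentration)
  v <- as.numeric(rate)
  if (length(S) != length(v))
    stop("concentration and rate must have equal length")
  if (any(S < 0)) stop("concentrations must be >= 0")
  nDistinct <- length(unique(S))
  if (nDistinct < length(spec$parameters) + 1L)
    stop("need at least ", length(spec$parameters) + 1L,
         " distinct concentrations to fit ", model)
  starts <- spec$startGrid(S, v)
  argList <- paste(sprintf("%s = %s", spec$parameters, spec$parameters),
                   collapse = ", ")
  fenv <- new.env(parent = environment())
  fenv$rateFun <- spec$rate
  form <- stats::as.formula(
    paste0("v ~ rateFun(S, c(", argList, "))"), env = fenv)
  best <- NULL
  diagnostics <- character()
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        form, start = as.list(st),
        lower = rep(sqrt(.Machine$double.eps), length(st)),
        data = data.frame(v = v, S = S),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      diagnostics <- c(diagnostics, conditionMessage(fit))
      next
    }
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("kinetic fit did not converge from any start (", model, "): ",
         paste(unique(diagnostics), collapse = "; "))
  fit <- best$fit
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(est)))
  methods::new("KineticFit", model = model,
               parameters = est[spec$parameters],
               stdErrors = stats::setNames(se[spec$parameters],
                                           spec$parameters),
               rss = best$rss, nObs = length(v),
               fitted = as.numeric(stats::fitted(fit)))
}

#' Read a kinetic dataset from CSV
#'
#' Expected columns: `concentration_uM`, `rate_per_s`, optional
#' `replicate`.
#'
#' @param path path to the CSV file.
#' @return data.frame with the columns above.
#' @export
readKineticData <- function(path) {
  d <- utils::read.csv(path)
  need <- c("concentration_uM", "rate_per_s")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("kinetic data must carry column(s): ", paste(miss, collapse = ", "))
  d
}

#' Normalize a screening plate against wildtype and blank controls
#'
#' Per-well score `(raw - mean(blank)) / (mean(wildtype) - mean(blank))`:
#' the blank mean maps to 0 and the wildtype mean to 1, so an improved
#' variant scores above 1. The score is invariant under any affine
#' transformation `a*x + b` (a > 0) of the raw signal, which removes
#' plate-level gain and offset.
#'
#' @param plate numeric vector (or matrix) of raw well activities.
#' @param roles character vector parallel to `plate` with entries
#'   `"sample"`, `"wildtype"` or `"blank"`; at least 2 wildtype and 2
#'   blank wells.
#' @param tol minimal wildtype - blank separation of the means.
#' @return numeric vector (or matrix) of normalized scores.
#' @export
normalizeScreen <- function(plate, roles, tol = 1e-8) {
  raw <- as.numeric(plate)
  roles <- as.character(roles)
  if (length(raw) != length(roles))
    stop("plate and roles must have equal length")
  bad <- setdiff(unique(roles), c("sample", "wildtype", "blank"))
  if (length(bad))
    stop("unknown well role(s): ", paste(bad, collapse = ", "))
  if (sum(roles == "wildtype") < 2L)
    stop("need >= 2 wildtype control wells")
  if (sum(roles == "blank") < 2L)
    stop("need >= 2 blank wells")
  wt <- mean(raw[roles == "wildtype"])
  bl <- mean(raw[roles == "blank"])
  if (abs(wt - bl) < tol)
    stop("wildtype and blank means are indistinguishable (", wt, " vs ",
         bl, "); cannot normalize")
  scores <- (raw - bl) / (wt - bl)
  if (is.matrix(plate))
    scores <- matrix(scores, nrow(plate), ncol(plate),
                     dimnames = dimnames(plate))
  else names(scores) <- names(plate)
  scores
}

#' Read a screening plate layout from CSV
#'
#' Expected columns: `well`, `role` (`sample` | `wildtype` | `blank`),
#' `raw`.
#'
#' @param path path to the CSV file.
#' @return data.frame with the columns above.
#' @export
readPlate <- function(path) {
  d <- utils::read.csv(path, colClasses = c(well = "character",
                                            role = "character",
                                            raw = "numeric"))
  need <- c("well", "role", "raw")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("plate layout must carry column(s): ", paste(miss, collapse = ", "))
  d
}

#' Call screening hits from normalized scores
#'
#' Wells reaching `score >= foldThreshold` (relative to the wildtype
#' score of 1) are flagged, ordered by descending score with ties broken
#' by well name.
#'
#' @param scores named numeric vector of normalized scores.
#' @param foldThreshold threshold > 1.
#' @return data.frame with `well` and `score`, ordered by score.
#' @export
callHits <- function(scores, foldThreshold) {
  stopifnot(foldThreshold > 1)
  if (is.null(names(scores)))
    names(scores) <- as.character(seq_along(scores))
  hit <- scores >= foldThreshold
  out <- data.frame(well = names(scores)[hit], score = unname(scores[hit]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$well), , drop = FALSE]
  rownames(out) <- NULL
  out
}
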