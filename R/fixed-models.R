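#' Fixed weighted-combination biomarker model
#'
#' A published weighted combination: named weights on feature levels plus an
#' intercept. Canonical values are the linear predictor
#' `sum(weight * level) + intercept`. Feature names carry a `_r` suffix in
#' the packaged models where the published weight applies to ratio-normalized
#' (metabolite) or relative (delta-Cq miRNA) levels rather than absolute
#' concentrations.
#'
#' @param name model label.
#' @param coefficients named numeric weights.
#' @param intercept intercept, default 0.
#' @param units optional named character vector documenting the unit of each
#'   term.
#' @return object of class `fixed_model`.
#' @seealso [packaged_model()], [canonical_values()]
#' @export
fixed_model <- function(name, coefficients, intercept = 0, units = NULL) {
  if (is.null(names(coefficients)) || any(!nzchar(names(coefficients))))
    stop("`coefficients` must be fully named")
  if (!is.numeric(coefficients) || anyNA(coefficients))
    stop("`coefficients` must be numeric and complete")
  structure(list(name = name,
                 coefficients = coefficients,
                 intercept = intercept,
                 units = units), class = "fixed_model")
}

#' @export
print.fixed_model <- function(x, ...) {
  cat(sprintf("fixed weighted-combination model: %s\n", x$name))
  terms <- sprintf("%+.4g * [%s]", x$coefficients, names(x$coefficients))
  cat(" ", paste(terms, collapse = " "),
      sprintf("%+.4g\n", x$intercept))
  invisible(x)
}

#' @export
coef.fixed_model <- function(object, ...)
  c(`(Intercept)` = object$intercept, object$coefficients)

#' Canonical values of a biomarker model
#'
#' The per-sample linear predictor `sum(weight * feature) + intercept` of a
#' fixed weighted combination or a fitted ridge logistic model; the quantity
#' that is thresholded for classification and compared between groups.
#'
#' @param model a [fixed_model()] or [ridge_logistic()] fit.
#' @param x samples x features table containing the model's features.
#' @return named numeric vector, one value per sample.
#' @examples
#' m <- fixed_model("toy", c(a = 2), intercept = -0.5)
#' canonical_values(m, matrix(c(0, 1), 2, 1,
#'                            dimnames = list(c("s1", "s2"), "a")))
#' @export
canonical_values <- function(model, x) UseMethod("canonical_values")

#' @export
canonical_values.fixed_model <- function(model, x) {
  vals <- as_values_matrix(x, "x")
  missing_feats <- setdiff(names(model$coefficients), colnames(vals))
  if (length(missing_feats))
    stop("feature(s) not resolvable in input: ",
         paste(missing_feats, collapse = ", "))
  drop(vals[, names(model$coefficients), drop = FALSE] %*%
         model$coefficients) + model$intercept
}

#' @export
canonical_values.ridge_logit <- function(model, x) {
  predict(model, x, type = "link")
}

#' Read a fixed model from a JSON file
#'
#' @param path JSON file with fields `name`, `intercept`, `coefficients`
#'   (object of feature: weight) and optional `units`.
#' @return a [fixed_model()].
#' @export
read_fixed_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fixed_model(name = obj$name,
              coefficients = unlist(obj$coefficients),
              intercept = if (is.null(obj$intercept)) 0 else obj$intercept,
              units = if (is.null(obj$units)) NULL else unlist(obj$units))
}

#' Packaged published biomarker models
#'
#' The four published weighted combinations ship with the package as JSON
#' coefficient files:
#' \describe{
#'   \item{`ca_metabolite`}{five-metabolite CA vs non-CA model
#'     (intercept 0.07).}
#'   \item{`aggressive_metabolite`}{three-metabolite non-aggressive vs
#'     aggressive model (intercept -0.48).}
#'   \item{`familial_metabolite`}{single-metabolite familial vs sporadic
#'     model (intercept -0.37).}
#'   \item{`cash_integrated`}{integrated CASH model: four proteins
#'     (absolute concentrations) plus ratio-level linoleic acid and three
#'     relative-level miRNAs; no intercept.}
#' }
#'
#' @param name one of the model ids above.
#' @return a [fixed_model()].
#' @examples
#' m <- packaged_model("familial_metabolite")
#' canonical_values(m, matrix(0, 1, 1,
#'   dimnames = list("s", "decanoyl-L-carnitine")))   # -0.37
#' @export
packaged_model <- function(name = c("ca_metabolite", "aggressive_metabolite",
                                    "familial_metabolite",
                                    "cash_integrated")) {
  name <- match.arg(name)
  path <- system.file("extdata", "models", paste0(name, ".json"),
                      package = "plasmapanel", mustWork = TRUE)
  read_fixed_model(path)
}
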