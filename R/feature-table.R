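#' Construct a feature table
#'
#' A feature table is the package's container for one omic layer: a numeric
#' samples x features matrix with sample ids as row names and feature ids as
#' column names, tagged with the layer it belongs to and its measurement
#' units. Missing cells are `NA`; observed values must be finite.
#'
#' @param values numeric matrix (samples in rows, features in columns) with
#'   row and column names.
#' @param layer one of `"metabolite"`, `"protein"`, `"mirna_cq"`,
#'   `"mirna_rel"`, `"ratio"`.
#' @param units free-text unit label (e.g. `"peak intensity"`, `"ng/ml"`,
#'   `"cycles"`).
#' @return a numeric matrix of class `feature_table` with `layer` and
#'   `units` attributes.
#' @examples
#' m <- matrix(rlnorm(12), 3, 4,
#'             dimnames = list(paste0("S", 1:3), paste0("F", 1:4)))
#' ft <- feature_table(m, layer = "metabolite", units = "peak intensity")
#' @export
feature_table <- function(values,
                          layer = c("metabolite", "protein", "mirna_cq",
                                    "mirna_rel", "ratio"),
                          units = "") {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have sample ids as rownames and feature ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated sample ids")
  if (anyDuplicated(colnames(values)))
    stop("duplicated feature ids")
  if (any(!is.finite(values) & !is.na(values)))
    stop("non-finite values present (use NA for missing cells)")
  structure(values, layer = layer, units = units,
            class = c("feature_table", class(values)))
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table [%s layer, %d samples x %d features, units: %s]\n",
              attr(x, "layer"), nrow(x), ncol(x),
              if (nzchar(attr(x, "units"))) attr(x, "units") else "unspecified"))
  cat(sprintf("missing cells: %d\n", sum(is.na(x))))
  k <- min(5L, nrow(x)); j <- min(5L, ncol(x))
  print(unclass(x)[seq_len(k), seq_len(j), drop = FALSE])
  invisible(x)
}

# Accept either a feature_table or a plain named numeric matrix.
as_values_matrix <- function(x, arg = "x") {
  if (inherits(x, "feature_table")) {
    out <- unclass(x)
    attr(out, "layer") <- NULL
    attr(out, "units") <- NULL
    return(out)
  }
  if (is.matrix(x) && is.numeric(x)) return(x)
  if (is.data.frame(x)) return(as.matrix(x))
  stop(sprintf("`%s` must be a feature_table or numeric matrix", arg))
}

# Rebuild a feature_table around transformed values, keeping the tags unless
# overridden.
rewrap <- function(values, template, layer = NULL, units = NULL) {
  if (!inherits(template, "feature_table")) return(values)
  feature_table(values,
                layer = if (is.null(layer)) attr(template, "layer") else layer,
                units = if (is.null(units)) attr(template, "units") else units)
}
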