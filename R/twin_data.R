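#' Twin-pair dataset
#'
#' Validates a pair-level data frame of bivariate twin observations and tags
#' it as a `twin_data` object.  One row per pair with columns `zygosity`
#' (`"MZ"` or `"DZ"`), and the trait values `x1`, `y1`, `x2`, `y2` (traits X
#' and Y for twin 1 and twin 2; the pair vector is ordered (x1, y1, x2, y2)
#' throughout the package).
#'
#' @param df a data frame with the required columns.
#' @param allow_missing logical; if `TRUE`, trait values may be `NA`
#'   (pairs with partially observed traits can then be analysed with the
#'   marginal likelihood, see [minus2_loglik()]).
#' @return The validated data frame with class `twin_data`.
#' @export
twin_data <- function(df, allow_missing = FALSE) {
  req <- c("zygosity", "x1", "y1", "x2", "y2")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[req]
  df$zygosity <- as.character(df$zygosity)
  bad <- which(!df$zygosity %in% c("MZ", "DZ"))
  if (length(bad))
    stop("unknown zygosity code at row ", bad[1], ": '", df$zygosity[bad[1]], "'")
  if (nrow(df)) {
    vals <- as.matrix(df[c("x1", "y1", "x2", "y2")])
    bad <- if (allow_missing) !is.finite(vals) & !is.na(vals)
           else !is.finite(vals)
    if (!is.numeric(vals) || any(bad))
      stop("trait values must be finite numerics",
           if (allow_missing) " (NA allowed)" else "")
  } else {
    for (col in c("x1", "y1", "x2", "y2")) df[[col]] <- numeric(0)
  }
  class(df) <- c("twin_data", "data.frame")
  df
}

#' @export
print.twin_data <- function(x, ...) {
  cat(sprintf("twin_data: %d pairs (%d MZ, %d DZ)\n",
              nrow(x), sum(x$zygosity == "MZ"), sum(x$zygosity == "DZ")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 4))
  invisible(x)
}

# Number of observed (non-missing) data points; 4 per complete pair.
n_datapoints <- function(data) {
  if (!nrow(data)) return(0L)
  sum(!is.na(as.matrix(data[c("x1", "y1", "x2", "y2")])))
}
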