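# broom-style tidiers for the package's fitted-result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.editing_concordance <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = c("(Intercept)", "x"),
                 estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' @export
glance.editing_concordance <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 pearson_r = x$pearson_r, r.squared = x$r_squared, n = x$n)
}

#' @export
tidy.editing_regression <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s),
                 estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' @export
glance.editing_regression <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r.squared = x$r_squared, n = x$n)
}

#' @export
tidy.editing_pca <- function(x, matrix = c("samples", "loadings"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "samples") return(x$samples)
  tibble::as_tibble(x$loadings, rownames = "gene")
}

#' @export
glance.editing_pca <- function(x, ...) {
  out <- tibble::as_tibble(as.list(stats::setNames(
    x$var_explained, paste0("var_explained_", colnames(x$loadings)))))
  out$n_top_genes <- x$n_top_genes
  out$n_samples <- nrow(x$samples)
  out
}
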