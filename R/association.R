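# Multivariate source-grouping support: Spearman correlation matrix and a
# rotated principal-component decomposition of the metal table.

#' Spearman correlation matrix
#'
#' Symmetric rank-correlation matrix (average-rank ties) across the numeric
#' columns of a table. Constant columns yield `NA` entries (undefined
#' correlation) off the diagonal.
#'
#' @param table Data frame of variables (non-numeric columns are dropped).
#' @return Symmetric numeric matrix with unit diagonal.
#' @export
correlation_matrix <- function(table) {
  num <- table[map_chr(table, function(x) class(x)[1]) %in%
                 c("numeric", "integer")]
  abort_if(ncol(num) < 2, "Need at least 2 numeric variables.",
           "aquarisk_bad_input")
  abort_if(sum(complete.cases(num)) < 3, "Need at least 3 complete rows.",
           "aquarisk_bad_input")
  # Constant columns are reported as NA below; silence cor()'s sd warning.
  m <- suppressWarnings(cor(as.matrix(num), method = "spearman"))
  constant <- map_dbl(num, sd) == 0
  m[constant, ] <- NA_real_
  m[, constant] <- NA_real_
  diag(m) <- 1
  m
}

#' Rotated principal-component loadings
#'
#' Principal components of the (Spearman, by default) correlation matrix of
#' standardized variables, optionally varimax-rotated. Explained variance
#' is recomputed after rotation as each component's sum of squared loadings
#' over the variable count. Sign convention: the largest-magnitude loading
#' of each component is positive.
#'
#' @param table Data frame of variables (e.g. the five metals).
#' @param n_components Number of retained components.
#' @param rotation `"varimax"` or `"none"`.
#' @param cor_method Correlation used for the decomposition.
#' @return A `pca_loadings` object: `loadings` (variables x components),
#'   `explained_pct`, `cumulative_pct`, `rotation`, `rotmat`, `eigenvalues`.
#' @export
pca_rotated <- function(table, n_components = 2,
                        rotation = c("varimax", "none"),
                        cor_method = c("spearman", "pearson")) {
  rotation <- match.arg(rotation)
  cor_method <- match.arg(cor_method)
  num <- table[map_chr(table, function(x) class(x)[1]) %in%
                 c("numeric", "integer")]
  p <- ncol(num)
  abort_if(n_components > p,
           "`n_components` cannot exceed the number of variables.",
           "aquarisk_bad_input")
  if (nrow(num) < p)
    rlang::warn("Fewer rows than variables; loadings may be unstable.")
  R <- cor(as.matrix(num), method = cor_method)
  abort_if(anyNA(R), "Correlation matrix has undefined entries.",
           "aquarisk_bad_input")
  eig <- eigen(R, symmetric = TRUE)
  abort_if(any(eig$values < -1e-8 * max(abs(eig$values))) ||
             max(eig$values) <= 0,
           "Correlation matrix is not positive semidefinite.",
           "aquarisk_bad_input")
  vals <- pmax(eig$values, 0)
  # Loadings: eigenvectors scaled by sqrt(eigenvalue) (correlation of each
  # variable with the component).
  L <- eig$vectors[, seq_len(n_components), drop = FALSE] %*%
    diag(sqrt(vals[seq_len(n_components)]), n_components)
  rotmat <- diag(n_components)
  if (rotation == "varimax" && n_components > 1) {
    vm <- varimax(L, normalize = TRUE)
    L <- L %*% vm$rotmat
    rotmat <- vm$rotmat
  }
  # Sign convention.
  for (k in seq_len(n_components)) {
    if (L[which.max(abs(L[, k])), k] < 0) {
      L[, k] <- -L[, k]
      rotmat[, k] <- -rotmat[, k]
    }
  }
  # Order components by post-rotation explained variance.
  ss <- colSums(L^2)
  ord <- order(ss, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  rotmat <- rotmat[, ord, drop = FALSE]
  ss <- ss[ord]
  dimnames(L) <- list(names(num), paste0("PC", seq_len(n_components)))
  structure(
    list(loadings = L,
         explained_pct = 100 * ss / p,
         cumulative_pct = cumsum(100 * ss / p),
         rotation = rotation, rotmat = rotmat,
         eigenvalues = vals, cor_method = cor_method),
    class = "pca_loadings"
  )
}

#' @export
print.pca_loadings <- function(x, digits = 3, ...) {
  cat("<pca_loadings> ", ncol(x$loadings), " components (",
      x$rotation, " rotation), cumulative variance ",
      format(x$cumulative_pct[length(x$cumulative_pct)], digits = 5),
      "%\n", sep = "")
  print(round(x$loadings, digits))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pca_loadings <- function(x, ...) {
  as_tibble(x$loadings, rownames = "variable") %>%
    tidyr::pivot_longer(-"variable", names_to = "component",
                        values_to = "loading")
}

#' @exportS3Method generics::glance
glance.pca_loadings <- function(x, ...) {
  tibble(n_components = ncol(x$loadings), rotation = x$rotation,
         cumulative_pct = x$cumulative_pct[length(x$cumulative_pct)])
}
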