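# Mantel and partial Mantel permutation tests on square organism matrices.
# "Stronger" is two-sided: a permutation counts when |rho_perm| > |rho_obs|.

offdiag_cells <- function(n, triangle) {
  if (triangle == "upper") which(upper.tri(matrix(0, n, n)))
  else which(row(matrix(0, n, n)) != col(matrix(0, n, n)))
}

mantel_vec <- function(m, cells, method) {
  v <- m[cells]
  if (method == "spearman") rank(v) else v
}

new_mantel_result <- function(rho, n_stronger, n_perm, method, triangle, partial = NA) {
  structure(
    list(rho = rho, p_value = (n_stronger + 1) / (n_perm + 1),
         n_perm = n_perm, n_stronger = n_stronger, method = method,
         triangle = triangle, partial = partial),
    class = "mantel_result")
}

#' Mantel permutation test between two square matrices
#'
#' Computes the correlation (Spearman by default) between the off-diagonal
#' elements of `x` and `y`, then permutes the organism labels of `x`
#' (applying one random relabelling simultaneously to rows and columns)
#' `n_perm` times.  The p-value is `(n + 1) / (N + 1)` where `n` counts the
#' permutations whose correlation is stronger in absolute value than the
#' observed one.
#'
#' @param x,y square matrices with rows/columns aligned to the same
#'   organisms.
#' @param n_perm number of permutations (default 10000).
#' @param method `"spearman"` or `"pearson"`.
#' @param triangle `"both"` uses every off-diagonal cell (appropriate for
#'   directional metrics); `"upper"` uses the upper triangle only (for
#'   symmetric matrices).
#' @param seed optional integer seed.
#' @return object of class `mantel_result` with `rho`, `p_value`, `n_perm`,
#'   `n_stronger`, `method`.
#' @export
mantel <- function(x, y, n_perm = 10000, method = c("spearman", "pearson"),
                   triangle = c("both", "upper"), seed = NULL) {
  method <- match.arg(method)
  triangle <- match.arg(triangle)
  x <- as.matrix(x); y <- as.matrix(y)
  if (!all(dim(x) == dim(y)) || nrow(x) != ncol(x)) {
    stop("x and y must be square matrices of the same dimension")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(x)
  cells <- offdiag_cells(n, triangle)
  vy <- mantel_vec(y, cells, method)
  vx <- mantel_vec(x, cells, method)
  if (sd(vx) == 0 || sd(vy) == 0) {
    stop("constant off-diagonal values: correlation undefined")
  }
  zy <- (vy - mean(vy)) / sd(vy)
  rho_obs <- mean(((vx - mean(vx)) / sd(vx)) * zy) * length(cells) / (length(cells) - 1)
  n_stronger <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    vxp <- mantel_vec(x[perm, perm], cells, method)
    if (sd(vxp) == 0) next
    r <- mean(((vxp - mean(vxp)) / sd(vxp)) * zy) * length(cells) / (length(cells) - 1)
    if (abs(r) > abs(rho_obs)) n_stronger <- n_stronger + 1L
  }
  new_mantel_result(rho_obs, n_stronger, n_perm, method, triangle)
}

#' Partial Mantel test controlling for a third matrix
#'
#' Partial correlation of the off-diagonals of `x` and `y` given `z`,
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`.  Only `x`
#' is permuted; `r_yz` is fixed.
#'
#' @inheritParams mantel
#' @param z the controlled matrix.
#' @export
partial_mantel <- function(x, y, z, n_perm = 10000,
                           method = c("spearman", "pearson"),
                           triangle = c("both", "upper"), seed = NULL) {
  method <- match.arg(method)
  triangle <- match.arg(triangle)
  x <- as.matrix(x); y <- as.matrix(y); z <- as.matrix(z)
  if (!all(dim(x) == dim(y)) || !all(dim(x) == dim(z)) || nrow(x) != ncol(x)) {
    stop("x, y and z must be square matrices of the same dimension")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(x)
  cells <- offdiag_cells(n, triangle)
  vy <- mantel_vec(y, cells, method)
  vz <- mantel_vec(z, cells, method)
  vx <- mantel_vec(x, cells, method)
  if (sd(vx) == 0 || sd(vy) == 0 || sd(vz) == 0) {
    stop("constant off-diagonal values: correlation undefined")
  }
  r_yz <- cor(vy, vz)
  if (abs(r_yz) >= 1 - 1e-12) {
    stop("y and z are perfectly correlated: partial correlation undefined")
  }
  partial_r <- function(vxp) {
    r_xy <- cor(vxp, vy); r_xz <- cor(vxp, vz)
    den <- sqrt((1 - r_xz^2) * (1 - r_yz^2))
    if (den < 1e-12) return(NA_real_)
    (r_xy - r_xz * r_yz) / den
  }
  rho_obs <- partial_r(vx)
  if (is.na(rho_obs)) stop("x is perfectly correlated with z: partial correlation undefined")
  n_stronger <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    r <- partial_r(mantel_vec(x[perm, perm], cells, method))
    if (!is.na(r) && abs(r) > abs(rho_obs)) n_stronger <- n_stronger + 1L
  }
  new_mantel_result(rho_obs, n_stronger, n_perm, method, triangle, partial = "z")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat("<mantel_result>", if (!is.na(x$partial)) "(partial)" else "",
      " rho =", format(x$rho, digits = 4),
      " p =", format(x$p_value, digits = 4),
      " (", x$n_stronger, "/", x$n_perm, " stronger)\n")
  invisible(x)
}
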