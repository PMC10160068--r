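#' Shannon diversity (natural log)
#'
#' H = -sum p_i ln p_i over positive entries, with p_i = x_i / sum(x).
#'
#' @param x non-negative abundance vector with at least one positive entry.
#' @return H in nats.
#' @export
shannon <- function(x) {
  if (any(x < 0)) abort_validation("negative abundance")
  s <- sum(x)
  if (s <= 0) abort_validation("all-zero abundance vector")
  p <- x[x > 0] / s
  -sum(p * log(p))
}

#' Bray-Curtis dissimilarity
#'
#' d = 1 - 2 sum(min(x_i, y_i)) / (sum x + sum y), in 0..1.
#'
#' @param x,y non-negative vectors of equal length, not both all-zero.
#' @return dissimilarity in 0..1.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) abort_validation("length mismatch")
  if (any(x < 0) || any(y < 0)) abort_validation("negative abundance")
  denom <- sum(x) + sum(y)
  if (denom <= 0) abort_validation("both vectors all-zero")
  1 - 2 * sum(pmin(x, y)) / denom
}

#' Bray-Curtis distance matrix between sample columns
#'
#' @param abundance matrix (features x samples).
#' @return symmetric matrix with zero diagonal, sample ids as dimnames.
#' @export
bray_curtis_matrix <- function(abundance) {
  n <- ncol(abundance)
  ids <- colnames(abundance)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- bray_curtis(abundance[, i], abundance[, j])
    }
  }
  d
}

#' Euclidean distance matrix between numeric covariate rows
#'
#' @param x data.frame or matrix (samples x covariates); rownames are ids.
#' @param scale standardize columns first (default TRUE).
#' @return symmetric distance matrix.
#' @export
covariate_distance <- function(x, scale = TRUE) {
  m <- as.matrix(x)
  if (scale) {
    sds <- apply(m, 2, stats::sd)
    sds[sds == 0] <- 1
    m <- sweep(sweep(m, 2, colMeans(m)), 2, sds, "/")
  }
  as.matrix(stats::dist(m))
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers -D^2/2, eigendecomposes, and builds coordinates from the
#' positive eigenvalues only. `variance_explained` is lambda_i over the sum
#' of positive eigenvalues; negative eigenvalues are reported, never folded
#' into coordinates. Sign convention: the first coordinate of each axis with
#' magnitude above 1e-8 is made positive.
#'
#' @param D symmetric distance matrix (zero diagonal).
#' @param k number of axes, 1 <= k < nrow(D).
#' @return list: coordinates (n x k), eigenvalues (all n), variance_explained
#'   (over positive eigenvalues).
#' @export
pcoa <- function(D, k = 2L) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (k >= n || k < 1) abort_validation("k must satisfy 1 <= k < n")
  if (max(abs(D - t(D))) > 1e-12) abort_validation("distance matrix not symmetric")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D * D) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- e$values > 1e-9 * max(abs(e$values), 1e-300)
  coords <- matrix(0, n, k, dimnames = list(rownames(D), paste0("PCo", 1:k)))
  n_pos <- sum(pos)
  use <- seq_len(min(k, n_pos))
  for (i in use) {
    ax <- e$vectors[, i] * sqrt(e$values[i])
    first <- which(abs(ax) > 1e-8)
    if (length(first) && ax[first[1]] < 0) ax <- -ax
    coords[, i] <- ax
  }
  ve <- if (n_pos > 0) e$values[seq_len(n_pos)] / sum(e$values[pos]) else numeric(0)
  list(coordinates = coords, eigenvalues = e$values,
       variance_explained = ve[seq_len(min(k, n_pos))],
       n_positive = n_pos)
}

#' Mantel permutation test
#'
#' Statistic: correlation (Spearman by default) of the upper-triangle
#' vectors of two distance matrices over the same ids. The null distribution
#' permutes the row/column labels of D2 jointly; one-sided p =
#' (1 + #permutations with statistic >= observed) / (1 + n_perm).
#' With `exhaustive = TRUE`, all n! - 1 non-identity permutations are
#' enumerated (n <= 8).
#'
#' @param D1,D2 distance matrices with matching dimnames order.
#' @param n_perm number of permutations (default 999).
#' @param method "spearman" (default) or "pearson".
#' @param seed RNG seed for the permutations.
#' @param exhaustive enumerate all permutations instead of sampling.
#' @return list: statistic, p_value, n_perm, method.
#' @export
mantel_test <- function(D1, D2, n_perm = 999L, method = c("spearman", "pearson"),
                        seed = 1L, exhaustive = FALSE) {
  method <- match.arg(method)
  D1 <- as.matrix(D1); D2 <- as.matrix(D2)
  if (!is.null(rownames(D1)) && !is.null(rownames(D2)) &&
      !identical(rownames(D1), rownames(D2))) {
    abort_validation("mantel: matrix ids do not match")
  }
  if (nrow(D1) != nrow(D2)) abort_validation("mantel: dimension mismatch")
  n <- nrow(D1)
  v1 <- upper_tri_vec(D1)
  stat_for <- function(perm) {
    cor(v1, upper_tri_vec(D2[perm, perm]), method = method)
  }
  obs <- stat_for(seq_len(n))
  if (exhaustive) {
    if (n > 8) abort_validation("exhaustive mantel limited to n <= 8")
    perms <- all_permutations(n)
    perms <- perms[-1, , drop = FALSE]  # drop identity (first in lex order)
    stats_perm <- apply(perms, 1, stat_for)
    n_perm <- nrow(perms)
  } else {
    if (n_perm < 1) abort_validation("n_perm must be >= 1")
    stats_perm <- withr::with_seed(seed, {
      vapply(seq_len(n_perm), function(i) stat_for(sample.int(n)), numeric(1))
    })
  }
  p <- (1 + sum(stats_perm >= obs - 1e-12)) / (1 + n_perm)
  list(statistic = obs, p_value = p, n_perm = as.integer(n_perm), method = method)
}

# All permutations of 1..n in lexicographic order (identity first).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    out <- rbind(out, cbind(first, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  unname(out)
}

#' Pearson correlation with two-sided t-based p-value
#'
#' r by the product-moment formula; p from t = r sqrt((n-2)/(1-r^2))
#' against t(n-2).
#'
#' @param x,y numeric vectors, n >= 3, non-constant.
#' @return list: statistic (r), p_value, method.
#' @export
pearson_test <- function(x, y) {
  n <- length(x)
  if (n < 3 || length(y) != n) abort_validation("pearson needs n >= 3 equal-length vectors")
  if (var(x) == 0 || var(y) == 0) abort_validation("constant vector")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(statistic = r, p_value = p, method = "pearson")
}

#' Two-sample t-test (Student or Welch)
#'
#' Student: pooled variance, df = n_a + n_b - 2. Welch: Satterthwaite df.
#' Two-sided p. Zero pooled variance with equal means gives t = 0, p = 1;
#' zero variance with unequal means is an error.
#'
#' @param a,b numeric samples, each n >= 2.
#' @param variant "student" (default) or "welch".
#' @return list: statistic, p_value, df, method.
#' @export
t_test <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) abort_validation("each sample needs n >= 2")
  va <- var(a); vb <- var(b)
  dm <- mean(a) - mean(b)
  if (va == 0 && vb == 0) {
    if (dm == 0) return(list(statistic = 0, p_value = 1,
                             df = if (variant == "student") na + nb - 2 else NA_real_,
                             method = variant))
    abort_validation("zero variance with unequal means")
  }
  if (variant == "student") {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tstat <- dm / se
  list(statistic = tstat, p_value = 2 * pt(-abs(tstat), df = df), df = df,
       method = variant)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin wrapper over [stats::p.adjust()] used when many correlations are
#' screened; reported alongside raw p-values.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values.
#' @export
adjust_fdr <- function(p) stats::p.adjust(p, method = "BH")
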