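#' Shannon alpha diversity
#'
#' Shannon index in natural-log units over the nonzero proportions of an
#' abundance vector.
#'
#' @param x Non-negative abundance vector (need not be normalised).
#' @return H in nats.
#' @export
shannon_diversity <- function(x) {
  if (any(x < 0)) stop("negative abundances")
  if (sum(x) == 0) stop("all-zero abundance vector")
  unname(vegan::diversity(x, index = "shannon"))
}

#' Element-wise log transform with pseudocount
#'
#' VRU data are normalised by log-transformation to tame the large
#' differences in relative abundance among viruses; the pseudocount handles
#' exact zeros. Default pseudocount is half the smallest nonzero value.
#'
#' @param values Numeric matrix or vector of non-negative abundances.
#' @param pseudocount Positive value added before \code{log}; 0 allowed only
#'   when no zeros are present. \code{NULL} picks half the smallest nonzero
#'   entry.
#' @return Transformed object of the same shape.
#' @export
log_transform <- function(values, pseudocount = NULL) {
  if (is.null(pseudocount)) {
    nz <- values[values > 0]
    if (length(nz) == 0) stop("all-zero table; cannot choose a pseudocount")
    pseudocount <- min(nz) / 2
  }
  if (pseudocount == 0 && any(values == 0)) {
    stop("zeros present; a positive pseudocount is required")
  }
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  log(values + pseudocount)
}

#' Pearson-correlation distance between samples
#'
#' d(i, j) = 1 - r(i, j), the Pearson correlation between the two samples'
#' (log-abundance) profiles; distances lie in [0, 2].
#'
#' @param x Numeric matrix, samples in rows, features in columns.
#' @return Symmetric distance matrix with zero diagonal, sample IDs as
#'   dimnames.
#' @export
pearson_distance <- function(x) {
  stopifnot(nrow(x) >= 2, ncol(x) >= 2)
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance sample profile: ",
         paste(rownames(x)[sds == 0], collapse = ", "))
  }
  d <- 1 - stats::cor(t(x))
  d[d < 0] <- 0          # clamp -eps from floating point
  diag(d) <- 0
  d
}

#' Principal coordinates analysis
#'
#' Classical metric scaling: Gower double centering of the squared distances
#' and eigendecomposition. Negative eigenvalues (possible for non-Euclidean
#' distances such as 1 - r) are reported but excluded from the
#' proportion-explained denominator.
#'
#' @param d Symmetric distance matrix.
#' @param k Number of axes to return (default all positive ones).
#' @return List of class \code{pcoa_result}: \code{coordinates} (n x k),
#'   \code{eigenvalues} (all, descending), \code{proportion_explained}
#'   (over positive eigenvalues only).
#' @export
pcoa <- function(d, k = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("PCoA needs at least 3 samples")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix not symmetric")
  cs <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = n - 1, eig = TRUE))
  eig <- cs$eig
  pos <- eig > 1e-8 * max(abs(eig))
  npos <- sum(pos)
  if (is.null(k)) k <- npos
  k <- min(k, npos)
  coords <- cs$points[, seq_len(k), drop = FALSE]
  rownames(coords) <- rownames(d)
  out <- list(coordinates = coords,
              eigenvalues = eig,
              proportion_explained = eig[seq_len(k)] / sum(eig[pos]))
  class(out) <- "pcoa_result"
  out
}

#' @export
print.pcoa_result <- function(x, ...) {
  k <- ncol(x$coordinates)
  cat("PCoA: ", nrow(x$coordinates), " samples, ", k, " axes\n", sep = "")
  cat("  proportion explained:",
      paste(sprintf("%.1f%%", 100 * x$proportion_explained[seq_len(min(3, k))]),
            collapse = ", "), "\n")
  invisible(x)
}

# Gower-centered inner-product matrix from a distance matrix
gower_center <- function(d) {
  a <- -0.5 * d^2
  rm <- rowMeans(a); gm <- mean(a)
  sweep(sweep(a, 1, rm), 2, rm) + gm
}

#' PERMANOVA from a distance matrix
#'
#' Permutational multivariate analysis of variance with sequential sums of
#' squares in the order the factors are given, as in the classic adonis
#' formulation: the total sum of squares is tr(G) of the Gower-centered
#' matrix, each term's SS is the sequential increment of tr(H G), the
#' pseudo-F compares each term's mean square to the residual one, and
#' p-values come from permuting sample labels.
#'
#' @param d Symmetric distance matrix.
#' @param meta data.frame of sample covariates, rows aligned with \code{d}.
#' @param factors Character vector of column names, in model order.
#' @param n_perm Number of permutations (ignored when \code{permutations}
#'   given).
#' @param seed Integer seed for the permutation stream.
#' @param permutations Optional integer matrix, one permutation per row, for
#'   exact tests by complete enumeration.
#' @return data.frame of class \code{permanova_result}: one row per factor
#'   plus a residual/total block, with \code{df}, \code{ss}, \code{r2},
#'   \code{f}, \code{p}.
#' @export
permanova <- function(d, meta, factors, n_perm = 999, seed = 1,
                      permutations = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(nrow(meta) == n, all(factors %in% names(meta)))
  if (is.null(permutations) && n_perm < 99) stop("n_perm must be >= 99")
  for (f in factors) {
    lev <- unique(as.character(meta[[f]]))
    if (length(lev) < 2) stop("factor ", f, " has fewer than 2 levels")
    if (length(lev) == n) stop("factor ", f, " is confounded with sample identity")
  }
  G <- gower_center(d)
  ss_total <- sum(diag(G))

  hats <- hat_sequence(meta, factors)
  stats_for <- function(Gp) {
    ss_seq <- numeric(length(factors))
    prev <- 0
    for (k in seq_along(factors)) {
      expl <- sum(hats[[k]] * Gp)   # tr(H_k G)
      ss_seq[k] <- expl - prev
      prev <- expl
    }
    ss_res <- ss_total - prev
    list(ss = ss_seq, ss_res = ss_res)
  }
  obs <- stats_for(G)
  df <- vapply(seq_along(factors), function(k) {
    qr_rank(meta, factors[seq_len(k)]) - qr_rank(meta, factors[seq_len(k - 1)])
  }, numeric(1))
  df_res <- n - 1 - sum(df)
  f_obs <- (obs$ss / df) / (obs$ss_res / df_res)

  if (is.null(permutations)) {
    set.seed(seed)
    permutations <- t(replicate(n_perm, sample.int(n)))
  }
  n_perm <- nrow(permutations)
  count_ge <- rep(0L, length(factors))
  for (p in seq_len(n_perm)) {
    idx <- permutations[p, ]
    st <- stats_for(G[idx, idx, drop = FALSE])
    f_p <- (st$ss / df) / (st$ss_res / df_res)
    count_ge <- count_ge + (f_p >= f_obs - 1e-12)
  }
  pval <- (1 + count_ge) / (1 + n_perm)
  out <- data.frame(
    term = c(factors, "Residual", "Total"),
    df = c(df, df_res, n - 1),
    ss = c(obs$ss, obs$ss_res, ss_total),
    r2 = c(obs$ss, obs$ss_res, ss_total) / ss_total,
    f = c(f_obs, NA, NA),
    p = c(pval, NA, NA),
    stringsAsFactors = FALSE
  )
  class(out) <- c("permanova_result", "data.frame")
  attr(out, "n_perm") <- n_perm
  out
}

# hat matrices of the nested model sequence X_1, (X_1, X_2), ...
hat_sequence <- function(meta, factors) {
  lapply(seq_along(factors), function(k) {
    X <- stats::model.matrix(
      stats::as.formula(paste("~", paste(factors[seq_len(k)], collapse = "+"))),
      data = meta)
    q <- qr(X)
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    Q %*% t(Q)
  })
}

qr_rank <- function(meta, factors) {
  if (length(factors) == 0) return(1)
  X <- stats::model.matrix(
    stats::as.formula(paste("~", paste(factors, collapse = "+"))), data = meta)
  qr(X)$rank
}

#' All permutations of 1..n (for exact PERMANOVA on tiny n)
#'
#' @param n Number of samples (n! rows; keep n small).
#' @return Integer matrix, one permutation per row.
#' @export
all_permutations <- function(n) {
  stopifnot(n >= 1, n <= 8)
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}
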