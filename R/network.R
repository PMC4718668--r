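#' Correlation networks from intersubject expression
#'
#' For one group, the adjacency matrix holds the Pearson correlation of
#' expression between every pair of regions computed across that group's
#' subjects ("coordinated gene expression", the IEG analogue of functional
#' connectivity). Each correlation carries a two-tailed p-value from the
#' conventional t-test with n - 2 degrees of freedom; thresholding zeroes
#' all non-significant entries, retaining sign and magnitude of the rest.
#'
#' @name cge_network
NULL

#' Two-tailed p-value of a Pearson correlation
#'
#' Uses the t statistic t = r * sqrt((n - 2) / (1 - r^2)) with df = n - 2.
#' `p(0, n) = 1`; `|r| = 1` gives p = 0 without overflow. A one-tailed
#' variant halves the two-tailed value for the observed sign.
#'
#' @param r Pearson coefficient(s), |r| <= 1.
#' @param n number of subjects (>= 4).
#' @param tails 2 (default) or 1.
#' @return p-value(s) in [0, 1].
#' @export
#' @examples
#' correlation_pvalue(0, 7)    # 1
#' correlation_pvalue(0.9, 7)  # ~0.0058
correlation_pvalue <- function(r, n, tails = 2) {
  if (any(n < 4)) stop("DomainError: n must be >= 4", call. = FALSE)
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) {
    stop("DomainError: |r| must be <= 1", call. = FALSE)
  }
  r <- pmin(pmax(r, -1), 1)
  df <- n - 2
  p <- ifelse(abs(r) >= 1, 0,
              2 * stats::pt(abs(r) * sqrt(df / (1 - r^2)), df,
                            lower.tail = FALSE))
  if (tails == 1) p <- p / 2
  pmin(p, 1)
}

#' Exact/subsampled permutation p-value for one correlation
#'
#' Reference test used for cross-checking the t-based p-value: the observed
#' |r| is compared with |r| under permutations of one variable's subject
#' labels. All n! pairings are enumerated when feasible, otherwise `max_perm`
#' random permutations are sampled (seeded).
#'
#' @param x,y numeric vectors of equal length n >= 4.
#' @param max_perm enumeration cutoff (default 5040 = 7!).
#' @param seed RNG seed for subsampling.
#' @return two-tailed permutation p-value.
#' @export
permutation_pvalue <- function(x, y, max_perm = 5040L, seed = 1L) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 4L)
  r_obs <- abs(stats::cor(x, y))
  if (factorial(n) <= max_perm) {
    perms <- all_permutations(n)
  } else {
    perms <- with_seed(seed, t(replicate(max_perm, sample.int(n))))
  }
  r_perm <- abs(apply(perms, 1L, function(ix) stats::cor(x, y[ix])))
  mean(r_perm >= r_obs - 1e-12)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

new_correlation_network <- function(gene, age, treatment, regions, r, p, n) {
  structure(list(gene = gene, age = age, treatment = treatment,
                 regions = regions, r = r, p = p, n = n),
            class = "correlation_network")
}

#' Build the intersubject correlation network for one group
#'
#' Subjects with any missing region are dropped listwise (the Fisher
#' comparison downstream assumes a single n per network). Regions with zero
#' variance across subjects get r = 0, p = 1 on all their edges, with a
#' warning. Diagonal entries are fixed at 0 (r) and 1 (p) and are never
#' treated as edges.
#'
#' @param table an `expression_table`.
#' @param gene,age,treatment group key.
#' @param registry region registry fixing matrix order and dimension.
#' @param tails 1 or 2 (default) tailed p-values.
#' @return a `correlation_network` with fields `r`, `p` (symmetric matrices
#'   over the registry regions) and `n` (subjects used).
#' @export
pearson_network <- function(table, gene, age, treatment,
                            registry = default_region_registry(),
                            tails = 2) {
  m <- group_matrix(table, gene, age, treatment, registry)
  n <- nrow(m)
  if (n < 4L) {
    stop("InsufficientSubjects: group (", gene, ", ", age, ", ", treatment,
         ") has n = ", n, " complete subjects (need >= 4)", call. = FALSE)
  }
  sds <- apply(m, 2L, stats::sd)
  degenerate <- sds == 0 | !is.finite(sds)
  if (any(degenerate)) {
    warning("ZeroVariance: region(s) with constant expression: ",
            paste(colnames(m)[degenerate], collapse = ", "),
            "; their edges are set r = 0, p = 1", call. = FALSE)
  }
  r <- suppressWarnings(stats::cor(m))
  r[degenerate, ] <- 0
  r[, degenerate] <- 0
  r[!is.finite(r)] <- 0
  diag(r) <- 0
  p <- correlation_pvalue(r, n, tails = tails)
  p[degenerate, ] <- 1
  p[, degenerate] <- 1
  diag(p) <- 1
  new_correlation_network(gene, age, treatment, colnames(m), r, p, n)
}

#' Threshold a correlation network by edge significance
#'
#' Entries with p >= alpha are set to zero; surviving entries keep the sign
#' and magnitude of r. Lowering alpha can only shrink the edge set.
#'
#' @param net a `correlation_network`.
#' @param alpha significance level in (0, 1); default 0.05.
#' @return a `thresholded_network` with weight matrix `w`.
#' @export
threshold_network <- function(net, alpha = 0.05) {
  stopifnot(inherits(net, "correlation_network"), alpha > 0, alpha < 1)
  w <- ifelse(net$p < alpha, net$r, 0)
  diag(w) <- 0
  structure(list(gene = net$gene, age = net$age, treatment = net$treatment,
                 regions = net$regions, w = w, alpha = alpha, n = net$n),
            class = "thresholded_network")
}

#' Number of retained (non-zero) edges of a thresholded network
#'
#' @param net a `thresholded_network`.
#' @return integer count of unique off-diagonal edges.
#' @export
edge_count <- function(net) {
  sum(net$w[upper.tri(net$w)] != 0)
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("<correlation_network> %s/%s/%s: %d x %d, n = %d subjects\n",
              x$gene, x$age, x$treatment, nrow(x$r), ncol(x$r), x$n))
  invisible(x)
}

#' @export
print.thresholded_network <- function(x, ...) {
  cat(sprintf(
    "<thresholded_network> %s/%s/%s: %d x %d, alpha = %g, %d edge(s)\n",
    x$gene, x$age, x$treatment, nrow(x$w), ncol(x$w), x$alpha,
    edge_count(x)))
  invisible(x)
}

#' Write a square matrix as CSV with region-id header row and column
#'
#' @param m square matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_square_csv <- function(m, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("region_id", colnames(m)), collapse = ","), con)
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])), collapse = ",")
  }, "")
  writeLines(rows, con)
  invisible(path)
}

#' Read a square CSV written by [write_square_csv()]
#'
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
read_square_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}
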