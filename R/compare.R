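#' Edge-wise statistical comparison of two correlation networks
#'
#' Drug-activated networks are compared with the matched baseline network
#' edge by edge: both correlation matrices are Fisher r-to-z transformed
#' (to improve normality), the per-edge difference of z scores is divided
#' by its standard error, sqrt(1/(n_a - 3) + 1/(n_b - 3)), and the
#' resulting standard-normal difference scores receive two-tailed p-values
#' corrected by false discovery rate across the family of unique edges
#' (default q = 0.35, a deliberately liberal level prioritizing the
#' avoidance of Type II errors in low signal-to-noise networks).
#' Comparison always uses the *unthresholded* r matrices; the per-group
#' thresholded states are consulted only to classify significant changes
#' into gain/loss of positive/negative coordinated expression, so the
#' difference map stays consistent with the visualized networks.
#'
#' @name network_compare
NULL

#' Fisher r-to-z transform
#'
#' z = atanh(r) = 0.5 * ln((1 + r) / (1 - r)). Values with |r| >= 1 - 1e-7
#' are clamped to that bound (with a warning) so degenerate perfect
#' correlations stay finite.
#'
#' @param r correlation coefficient(s), |r| <= 1.
#' @return z value(s).
#' @export
#' @examples
#' fisher_z(0.5)  # 0.5493061
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) {
    stop("DomainError: |r| must be <= 1", call. = FALSE)
  }
  eps <- 1e-7
  clamped <- abs(r) > 1 - eps
  if (any(clamped, na.rm = TRUE)) {
    warning(sum(clamped, na.rm = TRUE),
            " correlation(s) with |r| ~ 1 clamped before the z transform",
            call. = FALSE)
    r <- pmin(pmax(r, -(1 - eps)), 1 - eps)
  }
  atanh(r)
}

#' Per-edge Fisher z difference scores between two networks
#'
#' Z = (z_a - z_b) / sqrt(1/(n_a - 3) + 1/(n_b - 3)), with a two-tailed
#' standard-normal p-value. Computed on the full (unthresholded) r
#' matrices. The convention is a = drug, b = baseline, so positive Z means
#' the correlation strengthened under drug.
#'
#' @param net_a,net_b `correlation_network` objects over identical region
#'   sets (a = drug, b = baseline).
#' @return data frame with one row per unique edge: `region_a`, `region_b`,
#'   `r_a`, `r_b`, `z_a`, `z_b`, `Z`, `p`.
#' @export
z_difference <- function(net_a, net_b) {
  stopifnot(inherits(net_a, "correlation_network"),
            inherits(net_b, "correlation_network"))
  if (!identical(net_a$regions, net_b$regions)) {
    stop("RegionMismatch: networks cover different region sets",
         call. = FALSE)
  }
  if (net_a$n < 4L || net_b$n < 4L) {
    stop("InsufficientSubjects: Fisher SE requires n > 3 in both groups",
         call. = FALSE)
  }
  regions <- net_a$regions
  idx <- which(upper.tri(net_a$r), arr.ind = TRUE)
  r_a <- net_a$r[idx]
  r_b <- net_b$r[idx]
  z_a <- suppressWarnings(fisher_z(r_a))
  z_b <- suppressWarnings(fisher_z(r_b))
  clamped <- abs(r_a) > 1 - 1e-7 | abs(r_b) > 1 - 1e-7
  se <- sqrt(1 / (net_a$n - 3) + 1 / (net_b$n - 3))
  Z <- (z_a - z_b) / se
  data.frame(region_a = regions[idx[, 1L]],
             region_b = regions[idx[, 2L]],
             r_a = r_a, r_b = r_b, z_a = z_a, z_b = z_b,
             Z = Z, p = 2 * stats::pnorm(-abs(Z)),
             clamped = clamped,
             stringsAsFactors = FALSE)
}

#' FDR adjustment of edge p-values
#'
#' Benjamini-Hochberg step-up by default (adjusted p_(i) = min over j >= i
#' of m * p_(j) / j, capped at 1); Benjamini-Yekutieli available for
#' dependence-robust control. Each network comparison is corrected as its
#' own family of unique edges.
#'
#' @param pvals vector of p-values in [0, 1].
#' @param q_level FDR level (default 0.35).
#' @param method `"BH"` (default) or `"BY"`.
#' @return data frame with `p`, `q_adj`, `significant`.
#' @export
fdr_adjust <- function(pvals, q_level = 0.35, method = c("BH", "BY")) {
  if (length(pvals) == 0L) stop("EmptyInput: no p-values", call. = FALSE)
  stopifnot(all(pvals >= 0 & pvals <= 1))
  method <- match.arg(method)
  q_adj <- stats::p.adjust(pvals, method = method)
  data.frame(p = pvals, q_adj = q_adj, significant = q_adj <= q_level)
}

# per-edge thresholded state: "pos", "neg" or "null"
edge_state <- function(w) {
  ifelse(w > 0, "pos", ifelse(w < 0, "neg", "null"))
}

#' Build a classified difference map
#'
#' Applies FDR correction to the z-difference p-values and classifies each
#' significant edge by the transition of its thresholded state from
#' baseline to drug: null->pos = `gain_positive`, pos->null =
#' `loss_positive`, null->neg = `gain_negative`, neg->null =
#' `loss_negative`, pos->neg / neg->pos = `sign_reversal`. Significant
#' edges whose state does not change (pos->pos or neg->neg strength
#' changes) keep class `none` and are flagged in the supplementary
#' `strength_change` column; non-significant edges are class `none`.
#'
#' @param diff per-edge statistics from [z_difference()].
#' @param thr_a,thr_b `thresholded_network` objects for the drug (a) and
#'   baseline (b) groups.
#' @param q_level FDR level (default 0.35).
#' @param method FDR variant passed to [fdr_adjust()].
#' @return a `difference_map`: the `diff` data frame plus `q_adj`,
#'   `significant`, `class`, `strength_change`, with attributes `q_level`,
#'   `method` and the two group labels.
#' @export
classify_edges <- function(diff, thr_a, thr_b, q_level = 0.35,
                           method = "BH") {
  stopifnot(inherits(thr_a, "thresholded_network"),
            inherits(thr_b, "thresholded_network"))
  if (!identical(thr_a$regions, thr_b$regions)) {
    stop("RegionMismatch: thresholded networks differ in regions",
         call. = FALSE)
  }
  adj <- fdr_adjust(diff$p, q_level = q_level, method = method)
  diff$q_adj <- adj$q_adj
  diff$significant <- adj$significant
  ia <- cbind(match(diff$region_a, thr_a$regions),
              match(diff$region_b, thr_a$regions))
  if (anyNA(ia)) {
    stop("RegionMismatch: difference edges not resolvable in networks",
         call. = FALSE)
  }
  s_a <- edge_state(thr_a$w[ia])
  s_b <- edge_state(thr_b$w[ia])
  cls <- rep("none", nrow(diff))
  strength <- rep(FALSE, nrow(diff))
  sig <- diff$significant
  trans <- paste(s_b, s_a, sep = "->")
  cls[sig & trans == "null->pos"] <- "gain_positive"
  cls[sig & trans == "pos->null"] <- "loss_positive"
  cls[sig & trans == "null->neg"] <- "gain_negative"
  cls[sig & trans == "neg->null"] <- "loss_negative"
  cls[sig & trans %in% c("pos->neg", "neg->pos")] <- "sign_reversal"
  strength[sig & trans %in% c("pos->pos", "neg->neg", "null->null")] <- TRUE
  diff$class <- cls
  diff$strength_change <- strength
  attr(diff, "q_level") <- q_level
  attr(diff, "method") <- method
  attr(diff, "group_a") <- group_label(thr_a$gene, thr_a$age,
                                       thr_a$treatment)
  attr(diff, "group_b") <- group_label(thr_b$gene, thr_b$age,
                                       thr_b$treatment)
  class(diff) <- c("difference_map", "data.frame")
  diff
}

#' Compare two groups end to end
#'
#' Convenience wrapper: builds both correlation networks, thresholds them,
#' computes z differences on the unthresholded matrices, FDR-adjusts, and
#' classifies.
#'
#' @param table an `expression_table`.
#' @param group_a,group_b lists with `gene`, `age`, `treatment`
#'   (a = drug, b = baseline).
#' @param registry region registry.
#' @param alpha visualization threshold for the state classification.
#' @param q_level,method FDR options.
#' @return a `difference_map`.
#' @export
compare_groups <- function(table, group_a, group_b,
                           registry = default_region_registry(),
                           alpha = 0.05, q_level = 0.35, method = "BH") {
  net_a <- pearson_network(table, group_a$gene, group_a$age,
                           group_a$treatment, registry)
  net_b <- pearson_network(table, group_b$gene, group_b$age,
                           group_b$treatment, registry)
  diff <- z_difference(net_a, net_b)
  classify_edges(diff, threshold_network(net_a, alpha),
                 threshold_network(net_b, alpha),
                 q_level = q_level, method = method)
}

#' Write a difference map as TSV
#'
#' Columns: `region_a, region_b, r_drug, r_base, Z, p, q_adj, significant,
#' class, strength_change`.
#'
#' @param diff a `difference_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_difference_map <- function(diff, path) {
  out <- data.frame(region_a = diff$region_a, region_b = diff$region_b,
                    r_drug = sprintf("%.17g", diff$r_a),
                    r_base = sprintf("%.17g", diff$r_b),
                    Z = sprintf("%.17g", diff$Z),
                    p = sprintf("%.17g", diff$p),
                    q_adj = sprintf("%.17g", diff$q_adj),
                    significant = diff$significant,
                    class = diff$class,
                    strength_change = diff$strength_change,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' @export
print.difference_map <- function(x, ...) {
  cat(sprintf("<difference_map> %s vs %s: %d edges, %d significant (q <= %g)\n",
              attr(x, "group_a"), attr(x, "group_b"), nrow(x),
              sum(x$significant), attr(x, "q_level")))
  sig <- x[x$significant, , drop = FALSE]
  if (nrow(sig) > 0L) print(table(sig$class))
  invisible(x)
}
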