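#' Community structure of thresholded weighted signed networks
#'
#' Communities are found by modularity maximization. For positive-only
#' weights the objective is the standard Newman-Girvan weighted modularity
#' with resolution gamma,
#'   Q = sum_c [ W_cc / 2m - gamma * (K_c / 2m)^2 ],
#' where W_cc is the total weight inside community c and K_c its total
#' degree. Thresholded networks can carry negative edges (significant
#' anticorrelations); these are handled with the asymmetric signed
#' composite
#'   Q* = Q+ - (m- / (m+ + m-)) * Q-,
#' computed on the positive and negative sub-networks separately, so that
#' positive structure dominates and sparse negative edges discourage - but
#' cannot by themselves dictate - co-assignment. A `positive_only` mode
#' zeroes negative weights instead.
#'
#' @name community
NULL

# Q of one sign's sub-network under the flat formula with tw = sum(w),
# k = rowSums(w) (diagonal included once, which makes the formula invariant
# under community aggregation).
modularity_part <- function(w, memb, gamma) {
  tw <- sum(w)
  if (tw <= 0) return(0)
  same <- outer(memb, memb, "==")
  k <- rowSums(w)
  kc <- rowsum(k, memb)
  sum(w[same]) / tw - gamma * sum(kc^2) / tw^2
}

split_signs <- function(w) {
  list(wp = pmax(w, 0), wn = pmax(-w, 0))
}

#' Modularity of a partition
#'
#' @param net a `thresholded_network` (or a plain symmetric weight matrix).
#' @param assignment community labels: a vector in region order, or named by
#'   region id.
#' @param gamma resolution parameter (default 1).
#' @param positive_only drop negative weights instead of using the signed
#'   composite.
#' @return modularity Q (Q* for signed input), 0 for an empty network.
#' @export
modularity_score <- function(net, assignment, gamma = 1,
                             positive_only = FALSE) {
  w <- if (inherits(net, "thresholded_network")) net$w else net
  regions <- colnames(w)
  if (!is.null(names(assignment)) && !is.null(regions)) {
    assignment <- assignment[regions]
  }
  if (length(assignment) != nrow(w) || anyNA(assignment)) {
    stop("assignment must cover every node exactly once", call. = FALSE)
  }
  memb <- match(assignment, unique(assignment))
  s <- split_signs(w)
  if (positive_only) s$wn[] <- 0
  mp <- sum(s$wp) / 2
  mn <- sum(s$wn) / 2
  if (mp + mn == 0) return(0)
  qp <- modularity_part(s$wp, memb, gamma)
  qn <- modularity_part(s$wn, memb, gamma)
  qp - (mn / (mp + mn)) * qn
}

# greedy local-moving sweeps on the signed pair: each node is offered every
# community it touches plus an empty one (singleton escape), taking the best
# strictly improving move, until a full sweep makes no move. memb uses
# labels in 1..n; lambda = mn/(mp+mn) is fixed from the original network.
local_moves <- function(wp, wn, memb, gamma, lambda, order) {
  n <- nrow(wp)
  twp <- sum(wp); twn <- sum(wn)
  kp <- rowSums(wp); kn <- rowSums(wn)
  Kp <- numeric(n)
  aggKp <- rowsum(kp, memb)
  Kp[as.integer(rownames(aggKp))] <- aggKp[, 1L]
  Kn <- numeric(n)
  aggKn <- rowsum(kn, memb)
  Kn[as.integer(rownames(aggKn))] <- aggKn[, 1L]
  size <- tabulate(memb, nbins = n)
  repeat {
    moved <- FALSE
    for (i in order) {
      a <- memb[i]
      lp <- numeric(n)
      ln <- numeric(n)
      aggp <- rowsum(wp[i, ], memb)
      aggn <- rowsum(wn[i, ], memb)
      lp[as.integer(rownames(aggp))] <- aggp[, 1L]
      ln[as.integer(rownames(aggn))] <- aggn[, 1L]
      lp[a] <- lp[a] - wp[i, i]
      ln[a] <- ln[a] - wn[i, i]
      # every non-empty community is a candidate (with negative weights a
      # zero-edge community can still be profitable through the degree
      # penalty), plus one empty community as a singleton escape
      cand <- which(size > 0L)
      if (size[a] > 1L) {
        empty <- which(size == 0L)
        if (length(empty) > 0L) cand <- c(cand, empty[1L])
      }
      gp <- if (twp > 0) {
        2 * (lp[cand] - lp[a]) / twp -
          (2 * gamma * kp[i] / twp^2) *
          (ifelse(cand == a, 0, kp[i] - Kp[a] + Kp[cand]))
      } else 0
      gn <- if (twn > 0) {
        2 * (ln[cand] - ln[a]) / twn -
          (2 * gamma * kn[i] / twn^2) *
          (ifelse(cand == a, 0, kn[i] - Kn[a] + Kn[cand]))
      } else 0
      gain <- gp - lambda * gn
      b <- cand[which.max(gain)]
      if (b != a && max(gain) > 1e-12) {
        memb[i] <- b
        Kp[a] <- Kp[a] - kp[i]; Kp[b] <- Kp[b] + kp[i]
        Kn[a] <- Kn[a] - kn[i]; Kn[b] <- Kn[b] + kn[i]
        size[a] <- size[a] - 1L; size[b] <- size[b] + 1L
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  memb
}

# Louvain: local moving + aggregation until the partition stops shrinking,
# then one refinement round of local moves at the original-node level.
louvain_signed <- function(wp0, wn0, gamma, lambda, order_fun) {
  n0 <- nrow(wp0)
  final <- seq_len(n0)      # original node -> current community
  wp <- wp0; wn <- wn0
  repeat {
    n <- nrow(wp)
    memb <- local_moves(wp, wn, seq_len(n), gamma, lambda, order_fun(n))
    labels <- match(memb, unique(memb))
    final <- labels[final]
    if (max(labels) == n) break
    M <- outer(labels, seq_len(max(labels)), "==") * 1
    wp <- t(M) %*% wp %*% M
    wn <- t(M) %*% wn %*% M
  }
  refined <- local_moves(wp0, wn0, match(final, unique(final)), gamma,
                         lambda, order_fun(n0))
  match(refined, unique(refined))
}

canonical_labels <- function(assignment) {
  match(assignment, unique(assignment))
}

new_partition <- function(regions, labels, Q, method, gamma, seed = NA_integer_,
                          restarts = NA_integer_) {
  labels <- canonical_labels(labels)
  names(labels) <- regions
  structure(list(assignment = labels, Q = Q, method = method,
                 gamma = gamma, seed = seed, restarts = restarts),
            class = "community_partition")
}

#' Detect communities by seeded multi-restart Louvain
#'
#' Runs a Louvain-style greedy agglomeration on the signed modularity
#' objective `restarts` times with randomized node orders (plus one pass in
#' natural order) and returns the best partition found. Deterministic given
#' `(seed, restarts)`. Isolated nodes end up as singleton communities; an
#' empty network yields the all-singleton partition with Q = 0.
#'
#' @param net a `thresholded_network` (or symmetric weight matrix with
#'   dimnames).
#' @param gamma resolution (default 1).
#' @param seed RNG seed for restart orders.
#' @param restarts number of randomized restarts (default 20).
#' @param positive_only zero out negative weights first.
#' @return a `community_partition` with fields `assignment` (named by
#'   region), `Q`, `method`, `gamma`, `seed`, `restarts`.
#' @export
detect_communities <- function(net, gamma = 1, seed = 1L, restarts = 20L,
                               positive_only = FALSE) {
  w <- if (inherits(net, "thresholded_network")) net$w else net
  regions <- colnames(w)
  if (is.null(regions)) regions <- paste0("V", seq_len(ncol(w)))
  s <- split_signs(w)
  if (positive_only) s$wn[] <- 0
  mp <- sum(s$wp) / 2
  mn <- sum(s$wn) / 2
  method <- if (positive_only) "louvain_positive" else "louvain_signed"
  if (mp + mn == 0) {
    return(new_partition(regions, seq_along(regions), 0, method, gamma,
                         seed, restarts))
  }
  lambda <- mn / (mp + mn)
  best <- NULL
  best_q <- -Inf
  with_seed(seed, {
    for (rep in seq_len(restarts + 1L)) {
      order_fun <- if (rep == 1L) {
        function(n) seq_len(n)
      } else {
        # freeze one shuffled order per pass
        local({
          cache <- list()
          function(n) {
            key <- as.character(n)
            if (is.null(cache[[key]])) cache[[key]] <<- sample.int(n)
            cache[[key]]
          }
        })
      }
      labels <- louvain_signed(s$wp, s$wn, gamma, lambda, order_fun)
      q <- modularity_score(w, labels, gamma, positive_only = positive_only)
      if (q > best_q + 1e-12 ||
          (abs(q - best_q) <= 1e-12 && !is.null(best) &&
             partition_precedes(labels, best))) {
        best <- canonical_labels(labels)
        best_q <- q
      }
    }
  })
  new_partition(regions, best, best_q, method, gamma, seed, restarts)
}

# tie-break order: fewer communities first, then lexicographically smaller
# canonical label vector
partition_precedes <- function(a, b) {
  a <- canonical_labels(a); b <- canonical_labels(b)
  na <- max(a); nb <- max(b)
  if (na != nb) return(na < nb)
  diff <- which(a != b)
  length(diff) > 0L && a[diff[1L]] < b[diff[1L]]
}

#' Exhaustive modularity maximization (test oracle)
#'
#' Enumerates every set partition of the nodes (Bell-number search) and
#' returns the argmax of the (signed) modularity. Ties are broken by fewest
#' communities, then lexicographically smallest assignment.
#'
#' @inheritParams detect_communities
#' @return a `community_partition`.
#' @export
brute_force_partition <- function(net, gamma = 1, positive_only = FALSE) {
  w <- if (inherits(net, "thresholded_network")) net$w else net
  n <- nrow(w)
  if (n > 10L) stop("TooLarge: brute force limited to <= 10 nodes",
                    call. = FALSE)
  regions <- colnames(w)
  if (is.null(regions)) regions <- paste0("V", seq_len(n))
  parts <- set_partitions(n)
  best <- parts[1L, ]
  best_q <- modularity_score(w, best, gamma, positive_only = positive_only)
  for (i in seq_len(nrow(parts))[-1L]) {
    lab <- parts[i, ]
    q <- modularity_score(w, lab, gamma, positive_only = positive_only)
    if (q > best_q + 1e-12 ||
        (abs(q - best_q) <= 1e-12 && partition_precedes(lab, best))) {
      best <- lab
      best_q <- q
    }
  }
  new_partition(regions, best, best_q, "brute_force", gamma)
}

# all set partitions of n elements as restricted-growth strings
set_partitions <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- set_partitions(n - 1L)
  out <- vector("list", nrow(sub))
  for (i in seq_len(nrow(sub))) {
    row <- sub[i, ]
    k <- max(row)
    out[[i]] <- cbind(matrix(row, k + 1L, n - 1L, byrow = TRUE),
                      seq_len(k + 1L))
  }
  do.call(rbind, out)
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %d communities, Q = %.4f (%s, gamma = %g)\n",
              max(x$assignment), x$Q, x$method, x$gamma))
  invisible(x)
}

#' Write a community partition as TSV
#'
#' Columns: `region_id, community, Q, method, seed`.
#'
#' @param partition a `community_partition`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  df <- data.frame(region_id = names(partition$assignment),
                   community = unname(partition$assignment),
                   Q = sprintf("%.17g", partition$Q),
                   method = partition$method,
                   seed = partition$seed,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}
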