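# Fixture builders shared across test files. Everything is generated in
# code; no binary data.

# evaluate expr under a fixed seed, restoring RNG state afterwards
with_seed_test <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

# a registry of n_regions generic regions split evenly into `blocks` area
# groups, written through the TSV loader so the reader path is exercised
mini_registry <- function(n_regions, blocks = 1L) {
  ids <- sprintf("R%02d", seq_len(n_regions))
  grp <- paste0("block", rep_len(seq_len(blocks), n_regions))
  path <- tempfile(fileext = ".tsv")
  writeLines(c("region_id\tfull_name\tarea_group\tx\ty",
               sprintf("%s\tregion %s\t%s\t%d\t%d", ids, ids, grp,
                       seq_len(n_regions), rep_len(1:5, n_regions))),
             path)
  load_region_registry(path)
}

# long-format expression rows for one group from a subjects x regions matrix
table_from_matrix <- function(m, gene = "cfos", age = "adult",
                              treatment = "saline") {
  data.frame(subject_id = rep(rownames(m), each = ncol(m)),
             age = age, treatment = treatment, gene = gene,
             region = rep(colnames(m), times = nrow(m)),
             value = as.vector(t(m)),
             stringsAsFactors = FALSE)
}

# a complete single-group table over a registry with values drawn iid
random_group_table <- function(registry, n_subjects, seed,
                               gene = "cfos", age = "adult",
                               treatment = "saline") {
  set.seed(seed)
  m <- matrix(abs(rnorm(n_subjects * nrow(registry), 100, 15)),
              nrow = n_subjects,
              dimnames = list(sprintf("s%02d", seq_len(n_subjects)),
                              registry$region_id))
  table_from_matrix(m, gene, age, treatment)
}

# symmetric signed weight matrix with ~60% density, weights in +-[0.2, 1]
random_signed_matrix <- function(n, seed, p_edge = 0.6, p_neg = 0.25) {
  set.seed(seed)
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  vals <- ifelse(runif(sum(ut)) < p_edge, runif(sum(ut), 0.2, 1), 0) *
    sample(c(-1, 1), sum(ut), replace = TRUE, prob = c(p_neg, 1 - p_neg))
  w[ut] <- vals
  w <- w + t(w)
  dimnames(w) <- list(paste0("V", seq_len(n)), paste0("V", seq_len(n)))
  w
}

# two disjoint unit-weight triangles on 6 nodes
two_triangles <- function() {
  w <- matrix(0, 6, 6)
  w[1, 2] <- w[2, 3] <- w[1, 3] <- 1
  w[4, 5] <- w[5, 6] <- w[4, 6] <- 1
  w <- w + t(w)
  dimnames(w) <- list(letters[1:6], letters[1:6])
  w
}

# wrap a plain weight matrix as a thresholded_network
as_thresholded <- function(w, alpha = 0.05, n = 7L) {
  structure(list(gene = "cfos", age = "adult", treatment = "test",
                 regions = colnames(w), w = w, alpha = alpha, n = n),
            class = "thresholded_network")
}
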