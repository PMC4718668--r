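make_net <- function(r, n, gene = "cfos", age = "adult",
                     treatment = "saline") {
  p <- cgenet::correlation_pvalue(r, n)
  diag(p) <- 1
  structure(list(gene = gene, age = age, treatment = treatment,
                 regions = colnames(r), r = r, p = p, n = n),
            class = "correlation_network")
}

sym <- function(n, fill = 0) {
  m <- matrix(fill, n, n)
  diag(m) <- 0
  dimnames(m) <- list(sprintf("R%02d", 1:n), sprintf("R%02d", 1:n))
  m
}

test_that("fisher z matches the closed form and clamps degenerate r", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3))
  rs <- c(-0.9, -0.3, 0.2, 0.7)
  expect_equal(fisher_z(-rs), -fisher_z(rs))
  expect_warning(z1 <- fisher_z(1), "clamped")
  expect_true(is.finite(z1))
  expect_error(fisher_z(1.2), "DomainError")
})

test_that("z difference scores follow the closed forms", {
  r_a <- sym(5)
  r_a["R01", "R02"] <- r_a["R02", "R01"] <- 0.9
  r_b <- sym(5)
  d <- z_difference(make_net(r_a, 7, treatment = "D2"),
                    make_net(r_b, 7))
  expect_equal(nrow(d), 10L)     # 5*4/2 unique edges
  e <- d[d$region_a == "R01" & d$region_b == "R02", ]
  # SE = sqrt(1/4 + 1/4) = 0.70711; Z = atanh(0.9)/SE ~ 2.082
  expect_equal(e$Z, atanh(0.9) / sqrt(0.5), tolerance = 1e-12)
  expect_equal(e$Z, 2.082, tolerance = 1e-3)
  expect_equal(e$p, 2 * pnorm(-abs(e$Z)))
  # identical matrices -> all Z = 0, p = 1
  d0 <- z_difference(make_net(r_a, 7), make_net(r_a, 7))
  expect_true(all(d0$Z == 0) && all(d0$p == 1))
  # unequal n enters through the SE
  d2 <- z_difference(make_net(r_a, 10, treatment = "D2"),
                     make_net(r_b, 5))
  expect_equal(d2[d2$region_a == "R01" & d2$region_b == "R02", "Z"],
               atanh(0.9) / sqrt(1 / 7 + 1 / 2))
})

test_that("group swap negates Z and preserves the significant set", {
  reg <- mini_registry(8)
  tab <- as_expression_table(rbind(
    random_group_table(reg, 7, seed = 71),
    random_group_table(reg, 7, seed = 72, treatment = "D2")), reg)
  net_a <- pearson_network(tab, "cfos", "adult", "D2", reg)
  net_b <- pearson_network(tab, "cfos", "adult", "saline", reg)
  thr_a <- threshold_network(net_a)
  thr_b <- threshold_network(net_b)
  fwd <- classify_edges(z_difference(net_a, net_b), thr_a, thr_b)
  rev <- classify_edges(z_difference(net_b, net_a), thr_b, thr_a)
  expect_equal(rev$Z, -fwd$Z)
  expect_equal(rev$p, fwd$p)
  expect_identical(rev$significant, fwd$significant)
  swap <- c(gain_positive = "loss_positive",
            loss_positive = "gain_positive",
            gain_negative = "loss_negative",
            loss_negative = "gain_negative",
            sign_reversal = "sign_reversal", none = "none")
  expect_identical(unname(swap[fwd$class]), rev$class)
})

test_that("mismatched regions and tiny groups are refused", {
  r5 <- sym(5); r4 <- sym(4)
  expect_error(z_difference(make_net(r5, 7), make_net(r4, 7)),
               "RegionMismatch")
  tiny <- structure(list(gene = "cfos", age = "adult", treatment = "D2",
                         regions = colnames(r5), r = r5,
                         p = matrix(1, 5, 5, dimnames = dimnames(r5)),
                         n = 3L),
                    class = "correlation_network")
  expect_error(z_difference(tiny, make_net(r5, 7)),
               "InsufficientSubjects")
})

test_that("BH adjustment matches the hand-executed step-up", {
  res <- fdr_adjust(c(0.01, 0.02, 0.9), q_level = 0.05)
  expect_equal(res$q_adj, c(0.03, 0.03, 0.9))
  expect_identical(res$significant, c(TRUE, TRUE, FALSE))
  # brute-force BH definition: p_(i) * m / i, then cumulative min from top
  set.seed(13)
  p <- runif(50)
  ord <- order(p)
  brute <- numeric(50)
  brute[ord] <- rev(cummin(rev(p[ord] * 50 / seq_len(50))))
  brute <- pmin(brute, 1)
  expect_equal(fdr_adjust(p)$q_adj, brute)
  expect_true(all(fdr_adjust(p)$q_adj >= p))
  expect_identical(fdr_adjust(rep(1, 10))$significant, rep(FALSE, 10))
  expect_error(fdr_adjust(numeric(0)), "EmptyInput")
})

test_that("significant edges classify by thresholded state transition", {
  r_a <- sym(6); r_b <- sym(6)
  w_a <- sym(6); w_b <- sym(6)
  put <- function(m, i, j, v) { m[i, j] <- v; m[j, i] <- v; m }
  # gain_positive: baseline null -> drug positive
  r_a <- put(r_a, 1, 2, 0.97); w_a <- put(w_a, 1, 2, 0.97)
  # loss_negative: baseline negative -> drug null
  r_b <- put(r_b, 3, 4, -0.97); w_b <- put(w_b, 3, 4, -0.97)
  # sign reversal
  r_a <- put(r_a, 5, 6, 0.97); w_a <- put(w_a, 5, 6, 0.97)
  r_b <- put(r_b, 5, 6, -0.97); w_b <- put(w_b, 5, 6, -0.97)
  net_a <- make_net(r_a, 30, treatment = "D2")
  net_b <- make_net(r_b, 30)
  dm <- classify_edges(z_difference(net_a, net_b),
                       as_thresholded(w_a), as_thresholded(w_b),
                       q_level = 0.35)
  cls <- function(i, j) {
    dm$class[dm$region_a == sprintf("R%02d", i) &
               dm$region_b == sprintf("R%02d", j)]
  }
  expect_equal(cls(1, 2), "gain_positive")
  expect_equal(cls(3, 4), "loss_negative")
  expect_equal(cls(5, 6), "sign_reversal")
  expect_true(all(dm$class[!dm$significant] == "none"))
  expect_true(all(dm$significant[dm$class != "none"]))
})

test_that("a planted gain is detected and classified at q = 0.35", {
  reg <- mini_registry(8)
  singleton_blocks <- as.list(setNames(reg$region_id, reg$region_id))
  base_spec <- covariance_spec(singleton_blocks)
  drug_spec <- covariance_spec(singleton_blocks,
                               edge_overrides = data.frame(
                                 region_a = "R01", region_b = "R02",
                                 target_r = 0.95))
  groups <- data.frame(gene = c("cfos", "cfos"), age = "adult",
                       treatment = c("saline", "D2"),
                       n_subjects = 30L, stringsAsFactors = FALSE)
  groups$spec <- list(base_spec, drug_spec)
  tab <- simulate_expression(simulation_design(groups, seed = 12L), reg)
  dm <- compare_groups(tab,
                       list(gene = "cfos", age = "adult", treatment = "D2"),
                       list(gene = "cfos", age = "adult",
                            treatment = "saline"), reg)
  hit <- dm[dm$region_a == "R01" & dm$region_b == "R02", ]
  expect_true(hit$significant)
  expect_equal(hit$class, "gain_positive")
})

test_that("detection count grows with per-group n for a fixed planted gain", {
  reg <- mini_registry(8)
  singleton_blocks <- as.list(setNames(reg$region_id, reg$region_id))
  base_spec <- covariance_spec(singleton_blocks)
  drug_spec <- covariance_spec(singleton_blocks,
                               edge_overrides = data.frame(
                                 region_a = c("R01", "R03", "R05"),
                                 region_b = c("R02", "R04", "R06"),
                                 target_r = 0.9))
  planted <- paste(c("R01", "R03", "R05"), c("R02", "R04", "R06"))
  # count recovered planted edges (true positives): total discovery counts
  # also include BH false positives whose expectation does not grow with n
  detected <- vapply(c(7L, 15L, 30L), function(n) {
    total <- 0L
    for (s in 1:4) {
      groups <- data.frame(gene = c("cfos", "cfos"), age = "adult",
                           treatment = c("saline", "D2"),
                           n_subjects = n, stringsAsFactors = FALSE)
      groups$spec <- list(base_spec, drug_spec)
      tab <- simulate_expression(simulation_design(groups,
                                                   seed = 1000L * s + n),
                                 reg)
      dm <- compare_groups(tab,
                           list(gene = "cfos", age = "adult",
                                treatment = "D2"),
                           list(gene = "cfos", age = "adult",
                                treatment = "saline"), reg)
      total <- total + sum(dm$significant[
        paste(dm$region_a, dm$region_b) %in% planted])
    }
    total
  }, 0L)
  expect_true(all(diff(detected) >= 0))
  expect_gt(detected[3], 0L)
})

test_that("planted z differences are re-estimated without bias at large n", {
  reg <- mini_registry(4)
  singleton_blocks <- as.list(setNames(reg$region_id, reg$region_id))
  base_spec <- covariance_spec(singleton_blocks)
  drug_spec <- covariance_spec(singleton_blocks,
                               edge_overrides = data.frame(
                                 region_a = "R01", region_b = "R02",
                                 target_r = 0.6))
  dz_planted <- atanh(0.6)
  errs <- vapply(1:30, function(s) {
    groups <- data.frame(gene = c("cfos", "cfos"), age = "adult",
                         treatment = c("saline", "D2"),
                         n_subjects = 1000L, stringsAsFactors = FALSE)
    groups$spec <- list(base_spec, drug_spec)
    tab <- simulate_expression(simulation_design(groups, seed = 500L + s),
                               reg)
    net_a <- pearson_network(tab, "cfos", "adult", "D2", reg)
    net_b <- pearson_network(tab, "cfos", "adult", "saline", reg)
    d <- z_difference(net_a, net_b)
    d[d$region_a == "R01" & d$region_b == "R02", "z_a"] -
      d[d$region_a == "R01" & d$region_b == "R02", "z_b"] - dz_planted
  }, 0)
  expect_lt(abs(mean(errs)), 0.02)
})

test_that("difference map TSV export carries the documented columns", {
  reg <- mini_registry(5)
  tab <- as_expression_table(rbind(
    random_group_table(reg, 7, seed = 81),
    random_group_table(reg, 7, seed = 82, treatment = "D2")), reg)
  dm <- compare_groups(tab,
                       list(gene = "cfos", age = "adult", treatment = "D2"),
                       list(gene = "cfos", age = "adult",
                            treatment = "saline"), reg)
  f <- tempfile(fileext = ".tsv")
  write_difference_map(dm, f)
  back <- utils::read.delim(f)
  expect_equal(names(back),
               c("region_a", "region_b", "r_drug", "r_base", "Z", "p",
                 "q_adj", "significant", "class", "strength_change"))
  expect_equal(nrow(back), 10L)
})
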