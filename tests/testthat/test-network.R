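tabs <- load_correlation_tables()
combined <- combine_correlation_tables(tabs)

test_that("correlation_table computes pairwise-complete Pearson cells", {
  set.seed(42)
  n <- 400
  ds <- rnorm(n)
  df <- data.frame(DS = ds, SC = ds,                      # exact duplicate
                   VM = rnorm(n), TL = rnorm(n))
  df$VM[1:5] <- NA                                        # pairwise deletion
  mt <- measure_table(df)
  ct <- correlation_table(mt)
  cell <- function(a, b) ct[(ct$measure1 == a & ct$measure2 == b) |
                            (ct$measure1 == b & ct$measure2 == a), ]
  expect_equal(cell("DS", "SC")$r, 1)
  expect_equal(cell("VM", "DS")$n, n - 5)
  indep <- cell("VM", "TL")
  expect_lt(abs(indep$r), 0.15)
  expect_warning(correlation_table(measure_table(
    data.frame(DS = c(1, 2, NA, NA), SC = c(NA, NA, 1, 2)))), "insufficient")
})

test_that("independent noise columns stay below |r| = 0.05 at n = 5000", {
  set.seed(7)
  df <- as.data.frame(matrix(rnorm(5000 * 4), ncol = 4))
  names(df) <- c("VM", "DS", "SC", "TL")
  ct <- correlation_table(measure_table(df))
  expect_true(all(abs(ct$r) < 0.05))
})

test_that("the full network reproduces the printed cross-domain edge lists", {
  full7 <- build_full_network(tabs$cross, alpha = 0.05)
  cd <- cross_domain_degree(full7)
  expect_equal(unname(cd["ASELs"]), 0)   # no links to the cognitive domain
  expect_equal(unname(cd["TMT"]), 0)     # no links to the oculomotor domain
  expect_equal(unname(cd["SC"]), 5)      # all oculomotor nodes but ASELs
  expect_equal(unname(cd["DS"]), 4)
  expect_equal(unname(cd["VM"]), 1)      # only GnGEs
  expect_equal(unname(cd["TL"]), 1)      # only ASLs
  expect_equal(unname(cd["VF"]), 3)      # ASLs, GnGLs, GnGELs (p<0.1 excluded)
  # all-ns table gives an empty edge set
  ns_tab <- tabs$cross
  ns_tab$sig_code <- "ns"
  expect_equal(nrow(build_full_network(ns_tab)$edges), 0)
})

test_that("thresholded networks follow the strict |r| > tau rule", {
  thr5 <- build_thresholded_network(tabs$cognitive, tau = 0.4)
  # brute-force count of printed cells exceeding 0.4
  expect_equal(nrow(thr5$edges), sum(abs(tabs$cognitive$r) > 0.4))
  expect_equal(nrow(thr5$edges), 11)
  expect_equal(unname(node_degree(thr5, "VF")), 5)
  expect_equal(unname(node_degree(thr5, "SC")), 5)
  # DS-TMT prints 0.39: strictly below threshold, no edge
  expect_false(any((thr5$edges$from == "DS" & thr5$edges$to == "TMT") |
                   (thr5$edges$from == "TMT" & thr5$edges$to == "DS")))
  thr6 <- build_thresholded_network(tabs$oculomotor, tau = 0.4)
  deg6 <- node_degree(thr6)
  expect_equal(unname(deg6["ASLs"]), unname(deg6["GnGLs"]))
  expect_equal(unname(deg6["ASLs"]), unname(deg6["ASEs"]))
  # all-zero table gives no edges
  zero <- tabs$cognitive; zero$r <- 0; zero$sig_code <- "ns"
  expect_equal(nrow(build_thresholded_network(zero)$edges), 0)
})

test_that("combined thresholded network has the published cross-domain shape", {
  thr <- build_thresholded_network(combined, tau = 0.4)
  dom <- setNames(thr$nodes$domain, thr$nodes$name)
  cross <- thr$edges[dom[thr$edges$from] != dom[thr$edges$to], ]
  expect_equal(nrow(cross), 3)
  cd <- cross_domain_degree(thr)
  expect_equal(unname(cd[c("ASLs", "GnGLs", "ASEs")]), c(1, 1, 1))
  expect_equal(unname(node_degree(thr, "ASELs")), 0)   # isolated
  expect_equal(central_nodes(thr), "SC")
  expect_setequal(central_nodes(build_thresholded_network(tabs$cognitive)),
                  c("VF", "SC"))
})

test_that("edge sign structure: within-domain positive, cross-domain negative", {
  thr <- build_thresholded_network(combined, tau = 0.4)
  full <- build_full_network(combined, alpha = 0.05)
  for (net in list(thr, full)) {
    dom <- setNames(net$nodes$domain, net$nodes$name)
    within <- dom[net$edges$from] == dom[net$edges$to]
    expect_true(all(net$edges$sign[within] > 0))
    expect_true(all(net$edges$sign[!within] < 0))
  }
})

test_that("every thresholded fixture edge is also a full-network edge", {
  thr <- build_thresholded_network(combined, tau = 0.4)
  full <- build_full_network(combined, alpha = 0.05)
  key <- function(net) paste(pmin(net$edges$from, net$edges$to),
                             pmax(net$edges$from, net$edges$to))
  expect_true(all(key(thr) %in% key(full)))
})

test_that("edge counts are monotone in tau and alpha", {
  taus <- c(0, 0.2, 0.4, 0.6, 0.8)
  n_thr <- vapply(taus, function(tau)
    nrow(build_thresholded_network(combined, tau)$edges), numeric(1))
  expect_true(all(diff(n_thr) <= 0))
  alphas <- c(0.001, 0.01, 0.05, 0.1)
  n_full <- vapply(alphas, function(a)
    nrow(build_full_network(combined, a)$edges), numeric(1))
  expect_true(all(diff(n_full) >= 0))
})

test_that("degree queries validate nodes and handle empty networks", {
  thr <- build_thresholded_network(combined, tau = 0.4)
  expect_error(node_degree(thr, "XX"), "unknown node")
  expect_error(cross_domain_degree(thr, "XX"), "unknown node")
  empty <- build_thresholded_network(combined, tau = 1)
  expect_true(all(node_degree(empty) == 0))
  expect_error(central_nodes(empty), "no edges")
  # single-edge network returns both endpoints as central
  one <- build_thresholded_network(combined, tau = 0.70)
  expect_equal(nrow(one$edges), 1)
  expect_setequal(central_nodes(one), c(one$edges$from, one$edges$to))
})

test_that("networks round-trip through GraphML and edge-list files", {
  thr <- build_thresholded_network(combined, tau = 0.4)
  for (fmt in c("graphml", "edgelist")) {
    f <- tempfile()
    export_network(thr, f, fmt)
    back <- import_network(f, fmt)
    expect_setequal(back$nodes$name, thr$nodes$name)
    expect_equal(back$nodes$domain[order(back$nodes$name)],
                 thr$nodes$domain[order(thr$nodes$name)])
    key <- function(net) paste(pmin(net$edges$from, net$edges$to),
                               pmax(net$edges$from, net$edges$to))
    expect_setequal(key(back), key(thr))
    expect_equal(sort(back$edges$weight), sort(thr$edges$weight))
    expect_equal(back$mode, thr$mode)
    expect_equal(back$param, thr$param)
  }
  # an empty network still writes all 12 nodes
  empty <- build_thresholded_network(combined, tau = 1)
  f <- tempfile()
  export_network(empty, f, "graphml")
  back <- import_network(f, "graphml")
  expect_equal(nrow(back$nodes), 12)
  expect_equal(nrow(back$edges), 0)
  expect_error(export_network(thr, tempfile(), "bogus"), "arg")
})

test_that("a simulated cohort recovers the fixture correlations at n = 5000", {
  cfg <- simulation_config(n_patients = 5000, n_controls = 2, seed = 99)
  coh <- simulate_cohort(cfg, "measures")
  pat <- coh[coh$group == "patient", measure_info()$measure]
  ct <- correlation_table(measure_table(pat))
  target <- target_correlation_matrix()
  err <- abs(ct$r - target[cbind(ct$measure1, ct$measure2)])
  expect_lt(max(err), 0.05)
})
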