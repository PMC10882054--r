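# Synapse-table filtering: cleft cutoff, redundancy removal (with brute-force
# oracle), aggregation, partner threshold, matrix modes, presence cut, and
# the end-to-end bookkeeping identities on synthetic data.

test_that("cleft-score filter keeps the >= 50 boundary inclusive", {
  tab <- make_synapses(c("a", "a", "a"), "t", 1:3 * 1000, 0, 0,
                       c(49.9, 50, 80))
  out <- filter_cleft_score(tab, 50)
  expect_equal(out$cleft_score, c(50, 80))
  expect_equal(nrow(filter_cleft_score(tab, 0)), 3)
  expect_equal(nrow(filter_cleft_score(tab, 100)), 0)
})

test_that("deduplication keeps the higher-score detection of a close pair", {
  tab <- make_synapses(c("a", "a"), "t", c(0, 30), c(0, 40), 0, c(90, 60))
  out <- deduplicate_synapses(tab, 100)  # 50 nm apart
  expect_equal(nrow(out), 1)
  expect_equal(out$cleft_score, 90)
  # exactly 100 nm apart: both retained ("less than 100 nm" rule)
  tab2 <- make_synapses(c("a", "a"), "t", c(0, 100), 0, 0, c(90, 60))
  expect_equal(nrow(deduplicate_synapses(tab2, 100)), 2)
  # different connections are never deduplicated against each other
  tab3 <- make_synapses(c("a", "b"), "t", c(0, 10), 0, 0, c(90, 60))
  expect_equal(nrow(deduplicate_synapses(tab3, 100)), 2)
  expect_error(deduplicate_synapses(tab, -5), "non-negative")
})

test_that("deduplication matches the exhaustive greedy oracle and is idempotent", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    tab <- make_synapses(
      pre = sample(c("p1", "p2"), n, replace = TRUE),
      post = sample(c("t1", "t2"), n, replace = TRUE),
      x = runif(n, 0, 400), y = runif(n, 0, 400), z = runif(n, 0, 400),
      score = round(runif(n, 50, 150), 1))
    got <- deduplicate_synapses(tab, 100)
    want <- oracle_dedup(tab, 100)
    rownames(want) <- NULL
    expect_identical(got, want)
    expect_identical(deduplicate_synapses(got, 100), got)
  }
})

test_that("aggregation counts cells and types with UNKNOWN fallback", {
  tab <- make_synapses(
    pre = c(rep("dm12_a", 4), rep("dm12_b", 6), rep("mystery", 2)),
    post = "t1", x = seq(0, 11000, by = 1000), y = 0, z = 0, score = 100)
  ann <- data.frame(segment_id = c("dm12_a", "dm12_b"),
                    type_label = "Dm12", hemisphere = "right")
  cnt <- aggregate_counts(tab, ann)
  mat <- build_connectivity_matrix(apply_partner_threshold(cnt, 1))
  expect_equal(unname(unclass(mat)["t1", "Dm12"]), 10)
  expect_equal(unname(attr(mat, "multiplicity")["t1", "Dm12"]), 2)
  expect_equal(unname(attr(mat, "unknown")["t1"]), 2)  # never dropped
  expect_error(aggregate_counts(tab, rbind(ann, ann)), "one row per segment")
})

test_that("partner threshold zeroes sub-threshold cells only", {
  tab <- make_synapses(
    pre = c(rep("a", 2), rep("b", 3), rep("c", 5)),
    post = "t1", x = seq(0, 9000, by = 1000), y = 0, z = 0, score = 100)
  ann <- data.frame(segment_id = c("a", "b", "c"),
                    type_label = c("A", "B", "C"), hemisphere = "right")
  cnt <- aggregate_counts(tab, ann)
  thr <- apply_partner_threshold(cnt, 3)
  expect_equal(thr$cells$n_synapses[order(thr$cells$pre_segment_id)],
               c(0L, 3L, 5L))
  # min 1 is the identity on positive counts; idempotence
  expect_equal(apply_partner_threshold(cnt, 1)$cells$n_synapses,
               cnt$cells$n_synapses)
  expect_equal(apply_partner_threshold(thr, 3)$cells, thr$cells)
  expect_error(apply_partner_threshold(cnt, 0), ">= 1")
  # all below threshold: zero matrix
  zero <- build_connectivity_matrix(apply_partner_threshold(cnt, 10))
  expect_true(all(unclass(zero) == 0))
})

test_that("matrix modes: relative rows divide by the full row total", {
  tab <- make_synapses(
    pre = c(rep("l3", 25), rep("mi4", 13), rep("ct1", 15)),
    post = "t1", x = seq_len(53) * 500, y = 0, z = 0, score = 100)
  ann <- data.frame(segment_id = c("l3", "mi4", "ct1"),
                    type_label = c("L3", "Mi4", "CT1"),
                    hemisphere = "right")
  cnt <- apply_partner_threshold(aggregate_counts(tab, ann), 3)
  rel <- build_connectivity_matrix(cnt, "relative")
  expect_equal(unname(unclass(rel)["t1", c("L3", "Mi4", "CT1")]),
               c(25, 13, 15) / 53, tolerance = 1e-12)
  expect_equal(sum(unclass(rel)), 1)  # no UNKNOWN -> rows sum to 1
  bin <- build_connectivity_matrix(cnt, "binary")
  expect_true(all(unclass(bin) %in% c(0, 1)))
  # zero-total row warns and stays zero
  cnt0 <- aggregate_counts(tab, ann, targets = c("t1", "ghost"))
  expect_warning(rel0 <- build_connectivity_matrix(
    apply_partner_threshold(cnt0, 3), "relative"), "zero total")
  expect_true(all(unclass(rel0)["ghost", ] == 0))
})

test_that("presence filter drops types below the cut, keeping the boundary", {
  m <- matrix(0, 100, 3, dimnames = list(sprintf("t%03d", 1:100),
                                         c("rare", "boundary", "common")))
  m[1:4, "rare"] <- 5       # 4% < 5%: dropped
  m[1:5, "boundary"] <- 5   # exactly 5%: kept (>= rule)
  m[1:60, "common"] <- 5
  cm <- structure(m, class = c("connectivity_matrix", "matrix", "array"),
                  mode_flag = "absolute",
                  unknown = setNames(numeric(100), rownames(m)),
                  dropped = setNames(numeric(100), rownames(m)),
                  row_total = rowSums(m), hemisphere = NULL,
                  multiplicity = (m > 0) + 0)
  out <- filter_by_presence(cm, 0.05)
  expect_equal(colnames(out), c("boundary", "common"))
  expect_equal(colnames(filter_by_presence(cm, 0)), colnames(m))
})

test_that("synthetic connectome bookkeeping is exact end to end", {
  cfg <- connectome_config(n_columns_per_hemisphere = c(25, 20), seed = 17)
  sim <- simulate_connectome(cfg)
  targets <- sim$truth$columns$target_cell_id
  tab <- deduplicate_synapses(filter_cleft_score(sim$synapses, 50), 100)
  # dedup removes exactly the injected duplicates (cleft filter removed decoys)
  expect_equal(nrow(tab), sum(sim$truth$planted_synapses))
  cnt <- apply_partner_threshold(aggregate_counts(tab, sim$annotations,
                                                  targets = targets), 3)
  mat <- build_connectivity_matrix(cnt, "absolute")
  # post-filter matrix equals the planted ground truth exactly
  common <- intersect(colnames(mat), colnames(sim$truth$planted_counts))
  expect_true(all(unclass(mat)[, common] ==
                    sim$truth$planted_counts[targets, common]))
  extra <- setdiff(colnames(sim$truth$planted_counts), colnames(mat))
  expect_true(all(sim$truth$planted_counts[, extra] == 0))
  # conservation: matrix + UNKNOWN + sub-threshold = post-dedup totals
  post_dedup <- table(factor(tab$post_cell_id, levels = targets))
  expect_equal(as.numeric(rowSums(unclass(mat)) + attr(mat, "unknown") +
                            attr(mat, "dropped")),
               as.numeric(post_dedup))
  expect_equal(as.numeric(attr(mat, "unknown")),
               as.numeric(sim$truth$unknown_synapses[targets]))
  expect_equal(as.numeric(attr(mat, "dropped")),
               as.numeric(sim$truth$subthreshold_synapses[targets]))
})

test_that("with everything annotated, all synapses map to named types", {
  cfg <- connectome_config(n_columns_per_hemisphere = c(10, 8), seed = 23,
                           unknown_rate = 0, subthreshold_rate = 0)
  sim <- simulate_connectome(cfg)
  tab <- deduplicate_synapses(filter_cleft_score(sim$synapses), 100)
  cnt <- apply_partner_threshold(
    aggregate_counts(tab, sim$annotations,
                     targets = sim$truth$columns$target_cell_id), 3)
  mat <- build_connectivity_matrix(cnt)
  expect_equal(sum(unclass(mat)), nrow(tab))  # 100% assigned
  expect_true(all(attr(mat, "unknown") == 0))
})
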