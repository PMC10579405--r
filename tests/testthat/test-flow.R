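test_that("normalisation standardises channels and preserves within-channel order", {
  ev <- pure_events("BT_live", n = 500)
  norm <- normalize_events(ev, flow_channels)
  for (ch in flow_channels) {
    expect_lt(abs(mean(norm[[ch]])), 1e-9)
    expect_lt(abs(stats::var(norm[[ch]]) - 1), 1e-9)
    expect_identical(order(norm[[ch]]), order(ev[[ch]]))
  }
  ## pointwise transform: ties stay tied
  tied <- data.frame(FSC = c(100, 100, 200), SSC = c(1, 2, 3),
                     FL_SG = c(5, 6, 7), FL_PI = c(1, 4, 9))
  tn <- normalize_events(tied, flow_channels)
  expect_equal(tn$FSC[1], tn$FSC[2])
})

test_that("normalisation reduces lognormal skewness and drops flat channels", {
  skewness <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3
  ev <- pure_events("inviable", n = 2000, seed = 5)
  raw_skew <- skewness(ev$FSC)
  norm <- normalize_events(ev, flow_channels)
  expect_lt(abs(skewness(norm$FSC)), abs(raw_skew))
  flat <- data.frame(FSC = rep(7, 50), SSC = rexp(50) + 1,
                     FL_SG = rexp(50) + 1, FL_PI = rexp(50) + 1)
  expect_warning(nf <- normalize_events(flat, flow_channels), "zero-variance")
  expect_false("FSC" %in% attr(nf, "channels"))
})

test_that("embedding is 3-D, seed-reproducible and separates distant clusters", {
  ev <- generate_flow_events(population_spec(
    fractions = c(BT_live = 0.5, RI_live = 0.5, inviable = 0, debris = 0,
                  blank = 0),
    total_events = 1200, separation_sd = 6, seed = 3))
  norm <- normalize_events(ev, flow_channels)
  X <- as.matrix(norm[attr(norm, "channels")])
  emb1 <- embed_events(X, seed = 11)
  expect_identical(dim(emb1), c(1200L, 3L))
  emb2 <- embed_events(X, seed = 11)
  expect_identical(emb1, emb2)  # bit-identical at fixed seed
  lab <- as.integer(factor(ev$truth_label))
  sil <- cluster::silhouette(lab, dist(emb1))
  expect_gt(mean(sil[, 3]), 0.5)
  ## tiny input: neighbour count is reduced with a warning
  expect_warning(embed_events(X[1:20, ], seed = 1), "n_neighbors")
})

test_that("blank-overlap flags follow the generator truth", {
  blank_only <- c(BT_live = 0, RI_live = 0, inviable = 0, debris = 0,
                  blank = 1)
  ## no blanks: nothing flagged
  s <- pure_events("BT_live", n = 300)
  norm <- normalize_events(s, flow_channels)
  emb <- embed_events(as.matrix(norm[attr(norm, "channels")]), seed = 2)
  expect_identical(remove_blank_overlap(emb, emb[0, , drop = FALSE]),
                   rep(FALSE, 300))
  ## sample drawn from the blank distribution: nearly all flagged
  sb <- generate_flow_events(population_spec(fractions = blank_only,
                                             total_events = 1000, seed = 6))
  bb <- generate_flow_events(population_spec(fractions = blank_only,
                                             total_events = 1000, seed = 7))
  pool <- normalize_events(rbind(sb[flow_channels], bb[flow_channels]))
  emb <- embed_events(as.matrix(pool[attr(pool, "channels")]), seed = 8)
  flagged <- remove_blank_overlap(emb[1:1000, ], emb[1001:2000, ])
  expect_gte(mean(flagged), 0.95)
  ## planted blank-like events among distant cell clusters
  mix <- generate_flow_events(population_spec(
    fractions = c(BT_live = 0.45, RI_live = 0.45, inviable = 0, debris = 0,
                  blank = 0.10),
    total_events = 2000, separation_sd = 6, seed = 9))
  bl <- generate_flow_events(population_spec(fractions = blank_only,
                                             total_events = 1000, seed = 10))
  pool <- normalize_events(rbind(mix[flow_channels], bl[flow_channels]))
  emb <- embed_events(as.matrix(pool[attr(pool, "channels")]), seed = 12)
  fl <- remove_blank_overlap(emb[1:2000, ], emb[2001:3000, ])
  planted <- mix$truth_label == "blank"
  expect_gte(mean(fl[planted]), 0.90)
  expect_lte(mean(fl[!planted]), 0.05)
})

test_that("gating recovers the generator categories at 6-SD separation", {
  ev <- generate_flow_events(population_spec(total_events = 3000,
                                             separation_sd = 6, seed = 42))
  blanks <- generate_flow_events(population_spec(
    fractions = c(BT_live = 0, RI_live = 0, inviable = 0, debris = 0.04,
                  blank = 0.96),
    total_events = 700, seed = 43))
  g <- gate_categories(ev, blanks, seed = 7)
  ## partition: every event in exactly one category
  expect_identical(sum(table(g$events$category)), nrow(ev))
  truth <- c(BT_live = "live", RI_live = "live", inviable = "inviable",
             debris = "debris", blank = "blank")[ev$truth_label]
  expect_gte(mean(truth == as.character(g$events$category)), 0.99)
  ## rule precedence: PI-positive events are inviable regardless of SG
  called <- g$events$category
  pi_pos <- normalize_events(rbind(ev[flow_channels],
                                   blanks[flow_channels]))$FL_PI[
    seq_len(nrow(ev))] > g$pi_threshold
  expect_true(all(called[pi_pos & called != "blank"] == "inviable"))
  expect_error(gate_categories(ev["FSC"], blanks), "FL_SG")
})

test_that("species assignment meets the separation-accuracy contract", {
  run_at <- function(sep) {
    bt_ref <- pure_events("BT_live", n = 2500, separation_sd = sep, seed = 1)
    ri_ref <- pure_events("RI_live", n = 2500, separation_sd = sep, seed = 2)
    co <- generate_flow_events(population_spec(
      fractions = c(BT_live = 0.5, RI_live = 0.5, inviable = 0, debris = 0,
                    blank = 0),
      total_events = 2000, separation_sd = sep, seed = 3))
    cl <- classify_species(co, list(BT = bt_ref, RI = ri_ref),
                           n_training = 2500, seed = 11)
    truth <- ifelse(co$truth_label == "BT_live", "BT", "RI")
    c(bt = mean(cl$species[truth == "BT"] == "BT"),
      ri = mean(cl$species[truth == "RI"] == "RI"))
  }
  acc <- vapply(c(2, 4, 6), run_at, numeric(2))
  ## >= 95% per species at 4-SD separation
  expect_gte(min(acc[, 2]), 0.95)
  ## overall accuracy monotone non-decreasing in separation
  overall <- colMeans(acc)
  expect_true(all(diff(overall) >= -0.005))
})

test_that("degenerate species-assignment inputs behave per contract", {
  bt_ref <- pure_events("BT_live", n = 800, seed = 21)
  ri_ref <- pure_events("RI_live", n = 800, seed = 22)
  ## co-culture drawn purely from the BT reference distribution
  co <- pure_events("BT_live", n = 400, seed = 23)
  cl <- classify_species(co, list(BT = bt_ref, RI = ri_ref),
                         n_training = 800, seed = 5)
  expect_gte(mean(cl$species == "BT"), 0.99)
  expect_true(all(cl$margin >= 0.5 & cl$margin <= 1))
  ## empty co-culture event set
  cl0 <- classify_species(co[0, ], list(BT = bt_ref, RI = ri_ref),
                          n_training = 800, seed = 5)
  expect_identical(nrow(cl0), 0L)
  ## missing reference species
  expect_error(classify_species(co, list(BT = bt_ref)), "both")
})

test_that("population counting applies the acquisition arithmetic exactly", {
  tab <- data.frame(category = rep(c("live", "debris"), c(50000, 100)))
  out <- count_populations(tab, dilution = 200, acquisition_volume_ul = 10)
  expect_equal(out$density_cells_per_ul[out$population == "live"], 1.0e6)
  expect_equal(count_populations(data.frame(category = rep("live", 123)),
                                 10, 10)$density_cells_per_ul, 123)
  ## zero live events and dilution equivariance
  none <- data.frame(category = character(0))
  expect_identical(nrow(count_populations(none, 10, 10)), 0L)
  d1 <- count_populations(tab, 10, 10)$density_cells_per_ul
  d2 <- count_populations(tab, 20, 10)$density_cells_per_ul
  expect_equal(d2, 2 * d1)
  expect_error(count_populations(tab, 0, 10), "dilution")
  expect_error(count_populations(tab, 10, 0), "volume")
})
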