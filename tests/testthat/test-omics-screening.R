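toy_stats <- function() {
  data.frame(feature = c("g1", "g2", "g3", "g4"),
             log2fc = c(2, -1, 0.5, 3),
             adj_p = c(0.01, 0.04, 0.001, 0.2))
}

test_that("DEG screening applies printed boundary semantics", {
  expect_equal(screen_degs(toy_stats()), list(up = "g1", down = "g2"))
  expect_equal(screen_degs(toy_stats()[0, ]), list(up = character(0),
                                                   down = character(0)))
  # |log2FC| >= 1 inclusive; adj_p < 0.05 strict
  edge <- data.frame(feature = c("a", "b", "c", "d"),
                     log2fc = c(1, -1, 1, 2),
                     adj_p = c(0.049, 0.049, 0.05, 0.05))
  s <- screen_degs(edge)
  expect_equal(s$up, "a")
  expect_equal(s$down, "b")
  # kind guard and malformed rows
  expect_error(screen_degs(cbind(toy_stats(), kind = "metabolite")),
               "gene rows only")
  bad <- toy_stats(); bad$adj_p[2] <- 1.5
  expect_error(screen_degs(bad), "g2")
})

test_that("DAM screening adds the inclusive VIP conjunct", {
  d <- data.frame(feature = c("m1", "m2", "m3"),
                  log2fc = c(5, -1, 2),
                  adj_p = c(0.001, 0.049, 0.01),
                  vip = c(0.99, 1, 0))
  s <- screen_dams(d)
  expect_equal(s$up, character(0)) # m1 excluded: VIP just below 1
  expect_equal(s$down, "m2")       # inclusive at all three boundaries
  d$vip <- 0
  expect_equal(screen_dams(d), list(up = character(0), down = character(0)))
  expect_error(screen_dams(d[, -4]), "vip")
})

test_that("screening is threshold-monotone and up/down disjoint", {
  sim <- simulate_feature_stats(sim_config(n_genes = 300, seed = 11), "G1")
  genes <- sim$stats[sim$stats$kind == "gene", ]
  base <- screen_degs(genes)
  expect_length(intersect(base$up, base$down), 0)
  for (fc in c(1.5, 2, 3)) {
    tight <- screen_degs(genes, fc_min = fc)
    expect_true(all(tight$up %in% base$up))
    expect_true(all(tight$down %in% base$down))
  }
  for (p in c(0.01, 0.005)) {
    tight <- screen_degs(genes, p_max = p)
    expect_true(all(c(tight$up, tight$down) %in% c(base$up, base$down)))
  }
  mets <- sim$stats[sim$stats$kind == "metabolite", ]
  basem <- screen_dams(mets)
  for (v in c(1.5, 2)) {
    tight <- screen_dams(mets, vip_min = v)
    expect_true(all(c(tight$up, tight$down) %in% c(basem$up, basem$down)))
  }
})

test_that("multiway overlap counts exclusive regions exactly", {
  sets <- list(A = c(1, 2, 3), B = c(2, 3), C = c(3, 4), D = 3)
  ov <- multiway_overlap(sets)
  expect_equal(nrow(ov), 2^4 - 1)
  expect_equal(ov$count[ov$region == "A&B&C&D"], 1L) # element 3
  expect_equal(ov$count[ov$region == "A"], 1L)       # element 1
  expect_equal(ov$count[ov$region == "C"], 1L)       # element 4
  expect_equal(ov$count[ov$region == "A&B"], 1L)     # element 2
  expect_equal(sum(ov$count), length(unique(unlist(sets))))
  # identical sets: everything in the common region
  same <- multiway_overlap(list(W = 1:5, X = 1:5, Y = 1:5, Z = 1:5))
  expect_equal(same$count[same$region == "W&X&Y&Z"], 5L)
  expect_equal(sum(same$count), 5L)
  # pairwise disjoint: empty common region
  dis <- multiway_overlap(list(A = 1:2, B = 3:4, C = 5:6, D = 7:8))
  expect_equal(dis$count[dis$region == "A&B&C&D"], 0L)
  expect_equal(sum(dis$count), 8L)
  expect_error(multiway_overlap(list(A = 1)), ">= 2 sets")
})

test_that("hypergeometric enrichment matches the closed-form example", {
  bg <- paste0("f", 1:10)
  res <- hypergeometric_enrichment(bg[1:4], list(S = bg[1:5]), background = bg)
  expect_equal(res$overlap, 4)
  expect_equal(res$p, 5 / 210, tolerance = 1e-12)
  # annotation set == background -> p = 1 for any selection
  res2 <- hypergeometric_enrichment(bg[c(2, 7)], list(All = bg),
                                    background = bg)
  expect_equal(res2$p, 1)
  # zero overlap -> p = 1
  res3 <- hypergeometric_enrichment(bg[1:2], list(S = bg[5:7]),
                                    background = bg)
  expect_equal(res3$overlap, 0)
  expect_equal(res3$p, 1)
  expect_error(hypergeometric_enrichment(c("zz"), list(S = bg[1:3]),
                                         background = bg), "outside background")
})

test_that("BH adjustment matches the hand-computed step-up examples", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.05)), c(0.01, 0.05))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # order-preserving and never below raw p
  withr::with_seed(5, {
    p <- runif(100)
    a <- bh_adjust(p)
    expect_true(all(a >= p - 1e-15))
    expect_true(all(a <= 1))
    o <- order(p)
    expect_true(all(diff(a[o]) >= -1e-15))
  })
})

test_that("synthetic feature stats drive screening recall as planted", {
  # de_fraction extremes
  none <- simulate_feature_stats(sim_config(n_genes = 100, de_fraction = 0,
                                            seed = 2), "G")
  s <- screen_degs(none$stats[none$stats$kind == "gene", ])
  expect_length(c(s$up, s$down), 0)
  all_de <- simulate_feature_stats(sim_config(n_genes = 100, de_fraction = 1,
                                              effect_log2fc = 5, seed = 2), "G")
  s2 <- screen_degs(all_de$stats[all_de$stats$kind == "gene", ])
  expect_setequal(c(s2$up, s2$down), all_de$stats$feature[all_de$stats$kind == "gene"])

  # recall >= 0.95 at the planted design point
  sim <- simulate_feature_stats(sim_config(n_genes = 1000, de_fraction = 0.1,
                                           seed = 7), "G1")
  genes <- sim$stats[sim$stats$kind == "gene", ]
  hits <- unlist(screen_degs(genes))
  truth <- grep("^gene", sim$truth$true_de_features$G1, value = TRUE)
  recall <- length(intersect(hits, truth)) / length(truth)
  expect_gte(recall, 0.95)
  # false positives among planted nulls controlled at p_max
  nulls <- setdiff(genes$feature, truth)
  fpr <- length(intersect(hits, nulls)) / length(nulls)
  expect_lte(fpr, 0.05)
})

test_that("screening recall is monotone in the planted effect size", {
  recalls <- vapply(c(1, 2, 4), function(fc) {
    sim <- simulate_feature_stats(sim_config(n_genes = 500, de_fraction = 0.2,
                                             effect_log2fc = fc, seed = 9), "G")
    genes <- sim$stats[sim$stats$kind == "gene", ]
    hits <- unlist(screen_degs(genes))
    truth <- grep("^gene", sim$truth$true_de_features$G, value = TRUE)
    length(intersect(hits, truth)) / length(truth)
  }, numeric(1))
  expect_true(all(diff(recalls) >= 0))
})
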