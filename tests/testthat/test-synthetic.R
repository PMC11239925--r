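# Generators: reproducibility, planted-truth bookkeeping, parameter recovery.

test_that("generators are bit-reproducible under a fixed seed", {
  m <- matrix(runif(32 * 32) < 0.3, 32, 32)
  expect_identical(gen_spot_field(100, m, 0.5, 0.5, seed = 7),
                   gen_spot_field(100, m, 0.5, 0.5, seed = 7))
  expect_identical(
    gen_dual_spot_fields(50, 40, 0.5, 0.3, seed = 7),
    gen_dual_spot_fields(50, 40, 0.5, 0.3, seed = 7))
  expect_identical(
    gen_release_traces(5, duration_s = 30, spont_rate = 0.1, seed = 7),
    gen_release_traces(5, duration_s = 30, spont_rate = 0.1, seed = 7))
  expect_identical(gen_spike_trains(4, 60, "independent_poisson", 2, seed = 7),
                   gen_spike_trains(4, 60, "independent_poisson", 2, seed = 7))
  des <- data.frame(genotype = "WT", condition = rep(c("control", "mir7_oex"), 3),
                    batch = 1, animal = 1:6)
  expect_identical(gen_expression_counts(50, des, seed = 7),
                   gen_expression_counts(50, des, seed = 7))
})

test_that("spot fields respect the planted colocalized fraction and mask geometry", {
  m <- matrix(FALSE, 40, 40); m[5:30, 8:25] <- TRUE
  # coloc_fraction = 1, no jitter: every spot sits on a true-mask pixel center
  tr <- gen_spot_field(300, m, coloc_fraction = 1, jitter_sd = 0, seed = 1)
  on_mask <- m[cbind(round(tr$spots$y) + 1, round(tr$spots$x) + 1)]
  expect_true(all(on_mask))
  expect_true(all(tr$is_coloc))
  expect_true(all(tr$spots$compartment %in% c("soma", "neurite")))
  # coloc_fraction = 0 over a 25%-coverage mask: on-mask fraction matches area
  m25 <- matrix(FALSE, 64, 64); m25[sample.int(64 * 64, 1024)] <- TRUE
  tr0 <- gen_spot_field(10000, m25, coloc_fraction = 0, jitter_sd = 0, seed = 2)
  frac <- mean(m25[cbind(round(tr0$spots$y) + 1, round(tr0$spots$x) + 1)])
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_lt(abs(frac - 0.25), 3 * se)
  expect_error(gen_spot_field(10, matrix(FALSE, 4, 4), 0.5, 0, seed = 1),
               "degenerate structure")
  expect_error(gen_spot_field(0, m, 0.5, 0, seed = 1))
})

test_that("dual spot fields plant exact pairings and reject infeasible ones", {
  du <- gen_dual_spot_fields(60, 40, coloc_fraction = 1, jitter_sd = 0, seed = 3)
  p <- mutual_nearest_neighbors(du$a, du$b)
  expect_equal(nrow(p), 40)
  expect_equal(max(p$distance), 0)
  du1 <- gen_dual_spot_fields(30, 1, coloc_fraction = 1, jitter_sd = 0, seed = 4)
  d <- sqrt((du1$a$x - du1$b$x)^2 + (du1$a$y - du1$b$y)^2)
  expect_equal(min(d), 0)
  expect_error(gen_dual_spot_fields(5, 40, coloc_fraction = 0.5, 0, seed = 1),
               "infeasible")
})

test_that("release traces carry the stated ground-truth events", {
  stim <- seq(2, 40, by = 2)          # 20 stimuli at 0.5 Hz
  tt <- gen_release_traces(10, duration_s = 60, evoked_p = 1,
                           stim_times = stim, seed = 5)
  expect_equal(unname(table(tt$events$synapse_id)), rep(20L, 10),
               ignore_attr = TRUE)
  expect_true(all(tt$events$frame == rep(tt$stim_frames + 1L, 10)))
  quiet <- gen_release_traces(5, duration_s = 60, spont_rate = 0,
                              evoked_p = 0, stim_times = stim, seed = 6)
  expect_equal(nrow(quiet$events), 0)
  # Poisson mean of spontaneous events: 0.05 Hz * 300 s = 15 per synapse
  sp <- gen_release_traces(400, duration_s = 300, spont_rate = 0.05, seed = 7)
  counts <- tabulate(sp$events$synapse_id, 400)
  expect_lt(abs(mean(counts) - 15), 3 * sqrt(15 / 400))
  expect_error(gen_release_traces(2, duration_s = 10, stim_times = c(5, 20),
                                  seed = 1),
               "duration too short")
})

test_that("spike-train generator modes and planted bursts behave as specified", {
  id <- gen_spike_trains(6, 120, "identical", rate = 1, seed = 8)
  tl <- split(id$trains$time_s, id$trains$electrode_id)
  for (e in 2:6) expect_identical(tl[[1]], tl[[e]])
  ip <- gen_spike_trains(20, 600, "independent_poisson", rate = 1, seed = 9)
  counts <- table(ip$trains$electrode_id)
  expect_lt(abs(mean(counts) - 600), 3 * sqrt(600 / 20))
  bu <- gen_spike_trains(2, 60, "independent_poisson", rate = 0,
                         burst_spec = list(2, 0.01, 6), seed = 10)
  tb <- bu$true_bursts[bu$true_bursts$electrode_id == 1, ]
  expect_equal(nrow(tb), 2)
  expect_equal(tb$end_s - tb$start_s, rep(0.05, 2))   # (6 - 1) * 0.01 s
  expect_error(gen_spike_trains(2, 1, "independent_poisson", 0,
                                burst_spec = list(10, 0.05, 10), seed = 1),
               "overflow")
  expect_true(!is.unsorted(bu$trains$time_s[bu$trains$electrode_id == 1]))
})

test_that("expression counts recover the planted fold change and batch truth", {
  des <- data.frame(genotype = rep("WT", 12),
                    condition = rep(c("control", "mir7_oex"), each = 6),
                    batch = rep(1:2, 6), animal = 1:12)
  tg <- sprintf("gene%04d", 1:100)
  # planted_log2fc = 0: target and non-target true means identical per sample
  t0 <- gen_expression_counts(300, des, tg, planted_log2fc = 0, seed = 11)
  expect_equal(t0$true_means[1, ], t0$true_means[200, ] *
                 t0$true_means[1, 1] / t0$true_means[200, 1])
  # planted -0.5 recovered from empirical log2FC of target genes
  tr <- gen_expression_counts(2000, des, tg, planted_log2fc = -0.5,
                              dispersion = 0.02, seed = 12)
  lfc <- log2_fold_change(tr$counts, which(des$condition == "mir7_oex"),
                          which(des$condition == "control"))
  mt <- mean(lfc[tg]); se <- sd(lfc[tg]) / sqrt(length(tg))
  expect_lt(abs(mt - (-0.5)), 3 * se)
  expect_lt(abs(mean(lfc[-(1:100)])), 3 * sd(lfc[-(1:100)]) / sqrt(1900))
  expect_error(gen_expression_counts(10, des, dispersion = 0, seed = 1))
  expect_true(all(tr$counts >= 0 & tr$counts == round(tr$counts)))
})

test_that("regulatory expression is the stated linear propagation", {
  net <- plant_two_tier_network(n_phenotype = 6, n_intermediate = 6,
                                n_targets = 20, seed = 13)
  rx <- gen_regulatory_expression(net, 15, n_decoy_genes = 5, noise_sd = 0,
                                  seed = 14)
  e <- net$edges
  for (g in c("reg01", "pheno03")) {
    pe <- e[e$to == g, ]
    expect_equal(rx$counts[g, ],
                 colSums(rx$counts[pe$from, , drop = FALSE] * pe$weight))
  }
  # single parent with weight 1: child equals parent exactly
  nodes <- data.frame(gene = c("t1", "r1", "p1"),
                      role = c("mir7_target", "intermediate", "phenotype"))
  edges <- data.frame(from = c("t1", "r1"), to = c("r1", "p1"), weight = 1)
  rx1 <- gen_regulatory_expression(gene_network(nodes, edges), 10,
                                   noise_sd = 0, seed = 15)
  expect_equal(rx1$counts["r1", ], rx1$counts["t1", ])
  expect_equal(rx1$counts["p1", ], rx1$counts["t1", ])
  # ill-tiered (cyclic) edge sets are rejected
  bad <- data.frame(from = c("p1", "t1"), to = c("r1", "r1"), weight = 1)
  expect_error(gene_network(nodes, bad), "tiered|cyclic")
})

test_that("planted two-tier networks satisfy the overlap-rule invariants", {
  net <- plant_two_tier_network(seed = 16)
  e1 <- net$edges[net$edges$step == 1, ]
  e2 <- net$edges[net$edges$step == 2, ]
  # every intermediate drives >= 2 phenotype genes
  expect_true(all(table(e1$from) >= 2))
  # every driving target drives exactly 2 intermediates
  expect_true(all(table(e2$from) == 2))
  # paired intermediates have exactly orthogonal weight vectors, so the
  # simulated intermediate tier is uncorrelated
  rx <- gen_regulatory_expression(net, 4000, noise_sd = 0, seed = 17)
  ims <- net$nodes$gene[net$nodes$role == "intermediate"]
  cc <- cor(t(rx$counts[ims, ]))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.1)
  # the phenotype tier is also mutually uncorrelated (orthogonal pairs)
  phv <- net$nodes$gene[net$nodes$role == "phenotype"]
  cph <- cor(t(rx$counts[phv, ]))
  expect_lt(max(abs(cph[upper.tri(cph)])), 0.1)
})
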