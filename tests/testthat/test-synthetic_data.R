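test_that("simulate_panel is deterministic, bimodal and clade-correlated", {
  a <- simulate_panel(94, tree_seed = 1, trait_seed = 2)
  b <- simulate_panel(94, tree_seed = 1, trait_seed = 2)
  expect_identical(a$panel, b$panel)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  c2 <- simulate_panel(94, tree_seed = 3, trait_seed = 4)
  expect_false(identical(a$panel, c2$panel))

  expect_length(a$panel, 94L)
  expect_true(all(a$panel <= 1))

  # bimodality: both modes populated, valley between them nearly empty
  n_low <- sum(a$panel < 0.3)
  n_high <- sum(a$panel > 0.7)
  expect_gt(n_low, 20)
  expect_gt(n_high, 20)
  expect_lt(sum(a$panel >= 0.3 & a$panel <= 0.7), 5)

  # clade correlation: susceptibility has strong phylogenetic signal, so
  # close relatives are likelier to share a class than random pairs
  d <- patristic_matrix(a$tree)[names(a$panel), names(a$panel)]
  same <- outer(a$panel > 0.5, a$panel > 0.5, "==")
  ut <- upper.tri(d)
  expect_lt(mean(d[ut][same[ut]]), mean(d[ut][!same[ut]]))

  # zero trait variance collapses everything into one class
  flat <- simulate_panel(4, tree_seed = 5, trait_seed = 6, trait_sigma = 0)
  expect_length(unique(flat$truth$class), 1L)
})

test_that("simulate_plate matches its stated marginals and truth", {
  truth <- synthetic_truth()
  p1 <- suppressWarnings(simulate_plate(truth, seed = 9))
  p2 <- suppressWarnings(simulate_plate(truth, seed = 9))
  expect_identical(p1, p2)
  expect_s3_class(p1, "plate_table")
  expect_true(all(p1$od24_raw >= 0))

  # control-OD empirical mean within 3 SE of mu per host
  m <- rbg_matrix(p1)
  for (i in seq_len(nrow(truth$hosts))) {
    h <- truth$hosts$host[i]
    ctrl <- p1$od24_corrected[p1$host == h & p1$phage == "CONTROL"]
    se <- truth$sigma_od / sqrt(length(ctrl))
    expect_lt(abs(mean(ctrl) - truth$hosts$mu_od[i]), 3 * se + 1e-9)
  }

  # limits: v_eff = 1 gives RBG near 1; v_eff = 0 tracks the control
  eff <- data.frame(line = "ECOR34s_1", host = "ECOR34s", delta_v = 0.83)
  t1 <- synthetic_truth(effects = eff)
  plate <- suppressWarnings(simulate_plate(t1, seed = 10))
  m1 <- rbg_matrix(plate)
  expect_equal(as.matrix(m1)["ECOR34s", "ECOR34s_1"], 1, tolerance = 0.05)
  expect_equal(as.matrix(m1)["ECOR9s", "ECOR13s_1"], 0, tolerance = 0.1)

  # true_virulence clamps to [0, 1]
  expect_equal(true_virulence(t1, "ECOR34s_1", "ECOR34s"), 1)
  expect_equal(true_virulence(t1, "BW1", "ECOR9s"), 0)
})

test_that("simulate_titers reflects treatment parameters and extinctions", {
  truth <- synthetic_truth()
  t1 <- simulate_titers(truth, seed = 11)
  expect_identical(t1, simulate_titers(truth, seed = 11))
  # 8 treatments x 3 lines x 3 replicates
  expect_equal(nrow(t1), 72L)
  # extinct treatments emit all-zero rows
  expect_true(all(t1$pfu_per_ml[t1$host %in% c("ECOR36s", "ECOR65s")] == 0))
  expect_true(all(t1$pfu_per_ml[!t1$host %in% c("ECOR36s", "ECOR65s")] > 0))

  # two treatments 2 log-SD apart: ANOVA on line means significant
  set.seed(12)
  sig <- 0
  for (s in 1:40) {
    hosts <- data.frame(host = c("K12s", "A", "B"),
                        class = c("permissive", rep("semi-permissive", 2)),
                        v0 = c(0.767, 0.2, 0.2), mu_od = 0.5, custom = TRUE)
    tt <- synthetic_truth(hosts = hosts, extinct = list(),
                          effects = data.frame(line = character(0),
                                               host = character(0),
                                               delta_v = numeric(0)),
                          titer_log10 = data.frame(
                            host = c("A", "B"),
                            log10_mean = c(8, 8.6), log10_sd = 0.3))
    ti <- simulate_titers(tt, seed = s)
    # power check at the measurement level (3 lines x 3 replicates per host)
    groups <- split(log10(ti$pfu_per_ml), ti$host)
    sig <- sig + (one_way_anova(groups)$p_value < 0.05)
  }
  expect_gte(sig / 40, 0.95)
})

test_that("titer ANOVA holds its size when treatments are identical", {
  set.seed(13)
  rej <- 0
  n_sim <- 200
  for (s in seq_len(n_sim)) {
    groups <- split(rnorm(18), rep(1:6, each = 3))
    rej <- rej + (one_way_anova(groups)$p_value < 0.05)
  }
  expect_lt(abs(rej / n_sim - 0.05), 2 * sqrt(0.05 * 0.95 / n_sim) + 0.01)
})

test_that("simulate_genome plants features and a consistent SNP", {
  g <- simulate_genome(length = 2000,
                       features = data.frame(id = "f", start = 100L,
                                             end = 400L, strand = "+",
                                             type = "ncRNA"),
                       snp_position = 250, seed = 14)
  expect_identical(g$sequence,
                   simulate_genome(2000, data.frame(id = "f", start = 100L,
                                                    end = 400L, strand = "+",
                                                    type = "ncRNA"),
                                   250, seed = 14)$sequence)
  expect_equal(g$variants$ref,
               substring(g$sequence, 250, 250))
  expect_false(g$variants$alt == g$variants$ref)

  # default geometry reproduces the planted locus
  gd <- simulate_genome(seed = 15)
  expect_true(all(c("rnaC_fwd", "rnaD_fwd", "rnaC_rev", "rnaD_rev") %in%
                    gd$features$id))
  expect_equal(gd$variants$position, 164264L)

  expect_error(simulate_genome(2000, data.frame(id = c("f", "f"),
                                                start = c(1L, 10L),
                                                end = c(5L, 20L),
                                                strand = "+", type = "gene"),
                               50, seed = 1),
               "duplicate")
  # minimal bundle
  tiny <- simulate_genome(10, data.frame(id = "f", start = 1L, end = 10L,
                                         strand = "+", type = "gene"),
                          5, seed = 1)
  expect_equal(nchar(tiny$sequence), 10L)
})

test_that("a written fixture study round-trips through the readers", {
  dir <- withr::local_tempdir()
  study <- suppressWarnings(write_fixture_study(dir, seed = 21))
  expect_true(all(file.exists(file.path(dir,
    c("plate.csv", "titers.csv", "tree.nwk", "panel.csv", "genome.fasta",
      "features.gff3", "variants.tsv", "config.json")))))

  plate <- suppressWarnings(read_plate_table(file.path(dir, "plate.csv"),
                                             blank = study$truth$blank))
  expect_equal(plate$od24_corrected, study$plate$od24_corrected,
               tolerance = 1e-9)
  titers <- read_titer_table(file.path(dir, "titers.csv"))
  expect_equal(titers$pfu_per_ml, study$titers$pfu_per_ml, tolerance = 1e-9)
  tree <- read_newick(file.path(dir, "tree.nwk"))
  expect_setequal(tree$tip.label, study$tree$tip.label)
  panel <- read_susceptibility_panel(file.path(dir, "panel.csv"))
  expect_equal(panel, study$panel, tolerance = 1e-9)
  bundle <- read_genome_bundle(file.path(dir, "genome.fasta"),
                               file.path(dir, "features.gff3"),
                               file.path(dir, "variants.tsv"))
  expect_identical(bundle$sequence, study$genome$sequence)
  expect_equal(bundle$features$start, study$genome$features$start)
  cfg <- read_config(file.path(dir, "config.json"))
  expect_equal(cfg$blank, study$truth$blank)
})

test_that("presence series encode the planted extinctions", {
  truth <- synthetic_truth()
  pres <- simulate_presence(truth)
  expect_equal(dim(pres), c(24L, 14L))
  ext <- apply(pres, 1, detect_extinction)
  # treatments with planted extinction after transfer 2
  expect_true(all(ext[paste0("ECOR36s_", 1:3)] == 3L))
  expect_equal(unname(ext[c("ECOR65s_1", "ECOR65s_2")]), c(3L, 3L))
  expect_equal(unname(ext["ECOR65s_3"]), 4L)
  # all surviving lines detected at the final transfer
  expect_true(all(is.na(ext[!(names(ext) %in%
    c(paste0("ECOR36s_", 1:3), paste0("ECOR65s_", 1:3)))])))
})
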