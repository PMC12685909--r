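# Synthetic-data generators emulating the serial-passage host-shift
# experiment: a clade-correlated bimodal susceptibility panel on a random
# tree, plate-reader OD tables with planted virulence effects, lognormal
# final titers with planted extinctions, and a phage genome with planted
# intergenic features and SNP. Ground truth is retained for
# parameter-recovery tests.

#' Ground truth for a synthetic host-shift study
#'
#' Assembles the design of a synthetic evolution experiment. The defaults
#' reproduce the real study's design: 9 assay hosts (1 permissive, 3
#' semi-permissive with intermediate ancestral RBG, 5 non-permissive with
#' ancestral RBG 0), 8 evolution hosts with 3 lines each (24 lines), 14
#' transfers, 6 assay replicates, blank OD 0.045, planted extinctions in two
#' treatments (leaving 18 surviving evolved lines), a strong planted
#' virulence gain (+0.81) for the lines evolved with the semi-permissive
#' host `ECOR34s`, and the observed virulence trade-offs of lines evolved
#' with `ECOR9s`, `ECOR69s` and `ECOR62s`. Host ids carry an `s` suffix as a
#' reminder that they are synthetic stand-ins for the real strains.
#'
#' @param hosts Data frame `host`, `class` (permissive / semi-permissive /
#'   non-permissive), `v0` (true ancestral virulence, equals expected
#'   ancestral RBG), `mu_od` (mean phage-free OD).
#' @param effects Data frame `line`, `host`, `delta_v`: planted per-line
#'   virulence changes on specific assay hosts (0 elsewhere).
#' @param extinct Named list: host -> integer vector of last-detected
#'   transfers for its 3 lines (treatments absent from the list survive).
#' @param sigma_od Additive OD noise SD (default 0.02, matching the
#'   tightness of the reported mean RBG +/- 0.02).
#' @param n_replicates Assay replicates per condition (6 in the main assay,
#'   3 in the collection-wide assay).
#' @param n_transfers Serial-passage transfers (default 14).
#' @param titer_log10 Data frame `host`, `log10_mean`, `log10_sd` of final
#'   titers for surviving treatments.
#' @param blank Sterile-medium OD added back onto simulated wells so that
#'   the reader's blank correction is exercised.
#' @param ancestor Ancestral phage id (default `"BW1"`).
#' @param moi Multiplicity of infection of the assay design (bookkeeping
#'   only; default 10).
#' @return A `synthetic_truth` list.
#' @export
synthetic_truth <- function(hosts = NULL, effects = NULL, extinct = NULL,
                            sigma_od = 0.02, n_replicates = 6L,
                            n_transfers = 14L, titer_log10 = NULL,
                            blank = 0.045, ancestor = "BW1", moi = 10) {
  if (is.null(hosts)) {
    hosts <- data.frame(
      host = c("K12s", "ECOR34s", "ECOR36s", "ECOR62s",
               "ECOR9s", "ECOR13s", "ECOR15s", "ECOR65s", "ECOR69s"),
      class = c("permissive", "semi-permissive", "semi-permissive",
                "semi-permissive", rep("non-permissive", 5)),
      v0 = c(0.767, 0.17, 0.544, 0.434, 0, 0, 0, 0, 0),
      mu_od = 0.5,
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(hosts$v0 <= 1), all(hosts$mu_od > 0))
  evo_hosts <- hosts$host[hosts$class != "permissive"]
  lines <- data.frame(
    line = paste0(rep(evo_hosts, each = 3L), "_", 1:3),
    host_during_evolution = rep(evo_hosts, each = 3L),
    stringsAsFactors = FALSE
  )
  if (is.null(extinct)) {
    extinct <- list()
    if ("ECOR36s" %in% evo_hosts) extinct$ECOR36s <- c(2L, 2L, 2L)
    if ("ECOR65s" %in% evo_hosts) extinct$ECOR65s <- c(2L, 2L, 3L)
  }
  lines$last_detected <- n_transfers
  for (h in names(extinct)) {
    idx <- which(lines$host_during_evolution == h)
    lines$last_detected[idx] <- as.integer(extinct[[h]])
  }
  lines$extinct <- lines$last_detected < n_transfers
  if (is.null(effects)) {
    effects <- rbind(
      data.frame(line = paste0("ECOR34s_", 1:3), host = "ECOR34s",
                 delta_v = 0.81),
      data.frame(line = paste0("ECOR9s_", 1:2), host = "ECOR36s",
                 delta_v = 0.211 - 0.544),
      data.frame(line = paste0("ECOR9s_", 1:2), host = "ECOR62s",
                 delta_v = 0.137 - 0.434),
      data.frame(line = paste0("ECOR9s_", 1:2), host = "K12s",
                 delta_v = 0.303 - 0.767),
      data.frame(line = paste0("ECOR69s_", 1:2), host = "ECOR36s",
                 delta_v = 0.008 - 0.544),
      data.frame(line = paste0("ECOR69s_", 1:2), host = "ECOR62s",
                 delta_v = 0.101 - 0.434),
      data.frame(line = paste0("ECOR69s_", 1:2), host = "K12s",
                 delta_v = 0.379 - 0.767),
      data.frame(line = paste0("ECOR62s_", 1:2), host = "ECOR36s",
                 delta_v = 0.867 - 0.544)
    )
    effects <- effects[effects$line %in% lines$line &
                         effects$host %in% hosts$host, , drop = FALSE]
  }
  if (is.null(titer_log10)) {
    defaults <- c(ECOR13s = 9.5, ECOR15s = 9.3, ECOR34s = 8.5,
                  ECOR9s = 7.5, ECOR62s = 7.7, ECOR69s = 7.3)
    surv <- unique(lines$host_during_evolution[!lines$extinct])
    titer_log10 <- data.frame(
      host = surv,
      log10_mean = ifelse(surv %in% names(defaults), defaults[surv], 8.5),
      log10_sd = 0.15,
      stringsAsFactors = FALSE
    )
  }
  stopifnot(sigma_od > 0)
  structure(
    list(hosts = hosts, lines = lines, effects = effects,
         sigma_od = sigma_od, n_replicates = as.integer(n_replicates),
         n_transfers = as.integer(n_transfers), titer_log10 = titer_log10,
         blank = blank, ancestor = ancestor, moi = moi),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "synthetic_truth: %d hosts, %d lines (%d extinct), %d transfers, %d replicates\n",
    nrow(x$hosts), nrow(x$lines), sum(x$lines$extinct), x$n_transfers,
    x$n_replicates))
  invisible(x)
}

#' True effective virulence of a phage on a host
#'
#' `clamp(v0 + delta_v, 0, 1)`: the ancestral virulence of the host plus any
#' planted per-line effect, clamped to the unit interval. For the ancestor,
#' `delta_v = 0`.
#'
#' @param truth A `synthetic_truth`.
#' @param phage Line id or the ancestor id.
#' @param host Assay host id.
#' @return The true effective virulence (expected RBG).
#' @export
true_virulence <- function(truth, phage, host) {
  v0 <- truth$hosts$v0[truth$hosts$host == host]
  if (!length(v0)) stop("unknown host '", host, "'")
  dv <- 0
  if (phage != truth$ancestor) {
    hit <- truth$effects$line == phage & truth$effects$host == host
    if (any(hit)) dv <- sum(truth$effects$delta_v[hit])
  }
  min(max(v0 + dv, 0), 1)
}

#' Simulate a clade-correlated bimodal susceptibility panel
#'
#' Draws a Yule (pure-birth) tree, evolves a continuous trait on it by
#' Brownian motion, and thresholds the trait at its median to split the
#' strains into a low-susceptibility class (RBG near 0) and a
#' high-susceptibility class (RBG near 0.9). Because the trait is heritable
#' on the tree, susceptibility is clade-correlated, and the resulting RBG
#' histogram is bimodal — the structure observed for the real isolate panel.
#'
#' @param n_strains Number of panel strains (>= 4; the real panel had 94).
#' @param tree_seed,trait_seed Seeds for the tree and the trait.
#' @param extra_taxa Optional ids of additional strains (e.g. the
#'   experimental hosts) grown on the same tree but excluded from the panel.
#' @param trait_sigma Brownian-motion rate; 0 collapses all strains into a
#'   single class.
#' @param high_mean,low_mean,high_sd,low_sd Class-conditional RBG
#'   distributions (defaults: modes near 0.9 and 0.05).
#' @return A list: `tree` ([ape::phylo] over panel + extra taxa), `panel`
#'   (named RBG vector over the panel strains), `truth` (classes, trait,
#'   threshold, seeds).
#' @export
simulate_panel <- function(n_strains = 94L, tree_seed = 1L, trait_seed = 2L,
                           extra_taxa = character(0), trait_sigma = 1,
                           high_mean = 0.9, low_mean = 0.05,
                           high_sd = 0.05, low_sd = 0.04) {
  if (n_strains < 4L) stop("n_strains must be >= 4")
  n_total <- n_strains + length(extra_taxa)
  set.seed(tree_seed)
  tree <- ape::rphylo(n_total, birth = 1, death = 0)
  panel_ids <- sprintf("S%03d", seq_len(n_strains))
  tree$tip.label <- c(panel_ids, extra_taxa)
  set.seed(trait_seed)
  trait <- if (trait_sigma > 0)
    ape::rTraitCont(tree, model = "BM", sigma = trait_sigma)
  else stats::setNames(rep(0, n_total), tree$tip.label)
  threshold <- stats::median(trait)
  high <- trait > threshold
  rbg <- numeric(n_total)
  rbg[high] <- stats::rnorm(sum(high), high_mean, high_sd)
  rbg[!high] <- stats::rnorm(sum(!high), low_mean, low_sd)
  rbg <- pmin(rbg, 1)
  names(rbg) <- tree$tip.label
  list(tree = tree,
       panel = rbg[panel_ids],
       truth = list(class = ifelse(high, "high", "low"),
                    trait = trait, threshold = threshold,
                    rbg_all = rbg,
                    tree_seed = tree_seed, trait_seed = trait_seed))
}

#' Simulate a cross-infection plate table
#'
#' Generates blank-uncorrected OD wells for every host: `n_replicates`
#' phage-free controls with OD ~ Normal(mu_host, sigma) truncated at 0, and
#' for the ancestor plus every surviving evolved line, with-phage wells
#' `OD = control_draw * (1 - v_eff) + Normal(0, sigma)` where `v_eff` is the
#' true effective virulence of that phage on that host. The blank offset is
#' added to every well, so [as_plate_table()]'s correction is exercised; the
#' expected RBG of a cell equals its true virulence by construction.
#'
#' @param truth A `synthetic_truth`.
#' @param seed Integer seed.
#' @return A `plate_table`.
#' @export
simulate_plate <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(seed)
  n <- truth$n_replicates
  phages <- c(truth$ancestor, truth$lines$line[!truth$lines$extinct])
  rows <- list()
  for (i in seq_len(nrow(truth$hosts))) {
    h <- truth$hosts$host[i]
    mu <- truth$hosts$mu_od[i]
    ctrl <- pmax(stats::rnorm(n, mu, truth$sigma_od), 0)
    rows[[length(rows) + 1L]] <- data.frame(
      host = h, phage = CONTROL_SENTINEL, replicate = seq_len(n),
      od24 = ctrl + truth$blank, stringsAsFactors = FALSE)
    for (p in phages) {
      v <- true_virulence(truth, p, h)
      base <- pmax(stats::rnorm(n, mu, truth$sigma_od), 0)
      od <- base * (1 - v) + stats::rnorm(n, 0, truth$sigma_od)
      od <- pmax(od, -truth$blank)          # raw OD must be >= 0
      rows[[length(rows) + 1L]] <- data.frame(
        host = h, phage = p, replicate = seq_len(n),
        od24 = od + truth$blank, stringsAsFactors = FALSE)
    }
  }
  as_plate_table(do.call(rbind, rows), blank = truth$blank)
}

#' Simulate final-transfer titers
#'
#' Lognormal titers for every line of every evolution-host treatment (3
#' replicate measurements per line): `titer = 10^Normal(log10_mean,
#' log10_sd)` with treatment-specific parameters. Extinct lines emit titer 0.
#'
#' @param truth A `synthetic_truth`.
#' @param seed Integer seed.
#' @param n_assay_replicates Replicate titer measurements per line
#'   (default 3).
#' @return A titer data frame: `line`, `host`, `replicate`, `pfu_per_ml`.
#' @export
simulate_titers <- function(truth, seed = 1L, n_assay_replicates = 3L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(seed)
  out <- list()
  for (i in seq_len(nrow(truth$lines))) {
    ln <- truth$lines[i, ]
    if (ln$extinct) {
      titer <- rep(0, n_assay_replicates)
    } else {
      par <- truth$titer_log10[truth$titer_log10$host ==
                                 ln$host_during_evolution, ]
      if (!nrow(par)) stop("no titer parameters for host ",
                           ln$host_during_evolution)
      titer <- 10^stats::rnorm(n_assay_replicates, par$log10_mean,
                               par$log10_sd)
    }
    out[[i]] <- data.frame(line = ln$line,
                           host = ln$host_during_evolution,
                           replicate = seq_len(n_assay_replicates),
                           pfu_per_ml = titer, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Per-transfer presence series of every line
#'
#' Deterministic spot-assay detection record implied by the truth: a line is
#' detected at every transfer up to its last-detected transfer.
#'
#' @param truth A `synthetic_truth`.
#' @return A logical matrix, lines x transfers.
#' @export
simulate_presence <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  m <- outer(truth$lines$last_detected, seq_len(truth$n_transfers), ">=")
  dimnames(m) <- list(truth$lines$line,
                      paste0("T", seq_len(truth$n_transfers)))
  m
}

#' Default two-layout annotation of the planted ncRNA locus
#'
#' Feature table for the planted noncoding locus of the synthetic phage
#' genome, mirroring the geometry of the rnaC/rnaD cluster: the locus spans
#' 164080-164335 with an ~138 bp element and an ~118 bp element. Because the
#' published coordinate account is ambiguous about orientation, both layouts
#' are provided: `forward` places rnaC at 164080-164217 and rnaD at
#' 164218-164335 on the plus strand; `reverse` transcribes the locus on the
#' minus strand with rnaC upstream in transcription order (164198-164335)
#' and rnaD downstream (164080-164197).
#'
#' @param layout `"forward"`, `"reverse"` or `"both"`.
#' @return A feature data frame (id, start, end, strand, type).
#' @export
phage_fixture_features <- function(layout = c("both", "forward", "reverse")) {
  layout <- match.arg(layout)
  fwd <- data.frame(
    id = c("rnaC_fwd", "rnaD_fwd"),
    start = c(164080L, 164218L), end = c(164217L, 164335L),
    strand = "+", type = "ncRNA", stringsAsFactors = FALSE)
  rev <- data.frame(
    id = c("rnaD_rev", "rnaC_rev"),
    start = c(164080L, 164198L), end = c(164197L, 164335L),
    strand = "-", type = "ncRNA", stringsAsFactors = FALSE)
  switch(layout, forward = fwd, reverse = rev, both = rbind(fwd, rev))
}

#' Simulate a phage genome bundle with planted features and SNP
#'
#' Uniform-random DNA of the requested length, the supplied features, and a
#' single SNP whose reference base matches the generated sequence and whose
#' alternate base is drawn uniformly from the other three bases.
#'
#' @param length Genome length in bp.
#' @param features Feature data frame (id, start, end, strand, type);
#'   defaults to [phage_fixture_features()] in both layouts.
#' @param snp_position Planted SNP position (default 164264).
#' @param seed Integer seed.
#' @return A `genome_bundle`.
#' @export
simulate_genome <- function(length = 170000L,
                            features = phage_fixture_features("both"),
                            snp_position = 164264L, seed = 1L) {
  length <- as.integer(length)
  if (anyDuplicated(features$id))
    stop("validation error: duplicate feature ids")
  if (any(features$end > length) || snp_position > length)
    stop("features and SNP must lie within [1, length]")
  set.seed(seed)
  seq <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
               collapse = "")
  ref <- substring(seq, snp_position, snp_position)
  alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
  variants <- data.frame(position = as.integer(snp_position),
                         ref = ref, alt = alt, stringsAsFactors = FALSE)
  new_genome_bundle(seq, features, variants)
}

#' Simulate a complete synthetic study
#'
#' One call producing every input of the three analyses, all derived
#' deterministically from a single seed: truth, plate table, titer table,
#' presence matrix, strain tree + susceptibility panel (with the
#' experimental hosts grafted onto the panel tree), and the genome bundle.
#'
#' @param seed Integer master seed; sub-seeds are derived from it.
#' @param truth Optional `synthetic_truth` (defaults to the full design).
#' @param n_panel Panel size (default 94).
#' @param genome_length Genome length for the variant fixture (default
#'   170 kb, long enough to hold the planted locus).
#' @return A list of class `synthetic_study`: `truth`, `plate`, `titers`,
#'   `presence`, `tree`, `panel`, `genome`, `seed`.
#' @export
simulate_study <- function(seed = 1L, truth = synthetic_truth(),
                           n_panel = 94L, genome_length = 170000L) {
  seed <- as.integer(seed)
  pan <- simulate_panel(n_panel, tree_seed = seed * 7L + 1L,
                        trait_seed = seed * 7L + 2L,
                        extra_taxa = truth$hosts$host)
  structure(list(
    truth = truth,
    plate = simulate_plate(truth, seed = seed * 7L + 3L),
    titers = simulate_titers(truth, seed = seed * 7L + 4L),
    presence = simulate_presence(truth),
    tree = pan$tree,
    panel = pan$panel,
    panel_truth = pan$truth,
    genome = simulate_genome(genome_length, seed = seed * 7L + 5L),
    seed = seed
  ), class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("synthetic_study (seed ", x$seed, ")\n", sep = "")
  print(x$truth)
  cat(sprintf("  plate: %d wells; titers: %d rows; panel: %d strains; genome: %d bp\n",
              nrow(x$plate), nrow(x$titers), length(x$panel),
              nchar(x$genome$sequence)))
  invisible(x)
}

#' Write a complete synthetic study to disk
#'
#' Materialises [simulate_study()] in the exact file dialects the readers
#' consume: `plate.csv`, `titers.csv`, `tree.nwk`, `panel.csv`,
#' `genome.fasta`, `features.gff3`, `variants.tsv` and `config.json`.
#'
#' @param dir Output directory (created if missing).
#' @param seed Integer master seed.
#' @param ... Passed to [simulate_study()].
#' @return Invisibly, the `synthetic_study` that was written.
#' @export
write_fixture_study <- function(dir, seed = 1L, ...) {
  study <- simulate_study(seed = seed, ...)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  plate_raw <- data.frame(host = study$plate$host, phage = study$plate$phage,
                          replicate = study$plate$replicate,
                          od24 = study$plate$od24_raw)
  write_results(plate_raw, file.path(dir, "plate.csv"))
  write_results(study$titers, file.path(dir, "titers.csv"))
  ape::write.tree(study$tree, file.path(dir, "tree.nwk"))
  write_results(data.frame(strain = names(study$panel), rbg = study$panel),
                file.path(dir, "panel.csv"))
  seqs <- Biostrings::DNAStringSet(study$genome$sequence)
  names(seqs) <- "synthetic_phage"
  Biostrings::writeXStringSet(seqs, file.path(dir, "genome.fasta"))
  f <- study$genome$features
  gff <- c("##gff-version 3",
           sprintf("synthetic_phage\thostshift\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                   f$type, f$start, f$end, f$strand, f$id))
  writeLines(gff, file.path(dir, "features.gff3"))
  v <- study$genome$variants
  writeLines(c("position\tref\talt",
               sprintf("%d\t%s\t%s", v$position, v$ref, v$alt)),
             file.path(dir, "variants.tsv"))
  cfg <- pipeline_config(blank = study$truth$blank, alpha = 0.05,
                         ancestor = study$truth$ancestor, seed = seed)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(study)
}
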