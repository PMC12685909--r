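# Orchestration of the three analyses: virulence (RBG matrix, change
# classification, titer ANOVA/Tukey, extinction summary), host range
# (native-range distances over cutoffs + gain-vs-distance regression) and
# variant context (window, overlaps, transcript offsets, conservation).

#' Run the virulence analysis
#'
#' From a plate table (and optionally a titer table and presence matrix),
#' computes the cross-infection RBG matrix, classifies per-line virulence
#' changes against the ancestor with Welch tests and per-host Holm
#' correction, runs the one-way ANOVA + Tukey HSD on final titers of
#' surviving treatments (unit of analysis: the mean of each line's replicate
#' titer measurements, giving df (k-1, 2k) for k treatments of 3 lines), and
#' summarises extinctions.
#'
#' @param plate A `plate_table`.
#' @param ancestor Ancestral phage id (must be present in the plate).
#' @param titers Optional titer data frame (`line`, `host`, `replicate`,
#'   `pfu_per_ml`).
#' @param presence Optional logical matrix lines x transfers of spot-assay
#'   detections.
#' @param alpha Significance level.
#' @param log10_titers Log10-transform line-mean titers before the ANOVA
#'   (default `FALSE`; the choice is recorded in the result).
#' @return A `virulence_analysis` list: `rbg`, `changes`, `titer_anova`,
#'   `titer_tukey`, `extinction`, `alpha`.
#' @export
run_virulence_analysis <- function(plate, ancestor, titers = NULL,
                                   presence = NULL, alpha = 0.05,
                                   log10_titers = FALSE) {
  if (!inherits(plate, "plate_table"))
    stop("virulence stage: 'plate' must be a plate_table")
  if (!ancestor %in% plate$phage)
    stop("configuration error: ancestor '", ancestor,
         "' not found in the plate table")
  rbg <- rbg_matrix(plate)
  changes <- classify_changes(rbg, ancestral_id = ancestor, alpha = alpha)
  titer_anova <- NULL
  titer_tukey <- NULL
  if (!is.null(titers)) {
    line_means <- stats::aggregate(pfu_per_ml ~ line + host, data = titers,
                                   FUN = mean)
    surviving <- line_means[line_means$pfu_per_ml > 0, , drop = FALSE]
    groups <- split(surviving$pfu_per_ml, surviving$host)
    groups <- groups[vapply(groups, length, 1L) >= 2L]
    if (length(groups) >= 2L) {
      if (log10_titers) groups <- lapply(groups, log10)
      titer_anova <- one_way_anova(groups)
      titer_anova$log10_transformed <- log10_titers
      titer_tukey <- tukey_hsd(groups)
    }
  }
  extinction <- NULL
  if (!is.null(presence)) {
    extinction <- data.frame(
      line = rownames(presence),
      extinction_transfer = apply(presence, 1, detect_extinction),
      stringsAsFactors = FALSE)
    extinction$extinct <- !is.na(extinction$extinction_transfer)
  }
  structure(list(rbg = rbg, changes = changes, titer_anova = titer_anova,
                 titer_tukey = titer_tukey, extinction = extinction,
                 alpha = alpha, ancestor = ancestor),
            class = "virulence_analysis")
}

#' @export
print.virulence_analysis <- function(x, ...) {
  cat("== Virulence analysis ==\n")
  print(x$rbg)
  n_sig <- sum(x$changes$label != "NO_CHANGE")
  cat(sprintf("%d of %d comparisons significant at alpha = %g (Holm per host)\n",
              n_sig, nrow(x$changes), x$alpha))
  sig <- x$changes[x$changes$label != "NO_CHANGE", , drop = FALSE]
  if (nrow(sig)) print.data.frame(sig, digits = 3)
  if (!is.null(x$titer_anova)) {
    cat("Final-titer ANOVA (line means by evolution host):\n  ")
    print(x$titer_anova)
  }
  if (!is.null(x$extinction)) {
    cat(sprintf("Extinct lines: %d of %d\n", sum(x$extinction$extinct),
                nrow(x$extinction)))
  }
  invisible(x)
}

#' Run the host-range analysis
#'
#' Computes the native-host-range distance profile of the focal strains over
#' a grid of RBG cutoffs, flags the strain with the maximal distance at the
#' primary cutoff, and regresses per-host mean virulence gain on distance.
#'
#' @param tree An [ape::phylo] over panel strains and focal strains.
#' @param panel Named ancestral-RBG vector of the panel strains.
#' @param gains Named vector: focal strain -> mean virulence gain of the
#'   lines evolved with it.
#' @param cutoffs RBG cutoffs (default c(0.3, 0.5, 0.7, 0.9)).
#' @param primary_cutoff Cutoff used for the regression and the
#'   maximal-distance flag (default 0.5).
#' @return A `hostrange_analysis` list: `profile`, `regression`,
#'   `distances` (at the primary cutoff), `max_distance_strain`.
#' @export
run_hostrange_analysis <- function(tree, panel, gains,
                                   cutoffs = c(0.3, 0.5, 0.7, 0.9),
                                   primary_cutoff = 0.5) {
  strains <- names(gains)
  if (is.null(strains)) stop("'gains' must be named by strain")
  profile <- cutoff_sensitivity(tree, panel, strains, cutoffs)
  dmat <- patristic_matrix(tree)
  distances <- vapply(strains, function(s)
    native_range_distance(tree, panel, s, primary_cutoff, dist = dmat), 1)
  regression <- gain_vs_distance(gains, distances)
  structure(list(profile = profile, regression = regression,
                 distances = distances,
                 max_distance_strain = strains[which.max(distances)],
                 primary_cutoff = primary_cutoff),
            class = "hostrange_analysis")
}

#' @export
print.hostrange_analysis <- function(x, ...) {
  cat("== Host-range analysis ==\n")
  cat(sprintf("Maximal native-range distance (cutoff %g): %s (%.4g)\n",
              x$primary_cutoff, x$max_distance_strain,
              max(x$distances)))
  cat("Virulence gain ~ native-range distance:\n")
  print(x$regression)
  invisible(x)
}

#' Run the variant context report
#'
#' For every variant of a genome bundle: the context window, the overlapping
#' features (with strand-aware transcript offsets and 5'/3'-half tags) or,
#' when intergenic, the flanking features with signed distances; plus
#' percent identity for any supplied pre-aligned sequence pairs.
#'
#' @param bundle A `genome_bundle`.
#' @param window Window width in bp (default 1000).
#' @param alignments Optional named list of `list(a =, b =)` aligned
#'   sequence pairs to report conservation for.
#' @return A `variant_report` list: `variants` (one entry per variant, each
#'   with `position`, `ref`, `alt`, `window`, `overlapping`, `hits`,
#'   `upstream`, `downstream`) and `identity` (named percent vector).
#' @export
run_variant_report <- function(bundle, window = 1000L, alignments = NULL) {
  stopifnot(inherits(bundle, "genome_bundle"))
  entries <- lapply(seq_len(nrow(bundle$variants)), function(i) {
    v <- bundle$variants[i, ]
    ov <- overlapping_features(bundle, v$position)
    hits <- lapply(seq_len(nrow(ov$overlapping)), function(j)
      transcript_position(ov$overlapping[j, ], v$position))
    list(position = v$position, ref = v$ref, alt = v$alt,
         window = extract_window(bundle, v$position, window),
         overlapping = ov$overlapping, hits = hits,
         upstream = ov$upstream, downstream = ov$downstream,
         intergenic = nrow(ov$overlapping) == 0L)
  })
  identity <- NULL
  if (!is.null(alignments)) {
    identity <- vapply(alignments, function(p)
      percent_identity(p$a, p$b), 1)
  }
  structure(list(variants = entries, identity = identity,
                 window_width = as.integer(window)),
            class = "variant_report")
}

#' @export
print.variant_report <- function(x, ...) {
  cat("== Variant context report ==\n")
  for (v in x$variants) {
    cat(sprintf("SNP %d %s>%s | window [%d, %d]%s | %s\n",
                v$position, v$ref, v$alt, v$window$start, v$window$end,
                if (v$window$truncated) " (truncated)" else "",
                if (v$intergenic) "intergenic" else
                  paste0(nrow(v$overlapping), " overlapping feature(s)")))
    for (h in v$hits)
      cat(sprintf("  %s (%s): transcript position %d of %d (%s)\n",
                  h$feature_id, h$strand, h$transcript_position,
                  h$feature_length, h$region_tag))
    if (v$intergenic) {
      if (!is.null(v$upstream$feature))
        cat(sprintf("  upstream: %s (distance %d)\n",
                    v$upstream$feature$id, v$upstream$distance))
      if (!is.null(v$downstream$feature))
        cat(sprintf("  downstream: %s (distance %+d)\n",
                    v$downstream$feature$id, v$downstream$distance))
    }
  }
  if (!is.null(x$identity))
    for (nm in names(x$identity))
      cat(sprintf("conservation %s: %.1f%%\n", nm, x$identity[nm]))
  invisible(x)
}

#' Run the full synthetic study end to end
#'
#' Convenience wrapper: simulates a complete study at the given seed and
#' runs all three analyses on it.
#'
#' @param seed Integer master seed.
#' @param alpha Significance level.
#' @param ... Passed to [simulate_study()].
#' @return A list: `study`, `virulence`, `hostrange`, `variant`.
#' @export
run_synthetic_study <- function(seed = 1L, alpha = 0.05, ...) {
  study <- simulate_study(seed = seed, ...)
  vir <- suppressWarnings(run_virulence_analysis(
    study$plate, ancestor = study$truth$ancestor, titers = study$titers,
    presence = study$presence, alpha = alpha))
  gains <- per_host_gain(vir$changes, study$truth)
  hr <- run_hostrange_analysis(study$tree, study$panel, gains)
  vr <- run_variant_report(study$genome)
  list(study = study, virulence = vir, hostrange = hr, variant = vr)
}

#' Mean virulence gain of each evolution-host treatment on its own host
#'
#' Averages, for each evolution host, the virulence gains of the lines
#' evolved with that host measured on that same host — the quantity
#' regressed against native-range distance. Hosts whose lines were all
#' extinct are dropped unless `include_extinct` is `TRUE` (extinct
#' treatments have no assayed lines either way).
#'
#' @param changes A `change_labels` data frame.
#' @param truth A `synthetic_truth` providing the line -> evolution-host map
#'   (or any data frame `lines` with `line`, `host_during_evolution`).
#' @param include_extinct Kept for symmetry; extinct lines are absent from
#'   plate data, so treatments with no surviving line yield no entry.
#' @return Named numeric vector: evolution host -> mean own-host gain.
#' @export
per_host_gain <- function(changes, truth, include_extinct = FALSE) {
  lines <- if (inherits(truth, "synthetic_truth")) truth$lines else truth
  idx <- match(changes$phage, lines$line)
  own <- !is.na(idx) &
    changes$host == lines$host_during_evolution[idx]
  own_rows <- changes[own, , drop = FALSE]
  if (!nrow(own_rows)) return(stats::setNames(numeric(0), character(0)))
  agg <- stats::aggregate(gain ~ host, data = own_rows, FUN = mean)
  stats::setNames(agg$gain, agg$host)
}
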