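# The central virulence statistic: reduction in bacterial growth (RBG),
# cross-infection RBG matrices, virulence gain, significance classification
# of evolved lines against the ancestor, and extinction bookkeeping.

#' Reduction in bacterial growth (RBG)
#'
#' The virulence measure: `RBG = 1 - OD24h(with phage) / mean(OD24h without
#' phage)`, computed on blank-corrected optical densities. RBG is 1 when the
#' phage suppresses growth completely, 0 when growth matches the phage-free
#' control, and can be negative when the culture grows beyond the control.
#'
#' @param od_with_phage Corrected OD of one or more wells exposed to phage
#'   (vectorised).
#' @param control_ods Corrected ODs of the phage-free control wells of the
#'   same host; their mean is the denominator shared by all replicates.
#' @return RBG value(s), same length as `od_with_phage`.
#' @export
compute_rbg <- function(od_with_phage, control_ods) {
  od_with_phage <- as.numeric(od_with_phage)
  control_ods <- as.numeric(control_ods)
  if (length(control_ods) == 0L) stop("control_ods must be non-empty")
  if (anyNA(od_with_phage) || anyNA(control_ods))
    stop("missing OD values not allowed")
  m <- mean(control_ods)
  if (m <= 0)
    stop("degenerate control: mean control OD <= 0 ",
         "(dead or blank-dominated control wells)")
  1 - od_with_phage / m
}

#' Cross-infection RBG matrix
#'
#' Computes per-replicate RBG for every (host, phage) pair of a plate table,
#' each against the mean of that host's phage-free control wells (one shared
#' denominator per host), plus cell means.
#'
#' @param plate A `plate_table` from [read_plate_table()] or
#'   [as_plate_table()].
#' @return An `rbg_matrix` object: list with `replicates` (long data frame:
#'   host, phage, replicate, rbg), `means` (host x phage matrix),
#'   `control_mean` (named per-host vector). `as.matrix()` returns the mean
#'   matrix.
#' @export
rbg_matrix <- function(plate) {
  if (!inherits(plate, "plate_table"))
    stop("'plate' must be a plate_table")
  is_ctrl <- plate$phage == CONTROL_SENTINEL
  phage_rows <- plate[!is_ctrl, , drop = FALSE]
  hosts <- unique(plate$host)
  control_mean <- vapply(hosts, function(h) {
    od <- plate$od24_corrected[is_ctrl & plate$host == h]
    if (!length(od)) return(NA_real_)
    mean(od)
  }, 1)
  names(control_mean) <- hosts
  if (nrow(phage_rows)) {
    no_ctrl <- unique(phage_rows$host[is.na(control_mean[phage_rows$host])])
    if (length(no_ctrl))
      stop("missing-control error: no CONTROL wells for host(s) ",
           paste(no_ctrl, collapse = ", "))
    rbg <- vapply(seq_len(nrow(phage_rows)), function(i) {
      h <- phage_rows$host[i]
      compute_rbg(phage_rows$od24_corrected[i],
                  plate$od24_corrected[is_ctrl & plate$host == h])
    }, 1)
    replicates <- data.frame(host = phage_rows$host,
                             phage = phage_rows$phage,
                             replicate = phage_rows$replicate,
                             rbg = rbg, stringsAsFactors = FALSE)
  } else {
    replicates <- data.frame(host = character(0), phage = character(0),
                             replicate = integer(0), rbg = numeric(0),
                             stringsAsFactors = FALSE)
  }
  phages <- unique(replicates$phage)
  means <- matrix(NA_real_, nrow = length(unique(replicates$host)),
                  ncol = length(phages),
                  dimnames = list(unique(replicates$host), phages))
  if (nrow(replicates)) {
    agg <- stats::aggregate(rbg ~ host + phage, data = replicates, FUN = mean)
    means[cbind(agg$host, agg$phage)] <- agg$rbg
  }
  structure(list(replicates = replicates, means = means,
                 control_mean = control_mean),
            class = "rbg_matrix")
}

#' @export
as.matrix.rbg_matrix <- function(x, ...) x$means

#' @export
print.rbg_matrix <- function(x, ...) {
  cat(sprintf("rbg_matrix: %d host(s) x %d phage(s), %d replicate values\n",
              nrow(x$means), ncol(x$means), nrow(x$replicates)))
  invisible(x)
}

#' @export
summary.rbg_matrix <- function(object, ...) {
  r <- object$replicates
  if (!nrow(r)) return(data.frame())
  agg_mean <- stats::aggregate(rbg ~ host + phage, data = r, FUN = mean)
  agg_sd <- stats::aggregate(rbg ~ host + phage, data = r, FUN = stats::sd)
  agg_n <- stats::aggregate(rbg ~ host + phage, data = r, FUN = length)
  out <- agg_mean
  names(out)[3] <- "mean_rbg"
  out$sd_rbg <- agg_sd$rbg     # dispersion reported as SD, not SEM
  out$n <- agg_n$rbg
  attr(out, "dispersion") <- "sd"
  out
}

#' Fetch the replicate RBG values of one cell
#'
#' @param x An `rbg_matrix`.
#' @param host,phage Cell identifiers.
#' @return Numeric vector of replicate RBG values (possibly empty).
#' @export
rbg_replicates <- function(x, host, phage) {
  stopifnot(inherits(x, "rbg_matrix"))
  r <- x$replicates
  r$rbg[r$host == host & r$phage == phage]
}

#' Virulence gain
#'
#' Change in virulence of an evolved phage relative to the ancestor on the
#' same host: `mean(evolved RBG) - mean(ancestral RBG)`. Positive values
#' indicate a gain in virulence, negative values a loss.
#'
#' @param evolved Replicate RBG values of the evolved line.
#' @param ancestral Replicate RBG values of the ancestral phage.
#' @return The gain (a single number).
#' @export
virulence_gain <- function(evolved, ancestral) {
  evolved <- as.numeric(evolved); ancestral <- as.numeric(ancestral)
  if (!length(evolved) || !length(ancestral))
    stop("validation error: both samples must be non-empty")
  mean(evolved) - mean(ancestral)
}

#' Classify virulence changes of evolved lines against the ancestor
#'
#' For every host, each evolved phage line is compared to the ancestral
#' phage with a two-sided Welch t-test on the replicate RBG values; within
#' each host the family of p-values is corrected by sequential Bonferroni
#' (Holm) adjustment — the family is all evolved lines tested against the
#' same host's ancestral measurements, never pooled across hosts. A line is
#' labelled `SIGNIFICANT_GAIN` or `SIGNIFICANT_LOSS` when the adjusted
#' p-value is below `alpha`, with the direction given by the sign of the
#' virulence gain; otherwise `NO_CHANGE`.
#'
#' @param matrix An `rbg_matrix` containing the ancestral phage and the
#'   evolved lines.
#' @param ancestral_id Phage id of the ancestor in the matrix.
#' @param alpha Significance level (default 0.05).
#' @return A `change_labels` data frame: `host`, `phage`, `gain`, `p_raw`,
#'   `p_adj`, `label`, `family_size`. Cells where either group has fewer
#'   than 2 replicates are labelled `NO_CHANGE` with `NA` p-values and a
#'   warning.
#' @export
classify_changes <- function(matrix, ancestral_id, alpha = 0.05) {
  stopifnot(inherits(matrix, "rbg_matrix"))
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  r <- matrix$replicates
  if (!ancestral_id %in% r$phage)
    stop("ancestral phage '", ancestral_id, "' not present in the matrix")
  hosts <- unique(r$host)
  rows <- list()
  skipped <- 0L
  for (h in hosts) {
    anc <- r$rbg[r$host == h & r$phage == ancestral_id]
    lines <- setdiff(unique(r$phage[r$host == h]), ancestral_id)
    if (!length(lines)) next
    fam <- data.frame(host = h, phage = lines, gain = NA_real_,
                      p_raw = NA_real_, stringsAsFactors = FALSE)
    for (i in seq_along(lines)) {
      ev <- r$rbg[r$host == h & r$phage == lines[i]]
      fam$gain[i] <- virulence_gain(ev, anc)
      if (length(ev) >= 2L && length(anc) >= 2L) {
        fam$p_raw[i] <- welch_t(ev, anc)$p_value
      } else {
        skipped <- skipped + 1L
      }
    }
    tested <- !is.na(fam$p_raw)
    fam$p_adj <- NA_real_
    fam$p_adj[tested] <- holm_adjust(fam$p_raw[tested])
    fam$label <- "NO_CHANGE"
    sig <- tested & fam$p_adj < alpha
    fam$label[sig & fam$gain > 0] <- "SIGNIFICANT_GAIN"
    fam$label[sig & fam$gain < 0] <- "SIGNIFICANT_LOSS"
    fam$family_size <- sum(tested)
    rows[[h]] <- fam
  }
  if (skipped > 0L)
    warning(skipped, " comparison(s) skipped (fewer than 2 replicates); ",
            "labelled NO_CHANGE")
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(host = character(0), phage = character(0),
                      gain = numeric(0), p_raw = numeric(0),
                      p_adj = numeric(0), label = character(0),
                      family_size = integer(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "adjustment") <- "holm (sequential Bonferroni)"
  attr(out, "ancestor") <- ancestral_id
  class(out) <- c("change_labels", "data.frame")
  out
}

#' @export
print.change_labels <- function(x, ...) {
  cat(sprintf("Virulence change classification vs ancestor '%s' (alpha = %g, %s)\n",
              attr(x, "ancestor"), attr(x, "alpha"), attr(x, "adjustment")))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Plot virulence gains per host
#'
#' Dot-and-arrow display of per-line virulence gains: each point is one
#' evolved line on one host; statistically significant changes are drawn as
#' arrows from zero to the gain, non-significant changes as dots.
#'
#' @param x A `change_labels` data frame.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.change_labels <- function(x, ...) {
  hosts <- unique(x$host)
  xi <- match(x$host, hosts) +
    stats::ave(seq_len(nrow(x)), x$host,
               FUN = function(i) seq_along(i) - (length(i) + 1) / 2) * 0.08
  sig <- x$label != "NO_CHANGE"
  graphics::plot(xi, x$gain, type = "n", xaxt = "n",
                 xlab = "Host during assay", ylab = "Virulence gain (RBG)",
                 ...)
  graphics::axis(1, at = seq_along(hosts), labels = hosts, las = 2,
                 cex.axis = 0.8)
  graphics::abline(h = 0, lty = 3, col = "grey50")
  graphics::points(xi[!sig], x$gain[!sig], pch = 16, col = "black")
  if (any(sig))
    graphics::arrows(xi[sig], 0, xi[sig], x$gain[sig], length = 0.08,
                     col = ifelse(x$gain[sig] > 0, "red", "blue"), lwd = 2)
  invisible(x)
}

#' Detect phage extinction in a presence series
#'
#' Given the per-transfer spot-assay detection record of one phage line
#' (transfers 1..T, `TRUE` = phage detected), returns the extinction
#' transfer: the first transfer from which the phage was never detected
#' again. A line detected at the final transfer is not extinct and yields
#' `NA`.
#'
#' @param detected Logical vector, one element per transfer.
#' @return Integer extinction transfer, or `NA_integer_` if the line
#'   survived to the final transfer.
#' @export
detect_extinction <- function(detected) {
  detected <- as.logical(detected)
  if (!length(detected) || anyNA(detected))
    stop("'detected' must be a non-empty logical vector")
  t_final <- length(detected)
  if (detected[t_final]) return(NA_integer_)
  last_seen <- if (any(detected)) max(which(detected)) else 0L
  as.integer(last_seen + 1L)
}
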