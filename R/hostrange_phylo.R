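# Genetic distance to the native host range: patristic distances on a
# strain phylogeny, susceptibility-thresholded native set, cutoff
# sensitivity, and the virulence-gain versus distance regression.

#' Patristic distance matrix
#'
#' All-pairs patristic distances between the leaves of a phylogeny: the sum
#' of branch lengths along the unique path between two leaves, in expected
#' substitutions per site.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @return A symmetric numeric matrix with zero diagonal, dimnames = leaf
#'   labels.
#' @export
patristic_matrix <- function(tree) {
  validate_phylogeny(tree)
  d <- stats::cophenetic(tree)
  # enforce exact symmetry and a zero diagonal against FP round-off
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

#' Susceptible strain set at an RBG cutoff
#'
#' Strains of an ancestral-susceptibility panel whose RBG is strictly
#' greater than the cutoff. The strict inequality matters at the boundary: a
#' strain with RBG exactly at the cutoff is excluded.
#'
#' @param panel Named numeric vector: strain id -> ancestral RBG.
#' @param cutoff RBG threshold.
#' @return Character vector of strain ids (possibly empty, with a warning).
#' @export
susceptible_set <- function(panel, cutoff) {
  if (!is.numeric(panel) || is.null(names(panel)))
    stop("panel must be a named numeric vector")
  if (!is.finite(cutoff) && !is.infinite(cutoff))
    stop("cutoff must be a number")
  out <- names(panel)[panel > cutoff]
  if (!length(out))
    warning("empty susceptible set at cutoff ", cutoff,
            ": downstream mean distance is undefined")
  out
}

#' Mean genetic distance to the native host range
#'
#' The average patristic distance from a focal strain to every panel strain
#' whose ancestral RBG exceeds the cutoff (the phage's native host range).
#' If the focal strain is itself in the susceptible set it is excluded from
#' its own reference set, since a self-distance of zero would deflate the
#' mean.
#'
#' @param tree An [ape::phylo] containing the focal strain and all panel
#'   strains as leaves.
#' @param panel Named numeric vector of ancestral RBG values.
#' @param strain Focal strain id.
#' @param cutoff RBG cutoff defining the susceptible set (default 0.5).
#' @param dist Optional precomputed [patristic_matrix()] (saves recomputing
#'   it across strains/cutoffs).
#' @return Mean patristic distance (a single number).
#' @export
native_range_distance <- function(tree, panel, strain, cutoff = 0.5,
                                  dist = NULL) {
  if (is.null(dist)) dist <- patristic_matrix(tree)
  if (!strain %in% rownames(dist))
    stop("lookup error: strain '", strain, "' is not a leaf of the tree")
  set <- susceptible_set(panel, cutoff)
  set <- setdiff(set, strain)
  if (!length(set))
    stop("undefined-distance error: susceptible set is empty at cutoff ",
         cutoff)
  absent <- setdiff(set, rownames(dist))
  if (length(absent))
    stop("lookup error: susceptible strain(s) not in the tree: ",
         paste(absent, collapse = ", "))
  mean(dist[strain, set])
}

#' Cutoff sensitivity of native-host-range distances
#'
#' Native-range distance of each focal strain at each RBG cutoff, with the
#' susceptible-set size and the within-cutoff rank of each strain's distance
#' (rank 1 = closest to the native range; ties share the minimum rank).
#' Cells whose susceptible set is empty are returned as `NA` with a warning.
#'
#' @param tree An [ape::phylo].
#' @param panel Named numeric vector of ancestral RBG values.
#' @param strains Focal strain ids.
#' @param cutoffs RBG cutoffs (default the four tested values 0.3, 0.5,
#'   0.7, 0.9).
#' @return A `native_range_profile` data frame: `strain`, `cutoff`,
#'   `set_size`, `mean_distance`, `rank`.
#' @export
cutoff_sensitivity <- function(tree, panel, strains,
                               cutoffs = c(0.3, 0.5, 0.7, 0.9)) {
  if (!length(cutoffs)) stop("cutoffs must be non-empty")
  dmat <- patristic_matrix(tree)
  out <- expand.grid(strain = strains, cutoff = cutoffs,
                     stringsAsFactors = FALSE)
  out$set_size <- NA_integer_
  out$mean_distance <- NA_real_
  for (i in seq_len(nrow(out))) {
    set <- suppressWarnings(susceptible_set(panel, out$cutoff[i]))
    set_i <- setdiff(set, out$strain[i])
    out$set_size[i] <- length(set_i)
    if (length(set_i)) {
      out$mean_distance[i] <- native_range_distance(
        tree, panel, out$strain[i], out$cutoff[i], dist = dmat)
    } else {
      warning("empty susceptible set for strain ", out$strain[i],
              " at cutoff ", out$cutoff[i], "; distance reported as NA")
    }
  }
  out$rank <- stats::ave(out$mean_distance, out$cutoff,
                         FUN = function(v) rank(v, ties.method = "min",
                                                na.last = "keep"))
  class(out) <- c("native_range_profile", "data.frame")
  out
}

#' Virulence gain versus distance to the native host range
#'
#' Simple linear regression of per-host mean virulence gain on the host's
#' genetic distance to the phage's native host range. Tests whether
#' adaptation is more likely for hosts closely related to the strains the
#' phage already infects.
#'
#' @param gains Named numeric vector: strain -> mean virulence gain of the
#'   lines evolved with that strain.
#' @param distances Named numeric vector: strain -> native-range distance.
#'   Names must match `gains` exactly (order-free).
#' @return An `hs_linfit` (see [linear_fit()]) with distance as predictor.
#' @export
gain_vs_distance <- function(gains, distances) {
  if (is.null(names(gains)) || is.null(names(distances)))
    stop("gains and distances must be named by strain")
  if (!setequal(names(gains), names(distances)))
    stop("key-alignment error: gains and distances cover different strains")
  strains <- names(gains)
  linear_fit(distances[strains], gains[strains])
}
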