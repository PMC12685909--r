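# Readers and writers for the external formats the pipeline touches:
# plate-reader OD tables, titer tables, Newick phylogenies, genome bundles
# (FASTA + GFF3 + variants), susceptibility panels and JSON run configs.

CONTROL_SENTINEL <- "CONTROL"

#' Read a plate-reader OD table
#'
#' Parses a long-format CSV of 24 h optical density measurements with columns
#' `host`, `phage`, `replicate`, `od24`, and blank-corrects every well
#' individually by subtracting the sterile-medium OD. Phage-free control
#' wells carry the sentinel phage id `"CONTROL"` (matched case-insensitively
#' and canonicalised).
#'
#' @param path Path to the CSV file.
#' @param blank Sterile-medium OD to subtract from every well. The main
#'   cross-infection assay used 0.045 (the default); the ECOR-collection
#'   assay used 0.0495 — it is a parameter, not a constant.
#' @return A `plate_table`: a data frame with columns `host`, `phage`,
#'   `replicate`, `od24_raw`, `od24_corrected`.
#' @details Corrected ODs may be negative (a well reading below the blank);
#'   they are kept as-is with a warning, because clamping at zero would bias
#'   the RBG statistic towards 1.
#' @seealso [rbg_matrix()] which consumes the corrected values.
#' @export
read_plate_table <- function(path, blank = 0.045) {
  if (!is.numeric(blank) || length(blank) != 1L || blank < 0)
    stop("'blank' must be a single non-negative OD value")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("host", "phage", "replicate", "od24")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("plate table format error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  as_plate_table(df[required], blank = blank)
}

#' Construct and validate a plate table
#'
#' Internal-facing constructor shared by [read_plate_table()] and the
#' synthetic-data generator. Validates uniqueness of
#' (host, phage, replicate), non-negative raw ODs and the presence of
#' control wells for every host that has phage wells.
#'
#' @param df Data frame with columns `host`, `phage`, `replicate`, `od24`.
#' @param blank Blank OD subtracted from every well.
#' @return A `plate_table` data frame.
#' @export
as_plate_table <- function(df, blank = 0.045) {
  df$host <- as.character(df$host)
  df$phage <- as.character(df$phage)
  df$phage[toupper(df$phage) == CONTROL_SENTINEL] <- CONTROL_SENTINEL
  df$replicate <- as.integer(df$replicate)
  df$od24 <- as.numeric(df$od24)
  if (any(is.na(df$replicate)) || any(df$replicate < 1L))
    stop("plate table validation error: replicate must be a positive integer")
  if (anyNA(df$od24) || any(df$od24 < 0))
    stop("plate table validation error: raw OD must be non-negative")
  key <- paste(df$host, df$phage, df$replicate, sep = "\r")
  if (anyDuplicated(key))
    stop("plate table validation error: duplicate (host, phage, replicate) records")
  phage_hosts <- unique(df$host[df$phage != CONTROL_SENTINEL])
  control_hosts <- unique(df$host[df$phage == CONTROL_SENTINEL])
  orphans <- setdiff(phage_hosts, control_hosts)
  if (length(orphans))
    stop("plate table validation error: no CONTROL wells for host(s) ",
         paste(orphans, collapse = ", "))
  out <- data.frame(host = df$host, phage = df$phage,
                    replicate = df$replicate,
                    od24_raw = df$od24,
                    od24_corrected = df$od24 - blank,
                    stringsAsFactors = FALSE)
  n_neg <- sum(out$od24_corrected < 0)
  if (n_neg > 0)
    warning(n_neg, " well(s) read below the blank; negative corrected OD kept")
  attr(out, "blank") <- blank
  class(out) <- c("plate_table", "data.frame")
  out
}

#' Read a final-transfer titer table
#'
#' CSV with columns `line`, `host`, `replicate`, `pfu_per_ml`: the phage
#' titer of each evolved line at the final serial-passage transfer, with the
#' host the line evolved with. A titer of 0 records an extinct line.
#'
#' @param path Path to the CSV file.
#' @return A data frame with columns `line`, `host`, `replicate`,
#'   `pfu_per_ml`.
#' @export
read_titer_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("line", "host", "replicate", "pfu_per_ml")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("titer table format error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  df <- df[required]
  df$pfu_per_ml <- as.numeric(df$pfu_per_ml)
  if (anyNA(df$pfu_per_ml) || any(df$pfu_per_ml < 0))
    stop("titer table validation error: pfu_per_ml must be >= 0")
  df$replicate <- as.integer(df$replicate)
  if (any(is.na(df$replicate)) || any(df$replicate < 1L))
    stop("titer table validation error: replicate must be a positive integer")
  df
}

#' Read a phylogeny from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] that enforces what the downstream
#' patristic-distance computations need: unique leaf labels and finite,
#' non-negative branch lengths on every edge (branch lengths are expected
#' substitutions per site).
#'
#' @param path Path to a Newick file (or a literal Newick string via `text`).
#' @param text Optional Newick string, used instead of `path`.
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tr <- tryCatch(
    if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e),
                             call. = FALSE),
    warning = function(w) stop("Newick parse error: ", conditionMessage(w),
                               call. = FALSE)
  )
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("Newick parse error: no tree could be read")
  validate_phylogeny(tr)
  tr
}

validate_phylogeny <- function(tr) {
  if (is.null(tr$edge.length))
    stop("Newick parse error: branch lengths are required for patristic distances")
  if (length(tr$edge.length) != nrow(tr$edge) ||
      anyNA(tr$edge.length) || any(!is.finite(tr$edge.length)))
    stop("Newick parse error: every edge must carry a finite branch length")
  if (any(tr$edge.length < 0))
    stop("phylogeny validation error: negative branch length")
  if (anyDuplicated(tr$tip.label))
    stop("phylogeny validation error: duplicate leaf labels")
  invisible(tr)
}

#' Read an ancestral-susceptibility panel
#'
#' CSV with columns `strain`, `rbg`: the RBG of the ancestral phage against
#' each strain of a susceptibility panel (e.g. a collection of natural and
#' clinical isolates). Values must be finite and at most 1; negative values
#' (growth above control) are allowed.
#'
#' @param path Path to the CSV file.
#' @return A named numeric vector of RBG values, names are strain ids.
#' @export
read_susceptibility_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("strain", "rbg") %in% names(df)))
    stop("panel format error: need columns strain, rbg")
  if (anyDuplicated(df$strain))
    stop("panel validation error: duplicate strain ids")
  v <- as.numeric(df$rbg)
  if (anyNA(v) || any(!is.finite(v)))
    stop("panel validation error: RBG values must be finite")
  if (any(v > 1))
    stop("panel validation error: RBG cannot exceed 1")
  names(v) <- as.character(df$strain)
  v
}

#' Read a genome bundle (FASTA + GFF3 + variants)
#'
#' Loads a single-contig phage genome, its feature annotation and a variant
#' table, and cross-validates them: features must lie within the sequence
#' and every variant's reference base must match the genome.
#'
#' @param fasta_path Single-sequence FASTA file.
#' @param gff_path GFF3 annotation (1-based inclusive coordinates).
#' @param variant_path Variant table: either a tab/whitespace-separated file
#'   with header columns `position`, `ref`, `alt`, or a VCF 4.x file (the
#'   CHROM/POS/REF/ALT subset is used; multi-allelic records are rejected).
#' @return A `genome_bundle`: list with `sequence` (character string),
#'   `features` (data frame: id, start, end, strand, type) and `variants`
#'   (data frame: position, ref, alt).
#' @export
read_genome_bundle <- function(fasta_path, gff_path, variant_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) != 1L)
    stop("genome FASTA must contain exactly one contig")
  sequence <- as.character(seqs[[1]])
  gr <- rtracklayer::import(gff_path)
  md <- S4Vectors::mcols(gr)
  ids <- if ("ID" %in% names(md)) as.character(md$ID) else rep(NA_character_, length(gr))
  if (anyNA(ids)) {
    fallback <- paste0(as.character(md$type), "_", seq_along(gr))
    ids[is.na(ids)] <- fallback[is.na(ids)]
  }
  features <- data.frame(
    id = ids,
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    type = as.character(md$type),
    stringsAsFactors = FALSE
  )
  variants <- read_variants(variant_path)
  new_genome_bundle(sequence, features, variants)
}

#' Construct and validate a genome bundle from in-memory parts
#'
#' @param sequence DNA string over A, C, G, T, N.
#' @param features Data frame with columns id, start, end, strand, type.
#' @param variants Data frame with columns position, ref, alt (may be empty).
#' @return A `genome_bundle` object.
#' @export
new_genome_bundle <- function(sequence, features, variants) {
  sequence <- toupper(as.character(sequence))
  if (grepl("[^ACGTN]", sequence))
    stop("genome validation error: sequence must be over {A,C,G,T,N}")
  L <- nchar(sequence)
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (any(features$start < 1L) || any(features$end > L) ||
      any(features$start > features$end))
    stop("genome validation error: feature coordinates outside [1, ",
         L, "] or start > end")
  if (!all(features$strand %in% c("+", "-")))
    stop("genome validation error: feature strand must be '+' or '-'")
  if (nrow(variants)) {
    variants$position <- as.integer(variants$position)
    if (any(variants$position < 1L) || any(variants$position > L))
      stop("genome validation error: variant position outside the genome")
    genome_base <- substring(sequence, variants$position, variants$position)
    bad <- toupper(variants$ref) != genome_base
    if (any(bad))
      stop("genome consistency error: variant ref base disagrees with the ",
           "genome at position(s) ",
           paste(variants$position[bad], collapse = ", "))
  }
  structure(list(sequence = sequence, features = features,
                 variants = variants),
            class = "genome_bundle")
}

#' @export
print.genome_bundle <- function(x, ...) {
  cat(sprintf("genome_bundle: %d bp, %d feature(s), %d variant(s)\n",
              nchar(x$sequence), nrow(x$features), nrow(x$variants)))
  invisible(x)
}

#' Read a variant table
#'
#' Accepts the minimal 3-column dialect (header `position`, `ref`, `alt`,
#' tab- or whitespace-separated) or a VCF 4.x file, of which only CHROM /
#' POS / REF / ALT are consumed. Multi-allelic VCF records are rejected.
#'
#' @param path Path to the variant file.
#' @return A data frame with columns `position`, `ref`, `alt`.
#' @export
read_variants <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##fileformat=VCF") || startsWith(first, "#CHROM")) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "##")]
    header_i <- which(startsWith(lines, "#CHROM"))
    if (length(header_i) != 1L) stop("VCF format error: missing #CHROM header")
    header <- strsplit(sub("^#", "", lines[header_i]), "\t")[[1]]
    body <- lines[-seq_len(header_i)]
    if (!length(body))
      return(data.frame(position = integer(0), ref = character(0),
                        alt = character(0), stringsAsFactors = FALSE))
    tab <- utils::read.table(text = body, sep = "\t",
                             col.names = header, stringsAsFactors = FALSE,
                             comment.char = "")
    if (any(grepl(",", tab$ALT, fixed = TRUE)))
      stop("VCF validation error: multi-allelic records are not supported")
    return(data.frame(position = as.integer(tab$POS),
                      ref = toupper(tab$REF), alt = toupper(tab$ALT),
                      stringsAsFactors = FALSE))
  }
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("position", "ref", "alt") %in% names(tab)))
    stop("variant table format error: need columns position, ref, alt")
  if (any(grepl(",", tab$alt, fixed = TRUE)))
    stop("variant validation error: multi-allelic records are not supported")
  data.frame(position = as.integer(tab$position),
             ref = toupper(tab$ref), alt = toupper(tab$alt),
             stringsAsFactors = FALSE)
}

#' Write a pipeline product to disk
#'
#' Serialises any tabular pipeline product as CSV with full numeric
#' precision (15 significant digits), so that writing and re-reading
#' round-trips values. `rbg_matrix` objects are written as a wide host x
#' phage matrix of mean RBG values.
#'
#' @param results A data frame, matrix or `rbg_matrix`.
#' @param path Output file path.
#' @return Invisibly, the path written.
#' @export
write_results <- function(results, path) {
  UseMethod("write_results")
}

#' @export
write_results.default <- function(results, path) {
  df <- as.data.frame(results)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(col) format(col, digits = 15,
                                                  scientific = FALSE,
                                                  trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
write_results.matrix <- function(results, path) {
  df <- as.data.frame(results)
  df <- cbind(data.frame(row = rownames(results), stringsAsFactors = FALSE), df)
  write_results.default(df, path)
}

#' @export
write_results.rbg_matrix <- function(results, path) {
  m <- as.matrix(results)
  hosts <- if (is.null(rownames(m))) character(0) else rownames(m)
  df <- cbind(data.frame(host = hosts, stringsAsFactors = FALSE),
              as.data.frame(m))
  write_results.default(df, path)
}

#' Read a pipeline run configuration (JSON)
#'
#' @param path Path to a JSON file with any of: `blank`, `alpha`, `cutoffs`,
#'   `window`, `ancestor`, `seed`, plus input/output paths.
#' @return A `pipeline_config` list (see [pipeline_config()]).
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, cfg)
}

#' Assemble a validated pipeline configuration
#'
#' @param blank Sterile-medium OD constant (default 0.045).
#' @param alpha Significance level in (0, 1).
#' @param cutoffs RBG cutoffs for the susceptible set.
#' @param window SNP context window width in bp.
#' @param ancestor Ancestral phage id in plate tables.
#' @param seed Integer seed for any stochastic step.
#' @param ... Further named entries (input paths, output directory) kept
#'   verbatim.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(blank = 0.045, alpha = 0.05,
                            cutoffs = c(0.3, 0.5, 0.7, 0.9),
                            window = 1000L, ancestor = "ANCESTOR",
                            seed = 1L, ...) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (blank < 0) stop("blank must be >= 0")
  if (window < 1) stop("window must be >= 1 bp")
  structure(c(list(blank = blank, alpha = alpha, cutoffs = cutoffs,
                   window = as.integer(window), ancestor = ancestor,
                   seed = as.integer(seed)), list(...)),
            class = "pipeline_config")
}
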