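# Plain-text interchange formats: BED-like gene-position tables, anchor
# tables, per-pair Ks tables, peak tables, topology-frequency tables
# (all TSV with header), CDS FASTA, and newick trees. Everything
# round-trips: write(read(x)) preserves content.

read_tsv_checked <- function(path, required, kind) {
  lines <- readLines(path)
  if (length(lines) < 1) stop(kind, " file is empty: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  miss <- setdiff(required, header)
  if (length(miss) > 0) {
    stop(kind, " file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  }
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  bad <- which(nf != length(header))
  if (length(bad) > 0) {
    stop("malformed ", kind, " record at line ", bad[1], " of ", path,
         ": expected ", length(header), " fields, found ", nf[bad[1]])
  }
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write gene-position tables
#'
#' BED-like TSV with columns chrom, rank, strand, gene (0-based gene
#' ranks).
#'
#' @param path File path.
#' @param positions data.frame as returned by
#'   \code{\link{gene_positions}}.
#' @return \code{read_positions}: the data.frame;
#'   \code{write_positions}: the path, invisibly.
#' @export
read_positions <- function(path) {
  read_tsv_checked(path, c("chrom", "rank", "strand", "gene"),
                   "gene-position")
}

#' @rdname read_positions
#' @export
write_positions <- function(positions, path) {
  write_tsv(positions[, c("chrom", "rank", "strand", "gene")], path)
}

#' Read / write anchor-pair tables
#'
#' Three-column TSV: gene_a, gene_b, score.
#'
#' @param path File path.
#' @param anchors data.frame with columns gene_a, gene_b, score.
#' @return \code{read_anchors}: the data.frame; \code{write_anchors}:
#'   the path, invisibly.
#' @export
read_anchors <- function(path) {
  read_tsv_checked(path, c("gene_a", "gene_b", "score"), "anchor")
}

#' @rdname read_anchors
#' @export
write_anchors <- function(anchors, path) {
  write_tsv(anchors[, c("gene_a", "gene_b", "score")], path)
}

#' Read / write a truth log
#'
#' @param path File path.
#' @param truth Truth log data.frame from \code{\link{simulate_history}}.
#' @return \code{read_truth_log}: the data.frame;
#'   \code{write_truth_log}: the path, invisibly.
#' @export
read_truth_log <- function(path) {
  read_tsv_checked(path, c("event_id", "event_type", "time_ma",
                           "gene_a", "gene_b", "expected_ks"),
                   "truth-log")
}

#' @rdname read_truth_log
#' @export
write_truth_log <- function(truth, path) {
  write_tsv(as.data.frame(truth), path)
}

#' Read / write CDS FASTA
#'
#' @param path File path.
#' @param cds Named character vector of sequences.
#' @param width Line-wrap width for writing (default 70).
#' @return \code{read_cds_fasta}: named character vector;
#'   \code{write_cds_fasta}: the path, invisibly.
#' @export
read_cds_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readDNAStringSet(path)
    return(stats::setNames(as.character(x), names(x)))
  }
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a FASTA file: ", path)
  idx <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste, character(1),
                 collapse = "")
  stats::setNames(seqs, sub("^>\\s*(\\S+).*$", "\\1", lines[hdr]))
}

#' @rdname read_cds_fasta
#' @export
write_cds_fasta <- function(cds, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(cds)) {
    writeLines(paste0(">", nm), con)
    s <- cds[[nm]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))),
               con)
  }
  invisible(path)
}

#' Read / write newick trees
#'
#' Thin wrappers over \pkg{ape} preserving branch lengths to 10
#' significant digits.
#'
#' @param path File path.
#' @param tree An \code{ape::phylo}.
#' @return \code{read_newick}: a \code{phylo}; \code{write_newick}: the
#'   path, invisibly.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

#' Read / write per-anchor Ks tables
#'
#' @param path File path.
#' @param ks_table data.frame from \code{\link{anchor_ks_table}}.
#' @return \code{read_ks_table}: the data.frame; \code{write_ks_table}:
#'   the path, invisibly.
#' @export
read_ks_table <- function(path) {
  read_tsv_checked(path, c("block_id", "gene_a", "gene_b", "ks",
                           "saturated"), "Ks")
}

#' @rdname read_ks_table
#' @export
write_ks_table <- function(ks_table, path) {
  write_tsv(ks_table, path)
}

#' Read / write peak tables
#'
#' TSV with columns species_i, species_j, mu, sigma.
#'
#' @param path File path.
#' @param peaks A \code{peak_table}.
#' @return \code{read_peaks}: a \code{peak_table}; \code{write_peaks}:
#'   the path, invisibly.
#' @export
read_peaks <- function(path) {
  d <- read_tsv_checked(path, c("species_i", "species_j", "mu"),
                        "peak-table")
  peak_table(d)
}

#' @rdname read_peaks
#' @export
write_peaks <- function(peaks, path) {
  sp <- do.call(rbind, strsplit(names(peaks), "-", fixed = TRUE))
  write_tsv(data.frame(species_i = sp[, 1], species_j = sp[, 2],
                       mu = vapply(peaks, `[[`, numeric(1), "mu"),
                       sigma = vapply(peaks, `[[`, numeric(1), "sigma")),
            path)
}

#' Read / write topology-frequency tables
#'
#' TSV with columns branch_id, q1, q2, q3, n.
#'
#' @param path File path.
#' @param freqs data.frame with those columns, or a list of
#'   \code{quartet_freqs}.
#' @return \code{read_freqs}: the data.frame; \code{write_freqs}: the
#'   path, invisibly.
#' @export
read_freqs <- function(path) {
  read_tsv_checked(path, c("branch_id", "q1", "q2", "q3", "n"),
                   "topology-frequency")
}

#' @rdname read_freqs
#' @export
write_freqs <- function(freqs, path) {
  if (!is.data.frame(freqs)) {
    freqs <- do.call(rbind, lapply(freqs, function(tf) {
      data.frame(branch_id = tf$branch_id, q1 = tf$freqs[["q1"]],
                 q2 = tf$freqs[["q2"]], q3 = tf$freqs[["q3"]],
                 n = tf$n_quartets)
    }))
  }
  write_tsv(freqs, path)
}

#' Default run configuration
#'
#' Stage parameters with the conventional defaults: KDE bandwidth
#' 0.025, mixture-fit acceptance R^2 0.95, minimum block size 10,
#' maximum chaining gap 25, 20,000 simulated gene trees, calibration
#' interval 115-130 Ma.
#'
#' @param ... Overrides of individual entries.
#' @return Named list of parameters.
#' @export
run_config <- function(...) {
  cfg <- list(bandwidth = 0.025, r2_min = 0.95, min_block = 10,
              max_gap = 25, n_genetrees = 20000, age_low = 115,
              age_high = 130, seed = 1)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) {
    stop("unknown config entries: ", paste(bad, collapse = ", "))
  }
  utils::modifyList(cfg, over)
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose entries override the defaults of
#'   \code{\link{run_config}}.
#' @return Named list of parameters.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read config files")
  }
  do.call(run_config, yaml::read_yaml(path))
}
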