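# Per-anchor Ks estimation over syntenic blocks and the per-block median
# summary used to place each block on the Ks axis.

#' Compute per-anchor Ks for syntenic blocks
#'
#' Runs the Nei-Gojobori / Jukes-Cantor estimator on every anchor pair of
#' every block. Sequences are taken from a combined named CDS vector.
#'
#' @param blocks A \code{syntenic_blocks} object.
#' @param cds Named character vector of coding sequences covering every
#'   anchor gene (for example \code{c(genomeA$cds, genomeB$cds)}).
#' @param ks_max Saturation cap passed to \code{\link{ks_jc}}.
#' @return The blocks, each with \code{ks_values} (numeric, NA when
#'   saturated), \code{saturated} (logical) and \code{median_ks} filled
#'   in by \code{\link{block_median_ks}}. Blocks whose anchors are all
#'   saturated are dropped with a message.
#' @export
blocks_ks <- function(blocks, cds, ks_max = 3) {
  out <- list()
  for (b in blocks) {
    miss <- setdiff(c(b$anchors$gene_a, b$anchors$gene_b), names(cds))
    if (length(miss) > 0) {
      stop("no CDS for gene(s): ", paste(utils::head(miss, 5),
                                         collapse = ", "))
    }
    kv <- mapply(function(ga, gb) {
      k <- ks_pair(cds[[ga]], cds[[gb]], ks_max = ks_max)
      c(ks = if (k$saturated) NA_real_ else k$ks,
        sat = as.numeric(k$saturated))
    }, b$anchors$gene_a, b$anchors$gene_b)
    b$ks_values <- unname(kv["ks", ])
    b$saturated <- unname(kv["sat", ]) > 0
    b <- block_median_ks(b)
    if (is.na(b$median_ks)) {
      message("dropping block ", b$chromosome_a, "~", b$chromosome_b,
              ": all ", length(b$ks_values), " anchor Ks saturated")
      next
    }
    out[[length(out) + 1L]] <- b
  }
  structure(out, class = "syntenic_blocks")
}

#' Median Ks of a syntenic block
#'
#' The block's representative Ks is the median over its unsaturated
#' anchor Ks values; saturated values are excluded and counted.
#'
#' @param block A \code{syntenic_block} with \code{ks_values} set (NA
#'   marks saturated anchors).
#' @param ks_values Optional replacement per-anchor Ks vector.
#' @return The block with \code{median_ks} and \code{n_saturated} set;
#'   \code{median_ks} is NA when every anchor is saturated.
#' @export
block_median_ks <- function(block, ks_values = NULL) {
  if (!is.null(ks_values)) block$ks_values <- ks_values
  if (is.null(block$ks_values)) stop("block has no ks_values")
  ok <- !is.na(block$ks_values)
  block$n_saturated <- sum(!ok)
  block$median_ks <- if (any(ok)) {
    stats::median(block$ks_values[ok])
  } else {
    NA_real_
  }
  block
}

#' Block median Ks values as a vector
#'
#' @param blocks A \code{syntenic_blocks} object processed by
#'   \code{\link{blocks_ks}}.
#' @return Numeric vector of per-block median Ks.
#' @export
block_medians <- function(blocks) {
  vapply(blocks, `[[`, numeric(1), "median_ks")
}

#' Per-anchor Ks table
#'
#' @param blocks A \code{syntenic_blocks} object processed by
#'   \code{\link{blocks_ks}}.
#' @return data.frame: block_id, gene_a, gene_b, ks, saturated.
#' @export
anchor_ks_table <- function(blocks) {
  do.call(rbind, lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    data.frame(block_id = i, gene_a = b$anchors$gene_a,
               gene_b = b$anchors$gene_b, ks = b$ks_values,
               saturated = b$saturated, stringsAsFactors = FALSE)
  }))
}
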