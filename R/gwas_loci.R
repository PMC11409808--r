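#' Locus selection configuration
#'
#' @param p_threshold Genome-wide significance threshold (default 5e-8).
#' @param window_kb Clump window in kilobases around each lead variant
#'   (default 250; inclusive on both ends in base pairs).
#' @return A `loci_config` list.
#' @export
loci_config <- function(p_threshold = 5e-8, window_kb = 250) {
  stopifnot(p_threshold > 0, p_threshold < 1, window_kb > 0)
  structure(list(p_threshold = p_threshold, window_kb = window_kb),
            class = "loci_config")
}

#' Select genomic risk loci by distance clumping
#'
#' Greedy clumping of the association summary statistics: the significant
#' variant with the smallest p-value becomes a lead, all significant
#' variants on the same chromosome within the window are absorbed into its
#' locus, and the procedure repeats on the remainder. P-value ties are
#' broken by position (smaller first). Distance clumping replaces
#' linkage-disequilibrium-based clumping, which a synthetic panel without
#' reference LD cannot support.
#'
#' @param stats A `summary_stats` data frame.
#' @param cfg A `loci_config`.
#' @return Data frame of loci: lead_id, chr, pos, beta, se, p, n_members,
#'   plus a `members` list-column of member variant ids. Zero rows when
#'   nothing is significant.
#' @export
select_loci <- function(stats, cfg = loci_config()) {
  sig <- stats[!is.na(stats$p) & stats$p < cfg$p_threshold, , drop = FALSE]
  sig <- sig[order(sig$chr, sig$pos), , drop = FALSE]
  window <- cfg$window_kb * 1000
  loci <- list()
  while (nrow(sig) > 0) {
    o <- order(sig$p, sig$pos)
    lead <- sig[o[1], , drop = FALSE]
    inwin <- sig$chr == lead$chr & abs(sig$pos - lead$pos) <= window
    members <- sig$variant_id[inwin]
    loci[[length(loci) + 1]] <- data.frame(
      lead_id = lead$variant_id, chr = lead$chr, pos = lead$pos,
      beta = lead$beta, se = lead$se, p = lead$p,
      n_members = sum(inwin))
    loci[[length(loci)]]$members <- list(members)
    sig <- sig[!inwin, , drop = FALSE]
  }
  if (length(loci) == 0) {
    out <- data.frame(lead_id = character(0), chr = integer(0),
                      pos = integer(0), beta = numeric(0), se = numeric(0),
                      p = numeric(0), n_members = integer(0))
    out$members <- list()
    return(out)
  }
  out <- do.call(rbind, loci)
  out[order(out$chr, out$pos), , drop = FALSE]
}
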