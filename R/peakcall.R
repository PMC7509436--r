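# Heterozygote base calling from Sanger-style chromatograph peak tables.
# A position is heterozygous when the secondary peak is a different base and
# its signal exceeds the given fraction of the primary signal (strictly:
# "higher than"); duplicated two-copy amplicons use a laxer threshold
# because a variant present in only one of four gene copies yields a
# proportionally weaker secondary peak.

#' Construct / validate a peak-trace table
#'
#' @param position Strictly increasing integer positions.
#' @param primary_base,secondary_base Base calls (`A`/`C`/`G`/`T`/`N`).
#' @param primary_signal,secondary_signal Non-negative linear intensities
#'   with `primary_signal >= secondary_signal`.
#' @return A `data.frame` of class `peak_trace`.
#' @export
peak_trace <- function(position, primary_base, primary_signal,
                       secondary_base, secondary_signal) {
  tr <- data.frame(position = as.integer(position),
                   primary_base = as.character(primary_base),
                   primary_signal = as.numeric(primary_signal),
                   secondary_base = as.character(secondary_base),
                   secondary_signal = as.numeric(secondary_signal),
                   stringsAsFactors = FALSE)
  if (any(diff(tr$position) <= 0L)) stop("positions must be strictly increasing")
  if (any(tr$primary_signal < 0 | tr$secondary_signal < 0)) {
    stop("negative signal")
  }
  if (any(tr$secondary_signal > tr$primary_signal)) {
    stop("secondary signal exceeds primary signal")
  }
  bases <- c("A", "C", "G", "T", "N")
  if (!all(tr$primary_base %in% bases) || !all(tr$secondary_base %in% bases)) {
    stop("bases must be one of A/C/G/T/N")
  }
  class(tr) <- c("peak_trace", "data.frame")
  tr
}

#' Read a peak-trace TSV
#'
#' Columns: `position`, `primary_base`, `primary_signal`, `secondary_base`,
#' `secondary_signal`; one file per accession x segment.
#'
#' @param path File path.
#' @return A [peak_trace()].
#' @export
read_peak_trace <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  peak_trace(tab$position, tab$primary_base, tab$primary_signal,
             tab$secondary_base, tab$secondary_signal)
}

#' Call a diploid consensus sequence from a peak trace
#'
#' Per position: if the secondary base differs from the primary and the
#' secondary/primary signal ratio is strictly greater than `threshold`, the
#' two-base IUPAC code is emitted; otherwise the primary base. A primary `N`
#' or zero primary signal yields `N`. Ties at exactly the threshold are
#' homozygous ("higher than" is taken literally). Optionally, positions in a
#' quality `mask` are forced to `N`, supporting manual exclusion of
#' poor-quality chromatograph regions.
#'
#' @param trace A [peak_trace()] (or data.frame in the same layout).
#' @param threshold Heterozygote ratio threshold in (0, 1]; use the
#'   segment's `het_ratio_threshold` (0.50 single-copy, 0.30 duplicated).
#' @param mask Optional integer vector of positions to force to `N`.
#' @return A single IUPAC consensus string, one symbol per trace row.
#' @export
call_consensus <- function(trace, threshold, mask = NULL) {
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must lie in (0, 1]")
  if (!inherits(trace, "peak_trace")) {
    trace <- peak_trace(trace$position, trace$primary_base, trace$primary_signal,
                        trace$secondary_base, trace$secondary_signal)
  }
  out <- trace$primary_base
  dead <- trace$primary_base == "N" | trace$primary_signal == 0
  out[dead] <- "N"
  het <- !dead &
    trace$secondary_base != "N" &
    trace$secondary_base != trace$primary_base &
    trace$secondary_signal / trace$primary_signal > threshold
  if (any(het)) {
    out[het] <- iupac_merge(trace$primary_base[het], trace$secondary_base[het])
  }
  if (!is.null(mask)) out[trace$position %in% mask] <- "N"
  paste(out, collapse = "")
}
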