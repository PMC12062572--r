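`%||%` <- function(a, b) if (is.null(a)) b else a

log_msg <- function(...) {
  message(format(Sys.time(), "[%H:%M:%S] "), sprintf(...))
}

#' Parse a region string
#'
#' Accepts `contig:start-end` (1-based inclusive, as on the command line) or a
#' bare contig name, returning 0-based half-open coordinates used internally.
#'
#' @param region Region string.
#' @param contig_lengths Named integer vector of contig lengths (used to
#'   complete bare-contig regions and to bounds-check).
#' @return List with `contig`, `start`, `end` (0-based half-open).
#' @export
parse_region <- function(region, contig_lengths = NULL) {
  m <- regmatches(region, regexec("^([^:]+)(:([0-9,]+)-([0-9,]+))?$", region))[[1]]
  if (length(m) == 0L) stop("cannot parse region: ", region)
  contig <- m[2]
  if (!is.null(contig_lengths) && !contig %in% names(contig_lengths)) {
    stop("contig not found in alignment file: ", contig)
  }
  if (m[3] == "") {
    if (is.null(contig_lengths)) stop("region without coordinates needs contig lengths")
    return(list(contig = contig, start = 0L,
                end = unname(contig_lengths[contig])))
  }
  start1 <- as.integer(gsub(",", "", m[4]))
  end1 <- as.integer(gsub(",", "", m[5]))
  if (start1 < 1L || end1 < start1) stop("invalid region coordinates: ", region)
  out <- list(contig = contig, start = start1 - 1L, end = end1)
  if (!is.null(contig_lengths) && out$end > contig_lengths[contig]) {
    stop("region end beyond contig length: ", region)
  }
  out
}
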